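#' Phantom configuration for synthetic slice images
#'
#' Describes the simulated specimen and scan: an annular tissue wall (a stand-in
#' for a ventricular cross-section) imaged at a fixed voxel size over a series
#' of staining durations. Intensity inside the wall is supplied separately as a
#' depth field (see [saturation_field()] and [render_slice()]).
#'
#' @param outer_radius Outer radius of the annulus in mm.
#' @param wall_thickness Wall thickness in mm; must be smaller than
#'   `outer_radius`.
#' @param voxel_size Voxel edge length in micrometres.
#' @param times Staining durations in hours; strictly increasing, starting at 0.
#' @param background_level Intensity (counts) of the background / sample-holder
#'   region, which is low-contrast compared to stained tissue.
#' @param noise_sd Standard deviation (counts) of additive zero-mean Gaussian
#'   detector noise; 0 gives noiseless images. Default is 1% of the dynamic
#'   range of the default intensity model (see [exact_model_params()]).
#' @param beam_hardening_slope Linear decrease of the intensity ceiling with
#'   depth, counts per mm (>= 0). Emulates the beam-hardening artifact that
#'   makes the ceiling highest at the outer surface.
#' @param seed Integer master seed; per-timepoint noise streams are derived
#'   from it by fixed offsets, so adding a timepoint never changes earlier
#'   images.
#'
#' @return An object of class `phantom_config`.
#' @export
#' @examples
#' cfg <- phantom_config(voxel_size = 44, noise_sd = 0)
#' cfg$times
phantom_config <- function(outer_radius = 3.2,
                           wall_thickness = 2.2,
                           voxel_size = 11,
                           times = c(0, 6, 13, 26, 39, 58),
                           background_level = 8000,
                           noise_sd = 200,
                           beam_hardening_slope = 1000,
                           seed = 1L) {
  stopifnot(is.numeric(outer_radius), length(outer_radius) == 1L,
            is.numeric(wall_thickness), length(wall_thickness) == 1L,
            is.numeric(voxel_size), length(voxel_size) == 1L,
            is.numeric(times), length(times) >= 1L,
            is.numeric(background_level), length(background_level) == 1L,
            is.numeric(noise_sd), length(noise_sd) == 1L,
            is.numeric(beam_hardening_slope), length(beam_hardening_slope) == 1L,
            is.numeric(seed), length(seed) == 1L)
  if (wall_thickness <= 0) stop("wall_thickness must be > 0")
  if (outer_radius <= wall_thickness)
    stop("outer_radius must exceed wall_thickness")
  if (voxel_size <= 0) stop("voxel_size must be > 0")
  if (any(times < 0)) stop("times must be non-negative")
  if (times[1] != 0) stop("first staining time must be 0")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (beam_hardening_slope < 0) stop("beam_hardening_slope must be >= 0")
  structure(list(outer_radius = outer_radius,
                 wall_thickness = wall_thickness,
                 voxel_size = voxel_size,
                 times = as.numeric(times),
                 background_level = background_level,
                 noise_sd = noise_sd,
                 beam_hardening_slope = beam_hardening_slope,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Exact saturation-model parameters
#'
#' Parameters of the closed-form intensity model used as simulation ground
#' truth: at depth `d` and staining time `t`,
#' `I(d, t) = Imax(d) - (Imax(d) - I0) * exp(-t / tau(d))` with a depth-graded
#' time constant `tau(d) = tau_surface * exp(tau_depth_rate * d)`. The
#' exponential depth dependence of `tau` makes the downstream staining-time
#' model exactly recoverable, providing closed-form ground truth for
#' end-to-end checks.
#'
#' @param I0 Native (unstained) tissue intensity in counts.
#' @param Imax_surface Saturated intensity at the outer surface, counts;
#'   must exceed `I0`.
#' @param tau_surface Time constant at depth 0, hours.
#' @param tau_depth_rate Exponential growth rate of the time constant with
#'   depth, per mm (>= 0).
#'
#' @return An object of class `exact_model_params`.
#' @export
exact_model_params <- function(I0 = 10000,
                               Imax_surface = 30000,
                               tau_surface = 5,
                               tau_depth_rate = 1) {
  stopifnot(is.numeric(I0), is.numeric(Imax_surface),
            is.numeric(tau_surface), is.numeric(tau_depth_rate))
  if (I0 < 0) stop("I0 must be >= 0")
  if (Imax_surface <= I0) stop("Imax_surface must exceed I0")
  if (tau_surface <= 0) stop("tau_surface must be > 0")
  if (tau_depth_rate < 0) stop("tau_depth_rate must be >= 0")
  structure(list(I0 = I0, Imax_surface = Imax_surface,
                 tau_surface = tau_surface, tau_depth_rate = tau_depth_rate),
            class = "exact_model_params")
}

#' Semi-infinite diffusion parameters
#'
#' Parameters of a physically motivated alternative ground-truth field: the
#' contrast agent enters the tissue by one-dimensional diffusion from the
#' bathing solution, so concentration follows the semi-infinite-medium
#' solution `C(d, t) = C0 * erfc(d / (2 * sqrt(D * t)))`.
#'
#' @param D Diffusion coefficient, mm^2 per hour (> 0).
#' @param C0 Surface concentration, arbitrary units (> 0).
#' @param intensity_gain Counts per concentration unit used when mapping
#'   concentration to image intensity.
#'
#' @return An object of class `diffusion_params`.
#' @export
diffusion_params <- function(D = 0.01, C0 = 1, intensity_gain = 20000) {
  if (D <= 0) stop("D must be > 0")
  if (C0 <= 0) stop("C0 must be > 0")
  structure(list(D = D, C0 = C0, intensity_gain = intensity_gain),
            class = "diffusion_params")
}

#' Exact saturation intensity at depth and time
#'
#' Evaluates the closed-form saturation model
#' `I(d, t) = Imax(d) - (Imax(d) - I0) * exp(-t / tau(d))`, with
#' `tau(d) = tau_surface * exp(tau_depth_rate * d)` and a linearly decreasing
#' intensity ceiling `Imax(d) = Imax_surface - imax_slope * d`, clamped so the
#' ceiling never falls below `I0`.
#'
#' @param params An [exact_model_params()] object.
#' @param depth Depth(s) below the stained surface, mm (>= 0).
#' @param time Staining time(s), hours (>= 0). `depth` and `time` are recycled
#'   to a common length.
#' @param imax_slope Decrease of the ceiling with depth, counts per mm (>= 0);
#'   typically `beam_hardening_slope` from a [phantom_config()].
#'
#' @return Intensity in counts, within `[I0, Imax(depth)]`.
#' @export
#' @examples
#' p <- exact_model_params()
#' saturation_intensity_exact(p, depth = 0, time = c(0, 6, 58))
saturation_intensity_exact <- function(params, depth, time, imax_slope = 0) {
  stopifnot(inherits(params, "exact_model_params"))
  if (any(depth < 0)) stop("depth must be >= 0")
  if (any(time < 0)) stop("time must be >= 0")
  if (imax_slope < 0) stop("imax_slope must be >= 0")
  imax <- pmax(params$I0, params$Imax_surface - imax_slope * depth)
  tau <- params$tau_surface * exp(params$tau_depth_rate * depth)
  imax - (imax - params$I0) * exp(-time / tau)
}

#' Concentration in a semi-infinite diffusing medium
#'
#' `C(d, t) = C0 * erfc(d / (2 * sqrt(D * t)))`; at `t = 0` the limiting
#' values are `C0` at the surface and 0 at any positive depth.
#'
#' @param params A [diffusion_params()] object.
#' @param depth Depth(s) in mm (>= 0).
#' @param time Time(s) in hours (>= 0).
#'
#' @return Concentration in `[0, C0]`, non-increasing in depth and
#'   non-decreasing in time.
#' @export
diffusion_concentration <- function(params, depth, time) {
  stopifnot(inherits(params, "diffusion_params"))
  if (any(depth < 0)) stop("depth must be >= 0")
  if (any(time < 0)) stop("time must be >= 0")
  n <- max(length(depth), length(time))
  depth <- rep_len(depth, n)
  time <- rep_len(time, n)
  out <- numeric(n)
  zero_t <- time == 0
  out[zero_t] <- ifelse(depth[zero_t] == 0, params$C0, 0)
  if (any(!zero_t)) {
    x <- depth[!zero_t] / (2 * sqrt(params$D * time[!zero_t]))
    # erfc(x) = 2 * pnorm(-x * sqrt(2))
    out[!zero_t] <- params$C0 * 2 * stats::pnorm(-x * sqrt(2))
  }
  out
}

#' Depth-to-intensity field from the exact saturation model
#'
#' Builds the `field(depth)` function that [render_slice()] expects, freezing
#' the staining time and wiring the phantom's beam-hardening slope into the
#' intensity ceiling.
#'
#' @param params An [exact_model_params()] object.
#' @param time Staining time in hours.
#' @param imax_slope Ceiling decrease with depth, counts per mm.
#'
#' @return A function of depth (mm) returning intensity (counts).
#' @export
saturation_field <- function(params, time, imax_slope = 0) {
  force(params); force(time); force(imax_slope)
  function(depth) saturation_intensity_exact(params, depth, time, imax_slope)
}

#' Single slice image
#'
#' A 2-D grayscale intensity grid with physical voxel size, representing one
#' reconstructed transverse slice at one staining timepoint. Pixels are stored
#' as a numeric matrix indexed `[row, col]` with row = y (down) and
#' col = x (right); pixel coordinates used elsewhere are 0-based `(x, y)`.
#'
#' @param pixels Numeric matrix of intensities in counts.
#' @param voxel_size_um Voxel edge length in micrometres.
#' @param time_h Staining duration of this image, hours.
#'
#' @return An object of class `slice_image`.
#' @export
slice_image <- function(pixels, voxel_size_um, time_h = NA_real_) {
  stopifnot(is.matrix(pixels), is.numeric(pixels),
            is.numeric(voxel_size_um), voxel_size_um > 0)
  structure(list(pixels = pixels, voxel_size_um = voxel_size_um,
                 time_h = time_h),
            class = "slice_image")
}

#' @export
print.slice_image <- function(x, ...) {
  cat(sprintf("<slice_image> %d x %d px, voxel %.3g um, t = %s h\n",
              nrow(x$pixels), ncol(x$pixels), x$voxel_size_um,
              format(x$time_h)))
  invisible(x)
}

#' Render one synthetic slice
#'
#' Draws the annular phantom: pixels whose radial distance from the image
#' centre lies within `[outer_radius - wall_thickness, outer_radius]` take
#' `field(depth)` where `depth = outer_radius - radial_distance`; all other
#' pixels take the background level. Zero-mean Gaussian noise with
#' `cfg$noise_sd` is added from a stream seeded by `cfg$seed` and the
#' timepoint index, so rendering is bit-reproducible for a fixed
#' configuration. The caller's random-number state is left untouched.
#'
#' @param cfg A [phantom_config()].
#' @param field Function of depth (mm) returning tissue intensity (counts);
#'   must be defined on `[0, wall_thickness]`.
#' @param time_index 1-based index into `cfg$times` selecting the timepoint.
#' @param dim Optional image side length in pixels; by default the smallest
#'   odd size containing the annulus plus a 3-pixel background margin.
#'
#' @return A [slice_image()].
#' @export
#' @examples
#' cfg <- phantom_config(outer_radius = 1, wall_thickness = 0.6,
#'                       voxel_size = 50, noise_sd = 0)
#' img <- render_slice(cfg, function(d) 30000 - 5000 * d, time_index = 1)
render_slice <- function(cfg, field, time_index = 1L, dim = NULL) {
  stopifnot(inherits(cfg, "phantom_config"), is.function(field))
  time_index <- as.integer(time_index)
  if (time_index < 1L || time_index > length(cfg$times))
    stop("time_index out of range of cfg$times")
  v <- cfg$voxel_size / 1000  # mm per pixel
  half_px <- cfg$outer_radius / v
  n_min <- 2L * (as.integer(ceiling(half_px)) + 3L) + 1L
  n <- if (is.null(dim)) n_min else as.integer(dim)
  if (n < n_min)
    stop(sprintf("image dimension %d too small to contain the annulus (need >= %d)",
                 n, n_min))
  c0 <- (n - 1) / 2  # centre, 0-based pixel units
  ax <- (seq_len(n) - 1) - c0
  r_mm <- v * sqrt(outer(ax^2, ax^2, `+`))  # [row=y, col=x]
  inner <- cfg$outer_radius - cfg$wall_thickness
  px <- matrix(cfg$background_level, n, n)
  in_wall <- r_mm >= inner & r_mm <= cfg$outer_radius
  px[in_wall] <- field(cfg$outer_radius - r_mm[in_wall])
  if (cfg$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed((cfg$seed + 7919L * time_index) %% .Machine$integer.max)
    px <- px + matrix(stats::rnorm(n * n, 0, cfg$noise_sd), n, n)
  }
  slice_image(px, cfg$voxel_size, cfg$times[time_index])
}

#' Simulate a full staining time series
#'
#' Renders one slice per staining duration in `cfg$times`, using the exact
#' saturation model as the tissue intensity field and the phantom's
#' beam-hardening slope as the ceiling gradient.
#'
#' @param cfg A [phantom_config()].
#' @param params An [exact_model_params()].
#' @param dim Optional image side length, passed to [render_slice()].
#'
#' @return List of [slice_image()]s, one per timepoint.
#' @export
simulate_stack <- function(cfg, params, dim = NULL) {
  stopifnot(inherits(cfg, "phantom_config"),
            inherits(params, "exact_model_params"))
  lapply(seq_along(cfg$times), function(i) {
    f <- saturation_field(params, cfg$times[i], cfg$beam_hardening_slope)
    render_slice(cfg, f, time_index = i, dim = dim)
  })
}
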