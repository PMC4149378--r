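#' Intensity line profile
#'
#' Ordered (distance, intensity) samples along a ray cast from outside the
#' tissue toward the lumen. Positions are in mm with uniform spacing equal to
#' the voxel size; each intensity is a width-averaged pixel value.
#'
#' @param positions Sample positions along the ray, mm; strictly increasing
#'   with constant step.
#' @param intensities Intensities in counts, same length as `positions`.
#' @param width_px Odd averaging width in pixels used at extraction.
#'
#' @return An object of class `line_profile`.
#' @export
line_profile <- function(positions, intensities, width_px = 1L) {
  stopifnot(is.numeric(positions), is.numeric(intensities))
  if (length(positions) != length(intensities))
    stop("positions and intensities must have the same length")
  if (length(positions) >= 2) {
    steps <- diff(positions)
    if (any(steps <= 0)) stop("positions must be strictly increasing")
    if (diff(range(steps)) > 1e-9 * steps[1])
      stop("positions must have constant spacing")
  }
  width_px <- as.integer(width_px)
  if (width_px < 1L || width_px %% 2L == 0L)
    stop("width_px must be odd and >= 1")
  structure(list(positions = as.numeric(positions),
                 intensities = as.numeric(intensities),
                 width_px = width_px),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %d samples, %.4g-%.4g mm, width %d px\n",
              length(x$positions), min(x$positions), max(x$positions),
              x$width_px))
  invisible(x)
}

#' @export
as.data.frame.line_profile <- function(x, ...) {
  data.frame(position_mm = x$positions, intensity = x$intensities)
}

#' Extract a width-averaged line profile from a slice
#'
#' Samples the image along the segment from `start` to `end` at one-pixel
#' steps; each profile sample is the arithmetic mean of `width_px`
#' nearest-neighbour pixels taken perpendicular to the ray, which suppresses
#' detector noise without smoothing along the sampling direction. Pixel
#' coordinates are 0-based `(x, y)` with x right and y down; no sub-pixel
#' interpolation is applied (nearest pixel wins).
#'
#' @param img A [slice_image()].
#' @param start,end Numeric `(x, y)` pixel coordinates; `start` should lie
#'   outside the tissue and `end` on the luminal side.
#' @param width_px Odd perpendicular averaging width, default 5.
#'
#' @return A [line_profile()] with spacing equal to the voxel size.
#' @export
extract_line_profile <- function(img, start, end, width_px = 5L) {
  stopifnot(inherits(img, "slice_image"),
            is.numeric(start), length(start) == 2L,
            is.numeric(end), length(end) == 2L)
  width_px <- as.integer(width_px)
  if (width_px < 1L || width_px %% 2L == 0L)
    stop("width_px must be odd and >= 1")
  d <- end - start
  len <- sqrt(sum(d^2))
  if (len == 0) stop("zero-length ray")
  u <- d / len
  perp <- c(-u[2], u[1])
  ks <- 0:floor(len)
  half <- (width_px - 1L) / 2L
  offs <- seq(-half, half)
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  vals <- vapply(ks, function(k) {
    ctr <- start + k * u
    xs <- round(ctr[1] + offs * perp[1])
    ys <- round(ctr[2] + offs * perp[2])
    if (any(xs < 0 | xs > nc - 1 | ys < 0 | ys > nr - 1))
      stop(sprintf("ray leaves image bounds at sample %d", k))
    mean(img$pixels[cbind(ys + 1, xs + 1)])
  }, numeric(1))
  v_mm <- img$voxel_size_um / 1000
  line_profile(ks * v_mm, vals, width_px)
}

# Gaussian smoothing of a numeric vector: kernel truncated at +/- 4 sigma,
# half-sample symmetric (edge-repeating) reflection padding. This padding
# conserves the vector mean exactly for a symmetric normalized kernel.
gaussian_smooth_vec <- function(x, sigma_px) {
  if (sigma_px <= 0) stop("sigma_px must be > 0")
  r <- max(1L, as.integer(ceiling(4 * sigma_px)))
  n <- length(x)
  if (n < 2L * r + 1L)
    stop(sprintf("profile length %d shorter than kernel support %d", n, 2L * r + 1L))
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  k <- k / sum(k)
  xp <- c(rev(x[1:r]), x, rev(x[(n - r + 1):n]))
  out <- as.numeric(stats::filter(xp, k, sides = 2))
  out[(r + 1):(r + n)]
}

#' Gaussian smoothing of a line profile
#'
#' Discrete convolution with a normalized Gaussian kernel truncated at
#' +/- 4 sigma, with reflection padding at the profile ends so that the
#' profile mean is conserved and constant profiles are fixed points.
#'
#' @param p A [line_profile()].
#' @param sigma_px Kernel standard deviation in samples (> 0).
#'
#' @return A smoothed [line_profile()] on the same positions.
#' @export
gaussian_smooth <- function(p, sigma_px) {
  stopifnot(inherits(p, "line_profile"))
  line_profile(p$positions, gaussian_smooth_vec(p$intensities, sigma_px),
               p$width_px)
}
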