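# Shared fixtures: small, fast phantoms and exact-model series.

# Coarse-voxel phantom for generic pipeline tests (small images).
tiny_phantom <- function(noise_sd = 0, voxel_size = 44, seed = 1L, ...) {
  phantom_config(voxel_size = voxel_size, noise_sd = noise_sd, seed = seed, ...)
}

# Noiseless intensity series from the saturation law at the standard
# staining schedule.
exact_series <- function(I0 = 10000, Imax = 30000, tau = 8,
                         times = c(0, 6, 13, 26, 39, 58)) {
  list(times = times,
       intensities = Imax - (Imax - I0) * exp(-times / tau),
       I0 = I0, Imax = Imax, tau = tau)
}

# A synthetic line profile: low background rising to a tissue plateau via a
# logistic ramp centred at sample `x0` with half-width `w` samples.
logistic_profile <- function(n = 300, x0 = 100, w = 4, background = 8000,
                             height = 20000, voxel_mm = 0.011) {
  x <- seq_len(n) - 1
  line_profile(x * voxel_mm, background + height / (1 + exp(-(x - x0) / w)))
}

# First tissue sample index (1-based) along a horizontal ray that starts at
# 0-based pixel x = x_start on the centre row of a rendered annulus.
first_tissue_index <- function(cfg, img, x_start = 1) {
  n <- nrow(img$pixels)
  c0 <- (n - 1) / 2
  v <- cfg$voxel_size / 1000
  xs <- x_start:(c0)
  r <- (c0 - xs) * v
  which(r <= cfg$outer_radius & r >= cfg$outer_radius - cfg$wall_thickness)[1]
}

# Continuous position (mm along the ray) of the true outer annulus boundary.
true_boundary_mm <- function(cfg, img, x_start = 1) {
  n <- nrow(img$pixels)
  c0 <- (n - 1) / 2
  v <- cfg$voxel_size / 1000
  (c0 - cfg$outer_radius / v - x_start) * v
}
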