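test_that("exact saturation model honours its boundary conditions", {
  p <- exact_model_params(I0 = 10000, Imax_surface = 30000, tau_surface = 5,
                          tau_depth_rate = 1)
  # unstained tissue sits at its native intensity at every depth
  expect_equal(saturation_intensity_exact(p, depth = c(0, 0.5, 2), time = 0),
               rep(10000, 3))
  # long-time limit is the (depth-dependent) ceiling
  expect_equal(saturation_intensity_exact(p, 0.5, 1e9, imax_slope = 1000),
               30000 - 1000 * 0.5)
  # half-saturation at t = tau(d) * ln 2
  d <- 0.7
  tau_d <- 5 * exp(1 * d)
  expect_equal(saturation_intensity_exact(p, d, tau_d * log(2)),
               30000 - (30000 - 10000) / 2)
})

test_that("exact saturation model is monotone in time and depth", {
  p <- exact_model_params()
  depths <- seq(0, 2, by = 0.25)
  times <- c(0, 2, 6, 13, 26, 39, 58)
  grid <- sapply(depths, function(d)
    saturation_intensity_exact(p, d, times, imax_slope = 1000))
  # increasing along time at each depth, non-increasing along depth at t > 0
  expect_true(all(apply(grid, 2, function(col) all(diff(col) > 0))))
  expect_true(all(apply(grid[-1, , drop = FALSE], 1,
                        function(row) all(diff(row) <= 1e-9))))
})

test_that("diffusion concentration matches an independent erfc oracle", {
  dp <- diffusion_params(D = 0.01, C0 = 1)
  x <- 0.5 / (2 * sqrt(0.01 * 6))
  # erfc via adaptive numerical integration of the Gaussian
  oracle <- 2 / sqrt(pi) * stats::integrate(function(u) exp(-u^2), x, Inf,
                                            rel.tol = 1e-12)$value
  expect_equal(diffusion_concentration(dp, 0.5, 6), oracle, tolerance = 1e-9)
  # boundary values
  expect_equal(diffusion_concentration(dp, 0, 3), 1)
  expect_equal(diffusion_concentration(dp, 0.2, 0), 0)
  expect_equal(diffusion_concentration(dp, 0, 0), 1)
})

test_that("diffusion concentration is self-similar under (d, t) -> (kd, k^2 t)", {
  dp <- diffusion_params(D = 0.037, C0 = 2.5)
  d <- c(0.05, 0.2, 0.8, 1.6)
  t <- c(1, 5, 20, 50)
  for (k in c(0.5, 2, 7)) {
    expect_equal(diffusion_concentration(dp, d, t),
                 diffusion_concentration(dp, k * d, k^2 * t),
                 tolerance = 1e-12)
  }
})

test_that("rendered noiseless slices reproduce the field and background exactly", {
  cfg <- phantom_config(outer_radius = 1, wall_thickness = 0.6,
                        voxel_size = 50, noise_sd = 0)
  img <- render_slice(cfg, function(d) rep(12345, length(d)), time_index = 1)
  n <- nrow(img$pixels)
  c0 <- (n - 1) / 2
  v <- cfg$voxel_size / 1000
  r <- v * sqrt(outer(((1:n) - 1 - c0)^2, ((1:n) - 1 - c0)^2, `+`))
  in_wall <- r >= 0.4 & r <= 1
  expect_true(all(img$pixels[in_wall] == 12345))
  expect_true(all(img$pixels[r > 1] == cfg$background_level))
  expect_error(render_slice(cfg, function(d) d, 1, dim = 11), "too small")
})

test_that("noiseless slice intensities along an oblique ray track the field", {
  cfg <- phantom_config(outer_radius = 1, wall_thickness = 0.6,
                        voxel_size = 22, noise_sd = 0,
                        beam_hardening_slope = 1000)
  p <- exact_model_params()
  f <- saturation_field(p, time = 58, imax_slope = cfg$beam_hardening_slope)
  img <- render_slice(cfg, f, time_index = 1)
  n <- nrow(img$pixels); c0 <- (n - 1) / 2
  v <- cfg$voxel_size / 1000
  # ray at ~30 degrees through the centre, nearest-pixel sampling width 1
  u <- c(cos(pi / 6), sin(pi / 6))
  start <- c(c0, c0) - u * (c0 - 1)
  prof <- extract_line_profile(img, start, c(c0, c0), width_px = 1)
  expect_length(prof$positions, floor(c0 - 1) + 1)
  drange <- 30000 - 10000
  for (k in seq_along(prof$positions)) {
    pos <- start + (k - 1) * u
    px <- round(pos)  # nearest pixel actually sampled
    r <- v * sqrt(sum((px - c0)^2))
    expected <- if (r >= 0.4 && r <= 1) f(1 - r) else cfg$background_level
    expect_lt(abs(prof$intensities[k] - expected), 0.005 * drange)
  }
})

test_that("rendering with noise is reproducible and leaves the caller RNG alone", {
  cfg <- phantom_config(outer_radius = 1, wall_thickness = 0.6,
                        voxel_size = 50, noise_sd = 150, seed = 42L)
  set.seed(999)
  before <- .Random.seed
  a <- render_slice(cfg, function(d) rep(20000, length(d)), time_index = 2)
  expect_identical(.Random.seed, before)
  b <- render_slice(cfg, function(d) rep(20000, length(d)), time_index = 2)
  expect_identical(a$pixels, b$pixels)
  # a different timepoint index draws a different stream
  c2 <- render_slice(cfg, function(d) rep(20000, length(d)), time_index = 3)
  expect_false(identical(a$pixels, c2$pixels))
})

test_that("stack TIFF round trip is lossless for 16-bit counts", {
  cfg <- phantom_config(outer_radius = 0.5, wall_thickness = 0.3,
                        voxel_size = 50, noise_sd = 0,
                        times = c(0, 6, 13, 26, 39, 58))
  p <- exact_model_params()
  images <- simulate_stack(cfg, p)
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(c(path, sub("\\.tif$", ".json", path))))
  write_stack(images, cfg$times, path, seed = cfg$seed)
  back <- read_stack(path)
  expect_equal(back$times, c(0, 6, 13, 26, 39, 58))
  expect_equal(back$voxel_size_um, 50)
  for (i in seq_along(images))
    expect_identical(back$images[[i]]$pixels, round(images[[i]]$pixels))
})

test_that("a stack without its metadata sidecar fails, naming the sidecar", {
  cfg <- phantom_config(outer_radius = 0.5, wall_thickness = 0.3,
                        voxel_size = 50, noise_sd = 0, times = c(0, 1, 2, 3))
  images <- simulate_stack(cfg, exact_model_params())
  path <- file.path(tempdir(), "orphan.tif")
  on.exit(unlink(c(path, sub("\\.tif$", ".json", path))))
  write_stack(images, cfg$times, path)
  file.remove(sub("\\.tif$", ".json", path))
  expect_error(read_stack(path), "orphan\\.json")
  expect_error(write_stack(images, c(0, 1), path), "mismatch")
})

test_that("phantom and model parameter invariants are enforced", {
  expect_error(phantom_config(wall_thickness = -1), "wall_thickness")
  expect_error(phantom_config(outer_radius = 1, wall_thickness = 2),
               "outer_radius")
  expect_error(phantom_config(times = c(1, 2, 3, 4)), "first staining time")
  expect_error(phantom_config(times = c(0, 6, 6, 13)), "strictly increasing")
  expect_error(phantom_config(noise_sd = -1), "noise_sd")
  expect_error(exact_model_params(Imax_surface = 100, I0 = 200), "Imax_surface")
  expect_error(exact_model_params(tau_surface = 0), "tau_surface")
  expect_error(diffusion_params(D = 0), "D must be")
})
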