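test_that("noiseless saturation series are recovered to high accuracy", {
  s <- exact_series(I0 = 10000, Imax = 30000, tau = 8)
  fit <- fit_saturation_curve(s$times, s$intensities)
  expect_equal(fit$I0, 10000, tolerance = 1e-4)
  expect_equal(fit$Imax, 30000, tolerance = 1e-4)
  expect_equal(fit$tau, 8, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-6 * 30000^2)
  expect_false(fit$degenerate)
  expect_true(fit$converged)
})

test_that("flat series are flagged degenerate, not fitted", {
  fit <- fit_saturation_curve(c(0, 6, 13, 26, 39, 58), rep(5000, 6))
  expect_true(fit$degenerate)
  expect_equal(fit$I0, 5000)
  expect_equal(fit$Imax, 5000)
  expect_true(is.na(fit$tau))
  expect_error(time_to_saturation(fit, 0.9), "degenerate")
})

test_that("fit preconditions are enforced", {
  expect_error(fit_saturation_curve(c(0, 6, 13), c(1, 2, 3)), "at least 4")
  expect_error(fit_saturation_curve(c(0, 6, 13, 26), c(1, 2, NA, 4)), "finite")
  expect_error(fit_saturation_curve(c(0, 6, 6, 26), c(1, 2, 3, 4)),
               "strictly increasing")
  expect_error(fit_saturation_curve(c(1, 6, 13, 26), c(1, 2, 3, 4)), "time 0")
})

test_that("median tau is recovered from noisy replicates", {
  s <- exact_series(I0 = 10000, Imax = 30000, tau = 8)
  set.seed(20)
  taus <- replicate(200, {
    y <- s$intensities + rnorm(length(s$times), 0, 0.01 * 30000)
    fit_saturation_curve(s$times, y)$tau
  })
  expect_lt(abs(median(taus) - 8) / 8, 0.05)
})

test_that("the fitted parameters are a fixed point of the simplex search", {
  s <- exact_series()
  set.seed(8)
  y <- s$intensities + rnorm(6, 0, 200)
  f1 <- fit_saturation_curve(s$times, y)
  # restart Nelder-Mead from the fitted solution on the same RSS surface
  rss <- function(theta) {
    pred <- theta[1] + exp(theta[2]) * (1 - exp(-s$times / exp(theta[3])))
    sum((pred - y)^2)
  }
  theta1 <- c(f1$I0, log(f1$Imax - f1$I0), log(f1$tau))
  re <- optim(theta1, rss, method = "Nelder-Mead",
              control = list(reltol = 1e-10, maxit = 5000))
  expect_lt(max(abs(re$par - theta1) / pmax(abs(theta1), 1e-12)), 1e-8)
})

test_that("saturation time has the closed form and its boundary behaviour", {
  f <- structure(list(depth = 0, I0 = 0, Imax = 2e4, tau = 6, rss = 0,
                      converged = TRUE, degenerate = FALSE),
                 class = "saturation_fit")
  # I0 = 0, s = 0.99: T = tau * ln(100)
  expect_equal(time_to_saturation(f, 0.99), 6 * log(100), tolerance = 1e-12)
  # tissue already at the target ratio stains for zero additional time
  g <- f; g$I0 <- 0.95 * g$Imax
  expect_equal(time_to_saturation(g, 0.95), 0)
  expect_gt(time_to_saturation(g, 0.99), 0)
  expect_error(time_to_saturation(f, 1), "in \\(0, 1\\)")
  # the fitted curve really is at ratio s at time T
  T90 <- time_to_saturation(f, 0.9)
  expect_equal(predict(f, T90) / f$Imax, 0.9, tolerance = 1e-12)
})

test_that("saturation time is invariant to intensity rescaling and monotone", {
  s <- exact_series(I0 = 8000, Imax = 25000, tau = 10)
  f <- fit_saturation_curve(s$times, s$intensities)
  for (a in c(0.2, 3, 117)) {
    fa <- fit_saturation_curve(s$times, a * s$intensities)
    expect_equal(time_to_saturation(fa, 0.95), time_to_saturation(f, 0.95),
                 tolerance = 1e-6)
  }
  # strictly increasing in s above I0/Imax, and in tau
  lv <- seq(0.4, 0.99, by = 0.01)
  Ts <- vapply(lv, function(x) time_to_saturation(f, x), numeric(1))
  expect_true(all(diff(Ts) > 0))
  f2 <- f; f2$tau <- f$tau * 2
  expect_equal(time_to_saturation(f2, 0.9), 2 * time_to_saturation(f, 0.9),
               tolerance = 1e-12)
})

test_that("closed-form saturation time agrees with a bisection oracle", {
  set.seed(14)
  for (i in 1:50) {
    I0 <- runif(1, 0, 1.5e4)
    Imax <- I0 + runif(1, 5e3, 3e4)
    tau <- runif(1, 1, 30)
    smin <- max(0.5, I0 / Imax + 0.01)
    s <- runif(1, smin, 0.995)
    f <- structure(list(depth = 0, I0 = I0, Imax = Imax, tau = tau, rss = 0,
                        converged = TRUE, degenerate = FALSE),
                   class = "saturation_fit")
    root <- uniroot(function(t) predict(f, t) / Imax - s,
                    c(0, 1e4), tol = 1e-12)$root
    expect_lt(abs(time_to_saturation(f, s) - root), 1e-9)
  }
})

test_that("the saturation table spans depths and levels and skips degenerate fits", {
  mk <- function(depth, tau, I0 = 1e4, Imax = 3e4)
    structure(list(depth = depth, I0 = I0, Imax = Imax, tau = tau, rss = 0,
                   converged = TRUE, degenerate = FALSE),
              class = "saturation_fit")
  # tau(d) = tau0 exp(beta d) with constant I0/Imax: T(d) proportional to exp(beta d)
  depths <- seq(0, 1.9, by = 0.1)
  fits <- lapply(depths, function(d) mk(d, tau = 5 * exp(1.2 * d)))
  tab <- build_saturation_table(fits, c(0.9, 0.95, 0.99))
  expect_s3_class(tab, "saturation_time_table")
  expect_equal(nrow(tab), 60L)
  t90 <- tab$T[tab$level == 0.9]
  expect_equal(t90 / t90[1], exp(1.2 * depths), tolerance = 1e-10)
  # identical fits at each depth give identical times per level
  same <- lapply(depths, function(d) mk(d, tau = 7))
  tab2 <- build_saturation_table(same, 0.95)
  expect_equal(length(unique(tab2$T)), 1L)
  # degenerate fit at one depth is skipped and named
  degen <- structure(list(depth = 0.5, I0 = 2e4, Imax = 2e4, tau = NA_real_,
                          rss = 0, converged = TRUE, degenerate = TRUE),
                     class = "saturation_fit")
  expect_warning(tab3 <- build_saturation_table(c(fits[1:5], list(degen)), 0.9),
                 "0.5")
  expect_equal(attr(tab3, "skipped_depths"), 0.5)
  expect_equal(nrow(tab3), 5L)
  expect_error(build_saturation_table(list(degen, degen), 0.9), "degenerate")
})
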