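#' Fit the exponential saturation curve to an intensity time course
#'
#' Fits `I(t) = Imax - (Imax - I0) * exp(-t / tau)` to one depth segment's
#' intensity-versus-staining-time series by unweighted least squares,
#' minimized with derivative-free simplex (Nelder-Mead) search. The model
#' says unstained tissue at native intensity `I0` tends exponentially toward
#' a saturated intensity `Imax` with time constant `tau`.
#'
#' Positivity of `tau` and of the intensity rise `Imax - I0` is enforced by
#' optimizing their logarithms, which keeps the simplex out of non-physical
#' regions without explicit constraints. Initialization: `I0` from the first
#' intensity, `Imax` from the last (inflated by 5% if the two coincide),
#' `tau` a third of the time span. The simplex is restarted from its own
#' solution until the parameters are stationary (and once from a perturbed
#' start if the first run fails to converge), so a fitted parameter set is a
#' fixed point of refitting.
#'
#' A series whose intensity range is below `1e-6` of its mean magnitude is
#' flagged `degenerate`: no kinetics are identifiable, `I0 = Imax = mean` and
#' `tau` is `NA`.
#'
#' @param times Staining times in hours; strictly increasing, starting at 0,
#'   at least 4 points (the model has 3 free parameters).
#' @param intensities Segment intensities in counts, one per time.
#' @param depth Optional depth label (mm) carried into the result.
#'
#' @return An object of class `saturation_fit` with fields `depth`, `I0`,
#'   `Imax`, `tau`, `rss`, `converged`, `degenerate`.
#' @export
#' @examples
#' t <- c(0, 6, 13, 26, 39, 58)
#' y <- 30000 - (30000 - 10000) * exp(-t / 8)
#' fit_saturation_curve(t, y)
fit_saturation_curve <- function(times, intensities, depth = NA_real_) {
  stopifnot(is.numeric(times), is.numeric(intensities))
  if (length(times) != length(intensities))
    stop("times and intensities must have the same length")
  if (length(times) < 4L)
    stop("at least 4 timepoints are required to fit 3 parameters")
  if (any(!is.finite(intensities))) stop("intensities must be finite")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (times[1] != 0) stop("the series must start at time 0")

  rng <- diff(range(intensities))
  if (rng < 1e-6 * abs(mean(intensities))) {
    m <- mean(intensities)
    return(new_saturation_fit(depth, I0 = m, Imax = m, tau = NA_real_,
                              rss = sum((intensities - m)^2),
                              converged = TRUE, degenerate = TRUE))
  }

  # theta = (I0, log(Imax - I0), log tau)
  rss_fun <- function(theta) {
    I0 <- theta[1]; rise <- exp(theta[2]); tau <- exp(theta[3])
    pred <- I0 + rise * (1 - exp(-times / tau))
    sum((pred - intensities)^2)
  }
  I0_init <- intensities[1]
  Imax_init <- intensities[length(intensities)]
  if (Imax_init <= I0_init) Imax_init <- I0_init + 0.05 * max(abs(I0_init), 1)
  theta <- c(I0_init, log(Imax_init - I0_init),
             log((times[length(times)] - times[1]) / 3))

  ctrl <- list(reltol = 1e-10, maxit = 5000L)
  fit <- stats::optim(theta, rss_fun, method = "Nelder-Mead", control = ctrl)
  if (fit$convergence != 0) {
    fit2 <- stats::optim(theta * 1.1 + 0.01, rss_fun, method = "Nelder-Mead",
                         control = ctrl)
    if (fit2$value < fit$value) fit <- fit2
  }
  # restart from the solution until stationary: mirrors common simplex practice
  for (i in 1:10) {
    nxt <- stats::optim(fit$par, rss_fun, method = "Nelder-Mead", control = ctrl)
    moved <- max(abs(nxt$par - fit$par) / pmax(abs(fit$par), 1e-12))
    if (nxt$value <= fit$value) fit <- nxt
    if (moved < 1e-9) break
  }
  new_saturation_fit(depth,
                     I0 = fit$par[1],
                     Imax = fit$par[1] + exp(fit$par[2]),
                     tau = exp(fit$par[3]),
                     rss = fit$value,
                     converged = fit$convergence == 0,
                     degenerate = FALSE)
}

new_saturation_fit <- function(depth, I0, Imax, tau, rss, converged, degenerate) {
  structure(list(depth = depth, I0 = I0, Imax = Imax, tau = tau, rss = rss,
                 converged = converged, degenerate = degenerate),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<saturation_fit> degenerate (flat series), I = %.6g\n", x$I0))
  } else {
    cat(sprintf("<saturation_fit> depth %s mm: I0 = %.6g, Imax = %.6g, tau = %.4g h (rss %.3g)\n",
                format(x$depth), x$I0, x$Imax, x$tau, x$rss))
  }
  invisible(x)
}

#' Predicted intensity from a saturation fit
#'
#' @param object A `saturation_fit`.
#' @param times Times (h) at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Predicted intensities in counts.
#' @export
predict.saturation_fit <- function(object, times, ...) {
  if (object$degenerate) return(rep(object$I0, length(times)))
  object$Imax - (object$Imax - object$I0) * exp(-times / object$tau)
}

#' Time to reach a saturation level
#'
#' Solves the fitted saturation curve for the time at which the intensity
#' ratio `I(t) / Imax` reaches level `s`, in closed form:
#' `T = tau * log((Imax - I0) / ((1 - s) * Imax))`, clamped at 0 for tissue
#' whose native intensity already meets the target ratio. Working with the
#' ratio `I / Imax` (rather than absolute intensity) removes the bias a
#' depth-dependent ceiling (beam hardening) would otherwise introduce.
#'
#' @param fit A non-degenerate `saturation_fit`.
#' @param s Target saturation level(s) in (0, 1), e.g. 0.90, 0.95, 0.99.
#'
#' @return Required staining time(s), hours (>= 0).
#' @export
time_to_saturation <- function(fit, s) {
  stopifnot(inherits(fit, "saturation_fit"))
  if (fit$degenerate)
    stop("saturation time is undefined for a degenerate (flat) fit")
  if (any(s <= 0 | s >= 1)) stop("saturation level s must be in (0, 1)")
  if (any((1 - s) * fit$Imax <= 0)) stop("(1 - s) * Imax must be positive")
  pmax(0, fit$tau * log((fit$Imax - fit$I0) / ((1 - s) * fit$Imax)))
}

#' Saturation-time table across depths and levels
#'
#' Evaluates [time_to_saturation()] for every non-degenerate per-depth fit at
#' every requested level. Degenerate fits are skipped; the skipped depths are
#' reported via a warning and attached as the `"skipped_depths"` attribute.
#'
#' @param fits List of `saturation_fit` objects, one per depth.
#' @param levels Saturation levels in (0, 1); default `c(0.90, 0.95, 0.99)`.
#'
#' @return A data frame of class `saturation_time_table` with columns
#'   `depth` (mm), `level`, `T` (hours).
#' @export
build_saturation_table <- function(fits, levels = c(0.90, 0.95, 0.99)) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  if (!all(vapply(fits, inherits, logical(1), "saturation_fit")))
    stop("fits must be a list of saturation_fit objects")
  if (any(levels <= 0 | levels >= 1)) stop("levels must lie in (0, 1)")
  degen <- vapply(fits, `[[`, logical(1), "degenerate")
  if (all(degen)) stop("all fits are degenerate; no saturation times can be derived")
  good <- fits[!degen]
  depths <- vapply(good, `[[`, numeric(1), "depth")
  if (length(unique(depths)) < 2L)
    stop("need >= 2 non-degenerate fits at distinct depths")
  skipped <- vapply(fits[degen], `[[`, numeric(1), "depth")
  if (length(skipped) > 0)
    warning(sprintf("skipping degenerate fits at depth(s): %s",
                    paste(format(skipped), collapse = ", ")))
  out <- do.call(rbind, lapply(good, function(f) {
    data.frame(depth = f$depth, level = levels,
               T = vapply(levels, function(s) time_to_saturation(f, s),
                          numeric(1)))
  }))
  rownames(out) <- NULL
  attr(out, "skipped_depths") <- as.numeric(skipped)
  class(out) <- c("saturation_time_table", "data.frame")
  out
}
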