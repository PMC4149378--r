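#' Staining-time-versus-depth model
#'
#' Container for the exponential depth rule `T(d) = A * exp(B * d)`: the
#' required staining time at the stained surface is `A` hours and grows by a
#' factor `exp(B)` per mm of tissue depth. On a semi-logarithmic plot the
#' relation is a straight line, which is how it is fitted (see
#' [fit_staining_time_model()]).
#'
#' @param level Saturation level the model applies to, in (0, 1).
#' @param A Staining time at zero depth, hours (> 0).
#' @param B Exponential depth rate, per mm.
#' @param n_points Number of (depth, time) points behind the fit.
#' @param r_squared_log Coefficient of determination on the log scale.
#'
#' @return An object of class `stain_time_model`.
#' @export
#' @examples
#' m <- stain_time_model(level = 0.90, A = 5.72, B = 1.04)
#' required_staining_time(m, d = c(0, 1, 2))
stain_time_model <- function(level, A, B, n_points = 2L, r_squared_log = 1) {
  stopifnot(is.numeric(level), is.numeric(A), is.numeric(B))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (A <= 0) stop("A must be > 0")
  if (n_points < 2) stop("n_points must be >= 2")
  if (r_squared_log < 0 || r_squared_log > 1)
    stop("r_squared_log must lie in [0, 1]")
  structure(list(level = level, A = A, B = B,
                 n_points = as.integer(n_points),
                 r_squared_log = r_squared_log),
            class = "stain_time_model")
}

#' @export
print.stain_time_model <- function(x, ...) {
  cat(sprintf("<stain_time_model> %.0f%% saturation: T(d) = %.4g * exp(%.4g * d)  [n = %d, R2(log) = %.4f]\n",
              100 * x$level, x$A, x$B, x$n_points, x$r_squared_log))
  invisible(x)
}

#' Fit the exponential staining-time-versus-depth rule
#'
#' Ordinary least squares of `log(T)` on depth: the exponential rule
#' `T = A * exp(B * d)` is a straight line on a semi-log plot, so
#' `A = exp(intercept)` and `B = slope`, and the fit is exactly invertible on
#' noiseless data. `r_squared_log` is the R-squared of that log-scale
#' regression (1 for a perfect two-point fit).
#'
#' @param depth Depths in mm; at least two distinct values.
#' @param T Required staining times in hours; all positive.
#' @param level Saturation level the entries correspond to.
#'
#' @return A [stain_time_model()].
#' @export
#' @examples
#' d <- seq(0, 1.9, by = 0.1)
#' fit_staining_time_model(d, 5 * exp(1.2 * d), level = 0.9)
fit_staining_time_model <- function(depth, T, level) {
  stopifnot(is.numeric(depth), is.numeric(T))
  if (length(depth) != length(T))
    stop("depth and T must have the same length")
  if (length(depth) < 2L) stop("need at least 2 points")
  if (any(T <= 0)) stop("all staining times must be > 0 (log-linear fit)")
  if (length(unique(depth)) < 2L) stop("all depths are identical; slope is unidentifiable")
  fit <- stats::lm(log(T) ~ depth)
  co <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((log(T) - mean(log(T)))^2)
  r2 <- if (tss < 1e-30) 1 else max(0, min(1, 1 - rss / tss))
  stain_time_model(level = level, A = exp(unname(co[1])), B = unname(co[2]),
                   n_points = length(depth), r_squared_log = r2)
}

#' Required staining time at a given depth
#'
#' Evaluates `T(d) = A * exp(B * d)` for a fitted or published coefficient
#' pair. With the reference coefficients this is the staining-time calculator
#' for planning I2KI incubation of cardiac tissue.
#'
#' @param m A [stain_time_model()].
#' @param d Depth(s) in mm (>= 0): the farthest tissue from the stained
#'   surface that must reach the model's saturation level.
#'
#' @return Required staining time(s), hours.
#' @export
required_staining_time <- function(m, d) {
  stopifnot(inherits(m, "stain_time_model"))
  if (any(d < 0)) stop("depth must be >= 0")
  m$A * exp(m$B * d)
}

#' Plan a staining protocol for a sample of given thickness
#'
#' Computes the recommended incubation time for a slab of tissue. With
#' single-sided staining the stain must diffuse through the full thickness;
#' staining from both surfaces simultaneously halves the maximum diffusion
#' distance, so twice the tissue can be stained in the same time.
#'
#' @param m A [stain_time_model()].
#' @param thickness Sample thickness in mm (> 0).
#' @param dual_sided Stain from both surfaces simultaneously?
#'
#' @return An object of class `stain_plan` with fields `thickness`, `level`,
#'   `dual_sided`, `effective_depth` (mm) and `recommended_time` (h).
#' @export
#' @examples
#' m <- stain_time_model(0.90, A = 5.72, B = 1.04)
#' plan_staining(m, thickness = 2, dual_sided = TRUE)
plan_staining <- function(m, thickness, dual_sided = FALSE) {
  stopifnot(inherits(m, "stain_time_model"), is.logical(dual_sided))
  if (thickness <= 0) stop("thickness must be > 0")
  eff <- if (dual_sided) thickness / 2 else thickness
  structure(list(thickness = thickness, level = m$level,
                 dual_sided = dual_sided, effective_depth = eff,
                 recommended_time = required_staining_time(m, eff)),
            class = "stain_plan")
}

#' @export
print.stain_plan <- function(x, ...) {
  cat(sprintf("<stain_plan> %.3g mm sample, %.0f%% saturation, %s: stain for %.3g h (effective depth %.3g mm)\n",
              x$thickness, 100 * x$level,
              if (x$dual_sided) "dual-sided" else "single-sided",
              x$recommended_time, x$effective_depth))
  invisible(x)
}

#' Fit one staining-time model per saturation level
#'
#' Turns a [build_saturation_table()] result into a coefficient table: one
#' `(A, B)` pair per saturation level. A level that cannot be fitted (for
#' example a single usable depth) is reported via a warning and listed in the
#' `"failed_levels"` attribute; the remaining levels are still returned.
#'
#' @param table A `saturation_time_table` (or data frame with columns
#'   `depth`, `level`, `T`).
#'
#' @return A list of [stain_time_model()]s, named by level.
#' @export
tabulate_models <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("depth", "level", "T") %in% names(table)))
  levels <- sort(unique(table$level))
  failed <- character(0)
  models <- list()
  for (lv in levels) {
    sub <- table[table$level == lv, , drop = FALSE]
    m <- tryCatch(fit_staining_time_model(sub$depth, sub$T, level = lv),
                  error = function(e) e)
    if (inherits(m, "error")) {
      failed <- c(failed, sprintf("level %.2f: %s", lv, conditionMessage(m)))
    } else {
      models[[format(lv)]] <- m
    }
  }
  if (length(models) == 0) stop("no saturation level could be fitted")
  if (length(failed) > 0)
    warning(sprintf("unfittable level(s): %s", paste(failed, collapse = "; ")))
  attr(models, "failed_levels") <- failed
  models
}

#' Coefficient table from a list of staining-time models
#'
#' @param models List of [stain_time_model()]s, e.g. from [tabulate_models()].
#' @return A data frame with columns `level`, `A_hours`, `B_per_mm`,
#'   `n_points`, `r_squared_log`.
#' @export
coefficients_table <- function(models) {
  stopifnot(is.list(models), length(models) >= 1L)
  out <- do.call(rbind, lapply(models, function(m) {
    data.frame(level = m$level, A_hours = m$A, B_per_mm = m$B,
               n_points = m$n_points, r_squared_log = m$r_squared_log)
  }))
  rownames(out) <- NULL
  out[order(out$level), , drop = FALSE]
}

#' Published reference coefficients for I2KI staining of mouse ventricle
#'
#' Coefficients of `T(d) = A * exp(B * d)` reported for whole mouse hearts
#' stained with I2KI and imaged by micro-CT at 11 um voxels, at three
#' saturation levels. Useful as a ready-made calculator for planning staining
#' of comparable cardiac tissue.
#'
#' @return A data frame with columns `level`, `A_hours`, `B_per_mm`.
#' @export
#' @examples
#' reference_stain_coefficients()
reference_stain_coefficients <- function() {
  path <- system.file("extdata", "reference_coefficients.csv",
                      package = "stainkinetics", mustWork = TRUE)
  utils::read.csv(path)
}

#' Reference coefficients as ready-to-use models
#'
#' @return A list of [stain_time_model()]s for the 90%, 95% and 99%
#'   saturation levels, named by level.
#' @export
#' @examples
#' ms <- reference_stain_models()
#' required_staining_time(ms[["0.9"]], d = 2)
reference_stain_models <- function() {
  co <- reference_stain_coefficients()
  out <- lapply(seq_len(nrow(co)), function(i)
    stain_time_model(co$level[i], co$A_hours[i], co$B_per_mm[i]))
  names(out) <- format(co$level)
  out
}
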