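#' Empirical survival curve of a response-time sample
#'
#' Builds the empirical survival function S(t) = proportion of the sample
#' strictly greater than t, evaluated at each unique sample value. The
#' strictly-greater convention makes -ln S finite everywhere except at the
#' maximum, which is always excluded from RevEx fitting.
#'
#' @param values Numeric RT sample in ms; at least 2 positive values.
#' @return An object of class `crt_survival`: a data frame with columns
#'   `value` (sorted unique values) and `survival`, with the sample size as
#'   attribute `n`.
#' @examples
#' survival_curve(c(1, 2, 3))  # S = 2/3, 1/3, 0
#' @export
survival_curve <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("`values` must not contain missing values")
  if (length(values) < 2) stop("need at least 2 values for a survival curve")
  if (any(values <= 0)) stop("`values` must be positive")
  n <- length(values)
  tab <- table(values)
  v <- as.numeric(names(tab))
  surv <- 1 - cumsum(as.numeric(tab)) / n
  out <- data.frame(value = v, survival = surv)
  attr(out, "n") <- n
  class(out) <- c("crt_survival", "data.frame")
  out
}

#' Fit the RevEx reverse-exponential model to a survival curve
#'
#' The RevEx model posits that RTs follow a two-parameter shifted
#' exponential, so the negative log of the survival function is linear in
#' time: -ln S(t) = (t - t0) / tau. The fit is ordinary least squares of
#' -ln S(t) on t over the curve points whose survival fraction lies inside
#' `fit_bounds` (default `[0.005, 0.995]`, trimming the extreme tails where
#' rare, task-unrelated slow responses produce a fall-off). The fitted
#' slope b and intercept a give the scale `tau = 1/b` and onset
#' `t0 = -a/b`; R-squared is computed on the transformed (linear) scale.
#'
#' @param curve A `crt_survival` curve, or a raw numeric RT sample (a curve
#'   is built automatically).
#' @param fit_bounds Survival-fraction interval used for fitting.
#' @return An object of class `crt_revex_fit`: a list with `slope`,
#'   `intercept`, `scale_ms`, `onset_ms`, `r2`, `fit_bounds`, `n` (sample
#'   size), and `n_points` (curve points used).
#' @examples
#' set.seed(1)
#' fit <- fit_revex(550 + rexp(5000, 1 / 330))
#' fit$r2 > 0.99
#' @export
fit_revex <- function(curve, fit_bounds = c(0.005, 0.995)) {
  if (!inherits(curve, "crt_survival")) curve <- survival_curve(curve)
  stopifnot(length(fit_bounds) == 2, fit_bounds[1] < fit_bounds[2],
            fit_bounds[1] >= 0, fit_bounds[2] <= 1)
  use <- curve$survival > 0 &
    curve$survival >= fit_bounds[1] & curve$survival <= fit_bounds[2]
  if (sum(use) < 10) {
    stop("fewer than 10 usable survival points inside fit_bounds; ",
         "sample too small or degenerate for a RevEx fit")
  }
  t <- curve$value[use]
  y <- -log(curve$survival[use])
  fit <- stats::lm.fit(cbind(1, t), y)
  a <- fit$coefficients[1]
  b <- fit$coefficients[2]
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  structure(
    list(slope = unname(b), intercept = unname(a),
         scale_ms = unname(1 / b), onset_ms = unname(-a / b),
         r2 = r2, fit_bounds = fit_bounds,
         n = attr(curve, "n"), n_points = sum(use)),
    class = "crt_revex_fit")
}

#' @export
print.crt_revex_fit <- function(x, ...) {
  cat("RevEx fit: -ln S(t) = a + b t\n")
  cat(sprintf("  onset t0 = %.1f ms, scale tau = %.1f ms, R^2 = %.4f\n",
              x$onset_ms, x$scale_ms, x$r2))
  cat(sprintf("  fitted on %d survival points (S in [%g, %g]) from n = %d\n",
              x$n_points, x$fit_bounds[1], x$fit_bounds[2], x$n))
  invisible(x)
}

#' Compare RevEx fits between two groups
#'
#' Fits the RevEx model to each group's RT sample and summarizes the
#' difference: the scale difference `delta_scale_ms` (group b minus group
#' a), the onset difference, which group has the slower tail (larger
#' scale), and an overlay table of both cumulative distributions on a
#' common probability grid. Typical use is the median-age split: fitting
#' per-subject mean RT-HITs below and above age 50.
#'
#' @param sample_a,sample_b Numeric RT samples.
#' @param labels Length-2 character labels for the groups.
#' @param fit_bounds Passed to [fit_revex()].
#' @return An object of class `crt_revex_comparison`: a list with `fit_a`,
#'   `fit_b`, `labels`, `delta_scale_ms`, `delta_onset_ms`, `slower_tail`
#'   (label of the larger-scale group, `NA` on a tie), and `overlay` (data
#'   frame `prob`, `q_a`, `q_b` of empirical quantiles).
#' @examples
#' set.seed(1)
#' cmp <- compare_groups(550 + rexp(2000, 1 / 300), 550 + rexp(2000, 1 / 360),
#'                       labels = c("under50", "over50"))
#' cmp$slower_tail
#' @export
compare_groups <- function(sample_a, sample_b, labels = c("a", "b"),
                           fit_bounds = c(0.005, 0.995)) {
  fit_a <- tryCatch(fit_revex(sample_a, fit_bounds),
                    error = function(e) stop("group '", labels[1], "': ",
                                             conditionMessage(e), call. = FALSE))
  fit_b <- tryCatch(fit_revex(sample_b, fit_bounds),
                    error = function(e) stop("group '", labels[2], "': ",
                                             conditionMessage(e), call. = FALSE))
  dt <- fit_b$scale_ms - fit_a$scale_ms
  probs <- seq(0.01, 0.99, by = 0.01)
  overlay <- data.frame(prob = probs,
                        q_a = unname(stats::quantile(sample_a, probs)),
                        q_b = unname(stats::quantile(sample_b, probs)))
  names(overlay)[2:3] <- paste0("q_", labels)
  structure(
    list(fit_a = fit_a, fit_b = fit_b, labels = labels,
         delta_scale_ms = dt,
         delta_onset_ms = fit_b$onset_ms - fit_a$onset_ms,
         slower_tail = if (dt > 0) labels[2] else if (dt < 0) labels[1] else NA_character_,
         overlay = overlay),
    class = "crt_revex_comparison")
}

#' @export
print.crt_revex_comparison <- function(x, ...) {
  cat(sprintf("RevEx comparison: %s vs %s\n", x$labels[1], x$labels[2]))
  cat(sprintf("  %s: tau %.1f ms, t0 %.1f ms, R^2 %.4f\n",
              x$labels[1], x$fit_a$scale_ms, x$fit_a$onset_ms, x$fit_a$r2))
  cat(sprintf("  %s: tau %.1f ms, t0 %.1f ms, R^2 %.4f\n",
              x$labels[2], x$fit_b$scale_ms, x$fit_b$onset_ms, x$fit_b$r2))
  cat(sprintf("  slower tail: %s (delta tau %.1f ms)\n", x$slower_tail, x$delta_scale_ms))
  invisible(x)
}
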