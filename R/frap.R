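#' FRAP intensity trace
#'
#' Mean bleach-region intensity per frame, with the number of pre-bleach
#' frames. The first `n_pre` entries are pre-bleach; the frame at index
#' `n_pre + 1` is the first post-bleach frame.
#'
#' @param times_s acquisition times in seconds, strictly increasing.
#' @param intensities mean ROI intensity F(t) per frame.
#' @param n_pre number of pre-bleach frames (default 3).
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(times_s, intensities, n_pre = 3L) {
  n_pre <- check_count(n_pre, "n_pre", min = 1L)
  times_s <- as.numeric(times_s); intensities <- as.numeric(intensities)
  if (length(times_s) != length(intensities))
    stop_amis("amisquant_format_error", "times and intensities differ in length")
  if (any(diff(times_s) <= 0))
    stop_amis("amisquant_format_error", "times must be strictly increasing")
  if (length(times_s) <= n_pre)
    stop_amis("amisquant_format_error", "trace has no post-bleach frames")
  structure(list(times_s = times_s, intensities = intensities, n_pre = n_pre),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("<frap_trace> %d pre + %d post frames, t = %g..%g s\n",
              x$n_pre, length(x$times_s) - x$n_pre, min(x$times_s),
              max(x$times_s)))
  invisible(x)
}

#' Normalise a FRAP trace
#'
#' Computes `FRAP(t) = (F(t) - F(0)) / (F(i) - F(0))` where `F(i)` is the
#' mean of the pre-bleach frames and `F(0)` the first post-bleach frame.
#' Post-bleach times are rebased so `t = 0` at the `F(0)` frame; by
#' construction the normalised value at `t = 0` is 0 and full recovery to
#' the pre-bleach level corresponds to 1. The normalisation is invariant
#' under affine intensity transforms `a * F + b` with `a > 0`.
#'
#' @param trace a [frap_trace()].
#' @return A `normalized_frap`: `times_s` (post-bleach, from 0), `values`,
#'   `F_i`, `F_0`.
#' @export
normalize_frap <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  n_pre <- trace$n_pre
  F_i <- mean(trace$intensities[seq_len(n_pre)])
  post <- (n_pre + 1L):length(trace$intensities)
  F_0 <- trace$intensities[post[1L]]
  if (F_i == F_0)
    stop_amis("amisquant_degenerate_trace_error",
              "F(i) equals F(0): no bleach detectable, normalisation undefined")
  structure(list(
    times_s = trace$times_s[post] - trace$times_s[post[1L]],
    values = (trace$intensities[post] - F_0) / (F_i - F_0),
    F_i = F_i, F_0 = F_0), class = "normalized_frap")
}

#' @export
print.normalized_frap <- function(x, ...) {
  cat(sprintf("<normalized_frap> %d frames over %g s, F(i) = %.4g, F(0) = %.4g\n",
              length(x$times_s), max(x$times_s), x$F_i, x$F_0))
  invisible(x)
}

#' Bleach depth of a FRAP trace
#'
#' Quality-control statistic for accepting a bleach event: the fraction of
#' the pre-bleach signal removed by the bleach, `1 - F(0) / F(i)`.
#'
#' @param trace a [frap_trace()].
#' @return Scalar bleach depth.
#' @export
bleach_depth <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  F_i <- mean(trace$intensities[seq_len(trace$n_pre)])
  if (F_i <= 0)
    stop_amis("amisquant_degenerate_trace_error",
              "non-positive pre-bleach level (%g)", F_i)
  F_0 <- trace$intensities[trace$n_pre + 1L]
  1 - F_0 / F_i
}

#' Fit the one-phase association model to a normalised FRAP curve
#'
#' Least-squares fit of `Y(t) = plateau * (1 - exp(-k t))` with the
#' intercept fixed at `Y(0) = 0`. The plateau is the mobile fraction: the
#' fraction of the bleached pool that exchanges on the measured timescale.
#' Fitting uses Levenberg-Marquardt least squares with
#' `plateau in [0, 2]`, `k in [0, 10] /s`, started from the mean of the
#' last five points (plateau) and the reciprocal half-rise time (k), with
#' a fixed schedule of seeded random restarts on non-convergence.
#'
#' @param norm a `normalized_frap` (or a [frap_trace()], which is
#'   normalised first).
#' @param n_restarts random restarts attempted after a failed fit.
#' @return A `frap_fit` object with components `plateau` (mobile
#'   fraction), `rate_k` (1/s), `rss`, `converged`, plus the data; methods
#'   [coef()], [predict()], [residuals()], `print`, `summary` and `plot`
#'   are provided.
#' @export
fit_one_phase_association <- function(norm, n_restarts = 3L) {
  if (inherits(norm, "frap_trace")) norm <- normalize_frap(norm)
  stopifnot(inherits(norm, "normalized_frap"))
  t <- norm$times_s; y <- norm$values
  if (length(t) < 5L)
    stop_amis("amisquant_precondition_error",
              "need >= 5 post-bleach points to fit, got %d", length(t))

  if (all(abs(y) < 1e-12)) {              # degenerate: nothing recovers
    fit <- list(plateau = 0, rate_k = 0, rss = 0, converged = TRUE)
    return(new_frap_fit(fit, norm))
  }

  plateau0 <- mean(tail(y, 5L))
  half <- which(y >= plateau0 / 2)
  k0 <- if (length(half) && t[half[1L]] > 0) log(2) / t[half[1L]] else 0.05
  starts <- list(c(plateau = max(min(plateau0, 2), 1e-3),
                   k = max(min(k0, 10), 1e-4)))
  for (i in seq_len(n_restarts))
    starts[[i + 1L]] <- with_seed(1000L + i, c(
      plateau = runif(1, 0.05, 1.5), k = 10^runif(1, -3, 0)))

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ plateau * (1 - exp(-k * t)),
                        start = as.list(s),
                        lower = c(plateau = 0, k = 0),
                        upper = c(plateau = 2, k = 10),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(plateau = unname(coef(fit)["plateau"]),
                     rate_k = unname(coef(fit)["k"]), rss = rss,
                     converged = fit$convInfo$isConv %||% TRUE)
      if (best$converged) break
    }
  }
  if (is.null(best))
    stop_amis("amisquant_fit_error",
              "one-phase association fit failed after %d restarts (n = %d, range %.3g..%.3g)",
              n_restarts, length(y), min(y), max(y))
  new_frap_fit(best, norm)
}

new_frap_fit <- function(fit, norm) {
  structure(list(plateau = fit$plateau, rate_k = fit$rate_k, rss = fit$rss,
                 converged = isTRUE(fit$converged), data = norm),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> mobile fraction %.4g, k = %.4g /s (t1/2 = %.3g s), RSS %.3g%s\n",
              x$plateau, x$rate_k,
              if (x$rate_k > 0) log(2) / x$rate_k else Inf, x$rss,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...) {
  c(plateau = object$plateau, rate_k = object$rate_k)
}

#' @export
predict.frap_fit <- function(object, times_s = NULL, ...) {
  t <- times_s %||% object$data$times_s
  object$plateau * (1 - exp(-object$rate_k * t))
}

#' @export
residuals.frap_fit <- function(object, ...) {
  object$data$values - predict(object)
}

#' @export
summary.frap_fit <- function(object, ...) {
  n <- length(object$data$times_s)
  sigma <- sqrt(object$rss / max(n - 2L, 1L))
  out <- list(coefficients = coef(object), rss = object$rss, sigma = sigma,
              n = n, half_time_s = if (object$rate_k > 0)
                log(2) / object$rate_k else Inf,
              converged = object$converged)
  class(out) <- "summary.frap_fit"
  out
}

#' @export
print.summary.frap_fit <- function(x, ...) {
  cat("One-phase association fit, Y(t) = plateau * (1 - exp(-k t)), Y(0) = 0\n")
  cat(sprintf("  mobile fraction (plateau): %.4g\n", x$coefficients["plateau"]))
  cat(sprintf("  rate k: %.4g /s   half-time: %.4g s\n",
              x$coefficients["rate_k"], x$half_time_s))
  cat(sprintf("  n = %d, RSS = %.4g, residual sigma = %.4g, converged: %s\n",
              x$n, x$rss, x$sigma, x$converged))
  invisible(x)
}

#' Plot a FRAP fit
#'
#' Normalised recovery points with the fitted association curve.
#'
#' @param x a `frap_fit`.
#' @param ... passed to [plot()].
#' @export
plot.frap_fit <- function(x, ...) {
  t <- x$data$times_s
  plot(t, x$data$values, xlab = "time after bleach (s)",
       ylab = "normalised recovery", ylim = range(0, 1, x$data$values), ...)
  tt <- seq(0, max(t), length.out = 200)
  lines(tt, predict(x, tt), col = "red3", lwd = 2)
  legend("bottomright", bty = "n", legend = sprintf(
    "mobile fraction %.2f, k = %.3g /s", x$plateau, x$rate_k))
  invisible(x)
}

#' Read FRAP traces from CSV
#'
#' Expected columns: `time_s`, `intensity`, `phase` (`"pre"` or `"post"`),
#' and optionally `trace_id` for files holding several traces.
#'
#' @param path CSV file path.
#' @return A list of [frap_trace()] objects, named by trace id.
#' @export
read_frap_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "intensity", "phase")
  if (!all(need %in% names(d)))
    stop_amis("amisquant_format_error",
              "FRAP CSV needs columns %s", paste(need, collapse = ", "))
  if (!all(d$phase %in% c("pre", "post")))
    stop_amis("amisquant_format_error", "phase must be 'pre' or 'post'")
  ids <- if ("trace_id" %in% names(d)) unique(d$trace_id) else "trace1"
  out <- lapply(ids, function(id) {
    di <- if ("trace_id" %in% names(d)) d[d$trace_id == id, ] else d
    di <- di[order(di$time_s), ]
    frap_trace(di$time_s, di$intensity, n_pre = sum(di$phase == "pre"))
  })
  setNames(out, ids)
}
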