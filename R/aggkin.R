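## Thioflavin-T aggregation kinetics: sigmoidal fits, halftimes, fold
## increase and aggregated fraction.
##
## The phenomenological model is
##   Y(t) = y_i + m_i t + (y_f + m_f t) / (1 + exp(-(t - t50) / k))
## where y_i + m_i t is the initial baseline, y_i + m_i t + y_f + m_f t
## the final plateau, t50 the halftime and k the transition time constant.
## The equation does not describe the underlying molecular processes; it
## extracts the main phenomenological parameter, the halftime.

#' Thioflavin-T kinetics trace
#'
#' @param t Strictly increasing time grid (h).
#' @param intensity ThT fluorescence intensity (a.u.), finite.
#' @param sample_id,replicate_id Identifiers.
#' @param conc Monomer concentration (uM).
#' @param pH Buffer pH.
#' @return Object of class `"tht_trace"`.
#' @export
tht_trace <- function(t, intensity, sample_id = "S1", conc = NA_real_,
                      pH = 3, replicate_id = 1L) {
  if (any(diff(t) <= 0))
    stop("'t' must be strictly increasing", call. = FALSE)
  if (length(intensity) != length(t) || any(!is.finite(intensity)))
    stop("'intensity' must be finite and match the time grid",
         call. = FALSE)
  structure(list(t = as.numeric(t), intensity = as.numeric(intensity),
                 sample_id = sample_id, conc = conc, pH = pH,
                 replicate_id = replicate_id),
            class = "tht_trace")
}

## model evaluation shared by the generator and the fitter
sigmoid_model <- function(p, t) {
  p[["y_i"]] + p[["m_i"]] * t +
    (p[["y_f"]] + p[["m_f"]] * t) / (1 + exp(-(t - p[["t50"]]) / p[["k"]]))
}

#' Fit the sigmoidal aggregation model to a ThT trace
#'
#' Least-squares fit of
#' `Y = y_i + m_i t + (y_f + m_f t) / (1 + exp(-(t - t50)/k))`.
#' Initial guesses are taken from the trace geometry (baselines from the
#' first and last 10% of points, `t50` from the first mid-intensity
#' crossing, `k` as 5% of the time span), with a small ladder of
#' deterministic restarts on failure.  Traces with no lag phase (signal
#' rising from the first point) are handled by allowing `t50` near the
#' start of the observation window.
#'
#' @param trace A `"tht_trace"` with at least 15 points.
#' @param noise_mult Flat-trace criterion: dynamic range below
#'   `noise_mult` times the robust noise level flags "no aggregation"
#'   (default 3).
#' @return Object of class `"sigmoid_fit"`: list with the fitted
#'   parameters `y_i, m_i, y_f, m_f, t50, k`, the residual sum of squares
#'   `rss`, `halftime` (the fitted `t50`), `t_half_amplitude` (diagnostic:
#'   first time the fitted curve crosses the midpoint of its own observed
#'   amplitude), `aggregating` (FALSE for flat traces, in which case no
#'   parameters are fitted) and `fold_increase`.
#' @export
fit_sigmoid <- function(trace, noise_mult = 3) {
  t <- trace$t; y <- trace$intensity
  if (length(t) < 15L)
    stop("at least 15 points are required", call. = FALSE)
  span <- diff(range(t))
  fold <- tryCatch(fold_increase(trace), error = function(e) NA_real_)

  ## flat-trace guard: the amplitude of the smoothed trace must rise
  ## above the point noise (the raw range of a long noisy trace always
  ## exceeds a few sigma even without any signal)
  sm <- stats::lowess(t, y, f = 0.1)$y
  noise <- stats::mad(y - sm)
  if (diff(range(sm)) < max(noise_mult * noise, 1e-12))
    return(structure(list(aggregating = FALSE, halftime = NA_real_,
                          fold_increase = fold,
                          flag = "no aggregation"),
                     class = "sigmoid_fit"))

  n10 <- max(3L, ceiling(0.1 * length(t)))
  head_i <- seq_len(n10)
  tail_i <- seq(length(t) - n10 + 1L, length(t))
  cf_i <- stats::coef(stats::lm(y[head_i] ~ t[head_i]))
  cf_f <- stats::coef(stats::lm(y[tail_i] ~ t[tail_i]))
  mid <- (min(y) + max(y)) / 2
  above <- which(y >= mid)
  t50_0 <- if (length(above)) t[above[1]] else t[1] + span / 2
  p0 <- c(y_i = cf_i[[1]], m_i = cf_i[[2]],
          y_f = cf_f[[1]] - cf_i[[1]], m_f = cf_f[[2]] - cf_i[[2]],
          t50 = t50_0, k = 0.05 * span)

  lower <- c(-Inf, -Inf, -Inf, -Inf, t[1] - span, 1e-6)
  upper <- c(Inf, Inf, Inf, Inf, t[length(t)] + span, Inf)
  restarts <- list(c(1, 1), c(0.5, 1), c(2, 1), c(1, 0.5), c(1, 2),
                   c(0.5, 0.5), c(2, 2), c(1, 4))
  best <- NULL
  for (rs in restarts) {
    pk <- p0
    pk[["t50"]] <- t[1] + (t50_0 - t[1]) * rs[1]
    pk[["k"]] <- p0[["k"]] * rs[2]
    pk <- pmin(pmax(pk, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pk,
                         fn = function(p) y - sigmoid_model(p, t),
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || fit$info %in% c(0, 9)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par,
                                                     rss = rss)
    if (1 - rss / sum((y - mean(y))^2) > 0.995) break
  }
  if (is.null(best))
    stop("sigmoid fit did not converge after multi-start", call. = FALSE)

  p <- best$par
  fitted <- sigmoid_model(p, t)
  mid_fit <- (min(fitted) + max(fitted)) / 2
  tg <- seq(t[1], t[length(t)], length.out = 2000L)
  fg <- sigmoid_model(p, tg)
  cross <- which(fg >= mid_fit)
  structure(list(y_i = p[["y_i"]], m_i = p[["m_i"]], y_f = p[["y_f"]],
                 m_f = p[["m_f"]], t50 = p[["t50"]], k = p[["k"]],
                 rss = best$rss, halftime = p[["t50"]],
                 t_half_amplitude = if (length(cross)) tg[cross[1]]
                                    else NA_real_,
                 aggregating = TRUE, flag = NULL,
                 fold_increase = fold),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (!x$aggregating) {
    cat("ThT trace: no aggregation detected\n")
  } else {
    cat(sprintf(
      "Sigmoidal ThT fit: t50 = %.3f h, k = %.3f h, fold increase = %.2f\n",
      x$t50, x$k, x$fold_increase))
  }
  invisible(x)
}

#' Fold increase of ThT fluorescence
#'
#' Ratio of the ThT intensity at the end of the experiment to the lowest
#' intensity observed over the trace.  The final value (not the peak) is
#' used deliberately, so late signal declines due to sedimentation of
#' large aggregates reduce the reported ratio.
#'
#' @param trace A `"tht_trace"`.
#' @return Final/minimum intensity ratio.
#' @export
fold_increase <- function(trace) {
  y <- trace$intensity
  lo <- min(y)
  if (lo <= 0)
    stop("minimum intensity must be positive for a fold increase",
         call. = FALSE)
  y[length(y)] / lo
}

#' Aggregated protein fraction from supernatant absorbance
#'
#' Fraction of protein converted into pelletable aggregates, from the
#' 280 nm absorbance of the initial solution and of the post-reaction
#' supernatant, both corrected for the absorbance contribution of the
#' ThT dye:
#' `fraction = 1 - (A_sup - A_blank) / (A_init - A_blank)`, clipped to
#' `[0, 1]` with a warning when measurement noise pushes it outside.
#'
#' @param a280_initial Initial absorbance at 280 nm.
#' @param a280_supernatant Supernatant absorbance at 280 nm after
#'   pelleting.
#' @param tht_blank_a280 Absorbance of the ThT blank (default 0).
#' @param tol Relative tolerance for a negative corrected supernatant
#'   before erroring (default 0.05).
#' @return Aggregated fraction in `[0, 1]`.
#' @export
aggregated_fraction <- function(a280_initial, a280_supernatant,
                                tht_blank_a280 = 0, tol = 0.05) {
  denom <- a280_initial - tht_blank_a280
  if (denom <= 0)
    stop("'a280_initial' must exceed the ThT blank", call. = FALSE)
  corr <- a280_supernatant - tht_blank_a280
  if (corr < -tol * denom)
    stop("corrected supernatant absorbance is negative beyond tolerance",
         call. = FALSE)
  f <- 1 - corr / denom
  if (f < 0 || f > 1) {
    warning("aggregated fraction clipped to [0, 1]")
    f <- min(max(f, 0), 1)
  }
  f
}
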