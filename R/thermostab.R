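## Extraction of melting temperature, aggregation onset, their
## log-concentration slopes and the Bence-Jones turbidity maximum from
## temperature-scan traces.

#' Melt-curve record
#'
#' Container for one capillary scan of a differential scanning fluorimetry
#' experiment: intrinsic fluorescence intensities at 330 and 350 nm along a
#' temperature ramp, with sample metadata.
#'
#' @param T_C Strictly increasing temperature grid (degC).
#' @param I330,I350 Fluorescence emission intensities at 330 / 350 nm.
#' @param conc Protein concentration (uM).
#' @param urea Urea concentration (M).
#' @param capillary_id,sample_id Identifiers.
#' @param scan_rate Scan rate (degC/min), metadata only.
#' @return Object of class `"melt_curve"` with the above fields plus
#'   `ratio` = `I350 / I330`.
#' @export
melt_curve <- function(T_C, I330, I350, conc = NA_real_, urea = 0,
                       capillary_id = "C1", sample_id = "S1",
                       scan_rate = 1) {
  if (any(diff(T_C) <= 0))
    stop("'T_C' must be strictly increasing", call. = FALSE)
  if (length(I330) != length(T_C) || length(I350) != length(T_C))
    stop("intensity channels must match the temperature grid",
         call. = FALSE)
  if (any(I330 <= 0))
    stop("I330 must be positive wherever the ratio is used", call. = FALSE)
  structure(list(T_C = as.numeric(T_C), I330 = as.numeric(I330),
                 I350 = as.numeric(I350), ratio = I350 / I330,
                 conc = conc, urea = urea, capillary_id = capillary_id,
                 sample_id = sample_id, scan_rate = scan_rate),
            class = "melt_curve")
}

#' DLS cumulant-radius trace
#'
#' @param T_C Strictly increasing temperature grid (degC).
#' @param radius Cumulant hydrodynamic radius (nm), positive.
#' @param conc Protein concentration (uM).
#' @param sample_id Identifier.
#' @return Object of class `"dls_trace"`.
#' @export
dls_trace <- function(T_C, radius, conc = NA_real_, sample_id = "S1") {
  if (any(diff(T_C) <= 0))
    stop("'T_C' must be strictly increasing", call. = FALSE)
  if (length(radius) != length(T_C))
    stop("'radius' must match the temperature grid", call. = FALSE)
  if (any(radius <= 0))
    stop("'radius' must be positive", call. = FALSE)
  structure(list(T_C = as.numeric(T_C), radius = as.numeric(radius),
                 conc = conc, sample_id = sample_id),
            class = "dls_trace")
}

#' Turbidity (back-reflection) trace
#'
#' @param T_C Strictly increasing temperature grid (degC).
#' @param turbidity Back-reflection turbidity signal.
#' @param conc Protein concentration (uM).
#' @param pH Buffer pH (the capillary Bence-Jones test runs at pH 5).
#' @param sample_id Identifier.
#' @return Object of class `"turbidity_trace"`.
#' @export
turbidity_trace <- function(T_C, turbidity, conc = NA_real_, pH = 5,
                            sample_id = "S1") {
  if (any(diff(T_C) <= 0))
    stop("'T_C' must be strictly increasing", call. = FALSE)
  if (length(turbidity) != length(T_C))
    stop("'turbidity' must match the temperature grid", call. = FALSE)
  structure(list(T_C = as.numeric(T_C), turbidity = as.numeric(turbidity),
                 conc = conc, pH = pH, sample_id = sample_id),
            class = "turbidity_trace")
}

## Savitzky-Golay smoothing with a window given in temperature units.
## Requires an (approximately) uniform grid, which thermal ramps provide.
smooth_trace <- function(T_C, y, smooth_window, order = 2L) {
  dT <- stats::median(diff(T_C))
  n <- round(smooth_window / dT)
  n <- max(n, order + 2L)
  if (n %% 2L == 0L) n <- n + 1L
  n <- min(n, if (length(y) %% 2L == 1L) length(y) else length(y) - 1L)
  if (n <= order) return(y)
  signal::sgolayfilt(y, p = order, n = n)
}

## Robust noise level of a trace from first differences of the residual
## around the smooth.
robust_noise <- function(y, smooth) {
  stats::mad(y - smooth)
}

#' Melting temperature from the derivative of the fluorescence ratio
#'
#' The melting temperature is the temperature at which the first
#' derivative of the 350/330 nm fluorescence-intensity ratio is maximal.
#' The ratio is first smoothed with a moving local quadratic
#' (Savitzky-Golay) filter, the derivative is taken by centred finite
#' differences, and the grid maximum is refined by local quadratic
#' interpolation.
#'
#' @param curve A `"melt_curve"`, or anything with `T_C` and `ratio`
#'   fields.
#' @param smooth_window Smoothing window in degC (default 2).
#' @return The melting temperature in degC, or `NA` (with a warning) when
#'   the ratio shows no transition (dynamic range below 5x the robust
#'   noise level).
#' @export
find_tm <- function(curve, smooth_window = 2) {
  T_C <- curve$T_C; ratio <- curve$ratio
  if (length(T_C) < 20L)
    stop("at least 20 points spanning the transition are required",
         call. = FALSE)
  sm <- smooth_trace(T_C, ratio, smooth_window)
  noise <- robust_noise(ratio, sm)
  if (diff(range(sm)) < max(5 * noise, 1e-8)) {
    warning("no unfolding transition detected (flat ratio)")
    return(NA_real_)
  }
  d <- numeric(length(sm))
  d[1] <- (sm[2] - sm[1]) / (T_C[2] - T_C[1])
  nn <- length(sm)
  d[nn] <- (sm[nn] - sm[nn - 1]) / (T_C[nn] - T_C[nn - 1])
  d[2:(nn - 1)] <- (sm[3:nn] - sm[1:(nn - 2)]) / (T_C[3:nn] - T_C[1:(nn - 2)])
  i <- which.max(d)
  if (i == 1L || i == nn) return(T_C[i])
  denom <- d[i - 1] - 2 * d[i] + d[i + 1]
  if (denom >= 0) return(T_C[i])        # not a proper local maximum
  dT <- (T_C[i + 1] - T_C[i - 1]) / 2
  T_C[i] + 0.5 * dT * (d[i - 1] - d[i + 1]) / denom
}

#' Aggregation-onset temperature from a DLS cumulant-radius trace
#'
#' Fits the cumulant radius versus temperature both with a linear model
#' (an extrapolation of the pre-aggregation baseline, fitted on the first
#' `baseline_frac` of the temperature span) and with a sigmoidal model on
#' the whole trace.  The onset of aggregation is the lowest temperature
#' at which the two fits first differ by more than `threshold` (relative
#' to the linear extrapolation; default 0.5%), located point-wise on a
#' fine temperature grid.  The sigmoidal model is a logistic growth term
#' on top of the same extrapolated linear baseline,
#' `r = a + b T + A / (1 + exp(-(T - Tc)/w))` with `(a, b)` taken from
#' the baseline fit, so the divergence between the two fits is the fitted
#' growth term alone.  Sharing the baseline keeps the 0.5% rule
#' meaningful under noise: two independently fitted baselines differ by
#' random amounts comparable to the threshold, and a flat-bottomed
#' logistic would diverge from any sloped baseline everywhere.
#'
#' @param trace A `"dls_trace"`.
#' @param threshold Relative divergence defining the onset (default
#'   0.005).
#' @param baseline_frac Fraction of the temperature span (from the low
#'   end) used for the baseline fit (default 0.25).
#' @return Object of class `"onset_result"`: list with `T_onset` (degC or
#'   `NA`), `detected`, `linear_fit` (intercept, slope), `sigmoid_fit`
#'   (named coefficients `a, b, A, Tc, w`, or `NULL`), `threshold` and
#'   `reason` when nothing was detected.
#' @export
find_tagg <- function(trace, threshold = 0.005, baseline_frac = 0.25) {
  T_C <- trace$T_C; r <- trace$radius
  if (length(T_C) < 20L)
    stop("at least 20 points are required", call. = FALSE)
  if (threshold <= 0)
    stop("'threshold' must be positive", call. = FALSE)

  base_idx <- T_C <= T_C[1] + baseline_frac * diff(range(T_C))
  if (sum(base_idx) < 3L)
    stop("baseline region has fewer than 3 points", call. = FALSE)
  lin <- stats::lm(r[base_idx] ~ T_C[base_idx])
  lin_cf <- unname(stats::coef(lin))

  none <- function(reason) structure(
    list(T_onset = NA_real_, detected = FALSE,
         linear_fit = c(intercept = lin_cf[1], slope = lin_cf[2]),
         sigmoid_fit = NULL, threshold = threshold, reason = reason),
    class = "onset_result")

  ## departure of the (smoothed) trace from the extrapolated baseline
  sm <- smooth_trace(T_C, r, 2)
  noise <- robust_noise(r, sm)
  lin_pred <- lin_cf[1] + lin_cf[2] * T_C
  excess <- sm - lin_pred
  if (max(excess) < max(5 * noise, 1e-8))
    return(none("flat trace: no aggregation signal"))

  ## logistic growth on top of the shared baseline:
  ## r = a + b T + A / (1 + exp(-(T - Tc)/w))
  resid0 <- r - lin_pred
  A0 <- max(excess)
  Tc0 <- T_C[which.min(abs(excess - A0 / 2))]
  w0 <- diff(range(T_C)) / 20
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(A = A0, Tc = Tc0, w = w0),
      fn = function(p) resid0 - p[1] / (1 + exp(-(T_C - p[2]) / p[3])),
      lower = c(0, -Inf, 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 400,
                                           ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 9))
    return(none("sigmoid fit did not converge"))
  p <- c(a = unname(lin_cf[1]), b = unname(lin_cf[2]), fit$par)

  Tg <- seq(T_C[1], T_C[length(T_C)], by = 0.01)
  lin_v <- lin_cf[1] + lin_cf[2] * Tg
  sig_v <- lin_v + p[["A"]] / (1 + exp(-(Tg - p[["Tc"]]) / p[["w"]]))
  div <- abs(sig_v - lin_v) / abs(lin_v)
  hit <- which(div > threshold)
  if (!length(hit))
    return(none("fits never diverge beyond the threshold"))
  structure(list(T_onset = Tg[hit[1]], detected = TRUE,
                 linear_fit = c(intercept = lin_cf[1], slope = lin_cf[2]),
                 sigmoid_fit = p, threshold = threshold, reason = NULL),
            class = "onset_result")
}

#' @export
print.onset_result <- function(x, ...) {
  if (x$detected)
    cat(sprintf("Aggregation onset: %.2f degC (%.1f%% divergence rule)\n",
                x$T_onset, 100 * x$threshold))
  else
    cat("Aggregation onset: none detected (", x$reason, ")\n", sep = "")
  invisible(x)
}

#' Slope of a thermal parameter versus log10 concentration
#'
#' Least-squares slope of Tm or Tagg values against the base-10 logarithm
#' of protein concentration, i.e. `d T / d log(c)` in degC per decade.
#' The dependence of the melting and aggregation-onset temperatures on
#' concentration is approximately linear on a logarithmic concentration
#' scale, so the slope is a single key parameter over the whole explored
#' range.  The slope is invariant under rescaling of the concentration
#' unit.
#'
#' @param values Numeric vector of Tm or Tagg values (degC).
#' @param concs Positive concentrations (any consistent unit).
#' @return Slope in degC per decade of concentration.
#' @export
logconc_slope <- function(values, concs) {
  if (length(values) != length(concs))
    stop("'values' and 'concs' must have the same length", call. = FALSE)
  keep <- is.finite(values) & is.finite(concs)
  if (sum(keep) < 3L)
    stop("at least 3 concentration points are required", call. = FALSE)
  if (any(concs[keep] <= 0))
    stop("'concs' must be positive", call. = FALSE)
  unname(stats::coef(stats::lm(values[keep] ~ log10(concs[keep])))[2L])
}

#' Turbidity maximum of a capillary Bence-Jones test scan
#'
#' Locates the temperature of maximal (smoothed) turbidity in a 25-90 degC
#' back-reflection scan.  Classical Bence-Jones behaviour is an increase
#' of turbidity around 50-60 degC followed by a partial clearing on
#' further heating; the `reversible` flag is set when the final turbidity
#' has dropped below half of the maximum rise above the starting baseline.
#' Traces whose dynamic range stays below 5x the robust noise level are
#' classified as showing no turbidity; traces still rising at the end of
#' the scan are flagged `"end_of_scan"` (reported as "> T_end").
#'
#' @param trace A `"turbidity_trace"`.
#' @param smooth_window Smoothing window in degC (default 2).
#' @return List of class `"turbidity_result"`: `T_max` (degC or `NA`),
#'   `category` (`"peak"`, `"end_of_scan"` or `"no_turbidity"`) and
#'   `reversible` (logical, `NA` when no turbidity).
#' @export
turbidity_maximum <- function(trace, smooth_window = 2) {
  T_C <- trace$T_C; y <- trace$turbidity
  if (diff(range(T_C)) < 40)
    stop("trace must span at least a 40 degC range", call. = FALSE)
  sm <- smooth_trace(T_C, y, smooth_window)
  noise <- robust_noise(y, sm)
  if (diff(range(sm)) < max(5 * noise, 1e-8))
    return(structure(list(T_max = NA_real_, category = "no_turbidity",
                          reversible = NA), class = "turbidity_result"))
  i <- which.max(sm)
  nn <- length(sm)
  baseline <- sm[1]
  rise <- sm[i] - baseline
  if (i >= nn - 1L) {
    return(structure(list(T_max = T_C[nn], category = "end_of_scan",
                          reversible = FALSE), class = "turbidity_result"))
  }
  ## quadratic refinement of the grid maximum
  denom <- sm[i - 1] - 2 * sm[i] + sm[i + 1]
  T_max <- if (i > 1L && denom < 0) {
    dT <- (T_C[i + 1] - T_C[i - 1]) / 2
    T_C[i] + 0.5 * dT * (sm[i - 1] - sm[i + 1]) / denom
  } else T_C[i]
  reversible <- (sm[nn] - baseline) < 0.5 * rise
  structure(list(T_max = T_max, category = "peak", reversible = reversible),
            class = "turbidity_result")
}

#' @export
print.turbidity_result <- function(x, ...) {
  if (x$category == "no_turbidity") cat("No turbidity detected\n")
  else if (x$category == "end_of_scan")
    cat(sprintf("Turbidity still rising at scan end (> %.0f degC)\n",
                x$T_max))
  else cat(sprintf("Turbidity maximum at %.1f degC (%sreversible)\n",
                   x$T_max, if (x$reversible) "" else "not "))
  invisible(x)
}
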