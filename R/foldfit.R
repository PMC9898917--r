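## Global two-state thermal + chemical unfolding analysis.
##
## The folding free energy combines the Gibbs-Helmholtz temperature
## dependence with the linear-extrapolation urea dependence:
##   dG(T, c) = dHm (1 - T/Tm) + dCp (T - Tm - T ln(T/Tm)) - m c
## with absolute temperatures, dG(Tm, 0) = 0, and the fraction unfolded
## f_u = 1 / (1 + exp(dG / RT)).  Fits are performed simultaneously on the
## raw fluorescence intensities at 330 and 350 nm across the whole urea
## grid, with the thermodynamic parameters shared and linear folded /
## unfolded baselines per wavelength.

## gas constant in kJ/(mol K)
R_GAS <- 8.314e-3

#' Two-state stability parameters
#'
#' @param Tm Midpoint temperature of thermal unfolding at zero denaturant
#'   (degC).
#' @param dHm van't Hoff enthalpy of unfolding at `Tm` (kJ/mol), positive
#'   for a cooperative unfolder.
#' @param dCp Heat-capacity change of unfolding (kJ/mol/K), nonnegative.
#' @param m_value Denaturant dependence of the free energy,
#'   `d dG / d [urea]` (kJ/mol/M), nonnegative.
#' @param baselines Named list with elements `"330"` and `"350"`, each a
#'   numeric vector `c(f_int, f_slope, u_int, u_slope)`: intercept and
#'   slope (per degC) of the folded and unfolded fluorescence baselines at
#'   that emission wavelength.
#' @return Object of class `"stability_params"`.
#' @export
stability_params <- function(Tm, dHm, dCp, m_value, baselines) {
  if (dHm <= 0) stop("'dHm' must be positive", call. = FALSE)
  if (dCp < 0) stop("'dCp' must be nonnegative", call. = FALSE)
  if (m_value < 0) stop("'m_value' must be nonnegative", call. = FALSE)
  if (!all(c("330", "350") %in% names(baselines)) ||
      !all(vapply(baselines, length, integer(1L)) == 4L))
    stop("'baselines' must hold 4 coefficients for each of \"330\", \"350\"",
         call. = FALSE)
  baselines <- lapply(baselines, function(b)
    stats::setNames(as.numeric(b), c("f_int", "f_slope", "u_int", "u_slope")))
  structure(list(Tm = Tm, dHm = dHm, dCp = dCp, m_value = m_value,
                 baselines = baselines),
            class = "stability_params")
}

#' @export
print.stability_params <- function(x, ...) {
  cat(sprintf(
    "Two-state stability: Tm = %.2f degC, dHm = %.0f kJ/mol, dCp = %.2f kJ/mol/K, m = %.2f kJ/mol/M\n",
    x$Tm, x$dHm, x$dCp, x$m_value))
  cat(sprintf("  dG(37 degC, 0 M urea) = %.2f kJ/mol\n", delta_g(x, 37, 0)))
  if (!is.null(x$rss)) cat(sprintf("  fit rss = %.4g (%s)\n", x$rss,
                                   if (isTRUE(x$converged)) "converged"
                                   else "NOT converged"))
  invisible(x)
}

#' Folding free energy at a given temperature and urea concentration
#'
#' Gibbs-Helmholtz plus linear-extrapolation free energy
#' `dG(T, c) = dHm (1 - T/Tm) + dCp (T - Tm - T ln(T/Tm)) - m c` with
#' temperatures in Kelvin; `dG(Tm, 0) = 0` by construction.
#'
#' @param params A `"stability_params"` object.
#' @param T_C Temperature(s) in degC.
#' @param urea Urea concentration(s) in M.
#' @return Free energy of unfolding in kJ/mol (vectorised).
#' @export
delta_g <- function(params, T_C, urea = 0) {
  Tk <- T_C + 273.15
  Tmk <- params$Tm + 273.15
  params$dHm * (1 - Tk / Tmk) +
    params$dCp * (Tk - Tmk - Tk * log(Tk / Tmk)) -
    params$m_value * urea
}

#' Fraction of unfolded protein
#'
#' `f_u = 1 / (1 + exp(dG / (R T)))`, evaluated stably.
#'
#' @inheritParams delta_g
#' @return Fraction unfolded in `[0, 1]` (vectorised).
#' @export
fraction_unfolded <- function(params, T_C, urea = 0) {
  Tk <- T_C + 273.15
  stats::plogis(-delta_g(params, T_C, urea) / (R_GAS * Tk))
}

#' Expected fluorescence intensity under the two-state model
#'
#' Population-weighted combination of linear folded and unfolded baselines:
#' `I = (1 - f_u)(a_f + b_f T) + f_u (a_u + b_u T)` with the
#' wavelength-specific baseline coefficients of `params`.
#'
#' @inheritParams delta_g
#' @param wavelength Emission wavelength, 330 or 350.
#' @return Expected intensity (vectorised over `T_C` / `urea`).
#' @export
signal_model <- function(params, T_C, urea = 0, wavelength = 330) {
  wl <- as.character(wavelength)
  if (!wl %in% c("330", "350"))
    stop("'wavelength' must be 330 or 350", call. = FALSE)
  b <- params$baselines[[wl]]
  fu <- fraction_unfolded(params, T_C, urea)
  (1 - fu) * (b[["f_int"]] + b[["f_slope"]] * T_C) +
    fu * (b[["u_int"]] + b[["u_slope"]] * T_C)
}

## -- global fitting -------------------------------------------------------

## flatten a stability_params (or start list) into the optimiser vector
params_to_vector <- function(p, fix_m) {
  v <- c(Tm = p$Tm, dHm = p$dHm, dCp = p$dCp)
  if (is.null(fix_m)) v <- c(v, m = p$m_value)
  for (wl in c("330", "350")) {
    b <- p$baselines[[wl]]
    names(b) <- paste0(c("f_int", "f_slope", "u_int", "u_slope"), wl)
    v <- c(v, b)
  }
  v
}

vector_to_params <- function(v, fix_m) {
  stability_params(
    Tm = v[["Tm"]], dHm = v[["dHm"]], dCp = v[["dCp"]],
    m_value = if (is.null(fix_m)) v[["m"]] else fix_m,
    baselines = list(
      "330" = v[paste0(c("f_int", "f_slope", "u_int", "u_slope"), "330")],
      "350" = v[paste0(c("f_int", "f_slope", "u_int", "u_slope"), "350")]))
}

## stack melt curves into flat vectors for the residual function
stack_curves <- function(curves) {
  list(
    T_C = unlist(lapply(curves, function(cv) c(cv$T_C, cv$T_C))),
    urea = unlist(lapply(curves, function(cv)
      rep(cv$urea, 2L * length(cv$T_C)))),
    is330 = unlist(lapply(curves, function(cv)
      rep(c(TRUE, FALSE), each = length(cv$T_C)))),
    I = unlist(lapply(curves, function(cv) c(cv$I330, cv$I350))))
}

model_intensity <- function(v, dat, fix_m) {
  Tk <- dat$T_C + 273.15
  Tmk <- v[["Tm"]] + 273.15
  m <- if (is.null(fix_m)) v[["m"]] else fix_m
  dG <- v[["dHm"]] * (1 - Tk / Tmk) +
    v[["dCp"]] * (Tk - Tmk - Tk * log(Tk / Tmk)) - m * dat$urea
  fu <- stats::plogis(-dG / (R_GAS * Tk))
  f_int <- ifelse(dat$is330, v[["f_int330"]], v[["f_int350"]])
  f_slo <- ifelse(dat$is330, v[["f_slope330"]], v[["f_slope350"]])
  u_int <- ifelse(dat$is330, v[["u_int330"]], v[["u_int350"]])
  u_slo <- ifelse(dat$is330, v[["u_slope330"]], v[["u_slope350"]])
  (1 - fu) * (f_int + f_slo * dat$T_C) + fu * (u_int + u_slo * dat$T_C)
}

## derivative-based initial guesses: apparent Tm from the lowest-urea
## curve (shifted to zero urea via the expected dG slope), baselines from
## the terminal 15% of the temperature span at the extreme urea values
initial_guess <- function(curves, fix_m) {
  ureas <- vapply(curves, `[[`, numeric(1L), "urea")
  m0 <- if (is.null(fix_m)) 7 else fix_m
  low <- curves[[which.min(ureas)]]
  tm_app <- suppressWarnings(find_tm(low))
  if (is.na(tm_app)) tm_app <- stats::median(low$T_C)
  dHm0 <- 400
  Tm0 <- tm_app + m0 * min(ureas) / (dHm0 / (tm_app + 273.15))

  lo_cv <- curves[ureas == min(ureas)]
  hi_cv <- curves[ureas == max(ureas)]
  baselines <- list()
  for (wl in c("330", "350")) {
    ch <- paste0("I", wl)
    Tf <- unlist(lapply(lo_cv, `[[`, "T_C"))
    yf <- unlist(lapply(lo_cv, `[[`, ch))
    keep <- Tf <= stats::quantile(Tf, 0.15)
    cf <- stats::coef(stats::lm(yf[keep] ~ Tf[keep]))
    Tu <- unlist(lapply(hi_cv, `[[`, "T_C"))
    yu <- unlist(lapply(hi_cv, `[[`, ch))
    keep <- Tu >= stats::quantile(Tu, 0.85)
    cu <- stats::coef(stats::lm(yu[keep] ~ Tu[keep]))
    baselines[[wl]] <- c(cf[[1]], cf[[2]], cu[[1]], cu[[2]])
  }
  list(Tm = Tm0, dHm = dHm0, dCp = 5, m_value = m0, baselines = baselines)
}

fit_bounds <- function(fix_m) {
  lower <- c(Tm = 0, dHm = 10, dCp = 0)
  upper <- c(Tm = 150, dHm = 3000, dCp = 20)
  if (is.null(fix_m)) {
    lower <- c(lower, m = 0); upper <- c(upper, m = 50)
  }
  bl <- rep(-Inf, 8L); bu <- rep(Inf, 8L)
  nm <- as.vector(outer(c("f_int", "f_slope", "u_int", "u_slope"),
                        c("330", "350"), paste0))
  names(bl) <- nm; names(bu) <- nm
  list(lower = c(lower, bl), upper = c(upper, bu))
}

#' Global two-state fit of a family of melt curves
#'
#' Simultaneous nonlinear least-squares fit of the two-state unfolding
#' model to the fluorescence intensities at both emission wavelengths of
#' all included melt curves across the urea grid.  The thermodynamic
#' parameters (`Tm`, `dHm`, `dCp`, and the m-value unless fixed) are
#' shared across all curves; linear folded and unfolded baselines are
#' shared per wavelength.  By default zero-urea curves are excluded,
#' because the simultaneous DLS scans show aggregation mostly in the
#' absence of urea and aggregation corrupts the unfolding signal; pass a
#' different `exclude` predicate for samples needing a wider exclusion
#' (e.g. everything below 2 M urea).
#'
#' The optimiser is Levenberg-Marquardt least squares started from
#' derivative-based guesses (apparent Tm from [find_tm()], baselines from
#' the terminal 15% of the scans), with up to `n_starts` deterministically
#' jittered restarts on failure.  `dCp` is bounded to `[0, 20]` kJ/mol/K
#' to prevent baseline/thermodynamics degeneracy on narrow scans.
#'
#' @param curves List of [melt_curve()] objects covering >= 2 urea
#'   concentrations after exclusion.
#' @param fix_m Fix the m-value at this value (kJ/mol/M) instead of
#'   fitting it; `NULL` (default) fits m freely.  A shared fixed value of
#'   7.1 is the conventional choice when comparing light chains.
#' @param exclude Predicate `function(curve) -> logical`; curves for which
#'   it returns TRUE are dropped.  Default drops zero-urea curves.
#' @param start Optional `"stability_params"` (or list with the same
#'   fields) used as starting point, e.g. for warm-started refits.
#' @param n_starts Maximum number of jittered restarts (default 10).
#' @return A `"stability_params"` object with extra fields `rss`,
#'   `converged`, `n_points`, `n_curves`, `dG37` (kJ/mol at 37 degC, zero
#'   urea) and `m_fixed`.
#' @export
global_fit <- function(curves, fix_m = NULL,
                       exclude = function(cv) cv$urea == 0,
                       start = NULL, n_starts = 10L) {
  if (inherits(curves, "melt_curve")) curves <- list(curves)
  if (!length(curves) || !all(vapply(curves, inherits, logical(1L),
                                     "melt_curve")))
    stop("'curves' must be a list of melt_curve objects", call. = FALSE)
  if (!is.null(exclude))
    curves <- Filter(function(cv) !isTRUE(exclude(cv)), curves)
  ureas <- vapply(curves, `[[`, numeric(1L), "urea")
  if (length(unique(ureas)) < 2L)
    stop("need curves at >= 2 urea concentrations after exclusion",
         call. = FALSE)

  dat <- stack_curves(curves)
  bounds <- fit_bounds(fix_m)
  guess <- if (is.null(start)) initial_guess(curves, fix_m) else start
  v0 <- params_to_vector(guess, fix_m)
  v0 <- pmin(pmax(v0, bounds$lower), bounds$upper)

  resid_fn <- function(v) {
    names(v) <- names(v0)
    dat$I - model_intensity(v, dat, fix_m)
  }

  ## deterministic jitter ladder for restarts
  jitter_tbl <- expand.grid(dTm = c(0, -5, 5, -10, 10),
                            fH = c(1, 0.6, 1.6))
  best <- NULL
  for (k in seq_len(min(n_starts, nrow(jitter_tbl)))) {
    vk <- v0
    vk[["Tm"]] <- v0[["Tm"]] + jitter_tbl$dTm[k]
    vk[["dHm"]] <- v0[["dHm"]] * jitter_tbl$fH[k]
    vk <- pmin(pmax(vk, bounds$lower), bounds$upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = vk, fn = resid_fn,
                         lower = bounds$lower, upper = bounds$upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || fit$info %in% c(0, 9)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    ## accept a start once the model explains essentially all variance
    r2 <- 1 - rss / sum((dat$I - mean(dat$I))^2)
    if (r2 > 0.99) break
  }
  if (is.null(best))
    stop(sprintf(
      "global fit did not converge after %d starts; check urea coverage and baselines",
      min(n_starts, nrow(jitter_tbl))), call. = FALSE)

  v <- best$fit$par
  names(v) <- names(v0)
  out <- vector_to_params(v, fix_m)
  out$rss <- best$rss
  out$converged <- TRUE
  out$n_points <- length(dat$I)
  out$n_curves <- length(curves)
  out$m_fixed <- !is.null(fix_m)
  out$dG37 <- delta_g(out, 37, 0)
  out
}

#' Stability estimate from one fit (kJ/mol at 37 degC)
#'
#' @param params A fitted `"stability_params"` object.
#' @return `dG(37 degC, 0 M urea)` in kJ/mol.
#' @export
dg37 <- function(params) delta_g(params, 37, 0)

#' Capillary-bootstrap confidence interval for the folding free energy
#'
#' Resamples the set of capillaries with replacement `n_boot` times (each
#' draw keeps all curves of the drawn capillary, duplicating capillaries
#' drawn more than once), refits the global two-state model warm-started
#' from the full-data fit, and reports the percentile 95% confidence
#' interval of `dG(37 degC)` (and of the m-value when it is free).
#' Replicates whose refit fails to converge are dropped with a count; more
#' than 20% drops is an error.
#'
#' @inheritParams global_fit
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Optional integer seed for the resampling.
#' @param level Confidence level (default 0.95).
#' @return Object of class `"stability_estimate"`: list with `dG37`,
#'   `ci_low`, `ci_high`, `n_boot`, `n_dropped`, `level`, the full-data
#'   `params`, the vector of bootstrap `boot_dG37`, and `m_ci` when the
#'   m-value was free.
#' @export
bootstrap_ci <- function(curves, n_boot = 100L, seed = NULL, fix_m = NULL,
                         exclude = function(cv) cv$urea == 0,
                         level = 0.95) {
  if (!is.null(exclude))
    curves <- Filter(function(cv) !isTRUE(exclude(cv)), curves)
  caps <- vapply(curves, `[[`, character(1L), "capillary_id")
  cap_ids <- unique(caps)
  if (length(cap_ids) < 2L)
    stop("bootstrap needs >= 2 capillaries", call. = FALSE)

  full <- global_fit(curves, fix_m = fix_m, exclude = NULL)
  boot_dg <- rep(NA_real_, n_boot)
  boot_m <- rep(NA_real_, n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      draw <- sample(cap_ids, length(cap_ids), replace = TRUE)
      idx <- unlist(lapply(draw, function(id) which(caps == id)))
      fit <- tryCatch(
        global_fit(curves[idx], fix_m = fix_m, exclude = NULL,
                   start = full, n_starts = 3L),
        error = function(e) NULL)
      if (!is.null(fit)) {
        boot_dg[b] <- fit$dG37
        boot_m[b] <- fit$m_value
      }
    }
  })
  ok <- is.finite(boot_dg)
  if (mean(!ok) > 0.2)
    stop(sprintf("%d of %d bootstrap refits failed to converge",
                 sum(!ok), n_boot), call. = FALSE)
  a <- (1 - level) / 2
  ci <- stats::quantile(boot_dg[ok], c(a, 1 - a), names = FALSE)
  out <- list(dG37 = full$dG37, ci_low = ci[1], ci_high = ci[2],
              n_boot = n_boot, n_dropped = sum(!ok), level = level,
              params = full, boot_dG37 = boot_dg[ok])
  if (is.null(fix_m))
    out$m_ci <- stats::quantile(boot_m[ok], c(a, 1 - a), names = FALSE)
  structure(out, class = "stability_estimate")
}

#' @export
print.stability_estimate <- function(x, ...) {
  cat(sprintf(
    "dG(37 degC) = %.2f kJ/mol, %d%% bootstrap CI [%.2f, %.2f] (%d/%d replicates)\n",
    x$dG37, round(100 * x$level), x$ci_low, x$ci_high,
    x$n_boot - x$n_dropped, x$n_boot))
  if (!is.null(x$m_ci))
    cat(sprintf("m-value = %.2f kJ/mol/M, CI [%.2f, %.2f]\n",
                x$params$m_value, x$m_ci[1], x$m_ci[2]))
  invisible(x)
}
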