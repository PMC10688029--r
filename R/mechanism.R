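#' Detect curvature of a Stern-Volmer plot
#'
#' Compares the intercept-fixed linear fit against the quadratic
#' (combined-model) fit. The quadratic term is retained when it is
#' individually significant (two-sided t-test at `alpha`) and its
#' inclusion improves r^2 by at least `min_r2_gain`; both conditions make
#' the by-eye judgement of "upward curvature" reproducible. The verdict
#' is slope-sign-agnostic: a clean negative-slope line is still "linear".
#'
#' @param series A [quenching_series()] with >= 4 concentrations.
#' @param alpha Significance level for the quadratic coefficient.
#' @param min_r2_gain Minimum r^2 improvement from the quadratic term.
#' @return `"linear"`, `"upward"` or `"downward"`, with the two fits
#'   attached as attributes `linear_fit` and `quadratic_fit`.
#' @export
detect_curvature <- function(series, alpha = 0.05, min_r2_gain = 0.01) {
  stopifnot(inherits(series, "quenching_series"))
  if (length(series$concentrations) < 4)
    stop("curvature detection needs at least 4 concentrations")
  lin <- sv_fit(series, "linear")
  quad <- sv_fit(series, "combined")
  cc <- quad$quad[["c"]]
  se <- quad$param_se[["c"]]
  df <- length(series$concentrations) - 2
  pval <- if (is.finite(se) && se > 0)
    2 * stats::pt(abs(cc / se), df = df, lower.tail = FALSE) else 1
  r2_lin <- if (is.na(lin$r_squared)) 0 else lin$r_squared
  r2_quad <- if (is.na(quad$r_squared)) 0 else quad$r_squared
  verdict <- if (pval < alpha && (r2_quad - r2_lin) >= min_r2_gain) {
    if (cc > 0) "upward" else "downward"
  } else "linear"
  structure(verdict, linear_fit = lin, quadratic_fit = quad,
            p_quadratic = pval, r2_gain = r2_quad - r2_lin)
}

# Is a linear Stern-Volmer slope indistinguishable from no quenching?
# True when the 95% CI of K_SV covers 0 or the fit explains little
# (r^2 < r2_min, e.g. PEG-like r^2 = 0.42).
is_negligible <- function(fit, r2_min = 0.5) {
  k <- fit$coefficients[["K_SV"]]
  se <- fit$param_se[["K_SV"]]
  df <- length(fit$series$concentrations) - 1
  tcrit <- stats::qt(0.975, df)
  ci_covers_zero <- is.finite(se) && (abs(k) <= tcrit * se)
  r2 <- fit$r_squared
  ci_covers_zero || is.na(r2) || r2 < r2_min
}

#' Classify the quenching mechanism from a two-temperature experiment
#'
#' Reproduces the standard decision logic for assigning a quenching
#' mechanism from Stern-Volmer isotherms measured at two temperatures:
#'
#' 1. Both plots linear with slopes indistinguishable from zero (95 percent
#'    CI covers 0 or r^2 below `negligible_r2`) — `"negligible"`.
#' 2. Both linear with significantly negative slopes — `"enhancement"`
#'    (fluorescence increases with cosolute, as for ethylene glycol).
#' 3. Both linear, K_SV rising with temperature beyond the combined
#'    standard errors, and k_q = K_SV/tau0 non-decreasing — `"dynamic"`
#'    (collisional quenching speeds up with diffusion).
#' 4. Both linear, K_SV falling with temperature beyond the combined
#'    standard errors — `"static"` (ground-state association weakens when
#'    heated; the slope is reported as K_S).
#' 5. Both plots upward-curved: the combined static/dynamic quadratic is
#'    attempted first; real positive roots give `"combined"`, otherwise a
#'    converged sphere-of-action fit gives `"sphere_of_action"`.
#' 6. Anything else (conflicting curvature verdicts, insignificant
#'    temperature trend) — `"inconclusive"`, with all fits attached; the
#'    classifier never silently picks a side.
#'
#' @param series_low,series_high [quenching_series()] at the lower and
#'   higher temperature (`series_low$temperature` must be smaller).
#' @param lifetimes A [lifetime_model()] used for the k_q criterion.
#' @param alpha,min_r2_gain Curvature thresholds, see [detect_curvature()].
#' @param negligible_r2 r^2 floor below which a linear fit is treated as
#'   no detectable quenching.
#' @return A `mechanism_call`: list with `label`, `constants` (named,
#'   model-appropriate), `evidence` (every fit attempted, curvature
#'   verdicts, k_q values and the thresholds used) and `annotations`.
#' @export
classify_mechanism <- function(series_low, series_high,
                               lifetimes = lifetime_model(3.1, 25),
                               alpha = 0.05, min_r2_gain = 0.01,
                               negligible_r2 = 0.5) {
  stopifnot(inherits(series_low, "quenching_series"),
            inherits(series_high, "quenching_series"))
  if (series_low$temperature >= series_high$temperature)
    stop("series_low must be at the lower temperature")

  curv_lo <- detect_curvature(series_low, alpha, min_r2_gain)
  curv_hi <- detect_curvature(series_high, alpha, min_r2_gain)
  lin_lo <- attr(curv_lo, "linear_fit")
  lin_hi <- attr(curv_hi, "linear_fit")

  ev <- list(
    curvature = c(low = as.character(curv_lo), high = as.character(curv_hi)),
    linear_fits = list(low = lin_lo, high = lin_hi),
    thresholds = list(alpha = alpha, min_r2_gain = min_r2_gain,
                      negligible_r2 = negligible_r2))

  k_lo <- lin_lo$coefficients[["K_SV"]]
  k_hi <- lin_hi$coefficients[["K_SV"]]
  se_lo <- lin_lo$param_se[["K_SV"]]
  se_hi <- lin_hi$param_se[["K_SV"]]
  tau_lo <- tau0_at_temperature(lifetimes, series_low$temperature)
  tau_hi <- tau0_at_temperature(lifetimes, series_high$temperature)
  kq <- suppressWarnings(c(low = bimolecular_rate(k_lo, tau_lo),
                           high = bimolecular_rate(k_hi, tau_hi)))
  ev$k_q <- kq
  ev$K_SV <- c(low = k_lo, high = k_hi)
  ev$K_SV_se <- c(low = se_lo, high = se_hi)

  call <- function(label, constants = NULL, annotations = character()) {
    structure(list(label = label, constants = constants, evidence = ev,
                   annotations = annotations,
                   temperatures = c(series_low$temperature,
                                    series_high$temperature)),
              class = "mechanism_call")
  }

  both_linear <- curv_lo == "linear" && curv_hi == "linear"
  both_upward <- curv_lo == "upward" && curv_hi == "upward"

  if (both_linear) {
    if (is_negligible(lin_lo, negligible_r2) &&
        is_negligible(lin_hi, negligible_r2))
      return(call("negligible", c(K_SV_low = k_lo, K_SV_high = k_hi)))
    if (k_lo < 0 && k_hi < 0)
      return(call("enhancement", c(K_SV_low = k_lo, K_SV_high = k_hi),
                  "negative Stern-Volmer slope: intensity rises with cosolute"))
    trend_sig <- abs(k_hi - k_lo) > (se_lo + se_hi)
    if (!trend_sig)
      return(call("inconclusive", c(K_SV_low = k_lo, K_SV_high = k_hi),
                  "K_SV temperature difference within combined standard errors"))
    kq_nondecreasing <- !any(is.na(kq)) && kq[["high"]] >= kq[["low"]]
    if (k_hi > k_lo && kq_nondecreasing)
      return(call("dynamic", c(K_D_low = k_lo, K_D_high = k_hi)))
    if (k_hi < k_lo)
      return(call("static", c(K_S_low = k_lo, K_S_high = k_hi)))
    return(call("inconclusive", c(K_SV_low = k_lo, K_SV_high = k_hi),
                "K_SV rose with temperature but k_q decreased"))
  }

  if (both_upward) {
    comb_lo <- sv_fit(series_low, "combined")
    comb_hi <- sv_fit(series_high, "combined")
    ev$combined_fits <- list(low = comb_lo, high = comb_hi)
    if (comb_lo$converged) {
      roots <- sort(comb_lo$coefficients)
      return(structure(
        list(label = "combined",
             constants = c(K_lo = unname(roots[1]), K_hi = unname(roots[2])),
             evidence = ev,
             annotations = "root labels K_D/K_S require temperature evidence",
             temperatures = c(series_low$temperature,
                              series_high$temperature)),
        class = "mechanism_call"))
    }
    sph_lo <- sv_fit(series_low, "sphere")
    sph_hi <- sv_fit(series_high, "sphere")
    ev$sphere_fits <- list(low = sph_lo, high = sph_hi)
    if (sph_lo$converged) {
      return(structure(
        list(label = "sphere_of_action",
             constants = c(K_D = sph_lo$coefficients[["K_D"]],
                           V = sph_lo$coefficients[["V"]]),
             evidence = ev,
             annotations = "combined static/dynamic quadratic had no real solutions",
             temperatures = c(series_low$temperature,
                              series_high$temperature)),
        class = "mechanism_call"))
    }
    return(call("inconclusive", NULL,
                "upward curvature but neither nonlinear model converged"))
  }

  call("inconclusive", c(K_SV_low = k_lo, K_SV_high = k_hi),
       sprintf("curvature verdicts disagree across temperatures (%s vs %s)",
               curv_lo, curv_hi))
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("Quenching mechanism: %s (T = %g vs %g degC)\n", x$label,
              x$temperatures[1], x$temperatures[2]))
  if (!is.null(x$constants)) {
    cat("  constants (1/M):\n")
    for (nm in names(x$constants))
      cat(sprintf("    %s = %.4g\n", nm, x$constants[[nm]]))
  }
  if (length(x$annotations))
    cat("  note:", paste(x$annotations, collapse = "; "), "\n")
  invisible(x)
}

#' Summarise peak intensity over a temperature ramp
#'
#' Tabulates the peak emission intensity of a set of spectra recorded over
#' a temperature ramp, the percent change relative to the lowest
#' temperature, and whether the intensity decreases monotonically with
#' temperature (the expected signature of collisional quenching by
#' solvent). If a matched reference ramp (e.g. buffer-only) is supplied,
#' an enhancement flag reports whether the sample sits above the reference
#' at every temperature.
#'
#' @param spectra List of [emission_spectrum()] at >= 2 distinct
#'   temperatures.
#' @param range Wavelength window for [peak_intensity()].
#' @param reference Optional list of reference spectra at the same
#'   temperatures.
#' @return A data.frame with columns `temperature_C`, `peak_au`,
#'   `pct_change` (vs the lowest temperature) and, when a reference is
#'   given, `ref_peak_au`; attributes `monotone_decrease` and
#'   `enhancement` carry the flags.
#' @export
summarize_temperature_ramp <- function(spectra, range = c(290, 450),
                                       reference = NULL) {
  stopifnot(is.list(spectra), length(spectra) >= 2)
  temps <- vapply(spectra, function(s) s$temperature, numeric(1))
  if (length(unique(temps)) < 2)
    stop("temperature ramp needs at least 2 distinct temperatures")
  ord <- order(temps)
  temps <- temps[ord]
  peaks <- vapply(spectra[ord], peak_intensity, numeric(1), range = range)
  out <- data.frame(temperature_C = temps, peak_au = peaks,
                    pct_change = percent_decrease(peaks[1], peaks))
  monotone <- all(diff(peaks) < 0)
  enh <- NA
  if (!is.null(reference)) {
    rtemps <- vapply(reference, function(s) s$temperature, numeric(1))
    rord <- order(rtemps)
    if (!isTRUE(all.equal(rtemps[rord], temps)))
      stop("reference ramp temperatures do not match the sample ramp")
    rpeaks <- vapply(reference[rord], peak_intensity, numeric(1),
                     range = range)
    out$ref_peak_au <- rpeaks
    enh <- all(peaks > rpeaks)
  }
  structure(out, monotone_decrease = monotone, enhancement = enh)
}
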