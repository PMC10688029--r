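#' Describe a crowding agent
#'
#' @param name Crowder label (e.g. `"dextran 40"`).
#' @param molar_mass Molar mass in g/mol, > 0.
#' @param crowder_class `"monomer"` or `"polymer"`.
#' @param hydrodynamic_radius Hydrodynamic radius in Angstrom (optional).
#' @return A `crowder_spec` object.
#' @export
crowder_spec <- function(name, molar_mass,
                         crowder_class = c("monomer", "polymer"),
                         hydrodynamic_radius = NA_real_) {
  crowder_class <- match.arg(crowder_class)
  molar_mass <- as.numeric(molar_mass)
  if (!is.finite(molar_mass) || molar_mass <= 0)
    stop("molar_mass must be a positive number (g/mol)")
  structure(
    list(name = as.character(name), molar_mass = molar_mass,
         crowder_class = crowder_class,
         hydrodynamic_radius = as.numeric(hydrodynamic_radius)),
    class = "crowder_spec")
}

#' Convert mass concentration to molarity
#'
#' mg/mL is numerically g/L, so molarity is simply `conc / molar_mass`.
#'
#' @param conc Mass concentration in mg/mL (>= 0); vectorised.
#' @param crowder A [crowder_spec()].
#' @return Molar concentration in mol/L.
#' @examples
#' mass_to_molar(300, crowder_spec("dextran 40", 40000, "polymer")) # 0.0075 M
#' @export
mass_to_molar <- function(conc, crowder) {
  stopifnot(inherits(crowder, "crowder_spec"))
  conc <- as.numeric(conc)
  if (any(conc < 0)) stop("mass concentration must be non-negative")
  conc / crowder$molar_mass
}

#' Construct a quenching titration series
#'
#' Holds replicate-averaged fluorescence ratios F0/F against molar
#' quencher concentration at one temperature. The first concentration
#' must be 0 with a ratio of exactly 1 (F0/F0).
#'
#' @param concentrations Molar quencher concentrations, ascending, first
#'   element 0.
#' @param ratio_mean Mean F0/F per concentration (> 0); first element 1.
#' @param ratio_sd Standard deviation of F0/F per concentration (optional).
#' @param n_replicates Number of replicates behind each mean.
#' @param temperature Temperature in degrees Celsius.
#' @param crowder Optional [crowder_spec()] attached for reporting.
#' @return A `quenching_series` object.
#' @export
quenching_series <- function(concentrations, ratio_mean, ratio_sd = NULL,
                             n_replicates = 1L, temperature = 25,
                             crowder = NULL) {
  concentrations <- as.numeric(concentrations)
  ratio_mean <- as.numeric(ratio_mean)
  if (length(concentrations) != length(ratio_mean))
    stop("concentrations and ratio_mean must have equal length")
  if (any(diff(concentrations) <= 0))
    stop("concentrations must be strictly increasing")
  if (concentrations[1] != 0)
    stop("the series must start at zero quencher concentration")
  if (ratio_mean[1] != 1)
    stop("F0/F at zero concentration must equal 1 exactly")
  if (any(ratio_mean <= 0)) stop("F0/F ratios must be positive")
  if (!is.null(ratio_sd)) {
    ratio_sd <- as.numeric(ratio_sd)
    if (length(ratio_sd) != length(ratio_mean))
      stop("ratio_sd length mismatch")
  }
  if (!is.null(crowder)) stopifnot(inherits(crowder, "crowder_spec"))
  structure(
    list(concentrations = concentrations, ratio_mean = ratio_mean,
         ratio_sd = ratio_sd, n_replicates = as.integer(n_replicates),
         temperature = as.numeric(temperature), crowder = crowder),
    class = "quenching_series")
}

#' @export
print.quenching_series <- function(x, ...) {
  cat(sprintf("Quenching series: %d concentrations (0-%.4g M), T = %g degC%s\n",
              length(x$concentrations), max(x$concentrations), x$temperature,
              if (!is.null(x$crowder)) paste0(", ", x$crowder$name) else ""))
  df <- data.frame(conc_M = x$concentrations, F0_over_F = x$ratio_mean)
  if (!is.null(x$ratio_sd)) df$sd <- x$ratio_sd
  print(df, row.names = FALSE)
  invisible(x)
}

#' Reference excited-state lifetime model
#'
#' Stores the fluorophore's mean excited-state lifetime in the absence of
#' quencher at a reference temperature. For free tryptophan the literature
#' value is 3.1 ns at 25 degC.
#'
#' @param tau0_ref Lifetime at the reference temperature, in ns (> 0).
#' @param T_ref Reference temperature in degrees Celsius.
#' @return A `lifetime_model` object.
#' @export
lifetime_model <- function(tau0_ref = 3.1, T_ref = 25) {
  tau0_ref <- as.numeric(tau0_ref)
  if (!is.finite(tau0_ref) || tau0_ref <= 0) stop("tau0_ref must be > 0")
  structure(list(tau0_ref = tau0_ref, T_ref = as.numeric(T_ref)),
            class = "lifetime_model")
}

#' Unquenched lifetime at a given temperature
#'
#' Applies the halving convention used for free tryptophan: the lifetime is
#' assumed to halve when the temperature (degrees Celsius scale) doubles,
#' i.e. `tau0(T) = tau0_ref * T_ref / T`. This reproduces the working
#' values 3.1 ns at 25 degC and 1.55 ns at 50 degC. The rule is a reporting
#' convention on the Celsius scale, not a physical diffusion model; see the
#' package vignette for discussion.
#'
#' @param model A [lifetime_model()].
#' @param T Temperature in degrees Celsius (> 0).
#' @return Lifetime in ns.
#' @export
tau0_at_temperature <- function(model, T) {
  stopifnot(inherits(model, "lifetime_model"))
  T <- as.numeric(T)
  if (any(T <= 0)) stop("temperature must be positive on the Celsius scale")
  model$tau0_ref * (model$T_ref / T)
}

#' Bimolecular quenching rate constant
#'
#' `k_q = K_SV / tau0`, the collision-rate-limited quenching constant.
#' For a negative Stern-Volmer constant (fluorescence enhancement) no
#' physically meaningful rate exists and `NA` is returned with a warning,
#' mirroring the convention of leaving such table cells empty.
#'
#' @param K_SV Stern-Volmer constant in 1/M.
#' @param tau0 Unquenched lifetime in ns (> 0).
#' @return k_q in 1/(M ns), or `NA` for negative `K_SV`.
#' @export
bimolecular_rate <- function(K_SV, tau0) {
  tau0 <- as.numeric(tau0)
  if (any(tau0 <= 0)) stop("tau0 must be positive")
  K_SV <- as.numeric(K_SV)
  out <- K_SV / tau0
  if (any(K_SV < 0)) {
    warning("negative K_SV (enhancement): k_q undefined, returning NA")
    out[K_SV < 0] <- NA_real_
  }
  out
}

#' Goodness of fit as squared Pearson correlation
#'
#' The coefficient of determination used throughout this package is the
#' square of the Pearson correlation between observed and fitted values,
#' applicable to both linear and nonlinear fits.
#'
#' @param observed,fitted Numeric vectors of equal length >= 2 with
#'   nonzero variance.
#' @return r squared, in `[0, 1]`.
#' @export
r_squared <- function(observed, fitted) {
  observed <- as.numeric(observed)
  fitted <- as.numeric(fitted)
  if (length(observed) != length(fitted) || length(observed) < 2)
    stop("observed and fitted must have equal length >= 2")
  if (stats::var(observed) == 0 || stats::var(fitted) == 0)
    stop("r_squared undefined: zero variance in observed or fitted values")
  stats::cor(observed, fitted)^2
}

# r^2 that degrades to NA instead of erroring, for fit objects where the
# fitted values can legitimately be constant (e.g. K_SV = 0).
r_squared_or_na <- function(observed, fitted) {
  if (length(observed) < 2 || stats::var(observed) == 0 ||
      stats::var(fitted) == 0) return(NA_real_)
  stats::cor(observed, fitted)^2
}
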