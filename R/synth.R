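# Run code under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Mean-one multiplicative lognormal noise applied per replicate ratio, then
# averaged. The zero-concentration point stays exactly 1 (each replicate's
# ratio there is F0/F0).
noisy_ratio_series <- function(q, mu, noise_cv, n_replicates,
                               temperature = 25, crowder = NULL) {
  n <- length(q)
  if (noise_cv > 0) {
    sigma <- sqrt(log(1 + noise_cv^2))
    reps <- matrix(mu, n, n_replicates) *
      matrix(exp(stats::rnorm(n * n_replicates, -sigma^2 / 2, sigma)),
             n, n_replicates)
  } else {
    reps <- matrix(mu, n, n_replicates)
  }
  reps[1, ] <- 1
  quenching_series(q, rowMeans(reps),
                   ratio_sd = apply(reps, 1, stats::sd),
                   n_replicates = n_replicates,
                   temperature = temperature, crowder = crowder)
}

#' Configure a synthetic quenching experiment
#'
#' Collects everything needed to generate titration series mimicking the
#' bench protocol: a tryptophan solution titrated with a crowding agent
#' over 0-300 mg/mL in 50 mg/mL steps, measured in triplicate, with
#' multiplicative instrument noise of about 1 percent on each intensity
#' ratio.
#'
#' @param mechanism One of `"dynamic"`, `"static"`, `"combined"`,
#'   `"sphere_of_action"`, `"enhancement"`.
#' @param true_params Named list of generating constants in 1/M:
#'   `K_D` (dynamic / sphere / combined), `K_S` (static / combined),
#'   `V` (sphere), `K_SV` (enhancement; negative).
#' @param crowder A [crowder_spec()] used to convert the mass grid to
#'   molarity.
#' @param conc_grid Mass concentrations in mg/mL, must include 0.
#'   Default `seq(0, 300, 50)`.
#' @param temperatures Temperatures in degC; default `c(25, 50)`.
#' @param n_replicates Replicates per point; default 3.
#' @param noise_cv Fractional multiplicative noise; default 0.01.
#' @param seed Integer seed, mandatory when `noise_cv > 0`.
#' @return A `sim_config` object.
#' @export
sim_config <- function(mechanism = c("dynamic", "static", "combined",
                                     "sphere_of_action", "enhancement"),
                       true_params, crowder,
                       conc_grid = seq(0, 300, by = 50),
                       temperatures = c(25, 50),
                       n_replicates = 3L, noise_cv = 0.01, seed = NULL) {
  mechanism <- match.arg(mechanism)
  stopifnot(inherits(crowder, "crowder_spec"))
  if (!0 %in% conc_grid) stop("conc_grid must include 0 (the F0 baseline)")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (noise_cv > 0 && is.null(seed))
    stop("a seed is mandatory for stochastic simulation")
  needed <- switch(mechanism,
    dynamic = "K_D", static = "K_S", combined = c("K_D", "K_S"),
    sphere_of_action = c("K_D", "V"), enhancement = "K_SV")
  missing <- setdiff(needed, names(true_params))
  if (length(missing))
    stop("true_params missing: ", paste(missing, collapse = ", "))
  structure(
    list(mechanism = mechanism, true_params = true_params,
         crowder = crowder, conc_grid = sort(as.numeric(conc_grid)),
         temperatures = as.numeric(temperatures),
         n_replicates = as.integer(n_replicates),
         noise_cv = as.numeric(noise_cv), seed = seed),
    class = "sim_config")
}

# Noiseless F0/F from each mechanism's law at molar concentrations.
sv_law <- function(mechanism, params, q) {
  switch(mechanism,
    dynamic = 1 + params$K_D * q,
    static = 1 + params$K_S * q,
    enhancement = 1 + params$K_SV * q,
    combined = (1 + params$K_D * q) * (1 + params$K_S * q),
    sphere_of_action = (1 + params$K_D * q) * exp(params$V * q),
    stop("unknown mechanism: ", mechanism))
}

#' Simulate a Gaussian emission band
#'
#' Generates a smooth unimodal emission band on a wavelength grid,
#' emulating the tryptophan emission spectrum recorded over 290-450 nm.
#' On a grid symmetric about `center` the barycentric mean of the
#' noiseless band equals `center` to grid resolution.
#'
#' @param center Band centre in nm.
#' @param width Gaussian standard deviation in nm (> 0).
#' @param amplitude Peak intensity in AU.
#' @param grid Wavelength grid in nm; default `seq(290, 450, by = 0.5)`.
#' @param ... Metadata passed to [emission_spectrum()].
#' @return An `emission_spectrum`.
#' @export
simulate_spectrum <- function(center = 350, width = 25, amplitude = 1000,
                              grid = seq(290, 450, by = 0.5), ...) {
  if (width <= 0) stop("width must be positive")
  if (length(grid) < 2) stop("degenerate wavelength grid")
  emission_spectrum(grid, amplitude * exp(-(grid - center)^2 / (2 * width^2)),
                    ...)
}

#' Simulate a quenching titration series
#'
#' Computes noiseless F0/F from the configured mechanism's Stern-Volmer
#' law at the molar concentrations corresponding to the mass grid, applies
#' mean-one multiplicative lognormal noise per replicate, and averages
#' replicates. The zero-concentration ratio is 1 exactly. Output is fully
#' reproducible from `(config, seed)`.
#'
#' @param cfg A [sim_config()].
#' @param temperature Temperature label for the series (degC).
#' @param params Generating constants; defaults to `cfg$true_params`
#'   (overridden internally by [simulate_temperature_pair()]).
#' @param seed_offset Integer mixed into the seed so different series from
#'   one config are independent yet reproducible.
#' @return A [quenching_series()].
#' @export
simulate_series <- function(cfg, temperature = cfg$temperatures[1],
                            params = cfg$true_params, seed_offset = 0L) {
  stopifnot(inherits(cfg, "sim_config"))
  q <- mass_to_molar(cfg$conc_grid, cfg$crowder)
  mu <- sv_law(cfg$mechanism, params, q)
  seed <- if (is.null(cfg$seed)) NULL else (cfg$seed + seed_offset) %% 2147483647L
  with_seed(seed,
    noisy_ratio_series(q, mu, cfg$noise_cv, cfg$n_replicates,
                       temperature = temperature, crowder = cfg$crowder))
}

# Van't Hoff association enthalpy (kcal/mol) that maps K from K1 at T1 to
# K2 at T2 (Kelvin). Negative for an association weakening with temperature.
vant_hoff_enthalpy <- function(K1, K2, T1_K, T2_K) {
  -GAS_CONSTANT_KCAL * log(K2 / K1) / (1 / T2_K - 1 / T1_K)
}

# Default static-quenching enthalpy: calibrated so that K_S falls from
# 160 to 115 1/M between 25 and 50 degC (dextran-like behaviour).
static_default_enthalpy <- function()
  vant_hoff_enthalpy(160, 115, 298.15, 323.15)

# Scale a static association constant from T1 to T2 (degC) by van't Hoff.
scale_static_K <- function(K, T1, T2, dH = static_default_enthalpy()) {
  T1_K <- T1 + 273.15; T2_K <- T2 + 273.15
  K * exp(-dH / GAS_CONSTANT_KCAL * (1 / T2_K - 1 / T1_K))
}

# Scale a collisional constant from T1 to T2 (degC) by the Kelvin ratio
# (diffusion speeds up roughly with absolute temperature).
scale_dynamic_K <- function(K, T1, T2) K * (T2 + 273.15) / (T1 + 273.15)

#' Simulate a two-temperature titration pair
#'
#' Generates the low- and high-temperature series used for mechanism
#' discrimination. Generating constants given in `cfg$true_params` apply
#' at the lower temperature; at the higher temperature collisional
#' constants (`K_D`, and `K_SV` of an enhancer) are scaled up by the
#' Kelvin-temperature ratio, while the static association constant `K_S`
#' is scaled down by a van't Hoff factor whose default enthalpy is
#' calibrated to reproduce a 160 to 115 1/M reduction between 25 and
#' 50 degC. The sphere-of-action volume `V` is temperature-invariant.
#'
#' @param cfg A [sim_config()] whose `temperatures` has exactly 2 entries.
#' @return Named list with `low` and `high` [quenching_series()].
#' @export
simulate_temperature_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$temperatures) != 2)
    stop("simulate_temperature_pair needs exactly two temperatures")
  T1 <- min(cfg$temperatures); T2 <- max(cfg$temperatures)
  p1 <- cfg$true_params
  p2 <- p1
  if (!is.null(p2$K_D)) p2$K_D <- scale_dynamic_K(p2$K_D, T1, T2)
  if (!is.null(p2$K_SV)) p2$K_SV <- scale_dynamic_K(p2$K_SV, T1, T2)
  if (!is.null(p2$K_S)) p2$K_S <- scale_static_K(p2$K_S, T1, T2)
  list(low = simulate_series(cfg, temperature = T1, params = p1,
                             seed_offset = 0L),
       high = simulate_series(cfg, temperature = T2, params = p2,
                              seed_offset = 1000003L))
}

#' Simulate an emission temperature ramp
#'
#' Generates one spectrum per temperature over a ramp (default 25-70 degC
#' in 5 degC steps), with peak intensity attenuated as temperature rises
#' (collisional quenching by solvent increases with diffusion) and
#' optional multiplicative noise.
#'
#' @param temperatures Ramp in degC.
#' @param base_amplitude Peak intensity at the lowest temperature (AU).
#' @param attenuation Fractional intensity loss per degC (default 0.012,
#'   giving a roughly 50 percent loss over 25 to 70 degC).
#' @param center,width Band parameters passed to [simulate_spectrum()].
#' @param noise_cv Multiplicative noise on the amplitude; default 0.
#' @param seed Seed, required when `noise_cv > 0`.
#' @param ... Metadata passed to [emission_spectrum()].
#' @return List of `emission_spectrum`, one per temperature.
#' @export
simulate_temperature_ramp <- function(temperatures = seq(25, 70, by = 5),
                                      base_amplitude = 1000,
                                      attenuation = 0.012,
                                      center = 350, width = 25,
                                      noise_cv = 0, seed = NULL, ...) {
  if (noise_cv > 0 && is.null(seed))
    stop("a seed is mandatory for stochastic simulation")
  amps <- base_amplitude * exp(-attenuation * (temperatures - min(temperatures)))
  if (noise_cv > 0) {
    sigma <- sqrt(log(1 + noise_cv^2))
    amps <- with_seed(seed,
      amps * exp(stats::rnorm(length(amps), -sigma^2 / 2, sigma)))
  }
  mapply(function(a, tt)
           simulate_spectrum(center, width, a, temperature = tt, ...),
         amps, temperatures, SIMPLIFY = FALSE)
}
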