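#' Read a crowder registry
#'
#' A registry is a JSON array of objects with fields `name`,
#' `molar_mass` (g/mol), `class` (`"monomer"`/`"polymer"`) and optional
#' `Rh` (Angstrom).
#'
#' @param path Path to the JSON registry.
#' @return Named list of [crowder_spec()] keyed by crowder name.
#' @export
read_crowder_registry <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  specs <- lapply(raw, function(r)
    crowder_spec(r$name, r$molar_mass, r$class,
                 if (is.null(r$Rh)) NA_real_ else r$Rh))
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Built-in registry of the eight studied crowding agents
#'
#' The four monomer crowders (dextrose, sucrose, ethylene glycol,
#' 1-ethyl-2-pyrrolidone) and their polymers (dextran 40, ficoll 70,
#' PEG 8, PVP 40) with molar masses and literature hydrodynamic radii.
#'
#' @return Named list of [crowder_spec()].
#' @export
trp_crowders <- function() {
  read_crowder_registry(system.file("extdata", "crowders.json",
                                    package = "quenchr", mustWork = TRUE))
}

#' Read a titration table into quenching series
#'
#' Expects a CSV with header columns `crowder`, `temperature_C`,
#' `replicate`, `intensity_au`, and either `conc_mg_per_ml` (converted to
#' molarity through the registry) or `conc_M`. Rows are grouped by
#' crowder and temperature; within each group, F0 is each replicate's own
#' zero-concentration intensity, so per-concentration F0/F ratios are
#' paired per replicate before averaging.
#'
#' @param path CSV path, or a data.frame already in that layout.
#' @param registry Named list of [crowder_spec()], required when
#'   concentrations are given in mg/mL.
#' @return Named list of [quenching_series()] keyed `"crowder@T"`.
#' @export
read_titration_csv <- function(path, registry = NULL) {
  df <- if (is.data.frame(path)) path
        else utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("crowder", "temperature_C", "replicate", "intensity_au")
  if (!all(need %in% names(df)))
    stop("titration table must have columns: ",
         paste(need, collapse = ", "),
         " plus conc_mg_per_ml or conc_M")
  has_mass <- "conc_mg_per_ml" %in% names(df)
  has_molar <- "conc_M" %in% names(df)
  if (!has_mass && !has_molar)
    stop("titration table needs a conc_mg_per_ml or conc_M column")
  out <- list()
  if (nrow(df) == 0) return(out)
  for (cr in unique(df$crowder)) {
    spec <- NULL
    if (has_mass && !has_molar) {
      if (is.null(registry) || is.null(registry[[cr]]))
        stop("mass concentrations given but crowder '", cr,
             "' is not in the registry")
      spec <- registry[[cr]]
    } else if (!is.null(registry)) spec <- registry[[cr]]
    for (tt in sort(unique(df$temperature_C[df$crowder == cr]))) {
      g <- df[df$crowder == cr & df$temperature_C == tt, ]
      g$conc <- if (has_molar) g$conc_M else mass_to_molar(g$conc_mg_per_ml, spec)
      if (!any(g$conc == 0))
        stop("no zero-concentration baseline for '", cr, "' at ", tt,
             " degC: F0/F is undefined")
      concs <- sort(unique(g$conc))
      reps <- sort(unique(g$replicate))
      ratio <- matrix(NA_real_, length(concs), length(reps))
      for (j in seq_along(reps)) {
        gr <- g[g$replicate == reps[j], ]
        F0 <- mean(gr$intensity_au[gr$conc == 0])
        for (i in seq_along(concs)) {
          Fi <- mean(gr$intensity_au[gr$conc == concs[i]])
          ratio[i, j] <- F0 / Fi
        }
      }
      out[[paste0(cr, "@", tt)]] <- quenching_series(
        concs, rowMeans(ratio),
        ratio_sd = if (length(reps) > 1) apply(ratio, 1, stats::sd) else NULL,
        n_replicates = length(reps), temperature = tt, crowder = spec)
    }
  }
  out
}

#' Write a titration table
#'
#' Writes the long-format CSV dialect read by [read_titration_csv()]:
#' comma-separated, UTF-8, header mandatory, decimal point, units encoded
#' in column names.
#'
#' @param df Data.frame with the titration columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a free-energy cycle ledger
#'
#' CSV with columns `complex`, `dG_bind_gas`, `dGsolv_X`, `dGsolv_L`,
#' `dGsolv_complex` and the table's printed derived values
#' `published_ddG_solv`, `published_dG_aq` (all kcal/mol).
#'
#' @param path CSV path.
#' @return List with `rows` (list of [free_energy_components()]),
#'   `published_ddG_solv` and `published_dG_aq`.
#' @export
read_energy_ledger <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("complex", "dG_bind_gas", "dGsolv_X", "dGsolv_L",
            "dGsolv_complex", "published_ddG_solv", "published_dG_aq")
  if (!all(need %in% names(df)))
    stop("ledger must have columns: ", paste(need, collapse = ", "))
  rows <- lapply(seq_len(nrow(df)), function(i)
    free_energy_components(label = df$complex[i],
                           dG_bind_gas = df$dG_bind_gas[i],
                           dGsolv_complex = df$dGsolv_complex[i],
                           dGsolv_X = df$dGsolv_X[i],
                           dGsolv_L = df$dGsolv_L[i]))
  list(rows = rows, published_ddG_solv = df$published_ddG_solv,
       published_dG_aq = df$published_dG_aq)
}

#' Packaged free-energy ledgers for the studied complexes
#'
#' `monomer_cycle_ledger()` returns the indole-monomer table (dextrose,
#' sucrose, 1-ethyl-2-pyrrolidone, ethylene glycol);
#' `polymer_cycle_ledger()` the Trp-polymer table (dextran, ficoll, PVP,
#' PEG). Both are DFT-derived component energies shipped as plain CSV.
#'
#' @return See [read_energy_ledger()].
#' @export
monomer_cycle_ledger <- function()
  read_energy_ledger(system.file("extdata", "indole_monomer_cycle.csv",
                                 package = "quenchr", mustWork = TRUE))

#' @rdname monomer_cycle_ledger
#' @export
polymer_cycle_ledger <- function()
  read_energy_ledger(system.file("extdata", "trp_polymer_cycle.csv",
                                 package = "quenchr", mustWork = TRUE))

#' Published Stern-Volmer constants for the monomer crowders
#'
#' Linear Stern-Volmer constants (1/M) fitted at 25 and 50 degC for the
#' four monomer crowders, with goodness of fit, shipped as plain CSV.
#' Used to derive bimolecular quenching rate constants.
#'
#' @return Data.frame with columns `crowder`, `K_SV_25`, `r2_25`,
#'   `K_SV_50`, `r2_50`.
#' @export
monomer_sv_constants <- function()
  utils::read.csv(system.file("extdata", "monomer_sv_constants.csv",
                              package = "quenchr", mustWork = TRUE),
                  stringsAsFactors = FALSE)

#' Configure an end-to-end analysis
#'
#' @param titration Titration CSV path or data.frame
#'   (see [read_titration_csv()]).
#' @param registry Registry path or named list of [crowder_spec()];
#'   default the built-in [trp_crowders()].
#' @param spectra Optional named list per crowder, each with
#'   blank-corrected `with` and `without` [emission_spectrum()].
#' @param ledger Optional cycle-ledger CSV path or the result of
#'   [read_energy_ledger()].
#' @param lifetimes A [lifetime_model()].
#' @param range Integration window (nm) for spectral summaries.
#' @param alpha,min_r2_gain,negligible_r2 Classifier thresholds, see
#'   [classify_mechanism()].
#' @param audit_tolerance Tolerance (kcal/mol) for [audit_cycle_table()].
#' @param seed Seed recorded in the report for provenance.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(titration, registry = trp_crowders(),
                            spectra = NULL, ledger = NULL,
                            lifetimes = lifetime_model(3.1, 25),
                            range = c(290, 450), alpha = 0.05,
                            min_r2_gain = 0.01, negligible_r2 = 0.5,
                            audit_tolerance = 0.15, seed = 1L) {
  if (is.character(registry)) registry <- read_crowder_registry(registry)
  if (is.character(ledger)) ledger <- read_energy_ledger(ledger)
  structure(list(titration = titration, registry = registry,
                 spectra = spectra, ledger = ledger, lifetimes = lifetimes,
                 range = range, alpha = alpha, min_r2_gain = min_r2_gain,
                 negligible_r2 = negligible_r2,
                 audit_tolerance = audit_tolerance, seed = seed),
            class = "analysis_config")
}

#' Run the full quenching-mechanism analysis
#'
#' Orchestrates the pipeline per crowder: replicate statistics from the
#' titration table, linear fits at each temperature, bimolecular rate
#' constants, mechanism classification from the two-temperature contrast,
#' spectral summaries (percent intensity decrease, barycentric shift with
#' significance flag) when spectra are supplied, and the thermodynamic
#' cycle with the K_S to binding-free-energy cross-check when a ledger is
#' supplied. A failure in one crowder is captured in its report entry and
#' does not abort the batch. Identical inputs and seed give identical
#' reports.
#'
#' @param cfg An [analysis_config()].
#' @return A `quench_report`: named list per crowder of plain
#'   (JSON-serialisable) results; full fit and call objects are attached
#'   under each entry's `detail` element.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  df <- if (is.data.frame(cfg$titration)) cfg$titration
        else utils::read.csv(cfg$titration, stringsAsFactors = FALSE)
  report <- list()
  for (cr in unique(df$crowder)) {
    report[[cr]] <- tryCatch({
      series <- read_titration_csv(df[df$crowder == cr, , drop = FALSE],
                                   cfg$registry)
      temps <- sort(as.numeric(sub("^.*@", "", names(series))))
      ss <- lapply(temps, function(tt) series[[paste0(cr, "@", tt)]])
      entry <- list(crowder = cr, temperatures_C = temps)
      fits <- lapply(ss, sv_fit, model = "linear")
      entry$linear_K_SV <- stats::setNames(
        vapply(fits, function(f) f$coefficients[["K_SV"]], numeric(1)),
        paste0("T", temps))
      entry$linear_r2 <- stats::setNames(
        vapply(fits, function(f) f$r_squared, numeric(1)), paste0("T", temps))
      entry$k_q <- stats::setNames(suppressWarnings(vapply(
        seq_along(temps), function(i)
          bimolecular_rate(entry$linear_K_SV[[i]],
                           tau0_at_temperature(cfg$lifetimes, temps[i])),
        numeric(1))), paste0("T", temps))
      call <- NULL
      if (length(temps) >= 2) {
        call <- classify_mechanism(ss[[1]], ss[[length(ss)]],
                                   lifetimes = cfg$lifetimes,
                                   alpha = cfg$alpha,
                                   min_r2_gain = cfg$min_r2_gain,
                                   negligible_r2 = cfg$negligible_r2)
        entry$mechanism <- call$label
        entry$mechanism_constants <- as.list(call$constants)
        entry$mechanism_notes <- call$annotations
        if (call$label == "static") {
          ks <- call$constants[["K_S_low"]]
          if (ks > 0)
            entry$dG_bind_from_K_S_kcal <- binding_energy_from_K(
              ks, 273.15 + temps[1])
        }
      }
      s1 <- ss[[1]]
      entry$percent_decrease_max_conc <-
        100 * (1 - 1 / s1$ratio_mean[length(s1$ratio_mean)])
      if (!is.null(cfg$spectra[[cr]])) {
        sp <- cfg$spectra[[cr]]
        shift <- delta_bcm(sp$with, sp$without, cfg$range)
        entry$delta_bcm_nm <- shift$delta
        entry$delta_bcm_significant <- shift$significant
        entry$percent_decrease_spectral <- percent_decrease(
          peak_intensity(sp$without, cfg$range),
          peak_intensity(sp$with, cfg$range))
      }
      if (!is.null(cfg$ledger)) {
        labs <- vapply(cfg$ledger$rows, `[[`, character(1), "label")
        hit <- grep(cr, labs, fixed = TRUE)
        if (length(hit) == 1) {
          cyc <- thermo_cycle(cfg$ledger$rows[[hit]])
          entry$thermo <- list(dG_bind_gas = cyc$dG_bind_gas,
                               ddG_solv = cyc$ddG_solv,
                               dG_bind_aq = cyc$dG_bind_aq)
        }
      }
      entry$detail <- list(fits = fits, mechanism_call = call)
      entry
    }, error = function(e) list(crowder = cr, error = conditionMessage(e)))
  }
  structure(report, class = "quench_report", seed = cfg$seed)
}

#' Write an analysis report as JSON
#'
#' Serialises a [run_full_analysis()] report to JSON, dropping the
#' non-serialisable `detail` elements (full fit objects) but keeping every
#' numeric result and mechanism label.
#'
#' @param report A `quench_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  clean <- lapply(report, function(e) { e$detail <- NULL; e })
  jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
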