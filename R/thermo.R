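# Gas constant in kcal/(mol K)
GAS_CONSTANT_KCAL <- 1.987e-3

#' Bundle free-energy components of a binding cycle
#'
#' One fluorophore-crowder complex in the thermodynamic cycle that
#' decomposes the aqueous binding free energy into a gas-phase binding
#' term plus a solvation difference. Supply either the three gas-phase
#' free energies or a precomputed gas-phase binding free energy.
#' All energies in kcal/mol. `X` is the fluorophore (indole or Trp),
#' `L` the crowder ligand.
#'
#' @param label Complex label (e.g. `"indole-dextrose"`).
#' @param G_complex_gas,G_X_gas,G_L_gas Gas-phase free energies of the
#'   complex and the free species (kcal/mol), or `NA` if `dG_bind_gas`
#'   is given directly.
#' @param dG_bind_gas Precomputed gas-phase binding free energy.
#' @param dGsolv_complex,dGsolv_X,dGsolv_L Solvation free energies
#'   (kcal/mol).
#' @return A `free_energy_components` object.
#' @export
free_energy_components <- function(label = NA_character_,
                                   G_complex_gas = NA_real_,
                                   G_X_gas = NA_real_, G_L_gas = NA_real_,
                                   dG_bind_gas = NA_real_,
                                   dGsolv_complex = NA_real_,
                                   dGsolv_X = NA_real_,
                                   dGsolv_L = NA_real_) {
  gas_triple <- all(is.finite(c(G_complex_gas, G_X_gas, G_L_gas)))
  if (!gas_triple && !is.finite(dG_bind_gas))
    stop("supply either the gas-phase triple or a precomputed dG_bind_gas")
  structure(
    list(label = as.character(label),
         G_complex_gas = G_complex_gas, G_X_gas = G_X_gas,
         G_L_gas = G_L_gas, dG_bind_gas = dG_bind_gas,
         dGsolv_complex = dGsolv_complex, dGsolv_X = dGsolv_X,
         dGsolv_L = dGsolv_L),
    class = "free_energy_components")
}

#' Gas-phase binding free energy
#'
#' `G(complex, g) - G(X, g) - G(L, g)`; falls back to the precomputed
#' value when the gas triple is absent.
#'
#' @param c A [free_energy_components()].
#' @return Gas-phase binding free energy in kcal/mol.
#' @export
gas_binding_energy <- function(c) {
  stopifnot(inherits(c, "free_energy_components"))
  if (all(is.finite(c(c$G_complex_gas, c$G_X_gas, c$G_L_gas))))
    return(c$G_complex_gas - c$G_X_gas - c$G_L_gas)
  if (is.finite(c$dG_bind_gas)) return(c$dG_bind_gas)
  stop("gas-phase components missing")
}

#' Solvation free-energy difference of binding
#'
#' `dGsolv(complex) - dGsolv(X) - dGsolv(L)`: the solvation penalty (or
#' gain) of forming the complex relative to the separated species.
#'
#' @param c A [free_energy_components()].
#' @return Solvation difference in kcal/mol.
#' @export
solvation_delta <- function(c) {
  stopifnot(inherits(c, "free_energy_components"))
  if (!all(is.finite(c(c$dGsolv_complex, c$dGsolv_X, c$dGsolv_L))))
    stop("solvation components missing")
  c$dGsolv_complex - c$dGsolv_X - c$dGsolv_L
}

#' Aqueous-phase binding free energy
#'
#' Closes the thermodynamic cycle: the aqueous binding free energy is the
#' gas-phase binding free energy plus the solvation difference, exactly
#' additive by construction.
#'
#' @param dG_gas Gas-phase binding free energy (kcal/mol).
#' @param ddG_solv Solvation free-energy difference (kcal/mol).
#' @return Aqueous binding free energy in kcal/mol.
#' @export
aqueous_binding_energy <- function(dG_gas, ddG_solv) {
  stopifnot(is.finite(dG_gas), is.finite(ddG_solv))
  dG_gas + ddG_solv
}

#' Evaluate the full thermodynamic cycle
#'
#' @param c A [free_energy_components()].
#' @return A `cycle_result`: list with `dG_bind_gas`, `ddG_solv`,
#'   `dG_bind_aq` (kcal/mol).
#' @export
thermo_cycle <- function(c) {
  g <- gas_binding_energy(c)
  s <- solvation_delta(c)
  structure(list(label = c$label, dG_bind_gas = g, ddG_solv = s,
                 dG_bind_aq = aqueous_binding_energy(g, s)),
            class = "cycle_result")
}

#' @export
print.cycle_result <- function(x, ...) {
  cat(sprintf("%s: dG_bind(g) = %.1f, ddG_solv = %.1f, dG_bind(aq) = %.1f kcal/mol\n",
              ifelse(is.na(x$label), "cycle", x$label),
              x$dG_bind_gas, x$ddG_solv, x$dG_bind_aq))
  invisible(x)
}

#' Audit a published free-energy cycle table
#'
#' Recomputes the derived rows of a published cycle table from its own
#' printed components and flags cells that disagree beyond rounding.
#' The solvation difference is recomputed from the three printed
#' solvation energies; the aqueous binding energy is recomputed as the
#' printed gas-phase binding energy plus the *printed* solvation
#' difference (the summation actually used to produce that row), so the
#' two checks are independent. The default tolerance, 0.15 kcal/mol, is
#' the worst case from 0.05-rounding of three addends printed to one
#' decimal.
#'
#' @param rows List of [free_energy_components()], one per complex.
#' @param published_ddG_solv,published_dG_aq Numeric vectors of the
#'   table's printed derived values, aligned with `rows`.
#' @param tolerance Mismatch tolerance in kcal/mol.
#' @return A data.frame with one row per complex: recomputed and printed
#'   values and logical flags `ddG_solv_mismatch`, `dG_aq_mismatch`.
#' @export
audit_cycle_table <- function(rows, published_ddG_solv, published_dG_aq,
                              tolerance = 0.15) {
  stopifnot(is.list(rows),
            length(published_ddG_solv) == length(rows),
            length(published_dG_aq) == length(rows))
  recompute <- lapply(rows, function(r) {
    list(label = r$label,
         dG_gas = gas_binding_energy(r),
         ddG = solvation_delta(r))
  })
  out <- data.frame(
    label = vapply(recompute, `[[`, character(1), "label"),
    dG_bind_gas = vapply(recompute, `[[`, numeric(1), "dG_gas"),
    ddG_solv_recomputed = vapply(recompute, `[[`, numeric(1), "ddG"),
    ddG_solv_published = as.numeric(published_ddG_solv),
    dG_aq_published = as.numeric(published_dG_aq),
    stringsAsFactors = FALSE)
  out$dG_aq_recomputed <- out$dG_bind_gas + out$ddG_solv_published
  out$ddG_solv_mismatch <-
    abs(out$ddG_solv_recomputed - out$ddG_solv_published) > tolerance
  out$dG_aq_mismatch <-
    abs(out$dG_aq_recomputed - out$dG_aq_published) > tolerance
  out
}

#' Binding free energy from an association constant
#'
#' `dG = -RT ln K`, with R = 1.987e-3 kcal/(mol K) and K dimensionless
#' relative to a 1 M standard state. The static quenching constant K_S
#' can be equated to the association constant when the fluorophore is
#' much more dilute than the quencher, so a fitted K_S converts directly
#' to an apparent binding free energy.
#'
#' @param K Association constant in 1/M (> 0).
#' @param T Absolute temperature in K; default 298.15.
#' @return Binding free energy in kcal/mol.
#' @examples
#' binding_energy_from_K(160) # about -3.0 kcal/mol
#' @export
binding_energy_from_K <- function(K, T = 298.15) {
  if (any(K <= 0)) stop("association constant must be positive")
  if (any(T <= 0)) stop("temperature must be positive (Kelvin)")
  -GAS_CONSTANT_KCAL * T * log(K)
}

#' Association constant from a binding free energy
#'
#' Inverse of [binding_energy_from_K()]: `K = exp(-dG / RT)`.
#'
#' @param dG Binding free energy in kcal/mol.
#' @param T Absolute temperature in K.
#' @return Association constant (1/M at the 1 M standard state).
#' @export
K_from_binding_energy <- function(dG, T = 298.15) {
  if (any(T <= 0)) stop("temperature must be positive (Kelvin)")
  exp(-dG / (GAS_CONSTANT_KCAL * T))
}
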