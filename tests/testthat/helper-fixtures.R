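# Shared fixtures built in code.

registry <- trp_crowders()

# Noiseless series on the bench concentration grid (0-300 mg/mL by 50) for
# a given mechanism/crowder.
exact_series <- function(mechanism, params, crowder,
                         conc_mg = seq(0, 300, 50), temperature = 25) {
  q <- mass_to_molar(conc_mg, crowder)
  mu <- quenchr:::sv_law(mechanism, params, q)
  quenching_series(q, mu, temperature = temperature, crowder = crowder)
}

# Gaussian band sampled on a fine grid, translated by `shift` nm.
band <- function(center, shift = 0, grid = seq(290, 450, by = 0.1),
                 amplitude = 1000, width = 15) {
  simulate_spectrum(center + shift, width, amplitude, grid)
}
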