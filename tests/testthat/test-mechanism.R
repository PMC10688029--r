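test_that("curvature detection separates linear from upward-curved plots", {
  lin <- exact_series("dynamic", list(K_D = 0.444), registry$sucrose)
  expect_equal(as.character(detect_curvature(lin)), "linear")
  neg <- exact_series("enhancement", list(K_SV = -0.0325),
                      registry$`ethylene glycol`)
  expect_equal(as.character(detect_curvature(neg)), "linear")
  sph <- exact_series("sphere_of_action", list(K_D = 710, V = 486),
                      registry$`PVP 40`, conc_mg = seq(0, 100, 100 / 6))
  expect_equal(as.character(detect_curvature(sph)), "upward")
  expect_error(detect_curvature(quenching_series(c(0, 1, 2), c(1, 2, 3))),
               "at least 4")
})

test_that("classifier labels dynamic quenching from a rising K_SV and k_q", {
  cfg <- sim_config("dynamic", list(K_D = 0.444), registry$sucrose,
                    noise_cv = 0.01, seed = 101)
  pr <- simulate_temperature_pair(cfg)
  mc <- classify_mechanism(pr$low, pr$high)
  expect_equal(mc$label, "dynamic")
  expect_gt(mc$constants[["K_D_high"]], mc$constants[["K_D_low"]])
  expect_gte(mc$evidence$k_q[["high"]], mc$evidence$k_q[["low"]])
})

test_that("classifier labels static quenching from a falling K_S (160 to ~115)", {
  cfg <- sim_config("static", list(K_S = 160), registry$`dextran 40`,
                    noise_cv = 0.01, seed = 202)
  pr <- simulate_temperature_pair(cfg)
  mc <- classify_mechanism(pr$low, pr$high)
  expect_equal(mc$label, "static")
  expect_equal(mc$constants[["K_S_low"]], 160, tolerance = 0.05)
  expect_equal(mc$constants[["K_S_high"]], 115, tolerance = 0.05)
})

test_that("classifier falls through to sphere-of-action only after the combined fit fails", {
  cfg <- sim_config("sphere_of_action", list(K_D = 266, V = 137),
                    registry$`ficoll 70`, noise_cv = 0.01, seed = 303)
  pr <- simulate_temperature_pair(cfg)
  mc <- classify_mechanism(pr$low, pr$high)
  expect_equal(mc$label, "sphere_of_action")
  expect_false(mc$evidence$combined_fits$low$converged)
  expect_true("sphere_fits" %in% names(mc$evidence))
  # combined data with real positive roots must label combined, never sphere
  cfg2 <- sim_config("combined", list(K_D = 100, K_S = 400),
                     registry$`dextran 40`, noise_cv = 0, seed = NULL)
  s25 <- simulate_series(cfg2, 25)
  s50 <- quenching_series(s25$concentrations,
                          quenchr:::sv_law("combined",
                                           list(K_D = 108, K_S = 287),
                                           s25$concentrations),
                          temperature = 50, crowder = registry$`dextran 40`)
  mc2 <- suppressWarnings(classify_mechanism(s25, s50))
  expect_equal(mc2$label, "combined")
})

test_that("classifier labels enhancement and negligible quenching", {
  cfg <- sim_config("enhancement", list(K_SV = -0.0325),
                    registry$`ethylene glycol`, noise_cv = 0.01, seed = 404)
  pr <- simulate_temperature_pair(cfg)
  mc <- classify_mechanism(pr$low, pr$high)
  expect_equal(mc$label, "enhancement")
  expect_lt(mc$constants[["K_SV_low"]], 0)
  # PEG-like: tiny slope drowned in noise at both temperatures
  cfgn <- sim_config("dynamic", list(K_D = 0.05), registry$`PEG 8`,
                     noise_cv = 0.02, seed = 505)
  prn <- simulate_temperature_pair(cfgn)
  mcn <- classify_mechanism(prn$low, prn$high)
  expect_equal(mcn$label, "negligible")
})

test_that("conflicting curvature across temperatures yields inconclusive with all fits attached", {
  lin25 <- exact_series("dynamic", list(K_D = 50), registry$`ficoll 70`,
                        temperature = 25)
  sph50 <- exact_series("sphere_of_action", list(K_D = 266, V = 137),
                        registry$`ficoll 70`, temperature = 50)
  mc <- classify_mechanism(lin25, sph50)
  expect_equal(mc$label, "inconclusive")
  expect_match(mc$annotations, "disagree")
  expect_named(mc$evidence$linear_fits, c("low", "high"))
})

test_that("insignificant temperature trends are inconclusive, not a coin flip", {
  # same generating constant at both temperatures under 1% noise: the
  # apparent K_SV difference is within the combined standard errors
  cfg <- sim_config("dynamic", list(K_D = 0.444), registry$sucrose,
                    noise_cv = 0.01, seed = 1)
  s25 <- simulate_series(cfg, 25, seed_offset = 0L)
  s50 <- simulate_series(cfg, 50, seed_offset = 7L)
  mc <- classify_mechanism(s25, s50)
  expect_equal(mc$label, "inconclusive")
  expect_match(mc$annotations, "standard errors")
})

test_that("temperature ramp summary flags monotone decrease and enhancement", {
  ramp <- simulate_temperature_ramp()
  tab <- summarize_temperature_ramp(ramp)
  expect_equal(nrow(tab), 10)  # 25-70 degC in 5 degC steps
  expect_true(attr(tab, "monotone_decrease"))
  expect_equal(tab$pct_change[1], 0)
  expect_true(all(diff(tab$pct_change) > 0))
  # constant ramp: no change anywhere
  const <- lapply(c(25, 40, 55), function(tt)
    simulate_spectrum(350, 25, 800, temperature = tt))
  tc <- summarize_temperature_ramp(const)
  expect_true(all(tc$pct_change == 0))
  expect_false(attr(tc, "monotone_decrease"))
  # sample consistently above buffer-only reference -> enhancement flag
  buffer <- simulate_temperature_ramp(base_amplitude = 1000)
  eg <- simulate_temperature_ramp(base_amplitude = 1200)
  te <- summarize_temperature_ramp(eg, reference = buffer)
  expect_true(attr(te, "enhancement"))
})
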