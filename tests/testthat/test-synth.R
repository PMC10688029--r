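test_that("simulated Gaussian bands have the requested barycentre", {
  s <- simulate_spectrum(350, 25, 1000, grid = seq(250, 450, by = 0.5))
  expect_equal(barycentric_mean(s, c(250, 450)), 350, tolerance = 1e-6)
  z <- simulate_spectrum(350, 25, 0)
  expect_true(all(z$intensities == 0))
  ref <- simulate_spectrum(350, 15, 1000, grid = seq(290, 450, 0.1))
  shf <- simulate_spectrum(351.47, 15, 1000, grid = seq(290, 450, 0.1))
  expect_equal(delta_bcm(shf, ref)$delta, 1.47, tolerance = 0.02)
  expect_error(simulate_spectrum(350, 0), "width")
  expect_error(simulate_spectrum(350, 25, grid = 300), "degenerate")
})

test_that("seeded simulation is exactly reproducible and noiseless simulation exact", {
  cfg <- sim_config("dynamic", list(K_D = 0.444), registry$sucrose,
                    noise_cv = 0.01, seed = 77)
  a <- simulate_series(cfg, 25)
  b <- simulate_series(cfg, 25)
  expect_identical(a, b)
  expect_equal(a$ratio_mean[1], 1)
  cfg0 <- sim_config("dynamic", list(K_D = 0.444), registry$sucrose,
                     noise_cv = 0)
  s0 <- simulate_series(cfg0, 25)
  f0 <- sv_fit(s0, "linear")
  expect_equal(coef(f0)[["K_SV"]], 0.444, tolerance = 1e-12)
  cfgs <- sim_config("sphere_of_action", list(K_D = 266, V = 137),
                     registry$`ficoll 70`, noise_cv = 0)
  fs <- sv_fit(simulate_series(cfgs, 25), "sphere")
  expect_lt(abs(coef(fs)[["K_D"]] - 266) / 266, 1e-4)
  expect_lt(abs(coef(fs)[["V"]] - 137) / 137, 1e-4)
  # a seed is demanded whenever noise is requested
  expect_error(sim_config("dynamic", list(K_D = 1), registry$sucrose,
                          noise_cv = 0.01), "seed")
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  cfg <- sim_config("dynamic", list(K_D = 0.444), registry$sucrose,
                    noise_cv = 0.01, seed = 9)
  invisible(simulate_series(cfg, 25))
  expect_identical(.Random.seed, before)
})

test_that("temperature pair scales static K down (160 -> ~115) and dynamic K up", {
  cfg <- sim_config("static", list(K_S = 160), registry$`dextran 40`,
                    noise_cv = 0)
  pr <- simulate_temperature_pair(cfg)
  k25 <- coef(sv_fit(pr$low, "linear"))[["K_SV"]]
  k50 <- coef(sv_fit(pr$high, "linear"))[["K_SV"]]
  expect_equal(k25, 160, tolerance = 1e-10)
  expect_equal(k50, 115, tolerance = 1e-6)  # van't Hoff calibration point
  cfgd <- sim_config("dynamic", list(K_D = 0.444), registry$sucrose,
                     noise_cv = 0)
  prd <- simulate_temperature_pair(cfgd)
  kd50 <- coef(sv_fit(prd$high, "linear"))[["K_SV"]]
  expect_equal(kd50, 0.444 * 323.15 / 298.15, tolerance = 1e-10)
  # equal temperatures give identical series
  cfge <- sim_config("dynamic", list(K_D = 0.444), registry$sucrose,
                     temperatures = c(25, 25), noise_cv = 0)
  expect_error(simulate_temperature_pair(
    sim_config("dynamic", list(K_D = 1), registry$sucrose,
               temperatures = c(25), noise_cv = 0)), "two temperatures")
  pre <- simulate_temperature_pair(cfge)
  expect_equal(pre$low$ratio_mean, pre$high$ratio_mean)
})

test_that("noisy parameter recovery is nearly unbiased at the default noise level", {
  # 60 seeded replicates of the bench design; bias < 2%
  ks <- vapply(1:60, function(i) {
    cfg <- sim_config("static", list(K_S = 160), registry$`dextran 40`,
                      noise_cv = 0.01, seed = 7000 + i)
    coef(sv_fit(simulate_series(cfg, 25), "linear"))[["K_SV"]]
  }, numeric(1))
  expect_lt(abs(mean(ks) - 160) / 160, 0.02)
})

test_that("simulate method on a fit reproduces the fitted law", {
  s <- exact_series("dynamic", list(K_D = 0.444), registry$sucrose)
  f <- sv_fit(s, "linear")
  sims <- simulate(f, nsim = 3, seed = 12, noise_cv = 0.01)
  expect_length(sims, 3)
  for (ss in sims) {
    expect_s3_class(ss, "quenching_series")
    expect_equal(ss$ratio_mean[1], 1)
    expect_equal(ss$ratio_mean, fitted(f), tolerance = 0.05)
  }
})
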