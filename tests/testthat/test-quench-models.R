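test_that("mass-to-molar conversion reproduces the bench molarities to 3 sig figs", {
  # (crowder, mg/mL, expected M) for the working concentrations
  cases <- list(
    list("dextrose", 300, 1.67), list("sucrose", 300, 0.876),
    list("ethylene glycol", 300, 4.83), list("1-ethyl-2-pyrrolidone", 300, 2.65),
    list("dextran 40", 300, 0.00750), list("ficoll 70", 300, 0.00429),
    list("PEG 8", 300, 0.0375), list("PVP 40", 100, 0.0025))
  for (cs in cases) {
    got <- mass_to_molar(cs[[2]], registry[[cs[[1]]]])
    expect_equal(signif(got, 3), cs[[3]], info = cs[[1]])
  }
  expect_equal(mass_to_molar(0, registry$sucrose), 0)
  expect_error(mass_to_molar(-1, registry$sucrose), "non-negative")
})

test_that("linear Stern-Volmer fit recovers exact slopes, including enhancement", {
  q <- seq(0, 0.9, length.out = 7)
  pos <- sv_fit(quenching_series(q, 1 + 0.444 * q), "linear")
  expect_equal(coef(pos)[["K_SV"]], 0.444, tolerance = 1e-12)
  expect_equal(pos$r_squared, 1, tolerance = 1e-12)
  neg <- sv_fit(quenching_series(q, 1 - 0.0325 * q), "linear")
  expect_equal(coef(neg)[["K_SV"]], -0.0325, tolerance = 1e-12)
  flat <- sv_fit(quenching_series(q, rep(1, 7)), "linear")
  expect_equal(coef(flat)[["K_SV"]], 0)
  expect_true(is.na(flat$r_squared))
  expect_error(sv_fit(quenching_series(c(0, 0.1), c(1, 1.1)), "linear"),
               "at least 3")
})

test_that("combined fit round-trips K_D/K_S and reduces to linear when K_S = 0", {
  s <- exact_series("combined", list(K_D = 2, K_S = 3), registry$sucrose)
  f <- suppressWarnings(sv_fit(s, "combined"))
  expect_true(f$converged)
  expect_equal(sort(unname(coef(f))), c(2, 3), tolerance = 1e-8)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  # root pair satisfies sum = b, product = c
  expect_equal(sum(coef(f)), unname(f$quad[["b"]]), tolerance = 1e-8)
  expect_equal(prod(coef(f)), unname(f$quad[["c"]]), tolerance = 1e-8)
  # K_S = 0 degenerates to the linear model
  s0 <- exact_series("dynamic", list(K_D = 0.444), registry$sucrose)
  f0 <- suppressWarnings(sv_fit(s0, "combined"))
  flin <- sv_fit(s0, "linear")
  expect_equal(min(coef(f0)), 0, tolerance = 1e-8)
  expect_equal(max(coef(f0)), coef(flin)[["K_SV"]], tolerance = 1e-6)
})

test_that("combined fit reports no real solutions on sphere-of-action data", {
  for (nm in c("ficoll 70", "PVP 40")) {
    p <- if (nm == "ficoll 70") list(K_D = 266, V = 137) else list(K_D = 710, V = 486)
    s <- exact_series("sphere_of_action", p, registry[[nm]],
                      conc_mg = if (nm == "PVP 40") seq(0, 100, 100 / 6)
                                else seq(0, 300, 50))
    f <- sv_fit(s, "combined")
    expect_false(f$converged)
    expect_match(f$reason, "no real solutions")
  }
})

test_that("sphere-of-action fit recovers generating constants to < 1e-4 relative error", {
  cases <- list(list("ficoll 70", 266, 137, seq(0, 300, 50)),
                list("PVP 40", 710, 486, seq(0, 100, 100 / 6)))
  for (cs in cases) {
    s <- exact_series("sphere_of_action", list(K_D = cs[[2]], V = cs[[3]]),
                      registry[[cs[[1]]]], conc_mg = cs[[4]])
    f <- sv_fit(s, "sphere")
    expect_true(f$converged)
    expect_lt(abs(coef(f)[["K_D"]] - cs[[2]]) / cs[[2]], 1e-4)
    expect_lt(abs(coef(f)[["V"]] - cs[[3]]) / cs[[3]], 1e-4)
    expect_gt(f$r_squared, 0.9999)
  }
  # V = 0 degenerates to the linear model
  s0 <- exact_series("dynamic", list(K_D = 160), registry$`dextran 40`)
  f0 <- sv_fit(s0, "sphere")
  expect_equal(coef(f0)[["V"]], 0, tolerance = 1e-6)
  expect_equal(coef(f0)[["K_D"]], coef(sv_fit(s0, "linear"))[["K_SV"]],
               tolerance = 1e-4)
})

test_that("noiseless simulate-fit round trips are exact for every model family", {
  fams <- list(
    list(mech = "dynamic", params = list(K_D = 0.444), model = "linear",
         crowder = registry$sucrose, truth = c(K_SV = 0.444)),
    list(mech = "static", params = list(K_S = 160), model = "linear",
         crowder = registry$`dextran 40`, truth = c(K_SV = 160)),
    list(mech = "enhancement", params = list(K_SV = -0.0325), model = "linear",
         crowder = registry$`ethylene glycol`, truth = c(K_SV = -0.0325)),
    list(mech = "combined", params = list(K_D = 5, K_S = 40), model = "combined",
         crowder = registry$`dextran 40`, truth = c(K_lo = 5, K_hi = 40)),
    list(mech = "sphere_of_action", params = list(K_D = 266, V = 137),
         model = "sphere", crowder = registry$`ficoll 70`,
         truth = c(K_D = 266, V = 137)))
  grid <- seq(0, 300, by = 50)  # 7 concentrations
  for (fm in fams) {
    s <- exact_series(fm$mech, fm$params, fm$crowder, conc_mg = grid)
    f <- suppressWarnings(sv_fit(s, fm$model))
    expect_true(f$converged, info = fm$mech)
    got <- coef(f)[names(fm$truth)]
    expect_lt(max(abs(got - fm$truth) / pmax(abs(fm$truth), 1e-12)), 1e-4)
  }
})

test_that("bimolecular rate reproduces printed k_q cells from K_SV and tau0", {
  lt <- lifetime_model(3.1, 25)
  tau25 <- tau0_at_temperature(lt, 25)
  tau50 <- tau0_at_temperature(lt, 50)
  expect_equal(tau25, 3.1)
  expect_equal(tau50, 1.55)
  expect_equal(round(bimolecular_rate(0.444, tau25), 3), 0.143)  # sucrose 25C
  expect_equal(round(bimolecular_rate(0.241, tau50), 3), 0.155)  # sucrose 50C
  expect_equal(round(bimolecular_rate(0.254, tau25), 4), 0.0819) # EP 25C
  expect_equal(round(bimolecular_rate(0.0415, tau25), 4), 0.0134) # dextrose 25C
  # EP 50C printed value carries input rounding; agree within 0.5%
  expect_equal(bimolecular_rate(0.138, tau50), 0.0888, tolerance = 0.005)
  expect_equal(bimolecular_rate(0, 3.1), 0)
  expect_true(is.na(suppressWarnings(bimolecular_rate(-0.03, 3.1))))
  expect_error(bimolecular_rate(0.4, 0), "positive")
})

test_that("lifetime halves when the Celsius temperature doubles", {
  lt <- lifetime_model(3.1, 25)
  expect_equal(tau0_at_temperature(lt, 50), 1.55)
  expect_equal(tau0_at_temperature(lt, 25), 3.1)
  expect_equal(tau0_at_temperature(lt, 100), 0.775)
  expect_error(tau0_at_temperature(lt, -5), "positive")
})

test_that("r_squared is the squared Pearson correlation", {
  set.seed(3)
  obs <- rnorm(20); fit <- 0.6 * obs + rnorm(20, sd = 0.3)
  # independent Pearson formula oracle
  oracle <- (sum((obs - mean(obs)) * (fit - mean(fit))) /
             sqrt(sum((obs - mean(obs))^2) * sum((fit - mean(fit))^2)))^2
  expect_equal(r_squared(obs, fit), oracle)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(c(-1, 1, -1, 1), c(1, 1, -1, -1)), 0)  # orthogonal
  expect_error(r_squared(obs, rep(1, 20)), "zero variance")
})

test_that("predict/fitted/residuals methods are coherent", {
  s <- exact_series("sphere_of_action", list(K_D = 266, V = 137),
                    registry$`ficoll 70`)
  f <- sv_fit(s, "sphere")
  expect_equal(predict(f), fitted(f), tolerance = 1e-8)
  expect_equal(residuals(f), s$ratio_mean - fitted(f))
  expect_equal(predict(f, 0), 1)
})
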