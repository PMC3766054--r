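test_that("noiseless chemostat generation inverts exactly through the analysis", {
  for (cond in c("reference_n2", "reference_co2", "prk_rubisco_n2",
                 "prk_rubisco_co2")) {
    cfg <- chemostat_fixture(cond)
    rec <- generate_chemostat(cfg, noise_sd = 0)
    y <- chemostat_yields(rec, cfg$params)
    expect_equal(mean(y$Y_biomass), cfg$Y_biomass, tolerance = 1e-6)
    expect_equal(mean(y$Y_ethanol), cfg$Y_ethanol, tolerance = 1e-6)
    expect_equal(mean(y$Y_glycerol), cfg$Y_glycerol, tolerance = 1e-6)
  }
})

test_that("generated off-gas CO2 inverts through net_co2_evolution", {
  cfg <- chemostat_fixture("reference_n2")
  rec <- generate_chemostat(cfg, noise_sd = 0, replicates = 1)
  evo <- net_co2_evolution(rec)
  # reconstruct the condition's net CO2 yield per mol hexose
  consumed_mol <- (24.8 / 180)
  y_co2 <- evo$co2_evolution / 1000 / (0.05 * consumed_mol)
  expect_gt(y_co2, 1.5)   # fermentative CO2 plus biosynthetic release
  expect_lt(y_co2, 2.2)
  # CO2-sparged conditions report a small fraction increment over 10%
  cfg2 <- chemostat_fixture("prk_rubisco_co2")
  rec2 <- generate_chemostat(cfg2, noise_sd = 0, replicates = 1)
  expect_gt(rec2$co2_out, 0.10)
  expect_lt(rec2$co2_out - 0.10, 0.02)
})

test_that("the seeding contract gives reproducible, replicate-distinct records", {
  cfg <- chemostat_fixture("reference_n2")
  a <- generate_chemostat(cfg, noise_sd = 0.01, seed = 11)
  b <- generate_chemostat(cfg, noise_sd = 0.01, seed = 11)
  c_ <- generate_chemostat(cfg, noise_sd = 0.01, seed = 12)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$ethanol, c_$ethanol)))
  expect_false(isTRUE(all.equal(a$ethanol[1], a$ethanol[2])))  # distinct streams
  bb <- generate_batch(batch_fixture("reference"), seed = 3)
  bb2 <- generate_batch(batch_fixture("reference"), seed = 3)
  expect_identical(bb, bb2)
})

test_that("measurement-noise propagation matches the nominal relative sd", {
  cfg <- chemostat_fixture("reference_n2")
  rec <- generate_chemostat(cfg, noise_sd = 0.01, replicates = 1000, seed = 42)
  y <- chemostat_yields(rec, cfg$params)
  expect_equal(sd(y$Y_ethanol) / mean(y$Y_ethanol), 0.01, tolerance = 0.2)
})

test_that("noiseless batch generation round-trips yields and growth kinetics", {
  for (strain in c("reference", "prk_rubisco")) {
    cfg <- batch_fixture(strain)
    ser <- generate_batch(cfg, noise_sd = 0, replicates = 1)
    y <- batch_yields(ser, cfg$params)
    expect_equal(y$Y_ethanol, cfg$Y_ethanol, tolerance = 1e-3)
    expect_equal(y$Y_glycerol, cfg$Y_glycerol, tolerance = 1e-3)
    expect_equal(y$Y_biomass, cfg$Y_biomass_mass, tolerance = 1e-3)
    fit <- fit_growth_rate(ser)
    expect_equal(fit$mu_max, cfg$mu_max, tolerance = 0.02)
  }
  # the two strains differ by the configured 10 h lag
  f1 <- fit_growth_rate(generate_batch(batch_fixture("reference"),
                                       noise_sd = 0, replicates = 1))
  f2 <- fit_growth_rate(generate_batch(batch_fixture("prk_rubisco"),
                                       noise_sd = 0, replicates = 1))
  expect_equal(f2$lag_time - f1$lag_time, 10, tolerance = 0.5)
})

test_that("generated data close carbon and electron recovery", {
  cfg <- chemostat_fixture("prk_rubisco_co2")
  rec <- generate_chemostat(cfg, noise_sd = 0, replicates = 1)
  y <- chemostat_yields(rec, cfg$params)
  evo <- net_co2_evolution(rec)
  y_co2 <- evo$co2_evolution / 1000 / (0.05 * 24.8 / 180)
  # parameters as reconciled for this condition
  cp <- redoxferm:::condition_params(cfg)
  bc <- balance_check(y, co2_yield = y_co2, params = cp$params)
  expect_equal(bc$carbon_recovery, 1, tolerance = 1e-6)
  expect_equal(bc$electron_recovery, 1, tolerance = 1e-6)
  expect_true(bc$pass)
})

test_that("flat series come out of a zero-growth-rate configuration", {
  cfg <- batch_fixture("reference")
  cfg$mu_max <- 0
  ser <- generate_batch(cfg, noise_sd = 0, replicates = 1)
  expect_equal(var(ser$biomass), 0)
  expect_equal(var(ser$sugar), 0)
  expect_equal(max(ser$ethanol), 0)
  cfg$inoculum <- 0
  expect_error(generate_batch(cfg), "inoculum")
})

test_that("simulating from a fitted model feeds the analysis pipeline", {
  fit <- redox_model(yield_set(0.083, 1.56, 0.14))
  rec <- simulate(fit, nsim = 2, seed = 4, mode = "reference",
                  noise_sd = 0)
  y <- chemostat_yields(rec, fit$params)
  expect_equal(mean(y$Y_glycerol), 0.14, tolerance = 1e-6)
  ser <- simulate(fit, nsim = 1, seed = 4, mode = "prk_rubisco",
                  type = "batch", noise_sd = 0)
  yb <- batch_yields(ser, fit$params)
  expect_equal(yb$Y_glycerol, 0, tolerance = 1e-6)
  expect_gt(yb$Y_ethanol, 1.65)
})

test_that("records survive a write/read round trip", {
  cfg <- chemostat_fixture("reference_n2")
  rec <- generate_chemostat(cfg, noise_sd = 0.01, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_records(rec, f)
  back <- read_chemostat_records(f)
  expect_equal(as.data.frame(back), as.data.frame(rec), tolerance = 1e-12)
  ser <- generate_batch(batch_fixture("reference"), seed = 2)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_records(ser, f2)
  expect_equal(as.data.frame(read_batch_series(f2)), as.data.frame(ser),
               tolerance = 1e-12)
})
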