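test_that("the PRK/Rubisco route stoichiometry is the documented linear map", {
  d1 <- rubisco_route_stoichiometry(1)
  expect_equal(d1[["ethanol"]], 2)
  expect_equal(d1[["nadh"]], -2)
  expect_equal(d1[["co2_fixed"]], 1)
  expect_equal(d1[["co2_emitted"]], 2)
  expect_equal(d1[["co2_net"]], 1)
  expect_equal(d1[["atp"]], 1)  # 2 pyruvate-kinase ATP minus 1 PRK ATP
  expect_equal(rubisco_route_stoichiometry(0), 0 * d1)
  expect_equal(rubisco_route_stoichiometry(7), 7 * d1)
  expect_error(rubisco_route_stoichiometry(-1), "v_rubisco")
})

test_that("Ru5P allocation prefers the oxidative PPP up to the NADPH demand", {
  expect_equal(allocate_ru5p(10, 30), c(v_oxppp = 10, v_nonoxppp = 0))
  expect_equal(allocate_ru5p(10, 8), c(v_oxppp = 4, v_nonoxppp = 6))
  # reference-style operation: NADPH balance closes, surplus Ru5P recycled
  expect_equal(allocate_ru5p(0, 6, recycle = TRUE),
               c(v_oxppp = 3, v_nonoxppp = -3))
  # both conventions agree whenever demand covers the NADPH-matched oxPPP
  expect_equal(allocate_ru5p(10, 8, recycle = TRUE), allocate_ru5p(10, 8))
  expect_error(allocate_ru5p(-1, 2), "ru5p_demand")
})

test_that("zero-growth reference scenario is pure alcoholic fermentation", {
  fd <- solve_scenario(stoich_params(y_atp = 0), "reference")
  expect_equal(fd$ethanol_out, 200)
  expect_equal(fd$glycerol_out, 0)
  expect_equal(fd$co2_net, 200)
  expect_equal(fd$fluxes[["v_biomass"]], 0)
})

test_that("all four balances and the electron balance close for every solved scenario", {
  set.seed(101)
  for (i in 1:40) {
    p <- random_stoich_params()
    for (mode in c("reference", "prk_rubisco")) {
      fd <- solve_scenario(p, mode)
      expect_lt(max(abs(fd$residuals[c("carbon", "nadh", "nadph", "atp",
                                       "normalization")])), 1e-9 * 100)
      expect_lt(abs(fd$residuals[["electron"]]), 1e-6 * 100)
      expect_true(all(fd$fluxes[c("v_ferment", "v_glycerol", "v_oxppp",
                                  "v_rubisco", "v_biomass")] >= 0))
    }
    # capacity-capped scenarios close too
    fd <- solve_scenario(p, "prk_rubisco", rubisco_capacity = 3)
    expect_lt(max(abs(fd$residuals[c("carbon", "nadh", "nadph", "atp")])),
              1e-9 * 100)
  }
})

test_that("glycerol falls and ethanol rises monotonically with Rubisco capacity", {
  p <- stoich_params()
  caps <- c(0, 1, 2, 4, 6, 8, Inf)
  sols <- lapply(caps, function(cc)
    solve_scenario(p, "prk_rubisco", rubisco_capacity = cc))
  eth <- vapply(sols, function(s) s$ethanol_out, numeric(1))
  gly <- vapply(sols, function(s) s$glycerol_out, numeric(1))
  expect_true(all(diff(eth) >= -1e-9))
  expect_true(all(diff(gly) <= 1e-9))
  expect_equal(gly[length(gly)], 0)
  # zero capacity reproduces the reference scenario exactly
  ref <- solve_scenario(p, "reference")
  expect_equal(sols[[1]]$ethanol_out, ref$ethanol_out)
  expect_equal(sols[[1]]$glycerol_out, ref$glycerol_out)
})

test_that("dissolved CO2 caps the Rubisco flux through the saturation factor", {
  p <- stoich_params()
  full <- solve_scenario(p, "prk_rubisco", rubisco_capacity = 10)
  half <- solve_scenario(p, "prk_rubisco", co2_dissolved = p$K_co2,
                         rubisco_capacity = 10)
  expect_equal(half$fluxes[["v_rubisco"]], 5, tolerance = 1e-9)
  none <- solve_scenario(p, "prk_rubisco", co2_dissolved = 0,
                         rubisco_capacity = 10)
  expect_equal(none$glycerol_out,
               solve_scenario(p, "reference")$glycerol_out)
  expect_lt(half$glycerol_out, none$glycerol_out)
  expect_gt(full$fluxes[["v_rubisco"]], half$fluxes[["v_rubisco"]])
})

test_that("infeasible parameterisations raise an error naming a balance", {
  # ATP-consuming catabolism cannot support the ATP-coupled biomass flux
  p <- stoich_params(atp_coeffs = list(ferment = -2))
  err <- tryCatch(solve_scenario(p, "reference"), error = identity)
  expect_s3_class(err, "redoxferm_infeasible")
  expect_match(conditionMessage(err), "balance")
})

test_that("yield conversion uses the hexose and biomass mass bases", {
  p <- stoich_params()
  fd <- solve_scenario(p, "reference")
  y <- predict_yields(fd, p)
  expect_equal(y$Y_ethanol, fd$ethanol_out / 100)
  expect_equal(y$Y_glycerol, fd$glycerol_out / 100)
  expect_equal(y$Y_biomass,
               fd$fluxes[["v_biomass"]] * 24.6 / (100 * 180))
  # frozen spot value: 60.7 Cmol per 100 mmol hexose at 24.6 g/Cmol
  expect_equal(60.7 * 24.6 / (100 * 180), 0.0829567, tolerance = 1e-6)
})

test_that("flux tables are written with a stable column order", {
  f <- withr::local_tempfile(fileext = ".tsv")
  fd <- solve_scenario(stoich_params(), "prk_rubisco")
  out <- write_flux_distribution(fd, f)
  back <- read.delim(f)
  expect_equal(names(back)[1:6],
               c("v_ferment", "v_glycerol", "v_oxppp", "v_nonoxppp",
                 "v_rubisco", "v_biomass"))
  expect_equal(back$ethanol_out, fd$ethanol_out)
})
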