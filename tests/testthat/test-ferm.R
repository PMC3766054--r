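make_record <- function(ethanol = 8.6, glycerol = 1.79, biomass = 2.08,
                        glucose_res = 0.1, galactose_res = 0.1,
                        co2_in = 0, co2_out = 0.0089, gas_flow = 30,
                        D = 0.05, id = 1) {
  data.frame(replicate_id = id, dilution_rate = D, glucose_in = 12.5,
             galactose_in = 12.5, glucose_res = glucose_res,
             galactose_res = galactose_res, biomass = biomass,
             ethanol = ethanol, glycerol = glycerol, gas_flow = gas_flow,
             co2_in = co2_in, co2_out = co2_out)
}

test_that("chemostat evaporation correction is the steady-state factor (D+k)/D", {
  expect_equal(correct_evaporation_chemostat(10, 0.05, 0.008),
               10 * 0.058 / 0.05)
  expect_equal(correct_evaporation_chemostat(7.3, 0.05, 0), 7.3)  # identity
  expect_equal(correct_evaporation_chemostat(0, 0.1, 0.008), 0)
  expect_error(correct_evaporation_chemostat(1, 0, 0.008), "dilution_rate")
})

test_that("batch evaporation correction reconstructs cumulative production", {
  tt <- seq(0, 10, by = 0.5)
  cc <- rep(4, length(tt))
  expect_equal(correct_evaporation_batch(tt, cc, 0), cc)          # identity
  # constant concentration: produced(t) = C (1 + k t) in closed form
  expect_equal(correct_evaporation_batch(tt, cc, 0.008),
               4 * (1 + 0.008 * tt))
  # true production known by construction: dC/dt = p - kC from C(0)=0
  k <- 0.008; p <- 0.6
  fine <- seq(0, 30, by = 0.001)
  conc <- p / k * (1 - exp(-k * fine))
  grid <- seq(0, 30, by = 1)
  est <- correct_evaporation_batch(grid, p / k * (1 - exp(-k * grid)), k)
  expect_equal(est[length(est)], p * 30, tolerance = 1e-4)
  expect_error(correct_evaporation_batch(c(0, 2, 1), c(1, 1, 1), k),
               "increasing")
})

test_that("chemostat yields use pooled hexose moles and correct evaporation", {
  rec <- make_record()
  y <- chemostat_yields(rec, stoich_params())
  consumed_g <- 24.8
  expect_equal(y$Y_biomass, 2.08 / consumed_g)
  expect_equal(y$Y_ethanol,
               (8.6 * 0.058 / 0.05 / 46.07) / (consumed_g / 180))
  expect_equal(y$Y_glycerol, (1.79 / 92.09) / (consumed_g / 180))
  expect_true(attr(y, "corrected"))
  # correction can be disabled
  y0 <- chemostat_yields(rec, stoich_params(), correct_evaporation = FALSE)
  expect_equal(y0$Y_ethanol, (8.6 / 46.07) / (consumed_g / 180))
  # zero products give zero yields
  z <- chemostat_yields(make_record(ethanol = 0, glycerol = 0, biomass = 0))
  expect_equal(unlist(z[c("Y_biomass", "Y_ethanol", "Y_glycerol")]),
               c(Y_biomass = 0, Y_ethanol = 0, Y_glycerol = 0))
})

test_that("yields are invariant to uniform concentration scaling", {
  rec <- make_record()
  scaled <- rec
  for (col in c("glucose_in", "galactose_in", "glucose_res", "galactose_res",
                "biomass", "ethanol", "glycerol"))
    scaled[[col]] <- 2 * scaled[[col]]
  expect_equal(as.data.frame(chemostat_yields(scaled))[-1],
               as.data.frame(chemostat_yields(rec))[-1])
})

test_that("record validation reports the offending row", {
  bad <- rbind(make_record(id = 1), make_record(glucose_res = 13, id = 2))
  expect_error(chemostat_yields(bad), "row 2.*residual")
  neg <- make_record(); neg$ethanol <- -1
  expect_error(as_chemostat_records(neg), "row 1")
  expect_error(chemostat_yields(make_record(glucose_res = 12.5,
                                            galactose_res = 12.5)),
               "no sugar consumed")
})

test_that("net CO2 evolution converts off-gas fractions through the molar volume", {
  rec <- rbind(make_record(co2_in = 0, co2_out = 0.0089, id = 1),
               make_record(co2_in = 0.10, co2_out = 0.108, id = 2),
               make_record(co2_in = 0.05, co2_out = 0.05, id = 3))
  evo <- net_co2_evolution(rec)
  expect_equal(evo$co2_evolution[1], 30 * 0.0089 / molar_volume(30) * 1000)
  expect_equal(evo$co2_evolution[2], 30 * 0.008 / molar_volume(30) * 1000)
  expect_equal(evo$co2_evolution[3], 0)
  expect_false(any(evo$net_fixation_flag))
  # apparent net fixation is flagged, not silently dropped
  expect_warning(evo2 <- net_co2_evolution(make_record(co2_in = 0.10,
                                                       co2_out = 0.09)),
                 "fixation")
  expect_true(evo2$net_fixation_flag)
})

test_that("balance check passes closed books and fails missing CO2", {
  pure <- yield_set(0, 2, 0)
  bc <- balance_check(pure, co2_yield = 2)
  expect_equal(bc$carbon_recovery, 1)
  expect_equal(bc$electron_recovery, 1)
  expect_true(bc$pass)
  bc0 <- balance_check(pure, co2_yield = 0)
  expect_equal(bc0$carbon_recovery, 2 / 3)
  expect_false(bc0$pass)
  # solver-produced yields close to 1 within numerical precision
  p <- calibrate_stoich(stoich_params(), yield_set(0.083, 1.56, 0.14))
  fd <- solve_scenario(p, "reference")
  bcm <- balance_check(predict_yields(fd, p), co2_yield = fd$co2_net / 100,
                       params = p)
  expect_equal(bcm$carbon_recovery, 1, tolerance = 1e-6)
  expect_equal(bcm$electron_recovery, 1, tolerance = 1e-6)
})

test_that("strain comparison reports percent changes, spread and t-tests", {
  ref <- yield_set(table1_duplicates(0.083, 0.000),
                   table1_duplicates(1.56, 0.03),
                   table1_duplicates(0.14, 0.00))
  eng <- yield_set(table1_duplicates(0.093, 0.001),
                   table1_duplicates(1.73, 0.02),
                   table1_duplicates(0.04, 0.00))
  cmp <- compare_strains(ref, eng)
  eth <- cmp[cmp$yield == "Y_ethanol", ]
  expect_equal(eth$percent_change, 100 * (1.73 - 1.56) / 1.56)
  expect_equal(eth$percent_change_rounded, 11)
  expect_equal(eth$ref_mean_deviation, 0.03)
  expect_equal(cmp[cmp$yield == "Y_biomass", "percent_change_rounded"], 12)
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  # identical arms: no change, p = 1
  same <- compare_strains(ref, ref)
  expect_equal(same$percent_change, rep(0, 3))
  expect_equal(same$p_value[2], 1)
  expect_error(compare_strains(yield_set(0.08, 1.5, 0.1), eng), "replicates")
})

test_that("percent change obeys the reversal identity pc(a,b) = -pc(b,a) b/a", {
  set.seed(9)
  for (i in 1:10) {
    a <- runif(1, 0.5, 2); b <- runif(1, 0.5, 2)
    pc <- function(x, y) 100 * (y - x) / x
    expect_equal(pc(a, b), -pc(b, a) * b / a)
  }
  ref <- yield_set(c(0.08, 0.086), c(1.5, 1.62), c(0.13, 0.15))
  eng <- yield_set(c(0.09, 0.096), c(1.7, 1.76), c(0.03, 0.05))
  fwd <- compare_strains(ref, eng)
  rev <- compare_strains(eng, ref)
  expect_equal(fwd$percent_change,
               -rev$percent_change * fwd$eng_mean / fwd$ref_mean)
})

test_that("zero reference yields flag the percent change as undefined", {
  ref <- yield_set(c(0.08, 0.09), c(1.5, 1.6), c(0, 0))
  eng <- yield_set(c(0.09, 0.10), c(1.7, 1.8), c(0.01, 0.02))
  cmp <- compare_strains(ref, eng)
  gly <- cmp[cmp$yield == "Y_glycerol", ]
  expect_true(gly$undefined_change)
  expect_true(is.na(gly$percent_change))
})
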