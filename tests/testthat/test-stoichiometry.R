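test_that("ideal gas conversion matches PV = nRT and is monotone", {
  expect_equal(ch4_volume_to_mmol(0, 312.65, 101.325), 0)
  expect_equal(ch4_volume_to_mmol(22414, 273.15, 101.325), 1000, tolerance = 1e-3)
  expect_equal(round(ch4_volume_to_mmol(87.3, 312.65, 101.325), 3), 3.403)

  # property grid: agrees with symbolic PV/RT to 1e-12 relative
  set.seed(11)
  for (i in 1:50) {
    v <- runif(1, 0, 5000); tk <- runif(1, 250, 330); p <- runif(1, 80, 120)
    expect_equal(ch4_volume_to_mmol(v, tk, p), p * v / (8.3145 * tk),
                 tolerance = 1e-12)
  }
  # monotonicity
  expect_gt(ch4_volume_to_mmol(100, 300), ch4_volume_to_mmol(99, 300))
  expect_lt(ch4_volume_to_mmol(100, 310), ch4_volume_to_mmol(100, 300))
  expect_error(ch4_volume_to_mmol(10, -1), "temperature")
  expect_error(ch4_volume_to_mmol(10, 300, 0), "pressure")
  expect_error(ch4_volume_to_mmol(-5, 300), "volume")
})

test_that("stoichiometric coefficients carry the field's signed values", {
  p1 <- h2_stoich_coefficients("propanyl_coa")
  p2 <- h2_stoich_coefficients("acetyl_coa")
  expect_equal(p1[["caproate"]], -4)
  expect_equal(p2[["caproate"]], 2)
  expect_equal(p1[c("acetate", "propionate", "butyrate", "valerate",
                    "methane")],
               c(acetate = 2, propionate = -1, butyrate = 2, valerate = -1,
                 methane = -4))
  iso <- h2_stoich_coefficients("propanyl_coa", include_iso = TRUE)
  expect_equal(iso[["isobutyrate"]], 2)
  expect_equal(iso[["isovalerate"]], -1)
  expect_error(h2_stoich_coefficients(extra = c(1, 2)), "named")
})

test_that("components multiply coefficients by daily amounts", {
  zero <- fermentation_profile()
  expect_true(all(h2_components(zero, "propanyl_coa") == 0))
  cap <- fermentation_profile(caproate = 1)
  expect_equal(h2_components(cap, "propanyl_coa")[["caproate"]], -4)
  expect_equal(h2_components(cap, "acetyl_coa")[["caproate"]], 2)
  ap <- fermentation_profile(acetate = 10, propionate = 4)
  comp <- h2_components(ap, "propanyl_coa")
  expect_equal(comp[["acetate"]], 20)
  expect_equal(comp[["propionate"]], -4)
  # product with reads but no coefficient errors
  odd <- fermentation_profile(formate = 1)
  expect_error(h2_components(odd, "propanyl_coa"), "formate")
  # but is allowed via an extended table
  tab <- h2_stoich_coefficients("propanyl_coa", extra = c(formate = 1))
  expect_equal(h2_components(odd, "propanyl_coa", tab)[["formate"]], 1)
})

test_that("production and utilization reproduce the published sums", {
  hyper <- reference_profile("hyper")
  normal <- reference_profile("normal")
  expect_equal(round(h2_production(hyper, "propanyl_coa"), 1), 71.6)
  expect_equal(round(h2_production(hyper, "acetyl_coa"), 1), 74.6)
  expect_equal(round(h2_utilization(normal, "propanyl_coa"), 1), 40.9)
  expect_equal(round(h2_utilization(normal, "acetyl_coa"), 1), 33.4)
  expect_equal(round(h2_utilization(hyper, "propanyl_coa"), 1), 33.2)
  expect_equal(round(h2_utilization(hyper, "acetyl_coa"), 1), 27.2)
  expect_equal(h2_production(fermentation_profile(), "propanyl_coa"), 0)
})

test_that("balance identities and degenerate cases behave", {
  gr <- h2_gain_recovery(c(80.6, 84.4), c(40.9, 33.4))
  expect_equal(gr$gain, c(39.7, 51.0))
  # balance point: production = utilization
  p <- fermentation_profile(acetate = 2, propionate = 4)
  b <- h2_balance(p)$propanyl_coa
  expect_equal(b$gain, 0)
  expect_equal(b$recovery, 100)
  # zero production with utilization -> recovery NA, no crash
  b0 <- h2_balance(fermentation_profile(propionate = 1))$propanyl_coa
  expect_true(is.na(b0$recovery))
  expect_equal(b0$utilization, 1)
})

test_that("pathway relations and homogeneity hold on random profiles", {
  set.seed(7)
  for (i in 1:25) {
    prof <- fermentation_profile(acetate = runif(1, 0, 40),
                                 propionate = runif(1, 0, 20),
                                 butyrate = runif(1, 0, 15),
                                 valerate = runif(1, 0, 5),
                                 caproate = runif(1, 0, 3),
                                 ch4_mmol = runif(1, 0, 5))
    cap <- prof$amounts[["caproate"]]
    b <- h2_balance(prof)
    p1 <- b$propanyl_coa; p2 <- b$acetyl_coa
    # caproate [2H] utilized (p1) is exactly twice caproate [2H] produced (p2)
    expect_equal(abs(p1$components[["caproate"]]),
                 2 * p2$components[["caproate"]])
    expect_equal(p2$production - p1$production, 2 * cap, tolerance = 1e-9)
    expect_equal(p1$utilization - p2$utilization, 4 * cap, tolerance = 1e-9)
    expect_equal(p1$gain + p1$utilization, p1$production, tolerance = 1e-9)
    expect_equal(p2$gain + p2$utilization, p2$production, tolerance = 1e-9)
    # homogeneity: scaling amounts by k scales the balance, recovery fixed
    k <- 3.7
    sprof <- fermentation_profile(acetate = k * prof$amounts[["acetate"]],
                                  propionate = k * prof$amounts[["propionate"]],
                                  butyrate = k * prof$amounts[["butyrate"]],
                                  valerate = k * prof$amounts[["valerate"]],
                                  caproate = k * cap,
                                  ch4_mmol = k * prof$amounts[["methane"]])
    sb <- h2_balance(sprof)$propanyl_coa
    expect_equal(sb$production, k * p1$production, tolerance = 1e-9)
    expect_equal(sb$gain, k * p1$gain, tolerance = 1e-9)
    expect_equal(sb$recovery, p1$recovery, tolerance = 1e-9)
  }
})

test_that("h2_balance_table vectorises over rows and converts CH4 volume", {
  df <- data.frame(sample = c("a", "b"),
                   acetate = c(25, 30), propionate = c(16, 15),
                   butyrate = c(10, 11), valerate = c(3, 3),
                   caproate = c(1.8, 2), ch4_ml = c(87.3, 60))
  out <- h2_balance_table(df, temperature = 312.65)
  expect_equal(nrow(out), 2)
  ch4_mmol <- ch4_volume_to_mmol(df$ch4_ml, 312.65)
  expect_equal(out$h2_methane_p1, -4 * ch4_mmol)
  expect_equal(out$h2_production_p1, 2 * df$acetate + 2 * df$butyrate)
  expect_equal(out$h2_gain_p2,
               out$h2_production_p2 - out$h2_utilization_p2)
  expect_error(h2_balance_table(df[-2]), "missing fermentation")
})
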