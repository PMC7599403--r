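test_that("fermentation generator is deterministic and truncates at zero", {
  cfg <- small_config(seed = 3)
  a <- simulate_fermentation(cfg)
  b <- simulate_fermentation(cfg)
  expect_identical(a$table, b$table)
  expect_true(all(a$table[c("ch4_ml", "acetate", "caproate")] >= 0))
  expect_equal(nrow(a$table), 2 * 12 * 2)  # runs x fermenters x days
  # no noise, no effects -> every cell equals its deterministic mean
  vars <- c("ch4_ml", "co2_ml", "o2_ml", "acetate", "propionate",
            "butyrate", "valerate", "caproate", "dm_out", "om_out")
  z0 <- setNames(rep(0, length(vars)), vars)
  zero <- simulation_config(seed = 1, n_runs = 1, n_days = 1,
    fermentation = list(sigma = z0, run_sigma = z0, osmolality = z0,
                        temperature = z0, betaine_low = z0,
                        betaine_high = z0))
  z <- simulate_fermentation(zero)
  expect_true(all(abs(z$table$ch4_ml - 87.3) < 1e-9))
  expect_true(all(abs(z$table$acetate - 29.95) < 1e-9))
})

test_that("marginal means of the generator mirror the configured shifts", {
  cfg <- simulation_config(seed = 10, n_runs = 6, n_days = 5)
  sim <- simulate_fermentation(cfg)
  tab <- sim$table
  diff_ch4 <- mean(tab$ch4_ml[tab$osmolality == "hyper"]) -
    mean(tab$ch4_ml[tab$osmolality == "normal"])
  expect_equal(diff_ch4, -38, tolerance = 0.15)  # |diff| within a few SE
  # stoichiometric recovery lands in the plausible band
  h2 <- h2_balance_table(cbind(tab[setdiff(names(tab), "temperature")],
                               temperature = tab$temperature_k))
  rec <- mean(h2$h2_recovery_p1, na.rm = TRUE)
  expect_gt(rec, 35)
  expect_lt(rec, 55)
})

test_that("community generator honours phase composition and depth", {
  cfg <- small_config(seed = 12)
  liq <- simulate_community(cfg, "liquid")
  sol <- simulate_community(cfg, "solid")
  expect_true(any(grepl("Methanosaeta", colnames(liq$counts))))
  expect_false(any(grepl("Methanosaeta", colnames(sol$counts))))
  expect_setequal(colnames(liq$counts), liq$taxonomy$otu)
  expect_true(all(liq$tree$tip.label %in% liq$taxonomy$otu))
  expect_true(ape::is.rooted(liq$tree))
  expect_true(all(liq$tree$edge.length >= 0))
  # determinism
  liq2 <- simulate_community(cfg, "liquid")
  expect_identical(liq$counts, liq2$counts)
  # genus relative abundances center on the configured means
  rel <- aggregate_taxa(liq$counts, liq$taxonomy, "genus")
  expect_equal(mean(rel[, "Methanobrevibacter"]), 0.49, tolerance = 0.05)
})

test_that("read depth averages near the configured mean", {
  cfg <- simulation_config(seed = 20, n_runs = 6, otus_per_genus = 30,
                           read_depth_mean = 66139)
  liq <- simulate_community(cfg, "liquid")
  sol <- simulate_community(cfg, "solid")
  depths <- c(rowSums(liq$counts), rowSums(sol$counts))
  expect_equal(length(depths), 144)
  expect_lt(abs(mean(depths) - 66139) / 66139, 0.05)
})

test_that("near-degenerate Dirichlet gives proportions at the means", {
  cfg <- small_config(seed = 30, dirichlet_concentration = 1e9)
  liq <- simulate_community(cfg, "liquid")
  rel <- aggregate_taxa(liq$counts, liq$taxonomy, "genus")
  # multinomial sampling noise at depth ~5000 dominates; means are close
  expect_equal(unname(colMeans(rel)["Methanobrevibacter"]), 0.49,
               tolerance = 0.02)
})

test_that("community effects >= 2 sigma are recovered in sign", {
  cfg <- simulation_config(seed = 77, n_runs = 6, otus_per_genus = 25,
                           read_depth_mean = 20000,
                           community = list(solid = list(effects = list(
                             osmolality = c(Methanobrevibacter = 0.5,
                                            Methanimicrococcus = -1.5)))))
  sol <- simulate_community(cfg, "solid")
  rel <- aggregate_taxa(sol$counts, sol$taxonomy, "genus")
  fit <- fit_factorial(rel[, "Methanimicrococcus"], sol$design)
  est <- factor_contrast(fit, "osmolality")$estimate
  expect_lt(est, 0)
  p <- fit$anova$p_value[fit$anova$effect == "osmolality"]
  expect_lt(p, 0.05)
})

test_that("invalid configurations fail before any sampling", {
  expect_error(simulation_config(), "seed")
  expect_error(simulation_config(seed = 1,
    community = list(liquid = list(means = c(a = 0.9, b = 0.2)))),
    "sum")
  expect_error(simulation_config(seed = 1,
    fermentation = list(sigma = c(ch4_ml = -1))), "deviations")
  expect_error(simulation_config(seed = 1, geometric_decay = 1.2),
               "community parameters")
})
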