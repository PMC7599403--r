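test_that("low-count filter drops OTUs below the read threshold", {
  m <- matrix(c(5, 0, 4, 6, 100, 400), nrow = 2,
              dimnames = list(c("s1", "s2"), c("low", "edge", "big")))
  # totals: low 5 (dropped), edge 10 (kept), big 500 (kept)
  out <- filter_low_count_otus(m, 10)
  expect_equal(colnames(out), c("edge", "big"))
  expect_equal(rownames(out), c("s1", "s2"))
  expect_equal(filter_low_count_otus(m, 0), m)
  m9 <- m; m9[1, "edge"] <- 3  # total 9 -> removed
  expect_equal(colnames(filter_low_count_otus(m9, 10)), "big")
})

test_that("rarefaction subsamples without replacement, deterministically", {
  m <- rbind(s1 = c(a = 900L, b = 100L), s2 = c(a = 40L, b = 10L))
  expect_warning(r <- rarefy_counts(m, 100, seed = 5), "below depth")
  expect_equal(rownames(r), "s1")
  expect_equal(sum(r), 100)
  # boundary: total exactly depth is kept unchanged
  r2 <- rarefy_counts(rbind(s = c(a = 60L, b = 40L)), 100, seed = 1)
  expect_equal(as.vector(r2), c(60, 40))
  # determinism and zero-pattern preservation
  big <- random_count_matrix(4, 30, lambda = 20)
  big[, 5] <- 0L
  ra <- rarefy_counts(big, 300, seed = 99)
  rb <- rarefy_counts(big, 300, seed = 99)
  expect_identical(ra, rb)
  expect_true(all(ra[, 5] == 0))
  expect_true(all(rowSums(ra) == 300))
  expect_true(all(ra <= big))
  expect_error(rarefy_counts(m, 1e6, seed = 1), "fewer than")
  expect_error(rarefy_counts(m, 100), "seed")
  # hypergeometric expectation: mean of OTU a over many seeds ~ 90
  means <- vapply(1:300, function(s)
    rarefy_counts(m[1, , drop = FALSE], 100, seed = s)[1, "a"], 0)
  expect_equal(mean(means), 90, tolerance = 0.02)
})

test_that("alpha diversity formulas match hand evaluation", {
  expect_equal(shannon_index(c(5, 0, 0)), 0)
  expect_equal(simpson_index(c(5, 0, 0)), 0)
  expect_equal(shannon_index(rep(3, 4)), 2)       # 4 even OTUs -> 2 bits
  expect_equal(simpson_index(rep(3, 4)), 0.75)
  expect_equal(shannon_index(c(2, 1, 1)), 1.5)
  expect_equal(simpson_index(c(2, 1, 1)), 0.625)
  expect_equal(simpson_index(c(2, 1, 1), "dominance"), 0.375)
  expect_equal(simpson_index(c(2, 1, 1), "inverse"), 1 / 0.375)
  a <- alpha_diversity(c(2, 1, 1))
  expect_equal(a$observed, 3)
  expect_equal(a$singles, 2)
  expect_error(shannon_index(c(0, 0)), "zero")
})

test_that("ACE follows the coverage formula with Chao1 fallback", {
  # no rare OTUs: ACE equals observed richness
  expect_equal(ace_richness(c(20, 30, 50)), 3)
  # frozen hand evaluation of the formula for counts (1,1,2,3,12):
  # S_abund=1, S_rare=4, F1=2, N_rare=7, C=5/7, F2=1 F3=1,
  # gamma2 = max(4/C * (2+6)/(7*6) - 1, 0) = max(0.0666..., 0)
  x <- c(1, 1, 2, 3, 12)
  c_ace <- 1 - 2 / 7
  g2 <- max((4 / c_ace) * 8 / 42 - 1, 0)
  expect_equal(ace_richness(x), 1 + 4 / c_ace + (2 / c_ace) * g2)
  # all rare reads singletons -> bias-corrected Chao1 with warning
  y <- c(1, 1, 1, 50)
  expect_warning(fb <- ace_richness(y), "Chao1")
  expect_equal(fb, chao1_richness(y))
  expect_equal(chao1_richness(c(1, 1, 1, 50)), 4 + 3 * 2 / 2)
  # estimator property on random vectors
  set.seed(21)
  for (i in 1:20) {
    v <- rpois(60, 2); v <- v[v > 0]
    if (!length(v) || sum(v <= 10 & v > 1) == 0) next
    expect_gte(ace_richness(v) + 1e-9, sum(v > 0))
  }
})

test_that("alpha metrics agree with the vegan reference to 1e-6", {
  set.seed(42)
  for (i in 1:100) {
    x <- rpois(80, sample(c(1, 3, 8), 1))
    if (sum(x) == 0 || sum(x > 0) < 2) next
    expect_equal(shannon_index(x, base = exp(1)),
                 unname(vegan::diversity(x, "shannon")), tolerance = 1e-6)
    expect_equal(simpson_index(x),
                 unname(vegan::diversity(x, "simpson")), tolerance = 1e-6)
    est <- vegan::estimateR(x)
    if (sum(x == 1) < sum(x[x <= 10]))  # vegan errors when C_ace = 0 too
      expect_equal(ace_richness(x), unname(est["S.ACE"]), tolerance = 1e-6)
    expect_equal(sum(x == 1),
                 sum(tabulate(x)[1]))  # singles: direct frequency count
  }
})

test_that("Shannon is maximal for the uniform distribution", {
  set.seed(8)
  for (i in 1:10) {
    k <- sample(3:12, 1)
    uneven <- rmultinom(1, 200, prob = runif(k, 0.2, 2))[, 1]
    uneven <- uneven + 1L  # keep richness fixed at k
    expect_lte(shannon_index(uneven), log2(k) + 1e-12)
  }
})

test_that("taxon aggregation yields sorted relative abundances", {
  m <- matrix(c(75L, 25L, 10L, 90L), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("o1", "o2")))
  tax <- small_taxonomy(c("o1", "o2"), c("gA", "gB"))
  rel <- aggregate_taxa(m, tax, "genus")
  expect_equal(rowSums(rel), c(s1 = 1, s2 = 1), tolerance = 1e-9)
  expect_equal(rel["s1", "gA"], 0.75)
  # one taxon only -> column of 1
  rel1 <- aggregate_taxa(m, small_taxonomy(c("o1", "o2"), c("g", "g")),
                         "genus")
  expect_equal(as.vector(rel1), c(1, 1))
  # phylum rank and conservation of totals through aggregation
  counts_by_phylum <- t(rowsum(t(m), tax$phylum))
  expect_equal(rowSums(counts_by_phylum), rowSums(m))
  expect_error(aggregate_taxa(m, tax[1, ], "genus"), "without taxonomy")
  expect_error(aggregate_taxa(m, tax, "species"))
})
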