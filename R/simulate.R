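# Synthetic Rusitec data generator. Emulates a 2 x 2 x 3 factorial
# (osmolality x temperature x betaine) with n runs of 12 fermenters, daily
# fermentation records whose baselines and treatment shifts mirror the
# magnitudes observed in betaine/heat/osmotic-stress Rusitec experiments,
# and per-phase archaeal OTU tables with genus-level composition, a
# coalescent-style phylogeny and realistic read depths. Exists so the whole
# pipeline can be exercised and validated by parameter recovery without any
# external data.

.ferm_vars <- c("ch4_ml", "co2_ml", "o2_ml", "acetate", "propionate",
                "butyrate", "valerate", "caproate", "dm_out", "om_out")

.default_fermentation <- function() {
  # baseline = marginal mean under normal osmolality; shifts are LS-mean
  # differences (hyper - normal, 42 - 39.5, betaine level - control)
  list(
    baseline = c(ch4_ml = 87.3, co2_ml = 423.8, o2_ml = 39.2,
                 acetate = 29.95, propionate = 16.4, butyrate = 10.4,
                 valerate = 3.23, caproate = 1.88,
                 dm_out = 4.84, om_out = 4.53),
    osmolality = c(ch4_ml = -38, co2_ml = -146.1, o2_ml = 0,
                   acetate = -4.8, propionate = 0.3, butyrate = 0.25,
                   valerate = -0.48, caproate = -0.385,
                   dm_out = 0.22, om_out = 0.23),
    temperature = c(ch4_ml = 3.2, co2_ml = 9, o2_ml = 0,
                    acetate = 1.2, propionate = -2.1, butyrate = -0.1,
                    valerate = 0.43, caproate = 0.36,
                    dm_out = 0, om_out = 0),
    betaine_low = c(ch4_ml = 9.5, co2_ml = 13.3, o2_ml = 0,
                    acetate = 1.75, propionate = 1.1, butyrate = 0.3,
                    valerate = 0, caproate = -0.115,
                    dm_out = 0, om_out = 0),
    betaine_high = c(ch4_ml = 43.6, co2_ml = 55, o2_ml = 0,
                     acetate = 2.9, propionate = 1.3, butyrate = 0.5,
                     valerate = -0.07, caproate = -0.215,
                     dm_out = 0, om_out = 0),
    sigma = c(ch4_ml = 5, co2_ml = 15, o2_ml = 2,
              acetate = 1.5, propionate = 0.8, butyrate = 0.5,
              valerate = 0.15, caproate = 0.1,
              dm_out = 0.2, om_out = 0.2),
    run_sigma = c(ch4_ml = 3, co2_ml = 8, o2_ml = 1,
                  acetate = 0.8, propionate = 0.4, butyrate = 0.3,
                  valerate = 0.08, caproate = 0.05,
                  dm_out = 0.1, om_out = 0.1),
    dm_in = 12, om_in = 11, ge_intake = 211.8
  )
}

.default_community <- function() {
  list(
    liquid = list(
      means = c(Methanobrevibacter = 0.49, VadinCA11 = 0.303,
                Methanosphaera = 0.043, Methanimicrococcus = 0.032,
                Methanobacterium = 1e-5, Methanosarcina = 1e-6,
                Methanosaeta = 3e-7, Crenarchaeota_unclassified = 8e-6),
      effects = list(  # logit-scale additive shifts, per genus
        osmolality = c(Methanosphaera = 0.50, Methanobacterium = 0.69,
                       Crenarchaeota_unclassified = 2.0),
        temperature = c(VadinCA11 = -0.155, Methanimicrococcus = 0.57),
        betaine_low = c(), betaine_high = c())),
    solid = list(
      means = c(Methanobrevibacter = 0.45, VadinCA11 = 0.27,
                Methanosphaera = 0.13, Methanimicrococcus = 0.01,
                Methanobacterium = 3e-5, Methanosarcina = 2e-5,
                Crenarchaeota_unclassified = 1e-3),
      effects = list(
        osmolality = c(Methanobrevibacter = 0.20,
                       Methanimicrococcus = -1.22),
        temperature = c(VadinCA11 = -0.25, Methanimicrococcus = 0.92),
        betaine_low = c(), betaine_high = c()))
  )
}

#' Configuration for the synthetic Rusitec generator
#'
#' Collects every tunable of the simulator with defaults emulating the
#' factorial betaine/heat/osmotic-stress study conditions: 6 runs of 12
#' fermenters (n = 6 per treatment cell), 5 sampling days, fermentation
#' baselines and treatment shifts at published LS-mean magnitudes, a mean
#' read depth of 66,139, and genus-level community composition per digesta
#' phase. All randomness flows from the single `seed`.
#'
#' @param seed integer seed (mandatory).
#' @param n_runs experimental runs (n per treatment cell).
#' @param n_days sampling days per fermenter.
#' @param fermentation list with elements `baseline`, `osmolality`,
#'   `temperature`, `betaine_low`, `betaine_high`, `sigma`, `run_sigma`
#'   (named per variable), `dm_in`, `om_in`, `ge_intake`; partial overrides
#'   are merged into the defaults.
#' @param community per-phase list (`liquid`, `solid`) of genus mean
#'   proportions and logit-scale treatment effects; partial overrides are
#'   merged. Proportions must sum to < 1 (remainder becomes an unclassified
#'   Euryarchaeota genus). The solid phase carries no *Methanosaeta*.
#' @param otus_per_genus OTUs simulated per genus.
#' @param read_depth_mean,read_depth_cv mean and coefficient of variation of
#'   per-sample read depth.
#' @param dirichlet_concentration concentration of the Dirichlet draw around
#'   the (shifted) genus means; larger = less compositional noise.
#' @param geometric_decay within-genus geometric abundance decay of OTUs
#'   (rank k weight proportional to `geometric_decay^k`), creating a
#'   realistic rare tail of singletons.
#' @param rarefaction_depth default rarefaction depth carried in the config.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed, n_runs = 6, n_days = 5,
                              fermentation = list(), community = list(),
                              otus_per_genus = 335,
                              read_depth_mean = 66139,
                              read_depth_cv = 0.05,
                              dirichlet_concentration = 200,
                              geometric_decay = 0.97,
                              rarefaction_depth = 41921) {
  if (missing(seed)) stop("an explicit integer 'seed' is required")
  ferm <- utils::modifyList(.default_fermentation(), fermentation)
  comm <- utils::modifyList(.default_community(), community)
  for (ph in names(comm)) {
    p <- comm[[ph]]$means
    if (any(p <= 0) || sum(p) >= 1)
      stop("phase '", ph, "': genus proportions must be positive and sum ",
           "to < 1 (remainder is unclassified)")
  }
  if (any(ferm$sigma < 0) || any(ferm$run_sigma < 0))
    stop("noise standard deviations must be >= 0")
  if (n_runs < 1 || n_days < 1 || otus_per_genus < 2)
    stop("invalid design sizes")
  if (read_depth_mean < 1 || read_depth_cv < 0 ||
      dirichlet_concentration <= 0 ||
      geometric_decay <= 0 || geometric_decay >= 1)
    stop("invalid community parameters")
  structure(list(seed = as.integer(seed), n_runs = n_runs, n_days = n_days,
                 fermentation = ferm, community = comm,
                 otus_per_genus = otus_per_genus,
                 read_depth_mean = read_depth_mean,
                 read_depth_cv = read_depth_cv,
                 dirichlet_concentration = dirichlet_concentration,
                 geometric_decay = geometric_decay,
                 rarefaction_depth = rarefaction_depth),
            class = "simulation_config")
}

.cell_shift <- function(ferm, osmolality, temperature, betaine) {
  ferm$baseline -
    0.5 * ferm$temperature -
    (ferm$betaine_low + ferm$betaine_high) / 3 +
    ferm$osmolality * (osmolality == "hyper") +
    ferm$temperature * (temperature == "42") +
    ferm$betaine_low * (betaine == "low") +
    ferm$betaine_high * (betaine == "high")
}

#' Simulate per-fermenter-day fermentation records
#'
#' For every fermenter-day, each variable is its treatment-cell mean (an
#' additive model whose marginal means reproduce the configured baselines
#' and LS-mean shifts) plus a run-level random effect and a residual, both
#' Gaussian. Negative draws are truncated at zero and counted. Methane is
#' generated on the volume scale consistently with the SCFA magnitudes, so
#' the downstream stoichiometric [2H] recovery lands in the plausible
#' 35-55% band.
#'
#' @param config a [simulation_config()].
#' @return list with `design` (the expanded fermenter-day design),
#'   `table` (fermentation records incl. nutrient flows and GE intake),
#'   `truth` (effects, baselines and noise actually used) and
#'   `n_truncated` (count of negative draws set to zero).
#' @export
simulate_fermentation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ferm <- config$fermentation
  design <- rusitec_design(config$n_runs)
  rows <- design[rep(seq_len(nrow(design)), each = config$n_days), ]
  rows$day <- rep(5 + seq_len(config$n_days), nrow(design))
  rownames(rows) <- NULL
  nv <- length(.ferm_vars)
  with_seed(config$seed, {
    run_eff <- matrix(stats::rnorm(config$n_runs * nv, 0,
                                   rep(ferm$run_sigma, each = config$n_runs)),
                      config$n_runs, nv,
                      dimnames = list(NULL, .ferm_vars))
    vals <- t(vapply(seq_len(nrow(rows)), function(i) {
      mu <- .cell_shift(ferm, rows$osmolality[i], rows$temperature[i],
                        rows$betaine[i])
      mu[.ferm_vars] + run_eff[as.integer(rows$run[i]), ] +
        stats::rnorm(nv, 0, ferm$sigma[.ferm_vars])
    }, numeric(nv)))
    colnames(vals) <- .ferm_vars
    n_trunc <- sum(vals < 0)
    vals[vals < 0] <- 0
    # nutrient outflow cannot exceed inflow
    vals[, "dm_out"] <- pmin(vals[, "dm_out"], ferm$dm_in)
    vals[, "om_out"] <- pmin(vals[, "om_out"], ferm$om_in)
    tab <- cbind(rows, as.data.frame(vals))
    tab$dm_in <- ferm$dm_in
    tab$om_in <- ferm$om_in
    tab$ge_intake <- ferm$ge_intake
    tab$temperature_k <- ifelse(tab$temperature == "42", 315.15, 312.65)
    tab$sample <- sprintf("R%sF%02d_d%d", tab$run,
                          as.integer(as.character(tab$fermenter)), tab$day)
    list(design = design, table = tab,
         truth = ferm[c("baseline", "osmolality", "temperature",
                        "betaine_low", "betaine_high", "sigma",
                        "run_sigma")],
         n_truncated = n_trunc)
  })
}

.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(x) 1 / (1 + exp(-x))

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# pure-birth clade per genus bound onto a coalescent backbone
.simulate_tree <- function(genera, otus_per_genus) {
  clades <- lapply(genera, function(g) {
    tr <- ape::rcoal(otus_per_genus)
    tr$tip.label <- sprintf("%s_OTU%03d", g, seq_len(otus_per_genus))
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
    tr$root.edge <- 0.5
    tr
  })
  backbone <- ape::rcoal(length(genera))
  backbone$tip.label <- genera
  backbone$edge.length <-
    backbone$edge.length / max(ape::node.depth.edgelength(backbone))
  tree <- backbone
  for (i in seq_along(genera)) {
    where <- which(tree$tip.label == genera[i])
    tree <- ape::bind.tree(tree, clades[[i]], where = where)
  }
  tree
}

#' Simulate a per-phase archaeal OTU table with tree and taxonomy
#'
#' Draws per-sample genus proportions from a Dirichlet distribution around
#' the phase's mean composition, with treatment effects applied as additive
#' shifts on the logit scale before renormalisation. Reads (depth drawn
#' around the configured mean) are allocated multinomially to OTUs within
#' each genus using geometric rank weights, so a realistic rare tail of
#' singleton OTUs exists. A coalescent-style tree with genus-level clades
#' and the OTU taxonomy map are returned alongside. The solid phase
#' contains no *Methanosaeta* (liquid-only genus).
#'
#' @param config a [simulation_config()].
#' @param phase `"liquid"` or `"solid"`.
#' @return list with `counts` (samples x OTUs), `tree` (`phylo`),
#'   `taxonomy` (data frame `otu`, `phylum`, `genus`), `design`, and
#'   `truth` (genus means and logit effects used).
#' @export
simulate_community <- function(config, phase = c("liquid", "solid")) {
  stopifnot(inherits(config, "simulation_config"))
  phase <- match.arg(phase)
  comm_spec <- config$community[[phase]]
  design <- rusitec_design(config$n_runs)
  genus_means <- c(comm_spec$means, unclassified = 1 - sum(comm_spec$means))
  genera <- names(genus_means)
  k <- config$otus_per_genus
  weights <- config$geometric_decay^(seq_len(k) - 1)
  weights <- weights / sum(weights)
  seed_offset <- if (phase == "liquid") 1L else 2L
  with_seed(config$seed + seed_offset, {
    tree <- .simulate_tree(genera, k)
    otu_ids <- sprintf("%s_OTU%03d", rep(genera, each = k),
                       rep(seq_len(k), length(genera)))
    taxonomy <- data.frame(
      otu = otu_ids,
      phylum = ifelse(startsWith(otu_ids, "Crenarchaeota"),
                      "Crenarchaeota", "Euryarchaeota"),
      genus = rep(genera, each = k))
    counts <- matrix(0L, nrow(design), length(otu_ids),
                     dimnames = list(
                       sprintf("R%sF%02d_%s", design$run,
                               as.integer(as.character(design$fermenter)),
                               phase),
                       otu_ids))
    for (i in seq_len(nrow(design))) {
      lg <- .logit(genus_means)
      for (fac in names(comm_spec$effects)) {
        eff <- comm_spec$effects[[fac]]
        if (!length(eff)) next
        on <- switch(fac,
                     osmolality = design$osmolality[i] == "hyper",
                     temperature = design$temperature[i] == "42",
                     betaine_low = design$betaine[i] == "low",
                     betaine_high = design$betaine[i] == "high")
        if (on) lg[names(eff)] <- lg[names(eff)] + eff
      }
      p <- .inv_logit(lg)
      p <- p / sum(p)
      if (is.finite(config$dirichlet_concentration))
        p <- .rdirichlet(config$dirichlet_concentration * p)
      depth <- max(1000L, round(stats::rnorm(1, config$read_depth_mean,
        config$read_depth_cv * config$read_depth_mean)))
      otu_p <- as.vector(outer(weights, p))  # k x genera, column-major
      counts[i, ] <- as.integer(stats::rmultinom(1, depth, otu_p))
    }
    list(counts = counts, tree = tree, taxonomy = taxonomy,
         design = design,
         truth = list(genus_means = genus_means, effects = comm_spec$effects))
  })
}

#' Simulate a complete synthetic Rusitec dataset
#'
#' Design table, fermentation records, one OTU table + tree + taxonomy per
#' digesta phase (liquid and solid; 2 x 72 = 144 community samples with 6
#' runs), and the ground-truth record of every effect injected.
#'
#' @param config a [simulation_config()].
#' @return list with `design`, `fermentation`, `communities` (per phase)
#'   and `truth`.
#' @export
simulate_rusitec <- function(config) {
  ferm <- simulate_fermentation(config)
  communities <- lapply(stats::setNames(nm = c("liquid", "solid")),
                        function(ph) simulate_community(config, ph))
  list(design = ferm$design, fermentation = ferm$table,
       communities = communities,
       truth = list(fermentation = ferm$truth,
                    community = lapply(communities, `[[`, "truth"),
                    n_truncated = ferm$n_truncated,
                    seed = config$seed))
}
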