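# Archaeal community diversity from OTU count tables: low-count filtering,
# rarefaction, alpha diversity (ACE, Shannon, Simpson, observed, singles)
# and genus/phylum aggregation. Count matrices are samples x OTUs with
# dimnames; the beta-diversity side lives in unifrac.R / pcoa.R.

.check_counts <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric samples x OTUs matrix")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  counts
}

#' Evaluate an expression with a local, seeded RNG
#'
#' Seeds the RNG for the duration of `expr` and restores the caller's RNG
#' state afterwards, so no function consumes or disturbs ambient randomness.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("an explicit integer 'seed' is required")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Remove OTUs with fewer than a minimum total read count
#'
#' Drops OTUs whose total count across all samples is below `min_reads`
#' (strictly less than; an OTU totalling exactly `min_reads` is kept).
#'
#' @param counts samples x OTUs integer matrix.
#' @param min_reads minimum total reads for an OTU to be retained.
#' @return the filtered matrix; sample rows are unchanged.
#' @export
filter_low_count_otus <- function(counts, min_reads = 10) {
  counts <- .check_counts(counts)
  if (min_reads < 0) stop("'min_reads' must be >= 0")
  counts[, colSums(counts) >= min_reads, drop = FALSE]
}

#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's reads uniformly at random without replacement to
#' exactly `depth` reads. Samples with fewer than `depth` total reads are
#' dropped with a warning. Deterministic given `seed`; the caller's RNG
#' state is untouched.
#'
#' @param counts samples x OTUs integer matrix.
#' @param depth target reads per sample.
#' @param seed integer seed (mandatory; no silent global RNG state).
#' @return rarefied matrix with every row summing to `depth`.
#' @export
rarefy_counts <- function(counts, depth = 41921, seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 ||
      !is.finite(seed))
    stop("an explicit integer 'seed' is required")
  counts <- .check_counts(counts)
  if (depth < 1) stop("'depth' must be >= 1")
  totals <- rowSums(counts)
  keep <- totals >= depth
  if (!any(keep))
    stop("all samples have fewer than ", depth, " reads; nothing to rarefy")
  if (any(!keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(utils::head(rownames(counts)[!keep], 5), collapse = ", "))
  counts <- counts[keep, , drop = FALSE]
  with_seed(seed, {
    out <- t(apply(counts, 1, function(x) {
      if (sum(x) == depth) return(x)
      reads <- sample.int(sum(x), depth)  # positions in the expanded pool
      breaks <- c(0, cumsum(x))
      tabulate(findInterval(reads, breaks, left.open = TRUE),
               nbins = length(x))
    }))
    dimnames(out) <- dimnames(counts)
    out
  })
}

#' Shannon diversity index
#'
#' H = -sum p_i log(p_i) over non-zero proportions. Reported in bits
#' (log base 2) by default.
#'
#' @param x one sample's count (or proportion) vector.
#' @param base logarithm base.
#' @return Shannon index.
#' @export
shannon_index <- function(x, base = 2) {
  x <- x[x > 0]
  if (!length(x)) stop("all-zero count vector")
  p <- x / sum(x)
  -sum(p * log(p, base = base))
}

#' Simpson diversity index
#'
#' Dominance D = sum p_i^2; reported as its complement 1 - D by default
#' (probability that two reads drawn at random are different OTUs).
#'
#' @param x one sample's count vector.
#' @param variant `"complement"` (1 - D), `"dominance"` (D) or
#'   `"inverse"` (1/D).
#' @return Simpson index in the chosen variant.
#' @export
simpson_index <- function(x, variant = c("complement", "dominance",
                                         "inverse")) {
  variant <- match.arg(variant)
  x <- x[x > 0]
  if (!length(x)) stop("all-zero count vector")
  p <- x / sum(x)
  D <- sum(p^2)
  switch(variant, complement = 1 - D, dominance = D, inverse = 1 / D)
}

#' Abundance-based coverage estimator (ACE) of richness
#'
#' Classic ACE: with rare OTUs those of `rare_threshold` or fewer reads,
#' S_ace = S_abund + S_rare / C_ace + (F1 / C_ace) * gamma^2, where
#' C_ace = 1 - F1 / N_rare is the sample coverage of the rare group and
#' gamma^2 the (non-negative) coefficient of variation term. When every rare
#' read is a singleton the coverage is zero and ACE is undefined; the
#' bias-corrected Chao1 estimate is returned with a warning.
#'
#' @param x one sample's count vector.
#' @param rare_threshold rare/abundant cutoff (reads), conventionally 10.
#' @return estimated richness (>= observed).
#' @export
ace_richness <- function(x, rare_threshold = 10) {
  x <- x[x > 0]
  if (!length(x)) stop("all-zero count vector")
  k <- rare_threshold
  rare <- x[x <= k]
  s_abund <- sum(x > k)
  s_rare <- length(rare)
  if (s_rare == 0) return(s_abund)
  f1 <- sum(rare == 1)
  n_rare <- sum(rare)
  c_ace <- 1 - f1 / n_rare
  if (c_ace <= 0) {
    warning("all rare reads are singletons; ACE undefined, ",
            "returning bias-corrected Chao1")
    return(chao1_richness(x))
  }
  fi <- tabulate(rare, nbins = k)
  i <- seq_len(k)
  gamma2 <- max(s_rare / c_ace * sum(i * (i - 1) * fi) /
                  (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Bias-corrected Chao1 richness
#'
#' S_chao1 = S_obs + F1 (F1 - 1) / (2 (F2 + 1)); used as the fallback when
#' ACE coverage is zero.
#'
#' @param x one sample's count vector.
#' @return estimated richness.
#' @export
chao1_richness <- function(x) {
  x <- x[x > 0]
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  length(x) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Alpha diversity summary per sample
#'
#' Computes ACE, Shannon (bits by default), Simpson (1 - D by default),
#' observed richness and singles (OTUs seen exactly once in the sample).
#'
#' @param counts samples x OTUs matrix, or a single sample's vector.
#' @param base Shannon logarithm base.
#' @param simpson_variant see [simpson_index()].
#' @param rare_threshold ACE rare/abundant cutoff.
#' @return data frame with one row per sample and columns `sample`, `ace`,
#'   `shannon`, `simpson`, `observed`, `singles`.
#' @export
alpha_diversity <- function(counts, base = 2,
                            simpson_variant = "complement",
                            rare_threshold = 10) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
    dimnames = list("sample_1", names(counts)))
  counts <- .check_counts(counts)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    x <- counts[i, ]
    if (sum(x) == 0) stop("sample '", rownames(counts)[i], "' has no reads")
    data.frame(sample = rownames(counts)[i],
               ace = ace_richness(x, rare_threshold),
               shannon = shannon_index(x, base),
               simpson = simpson_index(x, simpson_variant),
               observed = sum(x > 0),
               singles = sum(x == 1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate an OTU table to relative abundance per taxon
#'
#' Sums counts of OTUs sharing a taxonomy label at the requested rank and
#' converts to per-sample relative abundances (rows sum to 1). Taxa are
#' ordered by decreasing mean abundance.
#'
#' @param counts samples x OTUs matrix.
#' @param taxonomy data frame with columns `otu`, `phylum`, `genus`; every
#'   OTU in `counts` must appear (use `"unclassified"` for unknowns).
#' @param rank `"phylum"` or `"genus"`.
#' @return samples x taxa relative-abundance matrix.
#' @export
aggregate_taxa <- function(counts, taxonomy, rank = c("genus", "phylum")) {
  rank <- match.arg(rank)
  counts <- .check_counts(counts)
  if (!all(c("otu", rank) %in% names(taxonomy)))
    stop("'taxonomy' needs columns 'otu' and '", rank, "'")
  missing <- setdiff(colnames(counts), taxonomy$otu)
  if (length(missing))
    stop("OTUs without taxonomy: ", paste(utils::head(missing, 5),
                                          collapse = ", "))
  labels <- taxonomy[[rank]][match(colnames(counts), taxonomy$otu)]
  agg <- t(rowsum(t(counts), group = labels))
  totals <- rowSums(agg)
  if (any(totals == 0)) stop("sample(s) with zero total reads")
  rel <- agg / totals
  rel[, order(-colMeans(rel)), drop = FALSE]
}
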