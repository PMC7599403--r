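# Readers and writers for the formats the pipeline touches (classic
# tab-separated OTU tables, taxonomy maps, newick trees, design and
# fermentation tables, square distance matrices) and the end-to-end
# pipeline driver. All writers use the decimal point and no thousands
# separators regardless of locale.

#' Read a classic tab-separated OTU table
#'
#' Layout: first column OTU id, one column per sample, optionally a
#' trailing `taxonomy` column with a semicolon-delimited lineage
#' (`phylum;genus`). Counts are validated as non-negative integers.
#'
#' @param path file path.
#' @return list with `counts` (samples x OTUs integer matrix) and
#'   `taxonomy` (data frame `otu`, `phylum`, `genus`, or `NULL` when the
#'   file has no taxonomy column).
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("OTU table needs an id column and >= 1 sample")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicate OTU ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  taxonomy <- NULL
  tax_col <- which(tolower(names(raw)) == "taxonomy")
  if (length(tax_col)) {
    lineage <- strsplit(as.character(raw[[tax_col]]), ";", fixed = TRUE)
    taxonomy <- data.frame(
      otu = ids,
      phylum = vapply(lineage, function(x)
        if (length(x) >= 1) trimws(x[1]) else "unclassified", ""),
      genus = vapply(lineage, function(x)
        if (length(x) >= 2) trimws(x[2]) else "unclassified", ""))
    raw <- raw[-tax_col]
  }
  mat <- as.matrix(raw[-1])
  num <- matrix(suppressWarnings(as.numeric(mat)), nrow(mat),
                dimnames = dimnames(mat))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer or negative count at OTU '", ids[bad[1, 1]],
         "', sample '", colnames(mat)[bad[1, 2]], "'")
  counts <- t(num)
  dimnames(counts) <- list(colnames(mat), ids)
  storage.mode(counts) <- "integer"
  list(counts = counts, taxonomy = taxonomy)
}

#' Write a classic tab-separated OTU table
#'
#' @param counts samples x OTUs matrix.
#' @param path output path.
#' @param taxonomy optional data frame `otu`, `phylum`, `genus`; written as
#'   a trailing semicolon-delimited `taxonomy` column.
#' @export
write_otu_table <- function(counts, path, taxonomy = NULL) {
  counts <- .check_counts(counts)
  out <- data.frame(`OTU ID` = colnames(counts), t(counts),
                    check.names = FALSE)
  if (!is.null(taxonomy)) {
    m <- match(colnames(counts), taxonomy$otu)
    if (anyNA(m)) stop("taxonomy missing for some OTUs")
    out$taxonomy <- paste(taxonomy$phylum[m], taxonomy$genus[m], sep = ";")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy map
#'
#' Two tab-separated columns: OTU id and a semicolon-delimited lineage
#' (`phylum;genus`). A header line is optional.
#'
#' @param path file path.
#' @return data frame with columns `otu`, `phylum`, `genus`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  header <- grepl("taxonomy", tolower(first), fixed = TRUE)
  raw <- utils::read.delim(path, header = header,
                           stringsAsFactors = FALSE)
  lineage <- strsplit(as.character(raw[[2]]), ";", fixed = TRUE)
  data.frame(
    otu = as.character(raw[[1]]),
    phylum = vapply(lineage, function(x)
      if (length(x) >= 1) trimws(x[1]) else "unclassified", ""),
    genus = vapply(lineage, function(x)
      if (length(x) >= 2) trimws(x[2]) else "unclassified", ""))
}

#' Read a rooted newick tree with branch lengths
#'
#' Thin validation wrapper around [ape::read.tree()]: requires a rooted
#' tree; missing branch lengths become 0 with a warning; negative lengths
#' are an error.
#'
#' @param path file path.
#' @return a `phylo` object.
#' @export
read_newick_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("newick parse error in '", path,
                                            "': ", conditionMessage(e)))
  if (is.null(tree)) stop("newick parse error in '", path, "'")
  if (!ape::is.rooted(tree)) stop("tree in '", path, "' is not rooted")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; using 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree
}

#' Write a square distance matrix as TSV
#' @param d `dist` object or square matrix.
#' @param path output path.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  utils::write.table(data.frame(sample = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset directory
#'
#' Serialises a [simulate_rusitec()] result: `design.tsv`,
#' `fermentation.tsv`, per phase `otu_<phase>.tsv` (with taxonomy column),
#' `tree_<phase>.nwk` and `taxonomy_<phase>.tsv`, plus `truth.json` and the
#' generating `config.json`.
#'
#' @param dataset result of [simulate_rusitec()].
#' @param dir output directory (created if needed).
#' @param config the [simulation_config()] used (stored for provenance).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(dataset$design, file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$fermentation,
                     file.path(dir, "fermentation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (ph in names(dataset$communities)) {
    com <- dataset$communities[[ph]]
    write_otu_table(com$counts, file.path(dir, paste0("otu_", ph, ".tsv")),
                    com$taxonomy)
    ape::write.tree(com$tree, file.path(dir, paste0("tree_", ph, ".nwk")))
    utils::write.table(
      data.frame(otu = com$taxonomy$otu,
                 taxonomy = paste(com$taxonomy$phylum, com$taxonomy$genus,
                                  sep = ";")),
      file.path(dir, paste0("taxonomy_", ph, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (!is.null(config))
    jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Run the full analysis pipeline on a synthetic or on-disk dataset
#'
#' Executes the analysis stages in order — [2H] stoichiometric balance, gas
#' metrics, community diversity (low-count filter, rarefaction, alpha
#' diversity, genus aggregation, weighted UniFrac, PCoA) per digesta phase,
#' and factorial statistics (LS means, effect tests, genus-parameter
#' Pearson correlations) — and writes tidy result tables plus a manifest
#' recording parameters, the rarefaction seed, warnings and output
#' checksums. Reruns with the same inputs and seed are byte-identical. On
#' any stage failure, partially written outputs are removed.
#'
#' @param dataset a [simulate_rusitec()] result, or a directory written by
#'   [write_dataset()].
#' @param out_dir output directory.
#' @param seed rarefaction seed (mandatory; refuses to run without one).
#' @param rarefaction_depth reads per sample after rarefaction.
#' @param min_reads low-count OTU filter threshold (total reads).
#' @param shannon_base Shannon logarithm base.
#' @param unifrac_normalized use the normalized weighted UniFrac variant.
#' @param ace_cutoff ACE rare/abundant threshold.
#' @param ch4_energy_density methane energy density, kJ/L.
#' @return named list of result objects, invisibly; files in `out_dir`.
#' @export
run_pipeline <- function(dataset, out_dir, seed,
                         rarefaction_depth = 41921, min_reads = 10,
                         shannon_base = 2, unifrac_normalized = FALSE,
                         ace_cutoff = 10, ch4_energy_density = 39.54) {
  if (missing(seed)) stop("an explicit rarefaction 'seed' is required")
  if (is.character(dataset)) dataset <- .read_dataset(dataset)
  created <- !dir.exists(out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  warnings_log <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
    p
  }
  stage <- "setup"
  res <- withCallingHandlers(tryCatch({
    stage <- "stoichiometry"
    h2in <- dataset$fermentation
    # the design's 'temperature' is a treatment label; the gas-law kelvin
    # temperature travels in 'temperature_k'
    h2in$temperature <- if ("temperature_k" %in% names(h2in))
      h2in$temperature_k else 312.65
    h2 <- h2_balance_table(h2in)
    h2$temperature <- dataset$fermentation$temperature
    emit(h2, "h2_balance.tsv")

    stage <- "gas_metrics"
    gas <- gas_metrics_table(dataset$fermentation,
                             ch4_energy_density = ch4_energy_density)
    emit(gas, "gas_metrics.tsv")

    stage <- "diversity"
    diversity <- list()
    for (ph in names(dataset$communities)) {
      com <- dataset$communities[[ph]]
      counts <- filter_low_count_otus(com$counts, min_reads)
      rare <- rarefy_counts(counts, rarefaction_depth, seed = seed)
      alpha <- alpha_diversity(rare, base = shannon_base,
                               rare_threshold = ace_cutoff)
      emit(alpha, paste0("alpha_", ph, ".tsv"))
      genus <- aggregate_taxa(counts, com$taxonomy, "genus")
      emit(data.frame(sample = rownames(genus), genus,
                      check.names = FALSE),
           paste0("genus_abundance_", ph, ".tsv"))
      d <- weighted_unifrac(rare, com$tree,
                            normalized = unifrac_normalized)
      write_distance_matrix(d, file.path(out_dir,
                                         paste0("unifrac_", ph, ".tsv")))
      written <- c(written, file.path(out_dir,
                                      paste0("unifrac_", ph, ".tsv")))
      ord <- pcoa_ordination(d)
      emit(data.frame(sample = rownames(ord$coordinates),
                      ord$coordinates[, seq_len(min(3,
                        ncol(ord$coordinates))), drop = FALSE]),
           paste0("pcoa_coords_", ph, ".tsv"))
      emit(data.frame(axis = seq_along(ord$explained),
                      explained_pct = ord$explained),
           paste0("pcoa_explained_", ph, ".tsv"))
      diversity[[ph]] <- list(alpha = alpha, genus = genus, unifrac = d,
                              pcoa = ord)
    }

    stage <- "factorial_stats"
    params <- c("ch4_ml", "co2_ml", "total_gas", "ch4_per_g_om",
                "ch4_per_g_dm", "mcr",
                "h2_production_p1", "h2_utilization_p1", "h2_gain_p1",
                "h2_recovery_p1", "h2_production_p2", "h2_utilization_p2",
                "h2_gain_p2", "h2_recovery_p2")
    merged <- cbind(gas, h2[setdiff(names(h2), names(gas))])
    fits <- lapply(stats::setNames(nm = intersect(params, names(merged))),
                   function(v) fit_factorial(merged[[v]], merged))
    lsm <- do.call(rbind, lapply(names(fits), function(v)
      cbind(response = v, fits[[v]]$lsmeans)))
    pvals <- do.call(rbind, lapply(names(fits), function(v)
      cbind(response = v, fits[[v]]$anova)))
    emit(lsm, "lsmeans.tsv")
    emit(pvals, "effect_tests.tsv")

    stage <- "correlations"
    ferm_means <- do.call(rbind, lapply(
      split(merged, interaction(merged$run, merged$fermenter, drop = TRUE)),
      function(g) {
        out <- g[1, c("run", "fermenter"), drop = FALSE]
        for (v in intersect(params, names(g))) out[[v]] <- mean(g[[v]])
        out
      }))
    correlations <- list()
    for (ph in names(diversity)) {
      genus <- diversity[[ph]]$genus
      key <- sub(paste0("_", ph, "$"), "", rownames(genus))
      fkey <- sprintf("R%sF%02d", ferm_means$run,
                      as.integer(as.character(ferm_means$fermenter)))
      m <- match(key, fkey)
      if (anyNA(m)) stop("community samples without fermentation records")
      pm <- pearson_matrix(genus[, colMeans(genus) > 1e-4, drop = FALSE],
                           ferm_means[m, intersect(params,
                                                   names(ferm_means))])
      long <- data.frame(
        genus = rep(rownames(pm$r), ncol(pm$r)),
        parameter = rep(colnames(pm$r), each = nrow(pm$r)),
        r = as.vector(pm$r), p_value = as.vector(pm$p),
        label = as.vector(pm$label))
      emit(long, paste0("correlations_", ph, ".tsv"))
      correlations[[ph]] <- pm
    }

    stage <- "manifest"
    manifest <- list(
      parameters = list(seed = seed, rarefaction_depth = rarefaction_depth,
                        min_reads = min_reads, shannon_base = shannon_base,
                        unifrac_normalized = unifrac_normalized,
                        ace_cutoff = ace_cutoff,
                        ch4_energy_density = ch4_energy_density),
      warnings = warnings_log,
      outputs = as.list(stats::setNames(tools::md5sum(sort(written)),
                                        basename(sort(written)))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    list(h2 = h2, gas = gas, diversity = diversity, fits = fits,
         correlations = correlations, manifest = manifest)
  }, error = function(e) {
    unlink(written)
    if (created) unlink(out_dir, recursive = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }), warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  invisible(res)
}

.read_dataset <- function(dir) {
  if (!dir.exists(dir)) stop("no such dataset directory: ", dir)
  design <- utils::read.delim(file.path(dir, "design.tsv"),
                              stringsAsFactors = FALSE)
  ferm <- utils::read.delim(file.path(dir, "fermentation.tsv"),
                            stringsAsFactors = FALSE,
                            check.names = FALSE)
  phases <- sub("^otu_(.*)\\.tsv$", "\\1",
                list.files(dir, pattern = "^otu_.*\\.tsv$"))
  communities <- lapply(stats::setNames(nm = phases), function(ph) {
    tab <- read_otu_table(file.path(dir, paste0("otu_", ph, ".tsv")))
    tree <- read_newick_tree(file.path(dir, paste0("tree_", ph, ".nwk")))
    list(counts = tab$counts, taxonomy = tab$taxonomy, tree = tree)
  })
  list(design = design, fermentation = ferm, communities = communities)
}
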