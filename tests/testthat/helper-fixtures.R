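# Shared fixture builders: tiny count matrices, trees and designs built in
# code at test time.

random_count_matrix <- function(n_samples, n_otus, lambda = 3,
                                prefix = "s") {
  m <- matrix(rpois(n_samples * n_otus, lambda), n_samples, n_otus,
              dimnames = list(paste0(prefix, seq_len(n_samples)),
                              paste0("OTU", seq_len(n_otus))))
  storage.mode(m) <- "integer"
  m
}

two_tip_star <- function() ape::read.tree(text = "(A:1,B:1):0;")

four_tip_tree <- function()
  ape::read.tree(text = "((A:1,B:1):0.5,(C:2,D:1):0.25):0;")

small_taxonomy <- function(otus, genera) {
  data.frame(otu = otus, phylum = "Euryarchaeota", genus = genera)
}

# fast fermentation-only config for simulator tests
small_config <- function(seed = 1, ...) {
  simulation_config(seed = seed, n_runs = 2, n_days = 2,
                    otus_per_genus = 25, read_depth_mean = 5000,
                    rarefaction_depth = 3000, ...)
}
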