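Package: rusitecarch
Title: Metabolic Hydrogen Balance and Archaeal Community Analysis for
    Rusitec Fermentation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in vitro rumen simulation (Rusitec)
    experiments under a factorial treatment design. Implements the
    stoichiometric metabolic-hydrogen ([2H]) balance of fermentation end
    products with both caproate pathways and Ideal-Gas-Law methane
    conversion, fermentation-gas metrics (total gas, gas fractions,
    apparent nutrient disappearance, methane yields and conversion rate),
    archaeal community diversity from OTU count tables (low-count
    filtering, rarefaction, ACE, Shannon, Simpson, singles, weighted
    UniFrac, principal coordinate analysis, taxon aggregation),
    least-squares-means factorial statistics with Pearson correlation
    tables, and a synthetic Rusitec data generator for end-to-end
    validation by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    car,
    emmeans,
    jsonlite,
    stats,
    tools,
    utils,
    vegan
Suggests:
    optparse,
    phyloseq,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
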