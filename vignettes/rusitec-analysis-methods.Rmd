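---
title: "Methods: metabolic hydrogen balance and archaeal community analysis for Rusitec experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolic hydrogen balance and archaeal community analysis for Rusitec experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rusitecarch)
```

# The system being modelled

The rumen simulation technique (Rusitec) keeps rumen microbiota fermenting in
continuous-flow vessels fed daily through nylon feed bags. The experiments
this package targets apply a 2 × 2 × 3 factorial of osmolality (normal
~295 vs hyperosmotic ~420 mOsmol/kg), incubation temperature (39.5 vs 42 °C)
and betaine supplementation (control, low, high), with each experimental run
carrying all 12 treatment cells, so *n* runs give *n* observations per cell.
Measured outputs are daily short-chain fatty acid (SCFA) production (mmol/d),
fermentation gas volumes (mL/d), apparent dry-/organic-matter disappearance
from the feed bags (g/d), and per-phase (liquid/solid digesta) archaeal 16S
OTU tables with a phylogeny.

# The metabolic hydrogen balance

Rumen fermentation redox bookkeeping is done in pairs of hydrogen atoms,
written [2H]. Each fermentation end product either releases or consumes
[2H] per mole formed, with the glucose-based stoichiometric coefficients:

| product | [2H]/mol |
|---|---|
| acetate | +2 |
| propionate | −1 |
| butyrate | +2 |
| valerate | −1 |
| caproate via 2 propionyl-CoA (pathway 1) | −4 |
| caproate via 2 acetyl-CoA (pathway 2) | +2 |
| methane | −4 |

Caproate can form by either route, and the two scenarios bracket the truth,
so `h2_balance()` always reports both. Total production is the sum of the
positive components (acetate, butyrate, and caproate under pathway 2); total
utilization is the magnitude sum of the negative ones (propionate, valerate,
methane, and caproate under pathway 1). The derived quantities are

* gain = production − utilization (mmol [2H]/d), and
* recovery % = 100 × utilization / production, left `NA` when production is
  zero (degenerate inputs must not abort a batch).

Methane enters the balance in moles. Measured CH~4~ volumes are converted
with the Ideal Gas Law, *n* = *PV/RT* (kPa · mL / (8.3145 J mol⁻¹ K⁻¹ · K)
= mmol). The conditions under which the published volumes were measured are
not recoverable: back-calculating from the printed aggregate values implies
a molar volume near 25.3 L/mol, matching neither 39.5 °C/1 atm (25.66) nor
25 °C/1 atm (24.47). We therefore expose temperature and pressure as
arguments and default to the treatment incubation temperature (312.65 K or
315.15 K) at 101.325 kPa rather than guessing a hidden calibration.

Two further conventions: the balance uses the straight-chain acids only
(the `include_iso` switch adds isobutyrate/isovalerate with the coefficients
of their n-forms, since the branched acids are measured but conventionally
excluded from the balance), and minor products such as formate or
heptanoate are excluded by default but can be added through the `extra`
argument of `h2_stoich_coefficients()`.

**Rounding.** When package output is compared against published LS means we
round half-to-even (R's `round()`), not half-away-from-zero. The printed
totals are rounded from full-precision model means, and the half-even
convention is the one that reproduces every printed utilization sum from
the printed components (e.g. 16.7 + 2.75 + 6.0 + 7.8 = 33.25 → printed
33.2). Note that the printed normal-osmolality production totals (80.6,
84.4) are *not* reachable from their printed components (which sum to 80.7,
84.5) under any rounding rule — a plain consequence of rounding before
summing — so identity checks use the cells that are arithmetically
consistent.

# Gas metrics

Total fermentation gas is CH~4~ + CO~2~ + O~2~; O~2~ is routinely measured
but rarely reported, so readers accept a missing O~2~ column as zero with a
warning. Apparent disappearance is feed-in minus residue-out per nutrient,
and methane yield is CH~4~ volume per gram degraded. The methane conversion
rate (MCR) expresses CH~4~ energy as a percentage of gross-energy intake;
the energy density of methane is not a measured quantity here and defaults
to the standard combustion value 39.54 kJ/L (configurable), with GE intake
supplied as data.

# Community diversity

Starting from a samples × OTUs count matrix:

1. **Low-count filter.** OTUs with fewer than 10 reads total across samples
   are removed (`filter_low_count_otus()`), mirroring standard practice for
   denoising clustered OTU tables.
2. **Rarefaction.** Counts are subsampled without replacement to a common
   depth, default 41,921 reads (the conventional "lowest sample" rule). An
   explicit integer seed is mandatory and the caller's RNG state is never
   touched, so batch runs are reproducible by construction.
3. **Alpha diversity.** Shannon (base-2 logarithm by default — the
   historical convention of the upstream analysis toolchains; configurable),
   Simpson reported as the complement 1 − D (matching the 0.90–0.91 range
   conventionally printed; D and 1/D available), observed richness, singles
   (OTUs seen exactly once in the sample, computed after rarefaction by
   default), and the abundance-based coverage estimator ACE with the
   conventional rare/abundant cutoff of 10 reads. When every rare read is a
   singleton the ACE coverage term is zero and the estimator is undefined;
   we return bias-corrected Chao1 with a warning instead of aborting.
4. **Weighted UniFrac.** The raw (unnormalized) form
   d(A,B) = Σ~b~ ℓ(b) · |p~A~(b) − p~B~(b)| over branches, with p~X~(b) the
   fraction of sample X's reads descending from b. The tip-depth-normalized
   variant is available via `normalized = TRUE`. Computed by a single
   postorder accumulation of per-branch proportion masses, then a Manhattan
   distance over branch-weighted profiles.
5. **PCoA.** Gower double-centering of squared distances and
   eigendecomposition. Negative eigenvalues (expected for non-Euclidean
   dissimilarities such as raw weighted UniFrac) are dropped from both the
   coordinates and the explained-variance denominator, and their count is
   reported; no Lingoes/Cailliez correction is applied.

The implementations are cross-checked in the test suite against independent
references (vegan for the alpha metrics — including verifying that the ACE
formula used is identical — phyloseq for both UniFrac variants, ape for
PCoA), but the package's own code paths are what run in the pipeline.

# Factorial statistics

The source experiments fit a mixed model with run as a random effect. This
package deliberately fits ordinary least squares with run as an additive
fixed block plus the full three-way factorial (`fit_factorial()`). For a
balanced design the least-squares means and treatment contrasts are
identical to the mixed-model point estimates, and no REML variance
components are needed downstream; the difference matters only for
unbalanced data, where the package warns. LS means are extracted with
emmeans and F-tests use type-III sums of squares (car); with the sum-to-zero
contrasts the model is parameterised accordingly. Repeated daily records of
a fermenter are always averaged before fitting — one value per experimental
unit — matching the convention of analysing microbial data without repeated
measures. P ≤ 0.05 is labelled significant and 0.05 < P ≤ 0.10 a tendency,
kept as distinct labels. Pearson correlations between genus abundances and
fermentation parameters use `cor.test()` per pair with the same labelling;
no multiple-testing correction is applied, matching the reporting
convention of this literature.

# The synthetic data generator

The generator (`simulate_rusitec()`) exists so the full pipeline can be
exercised and validated by parameter recovery without any external data.
Its defaults are the study conditions: 6 runs × 12 fermenters × 5 sampling
days, fermentation baselines and treatment shifts set to the published
LS-mean magnitudes (e.g. CH~4~ 87.3 mL/d at normal osmolality with a
−38 mL/d hyperosmolality shift, residual σ = 5 and run-level σ = 3 mL/d),
GE intake 211.8 kJ/d (back-solved from the printed MCR), and per-phase
genus compositions at the published means (liquid: *Methanobrevibacter*
0.49, Vadin CA11 0.30, *Methanosphaera* 0.043, …; the solid phase carries
no *Methanosaeta*), with read depth averaging 66,139 and 3,015 OTUs across
9 genus-level groups (335 per genus — the published OTU count divided
evenly). Where the literature reports no value (σ's of minor variables,
the Dirichlet concentration of 200, the within-genus geometric decay of
0.97) we chose magnitudes a practitioner would call realistic for Rusitec
data once, and they are not tuned thereafter.

The effect model is additive on the measurement scale for fermentation
variables (the intercept is chosen so the *marginal* means reproduce the
configured column means under the balanced design) and additive on the
logit scale for genus proportions, renormalised before the Dirichlet draw.
Reads are allocated multinomially to OTUs using geometric rank weights
within each genus so that a rare tail with singletons exists and ACE and
singles are genuinely exercised. The phylogeny is a coalescent backbone
over genera with coalescent clades grafted per genus, unit-scaled; its only
adequacy claim is that UniFrac separates groups when injected effects are
large. Negative Gaussian draws are truncated at zero and counted.

What the generator does **not** emulate: the dominance structure of real
archaeal communities (real samples show Shannon ≈ 4.7 bits at ~1,500
observed OTUs, i.e. far more uneven than a geometric-within-genus
allocation at this depth), compositional correlations between taxa beyond
the Dirichlet, day-to-day autocorrelation within fermenter, and any
sequencing artefacts (chimeras, clustering noise). Passing recovery tests
therefore demonstrates correctness of the estimators under a clean
generative model, not robustness to real-data pathologies.

# Problem sizes and numerical choices

The validation suite runs the complete pipeline on the full 144-sample
dataset (2 phases × 72 fermenter-runs) at the default depth and OTU count,
twice, to demonstrate seed determinism; recovery experiments use 200
simulation replicates of the 6-run design. Tolerances: diversity metrics
agree with references to 1e-6; stoichiometric identities hold to 1e-9
relative; PCoA round-trips Euclidean configurations to 1e-8. Ties and
degenerate cases (zero production, zero gas totals, zero-variance
correlation inputs, all-singleton ACE) return `NA` or a documented fallback
rather than erroring, so a single degenerate fermenter-day never aborts a
batch.

# Known limitations

* The [2H] balance is stoichiometric bookkeeping only — no thermodynamics
  of dissolved H~2~, no methanogen kinetics, no betaine degradation term
  (betaine itself can yield CH~4~, which the balance attributes to [2H]).
* SCFA "daily production" is consumed as already-computed mmol/d; outflow
  vs pool accounting upstream is the caller's responsibility.
* OLS with a fixed run block is not REML: variance components and
  Satterthwaite degrees of freedom are out of scope, and for unbalanced
  designs the LS means are model-based approximations.
* Published alpha-diversity values and PCoA percentages depend on the
  deposited raw reads and their upstream OTU clustering, which this package
  deliberately does not reimplement; they are not reproduction targets.
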