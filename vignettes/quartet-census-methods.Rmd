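---
title: "Methods: quartet likelihoods, model selection, and the gene-tree census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quartet likelihoods, model selection, and the gene-tree census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(quartetcensus)
```

# The problem

Four lineages — labelled by role `Z` (zokor), `B` (bamboo rat), `S` (blind
mole rat) and `O` (outgroup) — admit exactly three unrooted tree topologies,
identified by which role pairs with `Z` across the internal branch:

* `T1` = ZB|SO,
* `T2` = ZS|BO,
* `T3` = ZO|BS.

Because the topology space is exhaustively enumerable, inference per gene is
a three-way likelihood comparison, and a collection of genes becomes a
*census*: how many genes support each topology above a bootstrap-support
cutoff, and does that distribution deviate from the uniform 1/3–1/3–1/3
null? A strong deviation toward one topology, together with a concatenated
analysis that recovers the same topology with full support, is the package's
headline result pattern.

# Likelihood machinery

## Pruning on a quartet

The log-likelihood of an alignment on a quartet is computed by Felsenstein's
pruning algorithm, summing over the two unobserved internal node states.
Columns are first compressed to unique site patterns with multiplicities; a
four-taxon alignment has at most $4^4 = 256$ patterns, so likelihood cost is
bounded regardless of alignment length. Gaps and ambiguity codes are treated
as missing data (partial likelihood 1 in every state). The inner loop is
implemented in C++; a brute-force enumeration over all 16 internal state
pairs is kept in the test suite as an independent oracle.

```{r}
aln <- codon_alignment(c(Z = "ACGTAC", B = "ACGTAC", S = "ACGAAC", O = "ACGAAT"))
log_likelihood(aln, "T1", c(0.1, 0.1, 0.1, 0.2, 0.05), model_params("JC"))
```

## Substitution models

The model space is the jModelTest-style family: 11 exchangeability schemes
(JC/F81 through SYM/GTR, encoded as tie patterns over the six rates AC, AG,
AT, CG, CT, GT with the GT class fixed to 1), crossed with equal or
empirical base frequencies and optional `+I` (invariant sites) and `+G`
(discrete gamma, 4 categories, mean-of-bin discretization) components —
88 models in `model_catalog("jmt88")`. Generators are scaled to one expected
substitution per unit branch length and exponentiated through a symmetrized
eigendecomposition, which is exact and stable for reversible models.

```{r}
model_spec("GTR+I+G")
discretize_gamma(0.5, 4)
```

## Fitting and model selection

`fit_model()` maximizes the likelihood on a fixed topology by coordinate
ascent: golden-section line searches over the five branch lengths (in C++)
interleaved with Nelder–Mead (or Brent, when one-dimensional) over the free
continuous parameters on log/logit scales. Starting values are fixed
(branches 0.1, `alpha` 1, `p_inv` 0.01, exchangeabilities 1), so fits are
deterministic. `select_model()` fits a catalog and picks the AIC/BIC winner;
the free-parameter count follows the jModelTest convention (substitution
parameters + 3 frequencies when unequal + I + G + 5 branch lengths).

Model selection runs *once per gene*, on the topology with the best
preliminary JC likelihood, and the selected family is reused for all three
topologies and all bootstrap replicates — re-selecting per replicate would
be both incompatible with the one-model-per-gene convention and roughly two
orders of magnitude slower.

# Per-gene inference and bootstrap

`infer_gene_tree()` evaluates all three topologies under the selected
family. Bootstrap support is nonparametric column resampling, implemented as
multinomial resampling of the compressed pattern counts (an equivalent,
length-independent formulation); each replicate re-optimizes branch lengths
warm-started from the full-data fit, and `fast = TRUE` freezes the
continuous model parameters at their full-data estimates. Exact likelihood
ties are credited `1/(number tied)` so supports remain well defined on
degenerate data. With `n_bootstrap = 0` the full-data winner receives
support 1 (split across ties).

# Fourfold-degenerate sites and saturation

`identify_4d_columns()` selects third codon positions at which every taxon's
codon is clean, the first two positions are identical across taxa, and the
shared leading 2-mer is one of the eight fourfold families (derived from the
standard genetic code, not hardcoded) — so any third-position difference is
synonymous. `concatenate()` joins genes into a supermatrix on all sites or
4D sites only, with RAxML-style partition bookkeeping, and `filter_short()`
applies a strict 100 bp floor first.

Saturation is screened with an entropy index: `Iss` is the mean per-column
Shannon entropy divided by its expectation under full saturation
(`full_saturation_entropy()`, exact by enumeration for up to 6 taxa —
1.3240 bits for 4 taxa at uniform frequencies). `iss_test()` compares `Iss`
to a critical value with a one-sample t statistic; `estimate_iss_c()`
operationalizes the critical value as the `Iss` at which simulated quartets
lose the true topology in 50% of replicates.

# The census

`tally()` counts a gene for a topology only when that topology is its best
*and* its support strictly exceeds the cutoff (a support of exactly 0.5 at
cutoff 0.5 is uncounted, matching the strict ">50%" convention);
`chisq_uniform()` tests the three counts against the uniform null with
df = 2. Statistics are kept at full precision and rendered half-up at 2
decimals only in reports. An external table of `(gene_id, best_topology,
support)` — e.g. posterior probabilities from a Bayesian analysis done
elsewhere — flows through the same code path.

```{r}
tb <- census_from_counts(c(1676, 1445, 1162), cutoff = 0.5)
percentages(tb)
tidy(chisq_uniform(tb))
```

# The simulator

`simulation_config()` generates quartet gene sets for end-to-end validation.
Defaults are chosen to emulate a nuclear transcriptome-scale census:

* gene lengths around 361 codons (negative binomial, dispersion 4, floored
  at 34 codons so genes can pass the 100 bp filter);
* a generating-topology mixture of (0.39, 0.34, 0.27) over T1/T2/T3 — a
  majority class with substantial discordance, the regime where a census is
  informative;
* short external branches (0.05, longer 0.15 outgroup) and a very short
  internal branch (0.02 substitutions/site), so per-gene signal is weak and
  bootstrap supports spread across the cutoff;
* an HKY-like model (transition/transversion exchangeabilities 4:1,
  frequencies 0.3/0.2/0.2/0.3) and codon-position rate multipliers
  (1, 0.5, 2.5) making third positions fastest, so 4D-site extraction is
  meaningful;
* root sequences drawn uniformly over the 61 sense codons, so the root
  carries no stop codons (`simulation_config_mito()` swaps in 13 genes with
  mitochondrial-like lengths and 5-fold faster branches).

These are phenomenological choices, not a coalescent model: the mixture
stands in for incomplete lineage sorting without modelling it, there are no
indels, and selection on codons is ignored. Each gene derives its own seed
from `(seed, gene index)`, so gene `i` is reproducible independently of
`n_genes`.

```{r, eval = FALSE}
cfg <- simulation_config(n_genes = 200, seed = 1)
genes <- simulate_gene_set(cfg)
res <- infer_genes(genes, n_bootstrap = 100, seed = 1, fast = TRUE)
tb <- tally(res, cutoff = 0.5)
chisq_uniform(tb)
concatenated_analysis(genes, n_bootstrap = 100, seed = 1)
```

# Numerical choices

* Transition probabilities come from the symmetrized eigendecomposition
  $S = D^{1/2} Q D^{-1/2}$; tiny negative entries are clamped at zero.
* Branch lengths are bounded to $[10^{-8}, 10]$; golden-section iteration
  counts are sized to the requested branch tolerance.
* Site likelihoods are floored at $10^{-300}$ before taking logs.
* Reported percentages and statistics use half-up rounding
  (`round_half_up()`), because base R's round-half-even would render
  borderline published values differently.

Problem sizes used in the package's own validation (e.g. 200 genes, 100
bootstrap replicates, 5,000-site model-selection replicates) were chosen to
run on a single CPU in minutes while leaving the statistical properties
testable; they are package choices, not external requirements.
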