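---
title: "Dual-state signature drug screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-state signature drug screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualscreen)
```

## The problem

Tumors such as glioblastoma contain cells in at least two interconvertible
states — a stem-like state (GSC) that drives recurrence and resists
conventional therapy, and a differentiated state (DGC) that makes up the
tumor bulk. A drug that kills one state can leave the other to regrow the
tumor, so a rational combination needs one agent per state. `dualscreen`
implements an in silico route to such combinations: derive a gene-expression
signature for each state from matched culture pairs, score a large cell-line
panel for how strongly it expresses each signature, and nominate drugs whose
sensitivity profile across the panel tracks the signature score. The package
also carries the downstream validation analyses — IC50 fitting, combination
synergy scoring, and a differential-expression filter for treatment
transcriptomes.

## Signature derivation: the signal-to-noise ranking

Given a genes × samples matrix with two groups A and B (at least two samples
each), every gene is scored with the signal-to-noise ratio

$$\mathrm{SNR} = \frac{\mu_A - \mu_B}{\sigma'_A + \sigma'_B},
\qquad \sigma' = \max(s,\; f\,|\mu|,\; a),$$

where $s$ is the within-group sample standard deviation and the two floors
(fractional $f$ and absolute $a$, both 0.2 by default) are the classic GSEA
"minimum standard deviation" guard: with three samples per group the raw
sample standard deviation is a very noisy denominator, and near-constant
genes would otherwise dominate the ranking. Both floors can be set to 0,
which restores two exact symmetries that the test suite asserts: SNR is
invariant under positive rescaling of a gene and is negated by swapping the
groups. The contrast is unpaired even when the samples arrive as matched
pairs — the metric is defined on group means — and the pairing is kept only
as sample metadata. Ties are broken by gene id so the ranking is
deterministic.

The signature pair is simply the top $n$ and bottom $n$ genes of the ranking
($n = 50$ by default, the size used to define the GSC/DGC signatures); the
bottom set is reversed so its strongest gene comes first. Whether SNR should
be computed on TPM or log-scale expression is not fixed by the method; the
default here is log2 expression (the `units` flag on `expression_matrix`
records the caller's claim).

## ssGSEA projection

For one sample, genes are ranked by decreasing expression (ties again broken
by id) and given absolute ranks $r_j$ with the top gene at $r = N$. For a
set $S$ the score is the sum over list positions of the difference between
two cumulative distributions,

$$\mathrm{score} = \sum_{i=1}^{N} \left[ P_{in}(i) - P_{out}(i) \right],
\qquad
P_{in}(i) = \frac{\sum_{j \in S,\ \mathrm{pos}(j) \le i} r_j^\alpha}
                 {\sum_{j \in S} r_j^\alpha},
\qquad
P_{out}(i) = \frac{\#\{j \notin S : \mathrm{pos}(j) \le i\}}{N - |S|}.$$

Because only ranks enter, the score is invariant under any strictly monotone
transformation of the sample's expression values — normalization choices
upstream (TPM vs RPKM vs log) shift the absolute scale of nothing. The
implementation is linear-time per sample; the test suite checks it against a
deliberately naive quadratic transcription of the two sums at `1e-12`
tolerance on every gene set of size ≤ 3 of an 8-gene sample.

Two settings follow the GenePattern projection module's defaults, since the
module is the field's reference implementation: $\alpha = 0.25$ and
normalization of the final table by its global range (max − min), which makes
the table's range exactly 1 without changing any correlation computed from
it. Both are configurable. Tie-breaking by gene id rather than by average
rank is a deliberate divergence risk: on data with many tied values other
implementations may differ slightly, but results here are reproducible
bit-for-bit. Each signature must attain at least 80% of its members in the
panel (`min_coverage`); below that the projection refuses to score rather
than silently degrade.

## The drug screen

With signature scores for each cell line and a drugs × cell-lines AUC matrix
(lower AUC = more sensitive), each drug gets a Pearson correlation $r$
between score and AUC over pairwise-complete cell lines, a two-sided p-value
via $t = r\sqrt{(n-2)/(1-r^2)}$, and a Benjamini–Hochberg q-value computed
across drugs within each signature (Bonferroni available). Candidate drugs
are the $k$ most negative correlations — high-scoring (e.g. stem-like) lines
being reliably more sensitive. No q-value gate is applied before ranking by
default, matching the lowest-correlation top-$k$ selection rule; the
q-values are reported so callers can gate. Drugs with fewer than `min_n`
complete pairs (default 10) or zero variance are excluded with an explicit
reason rather than dropped.

## Pharmacology

**4PL fitting.** Dose-response viability is fit with the four-parameter
logistic in $\log_{10}$-dose space:

$$Y = \mathrm{Bottom} + \frac{\mathrm{Top} - \mathrm{Bottom}}
      {1 + 10^{(X - \log_{10}\mathrm{IC50})\cdot \mathrm{Hill}}},$$

the "log(inhibitor) vs response — variable slope" form, written with the
exponent sign that makes positive Hill mean viability *decreasing* with dose
(the convention GraphPad uses for inhibition data; the curve at
$X = \log_{10}\mathrm{IC50}$ is exactly the plateau midpoint either way).
Zero-dose wells are excluded from the fit — $\log 0$ is undefined, and the
vehicle's role is to anchor the percent-inhibition normalization, not the
curve. The optimizer is multi-start Levenberg–Marquardt: three deterministic
heuristic starts (Top = max response, Bottom = min response, LogIC50 at the
dose nearest the half-range crossing, Hill ∈ {0.5, 1, 2}) plus seeded random
starts inside the parameter box, keeping the lowest-RSS solution. On
noiseless model data this recovers all four parameters to $10^{-6}$ from any
seed; at 5 percentage points of Gaussian noise on a 5-dose grid with
triplicates the median LogIC50 error stays below 0.1 log units.

**HSA synergy.** The highest-single-agent reference model sets the expected
combination effect to the maximum of the two monotherapy effects at the
corresponding doses, $E(a,b) = \max(I(a,0), I(0,b))$. The synergy score is
the mean of the observed-minus-expected excess over the combination cells
only (both doses > 0); monotherapy margins are never averaged in, and no
baseline correction is applied to the inhibition matrix before scoring
(external synergy tools offer both options and do not agree on defaults, so
this is a documented divergence risk when comparing absolute scores across
tools; `combination_matrix(normalize = TRUE)` re-anchors a matrix whose
vehicle cell is nonzero). Classification bands follow the standard reading:
score < −10 antagonistic, −10 to 10 **inclusive** additive, > 10
synergistic.

**DEG rule.** Treatment-vs-control transcriptomes are filtered by: z-score
each gene across the compared samples, unpaired Student t-test per gene on
the standardized values, BH adjustment across genes, and the call
`(FC > 2 or FC < 0.5) and FDR < 0.05` with strict inequalities — a gene at
fold change exactly 2 is never flagged. Testing standardized rather than raw
values is statistically unusual (it discards the scale information a
log-space t-test would use) but is implemented literally because it is the
published filter this package reproduces; `on = "log2"` switches to testing
`log2(TPM + 1)` for users who prefer convention, and Welch's correction is
available via `var_equal = FALSE`. The fold change is computed on raw TPM
group means with a 0.01 TPM pseudocount for stability near zero (no
pseudocount is part of the published rule). Z-scores are computed across the
two compared groups by default; `scope = "all"` standardizes across every
sample in the matrix instead, since the published description is ambiguous
on this point.

## What the synthetic generators emulate — and what they do not

The generators are first-class, seeded, pure functions (the global RNG
stream is never touched) that expose their ground truth, so every recovery
claim in the test suite is checkable.

* `sim_matched_expression` emulates matched stem-like/differentiated culture
  pairs: per-gene log-normal baselines (location 3, scale 1 on log2 TPM —
  fixture values, not biological claims), a per-gene *culture-line effect*
  shared by the two members of a pair (sd 0.5), and small residual noise
  (sd 0.1). The shared pair effect is the load-bearing design choice: in
  real matched pairs, patient-line heterogeneity dominates within-group
  variance but cancels in the group-mean difference, which is what lets an
  unpaired SNR with three samples per group separate planted effects from
  thousands of null genes. With independent noise of the same within-group
  magnitude, no ranking statistic could do so at these sample sizes. Planted
  genes are shifted by `effect_sd_units` × the within-group pooled sd
  (default 2), half up in each state.
* `sim_cell_line_panel` gives each line a latent state score ~ Uniform(0,1);
  stem-signature genes rise linearly with it (2 log2 units across the axis),
  differentiated-signature genes fall, background genes are noise (sd 0.5).
* `sim_drug_response` plants associated drugs with
  `AUC = μ₀ + slope·state + ε`; the default slope −1 with noise sd 0.385
  gives a population correlation of −0.6 against the uniform state score —
  a strong but realistic screen hit. Non-associated drugs draw AUC
  independently with a matched marginal spread, and a `missing_rate` option
  emulates sparse response portals.
* `sim_dose_response` and `sim_combination` generate viability and
  inhibition grids from 4PL truths on the study's dose grids
  (combination defaults 0–100 nM × 0–500 nM); the combination generator adds
  a planted HSA excess `delta` to combination cells, with noiseless,
  vehicle-anchored margins so the planted excess equals the recovered score
  exactly at zero noise.

None of the generators attempt real panels' gene–gene covariance, lineage
structure, batch effects, or the non-random missingness of response portals.
Passing recovery tests therefore demonstrates that the statistics are
implemented correctly and behave as designed under their stated assumptions
— not that the screen's nominations on real data are correct, which depends
on data quality and on the biological validity of the signatures.

## Numerical and design choices

* All gene-id matching is case-insensitive after whitespace stripping;
  symbol case is inconsistent across public expression resources.
* Missing AUC values stay `NA` (never 0); statistics are pairwise-complete
  with per-drug `n_pairs` reported.
* Preranked GSEA uses gene-label permutations (not phenotype permutations,
  which are meaningless at n = 3/group), sign-stratified NES normalization,
  and the conservative `(1 + k)/(n + 1)` p-value, bounded below by
  `1/(n_perm + 1)`.
* Degenerate inputs fail loudly and early: duplicate identifiers, gene sets
  covering the whole ranking, zero-variance vectors, non-positive vehicle
  means, dose grids without a vehicle anchor, fewer than 5 nonzero doses.
* Problem sizes in the test suite and acceptance script — 5,000-gene
  matched simulations over 25 seeds, 60-line × 100-drug screens over
  50 seeds, 100 noisy dose-response fits — were chosen as the smallest
  designs at which the recovery properties are comfortably identified.

## Reproducing published nominations with real data

The screen's published validation — top-3 candidates GSK-J4, SR8278 and
belinostat for the stem-like signature and dasatinib, lovastatin and
fluvastatin for the differentiated signature — requires the public CCLE
expression panel and CTRP AUC matrix, which are version-dependent external
downloads and are deliberately not bundled or tested here. The recipe: write
the CCLE expression matrix as GCT/TSV and the CTRP per-compound AUC table as
drugs × cell-lines CSV (named as in `read_drug_response`), derive signatures
from the matched-pair accession with `cmd_signatures`, then run `cmd_screen`
with defaults and `top_k = 3`.

## Known limitations

* Absolute ssGSEA scores depend on the unstated settings of the reference
  projection tool (α, normalization); correlation-based screening downstream
  is insensitive to these, but absolute scores should not be compared across
  implementations.
* The synergy score's averaging convention (combination cells only, no
  baseline correction) may differ from external tools' defaults; published
  absolute synergy scores are therefore not exactly recomputable from dose
  grids alone.
* The DEG filter is a mean/t/FDR rule, not a count-model analysis; it has no
  dispersion shrinkage and inherits the low power of n = 3 designs.
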