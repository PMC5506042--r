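---
title: "Dual eigen-analysis of tissue-specific expression profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual eigen-analysis of tissue-specific expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualeigen)
```

## The problem and the model

Longitudinal treatment studies of bulk expression — here the motivating
design is outbred mice on a high-fat diet (HFD) versus regular chow (RC),
with tissues profiled at weeks 1, 9 and 18 — confound two kinds of
structure: *endogenous* variation that every animal undergoes (development,
aging, tissue function) and *exogenous* variation imposed by the treatment.
With three animals per diet-by-week cell and heterogeneous genetic
backgrounds, per-gene tests are weak; the unit of analysis in this package
is instead the eigen-structure of the whole profile.

The log2 expression profile of one tissue is a matrix `E` with `g` genes in
rows and `s` samples in columns, decomposed as

    E = sum_k rho_k u_k v_k'

with nonincreasing singular values `rho_k`, orthonormal *gene eigenvectors*
`u_k` and orthonormal *sample eigenvectors* `v_k`. A sample eigenvector
carries the macro-biology of a component (which samples it separates: diet
groups, ages, phenotype subgroups); its coupled gene eigenvector carries the
micro-biology (which genes load at its two ends).

The *dual* part is the key device for separating endogenous from exogenous
structure: the decomposition is computed twice, once on the pooled
(treatment + control) profile and once on the control-only columns. A
component present in both — gene eigenvectors nearly collinear — existed
without the treatment and is *endogenous*; a pooled component with no
counterpart in the control-only decomposition, whose sample loadings
separate the diet groups, is an *exogenous candidate*: the treatment axis
that vanishes when treated samples are removed.

## Conventions of the decomposition

**Centering.** The default gene- (row-) centers `E` before the SVD. An
uncentered log-intensity matrix is dominated by a rank-1 "grand profile"
component carrying essentially the mean expression of every gene; leading
components that explain on the order of 10–16 % of the total — the regime
this analysis operates in — are only possible once that mean structure is
removed. The mode (`none`, `gene`, `sample`, `double`) is configurable and
recorded in every output.

**Contribution percentages.** The contribution of the top `K` components is
`100 * sum(rho[1:K]) / sum(rho)` — linear in the singular values, not in
their squares. This is the convention under which the published per-tissue
cumulative percentages are internally consistent (the quadratic convention
is not), and it is scale-invariant.

**Sign anchoring.** A component is invariant when `u_k` and `v_k` flip
together, so signs are fixed by the sample side: `v_k` is flipped until its
Spearman correlation with a chosen anchor attribute (week by default) is
nonnegative. A zero or undefined correlation falls back to making the
largest-magnitude sample loading positive, and the component is flagged.
Anchoring never changes `rho` or the reconstruction.

## Matching, association, classification

Only gene eigenvectors are compared across the two decompositions — the
sample sets differ, so sample eigenvectors are not commensurable. Matching
is greedy on the `top_k x top_k` matrix of absolute cosines, largest first,
each control component used at most once, pairs below `min_similarity`
(default 0.3) left unmatched. On the well-separated spectra this analysis
inspects, greedy and optimal assignment coincide, and greedy is auditable.

Sample loadings are associated with design factors as follows: binary
factors (diet, phenotype subgroup) by a two-sided Wilcoxon rank-sum test,
exact when both groups have at most 12 tie-free samples; ordinal and
continuous factors (week, tolerance-test AUCs) by Spearman correlation with
a t-approximation p-value, restricted to samples with observed values.
P-values are Bonferroni-adjusted across the factors tested per component.
These choices are declared defaults, not inferences: the analysis is robust
to monotone transforms on either side, which is what the rank-based tests
encode.

Classification: a matched component with similarity at or above
`sim_threshold` (default 0.6) is endogenous; an *unmatched* component whose
adjusted diet p-value is at most `alpha` (default 0.05) is an exogenous
candidate; everything else is unclassified. Restricting exogenous
eligibility to components unmatched at the matching stage makes the rule
monotone in `sim_threshold`.

One behavior deserves emphasis because it is a property of the method, not
of an implementation: the control profile is a *column subset* of the
pooled profile, so the two decompositions share the control samples' noise.
Near the noise floor, a pooled noise component can genuinely match a
control noise component with |cos| around 0.7–0.8. Such components sit at
singular values near the spectral edge and associate with no factor;
interpretation should stay within the components whose contribution stands
clear of the floor, as the per-component report makes visible.

## Enrichment by Wilcoxon rank-scoring

Gene loadings are ranked ascending with midranks for ties; a gene set's
statistic is its members' rank-sum, tested one-sidedly at either end.
Midranks make the two-end duality exact: up-enrichment at one end equals
down-enrichment at the other, `p_low(u) == p_high(-u)` to machine
precision. The p-value is exact (the rank-sum null recursion) for sets of
at most 10 genes in universes of at most 1000 — thresholds chosen for
desk-scale runtime and configurable — and otherwise a tie-corrected normal
approximation with continuity correction. The approximation is accurate in
the moderate-p regime but, like every normal tail bound, diverges from the
exact tail by orders of magnitude at extreme statistics; conclusions about
"astronomically small" p-values should rely on the exact path or on the
Bonferroni-adjusted ordering, not on the approximate magnitude. Collections
are scored at both ends per set, Bonferroni-corrected by the number of sets
scored, with a minimum effective set size of 5 after intersection with the
universe. The same functions accept any per-gene statistic (for example
group mean differences), not only eigenvector loadings.

## Motif association

The binding-affinity stage is a deliberately self-contained variant of
affinity-profile regression methods. A position frequency matrix (JASPAR
4-row text) is normalized with a pseudocount (default 0.01) against a
background composition (default uniform); each promoter is scanned on both
strands with the log2-odds matrix (`N` scores as background, zero), and the
per-gene best score is converted to significance through the *exact*
single-position null distribution, computed by column-wise convolution on a
millibit grid. Significance is combined over the `2(L - W + 1)` scanned
positions as `1 - (1 - p)^n` and transformed to a binding strength
`-log10(combined)`, monotone decreasing in significance.

Association with a component is the maximum absolute mean-centered running
sum of affinities along the loading-sorted gene list, with an add-one
permutation p-value (`n_perm` default 999, seeded). The statistic is
symmetric under reversal of the sort (the end label swaps) and degenerates
gracefully: constant affinity scores 0 with p = 1. The upstream-region
length is configuration (the simulator's default is 500 bases), as is the
choice of matrices; nothing in the package depends on external scanning
tools.

## Spatial normalization and summarization

Probe-level chips (1002 x 1002 probes, 11 probes per probeset in the
motivating platform) are normalized target-against-reference within
overlapping 50 x 50 subarrays (overlap 25 both ways). Windows step by
`size - overlap`; when the step sequence cannot reach the edge (1002 is not
a multiple of 25), one extra window is anchored at `length - size`, so
coverage is complete — at most 4 windows per interior probe, up to 9 in the
anchored corner where a third layer per axis appears.

Within each window the reference is regressed on the target with a one-knot
continuous piecewise-linear model fitted by least trimmed squares:
minimize the sum of the `h = ceiling(0.75 n)` smallest squared residuals.
Knot candidates are the deciles of the target intensities in the window and
are scanned exhaustively. The LTS optimum is attained by the least-squares
fit of some h-subset, so small instances (n at most 20) are solved exactly
by subset enumeration; production-size windows (2500 probes) use
deterministic concentration steps (a full least-squares start plus
order-statistics elemental starts, iterated refits on the h smallest
residuals). The direction — reference on target — makes the fitted value an
adjustment of the target onto the reference scale; probes in several
windows average their adjusted values. Self-normalization is the identity
to floating-point precision, and region-wise constant distortions are
absorbed exactly wherever a window sees a single regime. All fitting is on
log2 intensities; raw TSV intensities are floored at 1.0 and
log-transformed at load.

Summarization fits the additive model
`log2 I(p, j) = mu + alpha_p + beta_j` per probeset across chips by median
polish and reports `mu + beta_j`. Designated reference chips participate in
the fit, anchoring the scale, and are excluded from the output. This is a
robust additive probe + chip model in the spirit of reference-anchored
summarization; the exact likelihood of the original reference-based model
and the choice of which arrays serve as references are configuration here,
not inference, and are prominently the user's responsibility in any
real-data application. Probesets with fewer than two probes fall back to
per-chip means and are flagged.

## The synthetic generator

The generator exists so that every downstream stage is testable without
external data, and its defaults are the study conditions: 18 samples (3 per
diet-by-week cell at weeks 1, 9, 18), a few thousand genes, one endogenous
and one exogenous planted component, i.i.d. Gaussian log-scale noise.

* The endogenous sample loading is the centered week — monotone in age in
  every sample. The exogenous loading starts from the HFD indicator, which
  in the balanced design is already exactly orthogonal to the week trend
  and exactly zero on control samples (Gram–Schmidt handles unbalanced
  layouts). Zeroing on controls is what makes the treatment component
  vanish from the control-only decomposition *by construction*; a
  week-scaled treatment loading cannot do this, because its week trend is
  shared with the endogenous axis and Gram–Schmidt then spreads it onto the
  control samples.
* Gene eigenvectors are random orthonormalized Gaussian directions.
* Strengths are parameterized on the per-gene scale: a component of
  strength `c` is planted with singular value `c * sqrt(n_genes)`, so
  `c / noise_sd` is the per-gene signal-to-noise ratio and recovery does
  not silently degrade as the universe grows. The defaults (endogenous 8,
  exogenous 5, noise 1) put both components well clear of the
  Marchenko–Pastur edge of the noise (about `sqrt(g) + sqrt(s)`), which is
  the regime the analysis assumes; no published effect sizes exist for
  these components, so the defaults are chosen for testability and stated
  here once.
* Tolerance-test AUCs are simulated for the oldest cohort with a treatment
  shift, and treated week-18 animals are split into better/worse subgroups
  by their simulated GTT — mirroring the attribute table the real design
  produces.
* Gene sets are planted at a designated extreme of a planted gene
  eigenvector among uniformly drawn null sets; promoters are i.i.d. uniform
  nucleotides with the motif consensus inserted at rank-dependent rates
  (default: probability 1 for the top 50 genes, 2 % background).

What the generator does *not* emulate: probe-sequence effects, count-based
noise, correlated gene modules, batch structure, or any real biological
pathway geometry. Passing the synthetic suite shows the machinery is
correct under the stated model; it does not certify recovery on real
arrays, where the noise is neither i.i.d. nor Gaussian and effect sizes are
unknown.

## Numerical choices and degenerate inputs

* Orthonormality is asserted at 1e-8 and reconstruction at 1e-6 relative —
  ordinary double-precision headroom for LAPACK SVDs.
* SVD ties are left in LAPACK order; matching breaks ties by scan order;
  enrichment rows sort by adjusted p with set name as the deterministic
  tie-break.
* Missing expression values are refused at load, never imputed. Duplicate
  gene or sample ids are errors naming the offender.
* Zero-variance genes under gene centering are kept as zero rows.
* Constant target intensities in a window trigger a flagged flat fallback
  fit; degenerate loadings give p = 1, flagged; constant affinity profiles
  score 0 with p = 1; sequences shorter than the motif get strength 0,
  flagged.
* All stochastic stages consume seeds derived from one global seed;
  reports are byte-reproducible from `(inputs, config, seed)`.

## Problem sizes in the shipped tests

The test suite and the acceptance script run at deliberately modest sizes:
2000-gene, 18-sample simulations (the design's native sample count) with
10–20 replicate seeds for recovery claims; a single full-size 1002 x 1002
chip for the self-normalization identity; 150-probe-wide chips for artifact
removal; exhaustive LTS oracles at 8–13 points; 2000-replicate null
calibrations for the rank tests. These sizes were chosen so the whole suite
documents the method's behavior in minutes on a desk machine.

## Limitations

* The exogenous/endogenous vocabulary is structural, not causal; an
  unmatched diet-associated component is a *candidate* whose biology needs
  independent evidence.
* With nested sample sets the noise is shared between the two
  decompositions, so matches near the spectral edge are uninformative (see
  above); the method offers no automatic significance cut on the spectrum.
* Reproducing published per-tissue singular values from deposited raw
  arrays is out of scope for the automated checks: it requires the original
  reference-array selections and centering conventions, which are not
  specified by the published record. The readers and the normalization
  stage accept such data; the contribution-percentage convention is
  verified against the published table directly.
* Bonferroni is the only multiplicity control offered, matching the
  analysis this package implements; FDR-based alternatives are outside its
  scope.
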