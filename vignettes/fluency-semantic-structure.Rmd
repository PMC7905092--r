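---
title: "Estimating semantic memory structure from category-fluency data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating semantic memory structure from category-fluency data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluencysvd)
```

## The model

Category fluency asks a subject to name as many members of a semantic
category (here, animals) as possible in one minute. The *order* and
*co-occurrence* of the produced items carry information about the
organisation of semantic memory that the raw word count misses: healthy
adults tend to recall in subcategory runs (pets, then carnivores, then
herbivores), while disorganised semantic memory produces flatter, less
cluster-bound output.

The package estimates that organisation in four stages.

**Cleaning.** Each raw token is trimmed, upper-cased, and synonym-mapped to
a canonical form, then classified in a fixed order: proper noun (surface
form flagged in the lexicon), intrusion (not a category member), repetition
(canonical form already produced by the same subject in the same session),
otherwise kept. The fixed order makes the three error classes mutually
exclusive and the cleaning total: kept + removed always equals the raw
count, and cleaning the kept list again removes nothing. A repetition is a
repeat of the same *canonical* item, so "dog" after "DOG", or a synonym of
an already-named item, counts as a repetition — the convention of normative
fluency scoring. The lexicon is an external file rather than a hard-coded
list because category norms differ between test batteries and languages.

**Item × subject matrix.** Within one (group, session) stratum, the binary
matrix $M$ has $M_{is} = 1$ iff subject $s$ produced item $i$. Cells are
binary rather than counts because repetitions are removed upstream; item
"co-occurrence" then means joint occurrence across subjects. Items never
produced in a stratum have no row. Rows and columns are sorted
alphabetically so results do not depend on input order.

**Semantic space.** $M = U D V^\top$ by singular value decomposition of
the raw binary matrix — no term weighting (no tf–idf or log-entropy
transform), matching the plain latent-semantic-analysis treatment of
occurrence matrices at this scale. The reduced dimensionality $k$ is the
smallest integer at which the cumulative *sum of singular values* reaches a
threshold fraction of the total (default 0.70). A variance-based variant
(cumulative $\sigma_i^2$) is available via `method = "variance"` but is not
the default: the selection rule this package follows is stated in terms of
the singular values themselves. Item vectors use the $U_k D_k$ convention,
the standard term-vector convention in latent semantic analysis; at
$k = \mathrm{rank}$ the cosines between item vectors equal the cosines
between the raw matrix rows exactly, which the test suite asserts at
tolerance 1e-8.

Each stratum is decomposed into **its own space** with its own $k$: the
comparison between groups happens at the level of cosine structure, not of
coordinates, so no alignment (e.g. Procrustes) across spaces is needed or
attempted. Whether one should instead restrict each matrix to a common item
subset *before* decomposition is genuinely open; this package decomposes
the full stratum matrix and extracts the item subset afterwards, which uses
all co-occurrence information and keeps the selection step independent of
the decomposition.

**Comparison.** Longitudinally, cosine profiles (one focal item against the
common frequent-item set) are compared across sessions; the common set is
chosen by the dual-session rule *count ≥ min_freq in both sessions*
(default 10, inclusive — an item appearing exactly 10 times passes). The
focal items are ranked by the baseline frequency table restricted to the
common set; the ranking session is configurable. Cross-sectionally, the
upper triangle of each stratum's cosine matrix over the reference cohort's
top-6 items is flattened into a pair vector in lexicographic pair order,
and the correlations with the reference vector at baseline ($r_{BH}$) and
follow-up ($r_{FH}$) are compared with Meng's z-test for dependent
overlapping correlations, one-tailed ($r_{BH} < r_{FH}$) as the planned
improvement contrast, at $\alpha = 0.05$.

## Meng's test: parameters and caveats

With $z(r)$ the Fisher transform, $\bar r^2 = (r_1^2 + r_2^2)/2$,
$f = \min\{1, (1 - r_{ov}) / (2 (1 - \bar r^2))\}$ (the cap at 1 is part of
the original method) and $h = (1 - f \bar r^2)/(1 - \bar r^2)$:

$$z = \left(z(r_1) - z(r_2)\right)
      \sqrt{\frac{n - 3}{2\,(1 - r_{ov})\,h}}.$$

The confidence interval is reported on the Fisher-z difference scale,
$\left(z(r_1) - z(r_2)\right) \pm z_{crit} \sqrt{2 (1 - r_{ov}) h/(n-3)}$.

Two points deserve emphasis:

* **The sample size is the pair count.** The correlated vectors have one
  entry per item pair — 15 for 6 items — so $n = 15$, not the number of
  subjects. This is the only sample size present in the computation, and it
  makes the test conservative relative to the cohort sizes involved.
* **Degenerate equality.** When $r_1 = r_2$ the statistic is exactly 0.
  This branch also covers the identical-input case $r_1 = r_2 = 1$ (three
  identical cohorts), where the Fisher transforms alone would diverge.

The test's calibration is checked by simulation: under a trivariate-normal
null with equal population correlations (0.4) and overlap 0.5, the
one-tailed rejection rate at $\alpha = 0.05$ over 10,000 seeded replicates
of size 50 falls in [0.040, 0.062].

Demographic tables are covered by summary-statistic tests: a pooled
two-sample t (equal variances, $df = n_1 + n_2 - 2$), Welch's t with
Satterthwaite df when a Levene test (mean-centred variant: one-way ANOVA on
absolute deviations from group means) rejects variance equality, and a 2×2
Pearson chi-square *without* continuity correction — the convention under
which the published sex-distribution statistic (1.295) reproduces exactly.

## The synthetic cohort generator

Clinical fluency transcripts are rarely shareable, so the package includes
a generative model rich enough to exercise every pipeline stage:

* a clustered vocabulary (pets / carnivores / herbivores) with Zipf-like
  popularity weights $1/\mathrm{rank}$, ranks interleaved across clusters so
  the most popular items span subcategories, as in empirical rankings;
* recall as sampling **without replacement**: the first item is drawn
  popularity-weighted from the whole vocabulary; each next item is drawn
  from the unused members of the current subcategory with probability
  `coherence` (moving on when the subcategory is exhausted), otherwise from
  all unused items. Switching on exhaustion rather than terminating keeps
  the list-length distribution independent of coherence;
* per-subject list lengths drawn from a normal distribution truncated to
  [1, vocabulary size];
* error injection after each recalled token at configured rates:
  repetitions duplicate an earlier token, intrusions insert out-of-category
  forms (fruit and furniture), proper-noun errors insert flagged pet names.

Identical configurations and seeds give byte-identical transcripts.

**Default scales.** Two canonical configurations are provided. The default
`synthetic_config()` emulates a healthy reference cohort: 335 subjects, a
36-item vocabulary (3 clusters of 12) and raw list length 20.9 ± 4.5 —
the reference cohort's published mean word count. The `study_configs()`
fixture used for end-to-end experiments mirrors the clinical study design
at the frequent-item scale: a 12-item vocabulary (3 clusters of 4), 28
patients measured twice and 335 reference subjects, with coherence 0.3 at
baseline and 0.8 at follow-up and reference. At this vocabulary size the
per-subject list length is mean 7 (patients) / 8 (controls) with SD 2.5:
published per-item frequencies over a 12-item frequent set sum to ≈ 7.1
items per patient and ≈ 7.9 per control, so these means reproduce the
observed per-item occurrence rates. (Using the raw word-count means of
16–21 with a 12-item vocabulary would be degenerate: every subject would
exhaust the vocabulary, the occurrence matrix would approach all-ones —
rank 1 — and pair vectors would lose their variance.) Error rates default
to 4% repetitions, 2% intrusions and 1% proper nouns per token, the order
of magnitude seen in clinical scoring practice.

**What the generator does and does not emulate.** It reproduces
subcategory-clustered recall, Zipf-like popularity, realistic cohort sizes
and error contamination, which is what the pipeline's validity rests on.
It does **not** model: the true (much larger) animal vocabulary and its
long tail; within-subject dependence between baseline and follow-up lists
(sessions are generated independently — any baseline–follow-up correlation
emerges from shared popularity and cluster structure, which is why the
synthetic overlap correlation runs lower than a real test–retest value);
age or education effects; or inter-item timing. Passing tests therefore
show the pipeline recovers planted structure of the kind the analysis
assumes — not that real cohorts satisfy those assumptions.

**A note on frequency-ranking fidelity.** With $1/\mathrm{rank}$ weights,
adjacent ranks near the top-6 boundary (1/6 vs 1/7) differ by less than
binomial sampling noise at 335 subjects, so the *exact* top-6 set is not
reproducible in ≥95% of replicates by any generator with these weights;
with coherent recall the cluster walk additionally boosts unpopular
cluster-mates, and long lists saturate top-item counts entirely. The
marginal-fidelity property is therefore tested in its robust form — with
coherence 0, the most frequent item is the highest-weight item and the
empirical counts are Spearman-concordant with the weights — and top-item
recovery is additionally verified across 100 small-cohort replicates.

## Numerical choices

* Ranking ties (equal counts) break alphabetically; pair vectors use
  lexicographic pair order — both purely for determinism.
* "Nonzero" singular values are those above $10^{-10} \sigma_1$; the
  cumulative-fraction comparison uses an absolute epsilon of $10^{-12}$ so
  an exact-boundary spectrum (e.g. cumulative fraction exactly 0.70)
  selects the smaller $k$.
* Cosines are clamped to $[-1, 1]$ and the diagonal set to 1 to absorb
  floating-point excess; zero-norm vectors are an error naming the item,
  never silently dropped.
* Requesting cosines or profiles for an item absent from a stratum matrix
  is an error naming the item and stratum.
* Reports serialise deterministically (`jsonlite`, full precision), so
  byte-identical JSON is the package's definition of end-to-end
  determinism.

## Problem sizes used by the test suite

The simulation-backed properties run at sizes chosen to make the checks
sharp but desk-scale: 50 replicates for the recovery, cluster-gap and
profile properties (28-subject patient cohorts, 12 items), 100 replicates
for top-item recovery (50-subject cohorts), 40 replicates for marginal
fidelity (335-subject cohorts), 10,000 replicates for the Meng null
calibration (size-50 samples), and a 1,500-subject cohort (>10,000 tokens)
for the error-injection accounting, which is held to three binomial
standard errors.

## Known limitations

* The dimension rule depends on the spectrum's shape; for very small or
  near-degenerate matrices the selected $k$ can be 1, at which all cosines
  are ±1 — the pipeline does not guard against over-reduction beyond
  reporting the cumulative fraction at $k$.
* Meng's test treats the 15 cosine pairs as independent observations; they
  share items, so the nominal $n$ overstates the effective information.
  This is inherent to the pair-vector design, and one reason the planned
  contrast is one-tailed rather than multiplied across item sets.
* The cleaning rules assume a single language and no stemming; synonym
  handling is exactly what the lexicon file declares.
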