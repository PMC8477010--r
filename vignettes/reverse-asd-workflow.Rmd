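---
title: "Methods: NB differential expression, preranked GSEA and reverse-ASD pattern analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NB differential expression, preranked GSEA and reverse-ASD pattern analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`revasd` analyzes a 2×2 genotype-by-treatment bulk RNA-seq design —
wild-type and *Shank2*-knockout mouse forebrain treated with vehicle or
memantine, three animals per cell — through six pairwise contrasts
(Veh-K/W, Mem-K/W, KO-M/V, WT-M/V, K-M/W-V, WT-M/KO-V), with gene-set
enrichment, directional disease-panel classification, and a
replicate-number power study. This vignette records the statistical model,
the defaults and why they were chosen, the numerical details, and what
the synthetic-data generator does and does not emulate.

## The count model and the Wald test

Counts are modelled as negative binomial: for gene $g$ in sample $j$,
$Y_{gj} \sim \mathrm{NB}(\mu_{gj},\, \alpha_g)$ with
$\mu_{gj} = s_j\, q_{g,\mathrm{group}(j)}$ and variance
$\mu + \alpha\mu^2$. The assumptions are the usual ones for bulk RNA-seq
at this scale: genes are treated independently, within-group samples are
exchangeable replicates, and library composition differences are captured
by a single scaling factor per sample.

**Size factors** use the median-of-ratios estimator: each sample's counts
are divided by the per-gene geometric mean across samples (genes with any
zero excluded from this pseudo-reference) and the per-sample median of
those ratios is taken. Factors are rescaled to geometric mean 1 so that
normalized counts stay on the raw-count scale; the rescaling is a
reporting convention and cancels from every contrast. A consequence worth
knowing: if essentially *all* genes shift by a common fold change,
normalization will absorb it — that is the estimator doing its job, and
it is why parameter-recovery checks against fully spiked simulations pass
known unit factors instead.

**Dispersion.** Gene-wise $\hat\alpha_g$ maximizes a Cox–Reid-adjusted
profile likelihood, evaluated on a 37-point log-spaced grid over
$[10^{-8}, 10]$ with one parabolic refinement step in $\log\alpha$
(accuracy well below the grid spacing, at a fraction of the cost of
per-gene numerical optimization). Group means are profiled out once from
the normalized counts rather than re-fitted at every grid value; at the
replicate numbers involved this pseudo-profile differs negligibly from
the exact profile. With three samples per group the gene-wise estimates
are far too noisy to plug into a Wald test directly, so by default they
are moderated: a parametric trend $\alpha(\mu) = a_0 + a_1/\mu$ is fitted
by iterated trimmed weighted least squares, and each gene's posterior
mode is taken under a log-normal prior centred on the trend whose
variance is the spread of the gene-wise estimates in excess of their
expected sampling variance ($\psi_1((m-p)/2)$, floored at 0.25). This is
the standard empirical-Bayes sharing of information across genes for
small-$n$ designs. The unmoderated estimate is kept alongside
(`moderate = FALSE` disables moderation entirely); it is the right
estimator to examine for consistency checks at large $n$, where the
prior's influence vanishes.

The design question we weighed here: a *purely* gene-wise maximum
likelihood fit, combined with a normal Wald reference, is measurably
anti-conservative at $n = 3$ (null type-I error near 0.11); switching to
a $t$ reference with the honest 4 residual degrees of freedom restores
calibration but makes genome-wide BH discovery at realistic effect sizes
essentially impossible — simulated power collapses to near zero, which no
three-replicate RNA-seq study design could accept. Moderated dispersions
with the normal reference give both: measured null type-I error is
≈ 0.05 at $n = 3$ and $n = 10$ on the full pipeline path (dispersions
estimated from all four design cells), and power lands in the range such
studies report. The test suite verifies the calibration on 1,000-gene
all-null simulations at both replicate numbers.

**Wald test.** For a contrast, group means are fitted by Newton iteration
on the log scale with the dispersion held fixed (8–10 iterations,
vectorized across genes; steps clamped to ±3 on the log scale). The
statistic is $\hat\beta/\mathrm{SE}(\hat\beta)$ with the standard error
from the Fisher information of both groups, referred to a two-sided
normal; p-values are floored at the smallest positive double. A group
whose counts are all zero gets the floored mean 0.5/Σs; genes with zero
counts in *both* contrast groups are excluded and reported. DEGs are
genes with Benjamini–Hochberg adjusted p < 0.05 — adjusted p-values
only, never a fold-change cutoff. No independent filtering or outlier
replacement is applied beyond the all-zero exclusion; with synthetic and
well-behaved inputs the simplest defensible rule is also the most
transparent one.

**PCA** is a diagnostic, not an inferential stage: samples are projected
from $\log_2(\text{normalized count} + 1)$ values. A regularized
log-type transform would differ mainly for very low counts and would add
a fitted component to a stage whose only job is to show group structure.

## Preranked GSEA

The ranking statistic is the fold change weighted by the inverse
p-value, $\mathrm{score} = \log_2\mathrm{FC} / \max(p, 10^{-300})$, over
*all* tested genes. The floor only prevents division by zero for
p-values at the double floor; the sign is the fold-change sign, and ties
are broken lexicographically by gene identifier so orderings are
reproducible. We considered ranking by raw (unlogged) fold change times
1/p; signed log2FC preserves the same ordering within each sign and
composes cleanly with the running-sum statistic, so the package fixes
the log2 form.

The enrichment score uses the classic, unweighted scheme: walking down
the ranked list, hits add $1/N_h$ and misses subtract $1/(N-N_h)$; ES is
the signed maximum deviation from zero, and the leading edge contains
the hits at or before the positive extremum (or strictly after the
negative one). Exact positive/negative ties of the two extrema — possible
because increments are rational — resolve to the positive extremum, with
a $10^{-12}$ guard so the incremental and closed-form code paths agree
bitwise.

The null model is **gene-set permutation**: `n_perm = 1000` random sets
of the same size drawn from the ranked list. NES divides ES by the mean
magnitude of same-sign null scores; the nominal p is the same-sign tail
fraction with the add-one rule (so $p \ge 1/(n_{\text{same}}+1)$ and a
zero p-value is impossible). The FDR q for each set compares the
same-sign tail fractions of the pooled null NES and the observed NES
distributions, clipped to [0, 1] and made monotone within each sign
stratum step-up style (each set takes the smallest raw q among sets no
more extreme), which removes non-monotone artifacts of finite
permutation counts. Per-set permutation streams derive from the master
seed plus a hash of the set name, so results are independent of
collection order and duplicated collections reproduce exactly.
Set-size bounds default to 15–500 after intersection with the ranked
list — the conventional preranked defaults — and are configurable.
Phenotype permutation and the weighted ($p=1$) scheme are deliberately
out of scope.

ORA is the hypergeometric upper tail $P(X \ge \text{overlap})$ against
the tested-gene universe, BH-adjusted across the collection. Homolog
mapping (applied before matching mouse genes to human-derived
collections) drops unmapped symbols with a report and resolves
one-to-many cases to the alphabetically first human symbol — an
arbitrary but deterministic rule, recorded per gene. The enrichment-map
graph connects significant sets with Jaccard similarity ≥ 0.25 by
default; the combined overlap coefficient used by some layout tools is a
visualization device and is not reimplemented.

## Reverse-ASD pattern calls

Each panel set carries an expected direction in ASD cortex: ASD-up
signatures (`up_in_ASD`), and ASD-down signatures plus ASD-risk sets
(`down_in_ASD`, risk genes tending to be downregulated in ASD). A
significant enrichment *against* the expected direction counts as
"reverse", one matching it as "like"; the group label is the majority
category (indeterminate on a tie or with nothing significant), and the
strength score is $\sum |NES|$ over significant sets, weighted +1/−1 for
reverse/like. The qualitative notion of a pattern "weakening" is
formalized as: strictly fewer significant sets concordant with the
reference call's dominant category *and* lower strength — both the
count and the extent of enrichment must drop, mirroring how such
patterns are described (number of enriched sets, NES and FDR values).
There is no canonical numeric boundary between a "weakened" and an
"eliminated" pattern; the verdict is an explicit formalization, and the
per-set NES/q deltas are always reported so a reader can apply their
own.

## The synthetic-data generator

The generator exists so that every downstream stage has a ground-truthed
input. It emulates the study conditions: a 2×2 design with 3
samples per cell, NB counts with per-gene dispersion, spiked effects with
known signs, and directional panels constructed to be enriched in known
directions. The `study-like` calibration profile is a set of documented
constants (not quantities fitted to the deposited data, which is out of
scope):

* baseline means log-normal with median 100 normalized counts
  (sdlog 1) — a realistic expressed-gene abundance spread;
* dispersions in [0.01, 0.5], drawn as
  $\exp(\log 0.01 + B \log 50)$ with $B \sim \mathrm{Beta}(1, 2.5)$,
  i.e. skewed toward the low dispersions typical of bulk brain tissue
  from inbred mice (median ≈ 0.03);
* a dense genotype effect — 5% of genes, $|\log_2\mathrm{FC}|$ uniform
  in [0.5, 2] — applied to both KO cells, and sparse, strong treatment
  effects — 1% of genes per genotype arm, $|\log_2\mathrm{FC}|$ in
  [1, 2] — mirroring the study's pattern of hundreds of genotype DEGs
  against a handful of treatment DEGs;
* signs equiprobable, effects gene-independent, library size factors 1
  (optionally jittered ±30% to exercise normalization).

The `shared-genotype` profile zeroes the treatment effects so the
genotype effect is identical in both arms — the construction under which
the two genotype contrasts' shared DEGs must agree in sign. The `null`
profile spikes nothing.

What the generator does **not** emulate: gene–gene correlation,
batch effects or technical covariates, GC or length bias, outlier counts, or any
transcript-level structure. Passing tests therefore demonstrate that the
estimators and the pipeline logic are correct under the stated model,
not that the model captures every feature of real tissue data.

Directional panels are built from the truth table of a chosen contrast:
`up_in_ASD` sets draw their core from genes truly *down* in the contrast
and `down_in_ASD` sets from genes truly *up* (the `reverse` pattern;
`like` swaps the mapping), diluted with a stated fraction (default 30%)
of null genes, ten sets in the arrangement of the real panels (four
ASD-related, six ASD-risk stand-ins — all suffixed `_synthetic`; none of
the real panel memberships, which are licensed resources, ship with the
package).

## The power study

For each contrast, the fitted comparison model freezes the pilot's
normalized group means (floored at 0.5 to avoid degenerate NB means),
the moderated dispersions, and — following the logic that truth must be
computable — the pilot's *called* DEGs as the true-DEG set, with
their estimated effects; all other genes are simulated with a common
mean across groups. Each replicate draws counts at $n$ per group with
unit library sizes, re-estimates size factors and dispersions, reruns
the Wald/BH/DEG-calling chain, and counts recalled (TP) versus missed
(FN) true DEGs; power is TP/(TP+FN) averaged over replicates (default
100, at $n \in \{3, 6, 9\}$). False positives among the non-DE genes
are recorded as an empirical FDR diagnostic but never enter the power
formula. Size factors are fixed at 1 during resimulation and
re-estimated during reanalysis; regenerating them per replicate would
conflate normalization variance with sampling variance at no benefit to
the question being asked (how many replicates are enough).

Note the selection effect built into this design, which is inherited
from defining truth as the pilot's discoveries: pilot-called genes are
biased toward large, well-estimated effects, so the power reported is
recall of *detectable* effects, not of all spiked effects — the
operationally relevant quantity when the question is whether three
replicates suffice to re-find what a pilot found.

## Problem sizes and reproducibility

The acceptance script runs the power experiment at 10,000 genes with 100
replicates per contrast at $n = 3$, and the concordance experiment at
5,000 genes; the test suite runs a 2,000-gene scaled version of the
power study and property tests sized so the whole suite completes in a
couple of minutes (1,000-draw BH oracle comparison, 500-instance ES
oracle comparison, 1,000-gene null calibrations). Every stochastic
operation takes an explicit seed, evaluates under it without touching
the session RNG state, and derives per-component substreams by hashing
component names, so identical configurations are bit-identical
end to end.

## Known limitations

* The DE model has no outlier handling and no independent filtering;
  heavy-tailed real data would need both.
* Gene-set permutation answers a different question from phenotype
  permutation (set coherence given the ranking, rather than association
  with the phenotype); with $n = 3$ per group phenotype permutation is
  not meaningful anyway.
* The moderated-dispersion Wald test remains mildly anti-conservative in
  the extreme small-sample corner (two groups of three with dispersions
  estimated from those six samples alone); estimating dispersions from
  all four design cells, as the pipeline does, removes most of this.
* Power is defined relative to pilot discoveries (see above), so it
  cannot be compared directly to power against the full spiked truth.
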