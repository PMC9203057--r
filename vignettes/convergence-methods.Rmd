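---
title: "Testing urban convergence of wildlife and human gut microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing urban convergence of wildlife and human gut microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microconverge)
```

## The scientific question

Urbanization changes what animals eat, where they shelter, and how often
they encounter people and their waste. A recurring observation in
comparative microbiome work is that the gut communities of
urban-dwelling wildlife look more "human" than those of their rural
conspecifics. `microconverge` packages the statistical machinery needed
to test that claim rigorously from 16S ASV (amplicon sequence variant)
feature tables: given count tables and sample metadata for several host
species sampled along an urban-rural gradient, plus reference human
cohorts, it quantifies whether urban wildlife gut microbiota have
converged toward human gut microbiota in community membership and
structure, which ASVs carry that signal, and whether the result survives
standard sensitivity protocols.

The package operates strictly downstream of denoising: its input is a
samples-by-ASVs count matrix. Primer trimming, ASV calling, contaminant
removal and taxonomy assignment are upstream concerns it deliberately
does not touch.

## Quality control and rarefaction

Two per-sample filters run before any diversity calculation, in a fixed
order:

1. **Group-wise depth filter.** A sample is removed when its total read
   depth lies more than three standard deviations below the mean depth
   of its group (`filter_low_depth()`, threshold $\bar d_g - 3 s_g$).
   Groups default to `source_dataset` because merged studies differ
   systematically in depth; judging a sample against a pooled mean
   would mostly detect which instrument it was sequenced on. The
   standard deviation is the sample ($n-1$) estimator; this is a
   configurable choice since the rule's provenance does not pin it
   down. Single-sample groups are retained with a warning ($s$ is
   undefined). Note that the rule has the usual masking property of
   moment-based outlier detection: several extreme low-depth samples in
   one small group inflate $s_g$ and can shield one another. The
   generator contract tests therefore assert removal only for faults
   that are alone in their group.
2. **Dominance filter.** A sample in which a single ASV accounts for
   strictly more than 75% of reads is removed (`filter_dominated()`);
   such profiles usually reflect amplification artifacts or residual
   contamination. The boundary is strict, so a sample at exactly 75% is
   kept. Zero-depth samples are removed with a separate flag.

Rarefaction (`rarefy()`) subsamples every retained sample without
replacement — a multivariate hypergeometric draw, matching the QIIME
convention — to `floor(0.9 * min(depth))` when `depth = "auto"`. The
90%-of-minimum rule keeps the shallowest retained sample usable while
still equalizing depth exactly. Two properties are load-bearing and
tested: every rarefied row sums exactly to the target, and rarefied
counts never exceed the input counts. The seed is a required argument
rather than an ambient global, so every rarefaction is logged and
reproducible. ASV columns that become all-zero are kept by default so
that ASV id spaces stay aligned across analysis subsets; `drop_empty`
removes them where alignment does not matter (e.g. before ANCOM).

A pipeline-level policy worth stating explicitly: **rarefaction depth is
recomputed per analysis subset.** Each species-plus-humans comparison
rarefies its own samples to 90% of *their* minimum depth, so no subset
is penalized by the shallowest sample of an unrelated subset.

## Diversity

Two dissimilarities drive all the distance-based inference, both in
$[0,1]$:

- binary **Sorensen-Dice**, $1 - 2|A \cap B| / (|A| + |B|)$ on
  presence/absence. This is the membership metric: when wildlife
  acquire human-associated ASVs at initially low abundance, presence
  changes long before abundance structure does.
- **Bray-Curtis**, $1 - 2\sum_i \min(x_i, y_i) / (\sum x + \sum y)$,
  the abundance-weighted complement.

Phylogenetic metrics (UniFrac) are intentionally absent: a
human-derived ASV closely related to one already present in rural
wildlife would be nearly invisible to them, and detecting exactly such
acquisitions is the point.

Alpha diversity uses **Chao1** (bias-corrected
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$ by default, classic
$S_{obs} + F_1^2/(2F_2)$ behind a switch) and **Shannon entropy**
(base 2 by default; the base is a parameter because conventions differ
between toolchains and the source convention is not documented).
Group differences in alpha diversity are tested with Kruskal-Wallis
(`kruskal_wallis()`, a wrapper over `stats::kruskal.test()` with the
all-tied degenerate case mapped to $H = 0, p = 1$).

**PCoA** (`pcoa()`) is the classical eigendecomposition of the
Gower-centered matrix $-\tfrac12 J D^2 J$. Negative eigenvalues — which
Bray-Curtis routinely produces — are reported untouched, with their
coordinate axes zeroed; no Lingoes/Cailliez correction is applied, so
eigenvalue bookkeeping stays transparent (their sum equals the trace of
the centered matrix, which the tests assert). The same centering
primitive underlies PERMANOVA and PERMDISP, which is the main reason
these are implemented in-package and then cross-checked against
`vegan::adonis2`, `vegan::betadisper` and `stats::cmdscale` in the test
suite rather than delegated to them.

## Permutation inference

### Monte Carlo comparison of between-group mean dissimilarities

The headline convergence test (`mc_group_comparison()`) compares two
sets of between-group distances from one matrix: pair A (urban
wildlife vs humans) against pair B (rural wildlife vs humans). The
statistic is the difference of means; the null is built by shuffling
group labels **among the samples whose labels distinguish the pairs**
(the human block, common to both pairs, stays fixed), recomputing the
statistic each time. Permuting labels rather than matrix entries
preserves the internal geometry of the distance matrix, which is what
makes the test exchangeable under the null. p-values carry the +1
Monte Carlo correction, so they are never exactly zero and are bounded
below by $1/(n_{perm}+1)$. With `n_perm = "exact"` all label
assignments are enumerated (supported when exactly two groups vary),
which the test suite uses to verify the Monte Carlo path against the
exact permutation distribution.

The default is two-sided. The humanization hypothesis is directional
(urban wildlife *closer* to humans), so the pipeline's headline test
uses `tail = "A_less"`; single comparisons keep the neutral default
because sidedness should be a visible analysis choice, not a buried
one.

### PERMANOVA (adonis) and PERMDISP

`adonis_dm()` partitions the total sum of squares of a distance matrix
among model terms through traces of projections of the Gower-centered
inner-product matrix onto nested model subspaces — sequential
(by-terms) sums of squares in the order given, the `adonis2`
convention. The canonical model here is
`distance ~ host_species + population + urban_status`. Because every
population has a single urban status, the third term is aliased with
the second and absorbs 0 df; the implementation warns rather than
silently renormalizing, and reports the term with zero SS. Significance
comes from raw permutation of sample identities (the default; residual
permutation under nested designs is a documented non-goal at this
scale). Under the Euclidean single-factor limit the partition equals
one-way ANOVA exactly, which is asserted to 1e-9.

`permdisp()` embeds samples in the positive-eigenvalue PCoA subspace,
measures each sample's distance to its group centroid (centroids, not
spatial medians), and permutes those distances across groups to test
the F statistic. This is the standard companion analysis that guards
against mistaking dispersion differences for location differences.

### Calibration

Both permutation tests are validated for type-I error: over 200
exchangeable-null simulations at 199 permutations, rejection at
$\alpha = 0.05$ must fall inside the binomial 95% CI around 0.05. This
is the single most important property of the whole inferential stack —
a miscalibrated permutation scheme silently invalidates every
downstream claim.

## ANCOM differential abundance

Compositional data forbid naive per-ASV tests, so differential
abundance uses ANCOM: for each ASV $i$, test every log-ratio
$\log\left((x_i + c)/(x_j + c)\right)$ for a group effect, and let
$W_i$ be the number of the $m-1$ ratios that reject after within-ASV
multiplicity correction. $W_{norm} = W/(m-1)$ lands on $[0,1]$ with
decision levels 0.7 (strong) and 0.5 (weak). The per-ratio test is
Mann-Whitney (normal approximation with tie correction, verified
against `wilcox.test`); with covariates — e.g. host species when
pooling all wildlife populations into one urban-vs-rural contrast — it
is a linear model on the log-ratio with a two-sided test of the group
coefficient, the simplest model consistent with covariate adjustment.

Numerical choices:

- **Pseudocount 1** before all log-ratios (configurable). At
  pseudocount 0 the transform is exactly scale-invariant per sample,
  which the tests exercise directly.
- **Within-ASV correction defaults to Holm.** The $m-1$ p-values of one
  ASV are strongly dependent — they share the numerator count — so when
  one ASV drifts by sampling chance, many of its ratios shift together
  and a false-discovery-rate correction lets a large fraction of them
  through at once, inflating $W$ under the null. With Holm the W
  statistic stays quiet on label-randomized data (all
  $W_{norm} < 0.5$ in $\ge 95\%$ of null simulations) while an 8-fold
  spiked ASV still reaches maximal $W_{norm} > 0.7$ in $\ge 90\%$ of
  replicates; with Benjamini-Hochberg the null arm fails that bar at
  any realistic overdispersion we simulated. Holm also matches the
  widely used scikit-bio ANCOM default. BH, Bonferroni and no
  correction remain available.
- Constant log-ratio vectors are untestable; such pairs are skipped and
  the ASV's denominator is reduced accordingly (`n_tests` in the
  result).
- ANCOM runs on rarefied counts, for consistency with the rest of the
  pipeline, and urban-vs-rural contrasts exclude semiurban samples.

The effect size reported alongside $W$ is the **CLR mean difference**:
mean centered-log-ratio value in the urban group minus the rural group,
per ASV. Its closed-form behaviour under a single-ASV spike (the spiked
ASV moves by $\log(c)(1 - 1/m)$, every other ASV by $-\log(c)/m$) is
asserted exactly in the tests.

## Exclusive ASV sharing

The presence-based fingerprint of humanization: ASVs found in urban
wildlife *and* humans but in no rural-wildlife sample
(`exclusive_shared_counts()`), against the mirror-image count.
"Present" defaults to $\ge 1$ read in $\ge 1$ sample of the group on
the rarefied table; both thresholds are exposed because the counts are
monotone in them and no canonical definition of group-level presence
exists. Unequal sample sizes inflate the larger group's presence
universe, so `subsampled_sharing()` draws rural subsets of the urban
size (the direction is fixed: rural populations are the larger ones in
this design) 10 times and reports replicate pairs and means. The human
reference set defaults to *all* human samples.

## Sensitivity protocols

`rerun_without()` re-executes an analysis closure with named samples
excluded (the outlier protocol); `subsample_runs()` repeats it on
fixed-size random subsets of one group (default 10-of-group, 5
replicates); `consensus()` applies the strictest reading of
"significant in all analyses": every run must reject, and a subsample
block counts as one run that rejects only when **all** of its
replicates do (a majority rule is available but is not the default).
Consensus is monotone — adding a run can only demote significance —
which the tests assert by enumeration.

## The synthetic-study generator

`generate_study()` emits (feature table, metadata, ground truth) for a
configurable multi-species urban-gradient study; it is first-class,
tested code, and every downstream claim about statistical behaviour is
made against its known truth.

The generative model, per sample:

1. Each host species has `m_core = 60` core ASVs with a geometric
   rank-abundance profile (ratio 0.93); humans additionally carry a
   `m_human_pool = 40`-ASV human-associated pool led by a focal
   *Bacteroides*-like ASV at an expected 15% relative abundance in
   urban humans (3% in rural humans — a five-fold urban enrichment that
   makes the focal ASV the strongest human differential signal, which
   parameter-recovery tests require ANCOM to rank first).
2. A wildlife population with humanization parameter $h \in [0,1]$
   mixes its species core with the (urban-)human pool profile at
   weight $w = 0.02 + 0.3h$: a convex mixture, the simplest mechanism
   that produces both presence-based (Sorensen-Dice) and
   abundance-based (Bray-Curtis) convergence while keeping host
   species the dominant factor even at $h = 1$. The 0.02 floor models
   background environmental exposure, so rural wildlife have a small,
   urban/rural-symmetric overlap with the human pool instead of an
   artificially clean zero.
3. The sample's composition is a Dirichlet draw around that profile at
   total concentration 50 (within the range of published
   Dirichlet-multinomial fits to gut data), and counts are multinomial
   at a lognormal depth (meanlog $\log 5000$, sdlog 0.15). The depth
   spread makes the 90%-of-minimum rarefaction rule non-trivial while
   keeping the 3-SD QC rule able to catch a lone injected depth fault.
4. Optional QC faults are injected per sample: depth cut to 1%
   (low-depth fault), 90% of reads moved to one ASV (dominance fault),
   or a wildlife sample generated at $h = 1$ (composition outlier, for
   the sensitivity protocol). Injected ids are recorded in the truth
   object.

The default study is one wildlife species (15 urban, 25 rural — the
rural excess makes equal-n subsampling meaningful) plus 20 urban and 15
rural humans, with urban wildlife at $h = 0.8$ and rural at $h = 0$.
`gradient_study()` replaces the species with one population per
requested $h$ level (e.g. 0.8/0.5/0.3/0), emulating an
urban-to-rural transect along which mean dissimilarity to humans must
be monotone.

What the generator does **not** emulate — and what green tests
therefore do not certify about real data: phylogenetic relatedness
among ASVs, shared taxa between wildlife species' cores, longitudinal
or host-individual structure, batch/primer effects between merged
datasets, and zero-inflation beyond what the Dirichlet-multinomial
induces. Passing parameter-recovery tests show the *statistics* behave
as designed under the assumed data-generating process, not that the
process captures every property of field data.

## Problem sizes and validation choices

The validation suite runs end-to-end on one CPU in well under a minute
of simulation-heavy work per property: 100-case oracle-equivalence
sweeps for the scalar metrics, 50-table rarefaction conservation, 200
null simulations at 199 permutations for calibration of each
permutation test, 50-replicate arms for ANCOM spike/null behaviour
(m = 20, n = 30/group, depth 5000), convergence detection (n =
15/group, 999 permutations) and the 4-level gradient monotonicity (n =
20/population), and 50 simulated studies per arm of the
sharing-asymmetry check. These sizes were chosen to keep each
acceptance property's Monte Carlo error comfortably inside its margin
while remaining cheap enough to run routinely.

## Known limitations

- PERMANOVA offers raw permutation only; restricted/nested permutation
  schemes are out of scope.
- The `anosim`-style analysis sometimes mentioned alongside these
  methods is intentionally not implemented: its conflation with
  rank-based group tests is ambiguous, and PERMANOVA plus the Monte
  Carlo mean-distance comparison cover the inferential need.
- ANCOM here is classic ANCOM (W on a 0-1 scale, as in the decision
  levels 0.5/0.7); bias-corrected ANCOM-BC, with its sampling-fraction
  model, is a non-goal.
- Exclusive-sharing counts are presence-based and therefore sensitive
  to rarefaction depth; the equal-n subsampling controls sample-size
  asymmetry but not depth asymmetry beyond what rarefaction removes.
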