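---
title: "Discovering synergistic compound pairs from gene-set reversal: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering synergistic compound pairs from gene-set reversal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generators emulate (and deliberately do not), and the
design decisions taken where the method leaves room.

## The problem

A disease such as a carcinoma dysregulates many transcriptional programs
at once — proliferation checkpoints, hormone response, stress response.
A compound whose perturbation profile pushes those programs back towards
the normal state is a therapeutic candidate, but single compounds rarely
reverse *all* of the disease programs.  The workflow therefore scores
reversal at the *gene-set* level and searches for two-compound
combinations whose reversal profiles complement each other, then
cross-checks the candidates with an orthogonal, purely structure-based
synergy model.

## Disease gene sets

Differential expression uses Welch's t-test on
median-of-ratios-normalized log2 counts.  This is an intentionally
simple stand-in for a full negative-binomial GLM: the workflow's
contribution begins downstream of DE calling, and externally produced
DE tables (e.g. from a dedicated RNA-seq pipeline) are accepted
verbatim.  Median-of-ratios size factors matter here: when a third of
the genome shifts several-fold in one direction, total-count scaling
leaks a spurious fold change into every null gene, while the
geometric-mean reference is robust to such composition shifts.  DEG
thresholds default to BH-adjusted p < 0.01 and |log2FC| > 1.

Over-representation uses the one-sided hypergeometric upper tail with
BH correction.  The size window (more than 5, fewer than 500 genes) is
applied *after* intersecting each set with the measured universe;
enrichment statistics only ever see measured genes.  The choice of
universe (all measured genes) is configurable because curated analyses
sometimes prefer all protein-coding genes.

Proximity of a gene set to the disease targets uses a random walk with
restart from the targets, `p ← (1 − r)·W·p + r·p0` with column-degree
normalization.  The restart probability is not a sensitive quantity for
*rankings* in the 0.3–0.7 range; the default 0.5 balances local and
global exploration.  A gene set's proximity is the arithmetic mean of
its members' stationary probabilities (median available), compared with
size-matched random gene sets drawn uniformly from the network
(1000 permutations, add-one empirical p so p is never zero, BH < 0.01).
Uniform size-matched sampling is the simplest defensible null; an
optional log2-degree-binned variant guards against hub bias, and the
opposite direction — permuting the target set and re-running the walk —
is implemented behind a flag for sensitivity analyses.

Redundant sets (overlap coefficient > 0.5) are pruned greedily in
ascending enrichment padj, ties broken towards the larger set and then
lexicographically, which makes the scan order — and hence the output —
deterministic and order-independent.

## The wAC reversal index

Disease DEGs of a set are labelled `+`/`−` (padj < 0.01,
|log2FC| > 0.5 — note the laxer fold-change cut than for DEG calling,
because here sign consistency rather than effect size carries the
information).  Treatment labels are assigned with the *opposite* sign at
the same effect threshold so that reversal counts as agreement, with
`0` for residual genes.  Profiles without per-gene significance (the
usual case for large perturbation compendia) are thresholded on the
effect value alone; when significance is present both thresholds apply.

Agreement uses Gwet's AC1 rather than Cohen's kappa because gene sets
are often direction-imbalanced (e.g. mostly upregulated), and kappa's
chance correction collapses under imbalance.  Genes are weighted
`w_i = 1 + b_i` with `b_i` the normalized betweenness centrality: the
affine form keeps every weight positive, reduces exactly to the
unweighted AC1 when betweenness is constant or the set lies outside the
network, and lets central genes contribute at most twice the weight of
peripheral ones.  The weights enter both the observed agreement `pa`
and the category proportions behind the expected agreement `pe`, so
both terms live on the same measure.

The category space for `pe` is the full ternary `{+, −, 0}` even though
the disease rater never emits `0` — the treatment rater does, and chance
agreement must be computed over the categories both raters can use.  A
binary mode exists for comparison.  The index is clipped to `[−1, 1]`
(its true lower bound is `−pe/(1 − pe)`); the raw value is kept for
diagnostics.  Cells with fewer than two labelled genes, or degenerate
`pe = 1`, are reported missing, never imputed.

## Signature sets, grading, PS and TCS

Signature sets must (a) show higher wAC among the known disease drugs
than among other compounds (one-sided Wilcoxon, exact for small
tie-free groups) and (b) correlate negatively with ln(IC50) in at least
one sensitivity panel (`panel_rule = "any"`; panels are reported
separately in practice, so requiring all of them is optional
strictness).  Raw p < 0.01 matches the stated significance convention;
a BH option exists.

Grading intervals per signature set come from the 50th and 80th
type-7 quantiles of the *positive* cohort's wAC: below q50 is weak (0),
q50 up to q80 moderate (0.5), at or above q80 strong (1).  Boundaries
are closed upward, so a candidate exactly matching the 80th percentile
of disease drugs earns the strong grade; the choice is documented
because the grading text alone does not fix it.  Missing wAC grades 0 —
absence of measured reversal is absence of evidence.  PS sums a
compound's grades; TCS sums the pair's per-set capped grades, so a pair
is rewarded for *covering* sets, not for doubling up on one.  The TCS
threshold generalizes the strict "all but one set" rule to `n − 1`.

## Structure-based synergy regression

Synergy targets are IQR-filtered (1.5× fences, type-7 quartiles) then
min-max normalized on all post-filter samples — the order the
preprocessing is usually described in; a train-only scaling mode exists
because fitting the scaler before the split leaks the test range
(a deliberate, documented trade-off of at most the two range
parameters).  Each unordered pair contributes both concatenation orders
as rows; the 80:20 split and the 5 CV folds partition *pairs*, so no
combination ever spans a boundary in either orientation.  Four model
families — randomized trees, bagged trees, gradient-boosted trees and a
single-hidden-layer network — compete on CV RMSE; the procedure (argmin
CV-RMSE selection, bagged fold-model prediction, order-averaged pair
prediction) is the method, not the particular model zoo.  ZIP is the
default target since it tends to be the most structure-predictable of
the four scores.  Permutation importance reports the mean RMSE increase
under per-column shuffling, named by fingerprint key.

## Combination index

The median-effect line is fit by least squares on
`log10(fa/(1 − fa)) ~ log10(dose)`.  Affected fractions are clipped to
`[0.005, 0.995]` to keep log-odds finite; the bounds are configurable
and a warning marks any clipping, because points at the clip boundary
bias the slope.  A non-positive slope aborts — that is a non-monotone
response, not a fittable curve.  CI is evaluated at the observed
combination effect level; per-dose CI tables support checkerboard
designs.  The caller supplies the fraction affected, as viability can
be normalized in more than one way.

## What the synthetic data emulate

The generators plant every effect the downstream stages are supposed to
find: a preferential-attachment interactome (scale-free, like real
protein networks) with hub-biased targets; planted disease modules
built around disjoint anchor-target groups and their neighbourhoods, so
each module is target-proximal without the modules collapsing into near
duplicates; negative-binomial counts whose planted DEGs are exactly the
module genes plus scattered background (about a third of the genome);
reverser compounds that flip planted DEG signs with graded strength;
ln(IC50) values linear in reversal strength; and a symmetric pairwise
synergy response driven by planted fingerprint bits
(`0.7·additive + 0.3·complementarity` over the causal bits).

The validation study conditions, fixed once: 300 genes, attachment 3,
25 targets; 20 + 20 samples, log2 effect 3, dispersion 0.2; 40 sets of
25–40 genes, 4 planted, 4 redundant pairs; 60 reference compounds with
12 positives of strength U(0.2, 0.8) under unit profile noise — wide
enough that the positive wAC distribution spreads and the grading
quantiles are informative, mirroring how real disease drugs span weak
to strong reversal; 20 candidates whose planted pair reverses
complementary halves of the modules at strength 1.0 (0.35 on the other
half, the broad weak activity real compounds show); synergy screens of
30–35 drugs, 48-bit fingerprints, 8 causal bits, interaction effect 1
against noise 0.05.  These sizes keep a full 20-replicate recovery run
inexpensive while leaving every statistical margin comfortable.

What the generators do *not* emulate — and what passing tests therefore
do not show about real data: landmark-gene imputation and other
platform artefacts of real perturbation compendia, batch effects,
dose- and time-dependence of profiles, correlated noise across
compounds, assay-specific synergy-score biases, and any chemistry in
the synthetic fingerprints (causal bits are an abstraction of
pharmacophore features, not substructures).  Real applications should
treat the planted-truth suite as a correctness check of the machinery,
not as evidence about biological effect sizes.

## Numerical choices and degenerate inputs

Empirical permutation p-values use the add-one estimator.  The RWR
iteration stops at L1 change < 1e-10 and is verified against a direct
linear solve; dangling-node mass is teleported back to the restart
vector so probabilities always sum to one.  Wilcoxon tests switch from
the exact distribution to the tie-corrected normal approximation beyond
group size 10 or in the presence of ties.  Quantiles and quartiles are
type 7 throughout.  Constant target vectors, empty gene sets, zero
overlap between panels, and profiles missing genes all produce errors
or explicit missing values with diagnostics rather than silent
coercion.  All generators are pure functions of (parameters, seed).

## Known limitations

The built-in DE test is not a dispersion-shrinking GLM and should not
be used for marginal real-data calls when a dedicated pipeline is
available.  PubChem and CDK-substructure fingerprints are consumed from
precomputed tables (their dialects vary by toolkit; only the bit-length
contract is enforced), while MACCS is computed natively.  Higher-order
combinations (three or more compounds), GSEA-style ranked enrichment,
diffusion kernels beyond RWR, and recomputation of synergy scores from
raw dose-response surfaces are out of scope.
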