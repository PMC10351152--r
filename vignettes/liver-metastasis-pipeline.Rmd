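---
title: "Models and methods behind LiverMetSig"
author: "LiverMetSig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind LiverMetSig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LiverMetSig)
```

# Overview

Colon-to-liver metastases express a hybrid transcriptional program: they
keep part of the primary tumor's colonic identity while adopting much of
the adjacent liver's. `LiverMetSig` implements the computational workflow
built on that observation — signature derivation from bulk RNA-seq,
pathway-level clustering stability, a connectivity-map style compound
screen, and organoid pharmacology scoring — together with a
synthetic-data module that plants known effects so every downstream
stage can be validated quantitatively. This vignette explains the models,
their assumptions, the tunable parameters, and the design decisions taken
where the methodology left genuine freedom.

# The synthetic cohort model

`simulateCohort()` draws negative-binomial counts with variance
$\mu + \phi\mu^2$ and a shared dispersion $\phi$ (default 0.1, a typical
bulk RNA-seq value for human tissue cohorts; per-gene dispersion
variation is deliberately not modelled — the DE stage estimates exactly
the model the generator uses, which keeps planted-recovery tests
interpretable). Each gene has a baseline log2 mean drawn uniformly on
[3, 8] (relative abundance scale); a liver program (default 40 genes) is
raised by `plantedLogFC` (default 6) in adjacent liver, a colon program
(default 40 genes) is raised by the same amount in colonic tissue, and
metastasis samples get the convex log-space mixture

$$\mu_{LM} = (1 - w)\,\mu_{CC} + w\,\mu_{AL}$$

with mixture weight $w$ (default 0.8). The mixture is taken in log space
because log2 fold-change is the effect scale of the whole pipeline; the
realized LM-vs-CC effect on a liver-program gene is therefore
$w \times$ `plantedLogFC` $\approx 4.8$ log2 units at the defaults,
comfortably but not trivially above the $|logFC| > 4$ call threshold.
Library sizes are drawn log-uniformly in $[10^6, 2\times10^7]$ per
sample — the cohort's real sequencing depths are unknown, and the spread
forces the normalization step to do real work. The default design is 8
patients each contributing a matched primary tumor (CC), first-wave
liver metastasis (LM1) and adjacent liver (AL) sample.

All randomness flows from one master seed through deterministic
substreams, so identical configurations give byte-identical cohorts.

What the generator does *not* emulate: batch effects, per-gene
dispersion trends, isoform structure, sample contamination, or the
partial-matching pattern of real surgical cohorts. Passing recovery
tests on this generator demonstrates that the statistics are implemented
correctly and calibrated under their own model; it does not show
robustness to the violations listed above.

# Differential expression

Counts are filtered with the strict rule "more than 10 counts in at
least 10% of the samples" (the fraction is computed over whatever matrix
is passed in, so per-contrast filtering is a caller choice).
Normalization uses trimmed-mean-of-M-values factors (30% two-sided trim
on log-ratios, 5% on log-intensities, precision-weighted, geometric mean
1) against the sample whose upper-quartile CPM is closest to the cohort
mean.

The test is a negative-binomial Wald contrast on normalized group means:
$logFC = \log_2\frac{m_A + 0.5}{m_B + 0.5}$ (the 0.5 pseudo-count keeps
zero-count genes finite and is far below the resolution of the
$|logFC| > 4$ threshold), with a delta-method standard error under the
NB variance at a method-of-moments dispersion pooled across groups and
shrunk 30% toward the across-gene median (genes with no within-group
variation get dispersion exactly 0). The statistic is referred to a t
distribution with $n_A + n_B - 2$ degrees of freedom rather than the
asymptotic normal: at the cohort sizes this pipeline targets (6–10
samples per group) the normal reference is visibly anticonservative,
while the t reference keeps the observed type-I fraction at nominal
p < 0.05 within $\pm 0.02$ across simulated null cohorts. A consensus
mode (`callDEConsensus()`) intersecting the t and normal variants is
available for users who want the conservative overlap of two test
families; the default is the single t-referred test.

Threshold presets mirror the study design: `paper` (BH-adjusted
p < 0.01, $|logFC| > 4$) for the in-house cohort and `public1` /
`public2` (raw p < $10^{-3}$ / 0.01) for the two public comparator
datasets. All inequalities are strict.

The 2-D sample embedding takes the 2000 most variable genes on log-CPM
(pseudo-count 1), centers genes, and returns the leading principal
coordinates with a fixed sign convention (largest-magnitude loading
positive) so plots are reproducible across runs.

# Signature derivation

Gene identity is by upper-cased symbol. The core signature is the exact
intersection of the up-regulated sets from the matched in-house
contrast, the unmatched in-house contrast, and any external datasets —
an all-inputs intersection, with full provenance recorded, so stricter
or looser readings (pairwise versus three-way) are reproducible by
configuration. The default signature is up-only: the biology of
interest is the liver program gained by metastases, and down-regulated
genes showed no reproducible core. "Liver-enriched" means the
annotation lists liver among a gene's enriched tissues; no
expression-level cutoff is applied, since atlas categories rather than
thresholds define enrichment. Over-representation against pathway
collections is a one-sided hypergeometric upper tail with BH correction
across pathways.

# Pathway clustering stability

Each pathway with **more than five** expressed genes is clustered at the
sample level (sample-level rather than gene-level clustering is what
makes "a group of metastatic samples clusters with liver tissue"
observable). The feature space is the pathway's expressed genes on
log-CPM, each gene standardized to zero mean and unit variance across
samples — without standardization a single high-variance gene dominates
the Euclidean geometry.

K is selected by the gap statistic: for $k = 1..k_{max}$, compare
$\log W_k$ of the data with its mean over 50 uniform reference draws
spanning each feature's observed range, and take the smallest $k$ with
$\mathrm{gap}(k) \ge \mathrm{gap}(k+1) - \mathrm{se}(k+1)$. K-means uses
k-means++ seeding, Lloyd iterations capped at 100, squared-Euclidean
distance.

Stability repeats the clustering 500 times with independent seeded
initializations. "Conserved composition" is read in its strictest
defensible form: a replica conserves the reference partition only when
the two partitions are identical up to label permutation (canonical-form
comparison). The reference partition is the replica with the lowest
within-cluster dispersion — the best local optimum found — which is one
of several defensible choices (first replica, consensus) and is
configurable in principle; the best-dispersion replica was chosen
because it makes the reference independent of replica ordering. A
pathway is stable when $\ge 95\%$ of replicas conserve it. Pathways
whose gap-selected K is 1 are recorded as trivially stable single
clusters but carry no block structure. Consensus blocks are named by
the majority anchor tissue class per cluster, ties broken by the
lexicographically smallest class and flagged.

# Connectivity screen

Query signatures must keep between 10 and 150 genes after dropping
genes absent from the reference (dropped genes are reported). Profiles
are ranked by differential-response score, descending, ties broken by
gene id (stable and deterministic). The enrichment statistic is the
classic weighted Kolmogorov–Smirnov running sum with uniform hit
weights: hits step $+1/n$, misses $-1/(N-n)$, and the enrichment is the
signed maximum deviation. Because the step sizes are rational, the
deviation can tie exactly in both directions; such a balanced excursion
is scored 0, which preserves the antisymmetry of the score under
profile negation. With both directions present the combined statistic
is $(ES_{up} - ES_{down})/2$; up-only queries (the pipeline's default
signatures) use $ES_{up}$ directly. Scores are scaled to
$[-100, +100]$.

The global score is the mean of a compound's per-context scores —
labelled as such, since cross-context summaries can also be rank-based.
Hits must score strictly below $-95$ in every required context
including the global one; the mechanism-class summary counts hits whose
global score falls in the $[-100, -50]$ band.

# Organoid pharmacology

The response score is the ratio of the products organoid count × mean
maximal diameter × viability at baseline versus after 72 h, so RS = 1
is no effect and larger is stronger response. The three-factor form is
canonical; a two-factor variant (count × diameter) is available via
`includeViability = FALSE`. A culture with no surviving signal at 72 h
gets RS = +Inf with an explicit flag rather than an error. Because an
RS cutoff for sensitivity is nowhere defined by the methodology, the
package classifies relative to a control: sensitive when
$RS_{treated} > RS_{control}(1 + m)$ with margin $m = 0.2$ by default,
reported in the output — the margin is a package decision, not a
community standard.

Bliss synergy on a dose grid uses the single-agent margins as the
independence model ($y_a + y_b - y_a y_b$), averages the excess over
combination cells only (margins have zero excess by construction and
would dilute the score), multiplies by 100, and classifies with the
bands $\le -10$ antagonistic, $(-10, 10]$ additive, $> 10$ synergistic.
The organoid simulator plants a constant excess on the combination
cells and adds Gaussian noise there; margins are left noise-free so the
planted excess is exactly the estimand — noisy margins would test
robustness, not correctness, and can be emulated by perturbing the grid
before scoring.

# Numerical and testing choices

Problem sizes in the test suite are chosen to make each statistical
guarantee measurable with stable Monte-Carlo error on a single CPU:
DE recovery and null calibration use 2000-gene cohorts with 8 matched
patients over 10 and 50 seeds respectively; gap/stability checks use
60-sample three-blob data over 20 seeds and 500-replica stability on
40 × 10 unstructured data; the connectivity null uses 1000 random
queries on 200-gene profiles; Bliss recovery averages 20 seeded 5 × 5
grids at noise sd 0.02. Brute-force oracles (step-up BH, double-loop
filtering, exhaustive KS walks, hypergeometric enumeration, exhaustive
partition search for within-cluster dispersion) are implemented
independently in the tests and never share code with the package.

# Known limitations

The DE test is a defined NB Wald procedure, not a re-implementation of
any particular GLM framework's internals; its guarantees are planted
recovery and null calibration, not numerical equality with other tools.
The connectivity score is the classic weighted-KS statistic, not a
replication of any live service's proprietary summary. Real perturbation
resources, tissue atlases and pathway databases are emulated by
generators and packaged fixtures; conclusions about real compounds
require the real resources. Clustering stability is sensitive to the
"identical partition" reading of conservation — a relaxed
similarity-index reading would mark more pathways stable.
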