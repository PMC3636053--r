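---
title: "Hit-rate signature profiling over pathway-derived subnets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hit-rate signature profiling over pathway-derived subnets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patient-level shotgun proteomics is notoriously inconsistent: two samples from
the same tissue may share only a small fraction of their reported proteins,
and across a small cohort almost no protein is detected in everyone. Working
protein-by-protein therefore discards most of the signal. The premise of
signature profiling is that detection is *context*-dependent: proteins are
detected as parts of complexes and pathway neighbourhoods, so aggregating
detection over a biologically coherent set of proteins produces a stable
per-sample statistic even when individual detections are unstable.

pspnet implements this programme end to end for two kinds of feature sets:

* **complexes** — curated gene sets (CORUM-like, read from GMT), and
* **pathway-derived subnets (PDSs)** — connected fragments of pathway graphs
  induced on cohort-supported proteins.

## Hit-rate profiles

For a feature set $C$ and a patient $i$ with detected-protein set $D_i$, the
hit rate is

$$ H_{C,i} \;=\; \frac{|C \cap D_i|}{|C|} \in [0, 1]. $$

The vector of hit rates over the feature collection is patient $i$'s
signature profile; `build_signature()` returns the cohort as a tibble with
patients in rows (class label in the second column) and features in columns.
Hit rates are kept as exact fractions — no binarisation — because the
downstream t-statistic operates on them. All-zero rows and columns are
retained; features smaller than `min_size` (default 4) are excluded with a
warning, since tiny sets make the fraction jump wildly with single
detections.

## PDS extraction

Candidate proteins are those detected in at least half of the patients of
either class; "at least half" of an odd class size rounds up
(`ceiling(n/2)`), and the candidate set is the union over the two classes so
both phenotypes contribute their characteristic proteins. Each pathway graph
(undirected gene pairs; direction in the input is ignored, duplicate and
reversed pairs collapse) is then restricted to the candidates. Removing the
unmapped proteins fragments the pathway into connected components, and every
component with at least 4 nodes becomes a PDS. Expression-level filters are
deliberately not applied: in sparse patient cohorts they shred the pathways
into fragments too small to profile.

Multiple PDSs from one pathway are numbered by decreasing size, ties broken
by the lexicographically smallest member — an arbitrary but deterministic
convention, so repeated runs give identical feature IDs.

## Clustering with bootstrap confidence

Patients are clustered on Euclidean distances between profiles with Ward's
minimum-variance linkage (`hclust` method `ward.D2`; heights on the distance
scale). Determinism comes from sorting patients by ID at load time and from
`hclust`'s deterministic agglomeration.

Cluster confidence uses multiscale bootstrap resampling of the *feature*
dimension. For each scale $r \in \{0.5, 0.6, \dots, 1.4\}$ (ten scales
straddling 1) and $B = 1000$ resamples per scale, `round(r * n_features)`
columns are drawn with replacement, patients are re-clustered, and the
bootstrap probability $BP_r$ of each observed cluster is the fraction of
resample trees containing exactly its leaf set. The probit-transformed curve

$$ \Phi^{-1}(1 - BP_r) \;\approx\; v\sqrt{r} + c/\sqrt{r} $$

is fitted by weighted least squares (binomial-variance weights; ordinary LS
if the weights degenerate), and the approximately unbiased confidence is
$AU = 100\,(1 - \Phi(v - c))$; $BP$ is reported at scale 1. Two numerical
choices matter:

* scales where $BP_r$ is exactly 0 or 1 carry no information about the curve
  (their probit quantile is infinite) and are excluded from the fit;
* when fewer than two informative scales remain the cluster is degenerate:
  it is essentially always (or never) recovered, and AU saturates to 100 (or
  0) by the mean-BP rule. A cluster never seen in any resample is
  additionally flagged.

Without the exclusion rule a perfectly supported cluster would present a
flat clamped curve and an AU near 50 — clearly wrong for a cluster recovered
in every single resample.

## Differential features

For each feature the two class-wise hit-rate lists $H_A$ (size $m$) and
$H_B$ (size $n$) are compared with the pooled two-sample t-statistic

$$ t \;=\; \frac{\bar H_A - \bar H_B}
   {S_{H_A,H_B}\sqrt{\tfrac1n + \tfrac1m}}, \qquad
   S_{H_A,H_B} = \sqrt{\frac{(m-1)S_{H_A}^2 + (n-1)S_{H_B}^2}{m+n-2}}. $$

Hit rates are bounded fractions, so no t-distribution is assumed; the null
is built by class-label permutation preserving group sizes. When the number
of distinct balanced assignments is at most `n_perm` (always the case for
the cohort sizes this method targets — a 6+7 cohort has 1716) the full
enumeration is used and the p-value is exact. Zero pooled variance is
handled explicitly: equal means give $t = 0$; unequal means give a signed
infinity sentinel that the permutation comparisons treat correctly.

### The tail rule, and why two variants exist

The classical rule in this literature takes the tail on the side of the
observed statistic with strict inequality: for $t \ge 0$,
$p = \#\{t^{\text{null}} > t\}/M$, and symmetrically below zero. That is the
package default (`alternative = "signed"`, `ties = "strict"`), but users
should understand its operating characteristics, which the test suite
measures:

* choosing the tail from the data makes it a one-sided test applied
  two-sidedly, so its null rejection rate is roughly **twice** the nominal
  level, and
* hit rates are discrete (multiples of $1/|C|$), the null t-values are
  heavily tied, and strict inequality drops every tie from the count —
  pushing the rate higher still (we measure ~0.13–0.16 at a nominal 0.05 for
  6+6 cohorts and complex sizes 4–25).

The calibrated variant `alternative = "two.sided"`, `ties = "midp"` compares
$|t|$ values and gives ties half weight; its measured null rate is
0.047–0.050 across the same conditions. The calibration-oriented analyses in
this package (the false-positive expectation of `n_features × α`, and
parameter recovery on synthetic cohorts) use the calibrated variant; the
default remains the classical rule for comparability. Benjamini–Hochberg
adjustment (`bh_adjust()`, a thin wrapper over `p.adjust`) is available in
both selection and the false-positive protocol.

### Ranking scores

Significant features are ranked per class from iTRAQ-style abundance ratios.
For every (member protein, patient) pair reported with ratio $\rho$, ratios
below 1 are inverted (a ratio and its reciprocal describe the same fold
change) and the excess over 1 accumulates: $S = \sum (\max(\rho, 1/\rho) - 1)$.
Large features would win on membership count alone, so the final score
divides $S$ by the number of **distinct member proteins reported by at least
one patient of the class** — not by the feature size. With members
$\{A,B,C,D\}$, two patients reporting $A$ at 1.1 and 1.2 and one reporting
$B$ at 5:

```{r, eval = FALSE}
prof <- tibble::tibble(
  patient_id = c("m1", "m2"), class = "mod",
  detected = list("A", c("A", "B")),
  ratios = list(c(A = 1.1), c(A = 1.2, B = 5)))
rank_score(prof, c("A", "B", "C", "D"))
#>   s_raw score n_reported
#>    4.3   2.15          2      # (0.1 + 0.2 + 4) / 2 — denominator 2, not 4
```

## False-positive behaviour

`fp_distribution()` estimates how many features a *homogeneous* class yields
under the selection procedure: the class is split into pseudo-groups of
sizes $\lfloor n/2 \rfloor$ / $\lceil n/2 \rceil$ at random, selection runs
on the pseudo-labels, and the count of "significant" features — all false
positives by construction — is recorded over many rounds, reported as
absolute and normalised histograms with mean/median/mode. Under a calibrated
test and independent null features the mean approaches
$n_{\text{features}} \times \alpha$; hidden substructure inside the class
(two latent subtypes, say) raises it, which is itself a diagnostic.

Two design points: each round uses 1000 inner permutations by default
(exhaustive enumeration supersedes this whenever the class is small enough,
which also makes per-round p-values exact and lets the implementation reuse
the split-by-feature t-matrix across rounds — an algebraically identical
fast path, asserted equal to the direct path in the tests). And the p-value
granularity bounds what the protocol can show: with 7 patients there are
only $\binom{7}{3} = 35$ balanced splits, so the smallest achievable
nonzero rejection rate at $\alpha = 0.05$ is $2/35 \approx 0.057$ — the
nominal expectation is unreachable below about 10 patients, which is why the
package's own calibration analyses use a 14-patient synthetic class
(3432 splits).

## Co-localisation of complexes and subnets

A pathway is *involved* if it contributed a significant PDS.
`overlap_enrichment()` compares the fraction of involved versus non-involved
pathways that share at least one protein (threshold configurable) with a
significant complex; the ratio of the two fractions measures how strongly
significant complexes co-locate with significant subnets.
`jaccard_overlaps()` computes, for co-located (PDS, complex) pairs, the
Jaccard score of their member sets — low values show co-location is not
driven by shared members. `score_regression()` regresses complex ranking
scores on PDS scores per class (OLS; $R^2$ and the F-test p are
direction-invariant, the slope is reported both ways), flags outliers by
studentised residual above 3, and reports a leave-out re-fit; outliers can
also be named explicitly, mirroring by-inspection removal.

## Ontology analysis

The OBO 1.2 / GAF 2.x readers keep term id, name, namespace and the
`is_a`/`part_of` parent edges; obsolete terms and `NOT`-qualified
annotations are excluded, and only direct annotations are stored.
`propagate_annotations()` propagates each protein to all ancestors
(`is_a`/`part_of` only — `regulates` is excluded, following standard
enrichment practice). *Informative terms* are those annotated (after
propagation) to at least 30 proteins with no child above 30 — the deepest
still-testable frontier; a child at exactly the threshold does not
disqualify its parent. Enrichment is an upper-tail hypergeometric test with
per-feature Bonferroni correction over the terms actually tested.

Association with a curated term list (e.g. lipid-related terms) is a
functional-class-scoring procedure: the feature's hit rate $a/n$ (members
annotated to a listed term or, by default, to any descendant of one) is
compared with the hit rates of 10,000 random protein sets of size $n$ drawn
without replacement from the universe; the p-value is the fraction of random
sets strictly exceeding the observed rate. The universe defaults to all
annotated proteins and is configurable (e.g. to all proteins appearing in
complexes) — the choice shifts p materially and is echoed in output headers.

## The synthetic cohort generator

No patient-level dataset ships with the package, so `simulate_preset()`
generates the full input bundle at the study's conditions: a 6 "mod" + 7
"poor" cohort; per-(patient, protein) independent Bernoulli detection at
background probability 0.3 (giving pairwise detection-set Jaccard
$p/(2-p) \approx 0.18$ — the low-overlap regime that motivates set-level
profiling); 40 connected pathways (random spanning trees plus extra edges,
partially shared protein namespace); 60 complexes of sizes 4–25 of which 10
carry class-linked signal (member detection probability 0.9 in one class,
0.2 in the other); log-normal iTRAQ-style ratios (σ = 0.25, ×1.5 shift for
signal proteins in the high-detection class); and a small ontology with a
planted informative-term frontier.

What the generator does **not** emulate: correlated co-detection beyond the
planted feature structure (a block-correlation option approximates
per-patient coverage differences), abundance-dependent detection, channel
crosstalk, and identification-level error. Passing tests on these synthetics
therefore demonstrate correctness of the machinery and its statistical
calibration under the stated model — not performance on any particular real
cohort.

## Problem sizes and numerical choices

The test-suite and acceptance analyses run at deliberately modest sizes:
523 null features × 14 patients × 1000–2000 bipartition rounds for the
false-positive expectation; 500 features (50 signal + 450 null) × 6+6
patients × 20 seeds for parameter recovery; B = 1000 bootstrap resamples per
scale for cluster confidence. These sizes give Monte-Carlo standard errors
comfortably inside the asserted tolerances. Other fixed choices: permutation
enumeration cutoff at `n_perm`; ratio values of exactly 1 contribute 0 to
ranking scores; empty-universe and zero-denominator cases return explicit
sentinels (`NA` ratio, score 0) rather than NaN.

## Limitations

* The classical tail rule is anti-conservative (see above); results quoted
  at "p ≤ 0.05" under it correspond to a true null rate nearer 0.10–0.16.
  The package makes both rules available rather than silently correcting.
* AU values are asymptotic approximations; at B = 1000 their own Monte-Carlo
  error near the 95 threshold is a few units, so "largest cluster with
  AU ≥ 95" should be read with that granularity.
* PDS extraction treats pathways as plain undirected graphs; edge semantics
  (activation, inhibition, compartment) are ignored.
* Identifier mapping is out of scope: all inputs must share one protein ID
  namespace.
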