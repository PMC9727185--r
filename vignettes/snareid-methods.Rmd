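---
title: "snareid: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{snareid: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models implemented by `snareid`, the choices
made where the design was genuinely open, and what the synthetic-data tests
do and do not establish. It is written for users who want to understand or
audit the pipeline, in the spirit of the long-form methods vignettes of
packages like DESeq2 or vegan.

## The task and its assumptions

The motivating problem is separating SNARE proteins (membrane-fusion
mediators) from the broader, structurally similar class of vesicular
transport proteins, given only amino-acid sequences. The pipeline makes the
usual assumptions of alignment-free sequence classification: that global
residue composition and the coarse positional layout of physicochemical
residue classes carry enough signal to separate the classes, and that
sequences are long enough (here, at least 2 residues after cleaning; in
practice tens to hundreds) for frequencies to be meaningful.

## The 188-dimensional descriptor

For a cleaned sequence of length $L$:

* **AAC (f1–f20).** $F_i = n_i / L$ for each standard residue, in fixed
  alphabetical order `ACDEFGHIKLMNPQRSTVWY`.
* **Per-property CTD blocks (f21–f188).** Eight physicochemical properties
  each partition the 20 residues into three disjoint groups, giving per
  property: 3 *composition* values $C_{A_i}/L$; 15 *distribution* values —
  for each group, the positions of the 1st,
  $\lceil 0.25 n_i \rceil$-th, $\lceil 0.50 n_i \rceil$-th,
  $\lceil 0.75 n_i \rceil$-th and $n_i$-th group occurrence divided by $L$;
  and 3 *transition* values — counts of adjacent pairs whose members fall in
  two different groups (unordered pairs (1,2), (1,3), (2,3)), divided by
  $L-1$.

Numerical conventions that had to be pinned:

* The distribution quantile index is $\max(1, \lceil q\,n_i \rceil)$ with
  1-based positions; a group absent from the sequence contributes five
  zeros. This is the convention of the classical CTD descriptor family, and
  pinning it makes golden tests exact.
* Within each property block the order is composition, distribution,
  transition; across properties the order is the row order of the shipped
  table (hydrophobicity, normalized van der Waals volume, polarity,
  polarizability, charge, secondary structure, solvent accessibility,
  surface tension). Feature indices are therefore reproducible across runs
  and versions.
* Non-standard residues (B, J, O, U, X, Z, gaps, `*`) are deleted during
  cleaning rather than remapped, and $L$ is the cleaned length. Mapping
  ambiguity codes onto property groups would have required inventing group
  assignments the descriptor literature does not define.

The eight groupings ship as a plain TSV
(`inst/extdata/ctd_property_groups.tsv`) and are part of the public
interface: they are data, not code, and users can substitute alternative
groupings. They follow the standard groupings of the CTD literature; the
surface-tension partition's first group is `GQDNAHR`.

## SMOTE balancing

Synthetic minority rows are $x_{new} = x + u\,(x_n - x)$ with
$u \sim U(0,1)$ and $x_n$ one of the $k$ (default 5) nearest minority
neighbors of $x$. Some write-ups print the difference as $|x - x_n|$; taken
literally, a coordinate-wise absolute value would break the defining
property that synthetic points lie on the segment between $x$ and $x_n$, so
the signed form is implemented and the $|\cdot|$ read as magnitude
notation. Base rows are used in whole passes over the minority set with a
random remainder; neighbor choice among the $k$ is uniform; distance ties
break to the lower row index. Every synthetic row carries `base`,
`neighbor` and `u` attributes so tests can verify collinearity exactly.

Target counts are configuration, not a rule: published protocols in this
area request specific post-balancing totals (e.g. 2,200 or 350) that are
not derivable from the raw counts, so `balance_dataset()` accepts
`"match"` (the majority count, default) or an explicit integer.

Where resampling meets cross-validation there is a leakage question: some
published protocols balance the *whole* dataset — including what later
becomes test material — before evaluating. `cross_validate()` defaults to
balancing only the training portion of each fold, after the split, so
synthetic points can never enter a test fold; `resample_all = TRUE`
reproduces the whole-dataset protocol for comparison but is not endorsed.

## The GHKNN classifier

For a test point $x$ and each class $c$, the $k' = \min(k, |c|)$ nearest
class members (input-space Euclidean; ties to lower index) form the
neighbor matrix $V$. Both the neighbors and the test point are centered by
the neighborhood centroid $\bar N$ ($\bar V = V - \bar N$,
$\bar x = x - \bar N$); centering is what makes the local hyperplane pass
through the centroid, and the input-space formulation requires it. The
coefficients solve

$$(K(\bar V,\bar V) + \lambda I + \mu L)\,\alpha = K(\bar V,\bar x),$$

a symmetric positive-definite system ($\lambda > 0$ guarantees
definiteness) solved directly, never via an explicit inverse. The squared
kernel-space distance to the class hyperplane is

$$d_c = K(\bar x,\bar x) + \alpha^\top K(\bar V,\bar V)\,\alpha
      - 2\,K(\bar V,\bar x)^\top \alpha,$$

clamped at zero (round-off negatives above $-10^{-10}$ are truncated;
anything more negative raises an error rather than silently masking a
numerical failure). The predicted class is the argmin of $d_c$; ties break
to the first label in the declared order (factor levels, else sorted
unique labels).

Open points that had to be decided:

* **Graph weights.** The regularizer's weights $\omega_{pq}$ are not fully
  specified in the HKNN/GHKNN literature. They are implemented as RBF
  similarities among the $k'$ neighbors with the *same* $\gamma$ as the
  kernel, zero diagonal (no self-loops), dense (no kNN sparsification), and
  $L = D - W$ is the unnormalized Laplacian. This is the simplest
  construction consistent with "coupling coefficients of similar
  neighbors", and it is pinned for reproducibility. Note the bookkeeping
  identity $\sum_{pq} \omega_{pq}(\alpha_p-\alpha_q)^2 = 2\,\alpha^\top L
  \alpha$: the solved system corresponds to the penalty
  $\mu\,\alpha^\top L \alpha$.
* **Neighborhood size.** $k$ is rarely stated in this literature; the
  default is 10, configurable, and classes smaller than $k$ use all their
  members.
* **No feature scaling by default.** The tuned default bandwidth
  $\gamma = 2^{-15}$ presumes raw 188-D descriptor magnitudes (all in
  $[0,1]$), so min–max scaling exists as an opt-in flag
  (`minmax_scale()`, `scale` in the config) and is off by default.
* **Baseline equivalence.** With a linear kernel and $\mu = 0$ the solve
  reduces to the classical input-space HKNN
  ($(\lambda I + \bar V \bar V^\top)\alpha = \bar V \bar x$,
  $d = \lVert \bar x - \bar V^\top \alpha \rVert^2$), and the test suite
  asserts distance agreement to $10^{-10}$ on random instances. This
  dual-route check (kernel path vs. independent input-space path) plus a
  generic numerical minimizer of the regularized objective are the two
  oracles guarding the solver.

Default parameters: $\lambda = 0.01$ (ridge weight), $\gamma = 2^{-15}$
(RBF bandwidth, on squared Euclidean descriptor distance),
$\mu = 0.1$ (graph weight), $k = 10$. These are the tuned values of the
motivating study and are what `ghknn_params()` reproduces. The sweep
harness (`sweep_parameter()`) varies exactly one of $\lambda, \gamma, \mu$
at a time while holding the others at their configured values, which is the
protocol under which those defaults were selected.

## Evaluation

SN $= TP/(TP+FN)$, SP $= TN/(TN+FP)$, ACC, and MCC
$= (TP\cdot TN - FP\cdot FN)/\sqrt{(TN+FN)(TP+FN)(TN+FP)(TP+FP)}$ are
computed from pooled (micro) confusion counts across stratified CV folds —
pooling was chosen over per-fold averaging because it makes reports exactly
recomputable from a single confusion table. Any metric with a zero
denominator is defined as 0 (the conventional guard; relevant only for
degenerate folds). Fold assignment is a seeded, shuffled round-robin within
each class, so every sample is tested exactly once and both classes appear
in every fold; a class smaller than the fold count is an error, not a
silent degradation.

## Synthetic data: what a green test establishes

Two generators stand in for curated datasets:

* `generate_labeled_set()` draws i.i.d. residues with uniform weights for
  negatives and bias-residue weights multiplied by $(1 +
  \text{bias\_strength})$ for positives (default bias set: the hydrophobic
  group `CLVIMFW`). Lengths are uniform on `[50, 400]`, a realistic span
  for transport-protein domains; the true length distribution of curated
  sets is unknown and irrelevant to the contracts being tested. With
  `bias_strength = 0` the populations are exchangeable, so cross-validated
  MCC near 0 is a genuine null check of the whole pipeline.
* `generate_feature_clusters()` emits two isotropic Gaussian classes in
  feature space. **Interpretation note:** `mean_shift` is the per-coordinate
  displacement of the positive center (the class means differ by
  `mean_shift` in every coordinate). The alternative reading — total
  Euclidean distance between centers — would make the package's own
  end-to-end recovery check (accuracy $\ge 0.95$ at a shift of 2 with unit
  spread in 188 dimensions) impossible for *any* classifier: the Bayes
  accuracy at total separation 2 is $\Phi(1) \approx 0.84$. The
  per-coordinate reading was fixed analytically, before any test was run,
  and is asserted in the generator's unit tests.

What the synthetic world does **not** emulate: homology structure and
redundancy between sequences, domain architecture, realistic length/
composition distributions, or the label noise of database annotation. A
green end-to-end test therefore establishes that the pipeline's mechanics
(featurization → balancing → classification → pooled metrics) are correct
and seeded-reproducible — not that any particular accuracy will transfer to
curated SNARE data, which requires the original external datasets.

## Known limitations

* The classifier is lazy (no trained model object); prediction cost is
  $O(n_{train})$ distance evaluations plus one $k' \times k'$ solve per
  test point per class. This is fine at the few-thousand-sample scale the
  method targets.
* Kernel-space neighbor search is out of scope: neighbors are always
  selected by input-space Euclidean distance, as in the HKNN heritage.
* Comparator descriptors (CTDC, GAAC, CKSAAGP) and deep-learning baselines
  are not implemented; the AAC-only descriptor is exposed for comparison.
* The CLI config format is JSON (flags override file values); every run
  appends a provenance line with parameters, seed and input digests so any
  report can be regenerated.
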