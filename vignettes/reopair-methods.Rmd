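---
title: "Methods: rank-based gene-pair diagnostics and prognostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-based gene-pair diagnostics and prognostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The relative expression ordering (REO) model

For two genes $G_i$, $G_j$ measured in the same sample, only the sign of
$G_i - G_j$ is used.  Across the $n$ samples of one class the package
estimates

$$P(G_i > G_j) = \frac{1}{n}\sum_{z=1}^{n} I[x_{iz} > x_{jz}], \qquad
  P(G_i < G_j) = \frac{1}{n}\sum_{z=1}^{n} I[x_{iz} < x_{jz}],$$

with $I$ the indicator function.  Ties contribute to neither probability, so
$P(>) + P(<) \le 1$ with equality exactly when no sample ties.  A pair is
**stable** in a class when one of these probabilities strictly exceeds the
threshold (default 0.9 — a pair ordered in exactly 90% of samples does *not*
qualify), and a **stable reversal pair** when it is stable in the tumor
class in one direction and stable in the normal class in the opposite
direction.  Reversal pairs are binarized into features: entry 1 when
$G_i > G_j$ in that sample, 0 otherwise (ties map to 0, consistent with the
strict definition of the indicator).

Because only within-sample orderings enter, every quantity — order
probabilities, mined pairs, binary profiles, and both pathway scorers — is
invariant under any strictly increasing per-sample transform of the
expression values.  This is the property that lets binary pair features
transfer across platforms without normalization; the test suite asserts it
directly.

Conventions fixed here because the strict/non-strict choices are otherwise
ambiguous:

* strict `>` at the stability threshold;
* ties count toward neither order probability and binarize to 0;
* pairs are stored in canonical lexicographic orientation (`gene_i <
  gene_j`) with an explicit `tumor_direction`, so (A,B) and (B,A) are one
  feature;
* when a validation cohort lacks one gene of a pair, the feature is imputed
  with the pair's majority binarized value over all training samples and the
  imputation is logged.  This keeps a fitted model applicable across
  platforms with incomplete gene coverage;
* multi-cohort training pools the class samples after per-sample rank use —
  REO needs no cross-cohort normalization.

# Synthetic data: what is planted and how

The generators define the study conditions under which every guarantee is
tested.

**Expression with planted reversal pairs.**  Values are continuous log-scale
intensities (the REO method uses only within-sample ranks, so count-level
detail adds nothing).  Each planted pair gives gene $i$ a class-dependent
mean offset $\delta$ over gene $j$ around their common baseline, with the
sign of $\delta$ flipped between classes.  Because the within-class
difference of the two genes is $N(\delta, 2\sigma^2)$ for noise sd
$\sigma$, choosing $\delta = \sqrt{2}\,\sigma\,\Phi^{-1}(p)$ sets the
within-class order probability to exactly the configured
`reversal_strength` $p$ (default 0.98).  Non-planted genes receive one
baseline mean each, identical in both classes, so they are exchangeable and
carry no class signal; the expected number of spurious reversal pairs at
threshold 0.9 with 100 samples per class is effectively zero, which the
tests confirm.

Gene-level structure (baseline means, which genes carry the planted pairs)
is drawn from a separate `structure_seed`, while `seed` drives only the
per-sample noise.  Cohorts generated with different seeds but one
`structure_seed` are therefore independent draws from the *same* simulated
disease — exactly what a training/validation cohort pair needs.  Without
this split, held-out cohorts would plant their signal on different genes and
no feature could transfer.

**CNV profiles.**  Cells are genes × cells matrices centered at the diploid
baseline 1, mimicking reference-based CNV inference output.  Each planted
cluster carries one contiguous aberrant gene block (random gain or loss) of
its own amplitude plus Gaussian noise; reference cells are noise around 1.
Two deliberate choices:

* Blocks are drawn uniformly but re-drawn to be pairwise disjoint whenever
  the gene axis has room.  Accidental block overlap between clusters would
  collapse the planted between-cluster separation, making recovery depend on
  the draw rather than on the configured amplitudes.
* Default amplitudes are 0.8 / 0.9 / 1.0 with noise sd 0.02 (amplitude gaps
  of five noise sds).  Amplitudes must be distinct so the cluster score
  ranking is well defined, but *near*-equal amplitudes keep the
  between-cluster geometry near-equilateral, which is where the elbow rule
  (below) identifies the true cluster number with a wide margin.  Strongly
  unequal amplitudes (say 0.2/0.5/1.0) create an elongated geometry in which
  the sharpest bend of the WSS curve genuinely sits at $k = 2$ — a property
  of the elbow heuristic itself, worth knowing when interpreting it on real
  data.

**Pathway cells.**  A configured fraction of cells has all gene-set genes
shifted up by `effect` (in units of the noise sd, default baseline sd 1).
With `effect = 0` the activity scores of active and inactive cells are
exchangeable; with `effect` ≥ 3 both scorers separate them almost
perfectly.

**Survival.**  Event times are exponential with rate
$\lambda_0 \exp(\sum_g \beta_g z_g)$ on z-scored expression — a
proportional-hazards model with known log hazard ratios — and censoring
times are independent exponentials with rate `censor_rate` (0 disables
censoring; the default 0.04 against baseline rate 0.1 yields roughly 30%
censoring).

What the generators do **not** emulate: read counts and UMI structure,
dropout, batch effects, doublets, cell-type composition, or the HMM
machinery of CNV inference.  Passing tests therefore demonstrate
correctness of the algorithms under clean planted structure, not robustness
to every artifact of real cohorts.

# CNV scoring and cluster-number selection

The per-cell CNV score is the mean squared deviation from the diploid
baseline, $\mathrm{mean}((v-1)^2)$ — zero for a diploid profile and
quadratic in aberration amplitude; a cluster's score is the mean over its
member cells, and the highest-scoring cluster is nominated as the most
aberrant (ties break to the lowest cluster ID).  Several conventions for
summarizing inferred CNV profiles exist; the mean squared deviation is the
dominant one and is stated prominently here because downstream nomination
depends on it.

Secondary clustering runs Lloyd k-means with k-means++ initialization and
10 seeded restarts for $k = 1..k_\max$, recording within- and
between-cluster sums of squares (their sum equals the total SS at every $k$,
asserted to 1e-6 relative tolerance).  The cluster number is chosen at the
elbow: $k^\* = \arg\max_{2 \le k \le k_\max - 1}
[(\mathrm{wss}(k{-}1) - \mathrm{wss}(k)) - (\mathrm{wss}(k) -
\mathrm{wss}(k{+}1))]$, with exact ties broken toward the smallest tied $k$
whose explained-variance ratio $\mathrm{bss}(k)/\mathrm{total}$ is within
0.01 of the next $k$'s.  The between-cluster sum of squares serves as this
plateau check — the natural quantitative reading of pairing an elbow plot
with a "betweenness" curve.  Degenerate input (no between-cell variation)
returns $k^\* = 1$ with a warning.

# Pathway activity scorers

Both scorers consume dense per-cell ranks (1 = highest expression), with
ties broken by one seeded random permutation per run so results are
reproducible and no gene is systematically favoured.

* **AUCell-style**: area under the set-gene recovery curve within the top
  fraction (default 5%) of the ranking, normalized by its maximum, giving a
  score in [0, 1].
* **ssGSEA-style**: weighted Kolmogorov–Smirnov running sum over the full
  ranking, in-set steps weighted by $(N - k + 1)^\alpha$ (default
  $\alpha = 0.25$), out-of-set steps $-1/(N - m)$; the score is the
  integrated running sum.  No cross-sample renormalization is applied, since
  the pipeline only compares scores between cell groups within one dataset.

Both are checked exactly against brute-force re-implementations on random
instances, and both must separate planted-activity cells (AUC ≥ 0.9) while
staying at chance for a null effect.

# The diagnostic model grid

Binary pair profiles feed a configurable grid of combinations over nine
methods: elastic net, gradient boosting, SVM (RBF), random forest, logistic
GLM, a two-component PLS-GLM, ridge, lasso, and CART.  The default grid is
every single classifier plus every ordered (selector → classifier) pair
with a selection-capable selector and selector ≠ classifier — 73 combos for
the full universe.  A selector is fit on training data only; sparse
penalized selectors keep the features with nonzero coefficients, tree
ensembles those with positive importance, dense methods the above-median
half, and a selector that vetoes everything falls back to all features.

Training-cohort AUC is computed from out-of-fold predictions under
stratified five-fold cross-validation with the whole selector+classifier
pipeline refit per fold, avoiding resubstitution optimism (a resubstitution
training AUC would be systematically higher).  Validation cohorts are
scored by the model fit on the full training set, always from binary
features recomputed within each cohort's own samples.  AUC uses the
normalized Mann–Whitney rank statistic with half-credit ties, verified
exactly against a pairwise concordance count.  Combos are ranked by the
mean AUC over all defined cohort AUCs; exact ties break to the simpler
model, then lexicographically.

The grid's **null calibration** permutes the class labels of *every* cohort
(training and validation) and expects all mean AUCs in [0.4, 0.6].
Permuting only the training labels does not produce a flat null: the binary
features still separate the validation classes, so a noise-trained model
scores validation cohorts near 0 or 1 depending on its random orientation —
a bimodal, not a null, distribution.  The all-cohort permutation is
therefore the package's definition of the grid's null experiment.

# Prognostic stage

Cox proportional-hazards fits (Efron tie handling, z-scored covariates) run
per gene (univariate) or jointly (multivariate); constant genes are dropped
with a warning, and fewer than 10 events triggers a stability warning.
Risk scores are the multivariate linear predictor; samples strictly above
the median score form the high-risk group (ties at the median go to
low-risk, so the high group is never the larger one).  Groups are compared
by Kaplan–Meier estimates and the log-rank test.  Harrell's concordance
index is implemented by explicit pair enumeration — a pair is usable when
the earlier time is an event (tied times only in event-vs-censored form),
score ties credit 0.5 — and is cross-checked in the tests against an
independent concordance routine.  Co-expression among the pair genes uses
Spearman correlation by default (Pearson by flag).

Each cohort is stratified at its *own* median risk score; applying a
training cohort's median to a validation cohort is a configuration choice
left to the caller.

# Pipeline, determinism, and problem sizes

`run_pipeline()` orders the stages — QC → CNV clustering/scoring → markers
∩ metabolic sets → reversal pairs → diagnostic grid → prognostics — writes
every artifact as fixed-format TSV (10 significant digits) and records MD5
checksums in a manifest; identical config + seed reproduces identical
checksums.  One top-level seed fans out to per-stage seeds through a
stage-name hash so stages can be rerun in isolation.  The cell-level QC
filter keeps cells with mitochondrial fraction < 10%, hemoglobin fraction
< 3%, and detected genes in [200, 8000] (fractions strict, gene bounds
inclusive), and reports every cell's statistics with failure reasons.

The test suite runs the grid once at full size (73 combos; 100+100 training
samples, two 80+80 validation cohorts, 5 planted pairs) and the permutation
null on the nine single-classifier combos × 10 permutations; pair mining is
exercised at 200 genes × 200 samples; Cox recovery at $n = 500$ over 20
seeds.  These sizes were chosen so each property is measured with
comfortable statistical margin while the whole suite stays quick to run.

# Known limitations

* The elbow heuristic is a heuristic: strongly anisometric cluster
  geometries move the sharpest WSS bend away from the true cluster number
  (see the CNV generator discussion above).
* The selector rules for dense methods (above-median importance) are a
  pragmatic convention; no claim of optimality is made.
* Pair mining uses fixed probability cutoffs; no multiplicity control over
  the pair universe is attempted, matching the method's design.
* The synthetic generators produce clean Gaussian structure; performance
  numbers on them are upper bounds on what heterogeneous real cohorts would
  give.
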