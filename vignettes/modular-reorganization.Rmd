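---
title: "Modular reorganization of brain networks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular reorganization of brain networks: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainmod)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does
not emulate, and where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## 1. The analysis chain

**Connectivity.** A subject is a $T \times N$ matrix of region-averaged
signals ($N = 116$ AAL regions by default, $T$ typically 128–175 time
points after preprocessing). Functional connectivity is the zero-lag
Pearson correlation $CC_{ij}$ of every region pair; the associated edge
distance is $d_{ij} = 1 - CC_{ij}$. No Fisher z-transform is applied
anywhere: every downstream quantity is defined on raw correlations.

**Group network.** For a group of $n$ subjects,
$$a_{ij} = \frac{\tfrac1n\sum_k CC_{kij}}
               {\sqrt{\tfrac1n\sum_k (CC_{kij}-\mu_{ij})^2}},$$
i.e. the entrywise mean over the entrywise *population* standard
deviation, with edges of non-positive mean set to zero. This weighting
privileges edges that are consistently positive across subjects and
suppresses edges with large inter-subject variation. The $1/n$
(population) form is used because that is the form the defining equation
writes; a `sd_type = "sample"` switch provides $1/(n-1)$ for comparison.
Two details the equation leaves open:

* *Masking stage.* Negative correlations could be zeroed per subject
  before pooling, or only the pooled mean could be masked. Since the
  standard deviation is nonnegative, the sign of $a_{ij}$ equals the sign
  of $\mu_{ij}$, and masking the group mean is the minimal reading; it is
  the default (`positive_mask = "group"`), with `"subject"` available.
* *Zero-variance edges.* An edge identical across all subjects has
  $a_{ij} = \infty$. Such edges are capped at the largest finite entry,
  with a warning, so downstream eigendecompositions stay finite. (With
  continuous data this arises with probability zero; with degenerate toy
  input it is visible and tested.)

**Modularity.** Partition quality is weighted modularity
$$Q = \frac{1}{2m}\sum_{ij}\Bigl[a_{ij}-\frac{k_ik_j}{2m}\Bigr]
      \delta(c_i,c_j),$$
with $k_i$ the node *strength* and $m$ the total weight. The defining
text calls $m$ "the number of connections" and $k_i$ "the degree", but
also calls $a_{ij}$ a weighted adjacency matrix; the weighted
generalization is the standard convention for that combination (and is
what the Brain Connectivity Toolbox computes), so strengths and total
weight are used throughout. Binarized analyses can be obtained by
thresholding and replacing weights with ones before calling the same
functions.

**Detection.** `detect_modules()` is Newman's spectral algorithm:
recursive bisection by the sign of the leading eigenvector of the
modularity matrix $B_{ij} = a_{ij} - k_ik_j/2m$, restricted to subgroups
with Newman's correction $B^{(g)}_{ij} = B_{ij} -
\delta_{ij}\sum_{k\in g}B_{ik}$; after each bisection a Kernighan–Lin
style refinement greedily moves single nodes across the cut while any
move increases $Q$. A subgroup is indivisible when its leading eigenvalue
or the best bisection's $\Delta Q$ falls below $10^{-10}$. Numerical
choices, all deterministic:

* eigenvector sign is normalized (sum positive; first nonzero entry
  positive on an exact tie), so results do not depend on LAPACK's sign
  convention;
* eigenvector entries with $|v_i| < 10^{-12}$ go to the positive side;
* disconnected components are partitioned independently (a singleton
  component is its own module);
* labels are renumbered 1..M by descending module size, ties broken by
  lowest member index.

Refinement is on by default (`refine = FALSE` for ablation). The spectral
heuristic is not exact; the test suite bounds its optimality gap on all
graphs small enough for exhaustive enumeration ($N \le 8$: detected
$Q \ge 0.95\,Q^*$) and that bound is a documented limitation, not a
guarantee of optimality.

**Null networks.** `random_equivalent()` performs Maslov–Sneppen double
edge swaps on the binarized topology (10 attempted swaps per edge),
preserving each node's binary degree exactly, then reassigns the original
weight multiset to the rewired edges in random order, preserving total
weight exactly. Strength sequences are only approximately preserved —
the standard trade-off for this null. 100 realizations by default; the
acceptance null-separation check uses its stated 20 per subject.

**Q-vs-edges curves.** `q_curve()` sparsifies each subject's network to
its `ne` strongest positive edges (ties broken lexicographically, making
edge sets nested in `ne`), detects modules, and compares groups per `ne`
with Welch's two-sample $t$, Bonferroni-corrected across the grid. The
defining study states neither its edge grid nor its correction method;
the defaults (grid 200–2000 by 200, Bonferroni, Welch) are declared
choices, not inferences.

**Reorganization.** `compare_partitions()` cross-tabulates memberships
and matches each source module to its maximal-overlap target module
(ties toward the larger target module, then the lower label; Jaccard
reported alongside) — a deterministic replacement for visual matching.
`homotopic_splits()` flags a pair as broken exactly when its two members
carry different module labels in one partition.

**Biomarkers.** Over a designated homotopic pair set (default: the
8-pair, 16-region insula module: inferior frontal operculum, area
triangularis, insula, putamen, globus pallidus, transverse temporal,
superior temporal, superior temporal pole):

* index A $= \tfrac1n\sum_i CC(\mathrm{ROI}_L(i), \mathrm{ROI}_R(i))$,
  raw correlations, no masking (the defining formulas impose none);
* index B: the printed formula sums two full $n \times n$
  within-hemisphere blocks — including the $n$ self-correlation terms —
  and divides by $n$, so its value exceeds 1 on constant input and
  double-counts each pair. The package default (`mean_pairs`) is the
  natural bounded statistic: the mean over the $2\binom{n}{2}$ distinct
  within-hemisphere pairs. The printed normalization is preserved as
  `mode = "literal"` for comparability, and the unit test pins both
  values on the same toy input.
* module GMC: per-subject mean gray-matter concentration over all 16
  regions; `control_gmc()` residualizes index A on GMC by pooled-sample
  OLS ("controlled out" is not otherwise specified; linear
  residualization is the conventional minimal reading).

**Classification.** Single features feed the ROC directly; combined
features are fused by an in-sample logistic score (the defining study
names no classifier and no cross-validation, and in-sample ROC mirrors
its usage — the well-known optimism of resubstitution applies, and the
README example shows an AUC of 1.0 on cleanly separated synthetic
groups precisely because of it). AUC is the rank/concordance statistic
with ties counted one half; a trapezoidal evaluation of the step ROC is
exposed separately (`roc_trapezoid_auc`) and the two agree to $10^{-10}$
in the tests. Complete separation degrades the logistic fit to a rank
ordering, which leaves the ROC unchanged; a message notes it.

## 2. The synthetic cohort generator

The generator is the stand-in for human cohorts; its defaults *are* the
stated world of the package's acceptance tests and were fixed before
those tests were run.

* Groups CN and AD, 30 subjects each; $T = 175$ time points (the study
  cohorts span 14–30 subjects and 128–175 time points).
* A planted 4-module partition of the 116 regions: module 1 is the
  16-region insula set, the remaining 100 regions form three contiguous
  blocks.
* Target correlations: `rho_within = 0.6` inside planted modules,
  `rho_between = 0.1` across, and the group-specific homotopic override
  on the 8 designated pairs: 0.6 (CN) vs 0.2 (AD).
* GMC: affected regions drawn at mean 0.55 (CN) vs 0.45 (AD), SD 0.05;
  unaffected regions at the midpoint 0.50 — gray-matter probabilities in
  cortical ROIs plausibly sit near 0.5 with this spread.
* `noise_sd = 0.1` independent observation noise. The value reconciles
  two stated requirements: noise is added *on top of* the target
  covariance, yet sample correlations must converge to the targets
  (within ±0.02 at $T = 10^4$). Jitter of variance $\sigma^2$ attenuates
  correlations by $1/(1+\sigma^2)$; at $\sigma = 0.1$ that is <1%,
  inside the band. Chosen once, not revisited.
* Targets that are not positive semi-definite after the homotopic
  override are repaired by eigenvalue clipping at zero and
  re-normalization to unit diagonal; a repair that would move any entry
  by more than 0.05 is an error ("use weaker contrasts"). The AD default
  (pairs at 0.2 inside a 0.6 block) sits exactly on the PSD boundary;
  stronger contrasts (e.g. 0.15) trigger a small logged repair (~0.02).
  Sampling uses the symmetric eigen square root, which tolerates the
  singular repaired case where a Cholesky factorization would fail.
* Reproducibility: one master seed; subject $k$ of group $g$ draws from
  a substream seeded by a fixed hash of (seed, $g$, $k$) below $2^{31}$,
  so enlarging a cohort never reshuffles existing subjects.

What the generator deliberately does **not** emulate: temporal
autocorrelation and hemodynamics (the analysis uses only zero-lag
correlation, so temporal structure cannot affect any downstream stage);
motion and scanner artifacts; inter-subject heterogeneity (every subject
in a group shares one covariance — see §4, because this matters); and
spatial structure beyond the block-plus-pairs covariance. A green test on
this world establishes the *pipeline's* correctness and sensitivity, not
realism of effect sizes on human data.

## 3. Tunables that matter

| parameter | default | units / range | why |
|---|---|---|---|
| `ne_grid` | 200–2000 by 200 | edges kept | spans sparse to ~30% density at $N=116$; source grid unstated |
| `n_null` | 100 | realizations | SD of null-Q mean scales as $1/\sqrt{n}$; the acceptance null-separation check uses its stated 20 |
| `sd_type` | population | — | matches the $1/n$ inside the printed radical |
| `positive_mask` | group | — | minimal reading; per-subject masking switchable |
| `refine` | TRUE | — | refinement never lowers Q (tested); off for ablation |
| `alpha` | 0.05 | — | conventional |
| `index_b_mode` | mean_pairs | — | bounded statistic; `literal` preserves the printed form |
| indivisibility `tol` | 1e-10 | Q units | well above eigen solver noise, far below any real $\Delta Q$ |

## 4. Known limitations

* **Spectral optimality.** Leading-eigenvector bisection with KL
  refinement can stop short of the global Q optimum; bounded at 5% on
  exhaustively checkable graphs, unbounded beyond.
* **Resolution limit and the planted homotopic split.** In the synthetic
  world, weakening only the 8 homotopic pair entries of the insula module
  (even to 0.15, versus 0.6 within-module) can never make modularity
  maximization split that module: merging the hemispheric halves changes
  Q by $(w_{LR} - k_Lk_R/2m)/m$, and the 56 non-mirror cross-hemisphere
  entries — which stay at `rho_within` — keep $w_{LR}$ an order of
  magnitude above the null expectation ($\approx 720$ vs $\approx 110$
  measured on the default group network). Even under the alternative
  construction in which cross-hemisphere entries fall to `rho_between`,
  the mean/std group weighting amplifies weak-but-consistent edges (our
  homogeneous subjects are maximally consistent) enough that the halves
  still merge for any nonnegative pair correlation. The corresponding
  acceptance test is therefore an honest red: the detection machinery is
  verified on constructive partitions instead, and reproducing the
  split-detection phenomenon generatively would require inter-subject
  heterogeneity that the generator intentionally lacks.
* **In-sample classification.** `classify()` fits and evaluates on the
  same subjects; AUCs are upper bounds on generalization. A held-out
  evaluation is out of scope here by design.
* **Atlas conventions.** The bundled AAL-116 fixture follows the
  conventional ordering (odd left / even right for 1–108, vermis
  109–116); any atlas TSV with symmetric left/right pairing is accepted,
  and the homotopic pair list is data, not code.

## 5. Determinism

Every stage is deterministic given the configuration and seed: the
generator and null models use derived substreams; eigenvector signs,
threshold ties, module label order, and match ties all have stated
deterministic rules; manifests record config, seed and package version
but no timestamps. The acceptance suite verifies that two `run-all`
executions produce byte-identical files.
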