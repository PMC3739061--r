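# brainmod

Modular reorganization analysis of resting-state brain functional
networks, packaged as a tested, reusable pipeline.

## The problem

Resting-state fMRI yields, per subject, one signal time course per atlas
region (here the 116-region AAL parcellation). Correlating every pair of
region time courses gives a functional connectivity network; community
("module") detection on such networks reveals how the brain organizes
into subnetworks. In neurodegenerative disease the *membership* of these
modules reorganizes even when global network statistics do not change —
in particular, homotopic (left–right mirror) region pairs that normally
sit in the same module can end up in different modules, and
interhemispheric connectivity over a designated pair set is a candidate
single-subject biomarker, alone or combined with regional gray-matter
concentration (GMC).

`brainmod` implements that analysis chain for anyone who has
region-averaged time series (TSV/CSV) and, optionally, region-level GMC
tables — plus a synthetic cohort generator with planted modular
covariance so the whole pipeline is testable without human data.

## The model

For subject *k*, connectivity is the Pearson correlation
`CC_ij` between region time courses, with edge distance
`d_ij = 1 − CC_ij`. The group network is the entrywise ratio of mean to
(population) standard deviation across the *n* subjects of a group,

```
a_ij = (1/n Σ_k CC_kij) / sqrt(1/n Σ_k (CC_kij − μ_ij)²),
```

kept only where the mean correlation is positive. Modules maximize the
weighted modularity

```
Q = 1/(2m) Σ_ij [a_ij − k_i k_j/(2m)] δ(c_i, c_j),
```

with node strength `k_i` and total weight `m`, via Newman's spectral
(leading-eigenvector) bisection with Kernighan–Lin style refinement, and
are benchmarked against degree-preserving (Maslov–Sneppen) random
networks. Reorganization between two group partitions is a cross-tab of
module memberships; a homotopic pair is "split" when its members carry
different module labels. The biomarkers over a designated pair set
(default: the 8-pair insula module) are

* **index A** — mean homotopic correlation `1/n Σ_i CC(ROI_L(i), ROI_R(i))`,
* **index B** — mean within-hemisphere correlation among the same regions,
* **module GMC** — per-subject mean gray-matter concentration over the set,

compared between groups by Welch's *t*, residualized on GMC by OLS, and
combined into a logistic score whose ROC/AUC (rank method, ties ½) is the
classification readout.

## Worked example

```r
library(brainmod)

spec <- cohort_spec(n_subjects = 12, seed = 7)   # CN vs AD, T = 175, AAL-116
res  <- run_pipeline(spec)

res$partitions$CN
#> <module_partition> 116 nodes in 4 modules; Q = 0.45528 [CN]
partition_nmi(res$partitions$CN, spec$module_plan)
#> [1] 1
```

The planted 4-module structure is recovered exactly (NMI = 1) and the
modularity of the control group network is Q ≈ 0.455. The biomarkers
separate the groups as planted:

```r
res$stats$index_A
#> index A: CN 0.592 (SD 0.035) vs AD 0.214 (SD 0.035),
#>          Welch t = 26.15, p = 4.6e-18, Cohen's d = 10.7
res$classification$auc
#> [1] 1
```

Index A sits near the planted homotopic correlations (0.6 in CN, 0.2 in
AD, both slightly attenuated by observation noise), and with a planted
GMC shift of 0.55 vs 0.45 the combined in-sample classifier separates the
two synthetic groups completely (AUC = 1; real cohorts are far noisier —
in-sample AUCs are optimistic by construction).

The same stages are scriptable from the shell:

```sh
Rscript -e 'brainmod::brainmod_cli()' simulate --out sim --seed 7
Rscript -e 'brainmod::brainmod_cli()' connectivity --in sim --out cc
Rscript -e 'brainmod::brainmod_cli()' group-network --in sim --groups sim/groups.tsv --out gn
Rscript -e 'brainmod::brainmod_cli()' modules --network gn/group_CN.tsv --out partition_CN.tsv
Rscript -e 'brainmod::brainmod_cli()' reorganize --source partition_CN.tsv --target partition_AD.tsv --out reorg.json
Rscript -e 'brainmod::brainmod_cli()' run-all --out results_full --seed 7
```

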