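---
title: "flowImpute: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flowImpute: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Conventional flow cytometry measures a dozen or two markers per cell.
Infinity Flow style experiments scale this to hundreds: cells stained with a
shared *backbone* antibody panel are split into wells, each well additionally
stained for one exploratory (*Infinity*) target on a common fluorochrome
(typically PE). Each well is acquired as its own FCS capture. Because every
capture measures the same backbone, a regression model trained within one
capture — backbone channels in, exploratory channel out — can predict
("impute") that exploratory marker for the events of *every* capture. Doing
this for all captures yields a single event-by-feature matrix spanning the
full exploratory repertoire, which can then be clustered and mined like a
single-cell genomics dataset.

flowImpute implements this workflow end to end: FCS 3.0/3.1 I/O, logicle
scaling, per-capture gradient-boosted regression with held-out validation,
optional isotype background correction, pooled or reference-file assembly,
seeded PCA/UMAP/Leiden wrappers, cluster-marker discovery, nearest-centroid
label transfer, and a synthetic-panel generator that provides ground truth
for every stage.

# The imputation model

For each capture $f$ and each of its annotated exploratory channels, the
events are partitioned at random into a training half and a validation half
(default fraction 0.5; the training size is round-half-up of
$\mathrm{fraction}\cdot n$). A gradient-boosted decision-tree regressor
(squared-error objective) is fit on the training events,

$$\hat y = F(\mathbf{x}_{\text{backbone}}),$$

and scored on the untouched validation events. Both the mean squared error
and the mean absolute error are stored on every model, together with the
Pearson correlation; reporting layers may display MSE on a log10 scale.
Keeping both metrics sidesteps the ambiguity over which one is "the"
accuracy measure — they are cheap and answer different questions.

Boosting hyperparameters default to 500 rounds, learning rate 0.05, maximum
depth 6, subsample 1.0, single thread. These are deliberately conservative,
desk-scale settings: deep enough to capture interactions between backbone
channels (one of the synthetic link families is a pure two-channel product,
invisible to additive models), slow enough a learning rate that 500 rounds
does not overfit 10 000 training events. All are exposed in
`boostParams()`. Training is bit-reproducible given the seed and one
thread; every model's seed is derived by hashing (run seed, file id, marker
name), so adding a capture to a run never perturbs the other models.

Validation events never appear in their own model's training rows
(asserted by index sets in the tests). The floor of 300 events per capture
(`minEvents`) is the practical minimum for a 50/50 split to leave a
trainable set; real captures are expected to carry at least 20 000 events.

# Scales and transforms

Regression operates on the logicle display scale by default. The logicle is
the inverse of the biexponential

$$B(y) = a e^{b y} - c e^{-d y} - f,$$

with coefficients fixed by the standard constraints ($B(1) = T$; data zero
at $x_1 = (A+W)/(M+A)$; $d$ solving $2(\ln d - \ln b) + w(b+d) = 0$ with
$w = W/(M+A)$, $b = (M+A)\ln 10$), continued by odd symmetry about
$(x_1, 0)$ for the negative domain, as in the published reference
implementation. Defaults are $T = 262144$, $M = 4.5$, $A = 0$, with the
linearization width $W$ estimated per channel from the 5th percentile of
negative events and clamped to $[0.25, M/2]$; channels without negative
events fall back to $W = 0.5$. When $W$ is estimated it is estimated once
from the data pooled across all captures, so every capture shares identical
channel scales — per-file scale estimation would reintroduce exactly the
batch artifact described below.

Numerically, the forward logicle is solved by safeguarded Newton iteration
inside a bisection bracket, converged to $|B(y) - x| \le T\cdot 10^{-10}$;
round-trip accuracy is better than $10^{-6}$ relative over
$[-0.1T,\, T]$. Scatter and time channels are always left linear; arcsinh
(default cofactor 150) is available per channel or globally.

Per-file z-score normalization is implemented (`zscore = TRUE`, sample-sd
convention with the $n-1$ denominator) but **off by default**. When capture
files differ in population composition — which is the rule, not the
exception, since captures are wells of the same experiment at different
times — per-file standardization maps the *same* raw backbone value to
*different* standardized coordinates in different files, so models trained
in different files disagree systematically on identical cells. The test
suite demonstrates this directly: on two synthetic captures with identical
biology but shifted population weights, per-file z-scoring inflates the
between-model prediction discrepancy for a fixed probe set by two orders of
magnitude relative to the default pipeline.

# Isotype background correction

Nonspecific antibody binding can be estimated from isotype-control
captures (same antibody class, no specific target). After imputation, each
assigned marker $m$ with isotype column $iso$ is corrected by ordinary
least squares across the pooled events:

$$m = \alpha + \beta\, iso + \varepsilon, \qquad
  m_{\text{corrected}} = m - \hat\beta\, iso.$$

Three choices were genuinely open and are fixed (and recorded in the fit
report so they are auditable):

* **The intercept is retained.** Subtracting $\hat\alpha$ would shift the
  marker's location, conflating background removal with re-centering; only
  the component that *tracks* the isotype is removed.
* **$\hat\beta$ is clamped at 0.** An isotype control can add background but
  cannot remove negative background; an anticorrelated fit is reported and
  skipped with a warning.
* **Correction operates on the regression (transformed) scale**, where the
  imputation itself lives.

Assignment plumbing: the annotation's `isotype_group` column links markers
to a group; the row flagged `isotype_control = TRUE` within a group is that
group's control. Note the model is identifiable only insofar as the true
marker signal is not collinear with the background process across events;
the linear correction removes *any* marker component that tracks the
isotype, which is the intended behaviour but means slope estimates on real
data absorb shared lineage structure.

# Assembly and export

The prediction substrate is either (a) a pooled matrix of `nPerFile`
(default 10 000) validation events sampled per capture without replacement,
or (b) every event of a separate backbone reference FCS, without
down-sampling. The final object is an `ImputedExperiment` (a
`SingleCellExperiment`): features in rows, ordered backbone block, imputed
block, passthrough block; per-event provenance (`source_file`,
`original_event_index`) in `colData`; the run configuration, seeds and the
resolved per-channel transform parameters in `metadata`, so raw-scale
values are recoverable from the export. Events are exported on the
regression scale. `h5ad` (AnnData-compatible HDF5), `feather` and `csv`
writers are provided; `h5ad` and `feather` round-trip the matrix exactly,
`csv` to 15 significant digits.

# Downstream wrappers

`embedAndCluster()` standardizes features (for embedding only — this never
feeds back into imputation), takes the top `nPcs = 30` principal
components (clamped with a warning at the feature count), builds a
`nNeighbors = 15` kNN graph, runs Leiden community detection (modularity
objective, resolution 1.0) and a 2-D UMAP. These are the community-standard
defaults. All stochastic stages are seeded; cluster ids are relabeled
contiguously from 0 by decreasing size. `subcluster()` reruns the stack on
one cluster only, namespacing child labels `parent.child` and never
touching labels outside the parent.

`markerFinder()` implements the single-pass indicator-correlation form of
cluster-marker ranking: each feature's Pearson correlation with every
cluster's idealized 0/1 membership profile, assignment to the argmax
cluster (ties to the lowest cluster id), ranked per cluster. Published
descriptions of this algorithm family span variants (intra-cluster
centering, iterative exclusion passes); the one-pass form is fixed here
because it is the defensible common core and is exactly checkable against
a brute-force oracle, which the tests do on random 200 × 50 matrices.

`labelTransfer()` is an explicit **simplification** of community-alignment
label transfer to its nearest-centroid core: each query event is assigned
the reference label whose centroid it best correlates with over the shared
(optionally renamed, e.g. protein-to-gene) features, with a correlation
floor (default 0.1) below which events are `"unassigned"`. Score ties
within $10^{-12}$ — exact equality is not robust to BLAS accumulation
order — break towards the lexicographically smallest label, with a
warning. No community matching or iterative refinement is performed.

# The synthetic panel generator

`generatePanel()` materializes a `SyntheticPanelSpec` as real FCS files
plus ground-truth tables, deterministically per seed (byte-identical
files). The generative model: events are a mixture of Gaussian populations
over the backbone channels **on the logicle display scale**, where each
exploratory marker is a known link function of the backbone plus additive
Gaussian noise plus (optionally) a planted multiple of a background
process; isotype-control captures measure the background plus noise. Link
families — linear, logistic (switch-like), and two-channel interaction —
span easy to hard regression regimes. In the default `"raw"` mode the
display values are pushed through the fixed biexponential
(`panelLogicleSpec()`: $T=262144, W=0.5, M=4.5, A=0$) before writing, so
the files carry realistic raw intensities and a pipeline run with the same
fixed logicle recovers the generative scale exactly — which is what makes
`attainableR()`,

$$r_{\max} = \frac{\mathrm{sd(link)}}
  {\sqrt{\mathrm{sd(link)}^2 + \sigma_{\text{noise}}^2}},$$

an exact ceiling for imputation accuracy on the regression scale. The
surrogate-backbone benchmark panel builds a 21-channel backbone whose last
10 channels are links of the first 11 plus noise, so predicting truly
"measured" channels from a surrogate backbone has computable attainable
accuracy.

Default generator conditions mirror the study design: 20 000 events per
capture, 50/50 split, 10 000 pooled validation events per file. The
background-driving backbone channel has a population-independent mean
(nonspecific binding independent of lineage); this keeps planted background
slopes identifiable by the linear correction — with lineage-dependent
background the OLS slope would rightly absorb the shared component.

What the generator does **not** emulate: spillover/compensation structure,
acquisition-time drift, non-Gaussian population shapes, doublets and
debris, and detector saturation. Passing tests therefore demonstrate the
pipeline's correctness and calibration under a clean additive-noise model,
not robustness to instrument artifacts.

# Problem sizes and numerical conventions

The shipped tests run the full pipeline at 3 000-event captures with
reduced boosting rounds for speed, and the acceptance checks at the full
20 000-event, 500-round study conditions; the 11-predicting-10
surrogate benchmark runs at 20 000 events. Other fixed conventions:
round-half-up for split sizes; sample sd for z-scores; integer FCS data
widened to doubles; FCS writes as FCS 3.1 float32 little-endian (big-endian
available); multi-dataset FCS files read the first dataset with a warning;
`$PnE` de-log is opt-in (modern float-mode files are already linear).

# Known limitations

* Imputed values are model predictions of the *conditional mean*; their
  dispersion understates true marker dispersion, and rare populations not
  separable in backbone space cannot be recovered.
* The FCS reader supports list-mode `$DATATYPE` F/D/I only; ASCII data and
  FCS 2.0 are rejected by design, and spillover matrices are not applied.
* `labelTransfer()` is nearest-centroid only; RNA-to-protein label transfer
  is inferential at best and should be treated as hypothesis generation.
* Leiden/UMAP determinism is guaranteed for fixed seeds on a single
  thread; results are not comparable across different library versions.
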