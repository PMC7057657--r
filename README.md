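# shootseg

Classical leaf/stem segmentation baselines for 3D plant shoot models.

High-resolution 3D plant models — X-ray CT scans of rosebushes voxelized at
~0.5 mm with organ-level labels are the motivating case — support automatic
measurement of plant architecture, but every architectural trait starts from
the same step: classifying each point or voxel as **leaf** or **stem** (the
stem class includes petioles). `shootseg` implements three classical
baselines for that step, the matching evaluation protocol, and a seeded
generator of labeled synthetic plants, so the full train/test loop runs
without any external dataset. It is aimed at plant-phenotyping researchers
who need reference baselines, and at method developers who need a controlled
test bed.

## The methods

**LFPC-u — unsupervised graph cut on point clouds.** Each point gets a
curvature (surface variation) estimate from the eigenvalues
λ₁ ≤ λ₂ ≤ λ₃ of its neighbourhood covariance, C(x) = λ₁/(λ₁+λ₂+λ₃) ∈ [0, ⅓],
and a flatness feature R(x) = ln max(C(x), c_ε) with c_ε = 0.015. A binary
labeling f over {leaf, stem} of the 1.4 mm-neighbourhood graph is scored by

    E(f) = w_D Σ_x D_x(f(x)) + w_V Σ_(i,j) V_ij · [f(i) ≠ f(j)]

with data term D_x(L) = R(x) − ln c_ε, D_x(S) = ln(⅓) − R(x) and smoothness
penalty V_ij = max(1/C_i, 1/C_j) (curvatures floored at c_ε). With
non-negative pairwise terms the energy is submodular, and
`minimize_energy()` finds the exact global minimum by s-t min-cut
(a Boykov–Kolmogorov-style max-flow in C++). Defaults w_D = 0.9, w_V = 0.1.

**LFPC-s — supervised multi-scale eigen-feature SVM.** Four eigenvalue
ratios, F₁ = λ₁/√(λ₂λ₃), F₂ = λ₂/λ₃, F₃ = λ₁/√(λ₁λ₂λ₃), F₄ = λ₁/λ₂,
computed at neighbourhood radii 2–7 mm (24 features), feed a two-class
linear SVM trained on one labeled model.

**LFVD — volumetric filter-bank random forest.** On the binary surface-voxel
mask, 22 channels per scale (Gaussian smoothing, gradient magnitude,
Laplacian of Gaussian, difference of Gaussians, structure-tensor and Hessian
eigenvalues and raw entries) at scales 0.7–10 mm feed a random forest voxel
classifier.

**Evaluation.** Per-class precision, recall and IoU = TP/(TP+FN+FP) over the
leaf/stem confusion, with points whose ground truth is flower (or pot, tag,
background) excluded from scoring.

## A worked example

Generate a labeled phantom, segment it with the unsupervised graph cut, and
score the result (about a minute end to end):

```r
library(shootseg)

ph <- generate_phantom(phantom_spec(seed = 2))
ph
#> <phantom seed 2: 279 x 216 x 176 voxels, 49746 surface points, leaf 82% / stem 18% of shoot>

seg <- segment_lfpc_u(ph$cloud)        # w_D = 0.9, w_V = 0.1, 1.4 mm edges
report <- evaluate_labels(ph$cloud$label, seg$pred)
report
#> Leaf/stem segmentation report (49746 points, 0 ignored)
#> # A tibble: 2 × 7
#>   class    tp    fp    fn precision recall   iou
#>   <chr> <int> <int> <int>     <dbl>  <dbl> <dbl>
#> 1 leaf  41823  1818   872     0.958  0.980 0.940
#> 2 stem   5233   872  1818     0.857  0.742 0.660
```

`seg` is the input cloud plus `curvature`, `flatness` and `pred` columns, so
it pipes straight into dplyr or `plot_cloud(seg, colour = "pred")`. Reading
the report: 98% of true leaf points were recovered (recall), 96% of leaf
calls were right (precision), and the leaf IoU — the strictest of the three
— is 0.94. Stems come out lower (IoU 0.66): thin petioles buried between
leaflets are partly misread as leaf, the characteristic failure mode of
curvature-driven segmentation.

The supervised pipelines follow the same pattern
(`fit_lfpc_s()`/`predict()` on clouds, `feature_bank()`/`fit_lfvd()`/
`segment_lfvd()` on volumes), and `run_benchmark()` chains everything:
phantom suite → train on model 1 → segment models 2..n → per-model and
summary CSV reports.

A thin command-line front end ships in `inst/cli/shootseg`
(`synth`, `segment mrf`, `evaluate`, `benchmark` subcommands).

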