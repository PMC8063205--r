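# radkinetics

Longitudinal radiomics kinetics for normal-tissue injury classification.

Head-and-neck radiotherapy patients get serial contrast-enhanced CT scans
anyway — at baseline and around 2 and 6 months after treatment. This
package asks whether the *temporal trajectory* of radiomic texture
features inside an irradiated mandibular subvolume can flag regions at
risk of osteoradionecrosis (ORN) earlier and better than a single
baseline scan or a before/after "delta" change. It is aimed at
quantitative-imaging researchers who want a tested, reproducible
implementation of the full analysis, plus a synthetic cohort generator
with known ground truth for method validation.

## What it computes

1. **Texture features** per VOI and time point, after trilinear
   resampling to 1 × 1 × 3 mm voxels and equal-width gray-level
   discretization: first-order statistics, GLCM (contrast, correlation,
   dissimilarity, cluster shade, IDMN, IMC1), GLRL (Galloway run-length
   features) and NGTDM (Amadasun–King neighbourhood gray-tone features,
   windows 3/5/7), each in 3D and 2.5D with directions merged.
2. **Screening**: iterative mean-|Spearman ρ| correlation filtering at
   the pre-treatment month (threshold 0.5) and two-sided Mann–Whitney
   tests with direction of the mean difference.
3. **Trajectory encoding**: natural cubic spline completion of each
   3-point trajectory onto integer months 0–6, univariate functional PCA
   per feature (quadrature-weighted eigenproblem, W^{1/2}CW^{1/2}), then
   multivariate FPCA on the stacked scores, yielding per-VOI trajectory
   scores ρ_im:

   X_ij(t) ≈ μ_j(t) + Σ_m ρ_im ψ_m^{(j)}(t)

4. **Models**: baseline, delta-2-month, delta-6-month, trajectory (MFPCA
   scores) and a baseline+trajectory ensemble, each a 500-tree random
   forest under patient-grouped Monte-Carlo cross-validation with a
   shared split schedule (paired comparisons).
5. **Evaluation**: ROC, trapezoidal AUC (= tie-corrected U/(n₁n₂)),
   DeLong or stratified-bootstrap 95% CI, Youden-optimal threshold and
   confusion matrices at a cutoff (probability below the cutoff ⇒ ORN).

See `vignettes/radiomics-kinetics.Rmd` for the full methods account and
design rationale.

## Worked example

Generate a "shape-signal" cohort — ORN and Control regions with
identical baseline *and* identical net-change distributions, where only
the month-2 detour of the ORN trajectories carries information — and
compare the five models:

```r
library(radkinetics)

co <- generateTrajectoryCohort(cohortSpec(
  nPatients = 100L, nOrnVois = 100L, nControlVois = 100L,
  signalMode = "shape", seed = 1L))
suite <- runModelSuite(co$table,
                       spec = modelSpec(nTrees = 300L, nRepeats = 25L,
                                        seed = 1L))
print(comparisonTable(suite), row.names = FALSE, digits = 3)
```

```
 representation   auc ci_low ci_high youden_threshold sensitivity specificity
         delta2 1.000  1.000   1.000            0.481        1.00        1.00
     trajectory 0.974  0.956   0.991            0.613        0.96        0.89
       ensemble 0.955  0.927   0.984            0.528        0.93        0.90
         delta6 0.609  0.531   0.688            0.466        0.49        0.71
       baseline 0.460  0.380   0.540            0.566        0.87        0.17
```

(The separable delta2 model's degenerate DeLong variance triggers the
seeded bootstrap fallback, with a warning.)

Reading it: the baseline model and the 6-month delta model are blind to
a signal that lives purely in the trajectory shape (AUC ≈ 0.5), while
the MFPCA trajectory model detects it almost perfectly. The 2-month
delta looks directly at the month of the detour, so it performs well in
this synthetic scenario by construction. The Youden columns give the
operating point maximising sensitivity + specificity − 1 on the
Control-probability scale.

The configuration-driven entry point writes a full report bundle
(screening table, per-model predictions and ROC points, comparison
table, JSON report) plus a manifest with every effective setting,
derived per-stage seeds and the input hash, so a run is reproducible
from the manifest alone:

```r
runPipeline(pipelineConfig(seed = 1L), outDir = "out")
```

A thin CLI wrapper with `simulate` and `run` subcommands is installed at
`inst/scripts/radkinetics.R`.

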