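# morphoval

Phantom-based validation of voxel-based morphometry (VBM) pipelines, at
desk scale.

VBM detects local anatomical change by registering every subject to a
common template and testing the log-Jacobian determinant of each
subject's deformation field voxelwise between groups. The outcome depends
strongly on registration choices — the gradient step size and the
regularization of the update and total deformation fields — and on the
template-building strategy, yet real studies offer no voxel-level ground
truth against which to tune them. `morphoval` is for researchers building
or tuning such pipelines (small-animal neuroimaging in particular): it
simulates labeled brain cohorts, induces *known* atrophy or hypertrophy in
chosen structures, runs a complete minimal VBM pipeline, and scores how
faithfully the induced change is recovered.

## What it computes

Given a structure with simulated volume change ΔV_sim (measured as the
mean Jacobian of the induced warp over the original mask) and a recovered
effect map (smoothed log-Jacobian group difference), the framework scores:

* **distance from target** |Δd| = |ΔV_sim − ΔV_impl|, with
  ΔV_impl = (exp(mean effect over the structure) − 1) × 100%;
* **sensitivity index** d′ = (μ_S − μ_N) / √(σ²_S + σ²_N), contrasting the
  structure's inner shell (signal) against its surrounding leakage region
  (noise);
* **ROC AUC** and **TPR@p = 0.05** over p-value thresholds, with TPR the
  fraction of structure voxels significant at the threshold and FPR the
  fraction of brain voxels outside the structure;
* **Dice coefficients** of atlas labels propagated through the pipeline
  against the generator's ground-truth labels;
* rank aggregation of these metrics across registration parameter sets
  (step, RegU, RegT) × (template cohort).

The registration engine is a greedy multi-resolution diffeomorphic method:
each iteration's update force is normalized to a maximum displacement of
`min(step, 0.4)` voxels, smoothed with a Gaussian of sigma `RegU`, composed
into the total field, which is optionally smoothed with sigma `RegT`.
Every produced field has a strictly positive Jacobian.

## Worked example

```r
library(morphoval)

cohort <- simulate_cohort(cohort_spec(seed = 42))     # 5 controls, 64^3
recipe <- phantom_recipe(list(
  list(label = 3, op = "erode",  radius = 1),          # right Hc: atrophy
  list(label = 4, op = "dilate", radius = 1)))         # left CPu: hypertrophy
study <- run_phantom_study(cohort, recipe,
                           params = registration_params(0.25, 3, 0.5),
                           mdt_cohort = "C", smooth_sigma = 3)
study$truth
study$eval
mean(study$dice$dice)
```

Output (seed 42):

```
  label     op n mean_percent_change sd_percent_change mean_log_jacobian
1     3  erode 5           -20.20681         0.3450111        -0.2278063
2     4 dilate 5            25.57058         0.6487317         0.2264098

  label     op   direction delta_v_simulated delta_v_implied  delta_d  d_prime       auc tpr_at_p05
1     3  erode     atrophy         -20.20681       -14.42363 5.783174 1.595857 0.9819372        100
2     4 dilate hypertrophy          25.57058        18.42861 7.141970 2.043760 0.9965127        100

[1] 0.92832
```

Reading it: the one-voxel erosion induced a −20.2% volume change in the
right hippocampus-like structure; the pipeline's recovered effect implies
−14.4%, i.e. |Δd| ≈ 5.8 percentage points of under-recovery (smoothing
dilutes the mean effect). Detection is nonetheless excellent: every
structure voxel is significant at p ≤ 0.05 (TPR 100%), the atrophy ROC has
AUC 0.98, and propagated labels overlap ground truth at Dice 0.93.

A parameter sweep over the full 2×3×2×2 grid (template cohort × step ×
RegU × RegT) with ranked output:

```r
sweep <- run_sweep(sweep_grid(), cohort, recipe, "sweep_out")
sweep$ranking
```

A thin command-line front end with subcommands (`synth`, `mask`,
`register`, `phantom`, `mdt`, `vbm`, `evaluate`, `rank`, `sweep`,
`verify`) is installed at `inst/cli/morphoval.R`.

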