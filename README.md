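# tlntcp — NTCP modelling of temporal-lobe injury after re-irradiation

Radiation-induced temporal-lobe injury (TLI) is the dominant late toxicity
when recurrent nasopharyngeal carcinoma is treated with a second course of
intensity-modulated radiotherapy. Deciding how much dose the lobes can
tolerate across *two* courses requires: converting both courses to a common
fractionation scale, accumulating them voxel by voxel (possibly discounting
the first course for recovery over the inter-course interval), summarising
the lobe dose with DVH indices, and fitting a dose–response model that can
be validated on held-out patients.

`tlntcp` is an R package plus a scripted analysis that implements this
pipeline for radiotherapy outcome modellers:

* **Dose algebra** — per-voxel EQD2 under the linear-quadratic model,
  `EQD2 = D·(d + α/β)/(2 + α/β)` with `d = D/n_fractions` and α/β = 3 Gy
  for late brain tissue; voxel-wise two-course accumulation
  `w·dose1 + dose2` with linear (`w = 1 − a·gap`), quadratic
  (`1 − a·gap²`), exponential (`exp(−a·gap)`) or no recovery weighting,
  clamped to [0, 1]; NIfTI import/export.
* **DVH metrics** — exact Dmax and D0.5cc–D5cc ("minimum dose to the
  hottest x cc", linearly interpolated within voxels) from sorted member
  doses; binned cumulative DVH curves for export.
* **NTCP model** — logistic regression `NTCP = 1/(1 + e^(−S))`,
  `S = β0 + Σ βi·xi`, fitted by monotone IRLS with Nagelkerke R²; a grid
  sweep over the recovery rate `a` (re-accumulate, re-extract, refit at
  each rate); forward selection under three data-availability protocols
  (re-RT indices only / both courses separately / accumulated dose);
  tolerance doses `TDp = (logit(p) − β0)/β1` with parametric-bootstrap
  intervals; dose–response curves.
* **Evaluation** — patient-level 2:1 train/validation splits, AUC with
  DeLong confidence intervals and p-value, Youden operating points.
* **Synthetic cohort generator** — paired dose grids, lobe masks, clinical
  covariates and per-lobe outcomes from a configurable ground-truth NTCP,
  so the whole pipeline runs and is tested end to end without patient data.

## Worked example

The numbered scripts under `analysis/` run the full workflow on a 78-patient
synthetic cohort (seed 20100) and write tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/03_time_model_sweep.R
Rscript analysis/04_ntcp_models.R
Rscript analysis/05_validation.R
```

which prints, among other things:

```
Per-lobe injury incidence: 32.7%; per-patient: 51.3%.
Accumulated D1.5cc: mean 106.8 Gy EQD2 (sd 17.5).

linear       best index dmax    R2_max 0.3872 at a = 0.0000
             plain-sum R2 for that index: 0.3872 (delta 0.0000)

Accumulated D1.5cc dose-response: S = 0.08764 × sum_d1_5cc − 10.5
  TD5 = 86.17 Gy EQD2 (95% bootstrap 63.65-95.83)
  TD50 = 119.77 Gy EQD2 (95% bootstrap 114.14-127.98)

accumulated            validation AUC 0.7582 (0.6144-0.9020), p = 0.00043
```

Reading this: the recovery-rate sweep peaks at `a = 0` — time-weighted
accumulation does not beat the plain voxel sum on this cohort, mirroring the
generator's ground truth (no recovery). The univariate dose-response on the
accumulated D1.5cc estimates TD50 ≈ 120 Gy EQD2 against a true value of
122.6 Gy, and the accumulated-dose model discriminates best on the held-out
patients.

The same steps in code:

```r
library(tlntcp)
cfg    <- simulation_config(n_patients = 78, seed = 20100)
cohort <- simulate_cohort(cfg)
sp     <- split_cohort(cohort, c(2, 1), seed = 20101)
m      <- build_ntcp(sp$train, protocol = "accumulated")
validate_model(m, sp$validation)
```

See `vignettes/temporal-lobe-ntcp.Rmd` for the model, its assumptions, the
generator's calibration and known limitations.

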