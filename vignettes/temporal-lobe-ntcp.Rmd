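---
title: "Modelling temporal-lobe injury after re-irradiation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling temporal-lobe injury after re-irradiation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients with locally recurrent nasopharyngeal carcinoma are often treated
with a second course of intensity-modulated radiotherapy. The temporal lobes
sit directly above the skull base and receive substantial dose in both
courses, so radiation-induced temporal-lobe injury (TLI) — enhancing
lesions, white-matter change or cysts on follow-up MRI — is the dominant
late toxicity. Planning a re-irradiation course therefore needs a
dose–response (NTCP, normal tissue complication probability) model for the
*cumulative* lobe dose, and an account of how much the first course still
"counts" after a recovery interval of years.

`tlntcp` implements that analysis end to end: voxel-wise EQD2 conversion and
two-course accumulation, DVH index extraction, logistic NTCP construction
under three data-availability protocols, tolerance-dose inversion, and
ROC-based validation — plus a synthetic cohort generator so the whole
pipeline is testable without patient data.

## Dose algebra

**EQD2.** Courses with different fraction sizes are made comparable with the
linear-quadratic conversion

$$EQD2 = D\,\frac{d + \alpha/\beta}{2 + \alpha/\beta},$$

applied per voxel with fraction dose $d = D/n_\text{fractions}$ (each course
is assumed uniformly fractionated; treatment plans do not record a per-voxel
fractionation). We use $\alpha/\beta = 3$ Gy, the conventional value for
late-responding brain tissue. Voxels at exactly 2 Gy per fraction are fixed
points; zero dose maps to zero. EQD2 grids carry their $\alpha/\beta$ so
that distributions converted under different ratios refuse to accumulate.

**Two-course accumulation.** The first course's grid is assumed already
deformed onto the re-irradiation frame (registration itself is out of scope;
grids must agree in shape, spacing and frame identifier, and no resampling
is performed). Accumulation is voxel-wise

$$\mathrm{dose}_\text{tot} = w(a, \text{gap})\cdot\mathrm{dose}_1 + \mathrm{dose}_2,$$

where the first-course weight follows one of four time-interval recovery
models: $w = 1$ (no recovery, the plain sum), $1 - a\,\text{gap}$ (linear),
$1 - a\,\text{gap}^2$ (quadratic) or $e^{-a\,\text{gap}}$ (exponential),
with the gap measured in months and $a \ge 0$ the recovery rate. At rates
around $2\times 10^{-3}$ per month the linear weight is $\approx 0.95$ at
the cohort's median 26-month interval — small but physiologically plausible
recovery. Linear and quadratic weights can go negative at large
$a\cdot\text{gap}$; we clamp to $[0, 1]$, since a negative first-course
contribution is unphysical. Whether published analyses clamped or simply
never explored rates that large is unknowable from the reported grids;
clamping makes every rate admissible.

## DVH indices

For a structure mask (binary, no partial-volume handling) the package
reports the maximum dose and DxCC — the minimum dose to the hottest $x$ cc —
for $x = 0.5, 1.0, \ldots, 5.0$. DxCC is computed exactly from the sorted
member voxel doses: cumulative voxel volumes define the points
$(k\,v_\text{cc},\, d_{(k)})$ and the dose is linearly interpolated within
the voxel where the cumulative volume crosses $x$. This is the standard
planning-system convention; the published definition does not specify an
interpolation rule, and the linear choice makes DxCC continuous in $x$,
with $D_{x\to 0^+} \to D_\text{max}$ and $D_{V_\text{total}}$ equal to the
minimum member dose. Volumes exceeding the structure are reported missing
rather than extrapolated. A binned cumulative DVH (default 0.1 Gy bins) is
available for export and plotting, but indices never pass through the
histogram: curve inversion agrees with the exact index only to within one
bin at voxel-aligned volumes, because a binned curve cannot see within-voxel
interpolation. Relative-volume doses (Dx%) are available as an optional
extra but the pipeline itself uses only Dmax and DxCC.

## The NTCP model

Injury is modelled by multivariate logistic regression,

$$NTCP = \frac{1}{1 + e^{-S}}, \qquad S = \beta_0 + \sum_i \beta_i x_i,$$

fitted by iteratively reweighted least squares with step-halving (the
log-likelihood trace is provably monotone), convergence at a relative
log-likelihood change below $10^{-8}$ (at most 100 iterations), a ridge
fallback ($10^{-6}$) only when the weighted normal equations are singular,
and a complete-separation flag. Model quality is summarised by Nagelkerke's
$R^2$ — the Cox–Snell $R^2 = 1 - e^{2(L_0 - L_1)/n}$ normalised by its
attainable maximum — which is invariant to affine rescaling of predictors.

**Recovery-rate sweep.** Whether the inter-course interval matters is asked
by a grid search: for each candidate rate $a$ (default grid 0 to 0.01 in
steps of $2\times10^{-4}$, which comfortably covers the region where
reported optima fall) the courses are recombined, indices re-extracted, and
the univariate Nagelkerke $R^2$ recorded per index; the per-index optimum is
the grid argmax with ties broken toward the smaller rate, so a flat surface
honestly reports "no recovery needed". The implementation pre-trims each
unit's voxel vectors to a provably sufficient candidate set (the weight is
non-increasing in $a$, so the hottest voxels at any rate are bounded by the
plain sum from above and the maximal-rate combination from below), which
makes the sweep several-fold faster while remaining bit-exact.

**Protocols and selection.** Three clinical scenarios determine the
candidate dosimetric predictors: re-irradiation indices only (first plan
lost), both courses' indices as separate covariates (plans available but not
accumulable), or accumulated-dose indices. Predictors enter by forward
selection on the Wald p-value (threshold 0.05), with at most one dosimetric
index per course: adjacent DxCC values of one smooth dose distribution are
correlated above 0.99, so a second index adds noise, not information. For
the same reason *which* index of the accumulated dose is selected is
essentially arbitrary among its neighbours — a selection-recovery test can
ask that the chosen index carries the true signal, not that it is literally
D1.5cc. Clinical covariates (age, sex, stage, prescriptions, chemotherapy
flags, and optionally the interval itself) can be offered to the same
selection; the default report is dose-only, reflecting that none of them
carries an effect in the generator's ground truth.

**Tolerance doses.** A single-predictor model inverts in closed form,
$TD_p = (\mathrm{logit}(p) - \beta_0)/\beta_1$, so $TD50 = -\beta_0/\beta_1$.
Uncertainty intervals come from a parametric bootstrap: 10,000 draws of
$(\beta_0, \beta_1)$ from the Wald covariance, each inverted, percentiles
2.5/97.5 reported, seeded for reproducibility; draws with non-positive slope
(no defined tolerance dose) are discarded and counted. No method for the
published ranges is stated anywhere we could mirror, so the bootstrap is a
deliberate, documented choice.

## Splitting and validation

Cohorts split 2:1 into training and validation *by patient*, never by lobe,
so paired lobes cannot leak across the split; 78 patients give exactly 52
and 26. Discrimination is summarised by the AUC — the Mann–Whitney
concordance with ties counted ½, computed with a fixed orientation (higher
score = higher risk) so that reversed predictors honestly score below 0.5 —
with DeLong 95% intervals and a DeLong test against AUC = 0.5. The reported
operating point maximises Youden's J over observed score thresholds
(rule: score ≥ cutoff is positive), ties broken toward the higher
specificity; the published tables report an operating point without naming
a criterion, and Youden's J is the standard default.

## The synthetic cohort generator

No patient data accompany the study this package operationalises, so the
generator is a first-class module, not a fixture. Per patient it samples:

* **regimens** — first course 66 Gy/30 fx or 70.4 Gy/32 fx (42%/58%),
  re-irradiation 60–66 Gy in 30–33 fx with the cohort's empirical weights;
* **gap** — log-normal, median 26 months, truncated to 12–108;
* **dose fields** — an isotropic exponential fall-off from a per-course
  hot-spot centre near the skull base (midline for the primary course,
  lateralised 5% of the grid extent toward the recurrence side for the
  re-irradiation course), scaled to the prescription times a hot-spot factor
  (mean 1.10, sd 0.10), fall-off length log-normal around 80 mm, centre
  jitter 4 mm, 3% multiplicative voxel noise;
* **anatomy** — two disjoint ellipsoidal lobes of ≈70 cc on a
  40×40×32 grid at 2.5 mm spacing (the grid is sized so that realistic
  lobe volumes fit with margin; smaller grids cannot hold two lobes of this
  size disjointly);
* **covariates** — sampled from the cohort's empirical frequencies, with no
  true effect on outcome;
* **outcomes** — per-lobe Bernoulli draws from a ground-truth logistic NTCP
  on D1.5cc of the true accumulated dose, by default the plain sum with
  slope 0.067 per Gy and intercept −8.216 (true TD50 ≈ 122.6 Gy EQD2).

The fall-off and hot-spot parameters were calibrated once so that the
accumulated D1.5cc distribution centres near 110 Gy EQD2 with a spread of
about 16 Gy and the mean latent per-lobe injury probability is close to 1/3,
matching the crude incidence scale of the modelled cohort; they are study
conditions, not tuning knobs. Simulation is reproducible: a master seed
derives per-patient seeds, in-mask voxel noise is drawn before out-of-mask
noise, and consequently the cohort table is byte-identical whether or not
full grids are written to disk (grids and masks export as NIfTI, the table
as CSV, with a manifest recording the seeds).

What the generator does *not* emulate: real IMRT dose fields (no beam
structure, no planning constraints — only the index distributions are
matched in scale), registration error, per-voxel fractionation effects, and
any within-patient correlation of lobe outcomes beyond shared dose. The last
point matters: observed TLI is predominantly bilateral, which suggests a
patient-level susceptibility component; adding such a frailty would make the
marginal outcome model non-logistic and would bias slope-recovery checks, so
we deliberately leave it out and note that passing recovery tests therefore
demonstrate correctness of the estimator under its own assumptions, not
robustness to frailty misspecification.

## Numerical and design choices

* **Analysis unit** — per-lobe by default (each lobe contributes its own
  DVH and outcome); a per-patient mode keeps the hotter lobe and defines the
  patient outcome as the OR of lobe outcomes. Published event bookkeeping is
  ambiguous on this; both modes are provided.
* **Problem sizes** — recovery studies in the test-suite run 50 replicates
  of 500-patient cohorts for tolerance-dose recovery and 50 replicates of
  300-patient cohorts for sweep recovery; these sizes give stable medians
  while a full cohort simulates in a few seconds.
* **Sweep identifiability** — with a true linear recovery rate of 0.002 per
  month, the $R^2(a)$ surface is extremely flat: the weight varies by only a
  few percent across realistic gaps, so the argmax has a sampling spread of
  many grid steps even at 300–500 patients. Recovering $a$ to within one
  grid step ($2\times10^{-4}$) in most replicates is therefore not
  achievable at these sample sizes — which is the flip side of the
  substantive finding that time-weighted accumulation barely differs from
  the plain sum. The corresponding acceptance check is kept at its nominal
  strictness and documents this expected failure rather than loosening the
  bar.
* **Ties and degenerate inputs** — empty masks, single-class outcomes,
  mismatched frames and out-of-range volumes all raise early, typed errors;
  AUC ties count ½; sweep fits that fail are recorded as missing, never
  fatal.
* **Bootstrap size** — 10,000 draws for reported tolerance-dose intervals;
  recovery studies use the closed-form point estimate only.

## Worked example

```{r, eval = FALSE}
library(tlntcp)

cfg <- simulation_config(n_patients = 78, seed = 20100)
cohort <- simulate_cohort(cfg)
sp <- split_cohort(cohort, c(2, 1), seed = 20101)

sw <- sweep_time_model(sp$train, "linear")
summary(sw)

m <- build_ntcp(sp$train, protocol = "accumulated")
validate_model(m, sp$validation)

fit <- fit_logistic(
  matrix(sp$train$table$sum_d1_5cc, ncol = 1,
         dimnames = list(NULL, "sum_d1_5cc")),
  sp$train$table$outcome)
tolerance_dose(fit, 0.5, n_boot = 10000, seed = 1)
```

The numbered scripts under `analysis/` run exactly this workflow at study
scale and write every table under `results/`.

## Known limitations

Registration, contouring and MRI diagnosis are upstream of this package and
taken as given. The generator's dose fields are caricatures with the right
index distributions, not plans. Outcome correlation between lobes is
dose-only (see above). Actuarial (time-to-event) injury modelling, LKB/probit
alternatives, gEUD and mean-dose metrics are intentionally out of scope:
the pipeline models binary incidence with a logistic dose response, and the
validation reflects discrimination, not calibration.
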