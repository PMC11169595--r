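small_cfg <- function(...) {
  simulation_config(n_patients = 6, seed = 123, ...)
}

test_that("cohort simulation is reproducible and internally consistent", {
  co1 <- simulate_cohort(small_cfg())
  co2 <- simulate_cohort(small_cfg())
  expect_identical(co1$table, co2$table)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(co1, f1); write_cohort_csv(co2, f2)
  expect_identical(readLines(f1), readLines(f2))

  tab <- co1$table
  expect_equal(nrow(tab), 12)  # two lobes per patient
  expect_true(all(tab$outcome %in% c(0, 1)))
  expect_true(all(tab$gap_months >= 12 & tab$gap_months <= 108))
  # indices ordered: dmax >= d0.5cc >= ... >= d5cc, all non-negative
  cols <- paste0("sum_", c("dmax", "d0_5cc", "d1cc", "d1_5cc", "d2cc",
                           "d2_5cc", "d3cc", "d3_5cc", "d4cc", "d4_5cc",
                           "d5cc"))
  m <- as.matrix(tab[, cols])
  expect_true(all(m >= 0))
  expect_true(all(t(apply(m, 1, diff)) <= 1e-9))
})

test_that("per-lobe doses agree between the fast path and written grids", {
  cfg <- small_cfg()
  co_fast <- simulate_cohort(cfg)
  dir <- tempfile()
  co_disk <- simulate_cohort(cfg, out_dir = dir)
  expect_identical(co_fast$table, co_disk$table)

  # recompute one lobe's index from the written NIfTI artefacts
  g <- read_dose_nifti(file.path(dir, "p001_course2.nii.gz"),
                       n_fractions = 30, frame_id = "frame-sim")
  m <- read_mask_nifti(file.path(dir, "mask_temporal_lobe_L.nii.gz"),
                       name = "temporal_lobe_L", frame_id = "frame-sim")
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  d <- g$values[m$values]
  # physical course-2 dose converted at the recorded fractionation matches
  # the stored EQD2 voxel vector
  row1 <- co_disk$table[1, ]
  cfg_ab <- cfg$alpha_beta
  nfrac <- cfg$course2_regimens$n_fractions[
    match(row1$rt_dose_recurrent, cfg$course2_regimens$dose_gy)]
  eq <- d * (d / nfrac + cfg_ab) / (2 + cfg_ab)
  expect_equal(sort(eq), sort(co_disk$dose[[1]]$d2), tolerance = 1e-6)
})

test_that("dose pairs respect limiting cases and scaling", {
  # no noise, infinite decay length: every voxel equals the peak
  cfg <- simulation_config(n_patients = 1, seed = 5, noise_sd = 0,
                           hotspot_decay_mm = Inf, hotspot_peak_sd = 0)
  pair <- simulate_dose_pair(cfg, seed = 9)
  v <- pair$course1$values
  expect_equal(max(v) - min(v), 0, tolerance = 1e-9)
  expect_equal(max(v), pair$params$peak1, tolerance = 1e-9)

  # doubling the prescriptions doubles every voxel dose
  cfg1 <- simulation_config(n_patients = 1, seed = 5)
  cfg2 <- simulation_config(
    n_patients = 1, seed = 5,
    course1_regimens = transform(cfg1$course1_regimens, dose_gy = 2 * dose_gy),
    course2_regimens = transform(cfg1$course2_regimens, dose_gy = 2 * dose_gy))
  p1 <- simulate_dose_pair(cfg1, seed = 4)
  p2 <- simulate_dose_pair(cfg2, seed = 4)
  expect_equal(p2$course1$values, 2 * p1$course1$values, tolerance = 1e-12)
  expect_equal(p2$course2$values, 2 * p1$course2$values, tolerance = 1e-12)

  # masks are disjoint, non-trivial, and D1.5cc lies within the lobe range
  expect_equal(sum(p1$masks$L$values & p1$masks$R$values), 0)
  vol <- voxel_volume_cc(p1$masks$L) * sum(p1$masks$L$values)
  expect_gt(vol, 40); expect_lt(vol, 120)
  e2 <- eqd2_convert(p1$course2, 3)
  d15 <- dose_at_volume(e2, p1$masks$L, 1.5)
  dl <- e2$values[p1$masks$L$values]
  expect_gte(d15, min(dl)); expect_lte(d15, max(dl))
})

test_that("outcome frequencies follow the latent ground-truth probabilities", {
  # dose-independent outcomes when the slope is zero
  cfg <- simulation_config(n_patients = 250, true_beta1 = 0,
                           true_beta0 = qlogis(0.3), seed = 31)
  co <- simulate_cohort(cfg)
  inc <- mean(co$table$outcome)
  se <- sqrt(0.3 * 0.7 / nrow(co$table))
  expect_lt(abs(inc - 0.3), 4 * se)
  expect_equal(unique(co$table$latent_p), 0.3, tolerance = 1e-12)

  # with the default ground truth, empirical incidence tracks the mean
  # latent probability within binomial error
  cfg2 <- simulation_config(n_patients = 400, seed = 32)
  co2 <- simulate_cohort(cfg2)
  p <- mean(co2$table$latent_p)
  se2 <- sqrt(p * (1 - p) / nrow(co2$table))
  expect_lt(abs(mean(co2$table$outcome) - p), 4 * se2)
  # and the calibrated defaults put the incidence in the vicinity of 1/3
  expect_gt(mean(co2$table$outcome), 0.2)
  expect_lt(mean(co2$table$outcome), 0.47)
})

test_that("configs are validated before any simulation runs", {
  expect_error(simulation_config(lobe_semiaxes_mm = c(60, 60, 60)),
               "too small")
  expect_error(simulation_config(n_patients = 0), "n_patients")
  expect_error(simulation_config(alpha_beta = 0), "alpha_beta")
})
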