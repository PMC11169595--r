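test_that("EQD2 conversion reproduces linear-quadratic hand values", {
  # 2 Gy per fraction is the fixed point of the transform
  g <- dose_grid(array(60, c(2, 2, 2)), c(2, 2, 2), n_fractions = 30)
  e <- eqd2_convert(g, alpha_beta = 3)
  expect_equal(e$values, g$values, tolerance = 1e-15)
  expect_equal(e$alpha_beta, 3)

  # 70.4 Gy in 32 fractions (d = 2.2 Gy) at alpha/beta = 3
  g2 <- dose_grid(array(70.4, c(1, 1, 1)), c(1, 1, 1), n_fractions = 32)
  expect_equal(as.numeric(eqd2_convert(g2, 3)$values), 70.4 * (2.2 + 3) / 5)
  expect_equal(as.numeric(eqd2_convert(g2, 3)$values), 73.216)

  # zero dose maps to zero
  g0 <- dose_grid(array(0, c(2, 2, 2)), c(1, 1, 1), n_fractions = 10)
  expect_true(all(eqd2_convert(g0, 3)$values == 0))
})

test_that("EQD2 is monotone in dose and validates its inputs", {
  withr_seed(7)
  for (r in 1:5) {
    v <- array(runif(27, 0, 70), c(3, 3, 3))
    inc <- array(runif(27, 0.1, 5), c(3, 3, 3))
    lo <- eqd2_convert(dose_grid(v, c(2, 2, 2), 30), 3)$values
    hi <- eqd2_convert(dose_grid(v + inc, c(2, 2, 2), 30), 3)$values
    expect_true(all(hi > lo))
  }
  g <- dose_grid(array(10, c(1, 1, 1)), c(1, 1, 1), 5)
  expect_error(eqd2_convert(g, 0), "alpha_beta")
  expect_error(eqd2_convert(g, -3), "alpha_beta")
  expect_error(dose_grid(array(10, c(1, 1, 1)), c(1, 1, 1), 0), "n_fractions")
  expect_error(dose_grid(array(-1, c(1, 1, 1)), c(1, 1, 1), 5), "non-negative")
})

test_that("time-model weights decay with the gap and stay in [0, 1]", {
  gaps <- seq(0, 120, by = 4)
  for (kind in c("linear", "quadratic", "exponential")) {
    w <- course1_weight(time_model(kind, 0.002), gaps)
    expect_true(all(diff(w) <= 0), info = kind)
    expect_true(all(w >= 0 & w <= 1), info = kind)
  }
  # no-recovery model and a = 0 give weight 1
  expect_equal(course1_weight(time_model("none"), gaps), rep(1, length(gaps)))
  expect_equal(course1_weight(time_model("linear", 0), gaps),
               rep(1, length(gaps)))
  # linear weight clamps at zero instead of going negative
  expect_equal(course1_weight(time_model("linear", 0.05), 100), 0)
  expect_error(time_model("linear", -1), "non-negative")
})

test_that("dose combination matches hand evaluation and its bounds", {
  mk <- function(x) eqd2_grid(array(x, c(1, 1, 1)), c(1, 1, 1), "f", 3)
  # linear model, a = 0.0022 at a 26-month gap: (1 - 0.0572)*50 + 60
  out <- combine_doses(mk(50), mk(60), time_model("linear", 0.0022), 26)
  expect_equal(as.numeric(out$values), (1 - 0.0022 * 26) * 50 + 60)
  expect_equal(as.numeric(out$values), 107.14)

  # a = 0 reduces to the plain voxel sum; huge exponential rate leaves course 2
  expect_equal(combine_doses(mk(50), mk(60), time_model("linear", 0), 26)$values,
               sum_plain(mk(50), mk(60))$values)
  expect_equal(
    as.numeric(combine_doses(mk(50), mk(60),
                             time_model("exponential", 1e6), 26)$values),
    60)

  withr_seed(11)
  a <- eqd2_grid(array(runif(27, 0, 60), c(3, 3, 3)), c(2, 2, 2), "f", 3)
  b <- eqd2_grid(array(runif(27, 0, 60), c(3, 3, 3)), c(2, 2, 2), "f", 3)
  for (kind in c("linear", "quadratic", "exponential")) {
    comb <- combine_doses(a, b, time_model(kind, 0.003), 40)$values
    expect_true(all(comb >= b$values - 1e-12))                # weight >= 0
    expect_true(all(comb <= sum_plain(a, b)$values + 1e-12))  # weight <= 1
  }
})

test_that("plain summation is symmetric with an additive identity", {
  withr_seed(3)
  a <- eqd2_grid(array(runif(8, 0, 50), c(2, 2, 2)), c(2, 2, 2), "f", 3)
  b <- eqd2_grid(array(runif(8, 0, 50), c(2, 2, 2)), c(2, 2, 2), "f", 3)
  zero <- eqd2_grid(array(0, c(2, 2, 2)), c(2, 2, 2), "f", 3)
  expect_equal(sum_plain(a, b)$values, sum_plain(b, a)$values)
  expect_equal(sum_plain(a, zero)$values, a$values)
})

test_that("grids on different frames or geometries refuse to combine", {
  a <- eqd2_grid(array(1, c(2, 2, 2)), c(2, 2, 2), "f1", 3)
  b <- eqd2_grid(array(1, c(2, 2, 2)), c(2, 2, 2), "f2", 3)
  expect_error(sum_plain(a, b), "frames")
  c3 <- eqd2_grid(array(1, c(3, 2, 2)), c(2, 2, 2), "f1", 3)
  expect_error(sum_plain(a, c3), "shapes")
  d <- eqd2_grid(array(1, c(2, 2, 2)), c(1, 2, 2), "f1", 3)
  expect_error(sum_plain(a, d), "spacing")
  e <- eqd2_grid(array(1, c(2, 2, 2)), c(2, 2, 2), "f1", alpha_beta = 2)
  expect_error(sum_plain(a, e), "alpha/beta")
})

test_that("dose grids and masks round-trip through NIfTI", {
  withr_seed(5)
  g <- dose_grid(array(runif(60, 0, 70), c(5, 4, 3)), c(2.5, 2.5, 3), 30, "f")
  path <- tempfile(fileext = ".nii.gz")
  write_dose_nifti(g, path)
  back <- read_dose_nifti(path, n_fractions = 30, frame_id = "f")
  expect_equal(back$values, g$values, tolerance = 1e-6)
  expect_equal(back$spacing, g$spacing, tolerance = 1e-6)

  m <- structure_mask(array(runif(60) < 0.5, c(5, 4, 3)) | TRUE,
                      c(2.5, 2.5, 3), "f", "lobe")
  mpath <- tempfile(fileext = ".nii.gz")
  write_mask_nifti(m, mpath)
  mback <- read_mask_nifti(mpath, name = "lobe", frame_id = "f")
  expect_identical(mback$values, m$values)
})
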