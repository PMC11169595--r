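# Fixtures are generated in code; nothing is read from disk.

# random EQD2 grid plus an irregular mask on the same frame
random_grid_mask <- function(dim = c(6, 6, 6), spacing = c(4, 5, 5),
                             seed = 1, frame = "t") {
  withr_seed(seed)
  vals <- array(runif(prod(dim), 0, 80), dim)
  m <- array(runif(prod(dim)) < 0.4, dim)
  if (!any(m)) m[1] <- TRUE
  list(grid = eqd2_grid(vals, spacing, frame_id = frame),
       mask = structure_mask(m, spacing, frame_id = frame, name = "s"))
}

# local set.seed that does not leak into other tests
withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  invisible(old)
}

# Independent DxCC oracle: descending sort, cumulative volumes, base-R
# interpolation through the (volume, dose) points.
oracle_dxcc <- function(doses, voxel_cc, x) {
  sdv <- sort(doses, decreasing = TRUE)
  cv <- voxel_cc * seq_along(sdv)
  stats::approx(x = c(0, cv), y = c(sdv[1], sdv), xout = x, ties = "ordered")$y
}

# Brute-force Mann-Whitney AUC: all positive x negative pairs, ties count 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Brute-force Youden search over all observed thresholds
oracle_youden <- function(scores, labels) {
  thr <- sort(unique(scores))
  best <- NULL
  for (t in thr) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec)) {
      best <- list(cutoff = t, j = j, sens = sens, spec = spec)
    }
  }
  best
}

# Fabricated small cohort with voxel dose vectors, for sweep/build tests.
# Outcomes follow a logistic ground truth on D1.5cc of the accumulated dose.
make_toy_cohort <- function(n_units = 80, n_vox = 60, voxel_cc = 0.25,
                            seed = 1, kind = "none", a = 0,
                            beta0 = -8.216, beta1 = 0.067,
                            gaps = NULL) {
  withr_seed(seed)
  dose <- vector("list", n_units)
  gap <- if (is.null(gaps)) runif(n_units, 12, 108) else rep(gaps, length.out = n_units)
  rows <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    base1 <- runif(1, 30, 60)
    base2 <- runif(1, 40, 70)
    d1 <- base1 * exp(rnorm(n_vox, 0, 0.15))
    d2 <- base2 * exp(rnorm(n_vox, 0, 0.15))
    dose[[i]] <- list(d1 = d1, d2 = d2)
    w <- course1_weight(time_model(kind, a), gap[i])
    x <- tlntcp:::indices_from_doses(w * d1 + d2, voxel_cc, 1.5)$d_cc[[1]]
    p <- plogis(beta0 + beta1 * x)
    idx <- function(v) tlntcp:::indices_from_doses(v, voxel_cc)
    row <- data.frame(unit_id = sprintf("u%03d", i),
                      patient_id = sprintf("p%03d", ceiling(i / 2)),
                      gap_months = gap[i], outcome = rbinom(1, 1, p))
    add <- function(row, prefix, ix) {
      row[[paste0(prefix, "_dmax")]] <- ix$dmax
      for (v in names(ix$d_cc)) {
        row[[gsub(".", "_", paste0(prefix, "_d", v, "cc"), fixed = TRUE)]] <-
          ix$d_cc[[v]]
      }
      row
    }
    row <- add(row, "crs1", idx(d1))
    row <- add(row, "crs2", idx(d2))
    row <- add(row, "sum", idx(d1 + d2))
    rows[[i]] <- row
  }
  tl_cohort(do.call(rbind, rows), dose = dose, voxel_cc = voxel_cc)
}

# a fitted-like model object with chosen coefficients, for identity checks
fake_model <- function(b0 = -8.216, b1 = 0.067, name = "sum_d1_5cc") {
  withr_seed(77)
  x <- rnorm(300, -b0 / b1, 18)
  y <- rbinom(300, 1, plogis(b0 + b1 * x))
  fit <- fit_logistic(matrix(x, ncol = 1, dimnames = list(NULL, name)), y)
  fit$coefficients <- stats::setNames(c(b0, b1), c("(Intercept)", name))
  fit
}

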