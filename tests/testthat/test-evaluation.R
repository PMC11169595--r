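test_that("patient-level splitting gives the documented sizes", {
  tab <- data.frame(unit_id = sprintf("u%d", 1:78),
                    patient_id = sprintf("p%d", 1:78),
                    gap_months = 20, outcome = rep(c(0, 1), 39))
  sp <- split_cohort(tab, ratio = c(2, 1), seed = 3)
  expect_equal(nrow(sp$train), 52)
  expect_equal(nrow(sp$validation), 26)

  small <- tab[1:3, ]
  sp3 <- split_cohort(small, c(2, 1), seed = 1)
  expect_equal(nrow(sp3$train), 2)
  expect_equal(nrow(sp3$validation), 1)
})

test_that("splits are deterministic, disjoint and exhaustive", {
  co <- make_toy_cohort(n_units = 60, seed = 8)  # two lobes per patient
  s1 <- split_cohort(co, seed = 42)
  s2 <- split_cohort(co, seed = 42)
  expect_identical(s1$train$table$unit_id, s2$train$table$unit_id)
  got <- sort(c(s1$train$table$unit_id, s1$validation$table$unit_id))
  expect_identical(got, sort(co$table$unit_id))
  # paired lobes stay on one side of the split
  expect_length(intersect(s1$train$table$patient_id,
                          s1$validation$table$patient_id), 0)
  expect_error(split_cohort(co$table[0, ]), "empty")
  expect_error(split_cohort(co, ratio = c(2, 0)), "positive")
})

test_that("AUC equals brute-force pairwise concordance", {
  withr_seed(31)
  for (r in 1:20) {
    n <- 20
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- rnorm(n)
    if (r %% 4 == 0) scores <- round(scores, 1)  # induce ties
    res <- auc_with_ci(scores, labels)
    expect_equal(res$auc, oracle_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC limiting cases and orientation identities hold", {
  labels <- c(0, 0, 0, 1, 1)
  expect_equal(auc_with_ci(labels, labels)$auc, 1)
  expect_equal(auc_with_ci(rep(1, 5), labels)$auc, 0.5)
  withr_seed(17)
  scores <- rnorm(30)
  labels <- rbinom(30, 1, 0.5)
  labels[1:2] <- c(0, 1)
  expect_equal(auc_with_ci(scores, labels)$auc +
                 auc_with_ci(-scores, labels)$auc, 1, tolerance = 1e-12)
  expect_error(auc_with_ci(scores, rep(1, 30)), "both classes")
})

test_that("DeLong intervals tighten as the sample grows", {
  width <- vapply(c(50, 500), function(n) {
    withr_seed(n)
    x <- rnorm(n, 0, 1)
    y <- rbinom(n, 1, plogis(1.5 * x))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    r <- auc_with_ci(x, y)
    r$ci_high - r$ci_low
  }, numeric(1))
  expect_lt(width[2], width[1])
})

test_that("Youden cutoffs match exhaustive threshold search", {
  withr_seed(13)
  for (r in 1:10) {
    n <- 25
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(rnorm(n), 1)
    got <- youden_cutoff(scores, labels)
    want <- oracle_youden(scores, labels)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$sensitivity, 100 * want$sens)
    expect_equal(got$specificity, 100 * want$spec)
  }
  # perfect separation scores
  perfect <- youden_cutoff(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$cutoff, 10)  # the single lowest positive score
})

test_that("validation scores rank identically under probability or S", {
  co <- make_toy_cohort(n_units = 120, seed = 14)
  sp <- split_cohort(co, seed = 2)
  m <- suppressWarnings(build_ntcp(sp$train, protocol = "accumulated"))
  res <- validate_model(m, sp$validation)
  expect_gte(res$auc, 0)
  tab <- sp$validation$table
  s_auc <- auc_with_ci(linear_score(m, tab[, m$terms, drop = FALSE]),
                       tab$outcome)$auc
  expect_equal(res$auc, s_auc, tolerance = 1e-12)
  # training-set concordance of a fitted model is at least chance
  tr <- validate_model(m, sp$train)
  expect_gte(tr$auc, 0.5)
  expect_error(validate_model(m, co$table[, 1:4]), "lacks predictor")
  expect_s3_class(attr(res, "curve"), "data.frame")
})

test_that("strong true effects yield high held-out AUC", {
  # effect size beta1 * sd(dose) ~ 3
  wins <- 0
  for (s in 1:10) {
    withr_seed(400 + s)
    x_tr <- rnorm(200, 100, 15)
    y_tr <- rbinom(200, 1, plogis(0.2 * (x_tr - 100)))
    x_va <- rnorm(100, 100, 15)
    y_va <- rbinom(100, 1, plogis(0.2 * (x_va - 100)))
    if (length(unique(y_tr)) < 2 || length(unique(y_va)) < 2) next
    fit <- fit_logistic(matrix(x_tr, ncol = 1, dimnames = list(NULL, "d")),
                        y_tr)
    auc <- auc_with_ci(ntcp_probability(fit, data.frame(d = x_va)),
                       y_va)$auc
    wins <- wins + (auc > 0.85)
  }
  expect_gte(wins, 9)
})
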