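#' Random training/validation split by patient
#'
#' Shuffles patients (never individual lobes, so paired lobes of one patient
#' cannot leak across the split) and allocates the first
#' `round(n * r_t / (r_t + r_v))` to training. The partition is disjoint,
#' exhaustive and reproducible under the seed.
#'
#' @param cohort A `tl_cohort` or data frame with a `patient_id` column.
#' @param ratio Two positive numbers, training:validation (default 2:1).
#' @param seed RNG seed for the shuffle.
#' @return List with elements `train` and `validation` of the same kind as
#'   `cohort`.
#' @export
split_cohort <- function(cohort, ratio = c(2, 1), seed = 1L) {
  tab <- cohort_table(cohort)
  if (!nrow(tab)) stop("empty cohort", call. = FALSE)
  if (length(ratio) != 2L || any(ratio <= 0)) {
    stop("`ratio` must be two positive numbers", call. = FALSE)
  }
  patients <- unique(tab$patient_id)
  n <- length(patients)
  n_train <- round(n * ratio[1] / sum(ratio))
  shuffled <- with_seed(seed, sample(patients))
  train_ids <- shuffled[seq_len(n_train)]
  in_train <- tab$patient_id %in% train_ids
  list(train = cohort_subset(cohort, which(in_train)),
       validation = cohort_subset(cohort, which(!in_train)))
}

#' AUC with DeLong confidence interval and operating point
#'
#' The area under the ROC curve equals the Mann–Whitney concordance
#' probability (ties counted 1/2), computed with a fixed orientation: higher
#' scores indicate the positive class. The 95\% confidence interval and the
#' p-value against AUC = 0.5 use DeLong's method, and the reported operating
#' point maximises Youden's J (see [youden_cutoff()]).
#'
#' @param scores Numeric risk scores (probabilities or linear predictors —
#'   the AUC is rank-invariant).
#' @param labels Binary 0/1 outcomes, both classes present.
#' @return A `roc_result`: `auc`, `ci_low`, `ci_high`, `p_value`, `cutoff`,
#'   `sensitivity` (\%), `specificity` (\%), `n_pos`, `n_neg`.
#' @export
auc_with_ci <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L) {
    stop("labels must contain both classes", call. = FALSE)
  }
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  v <- suppressWarnings(pROC::var(r, method = "delong"))
  p_value <- if (is.finite(v) && v > 0) {
    2 * stats::pnorm(-abs(auc - 0.5) / sqrt(v))
  } else if (auc == 0.5) 1 else 0
  yc <- youden_cutoff(scores, labels)
  structure(
    list(auc = auc, ci_low = ci[1], ci_high = ci[3], p_value = p_value,
         cutoff = yc$cutoff, sensitivity = yc$sensitivity,
         specificity = yc$specificity,
         n_pos = sum(labels == 1), n_neg = sum(labels == 0)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.4f (%.4f–%.4f), p = %.3g | cutoff %.4g: sens %.1f%%, spec %.1f%% (%d+/%d-)\n",
              x$auc, x$ci_low, x$ci_high, x$p_value, x$cutoff,
              x$sensitivity, x$specificity, x$n_pos, x$n_neg))
  invisible(x)
}

#' Operating point maximising Youden's J
#'
#' Searches all observed score values as candidate cutoffs under the rule
#' "score >= cutoff is called positive" and maximises
#' sensitivity + specificity − 1. Ties are broken toward the higher
#' specificity (and then the higher cutoff).
#'
#' @inheritParams auc_with_ci
#' @return List with `cutoff`, `sensitivity` (\%) and `specificity` (\%).
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L) {
    stop("labels must contain both classes", call. = FALSE)
  }
  thr <- sort(unique(scores))
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[order(spec[best], thr[best], decreasing = TRUE)][1]
  list(cutoff = thr[best], sensitivity = 100 * sens[best],
       specificity = 100 * spec[best])
}

#' ROC curve points for export
#'
#' @inheritParams auc_with_ci
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.numeric(labels)
  thr <- c(-Inf, sort(unique(scores)), Inf)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(neg >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(pos >= t), numeric(1))
  )
}

#' Validate a fitted NTCP model on held-out units
#'
#' Scores every validation unit with [ntcp_probability()] and summarises
#' discrimination with [auc_with_ci()]; the ROC curve points are attached as
#' attribute `"curve"`.
#'
#' @param model An `ntcp_logistic` fitted on training data only.
#' @param cohort Validation `tl_cohort` or table containing every model
#'   predictor column.
#' @return A `roc_result` with attribute `curve`.
#' @export
validate_model <- function(model, cohort) {
  tab <- cohort_table(cohort)
  missing <- setdiff(model$terms, names(tab))
  if (length(missing)) {
    stop("validation cohort lacks predictor column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  scores <- ntcp_probability(model, tab[, model$terms, drop = FALSE])
  res <- auc_with_ci(scores, tab$outcome)
  attr(res, "curve") <- roc_points(scores, tab$outcome)
  res
}

#' @export
as.data.frame.roc_result <- function(x, ...) {
  data.frame(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
             p_value = x$p_value, cutoff = x$cutoff,
             sensitivity = x$sensitivity, specificity = x$specificity,
             n_pos = x$n_pos, n_neg = x$n_neg)
}
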