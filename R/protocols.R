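#' Build a multivariate NTCP model under a data-availability protocol
#'
#' Three clinical scenarios determine which dosimetric predictors are on the
#' table:
#' \describe{
#'   \item{`"reRT_only"`}{the first-course plan is unavailable; only
#'     re-irradiation (`crs2_`) indices are candidates;}
#'   \item{`"both_courses_separate"`}{both plans exist but cannot be
#'     accumulated; first- (`crs1_`) and second-course (`crs2_`) indices enter
#'     as separate covariates;}
#'   \item{`"accumulated"`}{the voxel-wise accumulated EQD2 (`sum_`) indices
#'     are candidates.}
#' }
#' Predictors are chosen by forward selection on the Wald p-value of the
#' entering term (entry threshold `entry_p`), retaining at most one
#' dosimetric index per course — adjacent DxCC indices of one distribution
#' are near-collinear, so allowing two would destabilise the fit. Clinical
#' covariates can optionally be offered to the same selection.
#'
#' @param cohort A `tl_cohort` or cohort table with index columns.
#' @param protocol One of `"accumulated"`, `"reRT_only"`,
#'   `"both_courses_separate"`.
#' @param include_clinical Offer clinical covariates to the selection?
#' @param clinical Clinical covariate column names considered when
#'   `include_clinical` is `TRUE`.
#' @param entry_p Wald p-value entry threshold for forward selection.
#' @return An `ntcp_logistic` fitted on the selected predictors, with
#'   `protocol` and `selection` (the entry order) attached. If no candidate
#'   passes the threshold an intercept-only model is returned with a warning.
#' @export
build_ntcp <- function(cohort,
                       protocol = c("accumulated", "reRT_only",
                                    "both_courses_separate"),
                       include_clinical = FALSE,
                       clinical = c("age", "gender_male", "gap_months",
                                    "t_primary", "n_primary", "t_recurrent",
                                    "n_recurrent", "rt_dose_primary",
                                    "rt_dose_recurrent", "induction_chemo",
                                    "concurrent_chemo"),
                       entry_p = 0.05) {
  protocol <- match.arg(protocol)
  tab <- cohort_table(cohort)
  y <- tab$outcome

  groups <- switch(protocol,
    reRT_only = list(crs2 = grep("^crs2_", names(tab), value = TRUE)),
    both_courses_separate = list(
      crs2 = grep("^crs2_", names(tab), value = TRUE),
      crs1 = grep("^crs1_", names(tab), value = TRUE)),
    accumulated = list(sum = grep("^sum_", names(tab), value = TRUE))
  )
  if (!all(lengths(groups) > 0)) {
    stop("cohort table lacks the index columns required by protocol '",
         protocol, "'", call. = FALSE)
  }
  if (include_clinical) {
    clin <- intersect(clinical, names(tab))
    groups <- c(groups, stats::setNames(as.list(clin), clin))
  }

  selected <- character(0)
  used_groups <- character(0)
  repeat {
    open <- unlist(groups[setdiff(names(groups), used_groups)],
                   use.names = FALSE)
    open <- setdiff(open, selected)
    if (!length(open)) break
    pvals <- vapply(open, function(cand) {
      cols <- c(selected, cand)
      fit <- tryCatch(
        suppressWarnings(fit_logistic(tab[, cols, drop = FALSE], y)),
        error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      fit$wald$p[match(cand, fit$wald$term)]
    }, numeric(1))
    if (all(is.na(pvals)) || min(pvals, na.rm = TRUE) >= entry_p) break
    best <- open[which.min(pvals)]
    selected <- c(selected, best)
    grp <- names(groups)[vapply(groups, function(g) best %in% g, logical(1))]
    used_groups <- c(used_groups, grp)
  }

  if (!length(selected)) {
    warning("no predictor passed the entry threshold; ",
            "returning an intercept-only model", call. = FALSE)
    fit <- fit_logistic(NULL, y)
  } else {
    fit <- fit_logistic(tab[, selected, drop = FALSE], y)
  }
  fit$protocol <- protocol
  fit$selection <- selected
  fit
}

#' Table-4-style report of a fitted NTCP model
#'
#' One row per model term with the Wald statistic, p-value, 95\% odds-ratio
#' confidence interval, the regression function in S-form and Nagelkerke R².
#'
#' @param model An `ntcp_logistic`.
#' @return A data frame.
#' @export
model_report <- function(model) {
  stopifnot(inherits(model, "ntcp_logistic"))
  tab <- model$wald[model$wald$term != "(Intercept)", , drop = FALSE]
  data.frame(
    protocol = model$protocol %||% NA_character_,
    term = tab$term,
    p_value = tab$p,
    wald = tab$wald,
    or_ci_95 = sprintf("%.3f–%.3f", tab$or_low, tab$or_high),
    regression_function = s_form(model),
    nagelkerke_r2 = model$nagelkerke_r2,
    row.names = NULL
  )
}
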