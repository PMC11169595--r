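#' Cohort container for the NTCP analysis
#'
#' A `tl_cohort` bundles the per-analysis-unit table (one row per temporal
#' lobe by default) with, optionally, the raw in-mask EQD2 voxel dose vectors
#' of both courses, which the time-model sweep needs in order to recombine
#' doses at arbitrary recovery rates.
#'
#' The table carries, per unit: identifiers (`unit_id`, `patient_id`,
#' `lobe`), the inter-course `gap_months`, clinical covariates, the binary
#' `outcome`, and dosimetric index columns named
#' `<course>_<index>` where course is `crs1` (deformed first-course EQD2),
#' `crs2` (re-irradiation EQD2) or `sum` (plain voxel-wise accumulated EQD2)
#' and index is `dmax`, `d0_5cc`, ..., `d5cc`.
#'
#' @param table Data frame as described above.
#' @param dose Optional list (one element per table row) of
#'   `list(d1 =, d2 =)` in-mask EQD2 voxel dose vectors.
#' @param voxel_cc Voxel volume in cc for the dose vectors.
#' @param config Optional simulation/analysis configuration to carry along.
#' @return A `tl_cohort` object.
#' @export
tl_cohort <- function(table, dose = NULL, voxel_cc = NULL, config = NULL) {
  stopifnot(is.data.frame(table))
  req <- c("unit_id", "patient_id", "gap_months", "outcome")
  missing <- setdiff(req, names(table))
  if (length(missing)) {
    stop("cohort table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(table$outcome %in% c(0, 1))) {
    stop("`outcome` must be binary 0/1", call. = FALSE)
  }
  if (any(table$gap_months < 0)) {
    stop("`gap_months` must be non-negative", call. = FALSE)
  }
  if (!is.null(dose) && length(dose) != nrow(table)) {
    stop("`dose` must have one element per table row", call. = FALSE)
  }
  structure(list(table = table, dose = dose, voxel_cc = voxel_cc,
                 config = config),
            class = "tl_cohort")
}

# accept either a tl_cohort or a bare table
cohort_table <- function(cohort) {
  if (inherits(cohort, "tl_cohort")) cohort$table else as.data.frame(cohort)
}

# row subset preserving dose vectors
cohort_subset <- function(cohort, rows) {
  if (!inherits(cohort, "tl_cohort")) {
    return(as.data.frame(cohort)[rows, , drop = FALSE])
  }
  tl_cohort(cohort$table[rows, , drop = FALSE],
            dose = if (!is.null(cohort$dose)) cohort$dose[rows],
            voxel_cc = cohort$voxel_cc, config = cohort$config)
}

#' @export
print.tl_cohort <- function(x, ...) {
  tab <- x$table
  cat(sprintf("<tl_cohort> %d units, %d patients, %d events (%.1f%%)%s\n",
              nrow(tab), length(unique(tab$patient_id)), sum(tab$outcome),
              100 * mean(tab$outcome),
              if (is.null(x$dose)) "" else ", voxel doses attached"))
  invisible(x)
}

#' Reduce a per-lobe cohort to one record per patient
#'
#' Keeps, for each patient, the hotter lobe as measured by `by` (an index
#' column of the table), and defines the patient outcome as the OR of the
#' lobe outcomes (a patient is injured if either lobe is).
#'
#' @param cohort A `tl_cohort` or cohort table with two rows per patient.
#' @param by Column used to pick the hotter lobe.
#' @return An object of the same kind with one row per patient.
#' @export
cohort_per_patient <- function(cohort, by = "sum_d1_5cc") {
  tab <- cohort_table(cohort)
  if (!by %in% names(tab)) stop("no column '", by, "' in cohort", call. = FALSE)
  keep <- unlist(lapply(split(seq_len(nrow(tab)), tab$patient_id),
                        function(i) i[which.max(tab[[by]][i])]))
  keep <- sort(unname(keep))
  out <- cohort_subset(cohort, keep)
  pat_out <- tapply(tab$outcome, tab$patient_id, max)
  if (inherits(out, "tl_cohort")) {
    out$table$outcome <- as.numeric(pat_out[as.character(out$table$patient_id)])
    out
  } else {
    out$outcome <- as.numeric(pat_out[as.character(out$patient_id)])
    out
  }
}

#' Write a cohort table as CSV
#'
#' @param cohort A `tl_cohort` or data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort_table(cohort), path, row.names = FALSE)
  invisible(path)
}
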