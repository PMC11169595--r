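#' Time-interval recovery model for two-course dose accumulation
#'
#' Normal tissue partially recovers from the first radiotherapy course as the
#' interval to re-irradiation grows. A time model down-weights the first
#' course's voxel dose by a factor that decays with the gap (in months)
#' between the two courses:
#' \describe{
#'   \item{`none`}{weight = 1 (plain voxel-wise EQD2 sum);}
#'   \item{`linear`}{weight = 1 − a·gap;}
#'   \item{`quadratic`}{weight = 1 − a·gap²;}
#'   \item{`exponential`}{weight = exp(−a·gap).}
#' }
#' Weights are clamped to \[0, 1\]: a negative first-course contribution is
#' unphysical, so large a·gap products reduce to "course 2 only".
#'
#' @param kind One of `"none"`, `"linear"`, `"quadratic"`, `"exponential"`.
#' @param a Non-negative recovery-rate parameter (per month for linear and
#'   exponential, per month squared for quadratic). Ignored when
#'   `kind = "none"`.
#' @return An object of class `time_model`.
#' @export
#' @examples
#' course1_weight(time_model("linear", 0.0022), gap_months = 26)
time_model <- function(kind = c("none", "linear", "quadratic", "exponential"),
                       a = 0) {
  kind <- match.arg(kind)
  if (length(a) != 1L || !is.finite(a) || a < 0) {
    stop("recovery rate `a` must be a single non-negative number", call. = FALSE)
  }
  structure(list(kind = kind, a = a), class = "time_model")
}

#' First-course weight implied by a time model
#'
#' @param model A [time_model()].
#' @param gap_months Non-negative interval(s) between the two courses (months).
#' @return Weight(s) in \[0, 1\] applied to the first course's dose.
#' @export
course1_weight <- function(model, gap_months) {
  stopifnot(inherits(model, "time_model"))
  if (any(!is.finite(gap_months)) || any(gap_months < 0)) {
    stop("`gap_months` must be non-negative", call. = FALSE)
  }
  w <- switch(model$kind,
    none        = rep(1, length(gap_months)),
    linear      = 1 - model$a * gap_months,
    quadratic   = 1 - model$a * gap_months^2,
    exponential = exp(-model$a * gap_months)
  )
  clamp01(w)
}

#' Combine two EQD2 course grids voxel-wise
#'
#' Accumulates a (deformed) first-course EQD2 grid and a second-course EQD2
#' grid on the shared registration frame as
#' `w * course1 + course2`, where `w` is the first-course weight of the time
#' model at the given inter-course gap. With `kind = "none"` (or `a = 0`) this
#' is the plain voxel-wise EQD2 sum.
#'
#' @param course1 `eqd2_grid` of the first course, deformed onto the second
#'   course's frame.
#' @param course2 `eqd2_grid` of the re-irradiation course.
#' @param model A [time_model()].
#' @param gap_months Interval between the two courses (months), scalar.
#' @return An `eqd2_grid` of accumulated dose.
#' @export
combine_doses <- function(course1, course2, model = time_model("none"),
                          gap_months = 0) {
  stopifnot(inherits(course1, "eqd2_grid"), inherits(course2, "eqd2_grid"))
  check_combinable(course1, course2)
  if (length(gap_months) != 1L) {
    stop("`gap_months` must be a scalar for grid combination", call. = FALSE)
  }
  w <- course1_weight(model, gap_months)
  new_eqd2_grid(w * course1$values + course2$values,
                course1$spacing, course1$frame_id, course1$alpha_beta)
}

#' Plain voxel-wise EQD2 sum of two courses
#'
#' @inheritParams combine_doses
#' @return An `eqd2_grid`; identical to [combine_doses()] with
#'   `time_model("none")`.
#' @export
sum_plain <- function(course1, course2) {
  combine_doses(course1, course2, time_model("none"), 0)
}
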