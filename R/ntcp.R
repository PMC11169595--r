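#' Linear predictor and complication probability of an NTCP model
#'
#' `linear_score` evaluates \eqn{S = \beta_0 + \sum_i \beta_i x_i};
#' `ntcp_probability` maps it through the logistic function
#' \eqn{1 / (1 + e^{-S})}.
#'
#' @param model An `ntcp_logistic` from [fit_logistic()] or [build_ntcp()].
#' @param newdata Data frame (or named vector) supplying a value for every
#'   model predictor.
#' @return Numeric vector of scores / probabilities, one per row of `newdata`.
#' @export
linear_score <- function(model, newdata) {
  stopifnot(inherits(model, "ntcp_logistic"))
  b <- model$coefficients
  terms <- model$terms
  if (!is.data.frame(newdata)) {
    newdata <- as.data.frame(as.list(newdata))
  }
  missing <- setdiff(terms, names(newdata))
  if (length(missing)) {
    stop("missing predictor value(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!length(terms)) return(rep(unname(b[1]), nrow(newdata)))
  X <- as.matrix(newdata[, terms, drop = FALSE])
  drop(b[1] + X %*% b[-1])
}

#' @rdname linear_score
#' @export
ntcp_probability <- function(model, newdata) {
  stats::plogis(linear_score(model, newdata))
}

#' Tolerance dose at a complication probability
#'
#' For a single-dose-predictor model, inverts the logistic dose-response:
#' \deqn{TD_p = \frac{\mathrm{logit}(p) - \beta_0}{\beta_1}.}
#' So TD50 = −β0/β1 and TD5 = (logit(0.05) − β0)/β1. The uncertainty interval
#' is a parametric bootstrap: `(β0, β1)` pairs are drawn from the fitted Wald
#' covariance, each inverted, and the 2.5/97.5 percentiles reported. Draws
#' with a non-positive slope (for which a tolerance dose is undefined) are
#' discarded.
#'
#' @param model An `ntcp_logistic` with exactly one (dose) predictor and a
#'   positive slope.
#' @param p Complication probability in (0, 1), e.g. 0.05 or 0.5.
#' @param n_boot Bootstrap draws for the interval (0 skips the interval).
#' @param seed RNG seed for the bootstrap.
#' @return A `td_estimate`: list with `p`, `dose` (Gy), `interval_low`,
#'   `interval_high`, `method`, `n_boot` and the number of discarded draws.
#' @export
tolerance_dose <- function(model, p, n_boot = 10000L, seed = 1L) {
  stopifnot(inherits(model, "ntcp_logistic"))
  if (length(model$coefficients) != 2L) {
    stop("tolerance doses require a model with exactly one dose predictor",
         call. = FALSE)
  }
  if (length(p) != 1L || p <= 0 || p >= 1) {
    stop("`p` must lie strictly between 0 and 1", call. = FALSE)
  }
  b0 <- model$coefficients[[1]]
  b1 <- model$coefficients[[2]]
  if (b1 <= 0) {
    stop("tolerance dose undefined: dose slope is not positive", call. = FALSE)
  }
  dose <- (stats::qlogis(p) - b0) / b1
  low <- high <- NA_real_
  dropped <- 0L
  if (n_boot > 0) {
    draws <- with_seed(seed,
      MASS::mvrnorm(n_boot, mu = model$coefficients, Sigma = model$vcov))
    ok <- draws[, 2] > 0
    dropped <- sum(!ok)
    td <- (stats::qlogis(p) - draws[ok, 1]) / draws[ok, 2]
    q <- stats::quantile(td, c(0.025, 0.975), names = FALSE)
    low <- q[1]
    high <- q[2]
  }
  structure(
    list(p = p, dose = dose, interval_low = low, interval_high = high,
         method = "parametric bootstrap of Wald covariance",
         n_boot = n_boot, n_dropped = dropped,
         predictor = model$terms[1]),
    class = "td_estimate"
  )
}

#' @export
print.td_estimate <- function(x, ...) {
  ci <- if (is.na(x$interval_low)) "" else
    sprintf(" (%.2f–%.2f Gy)", x$interval_low, x$interval_high)
  cat(sprintf("TD%g of %s: %.2f Gy%s\n", 100 * x$p, x$predictor, x$dose, ci))
  invisible(x)
}

#' Dose-response curve of a single-predictor NTCP model
#'
#' @param model An `ntcp_logistic` with one dose predictor.
#' @param from,to Dose range (Gy); `to` defaults to the dose at NTCP = 0.99.
#' @param step Dose step (Gy).
#' @return A data frame with columns `dose` and `ntcp`, monotone
#'   non-decreasing for a positive slope.
#' @export
dose_response_curve <- function(model, from = 0, to = NULL, step = 0.5) {
  stopifnot(inherits(model, "ntcp_logistic"))
  if (length(model$coefficients) != 2L) {
    stop("dose-response curve requires a single-predictor model", call. = FALSE)
  }
  if (is.null(to)) to <- tolerance_dose(model, 0.99, n_boot = 0)$dose
  dose <- seq(from, to, by = step)
  nd <- stats::setNames(data.frame(dose), model$terms[1])
  data.frame(dose = dose, ntcp = ntcp_probability(model, nd))
}
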