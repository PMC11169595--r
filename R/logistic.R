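#' Fit a logistic dose-response model by IRLS
#'
#' Maximum-likelihood logistic regression for binary complication outcomes,
#' the workhorse behind every NTCP fit in this package:
#' \deqn{NTCP = \frac{1}{1 + e^{-S}}, \qquad S = \beta_0 + \sum_i \beta_i x_i.}
#' Fitting uses iteratively reweighted least squares with step-halving (so the
#' log-likelihood never decreases between iterations), a small ridge fallback
#' when the weighted normal equations are singular, and convergence declared
#' when the relative log-likelihood change drops below `tol`.
#'
#' @param predictors Data frame or numeric matrix of predictors (no intercept
#'   column; one is added internally), or `NULL` for an intercept-only fit.
#' @param outcome Binary 0/1 vector with both classes present.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum IRLS iterations.
#' @param ridge Ridge penalty added to the normal equations only when they are
#'   numerically singular.
#' @return An `ntcp_logistic` object: coefficients, covariance (inverse
#'   observed information), Wald table (`estimate`, `se`, `z`, `wald`, `p`,
#'   odds-ratio CI), log-likelihoods, Nagelkerke R², iteration trace and
#'   convergence/separation flags.
#' @seealso [nagelkerke_r2()], [ntcp_probability()], [tolerance_dose()]
#' @export
fit_logistic <- function(predictors, outcome, tol = 1e-8, max_iter = 100L,
                         ridge = 1e-6) {
  y <- as.numeric(outcome)
  if (anyNA(y)) stop("missing values in model data", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("outcome must contain both classes", call. = FALSE)
  }
  if (is.null(predictors)) {
    X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    if (is.null(dim(predictors))) {
      predictors <- matrix(predictors, ncol = 1,
                           dimnames = list(NULL, "x"))
    }
    X <- as.matrix(as.data.frame(predictors))
    if (!is.numeric(X)) stop("predictors must be numeric", call. = FALSE)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (anyNA(X)) stop("missing values in model data", call. = FALSE)
    if (nrow(X) != length(y)) {
      stop("predictors and outcome lengths differ", call. = FALSE)
    }
    X <- cbind("(Intercept)" = 1, X)
  }
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("more coefficients than observations", call. = FALSE)

  loglik <- function(beta) {
    eta <- drop(X %*% beta)
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }

  beta <- numeric(p)
  ll <- loglik(beta)
  trace <- ll
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    XtWX <- crossprod(X * sqrt(w))
    R <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(R)) R <- chol(XtWX + diag(ridge, p))
    delta <- backsolve(R, forwardsolve(t(R), drop(crossprod(X, y - mu))))
    # step-halving guarantees a monotone log-likelihood trace
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      ll_new <- loglik(beta_new)
      if (ll_new >= ll - 1e-10 || step < 1e-8) break
      step <- step / 2
    }
    beta <- beta_new
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < tol * (abs(ll) + 0.1)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  XtWX <- crossprod(X * sqrt(w))
  R <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(R)) R <- chol(XtWX + diag(ridge, p))
  vcov <- chol2inv(R)
  dimnames(vcov) <- list(colnames(X), colnames(X))

  separation <- max(abs(beta)) > 50 ||
    (all(mu[y == 1] > 1 - 1e-6) && all(mu[y == 0] < 1e-6))
  if (separation) {
    warning("possible complete separation: coefficients are unreliable",
            call. = FALSE)
  }

  pbar <- mean(y)
  ll_null <- n * (pbar * log(pbar) + (1 - pbar) * log(1 - pbar))

  est <- stats::setNames(beta, colnames(X))
  se <- sqrt(diag(vcov))
  z <- est / se
  wald_tab <- data.frame(
    term = colnames(X), estimate = est, se = se, z = z, wald = z^2,
    p = 2 * stats::pnorm(-abs(z)),
    or_low = exp(est - 1.96 * se), or_high = exp(est + 1.96 * se),
    row.names = NULL
  )

  structure(
    list(coefficients = est, vcov = vcov, wald = wald_tab,
         loglik = ll, loglik_null = ll_null, n = n,
         nagelkerke_r2 = nagelkerke_r2(ll, ll_null, n),
         trace = trace, converged = converged, separation = separation,
         terms = colnames(X)[-1]),
    class = "ntcp_logistic"
  )
}

#' Nagelkerke pseudo R-squared
#'
#' Cox–Snell R² = 1 − exp(2(L0 − L1)/n), normalised by its attainable maximum
#' 1 − exp(2 L0 / n) so that a perfectly predictive model reaches 1.
#'
#' @param loglik_model Log-likelihood of the fitted model.
#' @param loglik_null Log-likelihood of the intercept-only model.
#' @param n Number of observations (> 0).
#' @return Value in \[0, 1\].
#' @export
nagelkerke_r2 <- function(loglik_model, loglik_null, n) {
  if (length(n) != 1L || !is.finite(n) || n <= 0) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  if (loglik_model < loglik_null - 1e-8) {
    stop("model log-likelihood is below the null log-likelihood", call. = FALSE)
  }
  r2_cs <- 1 - exp(2 * (loglik_null - loglik_model) / n)
  denom <- 1 - exp(2 * loglik_null / n)
  if (denom <= 0) return(0)
  clamp01(r2_cs / denom)[[1]]
}

#' @export
coef.ntcp_logistic <- function(object, ...) object$coefficients

#' @export
vcov.ntcp_logistic <- function(object, ...) object$vcov

#' @export
logLik.ntcp_logistic <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
print.ntcp_logistic <- function(x, digits = 4, ...) {
  cat("<ntcp_logistic>", if (!is.null(x$protocol)) paste0("protocol '", x$protocol, "'"), "\n")
  cat(" ", s_form(x, digits = digits), "\n")
  tab <- x$wald
  tab$estimate <- signif(tab$estimate, digits)
  tab$se <- signif(tab$se, digits)
  tab$wald <- signif(tab$wald, digits)
  tab$p <- signif(tab$p, 3)
  tab$or_ci <- sprintf("%.3f-%.3f", tab$or_low, tab$or_high)
  print(tab[, c("term", "estimate", "se", "wald", "p", "or_ci")],
        row.names = FALSE)
  cat(sprintf("  n = %d, logLik = %.3f, Nagelkerke R^2 = %.4f%s\n",
              x$n, x$loglik, x$nagelkerke_r2,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Regression function of a fitted model in S-form
#'
#' Formats the linear predictor as a string such as
#' `"S = 0.067 x sum_d1_5cc - 8.216"`.
#'
#' @param model An `ntcp_logistic`.
#' @param digits Significant digits.
#' @return A character scalar.
#' @export
s_form <- function(model, digits = 4) {
  b <- model$coefficients
  slopes <- b[-1]
  parts <- sprintf("%s × %s", signif(slopes, digits), names(slopes))
  rhs <- paste(parts, collapse = " + ")
  b0 <- signif(b[1], digits)
  if (length(slopes) == 0) {
    sprintf("S = %s", b0)
  } else if (b0 < 0) {
    sprintf("S = %s − %s", rhs, abs(b0))
  } else {
    sprintf("S = %s + %s", rhs, b0)
  }
}
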