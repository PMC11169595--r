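#' Create a physical dose grid
#'
#' A `dose_grid` holds one treatment course's 3D physical dose distribution
#' together with its voxel geometry and the number of fractions the course was
#' delivered in. Two grids can only be combined when they live on the same
#' registration frame (same shape, spacing and `frame_id`); no resampling or
#' registration is performed by this package.
#'
#' @param values 3D numeric array of physical dose per voxel (Gy), all finite
#'   and non-negative.
#' @param spacing Numeric vector of length 3: voxel edge lengths (mm).
#' @param n_fractions Positive integer: number of fractions delivering the grid.
#' @param frame_id Identifier of the registration frame the grid lives on.
#'
#' @return An object of class `dose_grid`.
#' @seealso [eqd2_convert()], [read_dose_nifti()]
#' @export
#' @examples
#' g <- dose_grid(array(60, c(2, 2, 2)), spacing = c(2, 2, 2), n_fractions = 30)
#' eqd2_convert(g, alpha_beta = 3)
dose_grid <- function(values, spacing, n_fractions, frame_id = "frame-1") {
  values <- if (is.array(values)) values else as.array(values)
  if (length(dim(values)) != 3L) {
    stop("`values` must be a 3D array of voxel doses", call. = FALSE)
  }
  if (!all(is.finite(values)) || any(values < 0)) {
    stop("voxel doses must be finite and non-negative", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive voxel edge lengths (mm)", call. = FALSE)
  }
  if (length(n_fractions) != 1L || !is.finite(n_fractions) || n_fractions < 1) {
    stop("`n_fractions` must be a positive integer", call. = FALSE)
  }
  structure(
    list(values = values, spacing = spacing,
         n_fractions = as.integer(n_fractions),
         frame_id = as.character(frame_id)),
    class = "dose_grid"
  )
}

new_eqd2_grid <- function(values, spacing, frame_id, alpha_beta) {
  structure(
    list(values = values, spacing = as.numeric(spacing),
         frame_id = as.character(frame_id), alpha_beta = alpha_beta),
    class = "eqd2_grid"
  )
}

#' Convert a physical dose grid to EQD2
#'
#' Rescales each voxel's total dose \eqn{D} to the equivalent dose in 2 Gy
#' fractions under the linear-quadratic model,
#' \deqn{EQD2 = D \cdot \frac{d + \alpha/\beta}{2 + \alpha/\beta},}
#' with per-voxel fraction dose \eqn{d = D / n_{fractions}} (uniform
#' fractionation within a course). For late-responding brain tissue the
#' conventional ratio is \eqn{\alpha/\beta = 3} Gy, the default. Voxels
#' receiving exactly 2 Gy per fraction are fixed points of the transform and
#' zero-dose voxels map to zero.
#'
#' @param grid A [dose_grid()].
#' @param alpha_beta Tissue alpha/beta ratio (Gy), strictly positive.
#' @return An `eqd2_grid` carrying the `alpha_beta` used.
#' @export
eqd2_convert <- function(grid, alpha_beta = 3) {
  stopifnot(inherits(grid, "dose_grid"))
  if (length(alpha_beta) != 1L || !is.finite(alpha_beta) || alpha_beta <= 0) {
    stop("`alpha_beta` must be a single positive value (Gy)", call. = FALSE)
  }
  if (grid$n_fractions < 1) stop("`n_fractions` must be >= 1", call. = FALSE)
  new_eqd2_grid(
    eqd2_values(grid$values, grid$n_fractions, alpha_beta),
    grid$spacing, grid$frame_id, alpha_beta
  )
}

# element-wise LQ transform on a bare numeric vector/array
eqd2_values <- function(dose, n_fractions, alpha_beta) {
  d <- dose / n_fractions
  dose * (d + alpha_beta) / (2 + alpha_beta)
}

#' Construct an EQD2 grid directly
#'
#' Wraps an array of already-converted EQD2 voxel values. Mostly useful in
#' tests and when importing EQD2 distributions computed elsewhere.
#'
#' @param values 3D array of EQD2 per voxel (Gy), non-negative.
#' @param spacing Voxel edge lengths (mm).
#' @param frame_id Registration frame identifier.
#' @param alpha_beta The alpha/beta ratio (Gy) the values were computed with.
#' @return An `eqd2_grid`.
#' @export
eqd2_grid <- function(values, spacing, frame_id = "frame-1", alpha_beta = 3) {
  values <- if (is.array(values)) values else as.array(values)
  if (length(dim(values)) != 3L) {
    stop("`values` must be a 3D array", call. = FALSE)
  }
  if (!all(is.finite(values)) || any(values < 0)) {
    stop("EQD2 values must be finite and non-negative", call. = FALSE)
  }
  if (alpha_beta <= 0) stop("`alpha_beta` must be positive", call. = FALSE)
  new_eqd2_grid(values, spacing, frame_id, alpha_beta)
}

# Shared-frame check for any two grid-like objects (dose, EQD2, mask).
check_combinable <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values))) {
    stop("grids are not combinable: shapes differ", call. = FALSE)
  }
  if (!isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-8))) {
    stop("grids are not combinable: voxel spacings differ", call. = FALSE)
  }
  if (!identical(a$frame_id, b$frame_id)) {
    stop("grids are not combinable: registration frames differ", call. = FALSE)
  }
  ab_a <- a$alpha_beta
  ab_b <- b$alpha_beta
  if (!is.null(ab_a) && !is.null(ab_b) && !isTRUE(all.equal(ab_a, ab_b))) {
    stop("grids are not combinable: alpha/beta ratios differ", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s voxels @ %s mm, %d fractions, frame '%s'\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              x$n_fractions, x$frame_id))
  cat(sprintf("  dose range %.2f-%.2f Gy\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.eqd2_grid <- function(x, ...) {
  cat(sprintf("<eqd2_grid> %s voxels @ %s mm, alpha/beta %.3g Gy, frame '%s'\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              x$alpha_beta, x$frame_id))
  cat(sprintf("  EQD2 range %.2f-%.2f Gy\n", min(x$values), max(x$values)))
  invisible(x)
}
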