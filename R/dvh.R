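#' Binary structure mask
#'
#' Marks the voxels belonging to one organ-at-risk structure (here a left or
#' right temporal lobe) on the shared registration frame. Masks are strictly
#' binary: no partial-volume treatment is applied at structure edges.
#'
#' @param values 3D logical (or 0/1) array; at least one voxel must be set.
#' @param spacing Voxel edge lengths (mm), matching the grids it is applied to.
#' @param frame_id Registration frame identifier.
#' @param name Structure label, e.g. `"temporal_lobe_L"`.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(values, spacing, frame_id = "frame-1",
                           name = "structure") {
  values <- if (is.array(values)) values else as.array(values)
  if (length(dim(values)) != 3L) {
    stop("mask `values` must be a 3D array", call. = FALSE)
  }
  storage.mode(values) <- "logical"
  if (anyNA(values)) stop("mask contains missing values", call. = FALSE)
  if (!any(values)) stop("empty structure mask: no voxel set", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be three positive voxel edge lengths (mm)", call. = FALSE)
  }
  structure(
    list(values = values, spacing = spacing,
         frame_id = as.character(frame_id), name = as.character(name)),
    class = "structure_mask"
  )
}

#' Voxel volume of a grid or mask, in cc
#'
#' @param x A grid or mask (anything carrying a `spacing` field in mm).
#' @return Volume of one voxel in cubic centimetres.
#' @export
voxel_volume_cc <- function(x) prod(x$spacing) / 1000

# doses of the voxels inside the mask, as a bare vector
mask_doses <- function(grid, mask) {
  stopifnot(inherits(grid, c("dose_grid", "eqd2_grid")),
            inherits(mask, "structure_mask"))
  check_combinable(grid, mask)
  as.vector(grid$values)[as.vector(mask$values)]
}

# The k largest values of v, sorted decreasing. Uses a partial sort so the
# per-call cost is O(n + k log k); exact, not approximate.
top_sorted <- function(v, k) {
  n <- length(v)
  if (k >= n) return(sort(v, decreasing = TRUE))
  p <- n - k + 1L
  vp <- sort(v, partial = p)
  sort(vp[p:n], decreasing = TRUE)
}

# Minimum dose to the hottest x cc, from voxel doses sorted decreasing.
# The cumulative-volume/dose curve passes through (k * voxel_cc, sorted[k]);
# within-voxel behaviour is linear interpolation between those points, and
# volumes below one voxel report the maximum dose. Vectorised over x_cc;
# volumes beyond the structure give NA (callers decide whether that errors).
dxcc_from_sorted <- function(sorted_desc, voxel_cc, x_cc) {
  n <- length(sorted_desc)
  k <- x_cc / voxel_cc
  vapply(k, function(ki) {
    if (!is.finite(ki) || ki <= 0) return(NA_real_)
    if (ki <= 1) return(sorted_desc[1L])
    if (ki > n + 1e-9) return(NA_real_)
    k0 <- floor(ki + 1e-12)
    frac <- ki - k0
    if (k0 >= n) return(sorted_desc[n])
    if (frac <= 1e-12) return(sorted_desc[k0])
    sorted_desc[k0] * (1 - frac) + sorted_desc[k0 + 1L] * frac
  }, numeric(1))
}

#' Minimum dose to the hottest x cc of a structure
#'
#' `DxCC` is defined as the minimum dose received by the hottest `x_cc` cubic
#' centimetres of the structure: member voxel doses are sorted in decreasing
#' order, voxel volumes are accumulated, and the dose is linearly interpolated
#' within the voxel in which the cumulative volume crosses `x_cc`. As
#' `x_cc` tends to zero the value tends to the structure's maximum dose; at
#' the full structure volume it equals the minimum member dose.
#'
#' @param grid A dose or EQD2 grid.
#' @param mask A [structure_mask()] on the same frame.
#' @param x_cc Volume(s) in cc; must be positive and no larger than the
#'   structure volume.
#' @return Dose(s) in Gy, one per element of `x_cc`.
#' @export
dose_at_volume <- function(grid, mask, x_cc) {
  d <- mask_doses(grid, mask)
  vcc <- voxel_volume_cc(mask)
  total <- vcc * length(d)
  if (any(x_cc <= 0)) stop("`x_cc` must be positive", call. = FALSE)
  if (any(x_cc > total + 1e-9)) {
    stop(sprintf("`x_cc` exceeds the structure volume (%.3f cc)", total),
         call. = FALSE)
  }
  dxcc_from_sorted(sort(d, decreasing = TRUE), vcc, x_cc)
}

#' Dose to the hottest fraction of a structure's volume
#'
#' Relative-volume counterpart of [dose_at_volume()] (Dx\% in planning-system
#' notation): `fraction = 0.01` gives the minimum dose to the hottest 1\% of
#' the structure volume.
#'
#' @inheritParams dose_at_volume
#' @param fraction Fraction(s) of the structure volume in (0, 1\].
#' @return Dose(s) in Gy.
#' @export
dose_at_relative_volume <- function(grid, mask, fraction) {
  if (any(fraction <= 0) || any(fraction > 1)) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  total <- voxel_volume_cc(mask) * sum(mask$values)
  dose_at_volume(grid, mask, fraction * total)
}

# names of the standard index set: dmax plus D0.5cc..D5cc in 0.5 cc steps
#' Standard dosimetric index names
#'
#' @param volumes_cc Volumes (cc) of the DxCC indices.
#' @return Character vector `c("dmax", "d0.5cc", ..., "d5cc")`.
#' @export
default_indices <- function(volumes_cc = seq(0.5, 5, by = 0.5)) {
  c("dmax", paste0("d", vapply(volumes_cc, vol_label, character(1)), "cc"))
}

# parse "d1.5cc" -> 1.5; "dmax" -> NA
index_volume <- function(index) {
  vapply(index, function(x) {
    if (x == "dmax") NA_real_ else as.numeric(sub("^d", "", sub("cc$", "", x)))
  }, numeric(1), USE.NAMES = FALSE)
}

# Core extraction on a bare dose vector; one partial sort serves every index.
indices_from_doses <- function(doses, voxel_cc, volumes_cc = seq(0.5, 5, by = 0.5)) {
  n <- length(doses)
  total <- n * voxel_cc
  if (!length(volumes_cc)) {
    return(list(dmax = max(doses),
                d_cc = stats::setNames(numeric(0), character(0))))
  }
  k <- min(n, ceiling(max(volumes_cc) / voxel_cc) + 1L)
  sd <- top_sorted(doses, k)
  d_cc <- dxcc_from_sorted(sd, voxel_cc, pmin(volumes_cc, Inf))
  d_cc[volumes_cc > total + 1e-9] <- NA_real_
  names(d_cc) <- vapply(volumes_cc, vol_label, character(1))
  list(dmax = sd[1L], d_cc = d_cc)
}

#' Extract the standard dosimetric index set of a structure
#'
#' Computes the maximum structure dose and the DxCC indices for
#' `volumes_cc` (by default 0.5 cc to 5 cc in 0.5 cc increments) directly from
#' the sorted member voxel doses — exact, with no histogram binning. Volumes
#' exceeding the structure volume are reported as `NA`.
#'
#' @inheritParams dose_at_volume
#' @param volumes_cc Volumes (cc) at which DxCC is extracted.
#' @return A `dose_index_set`: list with `structure`, `dmax` (Gy), `d_cc`
#'   (named numeric, Gy), `volumes_cc` and `total_volume_cc`.
#' @export
extract_indices <- function(grid, mask, volumes_cc = seq(0.5, 5, by = 0.5)) {
  d <- mask_doses(grid, mask)
  vcc <- voxel_volume_cc(mask)
  idx <- indices_from_doses(d, vcc, volumes_cc)
  structure(
    list(structure = mask$name, dmax = idx$dmax, d_cc = idx$d_cc,
         volumes_cc = volumes_cc, total_volume_cc = vcc * length(d)),
    class = "dose_index_set"
  )
}

#' @export
as.data.frame.dose_index_set <- function(x, ...) {
  out <- data.frame(structure = x$structure, dmax = x$dmax)
  for (i in seq_along(x$d_cc)) {
    out[[safe_name(paste0("d", names(x$d_cc)[i], "cc"))]] <- unname(x$d_cc[i])
  }
  out
}

#' @export
print.dose_index_set <- function(x, ...) {
  cat(sprintf("<dose_index_set> '%s' (%.2f cc)\n", x$structure,
              x$total_volume_cc))
  cat(sprintf("  Dmax = %.2f Gy\n", x$dmax))
  lbl <- paste0("D", names(x$d_cc), "cc")
  cat(paste(sprintf("  %-7s = %s Gy", lbl,
                    ifelse(is.na(x$d_cc), "NA", sprintf("%.2f", x$d_cc))),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Cumulative dose-volume histogram of a structure
#'
#' Tabulates the absolute volume (cc) receiving at least each dose level, on a
#' regular grid of dose edges from 0 to the structure maximum. The binned
#' curve is intended for export and plotting; the dosimetric indices are
#' computed exactly from sorted voxel doses by [extract_indices()].
#'
#' @inheritParams dose_at_volume
#' @param bin_width Dose bin width in Gy (default 0.1).
#' @return A `dvh_curve`: list with `dose_edges` (Gy), `volume_at_or_above`
#'   (cc), `total_volume_cc` and `structure`.
#' @export
cumulative_dvh <- function(grid, mask, bin_width = 0.1) {
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  d <- mask_doses(grid, mask)
  vcc <- voxel_volume_cc(mask)
  top <- max(d)
  edges <- seq(0, ceiling(top / bin_width + 1e-9) * bin_width, by = bin_width)
  vol <- vapply(edges, function(e) vcc * sum(d >= e), numeric(1))
  structure(
    list(dose_edges = edges, volume_at_or_above = vol,
         total_volume_cc = vcc * length(d), structure = mask$name),
    class = "dvh_curve"
  )
}

#' Invert a cumulative DVH curve at a volume
#'
#' Returns the highest tabulated dose level still covering at least `x_cc`;
#' exact to within one bin width of the sorted-voxel [dose_at_volume()].
#'
#' @param dvh A `dvh_curve` from [cumulative_dvh()].
#' @param x_cc Volume in cc.
#' @return Dose in Gy.
#' @export
dvh_dose_at_volume <- function(dvh, x_cc) {
  stopifnot(inherits(dvh, "dvh_curve"))
  if (x_cc <= 0 || x_cc > dvh$total_volume_cc + 1e-9) {
    stop("`x_cc` outside (0, total volume]", call. = FALSE)
  }
  max(dvh$dose_edges[dvh$volume_at_or_above >= x_cc - 1e-12])
}

#' @export
as.data.frame.dvh_curve <- function(x, ...) {
  data.frame(structure = x$structure, dose_gy = x$dose_edges,
             volume_cc = x$volume_at_or_above)
}

#' Export DVH curves or index sets as CSV
#'
#' `write_dvh_csv` writes one or more curves with columns
#' `structure, dose_gy, volume_cc`; `write_indices_csv` writes one row per
#' structure with columns `structure, dmax, d0_5cc, ..., d5cc` (missing
#' volumes blank).
#'
#' @param x A `dvh_curve` / `dose_index_set` or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dvh_csv <- function(x, path) {
  if (inherits(x, "dvh_curve")) x <- list(x)
  out <- do.call(rbind, lapply(x, as.data.frame))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dvh_csv
#' @export
write_indices_csv <- function(x, path) {
  if (inherits(x, "dose_index_set")) x <- list(x)
  out <- do.call(rbind, lapply(x, as.data.frame))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
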