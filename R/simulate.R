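#' Configuration of the synthetic re-irradiation cohort generator
#'
#' The generator emulates the study conditions of a two-course IMRT cohort
#' for recurrent nasopharyngeal carcinoma: per patient it produces a
#' first-course dose grid (already "deformed" onto the shared frame), a
#' re-irradiation dose grid, left/right temporal-lobe masks, clinical
#' covariates, the inter-course gap, and per-lobe binary injury outcomes
#' drawn from a configurable ground-truth logistic NTCP applied to a chosen
#' dosimetric index of the true accumulated dose.
#'
#' Dose fields are smooth exponential fall-offs from a per-course hot-spot
#' centre near the skull base (midline for the primary course, lateralised
#' toward the recurrence side for the re-irradiation course), scaled to the
#' sampled prescription and perturbed by multiplicative log-normal voxel
#' noise. Lobe masks are two disjoint ellipsoids of realistic volume.
#'
#' Defaults mirror the modelled cohort: 78 patients; first-course regimens
#' 66 Gy/30 fx or 70.4 Gy/32 fx; re-irradiation 60–66 Gy in 30–33 fx;
#' inter-course gaps log-normal with median 26 months truncated to 12–108;
#' ground-truth NTCP on the plain-sum D1.5cc with slope 0.067 per Gy and
#' intercept −8.216 (so the true TD50 is about 122.6 Gy EQD2); clinical
#' covariates carry no true effect. The hot-spot geometry (fall-off length
#' 80 mm with wide patient-to-patient log-normal variation, peak factor 1.10)
#' is calibrated so the accumulated D1.5cc distribution centres near 110 Gy
#' EQD2 with a spread of about 16 Gy and the mean latent per-lobe injury
#' probability is close to 1/3.
#'
#' @param n_patients Number of patients.
#' @param grid_dim,spacing Grid shape and voxel spacing (mm).
#' @param course1_regimens,course2_regimens Data frames with columns
#'   `dose_gy`, `n_fractions`, `weight` (sampling probabilities).
#' @param gap_meanlog,gap_sdlog,gap_range_months Log-normal gap distribution
#'   (months) and truncation range.
#' @param lobe_semiaxes_mm Ellipsoid semi-axes of each lobe (mm).
#' @param hotspot_decay_mm,hotspot_decay_sdlog Median and log-sd of the
#'   per-course exponential fall-off length (mm).
#' @param hotspot_peak_mean,hotspot_peak_sd Mean/sd of the multiplicative
#'   hot-spot factor applied to the prescription dose.
#' @param course2_lateral_frac Lateral offset of the re-irradiation hot-spot
#'   centre toward the recurrence side, as a fraction of the grid extent.
#' @param center_jitter_mm Isotropic sd of the hot-spot centre jitter (mm).
#' @param noise_sd Log-sd of multiplicative voxel noise.
#' @param alpha_beta Alpha/beta ratio (Gy) used for all EQD2 conversions.
#' @param true_model Ground-truth [time_model()] used when accumulating the
#'   two courses for outcome generation.
#' @param true_index Index of the true accumulated dose driving outcomes
#'   (e.g. `"d1.5cc"`).
#' @param true_beta0,true_beta1 Ground-truth logistic intercept and slope
#'   (per Gy).
#' @param seed Cohort RNG seed.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(
    n_patients = 78,
    grid_dim = c(40L, 40L, 32L),
    spacing = c(2.5, 2.5, 2.5),
    course1_regimens = data.frame(dose_gy = c(66, 70.4),
                                  n_fractions = c(30L, 32L),
                                  weight = c(33, 45) / 78),
    course2_regimens = data.frame(dose_gy = c(60, 62, 64, 66),
                                  n_fractions = c(30L, 31L, 32L, 33L),
                                  weight = c(16, 5, 4, 53) / 78),
    gap_meanlog = log(26), gap_sdlog = 0.55,
    gap_range_months = c(12, 108),
    lobe_semiaxes_mm = c(20, 28, 30),
    hotspot_decay_mm = 80, hotspot_decay_sdlog = 0.45,
    hotspot_peak_mean = 1.10, hotspot_peak_sd = 0.10,
    course2_lateral_frac = 0.05,
    center_jitter_mm = 4,
    noise_sd = 0.03,
    alpha_beta = 3,
    true_model = time_model("none"),
    true_index = "d1.5cc",
    true_beta0 = -8.216, true_beta1 = 0.067,
    seed = 1L) {
  cfg <- list(n_patients = n_patients, grid_dim = as.integer(grid_dim),
              spacing = as.numeric(spacing),
              course1_regimens = course1_regimens,
              course2_regimens = course2_regimens,
              gap_meanlog = gap_meanlog, gap_sdlog = gap_sdlog,
              gap_range_months = gap_range_months,
              lobe_semiaxes_mm = lobe_semiaxes_mm,
              hotspot_decay_mm = hotspot_decay_mm,
              hotspot_decay_sdlog = hotspot_decay_sdlog,
              hotspot_peak_mean = hotspot_peak_mean,
              hotspot_peak_sd = hotspot_peak_sd,
              course2_lateral_frac = course2_lateral_frac,
              center_jitter_mm = center_jitter_mm,
              noise_sd = noise_sd, alpha_beta = alpha_beta,
              true_model = true_model, true_index = true_index,
              true_beta0 = true_beta0, true_beta1 = true_beta1,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1, length(cfg$grid_dim) == 3,
            all(cfg$grid_dim >= 4), all(cfg$spacing > 0),
            all(cfg$course1_regimens$n_fractions >= 1),
            all(cfg$course2_regimens$n_fractions >= 1),
            all(cfg$course1_regimens$dose_gy >= 0),
            all(cfg$course2_regimens$dose_gy >= 0),
            cfg$hotspot_decay_mm > 0, cfg$noise_sd >= 0,
            cfg$alpha_beta > 0,
            inherits(cfg$true_model, "time_model"))
  extent <- cfg$grid_dim * cfg$spacing
  centers <- lobe_centers(cfg)
  for (s in rownames(centers)) {
    lo <- centers[s, ] - cfg$lobe_semiaxes_mm
    hi <- centers[s, ] + cfg$lobe_semiaxes_mm
    if (any(lo < 0) || any(hi > extent)) {
      stop("grid too small to contain the lobe masks; enlarge `grid_dim` ",
           "or shrink `lobe_semiaxes_mm`", call. = FALSE)
    }
  }
  invisible(TRUE)
}

# lobe centres in mm, one row per side
lobe_centers <- function(cfg) {
  extent <- cfg$grid_dim * cfg$spacing
  rbind(L = c(0.30, 0.50, 0.60) * extent,
        R = c(0.70, 0.50, 0.60) * extent)
}

# hot-spot base centres in mm
course_centers <- function(cfg, side) {
  extent <- cfg$grid_dim * cfg$spacing
  c1 <- c(0.50, 0.52, 0.175) * extent
  lat <- cfg$course2_lateral_frac * (if (side == "L") -1 else 1)
  c2 <- c(0.50 + lat, 0.52, 0.225) * extent
  rbind(course1 = c1, course2 = c2)
}

# Precomputed geometry shared by every patient of one configuration:
# voxel-centre coordinates, lobe membership and in-mask coordinate matrices.
sim_geometry <- function(cfg) {
  dm <- cfg$grid_dim
  sp <- cfg$spacing
  ax <- lapply(1:3, function(k) (seq_len(dm[k]) - 0.5) * sp[k])
  centers <- lobe_centers(cfg)
  semi <- cfg$lobe_semiaxes_mm
  # ellipsoid membership via outer sums of per-axis squared normalised offsets
  member <- function(ctr) {
    qx <- ((ax[[1]] - ctr[1]) / semi[1])^2
    qy <- ((ax[[2]] - ctr[2]) / semi[2])^2
    qz <- ((ax[[3]] - ctr[3]) / semi[3])^2
    q <- outer(outer(qx, qy, "+"), qz, "+")
    q < 1
  }
  mask_L <- member(centers["L", ])
  mask_R <- member(centers["R", ])
  coords_all <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  idx_L <- which(as.vector(mask_L))
  idx_R <- which(as.vector(mask_R))
  list(
    mask = list(L = mask_L, R = mask_R),
    idx = list(L = idx_L, R = idx_R),
    idx_rest = setdiff(seq_len(prod(dm)), c(idx_L, idx_R)),
    coords = list(L = coords_all[as.vector(mask_L), , drop = FALSE],
                  R = coords_all[as.vector(mask_R), , drop = FALSE]),
    coords_all = coords_all,
    voxel_cc = prod(sp) / 1000,
    n_vox = prod(dm)
  )
}

# Per-patient random parameters (consumes RNG).
draw_patient <- function(cfg) {
  r1 <- cfg$course1_regimens[
    sample.int(nrow(cfg$course1_regimens), 1, prob = cfg$course1_regimens$weight), ]
  r2 <- cfg$course2_regimens[
    sample.int(nrow(cfg$course2_regimens), 1, prob = cfg$course2_regimens$weight), ]
  gap <- min(max(exp(stats::rnorm(1, cfg$gap_meanlog, cfg$gap_sdlog)),
                 cfg$gap_range_months[1]), cfg$gap_range_months[2])
  side <- sample(c("L", "R"), 1)
  cc <- course_centers(cfg, side)
  jitter <- matrix(stats::rnorm(6, 0, cfg$center_jitter_mm), 2, 3)
  list(
    regimen1 = r1, regimen2 = r2, gap_months = gap, side = side,
    center1 = cc["course1", ] + jitter[1, ],
    center2 = cc["course2", ] + jitter[2, ],
    decay1 = cfg$hotspot_decay_mm * exp(stats::rnorm(1, 0, cfg$hotspot_decay_sdlog)),
    decay2 = cfg$hotspot_decay_mm * exp(stats::rnorm(1, 0, cfg$hotspot_decay_sdlog)),
    peak1 = r1$dose_gy * max(stats::rnorm(1, cfg$hotspot_peak_mean,
                                          cfg$hotspot_peak_sd), 0),
    peak2 = r2$dose_gy * max(stats::rnorm(1, cfg$hotspot_peak_mean,
                                          cfg$hotspot_peak_sd), 0),
    covariates = draw_covariates(cfg)
  )
}

# Clinical covariates with the cohort's empirical frequencies; none of them
# has a true effect on the outcome.
draw_covariates <- function(cfg) {
  list(
    age = round(min(max(stats::rnorm(1, 46, 9), 25), 70)),
    gender_male = stats::rbinom(1, 1, 59 / 78),
    t_primary = sample(c(1, 2, 3, 4), 1,
                       prob = c(20.5, 20.5, 21, 16) / 78),
    n_primary = sample(c(0, 1, 2, 3), 1, prob = c(23, 23, 16, 16) / 78),
    t_recurrent = sample(c(1, 2, 3, 4), 1,
                         prob = c(21.5, 21.5, 26, 9) / 78),
    n_recurrent = sample(c(0, 1, 2), 1, prob = c(55, 22, 1) / 78),
    induction_chemo = stats::rbinom(1, 1, 37 / 78),
    concurrent_chemo = stats::rbinom(1, 1, 18 / 78)
  )
}

# physical dose of one course at the given coordinates (mm)
dose_field <- function(coords, center, peak, decay, noise) {
  d2 <- (coords[, 1] - center[1])^2 + (coords[, 2] - center[2])^2 +
    (coords[, 3] - center[3])^2
  fall <- if (is.infinite(decay)) 1 else exp(-sqrt(d2) / decay)
  pmax(peak * fall * noise, 0)
}

# Multiplicative voxel noise for the two courses. In-mask voxels (left lobe
# then right lobe, course 1 then course 2) are always drawn FIRST, so the
# mask-only fast path and the full-grid path see bitwise-identical in-mask
# noise; the full path draws the out-of-mask voxels afterwards. With
# `full = FALSE` each course's vector holds the in-mask values in
# c(idx L, idx R) order.
draw_pair_noise <- function(cfg, geom, full = TRUE) {
  n_mask <- length(geom$idx$L) + length(geom$idx$R)
  if (cfg$noise_sd == 0) {
    one <- rep(1, if (full) geom$n_vox else n_mask)
    return(list(course1 = one, course2 = one))
  }
  m1 <- exp(stats::rnorm(n_mask, 0, cfg$noise_sd))
  m2 <- exp(stats::rnorm(n_mask, 0, cfg$noise_sd))
  if (!full) return(list(course1 = m1, course2 = m2))
  mk <- function(m) {
    out <- numeric(geom$n_vox)
    out[c(geom$idx$L, geom$idx$R)] <- m
    out[geom$idx_rest] <- exp(stats::rnorm(length(geom$idx_rest), 0,
                                           cfg$noise_sd))
    out
  }
  list(course1 = mk(m1), course2 = mk(m2))
}

#' Simulate one patient's paired dose grids and lobe masks
#'
#' @param config A [simulation_config()].
#' @param seed Patient RNG seed.
#' @return List with `course1` and `course2` ([dose_grid()]s on the shared
#'   frame), `masks` (list of L/R [structure_mask()]s) and the sampled
#'   patient `params`.
#' @export
simulate_dose_pair <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  geom <- sim_geometry(config)
  with_seed(seed, {
    pars <- draw_patient(config)
    noise <- draw_pair_noise(config, geom)
    v1 <- dose_field(geom$coords_all, pars$center1, pars$peak1, pars$decay1,
                     noise$course1)
    v2 <- dose_field(geom$coords_all, pars$center2, pars$peak2, pars$decay2,
                     noise$course2)
    frame <- "frame-sim"
    list(
      course1 = dose_grid(array(v1, config$grid_dim), config$spacing,
                          pars$regimen1$n_fractions, frame),
      course2 = dose_grid(array(v2, config$grid_dim), config$spacing,
                          pars$regimen2$n_fractions, frame),
      masks = list(
        L = structure_mask(geom$mask$L, config$spacing, frame,
                           "temporal_lobe_L"),
        R = structure_mask(geom$mask$R, config$spacing, frame,
                           "temporal_lobe_R")),
      params = pars
    )
  })
}

#' Simulate a full synthetic cohort
#'
#' Realises every pipeline input: per-lobe EQD2 voxel dose vectors for both
#' courses, the plain-sum accumulated dose, the full dosimetric index table
#' (`crs1_`, `crs2_`, `sum_` prefixes), clinical covariates, and binary
#' outcomes drawn Bernoulli from the ground-truth NTCP evaluated on
#' `true_index` of the true accumulated dose (`true_model` applied at the
#' patient's gap). Reproducible: the same config (including seed) yields a
#' byte-identical cohort table whether or not grids are written to disk.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory; when given, per-patient dose grids and
#'   the lobe masks are written as NIfTI, the cohort table as CSV, and a
#'   small manifest recording the seeds.
#' @return A [tl_cohort()] with voxel dose vectors attached.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  geom <- sim_geometry(config)
  n <- config$n_patients
  patient_seeds <- with_seed(config$seed,
                             sample.int(.Machine$integer.max - 1L, n))
  write_grids <- !is.null(out_dir)
  if (write_grids) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  idx_vols <- seq(0.5, 5, by = 0.5)
  rows <- vector("list", 2L * n)
  dose <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    res <- with_seed(patient_seeds[i], {
      pars <- draw_patient(config)
      noise <- draw_pair_noise(config, geom, full = write_grids)
      list(pars = pars, noise1 = noise$course1, noise2 = noise$course2)
    })
    pars <- res$pars
    w_true <- course1_weight(config$true_model, pars$gap_months)
    if (write_grids) {
      v1 <- dose_field(geom$coords_all, pars$center1, pars$peak1,
                       pars$decay1, res$noise1)
      v2 <- dose_field(geom$coords_all, pars$center2, pars$peak2,
                       pars$decay2, res$noise2)
      pid <- sprintf("p%03d", i)
      write_volume_nifti(array(v1, config$grid_dim), config$spacing,
                         file.path(out_dir, paste0(pid, "_course1.nii.gz")))
      write_volume_nifti(array(v2, config$grid_dim), config$spacing,
                         file.path(out_dir, paste0(pid, "_course2.nii.gz")))
    }
    n_L <- length(geom$idx$L)
    for (side in c("L", "R")) {
      ii <- geom$idx[[side]]
      # fast-path noise vectors hold c(left lobe, right lobe) values
      jj <- if (side == "L") seq_len(n_L) else n_L + seq_along(geom$idx$R)
      phys1 <- if (write_grids) v1[ii] else
        dose_field(geom$coords[[side]], pars$center1, pars$peak1,
                   pars$decay1, res$noise1[jj])
      phys2 <- if (write_grids) v2[ii] else
        dose_field(geom$coords[[side]], pars$center2, pars$peak2,
                   pars$decay2, res$noise2[jj])
      d1 <- eqd2_values(phys1, pars$regimen1$n_fractions, config$alpha_beta)
      d2 <- eqd2_values(phys2, pars$regimen2$n_fractions, config$alpha_beta)
      true_comb <- w_true * d1 + d2
      vol <- index_volume(config$true_index)
      x_true <- if (is.na(vol)) max(true_comb) else
        indices_from_doses(true_comb, geom$voxel_cc, vol)$d_cc[[1]]
      latent_p <- stats::plogis(config$true_beta0 + config$true_beta1 * x_true)
      outcome <- with_seed(patient_seeds[i] %% 1000000L * 2L +
                             (side == "R") + 7L,
                           stats::rbinom(1, 1, latent_p))
      k <- 2L * (i - 1L) + (side == "R") + 1L
      row <- data.frame(
        unit_id = sprintf("p%03d_%s", i, side),
        patient_id = sprintf("p%03d", i),
        lobe = side,
        gap_months = pars$gap_months,
        rt_dose_primary = pars$regimen1$dose_gy,
        rt_dose_recurrent = pars$regimen2$dose_gy,
        true_index_value = x_true,
        latent_p = latent_p,
        outcome = outcome
      )
      for (nm in names(pars$covariates)) row[[nm]] <- pars$covariates[[nm]]
      i1 <- indices_from_doses(d1, geom$voxel_cc, idx_vols)
      i2 <- indices_from_doses(d2, geom$voxel_cc, idx_vols)
      is <- indices_from_doses(d1 + d2, geom$voxel_cc, idx_vols)
      add_idx <- function(row, prefix, idx) {
        row[[paste0(prefix, "_dmax")]] <- idx$dmax
        for (v in names(idx$d_cc)) {
          row[[safe_name(paste0(prefix, "_d", v, "cc"))]] <- idx$d_cc[[v]]
        }
        row
      }
      row <- add_idx(row, "crs1", i1)
      row <- add_idx(row, "crs2", i2)
      row <- add_idx(row, "sum", is)
      rows[[k]] <- row
      dose[[k]] <- list(d1 = d1, d2 = d2)
    }
  }
  tab <- do.call(rbind, rows)
  cohort <- tl_cohort(tab, dose = dose, voxel_cc = geom$voxel_cc,
                      config = config)
  if (write_grids) {
    write_mask_nifti(structure_mask(geom$mask$L, config$spacing, "frame-sim",
                                    "temporal_lobe_L"),
                     file.path(out_dir, "mask_temporal_lobe_L.nii.gz"))
    write_mask_nifti(structure_mask(geom$mask$R, config$spacing, "frame-sim",
                                    "temporal_lobe_R"),
                     file.path(out_dir, "mask_temporal_lobe_R.nii.gz"))
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    writeLines(c(
      "generator: tlntcp synthetic cohort",
      paste0("seed: ", config$seed),
      paste0("n_patients: ", n),
      paste0("alpha_beta: ", config$alpha_beta),
      paste0("true_model: ", config$true_model$kind),
      paste0("true_a: ", config$true_model$a),
      paste0("true_index: ", config$true_index),
      paste0("true_beta0: ", config$true_beta0),
      paste0("true_beta1: ", config$true_beta1)
    ), file.path(out_dir, "manifest.yaml"))
  }
  cohort
}
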