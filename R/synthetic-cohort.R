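#' Configuration for a synthetic two-group cohort
#'
#' Collects every knob of the synthetic-data generator. The defaults emulate
#' the study conditions the package targets: 47 pre-radiotherapy and 64
#' post-radiotherapy subjects, 240 BOLD frames at TR 2.4 s, a 164-region
#' scheme (100 cortical + 14 subcortical + 50 white matter), block-constant
#' baseline correlations, post-group Fisher-z reductions on a set of
#' white-matter and gray-matter regions, and radiation-dose variables with
#' prescribed partial correlations to specific GW-FCS values.
#'
#' @param n_pre,n_post Subjects per group.
#' @param n_frames BOLD frames acquired per subject (before volume dropping).
#' @param tr Repetition time in seconds.
#' @param n_cortical,n_subcortical,n_wm Region counts of the scheme.
#' @param baseline_wm_corr Baseline Pearson correlation between any two
#'   white-matter regions, in `[0, 1)`.
#' @param baseline_gw_corr Baseline correlation between a gray-matter and a
#'   white-matter region, in `[0, 1)`.
#' @param baseline_gm_corr Baseline correlation between two gray-matter
#'   regions, in `[0, 1)` (block level not targeted by any FCS statistic,
#'   but the joint matrix needs one).
#' @param effect_map Tibble with columns `region`, `delta_z`: for the post
#'   group, the named region's correlations to its FCS family are lowered so
#'   its mean Fisher-z drops by `delta_z`. `NULL` for a null cohort.
#' @param dose_targets Tibble with columns `region`, `dose_var`, `target_r`:
#'   dose variables to attach to post-group subjects with the given partial
#'   correlation (age, sex, mean FD as covariates) to that region's GW-FCS.
#'   Only the first row per `dose_var` drives the construction. `NULL` for
#'   no dose variables.
#' @param n_dose Number of post-group subjects carrying dose values.
#' @param motion_spike_rate Per-frame probability of a motion spike.
#' @param age_mean,age_sd Length-2 vectors `(pre, post)` of age moments.
#' @param sex_male_prob Probability of male sex (both groups).
#' @param euler_mean,euler_sd Moments of the simulated surface Euler number.
#' @param seed Master seed; every subject-level stream derives from it.
#' @return A list of class `wmfcs_config`.
#' @examples
#' cfg <- cohort_config(n_pre = 5, n_post = 5, n_frames = 40,
#'                      n_cortical = 8, n_subcortical = 2, n_wm = 6,
#'                      effect_map = NULL, dose_targets = NULL, seed = 7)
#' @export
cohort_config <- function(n_pre = 47, n_post = 64,
                          n_frames = 240, tr = 2.4,
                          n_cortical = 100, n_subcortical = 14, n_wm = 50,
                          baseline_wm_corr = 0.32,
                          baseline_gw_corr = 0.28,
                          baseline_gm_corr = 0.30,
                          effect_map = default_effect_map(),
                          dose_targets = default_dose_targets(),
                          n_dose = 37,
                          motion_spike_rate = 0.02,
                          age_mean = c(46.7, 43.4), age_sd = c(9.6, 9.9),
                          sex_male_prob = 0.75,
                          euler_mean = -50, euler_sd = 15,
                          seed = 1L) {
  assert_scalar_number(n_pre, "n_pre", min = 2)
  assert_scalar_number(n_post, "n_post", min = 2)
  if (n_pre + n_post <= 5) {
    abort("Total subjects must exceed the number of model covariates + 2.")
  }
  assert_scalar_number(n_frames, "n_frames", min = 1)
  assert_scalar_number(tr, "tr", min = 1e-6)
  for (nm in c("baseline_wm_corr", "baseline_gw_corr", "baseline_gm_corr")) {
    assert_scalar_number(get(nm), nm, min = 0, max = 1 - 1e-12)
  }
  assert_scalar_number(motion_spike_rate, "motion_spike_rate",
                       min = 0, max = 1 - 1e-12)
  if (!is.null(effect_map)) {
    stopifnot(all(c("region", "delta_z") %in% names(effect_map)))
  }
  if (!is.null(dose_targets)) {
    stopifnot(all(c("region", "dose_var", "target_r") %in% names(dose_targets)))
    if (any(abs(dose_targets$target_r) >= 1)) {
      abort("All `target_r` must lie strictly inside (-1, 1).")
    }
  }
  cfg <- list(
    n_pre = as.integer(n_pre), n_post = as.integer(n_post),
    n_frames = as.integer(n_frames), tr = tr,
    n_cortical = as.integer(n_cortical),
    n_subcortical = as.integer(n_subcortical),
    n_wm = as.integer(n_wm),
    baseline_wm_corr = baseline_wm_corr,
    baseline_gw_corr = baseline_gw_corr,
    baseline_gm_corr = baseline_gm_corr,
    effect_map = effect_map, dose_targets = dose_targets,
    n_dose = as.integer(n_dose),
    motion_spike_rate = motion_spike_rate,
    age_mean = age_mean, age_sd = age_sd,
    sex_male_prob = sex_male_prob,
    euler_mean = euler_mean, euler_sd = euler_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "wmfcs_config"
  cfg
}

#' Default summary-matched effect map
#'
#' Post-group Fisher-z reductions for five white-matter and six gray-matter
#' regions, matched to the group mean differences of the reference summary
#' table (pre minus post, z units). These are summary-matched simulation
#' targets, not patient data.
#'
#' @return A tibble with columns `region` and `delta_z`.
#' @export
default_effect_map <- function() {
  tibble::tribble(
    ~region, ~delta_z,
    "lh_Superior_cerebellar_peduncle", 0.06,
    "rh_Anterior_limb_of_internal_capsule", 0.06,
    "rh_Posterior_thalamic_radiation", 0.08,
    "lh_Posterior_thalamic_radiation", 0.08,
    "lh_Tapetum", 0.06,
    "rh_Caudate", 0.07,
    "lh_Vis_4", 0.07,
    "lh_Vis_5", 0.06,
    "lh_Vis_8", 0.08,
    "rh_Vis_4", 0.06,
    "rh_Default_PFCv_2", 0.08
  )
}

#' Default summary-matched dose targets
#'
#' Partial correlations (age, sex and mean FD as covariates) between GW-FCS
#' of visual-cortex regions and the maximum radiation dose delivered to the
#' brainstem and left temporal lobe.
#'
#' @return A tibble with columns `region`, `dose_var`, `target_r`.
#' @export
default_dose_targets <- function() {
  tibble::tribble(
    ~region, ~dose_var, ~target_r,
    "lh_Vis_8", "mdrt_brainstem", -0.35,
    "lh_Vis_8", "mdrt_left_temporal", -0.46,
    "rh_Vis_4", "mdrt_left_temporal", -0.38
  )
}

#' Build a group's target region-correlation matrix
#'
#' Constructs a block-constant Pearson correlation matrix over the scheme's
#' regions (WM--WM, GM--WM and GM--GM levels) and, for the post group,
#' lowers each affected region's correlations to its FCS family so that the
#' implied mean Fisher-z over that family drops by the configured amount
#' (entries move as `r' = tanh(atanh(r) - delta_z)`, so a single-region
#' effect is exact). The result is checked for positive definiteness.
#'
#' @param scheme Parcellation scheme tibble.
#' @param baseline_wm_corr,baseline_gw_corr,baseline_gm_corr Block baselines
#'   in `[0, 1)`.
#' @param effect_map Tibble (`region`, `delta_z`) or `NULL`.
#' @param group `"pre"` (baseline matrix) or `"post"` (effects applied).
#' @return A symmetric positive-definite correlation matrix with unit
#'   diagonal, region names on both dimensions.
#' @export
build_target_correlation <- function(scheme,
                                     baseline_wm_corr = 0.32,
                                     baseline_gw_corr = 0.28,
                                     baseline_gm_corr = 0.30,
                                     effect_map = NULL,
                                     group = c("pre", "post")) {
  group <- match.arg(group)
  validate_scheme(scheme)
  for (nm in c("baseline_wm_corr", "baseline_gw_corr", "baseline_gm_corr")) {
    assert_scalar_number(get(nm), nm, min = 0, max = 1 - 1e-12)
  }
  n <- nrow(scheme)
  is_wm <- scheme$tissue_class == "wm"
  if (sum(is_wm) < 2) abort("Scheme needs at least 2 white-matter regions.")

  R <- matrix(baseline_gm_corr, n, n)
  R[is_wm, is_wm] <- baseline_wm_corr
  R[!is_wm, is_wm] <- baseline_gw_corr
  R[is_wm, !is_wm] <- baseline_gw_corr
  diag(R) <- 1
  dimnames(R) <- list(scheme$name, scheme$name)

  if (group == "post" && !is.null(effect_map) && nrow(effect_map) > 0) {
    unknown <- setdiff(effect_map$region, scheme$name)
    if (length(unknown)) {
      abort(paste0("effect_map names regions absent from the scheme: ",
                   paste(unknown, collapse = ", ")))
    }
    for (k in seq_len(nrow(effect_map))) {
      reg <- effect_map$region[k]
      delta <- effect_map$delta_z[k]
      i <- match(reg, scheme$name)
      family <- if (is_wm[i]) which(is_wm & scheme$name != reg) else which(is_wm)
      r_new <- tanh(atanh(R[i, family]) - delta)
      if (any(abs(r_new) >= 1)) {
        abort(sprintf(
          "Effect on region %s drives a correlation outside (-1, 1).", reg))
      }
      R[i, family] <- r_new
      R[family, i] <- r_new
    }
  }

  ok <- tryCatch({ chol(R); TRUE }, error = function(e) FALSE)
  if (!ok) {
    blocks <- if (!is.null(effect_map) && group == "post") {
      paste(effect_map$region, collapse = ", ")
    } else "baseline blocks"
    abort(paste0(
      "Target correlation matrix is not positive definite; offending ",
      "construction: ", blocks,
      sprintf(" (baselines wm=%.3g, gw=%.3g, gm=%.3g).",
              baseline_wm_corr, baseline_gw_corr, baseline_gm_corr)))
  }
  R
}

#' Simulate a rigid-motion trace with optional censorable spikes
#'
#' Baseline motion is a small-increment random walk in three translations
#' (mm) and three rotations (radians), tuned so framewise displacement stays
#' far below the 0.5 mm censoring threshold. With probability `spike_rate`
#' each frame (from the second on) receives a step displacement large enough
#' that its FD exceeds 0.5 mm; the injected frame indices are returned in
#' the `spike_frames` attribute for use as a test oracle.
#'
#' @param n_frames Number of frames.
#' @param spike_rate Per-frame spike probability in `[0, 1)`.
#' @param seed Optional integer seed.
#' @param jitter_trans_sd,jitter_rot_sd Baseline increment SDs (mm, rad).
#' @param spike_min,spike_max Spike step magnitude range (mm).
#' @return A tibble with columns `trans_x`, `trans_y`, `trans_z` (mm) and
#'   `rot_x`, `rot_y`, `rot_z` (radians), one row per frame, with attribute
#'   `spike_frames`.
#' @export
simulate_motion <- function(n_frames, spike_rate = 0, seed = NULL,
                            jitter_trans_sd = 0.008, jitter_rot_sd = 8e-5,
                            spike_min = 0.7, spike_max = 1.2) {
  assert_scalar_number(n_frames, "n_frames", min = 1)
  assert_scalar_number(spike_rate, "spike_rate", min = 0, max = 1 - 1e-12)
  if (!is.null(seed)) set.seed(seed)
  n_frames <- as.integer(n_frames)

  inc <- cbind(matrix(rnorm(n_frames * 3, sd = jitter_trans_sd), n_frames, 3),
               matrix(rnorm(n_frames * 3, sd = jitter_rot_sd), n_frames, 3))
  inc[1, ] <- 0
  spike_frames <- integer(0)
  if (n_frames > 1 && spike_rate > 0) {
    hit <- which(rbinom(n_frames - 1L, 1L, spike_rate) == 1L) + 1L
    if (length(hit)) {
      spike_frames <- hit
      steps <- runif(length(hit), spike_min, spike_max) *
        sample(c(-1, 1), length(hit), replace = TRUE)
      inc[hit, 1] <- inc[hit, 1] + steps
    }
  }
  pos <- apply(inc, 2, cumsum)
  if (n_frames == 1L) pos <- matrix(pos, nrow = 1L)
  colnames(pos) <- motion_cols
  trace <- tibble::as_tibble(as.data.frame(pos))
  attr(trace, "spike_frames") <- spike_frames
  trace
}

#' Simulate a radiation-dose variable with a prescribed partial correlation
#'
#' Builds a dose vector (in Gray) whose population partial correlation with
#' `fcs_values`, given the covariates, equals `target_partial_r`: the dose
#' is an affine combination of the covariate-residualized FCS (weight
#' `target_partial_r`) and covariate-residualized independent noise (weight
#' `sqrt(1 - r^2)`), rescaled to a Gray-like location and spread. The sample
#' partial-correlation estimate converges to the target as n grows and has
#' the usual `(1 - r^2)/sqrt(n)`-scale sampling spread.
#'
#' @param fcs_values Numeric vector of per-subject FCS values.
#' @param covariates Data frame or matrix of covariates (one row per
#'   subject), e.g. age, sex, mean FD.
#' @param target_partial_r Target partial correlation, strictly inside
#'   `(-1, 1)`.
#' @param seed Optional integer seed.
#' @param dose_mean,dose_sd Location and spread of the returned dose (Gy).
#' @return Numeric vector of doses (Gray), one per subject.
#' @export
simulate_dose <- function(fcs_values, covariates, target_partial_r,
                          seed = NULL, dose_mean = 54, dose_sd = 6) {
  assert_scalar_number(target_partial_r, "target_partial_r",
                       min = -1 + 1e-12, max = 1 - 1e-12)
  x <- as.numeric(fcs_values)
  C <- as.matrix(covariates)
  storage.mode(C) <- "double"
  n <- length(x)
  g <- ncol(C)
  if (nrow(C) != n) abort("`covariates` must have one row per subject.")
  if (n < g + 3) abort("Need at least `ncol(covariates) + 3` subjects.")
  if (sd(x) == 0) abort("`fcs_values` is constant: partial correlation undefined.")
  if (!is.null(seed)) set.seed(seed)

  X <- cbind(1, C)
  ex <- lm.fit(X, x)$residuals
  if (sd(ex) == 0) {
    abort("FCS is collinear with the covariates: residual variance is zero.")
  }
  eu <- lm.fit(X, rnorm(n))$residuals
  latent <- target_partial_r * ex / sd(ex) +
    sqrt(1 - target_partial_r^2) * eu / sd(eu)
  dose_mean + dose_sd * latent
}

#' Simulate a complete synthetic cohort
#'
#' Generates subject metadata (age, sex, Euler number, clinical staging),
#' per-subject motion traces with censorable spikes, and per-subject region
#' time series drawn from a zero-mean multivariate normal whose correlation
#' matrix comes from [build_target_correlation()]; post-group subjects use
#' the effect-modified matrix. If dose targets are configured, dose values
#' are attached to a subset of post-group subjects via [simulate_dose()],
#' using each subject's GW-FCS of the target region (computed from the raw
#' generated series) and age/sex/mean-FD covariates.
#'
#' Fully deterministic given `config$seed`: subject-level streams are
#' derived from the master seed.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `wmfcs_cohort`: a list with `records`
#'   (subject tibble), `motion` (named list of motion tibbles), `timeseries`
#'   (named list of regions x frames matrices), `scheme`, and `config`.
#' @examples
#' cfg <- cohort_config(n_pre = 4, n_post = 4, n_frames = 30,
#'                      n_cortical = 6, n_subcortical = 2, n_wm = 4,
#'                      effect_map = NULL, dose_targets = NULL, seed = 1)
#' coh <- simulate_cohort(cfg)
#' coh$records
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "wmfcs_config"))
  scheme <- default_scheme(config$n_cortical, config$n_subcortical,
                           config$n_wm)
  R_pre <- build_target_correlation(
    scheme, config$baseline_wm_corr, config$baseline_gw_corr,
    config$baseline_gm_corr, effect_map = NULL, group = "pre")
  R_post <- build_target_correlation(
    scheme, config$baseline_wm_corr, config$baseline_gw_corr,
    config$baseline_gm_corr, effect_map = config$effect_map, group = "post")
  chol_pre <- chol(R_pre)
  chol_post <- chol(R_post)

  n <- config$n_pre + config$n_post
  group <- rep(c("pre", "post"), c(config$n_pre, config$n_post))

  set.seed(config$seed)
  gi <- ifelse(group == "pre", 1L, 2L)
  age <- rnorm(n, mean = config$age_mean[gi], sd = config$age_sd[gi])
  sex <- ifelse(runif(n) < config$sex_male_prob, "male", "female")
  euler <- round(rnorm(n, config$euler_mean, config$euler_sd))
  # clinical staging with missing records, proportions as in the emulated
  # study table (pre 4/34/9 of 47; post 7/45/12 of 64)
  staging_probs <- list(pre = c(4, 34, 9) / 47, post = c(7, 45, 12) / 64)
  staging <- vapply(group, function(gr) {
    sample(c("I/II", "III/IV", NA_character_), 1L,
           prob = staging_probs[[gr]])
  }, character(1))

  records <- tibble::tibble(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = factor(group, levels = c("pre", "post")),
    age = age,
    sex = factor(sex, levels = c("female", "male")),
    euler = as.integer(euler),
    staging = staging,
    mean_fd = NA_real_,
    mdrt_brainstem = NA_real_,
    mdrt_left_temporal = NA_real_
  )

  motion <- vector("list", n)
  timeseries <- vector("list", n)
  for (i in seq_len(n)) {
    motion[[i]] <- simulate_motion(config$n_frames, config$motion_spike_rate,
                                   seed = derive_seed(config$seed, i))
    ch <- if (group[i] == "pre") chol_pre else chol_post
    set.seed(derive_seed(config$seed, n + i))
    ts <- t(mvn_draw(config$n_frames, ch))
    rownames(ts) <- scheme$name
    attr(ts, "tr") <- config$tr
    timeseries[[i]] <- ts
  }
  names(motion) <- names(timeseries) <- records$subject_id

  if (!is.null(config$dose_targets) && nrow(config$dose_targets) > 0 &&
      config$n_dose > 0) {
    records <- attach_dose(records, timeseries, motion, scheme, config)
  }

  structure(list(records = records, motion = motion,
                 timeseries = timeseries, scheme = scheme, config = config),
            class = "wmfcs_cohort")
}

# Internal: attach dose variables to a subset of post-group subjects.
# Each dose variable is constructed from its first listed target
# (region, partial r); additional rows for the same variable are emergent,
# not enforced.
attach_dose <- function(records, timeseries, motion, scheme, config) {
  post_idx <- which(records$group == "post")
  n_dose <- min(config$n_dose, length(post_idx))
  set.seed(derive_seed(config$seed, 999983L))
  dosed <- sort(sample(post_idx, n_dose))
  if (n_dose < 6) {
    warn("Fewer than 6 dosed subjects: dose construction skipped.")
    return(records)
  }

  mean_fd <- vapply(dosed, function(i) {
    tr <- as_motion_matrix(motion[[i]])
    keep <- tr[-seq_len(min(5L, nrow(tr) - 1L)), , drop = FALSE]
    mean(compute_fd(keep)$fd)
  }, numeric(1))
  covs <- cbind(age = records$age[dosed],
                sex = as.integer(records$sex[dosed] == "male"),
                mean_fd = mean_fd)

  targets <- config$dose_targets
  first <- targets[!duplicated(targets$dose_var), , drop = FALSE]
  for (k in seq_len(nrow(first))) {
    reg <- first$region[k]
    if (!reg %in% scheme$name) {
      abort(sprintf("Dose target region %s is absent from the scheme.", reg))
    }
    fcs_vals <- vapply(dosed, function(i) {
      fc <- fc_matrix(timeseries[[i]])
      gw <- gw_fcs(fc, scheme)
      gw$value[gw$region == reg]
    }, numeric(1))
    dose <- simulate_dose(fcs_vals, covs, first$target_r[k],
                          seed = derive_seed(config$seed, 500000L + k))
    records[[first$dose_var[k]]][dosed] <- dose
  }
  records
}

#' @export
print.wmfcs_cohort <- function(x, ...) {
  cat(sprintf(
    "<wmfcs_cohort> %d subjects (%d pre, %d post), %d regions x %d frames\n",
    nrow(x$records), sum(x$records$group == "pre"),
    sum(x$records$group == "post"), nrow(x$scheme), x$config$n_frames))
  invisible(x)
}

#' Render region time series onto a voxel grid
#'
#' Produces a 4D BOLD array and a matching 3D label volume in which every
#' voxel of a region carries that region's series plus independent Gaussian
#' noise. Voxels are allotted to regions in equal contiguous blocks of the
#' linearized grid; leftover voxels stay unlabeled.
#'
#' @param region_ts Regions x frames matrix (rownames = region names).
#' @param scheme Parcellation scheme tibble (row order = matrix row order).
#' @param grid_shape Integer vector of length 3; `prod(grid_shape)` must be
#'   at least the number of regions.
#' @param voxel_noise_sd SD of i.i.d. voxel noise added to the region signal.
#' @param seed Optional integer seed.
#' @return A list with `bold` (4D array) and `labels` (3D integer array of
#'   scheme ids, 0 = unlabeled).
#' @export
render_voxel_data <- function(region_ts, scheme, grid_shape = c(7, 6, 4),
                              voxel_noise_sd = 0, seed = NULL) {
  region_ts <- as_ts_matrix(region_ts)
  validate_scheme(scheme)
  if (length(grid_shape) != 3L) abort("`grid_shape` must have length 3.")
  n_reg <- nrow(scheme)
  n_vox <- prod(grid_shape)
  if (n_vox < n_reg) {
    abort(sprintf("Grid of %d voxels cannot host %d regions (need >= 1 voxel each).",
                  n_vox, n_reg))
  }
  if (nrow(region_ts) != n_reg) {
    abort("`region_ts` must have one row per scheme region.")
  }
  if (!is.null(seed)) set.seed(seed)

  per <- n_vox %/% n_reg
  assign_vec <- c(rep(scheme$id, each = per),
                  rep(0L, n_vox - per * n_reg))
  labels <- array(as.integer(assign_vec), dim = grid_shape)

  n_frames <- ncol(region_ts)
  flat <- matrix(0, n_vox, n_frames)
  lab_idx <- match(assign_vec, scheme$id)
  in_mask <- !is.na(lab_idx)
  flat[in_mask, ] <- region_ts[lab_idx[in_mask], , drop = FALSE]
  if (voxel_noise_sd > 0) {
    flat[in_mask, ] <- flat[in_mask, ] +
      matrix(rnorm(sum(in_mask) * n_frames, sd = voxel_noise_sd),
             sum(in_mask), n_frames)
  }
  bold <- array(flat, dim = c(grid_shape, n_frames))
  list(bold = bold, labels = labels)
}

#' Write a synthetic cohort to disk
#'
#' Writes `participants.tsv`, `scheme.tsv`, one motion TSV and one region
#' time-series TSV per subject (frames in rows, regions in columns with a
#' header of region names). With `nifti = TRUE`, additionally renders each
#' subject's series onto a voxel grid and writes gzipped NIfTI BOLD plus a
#' shared label volume.
#'
#' @param cohort A `wmfcs_cohort`.
#' @param dir Output directory (created if needed).
#' @param nifti Also write NIfTI volumes (default `FALSE`).
#' @param grid_shape Grid used when `nifti = TRUE`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, nifti = FALSE, grid_shape = c(7, 6, 4)) {
  stopifnot(inherits(cohort, "wmfcs_cohort"))
  dir.create(file.path(dir, "motion"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "timeseries"), showWarnings = FALSE)
  readr::write_tsv(cohort$records, file.path(dir, "participants.tsv"))
  write_scheme(cohort$scheme, file.path(dir, "scheme.tsv"))
  for (id in cohort$records$subject_id) {
    readr::write_tsv(cohort$motion[[id]],
                     file.path(dir, "motion", paste0(id, "_motion.tsv")))
    ts_df <- tibble::as_tibble(t(cohort$timeseries[[id]]))
    readr::write_tsv(ts_df,
                     file.path(dir, "timeseries", paste0(id, "_ts.tsv")))
  }
  if (nifti) {
    dir.create(file.path(dir, "nifti"), showWarnings = FALSE)
    first <- TRUE
    for (id in cohort$records$subject_id) {
      vox <- render_voxel_data(cohort$timeseries[[id]], cohort$scheme,
                               grid_shape = grid_shape)
      RNifti::writeNifti(RNifti::asNifti(vox$bold),
                         file.path(dir, "nifti", paste0(id, "_bold.nii.gz")))
      if (first) {
        RNifti::writeNifti(RNifti::asNifti(vox$labels),
                           file.path(dir, "nifti", "labels.nii.gz"))
        first <- FALSE
      }
    }
  }
  invisible(dir)
}
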