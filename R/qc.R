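#' Power's framewise displacement
#'
#' FD at frame t (t >= 2) is the sum of the absolute frame-to-frame changes
#' of the three translations plus `head_radius` times the sum of absolute
#' rotation changes (small-angle arc length on a sphere of that radius).
#' The first frame has FD 0 by convention. Frames with FD above `threshold`
#' are flagged as motion outliers.
#'
#' @param trace Motion trace: tibble or matrix with columns
#'   `trans_x`, `trans_y`, `trans_z` (mm) and `rot_x`, `rot_y`, `rot_z`.
#' @param head_radius Sphere radius in mm converting rotations to
#'   displacements (default 50, the metric's usual convention).
#' @param threshold Outlier threshold in mm (default 0.5).
#' @param rotation_units `"radians"` (default) or `"degrees"`.
#' @return A tibble with columns `frame`, `fd` (mm) and `outlier` (logical),
#'   with attribute `threshold`.
#' @examples
#' tr <- tibble::tibble(trans_x = c(0, 0.1), trans_y = 0, trans_z = 0,
#'                      rot_x = c(0, 0.002), rot_y = 0, rot_z = 0)
#' compute_fd(tr)  # FD at frame 2 = 0.1 + 50 * 0.002 = 0.2
#' @export
compute_fd <- function(trace, head_radius = 50, threshold = 0.5,
                       rotation_units = c("radians", "degrees")) {
  rotation_units <- match.arg(rotation_units)
  m <- as_motion_matrix(trace)
  assert_scalar_number(head_radius, "head_radius", min = 1e-9)
  if (!all(is.finite(m))) {
    bad <- which(!apply(is.finite(m), 1, all))[1]
    abort(sprintf("Non-finite motion parameter at frame %d.", bad))
  }
  if (rotation_units == "degrees") {
    m[, 4:6] <- m[, 4:6] * pi / 180
  }
  n <- nrow(m)
  fd <- numeric(n)
  if (n > 1) {
    d <- abs(diff(m))
    fd[-1] <- rowSums(d[, 1:3, drop = FALSE]) +
      head_radius * rowSums(d[, 4:6, drop = FALSE])
  }
  out <- tibble::tibble(frame = seq_len(n), fd = fd, outlier = fd > threshold)
  attr(out, "threshold") <- threshold
  out
}

#' Modified Z-scores (median/MAD based)
#'
#' `score_i = 0.6745 * (x_i - median) / MAD` with
#' `MAD = median(|x - median|)`. When the MAD is zero the mean absolute
#' deviation takes its place (`0.6745 * (x_i - median) /
#' (1.253314 * mean|x - median|)`); if that is zero too (all values equal),
#' all scores are 0. Used to flag poor-quality surface reconstructions by
#' their Euler number (scores below -3.5 are conventionally excluded).
#'
#' @param values Numeric vector, length at least 3.
#' @return Numeric vector of scores, same length.
#' @examples
#' modified_zscore(c(-20, -22, -18, -21, -200))
#' @export
modified_zscore <- function(values) {
  x <- as.numeric(values)
  if (length(x) < 3) abort("`values` must contain at least 3 numbers.")
  if (anyNA(x) || !all(is.finite(x))) abort("`values` must be finite.")
  med <- median(x)
  dev <- abs(x - med)
  mad0 <- median(dev)
  if (mad0 > 0) {
    0.6745 * (x - med) / mad0
  } else {
    mean_ad <- mean(dev)
    if (mean_ad == 0) return(rep(0, length(x)))
    0.6745 * (x - med) / (1.253314 * mean_ad)
  }
}

#' Subject-level quality control report
#'
#' Applies the three subject-exclusion rules: Euler-number modified Z-score
#' below `euler_threshold`, mean framewise displacement above `mean_fd_max`,
#' and motion-outlier ratio (flagged frames / total frames) above
#' `ratio_max`. Any single rule triggers exclusion (`rule = "any"`); set
#' `rule = "both_motion"` to require the two motion criteria jointly.
#' The computed mean FD is written back into the records for use as a model
#' covariate downstream.
#'
#' @param records Subject tibble with columns `subject_id` and `euler`.
#' @param fd_list Named list (by subject id) of FD tibbles from
#'   [compute_fd()].
#' @param euler_threshold Modified-Z cutoff (default -3.5).
#' @param mean_fd_max Mean FD cutoff in mm (default 0.5).
#' @param ratio_max Outlier-ratio cutoff (default 0.3).
#' @param rule `"any"` (either motion criterion excludes, default) or
#'   `"both_motion"` (both must fail).
#' @return A tibble (one row per subject): `subject_id`, `euler_z`,
#'   `mean_fd`, `outlier_ratio`, `included`, `exclusion_reasons`
#'   (comma-separated; empty when included), plus all original record
#'   columns with `mean_fd` filled in.
#' @export
qc_subjects <- function(records, fd_list, euler_threshold = -3.5,
                        mean_fd_max = 0.5, ratio_max = 0.3,
                        rule = c("any", "both_motion")) {
  rule <- match.arg(rule)
  missing <- setdiff(records$subject_id, names(fd_list))
  if (length(missing)) {
    abort(paste0("Missing FD series for subject(s): ",
                 paste(missing, collapse = ", ")))
  }
  euler_z <- modified_zscore(records$euler)
  mean_fd <- unname(vapply(records$subject_id,
                           function(id) mean(fd_list[[id]]$fd), numeric(1)))
  ratio <- unname(vapply(records$subject_id,
                         function(id) mean(fd_list[[id]]$outlier),
                         numeric(1)))

  fail_euler <- euler_z < euler_threshold
  fail_fd <- mean_fd > mean_fd_max
  fail_ratio <- ratio > ratio_max
  fail_motion <- if (rule == "any") fail_fd | fail_ratio else fail_fd & fail_ratio
  included <- !fail_euler & !fail_motion

  reasons <- purrr::pmap_chr(
    list(fail_euler, fail_fd, fail_ratio, fail_motion),
    function(fe, ff, fr, fm) {
      r <- character(0)
      if (fe) r <- c(r, "euler")
      if (fm) {
        if (ff) r <- c(r, "mean_fd")
        if (fr) r <- c(r, "outlier_ratio")
      }
      paste(r, collapse = ",")
    })

  out <- records
  out$mean_fd <- unname(mean_fd)
  dplyr::bind_cols(
    tibble::tibble(subject_id = records$subject_id,
                   euler_z = euler_z,
                   mean_fd = mean_fd,
                   outlier_ratio = ratio,
                   included = included,
                   exclusion_reasons = reasons),
    dplyr::select(out, -dplyr::any_of(c("subject_id", "mean_fd")))
  )
}
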