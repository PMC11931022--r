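#' Fisher-z functional connectivity matrix
#'
#' Pearson correlations between all region pairs, Fisher-z transformed
#' (`atanh`). Correlations are clipped to `|r| <= 1 - 1e-7` before the
#' transform so z stays finite (clipping is reported). The diagonal is
#' masked as `NA`. Regions with zero temporal variance get `NA` rows and
#' columns, with a warning.
#'
#' @param ts Regions x frames matrix (at least 3 frames).
#' @param clip Correlation clipping bound (default `1 - 1e-7`).
#' @return A symmetric regions x regions matrix of class `wmfcs_fc` with
#'   `NA` diagonal and region names on both dimensions.
#' @examples
#' ts <- matrix(rnorm(4 * 100), 4, dimnames = list(paste0("r", 1:4), NULL))
#' z <- fc_matrix(ts)
#' @export
fc_matrix <- function(ts, clip = 1 - 1e-7) {
  ts <- as_ts_matrix(ts)
  if (ncol(ts) < 3) abort("Need at least 3 frames to correlate.")
  sds <- apply(ts, 1, sd)
  degenerate <- sds == 0 | !is.finite(sds)
  if (any(degenerate)) {
    warn(sprintf("%d zero-variance region(s) set to NA: %s",
                 sum(degenerate),
                 paste(head(rownames(ts)[degenerate], 5), collapse = ", ")))
  }
  r <- suppressWarnings(cor(t(ts)))
  r[degenerate, ] <- NA_real_
  r[, degenerate] <- NA_real_
  off <- abs(r) > clip & row(r) != col(r)
  n_clipped <- sum(off, na.rm = TRUE)
  if (n_clipped > 0) {
    warn(sprintf("%d off-diagonal correlation(s) clipped to |r| = %g.",
                 n_clipped, clip))
    r[which(off)] <- sign(r[which(off)]) * clip
  }
  z <- atanh(r)
  diag(z) <- NA_real_
  class(z) <- c("wmfcs_fc", class(z))
  z
}

fc_as_matrix <- function(fc) {
  z <- unclass(fc)
  if (!is.matrix(z) || nrow(z) != ncol(z)) {
    abort("`fc` must be a square connectivity matrix.")
  }
  z
}

scheme_index <- function(fc, scheme, names) {
  if (!is.null(rownames(fc))) {
    idx <- match(names, rownames(fc))
    if (anyNA(idx)) {
      abort("Scheme regions missing from the connectivity matrix.")
    }
    idx
  } else {
    match(names, scheme$name)
  }
}

#' White-matter functional connectivity strength (WW-FCS)
#'
#' For every white-matter region, the arithmetic mean of its Fisher-z
#' connectivity with the other white-matter regions (self-pairs excluded).
#' Missing entries are dropped from the mean with their count recorded.
#'
#' @param fc Connectivity matrix from [fc_matrix()].
#' @param scheme Parcellation scheme tibble.
#' @param absolute Average `|z|` instead of signed z (default `FALSE`;
#'   signed averaging is the defined measure).
#' @return A tibble with columns `region`, `family` (`"WW"`), `value` and
#'   `n_missing` (neighbors excluded from the mean).
#' @export
ww_fcs <- function(fc, scheme, absolute = FALSE) {
  z <- fc_as_matrix(fc)
  validate_scheme(scheme)
  wm <- wm_regions(scheme)
  if (length(wm) < 2) abort("The white-matter family must contain >= 2 regions.")
  idx <- scheme_index(z, scheme, wm)
  sub <- z[idx, idx, drop = FALSE]
  diag(sub) <- NA_real_
  if (absolute) sub <- abs(sub)
  value <- rowMeans(sub, na.rm = TRUE)
  n_missing <- rowSums(is.na(sub)) - 1L
  value[n_missing >= length(wm) - 1L] <- NA_real_
  tibble::tibble(region = wm, family = "WW",
                 value = unname(value), n_missing = unname(n_missing))
}

#' Gray-to-white functional connectivity strength (GW-FCS)
#'
#' For every gray-matter region (cortical or subcortical), the arithmetic
#' mean of its Fisher-z connectivity with all white-matter regions.
#'
#' @inheritParams ww_fcs
#' @return A tibble with columns `region`, `family` (`"GW"`), `value`,
#'   `n_missing`.
#' @export
gw_fcs <- function(fc, scheme, absolute = FALSE) {
  z <- fc_as_matrix(fc)
  validate_scheme(scheme)
  wm <- wm_regions(scheme)
  gm <- gm_regions(scheme)
  if (length(wm) < 1) abort("The white-matter family is empty.")
  wi <- scheme_index(z, scheme, wm)
  gi <- scheme_index(z, scheme, gm)
  sub <- z[gi, wi, drop = FALSE]
  if (absolute) sub <- abs(sub)
  value <- rowMeans(sub, na.rm = TRUE)
  n_missing <- rowSums(is.na(sub))
  value[n_missing >= length(wm)] <- NA_real_
  tibble::tibble(region = gm, family = "GW",
                 value = unname(value), n_missing = unname(n_missing))
}

#' Both FCS families for one subject
#'
#' @inheritParams ww_fcs
#' @return Row-bound [ww_fcs()] and [gw_fcs()] tibbles.
#' @export
compute_fcs <- function(fc, scheme, absolute = FALSE) {
  dplyr::bind_rows(ww_fcs(fc, scheme, absolute = absolute),
                   gw_fcs(fc, scheme, absolute = absolute))
}

#' Subject-level FCS table for a whole cohort
#'
#' Maps [fc_matrix()] + [compute_fcs()] over a list of (cleaned) region
#' time series.
#'
#' @param ts_list Named list of regions x frames matrices (names = subject
#'   ids).
#' @param scheme Parcellation scheme tibble.
#' @return A tibble with columns `subject_id`, `region`, `family`, `value`,
#'   `n_missing`.
#' @export
cohort_fcs <- function(ts_list, scheme) {
  purrr::imap_dfr(ts_list, function(ts, id) {
    dplyr::mutate(compute_fcs(fc_matrix(ts), scheme),
                  subject_id = id, .before = 1)
  })
}

#' Write / read an FCS table
#'
#' TSV with columns `subject_id`, `region`, `family`, `value`
#' (and `n_missing` if present).
#'
#' @param fcs FCS tibble.
#' @param path File path.
#' @return `read_fcs()` returns the tibble; `write_fcs()` the path,
#'   invisibly.
#' @export
write_fcs <- function(fcs, path) {
  readr::write_tsv(fcs, path)
  invisible(path)
}

#' @rdname write_fcs
#' @export
read_fcs <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
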