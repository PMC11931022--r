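#' Drop initial volumes from a time series and its motion trace
#'
#' Removes the first `n` frames from both the region time series and the
#' motion trace, keeping them frame-aligned (signal-equilibration frames are
#' conventionally discarded; 240 acquired frames become 235 with the
#' defaults).
#'
#' @param ts Regions x frames numeric matrix.
#' @param trace Motion trace (tibble/matrix, one row per frame).
#' @param n Number of initial frames to drop (default 5).
#' @return A list with elements `ts` and `trace`.
#' @export
drop_initial_volumes <- function(ts, trace, n = 5) {
  ts <- as_ts_matrix(ts)
  m <- as_motion_matrix(trace)
  if (nrow(m) != ncol(ts)) {
    abort("Motion trace and time series disagree on frame count.")
  }
  if (n >= ncol(ts)) {
    abort(sprintf("Cannot drop %d frames from a %d-frame series.", n, ncol(ts)))
  }
  if (n > 0) {
    keep <- -seq_len(n)
    ts2 <- ts[, keep, drop = FALSE]
    attr(ts2, "tr") <- attr(ts, "tr")
    m <- m[keep, , drop = FALSE]
  } else {
    ts2 <- ts
  }
  list(ts = ts2, trace = tibble::as_tibble(as.data.frame(m)))
}

#' Replace motion-flagged frames by interpolation
#'
#' Frames flagged as motion outliers are replaced, per region, by linear
#' interpolation between the nearest unflagged neighbors; flagged frames at
#' the series edges take the nearest unflagged value. Unflagged frames are
#' untouched. Re-applying with the same flags is a no-op.
#'
#' @param ts Regions x frames matrix.
#' @param fd FD tibble from [compute_fd()] (aligned to `ts` frames), or a
#'   logical vector of flags.
#' @param threshold Recomputes flags as `fd$fd > threshold` when `fd` is an
#'   FD tibble (default 0.5 mm).
#' @return The interpolated matrix, with attribute `frame_provenance`
#'   (`"raw"`/`"interpolated"` per frame).
#' @export
censor_interpolate <- function(ts, fd, threshold = 0.5) {
  ts <- as_ts_matrix(ts)
  flags <- if (is.logical(fd)) fd else fd$fd > threshold
  if (length(flags) != ncol(ts)) {
    abort("FD flags must align with the time-series frames.")
  }
  if (all(flags)) abort("All frames are flagged: nothing left to interpolate from.")
  bad <- which(flags)
  if (length(bad)) {
    good <- which(!flags)
    for (r in seq_len(nrow(ts))) {
      ts[r, bad] <- approx(good, ts[r, good], xout = bad, rule = 2)$y
    }
  }
  attr(ts, "frame_provenance") <-
    ifelse(flags, "interpolated", "raw")
  ts
}

#' Friston 24-parameter nuisance design with polynomial trends
#'
#' Columns, in order: the 6 rigid motion parameters; their one-frame-lagged
#' versions (first frame zero-padded); the squares of both sets; then a
#' linear and a quadratic trend over the frame index (centered and scaled).
#'
#' @param trace Motion trace (tibble/matrix with the 6 canonical columns).
#' @return A frames x 26 numeric matrix with labeled columns.
#' @export
build_friston24 <- function(trace) {
  m <- as_motion_matrix(trace)
  n <- nrow(m)
  if (n < 2) abort("Need at least 2 frames to build the design.")
  lag <- rbind(0, m[-n, , drop = FALSE])
  design <- cbind(m, lag, m^2, lag^2)
  colnames(design) <- c(motion_cols,
                        paste0(motion_cols, "_lag"),
                        paste0(motion_cols, "_sq"),
                        paste0(motion_cols, "_lag_sq"))
  tt <- (seq_len(n) - (n + 1) / 2) / n
  design <- cbind(design, trend_linear = tt, trend_quadratic = tt^2)
  design
}

#' Regress a nuisance design out of a time series
#'
#' Per-region ordinary least squares of the signal on the design plus an
#' intercept; the output is the residual series. Rank-deficient designs are
#' handled by pivoting (collinear columns contribute nothing) with a
#' warning.
#'
#' @param ts Regions x frames matrix.
#' @param design Frames x p numeric matrix (intercept added internally).
#' @return Residual matrix, same shape as `ts`.
#' @export
nuisance_regress <- function(ts, design) {
  ts <- as_ts_matrix(ts)
  design <- as.matrix(design)
  if (!all(is.finite(design))) abort("Nuisance design contains non-finite values.")
  if (nrow(design) != ncol(ts)) {
    abort("Design rows must equal time-series frames.")
  }
  X <- cbind(intercept = 1, design)
  fit <- lm.fit(X, t(ts))
  if (fit$rank < ncol(X)) {
    warn(sprintf("Nuisance design is rank deficient (%d of %d columns used).",
                 fit$rank, ncol(X)))
  }
  res <- t(fit$residuals)
  dimnames(res) <- dimnames(ts)
  attr(res, "tr") <- attr(ts, "tr")
  res
}

# frequencies of the DCT-II basis over n frames at sampling interval tr:
# component k has frequency k / (2 * n * tr)
dct_basis <- function(n, k_set) {
  t_idx <- seq_len(n) - 0.5
  vapply(k_set, function(k) cos(pi * k * t_idx / n), numeric(n))
}

#' High-pass filter by discrete-cosine projection
#'
#' Removes the mean and every discrete-cosine component whose frequency
#' `k / (2 * n_frames * tr)` lies below `cutoff`, by regressing them out;
#' components at or above the cutoff pass through. This is an exact linear
#' projection, so filtering commutes with other projection-based cleaning.
#'
#' @param ts Regions x frames matrix.
#' @param tr Repetition time in seconds (taken from the matrix's `tr`
#'   attribute when omitted).
#' @param cutoff High-pass cutoff in Hz (default 0.01).
#' @return Filtered matrix, same shape.
#' @export
highpass_filter <- function(ts, tr = NULL, cutoff = 0.01) {
  ts <- as_ts_matrix(ts)
  tr <- tr %||% attr(ts, "tr")
  if (is.null(tr)) abort("`tr` must be supplied (or set as an attribute).")
  assert_scalar_number(tr, "tr", min = 1e-9)
  n <- ncol(ts)
  if (n < 8) abort("Need at least 8 frames to high-pass filter.")
  nyquist <- 1 / (2 * tr)
  if (cutoff >= nyquist) {
    abort(sprintf("Cutoff %.4g Hz is at or above Nyquist (%.4g Hz).",
                  cutoff, nyquist))
  }
  k_max <- ceiling(2 * n * tr * cutoff) - 1L
  X <- cbind(intercept = rep(1, n),
             if (k_max >= 1) dct_basis(n, seq_len(k_max)))
  fit <- lm.fit(X, t(ts))
  res <- t(fit$residuals)
  dimnames(res) <- dimnames(ts)
  attr(res, "tr") <- tr
  res
}

#' Full frame-level cleaning pipeline for one subject
#'
#' Applies, in fixed order: initial-volume dropping; framewise-displacement
#' computation on the dropped trace; censoring of FD-flagged frames with
#' neighbor interpolation; then nuisance regression (Friston 24-parameter
#' motion model plus linear and quadratic trends) and discrete-cosine
#' high-pass filtering as one joint least-squares projection onto the
#' orthogonal complement of the combined span. Projecting jointly (rather
#' than one model after the other) keeps the residuals orthogonal to every
#' nuisance and drift column at once; sequential projections onto
#' non-orthogonal subspaces would reintroduce part of what the first stage
#' removed.
#'
#' @param ts Regions x frames matrix (raw).
#' @param trace Motion trace aligned to `ts`.
#' @param tr Repetition time (s); defaults to the matrix's `tr` attribute.
#' @param n_drop Initial frames to discard (default 5).
#' @param fd_threshold Censoring threshold in mm (default 0.5).
#' @param cutoff High-pass cutoff in Hz (default 0.01).
#' @param head_radius FD rotation radius in mm (default 50).
#' @return Cleaned regions x frames matrix with attributes `stages`
#'   (ordered stage names), `fd` (the FD tibble) and `frame_provenance`.
#' @export
clean_timeseries <- function(ts, trace, tr = NULL, n_drop = 5,
                             fd_threshold = 0.5, cutoff = 0.01,
                             head_radius = 50) {
  ts <- as_ts_matrix(ts)
  tr <- tr %||% attr(ts, "tr")
  dropped <- drop_initial_volumes(ts, trace, n = n_drop)
  fd <- compute_fd(dropped$trace, head_radius = head_radius,
                   threshold = fd_threshold)
  censored <- censor_interpolate(dropped$ts, fd, threshold = fd_threshold)
  design <- build_friston24(dropped$trace)
  if (is.null(tr)) abort("`tr` must be supplied (or set as an attribute).")
  n <- ncol(censored)
  nyquist <- 1 / (2 * tr)
  if (cutoff >= nyquist) {
    abort(sprintf("Cutoff %.4g Hz is at or above Nyquist (%.4g Hz).",
                  cutoff, nyquist))
  }
  k_max <- ceiling(2 * n * tr * cutoff) - 1L
  if (k_max >= 1) {
    dct <- dct_basis(n, seq_len(k_max))
    colnames(dct) <- paste0("dct_", seq_len(k_max))
    design <- cbind(design, dct)
  }
  out <- nuisance_regress(censored, design)
  attr(out, "tr") <- tr
  attr(out, "stages") <- c("drop_initial_volumes", "compute_fd",
                           "censor_interpolate", "nuisance_regress",
                           "highpass_filter")
  attr(out, "projection") <- "joint"
  attr(out, "fd") <- fd
  attr(out, "frame_provenance") <- attr(censored, "frame_provenance")
  out
}
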