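# internal helpers shared across modules

# deterministic sub-seed derivation: keeps every derived seed a valid 32-bit
# integer whatever the master seed is
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(i)) %% 2147483647L)
}

# draw n x d rows from N(0, Sigma) given a pre-computed upper Cholesky factor
mvn_draw <- function(n, chol_upper) {
  d <- ncol(chol_upper)
  matrix(rnorm(n * d), n, d) %*% chol_upper
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min || x > max) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, min, max, x))
  }
  invisible(x)
}

# coerce a motion trace (tibble or matrix) to a frames x 6 numeric matrix
# with the canonical column order
motion_cols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")

as_motion_matrix <- function(trace) {
  if (is.data.frame(trace)) {
    missing <- setdiff(motion_cols, names(trace))
    if (length(missing)) {
      abort(paste0("Motion trace is missing columns: ",
                   paste(missing, collapse = ", ")))
    }
    trace <- as.matrix(trace[motion_cols])
  }
  if (!is.matrix(trace) || ncol(trace) != 6L) {
    abort("Motion trace must be a data frame or matrix with 6 columns.")
  }
  storage.mode(trace) <- "double"
  colnames(trace) <- motion_cols
  trace
}

# region x frames numeric matrix with region-name rownames
as_ts_matrix <- function(ts) {
  if (is.data.frame(ts)) ts <- as.matrix(ts)
  if (!is.matrix(ts) || !is.numeric(ts)) {
    abort("Time series must be a numeric matrix (regions x frames).")
  }
  ts
}
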