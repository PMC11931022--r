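# shared fixtures and independent oracles, all built in code

make_scheme <- function(classes) {
  tibble::tibble(id = seq_along(classes),
                 name = paste0("R", seq_along(classes)),
                 hemisphere = "mid",
                 tissue_class = classes)
}

motion_tbl <- function(m) {
  m <- matrix(m, ncol = 6)
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  tibble::as_tibble(as.data.frame(m))
}

zero_motion <- function(n) motion_tbl(matrix(0, n, 6))

# FD oracle: direct loop over the defining formula
fd_oracle <- function(m, radius = 50) {
  m <- as.matrix(m)
  n <- nrow(m)
  fd <- numeric(n)
  for (t in seq_len(n)[-1]) {
    fd[t] <- sum(abs(m[t, 1:3] - m[t - 1, 1:3])) +
      radius * sum(abs(m[t, 4:6] - m[t - 1, 4:6]))
  }
  fd
}

# FCS oracle: naive double loop over pairs
fcs_oracle <- function(z, scheme) {
  wm <- which(scheme$tissue_class == "wm")
  gm <- which(scheme$tissue_class != "wm")
  ww <- vapply(wm, function(i) {
    mean(vapply(setdiff(wm, i), function(j) z[i, j], numeric(1)))
  }, numeric(1))
  gw <- vapply(gm, function(g) {
    mean(vapply(wm, function(j) z[g, j], numeric(1)))
  }, numeric(1))
  list(ww = unname(ww), gw = unname(gw))
}

# BH oracle: exhaustive step-up threshold search returning the rejection set
bh_reject_oracle <- function(p, alpha, m = length(p)) {
  o <- order(p)
  sorted <- p[o]
  ks <- which(sorted <= seq_along(sorted) * alpha / m)
  if (length(ks) == 0) return(rep(FALSE, length(p)))
  p <= sorted[max(ks)]
}

# partial-correlation oracle: precision-matrix identity
pcor_oracle <- function(x, y, C) {
  M <- cbind(x, y, as.matrix(C))
  Om <- solve(stats::cov(M))
  -Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2])
}

# random symmetric z matrix with NA diagonal
random_z <- function(n, seed) {
  set.seed(seed)
  z <- matrix(rnorm(n * n, sd = 0.4), n, n)
  z <- (z + t(z)) / 2
  diag(z) <- NA_real_
  z
}
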