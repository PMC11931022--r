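test_that("pooled t reproduces the printed summary-table statistics", {
  # superior cerebellar peduncle row: 0.25 (0.11) n=47 vs 0.19 (0.10) n=64
  scp <- pooled_t_from_summary(0.25, 0.11, 47, 0.19, 0.10, 64)
  expect_equal(round(scp$statistic, 2), -2.99)
  expect_equal(scp$df, 109)

  # age row: 46.70 (9.55) vs 43.39 (9.93) -> p prints as 0.081
  age <- pooled_t_from_summary(46.70, 9.55, 47, 43.39, 9.93, 64)
  expect_equal(signif(age$p.value, 2), 0.081)

  expect_equal(pooled_t_from_summary(1, 1, 10, 1, 1, 12)$statistic, 0)
  expect_error(pooled_t_from_summary(1, 0, 10, 1, 1, 12), "positive")
})

test_that("BH adjustment matches the hand example and the step-up oracle", {
  p <- c(0.00039, 0.0012, 0.0018, 0.0033, 0.0035)
  expect_equal(fdr_bh(p, m = 50), c(0.0195, 0.030, 0.030, 0.035, 0.035),
               tolerance = 1e-12)
  expect_equal(fdr_bh(0.03, m = 1), 0.03)
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_bh(c(0.1, 0.2), m = 1), "at least")

  # rejection sets agree with the exhaustive threshold search
  set.seed(90)
  for (i in 1:200) {
    p <- runif(sample(3:30, 1))^sample(1:3, 1)
    m <- length(p) + sample(0:20, 1)
    alpha <- runif(1, 0.01, 0.2)
    expect_identical(fdr_bh(p, m) <= alpha, bh_reject_oracle(p, alpha, m))
  }
})

test_that("partial correlation equals the precision-matrix oracle", {
  set.seed(91)
  for (i in 1:20) {
    n <- 12; g <- 3
    C <- matrix(rnorm(n * g), n, g)
    x <- rnorm(n) + C %*% rnorm(g)
    y <- rnorm(n) + C %*% rnorm(g)
    res <- partial_corr(x, y, C)
    expect_equal(res$estimate, pcor_oracle(x, y, C), tolerance = 1e-12)
    expect_equal(res$df, n - 2 - g)
    expect_equal(res$p.value,
                 2 * pt(-abs(res$estimate * sqrt((n - 2 - g) /
                                                 (1 - res$estimate^2))),
                        n - 2 - g))
  }

  # no covariates: plain Pearson correlation
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(partial_corr(x, y)$estimate, cor(x, y), tolerance = 1e-12)

  # y driven purely by covariates: partial r near 0 at large n
  set.seed(92)
  n <- 5000
  C <- matrix(rnorm(n * 2), n, 2)
  y2 <- C %*% c(1, -2) + rnorm(n)
  x2 <- rnorm(n)
  expect_lt(abs(partial_corr(x2, y2, C)$estimate), 0.05)

  expect_error(partial_corr(rep(1, 10), rnorm(10)), "Zero-variance")
})

test_that("region group test reduces to the pooled t without covariates", {
  set.seed(93)
  records <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:40),
    group = factor(rep(c("pre", "post"), each = 20), c("pre", "post")))
  fcs <- tibble::tibble(subject_id = records$subject_id,
                        region = "R1", family = "WW",
                        value = rnorm(40, mean = rep(c(0.3, 0.25), each = 20),
                                      sd = 0.1))
  gt <- region_group_test(fcs, records, covariates = character(0))
  res <- tidy(gt)
  ref <- pooled_t_from_summary(
    mean(fcs$value[1:20]), sd(fcs$value[1:20]), 20,
    mean(fcs$value[21:40]), sd(fcs$value[21:40]), 20)
  expect_equal(res$statistic, ref$statistic, tolerance = 1e-10)
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-10)
  expect_equal(res$estimate, ref$estimate, tolerance = 1e-10)
  expect_equal(res$mean_pre, mean(fcs$value[1:20]))
  expect_equal(res$n_post, 20)

  # relabeled identical distributions at large n: t near 0
  set.seed(94)
  big <- tibble::tibble(
    subject_id = sprintf("b%04d", 1:4000),
    group = factor(rep(c("pre", "post"), each = 2000), c("pre", "post")))
  fcs_big <- tibble::tibble(subject_id = big$subject_id, region = "R1",
                            family = "WW", value = rnorm(4000, 0.3, 0.1))
  gt_big <- region_group_test(fcs_big, big, covariates = character(0))
  expect_lt(abs(tidy(gt_big)$statistic), 2.5)
})

test_that("region group test adjusts for covariates and flags collinearity", {
  set.seed(95)
  n <- 60
  records <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:n),
    group = factor(rep(c("pre", "post"), each = n / 2), c("pre", "post")),
    age = rnorm(n, 45, 10),
    sex = factor(sample(c("male", "female"), n, TRUE), c("female", "male")),
    mean_fd = runif(n, 0.05, 0.3))
  # FCS depends on age only: adjusted group effect should be null-ish,
  # and the age-driven confound is absorbed
  fcs <- tibble::tibble(subject_id = records$subject_id, region = "R1",
                        family = "GW",
                        value = 0.2 + 0.01 * records$age + rnorm(n, 0, 0.02))
  gt <- region_group_test(fcs, records)
  expect_equal(tidy(gt)$n_pre, 30)
  expect_true(abs(tidy(gt)$statistic) < 3)
  g <- glance(gt)
  expect_equal(g$n_regions, 1L)
  expect_equal(g$n_covariates, 3L)

  # collinear covariate: duplicate of the group indicator
  records$dupe <- as.integer(records$group == "post")
  expect_error(region_group_test(fcs, records,
                                 covariates = c("age", "dupe")),
               "Collinear")
})

test_that("family-wise BH uses the configured family sizes", {
  set.seed(96)
  n <- 30
  records <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:n),
    group = factor(rep(c("pre", "post"), each = n / 2), c("pre", "post")))
  fcs <- tidyr::expand_grid(subject_id = records$subject_id,
                            region = c("W1", "W2", "G1")) |>
    dplyr::mutate(family = ifelse(startsWith(region, "W"), "WW", "GW"),
                  value = rnorm(dplyr::n(), 0.3, 0.1))
  gt <- region_group_test(fcs, records, covariates = character(0),
                          fdr_m = c(WW = 50, GW = 114))
  res <- tidy(gt)
  ww <- dplyr::filter(res, family == "WW")
  expect_equal(ww$p.fdr, fdr_bh(ww$p.value, m = 50))
  gw <- dplyr::filter(res, family == "GW")
  expect_equal(gw$p.fdr, fdr_bh(gw$p.value, m = 114))
})

test_that("dose association reports df = n - 2 - g over complete cases", {
  set.seed(97)
  n <- 45
  records <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:n),
    group = factor(rep("post", n), c("pre", "post")),
    age = rnorm(n, 45, 10),
    sex = factor(sample(c("male", "female"), n, TRUE), c("female", "male")),
    mean_fd = runif(n, 0.05, 0.3),
    mdrt_brainstem = c(rnorm(37, 54, 6), rep(NA, 8)))
  fcs <- tibble::tibble(subject_id = records$subject_id, region = "lh_Vis_8",
                        family = "GW", value = rnorm(n, 0.28, 0.05))
  res <- dose_association(fcs, records, dose_vars = "mdrt_brainstem",
                          regions = "lh_Vis_8")
  expect_equal(res$n, 37)
  expect_equal(res$df, 37 - 2 - 3)
  expect_equal(res$n_excluded, 8)

  # shuffled dose: no association
  set.seed(98)
  shuffled <- vapply(1:200, function(i) {
    rec2 <- records
    rec2$mdrt_brainstem <- sample(rec2$mdrt_brainstem)
    dose_association(fcs, rec2, dose_vars = "mdrt_brainstem",
                     regions = "lh_Vis_8")$estimate
  }, numeric(1))
  expect_lt(abs(mean(shuffled)), 0.05)

  records$mdrt_brainstem <- NA_real_
  expect_error(dose_association(fcs, records, dose_vars = "mdrt_brainstem",
                                regions = "lh_Vis_8"),
               "dose-complete")
})

test_that("post hoc power follows the noncentral-t distribution", {
  # null effect: power equals the significance level
  expect_equal(posthoc_power_two_sample(0.3, 0.1, 47, 0.3, 0.1, 64)$power,
               0.05, tolerance = 1e-10)

  # printed-summary configuration: power about 0.84, cross-checked by
  # Monte-Carlo pooled t tests
  pw <- posthoc_power_two_sample(0.25, 0.11, 47, 0.19, 0.10, 64)
  expect_equal(pw$power, 0.84, tolerance = 0.005)
  set.seed(99)
  nrep <- 10000
  x <- matrix(rnorm(47 * nrep, 0.25, 0.11), 47)
  y <- matrix(rnorm(64 * nrep, 0.19, 0.10), 64)
  sp2 <- (46 * apply(x, 2, var) + 63 * apply(y, 2, var)) / 109
  tstat <- (colMeans(y) - colMeans(x)) / sqrt(sp2 * (1 / 47 + 1 / 64))
  mc <- mean(abs(tstat) > qt(0.975, 109))
  expect_equal(mc, pw$power, tolerance = 0.015)

  # power grows to 1 with n at fixed d
  powers <- vapply(c(20, 50, 100, 400),
                   function(n) posthoc_power_two_sample(
                     0.25, 0.11, n, 0.19, 0.10, n)$power, numeric(1))
  expect_true(all(diff(powers) > 0))
  expect_gt(powers[4], 0.999)
})

test_that("demographics table reproduces the printed group comparisons", {
  # sex 2x2 [[36,11],[47,17]] with continuity correction -> p prints 0.87
  records <- tibble::tibble(
    group = factor(rep(c("pre", "post"), c(47, 64)), c("pre", "post")),
    sex = factor(c(rep("male", 36), rep("female", 11),
                   rep("male", 47), rep("female", 17)), c("female", "male")),
    staging = c(rep("I/II", 4), rep("III/IV", 34), rep(NA, 9),
                rep("I/II", 7), rep("III/IV", 45), rep(NA, 12)),
    age = NA_real_)
  records$age <- NULL
  demo <- demographics_table(records)
  sex_row <- demo[demo$variable == "sex", ]
  expect_equal(round(sex_row$p.value, 2), 0.87)
  stg_row <- demo[demo$variable == "clinical staging", ]
  expect_equal(round(stg_row$p.value, 3), 0.675)
  expect_equal(stg_row$n_missing, 21)

  # identical groups: p = 1 everywhere
  ident <- tibble::tibble(
    group = factor(rep(c("pre", "post"), each = 20), c("pre", "post")),
    age = rep(rnorm(20), 2),
    sex = factor(rep(rep(c("male", "female"), c(15, 5)), 2),
                 c("female", "male")))
  demo2 <- demographics_table(ident)
  expect_true(all(demo2$p.value == 1))

  # empty cell falls back to Fisher's exact test
  lop <- tibble::tibble(
    group = factor(rep(c("pre", "post"), each = 10), c("pre", "post")),
    sex = factor(c(rep("male", 10), rep("male", 8), rep("female", 2)),
                 c("female", "male")))
  expect_warning(demo3 <- demographics_table(lop), "Fisher")
  expect_equal(demo3$method[demo3$variable == "sex"], "Fisher exact")
})
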