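test_that("target correlation construction is exact in z-space", {
  sch <- default_scheme(4, 2, 8)
  pre <- build_target_correlation(sch, 0.3, 0.2, 0.25, NULL, "pre")
  expect_true(isSymmetric(pre))
  expect_equal(unname(diag(pre)), rep(1, 14))
  expect_equal(unname(pre["WM_1", "WM_2"]), 0.3)
  expect_equal(unname(pre["lh_Ctx_1", "WM_2"]), 0.2)
  expect_equal(unname(pre["lh_Ctx_1", "rh_Ctx_1"]), 0.25)

  # empty effect map: pre and post identical
  post0 <- build_target_correlation(sch, 0.3, 0.2, 0.25,
                                    effect_map = NULL, group = "post")
  expect_identical(pre, post0)

  # a single-region z reduction lowers that region's family mean z exactly
  em <- tibble::tibble(region = "WM_1", delta_z = 0.06)
  post <- build_target_correlation(sch, 0.3, 0.2, 0.25, em, "post")
  others <- setdiff(wm_regions(sch), "WM_1")
  expect_equal(mean(atanh(pre["WM_1", others])) -
                 mean(atanh(post["WM_1", others])),
               0.06, tolerance = 1e-12)
  # a gray-matter effect touches only its white-matter entries
  em2 <- tibble::tibble(region = "lh_Ctx_1", delta_z = 0.05)
  post2 <- build_target_correlation(sch, 0.3, 0.2, 0.25, em2, "post")
  expect_equal(mean(atanh(pre["lh_Ctx_1", wm_regions(sch)])) -
                 mean(atanh(post2["lh_Ctx_1", wm_regions(sch)])),
               0.05, tolerance = 1e-12)
  expect_equal(post2["lh_Ctx_1", "rh_Ctx_1"], pre["lh_Ctx_1", "rh_Ctx_1"])

  # guards: unknown region; geometrically infeasible reduction
  expect_error(build_target_correlation(
    sch, 0.3, 0.2, 0.25, tibble::tibble(region = "nope", delta_z = 0.1),
    "post"), "absent")
  expect_error(build_target_correlation(
    sch, 0.999, 0.999, 0.999,
    tibble::tibble(region = "WM_1", delta_z = 0.5), "post"),
    "positive definite")
})

test_that("simulated motion stays sub-threshold except at injected spikes", {
  # no spikes: FD comfortably below the censoring threshold
  m0 <- simulate_motion(235, spike_rate = 0, seed = 41)
  expect_true(all(compute_fd(m0)$fd < 0.5))
  expect_length(attr(m0, "spike_frames"), 0)

  # spikes flag exactly the injected frames
  m1 <- simulate_motion(235, spike_rate = 0.1, seed = 42)
  fd1 <- compute_fd(m1)
  expect_setequal(which(fd1$outlier), attr(m1, "spike_frames"))

  # spike fraction within the binomial 99% interval for p = 0.1
  bounds <- qbinom(c(0.005, 0.995), 234, 0.1)
  expect_gte(sum(fd1$outlier), bounds[1])
  expect_lte(sum(fd1$outlier), bounds[2])

  # single frame: FD series is the single value 0
  m2 <- simulate_motion(1, spike_rate = 0.5, seed = 43)
  expect_equal(compute_fd(m2)$fd, 0)

  expect_error(simulate_motion(10, spike_rate = 1.2), "spike_rate")
})

test_that("dose construction attains the target partial correlation", {
  set.seed(51)
  n <- 2000
  covs <- cbind(age = rnorm(n, 45, 10), sex = rbinom(n, 1, 0.75),
                mean_fd = runif(n, 0.05, 0.3))
  fcs <- 0.3 + 0.005 * covs[, "age"] + rnorm(n, sd = 0.1)

  d0 <- simulate_dose(fcs, covs, target_partial_r = 0, seed = 52)
  expect_lt(abs(partial_corr(fcs, d0, covs)$estimate), 0.05)

  d1 <- simulate_dose(fcs, covs, target_partial_r = -0.46, seed = 53)
  est <- partial_corr(fcs, d1, covs)
  expect_equal(est$estimate, -0.46, tolerance = 0.04)
  expect_true(all(d1 > 0))  # Gray-scale values

  expect_error(simulate_dose(rep(0.3, 20), covs[1:20, ], -0.4, seed = 1),
               "constant")
})

test_that("study-scale dose estimates have the expected sampling spread", {
  # n = 37, 400 replicates: estimates bracket the target with SD near
  # the large-sample (1 - r^2)/sqrt(n) scale
  set.seed(55)
  n <- 37
  covs <- cbind(age = rnorm(n, 45, 10), sex = rbinom(n, 1, 0.75),
                mean_fd = runif(n, 0.05, 0.3))
  fcs <- rnorm(n, 0.3, 0.1)
  ests <- vapply(seq_len(400), function(i) {
    d <- simulate_dose(fcs, covs, -0.46, seed = 1000 + i)
    partial_corr(fcs, d, covs)$estimate
  }, numeric(1))
  expect_lt(quantile(ests, 0.1), -0.46)
  expect_gt(quantile(ests, 0.9), -0.46)
  ref_sd <- (1 - 0.46^2) / sqrt(n)
  expect_gt(sd(ests), ref_sd / 2)
  expect_lt(sd(ests), ref_sd * 2)
})

test_that("cohort simulation is deterministic and null when unperturbed", {
  cfg <- cohort_config(n_pre = 40, n_post = 40, n_frames = 100,
                       n_cortical = 6, n_subcortical = 2, n_wm = 8,
                       effect_map = NULL, dose_targets = NULL,
                       motion_spike_rate = 0, seed = 21)
  coh <- simulate_cohort(cfg)
  expect_s3_class(coh, "wmfcs_cohort")
  expect_equal(dim(coh$timeseries[[1]]), c(16, 100))
  expect_equal(nrow(coh$records), 80)
  expect_equal(levels(coh$records$group), c("pre", "post"))

  # bit-reproducible under the same seed
  coh2 <- simulate_cohort(cfg)
  expect_identical(coh$timeseries, coh2$timeseries)
  expect_identical(coh$records, coh2$records)

  # null effect map: group mean WW-FCS difference is small
  fcs <- cohort_fcs(coh$timeseries, coh$scheme)
  ww <- dplyr::filter(fcs, family == "WW")
  ww <- dplyr::inner_join(ww, coh$records[c("subject_id", "group")],
                          by = "subject_id")
  diff <- mean(ww$value[ww$group == "post"]) -
    mean(ww$value[ww$group == "pre"])
  expect_lt(abs(diff), 0.02)
})

test_that("dose targets propagate into the cohort records", {
  cfg <- cohort_config(n_pre = 6, n_post = 30, n_frames = 60,
                       n_cortical = 100, n_subcortical = 14, n_wm = 50,
                       n_dose = 20, motion_spike_rate = 0, seed = 77)
  coh <- simulate_cohort(cfg)
  dosed <- !is.na(coh$records$mdrt_brainstem)
  expect_equal(sum(dosed), 20)
  expect_true(all(coh$records$group[dosed] == "post"))
  expect_true(all(!is.na(coh$records$mdrt_left_temporal[dosed])))
})

test_that("voxel rendering round-trips through extraction", {
  sch <- default_scheme(4, 2, 4)
  set.seed(61)
  ts <- matrix(rnorm(10 * 50), 10, dimnames = list(sch$name, NULL))

  # noiseless: exact recovery
  vox <- render_voxel_data(ts, sch, grid_shape = c(5, 2, 1))
  rec <- extract_mean_timeseries(vox$bold, vox$labels, sch)
  expect_equal(rec, ts, ignore_attr = TRUE, tolerance = 1e-12)

  # unit noise over 10 voxels/region: recovered series correlate > 0.9
  vox2 <- render_voxel_data(ts, sch, grid_shape = c(10, 10, 1),
                            voxel_noise_sd = 1, seed = 62)
  rec2 <- extract_mean_timeseries(vox2$bold, vox2$labels, sch)
  cors <- vapply(seq_len(10), function(i) cor(rec2[i, ], ts[i, ]), numeric(1))
  expect_true(all(cors > 0.9))

  # capacity guard: 164 regions cannot fit 128 voxels
  big <- default_scheme()
  expect_error(render_voxel_data(matrix(0, 164, 5), big,
                                 grid_shape = c(8, 8, 2)),
               "cannot host")
})

test_that("rendered voxel data round-trips through the full cleaning path", {
  # zero voxel noise + no motion spikes: FCS from rendered-then-extracted
  # data matches FCS from the generating region series to 1e-6
  cfg <- cohort_config(n_pre = 3, n_post = 3, n_frames = 40,
                       n_cortical = 4, n_subcortical = 2, n_wm = 4,
                       effect_map = NULL, dose_targets = NULL,
                       motion_spike_rate = 0, seed = 65)
  coh <- simulate_cohort(cfg)
  id <- coh$records$subject_id[1]
  ts <- coh$timeseries[[id]]
  mot <- coh$motion[[id]]
  vox <- render_voxel_data(ts, coh$scheme, grid_shape = c(5, 2, 1))
  extracted <- extract_mean_timeseries(vox$bold, vox$labels, coh$scheme)

  direct <- compute_fcs(fc_matrix(clean_timeseries(ts, mot, tr = 2.4)),
                        coh$scheme)
  roundtrip <- compute_fcs(fc_matrix(clean_timeseries(extracted, mot,
                                                      tr = 2.4)),
                           coh$scheme)
  expect_equal(roundtrip$value, direct$value, tolerance = 1e-6)
})
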