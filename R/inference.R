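#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sort ascending, `q_(i) = min_{j >= i} m * p_(j) / j`,
#' clip at 1, restore the original order. The family size `m` may exceed the
#' number of supplied p-values when the supplied subset is known to contain
#' the smallest members of the family (e.g. only the printed significant
#' rows of a table).
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @param m Family size (default `length(pvalues)`).
#' @return Adjusted p-values in the original order.
#' @examples
#' fdr_bh(c(0.00039, 0.0012, 0.0018, 0.0033, 0.0035), m = 50)
#' @export
fdr_bh <- function(pvalues, m = length(pvalues)) {
  p <- as.numeric(pvalues)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  if (m < length(p)) abort("`m` must be at least `length(pvalues)`.")
  p.adjust(p, method = "BH", n = m)
}

#' Pooled-variance two-sample t statistic from summary statistics
#'
#' Student's two-sample t with the pooled variance estimate; the sign
#' follows `m2 - m1` (group 2 minus group 1).
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return A one-row tibble: `estimate` (`m2 - m1`), `statistic`, `df`,
#'   `p.value` (two-sided).
#' @examples
#' pooled_t_from_summary(0.25, 0.11, 47, 0.19, 0.10, 64)
#' @export
pooled_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) abort("Both groups need at least 2 subjects.")
  if (s1 <= 0 || s2 <= 0) abort("Group SDs must be positive.")
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  se <- sp * sqrt(1 / n1 + 1 / n2)
  tval <- (m2 - m1) / se
  df <- n1 + n2 - 2
  tibble::tibble(estimate = m2 - m1, statistic = tval, df = df,
                 p.value = 2 * pt(-abs(tval), df))
}

#' Post hoc power of the two-sided pooled-variance t test
#'
#' Power at the observed effect size `d = |m1 - m2| / pooled SD`, computed
#' from the noncentral t distribution with `n1 + n2 - 2` degrees of freedom
#' and noncentrality `d * sqrt(n1 * n2 / (n1 + n2))`.
#'
#' @inheritParams pooled_t_from_summary
#' @param alpha Two-sided significance level (default 0.05).
#' @return A one-row tibble: `d`, `df`, `ncp`, `power`.
#' @examples
#' posthoc_power_two_sample(0.25, 0.11, 47, 0.19, 0.10, 64)
#' @export
posthoc_power_two_sample <- function(m1, s1, n1, m2, s2, n2, alpha = 0.05) {
  if (n1 < 2 || n2 < 2) abort("Both groups need at least 2 subjects.")
  if (s1 <= 0 || s2 <= 0) abort("Group SDs must be positive.")
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  d <- abs(m1 - m2) / sp
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  crit <- qt(1 - alpha / 2, df)
  power <- 1 - pt(crit, df, ncp = ncp) + pt(-crit, df, ncp = ncp)
  tibble::tibble(d = d, df = df, ncp = ncp, power = power)
}

#' Partial correlation given covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' regression on the covariates (plus intercept). The t statistic uses
#' `df = n - 2 - g` where `g` is the number of covariates.
#'
#' @param x,y Numeric vectors.
#' @param covariates Data frame / matrix of covariates, or `NULL` for the
#'   plain Pearson correlation.
#' @return A one-row tibble: `estimate` (partial r), `statistic`, `df`,
#'   `p.value`, `n`, `n_covariates`.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have the same length.")
  g <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= g + 2) abort("Need more than `n_covariates + 2` observations.")
  if (g > 0) {
    C <- as.matrix(covariates)
    storage.mode(C) <- "double"
    X <- cbind(1, C)
    ex <- lm.fit(X, x)$residuals
    ey <- lm.fit(X, y)$residuals
  } else {
    ex <- x - mean(x)
    ey <- y - mean(y)
  }
  if (sd(ex) == 0 || sd(ey) == 0) {
    abort("Zero-variance residuals: partial correlation undefined.")
  }
  r <- cor(ex, ey)
  df <- n - 2L - g
  tval <- r * sqrt(df / (1 - r^2))
  tibble::tibble(estimate = r, statistic = tval, df = df,
                 p.value = 2 * pt(-abs(tval), df), n = n, n_covariates = g)
}

#' Per-region covariate-adjusted group comparison
#'
#' For every region in the FCS table, fits ordinary least squares of FCS on
#' group (post = 1) plus the requested covariates (sex is coded male = 1)
#' and reports the group coefficient, its t statistic and two-sided p-value.
#' Within each FCS family, p-values are Benjamini-Hochberg adjusted with the
#' configured family size. Subjects with missing FCS or covariates are
#' dropped listwise per region.
#'
#' @param fcs Subject-level FCS tibble (`subject_id`, `region`, `family`,
#'   `value`), e.g. from [cohort_fcs()].
#' @param records Subject tibble with `subject_id`, `group` (factor with
#'   levels `pre`, `post`) and the covariate columns.
#' @param covariates Character vector of record columns to adjust for
#'   (default `c("age", "sex", "mean_fd")`); `character(0)` reduces the
#'   model to the pooled two-sample t test.
#' @param fdr_m Named numeric vector of family sizes for the BH correction,
#'   e.g. `c(WW = 50, GW = 114)`; defaults to the number of regions tested
#'   in each family.
#' @param alpha Significance level used by `glance()` and the report
#'   (default 0.05).
#' @return An object of class `wmfcs_group_test`; `tidy()` returns the
#'   per-region results tibble (`region`, `family`, `n_pre`, `n_post`,
#'   `mean_pre`, `sd_pre`, `mean_post`, `sd_post`, `estimate`, `statistic`,
#'   `p.value`, `p.fdr`), `glance()` a one-row summary.
#' @export
region_group_test <- function(fcs, records,
                              covariates = c("age", "sex", "mean_fd"),
                              fdr_m = NULL, alpha = 0.05) {
  stopifnot(all(c("subject_id", "region", "family", "value") %in% names(fcs)))
  stopifnot(all(c("subject_id", "group") %in% names(records)))
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov)) {
    abort(paste0("Covariate(s) absent from records: ",
                 paste(missing_cov, collapse = ", ")))
  }
  rec <- records
  rec$group_post <- as.integer(rec$group == "post")
  if ("sex" %in% covariates) {
    rec$sex <- as.integer(as.character(rec$sex) == "male")
  }
  dat <- dplyr::inner_join(
    fcs, dplyr::select(rec, dplyr::all_of(c("subject_id", "group_post",
                                            covariates))),
    by = "subject_id")

  results <- dat |>
    dplyr::group_by(.data$family, .data$region) |>
    dplyr::group_modify(function(d, key) {
      d <- d[complete.cases(d[c("value", "group_post", covariates)]), ,
             drop = FALSE]
      n_pre <- sum(d$group_post == 0)
      n_post <- sum(d$group_post == 1)
      if (n_pre < 2 || n_post < 2) {
        return(tibble::tibble(
          n_pre = n_pre, n_post = n_post,
          mean_pre = NA_real_, sd_pre = NA_real_,
          mean_post = NA_real_, sd_post = NA_real_,
          estimate = NA_real_, statistic = NA_real_, p.value = NA_real_))
      }
      X <- cbind(intercept = 1, group_post = d$group_post,
                 as.matrix(d[covariates]))
      qx <- qr(X)
      if (qx$rank < ncol(X)) {
        bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
        abort(paste0("Collinear design for region ", key$region,
                     "; offending column(s): ", paste(bad, collapse = ", ")))
      }
      fit <- lm.fit(X, d$value)
      rdf <- nrow(X) - ncol(X)
      sigma2 <- sum(fit$residuals^2) / rdf
      XtX_inv <- chol2inv(chol(crossprod(X)))
      se <- sqrt(sigma2 * XtX_inv[2, 2])
      tval <- unname(fit$coefficients["group_post"]) / se
      tibble::tibble(
        n_pre = n_pre, n_post = n_post,
        mean_pre = mean(d$value[d$group_post == 0]),
        sd_pre = sd(d$value[d$group_post == 0]),
        mean_post = mean(d$value[d$group_post == 1]),
        sd_post = sd(d$value[d$group_post == 1]),
        estimate = unname(fit$coefficients["group_post"]),
        statistic = tval,
        p.value = 2 * pt(-abs(tval), rdf))
    }) |>
    dplyr::ungroup()

  results <- results |>
    dplyr::group_by(.data$family) |>
    dplyr::mutate(p.fdr = {
      ok <- !is.na(.data$p.value)
      m_fam <- if (!is.null(fdr_m) && .data$family[1] %in% names(fdr_m)) {
        max(fdr_m[[.data$family[1]]], sum(ok))
      } else sum(ok)
      out <- rep(NA_real_, dplyr::n())
      out[ok] <- fdr_bh(.data$p.value[ok], m = m_fam)
      out
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(factor(.data$family, levels = c("WW", "GW")), .data$region)

  structure(list(results = results, covariates = covariates,
                 fdr_m = fdr_m, alpha = alpha),
            class = "wmfcs_group_test")
}

#' @export
print.wmfcs_group_test <- function(x, ...) {
  n_sig <- sum(x$results$p.fdr < x$alpha, na.rm = TRUE)
  cat(sprintf(
    "<wmfcs_group_test> %d regions tested (%s); %d FDR-significant at q < %g\n",
    nrow(x$results),
    paste(unique(x$results$family), collapse = " + "),
    n_sig, x$alpha))
  print(x$results, ...)
  invisible(x)
}

#' @rdname region_group_test
#' @param x A `wmfcs_group_test` object.
#' @param ... Unused.
#' @method tidy wmfcs_group_test
#' @export
tidy.wmfcs_group_test <- function(x, ...) {
  x$results
}

#' @rdname region_group_test
#' @method glance wmfcs_group_test
#' @export
glance.wmfcs_group_test <- function(x, ...) {
  res <- x$results
  tibble::tibble(
    n_regions = nrow(res),
    n_sig_ww = sum(res$family == "WW" & res$p.fdr < x$alpha, na.rm = TRUE),
    n_sig_gw = sum(res$family == "GW" & res$p.fdr < x$alpha, na.rm = TRUE),
    alpha = x$alpha,
    n_covariates = length(x$covariates)
  )
}

#' Dose-FCS partial correlations
#'
#' For each (region, dose variable) pair, the partial correlation between
#' subject-level FCS and the dose, adjusting for the covariates, over
#' dose-complete subjects of the requested group. Subjects lacking the dose
#' are excluded and counted.
#'
#' @param fcs Subject-level FCS tibble.
#' @param records Subject tibble with `group`, dose and covariate columns.
#' @param dose_vars Dose column names (default the two MDRT variables).
#' @param regions Regions to test (default: all in `fcs`).
#' @param covariates Covariate columns (default `c("age", "sex", "mean_fd")`).
#' @param group Group whose subjects enter the analysis (default `"post"`;
#'   `NULL` for all).
#' @return A tibble: `region`, `family`, `dose_var`, `estimate`,
#'   `statistic`, `df`, `p.value`, `n`, `n_excluded`.
#' @export
dose_association <- function(fcs, records,
                             dose_vars = c("mdrt_brainstem",
                                           "mdrt_left_temporal"),
                             regions = NULL,
                             covariates = c("age", "sex", "mean_fd"),
                             group = "post") {
  rec <- records
  if (!is.null(group)) rec <- dplyr::filter(rec, .data$group == !!group)
  if ("sex" %in% covariates) {
    rec$sex <- as.integer(as.character(rec$sex) == "male")
  }
  if (is.null(regions)) regions <- unique(fcs$region)
  grid <- tidyr::expand_grid(region = regions, dose_var = dose_vars)

  purrr::pmap_dfr(grid, function(region, dose_var) {
    d <- dplyr::inner_join(
      dplyr::filter(fcs, .data$region == !!region),
      dplyr::select(rec, dplyr::all_of(c("subject_id", dose_var, covariates))),
      by = "subject_id")
    complete <- complete.cases(d[c("value", dose_var, covariates)])
    n_excluded <- sum(!complete)
    d <- d[complete, , drop = FALSE]
    if (nrow(d) < length(covariates) + 3) {
      abort(sprintf(
        "Region %s / %s: only %d dose-complete subjects (need >= %d).",
        region, dose_var, nrow(d), length(covariates) + 3))
    }
    res <- partial_corr(d$value, d[[dose_var]],
                        covariates = d[covariates])
    tibble::tibble(region = region, family = d$family[1], dose_var = dose_var,
                   estimate = res$estimate, statistic = res$statistic,
                   df = res$df, p.value = res$p.value, n = res$n,
                   n_excluded = n_excluded)
  })
}

#' Group demographics comparison table
#'
#' Continuous variables (age, mean FD) are compared by the pooled-variance
#' two-sample t test; sex by a continuity-corrected chi-square on the 2x2
#' counts; clinical staging by chi-square without continuity correction on
#' available cases (missing staging is counted). If any contingency cell is
#' empty the comparison switches to Fisher's exact test with a warning.
#'
#' @param records Subject tibble with `group` and any of `age`, `sex`,
#'   `staging`, `mean_fd`.
#' @return A tibble: `variable`, `pre`, `post` (formatted summaries),
#'   `statistic`, `p.value`, `method`, `n_missing`.
#' @export
demographics_table <- function(records) {
  stopifnot("group" %in% names(records))
  pre <- dplyr::filter(records, .data$group == "pre")
  post <- dplyr::filter(records, .data$group == "post")
  if (nrow(pre) < 2 || nrow(post) < 2) {
    abort("Need at least 2 subjects per group.")
  }
  rows <- list()

  cont_row <- function(var, label) {
    x <- pre[[var]]; y <- post[[var]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    res <- pooled_t_from_summary(mean(x), sd(x), length(x),
                                 mean(y), sd(y), length(y))
    n_miss <- sum(is.na(pre[[var]])) + sum(is.na(post[[var]]))
    tibble::tibble(
      variable = label,
      pre = sprintf("%.2f (%.2f)", mean(x), sd(x)),
      post = sprintf("%.2f (%.2f)", mean(y), sd(y)),
      statistic = res$statistic, p.value = res$p.value,
      method = "pooled two-sample t",
      n_missing = n_miss)
  }

  cat_row <- function(var, label, correct) {
    tab <- table(factor(records$group, levels = c("pre", "post")),
                 records[[var]])
    n_missing <- sum(is.na(records[[var]]))
    if (any(tab == 0)) {
      warn(sprintf("Empty cell in %s table: using Fisher's exact test.",
                   label))
      ft <- fisher.test(tab)
      stat <- NA_real_; pv <- ft$p.value; method <- "Fisher exact"
    } else if (identical(tab[1, ] / sum(tab[1, ]), tab[2, ] / sum(tab[2, ]))) {
      stat <- 0; pv <- 1
      method <- paste0("chi-square", if (correct) " (continuity corrected)")
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = correct))
      stat <- unname(ct$statistic); pv <- ct$p.value
      method <- paste0("chi-square", if (correct) " (continuity corrected)")
    }
    tibble::tibble(
      variable = label,
      pre = paste(sprintf("%s: %d", colnames(tab), tab[1, ]), collapse = "; "),
      post = paste(sprintf("%s: %d", colnames(tab), tab[2, ]), collapse = "; "),
      statistic = stat, p.value = pv, method = method,
      n_missing = n_missing)
  }

  if ("age" %in% names(records)) rows <- c(rows, list(cont_row("age", "age")))
  if ("sex" %in% names(records)) {
    rows <- c(rows, list(cat_row("sex", "sex", correct = TRUE)))
  }
  if ("staging" %in% names(records) && any(!is.na(records$staging))) {
    rows <- c(rows, list(cat_row("staging", "clinical staging",
                                 correct = FALSE)))
  }
  if ("mean_fd" %in% names(records) && any(!is.na(records$mean_fd))) {
    rows <- c(rows, list(cont_row("mean_fd", "mean FD")))
  }
  dplyr::bind_rows(rows)
}
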