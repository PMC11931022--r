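#' Default end-to-end run configuration
#'
#' A plain list (YAML-serializable) holding every threshold and constant of
#' the pipeline: QC cutoffs (Euler modified-Z -3.5, mean FD 0.5 mm, outlier
#' ratio 0.3), preprocessing constants (drop 5 volumes, censor at FD 0.5 mm,
#' high-pass 0.01 Hz, TR 2.4 s), FDR family sizes (WW 50, GW 114), the
#' significance level, the synthetic-cohort settings and the master seed.
#'
#' @param seed Master seed.
#' @return A nested list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(),  # overrides passed to cohort_config()
    qc = list(euler_threshold = -3.5, mean_fd_max = 0.5, ratio_max = 0.3,
              rule = "any"),
    preprocess = list(n_drop = 5, fd_threshold = 0.5, cutoff = 0.01,
                      head_radius = 50),
    fdr_m = list(WW = 50, GW = 114),
    alpha = 0.05
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !tibble::is_tibble(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      # base[nm] <- list(...) keeps explicit NULLs instead of deleting
      base[nm] <- list(user[[nm]])
    }
  }
  base
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, applies subject QC, cleans every included subject's
#' time series, computes subject-level WW-FCS and GW-FCS, runs the
#' covariate-adjusted group comparison with BH-FDR, the demographics table,
#' dose partial correlations (over FDR-significant regions, when dose data
#' exist) and post hoc power, and writes all tables plus a JSON run manifest
#' to `out_dir`. Deterministic for a fixed seed: re-running reproduces every
#' output bit for bit.
#'
#' @param config A config list (see [default_config()]; partial lists are
#'   merged over the defaults) or a path to a YAML file with the same
#'   structure.
#' @param out_dir Output directory (created). `NULL` skips writing.
#' @return Invisibly, a list with `records`, `qc`, `fcs`, `group_test`,
#'   `demographics`, `dose`, `power`, `manifest` and `out_dir`.
#' @examples
#' \donttest{
#' cfg <- default_config(seed = 42)
#' cfg$cohort <- list(n_pre = 8, n_post = 8, n_frames = 60,
#'                    n_cortical = 10, n_subcortical = 2, n_wm = 6,
#'                    effect_map = NULL, dose_targets = NULL)
#' res <- run_pipeline(cfg)
#' glance(res$group_test)
#' }
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  cohort_args <- cfg$cohort
  cohort_args$seed <- cohort_args$seed %||% cfg$seed
  cohort <- simulate_cohort(do.call(cohort_config, cohort_args))

  pp <- cfg$preprocess
  cleaned <- lapply(cohort$records$subject_id, function(id) {
    clean_timeseries(cohort$timeseries[[id]], cohort$motion[[id]],
                     tr = cohort$config$tr, n_drop = pp$n_drop,
                     fd_threshold = pp$fd_threshold, cutoff = pp$cutoff,
                     head_radius = pp$head_radius)
  })
  names(cleaned) <- cohort$records$subject_id
  fd_list <- lapply(cleaned, attr, "fd")

  qc <- qc_subjects(cohort$records, fd_list,
                    euler_threshold = cfg$qc$euler_threshold,
                    mean_fd_max = cfg$qc$mean_fd_max,
                    ratio_max = cfg$qc$ratio_max,
                    rule = cfg$qc$rule)
  if (!any(qc$included)) {
    abort(paste0(
      "Stage qc: all subjects excluded. Reasons: ",
      paste(unique(qc$exclusion_reasons[qc$exclusion_reasons != ""]),
            collapse = "; ")))
  }
  included <- dplyr::filter(qc, .data$included)

  fcs <- cohort_fcs(cleaned[included$subject_id], cohort$scheme)
  fdr_m <- unlist(cfg$fdr_m)
  gt <- region_group_test(fcs, included, fdr_m = fdr_m, alpha = cfg$alpha)
  demo <- demographics_table(included)

  res <- tidy(gt)
  sig <- dplyr::filter(res, .data$p.fdr < cfg$alpha)
  dose <- NULL
  dose_vars <- intersect(c("mdrt_brainstem", "mdrt_left_temporal"),
                         names(included))
  has_dose <- length(dose_vars) > 0 &&
    any(!is.na(as.matrix(included[dose_vars])))
  if (has_dose && nrow(sig) > 0) {
    dose <- tryCatch(
      dose_association(fcs, included, dose_vars = dose_vars,
                       regions = sig$region),
      error = function(e) {
        warn(paste0("Dose association skipped: ", conditionMessage(e)))
        NULL
      })
  }

  power <- res |>
    dplyr::filter(!is.na(.data$statistic)) |>
    dplyr::rowwise() |>
    dplyr::mutate(posthoc_power_two_sample(
      .data$mean_pre, .data$sd_pre, .data$n_pre,
      .data$mean_post, .data$sd_post, .data$n_post,
      alpha = cfg$alpha)[c("d", "power")]) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("region", "family", "d", "power")))

  manifest <- list(
    package_version = as.character(utils::packageVersion("wmfcs")),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg),
    config = cfg[setdiff(names(cfg), "cohort")],
    n_subjects = nrow(qc),
    n_included = nrow(included),
    n_excluded = sum(!qc$included),
    stages = c("simulate", "qc", "preprocess", "fcs", "stats", "report")
  )

  out <- list(records = cohort$records, qc = qc, fcs = fcs, group_test = gt,
              demographics = demo, dose = dose, power = power,
              manifest = manifest, scheme = cohort$scheme, out_dir = out_dir)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(cohort$records, file.path(out_dir, "participants.tsv"))
    readr::write_tsv(qc, file.path(out_dir, "qc_report.tsv"))
    write_fcs(fcs, file.path(out_dir, "fcs.tsv"))
    readr::write_tsv(res, file.path(out_dir, "table2.tsv"))
    readr::write_tsv(demo, file.path(out_dir, "demographics.tsv"))
    readr::write_tsv(power, file.path(out_dir, "power.tsv"))
    if (!is.null(dose)) {
      readr::write_tsv(dose, file.path(out_dir, "dose_assoc.tsv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    render_report(out_dir, alpha = cfg$alpha)
  }
  invisible(out)
}

format_p <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return("NA")
    format(signif(x, 2), scientific = x < 1e-4)
  }, character(1))
}

#' Render a markdown report from a pipeline run directory
#'
#' Produces `report.md` with the demographics table, the FDR-significant
#' regions per FCS family, and (when present) the dose-association table.
#' Means, SDs and t statistics are rounded to 2 decimals; p-values to 2
#' significant figures. The underlying TSVs keep full precision.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @param alpha Significance level used to list findings (default 0.05).
#' @return The report path, invisibly.
#' @export
render_report <- function(run_dir, alpha = 0.05) {
  t2_path <- file.path(run_dir, "table2.tsv")
  demo_path <- file.path(run_dir, "demographics.tsv")
  if (!file.exists(t2_path) || !file.exists(demo_path)) {
    abort("Run directory is missing stats tables; run the pipeline first.")
  }
  t2 <- readr::read_tsv(t2_path, show_col_types = FALSE)
  demo <- readr::read_tsv(demo_path, show_col_types = FALSE)

  lines <- c("# White-matter FCS analysis report", "")
  lines <- c(lines, "## Demographics", "",
             "| Variable | pre-RT | post-RT | p |",
             "|---|---|---|---|",
             sprintf("| %s | %s | %s | %s |", demo$variable, demo$pre,
                     demo$post, format_p(demo$p.value)),
             "")

  for (fam in c("WW", "GW")) {
    sub <- dplyr::filter(t2, .data$family == fam, .data$p.fdr < alpha)
    lines <- c(lines, sprintf("## %s-FCS group differences", fam), "")
    if (nrow(sub) == 0) {
      lines <- c(lines,
                 sprintf("No FDR-significant regions in the %s family at q < %g.",
                         fam, alpha), "")
    } else {
      lines <- c(lines,
                 "| Region | pre-RT | post-RT | t | p | p-FDR |",
                 "|---|---|---|---|---|---|",
                 sprintf("| %s | %.2f (%.2f) | %.2f (%.2f) | %.2f | %s | %s |",
                         sub$region, sub$mean_pre, sub$sd_pre, sub$mean_post,
                         sub$sd_post, sub$statistic, format_p(sub$p.value),
                         format_p(sub$p.fdr)),
                 "")
    }
  }

  dose_path <- file.path(run_dir, "dose_assoc.tsv")
  if (file.exists(dose_path)) {
    dose <- readr::read_tsv(dose_path, show_col_types = FALSE)
    lines <- c(lines, "## Dose associations (partial correlations)", "",
               "| Region | Dose | r | p | n | df |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %s | %.2f | %s | %d | %d |",
                       dose$region, dose$dose_var, dose$estimate,
                       format_p(dose$p.value), dose$n, dose$df),
               "")
  }

  path <- file.path(run_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
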