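# wmfcs

Functional connectivity strength (FCS) analysis of white-matter BOLD
signals in resting-state fMRI, built for studies that compare groups of
subjects — for example nasopharyngeal-carcinoma patients observed before
versus after radiation therapy — and relate regional connectivity to
continuous clinical variables such as radiation dose.

Low-frequency BOLD fluctuations in white matter carry structured signal,
and averaging a region's Fisher-z correlations over a family of other
regions gives a simple, interpretable per-region statistic:

- **WW-FCS** of a white-matter region *i*:
  `mean over j in WM, j != i of z_ij`, its mean Fisher-z connectivity with
  the other white-matter regions;
- **GW-FCS** of a gray-matter region *g*:
  `mean over j in WM of z_gj`, its mean Fisher-z connectivity with all
  white-matter regions;

where `z = atanh(r)` and `r` is the Pearson correlation between cleaned
region-mean time series. Group differences are tested per region by
ordinary least squares of FCS on group with age, sex and mean framewise
displacement (FD) as covariates, corrected across each family by the
Benjamini–Hochberg step-up procedure; dose–FCS associations use partial
correlation with the same covariates; post hoc power comes from the
noncentral t distribution.

The package covers the whole workflow in tidyverse style (tibbles in,
tibbles out, everything pipeable):

| Stage | Functions |
|---|---|
| Synthetic cohorts with prescribed correlation structure | `cohort_config()`, `simulate_cohort()`, `build_target_correlation()`, `simulate_motion()`, `simulate_dose()`, `render_voxel_data()` |
| Quality control | `compute_fd()`, `modified_zscore()`, `qc_subjects()` |
| Frame-level cleaning | `drop_initial_volumes()`, `censor_interpolate()`, `build_friston24()`, `nuisance_regress()`, `highpass_filter()`, `clean_timeseries()` |
| Parcellation | `default_scheme()`, `combine_atlases()`, `extract_mean_timeseries()` |
| Connectivity | `fc_matrix()`, `ww_fcs()`, `gw_fcs()`, `cohort_fcs()` |
| Inference | `region_group_test()` (+ `tidy()`/`glance()`/`autoplot()`), `pooled_t_from_summary()`, `fdr_bh()`, `partial_corr()`, `dose_association()`, `posthoc_power_two_sample()`, `demographics_table()` |
| Orchestration | `default_config()`, `run_pipeline()`, `render_report()` |

No patient data ship with the package: the synthetic-cohort generator
produces multivariate-normal region time series whose block correlation
structure, group effects (Fisher-z reductions in named regions), motion
spikes and dose variables emulate the study conditions, so every stage is
testable end to end.

## Worked example

Summary-level utilities reproduce published-table statistics directly.
For a white-matter region with group summaries 0.25 (SD 0.11, n = 47)
versus 0.19 (SD 0.10, n = 64):

```r
library(wmfcs)
pooled_t_from_summary(0.25, 0.11, 47, 0.19, 0.10, 64)
#>   estimate statistic    df p.value
#> 1    -0.06     -2.99   109 0.00341
posthoc_power_two_sample(0.25, 0.11, 47, 0.19, 0.10, 64)
#>       d    df   ncp power
#> 1 0.575   109  2.99 0.843
```

So that group difference corresponds to a pooled t of −2.99 (p = 0.0034)
with 84% post hoc power at alpha = 0.05.

A full synthetic run — simulate, QC, clean, connect, test — takes a few
seconds:

```r
res <- run_pipeline(default_config(seed = 42), out_dir = "demo_run")
glance(res$group_test)
#>   n_regions n_sig_ww n_sig_gw alpha n_covariates
#> 1       164        5        6  0.05            3
```

All five white-matter and six gray-matter regions carrying configured
effects are FDR-significant, e.g.:

```r
dplyr::filter(tidy(res$group_test), p.fdr < 0.05)
#>   family region                          mean_pre mean_post estimate ...
#> 1 WW     lh_Posterior_thalamic_radiation    0.339     0.250  -0.0879
#> 2 WW     lh_Superior_cerebellar_peduncle    0.325     0.264  -0.0623
#> ...
```

and the dose variables attached to the post-therapy group recover their
configured partial correlations at n = 37:

```r
dplyr::filter(res$dose, region == "lh_Vis_8")
#>   region   dose_var           estimate statistic df p.value  n
#> 1 lh_Vis_8 mdrt_brainstem       -0.363     -2.20 32 0.0350  37
#> 2 lh_Vis_8 mdrt_left_temporal   -0.502     -3.28 32 0.00251 37
```

`run_pipeline()` writes `participants.tsv`, `qc_report.tsv`, `fcs.tsv`,
`table2.tsv`, `demographics.tsv`, `power.tsv`, `dose_assoc.tsv`, a JSON
run manifest and a rounded markdown report into the output directory; the
run is bit-reproducible from the seed.

## Documentation

The methods vignette (`vignettes/wmfcs-methods.Rmd`) describes the
generative model, the cleaning pipeline and its joint-projection design,
the FCS definitions, the inference conventions (group and sex coding, FDR
family sizes, partial-correlation degrees of freedom) and the known
limitations of the synthetic cohorts.
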