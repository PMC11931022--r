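#' Build the default 164-region combined parcellation scheme
#'
#' The scheme combines a 100-parcel cortical atlas (Schaefer-style network
#' labels), 14 subcortical structures and 50 white-matter tract regions
#' (JHU-style labels) into one ordered lookup: cortical regions first
#' (ids 1--100, left then right hemisphere), then subcortical (101--114),
#' then white matter (115--164). The `tissue_class` column defines the two
#' FCS families: the gray-matter family is `cortical` plus `subcortical`
#' (114 regions by default), the white-matter family is `wm` (50 regions).
#'
#' Non-default counts generate placeholder names with the same structure and
#' are useful for small simulation studies.
#'
#' @param n_cortical Number of cortical regions (default 100; must be even).
#' @param n_subcortical Number of subcortical regions (default 14; even).
#' @param n_wm Number of white-matter regions (default 50).
#' @return A tibble with columns `id`, `name`, `hemisphere`
#'   (`"lh"`, `"rh"` or `"mid"`) and `tissue_class`
#'   (`"cortical"`, `"subcortical"` or `"wm"`).
#' @examples
#' scheme <- default_scheme()
#' dplyr::count(scheme, tissue_class)
#' @export
default_scheme <- function(n_cortical = 100, n_subcortical = 14, n_wm = 50) {
  if (n_cortical < 2 || n_cortical %% 2 != 0) {
    abort("`n_cortical` must be a positive even number.")
  }
  if (n_subcortical < 2 || n_subcortical %% 2 != 0) {
    abort("`n_subcortical` must be a positive even number.")
  }
  if (n_wm < 2) abort("`n_wm` must be at least 2.")

  cort <- scheme_names_cortical(n_cortical)
  subc <- scheme_names_subcortical(n_subcortical)
  wm <- scheme_names_wm(n_wm)

  tibble::tibble(
    id = seq_len(n_cortical + n_subcortical + n_wm),
    name = c(cort$name, subc$name, wm$name),
    hemisphere = c(cort$hemisphere, subc$hemisphere, wm$hemisphere),
    tissue_class = rep(c("cortical", "subcortical", "wm"),
                       c(n_cortical, n_subcortical, n_wm))
  )
}

# 50-per-hemisphere Schaefer-style names for the default; placeholder names
# otherwise
scheme_names_cortical <- function(n) {
  half <- n / 2L
  if (half == 50L) {
    nets <- c(Vis = 9L, SomMot = 8L, DorsAttn = 7L, SalVentAttn = 7L,
              Limbic = 5L, Cont = 6L)
    base <- unlist(lapply(names(nets), function(nm) {
      paste0(nm, "_", seq_len(nets[[nm]]))
    }))
    default_sub <- c("Temp", "PFCv", "PFCdPFCm", "pCunPCC")
    base <- c(base, paste0("Default_", rep(default_sub, each = 2L), "_",
                           rep(1:2, times = 4L)))
  } else {
    base <- paste0("Ctx_", seq_len(half))
  }
  list(
    name = c(paste0("lh_", base), paste0("rh_", base)),
    hemisphere = rep(c("lh", "rh"), each = half)
  )
}

scheme_names_subcortical <- function(n) {
  half <- n / 2L
  if (half == 7L) {
    base <- c("Thalamus", "Caudate", "Putamen", "Pallidum",
              "Hippocampus", "Amygdala", "Accumbens")
  } else {
    base <- paste0("Subctx_", seq_len(half))
  }
  list(
    name = c(paste0("lh_", base), paste0("rh_", base)),
    hemisphere = rep(c("lh", "rh"), each = half)
  )
}

scheme_names_wm <- function(n) {
  if (n == 50L) {
    midline <- c("Genu_of_corpus_callosum", "Body_of_corpus_callosum",
                 "Splenium_of_corpus_callosum", "Fornix",
                 "Middle_cerebellar_peduncle", "Pontine_crossing_tract")
    paired <- c("Corticospinal_tract", "Medial_lemniscus",
                "Inferior_cerebellar_peduncle", "Superior_cerebellar_peduncle",
                "Cerebral_peduncle", "Anterior_limb_of_internal_capsule",
                "Posterior_limb_of_internal_capsule",
                "Retrolenticular_part_of_internal_capsule",
                "Anterior_corona_radiata", "Superior_corona_radiata",
                "Posterior_corona_radiata", "Posterior_thalamic_radiation",
                "Sagittal_stratum", "External_capsule",
                "Cingulum_cingulate_gyrus", "Cingulum_hippocampus",
                "Fornix_cres_Stria_terminalis",
                "Superior_longitudinal_fasciculus",
                "Superior_fronto_occipital_fasciculus",
                "Inferior_longitudinal_fasciculus",
                "Uncinate_fasciculus", "Tapetum")
    list(
      name = c(midline,
               paste0(rep(c("lh_", "rh_"), times = length(paired)),
                      rep(paired, each = 2L))),
      hemisphere = c(rep("mid", length(midline)),
                     rep(c("lh", "rh"), times = length(paired)))
    )
  } else {
    list(name = paste0("WM_", seq_len(n)), hemisphere = rep("mid", n))
  }
}

validate_scheme <- function(scheme) {
  req <- c("id", "name", "hemisphere", "tissue_class")
  missing <- setdiff(req, names(scheme))
  if (length(missing)) {
    abort(paste0("Scheme is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(scheme$id)) abort("Scheme ids must be unique.")
  if (anyDuplicated(scheme$name)) abort("Scheme names must be unique.")
  bad <- setdiff(unique(scheme$tissue_class),
                 c("cortical", "subcortical", "wm"))
  if (length(bad)) {
    abort(paste0("Unknown tissue_class value(s): ", paste(bad, collapse = ", ")))
  }
  invisible(scheme)
}

#' Family membership helpers
#'
#' `wm_regions()` returns the white-matter family of a scheme;
#' `gm_regions()` the gray-matter family (cortical plus subcortical).
#'
#' @param scheme A parcellation scheme tibble (see [default_scheme()]).
#' @return A character vector of region names in scheme order.
#' @export
wm_regions <- function(scheme) {
  scheme$name[scheme$tissue_class == "wm"]
}

#' @rdname wm_regions
#' @export
gm_regions <- function(scheme) {
  scheme$name[scheme$tissue_class %in% c("cortical", "subcortical")]
}

#' Read or write a parcellation scheme lookup table
#'
#' The on-disk format is a TSV with columns `id`, `name`, `hemisphere`,
#' `tissue_class`.
#'
#' @param path File path.
#' @param scheme Scheme tibble to write.
#' @return `read_scheme()` returns the scheme tibble; `write_scheme()`
#'   returns `path` invisibly.
#' @export
read_scheme <- function(path) {
  scheme <- readr::read_tsv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              id = readr::col_integer(),
                              name = readr::col_character(),
                              hemisphere = readr::col_character(),
                              tissue_class = readr::col_character()
                            ))
  validate_scheme(scheme)
  scheme
}

#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, path) {
  validate_scheme(scheme)
  readr::write_tsv(scheme, path)
  invisible(path)
}

#' Combine per-tissue label volumes into one contiguous parcellation
#'
#' Re-indexes the labels of several atlases (e.g. cortical, subcortical,
#' white matter) into one contiguous id space, preserving the order
#' (atlas, original id). When a voxel carries a label in more than one
#' atlas the earlier-listed atlas wins by default; the number of such
#' conflicts is reported.
#'
#' @param volumes A list of 3D integer arrays on the same grid
#'   (0 = unlabeled).
#' @param lookups A list (same length) of tibbles with columns `id`, `name`,
#'   `hemisphere`, `tissue_class` describing each atlas's labels.
#' @return A list with elements `labels` (3D integer array with the combined
#'   contiguous ids), `scheme` (the combined scheme tibble) and `n_conflicts`
#'   (count of voxels labeled by more than one atlas).
#' @export
combine_atlases <- function(volumes, lookups) {
  if (length(volumes) == 0L) abort("At least one label volume is required.")
  if (length(volumes) != length(lookups)) {
    abort("`volumes` and `lookups` must have the same length.")
  }
  dims <- lapply(volumes, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort("All label volumes must share the same grid dimensions.")
  }

  rows <- list()
  out <- array(0L, dim = dims[[1]])
  taken <- array(FALSE, dim = dims[[1]])
  n_conflicts <- 0L
  next_id <- 1L
  for (k in seq_along(volumes)) {
    vol <- volumes[[k]]
    lut <- lookups[[k]]
    ids <- sort(unique(as.integer(vol[vol != 0L])))
    if (length(ids) == 0L) abort(sprintf("Atlas %d contains no labels.", k))
    if (anyDuplicated(lut$id)) {
      abort(sprintf("Atlas %d lookup has duplicated ids.", k))
    }
    missing <- setdiff(ids, lut$id)
    if (length(missing)) {
      abort(sprintf("Atlas %d has labels absent from its lookup: %s",
                    k, paste(missing, collapse = ", ")))
    }
    lut <- lut[match(ids, lut$id), , drop = FALSE]
    new_ids <- seq.int(next_id, length.out = length(ids))
    rows[[k]] <- tibble::tibble(
      id = as.integer(new_ids),
      name = lut$name,
      hemisphere = lut$hemisphere,
      tissue_class = lut$tissue_class
    )
    labeled <- vol != 0L
    n_conflicts <- n_conflicts + sum(labeled & taken)
    keep <- labeled & !taken
    remap <- integer(max(ids))
    remap[ids] <- new_ids
    out[keep] <- remap[vol[keep]]
    taken <- taken | labeled
    next_id <- next_id + length(ids)
  }
  scheme <- dplyr::bind_rows(rows)
  validate_scheme(scheme)
  list(labels = out, scheme = scheme, n_conflicts = n_conflicts)
}

#' Extract region-mean time series from a 4D BOLD array
#'
#' Computes, for each region of `scheme`, the unweighted mean over that
#' region's voxels at every frame. Regions with no voxels yield rows of `NA`
#' and are reported with a warning.
#'
#' @param bold 4D numeric array (x, y, z, frames) or a path to a NIfTI file.
#' @param labels 3D integer array on the same grid (or a NIfTI path) whose
#'   values are scheme ids; 0 marks unlabeled voxels.
#' @param scheme Parcellation scheme tibble.
#' @return A regions x frames numeric matrix with `scheme$name` rownames and
#'   attribute `missing_regions` (character vector of empty regions).
#' @export
extract_mean_timeseries <- function(bold, labels, scheme) {
  if (is.character(bold)) bold <- as.array(RNifti::readNifti(bold))
  if (is.character(labels)) {
    labels <- as.array(RNifti::readNifti(labels))
    storage.mode(labels) <- "integer"
  }
  validate_scheme(scheme)
  if (length(dim(bold)) != 4L) abort("`bold` must be a 4D array.")
  if (!identical(dim(bold)[1:3], dim(labels))) {
    abort("`bold` and `labels` must share the same spatial grid.")
  }
  n_frames <- dim(bold)[4]
  vox_labels <- as.integer(labels)
  flat <- matrix(bold, nrow = prod(dim(labels)), ncol = n_frames)
  in_mask <- vox_labels != 0L
  if (!any(in_mask)) abort("No labeled voxels found: all regions are empty.")
  sums <- rowsum(flat[in_mask, , drop = FALSE], group = vox_labels[in_mask])
  counts <- tabulate(vox_labels[in_mask], nbins = max(scheme$id))
  present <- as.integer(rownames(sums))

  ts <- matrix(NA_real_, nrow = nrow(scheme), ncol = n_frames,
               dimnames = list(scheme$name, NULL))
  idx <- match(present, scheme$id)
  if (anyNA(idx)) {
    abort("Label volume contains ids absent from the scheme.")
  }
  ts[idx, ] <- sums / counts[present]
  missing_regions <- scheme$name[!(scheme$id %in% present)]
  if (length(missing_regions) == nrow(scheme)) {
    abort("All regions are empty on this grid.")
  }
  if (length(missing_regions)) {
    warn(sprintf("%d region(s) have no voxels: %s",
                 length(missing_regions),
                 paste(head(missing_regions, 5), collapse = ", ")))
  }
  attr(ts, "missing_regions") <- missing_regions
  ts
}
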