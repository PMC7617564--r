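# Masking, voxelwise map fitting and atlas-region aggregation.

#' Masking and region thresholds
#'
#' @param gm_pve_threshold Minimum grey-matter partial volume estimate for a
#'   voxel to enter the grey-matter mask (default 0.50, "at least 50%").
#' @param m0_fraction_threshold Voxels must exceed this fraction of the
#'   maximum M0 signal (default 0.50), excluding EPI drop-out areas.
#' @param region_pve_threshold Minimum regional partial volume estimate for
#'   a voxel to count towards a region (default 0.25).
#'
#' @return An object of class `mask_spec`.
#' @export
mask_spec <- function(gm_pve_threshold = 0.50,
                      m0_fraction_threshold = 0.50,
                      region_pve_threshold = 0.25) {
  v <- c(gm_pve_threshold, m0_fraction_threshold, region_pve_threshold)
  if (any(!is.finite(v)) || any(v <= 0) || any(v >= 1))
    stop("all mask thresholds must lie strictly in (0, 1)")
  structure(list(gm_pve_threshold = gm_pve_threshold,
                 m0_fraction_threshold = m0_fraction_threshold,
                 region_pve_threshold = region_pve_threshold),
            class = "mask_spec")
}

#' Analysis mask from grey-matter PVE and M0
#'
#' `mask = (gm_pve >= gm_pve_threshold) & (m0 > m0_fraction_threshold *
#' max(m0))`.
#'
#' @param gm_pve Grey-matter partial volume estimate volume (3D array).
#' @param m0 Equilibrium signal volume, same grid.
#' @param spec A [mask_spec()].
#'
#' @return Logical array of the same dimensions.
#' @export
build_mask <- function(gm_pve, m0, spec = mask_spec()) {
  if (!identical(dim(gm_pve), dim(m0)))
    stop("gm_pve and m0 volumes must share a grid")
  gm_pve >= spec$gm_pve_threshold &
    m0 > spec$m0_fraction_threshold * max(m0, na.rm = TRUE)
}

#' Voxelwise kinetic-model fitting over a masked volume
#'
#' Applies [fit_voxel()] + [postprocess_fit()] to every masked voxel of a
#' study. The slice index of a voxel is its (zero-based) position along the
#' third array axis. Per-voxel failures are recorded, not propagated.
#'
#' @param study A `study_image` as produced by [simulate_study()] (fields
#'   `dm` 4D array indexed by LCT on the 4th axis, `m0`, `timing`), or any
#'   list with those fields.
#' @param mask Logical array; default from [build_mask()] on the study's
#'   `gm_pve` and `m0`.
#' @param consts A [physio_constants()].
#' @param timing An [acquisition_timing()]; defaults to the study's.
#' @param lct_subset Optional logical or integer index selecting a subset of
#'   LCTs (used by the truncation experiment).
#'
#' @return An object of class `param_maps`: 3D arrays `f`, `cbf`,
#'   `bolus_duration`, `macro_bv`, `macro_bolus_duration`, `sse` (NaN
#'   outside the mask), logical arrays `boundary_flag`, `macro_excluded`,
#'   `converged`, plus the `mask` and `timing` used.
#' @export
fit_image <- function(study, mask = NULL, consts = physio_constants(),
                      timing = study$timing, lct_subset = NULL) {
  dm <- study$dm
  if (length(dim(dm)) != 4L) stop("study$dm must be a 4D array (x, y, z, LCT)")
  if (is.null(mask)) mask <- build_mask(study$gm_pve, study$m0)
  if (!identical(dim(mask), dim(dm)[1:3]))
    stop("mask grid does not match the image grid")
  lct <- timing$lct_values
  if (!is.null(lct_subset)) {
    lct <- lct[lct_subset]
    dm <- dm[, , , lct_subset, drop = FALSE]
    timing <- acquisition_timing(lct, timing$crusher_to_readout,
                                 timing$slice_delay, timing$n_slices)
  }
  if (dim(dm)[4L] != length(lct))
    stop("4th dimension of dm must match the number of LCTs")
  dims <- dim(dm)[1:3]
  shell <- array(NaN, dims)
  maps <- list(f = shell, cbf = shell, bolus_duration = shell,
               macro_bv = shell, macro_bolus_duration = shell, sse = shell,
               boundary_flag = array(NA, dims),
               macro_excluded = array(NA, dims),
               converged = array(NA, dims))
  idx <- which(mask, arr.ind = TRUE)
  for (v in seq_len(nrow(idx))) {
    i <- idx[v, 1L]; j <- idx[v, 2L]; k <- idx[v, 3L]
    fr <- tryCatch(
      postprocess_fit(fit_voxel(
        voxel_series(dm[i, j, k, ], lct, k - 1L, study$m0[i, j, k]),
        timing, consts)),
      error = function(e) NULL)
    if (is.null(fr)) { maps$converged[i, j, k] <- FALSE; next }
    p <- fr$params
    maps$f[i, j, k] <- p$f
    maps$cbf[i, j, k] <- f_to_cbf(p$f)
    maps$bolus_duration[i, j, k] <- p$bolus_duration
    maps$macro_bv[i, j, k] <- p$macro_bv
    maps$macro_bolus_duration[i, j, k] <- p$macro_bolus_duration
    maps$sse[i, j, k] <- fr$sse
    maps$boundary_flag[i, j, k] <- fr$boundary_flag
    maps$macro_excluded[i, j, k] <- fr$macro_excluded
    maps$converged[i, j, k] <- fr$converged
  }
  maps$mask <- mask
  maps$timing <- timing
  class(maps) <- "param_maps"
  maps
}

#' Per-region medians of fitted parameter maps for one subject
#'
#' A region comprises the voxels inside the analysis mask whose regional
#' partial volume estimate reaches `region_pve_threshold`. Medians are taken
#' across voxels; the macrovascular bolus-duration median excludes voxels
#' flagged by [postprocess_fit()] as having no macrovascular signal. A final
#' `grey_matter` row summarises the whole mask.
#'
#' @param maps A `param_maps` object from [fit_image()].
#' @param region_pve Named list of regional partial-volume-estimate volumes.
#' @param mask Logical analysis mask (default: the one stored in `maps`).
#' @param spec A [mask_spec()] (uses `region_pve_threshold`).
#'
#' @return A data.frame with one row per region plus `grey_matter`:
#'   `n_voxels`, `n_macro_voxels` and the voxelwise medians of CBF
#'   (ml/100 g/min), bolus duration (s), macrovascular blood volume
#'   (fraction) and macrovascular bolus duration (s), and the
#'   boundary-flag fraction. Empty regions get `n_voxels = 0` and NaN.
#' @export
region_medians <- function(maps, region_pve, mask = maps$mask,
                           spec = mask_spec()) {
  stopifnot(inherits(maps, "param_maps"), is.list(region_pve))
  one <- function(sel) {
    n <- sum(sel)
    if (n == 0)
      return(data.frame(n_voxels = 0L, n_macro_voxels = 0L, cbf = NaN,
                        bolus_duration = NaN, macro_bv = NaN,
                        macro_bolus_duration = NaN, boundary_fraction = NaN))
    msel <- sel & !maps$macro_excluded
    data.frame(
      n_voxels = n,
      n_macro_voxels = sum(msel, na.rm = TRUE),
      cbf = stats::median(maps$cbf[sel]),
      bolus_duration = stats::median(maps$bolus_duration[sel]),
      macro_bv = stats::median(maps$macro_bv[sel]),
      macro_bolus_duration =
        if (any(msel, na.rm = TRUE))
          stats::median(maps$macro_bolus_duration[msel], na.rm = TRUE)
        else NaN,
      boundary_fraction = mean(maps$boundary_flag[sel], na.rm = TRUE))
  }
  rows <- lapply(names(region_pve), function(r) {
    if (!identical(dim(region_pve[[r]]), dim(mask)))
      stop("region PVE volume '", r, "' does not match the mask grid")
    one(mask & region_pve[[r]] >= spec$region_pve_threshold)
  })
  rows <- c(rows, list(one(mask)))
  out <- do.call(rbind, rows)
  out <- cbind(region = c(names(region_pve), "grey_matter"), out)
  rownames(out) <- NULL
  out
}

#' Group summary of per-subject region medians
#'
#' Group statistics are computed across subjects (mean and standard
#' deviation of the per-subject medians), never across pooled voxels.
#'
#' @param medians_list List of per-subject data.frames from
#'   [region_medians()] (identical region sets).
#'
#' @return A data.frame of class `region_summary`, one row per region:
#'   `n_subjects`, mean voxel count, and `<param>_mean` / `<param>_sd`
#'   columns for CBF, bolus duration, macrovascular blood volume and
#'   macrovascular bolus duration, plus the mean boundary fraction.
#' @export
summarize_regions <- function(medians_list) {
  if (inherits(medians_list, "data.frame")) medians_list <- list(medians_list)
  regions <- medians_list[[1L]]$region
  for (m in medians_list)
    if (!identical(m$region, regions))
      stop("all subjects must share the same region set")
  params <- c("cbf", "bolus_duration", "macro_bv", "macro_bolus_duration")
  out <- data.frame(region = regions,
                    n_subjects = length(medians_list),
                    n_voxels_mean = rowMeans(sapply(medians_list,
                                                    function(m) m$n_voxels)))
  for (p in params) {
    vals <- sapply(medians_list, function(m) m[[p]])
    vals <- matrix(vals, nrow = length(regions))
    out[[paste0(p, "_mean")]] <- apply(vals, 1L, mean, na.rm = TRUE)
    out[[paste0(p, "_sd")]] <- apply(vals, 1L, stats::sd, na.rm = TRUE)
  }
  out$boundary_fraction_mean <-
    rowMeans(sapply(medians_list, function(m) m$boundary_fraction))
  class(out) <- c("region_summary", "data.frame")
  out
}
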