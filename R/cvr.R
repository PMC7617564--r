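# Cerebrovascular reactivity: per-LCT signal percent change, model-based
# CVR in %/mmHg, and the truncated-LCT identifiability experiment.

#' Per-LCT percentage signal change between conditions
#'
#' For each LCT, computes the voxelwise percentage change
#' `100 * (dm_hyper - dm_normo) / dm_normo`, takes the median across each
#' region's voxels (excluding voxels with nonpositive baseline signal, whose
#' ratio is meaningless), then averages the medians across regions.
#'
#' @param dm_normo,dm_hyper 4D difference-signal arrays with matched LCT
#'   axes (condition baseline / challenge).
#' @param mask Logical analysis mask.
#' @param region_pve Named list of regional PVE volumes; `NULL` treats the
#'   whole mask as a single region.
#' @param spec A [mask_spec()] (uses `region_pve_threshold`).
#'
#' @return A list of class `dm_percent_change`: `per_lct` (region-averaged
#'   median percent change per LCT), `per_region` (region x LCT matrix),
#'   `n_excluded` (voxel-LCT pairs dropped for nonpositive baseline).
#'   An all-excluded region yields NaN with a warning.
#' @export
dm_percent_change <- function(dm_normo, dm_hyper, mask, region_pve = NULL,
                              spec = mask_spec()) {
  if (!identical(dim(dm_normo), dim(dm_hyper)))
    stop("condition arrays must have identical dimensions (matched LCTs)")
  n_lct <- dim(dm_normo)[4L]
  sels <- if (is.null(region_pve)) list(whole_mask = mask)
          else lapply(region_pve, function(p)
            mask & p >= spec$region_pve_threshold)
  n_excluded <- 0L
  per_region <- t(vapply(sels, function(sel) {
    vapply(seq_len(n_lct), function(l) {
      base <- dm_normo[, , , l][sel]
      hyp <- dm_hyper[, , , l][sel]
      keep <- base > 0
      n_excluded <<- n_excluded + sum(!keep)
      if (!any(keep)) return(NaN)
      stats::median(100 * (hyp[keep] - base[keep]) / base[keep])
    }, numeric(1))
  }, numeric(n_lct)))
  if (any(is.nan(per_region)))
    warning("some regions had no voxels with positive baseline signal")
  structure(list(per_lct = colMeans(per_region, na.rm = TRUE),
                 per_region = per_region, n_excluded = n_excluded),
            class = "dm_percent_change")
}

#' Cerebrovascular reactivity from CBF estimates
#'
#' Per subject: `100 * (cbf_hyper - cbf_normo) / cbf_normo / delta_petco2`
#' in %/mmHg. Group statistics are the mean and SD of the per-subject
#' values (the order matters: CVR of group means is a different number).
#' Subjects with a nonpositive baseline CBF get NaN.
#'
#' @param cbf_normo,cbf_hyper Per-subject CBF values (any consistent unit).
#' @param delta_petco2 Per-subject end-tidal CO2 increase, mmHg; must be
#'   positive.
#'
#' @return A list of class `cvr_result`: `per_subject` (%/mmHg), `mean`,
#'   `sd`, `percent_cbf_change` (per subject), `delta_petco2`.
#' @export
cvr_from_cbf <- function(cbf_normo, cbf_hyper, delta_petco2) {
  n <- length(cbf_normo)
  stopifnot(length(cbf_hyper) == n)
  delta_petco2 <- rep_len(delta_petco2, n)
  if (any(delta_petco2 <= 0))
    stop("delta_petco2 must be positive for %/mmHg outputs")
  pct <- 100 * (cbf_hyper - cbf_normo) / cbf_normo
  pct[cbf_normo <= 0] <- NaN
  cvr <- pct / delta_petco2
  structure(list(per_subject = cvr,
                 mean = mean(cvr, na.rm = TRUE),
                 sd = stats::sd(cvr, na.rm = TRUE),
                 percent_cbf_change = pct,
                 delta_petco2 = delta_petco2),
            class = "cvr_result")
}

#' @export
print.cvr_result <- function(x, ...) {
  cat(sprintf("CVR: %.2f +/- %.2f %%/mmHg over %d subjects (CBF change %.1f +/- %.1f %%)\n",
              x$mean, x$sd, length(x$per_subject),
              mean(x$percent_cbf_change, na.rm = TRUE),
              stats::sd(x$percent_cbf_change, na.rm = TRUE)))
  invisible(x)
}

#' Truncated-LCT refit experiment
#'
#' Refits a study using only the LCTs up to `max_lct` and compares the
#' grey-matter summaries with the full-LCT fit. When the true bolus
#' duration reaches or exceeds the truncation point, the sum of squares is
#' flat in bolus duration beyond the largest remaining LCT: estimates pile
#' up at that boundary, and the truncated estimate drops below the
#' full-data one.
#'
#' @param study A `study_image`.
#' @param max_lct Truncation point, seconds; at least 6 LCTs must remain.
#' @param mask Logical analysis mask (default from the study volumes).
#' @param consts A [physio_constants()].
#'
#' @return A list of class `truncation_result`: `full` and `truncated`
#'   `param_maps`, `comparison` (data.frame of GM medians and boundary-flag
#'   fractions for both fits), and `bd_values` (full / truncated fitted
#'   bolus-duration vectors over the mask, histogram-ready).
#' @export
truncation_experiment <- function(study, max_lct, mask = NULL,
                                  consts = physio_constants()) {
  lct <- study$timing$lct_values
  if (max_lct < min(lct) || max_lct > max(lct))
    stop("max_lct must lie within the study's LCT range")
  keep <- lct <= max_lct + 1e-9
  if (sum(keep) < 6L)
    stop("fewer than 6 LCTs remain below max_lct; the fit is underdetermined")
  if (is.null(mask)) mask <- build_mask(study$gm_pve, study$m0)
  full <- fit_image(study, mask, consts)
  trunc <- fit_image(study, mask, consts, lct_subset = keep)
  gm <- function(maps, label) data.frame(
    fit = label,
    max_lct = max(maps$timing$lct_values),
    bolus_duration = stats::median(maps$bolus_duration[mask]),
    cbf = stats::median(maps$cbf[mask]),
    boundary_fraction = mean(maps$boundary_flag[mask], na.rm = TRUE))
  structure(list(full = full, truncated = trunc,
                 comparison = rbind(gm(full, "full"), gm(trunc, "truncated")),
                 bd_values = list(full = full$bolus_duration[mask],
                                  truncated = trunc$bolus_duration[mask])),
            class = "truncation_result")
}
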