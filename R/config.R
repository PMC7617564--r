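# YAML run configuration and JSON provenance sidecars.

config_schema <- list(
  paths = c("dm", "m0", "gm_pve", "atlas", "region_pve_dir", "out"),
  timing = c("lct_values", "crusher_to_readout", "slice_delay", "n_slices"),
  physio = c("alpha", "alpha_bgs", "t1_blood", "t1_tissue", "lambda_bt"),
  mask = c("gm_pve_threshold", "m0_fraction_threshold", "region_pve_threshold"),
  phantom = c("grid", "condition_table", "n_subjects", "noise_sd",
              "n_pairs_per_lct", "m0_brain", "m0_background"),
  seed = NULL,
  conditions = NULL,
  petco2_delta = NULL)

check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown))
    stop("unknown key(s) in ", where, ": ", paste(unknown, collapse = ", "))
}

#' Read and validate a YAML run configuration
#'
#' The schema is validated before any computation: unknown keys anywhere
#' are rejected. Recognised blocks: `paths`, `timing` (constructs an
#' [acquisition_timing()]), `physio` ([physio_constants()]), `mask`
#' ([mask_spec()]), `phantom`, `seed`, `conditions`, `petco2_delta`.
#'
#' @param path YAML file.
#' @return A list of class `run_config` with parsed component objects
#'   (`timing`, `physio`, `mask` where present) plus the raw blocks.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, names(config_schema), "config")
  for (blk in c("paths", "timing", "physio", "mask", "phantom"))
    if (!is.null(cfg[[blk]]))
      check_keys(cfg[[blk]], config_schema[[blk]], blk)
  out <- cfg
  if (!is.null(cfg$timing))
    out$timing <- do.call(acquisition_timing, cfg$timing)
  out$physio <- if (is.null(cfg$physio)) physio_constants()
                else do.call(physio_constants, cfg$physio)
  out$mask <- if (is.null(cfg$mask)) mask_spec()
              else do.call(mask_spec, cfg$mask)
  structure(out, class = "run_config")
}

#' Write a JSON provenance sidecar
#'
#' Records the constants, thresholds, seed and software version used by a
#' pipeline stage. Deliberately timestamp-free so repeated runs with the
#' same seed produce byte-identical outputs.
#'
#' @param path Output JSON path.
#' @param consts A [physio_constants()].
#' @param mask_spec A [mask_spec()].
#' @param seed Integer seed used.
#' @param extra Named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, consts = physio_constants(),
                             mask_spec = NULL, seed = NULL, extra = list()) {
  payload <- c(list(
    software = "vsaslkin",
    version = as.character(utils::packageVersion("vsaslkin")),
    physio = unclass(consts)),
    if (!is.null(mask_spec)) list(mask = unclass(mask_spec)),
    if (!is.null(seed)) list(seed = seed),
    extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write region or CVR summaries as CSV
#'
#' Region summaries are written one row per region with mean/SD columns;
#' macrovascular blood volume is reported in percent. CVR results are
#' written one row per subject plus a `group` row. Empty summaries yield a
#' header-only file.
#'
#' @param x A `region_summary` data.frame from [summarize_regions()], or a
#'   `cvr_result` from [cvr_from_cbf()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path) {
  if (inherits(x, "cvr_result")) {
    n <- length(x$per_subject)
    df <- data.frame(
      subject = c(as.character(seq_len(n)), "group_mean", "group_sd"),
      cvr_pct_per_mmhg = c(x$per_subject, x$mean, x$sd),
      percent_cbf_change = c(x$percent_cbf_change,
                             mean(x$percent_cbf_change, na.rm = TRUE),
                             stats::sd(x$percent_cbf_change, na.rm = TRUE)),
      delta_petco2_mmhg = c(x$delta_petco2, mean(x$delta_petco2),
                            stats::sd(x$delta_petco2)))
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  df <- as.data.frame(x)
  for (col in c("macro_bv_mean", "macro_bv_sd"))
    if (col %in% names(df)) {
      df[[sub("macro_bv", "macro_bv_pct", col)]] <- 100 * df[[col]]
      df[[col]] <- NULL
    }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
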