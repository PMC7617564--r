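#' Physiological constants for VSASL quantification
#'
#' Fixed scalars of the kinetic model: labelling efficiency, background
#' suppression attenuation, longitudinal relaxation times and the
#' blood--tissue partition coefficient. Defaults are the values commonly
#' used for FT-VSI VSASL at 3T.
#'
#' @param alpha Inversion (labelling) efficiency, dimensionless (default 0.56).
#' @param alpha_bgs Residual signal attenuation caused by the background
#'   suppression pulses, dimensionless (default 0.86).
#' @param t1_blood Longitudinal relaxation time of arterial blood, seconds
#'   (default 1.6).
#' @param t1_tissue Longitudinal relaxation time of tissue, seconds
#'   (default 1.3).
#' @param lambda_bt Blood--tissue partition coefficient, ml/g (default 0.9).
#'
#' @return An object of class `physio_constants`.
#' @export
#' @examples
#' physio_constants()
physio_constants <- function(alpha = 0.56, alpha_bgs = 0.86,
                             t1_blood = 1.6, t1_tissue = 1.3,
                             lambda_bt = 0.9) {
  vals <- c(alpha = alpha, alpha_bgs = alpha_bgs, t1_blood = t1_blood,
            t1_tissue = t1_tissue, lambda_bt = lambda_bt)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all physiological constants must be finite and strictly positive")
  if (alpha > 1 || alpha_bgs > 1)
    stop("alpha and alpha_bgs are efficiencies and cannot exceed 1")
  structure(list(alpha = alpha, alpha_bgs = alpha_bgs, t1_blood = t1_blood,
                 t1_tissue = t1_tissue, lambda_bt = lambda_bt),
            class = "physio_constants")
}

#' Acquisition timing geometry
#'
#' Describes the sampled label-to-crusher times (LCT) and the readout delay
#' geometry of a 2D ascending-slice EPI readout: a fixed delay between the
#' vascular crushing module and the first slice, plus a constant per-slice
#' increment.
#'
#' @param lct_values Strictly increasing positive label-to-crusher times,
#'   seconds.
#' @param crusher_to_readout Delay from crusher module to the first slice,
#'   seconds (default 0.050).
#' @param slice_delay Additional delay per ascending slice, seconds
#'   (default 0.0425).
#' @param n_slices Number of slices (default 15).
#'
#' @return An object of class `acquisition_timing`.
#' @export
acquisition_timing <- function(lct_values,
                               crusher_to_readout = 0.050,
                               slice_delay = 0.0425,
                               n_slices = 15L) {
  lct_values <- as.numeric(lct_values)
  if (length(lct_values) < 1 || any(!is.finite(lct_values)) ||
      any(lct_values <= 0))
    stop("lct_values must be positive and finite")
  if (is.unsorted(lct_values, strictly = TRUE))
    stop("lct_values must be strictly increasing")
  if (crusher_to_readout < 0 || slice_delay < 0)
    stop("readout delays must be nonnegative")
  n_slices <- as.integer(n_slices)
  if (n_slices < 1) stop("n_slices must be at least 1")
  structure(list(lct_values = lct_values,
                 crusher_to_readout = crusher_to_readout,
                 slice_delay = slice_delay,
                 n_slices = n_slices),
            class = "acquisition_timing")
}

#' Label-to-readout time for a slice
#'
#' Converts a label-to-crusher time to the effective label-to-readout time of
#' a given slice: `lct + crusher_to_readout + slice_index * slice_delay`.
#' Slices are indexed from 0 (first acquired, bottom of the ascending stack).
#'
#' @param lct Label-to-crusher time(s), seconds. Vectorised.
#' @param slice_index Zero-based slice index, `0 <= slice_index < n_slices`.
#' @param timing An [acquisition_timing()] object.
#'
#' @return Label-to-readout time(s) in seconds.
#' @export
#' @examples
#' tm <- acquisition_timing(lct_values = c(0.55, 1.39))
#' readout_time(1.39, 0L, tm)  # 1.44 s
readout_time <- function(lct, slice_index, timing) {
  stopifnot(inherits(timing, "acquisition_timing"))
  slice_index <- as.integer(slice_index)
  if (length(slice_index) != 1 || is.na(slice_index) ||
      slice_index < 0L || slice_index >= timing$n_slices)
    stop("slice_index must satisfy 0 <= slice_index < n_slices")
  lct + timing$crusher_to_readout + slice_index * timing$slice_delay
}

#' Tissue parameter set for one voxel
#'
#' The four fitted quantities of the two-compartment model plus the voxel's
#' equilibrium signal. Perfusion `f` is stored in ml/g/s throughout; the
#' conventional CBF unit ml/100 g/min (factor 6000) is applied only when
#' reporting. Fitted values of `f` and `macro_bv` may be negative (the search
#' is unconstrained); signs are handled post hoc.
#'
#' @param f Perfusion, ml/g/s.
#' @param bolus_duration Tissue bolus duration tau, seconds.
#' @param macro_bv Apparent macrovascular blood volume fraction,
#'   dimensionless.
#' @param macro_bolus_duration Macrovascular bolus duration tau_macro,
#'   seconds.
#' @param m0 Equilibrium (proton density) signal of the voxel, must be
#'   positive.
#'
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(f, bolus_duration, macro_bv,
                          macro_bolus_duration, m0) {
  if (!is.finite(m0) || m0 <= 0) stop("m0 must be finite and positive")
  structure(list(f = f, bolus_duration = bolus_duration,
                 macro_bv = macro_bv,
                 macro_bolus_duration = macro_bolus_duration, m0 = m0),
            class = "tissue_params")
}

#' @export
print.physio_constants <- function(x, ...) {
  cat("VSASL physiological constants:\n")
  cat(sprintf("  alpha = %.3f, alpha_bgs = %.3f\n", x$alpha, x$alpha_bgs))
  cat(sprintf("  T1 blood = %.3f s, T1 tissue = %.3f s, lambda = %.2f ml/g\n",
              x$t1_blood, x$t1_tissue, x$lambda_bt))
  invisible(x)
}

#' @export
print.acquisition_timing <- function(x, ...) {
  cat(sprintf("Acquisition timing: %d LCTs in [%.3g, %.3g] s, %d slices\n",
              length(x$lct_values), min(x$lct_values), max(x$lct_values),
              x$n_slices))
  cat(sprintf("  crusher-to-readout %.4g s, per-slice delay %.4g s\n",
              x$crusher_to_readout, x$slice_delay))
  invisible(x)
}

# CBF unit conversion: ml/g/s -> ml/100 g/min
#' Convert perfusion to conventional CBF units
#'
#' @param f Perfusion in ml/g/s.
#' @return CBF in ml/100 g/min (`f * 6000`).
#' @export
f_to_cbf <- function(f) f * 6000

#' @rdname f_to_cbf
#' @param cbf CBF in ml/100 g/min.
#' @export
cbf_to_f <- function(cbf) cbf / 6000
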