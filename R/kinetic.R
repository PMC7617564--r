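# Two-compartment VSASL forward model.
#
# Tissue compartment: Buxton-style general kinetic model specialised to
# velocity-selective labelling with instantaneous bolus arrival. Because the
# readout always follows the vascular crusher (t > LCT >= tau_eff), only the
# post-delivery branch is needed; the inflow branch (t < tau) of the general
# model is deliberately not implemented.
#
# Macrovascular compartment: residual intravascular signal surviving the
# crusher, decaying with blood T1 and vanishing as a step once the
# macrovascular bolus has washed out.

# Apparent tissue relaxation rate including perfusion clearance:
# 1/T1' = 1/T1_tissue + f/lambda.
t1_prime_rate <- function(f, consts) 1 / consts$t1_tissue + f / consts$lambda_bt

# k = 1/T1_blood - 1/T1'
k_rate <- function(f, consts) 1 / consts$t1_blood - t1_prime_rate(f, consts)

#' Correction factor qp(t) of the tissue kinetic model
#'
#' `qp(t) = exp(k t) (1 - exp(-k tau)) / (k tau)` with
#' `k = 1/T1_blood - 1/T1'` and `1/T1' = 1/T1_tissue + f/lambda`. The factor
#' accounts for the difference between blood and tissue longitudinal
#' relaxation during delivery. The singularity at `k -> 0` is removable; for
#' `|k tau| < 1e-6` a series expansion is used to avoid cancellation.
#'
#' @param f Perfusion, ml/g/s.
#' @param tau_eff Effective bolus duration `min(bolus_duration, LCT)`,
#'   seconds; must be positive.
#' @param t Label-to-readout time(s), seconds; `t >= tau_eff`.
#' @param consts A [physio_constants()] object.
#'
#' @return Dimensionless correction factor, same length as `t`.
#' @export
qp_factor <- function(f, tau_eff, t, consts) {
  if (any(tau_eff <= 0)) stop("tau_eff must be strictly positive")
  k <- k_rate(f, consts)
  x <- k * tau_eff
  # (1 - exp(-x))/x with series fallback near the removable singularity
  frac <- ifelse(abs(x) < 1e-6,
                 1 - x / 2 + x^2 / 6,
                 -expm1(-x) / x)
  exp(k * t) * frac
}

#' Tissue compartment difference signal
#'
#' Closed form of the post-delivery tissue kinetic model:
#' `dM(t) = 2 alpha alpha_bgs f tau_eff M0 exp(-t/T1_blood) qp(t)` with
#' `tau_eff = min(bolus_duration, LCT)`: when the trailing edge of the
#' labelled bolus has not yet arrived at crusher time, the crusher defines
#' the effective bolus.
#'
#' @param params A [tissue_params()] object (uses `f`, `bolus_duration`,
#'   `m0`).
#' @param lct Label-to-crusher time(s), seconds. Vectorised jointly with `t`.
#' @param t Label-to-readout time(s), seconds; `t >= lct` elementwise.
#' @param consts A [physio_constants()] object.
#'
#' @return Difference signal in the units of `m0`.
#' @export
delta_m_tissue <- function(params, lct, t, consts) {
  if (any(t < lct)) stop("readout time t must not precede the crusher (t >= lct)")
  f <- params$f
  bd <- params$bolus_duration
  if (f == 0 || bd == 0) return(rep(0, length(t)))
  tau_eff <- pmin(bd, lct)
  2 * consts$alpha * consts$alpha_bgs * f * tau_eff * params$m0 *
    exp(-t / consts$t1_blood) * qp_factor(f, tau_eff, t, consts)
}

#' Macrovascular compartment difference signal
#'
#' Residual intravascular signal not removed by the vascular crushing
#' module: `2 alpha alpha_bgs macroBV M0 exp(-t/T1_blood)` while
#' `t <= tau_macro`, exactly zero afterwards (step trailing edge).
#'
#' @param params A [tissue_params()] object (uses `macro_bv`,
#'   `macro_bolus_duration`, `m0`).
#' @param t Label-to-readout time(s), seconds; must be positive.
#' @param consts A [physio_constants()] object.
#'
#' @return Difference signal in the units of `m0`.
#' @export
delta_m_macro <- function(params, t, consts) {
  if (any(t <= 0)) stop("t must be positive")
  amp <- 2 * consts$alpha * consts$alpha_bgs * params$macro_bv * params$m0
  ifelse(t <= params$macro_bolus_duration, amp * exp(-t / consts$t1_blood), 0)
}

#' Total modelled difference signal at a slice's readout time
#'
#' Sum of the tissue and macrovascular compartments evaluated at
#' `t = readout_time(lct, slice_index, timing)`.
#'
#' @inheritParams delta_m_tissue
#' @param slice_index Zero-based slice index.
#' @param timing An [acquisition_timing()] object.
#'
#' @return Difference signal(s) in the units of `m0`.
#' @export
delta_m_total <- function(params, lct, slice_index, timing, consts) {
  t <- readout_time(lct, slice_index, timing)
  delta_m_tissue(params, lct, t, consts) + delta_m_macro(params, t, consts)
}
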