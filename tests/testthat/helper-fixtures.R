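# Shared fixtures and independent oracles.

exp1_timing <- function(n_slices = 15L)
  acquisition_timing(c(0.55, 0.66, 0.8, 0.96, 1.15, 1.39, 1.67, 2, 2.4, 2.9, 3.5),
                     n_slices = n_slices)

exp2_timing <- function(n_slices = 15L)
  acquisition_timing(c(0.55, 0.66, 0.8, 0.96, 1.15, 1.39, 1.67, 2),
                     n_slices = n_slices)

# Table-derived grey-matter parameter sets (rest 2 cm/s and hypercapnia)
gm_rest_params <- function(m0 = 1000)
  tissue_params(f = 57 / 6000, bolus_duration = 2.20, macro_bv = 0.001,
                macro_bolus_duration = 1.22, m0 = m0)

gm_co2_params <- function(m0 = 1000)
  tissue_params(f = 83 / 6000, bolus_duration = 1.43, macro_bv = 0.0015,
                macro_bolus_duration = 1.22, m0 = m0)

# Independent oracle for the tissue compartment: brute-force numerical
# convolution of delivery (blood T1 decay) with the tissue residue function
# (apparent T1'), instantaneous arrival. Never calls the closed form.
conv_oracle_tissue <- function(f, bolus_duration, m0, lct, t,
                               consts = physio_constants()) {
  tau_eff <- min(bolus_duration, lct)
  if (f == 0 || tau_eff <= 0) return(0)
  t1p <- 1 / (1 / consts$t1_tissue + f / consts$lambda_bt)
  int <- stats::integrate(function(s)
    exp(-s / consts$t1_blood) * exp(-(t - s) / t1p),
    0, tau_eff, rel.tol = 1e-12, abs.tol = 0)$value
  2 * consts$alpha * consts$alpha_bgs * m0 * f * int
}

# Clean single-voxel series from a parameter set (slice 0 unless stated)
clean_series <- function(params, timing, slice_index = 0L) {
  dm <- delta_m_total(params, timing$lct_values, slice_index, timing,
                      physio_constants())
  voxel_series(dm, timing$lct_values, slice_index, params$m0)
}

# Small noise-free phantom preset for pipeline tests
tiny_preset <- function(preset = experiment1_preset, grid = c(14L, 14L, 6L),
                        seed = 42L, n_subjects = 1L, noise_sd = 0,
                        regions = NULL, sds_zero = FALSE, ...) {
  pre <- preset(grid = grid, seed = seed, ...)
  pre$spec$n_subjects <- as.integer(n_subjects)
  pre$spec$noise_sd <- noise_sd
  if (!is.null(regions)) pre$spec$regions <- regions
  if (sds_zero)
    pre$spec$regions[c("bd_sd", "cbf_sd", "macro_bv_sd", "tmacro_sd")] <- 0
  pre
}

# Independent oracle for paired t-test power: chi-square mixture
# representation  P(|T| > c) = E_W[ Phi(ncp - c sqrt(W/df))
#                               + Phi(-ncp - c sqrt(W/df)) ],  W ~ chisq_df,
# evaluated by numeric integration (never calls pt(ncp)).
power_oracle <- function(n, dz, alpha = 0.05) {
  df <- n - 1
  ncp <- dz * sqrt(n)
  crit <- stats::qt(1 - alpha / 2, df)
  stats::integrate(function(w)
    stats::dchisq(w, df) *
      (stats::pnorm(ncp - crit * sqrt(w / df)) +
       stats::pnorm(-ncp - crit * sqrt(w / df))),
    0, Inf, rel.tol = 1e-10)$value
}
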