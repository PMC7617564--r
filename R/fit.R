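# Multi-start unconstrained least-squares estimation of the four kinetic
# parameters (f, bolus_duration, macro_bv, macro_bolus_duration) per voxel.
#
# The macrovascular bolus duration enters the model through a step function,
# so the sum of squares is piecewise constant in tau_macro between
# consecutive readout times and a quasi-Newton step cannot move it. It is
# therefore refined by profiling over the readout-time breakpoints (with a
# closed-form macro_bv per candidate) and reported as the smallest value
# consistent with the winning inclusion set; the smooth parameters are then
# re-polished. The same smallest-consistent-value convention resolves the
# flat-sum-of-squares regime of bolus_duration above the largest LCT.

#' Observed difference-signal series for one voxel
#'
#' @param dm_values Observed difference signal per LCT (already averaged over
#'   tag/control pairs), signal units.
#' @param lct_values Label-to-crusher times, seconds; same length as
#'   `dm_values`.
#' @param slice_index Zero-based slice index of the voxel.
#' @param m0 Equilibrium signal of the voxel; must be positive.
#'
#' @return An object of class `voxel_series`.
#' @export
voxel_series <- function(dm_values, lct_values, slice_index, m0) {
  if (length(dm_values) != length(lct_values))
    stop("dm_values and lct_values must have equal length")
  if (!is.finite(m0) || m0 <= 0) stop("m0 must be finite and positive")
  structure(list(dm_values = as.numeric(dm_values),
                 lct_values = as.numeric(lct_values),
                 slice_index = as.integer(slice_index),
                 m0 = as.numeric(m0)),
            class = "voxel_series")
}

# Fast forward model on a raw parameter vector c(f, bd, mbv, tmacro).
# Negative bolus durations give zero tissue signal (continuous at 0);
# negative f / macro_bv are permitted during the unconstrained search.
vs_model <- function(par, lct, t, m0, consts) {
  f <- par[1L]; bd <- par[2L]; mbv <- par[3L]; tm <- par[4L]
  amp <- 2 * consts$alpha * consts$alpha_bgs * m0
  eb <- exp(-t / consts$t1_blood)
  out <- ifelse(t <= tm, amp * mbv * eb, 0)
  tau <- pmin(bd, lct)
  pos <- tau > 0
  if (f != 0 && any(pos)) {
    k <- 1 / consts$t1_blood - (1 / consts$t1_tissue + f / consts$lambda_bt)
    x <- k * tau[pos]
    frac <- ifelse(abs(x) < 1e-6, 1 - x / 2 + x^2 / 6, -expm1(-x) / x)
    out[pos] <- out[pos] +
      amp * f * tau[pos] * eb[pos] * exp(k * t[pos]) * frac
  }
  out
}

#' Residual sum of squares of the kinetic model for one voxel
#'
#' Sum over LCTs of squared differences between the observed series and the
#' forward model evaluated at the voxel's readout times. This is the
#' quantity minimised by [fit_voxel()] (internally scaled by `m0^2` for
#' conditioning).
#'
#' @param params A [tissue_params()] object.
#' @param series A [voxel_series()].
#' @param timing An [acquisition_timing()].
#' @param consts A [physio_constants()].
#'
#' @return Residual sum of squares, signal units squared.
#' @export
objective <- function(params, series, timing, consts) {
  t <- readout_time(series$lct_values, series$slice_index, timing)
  pred <- vs_model(c(params$f, params$bolus_duration, params$macro_bv,
                     params$macro_bolus_duration),
                   series$lct_values, t, params$m0, consts)
  sum((series$dm_values - pred)^2)
}

#' Default multi-start grid
#'
#' Starting values for the multi-start search: bolus duration starts
#' spanning the physiological range, macrovascular bolus duration starts
#' covering the sub-second to ~1.3 s range (retained for interface
#' compatibility; [fit_voxel()] enumerates the macro inclusion sets
#' exhaustively), a fixed small macro_bv, and two perfusion starts
#' obtained by inverting the model with `qp ~ 1`: one from the shortest
#' LCTs and one from mid/late LCTs where macrovascular contamination has
#' washed out.
#'
#' @param series A [voxel_series()].
#' @param timing An [acquisition_timing()].
#' @param consts A [physio_constants()].
#' @param bd_starts Bolus-duration starting values, seconds.
#' @param tm_starts Macrovascular bolus-duration starting values, seconds.
#' @param mbv_start Macrovascular blood volume starting value.
#'
#' @return A matrix with one row per start, columns `f`, `bd`, `mbv`, `tm`.
#' @export
default_start_grid <- function(series, timing, consts,
                               bd_starts = c(0.8, 1.4, 2.2, 3.0),
                               tm_starts = c(0.4, 0.9, 1.3),
                               mbv_start = 0.001) {
  lct <- series$lct_values
  t <- readout_time(lct, series$slice_index, timing)
  amp <- 2 * consts$alpha * consts$alpha_bgs * series$m0
  inv <- function(j) {   # invert the tissue model with qp ~ 1, tau = LCT
    f <- mean(series$dm_values[j] /
                (amp * lct[j] * exp(-t[j] / consts$t1_blood)))
    if (!is.finite(f)) f <- 0.005
    min(max(f, 1e-4), 0.05)
  }
  f_short <- inv(seq_len(min(2L, length(lct))))
  # second start from mid/late LCTs, where residual macrovascular signal
  # has typically washed out and cannot bias the perfusion estimate
  late <- which(t > 1.3)
  f_starts <- unique(c(f_short, if (length(late)) inv(late)))
  grid <- expand.grid(f = f_starts, bd = bd_starts, tm = tm_starts)
  cbind(f = grid$f, bd = grid$bd,
        mbv = rep(mbv_start, nrow(grid)), tm = grid$tm)
}

# One BFGS run; returns list(par, value, convergence) or NULL on failure.
run_bfgs <- function(par, nobj, free = seq_along(par), maxit = 500L) {
  fixed <- par
  fn <- function(p) {
    fixed[free] <- p
    v <- nobj(fixed)
    if (!is.finite(v)) .Machine$double.xmax else v
  }
  pscale <- c(0.01, 1, 0.001, 1)[free]
  res <- tryCatch(
    stats::optim(par[free], fn, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-12,
                                parscale = pscale)),
    error = function(e) NULL)
  if (is.null(res)) return(NULL)
  fixed[free] <- res$par
  list(par = fixed, value = res$value, convergence = res$convergence)
}

#' Fit the kinetic model to one voxel by multi-start least squares
#'
#' Minimises the (M0-normalised) residual sum of squares over the four
#' parameters. Because the macrovascular trailing edge is a step, the
#' objective is piecewise constant in the macrovascular bolus duration
#' between consecutive readout times; the fitter therefore enumerates all
#' macro inclusion sets exactly, profiles the (linear) macrovascular
#' amplitude in closed form, and solves the remaining smooth
#' (f, bolus duration) problem by a compiled simplex search from every
#' start, followed by a quasi-Newton (BFGS) polish of the winner. Ties are
#' broken towards the smallest bolus duration, then the smallest
#' macrovascular bolus duration. A bolus duration fitted beyond the
#' largest LCT is reported as the largest LCT (the smallest value with an
#' identical model; the sum of squares is flat beyond it) and flagged as a
#' boundary estimate; the macrovascular bolus duration is reported as the
#' last readout time carrying macrovascular signal (the smallest value
#' consistent with the data).
#'
#' @param series A [voxel_series()] with at least 6 LCT points.
#' @param timing An [acquisition_timing()].
#' @param consts A [physio_constants()].
#' @param starts Start matrix as from [default_start_grid()] (the default).
#'
#' @return An object of class `fit_result`: fields `params`
#'   ([tissue_params()]), `sse` (signal units squared), `n_starts_converged`,
#'   `start_used`, `converged`, `boundary_flag` (bolus duration at or beyond
#'   98% of the largest LCT), `degenerate` (constant input series), and
#'   `macro_excluded` (set by [postprocess_fit()]).
#' @export
fit_voxel <- function(series, timing, consts, starts = NULL) {
  stopifnot(inherits(series, "voxel_series"))
  n <- length(series$lct_values)
  if (n < 6L)
    stop("fit_voxel needs at least 6 LCT points (4 free parameters + margin)")
  if (is.null(starts)) starts <- default_start_grid(series, timing, consts)
  lct <- series$lct_values
  t <- readout_time(lct, series$slice_index, timing)
  m0 <- series$m0
  dmn <- series$dm_values / m0
  nobj <- function(par) {
    cpp_nobj(par, lct, t, dmn, consts$alpha, consts$alpha_bgs,
             consts$t1_blood, consts$t1_tissue, consts$lambda_bt)
  }
  max_lct <- max(lct)

  # The macro compartment is linear in macro_bv and piecewise constant in
  # tau_macro (breakpoints at the readout times), so both are profiled out
  # in closed form via cumulative sums; BFGS searches only (f, bd).
  amp <- 2 * consts$alpha * consts$alpha_bgs   # macro basis amplitude (M0 = 1)
  eb <- exp(-t / consts$t1_blood)
  bsig <- amp * eb
  cum_bb <- cumsum(bsig * bsig)
  profile_macro <- function(r0) {
    # best (macro_bv, tau_macro) for tissue residual r0; smallest-tau_macro
    # tie-break. Candidate j includes readout times t[1..j]; j = 0 is none.
    cum_br <- cumsum(bsig * r0)
    ss0 <- sum(r0 * r0)
    sse <- c(ss0, ss0 - cum_br^2 / cum_bb)
    j <- which(sse <= min(sse) + 1e-12 * (1 + min(sse)))[1L] - 1L
    if (j == 0L) list(mbv = 0, tm = 0, sse = ss0)
    else list(mbv = cum_br[j] / cum_bb[j], tm = t[j], sse = sse[j + 1L])
  }
  pobj <- function(fb) {
    cpp_profile_obj(fb, lct, t, dmn, bsig, cum_bb,
                    consts$alpha, consts$alpha_bgs, consts$t1_blood,
                    consts$t1_tissue, consts$lambda_bt)
  }
  run_fb <- function(fb0, reltol = 1e-8) {
    # exploration runs use a looser tolerance; the final BFGS polish is tight
    fn <- function(p) { v <- pobj(p); if (is.finite(v)) v else .Machine$double.xmax }
    tryCatch(stats::optim(fb0, fn, method = "BFGS",
                          control = list(maxit = 500L, reltol = reltol,
                                         parscale = c(0.01, 1))),
             error = function(e) NULL)
  }
  f_starts <- unique(starts[, "f"])
  bd_starts <- unique(starts[, "bd"])
  # exploration: exhaustive over the discrete macro inclusion sets (the
  # only values tau_macro can take), each a smooth 2-parameter (f, bd)
  # problem with the macro amplitude profiled out, solved by Nelder-Mead
  # from every start; all in compiled code
  expl <- cpp_explore(lct, t, dmn, bsig, f_starts, bd_starts,
                      consts$alpha, consts$alpha_bgs, consts$t1_blood,
                      consts$t1_tissue, consts$lambda_bt, 1e-9, 300L)
  vals <- expl[, 4L]
  n_conv <- sum(is.finite(vals))
  best_val <- min(vals)
  tied <- which(vals <= best_val + 1e-10 * (1 + best_val))
  # tie-break: smallest (clamped) bolus duration, then fewest macro points
  ord <- tied[order(pmin(expl[tied, 2L], max_lct), expl[tied, 3L])]
  win <- ord[1L]
  start_used <- (win - 1L) %% (length(f_starts) * length(bd_starts)) + 1L
  fb <- expl[win, 1:2]
  # quasi-Newton refinement of the winner on the profiled objective
  pol_fb <- run_fb(fb, reltol = 1e-13)
  if (!is.null(pol_fb) && pol_fb$value <= pobj(fb)) fb <- pol_fb$par
  if (is.infinite(best_val) && is.null(pol_fb)) {
    return(structure(list(
      params = tissue_params(NaN, NaN, NaN, NaN, m0), sse = NaN,
      n_starts_converged = 0L, start_used = NA_integer_, converged = FALSE,
      boundary_flag = NA, degenerate = TRUE, macro_excluded = NA),
      class = "fit_result"))
  }

  par <- c(fb[1L], fb[2L], 0, 0)
  for (pass in 1:2) {
    tis <- vs_model(c(par[1L], par[2L], 0, 0), lct, t, 1, consts)
    pm <- profile_macro(dmn - tis)
    tm_stable <- pass > 1L && pm$tm == par[4L]
    par[3L] <- pm$mbv
    par[4L] <- pm$tm
    if (tm_stable) break
    # polish the smooth parameters at the chosen inclusion set
    pol <- run_bfgs(par, nobj, free = 1:3)
    if (!is.null(pol) && pol$value <= nobj(par)) par <- pol$par
  }

  # flat regime: any bolus duration >= max LCT yields an identical model
  if (par[2L] > max_lct) par[2L] <- max_lct
  boundary <- is.finite(par[2L]) && par[2L] >= 0.98 * max_lct
  structure(list(
    params = tissue_params(par[1L], par[2L], par[3L], par[4L], m0),
    sse = nobj(par) * m0^2,
    n_starts_converged = n_conv,
    start_used = start_used,
    converged = TRUE,
    boundary_flag = boundary,
    degenerate = stats::sd(series$dm_values) == 0,
    macro_excluded = NA), class = "fit_result")
}

#' Post-hoc physiological consistency rules
#'
#' Bolus duration is set to zero when fitted perfusion is zero or negative;
#' the macrovascular bolus duration is set to zero, and the voxel flagged
#' for exclusion from macrovascular bolus-duration averages, when the fitted
#' macrovascular blood volume is zero or negative (no macrovascular signal
#' to characterise).
#'
#' @param result A `fit_result` from [fit_voxel()].
#' @return The modified `fit_result` with `macro_excluded` set.
#' @export
postprocess_fit <- function(result) {
  stopifnot(inherits(result, "fit_result"))
  p <- result$params
  if (is.finite(p$f) && p$f <= 0) p$bolus_duration <- 0
  excl <- is.finite(p$macro_bv) && p$macro_bv <= 0
  if (excl) p$macro_bolus_duration <- 0
  result$params <- p
  result$macro_excluded <- excl
  result
}

#' @export
print.fit_result <- function(x, ...) {
  p <- x$params
  cat("VSASL voxel fit:\n")
  cat(sprintf("  CBF %.2f ml/100g/min (f = %.4g ml/g/s), bolus duration %.3f s\n",
              f_to_cbf(p$f), p$f, p$bolus_duration))
  cat(sprintf("  macroBV %.3g (%.3f%%), macro bolus duration %.3f s\n",
              p$macro_bv, 100 * p$macro_bv, p$macro_bolus_duration))
  cat(sprintf("  sse %.4g, %d exploration runs, boundary %s\n",
              x$sse, x$n_starts_converged, x$boundary_flag))
  invisible(x)
}
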