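# Synthetic multi-subject phantom studies with the statistical structure the
# analysis assumes: region-wise parameter draws across subjects, a partial-
# volume taper at the brain edge to exercise the GM threshold, a low-signal
# M0 pocket to exercise the 50%-of-maximum rule, and additive Gaussian noise
# from the tag/control subtraction.

#' Regional kinetic parameters used by the phantom generator
#'
#' Group mean and across-subject standard deviation of bolus duration, CBF,
#' macrovascular blood volume and macrovascular bolus duration for the nine
#' atlas regions (four lobes, cerebellum, four subcortical structures) plus
#' a whole grey-matter row. Conditions: `vc2`/`vc3`/`vc4` (cut-off velocity
#' 2/3/4 cm/s at rest), `air` (normocapnia) and `co2` (hypercapnia).
#' Regional macrovascular values are not available, so the grey-matter level
#' values are applied to every region.
#'
#' @param condition One of `"vc2"`, `"vc3"`, `"vc4"`, `"air"`, `"co2"`.
#' @param include_gm Keep the aggregate `grey_matter` row (default FALSE:
#'   only paintable regions are returned).
#'
#' @return A data.frame with columns `region`, `bd_mean`, `bd_sd`,
#'   `cbf_mean`, `cbf_sd`, `macro_bv_mean`, `macro_bv_sd`, `tmacro_mean`,
#'   `tmacro_sd`.
#' @export
region_param_table <- function(condition = c("vc2", "vc3", "vc4", "air", "co2"),
                               include_gm = FALSE) {
  condition <- match.arg(condition)
  path <- system.file("extdata", "region_params.csv", package = "vsaslkin",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- tab[tab$condition == condition, , drop = FALSE]
  if (!include_gm) tab <- tab[tab$region != "grey_matter", , drop = FALSE]
  tab$condition <- NULL
  rownames(tab) <- NULL
  tab
}

#' Background-suppression inversion timings (protocol documentation)
#'
#' Static protocol table: delays from the end of the labelling module to the
#' centre of each of the three background-suppression inversion pulses, per
#' LCT. These timings enter no computation here -- their net effect on the
#' difference signal is summarised by the `alpha_bgs` constant.
#'
#' @return A data.frame with columns `lct_ms` and `inversion1_ms..3`.
#' @export
bgs_timing_table <- function() {
  utils::read.csv(system.file("extdata", "bgs_timing.csv",
                              package = "vsaslkin", mustWork = TRUE))
}

#' Experimental condition descriptor
#'
#' Hypercapnia is modelled as multiplicative scaling of the baseline draws:
#' `cbf_scale` on perfusion, `bolus_scale` on bolus duration, and
#' `macro_bv_scale` on macrovascular blood volume. The end-tidal CO2
#' increase for the condition is drawn per subject from
#' `Normal(petco2_delta_mean, petco2_delta_sd)`.
#'
#' @param name Condition label.
#' @param cbf_scale,bolus_scale,macro_bv_scale Multiplicative factors
#'   (default 1).
#' @param petco2_delta_mean,petco2_delta_sd End-tidal CO2 increase over
#'   baseline, mmHg (default 0).
#' @return A list of class `condition_spec`.
#' @export
condition_spec <- function(name, cbf_scale = 1, bolus_scale = 1,
                           macro_bv_scale = 1, petco2_delta_mean = 0,
                           petco2_delta_sd = 0) {
  stopifnot(is.character(name), length(name) == 1L,
            cbf_scale > 0, bolus_scale > 0, macro_bv_scale > 0,
            petco2_delta_sd >= 0)
  structure(list(name = name, cbf_scale = cbf_scale,
                 bolus_scale = bolus_scale, macro_bv_scale = macro_bv_scale,
                 petco2_delta_mean = petco2_delta_mean,
                 petco2_delta_sd = petco2_delta_sd),
            class = "condition_spec")
}

#' Phantom study specification
#'
#' @param grid 3D dimensions, slice axis last (default `c(32, 32, 15)`).
#' @param regions Region parameter data.frame as from
#'   [region_param_table()] (exactly 9 rows for the default geometry).
#' @param n_subjects Number of subjects.
#' @param noise_sd Noise standard deviation as a fraction of the voxel M0
#'   (default 0.002); each tag/control difference receives
#'   `Normal(0, noise_sd * M0 * sqrt(2))` noise.
#' @param n_pairs_per_lct Tag/control pairs averaged per LCT (default 4).
#' @param seed Random seed for the whole study.
#' @param conditions List of [condition_spec()]s (default: a single
#'   unscaled normocapnia condition).
#' @param m0_brain,m0_background Equilibrium signal inside / outside the
#'   phantom brain (arbitrary units).
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(32L, 32L, 15L),
                         regions = region_param_table("vc2"),
                         n_subjects = 13L,
                         noise_sd = 0.002,
                         n_pairs_per_lct = 4L,
                         seed = 1L,
                         conditions = list(condition_spec("normocapnia")),
                         m0_brain = 1000,
                         m0_background = 50) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3L, all(grid >= 6L))
  if (anyDuplicated(regions$region))
    stop("region labels must be unique")
  sds <- as.matrix(regions[, c("bd_sd", "cbf_sd", "macro_bv_sd", "tmacro_sd")])
  if (any(sds < 0)) stop("parameter standard deviations must be nonnegative")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  nm <- vapply(conditions, function(cc) cc$name, character(1))
  if (anyDuplicated(nm)) stop("condition names must be unique")
  structure(list(grid = grid, regions = regions,
                 n_subjects = as.integer(n_subjects), noise_sd = noise_sd,
                 n_pairs_per_lct = as.integer(n_pairs_per_lct),
                 seed = as.integer(seed), conditions = conditions,
                 m0_brain = m0_brain, m0_background = m0_background),
            class = "phantom_spec")
}

# Deterministic phantom geometry: a rectangular "brain" with a one-voxel
# partial-volume shell, partitioned into a 3x3 block of regions spanning all
# slices, plus a low-M0 pocket in the corner of the first region.
phantom_geometry <- function(grid, region_names, m0_brain, m0_background) {
  nx <- grid[1L]; ny <- grid[2L]; nz <- grid[3L]
  mx <- max(2L, round(nx * 0.12)); my <- max(2L, round(ny * 0.12))
  bx <- (mx + 1L):(nx - mx); by <- (my + 1L):(ny - my); bz <- seq_len(nz)
  brain <- array(FALSE, grid); brain[bx, by, bz] <- TRUE
  core <- array(FALSE, grid)
  core[bx[-c(1L, length(bx))], by[-c(1L, length(by))], bz] <- TRUE
  shell <- brain & !core

  # 3x3 in-plane partition of the brain box
  cutx <- floor(seq(min(bx) - 1L, max(bx), length.out = 4L))
  cuty <- floor(seq(min(by) - 1L, max(by), length.out = 4L))
  atlas <- array(0L, grid)
  xi <- array(0L, grid); yi <- array(0L, grid)
  for (b in 1:3) {
    xi[(cutx[b] + 1L):cutx[b + 1L], , ] <- b
    yi[, (cuty[b] + 1L):cuty[b + 1L], ] <- b
  }
  lab <- (xi - 1L) * 3L + yi
  atlas[brain] <- lab[brain]

  region_pve <- stats::setNames(lapply(seq_along(region_names), function(r) {
    pve <- array(0, grid)
    pve[atlas == r & core] <- 1
    pve[atlas == r & shell] <- 0.20     # below the 25% region threshold
    pve
  }), region_names)

  gm_pve <- array(0, grid)
  gm_pve[core] <- 1
  gm_pve[shell] <- 0.45                 # below the 50% GM threshold

  m0 <- array(m0_background, grid)
  m0[brain] <- m0_brain
  # low-signal pocket (EPI drop-off analogue) in the corner of region 1
  px <- bx[seq_len(max(2L, length(bx) %/% 4L))]
  py <- by[seq_len(max(2L, length(by) %/% 4L))]
  pz <- bz[seq_len(max(1L, nz %/% 4L))]
  pocket <- array(FALSE, grid); pocket[px, py, pz] <- TRUE
  m0[pocket] <- 0.3 * m0_brain          # fails the 50%-of-max rule

  list(brain = brain, core = core, shell = shell, atlas = atlas,
       region_pve = region_pve, gm_pve = gm_pve, m0 = m0, pocket = pocket,
       expected_mask = gm_pve >= 0.5 & m0 > 0.5 * max(m0))
}

# one truncated-normal draw per (region, parameter): negative draws redrawn
draw_positive <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate per-subject ground-truth parameter maps
#'
#' For each subject, one parameter set per region is drawn from the normal
#' distributions in `spec$regions` (negative draws redrawn, keeping truth
#' maps physical), and painted onto the phantom geometry. Across-subject
#' variability is region-wise, not voxelwise: within one subject every voxel
#' of a region shares the same truth.
#'
#' @param spec A [phantom_spec()].
#'
#' @return A list of `n_subjects` truth objects, each with ground-truth
#'   maps `f`, `bolus_duration`, `macro_bv`, `macro_bolus_duration`
#'   (3D arrays, zero outside the brain), the geometry volumes (`m0`,
#'   `gm_pve`, `atlas`, `region_pve`, `expected_mask`), and
#'   `region_truth`, the drawn per-region parameter table.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec$grid, spec$regions$region,
                          spec$m0_brain, spec$m0_background)
  set.seed(spec$seed)
  nr <- nrow(spec$regions)
  lapply(seq_len(spec$n_subjects), function(s) {
    rt <- data.frame(
      region = spec$regions$region,
      f = draw_positive(nr, spec$regions$cbf_mean, spec$regions$cbf_sd) / 6000,
      bolus_duration = draw_positive(nr, spec$regions$bd_mean,
                                     spec$regions$bd_sd),
      macro_bv = draw_positive(nr, spec$regions$macro_bv_mean,
                               spec$regions$macro_bv_sd),
      macro_bolus_duration = draw_positive(nr, spec$regions$tmacro_mean,
                                           spec$regions$tmacro_sd))
    paint <- function(vals) {
      m <- array(0, spec$grid)
      for (r in seq_len(nr)) m[geo$atlas == r] <- vals[r]
      m
    }
    list(subject = s,
         f = paint(rt$f),
         bolus_duration = paint(rt$bolus_duration),
         macro_bv = paint(rt$macro_bv),
         macro_bolus_duration = paint(rt$macro_bolus_duration),
         m0 = geo$m0, gm_pve = geo$gm_pve, atlas = geo$atlas,
         region_pve = geo$region_pve, expected_mask = geo$expected_mask,
         region_truth = rt)
  })
}

# Clean difference signal for one slice of truth maps at one LCT (array op).
dm_clean_slice <- function(f, bd, mbv, tmacro, m0, lct, t, consts) {
  amp <- 2 * consts$alpha * consts$alpha_bgs * m0
  eb <- exp(-t / consts$t1_blood)
  tau <- pmin(bd, lct)
  k <- 1 / consts$t1_blood - (1 / consts$t1_tissue + f / consts$lambda_bt)
  x <- k * tau
  frac <- ifelse(abs(x) < 1e-6, 1 - x / 2 + x^2 / 6, -expm1(-x) / x)
  tis <- ifelse(tau > 0 & f != 0, amp * f * tau * eb * exp(k * t) * frac, 0)
  mac <- ifelse(t <= tmacro, amp * mbv * eb, 0)
  tis + mac
}

#' Simulate one acquired study from ground-truth maps
#'
#' Evaluates the forward model at every voxel's slice readout time for every
#' LCT, applies the condition scaling, and averages `n_pairs` noisy
#' tag/control differences: each difference receives additive
#' `Normal(0, noise_sd * M0 * sqrt(2))` noise (the subtraction of two
#' noisy images).
#'
#' @param truth One element of [make_phantom()]'s output.
#' @param timing An [acquisition_timing()]; `n_slices` must equal the grid's
#'   slice count.
#' @param consts A [physio_constants()].
#' @param noise_sd Noise fraction of the voxel M0.
#' @param n_pairs Tag/control pairs averaged per LCT.
#' @param seed Seed for this study's noise and physiological draws.
#' @param condition A [condition_spec()].
#'
#' @return An object of class `study_image`: `dm` (4D array, LCT on axis 4),
#'   `m0`, `gm_pve`, `atlas`, `region_pve`, `timing`, `condition` (name),
#'   `petco2_delta` (mmHg), `truth` (scaled truth maps actually simulated,
#'   plus the unscaled input truth as `truth$baseline`).
#' @export
simulate_study <- function(truth, timing, consts = physio_constants(),
                           noise_sd = 0.002, n_pairs = 4L, seed = 1L,
                           condition = condition_spec("normocapnia")) {
  grid <- dim(truth$f)
  if (grid[3L] != timing$n_slices)
    stop("grid slice count must match timing n_slices")
  set.seed(as.integer(seed))
  petco2 <- if (condition$petco2_delta_sd > 0 ||
                condition$petco2_delta_mean != 0)
    stats::rnorm(1L, condition$petco2_delta_mean, condition$petco2_delta_sd)
  else 0
  f <- truth$f * condition$cbf_scale
  bd <- truth$bolus_duration * condition$bolus_scale
  mbv <- truth$macro_bv * condition$macro_bv_scale
  tmac <- truth$macro_bolus_duration
  lct <- timing$lct_values
  dm <- array(0, c(grid, length(lct)))
  for (l in seq_along(lct)) {
    for (k in seq_len(grid[3L])) {
      t <- readout_time(lct[l], k - 1L, timing)
      clean <- dm_clean_slice(f[, , k], bd[, , k], mbv[, , k], tmac[, , k],
                              truth$m0[, , k], lct[l], t, consts)
      if (noise_sd > 0) {
        nsd <- noise_sd * truth$m0[, , k] * sqrt(2)
        acc <- array(0, grid[1:2])
        for (p in seq_len(n_pairs))
          acc <- acc + clean + array(stats::rnorm(prod(grid[1:2])), grid[1:2]) * nsd
        dm[, , k, l] <- acc / n_pairs
      } else {
        dm[, , k, l] <- clean
      }
    }
  }
  structure(list(dm = dm, m0 = truth$m0, gm_pve = truth$gm_pve,
                 atlas = truth$atlas, region_pve = truth$region_pve,
                 timing = timing, condition = condition$name,
                 petco2_delta = petco2,
                 truth = list(f = f, bolus_duration = bd, macro_bv = mbv,
                              macro_bolus_duration = tmac,
                              region_truth = truth$region_truth,
                              expected_mask = truth$expected_mask,
                              baseline = truth)),
            class = "study_image")
}

#' Presets emulating the two acquisition designs
#'
#' `experiment1_preset()`: 11 LCTs from 0.55 to 3.5 s, 13 subjects, one
#' resting condition, regional parameters for the chosen cut-off velocity.
#' `experiment2_preset()`: the first 8 LCTs (maximum 2.0 s), 19 subjects
#' (the a-priori sample size), baseline parameters from the normocapnia
#' column plus a hypercapnia condition scaling CBF by 1.45, bolus duration
#' by 1.43/1.65 and macrovascular blood volume by 1.5, with a per-subject
#' end-tidal CO2 increase drawn from Normal(8.3, 2.4) mmHg.
#'
#' @param vcutoff Cut-off velocity condition for experiment 1.
#' @param grid Phantom grid (default `c(32, 32, 15)`).
#' @param seed Study seed.
#' @return A list with elements `spec` ([phantom_spec()]) and `timing`
#'   ([acquisition_timing()]).
#' @export
experiment1_preset <- function(vcutoff = c("vc2", "vc3", "vc4"),
                               grid = c(32L, 32L, 15L), seed = 1L) {
  vcutoff <- match.arg(vcutoff)
  timing <- acquisition_timing(
    c(0.55, 0.66, 0.8, 0.96, 1.15, 1.39, 1.67, 2, 2.4, 2.9, 3.5),
    n_slices = grid[3L])
  spec <- phantom_spec(grid = grid, regions = region_param_table(vcutoff),
                       n_subjects = 13L, seed = seed)
  list(spec = spec, timing = timing)
}

#' @rdname experiment1_preset
#' @export
experiment2_preset <- function(grid = c(32L, 32L, 15L), seed = 1L) {
  timing <- acquisition_timing(
    c(0.55, 0.66, 0.8, 0.96, 1.15, 1.39, 1.67, 2),
    n_slices = grid[3L])
  spec <- phantom_spec(
    grid = grid, regions = region_param_table("air"), n_subjects = 19L,
    seed = seed,
    conditions = list(
      condition_spec("normocapnia"),
      condition_spec("hypercapnia", cbf_scale = 1.45,
                     bolus_scale = 1.43 / 1.65, macro_bv_scale = 1.5,
                     petco2_delta_mean = 8.3, petco2_delta_sd = 2.4)))
  list(spec = spec, timing = timing)
}

#' Simulate a full multi-subject, multi-condition study
#'
#' Driver tying [make_phantom()] and [simulate_study()] together. Each
#' subject-condition simulation gets a seed derived deterministically from
#' the study seed, so the whole study is reproducible end to end.
#'
#' @param preset A list with `spec` and `timing` as from
#'   [experiment1_preset()] / [experiment2_preset()].
#' @param consts A [physio_constants()].
#'
#' @return A list with `timing`, `spec`, and `subjects`: per subject a list
#'   with the `truth` and one `study_image` per condition (named by
#'   condition).
#' @export
simulate_experiment <- function(preset, consts = physio_constants()) {
  spec <- preset$spec
  truths <- make_phantom(spec)
  subjects <- lapply(seq_len(spec$n_subjects), function(s) {
    studies <- stats::setNames(lapply(seq_along(spec$conditions), function(ci) {
      simulate_study(truths[[s]], preset$timing, consts,
                     noise_sd = spec$noise_sd,
                     n_pairs = spec$n_pairs_per_lct,
                     seed = (spec$seed * 10007L + s * 131L + ci) %% 2147483647L,
                     condition = spec$conditions[[ci]])
    }), vapply(spec$conditions, function(cc) cc$name, character(1)))
    list(truth = truths[[s]], studies = studies)
  })
  list(spec = spec, timing = preset$timing, subjects = subjects)
}

#' Grey-matter mean signal series of a study
#'
#' Averages the observed difference signal and M0 over the masked voxels of
#' one slice (the centre slice by default), yielding a high-SNR series the
#' model can be fitted to directly -- the curve-level analogue of a
#' grey-matter average fit.
#'
#' @param study A `study_image`.
#' @param mask Logical mask (default [build_mask()] on the study).
#' @param slice_index Zero-based slice to average over (default: centre
#'   slice). Restricting to one slice keeps a single well-defined readout
#'   time per LCT.
#'
#' @return A [voxel_series()].
#' @export
gm_mean_series <- function(study, mask = NULL, slice_index = NULL) {
  if (is.null(mask)) mask <- build_mask(study$gm_pve, study$m0)
  nz <- dim(study$m0)[3L]
  if (is.null(slice_index)) slice_index <- (nz - 1L) %/% 2L
  k <- slice_index + 1L
  sel <- mask[, , k]
  if (!any(sel)) stop("no masked voxels in the requested slice")
  dm <- apply(study$dm[, , k, , drop = FALSE], 4L,
              function(sl) mean(sl[sel]))
  voxel_series(dm, study$timing$lct_values, slice_index,
               mean(study$m0[, , k][sel]))
}
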