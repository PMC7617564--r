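consts <- physio_constants()

test_that("build_mask applies both thresholds", {
  dims <- c(4L, 4L, 2L)
  gm <- array(1, dims)
  m0 <- array(100, dims)
  expect_true(all(build_mask(gm, m0)))
  gm[1, 1, 1] <- 0.49                       # just below "at least 50%"
  gm[2, 1, 1] <- 0.50                       # inclusive threshold
  m0[3, 1, 1] <- 50                         # not > 50% of max
  m0[4, 1, 1] <- 51
  mask <- build_mask(gm, m0)
  expect_false(mask[1, 1, 1])
  expect_true(mask[2, 1, 1])
  expect_false(mask[3, 1, 1])
  expect_true(mask[4, 1, 1])
  expect_error(build_mask(gm, array(1, c(3, 4, 2))), "grid")
  expect_error(mask_spec(gm_pve_threshold = 0), "strictly in")
})

test_that("phantom mask matches the generator's ground-truth bookkeeping", {
  pre <- tiny_preset()
  truth <- make_phantom(pre$spec)[[1]]
  mask <- build_mask(truth$gm_pve, truth$m0)
  expect_identical(mask, truth$expected_mask)
  expect_gt(sum(mask), 0)
  # the low-M0 pocket and PVE shell are excluded by construction
  expect_lt(sum(mask), sum(truth$gm_pve > 0))
})

test_that("fit_image covers the mask and round-trips noise-free truth", {
  pre <- tiny_preset()                       # noise_sd = 0, 1 subject
  sim <- simulate_experiment(pre)
  st <- sim$subjects[[1]]$studies[[1]]
  mask <- build_mask(st$gm_pve, st$m0)
  maps <- fit_image(st, mask)
  # every masked voxel fitted, every unmasked voxel NaN
  expect_true(all(is.finite(maps$cbf[mask])))
  expect_identical(sum(is.nan(maps$cbf)), sum(!mask))
  # voxelwise recovery of the painted ground truth within 1%
  tr <- st$truth
  rel <- function(est, ref, sel = mask) max(abs(est[sel] - ref[sel]) / ref[sel])
  expect_lt(rel(maps$f, tr$f), 0.01)
  expect_lt(rel(maps$bolus_duration, tr$bolus_duration), 0.01)
  # the macro compartment is only observable in voxels whose first slice
  # readout precedes the macro washout; elsewhere the data carry no
  # macrovascular signal and the fit correctly reports zero
  first_t <- array(readout_time(st$timing$lct_values[1],
                                0L, st$timing), dim(mask))
  for (k in seq_len(dim(mask)[3]))
    first_t[, , k] <- readout_time(st$timing$lct_values[1], k - 1L,
                                   st$timing)
  visible <- mask & tr$macro_bolus_duration >= first_t
  expect_lt(rel(maps$macro_bv, tr$macro_bv, visible), 0.01)
  invisible_vox <- mask & !visible
  if (any(invisible_vox))
    expect_lt(max(abs(maps$macro_bv[invisible_vox])), 1e-6)
  expect_true(all(maps$converged[mask]))
  # truncation support: refitting on an LCT subset matches dimensions
  maps_t <- fit_image(st, mask, lct_subset = st$timing$lct_values <= 2.0)
  expect_equal(length(maps_t$timing$lct_values), 8L)
})

test_that("region medians recover per-region truth and respect thresholds", {
  pre <- tiny_preset()
  sim <- simulate_experiment(pre)
  st <- sim$subjects[[1]]$studies[[1]]
  maps <- fit_image(st)
  med <- region_medians(maps, st$region_pve)
  expect_identical(med$region,
                   c(names(st$region_pve), "grey_matter"))
  rt <- st$truth$region_truth
  for (r in seq_len(nrow(rt))) {
    row <- med[med$region == rt$region[r], ]
    expect_gt(row$n_voxels, 0)
    expect_lt(abs(row$bolus_duration - rt$bolus_duration[r]) /
                rt$bolus_duration[r], 0.01)
    expect_lt(abs(row$cbf - 6000 * rt$f[r]) / (6000 * rt$f[r]), 0.01)
  }
  # a region fully below the PVE threshold is empty
  rp <- st$region_pve
  rp[["caudate"]] <- rp[["caudate"]] * 0.2
  med2 <- region_medians(maps, rp)
  expect_identical(med2$n_voxels[med2$region == "caudate"], 0L)
  expect_true(is.nan(med2$cbf[med2$region == "caudate"]))
})

test_that("constant single-region phantom yields the constant as median", {
  dims <- c(6L, 6L, 2L)
  maps <- structure(list(
    cbf = array(57, dims), f = array(57 / 6000, dims),
    bolus_duration = array(2.2, dims), macro_bv = array(0.001, dims),
    macro_bolus_duration = array(1.2, dims), sse = array(0, dims),
    boundary_flag = array(FALSE, dims), macro_excluded = array(FALSE, dims),
    converged = array(TRUE, dims), mask = array(TRUE, dims)),
    class = "param_maps")
  med <- region_medians(maps, list(all = array(1, dims)))
  expect_equal(med$cbf, c(57, 57))
  expect_equal(med$bolus_duration, c(2.2, 2.2))
})

test_that("macro-excluded voxels are dropped from macro bolus medians only", {
  dims <- c(4L, 1L, 1L)
  base <- array(1, dims)
  maps <- structure(list(
    cbf = base * 50, f = base * 50 / 6000, bolus_duration = base * 2,
    macro_bv = array(c(0.001, 0.002, 0, 0), dims),
    macro_bolus_duration = array(c(1.0, 1.4, 0, 0), dims),
    sse = base * 0, boundary_flag = base == 0,
    macro_excluded = array(c(FALSE, FALSE, TRUE, TRUE), dims),
    converged = base == 1, mask = base == 1), class = "param_maps")
  med <- region_medians(maps, list(all = base))
  expect_equal(med$n_macro_voxels[1], 2L)
  expect_equal(med$macro_bolus_duration[1], 1.2)   # median of 1.0, 1.4
  expect_equal(med$bolus_duration[1], 2)           # all four voxels
})

test_that("group summaries aggregate across subjects, not voxels", {
  mk <- function(cbf, bd) data.frame(
    region = c("a", "grey_matter"), n_voxels = c(10L, 20L),
    n_macro_voxels = c(5L, 10L), cbf = cbf, bolus_duration = bd,
    macro_bv = 0.001, macro_bolus_duration = 1.2, boundary_fraction = 0)
  summ <- summarize_regions(list(mk(c(50, 55), c(2.0, 2.2)),
                                 mk(c(60, 65), c(2.4, 2.6))))
  expect_equal(summ$n_subjects, c(2L, 2L))
  expect_equal(summ$cbf_mean, c(55, 60))
  expect_equal(summ$cbf_sd, c(sd(c(50, 60)), sd(c(55, 65))))
  expect_equal(summ$bolus_duration_mean, c(2.2, 2.4))
  expect_error(summarize_regions(list(mk(1, 1), mk(1, 1)[1, ])),
               "same region set")
})
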