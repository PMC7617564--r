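consts <- physio_constants()

test_that("zero-SD phantoms are identical across subjects; seeds reproduce", {
  pre <- tiny_preset(n_subjects = 3L, sds_zero = TRUE)
  ph <- make_phantom(pre$spec)
  expect_identical(ph[[1]]$region_truth[-1], ph[[2]]$region_truth[-1])
  expect_identical(ph[[2]]$bolus_duration, ph[[3]]$bolus_duration)
  expect_equal(ph[[1]]$region_truth$bolus_duration,
               pre$spec$regions$bd_mean)
  # seeded determinism end to end, including the simulated study
  pre2 <- tiny_preset(n_subjects = 2L, noise_sd = 0.002, seed = 77L)
  s1 <- simulate_experiment(pre2)
  s2 <- simulate_experiment(pre2)
  expect_identical(s1$subjects[[2]]$studies[[1]]$dm,
                   s2$subjects[[2]]$studies[[1]]$dm)
})

test_that("parameter draws follow the stated normal distributions", {
  # 19 subjects x 9 regions drawing from the grey-matter row distribution
  tab <- region_param_table("vc2", include_gm = TRUE)
  gm <- tab[tab$region == "grey_matter", ]
  regions <- do.call(rbind, replicate(9, gm, simplify = FALSE))
  regions$region <- paste0("r", 1:9)
  spec <- phantom_spec(grid = c(14L, 14L, 6L), regions = regions,
                       n_subjects = 19L, seed = 123L)
  draws <- unlist(lapply(make_phantom(spec),
                         function(s) s$region_truth$bolus_duration))
  expect_length(draws, 171L)
  se <- gm$bd_sd / sqrt(length(draws))
  expect_lt(abs(mean(draws) - gm$bd_mean), 3 * se)
  expect_true(all(draws > 0))
  bad <- regions; bad$bd_sd <- -1
  expect_error(phantom_spec(regions = bad), "nonnegative")
})

test_that("noise-free simulation equals the closed-form model exactly", {
  pre <- tiny_preset()
  sim <- simulate_experiment(pre)
  st <- sim$subjects[[1]]$studies[[1]]
  tr <- st$truth
  idx <- which(build_mask(st$gm_pve, st$m0), arr.ind = TRUE)
  for (v in c(1L, nrow(idx) %/% 2L, nrow(idx))) {
    i <- idx[v, 1]; j <- idx[v, 2]; k <- idx[v, 3]
    p <- tissue_params(tr$f[i, j, k], tr$bolus_duration[i, j, k],
                       tr$macro_bv[i, j, k],
                       tr$macro_bolus_duration[i, j, k], st$m0[i, j, k])
    expect_equal(st$dm[i, j, k, ],
                 delta_m_total(p, st$timing$lct_values, k - 1L,
                               st$timing, consts))
  }
})

test_that("averaging more tag/control pairs shrinks variance accordingly", {
  pre <- tiny_preset(grid = c(10L, 10L, 6L), noise_sd = 0.002)
  truth <- make_phantom(pre$spec)[[1]]
  vox_val <- function(n_pairs, seed)
    simulate_study(truth, pre$timing, consts, noise_sd = 0.002,
                   n_pairs = n_pairs, seed = seed)$dm[5, 5, 3, 1]
  v2 <- var(vapply(1:300, function(s) vox_val(2L, s), numeric(1)))
  v4 <- var(vapply(1:300, function(s) vox_val(4L, 1000L + s), numeric(1)))
  expect_gt(v2 / v4, 1.4)     # ratio 2 within Monte-Carlo slack
  expect_lt(v2 / v4, 2.8)
  # absolute scale: var of mean = (noise_sd * m0 * sqrt(2))^2 / n_pairs
  expect_equal(v4, (0.002 * 1000 * sqrt(2))^2 / 4, tolerance = 0.25)
})

test_that("condition scaling is applied before evaluation", {
  pre <- tiny_preset(preset = experiment2_preset, sds_zero = TRUE)
  truth <- make_phantom(pre$spec)[[1]]
  hyper <- pre$spec$conditions[[2]]
  st_n <- simulate_study(truth, pre$timing, consts, noise_sd = 0, seed = 1L,
                         condition = pre$spec$conditions[[1]])
  st_h <- simulate_study(truth, pre$timing, consts, noise_sd = 0, seed = 1L,
                         condition = hyper)
  expect_equal(st_h$truth$f, st_n$truth$f * 1.45)
  expect_equal(st_h$truth$bolus_duration,
               st_n$truth$bolus_duration * 1.43 / 1.65)
  expect_equal(st_h$truth$macro_bv, st_n$truth$macro_bv * 1.5)
  expect_identical(st_n$petco2_delta, 0)
})

test_that("experiment presets encode the acquisition designs", {
  p1 <- experiment1_preset()
  expect_length(p1$timing$lct_values, 11L)
  expect_equal(max(p1$timing$lct_values), 3.5)
  expect_equal(p1$spec$n_subjects, 13L)
  expect_length(p1$spec$conditions, 1L)
  p2 <- experiment2_preset()
  expect_length(p2$timing$lct_values, 8L)
  expect_equal(max(p2$timing$lct_values), 2.0)
  expect_equal(p2$spec$n_subjects, 19L)
  hyper <- p2$spec$conditions[[2]]
  expect_equal(hyper$petco2_delta_mean, 8.3)
  expect_equal(hyper$petco2_delta_sd, 2.4)
  expect_equal(hyper$cbf_scale, 1.45)
  # per-subject end-tidal CO2 increases are drawn from the stated normal
  pre <- tiny_preset(preset = experiment2_preset, n_subjects = 12L,
                     seed = 5L)
  sim <- simulate_experiment(pre)
  dpet <- vapply(sim$subjects,
                 function(s) s$studies$hypercapnia$petco2_delta, numeric(1))
  expect_gt(sd(dpet), 0)
  expect_lt(abs(mean(dpet) - 8.3), 3 * 2.4 / sqrt(12))
})

test_that("grey-matter mean series averages masked voxels of one slice", {
  pre <- tiny_preset(sds_zero = TRUE)
  sim <- simulate_experiment(pre)
  st <- sim$subjects[[1]]$studies[[1]]
  ser <- gm_mean_series(st)
  expect_s3_class(ser, "voxel_series")
  expect_length(ser$dm_values, 11L)
  expect_equal(ser$m0, 1000)
  # slice restriction keeps a single readout time: noise-free GM mean of a
  # zero-SD phantom slice still fits the kinetic model pointwise
  fr <- fit_voxel(ser, st$timing, consts)
  expect_lt(fr$sse / ser$m0^2, 1e-4)
})
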