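# Synthetic cohort generator: ROI construction, determinism, and the
# injected class effects seen through the activity maps.

test_that("spherical ROI matches exhaustive distance enumeration", {
  gs <- c(16, 16, 16)
  roi <- make_spherical_roi(c(8, 8, 8), 3, gs)
  # independent oracle: scan every voxel
  count <- 0L
  for (i in 1:16) for (j in 1:16) for (k in 1:16)
    if ((i - 8)^2 + (j - 8)^2 + (k - 8)^2 <= 9) count <- count + 1L
  expect_identical(sum(roi), count)

  expect_identical(sum(make_spherical_roi(c(4, 5, 6), 0.5, c(8, 8, 8))), 1L)
  expect_true(all(make_spherical_roi(c(4, 4, 4), 100, c(8, 8, 8))))
  expect_error(make_spherical_roi(c(0, 4, 4), 2, c(8, 8, 8)), "outside")
})

test_that("scan simulation is reproducible and label-blind under null effects", {
  cfg <- simulation_config(grid_shape = c(12, 12, 12), n_timepoints = 40,
                           tr = 3, noise_sd = 0.5, seed = 1)
  a <- simulate_scan(cfg, "s1", "AD", rng_seed = 99)
  b <- simulate_scan(cfg, "s1", "AD", rng_seed = 99)
  expect_identical(a$data, b$data)
  # with no ROI effects the label does not enter the generative process
  nc <- simulate_scan(cfg, "s1", "NC", rng_seed = 99)
  expect_identical(a$data, nc$data)
  # distinct streams differ
  expect_false(identical(a$data,
                         simulate_scan(cfg, "s1", "AD", rng_seed = 100)$data))
})

test_that("band is validated at construction", {
  expect_error(simulation_config(n_timepoints = 32, tr = 0.1),
               "fewer than 2 DFT bins")
})

test_that("cohort bookkeeping: counts, subjects, determinism", {
  cfg <- simulation_config(grid_shape = c(12, 12, 12), n_timepoints = 40,
                           tr = 3, n_subjects_per_class = 2,
                           scans_per_subject = 3, noise_sd = 0.2, seed = 5)
  co <- generate_cohort(cfg)
  expect_length(co$scans, 12)
  expect_length(unique(co$manifest$subject_id), 4)
  expect_equal(as.integer(table(co$manifest$label)), c(6L, 6L))
  for (cl in c("AD", "NC"))
    expect_equal(sum(co$manifest$label == cl),
                 cfg$n_subjects_per_class * cfg$scans_per_subject)
  co2 <- generate_cohort(cfg)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$scans[[5]]$data, co2$scans[[5]]$data)
})

test_that("amplitude_scale drives the in-ROI ALFF ratio exactly at zero noise", {
  gs <- c(14, 14, 14)
  roi <- make_spherical_roi(c(5, 7, 7), 2, gs)
  for (s in c(1.3, 1.8)) {
    cfg <- simulation_config(grid_shape = gs, n_timepoints = 60, tr = 3,
                             noise_sd = 0, seed = 3,
                             roi_effects = list(roi_effect(roi, "amplitude_scale",
                                                           s, "AD")))
    sc <- simulate_scan(cfg, "x", "AD", rng_seed = 17)
    m <- alff_map(sc)
    inr <- mean(m$data[roi & sc$brain_mask])
    outr <- mean(m$data[sc$brain_mask & !roi])
    expect_equal(inr / outr, s, tolerance = 1e-10)
  }
})

test_that("in-ROI ALFF increases monotonically with amplitude scale", {
  gs <- c(14, 14, 14)
  roi <- make_spherical_roi(c(5, 7, 7), 2, gs)
  vals <- sapply(c(1, 1.5, 2.2), function(s) {
    cfg <- simulation_config(grid_shape = gs, n_timepoints = 60, tr = 3,
                             noise_sd = 0.5, seed = 3,
                             roi_effects = list(roi_effect(roi, "amplitude_scale",
                                                           s, "AD")))
    sc <- simulate_scan(cfg, "x", "AD", rng_seed = 17)  # paired seed
    mean(alff_map(sc)$data[roi & sc$brain_mask])
  })
  expect_true(all(diff(vals) > 0))
})

test_that("full coherence with zero noise gives ReHo 1 in the ROI interior", {
  gs <- c(14, 14, 14)
  roi <- make_spherical_roi(c(7, 7, 7), 3, gs)
  cfg <- simulation_config(grid_shape = gs, n_timepoints = 60, tr = 3,
                           noise_sd = 0, seed = 2,
                           roi_effects = list(roi_effect(roi, "coherence_boost",
                                                         1, "AD")))
  sc <- simulate_scan(cfg, "x", "AD", rng_seed = 4)
  rh <- reho_map(sc)
  interior <- make_spherical_roi(c(7, 7, 7), 1.5, gs)  # clusters fully in ROI
  expect_true(all(abs(rh$data[interior] - 1) < 1e-10))
})

test_that("homotopy shift of +1 at zero noise drives mirrored-pair correlation to 1", {
  gs <- c(14, 14, 14)
  roi <- make_spherical_roi(c(4, 7, 7), 2, gs)   # off-midline, mirror in mask
  cfg <- simulation_config(grid_shape = gs, n_timepoints = 60, tr = 3,
                           noise_sd = 0, seed = 2,
                           roi_effects = list(roi_effect(roi, "homotopy_shift",
                                                         1, "AD")))
  sc <- simulate_scan(cfg, "x", "AD", rng_seed = 9)
  vm <- vmhc_map(sc)
  expect_true(all(abs(vm$data[roi] - atanh(1 - 1e-7)) < 1e-6))
})

test_that("neutral cohorts reject a class difference at about the nominal rate", {
  # two-sample t-test on per-scan mean ALFF, repeated cohorts, alpha = 0.1
  rej <- 0L; n_rep <- 25L
  for (r in seq_len(n_rep)) {
    cfg <- simulation_config(grid_shape = c(10, 10, 10), n_timepoints = 40,
                             tr = 3, n_subjects_per_class = 3, noise_sd = 0.5,
                             seed = 100 + r)
    co <- generate_cohort(cfg)
    m <- vapply(co$scans, function(s) mean(alff_map(s)$data[s$brain_mask]),
                numeric(1))
    p <- stats::t.test(m[co$manifest$label == "AD"],
                       m[co$manifest$label == "NC"])$p.value
    if (p < 0.1) rej <- rej + 1L
  }
  expect_lte(rej, qbinom(0.999, n_rep, 0.1))   # not anti-conservative
})

test_that("cohorts round-trip through NIfTI files", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(grid_shape = c(10, 10, 10), n_timepoints = 40,
                           tr = 3, n_subjects_per_class = 2, noise_sd = 0.3,
                           seed = 8)
  co <- generate_cohort(cfg, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(dir)
  expect_equal(back$manifest$scan_id, co$manifest$scan_id)
  expect_equal(back$scans[[3]]$data, co$scans[[3]]$data, tolerance = 1e-6)
  expect_equal(back$scans[[3]]$tr, 3)
  # stage isolation: maps from files equal maps computed in memory
  expect_equal(alff_map(back$scans[[1]])$data, alff_map(co$scans[[1]])$data,
               tolerance = 1e-6)
})
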