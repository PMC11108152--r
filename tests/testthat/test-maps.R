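# Activity-map formulas: spectral decomposition, ALFF/fALFF, Kendall's W,
# ReHo, VMHC, stacking and normalization.

test_that("DFT amplitudes recover pure sinusoids and satisfy Parseval", {
  tr <- 2; n <- 101; tt <- (0:(n - 1)) * tr   # odd length: no Nyquist bin
  sp0 <- dft_coefficients(rep(3.7, n), tr)
  expect_true(all(abs(c(sp0$a, sp0$b)) < 1e-12))

  k <- 7; f <- k / (n * tr); A <- 2.5
  sp <- dft_coefficients(A * cos(2 * pi * f * tt), tr)
  expect_equal(sp$a[k], A, tolerance = 1e-10)
  expect_lt(max(abs(c(sp$a[-k], sp$b[-k]))), 1e-10)

  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(n)
    sp <- dft_coefficients(x, tr)
    # Parseval: sum of per-sinusoid powers equals the series variance
    expect_equal(sum((sp$a^2 + sp$b^2) / 2), mean((x - mean(x))^2),
                 tolerance = 1e-10)
  }
  expect_error(dft_coefficients(c(1, NA, 3, 4), tr), "non-finite")
})

test_that("band-bin selection is the open interval and errors when empty", {
  tr <- 3; n <- 120
  sp <- dft_coefficients(rnorm(n), tr)
  idx <- band_bins(sp, c(0.01, 0.1))
  # oracle: exhaustive scan of the bin frequencies
  expected <- which(sapply(seq_along(sp$freqs), function(k) {
    f <- k / (n * tr); f > 0.01 && f < 0.1
  }))
  expect_identical(idx, expected)
  # full band: every bin below Nyquist
  full <- band_bins(sp, c(0, 1 / (2 * tr) + 1e-9))
  expect_identical(full, seq_along(sp$freqs))
  expect_error(band_bins(sp, c(0.2, 0.4)), "no DFT bins")
})

test_that("ALFF and fALFF match their closed forms", {
  fx <- make_fixtures(1)
  for (cs in fx$spectral_cases) {
    expect_equal(alff(cs$series, cs$tr), cs$alff, tolerance = 1e-8)
    expect_equal(falff(cs$series, cs$tr), cs$falff, tolerance = 1e-8)
  }
  expect_equal(alff(rep(0, 50), 2), 0)
  expect_equal(falff(rep(0, 50), 2), 0)   # zero-power convention
})

test_that("fALFF is a proportion on arbitrary series", {
  set.seed(11)
  for (i in 1:200) {
    x <- rnorm(sample(40:120, 1))
    v <- falff(x, tr = sample(c(1, 2, 3), 1))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("kendall_w agrees with the brute-force oracle and its exact cases", {
  expect_equal(kendall_w(matrix(rep(1:5, 4), 5, 4)), 1)
  expect_equal(kendall_w(cbind(1:3, 3:1)), 0)
  set.seed(42)
  for (i in 1:50) {
    n <- sample(2:8, 1); K <- sample(2:27, 1)
    x <- matrix(rnorm(n * K), n, K)
    expect_equal(kendall_w(x), kendall_w_bruteforce(x), tolerance = 1e-12)
  }
  # ties handled by average ranks
  xt <- cbind(c(1, 1, 2, 3), c(2, 2, 2, 4), c(1, 2, 3, 4))
  expect_equal(kendall_w(xt), kendall_w_bruteforce(xt), tolerance = 1e-12)
  expect_error(kendall_w(matrix(c(1, NaN, 2, 3), 2)), "non-finite")
  expect_error(kendall_w(matrix(1:3, 3, 1)), "K >= 2")
})

test_that("ReHo under independent noise matches the Monte-Carlo null of W", {
  mask <- array(TRUE, c(8, 8, 8))
  set.seed(2)
  sc <- toy_scan(matrix(rnorm(512 * 60), 512, 60), mask, tr = 3)
  rh <- reho_map(sc)
  interior <- array(FALSE, c(8, 8, 8)); interior[2:7, 2:7, 2:7] <- TRUE
  observed <- mean(rh$data[interior])          # all K = 27 clusters
  # Monte-Carlo oracle: W of 27 independent band-limited series
  w_null <- replicate(300, {
    x <- fmrixcam:::ideal_bandpass(matrix(rnorm(27 * 60), 27, 60), 3,
                                   c(0.01, 0.1))
    kendall_w_bruteforce(t(x))
  })
  expect_equal(observed, mean(w_null), tolerance = 0.2)
  expect_true(all(rh$data >= 0 & rh$data <= 1))
})

test_that("ReHo flags clusters smaller than two members", {
  mask <- array(FALSE, c(8, 8, 8)); mask[4, 4, 4] <- TRUE
  sc <- toy_scan(matrix(rnorm(60), 1, 60), mask, tr = 3)
  rh <- reho_map(sc)
  expect_true(rh$missing[4, 4, 4])
  expect_equal(rh$data[4, 4, 4], 0)
})

test_that("VMHC recovers constructed correlations and is mirror-symmetric", {
  gs <- c(8, 8, 8)
  mask <- array(TRUE, gs)
  set.seed(5)
  nt <- 60
  left <- matrix(rnorm(4 * 8 * 8 * nt), 4 * 64, nt)
  # right half = exact mirror copy -> r = 1 everywhere
  X <- matrix(0, 512, nt)
  idx <- arrayInd(1:512, gs)
  for (v in 1:512) {
    src <- if (idx[v, 1] <= 4) v else
      (9 - idx[v, 1]) + 8 * (idx[v, 2] - 1) + 64 * (idx[v, 3] - 1)
    li <- which(idx[, 1] <= 4)
    X[v, ] <- left[match(src, li), ]
  }
  sc <- toy_scan(X, mask, tr = 3)
  vm <- vmhc_map(sc)
  expect_true(all(abs(vm$data[!vm$missing] - atanh(1 - 1e-7)) < 1e-9))

  # anti-correlated pair: right half = -left -> z = -atanh(1 - 1e-7)
  Xn <- X
  Xn[idx[, 1] > 4, ] <- -Xn[idx[, 1] > 4, ]
  vmn <- vmhc_map(toy_scan(Xn, mask, tr = 3))
  expect_true(all(abs(vmn$data[!vmn$missing] + atanh(1 - 1e-7)) < 1e-9))

  # independent halves: z near zero; map mirror-symmetric by construction
  set.seed(9)
  sc3 <- toy_scan(matrix(rnorm(512 * 120), 512, 120), mask, tr = 3)
  vm3 <- vmhc_map(sc3)
  flipped <- vm3$data[8:1, , ]
  expect_equal(vm3$data, flipped, tolerance = 1e-12)
  expect_lt(mean(abs(vm3$data[!vm3$missing])), 3 / sqrt(60))
})

test_that("VMHC flags unpaired and degenerate voxels", {
  gs <- c(9, 8, 8)                       # odd first axis: midplane self-pairs
  mask <- array(TRUE, gs)
  set.seed(1)
  sc <- toy_scan(matrix(rnorm(prod(gs) * 40), prod(gs), 40), mask, tr = 3)
  vm <- vmhc_map(sc)
  expect_true(all(vm$missing[5, , ]))    # midplane flagged
  half <- array(TRUE, gs); half[6:9, , ] <- FALSE
  sch <- toy_scan(matrix(rnorm(sum(half) * 40), sum(half), 40), half, tr = 3)
  vmh <- vmhc_map(sch)
  expect_true(all(vmh$missing[half]))    # mirrors all out of mask
})

test_that("map stacking enforces the shared grid and round-trips", {
  fx <- tiny_experiment_data()
  sc <- fx$cohort$scans[[1]]
  maps <- lapply(c("alff", "falff", "reho", "vmhc"),
                 function(k) activity_map(sc, k))
  st <- stack_maps(maps)
  expect_identical(dim(st$data), c(dim(sc$data)[1:3], 4L))
  expect_identical(st$kinds, c("ALFF", "fALFF", "ReHo", "VMHC"))
  one <- stack_maps(maps[1])
  expect_equal(one$data[, , , 1], maps[[1]]$data)
  small <- maps[[1]]; small$mask <- !small$mask
  expect_error(stack_maps(list(maps[[2]], small)), "mask")
})

test_that("z-score normalization standardizes and is affine-invariant", {
  fx <- tiny_experiment_data()
  m <- alff_map(fx$cohort$scans[[1]])
  expect_identical(normalize_map(m, "none"), m)
  z <- normalize_map(m, "zscore_within_mask")
  expect_lt(abs(mean(z$data[z$mask])), 1e-10)
  expect_lt(abs(stats::sd(z$data[z$mask]) - 1), 1e-10)
  m2 <- m; m2$data[m2$mask] <- 3.2 * m2$data[m2$mask] + 7
  z2 <- normalize_map(m2, "zscore_within_mask")
  expect_equal(z$data, z2$data, tolerance = 1e-10)
  mc <- m; mc$data[mc$mask] <- 5
  expect_error(normalize_map(mc, "zscore_within_mask"), "zero")
})

test_that("scaling a series scales ALFF linearly, leaving fALFF and ReHo fixed", {
  set.seed(3)
  x <- rnorm(80); tr <- 2; c0 <- 4.5
  expect_equal(alff(c0 * x, tr), c0 * alff(x, tr), tolerance = 1e-10)
  expect_equal(falff(c0 * x, tr), falff(x, tr), tolerance = 1e-10)
  mask <- array(TRUE, c(6, 6, 6))
  X <- matrix(rnorm(216 * 60), 216, 60)
  r1 <- reho_map(toy_scan(X, mask, tr = 3))
  r2 <- reho_map(toy_scan(c0 * X, mask, tr = 3))
  expect_equal(r1$data, r2$data, tolerance = 1e-12)
})

test_that("in-band selection equals computing ALFF after an ideal band-pass", {
  set.seed(8)
  x <- rnorm(90); tr <- 2.5
  xf <- drop(fmrixcam:::ideal_bandpass(matrix(x, 1), tr, c(0.01, 0.1)))
  expect_equal(alff(x, tr), alff(xf, tr), tolerance = 1e-8)
})
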