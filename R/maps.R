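# Voxel-wise resting-state functional activity maps.
#
# Spectral convention: a de-meaned series x(t) of length n sampled every tr
# seconds is written as sum_k [a_k cos(2 pi f_k t) + b_k sin(2 pi f_k t)] over
# the one-sided DFT bins f_k = k/(n*tr), k = 1..floor(n/2). The amplitudes are
# per-sinusoid (2/n scaling for interior bins, 1/n at the Nyquist bin for even
# n), so a pure cosine of amplitude A on an interior bin yields a_k = A.

#' One-sided DFT amplitude decomposition of a time series
#'
#' @param series Numeric vector, length >= 4, finite values.
#' @param tr Sampling interval (repetition time) in seconds.
#' @return A `spectrum` object: list with `a` (cosine amplitudes), `b` (sine
#'   amplitudes), `freqs` (Hz) and `n_terms`. The de-meaned series is exactly
#'   `sum_k a_k cos(2 pi f_k t) + b_k sin(2 pi f_k t)` at the sample times.
#' @export
dft_coefficients <- function(series, tr) {
  if (length(series) < 4) stop("series must have length >= 4")
  if (!all(is.finite(series))) stop("series contains non-finite values")
  n <- length(series)
  X <- stats::fft(series - mean(series))
  half <- floor(n / 2)
  k <- seq_len(half)
  scale <- rep(2 / n, half)
  if (n %% 2 == 0) scale[half] <- 1 / n   # Nyquist bin is its own conjugate
  a <- Re(X[k + 1]) * scale
  b <- -Im(X[k + 1]) * scale
  structure(list(a = a, b = b, freqs = k / (n * tr), n_terms = half),
            class = "spectrum")
}

#' In-band bin indices of a spectrum
#'
#' Returns the indices k of bins with `band[1] < f_k < band[2]` (open
#' interval).
#'
#' @param spectrum A `spectrum` from [dft_coefficients()].
#' @param band Numeric length-2, Hz.
#' @return Integer vector of bin indices.
#' @export
band_bins <- function(spectrum, band = c(0.01, 0.1)) {
  stopifnot(band[1] < band[2])
  idx <- which(spectrum$freqs > band[1] & spectrum$freqs < band[2])
  if (!length(idx))
    stop("no DFT bins fall strictly inside the band; ",
         "use a longer series or a smaller tr")
  idx
}

#' Amplitude of low-frequency fluctuation (ALFF) of one series
#'
#' Mean per-sinusoid spectral amplitude `sqrt(a_k^2 + b_k^2)` over the in-band
#' bins. The divisor is the number of in-band bins (`norm = "band_bins"`,
#' default, the mean in-band amplitude) or the series length
#' (`norm = "series_length"`).
#'
#' @param series Numeric vector.
#' @param tr Repetition time in seconds.
#' @param band Frequency band in Hz (open interval).
#' @param norm Normalization convention, see above.
#' @return Nonnegative scalar.
#' @export
alff <- function(series, tr, band = c(0.01, 0.1),
                 norm = c("band_bins", "series_length")) {
  norm <- match.arg(norm)
  sp <- dft_coefficients(series, tr)
  idx <- band_bins(sp, band)
  amp <- sqrt(sp$a[idx]^2 + sp$b[idx]^2)
  sum(amp) / switch(norm, band_bins = length(idx),
                    series_length = length(series))
}

#' Fractional ALFF (fALFF) of one series
#'
#' Ratio of summed in-band spectral amplitude to summed amplitude over all
#' frequency bins; always in \[0, 1\]. Returns 0 for a zero-power series.
#'
#' @inheritParams alff
#' @return Scalar in \[0, 1\].
#' @export
falff <- function(series, tr, band = c(0.01, 0.1)) {
  sp <- dft_coefficients(series, tr)
  idx <- band_bins(sp, band)
  amp <- sqrt(sp$a^2 + sp$b^2)
  tot <- sum(amp)
  if (tot <= 0) return(0)
  sum(amp[idx]) / tot
}

#' Kendall's coefficient of concordance (KCC / W)
#'
#' Concordance of K series over n time points: each column is ranked 1..n
#' (average ranks on ties, no tie-correction term), the rank sums R_i are
#' formed across columns, and
#' `W = (sum R_i^2 - n * Rbar^2) / (K^2 (n^3 - n) / 12)` with
#' `Rbar = (n + 1) K / 2`.
#'
#' @param cluster_series Numeric matrix, n time points x K series, n >= 2,
#'   K >= 2.
#' @return Scalar in \[0, 1\].
#' @export
kendall_w <- function(cluster_series) {
  x <- as.matrix(cluster_series)
  n <- nrow(x); K <- ncol(x)
  if (n < 2 || K < 2) stop("kendall_w needs n >= 2 time points and K >= 2 series")
  if (!all(is.finite(x))) stop("kendall_w: non-finite input")
  R <- rowSums(apply(x, 2, rank))
  rbar <- (n + 1) * K / 2
  (sum(R^2) - n * rbar^2) / (K^2 * (n^3 - n) / 12)
}

# Ideal band-pass: zero all DFT bins outside the open band (including DC and,
# for the two-sided transform, the mirrored bins). X is V x T.
ideal_bandpass <- function(X, tr, band = c(0.01, 0.1)) {
  n <- ncol(X)
  k <- band_bin_indices(n, tr, band)
  if (!length(k)) stop("band contains no DFT bins at this tr / length")
  keep <- logical(n)
  keep[k + 1] <- TRUE
  keep[n + 1 - k] <- TRUE           # conjugate bins
  F <- stats::mvfft(t(X))           # T x V
  F[!keep, ] <- 0
  t(Re(stats::mvfft(F, inverse = TRUE))) / n
}

# In-mask voxel series as a Vm x T matrix.
mask_series <- function(scan) {
  gs <- dim(scan$data)[1:3]
  nt <- dim(scan$data)[4]
  flat <- matrix(scan$data, prod(gs), nt)
  flat[which(scan$brain_mask), , drop = FALSE]
}

new_activity_map <- function(data, kind, mask, missing, scan,
                             params = list()) {
  structure(list(data = data, kind = kind, mask = mask, missing = missing,
                 provenance = c(list(scan_id = scan$scan_id), params)),
            class = "activity_map")
}

#' @export
print.activity_map <- function(x, ...) {
  v <- x$data[x$mask & !x$missing]
  cat(sprintf("<activity_map %s> %s grid, %d in-mask voxels (%d missing), range [%.4g, %.4g]\n",
              x$kind, paste(dim(x$data), collapse = "x"), sum(x$mask),
              sum(x$missing), min(v), max(v)))
  invisible(x)
}

#' ALFF map of a scan
#'
#' @param scan A `scan4d`.
#' @param band Frequency band in Hz.
#' @param norm ALFF divisor convention, see [alff()].
#' @return An `activity_map` of kind `"ALFF"`; zero outside the mask.
#' @export
alff_map <- function(scan, band = c(0.01, 0.1),
                     norm = c("band_bins", "series_length")) {
  norm <- match.arg(norm)
  spec <- mask_spectra(scan)
  idx <- which(spec$freqs > band[1] & spec$freqs < band[2])
  if (!length(idx)) stop("no DFT bins fall strictly inside the band")
  vals <- rowSums(spec$amp[, idx, drop = FALSE]) /
    switch(norm, band_bins = length(idx),
           series_length = dim(scan$data)[4])
  fill_map(vals, scan, "ALFF", params = list(band = band, norm = norm))
}

#' fALFF map of a scan
#'
#' @inheritParams alff_map
#' @return An `activity_map` of kind `"fALFF"`; voxels with zero total power
#'   are set to 0 and flagged missing.
#' @export
falff_map <- function(scan, band = c(0.01, 0.1)) {
  spec <- mask_spectra(scan)
  idx <- which(spec$freqs > band[1] & spec$freqs < band[2])
  if (!length(idx)) stop("no DFT bins fall strictly inside the band")
  tot <- rowSums(spec$amp)
  num <- rowSums(spec$amp[, idx, drop = FALSE])
  vals <- ifelse(tot > 0, num / pmax(tot, .Machine$double.xmin), 0)
  fill_map(vals, scan, "fALFF", missing_in = tot <= 0,
           params = list(band = band))
}

# Per-voxel one-sided amplitude spectra (Vm x half) for all in-mask voxels.
mask_spectra <- function(scan) {
  X <- mask_series(scan)
  n <- ncol(X)
  half <- floor(n / 2)
  F <- stats::mvfft(t(X - rowMeans(X)))   # T x Vm
  scale <- rep(2 / n, half)
  if (n %% 2 == 0) scale[half] <- 1 / n
  amp <- t(Mod(F[2:(half + 1), , drop = FALSE])) *
    matrix(scale, nrow = ncol(F), ncol = half, byrow = TRUE)
  list(amp = amp, freqs = seq_len(half) / (n * scan$tr))
}

fill_map <- function(vals, scan, kind, missing_in = NULL, params = list()) {
  gs <- dim(scan$data)[1:3]
  data <- array(0, gs); miss <- array(FALSE, gs)
  vin <- which(scan$brain_mask)
  if (!is.null(missing_in)) {
    vals[missing_in] <- 0
    miss[vin] <- missing_in
  }
  data[vin] <- vals
  new_activity_map(data, kind, scan$brain_mask, miss, scan, params)
}

# 3D neighborhood offsets for cluster sizes 7 (faces), 19 (faces+edges),
# 27 (full cube).
neighborhood_offsets <- function(K = 27) {
  stopifnot(K %in% c(7, 19, 27))
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  lim <- switch(as.character(K), "7" = 1, "19" = 2, "27" = 3)
  g[ord <= lim, , drop = FALSE]
}

#' Regional homogeneity (ReHo) map
#'
#' Per in-mask voxel, Kendall's coefficient of concordance over the voxel and
#' its in-mask neighbors (cluster size `neighborhood` = 7, 19 or 27), applied
#' to ideally band-pass-filtered series. Voxels whose available in-mask
#' cluster has fewer than 2 members are flagged missing.
#'
#' @param scan A `scan4d`.
#' @param band Frequency band in Hz.
#' @param neighborhood Cluster size: 7, 19 or 27 (default).
#' @return An `activity_map` of kind `"ReHo"` with values in \[0, 1\].
#' @export
reho_map <- function(scan, band = c(0.01, 0.1), neighborhood = 27) {
  gs <- dim(scan$data)[1:3]
  if (!any(scan$brain_mask)) stop("empty brain mask")
  X <- ideal_bandpass(mask_series(scan), scan$tr, band)
  n <- ncol(X)
  RNK <- t(apply(X, 1, rank))            # Vm x T, average ranks on ties

  vin <- which(scan$brain_mask)
  pos <- integer(prod(gs)); pos[vin] <- seq_along(vin)
  offs <- neighborhood_offsets(neighborhood)
  ac <- arrayInd(vin, gs)
  ii <- list(); jj <- list()
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(ac, 2, offs[o, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= gs[1] & nb[, 2] >= 1 & nb[, 2] <= gs[2] &
      nb[, 3] >= 1 & nb[, 3] <= gs[3]
    lin <- nb[ok, 1] + gs[1] * (nb[ok, 2] - 1) + gs[1] * gs[2] * (nb[ok, 3] - 1)
    inm <- pos[lin] > 0
    ii[[o]] <- which(ok)[inm]
    jj[[o]] <- pos[lin][inm]
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                            dims = c(length(vin), length(vin)))
  K <- Matrix::rowSums(A)
  SR <- as.matrix(A %*% RNK)             # cluster rank sums per timepoint
  numer <- rowSums(SR^2) - n * K^2 * (n + 1)^2 / 4
  denom <- K^2 * (n^3 - n) / 12
  w <- ifelse(K >= 2, numer / denom, 0)
  fill_map(w, scan, "ReHo", missing_in = K < 2,
           params = list(band = band, neighborhood = neighborhood))
}

#' Voxel-mirrored homotopic connectivity (VMHC) map
#'
#' For each in-mask voxel, the Pearson correlation between its band-filtered
#' series and that of its mirror voxel (reflection of the first spatial axis
#' about its midplane), Fisher z-transformed with r clipped to
#' +/- (1 - 1e-7). Pairs whose mirror is outside the mask, pairs containing a
#' zero-variance series, and midplane self-pairs (odd first axis) are flagged
#' missing.
#'
#' @param scan A `scan4d`.
#' @param band Frequency band in Hz.
#' @return An `activity_map` of kind `"VMHC"` (Fisher z values).
#' @export
vmhc_map <- function(scan, band = c(0.01, 0.1)) {
  gs <- dim(scan$data)[1:3]
  if (!any(scan$brain_mask)) stop("empty brain mask")
  X <- ideal_bandpass(mask_series(scan), scan$tr, band)
  vin <- which(scan$brain_mask)
  pos <- integer(prod(gs)); pos[vin] <- seq_along(vin)
  ac <- arrayInd(vin, gs)
  mx <- mirror_index(ac[, 1], gs[1])
  mlin <- mx + gs[1] * (ac[, 2] - 1) + gs[1] * gs[2] * (ac[, 3] - 1)
  mpos <- pos[mlin]
  selfpair <- mx == ac[, 1]
  valid <- mpos > 0 & !selfpair

  Xc <- X - rowMeans(X)
  ss <- rowSums(Xc^2)
  r <- rep(NA_real_, length(vin))
  v <- which(valid)
  num <- rowSums(Xc[v, , drop = FALSE] * Xc[mpos[v], , drop = FALSE])
  den <- sqrt(ss[v] * ss[mpos[v]])
  good <- den > 0
  r[v[good]] <- num[good] / den[good]
  miss <- !valid; miss[v[!good]] <- TRUE
  rc <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- ifelse(miss, 0, atanh(rc))
  fill_map(z, scan, "VMHC", missing_in = miss, params = list(band = band))
}

#' Compute one activity map by kind
#'
#' @param scan A `scan4d`.
#' @param kind One of `"alff"`, `"falff"`, `"reho"`, `"vmhc"` (case
#'   insensitive).
#' @param band Frequency band in Hz.
#' @param ... Passed to the kind-specific map function.
#' @return An `activity_map`.
#' @export
activity_map <- function(scan, kind, band = c(0.01, 0.1), ...) {
  switch(tolower(kind),
         alff = alff_map(scan, band, ...),
         falff = falff_map(scan, band, ...),
         reho = reho_map(scan, band, ...),
         vmhc = vmhc_map(scan, band, ...),
         stop("unknown map kind: ", kind))
}

#' Stack activity maps into a multi-channel volume
#'
#' @param maps List of `activity_map`s sharing grid and mask. The canonical
#'   channel order for combined inputs is ALFF, fALFF, ReHo, VMHC.
#' @return A `map_stack`: list with `data` (4D array x,y,z,channel), `kinds`,
#'   `mask`.
#' @export
stack_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  for (m in maps) stopifnot(inherits(m, "activity_map"))
  d1 <- dim(maps[[1]]$data)
  for (m in maps) {
    if (!identical(dim(m$data), d1)) stop("maps have different grid shapes")
    if (!identical(which(m$mask), which(maps[[1]]$mask)))
      stop("maps have different masks")
  }
  data <- array(0, c(d1, length(maps)))
  for (j in seq_along(maps)) data[, , , j] <- maps[[j]]$data
  structure(list(data = data, kinds = vapply(maps, `[[`, "", "kind"),
                 mask = maps[[1]]$mask,
                 scan_id = maps[[1]]$provenance$scan_id),
            class = "map_stack")
}

#' Normalize an activity map
#'
#' @param map An `activity_map`.
#' @param mode `"none"` (identity) or `"zscore_within_mask"` (center and scale
#'   using the in-mask mean and sd; outside-mask voxels stay 0).
#' @return An `activity_map`.
#' @export
normalize_map <- function(map, mode = c("none", "zscore_within_mask")) {
  mode <- match.arg(mode)
  if (mode == "none") return(map)
  v <- map$data[map$mask]
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("zero in-mask standard deviation")
  map$data[map$mask] <- (v - mean(v)) / s
  map$data[!map$mask] <- 0
  map
}

#' Write an activity map (and its missing-value flag) as NIfTI
#'
#' @param map An `activity_map`.
#' @param path Output `.nii.gz` path; the companion missing-mask is written
#'   alongside with suffix `_missing`.
#' @export
write_map <- function(map, path) {
  RNifti::writeNifti(RNifti::asNifti(map$data), path)
  mpath <- sub("(\\.nii(\\.gz)?)$", "_missing\\1", path)
  RNifti::writeNifti(RNifti::asNifti(map$missing + 0), mpath)
  invisible(path)
}
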