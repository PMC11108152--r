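# Synthetic resting-state fMRI cohort generator.
#
# Scans are built as baseline + band-limited BOLD-like signal + white noise on
# a brain-shaped mask. The band-limited component is a sum of sinusoids placed
# on exact DFT bins strictly inside the low-frequency band, which makes ALFF
# and fALFF closed-form checkable. Class effects are injected into named ROIs:
# amplitude scaling (ALFF contrast), a shared latent series mixed into the ROI
# (ReHo contrast), and correlated mirrored-pair construction (VMHC contrast).

#' Spherical region-of-interest mask
#'
#' Builds a boolean 3D mask of all voxels whose Euclidean distance (in voxel
#' units) from `center` is at most `radius`.
#'
#' @param center Integer triple, voxel coordinates (1-based) of the sphere
#'   center; must lie inside the grid.
#' @param radius Sphere radius in voxels (>= 0.5; radius 0.5 gives a single
#'   voxel).
#' @param grid_shape Integer triple of grid dimensions.
#' @return A logical array of dimension `grid_shape`.
#' @export
make_spherical_roi <- function(center, radius, grid_shape) {
  stopifnot(length(center) == 3, length(grid_shape) == 3, radius >= 0.5)
  if (any(center < 1) || any(center > grid_shape))
    stop("ROI center lies outside the grid")
  d2 <- outer(
    outer((seq_len(grid_shape[1]) - center[1])^2,
          (seq_len(grid_shape[2]) - center[2])^2, `+`),
    (seq_len(grid_shape[3]) - center[3])^2, `+`)
  array(d2 <= radius^2, dim = grid_shape)
}

#' Ellipsoidal brain mask inscribed in the grid
#'
#' Default brain-shaped mask: the ellipsoid inscribed in the grid, shrunk by
#' `margin` voxels on each semi-axis. It is mirror-symmetric about every axis
#' midplane, which matters for homotopic (VMHC) analyses.
#'
#' @param grid_shape Integer triple of grid dimensions.
#' @param margin Shrink applied to each semi-axis, in voxels.
#' @return Logical array of dimension `grid_shape`.
#' @export
default_brain_mask <- function(grid_shape, margin = 1) {
  ctr <- (grid_shape + 1) / 2
  semi <- pmax(grid_shape / 2 - margin, 1)
  u <- outer(
    outer(((seq_len(grid_shape[1]) - ctr[1]) / semi[1])^2,
          ((seq_len(grid_shape[2]) - ctr[2]) / semi[2])^2, `+`),
    ((seq_len(grid_shape[3]) - ctr[3]) / semi[3])^2, `+`)
  array(u <= 1, dim = grid_shape)
}

#' Describe one ROI-localized class effect
#'
#' @param roi_mask Logical 3D array selecting the affected voxels (will be
#'   intersected with the brain mask).
#' @param kind One of `"amplitude_scale"` (multiply the band-limited component
#'   by `magnitude`), `"coherence_boost"` (mix a shared ROI-wide latent series
#'   with weight `magnitude` in \[0,1\]; the variance-preserving mixture
#'   `sqrt(1-m^2)*own + m*shared` is used so band power is unchanged), or
#'   `"homotopy_shift"` (set the band-component correlation of mirrored voxel
#'   pairs to `magnitude` in \[-1,1\]; the baseline pairing is independent,
#'   so `magnitude` is also the correlation delta).
#' @param magnitude Effect size, range depending on `kind` (see above).
#' @param applies_to_class Label (`"AD"` or `"NC"`) whose scans receive the
#'   effect.
#' @return An object of class `roi_effect`.
#' @export
roi_effect <- function(roi_mask, kind = c("amplitude_scale", "coherence_boost",
                                          "homotopy_shift"),
                       magnitude, applies_to_class = "AD") {
  kind <- match.arg(kind)
  if (kind == "amplitude_scale" && magnitude < 0)
    stop("amplitude_scale magnitude must be >= 0")
  if (kind == "coherence_boost" && (magnitude < 0 || magnitude > 1))
    stop("coherence_boost magnitude must lie in [0, 1]")
  if (kind == "homotopy_shift" && abs(magnitude) > 1)
    stop("homotopy_shift magnitude must lie in [-1, 1]")
  structure(list(roi_mask = roi_mask, kind = kind, magnitude = magnitude,
                 applies_to_class = applies_to_class),
            class = "roi_effect")
}

#' Simulation configuration
#'
#' @param grid_shape Integer triple of voxel grid dimensions (each >= 8).
#' @param n_timepoints Number of time points (>= 32).
#' @param tr Repetition time in seconds; together with `n_timepoints` it must
#'   place at least 2 DFT bins strictly inside `band`.
#' @param n_subjects_per_class Subjects per class.
#' @param scans_per_subject Scans per subject (>= 1).
#' @param noise_sd Standard deviation of additive white noise.
#' @param smoothing_fwhm Spatial Gaussian smoothing FWHM in voxels (0 = off).
#' @param seed Integer master seed; all per-subject random streams derive
#'   from it.
#' @param roi_effects List of [roi_effect()] objects.
#' @param band Low-frequency band in Hz (open interval).
#' @param n_sinusoids Number of DFT-bin sinusoids per voxel in the band-limited
#'   component.
#' @param signal_amp Amplitude of each sinusoid.
#' @param baseline Constant baseline intensity inside the mask.
#' @param brain_mask Optional logical 3D mask; defaults to the inscribed
#'   ellipsoid.
#' @param voxel_size Isotropic voxel size in mm recorded in NIfTI headers.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(grid_shape = c(24, 28, 24), n_timepoints = 120,
                              tr = 3.0, n_subjects_per_class = 10,
                              scans_per_subject = 1, noise_sd = 1.0,
                              smoothing_fwhm = 0, seed = 1,
                              roi_effects = list(), band = c(0.01, 0.1),
                              n_sinusoids = 6, signal_amp = 1.0,
                              baseline = 100, brain_mask = NULL,
                              voxel_size = 3) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8),
            n_timepoints >= 32, tr > 0, n_subjects_per_class >= 1,
            scans_per_subject >= 1, noise_sd >= 0, smoothing_fwhm >= 0,
            n_sinusoids >= 1, signal_amp > 0)
  bins <- band_bin_indices(n_timepoints, tr, band)
  if (length(bins) < 2)
    stop("fewer than 2 DFT bins fall strictly inside the band; ",
         "use a longer series or smaller tr")
  if (is.null(brain_mask)) brain_mask <- default_brain_mask(grid_shape)
  stopifnot(identical(dim(brain_mask), as.integer(grid_shape)) ||
              identical(dim(brain_mask), grid_shape))
  for (ef in roi_effects) stopifnot(inherits(ef, "roi_effect"))
  structure(list(grid_shape = as.integer(grid_shape),
                 n_timepoints = as.integer(n_timepoints), tr = tr,
                 n_subjects_per_class = as.integer(n_subjects_per_class),
                 scans_per_subject = as.integer(scans_per_subject),
                 noise_sd = noise_sd, smoothing_fwhm = smoothing_fwhm,
                 seed = as.integer(seed), roi_effects = roi_effects,
                 band = band, n_sinusoids = as.integer(n_sinusoids),
                 signal_amp = signal_amp, baseline = baseline,
                 brain_mask = brain_mask, voxel_size = voxel_size),
            class = "simulation_config")
}

# DFT-bin frequencies strictly inside the open band, for a series of length n
# sampled every tr seconds. Bin k (k = 1..floor(n/2)) sits at k/(n*tr) Hz.
band_bin_indices <- function(n, tr, band = c(0.01, 0.1)) {
  k <- seq_len(floor(n / 2))
  f <- k / (n * tr)
  k[f > band[1] & f < band[2]]
}

# Evenly spaced subset of the in-band bins used as signal carriers.
signal_bins <- function(config) {
  bins <- band_bin_indices(config$n_timepoints, config$tr, config$band)
  m <- min(config$n_sinusoids, length(bins))
  bins[unique(round(seq(1, length(bins), length.out = m)))]
}

# Band-limited series matrix (n_series x T): each row is a sum of sinusoids on
# the carrier bins with uniform random phases.  Power per row is
# sum(A^2)/2 per carrier.
band_limited_series <- function(n_series, config) {
  tt <- (seq_len(config$n_timepoints) - 1) * config$tr
  bins <- signal_bins(config)
  omega <- 2 * pi * bins / (config$n_timepoints * config$tr)
  phases <- matrix(stats::runif(n_series * length(bins), 0, 2 * pi),
                   n_series, length(bins))
  cw <- cos(outer(omega, tt))   # M x T
  sw <- sin(outer(omega, tt))
  config$signal_amp * (cos(phases) %*% cw - sin(phases) %*% sw)
}

# Mirror a 1-based index along an axis of length n (reflection about the
# midplane; on odd n the middle index maps to itself).
mirror_index <- function(i, n) n + 1L - i

#' Simulate one 4D scan
#'
#' Generates a single subject-scan: inside the brain mask each voxel's series
#' is baseline + band-limited signal + white noise; ROI effects whose
#' `applies_to_class` matches `label` are applied (in list order) to the
#' band-limited component before noise; optional Gaussian spatial smoothing is
#' applied last. Fully reproducible from `rng_seed`.
#'
#' @param config A [simulation_config()].
#' @param subject_id,scan_id,label Scan metadata; `label` is `"AD"` or `"NC"`.
#' @param rng_seed Integer seed for this scan's random stream.
#' @return An object of class `scan4d` with fields `data` (4D array), `tr`,
#'   `brain_mask`, `subject_id`, `scan_id`, `label`.
#' @export
simulate_scan <- function(config, subject_id, label, scan_id = subject_id,
                          rng_seed = config$seed) {
  stopifnot(label %in% c("AD", "NC"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rng_seed)

  gs <- config$grid_shape
  mask <- config$brain_mask
  vin <- which(mask)                     # linear indices of in-mask voxels
  nt <- config$n_timepoints
  B <- band_limited_series(length(vin), config)   # Vm x T

  pos <- integer(prod(gs)); pos[vin] <- seq_along(vin)
  for (ef in config$roi_effects) {
    if (ef$applies_to_class != label) next
    roi <- which(ef$roi_mask & mask)
    ridx <- pos[roi]
    if (!length(ridx)) next
    if (ef$kind == "amplitude_scale") {
      B[ridx, ] <- B[ridx, ] * ef$magnitude
    } else if (ef$kind == "coherence_boost") {
      shared <- band_limited_series(1L, config)
      w <- ef$magnitude
      B[ridx, ] <- sqrt(1 - w^2) * B[ridx, ] +
        w * matrix(shared, length(ridx), nt, byrow = TRUE)
    } else { # homotopy_shift
      rho <- ef$magnitude
      ac <- arrayInd(roi, gs)
      mir <- cbind(mirror_index(ac[, 1], gs[1]), ac[, 2], ac[, 3])
      mlin <- mir[, 1] + gs[1] * (mir[, 2] - 1) + gs[1] * gs[2] * (mir[, 3] - 1)
      keep <- ac[, 1] < mirror_index(ac[, 1], gs[1]) & mask[mlin]
      vsrc <- pos[roi[keep]]; vdst <- pos[mlin[keep]]
      B[vdst, ] <- rho * B[vsrc, ] + sqrt(1 - rho^2) * B[vdst, ]
    }
  }

  dat <- array(0, dim = c(gs, nt))
  flat <- matrix(0, prod(gs), nt)
  noise <- if (config$noise_sd > 0)
    matrix(stats::rnorm(length(vin) * nt, 0, config$noise_sd),
           length(vin), nt) else 0
  flat[vin, ] <- config$baseline + B + noise
  dat[] <- flat
  if (config$smoothing_fwhm > 0)
    dat <- smooth_4d(dat, config$smoothing_fwhm)

  structure(list(data = dat, tr = config$tr, brain_mask = mask,
                 subject_id = subject_id, scan_id = scan_id, label = label),
            class = "scan4d")
}

# Save/restore .Random.seed so simulation does not disturb the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Separable Gaussian smoothing of each 3D volume of a 4D array.
# sigma = fwhm / (2*sqrt(2*log(2))) in voxels.
smooth_4d <- function(dat, fwhm) {
  sigma <- fwhm / 2.3548200450309493
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  smooth_axis <- function(a, axis) {
    n <- dim(a)[axis]
    out <- array(0, dim(a))
    for (j in seq_along(kern)) {
      off <- j - half - 1L
      src <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate edges
      idx <- switch(axis, `1` = list(src, TRUE, TRUE),
                    `2` = list(TRUE, src, TRUE), `3` = list(TRUE, TRUE, src))
      out <- out + kern[j] * a[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
    }
    out
  }
  for (ax in 1:3) dat <- smooth_axis(dat, ax)
  dat
}

#' Generate a labeled cohort of synthetic scans
#'
#' Produces `n_subjects_per_class * scans_per_subject` scans per class with
#' per-subject random streams derived deterministically from `config$seed`.
#' Optionally writes one NIfTI file per scan plus a CSV manifest.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory; when given, scans are written as
#'   `.nii.gz` and a `manifest.csv` (subject_id, scan_id, label, path) is
#'   created.
#' @return An object of class `cohort`: list with `scans` (list of `scan4d`)
#'   and `manifest` (data.frame).
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n_subj <- config$n_subjects_per_class
  labels <- rep(c("AD", "NC"), each = n_subj)
  subj_ids <- sprintf("%s%02d", labels, rep(seq_len(n_subj), 2))
  subj_seeds <- sample.int(.Machine$integer.max - 1L,
                           2L * n_subj * config$scans_per_subject)

  scans <- list(); man <- list(); k <- 0L
  for (i in seq_along(subj_ids)) {
    for (s in seq_len(config$scans_per_subject)) {
      k <- k + 1L
      sid <- sprintf("%s_s%d", subj_ids[i], s)
      scans[[k]] <- simulate_scan(config, subj_ids[i], labels[i],
                                  scan_id = sid, rng_seed = subj_seeds[k])
      man[[k]] <- data.frame(subject_id = subj_ids[i], scan_id = sid,
                             label = labels[i], path = NA_character_,
                             stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, man)
  cohort <- structure(list(scans = scans, manifest = manifest),
                      class = "cohort")
  if (!is.null(out_dir)) cohort <- write_cohort(cohort, out_dir,
                                                voxel_size = config$voxel_size)
  cohort
}

#' Write a cohort to NIfTI files plus a CSV manifest
#'
#' @param cohort A `cohort` object.
#' @param out_dir Output directory (created if missing).
#' @param voxel_size Isotropic voxel size in mm for the NIfTI header.
#' @return The cohort with `manifest$path` filled in.
#' @export
write_cohort <- function(cohort, out_dir, voxel_size = 3) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$scans)) {
    sc <- cohort$scans[[i]]
    path <- file.path(out_dir, paste0(sc$scan_id, ".nii.gz"))
    img <- RNifti::asNifti(sc$data)
    RNifti::pixdim(img) <- c(rep(voxel_size, 3), sc$tr)
    RNifti::writeNifti(img, path)
    cohort$manifest$path[cohort$manifest$scan_id == sc$scan_id] <- path
  }
  mask_path <- file.path(out_dir, "brain_mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(cohort$scans[[1]]$brain_mask + 0), mask_path)
  utils::write.csv(cohort$manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  cohort
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv`, per-scan NIfTI files and
#'   `brain_mask.nii.gz`.
#' @param tr Repetition time in seconds (read from the NIfTI header when
#'   available).
#' @return A `cohort` object.
#' @export
read_cohort <- function(dir, tr = NULL) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  mask <- RNifti::readNifti(file.path(dir, "brain_mask.nii.gz")) > 0.5
  scans <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- RNifti::readNifti(manifest$path[i])
    tr_i <- if (!is.null(tr)) tr else RNifti::pixdim(img)[4]
    structure(list(data = array(as.vector(img), dim = dim(img)), tr = tr_i,
                   brain_mask = array(mask, dim = dim(img)[1:3]),
                   subject_id = manifest$subject_id[i],
                   scan_id = manifest$scan_id[i],
                   label = manifest$label[i]),
              class = "scan4d")
  })
  structure(list(scans = scans, manifest = manifest), class = "cohort")
}
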