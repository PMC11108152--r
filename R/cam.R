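# 3D class activation mapping.
#
# Grad-CAM: neuron importance weights alpha_k^c = (1/Z) sum_ijl dy^c/dA^k_ijl
# (global average pooling of the class-score gradient over the capture-layer
# feature maps), coarse heatmap L^c = ReLU(sum_k alpha_k^c A^k). Classic CAM
# (GAP-head models only) uses the head's linear weights w_k^c in place of
# alpha; on a GAP-head model the two are proportional (alpha = w / Z), so the
# heatmaps coincide after unit-max normalization.

new_heatmap <- function(data, class_index, resolution = c("coarse", "full"),
                        normalization = "raw", scan_id = NULL) {
  structure(list(data = data, class_index = class_index,
                 resolution = match.arg(resolution),
                 normalization = normalization, scan_id = scan_id),
            class = "heatmap")
}

#' Grad-CAM coarse heatmap
#'
#' @param model A trained `network`.
#' @param stack Input `map_stack` or array.
#' @param class_index Class whose score is explained (1 = AD, 2 = NC);
#'   `NULL` uses the predicted class.
#' @return A `heatmap` at capture-layer resolution (all values >= 0).
#' @export
gradcam <- function(model, stack, class_index = NULL) {
  if (is.null(class_index)) {
    p <- predict_stack(model, stack)
    class_index <- which.max(p)
  }
  cap <- capture(model, stack, class_index)
  C <- dim(cap$activations)[4]
  A <- matrix(cap$activations, ncol = C)
  G <- matrix(cap$gradients, ncol = C)
  alpha <- colMeans(G)                       # (1/Z) sum of gradients
  L <- pmax(A %*% alpha, 0)
  new_heatmap(array(L, dim(cap$activations)[1:3]), class_index,
              scan_id = if (inherits(stack, "map_stack")) stack$scan_id)
}

#' Classic CAM heatmap (GAP-head models)
#'
#' Uses the head's linear weights w_k^c directly:
#' `L^c = ReLU(sum_k w_k^c A^k)`.
#'
#' @inheritParams gradcam
#' @return A `heatmap` at capture-layer resolution.
#' @export
cam_gap <- function(model, stack, class_index = NULL) {
  if (model$spec$head != "gap") stop("CAM requires a GAP head")
  if (is.null(class_index)) {
    p <- predict_stack(model, stack)
    class_index <- which.max(p)
  }
  cap <- capture(model, stack, class_index)
  C <- dim(cap$activations)[4]
  A <- matrix(cap$activations, ncol = C)
  w <- model$layers[[length(model$layers)]]$W[, class_index]
  L <- pmax(A %*% w, 0)
  new_heatmap(array(L, dim(cap$activations)[1:3]), class_index,
              scan_id = if (inherits(stack, "map_stack")) stack$scan_id)
}

#' Trilinear upsampling of a coarse heatmap
#'
#' Align-corners trilinear interpolation: output corner voxels coincide with
#' input corner voxels; values stay nonnegative.
#'
#' @param coarse A coarse `heatmap` (or 3D array).
#' @param target_shape Integer triple, each >= the coarse dimension.
#' @return A `heatmap` at `target_shape` resolution.
#' @export
upsample <- function(coarse, target_shape) {
  a <- if (inherits(coarse, "heatmap")) coarse$data else coarse
  src <- dim(a)
  if (any(target_shape < src))
    stop("target shape must be >= coarse shape in every dimension")
  # per-axis source coordinate (1-based) and its floor/weight
  ax <- lapply(1:3, function(d) {
    n_out <- target_shape[d]; n_in <- src[d]
    s <- if (n_out == 1 || n_in == 1) rep(1, n_out)
    else 1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
    lo <- pmin(floor(s), n_in - 1); lo <- pmax(lo, 1)
    list(lo = as.integer(lo), w = s - lo)
  })
  out <- array(0, target_shape)
  W1 <- ax[[1]]$w; W2 <- ax[[2]]$w; W3 <- ax[[3]]$w
  for (o1 in 0:1) for (o2 in 0:1) for (o3 in 0:1) {
    i1 <- pmin(ax[[1]]$lo + o1, src[1])
    i2 <- pmin(ax[[2]]$lo + o2, src[2])
    i3 <- pmin(ax[[3]]$lo + o3, src[3])
    w <- outer(outer(if (o1) W1 else 1 - W1,
                     if (o2) W2 else 1 - W2), if (o3) W3 else 1 - W3)
    out <- out + w * a[i1, i2, i3, drop = FALSE]
  }
  out[out < 0] <- 0      # clamp tiny negative round-off
  if (inherits(coarse, "heatmap"))
    new_heatmap(out, coarse$class_index, "full", coarse$normalization,
                coarse$scan_id)
  else out
}

#' Scale a heatmap so its maximum is 1
#'
#' @param hm A `heatmap`. Identically-zero heatmaps are returned unchanged.
#' @return A `heatmap` with `normalization = "unit_max"`.
#' @export
unit_max <- function(hm) {
  m <- max(hm$data)
  if (m > 0) hm$data <- hm$data / m
  hm$normalization <- "unit_max"
  hm
}

#' Per-voxel average of heatmaps
#'
#' @param heatmaps Nonempty list of `heatmap`s with identical shape.
#' @param normalization `"unit_max"` (normalize each heatmap to max 1 before
#'   averaging, so no single high-magnitude sample dominates) or `"raw"`.
#' @return A `heatmap`.
#' @export
average_heatmaps <- function(heatmaps, normalization = c("unit_max", "raw")) {
  normalization <- match.arg(normalization)
  if (!length(heatmaps)) stop("no heatmaps to average")
  d1 <- dim(heatmaps[[1]]$data)
  acc <- array(0, d1)
  for (h in heatmaps) {
    stopifnot(identical(dim(h$data), d1))
    if (normalization == "unit_max") h <- unit_max(h)
    acc <- acc + h$data
  }
  new_heatmap(acc / length(heatmaps), heatmaps[[1]]$class_index,
              if (heatmaps[[1]]$resolution == "full") "full" else "coarse",
              normalization)
}

#' Heatmap concentration inside a region of interest
#'
#' Quantifies how much of a heatmap's mass falls in an ROI relative to the
#' ROI's share of the brain volume. A concentration of 1 means the heatmap is
#' (on average) uniform over the brain; values > 1 mean the ROI is
#' highlighted.
#'
#' @param heatmap A `heatmap` (full or coarse resolution) or 3D array.
#' @param roi_mask Logical array, subset of `brain_mask`, same shape as the
#'   heatmap.
#' @param brain_mask Logical array, same shape.
#' @return List: `mass_fraction`, `volume_fraction`, `concentration`,
#'   `argmax_in_roi`.
#' @export
roi_concentration <- function(heatmap, roi_mask, brain_mask) {
  h <- if (inherits(heatmap, "heatmap")) heatmap$data else heatmap
  stopifnot(identical(dim(h), dim(roi_mask)),
            identical(dim(h), dim(brain_mask)))
  if (any(roi_mask & !brain_mask)) stop("roi_mask must lie inside brain_mask")
  tot <- sum(h[brain_mask])
  if (tot <= 0) stop("heatmap has zero total mass inside the brain mask")
  mass <- sum(h[roi_mask]) / tot
  vol <- sum(roi_mask) / sum(brain_mask)
  hb <- h; hb[!brain_mask] <- -Inf
  list(mass_fraction = mass, volume_fraction = vol,
       concentration = mass / vol,
       argmax_in_roi = roi_mask[which.max(hb)])
}
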