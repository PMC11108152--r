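# 3D VGG-style classifier: conv blocks (3x3x3 conv + batch norm + ReLU) with
# 2x2x2 max-pooling between blocks, topped either by the fully connected head
# (flatten -> FC -> ReLU -> dropout -> FC -> ReLU -> dropout -> FC -> softmax)
# or by the global-average-pooling head (GAP -> linear -> softmax). In the GAP
# variant the final max-pool is omitted so that the single linear layer acts
# directly on the capture-layer feature maps; this is what makes the classic
# CAM construction exact and keeps heatmap resolution.

#' Describe a 3D VGG-style network
#'
#' @param input_shape Integer triple of spatial input dimensions.
#' @param in_channels Number of input channels (1 for a single activity map,
#'   4 for the combined ALFF/fALFF/ReHo/VMHC stack).
#' @param blocks List of `c(n_convs, n_channels)` pairs, one per VGG block.
#'   The classic 3D-VGG16 trunk is
#'   `list(c(2,64), c(2,128), c(3,256), c(3,512), c(3,512))` (13 conv layers).
#' @param head `"gap"` (global average pooling + one linear layer) or `"fc"`
#'   (two hidden fully connected layers + classifier).
#' @param fc_units Hidden unit counts of the FC head.
#' @param dropout Dropout rate in the FC head (active only during training).
#' @param n_classes Number of output classes.
#' @param width_scale Multiplier applied to every block's channel count
#'   (rounded, minimum 1); shrinks the network for CPU-scale experiments.
#' @param preset `"paper_faithful"` (61x73x61 input, full-width 13-conv
#'   trunk, FC 2048/1024) or `"desk"` (24x28x24 input, two narrow blocks;
#'   sized so the capture-layer receptive field stays local relative to the
#'   brain, which keeps CAM localization meaningful) — presets fill every
#'   other argument and may be partially overridden.
#' @return A `network_spec` object.
#' @export
network_spec <- function(input_shape = c(24, 28, 24), in_channels = 4,
                         blocks = list(c(1, 8), c(2, 16)),
                         head = c("gap", "fc"), fc_units = c(2048, 1024),
                         dropout = 0.5, n_classes = 2, width_scale = 1,
                         preset = NULL) {
  head <- match.arg(head)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("paper_faithful", "desk"))
    if (preset == "paper_faithful") {
      if (missing(input_shape)) input_shape <- c(61, 73, 61)
      if (missing(blocks))
        blocks <- list(c(2, 64), c(2, 128), c(3, 256), c(3, 512), c(3, 512))
    } else {
      if (missing(input_shape)) input_shape <- c(24, 28, 24)
      if (missing(blocks)) blocks <- list(c(1, 8), c(2, 16))
    }
  }
  ch <- vapply(blocks, function(b) max(1L, as.integer(round(b[2] * width_scale))), 1L)
  blocks <- Map(function(b, c) c(as.integer(b[1]), c), blocks, ch)
  n_pools <- length(blocks) - as.integer(head == "gap")
  final <- input_shape
  for (i in seq_len(n_pools)) final <- pmax(final %/% 2L, 1L)
  min_shape <- 2L^n_pools
  if (any(input_shape %/% (2L^n_pools) < 1))
    stop("input too small for ", n_pools, " pooling stages; each spatial ",
         "dimension must be at least ", min_shape)
  structure(list(input_shape = as.integer(input_shape),
                 in_channels = as.integer(in_channels), blocks = blocks,
                 head = head, fc_units = as.integer(fc_units),
                 dropout = dropout, n_classes = as.integer(n_classes),
                 width_scale = width_scale),
            class = "network_spec")
}

#' Number of convolutional layers in a spec
#' @param spec A `network_spec`.
#' @return Integer count.
#' @export
n_conv_layers <- function(spec) sum(vapply(spec$blocks, `[`, 1, 1))

#' Build (initialize) a network from its spec
#'
#' He-initialized weights; batch-norm scale 1, shift 0, running statistics
#' (0, 1).
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed fixing the initialization.
#' @return A `network` object: layer list, capture index (ReLU output of the
#'   last conv of the last block) and bookkeeping.
#' @export
build_network <- function(spec, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  layers <- list()
  cin <- spec$in_channels
  nb <- length(spec$blocks)
  for (bi in seq_len(nb)) {
    ncv <- spec$blocks[[bi]][1]; cout <- spec$blocks[[bi]][2]
    for (ci in seq_len(ncv)) {
      fan_in <- 27 * cin
      layers[[length(layers) + 1]] <- list(
        type = "conv",
        W = matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout),
        b = numeric(cout))
      layers[[length(layers) + 1]] <- list(
        type = "bn", gamma = rep(1, cout), beta = numeric(cout),
        run_mean = numeric(cout), run_var = rep(1, cout))
      layers[[length(layers) + 1]] <- list(type = "relu")
      cin <- cout
    }
    if (bi < nb || spec$head == "fc")
      layers[[length(layers) + 1]] <- list(type = "pool")
  }
  capture_index <- max(which(vapply(layers, `[[`, "", "type") == "relu"))

  if (spec$head == "gap") {
    layers[[length(layers) + 1]] <- list(type = "gap")
    layers[[length(layers) + 1]] <- list(
      type = "dense",
      W = matrix(stats::rnorm(cin * spec$n_classes, 0, sqrt(2 / cin)),
                 cin, spec$n_classes),
      b = numeric(spec$n_classes))
  } else {
    dims <- spec$input_shape
    for (i in seq_along(spec$blocks)) dims <- pmax(dims %/% 2L, 1L)
    flat <- prod(dims) * cin
    layers[[length(layers) + 1]] <- list(type = "flatten")
    units <- c(flat, spec$fc_units, spec$n_classes)
    for (u in seq_len(length(units) - 1)) {
      layers[[length(layers) + 1]] <- list(
        type = "dense",
        W = matrix(stats::rnorm(units[u] * units[u + 1], 0, sqrt(2 / units[u])),
                   units[u], units[u + 1]),
        b = numeric(units[u + 1]))
      if (u < length(units) - 1) {
        layers[[length(layers) + 1]] <- list(type = "relu_fc")
        layers[[length(layers) + 1]] <- list(type = "dropout", p = spec$dropout)
      }
    }
  }
  structure(list(spec = spec, layers = layers, capture_index = capture_index,
                 capture_layer = "last_conv_relu"),
            class = "network")
}

#' Total trainable parameter count
#' @param model A `network`.
#' @return Integer.
#' @export
n_params <- function(model) {
  sum(vapply(model$layers, function(l) {
    switch(l$type,
           conv = , dense = length(l$W) + length(l$b),
           bn = length(l$gamma) + length(l$beta),
           0L)
  }, numeric(1)))
}

# Convert a map_stack (or plain 4D/3D array) to the network's input matrix.
stack_input <- function(stack) {
  a <- if (inherits(stack, "map_stack")) stack$data else stack
  if (length(dim(a)) == 3) dim(a) <- c(dim(a), 1L)
  d <- dim(a)
  list(x = matrix(a, prod(d[1:3]), d[4]), dims = d[1:3])
}

# Forward pass over a batch. xs: list of input matrices (V x C, same dims).
# Returns logits, per-layer caches, and updated model (running BN stats when
# train = TRUE). store_outs keeps each layer's output (used by capture()).
net_forward <- function(model, xs, dims, train = FALSE, store_outs = FALSE) {
  batch <- length(xs)
  x <- do.call(rbind, xs)
  caches <- vector("list", length(model$layers))
  outs <- if (store_outs) vector("list", length(model$layers)) else NULL
  spatial <- TRUE
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$type == "conv") {
      r <- conv_forward(x, l$W, l$b, dims, batch)
      x <- r$y; caches[[i]] <- r$cache
    } else if (l$type == "bn") {
      r <- bn_forward(x, l$gamma, l$beta, l$run_mean, l$run_var, train)
      x <- r$y; caches[[i]] <- r$cache
      if (train) {
        model$layers[[i]]$run_mean <- r$run_mean
        model$layers[[i]]$run_var <- r$run_var
      }
    } else if (l$type %in% c("relu", "relu_fc")) {
      caches[[i]] <- list(mask = x > 0)
      x <- x * caches[[i]]$mask
    } else if (l$type == "pool") {
      r <- pool_forward(x, dims, batch)
      x <- r$y; dims <- r$dims_out; caches[[i]] <- r$cache
    } else if (l$type == "gap") {
      r <- gap_forward(x, dims, batch)
      x <- r$y; caches[[i]] <- r$cache; spatial <- FALSE
    } else if (l$type == "flatten") {
      r <- flatten_forward(x, dims, batch)
      x <- r$y; caches[[i]] <- r$cache; spatial <- FALSE
    } else if (l$type == "dense") {
      r <- dense_forward(x, l$W, l$b)
      x <- r$y; caches[[i]] <- r$cache
    } else if (l$type == "dropout") {
      if (train) {
        keep <- (matrix(stats::runif(length(x)), nrow(x)) > l$p) / (1 - l$p)
        x <- x * keep
        caches[[i]] <- list(keep = keep)
      } else caches[[i]] <- list(keep = NULL)
    }
    if (store_outs) outs[[i]] <- list(x = x, dims = dims)
    if (i == model$capture_index) model$.capture_dims <- dims
  }
  list(logits = x, caches = caches, outs = outs, model = model,
       capture_dims = model$.capture_dims)
}

# Backward pass. Returns per-layer parameter gradients; when stop_at > 0,
# stops there and also returns the gradient w.r.t. that layer's output.
net_backward <- function(model, caches, dlogits, stop_at = 0) {
  grads <- vector("list", length(model$layers))
  dx <- dlogits
  for (i in rev(seq_along(model$layers))) {
    if (i == stop_at) return(list(grads = grads, dx = dx))
    l <- model$layers[[i]]
    if (l$type == "conv") {
      r <- conv_backward(dx, l$W, caches[[i]])
      grads[[i]] <- list(W = r$dW, b = r$db); dx <- r$dx
    } else if (l$type == "bn") {
      r <- bn_backward(dx, caches[[i]])
      grads[[i]] <- list(gamma = r$dgamma, beta = r$dbeta); dx <- r$dx
    } else if (l$type %in% c("relu", "relu_fc")) {
      dx <- dx * caches[[i]]$mask
    } else if (l$type == "pool") {
      dx <- pool_backward(dx, caches[[i]])
    } else if (l$type == "gap") {
      dx <- gap_backward(dx, caches[[i]])
    } else if (l$type == "flatten") {
      dx <- flatten_backward(dx, caches[[i]])
    } else if (l$type == "dense") {
      r <- dense_backward(dx, l$W, caches[[i]])
      grads[[i]] <- list(W = r$dW, b = r$db); dx <- r$dx
    } else if (l$type == "dropout") {
      if (!is.null(caches[[i]]$keep)) dx <- dx * caches[[i]]$keep
    }
  }
  list(grads = grads, dx = dx)
}

# Run the tail of the network (layers after `start_index`) on given
# activations, in evaluation mode. Used by the finite-difference gradient
# check of the Grad-CAM weights.
net_forward_from <- function(model, x, dims, start_index, batch = 1) {
  for (i in seq(start_index + 1, length(model$layers))) {
    l <- model$layers[[i]]
    if (l$type == "conv") {
      x <- conv_forward(x, l$W, l$b, dims, batch)$y
    } else if (l$type == "bn") {
      x <- bn_forward(x, l$gamma, l$beta, l$run_mean, l$run_var, FALSE)$y
    } else if (l$type %in% c("relu", "relu_fc")) {
      x <- x * (x > 0)
    } else if (l$type == "pool") {
      r <- pool_forward(x, dims, batch); x <- r$y; dims <- r$dims_out
    } else if (l$type == "gap") {
      x <- gap_forward(x, dims, batch)$y
    } else if (l$type == "flatten") {
      x <- flatten_forward(x, dims, batch)$y
    } else if (l$type == "dense") {
      x <- dense_forward(x, l$W, l$b)$y
    }
  }
  x
}

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 5e-5,
#' weight decay 5e-4, batch size 4, cross-entropy loss on two classes.
#'
#' @param lr Learning rate.
#' @param weight_decay L2 penalty added to conv/dense weight gradients.
#' @param batch_size Mini-batch size.
#' @param n_epochs Training epochs.
#' @param seed Seed fixing initialization, shuffling and dropout.
#' @return A `train_config` object.
#' @export
train_config <- function(lr = 5e-5, weight_decay = 5e-4, batch_size = 4,
                         n_epochs = 60, seed = 1) {
  stopifnot(lr > 0, weight_decay >= 0, batch_size >= 1, n_epochs >= 1)
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 n_epochs = as.integer(n_epochs), seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(layers) {
  lapply(layers, function(l) {
    nm <- intersect(names(l), c("W", "b", "gamma", "beta"))
    if (!length(nm)) return(NULL)
    st <- lapply(nm, function(p) list(m = l[[p]] * 0, v = l[[p]] * 0))
    names(st) <- nm
    st
  })
}

adam_step <- function(layers, grads, state, t, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    if (is.null(grads[[i]])) next
    for (p in names(grads[[i]])) {
      gname <- if (p %in% c("gamma", "beta")) p else p
      g <- grads[[i]][[p]]
      if (p == "W" && wd > 0) g <- g + wd * layers[[i]]$W
      s <- state[[i]][[gname]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      layers[[i]][[gname]] <- layers[[i]][[gname]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[gname]] <- s
    }
  }
  list(layers = layers, state = state)
}

label_index <- function(labels) ifelse(labels == "AD", 1L, 2L)

#' Train a network on labeled map stacks
#'
#' Minimizes the mean cross-entropy with Adam (learning rate, weight decay and
#' batch size from `config`), shuffling with a seeded order each epoch.
#' Dropout is active only in the FC head. The weights of the epoch with the
#' lowest training loss are kept (no test-set peeking).
#'
#' @param model A `network` from [build_network()].
#' @param stacks List of `map_stack`s (or arrays) sharing shape/channels.
#' @param labels Character vector of `"AD"`/`"NC"`, one per stack.
#' @param config A [train_config()].
#' @param verbose Print per-epoch loss.
#' @return The trained `network`, with a `training_log` data.frame attached
#'   (per-epoch loss and accuracy).
#' @export
train_model <- function(model, stacks, labels, config = train_config(),
                        verbose = FALSE) {
  stopifnot(length(stacks) == length(labels), length(stacks) >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  ins <- lapply(stacks, stack_input)
  dims <- ins[[1]]$dims
  yidx <- label_index(labels)
  state <- adam_init(model$layers)
  t <- 0
  log <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
  best <- list(loss = Inf, layers = model$layers)
  for (ep in seq_len(config$n_epochs)) {
    ord <- sample(length(ins))
    tot_loss <- 0; n_correct <- 0
    for (start in seq(1, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, length(ord))]
      fw <- net_forward(model, lapply(ins[idx], `[[`, "x"), dims, train = TRUE)
      model <- fw$model
      ce <- softmax_ce(fw$logits, yidx[idx])
      if (!is.finite(ce$loss))
        stop("NaN/Inf training loss at epoch ", ep,
             "; lower the learning rate")
      bw <- net_backward(model, fw$caches, ce$dlogits)
      t <- t + 1
      upd <- adam_step(model$layers, bw$grads, state, t,
                       config$lr, config$weight_decay)
      model$layers <- upd$layers; state <- upd$state
      tot_loss <- tot_loss + ce$loss * length(idx)
      n_correct <- n_correct + sum(max.col(ce$p) == yidx[idx])
    }
    ep_loss <- tot_loss / length(ins)
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss,
                                 accuracy = n_correct / length(ins)))
    if (ep_loss < best$loss) best <- list(loss = ep_loss, layers = model$layers)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep, ep_loss,
                      n_correct / length(ins)))
  }
  model$layers <- best$layers
  model <- bn_recalibrate(model, ins, config$batch_size)
  model$training_log <- log
  model
}

# Precise batch-norm recalibration: with weights frozen, run the training
# inputs forward in train mode and replace each BN layer's running statistics
# by the average batch statistics at the final weights. Without this the
# running estimates lag the weight trajectory, which biases evaluation-mode
# predictions.
bn_recalibrate <- function(model, ins, batch_size) {
  bn_idx <- which(vapply(model$layers, `[[`, "", "type") == "bn")
  if (!length(bn_idx)) return(model)
  acc_m <- list(); acc_v <- list(); n_b <- 0
  dims <- ins[[1]]$dims
  for (start in seq(1, length(ins), by = batch_size)) {
    idx <- start:min(start + batch_size - 1, length(ins))
    x <- do.call(rbind, lapply(ins[idx], `[[`, "x"))
    d <- dims; batch <- length(idx)
    n_b <- n_b + 1
    for (i in seq_along(model$layers)) {
      l <- model$layers[[i]]
      if (l$type == "conv") {
        x <- conv_forward(x, l$W, l$b, d, batch)$y
      } else if (l$type == "bn") {
        m <- colMeans(x); v <- pmax(colMeans(x^2) - m^2, 0)
        key <- as.character(i)
        acc_m[[key]] <- if (is.null(acc_m[[key]])) m else acc_m[[key]] + m
        acc_v[[key]] <- if (is.null(acc_v[[key]])) v else acc_v[[key]] + v
        x <- bn_forward(x, l$gamma, l$beta, m, v, FALSE)$y
      } else if (l$type %in% c("relu", "relu_fc")) {
        x <- x * (x > 0)
      } else if (l$type == "pool") {
        r <- pool_forward(x, d, batch); x <- r$y; d <- r$dims_out
      } else if (l$type == "gap") {
        x <- gap_forward(x, d, batch)$y
      } else if (l$type == "flatten") {
        x <- flatten_forward(x, d, batch)$y
      } else if (l$type == "dense") {
        x <- dense_forward(x, l$W, l$b)$y
      } # dropout: identity with frozen weights
    }
  }
  for (i in bn_idx) {
    key <- as.character(i)
    model$layers[[i]]$run_mean <- acc_m[[key]] / n_b
    model$layers[[i]]$run_var <- acc_v[[key]] / n_b
  }
  model
}

#' Class probabilities for one map stack
#'
#' Evaluation mode: dropout off, batch norm uses running statistics.
#'
#' @param model A trained `network`.
#' @param stack A `map_stack` or array matching the model input.
#' @return Named numeric 2-vector of probabilities (`AD`, `NC`), summing
#'   to 1.
#' @export
predict_stack <- function(model, stack) {
  inp <- stack_input(stack)
  if (ncol(inp$x) != model$spec$in_channels)
    stop("input has ", ncol(inp$x), " channels but the model expects ",
         model$spec$in_channels)
  if (!identical(as.integer(inp$dims), model$spec$input_shape))
    stop("input shape ", paste(inp$dims, collapse = "x"),
         " does not match model input ",
         paste(model$spec$input_shape, collapse = "x"))
  fw <- net_forward(model, list(inp$x), inp$dims, train = FALSE)
  p <- drop(softmax_rows(fw$logits))
  names(p) <- c("AD", "NC")[seq_along(p)]
  p
}

#' Capture-layer activations and class-score gradients
#'
#' Runs the model in evaluation mode, records the feature maps A^k at the
#' capture layer (ReLU output of the last convolutional layer), and
#' backpropagates the pre-softmax class score y^c to obtain dy^c/dA^k.
#'
#' @param model A trained `network`.
#' @param stack Input `map_stack` or array.
#' @param class_index 1 = AD, 2 = NC.
#' @return List with `activations` and `gradients` (both 4D arrays of
#'   dimension capture-dims x channels), `dims`, `logits`.
#' @export
capture <- function(model, stack, class_index = 1) {
  inp <- stack_input(stack)
  fw <- net_forward(model, list(inp$x), inp$dims, train = FALSE,
                    store_outs = TRUE)
  ci <- model$capture_index
  A <- fw$outs[[ci]]$x
  cdims <- fw$outs[[ci]]$dims
  dlogits <- matrix(0, 1, ncol(fw$logits))
  dlogits[1, class_index] <- 1
  bw <- net_backward(model, fw$caches, dlogits, stop_at = ci)
  list(activations = array(A, c(cdims, ncol(A))),
       gradients = array(bw$dx, c(cdims, ncol(A))),
       dims = cdims, logits = drop(fw$logits))
}

#' Pre-softmax class scores from given capture-layer activations
#'
#' Evaluates only the layers after the capture layer; used as the
#' finite-difference oracle for the Grad-CAM gradients.
#'
#' @param model A `network`.
#' @param activations 4D array (capture dims x channels) or matrix.
#' @param dims Spatial dims of the activations (inferred from an array).
#' @return Numeric vector of class scores (logits).
#' @export
score_from_capture <- function(model, activations, dims = NULL) {
  if (is.null(dims)) dims <- dim(activations)[1:3]
  x <- matrix(activations, prod(dims), length(activations) / prod(dims))
  drop(net_forward_from(model, x, dims, model$capture_index, batch = 1))
}
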