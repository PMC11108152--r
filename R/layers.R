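# Layer primitives for the 3D convolutional network.
#
# Feature tensors are stored as dense matrices of shape (batch * n_voxels) x
# n_channels, rows sample-major (sample b occupies a contiguous block of
# n_voxels rows, voxels in column-major order of the spatial grid). 3x3x3
# convolution is evaluated as im2col + one BLAS matrix product; im2col,
# col2im and max pooling are implemented in C++ (src/convops.cpp).

conv_forward <- function(x, W, bias, dims, batch) {
  r <- .conv3d_forward(x, W, bias, as.integer(dims), as.integer(batch))
  list(y = r$y, cache = list(x = x, dims = dims, batch = batch))
}

conv_backward <- function(dy, W, cache) {
  .conv3d_backward(dy, cache$x, W, as.integer(cache$dims),
                   as.integer(cache$batch))
}

pool_forward <- function(x, dims, batch) {
  r <- .maxpool_forward(x, as.integer(dims), as.integer(batch))
  list(y = r$y, dims_out = r$dout,
       cache = list(am = r$argmax, n_in = nrow(x)))
}

pool_backward <- function(dy, cache) {
  .maxpool_backward(dy, cache$am, cache$n_in)
}

bn_forward <- function(x, gamma, beta, run_mean, run_var, train,
                       momentum = 0.1, eps = 1e-5) {
  if (train) {
    m <- colMeans(x)
    v <- colMeans(x^2) - m^2
    v <- pmax(v, 0)
  } else {
    m <- run_mean; v <- run_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (x - matrix(m, nrow(x), ncol(x), byrow = TRUE)) *
    matrix(invstd, nrow(x), ncol(x), byrow = TRUE)
  y <- xhat * matrix(gamma, nrow(x), ncol(x), byrow = TRUE) +
    matrix(beta, nrow(x), ncol(x), byrow = TRUE)
  new_rm <- if (train) (1 - momentum) * run_mean + momentum * m else run_mean
  new_rv <- if (train) (1 - momentum) * run_var + momentum * v else run_var
  list(y = y, cache = list(xhat = xhat, invstd = invstd, gamma = gamma),
       run_mean = new_rm, run_var = new_rv)
}

bn_backward <- function(dy, cache) {
  N <- nrow(dy)
  g <- matrix(cache$gamma, N, ncol(dy), byrow = TRUE)
  dxhat <- dy * g
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- (dxhat - matrix(s1 / N, N, ncol(dy), byrow = TRUE) -
           cache$xhat * matrix(s2 / N, N, ncol(dy), byrow = TRUE)) *
    matrix(cache$invstd, N, ncol(dy), byrow = TRUE)
  list(dx = dx, dgamma = colSums(dy * cache$xhat), dbeta = colSums(dy))
}

gap_forward <- function(x, dims, batch) {
  V <- prod(dims)
  grp <- rep(seq_len(batch), each = V)
  y <- rowsum(x, grp) / V
  list(y = y, cache = list(V = V, batch = batch))
}

gap_backward <- function(dy, cache) {
  dy[rep(seq_len(cache$batch), each = cache$V), , drop = FALSE] / cache$V
}

flatten_forward <- function(x, dims, batch) {
  V <- prod(dims); C <- ncol(x)
  y <- matrix(0, batch, V * C)
  for (b in seq_len(batch))
    y[b, ] <- as.vector(x[((b - 1) * V + 1):(b * V), , drop = FALSE])
  list(y = y, cache = list(V = V, C = C, batch = batch))
}

flatten_backward <- function(dy, cache) {
  dx <- matrix(0, cache$batch * cache$V, cache$C)
  for (b in seq_len(cache$batch))
    dx[((b - 1) * cache$V + 1):(b * cache$V), ] <-
      matrix(dy[b, ], cache$V, cache$C)
  dx
}

dense_forward <- function(x, W, bias) {
  y <- x %*% W + matrix(bias, nrow(x), length(bias), byrow = TRUE)
  list(y = y, cache = list(x = x))
}

dense_backward <- function(dy, W, cache) {
  list(dx = tcrossprod(dy, W), dW = crossprod(cache$x, dy), db = colSums(dy))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean cross-entropy over the batch plus gradient w.r.t. the logits.
softmax_ce <- function(logits, class_idx) {
  p <- softmax_rows(logits)
  B <- nrow(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(B), class_idx)], 1e-12)))
  dlogits <- p
  dlogits[cbind(seq_len(B), class_idx)] <-
    dlogits[cbind(seq_len(B), class_idx)] - 1
  list(loss = loss, p = p, dlogits = dlogits / B)
}
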