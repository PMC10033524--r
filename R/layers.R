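# Primitive trainable layers (forward + hand-derived backward passes).
# Feature maps are 4D double arrays (rows, cols, slices, channels).
# Convolution weights live as a (k^3 * cin) x cout matrix matching the
# im2col column order of the C++ kernel.

conv_layer <- function(cin, cout, k = 3L, stride = c(1L, 1L, 1L), dilation = 1L) {
  fan_in <- k^3 * cin
  W <- matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout)
  list(type = "conv", W = W, b = numeric(cout), k = as.integer(k),
       stride = as.integer(stride), dilation = as.integer(dilation),
       cin = as.integer(cin), cout = as.integer(cout))
}

conv_fw <- function(layer, x) {
  conv3d_forward_cpp(x, dim(x), layer$W, layer$b, layer$k, layer$stride,
                     layer$dilation)
}

conv_bw <- function(layer, x, dy) {
  conv3d_backward_cpp(x, dim(x), layer$W, layer$k, layer$stride,
                      layer$dilation, dy)
}

# Batch normalization over all voxels of the (single-volume) batch, per
# channel. Statistics are always the current batch's: with batch size 1 this
# is instance normalization, used identically at train and inference time.
bn_layer <- function(ch, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, ch), beta = numeric(ch),
       eps = eps, ch = as.integer(ch))
}

bn_fw <- function(layer, x) {
  r <- bn_forward_cpp(x, dim(x), layer$gamma, layer$beta, layer$eps)
  list(y = r$y, cache = list(x = x, mu = as.numeric(r$mu),
                             invstd = as.numeric(r$invstd)))
}

bn_bw <- function(layer, cache, dy) {
  r <- bn_backward_cpp(cache$x, dim(cache$x), layer$gamma, cache$mu,
                       cache$invstd, dy)
  list(dx = r$dx, dgamma = as.numeric(r$dgamma), dbeta = as.numeric(r$dbeta))
}

# PReLU with one learnable negative slope per channel.
prelu_layer <- function(ch, init = 0.25) {
  list(type = "prelu", alpha = rep(init, ch), ch = as.integer(ch))
}

prelu_fw <- function(layer, x) {
  list(y = prelu_forward_cpp(x, dim(x), layer$alpha), cache = list(x = x))
}

prelu_bw <- function(layer, cache, dy) {
  r <- prelu_backward_cpp(cache$x, dim(cache$x), layer$alpha, dy)
  list(dx = r$dx, dalpha = as.numeric(r$dalpha))
}

# Softmax over the channel axis of a (rows, cols, slices, C) array.
softmax4 <- function(z) {
  d <- dim(z)
  n <- prod(d[1:3]); ch <- d[4]
  zm <- matrix(z, n, ch)
  m <- zm[, 1]
  for (j in seq_len(ch)[-1]) m <- pmax(m, zm[, j])
  zm <- zm - m
  e <- exp(zm)
  p <- e / rowSums(e)
  dim(p) <- d
  p
}

layer_param_names <- function(layer) {
  switch(layer$type,
         conv = c("W", "b"),
         bn = c("gamma", "beta"),
         prelu = "alpha",
         character(0))
}
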