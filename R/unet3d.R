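#' Progressive-dilated 3D U-Net model specification
#'
#' Describes one member of the architecture family. Each encoder level is
#' three 3x3x3 convolutions with dilation rates 1, 2 and 4 (the "progressive
#' dilation" pattern), every convolution followed by batch normalization and
#' PReLU; the level's first convolution carries the level's stride and
#' downsamples. A bridge of two normalized convolutions plus a residual
#' block (two convolutions, dilation 1, no normalization, PReLU, additive
#' identity skip) sits at the bottom. The decoder upsamples level by level
#' (parameter-free nearest neighbour), concatenates each upsampled map with
#' the dilation-4 encoder output at that resolution, and applies two
#' normalized convolutions; the head is a 3-filter (1,1,1) convolution with
#' batch normalization, PReLU and a channel softmax.
#'
#' The study architectures have 4, 5 or 6 levels; smaller block counts are
#' accepted for tiny smoke-test models.
#'
#' @param num_blocks number of encoder/decoder resolution levels (2-6).
#' @param base_filters filters at the first level; doubled per level
#'   (`filter_growth`) and capped at `filter_cap`.
#' @param filter_growth per-level filter multiplier.
#' @param filter_cap maximum filters at any level.
#' @param kernel isotropic convolution kernel size (head is always 1).
#' @param dilations dilation rates of the three convolutions in each level.
#' @param input_shape spatial input shape `(rows, cols, slices)`.
#' @param num_classes output classes (3: background, wall, tumor).
#' @param stride_policy list of `num_blocks` stride triples; default from
#'   [default_stride_policy()].
#' @param merge `"concat"` (standard) or `"add"` for the skip merge.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(num_blocks = 5L, base_filters = 16L, filter_growth = 2,
                       filter_cap = 256L, kernel = 3L, dilations = c(1L, 2L, 4L),
                       input_shape = c(128L, 128L, 32L), num_classes = 3L,
                       stride_policy = NULL, merge = c("concat", "add")) {
  merge <- match.arg(merge)
  num_blocks <- as.integer(num_blocks)
  if (num_blocks < 2L || num_blocks > 6L)
    stop("num_blocks must be between 2 and 6 (study architectures: 4, 5, 6)")
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3L || any(input_shape < 1L))
    stop("input_shape must be three positive integers")
  if (is.null(stride_policy))
    stride_policy <- default_stride_policy(num_blocks, input_shape)
  stride_policy <- lapply(stride_policy, as.integer)
  if (length(stride_policy) != num_blocks)
    stop("stride_policy must have one stride triple per block")
  if (!all(unlist(stride_policy) %in% c(1L, 2L)))
    stop("stride components must be 1 or 2")
  spec <- list(num_blocks = num_blocks, base_filters = as.integer(base_filters),
               filter_growth = filter_growth, filter_cap = as.integer(filter_cap),
               kernel = as.integer(kernel), dilations = as.integer(dilations),
               input_shape = input_shape, num_classes = as.integer(num_classes),
               stride_policy = stride_policy, merge = merge)
  class(spec) <- "model_spec"
  spec
}

#' Default stride policy for a given depth and input shape
#'
#' Every level strides `(2,2,2)` while each axis can still be halved; an
#' axis that would collapse below one voxel keeps stride 1 from that level
#' on. For the standard `128 x 128 x 32` input the 6-block policy clamps the
#' slice axis at level 6 (`(2,2,1)`), since 32 slices support only five
#' halvings.
#'
#' @param num_blocks number of levels.
#' @param input_shape spatial input shape.
#' @return List of `num_blocks` integer stride triples.
#' @export
default_stride_policy <- function(num_blocks, input_shape = c(128L, 128L, 32L)) {
  sizes <- as.integer(input_shape)
  policy <- vector("list", num_blocks)
  for (i in seq_len(num_blocks)) {
    s <- ifelse(sizes >= 2L, 2L, 1L)
    policy[[i]] <- as.integer(s)
    sizes <- as.integer(ceiling(sizes / s))
  }
  policy
}

level_filters <- function(spec) {
  f <- pmin(spec$base_filters * spec$filter_growth^(seq_len(spec$num_blocks) - 1),
            spec$filter_cap)
  as.integer(round(f))
}

bridge_filters <- function(spec) {
  as.integer(round(min(spec$base_filters * spec$filter_growth^spec$num_blocks,
                       spec$filter_cap)))
}

# Spatial shapes entering each level: shapes[[1]] = input, shapes[[i+1]] =
# shape after level i's stride. Errors if a stride would collapse an axis.
level_shapes <- function(spec) {
  shapes <- vector("list", spec$num_blocks + 1L)
  shapes[[1]] <- spec$input_shape
  for (i in seq_len(spec$num_blocks)) {
    s <- spec$stride_policy[[i]]
    cur <- shapes[[i]]
    bad <- which(s > 1L & cur < 2L)
    if (length(bad))
      stop(sprintf("stride_policy level %d would collapse axis %d (size %d) below 1",
                   i, bad[1], cur[bad[1]]))
    shapes[[i + 1]] <- as.integer(ceiling(cur / s))
  }
  shapes
}

#' Build a progressive-dilated 3D U-Net
#'
#' Instantiates all trainable parameters (He-initialized convolutions, unit
#' batch-norm scales, PReLU slopes 0.25) for a [model_spec()]. The returned
#' model is a plain parameter container; [predict.unet3d()] runs the forward
#' pass and [train()] fits it.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `unet3d`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  shapes <- level_shapes(spec)
  f <- level_filters(spec)
  fb <- bridge_filters(spec)
  B <- spec$num_blocks
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)

  layers <- list()
  meta <- list()
  add_cbp <- function(prefix, cin, cout, role, level, stride = c(1L, 1L, 1L),
                      dilation = 1L, k = spec$kernel, bn = TRUE) {
    layers[[paste0(prefix, "_conv")]] <<- conv_layer(cin, cout, k, stride, dilation)
    if (bn) layers[[paste0(prefix, "_bn")]] <<- bn_layer(cout)
    layers[[paste0(prefix, "_prelu")]] <<- prelu_layer(cout)
    meta[[length(meta) + 1L]] <<- data.frame(
      name = prefix, role = role, level = level, kernel = k,
      dilation = dilation, stride = paste(stride, collapse = "x"),
      cin = cin, cout = cout, normalized = bn, activation = "PReLU")
  }

  for (i in seq_len(B)) {
    cin <- if (i == 1L) 1L else f[i - 1]
    add_cbp(sprintf("enc%d_1", i), cin, f[i], "encoder", i,
            stride = spec$stride_policy[[i]], dilation = spec$dilations[1])
    add_cbp(sprintf("enc%d_2", i), f[i], f[i], "encoder", i,
            dilation = spec$dilations[2])
    add_cbp(sprintf("enc%d_3", i), f[i], f[i], "encoder", i,
            dilation = spec$dilations[3])
  }
  add_cbp("bridge_1", f[B], fb, "bridge", B)
  add_cbp("bridge_2", fb, fb, "bridge", B)
  add_cbp("res_1", fb, fb, "residual", B, bn = FALSE)
  add_cbp("res_2", fb, fb, "residual", B, bn = FALSE)
  dec_in <- fb
  for (i in rev(seq_len(B))) {
    fo <- f[max(i - 1L, 1L)]
    cin <- if (i > 1L) {
      if (spec$merge == "add" && dec_in != f[i - 1])
        stop("merge = 'add' requires matching channel counts (use filter_growth = 1)")
      if (spec$merge == "add") dec_in else dec_in + f[i - 1]
    } else dec_in
    add_cbp(sprintf("dec%d_1", i), cin, fo, "decoder", i)
    add_cbp(sprintf("dec%d_2", i), fo, fo, "decoder", i)
    dec_in <- fo
  }
  add_cbp("head", dec_in, spec$num_classes, "head", 0L, k = 1L)

  structure(list(spec = spec, layers = layers, shapes = shapes,
                 filters = f, bridge_filters = fb,
                 summary = do.call(rbind, meta), seed = as.integer(seed)),
            class = "unet3d")
}

#' @export
print.unet3d <- function(x, ...) {
  cat(sprintf(paste0("<unet3d> %d blocks, base %d filters, input %s, ",
                     "%d classes, %s trainable parameters\n"),
              x$spec$num_blocks, x$spec$base_filters,
              paste(x$spec$input_shape, collapse = "x"),
              x$spec$num_classes, format(count_params(x), big.mark = ",")))
  invisible(x)
}

# conv (+ optional bn) + prelu forward; returns output and cache
fw_cbp <- function(model, prefix, x, keep_cache, bn = TRUE) {
  cl <- model$layers[[paste0(prefix, "_conv")]]
  y <- conv_fw(cl, x)
  cc <- if (keep_cache) list(x = x) else NULL
  if (bn) {
    r <- bn_fw(model$layers[[paste0(prefix, "_bn")]], y)
    y <- r$y
    if (keep_cache) cc$bn <- r$cache
  }
  r <- prelu_fw(model$layers[[paste0(prefix, "_prelu")]], y)
  if (keep_cache) cc$prelu <- r$cache
  list(y = r$y, cache = cc)
}

bw_cbp <- function(model, prefix, cc, dy, grads, bn = TRUE) {
  pb <- prelu_bw(model$layers[[paste0(prefix, "_prelu")]], cc$prelu, dy)
  grads[[paste0(prefix, "_prelu.alpha")]] <- pb$dalpha
  dy <- pb$dx
  if (bn) {
    bb <- bn_bw(model$layers[[paste0(prefix, "_bn")]], cc$bn, dy)
    grads[[paste0(prefix, "_bn.gamma")]] <- bb$dgamma
    grads[[paste0(prefix, "_bn.beta")]] <- bb$dbeta
    dy <- bb$dx
  }
  cl <- model$layers[[paste0(prefix, "_conv")]]
  cb <- conv_bw(cl, cc$x, dy)
  grads[[paste0(prefix, "_conv.W")]] <- cb$dW
  grads[[paste0(prefix, "_conv.b")]] <- as.numeric(cb$db)
  cb$dx
}

# Forward pass. Returns class probabilities (rows, cols, slices, classes)
# and, when keep_cache = TRUE, everything backward needs.
unet_forward <- function(model, x, keep_cache = FALSE) {
  spec <- model$spec
  B <- spec$num_blocks
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (!identical(as.integer(dim(x)[1:3]), spec$input_shape))
    stop(sprintf("input shape %s does not match the model's input_shape %s",
                 paste(dim(x)[1:3], collapse = "x"),
                 paste(spec$input_shape, collapse = "x")))
  cache <- if (keep_cache)
    list(enc = vector("list", B), dec = vector("list", B)) else NULL
  h <- x
  skips <- vector("list", B)
  for (i in seq_len(B)) {
    lev <- vector("list", 3L)
    for (j in 1:3) {
      r <- fw_cbp(model, sprintf("enc%d_%d", i, j), h, keep_cache)
      h <- r$y
      lev[[j]] <- r$cache
    }
    skips[[i]] <- h
    if (keep_cache) cache$enc[[i]] <- lev
  }
  br <- vector("list", 2L)
  for (j in 1:2) {
    r <- fw_cbp(model, sprintf("bridge_%d", j), h, keep_cache)
    h <- r$y
    br[[j]] <- r$cache
  }
  res_in <- h
  r1 <- fw_cbp(model, "res_1", h, keep_cache, bn = FALSE)
  r2 <- fw_cbp(model, "res_2", r1$y, keep_cache, bn = FALSE)
  h <- res_in + r2$y
  if (keep_cache) {
    cache$bridge <- br
    cache$res <- list(r1$cache, r2$cache)
  }
  for (i in rev(seq_len(B))) {
    factor <- spec$stride_policy[[i]]
    target <- model$shapes[[i]]
    hu <- upsample_nn_cpp(h, dim(h), factor, target)
    dc <- list(up_indim = dim(h), ch_up = dim(hu)[4])
    if (i > 1L) {
      skip <- skips[[i - 1]]
      h <- if (spec$merge == "add") hu + skip
      else array(c(hu, skip), c(dim(hu)[1:3], dim(hu)[4] + dim(skip)[4]))
    } else h <- hu
    for (j in 1:2) {
      r <- fw_cbp(model, sprintf("dec%d_%d", i, j), h, keep_cache)
      h <- r$y
      dc[[paste0("c", j)]] <- r$cache
    }
    if (keep_cache) cache$dec[[i]] <- dc
  }
  hh <- fw_cbp(model, "head", h, keep_cache)
  if (keep_cache) cache$head <- hh$cache
  probs <- softmax4(hh$y)
  list(probs = probs, cache = cache)
}

# Backward pass from the gradient at the softmax input (logits). Returns a
# named list of parameter gradients ("<layer>.<param>").
unet_backward <- function(model, cache, dz) {
  spec <- model$spec
  B <- spec$num_blocks
  grads <- new.env(parent = emptyenv())
  d <- bw_cbp(model, "head", cache$head, dz, grads)
  dskip <- vector("list", B)
  for (i in seq_len(B)) {
    dc <- cache$dec[[i]]
    d <- bw_cbp(model, sprintf("dec%d_2", i), dc$c2, d, grads)
    d <- bw_cbp(model, sprintf("dec%d_1", i), dc$c1, d, grads)
    if (i > 1L) {
      if (spec$merge == "add") {
        dup <- d
        dskip[[i - 1]] <- d
      } else {
        ch_up <- dc$ch_up
        dup <- d[, , , seq_len(ch_up), drop = FALSE]
        dskip[[i - 1]] <- d[, , , (ch_up + 1L):dim(d)[4], drop = FALSE]
      }
    } else dup <- d
    d <- upsample_nn_backward_cpp(dup, dim(dup), spec$stride_policy[[i]],
                                  dc$up_indim[1:3])
  }
  # residual block: out = res_in + res_2(res_1(res_in))
  dres <- d
  db <- bw_cbp(model, "res_2", cache$res[[2]], dres, grads, bn = FALSE)
  db <- bw_cbp(model, "res_1", cache$res[[1]], db, grads, bn = FALSE)
  d <- dres + db
  d <- bw_cbp(model, "bridge_2", cache$bridge[[2]], d, grads)
  d <- bw_cbp(model, "bridge_1", cache$bridge[[1]], d, grads)
  for (i in rev(seq_len(B))) {
    if (!is.null(dskip[[i]])) d <- d + dskip[[i]]
    for (j in 3:1)
      d <- bw_cbp(model, sprintf("enc%d_%d", i, j), cache$enc[[i]][[j]], d, grads)
  }
  as.list(grads)
}

#' Predict class probabilities for one volume
#'
#' @param object a trained or freshly built [build_model()] network.
#' @param image numeric 3D array matching the model's `input_shape` (a
#'   preprocessed, normalized intensity volume).
#' @param ... unused.
#' @return A `(rows, cols, slices, 3)` probability array whose channels
#'   (background, wall, tumor) sum to 1 at every voxel.
#' @export
predict.unet3d <- function(object, image, ...) {
  unet_forward(object, image, keep_cache = FALSE)$probs
}

#' Per-layer summary table of a built model
#'
#' One row per convolution with its role (encoder / bridge / residual /
#' decoder / head), level, kernel, dilation, stride, channel counts, whether
#' batch normalization follows it, and its activation. Structural
#' verification (encoder convolution counts, head filters, unnormalized
#' residual convolutions) reads from this table.
#'
#' @param model a [build_model()] network.
#' @return A data frame (class `layer_summary`).
#' @export
summarize <- function(model) {
  stopifnot(inherits(model, "unet3d"))
  s <- model$summary
  s$n_weights <- s$kernel^3 * s$cin * s$cout
  s$n_bias <- s$cout
  class(s) <- c("layer_summary", "data.frame")
  s
}

#' Total trainable parameter count
#'
#' @param model a [build_model()] network.
#' @return Integer: total number of trainable scalars (convolution weights
#'   and biases, batch-norm scales and shifts, PReLU slopes).
#' @export
count_params <- function(model) {
  stopifnot(inherits(model, "unet3d"))
  sum(vapply(model$layers, function(l) {
    sum(vapply(layer_param_names(l), function(p) length(l[[p]]), 0))
  }, 0))
}

# Named flat views of all trainable parameters ("<layer>.<param>")
get_params <- function(model) {
  out <- list()
  for (nm in names(model$layers)) {
    l <- model$layers[[nm]]
    for (p in layer_param_names(l)) out[[paste0(nm, ".", p)]] <- l[[p]]
  }
  out
}

set_params <- function(model, params) {
  for (key in names(params)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    model$layers[[parts[1]]][[parts[2]]] <- params[[key]]
  }
  model
}
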