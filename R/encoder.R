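# Encoder: fully convolutional network mapping a gaze-centered viewing
# patch to a binary electrode activation map.

#' Encoder configuration
#'
#' Describes the fully convolutional encoder that turns a `patch_size` x
#' `patch_size` RGB viewing patch into a binary `grid_size` x `grid_size`
#' electrode activation map.  The default architecture has 13 layer
#' groups: four convolution layers (channels 3-8-16-32-64, the third and
#' fourth followed by 2x2 max pooling), four two-convolution residual
#' blocks at 64 channels, and four decoder convolutions
#' (64-32-16-8-3-1, the first followed by pooling).  Batch
#' normalization is applied on groups 1-11, leaky rectifier activations
#' on groups 1-12, and a sigmoid on group 13; all kernels are 3x3 with
#' stride 1 and padding 1.  Because the three pooling stages halve the
#' resolution three times, the input patch is first resized to
#' `internal_size = grid_size * 8` pixels so that the output lands
#' exactly on the electrode grid.
#'
#' @param patch_size Side length (pixels) of the input viewing patch.
#' @param grid_size Side length of the electrode grid (default 32,
#'   giving a 32 x 32 activation map).
#' @param internal_size Resolution the patch is resized to before the
#'   network; must equal `grid_size * 8`.
#' @param width Channel width multiplier applied to the 8-16-32-64
#'   backbone channels (the fixed 3-channel and 1-channel groups near
#'   the output are not scaled).  `width = 1` is the reference
#'   architecture; smaller values give cheaper variants for desk-scale
#'   experiments.
#' @param n_res_blocks Number of residual blocks in the middle of the
#'   network (reference architecture: 4).
#' @param binarize_threshold Threshold in (0, 1) applied to the sigmoid
#'   output; map elements are active where the sigmoid output is
#'   strictly greater than the threshold.
#' @return An object of class `spv_encoder_config`.
#' @export
encoder_config <- function(patch_size = 100L, grid_size = 32L,
                           internal_size = grid_size * 8L, width = 1,
                           n_res_blocks = 4L, binarize_threshold = 0.5) {
  patch_size <- as.integer(patch_size)
  grid_size <- as.integer(grid_size)
  internal_size <- as.integer(internal_size)
  if (patch_size < 8L) stop("`patch_size` must be at least 8 pixels")
  if (internal_size != grid_size * 8L) {
    stop("`internal_size` must equal grid_size * 2^3 = ", grid_size * 8L,
         " (three pooling stages); got ", internal_size)
  }
  if (binarize_threshold <= 0 || binarize_threshold >= 1) {
    stop("`binarize_threshold` must lie strictly inside (0, 1)")
  }
  if (n_res_blocks < 0L) stop("`n_res_blocks` must be >= 0")
  ch <- function(c) max(1L, as.integer(round(c * width)))
  structure(
    list(patch_size = patch_size, grid_size = grid_size,
         internal_size = internal_size, width = width,
         n_res_blocks = as.integer(n_res_blocks),
         binarize_threshold = binarize_threshold,
         channels = c(ch(8), ch(16), ch(32), ch(64))),
    class = "spv_encoder_config")
}

#' Initialize an encoder
#'
#' Builds the encoder network described by an [encoder_config()] and
#' initializes its weights (He-scaled Gaussian draws) from `rng_seed`.
#'
#' @param config An [encoder_config()].
#' @param rng_seed Integer seed; the same seed reproduces the same
#'   initial weights exactly.
#' @return An object of class `spv_encoder`.
#' @export
init_encoder <- function(config = encoder_config(), rng_seed = 1L) {
  if (!inherits(config, "spv_encoder_config")) {
    stop("`config` must be created by encoder_config()")
  }
  cc <- config$channels
  net <- with_seed(rng_seed, {
    n <- list()
    add <- function(n, group, ...) {
      for (l in list(...)) {
        l$group <- group
        n[[length(n) + 1L]] <- l
      }
      n
    }
    n <- add(n, 1L, nn_conv(3L, cc[1]), nn_bn(cc[1]), nn_lrelu())
    n <- add(n, 2L, nn_conv(cc[1], cc[2]), nn_bn(cc[2]), nn_lrelu())
    n <- add(n, 3L, nn_conv(cc[2], cc[3]), nn_bn(cc[3]), nn_lrelu(), nn_pool())
    n <- add(n, 4L, nn_conv(cc[3], cc[4]), nn_bn(cc[4]), nn_lrelu(), nn_pool())
    g <- 4L
    for (i in seq_len(config$n_res_blocks)) {
      g <- g + 1L
      n <- add(n, g, nn_res(cc[4]))
    }
    n <- add(n, g + 1L, nn_conv(cc[4], cc[3]), nn_bn(cc[3]), nn_lrelu(), nn_pool())
    n <- add(n, g + 2L, nn_conv(cc[3], cc[2]), nn_bn(cc[2]), nn_lrelu())
    n <- add(n, g + 3L, nn_conv(cc[2], cc[1]), nn_bn(cc[1]), nn_lrelu())
    n <- add(n, g + 4L, nn_conv(cc[1], 3L), nn_lrelu())
    n <- add(n, g + 5L, nn_conv(3L, 1L), nn_sigmoid())
    n
  })
  structure(list(config = config, net = net, rng_seed = rng_seed),
            class = "spv_encoder")
}

#' @export
print.spv_encoder <- function(x, ...) {
  cfg <- x$config
  cat("<spv_encoder> ", cfg$patch_size, "x", cfg$patch_size, " patch -> ",
      cfg$grid_size, "x", cfg$grid_size, " binary map (",
      n_layer_groups(x), " layer groups, ",
      format(length(spv_params(x)), big.mark = ","), " parameters)\n", sep = "")
  invisible(x)
}

#' Number of layer groups in an encoder
#'
#' Counts the layer groups (rows of the architecture table) of an
#' encoder: convolution groups and residual blocks each count once.
#'
#' @param encoder An `spv_encoder`.
#' @return Integer scalar.
#' @export
n_layer_groups <- function(encoder) {
  max(vapply(encoder$net, function(l) l$group, integer(1)))
}

#' Flat parameter vector of a model object
#'
#' Returns every trainable parameter of an encoder, backbone, or
#' recognition unit as one numeric vector, in a fixed order.  Useful for
#' checking that weights are (or are not) changed by an operation.
#'
#' @param object An `spv_encoder`, `spv_backbone`, `spv_blind_unit` or
#'   `spv_sighted_unit`.
#' @return Numeric vector.
#' @export
spv_params <- function(object) {
  UseMethod("spv_params")
}

#' @export
spv_params.spv_encoder <- function(object) net_param_vector(object$net)

# patch argument -> P x P x 3 array with validation
patch_pixels <- function(patch, patch_size) {
  px <- if (inherits(patch, "spv_patch")) patch$pixels else patch
  if (!is.array(px) || length(dim(px)) != 3L || dim(px)[3] != 3L) {
    stop("patch must be a P x P x 3 array (or an spv_patch)")
  }
  if (dim(px)[1] != patch_size || dim(px)[2] != patch_size) {
    stop("patch has shape ", dim(px)[1], "x", dim(px)[2],
         " but the encoder expects ", patch_size, "x", patch_size)
  }
  px
}

# patches (list of arrays) -> encoder input state at internal resolution
encoder_input_state <- function(encoder, patches) {
  cfg <- encoder$config
  res <- lapply(patches, function(p) {
    px <- patch_pixels(p, cfg$patch_size)
    (resize_img(px, cfg$internal_size, cfg$internal_size) - 0.5) / 0.5
  })
  stack_tensors(res)
}

new_activation_map <- function(soft, values, grid_size, threshold) {
  structure(list(values = values, soft_values = soft,
                 grid_size = grid_size, threshold = threshold),
            class = "spv_activation_map")
}

#' @export
print.spv_activation_map <- function(x, ...) {
  cat("<spv_activation_map> ", x$grid_size, "x", x$grid_size, ", ",
      sum(x$values), " active elements\n", sep = "")
  invisible(x)
}

# single-channel (B*g*g) x 1 tensor column -> list of g x g matrices
split_maps <- function(col, B, g) {
  lapply(seq_len(B), function(b) {
    rows <- ((b - 1) * g * g + 1):(b * g * g)
    matrix(col[rows], g, g, byrow = TRUE)
  })
}

#' Encode a viewing patch as a binary activation map
#'
#' Runs the encoder in evaluation mode: the patch is resized to the
#' internal resolution, passed through the network, and the sigmoid
#' output is thresholded (strictly greater than) at the configured
#' binarization threshold, mimicking a Heaviside step on the output
#' layer.  Both the binary values and the pre-threshold sigmoid outputs
#' are returned.
#'
#' @param encoder An [init_encoder()] result.
#' @param patch A `patch_size` x `patch_size` x 3 array with values in
#'   \[0, 1\], or an `spv_patch` from [extract_patch()].
#' @return An `spv_activation_map`: list with `values` (0/1 integer
#'   matrix), `soft_values` (sigmoid outputs), `grid_size`, `threshold`.
#' @export
encode <- function(encoder, patch) {
  st <- encoder_input_state(encoder, list(patch))
  f <- net_forward(encoder$net, st, training = FALSE)
  g <- encoder$config$grid_size
  soft <- matrix(f$st$x[, 1], g, g, byrow = TRUE)
  vals <- matrix(as.integer(soft > encoder$config$binarize_threshold), g, g)
  new_activation_map(soft, vals, g, encoder$config$binarize_threshold)
}

#' Encode with gradient support (straight-through binarization)
#'
#' Runs the encoder in training mode and retains the forward caches so
#' gradients of a downstream scalar can be propagated back through the
#' binarization to the encoder weights.  The forward values are the same
#' binary map as [encode()] produces; the backward pass treats the
#' thresholding as the identity on the sigmoid outputs (a
#' straight-through estimator), so gradients flow through the sigmoid
#' and the convolutional stack as if no thresholding had occurred.
#'
#' @inheritParams encode
#' @return An `spv_encoding`: the activation `map` plus the recorded
#'   forward pass, consumable by [encoding_backward()].  Note that
#'   training mode uses batch statistics in the normalization layers, so
#'   the map can differ slightly from the evaluation-mode [encode()]
#'   output; the evaluation-mode output itself is unaffected by calls to
#'   this function except for the running-statistics update.
#' @export
encode_for_training <- function(encoder, patch) {
  st <- encoder_input_state(encoder, list(patch))
  f <- net_forward(encoder$net, st, training = TRUE)
  g <- encoder$config$grid_size
  soft <- matrix(f$st$x[, 1], g, g, byrow = TRUE)
  vals <- matrix(as.integer(soft > encoder$config$binarize_threshold), g, g)
  structure(list(map = new_activation_map(soft, vals, g,
                                          encoder$config$binarize_threshold),
                 encoder = structure(list(config = encoder$config, net = f$net,
                                          rng_seed = encoder$rng_seed),
                                     class = "spv_encoder"),
                 fwd = f),
            class = "spv_encoding")
}

#' Backpropagate through a recorded encoding
#'
#' Given the gradient of some scalar loss with respect to the binary map
#' values, applies the straight-through rule (gradient passes unchanged
#' to the sigmoid outputs) and backpropagates through the encoder,
#' returning the parameter gradients.
#'
#' @param encoding An [encode_for_training()] result.
#' @param d_values Gradient with respect to the map values
#'   (`grid_size` x `grid_size` matrix).
#' @return List with `grads` (nested, parallel to the network) and
#'   `first_layer_grad_norm`, the Euclidean norm of the first
#'   convolution's weight gradient.
#' @export
encoding_backward <- function(encoding, d_values) {
  enc <- encoding$encoder
  g <- enc$config$grid_size
  # straight-through: d soft = d values, identically
  dy <- matrix(as.numeric(t(d_values)), ncol = 1)
  bk <- net_backward(enc$net, encoding$fwd, dy)
  list(grads = bk$grads,
       first_layer_grad_norm = sqrt(sum(bk$grads[[1]]$W^2)))
}
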