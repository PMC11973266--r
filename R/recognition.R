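# Recognition backbone and the blind / sighted units.
#
# The backbone is a staged residual classification network.  Splitting
# it at `split_index` yields a feature extractor (stages 1..k) and a
# classifier (stages k+1..n).  The sighted unit is a frozen copy of the
# feature extractor applied to background-free viewing patches; the
# blind unit is the full (trainable) backbone applied to phosphene
# frames.  A plugin registry allows alternative backbones (for example
# a large pretrained residual network split after its sixth unit) to be
# dropped in; the default is a compact 8-stage surrogate trained from
# scratch, which keeps the package self-contained.

#' Build the surrogate recognition backbone
#'
#' Constructs a compact 8-stage residual classification network:
#' stages 1-7 are convolution/residual stages (three of them downsample
#' by 2x2 max pooling) and stage 8 is global average pooling plus a
#' linear classification head.  The default `split_index` of 4 mirrors,
#' at surrogate scale, splitting a deep residual network after its
#' early feature-extraction units.
#'
#' @param n_classes Number of object classes of the classification head.
#' @param input_size Input image side length in pixels (the simulator
#'   frame size, so the blind and sighted paths see the same geometry).
#' @param base_channels Channel width of the first stage (later stages
#'   use 2x and 4x this width).
#' @param split_index Default stage at which [split_backbone()] and the
#'   blind/sighted units divide features from classification.
#' @param rng_seed Integer seed for weight initialization.
#' @return An object of class `spv_backbone`.
#' @export
build_backbone <- function(n_classes = 2L, input_size = 256L,
                           base_channels = 8L, split_index = 4L,
                           rng_seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("`n_classes` must be >= 2")
  b <- as.integer(base_channels)
  net <- with_seed(rng_seed, {
    layers <- list()
    stage <- integer(0)
    add <- function(s, ...) {
      for (l in list(...)) {
        layers[[length(layers) + 1L]] <<- l
        stage <<- c(stage, s)
      }
    }
    add(1L, nn_conv(3L, b), nn_bn(b), nn_lrelu())
    add(2L, nn_conv(b, 2L * b), nn_bn(2L * b), nn_lrelu(), nn_pool())
    add(3L, nn_res(2L * b))
    add(4L, nn_conv(2L * b, 4L * b), nn_bn(4L * b), nn_lrelu(), nn_pool())
    add(5L, nn_res(4L * b))
    add(6L, nn_conv(4L * b, 4L * b), nn_bn(4L * b), nn_lrelu(), nn_pool())
    add(7L, nn_res(4L * b))
    add(8L, nn_gap(), nn_linear(4L * b, n_classes))
    list(layers = layers, stage = stage)
  })
  structure(list(net = net$layers, stage = net$stage, n_stages = 8L,
                 n_classes = n_classes, input_size = as.integer(input_size),
                 base_channels = b, split_index = as.integer(split_index),
                 rng_seed = rng_seed),
            class = "spv_backbone")
}

#' @export
print.spv_backbone <- function(x, ...) {
  cat("<spv_backbone> ", x$n_stages, " stages, split at ", x$split_index,
      ", ", x$n_classes, " classes, input ", x$input_size, "x",
      x$input_size, "\n", sep = "")
  invisible(x)
}

#' @export
spv_params.spv_backbone <- function(object) net_param_vector(object$net)

# normalize an image (or frame replicated to 3 channels) into the
# backbone's expected input state
backbone_input_state <- function(imgs) {
  st <- stack_tensors(imgs)
  st$x <- (st$x - 0.5) / 0.5
  st
}

frame_to_rgb <- function(frame) {
  m <- unclass(frame)
  array(rep(m, 3L), c(dim(m), 3L))
}

#' Split a backbone into feature extractor and classifier
#'
#' Divides the backbone's stages at `split_index`: stages
#' `1..split_index` form the feature extractor and the remaining stages
#' the classifier.  Composing the two parts reproduces the full
#' backbone's output exactly.
#'
#' @param backbone An `spv_backbone`.
#' @param split_index Stage index in `1..(n_stages - 1)`.
#' @return A list with elements `feature_extractor` and `classifier`,
#'   each an `spv_backbone_part`.
#' @export
split_backbone <- function(backbone, split_index = backbone$split_index) {
  if (!inherits(backbone, "spv_backbone")) stop("`backbone` must be an spv_backbone")
  split_index <- as.integer(split_index)
  if (split_index < 1L || split_index >= backbone$n_stages) {
    stop("`split_index` must lie in 1..", backbone$n_stages - 1L)
  }
  feat <- backbone$stage <= split_index
  part <- function(keep, role) {
    structure(list(net = backbone$net[keep], stage = backbone$stage[keep],
                   role = role, n_classes = backbone$n_classes,
                   input_size = backbone$input_size),
              class = "spv_backbone_part")
  }
  list(feature_extractor = part(feat, "feature_extractor"),
       classifier = part(!feat, "classifier"))
}

#' Forward pass through a backbone or backbone part
#'
#' Evaluation-mode forward pass.  For a full backbone the result is the
#' matrix of logits; for a part it is the output of that part's layers
#' (a feature state for the feature extractor).
#'
#' @param object An `spv_backbone` or `spv_backbone_part`.
#' @param imgs A list of H x W x 3 arrays in \[0, 1\], or a feature
#'   state produced by a feature extractor.
#' @return For classifier-containing objects a B x n_classes logit
#'   matrix; otherwise a feature state (internal list).
#' @export
backbone_forward <- function(object, imgs) {
  st <- if (is.list(imgs) && !is.null(imgs$x)) imgs else backbone_input_state(imgs)
  f <- net_forward(object$net, st, training = FALSE)
  if (identical(object$role, "feature_extractor")) f$st else f$st$x
}

# feature state -> H x W x C array (FeatureMap)
state_to_feature_map <- function(st) {
  structure(tensor_to_img(st$x, st$H, st$W), class = "spv_feature_map")
}

#' Create the sighted unit
#'
#' The sighted unit is a frozen copy of the backbone's feature extractor
#' (stages `1..split_index`).  It processes background-free viewing
#' patches, resized to the backbone input size so that its feature maps
#' are shape-compatible with the blind unit's, and never receives
#' gradients.
#'
#' @param backbone A (typically pretrained) `spv_backbone`.
#' @param split_index Stage at which to split; defaults to the
#'   backbone's own.
#' @return An object of class `spv_sighted_unit`.
#' @export
sighted_unit <- function(backbone, split_index = backbone$split_index) {
  parts <- split_backbone(backbone, split_index)
  structure(list(net = parts$feature_extractor$net,
                 split_index = as.integer(split_index),
                 input_size = backbone$input_size),
            class = "spv_sighted_unit")
}

#' Create the blind unit
#'
#' The blind unit is the full backbone acting on phosphene frames: its
#' feature-extraction stages (`1..split_index`) are compared against the
#' sighted unit by the perceptual loss, and its classification stages
#' predict the object class from the simulated percept.  All of its
#' parameters are trainable.
#'
#' @inheritParams sighted_unit
#' @return An object of class `spv_blind_unit`.
#' @export
blind_unit <- function(backbone, split_index = backbone$split_index) {
  if (split_index < 1L || split_index >= backbone$n_stages) {
    stop("`split_index` must lie in 1..", backbone$n_stages - 1L)
  }
  backbone$split_index <- as.integer(split_index)
  structure(list(backbone = backbone, split_index = as.integer(split_index)),
            class = "spv_blind_unit")
}

#' @export
spv_params.spv_sighted_unit <- function(object) net_param_vector(object$net)

#' @export
spv_params.spv_blind_unit <- function(object) net_param_vector(object$backbone$net)

#' Sighted-unit features of a background-free patch
#'
#' Resizes the (background-removed) patch to the unit's input size,
#' normalizes it, and runs the frozen feature extractor in evaluation
#' mode.  Calling it twice on the same patch gives identical output;
#' no gradient path to the sighted weights exists.
#'
#' @param unit An [sighted_unit()].
#' @param patch An `spv_patch` with `background_removed = TRUE` (patches
#'   with background violate the unit's contract and raise an error).
#' @return An `spv_feature_map` (H x W x C array).
#' @export
sighted_features <- function(unit, patch) {
  if (!inherits(patch, "spv_patch") || !isTRUE(patch$background_removed)) {
    stop("the sighted unit only accepts background-removed patches; ",
         "use mask_background() first")
  }
  img <- resize_img(patch$pixels, unit$input_size, unit$input_size)
  st <- backbone_input_state(list(img))
  f <- net_forward(unit$net, st, training = FALSE)
  state_to_feature_map(f$st)
}

#' Blind-unit features of a phosphene frame
#'
#' Replicates the single-channel frame to the three channels the
#' backbone expects, normalizes it, and runs the (trainable) feature
#' extractor in evaluation mode.
#'
#' @param unit A [blind_unit()].
#' @param frame An `spv_frame` or a square numeric matrix in \[0, 1\]
#'   matching the backbone input size.
#' @return An `spv_feature_map` with the same shape as the sighted
#'   unit's output for a matched input size.
#' @export
blind_features <- function(unit, frame) {
  st <- blind_input_state(unit, list(frame))
  parts <- split_backbone(unit$backbone, unit$split_index)
  f <- net_forward(parts$feature_extractor$net, st, training = FALSE)
  state_to_feature_map(f$st)
}

blind_input_state <- function(unit, frames) {
  sz <- unit$backbone$input_size
  imgs <- lapply(frames, function(fr) {
    m <- unclass(fr)
    if (!is.matrix(m) || nrow(m) != sz || ncol(m) != sz) {
      stop("frame must be a ", sz, "x", sz, " matrix")
    }
    frame_to_rgb(m)
  })
  backbone_input_state(imgs)
}

#' Classify a phosphene frame
#'
#' Runs the full blind unit (feature extractor and classifier) on a
#' frame and returns softmax class probabilities.
#'
#' @inheritParams blind_features
#' @return Numeric vector of length `n_classes`; nonnegative, sums to 1.
#' @export
classify <- function(unit, frame) {
  st <- blind_input_state(unit, list(frame))
  f <- net_forward(unit$backbone$net, st, training = FALSE)
  drop(softmax(f$st$x))
}

softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Pretrain the surrogate backbone on labeled patches
#'
#' Trains the full backbone with cross-entropy on (typically
#' background-removed) viewing patches.  The trained backbone then
#' serves both as the frozen sighted reference and as the
#' initialization of the blind unit, playing the role a large
#' pretrained classification network plays at full scale.
#'
#' @param patches A tibble with list-column `patch_nobg` (or `patch`)
#'   of P x P x 3 arrays and integer column `label` (0-based classes).
#' @param backbone An `spv_backbone` to train.
#' @param epochs,batch_size,learning_rate Optimization parameters.
#' @param rng_seed Seed controlling shuffling.
#' @return The trained `spv_backbone`.
#' @export
pretrain_backbone <- function(patches, backbone, epochs = 3L,
                              batch_size = 16L, learning_rate = 1e-3,
                              rng_seed = 1L) {
  col <- if ("patch_nobg" %in% names(patches)) "patch_nobg" else "patch"
  imgs <- lapply(patches[[col]], function(p) {
    px <- if (inherits(p, "spv_patch")) p$pixels else p
    resize_img(px, backbone$input_size, backbone$input_size)
  })
  labels <- as.integer(patches$label) + 1L
  n <- length(imgs)
  opt <- adam_init(backbone$net)
  with_seed(rng_seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        ix <- ord[start:min(start + batch_size - 1L, n)]
        st <- backbone_input_state(imgs[ix])
        f <- net_forward(backbone$net, st, training = TRUE)
        backbone$net <- f$net
        ce <- softmax_ce(f$st$x, labels[ix], backbone$n_classes)
        bk <- net_backward(backbone$net, f, ce$dlogits)
        upd <- adam_step(backbone$net, bk$grads, opt, learning_rate)
        backbone$net <- upd$net
        opt <- upd$state
      }
    }
  })
  backbone
}

# mean cross-entropy over the batch + gradient wrt logits
softmax_ce <- function(logits, labels1, n_classes) {
  p <- softmax(logits)
  n <- nrow(logits)
  picked <- p[cbind(seq_len(n), labels1)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  onehot <- matrix(0, n, n_classes)
  onehot[cbind(seq_len(n), labels1)] <- 1
  list(loss = loss, dlogits = (p - onehot) / n)
}
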