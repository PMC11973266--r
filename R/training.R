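# End-to-end training: perceptual loss, weighted loss combination,
# gradient routing, and the training/evaluation loops.

#' Perceptual (feature-matching) loss
#'
#' Squared L2 norm of the difference between the sighted and blind
#' feature maps, normalized by the number of feature elements
#' (`W * H * C`): `sum((s - b)^2) / (W * H * C)`.  Zero iff the maps are
#' identical.
#'
#' @param feat_sighted,feat_blind Feature maps (`spv_feature_map` or
#'   plain arrays) of identical shape.
#' @return Nonnegative numeric scalar.
#' @export
perceptual_loss <- function(feat_sighted, feat_blind) {
  a <- unclass(feat_sighted)
  b <- unclass(feat_blind)
  if (!identical(dim(a), dim(b))) {
    stop("feature maps must have identical shapes; got ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  }
  sum((a - b)^2) / length(a)
}

#' Combined training loss
#'
#' Convex combination `gamma * L_P + (1 - gamma) * L_CE` of the
#' perceptual loss and the cross-entropy loss.  The default weighting
#' `gamma = 0.75` favors perceptual alignment three-to-one over
#' classification.
#'
#' @param L_P Perceptual loss term (finite numeric scalar).
#' @param L_CE Cross-entropy loss term.
#' @param gamma Weight in \[0, 1\].
#' @return Numeric scalar.
#' @export
combined_loss <- function(L_P, L_CE, gamma = 0.75) {
  if (!is.finite(L_P) || !is.finite(L_CE)) stop("loss terms must be finite")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma > 1) {
    stop("`gamma` must be a single value in [0, 1]")
  }
  gamma * L_P + (1 - gamma) * L_CE
}

#' Training configuration
#'
#' @param gamma Weight of the perceptual loss in the combined objective
#'   (default 0.75).
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Number of passes over the training set.
#' @param clip_norm Global gradient-norm clip applied separately to the
#'   encoder and blind-unit gradients each step (`Inf` disables);
#'   tempers the occasional large steps the straight-through estimator
#'   produces.
#' @param lr_decay Multiplicative per-epoch learning-rate decay (epoch
#'   `e` uses `learning_rate * lr_decay^(e - 1)`); annealing stabilizes
#'   the late epochs of short schedules.
#' @param rng_seed Seed controlling shuffling (and any fresh
#'   initialization performed by the caller).
#' @return An object of class `spv_loss_config`.
#' @export
loss_config <- function(gamma = 0.75, learning_rate = 2e-3, batch_size = 8L,
                        epochs = 5L, clip_norm = 5, lr_decay = 0.6,
                        rng_seed = 1L) {
  if (gamma < 0 || gamma > 1) stop("`gamma` must lie in [0, 1]")
  if (learning_rate <= 0) stop("`learning_rate` must be positive")
  if (lr_decay <= 0 || lr_decay > 1) stop("`lr_decay` must lie in (0, 1]")
  structure(list(gamma = gamma, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), clip_norm = clip_norm,
                 lr_decay = lr_decay, rng_seed = as.integer(rng_seed)),
            class = "spv_loss_config")
}

# ---- shared forward/backward core ------------------------------------
#
# One supervised step on a batch: encoder (training mode, straight-
# through binarization) -> simulator (fixed linear renderer) -> blind
# feature extractor -> [perceptual loss vs sighted features] -> blind
# classifier -> cross-entropy.  Gradient routing falls out of the graph:
# encoder and blind feature stages receive gamma * dL_P + (1 - gamma) *
# dL_CE, classifier stages receive only the (1 - gamma)-weighted
# cross-entropy gradient, and the sighted unit is outside the graph.

pipeline_batch <- function(encoder, blind, sim_config, enc_state,
                           sighted_feats, labels1, gamma, train = TRUE) {
  g <- encoder$config$grid_size
  B <- enc_state$B
  fenc <- net_forward(encoder$net, enc_state, training = train)
  encoder$net <- fenc$net
  soft <- fenc$st$x[, 1]
  binary <- as.numeric(soft > encoder$config$binarize_threshold)
  maps <- split_maps(binary, B, g)
  tpl <- sim_config$template * sim_config$brightness
  frames <- lapply(maps, function(m) pmin(kronecker(m, tpl), 1))
  bst <- blind_input_state(blind, frames)

  parts <- split_backbone(blind$backbone, blind$split_index)
  nfeat <- length(parts$feature_extractor$net)
  f1 <- net_forward(parts$feature_extractor$net, bst, training = train)
  f2 <- net_forward(parts$classifier$net, f1$st, training = train)
  blind$backbone$net <- c(f1$net, f2$net)

  ce <- softmax_ce(f2$st$x, labels1, blind$backbone$n_classes)
  nelem <- nrow(sighted_feats) / B * ncol(sighted_feats)
  diff <- f1$st$x - sighted_feats
  L_P <- sum(diff * diff) / (nelem * B)

  out <- list(encoder = encoder, blind = blind, L_P = L_P, L_CE = ce$loss,
              probs = softmax(f2$st$x))
  if (!train) return(out)

  bk2 <- net_backward(f2$net, f2, ce$dlogits * (1 - gamma))
  dfeat <- gamma * 2 * diff / (nelem * B) + bk2$dx
  bk1 <- net_backward(f1$net, f1, dfeat)

  # back through input normalization (scale 2) and channel replication
  dframe_col <- 2 * (bk1$dx[, 1] + bk1$dx[, 2] + bk1$dx[, 3])
  F <- sim_config$frame_size
  dsoft <- numeric(B * g * g)
  for (b in seq_len(B)) {
    rows <- ((b - 1) * F * F + 1):(b * F * F)
    dframe <- matrix(dframe_col[rows], F, F, byrow = TRUE)
    preclip <- kronecker(maps[[b]], tpl)
    dmap <- simulate_backward(dframe, (preclip <= 1) * 1, sim_config)
    dsoft[((b - 1) * g * g + 1):(b * g * g)] <- as.numeric(t(dmap))
  }
  # straight-through: d binary -> d soft unchanged
  bk0 <- net_backward(encoder$net, fenc, matrix(dsoft, ncol = 1))

  out$enc_grads <- bk0$grads
  out$blind_grads <- c(bk1$grads, bk2$grads)
  out
}

#' One end-to-end training step
#'
#' Performs one Adam step of the combined objective on a batch.  The
#' encoder and the blind unit's feature-extraction stages are updated
#' with gradients of `gamma * L_P + (1 - gamma) * L_CE`; the blind
#' classifier stages receive gradients of the cross-entropy term only;
#' the sighted unit receives none (it is outside the computation graph).
#'
#' @param encoder An `spv_encoder`.
#' @param blind A [blind_unit()].
#' @param sighted The frozen [sighted_unit()] providing reference
#'   features.
#' @param batch A tibble with list-columns `patch` (encoder input),
#'   `patch_nobg` (sighted input) and integer column `label` (0-based).
#' @param sim_config A [simulator_config()] whose frame size equals the
#'   backbone input size.
#' @param config A [loss_config()].
#' @param opt Optimizer state from a previous step, or `NULL` to start
#'   fresh.
#' @return List with updated `encoder`, `blind`, `opt`, and `record`,
#'   a one-row tibble (`L_P`, `L_CE`, `L`) satisfying
#'   `L = gamma * L_P + (1 - gamma) * L_CE`.
#' @export
train_step <- function(encoder, blind, sighted, batch,
                       sim_config = simulator_config(), config = loss_config(),
                       opt = NULL) {
  if (nrow(batch) == 0L) stop("`batch` must contain at least one example")
  enc_state <- encoder_input_state(encoder, batch$patch)
  sf <- precompute_sighted(sighted, batch$patch_nobg)
  labels1 <- as.integer(batch$label) + 1L
  if (is.null(opt)) {
    opt <- list(enc = adam_init(encoder$net), blind = adam_init(blind$backbone$net))
  }
  r <- pipeline_batch(encoder, blind, sim_config, enc_state, sf, labels1,
                      config$gamma, train = TRUE)
  ue <- adam_step(r$encoder$net, clip_grads(r$enc_grads, config$clip_norm),
                  opt$enc, config$learning_rate)
  ub <- adam_step(r$blind$backbone$net,
                  clip_grads(r$blind_grads, config$clip_norm), opt$blind,
                  config$learning_rate)
  r$encoder$net <- ue$net
  r$blind$backbone$net <- ub$net
  list(encoder = r$encoder, blind = r$blind,
       opt = list(enc = ue$state, blind = ub$state),
       record = tibble::tibble(
         L_P = r$L_P, L_CE = r$L_CE,
         L = combined_loss(r$L_P, r$L_CE, config$gamma)))
}

# sighted features for a list of background-removed patches, stacked in
# the blind feature layout ((B*Hf*Wf) x Cf)
precompute_sighted <- function(sighted, patches_nobg) {
  feats <- lapply(patches_nobg, function(p) {
    px <- if (inherits(p, "spv_patch")) {
      if (!isTRUE(p$background_removed)) {
        stop("sighted-unit inputs must be background-removed patches")
      }
      p$pixels
    } else p
    img <- resize_img(px, sighted$input_size, sighted$input_size)
    st <- backbone_input_state(list(img))
    net_forward(sighted$net, st, training = FALSE)$st$x
  })
  do.call(rbind, feats)
}

#' Train the full pipeline end to end
#'
#' Runs the complete optimization: for `config$epochs` epochs the
#' training patches are shuffled into minibatches and each minibatch
#' takes one combined-objective Adam step ([train_step()] semantics).
#' After every epoch the validation accuracy of the evaluation-mode
#' pipeline (encode, render, classify) is recorded, and the
#' best-validation encoder and blind unit are retained.  Training is
#' deterministic for a fixed `config$rng_seed` (single-threaded BLAS).
#'
#' @param data A list with tibbles `train` and `val` as produced by
#'   [build_patch_dataset()] (columns `patch`, `patch_nobg`, `label`).
#' @param encoder An initialized `spv_encoder` (see [init_encoder()]).
#' @param backbone A (typically pretrained) `spv_backbone`; its frozen
#'   feature extractor becomes the sighted unit and a trainable copy
#'   becomes the blind unit.
#' @param sim_config A [simulator_config()]; its frame size must equal
#'   the backbone input size.
#' @param config A [loss_config()].
#' @param verbose Print one line per epoch.
#' @return An object of class `pointspv_fit`: list with the trained
#'   `encoder`, `blind`, `sighted`, `records` (one row per epoch:
#'   `epoch`, `L_P`, `L_CE`, `L`, `val_accuracy`), `best` (epoch and
#'   accuracy of the retained checkpoint) and the configurations.
#' @export
train_pointspv <- function(data, encoder, backbone,
                           sim_config = simulator_config(),
                           config = loss_config(), verbose = FALSE) {
  if (nrow(data$train) == 0L || nrow(data$val) == 0L) {
    stop("training and validation sets must both be nonempty")
  }
  if (sim_config$frame_size != backbone$input_size) {
    stop("simulator frame size (", sim_config$frame_size,
         ") must equal the backbone input size (", backbone$input_size, ")")
  }
  sighted <- sighted_unit(backbone)
  blind <- blind_unit(backbone)
  g <- encoder$config$grid_size

  enc_state_all <- encoder_input_state(encoder, data$train$patch)
  # per-sample encoder input tensors (rows of the stacked state)
  n_tr <- nrow(data$train)
  isz <- encoder$config$internal_size
  row_of <- function(i) ((i - 1) * isz * isz + 1):(i * isz * isz)
  sighted_tr <- precompute_sighted(sighted, data$train$patch_nobg)
  nf_rows <- nrow(sighted_tr) / n_tr
  labels_tr <- as.integer(data$train$label) + 1L

  opt <- list(enc = adam_init(encoder$net), blind = adam_init(blind$backbone$net))
  records <- list()
  best <- list(val_accuracy = -Inf, epoch = 0L, encoder = encoder, blind = blind)

  with_seed(config$rng_seed, {
    for (ep in seq_len(config$epochs)) {
      lr_ep <- config$learning_rate * config$lr_decay^(ep - 1)
      ord <- sample.int(n_tr)
      lp_sum <- lce_sum <- 0
      nb <- 0L
      for (start in seq(1L, n_tr, by = config$batch_size)) {
        ix <- ord[start:min(start + config$batch_size - 1L, n_tr)]
        B <- length(ix)
        est <- new_state(enc_state_all$x[unlist(lapply(ix, row_of)), , drop = FALSE],
                         B, isz, isz)
        sf <- sighted_tr[unlist(lapply(ix, function(i)
          ((i - 1) * nf_rows + 1):(i * nf_rows))), , drop = FALSE]
        r <- pipeline_batch(encoder, blind, sim_config, est, sf,
                            labels_tr[ix], config$gamma, train = TRUE)
        if (!is.finite(r$L_P) || !is.finite(r$L_CE)) {
          stop("training diverged (non-finite loss) at epoch ", ep,
               "; reduce the learning rate")
        }
        ue <- adam_step(r$encoder$net,
                        clip_grads(r$enc_grads, config$clip_norm),
                        opt$enc, lr_ep)
        ub <- adam_step(r$blind$backbone$net,
                        clip_grads(r$blind_grads, config$clip_norm),
                        opt$blind, lr_ep)
        encoder <- r$encoder
        blind <- r$blind
        encoder$net <- ue$net
        blind$backbone$net <- ub$net
        opt <- list(enc = ue$state, blind = ub$state)
        lp_sum <- lp_sum + r$L_P
        lce_sum <- lce_sum + r$L_CE
        nb <- nb + 1L
      }
      acc <- evaluate_pipeline(encoder, blind, sim_config, data$val)
      records[[ep]] <- tibble::tibble(
        epoch = ep, L_P = lp_sum / nb, L_CE = lce_sum / nb,
        L = combined_loss(lp_sum / nb, lce_sum / nb, config$gamma),
        val_accuracy = acc)
      if (acc > best$val_accuracy) {
        best <- list(val_accuracy = acc, epoch = ep,
                     encoder = encoder, blind = blind)
      }
      if (verbose) {
        message(sprintf("epoch %d: L_P %.4f  L_CE %.4f  val acc %.3f",
                        ep, lp_sum / nb, lce_sum / nb, acc))
      }
    }
  })
  structure(list(encoder = best$encoder, blind = best$blind, sighted = sighted,
                 final_encoder = encoder, final_blind = blind,
                 records = if (length(records)) dplyr::bind_rows(records)
                           else tibble::tibble(epoch = integer(), L_P = numeric(),
                                               L_CE = numeric(), L = numeric(),
                                               val_accuracy = numeric()),
                 best = list(epoch = best$epoch,
                             val_accuracy = best$val_accuracy),
                 sim_config = sim_config, config = config),
            class = "pointspv_fit")
}

#' @export
print.pointspv_fit <- function(x, ...) {
  cat("<pointspv_fit> ", nrow(x$records), " epochs", sep = "")
  if (nrow(x$records)) {
    cat("; best val accuracy ", signif(x$best$val_accuracy, 3),
        " (epoch ", x$best$epoch, ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

# evaluation-mode accuracy of encode -> simulate -> classify
evaluate_pipeline <- function(encoder, blind, sim_config, patches) {
  correct <- 0L
  for (i in seq_len(nrow(patches))) {
    map <- encode(encoder, patches$patch[[i]])
    frame <- simulate_phosphenes(map, sim_config)
    p <- classify(blind, frame)
    if (which.max(p) - 1L == as.integer(patches$label[[i]])) correct <- correct + 1L
  }
  correct / nrow(patches)
}

#' Evaluate recognition accuracy of a trained pipeline
#'
#' Fraction of labeled patches whose phosphene rendering
#' (`simulate(encode(patch))`) is classified correctly (argmax) by the
#' blind unit, in evaluation mode.
#'
#' @param fit A `pointspv_fit`, or a list with elements `encoder`,
#'   `blind` and `sim_config`.
#' @param patches A tibble with list-column `patch` and column `label`.
#' @return Accuracy in \[0, 1\].
#' @export
evaluate_accuracy <- function(fit, patches) {
  if (nrow(patches) == 0L) stop("`patches` must be nonempty")
  evaluate_pipeline(fit$encoder, fit$blind, fit$sim_config, patches)
}
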