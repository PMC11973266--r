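# Point sampling: random viewing points inside an object's segmentation
# mask, fixed-size patch extraction, and background-masked counterparts.

#' Sample a random viewing point on the target object
#'
#' Draws a point uniformly over the foreground pixels of the scene's
#' segmentation mask, simulating a possible gaze location on the object.
#'
#' @param scene An `spv_scene` / segmented image (list with `image`,
#'   `mask`).
#' @param rng_seed Optional integer seed; if `NULL` the current RNG
#'   state is used (so repeated calls give fresh draws).
#' @return Named numeric vector `c(y, x)` in 0-based pixel coordinates;
#'   always a mask-foreground pixel.
#' @export
sample_viewing_point <- function(scene, rng_seed = NULL) {
  fg <- which(scene$mask == 1L)
  if (length(fg) == 0L) stop("cannot sample a viewing point: mask is empty")
  draw <- function() {
    i <- fg[sample.int(length(fg), 1L)]
    H <- nrow(scene$mask)
    c(y = as.numeric((i - 1L) %% H), x = as.numeric((i - 1L) %/% H))
  }
  if (is.null(rng_seed)) draw() else with_seed(rng_seed, draw())
}

#' Extract a fixed-size patch centered on a viewing point
#'
#' Crops the `patch_size` window whose center is the viewing point.  If
#' the point lies closer than half a patch to the image border, the
#' window is clamped (shifted) to lie fully inside the image, so every
#' patch contains only real pixels; the stored `center` remains the
#' sampled point, which is then off-center in the patch.
#'
#' @param scene An `spv_scene`.
#' @param pt Viewing point `c(y, x)` (0-based) from
#'   [sample_viewing_point()].
#' @param patch_size Patch side length in pixels (default 100); must not
#'   exceed either image dimension.
#' @return An `spv_patch`: list with `pixels` (`patch_size^2 x 3`
#'   array), `center`, `window` (0-based `c(top, left)`), `source_id`,
#'   `label`, `background_removed = FALSE`.
#' @export
extract_patch <- function(scene, pt, patch_size = 100L) {
  H <- nrow(scene$mask)
  W <- ncol(scene$mask)
  patch_size <- as.integer(patch_size)
  if (patch_size > min(H, W)) {
    stop("`patch_size` (", patch_size, ") exceeds the image size (",
         H, "x", W, ")")
  }
  y <- round(as.numeric(pt[["y"]]))
  x <- round(as.numeric(pt[["x"]]))
  if (y < 0 || y >= H || x < 0 || x >= W) stop("viewing point lies outside the image")
  top <- as.integer(min(max(y - patch_size %/% 2L, 0L), H - patch_size))
  left <- as.integer(min(max(x - patch_size %/% 2L, 0L), W - patch_size))
  pixels <- scene$image[(top + 1L):(top + patch_size),
                        (left + 1L):(left + patch_size), , drop = FALSE]
  structure(list(pixels = pixels, center = c(y = y, x = x),
                 window = c(top = top, left = left),
                 patch_size = patch_size,
                 source_id = scene$scene_id, label = scene$label,
                 background_removed = FALSE),
            class = "spv_patch")
}

#' @export
print.spv_patch <- function(x, ...) {
  cat("<spv_patch> ", x$patch_size, "x", x$patch_size, " from ",
      x$source_id %||% "?", " at (", x$center[["y"]], ",", x$center[["x"]],
      ")", if (isTRUE(x$background_removed)) ", background removed", "\n",
      sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove the background from a patch
#'
#' Sets every patch pixel outside the object's segmentation mask to 0
#' (black), leaving foreground pixels untouched.  Idempotent.  The
#' patch must originate from `scene` (matching `source_id`).
#'
#' @param patch An `spv_patch` from [extract_patch()].
#' @param scene The `spv_scene` the patch was extracted from.
#' @return The patch with background zeroed and
#'   `background_removed = TRUE`.
#' @export
mask_background <- function(patch, scene) {
  if (!identical(patch$source_id, scene$scene_id)) {
    stop("patch source_id (", patch$source_id, ") does not match scene (",
         scene$scene_id, ")")
  }
  P <- patch$patch_size
  top <- patch$window[["top"]]
  left <- patch$window[["left"]]
  sub <- scene$mask[(top + 1L):(top + P), (left + 1L):(left + P)]
  out <- patch
  bg <- sub == 0L
  for (c in 1:3) {
    ch <- out$pixels[, , c]
    ch[bg] <- 0
    out$pixels[, , c] <- ch
  }
  out$background_removed <- TRUE
  out
}

#' Build a train/validation patch dataset from segmented scenes
#'
#' Samples `points_per_object` viewing points per scene, extracts each
#' patch together with its background-masked twin, and splits the
#' result.  By default the split is performed at the source-image
#' level -- all patches of one scene land in the same split -- which
#' prevents near-duplicate leakage between training and validation; a
#' patch-level mode is available for the alternative protocol in which
#' patches of one object may go to either split.
#'
#' @param scenes List of `spv_scene` objects.
#' @param points_per_object Viewing points sampled per scene (>= 1).
#' @param split_fraction Fraction of units assigned to training,
#'   strictly between 0 and 1; both splits must end up nonempty.
#' @param patch_size Patch side length (default 100).
#' @param rng_seed Integer seed; fixed seed reproduces the split.
#' @param level `"image"` (default) or `"patch"` split granularity.
#' @return List with tibbles `train` and `val`; columns `patch_id`,
#'   `source_id`, `label`, `y`, `x`, `split` and list-columns `patch`
#'   (with background) and `patch_nobg`.
#' @export
build_patch_dataset <- function(scenes, points_per_object = 5L,
                                split_fraction = 0.8, patch_size = 100L,
                                rng_seed = 1L, level = c("image", "patch")) {
  level <- match.arg(level)
  if (points_per_object < 1L) stop("`points_per_object` must be >= 1")
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("`split_fraction` must lie strictly between 0 and 1")
  }
  with_seed(rng_seed, {
    rows <- list()
    for (sc in scenes) {
      for (k in seq_len(points_per_object)) {
        pt <- sample_viewing_point(sc)
        p <- extract_patch(sc, pt, patch_size)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          patch_id = sprintf("%s_p%02d", sc$scene_id, k),
          source_id = sc$scene_id, label = sc$label,
          y = pt[["y"]], x = pt[["x"]],
          patch = list(p), patch_nobg = list(mask_background(p, sc)))
      }
    }
    all <- dplyr::bind_rows(rows)
    if (level == "image") {
      ids <- unique(all$source_id)
      n_train <- round(split_fraction * length(ids))
      if (n_train < 1L || n_train >= length(ids)) {
        stop("too few scenes (", length(ids), ") for a nonempty ",
             "train/validation split at fraction ", split_fraction)
      }
      train_ids <- sample(ids, n_train)
      is_train <- all$source_id %in% train_ids
    } else {
      n_train <- round(split_fraction * nrow(all))
      if (n_train < 1L || n_train >= nrow(all)) {
        stop("too few patches (", nrow(all), ") for a nonempty split")
      }
      is_train <- seq_len(nrow(all)) %in% sample.int(nrow(all), n_train)
    }
    all$split <- ifelse(is_train, "train", "val")
    list(train = dplyr::filter(all, .data$split == "train"),
         val = dplyr::filter(all, .data$split == "val"))
  })
}
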