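# Synthetic two-class segmented scenes and gaze logs.
#
# Scenes stand in for photographs with per-object segmentation masks:
# one target object from one of K visually distinct classes is rendered
# on a filtered-noise background.  The default two classes differ in
# correlated global and local cues, the way animal categories do: class
# 0 is a roundish blob with protrusions and a spotted coat, class 1 an
# elongated ellipse with a striped coat.  Silhouettes alone separate
# the classes by coarse shape statistics, while the coat texture makes
# the class recoverable from a gaze-sized patch that sees only part of
# the object.  Coordinates are 0-based (y, x), origin top-left.

#' Generate one synthetic segmented scene
#'
#' Renders a single target object of the requested class on a textured
#' (or plain) background and returns the image together with its exact
#' binary segmentation mask.  Class 0 is a round blob with sinusoidal
#' protrusions and a spotted coat; class 1 is an elongated ellipse at a
#' random orientation with a striped coat (additional classes alternate
#' between the two families).  Object placement, size, orientation,
#' base color, coat phase and background texture are drawn from
#' `rng_seed`; the same seed yields a bit-identical scene.
#'
#' @param class_label Integer class in `0..(n_classes - 1)`.
#' @param size Integer vector `c(H, W)`, both at least 128.
#' @param rng_seed Integer seed.
#' @param n_classes Number of classes (default 2).
#' @param background `"texture"` (default) for filtered noise, or
#'   `"plain"` for a uniform light background (the ceiling-effect
#'   scenario with white backgrounds).
#' @param scene_id Identifier stored with the scene.
#' @return An `spv_scene`: list with `image` (H x W x 3 array in
#'   \[0, 1\]), `mask` (H x W 0/1 integer matrix, 1 = target object),
#'   `label`, `scene_id`.
#' @export
generate_scene <- function(class_label, size = c(256L, 256L), rng_seed = 1L,
                           n_classes = 2L, background = c("texture", "plain"),
                           scene_id = sprintf("scene_%03d_%d", rng_seed, class_label)) {
  background <- match.arg(background)
  if (length(size) != 2L || any(size < 128L)) {
    stop("`size` must be c(H, W) with both dimensions >= 128")
  }
  class_label <- as.integer(class_label)
  if (class_label < 0L || class_label >= n_classes) {
    stop("`class_label` must lie in 0..", n_classes - 1L)
  }
  H <- as.integer(size[1])
  W <- as.integer(size[2])
  with_seed(rng_seed, {
    img <- synth_background(H, W, background)
    shape <- synth_shape(class_label, H, W)
    col <- synth_object_color()
    # coat texture: spots for even classes, stripes for odd ones --
    # a patch-local cue correlated with the global silhouette family
    coat <- synth_coat(class_label, H, W, shape)
    speck <- matrix(runif(H * W, -0.03, 0.03), H, W)
    idx <- which(shape$mask == 1L)
    for (c in 1:3) {
      ch <- img[, , c]
      ch[idx] <- pmin(pmax(col[c] * coat[idx] + speck[idx], 0), 1)
      img[, , c] <- ch
    }
    structure(list(image = img, mask = shape$mask, label = class_label,
                   scene_id = scene_id),
              class = "spv_scene")
  })
}

# smooth noise texture: low-resolution uniform noise upsampled bilinearly
synth_background <- function(H, W, background) {
  img <- array(0, c(H, W, 3))
  if (background == "plain") {
    img[, , ] <- 0.92
    return(img)
  }
  base <- runif(1, 0.35, 0.6)
  for (c in 1:3) {
    coarse <- matrix(runif(ceiling(H / 16) * ceiling(W / 16), -0.12, 0.12),
                     ceiling(H / 16))
    fine <- matrix(runif(ceiling(H / 4) * ceiling(W / 4), -0.04, 0.04),
                   ceiling(H / 4))
    img[, , c] <- pmin(pmax(base + runif(1, -0.05, 0.05) +
                              cpp_resize_bilinear(coarse, H, W) +
                              cpp_resize_bilinear(fine, H, W), 0), 1)
  }
  img
}

# dark or saturated object color, well separated from the mid-gray texture
synth_object_color <- function() {
  hue <- runif(1)
  v <- runif(1, 0.55, 0.95)
  s <- runif(1, 0.5, 1)
  grDevices::col2rgb(grDevices::hsv(hue, s, v))[, 1] / 255
}

# multiplicative coat pattern in [0.35, 1.15]: spots (even classes) or
# stripes (odd classes), at a spatial period of roughly 20-30 px so the
# cue survives both patch cropping and downsampling
synth_coat <- function(class_label, H, W, shape) {
  ys <- matrix(0:(H - 1), H, W)
  xs <- matrix(0:(W - 1), H, W, byrow = TRUE)
  period <- runif(1, 20, 30)
  phase_y <- runif(1, 0, period)
  phase_x <- runif(1, 0, period)
  if (class_label %% 2L == 0L) {
    # quasi-regular spot lattice
    f <- 2 * pi / period
    spots <- sin(f * (ys + phase_y)) * sin(f * (xs + phase_x))
    pattern <- (spots > 0.25) * 1
  } else {
    # stripes perpendicular to the body axis
    ang <- shape$angle %||% runif(1, 0, pi)
    u <- (xs - shape$cx) * cos(ang) + (ys - shape$cy) * sin(ang)
    pattern <- (sin(2 * pi * u / period + phase_x) > 0) * 1
  }
  0.35 + 0.8 * pattern
}

# rasterize the class-specific silhouette; returns mask + placement
synth_shape <- function(class_label, H, W) {
  scale <- runif(1, 0.18, 0.26) * min(H, W)
  cy <- runif(1, 0.38, 0.62) * H
  cx <- runif(1, 0.38, 0.62) * W
  ys <- matrix(0:(H - 1), H, W)
  xs <- matrix(0:(W - 1), H, W, byrow = TRUE)
  dy <- ys - cy
  dx <- xs - cx
  if (class_label %% 2L == 0L) {
    # round blob with k protrusions: r(theta) = scale (1 + a cos(k theta + phi))
    k <- sample(5:8, 1)
    a <- runif(1, 0.15, 0.28)
    phi <- runif(1, 0, 2 * pi)
    theta <- atan2(dy, dx)
    r <- scale * (1 + a * cos(k * theta + phi))
    mask <- (dy^2 + dx^2 <= r^2)
  } else {
    # elongated ellipse, aspect ratio 2.5-4.5, random orientation
    ratio <- runif(1, 2.5, 4.5)
    ang <- runif(1, 0, pi)
    aa <- scale * sqrt(ratio)     # semi-major
    bb <- scale / sqrt(ratio)     # semi-minor
    u <- dx * cos(ang) + dy * sin(ang)
    v <- -dx * sin(ang) + dy * cos(ang)
    mask <- (u / aa)^2 + (v / bb)^2 <= 1
  }
  mask <- matrix(as.integer(mask), H, W)
  if (sum(mask) == 0L) mask[round(cy) + 1L, round(cx) + 1L] <- 1L
  list(mask = mask, cy = cy, cx = cx, scale = scale,
       angle = if (class_label %% 2L == 1L) ang else NULL)
}

#' Generate a balanced synthetic dataset
#'
#' Generates `n` scenes with class labels balanced to within one scene
#' per class and unique scene ids.  Scene-level seeds are derived
#' deterministically from `rng_seed`, so the id and content sequence is
#' reproducible.
#'
#' @param n Number of scenes (>= 1).
#' @param n_classes Number of classes `K`.
#' @param size `c(H, W)` passed to [generate_scene()].
#' @param rng_seed Integer seed.
#' @param background Passed to [generate_scene()].
#' @return List of `spv_scene` objects.
#' @export
generate_dataset <- function(n, n_classes = 2L, size = c(256L, 256L),
                             rng_seed = 1L, background = "texture") {
  if (n < 1L) stop("`n` must be at least 1")
  labels <- rep(0:(n_classes - 1L), length.out = n)
  seeds <- with_seed(rng_seed, sample.int(2^30, n))
  lapply(seq_len(n), function(i) {
    generate_scene(labels[i], size = size, rng_seed = seeds[i],
                   n_classes = n_classes, background = background,
                   scene_id = sprintf("scene_%04d", i))
  })
}

#' @export
print.spv_scene <- function(x, ...) {
  cat("<spv_scene> ", x$scene_id, ": ", nrow(x$mask), "x", ncol(x$mask),
      ", class ", x$label, ", ", sum(x$mask), " mask px\n", sep = "")
  invisible(x)
}

#' Generate a synthetic gaze log for a scene
#'
#' Emulates a plausible fixation sequence over a stimulus: fixation
#' centers are drawn mostly (probability 0.75) uniformly inside the
#' target mask's bounding box and otherwise uniformly over the image,
#' with fixation durations around 250 ms and brief saccade samples
#' between consecutive fixations.  The response time follows the last
#' sample.
#'
#' @param scene An `spv_scene` (or any list with a `mask` matrix and a
#'   `scene_id`).
#' @param n_fixations Number of fixation events (>= 0).
#' @param rng_seed Integer seed.
#' @param trial_id Identifier for the log.
#' @return An `spv_gaze_log`: list with `trial_id`, `samples` (tibble
#'   with `t_ms`, `x`, `y`, `event` in {"fixation", "saccade"}, strictly
#'   increasing `t_ms`) and `response_t` (ms, at or after the last
#'   sample).
#' @export
generate_gaze_log <- function(scene, n_fixations = 10L, rng_seed = 1L,
                              trial_id = paste0(scene$scene_id, "_trial")) {
  if (n_fixations < 0L) stop("`n_fixations` must be >= 0")
  H <- nrow(scene$mask)
  W <- ncol(scene$mask)
  bb <- mask_bbox(scene$mask)
  with_seed(rng_seed, {
    t <- 0
    rows <- list()
    prev <- NULL
    for (i in seq_len(n_fixations)) {
      if (runif(1) < 0.75) {
        y <- runif(1, bb$ymin, bb$ymax)
        x <- runif(1, bb$xmin, bb$xmax)
      } else {
        y <- runif(1, 0, H - 1)
        x <- runif(1, 0, W - 1)
      }
      if (!is.null(prev)) {
        # one mid-flight saccade sample between fixations
        t <- t + round(runif(1, 20, 40))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          t_ms = t, x = (prev[2] + x) / 2, y = (prev[1] + y) / 2,
          event = "saccade")
      }
      t <- t + round(runif(1, 180, 320))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        t_ms = t, x = x, y = y, event = "fixation")
      prev <- c(y, x)
    }
    samples <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(t_ms = numeric(), x = numeric(), y = numeric(),
                     event = character())
    structure(list(trial_id = trial_id, samples = samples,
                   response_t = (if (nrow(samples)) max(samples$t_ms) else 0) +
                     round(stats::runif(1, 300, 800))),
              class = "spv_gaze_log")
  })
}

mask_bbox <- function(mask) {
  idx <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask has no foreground pixels")
  list(ymin = min(idx[, 1]) - 1L, ymax = max(idx[, 1]) - 1L,
       xmin = min(idx[, 2]) - 1L, xmax = max(idx[, 2]) - 1L)
}

#' @export
print.spv_gaze_log <- function(x, ...) {
  cat("<spv_gaze_log> ", x$trial_id, ": ", nrow(x$samples), " samples (",
      sum(x$samples$event == "fixation"), " fixations), response at ",
      x$response_t, " ms\n", sep = "")
  invisible(x)
}
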