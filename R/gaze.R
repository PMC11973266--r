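# Offline gaze-contingent presentation: for each gaze location, crop a
# patch from the stimulus, process it with the encoder pipeline or the
# Canny baseline, and composite the result inside a circular aperture
# at the gaze location on an otherwise blank screen frame.

#' Gaze-contingent rendering configuration
#'
#' @param screen_size `c(H, W)` of the presentation screen in pixels
#'   (default 1080 x 1920).
#' @param patch_size Side of the patch cropped around the gaze point.
#' @param aperture_radius Radius (pixels) of the circular region in
#'   which the processed content is shown; defaults to half the patch
#'   size.  The aperture must fit on the screen.
#' @param method `"pointspv"` (encoder + simulator) or `"canny"`.
#' @param canny_low,canny_high Hysteresis thresholds on the 8-bit
#'   intensity scale (defaults 100 and 200, `low < high`).
#' @param canny_sigma Gaussian smoothing width (pixels) before edge
#'   detection.
#' @param canny_mode `"through_simulator"` (default): the edge map is
#'   max-pooled onto the electrode grid, binarized, and rendered by the
#'   phosphene simulator so both methods produce commensurable
#'   phosphene frames; `"raw_edges"`: the edge map itself is resized to
#'   the frame size.
#' @param blank_saccades Render blank frames for saccade samples
#'   (default `FALSE`: representations update during saccades too).
#' @param sim_config Simulator used to render either method's frames.
#' @return An object of class `spv_render_config`.
#' @export
render_config <- function(screen_size = c(1080L, 1920L), patch_size = 100L,
                          aperture_radius = patch_size / 2,
                          method = c("pointspv", "canny"),
                          canny_low = 100, canny_high = 200, canny_sigma = 1.0,
                          canny_mode = c("through_simulator", "raw_edges"),
                          blank_saccades = FALSE,
                          sim_config = simulator_config()) {
  method <- match.arg(method)
  canny_mode <- match.arg(canny_mode)
  if (canny_low >= canny_high) stop("`canny_low` must be smaller than `canny_high`")
  if (2 * aperture_radius > min(screen_size)) {
    stop("aperture does not fit on the screen")
  }
  structure(list(screen_size = as.integer(screen_size),
                 patch_size = as.integer(patch_size),
                 aperture_radius = aperture_radius, method = method,
                 canny_low = canny_low, canny_high = canny_high,
                 canny_sigma = canny_sigma, canny_mode = canny_mode,
                 blank_saccades = blank_saccades, sim_config = sim_config),
            class = "spv_render_config")
}

rgb_to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Canny edge-detection representation of a patch
#'
#' The conventional baseline: the patch is converted to grayscale and
#' edges are detected with the Canny algorithm (Gaussian smoothing,
#' Sobel gradients, non-maximum suppression, hysteresis thresholding at
#' `canny_low`/`canny_high` on the 8-bit scale).  In
#' `"through_simulator"` mode the edge map is max-pooled onto the
#' electrode grid, binarized, and rendered as phosphenes -- an
#' apples-to-apples comparison with the encoder pipeline; in
#' `"raw_edges"` mode the edge map itself is resized to the frame size.
#'
#' @param patch An `spv_patch` or P x P x 3 array (values in \[0, 1\]).
#' @param config An [render_config()].
#' @return An `spv_frame` of the simulator's frame size.
#' @export
canny_representation <- function(patch, config = render_config(method = "canny")) {
  px <- if (inherits(patch, "spv_patch")) patch$pixels else patch
  gray <- rgb_to_gray(px) * 255
  edges <- cpp_canny(gray, config$canny_low, config$canny_high,
                     config$canny_sigma)
  sim <- config$sim_config
  if (config$canny_mode == "through_simulator") {
    g <- sim$grid_size
    pooled <- block_max_pool(edges, g)
    map <- matrix(as.integer(pooled > 0), g, g)
    simulate_phosphenes(map, sim)
  } else {
    fr <- cpp_resize_bilinear(edges, sim$frame_size, sim$frame_size)
    structure(pmin(pmax(fr, 0), 1), class = c("spv_frame", "matrix"),
              config = sim)
  }
}

# adaptive block max pooling of an H x W matrix onto a g x g grid
block_max_pool <- function(m, g) {
  H <- nrow(m)
  W <- ncol(m)
  yb <- floor(seq_len(g + 1L) - 1L) * H / g
  xb <- floor(seq_len(g + 1L) - 1L) * W / g
  out <- matrix(0, g, g)
  for (r in seq_len(g)) {
    ys <- (floor(yb[r]) + 1L):floor(yb[r + 1L])
    for (c in seq_len(g)) {
      xs <- (floor(xb[c]) + 1L):floor(xb[c + 1L])
      out[r, c] <- max(m[ys, xs])
    }
  }
  out
}

#' Render one gaze-contingent screen frame
#'
#' Extracts the patch around the gaze location from the full-screen
#' stimulus (window clamped at the borders, as in [extract_patch()]),
#' processes it with the selected representation method, resizes the
#' result to the aperture's bounding box, masks it with the circular
#' aperture, and composites it at the gaze location on a black screen
#' frame.  Every pixel outside the aperture disk is 0.
#'
#' @param image Stimulus at screen resolution: H x W x 3 array or H x W
#'   grayscale matrix, values in \[0, 1\].
#' @param gaze Gaze location `c(y, x)` in 0-based screen coordinates;
#'   must be on screen.
#' @param encoder An `spv_encoder` (required for `method = "pointspv"`,
#'   ignored for `"canny"`).
#' @param config An [render_config()].
#' @return An `spv_screen_frame`: list with `pixels` (screen-size
#'   matrix), `gaze`, `method`, and optionally `t_ms`.
#' @export
render_frame <- function(image, gaze, encoder = NULL,
                         config = render_config()) {
  H <- config$screen_size[1]
  W <- config$screen_size[2]
  dims <- if (is.matrix(image)) dim(image) else dim(image)[1:2]
  if (dims[1] != H || dims[2] != W) {
    stop("stimulus must be at screen resolution ", H, "x", W)
  }
  gy <- as.numeric(gaze[[1]])
  gx <- as.numeric(gaze[[2]])
  if (gy < 0 || gy > H - 1 || gx < 0 || gx > W - 1) {
    stop("gaze location lies off screen")
  }
  img3 <- if (is.matrix(image)) array(rep(image, 3), c(dim(image), 3)) else image
  scene_like <- list(image = img3,
                     mask = matrix(1L, H, W),
                     scene_id = "screen", label = NA_integer_)
  patch <- extract_patch(scene_like, c(y = gy, x = gx), config$patch_size)
  frame <- switch(config$method,
    pointspv = {
      if (is.null(encoder)) stop("`encoder` is required for method = \"pointspv\"")
      simulate_phosphenes(encode(encoder, patch), config$sim_config)
    },
    canny = canny_representation(patch, config))

  r <- config$aperture_radius
  side <- as.integer(ceiling(2 * r))
  disk_img <- cpp_resize_bilinear(unclass(frame), side, side)
  # aperture mask over the bounding box (0-based coords, center at gaze)
  top <- round(gy - r)
  left <- round(gx - r)
  ys <- top:(top + side - 1L)
  xs <- left:(left + side - 1L)
  keep_y <- ys >= 0 & ys <= H - 1
  keep_x <- xs >= 0 & xs <= W - 1
  pix <- matrix(0, H, W)
  if (any(keep_y) && any(keep_x)) {
    suby <- ys[keep_y]
    subx <- xs[keep_x]
    dy2 <- (suby - gy)^2
    dx2 <- (subx - gx)^2
    disk <- outer(dy2, dx2, "+") <= r^2
    content <- disk_img[keep_y, keep_x, drop = FALSE] * disk
    pix[suby + 1L, subx + 1L] <- content
  }
  structure(list(pixels = pix, gaze = c(y = gy, x = gx),
                 method = config$method, t_ms = NA_real_),
            class = "spv_screen_frame")
}

#' @export
print.spv_screen_frame <- function(x, ...) {
  cat("<spv_screen_frame> ", nrow(x$pixels), "x", ncol(x$pixels),
      ", method ", x$method, ", gaze (", x$gaze[["y"]], ",",
      x$gaze[["x"]], ")\n", sep = "")
  invisible(x)
}

#' Replay a gaze log as a sequence of screen frames
#'
#' Renders one frame per gaze sample, in timestamp order.  Saccade
#' samples are rendered like fixations (representations update during
#' saccades too) unless `config$blank_saccades` is set, in which case
#' they produce blank frames.  Deterministic: replaying the same log
#' twice yields identical frame sequences.
#'
#' @param image Stimulus at screen resolution.
#' @param gaze_log An `spv_gaze_log` (or tibble with `t_ms`, `x`, `y`,
#'   `event`).
#' @param encoder Encoder for the `"pointspv"` method.
#' @param config An [render_config()].
#' @return List of `spv_screen_frame`s (empty for an empty log).
#' @export
simulate_session <- function(image, gaze_log, encoder = NULL,
                             config = render_config()) {
  samples <- if (inherits(gaze_log, "spv_gaze_log")) gaze_log$samples else gaze_log
  if (nrow(samples) == 0L) return(list())
  samples <- samples[order(samples$t_ms), ]
  lapply(seq_len(nrow(samples)), function(i) {
    if (isTRUE(config$blank_saccades) && samples$event[i] == "saccade") {
      fr <- structure(list(pixels = matrix(0, config$screen_size[1],
                                           config$screen_size[2]),
                           gaze = c(y = samples$y[i], x = samples$x[i]),
                           method = config$method, t_ms = samples$t_ms[i]),
                      class = "spv_screen_frame")
      return(fr)
    }
    fr <- render_frame(image, c(samples$y[i], samples$x[i]), encoder, config)
    fr$t_ms <- samples$t_ms[i]
    fr
  })
}
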