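# Phosphene simulator: fixed (non-trainable) renderer mapping each
# electrode of the grid to a preassigned frame location and drawing
# active electrodes as equally sized dot phosphenes.

#' Simulator configuration
#'
#' The simulated percept is a `frame_size` x `frame_size` grayscale
#' frame divided into `grid_size` x `grid_size` equal cells; electrode
#' (r, c) of the activation map is rendered, when active, as a dot
#' phosphene centered at pixel `((r + 0.5) s, (c + 0.5) s)` with
#' `s = frame_size / grid_size` (0-based coordinates, cell-centered
#' registration).  The dot profile is either an isotropic Gaussian
#' (peak 1 at the center, standard deviation `dot_sigma`) or a flat
#' disk; both are truncated to a radius of `s/2 - 1` pixels so each
#' phosphene stays strictly inside its own cell and phosphenes from
#' neighboring electrodes never touch.
#'
#' @param frame_size Output frame side length in pixels (default 256).
#' @param grid_size Electrode grid side length (default 32).
#' @param dot_profile `"gaussian"` (default) or `"disk"`.
#' @param dot_sigma Gaussian standard deviation in pixels; defaults to a
#'   quarter of the cell spacing.
#' @param brightness Peak brightness of one phosphene (default 1, the
#'   binary-activation assumption); frames are clipped to \[0, 1\].
#' @return An object of class `spv_simulator_config`.
#' @export
simulator_config <- function(frame_size = 256L, grid_size = 32L,
                             dot_profile = c("gaussian", "disk"),
                             dot_sigma = NULL, brightness = 1.0) {
  frame_size <- as.integer(frame_size)
  grid_size <- as.integer(grid_size)
  dot_profile <- match.arg(dot_profile)
  if (frame_size %% grid_size != 0L) {
    stop("`frame_size` must be divisible by `grid_size`")
  }
  s <- frame_size %/% grid_size
  if (s < 2L) stop("cell spacing must be at least 2 pixels")
  if (is.null(dot_sigma)) dot_sigma <- s / 4
  if (dot_sigma <= 0) stop("`dot_sigma` must be positive")
  if (brightness <= 0) stop("`brightness` must be positive")
  cfg <- structure(
    list(frame_size = frame_size, grid_size = grid_size,
         dot_profile = dot_profile, dot_sigma = dot_sigma,
         brightness = brightness, spacing = s),
    class = "spv_simulator_config")
  cfg$template <- dot_template(cfg)
  cfg
}

# s x s dot template; footprint truncated to radius s/2 - 1 so adjacent
# cells' dots are separated by at least one zero pixel.
dot_template <- function(cfg) {
  s <- cfg$spacing
  ctr <- s / 2                    # 0-based center within the cell
  d2 <- outer((0:(s - 1) - ctr)^2, (0:(s - 1) - ctr)^2, "+")
  r_cut <- max(1, s / 2 - 1)
  tpl <- if (cfg$dot_profile == "gaussian") {
    exp(-d2 / (2 * cfg$dot_sigma^2))
  } else {
    matrix(1, s, s)
  }
  tpl[d2 > r_cut^2] <- 0
  tpl
}

#' Phosphene center coordinates
#'
#' @param config A [simulator_config()].
#' @return A tibble with one row per electrode: `row`, `col` (0-based
#'   grid indices) and `y`, `x` (0-based pixel coordinates of the dot
#'   center, `(row + 0.5) * spacing` etc.).
#' @export
phosphene_centers <- function(config = simulator_config()) {
  g <- config$grid_size
  s <- config$spacing
  grid <- expand.grid(col = 0:(g - 1), row = 0:(g - 1))[, c("row", "col")]
  tibble::tibble(row = grid$row, col = grid$col,
                 y = (grid$row + 0.5) * s, x = (grid$col + 0.5) * s)
}

map_matrix <- function(map, grid_size) {
  m <- if (inherits(map, "spv_activation_map")) map$values else map
  if (!is.matrix(m) || nrow(m) != grid_size || ncol(m) != grid_size) {
    stop("activation map must be a ", grid_size, "x", grid_size, " matrix")
  }
  if (!all(m %in% c(0, 1))) stop("activation map must be binary (0/1)")
  m
}

#' Render an activation map as a phosphene frame
#'
#' Deterministically renders each active electrode as a dot phosphene at
#' its preassigned frame location.  Rendering is a fixed linear operator
#' over the map followed by clipping to \[0, 1\]: the frame is the
#' Kronecker product of the map with the dot template times the
#' brightness.  An all-zero map yields an all-zero frame.
#'
#' @param map An `spv_activation_map` or a binary `grid_size` x
#'   `grid_size` matrix.
#' @param config A [simulator_config()] whose `grid_size` matches the map.
#' @return An `spv_frame`: a `frame_size` x `frame_size` numeric matrix
#'   with values in \[0, 1\] and the configuration attached as an
#'   attribute.
#' @export
simulate_phosphenes <- function(map, config = simulator_config()) {
  m <- map_matrix(map, config$grid_size)
  frame <- pmin(kronecker(m, config$template * config$brightness), 1)
  structure(frame, class = c("spv_frame", "matrix"), config = config)
}

# adjoint of the (pre-clip) rendering operator: frame gradient -> map
# gradient.  `clip_mask` (0/1 matrix, optional) zeroes gradients where
# the forward clip saturated; with the default unit brightness the
# pre-clip frame never exceeds 1 and the mask is all ones.
simulate_backward <- function(dframe, clip_mask, config) {
  g <- config$grid_size
  s <- config$spacing
  if (!is.null(clip_mask)) dframe <- dframe * clip_mask
  arr <- array(dframe, c(s, g, s, g))                 # (iw, r, jw, c)
  m1 <- matrix(aperm(arr, c(1, 3, 2, 4)), nrow = s * s)
  matrix(colSums(m1 * as.vector(config$template * config$brightness)), g, g)
}

#' @export
print.spv_frame <- function(x, ...) {
  cat("<spv_frame> ", nrow(x), "x", ncol(x), ", mean intensity ",
      signif(mean(x), 3), "\n", sep = "")
  invisible(x)
}
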