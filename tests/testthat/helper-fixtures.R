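# Shared fixtures and independent oracles, all built in code.

# small-scale configurations used throughout the suite
tiny_encoder_config <- function(grid_size = 8L, width = 0.25, n_res = 1L) {
  encoder_config(patch_size = 64L, grid_size = grid_size, width = width,
                 n_res_blocks = n_res)
}

tiny_sim_config <- function(frame_size = 64L, grid_size = 8L) {
  simulator_config(frame_size = frame_size, grid_size = grid_size)
}

tiny_backbone <- function(n_classes = 2L, input_size = 64L, seed = 1L) {
  build_backbone(n_classes = n_classes, input_size = input_size,
                 base_channels = 4L, split_index = 4L, rng_seed = seed)
}

# a deterministic little patch dataset (shared, cached per session)
tiny_patch_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      scenes <- generate_dataset(10, n_classes = 2, size = c(128, 128),
                                 rng_seed = 42)
      cache <<- build_patch_dataset(scenes, points_per_object = 2,
                                    split_fraction = 0.8, patch_size = 64,
                                    rng_seed = 42)
    }
    cache
  }
})

random_patch <- function(P = 64L, seed = 1L) {
  withr::with_seed(seed, array(runif(P * P * 3), c(P, P, 3)))
}

# ---- independent oracles ---------------------------------------------

# second-moment elongation classifier over the mask (shape statistics)
moment_classify <- function(mask, threshold = 1.8) {
  idx <- which(mask == 1L, arr.ind = TRUE)
  e <- eigen(stats::cov(idx), symmetric = TRUE, only.values = TRUE)$values
  as.integer(sqrt(e[1] / max(e[2], 1e-12)) > threshold)
}

# brute-force double-loop perceptual loss
brute_perceptual <- function(a, b) {
  d <- dim(a)
  s <- 0
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      for (k in seq_len(d[3]))
        s <- s + (a[i, j, k] - b[i, j, k])^2
  s / prod(d)
}

# brute-force coverage: explicit per-pixel max over fixation kernels
brute_coverage <- function(fixations, H, W, sigma = 50) {
  total <- 0
  for (py in 0:(H - 1)) {
    for (px in 0:(W - 1)) {
      best <- 0
      for (i in seq_len(nrow(fixations))) {
        d2 <- (py - fixations[i, 1])^2 + (px - fixations[i, 2])^2
        best <- max(best, exp(-d2 / (2 * sigma^2)))
      }
      total <- total + best
    }
  }
  total / (H * W)
}

# connected components of a frame's nonzero pixels (8-connectivity),
# counted via igraph on the pixel adjacency graph
count_blobs <- function(frame) {
  m <- unclass(frame) > 0
  H <- nrow(m)
  W <- ncol(m)
  on <- which(m)
  if (length(on) == 0L) return(0L)
  id <- matrix(0L, H, W)
  id[on] <- seq_along(on)
  edges <- list()
  for (dy in c(0L, 1L)) {
    for (dx in c(-1L, 0L, 1L)) {
      if (dy == 0L && dx <= 0L) next
      ys <- seq_len(H - dy)
      xs <- seq_len(W)[(1 + max(0, -dx)):(W - max(0, dx))]
      a <- id[ys, xs, drop = FALSE]
      b <- id[ys + dy, xs + dx, drop = FALSE]
      keep <- a > 0 & b > 0
      if (any(keep)) edges[[length(edges) + 1L]] <- cbind(a[keep], b[keep])
    }
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, c(list(cbind(seq_along(on),
                                                               seq_along(on))),
                                                    edges)),
                                   directed = FALSE)
  as.integer(igraph::components(g)$no)
}

# brute-force clamped-window arithmetic for patch extraction
brute_window <- function(y, x, P, H, W) {
  top <- y - P %/% 2
  left <- x - P %/% 2
  c(top = as.integer(min(max(top, 0), H - P)),
    left = as.integer(min(max(left, 0), W - P)))
}

# brute-force disk rasterization: 0-based pixel coords within radius
brute_disk_count <- function(gy, gx, r, H, W) {
  n <- 0L
  for (py in 0:(H - 1))
    for (px in 0:(W - 1))
      if ((py - gy)^2 + (px - gx)^2 <= r^2) n <- n + 1L
  n
}
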