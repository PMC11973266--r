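# File interchange: PNG image/mask pairs with an index CSV, COCO-style
# JSON annotations (uncompressed RLE and polygons), gaze-log and
# trial-record CSVs, and checkpoint save/load.

#' Write scenes as PNG pairs with an index CSV
#'
#' Each scene is written as `<scene_id>.png` (RGB image) and
#' `<scene_id>_mask.png` (8-bit binary mask), plus one `index.csv` with
#' columns `scene_id`, `label`, `image`, `mask`.
#'
#' @param scenes List of `spv_scene` objects.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the index tibble.
#' @export
write_scenes <- function(scenes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- purrr::map_dfr(scenes, function(sc) {
    img_file <- paste0(sc$scene_id, ".png")
    mask_file <- paste0(sc$scene_id, "_mask.png")
    png::writePNG(sc$image, file.path(dir, img_file))
    png::writePNG(sc$mask + 0.0, file.path(dir, mask_file))
    tibble::tibble(scene_id = sc$scene_id, label = sc$label,
                   image = img_file, mask = mask_file)
  })
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(idx)
}

#' Read scenes written by [write_scenes()]
#'
#' @param dir Directory containing `index.csv` and the PNG pairs.
#' @return List of `spv_scene` objects.
#' @export
read_scenes <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "index.csv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(idx)), function(i) {
    img <- png::readPNG(file.path(dir, idx$image[i]))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
    mask <- png::readPNG(file.path(dir, idx$mask[i]))
    if (length(dim(mask)) == 3L) mask <- mask[, , 1]
    structure(list(image = img, mask = matrix(as.integer(mask > 0.5),
                                              nrow(mask), ncol(mask)),
                   label = as.integer(idx$label[i]),
                   scene_id = as.character(idx$scene_id[i])),
              class = "spv_scene")
  })
}

# ---- COCO-style annotations ------------------------------------------

# uncompressed RLE, column-major pixel order, starting with a run of 0s
mask_to_rle <- function(mask) {
  v <- as.integer(mask)                  # column-major
  r <- rle(v)
  counts <- r$lengths
  if (r$values[1] == 1L) counts <- c(0L, counts)
  list(size = c(nrow(mask), ncol(mask)), counts = as.integer(counts))
}

rle_to_mask <- function(rle_obj) {
  counts <- as.integer(unlist(rle_obj$counts))
  size <- as.integer(unlist(rle_obj$size))
  vals <- rep(rep(c(0L, 1L), length.out = length(counts)), counts)
  matrix(vals, size[1], size[2])
}

# even-odd scanline fill of a polygon given as flat c(x1,y1,x2,y2,...)
# in 0-based pixel coordinates
polygon_to_mask <- function(poly, H, W) {
  xs <- poly[seq(1, length(poly), by = 2)]
  ys <- poly[seq(2, length(poly), by = 2)]
  n <- length(xs)
  mask <- matrix(0L, H, W)
  for (row in 0:(H - 1)) {
    yc <- row
    crossings <- numeric(0)
    j <- n
    for (i in seq_len(n)) {
      if ((ys[i] > yc) != (ys[j] > yc)) {
        crossings <- c(crossings,
                       xs[i] + (yc - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i]))
      }
      j <- i
    }
    if (length(crossings) < 2) next
    crossings <- sort(crossings)
    for (k in seq(1, length(crossings) - 1, by = 2)) {
      lo <- max(0L, ceiling(crossings[k]))
      hi <- min(W - 1L, floor(crossings[k + 1]))
      if (lo <= hi) mask[row + 1L, (lo:hi) + 1L] <- 1L
    }
  }
  mask
}

#' Write COCO-style JSON annotations for scenes
#'
#' Emits a single JSON file with `images`, `annotations` (uncompressed
#' column-major RLE segmentations) and `categories`, alongside the PNG
#' images written by [write_scenes()].
#'
#' @param scenes List of `spv_scene` objects.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_coco_annotations <- function(scenes, path) {
  images <- purrr::imap(scenes, function(sc, i) {
    list(id = i, file_name = paste0(sc$scene_id, ".png"),
         height = nrow(sc$mask), width = ncol(sc$mask))
  })
  annotations <- purrr::imap(scenes, function(sc, i) {
    list(id = i, image_id = i, category_id = sc$label + 1L,
         segmentation = mask_to_rle(sc$mask), iscrowd = 1L,
         area = sum(sc$mask))
  })
  categories <- lapply(sort(unique(vapply(scenes, `[[`, integer(1), "label"))),
                       function(l) list(id = l + 1L, name = paste0("class_", l)))
  jsonlite::write_json(list(images = images, annotations = annotations,
                            categories = categories),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read COCO-style JSON annotations
#'
#' Supports uncompressed RLE segmentations (`counts` as an integer
#' array, column-major) and polygon segmentations (lists of flat
#' `x, y` rings filled with the even-odd rule).  Images are loaded from
#' `images_dir` when present; otherwise scenes carry only masks.
#'
#' @param path JSON annotation file.
#' @param images_dir Directory with the referenced images, or `NULL`.
#' @return List of `spv_scene` objects (labels are `category_id - 1`).
#' @export
read_coco_annotations <- function(path, images_dir = NULL) {
  doc <- jsonlite::read_json(path)
  imgs <- setNames(doc$images, vapply(doc$images, function(x)
    as.character(x$id), character(1)))
  lapply(doc$annotations, function(an) {
    info <- imgs[[as.character(an$image_id)]]
    H <- info$height
    W <- info$width
    seg <- an$segmentation
    mask <- if (!is.null(seg$counts)) {
      rle_to_mask(seg)
    } else {
      m <- matrix(0L, H, W)
      for (ring in seg) {
        pm <- polygon_to_mask(as.numeric(unlist(ring)), H, W)
        m <- (m + pm) %% 2L          # even-odd across rings
      }
      m
    }
    image <- if (!is.null(images_dir) &&
                 file.exists(file.path(images_dir, info$file_name))) {
      img <- png::readPNG(file.path(images_dir, info$file_name))
      if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
      img[, , 1:3, drop = FALSE]
    } else {
      array(0, c(H, W, 3))
    }
    structure(list(image = image, mask = mask,
                   label = as.integer(an$category_id) - 1L,
                   scene_id = tools::file_path_sans_ext(info$file_name)),
              class = "spv_scene")
  })
}

# ---- gaze logs and trial records -------------------------------------

#' Write gaze logs to CSV
#'
#' Long format with header `trial_id,t_ms,x,y,event`; the response time
#' is stored as a final `response` event row per trial.
#'
#' @param logs A single `spv_gaze_log` or a list of them.
#' @param path Output CSV path.
#' @return Invisibly, the written tibble.
#' @export
write_gaze_logs <- function(logs, path) {
  if (inherits(logs, "spv_gaze_log")) logs <- list(logs)
  out <- purrr::map_dfr(logs, function(lg) {
    dplyr::bind_rows(
      dplyr::mutate(lg$samples, trial_id = lg$trial_id, .before = 1),
      tibble::tibble(trial_id = lg$trial_id, t_ms = lg$response_t,
                     x = NA_real_, y = NA_real_, event = "response"))
  })
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Read gaze logs from CSV
#'
#' @param path CSV written by [write_gaze_logs()] (or with the same
#'   header).
#' @return List of `spv_gaze_log` objects.
#' @export
read_gaze_logs <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(d, d$trial_id), function(g) {
    g <- g[order(g$t_ms), ]
    resp <- g$event == "response"
    structure(list(trial_id = g$trial_id[1],
                   samples = tibble::as_tibble(
                     g[!resp, c("t_ms", "x", "y", "event")]),
                   response_t = if (any(resp)) max(g$t_ms[resp]) else NA_real_),
              class = "spv_gaze_log")
  })
}

#' Write and read trial records
#'
#' One row per trial; the fixation list is JSON-encoded into a single
#' column so the file stays a flat CSV.
#'
#' @param trials Trial tibble (see [block_metrics()]).
#' @param path CSV path.
#' @return `write_trials()`: invisibly, `path`; `read_trials()`: the
#'   trial tibble with a restored `fixations` list-column.
#' @export
write_trials <- function(trials, path) {
  flat <- trials
  if ("fixations" %in% names(flat)) {
    flat$fixations <- vapply(flat$fixations, function(f)
      as.character(jsonlite::toJSON(as.data.frame(f), digits = NA)),
      character(1))
  }
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if ("fixations" %in% names(d)) {
    d$fixations <- lapply(d$fixations, function(s)
      tibble::as_tibble(jsonlite::fromJSON(s)))
  }
  d
}

# ---- maps, frames, checkpoints ---------------------------------------

#' Write an activation map or frame to disk
#'
#' Maps are written as CSV (0/1 integers); frames as 8-bit grayscale
#' PNG (`round(255 * pixel)`).
#'
#' @param x An `spv_activation_map` or `spv_frame`.
#' @param path Output path (`.csv` for maps, `.png` for frames).
#' @return Invisibly, `path`.
#' @export
write_spv <- function(x, path) {
  if (inherits(x, "spv_activation_map")) {
    utils::write.table(x$values, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else if (inherits(x, "spv_frame") || inherits(x, "spv_screen_frame")) {
    m <- if (inherits(x, "spv_screen_frame")) x$pixels else unclass(x)
    png::writePNG(m, path)
  } else {
    stop("don't know how to write objects of class ", class(x)[1])
  }
  invisible(path)
}

#' Save or load a model checkpoint
#'
#' The model (encoder, backbone, blind unit, or full fit) is serialized
#' as an opaque binary alongside a small JSON sidecar recording the
#' class and, when available, configuration and seed.
#'
#' @param object Model object to save.
#' @param path Checkpoint path (the sidecar gets `.json` appended).
#' @return `save_checkpoint()`: invisibly, `path`;
#'   `load_checkpoint()`: the restored object.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  meta <- list(class = class(object)[1],
               rng_seed = object$rng_seed,
               saved = format(Sys.time(), tz = "UTC"))
  cfg <- object$config
  if (!is.null(cfg)) meta$config <- unclass(cfg)[!vapply(unclass(cfg), is.list, logical(1))]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
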