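# Backbone plugin registry: alternative recognition backbones can be
# registered by name (e.g. a wrapper around a large pretrained residual
# network split after its sixth unit) and retrieved by the training
# tools.  The built-in "surrogate" entry is the compact 8-stage network.

.backbone_registry <- new.env(parent = emptyenv())

#' Register or retrieve a backbone builder
#'
#' A builder is a function `(n_classes, input_size, rng_seed, ...)`
#' returning an `spv_backbone`.  The `"surrogate"` builder
#' ([build_backbone()]) is pre-registered.
#'
#' @param name Registry key.
#' @param builder Builder function (for `register_backbone`).
#' @param ... Arguments forwarded to the builder (for `get_backbone`).
#' @return `register_backbone()`: invisibly, `name`; `get_backbone()`:
#'   the built `spv_backbone`; `list_backbones()`: character vector of
#'   registered names.
#' @export
register_backbone <- function(name, builder) {
  stopifnot(is.character(name), is.function(builder))
  assign(name, builder, envir = .backbone_registry)
  invisible(name)
}

#' @rdname register_backbone
#' @export
get_backbone <- function(name, ...) {
  if (!exists(name, envir = .backbone_registry, inherits = FALSE)) {
    stop("no backbone registered under '", name, "'; see list_backbones()")
  }
  get(name, envir = .backbone_registry)(...)
}

#' @rdname register_backbone
#' @export
list_backbones <- function() sort(ls(.backbone_registry))

.onLoad <- function(libname, pkgname) {
  register_backbone("surrogate", build_backbone)
}
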