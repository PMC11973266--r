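# broom-style accessors for fitted pipelines.

#' Tidy the per-epoch training records
#'
#' @param x A `pointspv_fit`.
#' @param ... Ignored.
#' @return The records tibble: `epoch`, `L_P`, `L_CE`, `L`,
#'   `val_accuracy`.
#' @method tidy pointspv_fit
#' @export
tidy.pointspv_fit <- function(x, ...) x$records

#' One-row summary of a fitted pipeline
#'
#' @param x A `pointspv_fit`.
#' @param ... Ignored.
#' @return A one-row tibble: `epochs`, `best_epoch`, `best_val_accuracy`,
#'   `final_L_P`, `final_L_CE`, `final_L`, `gamma`, `n_params_encoder`,
#'   `n_params_blind`.
#' @method glance pointspv_fit
#' @export
glance.pointspv_fit <- function(x, ...) {
  r <- x$records
  last <- if (nrow(r)) r[nrow(r), ] else
    tibble::tibble(L_P = NA_real_, L_CE = NA_real_, L = NA_real_)
  tibble::tibble(
    epochs = nrow(r),
    best_epoch = x$best$epoch,
    best_val_accuracy = x$best$val_accuracy,
    final_L_P = last$L_P, final_L_CE = last$L_CE, final_L = last$L,
    gamma = x$config$gamma,
    n_params_encoder = length(spv_params(x$encoder)),
    n_params_blind = length(spv_params(x$blind)))
}
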