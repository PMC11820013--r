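#' Save a fitted model as a single-file checkpoint
#'
#' The checkpoint is one file holding every parameter array plus a JSON
#' configuration block (fusion mode, dimensions, seed, training history).
#' [load_camil()] refuses checkpoints whose arrays disagree with their
#' declared dimensions.
#'
#' @param model a fitted [camil()] model.
#' @param path file to write (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_camil <- function(model, path) {
  stopifnot(inherits(model, "camil"))
  obj <- list(format = "camil-checkpoint", version = 1L,
              config_json = jsonlite::toJSON(model$config, auto_unbox = TRUE,
                                             digits = NA),
              params = model$params[c("dim_in", "dim_model", "dim_hidden",
                                      "fusion", .trainable)],
              history = model$history, best_epoch = model$best_epoch,
              best_val_auc = model$best_val_auc, fitted = model$fitted,
              labels = model$labels)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_camil()].
#' @return A `camil` model object.
#' @export
load_camil <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "camil-checkpoint")) {
    stop("not a camil checkpoint: '", path, "'")
  }
  config <- jsonlite::fromJSON(obj$config_json)
  p <- obj$params
  C <- p$dim_model
  expect_dim <- list(W_enc = c(p$dim_in, C), b_enc = C,
                     W_A = c(C, C), b_A = C, W_B = c(C, C), b_B = C,
                     W_D = c(C, C), b_D = C, alpha = 1, beta = 1,
                     W_fuse = c(2L * C, C), b_fuse = C,
                     W_dec = c(C, C), b_dec = C,
                     V_pool = c(p$dim_hidden, C), w_pool = p$dim_hidden,
                     w_cls = C, b_cls = 1)
  for (nm in names(expect_dim)) {
    want <- expect_dim[[nm]]
    got <- if (is.matrix(p[[nm]])) dim(p[[nm]]) else length(p[[nm]])
    if (!identical(as.integer(got), as.integer(want))) {
      stop("checkpoint dimension mismatch for ", nm, ": stored ",
           paste(got, collapse = "x"), ", config implies ",
           paste(want, collapse = "x"))
    }
    if (!all(is.finite(p[[nm]]))) stop("non-finite parameters in ", nm)
  }
  if (!identical(p$fusion, config$fusion) ||
      !identical(as.integer(p$dim_model), as.integer(config$dim_model))) {
    stop("checkpoint config block disagrees with stored parameters")
  }
  class(p) <- "camil_params"
  structure(list(params = p, history = obj$history,
                 best_epoch = obj$best_epoch,
                 best_val_auc = obj$best_val_auc, config = config,
                 fitted = obj$fitted, labels = obj$labels,
                 call = quote(load_camil())),
            class = "camil")
}
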