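#' Cosine-annealed learning rate
#'
#' Learning rate for 1-based `epoch` of `epochs`, decaying from `lr0` at
#' the first epoch to 0 at the last along a half cosine (no restarts).
#'
#' @param epoch 1-based epoch index.
#' @param epochs total epoch budget.
#' @param lr0 initial learning rate.
#' @return numeric learning rate.
#' @export
cosine_lr <- function(epoch, epochs, lr0) {
  if (epochs <= 1L) return(lr0)
  lr0 * 0.5 * (1 + cos(pi * (epoch - 1) / (epochs - 1)))
}

#' Low-level training loop
#'
#' Trains a parameter set on bags with Adam (one bag per batch), cosine
#' annealing of the learning rate over the epoch budget, L2 weight decay,
#' and early stopping on validation AUC: training halts once `patience`
#' consecutive epochs bring no improvement, and the parameters from the
#' best-validation-AUC epoch are returned.
#'
#' Most users should call [camil()], which owns the validation split and
#' returns a full model object; this function is the engine underneath.
#'
#' @param bags training bags (at least one per class).
#' @param params initial [camil_params()].
#' @param val_bags validation bags used for the early-stopping monitor.
#' @param lr initial learning rate.
#' @param weight_decay L2 penalty coefficient folded into the gradients.
#' @param epochs epoch budget.
#' @param patience epochs without validation-AUC improvement before
#'   stopping.
#' @param seed seed for the epoch-wise bag shuffling.
#' @param verbose print per-epoch progress.
#' @return list with `params` (best epoch) and `history` (data.frame with
#'   epoch, lr, train_loss, val_auc).
#' @export
camil_train <- function(bags, params, val_bags, lr = 1e-4,
                        weight_decay = 1e-5, epochs = 50L, patience = 10L,
                        seed = 1L, verbose = FALSE) {
  ys <- vapply(bags, function(b) b$label, numeric(1))
  if (length(unique(ys)) < 2L) {
    stop("single-class training set: need at least one bag per class")
  }
  yv <- vapply(val_bags, function(b) b$label, numeric(1))
  if (length(unique(yv)) < 2L) {
    stop("validation set must contain both classes to monitor AUC")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  m <- lapply(.trainable, function(nm) params[[nm]] * 0)
  v <- m
  names(m) <- names(v) <- .trainable
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L

  best <- list(auc = -Inf, loss = Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     train_loss = numeric(), val_auc = numeric(),
                     val_loss = numeric())
  stale <- 0L
  for (ep in seq_len(epochs)) {
    lr_ep <- cosine_lr(ep, epochs, lr)
    ord <- sample.int(length(bags))
    loss_sum <- 0
    for (i in ord) {
      bag <- bags[[i]]
      fw <- camil_forward_cache(bag$X, params)
      loss <- bce_loss(fw$prob, bag$label)
      if (!is.finite(loss)) {
        stop("NaN/Inf loss at epoch ", ep, ", bag '", bag$slide_id,
             "' (prob=", fw$prob, "); aborting")
      }
      loss_sum <- loss_sum + loss
      g <- camil_backward(params, fw$cache, y = bag$label)$grads
      t <- t + 1L
      for (nm in .trainable) {
        gi <- g[[nm]] + weight_decay * params[[nm]]
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gi
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gi^2
        mhat <- m[[nm]] / (1 - b1^t)
        vhat <- v[[nm]] / (1 - b2^t)
        params[[nm]] <- params[[nm]] - lr_ep * mhat / (sqrt(vhat) + eps)
      }
    }
    probs <- vapply(val_bags,
                    function(b) camil_forward_cache(b$X, params)$prob,
                    numeric(1))
    vauc <- auc_score(yv, probs)
    vloss <- mean(mapply(bce_loss, probs, yv))
    hist <- rbind(hist, data.frame(epoch = ep, lr = lr_ep,
                                   train_loss = loss_sum / length(bags),
                                   val_auc = vauc, val_loss = vloss))
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  val AUC %.4f (loss %.4f)",
                      ep, lr_ep, loss_sum / length(bags), vauc, vloss))
    }
    ## monitor: AUC first, validation loss as the tie-break, so equally
    ## discriminative epochs still improve calibration
    if (vauc > best$auc || (vauc == best$auc && vloss < best$loss)) {
      best <- list(auc = vauc, loss = vloss, params = params, epoch = ep)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  list(params = best$params, history = hist, best_epoch = best$epoch,
       best_val_auc = best$auc)
}

#' Fit a cascaded-attention MIL classifier
#'
#' Fits the full network — input encoder, cascaded spatial/channel
#' attention block, decoder, attention pooling, sigmoid head — to a list
#' of labeled bags by bag-level binary cross-entropy. Optimization uses
#' Adam with one bag per batch, cosine-annealed learning rate, L2 weight
#' decay, and early stopping on validation AUC; the returned model holds
#' the parameters from the best validation epoch.
#'
#' When no `val_bags` are supplied, a stratified fraction of the training
#' bags is held out internally as the early-stopping monitor (those bags
#' do not contribute gradient updates).
#'
#' @param bags list of [mil_bag()] objects with both classes present.
#' @param fusion attention fusion mode, see [cascaded_block()]. The
#'   default cascade applies spatial attention first, then channel
#'   attention.
#' @param dim_model network width; `NULL` (default) means
#'   equal-dimensional encoding (width = input channel count).
#' @param dim_hidden attention-pooling scorer hidden width.
#' @param lr,weight_decay,epochs,patience optimizer settings; defaults are
#'   Adam at 1e-4, weight decay 1e-5, 50 epochs, patience 10.
#' @param val_bags optional explicit validation bags; otherwise
#'   `val_fraction` of `bags` is split off (stratified).
#' @param val_fraction fraction held out for early stopping when
#'   `val_bags` is `NULL`.
#' @param threshold decision threshold stored for [predict.camil()]'s
#'   class output and [summary.camil()].
#' @param seed one seed driving initialization, the validation split, and
#'   epoch shuffling.
#' @param verbose print per-epoch progress.
#' @return An object of class `camil`: list with `params`, `history`,
#'   `config`, `best_epoch`, `fitted` (training-bag probabilities),
#'   `labels`, `call`.
#' @examples
#' bags <- simulate_mil_bags(n_bags = 24, instances_per_bag = c(8, 15),
#'                           feature_dim = 16, signal_channels = 4,
#'                           effect_size = 3, seed = 1)
#' fit <- camil(bags, epochs = 3, seed = 1)
#' predict(fit, bags[[1]])
#' @export
camil <- function(bags, fusion = c("spatial_then_channel",
                                   "channel_then_spatial",
                                   "spatial_only", "channel_only",
                                   "parallel_concat"),
                  dim_model = NULL, dim_hidden = 128L,
                  lr = 1e-4, weight_decay = 1e-5, epochs = 50L,
                  patience = 10L, val_bags = NULL, val_fraction = 0.2,
                  threshold = 0.5, seed = 1L, verbose = FALSE) {
  fusion <- match.arg(fusion)
  stopifnot(length(bags) >= 2L, epochs >= 1L, lr > 0,
            threshold > 0, threshold < 1)
  lapply(bags, validate_bag)
  dim_in <- ncol(bags[[1]]$X)
  if (any(vapply(bags, function(b) ncol(b$X), integer(1)) != dim_in)) {
    stop("bags have mixed channel counts")
  }
  if (is.null(dim_model)) dim_model <- dim_in

  train_bags <- bags
  if (is.null(val_bags)) {
    ys <- vapply(bags, function(b) b$label, numeric(1))
    idx <- stratified_holdout(ys, val_fraction, seed = seed)
    val_bags <- bags[idx]
    train_bags <- bags[-idx]
  }
  params <- camil_params(dim_in, dim_model = dim_model,
                         dim_hidden = dim_hidden, fusion = fusion,
                         seed = seed)
  tr <- camil_train(train_bags, params, val_bags, lr = lr,
                    weight_decay = weight_decay, epochs = epochs,
                    patience = patience, seed = seed, verbose = verbose)
  fitted_probs <- vapply(bags,
                         function(b) camil_forward_cache(b$X, tr$params)$prob,
                         numeric(1))
  names(fitted_probs) <- vapply(bags, function(b) b$slide_id, character(1))
  structure(list(
    params = tr$params, history = tr$history, best_epoch = tr$best_epoch,
    best_val_auc = tr$best_val_auc,
    config = list(fusion = fusion, dim_in = dim_in, dim_model = dim_model,
                  dim_hidden = dim_hidden, lr = lr,
                  weight_decay = weight_decay, epochs = epochs,
                  patience = patience, val_fraction = val_fraction,
                  threshold = threshold, seed = seed),
    fitted = fitted_probs,
    labels = vapply(bags, function(b) b$label, numeric(1)),
    call = match.call()
  ), class = "camil")
}

## stratified holdout indices: round(frac * n) per class, at least 1
stratified_holdout <- function(ys, frac, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed) + 1L)
  idx <- integer(0)
  for (cl in unique(ys)) {
    pool <- which(ys == cl)
    k <- max(1L, round(frac * length(pool)))
    if (k >= length(pool)) {
      stop("validation fraction leaves no training bags for class ", cl)
    }
    idx <- c(idx, sample(pool, k))
  }
  sort(idx)
}

#' Predict bag probabilities from a fitted model
#'
#' @param object a fitted [camil()] model.
#' @param newdata a `mil_bag`, a list of them, or a bare instance matrix.
#' @param type `"prob"` (default), `"logit"`, `"class"` (thresholded at
#'   the model's stored threshold), or `"weights"` (per-instance attention
#'   pooling weights; list when `newdata` has several bags).
#' @param ... unused.
#' @return Numeric vector (or list for `type = "weights"`).
#' @export
predict.camil <- function(object, newdata, type = c("prob", "logit",
                                                    "class", "weights"),
                          ...) {
  type <- match.arg(type)
  single <- inherits(newdata, "mil_bag") || is.matrix(newdata)
  bag_list <- if (single) list(newdata) else newdata
  out <- lapply(bag_list, camil_forward, params = object$params)
  res <- switch(type,
    prob = vapply(out, `[[`, numeric(1), "prob"),
    logit = vapply(out, `[[`, numeric(1), "logit"),
    class = as.integer(vapply(out, `[[`, numeric(1), "prob") >=
                         object$config$threshold),
    weights = lapply(out, `[[`, "instance_weights")
  )
  if (type == "weights" && single) res <- res[[1]]
  res
}

#' @export
print.camil <- function(x, ...) {
  cat("Cascaded-attention MIL classifier\n")
  cat("  fusion: ", x$config$fusion, "   dims: ", x$config$dim_in, " -> ",
      x$config$dim_model, "\n", sep = "")
  cat("  trained ", nrow(x$history), " epochs (best epoch ", x$best_epoch,
      ", val AUC ", sprintf("%.3f", x$best_val_auc), ")\n", sep = "")
  cat("  gates: alpha = ", sprintf("%.4f", x$params$alpha), ", beta = ",
      sprintf("%.4f", x$params$beta), "\n", sep = "")
  invisible(x)
}

#' @export
summary.camil <- function(object, ...) {
  mets <- binary_metrics(object$labels, object$fitted,
                         threshold = object$config$threshold)
  mets["auc"] <- auc_score(object$labels, object$fitted)
  out <- list(model = object, training_metrics = mets)
  class(out) <- "summary.camil"
  out
}

#' @export
print.summary.camil <- function(x, ...) {
  print(x$model)
  cat("  training-set metrics (threshold ",
      x$model$config$threshold, "):\n", sep = "")
  m <- x$training_metrics
  cat("   ", paste(sprintf("%s %.3f", names(m), m), collapse = "  "), "\n")
  invisible(x)
}

#' @export
coef.camil <- function(object, ...) {
  object$params[.trainable]
}

#' @export
fitted.camil <- function(object, ...) object$fitted

#' @export
residuals.camil <- function(object, ...) object$labels - object$fitted

#' Plot training history
#'
#' Training loss and validation AUC per epoch, with the best (restored)
#' epoch marked.
#'
#' @param x a fitted [camil()] model.
#' @param ... passed to [plot.default()].
#' @export
plot.camil <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
       ylab = "training loss", main = "loss", ...)
  plot(h$epoch, h$val_auc, type = "l", xlab = "epoch",
       ylab = "validation AUC", main = "early-stop monitor", ...)
  graphics::abline(v = x$best_epoch, lty = 2, col = "grey40")
  invisible(x)
}
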