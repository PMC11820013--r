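#' Construct a bag of instance feature vectors
#'
#' A bag is one slide's worth of instances under the standard MIL
#' assumption: the bag label is 1 if and only if at least one instance is
#' positive, but only the bag label is observed by any model. Instances are
#' the rows of the feature matrix `X` (one patch each).
#'
#' Ground-truth instance labels, when known (synthetic data only), travel
#' with the bag but are deliberately kept out of the model-visible surface:
#' no fitting or prediction code reads them, and they are only reachable
#' through [instance_labels()].
#'
#' @param X numeric matrix, N instances x C channels. All entries finite.
#' @param label bag label, 0 or 1.
#' @param slide_id character scalar identifying the slide.
#' @param coords optional patch-record `data.frame` (see [tile_slide()])
#'   with one row per instance, giving each patch's level-0 pixel offsets.
#' @param instance_labels optional 0/1 vector of length N of ground-truth
#'   instance labels. Must be consistent with `label` under the MIL rule.
#'
#' @return An object of class `mil_bag`.
#' @seealso [validate_bag()], [mil_bag_label()], [simulate_mil_bags()]
#' @export
mil_bag <- function(X, label, slide_id = "slide", coords = NULL,
                    instance_labels = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  bag <- structure(
    list(slide_id = as.character(slide_id)[1], X = X, label = label,
         coords = coords),
    class = "mil_bag"
  )
  if (!is.null(instance_labels)) {
    attr(bag, "instance_labels") <- as.integer(instance_labels)
  }
  validate_bag(bag)
}

#' Ground-truth instance labels of a bag
#'
#' Accessor for the hidden per-instance labels carried by synthetic bags.
#' Returns `NULL` when the bag has none (the usual case for real slides,
#' where only the slide label is known).
#'
#' @param bag a `mil_bag`.
#' @return Integer 0/1 vector of length N, or `NULL`.
#' @export
instance_labels <- function(bag) {
  attr(bag, "instance_labels", exact = TRUE)
}

#' Validate a bag against the MIL invariants
#'
#' Checks that the feature matrix is non-empty and finite, the label is
#' binary, and — when ground-truth instance labels are present — that they
#' are consistent with the bag label under the MIL rule: a negative bag
#' contains no positive instance, a positive bag at least one.
#'
#' @param bag a `mil_bag`.
#' @return The bag, unchanged, if all invariants hold; otherwise an error.
#' @export
validate_bag <- function(bag) {
  if (!inherits(bag, "mil_bag")) stop("not a 'mil_bag' object")
  X <- bag$X
  if (!is.matrix(X) || nrow(X) < 1L || ncol(X) < 1L) {
    stop("empty bag: feature matrix must have at least one instance row")
  }
  if (!all(is.finite(X))) stop("non-finite features (NaN/Inf) in bag '",
                               bag$slide_id, "'")
  y <- bag$label
  if (length(y) != 1L || is.na(y) || !(y %in% c(0, 1))) {
    stop("bag label must be a single 0 or 1")
  }
  il <- instance_labels(bag)
  if (!is.null(il)) {
    if (length(il) != nrow(X)) {
      stop("instance_labels length does not match instance count")
    }
    if (anyNA(il) || !all(il %in% c(0L, 1L))) {
      stop("instance labels must be 0/1")
    }
    if (mil_bag_label(il) != y) {
      stop("MIL contradiction: bag label ", y,
           " inconsistent with instance labels (positive bag needs >= 1 ",
           "positive instance; negative bag needs none)")
    }
  }
  if (!is.null(bag$coords) && nrow(bag$coords) != nrow(X)) {
    stop("coords row count does not match instance count")
  }
  bag
}

#' Bag label implied by instance labels
#'
#' The MIL aggregation rule: a bag is positive iff at least one of its
#' instances is positive.
#'
#' @param labels 0/1 vector of instance labels, length >= 1.
#' @return 0 or 1.
#' @export
mil_bag_label <- function(labels) {
  if (length(labels) < 1L) stop("empty instance-label vector")
  as.integer(any(labels == 1))
}

#' Instance-score aggregation baselines
#'
#' `max_aggregate()` reduces instance scores to a bag score by taking the
#' maximum — the classical instance-level MIL aggregator. `mean_aggregate()`
#' takes the mean. Both serve as baselines against attention pooling.
#'
#' @param scores numeric vector of instance scores, length >= 1.
#' @return A single numeric bag score.
#' @export
max_aggregate <- function(scores) {
  if (length(scores) < 1L) stop("empty score vector")
  max(scores)
}

#' @rdname max_aggregate
#' @export
mean_aggregate <- function(scores) {
  if (length(scores) < 1L) stop("empty score vector")
  mean(scores)
}

#' @export
print.mil_bag <- function(x, ...) {
  cat("MIL bag '", x$slide_id, "': ", nrow(x$X), " instances x ",
      ncol(x$X), " channels, label ", x$label,
      if (!is.null(instance_labels(x))) " (ground-truth instance labels present)",
      "\n", sep = "")
  invisible(x)
}
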