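#' On-disk feature store for bags of patch features
#'
#' A feature store holds one group per slide — the N x C instance feature
#' matrix, the N x 2 patch coordinates, and the slide label and
#' magnification as attributes — plus a store-level channel count that is
#' enforced across slides. It is laid out as a directory of flat binary
#' float64 arrays with JSON metadata, so features round-trip bit-exactly:
#'
#' ```
#' store/
#'   store.json                 feature_dim, magnification, slide ids
#'   slides/<slide_id>/
#'     features.bin             N*C doubles, column-major
#'     meta.json                n_instances, label, magnification
#'     coords.csv               patch records (when the bag has them)
#'     instance_labels.json     ground-truth sidecar (synthetic bags only)
#' ```
#'
#' Ground-truth instance labels are written as a sidecar next to, but never
#' inside, the model-visible data; [read_feature_store()] only attaches
#' them when asked.
#'
#' @param bags list of [mil_bag()] objects sharing one channel count.
#' @param path directory to create (must not already contain a store unless
#'   `overwrite = TRUE`).
#' @param overwrite replace an existing store at `path`.
#' @return `path`, invisibly, with class `camil_feature_store`.
#' @export
write_feature_store <- function(bags, path, overwrite = FALSE) {
  if (length(bags) < 1L) stop("empty bag list")
  lapply(bags, validate_bag)
  dims <- vapply(bags, function(b) ncol(b$X), integer(1))
  if (length(unique(dims)) != 1L) {
    stop("mixed channel counts across bags: ",
         paste(unique(dims), collapse = ", "))
  }
  ids <- vapply(bags, function(b) b$slide_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate slide ids")
  bad <- grepl("[/\\\\]", ids)
  if (any(bad)) stop("slide ids must not contain path separators: ",
                     paste(ids[bad], collapse = ", "))
  if (dir.exists(file.path(path, "slides"))) {
    if (!overwrite) stop("feature store already exists at '", path, "'")
    unlink(file.path(path, "slides"), recursive = TRUE)
  }
  dir.create(file.path(path, "slides"), recursive = TRUE, showWarnings = FALSE)

  mags <- vapply(bags, function(b) {
    if (!is.null(b$coords) && "magnification" %in% names(b$coords)) {
      as.character(b$coords$magnification[1])
    } else "none"
  }, character(1))

  for (b in bags) {
    gdir <- file.path(path, "slides", b$slide_id)
    dir.create(gdir, showWarnings = FALSE)
    con <- file(file.path(gdir, "features.bin"), "wb")
    writeBin(as.vector(b$X), con, size = 8L, endian = "little")
    close(con)
    meta <- list(slide_id = b$slide_id, n_instances = nrow(b$X),
                 feature_dim = ncol(b$X), label = as.integer(b$label),
                 magnification = if (!is.null(b$coords) &&
                                     "magnification" %in% names(b$coords)) {
                   as.character(b$coords$magnification[1])
                 } else "none")
    jsonlite::write_json(meta, file.path(gdir, "meta.json"),
                         auto_unbox = TRUE)
    if (!is.null(b$coords)) {
      utils::write.csv(b$coords, file.path(gdir, "coords.csv"),
                       row.names = FALSE)
    }
    il <- instance_labels(b)
    if (!is.null(il)) {
      jsonlite::write_json(list(slide_id = b$slide_id,
                                instance_labels = il),
                           file.path(gdir, "instance_labels.json"),
                           auto_unbox = TRUE)
    }
  }
  root <- list(format = "camil-feature-store", version = 1L,
               feature_dim = dims[1],
               magnification = unique(mags),
               slide_ids = sort(ids))
  jsonlite::write_json(root, file.path(path, "store.json"),
                       auto_unbox = TRUE)
  invisible(structure(path, class = "camil_feature_store"))
}

#' Read bags back from a feature store
#'
#' Bags are returned in lexicographic slide-id order (deterministic
#' regardless of write order). Feature matrices are restored bit-exactly.
#'
#' @param path store directory written by [write_feature_store()].
#' @param slide_ids optional character vector restricting which slides to
#'   load; an unknown id is an error.
#' @param with_instance_labels attach the ground-truth sidecar (when
#'   present) to each returned bag. Off by default: the sidecar is test
#'   scaffolding, not model input.
#' @return list of `mil_bag` objects.
#' @export
read_feature_store <- function(path, slide_ids = NULL,
                               with_instance_labels = FALSE) {
  rootf <- file.path(path, "store.json")
  if (!file.exists(rootf)) stop("no feature store at '", path, "'")
  root <- jsonlite::read_json(rootf, simplifyVector = TRUE)
  ids <- sort(as.character(root$slide_ids))
  if (!is.null(slide_ids)) {
    unknown <- setdiff(slide_ids, ids)
    if (length(unknown)) stop("unknown slide id(s): ",
                              paste(unknown, collapse = ", "))
    ids <- sort(slide_ids)
  }
  C <- as.integer(root$feature_dim)
  lapply(ids, function(id) {
    gdir <- file.path(path, "slides", id)
    metaf <- file.path(gdir, "meta.json")
    if (!file.exists(metaf)) stop("missing group for slide '", id, "'")
    meta <- jsonlite::read_json(metaf, simplifyVector = TRUE)
    n <- as.integer(meta$n_instances)
    if (as.integer(meta$feature_dim) != C) {
      stop("slide '", id, "' feature_dim disagrees with store")
    }
    con <- file(file.path(gdir, "features.bin"), "rb")
    v <- readBin(con, "double", n = n * C, size = 8L, endian = "little")
    close(con)
    if (length(v) != n * C) stop("truncated features for slide '", id, "'")
    X <- matrix(v, nrow = n, ncol = C)
    coords <- NULL
    cf <- file.path(gdir, "coords.csv")
    if (file.exists(cf)) {
      coords <- utils::read.csv(cf, stringsAsFactors = FALSE)
      if (nrow(coords) != n) {
        stop("shape mismatch: coords rows != feature rows for slide '",
             id, "'")
      }
    }
    il <- NULL
    ilf <- file.path(gdir, "instance_labels.json")
    if (with_instance_labels && file.exists(ilf)) {
      il <- as.integer(jsonlite::read_json(ilf,
                                           simplifyVector = TRUE)$instance_labels)
    }
    mil_bag(X, label = as.integer(meta$label), slide_id = id,
            coords = coords, instance_labels = il)
  })
}
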