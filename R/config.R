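#' Load, validate, and dump a run configuration
#'
#' A run configuration is one YAML document wiring all pipeline stages:
#' a global `seed`, a `paths` block, and per-stage blocks (`simulate`,
#' `tiling`, `encoder`, `model`, `train`, `evaluate`, `heatmap`). Missing
#' fields take package defaults; `dump(parse(file))` is semantically
#' identical to the file.
#'
#' @param x path to a YAML file, or an already-parsed list.
#' @return Canonicalized config list of class `camil_config`.
#' @export
camil_config <- function(x = list()) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  defaults <- list(
    seed = 1L, log_level = "info",
    paths = list(store = "store", checkpoint = "model.rds",
                 metrics = "metrics.json", history = "history.csv",
                 heatmap_png = "heatmap.png", heatmap_csv = "heatmap.csv",
                 slide_image = NULL, manifest = "patches.csv"),
    simulate = list(n_bags = 200L, instances_per_bag = c(20L, 60L),
                    feature_dim = 512L, witness_rate = 0.1,
                    effect_size = 2, signal_channels = 8L,
                    positive_bag_fraction = 0.5),
    tiling = list(patch_size = 256L, magnifications = "20x",
                  min_tissue_fraction = 0.35, stride = NULL),
    encoder = list(name = "toy_histogram", output_dim = 512L,
                   normalize = FALSE),
    model = list(fusion = "spatial_then_channel", dim_model = NULL,
                 dim_hidden = 128L),
    train = list(lr = 1e-4, weight_decay = 1e-5, epochs = 50L,
                 patience = 10L, val_fraction = 0.2, threshold = 0.5,
                 test_fraction = 0.25, folds = 10L),
    evaluate = list(mode = "fixed"),
    heatmap = list(slide = NULL, downsample = 1L)
  )
  merged <- utils::modifyList(defaults, cfg, keep.null = TRUE)
  stopifnot(is.numeric(merged$seed),
            merged$train$lr > 0, merged$train$epochs >= 1,
            merged$train$threshold > 0, merged$train$threshold < 1,
            merged$train$folds >= 2)
  if (!merged$evaluate$mode %in% c("fixed", "cv")) {
    stop("evaluate$mode must be 'fixed' or 'cv'")
  }
  structure(merged, class = "camil_config")
}

#' @rdname camil_config
#' @param cfg a `camil_config`.
#' @param path YAML file to write.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

## cheap deterministic hash of a config (content fingerprint in manifests)
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        null = "null")
  v <- utf8ToInt(as.character(s))
  sprintf("%08x",
          as.integer(Reduce(function(h, c) (h * 31 + c) %% 2147483647,
                            v, 7)))
}

## per-stage seed derived from the global seed: one global seed fans out
## into a named substream per stage, all below 2^31
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1000003 +
                sum(utf8ToInt(stage)) * 2654435761) %% 2147483629)
}

camil_log <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet")) {
    message("[camil] ", ...)
  }
}

write_stage_manifest <- function(cfg, stage, inputs, outputs) {
  man <- list(stage = stage, seed = stage_seed(cfg$seed, stage),
              global_seed = cfg$seed, config_hash = config_hash(cfg),
              inputs = inputs, outputs = outputs)
  path <- paste0(outputs[[1]], ".manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  path
}

#' Run one pipeline stage
#'
#' Executes a stage of the slide-to-prediction pipeline against a run
#' configuration, writing the stage's artifacts and a manifest (inputs,
#' config hash, seed, outputs) that makes the run exactly reproducible.
#'
#' Stages: `"simulate"` (synthetic bags -> feature store),
#' `"preprocess"` (slide image -> filtered patch manifest),
#' `"featurize"` (manifest + image -> feature store),
#' `"train"` (store -> checkpoint + history), `"evaluate"` (checkpoint +
#' store -> metrics JSON; or cross-validation with `evaluate$mode:
#' "cv"`), `"heatmap"` (checkpoint + store -> activation PNG/CSV).
#'
#' @param stage stage name.
#' @param config a [camil_config()], a list, or a YAML path.
#' @return list of output paths, invisibly.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, c("simulate", "preprocess", "featurize",
                              "train", "evaluate", "heatmap"))
  cfg <- camil_config(config)
  p <- cfg$paths
  out <- switch(stage,
    simulate = {
      sc <- cfg$simulate
      bags <- simulate_mil_bags(
        n_bags = sc$n_bags, instances_per_bag = sc$instances_per_bag,
        feature_dim = sc$feature_dim, witness_rate = sc$witness_rate,
        effect_size = sc$effect_size, signal_channels = sc$signal_channels,
        positive_bag_fraction = sc$positive_bag_fraction,
        seed = stage_seed(cfg$seed, "simulate"))
      write_feature_store(bags, p$store, overwrite = TRUE)
      camil_log(cfg, "simulate: wrote ", length(bags), " bags to ", p$store)
      list(store = p$store)
    },
    preprocess = {
      if (is.null(p$slide_image)) stop("paths$slide_image not set")
      if (!file.exists(p$slide_image)) {
        stop("slide image not found: ", p$slide_image)
      }
      tc <- cfg$tiling
      tcfg <- tiling_config(patch_size = tc$patch_size,
                            magnifications = tc$magnifications,
                            min_tissue_fraction = tc$min_tissue_fraction,
                            stride = if (is.null(tc$stride)) tc$patch_size
                                     else tc$stride)
      img <- read_slide_image(p$slide_image)
      recs <- tile_slide(img, tcfg,
                         slide_id = tools::file_path_sans_ext(
                           basename(p$slide_image)))
      kept <- filter_patches(recs, tcfg$min_tissue_fraction)
      write_patch_manifest(kept, p$manifest)
      camil_log(cfg, "preprocess: ", nrow(kept), "/", nrow(recs),
                " patches kept")
      list(manifest = p$manifest)
    },
    featurize = {
      if (is.null(p$slide_image)) stop("paths$slide_image not set")
      recs <- read_patch_manifest(p$manifest)
      img <- read_slide_image(p$slide_image)
      spec <- encoder_spec(name = cfg$encoder$name,
                           output_dim = cfg$encoder$output_dim,
                           normalize = cfg$encoder$normalize)
      bags <- lapply(split(recs, recs$slide_id), function(r) {
        X <- encode_patches(extract_patches(img, r), spec)
        lab <- cfg$featurize$labels[[r$slide_id[1]]]
        mil_bag(X, label = if (is.null(lab)) 0L else lab,
                slide_id = r$slide_id[1], coords = r)
      })
      write_feature_store(unname(bags), p$store, overwrite = TRUE)
      camil_log(cfg, "featurize: ", length(bags), " slide(s) encoded")
      list(store = p$store)
    },
    train = {
      bags <- read_feature_store(p$store)
      tr <- cfg$train
      ys <- vapply(bags, function(b) b$label, numeric(1))
      test_idx <- integer(0)
      if (tr$test_fraction > 0) {
        test_idx <- stratified_holdout(ys, tr$test_fraction,
                                       seed = stage_seed(cfg$seed, "split"))
      }
      train_bags <- if (length(test_idx)) bags[-test_idx] else bags
      fit <- camil(train_bags, fusion = cfg$model$fusion,
                   dim_model = cfg$model$dim_model,
                   dim_hidden = cfg$model$dim_hidden, lr = tr$lr,
                   weight_decay = tr$weight_decay, epochs = tr$epochs,
                   patience = tr$patience, val_fraction = tr$val_fraction,
                   threshold = tr$threshold,
                   seed = stage_seed(cfg$seed, "train"))
      fit$config$test_slides <- vapply(bags[test_idx],
                                       function(b) b$slide_id, character(1))
      save_camil(fit, p$checkpoint)
      utils::write.csv(fit$history, p$history, row.names = FALSE)
      camil_log(cfg, "train: best epoch ", fit$best_epoch, ", val AUC ",
                sprintf("%.3f", fit$best_val_auc))
      list(checkpoint = p$checkpoint, history = p$history)
    },
    evaluate = {
      bags <- read_feature_store(p$store)
      tr <- cfg$train
      if (cfg$evaluate$mode == "cv") {
        cv <- cross_validate(bags, folds = tr$folds,
                             seed = stage_seed(cfg$seed, "cv"),
                             threshold = tr$threshold,
                             fusion = cfg$model$fusion,
                             dim_model = cfg$model$dim_model,
                             dim_hidden = cfg$model$dim_hidden,
                             lr = tr$lr, weight_decay = tr$weight_decay,
                             epochs = tr$epochs, patience = tr$patience,
                             val_fraction = tr$val_fraction)
        rep <- list(mode = "cv", folds = tr$folds,
                    mean = as.list(cv$mean), sd = as.list(cv$sd),
                    per_fold = cv$per_fold)
      } else {
        fit <- load_camil(p$checkpoint)
        ids <- fit$config$test_slides
        eval_bags <- if (length(ids)) {
          bags[vapply(bags, function(b) b$slide_id %in% ids, logical(1))]
        } else bags
        ys <- vapply(eval_bags, function(b) b$label, numeric(1))
        probs <- predict(fit, eval_bags)
        m <- binary_metrics(ys, probs, threshold = tr$threshold)
        rep <- list(mode = "fixed", n_bags = length(eval_bags),
                    metrics = c(as.list(m),
                                list(auc = auc_score(ys, probs))))
      }
      jsonlite::write_json(rep, p$metrics, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
      camil_log(cfg, "evaluate: wrote ", p$metrics)
      list(metrics = p$metrics)
    },
    heatmap = {
      fit <- load_camil(p$checkpoint)
      bags <- read_feature_store(p$store)
      id <- cfg$heatmap$slide
      if (is.null(id)) id <- bags[[1]]$slide_id
      bag <- bags[[match(id, vapply(bags, function(b) b$slide_id,
                                    character(1)))]]
      if (is.null(bag$coords)) {
        ## bags without slide geometry get synthetic grid coordinates
        n <- nrow(bag$X); ncols <- ceiling(sqrt(n))
        bag$coords <- data.frame(
          slide_id = bag$slide_id,
          x = ((seq_len(n) - 1L) %% ncols) * 16L,
          y = ((seq_len(n) - 1L) %/% ncols) * 16L,
          size = 16L, magnification = "20x",
          tissue_fraction = NA_real_)
      }
      dims <- c(max(bag$coords$x + bag$coords$size),
                max(bag$coords$y + bag$coords$size))
      map <- instance_activations(fit, bag)
      write_heatmap(map, dims, png_path = p$heatmap_png,
                    csv_path = p$heatmap_csv,
                    downsample = cfg$heatmap$downsample)
      camil_log(cfg, "heatmap: wrote ", p$heatmap_png)
      list(heatmap_png = p$heatmap_png, heatmap_csv = p$heatmap_csv)
    }
  )
  write_stage_manifest(cfg, stage, inputs = p[!vapply(p, is.null,
                                                      logical(1))],
                       outputs = out)
  invisible(out)
}
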