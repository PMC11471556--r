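#' Pipeline configuration
#'
#' Bundles every stage configuration of the end-to-end flow: synthetic
#' fixtures (or an input directory), hybrid enhancement, autoencoder
#' augmentation of the training partition, training of both architectures,
#' self-attention feature extraction on the test partition, concatenation
#' fusion, HLO feature selection and shallow-classifier evaluation. Stage
#' seeds are derived deterministically from the master seed, so stages can
#' be re-run independently yet reproducibly.
#'
#' Defaults are full study scale (1000 images per class after
#' augmentation, 100 training epochs, 100 HLO generations, full-width
#' models); tests and examples pass reduced values through the same
#' fields.
#'
#' @param out_dir artifact directory.
#' @param data_dir optional directory-per-class input tree; when `NULL`
#'   synthetic leaf fixtures are generated.
#' @param stages character vector of enabled stages, a subset of
#'   `c("fixtures", "enhance", "augment", "train", "extract", "fuse",
#'   "select", "classify")`, run in that order.
#' @param master_seed integer master seed.
#' @param fixture_classes,fixture_per_class,fixture_side,fixture_contrast
#'   synthetic fixture shape.
#' @param haze,bihe [haze_config()] / [bihe_config()].
#' @param augment an [augment_config()].
#' @param train a [train_config()].
#' @param input_side,width_scale model scale passed to the builders.
#' @param hlo an [hlo_config()].
#' @param presets classifier preset names to evaluate.
#' @param folds cross-validation folds for the classify stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("leafsight_run_"),
                            data_dir = NULL,
                            stages = c("fixtures", "enhance", "augment",
                                       "train", "extract", "fuse", "select",
                                       "classify"),
                            master_seed = 1L,
                            fixture_classes = 4L, fixture_per_class = 24L,
                            fixture_side = 64L, fixture_contrast = 0.3,
                            haze = haze_config(), bihe = bihe_config(),
                            augment = augment_config(),
                            train = train_config(),
                            input_side = 224L, width_scale = 1,
                            hlo = hlo_config(),
                            presets = c("SWNN", "MN2", "N3", "BiN2", "TiN2"),
                            folds = 10L) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(out_dir = out_dir, data_dir = data_dir, stages = stages,
                 master_seed = as.integer(master_seed),
                 fixture_classes = fixture_classes,
                 fixture_per_class = fixture_per_class,
                 fixture_side = fixture_side,
                 fixture_contrast = fixture_contrast,
                 haze = haze, bihe = bihe, augment = augment, train = train,
                 input_side = as.integer(input_side),
                 width_scale = width_scale, hlo = hlo, presets = presets,
                 folds = as.integer(folds)),
            class = "pipeline_config")
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order — fixtures, enhance, augment,
#' train (both architectures on the stratified 60:10:30 training split),
#' extract (self-attention features of the test partition from both
#' models), fuse, select, classify (every preset, before and after
#' selection) — writing each stage's artifacts and seed into a JSON
#' manifest under `cfg$out_dir`. Deterministic stages reproduce identical
#' artifact hashes under a fixed master seed. A stage failure aborts with
#' the stage name; completed artifacts persist.
#'
#' @param cfg a [pipeline_config()].
#' @return A list with `manifest` (per-stage records), `reports`
#'   (per-preset `eval_report`s pre/post selection, when the classify
#'   stage runs) and the principal in-memory artifacts.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  state <- new.env(parent = emptyenv())
  log_stage <- function(stage, seed, artifacts) {
    files <- artifacts[file.exists(artifacts)]
    manifest[[stage]] <<- list(
      stage = stage, seed = seed, artifacts = artifacts,
      md5 = if (length(files)) unname(tools::md5sum(files)) else character())
    manifest_path <- file.path(cfg$out_dir, "manifest.json")
    jsonlite::write_json(unname(manifest), manifest_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run_stage <- function(stage, fn) {
    if (!stage %in% cfg$stages) return(invisible(NULL))
    seed <- derive_seed(cfg$master_seed, stage)
    res <- tryCatch(fn(seed), error = function(e)
      stop("pipeline stage `", stage, "` failed: ", conditionMessage(e),
           call. = FALSE))
    log_stage(stage, seed, res)
    invisible(NULL)
  }

  run_stage("fixtures", function(seed) {
    if (is.null(cfg$data_dir)) {
      set <- make_leaf_images(cfg$fixture_classes, cfg$fixture_per_class,
                              cfg$fixture_side, cfg$fixture_contrast,
                              seed = seed)
      state$images <- set$images; state$labels <- set$labels
      state$classes <- set$classes
    } else {
      tree <- read_image_tree(cfg$data_dir)
      state$images <- tree$images; state$labels <- tree$labels
      state$classes <- tree$classes
    }
    p <- file.path(cfg$out_dir, "dataset.json")
    jsonlite::write_json(list(n = length(state$images),
                              classes = state$classes,
                              per_class = as.vector(table(state$labels))),
                         p, auto_unbox = TRUE, pretty = TRUE)
    p
  })

  run_stage("enhance", function(seed) {
    state$images <- lapply(state$images, enhance, haze_cfg = cfg$haze,
                           bihe_cfg = cfg$bihe)
    p <- file.path(cfg$out_dir, "enhanced_preview.png")
    write_image(state$images[[1]], p)
    p
  })

  # the stratified split precedes augmentation so generated variants of a
  # training image can never leak into validation or test
  split <- NULL
  if (!is.null(state$labels)) {
    split <- split_dataset(state$labels, train_config(
      split = cfg$train$split, seed = derive_seed(cfg$master_seed, "split")))
    state$split <- split
  }

  run_stage("augment", function(seed) {
    tr_lab <- state$labels[split$train]
    aug_images <- list(); aug_labels <- integer()
    for (k in sort(unique(tr_lab))) {
      idx <- split$train[state$labels[split$train] == k]
      ccfg <- cfg$augment
      ccfg$seed <- derive_seed(seed, paste0("class", k))
      gen <- generate_class(state$images[idx], ccfg)
      aug_images <- c(aug_images, gen$images)
      aug_labels <- c(aug_labels, rep(k, length(gen$images)))
    }
    state$train_images <- aug_images
    state$train_labels <- aug_labels
    p <- file.path(cfg$out_dir, "augmentation.json")
    jsonlite::write_json(list(per_class = as.vector(table(aug_labels))),
                         p, auto_unbox = TRUE)
    p
  })
  if (!"augment" %in% cfg$stages) {
    state$train_images <- state$images[split$train]
    state$train_labels <- state$labels[split$train]
  }

  run_stage("train", function(seed) {
    k <- length(unique(state$labels))
    paths <- character()
    for (arch in c("brwsa", "ibrwsa")) {
      builder <- if (arch == "brwsa") build_brwsa else build_ibrwsa
      g <- builder(k, input_side = cfg$input_side,
                   width_scale = cfg$width_scale)
      tcfg <- cfg$train
      tcfg$seed <- derive_seed(seed, arch)
      fit <- train_model(g, state$train_images, state$train_labels,
                         state$images[split$val], state$labels[split$val],
                         tcfg)
      state[[paste0("model_", arch)]] <- fit$model
      p <- file.path(cfg$out_dir, paste0("history_", arch, ".csv"))
      utils::write.csv(fit$history, p, row.names = FALSE)
      paths <- c(paths, p)
    }
    paths
  })

  run_stage("extract", function(seed) {
    te <- split$test
    paths <- character()
    for (arch in c("brwsa", "ibrwsa")) {
      f <- extract_features(state[[paste0("model_", arch)]],
                            state$images[te], state$labels[te])
      state[[paste0("features_", arch)]] <- f
      p <- file.path(cfg$out_dir, paste0("features_", arch, ".csv"))
      write_features_csv(f, p)
      paths <- c(paths, p)
    }
    paths
  })

  run_stage("fuse", function(seed) {
    state$fused <- fuse(state$features_brwsa, state$features_ibrwsa)
    p <- file.path(cfg$out_dir, "features_fused.csv")
    write_features_csv(state$fused, p)
    p
  })

  run_stage("select", function(seed) {
    hcfg <- cfg$hlo
    hcfg$seed <- seed
    state$selection <- select_features(state$fused, hcfg)
    pm <- file.path(cfg$out_dir, "mask.txt")
    writeLines(paste(state$selection$mask, collapse = " "), pm)
    pt <- file.path(cfg$out_dir, "selection_trace.csv")
    utils::write.csv(data.frame(generation = seq_along(state$selection$trace),
                                best_cost = state$selection$trace),
                     pt, row.names = FALSE)
    ps <- file.path(cfg$out_dir, "selected_columns.txt")
    writeLines(state$selection$reduced$tags, ps)
    c(pm, pt, ps)
  })

  run_stage("classify", function(seed) {
    reports <- list()
    paths <- character()
    for (preset in cfg$presets) {
      for (phase in c("fused", "selected")) {
        feats <- if (phase == "fused") state$fused
                 else state$selection$reduced
        if (is.null(feats)) next
        rp <- fit_predict_cv(feats, preset, folds = cfg$folds,
                             seed = derive_seed(seed, paste0(preset, phase)))
        reports[[paste(preset, phase, sep = "_")]] <- rp
        p <- file.path(cfg$out_dir,
                       sprintf("report_%s_%s.json", preset, phase))
        write_eval_report(rp, p)
        paths <- c(paths, p)
      }
    }
    state$reports <- reports
    paths
  })

  list(manifest = manifest, reports = state$reports %||% list(),
       split = state$split,
       selection = state$selection %||% NULL,
       fused = state$fused %||% NULL,
       out_dir = cfg$out_dir)
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; nested
#' blocks `haze`, `bihe`, `augment`, `train` and `hlo` override fields of
#' the corresponding stage configurations.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sub_cfgs <- c("haze", "bihe", "augment", "train", "hlo")
  args <- y[setdiff(names(y), sub_cfgs)]
  for (s in sub_cfgs) {
    if (!is.null(y[[s]])) {
      base <- switch(s, haze = haze_config, bihe = bihe_config,
                     augment = augment_config, train = train_config,
                     hlo = hlo_config)
      args[[s]] <- do.call(base, y[[s]])
    }
  }
  do.call(pipeline_config, args)
}
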