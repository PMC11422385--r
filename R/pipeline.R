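#' Default end-to-end pipeline configuration
#'
#' Desk-scale defaults for the simulate -> fuse -> train -> evaluate run.
#'
#' @return Named list; see [run_pipeline()] for the meaning of each field.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    stages = list(simulate = TRUE, segment = FALSE, fuse = TRUE,
                  train = TRUE, evaluate = TRUE),
    mode = "lesion_focused",            # or "baseline" (raw images)
    n_patients = 20L,
    images_per_patient = 2L,
    image_size = 128L,
    mix = c(GLAU = 0.2, AMD = 0.2, RVO = 0.2, DR = 0.2, NORM = 0.2),
    attention_channels = "default",
    fov_threshold = 10L,
    registry = "canonical",
    model = list(width_multiplier = 0.125, input_size = 64L, lr = 2e-3,
                 batch_size = 16L, max_epochs = 6L, patience = 2L),
    segmentation = list(class = "optic disc", width_multiplier = 0.0625,
                        input_size = 64L, max_epochs = 4L, patience = 2L),
    threshold_policy = "youden",        # youden | screening | hospital
    cache_dir = NULL,
    out_dir = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Returns every violation found (not only the first); an empty character
#' vector means the configuration is runnable.
#'
#' @param config named list (or path to a YAML/JSON file).
#' @return Character vector of issues.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  issues <- character(0)
  note <- function(msg) issues <<- c(issues, msg)
  if (is.null(config$seed) || !is.numeric(config$seed) || config$seed < 0) {
    note("seed must be a non-negative integer")
  }
  st <- config$stages
  if (is.null(st)) {
    note("stages block is missing")
    st <- list()
  }
  if (!is.null(config$mode) &&
      !config$mode %in% c("lesion_focused", "baseline")) {
    note("mode must be 'lesion_focused' or 'baseline'")
  }
  if (isTRUE(st$fuse) && is.null(config$registry)) {
    note("registry: fusion stage is enabled but no registry is configured")
  }
  if (isTRUE(st$train) && !isTRUE(st$simulate) &&
      is.null(config$cohort_dir)) {
    note("train stage needs either the simulate stage or a cohort_dir")
  }
  if (!is.null(config$mix) && abs(sum(config$mix) - 1) > 1e-6) {
    note("mix must sum to 1")
  }
  if (!is.null(config$n_patients) && config$n_patients < 10 &&
      isTRUE(st$train)) {
    note("n_patients must be >= 10 for a 7:1:2 patient split")
  }
  if (!is.null(config$threshold_policy) &&
      !config$threshold_policy %in% c("youden", "screening", "hospital")) {
    note("threshold_policy must be youden, screening or hospital")
  }
  wm <- config$model$width_multiplier
  if (!is.null(wm) && (wm <= 0 || wm > 1)) {
    note("model.width_multiplier must lie in (0, 1]")
  }
  issues
}

#' Read a pipeline configuration file
#' @param path YAML or JSON file.
#' @return Named list merged over [default_pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  out <- utils::modifyList(default_pipeline_config(), cfg)
  if (!is.null(out$mix)) out$mix <- unlist(out$mix)
  out
}

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(serialize(config, NULL, version = 2), tf)
  unname(tools::md5sum(tf))
}

#' Operating threshold under a screening/hospital policy
#'
#' `youden` maximizes J; `screening` picks the lowest threshold with
#' sensitivity >= 0.95 (catch more potential cases for referral);
#' `hospital` picks the highest threshold with specificity >= 0.95
#' (minimize misdiagnosis).
#'
#' @param roc a [compute_roc()] result.
#' @param policy one of `"youden"`, `"screening"`, `"hospital"`.
#' @return list with `threshold`, `sensitivity`, `specificity`.
#' @export
policy_threshold <- function(roc, policy = c("youden", "screening",
                                             "hospital")) {
  policy <- match.arg(policy)
  if (policy == "youden") {
    y <- select_optimal_threshold(roc)
    return(y[c("threshold", "sensitivity", "specificity")])
  }
  ok <- if (policy == "screening") roc$sensitivity >= 0.95
        else roc$specificity >= 0.95
  if (!any(ok)) ok <- rep(TRUE, length(roc$thresholds))
  pick <- if (policy == "screening") {
    cand <- which(ok)
    cand[which.max(roc$specificity[cand])]
  } else {
    cand <- which(ok)
    cand[which.max(roc$sensitivity[cand])]
  }
  list(threshold = roc$thresholds[pick],
       sensitivity = roc$sensitivity[pick],
       specificity = roc$specificity[pick])
}

#' Run the end-to-end desk-scale pipeline
#'
#' Executes the enabled stages in order - simulate (synthetic cohort),
#' segment (optional per-class segmentation demonstration), fuse
#' (lesion-focused compositing; skipped in baseline mode), train (diagnosis
#' classifier on a 7:1:2 patient split) and evaluate (test-set micro/macro
#' AUROC, per-disease Youden confusion matrices, median-split risk
#' stratification) - and returns a machine-readable report. Identical
#' config and seed give an identical report.
#'
#' @param config named list (see [default_pipeline_config()]) or a path to
#'   a YAML/JSON configuration.
#' @return list report: `config_hash`, `mode`, `seed`, and per-stage
#'   metrics. Written to `out_dir/report.json` when `out_dir` is set.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  issues <- validate_config(config)
  if (length(issues) > 0) {
    stop("invalid pipeline config:\n  - ", paste(issues, collapse = "\n  - "),
         call. = FALSE)
  }
  report <- list(config_hash = .config_hash(config), seed = config$seed,
                 mode = if (isTRUE(config$stages$fuse)) config$mode
                        else "baseline")
  cohort <- NULL
  if (isTRUE(config$stages$simulate)) {
    cohort <- generate_cohort(config$n_patients, config$mix,
                              config$images_per_patient, seed = config$seed,
                              size = config$image_size)
    report$simulate <- list(n_images = nrow(cohort$manifest),
                            n_patients = length(unique(
                              cohort$manifest$patient_id)),
                            class_counts = as.list(table(
                              cohort$manifest$disease)))
  } else if (!is.null(config$cohort_dir)) {
    stop("loading external cohorts requires stage inputs under cohort_dir; ",
         "not found: ", config$cohort_dir, call. = FALSE)
  }
  if (isTRUE(config$stages$segment)) {
    sg <- config$segmentation
    stats <- compute_normalization_stats(
      lapply(cohort$images, function(f) f$image))
    ch <- lookup_channels(canonical_registry(), sg$class)
    samples <- lapply(cohort$images, function(f) {
      list(x = normalize_image(f$image, stats, size = sg$input_size),
           target = resize_array(f$masks$planes[, , ch + 1L] * 1.0,
                                 sg$input_size, sg$input_size,
                                 method = "nearest"),
           patient_id = f$image$patient_id)
    })
    mdl <- build_retina_unet(seg_model_spec(sg$class, sg$width_multiplier,
                                            sg$input_size,
                                            seed = config$seed))
    tr <- train_segmentation(mdl, samples,
                             config = list(seed = config$seed, lr = 1e-3,
                                           batch_size = 8L,
                                           max_epochs = sg$max_epochs,
                                           patience = sg$patience))
    ious <- vapply(tr$split$val, function(i) {
      compute_iou(predict_mask(tr$model, samples[[i]]$x),
                  samples[[i]]$target)
    }, numeric(1))
    report$segment <- list(class = sg$class, val_iou = mean(ious),
                           epochs = nrow(tr$log))
  }
  images <- lapply(cohort$images, function(f) f$image)
  if (isTRUE(config$stages$fuse) && config$mode == "lesion_focused") {
    cache <- fusion_cache(config$cache_dir)
    channels <- select_attention_channels(canonical_registry(),
                                          config$attention_channels)
    images <- lapply(cohort$images, function(f) {
      lesion_focused_image(f$image, f$masks, channels,
                           config$fov_threshold, cache)
    })
    report$fuse <- c(list(n_channels = length(channels)), cache_stats(cache))
  }
  if (isTRUE(config$stages$train)) {
    md <- config$model
    spec <- classifier_spec(num_classes = length(config$mix),
                            width_multiplier = md$width_multiplier,
                            input_size = md$input_size, seed = config$seed)
    model <- build_classifier(spec)
    labels <- factor(cohort$manifest$disease, levels = names(config$mix))
    tr <- train_diagnosis(model, images, labels,
                          cohort$manifest$patient_id,
                          config = list(seed = config$seed, lr = md$lr,
                                        batch_size = md$batch_size,
                                        max_epochs = md$max_epochs,
                                        patience = md$patience))
    report$train <- list(epochs = nrow(tr$log),
                         best_val_loss = min(tr$log$val_loss))
    if (isTRUE(config$stages$evaluate)) {
      ix <- tr$split$test
      preds <- predict_proba(tr$model, images[ix], class_names = tr$classes)
      preds$true_label <- as.character(labels[ix])
      sc <- as.matrix(preds[, tr$classes, drop = FALSE])
      present <- intersect(tr$classes, unique(preds$true_label))
      mm <- if (length(present) >= 2) {
        micro_macro_auroc(sc, preds$true_label)
      } else list(micro = NA_real_, macro = NA_real_)
      per_disease <- list()
      for (cls in present) {
        y <- preds$true_label == cls
        if (length(unique(y)) < 2) next
        roc <- compute_roc(preds[[cls]], y)
        thr <- policy_threshold(roc, config$threshold_policy)
        pred_pos <- preds[[cls]] >= thr$threshold
        cm <- confusion_from_counts(sum(y), sum(pred_pos & y),
                                    sum(!y), sum(pred_pos & !y))
        per_disease[[cls]] <- list(auroc = roc$auc,
                                   threshold = thr$threshold,
                                   accuracy = cm$accuracy,
                                   sensitivity = cm$sensitivity,
                                   specificity = cm$specificity)
      }
      report$evaluate <- list(micro_auroc = mm$micro, macro_auroc = mm$macro,
                              threshold_policy = config$threshold_policy,
                              per_disease = per_disease)
      if (!is.null(config$out_dir)) {
        if (!dir.exists(config$out_dir)) dir.create(config$out_dir,
                                                    recursive = TRUE)
        write_predictions(preds,
                          file.path(config$out_dir, "predictions.csv"))
      }
    }
  }
  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir)) dir.create(config$out_dir,
                                                recursive = TRUE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
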