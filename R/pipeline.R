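#' Pipeline configuration
#'
#' One configuration object tying the stages together: simulation,
#' segmentation, rule-based calling, optional CNN training, and evaluation.
#' All randomness flows from one master seed, recorded in the run manifest.
#'
#' @param sim A \code{\link{sim_params}} object (or \code{NULL} to skip
#'   simulation and read images from \code{input_dir}).
#' @param segment A \code{\link{segment_params}} object.
#' @param call A \code{\link{call_params}} object.
#' @param model A \code{\link{cnn_config}} or \code{NULL} to skip the CNN
#'   path.
#' @param eval A \code{\link{split_spec}} object.
#' @param n_images Number of images to simulate.
#' @param ctc_prevalence CTC prevalence used by the simulator.
#' @param input_dir Directory of existing images (used when \code{sim} is
#'   \code{NULL}); must exist at run time.
#' @param output_dir Directory for all outputs.
#' @param seed Master seed; overrides the sub-config seeds.
#' @param log_level One of \code{"debug"}, \code{"info"}, \code{"warning"}.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = sim_params(), segment = segment_params(),
                            call = call_params(), model = NULL,
                            eval = split_spec(), n_images = 20,
                            ctc_prevalence = 0.049,
                            input_dir = NULL, output_dir = tempfile("ctcfish_run_"),
                            seed = 1L,
                            log_level = c("info", "debug", "warning")) {
  log_level <- match.arg(log_level)
  stopifnot(is.null(sim) || inherits(sim, "sim_params"),
            inherits(segment, "segment_params"),
            inherits(call, "call_params"),
            is.null(model) || inherits(model, "cnn_config"),
            inherits(eval, "split_spec"), n_images >= 1)
  structure(list(sim = sim, segment = segment, call = call, model = model,
                 eval = eval, n_images = as.integer(n_images),
                 ctc_prevalence = ctc_prevalence,
                 input_dir = input_dir, output_dir = output_dir,
                 seed = as.integer(seed), log_level = log_level),
            class = "pipeline_config")
}

pipe_log <- function(config, level, ...) {
  levels <- c(debug = 1, info = 2, warning = 3)
  if (levels[level] >= levels[config$log_level]) message("[", level, "] ", ...)
}

#' Run the full identification pipeline
#'
#' Executes simulate (or load) -> segment -> rule-based calling and,
#' when a model config is present, CNN training with stratified split,
#' majority down-sampling, and k-fold cross-validation. Writes images, the
#' crop manifest, the call table, evaluation reports, and a run-manifest
#' JSON recording the config hash, seeds, and per-stage row counts.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Invisibly, a run summary list (also serialized to
#'   \code{run_manifest.json} in the output directory).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  summary <- list(config_hash = simple_hash(unclass(config)),
                  seed = config$seed, counts = list())

  # stage 1: images
  if (!is.null(config$sim)) {
    pipe_log(config, "info", "simulating ", config$n_images, " images")
    sim <- config$sim
    sim$seed <- config$seed
    ds <- withCallingHandlers(
      generate_dataset(config$n_images, sim, config$ctc_prevalence,
                       dir = file.path(out_dir, "images")),
      error = function(e) stop("stage simulate failed: ", conditionMessage(e)))
    images <- ds$images
    truth <- ds$manifest
  } else {
    if (is.null(config$input_dir) || !dir.exists(config$input_dir))
      stop("stage load failed: input directory does not exist: ",
           config$input_dir %||% "<unset>")
    paths <- list.files(config$input_dir, pattern = "\\.png$", full.names = TRUE)
    if (length(paths) == 0)
      stop("stage load failed: no PNG images in ", config$input_dir)
    images <- lapply(sort(paths), read_image)
    mf <- file.path(config$input_dir, "manifest.csv")
    truth <- if (file.exists(mf)) utils::read.csv(mf, stringsAsFactors = FALSE) else NULL
  }
  summary$counts$images <- length(images)
  summary$counts$cells_rendered <- if (!is.null(truth)) nrow(truth) else NA

  # stage 2: segmentation
  crops <- tryCatch(
    unlist(lapply(images, segment_cells, params = config$segment),
           recursive = FALSE),
    error = function(e) stop("stage segment failed: ", conditionMessage(e)))
  crops <- crops %||% list()
  pipe_log(config, "info", length(crops), " crops segmented")
  summary$counts$crops <- length(crops)
  crop_manifest <- write_crops(crops, file.path(out_dir, "crops"))

  # stage 3: rule-based calls
  calls <- tryCatch(call_cells(crops, config$call),
                    error = function(e) stop("stage call failed: ",
                                             conditionMessage(e)))
  utils::write.csv(calls, file.path(out_dir, "calls.csv"), row.names = FALSE)
  summary$counts$calls <- nrow(calls)

  # match to ground truth when available
  if (!is.null(truth) && length(crops) > 0) {
    boxes <- do.call(rbind, lapply(crops, `[[`, "box"))
    m <- match_boxes_to_truth(boxes, truth)
    summary$segmentation_recall <- m$recall
    keep <- !is.na(m$box_label) & calls$label != "excluded"
    if (any(keep)) {
      rule_rep <- confusion_stats(calls$label[keep] == "CTC",
                                  m$box_label[keep] == "CTC")
      write_report(rule_rep, file.path(out_dir, "rule_report.json"))
      summary$rule_sensitivity <- rule_rep$sensitivity
      summary$rule_specificity <- rule_rep$specificity
      summary$rule_agreement <- mean((calls$label[keep] == "CTC") ==
                                     (m$box_label[keep] == "CTC"))
    }

    # stage 4: CNN path
    if (!is.null(config$model) && any(keep) &&
        length(unique(m$box_label[keep])) == 2) {
      cfg <- config$model
      cfg$seed <- config$seed
      labels <- m$box_label[keep]
      xcrops <- crops[keep]
      sp <- config$eval
      sp$seed <- config$seed
      split <- stratified_split(labels, sp)
      bal <- downsample_majority(labels[split$train], seed = config$seed,
                                 indices = split$train)
      x <- crops_to_tensor(xcrops, cfg)
      y <- as_binary_labels(labels)
      cv <- kfold_cv(bal, y[bal], sp$k_folds, config$seed,
                     train_fn = function(idx, yy) {
                       m0 <- build_model(cfg)
                       train_cnn(m0, x[, , , idx, drop = FALSE], yy)
                     },
                     predict_fn = function(fit, idx)
                       predict(fit, x[, , , idx, drop = FALSE]))
      final <- train_cnn(build_model(cfg), x[, , , bal, drop = FALSE], y[bal])
      test_scores <- predict(final, x[, , , split$test, drop = FALSE])
      test_rep <- confusion_stats(as.numeric(test_scores >= 0.5),
                                  y[split$test], scores = test_scores)
      write_report(test_rep, file.path(out_dir, "cnn_test_report.json"))
      write_report(cv$pooled, file.path(out_dir, "cnn_cv_report.json"))
      utils::write.csv(final$history, file.path(out_dir, "training_history.csv"),
                       row.names = FALSE)
      save_model(final, file.path(out_dir, "model.ckpt"))
      summary$cnn_cv_auc <- cv$pooled$auc
      summary$cnn_test_auc <- test_rep$auc
      summary$counts$train <- length(split$train)
      summary$counts$test <- length(split$test)
      summary$counts$train_balanced <- length(bal)
    }
  }

  jsonlite::write_json(summary, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
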