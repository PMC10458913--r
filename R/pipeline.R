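`%||%` <- function(a, b) if (is.null(a)) b else a

#' End-to-end pipeline configuration
#'
#' Resolves every stage of the beat-classification pipeline into one
#' object: data source, denoiser, rebalancing, network and training
#' settings, classifier head, ablation switches and a global seed from
#' which each stochastic stage derives its own.
#'
#' @param source Data source: `list(type = "synthetic", class_counts = ...,
#'   beat_length = ..., sampling_rate = ..., noise = noise_spec(...))` or
#'   `list(type = "file", path = ..., delimiter = ",")`. The default recipe
#'   draws 200 beats per class at 187 samples / 125 Hz under moderate
#'   contamination (Gaussian sigma 0.1, baseline wander 0.3 at 0.3 Hz,
#'   powerline 0.15 at 50 Hz, motion bursts rate 0.3 amplitude 0.4, 5%
#'   contact loss of 10 samples).
#' @param denoise A [denoise_config()].
#' @param rebalance List with optional `target_per_class` (default: the
#'   largest per-class count of the training partition) and optional
#'   `majority_subsample = list(class, n_keep)` applied first.
#' @param split List with `train_fraction` (default 0.8) and `stratified`
#'   (default `TRUE`).
#' @param model An [rdcnn_config()].
#' @param train A [train_config()] (its seed is overridden by the global
#'   seed).
#' @param svm List with `C`, `kernel`, `gamma` for [fit_ova_svm()].
#' @param enable_denoise,enable_rebalance Ablation switches (default both
#'   `TRUE`). With denoising disabled, lost samples are zero-filled so the
#'   network still receives finite input.
#' @param output_dir Optional directory for run artifacts (manifest,
#'   history, metrics, confusion matrix, model archive).
#' @param seed Global integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(source = NULL, denoise = denoise_config(),
                            rebalance = list(target_per_class = NULL,
                                             majority_subsample = NULL),
                            split = list(train_fraction = 0.8,
                                         stratified = TRUE),
                            model = rdcnn_config(), train = train_config(),
                            svm = list(C = 1, kernel = "linear", gamma = 1e-4),
                            enable_denoise = TRUE, enable_rebalance = TRUE,
                            output_dir = NULL, seed = 0) {
  if (is.null(source))
    source <- list(
      type = "synthetic",
      class_counts = stats::setNames(rep(200, 5), as.character(0:4)),
      beat_length = 187, sampling_rate = 125,
      noise = noise_spec(gaussian_sigma = 0.1, baseline_amplitude = 0.3,
                         baseline_freq = 0.3, powerline_amplitude = 0.15,
                         powerline_freq = 50, motion_burst_rate = 0.3,
                         motion_amplitude = 0.4, contact_loss_prob = 0.05,
                         gap_length = 10))
  stopifnot(source$type %in% c("synthetic", "file"),
            inherits(denoise, "denoise_config"),
            inherits(model, "rdcnn_config"),
            inherits(train, "train_config"))
  cfg <- list(source = source, denoise = denoise, rebalance = rebalance,
              split = split, model = model, train = train, svm = svm,
              enable_denoise = isTRUE(enable_denoise),
              enable_rebalance = isTRUE(enable_rebalance),
              output_dir = output_dir, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

# Cheap order-invariant-enough fingerprint used to verify that ablation arms
# saw identical input data.
data_checksum <- function(beats, labels) {
  sprintf("%dx%d|%.10e|%.10e|%d|%.10e",
          nrow(beats), ncol(beats),
          sum(beats, na.rm = TRUE), sum(beats^2, na.rm = TRUE),
          sum(is.na(beats)), sum(labels * seq_along(labels)))
}

resolve_dataset <- function(config) {
  src <- config$source
  if (src$type == "synthetic") {
    generate_dataset(src$class_counts, src$beat_length %||% 187,
                     src$noise %||% noise_spec(),
                     src$sampling_rate %||% 125, seed = config$seed)
  } else {
    d <- read_beats(src$path, src$delimiter %||% ",")
    list(beats = d$beats, labels = d$labels, masks = is.na(d$beats))
  }
}

#' Run the full classification pipeline
#'
#' Executes: data resolution -> denoising (if enabled) -> stratified
#' train/test split -> class rebalancing of the training partition (if
#' enabled) -> network training -> feature extraction -> one-versus-all SVM
#' fit -> evaluation on the held-out partition. Rebalancing is applied to
#' the training partition only, so no test row is ever duplicated into
#' training. A manifest capturing the fully resolved configuration is
#' returned (and written when `output_dir` is set), and re-running from the
#' manifest reproduces the report.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_result`: list with `report` (a
#'   [multiclass_report()] on the test partition), `model`, `svm`,
#'   `history`, `manifest`, `checksum` (input-data fingerprint) and
#'   `predictions`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  fs <- config$source$sampling_rate %||% 125

  data <- resolve_dataset(config)
  checksum <- data_checksum(data$beats, data$labels)

  beats <- data$beats
  if (config$enable_denoise) {
    beats <- denoise_beats(beats, data$masks, config$denoise, fs)
  } else {
    beats[is.na(beats)] <- 0 # zero-fill lost samples; no other correction
  }

  sp <- split_train_test(beats, data$labels,
                         train_fraction = config$split$train_fraction %||% 0.8,
                         stratified = config$split$stratified %||% TRUE,
                         seed = seed + 1L)
  tr <- sp$train; te <- sp$test

  if (config$enable_rebalance) {
    ms <- config$rebalance$majority_subsample
    if (!is.null(ms))
      tr <- subsample_majority(tr$beats, tr$labels, ms$class %||% 0,
                               ms$n_keep, seed = seed + 2L)
    target <- config$rebalance$target_per_class %||%
      max(tabulate(tr$labels + 1L, nbins = config$model$n_classes))
    tr <- resample_to_balance(tr$beats, tr$labels, target, seed = seed + 3L)
  }

  model <- build_model(config$model, ncol(beats), seed = seed + 4L)
  tc <- config$train
  tc$seed <- seed + 5L
  model <- train_model(model, tr$beats, tr$labels, tc)

  feat_tr <- extract_features(model, tr$beats)
  feat_te <- extract_features(model, te$beats)
  svm <- fit_ova_svm(feat_tr, tr$labels, C = config$svm$C %||% 1,
                     kernel = config$svm$kernel %||% "linear",
                     gamma = config$svm$gamma %||% 1e-4, seed = seed + 6L)
  pred <- predict_labels(svm, feat_te)
  report <- multiclass_report(te$labels, pred$labels, pred$scores,
                              n_classes = config$model$n_classes)

  manifest <- build_manifest(config)
  result <- structure(list(report = report, model = model, svm = svm,
                           history = model$history, manifest = manifest,
                           checksum = checksum,
                           predictions = list(labels = pred$labels,
                                              scores = pred$scores,
                                              truth = te$labels)),
                      class = "pipeline_result")
  if (!is.null(config$output_dir)) write_artifacts(result, config)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$report)
  invisible(x)
}

# ---- manifest -------------------------------------------------------------

build_manifest <- function(config) {
  src <- config$source
  if (!is.null(src$noise)) src$noise <- unclass(src$noise)
  # a named list serialises as a JSON object, keeping the class ids
  if (!is.null(src$class_counts)) src$class_counts <- as.list(src$class_counts)
  list(package = "ecgbeats",
       version = as.character(utils::packageVersion("ecgbeats")),
       seed = config$seed,
       source = src,
       denoise = unclass(config$denoise),
       rebalance = config$rebalance,
       split = config$split,
       model = unclass(config$model),
       train = unclass(config$train),
       svm = config$svm,
       enable_denoise = config$enable_denoise,
       enable_rebalance = config$enable_rebalance)
}

#' Rebuild a pipeline configuration from a manifest
#'
#' A manifest (as returned in `pipeline_result$manifest` or written to
#' `manifest.json`) fully determines a run; this reconstructs the
#' [pipeline_config()] so the run can be repeated.
#'
#' @param manifest Manifest list or path to a manifest JSON file.
#' @return A [pipeline_config()].
#' @export
manifest_to_config <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::fromJSON(manifest, simplifyVector = TRUE)
  src <- manifest$source
  if (!is.null(src$class_counts)) src$class_counts <- unlist(src$class_counts)
  if (!is.null(src$noise))
    src$noise <- do.call(noise_spec, lapply(src$noise, function(x) x))
  dn <- manifest$denoise
  denoise <- denoise_config(
    interpolation_kind = dn$interpolation_kind,
    baseline_window_short = dn$baseline_window_short,
    baseline_window_long = dn$baseline_window_long,
    notch_freq = dn$notch_freq, notch_quality = dn$notch_quality,
    wavelet_family = dn$wavelet_family,
    decomposition_levels = dn$decomposition_levels,
    threshold_rule = dn$threshold_rule,
    stages = unlist(dn$stages), znormalize = dn$znormalize)
  model <- do.call(rdcnn_config, as.list(manifest$model))
  train <- do.call(train_config, as.list(manifest$train))
  rebalance <- manifest$rebalance
  if (length(rebalance) == 0L)
    rebalance <- list(target_per_class = NULL, majority_subsample = NULL)
  pipeline_config(source = src, denoise = denoise, rebalance = rebalance,
                  split = manifest$split, model = model, train = train,
                  svm = manifest$svm,
                  enable_denoise = manifest$enable_denoise,
                  enable_rebalance = manifest$enable_rebalance,
                  seed = manifest$seed)
}

write_artifacts <- function(result, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  od <- config$output_dir
  jsonlite::write_json(result$manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(as.list(glance(result$report)),
                       file.path(od, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.table(result$report$confusion, file.path(od, "confusion.csv"),
              sep = ",", col.names = FALSE, row.names = FALSE)
  write.table(result$history, file.path(od, "history.csv"), sep = ",",
              row.names = FALSE)
  saveRDS(list(model = result$model, svm = result$svm),
          file.path(od, "model.rds"))
  invisible(od)
}

#' Ablation study over the denoise / rebalance switches
#'
#' Runs the pipeline once per flag combination with the same data and seed
#' (input equality is verifiable through the `checksum` column) and
#' tabulates the resulting metrics.
#'
#' @param config Base [pipeline_config()].
#' @param flag_grid Data frame with logical columns `enable_denoise` and
#'   `enable_rebalance`; defaults to the full 2 x 2 grid.
#' @return Tibble with one row per combination: the two flags, accuracy,
#'   macro F1, kappa, macro AUC and the input checksum. The full
#'   `pipeline_result`s are attached as the `"results"` attribute.
#' @export
run_ablation <- function(config = pipeline_config(), flag_grid = NULL) {
  if (is.null(flag_grid))
    flag_grid <- expand.grid(enable_denoise = c(FALSE, TRUE),
                             enable_rebalance = c(FALSE, TRUE))
  if (nrow(flag_grid) == 0L) stop("empty flag grid", call. = FALSE)
  results <- vector("list", nrow(flag_grid))
  rows <- vector("list", nrow(flag_grid))
  for (i in seq_len(nrow(flag_grid))) {
    cfg <- config
    cfg$enable_denoise <- isTRUE(flag_grid$enable_denoise[i])
    cfg$enable_rebalance <- isTRUE(flag_grid$enable_rebalance[i])
    res <- run_pipeline(cfg)
    results[[i]] <- res
    rows[[i]] <- tibble::tibble(
      enable_denoise = cfg$enable_denoise,
      enable_rebalance = cfg$enable_rebalance,
      accuracy = res$report$accuracy,
      macro_f1 = res$report$macro_f1,
      kappa = res$report$kappa,
      auc_macro = res$report$auc_macro,
      checksum = res$checksum)
  }
  out <- do.call(rbind, rows)
  attr(out, "results") <- results
  out
}
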