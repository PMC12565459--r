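#' Configuration of a full pipeline run
#'
#' @param out_dir Run directory (created if needed).
#' @param phantom A [phantom_params()] object (defines the cohort).
#' @param image_types Image types to process: original weight names and/or
#'   `A+B` fusion pairs (default: all four weights plus the six study pairs).
#' @param fusion A [fusion_config()].
#' @param extraction An [extraction_config()].
#' @param selection List with `max_iter`, `alpha`, `nrounds` for
#'   [boruta_select()].
#' @param grading List with `k`, `budget`, `menu` for [model_search()].
#' @param seed Master seed: fixes phantom, shadow permutations, folds and
#'   model search.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       phantom = phantom_params(n_subjects = 40L),
                       image_types = c(modality_names(), fusion_pairs()),
                       fusion = fusion_config(),
                       extraction = extraction_config(),
                       selection = list(max_iter = 50L, alpha = 0.05, nrounds = 30L),
                       grading = list(k = 10L, budget = length(model_menu()),
                                      menu = model_menu()),
                       seed = 1L) {
  pairs <- image_types[grepl("+", image_types, fixed = TRUE)]
  for (p in pairs) {
    parts <- strsplit(p, "+", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !all(parts %in% modality_names()) ||
        parts[1] == parts[2])
      eg_abort(paste0("invalid image type: ", p), "invalid_parameter")
  }
  structure(list(out_dir = out_dir, phantom = phantom,
                 image_types = image_types, fusion = fusion,
                 extraction = extraction, selection = selection,
                 grading = grading, seed = as.integer(seed)),
            class = "run_config")
}

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  cfg <- config; cfg$out_dir <- NULL
  writeLines(jsonlite::toJSON(rapply(unclass(cfg), unclass, how = "replace"),
                              auto_unbox = TRUE, digits = NA, force = TRUE), tf)
  unname(tools::md5sum(tf))
}

.log_line <- function(log_file, stage, subject, t0) {
  line <- sprintf("%s\tstage=%s\tsubject=%s\twall_s=%.2f",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, subject,
                  as.numeric(Sys.time()) - t0)
  cat(line, "\n", file = log_file, append = TRUE, sep = "")
}

.select_training_features <- function(sel) {
  if (length(sel$confirmed) > 0) return(sel$confirmed)
  # fall back to the highest-hit-rate features when nothing is confirmed
  warning("no confirmed features; falling back to the 5 highest hit rates")
  names(sort(sel$hits, decreasing = TRUE))[seq_len(min(5, length(sel$hits)))]
}

#' Run the complete pipeline: simulate, fuse, quality, extract, select, train
#'
#' Executes every stage for the configured image types over a synthetic
#' cohort, writing per-stage artifacts under `config$out_dir`. Stages are
#' idempotent: a stage whose output already exists for the same configuration
#' hash is not recomputed. Subjects whose edema ROI is empty are excluded
#' with a logged reason. One master seed fixes the phantom, the shadow
#' permutations, the CV folds and the model search.
#'
#' @param config A [run_config()].
#' @return A list of class `run_result`: `summary` (tibble of mean CV metrics
#'   per image type), `reports` (named list of `model_search` objects),
#'   `selections` (named list of `boruta_result`s), `quality` (tibble),
#'   `manifest`, `out_dir`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("features", "selection", "reports", "quality"))
    dir.create(file.path(config$out_dir, d), showWarnings = FALSE)
  log_file <- file.path(config$out_dir, "log.txt")
  hash_file <- file.path(config$out_dir, "config_hash.txt")
  hash <- .config_hash(config)
  fresh <- !(file.exists(hash_file) && identical(readLines(hash_file)[1], hash))
  if (fresh) {
    unlink(list.files(config$out_dir, recursive = TRUE, full.names = TRUE))
    writeLines(hash, hash_file)
    for (d in c("features", "selection", "reports", "quality"))
      dir.create(file.path(config$out_dir, d), showWarnings = FALSE)
  }
  yaml::write_yaml(list(seed = config$seed, image_types = config$image_types,
                        n_subjects = config$phantom$n_subjects),
                   file.path(config$out_dir, "run_config.yaml"))

  ph <- config$phantom; ph$seed <- config$seed
  t0 <- as.numeric(Sys.time())
  cohort <- generate_cohort(ph)
  .log_line(log_file, "simulate", "all", t0)

  # exclusion pass: drop subjects without a usable edema ROI
  keep <- vapply(cohort$subjects, function(rec) {
    ok <- sum(rec$mask == config$extraction$roi$label) >=
      config$extraction$roi$min_voxels
    if (!ok) .log_line(log_file, "exclude-empty-roi", rec$subject_id,
                       as.numeric(Sys.time()))
    ok
  }, logical(1))
  cohort$manifest$excluded <- !keep
  cohort$subjects <- cohort$subjects[keep]
  man <- cohort$manifest
  utils::write.csv(man, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)

  feature_tables <- list(); quality_rows <- list()
  for (it in config$image_types) {
    fpath <- file.path(config$out_dir, "features", paste0(gsub("\\+", "_", it), ".csv"))
    if (file.exists(fpath)) {
      feature_tables[[it]] <- tibble::as_tibble(utils::read.csv(fpath, check.names = FALSE))
      next
    }
    t0 <- as.numeric(Sys.time())
    is_pair <- grepl("+", it, fixed = TRUE)
    rows <- list()
    for (rec in cohort$subjects) {
      ts <- as.numeric(Sys.time())
      vol <- if (is_pair) {
        fused <- fuse_subject_pair(rec, it, config$fusion)
        parts <- strsplit(it, "+", fixed = TRUE)[[1]]
        quality_rows[[length(quality_rows) + 1L]] <- dplyr::mutate(
          fusion_quality(fused, rec$modalities[parts], it),
          subject_id = rec$subject_id, .before = 1)
        fused
      } else rec$modalities[[it]]
      fv <- extract_features(vol, rec$mask, rec$spacing, config$extraction)
      rows[[rec$subject_id]] <- tibble::tibble(
        subject_id = rec$subject_id, grade = rec$grade, image_type = it,
        !!!as.list(fv))
      .log_line(log_file, paste0("extract:", it), rec$subject_id, ts)
    }
    feature_tables[[it]] <- dplyr::bind_rows(rows)
    utils::write.csv(feature_tables[[it]], fpath, row.names = FALSE)
    .log_line(log_file, paste0("features:", it), "all", t0)
  }
  quality <- if (length(quality_rows)) dplyr::bind_rows(quality_rows) else
    tibble::tibble()
  if (nrow(quality))
    utils::write.csv(quality, file.path(config$out_dir, "quality", "quality.csv"),
                     row.names = FALSE)

  selections <- list(); reports <- list(); summary_rows <- list()
  for (it in config$image_types) {
    t0 <- as.numeric(Sys.time())
    ft <- feature_tables[[it]]
    feats <- setdiff(names(ft), c("subject_id", "grade", "image_type"))
    scaled <- suppressWarnings(minmax_scale(ft[feats]))
    sel_path <- file.path(config$out_dir, "selection",
                          paste0(gsub("\\+", "_", it), ".json"))
    rep_path <- file.path(config$out_dir, "reports",
                          paste0(gsub("\\+", "_", it), ".json"))
    if (file.exists(sel_path) && file.exists(rep_path)) {
      selj <- jsonlite::read_json(sel_path, simplifyVector = TRUE)
      repj <- jsonlite::read_json(rep_path, simplifyVector = TRUE)
      selections[[it]] <- selj; reports[[it]] <- repj
      summary_rows[[it]] <- tibble::tibble(
        image_type = it, fused = grepl("+", it, fixed = TRUE),
        best_model = repj$best_model, n_selected = repj$n_features,
        !!!repj$mean_metrics)
      next
    }
    sel <- boruta_select(scaled, ft$grade,
                         max_iter = config$selection$max_iter,
                         alpha = config$selection$alpha,
                         nrounds = config$selection$nrounds %||% 30L,
                         seed = config$seed)
    selections[[it]] <- sel
    jsonlite::write_json(list(confirmed = sel$confirmed,
                              tentative = sel$tentative,
                              rejected = sel$rejected,
                              n_iterations = sel$n_iterations), sel_path)
    utils::write.csv(sel$history,
                     file.path(config$out_dir, "selection",
                               paste0(gsub("\\+", "_", it), "_history.csv")),
                     row.names = FALSE)
    .log_line(log_file, paste0("select:", it), "all", t0)

    t0 <- as.numeric(Sys.time())
    use <- suppressWarnings(.select_training_features(sel))
    ms <- model_search(scaled[use], ft$grade, menu = config$grading$menu,
                       budget = config$grading$budget, k = config$grading$k,
                       seed = config$seed)
    reports[[it]] <- ms
    jsonlite::write_json(
      list(image_type = it, best_model = ms$best_spec$name,
           hyperparameters = ms$best_spec$hyperparameters,
           mean_metrics = as.list(ms$best_report$mean_metrics),
           pooled_metrics = as.list(ms$best_report$pooled_metrics),
           confusion = unclass(ms$best_report$confusion),
           n_features = length(use)),
      file.path(config$out_dir, "reports", paste0(gsub("\\+", "_", it), ".json")),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(ms$best_report$roc,
                     file.path(config$out_dir, "reports",
                               paste0(gsub("\\+", "_", it), "_roc.csv")),
                     row.names = FALSE)
    summary_rows[[it]] <- tibble::tibble(
      image_type = it, fused = grepl("+", it, fixed = TRUE),
      best_model = ms$best_spec$name, n_selected = length(use),
      !!!as.list(ms$best_report$mean_metrics))
    .log_line(log_file, paste0("train:", it), "all", t0)
  }
  summary <- dplyr::bind_rows(summary_rows)
  utils::write.csv(summary, file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)
  structure(list(summary = summary, reports = reports,
                 selections = selections, quality = quality, manifest = man,
                 out_dir = config$out_dir), class = "run_result")
}

#' Cross-image-type performance heatmap
#'
#' The mean CV metrics of the best classifier per image type, as a tile plot
#' (original weights vs fused pairs).
#'
#' @param summary The `summary` tibble of a `run_result`.
#' @return A ggplot object.
#' @export
plot_performance_matrix <- function(summary) {
  long <- tidyr::pivot_longer(summary,
                              cols = c("accuracy", "precision", "recall", "f1", "auc"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$image_type, y = .data$metric,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean CV") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
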