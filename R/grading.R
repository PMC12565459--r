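#' Inverse-frequency class weights
#'
#' `weight(c) = n / (2 * n_c)`: the minority class receives the larger
#' weight, and the weighted class sizes satisfy
#' `sum_c weight(c) * n_c = n`.
#'
#' @param y Binary label vector.
#' @return Named numeric vector of two weights.
#' @export
class_weights <- function(y) {
  y <- as.character(y)
  tab <- table(y)
  if (length(tab) < 2L) eg_abort("y must contain both classes", "invalid_labels")
  w <- length(y) / (2 * as.numeric(tab))
  setNames(w, names(tab))
}

#' Classification metrics, confusion matrix and ROC points
#'
#' Accuracy, precision, recall and F1 with HGG (or `positive`) as the
#' positive class; AUC via the rank statistic with tie-averaging; 2x2
#' confusion matrix ordered (LGG, HGG) as (negative, positive), rows = truth.
#' Precision with no positive predictions is reported as 0 with a warning.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param y_score Numeric scores (higher = more positive), used for AUC/ROC.
#' @param positive Positive class (default `"HGG"`).
#' @return List of class `eval_metrics`: `metrics` (named numeric),
#'   `confusion` (2x2 matrix), `roc` (tibble fpr/tpr/threshold).
#' @export
evaluate_predictions <- function(y_true, y_pred, y_score = NULL,
                                 positive = "HGG") {
  if (length(y_true) != length(y_pred))
    eg_abort("length mismatch", "invalid_input")
  enc <- .encode_labels(y_true, positive)
  pos <- enc$pos; neg <- enc$neg
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  tp <- sum(y_true == pos & y_pred == pos)
  fp <- sum(y_true == neg & y_pred == pos)
  fn <- sum(y_true == pos & y_pred == neg)
  tn <- sum(y_true == neg & y_pred == neg)
  acc <- (tp + tn) / length(y_true)
  prec <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("no positive predictions; precision reported as 0"); 0
  }
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  auc <- NA_real_
  roc <- NULL
  if (!is.null(y_score)) {
    if (any(!is.finite(y_score))) eg_abort("non-finite scores", "invalid_input")
    ispos <- y_true == pos
    n1 <- sum(ispos); n0 <- sum(!ispos)
    r <- rank(y_score)   # ties averaged
    auc <- (sum(r[ispos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    thr <- c(Inf, sort(unique(y_score), decreasing = TRUE))
    roc <- tibble::tibble(
      threshold = thr,
      tpr = vapply(thr, function(t) sum(y_score >= t & ispos) / n1, numeric(1)),
      fpr = vapply(thr, function(t) sum(y_score >= t & !ispos) / n0, numeric(1)))
  }
  cm <- matrix(c(tn, fp, fn, tp), 2, 2, byrow = TRUE,
               dimnames = list(truth = c(neg, pos), predicted = c(neg, pos)))
  structure(list(metrics = c(accuracy = acc, precision = prec, recall = rec,
                             f1 = f1, auc = auc),
                 confusion = cm, roc = roc, positive = pos),
            class = "eval_metrics")
}

.stratified_folds <- function(y, k, seed) {
  y <- as.character(y)
  folds <- integer(length(y))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  folds
}

#' Stratified k-fold cross-validation of one classifier
#'
#' Stratified fold assignment under the given seed; per-fold training with
#' class weights and evaluation on the held-out fold; metrics are reported
#' both as unweighted fold means and pooled over the out-of-fold predictions
#' (one pooled confusion matrix and ROC). If the minority class has fewer
#' than `k` members, `k` is reduced with a warning.
#'
#' @param X Feature data frame or matrix (numeric columns only are used).
#' @param y Binary labels.
#' @param spec A [model_spec()].
#' @param k Number of folds (default 10).
#' @param seed Seed fixing folds and model randomness.
#' @param positive Positive class (default `"HGG"`).
#' @return An object of class `model_report`.
#' @export
cross_validate <- function(X, y, spec, k = 10L, seed = 1L, positive = "HGG") {
  Xdf <- as.data.frame(X)
  Xm <- as.matrix(Xdf[vapply(Xdf, is.numeric, logical(1))])
  y <- as.character(y)
  min_class <- min(table(y))
  if (min_class < k) {
    k <- max(2L, as.integer(min_class))
    warning("minority class smaller than k; folds reduced to ", k)
  }
  folds <- .stratified_folds(y, k, seed)
  oof_score <- numeric(length(y)); oof_pred <- character(length(y))
  fold_rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    fit <- fit_classifier(spec, Xm[tr, , drop = FALSE], y[tr],
                          seed = seed + f, positive = positive)
    sc <- fit$score(Xm[te, , drop = FALSE])
    pred <- ifelse(sc >= 0, fit$positive, fit$negative)
    oof_score[te] <- sc; oof_pred[te] <- pred
    ev <- suppressWarnings(evaluate_predictions(y[te], pred, sc, positive))
    fold_rows[[f]] <- tibble::tibble(fold = f, !!!as.list(ev$metrics))
  }
  fold_metrics <- dplyr::bind_rows(fold_rows)
  pooled <- suppressWarnings(
    evaluate_predictions(y, oof_pred, oof_score, positive))
  mean_metrics <- colMeans(fold_metrics[, -1], na.rm = TRUE)
  structure(list(spec = spec, k = k, cv_seed = seed,
                 fold_metrics = fold_metrics, mean_metrics = mean_metrics,
                 pooled_metrics = pooled$metrics, confusion = pooled$confusion,
                 roc = pooled$roc, positive = pooled$positive,
                 oof = tibble::tibble(truth = y, predicted = oof_pred,
                                      score = oof_score, fold = folds)),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("Cross-validated", x$spec$name, "(k =", x$k, ")\n")
  cat("mean fold metrics:\n")
  print(round(x$mean_metrics, 4))
  cat("pooled confusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' @exportS3Method generics::tidy model_report
tidy.model_report <- function(x, ...) x$fold_metrics

#' @exportS3Method generics::glance model_report
glance.model_report <- function(x, ...) {
  tibble::tibble(model = x$spec$name, k = x$k, seed = x$cv_seed,
                 !!!as.list(setNames(x$mean_metrics,
                                     paste0("mean_", names(x$mean_metrics)))),
                 pooled_accuracy = unname(x$pooled_metrics["accuracy"]),
                 pooled_auc = unname(x$pooled_metrics["auc"]))
}

#' ROC curve of the pooled out-of-fold predictions
#' @param object A `model_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot model_report
autoplot.model_report <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = paste0(object$spec$name, " (pooled AUC = ",
                                 round(object$pooled_metrics["auc"], 3), ")")) +
    ggplot2::theme_minimal()
}

#' Seeded random search over the classifier menu
#'
#' Deterministic stand-in for an evolutionary pipeline search: `budget`
#' configurations are allocated round-robin over the menu (the first per
#' model being its defaults, later ones seeded random draws within
#' documented ranges), each evaluated by [cross_validate()], and ranked by
#' mean CV accuracy with ties broken by mean F1 then lexicographic name.
#'
#' @param X Feature table.
#' @param y Binary labels.
#' @param menu Character vector of classifier names.
#' @param budget Total configurations to evaluate (>= `length(menu)`).
#' @param k Folds per evaluation.
#' @param seed Master seed.
#' @param positive Positive class.
#' @param class_weighted Train with class weights (default TRUE).
#' @return List of class `model_search`: `best_spec`, `best_report`,
#'   `leaderboard` (tibble).
#' @export
model_search <- function(X, y, menu = model_menu(), budget = length(menu),
                         k = 10L, seed = 1L, positive = "HGG",
                         class_weighted = TRUE) {
  if (length(menu) == 0L) eg_abort("empty menu", "invalid_parameter")
  if (budget < length(menu))
    eg_abort("budget must be at least the menu size", "invalid_parameter")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  draws <- runif(budget * 40)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  di <- 0L
  rng <- function() { di <<- di + 1L; draws[di] }
  rows <- vector("list", budget); reports <- vector("list", budget)
  for (b in seq_len(budget)) {
    name <- menu[(b - 1L) %% length(menu) + 1L]
    hp <- if (b <= length(menu)) list() else sample_hyperparameters(name, rng)
    spec <- model_spec(name, hp, class_weighted = class_weighted)
    rep_b <- suppressWarnings(
      cross_validate(X, y, spec, k = k, seed = seed, positive = positive))
    reports[[b]] <- rep_b
    rows[[b]] <- tibble::tibble(config = b, model = name,
                                accuracy = unname(rep_b$mean_metrics["accuracy"]),
                                f1 = unname(rep_b$mean_metrics["f1"]),
                                auc = unname(rep_b$mean_metrics["auc"]))
  }
  lb <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$accuracy),
                       dplyr::desc(.data$f1), .data$model)
  best <- lb$config[1]
  structure(list(best_spec = reports[[best]]$spec,
                 best_report = reports[[best]], leaderboard = lb,
                 seed = seed), class = "model_search")
}

#' @export
print.model_search <- function(x, ...) {
  cat("Model search winner:", x$best_spec$name, "\n")
  print(head(x$leaderboard, 8))
  invisible(x)
}

#' Named classifier presets from the study's winning pipelines
#'
#' The best classifier per image type, with the published hyperparameters,
#' mapped onto this package's menu (scikit-learn gradient-boosting parameters
#' map onto the xgboost-backed `gradient_boosting` entry; stacked pipelines
#' are represented by their lead estimator).
#'
#' @return Named list of [model_spec()] objects. The headline preset is
#'   `paper_t1gd_flair_sgd`: an elastic-net SGD classifier with alpha 0.001,
#'   eta0 0.01, invscaling learning rate, power_t 0.1, l1_ratio 0.25.
#' @export
paper_presets <- function() {
  list(
    paper_flair_gb = model_spec("gradient_boosting",
      list(eta = 0.01, max_depth = 8, nrounds = 100, subsample = 0.6501)),
    paper_t1_gb = model_spec("gradient_boosting",
      list(eta = 0.5, max_depth = 2, nrounds = 100, subsample = 0.55,
           colsample_bytree = 0.1)),
    paper_t1gd_bnb = model_spec("bernoulli_nb",
      list(alpha = 100, fit_prior = FALSE)),
    paper_t2_sgd = model_spec("sgd",
      list(alpha = 0.01, eta0 = 0.1, fit_intercept = FALSE, l1_ratio = 0.25,
           learning_rate = "constant", penalty = "elasticnet", power_t = 10)),
    paper_t1_flair_mlp = model_spec("mlp", list(alpha = 1e-4)),
    paper_t1gd_flair_sgd = model_spec("sgd",
      list(alpha = 0.001, eta0 = 0.01, fit_intercept = TRUE, l1_ratio = 0.25,
           learning_rate = "invscaling", penalty = "elasticnet",
           power_t = 0.1)),
    paper_t1gd_t1_gb = model_spec("gradient_boosting",
      list(eta = 0.1, max_depth = 3, nrounds = 100, subsample = 0.7,
           colsample_bytree = 0.95)),
    paper_t1gd_t2_gb = model_spec("gradient_boosting",
      list(eta = 0.1, max_depth = 10, nrounds = 100, subsample = 0.5,
           colsample_bytree = 0.5)),
    paper_t2_flair_knn = model_spec("knn", list(k = 39)),
    paper_t2_t1_mlp = model_spec("mlp", list(alpha = 1e-4)))
}
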