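#' Min-max scale a feature table to \[0, 1\]
#'
#' Each feature column is mapped by `(x - min) / (max - min)`; constant
#' columns are mapped to 0 with a warning. The per-feature `(min, max)` pairs
#' are attached so the identical transform can be applied to held-out rows
#' with [minmax_apply()].
#'
#' @param table Data frame of numeric features (non-feature columns such as
#'   `subject_id`, `grade`, `image_type` are passed through untouched).
#' @return A tibble of the same shape with attribute `ranges` (tibble:
#'   feature, min, max).
#' @export
minmax_scale <- function(table) {
  tbl <- tibble::as_tibble(table)
  if (nrow(tbl) < 2L) eg_abort("need at least two rows to scale", "invalid_parameter")
  num <- names(tbl)[vapply(tbl, is.numeric, logical(1))]
  if (any(!vapply(tbl[num], function(x) all(is.finite(x)), logical(1))))
    eg_abort("non-finite feature values", "invalid_input")
  rng <- tibble::tibble(feature = num,
                        min = unname(vapply(tbl[num], min, numeric(1))),
                        max = unname(vapply(tbl[num], max, numeric(1))))
  const <- rng$feature[rng$max == rng$min]
  if (length(const))
    warning(length(const), " constant feature(s) scaled to 0")
  for (i in seq_along(num)) {
    f <- num[i]
    tbl[[f]] <- if (rng$max[i] > rng$min[i])
      (tbl[[f]] - rng$min[i]) / (rng$max[i] - rng$min[i]) else rep(0, nrow(tbl))
  }
  attr(tbl, "ranges") <- rng
  tbl
}

#' Apply a stored min-max transform to new rows
#'
#' @param table Data frame with the same feature columns.
#' @param ranges The `ranges` attribute of a [minmax_scale()] result.
#' @return Scaled tibble (values may fall outside \[0, 1\] if the new data
#'   exceed the training range).
#' @export
minmax_apply <- function(table, ranges) {
  tbl <- tibble::as_tibble(table)
  for (i in seq_len(nrow(ranges))) {
    f <- ranges$feature[i]
    if (!f %in% names(tbl)) next
    tbl[[f]] <- if (ranges$max[i] > ranges$min[i])
      (tbl[[f]] - ranges$min[i]) / (ranges$max[i] - ranges$min[i])
    else rep(0, nrow(tbl))
  }
  tbl
}

# gain importance of every feature (zero for features never used in a split)
.xgb_gain <- function(X, y01, weights, nrounds, seed, nthread = 1L,
                      subsample = 0.8, colsample = 1 / 3) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y01, weight = weights)
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 3, eta = 0.3,
                  subsample = subsample, colsample_bytree = colsample,
                  nthread = nthread, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0)
  imp <- xgboost::xgb.importance(model = fit)
  gain <- setNames(rep(0, ncol(X)), colnames(X))
  if (!is.null(imp) && nrow(imp)) gain[imp$Feature] <- imp$Gain
  gain
}

#' Boruta-style all-relevant feature selection
#'
#' Iteratively compares each feature's gradient-boosted-tree gain importance
#' against the maximum importance among shadow features (column-wise
#' permutations of the whole feature block appended to the data). A feature
#' scores a "hit" in an iteration when it beats the shadow maximum; after
#' each iteration a two-sided binomial test on the accumulated hit counts
#' (Bonferroni-corrected over the full feature set) promotes features to
#' `confirmed` or `rejected`. Features still undecided after `max_iter`
#' iterations are `tentative`.
#'
#' The boosted ensemble subsamples rows (`subsample`) and features per tree
#' (`colsample_bytree`), mirroring the random-forest dilution the reference
#' algorithm relies on; a deterministic full-feature booster would let a
#' chance-correlated feature persistently beat the refreshed shadow maximum
#' and inflate the false-confirmation rate.
#'
#' @param X Data frame or matrix of scaled features (no missing values).
#' @param y Binary labels (factor or character; e.g. LGG/HGG).
#' @param max_iter Maximum number of iterations (>= 5; default 100).
#' @param alpha Test level (default 0.05).
#' @param seed Master seed; shadow permutations use an iteration-specific
#'   stream derived from it.
#' @param nrounds Boosting rounds per iteration (default 30).
#' @param subsample,colsample_bytree Row and per-tree feature subsampling of
#'   the boosted ensemble (defaults 0.8 and 1/3).
#' @param early_stop Stop early when no features remain undecided.
#' @return An object of class `boruta_result`: `confirmed`, `tentative`,
#'   `rejected` (character vectors), `hits`, `n_iterations`, `history`
#'   (long tibble of importances), `seed`.
#' @export
boruta_select <- function(X, y, max_iter = 100L, alpha = 0.05, seed = 1L,
                          nrounds = 30L, subsample = 0.8,
                          colsample_bytree = 1 / 3, early_stop = TRUE) {
  if (max_iter < 5L) eg_abort("max_iter must be >= 5", "invalid_parameter")
  Xm <- as.matrix(as.data.frame(X)[vapply(as.data.frame(X), is.numeric, logical(1))])
  if (anyNA(Xm)) eg_abort("missing values in X", "invalid_input")
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2L) eg_abort("y must contain exactly two classes", "invalid_labels")
  y01 <- as.numeric(y == classes[2])
  w <- unname(class_weights(y)[y])
  p <- ncol(Xm); feat <- colnames(Xm)
  hits <- setNames(rep(0L, p), feat)
  status <- setNames(rep("undecided", p), feat)
  history <- vector("list", max_iter)
  it <- 0L
  for (iter in seq_len(max_iter)) {
    it <- iter
    iter_seed <- (as.numeric(seed) * 7919 + iter * 104729) %% 2147483647
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(iter_seed)
    shadow <- apply(Xm, 2, sample)
    colnames(shadow) <- paste0(".shadow_", feat)
    gain <- .xgb_gain(cbind(Xm, shadow), y01, w, nrounds, seed = iter_seed,
                      subsample = subsample, colsample = colsample_bytree)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    shadow_max <- max(gain[paste0(".shadow_", feat)])
    hit <- gain[feat] > shadow_max
    hits <- hits + as.integer(hit)
    history[[iter]] <- tibble::tibble(iteration = iter, feature = feat,
                                      importance = unname(gain[feat]),
                                      shadow_max = shadow_max,
                                      hit = unname(hit))
    und <- names(status)[status == "undecided"]
    if (length(und) > 0) {
      thr <- alpha / 2 / p   # two-sided, Bonferroni over all features
      p_hi <- pbinom(hits[und] - 1L, iter, 0.5, lower.tail = FALSE)
      p_lo <- pbinom(hits[und], iter, 0.5)
      status[und[p_hi < thr]] <- "confirmed"
      status[und[p_lo < thr & p_hi >= thr]] <- "rejected"
    }
    if (early_stop && !any(status == "undecided")) break
  }
  structure(list(confirmed = names(status)[status == "confirmed"],
                 tentative = names(status)[status == "undecided"],
                 rejected = names(status)[status == "rejected"],
                 hits = hits, n_iterations = it,
                 history = dplyr::bind_rows(history[seq_len(it)]),
                 alpha = alpha, seed = seed),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  cat("Boruta-style selection after", x$n_iterations, "iterations:\n",
      length(x$confirmed), "confirmed,", length(x$tentative), "tentative,",
      length(x$rejected), "rejected\n")
  invisible(x)
}

#' Tidy a Boruta selection result
#'
#' @param x A `boruta_result`.
#' @param ... Unused.
#' @return Tibble: `feature`, `decision`, `hits`, `hit_rate`,
#'   `mean_importance`.
#' @exportS3Method generics::tidy boruta_result
tidy.boruta_result <- function(x, ...) {
  imp <- x$history |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(mean_importance = mean(.data$importance), .groups = "drop")
  dec <- tibble::tibble(
    feature = c(x$confirmed, x$tentative, x$rejected),
    decision = rep(c("confirmed", "tentative", "rejected"),
                   c(length(x$confirmed), length(x$tentative), length(x$rejected))))
  dec$hits <- unname(x$hits[dec$feature])
  dec$hit_rate <- dec$hits / x$n_iterations
  dplyr::arrange(dplyr::left_join(dec, imp, by = "feature"),
                 dplyr::desc(.data$hit_rate))
}

#' @exportS3Method generics::glance boruta_result
glance.boruta_result <- function(x, ...) {
  tibble::tibble(n_confirmed = length(x$confirmed),
                 n_tentative = length(x$tentative),
                 n_rejected = length(x$rejected),
                 n_iterations = x$n_iterations, alpha = x$alpha, seed = x$seed)
}

#' Importance-history plot for a Boruta selection
#' @param object A `boruta_result`.
#' @param top Number of top features to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot boruta_result
autoplot.boruta_result <- function(object, top = 20L, ...) {
  td <- head(tidy(object), top)
  hist <- dplyr::filter(object$history, .data$feature %in% td$feature)
  ggplot2::ggplot(hist, ggplot2::aes(x = stats::reorder(.data$feature, .data$importance,
                                                        FUN = stats::median),
                                     y = .data$importance)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = mean(object$history$shadow_max),
                        linetype = 2, colour = "red") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "gain importance",
                  caption = "dashed line: mean max shadow importance") +
    ggplot2::theme_minimal()
}
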