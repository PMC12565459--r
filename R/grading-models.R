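# Classifier menu: each entry knows how to fit (with optional class weights)
# and how to score new rows (higher score = more likely the positive class).

#' Classifier specification
#'
#' @param name One of `model_menu()` (plus `"majority"`, a degenerate
#'   always-majority baseline useful for sanity checks).
#' @param hyperparameters Named list; see the per-model defaults in
#'   [default_hyperparameters()].
#' @param class_weighted Apply inverse-frequency class weights during
#'   training (default TRUE; for `knn` the weights enter the neighbour vote).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(name, hyperparameters = list(), class_weighted = TRUE) {
  if (!name %in% c(model_menu(), "majority"))
    eg_abort(paste0("unknown classifier: ", name), "invalid_parameter")
  hp <- utils::modifyList(default_hyperparameters(name), hyperparameters)
  structure(list(name = name, hyperparameters = hp,
                 class_weighted = isTRUE(class_weighted)),
            class = "model_spec")
}

#' The fixed classifier menu
#' @return Character vector of the eight menu entries.
#' @export
model_menu <- function() {
  c("gradient_boosting", "sgd", "mlp", "knn", "bernoulli_nb",
    "random_forest", "logistic_regression", "svm")
}

#' Default hyperparameters per menu entry
#' @param name Menu entry.
#' @return Named list of defaults.
#' @export
default_hyperparameters <- function(name) {
  switch(name,
    gradient_boosting = list(nrounds = 100, eta = 0.1, max_depth = 3,
                             subsample = 1, colsample_bytree = 1),
    sgd = list(loss = "hinge", alpha = 1e-4, penalty = "elasticnet",
               l1_ratio = 0.15, learning_rate = "optimal", eta0 = 0.01,
               power_t = 0.5, fit_intercept = TRUE, epochs = 50),
    mlp = list(size = 5, alpha = 1e-4, maxit = 200),
    knn = list(k = 5),
    bernoulli_nb = list(alpha = 1, binarize = 0.5, fit_prior = TRUE),
    random_forest = list(num_trees = 300, mtry_frac = NA_real_),
    logistic_regression = list(lambda = 1e-3),
    svm = list(kernel = "radial", cost = 1),
    majority = list(),
    eg_abort(paste0("unknown classifier: ", name), "invalid_parameter"))
}

# encode labels: returns list(y factor with levels c(neg, pos), pos, neg)
.encode_labels <- function(y, positive = "HGG") {
  y <- as.character(y)
  cls <- sort(unique(y))
  if (length(cls) != 2L) eg_abort("need exactly two classes", "invalid_labels")
  pos <- if (positive %in% cls) positive else cls[2]
  neg <- setdiff(cls, pos)
  list(y = factor(y, levels = c(neg, pos)), pos = pos, neg = neg)
}

# elastic-net linear classifier trained by stochastic (sub)gradient descent;
# mirrors the usual SGD conventions: hinge or logistic loss, penalty
# alpha*(l1_ratio*|w|_1 + (1-l1_ratio)/2*|w|_2^2), learning-rate schedules
# constant, invscaling (eta0/t^power_t) and optimal (1/(alpha*(t+t0))).
.fit_sgd <- function(X, y01, sw, hp, seed) {
  yy <- ifelse(y01 == 1, 1, -1)
  n <- nrow(X); p <- ncol(X)
  w <- rep(0, p); b <- 0
  t <- 0; t0 <- 1
  logloss <- identical(hp$loss, "log")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  for (ep in seq_len(hp$epochs)) {
    for (i in sample.int(n)) {
      t <- t + 1
      eta <- switch(hp$learning_rate,
                    constant = hp$eta0,
                    invscaling = hp$eta0 / t^hp$power_t,
                    optimal = 1 / (hp$alpha * (t + t0)),
                    hp$eta0)
      f <- sum(w * X[i, ]) + b
      g <- if (logloss) -yy[i] / (1 + exp(yy[i] * f))
           else if (yy[i] * f < 1) -yy[i] else 0
      g <- g * sw[i]
      w <- w - eta * (g * X[i, ] +
                        hp$alpha * (hp$l1_ratio * sign(w) + (1 - hp$l1_ratio) * w))
      if (isTRUE(hp$fit_intercept)) b <- b - eta * g
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(w = w, b = b)
}

.fit_bernoulli_nb <- function(X, y01, sw, hp) {
  B <- (X > hp$binarize) * 1
  w1 <- sw * (y01 == 1); w0 <- sw * (y01 == 0)
  n1 <- sum(w1); n0 <- sum(w0)
  th1 <- (colSums(B * w1) + hp$alpha) / (n1 + 2 * hp$alpha)
  th0 <- (colSums(B * w0) + hp$alpha) / (n0 + 2 * hp$alpha)
  prior <- if (isTRUE(hp$fit_prior)) c(n0, n1) / (n0 + n1) else c(0.5, 0.5)
  list(th0 = th0, th1 = th1, prior = prior, binarize = hp$binarize)
}

.predict_bernoulli_nb <- function(fit, X) {
  B <- (X > fit$binarize) * 1
  l1 <- B %*% log(fit$th1) + (1 - B) %*% log(1 - fit$th1) + log(fit$prior[2])
  l0 <- B %*% log(fit$th0) + (1 - B) %*% log(1 - fit$th0) + log(fit$prior[1])
  as.numeric(l1 - l0)
}

# fit one classifier; returns list(score = function(Xnew) numeric)
fit_classifier <- function(spec, X, y, seed = 1L, positive = "HGG") {
  enc <- .encode_labels(y, positive)
  y01 <- as.numeric(enc$y == enc$pos)
  cw <- if (spec$class_weighted) class_weights(as.character(enc$y)) else
    setNames(c(1, 1), levels(enc$y))
  sw <- unname(cw[as.character(enc$y)])
  hp <- spec$hyperparameters
  X <- as.matrix(X)
  score_fun <- switch(spec$name,
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y01, weight = sw)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = hp$eta,
                      max_depth = hp$max_depth, subsample = hp$subsample,
                      colsample_bytree = hp$colsample_bytree,
                      nthread = 1L, seed = seed),
        data = dtrain, nrounds = hp$nrounds, verbose = 0)
      function(Xn) predict(fit, xgboost::xgb.DMatrix(as.matrix(Xn))) - 0.5
    },
    sgd = {
      fit <- .fit_sgd(X, y01, sw, hp, seed)
      function(Xn) as.numeric(as.matrix(Xn) %*% fit$w + fit$b)
    },
    mlp = {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(seed)
      fit <- nnet::nnet(X, y01, size = hp$size, decay = hp$alpha,
                        maxit = hp$maxit, weights = sw, entropy = TRUE,
                        trace = FALSE,
                        MaxNWts = hp$size * (ncol(X) + 2) + 1000)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      function(Xn) as.numeric(predict(fit, as.matrix(Xn))) - 0.5
    },
    knn = {
      # k nearest neighbours with class-weighted votes: under inverse-frequency
      # weights the two classes contribute equal total vote mass, so an
      # uninformative neighbourhood scores near 0 even on imbalanced cohorts
      k <- min(hp$k, nrow(X))
      wv <- sw
      pos <- as.numeric(enc$y == enc$pos)
      tr_sq <- rowSums(X^2)
      function(Xn) {
        Xn <- as.matrix(Xn)
        d2 <- outer(rowSums(Xn^2), tr_sq, `+`) - 2 * Xn %*% t(X)
        apply(d2, 1, function(dr) {
          nb <- order(dr)[seq_len(k)]
          sum(wv[nb] * pos[nb]) / sum(wv[nb]) - 0.5
        })
      }
    },
    bernoulli_nb = {
      fit <- .fit_bernoulli_nb(X, y01, sw, hp)
      function(Xn) .predict_bernoulli_nb(fit, as.matrix(Xn))
    },
    random_forest = {
      mtry <- if (is.na(hp$mtry_frac)) NULL else
        max(1L, floor(hp$mtry_frac * ncol(X)))
      df <- data.frame(X, check.names = FALSE)
      fit <- ranger::ranger(x = df, y = enc$y, num.trees = hp$num_trees,
                            mtry = mtry, probability = TRUE, seed = seed,
                            num.threads = 1L,
                            class.weights = if (spec$class_weighted)
                              unname(cw[levels(enc$y)]) else NULL)
      function(Xn) predict(fit, data.frame(as.matrix(Xn), check.names = FALSE),
                           num.threads = 1L)$predictions[, enc$pos] - 0.5
    },
    logistic_regression = {
      pad <- ncol(X) < 2  # glmnet requires at least two predictors
      Xl <- if (pad) cbind(X, .pad0 = 0) else X
      fit <- glmnet::glmnet(Xl, enc$y, family = "binomial", alpha = 0,
                            lambda = hp$lambda, weights = sw,
                            standardize = FALSE)
      function(Xn) {
        Xn <- as.matrix(Xn)
        if (pad) Xn <- cbind(Xn, .pad0 = 0)
        as.numeric(predict(fit, Xn, type = "link"))
      }
    },
    svm = {
      fit <- e1071::svm(X, enc$y, kernel = hp$kernel, cost = hp$cost,
                        class.weights = if (spec$class_weighted)
                          cw[levels(enc$y)] else NULL, scale = FALSE)
      # e1071 labels decision values "A/B": positive score favours A
      dv_name <- colnames(attr(predict(fit, X[1, , drop = FALSE],
                                       decision.values = TRUE),
                               "decision.values"))[1]
      flip <- !startsWith(dv_name, paste0(enc$pos, "/"))
      function(Xn) {
        dv <- attr(predict(fit, as.matrix(Xn), decision.values = TRUE),
                   "decision.values")[, 1]
        if (flip) -dv else dv
      }
    },
    majority = {
      maj <- names(which.max(table(as.character(enc$y))))
      function(Xn) rep(if (maj == enc$pos) 0.5 else -0.5, nrow(as.matrix(Xn)))
    })
  structure(list(spec = spec, score = score_fun, positive = enc$pos,
                 negative = enc$neg), class = "fitted_classifier")
}

#' @export
predict.fitted_classifier <- function(object, newdata, type = c("class", "score"), ...) {
  sc <- object$score(newdata)
  if (match.arg(type) == "score") return(sc)
  ifelse(sc >= 0, object$positive, object$negative)
}

# seeded random hyperparameter draw within documented ranges
sample_hyperparameters <- function(name, rng) {
  ru <- function(lo, hi) lo + (hi - lo) * rng()
  rlog <- function(lo, hi) exp(log(lo) + (log(hi) - log(lo)) * rng())
  pick <- function(v) v[[ceiling(rng() * length(v))]]
  switch(name,
    gradient_boosting = list(nrounds = pick(c(50, 100, 200)),
                             eta = rlog(0.01, 0.5),
                             max_depth = pick(2:8),
                             subsample = ru(0.5, 1), colsample_bytree = ru(0.5, 1)),
    sgd = list(loss = pick(c("hinge", "log")), alpha = rlog(1e-4, 1e-1),
               penalty = "elasticnet", l1_ratio = ru(0, 1),
               learning_rate = pick(c("constant", "invscaling", "optimal")),
               eta0 = rlog(1e-3, 1e-1), power_t = ru(0.1, 1),
               fit_intercept = TRUE, epochs = 50),
    mlp = list(size = pick(2:10), alpha = rlog(1e-4, 1e-1), maxit = 200),
    knn = list(k = pick(seq(3, 41, by = 2))),
    bernoulli_nb = list(alpha = rlog(0.01, 100), binarize = 0.5,
                        fit_prior = pick(c(TRUE, FALSE))),
    random_forest = list(num_trees = pick(c(200, 300, 500)),
                         mtry_frac = ru(0.1, 1)),
    logistic_regression = list(lambda = rlog(1e-4, 1)),
    svm = list(kernel = pick(c("linear", "radial")), cost = rlog(0.01, 10)),
    list())
}
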