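test_that("class weights follow n / (2 * n_c)", {
  w <- class_weights(c(rep("HGG", 81), rep("LGG", 19)))
  expect_equal(unname(w["HGG"]), 100 / 162)
  expect_equal(unname(w["LGG"]), 100 / 38)
  expect_gt(w["LGG"], w["HGG"])   # minority gets the larger weight
  wb <- class_weights(rep(c("HGG", "LGG"), 25))
  expect_equal(unname(wb), c(1, 1))
  # weighted class sizes sum to n
  y <- c(rep("HGG", 81), rep("LGG", 19))
  expect_equal(sum(class_weights(y)[y]), 100)
  expect_error(class_weights(rep("HGG", 5)), class = "invalid_labels")
})

test_that("evaluation matches hand-counted confusion arithmetic", {
  ev <- evaluate_predictions(
    y_true = c("HGG", "HGG", "HGG", "LGG", "LGG"),
    y_pred = c("HGG", "HGG", "LGG", "HGG", "LGG"))
  expect_equal(unname(ev$metrics["accuracy"]), 3 / 5)
  expect_equal(unname(ev$metrics["precision"]), 2 / 3)
  expect_equal(unname(ev$metrics["recall"]), 2 / 3)
  expect_equal(unname(ev$metrics["f1"]), 2 / 3)
  expect_equal(as.vector(ev$confusion), c(1, 1, 1, 2))  # (LGG,HGG) ordering
  expect_equal(sum(ev$confusion), 5)
  # perfect ranking
  ev2 <- evaluate_predictions(c("HGG", "HGG", "LGG", "LGG"),
                              c("HGG", "HGG", "LGG", "LGG"),
                              c(0.9, 0.8, 0.3, 0.2))
  expect_equal(unname(ev2$metrics["auc"]), 1)
  expect_equal(sum(ev2$confusion[row(ev2$confusion) != col(ev2$confusion)]), 0)
  expect_warning(
    evp <- evaluate_predictions(c("HGG", "LGG"), c("LGG", "LGG")),
    "precision")
  expect_equal(unname(evp$metrics["precision"]), 0)
  expect_error(evaluate_predictions("HGG", c("HGG", "LGG")), class = "invalid_input")
})

test_that("AUC is the tie-averaged rank statistic, invariant to monotone maps", {
  set.seed(12)
  y <- rep(c("HGG", "LGG"), each = 30)
  s <- rnorm(60) + (y == "HGG")
  a1 <- evaluate_predictions(y, ifelse(s > 0, "HGG", "LGG"), s)$metrics["auc"]
  a2 <- evaluate_predictions(y, ifelse(s > 0, "HGG", "LGG"), exp(3 * s))$metrics["auc"]
  expect_equal(a1, a2)
  # cross-check against an independent implementation
  skip_if_not_installed("pROC")
  a_ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                          levels = c("LGG", "HGG"),
                                          direction = "<", quiet = TRUE)))
  expect_equal(unname(a1), a_ref, tolerance = 1e-12)
})

test_that("cross-validation is stratified, deterministic and reports pooled truth", {
  set.seed(13)
  n <- 120
  y <- c(rep("HGG", 90), rep("LGG", 30))
  X <- data.frame(f1 = as.numeric(y == "HGG") + rnorm(n, 0, 0.25),
                  f2 = rnorm(n))
  spec <- model_spec("logistic_regression")
  r1 <- cross_validate(X, y, spec, k = 10, seed = 4)
  r2 <- cross_validate(X, y, spec, k = 10, seed = 4)
  expect_identical(r1$mean_metrics, r2$mean_metrics)
  expect_identical(r1$confusion, r2$confusion)
  # pooled confusion row sums equal the true class counts
  expect_equal(unname(rowSums(r1$confusion)), c(30, 90))
  expect_gte(unname(r1$mean_metrics["accuracy"]), 0.9)
  expect_equal(nrow(tidy(r1)), 10)
  expect_s3_class(glance(r1), "tbl_df")
  # fold reduction path when the minority class is smaller than k
  ys <- c(rep("HGG", 30), rep("LGG", 5))
  Xs <- data.frame(f = rnorm(35), g = rnorm(35))
  expect_warning(rs <- cross_validate(Xs, ys, spec, k = 10, seed = 1),
                 "folds reduced")
  expect_equal(rs$k, 5)
})

test_that("permuted labels drive CV accuracy to chance", {
  set.seed(14)
  n <- 100
  X <- data.frame(matrix(rnorm(n * 20), n))
  accs <- vapply(1:10, function(s) {
    y <- sample(rep(c("HGG", "LGG"), each = n / 2))
    unname(cross_validate(X, y, model_spec("logistic_regression"),
                          k = 5, seed = s)$mean_metrics["accuracy"])
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("every menu entry trains and scores, and weighting is a no-op when balanced", {
  set.seed(15)
  n <- 60
  y <- rep(c("HGG", "LGG"), each = n / 2)
  X <- data.frame(f1 = as.numeric(y == "HGG") + rnorm(n, 0, 0.4),
                  f2 = rnorm(n))
  for (nm in model_menu()) {
    fit <- fit_classifier(model_spec(nm), X, y, seed = 2)
    sc <- fit$score(X)
    expect_true(all(is.finite(sc)), info = nm)
    expect_gte(suppressWarnings(
      evaluate_predictions(y, predict(fit, X), sc)$metrics["auc"]), 0.6)
  }
  # balanced data: weighted and unweighted linear fits coincide
  f_w <- fit_classifier(model_spec("logistic_regression", class_weighted = TRUE),
                        X, y, seed = 3)
  f_u <- fit_classifier(model_spec("logistic_regression", class_weighted = FALSE),
                        X, y, seed = 3)
  expect_equal(f_w$score(X), f_u$score(X), tolerance = 1e-8)
})

test_that("model search ranks by accuracy and honours its budget", {
  set.seed(16)
  n <- 80
  y <- rep(c("HGG", "LGG"), each = n / 2)
  X <- data.frame(f1 = as.numeric(y == "HGG") + rnorm(n, 0, 0.2))
  ms <- model_search(X, y, menu = c("majority", "gradient_boosting"),
                     budget = 2, k = 5, seed = 6)
  expect_equal(ms$best_spec$name, "gradient_boosting")
  expect_equal(nrow(ms$leaderboard), 2)   # exactly one config per model
  expect_error(model_search(X, y, menu = character(0)), class = "invalid_parameter")
  expect_error(model_search(X, y, menu = model_menu(), budget = 2),
               class = "invalid_parameter")
})

test_that("the published SGD preset loads and trains on phantom-like features", {
  presets <- paper_presets()
  sgd <- presets$paper_t1gd_flair_sgd
  expect_equal(sgd$name, "sgd")
  expect_equal(sgd$hyperparameters$alpha, 0.001)
  expect_equal(sgd$hyperparameters$eta0, 0.01)
  expect_equal(sgd$hyperparameters$l1_ratio, 0.25)
  expect_equal(sgd$hyperparameters$learning_rate, "invscaling")
  expect_equal(sgd$hyperparameters$power_t, 0.1)
  set.seed(17)
  n <- 60
  y <- rep(c("HGG", "LGG"), c(48, 12))
  X <- data.frame(f1 = as.numeric(y == "HGG") + rnorm(n, 0, 0.3),
                  f2 = runif(n))
  rep_sgd <- cross_validate(X, y, sgd, k = 5, seed = 7)
  expect_true(all(is.finite(rep_sgd$mean_metrics)))
  expect_gte(unname(rep_sgd$mean_metrics["accuracy"]), 0.7)
})
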