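#' Benchmark configuration
#'
#' @param modelNames classifier panel to benchmark; defaults to all ten
#'   registered families. Panel members whose backend package is not
#'   installed are skipped at run time with a warning.
#' @param fractions training fractions of the non-holdout pool (default
#'   0.1, 0.2, ..., 1.0 — the equal-interval learning curve).
#' @param holdoutFraction stratified holdout drawn once and reused as the
#'   test set for every fraction (default 0.3).
#' @param seed master seed for the splits and model fits.
#' @param positiveLabel label treated as the positive class.
#' @param classWeight `"none"` (default) or `"balanced"`; applied where a
#'   backend supports observation weights and recorded in the report.
#' @param threshold probability cut for accuracy/F1 (default 0.5).
#' @return a list of class `benchConfig`.
#' @export
benchConfig <- function(modelNames = names(modelRegistry()),
                        fractions = seq(0.1, 1, by = 0.1),
                        holdoutFraction = 0.3, seed = 0L,
                        positiveLabel = "HC_HYPOXIC",
                        classWeight = c("none", "balanced"),
                        threshold = 0.5) {
  classWeight <- match.arg(classWeight)
  stopifnot(length(modelNames) >= 1L, all(fractions > 0), all(fractions <= 1),
            holdoutFraction > 0, holdoutFraction < 1)
  unknown <- setdiff(modelNames, names(modelRegistry()))
  if (length(unknown))
    stop(sprintf("unknown model(s): %s", paste(unknown, collapse = ", ")))
  structure(list(modelNames = modelNames, fractions = fractions,
                 holdoutFraction = holdoutFraction, seed = as.integer(seed),
                 positiveLabel = positiveLabel, classWeight = classWeight,
                 threshold = threshold),
            class = "benchConfig")
}

.obsWeights <- function(y, classWeight) {
  if (classWeight != "balanced") return(rep(1, length(y)))
  n1 <- sum(y); n0 <- length(y) - n1
  ifelse(y == 1, length(y) / (2 * n1), length(y) / (2 * n0))
}

#' The classifier registry
#'
#' Maps the ten benchmark model families to their R backends. Each entry has
#' `available()`, `fit(X, y, seed, weights)` and `predict(fit, X)` (returning
#' the positive-class probability). Families without an installed backend
#' are skipped by [runBenchmark()] with a warning.
#'
#' @return named list of registry entries.
#' @export
modelRegistry <- function() {
  reg <- list()
  reg$logistic_regression <- list(
    available = function() TRUE,
    fit = function(X, y, seed, w) {
      df <- data.frame(.y = y, X, check.names = FALSE)
      suppressWarnings(glm(.y ~ ., data = df, family = binomial(),
                           weights = w))
    },
    predict = function(fit, X) {
      suppressWarnings(unname(predict(fit,
        newdata = data.frame(X, check.names = FALSE), type = "response")))
    })
  reg$linear_svm <- list(
    available = function() requireNamespace("e1071", quietly = TRUE),
    fit = function(X, y, seed, w) {
      .withSeed(seed, function()
        suppressWarnings(e1071::svm(x = X, y = factor(y, 0:1),
                                    kernel = "linear", probability = TRUE,
                                    scale = TRUE)))
    },
    predict = function(fit, X) {
      p <- predict(fit, X, probability = TRUE)
      unname(attr(p, "probabilities")[, "1"])
    })
  reg$random_forest <- list(
    available = function() requireNamespace("ranger", quietly = TRUE),
    fit = function(X, y, seed, w) {
      ranger::ranger(x = X, y = factor(y, 0:1), probability = TRUE,
                     num.trees = 200, seed = seed, num.threads = 1,
                     case.weights = w)
    },
    predict = function(fit, X)
      unname(predict(fit, data = X, num.threads = 1)$predictions[, "1"]))
  reg$decision_tree <- list(
    available = function() requireNamespace("rpart", quietly = TRUE),
    fit = function(X, y, seed, w) {
      df <- data.frame(.y = factor(y, 0:1), X, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class", weights = w)
    },
    predict = function(fit, X)
      unname(predict(fit, newdata = data.frame(X, check.names = FALSE),
                     type = "prob")[, "1"]))
  reg$naive_bayes <- list(
    available = function() requireNamespace("e1071", quietly = TRUE),
    fit = function(X, y, seed, w) {
      fit <- e1071::naiveBayes(x = as.data.frame(X), y = factor(y, 0:1))
      # floor per-class sds so constant features cannot yield NaN densities
      sdFloor <- 1e-6 * mean(apply(X, 2, sd)) + 1e-12
      fit$tables <- lapply(fit$tables, function(tb) {
        tb[, 2] <- pmax(tb[, 2], sdFloor); tb
      })
      fit
    },
    predict = function(fit, X)
      unname(predict(fit, as.data.frame(X), type = "raw")[, "1"]))
  reg$mlp <- list(
    available = function() requireNamespace("nnet", quietly = TRUE),
    fit = function(X, y, seed, w) {
      ctr <- colMeans(X)
      scl <- pmax(apply(X, 2, sd), 1e-8)
      Xs <- scale(X, ctr, scl)
      net <- .withSeed(seed, function()
        nnet::nnet(x = Xs, y = y, size = 8, decay = 1e-3, maxit = 100,
                   entropy = TRUE, trace = FALSE, MaxNWts = 1e5))
      list(net = net, ctr = ctr, scl = scl)
    },
    predict = function(fit, X)
      as.numeric(predict(fit$net, scale(X, fit$ctr, fit$scl))))
  .xgbFit <- function(X, y, seed, w, eta, depth) {
    d <- xgboost::xgb.DMatrix(X, label = y, weight = w)
    xgboost::xgb.train(params = list(objective = "binary:logistic",
                                     eta = eta, max_depth = depth,
                                     nthread = 1, seed = seed),
                       data = d, nrounds = 100, verbose = 0)
  }
  reg$extreme_gradient_boosting <- list(
    available = function() requireNamespace("xgboost", quietly = TRUE),
    fit = function(X, y, seed, w) .xgbFit(X, y, seed, w, 0.3, 6),
    predict = function(fit, X) predict(fit, xgboost::xgb.DMatrix(X)))
  reg$gradient_boosted_trees <- list(
    available = function() requireNamespace("xgboost", quietly = TRUE),
    # classic gradient boosting machine settings: shallow trees, slow rate
    fit = function(X, y, seed, w) .xgbFit(X, y, seed, w, 0.1, 3),
    predict = function(fit, X) predict(fit, xgboost::xgb.DMatrix(X)))
  reg$light_gradient_boosting <- list(
    available = function() requireNamespace("lightgbm", quietly = TRUE),
    fit = function(X, y, seed, w) {
      d <- lightgbm::lgb.Dataset(X, label = y, weight = w)
      lightgbm::lgb.train(params = list(objective = "binary",
                                        num_threads = 1, seed = seed,
                                        verbosity = -1),
                          data = d, nrounds = 100)
    },
    predict = function(fit, X) as.numeric(predict(fit, X)))
  reg$categorical_boosting <- list(
    available = function() requireNamespace("catboost", quietly = TRUE),
    fit = function(X, y, seed, w) {
      pool <- catboost::catboost.load_pool(X, label = y, weight = w)
      catboost::catboost.train(pool, params = list(
        loss_function = "Logloss", random_seed = seed, logging_level =
          "Silent"))
    },
    predict = function(fit, X)
      catboost::catboost.predict(fit, catboost::catboost.load_pool(X),
                                 prediction_type = "Probability"))
  reg
}

#' Stratified learning-curve splits
#'
#' One stratified holdout of `holdoutFraction` is drawn once (seeded) and
#' reused as the test set for every training fraction. For each fraction
#' `f`, the training set is an independent seeded stratified draw from the
#' remaining pool with per-class sizes `floor(f * poolClass)` (at least 1
#' per class).
#'
#' @param labels named logical (or 0/1) vector: TRUE for the positive class.
#' @param cfg a [benchConfig()].
#' @return list of `list(fraction, train, test)` with cell-id vectors.
#' @export
equalIntervalSplits <- function(labels, cfg) {
  stopifnot(inherits(cfg, "benchConfig"), !is.null(names(labels)))
  y <- as.logical(labels)
  ids <- names(labels)
  pos <- ids[y]; neg <- ids[!y]
  if (length(pos) < 10L || length(neg) < 10L)
    stop("need at least 10 cells per class")
  .withSeed(cfg$seed, function() {
    testPos <- sample(pos, floor(cfg$holdoutFraction * length(pos)))
    testNeg <- sample(neg, floor(cfg$holdoutFraction * length(neg)))
    test <- c(sort(testPos), sort(testNeg))
    poolPos <- setdiff(pos, testPos)
    poolNeg <- setdiff(neg, testNeg)
    lapply(cfg$fractions, function(f) {
      nP <- max(1L, floor(f * length(poolPos)))
      nN <- max(1L, floor(f * length(poolNeg)))
      train <- c(sort(sample(poolPos, nP)), sort(sample(poolNeg, nN)))
      if (length(train) < 2L)
        stop(sprintf("fraction %.2f yields fewer than 2 training cells", f))
      list(fraction = f, train = train, test = test)
    })
  })
}

#' Accuracy, AUROC and F1 for probability scores
#'
#' AUROC uses the rank (Mann-Whitney) formulation with ties credited 0.5;
#' accuracy and F1 (positive class) are computed at the threshold, calling a
#' cell positive when its score is strictly greater than the threshold.
#' With single-class truth the AUROC is undefined and reported as `NA` with
#' a warning.
#'
#' @param truth logical or 0/1 vector.
#' @param scoreVec numeric scores, higher = more positive.
#' @param threshold classification cut (default 0.5).
#' @return list with `accuracy`, `auroc`, `f1`.
#' @export
evaluateScores <- function(truth, scoreVec, threshold = 0.5) {
  y <- as.integer(as.logical(truth))
  stopifnot(length(y) == length(scoreVec))
  n1 <- sum(y); n0 <- length(y) - n1
  if (n1 == 0L || n0 == 0L) {
    warning("single-class truth: AUROC undefined")
    auroc <- NA_real_
  } else {
    r <- rank(scoreVec)
    auroc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  pred <- as.integer(scoreVec > threshold)
  acc <- mean(pred == y)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  list(accuracy = acc, auroc = auroc, f1 = f1)
}

#' Average-rank model selection
#'
#' Ranks models per metric within every (fraction, dataset) condition,
#' averages ranks per model and metric, and returns the model minimising the
#' mean of the three per-metric average ranks (ties broken by AUROC rank,
#' then name). Also reports the intersection of the models ranked in the
#' top 3 for every metric on average.
#'
#' @param results benchmark results data.frame (see
#'   [BenchmarkReport-class]).
#' @param selectionMode feature mode used for selection (default
#'   `"embedding"`; falls back to all rows when absent).
#' @return list with `meanRanks` (data.frame), `top3Intersection`,
#'   `selectedModel`.
#' @export
rankAndSelect <- function(results, selectionMode = "embedding") {
  sub <- results[!is.na(results$auroc), , drop = FALSE]
  if (selectionMode %in% sub$feature_mode)
    sub <- sub[sub$feature_mode == selectionMode, , drop = FALSE]
  if (!nrow(sub)) stop("no benchmark rows to rank")
  cond <- interaction(sub$fraction, sub$dataset, drop = TRUE)
  metrics <- c("accuracy", "auroc", "f1")
  models <- sort(unique(sub$model))
  perMetric <- matrix(NA_real_, length(models), length(metrics),
                      dimnames = list(models, metrics))
  for (m in metrics) {
    rk <- stats::ave(-sub[[m]], cond, FUN = function(v)
      rank(v, ties.method = "average"))
    agg <- tapply(rk, sub$model, mean)
    perMetric[names(agg), m] <- agg
  }
  meanRank <- rowMeans(perMetric)
  topPerMetric <- lapply(metrics, function(m) {
    r <- rank(perMetric[, m], ties.method = "min")
    models[r <= 3]
  })
  top3 <- Reduce(intersect, topPerMetric)
  ord <- order(meanRank, perMetric[, "auroc"], models, method = "radix")
  mr <- data.frame(model = models,
                   accuracy_rank = unname(perMetric[, "accuracy"]),
                   auroc_rank = unname(perMetric[, "auroc"]),
                   f1_rank = unname(perMetric[, "f1"]),
                   mean_rank = unname(meanRank),
                   stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(mr) <- NULL
  list(meanRanks = mr, top3Intersection = sort(top3),
       selectedModel = models[ord][1L])
}

.binaryLabels <- function(labels, positiveLabel = "HC_HYPOXIC") {
  if (is(labels, "HypoxiaLabels")) {
    st <- status(labels)
    st <- st[st != "LOW_CONF"]
    stats::setNames(st == positiveLabel, names(st))
  } else {
    stopifnot(!is.null(names(labels)))
    stats::setNames(as.logical(labels), names(labels))
  }
}

#' Train one classifier on a feature matrix
#'
#' @param modelName a registry model name.
#' @param features a [FeatureMatrix-class].
#' @param labels a [HypoxiaLabels-class] (high-confidence cells used) or a
#'   named logical vector.
#' @param seed integer seed.
#' @param classWeight `"none"` or `"balanced"`.
#' @return an object of class `hypoxiaClassifier`.
#' @export
trainClassifier <- function(modelName, features, labels, seed = 0L,
                            classWeight = "none") {
  reg <- modelRegistry()
  stopifnot(modelName %in% names(reg), is(features, "FeatureMatrix"))
  entry <- reg[[modelName]]
  if (!entry$available())
    stop(sprintf("backend for '%s' is not installed", modelName))
  yb <- .binaryLabels(labels)
  ids <- intersect(names(yb), cellIds(features))
  X <- featureValues(features)[ids, , drop = FALSE]
  y <- as.integer(yb[ids])
  fit <- entry$fit(X, y, as.integer(seed), .obsWeights(y, classWeight))
  structure(list(name = modelName, fit = fit, predictFun = entry$predict,
                 d = ncol(X), featureMode = featureMode(features),
                 seed = as.integer(seed)),
            class = "hypoxiaClassifier")
}

#' Learning-curve benchmark across models, feature modes and fractions
#'
#' Every available model is trained on each stratified training fraction of
#' each feature matrix and scored (accuracy, AUROC, F1) on the fixed
#' internal holdout plus any extra validation sets. Models are then ranked
#' per metric, averaged, and the best mean-rank model on embedding features
#' is selected; paired embedding-minus-raw metric deltas are reported when
#' both modes are present.
#'
#' @param featuresByMode named list of [FeatureMatrix-class] objects, e.g.
#'   `list(embedding = ..., raw_counts = ...)`; all must cover the labeled
#'   cells.
#' @param labels a [HypoxiaLabels-class] or named logical vector (TRUE =
#'   positive class).
#' @param cfg a [benchConfig()].
#' @param extraValidation optional list of
#'   `list(featuresByMode =, truth =, tag =)` external evaluation sets.
#' @return a [BenchmarkReport-class].
#' @export
runBenchmark <- function(featuresByMode, labels, cfg = benchConfig(),
                         extraValidation = NULL) {
  stopifnot(inherits(cfg, "benchConfig"), length(featuresByMode) >= 1L)
  yb <- .binaryLabels(labels, cfg$positiveLabel)
  reg <- modelRegistry()
  avail <- vapply(cfg$modelNames, function(nm) reg[[nm]]$available(),
                  logical(1))
  if (any(!avail))
    warning(sprintf("skipping model(s) without an installed backend: %s",
                    paste(cfg$modelNames[!avail], collapse = ", ")))
  models <- cfg$modelNames[avail]
  if (!length(models)) stop("no model backend available")

  mats <- lapply(featuresByMode, function(fm) {
    stopifnot(is(fm, "FeatureMatrix"))
    missing <- setdiff(names(yb), cellIds(fm))
    if (length(missing))
      stop(sprintf("feature matrix misses %d labeled cells",
                   length(missing)))
    featureValues(fm)[names(yb), , drop = FALSE]
  })
  modeOf <- vapply(featuresByMode, featureMode, character(1))
  splits <- equalIntervalSplits(yb, cfg)

  rows <- list()
  for (sp in splits) {
    f <- sp$fraction
    for (mi in seq_along(models)) {
      nm <- models[mi]
      mseed <- (cfg$seed + 131L * mi + as.integer(round(1000 * f))) %%
        2147483647L
      for (fmName in names(mats)) {
        X <- mats[[fmName]]
        ytr <- as.integer(yb[sp$train])
        fit <- reg[[nm]]$fit(X[sp$train, , drop = FALSE], ytr, mseed,
                             .obsWeights(ytr, cfg$classWeight))
        evalSets <- c(list(list(X = X[sp$test, , drop = FALSE],
                                truth = yb[sp$test], tag = "holdout")),
                      lapply(extraValidation, function(ev) {
                        fm2 <- ev$featuresByMode[[fmName]]
                        list(X = featureValues(fm2)[names(ev$truth), ,
                                                    drop = FALSE],
                             truth = ev$truth, tag = ev$tag)
                      }))
        for (es in evalSets) {
          sc <- reg[[nm]]$predict(fit, es$X)
          mt <- evaluateScores(es$truth, sc, cfg$threshold)
          rows[[length(rows) + 1L]] <- data.frame(
            model = nm, feature_mode = modeOf[[fmName]], fraction = f,
            dataset = es$tag, accuracy = mt$accuracy, auroc = mt$auroc,
            f1 = mt$f1, stringsAsFactors = FALSE)
        }
      }
    }
  }
  results <- do.call(rbind, rows)

  deltas <- data.frame()
  if (all(c("embedding", "raw_counts") %in% results$feature_mode)) {
    emb <- results[results$feature_mode == "embedding", ]
    raw <- results[results$feature_mode == "raw_counts", ]
    deltas <- merge(emb, raw, by = c("model", "fraction", "dataset"),
                    suffixes = c("_embedding", "_raw"))
    for (m in c("accuracy", "auroc", "f1"))
      deltas[[paste0("delta_", m)]] <-
        deltas[[paste0(m, "_embedding")]] - deltas[[paste0(m, "_raw")]]
    deltas <- deltas[c("model", "fraction", "dataset", "delta_accuracy",
                       "delta_auroc", "delta_f1")]
  }
  sel <- rankAndSelect(results, "embedding")
  new("BenchmarkReport", results = results, meanRanks = sel$meanRanks,
      top3Intersection = sel$top3Intersection,
      selectedModel = sel$selectedModel, deltas = deltas,
      config = unclass(cfg))
}

#' Predict the hypoxic state of low-confidence cells
#'
#' Applies a trained classifier to the feature rows of low-confidence cells
#' and thresholds the positive-class probability: strictly greater than the
#' threshold is `HYPOXIC`, otherwise `NORMOXIC` (a probability of exactly
#' the threshold is called `NORMOXIC`).
#'
#' @param model a `hypoxiaClassifier` from [trainClassifier()].
#' @param features a [FeatureMatrix-class] for the cells to classify, with
#'   the same feature mode and dimensionality the model was trained on.
#' @param threshold probability cut (default 0.5).
#' @return data.frame with `cell_id`, `probability`, `predicted_status`.
#' @export
classifyLowConfidence <- function(model, features, threshold = 0.5) {
  stopifnot(inherits(model, "hypoxiaClassifier"),
            is(features, "FeatureMatrix"))
  X <- featureValues(features)
  if (ncol(X) != model$d)
    stop(sprintf("dimensionality mismatch: model expects %d features, got %d",
                 model$d, ncol(X)))
  p <- model$predictFun(model$fit, X)
  data.frame(cell_id = rownames(X), probability = as.numeric(p),
             predicted_status = ifelse(p > threshold, "HYPOXIC", "NORMOXIC"),
             stringsAsFactors = FALSE)
}
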