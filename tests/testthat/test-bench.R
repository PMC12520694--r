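test_that("stratified split arithmetic matches the worked example", {
  y <- stats::setNames(c(rep(TRUE, 20), rep(FALSE, 80)),
                       sprintf("c%03d", 1:100))
  cfg <- benchConfig(modelNames = "logistic_regression",
                     fractions = c(0.5, 1.0), holdoutFraction = 0.3,
                     seed = 1)
  sp <- equalIntervalSplits(y, cfg)
  expect_length(sp[[1]]$test, 30L)
  expect_equal(sum(y[sp[[1]]$test]), 6)          # 6 positives in holdout
  expect_length(sp[[1]]$train, 35L)              # f = 0.5 of the 70 pool
  expect_equal(sum(y[sp[[1]]$train]), 7)
  expect_length(sp[[2]]$train, 70L)              # f = 1.0 takes the pool
  expect_identical(sp[[1]]$test, sp[[2]]$test)   # holdout fixed across f

  # determinism and stratification under reseeding
  sp2 <- equalIntervalSplits(y, cfg)
  expect_identical(sp, sp2)
  cfg3 <- benchConfig(modelNames = "logistic_regression",
                      fractions = c(0.5, 1.0), holdoutFraction = 0.3,
                      seed = 2)
  sp3 <- equalIntervalSplits(y, cfg3)
  expect_false(identical(sp3[[1]]$train, sp[[1]]$train))
  expect_equal(sum(y[sp3[[1]]$train]), 7)        # proportions preserved
})

test_that("metric computation matches the worked 4-cell example", {
  m <- evaluateScores(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.2))
  expect_equal(m$auroc, 0.75)
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$f1, 0.5)

  perfect <- evaluateScores(c(0, 1, 1), c(0.1, 0.8, 0.9))
  expect_equal(unlist(perfect), c(accuracy = 1, auroc = 1, f1 = 1))

  flat <- evaluateScores(c(1, 0, 1, 0), rep(0.7, 4))
  expect_equal(flat$auroc, 0.5)

  expect_warning(single <- evaluateScores(c(1, 1), c(0.2, 0.9)),
                 "single-class")
  expect_true(is.na(single$auroc))
  expect_equal(single$accuracy, 0.5)
})

test_that("metrics are invariant to permuting cell order", {
  set.seed(12)
  y <- rbinom(80, 1, 0.3)
  s <- runif(80)
  base <- evaluateScores(y, s)
  perm <- sample(80)
  expect_equal(evaluateScores(y[perm], s[perm]), base)
})

test_that("mean-rank selection reproduces the 3-model worked table", {
  res <- data.frame(
    model = c("A", "B", "C"), feature_mode = "embedding", fraction = 1,
    dataset = "holdout",
    accuracy = c(0.9, 0.8, 0.7), auroc = c(0.8, 0.9, 0.7),
    f1 = c(0.9, 0.8, 0.7), stringsAsFactors = FALSE)
  sel <- rankAndSelect(res)
  mr <- sel$meanRanks
  expect_equal(mr$mean_rank[mr$model == "A"], 4 / 3, tolerance = 1e-12)
  expect_equal(mr$mean_rank[mr$model == "B"], 5 / 3, tolerance = 1e-12)
  expect_equal(mr$mean_rank[mr$model == "C"], 3)
  expect_identical(sel$selectedModel, "A")
  expect_identical(sel$top3Intersection, c("A", "B", "C"))

  solo <- rankAndSelect(res[res$model == "A", ])
  expect_identical(solo$selectedModel, "A")
  expect_equal(solo$meanRanks$mean_rank, 1)
})

test_that("the benchmark produces a complete, well-formed report", {
  fx <- blobFeatures(n = 120, seed = 3)
  raw <- new("FeatureMatrix", values = featureValues(fx$features) + 0,
             featureMode = "raw_counts", provenance = list())
  cfg <- benchConfig(modelNames = c("logistic_regression", "decision_tree",
                                    "naive_bayes"),
                     fractions = c(0.5, 1.0), holdoutFraction = 0.3,
                     seed = 11)
  rp <- runBenchmark(list(embedding = fx$features, raw_counts = raw),
                     fx$labels, cfg)
  res <- benchResults(rp)
  # completeness: models x modes x fractions x evaluation sets
  expect_equal(nrow(res), 3 * 2 * 2 * 1)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  expect_true(all(res$auroc >= 0 & res$auroc <= 1))
  expect_true(all(res$f1 >= 0 & res$f1 <= 1, na.rm = TRUE))
  expect_true(selectedModel(rp) %in% cfg$modelNames)
  expect_true(all(topModels(rp) %in% cfg$modelNames))
  expect_equal(nrow(rp@deltas), 3 * 2 * 1)

  # a model without an installed backend is skipped with a warning
  cfg2 <- benchConfig(modelNames = c("logistic_regression",
                                     "categorical_boosting"),
                      fractions = 1.0, holdoutFraction = 0.3, seed = 11)
  if (!requireNamespace("catboost", quietly = TRUE)) {
    expect_warning(rp2 <- runBenchmark(list(embedding = fx$features),
                                       fx$labels, cfg2),
                   "without an installed backend")
    expect_identical(unique(benchResults(rp2)$model),
                     "logistic_regression")
  }
})

test_that("learning curves do not degrade from 10% to 100% training data", {
  aucs <- sapply(1:5, function(s) {
    fx <- blobFeatures(n = 220, sep = 1.4, seed = 100 + s)
    cfg <- benchConfig(modelNames = "logistic_regression",
                       fractions = c(0.1, 1.0), holdoutFraction = 0.3,
                       seed = s)
    res <- benchResults(runBenchmark(list(embedding = fx$features),
                                     fx$labels, cfg))
    c(low = res$auroc[res$fraction == 0.1],
      high = res$auroc[res$fraction == 1.0])
  })
  expect_gte(mean(aucs["high", ]), mean(aucs["low", ]))
})

test_that("low-confidence prediction applies a strict probability threshold", {
  fake <- structure(list(name = "fake", fit = NULL,
                         predictFun = function(fit, X)
                           c(0.99, 0.5, 0.2),
                         d = 2L, featureMode = "embedding", seed = 0L),
                    class = "hypoxiaClassifier")
  fm <- new("FeatureMatrix",
            values = matrix(0, 3, 2,
                            dimnames = list(c("x1", "x2", "x3"), NULL)),
            featureMode = "embedding", provenance = list())
  pr <- classifyLowConfidence(fake, fm)
  expect_identical(pr$predicted_status, c("HYPOXIC", "NORMOXIC", "NORMOXIC"))

  wide <- new("FeatureMatrix",
              values = matrix(0, 3, 5, dimnames = list(c("a", "b", "c"),
                                                       NULL)),
              featureMode = "embedding", provenance = list())
  expect_error(classifyLowConfidence(fake, wide),
               "dimensionality mismatch")
})

test_that("intermediates near the hypoxic archetype are predicted hypoxic", {
  sim <- simulateHypoxia(simParams(nCells = 800, nGenes = 1000,
                                   setSize = 30,
                                   intermediateMixing = 0.8, seed = 7))
  norm <- logNormalize(sim$counts)
  sm <- suppressMessages(ssgseaScore(norm, sim$sets))
  lb <- labelHypoxia(sm, seed = 7)
  sig <- deriveSignature(norm, lb, sim$annotation)
  emb <- suppressMessages(
    buildFeatures(norm, embeddingSpec("svd_fallback", dim = 20, seed = 7),
                  sig))
  clf <- trainClassifier("logistic_regression", emb, lb, seed = 7)
  inter <- sim$truth$cell_id[sim$truth$true_state == "INTERMEDIATE"]
  fmInter <- new("FeatureMatrix",
                 values = featureValues(emb)[inter, , drop = FALSE],
                 featureMode = "embedding", provenance = list())
  pr <- classifyLowConfidence(clf, fmInter)
  expect_gte(mean(pr$predicted_status == "HYPOXIC"), 0.8)
})
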