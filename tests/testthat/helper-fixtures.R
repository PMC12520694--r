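# Fixture builders shared across test files. Expensive objects are memoised
# in .fixtureCache so several test files can reuse one computation.

.fixtureCache <- new.env(parent = emptyenv())

memoFixture <- function(name, build) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, build(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

# Dense matrix -> NormalizedMatrix without renormalising (values used as-is).
normFromDense <- function(mat) {
  new("NormalizedMatrix",
      values = as(as(as(Matrix::Matrix(mat, sparse = TRUE), "dMatrix"),
                     "generalMatrix"), "CsparseMatrix"),
      scaleFactor = 1e4)
}

randomNorm <- function(nCells, nGenes, seed, zeroFrac = 0.3) {
  set.seed(seed)
  m <- matrix(round(rexp(nCells * nGenes), 3), nCells, nGenes)
  m[runif(length(m)) < zeroFrac] <- 0
  dimnames(m) <- list(sprintf("c%02d", seq_len(nCells)),
                      sprintf("g%02d", seq_len(nGenes)))
  normFromDense(m)
}

# A MixtureFit with essentially certain assignments around two centres.
sharpFit <- function(lowMean = 0, highMean = 10) {
  new("MixtureFit", means = c(lowMean, highMean), variances = c(1, 1),
      weights = c(0.5, 0.5), logLik = 0, logLikTrace = c(-1, 0),
      nIter = 2L, converged = TRUE, highComponent = 2L)
}

scoreMatrixOf <- function(m) {
  new("ScoreMatrix", scores = m, alpha = 0.25,
      coverage = stats::setNames(rep(1, ncol(m)), colnames(m)))
}

# Small labeled Gaussian feature fixture for benchmark mechanics tests.
blobFeatures <- function(n = 120, d = 4, sep = 2.5, seed = 1,
                         posFrac = 0.3) {
  set.seed(seed)
  nPos <- round(posFrac * n)
  y <- c(rep(TRUE, nPos), rep(FALSE, n - nPos))
  X <- matrix(rnorm(n * d), n, d)
  X[y, 1] <- X[y, 1] + sep
  ids <- sprintf("b%03d", seq_len(n))
  dimnames(X) <- list(ids, sprintf("f%d", seq_len(d)))
  fm <- new("FeatureMatrix", values = X, featureMode = "embedding",
            provenance = list())
  list(features = fm, labels = stats::setNames(y, ids))
}

# The full study-scale synthetic run reused by the acceptance tests:
# the generator's default conditions (2000 cells, seed 7, theta = 4).
fullPipelineRun <- function() {
  memoFixture("fullPipeline", function() {
    outdir <- file.path(tempdir(), "schypoxia-acceptance-run")
    t0 <- Sys.time()
    manifest <- suppressMessages(runPipeline(list(
      outdir = outdir, seed = 7,
      simulate = list(enabled = TRUE, seed = 7))))
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    truth <- read.delim(file.path(outdir, "simulated", "truth.tsv"))
    labels <- readLabels(file.path(outdir, "labels.tsv"))
    bench <- read.delim(file.path(outdir, "benchmark.tsv"))
    summ <- jsonlite::read_json(file.path(outdir, "bench_summary.json"))
    list(outdir = outdir, manifest = manifest, truth = truth,
         labels = labels, bench = bench, selected = summ$selected_model,
         elapsed = elapsed)
  })
}

# A reduced pipeline configuration for determinism checks.
smallPipelineConfig <- function(outdir, seed = 3) {
  list(outdir = outdir, seed = seed,
       simulate = list(enabled = TRUE, n_cells = 400L, n_genes = 600L,
                       set_size = 30L, seed = seed),
       features = list(provider = "svd", dim = 20L),
       bench = list(enabled = TRUE, holdout = 0.3,
                    fractions = c(0.3, 1.0),
                    models = c("logistic_regression", "decision_tree",
                               "naive_bayes")))
}
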