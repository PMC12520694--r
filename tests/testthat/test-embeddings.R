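.sigOf <- function(genes) {
  data.frame(gene_id = genes, log2_fc = 1, p_value = 0.001, adj_p = 0.01,
             pct_hypoxic = 1, pct_normoxic = 1, is_protein_coding = TRUE,
             passes = TRUE, stringsAsFactors = FALSE)
}

test_that("SVD fallback is deterministic and caps dim at the input rank", {
  nm <- randomNorm(12, 30, seed = 3)
  spec <- embeddingSpec("svd_fallback", dim = 5, seed = 1)
  f1 <- buildFeatures(nm, spec)
  f2 <- buildFeatures(nm, spec)
  expect_identical(featureValues(f1), featureValues(f2))
  expect_identical(featureMode(f1), "embedding")

  # rank-3 input: three independent cell archetypes, 40 requested dims
  set.seed(2)
  basis <- matrix(abs(rnorm(3 * 20)), 3, 20)
  mix <- matrix(runif(9 * 3), 9, 3)
  low <- mix %*% basis
  dimnames(low) <- list(sprintf("c%d", 1:9), sprintf("g%02d", 1:20))
  capped <- suppressMessages(
    buildFeatures(normFromDense(low), embeddingSpec("svd_fallback",
                                                    dim = 40, seed = 1)))
  expect_lte(ncol(featureValues(capped)), 3L)
  expect_message(
    buildFeatures(normFromDense(low), embeddingSpec("svd_fallback",
                                                    dim = 40, seed = 1)),
    "capped")
})

test_that("sign-fixed SVD features are invariant to cell order", {
  nm <- randomNorm(10, 25, seed = 6)
  spec <- embeddingSpec("svd_fallback", dim = 4, seed = 1)
  base <- featureValues(buildFeatures(nm, spec))
  perm <- sample(10)
  nm2 <- normFromDense(as.matrix(exprValues(nm))[perm, ])
  shuffled <- featureValues(buildFeatures(nm2, spec))
  expect_equal(shuffled[rownames(base), ], base, tolerance = 1e-9)
})

test_that("raw signature features are the signature genes in order", {
  nm <- randomNorm(8, 20, seed = 4)
  sig <- .sigOf(c("g07", "g03", "g15"))
  fm <- buildFeatures(nm, embeddingSpec("raw_signature"), sig)
  expect_identical(featureMode(fm), "raw_counts")
  expect_identical(colnames(featureValues(fm)), c("g07", "g03", "g15"))
  expect_equal(featureValues(fm)[, "g03"],
               as.matrix(exprValues(nm))[, "g03"])
  expect_error(buildFeatures(nm, embeddingSpec("raw_signature")),
               "non-empty signature")
})

test_that("embedding features tolerate gene missingness better than raw features", {
  set.seed(40)
  nm <- randomNorm(30, 60, seed = 40, zeroFrac = 0.2)
  sigGenes <- sprintf("g%02d", 1:15)
  sig <- .sigOf(sigGenes)
  spec <- embeddingSpec("svd_fallback", dim = 6, seed = 1)
  svdBase <- featureValues(buildFeatures(nm, spec, sig))
  rawBase <- featureValues(buildFeatures(nm, embeddingSpec("raw_signature"),
                                         sig))
  rowCosDist <- function(a, b) {
    mean(vapply(seq_len(nrow(a)), function(i) {
      na <- sqrt(sum(a[i, ]^2)); nb <- sqrt(sum(b[i, ]^2))
      if (na == 0 || nb == 0) return(1)
      1 - sum(a[i, ] * b[i, ]) / (na * nb)
    }, numeric(1)))
  }
  # delete 20% of NON-signature genes -> recompute embedding features
  dropNonSig <- sample(setdiff(colnames(exprValues(nm)), sigGenes), 9)
  nmDrop <- normFromDense(
    as.matrix(exprValues(nm))[, setdiff(colnames(exprValues(nm)),
                                        dropNonSig)])
  svdAfter <- featureValues(buildFeatures(nmDrop, spec, sig))
  svdDist <- rowCosDist(svdAfter[, colnames(svdBase), drop = FALSE],
                        svdBase)
  # delete 20% of SIGNATURE genes -> raw features lose that signal
  dropSig <- sample(sigGenes, 3)
  rawAfter <- rawBase
  rawAfter[, dropSig] <- 0          # a missing gene contributes nothing
  rawDist <- rowCosDist(rawAfter, rawBase)
  expect_lt(svdDist, rawDist)
})

test_that("provider spec validates its fields", {
  expect_error(embeddingSpec("external_file"), "sourcePath")
  expect_error(embeddingSpec("svd_fallback", dim = 1), "dim >= 2")
  expect_error(embeddingSpec("raw_signature", sourcePath = "x"),
               "only applies")
})
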