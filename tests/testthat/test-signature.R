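test_that("rank-sum worked examples: extreme split and all-ties", {
  r <- rankSumTest(c(10, 11, 12), c(1, 2, 3))
  expect_equal(r$statistic, 9)
  expect_equal(r$p, 0.1, tolerance = 1e-12)

  tied <- rankSumTest(c(5, 5, 5), c(5, 5, 5))
  expect_equal(tied$statistic, 4.5)   # null mean n1*n2/2
  expect_equal(tied$p, 1)
})

test_that("approximate mode agrees with the exact distribution at n1 = n2 = 50", {
  set.seed(31)
  x <- rnorm(50); y <- rnorm(50)
  approx <- rankSumTest(x, y)
  U <- approx$statistic
  exact <- min(1, 2 * min(pwilcox(U, 50, 50), 1 - pwilcox(U - 1, 50, 50)))
  expect_lt(abs(approx$p - exact), 0.01)
})

test_that("tie-corrected approximation matches the reference implementation", {
  set.seed(6)
  for (i in 1:10) {
    x <- sample(0:5, 30, replace = TRUE)
    y <- sample(0:5, 40, replace = TRUE)
    ours <- rankSumTest(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                               exact = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("swapping groups mirrors the statistic and keeps p", {
  set.seed(9)
  x <- rnorm(15); y <- rnorm(20, 1)
  a <- rankSumTest(x, y)
  b <- rankSumTest(y, x)
  expect_equal(a$statistic + b$statistic, 15 * 20)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

.sigFixture <- function(nPerGroup = 60, nGenes = 30, fold = 4, seed = 13) {
  set.seed(seed)
  n <- 2 * nPerGroup
  vals <- matrix(log1p(rnbinom(n * nGenes, mu = 5, size = 2)), n, nGenes)
  status <- rep(c("HC_HYPOXIC", "HC_NORMOXIC"), each = nPerGroup)
  vals[status == "HC_HYPOXIC", 1] <-
    log1p(rnbinom(nPerGroup, mu = 5 * fold, size = 2))  # planted up gene
  vals[, 2] <- log1p(3)                  # identical in every cell
  dimnames(vals) <- list(sprintf("c%03d", 1:n), sprintf("g%02d", 1:nGenes))
  grp <- matrix(ifelse(status == "HC_HYPOXIC", "HIGH", "LOW"), n, 1,
                dimnames = list(rownames(vals), "S1"))
  lb <- new("HypoxiaLabels", cellId = rownames(vals), status = status,
            perSetGroup = grp,
            posteriorHigh = matrix(0.5, n, 1,
                                   dimnames = dimnames(grp)),
            fits = list())
  ann <- data.frame(gene_id = colnames(vals),
                    is_protein_coding = c(rep(TRUE, nGenes - 1), FALSE),
                    is_mitochondrial = FALSE)
  list(norm = normFromDense(vals), labels = lb, ann = ann)
}

test_that("a planted 4-fold gene passes; a constant gene does not", {
  fx <- .sigFixture()
  sig <- deriveSignature(fx$norm, fx$labels, fx$ann)
  g1 <- sig[sig$gene_id == "g01", ]
  expect_true(g1$passes)
  expect_gt(g1$log2_fc, 0.25)
  g2 <- sig[sig$gene_id == "g02", ]
  expect_equal(g2$log2_fc, 0)
  expect_false(g2$passes)
  # protein-coding is part of the pass rule
  gLast <- sig[sig$gene_id == "g30", ]
  if (nrow(gLast)) expect_false(gLast$passes)
  # sorted by decreasing fold change
  expect_false(is.unsorted(rev(sig$log2_fc)))
})

test_that("signature derivation needs enough cells per group", {
  fx <- .sigFixture(nPerGroup = 30)
  fx$labels@status[fx$labels@status == "HC_HYPOXIC"][1] <- "HC_HYPOXIC"
  small <- fx$labels
  small@status <- c(rep("HC_HYPOXIC", 2), rep("HC_NORMOXIC", 58))
  small@perSetGroup[, 1] <- ifelse(small@status == "HC_HYPOXIC", "HIGH",
                                   "LOW")
  expect_error(deriveSignature(fx$norm, small, fx$ann),
               "insufficient labeled cells")
})
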