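.annFor <- function(genes, mito = character()) {
  data.frame(gene_id = genes, is_protein_coding = TRUE,
             is_mitochondrial = genes %in% mito, stringsAsFactors = FALSE)
}

test_that("detected-gene threshold is a strict 'fewer than'", {
  nGenes <- 600L
  genes <- sprintf("g%03d", seq_len(nGenes))
  m <- Matrix::sparseMatrix(
    i = c(rep(1L, 499), rep(2L, 500), rep(3L, 600)),
    j = c(1:499, 1:500, 1:600), x = 1,
    dims = c(3, nGenes), dimnames = list(c("c499", "c500", "c600"), genes))
  cc <- CellCounts(m)
  res <- qcFilter(cc, .annFor(genes),
                  qcParams(minGenesPerCell = 500,
                           minCellsPerGeneFraction = 0))
  expect_false("c499" %in% cellIds(res$counts))
  expect_true(all(c("c500", "c600") %in% cellIds(res$counts)))
  expect_equal(res$report$removed_low_genes, 1L)
})

test_that("mito boundary: exactly 20% retained, just over removed", {
  genes <- c("MITO1", sprintf("g%02d", 1:9))
  rows <- rbind(
    at20 = c(200, rep(89L, 8), 88),  # 200 / 1000 = 0.20 exactly
    over = c(201, rep(89L, 8), 87),  # 201 / 1000 = 0.201
    low = c(10, rep(110L, 9)))
  dimnames(rows) <- list(c("at20", "over", "low"), genes)
  cc <- CellCounts(rows)
  res <- qcFilter(cc, .annFor(genes, mito = "MITO1"),
                  qcParams(minGenesPerCell = 0, maxMitoFraction = 0.20,
                           minCellsPerGeneFraction = 0))
  expect_true("at20" %in% cellIds(res$counts))
  expect_false("over" %in% cellIds(res$counts))
  expect_equal(res$report$removed_high_mito, 1L)
})

test_that("permissive thresholds with no doublets change nothing, and QC is idempotent", {
  sim <- simulateHypoxia(simParams(nCells = 150, nGenes = 300,
                                   setSize = 20, seed = 11))
  identity <- qcFilter(sim$counts, sim$annotation,
                       qcParams(minGenesPerCell = 0, maxMitoFraction = 1,
                                minCellsPerGeneFraction = 0),
                       doubletFlags = rep(FALSE, 150))
  expect_equal(as.matrix(counts(identity$counts)),
               as.matrix(counts(sim$counts)))

  once <- qcFilter(sim$counts, sim$annotation, qcParams(minGenesPerCell = 50))
  twice <- qcFilter(once$counts, sim$annotation,
                    qcParams(minGenesPerCell = 50))
  expect_identical(cellIds(twice$counts), cellIds(once$counts))
  expect_identical(geneIds(twice$counts), geneIds(once$counts))
  expect_equal(twice$report$removed_cells_total, 0L)
  expect_equal(twice$report$removed_dropout_genes, 0L)

  # partition: retained + removed = input
  expect_equal(once$report$n_cells_out +
                 once$report$removed_cells_total, once$report$n_cells_in)
})

test_that("doublet flags remove cells and QC can empty the matrix", {
  genes <- sprintf("g%02d", 1:20)
  m <- matrix(5L, 4, 20, dimnames = list(sprintf("c%d", 1:4), genes))
  cc <- CellCounts(m)
  flags <- stats::setNames(c(TRUE, FALSE, TRUE, FALSE), cellIds(cc))
  res <- qcFilter(cc, .annFor(genes),
                  qcParams(minGenesPerCell = 0,
                           minCellsPerGeneFraction = 0),
                  doubletFlags = flags)
  expect_identical(cellIds(res$counts), c("c2", "c4"))
  expect_equal(res$report$removed_doublet, 2L)

  expect_error(
    qcFilter(cc, .annFor(genes), qcParams(minGenesPerCell = 100)),
    "empty matrix after QC")
})

test_that("log-normalization matches its closed form and is scale invariant per cell", {
  genes <- sprintf("g%d", 1:4)
  m <- matrix(c(1L, 2L, 3L, 4L,
                2L, 4L, 6L, 8L), 2, 4, byrow = TRUE,
              dimnames = list(c("c1", "c2"), genes))
  nm <- logNormalize(CellCounts(m), scaleFactor = 1e4)
  v <- as.matrix(exprValues(nm))
  expect_equal(v["c1", "g1"], log(1 + 1 * 1e4 / 10), tolerance = 1e-12)
  expect_equal(v["c1", "g1"], 6.908755, tolerance = 1e-6)
  # doubling every count in a cell leaves its values unchanged
  expect_equal(v["c2", ], v["c1", ], tolerance = 1e-12)

  m2 <- m; m2[1, ] <- 0L
  expect_error(logNormalize(CellCounts(m2)), "zero total")
  m3 <- m; m3[1, 1] <- 0L
  expect_equal(as.matrix(exprValues(logNormalize(CellCounts(m3))))["c1", "g1"],
               0)
})
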