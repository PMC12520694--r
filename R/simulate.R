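#' Simulation parameters for planted hypoxia states
#'
#' Defaults describe a desk-scale cohort: 2000 cells by 2000 genes, seven
#' disjoint 50-gene hypoxia sets, 10% planted hypoxic cells, 20%
#' intermediate cells (mixing weight 0.5), a four-fold hypoxic effect,
#' log-normal library sizes around 10,000 counts, and negative-binomial
#' dispersion 0.3 (variance `mu + phi * mu^2`).
#'
#' @param nCells,nGenes matrix dimensions.
#' @param nSets,setSize number and size of planted hypoxia gene sets.
#' @param fracHypoxic,fracIntermediate planted state fractions (the
#'   remainder is normoxic).
#' @param effectMultiplier fold change `theta >= 1` applied to hypoxia-set
#'   genes in hypoxic cells.
#' @param intermediateMixing exponent weight in `(0, 1)` for intermediate
#'   cells: their effect is `theta^mixing`.
#' @param libSizeLogMean,libSizeLogSd log-normal library-size parameters.
#' @param dispersion negative-binomial dispersion `phi > 0`.
#' @param fracMitoGenes fraction of genes flagged mitochondrial (baseline
#'   rates only, never in a hypoxia set).
#' @param fracNonCoding fraction of genes marked non-protein-coding (drawn
#'   outside the hypoxia sets).
#' @param overlapCore genes shared by all sets when > 0 (MSigDB hypoxia
#'   sets overlap heavily; 0 keeps sets disjoint, the default).
#' @param seed integer seed.
#' @return list of class `simParams`.
#' @export
simParams <- function(nCells = 2000L, nGenes = 2000L, nSets = 7L,
                      setSize = 50L, fracHypoxic = 0.10,
                      fracIntermediate = 0.20, effectMultiplier = 4,
                      intermediateMixing = 0.5,
                      libSizeLogMean = log(1e4), libSizeLogSd = 0.35,
                      dispersion = 0.3, fracMitoGenes = 0.01,
                      fracNonCoding = 0.10, overlapCore = 0L, seed = 0L) {
  stopifnot(fracHypoxic >= 0, fracIntermediate >= 0,
            fracHypoxic + fracIntermediate <= 1,
            effectMultiplier >= 1, intermediateMixing > 0,
            intermediateMixing < 1, dispersion > 0,
            overlapCore >= 0, overlapCore < setSize)
  uniquePerSet <- setSize - overlapCore
  if (overlapCore + nSets * uniquePerSet + ceiling(fracMitoGenes * nGenes) >
      nGenes)
    stop("gene sets and mito genes do not fit into nGenes")
  structure(list(nCells = as.integer(nCells), nGenes = as.integer(nGenes),
                 nSets = as.integer(nSets), setSize = as.integer(setSize),
                 fracHypoxic = fracHypoxic,
                 fracIntermediate = fracIntermediate,
                 effectMultiplier = effectMultiplier,
                 intermediateMixing = intermediateMixing,
                 libSizeLogMean = libSizeLogMean,
                 libSizeLogSd = libSizeLogSd, dispersion = dispersion,
                 fracMitoGenes = fracMitoGenes,
                 fracNonCoding = fracNonCoding,
                 overlapCore = as.integer(overlapCore),
                 seed = as.integer(seed)),
            class = "simParams")
}

#' Simulate negative-binomial counts with planted hypoxia states
#'
#' Gene baseline rates `p_g` are drawn log-normal and normalized to sum to
#' one; cell library sizes `L_i` are log-normal. The expected count is
#' `mu_ig = L_i * p_g * theta^(e_i * m_g)` where `m_g = 1` for hypoxia-set
#' genes (0 otherwise) and the per-cell effect `e_i` is 1 for hypoxic cells,
#' the mixing weight for intermediate cells and 0 for normoxic cells.
#' Counts are negative-binomial with variance `mu + phi * mu^2`.
#' Mitochondrial genes keep baseline rates and never join a hypoxia set.
#'
#' @param params a [simParams()] bundle.
#' @return list with `counts` ([CellCounts-class]), `truth` (data.frame:
#'   `cell_id`, `true_state`, `effect`), `sets` ([GeneSetList-class]) and
#'   `annotation` (gene annotation data.frame).
#' @export
simulateHypoxia <- function(params = simParams()) {
  stopifnot(inherits(params, "simParams"))
  p <- params
  .withSeed(p$seed, function() {
    genes <- sprintf("G%05d", seq_len(p$nGenes))
    cells <- sprintf("C%05d", seq_len(p$nCells))

    nMito <- ceiling(p$fracMitoGenes * p$nGenes)
    mitoIdx <- if (nMito > 0) seq(p$nGenes - nMito + 1L, p$nGenes) else
      integer()
    if (nMito > 0) genes[mitoIdx] <- sprintf("MT-G%03d", seq_len(nMito))

    core <- if (p$overlapCore > 0) seq_len(p$overlapCore) else integer()
    uniquePerSet <- p$setSize - p$overlapCore
    setIdx <- lapply(seq_len(p$nSets), function(k) {
      own <- p$overlapCore + (k - 1L) * uniquePerSet + seq_len(uniquePerSet)
      sort(c(core, own))
    })
    memb <- rep(FALSE, p$nGenes)
    memb[unlist(setIdx)] <- TRUE
    sets <- GeneSetList(
      stats::setNames(lapply(setIdx, function(ix) genes[ix]),
                      sprintf("HYPOXIA_SET_%d", seq_len(p$nSets))),
      stats::setNames(rep("planted hypoxia program", p$nSets),
                      sprintf("HYPOXIA_SET_%d", seq_len(p$nSets))))

    baseline <- rlnorm(p$nGenes, meanlog = 0, sdlog = 1)
    baseline <- baseline / sum(baseline)
    lib <- rlnorm(p$nCells, p$libSizeLogMean, p$libSizeLogSd)

    nH <- floor(p$fracHypoxic * p$nCells)
    nI <- floor(p$fracIntermediate * p$nCells)
    state <- c(rep("HYPOXIC", nH), rep("INTERMEDIATE", nI),
               rep("NORMOXIC", p$nCells - nH - nI))
    state <- sample(state)
    eff <- c(HYPOXIC = 1, INTERMEDIATE = p$intermediateMixing,
             NORMOXIC = 0)[state]

    size <- 1 / p$dispersion
    boost <- p$effectMultiplier^eff          # per-cell multiplier on set genes
    triplets <- vector("list", p$nCells)
    for (i in seq_len(p$nCells)) {
      mu <- lib[i] * baseline
      if (eff[i] > 0) mu[memb] <- mu[memb] * boost[i]
      cnt <- rnbinom(p$nGenes, size = size, mu = mu)
      nz <- which(cnt > 0L)
      triplets[[i]] <- list(j = nz, x = cnt[nz])
    }
    lens <- vapply(triplets, function(t) length(t$j), integer(1))
    m <- sparseMatrix(
      i = rep.int(seq_len(p$nCells), lens),
      j = unlist(lapply(triplets, `[[`, "j")),
      x = unlist(lapply(triplets, `[[`, "x")),
      dims = c(p$nCells, p$nGenes), dimnames = list(cells, genes))

    nonCodingPool <- setdiff(which(!memb), mitoIdx)
    nNC <- min(length(nonCodingPool), floor(p$fracNonCoding * p$nGenes))
    ncIdx <- sample(nonCodingPool, nNC)
    annotation <- data.frame(
      gene_id = genes,
      is_protein_coding = !(seq_len(p$nGenes) %in% ncIdx),
      is_mitochondrial = seq_len(p$nGenes) %in% mitoIdx,
      stringsAsFactors = FALSE)

    truth <- data.frame(cell_id = cells, true_state = state,
                        effect = unname(eff), stringsAsFactors = FALSE)
    list(counts = CellCounts(m, datasetTag = "synthetic"), truth = truth,
         sets = sets, annotation = annotation)
  })
}

#' Write the simulated fixture bundle to disk
#'
#' Emits the MatrixMarket triplet bundle, the GMT file, the annotation
#' table and the ground-truth table under `dir`.
#'
#' @param sim output of [simulateHypoxia()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeSimBundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCounts(sim$counts, file.path(dir, "counts"))
  writeGmt(sim$sets, file.path(dir, "hypoxia_sets.gmt"))
  writeTsv(sim$annotation, file.path(dir, "annotation.tsv"))
  writeTsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
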