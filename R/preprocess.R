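#' QC parameter bundle
#'
#' Thresholds for cell and gene filtering. Cells with fewer than
#' `minGenesPerCell` detected genes (strict) or a mitochondrial count
#' fraction over `maxMitoFraction` (strict) are removed, as are flagged
#' doublets; genes detected in fewer than `minCellsPerGeneFraction` of the
#' retained cells are treated as high-dropout genes and removed.
#'
#' @param minGenesPerCell minimum detected genes per retained cell
#'   (default 500).
#' @param maxMitoFraction maximum mitochondrial content (default 0.20).
#' @param minCellsPerGeneFraction detection fraction below which a gene is
#'   dropped (default 0.001).
#' @param dropDoublets whether supplied doublet flags remove cells.
#' @return a named list of class `qcParams`.
#' @export
qcParams <- function(minGenesPerCell = 500L, maxMitoFraction = 0.20,
                     minCellsPerGeneFraction = 0.001, dropDoublets = TRUE) {
  stopifnot(minGenesPerCell >= 0, maxMitoFraction >= 0, maxMitoFraction <= 1,
            minCellsPerGeneFraction >= 0, minCellsPerGeneFraction <= 1)
  structure(list(minGenesPerCell = as.integer(minGenesPerCell),
                 maxMitoFraction = maxMitoFraction,
                 minCellsPerGeneFraction = minCellsPerGeneFraction,
                 dropDoublets = isTRUE(dropDoublets)),
            class = "qcParams")
}

#' Filter cells and genes by quality control rules
#'
#' Removes cells with fewer detected genes than the threshold, cells whose
#' mitochondrial count fraction exceeds the threshold, and flagged doublets;
#' then removes genes detected in fewer than the configured fraction of the
#' retained cells. Mitochondrial genes are identified from the annotation
#' flags, with a `"MT-"` name-prefix fallback when no gene is flagged. Genes
#' absent from the annotation are treated as non-mitochondrial,
#' non-protein-coding, with a message.
#'
#' @param x a [CellCounts-class].
#' @param annotation data.frame as from [readGeneAnnotation()].
#' @param params a [qcParams()] bundle.
#' @param doubletFlags optional logical vector (or named by cell id).
#' @return list with elements `counts` (filtered [CellCounts-class]) and
#'   `report` (per-rule removal counts).
#' @export
qcFilter <- function(x, annotation, params = qcParams(),
                     doubletFlags = NULL) {
  stopifnot(is(x, "CellCounts"), inherits(params, "qcParams"))
  m <- x@counts
  genes <- geneIds(x)
  miss <- setdiff(genes, annotation$gene_id)
  if (length(miss))
    message(sprintf(paste0("%d genes missing from annotation; treated as ",
                           "non-mitochondrial, non-coding"), length(miss)))
  mito <- annotation$gene_id[annotation$is_mitochondrial]
  isMito <- genes %in% mito
  if (!any(isMito)) isMito <- startsWith(genes, "MT-")

  detected <- Matrix::rowSums(m > 0)
  total <- Matrix::rowSums(m)
  mitoFrac <- if (any(isMito))
    Matrix::rowSums(m[, isMito, drop = FALSE]) / pmax(total, 1) else
    numeric(nrow(m))

  lowGenes <- detected < params$minGenesPerCell
  highMito <- mitoFrac > params$maxMitoFraction
  doublet <- rep(FALSE, nrow(m))
  if (!is.null(doubletFlags) && params$dropDoublets) {
    if (!is.null(names(doubletFlags)))
      doublet <- unname(doubletFlags[cellIds(x)]) %in% TRUE
    else {
      stopifnot(length(doubletFlags) == nrow(m))
      doublet <- doubletFlags %in% TRUE
    }
  }
  keepCell <- !(lowGenes | highMito | doublet)
  if (!any(keepCell)) stop("empty matrix after QC")
  mKeep <- m[keepCell, , drop = FALSE]

  detInCells <- Matrix::colSums(mKeep > 0)
  dropoutGene <- detInCells < params$minCellsPerGeneFraction * nrow(mKeep)
  keepGene <- !dropoutGene
  if (!any(keepGene)) stop("empty matrix after QC")

  report <- list(
    n_cells_in = nrow(m), n_cells_out = sum(keepCell),
    n_genes_in = ncol(m), n_genes_out = sum(keepGene),
    removed_low_genes = sum(lowGenes),
    removed_high_mito = sum(highMito),
    removed_doublet = sum(doublet),
    removed_cells_total = sum(!keepCell),
    removed_dropout_genes = sum(dropoutGene),
    genes_missing_annotation = length(miss))

  out <- CellCounts(mKeep[, keepGene, drop = FALSE],
                    datasetTag = x@datasetTag)
  list(counts = out, report = report)
}

#' Library-size log-normalization
#'
#' `value(c, g) = log(1 + count(c, g) * scaleFactor / total(c))`. Rank-based
#' downstream scoring and the affine-invariant mixture labeling make this
#' light-weight transform sufficient; see the package vignette.
#'
#' @param x a [CellCounts-class] that passed QC.
#' @param scaleFactor library-size scale (default 1e4, i.e. log1p-CPM/100).
#' @return a [NormalizedMatrix-class].
#' @export
logNormalize <- function(x, scaleFactor = 1e4) {
  stopifnot(is(x, "CellCounts"), scaleFactor > 0)
  total <- Matrix::rowSums(x@counts)
  if (any(total == 0))
    stop(sprintf("%d cells have zero total count; run qcFilter first",
                 sum(total == 0)))
  v <- Diagonal(x = scaleFactor / total) %*% x@counts
  v <- as(v, "CsparseMatrix")
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(x@counts)
  new("NormalizedMatrix", values = as(v, "dgCMatrix"),
      scaleFactor = scaleFactor)
}
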