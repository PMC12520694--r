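#' Wilcoxon/Mann-Whitney rank-sum test
#'
#' Computes the Mann-Whitney U statistic for `x` against `y` with average
#' ranks for ties. When the combined sample size is at most 12 and there are
#' no ties the two-sided p-value is exact (null permutation distribution of
#' U); otherwise a normal approximation with tie correction and continuity
#' correction is used. When the tie-corrected null variance is zero (all
#' observations identical) the statistic sits at its null mean and p = 1.
#'
#' @param x,y numeric vectors, each non-empty.
#' @return list with `statistic` (U for the first sample) and `p` (two-sided).
#' @export
rankSumTest <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  z <- c(x, y)
  r <- rank(z)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(z) > 0L
  if (n1 + n2 <= 12L && !ties) {
    pl <- pwilcox(U, n1, n2)
    pg <- 1 - pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(pl, pg))
  } else {
    mU <- n1 * n2 / 2
    tab <- table(z)
    n <- n1 + n2
    s2 <- n1 * n2 / 12 * ((n + 1) - sum(tab^3 - tab) / (n * (n - 1)))
    if (s2 <= 0) return(list(statistic = U, p = 1))
    cc <- sign(U - mU) * 0.5
    zstat <- (U - mU - cc) / sqrt(s2)
    p <- min(1, 2 * pnorm(-abs(zstat)))
  }
  list(statistic = U, p = p)
}

#' Derive the hypoxia gene signature
#'
#' Tests every sufficiently detected gene between high-confidence hypoxic
#' and high-confidence normoxic cells with the rank-sum test on normalized
#' expression. The fold change is
#' `log2((mean(expm1(hypoxic)) + 1) / (mean(expm1(normoxic)) + 1))`. A gene
#' passes when `p < pThresh`, `log2FC > lfcThresh` and it is protein-coding;
#' BH-adjusted p-values are reported for transparency but not used in the
#' filter (the raw-p cutoff is the operative rule).
#'
#' @param norm a [NormalizedMatrix-class].
#' @param labels a [HypoxiaLabels-class] on the same cells.
#' @param annotation data.frame as from [readGeneAnnotation()].
#' @param pThresh raw p-value cutoff (default 0.05).
#' @param lfcThresh log2 fold-change cutoff (default 0.25); only genes UP in
#'   hypoxic cells can pass.
#' @param minPct a gene is tested only when detected in at least this
#'   fraction of either group (default 0.10).
#' @return data.frame sorted by decreasing `log2_fc` with columns `gene_id`,
#'   `log2_fc`, `p_value`, `adj_p`, `pct_hypoxic`, `pct_normoxic`,
#'   `is_protein_coding`, `passes`.
#' @export
deriveSignature <- function(norm, labels, annotation, pThresh = 0.05,
                            lfcThresh = 0.25, minPct = 0.10) {
  stopifnot(is(norm, "NormalizedMatrix"), is(labels, "HypoxiaLabels"))
  st <- status(labels)
  hCells <- names(st)[st == "HC_HYPOXIC"]
  nCells <- names(st)[st == "HC_NORMOXIC"]
  hCells <- intersect(hCells, cellIds(norm))
  nCells <- intersect(nCells, cellIds(norm))
  if (length(hCells) < 3L || length(nCells) < 3L)
    stop("insufficient labeled cells in a high-confidence group")

  vh <- as.matrix(norm@values[hCells, , drop = FALSE])
  vn <- as.matrix(norm@values[nCells, , drop = FALSE])
  pctH <- colMeans(vh > 0)
  pctN <- colMeans(vn > 0)
  testable <- pctH >= minPct | pctN >= minPct
  genes <- geneIds(norm)[testable]
  if (!length(genes)) stop("no genes pass the detection filter")

  coding <- genes %in% annotation$gene_id[annotation$is_protein_coding]
  pv <- numeric(length(genes))
  lfc <- numeric(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    xh <- vh[, g]; xn <- vn[, g]
    pv[i] <- rankSumTest(xh, xn)$p
    lfc[i] <- log2((mean(expm1(xh)) + 1) / (mean(expm1(xn)) + 1))
  }
  out <- data.frame(gene_id = genes, log2_fc = lfc, p_value = pv,
                    adj_p = p.adjust(pv, "BH"),
                    pct_hypoxic = unname(pctH[genes]),
                    pct_normoxic = unname(pctN[genes]),
                    is_protein_coding = coding,
                    stringsAsFactors = FALSE)
  out$passes <- out$p_value < pThresh & out$log2_fc > lfcThresh &
    out$is_protein_coding
  out[order(-out$log2_fc), , drop = FALSE]
}
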