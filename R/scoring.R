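#' Per-cell ssGSEA activity scores
#'
#' Single-sample gene-set enrichment: for each cell, genes are ranked by
#' expression in decreasing order and given rank weights
#' `r = N - position + 1`; ties in expression receive the average of their
#' rank weights, and the running-sum order among tied genes is fixed by
#' ascending gene id so scores are fully deterministic on sparse,
#' zero-inflated data. The enrichment score of a set G is
#' \deqn{ES(G) = \sum_{i=1}^{N} [P_{in}(i) - P_{out}(i)]}
#' where `P_in(i)` is the alpha-weighted fraction of in-set rank weight
#' accumulated through position `i` and `P_out(i)` the unweighted fraction
#' of out-of-set genes passed. Scores are rank-based, hence invariant to any
#' strictly increasing per-cell transform of expression.
#'
#' @param norm a [NormalizedMatrix-class] (cells x genes).
#' @param sets a [GeneSetList-class]; genes absent from the matrix are
#'   dropped per set (coverage is recorded on the result).
#' @param alpha rank-weight exponent (default 0.25, the canonical ssGSEA
#'   weighting; 0 gives the unweighted member ECDF).
#' @param minGenesPresent minimum genes a set must retain after intersection
#'   with the matrix.
#' @return a [ScoreMatrix-class] (cells x sets).
#' @export
ssgseaScore <- function(norm, sets, alpha = 0.25, minGenesPresent = 3L) {
  stopifnot(is(norm, "NormalizedMatrix"), is(sets, "GeneSetList"),
            alpha >= 0, minGenesPresent >= 1)
  genes <- geneIds(norm)
  N <- length(genes)
  idOrd <- order(genes, method = "radix")
  m <- norm@values[, idOrd, drop = FALSE]   # columns ascending by gene id
  gid <- colnames(m)

  setNm <- names(sets)
  memb <- matrix(FALSE, N, length(setNm), dimnames = list(NULL, setNm))
  coverage <- stats::setNames(numeric(length(setNm)), setNm)
  for (k in seq_along(setNm)) {
    g <- sets@sets[[k]]
    inMat <- g[g %in% gid]
    coverage[k] <- length(inMat) / length(g)
    if (length(inMat) < minGenesPresent)
      stop(sprintf("gene set '%s' retains %d genes (< %d) in the matrix",
                   setNm[k], length(inMat), minGenesPresent))
    if (length(inMat) == N)
      stop(sprintf("degenerate gene set '%s' covers every gene", setNm[k]))
    memb[match(inMat, gid), k] <- TRUE
  }
  if (any(coverage < 1))
    message(sprintf("genes missing from matrix for %d set(s); coverage: %s",
                    sum(coverage < 1),
                    paste(sprintf("%s=%.2f", setNm[coverage < 1],
                                  coverage[coverage < 1]), collapse = ", ")))

  nIn <- colSums(memb)
  out <- matrix(NA_real_, nrow(m), length(setNm),
                dimnames = list(rownames(m), setNm))
  chunk <- 512L
  for (start in seq(1L, nrow(m), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(m))
    dense <- as.matrix(m[idx, , drop = FALSE])
    for (r in seq_along(idx)) {
      x <- dense[r, ]
      ord <- order(x, decreasing = TRUE, method = "radix")  # stable: id ties
      xs <- x[ord]
      starts <- which(c(TRUE, xs[-1L] != xs[-N]))
      ends <- c(starts[-1L] - 1L, N)
      lens <- ends - starts + 1L
      grp <- rep.int(seq_along(starts), lens)
      w <- (N + 1 - (starts + ends) / 2)[grp]   # tie-averaged rank weights
      wa <- if (alpha == 1) w else w^alpha
      for (k in seq_along(setNm)) {
        inPos <- memb[ord, k]
        pin <- cumsum(wa * inPos) / sum(wa[inPos])
        pout <- cumsum(!inPos) / (N - nIn[k])
        out[idx[r], k] <- sum(pin - pout)
      }
    }
  }
  new("ScoreMatrix", scores = out, alpha = alpha, coverage = coverage)
}
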