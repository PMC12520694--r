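#' Embedding provider specification
#'
#' Declares where classifier features come from: `"external_file"` ingests
#' a cells x d table exported from an external embedder (e.g. a pretrained
#' single-cell foundation model); `"svd_fallback"` computes a deterministic
#' truncated SVD of the centered normalized matrix so the full workflow runs
#' offline; `"raw_signature"` uses normalized expression of the passing
#' signature genes (the raw-count comparator of the benchmark).
#'
#' @param kind one of `"external_file"`, `"svd_fallback"`, `"raw_signature"`.
#' @param dim target dimensionality for `svd_fallback` (default 50).
#' @param seed integer recorded in the provenance.
#' @param sourcePath file path, required iff `kind = "external_file"`.
#' @return a list of class `embeddingSpec`.
#' @export
embeddingSpec <- function(kind = c("svd_fallback", "external_file",
                                   "raw_signature"),
                          dim = 50L, seed = 0L, sourcePath = NULL) {
  kind <- match.arg(kind)
  if (kind == "external_file" && is.null(sourcePath))
    stop("sourcePath is required for an external_file provider")
  if (kind != "external_file" && !is.null(sourcePath))
    stop("sourcePath only applies to an external_file provider")
  if (kind == "svd_fallback" && dim < 2L)
    stop("svd_fallback needs dim >= 2")
  structure(list(kind = kind, dim = as.integer(dim),
                 seed = as.integer(seed), sourcePath = sourcePath),
            class = "embeddingSpec")
}

.topVariableGenes <- function(norm, n = 2000L) {
  m <- norm@values
  mu <- Matrix::colSums(m) / nrow(m)
  ex2 <- Matrix::colSums(m^2) / nrow(m)
  v <- ex2 - mu^2
  genes <- geneIds(norm)
  genes[order(-v, genes, method = "radix")][seq_len(min(n, length(genes)))]
}

.svdFeatures <- function(norm, genes, dim) {
  x <- as.matrix(norm@values[, genes, drop = FALSE])
  x <- sweep(x, 2L, colMeans(x))
  sv <- svd(x)
  tolr <- max(dim(x)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tolr)
  k <- min(dim, rank)
  if (k < dim)
    message(sprintf("requested dim %d exceeds input rank %d; capped", dim,
                    rank))
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    # sign fixed by the largest-magnitude gene loading (first on ties)
    piv <- which.max(abs(v[, j]))
    if (v[piv, j] < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  f <- u %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(f) <- list(rownames(x), sprintf("SVD%02d", seq_len(k)))
  f
}

#' Build the classifier feature matrix
#'
#' @param norm a [NormalizedMatrix-class].
#' @param spec an [embeddingSpec()].
#' @param signature optional signature data.frame from [deriveSignature()];
#'   required for `raw_signature`, and used to restrict the SVD gene space
#'   when available (otherwise the 2000 most variable genes are used).
#' @return a [FeatureMatrix-class]; `feature_mode` is `"embedding"` for
#'   `external_file` and `svd_fallback`, `"raw_counts"` for `raw_signature`.
#' @export
buildFeatures <- function(norm, spec, signature = NULL) {
  stopifnot(is(norm, "NormalizedMatrix"), inherits(spec, "embeddingSpec"))
  sigGenes <- if (!is.null(signature))
    intersect(signature$gene_id[signature$passes], geneIds(norm)) else
    character()
  if (spec$kind == "external_file") {
    m <- readEmbedding(spec$sourcePath, cellIds(norm))
    mode <- "embedding"
  } else if (spec$kind == "svd_fallback") {
    genes <- if (length(sigGenes) >= 2L) sigGenes else .topVariableGenes(norm)
    m <- .svdFeatures(norm, genes, spec$dim)
    mode <- "embedding"
  } else {
    if (!length(sigGenes))
      stop("raw_signature features need a non-empty signature")
    m <- as.matrix(norm@values[, sigGenes, drop = FALSE])
    mode <- "raw_counts"
  }
  new("FeatureMatrix", values = m, featureMode = mode,
      provenance = list(spec = unclass(spec), n_signature_genes =
                          length(sigGenes)))
}
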