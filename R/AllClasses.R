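#' @title Core S4 classes
#' @name scHypoxia-classes
#' @description S4 containers for the artifacts the workflow passes between
#'   stages: raw counts, parsed gene sets, normalized expression, per-cell
#'   gene-set scores, mixture fits, consensus labels, feature matrices and
#'   benchmark reports.
NULL

.checkUnique <- function(x, what) {
  if (anyDuplicated(x)) {
    dup <- unique(x[duplicated(x)])
    return(sprintf("duplicate %s: %s", what,
                   paste(utils::head(dup, 5), collapse = ", ")))
  }
  NULL
}

#' CellCounts: sparse raw count matrix (cells x genes)
#'
#' Rows are cells, columns are genes; dimnames carry the identifiers.
#' Entries must be non-negative integers.
#'
#' @slot counts a [Matrix::dgCMatrix] of raw counts, cells in rows.
#' @slot datasetTag single string naming the dataset of origin.
#' @export
setClass("CellCounts",
  slots = c(counts = "dgCMatrix", datasetTag = "character"))

setValidity("CellCounts", function(object) {
  m <- object@counts
  msgs <- character()
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msgs <- c(msgs, "counts must have cell (row) and gene (column) names")
  else {
    msgs <- c(msgs, .checkUnique(rownames(m), "cell ids"),
              .checkUnique(colnames(m), "gene ids"))
  }
  if (length(m@x) && (any(m@x < 0) || any(m@x != round(m@x))))
    msgs <- c(msgs, "counts must be non-negative integers")
  if (length(object@datasetTag) != 1L)
    msgs <- c(msgs, "datasetTag must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CellCounts object
#'
#' @param counts matrix-like of non-negative integer counts, cells x genes.
#' @param cellIds,geneIds identifiers; taken from dimnames when `NULL`.
#' @param datasetTag dataset label stored with the object.
#' @return a [CellCounts-class] object.
#' @export
CellCounts <- function(counts, cellIds = NULL, geneIds = NULL,
                       datasetTag = "unnamed") {
  m <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (!is.null(cellIds)) rownames(m) <- cellIds
  if (!is.null(geneIds)) colnames(m) <- geneIds
  new("CellCounts", counts = m, datasetTag = datasetTag)
}

#' GeneSetList: a named collection of gene sets
#'
#' @slot sets named list of character vectors (unique gene ids per set).
#' @slot descriptions named character vector, parallel to `sets`.
#' @export
setClass("GeneSetList",
  slots = c(sets = "list", descriptions = "character"))

setValidity("GeneSetList", function(object) {
  msgs <- character()
  if (is.null(names(object@sets)) || any(!nzchar(names(object@sets))))
    msgs <- c(msgs, "every gene set must be named")
  else msgs <- c(msgs, .checkUnique(names(object@sets), "set names"))
  for (nm in names(object@sets)) {
    g <- object@sets[[nm]]
    if (!length(g)) msgs <- c(msgs, sprintf("set '%s' is empty", nm))
    if (anyDuplicated(g))
      msgs <- c(msgs, sprintf("set '%s' has duplicate genes", nm))
  }
  if (!identical(names(object@descriptions), names(object@sets)))
    msgs <- c(msgs, "descriptions must be named like sets")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneSetList
#'
#' @param sets named list of character gene-id vectors.
#' @param descriptions optional named character vector of descriptions.
#' @return a [GeneSetList-class].
#' @export
GeneSetList <- function(sets, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  new("GeneSetList", sets = sets, descriptions = descriptions[names(sets)])
}

#' NormalizedMatrix: log-normalized expression (cells x genes)
#'
#' Values are `log(1 + count * scaleFactor / cellTotal)`; zeros stay zero so
#' the matrix remains sparse.
#'
#' @slot values sparse real matrix, cells in rows.
#' @slot scaleFactor library-size scale factor used (default 1e4).
#' @export
setClass("NormalizedMatrix",
  slots = c(values = "dgCMatrix", scaleFactor = "numeric"))

setValidity("NormalizedMatrix", function(object) {
  m <- object@values
  msgs <- character()
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msgs <- c(msgs, "values must carry cell and gene names")
  if (length(m@x) && (any(!is.finite(m@x)) || any(m@x < 0)))
    msgs <- c(msgs, "values must be finite and non-negative")
  if (length(object@scaleFactor) != 1L || object@scaleFactor <= 0)
    msgs <- c(msgs, "scaleFactor must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' ScoreMatrix: per-cell gene-set activity scores
#'
#' @slot scores dense real matrix, cells x gene sets.
#' @slot alpha rank-weight exponent used by the ssGSEA running sum.
#' @slot coverage per-set fraction of its genes found in the expression
#'   matrix.
#' @export
setClass("ScoreMatrix",
  slots = c(scores = "matrix", alpha = "numeric", coverage = "numeric"))

setValidity("ScoreMatrix", function(object) {
  msgs <- character()
  if (any(!is.finite(object@scores)))
    msgs <- c(msgs, "scores must be finite")
  if (is.null(rownames(object@scores)) || is.null(colnames(object@scores)))
    msgs <- c(msgs, "scores must carry cell and set names")
  if (!identical(names(object@coverage), colnames(object@scores)))
    msgs <- c(msgs, "coverage must be named by set")
  if (length(msgs)) msgs else TRUE
})

#' MixtureFit: a two-component univariate Gaussian mixture fit
#'
#' @slot means,variances,weights component parameters (length 2).
#' @slot logLik final log-likelihood of the best EM run.
#' @slot logLikTrace per-iteration log-likelihood of the best run
#'   (non-decreasing).
#' @slot nIter iterations used by the best run.
#' @slot converged whether the tolerance was reached before `maxIter`.
#' @slot highComponent index (1 or 2) of the larger-mean component.
#' @export
setClass("MixtureFit",
  slots = c(means = "numeric", variances = "numeric", weights = "numeric",
            logLik = "numeric", logLikTrace = "numeric", nIter = "integer",
            converged = "logical", highComponent = "integer"))

setValidity("MixtureFit", function(object) {
  msgs <- character()
  if (length(object@means) != 2L || length(object@variances) != 2L ||
      length(object@weights) != 2L)
    msgs <- c(msgs, "means, variances and weights must have length 2")
  if (any(object@variances <= 0)) msgs <- c(msgs, "variances must be positive")
  if (abs(sum(object@weights) - 1) > 1e-9 || any(object@weights <= 0) ||
      any(object@weights >= 1))
    msgs <- c(msgs, "weights must lie in (0,1) and sum to 1")
  if (!object@highComponent %in% 1:2)
    msgs <- c(msgs, "highComponent must be 1 or 2")
  if (length(msgs)) msgs else TRUE
})

#' HypoxiaLabels: per-cell consensus hypoxia status
#'
#' Status is `HC_HYPOXIC` iff the cell falls in the high component for every
#' gene set, `HC_NORMOXIC` iff in the low component for every set, and
#' `LOW_CONF` otherwise.
#'
#' @slot cellId cell identifiers.
#' @slot status character vector over `HC_HYPOXIC`, `HC_NORMOXIC`,
#'   `LOW_CONF`.
#' @slot perSetGroup character matrix (cells x sets) of `HIGH`/`LOW` calls.
#' @slot posteriorHigh numeric matrix (cells x sets) of posterior
#'   probabilities of the high component.
#' @slot fits list of [MixtureFit-class], one per gene set.
#' @export
setClass("HypoxiaLabels",
  slots = c(cellId = "character", status = "character",
            perSetGroup = "matrix", posteriorHigh = "matrix", fits = "list"))

setValidity("HypoxiaLabels", function(object) {
  msgs <- character()
  n <- length(object@cellId)
  if (length(object@status) != n || nrow(object@perSetGroup) != n ||
      nrow(object@posteriorHigh) != n)
    msgs <- c(msgs, "per-cell slots must agree in length")
  if (!all(object@status %in% c("HC_HYPOXIC", "HC_NORMOXIC", "LOW_CONF")))
    msgs <- c(msgs, "invalid status value")
  if (!all(object@perSetGroup %in% c("HIGH", "LOW")))
    msgs <- c(msgs, "perSetGroup entries must be HIGH or LOW")
  allHigh <- rowSums(object@perSetGroup == "HIGH") == ncol(object@perSetGroup)
  allLow  <- rowSums(object@perSetGroup == "LOW")  == ncol(object@perSetGroup)
  want <- ifelse(allHigh, "HC_HYPOXIC", ifelse(allLow, "HC_NORMOXIC",
                                               "LOW_CONF"))
  if (!identical(unname(want), unname(object@status)))
    msgs <- c(msgs, "status inconsistent with the all-sets consensus rule")
  if (length(msgs)) msgs else TRUE
})

#' FeatureMatrix: per-cell classifier features
#'
#' @slot values dense real matrix, cells x features.
#' @slot featureMode `"embedding"` or `"raw_counts"`.
#' @slot provenance list describing how the features were produced.
#' @export
setClass("FeatureMatrix",
  slots = c(values = "matrix", featureMode = "character",
            provenance = "list"))

setValidity("FeatureMatrix", function(object) {
  msgs <- character()
  if (any(!is.finite(object@values))) msgs <- c(msgs, "values must be finite")
  if (is.null(rownames(object@values)))
    msgs <- c(msgs, "values must carry cell names")
  if (!object@featureMode %in% c("embedding", "raw_counts"))
    msgs <- c(msgs, "featureMode must be 'embedding' or 'raw_counts'")
  if (length(msgs)) msgs else TRUE
})

#' BenchmarkReport: learning-curve benchmark results and model selection
#'
#' @slot results long-format data.frame: model, feature_mode, fraction,
#'   dataset, accuracy, auroc, f1.
#' @slot meanRanks per-model average metric ranks on the selection feature
#'   mode.
#' @slot top3Intersection models ranked in the top 3 for every metric on
#'   average.
#' @slot selectedModel model minimising the mean rank.
#' @slot deltas paired embedding-minus-raw metric differences per condition
#'   (empty when a single mode was benchmarked).
#' @slot config the benchmark configuration used.
#' @export
setClass("BenchmarkReport",
  slots = c(results = "data.frame", meanRanks = "data.frame",
            top3Intersection = "character", selectedModel = "character",
            deltas = "data.frame", config = "list"))

setValidity("BenchmarkReport", function(object) {
  msgs <- character()
  need <- c("model", "feature_mode", "fraction", "dataset",
            "accuracy", "auroc", "f1")
  if (!all(need %in% names(object@results)))
    msgs <- c(msgs, "results must contain the standard benchmark columns")
  if (length(object@selectedModel) != 1L)
    msgs <- c(msgs, "selectedModel must be a single model name")
  if (!all(object@top3Intersection %in% unique(object@results$model)))
    msgs <- c(msgs, "top3Intersection must be benchmarked models")
  if (length(msgs)) msgs else TRUE
})
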