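#' Accessors for scHypoxia classes
#'
#' `cellIds()` and `geneIds()` return identifiers, `counts()` the sparse
#' count matrix, `exprValues()` normalized expression, `scores()` the
#' cells x sets score matrix, `geneSets()` the named list of gene sets,
#' `status()` the per-cell consensus status, `featureValues()` the feature
#' matrix, and `selectedModel()` / `benchResults()` / `meanRanks()` /
#' `topModels()` the pieces of a benchmark report.
#'
#' @param x an scHypoxia object.
#' @return the slot content described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("status", function(x) standardGeneric("status"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("featureMode", function(x) standardGeneric("featureMode"))
#' @rdname accessors
#' @export
setGeneric("selectedModel", function(x) standardGeneric("selectedModel"))
#' @rdname accessors
#' @export
setGeneric("benchResults", function(x) standardGeneric("benchResults"))
#' @rdname accessors
#' @export
setGeneric("meanRanks", function(x) standardGeneric("meanRanks"))
#' @rdname accessors
#' @export
setGeneric("topModels", function(x) standardGeneric("topModels"))

#' @rdname accessors
#' @export
setMethod("cellIds", "CellCounts", function(x) rownames(x@counts))
#' @rdname accessors
#' @export
setMethod("geneIds", "CellCounts", function(x) colnames(x@counts))
#' @rdname accessors
#' @param object a [CellCounts-class] (for the `counts` method).
#' @param ... ignored.
#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "CellCounts", function(object, ...) object@counts)
#' @rdname accessors
#' @export
setMethod("cellIds", "NormalizedMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("geneIds", "NormalizedMatrix", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("exprValues", "NormalizedMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("cellIds", "ScoreMatrix", function(x) rownames(x@scores))
#' @rdname accessors
#' @export
setMethod("scores", "ScoreMatrix", function(x) x@scores)
#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetList", function(x) x@sets)
#' @rdname accessors
#' @export
setMethod("cellIds", "HypoxiaLabels", function(x) x@cellId)
#' @rdname accessors
#' @export
setMethod("status", "HypoxiaLabels", function(x)
  stats::setNames(x@status, x@cellId))
#' @rdname accessors
#' @export
setMethod("cellIds", "FeatureMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("featureMode", "FeatureMatrix", function(x) x@featureMode)
#' @rdname accessors
#' @export
setMethod("selectedModel", "BenchmarkReport", function(x) x@selectedModel)
#' @rdname accessors
#' @export
setMethod("benchResults", "BenchmarkReport", function(x) x@results)
#' @rdname accessors
#' @export
setMethod("meanRanks", "BenchmarkReport", function(x) x@meanRanks)
#' @rdname accessors
#' @export
setMethod("topModels", "BenchmarkReport", function(x) x@top3Intersection)

#' @rdname accessors
#' @export
setMethod("length", "GeneSetList", function(x) length(x@sets))
#' @rdname accessors
#' @export
setMethod("names", "GeneSetList", function(x) names(x@sets))

setMethod("show", "CellCounts", function(object) {
  cat(sprintf("CellCounts: %d cells x %d genes (dataset '%s'), %d non-zeros\n",
              nrow(object@counts), ncol(object@counts), object@datasetTag,
              length(object@counts@x)))
})

setMethod("show", "GeneSetList", function(object) {
  sz <- vapply(object@sets, length, integer(1))
  cat(sprintf("GeneSetList: %d sets (sizes %s)\n", length(object@sets),
              paste(utils::head(sz, 8), collapse = ", ")))
})

setMethod("show", "NormalizedMatrix", function(object) {
  cat(sprintf("NormalizedMatrix: %d cells x %d genes, scale factor %g\n",
              nrow(object@values), ncol(object@values), object@scaleFactor))
})

setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf("ScoreMatrix: %d cells x %d gene sets (alpha = %g)\n",
              nrow(object@scores), ncol(object@scores), object@alpha))
})

setMethod("show", "MixtureFit", function(object) {
  cat(sprintf(paste0("MixtureFit: means %.4g / %.4g, weights %.3f / %.3f, ",
                     "logLik %.4f (%d iter, %s)\n"),
              object@means[1], object@means[2], object@weights[1],
              object@weights[2], object@logLik, object@nIter,
              if (object@converged) "converged" else "not converged"))
})

setMethod("show", "HypoxiaLabels", function(object) {
  tab <- table(factor(object@status,
                      c("HC_HYPOXIC", "HC_NORMOXIC", "LOW_CONF")))
  cat(sprintf(paste0("HypoxiaLabels: %d cells over %d gene sets — ",
                     "%d HC_HYPOXIC, %d HC_NORMOXIC, %d LOW_CONF\n"),
              length(object@cellId), ncol(object@perSetGroup),
              tab[["HC_HYPOXIC"]], tab[["HC_NORMOXIC"]], tab[["LOW_CONF"]]))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix (%s): %d cells x %d features\n",
              object@featureMode, nrow(object@values), ncol(object@values)))
})

setMethod("show", "BenchmarkReport", function(object) {
  cat(sprintf(paste0("BenchmarkReport: %d rows (%d models, %d fractions); ",
                     "selected model '%s'; top-3 intersection: %s\n"),
              nrow(object@results), length(unique(object@results$model)),
              length(unique(object@results$fraction)), object@selectedModel,
              paste(object@top3Intersection, collapse = ", ")))
})
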