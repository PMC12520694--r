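#' @title Readers and writers for on-disk artifacts
#' @description MatrixMarket triplet and dense-table count readers, GMT
#'   gene-set parsing, embedding ingestion, and tab-delimited writers for
#'   every table the pipeline emits. All writers emit UTF-8, tab-delimited
#'   text with a header row; numeric columns are formatted so that a
#'   write/read round trip is exact.
#' @name io
NULL

.detectDelim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

.readTable <- function(path) {
  read.delim(path, sep = .detectDelim(path), header = TRUE,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a data.frame as a lossless TSV
#'
#' Doubles are written with 17 significant digits so re-reading reproduces
#' them bit for bit; used by every pipeline stage writer.
#'
#' @param df a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

.findOne <- function(dir, patterns, what) {
  for (p in patterns) {
    hit <- list.files(dir, pattern = p, full.names = TRUE)
    if (length(hit)) return(hit[[1L]])
  }
  stop(sprintf("no %s file found in '%s'", what, dir))
}

#' Read a single-cell count matrix
#'
#' Two layouts are supported: `"mtx_triplet"` — a directory holding a
#' MatrixMarket coordinate file plus features and barcodes tables (the 10x
#' export convention) — and `"dense_table"` — a delimited table whose first
#' column is the cell id and whose header row names the genes. Orientation
#' is auto-detected from which id table matches which matrix dimension and
#' normalized to cells x genes.
#'
#' @param path directory (`mtx_triplet`) or file (`dense_table`).
#' @param layout one of `"mtx_triplet"`, `"dense_table"`.
#' @param datasetTag label stored on the returned object.
#' @return a [CellCounts-class].
#' @export
readCounts <- function(path, layout = c("mtx_triplet", "dense_table"),
                       datasetTag = basename(path)) {
  layout <- match.arg(layout)
  if (layout == "mtx_triplet") {
    mtx <- .findOne(path, "\\.mtx$", "MatrixMarket")
    feat <- .findOne(path, c("^features\\.tsv$", "^genes\\.tsv$"), "features")
    bar <- .findOne(path, "^barcodes\\.tsv$", "barcodes")
    m <- as(readMM(mtx), "CsparseMatrix")
    genes <- read.delim(feat, header = FALSE,
                        stringsAsFactors = FALSE)[[1L]]
    cells <- read.delim(bar, header = FALSE,
                        stringsAsFactors = FALSE)[[1L]]
    if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
      m <- Matrix::t(m)                       # features-in-rows convention
    } else if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
      # already cells x genes
    } else {
      stop(sprintf(paste0("dimension mismatch: matrix is %d x %d but ",
                          "features has %d rows and barcodes %d rows"),
                   nrow(m), ncol(m), length(genes), length(cells)))
    }
    dimnames(m) <- list(cells, genes)
    CellCounts(m, datasetTag = datasetTag)
  } else {
    tab <- .readTable(path)
    cells <- as.character(tab[[1L]])
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- cells
    CellCounts(vals, datasetTag = datasetTag)
  }
}

#' Write a CellCounts object as a MatrixMarket triplet bundle
#'
#' Emits `matrix.mtx` (genes in rows, the 10x convention), `features.tsv`
#' and `barcodes.tsv` into `dir`.
#'
#' @param x a [CellCounts-class].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeCounts <- function(x, dir) {
  stopifnot(is(x, "CellCounts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMM(Matrix::t(x@counts), file.path(dir, "matrix.mtx"))
  writeLines(geneIds(x), file.path(dir, "features.tsv"))
  writeLines(cellIds(x), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Parse a GMT gene-set file
#'
#' Each non-empty line is `name<TAB>description<TAB>gene...`. Duplicate
#' genes within a line are dropped keeping the first occurrence; identifiers
#' are matched case-sensitively after trimming whitespace.
#'
#' @param path GMT file.
#' @return a [GeneSetList-class] preserving file order.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[[i]]))) next
    fields <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]])
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(fields) < 3L || !length(genes))
      stop(sprintf("no genes on line %d", i))
    nm <- fields[[1L]]
    if (nm %in% names(sets))
      stop(sprintf("duplicate set name '%s' on line %d", nm, i))
    sets[[nm]] <- genes[!duplicated(genes)]
    descs[[nm]] <- fields[[2L]]
  }
  if (!length(sets)) stop(sprintf("no gene sets in '%s'", path))
  GeneSetList(sets, descs)
}

#' Write a GeneSetList in GMT format
#'
#' @param x a [GeneSetList-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(x, path) {
  stopifnot(is(x, "GeneSetList"))
  lines <- vapply(names(x@sets), function(nm) {
    paste(c(nm, x@descriptions[[nm]], x@sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an externally computed cell-embedding table
#'
#' A delimited table whose first column is the cell id and remaining columns
#' the embedding dimensions, e.g. exported from a pretrained single-cell
#' foundation model. Rows are reordered to match `expectedCells` exactly.
#'
#' @param path delimited file (tab or comma, auto-detected).
#' @param expectedCells character vector of required cell ids, in the order
#'   the returned rows must follow.
#' @return numeric matrix (cells x d) with `expectedCells` as rownames.
#' @export
readEmbedding <- function(path, expectedCells) {
  tab <- .readTable(path)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate cell ids in embedding file")
  missing <- setdiff(expectedCells, ids)
  if (length(missing)) {
    shown <- utils::head(missing, 10L)
    stop(sprintf("missing cells: %s%s", paste(shown, collapse = ", "),
                 if (length(missing) > 10L) ", ..." else ""))
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("non-finite value in embedding")
  if (ncol(m) < 2L) stop("embedding must have at least 2 dimensions")
  rownames(m) <- ids
  m[expectedCells, , drop = FALSE]
}

#' Read a gene annotation table
#'
#' Requires columns `gene_id`, `is_protein_coding`, `is_mitochondrial`
#' (logical or 0/1), one row per gene.
#'
#' @param path delimited file.
#' @return data.frame with the three columns, logicals coerced.
#' @export
readGeneAnnotation <- function(path) {
  tab <- .readTable(path)
  need <- c("gene_id", "is_protein_coding", "is_mitochondrial")
  if (!all(need %in% names(tab)))
    stop(sprintf("annotation must have columns: %s",
                 paste(need, collapse = ", ")))
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene_id in annotation")
  tab$is_protein_coding <- as.logical(tab$is_protein_coding)
  tab$is_mitochondrial <- as.logical(tab$is_mitochondrial)
  tab[need]
}

#' Write consensus hypoxia labels as a tab-delimited table
#'
#' One row per cell: `cell_id`, `status`, one `group_<set>` column and one
#' `posterior_<set>` column per gene set.
#'
#' @param labels a [HypoxiaLabels-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeLabels <- function(labels, path) {
  stopifnot(is(labels, "HypoxiaLabels"))
  k <- colnames(labels@perSetGroup)
  df <- data.frame(cell_id = labels@cellId, status = labels@status,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in k) df[[paste0("group_", nm)]] <- labels@perSetGroup[, nm]
  for (nm in k) df[[paste0("posterior_", nm)]] <- labels@posteriorHigh[, nm]
  writeTsv(df, path)
}

#' Read a label table written by [writeLabels()]
#'
#' @param path label TSV.
#' @return a [HypoxiaLabels-class] (without mixture fits).
#' @export
readLabels <- function(path) {
  tab <- .readTable(path)
  gcols <- grep("^group_", names(tab), value = TRUE)
  pcols <- grep("^posterior_", names(tab), value = TRUE)
  setsNm <- sub("^group_", "", gcols)
  grp <- as.matrix(tab[gcols])
  post <- as.matrix(tab[pcols])
  storage.mode(post) <- "double"
  dimnames(grp) <- list(tab$cell_id, setsNm)
  dimnames(post) <- list(tab$cell_id, setsNm)
  new("HypoxiaLabels", cellId = as.character(tab$cell_id),
      status = as.character(tab$status), perSetGroup = grp,
      posteriorHigh = post, fits = list())
}
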