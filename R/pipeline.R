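#' @title Pipeline orchestration
#' @description Runs the staged workflow (simulate/load -> qc -> normalize ->
#'   score -> label -> signature -> features -> bench -> predict) from a
#'   declarative configuration, caching stage outputs keyed by a digest of
#'   their parameters and upstream inputs, and writing a reproducibility
#'   manifest.
#' @name pipeline
NULL

.md5String <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}

.md5Params <- function(x) {
  .md5String(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                           digits = NA, null = "null")))
}

.md5File <- function(path) unname(tools::md5sum(path))

.logStage <- function(stage, msg, logFile = NULL) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  message(line)
  if (!is.null(logFile)) cat(line, "\n", file = logFile, append = TRUE)
}

.defaultConfig <- function() {
  list(
    outdir = "schypoxia_run",
    seed = 0L,
    inputs = list(counts = NULL, counts_layout = "mtx_triplet", gmt = NULL,
                  annotation = NULL, doublets = NULL, embedding = NULL),
    simulate = list(enabled = FALSE),
    qc = list(enabled = TRUE, min_genes = 500L, max_mito = 0.20,
              min_cells_frac = 0.001),
    normalize = list(scale_factor = 1e4),
    score = list(alpha = 0.25, min_genes_present = 3L),
    label = list(posterior_cut = 0.5, n_init = 5L),
    signature = list(p = 0.05, lfc = 0.25, min_pct = 0.10),
    features = list(provider = "svd", dim = 50L, file = NULL),
    bench = list(enabled = TRUE, holdout = 0.3,
                 fractions = seq(0.1, 1, by = 0.1), models = NULL,
                 class_weight = "none"),
    predict = list(enabled = TRUE, threshold = 0.5))
}

.mergeConfig <- function(user) {
  cfg <- .defaultConfig()
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], user[[nm]])
    else cfg[[nm]] <- user[[nm]]
  }
  cfg
}

.stageSeed <- function(seed, idx) (as.integer(seed) + 7919L * idx) %%
  2147483647L

#' Run the full hypoxia-classification pipeline
#'
#' Stages execute in order; each stage's outputs are written under
#' `outdir` and keyed by a digest of its parameters and upstream digests,
#' so a rerun with an unchanged configuration reuses the cached files.
#' Any stage error aborts the run naming the failing stage; outputs of
#' completed stages are retained.
#'
#' @param config a YAML file path or a nested list. Top-level keys:
#'   `outdir`, `seed`, `inputs`, and one section per stage (`simulate`,
#'   `qc`, `normalize`, `score`, `label`, `signature`, `features`, `bench`,
#'   `predict`). See `vignette("hypoxia-classification")`.
#' @return the run manifest, invisibly (also written to
#'   `outdir/manifest.json`).
#' @export
runPipeline <- function(config) {
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- .mergeConfig(user)
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outdir, "events.log")

  prevManifest <- NULL
  mPath <- file.path(outdir, "manifest.json")
  if (file.exists(mPath))
    prevManifest <- tryCatch(jsonlite::read_json(mPath),
                             error = function(e) NULL)

  manifest <- list(tool = "scHypoxia",
                   version = as.character(utils::packageVersion("scHypoxia")),
                   config = cfg, input_digests = list(), stages = list(),
                   counts = list())
  # keep a manifest of whatever completed, even when a later stage aborts
  on.exit(try(jsonlite::write_json(manifest, mPath, auto_unbox = TRUE,
                                   digits = NA, pretty = TRUE,
                                   null = "null", force = TRUE),
              silent = TRUE), add = TRUE)

  cached <- function(stage, key, files) {
    prev <- prevManifest$stages[[stage]]
    if (is.null(prev) || !identical(prev$key, key)) return(FALSE)
    all(vapply(names(files), function(nm) {
      f <- files[[nm]]
      file.exists(f) && identical(.md5File(f), prev$outputs[[nm]])
    }, logical(1)))
  }
  record <- function(stage, key, seed, params, files, hit, extra = list()) {
    manifest$stages[[stage]] <<- c(
      list(key = key, seed = seed, params = params,
           outputs = lapply(files, .md5File), cache_hit = hit), extra)
  }
  runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  ## ---- stage 1: counts + gene sets + annotation -------------------------
  simDir <- file.path(outdir, "simulated")
  if (isTRUE(cfg$simulate$enabled)) {
    simArgs <- cfg$simulate[setdiff(names(cfg$simulate), "enabled")]
    names(simArgs) <- gsub("_(\\w)", "\\U\\1", names(simArgs), perl = TRUE)
    if (is.null(simArgs$seed)) simArgs$seed <- .stageSeed(cfg$seed, 1L)
    sp <- do.call(simParams, simArgs)
    key <- .md5Params(list(stage = "simulate", params = unclass(sp)))
    files <- list(mtx = file.path(simDir, "counts", "matrix.mtx"),
                  gmt = file.path(simDir, "hypoxia_sets.gmt"),
                  annotation = file.path(simDir, "annotation.tsv"),
                  truth = file.path(simDir, "truth.tsv"))
    hit <- cached("simulate", key, files)
    sim <- runStage("simulate", {
      if (hit) {
        .logStage("simulate", "cache hit", logFile)
        list(counts = readCounts(file.path(simDir, "counts"), "mtx_triplet",
                                 datasetTag = "synthetic"),
             sets = readGmt(files$gmt),
             annotation = readGeneAnnotation(files$annotation),
             truth = .readTable(files$truth))
      } else {
        .logStage("simulate", "generating synthetic cohort", logFile)
        s <- simulateHypoxia(sp)
        writeSimBundle(s, simDir)
        s
      }
    })
    record("simulate", key, sp$seed, unclass(sp), files, hit)
    countsRaw <- sim$counts; sets <- sim$sets; annotation <- sim$annotation
    doublets <- NULL
  } else {
    inp <- cfg$inputs
    if (is.null(inp$counts) || is.null(inp$gmt) || is.null(inp$annotation))
      stop("stage 'input' failed: counts, gmt and annotation are required ",
           "when simulate is disabled")
    countsRaw <- runStage("input",
      readCounts(inp$counts, inp$counts_layout))
    sets <- runStage("input", readGmt(inp$gmt))
    annotation <- runStage("input", readGeneAnnotation(inp$annotation))
    doublets <- NULL
    if (!is.null(inp$doublets)) {
      dt <- .readTable(inp$doublets)
      doublets <- stats::setNames(as.logical(dt[[2L]]),
                                  as.character(dt[[1L]]))
    }
    for (nm in c("counts", "gmt", "annotation"))
      if (!is.null(inp[[nm]]) && file.exists(inp[[nm]]) &&
          !dir.exists(inp[[nm]]))
        manifest$input_digests[[nm]] <- .md5File(inp[[nm]])
  }
  manifest$counts$cells_input <- nrow(counts(countsRaw))

  ## ---- stage 2: qc ------------------------------------------------------
  qcKey <- .md5Params(list(stage = "qc", params = cfg$qc,
                           up = manifest$stages$simulate$key,
                           n = dim(counts(countsRaw))))
  qcDir <- file.path(outdir, "qc_counts")
  qcFiles <- list(mtx = file.path(qcDir, "matrix.mtx"),
                  report = file.path(outdir, "qc_report.json"))
  qcHit <- cached("qc", qcKey, qcFiles)
  qcRes <- runStage("qc", {
    if (!isTRUE(cfg$qc$enabled)) {
      list(counts = countsRaw, report = list(skipped = TRUE))
    } else if (qcHit) {
      .logStage("qc", "cache hit", logFile)
      list(counts = readCounts(qcDir, "mtx_triplet",
                               datasetTag = countsRaw@datasetTag),
           report = jsonlite::read_json(qcFiles$report))
    } else {
      .logStage("qc", "filtering cells and genes", logFile)
      r <- qcFilter(countsRaw, annotation,
                    qcParams(cfg$qc$min_genes, cfg$qc$max_mito,
                             cfg$qc$min_cells_frac),
                    doubletFlags = doublets)
      writeCounts(r$counts, qcDir)
      jsonlite::write_json(r$report, qcFiles$report, auto_unbox = TRUE)
      r
    }
  })
  qcCounts <- qcRes$counts
  record("qc", qcKey, NA, cfg$qc,
         if (isTRUE(cfg$qc$enabled)) qcFiles else list(), qcHit,
         list(report = qcRes$report))
  manifest$counts$cells_post_qc <- nrow(counts(qcCounts))

  ## ---- stage 3: normalize (recomputed in memory; cheap, deterministic) --
  normKey <- .md5Params(list(stage = "normalize", params = cfg$normalize,
                             up = qcKey))
  norm <- runStage("normalize",
                   logNormalize(qcCounts, cfg$normalize$scale_factor))
  record("normalize", normKey, NA, cfg$normalize, list(), qcHit)

  ## ---- stage 4: score ---------------------------------------------------
  scoreKey <- .md5Params(list(stage = "score", params = cfg$score,
                              up = normKey))
  scoreFile <- list(scores = file.path(outdir, "scores.tsv"))
  scoreHit <- cached("score", scoreKey, scoreFile)
  scoreMat <- runStage("score", {
    if (scoreHit) {
      .logStage("score", "cache hit", logFile)
      tab <- .readTable(scoreFile$scores)
      m <- as.matrix(tab[, -1L, drop = FALSE])
      rownames(m) <- tab[[1L]]
      cov <- unlist(prevManifest$stages$score$coverage)
      new("ScoreMatrix", scores = m, alpha = cfg$score$alpha,
          coverage = stats::setNames(as.numeric(cov[colnames(m)]),
                                     colnames(m)))
    } else {
      .logStage("score", sprintf("ssGSEA over %d sets", length(sets)),
                logFile)
      sm <- suppressMessages(
        ssgseaScore(norm, sets, alpha = cfg$score$alpha,
                    minGenesPresent = cfg$score$min_genes_present))
      writeTsv(data.frame(cell_id = cellIds(sm), scores(sm),
                          check.names = FALSE), scoreFile$scores)
      sm
    }
  })
  record("score", scoreKey, NA, cfg$score, scoreFile, scoreHit,
         list(coverage = as.list(scoreMat@coverage)))

  ## ---- stage 5: label ---------------------------------------------------
  labelSeed <- .stageSeed(cfg$seed, 5L)
  labelKey <- .md5Params(list(stage = "label", params = cfg$label,
                              seed = labelSeed, up = scoreKey))
  labelFile <- list(labels = file.path(outdir, "labels.tsv"))
  labelHit <- cached("label", labelKey, labelFile)
  labels <- runStage("label", {
    if (labelHit) {
      .logStage("label", "cache hit", logFile)
      readLabels(labelFile$labels)
    } else {
      .logStage("label", "fitting per-set Gaussian mixtures", logFile)
      lb <- labelHypoxia(scoreMat, seed = labelSeed,
                         posteriorCut = cfg$label$posterior_cut,
                         nInit = cfg$label$n_init)
      writeLabels(lb, labelFile$labels)
      lb
    }
  })
  labCounts <- as.list(table(status(labels)))
  record("label", labelKey, labelSeed, cfg$label, labelFile, labelHit,
         list(label_counts = labCounts))
  manifest$counts$labels <- labCounts

  ## ---- stage 6: signature ----------------------------------------------
  sigKey <- .md5Params(list(stage = "signature", params = cfg$signature,
                            up = c(normKey, labelKey)))
  sigFile <- list(signature = file.path(outdir, "signature.tsv"))
  sigHit <- cached("signature", sigKey, sigFile)
  signature <- runStage("signature", {
    if (sigHit) {
      .logStage("signature", "cache hit", logFile)
      tab <- .readTable(sigFile$signature)
      tab$passes <- as.logical(tab$passes)
      tab$is_protein_coding <- as.logical(tab$is_protein_coding)
      tab
    } else {
      .logStage("signature", "rank-sum differential expression", logFile)
      sg <- deriveSignature(norm, labels, annotation,
                            pThresh = cfg$signature$p,
                            lfcThresh = cfg$signature$lfc,
                            minPct = cfg$signature$min_pct)
      writeTsv(sg, sigFile$signature)
      sg
    }
  })
  record("signature", sigKey, NA, cfg$signature, sigFile, sigHit,
         list(n_passing = sum(signature$passes)))
  manifest$counts$signature_size <- sum(signature$passes)

  ## ---- stage 7: features ------------------------------------------------
  featSeed <- .stageSeed(cfg$seed, 7L)
  featKey <- .md5Params(list(stage = "features", params = cfg$features,
                             seed = featSeed, up = c(normKey, sigKey)))
  featFiles <- list(embedding = file.path(outdir, "features_embedding.tsv"),
                    raw = file.path(outdir, "features_raw.tsv"))
  featHit <- cached("features", featKey, featFiles)
  feats <- runStage("features", {
    if (featHit) {
      .logStage("features", "cache hit", logFile)
      lapply(stats::setNames(c("embedding", "raw"),
                             c("embedding", "raw_counts")), function(nm) {
        tab <- .readTable(featFiles[[nm]])
        m <- as.matrix(tab[, -1L, drop = FALSE])
        rownames(m) <- tab[[1L]]
        new("FeatureMatrix", values = m,
            featureMode = if (nm == "embedding") "embedding" else
              "raw_counts",
            provenance = list(cached = TRUE))
      })
    } else {
      .logStage("features", sprintf("building %s + raw features",
                                    cfg$features$provider), logFile)
      embSpec <- switch(cfg$features$provider,
        svd = embeddingSpec("svd_fallback", dim = cfg$features$dim,
                            seed = featSeed),
        external = embeddingSpec("external_file",
                                 sourcePath = cfg$features$file,
                                 seed = featSeed),
        stop("features.provider must be 'svd' or 'external'"))
      emb <- suppressMessages(buildFeatures(norm, embSpec, signature))
      raw <- buildFeatures(norm, embeddingSpec("raw_signature"), signature)
      writeTsv(data.frame(cell_id = cellIds(emb), featureValues(emb),
                          check.names = FALSE), featFiles$embedding)
      writeTsv(data.frame(cell_id = cellIds(raw), featureValues(raw),
                          check.names = FALSE), featFiles$raw)
      list(embedding = emb, raw_counts = raw)
    }
  })
  record("features", featKey, featSeed, cfg$features, featFiles, featHit)

  ## ---- stage 8: bench ---------------------------------------------------
  benchRan <- isTRUE(cfg$bench$enabled)
  report <- NULL
  benchSeed <- .stageSeed(cfg$seed, 8L)
  if (benchRan) {
    models <- cfg$bench$models
    if (is.null(models)) models <- names(modelRegistry())
    bcfg <- benchConfig(modelNames = models,
                        fractions = as.numeric(cfg$bench$fractions),
                        holdoutFraction = cfg$bench$holdout,
                        seed = benchSeed,
                        classWeight = cfg$bench$class_weight)
    benchKey <- .md5Params(list(stage = "bench", params = cfg$bench,
                                seed = benchSeed, up = featKey))
    benchFiles <- list(results = file.path(outdir, "benchmark.tsv"),
                       summary = file.path(outdir, "bench_summary.json"))
    benchHit <- cached("bench", benchKey, benchFiles)
    report <- runStage("bench", {
      if (benchHit) {
        .logStage("bench", "cache hit", logFile)
        res <- .readTable(benchFiles$results)
        summ <- jsonlite::read_json(benchFiles$summary)
        sel <- rankAndSelect(res, "embedding")
        new("BenchmarkReport", results = res, meanRanks = sel$meanRanks,
            top3Intersection = unlist(summ$top3_intersection),
            selectedModel = summ$selected_model, deltas = data.frame(),
            config = unclass(bcfg))
      } else {
        .logStage("bench", sprintf("benchmarking %d models x %d fractions",
                                   length(models),
                                   length(bcfg$fractions)), logFile)
        rp <- withCallingHandlers(
          runBenchmark(feats, labels, bcfg),
          warning = function(w) {
            .logStage("bench", conditionMessage(w), logFile)
            invokeRestart("muffleWarning")
          })
        writeTsv(benchResults(rp), benchFiles$results)
        jsonlite::write_json(
          list(selected_model = selectedModel(rp),
               top3_intersection = topModels(rp),
               mean_ranks = meanRanks(rp)),
          benchFiles$summary, auto_unbox = TRUE, digits = NA)
        rp
      }
    })
    record("bench", benchKey, benchSeed, cfg$bench, benchFiles, benchHit,
           list(selected_model = selectedModel(report),
                top3_intersection = as.list(topModels(report))))
    manifest$counts$models_run <- unique(benchResults(report)$model)
  }

  ## ---- stage 9: predict -------------------------------------------------
  if (isTRUE(cfg$predict$enabled)) {
    predSeed <- .stageSeed(cfg$seed, 9L)
    if (is.null(report))
      runStage("predict", stop("no trained model (bench stage disabled)"))
    predKey <- .md5Params(list(stage = "predict", params = cfg$predict,
                               seed = predSeed,
                               up = manifest$stages$bench$key))
    predFile <- list(predictions = file.path(outdir, "predictions.tsv"))
    predHit <- cached("predict", predKey, predFile)
    preds <- runStage("predict", {
      if (predHit) {
        .logStage("predict", "cache hit", logFile)
        .readTable(predFile$predictions)
      } else {
        .logStage("predict", sprintf("classifying low-confidence cells with %s",
                                     selectedModel(report)), logFile)
        clf <- trainClassifier(selectedModel(report), feats$embedding,
                               labels, seed = predSeed,
                               classWeight = cfg$bench$class_weight)
        st <- status(labels)
        lowIds <- names(st)[st == "LOW_CONF"]
        lowFeat <- new("FeatureMatrix",
                       values = featureValues(feats$embedding)[lowIds, ,
                                                               drop = FALSE],
                       featureMode = "embedding",
                       provenance = list(subset = "LOW_CONF"))
        pr <- classifyLowConfidence(clf, lowFeat,
                                    threshold = cfg$predict$threshold)
        writeTsv(pr, predFile$predictions)
        pr
      }
    })
    record("predict", predKey, predSeed, cfg$predict, predFile, predHit,
           list(n_predicted = nrow(preds),
                predicted_counts = as.list(table(preds$predicted_status))))
  }

  jsonlite::write_json(manifest, mPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(manifest)
}
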