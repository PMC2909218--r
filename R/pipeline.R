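# Tiny FNV-1a hash for provenance headers (no external digest dependency).
# The 32-bit state is kept as a double and split into 16-bit halves for the
# xor and the modular multiply, since R integers are signed 32-bit.
.configHash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    lo <- bitwXor(as.integer(h %% 65536), as.integer(b %% 65536))
    hi <- bitwXor(as.integer(h %/% 65536), as.integer(b %/% 65536))
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.stage <- function(name, log, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full processing pipeline
#'
#' Orchestrates, end to end: extraction of FE files (or synthetic
#' generation), replicate collapse and log2 transform, normalization to the
#' mean reference, the variance/QC report, expressed-gene calling against
#' the negative-control background, and classical MDS. Every tabular
#' output is written as TSV with a provenance comment header (config hash
#' and seed); identical configuration and seed give byte-identical
#' outputs.
#'
#' @param config a named list, or path to a YAML file holding one, with
#'   elements:
#'   \describe{
#'     \item{inputDir}{directory of FE files (omit when simulating).}
#'     \item{simulate}{named list of [simConfig()] arguments; when present
#'       a synthetic dataset is generated under `outputDir/fe`.}
#'     \item{outputDir}{where all stage outputs are written (required).}
#'     \item{method}{normalization method, default `"loess"`.}
#'     \item{segments}{loess smoothing scale, default 10.}
#'     \item{leaveOneOut}{exclude each array from its own reference.}
#'     \item{controlProbe}{negative-control probe name, default
#'       `"(-)3xSLv1"`.}
#'     \item{thresholds}{call thresholds, default `seq(0, 1, 0.1)`.}
#'     \item{kMax, cutoff}{MDS dimensions to retain and goodness-of-fit
#'       cutoff (default 0.8).}
#'     \item{seed}{integer seed, default 1.}
#'   }
#' @param verbose print stage progress to stderr.
#' @return invisibly, a list with the main result objects (`cy3`, `cy5`,
#'   normalized matrices, `qc`, `background`, `callCurves`, `mds`) and
#'   `outputs`, the named vector of files written.
#' @examples
#' out <- runPipeline(list(
#'   simulate = list(nProbes = 120, nReplicateProbes = 6,
#'                   negativeControlCount = 10, nArrays = 4),
#'   outputDir = tempfile(), seed = 5))
#' names(out$outputs)
#' @export
runPipeline <- function(config, verbose = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$outputDir))
  seed <- as.integer(config$seed %||% 1L)
  method <- config$method %||% "loess"
  segments <- config$segments %||% 10L
  controlProbe <- config$controlProbe %||% "(-)3xSLv1"
  thresholds <- config$thresholds %||% seq(0, 1, by = 0.1)
  cutoff <- config$cutoff %||% 0.8
  outDir <- config$outputDir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  # hash the analysis-relevant configuration only: where the outputs go
  # must not change what they contain
  hash <- .configHash(config[sort(setdiff(names(config), "outputDir"))])
  prov <- c(paste0("config_hash: ", hash), paste0("seed: ", seed))
  note <- function(...) if (verbose) message("[pipeline] ", ...)
  logLines <- c(paste0("# run log (config ", hash, ", seed ", seed, ")"),
                paste0("R version: ", getRversion()),
                paste0("AgiPipe version: ",
                       as.character(utils::packageVersion("AgiPipe"))))

  inputDir <- config$inputDir
  if (!is.null(config$simulate)) {
    note("simulate")
    inputDir <- file.path(outDir, "fe")
    .stage("simulate", logLines, {
      cfg <- do.call(simConfig, c(config$simulate, list(seed = seed)))
      generateDataset(cfg, inputDir)
    })
    logLines <- c(logLines, "stage simulate: ok")
  }
  if (is.null(inputDir) || !dir.exists(inputDir))
    stop("pipeline stage 'extract' failed: input directory not found: ",
         inputDir %||% "<missing>")

  note("extract")
  tables <- .stage("extract", logLines,
                   readFeatureExtractionDir(inputDir,
                                            pattern = "^array.*\\.txt$|^.*\\.txt$"))
  tables <- tables[!grepl("^truth_", names(tables))]
  logLines <- c(logLines, paste0("stage extract: ", length(tables),
                                 " arrays"))

  note("preprocess")
  prep <- .stage("preprocess", logLines, {
    list(cy3 = buildChannelMatrix(tables, "Cy3",
                                  negativeControlProbe = controlProbe),
         cy5 = buildChannelMatrix(tables, "Cy5",
                                  negativeControlProbe = controlProbe))
  })
  outputs <- c(
    raw_cy3 = writeSignalMatrix(prep$cy3,
                                file.path(outDir, "raw_cy3.tsv"), prov),
    raw_cy5 = writeSignalMatrix(prep$cy5,
                                file.path(outDir, "raw_cy5.tsv"), prov))
  logLines <- c(logLines, paste0("stage preprocess: ", nrow(prep$cy3),
                                 " probes"))

  note("normalize (", method, ")")
  norm <- .stage("normalize", logLines, {
    list(cy3 = normalizeToReference(prep$cy3, method = method,
                                    segments = segments,
                                    leaveOneOut = isTRUE(config$leaveOneOut)),
         cy5 = normalizeToReference(prep$cy5, method = method,
                                    segments = segments,
                                    leaveOneOut = isTRUE(config$leaveOneOut)))
  })
  outputs <- c(outputs,
    norm_cy3 = writeSignalMatrix(norm$cy3,
                                 file.path(outDir, "norm_cy3.tsv"), prov),
    norm_cy5 = writeSignalMatrix(norm$cy5,
                                 file.path(outDir, "norm_cy5.tsv"), prov))
  logLines <- c(logLines, paste0("stage normalize: ", method))

  note("qc")
  qc <- .stage("qc", logLines, channelStats(norm$cy5, norm$cy3))
  qcPath <- file.path(outDir, "qc_report.tsv")
  writeVarianceReport(qc, qcPath)
  sv <- if (ncol(norm$cy3) >= 3L) sdVsMean(norm$cy3) else NULL
  qcs <- file.path(outDir, "qc_summary.tsv")
  con <- file(qcs, "wt"); writeLines(paste0("# ", prov), con)
  s <- reportSummary(qc)
  writeLines("statistic\tvalue", con)
  writeLines(sprintf("%s\t%.6f", c("meanSdCy5", "meanSdCy3", "meanCov",
                                   "meanCor", "sdDifference"),
                     c(s$meanSdCy5, s$meanSdCy3, s$meanCov, s$meanCor,
                       s$sdDifference)), con)
  if (!is.null(sv))
    writeLines(sprintf("%s\t%.6f", c("sdVsMeanSlope", "sdVsMeanR2"),
                       c(sv$slope, sv$r.squared)), con)
  close(con)
  outputs <- c(outputs, qc_report = qcPath, qc_summary = qcs)
  logLines <- c(logLines, "stage qc: ok")

  note("call")
  callRes <- .stage("call", logLines, {
    bg <- fitBackground(norm$cy5, controlProbe = controlProbe)
    v <- signalValues(norm$cy5)[!isNegativeControl(norm$cy5), ,
                                drop = FALSE]
    curves <- lapply(colnames(v), function(a)
      callExpressed(v[, a], bg, thresholds, arrayId = a))
    names(curves) <- colnames(v)
    list(bg = bg, curves = curves)
  })
  callPath <- file.path(outDir, "call_curves.tsv")
  con <- file(callPath, "wt"); writeLines(paste0("# ", prov), con)
  writeLines(paste(c("threshold", names(callRes$curves), "mean"),
                   collapse = "\t"), con)
  fracs <- vapply(callRes$curves, fractionOn,
                  numeric(length(thresholds)))
  fracs <- cbind(fracs, mean = rowMeans(fracs))
  writeLines(vapply(seq_along(thresholds), function(i)
    paste(c(sprintf("%.3f", thresholds[i]), sprintf("%.6f", fracs[i, ])),
          collapse = "\t"), character(1)), con)
  close(con)
  outputs <- c(outputs, call_curves = callPath)
  logLines <- c(logLines, "stage call: ok")

  note("mds")
  mdsRes <- if (ncol(norm$cy5) >= 3L) {
    .stage("mds", logLines, {
      ann <- data.frame(arrayId = arrayIds(norm$cy5))
      annPath <- file.path(inputDir, "truth_arrays.tsv")
      if (file.exists(annPath)) {
        tr <- utils::read.delim(annPath, stringsAsFactors = FALSE)
        ann <- merge(ann, tr, by = "arrayId", sort = FALSE)
      }
      classicalMDS(distanceMatrix(norm$cy5),
                   kMax = config$kMax %||% NULL, cutoff = cutoff,
                   annotations = ann)
    })
  } else NULL
  if (!is.null(mdsRes)) {
    sc <- file.path(outDir, "mds_scores.tsv")
    writeSignalMatrix(t(mdsPoints(mdsRes)), sc, prov)
    eg <- file.path(outDir, "mds_fit.tsv")
    con <- file(eg, "wt"); writeLines(paste0("# ", prov), con)
    writeLines("k\teigenvalue\tpk", con)
    ev <- eigenvalues(mdsRes); pk <- goodnessCurve(mdsRes)
    writeLines(sprintf("%d\t%.10g\t%.6f", seq_along(pk),
                       ev[seq_along(pk)], pk), con)
    writeLines(sprintf("# selected_k\t%d", selectedK(mdsRes)), con)
    close(con)
    outputs <- c(outputs, mds_scores = sc, mds_fit = eg)
    logLines <- c(logLines, paste0("stage mds: selected k = ",
                                   selectedK(mdsRes)))
  }

  logPath <- file.path(outDir, "run_log.txt")
  writeLines(logLines, logPath)
  outputs <- c(outputs, run_log = logPath)
  invisible(list(cy3 = prep$cy3, cy5 = prep$cy5,
                 normCy3 = norm$cy3, normCy5 = norm$cy5,
                 qc = qc, background = callRes$bg,
                 callCurves = callRes$curves, mds = mdsRes,
                 outputs = outputs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
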