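#' Read one Agilent Feature Extraction text file
#'
#' Feature Extraction (FE) output is a tab-delimited text file made of
#' stanzas (`FEPARAMS`, `STATS`, ...) followed by a `FEATURES` stanza: a
#' line whose first field is the token `FEATURES` and whose remaining
#' fields name the columns, followed by one `DATA` line per spotted
#' feature. Only the `FEATURES` stanza is consumed; columns are located by
#' name, so column order and extra columns are irrelevant. Rows whose
#' median signals are non-numeric or not strictly positive are dropped and
#' counted in the parse report rather than clamped, so that a log2
#' transform downstream is always valid.
#'
#' @param path path to an FE text file.
#' @param arrayId identifier for the array; defaults to the file name
#'   without extension.
#' @return A [FeatureTable-class] with one record per retained feature.
#' @examples
#' cfg <- simConfig(nProbes = 50, nReplicateProbes = 5,
#'                  negativeControlCount = 5, nArrays = 1, seed = 1)
#' d <- generateDataset(cfg, dir = tempfile())
#' ft <- readFeatureExtraction(d$files[1])
#' ft
#' @export
readFeatureExtraction <- function(path, arrayId = NULL) {
  if (!file.exists(path))
    stop("FE file not found: ", path)
  if (is.null(arrayId))
    arrayId <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  first <- sub("\t.*$", "", lines)
  hdr <- which(first == "FEATURES")
  if (length(hdr) == 0L)
    stop("no FEATURES block found in '", path, "'")
  hdr <- hdr[1L]
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]][-1L]
  required <- c("ProbeName", "ControlType", "gMedianSignal", "rMedianSignal")
  missing <- setdiff(required, cols)
  if (length(missing))
    stop("FEATURES block of '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "))
  body <- lines[-seq_len(hdr)]
  body <- body[seq_len(match(FALSE, sub("\t.*$", "", body) == "DATA",
                             nomatch = length(body) + 1L) - 1L)]
  if (length(body) == 0L)
    stop("FEATURES block of '", path, "' contains zero data rows")
  fields <- strsplit(body, "\t", fixed = TRUE)
  pick <- function(name) {
    j <- match(name, cols) + 1L  # field 1 is the DATA token
    vapply(fields, function(f) if (length(f) >= j) f[j] else NA_character_,
           character(1))
  }
  probe <- pick("ProbeName")
  ctype <- suppressWarnings(as.integer(pick("ControlType")))
  g <- suppressWarnings(as.numeric(pick("gMedianSignal")))
  r <- suppressWarnings(as.numeric(pick("rMedianSignal")))
  idx <- if ("FeatureNum" %in% cols)
    suppressWarnings(as.integer(pick("FeatureNum")))
  else seq_along(probe)
  bad <- !is.finite(g) | !is.finite(r) | g <= 0 | r <= 0 |
    is.na(probe) | !nzchar(probe) | is.na(ctype)
  report <- character(0)
  if (any(bad))
    report <- sprintf("row %d dropped: unparseable or non-positive signal (probe '%s')",
                      which(bad), ifelse(is.na(probe[bad]), "?", probe[bad]))
  keep <- !bad
  if (!any(keep))
    stop("all data rows of '", path, "' were unparseable")
  new("FeatureTable",
      arrayId = arrayId,
      features = data.frame(
        featureIndex = idx[keep],
        probeName = probe[keep],
        controlType = ctype[keep],
        gMedianSignal = g[keep],
        rMedianSignal = r[keep],
        stringsAsFactors = FALSE
      ),
      parseReport = report,
      nDropped = sum(bad))
}

#' Read every FE file in a directory
#'
#' @param dir directory containing FE text files.
#' @param pattern file-name pattern (default `"\\.txt$"`).
#' @return named list of [FeatureTable-class] objects.
#' @export
readFeatureExtractionDir <- function(dir, pattern = "\\.txt$") {
  paths <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(paths) == 0L)
    stop("no FE files matching '", pattern, "' in ", dir)
  tabs <- lapply(paths, readFeatureExtraction)
  names(tabs) <- vapply(tabs, arrayId, character(1))
  if (anyDuplicated(names(tabs)))
    stop("duplicate array ids among FE files in ", dir)
  tabs
}

#' Write / read a probe-by-array signal matrix as TSV
#'
#' Plain UTF-8 TSV: optional leading comment lines starting with `#`, then
#' a header row (`probe_id` followed by the array ids) and one row per
#' probe. Values are written with 17 significant digits so that a
#' write/read round trip is bit-exact.
#'
#' @param m a [ChannelMatrix-class] or a numeric matrix with dimnames.
#' @param path output/input file path.
#' @param comments optional character vector written as `# `-prefixed
#'   provenance lines before the header.
#' @return `writeSignalMatrix` returns `path` invisibly;
#'   `readSignalMatrix` returns a numeric matrix with probe ids as row
#'   names and array ids as column names.
#' @export
writeSignalMatrix <- function(m, path, comments = character(0)) {
  v <- .signalOf(m)
  if (nrow(v) == 0L || ncol(v) == 0L)
    stop("refusing to write an empty matrix")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  writeLines(paste(c("probe_id", colnames(v)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], sprintf("%.17g", v[i, ])), collapse = "\t"),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname writeSignalMatrix
#' @export
readSignalMatrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2L)
    stop("signal matrix file '", path, "' has no data rows")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  arrays <- header[-1L]
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  if (any(lengths(fields) != length(header)))
    stop("ragged rows in signal matrix file '", path, "'")
  probes <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(probes))
    stop("duplicate probe ids in '", path, "': ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  v <- matrix(as.numeric(unlist(lapply(fields, `[`, -1L))),
              nrow = length(probes), ncol = length(arrays), byrow = TRUE,
              dimnames = list(probes, arrays))
  if (any(!is.finite(v)))
    stop("non-finite values in '", path, "'")
  v
}

# Accept either a ChannelMatrix or a plain numeric matrix.
.signalOf <- function(m) {
  if (is(m, "ChannelMatrix")) assay(m, "signal")
  else if (is.matrix(m) && is.numeric(m)) m
  else stop("expected a ChannelMatrix or a numeric matrix")
}
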