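#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

IHC_CLASSES <- c("cold", "altered", "hot", "indeterminate")

## Coerce the expression argument of user-facing functions to a plain
## genes x samples TPM matrix, whatever container it arrived in.
.tpmMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    nm <- SummarizedExperiment::assayNames(x)
    a <- if ("tpm" %in% nm) SummarizedExperiment::assay(x, "tpm")
         else SummarizedExperiment::assay(x)
    return(as.matrix(a))
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression input must be a numeric matrix or SummarizedExperiment")
  x
}

.checkExpressionValues <- function(mat, what = "expression matrix") {
  bad <- which(!is.finite(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    g <- rownames(mat)[bad[1, 1]]
    s <- colnames(mat)[bad[1, 2]]
    stop(sprintf(
      "%s contains a negative, missing or non-finite value at gene '%s', sample '%s'",
      what, if (is.null(g)) bad[1, 1] else g,
      if (is.null(s)) bad[1, 2] else s))
  }
  invisible(mat)
}

#' Read and write TPM expression matrices
#'
#' Expression matrices are tab-separated text, genes as rows and samples as
#' columns, with the first column holding gene symbols and the header row
#' holding sample identifiers (the common TPM export layout; use
#' \code{transpose = TRUE} for samples-as-rows files). Gene symbols are
#' canonicalised through the alias map on read; values must be finite and
#' non-negative.
#'
#' @param path File path.
#' @param aliasMap Named character vector mapping alias to canonical gene
#'   symbols (see [defaultAliasMap()]); use \code{character(0)} to disable.
#' @param transpose If \code{TRUE} the file is samples x genes and is
#'   transposed after reading.
#' @param x For \code{writeExpressionMatrix}: a
#'   \linkS4class{SummarizedExperiment} or numeric genes x samples matrix.
#' @return \code{readExpressionMatrix}: a
#'   \linkS4class{SummarizedExperiment} with a single \code{"tpm"} assay.
#'   \code{writeExpressionMatrix}: the path, invisibly.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(c(0, 1, 2, 3), 2, 2,
#'             dimnames = list(c("CXCL9", "CD27"), c("s1", "s2")))
#' writeExpressionMatrix(m, tf)
#' se <- readExpressionMatrix(tf)
#' SummarizedExperiment::assay(se, "tpm")
#' @export
readExpressionMatrix <- function(path, aliasMap = defaultAliasMap(),
                                 transpose = FALSE) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("expression file needs a gene column plus at least one sample")
  genes <- as.character(tab[[1L]])
  sampleIds <- names(tab)[-1L]  # before subsetting, which uniquifies names
  vals <- tab[, -1L, drop = FALSE]
  # columns that are entirely NA are read as logical; keep them numeric so
  # the value check can name the offending cell
  allNA <- vapply(vals, function(v) is.logical(v) && all(is.na(v)),
                  logical(1))
  vals[allNA] <- lapply(vals[allNA], as.numeric)
  if (!all(vapply(vals, is.numeric, logical(1))))
    stop("expression matrix contains non-numeric values")
  mat <- as.matrix(vals)
  dimnames(mat) <- list(genes, sampleIds)
  if (transpose) mat <- t(mat)
  if (anyDuplicated(colnames(mat)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]),
               collapse = ", "))
  rownames(mat) <- canonicalizeSymbols(rownames(mat), aliasMap)
  if (anyDuplicated(rownames(mat)))
    stop("duplicate gene symbols after alias canonicalisation: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]),
               collapse = ", "))
  .checkExpressionValues(mat, basename(path))
  SummarizedExperiment(assays = list(tpm = mat))
}

#' @rdname readExpressionMatrix
#' @export
writeExpressionMatrix <- function(x, path) {
  mat <- .tpmMatrix(x)
  .checkExpressionValues(mat)
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write per-sample IHC annotations
#'
#' Annotations are tab-separated with required columns \code{sample_id} and
#' \code{ihc_class} (one of cold / altered / hot / indeterminate) and
#' optional non-negative \code{cd45_density}, \code{cd8_density},
#' \code{cd4_density} (cells per mm2) and \code{pdl1_percent} (0-100).
#'
#' @param path File path.
#' @param annotations For the writer, a data.frame as returned by the reader.
#' @return A validated data.frame.
#' @export
readIHCAnnotations <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  validateIHCAnnotations(tab)
}

#' @rdname readIHCAnnotations
#' @export
writeIHCAnnotations <- function(annotations, path) {
  validateIHCAnnotations(annotations)
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname readIHCAnnotations
#' @export
validateIHCAnnotations <- function(annotations) {
  if (!all(c("sample_id", "ihc_class") %in% names(annotations)))
    stop("annotations need columns 'sample_id' and 'ihc_class'")
  annotations$sample_id <- as.character(annotations$sample_id)
  annotations$ihc_class <- as.character(annotations$ihc_class)
  if (anyDuplicated(annotations$sample_id))
    stop("duplicate sample ids in annotations")
  bad <- setdiff(unique(annotations$ihc_class), IHC_CLASSES)
  if (length(bad))
    stop("unknown IHC class: ", paste(bad, collapse = ", "))
  for (col in c("cd45_density", "cd8_density", "cd4_density")) {
    v <- annotations[[col]]
    if (!is.null(v) && any(v < 0, na.rm = TRUE))
      stop("'", col, "' must be non-negative")
  }
  p <- annotations$pdl1_percent
  if (!is.null(p) && any(p < 0 | p > 100, na.rm = TRUE))
    stop("'pdl1_percent' must lie in [0, 100]")
  annotations
}

#' Read a gene panel (one symbol per line)
#'
#' @param path File path; blank lines and lines starting with '#' are
#'   skipped.
#' @param aliasMap Alias map used to canonicalise the symbols.
#' @return Character vector of unique canonical gene symbols.
#' @export
readGenePanel <- function(path, aliasMap = defaultAliasMap()) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(canonicalizeSymbols(lines, aliasMap))
}

#' Serialise a signature together with its calibration
#'
#' A signature and the calibration that makes its scores reproducible are
#' stored in one JSON document so that scoring a new cohort needs a single
#' artefact. The round-trip is lossless, and re-writing the same objects is
#' byte-identical.
#'
#' @param sig A [GeneSignature-class].
#' @param calib A [ScoreCalibration-class].
#' @param path File path.
#' @return \code{writeSignature}: the path, invisibly.
#'   \code{readSignature}: a list with elements \code{signature} and
#'   \code{calibration}.
#' @examples
#' tf <- tempfile(fileext = ".json")
#' writeSignature(ipassSignature(), ipassCalibration(), tf)
#' readSignature(tf)$signature
#' @export
writeSignature <- function(sig, calib, path) {
  stopifnot(methods::is(sig, "GeneSignature"),
            methods::is(calib, "ScoreCalibration"))
  methods::validObject(sig)
  methods::validObject(calib)
  doc <- list(
    name = sig@name,
    genes = as.list(sig@genes),
    calibration = list(
      raw_min = calib@rawMin, raw_max = calib@rawMax,
      norm_threshold = calib@normThreshold,
      raw_threshold = calib@rawThreshold,
      log_base = calib@logBase, pseudocount = calib@pseudocount))
  if (length(sig@rankScores))
    doc$rank_scores <- as.list(sig@rankScores)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname writeSignature
#' @export
readSignature <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (f in c("name", "genes", "calibration"))
    if (is.null(doc[[f]]))
      stop("signature file is missing required field '", f, "'")
  cal <- doc$calibration
  for (f in c("raw_min", "raw_max", "norm_threshold", "log_base",
              "pseudocount"))
    if (is.null(cal[[f]]))
      stop("signature file is missing calibration field '", f, "'")
  sig <- GeneSignature(unlist(doc$genes), name = doc$name,
                       rankScores = if (is.null(doc$rank_scores)) NULL
                                    else unlist(doc$rank_scores))
  calib <- ScoreCalibration(rawMin = cal$raw_min, rawMax = cal$raw_max,
                            normThreshold = cal$norm_threshold,
                            rawThreshold = cal$raw_threshold,
                            logBase = cal$log_base,
                            pseudocount = cal$pseudocount)
  list(signature = sig, calibration = calib)
}

#' Read an epitope-prediction table
#'
#' Tab-separated with columns \code{mutation_id}, \code{hla_allele},
#' \code{mut_ic50}, \code{wt_ic50} (nM, positive) and \code{gene_tpm}
#' (non-negative). Optionally a \code{sample_id} column.
#'
#' @param path File path.
#' @return A validated data.frame.
#' @export
readEpitopeTable <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  validateEpitopeTable(tab)
}

#' @rdname readEpitopeTable
#' @param table A data.frame to validate.
#' @export
validateEpitopeTable <- function(table) {
  need <- c("mutation_id", "hla_allele", "mut_ic50", "wt_ic50", "gene_tpm")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("epitope table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(table)) {
    if (any(!is.finite(table$mut_ic50)) || any(table$mut_ic50 <= 0) ||
        any(!is.finite(table$wt_ic50)) || any(table$wt_ic50 <= 0))
      stop("IC50 affinities must be positive and finite")
    if (any(!is.finite(table$gene_tpm)) || any(table$gene_tpm < 0))
      stop("gene_tpm must be non-negative and finite")
  }
  table
}

#' Read a TCR clonotype table
#'
#' Tab-separated with columns \code{sample_id}, \code{clone_id} and
#' \code{read_count} (positive integers); clone ids must be unique within a
#' sample.
#'
#' @param path File path.
#' @return A validated data.frame.
#' @export
readCloneTable <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  validateCloneTable(tab)
}

#' @rdname readCloneTable
#' @param table A data.frame to validate.
#' @export
validateCloneTable <- function(table) {
  need <- c("sample_id", "clone_id", "read_count")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("clone table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(table)) {
    if (any(table$read_count < 1) ||
        any(table$read_count != round(table$read_count)))
      stop("read_count must be a positive integer")
    dup <- duplicated(table[, c("sample_id", "clone_id")])
    if (any(dup))
      stop("clone ids must be unique within a sample")
  }
  table
}

#' Read archetype gene-set definitions
#'
#' A JSON document with fields \code{scoring} (a method tag, currently
#' \code{"mean_zscore"}) and \code{sets}, an object mapping archetype name
#' to a non-empty gene list. The file shipped under \code{extdata} is a
#' synthetic example: the published 12 archetype gene sets are an external
#' input that users supply in this format.
#'
#' @param path File path.
#' @param aliasMap Alias map applied to every gene list.
#' @return A list with elements \code{scoring} (character) and \code{sets}
#'   (named list of character vectors).
#' @export
readArchetypeSets <- function(path, aliasMap = defaultAliasMap()) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(doc$sets) || !length(doc$sets))
    stop("archetype file needs a non-empty 'sets' object")
  sets <- lapply(doc$sets, function(g) unique(canonicalizeSymbols(g, aliasMap)))
  if (anyDuplicated(names(sets)))
    stop("archetype names must be unique")
  if (any(!vapply(sets, length, integer(1))))
    stop("every archetype gene set must be non-empty")
  list(scoring = if (is.null(doc$scoring)) "mean_zscore" else doc$scoring,
       sets = sets)
}
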