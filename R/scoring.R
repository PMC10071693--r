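#' The shipped IPASS signature and calibration
#'
#' \code{ipassSignature()} returns the default 15-gene T-cell-infiltration
#' signature instance and \code{ipassCalibration()} the accompanying score
#' calibration, both read from the JSON artefact shipped under
#' \code{extdata}.
#'
#' Two caveats make this instance a reference template rather than an exact
#' reproduction. First, the underlying patient cohort is controlled-access,
#' so the calibration's raw-score extremes (\code{rawMin} 0.2, \code{rawMax}
#' 1.88) are surrogates chosen to reproduce the published classification
#' threshold pair exactly: a normalised threshold of -0.25 corresponds to a
#' raw (mean log2(TPM+1)) threshold of 0.83. Second, only 14 of the 15
#' member genes are publicly documented by symbol; the 15th slot is filled
#' with CXCL10 (an interferon-gamma-inducible chemokine, like the members
#' CXCL9 and CXCL11) as a clearly flagged surrogate. Users with access to
#' the definitive gene list and cohort extremes should write their own
#' signature file with [writeSignature()] and load it instead.
#'
#' @return \code{ipassSignature}: a [GeneSignature-class] with 15 genes;
#'   \code{ipassCalibration}: a [ScoreCalibration-class].
#' @examples
#' ipassSignature()
#' invertNormalization(-0.25, ipassCalibration())  # 0.83
#' @export
ipassSignature <- function() {
  path <- system.file("extdata", "ipass_signature.json", package = "ipass")
  readSignature(path)$signature
}

#' @rdname ipassSignature
#' @export
ipassCalibration <- function() {
  path <- system.file("extdata", "ipass_signature.json", package = "ipass")
  readSignature(path)$calibration
}

#' Raw IPASS score: mean log-transformed TPM over the signature genes
#'
#' For each sample the raw score is the arithmetic mean, over the signature
#' genes, of \code{log(TPM + pseudocount)} in base \code{logBase} (defaults
#' log2(TPM + 1)). Every signature gene must be present in the matrix after
#' alias canonicalisation; missing genes are an error, never silently
#' imputed.
#'
#' @param x \linkS4class{SummarizedExperiment} (assay \code{"tpm"}) or
#'   numeric genes x samples TPM matrix.
#' @param sig A [GeneSignature-class].
#' @param logBase,pseudocount Log-transform parameters; when \code{calib}
#'   is given its values are used instead.
#' @param calib Optional [ScoreCalibration-class] supplying the transform.
#' @param aliasMap Alias map used to canonicalise the matrix's gene symbols
#'   before matching; \code{character(0)} disables canonicalisation.
#' @return Named numeric vector of raw scores, one per sample.
#' @examples
#' m <- matrix(1, nrow = 15, ncol = 2,
#'             dimnames = list(signatureGenes(ipassSignature()),
#'                             c("s1", "s2")))
#' rawScores(m, ipassSignature())  # log2(1 + 1) = 1 for every sample
#' @export
rawScores <- function(x, sig, calib = NULL, logBase = 2, pseudocount = 1,
                      aliasMap = defaultAliasMap()) {
  mat <- .tpmMatrix(x)
  .checkExpressionValues(mat)
  if (!is.null(calib)) {
    stopifnot(methods::is(calib, "ScoreCalibration"))
    logBase <- calib@logBase
    pseudocount <- calib@pseudocount
  }
  rownames(mat) <- canonicalizeSymbols(rownames(mat), aliasMap)
  genes <- canonicalizeSymbols(sig@genes, aliasMap)
  missing <- setdiff(genes, rownames(mat))
  if (length(missing))
    stop("signature genes missing from matrix: ",
         paste(missing, collapse = ", "))
  sub <- mat[genes, , drop = FALSE]
  colMeans(log(sub + pseudocount, base = logBase))
}

#' Fit a min-max score calibration on a cohort
#'
#' Sets \code{rawMin}/\code{rawMax} to the cohort's raw-score extremes and
#' recomputes the raw-scale threshold as the value mapping to
#' \code{normThreshold} under the resulting min-max normalisation.
#'
#' @param raw Numeric vector of raw scores with at least two distinct
#'   values.
#' @param normThreshold Normalised classification threshold, default -0.25.
#' @param logBase,pseudocount Recorded log-transform parameters.
#' @return A [ScoreCalibration-class].
#' @examples
#' fitCalibration(c(0, 1, 2))   # rawMin 0, rawMax 2
#' @export
fitCalibration <- function(raw, normThreshold = -0.25, logBase = 2,
                           pseudocount = 1) {
  raw <- raw[is.finite(raw)]
  if (length(unique(raw)) < 2L)
    stop("cannot calibrate: fewer than two distinct raw scores")
  ScoreCalibration(rawMin = min(raw), rawMax = max(raw),
                   normThreshold = normThreshold, logBase = logBase,
                   pseudocount = pseudocount)
}

#' Min-max normalisation of raw scores onto [-1, 1]
#'
#' \code{normalizeScores} maps raw scores linearly so the calibration's
#' \code{rawMin} becomes -1 and \code{rawMax} becomes +1; values outside
#' the calibration range (e.g. prospective samples scored against a frozen
#' calibration) are clipped into [-1, 1] with a warning.
#' \code{invertNormalization} is the exact inverse on the calibration
#' range.
#'
#' @param raw,norm Numeric score vectors.
#' @param calib A [ScoreCalibration-class].
#' @return Numeric vector of the same length.
#' @examples
#' calib <- ipassCalibration()
#' invertNormalization(normThreshold(calib), calib)  # raw threshold 0.83
#' @export
normalizeScores <- function(raw, calib) {
  stopifnot(methods::is(calib, "ScoreCalibration"))
  norm <- 2 * (raw - calib@rawMin) / (calib@rawMax - calib@rawMin) - 1
  out <- norm < -1 | norm > 1
  if (any(out, na.rm = TRUE)) {
    warning(sum(out, na.rm = TRUE),
            " score(s) outside the calibration range were clipped to [-1, 1]")
    norm <- pmin(pmax(norm, -1), 1)
  }
  norm
}

#' @rdname normalizeScores
#' @export
invertNormalization <- function(norm, calib) {
  stopifnot(methods::is(calib, "ScoreCalibration"))
  calib@rawMin + (norm + 1) / 2 * (calib@rawMax - calib@rawMin)
}

#' Classify normalised scores as T-cell infiltrated or cold
#'
#' A sample is called \code{t_cell_infiltrated} when its normalised score is
#' greater than or equal to the calibration's threshold (boundary
#' inclusive), \code{cold} otherwise.
#'
#' @param norm Numeric vector of normalised scores.
#' @param calib A [ScoreCalibration-class].
#' @return Character vector of labels, named like \code{norm}.
#' @examples
#' classifyScores(c(-0.25, -0.26, 1), ipassCalibration())
#' @export
classifyScores <- function(norm, calib) {
  stopifnot(methods::is(calib, "ScoreCalibration"))
  out <- ifelse(norm >= calib@normThreshold, "t_cell_infiltrated", "cold")
  names(out) <- names(norm)
  out
}

#' Score and classify a cohort in one call
#'
#' Runs [rawScores()], [normalizeScores()] and [classifyScores()] against a
#' frozen signature + calibration pair.
#'
#' @inheritParams rawScores
#' @param calib A [ScoreCalibration-class].
#' @return data.frame with columns \code{sample_id}, \code{raw_score},
#'   \code{norm_score}, \code{label}.
#' @examples
#' m <- matrix(2^seq(0, 5, length.out = 30) - 1, nrow = 15,
#'             dimnames = list(signatureGenes(ipassSignature()),
#'                             c("s1", "s2")))
#' scoreSamples(m, ipassSignature(), ipassCalibration())
#' @export
scoreSamples <- function(x, sig, calib, aliasMap = defaultAliasMap()) {
  raw <- rawScores(x, sig, calib = calib, aliasMap = aliasMap)
  norm <- normalizeScores(raw, calib)
  data.frame(sample_id = names(raw), raw_score = unname(raw),
             norm_score = unname(norm),
             label = unname(classifyScores(norm, calib)),
             stringsAsFactors = FALSE)
}
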