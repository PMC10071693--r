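#' @import methods
NULL

#' GeneSignature: an ordered gene-expression signature
#'
#' Holds an ordered set of HGNC gene symbols, optionally with the importance
#' values (e.g. mean decrease in Gini impurity) that ranked them. The IPASS
#' signature is an instance with exactly 15 genes.
#'
#' @slot name Single character, the signature's name.
#' @slot genes Character vector of unique gene symbols, ordered from most to
#'   least important.
#' @slot rankScores Numeric vector of non-negative importance values aligned
#'   with \code{genes} and sorted non-increasing, or length zero when no
#'   ranking is available.
#'
#' @seealso [GeneSignature()] for the constructor, [ipassSignature()] for the
#'   shipped default instance.
#' @exportClass GeneSignature
setClass("GeneSignature",
  representation(name = "character", genes = "character",
                 rankScores = "numeric"),
  prototype(name = "signature", genes = character(0),
            rankScores = numeric(0)))

setValidity("GeneSignature", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || is.na(object@name))
    msg <- c(msg, "'name' must be a single non-missing string")
  if (length(object@genes) == 0L)
    msg <- c(msg, "'genes' must contain at least one symbol")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "'genes' must be unique")
  rs <- object@rankScores
  if (length(rs)) {
    if (length(rs) != length(object@genes))
      msg <- c(msg, "'rankScores' must match 'genes' in length")
    if (any(!is.finite(rs)) || any(rs < 0))
      msg <- c(msg, "'rankScores' must be finite and non-negative")
    if (is.unsorted(rev(rs)))
      msg <- c(msg, "'rankScores' must be sorted non-increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSignature
#'
#' @param genes Character vector of unique gene symbols, ordered from most to
#'   least important.
#' @param name Signature name.
#' @param rankScores Optional non-negative importance values aligned with
#'   \code{genes}; must be non-increasing.
#' @return A [GeneSignature-class] object.
#' @examples
#' GeneSignature(c("CXCL9", "CD27"), name = "toy", rankScores = c(2, 1))
#' @export
GeneSignature <- function(genes, name = "signature", rankScores = NULL) {
  new("GeneSignature", name = as.character(name),
      genes = as.character(genes),
      rankScores = if (is.null(rankScores)) numeric(0)
                   else as.numeric(rankScores))
}

#' ScoreCalibration: min-max normalisation parameters for IPASS
#'
#' Freezes everything needed to reproduce a normalised IPASS from TPM: the
#' log transform (base and pseudocount), the cohort raw-score extremes used
#' for min-max normalisation onto [-1, 1], and the classification threshold
#' on both scales. The invariant \code{normalize(rawThreshold) ==
#' normThreshold} is enforced to 1e-9.
#'
#' @slot rawMin,rawMax Cohort minimum and maximum raw score (rawMin < rawMax).
#' @slot normThreshold Classification threshold on the normalised scale,
#'   inside (-1, 1); samples at or above it are called T-cell infiltrated.
#' @slot rawThreshold The same threshold on the raw-score scale.
#' @slot logBase Base of the log transform applied to TPM (default 2).
#' @slot pseudocount Offset added to TPM before the log (default 1).
#'
#' @seealso [ScoreCalibration()], [fitCalibration()], [ipassCalibration()].
#' @exportClass ScoreCalibration
setClass("ScoreCalibration",
  representation(rawMin = "numeric", rawMax = "numeric",
                 normThreshold = "numeric", rawThreshold = "numeric",
                 logBase = "numeric", pseudocount = "numeric"))

setValidity("ScoreCalibration", function(object) {
  msg <- character(0)
  for (s in c("rawMin", "rawMax", "normThreshold", "rawThreshold",
              "logBase", "pseudocount")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (!length(msg)) {
    if (object@rawMin >= object@rawMax)
      msg <- c(msg, "'rawMin' must be strictly less than 'rawMax'")
    if (object@logBase <= 0 || object@logBase == 1)
      msg <- c(msg, "'logBase' must be positive and != 1")
    if (object@pseudocount < 0)
      msg <- c(msg, "'pseudocount' must be non-negative")
    if (object@normThreshold <= -1 || object@normThreshold >= 1)
      msg <- c(msg, "'normThreshold' must lie inside (-1, 1)")
    if (!length(msg)) {
      norm <- 2 * (object@rawThreshold - object@rawMin) /
        (object@rawMax - object@rawMin) - 1
      if (abs(norm - object@normThreshold) > 1e-9)
        msg <- c(msg, paste0("'rawThreshold' does not map to ",
                             "'normThreshold' under (rawMin, rawMax)"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ScoreCalibration
#'
#' If \code{rawThreshold} is omitted it is computed as the raw score that
#' maps to \code{normThreshold} under the min-max normalisation defined by
#' \code{(rawMin, rawMax)}.
#'
#' @param rawMin,rawMax Cohort raw-score extremes; \code{rawMin < rawMax}.
#' @param normThreshold Normalised classification threshold, default -0.25.
#' @param rawThreshold Optional raw-scale threshold; must be consistent with
#'   \code{normThreshold} to within 1e-9.
#' @param logBase,pseudocount Parameters of the log transform used when the
#'   raw score was computed.
#' @return A [ScoreCalibration-class] object.
#' @examples
#' ScoreCalibration(rawMin = 0.2, rawMax = 1.88)  # rawThreshold 0.83
#' @export
ScoreCalibration <- function(rawMin, rawMax, normThreshold = -0.25,
                             rawThreshold = NULL, logBase = 2,
                             pseudocount = 1) {
  if (is.null(rawThreshold))
    rawThreshold <- rawMin + (normThreshold + 1) / 2 * (rawMax - rawMin)
  new("ScoreCalibration", rawMin = as.numeric(rawMin),
      rawMax = as.numeric(rawMax), normThreshold = as.numeric(normThreshold),
      rawThreshold = as.numeric(rawThreshold), logBase = as.numeric(logBase),
      pseudocount = as.numeric(pseudocount))
}

#' DerivationReport: everything produced by a signature derivation run
#'
#' @slot signature The extracted [GeneSignature-class].
#' @slot calibration [ScoreCalibration-class] fitted on the scored cohort.
#' @slot importances data.frame with columns \code{gene} and
#'   \code{importance} (mean decrease in Gini) for every panel gene trained
#'   on, sorted by decreasing importance.
#' @slot trainIds,testIds Sample identifiers of the stratified split.
#' @slot testMetrics List of classification metrics on the held-out test set
#'   (see [classificationMetrics()]).
#' @slot params List echoing the derivation parameters, including the seed.
#'
#' @seealso [deriveIPASS()].
#' @exportClass DerivationReport
setClass("DerivationReport",
  representation(signature = "GeneSignature",
                 calibration = "ScoreCalibration",
                 importances = "data.frame",
                 trainIds = "character", testIds = "character",
                 testMetrics = "list", params = "list"))

setValidity("DerivationReport", function(object) {
  msg <- character(0)
  if (length(intersect(object@trainIds, object@testIds)))
    msg <- c(msg, "train and test ids must be disjoint")
  if (!all(c("gene", "importance") %in% names(object@importances)))
    msg <- c(msg, "'importances' needs columns 'gene' and 'importance'")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "GeneSignature", function(object) {
  cat(sprintf("GeneSignature '%s' with %d genes\n", object@name,
              length(object@genes)))
  cat("  genes:", paste(utils::head(object@genes, 8), collapse = ", "),
      if (length(object@genes) > 8) "..." else "", "\n")
  if (length(object@rankScores))
    cat(sprintf("  rank scores: %.4g .. %.4g\n",
                object@rankScores[1], utils::tail(object@rankScores, 1)))
})

setMethod("show", "ScoreCalibration", function(object) {
  cat("ScoreCalibration\n")
  cat(sprintf("  raw range     : [%.4g, %.4g]\n", object@rawMin,
              object@rawMax))
  cat(sprintf("  threshold     : %.4g (normalised) / %.4g (raw)\n",
              object@normThreshold, object@rawThreshold))
  cat(sprintf("  log transform : log%g(TPM + %g)\n", object@logBase,
              object@pseudocount))
})

setMethod("show", "DerivationReport", function(object) {
  cat(sprintf("DerivationReport: %d-gene signature from %d train / %d test samples\n",
              length(object@signature@genes), length(object@trainIds),
              length(object@testIds)))
  show(object@signature)
  show(object@calibration)
  m <- object@testMetrics
  if (length(m))
    cat(sprintf("  test metrics  : accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
                m$accuracy, m$sensitivity, m$specificity))
})

## ---- accessors ----------------------------------------------------------

#' Accessors for signature, calibration and derivation objects
#'
#' @param object A [GeneSignature-class], [ScoreCalibration-class] or
#'   [DerivationReport-class] as appropriate.
#' @return \code{signatureGenes}: character vector of gene symbols;
#'   \code{rankScores}: numeric importance values (possibly length zero);
#'   \code{rawThreshold}/\code{normThreshold}: single numbers;
#'   \code{rawRange}: numeric \code{c(rawMin, rawMax)};
#'   \code{signature}/\code{calibration}/\code{importances}/
#'   \code{testMetrics}: the corresponding component of a report.
#' @name accessors
#' @examples
#' signatureGenes(ipassSignature())
#' rawThreshold(ipassCalibration())
NULL

#' @rdname accessors
#' @export
setGeneric("signatureGenes", function(object) standardGeneric("signatureGenes"))
#' @rdname accessors
#' @export
setMethod("signatureGenes", "GeneSignature", function(object) object@genes)

#' @rdname accessors
#' @export
setGeneric("rankScores", function(object) standardGeneric("rankScores"))
#' @rdname accessors
#' @export
setMethod("rankScores", "GeneSignature", function(object) object@rankScores)

#' @rdname accessors
#' @export
setGeneric("rawRange", function(object) standardGeneric("rawRange"))
#' @rdname accessors
#' @export
setMethod("rawRange", "ScoreCalibration",
          function(object) c(object@rawMin, object@rawMax))

#' @rdname accessors
#' @export
setGeneric("normThreshold", function(object) standardGeneric("normThreshold"))
#' @rdname accessors
#' @export
setMethod("normThreshold", "ScoreCalibration",
          function(object) object@normThreshold)

#' @rdname accessors
#' @export
setGeneric("rawThreshold", function(object) standardGeneric("rawThreshold"))
#' @rdname accessors
#' @export
setMethod("rawThreshold", "ScoreCalibration",
          function(object) object@rawThreshold)

#' @rdname accessors
#' @export
setGeneric("derivedSignature", function(object) standardGeneric("derivedSignature"))
#' @rdname accessors
#' @export
setMethod("derivedSignature", "DerivationReport",
          function(object) object@signature)

#' @rdname accessors
#' @export
setGeneric("calibration", function(object) standardGeneric("calibration"))
#' @rdname accessors
#' @export
setMethod("calibration", "DerivationReport", function(object) object@calibration)

#' @rdname accessors
#' @export
setGeneric("importances", function(object) standardGeneric("importances"))
#' @rdname accessors
#' @export
setMethod("importances", "DerivationReport", function(object) object@importances)

#' @rdname accessors
#' @export
setGeneric("testMetrics", function(object) standardGeneric("testMetrics"))
#' @rdname accessors
#' @export
setMethod("testMetrics", "DerivationReport", function(object) object@testMetrics)

#' @rdname accessors
#' @export
setMethod("signatureGenes", "DerivationReport",
          function(object) object@signature@genes)
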