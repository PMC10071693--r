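#' Merge IHC classes into a binary infiltration label
#'
#' Pathologist hot and altered classes are pooled into a single
#' \code{inflamed} group (both harbour intratumoural or peripheral
#' T-cells); cold stays \code{cold}; indeterminate samples are dropped with
#' a message.
#'
#' @param annotations data.frame with columns \code{sample_id} and
#'   \code{ihc_class} (see [readIHCAnnotations()]).
#' @param inflamedClasses IHC classes pooled into the positive group.
#' @return Named factor with levels \code{c("cold", "inflamed")}, named by
#'   sample id; indeterminate samples are absent.
#' @examples
#' ann <- data.frame(sample_id = c("a", "b", "c"),
#'                   ihc_class = c("hot", "altered", "cold"))
#' mergeIHCLabels(ann)
#' @export
mergeIHCLabels <- function(annotations, inflamedClasses = c("hot", "altered")) {
  annotations <- validateIHCAnnotations(annotations)
  keep <- annotations$ihc_class != "indeterminate"
  nDropped <- sum(!keep)
  if (nDropped)
    message("excluding ", nDropped, " indeterminate sample(s)")
  annotations <- annotations[keep, , drop = FALSE]
  if (!nrow(annotations))
    stop("no samples left after excluding indeterminate classifications")
  lab <- ifelse(annotations$ihc_class %in% inflamedClasses,
                "inflamed", "cold")
  factor(stats::setNames(lab, annotations$sample_id),
         levels = c("cold", "inflamed"))
}

#' Restrict an expression matrix to a gene panel
#'
#' Keeps the intersection of panel and matrix genes in the matrix's
#' original row order, logging how many panel genes are absent.
#'
#' @param x \linkS4class{SummarizedExperiment} or genes x samples matrix.
#' @param panel Character vector of panel gene symbols.
#' @param aliasMap Alias map applied to both gene lists before matching.
#' @return genes x samples numeric matrix restricted to the panel.
#' @export
filterPanelGenes <- function(x, panel, aliasMap = defaultAliasMap()) {
  mat <- .tpmMatrix(x)
  rownames(mat) <- canonicalizeSymbols(rownames(mat), aliasMap)
  panel <- unique(canonicalizeSymbols(panel, aliasMap))
  keep <- rownames(mat) %in% panel
  if (!any(keep))
    stop("no panel genes found in the expression matrix")
  nMissing <- length(setdiff(panel, rownames(mat)))
  if (nMissing)
    message(nMissing, " panel gene(s) absent from the matrix")
  mat[keep, , drop = FALSE]
}

#' Stratified train/test split with largest-remainder allocation
#'
#' Samples are split per class so the train fraction is respected within
#' both the inflamed and the cold group. The train set receives
#' \code{floor(fraction * N)} samples overall (an odd cohort therefore puts
#' the extra sample in the test set); per-class counts are the class floors
#' topped up by largest remainder, and each class keeps at least one sample
#' on either side. Which samples land where is random but deterministic
#' given the seed.
#'
#' @param labels Named factor/character of binary class labels, named by
#'   sample id.
#' @param trainFraction Fraction of samples assigned to training, in (0,1).
#' @param seed Integer RNG seed.
#' @return List with character vectors \code{trainIds} and \code{testIds}.
#' @examples
#' labs <- setNames(rep(c("inflamed", "cold"), c(25, 44)),
#'                  sprintf("s%02d", 1:69))
#' sp <- stratifiedSplit(labs, 0.5, seed = 1)
#' lengths(sp)  # 34 train, 35 test
#' @export
stratifiedSplit <- function(labels, trainFraction = 0.5, seed = 1) {
  if (is.null(names(labels)))
    stop("'labels' must be named by sample id")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("'trainFraction' must lie strictly between 0 and 1")
  labels <- droplevels(as.factor(labels))
  classes <- levels(labels)
  if (length(classes) < 2L)
    stop("need two classes to stratify")
  counts <- table(labels)
  if (any(counts < 2L))
    stop("cannot stratify: class '", names(counts)[which.min(counts)],
         "' has fewer than 2 samples")
  nTrain <- floor(trainFraction * length(labels))
  base <- floor(trainFraction * as.numeric(counts))
  rem <- trainFraction * as.numeric(counts) - base
  # top up by largest remainder; ties favour the larger class, then name
  ord <- order(-rem, -as.numeric(counts), names(counts))
  left <- nTrain - sum(base)
  alloc <- base
  i <- 1L
  while (left > 0L) {
    j <- ord[(i - 1L) %% length(ord) + 1L]
    if (alloc[j] < counts[j] - 1L) {
      alloc[j] <- alloc[j] + 1L
      left <- left - 1L
    }
    i <- i + 1L
  }
  alloc <- pmax(alloc, 1L)  # both sides keep >= 1 member per class
  set.seed(as.integer(seed))
  trainIds <- character(0)
  for (k in seq_along(classes)) {
    ids <- names(labels)[labels == classes[k]]
    trainIds <- c(trainIds, sample(ids, alloc[k]))
  }
  list(trainIds = sort(trainIds),
       testIds = sort(setdiff(names(labels), trainIds)))
}

#' Train a random-forest classifier and extract Gini importances
#'
#' Fits a decision forest (Gini impurity criterion) of \code{nTrees} trees
#' with \code{mtry} features per split (default: square root of the feature
#' count) on a genes x samples matrix, and returns the fit together with
#' the mean decrease in Gini impurity for every input gene. Training is
#' deterministic given the seed.
#'
#' @param x genes x samples numeric matrix (training samples only).
#' @param labels Binary factor of training labels, aligned with the
#'   columns of \code{x} (or named by sample id).
#' @param nTrees Number of trees, default 500.
#' @param mtry Features per split; \code{NULL} for floor(sqrt(p)).
#' @param seed Integer RNG seed.
#' @return List with elements \code{forest} (the randomForest fit) and
#'   \code{importance} (named numeric, mean decrease in Gini, one entry per
#'   gene).
#' @export
trainClassifier <- function(x, labels, nTrees = 500, mtry = NULL, seed = 1) {
  mat <- .tpmMatrix(x)
  labels <- droplevels(as.factor(labels))
  if (!is.null(names(labels)) && !is.null(colnames(mat))) {
    miss <- setdiff(colnames(mat), names(labels))
    if (length(miss))
      stop("no label for sample(s): ", paste(miss, collapse = ", "))
    labels <- labels[colnames(mat)]
  }
  if (length(labels) != ncol(mat))
    stop("one label per sample required")
  if (nlevels(labels) < 2L)
    stop("training labels contain a single class")
  if (any(table(labels) < 2L))
    stop("need at least 2 training samples per class")
  feat <- t(mat)  # samples x genes
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(feat))))
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(x = feat, y = labels, ntree = nTrees,
                                    mtry = mtry, importance = FALSE)
  imp <- randomForest::importance(fit, type = 2)[, 1]
  names(imp) <- rownames(randomForest::importance(fit, type = 2))
  list(forest = fit, importance = imp)
}

#' Extract the top-k genes by importance
#'
#' Orders genes by decreasing importance, breaking ties by lexicographic
#' gene symbol so the extraction is reproducible, and keeps the top
#' \code{k}.
#'
#' @param importance Named numeric vector of non-negative importances.
#' @param k Number of genes to keep, default 15.
#' @param name Name given to the resulting signature.
#' @return A [GeneSignature-class] with \code{rankScores} carrying the
#'   importances.
#' @examples
#' extractSignature(c(A = 0.5, B = 0.3, C = 0.3, D = 0.1), k = 2)
#' @export
extractSignature <- function(importance, k = 15, name = "derived") {
  if (is.null(names(importance)))
    stop("'importance' must be named by gene")
  if (k > length(importance))
    stop("k = ", k, " exceeds the ", length(importance),
         " genes with defined importance")
  ord <- order(-importance, names(importance))
  top <- importance[ord][seq_len(k)]
  GeneSignature(names(top), name = name, rankScores = unname(top))
}

#' Derive a T-cell-infiltration signature from an IHC-labelled cohort
#'
#' End-to-end derivation: merge IHC classes to a binary label (dropping
#' indeterminate samples), restrict the matrix to the immune gene panel,
#' stratified train/test split, random-forest training on the training set
#' only, extraction of the top-\code{k} genes by Gini importance, scoring
#' of the full supplied cohort, min-max calibration on those scores, and
#' classification metrics on the held-out test set. The whole run is a pure
#' function of its inputs and the seed.
#'
#' @param x \linkS4class{SummarizedExperiment} or genes x samples TPM
#'   matrix covering at least the labelled samples.
#' @param annotations IHC annotation data.frame; if \code{NULL} and
#'   \code{x} is a SummarizedExperiment, taken from
#'   \code{colData(x)$ihc_class}.
#' @param panel Character vector of panel gene symbols (e.g. an immune
#'   profiling panel); \code{NULL} uses every gene in the matrix.
#' @param k Signature size, default 15.
#' @param trainFraction,nTrees,mtry,seed,inflamedClasses See the stagewise
#'   functions.
#' @param normThreshold Normalised classification threshold, default -0.25.
#' @param logBase,pseudocount Log-transform parameters for scoring.
#' @param calibrateOn \code{"all"} (default) fits the calibration on every
#'   scored sample supplied, mirroring calibration on an entire cohort;
#'   \code{"train"} restricts it to the training set.
#' @return A [DerivationReport-class].
#' @examples
#' coh <- simulateCohort(nCold = 12, nAltered = 6, nHot = 2, nGenes = 60,
#'                       nPanel = 40, nInformative = 5, seed = 7)
#' rep <- deriveIPASS(coh, panel = S4Vectors::metadata(coh)$panel, k = 5,
#'                    seed = 7)
#' signatureGenes(rep)
#' @export
deriveIPASS <- function(x, annotations = NULL, panel = NULL, k = 15,
                        trainFraction = 0.5, nTrees = 500, mtry = NULL,
                        seed = 1, inflamedClasses = c("hot", "altered"),
                        normThreshold = -0.25, logBase = 2, pseudocount = 1,
                        calibrateOn = c("all", "train")) {
  calibrateOn <- match.arg(calibrateOn)
  if (is.null(annotations)) {
    if (!methods::is(x, "SummarizedExperiment") ||
        is.null(SummarizedExperiment::colData(x)$ihc_class))
      stop("supply 'annotations' or a SummarizedExperiment with an ",
           "'ihc_class' column in colData")
    cd <- SummarizedExperiment::colData(x)
    annotations <- data.frame(sample_id = colnames(x),
                              ihc_class = as.character(cd$ihc_class),
                              stringsAsFactors = FALSE)
  }
  mat <- .tpmMatrix(x)
  .checkExpressionValues(mat)
  labels <- mergeIHCLabels(annotations, inflamedClasses)
  miss <- setdiff(names(labels), colnames(mat))
  if (length(miss))
    stop("labelled sample(s) missing from matrix: ",
         paste(miss, collapse = ", "))
  panelMat <- if (is.null(panel)) mat else filterPanelGenes(mat, panel)
  if (k > nrow(panelMat))
    stop("k exceeds the number of panel genes present in the matrix")

  split <- stratifiedSplit(labels, trainFraction, seed = seed)
  trained <- trainClassifier(panelMat[, split$trainIds, drop = FALSE],
                             labels[split$trainIds], nTrees = nTrees,
                             mtry = mtry, seed = seed)
  sig <- extractSignature(trained$importance, k = k, name = "derived")

  raw <- rawScores(mat, sig, logBase = logBase, pseudocount = pseudocount,
                   aliasMap = character(0))
  calibScores <- switch(calibrateOn, all = raw, train = raw[split$trainIds])
  calib <- fitCalibration(calibScores, normThreshold = normThreshold,
                          logBase = logBase, pseudocount = pseudocount)

  normTest <- normalizeScores(raw[split$testIds], calib)
  predTest <- classifyScores(normTest, calib)
  cm <- confusion2x2(predTest == "t_cell_infiltrated",
                     labels[split$testIds] == "inflamed")
  imp <- trained$importance
  impDf <- data.frame(gene = names(imp), importance = unname(imp),
                      stringsAsFactors = FALSE)
  impDf <- impDf[order(-impDf$importance, impDf$gene), ]
  rownames(impDf) <- NULL

  new("DerivationReport", signature = sig, calibration = calib,
      importances = impDf, trainIds = split$trainIds,
      testIds = split$testIds,
      testMetrics = classificationMetrics(cm),
      params = list(k = k, trainFraction = trainFraction, nTrees = nTrees,
                    mtry = mtry, seed = seed,
                    inflamedClasses = inflamedClasses,
                    normThreshold = normThreshold, logBase = logBase,
                    pseudocount = pseudocount, calibrateOn = calibrateOn))
}
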