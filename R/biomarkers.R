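#' Filter predicted neoepitopes and count neoantigens
#'
#' A candidate neoepitope is kept when the mutant peptide binds strongly
#' (IC50 strictly below \code{mutCut} nM), the wild-type peptide does not
#' (IC50 strictly above \code{wtCut} nM) and the source gene is expressed
#' (TPM strictly above \code{tpmCut}). Each mutation with at least one
#' passing epitope counts as exactly one neoantigen, regardless of how many
#' epitopes or HLA alleles pass.
#'
#' @param table Epitope-prediction data.frame (see [readEpitopeTable()]).
#' @param mutCut Mutant IC50 upper cut-off in nM, default 500.
#' @param wtCut Wild-type IC50 lower cut-off in nM, default 500.
#' @param tpmCut Expression lower cut-off in TPM, default 1.
#' @return List with \code{passing} (the retained rows) and
#'   \code{nNeoantigens} (distinct mutations among them). With a
#'   \code{sample_id} column, \code{nNeoantigens} is a named per-sample
#'   vector.
#' @examples
#' tab <- data.frame(mutation_id = c("m1", "m1", "m2"),
#'                   hla_allele = c("A*01:01", "B*07:02", "A*01:01"),
#'                   mut_ic50 = c(300, 450, 700),
#'                   wt_ic50 = c(600, 900, 800),
#'                   gene_tpm = c(2, 2, 5))
#' filterNeoepitopes(tab)$nNeoantigens  # m1 passes twice -> 1 neoantigen
#' @export
filterNeoepitopes <- function(table, mutCut = 500, wtCut = 500,
                              tpmCut = 1) {
  table <- validateEpitopeTable(table)
  keep <- table$mut_ic50 < mutCut & table$wt_ic50 > wtCut &
    table$gene_tpm > tpmCut
  passing <- table[keep, , drop = FALSE]
  if ("sample_id" %in% names(passing) && nrow(table) &&
      "sample_id" %in% names(table)) {
    ids <- unique(table$sample_id)
    n <- vapply(ids, function(s) {
      length(unique(passing$mutation_id[passing$sample_id == s]))
    }, integer(1))
    names(n) <- ids
  } else {
    n <- length(unique(passing$mutation_id))
  }
  list(passing = passing, nNeoantigens = n)
}

#' PD-L1 positivity by immunohistochemistry
#'
#' A tumour is PD-L1 positive when at least 1 percent of total cells show
#' membranous staining (cytoplasmic-only staining does not count and must
#' not be included in the input percentage).
#'
#' @param percent Percentage of cells with positive membranous staining,
#'   in [0, 100] (vectorised).
#' @param threshold Positivity cut-off in percent, default 1 (inclusive).
#' @return Character vector, \code{"positive"} or \code{"negative"}.
#' @examples
#' classifyPDL1(c(0, 0.9, 1, 40))
#' @export
classifyPDL1 <- function(percent, threshold = 1) {
  if (any(!is.finite(percent) | percent < 0 | percent > 100))
    stop("'percent' must lie in [0, 100]")
  ifelse(percent >= threshold, "positive", "negative")
}

#' Concordance between PD-L1 IHC and PD-L1 RNA expression
#'
#' Cross-tabulates PD-L1 IHC status (positive at >= 1 percent membranous
#' staining) against RNA expression dichotomised at \code{tpmCut}
#' (RNA-high strictly above the cut, which is descriptive rather than a
#' validated threshold).
#'
#' @param percent IHC percentages in [0, 100].
#' @param tpm PD-L1 TPM values, same length.
#' @param tpmCut RNA-high cut-off in TPM, default 3 (strict >).
#' @param ihcThreshold IHC positivity cut-off in percent, default 1.
#' @return 2x2 integer table, IHC (positive/negative) x RNA (high/low).
#' @examples
#' pdl1Concordance(percent = c(2, 0.5, 0), tpm = c(5, 4, 1))
#' @export
pdl1Concordance <- function(percent, tpm, tpmCut = 3, ihcThreshold = 1) {
  if (length(percent) != length(tpm))
    stop("'percent' and 'tpm' must have the same length")
  ihc <- factor(classifyPDL1(percent, ihcThreshold),
                levels = c("positive", "negative"))
  rna <- factor(ifelse(tpm > tpmCut, "high", "low"),
                levels = c("high", "low"))
  table(ihc = ihc, rna = rna)
}

#' Score samples against immune-archetype gene sets and assign the
#' dominant archetype
#'
#' Each archetype score is the mean, over the set's genes present in the
#' matrix, of the per-gene cohort z-score of log2(TPM+1): cohort
#' standardisation makes the 12 archetype scores comparable within a
#' sample. \code{assignArchetypes} gives every sample the archetype with
#' its maximum score; exact ties are broken alphabetically and flagged.
#'
#' @param x \linkS4class{SummarizedExperiment} or genes x samples TPM
#'   matrix with at least two samples.
#' @param sets Named list of gene sets, or the list returned by
#'   [readArchetypeSets()].
#' @param aliasMap Alias map applied to matrix and set genes.
#' @param scores For \code{assignArchetypes}: the matrix returned by
#'   \code{scoreArchetypes}.
#' @return \code{scoreArchetypes}: numeric samples x archetypes matrix.
#'   \code{assignArchetypes}: data.frame with columns \code{sample_id},
#'   \code{archetype}, \code{score} and logical \code{tie}.
#' @examples
#' m <- matrix(2^rnorm(40, 4), nrow = 4,
#'             dimnames = list(c("CD8A", "GZMB", "COL1A1", "FAP"),
#'                             paste0("s", 1:10)))
#' sc <- scoreArchetypes(m, list(IR = c("CD8A", "GZMB"),
#'                               ISR = c("COL1A1", "FAP")))
#' assignArchetypes(sc)
#' @export
scoreArchetypes <- function(x, sets, aliasMap = defaultAliasMap()) {
  if (!is.null(sets$sets) && is.list(sets$sets)) sets <- sets$sets
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("'sets' must be a uniquely named list of gene vectors")
  mat <- .tpmMatrix(x)
  if (ncol(mat) < 2L)
    stop("archetype scoring needs at least two samples (cohort z-scores)")
  rownames(mat) <- canonicalizeSymbols(rownames(mat), aliasMap)
  lg <- log2(mat + 1)
  z <- t(scale(t(lg)))  # per-gene cohort z-score
  const <- apply(lg, 1L, function(r) stats::sd(r) == 0)
  if (all(const))
    stop("degenerate cohort: every gene is constant across samples")
  scores <- matrix(NA_real_, nrow = ncol(mat), ncol = length(sets),
                   dimnames = list(colnames(mat), names(sets)))
  for (nm in names(sets)) {
    genes <- canonicalizeSymbols(sets[[nm]], aliasMap)
    present <- intersect(genes, rownames(mat)[!const])
    if (!length(present))
      stop("archetype '", nm,
           "' has no usable genes in the expression matrix")
    scores[, nm] <- colMeans(z[present, , drop = FALSE])
  }
  scores
}

#' @rdname scoreArchetypes
#' @export
assignArchetypes <- function(scores) {
  if (is.null(colnames(scores)))
    stop("'scores' must have archetype column names")
  ord <- order(colnames(scores))  # alphabetical tie-break
  scores <- scores[, ord, drop = FALSE]
  pick <- apply(scores, 1L, which.max)
  maxScore <- scores[cbind(seq_len(nrow(scores)), pick)]
  tie <- vapply(seq_len(nrow(scores)), function(i) {
    sum(scores[i, ] == maxScore[i]) > 1L
  }, logical(1))
  if (any(tie))
    warning(sum(tie), " sample(s) had tied archetype scores; ",
            "ties broken alphabetically")
  data.frame(sample_id = rownames(scores),
             archetype = colnames(scores)[pick],
             score = unname(maxScore), tie = tie,
             stringsAsFactors = FALSE)
}

#' Summarise TCR clonotype tables per sample
#'
#' For each sample: the number of distinct clones, the total read count and
#' each clone's read proportion (summing to one).
#'
#' @param table Clonotype data.frame (see [readCloneTable()]).
#' @return List keyed by sample id; each element has \code{n_clones},
#'   \code{total_reads}, \code{proportions} (named by clone id) and a
#'   logical \code{empty} flag for samples with no clones.
#' @examples
#' tab <- data.frame(sample_id = "s1", clone_id = c("c1", "c2"),
#'                   read_count = c(5, 5))
#' summarizeClones(tab)$s1$proportions
#' @export
summarizeClones <- function(table) {
  table <- validateCloneTable(table)
  ids <- unique(table$sample_id)
  out <- lapply(ids, function(s) {
    rows <- table[table$sample_id == s, , drop = FALSE]
    total <- sum(rows$read_count)
    if (!nrow(rows) || total == 0)
      return(list(n_clones = 0L, total_reads = 0L,
                  proportions = numeric(0), empty = TRUE))
    list(n_clones = nrow(rows), total_reads = as.integer(total),
         proportions = stats::setNames(rows$read_count / total,
                                       rows$clone_id),
         empty = FALSE)
  })
  stats::setNames(out, ids)
}
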