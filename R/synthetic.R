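#' Simulate an IHC-labelled expression cohort with planted immune structure
#'
#' Generates a synthetic bulk-RNA-seq cohort emulating the structure the
#' signature derivation assumes: log-normal TPM with a set of informative
#' immune genes over-expressed in inflamed (hot/altered) samples. Per-gene
#' baselines are drawn from Normal(\code{baselineLog2Mean},
#' \code{baselineLog2SD}); each sample's log2-TPM is baseline plus a class
#' effect on the informative genes (hot: \code{effectHot}; altered:
#' \code{effectAltered}; cold: 0) plus Normal(0, \code{noiseSD}) noise; TPM
#' is \code{2^log2 - 1} floored at zero, so with the default log2(TPM+1)
#' scoring transform planted effects translate directly into score
#' separation. Everything is deterministic given the seed.
#'
#' Default class counts (45 cold / 20 altered / 5 hot) mirror a
#' 70-sample labelled cohort with roughly a third of samples inflamed, the
#' typical proportion for high-risk paediatric tumours read out by CD8
#' IHC; the altered class receives an intermediate effect because it pools
#' moderate and peripherally restricted infiltration.
#'
#' @param nCold,nAltered,nHot Per-class sample counts (total >= 4).
#' @param nGenes Total genes, default 1000.
#' @param nPanel Genes in the immune panel (first \code{nPanel} genes),
#'   default 766.
#' @param nInformative Planted informative genes (a subset of the panel),
#'   default 15.
#' @param baselineLog2Mean,baselineLog2SD Baseline log2-TPM distribution.
#' @param effectHot,effectAltered Class effects in log2 units.
#' @param noiseSD Per-observation log2 noise standard deviation.
#' @param seed Integer RNG seed.
#' @return A \linkS4class{SummarizedExperiment} with assay \code{"tpm"},
#'   \code{colData} columns \code{sample_id} and \code{ihc_class}, and
#'   \code{metadata} holding \code{informativeGenes}, \code{panel} and the
#'   simulation \code{params}.
#' @examples
#' coh <- simulateCohort(nCold = 6, nAltered = 3, nHot = 1, nGenes = 50,
#'                       nPanel = 30, nInformative = 4, seed = 1)
#' table(SummarizedExperiment::colData(coh)$ihc_class)
#' @export
simulateCohort <- function(nCold = 45, nAltered = 20, nHot = 5,
                           nGenes = 1000, nPanel = 766, nInformative = 15,
                           baselineLog2Mean = 3, baselineLog2SD = 1,
                           effectHot = 2.0, effectAltered = 1.2,
                           noiseSD = 0.5, seed = 1) {
  n <- nCold + nAltered + nHot
  if (any(c(nCold, nAltered, nHot) < 0) || n < 4)
    stop("class counts must be non-negative with total >= 4")
  if (!(nInformative <= nPanel && nPanel <= nGenes))
    stop("need nInformative <= nPanel <= nGenes")
  if (baselineLog2SD < 0 || noiseSD < 0)
    stop("standard deviations must be non-negative")
  set.seed(as.integer(seed))

  genes <- sprintf("GENE%04d", seq_len(nGenes))
  panel <- genes[seq_len(nPanel)]
  informative <- sample(panel, nInformative)
  classes <- rep(c("cold", "altered", "hot"), c(nCold, nAltered, nHot))
  samples <- sprintf("S%03d", seq_len(n))

  baseline <- stats::rnorm(nGenes, baselineLog2Mean, baselineLog2SD)
  effect <- c(cold = 0, altered = effectAltered, hot = effectHot)
  lg <- matrix(baseline, nrow = nGenes, ncol = n,
               dimnames = list(genes, samples))
  shift <- matrix(0, nrow = nGenes, ncol = n)
  shift[genes %in% informative, ] <-
    rep(effect[classes], each = nInformative)
  lg <- lg + shift + matrix(stats::rnorm(nGenes * n, 0, noiseSD),
                            nrow = nGenes)
  tpm <- pmax(2^lg - 1, 0)

  SummarizedExperiment(
    assays = list(tpm = tpm),
    colData = S4Vectors::DataFrame(sample_id = samples,
                                   ihc_class = classes,
                                   row.names = samples),
    metadata = list(informativeGenes = sort(informative), panel = panel,
                    params = list(nCold = nCold, nAltered = nAltered,
                                  nHot = nHot, nGenes = nGenes,
                                  nPanel = nPanel,
                                  nInformative = nInformative,
                                  baselineLog2Mean = baselineLog2Mean,
                                  baselineLog2SD = baselineLog2SD,
                                  effectHot = effectHot,
                                  effectAltered = effectAltered,
                                  noiseSD = noiseSD, seed = seed)))
}

#' Extract the IHC annotation table of a simulated cohort
#'
#' @param cohort A \linkS4class{SummarizedExperiment} from
#'   [simulateCohort()].
#' @return data.frame with columns \code{sample_id} and \code{ihc_class}.
#' @export
cohortAnnotations <- function(cohort) {
  cd <- SummarizedExperiment::colData(cohort)
  data.frame(sample_id = as.character(cd$sample_id),
             ihc_class = as.character(cd$ihc_class),
             stringsAsFactors = FALSE)
}

#' Simulate an epitope-prediction table with known ground truth
#'
#' Generates candidate neoepitopes straddling the filtering boundaries
#' (mutant IC50 500 nM, wild-type IC50 500 nM, expression 1 TPM). A
#' deterministic number of mutations, \code{round(passFraction *
#' nMutations)}, receive at least one epitope passing all three cut-offs;
#' the remaining epitopes each violate at least one cut-off, so the
#' expected neoantigen count is known exactly.
#'
#' @param nMutations Number of distinct mutations.
#' @param epitopesPerMutation Predicted epitopes (HLA contexts) per
#'   mutation.
#' @param passFraction Fraction of mutations that should pass, in [0, 1].
#' @param seed Integer RNG seed.
#' @return List with \code{table} (an epitope-prediction data.frame) and
#'   \code{truthCount} (the planted neoantigen count).
#' @examples
#' sim <- simulateEpitopes(10, 3, passFraction = 0.5, seed = 1)
#' sim$truthCount
#' @export
simulateEpitopes <- function(nMutations, epitopesPerMutation = 3,
                             passFraction = 0.5, seed = 1) {
  if (nMutations < 1 || epitopesPerMutation < 1)
    stop("'nMutations' and 'epitopesPerMutation' must be positive")
  if (passFraction < 0 || passFraction > 1)
    stop("'passFraction' must lie in [0, 1]")
  set.seed(as.integer(seed))
  nPass <- round(passFraction * nMutations)
  passing <- sample(nMutations) <= nPass  # which mutations carry a pass
  hla <- c("A*01:01", "A*02:01", "B*07:02", "B*08:01", "C*07:01")

  rows <- lapply(seq_len(nMutations), function(m) {
    k <- epitopesPerMutation
    # per-epitope: does this row satisfy all three cut-offs?
    ok <- if (passing[m]) c(TRUE, stats::runif(k - 1) < 0.5)
          else rep(FALSE, k)
    mut <- ifelse(ok, stats::runif(k, 20, 499),
                  stats::runif(k, 501, 5000))
    wt <- ifelse(ok, stats::runif(k, 501, 8000),
                 stats::runif(k, 501, 8000))
    tpm <- rep(NA_real_, k)
    tpm[ok] <- stats::runif(sum(ok), 1.001, 80)
    # failing rows fail via IC50 above; give some a low-TPM failure mode too
    lowTpm <- !ok & stats::runif(k) < 0.3
    tpm[!ok] <- ifelse(lowTpm[!ok], stats::runif(sum(!ok), 0, 0.999),
                       stats::runif(sum(!ok), 1.001, 80))
    data.frame(mutation_id = sprintf("MUT%04d", m),
               hla_allele = sample(hla, k, replace = TRUE),
               mut_ic50 = mut, wt_ic50 = wt, gene_tpm = tpm,
               stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, rows)
  list(table = validateEpitopeTable(table), truthCount = as.integer(nPass))
}
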