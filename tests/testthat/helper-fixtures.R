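# Shared fixtures and independent oracles, built in code at test time.

# genes x samples TPM matrix with the full shipped signature as rows
makeSignatureMatrix <- function(tpm, nSamples = 1,
                                genes = signatureGenes(ipassSignature())) {
  m <- matrix(tpm, nrow = length(genes), ncol = nSamples,
              dimnames = list(genes, sprintf("s%03d", seq_len(nSamples))))
  m
}

# random seeded TPM matrix (log-normal-ish, valid values)
makeRandomMatrix <- function(nGenes = 20, nSamples = 10, seed = 1,
                             prefix = "G") {
  set.seed(seed)
  m <- matrix(round(2^rnorm(nGenes * nSamples, 3, 1) - 1, 6),
              nrow = nGenes,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(nGenes)),
                              sprintf("s%03d", seq_len(nSamples))))
  m[m < 0] <- 0
  m
}

# independent two-sided Fisher oracle: full enumeration over the
# hypergeometric support with explicit binomial coefficients
fisherOracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  prob <- vapply(support, function(x) {
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  }, numeric(1))
  pObs <- prob[support == a]
  sum(prob[prob <= pObs * (1 + 1e-7)])
}

# brute-force neoepitope row scan (loop, no vectorised reuse of the
# implementation)
neoepitopeOracle <- function(tab, mutCut = 500, wtCut = 500, tpmCut = 1) {
  keep <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    keep[i] <- tab$mut_ic50[i] < mutCut && tab$wt_ic50[i] > wtCut &&
      tab$gene_tpm[i] > tpmCut
  }
  list(keep = keep,
       count = length(unique(tab$mutation_id[keep])))
}
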