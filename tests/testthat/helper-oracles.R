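## Independent reference implementations used as oracles. These are
## deliberately written as plain transcriptions of the textbook formulas /
## verbal rules, structured differently from the package's vectorized code
## paths.

## Weir & Cockerham (1984) theta for ONE locus from explicit genotype
## lists: pops is a list, each element an n_i x 2 matrix of allele indices
## (1..k, no NA). Returns the summed a, b, c components and theta.
wcThetaOracle <- function(pops, k = max(unlist(pops))) {
  r <- length(pops)
  n <- vapply(pops, nrow, integer(1))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  sumA <- sumB <- sumC <- 0
  for (u in seq_len(k)) {
    p <- vapply(pops, function(g) mean(g == u), numeric(1))
    h <- vapply(pops, function(g)
      mean((g[, 1] == u) != (g[, 2] == u)), numeric(1))
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
         ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    sumA <- sumA + a; sumB <- sumB + b; sumC <- sumC + cc
  }
  list(a = sumA, b = sumB, c = sumC,
       theta = sumA / (sumA + sumB + sumC))
}

## Build a GenotypeMatrix from a list of per-population n_i x 2 allele
## index matrices at a single locus (alleles named A1..Ak).
gmFromPops <- function(pops, k = max(unlist(pops))) {
  cat1 <- paste0("H", seq_len(k))
  a1 <- matrix(unlist(lapply(pops, function(g) g[, 1])), ncol = 1)
  a2 <- matrix(unlist(lapply(pops, function(g) g[, 2])), ncol = 1)
  coll <- rep(paste0("P", seq_along(pops)),
              vapply(pops, nrow, integer(1)))
  GenotypeMatrix(a1, a2, list(loc1 = cat1), coll,
                 individuals = paste0("i", seq_along(coll)),
                 loci = "loc1")
}

## Random genotype tables for the theta cross-check: nPops populations of
## varying size at one locus with k alleles.
randomPops <- function(nPops, k, nMin = 5, nMax = 40) {
  lapply(seq_len(nPops), function(i) {
    n <- sample(nMin:nMax, 1)
    p <- rgamma(k, 1); p <- p / sum(p)
    matrix(sample.int(k, 2 * n, replace = TRUE, prob = p), ncol = 2)
  })
}

## Trimming oracle: enumerates prefix cuts "through the first m SNPs" and
## suffix cuts "through the last q SNPs" and returns the minimal cuts that
## satisfy the flank rule (the verbal greedy rule in closed form).
trimOracle <- function(len, offs, flank) {
  offs <- sort(offs)
  nS <- length(offs)
  startOf <- function(m) if (m == 0) 0L else offs[m] + 1L
  m <- nS
  for (cand in 0:nS) {
    remaining <- offs[offs >= startOf(cand)]
    if (!length(remaining) || remaining[1] - startOf(cand) >= flank) {
      m <- cand; break
    }
  }
  start <- startOf(m)
  rem <- offs[offs >= start]
  endOf <- function(q) if (q == 0) len else rem[length(rem) - q + 1L]
  q <- length(rem)
  for (cand in 0:length(rem)) {
    remaining <- rem[rem < endOf(cand)]
    if (!length(remaining) ||
        (endOf(cand) - 1L - remaining[length(remaining)]) >= flank) {
      q <- cand; break
    }
  }
  end <- endOf(q)
  kept <- offs[offs >= start & offs < end]
  list(start = start, end = end, kept = kept,
       removed = length(kept) == 0)
}

## A small in-memory panel + matching genotypes for amplicon QC tests.
## Loci are 100 bp with interior SNPs so trimming keeps everything
## (flank is reduced accordingly).
makeTestPanel <- function(nLoci = 8L, nInd = 6L, seed = 42L,
                          years = c("1999", "2018")) {
  set.seed(seed)
  dp <- DriftParams(nLoci = nLoci,
                    years = as.integer(years),
                    sampleSizes = rep(ceiling(nInd / length(years)),
                                      length(years)),
                    neBaseline = 1000L, missingness = 0, seed = seed)
  sim <- simulateTemporalGenotypes(dp)
  ref <- simulateReferenceWithLoci(nLoci, locusLen = 110L, seed = seed + 1L,
                                   catalog = alleleCatalog(sim$gm),
                                   snpPlacement = "interior")
  panel <- simulatePanel(ref$loci, flank = 33L, maxTemplate = 150L)
  gm <- projectGenotypes(sim$gm, panel)
  list(panel = panel, gm = gm, gmFull = sim$gm, ref = ref)
}

## Direct multinomial log-likelihood of a genotype (i, j) given counts —
## used to derive expected ML calls independently of the caller.
dmnLoglik <- function(counts, i, j, eps) {
  k <- length(counts)
  w <- numeric(k)
  if (i == j) w[i] <- 1 else w[c(i, j)] <- 0.5
  sum(counts * log((1 - eps) * w + eps / k))
}
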