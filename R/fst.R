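## Weir & Cockerham (1984) variance components on microhaplotype alleles.
## All computations run on "expanded" matrices with one column per
## (locus, allele): D holds per-individual allele dosage (0/1/2), H marks
## heterozygous carriers (exactly one copy). Collections are the
## populations.

## Expand a GenotypeMatrix into dosage/heterozygote-indicator matrices.
alleleDosage <- function(gm) {
  n <- nInd(gm); L <- nLoci(gm)
  k <- lengths(gm@alleles)
  C <- sum(k)
  colLocus <- rep.int(seq_len(L), k)
  colAllele <- unlist(lapply(k, seq_len), use.names = FALSE)
  D <- matrix(NA_real_, n, C)
  H <- matrix(NA_real_, n, C)
  col <- 0L
  for (j in seq_len(L)) {
    a1 <- gm@a1[, j]; a2 <- gm@a2[, j]
    for (u in seq_len(k[j])) {
      col <- col + 1L
      d <- (a1 == u) + (a2 == u)
      D[, col] <- d
      H[, col] <- as.numeric(d == 1)
    }
  }
  colnames(D) <- colnames(H) <-
    paste(gm@loci[colLocus], colAllele, sep = ".")
  list(D = D, H = H, called = !is.na(gm@a1), colLocus = colLocus,
       colAllele = colAllele)
}

## Core W&C component computation from per-group summaries.
## N: r x L genotyped counts; S: r x C allele-copy sums; Het: r x C
## heterozygote counts; colLocus maps columns of S/Het to loci.
## Returns per-column a, b, c vectors.
wcFromSummaries <- function(N, S, Het, colLocus) {
  r <- colSums(N > 0)                      # effective populations per locus
  sumN <- colSums(N)
  nbarL <- sumN / r
  ncL <- (r * nbarL - colSums(N^2) / (r * nbarL)) / pmax(r - 1, 1)
  Ncol <- N[, colLocus, drop = FALSE]
  p <- S / (2 * Ncol); p[Ncol == 0] <- 0
  h <- Het / Ncol; h[Ncol == 0] <- 0
  rC <- r[colLocus]; nbar <- nbarL[colLocus]; nc <- ncL[colLocus]
  pbar <- colSums(Ncol * p) / (rC * nbar)
  s2 <- colSums(Ncol * sweep(p, 2, pbar)^2) / ((rC - 1) * nbar)
  hbar <- colSums(Ncol * h) / (rC * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (rC - 1) / rC * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (rC - 1) / rC * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- rC < 2 | nbar <= 1 | !is.finite(nc) | nc <= 0
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  list(a = a, b = b, c = cc, colLocus = colLocus)
}

## Group summaries for a genotype matrix under a grouping factor.
groupSummaries <- function(ad, groups) {
  g <- as.factor(groups)
  D0 <- ad$D; D0[is.na(D0)] <- 0
  H0 <- ad$H; H0[is.na(H0)] <- 0
  N <- rowsum(ad$called + 0, g)
  S <- rowsum(D0, g)
  Het <- rowsum(H0, g)
  list(N = N, S = S, Het = Het)
}

#' Per-locus temporal F_ST (Weir-Cockerham theta)
#'
#' Treats each collection (year) as a population and computes the
#' Weir-Cockerham (1984) theta per locus on microhaplotype alleles,
#' summing variance components over alleles. Loci monomorphic across all
#' collections are flagged undefined, never silently zero.
#'
#' @param gm a \linkS4class{GenotypeMatrix} with >= 2 collections.
#' @return data.frame (locusId, theta, defined).
#' @export
perLocusTemporalFst <- function(gm) {
  if (length(unique(collections(gm))) < 2L)
    stop("at least two collections are required")
  ad <- alleleDosage(gm)
  gs <- groupSummaries(ad, collections(gm))
  comps <- wcFromSummaries(gs$N, gs$S, gs$Het, ad$colLocus)
  A <- rowsum(comps$a, comps$colLocus)
  Tot <- rowsum(comps$a + comps$b + comps$c, comps$colLocus)
  theta <- as.vector(A / Tot)
  defined <- is.finite(theta) & abs(as.vector(Tot)) > 1e-12
  theta[!defined] <- NA_real_
  data.frame(locusId = lociIds(gm), theta = theta, defined = defined,
             stringsAsFactors = FALSE)
}

## Multilocus theta (ratio of summed components) for a grouping.
multilocusTheta <- function(gm, groups, loci = NULL) {
  ad <- alleleDosage(gm)
  keep <- if (is.null(loci)) rep(TRUE, ncol(ad$D))
          else ad$colLocus %in% match(loci, lociIds(gm))
  gs <- groupSummaries(ad, groups)
  comps <- wcFromSummaries(gs$N, gs$S, gs$Het, ad$colLocus)
  sum(comps$a[keep], na.rm = TRUE) /
    sum((comps$a + comps$b + comps$c)[keep], na.rm = TRUE)
}

## Vectorized two-group W&C theta across permutation rows.
## PA: nPerm x n 0/1 membership of group A. Returns theta per row.
thetaPermuted <- function(PA, D0, H0, called, colLocus) {
  NA_ <- PA %*% called
  NB_ <- matrix(colSums(called), nrow(PA), ncol(called), byrow = TRUE) - NA_
  SA <- PA %*% D0
  SB <- matrix(colSums(D0), nrow(PA), ncol(D0), byrow = TRUE) - SA
  HetA <- PA %*% H0
  HetB <- matrix(colSums(H0), nrow(PA), ncol(H0), byrow = TRUE) - HetA
  r <- 2
  NAc <- NA_[, colLocus, drop = FALSE]; NBc <- NB_[, colLocus, drop = FALSE]
  nbar <- (NA_ + NB_) / 2
  nc <- (r * nbar - (NA_^2 + NB_^2) / (r * nbar)) / (r - 1)
  nbarC <- nbar[, colLocus, drop = FALSE]
  ncC <- nc[, colLocus, drop = FALSE]
  pA <- SA / (2 * NAc); pA[NAc == 0] <- 0
  pB <- SB / (2 * NBc); pB[NBc == 0] <- 0
  hA <- HetA / NAc; hA[NAc == 0] <- 0
  hB <- HetB / NBc; hB[NBc == 0] <- 0
  pbar <- (NAc * pA + NBc * pB) / (r * nbarC)
  s2 <- (NAc * (pA - pbar)^2 + NBc * (pB - pbar)^2) / ((r - 1) * nbarC)
  hbar <- (NAc * hA + NBc * hB) / (r * nbarC)
  a <- nbarC / ncC *
    (s2 - 1 / (nbarC - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbarC / (nbarC - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbarC - 1) / (4 * nbarC) * hbar)
  cc <- hbar / 2
  bad <- !is.finite(a) | !is.finite(b) | NAc == 0 | NBc == 0 | nbarC <= 1
  a[bad] <- 0; b[bad] <- 0; cc[bad] <- 0
  rowSums(a) / rowSums(a + b + cc)
}

#' Pairwise temporal F_ST with permutation tests and bootstrap CIs
#'
#' Multilocus Weir-Cockerham theta (ratio of summed variance components)
#' for every pair of collections. Significance: individuals are shuffled
#' between the pair's two collections; the one-sided p-value is the
#' fraction of permutations with theta* >= theta-hat, with the +1/(n+1)
#' correction. Confidence intervals: percentile bootstrap over loci.
#'
#' @param gm a \linkS4class{GenotypeMatrix} with >= 2 collections.
#' @param nPerm permutations per pair (0 skips the test).
#' @param nBoot bootstrap iterations over loci (0 skips CIs).
#' @param seed RNG seed.
#' @param permChunk permutations processed per block (memory control).
#' @return List with matrices \code{theta}, \code{p}, \code{lo},
#'   \code{hi} (collections x collections) and \code{pairs}, a long-format
#'   data.frame.
#' @export
pairwiseFst <- function(gm, nPerm = 10000L, nBoot = 1000L, seed = 1L,
                        permChunk = 1000L) {
  set.seed(seed)
  colls <- sort(unique(collections(gm)))
  if (length(colls) < 2L) stop("at least two collections are required")
  ad <- alleleDosage(gm)
  D0 <- ad$D; D0[is.na(D0)] <- 0
  H0 <- ad$H; H0[is.na(H0)] <- 0
  called <- ad$called + 0
  m <- length(colls)
  theta <- p <- lo <- hi <- matrix(NA_real_, m, m,
                                   dimnames = list(colls, colls))
  pairs <- list()
  for (i in seq_len(m - 1)) for (j in seq((i + 1), m)) {
    selA <- collections(gm) == colls[i]
    selB <- collections(gm) == colls[j]
    if (sum(selA) < 2L || sum(selB) < 2L) next    # undefined entry
    sel <- selA | selB
    Dp <- D0[sel, , drop = FALSE]; Hp <- H0[sel, , drop = FALSE]
    Cp <- called[sel, , drop = FALSE]
    isA <- selA[sel]
    obs <- thetaPermuted(matrix(as.numeric(isA), 1), Dp, Hp, Cp, ad$colLocus)
    theta[i, j] <- theta[j, i] <- obs
    if (nPerm > 0) {
      nA <- sum(isA); n <- length(isA)
      exceed <- 0L
      left <- nPerm
      while (left > 0) {
        k <- min(permChunk, left)
        PA <- matrix(0, k, n)
        for (b in seq_len(k)) PA[b, sample.int(n, nA)] <- 1
        ts <- thetaPermuted(PA, Dp, Hp, Cp, ad$colLocus)
        exceed <- exceed + sum(ts >= obs, na.rm = TRUE)
        left <- left - k
      }
      p[i, j] <- p[j, i] <- (exceed + 1) / (nPerm + 1)
    }
    if (nBoot > 0) {
      ## per-locus summed components for the observed split
      gs <- groupSummaries(list(D = Dp, H = Hp, called = Cp == 1,
                                colLocus = ad$colLocus),
                           ifelse(isA, "A", "B"))
      comps <- wcFromSummaries(gs$N, gs$S, gs$Het, ad$colLocus)
      A <- rowsum(ifelse(is.na(comps$a), 0, comps$a), ad$colLocus)
      Tt <- rowsum(ifelse(is.na(comps$a + comps$b + comps$c), 0,
                          comps$a + comps$b + comps$c), ad$colLocus)
      L <- length(A)
      idx <- matrix(sample.int(L, L * nBoot, replace = TRUE), L)
      tb <- colSums(matrix(A[idx], L)) / colSums(matrix(Tt[idx], L))
      qs <- quantile(tb, c(0.025, 0.975), na.rm = TRUE)
      lo[i, j] <- lo[j, i] <- qs[1]
      hi[i, j] <- hi[j, i] <- qs[2]
    }
    pairs[[length(pairs) + 1L]] <-
      data.frame(collection1 = colls[i], collection2 = colls[j],
                 theta = theta[i, j], p = p[i, j], lo = lo[i, j],
                 hi = hi[i, j], stringsAsFactors = FALSE)
  }
  list(theta = theta, p = p, lo = lo, hi = hi,
       pairs = do.call(rbind, pairs))
}
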