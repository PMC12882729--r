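#' Depth and missingness filter
#'
#' Loci are discarded when mean depth of coverage is lower than
#' \code{minMeanDepth} (strictly below: 20.0 is retained, 19.9 is not);
#' individuals are retained only when their missing-data fraction is below
#' \code{maxIndMissing} (an individual at exactly 25\% is dropped).
#' Individuals are dropped before any locus missingness statistic is
#' computed.
#'
#' @param loci list of \linkS4class{MicrohapLocus} with \code{meanDepth}
#'   set.
#' @param gm a \linkS4class{GenotypeMatrix} over (at least) those loci.
#' @param minMeanDepth minimum mean depth (default 20).
#' @param maxIndMissing maximum tolerated individual missingness
#'   (default 0.25).
#' @return A \linkS4class{FilterReport}.
#' @export
depthMissingnessFilter <- function(loci, gm, minMeanDepth = 20,
                                   maxIndMissing = 0.25) {
  depths <- vapply(loci, function(l) l@meanDepth, numeric(1))
  if (anyNA(depths))
    stop("meanDepth missing for loci: ",
         paste(vapply(loci[is.na(depths)], locusId, character(1)),
               collapse = ", "))
  ids <- vapply(loci, locusId, character(1))
  miss <- missingness(gm)
  dropInd <- individuals(gm)[miss >= maxIndMissing]
  keepInd <- setdiff(individuals(gm), dropInd)
  lowDepth <- ids[depths < minMeanDepth]
  excluded <- data.frame(locusId = lowDepth,
                         reason = rep("depth", length(lowDepth)),
                         stringsAsFactors = FALSE)
  new("FilterReport", retainedLoci = setdiff(ids, lowDepth),
      excluded = excluded, retainedIndividuals = keepInd,
      droppedIndividuals = dropInd,
      details = list(meanDepth = setNames(depths, ids),
                     indMissingness = miss))
}

## Classic chi-square goodness-of-fit of diploid genotype counts against
## Hardy-Weinberg expectations; genotype classes are the k(k+1)/2 unordered
## allele pairs, df = #classes - #alleles (frequencies estimated).
hweChisqP <- function(a1, a2) {
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  if (n == 0) return(NA_real_)
  k <- max(a1, a2)
  freq <- tabulate(c(a1, a2), nbins = k) / (2 * n)
  if (sum(freq > 0) < 2) return(NA_real_)   # monomorphic: nothing to test
  obs <- matrix(0, k, k)
  for (i in seq_len(n)) obs[a1[i], a2[i]] <- obs[a1[i], a2[i]] + 1
  stat <- 0; classes <- 0L
  for (u in seq_len(k)) for (v in u:k) {
    e <- if (u == v) n * freq[u]^2 else 2 * n * freq[u] * freq[v]
    if (e <= 0) next
    classes <- classes + 1L
    stat <- stat + (obs[u, v] - e)^2 / e
  }
  df <- classes - sum(freq > 0)
  if (df < 1) return(NA_real_)
  pchisq(stat, df, lower.tail = FALSE)
}

#' Hardy-Weinberg equilibrium filter
#'
#' Within each collection, a chi-square goodness-of-fit test of observed
#' diploid genotype counts against HWE expectations from that collection's
#' allele frequencies (multi-allelic loci use all genotype classes);
#' p-values are corrected across loci within each collection. A locus is
#' excluded only when it is corrected-significant in EVERY collection; a
#' collection with no called genotypes at a locus cannot reject and counts
#' as non-significant.
#'
#' @param gm a \linkS4class{GenotypeMatrix} with >= 1 collection.
#' @param alpha significance level (default 0.05).
#' @param correction multiple-testing family passed to
#'   \code{\link[stats]{p.adjust}} (default "bonferroni").
#' @return A \linkS4class{FilterReport}; \code{details$hweP} holds the raw
#'   per-locus per-collection p-value matrix, \code{details$hwePadj} the
#'   corrected one.
#' @export
hweFilter <- function(gm, alpha = 0.05, correction = "bonferroni") {
  colls <- sort(unique(collections(gm)))
  L <- nLoci(gm)
  P <- matrix(NA_real_, L, length(colls),
              dimnames = list(lociIds(gm), colls))
  for (ci in seq_along(colls)) {
    sel <- collections(gm) == colls[ci]
    for (j in seq_len(L))
      P[j, ci] <- hweChisqP(gm@a1[sel, j], gm@a2[sel, j])
  }
  Padj <- apply(P, 2, p.adjust, method = correction)
  if (is.null(dim(Padj))) Padj <- matrix(Padj, L, length(colls),
                                         dimnames = dimnames(P))
  sig <- !is.na(Padj) & Padj < alpha
  excludeAll <- rowSums(sig) == length(colls)   # significant in EVERY one
  exc <- lociIds(gm)[excludeAll]
  new("FilterReport",
      retainedLoci = setdiff(lociIds(gm), exc),
      excluded = data.frame(locusId = exc,
                            reason = rep("HWE", length(exc)),
                            stringsAsFactors = FALSE),
      retainedIndividuals = individuals(gm),
      details = list(hweP = P, hwePadj = Padj))
}

#' Linkage-disequilibrium filter
#'
#' One SNP is selected at random per locus (seeded); pairwise r^2 is the
#' squared Pearson correlation of diploid dosage vectors (0/1/2) over
#' individuals called at both loci — a composite, phase-free estimator.
#' Each pair is tested with the chi-square statistic n*r^2 against
#' chi-square(1); the correction is applied across all locus pairs. From
#' every corrected-significant pair one locus is removed — the member with
#' the higher missingness, ties broken towards the lexicographically larger
#' id — and removal cascades until no significant pair remains among
#' retained loci.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param alpha significance level (default 0.05).
#' @param correction multiple-testing family (default "bonferroni").
#' @param seed seed for the per-locus SNP selection.
#' @return A \linkS4class{FilterReport}; \code{details$ldPairs} tabulates
#'   (locus1, locus2, r2, n, p, padj, significant), \code{details$snpChoice}
#'   records the selected SNP index per locus.
#' @export
ldFilter <- function(gm, alpha = 0.05, correction = "bonferroni", seed = 1L) {
  set.seed(seed)
  L <- nLoci(gm)
  if (L < 2L)
    return(new("FilterReport", retainedLoci = lociIds(gm),
               retainedIndividuals = individuals(gm),
               details = list(ldPairs = data.frame())))
  hapLen <- vapply(gm@alleles, function(a) nchar(a[1]), integer(1))
  ## the per-locus choice is keyed to the locus id so that re-running the
  ## filter on a subset selects the same SNPs (idempotent chain)
  snpChoice <- vapply(seq_len(L), function(j) {
    set.seed((seed + sum(utf8ToInt(lociIds(gm)[j]))) %% 2147483647L)
    sample.int(hapLen[j], 1L)
  }, integer(1))
  set.seed(seed)
  ## dosage of one (arbitrary but fixed) base at the chosen SNP
  dosage <- matrix(NA_real_, nInd(gm), L)
  for (j in seq_len(L)) {
    bases <- substr(gm@alleles[[j]], snpChoice[j], snpChoice[j])
    refBase <- sort(unique(bases))[1]
    isRef <- as.numeric(bases == refBase)
    dosage[, j] <- isRef[gm@a1[, j]] + isRef[gm@a2[, j]]
  }
  pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  cm <- suppressWarnings(cor(dosage, use = "pairwise.complete.obs"))
  cm[!is.finite(cm)] <- 0
  nm <- crossprod((!is.na(dosage)) + 0)
  r2 <- cm[pairs]^2
  n <- nm[pairs]
  r2[n <= 2] <- 0
  p <- pchisq(n * r2, df = 1, lower.tail = FALSE)
  padj <- p.adjust(p, method = correction)
  sig <- padj < alpha
  ldPairs <- data.frame(locus1 = lociIds(gm)[pairs[, 1]],
                        locus2 = lociIds(gm)[pairs[, 2]],
                        r2 = r2, n = n, p = p, padj = padj,
                        significant = sig, stringsAsFactors = FALSE)
  miss <- colMeans(is.na(gm@a1))
  names(miss) <- lociIds(gm)
  removed <- character(0)
  ord <- order(padj)
  for (q in ord[sig[ord]]) {
    l1 <- ldPairs$locus1[q]; l2 <- ldPairs$locus2[q]
    if (l1 %in% removed || l2 %in% removed) next
    removed <- c(removed,
                 if (miss[l1] > miss[l2]) l1
                 else if (miss[l2] > miss[l1]) l2
                 else max(l1, l2))
  }
  new("FilterReport",
      retainedLoci = setdiff(lociIds(gm), removed),
      excluded = data.frame(locusId = removed,
                            reason = rep("LD", length(removed)),
                            stringsAsFactors = FALSE),
      retainedIndividuals = individuals(gm),
      details = list(ldPairs = ldPairs, snpChoice = snpChoice))
}

#' Run the full pre-panel filter chain
#'
#' Pipelines the filters in their canonical order:
#' depth/missingness, then HWE, then LD; the chain is idempotent.
#'
#' @param loci list of \linkS4class{MicrohapLocus}.
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param minMeanDepth,maxIndMissing,alpha,correction,seed parameters of
#'   the individual filters.
#' @return A \linkS4class{FilterReport} with the combined exclusions and
#'   the per-stage reports under \code{details$stages}.
#' @export
runLocusFilters <- function(loci, gm, minMeanDepth = 20,
                            maxIndMissing = 0.25, alpha = 0.05,
                            correction = "bonferroni", seed = 1L) {
  r1 <- depthMissingnessFilter(loci, gm, minMeanDepth, maxIndMissing)
  gm1 <- gm[r1@retainedIndividuals, intersect(lociIds(gm), r1@retainedLoci)]
  r2 <- hweFilter(gm1, alpha, correction)
  gm2 <- gm1[, r2@retainedLoci]
  r3 <- ldFilter(gm2, alpha, correction, seed)
  excluded <- rbind(r1@excluded, r2@excluded, r3@excluded)
  new("FilterReport", retainedLoci = r3@retainedLoci, excluded = excluded,
      retainedIndividuals = r1@retainedIndividuals,
      droppedIndividuals = r1@droppedIndividuals,
      details = list(stages = list(depth = r1, hwe = r2, ld = r3)))
}
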