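#' Exact rarefied allele count for one locus
#'
#' Hypergeometric expectation of the number of distinct alleles in a
#' subsample of \code{g} gene copies: \code{sum_u 1 - C(N - N_u, g)/C(N, g)}
#' where \code{N_u} are allele copy counts and \code{N = sum(N_u)}.
#'
#' @param counts integer allele copy counts.
#' @param g rarefaction size (gene copies).
#' @return Expected allele count (NA when \code{g > N}).
#' @export
rarefiedAlleleCount <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g > N) return(NA_real_)
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Per-collection genetic diversity statistics
#'
#' For each collection: rarefied allelic richness A_R (exact hypergeometric
#' expectation, averaged over loci), observed heterozygosity H_O, Nei's
#' unbiased expected heterozygosity H_E, and the multilocus inbreeding
#' coefficient F_IS = 1 - sum(H_O)/sum(H_E) over loci polymorphic in that
#' collection (monomorphic loci carry no information about heterozygote
#' deficit and are excluded from F_IS). 95\% confidence intervals by
#' percentile bootstrap over loci.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param g rarefaction size in gene copies, or "auto" (twice the smallest
#'   per-locus genotyped count over all collections). Loci with fewer
#'   copies than \code{g} in a collection are skipped for A_R with a
#'   warning.
#' @param nBoot bootstrap iterations (0 skips CIs).
#' @param seed RNG seed for the bootstrap.
#' @return data.frame with one row per collection: n, polymorphic count and
#'   point estimate + CI for AR, HO, HE, FIS.
#' @export
diversityStats <- function(gm, g = "auto", nBoot = 1000L, seed = 1L) {
  set.seed(seed)
  colls <- sort(unique(collections(gm)))
  L <- nLoci(gm)
  ## per collection x locus: n called, HO, HE, allele copy counts
  perLocus <- list()
  minCopies <- Inf
  for (cc in colls) {
    sel <- collections(gm) == cc
    a1 <- gm@a1[sel, , drop = FALSE]; a2 <- gm@a2[sel, , drop = FALSE]
    n <- colSums(!is.na(a1))
    minCopies <- min(minCopies, 2 * n[n > 0])
    ho <- he <- rep(NA_real_, L)
    counts <- vector("list", L)
    for (j in seq_len(L)) {
      if (n[j] < 2) next
      k <- length(gm@alleles[[j]])
      tab <- tabulate(c(a1[, j], a2[, j]), nbins = k)
      counts[[j]] <- tab
      pr <- tab / sum(tab)
      ho[j] <- mean(a1[!is.na(a1[, j]), j] != a2[!is.na(a2[, j]), j])
      nn <- n[j]
      he[j] <- (2 * nn / (2 * nn - 1)) * (1 - sum(pr^2))
    }
    perLocus[[cc]] <- list(n = n, ho = ho, he = he, counts = counts)
  }
  if (identical(g, "auto")) g <- as.integer(minCopies)
  rows <- lapply(colls, function(cc) {
    pl <- perLocus[[cc]]
    ar <- vapply(seq_len(L), function(j) {
      if (is.null(pl$counts[[j]])) return(NA_real_)
      rarefiedAlleleCount(pl$counts[[j]], g)
    }, numeric(1))
    if (any(is.na(ar) & !vapply(pl$counts, is.null, logical(1))))
      warning(sprintf(
        "collection %s: %d loci with fewer than g=%d copies skipped for A_R",
        cc, sum(is.na(ar) & !vapply(pl$counts, is.null, logical(1))), g))
    poly <- !is.na(pl$he) & pl$he > 0
    stat <- function(idx) {
      pj <- idx[poly[idx]]
      c(AR = mean(ar[idx], na.rm = TRUE),
        HO = mean(pl$ho[idx], na.rm = TRUE),
        HE = mean(pl$he[idx], na.rm = TRUE),
        FIS = if (length(pj)) 1 - sum(pl$ho[pj]) / sum(pl$he[pj])
              else NA_real_)
    }
    pt <- stat(seq_len(L))
    ci <- matrix(NA_real_, 2, 4,
                 dimnames = list(c("lo", "hi"), names(pt)))
    if (nBoot > 0 && L > 1) {
      bs <- vapply(seq_len(nBoot), function(b)
        stat(sample.int(L, L, replace = TRUE)), numeric(4))
      ci[] <- apply(bs, 1, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
    }
    data.frame(collection = cc, n = max(pl$n), g = g,
               polymorphic = sum(poly),
               AR = pt["AR"], AR_lo = ci["lo", "AR"], AR_hi = ci["hi", "AR"],
               HO = pt["HO"], HO_lo = ci["lo", "HO"], HO_hi = ci["hi", "HO"],
               HE = pt["HE"], HE_lo = ci["lo", "HE"], HE_hi = ci["hi", "HE"],
               FIS = pt["FIS"], FIS_lo = ci["lo", "FIS"],
               FIS_hi = ci["hi", "FIS"],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
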