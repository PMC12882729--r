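## Per-round GT-seq QC: read classification, probe-based allele counting,
## ML genotyping, concordance, removal recommendations, stopping rule and
## sex assignment.

readPool <- function(reads) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    x <- Biostrings::readDNAStringSet(reads, format = "fastq")
    setNames(as.character(x), sub("\\s.*$", "", names(x)))
  } else if (is.character(reads)) reads
  else setNames(as.character(reads), names(reads))
}

#' Classify amplicon reads into on-target / interaction / unknown
#'
#' A read whose leading bases exactly match the forward primer of locus i
#' and which contains any allele probe of i is on-target(i); one that
#' matches fwd(i) but contains a primer sequence (fwd, rev, or a reverse
#' complement of either) of a different pair j is a primer interaction
#' (i, j); a read matching fwd(i) but neither, or no forward primer at
#' all, is unknown. Forward primers must be unique and prefix-free across
#' the panel (collision is an error).
#'
#' @param reads FASTQ path, named character vector or DNAStringSet.
#' @param panel list of \linkS4class{PanelEntry}.
#' @param returnLabels also return the per-read label table.
#' @return A \linkS4class{ReadClassSummary}.
#' @export
classifyReads <- function(reads, panel, returnLabels = FALSE) {
  reads <- readPool(reads)
  lociP <- vapply(panel, locusId, character(1))
  fwd <- vapply(panel, function(e) e@primer@fwd, character(1))
  if (anyDuplicated(fwd)) stop("duplicate forward primers in panel")
  for (i in seq_along(fwd)) {
    pref <- startsWith(fwd[-i], fwd[i])
    if (any(pref))
      stop(sprintf("forward primer of %s is a prefix of %s",
                   lociP[i], lociP[-i][pref][1]))
  }
  nR <- length(reads)
  locusOf <- rep(NA_integer_, nR)
  for (len in sort(unique(nchar(fwd)))) {
    idxP <- which(nchar(fwd) == len)
    m <- match(substr(reads, 1L, len), fwd[idxP])
    hit <- !is.na(m) & is.na(locusOf)
    locusOf[hit] <- idxP[m[hit]]
  }
  cls <- rep("unknown", nR)
  jOf <- rep(NA_integer_, nR)
  ## on-target: any probe of the read's own locus present
  probeRx <- lapply(panel, function(e)
    vapply(unique(e@probes$probe), probeRegex, character(1)))
  for (i in seq_along(panel)) {
    idx <- which(locusOf == i)
    if (!length(idx)) next
    ok <- rep(FALSE, length(idx))
    for (rx in probeRx[[i]])
      ok <- ok | grepl(rx, reads[idx], perl = TRUE)
    cls[idx[ok]] <- "on_target"
  }
  ## interactions: other-pair primer contained downstream of the fwd match
  cand <- which(!is.na(locusOf) & cls == "unknown")
  if (length(cand)) {
    pats <- do.call(rbind, lapply(seq_along(panel), function(j) {
      e <- panel[[j]]
      data.frame(j = j,
                 pat = c(e@primer@fwd, e@primer@rev,
                         revComp(e@primer@fwd), revComp(e@primer@rev)),
                 stringsAsFactors = FALSE)
    }))
    pats <- pats[!duplicated(pats$pat), ]
    bestPos <- rep(Inf, length(cand))
    for (q in seq_len(nrow(pats))) {
      pos <- regexpr(pats$pat[q], reads[cand], fixed = TRUE)
      sel <- pos > 0 & pos < bestPos & pats$j[q] != locusOf[cand]
      bestPos[sel] <- pos[sel]
      jOf[cand[sel]] <- pats$j[q]
    }
    cls[cand[!is.na(jOf[cand])]] <- "interaction"
  }
  onTarget <- integer(length(panel))
  names(onTarget) <- lociP
  tb <- table(factor(locusOf[cls == "on_target"], levels = seq_along(panel)))
  onTarget[] <- as.integer(tb)
  intIdx <- which(cls == "interaction")
  interactions <- if (length(intIdx)) {
    agg <- as.data.frame(table(locusI = lociP[locusOf[intIdx]],
                               locusJ = lociP[jOf[intIdx]]),
                         stringsAsFactors = FALSE)
    agg <- agg[agg$Freq > 0, ]
    data.frame(locusI = agg$locusI, locusJ = agg$locusJ,
               count = as.integer(agg$Freq), stringsAsFactors = FALSE)
  } else data.frame(locusI = character(0), locusJ = character(0),
                    count = integer(0))
  labels <- if (returnLabels)
    data.frame(read = names(reads) %||% as.character(seq_len(nR)),
               class = cls,
               locusI = ifelse(is.na(locusOf), NA_character_,
                               lociP[locusOf]),
               locusJ = ifelse(is.na(jOf), NA_character_, lociP[jOf]),
               stringsAsFactors = FALSE)
  else data.frame()
  new("ReadClassSummary", total = nR, onTarget = onTarget,
      interactions = interactions,
      unknown = as.integer(nR - sum(onTarget) - sum(interactions$count)),
      proportionInteractions =
        if (nR) sum(interactions$count) / nR else 0,
      labels = labels)
}

#' Count SNP-allele reads per individual via probes
#'
#' For every on-target read and every SNP of its locus, the allele whose
#' probe matches the read increments that allele's count (IUPAC positions
#' in probes match their expansion set); a read matching no probe at a SNP
#' is uncalled there. Haplotype-allele counts are accumulated in parallel:
#' a read whose per-SNP matches are complete contributes one count to that
#' haplotype (phase is read directly off the single-end read).
#'
#' @param reads FASTQ path or named character vector; read names must be
#'   \code{<individual>:<serial>} or an explicit \code{individualMap} must
#'   be given.
#' @param panel list of \linkS4class{PanelEntry}.
#' @param individualMap optional named vector read name -> individual.
#' @return An \linkS4class{AlleleCounts}.
#' @export
countAlleles <- function(reads, panel, individualMap = NULL) {
  reads <- readPool(reads)
  if (is.null(names(reads)) || !all(nzchar(names(reads))))
    stop("reads must be named to identify individuals")
  inds <- if (!is.null(individualMap)) {
    mp <- individualMap[names(reads)]
    if (anyNA(mp))
      stop("individuals absent from map: ",
           paste(head(names(reads)[is.na(mp)]), collapse = ", "))
    unname(mp)
  } else sub(":[0-9]+$", "", names(reads))
  summ <- classifyReads(reads, panel, returnLabels = TRUE)
  lab <- summ@labels
  snpRows <- list(); hapRows <- list(); depthRows <- list()
  for (e in panel) {
    loc <- locusId(e)
    idx <- which(lab$class == "on_target" & lab$locusI == loc)
    if (!length(idx)) next
    rd <- reads[idx]; ri <- inds[idx]
    offs <- sort(unique(e@probes$snpOffset))
    perSnpAllele <- matrix(NA_character_, length(idx), length(offs))
    for (s in seq_along(offs)) {
      pr <- e@probes[e@probes$snpOffset == offs[s], , drop = FALSE]
      for (q in seq_len(nrow(pr))) {
        hitq <- grepl(probeRegex(pr$probe[q]), rd, perl = TRUE)
        perSnpAllele[hitq & is.na(perSnpAllele[, s]), s] <- pr$allele[q]
      }
      called <- !is.na(perSnpAllele[, s])
      if (any(called)) {
        tb <- as.data.frame(table(individual = ri[called],
                                  allele = perSnpAllele[called, s]),
                            stringsAsFactors = FALSE)
        tb <- tb[tb$Freq > 0, ]
        snpRows[[length(snpRows) + 1L]] <-
          data.frame(individual = tb$individual, locusId = loc,
                     snpOffset = offs[s], allele = tb$allele,
                     count = as.integer(tb$Freq), stringsAsFactors = FALSE)
      }
    }
    full <- rowSums(is.na(perSnpAllele)) == 0
    if (any(full)) {
      hap <- apply(perSnpAllele[full, , drop = FALSE], 1, paste,
                   collapse = "")
      tb <- as.data.frame(table(individual = ri[full], allele = hap),
                          stringsAsFactors = FALSE)
      tb <- tb[tb$Freq > 0, ]
      hapRows[[length(hapRows) + 1L]] <-
        data.frame(individual = tb$individual, locusId = loc,
                   allele = tb$allele, count = as.integer(tb$Freq),
                   stringsAsFactors = FALSE)
    }
    dtb <- as.data.frame(table(individual = ri), stringsAsFactors = FALSE)
    depthRows[[length(depthRows) + 1L]] <-
      data.frame(individual = dtb$individual, locusId = loc,
                 depth = as.integer(dtb$Freq), stringsAsFactors = FALSE)
  }
  bindOr <- function(rows, proto) if (length(rows)) do.call(rbind, rows)
    else proto
  new("AlleleCounts",
      hapCounts = bindOr(hapRows,
        data.frame(individual = character(0), locusId = character(0),
                   allele = character(0), count = integer(0))),
      snpCounts = bindOr(snpRows,
        data.frame(individual = character(0), locusId = character(0),
                   snpOffset = integer(0), allele = character(0),
                   count = integer(0))),
      depth = bindOr(depthRows,
        data.frame(individual = character(0), locusId = character(0),
                   depth = integer(0))))
}

#' Maximum-likelihood genotype call for one locus
#'
#' Multinomial model over the locus's k alleles: for genotype g the
#' expected proportion of reads carrying allele l is
#' \code{(1 - eps) * w_l(g) + eps / k}, where w is 1 for the homozygous
#' allele, 0.5 each for the two heterozygous alleles, 0 otherwise. Returns
#' the argmax over unordered allele pairs.
#'
#' @param counts named (by allele) or positional numeric count vector over
#'   the locus catalogue.
#' @param eps per-read misassignment rate (default 0.01).
#' @return List with \code{g1}, \code{g2} (allele indices, g1 <= g2) and
#'   \code{loglik}.
#' @export
mlGenotypeCall <- function(counts, eps = 0.01) {
  k <- length(counts)
  best <- NULL; bestLL <- -Inf
  for (i in seq_len(k)) for (j in i:k) {
    w <- numeric(k)
    if (i == j) w[i] <- 1 else { w[i] <- 0.5; w[j] <- 0.5 }
    pr <- (1 - eps) * w + eps / k
    ll <- sum(counts * log(pr))
    if (ll > bestLL) { bestLL <- ll; best <- c(i, j) }
  }
  list(g1 = best[1], g2 = best[2], loglik = bestLL)
}

#' Call microhaplotype genotypes by maximum likelihood
#'
#' Per individual and locus, haplotype-allele read counts are evaluated
#' under the multinomial model of \code{\link{mlGenotypeCall}}; total
#' depth below \code{minDepth} yields a missing call. The locus catalogue
#' is the full combination set of the panel's per-SNP alleles, so
#' unobserved recombinant haplotypes are representable.
#'
#' @param ac an \linkS4class{AlleleCounts}.
#' @param panel list of \linkS4class{PanelEntry}.
#' @param collections named vector individual -> collection label (default
#'   a single collection "0").
#' @param eps per-read misassignment rate (default 0.01).
#' @param minDepth minimum haplotype-informative depth (default 10).
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
callGenotypesMl <- function(ac, panel, collections = NULL, eps = 0.01,
                            minDepth = 10L) {
  lociP <- vapply(panel, locusId, character(1))
  catalogs <- lapply(panel, function(e) {
    byS <- lapply(split(e@probes$allele, e@probes$snpOffset), unique)
    byS <- byS[order(as.integer(names(byS)))]
    combos <- do.call(expand.grid, c(byS, list(stringsAsFactors = FALSE)))
    sort(unique(apply(combos, 1, paste, collapse = "")))
  })
  names(catalogs) <- lociP
  inds <- sort(unique(ac@hapCounts$individual))
  if (!length(inds)) stop("no haplotype counts to genotype")
  n <- length(inds); L <- length(lociP)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  hc <- ac@hapCounts
  key <- paste(hc$individual, hc$locusId, sep = "\r")
  split_hc <- split(seq_len(nrow(hc)), key)
  for (kk in names(split_hc)) {
    parts <- strsplit(kk, "\r", fixed = TRUE)[[1]]
    ii <- match(parts[1], inds); jj <- match(parts[2], lociP)
    if (is.na(jj)) next
    cat_j <- catalogs[[jj]]
    rows <- split_hc[[kk]]
    counts <- numeric(length(cat_j))
    m <- match(hc$allele[rows], cat_j)
    keep <- !is.na(m)
    counts[m[keep]] <- hc$count[rows][keep]
    if (sum(counts) < minDepth) next
    g <- mlGenotypeCall(counts, eps)
    a1[ii, jj] <- g$g1; a2[ii, jj] <- g$g2
  }
  coll <- if (is.null(collections)) setNames(rep("0", n), inds)
          else collections
  GenotypeMatrix(a1, a2, setNames(catalogs, lociP), unname(coll[inds]),
                 individuals = inds, loci = lociP)
}

#' Project genotypes onto a panel's retained SNPs
#'
#' Trimming for primer compatibility can drop SNPs from a locus, so an
#' assay panel may interrogate a subset of the haplotype sites of an
#' upstream genotype dataset. This restricts each locus's haplotype
#' catalogue to the panel's retained sites (using the trimming record),
#' merging haplotypes that become indistinguishable, so that upstream and
#' panel-derived genotypes are directly comparable.
#'
#' @param gm a \linkS4class{GenotypeMatrix} with full haplotypes.
#' @param panel list of \linkS4class{PanelEntry} (loci must exist in
#'   \code{gm}).
#' @return A \linkS4class{GenotypeMatrix} over the panel loci.
#' @export
projectGenotypes <- function(gm, panel) {
  lociP <- unname(vapply(panel, locusId, character(1)))
  stopifnot(all(lociP %in% lociIds(gm)))
  jIdx <- match(lociP, lociIds(gm))
  n <- nInd(gm); L <- length(lociP)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  catal <- vector("list", L); names(catal) <- lociP
  for (q in seq_len(L)) {
    e <- panel[[q]]
    orig <- e@locus@snps$origIndex %||% seq_len(nrow(e@locus@snps))
    full <- gm@alleles[[jIdx[q]]]
    proj <- vapply(full, function(h)
      paste(vapply(orig, function(i) substr(h, i, i), character(1)),
            collapse = ""), character(1))
    cat_q <- sort(unique(unname(proj)))
    remap <- match(proj, cat_q)
    catal[[q]] <- cat_q
    a1[, q] <- remap[gm@a1[, jIdx[q]]]
    a2[, q] <- remap[gm@a2[, jIdx[q]]]
  }
  GenotypeMatrix(a1, a2, catal, collections(gm),
                 individuals = individuals(gm), loci = lociP)
}

#' Genotype concordance between two datasets
#'
#' Individuals genotyped for fewer than \code{minCallRate} of the shared
#' loci (in either dataset) are excluded; per-SNP accuracy is the fraction
#' of matching unordered genotypes among calls present in both datasets;
#' the overall accuracy is the mean over SNPs.
#'
#' @param a,b \linkS4class{GenotypeMatrix} objects sharing individuals and
#'   loci by id.
#' @param minCallRate per-individual call-rate gate (default 0.70).
#' @return List with \code{perSnp} (locusId, snpIndex, nCompared,
#'   accuracy), \code{overall} (mean per-SNP accuracy) and
#'   \code{individualsUsed}.
#' @export
genotypeConcordance <- function(a, b, minCallRate = 0.70) {
  inds <- intersect(individuals(a), individuals(b))
  loci <- intersect(lociIds(a), lociIds(b))
  if (!length(inds)) stop("no shared individuals")
  if (!length(loci)) stop("no shared loci")
  aa <- a[inds, loci]; bb <- b[inds, loci]
  lenA <- vapply(alleleCatalog(aa), function(x) nchar(x[1]), integer(1))
  lenB <- vapply(alleleCatalog(bb), function(x) nchar(x[1]), integer(1))
  if (any(lenA != lenB))
    stop("haplotype site sets differ for shared loci (",
         paste(head(loci[lenA != lenB], 3), collapse = ", "),
         "...); project one dataset onto the panel first ",
         "(see projectGenotypes)")
  crA <- 1 - missingness(aa); crB <- 1 - missingness(bb)
  keep <- inds[crA >= minCallRate & crB >= minCallRate]
  aa <- aa[keep, ]; bb <- bb[keep, ]
  csA <- callStrings(aa); csB <- callStrings(bb)
  perSnp <- list()
  for (j in seq_along(loci)) {
    sLen <- nchar(alleleCatalog(aa)[[j]][1])
    for (s in seq_len(sLen)) {
      gA <- snpGenotypeFromCall(csA[, j], s)
      gB <- snpGenotypeFromCall(csB[, j], s)
      both <- !is.na(gA) & !is.na(gB)
      perSnp[[length(perSnp) + 1L]] <-
        data.frame(locusId = loci[j], snpIndex = s,
                   nCompared = sum(both),
                   accuracy = if (any(both)) mean(gA[both] == gB[both])
                              else NA_real_,
                   stringsAsFactors = FALSE)
    }
  }
  perSnp <- do.call(rbind, perSnp)
  list(perSnp = perSnp,
       overall = mean(perSnp$accuracy, na.rm = TRUE),
       individualsUsed = keep)
}

## Unordered single-SNP genotype string from a "hap1/hap2" call.
snpGenotypeFromCall <- function(calls, s) {
  out <- rep(NA_character_, length(calls))
  ok <- calls != MISSING_CALL & !is.na(calls)
  if (!any(ok)) return(out)
  parts <- strsplit(calls[ok], "/", fixed = TRUE)
  b1 <- substr(vapply(parts, `[`, character(1), 1L), s, s)
  b2 <- substr(vapply(parts, `[`, character(1), 2L), s, s)
  out[ok] <- paste(pmin(b1, b2), pmax(b1, b2), sep = "/")
  out
}

#' Flag over- and under-represented loci
#'
#' Compares each locus's share of on-target reads to the panel mean share;
#' shares above \code{overFold} times the mean are over-amplifying, below
#' \code{underFold} times the mean (including zero reads) under-amplifying.
#'
#' @param rc a \linkS4class{ReadClassSummary} with >= 1 on-target read.
#' @param overFold,underFold fold thresholds (defaults 10 and 0.1).
#' @return List with \code{over} and \code{under} locus-id vectors.
#' @export
flagRepresentation <- function(rc, overFold = 10, underFold = 0.1) {
  tot <- sum(rc@onTarget)
  if (tot == 0) stop("no on-target reads")
  share <- rc@onTarget / tot
  m <- 1 / length(share)
  list(over = names(share)[share > overFold * m],
       under = names(share)[share < underFold * m])
}

#' Recommend primer-pair and SNP removals for the next round
#'
#' Primer pairs are ranked by their involvement in interaction reads and
#' greedily removed until the removed pairs cover at least
#' \code{interactionShareCutoff} of all interaction reads. When a pair
#' interacts predominantly (> 50\% of its interactions) with one single
#' other pair, only the member of that duo whose locus has the lower
#' temporal theta is removed (the higher-theta locus is retained; with
#' theta unavailable the member with more interactions goes). SNPs with
#' accuracy below \code{accuracyCutoff} are dropped; their locus is removed
#' only when no SNP passes. Over/under-amplifying loci are appended.
#'
#' @param rc a \linkS4class{ReadClassSummary}.
#' @param locusFst data.frame from \code{\link{perLocusTemporalFst}} (may
#'   be NULL).
#' @param snpAccuracy optional data.frame (locusId, snpIndex, accuracy).
#' @param interactionShareCutoff cumulative interaction share to remove
#'   (default 0.90).
#' @param accuracyCutoff per-SNP accuracy threshold (default 0.90).
#' @param representation apply \code{\link{flagRepresentation}} (default
#'   TRUE; disabled automatically with no on-target reads).
#' @param overFold,underFold representation thresholds.
#' @return List with \code{removals} (locusId, reason) and
#'   \code{snpRemovals} (locusId, snpIndex).
#' @export
recommendRemovals <- function(rc, locusFst = NULL, snpAccuracy = NULL,
                              interactionShareCutoff = 0.90,
                              accuracyCutoff = 0.90,
                              representation = TRUE,
                              overFold = 10, underFold = 0.1) {
  theta <- if (!is.null(locusFst))
    setNames(locusFst$theta, locusFst$locusId) else numeric(0)
  ints <- rc@interactions
  removals <- list()
  totalInt <- sum(ints$count)
  if (totalInt > 0) {
    live <- ints
    removedShare <- 0
    repeat {
      if (removedShare >= interactionShareCutoff || !nrow(live)) break
      inv <- tapply(c(live$count, live$count), c(live$locusI, live$locusJ),
                    sum)
      top <- names(inv)[which.max(inv)]
      ## predominant single partner?
      mine <- live[live$locusI == top | live$locusJ == top, , drop = FALSE]
      partner <- ifelse(mine$locusI == top, mine$locusJ, mine$locusI)
      pshare <- tapply(mine$count, partner, sum) / sum(mine$count)
      victim <- top
      if (length(pshare) && max(pshare) > 0.5) {
        duo <- names(pshare)[which.max(pshare)]
        thTop <- theta[top]; thDuo <- theta[duo]
        victim <- if (!is.na(thTop) && !is.na(thDuo)) {
          if (thTop < thDuo) top else duo
        } else {
          invTop <- sum(mine$count)
          invDuo <- inv[duo]
          if (invDuo > invTop) duo else top
        }
      }
      removals[[length(removals) + 1L]] <-
        data.frame(locusId = victim, reason = "interaction",
                   stringsAsFactors = FALSE)
      live <- live[live$locusI != victim & live$locusJ != victim, ,
                   drop = FALSE]
      removedShare <- (totalInt - sum(live$count)) / totalInt
    }
  }
  snpRemovals <- data.frame(locusId = character(0), snpIndex = integer(0))
  if (!is.null(snpAccuracy) && nrow(snpAccuracy)) {
    bad <- snpAccuracy[!is.na(snpAccuracy$accuracy) &
                         snpAccuracy$accuracy < accuracyCutoff, ,
                       drop = FALSE]
    snpRemovals <- bad[, c("locusId", "snpIndex")]
    for (loc in unique(bad$locusId)) {
      accs <- snpAccuracy$accuracy[snpAccuracy$locusId == loc]
      if (all(is.na(accs) | accs < accuracyCutoff))
        removals[[length(removals) + 1L]] <-
          data.frame(locusId = loc, reason = "low_accuracy",
                     stringsAsFactors = FALSE)
    }
  }
  if (representation && sum(rc@onTarget) > 0) {
    fl <- flagRepresentation(rc, overFold, underFold)
    if (length(fl$over))
      removals[[length(removals) + 1L]] <-
        data.frame(locusId = fl$over, reason = "over_amp",
                   stringsAsFactors = FALSE)
    if (length(fl$under))
      removals[[length(removals) + 1L]] <-
        data.frame(locusId = fl$under, reason = "under_amp",
                   stringsAsFactors = FALSE)
  }
  rem <- if (length(removals)) do.call(rbind, removals)
         else data.frame(locusId = character(0), reason = character(0))
  rem <- rem[!duplicated(rem$locusId), , drop = FALSE]
  rownames(rem) <- NULL
  list(removals = rem, snpRemovals = snpRemovals)
}

#' Assess an optimization round against the stopping rule
#'
#' The multiplex is accepted when the proportion of reads from primer
#' interactions is lower than one third of total reads AND genotype
#' accuracy exceeds 95\%; an unavailable accuracy (genotyping rate too
#' low) always means continue.
#'
#' @param rc a \linkS4class{ReadClassSummary} (or the interaction
#'   proportion directly).
#' @param accuracy mean genotype accuracy as a fraction (NA allowed).
#' @param removals optional removal table to carry along.
#' @return A \linkS4class{RoundAssessment}.
#' @export
assessRound <- function(rc, accuracy, removals = data.frame()) {
  prop <- if (is(rc, "ReadClassSummary")) rc@proportionInteractions
          else as.numeric(rc)
  stop <- isTRUE(prop < 1 / 3) && !is.na(accuracy) && isTRUE(accuracy > 0.95)
  reason <- if (is.na(accuracy)) "accuracy unavailable"
    else if (stop) "interaction and accuracy criteria met"
    else if (prop >= 1 / 3 && accuracy <= 0.95)
      "interactions >= 1/3 and accuracy <= 95%"
    else if (prop >= 1 / 3) "interactions >= 1/3"
    else "accuracy <= 95%"
  new("RoundAssessment", proportionInteractions = prop,
      accuracy = as.numeric(accuracy), stop = stop, reason = reason,
      removals = removals)
}

#' Assign sex from a two-SNP sex-linked locus
#'
#' Looks each individual's unordered diplotype at the sex locus up in a
#' user-provided mapping (the diplotype-to-sex rule is species- and
#' marker-specific and ships as configuration). A missing call at either
#' SNP, or a diplotype absent from the mapping, is UNRESOLVED.
#'
#' @param gm a \linkS4class{GenotypeMatrix} containing the sex locus.
#' @param sexLocus locus id.
#' @param mapping named character vector, e.g.
#'   \code{c("AG/CT" = "female", "CT/CT" = "male")} (diplotype keys in
#'   canonical sorted order).
#' @return Named character vector individual -> label or "UNRESOLVED".
#' @export
assignSex <- function(gm, sexLocus, mapping) {
  if (!is.character(mapping) || is.null(names(mapping)) ||
      !all(grepl("/", names(mapping))))
    stop("mapping must be a named character vector keyed by 'hap1/hap2'")
  j <- match(sexLocus, lociIds(gm))
  if (is.na(j)) stop("sex locus ", sexLocus, " absent from genotypes")
  cs <- callStrings(gm)[, j]
  canon <- vapply(strsplit(cs, "/", fixed = TRUE), function(p)
    if (length(p) == 2L) paste(pmin(p[1], p[2]), pmax(p[1], p[2]), sep = "/")
    else NA_character_, character(1))
  out <- mapping[canon]
  out[is.na(out)] <- "UNRESOLVED"
  setNames(unname(out), individuals(gm))
}
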