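randLocus <- function(len, offs, id = "t1") {
  sq <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  alleles <- lapply(offs, function(o) {
    ref <- sq[o + 1L]
    sort(c(ref, sample(setdiff(c("A", "C", "G", "T"), ref), 1)))
  })
  MicrohapLocus(id, paste(sq, collapse = ""), snpOffsets = offs,
                snpAlleles = alleles)
}

test_that("SNP-position trimming follows the iterative edge rule", {
  set.seed(4)
  ## 100 bp locus, single SNP at offset 49: untouched (flanks 49 and 50)
  l1 <- randLocus(100L, 49L)
  t1 <- trimSnpsForPrimers(l1, flank = 33L)
  expect_length(t1@removed, 0)
  expect_equal(nchar(t1@sequence), 100L)
  expect_equal(t1@snps$offset, 49L)

  ## 120 bp locus, single SNP at offset 10: inside the first 33 bp, so the
  ## SNP is discarded and no SNP remains -> REMOVED(no_snps)
  l2 <- randLocus(120L, 10L)
  t2 <- trimSnpsForPrimers(l2, flank = 33L)
  expect_equal(t2@removed, "no_snps")
  expect_equal(t2@discardedSnps, 1L)

  ## boundary: a SNP at 0-based offset 32 has only 32 bases before it ->
  ## trimmed (and the rescan restarts after it); at offset 33 it has
  ## exactly 33 -> kept untouched
  t32 <- trimSnpsForPrimers(randLocus(140L, c(32L, 80L)), 33L)
  expect_equal(t32@keptStart, 33L)
  expect_equal(t32@snps$offset, 80L - 33L)
  expect_equal(t32@discardedSnps, 1L)
  t33 <- trimSnpsForPrimers(randLocus(140L, c(33L, 80L)), 33L)
  expect_equal(t33@keptStart, 0L)
  expect_equal(t33@snps$offset, c(33L, 80L))
  ## cascade: after cutting through offset 32 the next SNP at 60 has only
  ## 27 bases of flank left and falls too -> nothing survives
  tCasc <- trimSnpsForPrimers(randLocus(120L, c(32L, 60L)), 33L)
  expect_equal(tCasc@removed, "no_snps")

  expect_error(trimSnpsForPrimers(l1, flank = 0L), "flank")
})

test_that("trimming matches the enumeration oracle on random loci", {
  set.seed(99)
  for (rep in 1:800) {
    len <- sample(20:80, 1)
    nS <- sample(1:5, 1)
    offs <- sort(sample(0:(len - 1), min(nS, len)))
    tr <- trimSnpsForPrimers(randLocus(len, offs), flank = 5L)
    or <- trimOracle(len, offs, flank = 5L)
    if (or$removed) {
      expect_equal(tr@removed, "no_snps")
    } else {
      expect_length(tr@removed, 0)
      expect_equal(tr@keptStart, or$start)
      expect_equal(tr@keptEnd, or$end)
      expect_equal(tr@snps$offset + tr@keptStart, or$kept)
    }
  }
})

test_that("trimming is idempotent and its two passes commute", {
  set.seed(7)
  for (rep in 1:200) {
    len <- sample(30:80, 1)
    offs <- sort(sample(0:(len - 1), sample(1:4, 1)))
    t1 <- trimSnpsForPrimers(randLocus(len, offs), flank = 6L)
    if (length(t1@removed)) next
    again <- MicrohapLocus(t1@locusId, t1@sequence,
                           snpOffsets = t1@snps$offset,
                           snpAlleles = t1@snps$alleles)
    t2 <- trimSnpsForPrimers(again, flank = 6L)
    expect_equal(t2@keptStart, 0L)
    expect_equal(nchar(t2@sequence), nchar(t1@sequence))
    expect_equal(t2@snps$offset, t1@snps$offset)
  }
})

test_that("template length gate keeps 150 and removes 151", {
  mk <- function(len) {
    l <- randLocus(len, as.integer(len %/% 2))
    trimSnpsForPrimers(l, flank = 5L)
  }
  set.seed(12)
  t150 <- mk(150L); t151 <- mk(151L); t40 <- mk(40L)
  expect_length(filterTemplateLength(t150)@removed, 0)
  expect_equal(filterTemplateLength(t151)@removed, "too_long")
  expect_length(filterTemplateLength(t40)@removed, 0)
})

test_that("probes are 17 nt, allele-centred, with IUPAC for neighbours", {
  ## isolated SNP: two probes differing only at the centre position
  sq <- "ACGTACGTAAGTTGGAACGTACGTACGTAC"   # offset 14 (15th base) is G
  l <- MicrohapLocus("p1", sq, snpOffsets = 14L,
                     snpAlleles = list(c("G", "T")))
  t <- new("TrimmedLocus", locusId = "p1", sequence = sq,
           snps = l@snps, keptStart = 0L, keptEnd = nchar(sq),
           discardedSnps = 0L, removed = character(0))
  pr <- buildProbes(t)
  expect_equal(nrow(pr), 2L)
  expect_equal(unique(nchar(pr$probe)), 17L)
  pg <- pr$probe[pr$allele == "G"]; pt <- pr$probe[pr$allele == "T"]
  expect_equal(substr(pg, 9, 9), "G")
  expect_equal(substr(pt, 9, 9), "T")
  expect_equal(substr(pg, 1, 8), substr(pt, 1, 8))
  expect_equal(substr(pg, 10, 17), substr(pt, 10, 17))
  ## monomorphic flank: probes are exact substrings of the
  ## allele-substituted template
  tmpl <- sq
  substr(tmpl, 15, 15) <- "G"
  expect_equal(pg, substr(tmpl, 7, 23))

  ## two SNPs 5 bp apart: each probe encodes the neighbour as IUPAC
  sq2 <- paste(rep("A", 30), collapse = "")
  sq2 <- paste0(substr(sq2, 1, 12), "G", substr(sq2, 14, 30))
  sq2 <- paste0(substr(sq2, 1, 17), "T", substr(sq2, 19, 30))
  l2 <- MicrohapLocus("p2", sq2, snpOffsets = c(12L, 17L),
                      snpAlleles = list(c("C", "G"), c("G", "T")))
  t2 <- new("TrimmedLocus", locusId = "p2", sequence = sq2,
            snps = l2@snps, keptStart = 0L, keptEnd = 30L,
            discardedSnps = 0L, removed = character(0))
  pr2 <- buildProbes(t2)
  p12C <- pr2$probe[pr2$snpOffset == 12 & pr2$allele == "C"]
  ## neighbour at offset 17 (G/T) sits 5 right of centre -> position 14 = K
  expect_equal(substr(p12C, 14, 14), "K")
  expect_equal(substr(p12C, 9, 9), "C")
  p17T <- pr2$probe[pr2$snpOffset == 17 & pr2$allele == "T"]
  ## neighbour at offset 12 (C/G) sits 5 left of centre -> position 4 = S
  expect_equal(substr(p17T, 4, 4), "S")

  ## flank shortfall violates the trimming contract
  lEdge <- MicrohapLocus("p3", "ACGTACGTAC", snpOffsets = 2L,
                         snpAlleles = list(c("G", "T")))
  tEdge <- new("TrimmedLocus", locusId = "p3", sequence = "ACGTACGTAC",
               snps = lEdge@snps, keptStart = 0L, keptEnd = 10L,
               discardedSnps = 0L, removed = character(0))
  expect_error(buildProbes(tEdge), "flank")
  expect_true(all(buildProbes(tEdge, allowTruncated = TRUE)$truncated))
})

test_that("primer specificity screening finds planted off-targets", {
  ref <- simulateReferenceWithLoci(4L, locusLen = 120L, seed = 31L,
                                   snpPlacement = "interior")
  panel <- simulatePanel(ref$loci, flank = 33L)
  e <- panel[[1]]
  src <- ref$loci[[locusId(e)]]
  target <- list(contig = src@contig, start = src@start,
                 end = src@start + nchar(src@sequence) - 1L)
  expect_equal(screenPrimerPair(e@primer, ref$genome, target)$status,
               "UNIQUE")

  ## duplicated locus copy -> off-target with coordinates
  ref2 <- simulateReferenceWithLoci(4L, locusLen = 120L, seed = 32L,
                                    duplicateFirst = TRUE,
                                    snpPlacement = "interior")
  panel2 <- simulatePanel(ref2$loci, flank = 33L)
  e2 <- panel2[[names(ref2$loci)[1]]]
  src2 <- ref2$loci[[1]]
  target2 <- list(contig = src2@contig, start = src2@start,
                  end = src2@start + nchar(src2@sequence) - 1L)
  sc <- screenPrimerPair(e2@primer, ref2$genome, target2)
  expect_equal(sc$status, "OFF_TARGET")
  expect_gt(nrow(sc$sites), 0)

  ## planted reverse-complement site is found with its strand recorded
  g3 <- ref$genome
  fwdRc <- revComp(e@primer@fwd)
  g3[["contig01"]] <- Biostrings::DNAString(
    paste0(as.character(g3[["contig01"]]), "TTTT", fwdRc))
  sc3 <- screenPrimerPair(e@primer, g3, target)
  expect_equal(sc3$status, "OFF_TARGET")
  expect_true("-" %in% sc3$sites$strand)

  ## primer found nowhere -> template/genome mismatch error
  alien <- new("PrimerPair", locusId = locusId(e),
               fwd = paste(rep("A", 25), collapse = ""),
               rev = paste(rep("C", 25), collapse = ""), rank = 1L,
               productStart = 0L, productEnd = 100L)
  expect_error(screenPrimerPair(alien, ref$genome, target), "mismatch")
})

test_that("candidate iteration returns the first specific pair", {
  ref <- simulateReferenceWithLoci(3L, locusLen = 130L, seed = 41L,
                                   snpPlacement = "interior")
  panel <- simulatePanel(ref$loci, flank = 33L)
  e <- panel[[1]]
  src <- ref$loci[[locusId(e)]]
  target <- list(contig = src@contig, start = src@start,
                 end = src@start + nchar(src@sequence) - 1L)
  t <- e@locus
  cand <- makeNaivePrimerCandidates(t, nCandidates = 3L)
  sel <- selectPrimerPair(cand, ref$genome, target)
  expect_equal(sel$pair@rank, 1L)

  ## plant an off-target for rank 1 only -> rank 2 wins
  g2 <- ref$genome
  g2[["contig01"]] <- Biostrings::DNAString(
    paste0(as.character(g2[["contig01"]]), "GGGG", cand[[1]]@fwd))
  sel2 <- selectPrimerPair(cand, g2, target)
  expect_equal(sel2$pair@rank, 2L)

  ## all candidates off-target -> REMOVED(no_specific_pair)
  g3 <- ref$genome
  extra <- paste(vapply(cand, function(p) p@fwd, character(1)),
                 collapse = "TT")
  g3[["contig01"]] <- Biostrings::DNAString(
    paste0(as.character(g3[["contig01"]]), "AA", extra))
  sel3 <- selectPrimerPair(cand, g3, target)
  expect_null(sel3$pair)
  expect_equal(sel3$removedReason, "no_specific_pair")

  expect_equal(selectPrimerPair(list(), ref$genome, target)$removedReason,
               "no_candidates")
})

test_that("probe construction conserves sequence context", {
  set.seed(55)
  for (rep in 1:25) {
    l <- randLocus(60L, sort(sample(12:47, sample(1:3, 1))))
    t <- trimSnpsForPrimers(l, flank = 12L)
    if (length(t@removed)) next
    pr <- buildProbes(t)
    for (q in seq_len(nrow(pr))) {
      o <- pr$snpOffset[q]
      tmplCh <- strsplit(t@sequence, "")[[1]]
      tmplCh[o + 1L] <- pr$allele[q]
      window <- paste(tmplCh[(o - 8L):(o + 8L) + 1L], collapse = "")
      ## the probe matches the allele-substituted template slice once
      ## IUPAC positions are expanded
      expect_true(grepl(paste0("^", gsub("([^ACGT])", ".", pr$probe[q]), "$"),
                        window))
    }
  }
})
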