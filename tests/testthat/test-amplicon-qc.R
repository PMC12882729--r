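test_that("read classification matches simulator truth exactly", {
  tp <- makeTestPanel(nLoci = 8L, nInd = 8L, seed = 61L)
  for (frac in c(0, 0.3)) {
    sim <- simulateAmpliconReads(tp$panel, tp$gm,
                                 ReadSimParams(meanDepth = 20,
                                               interactionFraction = frac,
                                               errorRate = 0, seed = 8L))
    rc <- classifyReads(sim$reads, tp$panel, returnLabels = TRUE)
    m <- merge(rc@labels, sim$truth, by = "read")
    expect_equal(mean(m$class.x == m$class.y), 1)
    isInt <- m$class.y == "interaction"
    if (any(isInt)) {
      expect_equal(m$locusI.x[isInt], m$locusI.y[isInt])
      expect_equal(m$locusJ.x[isInt], m$locusJ.y[isInt])
    }
    expect_equal(rc@proportionInteractions,
                 mean(sim$truth$class == "interaction"))
  }
})

test_that("constructed chimeras and degenerate pools classify correctly", {
  tp <- makeTestPanel(nLoci = 4L, seed = 62L)
  p <- tp$panel
  iLoc <- names(p)[1]; jLoc <- names(p)[2]
  set.seed(1)
  filler <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  read <- paste0(p[[iLoc]]@primer@fwd, filler, p[[jLoc]]@primer@rev)
  rc <- classifyReads(setNames(read, "x:000001"), p, returnLabels = TRUE)
  expect_equal(rc@labels$class, "interaction")
  expect_equal(rc@labels$locusI, iLoc)
  expect_equal(rc@labels$locusJ, jLoc)

  ## read with fwd primer but neither probe nor foreign primer -> unknown
  junk <- paste0(p[[iLoc]]@primer@fwd,
                 paste(rep("A", 100), collapse = ""))
  rcU <- classifyReads(setNames(junk, "x:000002"), p, returnLabels = TRUE)
  expect_equal(rcU@labels$class, "unknown")

  ## empty pool -> zero totals
  rc0 <- classifyReads(setNames(character(0), character(0)), p)
  expect_equal(rc0@total, 0L)
  expect_equal(rc0@proportionInteractions, 0)

  ## colliding forward primers are rejected
  pBad <- p
  pBad[[2]]@primer@fwd <- p[[1]]@primer@fwd
  expect_error(classifyReads(setNames(read, "r:000001"), pBad), "primer")
})

test_that("probe-based allele counting is exact on constructed pools", {
  tp <- makeTestPanel(nLoci = 4L, seed = 63L)
  loc <- names(tp$panel)[1]
  j <- match(loc, lociIds(tp$gm))
  gm1 <- tp$gm[1, ]
  ## force a homozygote for catalogue allele 1
  gm1@a1[1, j] <- 1L; gm1@a2[1, j] <- 1L
  sim <- simulateAmpliconReads(tp$panel[loc], gm1,
                               ReadSimParams(meanDepth = 30,
                                             interactionFraction = 0,
                                             errorRate = 0, seed = 4L))
  ac <- countAlleles(sim$reads, tp$panel[loc])
  hap <- alleleCatalog(gm1)[[j]][1]
  hc <- ac@hapCounts
  expect_equal(sum(hc$count[hc$allele == hap]), length(sim$reads))
  expect_equal(sum(hc$count[hc$allele != hap]), 0L)

  ## a mismatch inside the probe window increments nothing at that SNP
  e <- tp$panel[[loc]]
  off <- e@locus@snps$offset[1]
  read <- sim$reads[1]
  bad <- read
  ## corrupt a flank base inside the 17 nt window: not the SNP itself and
  ## not a neighbouring SNP position (those are IUPAC-tolerant)
  flankPos <- setdiff((off - 8L):(off + 8L), e@locus@snps$offset)
  pos <- flankPos[flankPos >= 0][3] + 1L      # read position, 1-based
  old <- substr(bad, pos, pos)
  substr(bad, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  acBad <- countAlleles(setNames(bad, "z:000001"), tp$panel[loc])
  expect_equal(sum(acBad@snpCounts$count[acBad@snpCounts$snpOffset == off]),
               0L)

  ## heterozygote at depth ~2000: both alleles within a binomial CI
  gmHet <- tp$gm[1, ]
  gmHet@a1[1, j] <- 1L; gmHet@a2[1, j] <- 2L
  simH <- simulateAmpliconReads(tp$panel[loc], gmHet,
                                ReadSimParams(meanDepth = 2000,
                                              dispersion = 1e6,
                                              interactionFraction = 0,
                                              errorRate = 0, seed = 5L))
  acH <- countAlleles(simH$reads, tp$panel[loc])
  hcH <- acH@hapCounts
  n <- sum(hcH$count)
  c1 <- sum(hcH$count[hcH$allele == alleleCatalog(gmHet)[[j]][1]])
  ci <- qbinom(c(0.0005, 0.9995), n, 0.5)
  expect_gte(c1, ci[1]); expect_lte(c1, ci[2])
})

test_that("the ML genotype caller follows the multinomial likelihood", {
  ## counts (20, 0) -> homozygote 1/1
  g <- mlGenotypeCall(c(20, 0), eps = 0.01)
  expect_equal(c(g$g1, g$g2), c(1L, 1L))
  ## counts (10, 10) -> heterozygote, and the direct likelihood agrees
  g2 <- mlGenotypeCall(c(10, 10), eps = 0.01)
  expect_equal(c(g2$g1, g2$g2), c(1L, 2L))
  llHet <- dmnLoglik(c(10, 10), 1, 2, 0.01)
  llHom <- max(dmnLoglik(c(10, 10), 1, 1, 0.01),
               dmnLoglik(c(10, 10), 2, 2, 0.01))
  expect_gt(llHet, llHom)
  expect_equal(g2$loglik, llHet, tolerance = 1e-12)
  ## scale consistency: x10 counts never changes the argmax
  set.seed(9)
  for (rep in 1:100) {
    k <- sample(2:4, 1)
    counts <- rpois(k, lambda = sample(1:30, k, TRUE))
    a <- mlGenotypeCall(counts, eps = 0.01)
    b <- mlGenotypeCall(counts * 10, eps = 0.01)
    expect_identical(c(a$g1, a$g2), c(b$g1, b$g2))
  }
  ## boundary derived from direct evaluation: for counts (c1, c2), the
  ## call flips hom->het exactly where the likelihoods cross
  for (c2 in 0:6) {
    counts <- c(40, c2)
    want <- which.max(c(dmnLoglik(counts, 1, 1, 0.01),
                        dmnLoglik(counts, 1, 2, 0.01)))
    got <- mlGenotypeCall(counts, eps = 0.01)
    expect_equal(got$g2, c(1L, 2L)[want])
  }
})

test_that("end-to-end genotyping from reads is accurate and gated by depth", {
  tp <- makeTestPanel(nLoci = 6L, nInd = 8L, seed = 64L)
  sim <- simulateAmpliconReads(tp$panel, tp$gm,
                               ReadSimParams(meanDepth = 40,
                                             interactionFraction = 0.1,
                                             errorRate = 0.001, seed = 6L))
  ac <- countAlleles(sim$reads, tp$panel)
  called <- callGenotypesMl(ac, tp$panel,
                            collections = setNames(collections(tp$gm),
                                                   individuals(tp$gm)))
  conc <- genotypeConcordance(tp$gm, called)
  expect_gt(conc$overall, 0.95)
  ## a very high depth gate empties the calls
  calledHi <- callGenotypesMl(ac, tp$panel, minDepth = 100000L)
  expect_true(all(is.na(calledHi@a1)))
})

test_that("concordance is exact on identity and corrupted copies", {
  tp <- makeTestPanel(nLoci = 10L, nInd = 20L, seed = 65L)
  gm <- tp$gm
  self <- genotypeConcordance(gm, gm)
  expect_equal(self$overall, 1)
  expect_true(all(self$perSnp$accuracy[self$perSnp$nCompared > 0] == 1))

  ## corrupt exactly 1 call in 20 per locus -> overall accuracy 95.0%
  gmBad <- gm
  for (j in seq_len(nLoci(gm))) {
    k <- length(alleleCatalog(gm)[[j]])
    i <- j %% nInd(gm) + 1L
    old <- gmBad@a1[i, j]
    gmBad@a1[i, j] <- gmBad@a2[i, j] <- (old %% k) + 1L
  }
  ## every corrupted call flips >= 1 SNP, so the per-SNP mean lies in
  ## [0.95, 1); single-SNP loci sit exactly at 95% (asserted separately
  ## in the concordance acceptance check)
  conc <- genotypeConcordance(gm, gmBad)
  expect_gte(conc$overall, 0.95 - 1e-9)
  expect_lt(conc$overall, 1)

  ## the 70% call-rate gate excludes sparse individuals
  gmGap <- gm
  gmGap@a1[1, 1:4] <- NA_integer_; gmGap@a2[1, 1:4] <- NA_integer_
  conc2 <- genotypeConcordance(gm, gmGap, minCallRate = 0.70)
  expect_false(individuals(gm)[1] %in% conc2$individualsUsed)
  expect_error(genotypeConcordance(gm[0, ], gm[0, ]), "shared")
})

test_that("representation flags react to skewed on-target shares", {
  mkRc <- function(onTarget) {
    new("ReadClassSummary", total = as.integer(sum(onTarget)),
        onTarget = onTarget,
        interactions = data.frame(locusI = character(0),
                                  locusJ = character(0),
                                  count = integer(0)),
        unknown = 0L, proportionInteractions = 0)
  }
  even <- setNames(rep(100L, 10), paste0("l", 1:10))
  fl <- flagRepresentation(mkRc(even))
  expect_length(fl$over, 0); expect_length(fl$under, 0)

  skew <- setNames(c(rep(10L, 99), 990L), paste0("l", 1:100))
  fl2 <- flagRepresentation(mkRc(skew))
  expect_equal(fl2$over, "l100")

  zero <- setNames(c(0L, rep(100L, 9)), paste0("l", 1:10))
  fl3 <- flagRepresentation(mkRc(zero))
  expect_equal(fl3$under, "l1")
})

test_that("removal recommendations cover interactions and duo tie-breaks", {
  mkRc <- function(ints, onTarget = setNames(rep(50L, 6), paste0("l", 1:6))) {
    new("ReadClassSummary",
        total = as.integer(sum(onTarget) + sum(ints$count)),
        onTarget = onTarget, interactions = ints, unknown = 0L,
        proportionInteractions = sum(ints$count) /
          (sum(onTarget) + sum(ints$count)))
  }
  ## one pair causing 97% of interactions -> that pair alone removed
  ints <- data.frame(locusI = c("l1", "l1", "l2"),
                     locusJ = c("l3", "l4", "l5"),
                     count = c(500L, 470L, 30L))
  rec <- recommendRemovals(mkRc(ints), representation = FALSE)
  expect_equal(rec$removals$locusId, "l1")
  expect_equal(rec$removals$reason, "interaction")

  ## duo: l1 and l2 interact only with each other; theta_l1 > theta_l2
  ## -> l2 removed, l1 kept
  duo <- data.frame(locusI = "l1", locusJ = "l2", count = 1000L)
  fst <- data.frame(locusId = c("l1", "l2"), theta = c(0.4, 0.1),
                    defined = TRUE)
  rec2 <- recommendRemovals(mkRc(duo), locusFst = fst,
                            representation = FALSE)
  expect_equal(rec2$removals$locusId, "l2")
  expect_false("l1" %in% rec2$removals$locusId)
  ## with theta unavailable the more-interacting member goes
  duo2 <- data.frame(locusI = c("l1", "l2"), locusJ = c("l2", "l3"),
                     count = c(900L, 300L))
  rec3 <- recommendRemovals(mkRc(duo2), representation = FALSE)
  expect_equal(rec3$removals$locusId[1], "l2")

  ## SNP accuracy: locus retained while any SNP passes
  snpAcc <- data.frame(locusId = c("l1", "l1", "l2"),
                       snpIndex = c(1L, 2L, 1L),
                       accuracy = c(0.85, 0.99, 0.70))
  rec4 <- recommendRemovals(mkRc(ints[0, ]), snpAccuracy = snpAcc,
                            representation = FALSE)
  expect_true("l2" %in% rec4$removals$locusId)
  expect_false("l1" %in% rec4$removals$locusId)
  expect_equal(nrow(rec4$snpRemovals), 2L)
  ## all-accurate loci never appear
  snpOk <- data.frame(locusId = "l6", snpIndex = 1L, accuracy = 0.99)
  rec5 <- recommendRemovals(mkRc(ints[0, ]), snpAccuracy = snpOk,
                            representation = FALSE)
  expect_equal(nrow(rec5$removals), 0L)
})

test_that("the stopping rule combines interactions and accuracy", {
  a1 <- assessRound(0.20, 0.983)
  expect_true(a1@stop)
  ## interactions at 35.5% with accuracy 95.3%: continue
  a2 <- assessRound(0.355, 0.953)
  expect_false(a2@stop)
  a3 <- assessRound(0.10, NA_real_)
  expect_false(a3@stop)
  expect_match(a3@reason, "accuracy unavailable")
  ## boundary: exactly one third is not below one third
  a4 <- assessRound(1 / 3, 0.99)
  expect_false(a4@stop)
})

test_that("sex assignment resolves diplotypes through the mapping", {
  calls <- matrix(c("AG/CT", "CT/CT", "-", "AG/AG"), 4, 1,
                  dimnames = list(paste0("i", 1:4), "HAM6"))
  gm <- gtFromCalls(calls, rep("2018", 4))
  mapping <- c("AG/CT" = "female", "CT/CT" = "male")
  sx <- assignSex(gm, "HAM6", mapping)
  expect_equal(unname(sx), c("female", "male", "UNRESOLVED", "UNRESOLVED"))
  expect_error(assignSex(gm, "HAM6", c(bad = "x")), "mapping")
  expect_error(assignSex(gm, "nope", mapping), "absent")

  ## simulated cohort labelled via the same mapping: 100% agreement
  set.seed(77)
  dip <- sample(names(mapping), 40, TRUE)
  gmC <- gtFromCalls(matrix(dip, 40, 1,
                            dimnames = list(paste0("s", 1:40), "HAM6")),
                     rep("2018", 40))
  sx2 <- assignSex(gmC, "HAM6", mapping)
  expect_equal(unname(sx2), unname(mapping[dip]))
})

test_that("projection restricts haplotypes to the panel's retained SNPs", {
  tp <- makeTestPanel(nLoci = 5L, seed = 66L)
  gmP <- projectGenotypes(tp$gmFull, tp$panel)
  for (nm in names(tp$panel)) {
    e <- tp$panel[[nm]]
    jF <- match(nm, lociIds(tp$gmFull)); jP <- match(nm, lociIds(gmP))
    orig <- e@locus@snps$origIndex
    fullHaps <- alleleCatalog(tp$gmFull)[[jF]]
    for (i in seq_len(nInd(gmP))) {
      a <- tp$gmFull@a1[i, jF]
      if (is.na(a)) { expect_true(is.na(gmP@a1[i, jP])); next }
      want <- paste(vapply(orig, function(s)
        substr(fullHaps[a], s, s), character(1)), collapse = "")
      got <- alleleCatalog(gmP)[[jP]][gmP@a1[i, jP]]
      gotOther <- alleleCatalog(gmP)[[jP]][gmP@a2[i, jP]]
      expect_true(want %in% c(got, gotOther))
    }
  }
})
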