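test_that("per-locus theta matches the fixed-difference and null toys", {
  ## fixed difference: pop1 all A/A (n=10), pop2 all C/C (n=10) -> theta 1
  pops <- list(matrix(1L, 10, 2), matrix(2L, 10, 2))
  gm <- gmFromPops(pops)
  fst <- perLocusTemporalFst(gm)
  expect_equal(fst$theta, 1)

  ## identical frequencies, large n -> |theta| < 0.02
  set.seed(21)
  n <- 500L
  mkPop <- function() matrix(sample.int(2L, 2 * n, TRUE), ncol = 2)
  gm2 <- gmFromPops(list(mkPop(), mkPop()))
  fst2 <- perLocusTemporalFst(gm2)
  expect_lt(abs(fst2$theta), 0.02)

  ## monomorphic locus is flagged undefined, never silently zero
  gm3 <- gmFromPops(list(matrix(1L, 8, 2), matrix(1L, 8, 2)), k = 2)
  fst3 <- perLocusTemporalFst(gm3)
  expect_false(fst3$defined)
  expect_true(is.na(fst3$theta))
})

test_that("theta matches an independent textbook implementation", {
  set.seed(31)
  for (rep in 1:120) {
    nPops <- sample(2:5, 1)
    k <- sample(2:4, 1)
    pops <- randomPops(nPops, k)
    if (length(unique(unlist(pops))) < 2) next
    gm <- gmFromPops(pops, k)
    got <- perLocusTemporalFst(gm)
    want <- wcThetaOracle(pops, k)
    if (is.na(got$theta)) {
      expect_true(abs(want$a + want$b + want$c) < 1e-12)
    } else {
      expect_equal(got$theta, want$theta, tolerance = 1e-12)
    }
  }
})

test_that("theta is invariant to allele relabelling and collection order", {
  set.seed(41)
  pops <- randomPops(3, 3)
  gm <- gmFromPops(pops, 3)
  base <- perLocusTemporalFst(gm)$theta
  ## relabel alleles 1<->3
  relab <- lapply(pops, function(g) matrix(c(3L, 2L, 1L)[g], ncol = 2))
  expect_equal(perLocusTemporalFst(gmFromPops(relab, 3))$theta, base,
               tolerance = 1e-12)
  ## permute individuals (collection order within the matrix)
  perm <- sample(nInd(gm))
  gmP <- gm[perm, ]
  expect_equal(perLocusTemporalFst(gmP)$theta, base, tolerance = 1e-12)
})

test_that("subset schemes draw top-theta plus seeded random complements", {
  set.seed(3)
  fst <- data.frame(locusId = sprintf("l%03d", 1:700),
                    theta = c(runif(650), rep(NA, 50)),
                    defined = c(rep(TRUE, 650), rep(FALSE, 50)))
  schemes <- list(list(name = "fst500", nTop = 500L, nRandom = 0L),
                  list(name = "rdm500", nTop = 0L, nRandom = 500L),
                  list(name = "fst250+rdm250", nTop = 250L, nRandom = 250L))
  subs <- buildSubsets(fst, schemes, seed = 9L)
  ## pure top scheme is exactly the 500 largest thetas
  ord <- fst$locusId[order(-fst$theta, fst$locusId)][1:500]
  expect_identical(subs$fst500, ord)
  ## undefined loci never selected
  expect_length(intersect(unlist(subs), fst$locusId[!fst$defined]), 0)
  ## random complement excludes the scheme's own top loci
  top250 <- fst$locusId[order(-fst$theta, fst$locusId)][1:250]
  mixed <- subs[["fst250+rdm250"]]
  expect_identical(mixed[1:250], top250)
  expect_length(intersect(mixed[251:500], top250), 0)
  ## reproducible under the same seed
  expect_identical(buildSubsets(fst, schemes, seed = 9L), subs)
  expect_error(buildSubsets(fst[1:100, ], schemes, seed = 1L), "available")
})

test_that("diversity statistics match closed forms on constructed loci", {
  set.seed(51)
  n <- 400L
  ## locus in HWE at p = 0.5 -> H_E ~ 0.5, F_IS ~ 0
  g1 <- replicate(n, paste(sort(sample(c("A", "C"), 2, TRUE)),
                           collapse = "/"))
  mono <- rep("G/G", n)
  calls <- cbind(l1 = g1, l2 = mono)
  rownames(calls) <- paste0("i", 1:n)
  gm <- gtFromCalls(calls, rep("1999", n))
  div <- diversityStats(gm, g = 20L, nBoot = 100L, seed = 1L)
  expect_equal(div$HE, mean(c(0.5, 0)), tolerance = 0.03)
  expect_lt(abs(div$FIS), 0.15)   # sampling SE of f at n=400 is ~0.05
  ## monomorphic locus: A_R = 1 at any g, excluded from F_IS
  expect_equal(div$polymorphic, 1L)
  gmMono <- gm[, "l2"]
  divM <- diversityStats(gmMono, g = 10L, nBoot = 0L)
  expect_equal(divM$AR, 1)
  expect_true(is.na(divM$FIS))

  ## exact rarefaction: counts (18, 2), g = 10 ->
  ## 2 - C(2,10)/C(20,10) - C(18,10)/C(20,10)
  expected <- (1 - choose(18, 10) / choose(20, 10)) + (1 - 0)
  expect_equal(rarefiedAlleleCount(c(18, 2), 10), expected,
               tolerance = 1e-12)
  expect_true(is.na(rarefiedAlleleCount(c(3, 2), 10)))
  ## bootstrap CIs contain the point estimate
  expect_true(div$HE_lo <= div$HE && div$HE <= div$HE_hi)
  expect_true(div$AR_lo <= div$AR && div$AR <= div$AR_hi)
})

test_that("pairwise theta behaves at the null and fixed-difference poles", {
  set.seed(61)
  ## one panmictic sample split at random -> theta ~ 0, p not extreme
  n <- 120L
  g <- replicate(n, paste(sort(sample(c("A", "C"), 2, TRUE,
                                      prob = c(0.6, 0.4))), collapse = "/"))
  calls <- matrix(g, n, 1, dimnames = list(paste0("i", 1:n), "l1"))
  gm <- gtFromCalls(calls, sample(rep(c("1999", "2018"), each = n / 2)))
  pw <- pairwiseFst(gm, nPerm = 300L, nBoot = 0L, seed = 2L)
  expect_lt(abs(pw$theta["1999", "2018"]), 0.03)
  expect_gt(pw$p["1999", "2018"], 0.01)

  ## fixed difference -> theta 1 and the smallest attainable p-value
  pops <- list(matrix(1L, 10, 2), matrix(2L, 10, 2))
  gmF <- gmFromPops(pops)
  pwF <- pairwiseFst(gmF, nPerm = 200L, nBoot = 50L, seed = 3L)
  expect_equal(pwF$theta["P1", "P2"], 1)
  expect_equal(pwF$p["P1", "P2"], 1 / 201)
})

test_that("temporal samples recover the one-lineage drift expectation", {
  ## two samples of one lineage t generations apart: E[theta] is half the
  ## two-branch divergence value, (1 - (1 - 1/(2Ne))^t) / 2
  Ne <- 100L; tg <- 10L; L <- 300L
  th <- vapply(1:6, function(seed) {
    dp <- DriftParams(nLoci = L, years = c(2000L, 2000L + tg),
                      sampleSizes = c(50L, 50L),
                      neSchedule = setNames(rep(Ne, tg + 1),
                                            2000:(2000 + tg)),
                      missingness = 0, seed = seed)
    gm <- simulateTemporalGenotypes(dp)$gm
    pairwiseFst(gm, nPerm = 0L, nBoot = 0L)$theta[1, 2]
  }, numeric(1))
  expected <- (1 - (1 - 1 / (2 * Ne))^tg) / 2
  se <- sd(th) / sqrt(length(th))
  expect_lt(abs(mean(th) - expected), 3 * se + 0.002)
})

test_that("DAPC separates structured groups and ignores unstructured ones", {
  set.seed(71)
  n <- 30L
  ## two groups from one distribution: reassignment near chance
  callsNull <- matrix(replicate(20 * 2 * n, paste(
    sort(sample(c("A", "C"), 2, TRUE)), collapse = "/")), 2 * n, 20)
  rownames(callsNull) <- paste0("i", seq_len(2 * n))
  colnames(callsNull) <- paste0("l", 1:20)
  gmNull <- gtFromCalls(callsNull, rep(c("1999", "2018"), each = n))
  dNull <- runDapc(gmNull, nPc = 3L, nDf = 1L, seed = 1L)
  expect_lt(dNull@assignProp, 0.9)

  ## fixed differences at 20 loci: full separation
  callsSep <- rbind(matrix("A/A", n, 20), matrix("C/C", n, 20))
  rownames(callsSep) <- paste0("i", seq_len(2 * n))
  colnames(callsSep) <- paste0("l", 1:20)
  ## one polymorphic filler column so PCA has >1 informative direction
  filler <- replicate(2 * n, paste(sort(sample(c("G", "T"), 2, TRUE)),
                                   collapse = "/"))
  callsSep <- cbind(callsSep, f1 = filler)
  gmSep <- gtFromCalls(callsSep, rep(c("1999", "2018"), each = n))
  dSep <- runDapc(gmSep, nPc = 2L, nDf = 1L, seed = 1L)
  expect_equal(dSep@assignProp, 1)
  expect_gt(abs(dSep@centroids["1999", 1] - dSep@centroids["2018", 1]), 1)

  ## permuting individual order leaves centroids unchanged
  perm <- sample(nInd(gmSep))
  dPerm <- runDapc(gmSep[perm, ], nPc = 2L, nDf = 1L, seed = 1L)
  expect_equal(abs(dPerm@centroids), abs(dSep@centroids), tolerance = 1e-9)

  ## a-score on unstructured data stays near zero
  dA <- runDapc(gmNull, nPc = "a-score", nDf = 1L, seed = 2L,
                aScorePerm = 5L)
  expect_lt(max(dA@aScoreTrace), 0.5)
})

test_that("subset comparison aligns centroid sets as configured", {
  mkRes <- function(centroids) {
    new("DapcResult", centroids = centroids,
        indCoords = centroids, varExplained = c(0.7, 0.3),
        nPc = 5L, assignProp = 1)
  }
  X <- matrix(c(0, 1, 0, -1, 0, 1, -1, 0), 4, 2,
              dimnames = list(paste0("Y", 1:4), NULL))
  complete <- mkRes(X)
  ## identity -> all d = 0
  sel <- compareSubsets(complete, list(same = mkRes(X)))
  expect_equal(max(sel@distances$d), 0, tolerance = 1e-12)
  expect_equal(sel@summary$meanD, 0, tolerance = 1e-12)

  ## 90-degree rotation: procrustes recovers it, raw does not
  R <- matrix(c(0, -1, 1, 0), 2, 2)
  Y <- X %*% R; rownames(Y) <- rownames(X)
  selP <- compareSubsets(complete, list(rot = mkRes(Y)),
                         alignment = "procrustes")
  expect_equal(selP@summary$meanD, 0, tolerance = 1e-9)
  selN <- compareSubsets(complete, list(rot = mkRes(Y)),
                         alignment = "none")
  expect_gt(selN@summary$meanD, 0.5)

  ## group mismatch is an error
  Z <- X; rownames(Z) <- paste0("Z", 1:4)
  expect_error(compareSubsets(complete, list(bad = mkRes(Z))), "mismatch")
})
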