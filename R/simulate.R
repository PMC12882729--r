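## Synthetic-data generators. The default DriftParams emulate the study
## conditions of the monitoring programme the toolkit targets: 12 temporal
## collections spanning 1999-2018 of a short-lived riverine minnow, with a
## multi-year population bottleneck in 2013-2014, microhaplotype loci of 2-4
## alleles and a few percent missing data. Locus count is scaled to 1,000
## (a workable stand-in for the genome-wide set; see the vignette).

#' Parameters for the temporal Wright-Fisher genotype simulator
#'
#' @slot nLoci number of microhaplotype loci.
#' @slot allelesPerLocusProbs sampling probabilities for 2/3/4 alleles per
#'   locus (named "2","3","4").
#' @slot dirichletAlpha concentration of the Dirichlet prior on initial
#'   allele frequencies.
#' @slot years,sampleSizes sampling years and per-year diploid sample sizes.
#' @slot neSchedule effective size per calendar year (named by year; allows
#'   a bottleneck).
#' @slot missingness i.i.d. per-genotype missing-call probability.
#' @slot generationsPerYear generations elapsing per calendar year.
#' @slot seed RNG seed.
#' @export
setClass("DriftParams",
  representation(nLoci = "integer", allelesPerLocusProbs = "numeric",
                 dirichletAlpha = "numeric", years = "integer",
                 sampleSizes = "integer", neSchedule = "integer",
                 missingness = "numeric", generationsPerYear = "integer",
                 seed = "integer"))

setValidity("DriftParams", function(object) {
  msg <- character(0)
  if (any(object@neSchedule < 1L)) msg <- c(msg, "Ne must be >= 1")
  if (length(object@years) != length(object@sampleSizes))
    msg <- c(msg, "years and sampleSizes must align")
  ne <- object@neSchedule[as.character(object@years)]
  if (any(!is.na(ne) & object@sampleSizes > 2L * ne))
    msg <- c(msg, "sample size must be <= 2*Ne in every sampled year")
  if (object@missingness < 0 || object@missingness > 1)
    msg <- c(msg, "missingness must lie in [0,1]")
  if (!identical(names(object@allelesPerLocusProbs), c("2", "3", "4")))
    msg <- c(msg, "allelesPerLocusProbs must be named 2,3,4")
  if (length(msg)) msg else TRUE
})

#' Construct DriftParams
#'
#' Defaults reproduce the monitored study system: 2,983 microhaplotype
#' loci genotyped in 12 collections (1999-2018, the monitoring years) of
#' 27-42 individuals each, one generation per year (a short-lived
#' species), 3\% missing data, and an Ne schedule (baseline 1,500 with a
#' bottleneck to 250 in 2013-2014) calibrated so that pairwise temporal
#' F_ST falls in the observed ~0.001-0.007 range (see the vignette).
#'
#' @param nLoci,allelesPerLocusProbs,dirichletAlpha,years,sampleSizes
#'   see slots.
#' @param neSchedule named integer vector year -> Ne; default fills
#'   1999-2018 at \code{neBaseline} with \code{neBottleneck} in 2013-2014.
#' @param neBaseline,neBottleneck used to build the default schedule.
#' @param missingness,generationsPerYear,seed see slots.
#' @return A \linkS4class{DriftParams}.
#' @export
DriftParams <- function(nLoci = 2983L,
                        allelesPerLocusProbs = c("2" = 0.6, "3" = 0.3, "4" = 0.1),
                        dirichletAlpha = 1,
                        years = c(1999L, 2000L, 2002L, 2004L, 2006L, 2008L,
                                  2009L, 2010L, 2012L, 2015L, 2017L, 2018L),
                        sampleSizes = c(30L, 42L, 30L, 27L, 30L, 30L, 30L,
                                        29L, 30L, 31L, 30L, 40L),
                        neSchedule = NULL, neBaseline = 1500L,
                        neBottleneck = 250L, missingness = 0.03,
                        generationsPerYear = 1L, seed = 1L) {
  if (is.null(neSchedule)) {
    yrs <- seq(min(years), max(years))
    neSchedule <- setNames(rep(as.integer(neBaseline), length(yrs)), yrs)
    neSchedule[as.character(intersect(c(2013L, 2014L), yrs))] <-
      as.integer(neBottleneck)
  }
  new("DriftParams", nLoci = as.integer(nLoci),
      allelesPerLocusProbs = allelesPerLocusProbs,
      dirichletAlpha = dirichletAlpha, years = as.integer(years),
      sampleSizes = as.integer(sampleSizes),
      neSchedule = setNames(as.integer(neSchedule), names(neSchedule)),
      missingness = missingness,
      generationsPerYear = as.integer(generationsPerYear),
      seed = as.integer(seed))
}

## Haplotype-string catalogues: a locus with k alleles is built on
## ceiling(log2(k)) SNP sites; alleles are distinct base combinations.
makeHaplotypeCatalog <- function(k) {
  s <- max(1L, ceiling(log2(k)))
  repeat {
    siteBases <- replicate(s, sample(DNA_BASES, 2L), simplify = FALSE)
    combos <- do.call(expand.grid,
                      c(siteBases, list(stringsAsFactors = FALSE)))
    haps <- apply(combos, 1, paste, collapse = "")
    if (length(unique(haps)) >= k) break
  }
  sample(unique(haps), k)
}

#' Simulate a temporal microhaplotype genotype series
#'
#' Allele frequencies follow multinomial Wright-Fisher updates (frequency
#' resampling with 2*Ne gene copies per generation); at each sampling year,
#' diploid genotypes are drawn under Hardy-Weinberg proportions at that
#' year's frequencies and missing calls are applied i.i.d.
#'
#' @param p a \linkS4class{DriftParams}.
#' @param initialFreqs optional list of per-locus allele-frequency vectors
#'   to start from (e.g. the truth of a previous run, to drift replicate
#'   populations from one ancestral state); drawn from the Dirichlet prior
#'   when NULL.
#' @param catalog optional named list of haplotype catalogues to reuse
#'   (required with \code{initialFreqs}).
#' @return List with \code{gm} (a \linkS4class{GenotypeMatrix};
#'   individuals named \code{Y<year>_<i>}) and \code{truth}: the per-year
#'   true allele-frequency list (per locus) plus the initial frequencies.
#' @export
simulateTemporalGenotypes <- function(p, initialFreqs = NULL,
                                      catalog = NULL) {
  validObject(p)
  set.seed(p@seed)
  L <- p@nLoci
  if (is.null(catalog)) {
    kPerLocus <- sample(c(2L, 3L, 4L), L, replace = TRUE,
                        prob = p@allelesPerLocusProbs)
    catalog <- lapply(kPerLocus, makeHaplotypeCatalog)
    names(catalog) <- sprintf("loc%04d", seq_len(L))
  } else {
    stopifnot(length(catalog) == L)
    kPerLocus <- lengths(catalog)
  }
  loci <- names(catalog)
  freq <- if (is.null(initialFreqs)) {
    lapply(kPerLocus, function(k) {
      g <- rgamma(k, shape = p@dirichletAlpha)
      g / sum(g)
    })
  } else {
    stopifnot(length(initialFreqs) == L)
    unname(initialFreqs)
  }
  ## the drift span follows the Ne schedule, so a population can drift
  ## for generations before (or without) being sampled
  years <- seq(min(c(p@years, as.integer(names(p@neSchedule)))),
               max(p@years))
  sampled <- list()
  for (y in years) {
    if (y %in% p@years)
      sampled[[as.character(y)]] <- freq
    ne <- unname(p@neSchedule[as.character(y)])
    if (is.na(ne))
      stop("neSchedule has no entry for year ", y)
    if (y < max(years)) {
      for (g in seq_len(p@generationsPerYear)) {
        freq <- lapply(freq, function(f)
          as.vector(rmultinom(1, 2L * ne, f)) / (2 * ne))
      }
    }
  }
  nTot <- sum(p@sampleSizes)
  a1 <- a2 <- matrix(NA_integer_, nTot, L)
  inds <- character(nTot); coll <- character(nTot)
  row <- 0L
  for (i in seq_along(p@years)) {
    y <- p@years[i]; n <- p@sampleSizes[i]
    fy <- sampled[[as.character(y)]]
    idx <- row + seq_len(n)
    inds[idx] <- sprintf("Y%d_%02d", y, seq_len(n))
    coll[idx] <- as.character(y)
    for (j in seq_len(L)) {
      gam <- sample.int(kPerLocus[j], 2L * n, replace = TRUE, prob = fy[[j]])
      a1[idx, j] <- gam[seq_len(n)]
      a2[idx, j] <- gam[n + seq_len(n)]
    }
    row <- row + n
  }
  if (p@missingness > 0) {
    drop <- matrix(runif(nTot * L) < p@missingness, nTot, L)
    a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  }
  gm <- GenotypeMatrix(a1, a2, catalog, coll, individuals = inds, loci = loci)
  truth <- lapply(sampled, function(fy) setNames(fy, loci))
  list(gm = gm, truth = truth)
}

#' Simulate a reference genome with embedded loci
#'
#' Builds a random genome and embeds locus sequences at known,
#' non-overlapping coordinates; SNP sites are placed within each locus
#' (alleles taken from \code{catalog} when given, so genotypes and
#' reference agree). Optionally inserts a duplicate copy of the first locus
#' to create a known off-target site for primer-specificity tests.
#'
#' @param nLoci number of loci to embed.
#' @param locusLen locus length (bp).
#' @param genomeLen total genome length; must fit all (possibly duplicated)
#'   loci.
#' @param seed RNG seed.
#' @param catalog optional named list of haplotype catalogues (as in a
#'   \linkS4class{GenotypeMatrix}); SNP counts/alleles follow it.
#' @param duplicateFirst insert a second copy of locus 1.
#' @param nContigs number of contigs to spread loci over.
#' @param snpPlacement "spread" places SNPs uniformly over the locus
#'   (exercises trimming); "interior" keeps them >= 40 bp from both ends.
#' @return List with \code{genome} (DNAStringSet) and \code{loci}
#'   (list of \linkS4class{MicrohapLocus} anchored on the genome).
#' @export
simulateReferenceWithLoci <- function(nLoci, locusLen = 150L,
                                      genomeLen = NULL, seed = 1L,
                                      catalog = NULL, duplicateFirst = FALSE,
                                      nContigs = 1L,
                                      snpPlacement = c("spread", "interior")) {
  snpPlacement <- match.arg(snpPlacement)
  set.seed(seed)
  nEmbed <- nLoci + as.integer(duplicateFirst)
  if (is.null(genomeLen)) genomeLen <- nEmbed * locusLen * 3L
  if (genomeLen < nEmbed * locusLen)
    stop("genome too short to embed ", nEmbed, " loci of ", locusLen, " bp")
  contigLen <- rep(genomeLen %/% nContigs, nContigs)
  contigLen[1] <- contigLen[1] + genomeLen %% nContigs
  contigs <- lapply(contigLen, function(l)
    sample(DNA_BASES, l, replace = TRUE))
  names(contigs) <- sprintf("contig%02d", seq_len(nContigs))
  perContig <- ceiling(nEmbed / nContigs)
  slots <- do.call(rbind, lapply(seq_len(nContigs), function(ci) {
    gap <- (contigLen[ci] - perContig * locusLen) %/% (perContig + 1L)
    if (gap < 0) stop("contigs too short for the requested loci")
    st <- gap + (seq_len(perContig) - 1L) * (locusLen + gap) + 1L
    data.frame(contig = names(contigs)[ci], start = st)
  }))[seq_len(nEmbed), ]
  loci <- vector("list", nLoci)
  ids <- if (!is.null(catalog)) names(catalog)[seq_len(nLoci)]
         else sprintf("loc%04d", seq_len(nLoci))
  seqs <- character(nLoci)
  for (j in seq_len(nLoci)) {
    if (!is.null(catalog)) {
      haps <- catalog[[j]]
      s <- nchar(haps[1])
      siteAlleles <- lapply(seq_len(s), function(i)
        sort(unique(substr(haps, i, i))))
    } else {
      s <- sample(1:2, 1)
      siteAlleles <- replicate(s, sort(sample(DNA_BASES, 2L)),
                               simplify = FALSE)
    }
    lo <- if (snpPlacement == "interior") 41L else 1L
    hi <- if (snpPlacement == "interior") locusLen - 40L else locusLen
    if (hi - lo + 1L < s) stop("locus too short for its SNPs")
    off <- sort(sample(seq(lo, hi), s))
    sq <- sample(DNA_BASES, locusLen, replace = TRUE)
    for (i in seq_len(s)) sq[off[i]] <- siteAlleles[[i]][1]
    seqs[j] <- paste(sq, collapse = "")
    loci[[j]] <- MicrohapLocus(ids[j], seqs[j], snpOffsets = off - 1L,
                               snpAlleles = siteAlleles,
                               contig = slots$contig[j],
                               start = slots$start[j])
  }
  embed <- function(contig, start, sq) {
    contigs[[contig]][seq(start, start + nchar(sq) - 1L)] <<-
      strsplit(sq, "")[[1]]
  }
  for (j in seq_len(nLoci))
    embed(slots$contig[j], slots$start[j], seqs[j])
  if (duplicateFirst)
    embed(slots$contig[nEmbed], slots$start[nEmbed], seqs[1])
  genome <- Biostrings::DNAStringSet(vapply(contigs, paste, character(1),
                                            collapse = ""))
  names(loci) <- ids
  list(genome = genome, loci = loci)
}

#' Parameters for the amplicon read simulator
#'
#' @slot meanDepth,dispersion negative-binomial per-locus per-individual
#'   depth (dispersion = NB size parameter).
#' @slot errorRate per-base substitution error rate applied downstream of
#'   the forward primer (the primer bases themselves are copied from the
#'   primer oligo and are error-free in this model).
#' @slot interactionFraction proportion of reads that are chimeric primer
#'   products.
#' @slot chimeraWeights optional named per-locus weights for how often a
#'   pair drives chimeras (uniform when empty).
#' @slot readLen read length (150 bp single-end by default).
#' @slot seed RNG seed.
#' @export
setClass("ReadSimParams",
  representation(meanDepth = "numeric", dispersion = "numeric",
                 errorRate = "numeric", interactionFraction = "numeric",
                 chimeraWeights = "numeric", readLen = "integer",
                 seed = "integer"),
  prototype(chimeraWeights = numeric(0)))

setValidity("ReadSimParams", function(object) {
  msg <- character(0)
  if (object@meanDepth <= 0) msg <- c(msg, "depth mean must be > 0")
  if (object@interactionFraction < 0 || object@interactionFraction > 1)
    msg <- c(msg, "interactionFraction must lie in [0,1]")
  if (object@errorRate < 0 || object@errorRate > 1)
    msg <- c(msg, "errorRate must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Construct ReadSimParams
#' @param meanDepth,dispersion,errorRate,interactionFraction,chimeraWeights,readLen,seed
#'   see slots.
#' @return A \linkS4class{ReadSimParams}.
#' @export
ReadSimParams <- function(meanDepth = 60, dispersion = 5, errorRate = 0.001,
                          interactionFraction = 0, chimeraWeights = numeric(0),
                          readLen = 150L, seed = 1L) {
  new("ReadSimParams", meanDepth = meanDepth, dispersion = dispersion,
      errorRate = errorRate, interactionFraction = interactionFraction,
      chimeraWeights = chimeraWeights, readLen = as.integer(readLen),
      seed = as.integer(seed))
}

applyBaseErrors <- function(seqChars, from, rate) {
  ## seqChars: character vector of single bases; positions >= from eligible
  if (rate <= 0) return(seqChars)
  n <- length(seqChars)
  if (from > n) return(seqChars)
  idx <- which(runif(n - from + 1L) < rate) + from - 1L
  for (i in idx) {
    seqChars[i] <- sample(setdiff(DNA_BASES, seqChars[i]), 1L)
  }
  seqChars
}

#' Simulate a multiplexed amplicon read pool
#'
#' On-target reads are the forward primer followed by the locus template
#' carrying one of the individual's two haplotype alleles (substitution
#' errors downstream of the primer at \code{errorRate}); interaction reads
#' are the forward primer of pair i followed by filler sequence containing
#' one primer (fwd, rev or a reverse complement) of another pair j. Every
#' read's true class is recorded.
#'
#' @param panel list of \linkS4class{PanelEntry} (all with primers and
#'   probes).
#' @param gm a \linkS4class{GenotypeMatrix} covering the panel loci (extra
#'   loci ignored); individuals lacking a locus call contribute no on-target
#'   reads there.
#' @param rp a \linkS4class{ReadSimParams}.
#' @param fastq optional path; when given, reads are written as
#'   Phred+33 FASTQ (constant Q30).
#' @return List with \code{reads} (named character vector; names
#'   \code{<individual>:<serial>}), \code{truth} (data.frame read,
#'   individual, class, locusI, locusJ) and \code{fastq} (path or NULL).
#' @export
simulateAmpliconReads <- function(panel, gm, rp = ReadSimParams(),
                                  fastq = NULL) {
  validObject(rp)
  set.seed(rp@seed)
  lociP <- unname(vapply(panel, locusId, character(1)))
  stopifnot(all(lociP %in% lociIds(gm)))
  gmIdx <- match(lociP, lociIds(gm))
  nP <- length(panel)
  inds <- individuals(gm)
  w <- if (length(rp@chimeraWeights)) rp@chimeraWeights[lociP] else
    setNames(rep(1, nP), lociP)
  w[is.na(w)] <- 0
  fwdLen <- vapply(panel, function(e) nchar(e@primer@fwd), integer(1))
  primerPool <- lapply(panel, function(e)
    c(e@primer@fwd, e@primer@rev, revComp(e@primer@fwd), revComp(e@primer@rev)))
  ## haplotype-substituted template per (panel locus, catalogue allele)
  hapTemplate <- lapply(seq_len(nP), function(jj) {
    e <- panel[[jj]]
    tmpl0 <- strsplit(e@locus@sequence, "")[[1]]
    offs <- e@locus@snps$offset
    ## retained SNPs may be a subset of the haplotype's sites: take each
    ## SNP's character from its position in the original haplotype string
    ## (projected catalogues already index 1..s)
    hapLen <- nchar(gm@alleles[[gmIdx[jj]]][1])
    orig <- if (hapLen > length(offs))
      e@locus@snps$origIndex %||% seq_along(offs)
    else seq_along(offs)
    unname(vapply(gm@alleles[[gmIdx[jj]]], function(hap) {
      tm <- tmpl0
      for (s in seq_along(offs))
        tm[offs[s] + 1L] <- substr(hap, orig[s], orig[s])
      paste(tm, collapse = "")
    }, character(1)))
  })
  padTo <- function(x, len) {
    ## pad with random bases / truncate to the read length
    short <- nchar(x) < len
    if (any(short))
      x[short] <- paste0(x[short], vapply(len - nchar(x[short]), function(k)
        paste(sample(DNA_BASES, k, replace = TRUE), collapse = ""),
        character(1)))
    substr(x, 1L, len)
  }
  readChunks <- list(); truthChunks <- list(); chunk <- 0L
  serial <- 0L
  for (ii in seq_along(inds)) {
    depths <- rnbinom(nP, size = rp@dispersion, mu = rp@meanDepth)
    for (jj in seq_len(nP)) {
      d <- depths[jj]
      if (d == 0L) next
      g1 <- gm@a1[ii, gmIdx[jj]]; g2 <- gm@a2[ii, gmIdx[jj]]
      nCh <- rbinom(1L, d, rp@interactionFraction)
      nOn <- d - nCh
      if (nOn > 0L && !is.na(g1)) {
        whichHap <- sample(c(g1, g2), nOn, replace = TRUE)
        reads <- hapTemplate[[jj]][whichHap]
        if (rp@errorRate > 0)
          reads <- vapply(reads, function(r) {
            ch <- applyBaseErrors(strsplit(r, "")[[1]], fwdLen[jj] + 1L,
                                  rp@errorRate)
            paste(ch, collapse = "")
          }, character(1), USE.NAMES = FALSE)
        reads <- padTo(reads, rp@readLen)
        nms <- sprintf("%s:%06d", inds[ii], serial + seq_len(nOn))
        serial <- serial + nOn
        chunk <- chunk + 1L
        readChunks[[chunk]] <- setNames(reads, nms)
        truthChunks[[chunk]] <- data.frame(
          read = nms, individual = inds[ii], class = "on_target",
          locusI = lociP[jj], locusJ = NA_character_,
          stringsAsFactors = FALSE)
      }
      if (nCh > 0L) {
        wOther <- w; wOther[jj] <- 0
        if (sum(wOther) == 0) { wOther[] <- 1; wOther[jj] <- 0 }
        js <- sample.int(nP, nCh, replace = TRUE, prob = wOther)
        reads <- vapply(seq_len(nCh), function(rr) {
          pj <- sample(primerPool[[js[rr]]], 1L)
          gap <- sample(2:20, 1L)
          paste0(panel[[jj]]@primer@fwd,
                 paste(sample(DNA_BASES, gap, replace = TRUE), collapse = ""),
                 pj)
        }, character(1))
        reads <- padTo(reads, rp@readLen)
        nms <- sprintf("%s:%06d", inds[ii], serial + seq_len(nCh))
        serial <- serial + nCh
        chunk <- chunk + 1L
        readChunks[[chunk]] <- setNames(reads, nms)
        truthChunks[[chunk]] <- data.frame(
          read = nms, individual = inds[ii], class = "interaction",
          locusI = lociP[jj], locusJ = lociP[js], stringsAsFactors = FALSE)
      }
    }
  }
  readsAll <- unlist(readChunks)
  if (is.null(readsAll)) readsAll <- setNames(character(0), character(0))
  truthDf <- if (length(truthChunks)) do.call(rbind, truthChunks)
    else data.frame(read = character(0), individual = character(0),
                    class = character(0), locusI = character(0),
                    locusJ = character(0))
  if (!is.null(fastq)) {
    dna <- Biostrings::DNAStringSet(readsAll)
    qual <- Biostrings::BStringSet(vapply(nchar(readsAll), function(l)
      paste(rep("?", l), collapse = ""), character(1)))
    Biostrings::writeXStringSet(dna, fastq, format = "fastq",
                                qualities = qual)
  }
  list(reads = readsAll, truth = truthDf, fastq = fastq)
}

#' Build an assay-ready panel from simulated loci
#'
#' Fixture plumbing for end-to-end simulation: trims each locus for primer
#' compatibility, gates template length, builds probes and attaches naive
#' rank-1 primer candidates (see
#' \code{\link{makeNaivePrimerCandidates}}). Loci removed by trimming or
#' the length gate are skipped.
#'
#' @param loci list of \linkS4class{MicrohapLocus}.
#' @param flank trimming flank (default 33).
#' @param maxTemplate template length gate (default 150).
#' @param primerLen naive primer length (default 20).
#' @return Named list of \linkS4class{PanelEntry}.
#' @export
simulatePanel <- function(loci, flank = 33L, maxTemplate = 150L,
                          primerLen = 20L) {
  out <- list()
  for (l in loci) {
    t <- trimSnpsForPrimers(l, flank)
    t <- filterTemplateLength(t, maxTemplate)
    if (length(t@removed)) next
    if (nchar(t@sequence) < 2L * primerLen) next
    cand <- makeNaivePrimerCandidates(t, nCandidates = 1L,
                                      primerLen = primerLen)
    probes <- buildProbes(t)
    out[[t@locusId]] <- PanelEntry(t, cand[[1]], probes)
  }
  out
}
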