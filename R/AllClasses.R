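## S4 classes for the panel-design workflow. Coordinates are 0-based
## half-open everywhere inside the package; 1-based only at VCF/report
## boundaries.

#' MicrohapLocus: a reference-anchored locus with its SNP sites
#'
#' A short sequence (typically a reduced-representation locus) carrying one
#' or more SNPs whose phased combinations form microhaplotype alleles.
#'
#' @slot locusId single identifier.
#' @slot sequence uppercase nucleotide string.
#' @slot snps data.frame with columns \code{offset} (0-based position within
#'   \code{sequence}) and \code{alleles} (list column of single-base allele
#'   vectors, each including the base present in \code{sequence}).
#' @slot contig,start optional anchor on a reference (1-based start;
#'   \code{NA} when unanchored).
#' @slot meanDepth mean sequencing depth observed for the locus.
#' @export
setClass("MicrohapLocus",
  representation(locusId = "character", sequence = "character",
                 snps = "data.frame", contig = "character",
                 start = "integer", meanDepth = "numeric"),
  prototype(contig = NA_character_, start = NA_integer_,
            meanDepth = NA_real_))

setValidity("MicrohapLocus", function(object) {
  msg <- character(0)
  if (length(object@locusId) != 1L || !nzchar(object@locusId))
    msg <- c(msg, "locusId must be a single non-empty string")
  if (length(object@sequence) != 1L || !nzchar(object@sequence))
    msg <- c(msg, "sequence must be non-empty")
  if (!all(c("offset", "alleles") %in% names(object@snps)))
    msg <- c(msg, "snps must have columns offset, alleles")
  else if (nrow(object@snps)) {
    off <- object@snps$offset
    if (any(off < 0L) || any(off >= nchar(object@sequence)))
      msg <- c(msg, "SNP offsets must lie within the sequence")
    if (is.unsorted(off, strictly = TRUE))
      msg <- c(msg, "SNP offsets must be strictly increasing")
    for (i in seq_len(nrow(object@snps))) {
      al <- object@snps$alleles[[i]]
      if (length(al) < 2L || anyDuplicated(al) || !all(al %in% DNA_BASES))
        msg <- c(msg, sprintf("SNP at offset %d needs >=2 unique A/C/G/T alleles",
                              off[i]))
      ref <- substr(object@sequence, off[i] + 1L, off[i] + 1L)
      if (!ref %in% al)
        msg <- c(msg, sprintf("alleles at offset %d must include the reference base %s",
                              off[i], ref))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MicrohapLocus
#'
#' @param locusId identifier.
#' @param sequence nucleotide string (case-normalized to uppercase).
#' @param snpOffsets integer vector of 0-based SNP positions.
#' @param snpAlleles list of character vectors, one per SNP.
#' @param contig,start optional reference anchor (1-based start).
#' @param meanDepth optional mean depth of coverage.
#' @return A \linkS4class{MicrohapLocus}.
#' @export
MicrohapLocus <- function(locusId, sequence, snpOffsets = integer(0),
                          snpAlleles = list(), contig = NA_character_,
                          start = NA_integer_, meanDepth = NA_real_) {
  snps <- data.frame(offset = as.integer(snpOffsets))
  snps$alleles <- lapply(snpAlleles, function(a) sort(toupper(a)))
  new("MicrohapLocus", locusId = as.character(locusId),
      sequence = toupper(sequence), snps = snps,
      contig = as.character(contig), start = as.integer(start),
      meanDepth = as.numeric(meanDepth))
}

#' TrimmedLocus: a locus after SNP-position trimming
#'
#' Result of \code{\link{trimSnpsForPrimers}}: the kept interval of the
#' original sequence with retained SNP offsets re-based to it, or a removal
#' marker when no SNP survives.
#'
#' @slot locusId identifier.
#' @slot sequence trimmed sequence ("" when removed).
#' @slot snps retained SNPs (offsets relative to the trimmed sequence).
#' @slot keptStart,keptEnd kept interval on the original sequence, 0-based
#'   half-open.
#' @slot discardedSnps number of SNPs discarded by trimming.
#' @slot removed zero-length when the locus is kept, otherwise the reason.
#' @export
setClass("TrimmedLocus",
  representation(locusId = "character", sequence = "character",
                 snps = "data.frame", keptStart = "integer",
                 keptEnd = "integer", discardedSnps = "integer",
                 removed = "character"),
  prototype(removed = character(0)))

setValidity("TrimmedLocus", function(object) {
  if (length(object@removed)) return(TRUE)
  if (object@keptStart < 0L || object@keptEnd < object@keptStart)
    return("kept interval out of bounds")
  if (nchar(object@sequence) != object@keptEnd - object@keptStart)
    return("sequence length inconsistent with kept interval")
  TRUE
})

#' PrimerPair: a ranked candidate primer pair for one locus
#'
#' @slot locusId target locus.
#' @slot fwd,rev primer sequences (5'->3'; \code{rev} anneals to the plus
#'   strand as its reverse complement).
#' @slot rank candidate order from the primer designer (1 = best).
#' @slot productStart,productEnd amplicon interval on the locus template,
#'   0-based half-open.
#' @export
setClass("PrimerPair",
  representation(locusId = "character", fwd = "character", rev = "character",
                 rank = "integer", productStart = "integer",
                 productEnd = "integer"))

setValidity("PrimerPair", function(object) {
  msg <- character(0)
  if (!nzchar(object@fwd) || !nzchar(object@rev))
    msg <- c(msg, "primer sequences must be non-empty")
  if (is.na(object@rank) || object@rank < 1L)
    msg <- c(msg, "rank must be >= 1")
  if (object@productEnd <= object@productStart)
    msg <- c(msg, "product interval must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Construct a PrimerPair
#'
#' With \code{strict = TRUE} (default) the standard multiplex design window
#' is enforced: primer lengths 18-25 bp and product size 100-150 bp.
#'
#' @param locusId,fwd,rev,rank,productStart,productEnd see slots.
#' @param strict enforce the design-window invariants.
#' @return A \linkS4class{PrimerPair}.
#' @export
PrimerPair <- function(locusId, fwd, rev, rank = 1L, productStart = 0L,
                       productEnd = NA_integer_, strict = TRUE) {
  fwd <- toupper(fwd); rev <- toupper(rev)
  if (is.na(productEnd)) productEnd <- productStart + 1L
  if (strict) {
    if (nchar(fwd) < 18L || nchar(fwd) > 25L ||
        nchar(rev) < 18L || nchar(rev) > 25L)
      stop("primer lengths must be between 18 and 25 bp")
    plen <- productEnd - productStart
    if (plen < 100L || plen > 150L)
      stop("product length must be between 100 and 150 bp")
  }
  new("PrimerPair", locusId = as.character(locusId), fwd = fwd, rev = rev,
      rank = as.integer(rank), productStart = as.integer(productStart),
      productEnd = as.integer(productEnd))
}

#' PanelEntry: a locus ready for assay
#'
#' Bundles a trimmed locus, its selected primer pair and per-SNP allele
#' probes, plus status flags used by the optimization loop.
#'
#' @slot locus a \linkS4class{TrimmedLocus}.
#' @slot primer a \linkS4class{PrimerPair}.
#' @slot probes data.frame with columns \code{locusId}, \code{snpOffset},
#'   \code{allele}, \code{probe}, \code{truncated}.
#' @slot active is the entry currently in the multiplex.
#' @slot removedReason reason when \code{active} is FALSE ("" otherwise).
#' @export
setClass("PanelEntry",
  representation(locus = "TrimmedLocus", primer = "PrimerPair",
                 probes = "data.frame", active = "logical",
                 removedReason = "character"),
  prototype(active = TRUE, removedReason = ""))

setValidity("PanelEntry", function(object) {
  if (length(object@locus@removed))
    return("cannot build a PanelEntry from a removed locus")
  if (object@locus@locusId != object@primer@locusId)
    return("locus and primer ids disagree")
  TRUE
})

#' Construct a PanelEntry
#' @param locus a \linkS4class{TrimmedLocus} (kept, not removed).
#' @param primer a \linkS4class{PrimerPair}.
#' @param probes probe table from \code{\link{buildProbes}}.
#' @return A \linkS4class{PanelEntry}.
#' @export
PanelEntry <- function(locus, primer, probes) {
  new("PanelEntry", locus = locus, primer = primer, probes = probes)
}

#' GenotypeMatrix: individuals x loci microhaplotype calls
#'
#' Diploid, unordered calls stored as two integer allele-index matrices;
#' \code{NA} in both marks a missing call. Each locus has an allele
#' catalogue of haplotype strings of equal length (single-SNP loci have
#' single-base alleles).
#'
#' @slot individuals ordered individual ids.
#' @slot collections per-individual collection (year) label.
#' @slot loci ordered locus ids.
#' @slot alleles named list (by locus) of haplotype-string catalogues.
#' @slot a1,a2 integer matrices (individuals x loci) of allele indices into
#'   the locus catalogue, normalized so a1 <= a2; NA = missing.
#' @export
setClass("GenotypeMatrix",
  representation(individuals = "character", collections = "character",
                 loci = "character", alleles = "list",
                 a1 = "matrix", a2 = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character(0)
  n <- length(object@individuals); L <- length(object@loci)
  if (length(object@collections) != n)
    msg <- c(msg, "collections must have one label per individual")
  if (any(is.na(object@collections)) || any(!nzchar(object@collections)))
    msg <- c(msg, "every individual needs a collection label")
  if (!identical(dim(object@a1), c(n, L)) ||
      !identical(dim(object@a2), c(n, L)))
    msg <- c(msg, "call matrices must be individuals x loci")
  if (!identical(names(object@alleles), object@loci))
    msg <- c(msg, "allele catalogue must be named by loci, in order")
  if (L && n) {
    for (j in seq_len(L)) {
      k <- length(object@alleles[[j]])
      cal <- c(object@a1[, j], object@a2[, j])
      if (any(!is.na(cal) & (cal < 1L | cal > k)))
        msg <- c(msg, sprintf("allele index out of catalogue at locus %s",
                              object@loci[j]))
      len <- nchar(object@alleles[[j]])
      if (length(unique(len)) > 1L)
        msg <- c(msg, sprintf("haplotype alleles of locus %s differ in length",
                              object@loci[j]))
    }
    if (any(is.na(object@a1) != is.na(object@a2)))
      msg <- c(msg, "a1/a2 must be NA together (missing is a dedicated state)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix from allele-index matrices
#'
#' @param a1,a2 integer matrices of allele indices (NA = missing); they are
#'   reordered so that a1 <= a2.
#' @param alleles named list of per-locus haplotype catalogues.
#' @param collections per-individual collection labels.
#' @param individuals,loci ids (default from dimnames).
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(a1, a2, alleles, collections,
                           individuals = rownames(a1), loci = names(alleles)) {
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  storage.mode(lo) <- "integer"; storage.mode(hi) <- "integer"
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(nrow(lo)))
  dimnames(lo) <- dimnames(hi) <- list(individuals, loci)
  new("GenotypeMatrix", individuals = as.character(individuals),
      collections = as.character(collections), loci = as.character(loci),
      alleles = alleles, a1 = lo, a2 = hi)
}

#' FilterReport: outcome of a locus/individual filtering step
#'
#' @slot retainedLoci,excluded retained ids and a data.frame of
#'   (locusId, reason) for exclusions; reasons are one of
#'   depth/HWE/LD/length.
#' @slot retainedIndividuals,droppedIndividuals individual ids.
#' @slot details per-filter diagnostics (HWE p-value matrix, LD pair table,
#'   ...).
#' @export
setClass("FilterReport",
  representation(retainedLoci = "character", excluded = "data.frame",
                 retainedIndividuals = "character",
                 droppedIndividuals = "character", details = "list"),
  prototype(excluded = data.frame(locusId = character(0),
                                  reason = character(0)),
            droppedIndividuals = character(0), details = list()))

#' ReadClassSummary: per-read classification of an amplicon pool
#'
#' @slot total total reads.
#' @slot onTarget named integer vector of on-target reads per locus.
#' @slot interactions data.frame (locusI, locusJ, count) of chimeric
#'   primer-interaction reads, keyed by the leading forward primer's locus
#'   (I) and the contained other-pair primer's locus (J).
#' @slot unknown reads assignable to no class.
#' @slot proportionInteractions interactions / total.
#' @slot labels optional per-read labels (read, class, locusI, locusJ).
#' @export
setClass("ReadClassSummary",
  representation(total = "integer", onTarget = "integer",
                 interactions = "data.frame", unknown = "integer",
                 proportionInteractions = "numeric", labels = "data.frame"),
  prototype(labels = data.frame()))

setValidity("ReadClassSummary", function(object) {
  tot <- sum(object@onTarget) + sum(object@interactions$count) + object@unknown
  if (object@total != tot) return("class counts must sum to total")
  if (object@total > 0 &&
      (object@proportionInteractions < 0 || object@proportionInteractions > 1))
    return("proportionInteractions must lie in [0,1]")
  TRUE
})

#' AlleleCounts: probe-based allele counts per individual
#'
#' @slot hapCounts data.frame (individual, locusId, allele, count) of
#'   haplotype-allele read counts (phase read directly off single-end reads).
#' @slot snpCounts data.frame (individual, locusId, snpOffset, allele,
#'   count) of per-SNP allele read counts.
#' @slot depth data.frame (individual, locusId, depth) of on-target depth.
#' @export
setClass("AlleleCounts",
  representation(hapCounts = "data.frame", snpCounts = "data.frame",
                 depth = "data.frame"))

#' RoundAssessment: stop/continue decision for one optimization round
#'
#' @slot proportionInteractions proportion of reads from primer interactions.
#' @slot accuracy mean genotype accuracy vs the reference dataset (fraction;
#'   NA when the genotyping rate was too low to estimate it).
#' @slot stop TRUE when interactions < 1/3 and accuracy > 0.95.
#' @slot reason human-readable explanation.
#' @slot removals recommended removals carried with the assessment.
#' @export
setClass("RoundAssessment",
  representation(proportionInteractions = "numeric", accuracy = "numeric",
                 stop = "logical", reason = "character",
                 removals = "data.frame"),
  prototype(removals = data.frame()))

setValidity("RoundAssessment", function(object) {
  want <- isTRUE(object@proportionInteractions < 1 / 3) &&
    !is.na(object@accuracy) && isTRUE(object@accuracy > 0.95)
  if (!identical(object@stop, want))
    return("stop flag must equal (interactions < 1/3) AND (accuracy > 0.95)")
  TRUE
})

#' DapcResult: discriminant analysis of principal components
#'
#' @slot centroids group (year) centroid coordinates in discriminant space
#'   (groups x axes).
#' @slot indCoords per-individual discriminant coordinates.
#' @slot varExplained per-axis fraction of discriminated variance.
#' @slot nPc number of principal components retained.
#' @slot aScoreTrace a-score per candidate number of PCs (empty when nPc
#'   was fixed).
#' @slot assignProp proportion of individuals reassigned to their own group.
#' @export
setClass("DapcResult",
  representation(centroids = "matrix", indCoords = "matrix",
                 varExplained = "numeric", nPc = "integer",
                 aScoreTrace = "numeric", assignProp = "numeric"),
  prototype(aScoreTrace = numeric(0)))

setValidity("DapcResult", function(object) {
  if (any(object@varExplained < -1e-9 | object@varExplained > 1 + 1e-9))
    return("variance fractions must lie in [0,1]")
  if (ncol(object@centroids) > max(1L, nrow(object@centroids) - 1L))
    return("number of discriminant axes must be <= groups - 1")
  TRUE
})

#' SelectionReport: subset-vs-complete panel comparison
#'
#' @slot distances data.frame (scheme, group, d) of per-year Euclidean
#'   distances between subset and complete-dataset DAPC centroids.
#' @slot summary data.frame (scheme, meanD, minD, maxD) ranked by meanD.
#' @slot chosen name of the scheme with the smallest mean distance.
#' @slot diversity optional per-scheme diversity tables.
#' @slot pairwiseFst optional per-scheme pairwise F_ST results.
#' @slot alignment alignment used ("procrustes" or "none").
#' @export
setClass("SelectionReport",
  representation(distances = "data.frame", summary = "data.frame",
                 chosen = "character", diversity = "list",
                 pairwiseFst = "list", alignment = "character"),
  prototype(diversity = list(), pairwiseFst = list()))

setValidity("SelectionReport", function(object) {
  if (nrow(object@summary) &&
      object@chosen != object@summary$scheme[which.min(object@summary$meanD)])
    return("chosen scheme must have the minimal mean distance")
  TRUE
})
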