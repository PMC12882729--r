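#' @include AllClasses.R
NULL

#' Accessors for GTseqPanel objects
#'
#' \code{individuals}, \code{collections}, \code{lociIds}, \code{alleleCatalog},
#' \code{nInd} and \code{nLoci} read the corresponding structure of a
#' \linkS4class{GenotypeMatrix}; \code{callStrings} renders calls as
#' "hap1/hap2" strings (missing = \code{"-"}); \code{missingness} returns the
#' per-individual fraction of missing calls.
#'
#' @param x object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))
#' @rdname accessors
#' @export
setGeneric("collections", function(x) standardGeneric("collections"))
#' @rdname accessors
#' @export
setGeneric("lociIds", function(x) standardGeneric("lociIds"))
#' @rdname accessors
#' @export
setGeneric("alleleCatalog", function(x) standardGeneric("alleleCatalog"))
#' @rdname accessors
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))
#' @rdname accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
#' @rdname accessors
#' @export
setGeneric("callStrings", function(x) standardGeneric("callStrings"))
#' @rdname accessors
#' @export
setGeneric("missingness", function(x) standardGeneric("missingness"))
#' @rdname accessors
#' @export
setGeneric("locusId", function(x) standardGeneric("locusId"))

#' @rdname accessors
#' @export
setMethod("individuals", "GenotypeMatrix", function(x) x@individuals)
#' @rdname accessors
#' @export
setMethod("collections", "GenotypeMatrix", function(x) x@collections)
#' @rdname accessors
#' @export
setMethod("lociIds", "GenotypeMatrix", function(x) x@loci)
#' @rdname accessors
#' @export
setMethod("alleleCatalog", "GenotypeMatrix", function(x) x@alleles)
#' @rdname accessors
#' @export
setMethod("nInd", "GenotypeMatrix", function(x) length(x@individuals))
#' @rdname accessors
#' @export
setMethod("nLoci", "GenotypeMatrix", function(x) length(x@loci))
#' @rdname accessors
#' @export
setMethod("locusId", "MicrohapLocus", function(x) x@locusId)
#' @rdname accessors
#' @export
setMethod("locusId", "TrimmedLocus", function(x) x@locusId)
#' @rdname accessors
#' @export
setMethod("locusId", "PrimerPair", function(x) x@locusId)
#' @rdname accessors
#' @export
setMethod("locusId", "PanelEntry", function(x) x@locus@locusId)

#' @rdname accessors
#' @export
setMethod("callStrings", "GenotypeMatrix", function(x) {
  out <- matrix(MISSING_CALL, nInd(x), nLoci(x),
                dimnames = list(x@individuals, x@loci))
  for (j in seq_len(nLoci(x))) {
    ok <- !is.na(x@a1[, j])
    if (any(ok)) {
      cat_j <- x@alleles[[j]]
      out[ok, j] <- paste(cat_j[x@a1[ok, j]], cat_j[x@a2[ok, j]], sep = "/")
    }
  }
  out
})

#' @rdname accessors
#' @export
setMethod("missingness", "GenotypeMatrix", function(x) {
  if (nLoci(x) == 0L)
    return(setNames(rep(0, nInd(x)), x@individuals))
  setNames(rowMeans(is.na(x@a1)), x@individuals)
})

#' Subset a GenotypeMatrix
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param i individual ids, indices, or logical mask.
#' @param j locus ids, indices, or logical mask.
#' @param ... ignored.
#' @param drop ignored (always FALSE).
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_along(x@individuals)
  if (missing(j)) j <- seq_along(x@loci)
  if (is.character(i)) i <- match(i, x@individuals)
  if (is.character(j)) j <- match(j, x@loci)
  if (anyNA(i) || anyNA(j)) stop("unknown individual or locus id in subset")
  new("GenotypeMatrix",
      individuals = x@individuals[i], collections = x@collections[i],
      loci = x@loci[j], alleles = x@alleles[j],
      a1 = x@a1[i, j, drop = FALSE], a2 = x@a2[i, j, drop = FALSE])
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d loci, %d collections\n",
              nInd(object), nLoci(object),
              length(unique(object@collections))))
  if (nInd(object))
    cat(sprintf("  collections: %s\n  mean missingness: %.3f\n",
                paste(sort(unique(object@collections)), collapse = " "),
                mean(missingness(object))))
})

setMethod("show", "MicrohapLocus", function(object) {
  cat(sprintf("MicrohapLocus %s: %d bp, %d SNP(s)\n", object@locusId,
              nchar(object@sequence), nrow(object@snps)))
})

setMethod("show", "TrimmedLocus", function(object) {
  if (length(object@removed))
    cat(sprintf("TrimmedLocus %s: REMOVED (%s)\n", object@locusId,
                object@removed))
  else
    cat(sprintf("TrimmedLocus %s: %d bp kept [%d,%d), %d SNP(s) retained, %d discarded\n",
                object@locusId, nchar(object@sequence), object@keptStart,
                object@keptEnd, nrow(object@snps), object@discardedSnps))
})

setMethod("show", "PrimerPair", function(object) {
  cat(sprintf("PrimerPair %s (rank %d): %s / %s, product [%d,%d)\n",
              object@locusId, object@rank, object@fwd, object@rev,
              object@productStart, object@productEnd))
})

setMethod("show", "PanelEntry", function(object) {
  cat(sprintf("PanelEntry %s: %d SNP(s), %d probes, %s\n",
              locusId(object), nrow(object@locus@snps), nrow(object@probes),
              if (object@active) "active"
              else paste0("removed: ", object@removedReason)))
})

setMethod("show", "FilterReport", function(object) {
  tab <- table(object@excluded$reason)
  cat(sprintf("FilterReport: %d loci retained, %d excluded (%s); %d individuals retained, %d dropped\n",
              length(object@retainedLoci), nrow(object@excluded),
              if (length(tab)) paste(names(tab), tab, sep = ":", collapse = ", ")
              else "none",
              length(object@retainedIndividuals),
              length(object@droppedIndividuals)))
})

setMethod("show", "ReadClassSummary", function(object) {
  cat(sprintf("ReadClassSummary: %d reads; %d on-target, %d interaction (%.1f%%), %d unknown\n",
              object@total, sum(object@onTarget),
              sum(object@interactions$count),
              100 * object@proportionInteractions, object@unknown))
})

setMethod("show", "RoundAssessment", function(object) {
  cat(sprintf("RoundAssessment: interactions %.1f%%, accuracy %s -> %s (%s)\n",
              100 * object@proportionInteractions,
              if (is.na(object@accuracy)) "NA"
              else sprintf("%.1f%%", 100 * object@accuracy),
              if (object@stop) "STOP" else "CONTINUE", object@reason))
})

setMethod("show", "DapcResult", function(object) {
  cat(sprintf("DapcResult: %d groups, %d DF axes, %d PCs retained, reassignment %.1f%%\n",
              nrow(object@centroids), ncol(object@centroids), object@nPc,
              100 * object@assignProp))
})

setMethod("show", "SelectionReport", function(object) {
  cat(sprintf("SelectionReport (%s alignment): chosen scheme %s\n",
              object@alignment, object@chosen))
  print(object@summary, row.names = FALSE)
})
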