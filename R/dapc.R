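#' Per-individual allele dosage table
#'
#' One column per (locus, allele) holding the individual's dosage (0/1/2);
#' NA where the locus call is missing. This is the multivariate input for
#' \code{\link{runDapc}}.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @return Numeric matrix, individuals x allele columns.
#' @export
dosageTable <- function(gm) {
  ad <- alleleDosage(gm)
  rownames(ad$D) <- individuals(gm)
  ad$D
}

imputeDosage <- function(X, groups, method = c("mean", "random_forest"),
                         rfTrees = 1000L) {
  method <- match.arg(method)
  gFac <- as.factor(groups)
  for (gl in levels(gFac)) {
    rows <- which(gFac == gl)
    sub <- X[rows, , drop = FALSE]
    miss <- which(colSums(is.na(sub)) > 0)
    if (!length(miss)) next
    if (method == "mean") {
      mns <- colMeans(sub, na.rm = TRUE)
      for (j in miss) {
        v <- sub[, j]
        v[is.na(v)] <- mns[j]
        X[rows, j] <- v
      }
    } else {
      if (!requireNamespace("randomForest", quietly = TRUE))
        stop("random_forest imputation needs the randomForest package")
      complete <- setdiff(seq_len(ncol(sub)), miss)
      predCols <- complete[seq_len(min(50L, length(complete)))]
      for (j in miss) {
        obs <- !is.na(sub[, j])
        if (sum(obs) < 5L || !length(predCols)) {
          mn <- mean(sub[, j], na.rm = TRUE)
          sub[!obs, j] <- if (is.nan(mn)) mean(X[, j], na.rm = TRUE) else mn
          next
        }
        fit <- randomForest::randomForest(
          x = sub[obs, predCols, drop = FALSE], y = sub[obs, j],
          ntree = rfTrees)
        sub[!obs, j] <- predict(fit, sub[!obs, predCols, drop = FALSE])
      }
      X[rows, ] <- sub
    }
  }
  ## columns missing for an entire group fall back to the overall mean
  if (anyNA(X)) {
    mns <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mns[idx[, 2]]
  }
  X
}

ldaFit <- function(scores, groups, nDf) {
  fit <- suppressWarnings(MASS::lda(scores, grouping = groups))
  pred <- predict(fit, scores)
  nAxes <- min(nDf, ncol(pred$x))
  ld <- pred$x[, seq_len(nAxes), drop = FALSE]
  list(fit = fit, pred = pred, ld = ld,
       varExplained = (fit$svd^2 / sum(fit$svd^2))[seq_len(nAxes)],
       assign = mean(as.character(pred$class) == as.character(groups)))
}

#' Discriminant analysis of principal components
#'
#' Genotypes are expanded into an allele-dosage table; missing values are
#' imputed within group (mean by default; \code{"random_forest"} fits
#' regression forests per allele column); principal components are computed
#' without scaling; a linear discriminant analysis on the retained PCs
#' yields group (collection) centroids in discriminant space. The number
#' of retained PCs is either fixed or chosen by the a-score: mean over
#' groups of (correct reassignment proportion minus its expectation under
#' permuted group labels), maximized over the candidate grid
#' \code{1..min(50, n - groups)}.
#'
#' @param gm a \linkS4class{GenotypeMatrix} (>= 2 collections, >= 3
#'   individuals each).
#' @param impute "mean" or "random_forest".
#' @param nPc number of PCs to retain, or "a-score".
#' @param nDf number of discriminant axes to keep (default 2).
#' @param seed RNG seed (a-score permutations).
#' @param aScorePerm label permutations per candidate (default 10).
#' @return A \linkS4class{DapcResult}.
#' @export
runDapc <- function(gm, impute = c("mean", "random_forest"),
                    nPc = "a-score", nDf = 2L, seed = 1L,
                    aScorePerm = 10L) {
  impute <- match.arg(impute)
  groups <- as.factor(collections(gm))
  if (nlevels(groups) < 2L) stop("DAPC needs at least two collections")
  if (any(table(groups) < 3L)) stop("every collection needs >= 3 individuals")
  set.seed(seed)
  X <- imputeDosage(dosageTable(gm), groups, impute)
  n <- nrow(X)
  keep <- which(apply(X, 2, var) > 0)
  X <- X[, keep, drop = FALSE]
  maxPc <- min(n - 1L, ncol(X))
  if (ncol(X) > n) {
    ## wide data: PCA via the n x n Gram matrix (scores only are needed)
    Xc <- sweep(X, 2, colMeans(X))
    eg <- eigen(tcrossprod(Xc), symmetric = TRUE)
    sdev <- sqrt(pmax(eg$values, 0) / (n - 1))
    scores <- sweep(eg$vectors, 2, sqrt(pmax(eg$values, 0)), "*")
  } else {
    pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = maxPc)
    sdev <- pc$sdev[seq_len(ncol(pc$x))]
    scores <- pc$x
  }
  usable <- which(sdev[seq_len(min(maxPc, ncol(scores)))] > 1e-8)
  scores <- scores[, usable, drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  grid <- seq_len(min(50L, n - nlevels(groups), ncol(scores)))
  trace <- numeric(0)
  if (identical(nPc, "a-score")) {
    trace <- vapply(grid, function(np) {
      s <- scores[, seq_len(np), drop = FALSE]
      obs <- ldaFit(s, groups, nDf)$assign
      perm <- vapply(seq_len(aScorePerm), function(b) {
        gl <- sample(groups)
        ldaFit(s, gl, nDf)$assign
      }, numeric(1))
      obs - mean(perm)
    }, numeric(1))
    names(trace) <- as.character(grid)
    nPc <- grid[which.max(trace)]
  } else {
    nPc <- min(as.integer(nPc), ncol(scores))
    if (nPc >= n) {
      warning("nPc capped at the number of usable components")
      nPc <- ncol(scores)
    }
  }
  res <- ldaFit(scores[, seq_len(nPc), drop = FALSE], groups, nDf)
  centroids <- rowsum(res$ld, groups) / as.vector(table(groups))
  new("DapcResult", centroids = centroids, indCoords = res$ld,
      varExplained = res$varExplained, nPc = as.integer(nPc),
      aScoreTrace = trace, assignProp = res$assign)
}

#' Build candidate locus subsets from per-locus F_ST
#'
#' Each scheme takes the \code{nTop} loci with the highest theta (undefined
#' excluded, ties broken by locus id) and fills up to \code{total} with a
#' random draw from the remaining defined loci — the random complement
#' explicitly excludes the already-selected top-theta loci within its
#' scheme.
#'
#' @param fst data.frame from \code{\link{perLocusTemporalFst}}.
#' @param schemes list of schemes, each \code{list(name, nTop, nRandom)};
#'   see \code{\link{defaultSchemes}}.
#' @param seed RNG seed for the random complements.
#' @return Named list of locus-id vectors.
#' @export
buildSubsets <- function(fst, schemes, seed = 1L) {
  set.seed(seed)
  def <- fst[fst$defined, , drop = FALSE]
  ord <- def[order(-def$theta, def$locusId), "locusId"]
  lapply2 <- function(s) {
    total <- s$nTop + s$nRandom
    if (total > length(ord))
      stop(sprintf("scheme %s needs %d loci but only %d are available",
                   s$name, total, length(ord)))
    top <- head(ord, s$nTop)
    pool <- setdiff(def$locusId, top)
    rnd <- if (s$nRandom > 0) sample(pool, s$nRandom) else character(0)
    c(top, rnd)
  }
  out <- lapply(schemes, lapply2)
  names(out) <- vapply(schemes, `[[`, character(1), "name")
  out
}

#' Default subset schemes
#'
#' The five 500-locus schemes used to pick a panel: all top-theta
#' (fst500), all random (rdm500), and the three mixtures
#' fst350+rdm150, fst250+rdm250, fst150+rdm350.
#'
#' @param total subset size (default 500).
#' @return List of scheme descriptors for \code{\link{buildSubsets}}.
#' @export
defaultSchemes <- function(total = 500L) {
  mk <- function(nTop) {
    nTop <- as.integer(round(nTop)); nRnd <- as.integer(total - nTop)
    name <- if (nRnd == 0L) paste0("fst", total)
      else if (nTop == 0L) paste0("rdm", total)
      else paste0("fst", nTop, "+rdm", nRnd)
    list(name = name, nTop = nTop, nRandom = nRnd)
  }
  list(mk(total), mk(0L), mk(total * 0.7), mk(total * 0.5), mk(total * 0.3))
}

#' Compare subset DAPCs against the complete-dataset DAPC
#'
#' Subset centroid sets are aligned to the complete-dataset centroid space
#' (default: orthogonal Procrustes — translation, rotation and reflection,
#' no scaling; \code{"none"} compares raw coordinates) and the per-group
#' Euclidean distance d between corresponding centroids is computed. The
#' scheme with the smallest mean d is chosen.
#'
#' @param complete \linkS4class{DapcResult} for the full dataset.
#' @param subsets named list of \linkS4class{DapcResult}, one per scheme.
#' @param alignment "procrustes" or "none".
#' @return A \linkS4class{SelectionReport}.
#' @export
compareSubsets <- function(complete, subsets,
                           alignment = c("procrustes", "none")) {
  alignment <- match.arg(alignment)
  X <- complete@centroids
  rows <- list(); summ <- list()
  for (nm in names(subsets)) {
    Y <- subsets[[nm]]@centroids
    if (!setequal(rownames(X), rownames(Y)))
      stop("group mismatch between complete and subset '", nm, "'")
    Y <- Y[rownames(X), , drop = FALSE]
    d <- min(ncol(X), ncol(Y))
    Xd <- X[, seq_len(d), drop = FALSE]; Yd <- Y[, seq_len(d), drop = FALSE]
    dg <- if (alignment == "procrustes") {
      ## residuals are computed in the aligned (centred) frame
      pr <- vegan::procrustes(Xd, Yd, scale = FALSE, symmetric = FALSE)
      as.vector(residuals(pr))
    } else sqrt(rowSums((Yd - Xd)^2))
    names(dg) <- rownames(Xd)
    rows[[nm]] <- data.frame(scheme = nm, group = rownames(Xd), d = dg,
                             stringsAsFactors = FALSE, row.names = NULL)
    summ[[nm]] <- data.frame(scheme = nm, meanD = mean(dg), minD = min(dg),
                             maxD = max(dg), stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, summ)
  summary <- summary[order(summary$meanD), , drop = FALSE]
  rownames(summary) <- NULL
  new("SelectionReport", distances = do.call(rbind, rows),
      summary = summary, chosen = summary$scheme[1],
      alignment = alignment)
}
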