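## Stage orchestration. Stages run in the canonical order
## simulate -> filter -> trim -> screen -> select -> qc; each writes its
## report plus a manifest (parameters, input hashes, seeds, package
## version) into the run directory, so a rerun from the same config and
## inputs reproduces the outputs.

#' Default pipeline configuration
#'
#' One flat list of every stage parameter with the package defaults;
#' override entries via \code{modifyList} or the \code{config} argument of
#' \code{\link{runPipeline}}. \code{seed} is the master seed from which
#' each stage derives its own.
#'
#' @return Named list.
#' @export
defaultConfig <- function() {
  list(
    seed = 1L,
    ## simulate
    nLoci = 1000L, locusLen = 150L, missingness = 0.03,
    neBaseline = 500L, neBottleneck = 50L,
    ## filter
    minMeanDepth = 20, maxIndMissing = 0.25, alpha = 0.05,
    correction = "bonferroni",
    ## trim / probes
    flank = 33L, maxTemplate = 150L, probeFlank = 8L,
    ## screen
    primerLen = 20L, nCandidates = 5L,
    ## select
    subsetTotal = 500L, nPc = 50L, nDf = 2L, alignment = "procrustes",
    nPerm = 1000L, nBoot = 200L, runPairwiseFst = FALSE,
    ## qc
    qcIndividuals = 12L, qcMeanDepth = 40, qcInteractionFraction = 0.5,
    qcDriverFraction = 0.25, qcMaxRounds = 4L, eps = 0.01, minDepth = 10L
  )
}

writeManifest <- function(dir, stage, params, files) {
  manifest <- list(stage = stage,
                   package = as.character(utils::packageVersion("GTseqPanel")),
                   params = params,
                   files = lapply(files, function(f)
                     list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the panel-development pipeline on synthetic data
#'
#' Executes the requested stages in canonical order inside \code{outDir}.
#' Stage inputs are taken from earlier stages' outputs in the same run
#' directory; a missing dependency stops the run before any work.
#'
#' @param config list of parameters (see \code{\link{defaultConfig}};
#'   partial lists are merged over the defaults).
#' @param stages subset of
#'   \code{c("simulate","filter","trim","screen","select","qc")}.
#' @param outDir run directory (created).
#' @return \code{outDir}, invisibly; each stage leaves
#'   \code{<stage>_manifest.json} plus its outputs there.
#' @export
runPipeline <- function(config = list(),
                        stages = c("simulate", "filter", "trim", "screen",
                                   "select", "qc"),
                        outDir = tempfile("gtseq_run_")) {
  cfg <- utils::modifyList(defaultConfig(), config)
  order <- c("simulate", "filter", "trim", "screen", "select", "qc")
  stages <- order[order %in% stages]
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  need <- function(f, stage) {
    p <- file.path(outDir, f)
    if (!file.exists(p))
      stop(sprintf("stage '%s' needs %s from an earlier stage", stage, f))
    p
  }
  state <- new.env()
  jsonlite::write_json(cfg, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  for (stage in stages) {
    message("[", stage, "] running")
    switch(stage,
    simulate = {
      dp <- DriftParams(nLoci = cfg$nLoci, missingness = cfg$missingness,
                        neBaseline = cfg$neBaseline,
                        neBottleneck = cfg$neBottleneck,
                        seed = deriveSeed(cfg$seed, 1L))
      sim <- simulateTemporalGenotypes(dp)
      ref <- simulateReferenceWithLoci(cfg$nLoci, cfg$locusLen,
                                       seed = deriveSeed(cfg$seed, 2L),
                                       catalog = alleleCatalog(sim$gm))
      ## attach simulated depths so the depth filter has data to act on
      set.seed(deriveSeed(cfg$seed, 3L))
      depths <- rnbinom(length(ref$loci), size = 8, mu = 60)
      for (i in seq_along(ref$loci)) ref$loci[[i]]@meanDepth <- depths[i]
      state$gm <- sim$gm; state$loci <- ref$loci; state$genome <- ref$genome
      gPath <- file.path(outDir, "genotypes.tsv")
      writeGenotypes(sim$gm, gPath)
      fPath <- file.path(outDir, "reference.fa")
      Biostrings::writeXStringSet(ref$genome, fPath)
      dPath <- file.path(outDir, "locus_depths.tsv")
      writeTsvWithHeader(data.frame(locus = names(ref$loci),
                                    mean_depth = depths), dPath,
                         "locus depths")
      writeManifest(outDir, "simulate",
                    cfg[c("seed", "nLoci", "locusLen", "missingness",
                          "neBaseline", "neBottleneck")],
                    c(gPath, fPath, dPath))
    },
    filter = {
      if (is.null(state$gm)) {
        state$gm <- readGenotypes(need("genotypes.tsv", stage))
        dep <- readTsvWithHeader(need("locus_depths.tsv", stage))
        state$loci <- lapply(seq_len(nrow(dep)), function(i)
          MicrohapLocus(dep$locus[i], "N", meanDepth = dep$mean_depth[i]))
      }
      rep <- runLocusFilters(state$loci, state$gm, cfg$minMeanDepth,
                             cfg$maxIndMissing, cfg$alpha, cfg$correction,
                             seed = deriveSeed(cfg$seed, 4L))
      state$filtered <- rep
      state$gmF <- state$gm[rep@retainedIndividuals,
                            intersect(lociIds(state$gm), rep@retainedLoci)]
      p1 <- file.path(outDir, "filter_excluded.tsv")
      writeTsvWithHeader(rep@excluded, p1, "filter exclusions")
      p2 <- file.path(outDir, "filter_summary.json")
      jsonlite::write_json(list(
        retainedLoci = length(rep@retainedLoci),
        excludedByReason = as.list(table(rep@excluded$reason)),
        retainedIndividuals = length(rep@retainedIndividuals),
        droppedIndividuals = length(rep@droppedIndividuals)),
        p2, auto_unbox = TRUE, pretty = TRUE)
      writeManifest(outDir, "filter",
                    cfg[c("minMeanDepth", "maxIndMissing", "alpha",
                          "correction")], c(p1, p2))
    },
    trim = {
      if (is.null(state$gmF)) stop("stage 'trim' needs the filter stage")
      keep <- lociIds(state$gmF)
      state$trimmed <- list()
      trimLog <- list()
      for (id in keep) {
        t <- trimSnpsForPrimers(state$loci[[id]], cfg$flank)
        t <- filterTemplateLength(t, cfg$maxTemplate)
        state$trimmed[[id]] <- t
        trimLog[[id]] <- data.frame(
          locus = id,
          status = if (length(t@removed)) t@removed else "kept",
          template_len = nchar(t@sequence),
          snps_retained = nrow(t@snps), snps_discarded = t@discardedSnps)
      }
      p <- file.path(outDir, "trim_report.tsv")
      writeTsvWithHeader(do.call(rbind, trimLog), p, "trim report")
      writeManifest(outDir, "trim", cfg[c("flank", "maxTemplate")], p)
    },
    screen = {
      if (is.null(state$trimmed)) stop("stage 'screen' needs the trim stage")
      panel <- list(); screenLog <- list()
      for (id in names(state$trimmed)) {
        t <- state$trimmed[[id]]
        if (length(t@removed)) next
        if (nchar(t@sequence) < 2L * cfg$primerLen) next
        cand <- makeNaivePrimerCandidates(t, cfg$nCandidates, cfg$primerLen)
        src <- state$loci[[id]]
        target <- list(contig = src@contig,
                       start = src@start + t@keptStart,
                       end = src@start + t@keptEnd - 1L)
        sel <- selectPrimerPair(cand, state$genome, target)
        if (is.null(sel$pair)) {
          screenLog[[id]] <- data.frame(locus = id, status = sel$removedReason)
          next
        }
        panel[[id]] <- PanelEntry(t, sel$pair, buildProbes(t, cfg$probeFlank))
        screenLog[[id]] <- data.frame(locus = id, status = "specific")
      }
      state$panel <- panel
      paths <- writePanelTables(panel, outDir)
      p <- file.path(outDir, "screen_report.tsv")
      writeTsvWithHeader(do.call(rbind, screenLog), p, "screen report")
      writeManifest(outDir, "screen", cfg[c("primerLen", "nCandidates")],
                    c(unname(paths), p))
    },
    select = {
      if (is.null(state$gmF)) stop("stage 'select' needs the filter stage")
      withPrimers <- if (!is.null(state$panel)) names(state$panel)
                     else lociIds(state$gmF)
      gmSel <- state$gmF[, intersect(lociIds(state$gmF), withPrimers)]
      fst <- perLocusTemporalFst(gmSel)
      total <- min(cfg$subsetTotal, sum(fst$defined) - 10L)
      schemes <- defaultSchemes(total)
      subsets <- buildSubsets(fst, schemes, seed = deriveSeed(cfg$seed, 5L))
      dapcAll <- runDapc(state$gmF, nPc = cfg$nPc, nDf = cfg$nDf,
                         seed = deriveSeed(cfg$seed, 6L))
      dapcSub <- lapply(subsets, function(ids)
        runDapc(gmSel[, ids], nPc = cfg$nPc, nDf = cfg$nDf,
                seed = deriveSeed(cfg$seed, 6L)))
      selRep <- compareSubsets(dapcAll, dapcSub, cfg$alignment)
      state$selection <- selRep
      state$subsets <- subsets
      state$fst <- fst
      state$chosen <- subsets[[selRep@chosen]]
      p1 <- file.path(outDir, "selection_summary.tsv")
      writeTsvWithHeader(selRep@summary, p1, "selection summary")
      p2 <- file.path(outDir, "selection_distances.tsv")
      writeTsvWithHeader(selRep@distances, p2, "selection distances")
      p3 <- file.path(outDir, "per_locus_fst.tsv")
      writeTsvWithHeader(fst, p3, "per-locus temporal theta")
      p4 <- file.path(outDir, "chosen_subset.tsv")
      writeTsvWithHeader(data.frame(locus = state$chosen), p4,
                         "chosen subset")
      files <- c(p1, p2, p3, p4)
      if (isTRUE(cfg$runPairwiseFst)) {
        pw <- pairwiseFst(state$gmF, nPerm = cfg$nPerm, nBoot = cfg$nBoot,
                          seed = deriveSeed(cfg$seed, 7L))
        p5 <- file.path(outDir, "pairwise_fst.tsv")
        writeTsvWithHeader(pw$pairs, p5, "pairwise theta")
        files <- c(files, p5)
      }
      writeManifest(outDir, "select",
                    cfg[c("subsetTotal", "nPc", "nDf", "alignment")], files)
    },
    qc = {
      if (is.null(state$panel) || is.null(state$chosen))
        stop("stage 'qc' needs the screen and select stages")
      panel <- state$panel[intersect(state$chosen, names(state$panel))]
      rounds <- optimizeMultiplex(
        panel, state$gmF, state$fst,
        nIndividuals = cfg$qcIndividuals, meanDepth = cfg$qcMeanDepth,
        interactionFraction = cfg$qcInteractionFraction,
        driverFraction = cfg$qcDriverFraction, maxRounds = cfg$qcMaxRounds,
        eps = cfg$eps, minDepth = cfg$minDepth,
        seed = deriveSeed(cfg$seed, 8L))
      p <- file.path(outDir, "qc_rounds.tsv")
      writeTsvWithHeader(rounds$table, p, "optimization rounds")
      writeManifest(outDir, "qc",
                    cfg[c("qcIndividuals", "qcMeanDepth",
                          "qcInteractionFraction", "qcMaxRounds")], p)
    })
  }
  invisible(outDir)
}

#' Simulate the iterative multiplex optimization loop
#'
#' Emulates the round-by-round panel optimization on synthetic reads: a
#' designated fraction of primer pairs drives most chimeric interactions;
#' each round classifies reads, genotypes individuals by maximum
#' likelihood, measures accuracy against the known genotypes, applies the
#' stopping rule and removes the recommended pairs before the next round.
#' The interaction load of a round scales with the interaction propensity
#' mass still present in the multiplex.
#'
#' @param panel named list of \linkS4class{PanelEntry}.
#' @param gm genotypes for the panel loci (source of truth for accuracy).
#' @param fst per-locus theta table (duo tie-breaks), may be NULL.
#' @param nIndividuals individuals sequenced per round.
#' @param meanDepth mean on-target depth per locus and individual.
#' @param interactionFraction round-1 chimera fraction of all reads.
#' @param driverFraction fraction of pairs designated interaction drivers
#'   (they carry 95\% of the chimera propensity).
#' @param maxRounds hard cap on rounds (default 4).
#' @param eps,minDepth genotyping parameters.
#' @param seed RNG seed.
#' @return List with \code{table} (one row per round: round, n_loci,
#'   interaction_pct, accuracy_pct, removed, stop) and
#'   \code{assessments}.
#' @export
optimizeMultiplex <- function(panel, gm, fst = NULL, nIndividuals = 12L,
                              meanDepth = 40, interactionFraction = 0.5,
                              driverFraction = 0.25, maxRounds = 4L,
                              eps = 0.01, minDepth = 10L, seed = 1L) {
  set.seed(seed)
  inds <- sample(individuals(gm), min(nIndividuals, nInd(gm)))
  gmS <- projectGenotypes(gm[inds, ], panel)
  nP <- length(panel)
  nDrivers <- max(1L, round(driverFraction * nP))
  drivers <- sample(names(panel), nDrivers)
  ## interaction propensity: drivers hold 95% of the mass
  w <- setNames(rep(0.05 / (nP - nDrivers), nP), names(panel))
  w[drivers] <- 0.95 / nDrivers
  propensity0 <- sum(w)
  rows <- list(); assessments <- list()
  live <- panel
  for (round in seq_len(maxRounds)) {
    frac <- min(0.99, interactionFraction * sum(w[names(live)]) / propensity0)
    rp <- ReadSimParams(meanDepth = meanDepth, dispersion = 8,
                        errorRate = 0.001, interactionFraction = frac,
                        chimeraWeights = w[names(live)],
                        seed = deriveSeed(seed, 100L + round))
    sim <- simulateAmpliconReads(live, gmS, rp)
    rc <- classifyReads(sim$reads, live)
    ac <- countAlleles(sim$reads, live)
    called <- tryCatch(
      callGenotypesMl(ac, live,
                      collections = setNames(collections(gmS),
                                             individuals(gmS)),
                      eps = eps, minDepth = minDepth),
      error = function(e) NULL)
    acc <- NA_real_; snpAcc <- NULL
    if (!is.null(called)) {
      conc <- tryCatch(genotypeConcordance(gmS, called, minCallRate = 0.70),
                       error = function(e) NULL)
      if (!is.null(conc) && nrow(conc$perSnp) &&
          any(conc$perSnp$nCompared > 0)) {
        acc <- conc$overall
        snpAcc <- data.frame(locusId = conc$perSnp$locusId,
                             snpIndex = conc$perSnp$snpIndex,
                             accuracy = conc$perSnp$accuracy)
      }
    }
    rec <- recommendRemovals(rc, fst, snpAcc,
                             representation = sum(rc@onTarget) > 0)
    as <- assessRound(rc, acc, rec$removals)
    assessments[[round]] <- as
    rows[[round]] <- data.frame(
      round = round, n_loci = length(live),
      interaction_pct = round(100 * rc@proportionInteractions, 1),
      accuracy_pct = if (is.na(acc)) NA_real_ else round(100 * acc, 1),
      removed = if (as@stop) 0L else nrow(rec$removals),
      stop = as@stop)
    if (as@stop) break
    drop <- intersect(rec$removals$locusId, names(live))
    if (length(drop) == 0L || length(drop) >= length(live)) break
    live <- live[setdiff(names(live), drop)]
  }
  list(table = do.call(rbind, rows), assessments = assessments,
       finalPanel = live, drivers = drivers)
}

#' Render human-readable reports for a pipeline run
#'
#' Builds the summary tables of a run directory: per-collection sample
#' sizes and missingness, the per-round optimization table, the
#' subset-selection ranking, and the panel composition (microhaplotype vs
#' single-SNP loci).
#'
#' @param runDir directory produced by \code{\link{runPipeline}}.
#' @return List of data.frames (collections, rounds, selection,
#'   composition); also written to \code{summary.txt} in the run
#'   directory.
#' @export
renderReports <- function(runDir) {
  if (!dir.exists(runDir) || !length(list.files(runDir)))
    stop("no stage reports in ", runDir)
  out <- list()
  gPath <- file.path(runDir, "genotypes.tsv")
  if (file.exists(gPath)) {
    gm <- readGenotypes(gPath)
    miss <- missingness(gm)
    out$collections <- do.call(rbind, lapply(
      sort(unique(collections(gm))), function(cc) {
        sel <- collections(gm) == cc
        data.frame(collection = cc, n = sum(sel),
                   missing = round(mean(miss[sel]), 3))
      }))
  }
  rPath <- file.path(runDir, "qc_rounds.tsv")
  if (file.exists(rPath)) out$rounds <- readTsvWithHeader(rPath)
  sPath <- file.path(runDir, "selection_summary.tsv")
  if (file.exists(sPath)) out$selection <- readTsvWithHeader(sPath)
  pPath <- file.path(runDir, "panel_probes.tsv")
  if (file.exists(pPath)) {
    probes <- readTsvWithHeader(pPath)
    snpPerLocus <- table(probes$locus)
    out$composition <- data.frame(
      loci = length(snpPerLocus),
      single_snp = sum(snpPerLocus == 1),
      microhaplotype = sum(snpPerLocus > 1),
      snps = nrow(probes))
  }
  txt <- file.path(runDir, "summary.txt")
  con <- file(txt, "w")
  for (nm in names(out)) {
    writeLines(paste0("== ", nm, " =="), con)
    writeLines(utils::capture.output(print(out[[nm]], row.names = FALSE)),
               con)
    writeLines("", con)
  }
  close(con)
  invisible(out)
}
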