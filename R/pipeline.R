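# End-to-end orchestration: QC -> classification -> domain split ->
# per-sample OTU analysis -> pooled tree, UniFrac, ordination,
# rarefaction and composition summaries, with per-stage read accounting.

#' Run the full amplicon community pipeline
#'
#' Stages, in order, per sample: read QC (\code{\link{qcSample}}),
#' taxonomy classification of the merged amplicons
#' (\code{\link{classifyReads}}), domain split
#' (\code{\link{splitByDomain}}); only fungi-binned reads enter OTU
#' analysis (\code{\link{buildOtuSample}}). OTU representatives of all
#' samples are then pooled for the phylogenetic comparison: a
#' neighbor-joining tree (\code{\link{buildTree}}), weighted and
#' unweighted UniFrac (\code{\link{unifrac}}), PCoA
#' (\code{\link{ordinatePcoa}}), rarefaction at a common depth and
#' composition summaries per rank.
#'
#' @param samples Named list; each element a list with \code{r1},
#'   \code{r2} (FASTQ paths or \code{QualityScaledDNAStringSet}s).
#' @param db A \code{\link{ReferenceDb}} (all domains; fungal records are
#'   used for OTU-representative classification and the tree references).
#' @param primers,params See \code{\link{lsuPrimers}},
#'   \code{\link{qcParams}}.
#' @param classify See \code{\link{classifyParams}}.
#' @param otuThreshold OTU identity threshold (default 0.97).
#' @param rarefactionDepth Common subsampling depth; defaults to the
#'   smallest per-sample fungal read count, and is clamped to it (with a
#'   warning) when requested larger.
#' @param rarefactionRepeats Resamples per depth (default 100).
#' @param seed Seed for the rarefaction resampling.
#' @param topK Taxa listed in composition summaries (5 used at phylum
#'   level).
#' @param outDir Optional directory for TSV reports.
#' @return A list (class \code{lsuPipelineReport}) with elements
#'   \code{qcTally}, \code{domainTable}, \code{otu} (per-sample results),
#'   \code{otuExperiment}, \code{lengthDist}, \code{richness},
#'   \code{rarefaction}, \code{tree}, \code{unifracWeighted},
#'   \code{unifracUnweighted}, \code{pcoaWeighted},
#'   \code{pcoaUnweighted}, \code{composition}.
#' @export
runPipeline <- function(samples, db, primers = lsuPrimers(),
                        params = qcParams(),
                        classify = classifyParams(),
                        otuThreshold = 0.97, rarefactionDepth = NULL,
                        rarefactionRepeats = 100L, seed = 1L,
                        topK = 15L, outDir = NULL) {
  stopifnot(length(samples) >= 1L, !is.null(names(samples)))
  fungalDb <- db[refLineages(db)[, "domain"] == "Fungi"]
  qc <- list()
  classified <- list()
  domainTabs <- list()
  otu <- list()
  lengthDist <- list()
  for (sm in names(samples)) {
    res <- qcSample(samples[[sm]]$r1, samples[[sm]]$r2, primers, params)
    qc[[sm]] <- res$tally
    amp <- res$amplicons
    cls <- classifyReads(as(amp, "DNAStringSet"), db, classify)
    classified[[sm]] <- cls
    spl <- splitByDomain(cls, totalMerged = length(amp))
    domainTabs[[sm]] <- spl$table
    fungalIds <- spl$bins$Fungi
    fungalAmp <- amp[names(amp) %in% fungalIds]
    lengthDist[[sm]] <- lengthDistribution(fungalAmp)
    otu[[sm]] <- buildOtuSample(as.character(fungalAmp), fungalDb,
                                threshold = otuThreshold)
  }
  qcTally <- do.call(rbind, qc)
  domainTable <- do.call(rbind, lapply(names(domainTabs), function(sm)
    cbind(sample = sm, domainTabs[[sm]])))
  # pooled OTU experiment: per-sample OTUs, sample-prefixed ids
  allIds <- unlist(lapply(names(otu), function(sm)
    paste0(sm, ".", otu[[sm]]$otus$otu_id)), use.names = FALSE)
  allCent <- unlist(lapply(otu, function(o) o$otus$centroid),
                    use.names = FALSE)
  counts <- matrix(0L, nrow = length(allIds), ncol = length(otu),
                   dimnames = list(allIds, names(otu)))
  off <- 0L
  for (sm in names(otu)) {
    k <- nrow(otu[[sm]]$otus)
    if (k > 0)
      counts[off + seq_len(k), sm] <- otu[[sm]]$otus$count
    off <- off + k
  }
  # classify OTU representatives against the fungal references only
  lin <- if (length(allCent)) {
    cls <- classifyReads(setNames(allCent, allIds), fungalDb, classify)
    asLineage(as.matrix(as.data.frame(cls[, taxRanks()])))
  } else emptyLineage(0L)
  oe <- OtuExperiment(counts, centroid = allCent, lineage = lin)
  # rarefaction at a common depth
  fungalReads <- vapply(otu, function(o) as.numeric(sum(o$otus$count)), 0)
  depth <- if (is.null(rarefactionDepth)) min(fungalReads) else
    rarefactionDepth
  if (depth > min(fungalReads)) {
    warning("rarefaction depth clamped to the smallest sample (",
            min(fungalReads), " reads)")
    depth <- min(fungalReads)
  }
  rare <- lapply(names(otu), function(sm)
    rarefactionCurve(setNames(otu[[sm]]$otus$count,
                              otu[[sm]]$otus$otu_id),
                     depths = depth, repeats = rarefactionRepeats,
                     seed = seed))
  names(rare) <- names(otu)
  richness <- data.frame(
    sample = names(otu),
    otus = vapply(otu, function(o) as.numeric(nrow(o$otus)), 0),
    rarefiedMean = vapply(rare, function(r) r$mean[1], 0),
    rarefiedSd = vapply(rare, function(r) r$sd[1], 0),
    depth = depth)
  # pooled tree + UniFrac + ordination
  tree <- buildTree(setNames(allCent, allIds))
  uw <- unifrac(tree, t(counts), mode = "weighted")
  uu <- unifrac(tree, t(counts), mode = "unweighted")
  pw <- ordinatePcoa(uw)
  pu <- ordinatePcoa(uu)
  composition <- lapply(setNames(nm = taxRanks()[-1]), function(rk)
    compositionSummary(lin, t(counts), level = rk,
                       topK = if (rk == "phylum") 5L else topK))
  report <- list(qcTally = qcTally, domainTable = domainTable,
                 classified = classified, otu = otu, otuExperiment = oe,
                 lengthDist = lengthDist, richness = richness,
                 rarefaction = rare, tree = tree, unifracWeighted = uw,
                 unifracUnweighted = uu, pcoaWeighted = pw,
                 pcoaUnweighted = pu, composition = composition)
  class(report) <- "lsuPipelineReport"
  if (!is.null(outDir)) .writeReport(report, outDir)
  report
}

.writeReport <- function(report, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f, rn = FALSE)
    utils::write.table(x, file.path(outDir, f), sep = "\t",
                       quote = FALSE, row.names = rn,
                       col.names = TRUE)
  wt(report$qcTally, "qc_tally.tsv", rn = TRUE)
  wt(report$domainTable, "domain_split.tsv")
  wt(report$richness, "otu_richness.tsv")
  for (sm in names(report$otu))
    wt(report$otu[[sm]]$otus, paste0("otus_", sm, ".tsv"))
  wt(as.data.frame(report$unifracWeighted), "unifrac_weighted.tsv",
     rn = TRUE)
  wt(as.data.frame(report$unifracUnweighted), "unifrac_unweighted.tsv",
     rn = TRUE)
  ape::write.tree(report$tree, file.path(outDir, "otu_tree.nwk"))
  for (rk in names(report$composition))
    wt(report$composition[[rk]], paste0("composition_", rk, ".tsv"),
       rn = TRUE)
  invisible(NULL)
}

#' @export
print.lsuPipelineReport <- function(x, ...) {
  cat("LSU amplicon pipeline report\n")
  cat("Samples:", paste(rownames(x$qcTally), collapse = ", "), "\n\n")
  cat("Read QC (counts; percentages relative to raw pairs):\n")
  print(round(x$qcTally, 1))
  cat("\nOTU richness (rarefied mean +/- sd at depth",
      x$richness$depth[1], "):\n")
  print(x$richness, row.names = FALSE)
  invisible(x)
}
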