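# Nearest-neighbor taxonomy assignment with lineage-consensus resolution
# and domain splitting.

#' Classification parameter set
#'
#' The nearest-neighbor search uses a seed-and-extend local alignment with
#' a fixed scoring scheme (match +1, mismatch -2, gap open -2, gap extend
#' -1); all references tied at the best score are kept. A hit is reported
#' only when it covers at least \code{minCoverage} of the query at
#' \code{minIdentity} identity or better; queries with no reported hit are
#' unclassified.
#'
#' @param minCoverage Minimum aligned fraction of the query.
#' @param minIdentity Minimum alignment identity.
#' @param wordSize Seed k-mer length for the candidate pre-screen.
#' @param maxCandidates Maximum candidate references aligned per query.
#' @param match,mismatch,gapOpen,gapExtend Alignment scores.
#' @return Named list of parameters.
#' @export
classifyParams <- function(minCoverage = 0.5, minIdentity = 0.5,
                           wordSize = 12L, maxCandidates = 32L,
                           match = 1L, mismatch = -2L, gapOpen = -2L,
                           gapExtend = -1L) {
  list(minCoverage = minCoverage, minIdentity = minIdentity,
       wordSize = as.integer(wordSize),
       maxCandidates = as.integer(maxCandidates),
       match = as.integer(match), mismatch = as.integer(mismatch),
       gapOpen = as.integer(gapOpen), gapExtend = as.integer(gapExtend))
}

#' Nearest reference neighbors of a query sequence
#'
#' Returns all references tied at the best local-alignment score, after
#' the reporting floor (coverage/identity) is applied.
#'
#' @param query A DNA string (length >= 50 recommended).
#' @param db A \code{\link{ReferenceDb}} (must be non-empty).
#' @param params See \code{\link{classifyParams}}.
#' @return data.frame with columns \code{ref_id}, \code{score},
#'   \code{identity} (identity of the best hit); zero rows when no hit
#'   clears the reporting threshold.
#' @export
nearestNeighbors <- function(query, db, params = classifyParams()) {
  if (length(db) == 0L) stop("empty reference set")
  res <- cpp_classify(as.character(query), as.character(refSequences(db)),
                      params$wordSize, params$maxCandidates,
                      params$minCoverage, params$minIdentity,
                      params$match, params$mismatch, params$gapOpen,
                      params$gapExtend)
  idx <- res$hits[[1]]
  data.frame(ref_id = refIds(db)[idx],
             score = rep(res$score[1], length(idx)),
             identity = rep(res$identity[1], length(idx)))
}

# lineages flagged as uncultured/unidentified placeholders
.isPlaceholderLineage <- function(lineage) {
  lab <- apply(lineage, 1, paste, collapse = " ")
  grepl("uncultured", lab, ignore.case = TRUE) |
    grepl("fungal_sp", lab, ignore.case = TRUE)
}

#' Resolve a set of candidate lineages to a consensus lineage
#'
#' Applies, in order: (1) lineages containing \code{"uncultured"} or
#' \code{"fungal_sp"} in any label (case-insensitive substring) are
#' demoted to all-unclassified and dropped when at least one non-demoted
#' lineage remains; (2) only lineages of maximal completeness are kept;
#' (3) at each rank the unique surviving label is emitted, otherwise the
#' rank is unclassified. Finally rank consistency is enforced: below the
#' first unclassified rank everything is unclassified. An empty input
#' yields an all-unclassified lineage.
#'
#' @param lineages A lineage matrix (rows = candidate lineages).
#' @return A single-row lineage matrix.
#' @export
#' @examples
#' resolveLineage(rbind(
#'   c("Fungi", "Basidiomycota", "Agaricomycetes", "Agaricales",
#'     "Mycenaceae", "Mycena", "Mycena chlorophos"),
#'   c("Fungi", "Basidiomycota", "Agaricomycetes", "Agaricales",
#'     "Marasmiaceae", "Marasmius", "Marasmius rotula")))
resolveLineage <- function(lineages) {
  if (is.null(lineages) || NROW(lineages) == 0L) return(emptyLineage(1L))
  lineages <- asLineage(lineages)
  demoted <- .isPlaceholderLineage(lineages)
  if (any(demoted)) {
    if (all(demoted)) {
      lineages <- emptyLineage(nrow(lineages))
    } else {
      lineages <- lineages[!demoted, , drop = FALSE]
    }
  }
  comp <- lineageCompleteness(lineages)
  lineages <- lineages[comp == max(comp), , drop = FALSE]
  out <- emptyLineage(1L)
  for (rk in taxRanks()) {
    lab <- unique(lineages[, rk])
    if (length(lab) == 1L) out[, rk] <- lab
  }
  # rank-consistency repair: truncate below the first unclassified rank
  uncl <- which(out[1, ] == unclassifiedLabel())
  if (length(uncl))
    out[1, seq(min(uncl), 7L)] <- unclassifiedLabel()
  out
}

# map a domain label to its reporting bin
.domainBin <- function(domain) {
  known <- c("Fungi", "Viridiplantae", "Metazoa")
  ifelse(domain %in% known, domain,
         ifelse(domain == unclassifiedLabel(), "unclassified", "other"))
}

#' Classify amplicons against a reference set
#'
#' Nearest-neighbor search for every query (identical queries are
#' dereplicated internally), lineage-consensus resolution over the tied
#' best hits, and domain binning.
#'
#' @param queries \code{DNAStringSet} (or character) of oriented merged
#'   amplicons.
#' @param db A \code{\link{ReferenceDb}}.
#' @param params See \code{\link{classifyParams}}.
#' @return \code{DataFrame} with \code{query_id}, the seven rank columns,
#'   \code{best_hits} (\code{CharacterList} of tied reference ids),
#'   \code{identity} and \code{domain_bin}.
#' @export
classifyReads <- function(queries, db, params = classifyParams()) {
  if (length(db) == 0L) stop("empty reference set")
  qs <- as.character(queries)
  ids <- names(qs)
  if (is.null(ids)) ids <- paste0("read", seq_along(qs))
  uq <- unique(qs)
  res <- cpp_classify(uq, as.character(refSequences(db)),
                      params$wordSize, params$maxCandidates,
                      params$minCoverage, params$minIdentity,
                      params$match, params$mismatch, params$gapOpen,
                      params$gapExtend)
  lin <- refLineages(db)
  uqLin <- matrix(unclassifiedLabel(), nrow = length(uq), ncol = 7L)
  uqHits <- vector("list", length(uq))
  for (i in seq_along(uq)) {
    idx <- res$hits[[i]]
    uqHits[[i]] <- refIds(db)[idx]
    uqLin[i, ] <- resolveLineage(lin[idx, , drop = FALSE])
  }
  m <- match(qs, uq)
  lineage <- asLineage(uqLin[m, , drop = FALSE])
  out <- S4Vectors::DataFrame(query_id = ids)
  for (rk in taxRanks()) out[[rk]] <- lineage[, rk]
  out$best_hits <- IRanges::CharacterList(uqHits[m])
  out$identity <- res$identity[m]
  out$domain_bin <- .domainBin(lineage[, "domain"])
  out
}

#' Split classified reads by domain
#'
#' Bins reads as Fungi / Viridiplantae / Metazoa / unclassified (domains
#' outside the three named ones are folded into unclassified for the
#' percentage table). Percentages are relative to the number of
#' high-quality merged reads.
#'
#' @param classified Output of \code{\link{classifyReads}}.
#' @param totalMerged Denominator for the percentages (defaults to the
#'   number of classified reads).
#' @return List with \code{bins} (list of query-id character vectors per
#'   bin) and \code{table} (data.frame: domain, count, percent).
#' @export
splitByDomain <- function(classified, totalMerged = nrow(classified)) {
  bin <- classified$domain_bin
  bin[bin == "other"] <- "unclassified"
  lev <- c("Fungi", "Viridiplantae", "Metazoa", "unclassified")
  bin <- factor(bin, levels = lev)
  counts <- table(bin)
  list(bins = split(classified$query_id, bin),
       table = data.frame(domain = lev,
                          count = as.integer(counts),
                          percent = 100 * as.integer(counts) /
                            max(1, totalMerged)))
}
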