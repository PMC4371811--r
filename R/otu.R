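# Per-sample OTU construction: dereplication, singleton removal, greedy
# 97% clustering, reference-based chimera filtering, read re-assignment.

#' Dereplicate amplicons into unique sequences with counts
#'
#' Exact-string dereplication; the result is sorted by count (descending),
#' ties broken lexicographically by sequence so the order is
#' deterministic. Counts are conserved.
#'
#' @param amplicons \code{DNAStringSet} or character vector of amplicon
#'   sequences.
#' @return data.frame with columns \code{sequence}, \code{count}.
#' @export
#' @examples
#' dereplicate(c("ACGT", "ACGT", "ACGA"))
dereplicate <- function(amplicons) {
  s <- as.character(amplicons)
  if (length(s) == 0L)
    return(data.frame(sequence = character(), count = integer()))
  tab <- table(s)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove singleton unique sequences
#'
#' Unique sequences observed exactly once are likely sequencing errors
#' and are excluded before clustering.
#'
#' @param uniques Output of \code{\link{dereplicate}}.
#' @param minCount Minimum count to keep (default 2).
#' @return The filtered data.frame.
#' @export
removeSingletons <- function(uniques, minCount = 2L) {
  out <- uniques[uniques$count >= minCount, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy centroid clustering at an identity threshold
#'
#' Unique sequences are visited in abundance order; each joins the first
#' existing centroid with global alignment identity at or above the
#' threshold, otherwise it founds a new centroid. Identity is matches /
#' alignment columns of an end-to-end alignment (terminal gaps
#' penalized).
#'
#' @param uniques Output of \code{\link{removeSingletons}} (must already
#'   be sorted by count desc, sequence asc -- \code{\link{dereplicate}}
#'   guarantees this).
#' @param threshold Identity threshold (default 0.97).
#' @return data.frame with columns \code{otu_id}, \code{centroid},
#'   \code{founding_count} (the centroid's own dereplicated count) in
#'   founding (abundance) order.
#' @export
clusterOtus <- function(uniques, threshold = 0.97) {
  if (nrow(uniques) == 0L)
    return(data.frame(otu_id = character(), centroid = character(),
                      founding_count = integer()))
  assign <- cpp_greedy_cluster(uniques$sequence, threshold)
  founder <- !duplicated(assign)
  data.frame(otu_id = sprintf("OTU_%04d", seq_len(sum(founder))),
             centroid = uniques$sequence[founder],
             founding_count = uniques$count[founder],
             stringsAsFactors = FALSE)
}

#' Reference-based two-parent chimera filter
#'
#' A centroid is flagged chimeric when a two-parent model (5' segment of
#' reference A spliced to the 3' segment of reference B at a single
#' breakpoint) explains it markedly better than any single reference:
#' model identity >= \code{modelIdentity}, best single-reference identity
#' <= model identity - \code{margin}, and each parent contributing at
#' least \code{minParentFrac} of the centroid. Parent candidates are
#' shortlisted by shared-k-mer counts.
#'
#' @param centroids Output of \code{\link{clusterOtus}} (or a character
#'   vector of centroid sequences).
#' @param db Reference \code{\link{ReferenceDb}}.
#' @param modelIdentity Minimum identity of the chimeric model.
#' @param margin Required advantage (identity points) of the model over
#'   the best single reference.
#' @param minParentFrac Minimum fraction of the centroid contributed by
#'   each parent.
#' @param nCandidates Parent candidates examined per centroid.
#' @return Logical vector: is each centroid chimeric?
#' @export
isChimeric <- function(centroids, db, modelIdentity = 0.99,
                       margin = 0.02, minParentFrac = 0.3,
                       nCandidates = 8L) {
  seqs <- if (is.data.frame(centroids)) centroids$centroid else
    as.character(centroids)
  n <- length(seqs)
  if (n == 0L) return(logical(0))
  refs <- as.character(refSequences(db))
  cand <- cpp_kmer_topn(seqs, refs, 12L, as.integer(nCandidates))
  out <- logical(n)
  for (i in seq_len(n)) {
    cidx <- cand[, i]
    cidx <- cidx[cidx > 0L]
    if (length(cidx) < 2L) next
    L <- nchar(seqs[i])
    prof <- lapply(cidx, function(j) cpp_match_profile(seqs[i], refs[j]))
    ident <- vapply(prof, mean, 0)
    bestSingle <- max(ident)
    lo <- ceiling(minParentFrac * L)
    hi <- L - lo
    if (hi < lo) next
    bestModel <- 0
    cums <- lapply(prof, function(p) cumsum(as.integer(p)))
    for (a in seq_along(cidx)) {
      for (b in seq_along(cidx)) {
        if (a == b) next
        # model matches for breakpoint k: left parent a, right parent b
        k <- lo:hi
        mm <- cums[[a]][k] + (cums[[b]][L] - cums[[b]][k])
        bestModel <- max(bestModel, max(mm) / L)
      }
    }
    out[i] <- bestModel >= modelIdentity &&
      bestSingle <= bestModel - margin
  }
  out
}

#' Drop chimeric centroids
#'
#' @inheritParams isChimeric
#' @return The non-chimeric subset of \code{centroids}.
#' @export
filterChimeras <- function(centroids, db, modelIdentity = 0.99,
                           margin = 0.02, minParentFrac = 0.3,
                           nCandidates = 8L) {
  flag <- isChimeric(centroids, db, modelIdentity, margin, minParentFrac,
                     nCandidates)
  if (is.data.frame(centroids)) {
    out <- centroids[!flag, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else centroids[!flag]
}

#' Re-assign unique reads to OTU centroids
#'
#' Every unique sequence (including singletons) maps to its best centroid
#' with global identity >= \code{threshold}; ties go to the more abundant
#' (earlier-founded) centroid. Unmapped uniques are tallied as
#' unassigned. Read counts are conserved: sum of OTU member counts plus
#' unassigned equals the sum of unique counts.
#'
#' @param uniques Output of \code{\link{dereplicate}} (all uniques,
#'   singletons included).
#' @param centroids Output of \code{\link{clusterOtus}} /
#'   \code{\link{filterChimeras}}.
#' @param threshold Identity cutoff (default 0.97).
#' @return List with \code{counts} (named integer, reads per OTU),
#'   \code{unassigned} (reads not mapping to any centroid) and
#'   \code{assignment} (integer index per unique, 0 = unassigned).
#' @export
reassignReads <- function(uniques, centroids, threshold = 0.97) {
  nOtu <- nrow(centroids)
  if (nrow(uniques) == 0L || nOtu == 0L)
    return(list(counts = setNames(integer(nOtu), centroids$otu_id),
                unassigned = sum(uniques$count),
                assignment = integer(nrow(uniques))))
  res <- cpp_assign_centroids(uniques$sequence, centroids$centroid,
                              threshold)
  counts <- integer(nOtu)
  hit <- res$index > 0L
  if (any(hit)) {
    agg <- tapply(uniques$count[hit], res$index[hit], sum)
    counts[as.integer(names(agg))] <- as.integer(agg)
  }
  list(counts = setNames(counts, centroids$otu_id),
       unassigned = sum(uniques$count[!hit]),
       assignment = res$index)
}

#' Per-sample OTU analysis
#'
#' Dereplication, singleton removal, greedy 97\% clustering, reference
#' chimera filtering and re-assignment of all unique reads, with read
#' accounting. Re-assignment includes singletons; the tally reports both
#' the with- and without-singleton read totals.
#'
#' @param amplicons Oriented fungal amplicons (\code{DNAStringSet} or
#'   character).
#' @param db Reference \code{\link{ReferenceDb}} used for chimera
#'   filtering.
#' @param threshold Clustering / re-assignment identity (default 0.97).
#' @param ... Passed to \code{\link{isChimeric}}.
#' @return List with \code{otus} (data.frame: otu_id, centroid, count),
#'   \code{unassigned}, and \code{tally} (reads, uniques, singletons,
#'   otusBeforeChimera, chimeric, otus).
#' @export
buildOtuSample <- function(amplicons, db, threshold = 0.97, ...) {
  uniq <- dereplicate(amplicons)
  nonsingle <- removeSingletons(uniq)
  cent <- clusterOtus(nonsingle, threshold)
  chim <- isChimeric(cent, db, ...)
  kept <- cent[!chim, , drop = FALSE]
  rownames(kept) <- NULL
  asg <- reassignReads(uniq, kept, threshold)
  list(otus = data.frame(otu_id = kept$otu_id, centroid = kept$centroid,
                         count = as.integer(asg$counts),
                         stringsAsFactors = FALSE),
       unassigned = asg$unassigned,
       tally = c(reads = sum(uniq$count), uniques = nrow(uniq),
                 singletons = nrow(uniq) - nrow(nonsingle),
                 otusBeforeChimera = nrow(cent),
                 chimeric = sum(chim), otus = nrow(kept)))
}
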