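# Paired-end amplicon QC: primer qualification, trimming, overlap merging,
# sliding-window quality filtering and orientation.

#' The fungal-specific LSU (28S rDNA) primer pair
#'
#' The amplicon targeted by this pair covers a variable region of the
#' large-subunit rDNA; with primers included, amplicons are expected at
#' 167--218 bp.
#'
#' @return Named character vector with elements \code{forward} (18 nt) and
#'   \code{reverse} (20 nt).
#' @export
#' @examples
#' lsuPrimers()
lsuPrimers <- function() {
  c(forward = "AACACGGACCAAGGAGTC", reverse = "CAGGCATAGTTCACCATCTT")
}

#' QC parameter set
#'
#' Defaults follow the protocol this pipeline implements: merging requires
#' at least 10 bp of overlap, merged reads shorter than 100 bp are
#' discarded, and every 5 bp sliding window must average Phred >= 30.
#'
#' @param minOverlap Minimum overlap (bp) for merging.
#' @param minMergedLen Minimum merged read length (bp).
#' @param window Sliding-window size (bp) for the quality filter.
#' @param minMeanQ Minimum mean Phred per window.
#' @param maxPrimerMismatches Substitutions tolerated in a whole-primer
#'   match.
#' @param maxMismatchDensity Maximum mismatch fraction in the merge
#'   overlap (the merger's default).
#' @return A named list of validated parameters.
#' @export
qcParams <- function(minOverlap = 10L, minMergedLen = 100L, window = 5L,
                     minMeanQ = 30, maxPrimerMismatches = 2L,
                     maxMismatchDensity = 0.25) {
  p <- list(minOverlap = as.integer(minOverlap),
            minMergedLen = as.integer(minMergedLen),
            window = as.integer(window), minMeanQ = minMeanQ,
            maxPrimerMismatches = as.integer(maxPrimerMismatches),
            maxMismatchDensity = maxMismatchDensity)
  stopifnot(p$minOverlap > 0, p$minMergedLen > 0, p$window > 0,
            p$minMeanQ > 0, p$maxPrimerMismatches >= 0,
            p$maxMismatchDensity >= 0)
  p
}

#' Find whole-primer hits on a read
#'
#' Scans the plus strand with the primer as given and the minus strand via
#' the primer's reverse complement. Hits are ungapped, cover the whole
#' primer, and allow at most \code{maxMismatches} substitutions.
#'
#' @param read A DNA string (character or \code{DNAString}).
#' @param primer Primer sequence.
#' @param maxMismatches Substitution tolerance.
#' @return data.frame with columns \code{start}, \code{end} (0-based,
#'   half-open) and \code{strand} (\code{"+"}/\code{"-"}).
#' @export
#' @examples
#' findPrimerHits(paste0(lsuPrimers()["forward"], "ACGTACGT"),
#'                lsuPrimers()["forward"])
findPrimerHits <- function(read, primer, maxMismatches = 2L) {
  read <- Biostrings::DNAString(as.character(read))
  primer <- Biostrings::DNAString(as.character(primer))
  hit <- function(p, strand) {
    m <- Biostrings::matchPattern(p, read, max.mismatch = maxMismatches,
                                  with.indels = FALSE)
    if (length(m) == 0L)
      return(data.frame(start = integer(), end = integer(),
                        strand = character()))
    data.frame(start = Biostrings::start(m) - 1L,
               end = Biostrings::end(m), strand = strand)
  }
  out <- rbind(hit(primer, "+"),
               hit(Biostrings::reverseComplement(primer), "-"))
  out[order(out$start), , drop = FALSE]
}

# vectorized plus-strand whole-primer matches over a DNAStringSet;
# returns an IRangesList
.primerMatches <- function(seqs, primer, maxMismatches) {
  Biostrings::vmatchPattern(primer, seqs, max.mismatch = maxMismatches,
                            with.indels = FALSE)
}

#' Qualify and trim read pairs on primer evidence
#'
#' A mate is qualified when exactly one whole primer (forward or reverse)
#' aligns once on its plus strand; a pair is qualified when both mates are
#' qualified and the two primers differ (they "form a pair"). Qualified
#' mates are trimmed so that nothing lies outside the primer: bases 5' of
#' the primer start are removed (the primer itself is retained) and, when
#' the opposite primer's reverse complement is also present (read-through),
#' bases 3' of that site are removed too. In the read-through case the
#' mate must also contain both primers whenever it is long enough to span
#' the implied amplicon.
#'
#' @param r1,r2 \code{QualityScaledDNAStringSet} of mate-1 / mate-2 reads.
#' @param primers Primer pair, see \code{\link{lsuPrimers}}.
#' @param params See \code{\link{qcParams}}.
#' @return List with \code{qualified} (logical per input pair), trimmed
#'   \code{r1}, \code{r2} (qualified pairs only, mate-1 oriented so that it
#'   carries the forward primer is NOT enforced here), and
#'   \code{primer1}, \code{primer2} (\code{"F"}/\code{"R"} per qualified
#'   pair).
#' @export
qualifyPairs <- function(r1, r2, primers = lsuPrimers(),
                         params = qcParams()) {
  stopifnot(length(r1) == length(r2))
  n <- length(r1)
  mm <- params$maxPrimerMismatches
  fwd <- Biostrings::DNAString(primers[["forward"]])
  rev <- Biostrings::DNAString(primers[["reverse"]])
  s1 <- as(r1, "DNAStringSet")
  s2 <- as(r2, "DNAStringSet")
  mate <- function(seqs) {
    plusF <- .primerMatches(seqs, fwd, mm)
    plusR <- .primerMatches(seqs, rev, mm)
    minusF <- .primerMatches(seqs, Biostrings::reverseComplement(fwd), mm)
    minusR <- .primerMatches(seqs, Biostrings::reverseComplement(rev), mm)
    nF <- lengths(plusF); nR <- lengths(plusR)
    ok <- (nF + nR) == 1L
    prm <- ifelse(nF == 1L, "F", ifelse(nR == 1L, "R", NA))
    prm[!ok] <- NA
    start <- rep(NA_integer_, length(seqs))
    start[ok & prm == "F"] <- unlist(IRanges::start(plusF[ok & prm == "F"]),
                                     use.names = FALSE)
    start[ok & prm == "R"] <- unlist(IRanges::start(plusR[ok & prm == "R"]),
                                     use.names = FALSE)
    # 3' site of the opposite primer (read-through), if any, after the
    # plus primer
    oppEnd <- rep(NA_integer_, length(seqs))
    for (i in which(ok)) {
      opp <- if (prm[i] == "F") minusR[[i]] else minusF[[i]]
      if (length(opp)) {
        e <- max(IRanges::end(opp))
        if (e > start[i]) oppEnd[i] <- e
      }
    }
    list(ok = ok, primer = prm, start = start, oppEnd = oppEnd)
  }
  m1 <- mate(s1)
  m2 <- mate(s2)
  qualified <- m1$ok & m2$ok & !is.na(m1$primer) & !is.na(m2$primer) &
    m1$primer != m2$primer
  # read-through consistency: if one mate shows both primers, the other
  # must too when long enough to span the implied amplicon
  both1 <- !is.na(m1$oppEnd)
  both2 <- !is.na(m2$oppEnd)
  imp1 <- m1$oppEnd - m1$start + 1L
  imp2 <- m2$oppEnd - m2$start + 1L
  w1 <- Biostrings::width(s1)
  w2 <- Biostrings::width(s2)
  bad <- (qualified & both1 & !both2 & w2 >= imp1) |
    (qualified & both2 & !both1 & w1 >= imp2)
  qualified[bad] <- FALSE
  keep <- which(qualified)
  trim <- function(x, m, idx) {
    w <- Biostrings::width(x)
    from <- m$start[idx]
    to <- ifelse(is.na(m$oppEnd[idx]), w[idx], m$oppEnd[idx])
    IRanges::narrow(x[idx], start = from, end = to)
  }
  list(qualified = qualified,
       r1 = trim(r1, m1, keep),
       r2 = trim(r2, m2, keep),
       primer1 = m1$primer[keep],
       primer2 = m2$primer[keep])
}

#' Merge qualified read pairs by overlap
#'
#' Mate 2 is reverse complemented, then the overlap (length >=
#' \code{minOverlap}, mismatch fraction <= \code{maxMismatchDensity})
#' maximizing the number of matching bases is used; ties prefer the longer
#' overlap. Disagreeing overlap bases take the higher-quality call and the
#' overlap quality is the per-base maximum of the two mates. Merged reads
#' shorter than \code{minMergedLen} are discarded (status
#' \code{"tooShort"}); pairs with no admissible overlap get status
#' \code{"unmerged"}.
#'
#' @param r1,r2 Trimmed, qualified mates (\code{QualityScaledDNAStringSet}).
#' @param params See \code{\link{qcParams}}.
#' @return List with \code{merged} (a \code{QualityScaledDNAStringSet} of
#'   the successfully merged amplicons) and \code{status} (factor per input
#'   pair: \code{merged}, \code{unmerged}, \code{tooShort}).
#' @export
mergePairs <- function(r1, r2, params = qcParams()) {
  stopifnot(length(r1) == length(r2))
  if (length(r1) == 0L)
    return(list(merged = .makeQSD(character(), list()),
                status = factor(character(),
                                levels = c("merged", "unmerged",
                                           "tooShort"))))
  s2rc <- Biostrings::reverseComplement(as(r2, "DNAStringSet"))
  q1 <- as.list(.qualInts(r1))
  q2 <- lapply(as.list(.qualInts(r2)), rev)
  res <- cpp_merge_pairs(as.character(as(r1, "DNAStringSet")), q1,
                         as.character(s2rc), q2, params$minOverlap,
                         params$maxMismatchDensity, params$minMergedLen)
  status <- factor(c("unmerged", "merged", "tooShort")[res$status + 1L],
                   levels = c("merged", "unmerged", "tooShort"))
  ok <- which(res$status == 1L)
  ids <- names(r1)
  merged <- .makeQSD(unlist(res$sequence[ok], use.names = FALSE),
                     res$quality[ok],
                     if (!is.null(ids)) ids[ok] else NULL)
  list(merged = merged, status = status)
}

#' Sliding-window quality filter
#'
#' A merged read passes when every sliding window of \code{window} bases
#' (step 1) has mean Phred quality at least \code{minMeanQ}; a read
#' shorter than the window is one window of its full length. The exact
#' boundary (mean equal to the threshold) passes.
#'
#' @param x \code{QualityScaledDNAStringSet} of merged reads.
#' @param params See \code{\link{qcParams}}.
#' @return Logical vector: pass?
#' @export
windowQualityFilter <- function(x, params = qcParams()) {
  w <- params$window
  thr <- params$minMeanQ
  vapply(as.list(.qualInts(x)), function(q) {
    n <- length(q)
    if (n == 0L) return(FALSE)
    if (n <= w) return(mean(q) >= thr)
    cs <- cumsum(c(0, q))
    sums <- cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]
    min(sums) / w >= thr
  }, logical(1))
}

#' Orient merged amplicons so the forward primer is at the 5' end
#'
#' Amplicons whose reverse complement carries the forward primer at its 5'
#' end (i.e. the merge produced the minus strand) are reverse
#' complemented. Amplicons matching neither orientation are flagged
#' (\code{mcols(x)$oriented == FALSE}) with a warning: after
#' qualification this cannot occur and signals pipeline misuse.
#'
#' @param x \code{QualityScaledDNAStringSet} of merged amplicons.
#' @param primers See \code{\link{lsuPrimers}}.
#' @param maxMismatches Substitution tolerance for the primer check.
#' @return \code{x} re-oriented, with an \code{oriented} metadata column.
#' @export
orientAmplicons <- function(x, primers = lsuPrimers(),
                            maxMismatches = 2L) {
  if (length(x) == 0L) {
    S4Vectors::mcols(x)$oriented <- logical(0)
    return(x)
  }
  fwd <- Biostrings::DNAString(primers[["forward"]])
  s <- as(x, "DNAStringSet")
  nf <- Biostrings::neditStartingAt(fwd, s, starting.at = 1,
                                    with.indels = FALSE)
  isFwd <- nf <= maxMismatches & Biostrings::width(s) >= length(fwd)
  src <- Biostrings::reverseComplement(s)
  nr <- Biostrings::neditStartingAt(fwd, src, starting.at = 1,
                                    with.indels = FALSE)
  isRev <- !isFwd & nr <= maxMismatches &
    Biostrings::width(s) >= length(fwd)
  if (any(isRev)) {
    quals <- as.list(.qualInts(x))
    flip <- .makeQSD(as.character(src[isRev]),
                     lapply(quals[isRev], rev), names(x)[isRev])
    out <- c(x[!isRev], flip)[order(c(which(!isRev), which(isRev)))]
  } else out <- x
  oriented <- isFwd | isRev
  if (!all(oriented))
    warning(sum(!oriented), " amplicon(s) carry no forward-primer motif ",
            "in either orientation")
  S4Vectors::mcols(out)$oriented <- oriented
  out
}

#' Run the full per-sample read QC
#'
#' Qualification, trimming, merging, window quality filtering and
#' orientation, with per-stage read accounting (raw pairs = qualified +
#' unqualified; qualified = merged + unmerged + too-short; merged =
#' high-quality + failed-quality).
#'
#' @param r1,r2 Mate FASTQ paths or \code{QualityScaledDNAStringSet}s.
#' @param primers See \code{\link{lsuPrimers}}.
#' @param params See \code{\link{qcParams}}.
#' @return List with \code{amplicons} (oriented, high-quality merged
#'   reads) and \code{tally} (named numeric: rawPairs, qualified, merged,
#'   unmerged, tooShort, highQuality, pctMerged, pctHighQuality;
#'   percentages relative to raw pairs).
#' @export
qcSample <- function(r1, r2, primers = lsuPrimers(), params = qcParams()) {
  if (is.character(r1)) r1 <- readFastqReads(r1)
  if (is.character(r2)) r2 <- readFastqReads(r2)
  qual <- qualifyPairs(r1, r2, primers, params)
  mrg <- mergePairs(qual$r1, qual$r2, params)
  hq <- windowQualityFilter(mrg$merged, params)
  amp <- orientAmplicons(mrg$merged[hq], primers)
  tally <- c(rawPairs = length(r1),
             qualified = sum(qual$qualified),
             merged = sum(mrg$status == "merged"),
             unmerged = sum(mrg$status == "unmerged"),
             tooShort = sum(mrg$status == "tooShort"),
             highQuality = sum(hq))
  tally <- c(tally,
             pctMerged = 100 * tally[["merged"]] /
               max(1, tally[["rawPairs"]]),
             pctHighQuality = 100 * tally[["highQuality"]] /
               max(1, tally[["rawPairs"]]))
  list(amplicons = amp, tally = tally)
}
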