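# Community comparison: amplicon length spectra, rarefaction, in-silico
# PCR of references, neighbor-joining trees, UniFrac distances, PCoA and
# taxonomy composition summaries.

#' Length distribution of merged amplicons
#'
#' @param amplicons \code{DNAStringSet}/character (or a
#'   \code{QualityScaledDNAStringSet}).
#' @return List with \code{histogram} (named integer table of lengths),
#'   \code{mode} (modal length) and \code{range}.
#' @export
lengthDistribution <- function(amplicons) {
  w <- if (is(amplicons, "XStringSet")) Biostrings::width(amplicons) else
    nchar(as.character(amplicons))
  if (length(w) == 0L)
    return(list(histogram = table(integer()), mode = NA_integer_,
                range = c(NA_integer_, NA_integer_)))
  h <- table(w)
  list(histogram = h,
       mode = as.integer(names(h)[which.max(h)]),
       range = range(w))
}

#' Rarefaction curve by repeated subsampling without replacement
#'
#' At each depth the reads are subsampled without replacement
#' \code{repeats} times and the number of distinct OTUs observed is
#' recorded; the mean and standard deviation over repeats are reported
#' (the "mean +/- sd" rarefied richness format).
#'
#' @param otuCounts Named integer vector: reads per OTU for one sample
#'   (or a per-read vector of OTU ids).
#' @param depths Integer vector of subsampling depths; depths above the
#'   read total are clamped with a warning.
#' @param repeats Number of resamples per depth (default 100).
#' @param seed RNG seed (default 1).
#' @return data.frame with columns \code{depth}, \code{mean}, \code{sd}.
#' @export
rarefactionCurve <- function(otuCounts, depths, repeats = 100L,
                             seed = 1L) {
  if (is.character(otuCounts) || is.factor(otuCounts)) {
    labels <- as.integer(factor(otuCounts))
  } else {
    labels <- rep(seq_along(otuCounts), otuCounts)
  }
  n <- length(labels)
  depths <- as.integer(depths)
  if (any(depths > n)) {
    warning("depth(s) above the read total were clamped to ", n)
    depths[depths > n] <- n
  }
  stopifnot(all(depths >= 1L))
  set.seed(seed)
  out <- lapply(depths, function(d) {
    rich <- replicate(repeats, {
      length(unique(labels[sample.int(n, d)]))
    })
    c(depth = d, mean = mean(rich), sd = stats::sd(rich))
  })
  as.data.frame(do.call(rbind, out))
}

#' In-silico PCR: extract primer-delimited segments from references
#'
#' A reference is kept when the forward primer and the reverse
#' complement of the reverse primer both occur (whole-primer, ungapped,
#' at most \code{maxMismatches} substitutions each) on the plus strand in
#' the correct orientation, with the implied amplicon length inside
#' \code{lengthWindow}. The extracted segment runs from the forward
#' primer start to the reverse binding-site end, primers included. When
#' several site pairs are admissible the leftmost forward site with its
#' nearest admissible reverse site is used.
#'
#' @param db A \code{\link{ReferenceDb}}.
#' @param primers See \code{\link{lsuPrimers}}.
#' @param maxMismatches Per-primer substitution tolerance.
#' @param lengthWindow Admissible amplicon length range (bp).
#' @return \code{DNAStringSet} of extracted segments, named by the kept
#'   reference ids.
#' @export
inSilicoPcr <- function(db, primers = lsuPrimers(), maxMismatches = 2L,
                        lengthWindow = c(1L, 300L)) {
  seqs <- refSequences(db)
  fwd <- Biostrings::DNAString(primers[["forward"]])
  rcRev <- Biostrings::reverseComplement(
    Biostrings::DNAString(primers[["reverse"]]))
  fh <- .primerMatches(seqs, fwd, maxMismatches)
  rh <- .primerMatches(seqs, rcRev, maxMismatches)
  segs <- character(0)
  keep <- character(0)
  for (i in seq_along(seqs)) {
    fs <- IRanges::start(fh[[i]])
    re <- IRanges::end(rh[[i]])
    if (length(fs) == 0L || length(re) == 0L) next
    found <- FALSE
    for (s in sort(fs)) {
      e <- re[re >= s + length(fwd)]
      e <- e[e - s + 1L >= lengthWindow[1] & e - s + 1L <= lengthWindow[2]]
      if (length(e)) {
        segs <- c(segs, as.character(Biostrings::subseq(seqs[[i]], s,
                                                        min(e))))
        keep <- c(keep, refIds(db)[i])
        found <- TRUE
        break
      }
    }
  }
  Biostrings::DNAStringSet(setNames(segs, keep))
}

#' Neighbor-joining tree over sequences
#'
#' Pairwise p-distances (1 - global alignment identity; gaps count as
#' differences) feed a neighbor-joining reconstruction; negative NJ
#' branch lengths are clamped to zero and the tree is rooted at its
#' midpoint. With fewer than three sequences a star (or single-leaf)
#' tree is returned with zero-length branches.
#'
#' @param seqs Named \code{DNAStringSet} or character vector (names
#'   become leaf labels).
#' @return An \code{ape::phylo} tree whose leaves are the input names.
#' @export
buildTree <- function(seqs) {
  ids <- names(seqs)
  s <- unname(as.character(seqs))
  if (is.null(ids)) ids <- paste0("seq", seq_along(s))
  n <- length(s)
  if (n == 0L) stop("no sequences")
  if (n < 3L) {
    txt <- if (n == 1L) paste0("(", ids[1], ":0);") else
      paste0("(", ids[1], ":0,", ids[2], ":0);")
    return(ape::read.tree(text = txt))
  }
  d <- cpp_pdist(s)
  dimnames(d) <- list(ids, ids)
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  phangorn::midpoint(tree)
}

#' UniFrac distances between samples
#'
#' Unweighted: the branch length leading only to leaves present in
#' exactly one of the two samples, divided by the branch length leading
#' to leaves present in either. Weighted (normalized): \eqn{\sum_b l_b
#' |p_{Ab} - p_{Bb}| / \sum_b l_b (p_{Ab} + p_{Bb})}, where \eqn{p_{Xb}}
#' is the fraction of sample X's reads descending from branch b; the
#' normalization keeps distances in [0, 1] and makes them invariant to
#' each sample's sequencing depth.
#'
#' @param tree \code{ape::phylo}; leaf labels must cover the count
#'   columns.
#' @param counts Sample x OTU matrix of read counts (column names =
#'   leaf labels), or an \code{\link{OtuExperiment}} (transposed
#'   internally).
#' @param mode \code{"weighted"} or \code{"unweighted"}.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
unifrac <- function(tree, counts, mode = c("weighted", "unweighted")) {
  mode <- match.arg(mode)
  if (is(counts, "OtuExperiment")) counts <- t(otuCounts(counts))
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0))
    stop("sample(s) with zero reads: ",
         paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
  tips <- tree$tip.label
  miss <- setdiff(colnames(counts), tips)
  if (length(miss))
    stop("count columns absent from the tree: ",
         paste(utils::head(miss), collapse = ", "))
  nTip <- length(tips)
  nSamp <- nrow(counts)
  tr <- ape::reorder.phylo(tree, "postorder")
  nNode <- nTip + tr$Nnode
  acc <- matrix(0, nrow = nNode, ncol = nSamp)
  idx <- match(tips, colnames(counts))
  hasCol <- !is.na(idx)
  acc[which(hasCol), ] <- t(counts[, idx[hasCol], drop = FALSE])
  for (e in seq_len(nrow(tr$edge)))
    acc[tr$edge[e, 1], ] <- acc[tr$edge[e, 1], ] + acc[tr$edge[e, 2], ]
  totals <- rowSums(counts)
  # per-edge fraction of each sample's reads descending from the edge
  p <- sweep(acc[tr$edge[, 2], , drop = FALSE], 2, totals, "/")
  len <- tr$edge.length
  if (is.null(len)) len <- rep(0, nrow(tr$edge))
  len[is.na(len)] <- 0
  d <- matrix(0, nSamp, nSamp,
              dimnames = list(rownames(counts), rownames(counts)))
  for (a in seq_len(nSamp - 1)) {
    for (b in (a + 1):nSamp) {
      pa <- p[, a]
      pb <- p[, b]
      if (mode == "weighted") {
        den <- sum(len * (pa + pb))
        val <- if (den > 0) sum(len * abs(pa - pb)) / den else 0
      } else {
        inA <- pa > 0
        inB <- pb > 0
        den <- sum(len[inA | inB])
        val <- if (den > 0) sum(len[xor(inA, inB)]) / den else 0
      }
      d[a, b] <- val
      d[b, a] <- val
    }
  }
  d
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric ordination: double-centering of \eqn{-D^2/2} and
#' eigendecomposition. Negative eigenvalues are reported but excluded
#' from the variance denominator; axes are ordered by eigenvalue.
#'
#' @param d Symmetric distance matrix (or \code{dist}).
#' @return List with \code{points} (samples x axes), \code{eig} (all
#'   eigenvalues) and \code{varExplained} (fraction of variance per
#'   positive axis).
#' @export
ordinatePcoa <- function(d) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  # cmdscale warns when fewer than k eigenvalues are positive (e.g. for
  # identical samples); the positive subspace is extracted below anyway
  res <- suppressWarnings(stats::cmdscale(d, k = max(1L, n - 1L),
                                          eig = TRUE))
  eig <- res$eig
  pos <- eig > 1e-12
  points <- res$points
  if (sum(pos) == 0L)
    points <- matrix(0, n, 1L, dimnames = list(attr(d, "Labels"), NULL))
  else if (ncol(points) > sum(pos))
    points <- points[, seq_len(sum(pos)), drop = FALSE]
  list(points = points, eig = eig,
       varExplained = if (any(pos)) eig[pos] / sum(eig[pos]) else
         numeric(0))
}

#' Taxonomy composition summary per sample
#'
#' At a taxonomic level, read fractions are computed per sample; the
#' \code{topK} taxa by mean fraction across samples are listed, the
#' remaining classified taxa are lumped into \code{"others"}, and the
#' remainder to 100\% is the unclassified fraction at that level.
#'
#' @param lineage Lineage matrix, one row per OTU.
#' @param counts Sample x OTU count matrix (or a named vector for one
#'   sample).
#' @param level One of \code{taxRanks()}.
#' @param topK Number of taxa listed (the convention is 15, and 5 at the
#'   phylum level).
#' @return data.frame: rows = topK taxa + \code{others} +
#'   \code{unclassified}, columns = samples, entries = fractions summing
#'   to 1 per sample.
#' @export
compositionSummary <- function(lineage, counts, level = "genus",
                               topK = 15L) {
  stopifnot(level %in% taxRanks())
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list("sample1",
                                                             names(counts)))
  counts <- as.matrix(counts)
  lineage <- asLineage(lineage)
  stopifnot(ncol(counts) == nrow(lineage))
  lab <- lineage[, level]
  totals <- rowSums(counts)
  frac <- sweep(counts, 1, pmax(totals, 1), "/")
  classified <- lab != unclassifiedLabel()
  taxa <- unique(lab[classified])
  byTaxon <- vapply(taxa, function(tx)
    rowSums(frac[, lab == tx, drop = FALSE]), numeric(nrow(counts)))
  if (nrow(counts) == 1L) byTaxon <- matrix(byTaxon, nrow = 1,
                                            dimnames = list(
                                              rownames(counts), taxa))
  ord <- order(colMeans(byTaxon), decreasing = TRUE)
  top <- utils::head(ord, topK)
  rest <- setdiff(ord, top)
  out <- t(byTaxon[, top, drop = FALSE])
  others <- if (length(rest)) colSums(t(byTaxon[, rest, drop = FALSE]))
    else numeric(nrow(counts))
  unclassified <- 1 - colSums(out) - others
  res <- rbind(out, others = others,
               unclassified = pmax(unclassified, 0))
  as.data.frame(res)
}
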