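# Shared fixtures and independent oracles. Oracles deliberately use
# different code paths (Biostrings::pairwiseAlignment, phangorn edge
# enumeration, closed forms) than the implementation they check.

FWD <- LSUpipe::lsuPrimers()[["forward"]]
REV <- LSUpipe::lsuPrimers()[["reverse"]]
RCREV <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(REV)))
RCFWD <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(FWD)))

randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate a sequence with k substitutions
mutateSeq <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  pos <- sample(seq_along(v), k)
  v[pos] <- vapply(v[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  paste(v, collapse = "")
}

# QualityScaledDNAStringSet from sequences (+ constant or per-read quals)
makeReads <- function(seqs, qual = 38L, ids = NULL) {
  if (is.null(ids)) ids <- paste0("r", seq_along(seqs))
  quals <- if (is.list(qual)) qual else if (length(qual) > 1L) list(qual)
    else lapply(nchar(seqs), function(n) rep(qual, n))
  qs <- Biostrings::PhredQuality(vapply(quals, function(q)
    intToUtf8(q + 33L), ""))
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(seqs, ids)), qs)
}

# a read pair covering `amplicon` from both ends (mate2 = reverse strand)
perfectPair <- function(amplicon, l1, l2, qual = 38L, id = "p1") {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(amplicon)))
  list(r1 = makeReads(substr(amplicon, 1, l1), qual, id),
       r2 = makeReads(substr(rc, 1, l2), qual, id))
}

# a primer-flanked amplicon with a random insert
makeAmplicon <- function(insertLen) {
  paste0(FWD, randSeq(insertLen), RCREV)
}

# --- independent oracle: global alignment via pairwiseAlignment ----------
# same objective as the package's scheme (match +1, mismatch -2, gap -2
# per column, terminal gaps penalized)
oracleGlobal <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  pwa <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 2,
                                       type = "global")
  aln <- nchar(as.character(Biostrings::alignedPattern(pwa)))
  list(score = Biostrings::score(pwa),
       identity = Biostrings::nmatch(pwa) / aln)
}

# greedy clustering recomputed from exhaustive oracle identities
oracleCluster <- function(seqs, threshold = 0.97) {
  n <- length(seqs)
  assign <- integer(n)
  centroids <- integer(0)
  for (i in seq_len(n)) {
    hit <- 0L
    for (c in centroids) {
      if (oracleGlobal(seqs[i], seqs[c])$identity >= threshold) {
        hit <- match(c, centroids)
        break
      }
    }
    if (hit == 0L) {
      centroids <- c(centroids, i)
      hit <- length(centroids)
    }
    assign[i] <- hit
  }
  assign
}

# --- independent oracle: UniFrac by explicit branch enumeration ----------
oracleUnifrac <- function(tree, counts, mode) {
  samples <- rownames(counts)
  totals <- rowSums(counts)
  edges <- tree$edge
  len <- tree$edge.length
  ntip <- length(tree$tip.label)
  d <- matrix(0, nrow(counts), nrow(counts),
              dimnames = list(samples, samples))
  # descendant tip sets per edge, via phangorn
  desc <- phangorn::Descendants(tree, edges[, 2], type = "tips")
  for (a in seq_len(nrow(counts) - 1)) {
    for (b in (a + 1):nrow(counts)) {
      num <- 0
      den <- 0
      for (e in seq_len(nrow(edges))) {
        tips <- tree$tip.label[desc[[e]]]
        ca <- sum(counts[a, tips])
        cb <- sum(counts[b, tips])
        if (mode == "weighted") {
          pa <- ca / totals[a]
          pb <- cb / totals[b]
          num <- num + len[e] * abs(pa - pb)
          den <- den + len[e] * (pa + pb)
        } else {
          inA <- ca > 0
          inB <- cb > 0
          if (xor(inA, inB)) num <- num + len[e]
          if (inA || inB) den <- den + len[e]
        }
      }
      d[a, b] <- d[b, a] <- if (den > 0) num / den else 0
    }
  }
  d
}

# small shared synthetic reference set (built once per test run)
tinyRefs <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- LSUpipe::generateReferenceDb(nTaxa = 60, seed = 42,
                                             nDecoyRecords = 8)
    cache
  }
})
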