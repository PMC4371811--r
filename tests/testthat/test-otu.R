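test_that("dereplication collapses exact duplicates and conserves counts", {
  u <- dereplicate(c("ACGT", "ACGT", "ACGA"))
  expect_equal(u$sequence, c("ACGT", "ACGA"))
  expect_equal(u$count, c(2L, 1L))
  expect_equal(nrow(dereplicate(character())), 0L)
  # deterministic tie-break: equal counts sort lexicographically
  u2 <- dereplicate(c("TTTT", "AAAA", "CCCC"))
  expect_equal(u2$sequence, c("AAAA", "CCCC", "TTTT"))
  # reads drawn from 3 templates, no error -> 3 uniques
  set.seed(21)
  tpl <- vapply(1:3, function(i) randSeq(120), "")
  reads <- sample(tpl, 1000, replace = TRUE)
  u3 <- dereplicate(reads)
  expect_equal(nrow(u3), 3L)
  expect_equal(sum(u3$count), 1000L)
})

test_that("singleton removal drops count-1 uniques only", {
  u <- data.frame(sequence = c("AAAA", "CCCC"), count = c(5L, 1L))
  expect_equal(removeSingletons(u)$sequence, "AAAA")
  all1 <- data.frame(sequence = c("AAAA", "CCCC"), count = c(1L, 1L))
  expect_equal(nrow(removeSingletons(all1)), 0L)
  all2 <- data.frame(sequence = c("AAAA", "CCCC"), count = c(2L, 3L))
  expect_equal(nrow(removeSingletons(all2)), 2L)
})

test_that("greedy 97% clustering matches the exhaustive pairwise-identity oracle", {
  set.seed(22)
  # mixed pool: 6 divergent templates, mutated copies at 1-4 subs,
  # plus a couple of in-between sequences
  tpl <- vapply(1:6, function(i) randSeq(160), "")
  seqs <- c(tpl, unlist(lapply(tpl, function(t)
    vapply(1:3, function(k) mutateSeq(t, sample(1:4, 1)), ""))))
  counts <- sample(2:50, length(seqs), replace = TRUE)
  u <- data.frame(sequence = seqs, count = counts,
                  stringsAsFactors = FALSE)
  u <- u[order(-u$count, u$sequence), ]
  rownames(u) <- NULL
  cent <- clusterOtus(u)
  oraAssign <- oracleCluster(u$sequence)
  # greedy clustering is fully determined by the centroid (founder) set:
  # the oracle's founders must equal the implementation's centroids
  founders <- u$sequence[!duplicated(oraAssign)]
  expect_identical(cent$centroid, founders)
  # two sequences 98% identical plus one 80% to both -> 2 OTUs
  a <- randSeq(150)
  b <- mutateSeq(a, 3) # 147/150 matches = 98%
  c_ <- mutateSeq(a, 30) # 80%
  u2 <- data.frame(sequence = c(a, b, c_), count = c(9L, 5L, 3L))
  expect_equal(nrow(clusterOtus(u2)), 2L)
  expect_equal(length(unique(oracleCluster(u2$sequence))), 2L)
  # all identical -> 1 OTU
  u3 <- data.frame(sequence = rep(a, 3), count = c(3L, 2L, 2L))
  expect_equal(nrow(clusterOtus(dereplicate(rep(a, 3)))), 1L)
  # 10 mutually <90% templates, error-free -> 10 OTUs
  tpl10 <- vapply(1:10, function(i) randSeq(140), "")
  u4 <- dereplicate(rep(tpl10, times = sample(2:8, 10, replace = TRUE)))
  expect_equal(nrow(clusterOtus(u4)), 10L)
  expect_equal(length(unique(oracleCluster(u4$sequence))), 10L)
})

test_that("no two final centroids reach 97% mutual identity", {
  set.seed(23)
  tpl <- vapply(1:5, function(i) randSeq(150), "")
  reads <- unlist(lapply(tpl, function(t)
    c(rep(t, 10), vapply(1:5, function(k) mutateSeq(t, 2), ""))))
  cent <- clusterOtus(removeSingletons(dereplicate(reads)))
  if (nrow(cent) > 1) {
    for (i in 1:(nrow(cent) - 1)) {
      for (j in (i + 1):nrow(cent)) {
        expect_lt(oracleGlobal(cent$centroid[i], cent$centroid[j])$identity,
                  0.97)
      }
    }
  }
})

test_that("two-parent chimera model flags splices but spares real centroids", {
  set.seed(24)
  refs <- tinyRefs()
  db <- refs$db
  amps <- refs$amplicons[!is.na(refs$amplicons)]
  # a centroid equal to a reference amplicon is kept
  expect_false(isChimeric(amps[[1]], db))
  # midpoint splice of two divergent reference amplicons is flagged
  a <- amps[[3]]; b <- amps[[10]]
  chimera <- paste0(substr(a, 1, round(nchar(a) / 2)),
                    substr(b, round(nchar(b) / 2) + 1, nchar(b)))
  expect_true(isChimeric(chimera, db))
  # a diverged (90%) sequence with no better two-parent model is kept
  far <- mutateSeq(amps[[5]], round(nchar(amps[[5]]) * 0.1))
  expect_false(isChimeric(far, db))
  # false-positive rate on chimera-free centroids is zero
  clean <- vapply(sample(seq_along(amps), 25), function(i)
    mutateSeq(amps[[i]], sample(0:2, 1)), "")
  expect_equal(sum(isChimeric(clean, db)), 0L)
  # injected chimeras are mostly caught (>= 80%)
  pairs <- replicate(20, sample(seq_along(amps), 2))
  chims <- vapply(1:20, function(k) {
    x <- amps[[pairs[1, k]]]; y <- amps[[pairs[2, k]]]
    u <- runif(1, 0.35, 0.65)
    paste0(substr(x, 1, round(u * nchar(x))),
           substr(y, round(u * nchar(y)) + 1, nchar(y)))
  }, "")
  expect_gte(mean(isChimeric(chims, db)), 0.8)
  expect_equal(nrow(filterChimeras(
    data.frame(otu_id = "OTU_0001", centroid = chimera,
               founding_count = 5L), db)), 0L)
})

test_that("re-assignment conserves read counts and respects the cutoff", {
  set.seed(25)
  tpl <- vapply(1:4, function(i) randSeq(150), "")
  reads <- c(rep(tpl[1], 20), rep(tpl[2], 10), rep(tpl[3], 5),
             vapply(1:8, function(i) mutateSeq(tpl[1], 2), ""),
             vapply(1:4, function(i) mutateSeq(tpl[4], 1), ""))
  uniq <- dereplicate(reads)
  cent <- clusterOtus(removeSingletons(uniq))
  asg <- reassignReads(uniq, cent)
  expect_equal(sum(asg$counts) + asg$unassigned, sum(uniq$count))
  # the centroid maps to its own OTU with identity 1
  self <- reassignReads(data.frame(sequence = cent$centroid[1],
                                   count = 1L), cent)
  expect_equal(unname(self$counts[1]), 1L)
  # a sequence below 97% to every centroid stays unassigned
  lone <- reassignReads(data.frame(sequence = randSeq(150), count = 7L),
                        cent)
  expect_equal(sum(lone$counts), 0L)
  expect_equal(lone$unassigned, 7L)
})

test_that("known template proportions are recovered through the OTU table", {
  set.seed(26)
  tpl <- vapply(1:3, function(i) randSeq(180), "")
  prob <- c(0.9, 0.07, 0.03)
  n <- 10000L
  pickN <- as.integer(rmultinom(1, n, prob))
  reads <- rep(tpl, pickN)
  # sprinkle 0.5% per-base substitution errors
  nerr <- rbinom(length(reads), nchar(reads), 0.005)
  err <- which(nerr > 0)
  reads[err] <- vapply(err, function(i) mutateSeq(reads[i], nerr[i]), "")
  uniq <- dereplicate(reads)
  cent <- clusterOtus(removeSingletons(uniq))
  asg <- reassignReads(uniq, cent)
  frac <- sort(asg$counts / sum(asg$counts), decreasing = TRUE)
  expect_equal(length(frac), 3L)
  expect_true(all(abs(frac - pickN / n) < 0.02))
})
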