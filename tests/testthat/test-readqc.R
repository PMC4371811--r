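test_that("whole-primer hits are found on both strands with a mismatch cap", {
  set.seed(1)
  read <- paste0(FWD, randSeq(150))
  h <- findPrimerHits(read, FWD)
  expect_equal(h$start, 0L)
  expect_equal(h$end, nchar(FWD))
  expect_equal(h$strand, "+")
  # primer present twice -> two hits
  read2 <- paste0(FWD, randSeq(40), FWD, randSeq(40))
  expect_equal(nrow(findPrimerHits(read2, FWD)), 2L)
  # three mismatches exceed the cap of two
  m3 <- mutateSeq(FWD, 3)
  expect_equal(nrow(findPrimerHits(paste0(m3, randSeq(50)), FWD,
                                   maxMismatches = 2L)), 0L)
  expect_equal(nrow(findPrimerHits(paste0(mutateSeq(FWD, 2), randSeq(50)),
                                   FWD, maxMismatches = 2L)), 1L)
  # minus strand: reverse complement of the primer
  read3 <- paste0(randSeq(30), RCFWD)
  h3 <- findPrimerHits(read3, FWD)
  expect_equal(h3$strand, "-")
  expect_equal(h3$end, 30L + nchar(FWD))
})

test_that("pair qualification requires one hit per mate forming a pair", {
  set.seed(2)
  amp <- makeAmplicon(150)
  pp <- perfectPair(amp, 145, 125)
  # 4 junk nt 5' of the forward primer on mate 1 -> trimmed away
  junk1 <- makeReads(paste0("ACGT", substr(amp, 1, 141)), 38L, "p1")
  q <- qualifyPairs(junk1, pp$r2)
  expect_true(q$qualified)
  expect_equal(Biostrings::width(q$r1), 141L)
  expect_true(startsWith(as.character(as(q$r1, "DNAStringSet"))[[1]], FWD))
  expect_setequal(c(q$primer1, q$primer2), c("F", "R"))
  # both mates carrying the forward primer do not form a pair
  qq <- qualifyPairs(pp$r1, pp$r1)
  expect_false(qq$qualified)
  # two forward-primer hits on one mate disqualify it
  double <- makeReads(paste0(FWD, randSeq(20), FWD, randSeq(60)), 38L, "p1")
  expect_false(qualifyPairs(double, pp$r2)$qualified)
  # quality is trimmed alongside the sequence
  q2 <- qualifyPairs(makeReads(paste0("ACGT", substr(amp, 1, 141)),
                               c(rep(2L, 4), rep(38L, 141)), "p1"),
                     pp$r2)
  expect_equal(unique(as(Biostrings::quality(q2$r1), "IntegerList")[[1]]),
               38L)
})

test_that("merging honors the overlap bound, the length floor and quality consensus", {
  set.seed(3)
  # 100+100 mates overlapping by exactly 10 -> merged length 190
  amp190 <- makeAmplicon(190 - 38)
  pp <- perfectPair(amp190, 100, 100)
  m <- mergePairs(pp$r1, pp$r2)
  expect_equal(as.character(m$status), "merged")
  expect_equal(Biostrings::width(m$merged), 190L)
  expect_equal(as.character(as(m$merged, "DNAStringSet"))[[1]], amp190)
  # 145+125 mates overlapping by 10 -> merged length 260
  amp260 <- makeAmplicon(260 - 38)
  m2 <- mergePairs(perfectPair(amp260, 145, 125)$r1,
                   perfectPair(amp260, 145, 125)$r2)
  expect_equal(Biostrings::width(m2$merged), 260L)
  # identical 50 bp mates: full overlap -> 50 bp merged -> discarded
  amp50 <- randSeq(50)
  m3 <- mergePairs(perfectPair(amp50, 50, 50)$r1,
                   perfectPair(amp50, 50, 50)$r2)
  expect_equal(as.character(m3$status), "tooShort")
  expect_equal(length(m3$merged), 0L)
  # no admissible overlap
  m4 <- mergePairs(makeReads(randSeq(80)), makeReads(randSeq(80)))
  expect_equal(as.character(m4$status), "unmerged")
  # disagreeing overlap base takes the higher-quality call; overlap
  # quality is the per-base maximum
  amp <- randSeq(200)
  r1s <- substr(amp, 1, 105)
  plus2 <- substr(amp, 96, 200) # overlap covers amplicon 96..105
  orig <- substr(plus2, 5, 5) # amplicon position 100
  sub <- setdiff(c("A", "C", "G", "T"), orig)[1]
  substr(plus2, 5, 5) <- sub
  r1 <- makeReads(r1s, 20L)
  r2 <- makeReads(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(plus2))), 35L)
  m5 <- mergePairs(r1, r2)
  s <- as.character(as(m5$merged, "DNAStringSet"))[[1]]
  expect_equal(Biostrings::width(m5$merged), 200L)
  expect_equal(substr(s, 100, 100), sub) # mate-2 (higher quality) wins
  q <- as(Biostrings::quality(m5$merged), "IntegerList")[[1]]
  expect_true(all(q[96:105] == 35L)) # per-base max in the overlap
  expect_true(all(q[1:95] == 20L))
})

test_that("merged length never exceeds len1 + len2 - minOverlap", {
  set.seed(4)
  l1 <- 80L; l2 <- 60L
  for (ov in seq(10L, l2, by = 7L)) {
    amp <- randSeq(l1 + l2 - ov)
    pp <- perfectPair(amp, l1, l2)
    m <- mergePairs(pp$r1, pp$r2, qcParams(minMergedLen = 10L))
    expect_equal(Biostrings::width(m$merged), l1 + l2 - ov)
    expect_lte(Biostrings::width(m$merged), l1 + l2 - 10L)
  }
})

test_that("window quality filter matches a direct window-mean oracle and is monotone", {
  oracleWindow <- function(q, w = 5, thr = 30) {
    if (length(q) <= w) return(mean(q) >= thr)
    all(vapply(seq_len(length(q) - w + 1),
               function(i) mean(q[i:(i + w - 1)]) >= thr, TRUE))
  }
  expect_true(windowQualityFilter(makeReads(randSeq(50), 40L)))
  # one run of five Q20 bases anywhere fails
  q <- rep(40L, 50); q[23:27] <- 20L
  expect_false(windowQualityFilter(makeReads(randSeq(50), list(q))))
  # exact boundary passes: (35*4 + 10)/5 = 30
  qb <- c(rep(35L, 49), 10L)
  expect_true(windowQualityFilter(makeReads(randSeq(50), list(qb))))
  expect_equal(oracleWindow(qb), TRUE)
  # random profiles agree with the oracle
  set.seed(5)
  for (i in 1:50) {
    qr <- sample(20:40, 30, replace = TRUE)
    expect_equal(
      windowQualityFilter(makeReads(randSeq(30), list(qr))),
      oracleWindow(qr), info = paste("case", i))
  }
  # monotonicity: raising any base quality never flips pass -> fail
  for (i in 1:20) {
    qr <- sample(25:35, 30, replace = TRUE)
    base <- windowQualityFilter(makeReads(randSeq(30), list(qr)))
    j <- sample(30, 1)
    qr2 <- qr; qr2[j] <- qr2[j] + sample(1:5, 1)
    up <- windowQualityFilter(makeReads(randSeq(30), list(qr2)))
    if (base) expect_true(up)
  }
})

test_that("orientation is an involution fixed by the forward primer", {
  set.seed(6)
  amp <- makeAmplicon(150)
  x <- makeReads(amp, 38L, "a1")
  o1 <- orientAmplicons(x)
  expect_identical(as.character(as(o1, "DNAStringSet"))[[1]], amp)
  expect_true(S4Vectors::mcols(o1)$oriented)
  # its reverse complement is flipped back
  rc <- makeReads(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(amp))), 38L, "a1")
  o2 <- orientAmplicons(rc)
  expect_identical(as.character(as(o2, "DNAStringSet"))[[1]], amp)
  # idempotent after the first application
  o3 <- orientAmplicons(o2)
  expect_identical(as.character(as(o3, "DNAStringSet")),
                   as.character(as(o2, "DNAStringSet")))
  # no primer in either orientation -> flagged
  expect_warning(o4 <- orientAmplicons(makeReads(randSeq(120))),
                 "no forward-primer motif")
  expect_false(S4Vectors::mcols(o4)$oriented)
})

test_that("per-sample QC conserves read accounting", {
  refs <- tinyRefs()
  sm <- generateSample(communitySpec(refs, "tuber", nReads = 400,
                                     seed = 9))
  qc <- qcSample(sm$r1, sm$r2)
  t <- qc$tally
  expect_equal(t[["qualified"]],
               t[["merged"]] + t[["unmerged"]] + t[["tooShort"]])
  expect_lte(t[["highQuality"]], t[["merged"]])
  expect_lte(t[["qualified"]], t[["rawPairs"]])
  expect_equal(length(qc$amplicons), t[["highQuality"]])
  expect_true(all(Biostrings::width(qc$amplicons) >= 100))
  # oriented amplicons start with the forward primer motif
  expect_true(all(Biostrings::neditStartingAt(
    Biostrings::DNAString(FWD), as(qc$amplicons, "DNAStringSet"),
    starting.at = 1) <= 2))
})
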