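test_that("length distribution reports exact histograms", {
  ld <- lengthDistribution(c(rep(strrep("A", 179), 5)))
  expect_equal(ld$mode, 179L)
  expect_equal(unname(ld$range), c(179L, 179L))
  expect_equal(as.integer(ld$histogram), 5L)
  empty <- lengthDistribution(character())
  expect_true(is.na(empty$mode))
  set.seed(31)
  lens <- sample(162:200, 500, replace = TRUE)
  ld2 <- lengthDistribution(vapply(lens, function(n)
    strrep("A", n), ""))
  expect_equal(unname(ld2$range), c(162L, 200L))
  expect_equal(sum(ld2$histogram), 500L)
})

test_that("rarefaction matches the closed-form hypergeometric expectation", {
  counts <- setNames(c(30L, 12L, 5L, 2L), paste0("o", 1:4))
  n <- sum(counts)
  # depth = total -> exact richness, sd 0
  full <- rarefactionCurve(counts, depths = n, repeats = 20, seed = 1)
  expect_equal(full$mean, 4)
  expect_equal(full$sd, 0)
  # depth 1 -> exactly one OTU
  one <- rarefactionCurve(counts, depths = 1, repeats = 20, seed = 1)
  expect_equal(one$mean, 1)
  expect_equal(one$sd, 0)
  # closed form: E[S_d] = S - sum_i C(n - n_i, d) / C(n, d)
  d <- 20L
  expected <- length(counts) -
    sum(exp(lchoose(n - counts, d) - lchoose(n, d)))
  got <- rarefactionCurve(counts, depths = d, repeats = 3000, seed = 2)
  expect_lt(abs(got$mean - expected), 0.05)
  # two-OTU sample with counts (1, n-1) at depth n/2:
  # mean = 1 + P(rare read sampled) = 2 - C(n-1, n/2) / C(n, n/2)
  n2 <- 40L
  counts2 <- c(rare = 1L, common = n2 - 1L)
  exp2 <- 2 - exp(lchoose(n2 - 1, n2 / 2) - lchoose(n2, n2 / 2))
  got2 <- rarefactionCurve(counts2, depths = n2 / 2, repeats = 4000,
                           seed = 3)
  expect_lt(abs(got2$mean - exp2), 0.03)
  # monotone in depth
  grid <- rarefactionCurve(counts, depths = c(1, 5, 10, 25, 49),
                           repeats = 400, seed = 4)
  expect_true(all(diff(grid$mean) >= 0))
  expect_warning(rarefactionCurve(counts, depths = n + 10, repeats = 5),
                 "clamped")
})

test_that("in-silico PCR extracts primer-delimited segments within the window", {
  set.seed(32)
  # forward + 150 nt + revcomp(reverse) -> segment of 18 + 150 + 20
  ref1 <- paste0(randSeq(30), FWD, randSeq(150), RCREV, randSeq(25))
  ref2 <- paste0(randSeq(30), FWD, randSeq(150))             # no reverse site
  ref3 <- paste0(FWD, randSeq(400), RCREV)                   # 438 > window
  db <- ReferenceDb(setNames(c(ref1, ref2, ref3), c("a", "b", "c")))
  seg <- inSilicoPcr(db)
  expect_equal(names(seg), "a")
  expect_equal(Biostrings::width(seg), 188L)
  expect_true(startsWith(as.character(seg)[[1]], FWD))
  expect_true(endsWith(as.character(seg)[[1]], RCREV))
  seg3 <- inSilicoPcr(db, lengthWindow = c(1L, 500L))
  expect_setequal(names(seg3), c("a", "c"))
})

test_that("neighbor joining recovers additive topology and handles edge cases", {
  # three identical sequences -> all pairwise tree distances zero
  s3 <- setNames(rep(strrep("ACGT", 30), 3), c("x", "y", "z"))
  t3 <- buildTree(s3)
  expect_setequal(t3$tip.label, c("x", "y", "z"))
  expect_equal(sum(t3$edge.length), 0)
  # duplicate sequences become zero-length siblings
  set.seed(33)
  base <- randSeq(120)
  t4 <- buildTree(setNames(c(base, base, mutateSeq(base, 30),
                             randSeq(120)), paste0("s", 1:4)))
  cd <- ape::cophenetic.phylo(t4)
  expect_equal(cd["s1", "s2"], 0)
  expect_true(all(t4$edge.length >= 0))
  # star tree below three leaves
  t2 <- buildTree(setNames(c("ACGTACGT", "ACGTTCGT"), c("a", "b")))
  expect_equal(ape::Ntip(t2), 2L)
  # additive distances: NJ on sequence-free input is checked through the
  # generating quartet -- (A,B) vs (C,D) with a long internal branch
  tplA <- randSeq(200)
  tplB <- mutateSeq(tplA, 6)      # A,B close
  tplC <- mutateSeq(tplA, 80)     # C far from A/B
  tplD <- mutateSeq(tplC, 6)      # D close to C
  tq <- buildTree(setNames(c(tplA, tplB, tplC, tplD), c("A", "B", "C", "D")))
  cd <- ape::cophenetic.phylo(tq)
  # four-point condition: AB + CD is the smallest pairing
  expect_lt(cd["A", "B"] + cd["C", "D"],
            min(cd["A", "C"] + cd["B", "D"], cd["A", "D"] + cd["B", "C"]))
})

test_that("UniFrac matches the brute-force branch enumeration oracle", {
  set.seed(34)
  for (rep in 1:60) {
    ntip <- sample(3:6, 1)
    tree <- ape::rtree(ntip)
    counts <- matrix(rpois(3 * ntip, 4), nrow = 3,
                     dimnames = list(paste0("s", 1:3), tree$tip.label))
    counts[1, ] <- counts[1, ] + 1 # no empty sample
    counts[2, ] <- counts[2, ] + 1
    counts[3, ] <- counts[3, ] + 1
    for (mode in c("weighted", "unweighted")) {
      got <- unifrac(tree, counts, mode)
      want <- oracleUnifrac(tree, counts, mode)
      expect_lt(max(abs(got - want)), 1e-12)
    }
  }
})

test_that("UniFrac satisfies metric sanity and invariances", {
  set.seed(35)
  tree <- ape::rtree(8)
  counts <- matrix(rpois(3 * 8, 5) + 1, nrow = 3,
                   dimnames = list(paste0("s", 1:3), tree$tip.label))
  for (mode in c("weighted", "unweighted")) {
    d <- unifrac(tree, counts, mode)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
    # triangle inequality
    expect_lte(d[1, 3], d[1, 2] + d[2, 3] + 1e-12)
    # identical abundance vectors -> 0
    same <- counts[c(1, 1), ]
    rownames(same) <- c("a", "b")
    expect_equal(unname(unifrac(tree, same, mode)["a", "b"]), 0)
  }
  # weighted mode ignores depth scaling
  scaled <- counts
  scaled[1, ] <- scaled[1, ] * 13L
  expect_equal(unifrac(tree, counts, "weighted"),
               unifrac(tree, scaled, "weighted"))
  # disjoint communities on a unit star tree -> unweighted distance 1
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  cm <- rbind(s1 = c(3, 5, 0, 0), s2 = c(0, 0, 2, 7))
  colnames(cm) <- c("a", "b", "c", "d")
  expect_equal(unname(unifrac(star, cm, "unweighted")["s1", "s2"]), 1)
  # zero-abundance OTU in both samples changes nothing
  tree9 <- ape::rtree(9)
  c8 <- cbind(counts, extra = 0L)
  colnames(c8) <- tree9$tip.label
  sub <- ape::drop.tip(tree9, tree9$tip.label[9])
  expect_equal(unifrac(tree9, c8, "weighted")[1, 2],
               unifrac(sub, c8[, 1:8], "weighted")[1, 2])
  # empty sample errors
  bad <- rbind(counts, empty = 0L)
  expect_error(unifrac(tree, bad, "weighted"), "zero reads")
})

test_that("PCoA reproduces distances in the positive-eigenvalue subspace", {
  # two samples -> one axis at 100%
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  p2 <- ordinatePcoa(d2)
  expect_equal(p2$varExplained[1], 1)
  # points on a line -> first axis explains everything
  x <- c(0, 1, 2.5, 4)
  dl <- as.matrix(stats::dist(x))
  pl <- ordinatePcoa(dl)
  expect_gt(pl$varExplained[1], 1 - 1e-9)
  # reconstruction: pairwise Euclidean distances of the embedding match
  # the input within the positive subspace
  set.seed(36)
  pts <- matrix(rnorm(5 * 3), 5)
  dd <- as.matrix(stats::dist(pts))
  pe <- ordinatePcoa(dd)
  rec <- as.matrix(stats::dist(pe$points))
  expect_lt(max(abs(rec - dd)), 1e-8)
  expect_equal(sum(pe$varExplained), 1)
})

test_that("composition summaries rank by mean fraction and close to 100%", {
  lin <- asLineage(rbind(
    c("Fungi", "Basidiomycota", "Agaricomycetes", "Agaricales",
      "Mycenaceae", "Mycena", "sp1"),
    c("Fungi", "Basidiomycota", "Agaricomycetes", "Agaricales",
      "Mycenaceae", "Mycena", "sp2"),
    c("Fungi", "Ascomycota", "Sordariomycetes", "Hypocreales",
      "Nectriaceae", "Fusarium", "sp3"),
    c("Fungi", rep("unclassified", 6))))
  counts <- rbind(s1 = c(70, 10, 15, 5), s2 = c(50, 30, 10, 10))
  cs <- compositionSummary(lin, counts, level = "genus", topK = 15)
  expect_equal(cs["Mycena", "s1"], 0.80)
  expect_equal(cs["Fusarium", "s2"], 0.10)
  expect_equal(unname(colSums(cs)), c(1, 1))
  expect_equal(cs["unclassified", "s1"], 0.05)
  # single taxon
  one <- compositionSummary(lin[1, , drop = FALSE],
                            matrix(c(10), 1, dimnames = list("s1", "o1")),
                            level = "genus")
  expect_equal(one["Mycena", "s1"], 1)
  # 20 taxa, topK 15 -> exactly 15 named + others + unclassified
  set.seed(37)
  lin20 <- emptyLineage(20)
  lin20[, "domain"] <- "Fungi"
  lin20[, "genus"] <- paste0("G", 1:20)
  c20 <- matrix(rpois(40, 10) + 1, nrow = 2,
                dimnames = list(c("s1", "s2"), paste0("o", 1:20)))
  cs20 <- compositionSummary(lin20, c20, level = "genus", topK = 15)
  expect_equal(nrow(cs20), 17L)
  expect_gt(cs20["others", "s1"], 0)
})
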