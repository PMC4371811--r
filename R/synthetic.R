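# Synthetic study generator: reference databases with realistic
# descriptions and partial lineages, and tuber-/soil-like communities
# rendered as paired-end reads with quality decay, substitution error and
# chimeras. Everything is driven by explicit integer seeds.

.randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# description templates that satisfy the LSU keep rule
.lsuDescriptions <- function(organism, i) {
  tpl <- c("%s 28S ribosomal RNA gene, partial sequence",
           "%s large subunit ribosomal RNA gene, partial sequence",
           "%s 26S ribosomal RNA gene, complete sequence",
           "%s LSU rRNA gene, partial",
           "%s 28S rRNA gene (partial)")
  sprintf(tpl[(i %% length(tpl)) + 1L], organism)
}

# decoy descriptions that must fail the keep rule
.decoyDescriptions <- function(organism, i) {
  tpl <- c("%s actin (act1) mRNA, complete cds",
           "%s internal transcribed spacer 1, partial sequence",
           "%s 18S ribosomal RNA gene, partial sequence",
           "%s elongation factor 1-alpha gene, partial cds")
  sprintf(tpl[(i %% length(tpl)) + 1L], organism)
}

.fungalPhyla <- c("Basidiomycota", "Ascomycota", "Mucoromycota",
                  "Chytridiomycota", "Glomeromycota")
.plantPhyla <- c("Streptophyta", "Chlorophyta")
.metazoanPhyla <- c("Arthropoda", "Nematoda", "Annelida")

# deterministic nested taxonomy: genus g sits in family g%/%3, order
# g%/%9, class g%/%27; phylum from the domain's pool by class index
.makeTaxonomy <- function(n, domain) {
  g <- seq_len(n) - 1L
  phyla <- switch(domain, Fungi = .fungalPhyla, Viridiplantae = .plantPhyla,
                  Metazoa = .metazoanPhyla)
  pre <- switch(domain, Fungi = "Fun", Viridiplantae = "Vir",
                Metazoa = "Met")
  cls <- g %/% 27L
  data.frame(
    domain = domain,
    phylum = phyla[(cls %% length(phyla)) + 1L],
    class = sprintf("%sclass%02d", pre, cls),
    order = sprintf("%sorder%02d", pre, g %/% 9L),
    family = sprintf("%saceae%02d", pre, g %/% 3L),
    genus = sprintf("%sgenus%03d", pre, g),
    species = sprintf("%sgenus%03d sp%d", pre, g, g),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic LSU reference database
#'
#' Reference sequences share a conserved primer-binding scaffold: a
#' random 5' flank, the forward primer site, a taxon-specific variable
#' insert of \code{insertRange} bp, the reverse primer binding site and a
#' random 3' flank. With the 18 + 20 bp primers included, primer-delimited
#' amplicons therefore span 167--218 bp for the default insert range. A
#' fraction of records are "uncultured" placeholder near-duplicates of
#' real taxa, a fraction carry partial lineages (unclassified below a
#' random rank), and non-fungal (plant and metazoan) taxa are included.
#' Optional decoy records (mRNA, spacer, small-subunit) exercise the
#' keyword selection.
#'
#' @param nTaxa Number of reference taxa.
#' @param seed Integer RNG seed.
#' @param insertRange Variable-insert length range (bp).
#' @param fractionUncultured Fraction of extra "uncultured" placeholder
#'   records (near-duplicates of real taxa with placeholder lineages).
#' @param fractionPartialLineage Fraction of taxa with unclassified lower
#'   ranks.
#' @param domainProbs Named probabilities for Fungi / Viridiplantae /
#'   Metazoa.
#' @param nDecoyRecords Number of non-LSU decoy records appended to the
#'   raw record table (never part of the curated db).
#' @return List with \code{db} (the curated \code{\link{ReferenceDb}}),
#'   \code{rawRecords} (data.frame id/sequence/description incl. decoys),
#'   \code{idToTaxon}, \code{taxonToLineage}, and \code{amplicons}
#'   (named character: the true primer-delimited amplicon per reference).
#' @export
generateReferenceDb <- function(nTaxa = 120L, seed = 1L,
                                insertRange = c(129L, 180L),
                                fractionUncultured = 0.05,
                                fractionPartialLineage = 0.3,
                                domainProbs = c(Fungi = 0.8,
                                                Viridiplantae = 0.1,
                                                Metazoa = 0.1),
                                nDecoyRecords = 0L) {
  set.seed(seed)
  primers <- lsuPrimers()
  rcRev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(primers[["reverse"]])))
  nDom <- pmax(0L, as.integer(round(nTaxa * domainProbs /
                                      sum(domainProbs))))
  nDom[1] <- nTaxa - sum(nDom[-1])
  doms <- rep(names(domainProbs), nDom)
  lin <- do.call(rbind, lapply(names(domainProbs), function(d)
    .makeTaxonomy(sum(doms == d), d)))
  n <- nrow(lin)
  ids <- sprintf("REF%05d", seq_len(n))
  inserts <- vapply(seq_len(n), function(i)
    .randSeq(sample(insertRange[1]:insertRange[2], 1)), "")
  amplicons <- paste0(primers[["forward"]], inserts, rcRev)
  seqs <- vapply(seq_len(n), function(i)
    paste0(.randSeq(sample(20:60, 1)), amplicons[i],
           .randSeq(sample(20:60, 1))), "")
  desc <- vapply(seq_len(n), function(i)
    .lsuDescriptions(lin$species[i], i), "")
  # partial lineages: unclassified from a random rank down
  nPart <- round(fractionPartialLineage * n)
  if (nPart > 0) {
    part <- sample(n, nPart)
    for (i in part) {
      from <- sample(2:7, 1) # never blank the domain
      lin[i, from:7] <- unclassifiedLabel()
    }
  }
  # uncultured placeholder records: near-duplicates of real taxa
  nUnc <- round(fractionUncultured * n)
  if (nUnc > 0) {
    src <- sample(n, nUnc, replace = TRUE)
    for (k in seq_len(nUnc)) {
      s <- strsplit(seqs[src[k]], "")[[1]]
      pos <- sample(seq_along(s), 2)
      s[pos] <- vapply(s[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      seqs <- c(seqs, paste(s, collapse = ""))
      amplicons <- c(amplicons, NA_character_)
      ids <- c(ids, sprintf("REF%05d", length(ids) + 1L))
      desc <- c(desc, sprintf(
        "Uncultured fungus clone c%03d 28S ribosomal RNA gene", k))
      lin <- rbind(lin, data.frame(
        domain = "Fungi", phylum = unclassifiedLabel(),
        class = unclassifiedLabel(), order = unclassifiedLabel(),
        family = unclassifiedLabel(), genus = unclassifiedLabel(),
        species = "uncultured fungus", stringsAsFactors = FALSE))
    }
  }
  nAll <- length(ids)
  taxonIds <- sprintf("TAX%05d", seq_len(nAll))
  raw <- data.frame(id = ids, sequence = seqs, description = desc,
                    stringsAsFactors = FALSE)
  if (nDecoyRecords > 0) {
    dID <- sprintf("DECOY%04d", seq_len(nDecoyRecords))
    raw <- rbind(raw, data.frame(
      id = dID,
      sequence = vapply(seq_len(nDecoyRecords), function(i)
        .randSeq(sample(150:400, 1)), ""),
      description = vapply(seq_len(nDecoyRecords), function(i)
        .decoyDescriptions(sprintf("Species d%03d", i), i), ""),
      stringsAsFactors = FALSE))
  }
  db <- ReferenceDb(setNames(seqs, ids), description = desc,
                    lineage = asLineage(lin))
  list(db = db,
       rawRecords = raw,
       idToTaxon = setNames(taxonIds, ids),
       taxonToLineage = {
         m <- asLineage(lin)
         rownames(m) <- taxonIds
         m
       },
       amplicons = setNames(amplicons, ids))
}

#' Specify a synthetic community sample
#'
#' \code{style = "tuber"} gives a small community with one dominant
#' fungal taxon (default relative abundance 0.90 of the fungal fraction,
#' in the spirit of orchid tubers dominated by a single mycobiont at
#' 85--97\%) plus a large plant fraction; \code{style = "soil"} gives a
#' rich community (up to 1000 fungal taxa) with Fisher log-series
#' abundances and a broad amplicon length spectrum.
#'
#' @param refs Output of \code{\link{generateReferenceDb}}.
#' @param style \code{"tuber"} or \code{"soil"}.
#' @param nReads Number of read pairs.
#' @param readLens Mate lengths, e.g. \code{c(145, 125)} or
#'   \code{c(100, 100)}.
#' @param dominantAbundance Tuber only: fungal-fraction abundance of the
#'   dominant taxon.
#' @param dominantRef Tuber only: reference id of the dominant taxon.
#'   Defaults to the first fungal reference in the database, so that
#'   tuber replicates generated with different seeds share their dominant
#'   mycobiont (as tubers of one host population do), while the minor
#'   taxa vary by seed.
#' @param nCommunityTaxa Number of fungal taxa in the community (tuber
#'   default 30; soil default 1000, capped at the fungal taxa available).
#' @param nonFungalFraction Named read fractions for
#'   \code{Viridiplantae} and \code{Metazoa} (defaults by style: tuber
#'   c(0.35, 0.02), soil c(0.02, 0.05)).
#' @param errorRate Mean per-base substitution probability (default
#'   0.005); per-base rates are modulated by the simulated quality.
#' @param chimeraRate Fraction of reads built as single-breakpoint
#'   two-parent chimeras.
#' @param tailQ Mean Phred at the final cycle (linear decay from Q38).
#'   The default sits just above the Q30 window-filter threshold, so the
#'   filter is exercised in both its pass and fail regimes.
#' @param junkRate Fraction of mates with 1--5 random bases 5' of the
#'   primer (exercises trimming).
#' @param logSeriesX Log-series parameter for soil abundances.
#' @param seed Integer RNG seed (drives everything in
#'   \code{\link{generateSample}}).
#' @return A \code{CommunitySpec} (validated list).
#' @export
communitySpec <- function(refs, style = c("tuber", "soil"),
                          nReads = 10000L, readLens = c(145L, 125L),
                          dominantAbundance = 0.90, dominantRef = NULL,
                          nCommunityTaxa = NULL,
                          nonFungalFraction = NULL,
                          errorRate = 0.005, chimeraRate = 0.01,
                          tailQ = 31, junkRate = 0.05,
                          logSeriesX = 0.9, seed = 1L) {
  style <- match.arg(style)
  if (is.null(nCommunityTaxa))
    nCommunityTaxa <- if (style == "tuber") 30L else 1000L
  if (is.null(nonFungalFraction))
    nonFungalFraction <- if (style == "tuber")
      c(Viridiplantae = 0.35, Metazoa = 0.02) else
      c(Viridiplantae = 0.02, Metazoa = 0.05)
  db <- refs$db
  amp <- refs$amplicons
  real <- !is.na(amp)
  domain <- refLineages(db)[, "domain"]
  pick <- function(dom, k) {
    cand <- which(real & domain == dom)
    if (length(cand) == 0L || k == 0L) return(integer())
    sample(cand, min(k, length(cand)))
  }
  set.seed(seed)
  fungal <- pick("Fungi", nCommunityTaxa)
  stopifnot(length(fungal) >= 1L)
  if (style == "tuber") {
    # the dominant mycobiont is a property of the study system, not of
    # the per-sample seed: replicates share it unless overridden
    if (is.null(dominantRef))
      dominantRef <- refIds(db)[which(real & domain == "Fungi")[1]]
    di <- match(dominantRef, refIds(db))
    stopifnot(!is.na(di), !is.na(amp[di]))
    fungal <- c(di, setdiff(fungal, di)[seq_len(length(fungal) - 1L)])
    rest <- length(fungal) - 1L
    w <- if (rest > 0) 0.7 ^ seq_len(rest) else numeric()
    ab <- c(dominantAbundance,
            if (rest > 0) (1 - dominantAbundance) * w / sum(w))
  } else {
    # per-taxon abundance drawn from the logarithmic (Fisher log-series)
    # distribution P(k) proportional to x^k / k
    k <- seq_len(2000L)
    ab <- sample(k, length(fungal), replace = TRUE,
                 prob = logSeriesX ^ k / k)
    ab <- ab / sum(ab)
  }
  nfTotal <- sum(nonFungalFraction)
  taxa <- data.frame(ref = refIds(db)[fungal],
                     abundance = ab * (1 - nfTotal),
                     domain = "Fungi", stringsAsFactors = FALSE)
  for (dom in names(nonFungalFraction)) {
    k <- if (style == "tuber" && dom == "Viridiplantae") 3L else 8L
    idx <- pick(dom, k)
    if (length(idx)) {
      w <- 0.5 ^ seq_along(idx)
      taxa <- rbind(taxa, data.frame(
        ref = refIds(db)[idx],
        abundance = nonFungalFraction[[dom]] * w / sum(w),
        domain = dom, stringsAsFactors = FALSE))
    }
  }
  taxa$abundance <- taxa$abundance / sum(taxa$abundance)
  ampLens <- nchar(amp[taxa$ref])
  if (sum(readLens) - min(ampLens) < 10L)
    stop("read lengths ", paste(readLens, collapse = "+"),
         " cannot span the shortest amplicon (", min(ampLens),
         " bp) with >= 10 bp overlap")
  spec <- list(style = style, taxa = taxa, amplicons = amp[taxa$ref],
               nReads = as.integer(nReads),
               readLens = as.integer(readLens),
               errorRate = errorRate, chimeraRate = chimeraRate,
               tailQ = tailQ, junkRate = junkRate, seed = as.integer(seed))
  class(spec) <- "CommunitySpec"
  spec
}

#' Render a community specification as paired-end reads
#'
#' Reads are drawn multinomially from the community's taxa; a fraction
#' are single-breakpoint chimeras of two templates (each parent
#' contributing at least 30\%); pair orientation is random; per-cycle
#' mean quality decays linearly from Q38 to \code{tailQ}; substitution
#' errors are placed with per-base probability proportional to the
#' quality-implied error rate, scaled to the requested mean
#' \code{errorRate}. The same seed reproduces the sample byte for byte.
#'
#' @param spec A \code{\link{communitySpec}}.
#' @return List with \code{r1}, \code{r2}
#'   (\code{QualityScaledDNAStringSet}) and \code{truth} (data.frame:
#'   read_id, ref (template), domain, chimera, ampliconLen).
#' @export
generateSample <- function(spec) {
  stopifnot(inherits(spec, "CommunitySpec"))
  set.seed(spec$seed)
  n <- spec$nReads
  l1 <- spec$readLens[1]
  l2 <- spec$readLens[2]
  nt <- nrow(spec$taxa)
  tmpl <- sample.int(nt, n, replace = TRUE, prob = spec$taxa$abundance)
  chim <- stats::runif(n) < spec$chimeraRate
  amps <- unname(spec$amplicons)
  ampSeq <- amps[tmpl]
  if (any(chim)) {
    other <- sample.int(nt, sum(chim), replace = TRUE,
                        prob = spec$taxa$abundance)
    u <- stats::runif(sum(chim), 0.3, 0.7)
    la <- nchar(amps[tmpl[chim]])
    lb <- nchar(amps[other])
    ampSeq[chim] <- paste0(
      substr(amps[tmpl[chim]], 1, round(u * la)),
      substr(amps[other], round(u * lb) + 1L, lb))
  }
  flip <- stats::runif(n) < 0.5
  ampSeq[flip] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(ampSeq[flip])))
  rcAll <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(ampSeq)))
  s1 <- substr(ampSeq, 1, l1)
  s2 <- substr(rcAll, 1, l2)
  # occasional junk 5' of the primer (read shifted, 3' truncated)
  junk1 <- stats::runif(n) < spec$junkRate
  junk2 <- stats::runif(n) < spec$junkRate
  addJunk <- function(s, take, len) {
    idx <- which(take)
    for (i in idx) {
      j <- sample(1:5, 1)
      s[i] <- substr(paste0(.randSeq(j), s[i]), 1, len)
    }
    s
  }
  s1 <- addJunk(s1, junk1, l1)
  s2 <- addJunk(s2, junk2, l2)
  qualProfile <- function(len) {
    mq <- seq(38, spec$tailQ, length.out = len)
    function(nr) {
      q <- matrix(round(rep(mq, each = nr) +
                          stats::rnorm(nr * len, 0, 2.5)), nrow = nr)
      q[q < 2] <- 2L
      q[q > 40] <- 40L
      q
    }
  }
  q1 <- qualProfile(l1)(n)
  q2 <- qualProfile(l2)(n)
  applyErrors <- function(s, q, len) {
    perr <- 10 ^ (-q / 10)
    perr <- perr * (spec$errorRate / mean(perr))
    hit <- matrix(stats::runif(length(perr)) < perr, nrow = nrow(q))
    if (any(hit)) {
      m <- matrix(unlist(strsplit(s, ""), use.names = FALSE),
                  nrow = len)
      # hit is reads x cycles; m is cycles x reads
      idx <- which(t(hit))
      m[idx] <- vapply(m[idx], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      s <- apply(m, 2, paste, collapse = "")
    }
    s
  }
  s1 <- applyErrors(s1, q1, l1)
  s2 <- applyErrors(s2, q2, l2)
  ids <- sprintf("read%06d", seq_len(n))
  r1 <- .makeQSD(s1, lapply(seq_len(n), function(i) q1[i, ]), ids)
  r2 <- .makeQSD(s2, lapply(seq_len(n), function(i) q2[i, ]), ids)
  truth <- data.frame(read_id = ids, ref = spec$taxa$ref[tmpl],
                      domain = spec$taxa$domain[tmpl], chimera = chim,
                      ampliconLen = nchar(ampSeq),
                      stringsAsFactors = FALSE)
  list(r1 = r1, r2 = r2, truth = truth)
}
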