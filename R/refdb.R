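# Reference-set curation: keyword selection of LSU records from raw
# (id, sequence, description) triples, and lineage attachment from
# id -> taxon and taxon -> seven-rank maps.

#' Does a description denote an LSU (large-subunit) ribosomal RNA record?
#'
#' A description is kept when it satisfies both of:
#' \itemize{
#'   \item the LSU rule: contains \code{"large"} or \code{"Large"} as a
#'     substring, OR a delimited \code{"LSU"} token, OR a delimited
#'     \code{"2xS"} token with x in 3..8 (e.g. \code{"28S"}, \code{"26S"});
#'     token delimiters are whitespace, \code{( ) [ ] , / -} or the string
#'     boundary;
#'   \item the ribosomal-RNA rule: contains \code{"rDNA"} or \code{"rRNA"},
#'     or \code{"ribosomal"} together with \code{"DNA"} or \code{"RNA"};
#' }
#' and is then excluded when it contains \code{"mRNA"} or \code{"spacer"}
#' as a substring (internal transcribed spacers and messenger RNAs are not
#' LSU rDNA).
#'
#' @param description Character vector of free-text record descriptions.
#' @return Logical vector: keep this record?
#' @export
#' @examples
#' isLsuDescription("Mycena sp. 28S ribosomal RNA gene, partial")
#' isLsuDescription("internal transcribed spacer 2 and 28S rRNA")
isLsuDescription <- function(description) {
  d <- as.character(description)
  d[is.na(d)] <- ""
  delim <- "[][(),/[:space:]-]"
  tokL <- paste0("(^|", delim, ")LSU($|", delim, ")")
  tok2 <- paste0("(^|", delim, ")2[3-8]S($|", delim, ")")
  keep <- grepl("[Ll]arge", d) | grepl(tokL, d) | grepl(tok2, d)
  ribo <- grepl("r[DR]NA", d) |
    (grepl("ribosomal", d) & grepl("[DR]NA", d))
  excl <- grepl("mRNA", d, fixed = TRUE) | grepl("spacer", d, fixed = TRUE)
  keep & ribo & !excl
}

#' Select LSU records from raw sequence records
#'
#' Applies \code{\link{isLsuDescription}} to each record's description and
#' returns the ids of the kept records, preserving input order. The
#' decision depends on the description only.
#'
#' @param records A data.frame with columns \code{id}, \code{sequence},
#'   \code{description} (extra columns ignored).
#' @return Character vector of selected record ids.
#' @export
selectLsuRecords <- function(records) {
  if (NROW(records) == 0L) return(character())
  records <- as.data.frame(records)
  as.character(records$id[isLsuDescription(records$description)])
}

#' Attach seven-rank lineages to selected records
#'
#' Each record id is mapped to a taxon id, and the taxon id to a
#' seven-rank lineage; ranks absent from the map (empty or \code{NA})
#' become \code{"unclassified"}. Records whose id is absent from the
#' id-to-taxon map (or whose taxon lacks a lineage) are retained with an
#' all-unclassified lineage and reported via a message. Sequences and
#' record count are never altered.
#'
#' @param records A data.frame with columns \code{id}, \code{sequence},
#'   \code{description}.
#' @param idToTaxon Named character vector: record id -> taxon id.
#' @param taxonToLineage A matrix or data.frame of seven rank columns with
#'   rownames (or an \code{id} column) giving taxon ids.
#' @return A \code{\link{ReferenceDb}} with one record per input row.
#' @export
attachLineages <- function(records, idToTaxon, taxonToLineage) {
  records <- as.data.frame(records)
  n <- nrow(records)
  ids <- as.character(records$id)
  tl <- as.data.frame(taxonToLineage)
  if ("id" %in% colnames(tl)) {
    rownames(tl) <- tl$id
    tl$id <- NULL
  }
  lin <- emptyLineage(n)
  taxon <- unname(idToTaxon[ids])
  hit <- !is.na(taxon) & taxon %in% rownames(tl)
  if (any(hit))
    lin[hit, ] <- asLineage(tl[taxon[hit], , drop = FALSE])
  if (any(!hit))
    message(sum(!hit), " record(s) without taxonomy mapping; ",
            "kept with all-unclassified lineage")
  ReferenceDb(setNames(as.character(records$sequence), ids),
              description = as.character(records$description),
              lineage = lin)
}

#' Build a curated reference set from raw records
#'
#' Runs keyword selection (\code{\link{selectLsuRecords}}) then lineage
#' attachment (\code{\link{attachLineages}}).
#'
#' @inheritParams attachLineages
#' @return A \code{\link{ReferenceDb}} of the selected, annotated records.
#' @export
buildReferenceDb <- function(records, idToTaxon, taxonToLineage) {
  records <- as.data.frame(records)
  keep <- records$id %in% selectLsuRecords(records)
  attachLineages(records[keep, , drop = FALSE], idToTaxon, taxonToLineage)
}

#' Read a reference set from FASTA + lineage TSV
#'
#' @param fasta Path to a FASTA of reference sequences; the first
#'   whitespace-delimited word of each header is the record id, the
#'   remainder the description.
#' @param lineageTsv Path to a TSV with header \code{id} plus the seven
#'   ranks; empty fields are unclassified. May be \code{NULL}.
#' @return A \code{\link{ReferenceDb}}.
#' @export
readReferenceDb <- function(fasta, lineageTsv = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  hdr <- names(seqs)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  names(seqs) <- id
  lin <- emptyLineage(length(seqs))
  if (!is.null(lineageTsv)) {
    tab <- utils::read.delim(lineageTsv, colClasses = "character")
    rownames(tab) <- tab$id
    hit <- id %in% rownames(tab)
    lin[hit, ] <- asLineage(tab[id[hit], taxRanks(), drop = FALSE])
  }
  ReferenceDb(seqs, description = desc, lineage = lin)
}

#' Write a reference set as FASTA + lineage TSV
#'
#' @param db A \code{\link{ReferenceDb}}.
#' @param fasta Output FASTA path (headers: \code{id description}).
#' @param lineageTsv Output TSV path (\code{id} + seven rank columns;
#'   unclassified ranks written as empty fields).
#' @return Invisibly, \code{db}.
#' @export
writeReferenceDb <- function(db, fasta, lineageTsv = NULL) {
  seqs <- refSequences(db)
  out <- seqs
  names(out) <- trimws(paste(refIds(db), refDescriptions(db)))
  Biostrings::writeXStringSet(out, fasta)
  if (!is.null(lineageTsv)) {
    lin <- refLineages(db)
    lin[lin == unclassifiedLabel()] <- ""
    tab <- data.frame(id = refIds(db), lin, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, lineageTsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(db)
}
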