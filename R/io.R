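# FASTQ / quality helpers. Reads are carried through the pipeline as
# QualityScaledDNAStringSet (Phred+33 on disk).

#' Read a FASTQ file into a QualityScaledDNAStringSet
#' @param path FASTQ path (gzip allowed).
#' @return A \code{QualityScaledDNAStringSet}.
#' @export
readFastqReads <- function(path) {
  Biostrings::readQualityScaledDNAStringSet(path)
}

#' Write reads as FASTQ (Phred+33)
#' @param x A \code{QualityScaledDNAStringSet}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeFastqReads <- function(x, path) {
  Biostrings::writeXStringSet(as(x, "DNAStringSet"), path,
                              format = "fastq",
                              qualities = Biostrings::BStringSet(
                                Biostrings::quality(x)))
  invisible(path)
}

# integer Phred vectors for each read
.qualInts <- function(x) {
  as(Biostrings::quality(x), "IntegerList")
}

# integer Phred vector -> Phred+33 string
.phredString <- function(q) {
  if (length(q) == 0L) return("")
  intToUtf8(pmin(q, 60L) + 33L)
}

# build a QualityScaledDNAStringSet from sequences + list of integer quals
.makeQSD <- function(seqs, qualInts, ids = NULL) {
  s <- Biostrings::DNAStringSet(seqs)
  qs <- Biostrings::PhredQuality(vapply(qualInts, .phredString, ""))
  x <- Biostrings::QualityScaledDNAStringSet(s, qs)
  if (!is.null(ids)) names(x) <- ids
  x
}
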