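#' The seven taxonomic ranks used throughout the package
#'
#' Lineages are represented as character matrices with these seven columns
#' (domain to species), using the distinguished label
#' \code{"unclassified"} for missing ranks.
#'
#' @return Character vector of the seven rank names, in fixed order.
#' @export
#' @examples
#' taxRanks()
taxRanks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

#' Distinguished label for a missing rank
#' @return The string used for unclassified ranks.
#' @export
unclassifiedLabel <- function() "unclassified"

#' Build a lineage matrix
#'
#' Coerces input to an n x 7 character matrix with the \code{\link{taxRanks}}
#' columns. Empty strings and \code{NA}s become \code{"unclassified"};
#' labels are compared after trimming surrounding whitespace, so labels
#' are trimmed on entry.
#'
#' @param x A character matrix or data.frame with seven columns, or a
#'   character vector of length seven (a single lineage).
#' @return Character matrix with columns \code{taxRanks()}.
#' @export
#' @examples
#' asLineage(c("Fungi", "Basidiomycota", "Agaricomycetes", "Agaricales",
#'             "Mycenaceae", "Mycena", "Mycena chlorophos"))
asLineage <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != 7L)
    stop("a lineage has exactly seven ranks (domain..species)")
  x[] <- trimws(as.character(x))
  x[is.na(x) | x == ""] <- unclassifiedLabel()
  colnames(x) <- taxRanks()
  x
}

#' Number of classified ranks in each lineage
#'
#' @param lineage A lineage matrix (see \code{\link{asLineage}}).
#' @return Integer vector in 0..7, one entry per row.
#' @export
#' @examples
#' lineageCompleteness(asLineage(c("Fungi", rep("", 6))))
lineageCompleteness <- function(lineage) {
  lineage <- asLineage(lineage)
  as.integer(rowSums(lineage != unclassifiedLabel()))
}

#' An all-unclassified lineage matrix
#' @param n Number of rows.
#' @return n x 7 matrix of \code{"unclassified"}.
#' @export
emptyLineage <- function(n = 1L) {
  asLineage(matrix(unclassifiedLabel(), nrow = n, ncol = 7L))
}

# ---------------------------------------------------------------------------

#' ReferenceDb: a taxonomy-annotated LSU reference set
#'
#' Holds reference sequences (a \code{DNAStringSet} named by record id),
#' their free-text descriptions, and a seven-rank lineage matrix, row for
#' row.
#'
#' @slot sequences \code{DNAStringSet}, names are unique record ids.
#' @slot description Character vector of free-text descriptions.
#' @slot lineage Character matrix, one row per record, columns
#'   \code{\link{taxRanks}}.
#' @export
setClass("ReferenceDb",
  representation(
    sequences = "DNAStringSet",
    description = "character",
    lineage = "matrix"
  )
)

setValidity("ReferenceDb", function(object) {
  n <- length(object@sequences)
  msg <- character()
  ids <- names(object@sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msg <- c(msg, "sequences must be named by record id")
  else if (anyDuplicated(ids))
    msg <- c(msg, "record ids must be unique")
  if (length(object@description) != n)
    msg <- c(msg, "description length must match sequence count")
  if (nrow(object@lineage) != n || ncol(object@lineage) != 7L)
    msg <- c(msg, "lineage must be an n x 7 character matrix")
  if (n > 0 && any(Biostrings::width(object@sequences) == 0L))
    msg <- c(msg, "sequences must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Construct a ReferenceDb
#'
#' @param sequences \code{DNAStringSet} (or named character vector) of
#'   reference sequences; names are record ids.
#' @param description Character vector of descriptions (defaults to empty
#'   strings).
#' @param lineage Lineage matrix, one row per sequence; defaults to
#'   all-unclassified.
#' @return A \code{ReferenceDb}.
#' @export
#' @examples
#' db <- ReferenceDb(c(r1 = "ACGTACGTACGT"),
#'                   description = "28S ribosomal RNA gene")
#' db
ReferenceDb <- function(sequences, description = NULL, lineage = NULL) {
  if (!is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  n <- length(sequences)
  if (is.null(description)) description <- character(n)
  if (is.null(lineage)) lineage <- emptyLineage(n) else
    lineage <- asLineage(lineage)
  rownames(lineage) <- names(sequences)
  new("ReferenceDb", sequences = sequences,
      description = as.character(description), lineage = lineage)
}

#' @describeIn ReferenceDb-class Record ids.
#' @param x,object A \code{ReferenceDb}.
#' @export
refIds <- function(x) names(x@sequences)

#' @describeIn ReferenceDb-class Reference sequences (\code{DNAStringSet}).
#' @export
refSequences <- function(x) x@sequences

#' @describeIn ReferenceDb-class Free-text descriptions.
#' @export
refDescriptions <- function(x) x@description

#' @describeIn ReferenceDb-class Seven-rank lineage matrix.
#' @export
refLineages <- function(x) x@lineage

#' @export
setMethod("length", "ReferenceDb", function(x) length(x@sequences))

#' @export
setMethod("[", "ReferenceDb", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, refIds(x))
  new("ReferenceDb", sequences = x@sequences[i],
      description = x@description[i],
      lineage = x@lineage[i, , drop = FALSE])
})

#' @export
setMethod("show", "ReferenceDb", function(object) {
  n <- length(object)
  cat("ReferenceDb with", n, "records\n")
  if (n > 0) {
    cat("  sequence widths:", min(width(object@sequences)), "-",
        max(width(object@sequences)), "bp\n")
    dom <- table(object@lineage[, "domain"])
    cat("  domains:",
        paste(names(dom), as.integer(dom), sep = ":", collapse = " "),
        "\n")
  }
  invisible(NULL)
})

# ---------------------------------------------------------------------------

#' OtuExperiment: pooled OTU table with centroids and lineages
#'
#' A thin \code{SummarizedExperiment} subclass: the \code{"counts"} assay
#' is OTU x sample read counts, \code{rowData} carries the centroid
#' sequence (column \code{centroid}) and the assigned seven-rank lineage
#' (columns \code{taxRanks()}).
#'
#' @export
setClass("OtuExperiment", contains = "SummarizedExperiment")

setValidity("OtuExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("centroid", taxRanks())
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an OtuExperiment
#'
#' @param counts OTU x sample integer matrix (rownames = OTU ids,
#'   colnames = sample ids).
#' @param centroid Character vector of centroid sequences, one per OTU.
#' @param lineage Lineage matrix, one row per OTU (default all
#'   unclassified).
#' @param sampleData Optional \code{DataFrame} of per-sample metadata.
#' @return An \code{OtuExperiment}.
#' @export
OtuExperiment <- function(counts, centroid, lineage = NULL,
                          sampleData = NULL) {
  counts <- as.matrix(counts)
  if (is.null(lineage)) lineage <- emptyLineage(nrow(counts)) else
    lineage <- asLineage(lineage)
  rd <- S4Vectors::DataFrame(centroid = as.character(centroid))
  for (rk in taxRanks()) rd[[rk]] <- lineage[, rk]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd,
    colData = if (is.null(sampleData))
      S4Vectors::DataFrame(row.names = colnames(counts)) else sampleData)
  new("OtuExperiment", se)
}

#' @describeIn OtuExperiment-class OTU x sample count matrix.
#' @param x An \code{OtuExperiment}.
#' @export
otuCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn OtuExperiment-class Centroid sequences, named by OTU id.
#' @export
otuCentroids <- function(x) {
  setNames(SummarizedExperiment::rowData(x)$centroid, rownames(x))
}

#' @describeIn OtuExperiment-class Assigned lineage matrix.
#' @export
otuLineages <- function(x) {
  rd <- SummarizedExperiment::rowData(x)
  m <- as.matrix(as.data.frame(rd[, taxRanks()]))
  rownames(m) <- rownames(x)
  asLineage(m)
}

#' @export
setMethod("show", "OtuExperiment", function(object) {
  cat("OtuExperiment:", nrow(object), "OTUs x", ncol(object), "samples\n")
  cat("  reads per sample:",
      paste(colnames(object), colSums(otuCounts(object)), sep = "=",
            collapse = " "), "\n")
  invisible(NULL)
})
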