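#' @useDynLib hervloci, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement subseq translate BStringSet matchPattern DNAString
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom IRanges IRanges coverage Views
#' @importFrom GenomeInfoDb seqlevels seqlengths seqinfo Seqinfo
#' @importFrom stats rbinom rmultinom rnorm runif setNames quantile median
#' @importFrom utils write.table read.delim head tail packageVersion
NULL

#' Catalogue of endogenous retrovirus elements
#'
#' A \code{Catalogue} holds one DNA sequence per element (provirus, solo LTR,
#' fragmentary LTR or host gene), treated downstream as an independent
#' "chromosome" for alignment, together with per-element metadata and
#' feature annotations (LTR regions, retroviral genes) as a
#' \link[GenomicRanges]{GRanges} keyed by element id.
#'
#' Element metadata columns (in \code{elementInfo}):
#' \describe{
#'   \item{id}{unique element identifier}
#'   \item{class}{one of \code{provirus}, \code{solo_ltr},
#'     \code{fragmentary_ltr}, \code{host_gene}}
#'   \item{ltr_group}{LTR phylogenetic group: \code{Hs}, \code{5A},
#'     \code{5B} or \code{unknown}}
#'   \item{type}{provirus type at the pol-env boundary: \code{type1}
#'     (292-bp deletion), \code{type2} or \code{unknown}}
#'   \item{divergence}{substitution proportion relative to the family
#'     ancestor (a proxy for age); \code{NA} when unknown}
#' }
#'
#' @slot elements a \link[Biostrings]{DNAStringSet}, one record per element,
#'   uppercase ACGTN.
#' @slot elementInfo a \link[S4Vectors]{DataFrame} with one row per element.
#' @slot features a \link[GenomicRanges]{GRanges} on element coordinates
#'   (1-based inclusive) with a \code{feature} metadata column naming the
#'   region (\code{U3}, \code{R}, \code{U5}, \code{leader}, \code{gag},
#'   \code{pro}, \code{pol}, \code{env}).
#'
#' @seealso [loadCatalogue()], [generateFamily()], [extractLTR()]
#' @export
setClass("Catalogue",
  representation(
    elements = "DNAStringSet",
    elementInfo = "DataFrame",
    features = "GRanges"
  )
)

setValidity("Catalogue", function(object) {
  ids <- names(object@elements)
  msgs <- character()
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    msgs <- c(msgs, "all elements must be named with nonempty ids")
  if (anyDuplicated(ids))
    msgs <- c(msgs, sprintf("duplicate element id(s): %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (nrow(object@elementInfo) != length(object@elements))
    msgs <- c(msgs, "elementInfo must have one row per element")
  if (length(object@features)) {
    fid <- as.character(seqnames(object@features))
    bad <- setdiff(unique(fid), ids)
    if (length(bad))
      msgs <- c(msgs, sprintf("features reference unknown element(s): %s",
                              paste(bad, collapse = ", ")))
    len <- setNames(width(object@elements), ids)
    over <- fid %in% ids &
      (start(object@features) < 1L | end(object@features) > len[fid])
    if (any(over))
      msgs <- c(msgs, sprintf("feature outside sequence bounds for element(s): %s",
                              paste(unique(fid[over]), collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn Catalogue number of elements
#' @param x a Catalogue
#' @export
setMethod("length", "Catalogue", function(x) length(x@elements))

#' @describeIn Catalogue element ids
#' @export
setMethod("names", "Catalogue", function(x) names(x@elements))

setMethod("show", "Catalogue", function(object) {
  cls <- table(object@elementInfo$class)
  cat("Catalogue of", length(object), "elements (",
      paste(sprintf("%s: %d", names(cls), as.integer(cls)), collapse = ", "),
      ")\n")
  cat("  features:", length(object@features), "annotation(s) on",
      length(unique(as.character(seqnames(object@features)))), "element(s)\n")
})

#' Ground-truth transcription profile for a synthetic family
#'
#' Holds the transcript sequences emitted by [makeTruthProfile()] together
#' with their source element, transcription mechanism, exon structure on the
#' (possibly flank-extended) reference record, and molar fractions in the
#' cell and virion samples. Fractions sum to 1 per sample over transcripts
#' with nonzero weight.
#'
#' @slot transcripts a \link[Biostrings]{DNAStringSet} of transcript
#'   sequences (already strand-resolved: the stored sequence is the
#'   transcript sense).
#' @slot info a \link[S4Vectors]{DataFrame} with columns
#'   \code{transcript_id}, \code{element_id}, \code{mechanism},
#'   \code{strand}, \code{exons} (\code{"start-end;start-end"} in reference
#'   coordinates), \code{cell_fraction}, \code{virion_fraction}.
#' @export
setClass("TruthProfile",
  representation(transcripts = "DNAStringSet", info = "DataFrame"))

setValidity("TruthProfile", function(object) {
  msgs <- character()
  if (nrow(object@info) != length(object@transcripts))
    msgs <- c(msgs, "info must have one row per transcript")
  for (col in c("cell_fraction", "virion_fraction")) {
    f <- object@info[[col]]
    if (length(f) && sum(f) > 0 && abs(sum(f) - 1) > 1e-8)
      msgs <- c(msgs, sprintf("%s must sum to 1 (got %.6f)", col, sum(f)))
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TruthProfile", function(object) {
  cat("TruthProfile with", length(object@transcripts), "transcript(s)\n")
  tab <- table(object@info$mechanism)
  cat("  mechanisms:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
})

#' Paired-end read library
#'
#' In-memory representation of a simulated (or loaded) paired-end library:
#' mate sequences, Phred+33 quality strings, and optional per-pair truth
#' labels (source transcript and fragment coordinates).
#'
#' @slot mate1,mate2 \link[Biostrings]{DNAStringSet}s of equal length.
#' @slot qual1,qual2 character vectors of Phred+33 quality strings.
#' @slot truth \code{DataFrame} with zero rows (no truth) or one row per
#'   pair: \code{pair_id}, \code{transcript_id}, \code{frag_start},
#'   \code{frag_end}, \code{strand}.
#' @export
setClass("ReadLibrary",
  representation(mate1 = "DNAStringSet", mate2 = "DNAStringSet",
                 qual1 = "character", qual2 = "character",
                 truth = "DataFrame"))

setValidity("ReadLibrary", function(object) {
  msgs <- character()
  n <- length(object@mate1)
  # a zero-length mate2 denotes a single-end library
  if (!(length(object@mate2) %in% c(0L, n)))
    msgs <- c(msgs, "mates differ in pair count")
  if (length(object@qual1) != n ||
      length(object@qual2) != length(object@mate2))
    msgs <- c(msgs, "quality vectors must match pair count")
  if (n && (any(nchar(object@qual1) != width(object@mate1)) ||
            any(nchar(object@qual2) != width(object@mate2))))
    msgs <- c(msgs, "sequence and quality lengths differ")
  if (nrow(object@truth) && nrow(object@truth) != n)
    msgs <- c(msgs, "truth table must have one row per pair")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ReadLibrary number of read pairs
#' @param x a ReadLibrary
#' @export
setMethod("length", "ReadLibrary", function(x) length(x@mate1))

setMethod("show", "ReadLibrary", function(object) {
  cat("ReadLibrary with", length(object), "pair(s);",
      if (nrow(object@truth)) "truth labels attached" else "no truth labels",
      "\n")
})

#' Fragment count table
#'
#' Per-element fragment mass under one counting mode, plus the run-level
#' mapped-fragment total \code{N} used as the per-million denominator for
#' FPKM. \code{N} counts every concordantly aligned pair in the run
#' (including host-context decoys) and is identical across counting modes, so
#' unique-only filtering lowers a locus's FPKM rather than silently
#' renormalising it away.
#'
#' @slot counts named numeric vector of fragment mass per element.
#' @slot mode counting mode: \code{unfiltered_uniform}, \code{unique_only} or
#'   \code{em_rescue}.
#' @slot strandMode \code{plus_stranded} or \code{unstranded}.
#' @slot nMapped total concordantly aligned pairs in the run (the FPKM
#'   denominator N).
#' @slot nCounted pairs contributing mass under this mode (after strand
#'   filtering and, for unique_only, multi-read removal).
#' @export
setClass("CountTable",
  representation(counts = "numeric", mode = "character",
                 strandMode = "character", nMapped = "numeric",
                 nCounted = "numeric"))

setMethod("show", "CountTable", function(object) {
  cat(sprintf("CountTable [%s, %s]: %d element(s), N = %d, counted pairs = %.2f\n",
              object@mode, object@strandMode, length(object@counts),
              as.integer(object@nMapped), object@nCounted))
})
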