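#' Construct a Catalogue
#'
#' Low-level constructor; most users obtain a Catalogue from
#' [loadCatalogue()] or [generateFamily()].
#'
#' @param elements named \link[Biostrings]{DNAStringSet} (or named character
#'   vector) of element sequences. Sequences are uppercased and RNA
#'   \code{U} is normalised to \code{T}.
#' @param elementInfo optional data.frame/DataFrame with columns \code{id},
#'   \code{class}, \code{ltr_group}, \code{type}, \code{divergence}; missing
#'   columns are filled with defaults (\code{provirus}/\code{unknown}).
#' @param features optional \link[GenomicRanges]{GRanges} of annotations on
#'   element coordinates with a \code{feature} metadata column.
#' @return a [Catalogue-class] object.
#' @export
Catalogue <- function(elements, elementInfo = NULL, features = GRanges()) {
  if (is.character(elements)) {
    elements <- DNAStringSet(toupper(chartr("u", "t", elements)))
  } else {
    elements <- DNAStringSet(toupper(as.character(elements)))
  }
  ids <- names(elements)
  if (is.null(elementInfo)) elementInfo <- DataFrame(id = ids)
  elementInfo <- DataFrame(elementInfo)
  if (is.null(elementInfo$id)) elementInfo$id <- ids
  if (is.null(elementInfo$class)) elementInfo$class <- "provirus"
  if (is.null(elementInfo$ltr_group)) elementInfo$ltr_group <- "unknown"
  if (is.null(elementInfo$type)) elementInfo$type <- "unknown"
  if (is.null(elementInfo$divergence)) elementInfo$divergence <- NA_real_
  elementInfo <- elementInfo[match(ids, elementInfo$id), , drop = FALSE]
  rownames(elementInfo) <- NULL
  if (length(features)) {
    suppressWarnings({
      # out-of-bound features surface as a validity error below
      GenomeInfoDb::seqlevels(features) <- ids
      GenomeInfoDb::seqlengths(features) <- setNames(width(elements), ids)
    })
  }
  new("Catalogue", elements = elements, elementInfo = elementInfo,
      features = features)
}

#' Element metadata accessor
#' @param x a [Catalogue-class]
#' @return DataFrame with one row per element.
#' @export
elementInfo <- function(x) x@elementInfo

#' Element sequences accessor
#' @param x a [Catalogue-class]
#' @param id optional element id(s) to subset.
#' @return a DNAStringSet.
#' @export
elementSeqs <- function(x, id = NULL) {
  if (is.null(id)) return(x@elements)
  .checkElement(x, id)
  x@elements[id]
}

#' Feature annotations accessor
#' @param x a [Catalogue-class]
#' @return GRanges of annotations.
#' @export
elementFeatures <- function(x) x@features

#' Ids of family (provirus) elements
#'
#' The provirus members define the "family" over which relative abundance is
#' normalised; solo LTRs, fragmentary LTRs and host genes are excluded.
#' @param x a [Catalogue-class]
#' @export
familyIds <- function(x) x@elementInfo$id[x@elementInfo$class == "provirus"]

.checkElement <- function(cat, id) {
  missing <- setdiff(id, names(cat))
  if (length(missing))
    stop("element unknown: ", paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

.featureSpan <- function(cat, id, feature) {
  f <- cat@features
  hit <- f[as.character(seqnames(f)) == id & f$feature == feature]
  if (!length(hit)) return(NULL)
  c(start(hit)[1], end(hit)[length(hit)])
}

#' Span of an LTR on an element
#'
#' @param cat a [Catalogue-class]
#' @param id element id
#' @param which \code{"5prime"} or \code{"3prime"}
#' @return integer \code{c(start, end)} (1-based inclusive) or \code{NULL}
#'   when the element carries no such annotation.
#' @export
ltrSpan <- function(cat, id, which = c("5prime", "3prime")) {
  which <- match.arg(which)
  .checkElement(cat, id)
  f <- cat@features
  ltr <- f[as.character(seqnames(f)) == id & f$feature %in% c("U3", "R", "U5")]
  if (!length(ltr)) {
    # degenerate classes: a solo or fragmentary LTR record *is* the LTR
    cls <- cat@elementInfo$class[match(id, cat@elementInfo$id)]
    if (cls %in% c("solo_ltr", "fragmentary_ltr"))
      return(c(1L, width(cat@elements[[id]])))
    return(NULL)
  }
  # cluster contiguous U3/R/U5 blocks into LTR units: the 5' LTR is the
  # leftmost cluster, the 3' LTR the rightmost (a single cluster is both)
  ord <- order(start(ltr))
  ltr <- ltr[ord]
  gap <- start(ltr)[-1] - end(ltr)[-length(ltr)]
  cl <- cumsum(c(1L, as.integer(gap > 100L)))
  pick <- ltr[cl == if (which == "5prime") min(cl) else max(cl)]
  c(min(start(pick)), max(end(pick)))
}

#' Extract an LTR sequence from a catalogue element
#'
#' Returns the 5' or 3' LTR subsequence on the element-sense strand. For solo
#' and fragmentary LTR records the whole record is the LTR. Errors
#' distinguish an unknown element from an element lacking the annotation.
#'
#' @inheritParams ltrSpan
#' @return a [Biostrings::DNAString] of the LTR.
#' @examples
#' cat <- generateFamily(familySpec(seed = 1))$catalogue
#' extractLTR(cat, names(cat)[1], "5prime")
#' @export
extractLTR <- function(cat, id, which = c("5prime", "3prime")) {
  which <- match.arg(which)
  .checkElement(cat, id)
  span <- ltrSpan(cat, id, which)
  if (is.null(span))
    stop("element has no LTR annotation: ", id, call. = FALSE)
  subseq(cat@elements[[id]], span[1], span[2])
}

#' Load a catalogue from FASTA + GTF
#'
#' Reads a multi-FASTA of element sequences (one record per element) and a
#' GTF of per-element annotations carrying \code{element_id} and
#' \code{feature_name} attributes. Sequences are uppercased and U normalised
#' to T. Duplicate FASTA ids and features outside sequence bounds are hard
#' errors.
#'
#' @param fasta_path multi-FASTA of element sequences.
#' @param gtf_path GTF annotation file; may contain zero features.
#' @param elementInfo optional element metadata (see [Catalogue()]); when
#'   \code{NULL}, metadata is recovered from an \code{elem_class} GTF
#'   attribute if present, else defaulted.
#' @return a [Catalogue-class].
#' @export
loadCatalogue <- function(fasta_path, gtf_path = NULL, elementInfo = NULL) {
  if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path)
  seqs <- readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate element id(s) in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  features <- GRanges()
  if (!is.null(gtf_path) && file.exists(gtf_path) &&
      length(readLines(gtf_path, n = 1)) > 0) {
    g <- rtracklayer::import(gtf_path, format = "gtf")
    if (length(g)) {
      bad <- !(as.character(seqnames(g)) %in% names(seqs))
      if (any(bad))
        stop("GTF references unknown element(s): ",
             paste(unique(as.character(seqnames(g))[bad]), collapse = ", "))
      lens <- setNames(width(seqs), names(seqs))
      out <- start(g) < 1 | end(g) > lens[as.character(seqnames(g))]
      if (any(out))
        stop("GTF feature outside sequence bounds for element(s): ",
             paste(unique(as.character(seqnames(g))[out]), collapse = ", "))
      feature <- if (!is.null(g$feature_name)) g$feature_name else g$type
      features <- GRanges(seqnames(g), IRanges(start(g), end(g)),
                          strand = strand(g), feature = as.character(feature))
      if (is.null(elementInfo) && !is.null(g$elem_class)) {
        info <- unique(data.frame(id = as.character(seqnames(g)),
                                  class = as.character(g$elem_class)))
        elementInfo <- info[!duplicated(info$id), , drop = FALSE]
      }
    }
  }
  Catalogue(seqs, elementInfo = elementInfo, features = features)
}

#' Write a catalogue as FASTA + GTF
#'
#' FASTA is wrapped at 60 columns; the GTF (2.2 dialect) carries
#' \code{gene_id}, \code{element_id}, \code{feature_name} and
#' \code{elem_class} attributes so a load/write/load round trip is the
#' identity on sequences and feature spans.
#'
#' @param cat a [Catalogue-class]
#' @param fasta_path,gtf_path output paths.
#' @return invisibly, the two paths.
#' @export
writeCatalogue <- function(cat, fasta_path, gtf_path) {
  writeXStringSet(cat@elements, fasta_path, width = 60L)
  f <- cat@features
  info <- cat@elementInfo
  if (length(f)) {
    ids <- as.character(seqnames(f))
    cls <- info$class[match(ids, info$id)]
    strands <- as.character(strand(f))
    strands[strands == "*"] <- "+"
    lines <- sprintf(
      "%s\thervloci\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; element_id \"%s\"; feature_name \"%s\"; elem_class \"%s\";",
      ids, f$feature, start(f), end(f), strands, ids, ids, f$feature, cls)
  } else lines <- character()
  writeLines(lines, gtf_path)
  invisible(c(fasta_path, gtf_path))
}
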