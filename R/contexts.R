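#' Host genomic contexts for catalogue elements
#'
#' For each element with a non-isolated scenario, the context embeds the
#' element in flanking host sequence, producing an extended reference record
#' (flank + element + flank) used for alignment and coverage, plus the
#' coordinates of any neighbor transcription unit and any engineered splice
#' junction. The five emulated situations mirror the configurations observed
#' around expressed proviruses:
#' \describe{
#'   \item{isolated}{no flanks; the element record itself is the reference.}
#'   \item{divergent_neighbor_gene}{a transcribed gene upstream in the
#'     opposite orientation (the PRODH-like configuration); the element's
#'     own 5' LTR drives its transcription.}
#'   \item{upstream_neighbor_gene}{a transcribed gene upstream in the same
#'     orientation reading through into the element.}
#'   \item{intronic}{the element resides in an intron of a host gene; its
#'     reads are pre-mRNA passengers.}
#'   \item{upstream_fragmentary_ltr}{a recent fragmentary LTR 551 bp
#'     upstream whose R region starts a transcript that splices (GT..AG)
#'     from its gag leader into the element's gag leader.}
#'   \item{antisense_neighbor}{a downstream element drives minus-strand
#'     transcription across the provirus.}
#' }
#'
#' @slot info \code{DataFrame}: \code{element_id}, \code{scenario},
#'   \code{offset} (bases of upstream context before the element),
#'   \code{ref_len}, \code{core_len}.
#' @slot refs \link[Biostrings]{DNAStringSet} of extended reference records,
#'   named by element id.
#' @slot neighbors \code{DataFrame}: \code{element_id}, \code{start},
#'   \code{end}, \code{strand} of neighbor transcription units in extended
#'   coordinates.
#' @slot splices \code{DataFrame}: engineered chimeric junctions
#'   (\code{element_id}, \code{donor} = last exon-1 base, \code{acceptor} =
#'   first exon-2 base, extended coordinates, plus \code{frag_len} and
#'   \code{tss} of the upstream fragment transcript).
#' @export
setClass("HostContexts",
  representation(info = "DataFrame", refs = "DNAStringSet",
                 neighbors = "DataFrame", splices = "DataFrame"))

setMethod("show", "HostContexts", function(object) {
  cat("HostContexts for", nrow(object@info), "element(s):\n")
  print(table(object@info$scenario))
})

.CONTEXT_SCENARIOS <- c("isolated", "divergent_neighbor_gene",
                        "upstream_neighbor_gene", "intronic",
                        "upstream_fragmentary_ltr", "antisense_neighbor")

.FRAG_LTR_GAP <- 551L   # fragmentary LTR sits 551 bp upstream of the element
.FRAG_DONOR <- 1074L    # last transcribed base of the fragment (gag leader)
.FRAG_TSS <- 826L       # transcription starts mid-R of the fragment
.ELEM_ACCEPTOR <- 1018L # splice lands at element gag-leader position 1018

#' Build host contexts for catalogue elements
#'
#' @param cat a [Catalogue-class].
#' @param scenarios named character vector mapping element ids to a scenario
#'   (see [HostContexts-class]). Elements not named are treated as isolated.
#' @param seed integer seed for the flanking host sequence.
#' @param flank flank length in bp on each side (default 2000).
#' @return a [HostContexts-class].
#' @export
buildHostContexts <- function(cat, scenarios, seed = 1L, flank = 2000L) {
  stopifnot(is(cat, "Catalogue"))
  .checkElement(cat, names(scenarios))
  bad <- setdiff(scenarios, .CONTEXT_SCENARIOS)
  if (length(bad)) stop("unknown scenario(s): ", paste(bad, collapse = ", "))
  withr::with_seed(seed, .buildHostContextsImpl(cat, scenarios, flank))
}

.buildHostContextsImpl <- function(cat, scenarios, flank) {
  info <- list(); refs <- character(); nb <- list(); sp <- list()
  ids <- names(cat)
  for (id in ids) {
    scen <- if (id %in% names(scenarios)) scenarios[[id]] else "isolated"
    elem <- as.character(cat@elements[[id]])
    len <- nchar(elem)
    if (scen == "isolated") {
      refs[[id]] <- elem
      info[[id]] <- data.frame(element_id = id, scenario = scen, offset = 0L,
                               ref_len = len, core_len = len)
      next
    }
    up <- .randBases(flank); down <- .randBases(flank)
    offset <- flank
    if (scen == "upstream_fragmentary_ltr") {
      # a recent LTR + gag-leader fragment placed so that 551 bp of host
      # sequence separate its end from the element start
      frag_len <- .FRAG_DONOR + 26L  # a little leader beyond the donor site
      frag <- .mutateSeq(substr(.buildContextDonor(cat), 1L, frag_len),
                         0.002)$seq
      frag <- .plant(frag, .FRAG_DONOR + 1L, "GT")  # intron starts after donor
      up <- paste0(frag, .randBases(.FRAG_LTR_GAP))
      offset <- nchar(up)
      sp[[id]] <- data.frame(element_id = id, donor = .FRAG_DONOR,
                             acceptor = offset + .ELEM_ACCEPTOR,
                             frag_len = frag_len, tss = .FRAG_TSS)
    }
    ref <- paste0(up, elem, down)
    if (scen == "divergent_neighbor_gene") {
      # neighbor transcribed away from the element, ending ~200 bp upstream
      nb[[id]] <- data.frame(element_id = id, start = 1L,
                             end = offset - 200L, strand = "-")
    } else if (scen == "upstream_neighbor_gene") {
      nb[[id]] <- data.frame(element_id = id, start = 1L,
                             end = offset - 200L, strand = "+")
    } else if (scen == "intronic") {
      nb[[id]] <- data.frame(element_id = id, start = 1L,
                             end = nchar(ref), strand = "+")
    } else if (scen == "antisense_neighbor") {
      nb[[id]] <- data.frame(element_id = id, start = offset + len + 1L,
                             end = offset + len + 800L, strand = "-")
    }
    refs[[id]] <- ref
    info[[id]] <- data.frame(element_id = id, scenario = scen,
                             offset = offset, ref_len = nchar(ref),
                             core_len = len)
  }
  rbindDF <- function(x) if (length(x)) DataFrame(do.call(rbind, x)) else
    DataFrame(element_id = character(0))
  new("HostContexts", info = DataFrame(do.call(rbind, unname(info))),
      refs = DNAStringSet(setNames(unlist(refs), names(refs))),
      neighbors = rbindDF(unname(nb)), splices = rbindDF(unname(sp)))
}

## template for the fragmentary LTR: the least diverged provirus in the
## catalogue (its LTR + leader approximate a recent LTR Hs element)
.buildContextDonor <- function(cat) {
  info <- cat@elementInfo
  prov <- info[info$class == "provirus", , drop = FALSE]
  pick <- prov$id[order(prov$divergence)][1]
  as.character(cat@elements[[pick]])
}

#' Empty (all-isolated) contexts
#' @param cat a [Catalogue-class].
#' @return a [HostContexts-class] with every element isolated.
#' @export
isolatedContexts <- function(cat) {
  buildHostContexts(cat, setNames(character(0), character(0)), seed = 1L)
}

#' Alignment reference records from a catalogue and its contexts
#'
#' @param cat a [Catalogue-class].
#' @param contexts optional [HostContexts-class]; when \code{NULL} the raw
#'   element records are used.
#' @return list with \code{seqs} (DNAStringSet), \code{offset} and
#'   \code{core_len} (named integer vectors per record).
#' @export
referenceSet <- function(cat, contexts = NULL) {
  if (is.null(contexts)) {
    list(seqs = cat@elements,
         offset = setNames(integer(length(cat)), names(cat)),
         core_len = setNames(width(cat@elements), names(cat)))
  } else {
    list(seqs = contexts@refs,
         offset = setNames(contexts@info$offset, contexts@info$element_id),
         core_len = setNames(contexts@info$core_len, contexts@info$element_id))
  }
}
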