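#' Reference protein lengths for the ancestral gene layout
#'
#' Amino-acid lengths (excluding the stop) of the intact ancestral ORFs:
#' gag 666, pro 299, pol 899, env 579.
#' @return named integer vector.
#' @export
ancestralOrfLengths <- function() {
  setNames(as.integer(.GENE_LEN / 3L - 1L), names(.GENE_LEN))
}

#' Find retroviral gene ORFs on an element
#'
#' Plain three-frame plus-strand ORF scan (proviral genes are
#' sense-encoded): for each annotated gene span, the longest ATG-initiated
#' stop-terminated ORF overlapping the span by at least 50\% is assigned to
#' that gene. Status is \code{full_length} when the ORF reaches at least
#' 95\% of the reference protein length, \code{truncated} otherwise, and
#' \code{absent} when no qualifying ORF exists.
#'
#' @param cat a [Catalogue-class].
#' @param id element id.
#' @param reference_lengths named aa lengths per gene
#'   (default [ancestralOrfLengths()]).
#' @param genes genes to assess.
#' @return data.frame: \code{element_id}, \code{gene}, \code{start},
#'   \code{end}, \code{length_aa}, \code{status}.
#' @export
findOrfs <- function(cat, id, reference_lengths = ancestralOrfLengths(),
                     genes = names(reference_lengths)) {
  .checkElement(cat, id)
  seq <- cat@elements[[id]]
  orfs <- .scanOrfs(seq)
  out <- lapply(genes, function(g) {
    sp <- .featureSpan(cat, id, g)
    row <- data.frame(element_id = id, gene = g, start = NA_integer_,
                      end = NA_integer_, length_aa = NA_integer_,
                      status = "absent", stringsAsFactors = FALSE)
    if (is.null(sp) || !nrow(orfs)) return(row)
    glen <- sp[2] - sp[1] + 1
    ov <- pmin(orfs$end, sp[2]) - pmax(orfs$start, sp[1]) + 1
    cand <- orfs[ov >= 0.5 * glen, , drop = FALSE]
    if (!nrow(cand)) return(row)
    best <- cand[which.max(cand$length_aa), ]
    row$start <- best$start; row$end <- best$end
    row$length_aa <- best$length_aa
    row$status <- if (best$length_aa >= 0.95 * reference_lengths[[g]])
      "full_length" else "truncated"
    row
  })
  do.call(rbind, out)
}

## all ATG..stop ORFs in the three plus-strand frames
.scanOrfs <- function(seq) {
  L <- length(seq)
  rows <- list()
  for (f in 1:3) {
    n <- L - f + 1L
    n <- n - n %% 3L
    if (n < 6L) next
    aa <- as.character(suppressWarnings(
      translate(subseq(seq, f, f + n - 1L), if.fuzzy.codon = "X")))
    m <- gregexpr("M[^*]*\\*", aa)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    start <- f + 3L * (as.integer(m) - 1L)
    end <- start + 3L * len - 1L
    rows[[f]] <- data.frame(start = start, end = end, length_aa = len - 1L)
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      length_aa = integer(0)))
  do.call(rbind, rows)
}

#' Classify an element as type 1 or type 2 at the pol-env boundary
#'
#' Type 1 proviruses carry a 292-bp deletion at the pol-env boundary (they
#' encode np9); type 2 proviruses are full length there (they encode rec).
#' The two flanks of a type-2 boundary reference window are anchored in the
#' element (best ungapped placement of 40-bp anchors); the inferred deletion
#' length is the difference between the reference and element inter-anchor
#' spans. Type 1 is called for deletions in [250, 330] (centred on 292 but
#' tolerant of flank micro-variation), type 2 for [-10, 10]; unplaceable
#' anchors (e.g. a solo LTR lacking the boundary region entirely) give
#' \code{unknown}.
#'
#' @param element element sequence (character/DNAString) or a
#'   [Catalogue-class] (then give \code{id}).
#' @param boundary_reference type-2 boundary window, e.g. from
#'   [polEnvBoundaryRef()].
#' @param id element id when \code{element} is a Catalogue.
#' @param anchor_len anchor length (bp).
#' @param max_anchor_mm maximum anchor mismatches (default 30\% of anchor).
#' @param type1_window,type2_window deletion-length windows.
#' @return list: \code{type} (\code{type1}/\code{type2}/\code{unknown}),
#'   \code{deletion_len} (NA when unknown).
#' @export
classifyType <- function(element, boundary_reference, id = NULL,
                         anchor_len = 40L, max_anchor_mm = NULL,
                         type1_window = c(250L, 330L),
                         type2_window = c(-10L, 10L)) {
  if (is(element, "Catalogue")) {
    .checkElement(element, id)
    element <- as.character(element@elements[[id]])
  }
  element <- as.character(element)
  ref <- as.character(boundary_reference)
  if (is.null(max_anchor_mm)) max_anchor_mm <- as.integer(0.3 * anchor_len)
  if (nchar(ref) < 2L * anchor_len + 1L)
    stop("boundary reference shorter than two anchors")
  left <- substr(ref, 1L, anchor_len)
  right <- substr(ref, nchar(ref) - anchor_len + 1L, nchar(ref))
  unknown <- list(type = "unknown", deletion_len = NA_integer_)
  if (nchar(element) < anchor_len) return(unknown)
  lhit <- cpp_best_match(left, element)
  rhit <- cpp_best_match(right, element)
  if (is.na(lhit[1]) || is.na(rhit[1]) ||
      lhit[2] > max_anchor_mm || rhit[2] > max_anchor_mm)
    return(unknown)
  elem_gap <- rhit[1] - (lhit[1] + anchor_len)
  ref_gap <- nchar(ref) - 2L * anchor_len
  if (elem_gap < 0) return(unknown)
  del <- ref_gap - elem_gap
  type <- if (del >= type1_window[1] && del <= type1_window[2]) "type1"
    else if (del >= type2_window[1] && del <= type2_window[2]) "type2"
    else "unknown"
  list(type = type, deletion_len = as.integer(del))
}

#' Allocate relative abundance to gene ORFs
#'
#' Each element's whole abundance is allocated to every gene for which it
#' carries an ORF — the maximum probability of that ORF being expressed —
#' so per-gene totals are non-exclusive and may jointly exceed 100.
#' Splicing is not considered. Elements with no ORF for any assessed gene
#' contribute to a \code{none} category.
#'
#' @param expression a [computeExpression()] data.frame (family rows used).
#' @param orf_calls data.frame of [findOrfs()] rows covering the same
#'   elements.
#' @return data.frame: \code{gene} (the assessed genes plus \code{none}),
#'   \code{full_length}, \code{truncated}, \code{total} (percent abundance).
#' @export
allocateOrfAbundance <- function(expression, orf_calls) {
  fam <- expression[!is.na(expression$abundance), , drop = FALSE]
  genes <- unique(orf_calls$gene)
  rows <- lapply(genes, function(g) {
    oc <- orf_calls[orf_calls$gene == g, , drop = FALSE]
    st <- setNames(oc$status, oc$element_id)[fam$element_id]
    fl <- sum(fam$abundance[!is.na(st) & st == "full_length"])
    tr <- sum(fam$abundance[!is.na(st) & st == "truncated"])
    data.frame(gene = g, full_length = fl, truncated = tr, total = fl + tr)
  })
  any_orf <- vapply(fam$element_id, function(e) {
    oc <- orf_calls[orf_calls$element_id == e, , drop = FALSE]
    nrow(oc) > 0 && any(oc$status != "absent")
  }, logical(1))
  none <- sum(fam$abundance[!any_orf])
  rbind(do.call(rbind, rows),
        data.frame(gene = "none", full_length = NA_real_,
                   truncated = NA_real_, total = none))
}

#' Scan an LTR for canonical promoter motifs
#'
#' Each catalogued motif is searched within a positional window around its
#' canonical position; the best hit is the offset with fewest mismatches
#' (ties to the smallest displacement). 0 mismatches is canonical, 1 to
#' \code{max_mm} is mutated, more is missing — matching the observed
#' spectrum of 1-3-nucleotide promoter-element mutations in old LTRs.
#'
#' @param ltr_seq LTR sequence (character or DNAString).
#' @param motifs motif catalogue (default [canonicalMotifCatalogue()]).
#' @param max_mm mismatch cap for a "mutated" call.
#' @param window positional tolerance (bp either side).
#' @return list: \code{hits} (data.frame \code{name}, \code{canonical_seq},
#'   \code{canonical_start}, \code{found_start}, \code{found_seq},
#'   \code{mismatches}, \code{status}), \code{summary} (named counts
#'   \code{n_canonical}, \code{n_mutated}, \code{n_missing}).
#' @export
scanPromoterMotifs <- function(ltr_seq, motifs = canonicalMotifCatalogue(),
                               max_mm = 3L, window = 15L) {
  s <- as.character(ltr_seq)
  L <- nchar(s)
  rows <- lapply(seq_len(nrow(motifs)), function(i) {
    m <- motifs[i, ]
    w <- nchar(m$seq)
    starts <- max(1L, m$start - window):min(L - w + 1L, m$start + window)
    row <- data.frame(name = m$name, canonical_seq = m$seq,
                      canonical_start = m$start, found_start = NA_integer_,
                      found_seq = NA_character_, mismatches = NA_integer_,
                      status = "missing", stringsAsFactors = FALSE)
    if (!length(starts) || starts[1] > L - w + 1L) return(row)
    subs <- substring(s, starts, starts + w - 1L)
    mm <- vapply(subs, function(x)
      sum(strsplit(x, "")[[1]] != strsplit(m$seq, "")[[1]]), integer(1),
      USE.NAMES = FALSE)
    o <- order(mm, abs(starts - m$start))
    best <- o[1]
    if (mm[best] <= max_mm) {
      row$found_start <- starts[best]
      row$found_seq <- subs[best]
      row$mismatches <- mm[best]
      row$status <- if (mm[best] == 0) "canonical" else "mutated"
    }
    row
  })
  hits <- do.call(rbind, rows)
  summary <- c(n_canonical = sum(hits$status == "canonical"),
               n_mutated = sum(hits$status == "mutated"),
               n_missing = sum(hits$status == "missing"))
  list(hits = hits, summary = summary)
}
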