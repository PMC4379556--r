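#' Build a seeded alignment index
#'
#' Exact-seed lookup over the forward strand of every reference record;
#' queries are searched in both orientations. With per-mate mismatch budget
#' m, a query of length L is probed with m+1 disjoint seeds, so by the
#' pigeonhole principle every location within the budget is guaranteed to be
#' found (completeness). Seeds are 2-bit packed, so \code{seed_len} is
#' capped at 31.
#'
#' @param reference a [Catalogue-class], a \code{referenceSet()} list, or a
#'   named DNAStringSet/character vector.
#' @param seed_len seed length (12-31; default 25). Queries shorter than
#'   \code{seed_len * (max_mm + 1)} raise an error at query time.
#' @return an object of class \code{"hervIndex"}.
#' @export
buildIndex <- function(reference, seed_len = 25L) {
  if (is(reference, "Catalogue")) reference <- referenceSet(reference)
  if (is.list(reference) && !is.null(reference$seqs)) {
    seqs <- as.character(reference$seqs)
    offset <- reference$offset
    core_len <- reference$core_len
  } else {
    nm <- names(reference)
    seqs <- setNames(as.character(reference), nm)
    offset <- setNames(integer(length(seqs)), nm)
    core_len <- setNames(nchar(seqs), nm)
  }
  if (is.null(names(seqs))) stop("reference records must be named")
  structure(list(ptr = cpp_index_build(unname(seqs), as.integer(seed_len)),
                 ids = names(seqs), lens = unname(nchar(seqs)),
                 offset = offset, core_len = core_len,
                 seed_len = as.integer(seed_len)),
            class = "hervIndex")
}

#' @export
print.hervIndex <- function(x, ...) {
  cat("hervIndex over", length(x$ids), "record(s),",
      sum(x$lens), "bp, seed length", x$seed_len, "\n")
  invisible(x)
}

#' Paired-end alignments
#'
#' All concordant locations for each pair. A pair is \emph{unique} iff
#' exactly one concordant location exists within the mismatch budget (not
#' merely one best location), mirroring the MAPQ-50 convention for uniquely
#' aligned reads: unique pairs get MAPQ 50, multi-mapped pairs MAPQ 1.
#' The inferred transcript strand of a location follows the fr-firststrand
#' convention (mate 2 carries transcript sense), i.e. it is the alignment
#' strand of mate 2.
#'
#' @slot hits \code{DataFrame}: \code{read} (pair index), \code{element},
#'   \code{pos1}, \code{strand1} (mate 1), \code{pos2}, \code{mm1},
#'   \code{mm2}, \code{ts} (inferred transcript strand).
#' @slot nPairs number of input pairs.
#' @slot readIds input pair ids.
#' @slot len1,len2 mate lengths per pair.
#' @export
setClass("PairAlignments",
  representation(hits = "DataFrame", nPairs = "integer",
                 readIds = "character", len1 = "integer", len2 = "integer"))

setMethod("show", "PairAlignments", function(object) {
  k <- tabulate(object@hits$read, object@nPairs)
  cat(sprintf(
    "PairAlignments: %d pair(s); %d aligned (%d unique, %d multi-mapped)\n",
    object@nPairs, sum(k > 0), sum(k == 1), sum(k > 1)))
})

#' @describeIn PairAlignments number of input pairs
#' @param x a PairAlignments
#' @export
setMethod("length", "PairAlignments", function(x) x@nPairs)

#' Locations per pair
#' @param aln a [PairAlignments-class]
#' @return integer vector: number of concordant locations per input pair.
#' @export
locationCounts <- function(aln) tabulate(aln@hits$read, aln@nPairs)

#' Align read pairs against an index
#'
#' Enumerates every per-mate hit within the per-mate mismatch budget
#' (ungapped, full length, N never matches), then keeps concordant
#' combinations: same record, opposite strands, FR orientation, implied
#' insert within bounds. All locations are reported; ties are never broken
#' here — allocation is the quantifier's job. Discordant-only pairs are
#' unaligned.
#'
#' @param lib a [ReadLibrary-class] (paired).
#' @param index a \code{buildIndex()} result.
#' @param max_mm per-mate mismatch budget (default 2).
#' @param insert_bounds numeric length-2: allowed implied insert range.
#' @return a [PairAlignments-class].
#' @export
alignPairs <- function(lib, index, max_mm = 2L, insert_bounds = c(90L, 600L)) {
  stopifnot(is(lib, "ReadLibrary"), inherits(index, "hervIndex"))
  r1 <- as.character(lib@mate1); r2 <- as.character(lib@mate2)
  if (length(r1) == 0) {
    hits <- DataFrame(read = integer(0), element = character(0),
                      pos1 = integer(0), strand1 = character(0),
                      pos2 = integer(0), mm1 = integer(0), mm2 = integer(0),
                      ts = character(0))
    return(new("PairAlignments", hits = hits, nPairs = 0L,
               readIds = character(0), len1 = integer(0), len2 = integer(0)))
  }
  df <- cpp_align_pairs(index$ptr, unname(r1), unname(r2), as.integer(max_mm),
                        as.integer(insert_bounds[1]),
                        as.integer(insert_bounds[2]))
  strand1 <- ifelse(df$strand1 > 0, "+", "-")
  hits <- DataFrame(read = df$read, element = index$ids[df$elem],
                    pos1 = df$pos1, strand1 = strand1, pos2 = df$pos2,
                    mm1 = df$mm1, mm2 = df$mm2,
                    ts = ifelse(strand1 == "+", "-", "+"))
  new("PairAlignments", hits = hits, nPairs = length(r1),
      readIds = names(lib@mate1), len1 = width(lib@mate1),
      len2 = width(lib@mate2))
}

#' Align single-end reads against an index
#'
#' @param reads DNAStringSet or character vector.
#' @param index a \code{buildIndex()} result.
#' @param max_mm mismatch budget.
#' @return DataFrame: \code{read}, \code{element}, \code{pos},
#'   \code{strand}, \code{mm}; attribute \code{nReads}.
#' @export
alignReads <- function(reads, index, max_mm = 2L) {
  r <- as.character(reads)
  df <- cpp_align_single(index$ptr, unname(r), as.integer(max_mm))
  out <- DataFrame(read = df$read, element = index$ids[df$elem],
                   pos = df$pos, strand = ifelse(df$strand > 0, "+", "-"),
                   mm = df$mm)
  metadata(out)$nReads <- length(r)
  out
}

#' Spliced (single-split) alignment of unaligned mates
#'
#' For mates that failed full-length alignment, attempts one split into two
#' same-orientation segments (each at least \code{min_segment} bases, each
#' within \code{segment_mm} mismatches) on one reference record, anchoring
#' the read's first and last \code{min_segment} bases and choosing the split
#' point that minimises total mismatches, preferring GT..AG intron
#' dinucleotides on ties. Records the junction (donor = last exon-1 base,
#' acceptor = first exon-2 base) and its GT-AG status.
#'
#' @param lib a [ReadLibrary-class].
#' @param reference a \code{referenceSet()} list (or Catalogue).
#' @param which_pairs integer indices of pairs to attempt (default: all).
#' @param min_segment minimum segment length.
#' @param segment_mm per-segment mismatch budget.
#' @param min_intron minimum intron length.
#' @return DataFrame of junction evidence: \code{read}, \code{mate},
#'   \code{element}, \code{strand}, \code{split_at} (read coordinate of the
#'   last exon-1 base), \code{donor}, \code{acceptor} (reference
#'   coordinates), \code{mm}, \code{gt_ag}.
#' @export
alignSpliced <- function(lib, reference, which_pairs = NULL,
                         min_segment = 20L, segment_mm = 1L,
                         min_intron = 20L, max_intron = 20000L,
                         filter_len = 30L) {
  if (is(reference, "Catalogue")) reference <- referenceSet(reference)
  refs <- as.character(reference$seqs)
  if (is.null(which_pairs)) which_pairs <- seq_len(length(lib))
  # fast prefilter: a splittable mate has its first and last filter_len
  # bases on the same record/orientation but on split diagonals
  sidx <- buildIndex(reference, seed_len = min(15L, filter_len %/%
                                                 (segment_mm + 1L)))
  out <- list()
  for (mate in 1:2) {
    seqs <- if (mate == 1) lib@mate1 else lib@mate2
    if (!length(seqs)) next
    idx_ok <- which_pairs[which_pairs <= length(seqs)]
    qs <- as.character(seqs[idx_ok])
    lens <- nchar(qs)
    use <- lens >= 2L * min_segment
    idx_ok <- idx_ok[use]; qs <- qs[use]; lens <- lens[use]
    if (!length(qs)) next
    for (orient in c("+", "-")) {
      qq <- if (orient == "+") qs else
        as.character(reverseComplement(DNAStringSet(qs)))
      pre <- substr(qq, 1L, filter_len)
      suf <- substr(qq, lens - filter_len + 1L, lens)
      h1 <- as.data.frame(alignReads(pre, sidx, max_mm = segment_mm))
      h2 <- as.data.frame(alignReads(suf, sidx, max_mm = segment_mm))
      h1 <- h1[h1$strand == "+", , drop = FALSE]
      h2 <- h2[h2$strand == "+", , drop = FALSE]
      if (!nrow(h1) || !nrow(h2)) next
      cand <- merge(h1[, c("read", "element", "pos")],
                    h2[, c("read", "element", "pos")],
                    by = c("read", "element"), suffixes = c("1", "2"))
      intron <- cand$pos2 - (cand$pos1 + lens[cand$read] - filter_len)
      cand <- cand[intron >= min_intron & intron <= max_intron, ,
                   drop = FALSE]
      if (!nrow(cand)) next
      for (r in unique(cand$read)) {
        best <- NULL
        for (rid in unique(cand$element[cand$read == r])) {
          cc <- .spliceScan(qq[r], refs[[rid]], min_segment, segment_mm,
                            min_intron)
          if (!is.null(cc)) {
            cc$element <- rid; cc$strand <- orient
            if (is.null(best) || cc$mm < best$mm ||
                (cc$mm == best$mm && cc$gt_ag && !best$gt_ag))
              best <- cc
          }
        }
        if (!is.null(best))
          out[[length(out) + 1L]] <- data.frame(
            read = idx_ok[r], mate = mate, element = best$element,
            strand = best$strand, split_at = best$split_at,
            donor = best$donor, acceptor = best$acceptor, mm = best$mm,
            gt_ag = best$gt_ag)
      }
    }
  }
  if (!length(out))
    return(DataFrame(read = integer(0), mate = integer(0),
                     element = character(0), strand = character(0),
                     split_at = integer(0), donor = integer(0),
                     acceptor = integer(0), mm = integer(0),
                     gt_ag = logical(0)))
  DataFrame(do.call(rbind, out))
}

## split-alignment search for one read orientation on one reference record
.spliceScan <- function(q, ref, min_segment, segment_mm, min_intron) {
  L <- nchar(q)
  if (L < 2L * min_segment) return(NULL)
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  rlen <- nchar(ref)
  refobj <- DNAString(ref)
  a_hits <- start(matchPattern(DNAString(substr(q, 1L, min_segment)), refobj,
                               max.mismatch = segment_mm))
  if (!length(a_hits)) return(NULL)
  e_hits <- start(matchPattern(DNAString(substr(q, L - min_segment + 1L, L)),
                               refobj, max.mismatch = segment_mm))
  if (!length(e_hits)) return(NULL)
  best <- NULL
  for (a in a_hits) {
    span <- min(L, rlen - a + 1L)
    rc1 <- strsplit(substr(ref, a, a + span - 1L), "", fixed = TRUE)[[1]]
    mmA <- cumsum(qc[seq_len(span)] != rc1)          # prefix mismatches
    for (eh in e_hits) {
      e_end <- eh + min_segment - 1L
      span2 <- min(L, e_end)
      rc2 <- strsplit(substr(ref, e_end - span2 + 1L, e_end), "",
                      fixed = TRUE)[[1]]
      mm_rev <- rev(cumsum(rev(qc[(L - span2 + 1L):L] != rc2)))
      # mmB[t] = mismatches of suffix starting at read position t
      mmB <- rep(Inf, L + 1L)
      mmB[L + 1L] <- 0
      mmB[(L - span2 + 1L):L] <- mm_rev
      pl <- seq(min_segment, L - min_segment)     # candidate split points
      pl <- pl[pl <= length(mmA)]
      ex2_start <- e_end - (L - pl) + 1L          # exon-2 reference start
      ok <- mmA[pl] <= segment_mm & mmB[pl + 1L] <= segment_mm &
        ex2_start > (a + pl - 1L) + min_intron & ex2_start >= 1L
      if (!any(ok)) next
      pl <- pl[ok]; ex2 <- ex2_start[ok]
      mmtot <- mmA[pl] + mmB[pl + 1L]
      donor <- a + pl - 1L
      gt <- substring(ref, donor + 1L, donor + 2L) == "GT" &
        substring(ref, ex2 - 2L, ex2 - 1L) == "AG"
      o <- order(mmtot, !gt)
      j <- o[1]
      cand <- list(split_at = pl[j], donor = donor[j], acceptor = ex2[j],
                   mm = mmtot[j], gt_ag = gt[j])
      if (is.null(best) || cand$mm < best$mm ||
          (cand$mm == best$mm && cand$gt_ag && !best$gt_ag))
        best <- cand
    }
  }
  best
}

#' Write alignments as SAM
#'
#' Emits one record per mate per location: the first location of a pair is
#' primary, the rest secondary (flag 0x100). MAPQ is 50 for unique pairs and
#' 1 for multi-mapped pairs, so downstream unique-only filtering is exactly
#' a MAPQ >= 50 filter; NH carries the location count and NM the per-mate
#' mismatch count.
#'
#' @param aln a [PairAlignments-class].
#' @param lib the [ReadLibrary-class] that was aligned (for sequences).
#' @param index the index used (for reference names and lengths).
#' @param path output SAM path.
#' @return invisibly, \code{path}.
#' @export
writeSam <- function(aln, lib, index, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", index$ids, index$lens),
               sprintf("@PG\tID:hervloci\tPN:hervloci\tVN:%s",
                       as.character(utils::packageVersion("hervloci")))),
             con)
  h <- aln@hits
  if (!nrow(h)) return(invisible(path))
  k <- tabulate(h$read, aln@nPairs)
  ord <- order(h$read)
  h <- h[ord, , drop = FALSE]
  first <- !duplicated(h$read)
  rc <- function(s) as.character(reverseComplement(DNAStringSet(s)))
  m1 <- as.character(lib@mate1)[h$read]
  m2 <- as.character(lib@mate2)[h$read]
  q1 <- lib@qual1[h$read]; q2 <- lib@qual2[h$read]
  rev1 <- h$strand1 == "-"
  m1[rev1] <- rc(m1[rev1]); q1[rev1] <- .revStr(q1[rev1])
  m2[!rev1] <- rc(m2[!rev1]); q2[!rev1] <- .revStr(q2[!rev1])
  ids <- aln@readIds[h$read]
  L1 <- aln@len1[h$read]; L2 <- aln@len2[h$read]
  mapq <- ifelse(k[h$read] == 1L, 50L, 1L)
  sec <- ifelse(first, 0L, 256L)
  nh <- k[h$read]
  plus_start <- ifelse(rev1, h$pos2, h$pos1)
  minus_end <- ifelse(rev1, h$pos1 + L1 - 1L, h$pos2 + L2 - 1L)
  tlen <- minus_end - plus_start + 1L
  flag1 <- 1L + 2L + ifelse(rev1, 16L, 0L) + ifelse(rev1, 0L, 32L) + 64L + sec
  flag2 <- 1L + 2L + ifelse(rev1, 0L, 16L) + ifelse(rev1, 32L, 0L) + 128L + sec
  rec <- function(flag, pos, mpos, seq, qual, L, mm, sign) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t%s\tNH:i:%d\tNM:i:%d",
            ids, flag, h$element, pos, mapq, L, mpos, sign * tlen, seq, qual,
            nh, mm)
  }
  lines1 <- rec(flag1, h$pos1, h$pos2, m1, q1, L1, h$mm1,
                ifelse(rev1, -1L, 1L))
  lines2 <- rec(flag2, h$pos2, h$pos1, m2, q2, L2, h$mm2,
                ifelse(rev1, 1L, -1L))
  writeLines(as.vector(rbind(lines1, lines2)), con)
  invisible(path)
}

.revStr <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                              collapse = ""), character(1), USE.NAMES = FALSE)
}
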