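#' Strand-aware coverage profiles over elements and their flanks
#'
#' Projects fragment spans (mate-1 start to mate-2 end) onto each reference
#' record and accumulates per-base depth separately for the two inferred
#' transcript strands; multi-mapped pairs contribute 1/k per location.
#' For unstranded libraries the strand split is meaningless and all depth is
#' recorded as plus; the resulting profiles carry
#' \code{strand_mode = "unstranded"} so the classifier knows antisense calls
#' are unavailable.
#'
#' @param aln a [PairAlignments-class].
#' @param index the \code{buildIndex()} used (supplies offsets/core
#'   lengths).
#' @param strand_mode \code{"plus_stranded"} (stranded library) or
#'   \code{"unstranded"}.
#' @param junctions optional [alignSpliced()] DataFrame of junction
#'   evidence.
#' @param unique_only use only uniquely aligned pairs (recommended for TSS
#'   estimation: multi-mapped reads from a young element's two near-identical
#'   LTRs otherwise smear coverage across both LTR copies).
#' @return named list of coverage profiles, one per reference record:
#'   each a list with \code{element_id}, \code{offset}, \code{core_len},
#'   \code{ref_len}, \code{plus}, \code{minus} (numeric depth vectors over
#'   the full record), \code{strand_mode}, \code{junctions}.
#' @export
buildCoverage <- function(aln, index,
                          strand_mode = c("plus_stranded", "unstranded"),
                          junctions = NULL, unique_only = FALSE) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(is(aln, "PairAlignments"))
  h <- aln@hits
  k <- tabulate(h$read, aln@nPairs)
  if (unique_only) h <- h[k[h$read] == 1L, , drop = FALSE]
  profiles <- list()
  for (i in seq_along(index$ids)) {
    id <- index$ids[i]
    reflen <- index$lens[i]
    sel <- h$element == id
    plus <- numeric(reflen); minus <- numeric(reflen)
    if (any(sel)) {
      hh <- h[sel, , drop = FALSE]
      L1 <- aln@len1[hh$read]; L2 <- aln@len2[hh$read]
      fs <- pmax(1L, pmin(hh$pos1, hh$pos2))
      fe <- pmin(reflen, pmax(hh$pos1 + L1 - 1L, hh$pos2 + L2 - 1L))
      w <- 1 / k[hh$read]
      ts <- if (strand_mode == "plus_stranded") hh$ts else
        rep("+", nrow(hh))
      for (s in c("+", "-")) {
        ssel <- ts == s
        if (!any(ssel)) next
        cov <- coverage(IRanges(fs[ssel], fe[ssel]), weight = w[ssel],
                        width = reflen)
        if (s == "+") plus <- as.numeric(cov) else minus <- as.numeric(cov)
      }
    }
    jx <- if (!is.null(junctions) && nrow(junctions))
      junctions[junctions$element == id, , drop = FALSE] else NULL
    profiles[[id]] <- list(element_id = id,
                           offset = unname(index$offset[id]),
                           core_len = unname(index$core_len[id]),
                           ref_len = reflen, plus = plus, minus = minus,
                           strand_mode = strand_mode, junctions = jx)
  }
  profiles
}

#' Default mechanism-classification thresholds
#'
#' All ratios except the silent floor, so classification is invariant to
#' global depth scaling. The values are package decisions (the original
#' analysis classified by visual inspection of coverage): mean element depth
#' below \code{silent_floor} is silent; a minus-strand depth fraction above
#' \code{antisense_fraction} is antisense (stranded data only); at least
#' \code{junction_min} spliced reads linking an upstream element into the
#' leader is chimeric; flank-to-element mean-depth ratios of
#' \code{flank_ratio} mark read-through (upstream only) or an intronic
#' passenger (both flanks, even pre-mRNA coverage); otherwise the element is
#' LTR-driven and the TSS is the first position whose depth exceeds
#' \code{tss_fraction} of the plateau (90th percentile of element depth).
#' @return named list of thresholds.
#' @export
mechanismThresholds <- function() {
  list(silent_floor = 0.1, antisense_fraction = 0.8, flank_ratio = 0.5,
       junction_min = 2L, tss_fraction = 0.1, leader_end = 1200L)
}

#' Classify the transcription mechanism of an element
#'
#' Decision sequence on a coverage profile: silent; antisense;
#' upstream-LTR chimeric (junction evidence into the leader); intronic
#' passenger (both flanks covered like the element — checked before
#' read-through, whose upstream-only condition it contains); read-through
#' (upstream flank covered); else LTR-driven, with the transcription start
#' site estimated as the first position where cumulative 5' depth exceeds
#' 10\% of the coverage plateau (expected at the U3-R border, position 793
#' of the canonical LTR).
#'
#' @param profile one element's profile from [buildCoverage()].
#' @param thresholds see [mechanismThresholds()].
#' @return list: \code{element_id}, \code{label}, \code{tss} (element
#'   coordinate, LTR-driven only), \code{metrics} (named numerics),
#'   \code{strand_mode}.
#' @export
classifyMechanism <- function(profile, thresholds = mechanismThresholds()) {
  th <- thresholds
  off <- profile$offset
  core <- profile$core_len
  idx <- (off + 1L):(off + core)
  p <- profile$plus[idx]; m <- profile$minus[idx]
  tot <- p + m
  mean_elem <- mean(tot)
  metrics <- c(mean_element_depth = mean_elem)
  res <- function(label, tss = NA_integer_)
    list(element_id = profile$element_id, label = label, tss = tss,
         metrics = metrics, strand_mode = profile$strand_mode)
  if (mean_elem < th$silent_floor) return(res("silent"))
  minus_frac <- if (sum(tot) > 0) sum(m) / sum(tot) else 0
  metrics["minus_fraction"] <- minus_frac
  stranded <- profile$strand_mode == "plus_stranded"
  if (stranded && minus_frac > th$antisense_fraction) return(res("antisense"))
  # dominant element strand drives the flank comparison
  s <- if (stranded && minus_frac > 0.5) "minus" else "plus"
  dep <- profile[[s]]
  elem_mean <- mean(dep[idx])
  up_mean <- if (off > 0) mean(dep[seq_len(off)]) else 0
  ndown <- profile$ref_len - off - core
  down_mean <- if (ndown > 0) mean(dep[(off + core + 1L):profile$ref_len]) else 0
  metrics["upstream_ratio"] <- if (elem_mean > 0) up_mean / elem_mean else 0
  metrics["downstream_ratio"] <- if (elem_mean > 0) down_mean / elem_mean else 0
  jx <- profile$junctions
  n_jx <- 0L
  if (!is.null(jx) && nrow(jx)) {
    into_leader <- jx$donor <= off &
      jx$acceptor > off & jx$acceptor <= off + th$leader_end
    n_jx <- sum(into_leader)
  }
  metrics["junction_reads"] <- n_jx
  if (n_jx >= th$junction_min) return(res("upstream_ltr_chimeric"))
  if (off > 0 && ndown > 0 &&
      up_mean >= th$flank_ratio * elem_mean &&
      down_mean >= th$flank_ratio * elem_mean)
    return(res("intronic_passenger"))
  if (off > 0 && up_mean >= th$flank_ratio * elem_mean)
    return(res("read_through"))
  plateau <- quantile(dep[idx], 0.9, names = FALSE)
  tss <- which(cumsum(dep[idx]) >= th$tss_fraction * plateau)[1]
  res("ltr_driven", tss = as.integer(tss))
}

#' Classify every profiled element
#'
#' @param profiles list from [buildCoverage()].
#' @param thresholds see [mechanismThresholds()].
#' @param elements optional ids to restrict to.
#' @return data.frame: \code{element_id}, \code{label}, \code{tss},
#'   \code{mean_depth}, \code{minus_fraction}, \code{upstream_ratio},
#'   \code{downstream_ratio}, \code{junction_reads}, \code{strand_mode}.
#' @export
classifyMechanisms <- function(profiles, thresholds = mechanismThresholds(),
                               elements = NULL) {
  if (!is.null(elements)) profiles <- profiles[elements]
  rows <- lapply(profiles, function(pr) {
    r <- classifyMechanism(pr, thresholds)
    g <- function(nm) if (nm %in% names(r$metrics)) r$metrics[[nm]] else NA_real_
    data.frame(element_id = r$element_id, label = r$label, tss = r$tss,
               mean_depth = g("mean_element_depth"),
               minus_fraction = g("minus_fraction"),
               upstream_ratio = g("upstream_ratio"),
               downstream_ratio = g("downstream_ratio"),
               junction_reads = g("junction_reads"),
               strand_mode = r$strand_mode, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write coverage profiles as BedGraph
#'
#' One track line per strand per element, on element+flank coordinates.
#' @param profiles list from [buildCoverage()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeBedGraph <- function(profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (pr in profiles) {
    for (s in c("plus", "minus")) {
      dep <- pr[[s]]
      if (all(dep == 0)) next
      r <- rle(dep)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      sel <- r$values != 0
      writeLines(sprintf("track type=bedGraph name=\"%s_%s\"",
                         pr$element_id, s), con)
      # BED half-open, 0-based; coordinates relative to record start
      writeLines(sprintf("%s\t%d\t%d\t%g", pr$element_id,
                         starts[sel] - 1L, ends[sel], r$values[sel]), con)
    }
  }
  invisible(path)
}
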