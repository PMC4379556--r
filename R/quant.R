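#' Count fragments per element
#'
#' Converts concordant pair locations into per-element fragment mass under
#' one of three modes:
#' \describe{
#'   \item{unfiltered_uniform}{each pair contributes 1/k to each of its k
#'     locations (a pair mapping to five locations gives each 20\% of a
#'     fragment).}
#'   \item{unique_only}{pairs with more than one location are discarded —
#'     the MAPQ-50 filter.}
#'   \item{em_rescue}{multi-read correction: starting from the uniform
#'     allocation, multi-mapped pairs are iteratively reallocated across
#'     their locations proportionally to current per-base abundance
#'     \eqn{c_i/L_i}, until the largest relative change drops below
#'     \code{tol} or \code{max_iter} iterations.}
#' }
#' With \code{strand_mode = "plus_stranded"} a location counts only when the
#' inferred transcript strand equals the element's sense strand. Locations
#' whose fragment does not overlap the element core (flank-only hits in
#' context-extended records) never contribute element mass. The FPKM
#' denominator \code{N} is the total number of concordantly aligned pairs in
#' the run and is identical across modes.
#'
#' Mass bookkeeping is done over location equivalence classes (pairs sharing
#' the same multiset of elements), which keeps the conservation identity
#' \eqn{\sum_i c_i =} counted pairs exact to floating-point rounding of a few
#' hundred terms.
#'
#' @param aln a [PairAlignments-class].
#' @param index the \code{buildIndex()} used for alignment (supplies record
#'   offsets/core lengths).
#' @param mode counting mode (see above).
#' @param strand_mode \code{"unstranded"} or \code{"plus_stranded"}.
#' @param tol,max_iter EM convergence controls.
#' @return a [CountTable-class].
#' @export
countFragments <- function(aln, index,
                           mode = c("unfiltered_uniform", "unique_only",
                                    "em_rescue"),
                           strand_mode = c("unstranded", "plus_stranded"),
                           tol = 1e-6, max_iter = 200L) {
  mode <- match.arg(mode)
  strand_mode <- match.arg(strand_mode)
  stopifnot(is(aln, "PairAlignments"))
  ids <- index$ids
  h <- aln@hits
  bad <- setdiff(unique(h$element), ids)
  if (length(bad))
    stop("alignment references unknown element(s): ",
         paste(bad, collapse = ", "))
  counts <- setNames(numeric(length(ids)), ids)
  n_mapped <- length(unique(h$read))
  if (!nrow(h)) {
    return(new("CountTable", counts = counts, mode = mode,
               strandMode = strand_mode, nMapped = 0, nCounted = 0))
  }
  # fragment span in record coordinates, for core-overlap filtering
  L1 <- aln@len1[h$read]; L2 <- aln@len2[h$read]
  fs <- pmin(h$pos1, h$pos2)
  fe <- pmax(h$pos1 + L1 - 1L, h$pos2 + L2 - 1L)
  off <- index$offset[h$element]
  core <- index$core_len[h$element]
  keep <- fe >= off + 1L & fs <= off + core
  if (strand_mode == "plus_stranded") keep <- keep & h$ts == "+"
  h <- h[keep, , drop = FALSE]
  if (!nrow(h)) {
    return(new("CountTable", counts = counts, mode = mode,
               strandMode = strand_mode, nMapped = n_mapped, nCounted = 0))
  }
  # per (read, element) location multiplicity, then per-read class key
  ei <- match(h$element, ids)
  pe <- paste(h$read, ei)
  first <- !duplicated(pe)
  readv <- h$read[first]
  elemv <- ei[first]
  multv <- as.integer(table(pe)[pe[first]])
  ord <- order(readv, elemv)
  readv <- readv[ord]; elemv <- elemv[ord]; multv <- multv[ord]
  grp <- split(seq_along(readv), readv)
  key <- vapply(grp, function(ii)
    paste(elemv[ii], multv[ii], sep = ":", collapse = ";"), character(1))
  n_counted <- length(grp)
  ec <- table(key)
  ec_keys <- names(ec)
  ec_n <- as.numeric(ec)
  ec_parts <- strsplit(ec_keys, ";", fixed = TRUE)
  ec_elem <- lapply(ec_parts, function(p)
    as.integer(vapply(strsplit(p, ":", fixed = TRUE), `[`, character(1), 1)))
  ec_mult <- lapply(ec_parts, function(p)
    as.numeric(vapply(strsplit(p, ":", fixed = TRUE), `[`, character(1), 2)))
  ec_k <- vapply(ec_mult, sum, numeric(1))   # total locations in class

  lens <- as.numeric(index$core_len[ids])
  accumulate <- function(weights_fun) {
    cc <- numeric(length(ids))
    for (j in seq_along(ec_keys)) {
      w <- weights_fun(j)
      cc[ec_elem[[j]]] <- cc[ec_elem[[j]]] + ec_n[j] * w
    }
    cc
  }
  if (mode == "unique_only") {
    sel <- ec_k == 1
    cc <- numeric(length(ids))
    for (j in which(sel)) cc[ec_elem[[j]]] <- cc[ec_elem[[j]]] + ec_n[j]
    n_counted <- sum(ec_n[sel])
  } else {
    cc <- accumulate(function(j) {
      w <- ec_mult[[j]] / ec_k[j]
      w[length(w)] <- 1 - sum(w[-length(w)])  # exact row sum
      w
    })
    if (mode == "em_rescue") {
      for (it in seq_len(max_iter)) {
        dens <- cc / lens[seq_along(cc)]
        cc_new <- accumulate(function(j) {
          d <- ec_mult[[j]] * dens[ec_elem[[j]]]
          s <- sum(d)
          if (s <= 0) d <- ec_mult[[j]] / ec_k[j] else d <- d / s
          d[length(d)] <- 1 - sum(d[-length(d)])
          d
        })
        rel <- max(abs(cc_new - cc) / pmax(cc, 1e-12))
        cc <- cc_new
        if (rel < tol) break
      }
    }
  }
  counts[] <- cc
  new("CountTable", counts = counts, mode = mode, strandMode = strand_mode,
      nMapped = n_mapped, nCounted = as.numeric(n_counted))
}

#' Multinomial log-likelihood of a count allocation
#'
#' The location-multinomial log-likelihood of the data underlying a
#' CountTable at abundance \code{counts} (used to verify that EM iterations
#' are monotone). Exposed for diagnostics and tests.
#'
#' @param aln,index,strand_mode as in [countFragments()].
#' @param counts named per-element mass vector.
#' @return log-likelihood (up to an additive constant).
#' @export
countLogLik <- function(aln, index, counts,
                        strand_mode = c("unstranded", "plus_stranded")) {
  strand_mode <- match.arg(strand_mode)
  h <- aln@hits
  L1 <- aln@len1[h$read]; L2 <- aln@len2[h$read]
  fs <- pmin(h$pos1, h$pos2)
  fe <- pmax(h$pos1 + L1 - 1L, h$pos2 + L2 - 1L)
  off <- index$offset[h$element]
  core <- index$core_len[h$element]
  keep <- fe >= off + 1L & fs <= off + core
  if (strand_mode == "plus_stranded") keep <- keep & h$ts == "+"
  h <- h[keep, , drop = FALSE]
  dens <- counts / as.numeric(index$core_len[names(counts)])
  theta <- dens / sum(dens)
  pr <- theta[h$element]
  by_read <- rowsum(as.numeric(pr), h$read)
  sum(log(by_read[by_read > 0]))
}

#' Compute FPKM and relative abundance
#'
#' FPKM for element i is \eqn{c_i \times 10^9 / (L_i N)} with \eqn{L_i} the
#' full element length and N the run's total mapped pair count. Relative
#' abundance is \eqn{100 \times F_i / \sum_{family} F_j} over family
#' (provirus) elements only; solo LTRs and host records receive FPKM but no
#' family abundance.
#'
#' @param ct a [CountTable-class].
#' @param cat the [Catalogue-class] quantified against.
#' @return data.frame: \code{element_id}, \code{class}, \code{mode},
#'   \code{strand_mode}, \code{fragments}, \code{length}, \code{fpkm},
#'   \code{abundance} (percent; NA off-family).
#' @export
computeExpression <- function(ct, cat) {
  stopifnot(is(ct, "CountTable"), is(cat, "Catalogue"))
  N <- ct@nMapped
  if (N <= 0) stop("no mapped fragments (N = 0)")
  ids <- intersect(names(ct@counts), names(cat))
  info <- cat@elementInfo
  lens <- setNames(width(cat@elements), names(cat))[ids]
  cnt <- ct@counts[ids]
  fpkm <- cnt * 1e9 / (as.numeric(lens) * N)
  cls <- info$class[match(ids, info$id)]
  fam <- cls == "provirus"
  tot <- sum(fpkm[fam])
  ab <- rep(NA_real_, length(ids))
  if (tot > 0) {
    ab[fam] <- 100 * fpkm[fam] / tot
  } else {
    warning("all family FPKM are zero; abundance undefined")
  }
  data.frame(element_id = ids, class = cls, mode = ct@mode,
             strand_mode = ct@strandMode, fragments = unname(cnt),
             length = unname(lens), fpkm = unname(fpkm),
             abundance = unname(ab), stringsAsFactors = FALSE)
}

#' Compare expression across counting modes
#'
#' Per element, FPKM under each supplied mode, the unique/unfiltered FPKM
#' ratio, and a "likely misassigned" flag for loci whose apparent expression
#' evaporates under unique-only filtering (unfiltered abundance at least
#' \code{flag_unfiltered} percent but unique-only abundance at most
#' \code{flag_unique} percent) — the signature of reads misaligned to a
#' closely related location.
#'
#' @param records named list of [computeExpression()] data.frames; names are
#'   modes and must include \code{unfiltered_uniform} and \code{unique_only}.
#' @param flag_unfiltered,flag_unique flag thresholds (percent abundance).
#' @return data.frame with per-mode fpkm/abundance columns, \code{ratio}
#'   and \code{flagged}.
#' @export
compareModes <- function(records, flag_unfiltered = 0.5, flag_unique = 0.1) {
  stopifnot(length(records) >= 2,
            all(c("unfiltered_uniform", "unique_only") %in% names(records)))
  base <- records[[1]][, c("element_id", "class")]
  out <- base
  for (m in names(records)) {
    r <- records[[m]]
    i <- match(base$element_id, r$element_id)
    out[[paste0("fpkm_", m)]] <- r$fpkm[i]
    out[[paste0("abundance_", m)]] <- r$abundance[i]
  }
  unf <- out$fpkm_unfiltered_uniform
  out$ratio <- ifelse(unf > 0, out$fpkm_unique_only / unf, NA_real_)
  out$flagged <- !is.na(out$abundance_unfiltered_uniform) &
    !is.na(out$abundance_unique_only) &
    out$abundance_unfiltered_uniform >= flag_unfiltered &
    out$abundance_unique_only <= flag_unique
  out
}
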