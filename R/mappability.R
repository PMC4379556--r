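#' Assess per-element mappability under unique-only filtering
#'
#' The in-silico simulation: every family element is sequenced uniformly to
#' the same depth (error-free 250-base paired reads by default), the pooled
#' reads are aligned back to the family reference, and expression is
#' quantified both unfiltered and unique-only. Because all elements are
#' equally represented, the mean unfiltered FPKM serves as the comparator:
#' underrepresentation is \eqn{u = 1 - F_{unq} / \bar F}, and elements with
#' \eqn{u >} \code{threshold} (default 0.15, i.e. affected by more than
#' 15\%) are flagged. A per-element variant
#' \eqn{u' = 1 - F_{unq}/F_{unf,i}} is emitted alongside for diagnostics,
#' since the global-mean comparator can over- or undershoot per-element loss
#' when lengths differ.
#'
#' @param cat a [Catalogue-class]; family (provirus) members are simulated.
#' @param depth fold-coverage per element.
#' @param read_len read length; elements shorter than this are excluded with
#'   a warning.
#' @param paired paired-end fragments (insert = 2 x read length) when TRUE;
#'   single-end placements when FALSE.
#' @param error_rate per-base substitution error rate (default 0:
#'   mappability is isolated from sequencing error).
#' @param seed integer seed.
#' @param threshold flag threshold on u.
#' @param max_mm per-mate mismatch budget for alignment.
#' @param seed_len index seed length.
#' @return data.frame sorted by decreasing u: \code{element_id},
#'   \code{f_unfiltered}, \code{f_unique}, \code{u}, \code{u_per_element},
#'   \code{flagged}.
#' @export
assessMappability <- function(cat, depth = 20, read_len = 250L,
                              paired = TRUE, error_rate = 0, seed = 1L,
                              threshold = 0.15, max_mm = 2L, seed_len = 25L) {
  stopifnot(is(cat, "Catalogue"))
  fam <- familyIds(cat)
  lens <- setNames(width(cat@elements), names(cat))[fam]
  short <- fam[lens < read_len]
  if (length(short)) {
    warning("element(s) shorter than read length excluded: ",
            paste(short, collapse = ", "))
    fam <- setdiff(fam, short)
  }
  if (!length(fam)) stop("no family element is long enough to simulate")
  sub <- Catalogue(cat@elements[fam],
                   elementInfo = cat@elementInfo[
                     match(fam, cat@elementInfo$id), , drop = FALSE],
                   features = GRanges())
  index <- buildIndex(sub, seed_len = seed_len)
  withr::with_seed(seed, {
    libs <- lapply(fam, function(id)
      simulateUniform(cat@elements[[id]], depth = depth, read_len = read_len,
                      error_rate = error_rate, paired = paired,
                      id_prefix = id))
    if (paired) {
      lib <- .concatLibraries(libs)
      aln <- alignPairs(lib, index, max_mm = max_mm,
                        insert_bounds = c(read_len, 2L * read_len))
      ct_unf <- countFragments(aln, index, "unfiltered_uniform")
      ct_unq <- countFragments(aln, index, "unique_only")
    } else {
      reads <- do.call(c, lapply(libs, function(x) x@mate1))
      hits <- alignReads(reads, index, max_mm = max_mm)
      ct_unf <- .countSingle(hits, index, unique_only = FALSE)
      ct_unq <- .countSingle(hits, index, unique_only = TRUE)
    }
  })
  N <- ct_unf@nMapped
  f_unf <- ct_unf@counts[fam] * 1e9 / (as.numeric(lens[fam]) * N)
  f_unq <- ct_unq@counts[fam] * 1e9 / (as.numeric(lens[fam]) * N)
  fbar <- mean(f_unf)
  u <- 1 - f_unq / fbar
  u_pe <- ifelse(f_unf > 0, 1 - f_unq / f_unf, NA_real_)
  out <- data.frame(element_id = fam, f_unfiltered = unname(f_unf),
                    f_unique = unname(f_unq), u = unname(u),
                    u_per_element = unname(u_pe),
                    flagged = unname(u > threshold),
                    stringsAsFactors = FALSE)
  out[order(-out$u), , drop = FALSE]
}

.concatLibraries <- function(libs) {
  new("ReadLibrary",
      mate1 = do.call(c, lapply(libs, function(x) x@mate1)),
      mate2 = do.call(c, lapply(libs, function(x) x@mate2)),
      qual1 = unlist(lapply(libs, function(x) x@qual1)),
      qual2 = unlist(lapply(libs, function(x) x@qual2)),
      truth = DataFrame())
}

## single-end counting used by the mappability single-read mode
.countSingle <- function(hits, index, unique_only) {
  ids <- index$ids
  counts <- setNames(numeric(length(ids)), ids)
  n_mapped <- length(unique(hits$read))
  if (!nrow(hits))
    return(new("CountTable", counts = counts,
               mode = if (unique_only) "unique_only" else "unfiltered_uniform",
               strandMode = "unstranded", nMapped = 0, nCounted = 0))
  k <- table(hits$read)[as.character(hits$read)]
  if (unique_only) {
    h <- hits[k == 1, , drop = FALSE]
    tab <- table(h$element)
    counts[names(tab)] <- as.numeric(tab)
    n_counted <- nrow(h)
  } else {
    mass <- rowsum(1 / as.numeric(k), hits$element)
    counts[rownames(mass)] <- mass[, 1]
    n_counted <- n_mapped
  }
  new("CountTable", counts = counts,
      mode = if (unique_only) "unique_only" else "unfiltered_uniform",
      strandMode = "unstranded", nMapped = n_mapped,
      nCounted = as.numeric(n_counted))
}
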