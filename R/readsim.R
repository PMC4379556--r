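#' Library simulation parameters
#'
#' Defaults mirror the sequenced libraries: 250-base paired-end reads; insert
#' size normal with mean 180 truncated to [98, 522] for the cell library and
#' mean 200 truncated to [100, 568] for the virion library; the cell library
#' is stranded (dUTP fr-firststrand: mate 2 carries the transcript-sense
#' sequence) and the virion library, built with whole-transcriptome
#' amplification that erases strand marks, is not. The insert-size SD is not
#' a published quantity; 65/75 place the published ranges in the far tails.
#'
#' @param read_len read length (bases).
#' @param insert_mean,insert_sd,insert_min,insert_max insert-size
#'   distribution (normal, truncated).
#' @param error_rate per-base substitution error probability.
#' @param stranded logical; dUTP fr-firststrand when TRUE.
#' @param n_fragments number of read pairs to simulate.
#' @param seed integer seed.
#' @return a list of class \code{"LibraryParams"}.
#' @export
libraryParams <- function(read_len = 250L, insert_mean = 180, insert_sd = 65,
                          insert_min = 98L, insert_max = 522L,
                          error_rate = 0.005, stranded = TRUE,
                          n_fragments = 50000L, seed = 1L) {
  stopifnot(insert_min <= insert_mean, insert_mean <= insert_max,
            error_rate >= 0, error_rate < 1, n_fragments >= 0)
  structure(list(read_len = as.integer(read_len), insert_mean = insert_mean,
                 insert_sd = insert_sd, insert_min = as.integer(insert_min),
                 insert_max = as.integer(insert_max), error_rate = error_rate,
                 stranded = stranded, n_fragments = as.integer(n_fragments),
                 seed = as.integer(seed)),
            class = "LibraryParams")
}

#' @rdname libraryParams
#' @export
cellLibraryParams <- function(...) {
  do.call(libraryParams, utils::modifyList(
    list(insert_mean = 180, insert_sd = 65, insert_min = 98L,
         insert_max = 522L, stranded = TRUE), list(...)))
}

#' @rdname libraryParams
#' @export
virionLibraryParams <- function(...) {
  do.call(libraryParams, utils::modifyList(
    list(insert_mean = 200, insert_sd = 75, insert_min = 100L,
         insert_max = 568L, stranded = FALSE), list(...)))
}

.Q_HI <- 37L  # base quality
.Q_LO <- 17L  # quality written at simulated error positions

## vectorised substitution errors on a character vector of reads;
## returns list(seqs, err_pos) where err_pos is a list of positions per read
.injectErrors <- function(reads, rate) {
  n <- length(reads)
  err <- vector("list", n)
  if (rate <= 0 || n == 0) return(list(seqs = reads, err = err))
  lens <- nchar(reads)
  k <- rbinom(n, lens, rate)
  idx <- which(k > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(lens[i], k[i])
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      alt <- bases[bases != chars[p]]
      chars[p] <- alt[sample.int(3L, 1L)]
    }
    reads[i] <- paste(chars, collapse = "")
    err[[i]] <- sort(pos)
  }
  list(seqs = reads, err = err)
}

.qualStrings <- function(lens, err) {
  hi <- rawToChar(as.raw(33L + .Q_HI))
  lo <- rawToChar(as.raw(33L + .Q_LO))
  q <- vapply(lens, function(L) strrep(hi, L), character(1))
  for (i in seq_along(err)) {
    if (is.null(err[[i]])) next
    for (p in err[[i]]) substr(q[i], p, p) <- lo
  }
  q
}

#' Simulate a paired-end library from a truth profile
#'
#' Fragments are allocated to transcripts by a multinomial over molar
#' fraction times transcript length (so longer transcripts yield
#' proportionally more fragments and FPKM recovers molar fraction); fragment
#' starts are uniform; insert sizes are truncated-normal. Mates are FR; for
#' stranded libraries mate 2 carries the transcript-sense sequence
#' (fr-firststrand), for unstranded libraries the orientation of each pair
#' is random. Substitution errors are i.i.d. per base; error positions get a
#' reduced quality. Transcripts shorter than the minimum insert are skipped
#' with a warning.
#'
#' @param truth a [TruthProfile-class].
#' @param sample \code{"cell"} or \code{"virion"}: selects the fraction
#'   column.
#' @param params a [libraryParams()].
#' @return a [ReadLibrary-class] with per-pair truth labels.
#' @export
simulateLibrary <- function(truth, sample = c("cell", "virion"),
                            params = libraryParams()) {
  sample <- match.arg(sample)
  withr::with_seed(params$seed, .simulateLibraryImpl(truth, sample, params))
}

.simulateLibraryImpl <- function(truth, sample, params) {
  info <- truth@info
  frac <- if (sample == "cell") info$cell_fraction else info$virion_fraction
  tseq <- as.character(truth@transcripts)
  tlen <- nchar(tseq)
  usable <- tlen >= params$insert_min & frac > 0
  if (any(frac > 0 & tlen < params$insert_min))
    warning("transcript(s) shorter than minimum insert skipped: ",
            paste(info$transcript_id[frac > 0 & tlen < params$insert_min],
                  collapse = ", "))
  n <- params$n_fragments
  if (n == 0 || !any(usable)) {
    return(new("ReadLibrary", mate1 = DNAStringSet(), mate2 = DNAStringSet(),
               qual1 = character(0), qual2 = character(0),
               truth = DataFrame(pair_id = character(0),
                                 transcript_id = character(0),
                                 frag_start = integer(0),
                                 frag_end = integer(0),
                                 strand = character(0))))
  }
  w <- frac * tlen
  w[!usable] <- 0
  counts <- as.integer(rmultinom(1L, n, w))
  ti <- rep(seq_along(counts), counts)
  ord <- sample.int(length(ti))  # interleave transcripts
  ti <- ti[ord]
  L <- tlen[ti]
  ins <- round(rnorm(length(ti), params$insert_mean, params$insert_sd))
  bad <- which(ins < params$insert_min | ins > params$insert_max | ins > L)
  guard <- 0L
  while (length(bad)) {
    ins[bad] <- round(rnorm(length(bad), params$insert_mean, params$insert_sd))
    ok <- ins[bad] >= params$insert_min & ins[bad] <= params$insert_max &
      ins[bad] <= L[bad]
    # transcripts barely longer than the minimum insert can stall rejection
    guard <- guard + 1L
    if (guard > 1000L) ins[bad][!ok] <- pmin(L[bad][!ok], params$insert_max)
    bad <- bad[!ok]
  }
  s <- 1L + floor(runif(length(ti)) * (L - ins + 1))
  e <- s + ins - 1L
  frag <- substr(tseq[ti], s, e)
  rl <- pmin(params$read_len, ins)
  sense <- substr(frag, 1L, rl)
  anti <- as.character(reverseComplement(DNAStringSet(
    substr(frag, ins - rl + 1L, ins))))
  if (params$stranded) {
    m2 <- sense; m1 <- anti
  } else {
    flip <- runif(length(ti)) < 0.5
    m2 <- ifelse(flip, anti, sense)
    m1 <- ifelse(flip, sense, anti)
  }
  e1 <- .injectErrors(m1, params$error_rate)
  e2 <- .injectErrors(m2, params$error_rate)
  ids <- sprintf("%s_frag%06d", sample, seq_along(ti))
  tr <- DataFrame(pair_id = ids,
                  transcript_id = info$transcript_id[ti],
                  frag_start = as.integer(s), frag_end = as.integer(e),
                  strand = info$strand[ti])
  new("ReadLibrary",
      mate1 = DNAStringSet(setNames(unname(e1$seqs), ids)),
      mate2 = DNAStringSet(setNames(unname(e2$seqs), ids)),
      qual1 = unname(.qualStrings(nchar(e1$seqs), e1$err)),
      qual2 = unname(.qualStrings(nchar(e2$seqs), e2$err)),
      truth = tr)
}

#' Uniform read simulation over a single element
#'
#' Emulates an in-silico sequencing simulator at fixed depth: fragments with
#' abutting 250-base mates (insert = 2 x read length) are placed uniformly
#' along the element, \code{ceiling(depth x len / (2 x read_len))} of them,
#' error-free by default. Used by [assessMappability()].
#'
#' @param seq element sequence (character or DNAString).
#' @param depth target fold-coverage.
#' @param read_len read length; the element must be at least this long.
#' @param error_rate per-base substitution error rate (default 0:
#'   mappability is assessed free of sequencing error).
#' @param paired simulate pairs (TRUE) or single-end reads at
#'   \code{ceiling(depth x len / read_len)} (FALSE).
#' @param id_prefix prefix for read ids.
#' @return a [ReadLibrary-class]; for single-end output mate2 is empty and
#'   reads live in mate1.
#' @export
simulateUniform <- function(seq, depth = 20, read_len = 250L,
                            error_rate = 0, paired = TRUE,
                            id_prefix = "sim") {
  seq <- as.character(seq)
  L <- nchar(seq)
  if (L < read_len) stop("element shorter than read length (", L, " < ",
                         read_len, ")")
  if (paired) {
    ins <- 2L * read_len
    n <- ceiling(depth * L / ins)
    if (n == 0)
      return(new("ReadLibrary", mate1 = DNAStringSet(), mate2 = DNAStringSet(),
                 qual1 = character(0), qual2 = character(0),
                 truth = DataFrame(pair_id = character(0))))
    ins <- min(ins, L)
    s <- 1L + floor(runif(n) * (L - ins + 1))
    frag <- substr(rep(seq, n), s, s + ins - 1L)
    rl <- min(read_len, ins)
    m2 <- substr(frag, 1L, rl)
    m1 <- as.character(reverseComplement(DNAStringSet(
      substr(frag, ins - rl + 1L, ins))))
    e1 <- .injectErrors(m1, error_rate)
    e2 <- .injectErrors(m2, error_rate)
    ids <- sprintf("%s_%06d", id_prefix, seq_len(n))
    new("ReadLibrary",
        mate1 = DNAStringSet(setNames(e1$seqs, ids)),
        mate2 = DNAStringSet(setNames(e2$seqs, ids)),
        qual1 = .qualStrings(nchar(e1$seqs), e1$err),
        qual2 = .qualStrings(nchar(e2$seqs), e2$err),
        truth = DataFrame(pair_id = ids, frag_start = as.integer(s),
                          frag_end = as.integer(s + ins - 1L)))
  } else {
    n <- ceiling(depth * L / read_len)
    s <- 1L + floor(runif(n) * (L - read_len + 1))
    reads <- substr(rep(seq, n), s, s + read_len - 1L)
    er <- .injectErrors(reads, error_rate)
    ids <- sprintf("%s_%06d", id_prefix, seq_len(n))
    new("ReadLibrary",
        mate1 = DNAStringSet(setNames(er$seqs, ids)),
        mate2 = DNAStringSet(),
        qual1 = .qualStrings(nchar(er$seqs), er$err), qual2 = character(0),
        truth = DataFrame(pair_id = ids, frag_start = as.integer(s),
                          frag_end = as.integer(s + read_len - 1L)))
  }
}

#' Trim a read library
#'
#' Fixed trimming policy: (1) adapter removal by exact 3'-overlap match of at
#' least 10 bases between the read 3' end and the adapter 5' end; (2) 3'
#' quality trimming at the first 4-base sliding window whose mean Phred
#' quality falls below the threshold; (3) pairs are kept only when both
#' mates survive at the minimum length.
#'
#' @param lib a [ReadLibrary-class].
#' @param qual_threshold sliding-window mean quality threshold.
#' @param min_len minimum mate length after trimming.
#' @param adapters character vector of adapter sequences (may be empty).
#' @return list with \code{library} (trimmed [ReadLibrary-class]) and
#'   \code{report} (data.frame of pair counts).
#' @export
trimReads <- function(lib, qual_threshold = 25, min_len = 100L,
                      adapters = character(0)) {
  stopifnot(is(lib, "ReadLibrary"))
  n <- length(lib)
  if (n == 0) {
    return(list(library = lib,
                report = data.frame(pairs_in = 0L, pairs_kept = 0L,
                                    pairs_dropped = 0L, adapters_removed = 0L,
                                    bases_quality_trimmed = 0L)))
  }
  trimMate <- function(seqs, quals) {
    s <- as.character(seqs)
    nad <- 0L
    if (length(adapters)) {
      for (ad in adapters) {
        res <- .stripAdapter(s, ad)
        nad <- nad + res$n
        s <- res$seqs
      }
      quals <- substr(quals, 1L, nchar(s))
    }
    keep <- cpp_window_trim(quals, 4L, qual_threshold)
    nq <- sum(nchar(s) - keep)
    list(seqs = substr(s, 1L, keep), quals = substr(quals, 1L, keep),
         n_adapter = nad, n_qual = nq)
  }
  t1 <- trimMate(lib@mate1, lib@qual1)
  single <- length(lib@mate2) == 0
  t2 <- if (single) list(seqs = character(0), quals = character(0),
                         n_adapter = 0L, n_qual = 0L)
        else trimMate(lib@mate2, lib@qual2)
  ok <- nchar(t1$seqs) >= min_len
  if (!single) ok <- ok & nchar(t2$seqs) >= min_len
  truth <- if (nrow(lib@truth)) lib@truth[ok, , drop = FALSE] else lib@truth
  out <- new("ReadLibrary",
             mate1 = DNAStringSet(setNames(t1$seqs[ok],
                                           names(lib@mate1)[ok])),
             mate2 = if (single) DNAStringSet() else
               DNAStringSet(setNames(t2$seqs[ok], names(lib@mate2)[ok])),
             qual1 = t1$quals[ok],
             qual2 = if (single) character(0) else t2$quals[ok],
             truth = truth)
  list(library = out,
       report = data.frame(pairs_in = n, pairs_kept = sum(ok),
                           pairs_dropped = n - sum(ok),
                           adapters_removed = t1$n_adapter + t2$n_adapter,
                           bases_quality_trimmed = t1$n_qual + t2$n_qual))
}

## remove a 3' adapter by exact suffix(read)-prefix(adapter) overlap >= 10 bp
.stripAdapter <- function(seqs, adapter, min_overlap = 10L) {
  nmod <- 0L
  lens <- nchar(seqs)
  alen <- nchar(adapter)
  for (i in seq_along(seqs)) {
    L <- lens[i]
    for (k in seq(min(L, alen), min_overlap)) {
      if (substr(seqs[i], L - k + 1L, L) == substr(adapter, 1L, k)) {
        seqs[i] <- substr(seqs[i], 1L, L - k)
        nmod <- nmod + 1L
        break
      }
    }
  }
  list(seqs = seqs, n = nmod)
}

#' Write a read library as a FASTQ pair (+ truth TSV)
#'
#' @param lib a [ReadLibrary-class].
#' @param prefix path prefix; writes \code{<prefix>_1.fq}, \code{<prefix>_2.fq}
#'   and, when truth labels exist, \code{<prefix>_truth.tsv}.
#' @return invisibly, the written paths.
#' @export
writeLibrary <- function(lib, prefix) {
  p1 <- paste0(prefix, "_1.fq"); p2 <- paste0(prefix, "_2.fq")
  m1 <- lib@mate1; m2 <- lib@mate2
  if (length(m1)) names(m1) <- paste0(names(m1), "/1")
  q1 <- BStringSet(unname(lib@qual1)); names(q1) <- names(m1)
  writeXStringSet(m1, p1, format = "fastq", qualities = q1)
  paths <- p1
  if (length(m2) && length(m1)) {
    names(m2) <- paste0(names(m2), "/2")
    q2 <- BStringSet(unname(lib@qual2)); names(q2) <- names(m2)
    writeXStringSet(m2, p2, format = "fastq", qualities = q2)
    paths <- c(paths, p2)
  } else {
    # still emit a valid empty mate-2 file so downstream tooling sees a pair
    file.create(p2)
    paths <- c(paths, p2)
  }
  if (nrow(lib@truth)) {
    pt <- paste0(prefix, "_truth.tsv")
    write.table(as.data.frame(lib@truth), pt, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, pt)
  }
  invisible(paths)
}

#' Read a FASTQ pair into a ReadLibrary
#'
#' @param fq1,fq2 FASTQ paths (Phred+33). \code{fq2} may be \code{NULL} for
#'   single-end data.
#' @return a [ReadLibrary-class] without truth labels.
#' @export
readLibrary <- function(fq1, fq2 = NULL) {
  readOne <- function(path) {
    if (file.size(path) == 0)
      return(list(seqs = DNAStringSet(), quals = character(0)))
    # structural pre-validation with record indices
    lines <- readLines(path)
    if (length(lines) %% 4 != 0)
      stop("malformed FASTQ in ", path, ": record ",
           length(lines) %/% 4 + 1, " is truncated", call. = FALSE)
    hd <- lines[seq(1, length(lines), by = 4)]
    if (any(!startsWith(hd, "@")))
      stop("malformed FASTQ record ", which(!startsWith(hd, "@"))[1],
           " in ", path, ": header does not start with @", call. = FALSE)
    sl <- nchar(lines[seq(2, length(lines), by = 4)])
    ql <- nchar(lines[seq(4, length(lines), by = 4)])
    if (any(sl != ql))
      stop("malformed FASTQ record ", which(sl != ql)[1], " in ", path,
           ": sequence and quality lengths differ", call. = FALSE)
    x <- tryCatch(readDNAStringSet(path, format = "fastq",
                                   with.qualities = TRUE),
                  error = function(e) stop("malformed FASTQ in ", path, ": ",
                                           conditionMessage(e),
                                           call. = FALSE))
    quals <- as.character(mcols(x)$qualities)
    names(x) <- sub("/[12]$", "", sub("\\s.*$", "", names(x)))
    list(seqs = x, quals = quals)
  }
  r1 <- readOne(fq1)
  if (is.null(fq2)) {
    return(new("ReadLibrary", mate1 = DNAStringSet(as.character(r1$seqs)),
               mate2 = DNAStringSet(), qual1 = r1$quals, qual2 = character(0),
               truth = DataFrame()))
  }
  r2 <- readOne(fq2)
  if (length(r1$seqs) != length(r2$seqs))
    stop("FASTQ mate files differ in record count")
  new("ReadLibrary",
      mate1 = DNAStringSet(setNames(as.character(r1$seqs), names(r1$seqs))),
      mate2 = DNAStringSet(setNames(as.character(r2$seqs), names(r2$seqs))),
      qual1 = r1$quals, qual2 = r2$quals, truth = DataFrame())
}
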