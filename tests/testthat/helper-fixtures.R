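suppressPackageStartupMessages({
  library(Biostrings)
  library(S4Vectors)
})

## fixtures are generated once per test run and cached
.fix <- new.env()

fixtureFamily <- function() {
  if (is.null(.fix$fam)) .fix$fam <- generateFamily(familySpec(seed = 7))
  .fix$fam
}

## minimal hand-built catalogue: two unrelated random elements
tinyCatalogue <- function(seed = 42, n = 2, len = 3000) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), character(1))
    names(seqs) <- paste0("E", seq_len(n))
    Catalogue(seqs)
  })
}

## random DNA string
randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutateAt <- function(seq, pos) {
  for (p in pos) {
    cur <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
  }
  seq
}

revcompChr <- function(x) as.character(reverseComplement(DNAString(x)))

## --- independent brute-force alignment oracle (Biostrings full scan) ------

oracleMateHits <- function(read, seqs, max_mm) {
  out <- list()
  for (id in names(seqs)) {
    subj <- DNAString(as.character(seqs[[id]]))
    for (strand in c("+", "-")) {
      pat <- DNAString(if (strand == "+") read else revcompChr(read))
      m <- matchPattern(pat, subj, max.mismatch = max_mm, with.indels = FALSE)
      if (length(m)) {
        mm <- Biostrings::neditStartingAt(pat, subj, starting.at = start(m),
                                          with.indels = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          element = id, pos = start(m), strand = strand, mm = mm)
      }
    }
  }
  if (!length(out))
    return(data.frame(element = character(0), pos = integer(0),
                      strand = character(0), mm = integer(0)))
  do.call(rbind, out)
}

## concordant-pair enumeration from per-mate oracle hits (independent of the
## package's pairing code)
oraclePairLocations <- function(r1, r2, seqs, max_mm, bounds) {
  h1 <- oracleMateHits(r1, seqs, max_mm)
  h2 <- oracleMateHits(r2, seqs, max_mm)
  locs <- character(0)
  if (!nrow(h1) || !nrow(h2)) return(locs)
  L1 <- nchar(r1); L2 <- nchar(r2)
  for (i in seq_len(nrow(h1))) for (j in seq_len(nrow(h2))) {
    if (h1$element[i] != h2$element[j]) next
    if (h1$strand[i] == h2$strand[j]) next
    if (h1$strand[i] == "+") {
      plus_start <- h1$pos[i]; minus_start <- h2$pos[j]; minus_len <- L2
    } else {
      plus_start <- h2$pos[j]; minus_start <- h1$pos[i]; minus_len <- L1
    }
    if (plus_start > minus_start) next
    ins <- minus_start + minus_len - plus_start
    if (ins < bounds[1] || ins > bounds[2]) next
    locs <- c(locs, paste(h1$element[i], h1$pos[i], h1$strand[i], h2$pos[j]))
  }
  sort(unique(locs))
}

packageLocations <- function(aln, read) {
  h <- as.data.frame(aln@hits)
  h <- h[h$read == read, , drop = FALSE]
  sort(unique(paste(h$element, h$pos1, h$strand1, h$pos2)))
}

## build a ReadLibrary directly from mate sequence vectors
makeLibrary <- function(m1, m2, ids = sprintf("r%04d", seq_along(m1))) {
  q <- function(s) strrep("F", nchar(s))
  new("ReadLibrary",
      mate1 = DNAStringSet(setNames(m1, ids)),
      mate2 = DNAStringSet(setNames(m2, ids)),
      qual1 = vapply(m1, q, character(1), USE.NAMES = FALSE),
      qual2 = vapply(m2, q, character(1), USE.NAMES = FALSE),
      truth = DataFrame())
}

## draw an error-free FR pair from a plus-strand transcript/element sequence
drawPair <- function(seq, start, insert, read_len = 100L) {
  frag <- substr(seq, start, start + insert - 1L)
  rl <- min(read_len, insert)
  m2 <- substr(frag, 1L, rl)
  m1 <- revcompChr(substr(frag, insert - rl + 1L, insert))
  list(m1 = m1, m2 = m2)
}

## seeded five-scenario mechanism suite (shared by module and acceptance
## tests; built once)
mechanismSuite <- function() {
  if (!is.null(.fix$mech)) return(.fix$mech)
  fam <- fixtureFamily()
  cat1 <- fam$catalogue
  scen <- c(P05 = "divergent_neighbor_gene", P06 = "upstream_neighbor_gene",
            P08 = "intronic", P11 = "upstream_fragmentary_ltr",
            P09 = "antisense_neighbor")
  ctx <- buildHostContexts(cat1, scen, seed = 2)
  plan <- defaultSamplePlan(cat1, ctx)
  plan <- plan[plan$element_id %in% names(scen), ]
  plan$cell_level <- rep(1 / nrow(plan), nrow(plan))
  truth <- makeTruthProfile(cat1, ctx, plan)
  lib <- simulateLibrary(truth, "cell",
                         cellLibraryParams(n_fragments = 6000, error_rate = 0,
                                           seed = 19))
  ref <- referenceSet(cat1, ctx)
  idx <- buildIndex(ref)
  aln <- alignPairs(lib, idx)
  k <- locationCounts(aln)
  jx <- alignSpliced(lib, ref, which_pairs = which(k == 0))
  prof <- buildCoverage(aln, idx, "plus_stranded", junctions = jx,
                        unique_only = TRUE)
  mech <- classifyMechanisms(prof, elements = names(scen))
  .fix$mech <- list(scenarios = scen, mech = mech, jx = jx,
                    n_aligned = sum(k > 0))
  .fix$mech
}
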