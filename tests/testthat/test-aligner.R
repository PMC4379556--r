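test_that("a query equal to an element prefix gets one plus-strand hit", {
  cat1 <- tinyCatalogue(seed = 1)
  idx <- buildIndex(cat1, seed_len = 20)
  q <- substr(as.character(elementSeqs(cat1)[["E1"]]), 1, 100)
  h <- as.data.frame(alignReads(q, idx, max_mm = 2))
  expect_equal(nrow(h), 1L)
  expect_equal(h$element, "E1")
  expect_equal(h$pos, 1L)
  expect_equal(h$strand, "+")
  expect_equal(h$mm, 0L)
  # reverse-complemented query found on the minus strand, same position
  hrc <- as.data.frame(alignReads(revcompChr(q), idx, max_mm = 2))
  expect_equal(hrc$strand, "-")
  expect_equal(hrc$pos, 1L)
})

test_that("seeded search equals brute force on planted-mismatch reads", {
  withr::with_seed(101, {
    cat1 <- tinyCatalogue(seed = 11, n = 3, len = 4000)
    seqs <- as.character(elementSeqs(cat1))
    idx <- buildIndex(cat1, seed_len = 20)
    reads <- vapply(1:100, function(i) {
      e <- sample(names(seqs), 1)
      s <- sample(nchar(seqs[[e]]) - 249, 1)
      r <- substr(seqs[[e]], s, s + 249)
      nmm <- sample(0:3, 1)  # sometimes beyond the budget
      if (nmm > 0) r <- mutateAt(r, sample(250, nmm))
      if (runif(1) < 0.5) r <- revcompChr(r)
      r
    }, character(1))
    h <- as.data.frame(alignReads(reads, idx, max_mm = 2))
    for (i in seq_along(reads)) {
      pkg <- h[h$read == i, c("element", "pos", "strand", "mm")]
      pkg <- pkg[order(pkg$element, pkg$pos, pkg$strand), ]
      ora <- oracleMateHits(reads[i], seqs, 2)
      ora <- ora[order(ora$element, ora$pos, ora$strand), ]
      expect_equal(unname(as.matrix(pkg)), unname(as.matrix(ora)),
                   label = paste("read", i))
    }
  })
})

test_that("pairs are unique on lone loci and multi on identical duplicates", {
  fam <- fixtureFamily()
  cat1 <- fam$catalogue
  seqs <- as.character(elementSeqs(cat1))
  idx <- buildIndex(cat1)
  # P11 (8% diverged) has no close paralog; P01/P02 are identical
  p11 <- drawPair(seqs[["P11"]], 3000, 300, 100)
  dup <- drawPair(seqs[["P01"]], 3000, 300, 100)
  lib <- makeLibrary(c(p11$m1, dup$m1), c(p11$m2, dup$m2))
  aln <- alignPairs(lib, idx, max_mm = 2, insert_bounds = c(90, 600))
  k <- locationCounts(aln)
  expect_equal(k[1], 1L)
  expect_gte(k[2], 2L)    # may also cross-map to other young paralogs
  h <- as.data.frame(slot(aln, "hits"))
  expect_true(all(c("P01", "P02") %in% h$element[h$read == 2]))
})

test_that("uniqueness tracks diagnostic-site coverage between close paralogs", {
  withr::with_seed(77, {
    base <- randomDNA(4000)
    mutpos <- sort(sample(4000, 20))       # ~99.5% identity
    par <- mutateAt(base, mutpos)
    seqs <- c(A = base, B = par)
    idx <- buildIndex(seqs, seed_len = 20)
    # a window covering at least one diagnostic site -> unique
    s_div <- mutpos[5] - 50
    pA <- drawPair(base, s_div, 200, 80)
    # a window in an identical region -> multi
    gaps <- which(diff(c(0, mutpos, 4000)) > 260)
    s_same <- c(0, mutpos)[gaps[1]] + 5
    pB <- drawPair(base, s_same, 200, 80)
    lib <- makeLibrary(c(pA$m1, pB$m1), c(pA$m2, pB$m2))
    aln <- alignPairs(lib, idx, max_mm = 2, insert_bounds = c(90, 600))
    # confirmed against the brute-force oracle
    for (i in 1:2) {
      m1 <- as.character(slot(lib, "mate1")[[i]])
      m2 <- as.character(slot(lib, "mate2")[[i]])
      expect_identical(packageLocations(aln, i),
                       oraclePairLocations(m1, m2, seqs, 2, c(90, 600)))
    }
    k <- locationCounts(aln)
    expect_equal(k[1], 1L)
    expect_gt(k[2], 1L)
  })
})

test_that("raising the mismatch budget never removes a location", {
  withr::with_seed(55, {
    cat1 <- tinyCatalogue(seed = 21, n = 2, len = 3000)
    seqs <- as.character(elementSeqs(cat1))
    idx <- buildIndex(cat1, seed_len = 15)
    reads <- vapply(1:30, function(i) {
      e <- sample(2, 1); s <- sample(2700, 1)
      mutateAt(substr(seqs[[e]], s, s + 119), sample(120, sample(0:2, 1)))
    }, character(1))
    for (m in 0:1) {
      h_lo <- as.data.frame(alignReads(reads, idx, max_mm = m))
      h_hi <- as.data.frame(alignReads(reads, idx, max_mm = m + 1))
      lo <- paste(h_lo$read, h_lo$element, h_lo$pos, h_lo$strand)
      hi <- paste(h_hi$read, h_hi$element, h_hi$pos, h_hi$strand)
      expect_true(all(lo %in% hi))
    }
  })
})

test_that("alignment is symmetric under pair reverse-complement + mate swap", {
  withr::with_seed(66, {
    cat1 <- tinyCatalogue(seed = 31, n = 2, len = 3000)
    seqs <- as.character(elementSeqs(cat1))
    idx <- buildIndex(cat1, seed_len = 15)
    p <- drawPair(seqs[["E1"]], 500, 250, 100)
    lib_f <- makeLibrary(p$m1, p$m2)
    # the same fragment sequenced from the opposite sense: mate roles swap
    # (equivalently, both mates reverse-complemented and the pair flipped)
    lib_r <- makeLibrary(p$m2, p$m1)
    a_f <- as.data.frame(slot(alignPairs(lib_f, idx), "hits"))
    a_r <- as.data.frame(slot(alignPairs(lib_r, idx), "hits"))
    expect_equal(nrow(a_f), nrow(a_r))
    # the physical fragment location is invariant and each mate's alignment
    # strand flips
    expect_setequal(paste(a_f$element, pmin(a_f$pos1, a_f$pos2)),
                    paste(a_r$element, pmin(a_r$pos1, a_r$pos2)))
    expect_setequal(a_r$strand1, setdiff(c("+", "-"), a_f$strand1))
  })
})

test_that("spliced alignment recovers engineered junctions exactly", {
  fam <- fixtureFamily()
  cat1 <- fam$catalogue
  ctx <- buildHostContexts(cat1, c(P11 = "upstream_fragmentary_ltr"), seed = 2)
  truth <- makeTruthProfile(cat1, ctx, data.frame(
    element_id = "P11", mechanism = "upstream_ltr_chimeric",
    cell_level = 1, packaging_eff = 1))
  spl <- as.data.frame(slot(ctx, "splices"))
  tx <- as.character(truthTranscripts(truth)[[1]])
  exon1 <- spl$donor - spl$tss + 1L
  # 50 error-free reads spanning the junction with >= 30 bases each side
  withr::with_seed(12, {
    starts <- sample(seq(exon1 - 120, exon1 - 30), 50, replace = TRUE)
  })
  reads <- substring(tx, starts, starts + 149)
  lib <- makeLibrary(reads, vapply(reads, revcompChr, character(1),
                                   USE.NAMES = FALSE))
  jx <- as.data.frame(alignSpliced(lib, referenceSet(cat1, ctx),
                                   which_pairs = seq_along(reads)))
  jx1 <- jx[jx$mate == 1, ]
  expect_equal(nrow(jx1), 50L)
  expect_true(all(jx1$donor == spl$donor))
  expect_true(all(jx1$acceptor == spl$acceptor))
  expect_true(all(jx1$gt_ag))
  expect_true(all(jx1$mm == 0))
})

test_that("a read within one exon is never split", {
  fam <- fixtureFamily()
  cat1 <- fam$catalogue
  seqs <- as.character(elementSeqs(cat1))
  idx <- buildIndex(cat1)
  p <- drawPair(seqs[["P11"]], 2000, 300, 120)
  lib <- makeLibrary(p$m1, p$m2)
  aln <- alignPairs(lib, idx)
  expect_equal(locationCounts(aln)[1], 1L)
  jx <- alignSpliced(lib, referenceSet(cat1), which_pairs = 1L)
  expect_equal(nrow(jx), 0L)
})

test_that("SAM output is valid and filterable at MAPQ 50", {
  fam <- fixtureFamily()
  cat1 <- fam$catalogue
  seqs <- as.character(elementSeqs(cat1))
  idx <- buildIndex(cat1)
  u <- drawPair(seqs[["P11"]], 3000, 300, 100)
  m <- drawPair(seqs[["P01"]], 3000, 300, 100)
  lib <- makeLibrary(c(u$m1, m$m1), c(u$m2, m$m2))
  aln <- alignPairs(lib, idx)
  sam <- tempfile(fileext = ".sam")
  writeSam(aln, lib, idx, sam)
  k <- locationCounts(aln)
  lines <- readLines(sam)
  body <- lines[!startsWith(lines, "@")]
  expect_equal(length(body), 2L * sum(k))  # two mates per location
  fields <- strsplit(body, "\t")
  mapq <- vapply(fields, function(f) as.integer(f[5]), integer(1))
  expect_equal(sum(mapq == 50), 2L)              # the unique pair
  expect_equal(sum(mapq == 1), 2L * k[2])        # every multi location
  expect_true(all(grepl("NH:i:", body)))
  # parses cleanly with a standard SAM reader
  bam <- suppressWarnings(Rsamtools::asBam(sam, tempfile(),
                                           indexDestination = FALSE))
  expect_true(file.exists(bam))
  recs <- Rsamtools::scanBam(bam)[[1]]
  expect_equal(length(recs$qname), 2L * sum(k))
})
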