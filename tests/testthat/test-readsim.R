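simTruth <- function() {
  if (is.null(.fix$simTruth)) {
    fam <- fixtureFamily()
    ctx <- isolatedContexts(fam$catalogue)
    plan <- data.frame(element_id = c("P05", "P08"),
                       mechanism = "ltr_driven",
                       cell_level = c(0.8, 0.2), packaging_eff = 1)
    .fix$simTruth <- makeTruthProfile(fam$catalogue, ctx, plan)
  }
  .fix$simTruth
}

test_that("zero fragments produce an empty but valid library", {
  lib <- simulateLibrary(simTruth(), "cell",
                         cellLibraryParams(n_fragments = 0, seed = 1))
  expect_equal(length(lib), 0L)
  p <- tempfile()
  writeLibrary(lib, p)
  expect_true(file.exists(paste0(p, "_1.fq")))
  expect_equal(file.size(paste0(p, "_1.fq")), 0)
})

test_that("error-free mates are exact FR substrings of their transcript", {
  truth <- simTruth()
  lib <- simulateLibrary(truth, "cell",
                         cellLibraryParams(n_fragments = 50, error_rate = 0,
                                           seed = 2))
  tseq <- setNames(as.character(truthTranscripts(truth)),
                   truthInfo(truth)$transcript_id)
  tr <- as.data.frame(slot(lib, "truth"))
  m1 <- unname(as.character(slot(lib, "mate1")))
  m2 <- unname(as.character(slot(lib, "mate2")))
  for (i in seq_len(length(lib))) {
    frag <- unname(substr(tseq[tr$transcript_id[i]], tr$frag_start[i],
                          tr$frag_end[i]))
    # stranded: mate2 = transcript sense 5' end, mate1 = revcomp of 3' end
    expect_identical(m2[i], substr(frag, 1, nchar(m2[i])))
    expect_identical(m1[i], revcompChr(substr(frag,
                                              nchar(frag) - nchar(m1[i]) + 1,
                                              nchar(frag))))
  }
  expect_equal(nrow(tr), length(lib))
})

test_that("fragment counts follow the length-weighted multinomial", {
  truth <- simTruth()  # two equal-length transcripts at 0.8/0.2
  lib <- simulateLibrary(truth, "cell",
                         cellLibraryParams(n_fragments = 10000, seed = 3))
  tr <- as.data.frame(slot(lib, "truth"))
  n1 <- sum(tr$transcript_id == "P05.ltr")
  sd3 <- 3 * sqrt(10000 * 0.8 * 0.2)
  expect_lt(abs(n1 - 8000), sd3)
})

test_that("simulation is byte-reproducible under a fixed seed", {
  l1 <- simulateLibrary(simTruth(), "cell",
                        cellLibraryParams(n_fragments = 200, seed = 9))
  l2 <- simulateLibrary(simTruth(), "cell",
                        cellLibraryParams(n_fragments = 200, seed = 9))
  p1 <- tempfile(); p2 <- tempfile()
  writeLibrary(l1, p1); writeLibrary(l2, p2)
  expect_identical(readLines(paste0(p1, "_1.fq")),
                   readLines(paste0(p2, "_1.fq")))
  expect_identical(readLines(paste0(p1, "_2.fq")),
                   readLines(paste0(p2, "_2.fq")))
})

test_that("FASTQ round trip preserves sequences and qualities", {
  lib <- simulateLibrary(simTruth(), "cell",
                         cellLibraryParams(n_fragments = 30, seed = 4))
  p <- tempfile()
  writeLibrary(lib, p)
  back <- readLibrary(paste0(p, "_1.fq"), paste0(p, "_2.fq"))
  expect_identical(as.character(slot(back, "mate1")),
                   as.character(slot(lib, "mate1")))
  expect_identical(slot(back, "qual2"), slot(lib, "qual2"))
})

test_that("malformed FASTQ is rejected with a useful error", {
  p <- tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "FF"), p)   # qual/seq length mismatch
  expect_error(readLibrary(p), "malformed FASTQ")
})

test_that("uniform simulation hits the fragment-count formula and depth", {
  elem <- withr::with_seed(5, randomDNA(5000))
  lib <- withr::with_seed(6, simulateUniform(elem, depth = 20, read_len = 250))
  expect_equal(length(lib), 200L)  # 20 * 5000 / (2 * 250)

  lib0 <- withr::with_seed(6, simulateUniform(elem, depth = 0))
  expect_equal(length(lib0), 0L)

  expect_error(simulateUniform(substr(elem, 1, 100), read_len = 250),
               "shorter")

  elem10 <- withr::with_seed(7, randomDNA(10000))
  lib10 <- withr::with_seed(8, simulateUniform(elem10, depth = 20))
  tr <- as.data.frame(slot(lib10, "truth"))
  total_bases <- sum(tr$frag_end - tr$frag_start + 1)
  expect_lt(abs(total_bases / 10000 - 20) / 20, 0.2)
})

test_that("trimming keeps clean reads, strips adapters, drops short mates", {
  m1 <- vapply(1:5, function(i) randomDNA(150), character(1))
  m2 <- vapply(1:5, function(i) randomDNA(150), character(1))
  lib <- makeLibrary(m1, m2)
  out <- trimReads(lib)
  expect_identical(as.character(slot(out$library, "mate1")),
                   as.character(slot(lib, "mate1")))
  expect_equal(out$report$pairs_kept, 5L)

  adapter <- "AGATCGGAAGAGCACACGTC"
  libA <- makeLibrary(paste0(m1[1], adapter), m2[1])
  outA <- trimReads(libA, adapters = adapter)
  expect_equal(Biostrings::width(slot(outA$library, "mate1")), 150L)
  expect_equal(outA$report$adapters_removed, 1L)

  # mate trimmed below 100 bases drops the whole pair
  lowq <- paste0(strrep("F", 98), strrep("#", 52))
  libQ <- new("ReadLibrary",
              mate1 = Biostrings::DNAStringSet(c(a = m1[1], b = m1[2])),
              mate2 = Biostrings::DNAStringSet(c(a = m2[1], b = m2[2])),
              qual1 = c(lowq, strrep("F", 150)),
              qual2 = rep(strrep("F", 150), 2),
              truth = S4Vectors::DataFrame())
  outQ <- trimReads(libQ)
  expect_equal(outQ$report$pairs_kept, 1L)
  expect_equal(outQ$report$pairs_dropped, 1L)
  expect_identical(names(slot(outQ$library, "mate1")), "b")
})
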