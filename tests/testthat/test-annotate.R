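test_that("an undiverged provirus carries all four full-length ORFs", {
  spec <- familySpec(divergences = c(A = 0),
                     duplicate_pairs = data.frame(a = character(0),
                                                  b = character(0),
                                                  divergence = numeric(0)),
                     type1_members = character(0),
                     solo_ltrs = setNames(numeric(0), character(0)),
                     hypermutated_members = character(0), seed = 3)
  fam <- generateFamily(spec)
  orfs <- findOrfs(fam$catalogue, "A")
  expect_equal(nrow(orfs), 4L)
  expect_true(all(orfs$status == "full_length"))
  expect_equal(orfs$length_aa[orfs$gene == "gag"], 666L)
  # invariant: span length = 3 * aa + 3 (stop included)
  expect_true(all(orfs$end - orfs$start + 1L == 3L * orfs$length_aa + 3L))
})

test_that("a premature stop 129 bp before the native stop truncates gag by 43 aa", {
  spec <- familySpec(divergences = c(A = 0),
                     duplicate_pairs = data.frame(a = character(0),
                                                  b = character(0),
                                                  divergence = numeric(0)),
                     type1_members = character(0),
                     solo_ltrs = setNames(numeric(0), character(0)),
                     hypermutated_members = character(0), seed = 3)
  fam <- generateFamily(spec)
  cat1 <- fam$catalogue
  seq <- as.character(elementSeqs(cat1)[["A"]])
  f <- elementFeatures(cat1)
  gag <- f[as.character(GenomicRanges::seqnames(f)) == "A" &
             f$feature == "gag"]
  stop_at <- BiocGenerics::end(gag) - 2L - 129L  # 43 codons early, in frame
  substr(seq, stop_at, stop_at + 2L) <- "TAA"
  cat2 <- Catalogue(setNames(seq, "A"), elementInfo = elementInfo(cat1),
                    features = f)
  orfs <- findOrfs(cat2, "A")
  gagrow <- orfs[orfs$gene == "gag", ]
  expect_equal(gagrow$status, "truncated")
  expect_equal(gagrow$length_aa, 666L - 43L)
})

test_that("a coding desert yields absent calls for every gene", {
  fam <- fixtureFamily()
  f <- elementFeatures(fam$catalogue)
  f <- f[as.character(GenomicRanges::seqnames(f)) == "P01"]
  cat1 <- Catalogue(setNames(strrep("A", 9500), "P01"), features = f)
  orfs <- findOrfs(cat1, "P01")
  expect_true(all(orfs$status == "absent"))
})

test_that("type classification handles boundary-less and engineered cases", {
  fam <- fixtureFamily()
  cat1 <- fam$catalogue
  bref <- polEnvBoundaryRef(cat1, "P01")
  expect_equal(nchar(bref), 600L)
  r1 <- classifyType(cat1, bref, id = "P04")   # engineered type 1
  expect_equal(r1$type, "type1")
  expect_equal(r1$deletion_len, 292L)
  r2 <- classifyType(cat1, bref, id = "P03")   # unmodified type 2
  expect_equal(r2$type, "type2")
  expect_equal(r2$deletion_len, 0L)
  r3 <- classifyType(cat1, bref, id = "S01")   # solo LTR: boundary absent
  expect_equal(r3$type, "unknown")
  expect_true(is.na(r3$deletion_len))
})

test_that("ORF abundance allocation is non-exclusive with a none category", {
  expr <- data.frame(element_id = c("E1", "E2"), class = "provirus",
                     abundance = c(60, 40))
  orfs <- data.frame(
    element_id = c("E1", "E1", "E1", "E2", "E2", "E2"),
    gene = rep(c("gag", "pol", "env"), 2),
    status = c("full_length", "truncated", "absent",
               "absent", "absent", "absent"))
  out <- allocateOrfAbundance(expr, orfs)
  expect_equal(out$total[out$gene == "gag"], 60)
  expect_equal(out$full_length[out$gene == "gag"], 60)
  expect_equal(out$total[out$gene == "pol"], 60)
  expect_equal(out$truncated[out$gene == "pol"], 60)
  expect_equal(out$total[out$gene == "env"], 0)
  expect_equal(out$total[out$gene == "none"], 40)

  # a zero-abundance element contributes nothing anywhere
  expr0 <- rbind(expr, data.frame(element_id = "E3", class = "provirus",
                                  abundance = 0))
  orfs0 <- rbind(orfs, data.frame(element_id = "E3", gene = "gag",
                                  status = "full_length"))
  out0 <- allocateOrfAbundance(expr0, orfs0)
  expect_equal(out0$total[out0$gene == "gag"], 60)
})

test_that("the canonical motif catalogue has exactly eight instances", {
  mot <- canonicalMotifCatalogue()
  expect_equal(nrow(mot), 8L)
  expect_setequal(mot$name, c("GA", "E1", "E2", "E3", "GC1", "GC2",
                              "TATA", "Inr"))
  expect_equal(mot$seq[mot$name == "TATA"], "AATAAATA")
  expect_true(all(nchar(mot$seq) == mot$end - mot$start + 1L))
})

test_that("motif scanning: canonical, planted mutation, random sequence", {
  spec <- familySpec(divergences = c(A = 0),
                     duplicate_pairs = data.frame(a = character(0),
                                                  b = character(0),
                                                  divergence = numeric(0)),
                     type1_members = character(0),
                     solo_ltrs = setNames(numeric(0), character(0)),
                     hypermutated_members = character(0), seed = 3)
  fam <- generateFamily(spec)
  ltr <- as.character(extractLTR(fam$catalogue, "A", "5prime"))
  r <- scanPromoterMotifs(ltr)
  expect_equal(unname(r$summary), c(8L, 0L, 0L))

  # TATA AATAAATA -> AATACATA: one motif becomes mutated with 1 mismatch
  ltr2 <- ltr
  substr(ltr2, 790 + 4, 790 + 4) <- "C"
  r2 <- scanPromoterMotifs(ltr2)
  expect_equal(unname(r2$summary["n_canonical"]), 7L)
  expect_equal(unname(r2$summary["n_mutated"]), 1L)
  tata <- r2$hits[r2$hits$name == "TATA", ]
  expect_equal(tata$mismatches, 1L)

  # random LTRs: short motifs hit by chance within the +/-15 window and the
  # 3-mismatch cap (an 8-mer beats 4 mismatches somewhere ~97% of the time),
  # but the three 12-bp E boxes are each missing with probability ~0.99,
  # so at least 3 motifs are missing in nearly every random sequence
  missing <- withr::with_seed(77, vapply(1:20, function(i)
    scanPromoterMotifs(randomDNA(968))$summary[["n_missing"]], integer(1)))
  expect_true(mean(missing >= 3) > 0.85)
  # counts always partition the 8 motifs
  r3 <- scanPromoterMotifs(randomDNA(968))
  expect_equal(sum(r3$summary), 8L)
})
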