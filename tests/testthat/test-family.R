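test_that("zero divergence reproduces the ancestor and identical LTRs", {
  spec <- familySpec(divergences = c(A = 0),
                     duplicate_pairs = data.frame(a = character(0),
                                                  b = character(0),
                                                  divergence = numeric(0)),
                     type1_members = character(0),
                     solo_ltrs = setNames(numeric(0), character(0)),
                     hypermutated_members = character(0), seed = 3)
  fam <- generateFamily(spec)
  expect_identical(as.character(elementSeqs(fam$catalogue)[["A"]]),
                   as.character(fam$ancestor))
  expect_identical(as.character(extractLTR(fam$catalogue, "A", "5prime")),
                   as.character(extractLTR(fam$catalogue, "A", "3prime")))
})

test_that("type-1 members are exactly 292 bp shorter and remapped", {
  fam <- fixtureFamily()
  cat1 <- fam$catalogue
  info <- elementInfo(cat1)
  lens <- setNames(Biostrings::width(elementSeqs(cat1)), names(cat1))
  t1 <- info$id[info$type == "type1"]
  t2 <- info$id[info$type == "type2"]
  expect_true(length(t1) >= 1)
  expect_true(all(lens[t1] == lens[t2][1] - 292L))
  # env annotation still inside the shortened element
  for (id in t1) {
    f <- elementFeatures(cat1)
    env <- f[as.character(GenomicRanges::seqnames(f)) == id &
               f$feature == "env"]
    expect_true(BiocGenerics::end(env) <= lens[id])
  }
})

test_that("realised substitution counts follow Binomial(len, divergence)", {
  d <- 0.02
  spec <- familySpec(divergences = c(X = d),
                     duplicate_pairs = data.frame(a = character(0),
                                                  b = character(0),
                                                  divergence = numeric(0)),
                     type1_members = character(0),
                     solo_ltrs = setNames(numeric(0), character(0)),
                     hypermutated_members = character(0), seed = 11)
  fam <- generateFamily(spec)
  L <- nchar(as.character(fam$ancestor))
  obs <- sum(strsplit(as.character(elementSeqs(fam$catalogue)[["X"]]),
                      "")[[1]] !=
               strsplit(as.character(fam$ancestor), "")[[1]])
  sd3 <- 3 * sqrt(L * d * (1 - d))
  expect_lt(abs(obs - L * d), sd3 + 2)  # +2 for the conserved-acceptor replant
})

test_that("duplicate pairs have the requested intra-pair divergence", {
  fam <- fixtureFamily()
  a <- as.character(elementSeqs(fam$catalogue)[["P01"]])
  b <- as.character(elementSeqs(fam$catalogue)[["P02"]])
  expect_identical(a, b)  # default pair is identical (intra-divergence 0)

  spec <- familySpec(duplicate_pairs = data.frame(a = "P01", b = "P02",
                                                  divergence = 0.01),
                     seed = 5)
  fam2 <- generateFamily(spec)
  a <- strsplit(as.character(elementSeqs(fam2$catalogue)[["P01"]]), "")[[1]]
  b <- strsplit(as.character(elementSeqs(fam2$catalogue)[["P02"]]), "")[[1]]
  ham <- sum(a != b) / length(a)
  expect_lt(abs(ham - 0.01), 3 * sqrt(0.01 * 0.99 / length(a)) + 1e-3)
})

test_that("the generator is byte-reproducible under a fixed seed", {
  f1 <- generateFamily(familySpec(seed = 99))
  f2 <- generateFamily(familySpec(seed = 99))
  expect_identical(as.character(elementSeqs(f1$catalogue)),
                   as.character(elementSeqs(f2$catalogue)))
  expect_identical(f1$ancestry, f2$ancestry)
  f3 <- generateFamily(familySpec(seed = 100))
  expect_false(identical(as.character(elementSeqs(f1$catalogue)),
                         as.character(elementSeqs(f3$catalogue))))
})

test_that("solo LTRs are single-LTR records with U3/R/U5 annotation", {
  fam <- fixtureFamily()
  cat1 <- fam$catalogue
  info <- elementInfo(cat1)
  solos <- info$id[info$class == "solo_ltr"]
  expect_equal(length(solos), 2L)
  lens <- Biostrings::width(elementSeqs(cat1)[solos])
  expect_true(all(lens == 968L))
})

test_that("every generated member is classified to its true type", {
  fam <- fixtureFamily()
  cat1 <- fam$catalogue
  info <- elementInfo(cat1)
  t2 <- info$id[info$type == "type2"][1]
  bref <- polEnvBoundaryRef(cat1, t2)
  for (i in seq_len(nrow(info))) {
    r <- classifyType(cat1, bref, id = info$id[i])
    expect_equal(r$type, info$type[i], label = info$id[i])
    if (info$type[i] == "type1") expect_equal(r$deletion_len, 292L)
    if (info$type[i] == "type2") expect_equal(r$deletion_len, 0L)
  }
})

test_that("invalid family specifications are rejected", {
  expect_error(familySpec(divergences = c(A = -0.1)))
  expect_error(familySpec(type1_members = "missing"), "not in family")
})
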