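## Canonical element architecture used by the generator. The LTR is 968 bp
## with U3 = 1-792, R = 793-870, U5 = 871-968, so the transcription start
## site (U3-R border) sits at LTR position 793 and the alternative start in
## R at 826. Internal genes are sized so that gag encodes 666 aa.

.LTR_LEN <- 968L
.U3 <- c(1L, 792L)
.R <- c(793L, 870L)
.U5 <- c(871L, 968L)
.TSS_U3R <- 793L
.LEADER_LEN <- 192L
.GENE_LEN <- c(gag = 2001L, pro = 900L, pol = 2700L, env = 1740L)
.ANCESTOR_LEN <- 9500L
.TYPE1_DEL_LEN <- 292L
# splice acceptor dinucleotide conserved in the gag leader; the intron of the
# upstream-LTR chimeric transcript ends here (acceptor = next base, 1018)
.LEADER_AG <- c(1016L, 1017L)

#' Canonical promoter motif catalogue for the HML-2 LTR
#'
#' The eight promoter-element motifs of the canonical 968-bp LTR, with their
#' canonical sequences and 1-based positions: a GA-rich motif, three enhancer
#' (E) boxes, two GC boxes, the TATA box and the initiator (Inr) element.
#'
#' @return data.frame with columns \code{name}, \code{start}, \code{end},
#'   \code{seq}.
#' @export
canonicalMotifCatalogue <- function() {
  data.frame(
    name = c("GA", "E1", "E2", "GC2", "GC1", "TATA", "Inr", "E3"),
    start = c(379L, 465L, 485L, 602L, 759L, 790L, 807L, 832L),
    end = c(386L, 476L, 496L, 606L, 763L, 797L, 812L, 843L),
    seq = c("GGGAAGGG", "TTGCAGTTGAGA", "AGGCATCTGTCT", "GGCGG", "CCCCC",
            "AATAAATA", "CTCAGA", "CTCCATATGCTG"),
    stringsAsFactors = FALSE)
}

#' Canonical LTR region layout
#'
#' @return list with \code{ltr_len}, \code{u3}, \code{r}, \code{u5},
#'   \code{tss} (the U3-R border position, 793) and \code{alt_tss} (826,
#'   within R).
#' @export
canonicalLtrLayout <- function() {
  list(ltr_len = .LTR_LEN, u3 = .U3, r = .R, u5 = .U5,
       tss = .TSS_U3R, alt_tss = 826L)
}

.randBases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.plant <- function(seq, at, what) {
  substr(seq, at, at + nchar(what) - 1L) <- what
  seq
}

## random LTR with the 8 canonical promoter motifs planted at their
## canonical positions
.buildCanonicalLTR <- function() {
  ltr <- .randBases(.LTR_LEN)
  mot <- canonicalMotifCatalogue()
  for (i in seq_len(nrow(mot))) ltr <- .plant(ltr, mot$start[i], mot$seq[i])
  ltr
}

## gene as an intact ORF: ATG + sense codons + TAA
.buildGene <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  body <- sample(sense, len / 3 - 2, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

## Jukes-Cantor-like point substitution: Binomial(L, d) positions, each to
## one of the other three bases uniformly
.mutateSeq <- function(seq, d) {
  L <- nchar(seq)
  n <- rbinom(1L, L, d)
  if (n == 0L) return(list(seq = seq, n_sub = 0L))
  pos <- sample.int(L, n)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    alt <- bases[bases != chars[p]]
    chars[p] <- alt[sample.int(3L, 1L)]
  }
  list(seq = paste(chars, collapse = ""), n_sub = n)
}

## strand-specific G->A hypermutation (APOBEC3G-like signature, no context
## model): replaces fraction h of plus-strand G positions
.hypermutate <- function(seq, h) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  gpos <- which(chars == "G")
  n <- round(h * length(gpos))
  if (n > 0) chars[sample(gpos, n)] <- "A"
  paste(chars, collapse = "")
}

#' Specification for a synthetic provirus family
#'
#' Defines the family the generator emulates: a set of descendants of a
#' common full-length ancestor spanning a divergence gradient from
#' just-integrated (human-specific LTR Hs-like) through old (LTR 5B-like)
#' loci, a post-integration duplicate pair, type-1 members carrying the
#' 292-bp pol-env deletion, solo-LTR recombinants and an APOBEC-hypermutated
#' member.
#'
#' @param divergences named numeric vector: per-provirus substitution
#'   proportion relative to the ancestor (0 = just integrated).
#' @param duplicate_pairs data.frame with columns \code{a}, \code{b},
#'   \code{divergence}: element \code{b} is a post-integration duplicate of
#'   \code{a} at the given intra-pair divergence (0 = identical). \code{b}
#'   must not appear in \code{divergences}.
#' @param type1_members ids receiving the 292-bp pol-env boundary deletion.
#' @param solo_ltrs named numeric vector: solo-LTR ids and the divergence of
#'   the (virtual) donor provirus each recombined from.
#' @param hypermutated_members ids receiving strand-specific G-to-A
#'   hypermutation at rate \code{hyper_rate}.
#' @param hyper_rate fraction of plus-strand G replaced by A.
#' @param ancestor_len,ltr_len,leader_len,gene_len ancestral architecture;
#'   defaults give a 9.5-kb provirus with a 968-bp LTR and a 666-aa gag.
#' @param seed integer seed; a fixed seed makes the whole family
#'   byte-reproducible.
#' @return a list of class \code{"FamilySpec"}.
#' @export
familySpec <- function(
    divergences = c(P01 = 0.002, P03 = 0.005, P04 = 0.01, P05 = 0.02,
                    P06 = 0.03, P07 = 0.04, P08 = 0.05, P09 = 0.06,
                    P10 = 0.07, P11 = 0.08, P12 = 0.015),
    duplicate_pairs = data.frame(a = "P01", b = "P02", divergence = 0),
    type1_members = c("P04", "P07", "P10"),
    solo_ltrs = c(S01 = 0.01, S02 = 0.05),
    hypermutated_members = "P12",
    hyper_rate = 0.3,
    ancestor_len = .ANCESTOR_LEN,
    ltr_len = .LTR_LEN,
    leader_len = .LEADER_LEN,
    gene_len = .GENE_LEN,
    seed = 20150304L) {
  stopifnot(all(divergences >= 0 & divergences <= 1))
  if (nrow(duplicate_pairs)) {
    stopifnot(all(duplicate_pairs$a %in% names(divergences)),
              !any(duplicate_pairs$b %in% names(divergences)),
              all(duplicate_pairs$divergence >= 0))
  }
  all_ids <- c(names(divergences), duplicate_pairs$b)
  bad <- setdiff(c(type1_members, hypermutated_members), all_ids)
  if (length(bad))
    stop("member(s) not in family: ", paste(bad, collapse = ", "))
  structure(list(divergences = divergences,
                 duplicate_pairs = duplicate_pairs,
                 type1_members = type1_members, solo_ltrs = solo_ltrs,
                 hypermutated_members = hypermutated_members,
                 hyper_rate = hyper_rate, ancestor_len = ancestor_len,
                 ltr_len = ltr_len, leader_len = leader_len,
                 gene_len = gene_len, seed = seed),
            class = "FamilySpec")
}

## ancestral layout in element coordinates
.ancestorLayout <- function(spec) {
  ltr <- spec$ltr_len
  leader <- c(ltr + 1L, ltr + spec$leader_len)
  pos <- leader[2]
  genes <- list()
  for (g in names(spec$gene_len)) {
    genes[[g]] <- c(pos + 1L, pos + spec$gene_len[[g]])
    pos <- pos + spec$gene_len[[g]]
  }
  ltr3 <- c(spec$ancestor_len - ltr + 1L, spec$ancestor_len)
  if (pos > ltr3[1] - 1L) stop("gene layout exceeds ancestor length")
  list(ltr5 = c(1L, ltr), leader = leader, genes = genes, ltr3 = ltr3,
       pol_env_boundary = genes$env[1])
}

.layoutGRanges <- function(id, layout, ltr_regions = TRUE) {
  feats <- list()
  add <- function(name, span) {
    feats[[length(feats) + 1L]] <<- data.frame(feature = name,
                                               start = span[1], end = span[2])
  }
  if (ltr_regions) {
    for (off in c(layout$ltr5[1] - 1L, layout$ltr3[1] - 1L)) {
      add("U3", .U3 + off); add("R", .R + off); add("U5", .U5 + off)
    }
  }
  add("leader", layout$leader)
  for (g in names(layout$genes)) add(g, layout$genes[[g]])
  df <- do.call(rbind, feats)
  GRanges(id, IRanges(df$start, df$end), strand = "+", feature = df$feature)
}

## shift/clip feature ranges through a deletion of del_len starting at
## del_start (1-based, inclusive)
.remapDeletion <- function(gr, del_start, del_len) {
  del_end <- del_start + del_len - 1L
  s <- start(gr); e <- end(gr)
  shift <- function(p) ifelse(p > del_end, p - del_len,
                              ifelse(p >= del_start, del_start - 1L, p))
  s2 <- ifelse(s >= del_start & s <= del_end, del_start, shift(s))
  e2 <- shift(e)
  keep <- e2 >= s2 & e2 >= 1L
  GRanges(as.character(seqnames(gr))[keep], IRanges(s2[keep], e2[keep]),
          strand = strand(gr)[keep], feature = gr$feature[keep])
}

#' Generate a synthetic provirus family
#'
#' Builds the ancestor (seeded uniform base sampling with canonical LTR,
#' promoter motifs, intact gene ORFs and identical 5'/3' LTRs), then derives
#' each family member by seeded binomial point substitution. Type-1 members
#' have exactly 292 contiguous bases deleted starting at the annotated
#' pol-env boundary (the env start); solo LTRs are the 5'-LTR U3+R of a
#' virtual donor fused to its 3'-LTR U5, the structure left by
#' LTR-LTR recombination. The gag-leader splice-acceptor dinucleotide (AG at
#' leader positions 1016-1017) is conserved across descendants.
#'
#' @param spec a [familySpec()].
#' @return list with \code{catalogue} (a [Catalogue-class]), \code{ancestry}
#'   (data.frame: id, class, parent, divergence, n_substitutions, type,
#'   hypermutated, ltr_group) and \code{ancestor} (character sequence of the
#'   ancestral provirus, with its layout as attribute \code{"layout"}).
#' @examples
#' fam <- generateFamily(familySpec(seed = 7))
#' fam$catalogue
#' @export
generateFamily <- function(spec = familySpec()) {
  stopifnot(inherits(spec, "FamilySpec"))
  withr::with_seed(spec$seed, .generateFamilyImpl(spec))
}

.generateFamilyImpl <- function(spec) {
  layout <- .ancestorLayout(spec)
  ltr <- .buildCanonicalLTR()
  leader <- .randBases(spec$leader_len)
  genes <- vapply(spec$gene_len, .buildGene, character(1))
  spacer <- .randBases(layout$ltr3[1] - 1L -
                         layout$genes[[length(layout$genes)]][2])
  ancestor <- paste0(ltr, leader, paste(genes, collapse = ""), spacer, ltr)
  ancestor <- .plant(ancestor, .LEADER_AG[1], "AG")
  # in-frame stop at the leader 3' end so the gag ORF starts at gag's own
  # ATG (each later gene is already preceded by its neighbor's stop codon)
  ancestor <- .plant(ancestor, layout$leader[2] - 2L, "TAA")
  stopifnot(nchar(ancestor) == spec$ancestor_len)
  attr(ancestor, "layout") <- layout

  seqs <- character(); anc_rows <- list()
  note <- function(...) anc_rows[[length(anc_rows) + 1L]] <<- data.frame(...)
  descend <- function(parent_seq, d, parent_name) {
    m <- .mutateSeq(parent_seq, d)
    m$seq <- .plant(m$seq, .LEADER_AG[1], "AG")  # conserved splice acceptor
    m
  }
  ltr_group_of <- function(d) {
    if (d <= 0.02) "Hs" else if (d <= 0.05) "5A" else "5B"
  }

  for (id in names(spec$divergences)) {
    d <- spec$divergences[[id]]
    m <- descend(ancestor, d, "ancestor")
    seqs[[id]] <- m$seq
    note(id = id, class = "provirus", parent = "ancestor", divergence = d,
         n_substitutions = m$n_sub,
         type = if (id %in% spec$type1_members) "type1" else "type2",
         hypermutated = id %in% spec$hypermutated_members,
         ltr_group = ltr_group_of(d))
  }
  if (nrow(spec$duplicate_pairs)) {
    for (i in seq_len(nrow(spec$duplicate_pairs))) {
      a <- spec$duplicate_pairs$a[i]; b <- spec$duplicate_pairs$b[i]
      dd <- spec$duplicate_pairs$divergence[i]
      m <- .mutateSeq(seqs[[a]], dd)
      m$seq <- .plant(m$seq, .LEADER_AG[1], "AG")
      seqs[[b]] <- m$seq
      da <- spec$divergences[[a]]
      note(id = b, class = "provirus", parent = a, divergence = da,
           n_substitutions = m$n_sub,
           type = if (b %in% spec$type1_members) "type1" else "type2",
           hypermutated = b %in% spec$hypermutated_members,
           ltr_group = ltr_group_of(da))
    }
  }

  ancestry <- do.call(rbind, anc_rows)
  feats <- list(); lens <- integer()

  # hypermutation, then the engineered type-1 deletion; features remapped
  for (id in names(seqs)) {
    s <- seqs[[id]]
    if (id %in% spec$hypermutated_members) s <- .hypermutate(s, spec$hyper_rate)
    gr <- .layoutGRanges(id, layout)
    if (id %in% spec$type1_members) {
      # 292 bp removed across the pol-env boundary (3' pol + 5' env)
      b <- layout$pol_env_boundary
      del_start <- b - .TYPE1_DEL_LEN %/% 2L
      if (del_start < 1L || del_start + .TYPE1_DEL_LEN - 1L > nchar(s))
        stop("pol-env deletion window extends past sequence for ", id)
      s <- paste0(substr(s, 1L, del_start - 1L),
                  substr(s, del_start + .TYPE1_DEL_LEN, nchar(s)))
      gr <- .remapDeletion(gr, del_start, .TYPE1_DEL_LEN)
    }
    seqs[[id]] <- s
    feats[[id]] <- gr
  }

  # solo LTRs: U3+R of the donor's 5' LTR fused to U5 of its 3' LTR
  for (sid in names(spec$solo_ltrs)) {
    d <- spec$solo_ltrs[[sid]]
    donor <- .mutateSeq(ancestor, d)$seq
    u3r <- substr(donor, .U3[1], .R[2])
    u5 <- substr(donor, layout$ltr3[1] - 1L + .U5[1],
                 layout$ltr3[1] - 1L + .U5[2])
    seqs[[sid]] <- paste0(u3r, u5)
    feats[[sid]] <- GRanges(sid, IRanges(c(.U3[1], .R[1], .U5[1]),
                                         c(.U3[2], .R[2], .U5[2])),
                            strand = "+", feature = c("U3", "R", "U5"))
    ancestry <- rbind(ancestry, data.frame(
      id = sid, class = "solo_ltr", parent = "ancestor", divergence = d,
      n_substitutions = NA_integer_, type = "unknown", hypermutated = FALSE,
      ltr_group = if (d <= 0.02) "Hs" else if (d <= 0.05) "5A" else "5B"))
  }

  info <- DataFrame(id = ancestry$id, class = ancestry$class,
                    ltr_group = ancestry$ltr_group, type = ancestry$type,
                    divergence = ancestry$divergence)
  features <- suppressWarnings(do.call(c, unname(feats)))
  cat <- Catalogue(setNames(unlist(seqs), names(seqs)),
                   elementInfo = info, features = features)
  list(catalogue = cat, ancestry = ancestry, ancestor = ancestor)
}

#' Pol-env boundary reference window
#'
#' Extracts the boundary window (default 600 bp centred on the annotated env
#' start) from a type-2 element or from the family ancestor, for use as the
#' reference in [classifyType()].
#'
#' @param x a [Catalogue-class] or an ancestor sequence returned by
#'   [generateFamily()].
#' @param id element id (when \code{x} is a Catalogue).
#' @param window window length in bp.
#' @return character DNA string of length \code{window}.
#' @export
polEnvBoundaryRef <- function(x, id = NULL, window = 600L) {
  half <- as.integer(window / 2)
  if (is(x, "Catalogue")) {
    .checkElement(x, id)
    sp <- .featureSpan(x, id, "env")
    if (is.null(sp)) stop("element has no env annotation: ", id)
    b <- sp[1]
    as.character(subseq(x@elements[[id]], b - half, b + half - 1L))
  } else {
    layout <- attr(x, "layout")
    b <- layout$pol_env_boundary
    substr(as.character(x), b - half, b + half - 1L)
  }
}
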