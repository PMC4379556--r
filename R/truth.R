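#' Default per-element sample plan
#'
#' Assigns each family element a transcription mechanism consistent with its
#' host context, a cell-sample expression fraction, and a virion packaging
#' efficiency. Packaging efficiency is a free per-element parameter (the
#' biology behind packaging selectivity — plausibly a 5'-leader signal — is
#' not modelled); young (low-divergence) elements default to efficient
#' packaging and old ones to poor packaging, reproducing the observed
#' preference for recently integrated loci in virions.
#'
#' @param cat a [Catalogue-class].
#' @param contexts a [HostContexts-class].
#' @param cell_levels optional named numeric vector of per-element cell
#'   expression fractions (proviruses; renormalised). Default: equal
#'   expression with the two oldest elements boosted (emulating the highly
#'   expressed old 5B locus).
#' @param packaging_eff optional named numeric vector in [0, 1]. Default:
#'   1 for divergence <= 0.02, 0.15 for (0.02, 0.05], 0.01 above, and one
#'   old locus at exactly 0 (never packaged).
#' @return data.frame: \code{element_id}, \code{mechanism},
#'   \code{cell_level}, \code{packaging_eff}.
#' @export
defaultSamplePlan <- function(cat, contexts, cell_levels = NULL,
                              packaging_eff = NULL) {
  info <- cat@elementInfo
  prov <- info[info$class == "provirus", , drop = FALSE]
  scen <- setNames(contexts@info$scenario, contexts@info$element_id)
  mech_of <- function(id) {
    switch(scen[[id]],
           isolated = "ltr_driven",
           divergent_neighbor_gene = "ltr_driven",
           upstream_neighbor_gene = "read_through",
           intronic = "intronic_passenger",
           upstream_fragmentary_ltr = "upstream_ltr_chimeric",
           antisense_neighbor = "antisense")
  }
  if (is.null(cell_levels)) {
    cell_levels <- setNames(rep(1, nrow(prov)), prov$id)
    old <- prov$id[order(-prov$divergence)]
    if (length(old)) cell_levels[old[1]] <- 4  # highly expressed old locus
  }
  cell_levels <- cell_levels / sum(cell_levels)
  if (is.null(packaging_eff)) {
    d <- setNames(prov$divergence, prov$id)
    packaging_eff <- ifelse(d <= 0.02, 1, ifelse(d <= 0.05, 0.15, 0.01))
    zero <- prov$id[order(-prov$divergence)]
    if (length(zero) > 1) packaging_eff[zero[2]] <- 0  # never packaged
    names(packaging_eff) <- prov$id
  }
  data.frame(element_id = prov$id,
             mechanism = vapply(prov$id, mech_of, character(1)),
             cell_level = unname(cell_levels[prov$id]),
             packaging_eff = unname(packaging_eff[prov$id]),
             stringsAsFactors = FALSE)
}

#' Build the ground-truth transcription profile
#'
#' Materialises transcript sequences for a sample plan. LTR-driven
#' transcripts start at the U3-R border (position 793 of the canonical 5'
#' LTR); read-through transcripts run from the upstream neighbor's start
#' through the element; intronic passengers span the whole pre-mRNA record;
#' upstream-LTR chimeras splice the fragment's gag leader (donor after
#' position 1074) into the element's gag leader (acceptor at 1018) across a
#' GT..AG intron; antisense transcripts are the reverse complement of the
#' element plus downstream flank. Divergent neighbor genes contribute their
#' own (minus-strand, upstream) transcripts. Virion fractions reweight the
#' cell profile by packaging efficiency; neighbor/host transcripts are
#' packaged non-specifically at low efficiency.
#'
#' @param cat a [Catalogue-class].
#' @param contexts a [HostContexts-class].
#' @param plan a sample plan as from [defaultSamplePlan()]. Cell levels are
#'   renormalised; a warning is issued when their sum differs from 1 by more
#'   than 1\%.
#' @param neighbor_level cell fraction allotted to each auxiliary neighbor
#'   transcript (before renormalisation).
#' @param neighbor_packaging packaging efficiency for non-element
#'   transcripts (non-specific background packaging).
#' @return a [TruthProfile-class].
#' @export
makeTruthProfile <- function(cat, contexts, plan = defaultSamplePlan(cat, contexts),
                             neighbor_level = 0.02,
                             neighbor_packaging = 0.05) {
  stopifnot(is(cat, "Catalogue"), is(contexts, "HostContexts"))
  .checkElement(cat, plan$element_id)
  if (abs(sum(plan$cell_level) - 1) > 0.01)
    warning("cell levels sum to ", signif(sum(plan$cell_level), 4),
            "; renormalising to 1")
  ref <- referenceSet(cat, contexts)
  scen <- setNames(contexts@info$scenario, contexts@info$element_id)
  tx <- list()
  add <- function(id, elem, mech, strand, exons, seq, cell, pack) {
    tx[[length(tx) + 1L]] <<- list(
      transcript_id = id, element_id = elem, mechanism = mech,
      strand = strand,
      exons = paste(sprintf("%d-%d", exons[, 1], exons[, 2]), collapse = ";"),
      seq = seq, cell = cell, pack = pack)
  }
  for (i in seq_len(nrow(plan))) {
    id <- plan$element_id[i]
    mech <- plan$mechanism[i]
    lvl <- plan$cell_level[i]
    eff <- plan$packaging_eff[i]
    r <- as.character(ref$seqs[[id]])
    off <- ref$offset[[id]]
    len <- ref$core_len[[id]]
    ltr5 <- ltrSpan(cat, id, "5prime")
    tss <- off + ltr5[1] + .TSS_U3R - 1L
    if (mech == "ltr_driven") {
      ex <- cbind(tss, off + len)
      add(paste0(id, ".ltr"), id, mech, "+", ex,
          substr(r, ex[1], ex[2]), lvl, eff)
    } else if (mech == "read_through") {
      nb <- contexts@neighbors[contexts@neighbors$element_id == id, ]
      ex <- cbind(nb$start[1], off + len)
      add(paste0(id, ".rt"), id, mech, "+", ex,
          substr(r, ex[1], ex[2]), lvl, eff)
    } else if (mech == "intronic_passenger") {
      ex <- cbind(1L, nchar(r))
      add(paste0(id, ".pre"), id, mech, "+", ex, r, lvl, eff)
    } else if (mech == "upstream_ltr_chimeric") {
      spl <- contexts@splices[contexts@splices$element_id == id, ]
      ex <- rbind(c(spl$tss[1], spl$donor[1]),
                  c(spl$acceptor[1], off + len))
      seq <- paste0(substr(r, ex[1, 1], ex[1, 2]),
                    substr(r, ex[2, 1], ex[2, 2]))
      add(paste0(id, ".chim"), id, mech, "+", ex, seq, lvl, eff)
    } else if (mech == "antisense") {
      ex <- cbind(off + 1L, nchar(r))
      seq <- as.character(reverseComplement(DNAString(substr(r, ex[1], ex[2]))))
      add(paste0(id, ".as"), id, mech, "-", ex, seq, lvl, eff)
    } else if (mech == "silent") {
      next
    } else stop("unknown mechanism: ", mech)
    # divergent neighbors transcribe their own gene away from the element
    if (!is.na(scen[id]) && scen[id] == "divergent_neighbor_gene") {
      nb <- contexts@neighbors[contexts@neighbors$element_id == id, ]
      ex <- cbind(nb$start[1], nb$end[1])
      seq <- as.character(reverseComplement(DNAString(substr(r, ex[1], ex[2]))))
      add(paste0(id, ".nbr"), id, "neighbor_gene", "-", ex, seq,
          neighbor_level, neighbor_packaging)
    }
  }
  cell <- vapply(tx, `[[`, numeric(1), "cell")
  pack <- vapply(tx, `[[`, numeric(1), "pack")
  cellf <- cell / sum(cell)
  vir <- cellf * pack
  virf <- if (sum(vir) > 0) vir / sum(vir) else vir
  info <- DataFrame(
    transcript_id = vapply(tx, `[[`, character(1), "transcript_id"),
    element_id = vapply(tx, `[[`, character(1), "element_id"),
    mechanism = vapply(tx, `[[`, character(1), "mechanism"),
    strand = vapply(tx, `[[`, character(1), "strand"),
    exons = vapply(tx, `[[`, character(1), "exons"),
    cell_fraction = cellf, virion_fraction = virf)
  seqs <- DNAStringSet(setNames(vapply(tx, `[[`, character(1), "seq"),
                                info$transcript_id))
  new("TruthProfile", transcripts = seqs, info = info)
}

#' Truth profile accessors
#' @param x a [TruthProfile-class]
#' @return \code{truthInfo}: the per-transcript DataFrame;
#'   \code{truthTranscripts}: the transcript DNAStringSet.
#' @export
truthInfo <- function(x) x@info

#' @rdname truthInfo
#' @export
truthTranscripts <- function(x) x@transcripts

#' Expected relative abundance implied by a truth profile
#'
#' Converts molar transcript fractions into the relative-abundance scale the
#' quantifier reports: expected fragment mass is proportional to fraction
#' times transcript length, expected FPKM divides by full element length,
#' and abundance renormalises FPKM over family (provirus) elements to 100.
#'
#' @param truth a [TruthProfile-class].
#' @param cat a [Catalogue-class].
#' @param sample \code{"cell"} or \code{"virion"}.
#' @return named numeric vector of expected abundance (percent) per family
#'   element.
#' @export
expectedAbundance <- function(truth, cat, sample = c("cell", "virion")) {
  sample <- match.arg(sample)
  info <- truth@info
  frac <- if (sample == "cell") info$cell_fraction else info$virion_fraction
  tlen <- width(truth@transcripts)
  fam <- familyIds(cat)
  elen <- setNames(width(cat@elements), names(cat))
  fpkm <- setNames(numeric(length(fam)), fam)
  for (i in seq_along(frac)) {
    e <- info$element_id[i]
    if (!(e %in% fam) || info$mechanism[i] == "neighbor_gene") next
    fpkm[e] <- fpkm[e] + frac[i] * tlen[i] / elen[e]
  }
  100 * fpkm / sum(fpkm)
}
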