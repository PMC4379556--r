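#' Default run configuration
#'
#' All analysis defaults equal the study parameters cited throughout the
#' package: per-mate mismatch budget 2, MAPQ-50 unique filtering, 250-base
#' reads, 20X mappability simulation depth with a 15\% underrepresentation
#' flag, 0.01\% detection floor for packaging comparisons, and 1000
#' bootstrap replicates. Per-stage seeds are derived from the master seed.
#'
#' @param seed master integer seed.
#' @param n_fragments read pairs per sample library.
#' @param bootstrap bootstrap replicates for the LTR tree.
#' @return nested configuration list.
#' @export
demoConfig <- function(seed = 20150304L, n_fragments = 50000L,
                       bootstrap = 1000L) {
  list(
    seed = as.integer(seed),
    family = list(),                      # familySpec() overrides
    scenarios = c(P05 = "divergent_neighbor_gene",
                  P06 = "upstream_neighbor_gene",
                  P08 = "intronic",
                  P11 = "upstream_fragmentary_ltr",
                  P09 = "antisense_neighbor"),
    flank = 2000L,
    reads = list(n_fragments = as.integer(n_fragments), read_len = 250L,
                 error_rate = 0.005),
    trim = list(qual_threshold = 25, min_len = 100L),
    align = list(max_mm = 2L, seed_len = 25L,
                 insert_bounds = c(90L, 600L)),
    quant = list(modes = c("unfiltered_uniform", "unique_only", "em_rescue")),
    mappability = list(depth = 20, read_len = 250L, threshold = 0.15),
    enrichment = list(floor = 0.01, similar_band = c(0.5, 2.0)),
    phylo = list(bootstrap = as.integer(bootstrap)),
    write_sam = TRUE
  )
}

#' Read a YAML run configuration
#'
#' Missing keys fall back to [demoConfig()] defaults.
#' @param path YAML file.
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(demoConfig(), user)
}

.stageSeed <- function(config, stage) {
  offs <- c(family = 11L, contexts = 23L, truth = 37L, cell = 41L,
            virion = 43L, mappability = 53L, phylo = 59L)
  (config$seed + offs[[stage]]) %% .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Executes simulate-family, build-contexts, truth, simulate-reads (cell
#' stranded, virion unstranded), trim, align, quantify (all modes),
#' mappability, annotate (ORFs, type, motifs), mechanism, cell-virion
#' comparison and LTR phylogeny, writing every product as plain text under
#' \code{outdir} plus a \code{manifest.json}. With fixed seeds the output
#' files are byte-identical across runs.
#'
#' @param config configuration list (see [demoConfig()]).
#' @param outdir output directory (created).
#' @return invisibly, a list with the in-memory stage products and the
#'   manifest.
#' @export
runPipeline <- function(config = demoConfig(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  declare <- function(...) files <<- c(files, file.path(outdir, c(...)))
  tsv <- function(df, name) {
    write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
    declare(name)
  }

  message("[family] generating synthetic family")
  spec <- do.call(familySpec, utils::modifyList(
    list(seed = .stageSeed(config, "family")), config$family))
  fam <- generateFamily(spec)
  cat <- fam$catalogue
  writeCatalogue(cat, file.path(outdir, "family.fa"),
                 file.path(outdir, "family.gtf"))
  declare("family.fa", "family.gtf")
  tsv(fam$ancestry, "ancestry.tsv")

  message("[contexts] building host contexts")
  contexts <- buildHostContexts(cat, config$scenarios,
                                seed = .stageSeed(config, "contexts"),
                                flank = config$flank)
  writeXStringSet(contexts@refs, file.path(outdir, "contexts.fa"), width = 60L)
  declare("contexts.fa")
  tsv(as.data.frame(contexts@info), "contexts.tsv")

  message("[truth] building truth profile")
  truth <- makeTruthProfile(cat, contexts)
  tsv(as.data.frame(truth@info), "truth_profile.tsv")

  ref <- referenceSet(cat, contexts)
  index <- buildIndex(ref, seed_len = config$align$seed_len)

  results <- list(catalogue = cat, contexts = contexts, truth = truth)
  expr <- list()
  for (samp in c("cell", "virion")) {
    message("[reads] simulating ", samp, " library")
    params <- if (samp == "cell")
      cellLibraryParams(n_fragments = config$reads$n_fragments,
                        read_len = config$reads$read_len,
                        error_rate = config$reads$error_rate,
                        seed = .stageSeed(config, samp))
    else
      virionLibraryParams(n_fragments = config$reads$n_fragments,
                          read_len = config$reads$read_len,
                          error_rate = config$reads$error_rate,
                          seed = .stageSeed(config, samp))
    lib <- simulateLibrary(truth, samp, params)
    writeLibrary(lib, file.path(outdir, samp))
    declare(paste0(samp, "_1.fq"), paste0(samp, "_2.fq"),
            paste0(samp, "_truth.tsv"))

    message("[trim] trimming ", samp)
    tr <- trimReads(lib, qual_threshold = config$trim$qual_threshold,
                    min_len = config$trim$min_len)
    tsv(tr$report, paste0(samp, "_trim_report.tsv"))
    lib <- tr$library

    message("[align] aligning ", samp)
    aln <- alignPairs(lib, index, max_mm = config$align$max_mm,
                      insert_bounds = config$align$insert_bounds)
    if (isTRUE(config$write_sam)) {
      writeSam(aln, lib, index, file.path(outdir, paste0(samp, ".sam")))
      declare(paste0(samp, ".sam"))
    }
    k <- locationCounts(aln)
    unaligned <- which(k == 0)
    jx <- alignSpliced(lib, ref, which_pairs = unaligned)

    strand_mode <- if (params$stranded) "plus_stranded" else "unstranded"
    message("[quant] quantifying ", samp)
    etabs <- list()
    for (mode in config$quant$modes) {
      ct <- countFragments(aln, index, mode = mode,
                           strand_mode = strand_mode)
      etabs[[mode]] <- computeExpression(ct, cat)
      tsv(etabs[[mode]], sprintf("expression_%s_%s.tsv", samp, mode))
    }
    expr[[samp]] <- etabs
    tsv(compareModes(etabs), sprintf("mode_comparison_%s.tsv", samp))

    message("[mechanism] classifying ", samp)
    profiles <- buildCoverage(aln, index, strand_mode = strand_mode,
                              junctions = jx, unique_only = TRUE)
    mech <- classifyMechanisms(profiles, elements = familyIds(cat))
    tsv(mech, sprintf("mechanism_%s.tsv", samp))
    writeBedGraph(profiles[familyIds(cat)],
                  file.path(outdir, sprintf("coverage_%s.bedgraph", samp)))
    declare(sprintf("coverage_%s.bedgraph", samp))
    results[[samp]] <- list(library = lib, alignments = aln,
                            junctions = jx, expression = etabs,
                            mechanism = mech)
  }

  message("[mappability] simulating")
  mapp <- assessMappability(cat, depth = config$mappability$depth,
                            read_len = config$mappability$read_len,
                            threshold = config$mappability$threshold,
                            seed = .stageSeed(config, "mappability"),
                            max_mm = config$align$max_mm,
                            seed_len = config$align$seed_len)
  tsv(mapp, "mappability.tsv")
  results$mappability <- mapp

  message("[annotate] ORFs, types, motifs")
  orfs <- do.call(rbind, lapply(familyIds(cat), function(id)
    findOrfs(cat, id)))
  tsv(orfs, "orfs.tsv")
  type2 <- cat@elementInfo$id[cat@elementInfo$type == "type2"]
  bref <- polEnvBoundaryRef(cat, type2[1])
  types <- do.call(rbind, lapply(familyIds(cat), function(id) {
    r <- classifyType(cat, bref, id = id)
    data.frame(element_id = id, type = r$type,
               deletion_len = r$deletion_len)
  }))
  tsv(types, "types.tsv")
  motifs <- do.call(rbind, lapply(familyIds(cat), function(id) {
    r <- scanPromoterMotifs(extractLTR(cat, id, "5prime"))
    cbind(element_id = id, r$hits)
  }))
  tsv(motifs, "motifs.tsv")
  orf_alloc <- allocateOrfAbundance(
    expr$cell$unique_only[expr$cell$unique_only$class == "provirus", ], orfs)
  tsv(orf_alloc, "orf_abundance.tsv")
  results$annotation <- list(orfs = orfs, types = types, motifs = motifs,
                             orf_abundance = orf_alloc)

  message("[compare] cell vs virion packaging")
  comp <- compareProfiles(expr$cell$unique_only, expr$virion$unique_only,
                          floor = config$enrichment$floor,
                          similar_band = config$enrichment$similar_band)
  tsv(comp, "packaging_comparison.tsv")
  results$comparison <- comp

  message("[phylo] LTR tree")
  ltrs <- DNAStringSet(vapply(familyIds(cat), function(id)
    as.character(extractLTR(cat, id, "5prime")), character(1)))
  d <- pDistance(ltrs)
  writeDistances(d, file.path(outdir, "ltr_distances.tsv"))
  tree <- bootstrapSupport(ltrs, n = config$phylo$bootstrap,
                           seed = .stageSeed(config, "phylo"))
  writeNewick(tree, file.path(outdir, "ltr_tree.nwk"))
  declare("ltr_distances.tsv", "ltr_tree.nwk")
  results$tree <- tree

  manifest <- list(
    package = "hervloci",
    version = as.character(utils::packageVersion("hervloci")),
    seed = config$seed,
    n_fragments = config$reads$n_fragments,
    files = sort(basename(unique(files))),
    rows = list(elements = length(cat),
                transcripts = length(truth@transcripts),
                cell_pairs_aligned = sum(locationCounts(
                  results$cell$alignments) > 0),
                virion_pairs_aligned = sum(locationCounts(
                  results$virion$alignments) > 0)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
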