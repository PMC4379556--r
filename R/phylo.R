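#' Pairwise p-distance with pairwise deletion
#'
#' Proportion of differing sites among the pairwise-comparable alignment
#' positions: for each pair, sites where either sequence carries a gap or an
#' ambiguous base (N) are deleted, so all available sites are used per
#' comparison. Requires an alignment (equal-length sequences).
#'
#' @param aligned named character vector, DNAStringSet or ape DNAbin of
#'   aligned sequences (>= 2).
#' @return symmetric numeric matrix of p-distances with zero diagonal.
#' @export
pDistance <- function(aligned) {
  bin <- .asDNAbin(aligned)
  if (nrow(bin) < 2) stop("need at least 2 sequences")
  d <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE,
                     as.matrix = TRUE)
  if (any(!is.finite(d)))
    stop("a sequence pair has zero comparable sites")
  d
}

.asDNAbin <- function(x) {
  if (inherits(x, "DNAbin")) return(as.matrix(x))
  s <- if (is.character(x)) x else as.character(x)
  if (length(unique(nchar(s))) != 1)
    stop("sequences are not aligned (unequal lengths)")
  m <- do.call(rbind, strsplit(tolower(s), "", fixed = TRUE))
  rownames(m) <- names(s)
  ape::as.DNAbin(m)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining; negative branch lengths are clamped
#' to zero by default. Branch lengths are in the distance's units (base
#' differences per site for a p-distance matrix).
#'
#' @param d symmetric distance matrix (>= 3 taxa) as from [pDistance()].
#' @param clamp_negative clamp negative branch lengths to 0.
#' @return an ape \code{phylo} (unrooted).
#' @export
neighborJoining <- function(d, clamp_negative = TRUE) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(as.dist(d))
  if (clamp_negative) tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds the
#' p-distance/NJ tree per replicate, and reports for each internal edge of
#' the original tree the percentage of replicates containing the same
#' bipartition (stored in \code{node.label}).
#'
#' @param aligned aligned sequences (as for [pDistance()], >= 3 taxa,
#'   >= 2 columns).
#' @param n number of bootstrap replicates (default 1000); \code{n = 0}
#'   returns the tree with no supports.
#' @param seed integer seed; supports are deterministic given the seed.
#' @return an ape \code{phylo} with percent supports as node labels.
#' @export
bootstrapSupport <- function(aligned, n = 1000L, seed = 1L) {
  bin <- .asDNAbin(aligned)
  ncol_aln <- ncol(bin)
  if (ncol_aln < 2) stop("alignment must have at least 2 columns")
  main <- neighborJoining(pDistance(bin))
  if (n <= 0) {
    main$node.label <- rep(NA_character_, main$Nnode)
    return(main)
  }
  trees <- withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
      rep_bin <- bin[, cols, drop = FALSE]
      d <- ape::dist.dna(rep_bin, model = "raw", pairwise.deletion = TRUE,
                         as.matrix = TRUE)
      d[!is.finite(d)] <- 1  # no comparable sites resampled: maximal distance
      neighborJoining(d)
    })
  })
  counts <- ape::prop.clades(main, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- as.character(round(100 * counts / n, 1))
  main
}

#' Write a tree in Newick format
#' @param tree an ape \code{phylo}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a distance matrix as TSV
#' @param d distance matrix.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeDistances <- function(d, path) {
  df <- data.frame(taxon = rownames(d), as.data.frame(d), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
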