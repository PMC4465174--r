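## Site-bootstrap support for NJ population networks: columns are resampled
## with replacement independently within each locus, the divergence matrix
## and NJ tree recomputed, and internal-edge bipartition frequencies
## attached to the point-estimate tree.

resample_alignment_columns <- function(aln, cols) {
  m <- seq_matrix(aln)[, cols, drop = FALSE]
  seqs <- apply(m, 1, paste, collapse = "")
  locus_alignment(aln$locus_name, aln$ids, seqs)
}

#' NJ tree with site-bootstrap support
#'
#' For each of `B` replicates, alignment columns are resampled with
#' replacement independently within each locus (preserving locus
#' structure), the divergence matrix is recomputed and a NJ tree built.
#' Support for each internal edge of the point-estimate tree is 100 times
#' the fraction of retained replicates whose tree contains the same leaf
#' bipartition. Replicates whose matrix contains an undefined cell (e.g.
#' FST 0/0) are dropped and counted; more than 50% dropped is an error.
#'
#' @inheritParams divergence_matrix
#' @param B number of bootstrap replicates (>= 1; the classic design uses
#'   100).
#' @param seed RNG seed (reproducibility contract).
#' @return the point-estimate `phylo` with `node.label` holding supports
#'   (root and trivial-split nodes empty), plus attributes
#'   `bootstrap_dropped` and `bootstrap_kept`.
#' @export
bootstrap_support <- function(alignments, samples,
                              statistic = c("Dxy", "Da", "FST"),
                              B = 100L, seed = 1L, scope = "combined",
                              haploid_loci = character(),
                              populations = NULL) {
  statistic <- match.arg(statistic)
  if (B < 1L) abort_input("B must be >= 1")
  dm0 <- divergence_matrix(alignments, samples, statistic, scope,
                           haploid_loci, populations)
  if (any(is.na(dm0$values)))
    abort_input("point-estimate matrix has undefined cells")
  tree0 <- neighbor_joining(dm0)
  splits0 <- tree_splits(tree0)
  tally <- setNames(numeric(length(splits0)), splits0)
  loci <- if (identical(scope, "combined")) names(alignments) else scope
  set.seed(seed)
  dropped <- 0L
  for (b in seq_len(B)) {
    res_aln <- alignments
    for (l in loci) {
      L <- alignments[[l]]$length
      res_aln[[l]] <- resample_alignment_columns(alignments[[l]],
                                                 sample.int(L, L, replace = TRUE))
    }
    dm <- tryCatch(divergence_matrix(res_aln, samples, statistic, scope,
                                     haploid_loci, populations),
                   semiperm_error = function(e) NULL)
    if (is.null(dm) || any(is.na(dm$values))) { dropped <- dropped + 1L; next }
    sp <- tree_splits(neighbor_joining(dm))
    hit <- splits0 %in% sp
    tally[hit] <- tally[hit] + 1
  }
  kept <- B - dropped
  if (dropped > B / 2)
    abort_bootstrap(sprintf("%d of %d bootstrap replicates undefined", dropped, B))
  support <- 100 * tally / kept
  # attach as node labels on the point-estimate tree
  n <- length(tree0$tip.label)
  cl <- clade_tips(tree0)
  labs <- character(tree0$Nnode)
  for (k in seq_len(tree0$Nnode)) {
    node <- n + k
    if (node == n + 1L) next  # root of the arbitrary rooting
    tc <- cl[[k]]
    if (length(tc) <= 1L || length(tc) >= n - 1L) next
    labs[k] <- format(support[[canonical_split(tc, tree0$tip.label)]])
  }
  tree0$node.label <- labs
  attr(tree0, "bootstrap_dropped") <- dropped
  attr(tree0, "bootstrap_kept") <- kept
  tree0
}

#' Write a population tree to newick
#'
#' Internal-node support values (when present) are emitted as node labels.
#' The tree is unrooted; the newick rooting is the arbitrary last-join
#' rooting of [neighbor_joining()].
#'
#' @param tree a `phylo`.
#' @param path output path.
#' @export
write_population_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
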