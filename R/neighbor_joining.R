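## Neighbor-joining population networks (Saitou-Nei agglomeration with the
## Q-criterion), with a deterministic tie rule.

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration. Determinism: labels are sorted
#' lexicographically before agglomeration and Q-matrix ties are broken by
#' the lowest (row, column) index pair in the current active ordering
#' (merged nodes are appended last). Negative branch lengths are kept and
#' flagged (attribute `negative_edges`), not zeroed. The returned tree is
#' unrooted (`ape` phylo, rooted arbitrarily at the last join).
#'
#' @param d symmetric numeric matrix with zero diagonal; dimnames are the
#'   population labels. A `divergence_matrix` is also accepted.
#' @return an unrooted `phylo` object with attribute `negative_edges`.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "divergence_matrix")) d <- d$values
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) abort_input("NJ needs >= 2 populations")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("p", seq_len(n))
  if (any(is.na(d)) || any(!is.finite(d)))
    abort_input("distance matrix has NA/NaN/Inf cells")
  if (max(abs(d - t(d))) > 1e-12) abort_input("distance matrix not symmetric")
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  repr <- rownames(d)          # newick fragment per active node
  fmt <- function(x) sprintf("%.17g", x)
  while (nrow(d) > 3L) {
    N <- nrow(d)
    r <- rowSums(d)
    Q <- (N - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    # lowest (row, col) pair among minima
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2))
    lj <- d[i, j] - li
    new_repr <- sprintf("(%s:%s,%s:%s)", repr[i], fmt(li), repr[j], fmt(lj))
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    lbl <- c(rownames(d)[keep], sprintf("u%d", N))
    rownames(d2) <- colnames(d2) <- lbl
    d <- d2
    repr <- c(repr[keep], new_repr)
  }
  nwk <- if (nrow(d) == 2L) {
    sprintf("(%s:%s,%s:%s);", repr[1], fmt(d[1, 2] / 2), repr[2],
            fmt(d[1, 2] / 2))
  } else {
    l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    sprintf("(%s:%s,%s:%s,%s:%s);", repr[1], fmt(l1), repr[2], fmt(l2),
            repr[3], fmt(l3))
  }
  tr <- ape::read.tree(text = nwk)
  attr(tr, "negative_edges") <- sum(tr$edge.length < 0)
  tr
}

## Tip-label sets below each internal node of a phylo.
clade_tips <- function(tree) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  kids <- vector("list", n + nn)
  for (i in seq_len(n)) kids[[i]] <- tree$tip.label[i]
  # edges in postorder so children resolve before parents
  for (e in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[e, 1]; c0 <- tree$edge[e, 2]
    kids[[p]] <- c(kids[[p]], kids[[c0]])
  }
  kids[seq(n + 1L, n + nn)]
}

## Canonical string for the bipartition induced by an internal node's clade:
## orient away from the lexicographically first label.
canonical_split <- function(tips_in_clade, all_tips) {
  anchor <- sort(all_tips)[1]
  side <- if (anchor %in% tips_in_clade) setdiff(all_tips, tips_in_clade)
          else tips_in_clade
  paste(sort(side), collapse = "|")
}

## All internal-edge bipartitions of an unrooted phylo (non-trivial splits).
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  cl <- clade_tips(tree)
  root <- n + 1L
  out <- character()
  for (k in seq_along(cl)) {
    node <- n + k
    if (node == root) next
    tc <- cl[[k]]
    if (length(tc) <= 1L || length(tc) >= n - 1L) next
    out <- c(out, canonical_split(tc, tree$tip.label))
  }
  unique(out)
}
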