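# Independent brute-force oracles: enumerate every column and every sequence
# pair directly. Deliberately naive and kept free of the package's internal
# helpers (only the public alphabet convention is shared).

oracle_cols <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  keep <- logical(ncol(m))
  for (j in seq_len(ncol(m)))
    keep[j] <- all(m[, j] %in% c("A", "C", "G", "T"))
  which(keep)
}

oracle_S <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  s <- 0L
  for (j in oracle_cols(seqs))
    if (length(unique(m[, j])) > 1L) s <- s + 1L
  s
}

oracle_K <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  cols <- oracle_cols(seqs)
  n <- length(seqs)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    tot <- tot + sum(m[i, cols] != m[j, cols])
    np <- np + 1
  }
  tot / np
}

oracle_pi <- function(seqs) {
  L <- length(oracle_cols(seqs))
  if (L == 0) return(0)
  oracle_K(seqs) / L
}

oracle_dxy <- function(sx, sy) {
  seqs <- c(sx, sy)
  m <- do.call(rbind, strsplit(seqs, ""))
  cols <- oracle_cols(seqs)
  if (length(cols) == 0) return(0)
  tot <- 0
  for (i in seq_along(sx)) for (j in seq_along(sy))
    tot <- tot + sum(m[i, cols] != m[length(sx) + j, cols])
  tot / (length(sx) * length(sy)) / length(cols)
}

random_alignment <- function(n, L, p_gap = 0.08, p_n = 0.04) {
  alpha <- c("A", "C", "G", "T", "-", "N")
  probs <- c(rep((1 - p_gap - p_n) / 4, 4), p_gap, p_n)
  vapply(seq_len(n), function(i)
    paste(sample(alpha, L, replace = TRUE, prob = probs), collapse = ""),
    character(1))
}

# exhaustive Spearman permutation p (independent of the package's generator)
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == n), ,
                 drop = FALSE]
  rx <- rank(x); ry <- rank(y)
  obs <- cor(rx, ry)
  rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
  mean(rhos <= obs + 1e-12)
}
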