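## Between-population divergence: Dxy, Da, Hudson's FST, and the pairwise
## divergence matrices (per locus and combined across loci).

## Cross-population mean pairwise difference count and L_eff, complete
## deletion over the union of both sequence sets.
cross_diff <- function(seqs_x, seqs_y) {
  all_seqs <- c(seqs_x, seqs_y)
  cols <- analyzed_columns(all_seqs)
  if (length(cols) == 0L) return(list(mean_diff = 0, L_eff = 0L))
  mx <- seq_matrix(seqs_x)[, cols, drop = FALSE]
  my <- seq_matrix(seqs_y)[, cols, drop = FALSE]
  bx <- base_counts(mx); by <- base_counts(my)
  matches <- bx$A * by$A + bx$C * by$C + bx$G * by$G + bx$T * by$T
  tot <- sum(nrow(mx) * nrow(my) - matches)
  list(mean_diff = tot / (nrow(mx) * nrow(my)), L_eff = length(cols))
}

#' Dxy: mean between-population per-site divergence
#'
#' Mean over all between-population sequence pairs of the per-site mismatch
#' proportion, with analyzed columns (complete deletion) computed over the
#' union of both populations' sequences.
#'
#' @param seqs_x,seqs_y aligned sequence sets of the two populations.
#' @return Dxy per site.
#' @export
dxy <- function(seqs_x, seqs_y) {
  cd <- cross_diff(seqs_x, seqs_y)
  if (cd$L_eff == 0L) {
    warning("no analyzable columns in the pooled pair; Dxy reported as 0")
    return(0)
  }
  cd$mean_diff / cd$L_eff
}

## Within-population pi computed on a fixed column set (the pooled pair's
## analyzed columns), so Da and FST decompose consistently.
pi_on_cols <- function(seqs, cols) {
  if (length(seqs) < 2L || length(cols) == 0L) return(0)
  m <- seq_matrix(seqs)[, cols, drop = FALSE]
  n <- nrow(m)
  npairs <- n * (n - 1) / 2
  bc <- base_counts(m)
  same <- (bc$A * (bc$A - 1) + bc$C * (bc$C - 1) +
           bc$G * (bc$G - 1) + bc$T * (bc$T - 1)) / 2
  (sum(npairs - same) / npairs) / length(cols)
}

#' Da: net between-population divergence
#'
#' `Da = Dxy - (pi_X + pi_Y)/2`, all three terms on the pooled pair's
#' analyzed columns.
#'
#' @inheritParams dxy
#' @return Da per site.
#' @export
da <- function(seqs_x, seqs_y) {
  pair_divergence(seqs_x, seqs_y)$Da
}

#' Hudson's FST
#'
#' `FST = 1 - Hw/Hb` with `Hw = (pi_X + pi_Y)/2` and `Hb = Dxy`. Undefined
#' (returned as `NA`) when `Hb = 0`. Negative estimates are reported
#' unclamped.
#'
#' @inheritParams dxy
#' @return FST (possibly negative), or `NA` when undefined.
#' @export
hudson_fst <- function(seqs_x, seqs_y) {
  pair_divergence(seqs_x, seqs_y)$FST
}

#' All three divergence components for one population pair
#'
#' @inheritParams dxy
#' @return list with `Dxy`, `Da`, `FST`, `Hw`, `L_eff`.
#' @export
pair_divergence <- function(seqs_x, seqs_y) {
  all_seqs <- c(seqs_x, seqs_y)
  cols <- analyzed_columns(all_seqs)
  cd <- cross_diff(seqs_x, seqs_y)
  Dxy <- if (cd$L_eff > 0) cd$mean_diff / cd$L_eff else 0
  Hw <- (pi_on_cols(seqs_x, cols) + pi_on_cols(seqs_y, cols)) / 2
  FST <- if (Dxy > 0) 1 - Hw / Dxy else NA_real_
  list(Dxy = Dxy, Da = Dxy - Hw, FST = FST, Hw = Hw, L_eff = cd$L_eff)
}

#' Pairwise population divergence matrix
#'
#' Fills a symmetric zero-diagonal matrix of the chosen statistic over all
#' unordered population pairs. `scope = "combined"` takes the
#' L_eff-weighted mean of per-locus Dxy/Da; combined FST is recomputed as
#' `1 - Hw/Hb` from the L_eff-weighted Hw and Dxy (ratio of averages).
#'
#' @param alignments named list of `locus_alignment`s.
#' @param samples a `sample_table`.
#' @param statistic one of `"Dxy"`, `"Da"`, `"FST"`.
#' @param scope `"combined"` or one locus name.
#' @param haploid_loci names of haploid loci.
#' @param populations optional data.frame (species, basin) restricting and
#'   ordering the populations; default: all populations with >= 1 copy,
#'   ordered by species then basin.
#' @return a `divergence_matrix`: list with `statistic`, `populations`
#'   (data.frame), `values` (matrix with `species|basin` dimnames), `L_eff`
#'   (per-cell matrix).
#' @export
divergence_matrix <- function(alignments, samples,
                              statistic = c("Dxy", "Da", "FST"),
                              scope = "combined",
                              haploid_loci = character(),
                              populations = NULL) {
  statistic <- match.arg(statistic)
  if (is.null(populations)) {
    populations <- unique(samples$records[c("species", "basin")])
    populations <- populations[order(populations$species, populations$basin), ]
  }
  loci <- if (identical(scope, "combined")) names(alignments) else scope
  if (!all(loci %in% names(alignments)))
    abort_input(sprintf("unknown locus scope: %s", scope))
  np <- nrow(populations)
  if (np < 2L) abort_input("divergence matrix needs >= 2 populations")
  lab <- paste(populations$species, populations$basin, sep = "|")
  vals <- matrix(0, np, np, dimnames = list(lab, lab))
  leff <- matrix(0L, np, np, dimnames = list(lab, lab))
  pop_seqs <- function(l, i)
    population_sequences(alignments[[l]], samples, populations$species[i],
                         populations$basin[i], haploid = l %in% haploid_loci)
  for (i in seq_len(np - 1L)) for (j in seq(i + 1L, np)) {
    num <- 0; hw_num <- 0; wsum <- 0
    for (l in loci) {
      sx <- pop_seqs(l, i); sy <- pop_seqs(l, j)
      if (length(sx) == 0L || length(sy) == 0L) next
      pd <- pair_divergence(sx, sy)
      if (pd$L_eff == 0L) next
      num <- num + pd$Dxy * pd$L_eff
      hw_num <- hw_num + pd$Hw * pd$L_eff
      wsum <- wsum + pd$L_eff
    }
    v <- if (wsum == 0) NA_real_ else {
      Dxy_c <- num / wsum; Hw_c <- hw_num / wsum
      switch(statistic,
             Dxy = Dxy_c,
             Da = Dxy_c - Hw_c,
             FST = if (Dxy_c > 0) 1 - Hw_c / Dxy_c else NA_real_)
    }
    vals[i, j] <- vals[j, i] <- v
    leff[i, j] <- leff[j, i] <- wsum
  }
  structure(list(statistic = statistic, populations = populations,
                 values = vals, L_eff = leff),
            class = "divergence_matrix")
}

#' @export
print.divergence_matrix <- function(x, ...) {
  cat(sprintf("<divergence_matrix> %s, %d populations\n",
              x$statistic, nrow(x$values)))
  print(round(x$values, 5))
  invisible(x)
}

#' Write a divergence matrix as square TSV
#' @param dm a `divergence_matrix` (or plain square matrix).
#' @param path output path.
#' @export
write_divergence_tsv <- function(dm, path) {
  m <- if (inherits(dm, "divergence_matrix")) dm$values else dm
  df <- data.frame(population = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square divergence matrix TSV
#' @param path path written by [write_divergence_tsv()].
#' @return numeric matrix with dimnames.
#' @export
read_divergence_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$population
  storage.mode(m) <- "double"
  m
}

#' Write a PHYLIP-style lower-triangle distance file
#' @param dm a `divergence_matrix` (or plain square matrix).
#' @param path output path.
#' @export
write_phylip_dist <- function(dm, path) {
  m <- if (inherits(dm, "divergence_matrix")) dm$values else dm
  n <- nrow(m)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", n), con)
  for (i in seq_len(n)) {
    row <- if (i == 1) "" else paste(sprintf("%.8f", m[i, seq_len(i - 1)]),
                                     collapse = "  ")
    writeLines(trimws(sprintf("%-12s  %s", rownames(m)[i], row), "right"), con)
  }
  invisible(path)
}
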