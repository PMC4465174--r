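## Sympatric-versus-allopatric polymorphism contrasts: Mann-Whitney U with
## tie-corrected normal approximation and Benjamini-Hochberg FDR across the
## family of polymorphism measures.

#' Mann-Whitney U with tie-corrected normal approximation
#'
#' `U` is the count of (x, y) pairs with x > y (ties counted half), from
#' mid-ranks. `z = (U - n1*n2/2) / sigma_ties` with the tie-corrected
#' standard deviation and no continuity correction; `p_raw` is the
#' two-sided normal P. When every value is tied across both samples the
#' result is the degenerate `z = 0, p = 1` (flagged).
#'
#' @param x,y numeric samples (both non-empty).
#' @return list with `U`, `z`, `p_raw`, `degenerate`.
#' @export
mann_whitney_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) abort_input("both samples must be non-empty")
  N <- n1 + n2
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2    # pairs with x > y (+ half-ties)
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0)
    return(list(U = U, z = 0, p_raw = 1, degenerate = TRUE))
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  list(U = U, z = z, p_raw = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min_{j >= i} m * p_(j) / j`, returned in the input order and
#' capped at 1.
#'
#' @param p numeric vector of raw p-values.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Sympatric-versus-allopatric polymorphism contrast
#'
#' One Mann-Whitney contrast per polymorphism measure (S, Hd, K, pi,
#' theta_W), the unit of analysis being the population and the value its
#' combined-loci statistic; the five raw P values are BH-corrected as one
#' family. `z` is positive when sympatric populations rank higher. The
#' `species` filter restricts the contrast to a species subset (the
#' classic design runs it within one genus).
#'
#' @param stats data.frame from [all_population_stats()] (combined rows are
#'   selected internally).
#' @param sympatry_map a `sympatry_map`.
#' @param species optional character vector of species to include.
#' @return data.frame: `statistic n_symp n_allo U z p_raw q_fdr`.
#' @export
sympatry_polymorphism_contrast <- function(stats, sympatry_map,
                                           species = NULL) {
  df <- stats[stats$locus == "combined", ]
  if (!is.null(species)) df <- df[df$species %in% species, ]
  if (nrow(df) == 0L) abort_input("no combined-loci rows after filtering")
  df$label <- vapply(seq_len(nrow(df)), function(i)
    population_label(sympatry_map, df$species[i], df$basin[i]), character(1))
  n_symp <- sum(df$label == "sympatric")
  n_allo <- sum(df$label == "allopatric")
  if (n_symp < 2L || n_allo < 2L)
    abort_input("each group needs >= 2 populations")
  measures <- c("S", "Hd", "K", "pi", "thetaW")
  rows <- lapply(measures, function(m) {
    mw <- mann_whitney_z(df[[m]][df$label == "sympatric"],
                         df[[m]][df$label == "allopatric"])
    data.frame(statistic = m, n_symp = n_symp, n_allo = n_allo,
               U = mw$U, z = mw$z, p_raw = mw$p_raw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_fdr <- bh_fdr(out$p_raw)
  out
}

#' Write a contrast table as TSV
#' @param contrast data.frame from [sympatry_polymorphism_contrast()].
#' @param path output path.
#' @export
write_contrast_tsv <- function(contrast, path) {
  write.table(contrast, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
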