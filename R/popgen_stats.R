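## popgen_stats: within-population polymorphism and between-population
## divergence from aligned haplotype sequences.

#' Columns analyzable under complete deletion
#'
#' Returns the (1-based) indices of alignment columns in which no sequence in
#' scope carries a gap (`-`) or an ambiguous base (`N`). All site statistics
#' in the package are computed over these columns only, with `L_eff` their
#' count — the "complete deletion" convention.
#'
#' @param seqs character vector of aligned sequences (or a
#'   `locus_alignment`).
#' @return integer vector of 1-based column indices.
#' @export
analyzed_columns <- function(seqs) {
  m <- seq_matrix(seqs)
  which(base_counts(m)$called == nrow(m))
}

## per-column counts of each called base (vectorized; backbone of all the
## site statistics)
base_counts <- function(m) {
  cA <- colSums(m == "A"); cC <- colSums(m == "C")
  cG <- colSums(m == "G"); cT <- colSums(m == "T")
  list(A = cA, C = cC, G = cG, T = cT, called = cA + cC + cG + cT)
}

#' Number of segregating sites
#'
#' Count of analyzed columns (complete deletion) holding two or more
#' distinct bases.
#'
#' @param seqs aligned sequences, n >= 2.
#' @return integer S.
#' @export
segregating_sites <- function(seqs) {
  m <- seq_matrix(seqs)
  if (nrow(m) < 2L) abort_undefined("S requires >= 2 sequences")
  bc <- base_counts(m)
  cols <- bc$called == nrow(m)
  if (!any(cols)) return(0L)
  k <- (bc$A > 0) + (bc$C > 0) + (bc$G > 0) + (bc$T > 0)
  sum(k[cols] > 1L)
}

#' Unbiased haplotype diversity
#'
#' `Hd = n/(n-1) * (1 - sum(p_k^2))` over allele copy counts, with allele
#' identity the allele table's exact-sequence identity (indels included).
#'
#' @param counts integer vector of allele copy counts (n = sum >= 2).
#' @return Hd in `[0, 1]`.
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) abort_undefined("Hd requires n >= 2 gene copies")
  (n / (n - 1)) * (1 - sum((counts / n)^2))
}

#' Mean number of pairwise differences (K)
#'
#' Average over all sequence pairs of the mismatch count across analyzed
#' columns (complete deletion over the set in scope).
#'
#' @param seqs aligned sequences, n >= 2.
#' @return K (in sites, not per site).
#' @export
mean_pairwise_differences <- function(seqs) {
  m <- seq_matrix(seqs)
  n <- nrow(m)
  if (n < 2L) abort_undefined("K requires >= 2 sequences")
  bc <- base_counts(m)
  cols <- bc$called == n
  if (!any(cols)) return(0)
  npairs <- n * (n - 1) / 2
  # per column: mismatching pairs = C(n,2) - sum_b C(c_b,2)
  same <- (bc$A * (bc$A - 1) + bc$C * (bc$C - 1) +
           bc$G * (bc$G - 1) + bc$T * (bc$T - 1)) / 2
  sum(npairs - same[cols]) / npairs
}

#' Per-site nucleotide diversity (pi)
#'
#' `pi = K / L_eff`; returns 0 with a warning when no column survives
#' complete deletion.
#'
#' @param seqs aligned sequences, n >= 2.
#' @return pi per analyzed site.
#' @export
nucleotide_diversity <- function(seqs) {
  cols <- analyzed_columns(seqs)
  if (length(cols) == 0L) {
    warning("no analyzable columns (L_eff = 0); pi reported as 0")
    return(0)
  }
  mean_pairwise_differences(seqs) / length(cols)
}

#' Watterson's theta per site
#'
#' `theta_W = S / (a_{n-1} * L_eff)` with `a_{n-1} = sum_{i=1}^{n-1} 1/i`.
#'
#' @param S segregating sites.
#' @param n gene copies (>= 2).
#' @param L_eff analyzed columns (> 0).
#' @return theta_W per site.
#' @export
watterson_theta <- function(S, n, L_eff) {
  if (n < 2) abort_undefined("theta_W requires n >= 2")
  if (L_eff <= 0) abort_undefined("theta_W requires L_eff > 0")
  S / (harmonic_number(n - 1) * L_eff)
}

#' Harmonic number a_n = sum_{i=1}^{n} 1/i
#' @param n non-negative integer.
#' @return a_n (0 for n = 0).
#' @export
harmonic_number <- function(n) if (n < 1) 0 else sum(1 / seq_len(n))

## Full per-population stats at one locus from a sequence set.
locus_pop_stats <- function(seqs, locus_name, species, basin) {
  n <- length(seqs)
  cols <- analyzed_columns(seqs)
  L_eff <- length(cols)
  if (n < 2L) {
    return(data.frame(species = species, basin = basin, locus = locus_name,
                      n = n, S = NA_integer_, Hd = NA_real_, K = NA_real_,
                      pi = NA_real_, thetaW = NA_real_, L_eff = L_eff,
                      stringsAsFactors = FALSE))
  }
  S <- segregating_sites(seqs)
  K <- mean_pairwise_differences(seqs)
  counts <- table(match(seqs, unique(seqs)))
  Hd <- haplotype_diversity(as.integer(counts))
  pi <- if (L_eff > 0) K / L_eff else 0
  th <- if (L_eff > 0) watterson_theta(S, n, L_eff) else 0
  data.frame(species = species, basin = basin, locus = locus_name,
             n = n, S = as.integer(S), Hd = Hd, K = K, pi = pi, thetaW = th,
             L_eff = L_eff, stringsAsFactors = FALSE)
}

#' Polymorphism statistics for one population, per locus and combined
#'
#' Per-locus rows report S, Hd, K, pi and theta_W for the (species, basin)
#' population; the `combined` row sums S and K over loci, takes the
#' L_eff-weighted mean of pi and theta_W, the unweighted mean of Hd
#' (`hd_mode = "mean"`, the default) or the haplotype diversity of
#' per-sample concatenated multilocus haplotypes (`hd_mode = "concat"`),
#' and reports n as the maximum per-locus gene-copy count.
#'
#' @param alignments named list of `locus_alignment` objects.
#' @param samples a `sample_table`.
#' @param species,basin population coordinates.
#' @param haploid_loci character vector naming haploid loci (mtDNA).
#' @param combine add the combined row (default `TRUE`).
#' @param hd_mode `"mean"` or `"concat"` combined-Hd rule.
#' @return data.frame, one row per locus (plus `combined`).
#' @export
population_stats <- function(alignments, samples, species, basin,
                             haploid_loci = character(), combine = TRUE,
                             hd_mode = c("mean", "concat")) {
  hd_mode <- match.arg(hd_mode)
  rows <- list()
  for (nm in names(alignments)) {
    seqs <- population_sequences(alignments[[nm]], samples, species, basin,
                                 haploid = nm %in% haploid_loci)
    if (length(seqs) == 0L) next
    rows[[nm]] <- locus_pop_stats(seqs, nm, species, basin)
  }
  if (length(rows) == 0L)
    abort_input(sprintf("population (%s, %s) absent from data", species, basin))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (combine) {
    ok <- !is.na(out$S)
    if (any(ok)) {
      w <- out$L_eff[ok]
      hd <- if (hd_mode == "mean") mean(out$Hd[ok]) else
        concat_hd(alignments[names(rows)[ok]], samples, species, basin,
                  haploid_loci)
      comb <- data.frame(
        species = species, basin = basin, locus = "combined",
        n = max(out$n[ok]), S = sum(out$S[ok]), Hd = hd, K = sum(out$K[ok]),
        pi = if (sum(w) > 0) sum(out$pi[ok] * w) / sum(w) else 0,
        thetaW = if (sum(w) > 0) sum(out$thetaW[ok] * w) / sum(w) else 0,
        L_eff = sum(w), stringsAsFactors = FALSE)
      out <- rbind(out, comb)
    }
  }
  out
}

## Multilocus concatenated-haplotype Hd: copy a of each sample concatenated
## across loci, likewise copy b; defined only when every locus has both
## copies of every sample in the population.
concat_hd <- function(alignments, samples, species, basin, haploid_loci) {
  parts <- list()
  for (nm in names(alignments)) {
    res <- resolve_haplotypes(alignments[[nm]]$ids, samples,
                              haploid = nm %in% haploid_loci)
    keep <- res$species == species & res$basin == basin
    res <- res[keep, ]
    key <- paste(res$sample_id, res$copy_index, sep = "|")
    parts[[nm]] <- setNames(alignments[[nm]]$seqs[res$haplotype_id], key)
  }
  common <- Reduce(intersect, lapply(parts, names))
  if (length(common) < 2)
    abort_undefined("concat Hd needs >= 2 multilocus haplotypes present at all loci")
  cat_seqs <- vapply(common, function(k)
    paste(vapply(parts, `[[`, character(1), k), collapse = ""), character(1))
  counts <- table(match(cat_seqs, unique(cat_seqs)))
  haplotype_diversity(as.integer(counts))
}

#' Population stats table for all populations (Table-4 style)
#'
#' @inheritParams population_stats
#' @return data.frame with per-locus and combined rows for every
#'   (species, basin) population present in the metadata.
#' @export
all_population_stats <- function(alignments, samples,
                                 haploid_loci = character(),
                                 hd_mode = c("mean", "concat")) {
  hd_mode <- match.arg(hd_mode)
  pops <- unique(samples$records[c("species", "basin")])
  out <- lapply(seq_len(nrow(pops)), function(i)
    tryCatch(population_stats(alignments, samples, pops$species[i],
                              pops$basin[i], haploid_loci, TRUE, hd_mode),
             semiperm_input_error = function(e) NULL))
  do.call(rbind, out)
}

#' Write the stats table as TSV
#'
#' Columns `species basin locus No S Hd K pi thetaW L_eff` (the `No` column
#' is the gene-copy count n).
#'
#' @param stats data.frame from [all_population_stats()].
#' @param path output path.
#' @export
write_stats_tsv <- function(stats, path) {
  out <- stats
  names(out)[names(out) == "n"] <- "No"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
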