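## Diagnostic-allele introgression classifier and the
## introgression-versus-divergence trend test.
##
## Rule: an allele carried by species A's sympatric population in a contact
## basin is called introgressed from species B when it is (i) absent from
## every allopatric population of A and (ii) present in any population of B.
## Ancestral polymorphism cannot then explain the sharing, because the
## allele would be expected in A's allopatric reference too.

#' Classify diagnostic (introgressed) alleles for one species pair
#'
#' Applies the diagnostic-allele rule in both directions (B into A and A
#' into B) for every non-excluded locus, restricted to the pair's sympatric
#' populations in `basin`. Every emitted call records the three presence
#' facts behind the decision.
#'
#' @param species_a,species_b the hybridizing pair.
#' @param basin contact basin (the pair must be sympatric there).
#' @param allele_tables named list of `allele_table`s (nuclear loci; an
#'   mtDNA table may be included for descriptive output but see
#'   [introgression_proportion()]).
#' @param sympatry_map a `sympatry_map`.
#' @param exclusions data.frame from [exclude_loci_for_pair()] (or `NULL`).
#' @return data.frame of calls: `basin species_a species_b direction locus
#'   allele_id copies present_in_recipient_allopatric presence_in_donor`.
#' @export
classify_diagnostic_alleles <- function(species_a, species_b, basin,
                                        allele_tables, sympatry_map,
                                        exclusions = NULL) {
  if (!pair_sympatric(sympatry_map, species_a, species_b, basin))
    abort_usage(sprintf("pair (%s, %s) is not sympatric in basin %s",
                        species_a, species_b, basin))
  excluded <- if (is.null(exclusions)) character() else exclusions$locus
  lab <- sympatry_map$labels
  allo_pops <- function(sp) lab[lab$species == sp & lab$label == "allopatric", ]
  calls <- list()
  for (locus in setdiff(names(allele_tables), excluded)) {
    tab <- allele_tables[[locus]]
    for (dir in list(c(species_a, species_b), c(species_b, species_a))) {
      recipient <- dir[1]; donor <- dir[2]
      allo <- allo_pops(recipient)
      if (nrow(allo) == 0L)
        abort_unresolved_ancestry(sprintf(
          paste0("species %s has no allopatric reference population and ",
                 "locus %s is not excluded; apply the locus-exclusion rule"),
          recipient, locus))
      symp_counts <- allele_counts(tab, recipient, basin)
      if (length(symp_counts) == 0L) next
      cnt <- tab$counts
      for (aid in names(symp_counts)) {
        in_allo <- any(vapply(seq_len(nrow(allo)), function(k)
          aid %in% cnt$allele_id[cnt$species == allo$species[k] &
                                 cnt$basin == allo$basin[k]], logical(1)))
        donor_rows <- cnt[cnt$allele_id == aid & cnt$species == donor, ]
        if (in_allo || nrow(donor_rows) == 0L) next
        donor_labels <- vapply(seq_len(nrow(donor_rows)), function(k)
          population_label(sympatry_map, donor, donor_rows$basin[k]),
          character(1))
        presence <- if (all(c("sympatric", "allopatric") %in% donor_labels))
          "both" else donor_labels[1]
        calls[[length(calls) + 1L]] <- data.frame(
          basin = basin, species_a = species_a, species_b = species_b,
          direction = sprintf("%s->%s", donor, recipient), locus = locus,
          allele_id = aid, copies = unname(symp_counts[aid]),
          present_in_recipient_allopatric = FALSE,
          presence_in_donor = presence, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(calls) == 0L)
    return(data.frame(basin = character(), species_a = character(),
                      species_b = character(), direction = character(),
                      locus = character(), allele_id = character(),
                      copies = integer(),
                      present_in_recipient_allopatric = logical(),
                      presence_in_donor = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, calls)
}

#' Locus exclusions for a species pair
#'
#' A locus is auto-excluded for a pair when either member (i) has no
#' allopatric population in the dataset and (ii) is monomorphic (one
#' distinct allele species-wide) at that locus: with no allopatric
#' reference, introgression-with-replacement cannot be distinguished from
#' retained ancestral polymorphism, so the locus is conservatively dropped.
#' Manual exclusions are always honored and logged with reason `"manual"`.
#'
#' @inheritParams classify_diagnostic_alleles
#' @param manual character vector of locus names to exclude by hand.
#' @return data.frame with columns `locus`, `reason` (zero rows when none).
#' @export
exclude_loci_for_pair <- function(species_a, species_b, allele_tables,
                                  sympatry_map, manual = character()) {
  lab <- sympatry_map$labels
  out <- list()
  for (locus in names(allele_tables)) {
    if (locus %in% manual) {
      out[[length(out) + 1L]] <- data.frame(locus = locus, reason = "manual",
                                            stringsAsFactors = FALSE)
      next
    }
    cnt <- allele_tables[[locus]]$counts
    for (sp in c(species_a, species_b)) {
      has_allo <- any(lab$species == sp & lab$label == "allopatric")
      n_alleles <- length(unique(cnt$allele_id[cnt$species == sp]))
      if (!has_allo && n_alleles == 1L) {
        out[[length(out) + 1L]] <- data.frame(
          locus = locus,
          reason = sprintf("no allopatric reference for %s and monomorphic", sp),
          stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(locus = character(), reason = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Per-pair introgression proportion
#'
#' Pools both directions. With `mode = "copies"` (default) the numerator is
#' the summed copy count over calls in the pair's sympatric populations and
#' the denominator the total gene copies sampled in both species' sympatric
#' populations in the basin across included loci; `mode = "alleles"` counts
#' distinct alleles instead. Excluded loci contribute to neither side.
#' Haploid/mtDNA loci should be left out of `allele_tables` here (the
#' trend analysis concerns nuclear alleles).
#'
#' @inheritParams classify_diagnostic_alleles
#' @param calls data.frame from [classify_diagnostic_alleles()].
#' @param mode `"copies"` or `"alleles"`.
#' @param divergence optional externally supplied pair divergence (mtDNA
#'   p-distance), carried through to the summary.
#' @return one-row data.frame: `species_a species_b basin proportion
#'   introgressed total divergence loci_included loci_excluded`.
#' @export
introgression_proportion <- function(species_a, species_b, basin, calls,
                                     allele_tables, exclusions = NULL,
                                     mode = c("copies", "alleles"),
                                     divergence = NA_real_) {
  mode <- match.arg(mode)
  excluded <- if (is.null(exclusions)) character() else exclusions$locus
  loci <- setdiff(names(allele_tables), excluded)
  if (length(loci) == 0L) abort_input("all loci excluded for this pair")
  total <- 0L
  for (locus in loci) for (sp in c(species_a, species_b)) {
    cc <- allele_counts(allele_tables[[locus]], sp, basin)
    total <- total + if (mode == "copies") sum(cc) else length(cc)
  }
  if (total == 0L)
    abort_input(sprintf("no sympatric gene copies sampled for (%s, %s) in %s",
                        species_a, species_b, basin))
  keep <- calls$locus %in% loci
  introgressed <- if (mode == "copies") sum(calls$copies[keep]) else sum(keep)
  data.frame(species_a = species_a, species_b = species_b, basin = basin,
             proportion = introgressed / total,
             introgressed = as.integer(introgressed), total = as.integer(total),
             divergence = divergence,
             loci_included = paste(loci, collapse = ","),
             loci_excluded = paste(excluded, collapse = ","),
             stringsAsFactors = FALSE)
}

## All permutations of 1..n (lexicographic), as an n! x n matrix.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' Introgression-versus-divergence trend test
#'
#' Spearman rank correlation of per-pair introgression proportion against
#' externally supplied pair divergence, with a one-sided exact permutation
#' P under the negative-association alternative:
#' `p_exact = #\{permutations with rho_perm <= rho_observed\} / n!`,
#' enumerating all `n!` permutations of one variable's ranks (mid-ranks
#' under ties). `r2` is the squared Pearson correlation of the raw values.
#'
#' @param proportions per-pair introgression proportions (length 3..10).
#' @param divergences matching divergence values (e.g. mtDNA p-distance),
#'   never recomputed from the analyzed loci.
#' @return list with `n_pairs`, `rho`, `p_exact`, `r2`.
#' @export
introgression_divergence_trend <- function(proportions, divergences) {
  n <- length(proportions)
  if (length(divergences) != n) abort_input("length mismatch")
  if (n < 3L) abort_input("trend test needs >= 3 pairs")
  if (n > 10L)
    abort_input("exact permutation path refused for n > 10 pairs")
  if (any(is.na(proportions)) || any(is.na(divergences)))
    abort_input("NA in trend inputs")
  rx <- rank(divergences); ry <- rank(proportions)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    abort_undefined("trend undefined: all-tied ranks")
  rho <- cor(rx, ry)
  perms <- all_permutations(n)
  # rho for each permutation of ry against fixed rx (Pearson on ranks)
  ry_perm <- matrix(ry[perms], nrow(perms))
  rho_perm <- as.vector(
    (ry_perm %*% (rx - mean(rx))) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry)))
  p_exact <- mean(rho_perm <= rho + 1e-12)
  r2 <- cor(divergences, proportions)^2
  list(n_pairs = n, rho = rho, p_exact = p_exact, r2 = r2)
}

#' Read a pairwise species-divergence table
#'
#' TSV with columns `species_a species_b p_distance`, the
#' introgression-independent divergence axis (typically mtDNA uncorrected
#' p-distance from an external source).
#'
#' @param path path to the TSV.
#' @return data.frame.
#' @export
read_divergence_pairs_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  req <- c("species_a", "species_b", "p_distance")
  if (!all(req %in% names(df)))
    abort_schema("divergence table needs columns species_a, species_b, p_distance")
  df
}

#' Look up a pair's divergence in a divergence table (order-free)
#' @param div_table data.frame from [read_divergence_pairs_tsv()].
#' @param species_a,species_b the pair.
#' @return numeric p-distance.
#' @export
pair_divergence_value <- function(div_table, species_a, species_b) {
  hit <- (div_table$species_a == species_a & div_table$species_b == species_b) |
         (div_table$species_a == species_b & div_table$species_b == species_a)
  if (!any(hit))
    abort_input(sprintf("pair (%s, %s) absent from divergence table",
                        species_a, species_b))
  div_table$p_distance[which(hit)[1]]
}
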