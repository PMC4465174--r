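## Four-pair secondary-contact panel: the simulation-to-classifier loop
## used to validate the introgression-versus-divergence trend machinery.

#' Introgression proportion for one simulated pair dataset
#'
#' Runs the full classifier path on a `sim_dataset` holding one
#' hybridizing pair: allele collapsing, sympatry map, locus exclusions,
#' diagnostic-allele calls, and the pooled-direction proportion over the
#' nuclear loci. Divergence is taken from the dataset's reference-locus
#' table.
#'
#' @param sim a `sim_dataset` from [simulate_dataset()] with exactly one
#'   contact event.
#' @param mode proportion denominator mode (see
#'   [introgression_proportion()]).
#' @return one-row pair summary data.frame.
#' @export
pair_summary_from_sim <- function(sim, mode = "copies") {
  ce <- sim$config$contact_events
  if (nrow(ce) != 1L) abort_input("expected a single-pair dataset")
  a <- ce$species_a; b <- ce$species_b; basin <- ce$basin
  ref_name <- sim$config$reference_locus$name %||% ""
  nuclear <- setdiff(names(sim$alignments), c(ref_name, sim$haploid_loci))
  tabs <- lapply(sim$alignments[nuclear], collapse_alleles, sim$samples)
  map <- build_sympatry_map(sim$samples)
  excl <- exclude_loci_for_pair(a, b, tabs, map)
  calls <- classify_diagnostic_alleles(a, b, basin, tabs, map, excl)
  divv <- pair_divergence_value(sim$divergence, a, b)
  introgression_proportion(a, b, basin, calls, tabs, excl, mode = mode,
                           divergence = divv)
}

#' Simulate a panel of hybridizing pairs with graded permeability
#'
#' One independent two-species secondary-contact dataset per pair, with
#' effective contact migration `Ms[i]` and species split time
#' `split_times[i]` (migration decreasing as divergence increases models
#' the gradual closing of a semi-permeable boundary). Per-pair seeds are
#' drawn from the RNG stream seeded by `seed`.
#'
#' @param Ms scaled contact migration per pair.
#' @param split_times species divergence times per pair (same length).
#' @param seed RNG seed.
#' @param ... passed to [config_species_pair()] (sample sizes, loci).
#' @return data.frame of pair summaries (one row per pair) with the
#'   reference-locus divergence attached.
#' @export
simulate_pair_panel <- function(Ms = c(2, 1, 0.3, 0.05),
                                split_times = c(2, 6, 12, 20),
                                seed = 1L, ...) {
  if (length(Ms) != length(split_times)) abort_input("length mismatch")
  set.seed(seed)
  pair_seeds <- sample.int(.Machine$integer.max - 1L, length(Ms))
  out <- lapply(seq_along(Ms), function(i) {
    cfg <- config_species_pair(M = Ms[i], split_time = split_times[i],
                               species = c(sprintf("sp%da", i),
                                           sprintf("sp%db", i)),
                               seed = pair_seeds[i], ...)
    pair_summary_from_sim(simulate_dataset(cfg))
  })
  do.call(rbind, out)
}

#' Trend recovery over replicate panels
#'
#' Repeats [simulate_pair_panel()] `n_rep` times and runs the
#' introgression-versus-divergence trend test on each replicate's four
#' (proportion, divergence) pairs.
#'
#' @param n_rep number of replicate panels.
#' @param seed RNG seed (replicate seeds drawn from it).
#' @inheritParams simulate_pair_panel
#' @return data.frame with one row per replicate: `rep`, `rho`, `p_exact`,
#'   `r2`.
#' @export
trend_recovery <- function(n_rep = 20L, seed = 1L,
                           Ms = c(2, 1, 0.3, 0.05),
                           split_times = c(2, 6, 12, 20), ...) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_rep)
  rows <- lapply(seq_len(n_rep), function(r) {
    panel <- simulate_pair_panel(Ms, split_times, seed = rep_seeds[r], ...)
    tr <- introgression_divergence_trend(panel$proportion, panel$divergence)
    data.frame(rep = r, rho = tr$rho, p_exact = tr$p_exact, r2 = tr$r2)
  })
  do.call(rbind, rows)
}
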