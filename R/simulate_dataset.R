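## Simulation configs and full synthetic datasets: phased FASTA per locus,
## sample metadata, an introgression-independent divergence table from a
## dedicated zero-migration reference locus, and truth tables.

#' Build and validate a simulation config
#'
#' Fields mirror the isolation-with-migration world: a species tree with
#' split times (coalescent units of 2*N0 generations), demes as
#' (species, basin) with relative sizes, secondary-contact events carrying
#' scaled migration M = 4*N0*m, loci with theta = 4*N0*mu*length, ploidy
#' and a permeability scalar s (effective per-locus migration is M*s), and
#' diploid sample counts per deme. Haploid loci use size multiplier 0.25
#' (mtDNA convention). Within-species demes merge into the species' first
#' listed deme at `within_species_merge_time`.
#'
#' @param species_tree data.frame: `species`, `parent` (NA for the root),
#'   `split_time` (NA for the root).
#' @param demes data.frame: `species`, `basin`, `relative_size`.
#' @param contact_events data.frame: `species_a`, `species_b`, `basin`,
#'   `start_time` (contact spans `[0, start_time]` looking backward), `M`.
#' @param loci data.frame: `name`, `length`, `theta`, `ploidy`
#'   (`"diploid"`/`"haploid"`), `s`.
#' @param samples_per_deme diploid individuals sampled per deme.
#' @param within_species_merge_time when same-species demes merge
#'   (backward), strictly before any species split.
#' @param reference_locus list(`name`, `length`, `theta`) for the
#'   zero-migration divergence-axis locus (NULL to skip).
#' @param seed mandatory RNG seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(species_tree, demes, contact_events, loci,
                       samples_per_deme = 10L,
                       within_species_merge_time = 0.75,
                       reference_locus = list(name = "ref", length = 1000L,
                                              theta = 5),
                       seed) {
  if (missing(seed)) abort_config("seed is mandatory")
  st <- species_tree
  if (sum(is.na(st$parent)) != 1L)
    abort_config("species tree needs exactly one root (parent = NA)")
  splits <- st$split_time[!is.na(st$parent)]
  if (any(splits <= 0)) abort_config("split times must be positive")
  for (i in which(!is.na(st$parent))) {
    p <- match(st$parent[i], st$species)
    if (is.na(p)) abort_config(sprintf("unknown parent %s", st$parent[i]))
    if (!is.na(st$split_time[p]) && st$split_time[i] >= st$split_time[p])
      abort_config("child split_time must precede its parent's")
  }
  if (!all(demes$species %in% st$species))
    abort_config("deme species absent from species tree")
  if (any(demes$relative_size <= 0)) abort_config("deme sizes must be positive")
  if (length(splits) && within_species_merge_time >= min(splits))
    abort_config("within_species_merge_time must precede all species splits")
  ce <- contact_events
  if (nrow(ce)) {
    for (i in seq_len(nrow(ce))) {
      for (sp in c(ce$species_a[i], ce$species_b[i]))
        if (!any(demes$species == sp & demes$basin == ce$basin[i]))
          abort_config(sprintf("contact names missing deme (%s, %s)",
                               sp, ce$basin[i]))
      if (ce$start_time[i] >= min(splits))
        abort_config("contact start_time must precede the species splits")
    }
  }
  if (!all(loci$ploidy %in% c("diploid", "haploid")))
    abort_config("locus ploidy must be diploid or haploid")
  if (any(loci$s < 0)) abort_config("permeability s must be >= 0")
  structure(list(species_tree = st, demes = demes, contact_events = ce,
                 loci = loci, samples_per_deme = as.integer(samples_per_deme),
                 within_species_merge_time = within_species_merge_time,
                 reference_locus = reference_locus, seed = as.integer(seed)),
            class = "sim_config")
}

#' Read / write a simulation config (JSON)
#'
#' @param path JSON file mirroring the [sim_config()] fields.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config not found: %s", path))
  x <- jsonlite::fromJSON(path)
  if (is.null(x$seed)) abort_config("config must carry a seed")
  sim_config(as.data.frame(x$species_tree), as.data.frame(x$demes),
             as.data.frame(x$contact_events), as.data.frame(x$loci),
             x$samples_per_deme %||% 10L,
             x$within_species_merge_time %||% 0.75,
             x$reference_locus, x$seed)
}

#' @rdname read_sim_config
#' @param config a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## deme id and per-species primary (first listed) deme
deme_id <- function(species, basin) paste(species, basin, sep = "@")

sim_world <- function(config) {
  d <- config$demes
  d$id <- deme_id(d$species, d$basin)
  primary <- tapply(d$id, d$species, `[`, 1L)
  merges <- list()
  for (sp in unique(d$species)) {
    extra <- d$id[d$species == sp & d$id != primary[[sp]]]
    for (e in extra)
      merges[[length(merges) + 1L]] <- data.frame(
        time = config$within_species_merge_time, from = e, to = primary[[sp]])
  }
  st <- config$species_tree
  for (i in which(!is.na(st$parent)))
    merges[[length(merges) + 1L]] <- data.frame(
      time = st$split_time[i], from = primary[[st$species[i]]],
      to = primary[[st$parent[i]]])
  merges <- if (length(merges)) do.call(rbind, merges) else NULL
  list(demes = d, merges = merges)
}

## species divergence time from the species tree (time to MRCA)
species_divergence_time <- function(st, a, b) {
  anc_path <- function(sp) {
    out <- data.frame(species = sp, time = 0)
    while (!is.na(st$parent[match(sp, st$species)])) {
      i <- match(sp, st$species)
      out <- rbind(out, data.frame(species = st$parent[i],
                                   time = st$split_time[i]))
      sp <- st$parent[i]
    }
    out
  }
  pa <- anc_path(a); pb <- anc_path(b)
  shared <- intersect(pa$species, pb$species)
  if (!length(shared)) abort_config("species do not share an ancestor")
  min(pmax(pa$time[match(shared, pa$species)],
           pb$time[match(shared, pb$species)]))
}

#' Simulate a full multilocus dataset
#'
#' Generates, per locus, a structured-coalescent genealogy and
#' infinite-sites sequences for all sampled demes; haplotype IDs follow the
#' package's phased-FASTA dialect (`<sample>_a`/`_b` nuclear, bare ID
#' haploid). The divergence table is computed from the dedicated
#' zero-migration reference locus as the mean uncorrected p-distance
#' between species, emulating an introgression-independent external
#' divergence axis. Loci are independent given the demography. Identical
#' (config, seed) gives byte-identical output.
#'
#' @param config a `sim_config`.
#' @return a `sim_dataset`: list with `alignments` (named list of
#'   `locus_alignment`), `samples` (`sample_table`), `haploid_loci`,
#'   `divergence` (data.frame species_a/species_b/p_distance),
#'   `truth_tips` (per-locus migrant flags), `truth_pairs` (per-pair
#'   fraction of cross-species coalescences postdating contact), `config`.
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  w <- sim_world(config)
  d <- w$demes
  ns <- config$samples_per_deme
  d$n <- ns
  samp <- do.call(rbind, lapply(seq_len(nrow(d)), function(i)
    data.frame(sample_id = sprintf("%s_%s_%02d", d$species[i], d$basin[i],
                                   seq_len(ns)),
               species = d$species[i], basin = d$basin[i],
               river = d$basin[i], region = "simulated",
               stringsAsFactors = FALSE)))
  samples <- sample_table(samp)
  ce <- config$contact_events
  loci <- config$loci
  if (!is.null(config$reference_locus))
    loci <- rbind(loci, data.frame(name = config$reference_locus$name,
                                   length = config$reference_locus$length,
                                   theta = config$reference_locus$theta,
                                   ploidy = "diploid", s = 0))
  alignments <- list()
  truth_tips <- list()
  truth_pairs <- list()
  for (li in seq_len(nrow(loci))) {
    loc <- loci[li, ]
    haploid <- loc$ploidy == "haploid"
    sizes <- setNames(d$relative_size * if (haploid) 0.25 else 1, d$id)
    tips <- character(); tip_sp <- character()
    for (i in seq_len(nrow(d))) {
      sid <- samp$sample_id[samp$species == d$species[i] &
                            samp$basin == d$basin[i]]
      ids <- if (haploid) sid else
        as.vector(rbind(paste0(sid, "_a"), paste0(sid, "_b")))
      tips <- c(tips, setNames(rep(d$id[i], length(ids)), ids))
      tip_sp <- c(tip_sp, rep(d$species[i], length(ids)))
    }
    contacts <- if (nrow(ce)) data.frame(
      deme_a = deme_id(ce$species_a, ce$basin),
      deme_b = deme_id(ce$species_b, ce$basin),
      end_time = ce$start_time,
      rate_per_lineage = ce$M * loc$s / 2) else NULL
    gen <- simulate_genealogy(sizes, tips, w$merges, contacts, tip_sp)
    seqs <- drop_mutations(gen, loc$theta, loc$length)
    alignments[[loc$name]] <- locus_alignment(loc$name, names(seqs), seqs)
    truth_tips[[loc$name]] <- data.frame(
      locus = loc$name, haplotype_id = gen$tip_label,
      deme_sampled = gen$tip_deme, migrant = gen$migrant_tip,
      stringsAsFactors = FALSE)
    if (nrow(ce)) {
      cc <- gen$cross_coalescences
      truth_pairs[[loc$name]] <- data.frame(
        locus = loc$name,
        n_cross = nrow(cc),
        frac_post_contact = if (nrow(cc)) mean(cc$post_contact) else NA_real_)
    }
  }
  divergence <- NULL
  if (!is.null(config$reference_locus) && nrow(ce)) {
    ref <- alignments[[config$reference_locus$name]]
    res <- resolve_haplotypes(ref$ids, samples, haploid = FALSE)
    divergence <- do.call(rbind, lapply(seq_len(nrow(ce)), function(i) {
      sx <- ref$seqs[res$species == ce$species_a[i]]
      sy <- ref$seqs[res$species == ce$species_b[i]]
      data.frame(species_a = ce$species_a[i], species_b = ce$species_b[i],
                 p_distance = dxy(sx, sy), stringsAsFactors = FALSE)
    }))
  }
  haploid_loci <- loci$name[loci$ploidy == "haploid"]
  structure(list(alignments = alignments, samples = samples,
                 haploid_loci = haploid_loci, divergence = divergence,
                 truth_tips = do.call(rbind, truth_tips),
                 truth_pairs = do.call(rbind, truth_pairs),
                 config = config),
            class = "sim_dataset")
}

#' Write a simulated dataset to a directory
#'
#' Emits one FASTA per locus, `metadata.tsv`, `divergence.tsv` (when a
#' reference locus was simulated; the reference locus itself gets no
#' FASTA), and `truth_tips.tsv` / `truth_pairs.tsv`.
#'
#' @param sim a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref_name <- sim$config$reference_locus$name %||% ""
  for (nm in names(sim$alignments)) {
    if (nm == ref_name) next
    write_locus_fasta(sim$alignments[[nm]], file.path(dir, paste0(nm, ".fasta")))
  }
  write.table(sim$samples$records, file.path(dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$divergence))
    write.table(sim$divergence, file.path(dir, "divergence.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$truth_tips))
    write.table(sim$truth_tips, file.path(dir, "truth_tips.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$truth_pairs))
    write.table(sim$truth_pairs, file.path(dir, "truth_pairs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Two-species secondary-contact config
#'
#' One hybridizing pair: each species holds a sympatric deme in the shared
#' contact basin plus an allopatric reference deme in its own basin.
#' Contact spans `[0, contact_start]`; same-species demes merge at
#' `within_merge`; the species split at `split_time`.
#'
#' @param M scaled contact migration (4*N0*m).
#' @param split_time species divergence time (coalescent units).
#' @param species two species names.
#' @param n_diploid diploids per deme.
#' @param n_loci,locus_length,theta,s nuclear locus panel.
#' @param contact_start,within_merge timing of contact and within-species
#'   deme merging.
#' @param seed RNG seed.
#' @return a `sim_config`.
#' @export
config_species_pair <- function(M, split_time = 4, species = c("spA", "spB"),
                                n_diploid = 10L, n_loci = 4L,
                                locus_length = 1000L, theta = 5, s = 1,
                                contact_start = 0.75, within_merge = 1.0,
                                seed = 1L) {
  a <- species[1]; b <- species[2]
  sim_config(
    species_tree = data.frame(species = c(a, b), parent = c(NA, a),
                              split_time = c(NA, split_time)),
    demes = data.frame(
      species = c(a, a, b, b),
      basin = c("contact", paste0("allo_", a), "contact", paste0("allo_", b)),
      relative_size = 1),
    contact_events = data.frame(species_a = a, species_b = b,
                                basin = "contact", start_time = contact_start,
                                M = M),
    loci = data.frame(name = paste0("nuc", seq_len(n_loci)),
                      length = locus_length, theta = theta,
                      ploidy = "diploid", s = s),
    samples_per_deme = n_diploid,
    within_species_merge_time = within_merge,
    seed = seed)
}

#' Barbel-like preset config
#'
#' Four species in two sister pairs, each pair in secondary contact in its
#' own basin, each species with an allopatric reference basin; four
#' nuclear loci with heterogeneous permeability s = (0.1, 1, 1, 0.1) — a
#' semi-permeable boundary — plus a haploid mtDNA locus.
#'
#' @param seed RNG seed.
#' @param M contact migration rate shared by both pairs.
#' @param n_diploid diploids per deme.
#' @return a `sim_config`.
#' @export
config_barbel_like <- function(seed = 1L, M = 1, n_diploid = 10L) {
  sim_config(
    species_tree = data.frame(
      species = c("sp1", "sp2", "sp3", "sp4"),
      parent = c(NA, "sp1", "sp1", "sp3"),
      split_time = c(NA, 3, 6, 3)),
    demes = data.frame(
      species = c("sp1", "sp1", "sp2", "sp2", "sp3", "sp3", "sp4", "sp4"),
      basin = c("bas1", "allo1", "bas1", "allo2",
                "bas2", "allo3", "bas2", "allo4"),
      relative_size = 1),
    contact_events = data.frame(
      species_a = c("sp1", "sp3"), species_b = c("sp2", "sp4"),
      basin = c("bas1", "bas2"), start_time = 0.5, M = M),
    loci = data.frame(
      name = c("nuc1", "nuc2", "nuc3", "nuc4", "mt1"),
      length = c(1000L, 1000L, 1000L, 1000L, 1000L),
      theta = 5,
      ploidy = c("diploid", "diploid", "diploid", "diploid", "haploid"),
      s = c(0.1, 1, 1, 0.1, 1)),
    samples_per_deme = n_diploid,
    within_species_merge_time = 0.75,
    seed = seed)
}

#' Hand-written micro fixtures
#'
#' Writes the byte-stable toy datasets used by the unit tests:
#' `zero-variation` (two demes of identical sequences), `trend-ranks`
#' (four pairs with strictly anti-concordant proportions and divergences),
#' and `fst-third` (the two-population alignment whose Hudson FST is 1/3).
#'
#' @param dir output directory.
#' @return named list of the paths written, invisibly.
#' @export
make_toy_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  # zero-variation: one locus, two populations, all sequences identical
  zv <- file.path(dir, "zero-variation")
  dir.create(zv, showWarnings = FALSE)
  writeLines(c(">X1_a", "ACGTACGT", ">X1_b", "ACGTACGT",
               ">Y1_a", "ACGTACGT", ">Y1_b", "ACGTACGT"),
             file.path(zv, "nuc1.fasta"))
  writeLines(c("sample_id\tspecies\tbasin\triver\tregion",
               "X1\tspX\tbasX\triverX\twest",
               "Y1\tspY\tbasY\triverY\teast"),
             file.path(zv, "metadata.tsv"))
  paths$zero_variation <- zv
  # trend-ranks: proportions strictly decreasing in divergence
  fr <- file.path(dir, "trend-ranks.tsv")
  writeLines(c("species_a\tspecies_b\tproportion\tdivergence",
               "s1\ts2\t0.20\t0.01",
               "s2\ts3\t0.12\t0.03",
               "s3\ts4\t0.05\t0.05",
               "s2\ts4\t0.01\t0.08"), fr)
  paths$trend_ranks <- fr
  # fst-third: X = {AAAA, AAAT}, Y = {TAAA, TAAT} -> FST = 1/3
  ft <- file.path(dir, "fst-third")
  dir.create(ft, showWarnings = FALSE)
  writeLines(c(">X1_a", "AAAA", ">X1_b", "AAAT",
               ">Y1_a", "TAAA", ">Y1_b", "TAAT"),
             file.path(ft, "nuc1.fasta"))
  writeLines(c("sample_id\tspecies\tbasin\triver\tregion",
               "X1\tspX\tbasX\triverX\twest",
               "Y1\tspY\tbasY\triverY\teast"),
             file.path(ft, "metadata.tsv"))
  paths$fst_third <- ft
  invisible(paths)
}
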