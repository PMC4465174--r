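test_that("config validation catches inconsistent worlds", {
  st <- data.frame(species = c("A", "B"), parent = c(NA, "A"),
                   split_time = c(NA, 2))
  demes <- data.frame(species = c("A", "B"), basin = c("g", "g"),
                      relative_size = 1)
  ce <- data.frame(species_a = "A", species_b = "B", basin = "g",
                   start_time = 0.5, M = 1)
  loci <- data.frame(name = "l1", length = 500L, theta = 2,
                     ploidy = "diploid", s = 1)
  expect_s3_class(sim_config(st, demes, ce, loci, seed = 1), "sim_config")
  expect_error(sim_config(st, demes, ce, loci),
               class = "semiperm_config_error")        # no seed
  ce_bad <- ce; ce_bad$start_time <- 3                 # after the split
  expect_error(sim_config(st, demes, ce_bad, loci, seed = 1),
               class = "semiperm_config_error")
  ce_bad2 <- ce; ce_bad2$basin <- "nope"
  expect_error(sim_config(st, demes, ce_bad2, loci, seed = 1),
               class = "semiperm_config_error")
  loci_bad <- loci; loci_bad$ploidy <- "triploid"
  expect_error(sim_config(st, demes, ce, loci_bad, seed = 1),
               class = "semiperm_config_error")
})

test_that("config JSON round-trip", {
  cfg <- config_species_pair(M = 1, split_time = 3, seed = 5)
  f <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$loci$theta, cfg$loci$theta)
  expect_equal(cfg2$contact_events$M, cfg$contact_events$M)
})

test_that("pairwise TMRCA has coalescent expectation 1 in a single deme", {
  set.seed(91)
  tm <- replicate(5000, {
    g <- simulate_genealogy(c(d = 1), c(t1 = "d", t2 = "d"))
    max(g$node_time)
  })
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 1), 3 * se)
})

test_that("no cross-deme coalescence precedes the merge when M = 0", {
  set.seed(92)
  for (rep in 1:20) {
    g <- simulate_genealogy(
      c(a = 1, b = 1),
      setNames(rep(c("a", "b"), each = 3), paste0("t", 1:6)),
      merges = data.frame(time = 10, from = "b", to = "a"))
    expect_true(all(g$cross_coalescences$time >= 10))
    expect_false(any(g$migrant_tip))
  }
})

test_that("fixed RNG state reproduces the tree; theta 0 gives identity", {
  sizes <- c(a = 1, b = 1)
  tips <- setNames(rep(c("a", "b"), each = 4), paste0("t", 1:8))
  mg <- data.frame(time = 2, from = "b", to = "a")
  set.seed(7); g1 <- simulate_genealogy(sizes, tips, mg)
  set.seed(7); g2 <- simulate_genealogy(sizes, tips, mg)
  expect_identical(g1$edge, g2$edge)
  expect_identical(g1$node_time, g2$node_time)
  seqs <- drop_mutations(g1, 0, 100)
  expect_true(all(seqs == seqs[1]))
})

test_that("neutral expectations: E[K] = theta, E[S] = theta * a_{n-1}", {
  set.seed(93)
  theta <- 5; n <- 10; L <- 2000
  Ks <- numeric(1000); Ss <- numeric(1000)
  for (i in 1:1000) {
    g <- simulate_genealogy(c(d = 1), setNames(rep("d", n), paste0("t", 1:n)))
    seqs <- drop_mutations(g, theta, L)
    Ks[i] <- mean_pairwise_differences(seqs)
    Ss[i] <- segregating_sites(seqs)
  }
  expect_lt(abs(mean(Ks) - theta), 3 * sd(Ks) / sqrt(1000))
  expect_lt(abs(mean(Ss) - theta * harmonic_number(n - 1)),
            3 * sd(Ss) / sqrt(1000))
})

test_that("mutation overflow raises a simulation error", {
  set.seed(94)
  g <- simulate_genealogy(c(d = 1), setNames(rep("d", 10), paste0("t", 1:10)))
  expect_error(drop_mutations(g, 1000, 3),
               class = "semiperm_simulation_error")
})

test_that("datasets are byte-deterministic given (config, seed)", {
  cfg <- config_species_pair(M = 1, split_time = 3, n_diploid = 4,
                             n_loci = 2, locus_length = 400, seed = 17)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$alignments$nuc1$seqs, s2$alignments$nuc1$seqs)
  expect_identical(s1$divergence, s2$divergence)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_sim_dataset(s1, d1); write_sim_dataset(s2, d2)
  f1 <- file.path(d1, "nuc1.fasta"); f2 <- file.path(d2, "nuc1.fasta")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("simulated datasets respect the metadata dialect and truth tables", {
  cfg <- config_barbel_like(seed = 23, n_diploid = 3)
  sim <- simulate_dataset(cfg)
  expect_setequal(names(sim$alignments),
                  c("nuc1", "nuc2", "nuc3", "nuc4", "mt1", "ref"))
  # nuclear locus: 2 copies per diploid; mtDNA: 1 bare-ID copy
  expect_equal(length(sim$alignments$nuc1$ids),
               2L * 3L * nrow(cfg$demes))
  expect_equal(length(sim$alignments$mt1$ids), 3L * nrow(cfg$demes))
  expect_true(all(grepl("_[ab]$", sim$alignments$nuc1$ids)))
  expect_false(any(grepl("_[ab]$", sim$alignments$mt1$ids)))
  # every haplotype resolves through the metadata
  res <- resolve_haplotypes(sim$alignments$nuc1$ids, sim$samples)
  expect_equal(nrow(res), length(sim$alignments$nuc1$ids))
  # truth tables well-formed
  expect_true(all(sim$truth_tips$migrant %in% c(TRUE, FALSE)))
  fr <- sim$truth_pairs$frac_post_contact
  expect_true(all(is.na(fr) | (fr >= 0 & fr <= 1)))
  # reference locus never migrates
  ref_truth <- sim$truth_tips[sim$truth_tips$locus == "ref", ]
  expect_false(any(ref_truth$migrant))
})

test_that("zero-migration contact yields zero introgression proportion", {
  set.seed(95)
  meds <- replicate(5, {
    cfg <- config_species_pair(M = 0, split_time = 4, n_diploid = 5,
                               n_loci = 2, locus_length = 600,
                               seed = sample.int(1e6, 1))
    pair_summary_from_sim(simulate_dataset(cfg))$proportion
  })
  expect_equal(median(meds), 0)
})

test_that("realized introgression is monotone in permeability s", {
  set.seed(96)
  mean_prop <- vapply(c(0, 0.5, 1), function(s) {
    props <- replicate(10, {
      cfg <- config_species_pair(M = 1, split_time = 4, n_diploid = 5,
                                 n_loci = 2, locus_length = 600, s = s,
                                 seed = sample.int(1e6, 1))
      pair_summary_from_sim(simulate_dataset(cfg))$proportion
    })
    mean(props)
  }, numeric(1))
  expect_true(all(diff(mean_prop) >= 0))
  expect_equal(mean_prop[1], 0)
})

test_that("toy fixtures are byte-stable and yield their advertised numbers", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- make_toy_fixtures(d1); make_toy_fixtures(d2)
  for (rel in c("zero-variation/nuc1.fasta", "trend-ranks.tsv",
                "fst-third/nuc1.fasta"))
    expect_identical(readLines(file.path(d1, rel)),
                     readLines(file.path(d2, rel)))

  # zero-variation -> all-zero statistics
  zv <- p1$zero_variation
  aln <- read_locus_fasta(file.path(zv, "nuc1.fasta"), "nuc1")
  st <- read_metadata_tsv(file.path(zv, "metadata.tsv"))
  ps <- population_stats(list(nuc1 = aln), st, "spX", "basX")
  expect_true(all(ps[ps$locus == "combined",
                     c("S", "Hd", "K", "pi", "thetaW")] == 0))

  # fst-third -> Hudson FST 1/3
  ft <- p1$fst_third
  aln2 <- read_locus_fasta(file.path(ft, "nuc1.fasta"), "nuc1")
  st2 <- read_metadata_tsv(file.path(ft, "metadata.tsv"))
  sx <- population_sequences(aln2, st2, "spX", "basX")
  sy <- population_sequences(aln2, st2, "spY", "basY")
  expect_equal(hudson_fst(sx, sy), 1 / 3)

  # trend-ranks -> rho = -1 downstream
  fr <- read.delim(p1$trend_ranks)
  expect_equal(introgression_divergence_trend(fr$proportion,
                                              fr$divergence)$rho, -1)
})
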