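test_that("analyzed columns use complete deletion (1-based indices)", {
  expect_equal(analyzed_columns(c("ACGT", "ACGT")), c(1L, 2L, 3L, 4L))
  expect_equal(analyzed_columns(c("AC-T", "ACGT", "ACGA")), c(1L, 2L, 4L))
  expect_equal(analyzed_columns(c("NNNN", "ACGT")), integer())
  expect_error(analyzed_columns(character()), class = "semiperm_input_error")
})

test_that("segregating sites, gapped columns excluded", {
  expect_equal(segregating_sites(c("ACGT", "ACGA")), 1L)
  expect_equal(segregating_sites(c("AC-T", "ACGT", "ACGA")), 1L)
  expect_equal(segregating_sites(c("ACGT", "ACGT")), 0L)
  expect_error(segregating_sites("ACGT"), class = "semiperm_undefined_error")
})

test_that("haplotype diversity matches the unbiased formula", {
  expect_equal(haplotype_diversity(c(2, 1, 1)), (4 / 3) * (1 - 6 / 16))
  expect_equal(haplotype_diversity(c(2)), 0)
  expect_equal(haplotype_diversity(c(1, 1)), 1)
  expect_error(haplotype_diversity(c(1)), class = "semiperm_undefined_error")
})

test_that("K, pi, thetaW worked examples", {
  expect_equal(mean_pairwise_differences(c("AAAA", "AAAT", "AATT")), 4 / 3)
  expect_equal(mean_pairwise_differences(c("ACGT", "ACGT")), 0)
  expect_equal(mean_pairwise_differences(c("A", "T")), 1)
  expect_equal(nucleotide_diversity(c("AAAA", "AAAT", "AATT")), 1 / 3)
  expect_equal(nucleotide_diversity(c("AT", "TA")), 1)
  expect_equal(watterson_theta(3, 4, 100), 3 / ((1 + 1 / 2 + 1 / 3) * 100))
  expect_equal(watterson_theta(0, 4, 100), 0)
  expect_equal(watterson_theta(2, 2, 10), 2 / 10)  # a_1 = 1
  expect_error(watterson_theta(1, 1, 10), class = "semiperm_undefined_error")
})

test_that("brute-force oracle equivalence on random alignments", {
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(2:10, 1); L <- sample(5:50, 1)
    seqs <- random_alignment(n, L)
    expect_identical(segregating_sites(seqs), oracle_S(seqs))
    expect_equal(mean_pairwise_differences(seqs), oracle_K(seqs))
    if (length(analyzed_columns(seqs)) > 0)
      expect_equal(nucleotide_diversity(seqs), oracle_pi(seqs))
    m <- sample(2:(n), 1)
    if (m < n) {
      sx <- seqs[1:m]; sy <- seqs[(m + 1):n]
      expect_equal(suppressWarnings(dxy(sx, sy)), oracle_dxy(sx, sy))
    }
    # sufficient-statistic identity
    cols <- analyzed_columns(seqs)
    if (length(cols) > 0) {
      S <- segregating_sites(seqs)
      th <- watterson_theta(S, n, length(cols))
      expect_equal(th * harmonic_number(n - 1) * length(cols), S)
    }
  }
})

test_that("duplicating a sequence never changes S", {
  set.seed(11)
  for (rep in 1:10) {
    seqs <- random_alignment(sample(2:6, 1), 20)
    aug <- c(seqs, seqs[1])
    expect_identical(segregating_sites(aug), segregating_sites(seqs))
  }
})

test_that("dxy / da / hudson_fst worked examples", {
  expect_equal(dxy(c("AAAA", "AAAA"), c("TTTT", "TTTT")), 1)
  expect_equal(dxy("AAAA", "AAAA"), 0)
  X <- c("AAAA", "AAAT"); Y <- c("TAAA", "TAAT")
  expect_equal(dxy(X, Y), 0.375)
  expect_equal(da(X, Y), 0.125)
  expect_equal(hudson_fst(X, Y), 1 - 0.25 / 0.375)
  expect_equal(hudson_fst(c("AAAA", "AAAA"), c("TTTT", "TTTT")), 1)
  expect_true(is.na(hudson_fst(c("AAAA", "AAAA"), c("AAAA", "AAAA"))))
  # fixed difference at every site: Da = Dxy
  expect_equal(da(c("AAAA", "AAAA"), c("TTTT", "TTTT")), 1)
})

test_that("Da <= Dxy over random population pairs", {
  set.seed(5)
  for (rep in 1:15) {
    sx <- random_alignment(sample(2:5, 1), 30)
    sy <- random_alignment(sample(2:5, 1), 30)
    pd <- pair_divergence(sx, sy)
    expect_lte(pd$Da, pd$Dxy + 1e-12)
    if (!is.na(pd$FST)) expect_equal(pd$FST, 1 - pd$Hw / pd$Dxy)
  }
})

make_three_pop_world <- function() {
  # 3 monomorphic populations with pairwise fixed differences 1, 2, 3 over
  # L = 10
  base <- strsplit("AAAAAAAAAA", "")[[1]]
  sA <- paste(base, collapse = "")
  sB <- base; sB[1] <- "C"; sB <- paste(sB, collapse = "")        # A-B: 1
  sC <- base; sC[2:3] <- "G"; sC <- paste(sC, collapse = "")      # A-C: 2, B-C: 3
  st <- sample_table(data.frame(
    sample_id = c("A1", "B1", "C1"), species = c("pA", "pB", "pC"),
    basin = "G", river = "r", region = "x"))
  aln <- locus_alignment("l", c("A1_a", "A1_b", "B1_a", "B1_b", "C1_a", "C1_b"),
                         c(sA, sA, sB, sB, sC, sC))
  list(aln = list(l = aln), samples = st)
}

test_that("divergence matrix: direct counts, symmetry, permutation", {
  w <- make_three_pop_world()
  dm <- divergence_matrix(w$aln, w$samples, "Dxy")
  v <- dm$values
  expect_equal(diag(v), setNames(rep(0, 3), rownames(v)))
  expect_equal(v["pA|G", "pB|G"], 0.1)
  expect_equal(v["pA|G", "pC|G"], 0.2)
  expect_equal(v["pB|G", "pC|G"], 0.3)
  expect_identical(v, t(v))
  pops <- dm$populations[c(3, 1, 2), ]
  dm2 <- divergence_matrix(w$aln, w$samples, "Dxy", populations = pops)
  expect_equal(dm2$values[rownames(v), colnames(v)], v)
})

test_that("population stats: per-locus and combined rules", {
  # locus1: L=100, one segregating site -> pi = 0.01; locus2: L=300, nine
  # sites -> pi = 0.03; combined pi is the L_eff-weighted mean 0.025
  s1a <- paste(rep("A", 100), collapse = "")
  s1b <- sub("^A", "T", s1a)
  s2a <- paste(rep("C", 300), collapse = "")
  s2b <- paste(c(rep("G", 9), rep("C", 291)), collapse = "")
  st <- sample_table(data.frame(sample_id = "S1", species = "A", basin = "G",
                                river = "r", region = "x"))
  alns <- list(l1 = locus_alignment("l1", c("S1_a", "S1_b"), c(s1a, s1b)),
               l2 = locus_alignment("l2", c("S1_a", "S1_b"), c(s2a, s2b)))
  ps <- population_stats(alns, st, "A", "G")
  comb <- ps[ps$locus == "combined", ]
  expect_equal(comb$pi, 0.025)
  expect_equal(comb$S, 10L)
  expect_equal(comb$K, 10)
  expect_equal(comb$L_eff, 400L)
  expect_equal(comb$Hd, 1)          # mean of per-locus Hd (both 1)
  expect_equal(comb$n, 2L)

  # single locus: combined equals the per-locus record
  ps1 <- population_stats(alns["l1"], st, "A", "G")
  expect_equal(ps1$pi[ps1$locus == "combined"], ps1$pi[ps1$locus == "l1"])

  # all-identical sequences -> all-zero record
  alns0 <- list(l1 = locus_alignment("l1", c("S1_a", "S1_b"), c(s1a, s1a)))
  z <- population_stats(alns0, st, "A", "G")
  expect_true(all(z[z$locus == "combined", c("S", "Hd", "K", "pi", "thetaW")] == 0))

  expect_error(population_stats(alns, st, "nope", "G"),
               class = "semiperm_input_error")
})

test_that("table and matrix writers round-trip", {
  w <- make_three_pop_world()
  dm <- divergence_matrix(w$aln, w$samples, "Dxy")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_divergence_tsv(dm, f)
  expect_equal(read_divergence_tsv(f), dm$values)

  fp <- withr::local_tempfile(fileext = ".dist")
  write_phylip_dist(dm, fp)
  lines <- readLines(fp)
  expect_equal(as.integer(trimws(lines[1])), 3L)
  expect_equal(length(lines), 4L)

  tab <- collapse_alleles(w$aln$l, w$samples)
  fa <- withr::local_tempfile(fileext = ".tsv")
  write_allele_table(tab, fa)
  back <- read.delim(fa)
  expect_equal(sum(back$count), 6L)
  expect_setequal(back$sequence, unname(tab$alleles[back$allele_id]))

  st <- all_population_stats(w$aln, w$samples)
  fs <- withr::local_tempfile(fileext = ".tsv")
  write_stats_tsv(st, fs)
  expect_true("No" %in% names(read.delim(fs, check.names = FALSE)))
})
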