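# Classifier worlds are stated as allele copy counts per population; note
# the rule fires in both directions, so a donor-typical allele must appear
# in the donor's allopatric sample when a test wants no reverse-direction
# ("echo") call on the donor's own copies.
make_tables <- function(world) {
  w <- build_world(world)
  tabs <- list(nuc1 = collapse_alleles(w$aln, w$samples))
  map <- build_sympatry_map(w$samples)
  list(tabs = tabs, map = map, samples = w$samples)
}

test_that("diagnostic rule: textbook call, ancestral block, disjoint sets", {
  world <- list(
    G = list(A = list("AAAAAA" = 8, "AAAATT" = 8, "TTTTTT" = 4),
             B = list("TTTTTT" = 6, "TTTTAA" = 4)),
    T = list(A = list("AAAAAA" = 6, "AAAATT" = 2)),
    H = list(B = list("TTTTTT" = 2, "TTTTAA" = 2)))
  x <- make_tables(world)
  calls <- classify_diagnostic_alleles("A", "B", "G", x$tabs, x$map)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$direction, "B->A")
  expect_equal(calls$copies, 4L)
  expect_equal(x$tabs$nuc1$alleles[[calls$allele_id]], "TTTTTT")
  expect_false(calls$present_in_recipient_allopatric)

  # allele in A_allo AND B: ancestral polymorphism, no call
  world2 <- list(
    G = list(A = list("TTTTTT" = 4), B = list("TTTTTT" = 6)),
    T = list(A = list("TTTTTT" = 2, "AAAAAA" = 2)),
    H = list(B = list("TTTTTT" = 2)))
  x2 <- make_tables(world2)
  expect_equal(nrow(classify_diagnostic_alleles("A", "B", "G", x2$tabs,
                                                x2$map)), 0L)

  # disjoint allele sets
  world3 <- list(
    G = list(A = list("AAAAAA" = 4), B = list("TTTTTT" = 4)),
    T = list(A = list("AAAAAA" = 2)),
    H = list(B = list("TTTTTT" = 2)))
  x3 <- make_tables(world3)
  expect_equal(nrow(classify_diagnostic_alleles("A", "B", "G", x3$tabs,
                                                x3$map)), 0L)
})

test_that("non-sympatric pair and missing allopatric reference error", {
  world <- list(
    G = list(A = list("AAAAAA" = 4), B = list("TTTTTT" = 4, "AAAAAA" = 2)),
    T = list(A = list("AAAAAA" = 2)))
  x <- make_tables(world)
  expect_error(classify_diagnostic_alleles("A", "B", "T", x$tabs, x$map),
               class = "semiperm_usage_error")
  # B has no allopatric population and nuc1 not excluded
  expect_error(classify_diagnostic_alleles("A", "B", "G", x$tabs, x$map),
               class = "semiperm_unresolved_ancestry_error")
})

test_that("locus exclusion rule: no-allopatric + monomorphic, manual", {
  world <- list(
    G = list(A = list("AAAAAA" = 4), B = list("TTTTTT" = 4)),
    T = list(A = list("AAAAAA" = 2)))
  x <- make_tables(world)   # B: single basin, monomorphic at nuc1
  ex <- exclude_loci_for_pair("A", "B", x$tabs, x$map)
  expect_equal(ex$locus, "nuc1")
  expect_match(ex$reason, "B")

  # polymorphic B in one basin: clause (ii) fails -> no auto exclusion
  worldp <- list(
    G = list(A = list("AAAAAA" = 4), B = list("TTTTTT" = 2, "TTTTAA" = 2)),
    T = list(A = list("AAAAAA" = 2)))
  xp <- make_tables(worldp)
  expect_equal(nrow(exclude_loci_for_pair("A", "B", xp$tabs, xp$map)), 0L)

  # species in two basins: no auto-exclusion regardless of monomorphism
  world2 <- list(
    G = list(A = list("AAAAAA" = 4), B = list("TTTTTT" = 4)),
    T = list(A = list("AAAAAA" = 2)),
    H = list(B = list("TTTTTT" = 2)))
  x2 <- make_tables(world2)
  expect_equal(nrow(exclude_loci_for_pair("A", "B", x2$tabs, x2$map)), 0L)
  exm <- exclude_loci_for_pair("A", "B", x2$tabs, x2$map, manual = "nuc1")
  expect_equal(exm$reason, "manual")
})

test_that("classifier soundness over random allele worlds", {
  for (seed in 1:25) {
    w <- random_world(seed)
    tabs <- list(nuc1 = collapse_alleles(w$aln, w$samples))
    map <- build_sympatry_map(w$samples)
    calls <- classify_diagnostic_alleles("A", "B", "G", tabs, map)
    if (nrow(calls) == 0L) next
    lab <- map$labels
    for (i in seq_len(nrow(calls))) {
      recipient <- sub("^.*->", "", calls$direction[i])
      allo <- lab[lab$species == recipient & lab$label == "allopatric", ]
      for (k in seq_len(nrow(allo))) {
        cc <- allele_counts(tabs$nuc1, allo$species[k], allo$basin[k])
        expect_false(calls$allele_id[i] %in% names(cc))
      }
    }
  }
})

test_that("introgression proportion: arithmetic and monotonicity", {
  # 4 introgressed of 20 copies in A, 1 of 10 in B -> 5/30
  world <- list(
    G = list(A = list("AAAAAA" = 10, "AAAATT" = 6, "TTTTTT" = 4),
             B = list("TTTTTT" = 6, "TTTTAA" = 3, "AAAATT" = 1)),
    T = list(A = list("AAAAAA" = 4, "AAAATT" = 2)),
    H = list(B = list("TTTTAA" = 2, "TTTTTT" = 2)))
  x <- make_tables(world)
  calls <- classify_diagnostic_alleles("A", "B", "G", x$tabs, x$map)
  # B->A: TTTTTT, 4 copies (absent in A_allo, present in B); A->B: AAAATT,
  # 1 copy (absent in B_allo, present in A). TTTTTT in B is covered by
  # B_allo, so no echo call on B's own copies.
  s <- introgression_proportion("A", "B", "G", calls, x$tabs)
  expect_equal(s$introgressed, 5L)
  expect_equal(s$total, 30L)
  expect_equal(s$proportion, 5 / 30)

  # no calls -> 0
  s0 <- introgression_proportion("A", "B", "G", calls[0, ], x$tabs)
  expect_equal(s0$proportion, 0)

  # monotone in calls with denominator fixed
  s1 <- introgression_proportion("A", "B", "G", calls[1, ], x$tabs)
  expect_lte(s1$proportion, s$proportion)

  # distinct-allele mode: 2 called alleles of 6 distinct sympatric
  # (A: 3 alleles + B: 3 alleles)
  sa <- introgression_proportion("A", "B", "G", calls, x$tabs,
                                 mode = "alleles")
  expect_equal(sa$proportion, 2 / 6)
})

test_that("complete-replacement proportion", {
  # A's sympatric sample fully B-typical: 20 of 20 called, B contributes 0
  world <- list(
    G = list(A = list("TTTTTT" = 20), B = list("TTTTAA" = 10)),
    T = list(A = list("AAAAAA" = 4)),
    H = list(B = list("TTTTTT" = 2, "TTTTAA" = 2)))
  x <- make_tables(world)
  calls <- classify_diagnostic_alleles("A", "B", "G", x$tabs, x$map)
  s <- introgression_proportion("A", "B", "G", calls, x$tabs)
  expect_equal(s$proportion, 20 / 30)
})

test_that("trend test: anti-concordant, concordant, tied-rank cases", {
  tr <- introgression_divergence_trend(c(0.2, 0.12, 0.05, 0.01), 1:4)
  expect_equal(tr$rho, -1)
  expect_equal(tr$p_exact, 1 / 24)
  expect_equal(floor(tr$p_exact * 1e4) / 1e4, 0.0416)

  up <- introgression_divergence_trend(c(0.01, 0.05, 0.12, 0.2), 1:4)
  expect_equal(up$rho, 1)
  expect_equal(up$p_exact, 1)

  # enumeration gives 4/24 here (one perm at -1, three at -0.8)
  mid <- introgression_divergence_trend(c(0.3, 0.1, 0.2, 0.05), 1:4)
  expect_equal(mid$rho, -0.8)
  expect_equal(mid$p_exact, 4 / 24)

  expect_error(introgression_divergence_trend(c(0.1, 0.2), 1:2),
               class = "semiperm_input_error")
  expect_error(introgression_divergence_trend(runif(11), 1:11),
               class = "semiperm_input_error")
})

test_that("exact P equals independent enumeration for n <= 6", {
  set.seed(23)
  for (n in c(3, 4, 5)) for (rep in 1:3) {
    x <- runif(n); y <- runif(n)
    tr <- introgression_divergence_trend(y, x)
    expect_equal(tr$p_exact, oracle_spearman_p(x, y))
  }
  # with ties in the proportions (mid-ranks)
  y <- c(0.2, 0, 0, 0.1)
  x <- c(1, 3, 4, 2)
  expect_equal(introgression_divergence_trend(y, x)$p_exact,
               oracle_spearman_p(x, y))
})

test_that("r2 is the squared Pearson correlation of raw values", {
  y <- c(0.28, 0.15, 0.06, 0.01); x <- c(0.01, 0.03, 0.06, 0.10)
  expect_equal(introgression_divergence_trend(y, x)$r2, cor(x, y)^2)
})

test_that("divergence table IO and lookup", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species_a\tspecies_b\tp_distance", "A\tB\t0.021", "B\tC\t0.05"),
             f)
  dt <- read_divergence_pairs_tsv(f)
  expect_equal(pair_divergence_value(dt, "B", "A"), 0.021)
  expect_error(pair_divergence_value(dt, "A", "C"),
               class = "semiperm_input_error")
})
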