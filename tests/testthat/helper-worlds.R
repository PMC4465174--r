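# In-code fixture builders: tiny populations assembled from explicit allele
# copy counts, so classifier scenarios can be stated declaratively.

# world: named list basin -> list(species -> named vector allele_seq -> copies)
# copies must be even (diploid samples, both copies of one sample identical
# unless split across two entries).
build_world <- function(world, locus_name = "nuc1") {
  ids <- character(); seqs <- character(); meta <- list()
  counter <- new.env()
  for (basin in names(world)) for (sp in names(world[[basin]])) {
    key <- paste(sp, basin, sep = ".")
    alleles <- world[[basin]][[sp]]
    copies <- unlist(alleles)
    total <- sum(copies)
    stopifnot(total %% 2 == 0)
    haps <- rep(names(alleles), copies)
    n_ind <- total / 2
    sid <- sprintf("%s_%s_%d", sp, basin, seq_len(n_ind))
    meta[[key]] <- data.frame(sample_id = sid, species = sp, basin = basin,
                              river = basin, region = "toy")
    ids <- c(ids, as.vector(rbind(paste0(sid, "_a"), paste0(sid, "_b"))))
    seqs <- c(seqs, haps)
  }
  list(aln = locus_alignment(locus_name, ids, seqs),
       samples = sample_table(do.call(rbind, meta)))
}

random_world <- function(seed) {
  set.seed(seed)
  pool <- vapply(1:8, function(i)
    paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = ""),
    character(1))
  pool <- unique(pool)
  pick <- function() {
    k <- sample(seq_along(pool), sample(1:3, 1))
    stats::setNames(as.list(2 * sample(1:3, length(k), replace = TRUE)),
                    pool[k])
  }
  world <- list(
    G = list(A = pick(), B = pick()),   # contact basin
    T = list(A = pick()),               # allopatric A
    H = list(B = pick()))               # allopatric B
  build_world(world)
}
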