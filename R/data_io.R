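## data_io: read/write standard formats, bind haplotypes to sample metadata,
## collapse sequences into alleles and per-population count tables.

LOCUS_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Read one locus alignment from FASTA
#'
#' Reads a per-locus FASTA of phased haplotype sequences into a
#' `locus_alignment` object. Sequences are uppercased on input; IDs are the
#' first whitespace-delimited token of each header and must be unique.
#' All sequences must have identical length (the files are pre-aligned) and
#' use only the alphabet `A C G T N -`.
#'
#' @param path path to a FASTA file.
#' @param locus_name name recorded for the locus (defaults to the file stem).
#' @return a `locus_alignment`: list with `locus_name`, `ids`, `seqs`
#'   (named character vector), and `length` (alignment columns).
#' @export
read_locus_fasta <- function(path, locus_name = NULL) {
  if (!file.exists(path)) abort_input(sprintf("FASTA file not found: %s", path))
  if (is.null(locus_name))
    locus_name <- sub("\\.(fa|fasta|fas)$", "", basename(path), ignore.case = TRUE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort_input(sprintf("no FASTA records in %s", path))
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  locus_alignment(locus_name, ids, seqs)
}

#' Construct a locus alignment from sequences in memory
#'
#' @param locus_name locus label.
#' @param ids haplotype IDs, unique within the locus.
#' @param seqs character vector of aligned sequences (already uppercase or
#'   uppercased here), equal lengths, alphabet `A C G T N -`.
#' @return a `locus_alignment` object.
#' @export
locus_alignment <- function(locus_name, ids, seqs) {
  seqs <- toupper(unname(seqs))
  ids <- as.character(ids)
  if (length(ids) != length(seqs)) abort_input("ids and seqs lengths differ")
  if (length(seqs) == 0L) abort_input("alignment has no sequences")
  if (anyDuplicated(ids))
    abort_metadata(sprintf("duplicate haplotype ID(s): %s",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    abort_alignment(sprintf(
      "ragged alignment in locus '%s': lengths %s", locus_name,
      paste(unique(lens), collapse = ", ")))
  if (lens[1] < 1L) abort_alignment("alignment length must be >= 1")
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    bad <- which(!ch %in% LOCUS_ALPHABET)
    if (length(bad))
      abort_alphabet(sprintf(
        "illegal character '%s' in record '%s' at column %d of locus '%s'",
        ch[bad[1]], ids[i], bad[1], locus_name))
  }
  names(seqs) <- ids
  structure(list(locus_name = locus_name, ids = ids, seqs = seqs,
                 length = unname(lens[1])),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %s: %d haplotypes x %d columns\n",
              x$locus_name, length(x$ids), x$length))
  invisible(x)
}

#' Write a locus alignment to FASTA
#'
#' Round-trips byte-identically with [read_locus_fasta()] for valid input.
#'
#' @param aln a `locus_alignment`.
#' @param path output path.
#' @export
write_locus_fasta <- function(aln, path) {
  set <- Biostrings::BStringSet(aln$seqs)
  names(set) <- aln$ids
  Biostrings::writeXStringSet(set, path, width = 20000L)
  invisible(path)
}

## Character matrix view of an alignment or plain sequence vector.
seq_matrix <- function(seqs) {
  if (inherits(seqs, "locus_alignment")) seqs <- seqs$seqs
  if (length(seqs) == 0L) abort_input("empty sequence set")
  m <- matrix(unlist(strsplit(unname(seqs), "", fixed = TRUE)),
              nrow = length(seqs), byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

#' Read a sample-metadata table
#'
#' Reads the tab-separated metadata table binding samples to species and
#' geography. Required columns: `sample_id`, `species`, `basin`, `river`,
#' `region` (header row required, order free).
#'
#' @param path path to the TSV.
#' @return a `sample_table`: list with `records` (data.frame) indexed by
#'   `sample_id`.
#' @export
read_metadata_tsv <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("metadata file not found: %s", path))
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   check.names = FALSE)
  sample_table(df)
}

#' Construct a sample table from a data.frame
#'
#' @param records data.frame with columns `sample_id`, `species`, `basin`,
#'   `river`, `region`.
#' @return a `sample_table` object.
#' @export
sample_table <- function(records) {
  req <- c("sample_id", "species", "basin", "river", "region")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    abort_schema(sprintf("metadata missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  records <- as.data.frame(lapply(records[req], as.character),
                           stringsAsFactors = FALSE)
  if (nrow(records) == 0L) abort_input("metadata table has no rows")
  if (anyDuplicated(records$sample_id))
    abort_metadata("duplicate sample_id in metadata")
  if (any(!nzchar(records$species)) || any(!nzchar(records$basin)))
    abort_metadata("species and basin must be non-empty")
  structure(list(records = records), class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %d samples, %d species, %d basins\n",
              nrow(x$records), length(unique(x$records$species)),
              length(unique(x$records$basin))))
  invisible(x)
}

#' Resolve haplotype IDs to samples and gene copies
#'
#' Haplotype-ID dialect: phased nuclear copies are `<sample_id>_a` and
#' `<sample_id>_b`; haploid (mtDNA) records carry the bare `sample_id`.
#' Copy indices are 0 (`_a` / bare) and 1 (`_b`).
#'
#' @param ids haplotype IDs from a locus alignment.
#' @param samples a `sample_table`.
#' @param haploid `TRUE` for a haploid locus (mtDNA): bare IDs, one copy per
#'   sample.
#' @return data.frame with `haplotype_id`, `sample_id`, `copy_index`,
#'   `species`, `basin`.
#' @export
resolve_haplotypes <- function(ids, samples, haploid = FALSE) {
  rec <- samples$records
  if (haploid) {
    unknown <- setdiff(ids, rec$sample_id)
    if (length(unknown))
      abort_metadata(sprintf("haplotype(s) reference unknown sample(s): %s",
                             paste(unknown, collapse = ", ")))
    sid <- ids
    copy <- rep(0L, length(ids))
  } else {
    has_suffix <- grepl("_[ab]$", ids)
    if (any(!has_suffix))
      abort_ploidy(sprintf(
        "nuclear haplotype ID(s) lack the _a/_b copy suffix: %s",
        paste(ids[!has_suffix], collapse = ", ")))
    sid <- sub("_[ab]$", "", ids)
    copy <- ifelse(grepl("_a$", ids), 0L, 1L)
    unknown <- setdiff(sid, rec$sample_id)
    if (length(unknown))
      abort_metadata(sprintf("haplotype(s) reference unknown sample(s): %s",
                             paste(unknown, collapse = ", ")))
    if (anyDuplicated(paste(sid, copy)))
      abort_ploidy("more than 2 copies for one (sample, locus)")
  }
  idx <- match(sid, rec$sample_id)
  data.frame(haplotype_id = ids, sample_id = sid, copy_index = copy,
             species = rec$species[idx], basin = rec$basin[idx],
             stringsAsFactors = FALSE)
}

#' Build a sympatry/allopatry map from basin co-occurrence
#'
#' A (species, basin) population is labelled `sympatric` when at least one
#' other study species occurs in the same basin, otherwise `allopatric`.
#' Explicit per-pair overrides (`species_a`, `species_b`, `basin`, `label`)
#' are applied last and logged in the returned object.
#'
#' @param samples a `sample_table`.
#' @param overrides optional data.frame with columns `species_a`,
#'   `species_b`, `basin`, `label` (label in `sympatric`/`allopatric`).
#' @return a `sympatry_map`: list with `basin_species` (named list),
#'   `labels` (data.frame species/basin/label), `overrides`.
#' @export
build_sympatry_map <- function(samples, overrides = NULL) {
  rec <- samples$records
  if (nrow(rec) == 0L) abort_input("empty sample table")
  pops <- unique(rec[c("species", "basin")])
  basin_species <- lapply(split(pops$species, pops$basin), unique)
  labels <- pops
  labels$label <- vapply(seq_len(nrow(pops)), function(i) {
    if (length(basin_species[[pops$basin[i]]]) >= 2) "sympatric" else "allopatric"
  }, character(1))
  if (!is.null(overrides) && nrow(overrides)) {
    req <- c("species_a", "species_b", "basin", "label")
    if (!all(req %in% names(overrides)))
      abort_schema("overrides need columns species_a, species_b, basin, label")
    for (i in seq_len(nrow(overrides))) {
      o <- overrides[i, ]
      present <- basin_species[[o$basin]]
      if (is.null(present) || !all(c(o$species_a, o$species_b) %in% present))
        abort_metadata(sprintf(
          "override names species/basin absent from data: (%s, %s) in %s",
          o$species_a, o$species_b, o$basin))
      if (!o$label %in% c("sympatric", "allopatric"))
        abort_metadata(sprintf("override label must be sympatric/allopatric: %s",
                               o$label))
    }
  }
  structure(list(basin_species = basin_species, labels = labels,
                 overrides = overrides),
            class = "sympatry_map")
}

#' Population label: sympatric or allopatric
#'
#' @param map a `sympatry_map`.
#' @param species,basin population coordinates.
#' @return `"sympatric"` or `"allopatric"`.
#' @export
population_label <- function(map, species, basin) {
  hit <- map$labels$label[map$labels$species == species &
                          map$labels$basin == basin]
  if (length(hit) == 0L)
    abort_input(sprintf("population (%s, %s) not in sympatry map", species, basin))
  hit[1]
}

#' Is a species pair sympatric in a basin?
#'
#' Both species must occur in the basin; an explicit override for the pair in
#' that basin takes precedence over co-occurrence.
#'
#' @param map a `sympatry_map`.
#' @param species_a,species_b the pair.
#' @param basin basin of putative contact.
#' @return logical.
#' @export
pair_sympatric <- function(map, species_a, species_b, basin) {
  ov <- map$overrides
  if (!is.null(ov) && nrow(ov)) {
    hit <- (ov$basin == basin) &
      ((ov$species_a == species_a & ov$species_b == species_b) |
       (ov$species_a == species_b & ov$species_b == species_a))
    if (any(hit)) return(ov$label[which(hit)[1]] == "sympatric")
  }
  present <- map$basin_species[[basin]]
  !is.null(present) && all(c(species_a, species_b) %in% present)
}

#' Collapse a locus alignment into an allele table
#'
#' Allele identity is exact full-string equality of the aligned sequence,
#' indels and Ns included. Copy counts are partitioned by population
#' (species, basin); allele IDs (`a1`, `a2`, ...) follow first-occurrence
#' order in the alignment.
#'
#' @param aln a `locus_alignment`.
#' @param samples a `sample_table`.
#' @param haploid `TRUE` for a haploid locus (bare-ID dialect).
#' @return an `allele_table`: list with `locus_name`, `alleles` (named
#'   character: allele_id -> sequence), `counts` (data.frame allele_id /
#'   species / basin / count), and `haplotypes` (per-haplotype assignment).
#' @export
collapse_alleles <- function(aln, samples, haploid = FALSE) {
  res <- resolve_haplotypes(aln$ids, samples, haploid = haploid)
  seqs <- aln$seqs
  allele_of <- match(seqs, unique(seqs))
  allele_ids <- paste0("a", allele_of)
  alleles <- setNames(unique(seqs), paste0("a", seq_along(unique(seqs))))
  hap <- cbind(res, allele_id = allele_ids, stringsAsFactors = FALSE)
  counts <- as.data.frame(table(allele_id = allele_ids,
                                pop = paste(res$species, res$basin, sep = "\r")),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0L, ]
  pop_split <- strsplit(counts$pop, "\r", fixed = TRUE)
  counts <- data.frame(
    allele_id = counts$allele_id,
    species = vapply(pop_split, `[[`, character(1), 1L),
    basin = vapply(pop_split, `[[`, character(1), 2L),
    count = as.integer(counts$Freq),
    stringsAsFactors = FALSE)
  counts <- counts[order(as.integer(sub("^a", "", counts$allele_id)),
                         counts$species, counts$basin), ]
  rownames(counts) <- NULL
  structure(list(locus_name = aln$locus_name, alleles = alleles,
                 counts = counts, haplotypes = hap),
            class = "allele_table")
}

#' @export
print.allele_table <- function(x, ...) {
  cat(sprintf("<allele_table> %s: %d alleles over %d populations\n",
              x$locus_name, length(x$alleles),
              nrow(unique(x$counts[c("species", "basin")]))))
  invisible(x)
}

#' Allele copy counts for one population
#'
#' @param tab an `allele_table`.
#' @param species,basin population coordinates.
#' @return named integer vector (allele_id -> copies), zero-length if the
#'   population was not sampled at this locus.
#' @export
allele_counts <- function(tab, species, basin) {
  sel <- tab$counts$species == species & tab$counts$basin == basin
  setNames(tab$counts$count[sel], tab$counts$allele_id[sel])
}

#' Export an allele table as TSV
#'
#' Columns: `locus allele_id species basin count sequence`.
#'
#' @param tab an `allele_table`.
#' @param path output path.
#' @export
write_allele_table <- function(tab, path) {
  out <- tab$counts
  out <- cbind(locus = tab$locus_name, out,
               sequence = unname(tab$alleles[out$allele_id]))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sequences of one population at one locus
#'
#' @param aln a `locus_alignment`.
#' @param samples a `sample_table`.
#' @param species,basin population coordinates.
#' @param haploid haploid-locus flag.
#' @return named character vector of aligned sequences (possibly empty).
#' @export
population_sequences <- function(aln, samples, species, basin, haploid = FALSE) {
  res <- resolve_haplotypes(aln$ids, samples, haploid = haploid)
  keep <- res$species == species & res$basin == basin
  aln$seqs[keep]
}
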