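## Pipeline orchestration: load -> stats -> divergence -> NJ -> introgression
## -> sympatry contrasts, with a single JSON run manifest.

#' Run the full analysis pipeline
#'
#' Executes, in order: data loading, the per-population stats table, the
#' divergence matrices (per locus and combined, for each requested
#' statistic), NJ trees with site-bootstrap support, introgression calls /
#' pair summaries / the trend test, and the sympatric-versus-allopatric
#' contrast. Stages that are undefined for the dataset (e.g. divergence
#' with a single population, a trend with fewer than three pairs) are
#' skipped with a logged reason; any other stage failure aborts naming the
#' stage, retaining the outputs already written.
#'
#' Analysis config (JSON or list): `loci` (list of `name`/`path`/optional
#' `haploid`), `metadata` (TSV path), optional `divergence` (pair TSV),
#' optional `overrides` (sympatry override TSV), `bootstrap_B` (default
#' 100), `statistics` (default Dxy/Da/FST), `denominator_mode`,
#' `manual_exclusions`, `contrast_species`, `seed`.
#'
#' @param config path to a JSON analysis config, or an equivalent list.
#' @param out_dir output directory.
#' @return the run manifest (list), invisibly; written as `manifest.json`.
#' @export
run_all <- function(config, out_dir) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    if (!file.exists(config)) abort_config(sprintf("config not found: %s", config))
    config <- jsonlite::fromJSON(config, simplifyDataFrame = FALSE)
  }
  loci_cfg <- config$loci
  if (is.null(loci_cfg) || is.null(config$metadata))
    abort_config("analysis config needs 'loci' and 'metadata'")
  inputs <- c(vapply(loci_cfg, `[[`, character(1), "path"),
              config$metadata, config$divergence, config$overrides)
  missing_in <- inputs[!file.exists(unlist(inputs))]
  if (length(missing_in))
    abort_config(sprintf("missing input file(s): %s",
                         paste(missing_in, collapse = ", ")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  warnings_log <- character()
  outputs <- character()
  note <- function(msg) warnings_log <<- c(warnings_log, msg)
  emit <- function(path) { outputs <<- c(outputs, path); path }
  stage <- function(name, expr) {
    tryCatch(expr, semiperm_input_error = function(e) {
      note(sprintf("stage %s skipped: %s", name, conditionMessage(e)))
      NULL
    }, error = function(e) {
      semiperm_abort("stage_error",
                     sprintf("stage %s failed: %s", name, conditionMessage(e)))
    })
  }

  ## load
  haploid_loci <- vapply(loci_cfg, function(l) isTRUE(l$haploid), logical(1))
  haploid_loci <- vapply(loci_cfg, `[[`, character(1), "name")[haploid_loci]
  alignments <- stage("load", {
    out <- lapply(loci_cfg, function(l) read_locus_fasta(l$path, l$name))
    names(out) <- vapply(loci_cfg, `[[`, character(1), "name")
    out
  })
  samples <- stage("load", read_metadata_tsv(config$metadata))
  overrides <- if (!is.null(config$overrides))
    read.delim(config$overrides, stringsAsFactors = FALSE) else NULL
  map <- stage("load", build_sympatry_map(samples, overrides))

  ## stats
  stats <- stage("stats", all_population_stats(alignments, samples,
                                               haploid_loci))
  if (!is.null(stats))
    emit(write_stats_tsv(stats, file.path(out_dir, "population_stats.tsv")))

  ## divergence + NJ
  statistics <- unlist(config$statistics) %||% c("Dxy", "Da", "FST")
  n_pops <- nrow(unique(samples$records[c("species", "basin")]))
  trees_done <- FALSE
  if (n_pops >= 2L) {
    for (st in statistics) {
      for (sc in c("combined", names(alignments))) {
        dm <- stage("divergence",
                    divergence_matrix(alignments, samples, st, sc, haploid_loci))
        if (is.null(dm)) next
        tag <- if (sc == "combined") "combined" else sc
        emit(write_divergence_tsv(
          dm, file.path(out_dir, sprintf("divergence_%s_%s.tsv", st, tag))))
        if (any(is.na(dm$values)))
          note(sprintf("divergence %s/%s has undefined cells", st, tag))
      }
    }
    for (st in intersect(statistics, c("Dxy", "Da"))) {
      tr <- stage("njtree", {
        if (n_pops < 3L) abort_input("NJ needs >= 3 populations to be informative")
        bootstrap_support(alignments, samples, st,
                          B = config$bootstrap_B %||% 100L, seed = seed,
                          haploid_loci = haploid_loci)
      })
      if (!is.null(tr)) {
        emit(write_population_tree(
          tr, file.path(out_dir, sprintf("njtree_%s_combined.nwk", st))))
        if (attr(tr, "bootstrap_dropped") > 0)
          note(sprintf("njtree %s: %d bootstrap replicates dropped", st,
                       attr(tr, "bootstrap_dropped")))
        trees_done <- TRUE
      }
    }
  } else note("stage divergence skipped: single population")

  ## introgression
  summaries <- NULL
  introg <- stage("introgress", {
    nuclear <- setdiff(names(alignments), haploid_loci)
    if (length(nuclear) == 0L) abort_input("no nuclear loci")
    tabs <- lapply(alignments[nuclear], collapse_alleles, samples)
    div_tab <- if (!is.null(config$divergence))
      read_divergence_pairs_tsv(config$divergence) else NULL
    pair_rows <- list(); call_rows <- list()
    for (basin in names(map$basin_species)) {
      spp <- sort(map$basin_species[[basin]])
      if (length(spp) < 2L) next
      for (ij in utils::combn(length(spp), 2, simplify = FALSE)) {
        a <- spp[ij[1]]; b <- spp[ij[2]]
        if (!pair_sympatric(map, a, b, basin)) next
        excl <- exclude_loci_for_pair(a, b, tabs, map,
                                      unlist(config$manual_exclusions))
        calls <- tryCatch(
          classify_diagnostic_alleles(a, b, basin, tabs, map, excl),
          semiperm_unresolved_ancestry_error = function(e) {
            note(sprintf("pair (%s, %s) in %s skipped: %s", a, b, basin,
                         conditionMessage(e)))
            NULL
          })
        if (is.null(calls)) next
        divv <- if (!is.null(div_tab))
          tryCatch(pair_divergence_value(div_tab, a, b),
                   semiperm_input_error = function(e) NA_real_) else NA_real_
        pair_rows[[length(pair_rows) + 1L]] <- introgression_proportion(
          a, b, basin, calls, tabs, excl,
          mode = config$denominator_mode %||% "copies", divergence = divv)
        call_rows[[length(call_rows) + 1L]] <- calls
      }
    }
    if (length(pair_rows) == 0L) abort_input("no sympatric pairs to analyze")
    list(summaries = do.call(rbind, pair_rows),
         calls = do.call(rbind, call_rows))
  })
  if (!is.null(introg)) {
    summaries <- introg$summaries
    emit_tsv <- function(df, name) {
      p <- file.path(out_dir, name)
      write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(p)
    }
    emit_tsv(summaries, "introgression_pairs.tsv")
    if (nrow(introg$calls)) emit_tsv(introg$calls, "introgression_calls.tsv")
    ok <- !is.na(summaries$divergence)
    if (sum(ok) >= 3L) {
      tr <- stage("trend",
                  introgression_divergence_trend(summaries$proportion[ok],
                                                 summaries$divergence[ok]))
      if (!is.null(tr)) {
        p <- file.path(out_dir, "trend.json")
        jsonlite::write_json(tr, p, auto_unbox = TRUE, digits = NA)
        emit(p)
      }
    } else note("stage trend skipped: fewer than 3 pairs with divergence")
  }

  ## contrasts
  contrast <- stage("contrast",
                    sympatry_polymorphism_contrast(stats, map,
                                                   unlist(config$contrast_species)))
  if (!is.null(contrast))
    emit(write_contrast_tsv(contrast, file.path(out_dir, "sympatry_contrast.tsv")))

  manifest <- list(
    tool = "semiperm",
    version = as.character(utils::packageVersion("semiperm")),
    seed = seed,
    config_path = cfg_path,
    config = config,
    inputs = lapply(unlist(inputs), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = as.list(outputs),
    warnings = as.list(warnings_log))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}
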