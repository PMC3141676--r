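#' Run the full small-RNA analysis chain on a simulated study
#'
#' Chains the stages in flow order: adapter trimming and filtering,
#' collapsing to tags, exact all-hits genome mapping, priority
#' annotation, and hairpin miRNA discovery on the non-annotated and
#' known-miRNA homolog tags.  Used by the analysis drivers, the tests
#' and the acceptance script.
#'
#' @param sim output of [make_genome()].
#' @param libs output of [make_libraries()].
#' @param config the [synthetic_config()] used.
#' @param n_shuffles shuffle count for the precursor stability test.
#' @param discover run the discovery stage (the expensive part).
#' @return list with `clean` (per-library inserts), `dropped`, `tags`,
#'   `index`, `hits`, `calls`, `categories`, `mirna_report`.
#' @export
run_small_rna_pipeline <- function(sim, libs, config, n_shuffles = 199,
                                   discover = TRUE) {
  clean <- list(); dropped <- list()
  for (lib in names(libs$reads)) {
    tf <- trim_and_filter(libs$reads[[lib]], config$adapter3,
                          config$adapter5)
    clean[[lib]] <- unname(tf$inserts)
    dropped[[lib]] <- tf$dropped
  }
  tags <- collapse_reads(clean)
  index <- build_index(sim$genome)
  hits <- map_tags(tags, index)
  nci <- index_ncrna(sim$ncrna_refs)
  calls <- classify_tags(tags, hits, nci, sim$known_mirnas,
                         sim$gene_models)
  categories <- summarize_categories(calls, tags)
  report <- NULL
  if (discover) {
    cand_cats <- c("non_annotated", "known_miRNA")
    sel <- calls$category %in% cand_cats
    ctags <- tags[sel, , drop = FALSE]
    chits <- hits[hits$seq %in% ctags$seq, , drop = FALSE]
    report <- discover_mirnas(ctags, chits, sim$genome,
                              n_shuffles = n_shuffles)
  }
  list(clean = clean, dropped = dropped, tags = tags, index = index,
       hits = hits, calls = calls, categories = categories,
       mirna_report = report)
}

#' Planted-miRNA recovery on one simulated study
#'
#' Simulates a study at the given seed, runs the pipeline, and scores
#' discovery against the planted truth: sensitivity = accepted planted
#' mature tags / planted hairpins; false accepts = accepted tags whose
#' reads did not originate from a planted hairpin locus.
#'
#' @param seed simulation seed.
#' @param jitter 5'-end jitter probability.
#' @param n_shuffles shuffle count (smaller than the default keeps
#'   replicated runs fast without changing the decision structure).
#' @param ... further arguments to [synthetic_config()].
#' @return list: n_planted, n_recovered, false_accepts, report.
#' @export
planted_recovery <- function(seed, jitter = 0.1, n_shuffles = 99, ...) {
  cfg <- synthetic_config(seed = seed, five_prime_jitter = jitter, ...)
  sim <- make_genome(cfg)
  libs <- make_libraries(sim, cfg)
  res <- run_small_rna_pipeline(sim, libs, cfg, n_shuffles = n_shuffles)
  hp <- sim$truth[sim$truth$kind == "hairpin", , drop = FALSE]
  mature <- substr(
    hp$payload, hp$mature_start - hp$start + 1, hp$mature_end - hp$start + 1)
  # reads actually emitted from planted hairpin loci (jittered variants
  # included): any accepted tag among them counts as a planted recovery
  planted_reads <- unique(
    libs$truth_reads$insert[libs$truth_reads$kind == "mature"])
  acc <- res$mirna_report$seq
  recovered <- sum(mature %in% acc)
  false_acc <- sum(!(acc %in% planted_reads))
  list(n_planted = nrow(hp), n_recovered = recovered,
       false_accepts = false_acc, report = res$mirna_report)
}
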