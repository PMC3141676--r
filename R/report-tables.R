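#' Published summary counts bundled with the package
#'
#' The package ships the printed summary tables of the P. tricornutum
#' small-RNA sequencing study whose methodology this pipeline
#' implements: per-library read counts (three libraries -- normal,
#' nitrogen-limited, silicon-limited growth), per-category tag counts,
#' pairwise library overlap counts, and the 13-row precursor
#' characteristics table.  All derived percentages and summary
#' statistics are recomputed from these counts by the package's own
#' arithmetic helpers, never stored.
#'
#' @param which one of `"libraries"`, `"categories"`, `"overlap"`,
#'   `"precursors"`.
#' @return data.frame.
#' @export
published_counts <- function(which = c("libraries", "categories",
                                       "overlap", "precursors")) {
  which <- match.arg(which)
  f <- c(libraries = "published_library_counts.tsv",
         categories = "published_category_counts.tsv",
         overlap = "published_overlap_counts.tsv",
         precursors = "published_precursor_table.tsv")[[which]]
  path <- system.file("extdata", f, package = "srnapipe", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Library summary arithmetic from printed counts
#'
#' Recomputes the derived columns of a library summary table (singleton
#' share as whole percent) from raw counts.
#'
#' @param counts data.frame with columns sample, total, unique,
#'   singleton (as from `published_counts("libraries")`).
#' @return the input with a `singleton_pct` column appended.
#' @export
library_table <- function(counts = published_counts("libraries")) {
  counts$singleton_pct <- pct_whole(counts$singleton, counts$unique)
  counts
}

#' Category percentage arithmetic from printed counts
#'
#' @param counts data.frame with columns category plus `<lib>_unique`
#'   and `<lib>_total` count columns.
#' @return the input with two-decimal percentage columns appended
#'   (share of each library's total row).
#' @export
category_table <- function(counts = published_counts("categories")) {
  libs <- unique(sub("_(unique|total)$", "",
                     grep("_(unique|total)$", names(counts), value = TRUE)))
  tot <- counts[counts$category == "Total", , drop = FALSE]
  for (lib in libs) {
    for (kind in c("unique", "total")) {
      col <- paste0(lib, "_", kind)
      counts[[paste0(col, "_pct")]] <- pct2(counts[[col]], tot[[col]][1])
    }
  }
  counts
}

#' Pairwise overlap arithmetic from printed counts
#'
#' Recomputes the union of unique tags and the two-decimal percentage
#' columns of a pairwise overlap table.
#'
#' @param counts data.frame with columns pair, libA, libB,
#'   unique_a, unique_b, common_unique, total_a, total_b, common_total.
#' @return data.frame with union_unique, common_unique_pct,
#'   grand_total, common_total_pct appended.
#' @export
overlap_table <- function(counts = published_counts("overlap")) {
  counts$union_unique <- counts$unique_a + counts$unique_b -
    counts$common_unique
  counts$common_unique_pct <- pct2(counts$common_unique,
                                   counts$union_unique)
  counts$grand_total <- counts$total_a + counts$total_b
  counts$common_total_pct <- pct2(counts$common_total, counts$grand_total)
  counts
}
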