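test_that("candidate selection applies the read and hit-count thresholds", {
  tags <- tag_table(c("A1", "A2", "A3", "A4"),
                    L1 = c(2L, 1L, 50L, 3L), L2 = c(0L, 0L, 0L, 0L))
  tags$seq <- vapply(1:4, function(i) rand_seq(20), "")
  mk_hits <- function(seq, n) if (n == 0) NULL else
    data.frame(chrom = "c", strand = "+", start = seq_len(n) * 100L,
               end = seq_len(n) * 100L + 19L, seq = seq,
               stringsAsFactors = FALSE)
  hits <- do.call(rbind, c(list(mk_hits(tags$seq[1], 20)),
                           list(mk_hits(tags$seq[2], 1)),
                           list(mk_hits(tags$seq[3], 21)),
                           list(mk_hits(tags$seq[4], 0))))
  keep <- select_candidates(tags, hits)
  expect_identical(keep, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("window extraction clips at chromosome ends and flips minus-strand hits", {
  set.seed(71)
  g <- Biostrings::DNAStringSet(c(c1 = rand_seq(10000)))
  hit <- data.frame(chrom = "c1", strand = "+", start = 501L, end = 521L,
                    stringsAsFactors = FALSE)
  w <- extract_window(hit, g, 300)
  expect_equal(nchar(w$seq), 621)
  expect_equal(c(w$mature_start, w$mature_end), c(301, 321))
  expect_equal(substr(w$seq, 301, 321),
               substr(as.character(g[[1]]), 501, 521))
  # left clip
  hit2 <- data.frame(chrom = "c1", strand = "+", start = 51L, end = 71L,
                     stringsAsFactors = FALSE)
  w2 <- extract_window(hit2, g, 300)
  expect_equal(nchar(w2$seq), 371)
  expect_equal(c(w2$mature_start, w2$mature_end), c(51, 71))
  # minus strand: the window is the reverse complement of the plus slice
  hit3 <- data.frame(chrom = "c1", strand = "-", start = 501L, end = 521L,
                     stringsAsFactors = FALSE)
  w3 <- extract_window(hit3, g, 300)
  expect_equal(w3$seq, revcomp(substr(as.character(g[[1]]), 201, 821)))
  expect_equal(substr(w3$seq, w3$mature_start, w3$mature_end),
               revcomp(substr(as.character(g[[1]]), 501, 521)))
})

test_that("hairpin criteria accept a clean planted stem and report its defects", {
  set.seed(72)
  hp <- perfect_hairpin(24, 10)
  window <- list(seq = paste0(rand_seq(60), hp$seq, rand_seq(60)),
                 mature_start = 61L, mature_end = 61L + 23L)
  hc <- hairpin_check(window)
  expect_true(hc$accepted)
  expect_gte(hc$paired_bases, 16)
  expect_equal(hc$bulges, 0L)
  expect_lte(hc$precursor_mfe, -18)
  # the precursor interval contains mature and star plus 20-nt flanks
  expect_lte(hc$precursor_start, 41)
  expect_gte(hc$precursor_end, 61 + nchar(hp$seq) - 1)
})

test_that("a mature placed in the terminal loop is rejected as loop-spanning", {
  set.seed(73)
  arm <- rand_seq(30)
  hp <- paste0(arm, rand_seq(10), revcomp(arm))
  # mature straddling the loop: last 8 of arm + loop + first 6 of star
  window <- list(seq = paste0(rand_seq(50), hp, rand_seq(50)),
                 mature_start = 50L + 23L, mature_end = 50L + 46L)
  hc <- hairpin_check(window)
  expect_false(hc$accepted)
  expect_match(hc$reason, "loop-spanning")
})

test_that("unstructured windows fail on pairing or energy", {
  set.seed(74)
  window <- list(seq = strrep("A", 200), mature_start = 90L,
                 mature_end = 110L)
  hc <- hairpin_check(window)
  expect_false(hc$accepted)
  # mature length bounds enforced before any folding
  w2 <- list(seq = rand_seq(200), mature_start = 50L, mature_end = 80L)
  expect_equal(hairpin_check(w2)$reason, "mature-length")
})

test_that("5' homogeneity counts redundant reads on the mature strand", {
  tags <- tag_table(c("AAAAAAAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCCCCCCC",
                      "GGGGGGGGGGGGGGGGGGGG"),
                    L = c(3L, 1L, 5L))
  hits <- data.frame(
    chrom = "c1", strand = c("+", "+", "-"),
    start = c(1000L, 1001L, 1005L), end = c(1019L, 1020L, 1024L),
    seq = tags$seq, stringsAsFactors = FALSE)
  pre <- list(chrom = "c1", strand = "+", start = 950L, end = 1100L)
  h <- five_prime_homogeneity(tags, hits, pre, mature_p5 = 1000L, lib = "L")
  # 3 reads at the mature 5' end; the +1-shifted tag adds 1; the minus
  # read is not on the mature strand
  expect_equal(h$num, 3L)
  expect_equal(h$den, 4L)
  expect_equal(h$fraction, 0.75)
  none <- five_prime_homogeneity(tags, hits,
                                 list(chrom = "c2", strand = "+",
                                      start = 1L, end = 100L), 1L, "L")
  expect_equal(none$den, 0L)
  expect_equal(none$fraction, 0)
})

test_that("the p-value/homogeneity decision follows the two-threshold rule", {
  expect_true(decide_mirna(0.019, c(PT1 = 6 / 9, PT2 = 0))$accepted)
  expect_true(decide_mirna(0.801, c(PT1 = 0, PT2 = 69 / 71))$accepted)
  expect_false(decide_mirna(0.5, c(PT1 = 0.5))$accepted)
  expect_false(decide_mirna(0.04, c(PT1 = 0.5))$accepted)   # needs > 0.5
  expect_true(decide_mirna(0.5, c(PT1 = 0.75))$accepted)    # >= 0.75
  # monotone: raising homogeneity never flips accept -> reject
  set.seed(75)
  for (i in 1:200) {
    p <- runif(1)
    h1 <- runif(1); h2 <- h1 + runif(1, 0, 1 - h1)
    d1 <- decide_mirna(p, c(L = h1))$accepted
    d2 <- decide_mirna(p, c(L = h2))$accepted
    expect_false(d1 && !d2)
  }
})

test_that("end-to-end discovery recovers planted miRNAs on the cached study", {
  fx <- small_sim()
  res <- run_small_rna_pipeline(fx$sim, fx$libs, fx$cfg, n_shuffles = 99)
  hp <- fx$sim$truth[fx$sim$truth$kind == "hairpin", ]
  mature <- substr(hp$payload, hp$mature_start - hp$start + 1,
                   hp$mature_end - hp$start + 1)
  rep <- res$mirna_report
  expect_true(all(mature %in% rep$seq))
  # report invariants
  expect_true(all(rep$len == as.integer(vapply(strsplit(rep$location, ":"),
                                               `[`, "", 3)) -
                    as.integer(vapply(strsplit(rep$location, ":"), `[`, "", 2)) + 1))
  expect_true(all(rep$mfe <= -18))
  expect_true(all(rep$bulges <= 4))
  for (cell in unlist(rep[c("PT1", "PT2", "PT3")])) {
    nd <- as.integer(strsplit(cell, "/")[[1]])
    expect_lte(nd[1], nd[2])
  }
})

test_that("report summaries use floor-mean length and two-decimal MFE", {
  rep <- data.frame(len = c(101L, 160L, 278L), mfe = c(-30.4, -42.7, -78.8))
  s <- precursor_summary(rep)
  expect_equal(s$len_mean, floor(mean(c(101, 160, 278))))
  expect_equal(s$len_max, 278)
  expect_equal(s$mfe_min, -78.8)
  expect_equal(s$mfe_mean, round_half_up(mean(rep$mfe), 2))
  expect_equal(precursor_summary(rep[0, ])$n, 0L)
})

test_that("report files round-trip through the declared formats", {
  fx <- small_sim()
  res <- run_small_rna_pipeline(fx$sim, fx$libs, fx$cfg, n_shuffles = 49)
  dir <- tempfile("mirna")
  write_mirna_report(res$mirna_report, dir)
  tab <- read.delim(file.path(dir, "mirna_report.tsv"))
  expect_equal(nrow(tab), nrow(res$mirna_report))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "mirna_precursors.fa"))
  expect_equal(length(fa), nrow(res$mirna_report))
  unlink(dir, recursive = TRUE)
})
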