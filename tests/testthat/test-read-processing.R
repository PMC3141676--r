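AD3 <- "TCGTATGCCGTCTTCTGCTTG"

test_that("adapter trimming keeps read-through inserts and drops the rest", {
  ins20 <- strrep("ACGT", 5)
  reads <- c(paste0(ins20, AD3),                    # clean 20-nt insert
             paste0(rand_seq(15), AD3),             # too short
             rand_seq(36),                          # no adapter
             paste0(rand_seq(33), AD3))             # too long
  set.seed(3)
  tf <- trim_and_filter(reads, AD3)
  expect_identical(unname(tf$inserts), ins20)
  expect_equal(unname(tf$dropped["too_short"]), 1L)
  expect_equal(unname(tf$dropped["no_adapter"]), 1L)
  expect_equal(unname(tf$dropped["too_long"]), 1L)
  expect_error(trim_and_filter(reads, ""), "adapter3")
})

test_that("quality and N filtering drop reads without returning them", {
  reads <- c(paste0(strrep("ACGT", 5), AD3),
             paste0("ACGTNACGTACGTACGTACG", AD3))
  qual <- c(strrep("I", nchar(reads[1])),
            strrep("I", nchar(reads[2])))
  attr(reads, "quality") <- qual
  tf <- trim_and_filter(reads, AD3)
  expect_equal(length(tf$inserts), 1L)
  expect_equal(unname(tf$dropped["low_quality"]), 1L)
  # low phred score inside the insert
  reads2 <- rep(paste0(strrep("ACGT", 5), AD3), 2)
  q <- strrep("I", nchar(reads2[1]))
  attr(reads2, "quality") <- c(q, paste0("I!!", substr(q, 4, nchar(q))))
  tf2 <- trim_and_filter(reads2, AD3, min_quality = 20)
  expect_equal(length(tf2$inserts), 1L)
})

test_that("read counts are conserved through trim and collapse", {
  set.seed(41)
  pool <- vapply(1:30, function(i) rand_seq(sample(18:28, 1)), "")
  reads <- paste0(sample(pool, 100, replace = TRUE), AD3)
  tf <- trim_and_filter(reads, AD3)
  expect_equal(length(tf$inserts) + sum(tf$dropped), 100L)
  tags <- collapse_reads(list(L1 = unname(tf$inserts)))
  expect_equal(sum(tags$L1), length(tf$inserts))
  expect_false(any(duplicated(tags$seq)))
})

test_that("collapsing merges copies within and across libraries", {
  tags <- collapse_reads(list(A = c("ACGTACGTACGTACGTAC", "ACGTACGTACGTACGTAC",
                                    "ACGTACGTACGTACGTAC"),
                              B = c("ACGTACGTACGTACGTAC", "TTTTACGTACGTACGTAC")))
  expect_equal(nrow(tags), 2)
  i <- match("ACGTACGTACGTACGTAC", tags$seq)
  expect_equal(tags$A[i], 3L)
  expect_equal(tags$B[i], 1L)
})

test_that("library summaries report singleton shares as whole percents", {
  tags <- tag_table(vapply(1:8, function(i) rand_seq(20 + i %% 3), ""),
                    L = c(1L, 1L, 1L, 1L, 1L, 1L, 5L, 9L))
  s <- summarize_library(tags, "L")
  expect_equal(s$unique_tags, 8L)
  expect_equal(s$singleton_tags, 6L)
  expect_equal(s$singleton_pct, 75)
  expect_equal(s$total_reads, 20)
  expect_equal(sum(s$length_hist["unique", ]), 8)
  expect_equal(sum(s$length_hist["total", ]), 20)
  # all-singleton library
  t2 <- tag_table(c("ACGTACGTACGTACGTACGT", "TGCATGCATGCATGCATGCA"),
                  L = c(1L, 1L))
  expect_equal(summarize_library(t2, "L")$singleton_pct, 100)
})

test_that("positional base fractions behave under weighting", {
  t1 <- tag_table(strrep("A", 24), L = 1L)
  b <- position_base_bias(t1, "unique")
  expect_true(all(b["A", ] == 1))
  expect_true(all(abs(colSums(b) - 1) < 1e-12))
  # count weighting: 9 copies vs 1 copy diverging at position 1
  t2 <- tag_table(c(paste0("A", strrep("C", 19)), paste0("G", strrep("C", 19))),
                  L = c(9L, 1L))
  bt <- position_base_bias(t2, "total")
  expect_equal(unname(bt["A", 1]), 0.9)
  expect_equal(unname(bt["G", 1]), 0.1)
  # near-uniform composition for many random tags
  set.seed(42)
  t3 <- tag_table(vapply(1:4000, function(i) rand_seq(24), ""),
                  L = rep(1L, 4000))
  bu <- position_base_bias(t3, "unique")
  sigma <- sqrt(0.25 * 0.75 / 4000)
  expect_true(all(abs(bu - 0.25) < 3 * sigma + 1e-9))
})

test_that("pairwise sample comparison reports overlap both ways", {
  set.seed(43)
  shared <- vapply(1:5, function(i) rand_seq(20), "")
  onlyA <- vapply(1:3, function(i) rand_seq(21), "")
  onlyB <- vapply(1:2, function(i) rand_seq(22), "")
  tags <- collapse_reads(list(
    A = c(rep(shared, 2), onlyA),          # shared counted twice in A
    B = c(shared, onlyB, onlyB)))
  cmp <- compare_samples(tags, "A", "B")
  expect_equal(cmp$unique_srna[1], 10)               # union 5+3+2
  expect_equal(cmp$unique_srna[2], 5)                # common
  expect_equal(cmp$unique_pct[2], 50)
  expect_equal(cmp$total_srna[2], 10 + 5)            # shared redundant reads
  # symmetry of the common counts
  cmp2 <- compare_samples(tags, "B", "A")
  expect_equal(cmp2$unique_srna[2], cmp$unique_srna[2])
  expect_equal(cmp2$total_srna[2], cmp$total_srna[2])
  # identical and disjoint libraries
  t3 <- collapse_reads(list(A = shared, B = shared))
  c3 <- compare_samples(t3, "A", "B")
  expect_equal(c3$unique_pct[2], 100)
  t4 <- collapse_reads(list(A = onlyA, B = onlyB))
  c4 <- compare_samples(t4, "A", "B")
  expect_equal(c4$unique_srna[2], 0)
  expect_equal(c4$unique_srna[3], 3)
  expect_equal(c4$unique_srna[4], 2)
})
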