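make_refs <- function(...) {
  recs <- list(...)
  seqs <- vapply(recs, `[[`, "", "seq")
  names(seqs) <- vapply(recs, `[[`, "", "name")
  list(seqs = seqs,
       meta = data.frame(name = names(seqs),
                         class = vapply(recs, `[[`, "", "class"),
                         source = vapply(recs, `[[`, "", "source"),
                         stringsAsFactors = FALSE))
}

test_that("noncoding-RNA matching finds exact fragments and honours source priority", {
  set.seed(61)
  rr <- rand_seq(200)
  refs <- make_refs(list(name = "rA", class = "rRNA", source = "genbank",
                         seq = rr),
                    list(name = "tB", class = "tRNA", source = "rfam",
                         seq = paste0(rand_seq(30), substr(rr, 50, 90),
                                      rand_seq(30))))
  idx <- index_ncrna(refs)
  # exact 21-nt fragment of the genbank rRNA, also present in the rfam
  # tRNA record: genbank wins
  frag <- substr(rr, 60, 80)
  hit <- match_ncrna(frag, idx)
  expect_equal(hit$class, "rRNA")
  expect_equal(hit$source, "genbank")
  expect_equal(hit$identity, 1)
  # random tags: nothing, confirmed against a direct scan
  for (i in 1:20) {
    tag <- rand_seq(22)
    h <- match_ncrna(tag, idx)
    in_ref <- any(vapply(refs$seqs, function(s)
      grepl(tag, s, fixed = TRUE), logical(1)))
    if (is.null(h)) expect_false(in_ref)
    else expect_gte(h$identity, 0.9)
  }
})

test_that("near-matches require >= 16 nt at >= 90% identity", {
  set.seed(62)
  rr <- rand_seq(120)
  refs <- make_refs(list(name = "r", class = "rRNA", source = "genbank",
                         seq = rr))
  idx <- index_ncrna(refs)
  frag <- substr(rr, 20, 41)  # 22 nt
  # two substitutions at the ends of the fragment: a clean 16+ core remains
  mut <- frag
  substr(mut, 1, 1) <- if (substr(mut, 1, 1) == "A") "C" else "A"
  expect_false(is.null(match_ncrna(mut, idx)))
  # a 15-nt exact island only: below the length floor
  short <- paste0(rand_seq(4), substr(rr, 50, 64), rand_seq(4))
  h <- match_ncrna(short, idx)
  if (!is.null(h)) expect_gte(h$length, 16)
})

test_that("known-miRNA homology tolerates 2 mismatches or 90% identity", {
  m <- c(mirX = "ACGTACGTACGTACGTACGT")  # 20 nt
  expect_equal(match_known_mirna("ACGTACGTACGTACGTACGT", m)$mismatches, 0)
  two <- "TCGTACGTACGTACGTACGA"
  expect_equal(match_known_mirna(two, m)$mismatches, 2)
  three <- "TCGTACGTACCTACGTACGA"          # 3 of 20 = 85% identity
  expect_null(match_known_mirna(three, m))
  # sliding absorbs a length difference of up to 2
  expect_false(is.null(match_known_mirna(paste0("GG", m[[1]]), m)))
  expect_null(match_known_mirna(paste0("GGG", m[[1]]), m))
})

test_that("gene overlap requires full containment and ranks exon over intron", {
  gm <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(101, 301), c(200, 400)),
    strand = c("+", "+"), type = c("exon", "intron"), gene_id = "g1")
  hit <- function(s, e, strand = "+")
    data.frame(chrom = "c1", strand = strand, start = s, end = e,
               stringsAsFactors = FALSE)
  expect_equal(classify_gene_overlap(hit(120, 140), gm), "exon_sense")
  expect_equal(classify_gene_overlap(hit(120, 140, "-"), gm), "exon_antisense")
  expect_equal(classify_gene_overlap(hit(310, 330, "-"), gm), "intron_antisense")
  # straddling the exon-intron boundary: no evidence
  expect_null(classify_gene_overlap(hit(190, 210), gm))
  # one exonic and one intronic hit: exon wins
  two <- rbind(hit(310, 330), hit(120, 140))
  expect_equal(classify_gene_overlap(two, gm), "exon_sense")
})

test_that("siRNA duplex detection demands the 2-nt 3' overhang geometry", {
  set.seed(63)
  a <- rand_seq(21)
  b <- paste0(revcomp(substr(a, 1, 19)), rand_seq(2))
  expect_true(is_sirna_duplex(a, b))
  expect_true(is_sirna_duplex(b, a))
  blunt <- revcomp(a)
  expect_false(is_sirna_duplex(a, blunt))
  found <- find_sirna_pairs(tag_table(c(a, b, blunt, rand_seq(21)),
                                      L = rep(1L, 4)))
  expect_equal(nrow(found), 1)
  expect_setequal(c(found$tagA, found$tagB), c(a, b))
  # random tags: any reported pair must satisfy the geometry predicate
  rnd <- tag_table(unique(vapply(1:500, function(i) rand_seq(21), "")))
  rnd$L <- 1L
  prs <- find_sirna_pairs(rnd)
  if (nrow(prs))
    expect_true(all(mapply(is_sirna_duplex, prs$tagA, prs$tagB)))
})

test_that("the priority chain decides every tag exactly once", {
  fx <- small_sim()
  res <- run_small_rna_pipeline(fx$sim, fx$libs, fx$cfg, discover = FALSE)
  calls <- res$calls
  expect_equal(nrow(calls), nrow(res$tags))
  expect_false(any(is.na(calls$category)))
  # expected truth categories are recovered for planted reads
  tr <- fx$libs$truth_reads
  nc_frag <- unique(tr$insert[tr$kind == "ncrna_frag"])
  got <- calls$category[match(nc_frag, calls$seq)]
  expect_true(all(got %in% c("rRNA", "tRNA", "snRNA", "snoRNA")))
  si <- unique(tr$insert[tr$kind == "sirna"])
  expect_true(all(calls$category[match(si, calls$seq)] == "siRNA"))
  km <- unique(tr$insert[tr$kind == "known_mirna"])
  expect_true(all(calls$category[match(km, calls$seq)] == "known_miRNA"))
  # category table partitions each library
  cat_tab <- res$categories
  for (lib in c("PT1", "PT2", "PT3")) {
    u <- cat_tab[[paste0(lib, "_unique")]]
    expect_equal(sum(u[-1]), u[1])
    t <- cat_tab[[paste0(lib, "_total")]]
    expect_equal(sum(t[-1]), t[1])
  }
})

test_that("priority is independent of evidence arrival order", {
  # a tag that is simultaneously an rRNA fragment and inside an exon
  set.seed(64)
  rr <- rand_seq(150)
  refs <- make_refs(list(name = "r", class = "rRNA", source = "genbank",
                         seq = rr))
  idx <- index_ncrna(refs)
  tag <- substr(rr, 40, 60)
  gm <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 300), strand = "+",
                               type = "exon", gene_id = "g")
  hits <- data.frame(chrom = "c1", strand = "+", start = 50L, end = 70L,
                     seq = tag, stringsAsFactors = FALSE)
  tags <- tag_table(tag, L = 2L)
  calls <- classify_tags(tags, hits, idx, c(m = rand_seq(21)), gm)
  expect_equal(calls$category, "rRNA")
})

test_that("phasing statistic separates phased from unphased loci", {
  set.seed(65)
  mk <- function(starts) data.frame(chrom = "c", strand = "+",
                                    start = starts, end = starts + 20L,
                                    stringsAsFactors = FALSE)
  perfect <- phasing_statistic(mk(21 * (1:30)), n_perm = 199)
  expect_equal(perfect$score, 1)
  expect_lt(perfect$p_value, 0.01)
  unif <- phasing_statistic(mk(sample(1000:5000, 210, replace = TRUE)),
                            n_perm = 199)
  expect_lt(unif$score, 0.2)
  expect_gt(unif$p_value, 0.05)
  mostly <- c(21 * sample(1:100, 90, replace = TRUE),
              sample(1000:2000, 10))
  ph <- phasing_statistic(mk(mostly), n_perm = 199)
  expect_lt(ph$p_value, 0.01)
})

test_that("repeat overlap counts distinct contained tags only", {
  reps <- GenomicRanges::GRanges("c1", IRanges::IRanges(1000, 1200))
  hits <- data.frame(
    chrom = "c1", strand = "+",
    start = c(1010L, 1050L, 1100L, 1190L, 500L),
    end = c(1030L, 1070L, 1120L, 1210L, 520L),
    seq = c("T1", "T1", "T1", "T2", "T3"),
    stringsAsFactors = FALSE)
  # T1 contained three times -> counts once; T2 straddles the boundary;
  # T3 is elsewhere
  expect_equal(repeat_overlap(hits, reps), 1L)
  expect_equal(repeat_overlap(hits, GenomicRanges::GRanges()), 0L)
})
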