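test_that("configuration is validated", {
  expect_error(synthetic_config(five_prime_jitter = 1.5), "jitter")
  expect_error(synthetic_config(mature_len_range = c(16, 24)), "mature_len_range")
  expect_error(synthetic_config(n_hairpin_loci = -1), "counts")
  expect_error(synthetic_config(adapter3 = ""), "adapter3")
})

test_that("regeneration with the same seed is byte-identical", {
  cfg <- synthetic_config(seed = 77)
  a <- make_genome(cfg); b <- make_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  la <- make_libraries(a, cfg); lb <- make_libraries(b, cfg)
  expect_identical(la$reads, lb$reads)
  expect_identical(la$truth_reads, lb$truth_reads)
})

test_that("planted payloads equal genome substrings (reverse-complemented on minus)", {
  fx <- small_sim()
  g <- as.character(fx$sim$genome)
  tr <- fx$sim$truth
  for (r in seq_len(nrow(tr))) {
    sub <- substr(g[[tr$chrom[r]]], tr$start[r], tr$end[r])
    if (tr$strand[r] == "-") sub <- revcomp(sub)
    expect_identical(tr$payload[r], sub, label = tr$name[r])
  }
})

test_that("the inverted-repeat pair are exact reverse complements", {
  fx <- small_sim()
  ir <- fx$sim$truth[fx$sim$truth$kind == "inverted_repeat", ]
  expect_equal(nrow(ir), 2)
  expect_identical(ir$payload[1], revcomp(ir$payload[2]))
})

test_that("every planted hairpin passes the hairpin criteria at its truth coordinates", {
  fx <- small_sim()
  hp <- fx$sim$truth[fx$sim$truth$kind == "hairpin", ]
  for (r in seq_len(nrow(hp))) {
    hit <- data.frame(chrom = hp$chrom[r], strand = hp$strand[r],
                      start = hp$mature_start[r], end = hp$mature_end[r],
                      stringsAsFactors = FALSE)
    win <- extract_window(hit, fx$sim$genome, 300)
    hc <- hairpin_check(win)
    expect_true(hc$accepted, label = hp$name[r])
    expect_gte(hc$paired_bases, 16)
    expect_lte(hc$bulges, 4)
    expect_lte(hc$precursor_mfe, -18)
  }
})

test_that("siRNA loci are emitted as duplexes with 2-nt 3' overhangs", {
  fx <- small_sim()
  si <- fx$sim$truth[fx$sim$truth$kind == "siRNA_pair", ]
  expect_equal(nrow(si), 2 * fx$cfg$n_sirna_pairs)
  locus <- sub("_(plus|minus)$", "", si$name)
  for (l in unique(locus)) {
    pair <- si[locus == l, ]
    expect_true(is_sirna_duplex(pair$payload[1], pair$payload[2]))
  }
})

test_that("insert lengths span [18, 28] and reads carry the 3' adapter", {
  fx <- small_sim()
  tr <- fx$libs$truth_reads
  real <- tr[!(tr$kind %in% c("too_short", "no_adapter")), ]
  expect_true(all(nchar(real$insert) >= 18 & nchar(real$insert) <= 28))
  # every well-formed read is insert + adapter prefix, truncated
  raw <- fx$libs$reads[[1]]
  tr1 <- tr[tr$library == names(fx$libs$reads)[1], ]
  ok <- tr1$kind != "no_adapter"
  expect_true(all(startsWith(raw[tr1$read_id[ok]], tr1$insert[ok])))
})

test_that("5' jitter hits its configured rate", {
  cfg <- synthetic_config(seed = 55, five_prime_jitter = 0.4,
                          nb_mean = 120, nb_size = 20)
  sim <- make_genome(cfg)
  libs <- make_libraries(sim, cfg)
  tr <- libs$truth_reads[libs$truth_reads$kind == "mature", ]
  n <- nrow(tr); k <- sum(tr$shifted)
  expect_gte(n, 500)
  # binomial 99% interval around 0.4
  bounds <- qbinom(c(0.005, 0.995), n, 0.4) / n
  expect_gte(k / n, bounds[1])
  expect_lte(k / n, bounds[2])
})

test_that("jitter zero means every mature read shares the planted 5' end", {
  cfg <- synthetic_config(seed = 56, five_prime_jitter = 0)
  sim <- make_genome(cfg)
  libs <- make_libraries(sim, cfg)
  tr <- libs$truth_reads[libs$truth_reads$kind == "mature", ]
  expect_gt(nrow(tr), 0)
  expect_false(any(tr$shifted))
  hp <- sim$truth[sim$truth$kind == "hairpin", ]
  mature <- substr(hp$payload, hp$mature_start - hp$start + 1,
                   hp$mature_end - hp$start + 1)
  expect_true(all(tr$insert %in% mature))
})

test_that("an overfull chromosome raises a sizing error naming the feature", {
  cfg <- synthetic_config(seed = 1, chrom_length = 900, n_hairpin_loci = 6)
  expect_error(make_genome(cfg), "too short")
})

test_that("simulation round-trips through the standard file formats", {
  fx <- small_sim()
  dir <- tempfile("simio")
  write_simulation(fx$sim, fx$libs, dir)
  g2 <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_identical(as.character(g2), as.character(fx$sim$genome))
  r2 <- read_fastq_reads(file.path(dir, "PT1.fastq"))
  expect_identical(unname(c(r2)), unname(c(fx$libs$reads$PT1)))
  gff <- rtracklayer::import(file.path(dir, "genes.gff3"))
  expect_equal(length(gff), length(fx$sim$gene_models))
  unlink(dir, recursive = TRUE)
})
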