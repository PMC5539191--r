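test_that("plastome construction obeys the LSC-IR-SSC-IR architecture", {
  tr <- make_plastome(20000L, 5000L, 4000L, seed = 2L)
  expect_equal(nchar(tr$circle), 34000L)
  # the two IR copies are exact reverse complements at their positions
  expect_equal(substr(tr$circle, 20001L, 25000L), tr$ir)
  expect_equal(substr(tr$circle, 29001L, 34000L), brute_revcomp(tr$ir))
  expect_identical(make_plastome(20000L, 5000L, 4000L, seed = 2L)$circle,
                   tr$circle)
  expect_false(identical(make_plastome(20000L, 5000L, 4000L, seed = 3L)$circle,
                         tr$circle))
  # IR expansion: SSC may be absent
  tr0 <- make_plastome(2000L, 500L, 0L, seed = 4L)
  expect_equal(nchar(tr0$circle), 3000L)
  expect_error(make_plastome(100L, 0L, 0L))
})

test_that("nuclear repeat families inflate their k-mer frequencies", {
  nuc <- make_nuclear(50000L, list(c(500L, 40L)), seed = 5L)
  expect_equal(nchar(nuc), 50000L)
  tab <- count_kmers(nuc, 31L)
  # the repeat unit contributes k-mers at ~40 copies vs 1 for the backbone
  expect_gte(max(tab$count), 30L)
  expect_equal(as.integer(stats::median(tab$count)), 1L)
  expect_identical(make_nuclear(50000L, list(c(500L, 40L)), seed = 5L), nuc)
  expect_error(make_nuclear(1000L, list(c(500L, 40L))), "repeat content")
  plain <- make_nuclear(20000L, seed = 6L)
  expect_equal(max(count_kmers(plain, 31L)$count), 1L)
})

test_that("read counts follow coverage and ids carry origin labels", {
  tr <- make_plastome(3000L, 1000L, 800L, seed = 7L)
  nuc <- make_nuclear(20000L, seed = 8L)
  p <- read_sim_params(seed = 9L, plastome_coverage = 50,
                       nuclear_coverage = 4)
  rs <- simulate_reads(tr, nuc, p)
  exp_cp <- round(50 * nchar(tr$circle) / (2 * p$read_length))
  exp_nuc <- round(4 * nchar(nuc) / (2 * p$read_length))
  expect_equal(n_pairs(rs), exp_cp + exp_nuc)
  expect_equal(sum(startsWith(rs$pairs$id1, "cp_")), exp_cp)
  expect_equal(sum(startsWith(rs$pairs$id1, "nuc_")), exp_nuc)
  expect_identical(simulate_reads(tr, nuc, p)$pairs, rs$pairs)
})

test_that("error-free plastome reads are substrings of the doubled circle", {
  tr <- make_plastome(3000L, 1000L, 800L, seed = 10L)
  rs <- simulate_reads(tr, NULL, read_sim_params(seed = 11L, error_rate = 0,
                                                 plastome_coverage = 10))
  doubled <- paste0(tr$circle, tr$circle)
  for (s in utils::head(c(rs$pairs$seq1, rs$pairs$seq2), 200L)) {
    expect_true(grepl(s, doubled, fixed = TRUE) ||
                  grepl(brute_revcomp(s), doubled, fixed = TRUE))
  }
  # and their k-mer table contains nothing absent from the circle
  reads_tab <- count_kmers(rs, 31L)
  circle_tab <- count_kmers(paste0(tr$circle,
                                   substr(tr$circle, 1L, 500L)), 31L)
  expect_true(all(reads_tab$kmer %in% circle_tab$kmer))
})

test_that("substitution errors grow the singleton volume, not the peaks", {
  tr <- make_plastome(3000L, 1000L, 800L, seed = 12L)
  h_of <- function(cov) {
    rs <- simulate_reads(tr, NULL, read_sim_params(seed = 13L,
                                                   error_rate = 0.01,
                                                   plastome_coverage = cov))
    kmer_histogram(count_kmers(rs, 31L))$rows
  }
  h50 <- h_of(50)
  h100 <- h_of(100)
  vol1 <- function(h) h$volume[h$frequency == 1L]
  expect_gt(vol1(h100), vol1(h50))
})

test_that("a coverage hole suppresses fragments overlapping it", {
  tr <- make_plastome(3000L, 1000L, 800L, seed = 14L)
  hole <- c(2000L, 2600L)
  rs <- simulate_reads(tr, NULL,
                       read_sim_params(seed = 15L, error_rate = 0,
                                       plastome_coverage = 50,
                                       coverage_hole = hole))
  probe <- substr(tr$circle, 2270L, 2319L) # 50 bp in the middle of the hole
  hits <- sum(grepl(probe, c(rs$pairs$seq1, rs$pairs$seq2), fixed = TRUE)) +
    sum(grepl(brute_revcomp(probe), c(rs$pairs$seq1, rs$pairs$seq2),
              fixed = TRUE))
  expect_equal(hits, 0L)
})
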