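test_that("canonicalization follows the middle-base rule", {
  expect_equal(canonical_kmer("CAT"), "CAT")    # middle A: unchanged
  expect_equal(canonical_kmer("ATG"), "CAT")    # middle T: flipped
  expect_equal(canonical_kmer("AAGAA"), "TTCTT") # middle G: flipped
  expect_error(canonical_kmer("ACGT"), "odd")
  expect_error(canonical_kmer("ANG"), class = "plastid_ambiguous_kmer")
})

test_that("canonicalization agrees with brute force over all 3- and 5-mers", {
  for (k in c(3L, 5L)) {
    all_kmers <- do.call(paste0, expand.grid(rep(list(BASES), k)))
    got <- canonical_kmer(all_kmers)
    want <- vapply(all_kmers, brute_canonical, character(1),
                   USE.NAMES = FALSE)
    expect_equal(got, want)
    # exactly one of {s, revcomp(s)} is canonical; the map is idempotent
    # and strand-symmetric
    rc <- vapply(all_kmers, brute_revcomp, character(1), USE.NAMES = FALSE)
    mid <- function(x) substr(x, (k + 1L) %/% 2L, (k + 1L) %/% 2L)
    expect_true(all(xor(mid(all_kmers) %in% c("A", "C"),
                        mid(rc) %in% c("A", "C"))))
    expect_equal(canonical_kmer(got), got)
    expect_equal(canonical_kmer(rc), got)
  }
})

test_that("counting tallies every window under canonicalization", {
  tab <- count_kmers("ACGT", 3L)
  expect_equal(tab$kmer, "ACG") # windows ACG and CGT -> canonical ACG
  expect_equal(tab$count, 2L)
  expect_equal(length(count_kmers("AC", 3L)$kmer), 0L)
  # strand symmetry: adding the reverse complement doubles every count
  s <- random_reads(1L, 60L, seed = 5L)
  one <- count_kmers(s, 7L)
  both <- count_kmers(c(s, brute_revcomp(s)), 7L)
  expect_equal(both$kmer, one$kmer)
  expect_equal(both$count, 2L * one$count)
})

test_that("counts match a brute-force recount and conserve window totals", {
  for (i in 1:20) {
    k <- c(3L, 5L, 7L)[i %% 3L + 1L]
    seqs <- random_reads(5L, 30L, seed = 100L + i, with_n = (i %% 2L == 0L))
    tab <- count_kmers(seqs, k)
    want <- brute_count(seqs, k)
    expect_equal(tab$kmer, want$kmer)
    expect_equal(tab$count, want$count)
    # conservation: counted + skipped == total windows
    total <- sum(pmax(0L, nchar(seqs) - k + 1L))
    expect_equal(sum(tab$count) + attr(tab, "skipped"), total)
  }
})

test_that("histogram rows satisfy volume = distinct * frequency", {
  h <- kmer_histogram(kmer_table(c("ACA", "ACC", "TCA"), c(2L, 2L, 5L)))
  expect_equal(h$rows$frequency, c(2L, 5L))
  expect_equal(h$rows$distinct, c(2L, 1L))
  expect_equal(h$rows$volume, c(4, 5))
  expect_equal(nrow(kmer_histogram(kmer_table(character(0),
                                              integer(0)))$rows), 0L)
  # all singletons: one row at f=1 with volume == distinct
  t1 <- kmer_table(c("ACA", "ACC", "ACG"), c(1L, 1L, 1L))
  h1 <- kmer_histogram(t1)
  expect_equal(h1$rows$frequency, 1L)
  expect_equal(h1$rows$volume, h1$rows$distinct)
  # property: histogram of counted reads reproduces a brute recount
  for (i in 1:10) {
    seqs <- random_reads(4L, 25L, seed = 300L + i)
    tab <- count_kmers(seqs, 5L)
    h <- kmer_histogram(tab)
    expect_true(all(h$rows$volume == h$rows$distinct * h$rows$frequency))
    expect_equal(sum(h$rows$distinct), length(tab$kmer))
    expect_equal(sum(h$rows$volume), sum(tab$count))
  }
})

test_that("frequency-band selection subsets and partitions the table", {
  tab <- count_kmers(random_reads(10L, 40L, seed = 9L), 5L)
  sel <- select_kmers_by_frequency(tab, 2L, 3L)
  expect_true(all(sel$count >= 2L & sel$count <= 3L))
  ident <- select_kmers_by_frequency(tab, 1L, Inf)
  expect_equal(ident$kmer, tab$kmer)
  # partition: [1,b] plus [b+1,max] recovers the full table
  lo <- select_kmers_by_frequency(tab, 1L, 2L)
  hi <- select_kmers_by_frequency(tab, 3L, Inf)
  expect_equal(sort(c(lo$kmer, hi$kmer), method = "radix"), tab$kmer)
  expect_error(select_kmers_by_frequency(tab, 5L, 2L))
})

test_that("table difference keeps entries absent from the positive table", {
  pos <- kmer_table("ACA", 9L)
  other <- kmer_table(c("ACA", "ACG"), c(2L, 3L))
  d <- table_difference(pos, other)
  expect_equal(d$kmer, "ACG")
  expect_equal(d$count, 3L)
  expect_equal(table_difference(kmer_table(character(0), integer(0)),
                                other)$kmer, other$kmer)
  expect_equal(length(table_difference(other, pos)$kmer), 0L)
  expect_error(table_difference(kmer_table("ACAGA", 1L), other), "different k")
})
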