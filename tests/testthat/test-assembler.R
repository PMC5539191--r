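test_that("a uniquely covered sequence assembles into itself", {
  s <- random_reads(1L, 100L, seed = 3L)
  rs <- read_set(singles = data.frame(id = paste0("r", 1:10),
                                      seq = rep(s, 10L),
                                      qual = strrep("I", 100L),
                                      stringsAsFactors = FALSE))
  asm <- debruijn_assemble(rs, 63L, min_edge_coverage = 3L)
  expect_equal(n_scaffolds(asm), 1L)
  expect_true(asm$scaffolds[[1]] == s || asm$scaffolds[[1]] == brute_revcomp(s))
})

test_that("error-free tiling reads reconstruct a linear template exactly", {
  template <- random_reads(1L, 5000L, seed = 11L)
  rs <- tiling_reads(template)
  # error-free input: no coverage cutoff, so the 1x-covered template ends
  # survive; K = 81 exercises the wide-K string-graph path
  for (K in c(63L, 81L)) {
    asm <- debruijn_assemble(rs, K, min_edge_coverage = 1L)
    expect_equal(n_scaffolds(asm), 1L)
    got <- asm$scaffolds[[1]]
    expect_true(got == template || got == brute_revcomp(template))
  }
})

test_that("reads from a circular template cover the whole circle", {
  circle <- random_reads(1L, 5000L, seed = 12L)
  rs <- tiling_reads(paste0(circle, substr(circle, 1L, 150L)))
  K <- 63L
  asm <- debruijn_assemble(rs, K, min_edge_coverage = 1L)
  expect_equal(n_scaffolds(asm), 1L)
  # the cycle is emitted with a K-1 self-overlap; merging closes it
  expect_gte(nchar(asm$scaffolds[[1]]), 5000L - K + 1L)
  closed <- overlap_merge(asm, min_overlap = 50L)
  expect_true(closed$circular)
  expect_equal(nchar(closed$scaffolds[[1]]), 5000L)
  expect_equal(circular_identity(closed, circle), 1)
})

test_that("the assembly sweep covers every batch x K combination", {
  fx <- small_fixture()
  batches <- batch_subsample(fx$reads, 2000L, 2000L, seed = 1L)
  cfg <- small_config()
  sw <- sweep_assemble(batches, c(21L, 31L), cfg)
  expect_equal(length(sw), length(batches) * 2L)
  provs <- t(vapply(sw, function(a)
    c(a$provenance$K, a$provenance$batch_size), integer(2)))
  expect_equal(sort(unique(provs[, 1])), c(21L, 31L))
  # a failing adapter skips pairs without aborting the sweep
  sw_fail <- sweep_assemble(batches, c(21L, 31L), cfg,
                            assemble_fn = function(b, K) stop("boom"))
  expect_equal(length(sw_fail), 0L)
  one <- sweep_assemble(batches[1], 21L, cfg)
  expect_equal(length(one), 1L)
})

test_that("homology filter keeps reference-like scaffolds only", {
  ref <- random_reads(1L, 2000L, seed = 21L)
  genuine <- substr(ref, 301L, 1500L)
  noise <- random_reads(1L, 1200L, seed = 22L)
  asm <- assembly(c(genuine, noise), provenance = list(K = 31L))
  kept <- filter_homology(asm, ref)
  expect_equal(unname(kept$scaffolds), genuine)
  # no reference: identity
  expect_equal(filter_homology(asm, NULL)$scaffolds, asm$scaffolds)
})

test_that("size filter drops scaffolds smaller than twice K", {
  withr::with_seed(1L, {
    s125 <- paste(sample(BASES, 125L, replace = TRUE), collapse = "")
    s126 <- paste(sample(BASES, 126L, replace = TRUE), collapse = "")
  })
  asm <- assembly(c(s125, s126), provenance = list(K = 63L))
  out <- filter_size(asm)
  expect_equal(unname(out$scaffolds), s126)
  expect_equal(n_scaffolds(filter_size(assembly(s125,
                                                provenance = list(K = 63L)))),
               0L)
  expect_equal(filter_size(assembly(s126, provenance = list(K = 63L)))$scaffolds[[1]],
               s126)
})

test_that("homology and size filters commute", {
  ref <- random_reads(1L, 3000L, seed = 23L)
  scafs <- c(substr(ref, 1L, 1000L),    # genuine, long
             substr(ref, 1200L, 1299L), # genuine, short
             random_reads(1L, 800L, seed = 24L),  # noise, long
             random_reads(1L, 90L, seed = 25L))   # noise, short
  asm <- assembly(scafs, provenance = list(K = 63L))
  a <- filter_size(filter_homology(asm, ref))
  b <- filter_homology(filter_size(asm), ref)
  expect_equal(a$scaffolds, b$scaffolds)
})

test_that("assembly length sanity check brackets plausible plastomes", {
  ranges <- pipeline_config()$size_ranges
  expect_true(sanity_check(mock_assembly(1L, 0L, 155461L), ranges))
  expect_false(sanity_check(mock_assembly(1L, 0L, 10000L), ranges))
  expect_false(sanity_check(mock_assembly(1L, 0L, 400000L), ranges))
})

test_that("ranking modes order candidates as documented", {
  a <- mock_assembly(1L, 0L, 150000L, seed = 1L)
  b <- mock_assembly(2L, 0L, 160000L, seed = 2L)
  # lexicographic: scaffold count dominates
  expect_equal(rank_assemblies(list(a, b), "lexicographic")$scaffolds,
               a$scaffolds)
  c1 <- mock_assembly(1L, 3L, 150000L, seed = 3L)
  c2 <- mock_assembly(2L, 0L, 150000L, seed = 4L)
  # scaffolds_plus_gaps: 2 + 0 beats 1 + 3
  expect_equal(rank_assemblies(list(c1, c2), "scaffolds_plus_gaps")$scaffolds,
               c2$scaffolds)
  # but lexicographic still prefers the single scaffold
  expect_equal(rank_assemblies(list(c1, c2), "lexicographic")$scaffolds,
               c1$scaffolds)
  single <- rank_assemblies(list(a), "lexicographic")
  expect_equal(single$scaffolds, a$scaffolds)
  expect_error(rank_assemblies(list()), "no assembly")
})

test_that("ranking is a deterministic total order", {
  cands <- lapply(1:8, function(i)
    mock_assembly(1L + i %% 3L, i %% 2L, 140000L + 1000L * (i %% 5L),
                  seed = i))
  for (mode in c("lexicographic", "scaffolds_plus_gaps")) {
    keys <- lapply(cands, plastid:::rank_key, mode = mode)
    cmp <- plastid:::compare_keys
    for (i in seq_along(keys)) for (j in seq_along(keys)) {
      # antisymmetry
      expect_equal(cmp(keys[[i]], keys[[j]]), -cmp(keys[[j]], keys[[i]]))
      for (l in seq_along(keys)) {
        # transitivity
        if (cmp(keys[[i]], keys[[j]]) <= 0L && cmp(keys[[j]], keys[[l]]) <= 0L)
          expect_lte(cmp(keys[[i]], keys[[l]]), 0L)
      }
    }
    best1 <- rank_assemblies(cands, mode)
    best2 <- rank_assemblies(cands, mode)
    expect_identical(best1$scaffolds, best2$scaffolds)
  }
})
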