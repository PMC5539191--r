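test_that("the internal mapper places reads exactly", {
  fx <- small_fixture()
  cc <- fx$truth$circle
  asm <- assembly(substr(cc, 1L, 3000L))
  # verbatim read
  rs <- read_set(singles = data.frame(
    id = c("fwd", "rev", "hang"),
    seq = c(substr(cc, 501L, 600L),
            brute_revcomp(substr(cc, 501L, 600L)),
            substr(cc, 2951L, 3050L)), # overhangs the right end by 50
    qual = strrep("I", 100L), stringsAsFactors = FALSE))
  aln <- map_reads(rs, asm, seed_len = 21L)$singles
  expect_equal(aln$pos[1], 500L)
  expect_equal(aln$strand[1], 1L)
  expect_equal(aln$mismatches[1], 0L)
  # reverse complement: same interval, opposite strand
  expect_equal(aln$pos[2], 500L)
  expect_equal(aln$strand[2], -1L)
  # end overhang is clipped and reported
  expect_equal(aln$pos[3], 2950L)
  expect_equal(aln$overhang_right[3], 50L)
  expect_equal(aln$overhang_left[3], 0L)
})

test_that("gap contexts flank every N run, truncated at scaffold ends", {
  s <- paste0(rand_dna(2000L, 1L), strrep("N", 100L),
              rand_dna(2000L, 2L))
  asm <- assembly(s)
  ctx <- extract_gap_contexts(asm, 500L)
  expect_length(ctx, 1L)
  expect_equal(nchar(ctx[[1]]$left_flank), 500L)
  expect_equal(nchar(ctx[[1]]$right_flank), 500L)
  expect_equal(ctx[[1]]$gap_start, 2001L)
  expect_equal(paste0(ctx[[1]]$left_flank, strrep("N", 100L),
                      ctx[[1]]$right_flank),
               substr(s, ctx[[1]]$region_start, ctx[[1]]$region_end))
  # gap 50 bases from the scaffold start: left flank truncates to 50
  s2 <- paste0(rand_dna(50L, 3L), strrep("N", 20L),
               rand_dna(900L, 4L))
  ctx2 <- extract_gap_contexts(assembly(s2), 500L)
  expect_equal(nchar(ctx2[[1]]$left_flank), 50L)
  # gap-free assembly: no contexts
  expect_length(extract_gap_contexts(assembly(rand_dna(500L, 5L))),
                0L)
})

test_that("stage 2 assembles band-selected reads into the plastome arcs", {
  fx <- small_fixture()
  cfg <- small_config(seed = 5L)
  tab <- count_kmers(fx$reads, cfg$k_count)
  pc <- detect_peaks(kmer_histogram(tab))
  best <- run_stage2(fx$reads, pc$band, cfg, table = tab)
  expect_lte(n_scaffolds(best), 3L)
  expect_equal(n_gaps(best), 0L)
  arcs <- nchar(fx$truth$lsc) + nchar(fx$truth$ir) + nchar(fx$truth$ssc)
  expect_gt(total_length(best), 0.98 * arcs)
  expect_lt(total_length(best), nchar(fx$truth$circle))
  expect_true(is.data.frame(attr(best, "sweep_stats")))
  expect_error(run_stage2(fx$reads, c(100000, 100001), cfg, table = tab),
               "band")
})

test_that("stage 3 refines to a circular assembly matching the truth", {
  fx <- small_fixture()
  cfg <- small_config(seed = 6L)
  tab <- count_kmers(fx$reads, cfg$k_count)
  pc <- detect_peaks(kmer_histogram(tab))
  s2 <- run_stage2(fx$reads, pc$band, cfg, table = tab)
  st <- run_stage3(fx$reads, s2, cfg)
  expect_true(st$best$circular)
  expect_equal(st$terminated_because, "circular")
  expect_equal(truth_identity(st$best, fx$truth), 1)
  # monotone quality across accepted iterations
  h <- st$history
  if (nrow(h) > 1L) {
    expect_true(all(diff(h$n_scaffolds) <= 0L | diff(h$total_length) > 0L))
  }
  # a circular seed terminates immediately
  done <- run_stage3(fx$reads, st$best, cfg)
  expect_equal(done$terminated_because, "circular")
  expect_equal(done$iteration, 0L)
})

test_that("stage 3 drops contamination that attracts no reads", {
  fx <- small_fixture()
  cfg <- small_config(seed = 7L, max_iterations = 3L)
  contaminated <- assembly(c(fx$truth$lsc, fx$truth$ir, fx$truth$ssc,
                             rand_dna(800L, 99L)),
                           provenance = list(K = 21L))
  st <- run_stage3(fx$reads, contaminated, cfg)
  expect_lt(n_scaffolds(st$best), n_scaffolds(contaminated))
  expect_equal(truth_identity(st$best, fx$truth), 1)
})

test_that("stage 3 respects an iteration limit of one", {
  fx <- small_fixture()
  cfg <- small_config(seed = 8L, max_iterations = 1L)
  seed_asm <- assembly(c(fx$truth$lsc, fx$truth$ir, fx$truth$ssc),
                       provenance = list(K = 21L))
  st <- run_stage3(fx$reads, seed_asm, cfg)
  expect_lte(st$iteration, 1L)
})

test_that("stage 4 is skipped for circular input and stalls without spanning reads", {
  fx <- small_fixture()
  cfg <- small_config(seed = 9L)
  circ <- assembly(fx$truth$circle, circular = TRUE)
  st <- run_stage4(fx$reads, circ, cfg)
  expect_equal(st$terminated_because, "circular")
  expect_identical(st$best$scaffolds, circ$scaffolds)
  # a coverage hole wider than the insert leaves nothing to span
  hole <- c(1500L, 2400L)
  rs_hole <- simulate_reads(fx$truth, NULL,
                            read_sim_params(seed = 77L, error_rate = 0,
                                            plastome_coverage = 60,
                                            coverage_hole = hole))
  cc <- fx$truth$circle
  split_asm <- assembly(c(substr(cc, 2500L, nchar(cc)),
                          substr(cc, 1L, 1400L)))
  st2 <- run_stage4(rs_hole, split_asm, cfg)
  # the origin-side junction is fully covered and may be rejoined, but the
  # hole itself can never be spanned or circularized
  expect_false(st2$best$circular)
  expect_equal(st2$terminated_because, "no_improvement")
})

test_that("stage 5 returns gap-free assemblies untouched", {
  fx <- small_fixture()
  cfg <- small_config(seed = 10L)
  asm <- assembly(fx$truth$circle, circular = TRUE)
  st <- run_stage5(fx$reads, asm, cfg)
  expect_equal(st$terminated_because, "all_gaps_closed")
  expect_identical(st$best$scaffolds, asm$scaffolds)
})

test_that("stage 5 closes a punched gap exactly and leaves other bases alone", {
  fx <- small_fixture()
  cfg <- small_config(seed = 11L)
  cc <- fx$truth$circle
  gapped <- paste0(substr(cc, 1L, 2000L), strrep("N", 150L),
                   substr(cc, 2151L, nchar(cc)))
  st <- run_stage5(fx$reads, assembly(gapped), cfg)
  expect_equal(st$terminated_because, "all_gaps_closed")
  expect_equal(st$best$scaffolds[[1]], cc)
})

test_that("the full pipeline is deterministic given one seed", {
  fx <- small_fixture()
  cfg <- small_config(seed = 12L)
  r1 <- run_pipeline(fx$reads, cfg)
  r2 <- run_pipeline(fx$reads, cfg)
  expect_identical(r1$final$scaffolds, r2$final$scaffolds)
  expect_identical(r1$band, r2$band)
  expect_true(r1$final$circular)
  expect_equal(truth_identity(r1$final, fx$truth), 1)
  expect_false(is.null(r1$layout))
})

test_that("stop_after halts the pipeline at the requested stage", {
  fx <- small_fixture()
  cfg <- small_config(seed = 13L)
  r <- run_pipeline(fx$reads, cfg, stop_after = 1L)
  expect_null(r$final)
  expect_gt(length(r$table$kmer), 0L)
  expect_gt(nrow(r$histogram$rows), 0L)
  # without auto band detection the pipeline halts asking for a band
  cfg_manual <- small_config(seed = 13L, auto_band = FALSE)
  expect_error(run_pipeline(fx$reads, cfg_manual), "band")
})

test_that("pipeline artifacts are persisted per stage", {
  fx <- small_fixture()
  cfg <- small_config(seed = 14L)
  out <- withr::local_tempdir()
  r <- run_pipeline(fx$reads, cfg, out_dir = out)
  expect_true(file.exists(file.path(out, "stage1_hist_bin25.tsv")))
  expect_true(file.exists(file.path(out, "stage2_sweep.tsv")))
  expect_true(file.exists(file.path(out, "final.fasta")))
  expect_true(file.exists(file.path(out, "run_manifest.json")))
  fasta <- read_fasta(file.path(out, "final.fasta"))
  expect_equal(unname(nchar(fasta)), unname(nchar(r$final$scaffolds)))
})
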