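test_that("exact end overlaps merge pairwise and close self-overlaps", {
  a <- rand_dna(600L, 1L)
  b <- paste0(substr(a, 501L, 600L), rand_dna(400L, 2L)) # 100 bp overlap
  m <- overlap_merge(assembly(c(a, b)), min_overlap = 50L)
  expect_equal(n_scaffolds(m), 1L)
  expect_equal(nchar(m$scaffolds[[1]]), 600L + 500L - 100L)
  # reverse-complemented partner merges too
  m2 <- overlap_merge(assembly(c(a, brute_revcomp(b))), min_overlap = 50L)
  expect_equal(nchar(m2$scaffolds[[1]]), 1000L)
  # a scaffold whose last 100 bp equal its first 100 bp becomes a circle
  s <- rand_dna(900L, 3L)
  circ <- paste0(s, substr(s, 1L, 100L))
  mc <- overlap_merge(assembly(circ), min_overlap = 50L)
  expect_true(mc$circular)
  expect_equal(nchar(mc$scaffolds[[1]]), 900L)
  # unmergeable scaffolds pass through
  lone <- overlap_merge(assembly(c(a, rand_dna(300L, 4L))),
                        min_overlap = 50L)
  expect_equal(n_scaffolds(lone), 2L)
})

test_that("contained scaffolds are absorbed", {
  a <- rand_dna(1000L, 5L)
  inner <- substr(a, 200L, 700L)
  m <- overlap_merge(assembly(c(a, inner)), min_overlap = 50L)
  expect_equal(unname(m$scaffolds), a)
  m2 <- overlap_merge(assembly(c(a, brute_revcomp(inner))),
                      min_overlap = 50L)
  expect_equal(unname(m2$scaffolds), a)
})

test_that("overlapping thirds of a plastome circle reassemble the truth", {
  tr <- make_plastome(3000L, 1000L, 800L, seed = 6L)
  cc <- tr$circle
  L <- nchar(cc)
  lsc_end <- 3000L
  # LSC + 500 into IR; IR tail + SSC + 500 into IR'; IR' tail + 200 into LSC
  p1 <- substr(cc, 1L, lsc_end + 500L)
  p2 <- substr(cc, lsc_end + 301L, lsc_end + 1000L + 800L + 500L)
  p3 <- paste0(substr(cc, lsc_end + 1000L + 800L + 301L, L),
               substr(cc, 1L, 200L))
  m <- overlap_merge(assembly(c(p1, p2, p3)), min_overlap = 50L)
  expect_true(m$circular)
  expect_equal(nchar(m$scaffolds[[1]]), L)
  expect_equal(circular_identity(m, cc), 1)
})

test_that("a shared IR fragment is duplicated into both junctions", {
  tr <- make_plastome(3000L, 1000L, 800L, seed = 7L)
  ov <- 30L
  # unitig-style fragments: single-copy arcs reach ov bases into each IR
  # copy, while the IR itself is one fragment used in two contexts
  lsc_u <- paste0(brute_revcomp(substr(tr$ir, 1L, ov)), tr$lsc,
                  substr(tr$ir, 1L, ov))
  ssc_u <- paste0(substr(tr$ir, 1000L - ov + 1L, 1000L), tr$ssc,
                  brute_revcomp(substr(tr$ir, 1000L - ov + 1L, 1000L)))
  m <- overlap_merge(assembly(c(lsc_u, tr$ir, ssc_u)), min_overlap = ov)
  expect_true(m$circular)
  expect_equal(nchar(m$scaffolds[[1]]), nchar(tr$circle))
  expect_gte(max(vapply(plastome_orientations(tr),
                        function(cc) circular_identity(m, cc), numeric(1))),
             1)
})

test_that("merging never edits non-junction bases", {
  a <- rand_dna(500L, 8L)
  b <- paste0(substr(a, 401L, 500L), rand_dna(300L, 9L))
  m <- overlap_merge(assembly(c(a, b)), min_overlap = 50L)
  s <- m$scaffolds[[1]]
  expect_true(grepl(a, s, fixed = TRUE) || grepl(brute_revcomp(a), s,
                                                 fixed = TRUE))
  expect_true(grepl(b, s, fixed = TRUE) || grepl(brute_revcomp(b), s,
                                                 fixed = TRUE))
})

test_that("pseudo-circularization duplicates the first n bases", {
  s <- rand_dna(800L, 10L)
  circ <- assembly(s, circular = TRUE)
  p <- pseudo_circularize(circ, 150L)
  expect_false(p$circular)
  expect_equal(nchar(p$scaffolds[[1]]), 950L)
  expect_equal(substr(p$scaffolds[[1]], 801L, 950L), substr(s, 1L, 150L))
  expect_equal(nchar(pseudo_circularize(circ, 0L)$scaffolds[[1]]), 800L)
  expect_error(pseudo_circularize(circ, 801L))
  expect_error(pseudo_circularize(assembly(s), 10L), "circular")
})

test_that("inverted repeat detection recovers the constructed layout", {
  tr <- exact_plastome(3000L, 1000L, 800L, seed = 11L)
  ir <- find_inverted_repeat(tr$circle, min_length = 500L)
  expect_equal(ir$ir_length, 1000L)
  expect_equal(ir$ir_starts, c(3001L, 4801L))
  expect_equal(ir$lsc_length, 3000L)
  expect_equal(ir$ssc_length, 800L)
  # rotation invariance: lengths survive an arbitrary rotation
  rot <- paste0(substr(tr$circle, 2501L, nchar(tr$circle)),
                substr(tr$circle, 1L, 2500L))
  ir2 <- find_inverted_repeat(rot, min_length = 500L)
  expect_equal(ir2$ir_length, 1000L)
  expect_equal(ir2$lsc_length, 3000L)
  expect_equal(ir2$ssc_length, 800L)
  # no qualifying self-reverse-complement: classed error
  expect_error(find_inverted_repeat(rand_dna(10000L, 12L),
                                    min_length = 1000L),
               class = "plastid_no_ir")
})

# brute force: longest maximal revcomp interval pair via anti-diagonal runs
brute_ir <- function(s, min_len) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best <- NULL
  for (d in 2:(2L * n)) { # i + j = d, match when ch[i] == comp(ch[j])
    i <- max(1L, d - n)
    run <- 0L
    while (i <= min(n, d - 1L)) {
      j <- d - i
      if (j >= 1L && j <= n && ch[i] == comp[[ch[j]]]) run <- run + 1L
      else run <- 0L
      # a run ending at (i, j) spans i-run+1..i matched to j..j+run-1
      if (run > 0L) {
        i1 <- i - run + 1L
        j1 <- d - i1
        l <- min(run, floor((j1 - i1 + 1L) / 2L)) # trim to disjoint halves
        if (l >= min_len && (is.null(best) || l > best[3]))
          best <- c(i1, j1 - l + 1L, l)
      }
      i <- i + 1L
    }
  }
  best
}

test_that("IR search agrees with a quadratic brute force on small circles", {
  for (seed in 13:15) {
    tr <- exact_plastome(220L, 80L, 60L, seed)
    s <- tr$circle
    got <- find_inverted_repeat(s, min_length = 50L, seed_k = 13L)
    want <- brute_ir(s, 50L)
    expect_equal(got$ir_length, want[3])
    expect_equal(got$ir_starts, sort(c(want[1], want[2])))
  }
})

test_that("layout outputs honour the SSC orientation ambiguity", {
  tr <- exact_plastome(3000L, 1000L, 800L, seed = 16L)
  asm <- assembly(tr$circle, circular = TRUE)
  three <- layout_outputs(asm, "three_linear", ir_min_length = 500L)
  expect_equal(vapply(three$sequences, nchar, integer(1)),
               c(LSC = 3000L, IR = 1000L, SSC = 800L))
  expect_equal(three$lsc, tr$lsc)
  two <- layout_outputs(asm, "two_circular", ir_min_length = 500L)
  expect_equal(sort(unname(vapply(two$sequences, nchar, integer(1)))),
               rep(nchar(tr$circle), 2L))
  expect_equal(sort(unname(unlist(two$sequences))),
               sort(plastome_orientations(tr)))
  one_a <- layout_outputs(asm, "one_circular", ir_min_length = 500L,
                          seed = 4L)
  one_b <- layout_outputs(asm, "one_circular", ir_min_length = 500L,
                          seed = 4L)
  expect_identical(one_a$sequences, one_b$sequences)
  expect_error(layout_outputs(assembly(tr$lsc), "three_linear"), "circular")
})

test_that("connectivity joins bridge supported ends with N runs", {
  a <- rand_dna(800L, 17L)
  b <- rand_dna(700L, 18L)
  asm <- assembly(c(a, b))
  cm <- structure(list(links = data.frame(
    end1 = "scaffold_1|right", end2 = "scaffold_2|left", count = 10L,
    stringsAsFactors = FALSE)), class = "connectivity_matrix")
  out <- rescaffold_with_matrix(asm, cm, min_support = 3L, gap_n = 100L)
  expect_equal(n_scaffolds(out), 1L)
  expect_equal(out$scaffolds[[1]], paste0(a, strrep("N", 100L), b))
  expect_equal(n_gaps(out), 1L)
  # below min_support: unchanged
  cm_lo <- structure(list(links = within(cm$links, count <- 2L)),
                     class = "connectivity_matrix")
  expect_equal(rescaffold_with_matrix(asm, cm_lo, 3L)$scaffolds,
               asm$scaffolds)
})

test_that("a linked chain of three scaffolds closes into a circle", {
  a <- rand_dna(600L, 19L)
  b <- rand_dna(500L, 20L)
  c3 <- rand_dna(400L, 21L)
  asm <- assembly(c(a, b, c3))
  cm <- structure(list(links = data.frame(
    end1 = c("scaffold_1|right", "scaffold_2|right", "scaffold_1|left"),
    end2 = c("scaffold_2|left", "scaffold_3|left", "scaffold_3|right"),
    count = c(9L, 8L, 7L), stringsAsFactors = FALSE)),
    class = "connectivity_matrix")
  out <- rescaffold_with_matrix(asm, cm, min_support = 3L, gap_n = 50L)
  expect_equal(n_scaffolds(out), 1L)
  expect_true(out$circular)
  expect_equal(n_gaps(out), 3L)
  expect_equal(nchar(out$scaffolds[[1]]), 600L + 500L + 400L + 3L * 50L)
})

test_that("spanning pairs from a split circle are counted between facing ends", {
  fx <- small_fixture()
  cc <- fx$truth$circle
  asm <- assembly(c(substr(cc, 1L, 2800L), substr(cc, 2801L, nchar(cc))))
  cm <- build_connectivity_matrix(fx$reads, asm, seed_len = 17L,
                                  end_window = 400L)
  expect_gt(nrow(cm$links), 0L)
  # both true junctions of the split circle are supported: the cut and the
  # wrap around the origin
  keys <- paste(cm$links$end1, cm$links$end2)
  cut <- match("scaffold_1|right scaffold_2|left", keys)
  origin <- match("scaffold_1|left scaffold_2|right", keys)
  expect_false(is.na(cut))
  expect_false(is.na(origin))
  expect_gte(cm$links$count[cut], 3L)
  expect_gte(cm$links$count[origin], 3L)
})
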