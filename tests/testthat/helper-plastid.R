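# Brute-force oracles and shared fixtures.

BASES <- c("A", "C", "G", "T")

brute_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# independent middle-base canonicalization
brute_canonical <- function(w) {
  k <- nchar(w)
  mid <- substr(w, (k + 1L) %/% 2L, (k + 1L) %/% 2L)
  if (mid %in% c("A", "C")) w else brute_revcomp(w)
}

# enumerate windows, skip those with N, tally canonical forms
brute_count <- function(seqs, k) {
  ws <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }))
  ws <- ws[!grepl("[^ACGT]", ws)]
  if (!length(ws)) return(list(kmer = character(0), count = integer(0)))
  can <- vapply(ws, brute_canonical, character(1), USE.NAMES = FALSE)
  t <- table(can)
  o <- order(names(t), method = "radix")
  list(kmer = names(t)[o], count = as.integer(t)[o])
}

rand_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(BASES, n, replace = TRUE),
                               collapse = ""))
}

random_reads <- function(n, len, seed, with_n = FALSE) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(BASES, len, replace = TRUE), collapse = ""), character(1))
    if (with_n) {
      hit <- runif(n) < 0.3
      for (i in which(hit)) {
        p <- sample.int(len, 1L)
        substr(seqs[i], p, p) <- "N"
      }
    }
    seqs
  })
}

# a single-end read set tiling a linear template on both strands
tiling_reads <- function(template, read_len = 100L, step = 2L) {
  n <- nchar(template)
  starts <- seq(1L, n - read_len + 1L, by = step)
  fwd <- substring(template, starts, starts + read_len - 1L)
  rev <- vapply(fwd, brute_revcomp, character(1), USE.NAMES = FALSE)
  seqs <- as.vector(rbind(fwd, rev))
  read_set(singles = data.frame(id = paste0("t", seq_along(seqs)),
                                seq = seqs, qual = strrep("I", read_len),
                                stringsAsFactors = FALSE))
}

# best identity of an assembly against a simulated plastome, over both SSC
# orientations
truth_identity <- function(asm, truth) {
  max(vapply(plastome_orientations(truth),
             function(cc) circular_identity(asm, cc), numeric(1)))
}

# small simulated genome for fast stage-level tests
small_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 31L, error_rate = 0, coverage = 60) {
    key <- paste(seed, error_rate, coverage, sep = "_")
    if (is.null(cache[[key]])) {
      truth <- make_plastome(3000L, 1000L, 800L, seed = seed)
      reads <- simulate_reads(truth, NULL,
                              read_sim_params(seed = seed + 1L,
                                              error_rate = error_rate,
                                              plastome_coverage = coverage))
      cache[[key]] <- list(truth = truth, reads = reads)
    }
    cache[[key]]
  }
})

small_config <- function(...) {
  toy_profile(K_values = c(21L, 31L), batch_start = 5000L,
              batch_increment = 5000L,
              size_ranges = list(total = c(3000, 12000),
                                 lsc = c(1000, 6000), ssc = c(0, 3000),
                                 ir = c(500, 3000)), ...)
}

# the standard toy conditions of the acceptance checks: a 34 kb plastome
# at 100x with 1% substitution errors over a 100 kb nuclear background
# at 2x
toy_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 7L, with_nuclear = TRUE) {
    key <- paste(seed, with_nuclear, sep = "_")
    if (is.null(cache[[key]])) {
      truth <- make_plastome(20000L, 5000L, 4000L, seed = seed)
      nuclear <- if (with_nuclear) make_nuclear(100000L, seed = seed + 1L)
      reads <- simulate_reads(truth, nuclear,
                              read_sim_params(seed = seed + 2L))
      cache[[key]] <- list(truth = truth, nuclear = nuclear, reads = reads)
    }
    cache[[key]]
  }
})

# a plastome whose planted IR is exactly maximal: chance extension of the
# IR match across a junction needs the flanking bases to be complementary,
# so pinning the first and last base of each single-copy arc to A blocks it
exact_plastome <- function(lsc_len, ir_len, ssc_len, seed) {
  pin <- function(s) {
    substr(s, 1L, 1L) <- "A"
    substr(s, nchar(s), nchar(s)) <- "A"
    s
  }
  lsc <- pin(rand_dna(lsc_len, seed))
  ir <- rand_dna(ir_len, seed + 50L)
  ssc <- pin(rand_dna(ssc_len, seed + 100L))
  structure(list(lsc = lsc, ir = ir, ssc = ssc,
                 circle = paste0(lsc, ir, ssc, brute_revcomp(ir))),
            class = "plastome_truth")
}

# build an assembly with prescribed scaffold count, gap count and exact
# total length; gaps (10 N each) are distributed round-robin
mock_assembly <- function(n_scaf, n_gaps, total_len, K = 63L, seed = 1L) {
  withr::with_seed(seed, {
    rand <- function(n) paste(sample(BASES, n, replace = TRUE),
                              collapse = "")
    lens <- rep(total_len %/% n_scaf, n_scaf)
    lens[1] <- lens[1] + total_len - sum(lens)
    gaps_in <- tabulate(rep(seq_len(n_scaf), length.out = n_gaps), n_scaf)
    seqs <- vapply(seq_len(n_scaf), function(i) {
      g <- gaps_in[i]
      body_len <- lens[i] - 10L * g
      part <- body_len %/% (g + 1L)
      parts <- c(rep(part, g), body_len - g * part)
      paste(vapply(parts, rand, character(1)), collapse = strrep("N", 10L))
    }, character(1))
    asm <- assembly(seqs, provenance = list(K = K))
    stopifnot(total_length(asm) == total_len, n_gaps(asm) == n_gaps)
    asm
  })
}
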