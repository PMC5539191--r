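# Ground-truth simulator: a synthetic plastome with LSC-IR-SSC-IR
# architecture at high copy number, a nuclear background with repeat
# families, and paired-end reads with substitution errors and origin labels
# in the read ids.

random_dna <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a plastome with LSC-IR-SSC-IR architecture
#'
#' Uniform-random LSC, IR and SSC sequences arranged on a circle as
#' LSC + IR + SSC + revcomp(IR), so that IR-derived k-mers occur at twice
#' the single-copy frequency. Deterministic per seed. `ssc_len = 0` yields
#' an IR-expansion-like genome.
#'
#' @param lsc_len,ir_len,ssc_len region lengths in bases
#'   (`lsc_len >= ssc_len >= 0`, `ir_len > 0`).
#' @param seed integer seed.
#' @return object of class `plastome_truth` with fields `lsc`, `ir`, `ssc`,
#'   `circle`.
#' @export
make_plastome <- function(lsc_len = 20000L, ir_len = 5000L, ssc_len = 4000L,
                          seed = 1L) {
  stopifnot(lsc_len >= ssc_len, ssc_len >= 0L, ir_len > 0L)
  parts <- withr::with_seed(seed, list(lsc = random_dna(lsc_len),
                                       ir = random_dna(ir_len),
                                       ssc = random_dna(ssc_len)))
  circle <- paste0(parts$lsc, parts$ir, parts$ssc, cpp_revcomp(parts$ir))
  structure(c(parts, list(circle = circle)), class = "plastome_truth")
}

#' @export
print.plastome_truth <- function(x, ...) {
  cat(sprintf("plastome_truth: LSC %d + IR %d + SSC %d + IR' %d = %d bp circle\n",
              nchar(x$lsc), nchar(x$ir), nchar(x$ssc), nchar(x$ir),
              nchar(x$circle)))
  invisible(x)
}

#' Simulate a nuclear background sequence with repeat families
#'
#' A uniform-random backbone with repeat units inserted at stated copy
#' numbers, so that a family's k-mers occur at roughly copy_number times
#' the background frequency in reads — allowing deliberate collisions with
#' the chloroplast frequency band.
#'
#' @param size total sequence length (bases), at least the summed repeat
#'   content.
#' @param repeat_families list of `c(unit_length, copy_number)` pairs.
#' @param seed integer seed.
#' @return a character sequence of length `size`.
#' @export
make_nuclear <- function(size = 100000L, repeat_families = list(),
                         seed = 1L) {
  rep_total <- sum(vapply(repeat_families,
                          function(f) as.integer(f[1]) * as.integer(f[2]),
                          integer(1)))
  if (size < rep_total)
    stop("size must be at least the summed repeat content", call. = FALSE)
  withr::with_seed(seed, {
    backbone <- random_dna(size - rep_total)
    pieces <- backbone
    for (f in repeat_families) {
      unit <- random_dna(as.integer(f[1]))
      for (i in seq_len(as.integer(f[2]))) {
        at <- sample.int(nchar(pieces) + 1L, 1L) - 1L
        pieces <- paste0(substr(pieces, 1L, at), unit,
                         substr(pieces, at + 1L, nchar(pieces)))
      }
    }
    pieces
  })
}

#' Read-simulation parameters
#'
#' @param read_length read length in bases (100 bp paired-end by default).
#' @param insert_mean,insert_sd fragment-size distribution
#'   (`insert_mean >= read_length`).
#' @param error_rate per-base substitution error rate.
#' @param plastome_coverage per-base coverage of the plastome single-copy
#'   regions.
#' @param nuclear_coverage per-base coverage of the nuclear background.
#' @param coverage_hole optional `c(start, end)` (1-based, on the plastome
#'   circle): fragments overlapping this interval are not sampled,
#'   emulating systematic sequence-dependent coverage loss.
#' @param seed integer seed.
#' @return list of class `read_sim_params`.
#' @export
read_sim_params <- function(read_length = 100L, insert_mean = 300L,
                            insert_sd = 30L, error_rate = 0.01,
                            plastome_coverage = 100, nuclear_coverage = 2,
                            coverage_hole = NULL, seed = 1L) {
  stopifnot(insert_mean >= read_length, error_rate >= 0,
            plastome_coverage >= 0, nuclear_coverage >= 0)
  structure(list(read_length = as.integer(read_length),
                 insert_mean = as.integer(insert_mean),
                 insert_sd = as.numeric(insert_sd),
                 error_rate = as.numeric(error_rate),
                 plastome_coverage = as.numeric(plastome_coverage),
                 nuclear_coverage = as.numeric(nuclear_coverage),
                 coverage_hole = coverage_hole,
                 seed = as.integer(seed)), class = "read_sim_params")
}

# sample fragments from a (possibly circular) template and emit mate pairs;
# ids are "<label>_<i>_<start>" with 1-based fragment start
sample_pairs <- function(template, circular, n, params, label,
                         hole = NULL) {
  rl <- params$read_length
  L <- nchar(template)
  if (n == 0L || L < rl)
    return(data.frame(id1 = character(), seq1 = character(),
                      qual1 = character(), id2 = character(),
                      seq2 = character(), qual2 = character(),
                      stringsAsFactors = FALSE))
  flen <- pmax(rl, pmin(round(rnorm(n, params$insert_mean, params$insert_sd)), L))
  tpl <- if (circular) paste0(template, substr(template, 1L, max(flen)))
  else template
  start <- if (circular) sample.int(L, n, replace = TRUE)
  else sample.int(max(1L, L - flen + 1L), n, replace = TRUE)
  if (!circular) {
    over <- start + flen - 1L > L
    start[over] <- pmax(1L, L - flen[over] + 1L)
  }
  if (!is.null(hole)) {
    # reject fragments overlapping the hole (on the circle)
    keep <- rep(TRUE, n)
    for (i in seq_len(n)) {
      if (circ_overlap(start[i] - 1L, flen[i], hole[1] - 1L,
                       hole[2] - hole[1] + 1L, L)) keep[i] <- FALSE
    }
    start <- start[keep]
    flen <- flen[keep]
    n <- sum(keep)
  }
  frag <- substr(rep(tpl, n), start, start + flen - 1L)
  m1 <- substr(frag, 1L, rl)
  m2 <- vapply(substr(frag, flen - rl + 1L, flen), cpp_revcomp, character(1),
               USE.NAMES = FALSE)
  # the fragment itself comes from either strand
  flip <- runif(n) < 0.5
  tmp <- m1[flip]
  m1[flip] <- m2[flip]
  m2[flip] <- tmp
  add_errors <- function(seqs) {
    if (params$error_rate == 0 || !length(seqs)) return(seqs)
    nb <- length(seqs) * rl
    hit <- which(runif(nb) < params$error_rate)
    if (!length(hit)) return(seqs)
    ri <- (hit - 1L) %/% rl + 1L
    pi <- (hit - 1L) %% rl + 1L
    for (j in seq_along(hit)) {
      old <- substr(seqs[ri[j]], pi[j], pi[j])
      new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      substr(seqs[ri[j]], pi[j], pi[j]) <- new
    }
    seqs
  }
  m1 <- add_errors(m1)
  m2 <- add_errors(m2)
  q <- strrep("I", rl)
  ids <- sprintf("%s_%d_%d", label, seq_len(n), start)
  data.frame(id1 = paste0(ids, "/1"), seq1 = m1, qual1 = q,
             id2 = paste0(ids, "/2"), seq2 = m2, qual2 = q,
             stringsAsFactors = FALSE)
}

#' Simulate paired-end WGS reads from a plastome plus nuclear background
#'
#' Fragments are sampled uniformly (positions wrap on the plastome circle),
#' fragment lengths are Normal(insert_mean, insert_sd), each mate is
#' read_length bases, substitution errors are applied at the stated rate,
#' and read ids encode the origin (`cp`/`nuc`) and 1-based fragment start.
#' Deterministic per `params$seed`.
#'
#' @param truth a [make_plastome()] result (or a circular sequence).
#' @param nuclear optional nuclear background sequence (linear).
#' @param params a [read_sim_params()].
#' @return a [read_set()]; the truth is attached as attribute `"truth"`.
#' @export
simulate_reads <- function(truth, nuclear = NULL,
                           params = read_sim_params()) {
  circle <- if (inherits(truth, "plastome_truth")) truth$circle
  else as.character(truth)
  rl <- params$read_length
  n_cp <- round(params$plastome_coverage * nchar(circle) / (2 * rl))
  n_nuc <- if (is.null(nuclear)) 0L
  else round(params$nuclear_coverage * nchar(nuclear) / (2 * rl))
  pairs <- withr::with_seed(params$seed, {
    cp <- sample_pairs(circle, TRUE, n_cp, params, "cp",
                       hole = params$coverage_hole)
    nuc <- if (n_nuc > 0L)
      sample_pairs(nuclear, FALSE, n_nuc, params, "nuc")
    rbind(cp, nuc)
  })
  out <- read_set(pairs = pairs)
  attr(out, "truth") <- truth
  out
}

#' Both valid circular configurations of a simulated plastome
#'
#' Short-read data cannot resolve the relative orientation of SSC and LSC,
#' so an assembly matching either configuration is correct. Returns the
#' truth circle and its SSC-flipped counterpart; compare an assembly with
#' `max(sapply(plastome_orientations(truth), circular_identity, query = asm))`.
#'
#' @param truth a [make_plastome()] result.
#' @return character vector of the two circular sequences.
#' @export
plastome_orientations <- function(truth) {
  stopifnot(inherits(truth, "plastome_truth"))
  c(truth$circle,
    paste0(truth$lsc, truth$ir, cpp_revcomp(truth$ssc),
           cpp_revcomp(truth$ir)))
}

#' Fraction of plastome-origin reads in a simulated read set
#'
#' Uses the origin labels written into simulated read ids.
#' @param rs a [read_set()] produced by [simulate_reads()].
#' @return fraction of pairs (plus singles) with plastome origin.
#' @export
plastome_read_fraction <- function(rs) {
  ids <- c(rs$pairs$id1, rs$singles$id)
  if (!length(ids)) return(NA_real_)
  mean(startsWith(ids, "cp_"))
}
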