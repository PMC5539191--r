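#' Detect the chloroplast peak pair in a k-mer volume histogram
#'
#' Automates the visual inspection step that separates chloroplast-derived
#' k-mers from sequencing error and nuclear background. The volume histogram
#' is smoothed with a moving average; local maxima above the error floor are
#' candidate peaks; the pair (p, q) with q within `tolerance` of 2p and the
#' largest combined volume is called as the single-copy (SC) and
#' inverted-repeat (IR) peaks. The selection band defaults to
#' `[p/2, 3q/2]`, clipped above the error floor.
#'
#' When no pair qualifies a classed error (`plastid_no_peaks`) is raised —
#' set the band manually in that case.
#'
#' @param hist a [kmer_histogram()].
#' @param tolerance allowed relative deviation of the IR mode from twice the
#'   SC mode.
#' @param error_floor frequency at or below which maxima are ignored;
#'   `NULL` (default) uses the first local minimum of the smoothed volume
#'   curve, which separates the error peak from genomic peaks.
#' @param smooth_window moving-average window (frequencies).
#' @return an object of class `peak_call` with fields `sc_mode`, `ir_mode`,
#'   `band` (c(f_min, f_max)), `score` and `error_floor`.
#' @export
detect_peaks <- function(hist, tolerance = 0.15, error_floor = NULL,
                         smooth_window = 5L) {
  stopifnot(inherits(hist, "kmer_histogram"))
  rows <- hist$rows
  if (nrow(rows) == 0L) stop("empty histogram", call. = FALSE)
  maxf <- max(rows$frequency)
  v <- numeric(maxf)
  v[rows$frequency] <- rows$volume
  w <- max(1L, as.integer(smooth_window))
  sm <- as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- 0
  if (is.null(error_floor)) {
    error_floor <- 1L
    if (maxf >= 3L) for (f in 2:(maxf - 1L)) {
      if (sm[f] <= sm[f - 1L] && sm[f] <= sm[f + 1L]) {
        error_floor <- f
        break
      }
    }
  }
  is_max <- function(f) {
    left <- if (f > 1L) sm[f - 1L] else -Inf
    right <- if (f < maxf) sm[f + 1L] else -Inf
    sm[f] > left && sm[f] >= right
  }
  cand <- (error_floor + 1L):maxf
  peaks <- cand[vapply(cand, is_max, logical(1)) & sm[cand] > 0]
  band_volume <- function(f) {
    lo <- max(1L, floor(0.8 * f))
    hi <- min(maxf, ceiling(1.2 * f))
    sum(v[lo:hi])
  }
  best <- NULL
  best_score <- -Inf
  if (length(peaks) >= 2L) {
    for (i in seq_len(length(peaks) - 1L)) for (j in (i + 1L):length(peaks)) {
      p <- peaks[i]; q <- peaks[j]
      if (abs(q - 2 * p) <= tolerance * 2 * p) {
        score <- band_volume(p) + band_volume(q)
        if (score > best_score) {
          best_score <- score
          best <- c(p, q)
        }
      }
    }
  }
  if (is.null(best))
    stop(structure(class = c("plastid_no_peaks", "error", "condition"),
                   list(message = paste("no chloroplast peak pair found;",
                                        "set the selection band manually"),
                        call = sys.call(-1))))
  p <- best[1]; q <- best[2]
  band <- c(max(error_floor + 1L, floor(p / 2)), as.integer(ceiling(1.5 * q)))
  structure(list(sc_mode = p, ir_mode = q, band = band,
                 score = best_score, error_floor = error_floor),
            class = "peak_call")
}

#' @export
print.peak_call <- function(x, ...) {
  cat(sprintf("peak_call: SC mode %d, IR mode %d (ratio %.2f), band [%d, %d]\n",
              x$sc_mode, x$ir_mode, x$ir_mode / x$sc_mode,
              x$band[1], x$band[2]))
  invisible(x)
}

#' Select reads containing k-mers from a table
#'
#' A read matches when at least one of its canonical k-mers is a key of
#' `kmers`. Pair handling: `either_mate` (default) keeps a pair when either
#' mate matches; `both_mates` requires both; `per_read` keeps pairs where
#' both mates match and demotes a pair with exactly one matching mate to a
#' single read. Input order is preserved and the output is always a subset
#' of the input.
#'
#' @param reads a [read_set()].
#' @param kmers a [kmer_table()] (counts are ignored, only membership).
#' @param pair_policy see above.
#' @param invert drop matching reads instead of keeping them (used for
#'   negative k-mer selection).
#' @return a [read_set()].
#' @export
select_reads <- function(reads, kmers,
                         pair_policy = c("either_mate", "both_mates",
                                         "per_read"),
                         invert = FALSE) {
  stopifnot(inherits(reads, "read_set"), inherits(kmers, "kmer_table"))
  pair_policy <- match.arg(pair_policy)
  k <- kmers$k
  match1 <- if (n_pairs(reads))
    cpp_seqs_match(reads$pairs$seq1, k, kmers$kmer) else logical(0)
  match2 <- if (n_pairs(reads))
    cpp_seqs_match(reads$pairs$seq2, k, kmers$kmer) else logical(0)
  matchs <- if (n_singles(reads))
    cpp_seqs_match(reads$singles$seq, k, kmers$kmer) else logical(0)
  if (invert) {
    match1 <- !match1; match2 <- !match2; matchs <- !matchs
    # inverting flips the semantics: either_mate drops a pair when either
    # mate matched the (negative) table
    keep_pair <- switch(pair_policy,
                        either_mate = match1 & match2,
                        both_mates = match1 | match2,
                        per_read = match1 & match2)
  } else {
    keep_pair <- switch(pair_policy,
                        either_mate = match1 | match2,
                        both_mates = match1 & match2,
                        per_read = match1 & match2)
  }
  out <- subset_reads(reads, which(keep_pair), which(matchs))
  if (pair_policy == "per_read" && !invert) {
    lone1 <- which(match1 & !match2)
    lone2 <- which(match2 & !match1)
    extra <- rbind(
      data.frame(id = reads$pairs$id1[lone1], seq = reads$pairs$seq1[lone1],
                 qual = reads$pairs$qual1[lone1], stringsAsFactors = FALSE),
      data.frame(id = reads$pairs$id2[lone2], seq = reads$pairs$seq2[lone2],
                 qual = reads$pairs$qual2[lone2], stringsAsFactors = FALSE))
    out <- read_set(out$pairs, rbind(out$singles, extra))
  }
  out
}

#' Nested batch subsampling of a read set
#'
#' Reads are shuffled once with the given seed; batches are prefixes of that
#' shuffle with sizes `start, start + increment, ...` up to the full set
#' (the final batch is always the complete read set), so batches are nested
#' and deterministic. Sizes count read pairs; singles, if present, are
#' included proportionally.
#'
#' @param reads a [read_set()].
#' @param start,increment batch sizes in read pairs (positive).
#' @param seed integer seed for the shuffle.
#' @return list of [read_set()] batches, smallest first.
#' @export
batch_subsample <- function(reads, start, increment, seed = 1L) {
  stopifnot(start > 0, increment > 0)
  np <- n_pairs(reads)
  ns <- n_singles(reads)
  base_n <- if (np > 0L) np else ns
  if (base_n == 0L) return(list(reads))
  perm <- withr::with_seed(seed, list(p = sample.int(max(np, 1L)),
                                      s = sample.int(max(ns, 1L))))
  sizes <- seq(from = min(start, base_n), to = base_n, by = increment)
  sizes <- unique(c(sizes[sizes < base_n], base_n))
  lapply(sizes, function(sz) {
    if (np > 0L) {
      pi <- sort(perm$p[seq_len(sz)])
      si <- if (ns > 0L)
        sort(perm$s[seq_len(min(ns, round(ns * sz / np)))]) else integer(0)
    } else {
      pi <- integer(0)
      si <- sort(perm$s[seq_len(sz)])
    }
    subset_reads(reads, pi, si)
  })
}
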