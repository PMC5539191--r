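#' Pipeline configuration
#'
#' Collects every tunable parameter of the five-stage assembly pipeline.
#' Defaults follow the published workflow: selection k-mers of size 31,
#' assembly K swept over all odd values between 63 and 99, read batches
#' starting at 100,000 pairs with 100,000-pair increments, 500 bp gap
#' flanks, and 1000-read gap-filling batches.
#'
#' @param k_count odd k used for selection k-mer tables (default 31).
#' @param K_values odd De Bruijn K values for the assembly sweep.
#' @param batch_start,batch_increment read-pair batch sizes for stage 2/3.
#' @param gap_flank bases of gap context on either side of a gap (stage 5).
#' @param gap_batch read(-pair) batch size and increment for stage 5.
#' @param size_ranges list of length-2 numeric ranges `total`, `lsc`, `ssc`,
#'   `ir` used by the assembly sanity check (bases).
#' @param max_iterations iteration cap per refinement stage.
#' @param ranking_mode `"lexicographic"` (scaffolds, then gaps, then length)
#'   or `"scaffolds_plus_gaps"` (scaffolds + gaps, then length).
#' @param output_layout `"three_linear"`, `"two_circular"` or
#'   `"one_circular"`.
#' @param pair_policy read-selection pair semantics, see [select_reads()].
#' @param min_edge_coverage De Bruijn coverage cutoff.
#' @param min_links read-pair support required to scaffold two contigs.
#' @param min_overlap minimum scaffold end overlap for merging (bases).
#' @param max_mismatch_rate tolerated mismatch fraction inside an overlap.
#' @param gap_n number of N characters placed in a bridged junction.
#' @param ir_min_length minimum inverted-repeat length to annotate.
#' @param tip_rounds De Bruijn tip-clipping rounds.
#' @param seed_len exact seed length for the internal read mapper.
#' @param end_window distance from a scaffold end (bases) within which an
#'   anchored read contributes to end harvesting / connectivity counting.
#' @param min_overhang minimum clipped overhang for a read to count as
#'   extending past a scaffold end.
#' @param reference optional chloroplast reference sequence(s) for the
#'   homology filter (character vector or path to a FASTA file); `NULL`
#'   skips the filter.
#' @param homology_min_shared minimum fraction of scaffold 31-mers shared
#'   with the reference to keep a scaffold.
#' @param auto_band run automatic peak detection when no band is supplied.
#' @param seed integer seed driving every stochastic step.
#' @return a validated list of class `plastid_config`.
#' @export
pipeline_config <- function(k_count = 31L,
                            K_values = seq(63L, 99L, by = 2L),
                            batch_start = 100000L,
                            batch_increment = 100000L,
                            gap_flank = 500L,
                            gap_batch = 1000L,
                            size_ranges = list(total = c(100e3, 250e3),
                                               lsc = c(60e3, 140e3),
                                               ssc = c(5e3, 30e3),
                                               ir = c(10e3, 60e3)),
                            max_iterations = 10L,
                            ranking_mode = c("lexicographic",
                                             "scaffolds_plus_gaps"),
                            output_layout = c("one_circular", "three_linear",
                                              "two_circular"),
                            pair_policy = c("either_mate", "both_mates",
                                            "per_read"),
                            min_edge_coverage = 3L,
                            min_links = 3L,
                            min_overlap = 50L,
                            max_mismatch_rate = 0,
                            gap_n = 100L,
                            ir_min_length = 1000L,
                            tip_rounds = 3L,
                            seed_len = 21L,
                            end_window = 500L,
                            min_overhang = 20L,
                            reference = NULL,
                            homology_min_shared = 0.2,
                            auto_band = TRUE,
                            seed = 1L) {
  cfg <- list(k_count = as.integer(k_count),
              K_values = as.integer(K_values),
              batch_start = as.integer(batch_start),
              batch_increment = as.integer(batch_increment),
              gap_flank = as.integer(gap_flank),
              gap_batch = as.integer(gap_batch),
              size_ranges = size_ranges,
              max_iterations = as.integer(max_iterations),
              ranking_mode = match.arg(ranking_mode),
              output_layout = match.arg(output_layout),
              pair_policy = match.arg(pair_policy),
              min_edge_coverage = as.integer(min_edge_coverage),
              min_links = as.integer(min_links),
              min_overlap = as.integer(min_overlap),
              max_mismatch_rate = as.numeric(max_mismatch_rate),
              gap_n = as.integer(gap_n),
              ir_min_length = as.integer(ir_min_length),
              tip_rounds = as.integer(tip_rounds),
              seed_len = as.integer(seed_len),
              end_window = as.integer(end_window),
              min_overhang = as.integer(min_overhang),
              reference = reference,
              homology_min_shared = as.numeric(homology_min_shared),
              auto_band = isTRUE(auto_band),
              seed = as.integer(seed))
  class(cfg) <- "plastid_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$k_count >= 3L, cfg$k_count %% 2L == 1L)
  if (any(cfg$K_values %% 2L == 0L) || any(cfg$K_values < 3L))
    stop("all assembly K values must be odd and >= 3", call. = FALSE)
  stopifnot(cfg$batch_start > 0L, cfg$batch_increment > 0L,
            cfg$gap_batch > 0L, cfg$max_iterations >= 1L)
  if (cfg$gap_flank < cfg$k_count)
    stop("gap_flank must be at least k_count", call. = FALSE)
  if (cfg$min_overlap < 20L)
    stop("min_overlap must be at least 20", call. = FALSE)
  for (nm in c("total", "lsc", "ssc", "ir")) {
    r <- cfg$size_ranges[[nm]]
    if (is.null(r) || length(r) != 2L || r[1] > r[2])
      stop("size_ranges$", nm, " must be a (lo, hi) range", call. = FALSE)
  }
  cfg
}

#' Toy-scale configuration profile
#'
#' Overrides the published problem-scale defaults with settings sized for
#' small simulated genomes: the K sweep runs over {21, 31, 41}, read batches
#' start at 10,000 pairs (10,000-pair increments), overlap merging accepts
#' K-1 = 20-base unitig junctions, and the sanity/IR ranges match a toy
#' plastome of a few tens of kilobases.
#'
#' @param ... overrides forwarded to [pipeline_config()] on top of the toy
#'   defaults.
#' @return a `plastid_config`.
#' @export
toy_profile <- function(...) {
  defaults <- list(K_values = c(21L, 31L, 41L),
                   batch_start = 10000L,
                   batch_increment = 10000L,
                   min_overlap = 20L,
                   ir_min_length = 500L,
                   seed_len = 17L,
                   size_ranges = list(total = c(20e3, 60e3),
                                      lsc = c(10e3, 40e3),
                                      ssc = c(0, 20e3),
                                      ir = c(500, 20e3)))
  args <- modifyList(defaults, list(...))
  do.call(pipeline_config, args)
}

#' Read a pipeline configuration from a YAML file
#'
#' Values present in the file override [pipeline_config()] defaults; nested
#' `size_ranges` entries are merged individually.
#'
#' @param path YAML file.
#' @param ... further overrides applied after the file.
#' @return a `plastid_config`.
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  base <- formals(pipeline_config)
  known <- names(base)
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(vals$size_ranges))
    vals$size_ranges <- modifyList(eval(base$size_ranges), vals$size_ranges)
  vals <- modifyList(vals, list(...))
  do.call(pipeline_config, vals)
}

#' @export
print.plastid_config <- function(x, ...) {
  cat("plastid pipeline configuration\n")
  cat(sprintf("  selection k: %d; assembly K: %s\n", x$k_count,
              paste(range(x$K_values), collapse = "..")))
  cat(sprintf("  batches: start %d, increment %d read pairs\n",
              x$batch_start, x$batch_increment))
  cat(sprintf("  ranking: %s; layout: %s; seed: %d\n",
              x$ranking_mode, x$output_layout, x$seed))
  invisible(x)
}
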