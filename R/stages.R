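# Orchestration of the five pipeline stages: initial band-selected assembly
# (stage 2), iterative re-selection and IR-aware merging (stage 3), scaffold
# end extension and spanning-read re-scaffolding (stage 4), and
# positive/negative k-mer gap filling (stage 5), plus the internal read
# mapper stages 4 and 5 depend on.

new_stage_state <- function(stage, iteration, best, history,
                            terminated_because) {
  structure(list(stage = stage, iteration = iteration, best = best,
                 history = history, terminated_because = terminated_because),
            class = "stage_state")
}

#' @export
print.stage_state <- function(x, ...) {
  cat(sprintf("stage %d state: %d iteration(s), terminated: %s\n",
              x$stage, x$iteration, x$terminated_because))
  print(x$best)
  invisible(x)
}

history_row <- function(iteration, asm) {
  data.frame(iteration = iteration, n_scaffolds = n_scaffolds(asm),
             n_gaps = n_gaps(asm), total_length = total_length(asm))
}

# shared filter chain: homology (if configured), then size; assemblies
# without sweep provenance are size-filtered at the smallest sweep K
apply_filters <- function(asm, config) {
  asm <- filter_homology(asm, config$reference, config$homology_min_shared,
                         k = config$k_count)
  K <- asm$provenance$K
  if (is.null(K) || is.na(K)) K <- min(config$K_values)
  filter_size(asm, K)
}

# TRUE when every interior non-N position of every scaffold is covered by
# at least one high-identity read placement with `margin` bases on both
# sides of it. A repeat-mediated misjoin juxtaposes sequence no read ever
# spans: reads crossing the false junction accumulate mismatches and fail
# the identity filter, leaving the junction uncovered. Scaffold edges and
# N-run neighbourhoods are exempt (only clipped or gap-spanning reads
# reach them).
assembly_supported <- function(reads, asm, config, margin = 10L,
                               min_identity = 0.9, max_reads = 6000L) {
  seqs <- read_sequences(reads)
  if (!length(seqs) || n_scaffolds(asm) == 0L) return(TRUE)
  if (length(seqs) > max_reads)
    seqs <- seqs[unique(round(seq(1L, length(seqs),
                                  length.out = max_reads)))]
  rl <- nchar(seqs)
  edge <- max(rl)
  # a circular assembly is validated across its origin by mapping onto the
  # pseudo-circularized sequence; its junction is then NOT exempt
  circular1 <- isTRUE(asm$circular) && n_scaffolds(asm) == 1L
  refs <- unname(asm$scaffolds)
  if (circular1) refs <- paste0(refs, substr(refs, 1L, edge))
  m <- cpp_map_reads(seqs, refs, as.integer(config$seed_len))
  aligned <- rl - m$overhang_left - m$overhang_right
  ok <- !is.na(m$ref) & m$matches >= min_identity * aligned
  for (r in seq_len(n_scaffolds(asm))) {
    s <- asm$scaffolds[[r]]
    L <- nchar(s)
    Lr <- nchar(refs[r])
    rows <- which(ok & m$ref == r)
    from <- pmax(1L, m$pos[rows] + 1L + margin)
    to <- pmin(Lr, m$pos[rows] + rl[rows] - margin)
    keep <- from <= to
    d <- integer(Lr + 1L)
    if (any(keep)) {
      d <- tabulate(from[keep], nbins = Lr + 1L) -
        tabulate(to[keep] + 1L, nbins = Lr + 1L)
    }
    cov <- cumsum(d)[seq_len(Lr)] > 0L
    if (circular1 && Lr > L) {
      wrap <- seq_len(Lr - L)
      cov[wrap] <- cov[wrap] | cov[L + wrap]
      cov <- cov[seq_len(L)]
    }
    exempt <- logical(L)
    if (!circular1) {
      exempt[seq_len(min(edge, L))] <- TRUE
      exempt[seq(max(1L, L - edge + 1L), L)] <- TRUE
    }
    nn <- gregexpr("N+", s)[[1]]
    if (nn[1] != -1L) {
      for (i in seq_along(nn)) {
        lo <- max(1L, as.integer(nn[i]) - edge)
        hi <- min(L, as.integer(nn[i]) + attr(nn, "match.length")[i] - 1L +
                    edge)
        exempt[lo:hi] <- TRUE
      }
    }
    # a chimeric junction leaves an uncovered run of at least ~2 x margin;
    # isolated uncovered bases are subsampling flukes and tolerated
    bad <- rle(!cov & !exempt)
    if (any(bad$values & bad$lengths > margin)) return(FALSE)
  }
  TRUE
}

#' Map reads onto an assembly with the internal seed-and-extend mapper
#'
#' Exact-seeded, ungapped placement: each read is put at the position
#' (either strand) maximising matching bases; clipped overhang lengths at
#' scaffold ends are reported. Reads with no exact seed are unmapped.
#' Deterministic.
#'
#' @param reads a [read_set()].
#' @param asm an [assembly()].
#' @param seed_len exact seed length.
#' @return list with data frames `mate1`, `mate2` and `singles`, each with
#'   columns `ref` (scaffold index, NA if unmapped), `scaffold` (id), `pos`
#'   (0-based leftmost position of the placement, may be negative for
#'   left-overhanging reads), `strand` (+1/-1), `matches`, `mismatches`,
#'   `overhang_left`, `overhang_right`.
#' @export
map_reads <- function(reads, asm, seed_len = 21L) {
  stopifnot(n_scaffolds(asm) > 0L)
  refs <- unname(asm$scaffolds)
  ids <- names(asm$scaffolds)
  one <- function(seqs) {
    if (!length(seqs))
      return(cbind(cpp_map_reads(character(0), refs, seed_len),
                   scaffold = character(0)))
    df <- cpp_map_reads(seqs, refs, as.integer(seed_len))
    df$scaffold <- ifelse(is.na(df$ref), NA_character_, ids[df$ref])
    df
  }
  list(mate1 = one(reads$pairs$seq1), mate2 = one(reads$pairs$seq2),
       singles = one(reads$singles$seq))
}

#' Stage 2: band-selected read extraction and initial assembly sweep
#'
#' Selects the k-mers inside the chosen frequency band, extracts the reads
#' containing them, assembles nested read batches across the K sweep,
#' filters each candidate by homology and size, discards assemblies whose
#' total length fails the sanity ranges, and returns the best-ranked
#' assembly with the sweep statistics attached (attribute `"sweep_stats"`).
#'
#' @param reads the full WGS [read_set()].
#' @param band numeric `c(f_min, f_max)` selection band (from
#'   [detect_peaks()] or chosen by inspection).
#' @param config a [pipeline_config()].
#' @param table optional precomputed [count_kmers()] table of `reads`.
#' @return the best [assembly()].
#' @export
run_stage2 <- function(reads, band, config = pipeline_config(),
                       table = NULL) {
  if (is.null(table)) table <- count_kmers(reads, config$k_count)
  km <- select_kmers_by_frequency(table, band[1], band[2])
  if (!length(km$kmer))
    stop("no k-mers inside the selection band; revise the band", call. = FALSE)
  sel <- select_reads(reads, km, config$pair_policy)
  if (n_pairs(sel) + n_singles(sel) == 0L)
    stop("band selection produced no reads; revise the band", call. = FALSE)
  batches <- batch_subsample(sel, config$batch_start,
                             config$batch_increment, config$seed)
  sweep <- sweep_assemble(batches, config$K_values, config, stage = 2L)
  sweep <- lapply(sweep, apply_filters, config = config)
  passed <- vapply(sweep, sanity_check, logical(1),
                   ranges = config$size_ranges)
  stats <- if (length(sweep))
    cbind(do.call(rbind, lapply(sweep, assembly_stats)),
          passed_sanity = passed)
  else data.frame()
  if (!any(passed))
    stop("no assembly survived filtering; revise the band or size ranges",
         call. = FALSE)
  best <- rank_assemblies(sweep[passed], config$ranking_mode)
  best$provenance$stage <- 2L
  attr(best, "sweep_stats") <- stats
  attr(best, "n_selected_pairs") <- n_pairs(sel)
  best
}

#' Stage 3: iterative re-selection and IR-aware overlap merging
#'
#' Each iteration counts the k-mers of the current best assembly, selects
#' matching reads from the full raw set, re-runs the batch x K sweep,
#' filters, applies the internal overlap merger to every candidate and
#' accepts the top-ranked candidate only when it strictly improves on the
#' current best. Stops when circular, when no improvement occurs, or at the
#' iteration limit.
#'
#' @param reads the full raw [read_set()].
#' @param seed_assembly the stage-2 best [assembly()].
#' @param config a [pipeline_config()].
#' @return a `stage_state`.
#' @export
run_stage3 <- function(reads, seed_assembly, config = pipeline_config()) {
  best <- seed_assembly
  # the internal merger is applied to the incumbent first: the stage-2 best
  # is raw assembler output whose contigs may already share junction
  # overlaps, and merging it can close the circle outright
  if (!isTRUE(best$circular)) {
    cand0 <- overlap_merge(best, config$min_overlap,
                           config$max_mismatch_rate)
    if ((compare_keys(rank_key(cand0, config$ranking_mode),
                      rank_key(best, config$ranking_mode)) < 0L ||
         isTRUE(cand0$circular)) &&
        sanity_check(cand0, config$size_ranges) &&
        assembly_supported(reads, cand0, config)) {
      best <- cand0
      best$provenance$stage <- 3L
      best$provenance$iteration <- 0L
    }
  }
  history <- history_row(0L, best)
  reason <- "iteration_limit"
  iter <- 0L
  if (isTRUE(best$circular)) {
    return(new_stage_state(3L, 0L, best, history, "circular"))
  }
  for (iter in seq_len(config$max_iterations)) {
    kt <- count_kmers(unname(best$scaffolds), config$k_count)
    sel <- select_reads(reads, kt, config$pair_policy)
    if (n_pairs(sel) + n_singles(sel) == 0L) {
      reason <- "no_improvement"
      iter <- iter - 1L
      break
    }
    batches <- batch_subsample(sel, config$batch_start,
                               config$batch_increment,
                               config$seed + iter)
    sweep <- sweep_assemble(batches, config$K_values, config, stage = 3L,
                            iteration = iter)
    sweep <- lapply(sweep, apply_filters, config = config)
    sweep <- lapply(sweep, overlap_merge, min_overlap = config$min_overlap,
                    max_mismatch_rate = config$max_mismatch_rate)
    passed <- vapply(sweep, sanity_check, logical(1),
                     ranges = config$size_ranges)
    if (!any(passed)) {
      reason <- "no_improvement"
      iter <- iter - 1L
      break
    }
    cand <- rank_assemblies(sweep[passed], config$ranking_mode)
    improved <- (compare_keys(rank_key(cand, config$ranking_mode),
                              rank_key(best, config$ranking_mode)) < 0L ||
                   (isTRUE(cand$circular) && !isTRUE(best$circular))) &&
      assembly_supported(reads, cand, config)
    if (!improved) {
      reason <- "no_improvement"
      iter <- iter - 1L
      break
    }
    best <- cand
    best$provenance$stage <- 3L
    best$provenance$iteration <- iter
    history <- rbind(history, history_row(iter, best))
    if (isTRUE(best$circular)) {
      reason <- "circular"
      break
    }
  }
  new_stage_state(3L, iter, best, history, reason)
}

# reads hanging over a scaffold end, plus mates of reads anchored near an
# end whose own mate is unmapped: one read set per scaffold end
harvest_end_reads <- function(reads, asm, aln, config) {
  ids <- names(asm$scaffolds)
  reflen <- nchar(asm$scaffolds)
  ends <- c(paste0(ids, "|left"), paste0(ids, "|right"))
  out <- stats::setNames(vector("list", length(ends)), ends)
  for (e in ends) out[[e]] <- list(seq = character(0), qual = character(0))
  add <- function(e, seq, qual) {
    out[[e]]$seq <<- c(out[[e]]$seq, seq)
    out[[e]]$qual <<- c(out[[e]]$qual, qual)
  }
  grab <- function(m, seqs, quals, mate_m = NULL, mate_seqs = NULL,
                   mate_quals = NULL) {
    ok <- !is.na(m$ref)
    # overhanging reads belong to the end they extend past
    left <- ok & m$overhang_left >= config$min_overhang
    right <- ok & m$overhang_right >= config$min_overhang
    for (i in which(left)) add(paste0(ids[m$ref[i]], "|left"), seqs[i], quals[i])
    for (i in which(right)) add(paste0(ids[m$ref[i]], "|right"), seqs[i], quals[i])
    # unmapped mates of end-anchored reads putatively lie beyond the end
    if (!is.null(mate_m)) {
      anchored_right <- ok & m$strand == 1L &
        (reflen[m$ref] - m$pos) <= config$end_window
      anchored_left <- ok & m$strand == -1L & (m$pos + nchar(seqs)) <=
        config$end_window
      lost <- is.na(mate_m$ref)
      for (i in which(anchored_right & lost))
        add(paste0(ids[m$ref[i]], "|right"), mate_seqs[i], mate_quals[i])
      for (i in which(anchored_left & lost))
        add(paste0(ids[m$ref[i]], "|left"), mate_seqs[i], mate_quals[i])
    }
  }
  grab(aln$mate1, reads$pairs$seq1, reads$pairs$qual1, aln$mate2,
       reads$pairs$seq2, reads$pairs$qual2)
  grab(aln$mate2, reads$pairs$seq2, reads$pairs$qual2, aln$mate1,
       reads$pairs$seq1, reads$pairs$qual1)
  grab(aln$singles, reads$singles$seq, reads$singles$qual)
  out
}

#' Stage 4: scaffold extension and spanning-read re-scaffolding
#'
#' Skipped (returned unchanged) when the input assembly is already
#' circular. Each iteration maps all raw reads back to the assembly,
#' harvests per-scaffold-end read sets (overhanging reads plus unmapped
#' mates of end-anchored reads), assembles each end set across the K sweep,
#' adds the new scaffolds, overlap-merges and filters, and accepts strict
#' improvements. After the final iteration a scaffold-end connectivity
#' matrix is built from spanning read pairs and used to bridge remaining
#' junctions with N runs, which may close the assembly into a circle.
#'
#' @param reads the full raw [read_set()].
#' @param asm the stage-3 best [assembly()].
#' @param config a [pipeline_config()].
#' @return a `stage_state`.
#' @export
run_stage4 <- function(reads, asm, config = pipeline_config()) {
  if (isTRUE(asm$circular))
    return(new_stage_state(4L, 0L, asm, history_row(0L, asm), "circular"))
  best <- asm
  history <- history_row(0L, best)
  reason <- "iteration_limit"
  iter <- 0L
  for (iter in seq_len(config$max_iterations)) {
    aln <- map_reads(reads, best, config$seed_len)
    end_sets <- harvest_end_reads(reads, best, aln, config)
    new_scafs <- character(0)
    for (e in names(end_sets)) {
      es <- end_sets[[e]]
      if (length(es$seq) < config$min_edge_coverage) next
      rs <- read_set(singles = data.frame(id = paste0(e, "_", seq_along(es$seq)),
                                          seq = es$seq, qual = es$qual,
                                          stringsAsFactors = FALSE))
      for (K in config$K_values) {
        sub <- tryCatch(
          debruijn_assemble(rs, K, config$min_edge_coverage,
                            do_scaffold = FALSE,
                            tip_rounds = config$tip_rounds),
          error = function(e) NULL)
        if (!is.null(sub) && n_scaffolds(sub) > 0L)
          new_scafs <- c(new_scafs, unname(filter_size(sub, K)$scaffolds))
      }
    }
    cand <- assembly(c(unname(best$scaffolds), unique(new_scafs)),
                     provenance = best$provenance)
    cand <- overlap_merge(cand, config$min_overlap, config$max_mismatch_rate)
    cand <- apply_filters(cand, config)
    improved <- (compare_keys(rank_key(cand, config$ranking_mode),
                              rank_key(best, config$ranking_mode)) < 0L ||
                   (isTRUE(cand$circular) && !isTRUE(best$circular))) &&
      assembly_supported(reads, cand, config)
    if (!improved) {
      reason <- "no_improvement"
      iter <- iter - 1L
      break
    }
    best <- cand
    best$provenance$stage <- 4L
    best$provenance$iteration <- iter
    history <- rbind(history, history_row(iter, best))
    if (isTRUE(best$circular)) {
      reason <- "circular"
      break
    }
  }
  if (!isTRUE(best$circular) && n_scaffolds(best) > 1L) {
    cm <- build_connectivity_matrix(reads, best, config$seed_len,
                                    config$end_window)
    bridged <- rescaffold_with_matrix(best, cm, config$min_links,
                                      config$gap_n, ambiguous = "greedy",
                                      min_overlap = config$min_overlap)
    if ((compare_keys(rank_key(bridged, config$ranking_mode),
                      rank_key(best, config$ranking_mode)) < 0L ||
         isTRUE(bridged$circular)) &&
        assembly_supported(reads, bridged, config)) {
      best <- bridged
      history <- rbind(history, history_row(iter + 1L, best))
      if (isTRUE(best$circular)) reason <- "circular"
    }
  }
  new_stage_state(4L, max(iter, 0L), best, history, reason)
}

#' Extract gap contexts from an assembly
#'
#' One context per maximal N run: up to `flank` bases of gap-free sequence
#' immediately left and right of the run, truncated at scaffold ends and at
#' adjacent gaps.
#'
#' @param asm an [assembly()].
#' @param flank maximum flank length (bases).
#' @return list of `gap_context` lists with fields `gap_id`, `scaffold`,
#'   `gap_start` (1-based), `gap_length`, `left_flank`, `right_flank`,
#'   `region_start`, `region_end` (1-based inclusive bounds of
#'   flank+gap+flank within the scaffold).
#' @export
extract_gap_contexts <- function(asm, flank = 500L) {
  out <- list()
  for (sid in names(asm$scaffolds)) {
    seq <- asm$scaffolds[[sid]]
    gaps <- scaffold_gaps(seq)
    if (!nrow(gaps)) next
    for (g in seq_len(nrow(gaps))) {
      gs <- gaps$start[g]
      gl <- gaps$length[g]
      left_lim <- if (g > 1L) gaps$start[g - 1L] + gaps$length[g - 1L] else 1L
      right_lim <- if (g < nrow(gaps)) gaps$start[g + 1L] - 1L else nchar(seq)
      ls <- max(left_lim, gs - flank)
      re <- min(right_lim, gs + gl - 1L + flank)
      out[[length(out) + 1L]] <- structure(list(
        gap_id = sprintf("%s_gap%d", sid, g), scaffold = sid,
        gap_start = gs, gap_length = gl,
        left_flank = substr(seq, ls, gs - 1L),
        right_flank = substr(seq, gs + gl, re),
        region_start = ls, region_end = re), class = "gap_context")
    }
  }
  out
}

# minimum read-k-mer support across the gap-spanning windows of a closure
# (the windows not fully inside a flank); an error base introduced by a
# low-coverage De Bruijn bubble drags this to the error depth, so ranking
# on it picks the read-consensus closure
closure_support <- function(closure, lf_len, rf_len, support_tab) {
  if (is.null(support_tab)) return(0)
  k <- support_tab$k
  lo <- max(1L, lf_len - k + 2L)
  hi <- min(nchar(closure) - k + 1L, nchar(closure) - rf_len + k - 1L)
  if (hi < lo) return(0)
  win <- canonical_kmer(substring(closure, lo:hi, (lo:hi) + k - 1L))
  cnt <- support_tab$count[match(win, support_tab$kmer)]
  cnt[is.na(cnt)] <- 0L
  min(cnt)
}

# best gap closure: a candidate scaffold anchored on the left flank's end
# and the right flank's start (either strand). Anchoring accepts either a
# suffix/prefix overlap of at least min_overlap bases or full containment
# of the flank inside the candidate (a spanning candidate). Qualifying
# closures are ranked by gap-spanning read support, then total anchored
# overlap. Returns the replacement for flank+gap+flank — beginning exactly
# at the left flank's first base and ending at the right flank's last —
# or NULL.
best_gap_closure <- function(ctx, candidates, min_overlap,
                             support_tab = NULL) {
  lf <- ctx$left_flank
  rf <- ctx$right_flank
  if (nchar(lf) < min_overlap || nchar(rf) < min_overlap) return(NULL)
  anchor_left <- function(s) {
    p <- regexpr(lf, s, fixed = TRUE)[1]
    if (p > 0L)
      return(list(seq = substr(s, p, nchar(s)), ov = nchar(lf)))
    ovl <- cpp_best_overlap(lf, s, min_overlap, 0)
    if (ovl >= min_overlap && ovl < nchar(s))
      return(list(seq = paste0(lf, substr(s, ovl + 1L, nchar(s))),
                  ov = ovl))
    NULL
  }
  anchor_right <- function(joined) {
    m <- gregexpr(rf, joined, fixed = TRUE)[[1]]
    if (m[1] > 0L) {
      p <- m[length(m)] # rightmost occurrence
      if (p > nchar(lf)) # the right flank must lie beyond the left one
        return(list(seq = substr(joined, 1L, p + nchar(rf) - 1L),
                    ov = nchar(rf)))
    }
    ovr <- cpp_best_overlap(joined, rf, min_overlap, 0, nchar(rf) - 1L)
    if (ovr >= min_overlap)
      return(list(seq = paste0(joined, substr(rf, ovr + 1L, nchar(rf))),
                  ov = ovr))
    NULL
  }
  best <- NULL
  best_score <- c(-Inf, -Inf)
  for (cand in candidates) {
    for (s in c(cand, cpp_revcomp(cand))) {
      left <- anchor_left(s)
      if (is.null(left)) next
      right <- anchor_right(left$seq)
      if (is.null(right)) next
      closure <- right$seq
      if (nchar(closure) < nchar(lf) + nchar(rf)) next
      if (grepl("N", closure, fixed = TRUE)) next
      score <- c(closure_support(closure, nchar(lf), nchar(rf),
                                 support_tab), left$ov + right$ov)
      if (score[1] > best_score[1] ||
          (score[1] == best_score[1] && score[2] > best_score[2])) {
        best_score <- score
        best <- closure
      }
    }
  }
  best
}

#' Stage 5: gap filling with positive/negative k-mer selection
#'
#' Each iteration extracts the gap contexts, builds a positive k-mer table
#' from them and a negative table from the assembly regions outside any
#' context, keeps raw reads containing a positive k-mer and discards those
#' containing a negative one, assembles the survivors in small nested
#' batches across the K sweep, re-scaffolds candidates with the internal
#' overlap merger, drops candidate scaffolds shorter than K, combines every
#' candidate with every gap context and splices the best qualifying
#' closure into the assembly. Iterates until all gaps are closed, no gap
#' improves, or the iteration limit.
#'
#' @param reads the full raw [read_set()].
#' @param asm an [assembly()] (returned unchanged if gap-free).
#' @param config a [pipeline_config()].
#' @return a `stage_state`.
#' @export
run_stage5 <- function(reads, asm, config = pipeline_config()) {
  if (n_gaps(asm) == 0L)
    return(new_stage_state(5L, 0L, asm, history_row(0L, asm),
                           "all_gaps_closed"))
  best <- asm
  history <- history_row(0L, best)
  reason <- "iteration_limit"
  iter <- 0L
  min_ov <- min(config$min_overlap, 20L)
  for (iter in seq_len(config$max_iterations)) {
    ctxs <- extract_gap_contexts(best, config$gap_flank)
    if (!length(ctxs)) {
      reason <- "all_gaps_closed"
      iter <- iter - 1L
      break
    }
    flank_seqs <- unlist(lapply(ctxs, function(c) c(c$left_flank,
                                                    c$right_flank)))
    flank_seqs <- flank_seqs[nchar(flank_seqs) >= config$k_count]
    pos <- count_kmers(flank_seqs, config$k_count)
    # non-context regions: scaffold sequence with context regions blanked
    masked <- asm_mask_regions(best, ctxs)
    neg <- table_difference(pos, count_kmers(masked, config$k_count))
    sel <- select_reads(reads, pos, config$pair_policy)
    sel <- select_reads(sel, neg, config$pair_policy, invert = TRUE)
    closed <- 0L
    if (n_pairs(sel) + n_singles(sel) > 0L) {
      support_tab <- count_kmers(sel, config$k_count)
      batches <- batch_subsample(sel, config$gap_batch, config$gap_batch,
                                 config$seed + 100L + iter)
      sweep <- sweep_assemble(batches, config$K_values, config, stage = 5L,
                              iteration = iter)
      sweep <- lapply(sweep, overlap_merge,
                      min_overlap = min_ov,
                      max_mismatch_rate = config$max_mismatch_rate)
      candidates <- character(0)
      for (a in sweep) {
        K <- a$provenance$K
        keep <- nchar(a$scaffolds) >= K
        candidates <- c(candidates, unname(a$scaffolds[keep]))
      }
      candidates <- unique(candidates)
      # splice best closures right-to-left so coordinates stay valid
      scafs <- best$scaffolds
      for (sid in unique(vapply(ctxs, `[[`, character(1), "scaffold"))) {
        sctx <- Filter(function(c) c$scaffold == sid, ctxs)
        ord <- order(-vapply(sctx, `[[`, integer(1), "region_start"))
        for (ctx in sctx[ord]) {
          closure <- best_gap_closure(ctx, candidates, min_ov, support_tab)
          if (is.null(closure)) next
          s <- scafs[[sid]]
          scafs[[sid]] <- paste0(substr(s, 1L, ctx$region_start - 1L),
                                 closure,
                                 substr(s, ctx$region_end + 1L, nchar(s)))
          closed <- closed + 1L
        }
      }
      if (closed > 0L) {
        best <- assembly(scafs, circular = best$circular,
                         provenance = best$provenance)
        best$provenance$stage <- 5L
        best$provenance$iteration <- iter
        history <- rbind(history, history_row(iter, best))
      }
    }
    if (closed == 0L) {
      reason <- "no_improvement"
      iter <- iter - 1L
      break
    }
    if (n_gaps(best) == 0L) {
      reason <- "all_gaps_closed"
      break
    }
  }
  if (n_gaps(best) == 0L) reason <- "all_gaps_closed"
  new_stage_state(5L, max(iter, 0L), best, history, reason)
}

# sequences of the assembly with every context region (flank+gap+flank)
# removed: the fragments outside gap contexts
asm_mask_regions <- function(asm, ctxs) {
  out <- character(0)
  for (sid in names(asm$scaffolds)) {
    seq <- asm$scaffolds[[sid]]
    regions <- Filter(function(c) c$scaffold == sid, ctxs)
    if (!length(regions)) {
      out <- c(out, seq)
      next
    }
    cuts <- sort(vapply(regions, function(c) c(c$region_start, c$region_end),
                        integer(2))[1, ])
    starts <- vapply(regions, `[[`, integer(1), "region_start")
    ends <- vapply(regions, `[[`, integer(1), "region_end")
    o <- order(starts)
    pos <- 1L
    for (i in o) {
      if (starts[i] > pos) out <- c(out, substr(seq, pos, starts[i] - 1L))
      pos <- max(pos, ends[i] + 1L)
    }
    if (pos <= nchar(seq)) out <- c(out, substr(seq, pos, nchar(seq)))
  }
  out[nchar(out) > 0L]
}

#' Run the complete five-stage pipeline
#'
#' Stage 1 counts canonical k-mers and builds the frequency/volume
#' histograms; the chloroplast band is then either supplied explicitly or
#' detected automatically from the SC/IR peak pair; stages 2-5 assemble,
#' refine, re-scaffold and gap-fill as described in the stage functions.
#' Stage 4 is skipped when stage 3 delivers a circular assembly; stage 5 is
#' skipped when no gaps remain. When the final assembly is circular the
#' configured layout is produced.
#'
#' @param input a directory of FASTQ files (see [scan_input_directory()])
#'   or a [read_set()].
#' @param config a [pipeline_config()].
#' @param band optional `c(f_min, f_max)`; when `NULL` and
#'   `config$auto_band` is TRUE the band comes from [detect_peaks()];
#'   when `NULL` otherwise the pipeline halts after stage 1.
#' @param out_dir optional directory for per-stage artifacts (FASTA
#'   assemblies, sweep statistics TSV, histogram TSVs, JSON manifest).
#' @param stop_after stop after this stage (1-5); stage 1 output is the
#'   k-mer table and histograms only.
#' @return list of class `plastid_run` with elements `table` (stage-1 k-mer
#'   table), `histogram`, `peaks` (or NULL), `band`, `stages` (list of
#'   stage results), `final` (an [assembly()]) and `layout` (or NULL).
#' @export
run_pipeline <- function(input, config = pipeline_config(), band = NULL,
                         out_dir = NULL, stop_after = 5L) {
  reads <- if (inherits(input, "read_set")) input
  else scan_input_directory(input)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  table <- count_kmers(reads, config$k_count)
  hist <- kmer_histogram(table)
  res <- list(table = table, histogram = hist, peaks = NULL, band = band,
              stages = list(), final = NULL, layout = NULL,
              config = config)
  class(res) <- "plastid_run"
  if (!is.null(out_dir)) {
    for (b in c(1L, 10L, 25L, 100L, 250L))
      write_histogram(hist, file.path(out_dir,
                                      sprintf("stage1_hist_bin%d.tsv", b)), b)
  }
  if (stop_after <= 1L) return(res)
  if (is.null(band)) {
    if (!config$auto_band)
      stop("stage 1 complete; choose a k-mer frequency band and re-run ",
           "with `band = c(f_min, f_max)`", call. = FALSE)
    res$peaks <- detect_peaks(hist)
    band <- res$peaks$band
    res$band <- band
  }
  s2 <- run_stage2(reads, band, config, table = table)
  res$stages$stage2 <- s2
  res$final <- s2
  if (!is.null(out_dir)) {
    write_assembly_fasta(s2, file.path(out_dir, "stage2_best.fasta"))
    write.table(attr(s2, "sweep_stats"),
                file.path(out_dir, "stage2_sweep.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  if (stop_after <= 2L) return(res)
  s3 <- run_stage3(reads, s2, config)
  res$stages$stage3 <- s3
  res$final <- s3$best
  if (!is.null(out_dir))
    write_assembly_fasta(s3$best, file.path(out_dir, "stage3_best.fasta"))
  if (stop_after > 3L) {
    s4 <- run_stage4(reads, res$final, config)
    res$stages$stage4 <- s4
    res$final <- s4$best
    if (!is.null(out_dir))
      write_assembly_fasta(s4$best, file.path(out_dir, "stage4_best.fasta"))
  }
  if (stop_after > 4L && n_gaps(res$final) > 0L) {
    s5 <- run_stage5(reads, res$final, config)
    res$stages$stage5 <- s5
    res$final <- s5$best
    if (!is.null(out_dir))
      write_assembly_fasta(s5$best, file.path(out_dir, "stage5_best.fasta"))
  }
  if (isTRUE(res$final$circular))
    res$layout <- layout_outputs(res$final, config$output_layout,
                                 config$ir_min_length, config$seed)
  if (!is.null(out_dir)) {
    manifest <- list(config = config[setdiff(names(config), "reference")],
                     band = band,
                     stats = assembly_stats(res$final),
                     stages_run = names(res$stages))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    write_assembly_fasta(res$final, file.path(out_dir, "final.fasta"))
  }
  res
}

#' @export
print.plastid_run <- function(x, ...) {
  cat("plastid pipeline run\n")
  if (!is.null(x$peaks)) print(x$peaks)
  if (!is.null(x$band))
    cat(sprintf("  band: [%d, %d]\n", x$band[1], x$band[2]))
  cat("  final: ")
  print(x$final)
  if (!is.null(x$layout)) print(x$layout)
  invisible(x)
}
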