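# Overlap-based merging aware of circularity and the inverted repeat, plus
# pseudo-circularization, IR detection, LSC/IR/SSC layout, and
# connectivity-matrix re-scaffolding.

# enumerate candidate suffix/prefix joins among scaffolds; each join is
# (i, oi, j, oj, ov): oriented scaffold i (orientation "f"/"r") extended by
# oriented scaffold j with an end overlap of ov bases. Containment-length
# overlaps are excluded. For i < j the four orientation combinations cover
# every distinct junction exactly once.
candidate_joins <- function(seqs, rcs, min_overlap, max_mm_rate) {
  n <- length(seqs)
  out <- list()
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    for (oi in c("f", "r")) for (oj in c("f", "r")) {
      a <- if (oi == "f") seqs[[i]] else rcs[[i]]
      b <- if (oj == "f") seqs[[j]] else rcs[[j]]
      ov <- cpp_best_overlap(a, b, min_overlap, max_mm_rate,
                             min(nchar(a), nchar(b)) - 1L)
      if (ov >= min_overlap)
        out[[length(out) + 1L]] <- list(i = i, oi = oi, j = j, oj = oj,
                                        ov = ov)
    }
  }
  out
}

# physical ends consumed by a join: extending oriented-i's right end uses
# physical end "right" of i when forward, "left" when reversed; attaching at
# oriented-j's left end uses physical "left"/"right" respectively.
join_ends <- function(jn) {
  list(i_end = if (jn$oi == "f") "right" else "left",
       j_end = if (jn$oj == "f") "left" else "right")
}

#' Overlap-based scaffold merging with IR and circle awareness
#'
#' Repeatedly merges scaffold pairs whose ends share an overlap of at least
#' `min_overlap` bases (any strand), longest overlap first. Scaffolds fully
#' contained in another are absorbed. A scaffold whose both physical ends
#' are each contested by two partners behaves like the plastome inverted
#' repeat — it legitimately joins two contexts in opposite orientations —
#' and is duplicated rather than treated as a conflict. A final single
#' scaffold whose end overlaps its own start is closed into a circular
#' assembly.
#'
#' @param asm an [assembly()].
#' @param min_overlap minimum end overlap in bases (>= 20).
#' @param max_mismatch_rate tolerated mismatch fraction within an overlap
#'   (0 = exact, the default).
#' @return a merged [assembly()]; unmergeable scaffolds pass through.
#' @export
overlap_merge <- function(asm, min_overlap = 50L, max_mismatch_rate = 0) {
  stopifnot(min_overlap >= 20L)
  seqs <- as.list(unname(asm$scaffolds))
  if (length(seqs) >= 2L) {
    rcs <- lapply(seqs, cpp_revcomp)
    # absorb contained scaffolds
    drop <- rep(FALSE, length(seqs))
    for (i in seq_along(seqs)) for (j in seq_along(seqs)) {
      if (i == j || drop[i] || drop[j]) next
      li <- nchar(seqs[[i]]); lj <- nchar(seqs[[j]])
      if (li > lj || (li == lj && i < j)) next
      if (grepl(seqs[[i]], seqs[[j]], fixed = TRUE) ||
          grepl(rcs[[i]], seqs[[j]], fixed = TRUE)) drop[i] <- TRUE
    }
    seqs <- seqs[!drop]
    rcs <- rcs[!drop]
    # IR-style duplication: both physical ends contested by >= 2 junctions
    is_dup <- rep(FALSE, length(seqs))
    if (length(seqs) >= 3L) {
      joins <- candidate_joins(seqs, rcs, min_overlap, max_mismatch_rate)
      uses <- list()
      for (jn in joins) {
        e <- join_ends(jn)
        uses[[length(uses) + 1L]] <- data.frame(
          scaf = c(jn$i, jn$j), end = c(e$i_end, e$j_end))
      }
      if (length(uses)) {
        uses <- do.call(rbind, uses)
        for (x in unique(uses$scaf)) {
          cl <- sum(uses$scaf == x & uses$end == "left")
          cr <- sum(uses$scaf == x & uses$end == "right")
          if (cl >= 2L && cr >= 2L) {
            seqs[[length(seqs) + 1L]] <- seqs[[x]]
            rcs[[length(rcs) + 1L]] <- rcs[[x]]
            is_dup <- c(is_dup, TRUE)
          }
        }
      }
    }
    # greedy merging, longest overlap first; when the top join competes
    # with others for an end (the signature of a repeat such as the IR),
    # each competitor is tried as the forced first merge and the
    # arrangement that best closes the genome wins
    first_joins <- list(NULL)
    joins0 <- candidate_joins(seqs, rcs, min_overlap, max_mismatch_rate)
    if (length(joins0) > 1L) {
      ovs <- vapply(joins0, `[[`, numeric(1), "ov")
      top <- joins0[[order(-ovs, vapply(joins0, `[[`, numeric(1), "i"),
                           vapply(joins0, `[[`, numeric(1), "j"))[1]]]
      end_key <- function(jn) {
        e <- join_ends(jn)
        c(paste0(jn$i, "|", e$i_end), paste0(jn$j, "|", e$j_end))
      }
      tk <- end_key(top)
      rivals <- Filter(function(jn) length(intersect(end_key(jn), tk)) > 0L,
                       joins0)
      if (length(rivals) > 1L) first_joins <- rivals
    }
    results <- lapply(first_joins, function(first)
      merge_greedy(seqs, rcs, is_dup, min_overlap, max_mismatch_rate,
                   first))
    score <- vapply(results, function(r)
      c(-as.numeric(r$circular), length(r$seqs),
        -sum(nchar(unlist(r$seqs)))), numeric(3))
    best <- results[[do.call(order, c(lapply(1:3, function(i) score[i, ]),
                                      list(seq_along(results))))[1]]]
    seqs <- best$seqs
    circular <- best$circular
  } else {
    closed <- close_circle(seqs, min_overlap, max_mismatch_rate)
    seqs <- closed$seqs
    circular <- closed$circular
  }
  assembly(unlist(seqs, use.names = FALSE), circular = circular,
           provenance = asm$provenance)
}

# one complete greedy merge pass (optionally seeded with a forced first
# join), followed by removal of unused duplicates and circularization
merge_greedy <- function(seqs, rcs, is_dup, min_overlap, max_mm_rate,
                         first = NULL) {
  apply_join <- function(jn) {
    a <- if (jn$oi == "f") seqs[[jn$i]] else rcs[[jn$i]]
    b <- if (jn$oj == "f") seqs[[jn$j]] else rcs[[jn$j]]
    m <- paste0(a, substr(b, jn$ov + 1L, nchar(b)))
    was_dup <- is_dup[jn$i] && is_dup[jn$j]
    seqs[[jn$i]] <<- m
    rcs[[jn$i]] <<- cpp_revcomp(m)
    seqs[[jn$j]] <<- NULL
    rcs[[jn$j]] <<- NULL
    is_dup[jn$i] <<- was_dup
    is_dup <<- is_dup[-jn$j]
  }
  if (!is.null(first)) apply_join(first)
  repeat {
    if (length(seqs) < 2L) break
    joins <- candidate_joins(seqs, rcs, min_overlap, max_mm_rate)
    if (!length(joins)) break
    ovs <- vapply(joins, `[[`, numeric(1), "ov")
    apply_join(joins[[order(-ovs, vapply(joins, `[[`, numeric(1), "i"),
                            vapply(joins, `[[`, numeric(1), "j"))[1]]])
  }
  # an IR copy that never merged is redundant with its original
  if (any(is_dup)) {
    keep <- !(is_dup & vapply(seq_along(seqs), function(i)
      any(vapply(seq_along(seqs), function(j)
        i != j && (seqs[[i]] == seqs[[j]] || seqs[[i]] == rcs[[j]]),
        logical(1))), logical(1)))
    seqs <- seqs[keep]
  }
  close_circle(seqs, min_overlap, max_mm_rate)
}

close_circle <- function(seqs, min_overlap, max_mm_rate) {
  circular <- FALSE
  if (length(seqs) == 1L) {
    s <- seqs[[1]]
    # the two copies of a terminal redundancy are assembled independently
    # and can disagree at isolated consensus-error positions, so the
    # self-overlap tolerates at least a sequencing-error-scale mismatch
    # rate even when junction merging is exact
    mm <- max(max_mm_rate, 0.01)
    try_close <- function(x) {
      ov <- cpp_best_overlap(x, x, min_overlap, mm, nchar(x) - 1L)
      if (ov >= min_overlap && ov < nchar(x)) substr(x, 1L, nchar(x) - ov)
      else NULL
    }
    closed <- try_close(s)
    if (is.null(closed)) closed <- flip_close(s, min_overlap, mm)
    if (is.null(closed)) closed <- ir_close(s, min_overlap)
    if (!is.null(closed)) {
      seqs[[1]] <- closed
      circular <- TRUE
    }
  }
  list(seqs = seqs, circular = circular)
}

# A walk around a plastome circle can be longer than one period and can
# switch SSC orientation when it re-enters the arc between the IR copies
# (the two orientations are indistinguishable to short inserts); its
# duplicated stretch then appears reverse-complemented and the plain
# suffix/prefix closure fails. The period is still visible: the walk's
# prefix reoccurs where the second turn begins. Each interior
# reoccurrence t of the prefix proposes the circle s[1 .. t-1]; the
# proposal is accepted when the entire walk maps back onto that circle at
# high identity (either strand, across the origin), which a chimera
# cannot do. Returns the circle sequence or NULL.
flip_close <- function(s, min_overlap, mm) {
  n <- nchar(s)
  probe <- substr(s, 1L, min(20L, min_overlap))
  occ <- gregexpr(probe, s, fixed = TRUE)[[1]]
  occ <- as.integer(occ[occ > 1L])
  if (!length(occ)) return(NULL)
  for (t in sort(occ, decreasing = TRUE)) {
    if (t - 1L < 2L * min_overlap) next
    # the turn must be supported by a tolerant common extension
    m <- cpp_common_prefix(substr(s, t, n), s, mm)
    if (m < min_overlap) next
    circ <- substr(s, 1L, t - 1L)
    ref <- paste0(circ, substr(circ, 1L, 200L))
    starts <- unique(c(seq(1L, n - 99L, by = 100L), n - 99L))
    win <- substring(s, starts, starts + 99L)
    mp <- cpp_map_reads(win, ref, 21L)
    explained <- !is.na(mp$ref) &
      mp$matches >= (1 - 2 * mm) * (100L - mp$overhang_left -
                                      mp$overhang_right)
    if (all(explained)) return(circ)
  }
  NULL
}

# A linear scaffold that traversed the plastome once but consumed its
# only copy of the IR interior (LSC + IR + SSC, in some rotation) cannot
# grow further: every end-extension contig is a substring of the interior
# IR and is absorbed. Its ends still betray the circle: the first and
# last bases are reverse complements of interior IR positions. When both
# anchors match uniquely inside the scaffold, the circle is the scaffold
# plus the reverse complement of the interval between the anchors (the
# regenerated second IR copy). Returns the circle or NULL.
ir_close <- function(s, min_overlap, anchor = 30L) {
  n <- nchar(s)
  if (n < 4L * anchor) return(NULL)
  find_unique <- function(pat) {
    occ <- gregexpr(pat, s, fixed = TRUE)[[1]]
    if (length(occ) == 1L && occ[1] > 0L) as.integer(occ[1]) else NA_integer_
  }
  p1 <- find_unique(cpp_revcomp(substr(s, 1L, anchor)))
  p2 <- find_unique(cpp_revcomp(substr(s, n - anchor + 1L, n)))
  if (is.na(p1) || is.na(p2)) return(NULL)
  # both anchors must sit inside the scaffold, in order, and imply an
  # appended IR stretch of meaningful length
  if (p1 <= anchor || p2 + anchor - 1L >= n - anchor) return(NULL)
  if (p2 - p1 - anchor < min_overlap) return(NULL)
  paste0(s, cpp_revcomp(substr(s, p1 + anchor, p2 - 1L)))
}

#' Pseudo-circularize a circular assembly
#'
#' Appends a copy of the first n bases to the end of the linearized circle
#' so that reads spanning the origin can be mapped across it.
#'
#' @param asm a circular [assembly()].
#' @param n number of bases to duplicate (0 <= n <= circle length).
#' @return a linear [assembly()] of length L + n with attribute
#'   `pseudo_circular_n`.
#' @export
pseudo_circularize <- function(asm, n) {
  if (!isTRUE(asm$circular))
    stop("pseudo_circularize requires a circular assembly", call. = FALSE)
  s <- asm$scaffolds[[1]]
  L <- nchar(s)
  if (n < 0L || n > L) stop("n must be between 0 and the circle length",
                            call. = FALSE)
  out <- assembly(paste0(s, substr(s, 1L, n)), circular = FALSE,
                  provenance = asm$provenance)
  attr(out, "pseudo_circular_n") <- as.integer(n)
  out
}

#' Locate the inverted repeat of a circular plastome sequence
#'
#' Finds the longest pair of disjoint intervals on the circle whose
#' sequences are exact reverse complements (seeded on shared k-mers and
#' extended maximally). The two remaining arcs are labelled LSC (longer)
#' and SSC (shorter; may have length 0 under IR expansion).
#'
#' @param x circular sequence (character scalar) or circular [assembly()].
#' @param min_length minimum IR length to report (default 1000).
#' @param seed_k seed k-mer size for the search.
#' @return list of class `plastome_ir` with 1-based inclusive interval
#'   annotations: `ir_starts` (length 2), `ir_length`, `lsc_start`,
#'   `lsc_length`, `ssc_start`, `ssc_length`, and `circle_length`.
#'   Raises a classed error (`plastid_no_ir`) if no inverted repeat of the
#'   required length exists.
#' @export
find_inverted_repeat <- function(x, min_length = 1000L, seed_k = 13L) {
  s <- if (inherits(x, "plastid_assembly")) {
    if (!isTRUE(x$circular)) stop("assembly is not circular", call. = FALSE)
    x$scaffolds[[1]]
  } else as.character(x)
  L <- nchar(s)
  cand <- cpp_find_ir(paste0(s, s), as.integer(min_length),
                      as.integer(seed_k))
  best <- NULL
  if (nrow(cand)) {
    seen <- character(0)
    for (r in seq_len(nrow(cand))) {
      a1 <- cand[r, 1] %% L
      a2 <- cand[r, 2] %% L
      len <- cand[r, 3]
      if (len > L %/% 2L) next
      key <- paste(sort(c(a1, a2)), len, collapse = ":")
      if (key %in% seen) next
      seen <- c(seen, key)
      if (circ_overlap(a1, len, a2, len, L)) next
      best <- c(min(a1, a2), max(a1, a2), len)
      break # candidates are sorted longest-first
    }
  }
  if (is.null(best))
    stop(structure(class = c("plastid_no_ir", "error", "condition"),
                   list(message = sprintf(
                     "no inverted repeat of length >= %d found", min_length),
                     call = sys.call(-1))))
  s1 <- best[1]; s2 <- best[2]; len <- best[3]
  e1 <- s1 + len  # 0-based half-open ends
  e2 <- s2 + len
  arc_a <- (s2 - e1) %% L   # between copy 1 and copy 2
  arc_b <- (s1 - e2) %% L   # wraps around the origin
  if (arc_a >= arc_b) {
    lsc <- c(e1, arc_a); ssc <- c(e2 %% L, arc_b)
  } else {
    lsc <- c(e2 %% L, arc_b); ssc <- c(e1, arc_a)
  }
  structure(list(ir_starts = c(s1, s2) + 1L, ir_length = len,
                 lsc_start = lsc[1] + 1L, lsc_length = lsc[2],
                 ssc_start = ssc[1] + 1L, ssc_length = ssc[2],
                 circle_length = L), class = "plastome_ir")
}

#' @export
print.plastome_ir <- function(x, ...) {
  cat(sprintf(
    "inverted repeat: 2 x %d bp at %d and %d; LSC %d bp, SSC %d bp (circle %d bp)\n",
    x$ir_length, x$ir_starts[1], x$ir_starts[2], x$lsc_length, x$ssc_length,
    x$circle_length))
  invisible(x)
}

#' Final plastome layout(s) of a circular assembly
#'
#' Because short-read insert sizes do not span a complete IR, the relative
#' orientation of SSC and LSC is ambiguous; the pipeline can emit the three
#' linear fragments (LSC, IR, SSC), both possible circular configurations,
#' or a single circular configuration chosen by seeded RNG.
#'
#' @param asm a circular [assembly()].
#' @param mode `"three_linear"`, `"two_circular"` or `"one_circular"`.
#' @param ir_min_length minimum IR length for annotation.
#' @param seed RNG seed for the `one_circular` choice.
#' @return object of class `plastome_layout`: fields `lsc`, `ir`, `ssc`,
#'   `orientation`, `circular_sequence` (for circular modes a list
#'   `sequences` holds every emitted record). When no IR is found only
#'   `one_circular` is permitted and the assembly's own circle is returned.
#' @export
layout_outputs <- function(asm, mode = c("one_circular", "three_linear",
                                         "two_circular"),
                           ir_min_length = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  if (!isTRUE(asm$circular))
    stop("layout requires a circular assembly", call. = FALSE)
  s <- asm$scaffolds[[1]]
  ir <- tryCatch(find_inverted_repeat(s, ir_min_length),
                 plastid_no_ir = function(e) NULL)
  if (is.null(ir)) {
    if (mode != "one_circular")
      stop("no inverted repeat found; only the one_circular layout is",
           " available", call. = FALSE)
    return(structure(list(lsc = NULL, ir = NULL, ssc = NULL,
                          orientation = 1L, circular_sequence = s,
                          mode = mode,
                          sequences = list(circular = s)),
                     class = "plastome_layout"))
  }
  lsc_seq <- circ_substr(s, ir$lsc_start - 1L, ir$lsc_length)
  ssc_seq <- circ_substr(s, ir$ssc_start - 1L, ir$ssc_length)
  # the IR copy that follows the LSC arc on the circle
  lsc_end0 <- (ir$lsc_start - 1L + ir$lsc_length) %% ir$circle_length
  ir_seq <- circ_substr(s, lsc_end0, ir$ir_length)
  orient1 <- paste0(lsc_seq, ir_seq, ssc_seq, cpp_revcomp(ir_seq))
  orient2 <- paste0(lsc_seq, ir_seq, cpp_revcomp(ssc_seq), cpp_revcomp(ir_seq))
  seqs <- switch(mode,
    three_linear = list(
      LSC = lsc_seq, IR = ir_seq, SSC = ssc_seq),
    two_circular = list(orientation_1 = orient1, orientation_2 = orient2),
    one_circular = {
      pick <- withr::with_seed(seed, sample.int(2L, 1L))
      stats::setNames(list(if (pick == 1L) orient1 else orient2),
                      paste0("orientation_", pick))
    })
  orientation <- if (mode == "one_circular")
    as.integer(sub("orientation_", "", names(seqs)[1])) else 1L
  structure(list(lsc = lsc_seq, ir = ir_seq, ssc = ssc_seq,
                 orientation = orientation,
                 circular_sequence = if (orientation == 1L) orient1 else orient2,
                 ir_annotation = ir, mode = mode, sequences = seqs),
            class = "plastome_layout")
}

#' @export
print.plastome_layout <- function(x, ...) {
  cat(sprintf("plastome layout (%s): %s\n", x$mode,
              paste(sprintf("%s=%d bp", names(x$sequences),
                            nchar(unlist(x$sequences))), collapse = ", ")))
  invisible(x)
}

#' Scaffold-end connectivity matrix
#'
#' Counts, for every pair of scaffold ends, the read pairs whose placements
#' link them: both mates mapped near an end (within `end_window`), facing
#' outward, on different scaffolds — or on the two ends of the same
#' scaffold, which is evidence of circularity.
#'
#' @param reads a [read_set()].
#' @param asm an [assembly()].
#' @param seed_len mapper seed length.
#' @param end_window maximum distance (bases) from the scaffold end.
#' @param max_pairs subsample cap on the pairs used for counting (evenly
#'   spaced, deterministic).
#' @return object of class `connectivity_matrix`: data frame `end1`,
#'   `end2`, `count` with ends labelled `"<scaffold id>|left"` /
#'   `"...|right"`, symmetric pairs stored once.
#' @export
build_connectivity_matrix <- function(reads, asm, seed_len = 21L,
                                      end_window = 500L,
                                      max_pairs = 10000L) {
  empty <- structure(list(links = data.frame(end1 = character(),
                                             end2 = character(),
                                             count = integer())),
                     class = "connectivity_matrix")
  np <- n_pairs(reads)
  if (np == 0L || n_scaffolds(asm) == 0L) return(empty)
  idx <- if (np > max_pairs)
    unique(round(seq(1L, np, length.out = max_pairs))) else seq_len(np)
  refs <- unname(asm$scaffolds)
  ids <- names(asm$scaffolds)
  reflen <- nchar(refs)
  m1 <- cpp_map_reads(reads$pairs$seq1[idx], refs, as.integer(seed_len))
  m2 <- cpp_map_reads(reads$pairs$seq2[idx], refs, as.integer(seed_len))
  rl1 <- nchar(reads$pairs$seq1[idx])
  rl2 <- nchar(reads$pairs$seq2[idx])
  end_of <- function(m, rl) {
    # the fragment continues past the read's 3' end: + strand points right,
    # - strand points left
    out <- rep(NA_character_, nrow(m))
    ok <- !is.na(m$ref)
    d_right <- reflen[m$ref] - (m$pos + rl)
    d_left <- m$pos
    right <- ok & m$strand == 1L & d_right <= end_window
    left <- ok & m$strand == -1L & d_left <= end_window
    out[right] <- paste0(ids[m$ref[right]], "|right")
    out[left] <- paste0(ids[m$ref[left]], "|left")
    out
  }
  e1 <- end_of(m1, rl1)
  e2 <- end_of(m2, rl2)
  ok <- !is.na(e1) & !is.na(e2) & e1 != e2
  if (!any(ok)) return(empty)
  a <- pmin(e1[ok], e2[ok])
  b <- pmax(e1[ok], e2[ok])
  agg <- aggregate(list(count = rep(1L, sum(ok))),
                   by = list(end1 = a, end2 = b), FUN = sum)
  agg <- agg[order(-agg$count, agg$end1, agg$end2), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(links = agg), class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix: %d linked end pair(s)\n",
              nrow(x$links)))
  if (nrow(x$links)) print(utils::head(x$links, 10L))
  invisible(x)
}

#' Re-scaffold using spanning-read connectivity
#'
#' Greedily joins scaffold ends supported by at least `min_support`
#' read(-pair)s, highest support first, each physical end used at most
#' once. Joined ends are bridged seamlessly when a direct sequence overlap
#' exists, otherwise with a run of `gap_n` N characters. A chain whose two
#' outer ends are linked closes into a circular assembly. Conflicting
#' lower-support joins are skipped (and logged).
#'
#' @param asm an [assembly()].
#' @param matrix a [build_connectivity_matrix()] result.
#' @param min_support minimum read-pair support (default 3).
#' @param gap_n N-run length for unspanned junctions.
#' @param ambiguous `"greedy"` resolves contested ends by support order;
#'   `"skip"` refuses to join any end with two or more qualifying partners
#'   (the conservative policy used during initial contig scaffolding).
#' @param min_overlap minimum direct overlap for a seamless junction.
#' @return a re-scaffolded [assembly()].
#' @export
rescaffold_with_matrix <- function(asm, matrix, min_support = 3L,
                                   gap_n = 100L,
                                   ambiguous = c("greedy", "skip"),
                                   min_overlap = 20L) {
  ambiguous <- match.arg(ambiguous)
  links <- matrix$links
  links <- links[links$count >= min_support, , drop = FALSE]
  if (ambiguous == "skip" && nrow(links)) {
    ends <- c(links$end1, links$end2)
    contested <- unique(ends[duplicated(ends)])
    keep <- !(links$end1 %in% contested) & !(links$end2 %in% contested)
    links <- links[keep, , drop = FALSE]
  }
  if (!nrow(links)) return(asm)
  ids <- names(asm$scaffolds)
  # chains of oriented scaffolds; orient +1 = forward
  chains <- lapply(ids, function(id)
    list(members = data.frame(id = id, orient = 1L,
                              stringsAsFactors = FALSE), circular = FALSE))
  chain_of <- stats::setNames(seq_along(ids), ids)
  chain_ends <- function(ch) {
    first <- ch$members[1, ]
    last <- ch$members[nrow(ch$members), ]
    c(start = paste0(first$id, "|", if (first$orient == 1L) "left" else "right"),
      end = paste0(last$id, "|", if (last$orient == 1L) "right" else "left"))
  }
  reverse_chain <- function(ch) {
    ch$members <- ch$members[rev(seq_len(nrow(ch$members))), , drop = FALSE]
    ch$members$orient <- -ch$members$orient
    ch
  }
  used_end <- character(0)
  for (r in seq_len(nrow(links))) {
    e1 <- links$end1[r]; e2 <- links$end2[r]
    if (e1 %in% used_end || e2 %in% used_end) {
      plastid_log("rescaffold: skipping conflicting join %s - %s (support %d)",
                  e1, e2, links$count[r])
      next
    }
    s1 <- sub("\\|(left|right)$", "", e1)
    s2 <- sub("\\|(left|right)$", "", e2)
    c1 <- chain_of[[s1]]; c2 <- chain_of[[s2]]
    if (is.na(c1) || is.na(c2)) next
    ch1 <- chains[[c1]]; ch2 <- chains[[c2]]
    if (ch1$circular || ch2$circular) next
    ends1 <- chain_ends(ch1); ends2 <- chain_ends(ch2)
    if (!(e1 %in% ends1) || !(e2 %in% ends2)) next # interior end
    if (c1 == c2) {
      # linking the two outer ends of one chain closes it
      if ((e1 == ends1["start"] && e2 == ends1["end"]) ||
          (e1 == ends1["end"] && e2 == ends1["start"])) {
        chains[[c1]]$circular <- TRUE
        used_end <- c(used_end, e1, e2)
      }
      next
    }
    if (e1 == ends1["start"]) ch1 <- reverse_chain(ch1)
    if (e2 == chain_ends(ch2)["end"]) ch2 <- reverse_chain(ch2)
    ch1$members <- rbind(ch1$members, ch2$members)
    chains[[c1]] <- ch1
    chains[[c2]] <- list(members = ch2$members[0, , drop = FALSE],
                         circular = FALSE, dead = TRUE)
    chain_of[ch1$members$id] <- c1
    used_end <- c(used_end, e1, e2)
  }
  live <- vapply(chains, function(ch) nrow(ch$members) > 0L &&
                   !isTRUE(ch$dead), logical(1))
  chains <- chains[live]
  gap_run <- strrep("N", gap_n)
  build_chain_seq <- function(ch) {
    segs <- lapply(seq_len(nrow(ch$members)), function(i) {
      s <- asm$scaffolds[[ch$members$id[i]]]
      if (ch$members$orient[i] == 1L) s else cpp_revcomp(s)
    })
    acc <- segs[[1]]
    for (i in seq_along(segs)[-1]) {
      ov <- cpp_best_overlap(acc, segs[[i]], min_overlap, 0,
                             min(nchar(acc), nchar(segs[[i]])) - 1L)
      acc <- if (ov >= min_overlap)
        paste0(acc, substr(segs[[i]], ov + 1L, nchar(segs[[i]])))
      else paste0(acc, gap_run, segs[[i]])
    }
    if (ch$circular) {
      ov <- cpp_best_overlap(acc, acc, min_overlap, 0, nchar(acc) - 1L)
      if (ov >= min_overlap && ov < nchar(acc)) {
        acc <- substr(acc, 1L, nchar(acc) - ov)
      } else {
        # place the junction N run away from the sequence boundary by
        # rotating the circle to the middle of its first scaffold
        full <- paste0(acc, gap_run)
        off <- nchar(segs[[1]]) %/% 2L
        acc <- paste0(substr(full, off + 1L, nchar(full)),
                      substr(full, 1L, off))
      }
    }
    acc
  }
  out_seqs <- vapply(chains, build_chain_seq, character(1))
  circular <- length(chains) == 1L && chains[[1]]$circular
  assembly(out_seqs, circular = circular, provenance = asm$provenance)
}
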