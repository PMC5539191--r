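#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors. `N` is its own
#' complement.
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  vapply(as.character(x), cpp_revcomp, character(1), USE.NAMES = FALSE)
}

plastid_log <- function(...) {
  if (isTRUE(getOption("plastid.verbose", FALSE))) message(sprintf(...))
}

#' Percent identity of a linear sequence against a circular reference
#'
#' Anchors the query on the doubled circle (either strand) with short exact
#' seeds and scores an ungapped alignment, so rotation and strand of the
#' circularization do not matter. Intended for validating assemblies against
#' a known circle (e.g. simulator truth).
#'
#' @param query linear sequence (character scalar) or circular [assembly()].
#' @param circle the reference circular sequence (character scalar).
#' @param anchor_len length of the exact seed used to fix the rotation.
#' @return identity fraction in `[0, 1]`: matching positions divided by the
#'   longer of query length and circle length. Returns 0 when no anchor
#'   places the query.
#' @export
circular_identity <- function(query, circle, anchor_len = 32L) {
  if (inherits(query, "plastid_assembly")) {
    stopifnot(isTRUE(query$circular))
    query <- query$scaffolds[[1]]
  }
  nq <- nchar(query)
  L <- nchar(circle)
  if (nq < anchor_len || L < anchor_len) return(0)
  doubled <- paste0(circle, circle)
  best <- 0
  denom <- max(nq, L)
  for (q in c(query, cpp_revcomp(query))) {
    # try a few anchors in case the query start is erroneous
    offs <- unique(pmin(nq - anchor_len + 1L,
                        c(1L, nq %/% 4L, nq %/% 2L, 3L * nq %/% 4L)))
    offs <- offs[offs >= 1L]
    for (off in offs) {
      seed <- substr(q, off, off + anchor_len - 1L)
      p <- regexpr(seed, doubled, fixed = TRUE)[1]
      if (p < 0) next
      start <- p - off + 1L
      if (start < 1L) start <- start + L
      ref <- substr(doubled, start, start + nq - 1L)
      d <- cpp_hamming(q, ref)
      id <- 1 - d / denom
      if (id > best) best <- id
    }
  }
  best
}

# positions are 0-based half-open internally; this extracts a circular
# substring given 0-based start and length
circ_substr <- function(s, start0, len) {
  L <- nchar(s)
  if (len == 0) return("")
  start0 <- start0 %% L
  if (start0 + len <= L) return(substr(s, start0 + 1L, start0 + len))
  paste0(substr(s, start0 + 1L, L), substr(s, 1L, start0 + len - L))
}

# do two circular intervals (0-based start, length) on a circle of size L
# share any position?
circ_overlap <- function(s1, l1, s2, l2, L) {
  if (l1 == 0 || l2 == 0) return(FALSE)
  split_iv <- function(s, l) {
    s <- s %% L
    if (s + l <= L) list(c(s, s + l)) else list(c(s, L), c(0, s + l - L))
  }
  for (a in split_iv(s1, l1)) for (b in split_iv(s2, l2)) {
    if (max(a[1], b[1]) < min(a[2], b[2])) return(TRUE)
  }
  FALSE
}
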