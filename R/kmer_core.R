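#' Canonical (ordinal) k-mer table
#'
#' A sorted map from canonical k-mer to occurrence count. The canonical
#' representative of a window and its reverse complement is the one whose
#' middle nucleotide is A or C — well-defined for odd k, since the middle
#' base of the reverse complement is always the complement of the middle
#' base.
#'
#' @param kmers character vector of canonical k-mers, strictly ascending.
#' @param counts positive integer counts, same length.
#' @param k k-mer size; inferred from `kmers` when omitted.
#' @param validate check the canonical-form and ordering invariants (skipped
#'   internally for tables produced by the counting kernel).
#' @return an object of class `kmer_table` with fields `k`, `kmer`, `count`.
#' @export
kmer_table <- function(kmers, counts, k = NULL, validate = TRUE) {
  kmers <- as.character(kmers)
  counts <- as.integer(counts)
  if (length(kmers) != length(counts))
    stop("kmers and counts differ in length", call. = FALSE)
  if (is.null(k)) k <- if (length(kmers)) nchar(kmers[[1]]) else NA_integer_
  k <- as.integer(k)
  if (validate && length(kmers)) {
    if (k %% 2L == 0L) stop("k must be odd", call. = FALSE)
    if (any(nchar(kmers) != k))
      stop("all k-mers must have length k", call. = FALSE)
    mid <- substr(kmers, (k + 1L) %/% 2L, (k + 1L) %/% 2L)
    if (!all(mid %in% c("A", "C")))
      stop("non-canonical k-mer (middle base not A/C)", call. = FALSE)
    if (is.unsorted_kmers(kmers) || anyDuplicated(kmers))
      stop("k-mers must be strictly ascending", call. = FALSE)
    if (any(counts < 1L)) stop("counts must be >= 1", call. = FALSE)
  }
  structure(list(k = k, kmer = kmers, count = counts), class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("kmer_table: %d canonical %d-mers, total count %.0f\n",
              length(x$kmer), x$k, sum(as.numeric(x$count))))
  invisible(x)
}

#' Canonical form of k-mer windows
#'
#' Returns each window unchanged if its middle base is A or C, otherwise its
#' reverse complement. Windows must have odd length and contain only ACGT;
#' a window containing N (or any other symbol) raises a classed error
#' (`plastid_ambiguous_kmer`) so callers can skip it.
#'
#' @param window character vector of equal, odd-length DNA windows.
#' @return character vector of canonical k-mers.
#' @export
canonical_kmer <- function(window) {
  window <- toupper(as.character(window))
  k <- unique(nchar(window))
  if (length(k) != 1L) stop("windows must share one length", call. = FALSE)
  if (k %% 2L == 0L) stop("k-mer length must be odd", call. = FALSE)
  if (!all(grepl("^[ACGT]+$", window)))
    stop(structure(class = c("plastid_ambiguous_kmer", "error", "condition"),
                   list(message = "ambiguous k-mer (non-ACGT base)",
                        call = sys.call(-1))))
  mid <- substr(window, (k + 1L) %/% 2L, (k + 1L) %/% 2L)
  flip <- !(mid %in% c("A", "C"))
  window[flip] <- revcomp(window[flip])
  window
}

#' Count canonical k-mers in reads or sequences
#'
#' Every length-k window of every sequence (both mates of every pair, plus
#' singles) contributes one count to its canonical k-mer. Windows containing
#' N are skipped; the number of skipped windows is recorded in the
#' `"skipped"` attribute. Sequences shorter than k contribute nothing.
#'
#' @param x a [read_set()], character vector of sequences, or
#'   `Biostrings::DNAStringSet`.
#' @param k odd k-mer size, >= 3.
#' @return a [kmer_table()].
#' @export
count_kmers <- function(x, k) {
  k <- as.integer(k)
  if (k < 3L || k %% 2L == 0L) stop("k must be odd and >= 3", call. = FALSE)
  seqs <- if (inherits(x, "read_set")) read_sequences(x) else as.character(x)
  res <- cpp_count_kmers(seqs, k)
  tab <- kmer_table(res$kmer, res$count, k, validate = FALSE)
  attr(tab, "skipped") <- res$skipped
  if (res$skipped > 0)
    plastid_log("count_kmers: skipped %.0f windows containing N", res$skipped)
  tab
}

#' Frequency histogram of a k-mer table
#'
#' For each occurrence frequency f, records the number of distinct canonical
#' k-mers occurring exactly f times and the volume distinct × f (the number
#' of read-window occurrences contributed at that frequency).
#'
#' @param table a [kmer_table()].
#' @return an object of class `kmer_histogram` with fields `k` and `rows`
#'   (data frame `frequency`, `distinct`, `volume`).
#' @export
kmer_histogram <- function(table) {
  stopifnot(inherits(table, "kmer_table"))
  if (!length(table$count)) {
    rows <- data.frame(frequency = integer(), distinct = integer(),
                       volume = numeric())
  } else {
    t <- table(table$count)
    frequency <- as.integer(names(t))
    distinct <- as.integer(t)
    o <- order(frequency)
    rows <- data.frame(frequency = frequency[o], distinct = distinct[o],
                       volume = as.numeric(distinct[o]) * frequency[o])
  }
  structure(list(k = table$k, rows = rows), class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("kmer_histogram (k=%d): %d frequencies, total volume %.0f\n",
              x$k, nrow(x$rows), sum(x$rows$volume)))
  invisible(x)
}

#' Subset a k-mer table by frequency band
#'
#' @param table a [kmer_table()].
#' @param f_min,f_max inclusive frequency bounds, `1 <= f_min <= f_max`.
#' @return a [kmer_table()] of the entries with counts inside the band,
#'   order preserved.
#' @export
select_kmers_by_frequency <- function(table, f_min, f_max = Inf) {
  stopifnot(inherits(table, "kmer_table"))
  if (f_min < 1 || f_min > f_max)
    stop("need 1 <= f_min <= f_max", call. = FALSE)
  keep <- table$count >= f_min & table$count <= f_max
  kmer_table(table$kmer[keep], table$count[keep], table$k, validate = FALSE)
}

#' Set difference of k-mer tables
#'
#' Entries of `other` whose k-mer does not occur in `positive` — the
#' negative-selection table construction used by the gap-filling stage.
#'
#' @param positive,other [kmer_table()] objects with the same k.
#' @return a [kmer_table()].
#' @export
table_difference <- function(positive, other) {
  stopifnot(inherits(positive, "kmer_table"), inherits(other, "kmer_table"))
  if (length(positive$kmer) && length(other$kmer) &&
      positive$k != other$k)
    stop("k-mer tables have different k", call. = FALSE)
  keep <- !(other$kmer %in% positive$kmer)
  kmer_table(other$kmer[keep], other$count[keep], other$k, validate = FALSE)
}
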