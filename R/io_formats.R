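#' Construct a read set
#'
#' The unit of selection and batching throughout the pipeline: a collection
#' of paired-end reads plus unpaired (single) reads. Pairs are stored
#' record-by-record so that mate1 and mate2 of a pair always originate from
#' the same record index of their source files.
#'
#' @param pairs data frame with columns `id1, seq1, qual1, id2, seq2, qual2`
#'   (qualities may be `NA` for FASTA-derived reads), or `NULL`.
#' @param singles data frame with columns `id, seq, qual`, or `NULL`.
#' @return an object of class `read_set`.
#' @export
read_set <- function(pairs = NULL, singles = NULL) {
  empty_pairs <- data.frame(id1 = character(), seq1 = character(),
                            qual1 = character(), id2 = character(),
                            seq2 = character(), qual2 = character(),
                            stringsAsFactors = FALSE)
  empty_singles <- data.frame(id = character(), seq = character(),
                              qual = character(), stringsAsFactors = FALSE)
  if (is.null(pairs) || nrow(pairs) == 0L) pairs <- empty_pairs
  if (is.null(singles) || nrow(singles) == 0L) singles <- empty_singles
  check_rec <- function(seq, qual, where) {
    if (!all(grepl("^[ACGTNacgtn]*$", seq)))
      stop("non-ACGTN characters in ", where, " sequences", call. = FALSE)
    ok <- is.na(qual) | nchar(qual) == nchar(seq)
    if (!all(ok))
      stop("sequence/quality length mismatch in ", where, call. = FALSE)
  }
  check_rec(pairs$seq1, pairs$qual1, "mate1")
  check_rec(pairs$seq2, pairs$qual2, "mate2")
  check_rec(singles$seq, singles$qual, "singles")
  structure(list(pairs = pairs, singles = singles), class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d pairs, %d singles\n",
              n_pairs(x), n_singles(x)))
  invisible(x)
}

#' Number of read pairs / single reads in a read set
#' @param rs a [read_set()].
#' @return integer count.
#' @export
n_pairs <- function(rs) nrow(rs$pairs)

#' @rdname n_pairs
#' @export
n_singles <- function(rs) nrow(rs$singles)

#' All read sequences of a read set as a character vector
#'
#' Order: mate1 of every pair, then mate2 of every pair, then singles.
#' @param rs a [read_set()].
#' @export
read_sequences <- function(rs) {
  c(rs$pairs$seq1, rs$pairs$seq2, rs$singles$seq)
}

# subset by pair / single row indices, preserving order
subset_reads <- function(rs, pair_idx, single_idx = integer(0)) {
  read_set(rs$pairs[pair_idx, , drop = FALSE],
           rs$singles[single_idx, , drop = FALSE])
}

read_fastq_file <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq",
                                 with.qualities = TRUE),
    error = function(e) stop("unparseable FASTQ file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

write_fastq_file <- function(df, path, id = df$id, seq = df$seq,
                             qual = df$qual) {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- id
  qual[is.na(qual)] <- vapply(nchar(seq[is.na(qual)]),
                              function(n) strrep("I", n), character(1))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Load a directory of FASTQ files into a read set
#'
#' Files whose names differ only in a mate token immediately before the
#' `.fastq`/`.fq` (optionally `.gz`) extension are paired record-by-record;
#' accepted tokens are `_1`/`_2`, `_R1`/`_R2` and `.1`/`.2`. All other files
#' contribute single-end reads. Gzip compression is handled transparently.
#'
#' @param path directory containing FASTQ files.
#' @return a [read_set()].
#' @export
scan_input_directory <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  files <- sort(list.files(path, pattern = "\\.(fastq|fq)(\\.gz)?$",
                           full.names = TRUE))
  if (!length(files)) stop("no FASTQ files found in ", path, call. = FALSE)
  core <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(files))
  m <- regmatches(core, regexpr("(_R?[12]|\\.[12])$", core))
  mate <- rep(NA_integer_, length(files))
  stem <- core
  has_tok <- lengths(regmatches(core, gregexpr("(_R?[12]|\\.[12])$", core))) > 0
  tok <- sub("^.*?(_R?[12]|\\.[12])$", "\\1", core)
  mate[has_tok] <- as.integer(sub("\\D*", "", tok[has_tok]))
  stem[has_tok] <- substr(core[has_tok], 1L,
                          nchar(core[has_tok]) - nchar(tok[has_tok]))
  pairs_list <- list()
  singles_list <- list()
  used <- rep(FALSE, length(files))
  for (s in unique(stem[has_tok])) {
    i1 <- which(stem == s & mate == 1L)
    i2 <- which(stem == s & mate == 2L)
    if (length(i1) == 1L && length(i2) == 1L) {
      r1 <- read_fastq_file(files[i1])
      r2 <- read_fastq_file(files[i2])
      if (nrow(r1) != nrow(r2))
        stop(sprintf("paired files have unequal record counts: %s (%d) vs %s (%d)",
                     files[i1], nrow(r1), files[i2], nrow(r2)), call. = FALSE)
      pairs_list[[s]] <- data.frame(id1 = r1$id, seq1 = r1$seq,
                                    qual1 = r1$qual, id2 = r2$id,
                                    seq2 = r2$seq, qual2 = r2$qual,
                                    stringsAsFactors = FALSE)
      used[c(i1, i2)] <- TRUE
    }
  }
  for (i in which(!used)) singles_list[[files[i]]] <- read_fastq_file(files[i])
  read_set(pairs = if (length(pairs_list)) do.call(rbind, c(pairs_list, make.row.names = FALSE)),
           singles = if (length(singles_list)) do.call(rbind, c(singles_list, make.row.names = FALSE)))
}

#' Write a read set as FASTQ files
#'
#' Pairs go to `<prefix>_1.fastq` / `<prefix>_2.fastq`, singles to
#' `<prefix>.fastq`, following the naming convention that
#' [scan_input_directory()] re-pairs.
#'
#' @param rs a [read_set()].
#' @param dir output directory (created if absent).
#' @param prefix file name prefix.
#' @return invisibly, the written paths.
#' @export
write_read_set <- function(rs, dir, prefix = "reads") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  if (n_pairs(rs) > 0L) {
    p1 <- file.path(dir, paste0(prefix, "_1.fastq"))
    p2 <- file.path(dir, paste0(prefix, "_2.fastq"))
    write_fastq_file(NULL, p1, rs$pairs$id1, rs$pairs$seq1, rs$pairs$qual1)
    write_fastq_file(NULL, p2, rs$pairs$id2, rs$pairs$seq2, rs$pairs$qual2)
    out <- c(out, p1, p2)
  }
  if (n_singles(rs) > 0L) {
    ps <- file.path(dir, paste0(prefix, ".fastq"))
    write_fastq_file(rs$singles, ps)
    out <- c(out, ps)
  }
  invisible(out)
}

#' Write / read a canonical k-mer table as TSV
#'
#' The on-disk format is two tab-separated columns, `kmer` and `count`, one
#' row per canonical k-mer in ascending lexicographic order, no header.
#' Reading verifies the format and ordering and round-trips exactly.
#'
#' @param table a [kmer_table()].
#' @param path output file.
#' @return `write_kmer_table` returns the path invisibly; `read_kmer_table`
#'   returns a [kmer_table()].
#' @export
write_kmer_table <- function(table, path) {
  stopifnot(inherits(table, "kmer_table"))
  if (is.unsorted_kmers(table$kmer))
    stop("k-mer table is not sorted", call. = FALSE)
  writeLines(if (length(table$kmer))
    paste0(table$kmer, "\t", table$count) else character(0), path)
  invisible(path)
}

is.unsorted_kmers <- function(x) {
  length(x) > 1L && !identical(order(x, method = "radix"), seq_along(x))
}

#' @rdname write_kmer_table
#' @export
read_kmer_table <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(kmer_table(character(0), integer(0)))
  ok <- grepl("^[ACGT]+\t[0-9]+$", lines)
  if (!all(ok))
    stop("malformed k-mer table row at line ", which(!ok)[1], " of ", path,
         call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kmers <- vapply(parts, `[[`, character(1), 1L)
  counts <- as.integer(vapply(parts, `[[`, character(1), 2L))
  if (is.unsorted_kmers(kmers))
    stop("k-mer table rows out of order in ", path, call. = FALSE)
  kmer_table(kmers, counts)
}

#' Bin a k-mer histogram
#'
#' Frequencies are grouped into half-open bins `[b, b + bin_size)` starting
#' at 1; distinct-k-mer counts and volumes are summed within each bin.
#'
#' @param hist a [kmer_histogram()].
#' @param bin_size one of 1 (unbinned), 10, 25, 100, 250.
#' @return data frame with columns `bin_start`, `distinct_kmers`, `volume`.
#' @export
bin_histogram <- function(hist, bin_size = 1L) {
  stopifnot(inherits(hist, "kmer_histogram"))
  if (!bin_size %in% c(1L, 10L, 25L, 100L, 250L))
    stop("bin_size must be one of 1, 10, 25, 100, 250", call. = FALSE)
  rows <- hist$rows
  if (nrow(rows) == 0L)
    return(data.frame(bin_start = integer(), distinct_kmers = integer(),
                      volume = numeric()))
  bin <- ((rows$frequency - 1L) %/% bin_size) * bin_size + 1L
  agg <- aggregate(cbind(distinct_kmers = rows$distinct,
                         volume = rows$volume), by = list(bin_start = bin),
                   FUN = sum)
  agg[order(agg$bin_start), , drop = FALSE]
}

#' Write a (possibly binned) k-mer volume histogram as TSV
#'
#' @param hist a [kmer_histogram()].
#' @param path output file.
#' @param bin_size frequency bin width, see [bin_histogram()].
#' @return the path, invisibly.
#' @export
write_histogram <- function(hist, path, bin_size = 1L) {
  agg <- bin_histogram(hist, bin_size)
  lines <- c("bin_start\tdistinct_kmers\tvolume",
             if (nrow(agg)) paste(agg$bin_start, agg$distinct_kmers,
                                  agg$volume, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write an assembly as FASTA
#'
#' Headers carry the scaffold id, length, gap count and, for circular
#' assemblies, a `circular` flag. Coordinates in any interval annotations
#' are 1-based inclusive.
#'
#' @param asm an [assembly()].
#' @param path output FASTA file.
#' @return the path, invisibly.
#' @export
write_assembly_fasta <- function(asm, path) {
  seqs <- asm$scaffolds
  ids <- names(seqs)
  hdr <- sprintf("%s length=%d gaps=%d%s", ids, nchar(seqs),
                 vapply(seqs, function(s) nrow(scaffold_gaps(s)), integer(1)),
                 if (isTRUE(asm$circular)) " circular" else "")
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read sequences from a FASTA file as a plain character vector
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- names(x)
  out
}
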