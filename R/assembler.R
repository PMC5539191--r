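#' Construct an assembly
#'
#' An ordered set of scaffolds over `{A,C,G,T,N}` plus a circularity flag
#' and provenance (which K, batch size, stage and iteration produced it).
#' Leading and trailing N runs are trimmed on construction; gap statistics
#' are derived from the maximal internal N runs.
#'
#' @param scaffolds character vector of scaffold sequences (optionally
#'   named; unnamed scaffolds get ids `scaffold_1`, ...).
#' @param circular is the assembly a closed circle? Requires exactly one
#'   scaffold.
#' @param provenance list with elements such as `K`, `batch_size`, `stage`,
#'   `iteration`.
#' @param coverage optional numeric per-scaffold mean read coverage.
#' @return an object of class `plastid_assembly`.
#' @export
assembly <- function(scaffolds = character(0), circular = FALSE,
                     provenance = list(), coverage = NULL) {
  scaffolds <- toupper(as.character(scaffolds))
  keep <- nchar(scaffolds) > 0L
  scaffolds <- scaffolds[keep]
  if (!is.null(coverage)) coverage <- coverage[keep]
  # no leading/trailing N runs
  scaffolds <- sub("^N+", "", sub("N+$", "", scaffolds))
  keep <- nchar(scaffolds) > 0L
  scaffolds <- scaffolds[keep]
  if (!is.null(coverage)) coverage <- coverage[keep]
  if (!all(grepl("^[ACGTN]*$", scaffolds)))
    stop("scaffolds must be over {A,C,G,T,N}", call. = FALSE)
  if (isTRUE(circular) && length(scaffolds) != 1L)
    stop("a circular assembly must consist of exactly one scaffold",
         call. = FALSE)
  if (length(scaffolds) &&
      (is.null(names(scaffolds)) || any(names(scaffolds) == "")))
    names(scaffolds) <- paste0("scaffold_", seq_along(scaffolds))
  structure(list(scaffolds = scaffolds, circular = isTRUE(circular),
                 provenance = provenance, coverage = coverage),
            class = "plastid_assembly")
}

#' @export
print.plastid_assembly <- function(x, ...) {
  cat(sprintf("assembly: %d scaffold(s), %d gap(s), %d bp%s\n",
              n_scaffolds(x), n_gaps(x), total_length(x),
              if (x$circular) ", circular" else ""))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance), unlist(x$provenance),
                               sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# maximal N runs of one scaffold: data frame (start, length), 1-based start
scaffold_gaps <- function(seq) {
  m <- gregexpr("N+", seq)[[1]]
  if (m[1] == -1L)
    return(data.frame(start = integer(), length = integer()))
  data.frame(start = as.integer(m), length = attr(m, "match.length"))
}

#' Assembly summary statistics
#' @param asm an [assembly()].
#' @return `n_scaffolds`/`n_gaps`/`total_length` return scalars;
#'   `assembly_stats` a one-row data frame.
#' @export
n_scaffolds <- function(asm) length(asm$scaffolds)

#' @rdname n_scaffolds
#' @export
n_gaps <- function(asm)
  sum(vapply(asm$scaffolds, function(s) nrow(scaffold_gaps(s)), integer(1)))

#' @rdname n_scaffolds
#' @export
total_length <- function(asm) sum(nchar(asm$scaffolds))

total_n_bases <- function(asm)
  sum(vapply(gregexpr("N", asm$scaffolds),
             function(m) if (m[1] == -1L) 0L else length(m), integer(1)))

#' @rdname n_scaffolds
#' @export
assembly_stats <- function(asm) {
  data.frame(n_scaffolds = n_scaffolds(asm), n_gaps = n_gaps(asm),
             total_length = total_length(asm), n_bases_n = total_n_bases(asm),
             circular = asm$circular,
             K = if (is.null(asm$provenance$K)) NA_integer_ else asm$provenance$K,
             batch_size = if (is.null(asm$provenance$batch_size))
               NA_integer_ else asm$provenance$batch_size)
}

#' Internal De Bruijn assembler
#'
#' Builds a node-centric De Bruijn graph over canonical K-mers of the reads,
#' removes nodes below the coverage cutoff, clips tips shorter than 2K,
#' emits maximal unambiguous paths as contigs, and (optionally) joins
#' contigs supported by at least `min_links` read pairs of unambiguous
#' orientation into scaffolds, inserting N runs where the junction is not
#' spanned by a direct overlap. Deterministic for a given input.
#'
#' @param reads a [read_set()].
#' @param K odd De Bruijn k-mer size (< read length).
#' @param min_edge_coverage coverage cutoff for graph edges/nodes.
#' @param min_links read-pair support needed to scaffold two contigs.
#' @param gap_n N-run length for unspanned junctions.
#' @param tip_rounds tip-clipping iterations.
#' @param do_scaffold run the paired-end scaffolding step.
#' @param seed_len mapper seed length used when counting links.
#' @return an [assembly()].
#' @export
debruijn_assemble <- function(reads, K, min_edge_coverage = 3L,
                              min_links = 3L, gap_n = 100L, tip_rounds = 3L,
                              do_scaffold = TRUE, seed_len = 21L) {
  stopifnot(K %% 2L == 1L, K >= 3L)
  prov <- list(K = as.integer(K), batch_size = n_pairs(reads),
               stage = NA_integer_, iteration = NA_integer_)
  seqs <- read_sequences(reads)
  if (!length(seqs)) return(assembly(character(0), provenance = prov))
  res <- cpp_assemble(seqs, as.integer(K), as.integer(min_edge_coverage),
                      as.integer(tip_rounds))
  ctg <- res$sequence
  cov <- res$coverage
  o <- order(-nchar(ctg), ctg)
  asm <- assembly(ctg[o], provenance = prov, coverage = cov[o])
  if (do_scaffold && n_pairs(reads) > 0L && n_scaffolds(asm) > 1L) {
    cm <- build_connectivity_matrix(reads, asm,
                                    seed_len = min(seed_len, K),
                                    max_pairs = 5000L)
    asm <- rescaffold_with_matrix(asm, cm, min_support = min_links,
                                  gap_n = gap_n, ambiguous = "skip")
    asm$provenance <- prov
  }
  asm
}

#' Assemble every (batch, K) combination of a parameter sweep
#'
#' @param batches list of [read_set()] batches (e.g. from
#'   [batch_subsample()]).
#' @param K_values odd K values.
#' @param config a [pipeline_config()] supplying assembler parameters.
#' @param assemble_fn optional adapter `function(batch, K)` returning an
#'   [assembly()]; defaults to the internal [debruijn_assemble()]. A failing
#'   adapter call is logged and that (batch, K) pair skipped.
#' @param stage,iteration provenance tags.
#' @return list of assemblies, ordered by batch then K.
#' @export
sweep_assemble <- function(batches, K_values, config = pipeline_config(),
                           assemble_fn = NULL, stage = NA_integer_,
                           iteration = NA_integer_) {
  stopifnot(length(batches) > 0L, length(K_values) > 0L)
  if (is.null(assemble_fn))
    assemble_fn <- function(batch, K)
      debruijn_assemble(batch, K,
                        min_edge_coverage = config$min_edge_coverage,
                        min_links = config$min_links, gap_n = config$gap_n,
                        tip_rounds = config$tip_rounds,
                        seed_len = config$seed_len)
  out <- list()
  for (b in seq_along(batches)) for (K in K_values) {
    asm <- tryCatch(assemble_fn(batches[[b]], K), error = function(e) {
      plastid_log("sweep: assembly failed for batch %d, K=%d: %s", b, K,
                  conditionMessage(e))
      NULL
    })
    if (is.null(asm)) next
    asm$provenance$K <- as.integer(K)
    asm$provenance$batch_size <- n_pairs(batches[[b]])
    asm$provenance$stage <- stage
    asm$provenance$iteration <- iteration
    out[[length(out) + 1L]] <- asm
  }
  out
}

#' Homology filter against a chloroplast reference
#'
#' Retains scaffolds sharing at least `min_shared` of their canonical
#' k-mers with the reference — a containment stand-in for a BLAST screen
#' against a representative good-quality chloroplast genome. With no
#' reference configured the assembly passes unchanged.
#'
#' @param asm an [assembly()].
#' @param reference reference sequence(s): character vector, a FASTA path,
#'   or `NULL` to skip.
#' @param min_shared minimum shared canonical k-mer fraction (default 0.2).
#' @param k k-mer size for containment (default 31).
#' @return the filtered [assembly()].
#' @export
filter_homology <- function(asm, reference = NULL, min_shared = 0.2,
                            k = 31L) {
  if (is.null(reference)) return(asm)
  if (length(reference) == 1L && file.exists(reference) &&
      !grepl("^[ACGTNacgtn]+$", reference))
    reference <- read_fasta(reference)
  ref_tab <- count_kmers(toupper(as.character(reference)), k)
  if (!n_scaffolds(asm)) return(asm)
  shared <- cpp_seq_containment(unname(asm$scaffolds), as.integer(k),
                                ref_tab$kmer)
  keep <- shared >= min_shared
  plastid_log("filter_homology: dropped %d of %d scaffolds",
              sum(!keep), length(keep))
  res <- assembly(asm$scaffolds[keep], circular = asm$circular && all(keep),
                  provenance = asm$provenance, coverage = asm$coverage[keep])
  res
}

#' Size filter: drop scaffolds shorter than twice K
#'
#' Removes any contig or scaffold smaller than twice the K used in its
#' assembly (a 2K-1 bp scaffold is removed; 2K bp is kept).
#'
#' @param asm an [assembly()].
#' @param K the assembly K; defaults to the provenance K.
#' @return the filtered [assembly()].
#' @export
filter_size <- function(asm, K = asm$provenance$K) {
  if (is.null(K) || is.na(K)) stop("K is required (none in provenance)",
                                   call. = FALSE)
  keep <- nchar(asm$scaffolds) >= 2L * K
  assembly(asm$scaffolds[keep], circular = asm$circular && all(keep),
           provenance = asm$provenance, coverage = asm$coverage[keep])
}

#' Assembly length sanity check
#'
#' `TRUE` iff the total assembly length falls inside the configured total
#' range and — when a plastome layout is supplied — the LSC/SSC/IR lengths
#' fall inside their ranges too.
#'
#' @param asm an [assembly()].
#' @param ranges list of ranges as in [pipeline_config()]`$size_ranges`.
#' @param layout optional [find_inverted_repeat()] annotation.
#' @return logical scalar.
#' @export
sanity_check <- function(asm, ranges, layout = NULL) {
  len <- total_length(asm)
  ok <- len >= ranges$total[1] && len <= ranges$total[2]
  if (ok && !is.null(layout)) {
    ok <- layout$lsc_length >= ranges$lsc[1] &&
      layout$lsc_length <= ranges$lsc[2] &&
      layout$ssc_length >= ranges$ssc[1] &&
      layout$ssc_length <= ranges$ssc[2] &&
      layout$ir_length >= ranges$ir[1] &&
      layout$ir_length <= ranges$ir[2]
  }
  ok
}

# ranking key: smaller is better, compared lexicographically
rank_key <- function(asm, mode) {
  s <- n_scaffolds(asm)
  g <- n_gaps(asm)
  len <- total_length(asm)
  nn <- total_n_bases(asm)
  if (mode == "lexicographic") c(s, g, -len, nn) else c(s + g, -len, nn)
}

compare_keys <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(-1L)
    if (a[i] > b[i]) return(1L)
  }
  0L
}

#' Rank a set of candidate assemblies and return the best
#'
#' Lexicographic mode minimises (number of scaffolds, number of gaps,
#' -total length); `scaffolds_plus_gaps` minimises (scaffolds + gaps,
#' -total length). Remaining ties are broken by fewer N bases, then by
#' position in the candidate list (sweep provenance order: smaller batch,
#' then smaller K). Deterministic.
#'
#' @param assemblies non-empty list of [assembly()] candidates.
#' @param mode `"lexicographic"` or `"scaffolds_plus_gaps"`.
#' @return the best [assembly()], with the full ranking attached as the
#'   `"ranking"` attribute (a data frame of per-candidate statistics).
#' @export
rank_assemblies <- function(assemblies,
                            mode = c("lexicographic", "scaffolds_plus_gaps")) {
  mode <- match.arg(mode)
  if (!length(assemblies))
    stop("no assembly survived filtering", call. = FALSE)
  keys <- lapply(assemblies, rank_key, mode = mode)
  o <- do.call(order, c(lapply(seq_along(keys[[1]]),
                               function(i) vapply(keys, `[`, numeric(1), i)),
                        list(seq_along(keys))))
  best <- assemblies[[o[1]]]
  stats <- do.call(rbind, lapply(assemblies, assembly_stats))
  stats$rank <- match(seq_along(assemblies), o)
  attr(best, "ranking") <- stats
  best
}
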