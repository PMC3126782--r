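#' Read-trimming specification
#'
#' Uniform end trimming applied before mapping: the study geometry removes
#' 4 nt from the 5' end (spurious adapter) and 12 nt from the 3' end
#' (sequencing-reaction degeneration), leaving 27 nt of a 43 nt read
#' (original 1-based positions 5..31).
#'
#' @param five_prime_trim,three_prime_trim nucleotides removed from each end.
#' @return object of class `trim_spec`.
#' @export
trim_spec <- function(five_prime_trim = 4L, three_prime_trim = 12L) {
  stopifnot(five_prime_trim >= 0, three_prime_trim >= 0)
  structure(list(five_prime_trim = as.integer(five_prime_trim),
                 three_prime_trim = as.integer(three_prime_trim)),
            class = "trim_spec")
}

#' Trim reads (and qualities) uniformly
#'
#' Returns the subsequence from `five_prime_trim` (0-based, inclusive) to
#' `length - three_prime_trim` (exclusive).  Reads too short to survive
#' trimming are excluded and tallied in the `excluded` attribute.
#'
#' @param reads character vector, `read_set`, or [Biostrings::DNAStringSet].
#' @param spec a [trim_spec()].
#' @param qualities optional quality strings, trimmed identically.
#' @return trimmed character vector with attributes `excluded` (count) and
#'   `excluded_idx`; trimmed `qualities` attached as an attribute when given.
#' @export
trim_reads <- function(reads, spec = trim_spec(), qualities = NULL) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  reads <- as.character(reads)
  len <- nchar(reads)
  keep <- len > spec$five_prime_trim + spec$three_prime_trim
  out <- substring(reads[keep], spec$five_prime_trim + 1L,
                   len[keep] - spec$three_prime_trim)
  attr(out, "excluded") <- sum(!keep)
  attr(out, "excluded_idx") <- which(!keep)
  if (!is.null(qualities)) {
    attr(out, "qualities") <- substring(qualities[keep],
                                        spec$five_prime_trim + 1L,
                                        len[keep] - spec$three_prime_trim)
  }
  if (attr(out, "excluded") > 0)
    message(attr(out, "excluded"), " read(s) too short after trimming; excluded")
  out
}

#' Build a k-mer seed index over a gene-condensed transcriptome
#'
#' Exact-match seed lookup over the forward strand of every isoform; the
#' mapper searches reads on both strands by reverse-complementing the read.
#' A hit is found iff a placement with at most `max_mismatches` mismatches
#' exists on either strand, guaranteed by the pigeonhole principle when
#' `seed_length * (max_mismatches + 1) <= trimmed read length` (enforced in
#' [map_library()]).
#'
#' @param transcriptome a `transcriptome` object, a named character vector,
#'   or a [Biostrings::DNAStringSet] with headers `GENEID|isoN` (anything
#'   before the first `|` is the gene; headers without `|` are one
#'   single-isoform gene each).
#' @param seed_length exact-seed length (default 6, the largest k with
#'   4k <= 27 for the study's 27 nt trimmed reads and 3 mismatches).
#' @return object of class `seed_index`.
#' @export
build_index <- function(transcriptome, seed_length = 6L) {
  seqs <- if (inherits(transcriptome, "transcriptome")) {
    as.character(transcriptome$sequences)
  } else if (methods::is(transcriptome, "XStringSet")) {
    as.character(transcriptome)
  } else if (is.character(transcriptome)) {
    transcriptome   # as.character() would silently drop the names
  } else stop("unsupported transcriptome input")
  if (length(seqs) == 0) stop("empty transcriptome")
  if (is.null(names(seqs))) stop("transcript sequences must be named")
  iso_id <- names(seqs)
  if (anyDuplicated(iso_id)) {
    stop("duplicate isoform IDs: ",
         paste(unique(iso_id[duplicated(iso_id)]), collapse = ", "))
  }
  gene <- sub("\\|.*$", "", iso_id)
  gene_ids <- unique(gene)
  ptr <- .cs_build_index(unname(seqs), match(gene, gene_ids),
                         as.integer(seed_length), length(gene_ids))
  stats <- .cs_index_stats(ptr)
  structure(list(ptr = ptr, gene_ids = gene_ids, iso_ids = iso_id,
                 seed_length = as.integer(seed_length),
                 n_seed_positions = stats$n_seed_positions),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat("seed_index:", length(x$iso_ids), "isoforms,", length(x$gene_ids),
      "genes, k =", x$seed_length, "(", x$n_seed_positions,
      "seed positions )\n")
  invisible(x)
}

#' Map a trimmed read library
#'
#' For each read, records ALL placements (isoform, 0-based offset, strand)
#' with at most `max_mismatches` mismatches on either strand; `N` and other
#' non-ACGT characters mismatch at every position.  Multiple placements
#' within one gene collapse to a single gene membership (isoforms are
#' condensed under the gene), retaining the minimum mismatch count.
#'
#' @param reads character vector of already-trimmed reads (or a trimmed
#'   vector from [trim_reads()]).
#' @param index a [build_index()] result.
#' @param max_mismatches maximum mismatches per placement (default 3, the
#'   study configuration).
#' @param best_stratum if `TRUE`, keep only minimal-mismatch placements per
#'   read instead of the all-hits default.
#' @param detail if `TRUE`, also return every (isoform, offset, strand)
#'   placement (small instances only; memory grows with hits).
#' @return object of class `hit_table`: `hits` (data frame `read`, `gene`
#'   id, `min_mismatches`; one row per read x distinct gene), `summary`
#'   (`n_reads`, `n_mapped`, `fraction_mapped`), `gene_ids`, and
#'   `placements` when `detail = TRUE` (gene-condensed coordinates are
#'   0-based internally).
#' @export
map_library <- function(reads, index, max_mismatches = 3L,
                        best_stratum = FALSE, detail = FALSE) {
  stopifnot(inherits(index, "seed_index"), max_mismatches >= 0)
  reads <- as.character(reads)
  rl <- nchar(reads)
  if (length(reads) && index$seed_length * (max_mismatches + 1L) > min(rl))
    stop("pigeonhole violated: seed_length * (max_mismatches + 1) exceeds ",
         "the shortest read; rebuild the index with a smaller seed_length")
  res <- .cs_map_reads(index$ptr, reads, as.integer(max_mismatches),
                       best_stratum, detail)
  hits <- data.frame(read = res$read,
                     gene = index$gene_ids[res$gene],
                     min_mismatches = res$min_mismatches,
                     stringsAsFactors = FALSE)
  out <- structure(list(
    hits = hits,
    summary = list(n_reads = length(reads), n_mapped = res$n_mapped,
                   fraction_mapped = if (length(reads)) res$n_mapped / length(reads) else 0),
    gene_ids = index$gene_ids
  ), class = "hit_table")
  if (detail) {
    p <- res$placements
    out$placements <- data.frame(
      read = p$read, isoform = index$iso_ids[p$isoform],
      gene = sub("\\|.*$", "", index$iso_ids[p$isoform]),
      start = p$start, strand = c("+", "-")[p$strand + 1L],
      mismatches = p$mismatches, stringsAsFactors = FALSE)
  }
  out
}

#' Distinct genes hit per read
#'
#' @param x a `hit_table`.
#' @return named list: for each mapped read index, the character vector of
#'   distinct gene IDs hit.
#' @export
distinct_genes <- function(x) {
  stopifnot(inherits(x, "hit_table"))
  split(x$hits$gene, x$hits$read)
}

#' @export
print.hit_table <- function(x, ...) {
  s <- x$summary
  cat(sprintf("hit_table: %d reads, %d mapped (%.2f%%)\n",
              s$n_reads, s$n_mapped, 100 * s$fraction_mapped))
  invisible(x)
}

#' Write a mapping summary TSV
#'
#' One row per library: reads, mapped reads and percentage, mirroring the
#' study's per-library mapping summary columns.
#'
#' @param summaries named list of `hit_table` summaries (or `hit_table`s).
#' @param path output path.
#' @export
write_mapping_summary <- function(summaries, path) {
  rows <- lapply(names(summaries), function(s) {
    x <- summaries[[s]]
    if (inherits(x, "hit_table")) x <- x$summary
    data.frame(sample = s, reads = x$n_reads, mapped_reads = x$n_mapped,
               mapped_pct = round(100 * x$fraction_mapped, 2))
  })
  df <- do.call(rbind, rows)
  write_tsv(df, path, comment = "mapping summary; mapped_pct = 100 * mapped_reads / reads")
  invisible(df)
}
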