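# Canonical TSV dialect: tab-separated, '.' decimal, header row, leading
# '#' comment lines naming units and conventions so outputs are
# self-describing.  Numbers are written at 15 significant digits so a
# write -> read round trip is lossless to >= 12 digits.

write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, what = "table", ...) {
  tryCatch(
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
               check.names = FALSE, ...),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        stop("empty ", what, ": ", path, call. = FALSE)
      stop(e)
    })
}

#' Read / write a gene annotation table
#'
#' Tab-separated with a header; required columns `gene_id` and `length`
#' (longest-transcript length, bp); optional `family` (Or/Ir/Gr/Obp) and
#' `pfam` (PfamA best hit).  Duplicate gene IDs are rejected.
#'
#' @param path file path.
#' @return data frame with columns `gene_id`, `length`, `family`, `pfam`.
#' @export
read_annotation <- function(path) {
  df <- read_tsv(path, "annotation")
  for (col in c("gene_id", "length"))
    if (!col %in% names(df)) stop("annotation is missing column: ", col)
  if (nrow(df) == 0) stop("empty annotation: ", path)
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup)) stop("duplicate gene ID(s): ", paste(unique(dup), collapse = ", "))
  if (any(df$length <= 0)) stop("annotation lengths must be > 0")
  for (col in c("family", "pfam")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
    df[[col]][df[[col]] %in% ""] <- NA_character_
  }
  df[, c("gene_id", "length", "family", "pfam")]
}

#' @rdname read_annotation
#' @param annotation the annotation data frame to write.
#' @export
write_annotation <- function(annotation, path) {
  write_tsv(annotation, path,
            comment = "gene annotation; length = longest transcript, bp")
}

#' Write / read FASTA and FASTQ
#'
#' FASTA via Biostrings.  FASTQ (Sanger/Phred+33) is written with constant
#' `I` qualities (the pipeline never uses qualities) and read by a tolerant
#' 4-line-block reader that skips malformed records with a logged count.
#'
#' @param x a `transcriptome`, [Biostrings::DNAStringSet] or named
#'   character vector (FASTA); a `read_set` or character vector (FASTQ).
#' @param path file path.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "transcriptome")) x <- x$sequences
  if (!methods::is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname write_fasta
#' @param ids read identifiers (defaults to `read<N>` or the `read_set` ids).
#' @export
write_fastq <- function(x, path, ids = NULL) {
  if (inherits(x, "read_set")) {
    ids <- ids %||% x$ids
    x <- x$reads
  }
  ids <- ids %||% sprintf("read%07d", seq_along(x))
  qual <- strrep("I", nchar(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", x, "\n+\n", qual), con)
  invisible(path)
}

#' @rdname write_fasta
#' @return `read_fastq`: list `reads`, `ids`, `qualities`, `n_skipped`.
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  trailing <- length(ln) %% 4L
  n_blocks <- length(ln) %/% 4L
  if (trailing) ln <- ln[seq_len(n_blocks * 4L)]
  i <- seq_len(n_blocks)
  hdr <- ln[4L * i - 3L]; seq <- ln[4L * i - 2L]
  plus <- ln[4L * i - 1L]; qual <- ln[4L * i]
  ok <- startsWith(hdr, "@") & startsWith(plus, "+") &
    nchar(seq) == nchar(qual) & nchar(seq) > 0L &
    !grepl("[^ACGTNacgtn]", seq)
  n_skipped <- sum(!ok) + (trailing > 0L)
  if (n_skipped > 0)
    message("read_fastq: skipped ", n_skipped, " malformed record(s)")
  list(reads = seq[ok], ids = sub("^@", "", hdr[ok]),
       qualities = qual[ok], n_skipped = n_skipped)
}

af1_columns <- function(samples) {
  c("gene_id", "length",
    paste0("rpkm_", samples), paste0("unique_", samples),
    paste0("total_", samples))
}

#' Write / read the six-sample count+RPKM table
#'
#' The supplementary-table dialect: one row per gene with columns
#' `gene_id`, `length` (longest transcript, bp), `rpkm_<S>`, `unique_<S>`
#' and `total_<S>` (weighted hits) for each sample label `<S>`, plus
#' optional `family` / `pfam` columns.  Columns are matched by header name;
#' extra columns are tolerated.  The reader reconstructs a [count_table()]
#' and [expression_table()], taking each sample's `N` as the column sum of
#' total hits, so a table in this dialect can be fed straight into the
#' enhancement and comparative modules.
#'
#' @param counts a [count_table()].
#' @param expr the matching [expression_table()].
#' @param path file path.
#' @export
write_counts_table <- function(counts, expr, path) {
  samples <- colnames(counts$weighted)
  df <- data.frame(gene_id = counts$annotation$gene_id,
                   length = counts$annotation$length,
                   stringsAsFactors = FALSE)
  for (s in samples) df[[paste0("rpkm_", s)]] <- expr$rpkm[, s]
  for (s in samples) df[[paste0("unique_", s)]] <- counts$unique[, s]
  for (s in samples) df[[paste0("total_", s)]] <- counts$weighted[, s]
  if (any(!is.na(counts$annotation$family))) df$family <- counts$annotation$family
  if (any(!is.na(counts$annotation$pfam))) df$pfam <- counts$annotation$pfam
  write_tsv(df, path, comment = paste0(
    "gene x sample counts; total_<S> = weighted hits (unique + fractional ",
    "multi-mapping shares); rpkm = 1e9*C/(L*N), N = column sum of total_<S>"))
  invisible(path)
}

#' @rdname write_counts_table
#' @param samples expected sample labels (default [SAMPLE_LABELS]).
#' @return `read_counts_table`: list with `counts` ([count_table()]) and
#'   `expr` ([expression_table()] recomputed from the stored totals).
#' @export
read_counts_table <- function(path, samples = SAMPLE_LABELS) {
  df <- read_tsv(path, "counts table")
  if (nrow(df) == 0) stop("empty counts table: ", path)
  need <- af1_columns(samples)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("counts table is missing column(s): ",
                         paste(miss, collapse = ", "))
  for (col in setdiff(need, c("gene_id"))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop("non-numeric value in column ", col,
           if (length(bad)) paste0(", row ", bad[1]) else "")
    }
  }
  ann <- data.frame(gene_id = df$gene_id, length = df$length,
                    family = df$family %||% NA_character_,
                    pfam = df$pfam %||% NA_character_,
                    stringsAsFactors = FALSE)
  cols <- lapply(samples, function(s) {
    out <- data.frame(gene_id = df$gene_id,
                      unique_hits = df[[paste0("unique_", s)]],
                      weighted_hits = df[[paste0("total_", s)]],
                      stringsAsFactors = FALSE)
    attr(out, "scheme") <- "stored"
    out
  })
  counts <- count_table(setNames(cols, samples), ann)
  list(counts = counts, expr = expression_table(counts))
}

#' Load the bundled six-library mapping summary
#'
#' The published per-library totals (reads, mapped reads, transcriptome-
#' mapped weighted reads, per-library expression summary) for the six
#' chemosensory-appendage libraries, shipped as a plain-text fixture.
#'
#' @param path defaults to the copy installed with the package.
#' @return data frame, one row per library.
#' @export
read_mapping_summary <- function(path = system.file("extdata",
                                                    "library_mapping_summary.tsv",
                                                    package = "chemoseq")) {
  df <- read_tsv(path)
  stopifnot(all(c("tissue", "reads", "transcriptome_reads") %in% names(df)))
  df
}

#' Pooled statistics over a mapping summary
#'
#' @param df a [read_mapping_summary()] data frame.
#' @return list: `mean_reads_millions` (mean of per-library read totals, in
#'   millions), `pooled_transcriptome_pct` (100 * pooled transcriptome-
#'   mapped reads / pooled reads).
#' @export
pooled_mapping_stats <- function(df = read_mapping_summary()) {
  list(mean_reads_millions = mean(df$reads) / 1e6,
       pooled_transcriptome_pct = 100 * sum(df$transcriptome_reads) / sum(df$reads))
}
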