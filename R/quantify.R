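#' Apportion mapped reads into unique and weighted per-gene counts
#'
#' A read hitting exactly one gene adds 1 to that gene's unique and weighted
#' counts.  A read hitting `k > 1` distinct genes adds to weighted counts
#' only, under one of two schemes:
#'
#' * `"equal"` (default): 1/k to each gene hit.
#' * `"rescue"`: apportioned proportionally to each candidate gene's unique
#'   count (uniform 1/k fallback when every candidate has zero uniques),
#'   the classic rescue heuristic of early RNA-seq quantifiers.
#'
#' Unmapped reads contribute nothing.  The two schemes agree exactly when no
#' read is ambiguous.
#'
#' @param hits a `hit_table` from [map_library()] (or its `hits` data frame).
#' @param gene_ids character vector of all annotated gene IDs (defines row
#'   order; genes never hit get zero counts).
#' @param scheme `"equal"` or `"rescue"`.
#' @return data frame `gene_id`, `unique_hits`, `weighted_hits`, with
#'   attribute `n_mapped` (sum of weighted hits equals it to 1e-6).
#' @export
weight_counts <- function(hits, gene_ids, scheme = c("equal", "rescue")) {
  scheme <- match.arg(scheme)
  if (inherits(hits, "hit_table")) hits <- hits$hits
  n <- length(gene_ids)
  uniq <- wt <- setNames(numeric(n), gene_ids)
  if (nrow(hits)) {
    k_per_read <- tabulate(hits$read)          # distinct genes hit per read
    k <- k_per_read[hits$read]
    gi <- match(hits$gene, gene_ids)
    if (anyNA(gi)) stop("hit table references genes absent from gene_ids")
    u <- tabulate(gi[k == 1L], nbins = n)
    uniq[] <- u
    if (scheme == "equal") {
      w <- 1 / k
    } else {
      # rescue: share ambiguous reads in proportion to unique evidence
      us <- u[gi]
      rs <- rowsum(us, hits$read)
      tot <- rs[match(hits$read, as.integer(rownames(rs))), 1L]
      w <- ifelse(k == 1L, 1, ifelse(tot > 0, us / tot, 1 / k))
    }
    agg <- rowsum(w, gi)
    wt[as.integer(rownames(agg))] <- agg[, 1L]
  }
  out <- data.frame(gene_id = gene_ids, unique_hits = as.numeric(uniq),
                    weighted_hits = as.numeric(wt), stringsAsFactors = FALSE)
  attr(out, "n_mapped") <- length(unique(hits$read))
  attr(out, "scheme") <- scheme
  out
}

#' Assemble a per-sample count table
#'
#' @param columns named list (by sample label) of [weight_counts()] results.
#' @param annotation gene annotation data frame (`gene_id`, `length`, ...).
#' @return object of class `count_table`: matrices `unique` and `weighted`
#'   (gene x sample), per-sample totals `N` (sums of weighted hits), the
#'   annotation, and the weighting `scheme`.
#' @export
count_table <- function(columns, annotation) {
  samples <- names(columns)
  stopifnot(length(samples) > 0, !is.null(annotation$gene_id))
  g <- annotation$gene_id
  uniq <- sapply(columns, function(cc) {
    stopifnot(identical(cc$gene_id, g))
    cc$unique_hits
  })
  wt <- sapply(columns, function(cc) cc$weighted_hits)
  dimnames(uniq) <- dimnames(wt) <- list(g, samples)
  structure(list(unique = uniq, weighted = wt, N = colSums(wt),
                 annotation = annotation,
                 scheme = attr(columns[[1]], "scheme") %||% "equal"),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$weighted), "genes x", ncol(x$weighted),
      "samples;", x$scheme, "weighting\n")
  cat("N (weighted mapped reads):",
      paste(sprintf("%s=%.0f", names(x$N), x$N), collapse = ", "), "\n")
  invisible(x)
}

#' Reads Per Kilobase of transcript per Million mapped reads
#'
#' `RPKM = 1e9 * C / (L * N)` for weighted count `C`, longest-transcript
#' length `L` in bp, and per-sample total mapped weighted reads `N`.
#'
#' @param C weighted read count(s).
#' @param L transcript length(s), bp.
#' @param N total mapped weighted reads in the sample.
#' @return numeric RPKM, zero iff `C` is zero.
#' @export
compute_rpkm <- function(C, L, N) {
  stopifnot(all(L > 0))
  if (any(N <= 0)) stop("N must be > 0: sample has no mapped reads")
  1e9 * C / (L * N)
}

#' Build an RPKM expression table from counts
#'
#' @param counts a [count_table()].
#' @return object of class `expr_table`: `rpkm` matrix (gene x sample),
#'   per-gene `L`, per-sample `N`, and the annotation.
#' @export
expression_table <- function(counts) {
  stopifnot(inherits(counts, "count_table"))
  L <- counts$annotation$length
  # samples with no mapped reads carry all-zero columns (flagged) rather
  # than undefined RPKM; compute_rpkm() itself stays strict about N > 0
  N_safe <- ifelse(counts$N > 0, counts$N, 1)
  rpkm <- sweep(sweep(counts$weighted, 1, L, "/"), 2, N_safe, "/") * 1e9
  structure(list(rpkm = rpkm, L = setNames(L, rownames(counts$weighted)),
                 N = counts$N, annotation = counts$annotation,
                 zero_n_samples = names(counts$N)[counts$N == 0]),
            class = "expr_table")
}

#' @export
print.expr_table <- function(x, ...) {
  cat("expr_table:", nrow(x$rpkm), "genes x", ncol(x$rpkm), "samples (RPKM)\n")
  invisible(x)
}

#' Per-sample expression summary
#'
#' Gene count with detectable expression (weighted hits > 0, equivalently
#' RPKM > 0) and the median/mean/sd RPKM over that detected set, mirroring
#' the per-library "Gene Expression Summary" columns.  Statistics are `NA`
#' when nothing is detected; sd is the sample standard deviation (n - 1),
#' flagged in the output.
#'
#' @param expr an [expression_table()].
#' @param sample sample label.
#' @return list `gene_count`, `median_rpkm`, `mean_rpkm`, `sd_rpkm`,
#'   `sd_type`.
#' @export
summarize_expression <- function(expr, sample) {
  stopifnot(inherits(expr, "expr_table"))
  if (!sample %in% colnames(expr$rpkm)) stop("unknown sample: ", sample)
  v <- expr$rpkm[, sample]
  det <- v > 0
  n <- sum(det)
  list(gene_count = n,
       median_rpkm = if (n) median(v[det]) else NA_real_,
       mean_rpkm = if (n) mean(v[det]) else NA_real_,
       sd_rpkm = if (n > 1) sd(v[det]) else NA_real_,
       sd_type = "sample (n-1)")
}
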