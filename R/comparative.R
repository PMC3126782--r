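#' A labelled gene set
#'
#' @param label set label, e.g. `"FA-enhanced"`.
#' @param members character vector of gene IDs (deduplicated).
#' @return object of class `gene_set`.
#' @export
gene_set <- function(label, members) {
  structure(list(label = label, members = unique(as.character(members))),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set", x$label, ":", length(x$members), "genes\n")
  invisible(x)
}

#' Pairwise overlap of two gene sets
#'
#' Reports `|A only|`, `|shared|`, `|B only|`, and the shared fraction as a
#' percentage of each set.  Percentages are rounded to the nearest integer
#' for reporting; exact values are retained.
#'
#' @param set_a,set_b [gene_set()]s (or plain character vectors).
#' @return list of class `venn_overlap`: `a_only`, `shared`, `b_only`,
#'   `pct_of_a`, `pct_of_b` (rounded), `pct_of_a_exact`, `pct_of_b_exact`,
#'   `labels`.
#' @export
venn_overlap <- function(set_a, set_b) {
  if (!inherits(set_a, "gene_set")) set_a <- gene_set("A", set_a)
  if (!inherits(set_b, "gene_set")) set_b <- gene_set("B", set_b)
  shared <- length(intersect(set_a$members, set_b$members))
  na <- length(set_a$members); nb <- length(set_b$members)
  pa <- if (na) 100 * shared / na else 0
  pb <- if (nb) 100 * shared / nb else 0
  structure(list(a_only = na - shared, shared = shared, b_only = nb - shared,
                 pct_of_a = round(pa), pct_of_b = round(pb),
                 pct_of_a_exact = pa, pct_of_b_exact = pb,
                 labels = c(set_a$label, set_b$label)),
            class = "venn_overlap")
}

#' @export
print.venn_overlap <- function(x, ...) {
  cat(sprintf("%s vs %s: %d | %d | %d (shared = %d%% of %s, %d%% of %s)\n",
              x$labels[1], x$labels[2], x$a_only, x$shared, x$b_only,
              x$pct_of_a, x$labels[1], x$pct_of_b, x$labels[2]))
  invisible(x)
}

#' RPKM profile matrix for one gene family
#'
#' Rows are the family's genes ordered by gene ID; columns follow the fixed
#' heatmap order [PROFILE_ORDER] (FP, FB, FA, MA, MB, MP) unless overridden.
#' Values are the stored RPKMs, untransformed; any rendering intensity
#' scale must be monotone in RPKM.
#'
#' @param expr an [expression_table()].
#' @param family family label present in the annotation (`Or`, `Ir`, ...).
#' @param sample_order column order; defaults to [PROFILE_ORDER] restricted
#'   to the samples present.
#' @return RPKM matrix (family genes x samples).
#' @export
family_profile <- function(expr, family, sample_order = NULL) {
  stopifnot(inherits(expr, "expr_table"))
  ann <- expr$annotation
  g <- sort(ann$gene_id[!is.na(ann$family) & ann$family == family])
  if (length(g) == 0) stop("unknown family: ", family)
  if (is.null(sample_order))
    sample_order <- PROFILE_ORDER[PROFILE_ORDER %in% colnames(expr$rpkm)]
  expr$rpkm[g, sample_order, drop = FALSE]
}

#' Tally Pfam (or chemosensory) families across enhanced gene sets
#'
#' For each family in the annotation's best-hit Pfam column, counts how many
#' members fall in each sample's enhanced set, together with the family's
#' total annotated size.  Genes without a Pfam hit drop out.  Families are
#' ranked by total enhanced representation (sum over the supplied sets)
#' descending, ties broken lexicographically by accession.
#'
#' @param enhanced_sets named list (by sample label) of [gene_set()]s or
#'   character vectors.
#' @param annotation annotation data frame with `gene_id` and `pfam`.
#' @return data frame `family`, `n_annotated`, one enhanced-count column
#'   per sample, `rank`.
#' @export
pfam_tally <- function(enhanced_sets, annotation) {
  ann <- annotation[!is.na(annotation$pfam) & annotation$pfam != "", ]
  if (nrow(ann) == 0) {
    return(data.frame(family = character(), n_annotated = integer()))
  }
  fams <- sort(unique(ann$pfam))
  out <- data.frame(family = fams,
                    n_annotated = as.integer(table(ann$pfam)[fams]),
                    stringsAsFactors = FALSE)
  for (s in names(enhanced_sets)) {
    m <- enhanced_sets[[s]]
    if (inherits(m, "gene_set")) m <- m$members
    out[[s]] <- vapply(fams, function(f)
      sum(ann$gene_id[ann$pfam == f] %in% m), integer(1))
  }
  score <- rowSums(out[, names(enhanced_sets), drop = FALSE])
  ord <- order(-score, out$family)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' A cross-sex normalization factor
#'
#' @param numerator,denominator the quantities whose ratio defines the
#'   factor (e.g. female and male sensilla counts, or female and male Orco
#'   RPKM).
#' @param basis one of `"sensilla_ratio"`, `"orco_rpkm_ratio"`, `"fixed"`.
#' @return object of class `normalization_factor`: exact `factor`,
#'   one-decimal `reported`, and provenance fields.
#' @export
normalization_factor <- function(numerator, denominator,
                                 basis = c("sensilla_ratio",
                                           "orco_rpkm_ratio", "fixed")) {
  basis <- match.arg(basis)
  if (denominator <= 0) stop("denominator must be > 0")
  if (numerator <= 0) stop("numerator must be > 0")
  f <- numerator / denominator
  structure(list(factor = f, reported = round(f, 1),
                 numerator = numerator, denominator = denominator,
                 basis = basis),
            class = "normalization_factor")
}

#' @export
print.normalization_factor <- function(x, ...) {
  cat(sprintf("normalization_factor %.1f (%s: %g/%g; exact %.6g)\n",
              x$reported, x$basis, x$numerator, x$denominator, x$factor))
  invisible(x)
}

#' Derive a co-receptor (Orco) based normalization factor
#'
#' The factor is the fold-difference in the reference gene's RPKM between
#' two samples, typically female over male antennae for the obligate Or
#' co-receptor.
#'
#' @param expr an [expression_table()].
#' @param ref_gene reference gene ID (the Orco analogue).
#' @param sample_num,sample_den numerator and denominator samples.
#' @return a [normalization_factor()] with basis `"orco_rpkm_ratio"`.
#' @export
derive_orco_factor <- function(expr, ref_gene, sample_num, sample_den) {
  stopifnot(inherits(expr, "expr_table"))
  if (!ref_gene %in% rownames(expr$rpkm)) stop("unknown gene: ", ref_gene)
  num <- expr$rpkm[ref_gene, sample_num]
  den <- expr$rpkm[ref_gene, sample_den]
  if (den == 0) stop("reference gene has zero RPKM in ", sample_den)
  normalization_factor(num, den, basis = "orco_rpkm_ratio")
}

#' Scale expression rows by a normalization factor
#'
#' Every RPKM is multiplied by the factor; the original values are retained
#' alongside.  Any positive factor preserves the within-sample RPKM
#' ranking.
#'
#' @param rows RPKM matrix or vector (e.g. one sample's column of a
#'   [family_profile()]).
#' @param factor a [normalization_factor()] or a positive number.
#' @return list `original`, `normalized`, `factor`.
#' @export
normalize_profile <- function(rows, factor) {
  f <- if (inherits(factor, "normalization_factor")) factor$factor else factor
  if (!is.numeric(f) || f <= 0) stop("factor must be > 0")
  list(original = rows, normalized = rows * f, factor = factor)
}

#' Score enhancement calls against simulated ground truth
#'
#' @param records an [run_comparison()] result whose comparison matches a
#'   truth label set (e.g. `"FA_vs_FB"`).
#' @param truth a [simulate_expression()] result.
#' @param comparison comparison name; defaults to the records' own.
#' @return list `sensitivity` (called-and-true / true), `fdp`
#'   (called-and-false / called; 0 when nothing called),
#'   `direction_errors` (truth-enhanced genes called in the wrong
#'   direction), plus the underlying tallies.
#' @export
recovery_metrics <- function(records, truth, comparison = NULL) {
  comparison <- comparison %||% attr(records, "comparison")
  lab <- truth$enhanced_labels[[comparison]]
  if (is.null(lab)) stop("truth does not cover comparison ", comparison)
  if (!setequal(names(lab), records$gene_id))
    stop("gene IDs in truth and records disagree")
  lab <- lab[records$gene_id]
  s <- attr(records, "samples")
  called_1 <- records$call == s[["sample_1"]]
  called_2 <- records$call == s[["sample_2"]]
  called <- called_1 | called_2
  true_pos <- (called_1 & lab == "tissue") | (called_2 & lab == "body")
  dir_err <- (called_2 & lab == "tissue") | (called_1 & lab == "body")
  n_true <- sum(lab != "none")
  list(sensitivity = if (n_true) sum(true_pos) / n_true else NA_real_,
       fdp = if (sum(called)) sum(called & !true_pos) / sum(called) else 0,
       direction_errors = sum(dir_err),
       n_true = n_true, n_called = sum(called),
       n_true_positive = sum(true_pos))
}
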