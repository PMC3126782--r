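#' Two-sided Fisher's exact test for 2x2 read-count tables
#'
#' For a gene with `a` reads out of `N1` mapped reads in sample 1 and `c`
#' out of `N2` in sample 2, the table is `(a, N1 - a; c, N2 - c)`.  The
#' two-sided p-value is the probability-mass definition: the sum of the
#' hypergeometric probabilities of all tables with the same margins whose
#' probability does not exceed that of the observed table (with the
#' conventional `1 + 1e-7` relative slack on "does not exceed").  Computed
#' in log space; p-values are floored at 1e-300.
#'
#' @param a,c per-gene read counts in samples 1 and 2 (vectors).
#' @param n1,n2 total mapped reads in samples 1 and 2 (recycled).
#' @return vector of p-values in `(0, 1]`.
#' @export
fisher_two_sided <- function(a, n1, c, n2) {
  m <- length(a)
  n1 <- rep_len(n1, m); n2 <- rep_len(n2, m); c <- rep_len(c, m)
  if (any(a < 0 | c < 0 | n1 < a | n2 < c))
    stop("contingency entries must be nonnegative (a <= N1, c <= N2)")
  log_slack <- log1p(1e-7)
  p <- numeric(m)
  for (i in seq_len(m)) {
    K <- a[i] + c[i]
    k <- max(0, K - n2[i]):min(K, n1[i])
    logp <- dhyper(k, n1[i], n2[i], K, log = TRUE)
    lobs <- dhyper(a[i], n1[i], n2[i], K, log = TRUE)
    p[i] <- sum(exp(logp[logp <= lobs + log_slack]))
  }
  pmin(1, pmax(p, 1e-300))
}

#' Bonferroni-corrected per-test threshold
#'
#' `alpha / n_tests`.  With the genome-wide default of one test per
#' annotated protein-coding gene (12669), alpha 0.05 gives 3.9e-6 at two
#' significant figures; the alternative transcript-level divisor 13319
#' gives 3.75e-6 — both are supported because published analyses are often
#' ambiguous about the divisor.
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @return the per-test threshold.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' RPKM ratio with the zero pseudo-value rule
#'
#' RPKM values of exactly 0 are replaced by `pseudo_rpkm` (default 0.10)
#' before division, so ratios and log2 ratios stay finite for genes absent
#' from one sample.  Applied for both calling and plotting.
#'
#' @param rpkm_1,rpkm_2 nonnegative RPKM values (vectors).
#' @param pseudo_rpkm the substitute for exact zeros.
#' @return list with `ratio` and `log2_ratio` vectors.
#' @export
ratio_with_pseudo <- function(rpkm_1, rpkm_2, pseudo_rpkm = 0.10) {
  stopifnot(pseudo_rpkm > 0, all(rpkm_1 >= 0), all(rpkm_2 >= 0))
  r1 <- ifelse(rpkm_1 == 0, pseudo_rpkm, rpkm_1)
  r2 <- ifelse(rpkm_2 == 0, pseudo_rpkm, rpkm_2)
  ratio <- r1 / r2
  list(ratio = ratio, log2_ratio = log2(ratio))
}

#' Significance policy for enhancement calling
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests Bonferroni divisor; by convention the number of annotated
#'   genes, not the number actually tested.
#' @param fold_threshold minimum RPKM fold difference (default 2).
#' @param pseudo_rpkm zero substitute for ratios (default 0.10).
#' @return object of class `significance_policy` carrying the derived
#'   per-test `threshold`.
#' @export
significance_policy <- function(alpha = 0.05, n_tests,
                                fold_threshold = 2, pseudo_rpkm = 0.10) {
  stopifnot(fold_threshold >= 1, pseudo_rpkm > 0)
  structure(list(alpha = alpha, n_tests = as.integer(n_tests),
                 threshold = bonferroni_threshold(alpha, n_tests),
                 fold_threshold = fold_threshold, pseudo_rpkm = pseudo_rpkm),
            class = "significance_policy")
}

#' Call tissue-enhanced genes between two samples
#'
#' For every annotated gene, builds the 2x2 table from weighted counts
#' rounded half-up to integers, computes the two-sided Fisher p-value and
#' the pseudo-value RPKM ratio, and calls the gene enhanced in `sample_1`
#' when `ratio >= fold_threshold` and `p < threshold`, enhanced in
#' `sample_2` when `1/ratio >= fold_threshold` and `p < threshold`, and
#' `"none"` otherwise.
#'
#' @param counts a [count_table()].
#' @param expr the matching [expression_table()].
#' @param sample_1,sample_2 distinct sample labels (e.g. `"FA"`, `"FB"`).
#' @param policy a [significance_policy()]; `n_tests` defaults to the
#'   annotation size when `policy` is omitted.
#' @return data frame of class `enhancement_records` with columns
#'   `gene_id`, `rpkm_1`, `rpkm_2`, `ratio`, `log2_ratio`, `p_value`,
#'   `call` (values `sample_1`, `sample_2` or `"none"`); attributes
#'   `comparison`, `samples`, `policy` and `summary` (enhanced totals per
#'   direction).
#' @export
run_comparison <- function(counts, expr, sample_1, sample_2, policy = NULL) {
  stopifnot(inherits(counts, "count_table"), inherits(expr, "expr_table"))
  if (identical(sample_1, sample_2)) stop("sample_1 and sample_2 are identical")
  for (s in c(sample_1, sample_2))
    if (!s %in% colnames(counts$weighted)) stop("unknown sample: ", s)
  if (is.null(policy))
    policy <- significance_policy(n_tests = nrow(counts$annotation))
  a <- round_half_up(counts$weighted[, sample_1])
  c_ <- round_half_up(counts$weighted[, sample_2])
  N1 <- round_half_up(counts$N[[sample_1]])
  N2 <- round_half_up(counts$N[[sample_2]])
  a <- pmin(a, N1); c_ <- pmin(c_, N2)   # guard rounding at the margin
  p <- fisher_two_sided(a, N1, c_, N2)
  rr <- ratio_with_pseudo(expr$rpkm[, sample_1], expr$rpkm[, sample_2],
                          policy$pseudo_rpkm)
  sig <- p < policy$threshold
  call <- rep("none", length(a))
  call[sig & rr$ratio >= policy$fold_threshold] <- sample_1
  call[sig & 1 / rr$ratio >= policy$fold_threshold] <- sample_2
  rec <- data.frame(gene_id = counts$annotation$gene_id,
                    rpkm_1 = expr$rpkm[, sample_1],
                    rpkm_2 = expr$rpkm[, sample_2],
                    ratio = rr$ratio, log2_ratio = rr$log2_ratio,
                    p_value = p, call = call,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(rec, "comparison") <- paste0(sample_1, "_vs_", sample_2)
  attr(rec, "samples") <- c(sample_1 = sample_1, sample_2 = sample_2)
  attr(rec, "policy") <- policy
  attr(rec, "summary") <- list(
    n_enhanced_1 = sum(call == sample_1),
    n_enhanced_2 = sum(call == sample_2),
    n_total = sum(call != "none"))
  class(rec) <- c("enhancement_records", "data.frame")
  rec
}

#' Plot-ready volcano table
#'
#' `log2_ratio` versus `-log10(p)` with a significance class per gene:
#' `"significant"` (passing both fold and p criteria — black points),
#' `"chemosensory_significant"` (significant genes carrying an Or/Ir/Gr/Obp
#' family tag — red points), `"non_significant"` (gray).  `-log10(p)` is
#' capped (p-values are floored at 1e-300 upstream); the cap is recorded in
#' the `cap` attribute.
#'
#' @param records an [run_comparison()] result.
#' @param annotation optional annotation with `gene_id`, `family` for the
#'   chemosensory class.
#' @param cap maximum `-log10(p)` (default 300).
#' @return data frame `gene_id`, `log2_ratio`, `neg_log10_p`, `class`, with
#'   attribute `cap`.
#' @export
volcano_table <- function(records, annotation = NULL, cap = 300) {
  if (nrow(records) == 0) {
    out <- data.frame(gene_id = character(), log2_ratio = numeric(),
                      neg_log10_p = numeric(), class = character())
    attr(out, "cap") <- cap
    return(out)
  }
  cls <- ifelse(records$call == "none", "non_significant", "significant")
  if (!is.null(annotation)) {
    fam <- annotation$family[match(records$gene_id, annotation$gene_id)]
    cls[cls == "significant" & !is.na(fam)] <- "chemosensory_significant"
  }
  out <- data.frame(gene_id = records$gene_id,
                    log2_ratio = records$log2_ratio,
                    neg_log10_p = pmin(-log10(records$p_value), cap),
                    class = cls, stringsAsFactors = FALSE)
  attr(out, "cap") <- cap
  out
}

#' Extract the enhanced gene set from comparison records
#'
#' @param records an [run_comparison()] result.
#' @param side which direction: `"sample_1"` (default) or `"sample_2"`.
#' @return a [gene_set()] labelled `"<sample>-enhanced"`.
#' @export
enhanced_set <- function(records, side = c("sample_1", "sample_2")) {
  side <- match.arg(side)
  s <- attr(records, "samples")[[side]]
  gene_set(paste0(s, "-enhanced"), records$gene_id[records$call == s])
}
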