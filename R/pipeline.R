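#' Run the full synthetic-data pipeline
#'
#' Binds every stage end to end on a simulated study: transcriptome and
#' ground truth, six read libraries, trimming, mapping, weighted counting,
#' RPKM, the four tissue-vs-body enhancement comparisons, cross-tissue and
#' cross-sex overlaps, the Pfam tally, and recovery scoring against truth.
#' Deterministic given `config$seed`.  When `outdir` is given, every
#' artifact is written as self-describing TSV/JSON plus the FASTA/FASTQ
#' inputs, and a log echoes each stage's parameters and tallies.
#'
#' @param config a [sim_config()].
#' @param outdir optional output directory (created if missing).
#' @param trim a [trim_spec()].
#' @param max_mismatches mapping mismatch budget (default 3).
#' @param scheme weighting scheme for [weight_counts()].
#' @param policy optional [significance_policy()]; defaults to alpha 0.05
#'   over the annotation size with a 2-fold filter.
#' @param write_reads also write per-sample FASTQ when `outdir` is given
#'   (off by default; files are large).
#' @return list: `truth`, `transcriptome`, `counts`, `expr`,
#'   `mapping_summaries`, `comparisons` (enhancement records per
#'   tissue-vs-body pair), `venn` (cross-tissue and cross-sex overlaps),
#'   `pfam` tally, `recovery` metrics per comparison, `expression_summary`.
#' @export
run_pipeline <- function(config, outdir = NULL, trim = trim_spec(),
                         max_mismatches = 3L, scheme = "equal",
                         policy = NULL, write_reads = FALSE) {
  validate_sim_config(config)
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  say("pipeline seed=", config$seed, " genes=", config$n_genes,
      " library_size=", config$library_size)
  tx <- build_transcriptome(config)
  truth <- simulate_expression(config)
  trimmed_len <- config$read_length - trim$five_prime_trim - trim$three_prime_trim
  seed_len <- max(1L, min(15L, trimmed_len %/% (max_mismatches + 1L)))
  idx <- build_index(tx, seed_length = seed_len)
  say("index: ", length(idx$iso_ids), " isoforms, k=", seed_len)
  cols <- list()
  map_summ <- list()
  for (s in config$samples) {
    rs <- simulate_reads(truth, tx, config, s)
    tr <- trim_reads(rs, trim)
    hm <- map_library(tr, idx, max_mismatches = max_mismatches)
    say(sprintf("%s: %d reads, %d trimmed-excluded, %d mapped (%.2f%%)",
                s, length(rs$reads), attr(tr, "excluded"),
                hm$summary$n_mapped, 100 * hm$summary$fraction_mapped))
    cols[[s]] <- weight_counts(hm, tx$annotation$gene_id, scheme = scheme)
    map_summ[[s]] <- hm$summary
    if (!is.null(outdir) && write_reads)
      write_fastq(rs, file.path(outdir, paste0(s, ".fastq")))
  }
  counts <- count_table(cols, tx$annotation)
  expr <- expression_table(counts)
  if (is.null(policy))
    policy <- significance_policy(n_tests = nrow(tx$annotation))
  comparisons <- list()
  recovery <- list()
  for (s in names(BODY_OF)[names(BODY_OF) %in% config$samples]) {
    cmp <- paste0(s, "_vs_", BODY_OF[[s]])
    rec <- run_comparison(counts, expr, s, BODY_OF[[s]], policy)
    comparisons[[cmp]] <- rec
    recovery[[cmp]] <- recovery_metrics(rec, truth, cmp)
    say(sprintf("%s: %d enhanced in %s, %d in %s; sensitivity %.3f, FDP %.3f",
                cmp, attr(rec, "summary")$n_enhanced_1, s,
                attr(rec, "summary")$n_enhanced_2, BODY_OF[[s]],
                recovery[[cmp]]$sensitivity, recovery[[cmp]]$fdp))
  }
  sets <- lapply(comparisons, enhanced_set)
  names(sets) <- sub("_vs_.*$", "", names(comparisons))
  venn <- list(
    FA_vs_FP = venn_overlap(sets$FA, sets$FP),
    MA_vs_MP = venn_overlap(sets$MA, sets$MP),
    FA_vs_MA = venn_overlap(sets$FA, sets$MA),
    FP_vs_MP = venn_overlap(sets$FP, sets$MP))
  pfam <- pfam_tally(sets, tx$annotation)
  expression_summary <- lapply(setNames(nm = config$samples),
                               function(s) summarize_expression(expr, s))
  out <- list(truth = truth, transcriptome = tx, counts = counts,
              expr = expr, mapping_summaries = map_summ,
              comparisons = comparisons, enhanced_sets = sets,
              venn = venn, pfam = pfam, recovery = recovery,
              expression_summary = expression_summary, log = log_lines)
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir, policy)
  out
}

write_pipeline_outputs <- function(out, outdir, policy) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(out$transcriptome, file.path(outdir, "transcriptome.fasta"))
  write_annotation(out$transcriptome$annotation,
                   file.path(outdir, "annotation.tsv"))
  write_counts_table(out$counts, out$expr, file.path(outdir, "counts.tsv"))
  write_mapping_summary(out$mapping_summaries,
                        file.path(outdir, "mapping_summary.tsv"))
  for (cmp in names(out$comparisons)) {
    rec <- out$comparisons[[cmp]]
    write_tsv(as.data.frame(rec), file.path(outdir, paste0(cmp, ".tsv")),
              comment = paste0(cmp, "; call per significance_policy alpha=",
                               policy$alpha, " n_tests=", policy$n_tests,
                               " fold=", policy$fold_threshold,
                               "; weighted counts rounded half-up"))
    vt <- volcano_table(rec, out$transcriptome$annotation)
    write_tsv(vt, file.path(outdir, paste0(cmp, ".volcano.tsv")),
              comment = paste0("volcano table; -log10 p capped at ",
                               attr(vt, "cap")))
  }
  summ <- list(
    venn = lapply(out$venn, unclass),
    recovery = out$recovery,
    enhanced = lapply(out$comparisons, attr, "summary"),
    expression_summary = out$expression_summary)
  jsonlite::write_json(summ, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (nrow(out$pfam))
    write_tsv(out$pfam, file.path(outdir, "pfam_tally.tsv"),
              comment = "Pfam best-hit tally over enhanced sets")
  writeLines(out$log, file.path(outdir, "pipeline.log"))
  invisible(outdir)
}
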