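#' Simulation configuration
#'
#' Describes a desk-scale stand-in for the six-library study design: a toy
#' transcriptome with paralog families (to induce multi-mapping), six
#' tissue/sex-structured expression profiles with designated enhanced gene
#' sets, and single-end 43 bp read libraries.
#'
#' @param n_genes number of genes.
#' @param n_paralog_families number of 2-gene paralog pairs; pairs occupy the
#'   last `2 * n_paralog_families` gene slots so that the default enhanced
#'   design (low gene indices) stays unambiguous.
#' @param paralog_divergence per-base substitution probability between the
#'   two copies of a paralog pair, in `[0, 0.5]`.  At 0 the copies are
#'   identical and every read from either maps ambiguously.
#' @param isoforms_per_gene isoforms per gene; isoform 1 is full length,
#'   further isoforms are 5' prefixes (alternative 3' ends).  The annotation
#'   records the longest isoform length.
#' @param transcript_length_range integer pair `(min, max)` bp.
#' @param base_expression `c(mu, sigma)` of the log-normal baseline relative
#'   abundance (natural-log scale).  Only `sigma` matters after per-column
#'   renormalization.
#' @param samples ordered sample labels; default [SAMPLE_LABELS].
#' @param enhanced_design named list (by non-body sample label) of data
#'   frames with columns `gene` (1-based index) and `fold` (> 1), the
#'   designed enhancement relative to the matched body sample.  `NULL` uses
#'   the default design described in the methods vignette; `list()` disables
#'   enhancement.
#' @param library_size reads per library.
#' @param read_length read length in bp (default 43, the study geometry).
#' @param error_rate per-base substitution sequencing-error probability.
#' @param antisense_fraction fraction of reads emitted antisense (default 0,
#'   sense-only; 0.5 emulates an unstranded protocol).
#' @param seed master seed; per-stage sub-seeds are derived from it.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500,
                       n_paralog_families = 10,
                       paralog_divergence = 0.02,
                       isoforms_per_gene = 1,
                       transcript_length_range = c(300L, 1500L),
                       base_expression = c(mu = 0, sigma = 1.5),
                       samples = SAMPLE_LABELS,
                       enhanced_design = NULL,
                       library_size = 200000L,
                       read_length = 43L,
                       error_rate = 0.005,
                       antisense_fraction = 0,
                       seed = 1L) {
  if (is.null(enhanced_design)) enhanced_design <- default_enhanced_design()
  cfg <- structure(list(
    n_genes = as.integer(n_genes),
    n_paralog_families = as.integer(n_paralog_families),
    paralog_divergence = paralog_divergence,
    isoforms_per_gene = as.integer(isoforms_per_gene),
    transcript_length_range = as.integer(transcript_length_range),
    base_expression = base_expression,
    samples = samples,
    enhanced_design = enhanced_design,
    library_size = as.integer(library_size),
    read_length = as.integer(read_length),
    error_rate = error_rate,
    antisense_fraction = antisense_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

# default stated world: 20 genes per antenna / 15 per palp with folds
# spanning the 2x calling threshold up to 8x, partial overlap between the
# sexes (chemosensory monomorphism).  Folds are capped at 8 so the designed
# mass stays a minor fraction of the library and column renormalization
# (closure) cannot erode true ratios below the 2-fold threshold; see the
# methods vignette.
default_enhanced_design <- function() {
  folds20 <- rep(c(2, 4, 8), times = c(6, 7, 7))
  folds15 <- rep(c(2, 4, 8), each = 5)
  list(
    FA = data.frame(gene = 1:20,  fold = folds20),
    MA = data.frame(gene = 11:30, fold = folds20),
    FP = data.frame(gene = 31:45, fold = folds15),
    MP = data.frame(gene = 41:55, fold = folds15)
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1, cfg$n_paralog_families >= 0,
            cfg$isoforms_per_gene >= 1, cfg$library_size > 0,
            cfg$read_length >= 1, length(cfg$transcript_length_range) == 2)
  if (cfg$paralog_divergence < 0 || cfg$paralog_divergence > 0.5)
    stop("paralog_divergence must lie in [0, 0.5]")
  if (cfg$error_rate < 0 || cfg$error_rate > 1)
    stop("error_rate must lie in [0, 1]")
  if (cfg$transcript_length_range[1] < cfg$read_length)
    stop("transcript_length_range min (", cfg$transcript_length_range[1],
         ") is below read_length (", cfg$read_length, ")")
  if (cfg$transcript_length_range[1] > cfg$transcript_length_range[2])
    stop("transcript_length_range must be (min, max)")
  if (2L * cfg$n_paralog_families > cfg$n_genes)
    stop("more paralog gene slots than genes")
  if (length(cfg$enhanced_design)) {
    if (is.null(names(cfg$enhanced_design)) ||
        !all(names(cfg$enhanced_design) %in% cfg$samples))
      stop("enhanced_design names must be sample labels")
    if (any(names(cfg$enhanced_design) %in% c("FB", "MB")))
      stop("enhanced_design is defined relative to body samples; ",
           "body samples cannot carry a design")
    for (s in names(cfg$enhanced_design)) {
      d <- cfg$enhanced_design[[s]]
      stopifnot(is.data.frame(d), all(c("gene", "fold") %in% names(d)))
      if (any(d$gene < 1 | d$gene > cfg$n_genes))
        stop("enhanced_design[", s, "] references genes outside 1..n_genes")
      if (any(d$fold <= 1))
        stop("enhanced_design fold multipliers must be > 1")
      if (anyDuplicated(d$gene))
        stop("enhanced_design[", s, "] lists a gene twice")
    }
  }
  invisible(cfg)
}

# deterministic per-stage sub-seeds (kept well below 2^31)
stage_seed <- function(cfg, stage, k = 0L) {
  offs <- c(transcriptome = 11L, expression = 23L, reads = 101L)
  (cfg$seed %% 2000000000L) + offs[[stage]] + 7L * as.integer(k)
}

gene_ids <- function(n) sprintf("SG%05d", seq_len(n))

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, rate) {
  if (rate == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  paste(ch, collapse = "")
}

#' Build a synthetic gene-condensed transcriptome
#'
#' Generates random transcript sequences, organises paralog pairs whose
#' copies differ at rate `paralog_divergence`, emits one FASTA record per
#' isoform (header `GENEID|isoN`), and derives the per-gene annotation with
#' the longest-isoform length.  A default chemosensory family / Pfam
#' labelling is attached so the comparative layer can be exercised:
#' genes 1-10 Or (PF02949), 11-16 Ir (PF00060), 41-44 Gr (PF08395),
#' 31-36 Obp (PF01395), all subject to `n_genes` being large enough.
#'
#' @param config a [sim_config()].
#' @return list of class `transcriptome` with elements `sequences`
#'   (named [Biostrings::DNAStringSet], one per isoform), `annotation`
#'   (data frame: `gene_id`, `length`, `family`, `pfam`), and `isoforms`
#'   (data frame: `iso_id`, `gene_id`, `length`).
#' @export
build_transcriptome <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config, "transcriptome"))
  n <- config$n_genes
  ids <- gene_ids(n)
  len_rng <- seq(config$transcript_length_range[1],
                 config$transcript_length_range[2])
  lens <- len_rng[sample.int(length(len_rng), n, replace = TRUE)]
  seqs <- character(n)
  base_start <- n - 2L * config$n_paralog_families
  for (g in seq_len(n)) {
    if (config$n_paralog_families > 0 && g > base_start &&
        (g - base_start) %% 2L == 0L) {
      # second member of a paralog pair: mutated copy of the first
      lens[g] <- lens[g - 1L]
      seqs[g] <- mutate_dna(seqs[g - 1L], config$paralog_divergence)
    } else {
      seqs[g] <- random_dna(lens[g])
    }
  }
  iso_gene <- rep(ids, each = config$isoforms_per_gene)
  iso_num <- rep(seq_len(config$isoforms_per_gene), times = n)
  iso_seq <- character(length(iso_gene))
  for (j in seq_along(iso_gene)) {
    g <- match(iso_gene[j], ids)
    if (iso_num[j] == 1L) {
      iso_seq[j] <- seqs[g]
    } else {
      lo <- max(config$read_length, ceiling(lens[g] / 2))
      cut_rng <- seq(lo, lens[g])
      iso_seq[j] <- substr(seqs[g], 1L,
                           cut_rng[sample.int(length(cut_rng), 1)])
    }
  }
  iso_id <- paste0(iso_gene, "|iso", iso_num)
  sequences <- Biostrings::DNAStringSet(setNames(iso_seq, iso_id))
  annotation <- data.frame(
    gene_id = ids, length = lens,
    family = NA_character_, pfam = NA_character_,
    stringsAsFactors = FALSE
  )
  fam <- list(Or = list(1:10, "PF02949"), Ir = list(11:16, "PF00060"),
              Gr = list(41:44, "PF08395"), Obp = list(31:36, "PF01395"))
  for (f in names(fam)) {
    idx <- fam[[f]][[1]]
    idx <- idx[idx <= n]
    annotation$family[idx] <- f
    annotation$pfam[idx] <- fam[[f]][[2]]
  }
  structure(list(sequences = sequences, annotation = annotation,
                 isoforms = data.frame(iso_id = iso_id, gene_id = iso_gene,
                                       length = nchar(iso_seq),
                                       stringsAsFactors = FALSE)),
            class = "transcriptome")
}

#' Simulate true expression profiles with enhancement labels
#'
#' Baseline relative abundances are drawn log-normal and shared by all six
#' samples; designed enhanced genes are multiplied by their fold in the
#' designated sample; columns are renormalized to sum to 1.  Truth labels
#' are recorded against the designed fold before renormalization.
#'
#' @param config a [sim_config()].
#' @return list of class `ground_truth`: `abundance` (gene x sample matrix,
#'   columns sum to 1), `enhanced_labels` (per comparison `"<s>_vs_<body>"`,
#'   a gene-named vector in `{tissue, body, none}`), `design` (the designed
#'   folds), `baseline`.
#' @export
simulate_expression <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config, "expression"))
  n <- config$n_genes
  ids <- gene_ids(n)
  mu <- config$base_expression[["mu"]]
  sigma <- config$base_expression[["sigma"]]
  baseline <- if (sigma == 0) rep(exp(mu), n) else rlnorm(n, mu, sigma)
  raw <- matrix(baseline, nrow = n, ncol = length(config$samples),
                dimnames = list(ids, config$samples))
  labels <- list()
  for (s in names(BODY_OF)[names(BODY_OF) %in% config$samples]) {
    lab <- setNames(rep("none", n), ids)
    d <- config$enhanced_design[[s]]
    if (!is.null(d)) {
      raw[d$gene, s] <- raw[d$gene, s] * d$fold
      lab[d$gene] <- "tissue"
    }
    labels[[paste0(s, "_vs_", BODY_OF[[s]])]] <- lab
  }
  abundance <- sweep(raw, 2, colSums(raw), "/")
  design <- lapply(config$enhanced_design, function(d)
    setNames(d$fold, ids[d$gene]))
  structure(list(abundance = abundance, enhanced_labels = labels,
                 design = design, baseline = setNames(baseline, ids)),
            class = "ground_truth")
}

#' Simulate a single-end read library for one sample
#'
#' Reads are drawn multinomially over (isoform, start position) cells with
#' weights `abundance(gene) x (isoform length - read_length + 1)`, start
#' positions uniform over valid positions, independent per-base substitution
#' errors at `error_rate`, and an optional antisense fraction.  Exactly
#' `library_size` reads are emitted.
#'
#' @param truth a [simulate_expression()] result.
#' @param transcriptome a [build_transcriptome()] result.
#' @param config the shared [sim_config()].
#' @param sample one of `config$samples`.
#' @return list of class `read_set`: `reads` (character), `ids`, and
#'   `truth` (data frame: source `gene_id`, `iso_id`, 1-based `start`,
#'   `strand`).
#' @export
simulate_reads <- function(truth, transcriptome, config, sample) {
  validate_sim_config(config)
  if (!sample %in% config$samples) stop("unknown sample: ", sample)
  if (length(transcriptome$sequences) == 0) stop("empty transcriptome")
  set.seed(stage_seed(config, "reads", match(sample, config$samples)))
  rl <- config$read_length
  iso <- transcriptome$isoforms
  ab <- truth$abundance[iso$gene_id, sample]
  eff <- iso$length - rl + 1L
  ok <- eff > 0L
  w <- ab * eff * ok
  if (sum(w) <= 0) stop("no isoform long enough to yield reads")
  counts <- as.vector(rmultinom(1, config$library_size, w))
  idx <- rep.int(seq_len(nrow(iso)), counts)
  starts <- floor(runif(length(idx)) * eff[idx]) + 1L
  iso_chr <- as.character(transcriptome$sequences)
  reads <- unname(substring(iso_chr[idx], starts, starts + rl - 1L))
  strand <- rep("+", length(reads))
  if (config$antisense_fraction > 0) {
    flip <- runif(length(reads)) < config$antisense_fraction
    if (any(flip)) {
      reads[flip] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(reads[flip])))
      strand[flip] <- "-"
    }
  }
  reads <- inject_errors(reads, rl, config$error_rate)
  perm <- sample.int(length(reads))  # shuffle so file order carries no signal
  structure(list(
    reads = reads[perm],
    ids = sprintf("%s:%07d", sample, seq_along(reads)),
    truth = data.frame(gene_id = iso$gene_id[idx][perm],
                       iso_id = iso$iso_id[idx][perm],
                       start = starts[perm], strand = strand[perm],
                       stringsAsFactors = FALSE)
  ), class = "read_set")
}

#' Expected read counts under the simulation model
#'
#' The multinomial expectation `library_size * w / sum(w)` with cell
#' weights `w = abundance(gene) x (isoform length - read_length + 1)`
#' summed per gene — the reference for power/recovery conditioning.
#'
#' @inheritParams simulate_reads
#' @return named numeric vector of expected per-gene read counts.
#' @export
expected_counts <- function(truth, transcriptome, config, sample) {
  iso <- transcriptome$isoforms
  eff <- pmax(iso$length - config$read_length + 1L, 0L)
  w <- truth$abundance[iso$gene_id, sample] * eff
  per_gene <- rowsum(w, iso$gene_id)[, 1L]
  config$library_size * per_gene / sum(per_gene)
}

inject_errors <- function(reads, rl, rate) {
  if (rate == 0 || length(reads) == 0) return(reads)
  total <- length(reads) * rl
  n_err <- rbinom(1, total, rate)
  if (n_err == 0) return(reads)
  at <- sample.int(total, n_err)
  ri <- ((at - 1L) %/% rl) + 1L
  pos <- ((at - 1L) %% rl) + 1L
  bases <- c("A", "C", "G", "T")
  for (j in seq_len(n_err)) {
    cur <- substr(reads[ri[j]], pos[j], pos[j])
    substr(reads[ri[j]], pos[j], pos[j]) <- sample(setdiff(bases, cur), 1)
  }
  reads
}
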