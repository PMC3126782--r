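test_that("trimming keeps 1-based positions 5..31 of a 43 bp read", {
  read <- paste(sample(c("A", "C", "G", "T"), 43, replace = TRUE),
                collapse = "")
  out <- trim_reads(read)
  expect_equal(nchar(out), 27)
  expect_equal(unclass(out)[1], substr(read, 5, 31))

  expect_equal(unclass(trim_reads(read, trim_spec(0, 0)))[1], read)

  # 4 + 12 = 16 leaves nothing of a 16 bp read
  short <- strrep("A", 16)
  suppressMessages(out2 <- trim_reads(c(read, short)))
  expect_length(out2, 1)
  expect_equal(attr(out2, "excluded"), 1)
  expect_equal(attr(out2, "excluded_idx"), 2L)
})

test_that("trimming cuts qualities identically", {
  out <- trim_reads(strrep("A", 43), qualities = paste(rep("I", 43), collapse = ""))
  expect_equal(nchar(attr(out, "qualities")), 27)
})

test_that("index construction counts seeds and rejects bad input", {
  tx <- setNames(paste(rep("ACGT", 25), collapse = ""), "g1|iso1")
  idx <- build_index(tx, seed_length = 9)
  expect_equal(idx$n_seed_positions, 92)  # 100 - 9 + 1
  expect_error(build_index(character(0)), "empty")
  expect_error(build_index(setNames(c("ACGTACGT", "ACGTACGT"),
                                    c("g1|iso1", "g1|iso1"))), "duplicate")
})

test_that("exact substrings are always retrieved, hitting their source gene", {
  cfg <- tiny_cfg(n_paralog_families = 0, seed = 21)
  tx <- build_transcriptome(cfg)
  idx <- build_index(tx)
  set.seed(99)
  seqs <- as.character(tx$sequences)
  picks <- sample(length(seqs), 200, replace = TRUE)
  starts <- vapply(picks, function(j)
    sample(nchar(seqs[j]) - 26, 1), integer(1))
  reads <- substring(seqs[picks], starts, starts + 26)
  hm <- map_library(reads, idx)
  expect_equal(hm$summary$n_mapped, 200)
  dg <- distinct_genes(hm)
  src <- tx$isoforms$gene_id[picks]
  for (i in seq_along(reads))
    expect_true(src[i] %in% dg[[as.character(i)]])
  expect_true(all(hm$hits$min_mismatches[
    paste(hm$hits$read, hm$hits$gene) %in% paste(seq_along(reads), src)] == 0))
})

test_that("zero-divergence paralog pairs produce two-gene hit sets", {
  cfg0 <- sim_config(n_genes = 2, n_paralog_families = 1,
                     paralog_divergence = 0, enhanced_design = list(),
                     transcript_length_range = c(150L, 200L),
                     library_size = 50, error_rate = 0, seed = 2)
  tx <- build_transcriptome(cfg0)
  truth <- simulate_expression(cfg0)
  rs <- simulate_reads(truth, tx, cfg0, "FB")
  hm <- map_library(trim_reads(rs), build_index(tx))
  dg <- distinct_genes(hm)
  expect_true(all(vapply(dg, length, integer(1)) == 2))
})

test_that("mapper equals the naive Hamming scan, placement for placement", {
  set.seed(31)
  cfg <- sim_config(n_genes = 5, n_paralog_families = 1,
                    paralog_divergence = 0.05, enhanced_design = list(),
                    transcript_length_range = c(120L, 250L), seed = 13)
  tx <- build_transcriptome(cfg)
  seqs <- as.character(tx$sequences)
  idx <- build_index(tx)
  # mix of exact substrings, mutated substrings, and random reads
  reads <- character(120)
  for (i in seq_len(120)) {
    if (i %% 3 == 0) {
      reads[i] <- paste(sample(c("A", "C", "G", "T", "N"), 27,
                               replace = TRUE, prob = c(rep(0.24, 4), 0.04)),
                        collapse = "")
    } else {
      j <- sample(length(seqs), 1)
      st <- sample(nchar(seqs[j]) - 26, 1)
      r <- substring(seqs[j], st, st + 26)
      nmut <- sample(0:4, 1)
      if (nmut) {
        pos <- sample(27, nmut)
        for (p in pos) substr(r, p, p) <- sample(c("A", "C", "G", "T", "N"), 1)
      }
      if (i %% 5 == 0) r <- revcomp_chr(r)
      reads[i] <- r
    }
  }
  hm <- map_library(reads, idx, max_mismatches = 3, detail = TRUE)
  got <- hm$placements
  for (i in seq_along(reads)) {
    want <- oracle_scan(reads[i], seqs, 3)
    mine <- got[got$read == i, c("isoform", "start", "strand", "mismatches")]
    mine$strand <- as.character(mine$strand)
    if (is.null(want)) {
      expect_equal(nrow(mine), 0)
    } else {
      o1 <- mine[order(mine$isoform, mine$start, mine$strand), ]
      o2 <- want[order(want$isoform, want$start, want$strand), ]
      rownames(o1) <- rownames(o2) <- NULL
      expect_equal(o1, o2)
    }
  }
})

test_that("raising max_mismatches never removes a hit", {
  d <- demo_run()
  reads <- trim_reads(simulate_reads(d$truth, d$tx, d$cfg, "FA"))[1:2000]
  prev <- NULL
  for (mm in 0:3) {
    hm <- map_library(reads, d$idx, max_mismatches = mm)
    key <- paste(hm$hits$read, hm$hits$gene)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
})

test_that("reverse-complementing reads and transcriptome leaves gene sets fixed", {
  cfg <- tiny_cfg(n_genes = 15, seed = 17)
  tx <- build_transcriptome(cfg)
  truth <- simulate_expression(cfg)
  reads <- trim_reads(simulate_reads(truth, tx, cfg, "FB"))[1:500]
  seqs <- as.character(tx$sequences)
  h1 <- map_library(reads, build_index(tx))
  h2 <- map_library(revcomp_chr(reads),
                    build_index(setNames(revcomp_chr(seqs), names(seqs))))
  expect_equal(h1$hits[, c("read", "gene")], h2$hits[, c("read", "gene")])
})

test_that("pigeonhole guard refuses unsafe seed lengths", {
  idx <- build_index(setNames(strrep("ACGT", 50), "g|iso1"), seed_length = 9)
  expect_error(map_library(strrep("A", 27), idx, max_mismatches = 3),
               "pigeonhole")
})
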