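test_that("config validation rejects impossible worlds", {
  expect_error(sim_config(transcript_length_range = c(30, 100)),
               "read_length")
  expect_error(tiny_cfg(enhanced_design = list(
    FA = data.frame(gene = 99, fold = 2))), "outside")
  expect_error(tiny_cfg(enhanced_design = list(
    FA = data.frame(gene = 1, fold = 1))), "> 1")
  expect_error(tiny_cfg(enhanced_design = list(
    FB = data.frame(gene = 1, fold = 2))), "body")
  expect_error(sim_config(paralog_divergence = 0.9), "0.5")
})

test_that("transcriptome generation is deterministic and honours paralogs", {
  cfg <- tiny_cfg()
  tx1 <- build_transcriptome(cfg)
  tx2 <- build_transcriptome(cfg)
  expect_identical(as.character(tx1$sequences), as.character(tx2$sequences))
  tx3 <- build_transcriptome(tiny_cfg(seed = 8))
  expect_false(identical(as.character(tx1$sequences),
                         as.character(tx3$sequences)))

  # zero divergence forces identical paralog copies
  cfg0 <- sim_config(n_genes = 2, n_paralog_families = 1,
                     paralog_divergence = 0, enhanced_design = list(),
                     transcript_length_range = c(100L, 200L), seed = 3)
  tx0 <- build_transcriptome(cfg0)
  expect_identical(as.character(tx0$sequences[[1]]),
                   as.character(tx0$sequences[[2]]))

  # nonzero divergence separates the copies at roughly the designed rate
  cfgd <- sim_config(n_genes = 2, n_paralog_families = 1,
                     paralog_divergence = 0.1, enhanced_design = list(),
                     transcript_length_range = c(1000L, 1000L), seed = 3)
  txd <- build_transcriptome(cfgd)
  d <- mapply(function(a, b) a != b,
              strsplit(as.character(txd$sequences[[1]]), "")[[1]],
              strsplit(as.character(txd$sequences[[2]]), "")[[1]])
  expect_gt(mean(d), 0.05)
  expect_lt(mean(d), 0.16)
})

test_that("annotation length is the longest emitted isoform per gene", {
  cfg <- tiny_cfg(n_genes = 50, isoforms_per_gene = 2)
  tx <- build_transcriptome(cfg)
  longest <- tapply(tx$isoforms$length, tx$isoforms$gene_id, max)
  expect_equal(as.vector(longest[tx$annotation$gene_id]),
               tx$annotation$length)
  expect_equal(nrow(tx$isoforms), 100)
})

test_that("expression profiles obey the design and normalization", {
  cfg <- tiny_cfg()
  truth <- simulate_expression(cfg)
  expect_equal(unname(colSums(truth$abundance)), rep(1, 6), tolerance = 1e-9)

  # designed genes are the labelled genes, and their post-renormalization
  # ratio equals fold x a common column factor (closure)
  lab <- truth$enhanced_labels$FA_vs_FB
  expect_setequal(names(lab)[lab == "tissue"],
                  names(truth$design$FA))
  r <- truth$abundance[names(truth$design$FA), "FA"] /
    truth$abundance[names(truth$design$FA), "FB"]
  expect_equal(unname(r / truth$design$FA),
               rep((r / truth$design$FA)[[1]], length(r)), tolerance = 1e-12)

  # no design: all six columns identical
  t0 <- simulate_expression(tiny_cfg(enhanced_design = list()))
  expect_equal(t0$abundance[, "FA"], t0$abundance[, "MP"])
  expect_true(all(t0$enhanced_labels$FA_vs_FB == "none"))

  # degenerate log-normal
  tflat <- simulate_expression(tiny_cfg(enhanced_design = list(),
                                        base_expression = c(mu = 0, sigma = 0)))
  expect_equal(unname(tflat$abundance[, "FB"]),
               rep(1 / cfg$n_genes, cfg$n_genes))
})

test_that("read simulation conserves library size and is deterministic", {
  cfg <- tiny_cfg()
  tx <- build_transcriptome(cfg)
  truth <- simulate_expression(cfg)
  rs1 <- simulate_reads(truth, tx, cfg, "FA")
  rs2 <- simulate_reads(truth, tx, cfg, "FA")
  expect_length(rs1$reads, cfg$library_size)
  expect_identical(rs1$reads, rs2$reads)
  expect_false(identical(rs1$reads,
                         simulate_reads(truth, tx, cfg, "FB")$reads))
  expect_error(simulate_reads(truth, tx, cfg, "XX"), "unknown sample")
})

test_that("error-free reads are exact substrings of their source", {
  cfg <- sim_config(n_genes = 1, n_paralog_families = 0, error_rate = 0,
                    enhanced_design = list(), library_size = 500,
                    transcript_length_range = c(300L, 300L), seed = 5)
  tx <- build_transcriptome(cfg)
  truth <- simulate_expression(cfg)
  rs <- simulate_reads(truth, tx, cfg, "FB")
  seq <- as.character(tx$sequences[[1]])
  expect_true(all(vapply(rs$reads, grepl, logical(1), x = seq, fixed = TRUE)))
  expect_true(all(nchar(rs$reads) == 43))
})

test_that("read counts split binomially by abundance x length weight", {
  # two equal-length genes at abundance 3:1 -> expected split 0.75/0.25
  cfg <- sim_config(n_genes = 2, n_paralog_families = 0, error_rate = 0,
                    enhanced_design = list(), library_size = 40000,
                    transcript_length_range = c(500L, 500L), seed = 11)
  tx <- build_transcriptome(cfg)
  truth <- structure(list(abundance = matrix(
    rep(c(0.75, 0.25), 6), nrow = 2,
    dimnames = list(tx$annotation$gene_id, cfg$samples))),
    class = "ground_truth")
  rs <- simulate_reads(truth, tx, cfg, "FA")
  n1 <- sum(rs$truth$gene_id == tx$annotation$gene_id[1])
  expect_lt(abs(n1 - 30000), 3 * sqrt(40000 * 0.75 * 0.25))
})

test_that("empirical read frequencies match multinomial expectation", {
  # chi-square goodness of fit not rejected at alpha = 0.01 for >= 19/20 seeds
  pass <- 0
  for (seed in 1:20) {
    cfg <- sim_config(n_genes = 20, n_paralog_families = 0,
                      base_expression = c(mu = 0, sigma = 0.3),
                      enhanced_design = list(), library_size = 20000,
                      transcript_length_range = c(300L, 800L), seed = seed)
    tx <- build_transcriptome(cfg)
    truth <- simulate_expression(cfg)
    rs <- simulate_reads(truth, tx, cfg, "FB")
    obs <- table(factor(rs$truth$gene_id, levels = tx$annotation$gene_id))
    exp_counts <- expected_counts(truth, tx, cfg, "FB")
    gof <- stats::chisq.test(as.vector(obs), p = exp_counts / sum(exp_counts))
    if (gof$p.value >= 0.01) pass <- pass + 1
  }
  expect_gte(pass, 19)
})

test_that("antisense fraction flips reads onto the reverse strand", {
  cfg <- tiny_cfg(antisense_fraction = 0.5, error_rate = 0,
                  library_size = 2000L)
  tx <- build_transcriptome(cfg)
  truth <- simulate_expression(cfg)
  rs <- simulate_reads(truth, tx, cfg, "FB")
  frac <- mean(rs$truth$strand == "-")
  expect_gt(frac, 0.45); expect_lt(frac, 0.55)
})
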