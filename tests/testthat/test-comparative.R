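test_that("venn overlap counts and percentages follow the definitions", {
  A <- gene_set("palp", paste0("g", 1:1906))
  B <- gene_set("antenna", c(paste0("g", 1:1158), paste0("h", 1:1119)))
  v <- venn_overlap(A, B)
  expect_equal(v$shared, 1158)
  expect_equal(v$a_only + v$shared, 1906)   # venn identity
  expect_equal(v$pct_of_a, 61)
  expect_equal(v$pct_of_a_exact, 100 * 1158 / 1906)

  d <- venn_overlap(c("a", "b"), c("c", "d"))
  expect_equal(c(d$shared, d$pct_of_a, d$pct_of_b), c(0, 0, 0))
  i <- venn_overlap(c("a", "b"), c("b", "a"))
  expect_equal(c(i$shared, i$pct_of_a, i$pct_of_b), c(2, 100, 100))
})

test_that("family profiles are raw RPKM rows in the fixed sample order", {
  d <- demo_run()
  # demo has only FB/FA columns; give explicit order
  m <- family_profile(d$expr, "Or", sample_order = c("FB", "FA"))
  or_genes <- sort(d$tx$annotation$gene_id[
    !is.na(d$tx$annotation$family) & d$tx$annotation$family == "Or"])
  expect_equal(rownames(m), or_genes)
  expect_equal(m, d$expr$rpkm[or_genes, c("FB", "FA")])
  expect_error(family_profile(d$expr, "Nope"), "unknown family")

  # designed FA-enhanced Or genes (fold >= 4, above the closure shrink)
  # dominate the FA column
  des <- d$truth$design$FA
  or_des <- intersect(or_genes, names(des)[des >= 4])
  expect_true(all(m[or_des, "FA"] > m[or_des, "FB"]))
})

test_that("pfam tallies count set members and respect annotation totals", {
  ann <- data.frame(gene_id = paste0("g", 1:6),
                    length = 100,
                    family = NA_character_,
                    pfam = c("PFX", "PFX", "PFX", "PFY", "PFY", NA),
                    stringsAsFactors = FALSE)
  tal <- pfam_tally(list(FA = c("g1", "g3", "g6"), FP = c("g4")), ann)
  expect_equal(tal$FA[tal$family == "PFX"], 2)
  expect_equal(tal$FP[tal$family == "PFY"], 1)
  expect_true(all(tal$FA <= tal$n_annotated))
  # g6 has no Pfam hit and drops out entirely
  expect_equal(sum(tal$FA), 2)
  # ranked by total representation
  expect_equal(tal$family[1], "PFX")
  empty <- pfam_tally(list(FA = "g1"),
                      data.frame(gene_id = "g1", length = 1,
                                 pfam = NA_character_))
  expect_equal(nrow(empty), 0)
})

test_that("normalization factors reproduce the published arithmetic", {
  f1 <- normalization_factor(630, 225, "sensilla_ratio")
  expect_equal(f1$reported, 2.8)
  f2 <- normalization_factor(916, 186, "orco_rpkm_ratio")
  expect_equal(f2$reported, 4.9)
  expect_equal(normalization_factor(5, 5, "fixed")$reported, 1)
  expect_error(normalization_factor(1, 0), "denominator")

  # scaling male Orco RPKM by the Orco factor approaches the female value
  sc <- normalize_profile(186, f2)
  expect_equal(sc$normalized, 916)
  sc2 <- normalize_profile(c(10, 20), 4.9)
  expect_equal(sc2$normalized, c(49, 98))
  expect_equal(sc2$original, c(10, 20))
  # positive factors preserve within-sample ranking
  v <- c(3, 1, 10, 7)
  expect_equal(order(normalize_profile(v, 2.8)$normalized), order(v))
})

test_that("Orco-style reference factors derive from the expression table", {
  w <- matrix(c(500, 8, 100, 8), ncol = 2,
              dimnames = list(c("orco", "x"), c("FA", "MA")))
  # filler equalizes library totals so the RPKM fold is exactly the count fold
  tt <- manual_tables(rbind(w, filler = c(492, 892)))
  expect_equal(sum(tt$counts$weighted[, "FA"]), sum(tt$counts$weighted[, "MA"]))
  f <- derive_orco_factor(tt$expr, "orco", "FA", "MA")
  expect_equal(f$factor, 5)
  expect_equal(f$basis, "orco_rpkm_ratio")
  tt$expr$rpkm["orco", "MA"] <- 0
  expect_error(derive_orco_factor(tt$expr, "orco", "FA", "MA"), "zero RPKM")
  expect_error(derive_orco_factor(tt$expr, "zz", "FA", "MA"), "unknown gene")
})

test_that("recovery metrics score callers against truth", {
  truth <- list(enhanced_labels = list(
    FA_vs_FB = c(g1 = "tissue", g2 = "tissue", g3 = "none", g4 = "none")))
  mk <- function(calls) {
    rec <- data.frame(gene_id = paste0("g", 1:4), call = calls,
                      stringsAsFactors = FALSE)
    attr(rec, "samples") <- c(sample_1 = "FA", sample_2 = "FB")
    attr(rec, "comparison") <- "FA_vs_FB"
    rec
  }
  perfect <- recovery_metrics(mk(c("FA", "FA", "none", "none")), truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$fdp, 0)
  expect_equal(perfect$direction_errors, 0)

  nothing <- recovery_metrics(mk(rep("none", 4)), truth)
  expect_equal(nothing$sensitivity, 0)
  expect_equal(nothing$fdp, 0)

  wrong <- recovery_metrics(mk(c("FB", "FA", "FA", "none")), truth)
  expect_equal(wrong$direction_errors, 1)
  expect_equal(wrong$sensitivity, 0.5)
  expect_equal(wrong$fdp, 2 / 3)

  bad <- mk(rep("none", 4)); bad$gene_id <- paste0("z", 1:4)
  expect_error(recovery_metrics(bad, truth), "disagree")
})
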