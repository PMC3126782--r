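# Independent oracles.  These deliberately share no code with the package
# paths they check.

# two-sided Fisher p by direct enumeration over all tables with the
# observed margins, using lchoose arithmetic only
fisher_enum <- function(a, n1, c, n2) {
  K <- a + c
  k <- max(0, K - n2):min(K, n1)
  lp <- lchoose(n1, k) + lchoose(n2, K - k) - lchoose(n1 + n2, K)
  lobs <- lchoose(n1, a) + lchoose(n2, c) - lchoose(n1 + n2, K)
  max(sum(exp(lp[lp <= lobs + log(1 + 1e-7)])), 1e-300)
}

revcomp_chr <- function(s) {
  vapply(s, function(x)
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]),
          collapse = ""), character(1), USE.NAMES = FALSE)
}

# naive all-offsets Hamming scan over every isoform and both strands;
# N mismatches everything (including another N)
oracle_scan <- function(read, seqs, max_mm) {
  out <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") read else revcomp_chr(read)
    qc <- strsplit(q, "")[[1]]
    L <- length(qc)
    for (j in seq_along(seqs)) {
      sc <- strsplit(seqs[[j]], "")[[1]]
      if (length(sc) < L) next
      for (st in 0:(length(sc) - L)) {
        win <- sc[(st + 1):(st + L)]
        mm <- sum(qc != win | qc == "N" | win == "N")
        if (mm <= max_mm)
          out <- rbind(out, data.frame(isoform = names(seqs)[j], start = st,
                                       strand = strand, mismatches = mm,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# distinct genes per read via Biostrings shift-or matching (independent of
# the package's seed index); returns a list of sorted gene-ID vectors
biostrings_gene_sets <- function(reads, seqs, max_mm) {
  subj <- Biostrings::DNAStringSet(seqs)
  genes <- sub("\\|.*$", "", names(seqs))
  lapply(reads, function(r) {
    fwd <- Biostrings::vcountPattern(r, subj, max.mismatch = max_mm)
    rev <- Biostrings::vcountPattern(revcomp_chr(r), subj, max.mismatch = max_mm)
    sort(unique(genes[fwd + rev > 0]))
  })
}
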