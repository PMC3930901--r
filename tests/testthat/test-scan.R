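expect_scan_equals_oracle <- function(seq, config = scan_config(),
                                      seq_id = "s") {
  got <- scan_sequence(seq_id, seq, config)
  thr <- ssrforge:::.effective_thresholds(config, seq_id)
  exp <- oracle_scan(seq, unname(thr))
  expect_equal(nrow(got), nrow(exp))
  if (nrow(exp)) {
    expect_equal(got$start, exp$start)
    expect_equal(got$end, exp$end)
    expect_equal(got$motif, exp$motif)
    expect_equal(got$repeat_count, exp$repeat_count)
  }
  invisible(got)
}

test_that("scan_sequence handles spec examples", {
  expect_equal(nrow(scan_sequence("s", "")), 0L)
  expect_equal(nrow(scan_sequence("s", strrep("A", 19))), 0L)
  expect_equal(scan_sequence("s", strrep("A", 20))$repeat_count, 20L)

  set.seed(7)
  repeat {   # flanks free of qualifying repeats and not extending the tract
    flank1 <- rand_dna(100); flank2 <- rand_dna(100)
    if (nrow(scan_sequence("s", paste0(flank1, flank2))) == 0L &&
        !substr(flank1, 100, 100) %in% c("A", "T") &&
        !substr(flank2, 1, 1) %in% c("A", "T")) break
  }
  got <- scan_sequence("s", paste0(flank1, strrep("AT", 9), flank2))
  expect_equal(nrow(got), 1L)
  expect_equal(got$class, "Di")
  expect_equal(got$family, "AT")
  expect_equal(got$repeat_count, 9L)
  expect_equal(got$tract_length, 18L)
  expect_equal(got$start, 101L)

  got_cg <- scan_sequence("s", paste0(flank1, strrep("CG", 8), flank2))
  expect_equal(got_cg$family, "CG")
  expect_equal(got_cg$class, "Di")
})

test_that("scan_sequence validates input", {
  expect_error(scan_sequence("s", "ACGTX"), "alphabet")
  # lowercase is accepted (FASTA case-insensitivity)
  expect_equal(scan_sequence("s", strrep("at", 10))$family, "AT")
})

test_that("runs containing N are broken at the N", {
  s <- paste0(strrep("AT", 5), "N", strrep("AT", 8))
  got <- scan_sequence("s", s)
  expect_equal(nrow(got), 1L)
  expect_equal(got$start, 12L)
  expect_equal(got$repeat_count, 8L)
  expect_equal(nrow(scan_sequence("s", strrep("N", 50))), 0L)
})

test_that("poly-A is Mono, never Di AA (primitivity)", {
  got <- scan_sequence("s", strrep("A", 30))
  expect_equal(got$class, "Mono")
  expect_equal(got$repeat_count, 30L)
  got2 <- scan_sequence("s", strrep("AT", 20))
  expect_equal(got2$class, "Di")
  expect_false(any(got2$class == "Tetra"))
})

test_that("scanner equals the brute-force oracle on random sequences", {
  set.seed(101)
  for (i in 1:150) {
    expect_scan_equals_oracle(rand_dna(2000))
  }
  # repeat-enriched sequences: splice random tracts into background
  set.seed(202)
  motifs <- c("A", "C", "AT", "AG", "CG", "AAG", "ACT", "AAAT",
              "AGATC", "AACGTC")
  for (i in 1:60) {
    s <- rand_dna(1500)
    for (j in 1:4) {
      m <- sample(motifs, 1)
      tract <- strrep(m, sample(3:25, 1))
      p <- sample(nchar(s) - nchar(tract), 1)
      s <- paste0(substr(s, 1, p), tract,
                  substr(s, p + nchar(tract) + 1, nchar(s)))
    }
    expect_scan_equals_oracle(s)
  }
})

test_that("maximality: one more unit either side breaks the repeat", {
  set.seed(33)
  for (i in 1:25) {
    s <- rand_dna(1000)
    tract <- strrep("AAG", 10)
    s <- paste0(substr(s, 1, 400), tract, substr(s, 401 + 30, 1000))
    loci <- scan_sequence("s", s)
    for (r in seq_len(nrow(loci))) {
      u <- nchar(loci$motif[r])
      a <- loci$start[r]; b <- loci$end[r]
      left <- substr(s, a - u, a - 1)
      right <- substr(s, b + 1, b + u)
      phase_l <- substr(s, a, a + u - 1)
      phase_r <- substr(s, b - u + 1, b)
      expect_false(nchar(left) == u && left == phase_l)
      expect_false(nchar(right) == u && right == phase_r)
    }
  }
})

test_that("raising a threshold never adds loci (monotonicity)", {
  set.seed(55)
  for (i in 1:15) {
    s <- rand_dna(1500)
    s <- paste0(s, strrep("AG", 9), strrep("AAT", 8), rand_dna(100))
    base <- scan_sequence("s", s, scan_config())
    for (cls in c("Di", "Tri")) {
      thr <- default_thresholds()
      thr[cls] <- thr[cls] + 1L
      up <- scan_sequence("s", s, scan_config(thr))
      key <- function(df) paste(df$start, df$motif)
      expect_true(all(key(up) %in% key(base)))
    }
  }
})

test_that("per-sequence overrides change only the targeted sequence", {
  s <- paste0(rand_dna(60), strrep("AT", 6), rand_dna(60))
  cfg <- scan_config(overrides = list(chr6 = c(Di = 5)))
  expect_equal(nrow(scan_sequence("chr1", s, cfg)), 0L)
  got <- scan_sequence("chr6", s, cfg)
  expect_equal(got$repeat_count, 6L)
})

test_that("scan_config validates thresholds", {
  expect_error(scan_config(c(Di = 1)), ">= 2")
  expect_error(scan_config(c(Umpteen = 4)), "unknown")
  expect_error(scan_config(flank_length = -1), "flank_length")
})

test_that("extract_flanks clips at sequence edges", {
  g <- c(chr1 = rand_dna(10000))
  loc <- list(seq_id = "chr1", start = 201L, end = 218L)
  fr <- extract_flanks(loc, g, 200L)
  expect_equal(c(fr$frag_start, fr$frag_end), c(1L, 418L))
  expect_equal(fr$left_clip, 0L)

  loc2 <- list(seq_id = "chr1", start = 1L, end = 20L)
  fr2 <- extract_flanks(loc2, g, 200L)
  expect_equal(c(fr2$frag_start, fr2$frag_end), c(1L, 220L))
  expect_equal(fr2$left_clip, 200L)

  loc3 <- list(seq_id = "chr1", start = 5001L, end = 5018L)
  fr3 <- extract_flanks(loc3, g, 50L)
  expect_equal(nchar(fr3$sequence), 18L + 100L)
  expect_equal(substr(fr3$sequence, fr3$tract_start, fr3$tract_end),
               substr(g[["chr1"]], 5001L, 5018L))

  expect_error(extract_flanks(list(seq_id = "nope", start = 1, end = 2), g),
               "missing sequence")
})

test_that("classify_genomic_context uses >= 1 bp overlap", {
  loci <- data.frame(locus_id = "L1", seq_id = "c1", start = 100L,
                     end = 120L)
  cds <- data.frame(seq_id = "c1", start = 50L, end = 200L)
  expect_equal(classify_genomic_context(loci, cds)$context, "coding")
  expect_equal(classify_genomic_context(loci, NULL)$context, "non-coding")
  edge <- data.frame(seq_id = "c1", start = 120L, end = 300L)
  expect_equal(classify_genomic_context(loci, edge)$context, "coding")
  miss <- data.frame(seq_id = "c1", start = 121L, end = 300L)
  expect_equal(classify_genomic_context(loci, miss)$context, "non-coding")
})

test_that("summarize_by_class_and_chrom totals add up", {
  empty <- summarize_by_class_and_chrom(scan_sequence("s", ""))
  expect_equal(empty$Total, 0L)

  loci <- rbind(
    data.frame(locus_id = c("a", "b"), seq_id = "c1", start = 1:2,
               end = 3:4, motif = "AT", family = "AT", class = "Di",
               repeat_count = 8L, tract_length = 16L),
    data.frame(locus_id = "c", seq_id = "c2", start = 1L, end = 3L,
               motif = "AAG", family = "AAG", class = "Tri",
               repeat_count = 8L, tract_length = 24L))
  tab <- summarize_by_class_and_chrom(loci)
  expect_equal(tab$Di[tab$seq_id == "c1"], 2L)
  expect_equal(tab$Total[tab$seq_id == "Total"], 3L)
  expect_equal(sum(tab$Total[tab$seq_id != "Total"]),
               tab$Total[tab$seq_id == "Total"])
})

test_that("loci tables round-trip through TSV and GFF3 is well-formed", {
  s <- paste0(rand_dna(100), strrep("AT", 9), rand_dna(100))
  loci <- scan_sequence("chr1", s)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_loci(loci, tsv)
  expect_equal(read_loci(tsv), loci)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_loci_gff3(loci, gff)
  lines <- readLines(gff)
  expect_equal(lines[1], "##gff-version 3")
  f <- strsplit(lines[2], "\t")[[1]]
  expect_equal(as.integer(f[4:5]), c(loci$start, loci$end))
  expect_equal(f[3], "microsatellite")
})
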