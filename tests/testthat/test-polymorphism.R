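test_that("anchor_flanks reproduces the tract on an identical assembly", {
  gen <- generate_genome(1, 10000, default_plants(), seed = 9)
  loci <- scan_genome(gen$genome)
  frag <- extract_flanks(loci[1, ], gen$genome, 200L)
  left <- substr(frag$sequence, 1, frag$tract_start - 1)
  right <- substr(frag$sequence, frag$tract_end + 1,
                  nchar(frag$sequence))
  iv <- anchor_flanks(left, right, gen$genome)
  expect_equal(iv$seq_id, "seq1")
  expect_equal(c(iv$start, iv$end), c(loci$start[1], loci$end[1]))
  expect_equal(iv$sequence, strrep("AT", 10))

  # left flank deleted -> unresolved
  cut <- gen$genome
  cut[["seq1"]] <- substr(cut[["seq1"]], loci$start[1], 10000)
  expect_null(anchor_flanks(left, right, cut))

  # flank shorter than the anchor -> unresolved
  expect_null(anchor_flanks(substr(left, 1, 30), right, gen$genome))
})

test_that("anchor_flanks tolerates few mismatches but not ambiguity", {
  gen <- generate_genome(1, 10000, default_plants(), seed = 13)
  loci <- scan_genome(gen$genome)
  frag <- extract_flanks(loci[2, ], gen$genome, 200L)
  left <- substr(frag$sequence, 1, frag$tract_start - 1)
  right <- substr(frag$sequence, frag$tract_end + 1, nchar(frag$sequence))

  # two substitutions inside the left anchor still anchor
  g2 <- gen$genome
  s <- g2[["seq1"]]
  for (p in c(loci$start[2] - 5L, loci$start[2] - 20L)) {
    cur <- substr(s, p, p)
    substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  g2[["seq1"]] <- s
  iv <- anchor_flanks(left, right, g2)
  expect_equal(c(iv$start, iv$end), c(loci$start[2], loci$end[2]))

  # anchor duplicated -> ambiguous -> unresolved
  g3 <- gen$genome
  anchor <- substr(left, nchar(left) - 49, nchar(left))
  g3[["seq1"]] <- paste0(g3[["seq1"]], strrep("N", 5), anchor)
  expect_null(anchor_flanks(left, right, g3))
})

test_that("measure_alt_tract measures family runs", {
  expect_equal(measure_alt_tract("ATATATATATAT", "AT"), 12L)
  expect_equal(measure_alt_tract(paste0("GG", strrep("AT", 6), "CC"), "AT"),
               12L)
  expect_equal(measure_alt_tract("GGGG", "AT"), 0L)
  # rotated phase counts toward the family
  expect_equal(measure_alt_tract("TATATATA", "AT"), 8L)
  # longest run wins
  expect_equal(measure_alt_tract("ATATCGGCATATATAT", "AT"), 8L)
  # a single unit occurrence measures one unit
  expect_equal(measure_alt_tract("GGATGG", "AT"), 2L)
})

test_that("call_polymorphism thresholds deltas", {
  r <- call_polymorphism(16, list(DQJ = 16, N10 = 20))
  expect_equal(r$status, "polymorphic")
  expect_equal(r$deltas[["N10"]], 4)
  expect_equal(call_polymorphism(16, list(DQJ = 16))$status, "monomorphic")
  expect_equal(call_polymorphism(16, list())$status, "unresolved")
  expect_equal(call_polymorphism(16, list(DQJ = 18), min_diff = 3)$status,
               "monomorphic")
})

test_that("comparing a genome to itself yields zero polymorphic loci", {
  gen <- generate_genome(1, 10000, default_plants(), seed = 17)
  loci <- scan_genome(gen$genome)
  cmp <- compare_loci(loci, gen$genome, list(self = gen$genome))
  expect_true(all(cmp$status == "monomorphic"))
  expect_true(all(cmp$self_delta == 0))
})

test_that("planted deltas are recovered exactly", {
  gen <- generate_genome(1, 10000, default_plants(), seed = 21)
  loci <- scan_genome(gen$genome)
  deltas <- c(2L, 0L, -3L, 1L, 0L)
  alt <- derive_genotype(gen$genome, gen$truth, deltas, snp_rate = 0.002,
                         seed = 22)
  cmp <- compare_loci(loci, gen$genome, list(alt = alt$genome))
  units <- nchar(loci$motif)
  expect_equal(cmp$alt_delta, deltas * units)
  expect_equal(cmp$status,
               ifelse(deltas != 0, "polymorphic", "monomorphic"))
})

test_that("SNPs planted inside anchors make loci unresolved", {
  gen <- generate_genome(1, 10000, default_plants(), seed = 31)
  loci <- scan_genome(gen$genome)
  alt <- derive_genotype(gen$genome, gen$truth, rep(1L, 5),
                         snp_rate = 0.5, seed = 32, mutate_anchors = TRUE)
  cmp <- compare_loci(loci, gen$genome, list(alt = alt$genome))
  expect_true(all(cmp$status == "unresolved"))
  expect_true(all(is.na(cmp$alt_len)))
})

test_that("summarize_rates recomputes percentages from counts", {
  gen <- generate_genome(2, 6000,
                         rbind(plant_spec("seq1", 1000L, "AT", 10L),
                               plant_spec("seq1", 3000L, "AAG", 9L),
                               plant_spec("seq2", 1500L, "AC", 11L)),
                         seed = 41)
  loci <- scan_genome(gen$genome)
  alt <- derive_genotype(gen$genome, gen$truth, c(2L, 0L, 1L),
                         snp_rate = 0, seed = 42)
  cmp <- compare_loci(loci, gen$genome, list(alt = alt$genome))
  rates <- summarize_rates(cmp, "seq_id")
  tot <- rates[rates$group == "Total", ]
  expect_equal(tot$n_total, 3L)
  expect_equal(tot$alt_polymorphic, 2L)
  expect_equal(tot$alt_pct,
               round_half_up(100 * tot$alt_polymorphic / tot$n_total, 1))
  expect_equal(sum(rates$n_total[rates$group != "Total"]), tot$n_total)
  expect_equal(nrow(summarize_rates(cmp[0, ], "seq_id")), 0L)
})

test_that("rate percentages match the published-table convention", {
  # percentage cells are 100 * polymorphic / total, half-up to 1 decimal
  expect_equal(round_half_up(100 * 1219 / 5020, 1), 24.3)
  expect_equal(round_half_up(100 * 2053 / 5020, 1), 40.9)
  expect_equal(round_half_up(0.05, 1), 0.1)   # half-up, not banker's
})
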