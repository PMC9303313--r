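test_that("semi-global distance handles the worked examples and edge cases", {
  expect_identical(semi_global_distance("ACGT", "TTACGTTT"), 0L)
  expect_identical(semi_global_distance("ACGT", "TTAGGTTT"), 1L)
  expect_identical(semi_global_distance("ACGT", "TTACGGTTT"), 1L)
  expect_identical(semi_global_distance("ACGT", ""), 4L)
  expect_error(semi_global_distance("", "ACGT"),
               class = "gapmertox_validation_error")
})

test_that("the DP core agrees with two independent oracles on random pairs", {
  set.seed(101)
  for (rep in 1:400) {
    pat <- rand_dna(sample(8:14, 1))
    txt <- rand_dna(sample(c(0, 5, 20, 100, 500), 1))
    got <- semi_global_distance(pat, txt)
    expect_identical(got, oracle_sg_distance(pat, txt))
    expect_identical(got, adist_sg_distance(pat, txt))
    if (got <= 3L) {
      # scan_transcript takes the ASO, whose reverse complement is `pat`
      hits <- scan_transcript(reverse_complement(pat), txt, d_max = 3)
      expect_identical(min(hits$d), got)
    }
  }
})

test_that("mismatch-only distance never beats edit distance", {
  set.seed(33)
  for (rep in 1:100) {
    pat <- rand_dna(10)
    txt <- rand_dna(sample(10:200, 1))
    expect_gte(mismatch_only_distance(pat, txt),
               semi_global_distance(pat, txt))
  }
})

test_that("scanning recovers planted sites with exact coordinates", {
  aso <- parse_gapmer("TS1")
  set.seed(5)
  bg <- rand_dna(120)
  rc <- reverse_complement(aso$sequence)
  tx0 <- paste0(substr(bg, 1, 50), rc, substr(bg, 65, 120))
  hits <- scan_transcript(aso, tx0, d_max = 0)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 50L)
  expect_identical(hits$end, 64L)
  expect_identical(hits$d, 0L)

  pl <- plant_site(bg, aso, d = 2, seed = 9)
  h2 <- scan_transcript(aso, pl$sequence, d_max = 2)
  expect_identical(min(h2$d), 2L)
  expect_identical(nrow(scan_transcript(aso, pl$sequence, d_max = 1)), 0L)
})

test_that("hit sets grow monotonically with d_max and bookkeeping is consistent", {
  aso <- parse_gapmer("TS2")
  set.seed(17)
  for (rep in 1:20) {
    tx <- plant_site(rand_dna(150), aso, d = sample(0:3, 1))$sequence
    prev_hits <- NULL
    for (dm in 0:3) {
      hits <- scan_transcript(aso, tx, d_max = dm)
      if (nrow(hits) > 0) {
        expect_identical(hits$d, hits$n_mismatch + hits$n_ins + hits$n_del)
        expect_identical(hits$end - hits$start,
                         nchar(aso$sequence) - hits$n_ins + hits$n_del)
        # gap-free alignment strings reproduce the decomposition
        aq <- strsplit(hits$aligned_query, "")
        at <- strsplit(hits$aligned_target, "")
        expect_identical(vapply(at, function(x) sum(x == "-"), 1L), hits$n_ins)
        expect_identical(vapply(aq, function(x) sum(x == "-"), 1L), hits$n_del)
      }
      # every site found at a stricter threshold is still covered here,
      # at a distance no worse than before (merging may widen intervals)
      if (!is.null(prev_hits) && nrow(prev_hits) > 0) {
        for (r in seq_len(nrow(prev_hits))) {
          over <- hits$start < prev_hits$end[r] & hits$end > prev_hits$start[r]
          expect_true(any(over))
          expect_lte(min(hits$d[over]), prev_hits$d[r])
        }
      }
      prev_hits <- hits
    }
  }
})

test_that("per-gene classification takes the minimum across transcripts", {
  aso <- parse_gapmer("TS1")
  set.seed(21)
  t_d2 <- plant_site(rand_dna(150), aso, d = 2)$sequence
  t_d1 <- plant_site(rand_dna(150), aso, d = 1)$sequence
  txome <- c(tx1 = t_d2, tx2 = t_d1)
  map <- tibble::tibble(transcript_id = c("tx1", "tx2"),
                        gene_id = c("geneA", "geneA"))
  got <- classify_offtargets(aso, txome, map)
  expect_identical(nrow(got), 1L)
  expect_identical(got$min_d, 1L)
  expect_identical(as.character(got$class), "d1")

  # three genes planted at d = 0, 1, 2 classify exactly
  seqs <- vapply(0:2, function(d)
    plant_site(rand_dna(200), aso, d = d)$sequence, character(1))
  names(seqs) <- paste0("t", 0:2)
  got3 <- classify_offtargets(aso, seqs, NULL)
  expect_identical(got3$min_d[order(got3$gene_id)], 0:2)
  expect_identical(as.character(got3$class[order(got3$gene_id)]),
                   c("d0", "d1", "d2"))

  expect_identical(nrow(classify_offtargets(aso, character(0), NULL)), 0L)
  expect_error(classify_offtargets(aso, txome,
                                   tibble::tibble(transcript_id = "tx1",
                                                  gene_id = "geneA")),
               class = "gapmertox_mapping_error")
})

test_that("the exclusion screen rejects d <= 1 complements and passes the rest", {
  aso_seq <- "GTTATGCCACCCTA"
  set.seed(31)
  bg <- rand_dna(100)
  hostile <- paste0(bg, reverse_complement(aso_seq), rand_dna(50))
  res <- exclusion_screen(aso_seq, c(tx = hostile))
  expect_false(res$pass)
  expect_identical(res$best_d, 0L)

  planted2 <- plant_site(rand_dna(200), aso_seq, d = 2, seed = 3)$sequence
  res2 <- exclusion_screen(aso_seq, c(tx = planted2))
  expect_true(res2$pass)
  expect_identical(res2$best_d, 2L)

  res0 <- exclusion_screen(c("ACGTACGTACGTAC", "GGGGCCCCAAAATT"),
                           character(0))
  expect_true(all(res0$pass))
  expect_true(all(is.na(res0$best_d)))

  expect_error(exclusion_screen(c("ACGT", "ACGTA"), character(0)),
               class = "gapmertox_validation_error")

  # mismatch-only mode is at least as strict a distance
  res_mm <- exclusion_screen(aso_seq, c(tx = planted2),
                             mode = "mismatch_only")
  expect_gte(res_mm$best_d, res2$best_d)
})
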