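test_that("reverse complement matches the hand-derived value and is an involution", {
  expect_identical(reverse_complement("GTTATGCCACCCTA"), "TAGGGTGGCATAAC")
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement(""), "")
  expect_identical(reverse_complement("acgu"), "ACGT")
  expect_error(reverse_complement("ACGN"), class = "gapmertox_alphabet_error")
  set.seed(11)
  for (len in c(1, 5, 14, 40)) {
    s <- rand_dna(len)
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("motif counting reproduces the screening-table counts and a naive scan", {
  tab <- ts_aso_table()
  for (i in seq_len(nrow(tab))) {
    counts <- count_motifs(tab$sequence[i])
    expect_identical(unname(counts["TGC"]), tab$tgc[i], label = tab$name[i])
    expect_identical(unname(counts["TCC"]), tab$tcc[i], label = tab$name[i])
  }
  expect_identical(unname(count_motifs("TGCTGC", "TGC")), 2L)
  expect_identical(unname(count_motifs("AAAA", "AAA")), 2L)  # overlaps count
  set.seed(7)
  for (rep in 1:25) {
    s <- rand_dna(sample(10:60, 1))
    m <- rand_dna(sample(2:4, 1))
    expect_identical(unname(count_motifs(s, m)), naive_motif_count(s, m))
  }
})

test_that("the modification registry holds 17 checked derivatives", {
  reg <- mod_registry()
  expect_identical(nrow(reg), 17L)
  expect_false(anyDuplicated(reg$code) > 0)
  attested <- c("C1", "C3", "T1", "T4", paste0("G", 1:8))
  expect_true(all(attested %in% reg$code))
  expect_setequal(reg$code[reg$novel_flag], c("G4", "G5", "G6", "G7"))
  expect_identical(registry_lookup("C1")$base_letter, "C")
  expect_identical(registry_lookup("C1")$chemistry_name, "5-hydroxycytosine")
  expect_error(registry_lookup("Z9"), class = "gapmertox_registry_error")
  expect_error(mod_registry(extra = data.frame(code = "X1", base_letter = "N")),
               class = "gapmertox_registry_error")
})

test_that("study-style names parse into validated gapmers", {
  ts1 <- parse_gapmer("TS1")
  expect_s3_class(ts1, "gapmer_aso")
  expect_identical(ts1$sequence, "GTTATGCCACCCTA")
  expect_identical(gap_region(ts1), 3:12)

  a <- parse_gapmer("TS1-C1-7")
  expect_identical(a$parent_id, "TS1")
  expect_identical(a$modifications$code, "C1")
  expect_identical(a$modifications$position, 7L)
  expect_identical(substring(a$sequence, 7, 7), "C")

  # position 2 lies in the 5' wing under the 2-10-2 design
  expect_error(parse_gapmer("TS1-C1-2"), class = "gapmertox_validation_error")
  expect_error(parse_gapmer("TS1-Z9-7"), class = "gapmertox_registry_error")
  # position 4 holds A, which no C-derivative may replace
  expect_error(parse_gapmer("TS1-C1-4"), class = "gapmertox_validation_error")
  expect_error(parse_gapmer("NOSUCH"), class = "gapmertox_parse_error")
})

test_that("parse_gapmer inverts format_gapmer on valid records", {
  ts1 <- parse_gapmer("TS1")
  triple <- apply_modification(
    apply_modification(apply_modification(ts1, "G1", 6), "T1", 5), "C1", 7)
  for (aso in list(ts1, parse_gapmer("TS1-C1-7"), triple)) {
    back <- parse_gapmer(as.data.frame(format_gapmer(aso)))
    expect_identical(back$id, aso$id)
    expect_identical(back$sequence, aso$sequence)
    expect_identical(back$wing5_len, aso$wing5_len)
    expect_identical(back$gap_len, aso$gap_len)
    expect_identical(back$modifications$code, aso$modifications$code)
    expect_identical(back$modifications$position, aso$modifications$position)
  }
})

test_that("modifications annotate without touching the base sequence", {
  ts1 <- parse_gapmer("TS1")
  a <- apply_modification(ts1, "C1", 7)
  expect_identical(a$id, "TS1-C1-7")
  expect_identical(a$sequence, ts1$sequence)

  triple <- apply_modification(
    apply_modification(apply_modification(ts1, "G1", 6), "T1", 5), "C1", 7)
  expect_identical(triple$id, "TS1-G1T1C1")
  expect_identical(nrow(triple$modifications), 3L)
  expect_identical(triple$sequence, ts1$sequence)

  expect_error(apply_modification(a, "C1", 7),
               class = "gapmertox_validation_error")
})

test_that("validate_design reports each violated invariant", {
  expect_length(validate_design(parse_gapmer("TS1")), 0)

  bad_len <- gapmer("X", "GTTATGCCACCCTA", wing5 = 3, gap = 10, wing3 = 3,
                    validate = FALSE)
  expect_match(validate_design(bad_len), "sequence length", all = FALSE)

  wrong_base <- gapmer("X", "GTTATGCCACCCTA",
                       modifications = data.frame(code = "G1", position = 4),
                       validate = FALSE)
  expect_match(validate_design(wrong_base), "position 4 holds A", all = FALSE)

  wing_pos <- gapmer("X", "GTTATGCCACCCTA",
                     modifications = data.frame(code = "T1", position = 2),
                     validate = FALSE)
  expect_match(validate_design(wing_pos), "wing", all = FALSE)
})

test_that("gapmer TSV round-trips through disk", {
  asos <- list(parse_gapmer("TS1"), parse_gapmer("TS1-C1-7"),
               parse_gapmer("TS5"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gapmer_tsv(asos, path)
  back <- read_gapmer_tsv(path)
  expect_named(back, c("TS1", "TS1-C1-7", "TS5"))
  expect_identical(back[["TS1-C1-7"]]$modifications$position, 7L)
})
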