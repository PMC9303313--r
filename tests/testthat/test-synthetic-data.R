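test_that("transcriptome generation is deterministic and honors its config", {
  cfg <- sim_config(seed = 3, n_genes = 5, len_range = c(200, 500))
  t1 <- make_transcriptome(cfg)
  t2 <- make_transcriptome(cfg)
  expect_identical(t1$sequences, t2$sequences)
  expect_identical(t1$tx2gene, t2$tx2gene)
  expect_true(all(nchar(t1$sequences) >= 200 & nchar(t1$sequences) <= 500))
  expect_identical(length(t1$sequences), 5L)
})

test_that("with no planted sites every configured ASO passes the screen", {
  asos <- ts_asos()[1:3]
  cfg <- sim_config(seed = 8, n_genes = 20, len_range = c(200, 300))
  txome <- make_transcriptome(cfg, asos = asos)
  res <- exclusion_screen(vapply(asos, `[[`, "", "sequence"),
                          txome$sequences)
  expect_true(all(res$pass))
})

test_that("plant_site embeds sites the scanner recovers at the exact distance", {
  aso <- parse_gapmer("TS1")
  set.seed(90)
  bg <- rand_dna(200)

  pl0 <- plant_site(bg, aso, d = 0)
  expect_true(grepl(reverse_complement(aso$sequence), pl0$sequence,
                    fixed = TRUE))

  pl2 <- plant_site(bg, aso, d = 2)
  expect_identical(oracle_sg_distance(reverse_complement(aso$sequence),
                                      pl2$sequence), 2L)
  expect_identical(nrow(scan_transcript(aso, pl2$sequence, d_max = 1)), 0L)

  for (d in 0:3) {
    for (rep in 1:5) {
      pl <- plant_site(rand_dna(150), aso, d = d)
      hits <- scan_transcript(aso, pl$sequence, d_max = 3)
      expect_identical(min(hits$d), d)
    }
  }
  expect_error(plant_site(bg, aso, d = 5), "between 0 and 3")
})

test_that("expression simulation follows its closed-form model", {
  genes <- paste0("g", 1:4)
  dist <- tibble::tibble(gene_id = genes, min_d = c(0L, 1L, 3L, 2L))

  quiet <- sim_config(delta0 = 0, sigma_expr = 0)
  e0 <- simulate_expression(quiet, dist, "a", genes, seed = 1)
  expect_true(all(e0$ratio == 1))

  exact <- sim_config(delta0 = 1, gamma = 0.5, d_eff = 2, sigma_expr = 0)
  e1 <- simulate_expression(exact, dist, "a", genes, seed = 1)
  expect_equal(e1$ratio, c(0.5, 2^-0.5, 1, 2^-0.25), tolerance = 1e-12)

  # CLT bound on the d0 class mean at realistic noise
  cfg <- sim_config(delta0 = 1, gamma = 0.5, sigma_expr = 0.1)
  genes2k <- paste0("g", 1:2000)
  dist2k <- tibble::tibble(gene_id = genes2k[1:500], min_d = 0L)
  e2 <- simulate_expression(cfg, dist2k, "a", genes2k, seed = 13)
  m_d0 <- mean(log2(e2$ratio[1:500]))
  expect_lt(abs(m_d0 - (-1)), 3 * 0.1 / sqrt(500))
})

test_that("toxicity simulation isolates hybridization-dependent and -independent drivers", {
  flat <- sim_config(alpha = log(40), beta_hyb = 0, sigma_tox = 0)
  idx <- tibble::tibble(aso_id = paste0("a", 1:5), value = runif(5, 0, 10))
  t0 <- simulate_toxicity(flat, idx, seed = 2)
  expect_equal(t0$ast, rep(40, 5))
  expect_equal(t0$alt, rep(40, 5))

  # protein-driven scenario: index carries no signal
  set.seed(95)
  idx100 <- tibble::tibble(aso_id = paste0("a", 1:100),
                           value = runif(100, 0, 10))
  indep <- sim_config(alpha = log(40), beta_hyb = 0,
                      beta_indep = setNames(rnorm(100, 0, 1), idx100$aso_id),
                      sigma_tox = 0.1)
  tox_i <- simulate_toxicity(indep, idx100, seed = 3)
  expect_lt(abs(correlate(idx100$value, tox_i$ast, log_y = TRUE)$r), 0.15)

  # hybridization-driven scenario: index explains log toxicity
  hyb <- sim_config(alpha = log(40), beta_hyb = 0.3, sigma_tox = 0.05)
  tox_h <- simulate_toxicity(hyb, idx100, seed = 4)
  expect_gt(correlate(idx100$value, tox_h$ast, log_y = TRUE)$r, 0.8)
})

test_that("fixture bundles are byte-identical per scenario and seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_fixture_bundle("null", seed = 5, dir = d1)
  make_fixture_bundle("null", seed = 5, dir = d2)
  files <- list.files(d1)
  expect_true(length(files) >= 8)
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
})

test_that("bundle ground truth survives the full pipeline round trip", {
  b <- make_fixture_bundle("paper_like", seed = 11)
  # planted distance classes are exactly what the search module reports;
  # rejection sampling guards d <= 2, so any extra genes sit at d = 3
  dist1 <- b$dist[b$dist$aso_id == "TS1", ]
  planted <- b$transcriptome$planted
  expect_setequal(dist1$gene_id[dist1$min_d <= 2], planted$gene_id)
  merged <- merge(dist1, planted[, c("gene_id", "d")], by = "gene_id")
  expect_identical(merged$min_d, merged$d)
  expect_true(all(dist1$min_d[!dist1$gene_id %in% planted$gene_id] == 3L))
  expect_identical(as.integer(table(factor(planted$d, levels = 0:2))),
                   c(5L, 30L, 120L))
})

test_that("the null scenario produces no hepatotoxicity calls", {
  b <- make_fixture_bundle("null", seed = 21)
  expect_false(any(classify_hepatotoxic(b$tox$ast, b$tox$alt)))
})

test_that("the paper-like scenario dissociates index from toxicity", {
  b <- make_fixture_bundle("paper_like", seed = 31)
  parent_idx <- b$indices$value[b$indices$aso_id == "TS1"]
  parent_ast <- b$tox$ast[b$tox$aso_id == "TS1"]
  for (a in setdiff(b$indices$aso_id, "TS1")) {
    ratio <- 100 * b$indices$value[b$indices$aso_id == a] / parent_idx
    expect_gt(ratio, 85); expect_lt(ratio, 115)
    expect_lt(b$tox$ast[b$tox$aso_id == a] / parent_ast, 0.1)
  }
})

test_that("the hybridization-driven counterfactual couples index and toxicity", {
  b <- make_fixture_bundle("hybridization_driven", seed = 41)
  ord_idx <- order(b$indices$value)
  expect_identical(order(b$tox$ast[ord_idx]), seq_along(ord_idx))
})
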