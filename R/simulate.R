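#' Simulation configuration
#'
#' Houses the data-generating assumptions that stand in for the study
#' system: a transcriptome in which complementary sites are planted at
#' known distances, RNase H-driven knockdown whose depth decays
#' geometrically with distance, and serum toxicity split into a
#' hybridization-dependent part (proportional to the off-target index) and
#' a hybridization-independent per-ASO part (the latent protein-interaction
#' term that nucleobase modifications reduce).
#'
#' The knockdown model for gene g with minimal distance d(g) is
#' `log2 ratio = -delta0 * gamma^d(g) * [d(g) <= d_eff] + N(0, sigma_expr)`;
#' the toxicity model is
#' `log AST = alpha + beta_hyb * index + beta_indep(aso) + N(0, sigma_tox)`
#' (ALT identically with its own noise draw). AST/ALT are simulated on the
#' log scale because observed values span roughly 300-15000 U/l.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of genes (one transcript per gene).
#' @param len_range transcript length bounds, uniform (default 200-500 nt).
#' @param planted_sites optional tibble (`aso_id`, `gene_id`, `d`) of
#'   complementary sites to embed.
#' @param delta0 log2 down-regulation at d = 0 (>= 0; default 2, i.e. 75%
#'   knockdown of perfectly complementary genes).
#' @param gamma decay of knockdown per unit distance, in (0, 1] (default
#'   0.5).
#' @param d_eff largest distance with any expression effect (default 2).
#' @param sigma_expr sd of log2-ratio noise (default 0.1, a typical
#'   microarray technical spread).
#' @param alpha baseline log AST/ALT (default `log(40)`, a normal murine
#'   serum level).
#' @param beta_hyb weight of the off-target index in log toxicity.
#' @param beta_indep named numeric vector of per-ASO
#'   hybridization-independent log-toxicity terms (missing ASOs get 0).
#' @param sigma_tox sd of log-toxicity noise (default 0.1).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 200L, len_range = c(200L, 500L),
                       planted_sites = NULL, delta0 = 2, gamma = 0.5,
                       d_eff = 2L, sigma_expr = 0.1, alpha = log(40),
                       beta_hyb = 0, beta_indep = NULL, sigma_tox = 0.1) {
  if (delta0 < 0) abort("`delta0` must be >= 0.")
  if (gamma <= 0 || gamma > 1) abort("`gamma` must be in (0, 1].")
  if (sigma_expr < 0 || sigma_tox < 0) abort("Noise sds must be >= 0.")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 len_range = as.integer(len_range),
                 planted_sites = planted_sites, delta0 = delta0,
                 gamma = gamma, d_eff = as.integer(d_eff),
                 sigma_expr = sigma_expr, alpha = alpha,
                 beta_hyb = beta_hyb, beta_indep = beta_indep,
                 sigma_tox = sigma_tox),
            class = "sim_config")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Embed an approximate complementary site into a transcript
#'
#' Takes the reverse complement of the ASO sequence, applies exactly `d`
#' random edits (a mix of substitutions, insertions and deletions), and
#' splices the result over a random window of the transcript. The plant is
#' only accepted if a full re-scan of the modified transcript reports a
#' minimal distance of exactly `d` (random edits can cancel, and the
#' flanking sequence can accidentally offer a better alignment); otherwise
#' it retries with fresh edits and placement.
#'
#' @param transcript background transcript sequence.
#' @param aso a `gapmer_aso` or DNA string.
#' @param d requested distance, 0-3.
#' @param seed optional seed (otherwise the current RNG stream is used).
#' @param max_tries retry budget (default 100).
#' @return list: `sequence` (modified transcript), `start`, `end` (0-based
#'   half-open planted interval), `d`.
#' @export
plant_site <- function(transcript, aso, d, seed = NULL, max_tries = 100L) {
  if (!is.null(seed)) set.seed(seed)
  if (d < 0L || d > 3L) abort("`d` must be between 0 and 3.")
  p <- as_aso_pattern(aso)
  pattern <- p$pattern
  transcript <- normalize_dna(transcript)
  n <- nchar(transcript)
  for (try in seq_len(max_tries)) {
    site <- mutate_site(pattern, d)
    w <- nchar(site)
    if (n < w) abort("Transcript too short to plant a site.")
    pos <- sample.int(n - w + 1L, 1L)
    cand <- paste0(substring(transcript, 1L, pos - 1L), site,
                   substring(transcript, pos + w, n))
    if (sg_distance_cpp(pattern, cand) == d) {
      return(list(sequence = cand, start = pos - 1L, end = pos - 1L + w,
                  d = as.integer(d)))
    }
  }
  abort(sprintf("Could not plant a d = %d site in %d tries.", d, max_tries),
        class = "gapmertox_plant_error")
}

# exactly d random edits applied to a site sequence
mutate_site <- function(site, d) {
  if (d == 0L) return(site)
  ch <- strsplit(site, "", fixed = TRUE)[[1]]
  ops <- sample(c("sub", "ins", "del"), d, replace = TRUE)
  for (op in ops) {
    i <- sample.int(length(ch), 1L)
    if (op == "sub") {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    } else if (op == "ins") {
      ch <- append(ch, sample(c("A", "C", "G", "T"), 1L), after = i)
    } else if (length(ch) > 1L) {
      ch <- ch[-i]
    }
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic transcriptome with known planted complementarity
#'
#' Draws one random transcript per gene (lengths uniform over
#' `cfg$len_range`), embeds the configured planted sites, and
#' rejection-samples so that no transcript carries an accidental
#' complementary region at d <= max(`d_eff`, 1) to any configured ASO
#' other than the planted ones. Planted distances are therefore
#' unambiguous ground truth, and with no planted sites every configured
#' ASO passes the exclusion screen by construction.
#'
#' @param cfg a [sim_config()] (uses `n_genes`, `len_range`,
#'   `planted_sites`, `d_eff`, and `seed` unless overridden).
#' @param asos list of configured `gapmer_aso` objects (or DNA strings)
#'   that the rejection check guards against.
#' @param seed RNG seed (default `cfg$seed`).
#' @param max_tries per-transcript regeneration budget.
#' @return list: `sequences` (named character, one transcript per gene),
#'   `tx2gene` (tibble `transcript_id`, `gene_id`), `planted` (tibble of
#'   realized sites with intervals).
#' @export
make_transcriptome <- function(cfg, asos = list(), seed = cfg$seed,
                               max_tries = 60L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  tx_ids <- sprintf("t%04d", seq_len(cfg$n_genes))
  plants <- cfg$planted_sites
  if (is.null(plants)) {
    plants <- tibble::tibble(aso_id = character(), gene_id = character(),
                             d = integer())
  }
  bad <- setdiff(plants$gene_id, gene_ids)
  if (length(bad) > 0L) {
    abort(paste0("Planted sites reference unknown genes: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  pats <- lapply(asos, as_aso_pattern)
  names(pats) <- vapply(pats, `[[`, "", "id")
  aso_seqs <- setNames(lapply(pats, function(p) reverse_complement(p$pattern)),
                       names(pats))
  d_guard <- max(cfg$d_eff, 1L)
  seqs <- character(cfg$n_genes)
  planted_rows <- list()
  for (gi in seq_len(cfg$n_genes)) {
    mine <- plants[plants$gene_id == gene_ids[gi], ]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      len <- sample(cfg$len_range[1]:cfg$len_range[2], 1L)
      tx <- random_dna(len)
      rows <- list()
      if (nrow(mine) > 0L) {
        failed <- FALSE
        for (pi in seq_len(nrow(mine))) {
          pl <- tryCatch(
            plant_site(tx, aso_seqs[[mine$aso_id[pi]]], mine$d[pi],
                       max_tries = 25L),
            error = function(e) NULL)
          if (is.null(pl)) { failed <- TRUE; break }
          tx <- pl$sequence
          rows[[pi]] <- tibble::tibble(aso_id = mine$aso_id[pi],
                                       gene_id = gene_ids[gi],
                                       transcript_id = tx_ids[gi],
                                       d = pl$d, start = pl$start,
                                       end = pl$end)
        }
        if (failed) next
      }
      # guard: every configured ASO must sit at its intended distance
      clean <- TRUE
      for (an in names(pats)) {
        want <- mine$d[mine$aso_id == an]
        got <- sg_distance_cpp(pats[[an]]$pattern, tx)
        if (length(want) > 0L) {
          if (got != min(want)) { clean <- FALSE; break }
        } else if (got <= d_guard) {
          clean <- FALSE; break
        }
      }
      if (!clean) next
      seqs[gi] <- tx
      planted_rows[[gi]] <- if (length(rows) > 0L) do.call(rbind, rows)
      ok <- TRUE
      break
    }
    if (!ok) {
      abort(sprintf(paste0("Could not generate a clean transcript for %s in ",
                           "%d tries; use longer transcripts or fewer ASOs."),
                    gene_ids[gi], max_tries),
            class = "gapmertox_rejection_error")
    }
  }
  planted <- do.call(rbind, planted_rows)
  if (is.null(planted)) {
    planted <- tibble::tibble(aso_id = character(), gene_id = character(),
                              transcript_id = character(), d = integer(),
                              start = integer(), end = integer())
  }
  list(sequences = setNames(seqs, tx_ids),
       tx2gene = tibble::tibble(transcript_id = tx_ids, gene_id = gene_ids),
       planted = planted)
}

#' Simulate an expression ratio table under the knockdown model
#'
#' Genes with a mapped distance at most `d_eff` are knocked down by
#' `knockdown_scale * delta0 * gamma^d` on the log2 scale; all genes
#' receive Gaussian log2 noise. Genes absent from the distance map get
#' pure noise.
#'
#' @param cfg a [sim_config()].
#' @param dist gene distance map (columns `gene_id`, `min_d`).
#' @param aso_id label for the output table.
#' @param genes full gene universe (character vector).
#' @param knockdown_scale multiplier on `delta0` for this ASO (default 1);
#'   scenario configs use it to encode modification-specific knockdown.
#' @param seed optional seed.
#' @return expression tibble: `aso_id`, `gene_id`, `ratio`,
#'   `control_intensity`.
#' @export
simulate_expression <- function(cfg, dist, aso_id, genes,
                                knockdown_scale = 1, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  d <- dist$min_d[match(genes, dist$gene_id)]
  effect <- ifelse(!is.na(d) & d <= cfg$d_eff,
                   -knockdown_scale * cfg$delta0 * cfg$gamma^ifelse(is.na(d), 0, d),
                   0)
  log2r <- effect + rnorm(length(genes), 0, cfg$sigma_expr)
  tibble::tibble(aso_id = aso_id, gene_id = genes, ratio = 2^log2r,
                 control_intensity = round(2^runif(length(genes), 6, 14), 1))
}

#' Simulate serum AST/ALT for a set of ASOs
#'
#' @param cfg a [sim_config()].
#' @param indices tibble with columns `aso_id`, `value` (off-target
#'   indices).
#' @param seed optional seed.
#' @return toxicity tibble: `aso_id`, `ast`, `alt` (U/l), `dose`,
#'   `n_animals`, `flags`.
#' @export
simulate_toxicity <- function(cfg, indices, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(indices)
  bi <- rep(0, n)
  if (!is.null(cfg$beta_indep)) {
    hit <- match(indices$aso_id, names(cfg$beta_indep))
    bi <- ifelse(is.na(hit), 0, cfg$beta_indep[hit])
  }
  mu <- cfg$alpha + cfg$beta_hyb * indices$value + bi
  tibble::tibble(aso_id = indices$aso_id,
                 ast = exp(mu + rnorm(n, 0, cfg$sigma_tox)),
                 alt = exp(mu + rnorm(n, 0, cfg$sigma_tox)),
                 dose = 20, n_animals = 4L, flags = "")
}
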