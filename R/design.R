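#' Configuration for random candidate design
#'
#' Candidate ASO sequences are drawn uniformly at random over ACGT (the
#' screening study drew random 14-mers), optionally constrained on GC
#' content and homopolymer runs, then pushed through the transcriptome
#' exclusion screen and a motif filter.
#'
#' @param k candidate length (default 14).
#' @param n_raw number of unique random candidates to draw.
#' @param seed integer RNG seed.
#' @param motif_list motifs used by the funnel (default TGC, TCC).
#' @param require_motif if `TRUE`, survivors must carry at least one motif
#'   occurrence.
#' @param screen_mode distance convention for the exclusion screen.
#' @param gc_bounds optional length-2 numeric, inclusive bounds on GC
#'   fraction.
#' @param max_homopolymer optional cap on the longest single-base run.
#' @return A list of class `design_config`.
#' @export
design_config <- function(k = 14L, n_raw = 100L, seed = 1L,
                          motif_list = c("TGC", "TCC"),
                          require_motif = FALSE,
                          screen_mode = c("edit", "mismatch_only"),
                          gc_bounds = NULL, max_homopolymer = NULL) {
  screen_mode <- match.arg(screen_mode)
  k <- as.integer(k); n_raw <- as.integer(n_raw)
  if (n_raw < 1L) abort("`n_raw` must be >= 1.")
  if (isTRUE(require_motif) && any(nchar(motif_list) > k)) {
    abort("`k` must be at least the longest required motif length.",
          class = "gapmertox_validation_error")
  }
  structure(list(k = k, n_raw = n_raw, seed = as.integer(seed),
                 motif_list = normalize_dna(motif_list),
                 require_motif = isTRUE(require_motif),
                 screen_mode = screen_mode, gc_bounds = gc_bounds,
                 max_homopolymer = max_homopolymer),
            class = "design_config")
}

gc_fraction <- function(seqs) {
  vapply(strsplit(seqs, "", fixed = TRUE),
         function(ch) mean(ch %in% c("G", "C")), numeric(1))
}

max_run <- function(seqs) {
  vapply(strsplit(seqs, "", fixed = TRUE),
         function(ch) max(rle(ch)$lengths), integer(1))
}

#' Draw unique random candidate sequences
#'
#' Deterministic for a fixed seed. Infeasible requests — more unique k-mers
#' than the alphabet allows, or constraints that cannot be satisfied within
#' a bounded number of batches — raise an error.
#'
#' @param cfg a [design_config()].
#' @return character vector of `n_raw` unique uppercase k-mers.
#' @export
generate_candidates <- function(cfg) {
  stopifnot(inherits(cfg, "design_config"))
  if (cfg$n_raw > 4^cfg$k) {
    abort(sprintf("Cannot draw %d unique %d-mers: only %.0f exist.",
                  cfg$n_raw, cfg$k, 4^cfg$k),
          class = "gapmertox_infeasible_error")
  }
  set.seed(cfg$seed)
  got <- character(0)
  tries <- 0L
  while (length(got) < cfg$n_raw) {
    tries <- tries + 1L
    if (tries > 200L) {
      abort("Candidate constraints look infeasible (retry budget exhausted).",
            class = "gapmertox_infeasible_error")
    }
    batch <- vapply(seq_len(cfg$n_raw), function(i)
      paste(sample(c("A", "C", "G", "T"), cfg$k, replace = TRUE),
            collapse = ""), character(1))
    if (!is.null(cfg$gc_bounds)) {
      gc <- gc_fraction(batch)
      batch <- batch[gc >= cfg$gc_bounds[1] & gc <= cfg$gc_bounds[2]]
    }
    if (!is.null(cfg$max_homopolymer)) {
      batch <- batch[max_run(batch) <= cfg$max_homopolymer]
    }
    got <- unique(c(got, batch))
  }
  got[seq_len(cfg$n_raw)]
}

#' Run the candidate selection funnel
#'
#' Stage 1 draws `n_raw` random candidates; stage 2 keeps those with no
#' complementary transcriptome region at d <= 1 (the exclusion screen);
#' stage 3 optionally keeps only motif-bearing sequences. Counts are
#' monotone non-increasing through the stages and every intermediate list
#' is kept so each count is reproducible.
#'
#' @param cfg a [design_config()].
#' @param transcriptome named character vector of transcripts.
#' @return A list of class `funnel_report`: `counts` (n_raw,
#'   n_screen_pass, n_survivors), `params`, `screen` (the
#'   [exclusion_screen()] table), `survivors` (tibble of surviving
#'   sequences with per-motif counts and `best_d`).
#' @export
design_funnel <- function(cfg, transcriptome) {
  stopifnot(inherits(cfg, "design_config"))
  raw <- generate_candidates(cfg)
  screen <- exclusion_screen(raw, transcriptome, mode = cfg$screen_mode)
  passing <- screen[screen$pass, ]
  mot <- t(vapply(passing$sequence, count_motifs,
                  integer(length(cfg$motif_list)),
                  motifs = cfg$motif_list))
  colnames(mot) <- cfg$motif_list
  surv <- cbind(passing[, c("candidate_id", "sequence", "best_d")],
                tibble::as_tibble(mot))
  if (cfg$require_motif) {
    surv <- surv[rowSums(mot) > 0L, ]
  }
  structure(list(
    counts = list(n_raw = length(raw),
                  n_screen_pass = nrow(passing),
                  n_survivors = nrow(surv)),
    params = unclass(cfg),
    screen = screen,
    survivors = tibble::as_tibble(surv)), class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat(sprintf("<funnel_report> raw %d -> screen-pass %d -> survivors %d\n",
              x$counts$n_raw, x$counts$n_screen_pass, x$counts$n_survivors))
  invisible(x)
}

#' Write a funnel report to disk
#'
#' Produces `funnel.json` (stage counts + parameters + seed),
#' `survivors.fasta`, and `survivors.tsv` (per-sequence motif counts).
#'
#' @param report a `funnel_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_funnel_report <- function(report, dir) {
  stopifnot(inherits(report, "funnel_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(
    list(counts = report$counts, params = report$params),
    file.path(dir, "funnel.json"), auto_unbox = TRUE, pretty = TRUE,
    null = "null")
  write_fasta_seqs(setNames(report$survivors$sequence,
                            report$survivors$candidate_id),
                   file.path(dir, "survivors.fasta"))
  readr::write_tsv(report$survivors, file.path(dir, "survivors.tsv"))
  invisible(dir)
}
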