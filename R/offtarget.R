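#' Semi-global edit distance of a short pattern against a text
#'
#' The complementarity measure "distance" (d) between an ASO and a
#' candidate region is the minimum total number of mismatches, insertions
#' and deletions over all alignments in which the pattern is consumed
#' end-to-end while both ends of the text are free — i.e. the minimum
#' Levenshtein distance between the pattern and any substring of the text.
#'
#' @param pattern non-empty DNA string (typically the reverse complement of
#'   an ASO).
#' @param text DNA string to scan (a transcript); may be empty, in which
#'   case the distance is the pattern length.
#' @return integer distance.
#' @examples
#' semi_global_distance("ACGT", "TTACGTTT")   # 0
#' semi_global_distance("ACGT", "TTAGGTTT")   # 1
#' @export
semi_global_distance <- function(pattern, text) {
  pattern <- normalize_dna(pattern)
  if (nchar(pattern) == 0L) {
    abort("Pattern must be non-empty.", class = "gapmertox_validation_error")
  }
  text <- normalize_dna(text)
  sg_distance_cpp(pattern, text)
}

#' Minimum mismatch count over all full-length windows (Hamming mode)
#'
#' Indel-free counterpart of [semi_global_distance()]; never smaller than
#' the edit-distance result on the same input. A text shorter than the
#' pattern scores the pattern length.
#'
#' @inheritParams semi_global_distance
#' @return integer mismatch count.
#' @export
mismatch_only_distance <- function(pattern, text) {
  pattern <- normalize_dna(pattern)
  if (nchar(pattern) == 0L) {
    abort("Pattern must be non-empty.", class = "gapmertox_validation_error")
  }
  hamming_min_cpp(pattern, normalize_dna(text))
}

as_aso_pattern <- function(aso) {
  if (inherits(aso, "gapmer_aso")) {
    list(id = aso$id, pattern = reverse_complement(aso$sequence))
  } else {
    seq <- normalize_dna(aso)
    id <- names(aso) %||% "aso"
    list(id = id, pattern = reverse_complement(seq))
  }
}

#' Scan one transcript for approximate complementary sites of an ASO
#'
#' The reverse complement of the ASO sequence is aligned semi-globally
#' along the transcript sense strand (ASO:RNA hybridization has a fixed
#' orientation, so only that strand is scanned). All sites with d below
#' the threshold are reported with their alignment decomposition;
#' overlapping shifted alignments of the same local region are merged,
#' keeping the lowest d, then the leftmost start, then the fewest indels.
#'
#' `n_ins` counts ASO bases opposite a gap in the transcript and `n_del`
#' transcript bases opposite a gap in the ASO, so for every hit
#' `end - start == pattern length - n_ins + n_del` and
#' `d == n_mismatch + n_ins + n_del`.
#'
#' @param aso a `gapmer_aso`, or a (possibly named) DNA string.
#' @param transcript transcript sequence (single DNA string).
#' @param d_max maximum distance to report (default 3).
#' @param transcript_id label for the output (default the name of
#'   `transcript`, else `"tx"`).
#' @return tibble of hits: `aso_id`, `transcript_id`, `start`, `end`
#'   (0-based half-open on the transcript), `d`, `n_mismatch`, `n_ins`,
#'   `n_del`, `aligned_query`, `aligned_target`.
#' @export
scan_transcript <- function(aso, transcript, d_max = 3L,
                            transcript_id = NULL) {
  p <- as_aso_pattern(aso)
  transcript_id <- transcript_id %||% names(transcript) %||% "tx"
  transcript <- normalize_dna(unname(transcript))
  if (d_max < 0L) abort("`d_max` must be >= 0.")
  hits <- sg_scan_cpp(p$pattern, transcript, as.integer(d_max))
  tibble::as_tibble(cbind(
    tibble::tibble(aso_id = rep(p$id, nrow(hits)),
                   transcript_id = rep(transcript_id, nrow(hits))),
    hits))
}

#' Distance class labels
#'
#' Pools distances of 3 or more into `d3plus`, matching the scatter-plot
#' grouping (d = 0 perfect complementarity, d = 1, d = 2, d >= 3).
#'
#' @param d integer vector of distances (NA allowed, mapped to `d3plus`).
#' @return factor with levels `d0`, `d1`, `d2`, `d3plus`.
#' @export
d_class <- function(d) {
  lab <- ifelse(is.na(d) | d >= 3L, "d3plus", paste0("d", d))
  factor(lab, levels = c("d0", "d1", "d2", "d3plus"))
}

#' Classify every gene of a transcriptome by minimal distance to an ASO
#'
#' Scans each transcript, takes the minimum d per gene across its
#' transcripts, and labels genes with the pooled distance classes used in
#' off-target scatter plots. Genes with no site at d <= `d_max` are absent
#' from the result (downstream they are treated as d >= 3).
#'
#' @param aso a `gapmer_aso` or a DNA string.
#' @param transcriptome named character vector of transcript sequences.
#' @param tx2gene tibble mapping `transcript_id` to `gene_id`; `NULL` uses
#'   the identity mapping. Transcripts without a mapping are an error.
#' @param d_max maximum distance to retain (default 3).
#' @return tibble (`gene_distance_map`): `aso_id`, `gene_id`, `min_d`,
#'   `class`.
#' @export
classify_offtargets <- function(aso, transcriptome, tx2gene = NULL,
                                d_max = 3L) {
  p <- as_aso_pattern(aso)
  ids <- names(transcriptome) %||% paste0("tx", seq_along(transcriptome))
  if (is.null(tx2gene)) {
    tx2gene <- tibble::tibble(transcript_id = ids, gene_id = ids)
  }
  missing <- setdiff(ids, tx2gene$transcript_id)
  if (length(missing) > 0L) {
    abort(paste0("Transcripts without gene mapping: ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "gapmertox_mapping_error")
  }
  if (length(transcriptome) == 0L) {
    return(tibble::tibble(aso_id = character(), gene_id = character(),
                          min_d = integer(),
                          class = d_class(integer())))
  }
  d <- vapply(transcriptome, function(tx)
    sg_distance_cpp(p$pattern, normalize_dna(tx)), integer(1))
  tab <- tibble::tibble(transcript_id = ids, d = d)
  tab <- dplyr::inner_join(tab, tx2gene, by = "transcript_id")
  out <- dplyr::summarise(dplyr::group_by(tab, .data$gene_id),
                          min_d = min(.data$d), .groups = "drop")
  out <- out[out$min_d <= d_max, ]
  tibble::tibble(aso_id = rep(p$id, nrow(out)), gene_id = out$gene_id,
                 min_d = as.integer(out$min_d), class = d_class(out$min_d))
}

#' Transcriptome exclusion screen for candidate ASO sequences
#'
#' A candidate passes when no complementary region with a perfect match or
#' a single edit (d <= 1) exists in any transcript. The default metric is
#' full edit distance (mismatches + indels); `mode = "mismatch_only"`
#' restricts edits to substitutions, since short-sequence search services
#' offer both conventions. The best distance found is reported for audit.
#'
#' @param candidates character vector of candidate sequences (all the same
#'   length; names used as ids when present).
#' @param transcriptome named character vector of transcripts; an empty
#'   transcriptome passes every candidate (`best_d` = NA).
#' @param mode `"edit"` (default) or `"mismatch_only"`.
#' @param max_d pass threshold: fail iff `best_d <= max_d` (default 1).
#' @return tibble: `candidate_id`, `sequence`, `best_d`, `pass`.
#' @export
exclusion_screen <- function(candidates, transcriptome,
                             mode = c("edit", "mismatch_only"),
                             max_d = 1L) {
  mode <- match.arg(mode)
  candidates <- normalize_dna(candidates)
  if (length(unique(nchar(candidates))) > 1L) {
    abort("All candidates must have the same length.",
          class = "gapmertox_validation_error")
  }
  ids <- names(candidates) %||% paste0("cand", seq_along(candidates))
  txs <- vapply(transcriptome, normalize_dna, character(1), USE.NAMES = FALSE)
  distfun <- if (mode == "edit") sg_distance_cpp else hamming_min_cpp
  best <- vapply(candidates, function(cand) {
    pat <- reverse_complement(cand)
    if (length(txs) == 0L) return(NA_integer_)
    min(vapply(txs, function(tx) distfun(pat, tx), integer(1)))
  }, integer(1), USE.NAMES = FALSE)
  tibble::tibble(candidate_id = ids, sequence = unname(candidates),
                 best_d = best,
                 pass = is.na(best) | best > max_d)
}
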