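#' Read toxicity and Tm tables
#'
#' Toxicity TSV columns: `aso_id`, `ast`, `alt`, optional `dose` (mg/kg,
#' default 20), `n_animals`, `flags`. Tm TSV columns: `aso_id`, `tm` (deg
#' C), `source` (`measured`/`predicted`), optional `parent_id`. Tm values
#' outside 0-120 deg C trigger a plausibility warning.
#'
#' @param path TSV file.
#' @return tibble.
#' @export
read_tox_tsv <- function(path) {
  tab <- tibble::as_tibble(readr::read_tsv(path, show_col_types = FALSE))
  if (!all(c("aso_id", "ast", "alt") %in% names(tab))) {
    abort("Toxicity table needs columns `aso_id`, `ast`, `alt`.",
          class = "gapmertox_validation_error")
  }
  if (any(tab$ast < 0 | tab$alt < 0, na.rm = TRUE)) {
    abort("AST/ALT must be >= 0.", class = "gapmertox_validation_error")
  }
  if (!"dose" %in% names(tab)) tab$dose <- 20
  tab
}

#' @rdname read_tox_tsv
#' @export
read_tm_tsv <- function(path) {
  tab <- tibble::as_tibble(readr::read_tsv(path, show_col_types = FALSE))
  if (!all(c("aso_id", "tm") %in% names(tab))) {
    abort("Tm table needs columns `aso_id`, `tm`.",
          class = "gapmertox_validation_error")
  }
  if (any(tab$tm < 0 | tab$tm > 120, na.rm = TRUE)) {
    warn("Tm values outside the physically plausible 0-120 degC range.")
  }
  tab
}

#' Hepatotoxicity call from serum aminotransferases
#'
#' An ASO counts as hepatotoxic when serum AST and ALT both exceed the
#' threshold (default 100 U/l, strict inequality) — the conjunctive
#' reading of an "AST/ALT > 100 U/l" rule, which every screening-positive
#' ASO satisfies on both markers. `rule = "or"` gives the disjunctive
#' variant for sensitivity analyses.
#'
#' @param ast,alt numeric vectors (U/l), element-wise paired.
#' @param threshold U/l cutoff (default 100).
#' @param rule `"and"` (default) or `"or"`.
#' @return logical vector.
#' @examples
#' classify_hepatotoxic(9437, 15602)  # TRUE
#' classify_hepatotoxic(100, 100)     # FALSE (strict)
#' @export
classify_hepatotoxic <- function(ast, alt, threshold = 100,
                                 rule = c("and", "or")) {
  rule <- match.arg(rule)
  if (rule == "and") ast > threshold & alt > threshold
  else ast > threshold | alt > threshold
}

#' Melting-temperature shift of a modified ASO
#'
#' `modified - parent`, in deg C; negative values mean the modification
#' destabilized the ASO:RNA duplex.
#'
#' @param modified_tm,parent_tm numeric Tm values (deg C). `parent_tm`
#'   must not be missing.
#' @return numeric delta Tm.
#' @export
delta_tm <- function(modified_tm, parent_tm) {
  if (any(is.na(parent_tm))) {
    abort("Missing parent Tm.", class = "gapmertox_validation_error")
  }
  modified_tm - parent_tm
}

#' Label Tm shifts across a table of modified ASOs
#'
#' Each modified record is resolved against its parent's Tm and labeled
#' `large_drop` when delta Tm < -`drop_cutoff` (default 5 deg C, the band
#' used to call duplex-destabilizing chemistries), `equivalent` when
#' |delta Tm| <= `equiv_band` (default 2 deg C), and `intermediate`
#' otherwise. Records whose `parent_id` does not resolve within the table
#' are an error listing the orphans.
#'
#' @param tm_table tibble with columns `aso_id`, `tm`, `parent_id` (NA for
#'   parents, which are passed through unlabeled).
#' @param drop_cutoff,equiv_band deg C (defaults 5 and 2).
#' @return list: `records` (modified rows with `delta_tm` and `label`),
#'   `counts` (named tally over labels).
#' @export
flag_tm_drops <- function(tm_table, drop_cutoff = 5, equiv_band = 2) {
  mod <- tm_table[!is.na(tm_table$parent_id), ]
  parents <- tm_table[is.na(tm_table$parent_id), ]
  orphan <- setdiff(mod$parent_id, parents$aso_id)
  if (length(orphan) > 0L) {
    abort(paste0("Modified records with unresolved parents: ",
                 paste(orphan, collapse = ", ")),
          class = "gapmertox_validation_error")
  }
  dtm <- delta_tm(mod$tm, parents$tm[match(mod$parent_id, parents$aso_id)])
  label <- ifelse(dtm < -drop_cutoff, "large_drop",
                  ifelse(abs(dtm) <= equiv_band, "equivalent",
                         "intermediate"))
  records <- tibble::tibble(aso_id = mod$aso_id, parent_id = mod$parent_id,
                            tm = mod$tm, delta_tm = dtm, label = label)
  counts <- c(large_drop = sum(label == "large_drop"),
              equivalent = sum(label == "equivalent"),
              intermediate = sum(label == "intermediate"))
  list(records = records, counts = counts)
}

#' Correlation between per-ASO quantities
#'
#' Thin wrapper over [stats::cor.test()] used for the toxicity-vs-Tm and
#' toxicity-vs-index comparisons. AST/ALT span two orders of magnitude, so
#' `log_y = TRUE` (natural log of y) is the conventional scale for serum
#' markers.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @param log_y log-transform y before correlating.
#' @return list: `r`, `p`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      log_y = FALSE) {
  method <- match.arg(method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) {
    abort("Need at least 3 complete pairs.",
          class = "gapmertox_validation_error")
  }
  if (log_y) y <- log(y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Correlation is undefined for a constant vector.",
          class = "gapmertox_undefined_correlation_error")
  }
  ct <- suppressWarnings(cor.test(x, y, method = method))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = method)
}
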