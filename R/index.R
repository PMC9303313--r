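#' Read an expression ratio table
#'
#' Columns `gene_id`, `ratio` (expression treated/control, strictly
#' positive) and optionally `control_intensity`; an `aso_id` column is kept
#' when present.
#'
#' @param path TSV file.
#' @return tibble.
#' @export
read_expression_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  validate_expression(tab)
  tibble::as_tibble(tab)
}

validate_expression <- function(expr) {
  if (!all(c("gene_id", "ratio") %in% names(expr))) {
    abort("Expression table needs columns `gene_id` and `ratio`.",
          class = "gapmertox_validation_error")
  }
  if (any(!is.finite(expr$ratio)) || any(expr$ratio <= 0)) {
    abort("Expression ratios must be finite and > 0.",
          class = "gapmertox_validation_error")
  }
  if (anyDuplicated(expr$gene_id)) {
    abort("Duplicate gene_id in expression table.",
          class = "gapmertox_validation_error")
  }
  invisible(expr)
}

#' Off-target down-regulation index
#'
#' Quantifies the breadth of hybridization-dependent knockdown for one ASO
#' treatment: over the genes whose minimal complementarity distance is at
#' most `d_cutoff` (default 2) and — with the default `direction = "down"`
#' — whose expression ratio is strictly below 1, the index sums the
#' absolute logarithm of the expression ratio. Ratios of exactly 1
#' contribute nothing either way, and genes absent from the distance map
#' count as d >= 3, so they are excluded at the default cutoff.
#'
#' The logarithm base (default 2) only rescales the index; ratios of two
#' indices computed in the same base, as in [index_ratio()], are
#' base-invariant.
#'
#' @param expr expression table (`gene_id`, `ratio`); see
#'   [read_expression_tsv()].
#' @param dist a gene distance map from [classify_offtargets()] (columns
#'   `gene_id`, `min_d`; an `aso_id` column, when present in both inputs,
#'   must agree).
#' @param d_cutoff maximal distance class included (default 2).
#' @param direction `"down"` (default) restricts to down-regulated genes;
#'   `"both"` sums over all qualifying genes.
#' @param log_base base of the logarithm (default 2).
#' @param missing_gene what to do when a gene in `dist` has no expression
#'   row: `"skip"` (default, with a warning) or `"strict"` (error).
#' @return list of class `offtarget_index`: `aso_id`, `d_cutoff`,
#'   `direction`, `value`, `n_genes_used`.
#' @examples
#' expr <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g4"),
#'                        ratio = c(0.5, 0.8, 0.25, 1.5))
#' dist <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g4"),
#'                        min_d = c(0L, 2L, 3L, 1L))
#' compute_offtarget_index(expr, dist)$value            # 1.3219...
#' compute_offtarget_index(expr, dist, d_cutoff = 3)$value  # 3.3219...
#' @export
compute_offtarget_index <- function(expr, dist, d_cutoff = 2L,
                                    direction = c("down", "both"),
                                    log_base = 2,
                                    missing_gene = c("skip", "strict")) {
  direction <- match.arg(direction)
  missing_gene <- match.arg(missing_gene)
  validate_expression(expr)
  expr_aso <- if ("aso_id" %in% names(expr)) expr$aso_id[1] else NULL
  dist_aso <- if ("aso_id" %in% names(dist)) dist$aso_id[1] else NULL
  aso_id <- expr_aso %||% dist_aso %||% NA_character_
  if (!is.null(expr_aso) && !is.null(dist_aso) &&
      !is.na(expr_aso) && !is.na(dist_aso) && expr_aso != dist_aso) {
    abort(sprintf("Expression table is for '%s' but distance map for '%s'.",
                  expr_aso, dist_aso),
          class = "gapmertox_validation_error")
  }
  qual <- dist[dist$min_d <= d_cutoff, ]
  miss <- setdiff(qual$gene_id, expr$gene_id)
  if (length(miss) > 0L) {
    if (missing_gene == "strict") {
      abort(paste0("Genes in distance map missing from expression table: ",
                   paste(head(miss, 5), collapse = ", ")),
            class = "gapmertox_missing_gene_error")
    }
    warn(sprintf("%d gene(s) in the distance map have no expression row; skipped.",
                 length(miss)))
    qual <- qual[!qual$gene_id %in% miss, ]
  }
  rows <- expr[match(qual$gene_id, expr$gene_id), ]
  if (direction == "down") rows <- rows[rows$ratio < 1, ]
  value <- sum(abs(log(rows$ratio, base = log_base)))
  structure(list(aso_id = aso_id, d_cutoff = as.integer(d_cutoff),
                 direction = direction, value = value,
                 n_genes_used = nrow(rows)),
            class = "offtarget_index")
}

#' @export
print.offtarget_index <- function(x, ...) {
  cat(sprintf("<offtarget_index> %s: %.4f over %d genes (d <= %d, %s)\n",
              x$aso_id, x$value, x$n_genes_used, x$d_cutoff, x$direction))
  invisible(x)
}

#' Modified-vs-parent index ratio, in percent
#'
#' The comparison used to ask whether a nucleobase modification changed an
#' ASO's off-target knockdown breadth: 100 x modified / parent. Both
#' indices must have been computed with the same cutoff and direction; the
#' result does not depend on the logarithm base.
#'
#' @param modified,parent `offtarget_index` objects.
#' @return percentage (numeric scalar).
#' @export
index_ratio <- function(modified, parent) {
  stopifnot(inherits(modified, "offtarget_index"),
            inherits(parent, "offtarget_index"))
  if (modified$d_cutoff != parent$d_cutoff ||
      modified$direction != parent$direction) {
    abort("Indices were computed with different cutoff/direction settings.",
          class = "gapmertox_validation_error")
  }
  if (parent$value == 0) {
    abort("Parent index is 0; the ratio is undefined.",
          class = "gapmertox_undefined_ratio_error")
  }
  100 * modified$value / parent$value
}

#' Per-distance-class expression summary
#'
#' The numeric backing of the off-target scatter plot: genes are grouped
#' by pooled distance class (genes absent from the distance map fall in
#' `d3plus`) and each class is summarized by its size, mean and median
#' log2 ratio, and fraction of down-regulated genes.
#'
#' @inheritParams compute_offtarget_index
#' @return tibble with one row per class `d0`, `d1`, `d2`, `d3plus`:
#'   `n`, `mean_log2_ratio`, `median_log2_ratio`, `frac_down` (NA for
#'   empty classes).
#' @export
dclass_scatter_summary <- function(expr, dist) {
  validate_expression(expr)
  d <- dist$min_d[match(expr$gene_id, dist$gene_id)]
  tab <- tibble::tibble(class = d_class(d),
                        log2_ratio = log2(expr$ratio))
  out <- dplyr::summarise(
    dplyr::group_by(tab, .data$class, .drop = FALSE),
    n = dplyr::n(),
    mean_log2_ratio = mean(.data$log2_ratio),
    median_log2_ratio = median(.data$log2_ratio),
    frac_down = mean(.data$log2_ratio < 0),
    .groups = "drop")
  out
}
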