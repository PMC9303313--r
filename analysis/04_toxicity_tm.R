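#!/usr/bin/env Rscript
# Stage 4: hepatotoxicity calls, Tm-shift bookkeeping, and the two
# correlation questions — does toxicity track the off-target index, and
# does it track the Tm shift? In the paper-like scenario neither should:
# toxicity is driven by the hybridization-independent per-ASO term.

suppressPackageStartupMessages(library(gapmertox))

bdir <- "results/bundle_paper_like"
if (!dir.exists(bdir)) stop("run analysis/02_offtarget_classes.R first")
if (!file.exists("results/offtarget_index.tsv"))
  stop("run analysis/03_expression_index.R first")

tox <- read_tox_tsv(file.path(bdir, "tox.tsv"))
tm <- read_tm_tsv(file.path(bdir, "tm.tsv"))
idx <- readr::read_tsv("results/offtarget_index.tsv", show_col_types = FALSE)

tox$hepatotoxic <- classify_hepatotoxic(tox$ast, tox$alt, threshold = 100)
cat("serum chemistry and calls:\n")
print(as.data.frame(tox[, c("aso_id", "ast", "alt", "hepatotoxic")]),
      digits = 4)

flags <- flag_tm_drops(tm)
cat("\nTm shifts vs parent:\n")
print(as.data.frame(flags$records), digits = 3)
cat(sprintf("large drops (delta Tm < -5 degC): %d; equivalent (within 2): %d\n",
            flags$counts["large_drop"], flags$counts["equivalent"]))

# with only 4 ASOs these are descriptive, not inferential; the scenario
# tests at n = 100 live in the package's test suite
ord <- match(tox$aso_id, idx$aso_id)
r_idx <- suppressWarnings(correlate(idx$index[ord], tox$ast, log_y = TRUE))
cat(sprintf("\nindex vs log AST: r = %.3f (n = %d)\n", r_idx$r, r_idx$n))
tm_ord <- match(tox$aso_id, tm$aso_id)
r_tm <- suppressWarnings(correlate(tm$tm[tm_ord], tox$ast, log_y = TRUE))
cat(sprintf("Tm vs log AST:    r = %.3f (n = %d)\n", r_tm$r, r_tm$n))

report <- merge(merge(tox, flags$records[, c("aso_id", "delta_tm", "label")],
                      by = "aso_id", all.x = TRUE),
                idx[, c("aso_id", "index", "ratio_vs_parent_pct")],
                by = "aso_id")
readr::write_tsv(report, "results/toxicity_report.tsv")
cat("wrote results/toxicity_report.tsv\n")
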