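#!/usr/bin/env Rscript
# Stage 3: off-target down-regulation index for the parent ASO and its
# nucleobase-modified analogues, from the bundle files written by
# 02_offtarget_classes.R (re-read from disk through the package's own
# readers to exercise the file contract).

suppressPackageStartupMessages(library(gapmertox))

bdir <- "results/bundle_paper_like"
if (!dir.exists(bdir)) stop("run analysis/02_offtarget_classes.R first")

dist <- readr::read_tsv(file.path(bdir, "distances.tsv"),
                        show_col_types = FALSE)
asos <- names(read_gapmer_tsv(file.path(bdir, "asos.tsv")))

rows <- lapply(asos, function(a) {
  expr <- read_expression_tsv(file.path(bdir, paste0("expression_", a, ".tsv")))
  idx <- compute_offtarget_index(expr, dist[dist$aso_id == a, ],
                                 d_cutoff = 2, direction = "down")
  tibble::tibble(aso_id = a, index = idx$value,
                 n_genes_used = idx$n_genes_used)
})
idx_tab <- do.call(rbind, rows)

parent <- idx_tab$index[idx_tab$aso_id == "TS1"]
idx_tab$ratio_vs_parent_pct <- 100 * idx_tab$index / parent
print(as.data.frame(idx_tab), digits = 4)
cat(sprintf(paste0("modified ASOs retain %.0f-%.0f%% of the parent's ",
                   "off-target down-regulation index\n"),
            min(idx_tab$ratio_vs_parent_pct[-1]),
            max(idx_tab$ratio_vs_parent_pct[-1])))

readr::write_tsv(idx_tab, "results/offtarget_index.tsv")
cat("wrote results/offtarget_index.tsv\n")
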