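#!/usr/bin/env Rscript
# Stage 1: random 14-mer candidate design and the transcriptome exclusion
# funnel. A synthetic transcriptome (no planted complementarity) stands in
# for the mRNA database; candidates with any complementary region at
# d <= 1 are excluded, then motif-bearing sequences are kept, mirroring a
# hepatotoxicity-motif-enriched selection.

suppressPackageStartupMessages(library(gapmertox))

dir.create("results", showWarnings = FALSE)

scfg <- sim_config(seed = 101, n_genes = 150, len_range = c(300, 600))
txome <- make_transcriptome(scfg)
cat(sprintf("transcriptome: %d transcripts, %d nt total\n",
            length(txome$sequences), sum(nchar(txome$sequences))))

cfg <- design_config(k = 14, n_raw = 2000, seed = 101,
                     motif_list = c("TGC", "TCC"), require_motif = TRUE)
funnel <- design_funnel(cfg, txome$sequences)
print(funnel)
cat(sprintf("screen removed %d candidates (d <= 1 complement present);\n",
            funnel$counts$n_raw - funnel$counts$n_screen_pass))
cat(sprintf("motif requirement removed %d more; %d survivors carry TGC/TCC.\n",
            funnel$counts$n_screen_pass - funnel$counts$n_survivors,
            funnel$counts$n_survivors))

write_funnel_report(funnel, "results/funnel")
cat("wrote results/funnel/{funnel.json,survivors.fasta,survivors.tsv}\n")
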