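#!/usr/bin/env Rscript
# Stage 6: chromosome-level differential-expression enrichment — per
# chromosome up/down tests, the X-vs-autosome Fisher contrast, a
# permutation null, and the zero-in-fertile gene summary.
suppressMessages(library(sterileX))

data_dir <- "results/data"
out <- "results/expression"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

de <- read_tsv(file.path(data_dir, "de_table.tsv"))

ud <- per_chromosome_updown_test(de)
perm <- permutation_enrichment(de, n_perm = 999, seed = 1)
tab <- merge(ud, perm, by = "chrom")
write_tsv(tab[order(tab$chrom), ], file.path(out, "chromosome_tests.tsv"))
sig_up <- tab$chrom[tab$direction == "up" & !is.na(tab$p_chisq) &
                      tab$p_chisq < 0.05]
message("up-enriched chromosomes (chi-squared p < 0.05): ",
        paste(sig_up, collapse = ", "))

ct <- x_autosome_contrast(de)
write_tsv(data.frame(x_up = ct$table[1, 1], x_not_up = ct$table[1, 2],
                     autosome_up = ct$table[2, 1],
                     autosome_not_up = ct$table[2, 2],
                     odds_ratio = ct$odds_ratio, fisher_p = ct$p),
          file.path(out, "x_autosome_contrast.tsv"))
message(sprintf("X upregulation: %d/%d genes (%.0f%%); Fisher p = %.2e",
                ct$table[1, 1], sum(ct$table[1, ]),
                100 * ct$table[1, 1] / sum(ct$table[1, ]), ct$p))

zf <- zero_in_fertile_summary(de)
write_tsv(data.frame(gene = zf$genes), file.path(out,
                                                 "zero_in_fertile_genes.tsv"))
message(sprintf(paste0("%d up-genes unexpressed in fertile testes: mean ",
                       "|lfc| %.2f vs %.2f (Student t = %.2f, p = %.2e)"),
                zf$n, zf$mean_lfc_zero_fertile, zf$mean_lfc_other_up,
                zf$t, zf$p))
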