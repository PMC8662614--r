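#!/usr/bin/env Rscript
# Stage 7: X-linked ancestry fine-mapping — per-marker association in the
# backcross cohort and the critical-interval scan, plus the GWAS
# significance-threshold transform.
suppressMessages(library(sterileX))

data_dir <- "results/data"
out <- "results/finemap"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

coh <- list(genotypes = read_tsv(file.path(data_dir,
                                           "cohort_genotypes.tsv")),
            phenotypes = read_tsv(file.path(data_dir,
                                            "cohort_phenotypes.tsv")))

assoc <- marker_association(coh)
write_tsv(assoc, file.path(out, "marker_association.tsv"))
message("peak marker concordance = ", round(max(assoc$concordance), 3))

ci <- scan_critical_interval(coh)
write_tsv(data.frame(start = ci$start, end = ci$end,
                     length_kb = ci$length_bp / 1000,
                     markers = paste(ci$markers, collapse = ","),
                     sterile_J = ci$sterile_J,
                     sterile_total = ci$sterile_total,
                     fertile_D = ci$fertile_D,
                     fertile_total = ci$fertile_total,
                     fisher_p = ci$fisher_p),
          file.path(out, "critical_interval.tsv"))
message(sprintf(paste0("critical interval %.2f-%.2f Mb (%d kb): %d/%d ",
                       "sterile J, %d/%d fertile D, Fisher p = %.2e"),
                ci$start / 1e6, ci$end / 1e6, ci$length_bp / 1000,
                ci$sterile_J, ci$sterile_total, ci$fertile_D,
                ci$fertile_total, ci$fisher_p))

# -log10 transform of the per-marker exact p values against the
# genome-wide threshold
fg <- flag_gwas(assoc$p, marker = assoc$marker, position = assoc$position)
write_tsv(fg, file.path(out, "gwas_flags.tsv"))
message(sum(fg$pass), " markers exceed -log10 p = ",
        round(-log10(5e-5), 2))
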