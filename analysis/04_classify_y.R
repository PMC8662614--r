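#!/usr/bin/env Rscript
# Stage 4: classify assembly contigs as Y-linked from depletion of female
# read coverage, calibrating the cutoff on seed contigs of known Y
# homology and checking the bimodal fraction histogram.
suppressMessages(library(sterileX))

data_dir <- "results/data"
out <- "results/y_classifier"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- read_fasta(file.path(data_dir, "genome.fa"))
lens <- setNames(Biostrings::width(genome), names(genome))
track <- read_depth_table(file.path(data_dir, "female_on_male.bedgraph"),
                          "bedgraph", contig_lengths = lens)

profiles <- coverage_profile(track)
write_tsv(profiles, file.path(out, "coverage_profiles.tsv"))

dc <- derive_cutoff(profiles, seed_contigs = "Y1", margin = 0.25)
write_tsv(dc$histogram, file.path(out, "fraction_histogram.tsv"))
message("seed mean fraction = ", round(dc$seed_mean, 3),
        "; cutoff = ", round(dc$cutoff, 3))

cls <- classify_contigs(profiles, dc$cutoff)
write_tsv(cls, file.path(out, "classification.tsv"))
truth_y <- grep("^Y", names(lens), value = TRUE)
called <- cls$contig[cls$call == "Y-candidate"]
message("Y-candidates: ", paste(called, collapse = ", "),
        " (truth: ", paste(truth_y, collapse = ", "), ")")
message("precision = ", mean(called %in% truth_y),
        ", recall = ", mean(truth_y %in% called))
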