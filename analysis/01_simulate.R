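#!/usr/bin/env Rscript
# Stage 1: generate every input the downstream analyses consume, at desk
# scale (locus lengths x0.1), with truth annotations alongside.
suppressMessages(library(sterileX))

seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

locus <- locus_spec(scale = 0.1)
genome_spec <- sexed_genome_spec(scale = 0.1)
g <- build_genome(locus, genome_spec, seed = seed)
write_fasta(g$seqs, file.path(out, "genome.fa"))
write_bed(g$features, file.path(out, "truth_features.bed"))
message("genome: ", length(g$seqs), " contigs, ",
        sum(contig_lengths(g)), " bp; ", nrow(g$features),
        " truth features")

# sexed depth tracks over the unmodified assembly (for the Y classifier)
male_lens <- contig_lengths(g)
tr_female <- simulate_depth(male_lens, sex = "female", mean_depth = 30,
                            seed = seed)
write_depth_table(tr_female, file.path(out, "female_on_male.bedgraph"),
                  "bedgraph")

# methylation call tables: 4 fertile vs 2 sterile whole-testis samples plus
# an unmethylated lambda spike-in
sites <- rbind(methylation_sites(800, contig = "X", start = 4000,
                                 spacing = 11),
               methylation_sites(1200, contig = "lambda", spacing = 4))
msim <- simulate_methylation_samples(sites, methyl_sim_spec(),
                                     n_fertile = 4, n_sterile = 2,
                                     seed = seed)
for (id in names(msim$samples))
  write_tsv(msim$samples[[id]], file.path(out, paste0("meth_", id, ".tsv")))
write_tsv(data.frame(sample = names(msim$groups),
                     group = unname(msim$groups)),
          file.path(out, "meth_groups.tsv"))
message("methylation: ", length(msim$samples), " samples, ",
        nrow(sites), " sites")

# backcross cohort (23 fertile / 16 sterile, 27 ancestry-informative
# markers) and a DE table with X-biased upregulation
coh <- simulate_cohort(seed = seed)
write_tsv(coh$genotypes, file.path(out, "cohort_genotypes.tsv"))
write_tsv(coh$phenotypes, file.path(out, "cohort_phenotypes.tsv"))
de <- simulate_de_table(seed = seed)
write_tsv(de, file.path(out, "de_table.tsv"))
message("cohort: ", nrow(coh$phenotypes), " individuals; DE table: ",
        nrow(de), " genes")
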