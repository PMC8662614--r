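#!/usr/bin/env Rscript
# Stage 2: annotate the compound macrosatellite on the simulated X — CTCF
# motif scan (max mismatch 13), array/spacer segmentation, unit extraction,
# CpG islands, p-distances and a bootstrapped NJ tree of the repeat units.
suppressMessages(library(sterileX))

data_dir <- "results/data"
out <- "results/repeats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- read_fasta(file.path(data_dir, "genome.fa"))
truth <- read_bed(file.path(data_dir, "truth_features.bed"))

hits <- scan_motif(genome[["X"]], ctcf_motif(), max_mismatch = 13,
                   contig = "X")
write_bed(data.frame(contig = hits$contig, start = hits$start,
                     end = hits$end,
                     name = sprintf("CTCF_mm%d", hits$mismatches),
                     score = hits$mismatches, strand = hits$strand),
          file.path(out, "ctcf_hits.bed"))
message(nrow(hits), " CTCF motif hits on the X")

anchor <- as.list(truth[truth$name == "anchor_gene", c("start", "end")])
arch <- segment_macrosatellite(hits, anchor, segment_params(scale = 0.1))
units <- do.call(rbind, lapply(arch$arrays, function(a)
  data.frame(contig = "X", start = a$units$start, end = a$units$end,
             name = a$units$name, score = ".", strand = "+")))
write_bed(units, file.path(out, "repeat_units.bed"))
message("architecture: ", nrow(arch$arrays$RA$units), " RA units (",
        arch$arrays$RA$signature, "), ", nrow(arch$arrays$RB$units),
        " RB units (", arch$arrays$RB$signature, "), spacer ",
        arch$spacer["end"] - arch$spacer["start"], " bp")

# truth comparison
tru_units <- truth[grepl("^R[AB]-[0-9]+$", truth$name), ]
exact <- all(sort(units$start) == sort(tru_units$start)) &&
  all(sort(units$end) == sort(tru_units$end))
message("unit boundaries equal truth: ", exact)

dots <- self_dotplot(genome[["X"]], word_size = 16)
write_tsv(dots, file.path(out, "self_dotplot.tsv"))

islands <- detect_cpg_islands(as.character(genome[["X"]]), min_len = 100)
if (nrow(islands))
  write_bed(data.frame(contig = "X", start = islands$start,
                       end = islands$end,
                       name = sprintf("CpG_%d", seq_len(nrow(islands)))),
            file.path(out, "cpg_islands.bed"))
message(nrow(islands), " CpG islands on the X")

aln <- extract_unit_alignment(genome, arch)
dm <- pairwise_p_distance(aln)
write_tsv(cbind(data.frame(unit = dm$labels), as.data.frame(dm$matrix)),
          file.path(out, "p_distance_matrix.tsv"))
gs <- group_distance_summary(dm)
write_tsv(data.frame(group = c(names(gs$within), "between"),
                     mean_p_distance = c(unname(gs$within), gs$between)),
          file.path(out, "group_distances.tsv"))
message("mean p-distances: within RA = ", round(gs$within["RA"], 3),
        ", within RB = ", round(gs$within["RB"], 3),
        ", between = ", round(gs$between, 3))

nj <- build_nj_tree(dm, bootstrap = list(replicates = 200, seed = 1,
                                         alignment = aln))
write_newick(nj$tree, file.path(out, "repeat_units_nj.nwk"))
message("NJ tree written; bootstrap support range ",
        paste(range(nj$tree$node.label), collapse = "-"))
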