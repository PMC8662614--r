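#!/usr/bin/env Rscript
# Stage 5: RRBS analysis — lambda spike-in conversion rates, uniting with
# the 10x/99.9th-percentile coverage filter, PCA, sliding-window t-tests
# over the repeat region and region-level group tests.
suppressMessages(library(sterileX))

data_dir <- "results/data"
out <- "results/methylation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

groups_tab <- read_tsv(file.path(data_dir, "meth_groups.tsv"))
groups <- setNames(groups_tab$group, groups_tab$sample)
samples <- lapply(groups_tab$sample, function(id)
  read_tsv(file.path(data_dir, paste0("meth_", id, ".tsv"))))
names(samples) <- groups_tab$sample

conv <- do.call(rbind, lapply(names(samples), function(id) {
  est <- estimate_conversion(samples[[id]])
  data.frame(sample = id, conversion = est$conversion,
             n_lambda_sites = est$n_sites)
}))
write_tsv(conv, file.path(out, "conversion_rates.tsv"))
message("bisulfite conversion: ",
        paste(sprintf("%s=%.4f", conv$sample, conv$conversion),
              collapse = ", "))

mat <- unite_and_filter(samples, min_depth = 10, upper_quantile = 0.999)
message("united matrix: ", nrow(mat$sites), " sites x ",
        length(mat$samples), " samples")

pca <- pca_mf(mat)
write_tsv(cbind(data.frame(sample = rownames(pca$scores),
                           group = unname(groups[rownames(pca$scores)])),
                as.data.frame(pca$scores[, 1:3])),
          file.path(out, "pca_scores.tsv"))
message("PC1 explains ", round(100 * pca$explained_variance[1], 1),
        "% of MF variance")

# the repeat region on the X (everything between anchor and control)
truth <- read_bed(file.path(data_dir, "truth_features.bed"))
region <- list(contig = "X",
               start = truth$start[truth$name == "RA"],
               end = truth$end[truth$name == "RB"])
sw <- sliding_window_tests(mat, groups, window_size = 20, step = 10,
                           region = region)
write_tsv(sw$windows, file.path(out, "window_tests.tsv"))
write_tsv(sw$per_cytosine, file.path(out, "per_cytosine_tests.tsv"))
message(nrow(sw$windows), " windows, ",
        sum(sw$windows$significant), " with mean p <= 0.05")

for (lab in c("RA", "RB")) {
  reg <- list(contig = "X", start = truth$start[truth$name == lab],
              end = truth$end[truth$name == lab])
  rg <- region_group_test(mat, reg, groups)
  message(sprintf("%s region: t = %.2f, df = %.2f, p = %.4f", lab,
                  rg$t, rg$df, rg$p))
  write_tsv(data.frame(region = lab, t = rg$t, df = rg$df, p = rg$p,
                       n_sites = rg$n_sites),
            file.path(out, paste0("region_test_", lab, ".tsv")))
}

# smoothed per-group MF track over the region (trailing moving average)
ord <- order(sw$per_cytosine$pos)
mf_cols <- grep("^mean_", names(sw$per_cytosine), value = TRUE)[1:2]
smoothed <- data.frame(pos = sw$per_cytosine$pos[ord])
for (cl in mf_cols)
  smoothed[[paste0(cl, "_ma20")]] <-
  moving_average(sw$per_cytosine[[cl]][ord], 20)
write_tsv(smoothed, file.path(out, "moving_averages.tsv"))
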