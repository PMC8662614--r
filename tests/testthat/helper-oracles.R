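# Independent oracles and small fixture builders used across the suite.

# exhaustive Hamming scan over both strands; the reference for scan_motif
brute_hamming_scan <- function(seq, pattern, max_mismatch,
                               both_strands = TRUE) {
  seq <- toupper(seq)
  pattern <- toupper(pattern)
  L <- nchar(seq)
  k <- nchar(pattern)
  revcomp_chr <- function(s) {
    v <- rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]])
    paste(v, collapse = "")
  }
  pats <- list(`+` = pattern)
  if (both_strands) pats$`-` <- revcomp_chr(pattern)
  out <- list()
  if (L >= k) {
    sv <- strsplit(seq, "")[[1]]
    for (strand in names(pats)) {
      pv <- strsplit(pats[[strand]], "")[[1]]
      for (s0 in 0:(L - k)) {
        mm <- sum(sv[(s0 + 1):(s0 + k)] != pv)
        if (mm <= max_mismatch)
          out[[length(out) + 1]] <- data.frame(
            start = s0, end = s0 + k, strand = strand, mismatches = mm)
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), ]
  rownames(res) <- NULL
  res
}

# two-sided Fisher exact p by full hypergeometric enumeration
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a small annotated genome + architecture at desk scale, shared by tests
desk_genome <- function(seed = 1, within_div = 0.028, within_div_B = 0.013,
                        ra1_mult = 3) {
  locus <- locus_spec(scale = 0.1, within_array_div = within_div,
                      within_array_div_B = within_div_B,
                      ra1_div_multiplier = ra1_mult)
  build_genome(locus, sexed_genome_spec(scale = 0.1), seed = seed)
}

desk_architecture <- function(genome) {
  hits <- scan_motif(genome$seqs[["X"]], ctcf_motif(), max_mismatch = 13,
                     contig = "X")
  anchor <- as.list(genome$features[genome$features$name == "anchor_gene",
                                    c("start", "end")])
  segment_macrosatellite(hits, anchor, segment_params(scale = 0.1))
}

# build a DE table realizing exact counts for a 2x2 contrast
de_from_counts <- function(x_up, x_not, a_up, a_not) {
  data.frame(
    gene = sprintf("g%d", seq_len(x_up + x_not + a_up + a_not)),
    chrom = c(rep("X", x_up + x_not), rep("A1", a_up + a_not)),
    log_fc = 0,
    status = c(rep("up", x_up), rep("ns", x_not),
               rep("up", a_up), rep("ns", a_not)),
    fertile_expressed = TRUE, stringsAsFactors = FALSE)
}

# hand-built methylation matrix (bypasses unite) for direct test control
manual_methyl_matrix <- function(mf, positions = NULL, contig = "X") {
  n <- nrow(mf)
  if (is.null(positions)) positions <- seq_len(n) * 10
  sites <- data.frame(contig = contig, pos = positions, strand = "+",
                      context = "CG", stringsAsFactors = FALSE)
  structure(list(sites = sites, mf = mf,
                 depth = matrix(30, n, ncol(mf),
                                dimnames = dimnames(mf)),
                 samples = colnames(mf)),
            class = "methylation_matrix")
}
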