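# Chromosome-level differential-expression enrichment downstream of an
# external DE fit.

#' Per-chromosome up/down balance tests
#'
#' For each chromosome, a chi-squared goodness-of-fit of (n_up, n_down)
#' against an equal split of the chromosome's DE genes (the denominator is
#' DE genes only), plus the exact two-sided binomial p (informative when
#' the DE count is small).
#'
#' @param de DE table (gene, chrom, log_fc, status, fertile_expressed).
#' @return data.frame: chrom, n_up, n_down, chisq, p_chisq, p_binom,
#'   direction.
#' @export
per_chromosome_updown_test <- function(de) {
  rows <- lapply(split(de, de$chrom), function(d) {
    n_up <- sum(d$status == "up")
    n_down <- sum(d$status == "down")
    k <- n_up + n_down
    if (k == 0) {
      chisq <- NA_real_; p_chisq <- NA_real_; p_binom <- NA_real_
    } else {
      chisq <- (n_up - k / 2)^2 / (k / 2) + (n_down - k / 2)^2 / (k / 2)
      p_chisq <- pchisq(chisq, df = 1, lower.tail = FALSE)
      p_binom <- binom.test(n_up, k, 0.5)$p.value
    }
    data.frame(chrom = d$chrom[1], n_up = n_up, n_down = n_down,
               chisq = chisq, p_chisq = p_chisq, p_binom = p_binom,
               direction = if (n_up > n_down) "up" else
                 if (n_down > n_up) "down" else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' X-versus-autosome upregulation contrast
#'
#' Builds the 2x2 table [[X up, X not-up], [autosome up, autosome not-up]]
#' and reports the two-sided Fisher exact p (hypergeometric) and the
#' cross-product odds ratio.
#'
#' @param de DE table.
#' @param x_chrom X chromosome name.
#' @param haldane Add 0.5 to every cell of the odds ratio when a zero cell
#'   is present (off by default).
#' @return List with `table`, `p` and `odds_ratio`.
#' @export
x_autosome_contrast <- function(de, x_chrom = "X", haldane = FALSE) {
  is_x <- de$chrom == x_chrom
  if (!any(is_x) || all(is_x)) stop("empty margin: need X and autosome genes")
  tab <- matrix(c(sum(is_x & de$status == "up"),
                  sum(is_x & de$status != "up"),
                  sum(!is_x & de$status == "up"),
                  sum(!is_x & de$status != "up")),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("X", "autosome"), c("up", "not_up")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in contrast table")
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  ct <- if (haldane && any(tab == 0)) tab + 0.5 else tab
  or <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
  list(table = tab, p = p, odds_ratio = or)
}

#' Permutation null for per-chromosome upregulation enrichment
#'
#' Up labels are shuffled over all genes (totals preserved); the empirical
#' p per chromosome is `(1 + #permutations with up-count >= observed) /
#' (n_perm + 1)`.
#'
#' @param de DE table.
#' @param n_perm Number of permutations.
#' @param seed Integer seed (reproducible).
#' @return data.frame: chrom, n_up_observed, p_perm.
#' @export
permutation_enrichment <- function(de, n_perm = 999, seed = 1) {
  if (n_perm < 100) warning("n_perm < 100: empirical p resolution is coarse")
  chrom <- factor(de$chrom)
  nc <- nlevels(chrom)
  ci <- as.integer(chrom)
  n <- nrow(de)
  n_up <- sum(de$status == "up")
  obs <- tabulate(ci[de$status == "up"], nbins = nc)
  with_seed(derive_seed(seed, "permutation"), {
    ge <- integer(nc)
    for (b in seq_len(n_perm)) {
      sel <- sample.int(n, n_up)
      cnt <- tabulate(ci[sel], nbins = nc)
      ge <- ge + (cnt >= obs)
    }
    data.frame(chrom = levels(chrom), n_up_observed = obs,
               p_perm = (1 + ge) / (n_perm + 1), stringsAsFactors = FALSE)
  })
}

#' Summary of upregulated genes lacking fertile expression
#'
#' Selects upregulated genes with `fertile_expressed = FALSE` and compares
#' their |log fold change| with the remaining upregulated genes using a
#' pooled-variance (Student) two-sided t-test.
#'
#' @param de DE table.
#' @return List with `genes`, `n`, `mean_lfc_zero_fertile`,
#'   `mean_lfc_other_up`, `t` and `p`.
#' @export
zero_in_fertile_summary <- function(de) {
  up <- de[de$status == "up", , drop = FALSE]
  zi <- up[!up$fertile_expressed, , drop = FALSE]
  other <- up[up$fertile_expressed, , drop = FALSE]
  if (nrow(zi) < 2 || nrow(other) < 2) stop("group size < 2")
  ht <- t.test(abs(zi$log_fc), abs(other$log_fc), var.equal = TRUE)
  list(genes = zi$gene, n = nrow(zi),
       mean_lfc_zero_fertile = mean(abs(zi$log_fc)),
       mean_lfc_other_up = mean(abs(other$log_fc)),
       t = unname(ht$statistic), p = ht$p.value)
}
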