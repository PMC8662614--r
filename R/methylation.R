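# RRBS methylation frequencies: spike-in conversion estimation, uniting and
# coverage-filtering multi-sample call tables, PCA, and sliding-window or
# region-level group tests.

#' Add methylation frequency (MF) to a call table
#'
#' MF is the methylated count divided by read depth. Calls at depth 0 are
#' dropped (their number is reported via a message).
#'
#' @param calls data.frame: contig, pos, strand, context, mC, depth.
#' @export
compute_mf <- function(calls) {
  drop <- calls$depth == 0
  if (any(drop)) {
    message(sum(drop), " zero-depth calls dropped")
    calls <- calls[!drop, , drop = FALSE]
  }
  if (any(calls$mC > calls$depth | calls$mC < 0))
    stop("methylated count outside [0, depth]")
  calls$mf <- calls$mC / calls$depth
  calls
}

#' Estimate bisulfite conversion from the unmethylated spike-in
#'
#' Conversion = 1 - mean MF over spike-in cytosines with depth at least
#' `min_depth`.
#'
#' @param calls Call table for one sample.
#' @param lambda_contig Spike-in contig name.
#' @param min_depth Minimum depth for a site to enter the estimate.
#' @return List with `conversion`, `mean_mf` and `n_sites`.
#' @export
estimate_conversion <- function(calls, lambda_contig = "lambda",
                                min_depth = 10) {
  sel <- calls$contig == lambda_contig & calls$depth >= min_depth
  if (!any(sel)) stop("no spike-in site with depth >= ", min_depth)
  mf <- calls$mC[sel] / calls$depth[sel]
  list(conversion = 1 - mean(mf), mean_mf = mean(mf), n_sites = sum(sel))
}

site_key <- function(d) paste(d$contig, d$pos, d$strand, d$context, sep = ":")

#' Unite per-sample call tables and apply the coverage filter
#'
#' Only sites present in every sample are kept; a site then survives only
#' if, in every sample, its depth is at least `min_depth` and at most that
#' sample's `upper_quantile` depth percentile (computed from the sample's
#' full call table with linear interpolation; sites strictly above the
#' percentile are removed). Calls on opposite strands of one CpG stay
#' distinct sites; all contexts are retained.
#'
#' @param samples Named list of call tables.
#' @param min_depth Minimum per-sample depth (default 10).
#' @param upper_quantile Upper depth quantile (default 0.999).
#' @return A `methylation_matrix`: list with `sites` (ordered data.frame),
#'   `mf` and `depth` (site x sample matrices) and `samples`.
#' @export
unite_and_filter <- function(samples, min_depth = 10, upper_quantile = 0.999) {
  stopifnot(length(samples) >= 2, !is.null(names(samples)))
  keys <- lapply(samples, site_key)
  filtered <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    ub <- quantile(s$depth, upper_quantile, type = 7, names = FALSE)
    keys[[i]][s$depth >= min_depth & s$depth <= ub]
  })
  common <- Reduce(intersect, filtered)
  if (length(common) == 0) stop("empty site intersection after filtering")
  ref <- samples[[1]]
  ref_keys <- keys[[1]]
  sites <- ref[match(common, ref_keys), c("contig", "pos", "strand", "context")]
  ord <- order(sites$contig, sites$pos, sites$strand, sites$context)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  common <- common[ord]
  mf <- depth <- matrix(NA_real_, nrow = length(common),
                        ncol = length(samples),
                        dimnames = list(common, names(samples)))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    idx <- match(common, keys[[i]])
    mf[, i] <- s$mC[idx] / s$depth[idx]
    depth[, i] <- s$depth[idx]
  }
  structure(list(sites = sites, mf = mf, depth = depth,
                 samples = names(samples)),
            class = "methylation_matrix")
}

#' PCA of the united methylation-frequency matrix
#'
#' Samples are observations; site MFs are column-centred before the
#' decomposition.
#'
#' @param mat A `methylation_matrix`.
#' @return List with `scores` (samples x PCs) and `explained_variance`
#'   (non-increasing fractions summing to at most 1).
#' @export
pca_mf <- function(mat) {
  if (length(mat$samples) < 3) stop("PCA needs at least 3 samples")
  X <- t(mat$mf)
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = pr$x, explained_variance = ev)
}

# vectorised Welch two-sample t-test over rows of two matrices
welch_rows <- function(X1, X2) {
  n1 <- ncol(X1); n2 <- ncol(X2)
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- apply(X1, 1, stats::var); v2 <- apply(X2, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  # identical groups: zero variance and zero difference -> no evidence
  degenerate <- se2 == 0
  t[degenerate & m1 == m2] <- 0
  p[degenerate & m1 == m2] <- 1
  data.frame(mean1 = m1, mean2 = m2, t = t, df = df, p = p)
}

#' Sliding-window per-cytosine group tests
#'
#' Sites (ordered by position) are tested per cytosine with a Welch
#' two-sample t-test of MF between the two groups; windows of
#' `window_size` cytosines advance by `step` cytosines while a full window
#' fits, and a window is flagged significant when its mean per-cytosine p
#' is at most `alpha`. Per-group window mean MFs (the plotting surface)
#' are also returned. No multiple-testing correction is applied.
#'
#' @param mat A `methylation_matrix`.
#' @param groups Named group label per sample (two groups, each >= 2
#'   samples).
#' @param window_size Cytosines per window (default 20).
#' @param step Step in cytosines (default 10).
#' @param alpha Window mean-p significance level.
#' @param region Optional region restriction: list(contig, start, end)
#'   with 0-based half-open bounds on position - 1.
#' @param contexts Optional context restriction (e.g. "CG").
#' @return List with `windows` (data.frame) and `per_cytosine`
#'   (data.frame of per-site tests).
#' @export
sliding_window_tests <- function(mat, groups, window_size = 20, step = 10,
                                 alpha = 0.05, region = NULL,
                                 contexts = NULL) {
  sel <- rep(TRUE, nrow(mat$sites))
  if (!is.null(region))
    sel <- sel & mat$sites$contig == region$contig &
      (mat$sites$pos - 1) >= region$start & (mat$sites$pos - 1) < region$end
  if (!is.null(contexts)) sel <- sel & mat$sites$context %in% contexts
  sites <- mat$sites[sel, , drop = FALSE]
  mf <- mat$mf[sel, , drop = FALSE]
  ord <- order(sites$contig, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  mf <- mf[ord, , drop = FALSE]

  g <- groups[mat$samples]
  lv <- unique(g)
  if (length(lv) != 2) stop("exactly two groups required")
  i1 <- which(g == lv[1]); i2 <- which(g == lv[2])
  if (length(i1) < 2 || length(i2) < 2)
    stop("each group needs at least 2 samples for the t-test")
  per <- welch_rows(mf[, i1, drop = FALSE], mf[, i2, drop = FALSE])
  per <- cbind(sites, per)
  names(per)[names(per) == "mean1"] <- paste0("mean_", lv[1])
  names(per)[names(per) == "mean2"] <- paste0("mean_", lv[2])

  n <- nrow(per)
  if (n < window_size) {
    windows <- data.frame()
  } else {
    starts <- seq(1, n - window_size + 1, by = step)
    windows <- do.call(rbind, lapply(seq_along(starts), function(w) {
      idx <- starts[w]:(starts[w] + window_size - 1)
      data.frame(window = w,
                 first_pos = per$pos[idx[1]],
                 last_pos = per$pos[idx[length(idx)]],
                 mean_mf_1 = mean(mf[idx, i1]),
                 mean_mf_2 = mean(mf[idx, i2]),
                 mean_p = mean(per$p[idx]))
    }))
    names(windows)[names(windows) == "mean_mf_1"] <- paste0("mean_mf_", lv[1])
    names(windows)[names(windows) == "mean_mf_2"] <- paste0("mean_mf_", lv[2])
    windows$significant <- windows$mean_p <= alpha
  }
  list(windows = windows, per_cytosine = per)
}

#' Welch t-test of region-mean methylation between two groups
#'
#' Per-sample mean MF over the region's sites is compared between groups
#' with a Welch two-sample t-test (Welch-Satterthwaite df, two-sided).
#'
#' @param mat A `methylation_matrix`.
#' @param region List(contig, start, end), 0-based half-open.
#' @param groups Named group label per sample.
#' @return List with `group_means`, `t`, `df`, `p` and `n_sites`.
#' @export
region_group_test <- function(mat, region, groups) {
  sel <- mat$sites$contig == region$contig &
    (mat$sites$pos - 1) >= region$start & (mat$sites$pos - 1) < region$end
  if (!any(sel)) stop("region contains no united site")
  g <- groups[mat$samples]
  lv <- unique(g)
  if (length(lv) != 2) stop("exactly two groups required")
  sample_means <- colMeans(mat$mf[sel, , drop = FALSE])
  x1 <- sample_means[g == lv[1]]
  x2 <- sample_means[g == lv[2]]
  if (length(x1) < 2 || length(x2) < 2) stop("group size < 2")
  w <- welch_rows(matrix(x1, 1), matrix(x2, 1))
  list(group_means = setNames(c(mean(x1), mean(x2)), lv),
       t = w$t, df = w$df, p = w$p, n_sites = sum(sel))
}

#' Trailing moving average
#'
#' Arithmetic mean over the trailing window of `n` values; the first
#' `n - 1` positions are `NA`.
#'
#' @param values Numeric vector.
#' @param n Window length (>= 1).
#' @export
moving_average <- function(values, n) {
  if (n < 1) stop("window must be >= 1")
  as.numeric(stats::filter(values, rep(1 / n, n), sides = 1))
}
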