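test_that("MF computation and conversion estimation follow their formulas", {
  calls <- data.frame(contig = "X", pos = 1:4, strand = "+", context = "CG",
                      mC = c(5L, 0L, 7L, 1L), depth = c(10L, 7L, 7L, 0L))
  expect_message(out <- compute_mf(calls), "1 zero-depth")
  expect_equal(out$mf, c(0.5, 0, 1))

  lam <- data.frame(contig = "lambda", pos = 1:3, strand = "+",
                    context = "CG", mC = c(0L, 0L, 3L),
                    depth = c(20L, 30L, 5L))
  est <- estimate_conversion(lam)
  expect_equal(est$conversion, 1)        # the depth-5 site is ignored
  expect_equal(est$n_sites, 2L)
  expect_error(estimate_conversion(lam[lam$depth < 10, ]), "spike-in")
})

test_that("conversion recovery is accurate across non-conversion rates", {
  for (f in c(0, 0.005, 0.02)) {
    sim <- simulate_methylation_samples(
      methylation_sites(1000, contig = "lambda"),
      methyl_sim_spec(non_conversion_rate = f, depth_mean = 60),
      n_fertile = 1, n_sterile = 1, seed = round(1000 * f) + 3)
    est <- estimate_conversion(sim$samples[[1]], min_depth = 30)
    expect_lt(abs(est$conversion - (1 - f)), 0.005)
  }
})

test_that("uniting keeps the all-sample intersection under the depth filter", {
  mk <- function(pos, depth) data.frame(contig = "X", pos = pos,
                                        strand = "+", context = "CG",
                                        mC = 0L, depth = depth)
  s1 <- mk(c(1, 2, 3, 4, 5), 20L)
  s2 <- mk(c(2, 3, 4, 8, 9), 20L)
  m <- unite_and_filter(list(a = s1, b = s2))
  expect_equal(m$sites$pos, c(2, 3, 4))

  # one low-depth site in one sample removes the site everywhere
  s2b <- s2
  s2b$depth[1] <- 5L
  m2 <- unite_and_filter(list(a = s1, b = s2b))
  expect_equal(m2$sites$pos, c(3, 4))

  # the 99.9% depth percentile removes extreme-depth sites, per the
  # linear-interpolation definition
  pos <- 1:1000
  depths <- c(rep(20L, 999), 5000L)
  s3 <- mk(pos, depths)
  s4 <- mk(pos, rep(20L, 1000))
  expected_ub <- quantile(depths, 0.999, type = 7, names = FALSE)
  expect_lt(expected_ub, 5000)
  m3 <- unite_and_filter(list(a = s3, b = s4))
  expect_equal(nrow(m3$sites), 999L)
  expect_false(1000 %in% m3$sites$pos)

  # invariant to sample order
  m4 <- unite_and_filter(list(b = s2, a = s1))
  expect_equal(m4$sites, m$sites)

  expect_error(unite_and_filter(list(a = mk(1:3, 20L), b = mk(7:9, 20L))),
               "empty site intersection")
})

test_that("PCA separates simulated groups and reports sane variance", {
  sim <- simulate_methylation_samples(
    methylation_sites(300), methyl_sim_spec(mean_fertile = 0.6,
                                            mean_sterile = 0.2,
                                            precision = 200,
                                            depth_mean = 60),
    n_fertile = 3, n_sterile = 3, seed = 5)
  mat <- unite_and_filter(sim$samples)
  pca <- pca_mf(mat)
  expect_lte(sum(pca$explained_variance), 1 + 1e-12)
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
  pc1 <- pca$scores[, 1]
  g <- sim$groups[rownames(pca$scores)]
  # silhouette of the two groups on PC1 is positive
  sil <- vapply(seq_along(pc1), function(i) {
    own <- pc1[g == g[i]]
    own <- own[names(own) != names(pc1)[i]]
    a <- mean(abs(pc1[i] - own))
    b <- mean(abs(pc1[i] - pc1[g != g[i]]))
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0)

  dup <- mat
  dup$mf <- cbind(mat$mf, dup1 = mat$mf[, 1])
  dup$depth <- cbind(mat$depth, dup1 = mat$depth[, 1])
  dup$samples <- c(mat$samples, "dup1")
  p2 <- pca_mf(dup)
  expect_equal(unname(p2$scores["dup1", ]),
               unname(p2$scores[mat$samples[1], ]))

  small <- mat
  small$mf <- mat$mf[, 1:2]
  small$samples <- mat$samples[1:2]
  expect_error(pca_mf(small), "at least 3")
})

test_that("per-cytosine Welch tests match stats::t.test to high precision", {
  set.seed(81)
  mf <- matrix(runif(50 * 6), 50, 6,
               dimnames = list(NULL, c(paste0("f", 1:4), paste0("s", 1:2))))
  mat <- manual_methyl_matrix(mf)
  groups <- setNames(rep(c("fertile", "sterile"), c(4, 2)), colnames(mf))
  sw <- sliding_window_tests(mat, groups, window_size = 10, step = 5)
  for (i in seq_len(50)) {
    ht <- t.test(mf[i, 1:4], mf[i, 5:6], var.equal = FALSE)
    expect_equal(sw$per_cytosine$t[i], unname(ht$statistic),
                 tolerance = 1e-10)
    expect_equal(sw$per_cytosine$df[i], unname(ht$parameter),
                 tolerance = 1e-10)
    expect_equal(sw$per_cytosine$p[i], ht$p.value, tolerance = 1e-10)
  }
})

test_that("window layout, null behaviour and power match expectations", {
  # 45 ordered sites produce exactly 3 full windows
  mf <- matrix(runif(45 * 4), 45, 4,
               dimnames = list(NULL, c("a", "b", "c", "d")))
  mat <- manual_methyl_matrix(mf)
  groups <- setNames(c("g1", "g1", "g2", "g2"), colnames(mf))
  sw <- sliding_window_tests(mat, groups)
  expect_equal(nrow(sw$windows), 3L)
  expect_equal(sw$windows$first_pos, mat$sites$pos[c(1, 11, 21)])
  expect_equal(sw$windows$last_pos, mat$sites$pos[c(20, 30, 40)])

  # identical group values: p = 1 everywhere, nothing flagged
  mf_id <- matrix(rep(runif(45), 4), 45, 4,
                  dimnames = list(NULL, c("a", "b", "c", "d")))
  sw_id <- sliding_window_tests(manual_methyl_matrix(mf_id), groups)
  expect_true(all(sw_id$per_cytosine$p == 1))
  expect_false(any(sw_id$windows$significant))

  expect_error(sliding_window_tests(mat, setNames(c("g1", "g1", "g1", "g2"),
                                                  colnames(mf))),
               "at least 2")

  # power at the study means under low dispersion: a significant window in
  # >= 80% of replicates
  hits <- 0
  for (r in 1:50) {
    sim <- simulate_methylation_samples(
      methylation_sites(200),
      methyl_sim_spec(depth_mean = 5000, precision = 1e5,
                      non_conversion_rate = 0),
      n_fertile = 4, n_sterile = 2, seed = 5000 + r)
    m <- unite_and_filter(sim$samples)
    s <- sliding_window_tests(m, sim$groups)
    if (nrow(s$windows) && any(s$windows$significant)) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.8)
})

test_that("under the null the per-cytosine p values are calibrated", {
  sim <- simulate_methylation_samples(
    methylation_sites(2500),
    methyl_sim_spec(mean_fertile = 0.2, mean_sterile = 0.2,
                    precision = 50, depth_mean = 40),
    n_fertile = 4, n_sterile = 4, seed = 17)
  mat <- unite_and_filter(sim$samples)
  sw <- sliding_window_tests(mat, sim$groups)
  frac <- mean(sw$per_cytosine$p <= 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("region-level Welch test matches the closed form", {
  mf <- matrix(0.2, 4, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  mat <- manual_methyl_matrix(mf)
  groups <- setNames(c("g1", "g1", "g2", "g2"), colnames(mf))
  rg <- region_group_test(mat, list(contig = "X", start = 0, end = 1e6),
                          groups)
  expect_equal(rg$t, 0)
  expect_equal(rg$p, 1)

  # hand-computed Welch on {1,2,3,4} vs {10,20}
  x <- c(1, 2, 3, 4); y <- c(10, 20)
  mfh <- rbind(c(x, y))  # one site whose per-sample means are the values
  math <- manual_methyl_matrix(mfh)
  colnames(math$mf) <- c(paste0("f", 1:4), paste0("s", 1:2))
  math$samples <- colnames(math$mf)
  gh <- setNames(rep(c("g1", "g2"), c(4, 2)), math$samples)
  rgh <- region_group_test(math, list(contig = "X", start = 0, end = 1e6),
                           gh)
  se2 <- var(x) / 4 + var(y) / 2
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 4)^2 / 3 + (var(y) / 2)^2 / 1)
  expect_equal(rgh$t, t_hand, tolerance = 1e-12)
  expect_equal(rgh$df, df_hand, tolerance = 1e-12)
  expect_equal(rgh$p, 2 * pt(abs(t_hand), df_hand, lower.tail = FALSE),
               tolerance = 1e-12)

  # exactly equal variances and equal n: Welch df = 2n - 2
  mfe <- rbind(c(1, 2, 3, 4, 11, 12, 13, 14) / 20)
  colnames(mfe) <- paste0("s", 1:8)
  mate <- manual_methyl_matrix(mfe)
  mate$samples <- colnames(mfe)
  ge <- setNames(rep(c("g1", "g2"), each = 4), colnames(mfe))
  rge <- region_group_test(mate, list(contig = "X", start = 0, end = 1e6),
                           ge)
  expect_equal(rge$df, 6)
})

test_that("moving averages use a trailing window with leading NAs", {
  expect_equal(moving_average(1:5, 1), as.numeric(1:5))
  expect_equal(moving_average(rep(3, 6), 4), c(NA, NA, NA, 3, 3, 3))
  set.seed(99)
  v <- rnorm(100)
  got <- moving_average(v, 7)
  cs <- cumsum(v)
  want <- c(rep(NA, 6), (cs[7:100] - c(0, cs[1:93])) / 7)
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(moving_average(1:3, 0), ">= 1")
})
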