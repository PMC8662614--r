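test_that("collapsing replaces each array by one representative unit", {
  g <- desk_genome(seed = 51)
  arch <- desk_architecture(g)
  col <- collapse_reference(g, arch)

  ul_a <- arch$arrays$RA$units$end[1] - arch$arrays$RA$units$start[1]
  ul_b <- arch$arrays$RB$units$end[1] - arch$arrays$RB$units$start[1]
  old_len <- contig_lengths(g)[["X"]]
  new_len <- unname(setNames(Biostrings::width(col$seqs),
                             names(col$seqs))["X"])
  expect_equal(old_len - new_len, 8 * ul_a + 11 * ul_b)

  expect_equal(col$collapse_map$label, c("RA", "RB"))
  expect_equal(col$collapse_map$n_units, c(9L, 12L))
  # representative equals brute-force argmin of distance-matrix row means
  aln <- extract_unit_alignment(g, arch)
  groups <- attr(aln, "groups")
  for (lab in c("RA", "RB")) {
    members <- names(aln)[groups == lab]
    D <- pairwise_p_distance(aln[members])$matrix
    want <- members[which.min(rowSums(D) / (length(members) - 1))]
    expect_equal(col$collapse_map$representative[
      col$collapse_map$label == lab], want)
  }

  # control gene keeps its sequence, at shifted coordinates
  ctl_old <- g$features[g$features$name == "control_gene", ]
  ctl_new <- col$features[col$features$name == "control_gene", ]
  expect_equal(ctl_old$end - ctl_old$start, ctl_new$end - ctl_new$start)
  old_seq <- substr(as.character(g$seqs[["X"]]), ctl_old$start + 1,
                    ctl_old$end)
  new_seq <- substr(as.character(col$seqs[["X"]]), ctl_new$start + 1,
                    ctl_new$end)
  expect_identical(old_seq, new_seq)

  # identical units: representative is the leftmost by position
  g0 <- desk_genome(seed = 52, within_div = 0, within_div_B = 0,
                    ra1_mult = 0)
  col0 <- collapse_reference(g0, desk_architecture(g0))
  expect_equal(col0$collapse_map$representative, c("RA-1", "RB-1"))

  expect_error(collapse_reference(g, NULL), "architecture absent")
})

test_that("feature-mean and genome-mean depth match accumulation oracles", {
  tr <- depth_track(list(c1 = rep(7L, 100)))
  expect_equal(mean_feature_depth(tr, list(contig = "c1", start = 0,
                                           end = 100)), 7)
  tr2 <- depth_track(list(c1 = c(0L, 10L)))
  expect_equal(mean_feature_depth(tr2, list(contig = "c1", start = 0,
                                            end = 2)), 5)
  expect_error(mean_feature_depth(tr2, list(contig = "c1", start = 0,
                                            end = 5)), "outside")
  expect_error(mean_feature_depth(tr2, list(contig = "nope", start = 0,
                                            end = 1)), "not in track")

  set.seed(61)
  v <- rpois(1000, 9)
  trr <- depth_track(list(a = v, b = rpois(1000, 3)))
  s <- sample.int(900, 1)
  f <- list(contig = "a", start = s, end = s + 50)
  acc <- 0
  for (i in (s + 1):(s + 50)) acc <- acc + v[i]
  expect_equal(mean_feature_depth(trr, f), acc / 50)

  expect_equal(genome_mean_depth(depth_track(list(a = rep(20L, 10))),
                                 exclude = NULL), 20)
  expect_equal(genome_mean_depth(depth_track(list(a = rep(10L, 50),
                                                  b = rep(30L, 50))),
                                 exclude = NULL), 20)
  # spike-in contig excluded by default
  expect_equal(genome_mean_depth(depth_track(list(a = rep(10L, 50),
                                                  lambda = rep(99L, 50)))),
               10)
  expect_error(genome_mean_depth(depth_track(list(lambda = rep(1L, 5)))),
               "empty track")
})

test_that("copy-number estimates recover truth with sex-correct controls", {
  g <- desk_genome(seed = 53)
  arch <- desk_architecture(g)
  col <- collapse_reference(g, arch)
  lens <- setNames(Biostrings::width(col$seqs), names(col$seqs))
  ctl <- as.list(col$features[col$features$name == "control_gene",
                              c("contig", "start", "end")])
  cm <- col$collapse_map
  cm$copies <- 10

  tr_m <- simulate_depth(lens, "male", mean_depth = 20, seed = 7,
                         collapse_map = cm)
  est_m <- estimate_copy_number(tr_m, col$collapse_map, ctl, sex = "male")
  expect_true(all(est_m$cn > 9 & est_m$cn < 11))
  expect_equal(est_m$ploidy_divisor, c(1L, 1L))

  # a female track carries no Y contigs
  lens_f <- lens[!grepl("^Y", names(lens))]
  tr_f <- simulate_depth(lens_f, "female", mean_depth = 20, seed = 8,
                         collapse_map = cm)
  est_f <- estimate_copy_number(tr_f, col$collapse_map, ctl, sex = "female")
  expect_true(all(est_f$cn > 9 & est_f$cn < 11))
  expect_equal(est_f$ploidy_divisor, c(2L, 2L))

  # control ratios approach 0.5 / 1.0 when the X is a small genome fraction
  big <- c(A1 = 1000000, X = 50000)
  big_ctl <- list(contig = "X", start = 20000, end = 30000)
  one <- data.frame(label = "RA", contig = "X", start = 0, end = 1000)
  trb_m <- simulate_depth(big, "male", 20, seed = 21, lambda_contig = NULL)
  expect_lt(abs(estimate_copy_number(trb_m, one, big_ctl,
                                     sex = "male")$control_ratio - 0.5),
            0.05)
  trb_f <- simulate_depth(big, "female", 20, seed = 22,
                          lambda_contig = NULL)
  expect_lt(abs(estimate_copy_number(trb_f, one, big_ctl,
                                     sex = "female")$control_ratio - 1.0),
            0.05)

  # invariance to uniform depth scaling
  tr_s <- tr_m
  tr_s$depth <- lapply(tr_s$depth, function(v) v * 3L)
  est_s <- estimate_copy_number(tr_s, col$collapse_map, ctl, sex = "male")
  expect_equal(est_s$cn, est_m$cn, tolerance = 1e-12)
  expect_equal(est_s$raw_ratio, est_m$raw_ratio, tolerance = 1e-12)

  est_u <- estimate_copy_number(tr_m, col$collapse_map, ctl, sex = "unknown")
  expect_true(all(est_u$ploidy_caveat))
})

test_that("copy-number recovery stays within 10% median error across truths", {
  g <- desk_genome(seed = 54)
  col <- collapse_reference(g, desk_architecture(g))
  lens <- setNames(Biostrings::width(col$seqs), names(col$seqs))
  ctl <- as.list(col$features[col$features$name == "control_gene",
                              c("contig", "start", "end")])
  for (truth in c(5, 12, 30)) {
    cm <- col$collapse_map
    cm$copies <- truth
    rel_err <- vapply(1:8, function(r) {
      tr <- simulate_depth(lens, "male", mean_depth = 20,
                           seed = 100 * truth + r, collapse_map = cm)
      est <- estimate_copy_number(tr, col$collapse_map, ctl, sex = "male")
      median(abs(est$cn - truth) / truth)
    }, 0)
    expect_lt(median(rel_err), 0.1)
  }
})
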