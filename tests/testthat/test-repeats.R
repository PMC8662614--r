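test_that("literal motif scan reports Hamming neighbourhoods on both strands", {
  m <- ctcf_motif()
  h <- scan_motif(m, m, max_mismatch = 13, both_strands = FALSE)
  expect_equal(h$start, 0L)
  expect_equal(h$mismatches, 0L)
  expect_equal(h$strand, "+")

  h2 <- scan_motif("ACGTACGA", "ACGT", max_mismatch = 1, both_strands = FALSE)
  expect_equal(h2$start, c(0L, 4L))
  expect_equal(h2$mismatches, c(0L, 1L))

  pat <- "AACCGT"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pat)))
  h3 <- scan_motif(rc, pat, max_mismatch = 0, both_strands = TRUE)
  expect_equal(nrow(h3), 1L)
  expect_equal(h3$strand, "-")
  expect_equal(h3$start, 0L)

  # pattern longer than sequence: empty, not an error
  expect_equal(nrow(scan_motif("ACG", "ACGTA", max_mismatch = 1)), 0L)
  # N in subject counts as a mismatch
  h4 <- scan_motif("ANGT", "ACGT", max_mismatch = 1, both_strands = FALSE)
  expect_equal(h4$mismatches, 1L)
  expect_error(scan_motif("ACGTA", "ACGT", max_mismatch = 4), "max_mismatch")
})

test_that("motif scan equals the exhaustive Hamming oracle on random cases", {
  set.seed(11)
  for (i in 1:100) {
    L <- sample(30:150, 1)
    k <- sample(4:10, 1)
    mm <- sample(0:3, 1)
    seq <- random_dna_str(L)
    pat <- random_dna_str(k)
    got <- scan_motif(seq, pat, max_mismatch = mm, both_strands = TRUE)
    want <- brute_hamming_scan(seq, pat, mm, both_strands = TRUE)
    expect_equal(got[, c("start", "end", "strand", "mismatches")], want,
                 info = sprintf("case %d (L=%d k=%d mm=%d)", i, L, k, mm))
  }
})

test_that("IUPAC scan uses class membership and matches the literal scan", {
  expect_equal(nrow(scan_iupac("A", "N", max_mismatch = 0,
                               both_strands = FALSE)), 1L)
  expect_equal(scan_iupac("GA", "RA", max_mismatch = 0,
                          both_strands = FALSE)$mismatches, 0L)
  # R does not cover C
  expect_equal(nrow(scan_iupac("CA", "RA", max_mismatch = 0,
                               both_strands = FALSE)), 0L)
  expect_error(scan_iupac("ACGT", "AXGT", max_mismatch = 1), "X")

  set.seed(12)
  for (i in 1:20) {
    seq <- random_dna_str(80)
    pat <- random_dna_str(6)
    mm <- sample(0:2, 1)
    expect_equal(scan_iupac(seq, pat, mm), scan_motif(seq, pat, mm))
  }

  # the IUPAC consensus accepts the literal motif with zero mismatches
  h <- scan_iupac(ctcf_motif(), ctcf_motif_iupac(), max_mismatch = 13,
                  both_strands = FALSE)
  expect_equal(h$start[1], 0L)
})

test_that("self-dotplot flags tandem duplications and inverted repeats", {
  set.seed(13)
  s <- random_dna_str(400)
  dup <- paste0(s, s)
  d <- self_dotplot(dup, word_size = 20, include_revcomp = FALSE)
  expect_true(all(d$y - d$x == 400))
  expect_equal(nrow(d), 381)  # one pair per word start along the duplication

  r <- self_dotplot(random_dna_str(1000), word_size = 12,
                    include_revcomp = FALSE)
  expect_lt(nrow(r), 5)  # expected off-diagonal matches < 1

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  pal <- paste0(s, rc)
  pd <- self_dotplot(pal, word_size = 20)
  expect_gt(sum(pd$strand == "-"), 0)

  expect_error(self_dotplot("ACGTACGT", word_size = 3), "word_size")
})

test_that("segmentation recovers the truth architecture exactly", {
  # divergence 0: unit boundaries equal truth to the base
  g0 <- desk_genome(seed = 21, within_div = 0, within_div_B = 0,
                    ra1_mult = 0)
  a0 <- desk_architecture(g0)
  tru_ra <- g0$features[grepl("^RA-[0-9]+$", g0$features$name), ]
  tru_rb <- g0$features[grepl("^RB-[0-9]+$", g0$features$name), ]
  expect_identical(a0$arrays$RA$units$start, sort(tru_ra$start))
  expect_identical(a0$arrays$RA$units$end, sort(tru_ra$end))
  expect_identical(a0$arrays$RB$units$start, sort(tru_rb$start))
  expect_identical(a0$arrays$RB$units$end, sort(tru_rb$end))

  # default (study-like) divergence: counts and motif signatures
  g <- desk_genome(seed = 22)
  a <- desk_architecture(g)
  expect_equal(nrow(a$arrays$RA$units), 9)
  expect_equal(nrow(a$arrays$RB$units), 12)
  expect_equal(a$arrays$RA$signature, "-")
  expect_equal(a$arrays$RB$signature, "-+")
  expect_equal(a$arrays$RA$motifs_per_unit, 1)
  expect_equal(a$arrays$RB$motifs_per_unit, 2)
  expect_equal(unname(a$spacer["end"] - a$spacer["start"]),
               g$features$end[g$features$name == "spacer"] -
                 g$features$start[g$features$name == "spacer"])

  # a single array cannot form a compound architecture
  hits <- scan_motif(g$seqs[["X"]], ctcf_motif(), contig = "X")
  ra_span <- c(g$features$start[g$features$name == "RA"],
               g$features$end[g$features$name == "RA"])
  only_ra <- hits[hits$start >= ra_span[1] & hits$end <= ra_span[2], ]
  anchor <- as.list(g$features[g$features$name == "anchor_gene",
                               c("start", "end")])
  expect_error(segment_macrosatellite(only_ra, anchor,
                                      segment_params(scale = 0.1)),
               "no compound architecture")
})

test_that("CpG island HMM matches an independent forward-backward oracle", {
  set.seed(31)
  at <- function(n) paste(sample(c("A", "T"), n, TRUE,
                                 prob = c(0.55, 0.45)), collapse = "")
  cg_block <- strrep("CG", 150)
  seq <- paste0(at(1000), cg_block, at(1000))

  res <- detect_cpg_islands(seq, return_posterior = TRUE)
  isl <- res$islands
  expect_equal(nrow(isl), 1L)
  block <- c(1000, 1300)  # 0-based bounds of the CG block
  overlap <- min(isl$end, block[2]) - max(isl$start, block[1])
  expect_gte(overlap / 300, 0.9)

  # independent oracle: scaled (non-log) forward-backward
  oracle_posterior <- function(s, persistence = 1 - 1e-4) {
    em <- sterileX:::cpg_emission_defaults()
    v <- strsplit(s, "")[[1]]
    b <- match(v, c("A", "C", "G", "T"))
    n <- length(v)
    E <- matrix(0.25, n, 2)
    for (i in 2:n) {
      E[i, 1] <- em$island[b[i - 1], b[i]]
      E[i, 2] <- em$background[b[i - 1], b[i]]
    }
    A <- matrix(c(persistence, 1 - persistence,
                  1 - persistence, persistence), 2, byrow = TRUE)
    al <- matrix(0, n, 2); sc <- numeric(n)
    al[1, ] <- 0.5 * E[1, ]; sc[1] <- sum(al[1, ]); al[1, ] <- al[1, ] / sc[1]
    for (i in 2:n) {
      al[i, ] <- (al[i - 1, ] %*% A) * E[i, ]
      sc[i] <- sum(al[i, ]); al[i, ] <- al[i, ] / sc[i]
    }
    be <- matrix(0, n, 2); be[n, ] <- 1
    for (i in (n - 1):1) {
      be[i, ] <- A %*% (E[i + 1, ] * be[i + 1, ]) / sc[i + 1]
    }
    g <- al * be
    g[, 1] / rowSums(g)
  }
  short <- paste0(at(300), strrep("CG", 60), at(300))
  got <- detect_cpg_islands(short, return_posterior = TRUE)$posterior
  want <- oracle_posterior(short)
  expect_lt(max(abs(got - want)), 1e-8)

  # uninformative limit: identical emissions leave the prior untouched
  em <- sterileX:::cpg_emission_defaults()
  em$island <- em$background
  flat <- detect_cpg_islands(random_dna_str(500), emissions = em,
                             return_posterior = TRUE)$posterior
  expect_lt(max(abs(flat - 0.5)), 1e-9)

  expect_equal(nrow(detect_cpg_islands(strrep("AT", 500))), 0L)
  em$island <- matrix(0, 4, 4, dimnames = dimnames(em$background))
  expect_error(detect_cpg_islands("ACGT", emissions = em), "degenerate")

  # secondary rule-based detector agrees on the clean case
  gg <- cpg_islands_gg(seq)
  expect_equal(nrow(gg), 1L)
  expect_lt(abs(gg$start - 1000), 200)
})

test_that("p-distance respects gap masking and hand enumeration", {
  d <- pairwise_p_distance(c(a = "AAAA", b = "AAAT"), groups = c("g", "g"))
  expect_equal(d$matrix["a", "b"], 0.25)

  d2 <- pairwise_p_distance(c(a = "AA-A", b = "AAAA"),
                            gap_mask_fraction = 0.10)
  expect_equal(d2$matrix["a", "b"], 0)  # gappy column masked

  d3 <- pairwise_p_distance(c(a = "ACGT", b = "ACGT"))
  expect_equal(d3$matrix["a", "b"], 0)
  expect_true(isSymmetric(d3$matrix))

  expect_error(pairwise_p_distance(c(a = "A---", b = "-AAA"),
                                   gap_mask_fraction = 0.1),
               "zero comparable")
  expect_error(pairwise_p_distance(c(a = "ACGT", b = "ACG")))

  # 3-sequence hand enumeration
  aln <- c(s1 = "AAAA", s2 = "AATT", s3 = "TTTT")
  dm <- pairwise_p_distance(aln, groups = c(A = "A", A = "A", B = "B"))
  expect_equal(dm$matrix["s1", "s2"], 0.5)
  expect_equal(dm$matrix["s1", "s3"], 1)
  expect_equal(dm$matrix["s2", "s3"], 0.5)
  gs <- group_distance_summary(dm)
  expect_equal(unname(gs$within["A"]), 0.5)
  expect_true(is.na(gs$within["B"]))
  expect_equal(gs$between, mean(c(1, 0.5)))
})

test_that("group distances recover the generating divergences", {
  # identical groups at cross-divergence d
  set.seed(41)
  s <- random_dna_str(2000)
  v <- strsplit(s, "")[[1]]
  idx <- sample(2000, 400)
  v[idx] <- vapply(v[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  t <- paste(v, collapse = "")
  dm <- pairwise_p_distance(c(a1 = s, a2 = s, b1 = t, b2 = t),
                            groups = c("A", "A", "B", "B"))
  gs <- group_distance_summary(dm)
  expect_equal(unname(gs$within), c(0, 0))
  expect_equal(gs$between, 0.2)

  # generator recovery at the study's RA within-array divergence
  g <- desk_genome(seed = 42, ra1_mult = 1)
  a <- desk_architecture(g)
  aln <- extract_unit_alignment(g, a)
  gsum <- group_distance_summary(pairwise_p_distance(aln))
  expect_lt(abs(gsum$within["RA"] - 0.028) / 0.028, 0.2)
})

test_that("neighbour joining is exact on additive matrices", {
  # 4 taxa, topology ab|cd with internal branch 1
  bl <- c(a = 2, b = 3, c = 4, d = 5)
  D <- matrix(0, 4, 4, dimnames = list(names(bl), names(bl)))
  D["a", "b"] <- D["b", "a"] <- bl["a"] + bl["b"]
  D["c", "d"] <- D["d", "c"] <- bl["c"] + bl["d"]
  for (x in c("a", "b")) for (y in c("c", "d"))
    D[x, y] <- D[y, x] <- bl[x] + bl[y] + 1
  dm <- structure(list(labels = names(bl), matrix = D, groups = NULL),
                  class = "distance_matrix")
  nj <- build_nj_tree(dm)
  co <- ape::cophenetic.phylo(nj$tree)[names(bl), names(bl)]
  expect_lt(max(abs(co - D)), 1e-9)
  # ab|cd split present
  expect_true(ape::is.monophyletic(ape::root(nj$tree, "c"), c("a", "b")))

  # 3 taxa: closed-form star resolution
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  dm3 <- structure(list(labels = c("a", "b", "c"), matrix = D3,
                        groups = NULL), class = "distance_matrix")
  t3 <- build_nj_tree(dm3)$tree
  expect_setequal(round(t3$edge.length, 9), c(1, 2, 3))

  expect_error(build_nj_tree(structure(list(labels = c("a", "b"),
                                            matrix = matrix(0, 2, 2),
                                            groups = NULL),
                                       class = "distance_matrix")),
               "at least 3")
})

test_that("repeat units resolve into reciprocally monophyletic arrays", {
  g <- desk_genome(seed = 43)
  a <- desk_architecture(g)
  aln <- extract_unit_alignment(g, a)
  dm <- pairwise_p_distance(aln)
  res <- build_nj_tree(dm, bootstrap = list(replicates = 50, seed = 1,
                                            alignment = aln))
  ra <- names(aln)[attr(aln, "groups") == "RA"]
  rb <- names(aln)[attr(aln, "groups") == "RB"]
  rooted <- ape::root(res$tree, rb[1])
  expect_true(ape::is.monophyletic(rooted, ra))
  expect_true(all(res$tree$node.label >= 0 & res$tree$node.label <= 100))
})
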