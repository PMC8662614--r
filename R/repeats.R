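# Macrosatellite architecture annotation: motif scanning with mismatch
# tolerance, self-dotplots, array/spacer segmentation, CpG-island HMM,
# p-distances and neighbour-joining trees of repeat units.

as_dnastring <- function(seq) {
  if (inherits(seq, "DNAString")) seq else Biostrings::DNAString(as.character(seq))
}

hit_frame <- function(contig, start, end, strand, mismatches) {
  data.frame(contig = contig, start = as.integer(start), end = as.integer(end),
             strand = strand, mismatches = as.integer(mismatches),
             stringsAsFactors = FALSE)
}

empty_hits <- function() hit_frame(character(), integer(), integer(),
                                   character(), integer())

scan_one_strand <- function(subject, pattern, max_mismatch, fixed) {
  k <- nchar(as.character(pattern))
  if (k > length(subject)) return(NULL)
  m <- Biostrings::matchPattern(pattern, subject, max.mismatch = max_mismatch,
                                with.indels = FALSE, fixed = fixed)
  if (length(m) == 0) return(NULL)
  # drop partial matches hanging over either end of the subject
  st <- BiocGenerics::start(m)
  keep <- st >= 1L & st + k - 1L <= length(subject)
  m <- m[keep]
  if (length(m) == 0) return(NULL)
  mm <- Biostrings::nmismatch(pattern, m, fixed = fixed)
  list(start = BiocGenerics::start(m) - 1L, mm = mm)
}

#' Scan a sequence for a literal motif allowing mismatches
#'
#' Every offset whose Hamming distance to the pattern is at most
#' `max_mismatch` is reported; with `both_strands = TRUE` the reverse
#' complement is also scanned and its hits are reported in forward-strand
#' coordinates. N in the subject counts as a mismatch.
#'
#' @param seq A DNAString, character scalar, or `ContigSeq`-like named
#'   character (names supply the contig id).
#' @param pattern Literal DNA pattern over A/C/G/T.
#' @param max_mismatch Maximum Hamming distance (default 13, the tolerance
#'   used for the 34-bp CTCF consensus).
#' @param both_strands Scan the reverse strand too.
#' @param contig Contig id recorded in the output.
#' @return data.frame: contig, start, end (0-based half-open), strand,
#'   mismatches; sorted by start then strand.
#' @export
scan_motif <- function(seq, pattern, max_mismatch = 13, both_strands = TRUE,
                       contig = "seq") {
  pattern <- toupper(as.character(pattern))
  if (nchar(pattern) < 4) stop("pattern length must be >= 4")
  if (max_mismatch < 0 || max_mismatch >= nchar(pattern))
    stop("require 0 <= max_mismatch < pattern length")
  if (!grepl("^[ACGT]+$", pattern))
    stop("literal pattern must be over A/C/G/T")
  subject <- as_dnastring(seq)
  pat <- Biostrings::DNAString(pattern)
  out <- list()
  fw <- scan_one_strand(subject, pat, max_mismatch, fixed = TRUE)
  if (!is.null(fw))
    out$fw <- hit_frame(contig, fw$start, fw$start + nchar(pattern), "+", fw$mm)
  if (both_strands) {
    rv <- scan_one_strand(subject, Biostrings::reverseComplement(pat),
                          max_mismatch, fixed = TRUE)
    if (!is.null(rv))
      out$rv <- hit_frame(contig, rv$start, rv$start + nchar(pattern), "-",
                          rv$mm)
  }
  if (!length(out)) return(empty_hits())
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Scan a sequence for an IUPAC ambiguity motif allowing mismatches
#'
#' A position matches when the subject base belongs to the IUPAC class of
#' the pattern position; non-membership counts as a mismatch. Otherwise the
#' contract is identical to [scan_motif()].
#'
#' @inheritParams scan_motif
#' @param pattern Pattern over the IUPAC nucleotide ambiguity alphabet.
#' @export
scan_iupac <- function(seq, pattern, max_mismatch = 13, both_strands = TRUE,
                       contig = "seq") {
  pattern <- toupper(as.character(pattern))
  if (max_mismatch < 0 || max_mismatch >= nchar(pattern))
    stop("require 0 <= max_mismatch < pattern length")
  chars <- unique(strsplit(pattern, "")[[1]])
  bad <- setdiff(chars, IUPAC_CODES)
  if (length(bad)) stop("invalid IUPAC code in pattern: ", bad[1])
  subject <- as_dnastring(seq)
  pat <- Biostrings::DNAString(pattern)
  out <- list()
  fw <- scan_one_strand(subject, pat, max_mismatch, fixed = "subject")
  if (!is.null(fw))
    out$fw <- hit_frame(contig, fw$start, fw$start + nchar(pattern), "+", fw$mm)
  if (both_strands) {
    rv <- scan_one_strand(subject, Biostrings::reverseComplement(pat),
                          max_mismatch, fixed = "subject")
    if (!is.null(rv))
      out$rv <- hit_frame(contig, rv$start, rv$start + nchar(pattern), "-",
                          rv$mm)
  }
  if (!length(out)) return(empty_hits())
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Exact-word self-dotplot coordinates
#'
#' Reports all exact word matches of a sequence against itself (forward,
#' excluding the trivial main diagonal) and, optionally, against its
#' reverse complement (inverted matches). Coordinates are 0-based word
#' start positions.
#'
#' @param seq Sequence (DNAString or character).
#' @param word_size Word length (>= 4).
#' @param include_revcomp Also report inverted matches.
#' @return data.frame: x, y, strand ("+" forward off-diagonal, "-"
#'   inverted).
#' @export
self_dotplot <- function(seq, word_size = 12, include_revcomp = TRUE) {
  if (word_size < 4) stop("word_size must be >= 4")
  s <- as.character(as_dnastring(seq))
  L <- nchar(s)
  if (L < word_size)
    return(data.frame(x = integer(), y = integer(), strand = character()))
  starts <- 1:(L - word_size + 1)
  words <- substring(s, starts, starts + word_size - 1)
  res <- list()
  grp <- split(starts - 1L, words)
  pairs <- lapply(grp[lengths(grp) >= 2], function(p) {
    cmb <- utils::combn(p, 2)
    data.frame(x = cmb[1, ], y = cmb[2, ], strand = "+")
  })
  if (length(pairs)) res$fw <- do.call(rbind, pairs)
  if (include_revcomp) {
    rc <- as.character(Biostrings::reverseComplement(as_dnastring(seq)))
    rwords <- substring(rc, starts, starts + word_size - 1)
    # word at 0-based offset j in the reverse complement covers original
    # positions [L - j - word_size, L - j)
    hitlist <- lapply(which(words %in% rwords), function(i) {
      js <- which(rwords == words[i]) - 1L
      data.frame(x = rep(i - 1L, length(js)), y = L - js - word_size,
                 strand = "-")
    })
    if (length(hitlist)) {
      inv <- do.call(rbind, hitlist)
      inv <- inv[inv$x <= inv$y, , drop = FALSE]  # one record per pair
      res$rv <- inv
    }
  }
  if (!length(res))
    return(data.frame(x = integer(), y = integer(), strand = character()))
  out <- do.call(rbind, res)
  out <- out[order(out$x, out$y, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Segmentation parameters for the compound-locus segmenter
#' @param unit_min,unit_max Admissible motif-lattice period (bp).
#' @param spacer_min Minimum gap between the two arrays (bp).
#' @param min_units Minimum units per array.
#' @param unit_offset_frac Fractional offset of a unit's first motif from
#'   the unit start (shared convention with the generator).
#' @param scale Length scale applied to unit_min/unit_max/spacer_min.
#' @export
segment_params <- function(unit_min = 3000, unit_max = 8000,
                           spacer_min = 20000, min_units = 3,
                           unit_offset_frac = 0.3, scale = 1) {
  list(unit_min = unit_min * scale, unit_max = unit_max * scale,
       spacer_min = spacer_min * scale, min_units = min_units,
       unit_offset_frac = unit_offset_frac)
}

#' Segment motif hits into a compound two-array macrosatellite architecture
#'
#' Motif hits closer than `unit_min` are collapsed into per-unit hit
#' groups; consecutive groups whose start-to-start lag lies in
#' `[unit_min, unit_max]` with a repeating strand signature form an array;
#' a gap of at least `spacer_min` between the two arrays defines the
#' spacer. Unit boundaries are placed on the periodic lattice fitted to
#' each array: the fitted period is the median inter-group lag and each
#' unit starts `round(unit_offset_frac * period)` before its group.
#' The array nearer the anchor is labelled RA.
#'
#' @param hits Motif hit data.frame from [scan_motif()].
#' @param anchor Anchor-gene interval (list or one-row data.frame with
#'   start, end) lying outside the hit span.
#' @param params A [segment_params()] list.
#' @return A `repeat_architecture`: list with `arrays` (named RA/RB, each
#'   holding `units`, `motif_hits`, `period`, `signature`,
#'   `motifs_per_unit`), `spacer` and `anchor`.
#' @export
segment_macrosatellite <- function(hits, anchor, params = segment_params()) {
  if (nrow(hits) < 2) stop("no compound architecture: too few motif hits")
  hits <- hits[order(hits$start), ]
  # collapse hits into per-unit groups; motifs within one unit sit closer
  # than half the minimum admissible period
  gap <- c(Inf, diff(hits$start))
  grp_id <- cumsum(gap >= params$unit_min / 2)
  groups <- split(seq_len(nrow(hits)), grp_id)
  g_start <- vapply(groups, function(i) min(hits$start[i]), 0)
  g_sig <- vapply(groups, function(i)
    paste(hits$strand[i], collapse = ""), "")
  m <- length(groups)
  # runs of consecutive groups with admissible lag and constant signature
  runs <- list()
  run <- 1L
  for (i in seq_len(m)[-1]) {
    lag <- g_start[i] - g_start[i - 1]
    if (lag >= params$unit_min && lag <= params$unit_max &&
        g_sig[i] == g_sig[i - 1]) {
      run <- c(run, i)
    } else {
      runs[[length(runs) + 1]] <- run
      run <- i
    }
  }
  runs[[length(runs) + 1]] <- run
  arrays <- Filter(function(r) length(r) >= params$min_units, runs)
  if (length(arrays) < 2) stop("no compound architecture: fewer than 2 arrays")
  if (length(arrays) > 2) {
    ord <- order(-lengths(arrays), vapply(arrays, function(r) g_start[r[1]], 0))
    arrays <- arrays[sort(ord[1:2])]
  }
  arrays <- arrays[order(vapply(arrays, function(r) g_start[r[1]], 0))]

  build_array <- function(r) {
    st <- g_start[r]
    period <- round(median(diff(st)))
    offset <- round(params$unit_offset_frac * period)
    unit_start <- as.integer(round(st) - offset)
    units <- data.frame(start = unit_start,
                        end = unit_start + as.integer(period))
    mh <- hits[unlist(groups[r]), , drop = FALSE]
    list(units = units, motif_hits = mh, period = period,
         signature = unname(g_sig[r[1]]),
         motifs_per_unit = nchar(unname(g_sig[r[1]])),
         span = c(units$start[1], units$end[nrow(units)]))
  }
  a1 <- build_array(arrays[[1]])
  a2 <- build_array(arrays[[2]])
  gap_between <- a2$span[1] - a1$span[2]
  if (gap_between < params$spacer_min)
    stop("no compound architecture: arrays not separated by a spacer")
  anchor_mid <- (anchor$start + anchor$end) / 2
  d1 <- min(abs(anchor_mid - a1$span))
  d2 <- min(abs(anchor_mid - a2$span))
  if (d1 <= d2) {
    ra <- a1; rb <- a2
  } else {
    ra <- a2; rb <- a1
  }
  label_units <- function(a, lab) {
    a$units$name <- sprintf("%s-%d", lab, seq_len(nrow(a$units)))
    a$label <- lab
    a
  }
  ra <- label_units(ra, "RA")
  rb <- label_units(rb, "RB")
  spacer <- c(start = a1$span[2], end = a2$span[1])
  out <- list(arrays = list(RA = ra, RB = rb), spacer = spacer,
              anchor = anchor)
  class(out) <- "repeat_architecture"
  out
}

#' Extract repeat-unit sequences from a genome given an architecture
#'
#' Units within an array share a length (substitution-only divergence), so
#' within-array units are returned already aligned; across arrays the
#' shorter units are right-padded with gaps to the longest unit, giving a
#' simple truth alignment adequate for low-divergence units.
#'
#' @param genome `annotated_genome` or named DNAStringSet.
#' @param architecture A `repeat_architecture`.
#' @param contig Contig holding the locus.
#' @return Named character vector of gapped, equal-length unit sequences
#'   with a `groups` attribute (RA/RB per unit).
#' @export
extract_unit_alignment <- function(genome, architecture, contig = "X") {
  seqs <- if (inherits(genome, "annotated_genome")) genome$seqs else genome
  s <- as.character(seqs[[contig]])
  units <- list()
  groups <- character()
  for (lab in names(architecture$arrays)) {
    a <- architecture$arrays[[lab]]
    for (i in seq_len(nrow(a$units))) {
      units[[a$units$name[i]]] <- substr(s, a$units$start[i] + 1,
                                         a$units$end[i])
      groups <- c(groups, lab)
    }
  }
  maxlen <- max(nchar(unlist(units)))
  aln <- vapply(units, function(u)
    paste0(u, strrep("-", maxlen - nchar(u))), "")
  attr(aln, "groups") <- setNames(groups, names(aln))
  aln
}

# classic dinucleotide transition tables for CpG-island vs background
# states (island keeps CpG; background suppresses it)
cpg_emission_defaults <- function() {
  island <- matrix(c(0.180, 0.274, 0.426, 0.120,
                     0.171, 0.368, 0.274, 0.188,
                     0.161, 0.339, 0.375, 0.125,
                     0.079, 0.355, 0.384, 0.182),
                   4, 4, byrow = TRUE,
                   dimnames = list(c("A", "C", "G", "T"),
                                   c("A", "C", "G", "T")))
  background <- matrix(c(0.300, 0.205, 0.285, 0.210,
                         0.322, 0.298, 0.078, 0.302,
                         0.248, 0.246, 0.298, 0.208,
                         0.177, 0.239, 0.292, 0.292),
                       4, 4, byrow = TRUE,
                       dimnames = dimnames(island))
  list(island = island, background = background)
}

logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log(exp(a - m) + exp(b - m)))
}

#' Detect CpG islands with a two-state forward-backward HMM
#'
#' A two-state (island/background) hidden Markov model with first-order
#' (dinucleotide) emissions is evaluated by the forward-backward algorithm
#' in log space; islands are maximal runs of positions whose island
#' posterior exceeds 0.5, at least `min_len` long.
#'
#' @param seq Sequence (DNAString or character).
#' @param persistence Per-base probability of staying in the current state
#'   (default 1 - 1e-4).
#' @param emissions List with `island` and `background` 4x4 conditional
#'   emission matrices (rows: previous base; columns: next base). Defaults
#'   to classic CpG-island dinucleotide tables.
#' @param min_len Minimum island length (bp).
#' @param init Initial state distribution c(island, background).
#' @param return_posterior Also return the per-base island posterior.
#' @return data.frame of islands (start, end, 0-based half-open;
#'   mean_posterior), or a list with `islands` and `posterior` when
#'   `return_posterior = TRUE`.
#' @export
detect_cpg_islands <- function(seq, persistence = 1 - 1e-4,
                               emissions = cpg_emission_defaults(),
                               min_len = 200, init = c(0.5, 0.5),
                               return_posterior = FALSE) {
  for (nm in c("island", "background")) {
    e <- emissions[[nm]]
    if (any(rowSums(e) <= 0) || any(e < 0))
      stop("degenerate emission parameters in ", nm, " matrix")
  }
  s <- strsplit(toupper(as.character(as_dnastring(seq))), "")[[1]]
  n <- length(s)
  if (n == 0) stop("empty sequence")
  bidx <- match(s, c("A", "C", "G", "T"))  # NA for N
  # per-position log emission under each state: first base uniform; N's
  # and transitions from N are uninformative (0.25)
  le <- matrix(log(0.25), nrow = n, ncol = 2)
  if (n > 1) {
    prev <- bidx[-n]
    cur <- bidx[-1]
    ok <- !is.na(prev) & !is.na(cur)
    le[-1, 1][ok] <- log(emissions$island[cbind(prev[ok], cur[ok])])
    le[-1, 2][ok] <- log(emissions$background[cbind(prev[ok], cur[ok])])
  }
  lt_stay <- log(persistence)
  lt_switch <- log(1 - persistence)
  # forward
  la <- matrix(-Inf, n, 2)
  la[1, ] <- log(init) + le[1, ]
  if (n > 1) for (i in 2:n) {
    la[i, 1] <- logsumexp2(la[i - 1, 1] + lt_stay, la[i - 1, 2] + lt_switch) +
      le[i, 1]
    la[i, 2] <- logsumexp2(la[i - 1, 1] + lt_switch, la[i - 1, 2] + lt_stay) +
      le[i, 2]
  }
  # backward
  lb <- matrix(0, n, 2)
  if (n > 1) for (i in (n - 1):1) {
    lb[i, 1] <- logsumexp2(lt_stay + le[i + 1, 1] + lb[i + 1, 1],
                           lt_switch + le[i + 1, 2] + lb[i + 1, 2])
    lb[i, 2] <- logsumexp2(lt_switch + le[i + 1, 1] + lb[i + 1, 1],
                           lt_stay + le[i + 1, 2] + lb[i + 1, 2])
  }
  lpost <- la + lb
  post <- 1 / (1 + exp(lpost[, 2] - lpost[, 1]))  # island posterior
  in_island <- post > 0.5
  r <- rle(in_island)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_len
  islands <- data.frame(start = starts[keep], end = ends[keep])
  islands$mean_posterior <- vapply(seq_len(nrow(islands)), function(i)
    mean(post[(islands$start[i] + 1):islands$end[i]]), 0)
  if (return_posterior) list(islands = islands, posterior = post) else islands
}

#' CpG islands by the Gardiner-Garden rule (secondary detector)
#'
#' Sliding-window screen for GC content > 50%, observed/expected CpG > 0.6
#' and length >= `min_len`; overlapping qualifying windows are merged.
#'
#' @param seq Sequence.
#' @param window Window size (bp).
#' @param step Step size (bp).
#' @param min_len Minimum merged length.
#' @export
cpg_islands_gg <- function(seq, window = 200, step = 50, min_len = 200) {
  s <- toupper(as.character(as_dnastring(seq)))
  L <- nchar(s)
  if (L < window) return(data.frame(start = integer(), end = integer()))
  starts <- seq(0, L - window, by = step)
  qual <- vapply(starts, function(st) {
    w <- substr(s, st + 1, st + window)
    g <- lengths(regmatches(w, gregexpr("G", w, fixed = TRUE)))
    c_ <- lengths(regmatches(w, gregexpr("C", w, fixed = TRUE)))
    cg <- lengths(regmatches(w, gregexpr("CG", w, fixed = TRUE)))
    gc <- (g + c_) / window
    obs_exp <- if (g * c_ > 0) cg * window / (g * c_) else 0
    gc > 0.5 && obs_exp > 0.6
  }, TRUE)
  if (!any(qual)) return(data.frame(start = integer(), end = integer()))
  iv <- IRanges::reduce(IRanges::IRanges(start = starts[qual] + 1,
                                         width = window))
  out <- data.frame(start = BiocGenerics::start(iv) - 1L,
                    end = BiocGenerics::end(iv))
  out[out$end - out$start >= min_len, , drop = FALSE]
}

#' Pairwise p-distances with gap-column masking
#'
#' Columns whose gap fraction exceeds `gap_mask_fraction` are removed;
#' for each pair, p is the mismatch fraction over the remaining columns
#' where both sequences are ungapped.
#'
#' @param aln Named character vector of equal-length aligned sequences
#'   (gaps as "-"), e.g. from [extract_unit_alignment()].
#' @param gap_mask_fraction Maximum tolerated per-column gap fraction.
#' @param groups Optional group label per sequence (defaults to the `groups`
#'   attribute of `aln` if present).
#' @return A `distance_matrix`: list with `labels`, `matrix` (symmetric,
#'   zero diagonal) and `groups`.
#' @export
pairwise_p_distance <- function(aln, gap_mask_fraction = 0.10,
                                groups = NULL) {
  if (is.null(groups)) groups <- attr(aln, "groups")
  labs <- names(aln)
  if (is.null(labs)) labs <- sprintf("seq%d", seq_along(aln))
  lens <- nchar(aln)
  if (length(unique(lens)) != 1) stop("aligned rows must share a length")
  M <- do.call(rbind, strsplit(unname(aln), ""))
  gapfrac <- colMeans(M == "-")
  M <- M[, gapfrac <= gap_mask_fraction, drop = FALSE]
  n <- length(aln)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- M[i, ] != "-" & M[j, ] != "-"
      if (!any(ok)) stop("zero comparable columns for pair ",
                         labs[i], " vs ", labs[j])
      p <- mean(M[i, ok] != M[j, ok])
      D[i, j] <- D[j, i] <- p
    }
  }
  structure(list(labels = labs, matrix = D,
                 groups = if (is.null(groups)) NULL else
                   setNames(unname(groups), labs)),
            class = "distance_matrix")
}

#' Within- and between-group mean distances
#'
#' @param dm A `distance_matrix` with group assignments.
#' @return List with `within` (named mean per group; `NA` when a group has
#'   fewer than 2 members) and `between` (mean over all cross-group pairs).
#' @export
group_distance_summary <- function(dm) {
  stopifnot(inherits(dm, "distance_matrix"), !is.null(dm$groups))
  g <- dm$groups[dm$labels]
  D <- dm$matrix
  n <- length(g)
  ut <- upper.tri(D)
  same <- outer(g, g, "==") & ut
  cross <- outer(g, g, "!=") & ut
  within <- vapply(unique(g), function(gr) {
    sel <- outer(g == gr, g == gr, "&") & ut
    if (sum(sel) == 0) NA_real_ else mean(D[sel])
  }, 0)
  list(within = within,
       between = if (any(cross)) mean(D[cross]) else NA_real_)
}

#' Neighbour-joining tree from a distance matrix, with optional bootstrap
#'
#' Standard neighbour joining (on additive matrices the tree's path lengths
#' reproduce the input distances). Bootstrap support resamples alignment
#' columns, recomputes the masked p-distance matrix and tree per replicate,
#' and reports per-split support in `[0, 100]`.
#'
#' @param dm A `distance_matrix`.
#' @param bootstrap Optional list with `replicates`, `seed` and `alignment`
#'   (the gapped alignment the distances came from).
#' @param gap_mask_fraction Mask fraction used for bootstrap distance
#'   recomputation.
#' @return List with `tree` (ape phylo, node labels carry support when
#'   bootstrapped) and `newick`.
#' @export
build_nj_tree <- function(dm, bootstrap = NULL, gap_mask_fraction = 0.10) {
  stopifnot(inherits(dm, "distance_matrix"))
  n <- length(dm$labels)
  if (n < 3) stop("neighbour joining needs at least 3 taxa")
  tree <- ape::nj(dm$matrix)
  if (!is.null(bootstrap)) {
    aln <- bootstrap$alignment
    B <- bootstrap$replicates
    stopifnot(!is.null(aln), !is.null(B))
    M <- do.call(rbind, strsplit(unname(aln), ""))
    trees <- with_seed(derive_seed(bootstrap$seed %||% 1, "bootstrap"), {
      lapply(seq_len(B), function(b) {
        cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
        res <- apply(M[, cols, drop = FALSE], 1, paste, collapse = "")
        names(res) <- names(aln)
        ape::nj(pairwise_p_distance(res, gap_mask_fraction)$matrix)
      })
    })
    cnt <- ape::prop.clades(tree, trees, rooted = FALSE)
    cnt[is.na(cnt)] <- 0
    tree$node.label <- round(100 * cnt / B)
  }
  list(tree = tree, newick = ape::write.tree(tree))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
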