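# Y-contig classification from depletion of female read coverage.

#' Per-contig coverage-depletion profile
#'
#' For each contig and threshold T, the fraction of nucleotide positions
#' with depth at or below T. Fractions are non-decreasing in T.
#'
#' @param track `depth_track` of female reads over male assembly contigs.
#' @param thresholds Depth thresholds (default 0/5/10/15).
#' @return data.frame: contig, length, and one `frac_le_T` column per
#'   threshold.
#' @export
coverage_profile <- function(track, thresholds = c(0, 5, 10, 15)) {
  thresholds <- sort(thresholds)
  rows <- lapply(names(track$depth), function(ctg) {
    v <- track$depth[[ctg]]
    if (length(v) == 0) stop("contig of length 0: ", ctg)
    fr <- vapply(thresholds, function(T) mean(v <= T), 0)
    out <- data.frame(contig = ctg, length = length(v))
    for (i in seq_along(thresholds))
      out[[sprintf("frac_le_%d", thresholds[i])]] <- fr[i]
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "thresholds") <- thresholds
  out
}

#' Derive a fraction cutoff from seed contigs of known Y homology
#'
#' The cutoff is the mean fraction of the seed contigs at the primary
#' threshold minus the margin (25 percentage points by default, mirroring
#' the 70-100% extraction band that arises from seed means near 0.95),
#' clipped to (0, 1]. A histogram of all contig fractions is returned for
#' the bimodality check.
#'
#' @param profiles Output of [coverage_profile()].
#' @param seed_contigs Contig ids of known Y-linked seed contigs.
#' @param margin Margin subtracted from the seed mean (fraction scale).
#' @param primary_threshold Depth threshold used for the cutoff.
#' @param bins Histogram bin count over [0, 1].
#' @return List with `cutoff`, `seed_mean` and `histogram` (bin_start,
#'   bin_end, count).
#' @export
derive_cutoff <- function(profiles, seed_contigs, margin = 0.25,
                          primary_threshold = 15, bins = 20) {
  if (length(seed_contigs) == 0) stop("empty seed contig set")
  col <- sprintf("frac_le_%d", primary_threshold)
  if (!col %in% names(profiles)) stop("threshold not profiled: ",
                                      primary_threshold)
  sel <- profiles$contig %in% seed_contigs
  if (!any(sel)) stop("no seed contig found in profiles")
  seed_mean <- mean(profiles[[col]][sel])
  cutoff <- min(max(seed_mean - margin, .Machine$double.eps), 1)
  breaks <- seq(0, 1, length.out = bins + 1)
  cnt <- table(cut(profiles[[col]], breaks, include.lowest = TRUE))
  list(cutoff = cutoff, seed_mean = seed_mean,
       histogram = data.frame(bin_start = breaks[-length(breaks)],
                              bin_end = breaks[-1],
                              count = as.integer(cnt)))
}

#' Best homology hit per contig from a 12-column hit table
#' @param hits Hit table from [read_hits()].
#' @param class Class label attached to these hits (e.g. "Y", "reference").
#' @return data.frame: contig, class, subject, pct_identity, bitscore
#'   (highest bitscore per contig).
#' @export
best_hits <- function(hits, class) {
  sp <- split(hits, hits$query)
  rows <- lapply(sp, function(h) {
    b <- h[which.max(h$bitscore), ]
    data.frame(contig = b$query, class = class, subject = b$subject,
               pct_identity = b$pct_identity, bitscore = b$bitscore,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify contigs as Y-candidate / not-Y / ambiguous
#'
#' A contig is a Y-candidate when its coverage-depletion fraction reaches
#' the cutoff, or falls within `ambiguous_band` below it while its best
#' homology hit is to the Y class; it is not-Y when the fraction falls
#' below `cutoff - ambiguous_band` and the best hit (if homology evidence
#' is supplied) is not to the Y class; everything else is ambiguous. With
#' no evidence table at all, low-fraction contigs are called not-Y on
#' coverage alone.
#'
#' @param profiles Output of [coverage_profile()].
#' @param cutoff Fraction cutoff (from [derive_cutoff()]).
#' @param evidence Optional data.frame of best hits per contig with
#'   columns contig, class, bitscore (rows from [best_hits()], possibly
#'   several classes per contig).
#' @param primary_threshold Depth threshold used for the call.
#' @param ambiguous_band Width of the ambiguous fraction band.
#' @param y_class Evidence class name counting as Y support.
#' @return data.frame sorted by fraction descending (ties by contig id):
#'   contig, length, fraction, call, best_class, best_bitscore.
#' @export
classify_contigs <- function(profiles, cutoff, evidence = NULL,
                             primary_threshold = 15, ambiguous_band = 0.1,
                             y_class = "Y") {
  col <- sprintf("frac_le_%d", primary_threshold)
  fraction <- profiles[[col]]
  best_class <- rep(NA_character_, nrow(profiles))
  best_score <- rep(NA_real_, nrow(profiles))
  if (!is.null(evidence) && nrow(evidence)) {
    sp <- split(evidence, evidence$contig)
    for (ctg in names(sp)) {
      i <- which(profiles$contig == ctg)
      if (!length(i)) next
      b <- sp[[ctg]][which.max(sp[[ctg]]$bitscore), ]
      best_class[i] <- b$class
      best_score[i] <- b$bitscore
    }
  }
  call <- character(nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    y_hit <- !is.na(best_class[i]) && best_class[i] == y_class
    nonyhit <- !is.na(best_class[i]) && best_class[i] != y_class
    if (fraction[i] >= cutoff || (fraction[i] >= cutoff - ambiguous_band &&
                                  y_hit)) {
      call[i] <- "Y-candidate"
    } else if (fraction[i] < cutoff - ambiguous_band &&
               (nonyhit || is.null(evidence))) {
      call[i] <- "not-Y"
    } else {
      call[i] <- "ambiguous"
    }
  }
  out <- data.frame(contig = profiles$contig, length = profiles$length,
                    fraction = fraction, call = call,
                    best_class = best_class, best_bitscore = best_score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fraction, out$contig), ]
  rownames(out) <- NULL
  out
}
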