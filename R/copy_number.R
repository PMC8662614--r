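# Copy-number estimation from read depth over collapsed tandem repeats,
# normalised to genome-wide depth with a single-copy control gene.

#' Collapse each repeat array to a single representative unit
#'
#' The representative of each array is the unit minimising the mean
#' p-distance to its array peers (ties broken leftmost); the array span is
#' replaced by that single unit in the modified reference, shifting all
#' downstream feature coordinates consistently. Optionally the divergent
#' first RA unit is kept as its own feature upstream of the representative.
#'
#' @param genome `annotated_genome`.
#' @param architecture A `repeat_architecture` on the same contig.
#' @param contig Contig holding the arrays.
#' @param keep_ra1 Keep RA-1 as a separate collapsed feature.
#' @return List with `seqs` (modified DNAStringSet), `collapse_map`
#'   (data.frame: label, contig, start, end in the modified reference,
#'   n_units, original_start, original_end) and `features` (input truth
#'   features with shifted coordinates; features inside a replaced array
#'   span are dropped).
#' @export
collapse_reference <- function(genome, architecture, contig = "X",
                               keep_ra1 = FALSE) {
  if (is.null(architecture)) stop("architecture absent")
  seqs <- genome$seqs
  s <- as.character(seqs[[contig]])
  aln <- extract_unit_alignment(genome, architecture, contig)
  groups <- attr(aln, "groups")

  pick_representative <- function(lab) {
    members <- names(aln)[groups == lab]
    if (length(members) == 1) return(members)
    dm <- pairwise_p_distance(aln[members],
                              groups = setNames(rep(lab, length(members)),
                                                members))
    rowmean <- rowSums(dm$matrix) / (length(members) - 1)
    members[which.min(rowmean)]  # which.min takes the first = leftmost
  }

  pieces <- list()
  map <- list()
  cursor <- 0L  # 0-based position in the original sequence
  new_cursor <- 0L
  arrays <- architecture$arrays[order(vapply(architecture$arrays,
                                             function(a) a$span[1], 0))]
  for (a in arrays) {
    lab <- a$label
    rep_name <- pick_representative(lab)
    rep_row <- which(a$units$name == rep_name)
    pieces[[length(pieces) + 1]] <- substr(s, cursor + 1, a$span[1])
    new_cursor <- new_cursor + (a$span[1] - cursor)
    if (keep_ra1 && lab == "RA" && rep_name != "RA-1") {
      ra1 <- a$units[a$units$name == "RA-1", ]
      pieces[[length(pieces) + 1]] <- substr(s, ra1$start + 1, ra1$end)
      map[[length(map) + 1]] <- data.frame(
        label = "RA-1", contig = contig, start = new_cursor,
        end = new_cursor + (ra1$end - ra1$start), n_units = 1L,
        representative = "RA-1",
        original_start = ra1$start, original_end = ra1$end)
      new_cursor <- new_cursor + (ra1$end - ra1$start)
    }
    u <- a$units[rep_row, ]
    pieces[[length(pieces) + 1]] <- substr(s, u$start + 1, u$end)
    map[[length(map) + 1]] <- data.frame(
      label = lab, contig = contig, start = new_cursor,
      end = new_cursor + (u$end - u$start),
      n_units = nrow(a$units), representative = rep_name,
      original_start = a$span[1], original_end = a$span[2])
    new_cursor <- new_cursor + (u$end - u$start)
    cursor <- a$span[2]
  }
  pieces[[length(pieces) + 1]] <- substr(s, cursor + 1, nchar(s))
  new_seq <- paste(pieces, collapse = "")

  # shift feature coordinates from original to modified reference
  spans <- do.call(rbind, lapply(arrays, function(a)
    data.frame(ostart = a$span[1], oend = a$span[2])))
  mapdf <- do.call(rbind, map)
  shift_pos <- function(p) {
    # cumulative bases removed before original position p
    removed <- 0
    for (i in seq_len(nrow(spans))) {
      if (p >= spans$oend[i]) {
        kept <- sum(mapdf$end[mapdf$original_start >= spans$ostart[i] &
                                mapdf$original_end <= spans$oend[i]] -
                      mapdf$start[mapdf$original_start >= spans$ostart[i] &
                                    mapdf$original_end <= spans$oend[i]])
        removed <- removed + (spans$oend[i] - spans$ostart[i]) - kept
      }
    }
    p - removed
  }
  feats <- genome$features
  on_ctg <- feats$contig == contig
  inside <- on_ctg & vapply(seq_len(nrow(feats)), function(i) {
    any(feats$start[i] < spans$oend & feats$end[i] > spans$ostart)
  }, TRUE)
  feats <- feats[!inside, , drop = FALSE]
  sel <- feats$contig == contig
  feats$start[sel] <- vapply(feats$start[sel], shift_pos, 0)
  feats$end[sel] <- vapply(feats$end[sel], shift_pos, 0)

  new_seqs <- as.character(seqs)
  new_seqs[[contig]] <- new_seq
  out_seqs <- Biostrings::DNAStringSet(new_seqs)
  list(seqs = out_seqs, collapse_map = mapdf, features = feats)
}

#' Mean per-base depth over a feature interval
#' @param track `depth_track`.
#' @param feature List/one-row data.frame with contig, start, end (0-based
#'   half-open).
#' @export
mean_feature_depth <- function(track, feature) {
  v <- track$depth[[feature$contig]]
  if (is.null(v)) stop("contig not in track: ", feature$contig)
  if (feature$start < 0 || feature$end > length(v) ||
      feature$start >= feature$end)
    stop("feature outside contig ", feature$contig)
  mean(v[(feature$start + 1):feature$end])
}

#' Genome-wide mean depth of a track
#' @param track `depth_track`.
#' @param exclude Contigs excluded from the mean (e.g. the spike-in).
#' @export
genome_mean_depth <- function(track, exclude = "lambda") {
  keep <- setdiff(names(track$depth), exclude)
  if (!length(keep)) stop("empty track")
  tot <- sum(vapply(track$depth[keep], function(v) sum(as.numeric(v)), 0))
  n <- sum(vapply(track$depth[keep], length, 0L))
  if (n == 0) stop("empty track")
  tot / n
}

#' Estimate per-haplotype repeat copy number from a collapsed reference
#'
#' For each collapsed array, `raw_ratio` is the mean depth over the
#' representative unit divided by genome-wide mean depth; `control_ratio`
#' is computed identically for a single-copy X control gene
#' (expected ~0.5 in hemizygous males, ~1.0 in diploid females); the
#' per-haplotype copy number is `cn = raw_ratio / control_ratio`. Dividing
#' female raw ratios by 2 — the uncorrected convention — is recoverable
#' from `raw_ratio` directly.
#'
#' @param track `depth_track` over the modified (collapsed) reference.
#' @param collapse_map Collapse map from [collapse_reference()] (or any
#'   data.frame with label, contig, start, end on the track).
#' @param control Control-gene interval on the X (contig, start, end).
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param exclude Contigs excluded from the genome mean.
#' @return data.frame: label, raw_ratio, control_ratio, cn,
#'   ploidy_divisor, ploidy_caveat.
#' @export
estimate_copy_number <- function(track, collapse_map, control,
                                 sex = track$sex, exclude = "lambda") {
  gmean <- genome_mean_depth(track, exclude = exclude)
  cmean <- mean_feature_depth(track, control)
  control_ratio <- cmean / gmean
  if (control_ratio <= 0) stop("control_ratio <= 0")
  ploidy_divisor <- if (identical(sex, "female")) 2L else 1L
  caveat <- !sex %in% c("male", "female")
  out <- lapply(seq_len(nrow(collapse_map)), function(i) {
    f <- collapse_map[i, ]
    raw <- mean_feature_depth(track, f) / gmean
    data.frame(label = f$label, raw_ratio = raw,
               control_ratio = control_ratio,
               cn = raw / control_ratio,
               ploidy_divisor = ploidy_divisor,
               ploidy_caveat = caveat, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
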