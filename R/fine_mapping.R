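# X-linked ancestry fine-mapping in a hemizygous backcross cohort, plus
# GWAS-threshold utilities.

#' Flag markers against the genome-wide significance threshold
#'
#' Transforms p values to -log10 and flags those meeting the uncorrected
#' threshold (default 5e-5, i.e. -log10 p = 4.30).
#'
#' @param p Numeric p values in (0, 1].
#' @param threshold_p Uncorrected significance threshold.
#' @param marker Optional marker ids.
#' @param position Optional positions.
#' @return data.frame: marker, position, p, neg_log10_p, pass.
#' @export
flag_gwas <- function(p, threshold_p = 5e-5, marker = NULL, position = NULL) {
  if (any(p <= 0 | p > 1)) stop("p values must lie in (0, 1]")
  nlp <- -log10(p)
  thr <- -log10(threshold_p)
  data.frame(marker = marker %||% sprintf("m%d", seq_along(p)),
             position = position %||% NA_integer_,
             p = p, neg_log10_p = nlp, pass = nlp >= thr,
             stringsAsFactors = FALSE)
}

cohort_calls <- function(cohort) {
  geno <- cohort$genotypes
  ind <- cohort$phenotypes$individual
  m <- as.matrix(geno[, ind, drop = FALSE])
  m[!m %in% c("D", "J")] <- NA
  list(calls = m, position = geno$position, marker = geno$marker,
       phenotype = setNames(cohort$phenotypes$phenotype, ind))
}

#' Per-marker ancestry-phenotype association
#'
#' For each marker, the 2x2 phenotype-by-ancestry table (missing calls
#' excluded), its two-sided Fisher exact p, and the concordance: the
#' fraction of individuals whose ancestry matches the phenotype-predicted
#' state (J if sterile, D if fertile).
#'
#' @param cohort List with `genotypes` (marker, position, one column per
#'   individual with calls in D/J) and `phenotypes` (individual,
#'   phenotype), as from [simulate_cohort()].
#' @return data.frame: marker, position, sterile_J, sterile_D, fertile_J,
#'   fertile_D, concordance, p.
#' @export
marker_association <- function(cohort) {
  cc <- cohort_calls(cohort)
  sterile <- cc$phenotype[colnames(cc$calls)] == "sterile"
  rows <- lapply(seq_along(cc$marker), function(i) {
    g <- cc$calls[i, ]
    ok <- !is.na(g)
    sJ <- sum(ok & sterile & g == "J")
    sD <- sum(ok & sterile & g == "D")
    fJ <- sum(ok & !sterile & g == "J")
    fD <- sum(ok & !sterile & g == "D")
    n <- sJ + sD + fJ + fD
    conc <- (sJ + fD) / n
    tab <- matrix(c(sJ, sD, fJ, fD), 2, byrow = TRUE)
    p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1 else
      fisher.test(tab)$p.value
    data.frame(marker = cc$marker[i], position = cc$position[i],
               sterile_J = sJ, sterile_D = sD, fertile_J = fJ,
               fertile_D = fD, concordance = conc, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scan for the critical ancestry interval
#'
#' Selects the maximal run of consecutive markers achieving the
#' cohort-wide maximum concordance (ties broken by longest run, then
#' leftmost); the interval spans the first to last marker of that run.
#' Counts and the Fisher exact p are reported for the run's consensus
#' ancestry pattern (an individual counts as J/D when all its non-missing
#' calls across the run agree).
#'
#' @param cohort Cohort list as for [marker_association()].
#' @return List with `start`, `end` (marker positions), `length_bp`,
#'   `markers`, `max_concordance`, `sterile_J`, `sterile_total`,
#'   `fertile_D`, `fertile_total` and `fisher_p`.
#' @export
scan_critical_interval <- function(cohort) {
  assoc <- marker_association(cohort)
  maxc <- max(assoc$concordance)
  if (maxc <= 0.5) stop("no associated region")
  at_max <- abs(assoc$concordance - maxc) < 1e-9
  r <- rle(at_max)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values)
  lens <- r$lengths[cand]
  best <- cand[which.max(lens)]  # longest run, first (leftmost) on ties
  run <- starts[best]:ends[best]

  cc <- cohort_calls(cohort)
  sterile <- cc$phenotype[colnames(cc$calls)] == "sterile"
  sub <- cc$calls[run, , drop = FALSE]
  state <- apply(sub, 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) NA_character_
    else if (all(g == "J")) "J" else if (all(g == "D")) "D" else "mixed"
  })
  sJ <- sum(sterile & state == "J", na.rm = TRUE)
  fD <- sum(!sterile & state == "D", na.rm = TRUE)
  tab <- matrix(c(sJ, sum(sterile) - sJ,
                  sum(!sterile & state == "J", na.rm = TRUE),
                  sum(!sterile) - sum(!sterile & state == "J", na.rm = TRUE)),
                2, byrow = TRUE)
  fisher_p <- fisher.test(tab)$p.value
  list(start = assoc$position[run[1]],
       end = assoc$position[run[length(run)]],
       length_bp = assoc$position[run[length(run)]] - assoc$position[run[1]],
       markers = assoc$marker[run],
       max_concordance = maxc,
       sterile_J = sJ, sterile_total = sum(sterile),
       fertile_D = fD, fertile_total = sum(!sterile),
       fisher_p = fisher_p)
}
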