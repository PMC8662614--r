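# Synthetic data generators. Every downstream stage of the pipeline can be
# exercised on these outputs; truth annotations always accompany the data.

#' Conserved CTCF motif consensus (literal, 34 bp)
#' @export
ctcf_motif <- function() "GAGTTTCGCTTGATGGCAGTGTTGCACCACGAAT"

#' Conserved CTCF motif consensus (IUPAC ambiguity form, 34 bp)
#' @export
ctcf_motif_iupac <- function() "VVNYTYYKSTKGRYGGCRVYRBWGYHCYRSVAAT"

# run expr with a fixed RNG seed, restoring the caller's RNG state after
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# single-hit substitution: each site mutates with probability rate, uniformly
# to one of the three other bases; expected p-distance to the input ~ rate
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- runif(length(v)) < rate
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(bases, b), 1L), "")
  }
  paste(v, collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

plant <- function(seq, insert, at) {
  # overwrite seq with insert at 0-based offset `at`
  stopifnot(at + nchar(insert) <= nchar(seq))
  paste0(substr(seq, 1, at), insert,
         substr(seq, at + nchar(insert) + 1, nchar(seq)))
}

#' Specification of the compound macrosatellite locus
#'
#' Defaults follow the felid locus: two tandem arrays of ~4.5/4.6 kb units
#' flanked around a ~33 kb spacer carrying five CTCF motifs, a single
#' reverse-strand motif in every RA unit and two opposed motifs in every RB
#' unit. `scale` shrinks all lengths (units, spacer, flanks) for fast tests
#' while keeping the 34-bp motif intact. Divergence knobs are target
#' pairwise p-distances.
#'
#' @param n_units_A,n_units_B Unit counts of the two arrays.
#' @param unit_len_A,unit_len_B Unit lengths in bp (before scaling).
#' @param spacer_len Spacer length in bp (before scaling).
#' @param motif Literal motif planted in units and spacer.
#' @param within_array_div Target pairwise p-distance among RA units.
#' @param within_array_div_B Target pairwise p-distance among RB units.
#' @param between_array_div Target RA-vs-RB consensus p-distance.
#' @param between_species_div Interspecific divergence knob (used by unit
#'   simulations across species; not used in single-genome builds).
#' @param ra1_div_multiplier Extra divergence multiplier for the first
#'   (most proximal) RA unit, which forms a divergent clade in real data.
#' @param unit_offset_frac Fractional offset of each unit's (first) motif
#'   from the unit start; shared convention with the segmenter.
#' @param scale Length scale knob (1 = full size, 0.1 for desk-scale tests).
#' @export
locus_spec <- function(n_units_A = 9, n_units_B = 12,
                       unit_len_A = 4554, unit_len_B = 4607,
                       spacer_len = 33000,
                       motif = ctcf_motif(),
                       within_array_div = 0.028,
                       within_array_div_B = 0.013,
                       between_array_div = 0.424,
                       between_species_div = 0.026,
                       ra1_div_multiplier = 3,
                       unit_offset_frac = 0.3,
                       scale = 1) {
  spec <- list(
    n_units_A = as.integer(n_units_A), n_units_B = as.integer(n_units_B),
    unit_len_A = as.integer(round(unit_len_A * scale)),
    unit_len_B = as.integer(round(unit_len_B * scale)),
    spacer_len = as.integer(round(spacer_len * scale)),
    motif = toupper(motif),
    within_array_div = within_array_div,
    within_array_div_B = within_array_div_B,
    between_array_div = between_array_div,
    between_species_div = between_species_div,
    ra1_div_multiplier = ra1_div_multiplier,
    unit_offset_frac = unit_offset_frac,
    scale = scale
  )
  stopifnot(spec$n_units_A >= 1, spec$n_units_B >= 1,
            spec$unit_len_A > 0, spec$unit_len_B > 0, spec$spacer_len > 0)
  divs <- c(spec$within_array_div, spec$within_array_div_B,
            spec$between_array_div, spec$between_species_div)
  if (any(divs < 0) || any(divs >= 1)) stop("divergences must lie in [0, 1)")
  if (min(spec$unit_len_A, spec$unit_len_B) < nchar(spec$motif))
    stop("unit length shorter than motif")
  class(spec) <- "locus_spec"
  spec
}

#' Specification of the sexed genome surrounding the locus
#'
#' @param autosome_lengths Named vector of autosome lengths in bp.
#' @param x_len Minimum X length in bp (the X is extended if the locus and
#'   control gene need more room).
#' @param y_lengths Named vector of Y contig lengths (male-only depth).
#' @param control_len Length of the single-copy X control gene (DMD-like).
#' @param lambda_len Length of the unmethylated spike-in contig (phage
#'   lambda, 48,502 bp full scale).
#' @param scale Length scale knob applied to all lengths except the motif.
#' @export
sexed_genome_spec <- function(autosome_lengths = c(A1 = 100000, A2 = 100000),
                              x_len = 50000,
                              y_lengths = c(Y1 = 30000, Y2 = 20000),
                              control_len = 10000,
                              lambda_len = 48502,
                              scale = 1) {
  spec <- list(
    autosome_lengths = round(autosome_lengths * scale),
    x_len = round(x_len * scale),
    y_lengths = round(y_lengths * scale),
    control_len = round(control_len * scale),
    lambda_len = round(lambda_len * scale),
    scale = scale
  )
  stopifnot(all(spec$autosome_lengths > 0), spec$control_len > 0,
            spec$lambda_len > 0)
  class(spec) <- "sexed_genome_spec"
  spec
}

# fractional spacer motif positions: irregular on purpose, so spacer motifs
# never form a periodic >=3 run that the segmenter could mistake for an array
SPACER_MOTIF_FRACS <- c(0.05, 0.33, 0.61, 0.89, 0.97)
SPACER_MOTIF_STRANDS <- c("+", "-", "+", "-", "+")

#' Build a synthetic annotated genome carrying the compound locus
#'
#' The X chromosome carries, in order: an anchor gene, the RA array (one
#' reverse-strand motif per unit), the spacer (five motifs of mixed strand),
#' the RB array (two opposed motifs per unit) and a single-copy control
#' gene. Autosomes, Y contigs and an unmethylated lambda spike-in contig are
#' emitted alongside. Truth features describe every array, unit, motif,
#' spacer, anchor and control.
#'
#' @param locus A [locus_spec()].
#' @param genome A [sexed_genome_spec()]; its `scale` should match the locus.
#' @param seed Integer seed; identical spec + seed gives identical bytes.
#' @return An `annotated_genome`: list with `seqs` (DNAStringSet),
#'   `features` (0-based half-open data.frame) and the two specs.
#' @export
build_genome <- function(locus = locus_spec(), genome = sexed_genome_spec(),
                         seed = 1) {
  with_seed(derive_seed(seed, "genome"), {
    m <- locus$motif
    mlen <- nchar(m)
    oA <- round(locus$unit_offset_frac * locus$unit_len_A)
    oB1 <- round(locus$unit_offset_frac * locus$unit_len_B)
    oB2 <- round(0.6 * locus$unit_len_B)
    if (oB2 - oB1 < mlen) stop("unit length shorter than motif spacing allows")

    consA <- plant(random_dna(locus$unit_len_A), revcomp(m), oA)
    consB <- mutate_seq(substr(consA, 1, min(locus$unit_len_A, locus$unit_len_B)),
                        locus$between_array_div)
    if (locus$unit_len_B > nchar(consB))
      consB <- paste0(consB, random_dna(locus$unit_len_B - nchar(consB)))
    consB <- plant(plant(consB, revcomp(m), oB1), m, oB2)

    unitsA <- character(locus$n_units_A)
    for (k in seq_len(locus$n_units_A)) {
      rate <- locus$within_array_div / 2
      if (k == 1L) rate <- rate * locus$ra1_div_multiplier
      unitsA[k] <- mutate_seq(consA, rate)
    }
    unitsB <- vapply(seq_len(locus$n_units_B), function(k)
      mutate_seq(consB, locus$within_array_div_B / 2), "")

    spacer <- random_dna(locus$spacer_len)
    sp_pos <- round(SPACER_MOTIF_FRACS * (locus$spacer_len - mlen))
    for (i in seq_along(sp_pos)) {
      ins <- if (SPACER_MOTIF_STRANDS[i] == "+") m else revcomp(m)
      spacer <- plant(spacer, ins, sp_pos[i])
    }

    flank <- max(200L, round(5000 * locus$scale))
    anchor_len <- max(100L, round(2000 * locus$scale))
    gap1 <- max(100L, round(3000 * locus$scale))
    gap2 <- max(100L, round(3000 * locus$scale))

    parts <- c(random_dna(flank), random_dna(anchor_len), random_dna(gap1),
               unitsA, spacer, unitsB,
               random_dna(gap2), random_dna(genome$control_len))
    x_seq <- paste(parts, collapse = "")
    if (nchar(x_seq) < genome$x_len)
      x_seq <- paste0(x_seq, random_dna(genome$x_len - nchar(x_seq)))

    # truth coordinates (0-based half-open)
    feats <- list()
    cur <- flank
    feats[[length(feats) + 1]] <- data.frame(
      contig = "X", start = cur, end = cur + anchor_len,
      name = "anchor_gene", strand = "+")
    cur <- cur + anchor_len + gap1
    ra_start <- cur
    for (k in seq_len(locus$n_units_A)) {
      us <- ra_start + (k - 1L) * locus$unit_len_A
      feats[[length(feats) + 1]] <- data.frame(
        contig = "X", start = us, end = us + locus$unit_len_A,
        name = sprintf("RA-%d", k), strand = "+")
      feats[[length(feats) + 1]] <- data.frame(
        contig = "X", start = us + oA, end = us + oA + mlen,
        name = sprintf("RA-%d_motif", k), strand = "-")
    }
    ra_end <- ra_start + locus$n_units_A * locus$unit_len_A
    feats[[length(feats) + 1]] <- data.frame(
      contig = "X", start = ra_start, end = ra_end, name = "RA", strand = "+")
    sp_start <- ra_end
    for (i in seq_along(sp_pos)) {
      feats[[length(feats) + 1]] <- data.frame(
        contig = "X", start = sp_start + sp_pos[i],
        end = sp_start + sp_pos[i] + mlen,
        name = sprintf("spacer_motif_%d", i), strand = SPACER_MOTIF_STRANDS[i])
    }
    sp_end <- sp_start + locus$spacer_len
    feats[[length(feats) + 1]] <- data.frame(
      contig = "X", start = sp_start, end = sp_end, name = "spacer",
      strand = ".")
    rb_start <- sp_end
    for (k in seq_len(locus$n_units_B)) {
      us <- rb_start + (k - 1L) * locus$unit_len_B
      feats[[length(feats) + 1]] <- data.frame(
        contig = "X", start = us, end = us + locus$unit_len_B,
        name = sprintf("RB-%d", k), strand = "+")
      feats[[length(feats) + 1]] <- data.frame(
        contig = "X", start = us + oB1, end = us + oB1 + mlen,
        name = sprintf("RB-%d_motif_1", k), strand = "-")
      feats[[length(feats) + 1]] <- data.frame(
        contig = "X", start = us + oB2, end = us + oB2 + mlen,
        name = sprintf("RB-%d_motif_2", k), strand = "+")
    }
    rb_end <- rb_start + locus$n_units_B * locus$unit_len_B
    feats[[length(feats) + 1]] <- data.frame(
      contig = "X", start = rb_start, end = rb_end, name = "RB", strand = "+")
    ctl_start <- rb_end + gap2
    feats[[length(feats) + 1]] <- data.frame(
      contig = "X", start = ctl_start, end = ctl_start + genome$control_len,
      name = "control_gene", strand = "+")

    seqs <- c(
      setNames(lapply(genome$autosome_lengths, random_dna),
               names(genome$autosome_lengths)),
      list(X = x_seq),
      setNames(lapply(genome$y_lengths, random_dna), names(genome$y_lengths)),
      list(lambda = random_dna(genome$lambda_len))
    )
    feats[[length(feats) + 1]] <- data.frame(
      contig = "lambda", start = 0L, end = genome$lambda_len,
      name = "lambda", strand = ".")

    features <- do.call(rbind, feats)
    features$start <- as.integer(features$start)
    features$end <- as.integer(features$end)
    out <- list(seqs = Biostrings::DNAStringSet(unlist(seqs)),
                features = features, locus = locus, genome = genome)
    class(out) <- "annotated_genome"
    out
  })
}

#' Contig lengths of an annotated genome (or pass-through for a named vector)
#' @param genome An `annotated_genome` or named numeric vector of lengths.
#' @export
contig_lengths <- function(genome) {
  if (inherits(genome, "annotated_genome"))
    setNames(Biostrings::width(genome$seqs), names(genome$seqs))
  else genome
}

#' Simulate a per-base read-depth track for a sexed sample
#'
#' Per-base depth is Poisson with expectation
#' `mean_depth * ploidy / 2`, where ploidy is 2 on autosomes, 1 (male) or
#' 2 (female) on the X, and 1 (male) or 0 (female) on Y contigs. When a
#' collapse map is supplied, the representative-unit interval's expectation
#' is multiplied by the per-haplotype copy count, emulating the pileup of
#' multi-mapping reads on a collapsed reference. The lambda spike-in contig,
#' if present, is simulated at `lambda_depth`.
#'
#' @param genome An `annotated_genome` or named vector of contig lengths.
#' @param sex `"male"` or `"female"`.
#' @param mean_depth Genome-wide target depth for a diploid region.
#' @param seed Integer seed.
#' @param collapse_map Optional data.frame with columns contig, start, end,
#'   label, copies (per-haplotype copy number of each collapsed array).
#' @param x_contig Name of the X contig.
#' @param y_contigs Names of Y contigs.
#' @param lambda_contig Name of the spike-in contig (skipped when absent).
#' @param lambda_depth Spike-in depth (defaults to `mean_depth`).
#' @return A `depth_track`.
#' @export
simulate_depth <- function(genome, sex = c("male", "female"), mean_depth = 20,
                           seed = 1, collapse_map = NULL,
                           x_contig = "X", y_contigs = NULL,
                           lambda_contig = "lambda", lambda_depth = NULL) {
  sex <- match.arg(sex)
  stopifnot(mean_depth > 0)
  lens <- contig_lengths(genome)
  if (is.null(y_contigs)) y_contigs <- grep("^Y", names(lens), value = TRUE)
  if (is.null(lambda_depth)) lambda_depth <- mean_depth
  if (!is.null(collapse_map)) {
    bad <- setdiff(collapse_map$contig, names(lens))
    if (length(bad)) stop("unknown contig in collapse_map: ", bad[1])
  }
  with_seed(derive_seed(seed, "depth"), {
    out <- list()
    for (ctg in names(lens)) {
      n <- lens[[ctg]]
      if (!is.null(lambda_contig) && ctg == lambda_contig) {
        lam <- rep(lambda_depth, n)
      } else {
        ploidy <- if (ctg %in% y_contigs) {
          if (sex == "male") 1 else 0
        } else if (ctg == x_contig) {
          if (sex == "male") 1 else 2
        } else 2
        lam <- rep(mean_depth * ploidy / 2, n)
        if (!is.null(collapse_map)) {
          cm <- collapse_map[collapse_map$contig == ctg, , drop = FALSE]
          for (i in seq_len(nrow(cm))) {
            idx <- (cm$start[i] + 1L):cm$end[i]
            lam[idx] <- lam[idx] * cm$copies[i]
          }
        }
      }
      out[[ctg]] <- if (all(lam == 0)) integer(n) else rpois(n, lam)
    }
    depth_track(out, sex = sex)
  })
}

#' Specification of the methylation simulator
#'
#' Group mean MFs default to the genome-wide means of the fertile and
#' sterile groups in the study design; per-site truth is Beta-distributed
#' around the group mean with the given precision, shared by all samples in
#' a group. Bisulfite non-conversion adds to the true MF (clamped to 1).
#'
#' @param mean_fertile,mean_sterile Group mean methylation frequencies.
#' @param precision Beta precision (a+b) of per-site true MF.
#' @param depth_mean Poisson mean of per-site, per-sample read depth.
#' @param non_conversion_rate Probability an unmethylated cytosine reads as
#'   methylated; lambda spike-in sites observe MF ~ this rate.
#' @export
methyl_sim_spec <- function(mean_fertile = 0.220, mean_sterile = 0.194,
                            precision = 20, depth_mean = 30,
                            non_conversion_rate = 0.005) {
  stopifnot(mean_fertile >= 0, mean_fertile <= 1,
            mean_sterile >= 0, mean_sterile <= 1,
            precision > 0, depth_mean > 0,
            non_conversion_rate >= 0, non_conversion_rate < 1)
  structure(list(mean_fertile = mean_fertile, mean_sterile = mean_sterile,
                 precision = precision, depth_mean = depth_mean,
                 non_conversion_rate = non_conversion_rate),
            class = "methyl_sim_spec")
}

#' Generate an ordered site table for the methylation simulator
#' @param n Number of cytosine sites.
#' @param contig Contig name.
#' @param start First position (1-based).
#' @param spacing Distance between consecutive sites.
#' @param context Context label recycled over sites.
#' @export
methylation_sites <- function(n, contig = "X", start = 1000, spacing = 50,
                              context = "CG") {
  data.frame(contig = contig, pos = start + (seq_len(n) - 1L) * spacing,
             strand = "+", context = rep(context, length.out = n),
             stringsAsFactors = FALSE)
}

#' Simulate per-sample methylation call tables
#'
#' Each sample's methylated count at a site is
#' Binomial(depth, clamp(site_mf + non_conversion_rate, 0, 1)); sites on the
#' lambda contig have true MF 0 so their observed MF approximates the
#' non-conversion rate. Sites drawn at depth 0 are absent from that sample's
#' table.
#'
#' @param sites Site table (contig, pos, strand, context); rows with
#'   `contig == lambda_contig` are treated as spike-in sites.
#' @param spec A [methyl_sim_spec()].
#' @param n_fertile,n_sterile Samples per group (study design: 4 fertile
#'   whole-testis felids vs 2 sterile).
#' @param seed Integer seed.
#' @param lambda_contig Name of the spike-in contig.
#' @return List with `samples` (named list of call data.frames: contig, pos,
#'   strand, context, mC, depth), `groups` (named group vector) and
#'   `truth` (per-site true MF per group).
#' @export
simulate_methylation_samples <- function(sites, spec = methyl_sim_spec(),
                                         n_fertile = 4, n_sterile = 2,
                                         seed = 1, lambda_contig = "lambda") {
  if (n_fertile < 1 || n_sterile < 1) stop("group sizes must be >= 1")
  with_seed(derive_seed(seed, "methylation"), {
    n_sites <- nrow(sites)
    is_lambda <- sites$contig == lambda_contig
    # one per-site random effect shared by both groups, shifted by the group
    # means: equal means give an exact null (identical per-site truths)
    mu_bar <- (spec$mean_fertile + spec$mean_sterile) / 2
    a <- mu_bar * spec$precision
    b <- (1 - mu_bar) * spec$precision
    base <- rbeta(n_sites, pmax(a, 1e-6), pmax(b, 1e-6))
    mf_f <- pmin(pmax(base + (spec$mean_fertile - mu_bar), 0), 1)
    mf_s <- pmin(pmax(base + (spec$mean_sterile - mu_bar), 0), 1)
    mf_f[is_lambda] <- 0
    mf_s[is_lambda] <- 0
    ids <- c(sprintf("fertile_%d", seq_len(n_fertile)),
             sprintf("sterile_%d", seq_len(n_sterile)))
    groups <- setNames(rep(c("fertile", "sterile"), c(n_fertile, n_sterile)),
                       ids)
    samples <- list()
    for (id in ids) {
      mf <- if (groups[[id]] == "fertile") mf_f else mf_s
      p <- pmin(mf + spec$non_conversion_rate, 1)
      depth <- rpois(n_sites, spec$depth_mean)
      mC <- rbinom(n_sites, depth, p)
      keep <- depth > 0
      samples[[id]] <- data.frame(
        contig = sites$contig[keep], pos = sites$pos[keep],
        strand = sites$strand[keep], context = sites$context[keep],
        mC = mC[keep], depth = depth[keep], stringsAsFactors = FALSE)
    }
    list(samples = samples, groups = groups,
         truth = data.frame(sites, mf_fertile = mf_f, mf_sterile = mf_s))
  })
}

#' Specification of the backcross cohort simulator
#'
#' Defaults mirror the study design: 23 fertile and 16 sterile X-hemizygous
#' backcross males genotyped at 27 ancestry-informative markers, with
#' exactly 14/16 sterile individuals carrying Jungle-cat (J) ancestry
#' across a 500-kb causal interval (93.74-94.24 Mb) and all fertile
#' individuals carrying domestic (D) ancestry there.
#'
#' @param n_fertile,n_sterile Cohort sizes.
#' @param n_markers Total marker count (>= n_causal_markers + 2).
#' @param causal_start,causal_end Causal interval bounds (bp); markers are
#'   placed exactly at both bounds.
#' @param n_causal_markers Markers inside the causal interval (>= 2).
#' @param marker_start,marker_end Span of the flanking marker grid.
#' @param discordant_sterile Sterile individuals carrying D in the interval.
#' @param recomb_rate Per-marker-step ancestry switch probability outside
#'   the causal block.
#' @export
cohort_spec <- function(n_fertile = 23, n_sterile = 16, n_markers = 27,
                        causal_start = 93740000, causal_end = 94240000,
                        n_causal_markers = 3,
                        marker_start = 90000000, marker_end = 98000000,
                        discordant_sterile = 2, recomb_rate = 0.1) {
  stopifnot(discordant_sterile <= n_sterile, n_causal_markers >= 2,
            causal_start < causal_end,
            marker_start < causal_start, causal_end < marker_end,
            recomb_rate >= 0, recomb_rate <= 1)
  n_flank <- n_markers - n_causal_markers
  if (n_flank < 2) stop("need at least one flanking marker on each side")
  structure(list(n_fertile = n_fertile, n_sterile = n_sterile,
                 n_markers = n_markers, causal_start = causal_start,
                 causal_end = causal_end, n_causal_markers = n_causal_markers,
                 marker_start = marker_start, marker_end = marker_end,
                 discordant_sterile = discordant_sterile,
                 recomb_rate = recomb_rate),
            class = "cohort_spec")
}

#' Simulate an X-hemizygous backcross cohort with a causal ancestry interval
#'
#' Each male carries a single ancestry state (D or J) per marker. Causal
#' interval markers are fixed by phenotype (J in all sterile individuals
#' except the configured discordant ones; D in all fertile individuals);
#' ancestry extends outward marker by marker, switching with probability
#' `recomb_rate` per step.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return List with `genotypes` (data.frame: marker, position, one column
#'   per individual), `phenotypes` (individual, phenotype) and
#'   `causal_interval` (start, end).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1) {
  with_seed(derive_seed(seed, "cohort"), {
    n_flank <- spec$n_markers - spec$n_causal_markers
    n_left <- ceiling(n_flank / 2)
    n_right <- n_flank - n_left
    left <- round(seq(spec$marker_start, spec$causal_start - 100000,
                      length.out = n_left))
    causal <- round(seq(spec$causal_start, spec$causal_end,
                        length.out = spec$n_causal_markers))
    right <- round(seq(spec$causal_end + 100000, spec$marker_end,
                       length.out = n_right))
    pos <- c(left, causal, right)
    if (any(diff(pos) <= 0)) stop("marker positions not strictly increasing")
    is_causal <- seq_along(pos) %in% (n_left + seq_len(spec$n_causal_markers))
    if (!any(is_causal)) stop("causal interval contains no marker")

    ids <- c(sprintf("F%02d", seq_len(spec$n_fertile)),
             sprintf("S%02d", seq_len(spec$n_sterile)))
    phen <- rep(c("fertile", "sterile"), c(spec$n_fertile, spec$n_sterile))
    discordant <- ids[phen == "sterile"][seq_len(spec$discordant_sterile)]

    geno <- matrix("", nrow = length(pos), ncol = length(ids),
                   dimnames = list(NULL, ids))
    ci <- which(is_causal)
    for (j in seq_along(ids)) {
      causal_state <- if (phen[j] == "sterile" && !(ids[j] %in% discordant))
        "J" else "D"
      g <- character(length(pos))
      g[ci] <- causal_state
      st <- causal_state
      for (i in rev(seq_len(min(ci) - 1))) {
        if (runif(1) < spec$recomb_rate) st <- if (st == "D") "J" else "D"
        g[i] <- st
      }
      st <- causal_state
      for (i in seq(max(ci) + 1, length.out = length(pos) - max(ci))) {
        if (runif(1) < spec$recomb_rate) st <- if (st == "D") "J" else "D"
        g[i] <- st
      }
      geno[, j] <- g
    }
    genotypes <- data.frame(marker = sprintf("SINE_%02d", seq_along(pos)),
                            position = pos, geno, stringsAsFactors = FALSE,
                            check.names = FALSE)
    list(genotypes = genotypes,
         phenotypes = data.frame(individual = ids, phenotype = phen,
                                 stringsAsFactors = FALSE),
         causal_interval = c(start = spec$causal_start,
                             end = spec$causal_end))
  })
}

#' Simulate a per-gene differential-expression table
#'
#' X-linked genes are flagged upregulated with probability `x_up_fraction`
#' (study estimate: 22% of X protein-coding genes), with log2 fold changes
#' around `x_up_mean_lfc` (2.45); a fixed-size subset of X up-genes is
#' flagged as unexpressed in fertile testes with larger fold changes
#' (3.28). Autosomal genes receive a configurable downregulation bias.
#'
#' @param genes_per_chromosome Named integer vector of gene counts. The
#'   default uses the felid karyotype (18 autosomes + X).
#' @param x_up_fraction Probability an X gene is upregulated.
#' @param x_up_mean_lfc Mean log2 fold change of X up-genes.
#' @param zero_in_fertile_n Number of X up-genes with zero fertile
#'   expression.
#' @param zero_in_fertile_mean_lfc Their mean log2 fold change.
#' @param autosome_down_fraction,autosome_up_fraction Per-gene probabilities
#'   of down/up status on autosomes.
#' @param lfc_sd SD of log2 fold changes around their means.
#' @param x_chrom Name of the X chromosome.
#' @param seed Integer seed.
#' @return data.frame: gene, chrom, log_fc, status (up/down/ns),
#'   fertile_expressed (logical).
#' @export
simulate_de_table <- function(genes_per_chromosome = NULL,
                              x_up_fraction = 0.22,
                              x_up_mean_lfc = 2.45,
                              zero_in_fertile_n = 22,
                              zero_in_fertile_mean_lfc = 3.28,
                              autosome_down_fraction = 0.10,
                              autosome_up_fraction = 0.02,
                              lfc_sd = 0.5, x_chrom = "X", seed = 1) {
  fr <- c(x_up_fraction, autosome_down_fraction, autosome_up_fraction)
  if (any(fr < 0) || any(fr > 1)) stop("fractions must lie in [0, 1]")
  if (is.null(genes_per_chromosome)) {
    auto <- c("A1", "A2", "A3", "B1", "B2", "B3", "B4", "C1", "C2",
              "D1", "D2", "D3", "D4", "E1", "E2", "E3", "F1", "F2")
    genes_per_chromosome <- c(setNames(rep(800L, length(auto)), auto),
                              setNames(650L, x_chrom))
  }
  with_seed(derive_seed(seed, "de"), {
    rows <- list()
    for (chrom in names(genes_per_chromosome)) {
      n <- genes_per_chromosome[[chrom]]
      gene <- sprintf("%s_g%04d", chrom, seq_len(n))
      if (chrom == x_chrom) {
        up <- runif(n) < x_up_fraction
        status <- ifelse(up, "up", "ns")
        lfc <- rnorm(n, 0, 0.3)
        lfc[up] <- rnorm(sum(up), x_up_mean_lfc, lfc_sd)
        fertile_expressed <- rep(TRUE, n)
        up_idx <- which(up)
        nz <- min(zero_in_fertile_n, length(up_idx))
        if (nz > 0) {
          zi <- sample(up_idx, nz)
          fertile_expressed[zi] <- FALSE
          lfc[zi] <- rnorm(nz, zero_in_fertile_mean_lfc, lfc_sd)
        }
      } else {
        u <- runif(n)
        status <- ifelse(u < autosome_down_fraction, "down",
                         ifelse(u < autosome_down_fraction +
                                  autosome_up_fraction, "up", "ns"))
        lfc <- rnorm(n, 0, 0.3)
        lfc[status == "down"] <- rnorm(sum(status == "down"), -1.5, lfc_sd)
        lfc[status == "up"] <- rnorm(sum(status == "up"), 1.5, lfc_sd)
        fertile_expressed <- rep(TRUE, n)
      }
      rows[[chrom]] <- data.frame(gene = gene, chrom = chrom, log_fc = lfc,
                                  status = status,
                                  fertile_expressed = fertile_expressed,
                                  stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
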