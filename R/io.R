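#' @importFrom stats setNames quantile rbinom rnorm rpois runif rbeta median
#'   pchisq pt fisher.test t.test binom.test prcomp sd phyper dhyper
#' @importFrom utils read.table write.table head tail
#' @importFrom Biostrings mismatch nmismatch matchPattern DNAString
#'   DNAStringSet reverseComplement
NULL

# All internal interval coordinates are 0-based half-open. Conversion to the
# 1-based conventions of GFF3 and depth TSV happens only at format boundaries.

#' Read a FASTA file into a named DNAStringSet
#'
#' Sequences are uppercased. IUPAC ambiguity codes other than N are rejected
#' by default, or mapped to N when `ambig = "to_N"`.
#'
#' @param path Path to a FASTA file.
#' @param ambig One of `"reject"` (default) or `"to_N"`: how to treat IUPAC
#'   ambiguity codes other than N.
#' @return A named [Biostrings::DNAStringSet] with unique, nonempty names.
#' @export
read_fasta <- function(path, ambig = c("reject", "to_N")) {
  ambig <- match.arg(ambig)
  stopifnot(file.exists(path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[1])
  names(seqs) <- ids
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(seqs) <- ids
  chars <- unique(unlist(strsplit(as.character(seqs), "")))
  bad <- setdiff(chars, c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    if (ambig == "reject") {
      stop("ambiguity codes other than N present: ", paste(bad, collapse = ","))
    }
    s <- as.character(seqs)
    s <- chartr(paste(bad, collapse = ""), strrep("N", length(bad)), s)
    seqs <- Biostrings::DNAStringSet(s)
    names(seqs) <- ids
  }
  seqs
}

#' Write a DNAStringSet to FASTA
#' @param seqs Named DNAStringSet.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read a per-base depth table into a depth track
#'
#' Supports the samtools-depth 3-column dialect (contig, 1-based position,
#' depth) and 4-column bedGraph (contig, 0-based start, end, depth). Both
#' dialects yield identical in-memory per-base tracks; positions absent from
#' the file take depth 0.
#'
#' @param path Path to the depth file.
#' @param dialect `"depth-tsv"` or `"bedgraph"`.
#' @param contig_lengths Optional named integer vector; when given, every
#'   track is padded with zeros to the contig length.
#' @return A `depth_track`: list with `depth` (named list of integer vectors,
#'   one per contig), `sample` and `sex` (both `NA` unless set later).
#' @export
read_depth_table <- function(path, dialect = c("depth-tsv", "bedgraph"),
                             contig_lengths = NULL) {
  dialect <- match.arg(dialect)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = c("character", rep("numeric", if (dialect == "bedgraph") 3 else 2)),
                    col.names = if (dialect == "bedgraph")
                      c("contig", "start", "end", "depth") else
                      c("contig", "pos", "depth"))
  if (any(tab$depth < 0)) stop("negative depth in ", path)
  out <- list()
  if (dialect == "depth-tsv") {
    if (any(tab$pos < 1)) stop("depth-tsv positions are 1-based; pos < 1 found")
    for (ctg in unique(tab$contig)) {
      sub <- tab[tab$contig == ctg, ]
      len <- if (!is.null(contig_lengths)) contig_lengths[[ctg]] else max(sub$pos)
      v <- integer(len)
      v[sub$pos] <- as.integer(sub$depth)
      out[[ctg]] <- v
    }
  } else {
    if (any(tab$start < 0) || any(tab$end <= tab$start))
      stop("bedGraph requires 0 <= start < end")
    for (ctg in unique(tab$contig)) {
      sub <- tab[tab$contig == ctg, ]
      sub <- sub[order(sub$start), ]
      if (any(sub$start[-1] < sub$end[-nrow(sub)]))
        stop("overlapping bedGraph intervals on contig ", ctg)
      len <- if (!is.null(contig_lengths)) contig_lengths[[ctg]] else max(sub$end)
      v <- integer(len)
      for (i in seq_len(nrow(sub))) {
        v[(sub$start[i] + 1L):sub$end[i]] <- as.integer(sub$depth[i])
      }
      out[[ctg]] <- v
    }
  }
  depth_track(out)
}

#' Construct a depth track object
#' @param depth Named list of non-negative integer vectors, one per contig.
#' @param sample Sample id.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @export
depth_track <- function(depth, sample = NA_character_, sex = "unknown") {
  stopifnot(is.list(depth), !is.null(names(depth)))
  structure(list(depth = depth, sample = sample, sex = sex),
            class = "depth_track")
}

#' Write a depth track
#' @param track A `depth_track`.
#' @param path Output path.
#' @param dialect `"depth-tsv"` or `"bedgraph"`.
#' @export
write_depth_table <- function(track, path, dialect = c("depth-tsv", "bedgraph")) {
  dialect <- match.arg(dialect)
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in names(track$depth)) {
    v <- track$depth[[ctg]]
    if (dialect == "depth-tsv") {
      keep <- v > 0L
      if (any(keep)) {
        writeLines(paste(ctg, which(keep), v[keep], sep = "\t"), con)
      }
    } else {
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      writeLines(paste(ctg, starts, ends, r$values, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a BED file of feature intervals
#'
#' BED is 0-based half-open; intervals are kept in that convention
#' internally.
#'
#' @param path Path to a BED file (3-6 columns).
#' @return A data.frame with columns contig, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    colClasses = "character")
  n <- ncol(tab)
  out <- data.frame(
    contig = tab[[1]],
    start = as.integer(tab[[2]]),
    end = as.integer(tab[[3]]),
    name = if (n >= 4) tab[[4]] else ".",
    score = if (n >= 5) tab[[5]] else ".",
    strand = if (n >= 6) tab[[6]] else ".",
    stringsAsFactors = FALSE
  )
  if (any(out$start >= out$end)) stop("BED interval with start >= end in ", path)
  out
}

#' Write feature intervals to BED6
#' @param features data.frame with contig, start, end, name and optionally
#'   score, strand.
#' @param path Output path.
#' @export
write_bed <- function(features, path) {
  stopifnot(all(c("contig", "start", "end", "name") %in% names(features)))
  if (any(features$start >= features$end)) stop("interval with start >= end")
  score <- if ("score" %in% names(features)) features$score else "."
  strand <- if ("strand" %in% names(features)) features$strand else "."
  lines <- paste(features$contig, features$start, features$end,
                 features$name, score, strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write feature intervals to GFF3 (1-based closed coordinates)
#' @param features data.frame of 0-based half-open intervals.
#' @param path Output path.
#' @param source Source column value.
#' @param type Feature type column value.
#' @export
write_gff3 <- function(features, path, source = "sterileX", type = "region") {
  strand <- if ("strand" %in% names(features)) features$strand else "."
  strand[!strand %in% c("+", "-")] <- "."
  lines <- c("##gff-version 3",
             paste(features$contig, source, type,
                   features$start + 1L, features$end, ".",
                   strand, ".", paste0("Name=", features$name), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a data.frame as a TSV file
#' @param tab data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV file with header
#' @param path Input path.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a phylogenetic tree (or newick string) to a newick file
#' @param tree An ape `phylo` object or a newick character scalar.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "phylo")) {
    ape::write.tree(tree, file = path)
  } else {
    writeLines(as.character(tree), path)
  }
  invisible(path)
}

#' Read a newick file into an ape phylo object
#' @param path Input path.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Read a 12-column tab-separated homology hit table
#'
#' Columns follow the standard tabular hit format: query, subject,
#' pct_identity, length, mismatches, gapopen, qstart, qend, sstart, send,
#' evalue, bitscore.
#'
#' @param path Input path.
#' @export
read_hits <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 12) stop("expected 12 columns in hit table, got ", ncol(tab))
  names(tab) <- c("query", "subject", "pct_identity", "length", "mismatches",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")
  tab
}

#' Derive a module-specific random seed from a master seed
#'
#' Each module draws its randomness from a stream seed derived from the one
#' run-level seed, so results are independent of module execution order.
#' The derivation is `(seed * 7919 + stream index) mod 2^31 - 1`, with
#' streams indexed by a fixed name table.
#'
#' @param seed Master integer seed.
#' @param stream Stream name, e.g. `"genome"`, `"depth"`, `"methylation"`,
#'   `"cohort"`, `"de"`, `"permutation"`, `"bootstrap"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  streams <- c(genome = 1L, depth = 2L, methylation = 3L, cohort = 4L,
               de = 5L, permutation = 6L, bootstrap = 7L, misc = 8L)
  if (!stream %in% names(streams)) stop("unknown seed stream: ", stream)
  as.integer((as.numeric(seed) * 7919 + streams[[stream]]) %% (2^31 - 1))
}

#' Read a YAML run configuration
#'
#' The config must contain a `seed`; keys outside `seed`, `paths` and
#' `parameters` are rejected by name.
#'
#' @param path Path to a YAML file.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), c("seed", "paths", "parameters"))
  if (length(unknown)) stop("unknown config key: ", unknown[1])
  if (is.null(cfg$seed)) stop("config must contain a seed")
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$paths)) cfg$paths <- list()
  if (is.null(cfg$parameters)) cfg$parameters <- list()
  cfg
}
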