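# Position frequency / weight matrices and both-strand scanning of
# upstream sequences. Scores are reported on the relative 0-1 scale
# (S - Smin) / (Smax - Smin), the JASPAR convention, so the database
# integration threshold of 0.65 and the stringent query threshold of 0.85
# are directly comparable across profiles of different length and
# information content.

#' Construct a position frequency matrix
#'
#' @param counts 4 x L numeric matrix of non-negative base counts, rows in
#'   A, C, G, T order; every column must have a positive total and the
#'   motif must be at least 4 columns long.
#' @param tf_id Identifier of the profile's transcription factor.
#' @param name Display name.
#' @return An object of class `pfm`.
#' @export
pfm <- function(counts, tf_id, name = tf_id) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PFM must have 4 rows (A, C, G, T)", call. = FALSE)
  if (ncol(counts) < 4L) stop("motif length must be >= 4", call. = FALSE)
  if (any(counts < 0) || anyNA(counts)) {
    stop("PFM counts must be non-negative", call. = FALSE)
  }
  if (any(colSums(counts) <= 0)) {
    stop("every PFM column must have a positive total", call. = FALSE)
  }
  rownames(counts) <- DNA_BASES
  structure(list(tf_id = as.character(tf_id), name = as.character(name),
                 counts = counts), class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("PFM", x$tf_id, paste0("(", x$name, "),"), ncol(x$counts), "bp\n")
  print(round(x$counts, 2))
  invisible(x)
}

#' Convert a frequency matrix to a log-odds weight matrix
#'
#' Column counts are smoothed with a pseudocount allocated proportionally
#' to the background and converted to log2 odds against that background:
#' `w[b, j] = log2( (n[b, j] + pc * bg[b]) / (colsum_j + pc) / bg[b] )`.
#' The attainable score range (sum of per-column minima / maxima) is
#' precomputed for the relative-score rescaling.
#'
#' @param x A [pfm()].
#' @param background Base composition (A, C, G, T), strictly positive,
#'   summing to 1. Default uniform.
#' @param pseudocount Total pseudocount per column, > 0 (default 1).
#' @return An object of class `pwm` with elements `weights` (4 x L),
#'   `background`, `score_min`, `score_max`.
#' @export
pfm_to_pwm <- function(x, background = rep(0.25, 4), pseudocount = 1) {
  stopifnot(inherits(x, "pfm"))
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  background <- as.numeric(background)
  if (length(background) != 4L || any(background <= 0)) {
    stop("background must be 4 strictly positive probabilities", call. = FALSE)
  }
  background <- background / sum(background)
  counts <- x$counts
  colsum <- colSums(counts)
  prob <- sweep(counts + outer(background * pseudocount, rep(1, ncol(counts))),
                2, colsum + pseudocount, "/")
  weights <- log2(prob / background)
  rownames(weights) <- DNA_BASES
  structure(list(tf_id = x$tf_id, name = x$name, weights = weights,
                 background = background,
                 score_min = sum(apply(weights, 2, min)),
                 score_max = sum(apply(weights, 2, max))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$tf_id, paste0("(", ncol(x$weights), " bp),"),
      "score range [", round(x$score_min, 3), ",",
      round(x$score_max, 3), "]\n")
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus and anti-consensus sequences of a weight matrix
#'
#' The consensus takes the highest-weight base at each column (relative
#' score exactly 1); the anti-consensus the lowest (relative score 0).
#' Ties resolve to the first base in A, C, G, T order.
#'
#' @param pwm A `pwm`.
#' @return A single DNA string.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$weights, 2, which.max)], collapse = "")
}

#' @rdname pwm_consensus
#' @export
pwm_anticonsensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$weights, 2, which.min)], collapse = "")
}

#' An upstream regulatory region
#'
#' A stretch of sequence immediately upstream of a pre-miRNA or gene start
#' (10 kb by default in the database), read 5' to 3' on the feature's
#' strand. `chrom`/`start`/`strand` anchor offset 0 of the sequence to the
#' genome: `start` is the 1-based genomic coordinate of the region's 5'
#' end, so on the minus strand increasing offsets walk leftwards along the
#' chromosome.
#'
#' @param target_id miRNA or gene the region belongs to.
#' @param sequence DNA string over A, C, G, T, N (case-insensitive).
#' @param chrom,start,strand Genomic anchor of the 5' end (1-based).
#' @return An object of class `upstream_region`.
#' @export
upstream_region <- function(target_id, sequence, chrom = NA_character_,
                            start = NA_integer_, strand = "+") {
  sequence <- toupper(as.character(sequence))
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence may only contain A, C, G, T, N", call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  structure(list(target_id = as.character(target_id), sequence = sequence,
                 chrom = as.character(chrom), start = as.integer(start),
                 strand = strand, length = nchar(sequence)),
            class = "upstream_region")
}

#' @export
print.upstream_region <- function(x, ...) {
  cat("Upstream region for", x$target_id, paste0("(", x$length, " bp)"),
      if (!is.na(x$chrom)) paste0("anchored at ", x$chrom, ":", x$start,
                                  " (", x$strand, ")") else "unanchored",
      "\n")
  invisible(x)
}

# Integer codes for A/C/G/T; N (or any other IUPAC code) becomes NA so
# windows containing it score NA and are skipped.
encode_dna <- function(sequence) {
  match(strsplit(sequence, "", fixed = TRUE)[[1]], DNA_BASES)
}

# Vectorized raw scores of all windows of `weights` along integer codes.
window_scores <- function(weights, codes) {
  L <- ncol(weights)
  nw <- length(codes) - L + 1L
  if (nw < 1L) return(numeric(0))
  s <- numeric(nw)
  for (j in seq_len(L)) {
    s <- s + weights[codes[j:(j + nw - 1L)] + (j - 1L) * 4L]
  }
  s
}

# Weight matrix that scores the reverse complement of a forward window.
revcomp_weights <- function(weights) {
  weights[4:1, rev(seq_len(ncol(weights))), drop = FALSE]
}

revcomp <- function(sequence) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(sequence, "", fixed = TRUE)[[1]]), collapse = ""))
}

empty_hits <- function() {
  data.frame(tf_id = character(), target_id = character(),
             start = integer(), end = integer(), strand = character(),
             raw_score = numeric(), rel_score = numeric(),
             pvalue = numeric(), in_cgi = logical(), in_promoter = logical(),
             site_seq = character(), stringsAsFactors = FALSE)
}

#' Scan an upstream region for binding sites on both strands
#'
#' Slides the weight matrix along the region and its reverse complement
#' and reports every window whose relative score
#' `(raw - score_min) / (score_max - score_min)` reaches
#' `min_rel_score`. Minus-strand windows are scored on the reverse
#' complement but reported in forward-sequence coordinates (0-based,
#' half-open). Windows overlapping an `N` are skipped. All qualifying
#' windows are reported, overlapping or not; hits are sorted by
#' `(target_id, start, strand)`.
#'
#' The database integrates predicted sites at a relative score above 0.65;
#' stringent queries use 0.85.
#'
#' @param pwm A [pfm_to_pwm()] weight matrix.
#' @param region An [upstream_region()] or a plain DNA string.
#' @param min_rel_score Threshold on the relative score (default 0.65).
#' @return A data frame of hits (`tf_id`, `target_id`, `start`, `end`,
#'   `strand`, `raw_score`, `rel_score`, `pvalue`, `in_cgi`,
#'   `in_promoter`, `site_seq`). `pvalue` is `NA` until
#'   [assign_pvalues()]; flags are `NA` until [annotate_hits()].
#' @export
scan_region <- function(pwm, region, min_rel_score = 0.65) {
  stopifnot(inherits(pwm, "pwm"),
            min_rel_score >= 0, min_rel_score <= 1)
  if (is.character(region)) region <- upstream_region("", region)
  L <- ncol(pwm$weights)
  if (region$length < L) {
    warning("region shorter than motif; no windows to scan", call. = FALSE)
    return(empty_hits())
  }
  codes <- encode_dna(region$sequence)
  span <- pwm$score_max - pwm$score_min
  raw_fwd <- window_scores(pwm$weights, codes)
  raw_rev <- window_scores(revcomp_weights(pwm$weights), codes)
  res <- list()
  for (strand in c("+", "-")) {
    raw <- if (strand == "+") raw_fwd else raw_rev
    # raw lies in [score_min, score_max] by construction; clamp the
    # floating-point drift of the two summation orders
    rel <- pmin(1, pmax(0, (raw - pwm$score_min) / span))
    keep <- which(!is.na(rel) & rel >= min_rel_score)
    if (!length(keep)) next
    site <- substring(region$sequence, keep, keep + L - 1L)
    if (strand == "-") site <- vapply(site, revcomp, character(1), USE.NAMES = FALSE)
    res[[strand]] <- data.frame(
      tf_id = pwm$tf_id, target_id = region$target_id,
      start = keep - 1L, end = keep - 1L + L, strand = strand,
      raw_score = raw[keep], rel_score = rel[keep],
      pvalue = NA_real_, in_cgi = NA, in_promoter = NA,
      site_seq = site, stringsAsFactors = FALSE)
  }
  if (!length(res)) return(empty_hits())
  hits <- do.call(rbind, res)
  hits <- hits[order(hits$target_id, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Calibrate relative scores to empirical p-values
#'
#' Scores a reference DNA sequence with the profile on both strands and
#' tabulates, on an ascending relative-score grid, the fraction of
#' reference windows scoring at least as high:
#' `empirical_p(s) = #\{windows with rel_score >= s\} / #windows`.
#' This gives each profile a score-to-p-value correspondence on a common
#' reference, so thresholds expressed as relative scores can be read as
#' significance levels.
#'
#' @param pwm A `pwm`.
#' @param reference Reference DNA string, at least 10 motif lengths long.
#' @param grid_step Grid spacing on `[0, 1]` (default 0.01).
#' @return A `calibration_table`: data frame `rel_score`, `empirical_p`
#'   with attributes `tf_id` and `n_windows`.
#' @export
calibrate_pvalues <- function(pwm, reference, grid_step = 0.01) {
  stopifnot(inherits(pwm, "pwm"), grid_step > 0, grid_step <= 1)
  reference <- toupper(as.character(reference))
  L <- ncol(pwm$weights)
  if (nchar(reference) < 10L * L) {
    stop("reference must be at least 10 motif lengths (", 10L * L,
         " bp) long", call. = FALSE)
  }
  codes <- encode_dna(reference)
  span <- pwm$score_max - pwm$score_min
  rel <- c(window_scores(pwm$weights, codes),
           window_scores(revcomp_weights(pwm$weights), codes))
  rel <- pmin(1, pmax(0, (rel[!is.na(rel)] - pwm$score_min) / span))
  if (!length(rel)) stop("reference contains no scorable window", call. = FALSE)
  grid <- seq(0, 1, by = grid_step)
  if (grid[length(grid)] < 1) grid <- c(grid, 1)
  # windows whose score mathematically equals a grid point must count as
  # exceeding it regardless of rounding; PWM score lattices are far
  # coarser than this tie tolerance
  emp <- vapply(grid, function(s) mean(rel >= s - 1e-9), numeric(1))
  structure(data.frame(rel_score = grid, empirical_p = emp),
            class = c("calibration_table", "data.frame"),
            tf_id = pwm$tf_id, n_windows = length(rel))
}

#' Look up calibrated p-values for relative scores
#'
#' Uses the step function of the calibration grid: the empirical p at the
#' largest grid score not exceeding the query, which never understates the
#' true exceedance fraction.
#'
#' @param calib A [calibrate_pvalues()] table.
#' @param rel_score Numeric vector of relative scores in `[0, 1]`.
#' @return Numeric vector of empirical p-values.
#' @export
pvalue_at <- function(calib, rel_score) {
  stopifnot(inherits(calib, "calibration_table"))
  idx <- findInterval(rel_score, calib$rel_score)
  idx[idx < 1L] <- 1L
  calib$empirical_p[idx]
}

#' @rdname pvalue_at
#' @param hits A hit data frame from [scan_region()].
#' @return For `assign_pvalues`, the hits with the `pvalue` column filled.
#' @export
assign_pvalues <- function(hits, calib) {
  hits$pvalue <- pvalue_at(calib, hits$rel_score)
  hits
}
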