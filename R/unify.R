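# Unification of heterogeneous miRNA->gene target-prediction scores onto a
# common uniform 0-1 scale. The two supported score families are the
# miRanda-derived scales of MicroCosm (13 to 23) and microRNA.org (140 to
# 205); the unified score is a per-source monotone rank transform so that
# a single threshold applies across sources.

#' Describe a raw score source
#'
#' @param name Source name, `"microcosm"` or `"mirandaorg"`.
#' @param score_min,score_max Hard bounds of the source's raw scale.
#'   Defaults: MicroCosm 13-23, microRNA.org 140-205.
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(name, score_min = NULL, score_max = NULL) {
  defaults <- list(microcosm = c(13, 23), mirandaorg = c(140, 205))
  if (is.null(score_min) || is.null(score_max)) {
    if (!name %in% names(defaults)) {
      stop("no default bounds for source '", name,
           "'; give score_min and score_max", call. = FALSE)
    }
    score_min <- defaults[[name]][1]
    score_max <- defaults[[name]][2]
  }
  if (score_min >= score_max) stop("score_min must be < score_max", call. = FALSE)
  structure(list(name = name, score_min = score_min, score_max = score_max),
            class = "source_spec")
}

#' @rdname source_spec
#' @export
default_source_specs <- function() {
  list(microcosm = source_spec("microcosm"),
       mirandaorg = source_spec("mirandaorg"))
}

#' Fit the per-source uniformizing transform
#'
#' For each source the transform is the empirical CDF of its raw-score
#' sample under the midpoint rank convention: the i-th of n sorted scores
#' maps to `(2i - 1) / (2n)`, tied values receiving the mean of their
#' ranks. Applied to the fitting sample this yields values uniformly
#' spread on (0, 1) up to rank granularity. The source bounds act as hard
#' clamps: raw values at or below `score_min` map to 0 and at or above
#' `score_max` to 1 whenever the bounds lie outside the observed sample.
#'
#' @param scores_by_source Named list, source name -> numeric raw scores
#'   (at least 2 distinct values per source).
#' @param specs Named list of [source_spec()]s (default both sources).
#' @param combine Multi-source combination rule, `"mean"` or `"max"`.
#' @return An object of class `unified_transform` holding one ascending
#'   breakpoint table per source.
#' @export
fit_transform <- function(scores_by_source, specs = default_source_specs(),
                          combine = c("mean", "max")) {
  combine <- match.arg(combine)
  maps <- lapply(names(scores_by_source), function(src) {
    x <- as.numeric(scores_by_source[[src]])
    x <- x[!is.na(x)]
    if (length(unique(x)) < 2L) {
      stop("source '", src, "' has a degenerate (constant) score sample",
           call. = FALSE)
    }
    spec <- specs[[src]]
    if (is.null(spec)) spec <- source_spec(src)
    n <- length(x)
    xs <- sort(x)
    p <- (2 * seq_len(n) - 1) / (2 * n)
    # Collapse ties to their mean midpoint rank.
    ux <- unique(xs)
    up <- vapply(ux, function(v) mean(p[xs == v]), numeric(1))
    bx <- ux; by <- up
    if (spec$score_min < ux[1]) { bx <- c(spec$score_min, bx); by <- c(0, by) }
    if (spec$score_max > ux[length(ux)]) {
      bx <- c(bx, spec$score_max); by <- c(by, 1)
    }
    list(spec = spec, breaks = data.frame(raw = bx, quantile = by))
  })
  names(maps) <- names(scores_by_source)
  structure(list(maps = maps, combine = combine),
            class = "unified_transform")
}

# Evaluate one source map; clamps out-of-bound raw scores with a warning.
apply_source_map <- function(map, raw) {
  lo <- map$spec$score_min; hi <- map$spec$score_max
  out_of_range <- !is.na(raw) & (raw < lo | raw > hi)
  if (any(out_of_range)) {
    warning(sum(out_of_range), " raw score(s) outside [", lo, ", ", hi,
            "] for source '", map$spec$name, "'; clamped", call. = FALSE)
    raw <- pmin(pmax(raw, lo), hi)
  }
  b <- map$breaks
  q <- stats::approx(b$raw, b$quantile, xout = raw, rule = 2, ties = "ordered")$y
  pmin(pmax(q, 0), 1)
}

#' Unify raw target-prediction scores
#'
#' Maps each present source score through its fitted quantile transform
#' and combines multi-source evidence with the transform's rule (mean by
#' default, equal weights). A single present source returns its quantile
#' directly; the result always lies between the smallest and largest
#' per-source quantile.
#'
#' @param raw_scores Named numeric vector or list, source name -> raw
#'   score; `NA` marks a missing source.
#' @param transform A [fit_transform()] object.
#' @return A unified score in `[0, 1]`.
#' @export
unify <- function(raw_scores, transform) {
  stopifnot(inherits(transform, "unified_transform"))
  raw_scores <- unlist(raw_scores)
  present <- names(raw_scores)[!is.na(raw_scores)]
  if (!length(present)) stop("at least one source score required", call. = FALSE)
  unknown <- setdiff(present, names(transform$maps))
  if (length(unknown)) {
    stop("no fitted map for source(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  q <- vapply(present, function(src) {
    apply_source_map(transform$maps[[src]], raw_scores[[src]])
  }, numeric(1))
  if (transform$combine == "max") max(q) else mean(q)
}

#' Add a unified-score column to a miRNA-target table
#'
#' @param df Data frame with optional `microcosm_score` and
#'   `mirandaorg_score` columns (NA = missing).
#' @param transform A [fit_transform()] object.
#' @return `df` with a `unified_score` column.
#' @export
unify_table <- function(df, transform) {
  cols <- intersect(c("microcosm", "mirandaorg"),
                    sub("_score$", "", grep("_score$", names(df), value = TRUE)))
  if (!length(cols)) stop("no *_score source columns found", call. = FALSE)
  df$unified_score <- vapply(seq_len(nrow(df)), function(i) {
    raw <- setNames(as.numeric(df[i, paste0(cols, "_score")]), cols)
    unify(raw, transform)
  }, numeric(1))
  df
}

#' Write / read a fitted transform as breakpoint TSVs
#'
#' Serializes each source map as a two-column (`raw`, `quantile`) table for
#' reproducibility.
#'
#' @param transform A [fit_transform()] object.
#' @param path Output TSV path (all sources stacked, `source` column).
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path) {
  rows <- do.call(rbind, lapply(names(transform$maps), function(src) {
    b <- transform$maps[[src]]$breaks
    data.frame(source = src, raw = as.character(b$raw),
               quantile = as.character(b$quantile), stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filtering presets for miRNA-target evidence
#'
#' Returns the documented raw-score equivalents of the packaged stringency
#' presets so filters can be expressed on either scale:
#' * `"stringent"`: unified score >= 0.8, which corresponds to
#'   MicroCosm score >= 17 with p <= 0.01 and microRNA.org score >= 152;
#'   at least 1 gene per miRNA.
#' * `"medium"`: MicroCosm score >= 16 with p <= 0.05 and microRNA.org
#'   score >= 150; at least 2 miRNAs per gene.
#'
#' @param name Preset name.
#' @return A named list of threshold values.
#' @export
preset_thresholds <- function(name) {
  presets <- list(
    stringent = list(unified_min = 0.8, microcosm_min = 17,
                     microcosm_p_max = 0.01, mirandaorg_min = 152,
                     min_targets_per_mirna = 1),
    medium = list(unified_min = NA_real_, microcosm_min = 16,
                  microcosm_p_max = 0.05, mirandaorg_min = 150,
                  min_mirnas_per_gene = 2))
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  presets[[name]]
}
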