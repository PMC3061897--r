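# Fisher-exact ranking of candidate regulators. Given a query list of
# targets (e.g. a down-regulated miRNA family) the module ranks every
# regulator wired to the query in the score-filtered table by the
# one-sided hypergeometric tail probability of the overlap, alongside the
# best edge score and the regulation counts used as filter criteria.

#' One-sided Fisher (hypergeometric tail) enrichment p-value
#'
#' Probability of drawing at least `k` of the regulator's `K` targets in a
#' query of size `n` from a universe of `N` targets:
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, computed exactly.
#'
#' @param k Observed overlap between query and the regulator's targets.
#' @param n Query size.
#' @param K Regulator degree (number of targets in the universe).
#' @param N Universe size.
#' @return The exact tail probability in `(0, 1]`. Vectorized.
#' @examples
#' fisher_p(4, 4, 5, 10) # choose(5,4) / choose(10,4)
#' @export
fisher_p <- function(k, n, K, N) {
  bad <- k < 0 | n < 0 | K < 0 | N < 0 | k > pmin(n, K) | K > N | n > N
  if (any(bad)) {
    stop("fisher_p requires 0 <= k <= min(n, K), K <= N, n <= N",
         call. = FALSE)
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Filter criteria for regulator ranking
#'
#' Bundles the ranking filters: the minimum edge quality score, the
#' minimum number of query targets per regulator, the Fisher p-value cap,
#' an optional minimum binding-site length, and an optional contextual
#' entity list. Two packaged presets mirror the documented stringencies
#' for TF ranking: `"stringent"` (score >= 0.85, >= 3 miRNAs per TF,
#' p <= 0.05) and `"permissive"` (score >= 0.65, site length >= 6,
#' >= 1 miRNA per TF).
#'
#' @param min_score Minimum edge score in `[0, 1]`.
#' @param min_targets_per_regulator Minimum query overlap `k` (>= 1).
#' @param max_p Fisher p-value cap in `(0, 1]`.
#' @param min_tfbs_len Optional minimum binding-site length.
#' @param context_list Optional character vector of entity ids.
#' @param preset Optional preset name overriding the numeric defaults.
#' @return An object of class `filter_criteria`.
#' @export
filter_criteria <- function(min_score = 0.85, min_targets_per_regulator = 3,
                            max_p = 0.05, min_tfbs_len = NULL,
                            context_list = NULL, preset = NULL) {
  if (!is.null(preset)) {
    presets <- list(
      stringent = list(min_score = 0.85, min_targets_per_regulator = 3,
                       max_p = 0.05, min_tfbs_len = NULL),
      permissive = list(min_score = 0.65, min_targets_per_regulator = 1,
                        max_p = 1, min_tfbs_len = 6))
    if (!preset %in% names(presets)) {
      stop("unknown preset '", preset, "'; available: ",
           paste(names(presets), collapse = ", "), call. = FALSE)
    }
    p <- presets[[preset]]
    min_score <- p$min_score
    min_targets_per_regulator <- p$min_targets_per_regulator
    max_p <- p$max_p
    min_tfbs_len <- p$min_tfbs_len
  }
  stopifnot(min_score >= 0, min_score <= 1,
            min_targets_per_regulator >= 1, max_p > 0, max_p <= 1)
  structure(list(min_score = min_score,
                 min_targets_per_regulator = min_targets_per_regulator,
                 max_p = max_p, min_tfbs_len = min_tfbs_len,
                 context_list = context_list),
            class = "filter_criteria")
}

#' Rank candidate regulators of a query list by Fisher enrichment
#'
#' For each regulator at the chosen level, counts the overlap `k` between
#' its targets and the query, its degree `K`, the effective query size `n`
#' and the universe size `N`, and scores the overlap with the exact
#' one-sided hypergeometric tail. The universe is the set of target-side
#' entities present in the score-filtered table at that level -- the
#' database itself, not the genome, is the statistical background.
#'
#' With `direction = "targets_of"` the roles transpose: the query is a
#' list of regulators and the ranked entities are their common targets
#' (e.g. genes enriched for miRNAs of the query family).
#'
#' Rows are kept when `k >= min_targets_per_regulator` and
#' `fisher_p <= max_p`, and sorted by `(fisher_p, -best_score,
#' regulator_id)` -- a total deterministic order.
#'
#' @param table An [interaction_table()].
#' @param query Character vector of entity ids.
#' @param level Regulation level to rank at (`TF_MIRNA`, `MIRNA_GENE`,
#'   `TF_GENE`).
#' @param criteria A [filter_criteria()].
#' @param direction `"regulators_of"` (default) or `"targets_of"`.
#' @param adjust Add a Benjamini-Hochberg `p_adjusted` column.
#' @param tfbs_counts Optional named vector, regulator id -> binding-site
#'   count from the scanner, surfaced as `tfbs_count`.
#' @return A data frame of enrichment rows: `regulator_id`,
#'   `hits_in_query` (k), `query_size` (n), `regulator_degree` (K),
#'   `universe_size` (N), `fisher_p`, `best_score`, `tfbs_count`.
#' @export
rank_regulators <- function(table, query, level,
                            criteria = filter_criteria(),
                            direction = c("regulators_of", "targets_of"),
                            adjust = FALSE, tfbs_counts = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(table, "interaction_table"),
            inherits(criteria, "filter_criteria"))
  level <- match.arg(level, c("TF_MIRNA", "MIRNA_GENE", "TF_GENE"))
  query <- unique(as.character(query))
  if (!length(query)) stop("empty query", call. = FALSE)
  unknown <- setdiff(query, table$entities$id)
  if (length(unknown)) {
    stop("query id(s) not in table: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  edges <- table$interactions
  edges <- edges[edges$level == level & edges$score >= criteria$min_score, ,
                 drop = FALSE]
  if (direction == "regulators_of") {
    reg <- edges$source_id; tgt <- edges$target_id
  } else {
    reg <- edges$target_id; tgt <- edges$source_id
  }
  universe <- unique(tgt)
  n_query <- intersect(query, universe)
  if (!length(n_query)) {
    warning("query does not intersect the universe at this level/score",
            call. = FALSE)
    return(empty_enrichment())
  }
  N <- length(universe)
  n <- length(n_query)
  regulators <- unique(reg)
  rows <- lapply(regulators, function(r) {
    sel <- reg == r
    targets <- unique(tgt[sel])
    hit <- intersect(targets, n_query)
    k <- length(hit)
    if (k < 1L) return(NULL)
    best <- if (k) max(edges$score[sel & tgt %in% hit]) else NA_real_
    data.frame(regulator_id = r, hits_in_query = k, query_size = n,
               regulator_degree = length(targets), universe_size = N,
               fisher_p = fisher_p(k, n, length(targets), N),
               best_score = best, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(empty_enrichment())
  rows$tfbs_count <- if (!is.null(tfbs_counts)) {
    as.integer(tfbs_counts[rows$regulator_id])
  } else NA_integer_
  keep <- rows$hits_in_query >= criteria$min_targets_per_regulator &
    rows$fisher_p <= criteria$max_p
  rows <- rows[keep, , drop = FALSE]
  rows <- rows[order(rows$fisher_p, -rows$best_score, rows$regulator_id), ,
               drop = FALSE]
  if (adjust) rows$p_adjusted <- p.adjust(rows$fisher_p, method = "BH")
  rownames(rows) <- NULL
  rows
}

empty_enrichment <- function() {
  data.frame(regulator_id = character(), hits_in_query = integer(),
             query_size = integer(), regulator_degree = integer(),
             universe_size = integer(), fisher_p = numeric(),
             best_score = numeric(), tfbs_count = integer(),
             stringsAsFactors = FALSE)
}

#' Contextual filtering against an expression-derived entity list
#'
#' Intersects candidates with a contextual list -- typically the
#' up-regulated genes of an experiment when ranking targets of a
#' down-regulated miRNA family. `keep` mode retains only members of the
#' list; `annotate` mode flags membership without removing anything.
#'
#' @param x Either a character vector of entity ids or an enrichment data
#'   frame from [rank_regulators()] (filtered on its `regulator_id`).
#' @param context_list Non-empty character vector of entity ids.
#' @param mode `"keep"` or `"annotate"`.
#' @return Same type as `x`; in annotate mode with an `in_context` flag
#'   (for data frames) or a named logical vector (for id vectors).
#' @export
context_filter <- function(x, context_list, mode = c("keep", "annotate")) {
  mode <- match.arg(mode)
  if (!length(context_list)) stop("context_list must be non-empty", call. = FALSE)
  context_list <- as.character(context_list)
  if (is.data.frame(x)) {
    inside <- x$regulator_id %in% context_list
    if (mode == "keep") {
      out <- x[inside, , drop = FALSE]
      rownames(out) <- NULL
      out
    } else {
      x$in_context <- inside
      x
    }
  } else {
    x <- as.character(x)
    inside <- x %in% context_list
    if (mode == "keep") x[inside] else setNames(inside, x)
  }
}
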