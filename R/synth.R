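# Seeded synthetic benchmark generation: random binding profiles at a
# requested information content, upstream sequences with planted consensus
# sites, and multi-level interaction networks with planted loop motifs and
# anti-correlated expression. Planted edges score strictly above the
# analysis thresholds and background edges strictly below, so ground truth
# is unambiguous and motif recovery can be checked exactly rather than
# statistically. All generators are deterministic under a fixed integer
# seed (withr::with_seed; no time-based state).

#' Generate a random binding profile at a target information content
#'
#' Each column gets one randomly chosen dominant base with the remaining
#' probability split evenly, the dominance solved numerically so that the
#' column's information content (2 - entropy, bits) matches the request.
#' Counts are scaled to a depth of 100 sequences.
#'
#' @param seed Integer seed.
#' @param length Motif length (>= 4, default 10).
#' @param information_content Bits per column, in `[0, 2]` (default 1).
#' @return A [pfm()].
#' @export
gen_pfm <- function(seed, length = 10, information_content = 1) {
  if (length < 4) stop("motif length must be >= 4", call. = FALSE)
  if (information_content < 0 || information_content > 2) {
    stop("information content per column must lie in [0, 2] bits",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    eps <- column_epsilon(information_content)
    counts <- vapply(seq_len(length), function(j) {
      p <- rep(eps, 4)
      p[sample.int(4, 1)] <- 1 - 3 * eps
      100 * p
    }, numeric(4))
    pfm(counts, tf_id = sprintf("SYNTF_%d", seed),
        name = sprintf("synthetic profile seed %d", seed))
  })
}

# Solve for the off-consensus probability eps giving the requested
# per-column information content under the (1-3e, e, e, e) shape.
column_epsilon <- function(ic) {
  if (ic >= 2 - 1e-9) return(1e-9)
  if (ic <= 1e-9) return(0.25)
  h <- function(e) {
    p <- c(1 - 3 * e, rep(e, 3))
    2 + sum(p * log2(p)) - ic  # IC(e) - ic
  }
  stats::uniroot(h, c(1e-9, 0.25 - 1e-9), tol = 1e-12)$root
}

#' Realized information content of a frequency matrix
#'
#' @param x A [pfm()].
#' @return Numeric vector of per-column information contents (bits).
#' @export
pfm_information_content <- function(x) {
  stopifnot(inherits(x, "pfm"))
  apply(x$counts, 2, function(cnt) {
    p <- cnt / sum(cnt)
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

# i.i.d. background sequence at the requested GC content.
random_dna <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a seed-fixed reference sequence for p-value calibration
#'
#' The calibration reference is an i.i.d. random sequence of configurable
#' length and GC content (defaults 100,000 bp at GC 0.41, a typical
#' mammalian genomic composition).
#'
#' @param seed Integer seed.
#' @param length Sequence length (default 1e5).
#' @param gc GC fraction (default 0.41).
#' @return A DNA string.
#' @export
gen_reference <- function(seed, length = 100000, gc = 0.41) {
  withr::with_seed(seed, random_dna(length, gc))
}

#' Generate an upstream region with planted consensus sites
#'
#' Plants `n_sites` copies of the profile's consensus (relative score
#' exactly 1) at recorded non-overlapping offsets in an i.i.d. background.
#' Offsets are drawn one per equal-width block of the sequence, which
#' guarantees non-overlap deterministically.
#'
#' @param seed Integer seed.
#' @param pfm A [pfm()] whose consensus is planted.
#' @param n_sites Number of planted sites (may be 0).
#' @param length Region length (default 10000, the database's upstream
#'   window).
#' @param gc Background GC fraction (default 0.41).
#' @param target_id Region id (default `"synthetic_region"`).
#' @return A list with elements `region` ([upstream_region()]) and
#'   `sites` (data frame of planted `start` offsets, 0-based, and the
#'   planted strand).
#' @export
gen_region_with_sites <- function(seed, pfm, n_sites, length = 10000,
                                  gc = 0.41, target_id = "synthetic_region") {
  stopifnot(inherits(pfm, "pfm"), n_sites >= 0)
  L <- ncol(pfm$counts)
  if (n_sites * L >= length / 2) {
    stop("too many sites for the region: need n_sites * motif_len < length/2",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    chars <- strsplit(random_dna(length, gc), "", fixed = TRUE)[[1]]
    starts <- integer(0)
    if (n_sites > 0) {
      block <- length %/% n_sites
      consensus <- strsplit(pwm_consensus(pfm_to_pwm(pfm)), "",
                            fixed = TRUE)[[1]]
      starts <- vapply(seq_len(n_sites), function(i) {
        lo <- (i - 1L) * as.integer(block)
        lo + sample.int(as.integer(block) - L + 1L, 1L) - 1L  # 0-based
      }, integer(1))
      for (s in starts) chars[(s + 1):(s + L)] <- consensus
    }
    list(region = upstream_region(target_id,
                                  paste(chars, collapse = "")),
         sites = data.frame(start = sort(starts),
                            strand = rep("+", n_sites),
                            stringsAsFactors = FALSE))
  })
}

#' Specification of a synthetic meta-regulation network
#'
#' Describes the scale, density and planted structure of a generated
#' network. Defaults: 30 TFs, 100 miRNAs, 500 genes, background edge
#' densities of 1% per level, background edge scores uniform on
#' `[0.1, 0.6]` (strictly below any analysis threshold), planted motif
#' edge scores uniform on `[0.9, 1]` (strictly above), and two planted
#' motifs of each kind.
#'
#' @param seed Integer seed.
#' @param n_tf,n_mirna,n_gene Node counts per type.
#' @param density Named numeric, background edge density per level
#'   (`tf_gene`, `tf_mirna`, `mirna_gene`, `ppi`).
#' @param planted Named integer, planted motif counts per kind (`fbl`,
#'   `ffl_mirna`, `ffl_tf`, `ffl_indirect`).
#' @param bg_score,planted_score Length-2 numeric ranges for background
#'   and planted edge scores.
#' @param species Species code for generated entities.
#' @return An object of class `synthesis_spec`.
#' @export
synthesis_spec <- function(seed = 1, n_tf = 30, n_mirna = 100, n_gene = 500,
                           density = c(tf_gene = 0.01, tf_mirna = 0.01,
                                       mirna_gene = 0.01, ppi = 0),
                           planted = c(fbl = 2, ffl_mirna = 2, ffl_tf = 2,
                                       ffl_indirect = 2),
                           bg_score = c(0.1, 0.6),
                           planted_score = c(0.9, 1),
                           species = "hsa") {
  if (bg_score[2] >= planted_score[1]) {
    stop("background scores must lie strictly below planted scores",
         call. = FALSE)
  }
  planted <- planted[c("fbl", "ffl_mirna", "ffl_tf", "ffl_indirect")]
  planted[is.na(planted)] <- 0
  names(planted) <- c("fbl", "ffl_mirna", "ffl_tf", "ffl_indirect")
  need_tf <- planted[["fbl"]] + planted[["ffl_mirna"]] + planted[["ffl_tf"]] +
    2 * planted[["ffl_indirect"]]
  need_mi <- sum(planted)
  need_g <- planted[["ffl_mirna"]] + planted[["ffl_tf"]] +
    planted[["ffl_indirect"]]
  if (n_tf < need_tf || n_mirna < need_mi || n_gene < need_g) {
    stop("not enough nodes to plant the requested motifs", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_tf = n_tf, n_mirna = n_mirna,
                 n_gene = n_gene, density = density, planted = planted,
                 bg_score = bg_score, planted_score = planted_score,
                 species = species),
            class = "synthesis_spec")
}

#' Generate a synthetic network with planted motifs and expression
#'
#' Builds an interaction table whose planted feedback / feedforward loops
#' sit on mutually disjoint node sets with super-threshold scores, over a
#' background of sub-threshold random edges, plus an expression table
#' assigning anti-correlated directions across planted miRNA-target pairs
#' (miRNAs down-regulated, their planted targets and reciprocal TFs
#' up-regulated -- the configuration of a repressed miRNA family whose
#' targets escape repression).
#'
#' @param spec A [synthesis_spec()].
#' @return A list with elements `table` (an [interaction_table()]),
#'   `truth` (named list of planted motif data frames, in the exact
#'   layout returned by [find_motifs()]), and `expression` (an
#'   [expression_table()]).
#' @export
gen_network <- function(spec) {
  stopifnot(inherits(spec, "synthesis_spec"))
  tf_ids <- sprintf("TF%03d", seq_len(spec$n_tf))
  mi_ids <- sprintf("%s-mir-%03d", spec$species, seq_len(spec$n_mirna))
  g_ids <- sprintf("G%04d", seq_len(spec$n_gene))
  ents <- entities(c(tf_ids, mi_ids, g_ids),
                   etype = rep(c("TF", "MIRNA", "GENE"),
                               c(spec$n_tf, spec$n_mirna, spec$n_gene)),
                   species = spec$species)
  withr::with_seed(spec$seed, {
    ps <- function(n) runif(n, spec$planted_score[1], spec$planted_score[2])
    bs <- function(n) runif(n, spec$bg_score[1], spec$bg_score[2])
    next_tf <- 0L; next_mi <- 0L; next_g <- 0L
    take_tf <- function() { next_tf <<- next_tf + 1L; tf_ids[next_tf] }
    take_mi <- function() { next_mi <<- next_mi + 1L; mi_ids[next_mi] }
    take_g <- function() { next_g <<- next_g + 1L; g_ids[next_g] }
    edges <- list()
    add_edge <- function(src, tgt, level, score) {
      edges[[length(edges) + 1L]] <<- data.frame(
        source_id = src, target_id = tgt, level = level, score = score,
        stringsAsFactors = FALSE)
      score
    }
    truth <- list(FBL = NULL, FFL_MIRNA = NULL, FFL_TF = NULL,
                  FFL_INDIRECT = NULL)
    down_mirnas <- character(0); up_targets <- character(0)
    for (i in seq_len(spec$planted[["fbl"]])) {
      t <- take_tf(); m <- take_mi()
      s1 <- add_edge(t, m, "TF_MIRNA", ps(1))
      s2 <- add_edge(m, t, "MIRNA_GENE", ps(1))
      truth$FBL <- rbind(truth$FBL, data.frame(
        kind = "FBL", tf = t, mirna = m, score_tf_mirna = s1,
        score_mirna_tf = s2, stringsAsFactors = FALSE))
      down_mirnas <- c(down_mirnas, m); up_targets <- c(up_targets, t)
    }
    for (i in seq_len(spec$planted[["ffl_mirna"]])) {
      m <- take_mi(); t <- take_tf(); g <- take_g()
      s1 <- add_edge(m, t, "MIRNA_GENE", ps(1))
      s2 <- add_edge(m, g, "MIRNA_GENE", ps(1))
      s3 <- add_edge(t, g, "TF_GENE", ps(1))
      truth$FFL_MIRNA <- rbind(truth$FFL_MIRNA, data.frame(
        kind = "FFL_MIRNA", mirna = m, tf = t, gene = g,
        score_mirna_tf = s1, score_mirna_gene = s2, score_tf_gene = s3,
        stringsAsFactors = FALSE))
      down_mirnas <- c(down_mirnas, m); up_targets <- c(up_targets, t, g)
    }
    for (i in seq_len(spec$planted[["ffl_tf"]])) {
      t <- take_tf(); m <- take_mi(); g <- take_g()
      s1 <- add_edge(t, m, "TF_MIRNA", ps(1))
      s2 <- add_edge(t, g, "TF_GENE", ps(1))
      s3 <- add_edge(m, g, "MIRNA_GENE", ps(1))
      truth$FFL_TF <- rbind(truth$FFL_TF, data.frame(
        kind = "FFL_TF", tf = t, mirna = m, gene = g,
        score_tf_mirna = s1, score_tf_gene = s2, score_mirna_gene = s3,
        stringsAsFactors = FALSE))
      down_mirnas <- c(down_mirnas, m); up_targets <- c(up_targets, g)
    }
    for (i in seq_len(spec$planted[["ffl_indirect"]])) {
      t1 <- take_tf(); t2 <- take_tf(); m <- take_mi(); g <- take_g()
      s1 <- add_edge(t1, t2, "TF_GENE", ps(1))
      s2 <- add_edge(t2, m, "TF_MIRNA", ps(1))
      s3 <- add_edge(t1, g, "TF_GENE", ps(1))
      s4 <- add_edge(m, g, "MIRNA_GENE", ps(1))
      truth$FFL_INDIRECT <- rbind(truth$FFL_INDIRECT, data.frame(
        kind = "FFL_INDIRECT", tf1 = t1, tf2 = t2, mirna = m, gene = g,
        score_tf1_tf2 = s1, score_tf2_mirna = s2, score_tf1_gene = s3,
        score_mirna_gene = s4, stringsAsFactors = FALSE))
      down_mirnas <- c(down_mirnas, m); up_targets <- c(up_targets, g)
    }
    planted_edges <- if (length(edges)) do.call(rbind, edges) else NULL

    # Sub-threshold background edges sampled per level at the given
    # densities; duplicates of planted pairs and self-pairs are dropped.
    bg_layer <- function(src_pool, tgt_pool, level, dens) {
      n_poss <- length(src_pool) * length(tgt_pool)
      n_draw <- round(dens * n_poss)
      if (n_draw < 1) return(NULL)
      idx <- sample.int(n_poss, n_draw)
      src <- src_pool[((idx - 1L) %% length(src_pool)) + 1L]
      tgt <- tgt_pool[((idx - 1L) %/% length(src_pool)) + 1L]
      ok <- src != tgt
      data.frame(source_id = src[ok], target_id = tgt[ok], level = level,
                 score = bs(sum(ok)), stringsAsFactors = FALSE)
    }
    bg <- rbind(
      bg_layer(tf_ids, c(g_ids, tf_ids), "TF_GENE",
               spec$density[["tf_gene"]]),
      bg_layer(tf_ids, mi_ids, "TF_MIRNA", spec$density[["tf_mirna"]]),
      bg_layer(mi_ids, c(g_ids, tf_ids), "MIRNA_GENE",
               spec$density[["mirna_gene"]]),
      if (spec$density[["ppi"]] > 0)
        bg_layer(c(tf_ids, g_ids), c(tf_ids, g_ids), "PPI",
                 spec$density[["ppi"]]))
    all_edges <- rbind(planted_edges, bg)
    if (is.null(all_edges) || !nrow(all_edges)) {
      all_edges <- data.frame(source_id = character(),
                              target_id = character(), level = character(),
                              score = numeric(), stringsAsFactors = FALSE)
    }
    pair_key <- paste(all_edges$source_id, all_edges$target_id,
                      all_edges$level, sep = "\r")
    all_edges <- all_edges[!duplicated(pair_key), , drop = FALSE]
    ints <- interactions(all_edges$source_id, all_edges$target_id,
                         all_edges$level, all_edges$score,
                         evidence = "predicted", source_db = "synthetic")
    tab <- interaction_table(ents, ints)

    up_targets <- setdiff(unique(up_targets), NA)
    expr <- expression_table(
      c(unique(down_mirnas), up_targets),
      c(-abs(rnorm(length(unique(down_mirnas)), 2, 0.3)),
        abs(rnorm(length(up_targets), 2, 0.3))))

    # Canonical sort, matching the motif finders' output layout.
    truth <- lapply(truth, function(m) {
      if (is.null(m)) return(NULL)
      keys <- setdiff(names(m)[!grepl("^score_", names(m))], "kind")
      m <- m[do.call(order, m[keys]), , drop = FALSE]
      rownames(m) <- NULL
      m
    })
    truth <- Filter(Negate(is.null), truth)
    list(table = tab, truth = truth, expression = expr)
  })
}
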