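# Independent brute-force oracles. These deliberately share no code with
# the package internals: per-window scalar loops for the scanner,
# binomial-coefficient sums for the hypergeometric tail, and typed
# expand.grid membership checks for the motif templates.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

# Score every window on both strands one at a time.
oracle_scan <- function(pwm, sequence, min_rel) {
  bases <- c("A", "C", "G", "T")
  code <- match(strsplit(toupper(sequence), "", fixed = TRUE)[[1]], bases)
  L <- ncol(pwm$weights)
  n <- length(code)
  span <- pwm$score_max - pwm$score_min
  comp <- c(4L, 3L, 2L, 1L)
  rows <- list()
  if (n >= L) for (s0 in seq_len(n - L + 1L)) {
    idx <- code[s0:(s0 + L - 1L)]
    if (anyNA(idx)) next
    raw_f <- 0
    raw_r <- 0
    for (j in seq_len(L)) {
      raw_f <- raw_f + pwm$weights[idx[j], j]
      raw_r <- raw_r + pwm$weights[comp[idx[L + 1L - j]], j]
    }
    rel_f <- (raw_f - pwm$score_min) / span
    rel_r <- (raw_r - pwm$score_min) / span
    if (rel_f >= min_rel) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = s0 - 1L, strand = "+", raw_score = raw_f, rel_score = rel_f,
        stringsAsFactors = FALSE)
    }
    if (rel_r >= min_rel) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = s0 - 1L, strand = "-", raw_score = raw_r, rel_score = rel_r,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), strand = character(),
                      raw_score = numeric(), rel_score = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact hypergeometric tail P(X >= k) for all k in 0..min(n, K).
oracle_hyper_tail_all <- function(n, K, N) {
  lo <- max(0L, n + K - N)
  hi <- min(n, K)
  ks <- lo:hi
  pmf <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  tail <- rev(cumsum(rev(pmf)))
  full <- rep(1, hi + 1L)             # k below the support floor: certain
  full[ks + 1L] <- tail
  full                                # index k + 1
}

oracle_hyper_tail <- function(k, n, K, N) {
  oracle_hyper_tail_all(n, K, N)[k + 1L]
}

# Motif oracles: enumerate typed tuples and test edge membership.
oracle_edge_keys <- function(graph) {
  e <- graph$edges
  paste(e$source_id, e$target_id, e$level)
}

oracle_fbl <- function(graph) {
  key <- oracle_edge_keys(graph)
  tfs <- sort(graph$nodes$id[graph$nodes$etype == "TF"])
  mis <- sort(graph$nodes$id[graph$nodes$etype == "MIRNA"])
  if (!length(tfs) || !length(mis)) return(character(0))
  grid <- expand.grid(tf = tfs, mirna = mis, stringsAsFactors = FALSE)
  has <- paste(grid$tf, grid$mirna, "TF_MIRNA") %in% key &
    paste(grid$mirna, grid$tf, "MIRNA_GENE") %in% key
  sort(paste(grid$tf[has], grid$mirna[has]))
}

oracle_ffl <- function(graph, kind) {
  key <- oracle_edge_keys(graph)
  tfs <- graph$nodes$id[graph$nodes$etype == "TF"]
  mis <- graph$nodes$id[graph$nodes$etype == "MIRNA"]
  tgt <- graph$nodes$id[graph$nodes$etype %in% c("GENE", "TF")]
  if (!length(tfs) || !length(mis) || !length(tgt)) return(character(0))
  grid <- expand.grid(tf = tfs, mirna = mis, gene = tgt,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$gene != grid$tf, , drop = FALSE]
  has <- if (kind == "FFL_MIRNA") {
    paste(grid$mirna, grid$tf, "MIRNA_GENE") %in% key &
      paste(grid$mirna, grid$gene, "MIRNA_GENE") %in% key &
      paste(grid$tf, grid$gene, "TF_GENE") %in% key
  } else {
    paste(grid$tf, grid$mirna, "TF_MIRNA") %in% key &
      paste(grid$tf, grid$gene, "TF_GENE") %in% key &
      paste(grid$mirna, grid$gene, "MIRNA_GENE") %in% key
  }
  if (kind == "FFL_MIRNA") {
    sort(paste(grid$mirna[has], grid$tf[has], grid$gene[has]))
  } else {
    sort(paste(grid$tf[has], grid$mirna[has], grid$gene[has]))
  }
}

oracle_ffl_indirect <- function(graph) {
  key <- oracle_edge_keys(graph)
  tfs <- graph$nodes$id[graph$nodes$etype == "TF"]
  mis <- graph$nodes$id[graph$nodes$etype == "MIRNA"]
  tgt <- graph$nodes$id[graph$nodes$etype %in% c("GENE", "TF")]
  if (length(tfs) < 2 || !length(mis) || !length(tgt)) return(character(0))
  grid <- expand.grid(tf1 = tfs, tf2 = tfs, mirna = mis, gene = tgt,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$tf1 != grid$tf2 & grid$gene != grid$tf1 &
                 grid$gene != grid$tf2, , drop = FALSE]
  has <- paste(grid$tf1, grid$tf2, "TF_GENE") %in% key &
    paste(grid$tf2, grid$mirna, "TF_MIRNA") %in% key &
    paste(grid$tf1, grid$gene, "TF_GENE") %in% key &
    paste(grid$mirna, grid$gene, "MIRNA_GENE") %in% key
  sort(paste(grid$tf1[has], grid$tf2[has], grid$mirna[has], grid$gene[has]))
}

# Member-id keys of a motif data frame, comparable to the oracles above.
motif_keys <- function(m) {
  if (!nrow(m)) return(character(0))
  cols <- setdiff(names(m)[!grepl("^score_", names(m))], "kind")
  sort(apply(m[cols], 1, paste, collapse = " "))
}
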