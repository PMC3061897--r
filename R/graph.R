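# Assembly of the multi-level regulation graph and exhaustive extraction
# of its loop motifs. The graph keeps directed regulatory edges (TF->gene,
# TF->miRNA, miRNA->gene) in one layer and undirected protein-protein
# interactions in a separate decorative layer that never enters motif
# templates. A TF node and its coding gene are a single node, so a
# miRNA->TF-messenger edge appears as a MIRNA_GENE edge targeting the TF.

#' Build a regulation graph from an interaction table
#'
#' Applies the two score cursors: transcriptional edges (`TF_GENE`,
#' `TF_MIRNA`) are kept when `score >= tf_threshold`, post-transcriptional
#' edges (`MIRNA_GENE`) when `score >= mirna_threshold`. The node set is
#' the entities referenced by surviving edges; expression directions are
#' attached where ids match; the PPI layer is carried along only on
#' request. Duplicate `(source, target, level)` edges collapse to the
#' best-scoring one; self-edges are impossible by table construction.
#'
#' @param table An [interaction_table()].
#' @param tf_threshold Score cursor for TF regulations (default 0.85).
#' @param mirna_threshold Score cursor for miRNA regulations (default 0.8).
#' @param expression Optional [expression_table()].
#' @param ppi Attach the PPI layer? Default `FALSE`.
#' @return An object of class `regulation_graph` with elements `nodes`,
#'   `edges`, `ppi`.
#' @export
build_graph <- function(table, tf_threshold = 0.85, mirna_threshold = 0.8,
                        expression = NULL, ppi = FALSE) {
  stopifnot(inherits(table, "interaction_table"),
            tf_threshold >= 0, tf_threshold <= 1,
            mirna_threshold >= 0, mirna_threshold <= 1)
  ints <- table$interactions
  is_tf <- ints$level %in% c("TF_GENE", "TF_MIRNA")
  is_mi <- ints$level == "MIRNA_GENE"
  keep <- (is_tf & ints$score >= tf_threshold) |
          (is_mi & ints$score >= mirna_threshold)
  edges <- ints[keep, c("source_id", "target_id", "level", "score")]
  # Best score wins among parallel edges from different source databases.
  edges <- edges[order(edges$source_id, edges$target_id, edges$level,
                       -edges$score), , drop = FALSE]
  ekey <- paste(edges$source_id, edges$target_id, edges$level, sep = "\r")
  edges <- edges[!duplicated(ekey), , drop = FALSE]

  ppi_edges <- ints[ints$level == "PPI", c("source_id", "target_id", "score")]
  if (!ppi) ppi_edges <- ppi_edges[0, , drop = FALSE]

  used <- unique(c(edges$source_id, edges$target_id,
                   ppi_edges$source_id, ppi_edges$target_id))
  nodes <- table$entities[table$entities$id %in% used, , drop = FALSE]
  nodes$expression <- rep(NA_character_, nrow(nodes))
  if (!is.null(expression)) {
    m <- match(nodes$id, expression$id)
    nodes$expression[!is.na(m)] <- expression$direction[m[!is.na(m)]]
  }
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges <- edges[order(edges$source_id, edges$target_id, edges$level), ,
                 drop = FALSE]
  rownames(nodes) <- rownames(edges) <- rownames(ppi_edges) <- NULL
  structure(list(nodes = nodes, edges = edges, ppi = ppi_edges,
                 tf_threshold = tf_threshold,
                 mirna_threshold = mirna_threshold),
            class = "regulation_graph")
}

#' @export
print.regulation_graph <- function(x, ...) {
  cat("Regulation graph:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "directed edges,", nrow(x$ppi), "PPI edges\n")
  cat("  score cursors: TF >=", x$tf_threshold, "; miRNA >=",
      x$mirna_threshold, "\n")
  invisible(x)
}

# Split helpers: directed edge layers by level, with endpoint typing.
graph_layers <- function(graph) {
  e <- graph$edges
  ntype <- setNames(graph$nodes$etype, graph$nodes$id)
  list(
    tm = e[e$level == "TF_MIRNA", , drop = FALSE],              # TF -> miRNA
    tg = e[e$level == "TF_GENE", , drop = FALSE],               # TF -> gene/TF
    mg = e[e$level == "MIRNA_GENE", , drop = FALSE],            # miRNA -> gene/TF
    ntype = ntype)
}

#' Find feedback loops (TF <-> miRNA reciprocal regulation)
#'
#' A feedback loop is a TF `t` and a miRNA `m` with both a transcriptional
#' edge `t -> m` and a post-transcriptional edge `m -> t` (the miRNA
#' repressing the TF's messenger). Enumeration is exhaustive and
#' duplicate-free, sorted by `(tf, mirna)`.
#'
#' @param graph A [build_graph()] object.
#' @return A data frame with columns `kind`, `tf`, `mirna`,
#'   `score_tf_mirna`, `score_mirna_tf`.
#' @export
find_fbl <- function(graph) {
  ly <- graph_layers(graph)
  mt <- ly$mg[ly$ntype[ly$mg$target_id] == "TF", , drop = FALSE]
  out <- merge(
    data.frame(tf = ly$tm$source_id, mirna = ly$tm$target_id,
               score_tf_mirna = ly$tm$score, stringsAsFactors = FALSE),
    data.frame(tf = mt$target_id, mirna = mt$source_id,
               score_mirna_tf = mt$score, stringsAsFactors = FALSE),
    by = c("tf", "mirna"))
  out <- cbind(kind = rep("FBL", nrow(out)), out)
  out <- out[order(out$tf, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find feedforward loops driven by a miRNA or a TF
#'
#' A feedforward loop is a regulator A regulating a second regulator B,
#' with both regulating a common target C. Two direct variants exist
#' here:
#' * `FFL_MIRNA` -- triples `(mirna, tf, gene)` with `m -> t`, `m -> g`
#'   and `t -> g`: the miRNA represses both a TF and one of that TF's
#'   targets.
#' * `FFL_TF` -- triples `(tf, mirna, gene)` with `t -> m`, `t -> g` and
#'   `m -> g`: the TF drives both a miRNA and one of the miRNA's targets.
#'
#' The common target may itself encode a TF. Enumeration is exhaustive,
#' duplicate-free, and sorted on the role-ordered member ids.
#'
#' @param graph A [build_graph()] object.
#' @param kind `"FFL_MIRNA"` or `"FFL_TF"`.
#' @return A role-labeled data frame of motif instances with per-edge
#'   scores.
#' @export
find_ffl <- function(graph, kind = c("FFL_MIRNA", "FFL_TF")) {
  kind <- match.arg(kind)
  ly <- graph_layers(graph)
  if (kind == "FFL_MIRNA") {
    mt <- ly$mg[ly$ntype[ly$mg$target_id] == "TF", , drop = FALSE]
    a <- data.frame(mirna = mt$source_id, tf = mt$target_id,
                    score_mirna_tf = mt$score, stringsAsFactors = FALSE)
    b <- data.frame(mirna = ly$mg$source_id, gene = ly$mg$target_id,
                    score_mirna_gene = ly$mg$score, stringsAsFactors = FALSE)
    x <- merge(a, b, by = "mirna")
    x <- x[x$gene != x$tf, , drop = FALSE]
    cc <- data.frame(tf = ly$tg$source_id, gene = ly$tg$target_id,
                     score_tf_gene = ly$tg$score, stringsAsFactors = FALSE)
    x <- merge(x, cc, by = c("tf", "gene"))
    x <- x[, c("mirna", "tf", "gene", "score_mirna_tf", "score_mirna_gene",
               "score_tf_gene")]
    x <- cbind(kind = rep("FFL_MIRNA", nrow(x)), x)
    x <- x[order(x$mirna, x$tf, x$gene), , drop = FALSE]
  } else {
    a <- data.frame(tf = ly$tm$source_id, mirna = ly$tm$target_id,
                    score_tf_mirna = ly$tm$score, stringsAsFactors = FALSE)
    b <- data.frame(tf = ly$tg$source_id, gene = ly$tg$target_id,
                    score_tf_gene = ly$tg$score, stringsAsFactors = FALSE)
    x <- merge(a, b, by = "tf")
    cc <- data.frame(mirna = ly$mg$source_id, gene = ly$mg$target_id,
                     score_mirna_gene = ly$mg$score, stringsAsFactors = FALSE)
    x <- merge(x, cc, by = c("mirna", "gene"))
    x <- x[, c("tf", "mirna", "gene", "score_tf_mirna", "score_tf_gene",
               "score_mirna_gene")]
    x <- cbind(kind = rep("FFL_TF", nrow(x)), x)
    x <- x[order(x$tf, x$mirna, x$gene), , drop = FALSE]
  }
  rownames(x) <- NULL
  x
}

#' Find indirect feedforward loops (TF -> TF -> miRNA)
#'
#' The indirect variant inserts an intermediate TF into the TF-driven
#' loop: quadruples `(tf1, tf2, mirna, gene)` with `t1 -> t2` (a
#' transcriptional edge onto a TF-coding gene), `t2 -> m`, `t1 -> g` and
#' `m -> g`. Exactly one intermediate is modeled and all four members
#' must be distinct; the collapse `t1 = t2` is the direct TF loop and is
#' excluded here.
#'
#' @param graph A [build_graph()] object.
#' @return A role-labeled data frame with per-edge scores, sorted on
#'   `(tf1, tf2, mirna, gene)`.
#' @export
find_ffl_indirect <- function(graph) {
  ly <- graph_layers(graph)
  tt <- ly$tg[ly$ntype[ly$tg$target_id] == "TF", , drop = FALSE]
  a <- data.frame(tf1 = tt$source_id, tf2 = tt$target_id,
                  score_tf1_tf2 = tt$score, stringsAsFactors = FALSE)
  b <- data.frame(tf2 = ly$tm$source_id, mirna = ly$tm$target_id,
                  score_tf2_mirna = ly$tm$score, stringsAsFactors = FALSE)
  x <- merge(a, b, by = "tf2")
  cc <- data.frame(tf1 = ly$tg$source_id, gene = ly$tg$target_id,
                   score_tf1_gene = ly$tg$score, stringsAsFactors = FALSE)
  x <- merge(x, cc, by = "tf1")
  x <- x[x$gene != x$tf2, , drop = FALSE]
  d <- data.frame(mirna = ly$mg$source_id, gene = ly$mg$target_id,
                  score_mirna_gene = ly$mg$score, stringsAsFactors = FALSE)
  x <- merge(x, d, by = c("mirna", "gene"))
  x <- x[, c("tf1", "tf2", "mirna", "gene", "score_tf1_tf2",
             "score_tf2_mirna", "score_tf1_gene", "score_mirna_gene")]
  x <- cbind(kind = rep("FFL_INDIRECT", nrow(x)), x)
  x <- x[order(x$tf1, x$tf2, x$mirna, x$gene), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Enumerate all requested motif kinds
#'
#' @param graph A [build_graph()] object.
#' @param kinds Subset of `FBL`, `FFL_MIRNA`, `FFL_TF`, `FFL_INDIRECT`.
#' @return A named list of motif data frames.
#' @export
find_motifs <- function(graph, kinds = c("FBL", "FFL_MIRNA", "FFL_TF",
                                         "FFL_INDIRECT")) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  out <- list()
  if ("FBL" %in% kinds) out$FBL <- find_fbl(graph)
  if ("FFL_MIRNA" %in% kinds) out$FFL_MIRNA <- find_ffl(graph, "FFL_MIRNA")
  if ("FFL_TF" %in% kinds) out$FFL_TF <- find_ffl(graph, "FFL_TF")
  if ("FFL_INDIRECT" %in% kinds) out$FFL_INDIRECT <- find_ffl_indirect(graph)
  out
}

#' Filter motifs or a graph by validated TF->miRNA interactions
#'
#' Published, experimentally validated TF->miRNA regulations can be used
#' as a filter: only motifs whose TF->miRNA constituent appears in the
#' validated list survive. The feedback loop and both TF-driven
#' feedforward variants carry such a constituent (`tf -> mirna`,
#' respectively `tf2 -> mirna` for the indirect form); the miRNA-driven
#' feedforward loop has none and is removed by the filter. Applied to a
#' graph, the filter restricts the `TF_MIRNA` edge layer.
#'
#' @param x A motif data frame, a list of them, or a `regulation_graph`.
#' @param validated Data frame with `source_id`, `target_id` columns (an
#'   interaction table's `interactions` element works directly), listing
#'   validated TF->miRNA pairs.
#' @return Same type as `x`, filtered.
#' @export
filter_by_validated <- function(x, validated) {
  if (is.data.frame(validated) && all(c("source_id", "target_id") %in%
                                      names(validated))) {
    vkey <- paste(validated$source_id, validated$target_id, sep = "\r")
  } else if (inherits(validated, "interaction_table")) {
    v <- validated$interactions
    v <- v[v$level == "TF_MIRNA", , drop = FALSE]
    vkey <- paste(v$source_id, v$target_id, sep = "\r")
  } else {
    stop("validated must be a data frame with source_id/target_id or an ",
         "interaction_table", call. = FALSE)
  }
  if (inherits(x, "regulation_graph")) {
    e <- x$edges
    drop <- e$level == "TF_MIRNA" &
      !paste(e$source_id, e$target_id, sep = "\r") %in% vkey
    x$edges <- e[!drop, , drop = FALSE]
    rownames(x$edges) <- NULL
    return(x)
  }
  if (is.data.frame(x)) {
    key <- switch(unique(c(x$kind, "NONE"))[1],
      FBL = paste(x$tf, x$mirna, sep = "\r"),
      FFL_TF = paste(x$tf, x$mirna, sep = "\r"),
      FFL_INDIRECT = paste(x$tf2, x$mirna, sep = "\r"),
      FFL_MIRNA = rep("\r\r", nrow(x)),   # no TF->miRNA constituent
      character(nrow(x)))
    out <- x[key %in% vkey, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  if (is.list(x)) return(lapply(x, filter_by_validated, validated = validated))
  stop("unsupported input to filter_by_validated", call. = FALSE)
}

#' Write motif instances as TSV
#'
#' @param motifs A motif data frame or named list from [find_motifs()].
#' @param path Output path or connection.
#' @return `path`, invisibly.
#' @export
write_motifs <- function(motifs, path) {
  if (is.data.frame(motifs)) motifs <- list(motifs)
  rows <- do.call(rbind, lapply(motifs, function(m) {
    if (!nrow(m)) return(NULL)
    member_cols <- intersect(c("tf", "tf1", "tf2", "mirna", "gene"), names(m))
    score_cols <- grep("^score_", names(m), value = TRUE)
    data.frame(kind = m$kind,
               members = apply(m[member_cols], 1, paste, collapse = ","),
               roles = paste(member_cols, collapse = ","),
               scores = apply(round(m[score_cols], 6), 1, paste,
                              collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(kind = character(), members = character(),
                       roles = character(), scores = character())
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
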