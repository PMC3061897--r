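# Deterministic text exports of the regulation graph. Node shapes encode
# the entity type (box = TF, diamond = miRNA, ellipse = gene) and fill
# colors the expression overlay (green = down-regulated, red =
# up-regulated), the canonical display convention. Node and edge order is
# stable, so identical graphs serialize to identical bytes.

node_shape <- function(etype) {
  c(TF = "box", MIRNA = "diamond", GENE = "ellipse")[etype]
}

node_color <- function(expression) {
  ifelse(is.na(expression), "gray",
         c(up = "red", down = "green", unchanged = "white")[expression])
}

#' Export a regulation graph as DOT, GraphML or SIF text
#'
#' All three formats are emitted with a stable node/edge ordering. DOT and
#' GraphML carry the node shape/color attributes and per-edge scores; SIF
#' is the minimal `source <TAB> level <TAB> target` interaction list, with
#' isolated nodes written as single-field lines (so its line count is the
#' edge count plus the isolated-node count). PPI edges are exported
#' undirected (`dir=none` in DOT).
#'
#' @param graph A [build_graph()] object.
#' @param format One of `"DOT"`, `"GraphML"`, `"SIF"`.
#' @param path Optional output path; when `NULL` the text is returned.
#' @return The serialized text as a character vector of lines (invisibly
#'   when `path` is given).
#' @export
export_graph <- function(graph, format = c("DOT", "GraphML", "SIF"),
                         path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(graph, "regulation_graph"))
  nodes <- graph$nodes[order(graph$nodes$id), , drop = FALSE]
  edges <- graph$edges[order(graph$edges$source_id, graph$edges$target_id,
                             graph$edges$level), , drop = FALSE]
  ppi <- graph$ppi[order(graph$ppi$source_id, graph$ppi$target_id), ,
                   drop = FALSE]
  lines <- switch(format,
    DOT = export_dot(nodes, edges, ppi),
    GraphML = export_graphml(nodes, edges, ppi),
    SIF = export_sif(nodes, edges, ppi))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

export_dot <- function(nodes, edges, ppi) {
  c("digraph metaregulation {",
    sprintf("  \"%s\" [shape=%s, style=filled, fillcolor=%s];",
            nodes$id, node_shape(nodes$etype), node_color(nodes$expression)),
    if (nrow(edges)) sprintf("  \"%s\" -> \"%s\" [label=\"%s\", score=%s];",
                             edges$source_id, edges$target_id, edges$level,
                             as.character(edges$score)),
    if (nrow(ppi)) sprintf("  \"%s\" -> \"%s\" [label=\"PPI\", dir=none, score=%s];",
                           ppi$source_id, ppi$target_id,
                           as.character(ppi$score)),
    "}")
}

export_sif <- function(nodes, edges, ppi) {
  connected <- unique(c(edges$source_id, edges$target_id,
                        ppi$source_id, ppi$target_id))
  isolated <- sort(setdiff(nodes$id, connected))
  c(if (nrow(edges)) paste(edges$source_id, edges$level, edges$target_id,
                           sep = "\t"),
    if (nrow(ppi)) paste(ppi$source_id, "PPI", ppi$target_id, sep = "\t"),
    isolated)
}

export_graphml <- function(nodes, edges, ppi) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  header <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <key id=\"symbol\" for=\"node\" attr.name=\"symbol\" attr.type=\"string\"/>",
    "  <key id=\"etype\" for=\"node\" attr.name=\"etype\" attr.type=\"string\"/>",
    "  <key id=\"species\" for=\"node\" attr.name=\"species\" attr.type=\"string\"/>",
    "  <key id=\"expression\" for=\"node\" attr.name=\"expression\" attr.type=\"string\"/>",
    "  <key id=\"shape\" for=\"node\" attr.name=\"shape\" attr.type=\"string\"/>",
    "  <key id=\"color\" for=\"node\" attr.name=\"color\" attr.type=\"string\"/>",
    "  <key id=\"level\" for=\"edge\" attr.name=\"level\" attr.type=\"string\"/>",
    "  <key id=\"score\" for=\"edge\" attr.name=\"score\" attr.type=\"double\"/>",
    "  <graph id=\"metaregulation\" edgedefault=\"directed\">")
  node_lines <- unlist(lapply(seq_len(nrow(nodes)), function(i) {
    n <- nodes[i, ]
    c(sprintf("    <node id=\"%s\">", esc(n$id)),
      sprintf("      <data key=\"symbol\">%s</data>", esc(n$symbol)),
      sprintf("      <data key=\"etype\">%s</data>", n$etype),
      sprintf("      <data key=\"species\">%s</data>", n$species),
      sprintf("      <data key=\"expression\">%s</data>",
              if (is.na(n$expression)) "" else n$expression),
      sprintf("      <data key=\"shape\">%s</data>", node_shape(n$etype)),
      sprintf("      <data key=\"color\">%s</data>", node_color(n$expression)),
      "    </node>")
  }))
  edge_line <- function(src, tgt, level, score) {
    c(sprintf("    <edge source=\"%s\" target=\"%s\">", esc(src), esc(tgt)),
      sprintf("      <data key=\"level\">%s</data>", level),
      sprintf("      <data key=\"score\">%s</data>", as.character(score)),
      "    </edge>")
  }
  edge_lines <- unlist(lapply(seq_len(nrow(edges)), function(i) {
    edge_line(edges$source_id[i], edges$target_id[i], edges$level[i],
              edges$score[i])
  }))
  ppi_lines <- unlist(lapply(seq_len(nrow(ppi)), function(i) {
    edge_line(ppi$source_id[i], ppi$target_id[i], "PPI", ppi$score[i])
  }))
  c(header, node_lines, edge_lines, ppi_lines, "  </graph>", "</graphml>")
}

#' Parse a GraphML export back into a regulation graph
#'
#' Reads the GraphML dialect written by [export_graph()]; parsing an
#' export and exporting again reproduces the text byte for byte.
#'
#' @param x Path to a GraphML file, or its lines as a character vector.
#' @return A `regulation_graph`.
#' @export
parse_graphml <- function(x) {
  doc <- if (length(x) == 1 && file.exists(x)) xml2::read_xml(x) else
    xml2::read_xml(paste(x, collapse = "\n"))
  ns <- c(g = "http://graphml.graphdrawing.org/xmlns")
  get_data <- function(node, key) {
    d <- xml2::xml_find_first(node,
                              sprintf(".//g:data[@key='%s']", key), ns)
    if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
  }
  node_els <- xml2::xml_find_all(doc, ".//g:node", ns)
  nodes <- data.frame(
    id = xml2::xml_attr(node_els, "id"),
    symbol = vapply(node_els, get_data, character(1), key = "symbol"),
    etype = vapply(node_els, get_data, character(1), key = "etype"),
    species = vapply(node_els, get_data, character(1), key = "species"),
    expression = vapply(node_els, get_data, character(1), key = "expression"),
    stringsAsFactors = FALSE)
  nodes$expression[nodes$expression == ""] <- NA_character_
  edge_els <- xml2::xml_find_all(doc, ".//g:edge", ns)
  alledges <- data.frame(
    source_id = xml2::xml_attr(edge_els, "source"),
    target_id = xml2::xml_attr(edge_els, "target"),
    level = vapply(edge_els, get_data, character(1), key = "level"),
    score = as.numeric(vapply(edge_els, get_data, character(1),
                              key = "score")),
    stringsAsFactors = FALSE)
  ppi <- alledges[alledges$level == "PPI",
                  c("source_id", "target_id", "score"), drop = FALSE]
  edges <- alledges[alledges$level != "PPI", , drop = FALSE]
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges <- edges[order(edges$source_id, edges$target_id, edges$level), ,
                 drop = FALSE]
  ppi <- ppi[order(ppi$source_id, ppi$target_id), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- rownames(ppi) <- NULL
  structure(list(nodes = nodes, edges = edges, ppi = ppi,
                 tf_threshold = NA_real_, mirna_threshold = NA_real_),
            class = "regulation_graph")
}
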