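# Graph assembly, motif enumeration, validated-interaction filtering and
# exports.

test_that("zero thresholds keep every interaction; cursors recount edges", {
  tab <- make_test_table()
  g0 <- build_graph(tab, 0, 0)
  expect_equal(nrow(g0$edges), nrow(tab$interactions))
  for (seed in 1:5) {
    rt <- make_random_table(seed + 10, p_edge = 0.3)
    tf_th <- 0.6; mi_th <- 0.4
    g <- build_graph(rt, tf_th, mi_th)
    e <- rt$interactions
    expected <- sum((e$level %in% c("TF_GENE", "TF_MIRNA") &
                       e$score >= tf_th) |
                      (e$level == "MIRNA_GENE" & e$score >= mi_th))
    expect_equal(nrow(g$edges), expected)
  }
})

test_that("expression directions attach to matching nodes", {
  tab <- make_test_table()
  expr <- expression_table(c("mirA", "TF1", "G1"), c(-2, 1.5, 0.7))
  g <- build_graph(tab, 0, 0, expression = expr)
  n <- g$nodes
  expect_equal(n$expression[n$id == "mirA"], "down")
  expect_equal(n$expression[n$id == "TF1"], "up")
  expect_true(is.na(n$expression[n$id == "mirB"]))
})

test_that("a planted reciprocal TF/miRNA pair is the unique feedback loop", {
  tab <- make_test_table() # TF1 -> mirA (0.95) and mirA -> TF1 (0.9)
  g <- build_graph(tab, 0.85, 0.8)
  fbl <- find_fbl(g)
  expect_equal(nrow(fbl), 1L)
  expect_equal(fbl$tf, "TF1")
  expect_equal(fbl$mirna, "mirA")
  expect_equal(fbl$score_tf_mirna, 0.95)
  expect_equal(fbl$score_mirna_tf, 0.9)
  # empty graph: no loops
  empty <- build_graph(tab, 1, 1)
  expect_equal(nrow(find_fbl(empty)), 0L)
})

test_that("feedforward templates require all three edges", {
  ents <- entities(c("T", "m", "g"), etype = c("TF", "MIRNA", "GENE"))
  full <- interaction_table(ents, interactions(
    c("T", "T", "m"), c("m", "g", "g"),
    c("TF_MIRNA", "TF_GENE", "MIRNA_GENE"), 0.9))
  g <- build_graph(full, 0.5, 0.5)
  ffl <- find_ffl(g, "FFL_TF")
  expect_equal(nrow(ffl), 1L)
  expect_equal(unlist(ffl[1, c("tf", "mirna", "gene")], use.names = FALSE),
               c("T", "m", "g"))
  # removing the miRNA->gene closing edge kills the loop
  partial <- interaction_table(ents, interactions(
    c("T", "T"), c("m", "g"), c("TF_MIRNA", "TF_GENE"), 0.9))
  expect_equal(nrow(find_ffl(build_graph(partial, 0.5, 0.5), "FFL_TF")), 0L)
  expect_error(find_ffl(g, "FBL"), "arg")
})

test_that("miRNA-driven loops may target a TF-coding gene", {
  ents <- entities(c("T1", "T2", "m"), etype = c("TF", "TF", "MIRNA"))
  tab <- interaction_table(ents, interactions(
    c("m", "m", "T1"), c("T1", "T2", "T2"),
    c("MIRNA_GENE", "MIRNA_GENE", "TF_GENE"), 0.9))
  ffl <- find_ffl(build_graph(tab, 0.5, 0.5), "FFL_MIRNA")
  expect_equal(nrow(ffl), 1L)
  expect_equal(unlist(ffl[1, c("mirna", "tf", "gene")], use.names = FALSE),
               c("m", "T1", "T2"))
})

test_that("indirect loops need a distinct intermediate TF", {
  ents <- entities(c("T1", "T2", "m", "g"),
                   etype = c("TF", "TF", "MIRNA", "GENE"))
  tab <- interaction_table(ents, interactions(
    c("T1", "T2", "T1", "m"), c("T2", "m", "g", "g"),
    c("TF_GENE", "TF_MIRNA", "TF_GENE", "MIRNA_GENE"), 0.9))
  ind <- find_ffl_indirect(build_graph(tab, 0.5, 0.5))
  expect_equal(nrow(ind), 1L)
  expect_equal(unlist(ind[1, c("tf1", "tf2", "mirna", "gene")],
                      use.names = FALSE), c("T1", "T2", "m", "g"))
  # a direct TF loop (t -> m, t -> g, m -> g) is not an indirect instance
  direct <- interaction_table(
    entities(c("T", "m", "g"), etype = c("TF", "MIRNA", "GENE")),
    interactions(c("T", "T", "m"), c("m", "g", "g"),
                 c("TF_MIRNA", "TF_GENE", "MIRNA_GENE"), 0.9))
  expect_equal(nrow(find_ffl_indirect(build_graph(direct, 0.5, 0.5))), 0L)
})

test_that("enumeration equals brute force on random graphs", {
  for (seed in 1:15) {
    tab <- make_random_table(seed + 200, n_tf = 6, n_mi = 8, n_g = 10,
                             p_edge = 0.2)
    g <- build_graph(tab, 0, 0)
    expect_equal(motif_keys(find_fbl(g)), oracle_fbl(g))
    expect_equal(motif_keys(find_ffl(g, "FFL_MIRNA")),
                 oracle_ffl(g, "FFL_MIRNA"))
    expect_equal(motif_keys(find_ffl(g, "FFL_TF")),
                 oracle_ffl(g, "FFL_TF"))
    expect_equal(motif_keys(find_ffl_indirect(g)), oracle_ffl_indirect(g))
  }
})

test_that("motif counts are monotone non-increasing in both cursors", {
  tab <- make_random_table(999, n_tf = 6, n_mi = 8, n_g = 10, p_edge = 0.35)
  counts <- function(tf_th, mi_th) {
    vapply(find_motifs(build_graph(tab, tf_th, mi_th)), nrow, integer(1))
  }
  base <- counts(0, 0)
  expect_true(all(counts(0.5, 0) <= base))
  expect_true(all(counts(0, 0.5) <= base))
  expect_true(all(counts(0.5, 0.5) <= counts(0.5, 0)))
})

test_that("reported motifs always exist at the active thresholds", {
  tab <- make_random_table(321, p_edge = 0.35)
  g <- build_graph(tab, 0.3, 0.25)
  key <- paste(g$edges$source_id, g$edges$target_id)
  fbl <- find_fbl(g)
  expect_true(all(paste(fbl$tf, fbl$mirna) %in% key))
  expect_true(all(paste(fbl$mirna, fbl$tf) %in% key))
  ffl <- find_ffl(g, "FFL_TF")
  expect_true(all(paste(ffl$tf, ffl$mirna) %in% key &
                    paste(ffl$tf, ffl$gene) %in% key &
                    paste(ffl$mirna, ffl$gene) %in% key))
})

test_that("validated TF->miRNA lists gate motifs and graphs", {
  tab <- make_test_table()
  g <- build_graph(tab, 0.85, 0.8)
  motifs <- find_motifs(g, c("FBL", "FFL_TF"))
  all_tm <- tab$interactions[tab$interactions$level == "TF_MIRNA", ]
  # superset of all TF->miRNA edges: identity
  expect_equal(filter_by_validated(motifs, all_tm), motifs)
  # empty validated list: nothing survives
  none <- data.frame(source_id = character(), target_id = character())
  expect_true(all(vapply(filter_by_validated(motifs, none), nrow,
                         integer(1)) == 0L))
  # random membership equals a per-motif recount
  for (seed in 1:5) {
    rt <- make_random_table(seed + 400, p_edge = 0.35)
    rg <- build_graph(rt, 0, 0)
    fbl <- find_fbl(rg)
    if (!nrow(fbl)) next
    keep <- withr::with_seed(seed, {
      fbl[sample(c(TRUE, FALSE), nrow(fbl), replace = TRUE), ]
    })
    v <- data.frame(source_id = keep$tf, target_id = keep$mirna)
    got <- filter_by_validated(fbl, v)
    manual <- fbl[paste(fbl$tf, fbl$mirna) %in% paste(v$source_id,
                                                      v$target_id), ]
    rownames(manual) <- NULL
    expect_equal(got, manual)
  }
  # graph filtering restricts the TF_MIRNA layer only
  gv <- filter_by_validated(g, data.frame(source_id = "TF1",
                                          target_id = "mirA"))
  e <- gv$edges
  expect_equal(sum(e$level == "TF_MIRNA"), 1L)
  expect_equal(sum(e$level == "MIRNA_GENE"),
               sum(g$edges$level == "MIRNA_GENE"))
})

test_that("a single feedback loop exports as a 2-node, 2-edge DOT graph", {
  ents <- entities(c("T", "m"), etype = c("TF", "MIRNA"))
  tab <- interaction_table(ents, interactions(
    c("T", "m"), c("m", "T"), c("TF_MIRNA", "MIRNA_GENE"), 0.9))
  g <- build_graph(tab, 0.5, 0.5)
  dot <- export_graph(g, "DOT")
  expect_equal(sum(grepl("shape=", dot)), 2L)
  expect_equal(sum(grepl("->", dot, fixed = TRUE)), 2L)
  expect_true(any(grepl("shape=diamond", dot))) # miRNA diamond
  expect_true(any(grepl("shape=box", dot)))     # TF square
  expect_error(export_graph(g, "PNG"), "arg")
})

test_that("expression colors follow the green-down / red-up convention", {
  ents <- entities(c("T", "m"), etype = c("TF", "MIRNA"))
  tab <- interaction_table(ents, interactions("T", "m", "TF_MIRNA", 0.9))
  expr <- expression_table(c("T", "m"), c(1.2, -0.8))
  dot <- export_graph(build_graph(tab, 0.5, 0.5, expression = expr), "DOT")
  expect_true(any(grepl("\"T\".*fillcolor=red", dot)))
  expect_true(any(grepl("\"m\".*fillcolor=green", dot)))
})

test_that("GraphML export -> parse -> export is byte-identical", {
  tab <- make_random_table(77, p_edge = 0.3)
  expr <- expression_table(tab$entities$id[1:5], c(-1, 2, 0, 1.5, -0.5))
  g <- build_graph(tab, 0.2, 0.2, expression = expr)
  x1 <- export_graph(g, "GraphML")
  g2 <- parse_graphml(x1)
  x2 <- export_graph(g2, "GraphML")
  expect_identical(x1, x2)
  expect_equal(g2$nodes$etype, g$nodes$etype)
  expect_equal(g2$edges$score, g$edges$score)
})

test_that("SIF line count is edge count plus isolated-node count", {
  tab <- make_test_table()
  g <- build_graph(tab, 0, 0)
  # add an isolated node by rebuilding with an extra entity
  g$nodes <- rbind(g$nodes,
                   data.frame(id = "LONER", symbol = "LONER",
                              etype = "GENE", species = "hsa",
                              expression = NA_character_))
  sif <- export_graph(g, "SIF")
  expect_length(sif, nrow(g$edges) + 1L)
  expect_true("LONER" %in% sif)
})
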