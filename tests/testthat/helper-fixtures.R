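# Programmatic fixtures shared across test files.

# A small hand-wired table: two TFs, three miRNAs, three genes, with a
# reciprocal TF/miRNA pair (TF1 <-> mirA) above any threshold.
make_test_table <- function() {
  ents <- entities(
    c("TF1", "TF2", "mirA", "mirB", "mirC", "G1", "G2", "G3"),
    etype = c("TF", "TF", "MIRNA", "MIRNA", "MIRNA",
              "GENE", "GENE", "GENE"))
  ints <- interactions(
    source_id = c("TF1", "TF1", "TF1", "TF2", "mirA", "mirA", "mirB", "TF1"),
    target_id = c("mirA", "mirB", "mirC", "mirA", "TF1", "G1", "G2", "G1"),
    level = c("TF_MIRNA", "TF_MIRNA", "TF_MIRNA", "TF_MIRNA",
              "MIRNA_GENE", "MIRNA_GENE", "MIRNA_GENE", "TF_GENE"),
    score = c(0.95, 0.9, 0.92, 0.3, 0.9, 0.85, 0.88, 0.95))
  interaction_table(ents, ints)
}

# A random single-species table with typed endpoints; scores uniform.
make_random_table <- function(seed, n_tf = 5, n_mi = 8, n_g = 10,
                              p_edge = 0.15) {
  withr::with_seed(seed, {
    tf <- sprintf("T%02d", seq_len(n_tf))
    mi <- sprintf("m%02d", seq_len(n_mi))
    g <- sprintf("g%02d", seq_len(n_g))
    ents <- entities(c(tf, mi, g),
                     etype = rep(c("TF", "MIRNA", "GENE"),
                                 c(n_tf, n_mi, n_g)))
    pick <- function(src, tgt, level) {
      grid <- expand.grid(s = src, t = tgt, stringsAsFactors = FALSE)
      grid <- grid[grid$s != grid$t, , drop = FALSE]
      grid <- grid[runif(nrow(grid)) < p_edge, , drop = FALSE]
      if (!nrow(grid)) return(NULL)
      interactions(grid$s, grid$t, level, runif(nrow(grid)))
    }
    ints <- rbind(pick(tf, mi, "TF_MIRNA"),
                  pick(tf, c(g, tf), "TF_GENE"),
                  pick(mi, c(g, tf), "MIRNA_GENE"))
    if (is.null(ints)) {
      ints <- interactions(character(), character(), character(), numeric())
    }
    interaction_table(ents, ints)
  })
}

make_random_pwm <- function(seed, len = NULL, ic = NULL) {
  withr::with_seed(seed * 1000 + 7, {
    if (is.null(len)) len <- sample(6:12, 1)
    if (is.null(ic)) ic <- runif(1, 0.8, 1.8)
  })
  pfm_to_pwm(gen_pfm(seed, len, ic))
}
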