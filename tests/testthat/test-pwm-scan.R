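# PWM conversion, both-strand scanning, empirical p-value calibration and
# hit annotation.

test_that("log-odds conversion matches the smoothing formula", {
  # uniform columns under a uniform background give zero weights
  u <- pfm(matrix(5, 4, 4), "U")
  wu <- pfm_to_pwm(u)
  expect_equal(unname(wu$weights), matrix(0, 4, 4))

  # skewed first column, hand-evaluated: w = log2((n + pc*bg)/(N + pc)/bg)
  counts <- cbind(c(97, 1, 1, 1), matrix(25, 4, 3))
  pw <- pfm_to_pwm(pfm(counts, "S"), pseudocount = 1)
  expect_equal(unname(pw$weights[1, 1]), log2((97 + 0.25) / 101 / 0.25))
  expect_equal(unname(pw$weights[2, 1]), log2((1 + 0.25) / 101 / 0.25))
  expect_gt(pw$weights[1, 1], 0)
  expect_lt(pw$weights[2, 1], 0)

  # attainable extrema are the per-column sums of extremes
  expect_equal(pw$score_min, sum(apply(pw$weights, 2, min)))
  expect_equal(pw$score_max, sum(apply(pw$weights, 2, max)))

  # degenerate inputs
  expect_error(pfm(matrix(c(0, 0, 0, 0, rep(1, 12)), 4), "Z"),
               "positive total")
  expect_error(pfm(matrix(1, 4, 3), "short"), "length")
  expect_error(pfm_to_pwm(u, pseudocount = 0), "pseudocount")
})

test_that("consensus scores 1, anti-consensus 0, for random profiles", {
  for (seed in 1:25) {
    pw <- make_random_pwm(seed)
    hc <- scan_region(pw, pwm_consensus(pw), min_rel_score = 0)
    expect_equal(max(hc$rel_score), 1)
    expect_equal(hc$raw_score[hc$strand == "+"], pw$score_max)
    ha <- scan_region(pw, pwm_anticonsensus(pw), min_rel_score = 0)
    expect_equal(min(ha$rel_score), 0)
    expect_true(all(hc$rel_score >= 0 & hc$rel_score <= 1))
  }
})

test_that("a planted consensus site is recovered at its offset", {
  p <- gen_pfm(11, 9, 1.6)
  pw <- pfm_to_pwm(p)
  gen <- gen_region_with_sites(12, p, n_sites = 0, length = 400)
  chars <- strsplit(gen$region$sequence, "")[[1]]
  chars[138:146] <- strsplit(pwm_consensus(pw), "")[[1]]
  region <- upstream_region("mir-x", paste(chars, collapse = ""))
  hits <- scan_region(pw, region, min_rel_score = 0.95)
  top <- hits[hits$rel_score == 1 & hits$strand == "+", ]
  expect_true(137 %in% top$start)
  expect_equal(hits[hits$start == 137 & hits$strand == "+", "site_seq"],
               pwm_consensus(pw))
  # whatever else passes 0.95 must agree with the brute-force scorer
  orc <- oracle_scan(pw, region$sequence, 0.95)
  expect_equal(hits$start, orc$start)
  expect_equal(hits$strand, orc$strand)
  expect_equal(hits$raw_score, orc$raw_score, tolerance = 1e-12)
})

test_that("scanning agrees with the sliding-window oracle", {
  for (seed in 1:10) {
    pw <- make_random_pwm(seed)
    seq <- gen_reference(seed + 500, 500)
    hits <- scan_region(pw, seq, min_rel_score = 0.65)
    orc <- oracle_scan(pw, seq, 0.65)
    expect_equal(hits$start, orc$start)
    expect_equal(hits$strand, orc$strand)
    expect_equal(hits$rel_score, orc$rel_score, tolerance = 1e-12)
  }
})

test_that("windows containing N are skipped", {
  pw <- make_random_pwm(3, len = 6)
  seq <- paste0(strrep("A", 20), "N", strrep("A", 20))
  hits <- scan_region(pw, seq, min_rel_score = 0)
  L <- 6
  # no reported window may touch the N at 0-based offset 20
  expect_true(all(hits$end <= 20 | hits$start >= 21))
  expect_equal(nrow(hits), 2 * 2 * (21 - L)) # both strands, both A-runs
})

test_that("short regions warn and return no hits", {
  pw <- make_random_pwm(4, len = 10)
  expect_warning(h <- scan_region(pw, "ACGT"), "shorter than motif")
  expect_equal(nrow(h), 0L)
})

test_that("threshold filtering is monotone (hit-set nesting)", {
  for (seed in 1:10) {
    pw <- make_random_pwm(seed + 40)
    seq <- gen_reference(seed + 600, 400)
    lo <- scan_region(pw, seq, 0.65)
    hi <- scan_region(pw, seq, 0.85)
    expect_true(all(paste(hi$start, hi$strand) %in%
                      paste(lo$start, lo$strand)))
    expect_true(all(hi$rel_score >= 0.85))
  }
})

test_that("scanning the reverse complement mirrors the hit set", {
  for (seed in 1:8) {
    pw <- make_random_pwm(seed + 80)
    seq <- gen_reference(seed + 700, 300)
    fwd <- scan_region(pw, seq, 0.6)
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]),
                collapse = "")
    rev_hits <- scan_region(pw, rc, 0.6)
    n <- nchar(seq)
    mirrored <- data.frame(start = n - fwd$end,
                           strand = ifelse(fwd$strand == "+", "-", "+"),
                           rel = fwd$rel_score)
    mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
    expect_equal(rev_hits$start, as.integer(mirrored$start))
    expect_equal(rev_hits$strand, as.character(mirrored$strand))
    expect_equal(rev_hits$rel_score, mirrored$rel, tolerance = 1e-12)
  }
})

test_that("calibration tabulates exact exceedance fractions", {
  pw <- make_random_pwm(9)
  ref <- gen_reference(123, 1000)
  calib <- calibrate_pvalues(pw, ref, grid_step = 0.05)
  expect_equal(calib$empirical_p[1], 1) # rel_score 0: every window
  # brute-force fraction at every grid point
  all_rel <- oracle_scan(pw, ref, 0)$rel_score
  for (i in seq_len(nrow(calib))) {
    expect_identical(calib$empirical_p[i],
                     mean(all_rel >= calib$rel_score[i] - 1e-9))
  }
  expect_true(all(diff(calib$empirical_p) <= 0))
  # the maximum observed score keeps exactly its multiplicity
  expect_equal(pvalue_at(calib, 1), sum(all_rel >= 1) / length(all_rel))
  expect_error(calibrate_pvalues(pw, "ACGTACGT"), "at least 10")
})

test_that("hits pick up calibrated p-values non-increasing in score", {
  pw <- make_random_pwm(10)
  ref <- gen_reference(321, 2000)
  calib <- calibrate_pvalues(pw, ref, grid_step = 0.01)
  hits <- assign_pvalues(scan_region(pw, gen_reference(55, 500), 0.5), calib)
  expect_true(all(hits$pvalue >= 0 & hits$pvalue <= 1))
  o <- order(hits$rel_score)
  expect_true(all(diff(hits$pvalue[o]) <= 1e-15))
})

test_that("CGI/promoter annotation respects half-open BED overlap", {
  hits <- data.frame(tf_id = "T", target_id = "m",
                     start = c(10L, 50L), end = c(20L, 60L),
                     strand = "+", raw_score = 1, rel_score = 0.9,
                     pvalue = NA_real_, in_cgi = NA, in_promoter = NA,
                     site_seq = "ACGTACGTAC", stringsAsFactors = FALSE)
  region <- upstream_region("m", strrep("A", 100), chrom = "chr1",
                            start = 1001L, strand = "+")
  # genomic span of hit 1 is 1011..1020 (1-based inclusive)
  inside <- data.frame(chrom = "chr1", start = 1005, end = 1015)
  abutting <- data.frame(chrom = "chr1", start = 1020, end = 1030) # 0-based:
  # covers genomic 1021.. so zero overlap with ..1020
  ann <- annotate_hits(hits, cgi = inside, promoters = abutting, region)
  expect_equal(ann$genome_start, c(1011L, 1051L))
  expect_equal(ann$in_cgi, c(TRUE, FALSE))
  expect_equal(ann$in_promoter, c(FALSE, FALSE))
  # interval on another chromosome never flags
  other <- data.frame(chrom = "chr2", start = 0, end = 1e6)
  expect_false(any(annotate_hits(hits, cgi = other, promoters = NULL,
                                 region)$in_cgi))
})

test_that("minus-strand anchors map offsets leftwards on the genome", {
  hits <- data.frame(tf_id = "T", target_id = "m", start = 0L, end = 10L,
                     strand = "+", raw_score = 1, rel_score = 1,
                     pvalue = NA_real_, in_cgi = NA, in_promoter = NA,
                     site_seq = "ACGTACGTAC", stringsAsFactors = FALSE)
  region <- upstream_region("m", strrep("A", 100), chrom = "chr5",
                            start = 5000L, strand = "-")
  ann <- annotate_hits(hits, NULL, NULL, region)
  expect_equal(ann$genome_start, 4991L)
  expect_equal(ann$genome_end, 5000L)
})

test_that("random annotation agrees with pairwise overlap checking", {
  withr::with_seed(77, {
    starts <- sort(sample(0:480, 20))
    hits <- data.frame(tf_id = "T", target_id = "m", start = starts,
                       end = starts + 8L, strand = "+", raw_score = 1,
                       rel_score = 0.9, pvalue = NA_real_, in_cgi = NA,
                       in_promoter = NA, site_seq = "ACGTACGT",
                       stringsAsFactors = FALSE)
    region <- upstream_region("m", strrep("A", 500), chrom = "chrX",
                              start = 100L, strand = "+")
    b_start <- sample(50:550, 5)
    bed <- data.frame(chrom = "chrX", start = b_start, end = b_start + 30)
    ann <- annotate_hits(hits, cgi = bed, promoters = NULL, region)
    # O(n*m) oracle on 1-based inclusive genomic spans
    for (i in seq_len(nrow(hits))) {
      g1 <- 100 + hits$start[i]
      g2 <- 100 + hits$end[i] - 1
      manual <- any(g1 <= bed$end & g2 >= bed$start + 1)
      expect_identical(ann$in_cgi[i], manual)
    }
  })
})

test_that("JASPAR flat files parse in both dialects and round-trip", {
  bracketed <- c(">M001 TFalpha",
                 "A [ 10 2 0 7 ]", "C [ 0 12 1 1 ]",
                 "G [ 2 0 13 2 ]", "T [ 2 0 0 4 ]")
  bare <- c(">M001 TFalpha", "10 2 0 7", "0 12 1 1", "2 0 13 2", "2 0 0 4")
  f1 <- withr::local_tempfile(); writeLines(bracketed, f1)
  f2 <- withr::local_tempfile(); writeLines(bare, f2)
  p1 <- read_jaspar(f1)[[1]]
  p2 <- read_jaspar(f2)[[1]]
  expect_equal(p1$counts, p2$counts)
  expect_equal(p1$name, "TFalpha")
  f3 <- withr::local_tempfile()
  write_jaspar(p1, f3)
  expect_equal(read_jaspar(f3)[[1]]$counts, p1$counts)
  # byte-stability of re-serialization
  f4 <- withr::local_tempfile()
  write_jaspar(read_jaspar(f3)[[1]], f4)
  expect_identical(readLines(f3), readLines(f4))
})

test_that("FASTA regions round-trip with their coordinate sidecar", {
  regions <- list(
    upstream_region("mir-a", "ACGTACGTACGTACGT", "chr1", 100L, "+"),
    upstream_region("mir-b", "GGGGCCCCAAAATTTT", "chr2", 900L, "-"))
  fa <- withr::local_tempfile(fileext = ".fa")
  sc <- withr::local_tempfile(fileext = ".tsv")
  write_regions(regions, fa, sc)
  back <- read_regions(fa, sc)
  expect_equal(back$`mir-a`$sequence, regions[[1]]$sequence)
  expect_equal(back$`mir-b`$start, 900L)
  expect_equal(back$`mir-b`$strand, "-")
})
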