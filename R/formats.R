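# File formats around the scanner: JASPAR flat PFMs, FASTA upstream
# regions with a coordinate sidecar, BED intervals, and the TFBS hit TSV.

#' Read JASPAR-format position frequency matrices
#'
#' Parses the flat JASPAR exchange format: a `>ID name` header followed by
#' four count rows in A, C, G, T order. Both common dialects are accepted
#' -- bracketed rows (`A [ 4 19 0 ]`) and bare whitespace-separated
#' numbers. When row labels are present they are honoured regardless of
#' order; unlabeled rows are taken as A, C, G, T.
#'
#' @param path Path to a flat PFM file (may hold several records).
#' @return A named list of [pfm()] objects.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no '>' headers found in PFM file", call. = FALSE)
  ends <- c(heads[-1] - 1L, length(lines))
  out <- list()
  for (i in seq_along(heads)) {
    hdr <- sub("^>\\s*", "", lines[heads[i]])
    toks <- strsplit(hdr, "\\s+")[[1]]
    tf_id <- toks[1]
    name <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else toks[1]
    body <- lines[(heads[i] + 1L):ends[i]]
    if (length(body) != 4L) {
      stop("PFM record '", tf_id, "' must have exactly 4 count rows",
           call. = FALSE)
    }
    labels <- toupper(sub("^\\s*([ACGTacgt])\\b.*$", "\\1", body))
    labeled <- labels %in% DNA_BASES & grepl("^\\s*[ACGTacgt][^0-9]", body)
    rows <- lapply(body, function(l) {
      l <- sub("^\\s*[ACGTacgt]\\s*", "", l)
      as.numeric(strsplit(trimws(gsub("[][]", " ", l)), "\\s+")[[1]])
    })
    if (any(lengths(rows) != length(rows[[1]]))) {
      stop("ragged count rows in PFM record '", tf_id, "'", call. = FALSE)
    }
    counts <- do.call(rbind, rows)
    if (all(labeled)) counts <- counts[match(DNA_BASES, labels), , drop = FALSE]
    out[[tf_id]] <- pfm(counts, tf_id = tf_id, name = name)
  }
  out
}

#' Write position frequency matrices in JASPAR flat format
#'
#' Emits the bracketed dialect (`A [ ... ]`), which [read_jaspar()] parses
#' back losslessly, so write-then-read is the identity.
#'
#' @param pfms A `pfm` or list of `pfm` objects.
#' @param path Output path or connection.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pfms, path) {
  if (inherits(pfms, "pfm")) pfms <- list(pfms)
  lines <- unlist(lapply(pfms, function(p) {
    c(paste0(">", p$tf_id, " ", p$name),
      vapply(seq_len(4), function(b) {
        paste0(DNA_BASES[b], " [ ",
               paste(as.character(p$counts[b, ]), collapse = " "), " ]")
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read upstream regions from FASTA plus a coordinate sidecar
#'
#' The FASTA record names are target ids; the sidecar TSV
#' (`target_id, chrom, start, strand, length`) anchors each region's 5'
#' end on the genome (1-based). Regions without a sidecar row are kept
#' unanchored.
#'
#' @param fasta Path to a FASTA file of upstream sequences.
#' @param sidecar Optional path to the coordinate TSV.
#' @return A named list of [upstream_region()] objects.
#' @export
read_regions <- function(fasta, sidecar = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  meta <- NULL
  if (!is.null(sidecar)) {
    meta <- read.table(sidecar, header = TRUE, sep = "\t", quote = "",
                       stringsAsFactors = FALSE)
  }
  out <- lapply(seq_along(seqs), function(i) {
    chrom <- NA_character_; start <- NA_integer_; strand <- "+"
    if (!is.null(meta)) {
      j <- match(ids[i], meta$target_id)
      if (!is.na(j)) {
        chrom <- as.character(meta$chrom[j])
        start <- as.integer(meta$start[j])
        strand <- as.character(meta$strand[j])
      }
    }
    upstream_region(ids[i], as.character(seqs[[i]]), chrom = chrom,
                    start = start, strand = strand)
  })
  names(out) <- ids
  out
}

#' Write upstream regions to FASTA plus sidecar
#'
#' @param regions List of [upstream_region()] objects.
#' @param fasta Output FASTA path.
#' @param sidecar Optional output path for the coordinate TSV.
#' @return `fasta`, invisibly.
#' @export
write_regions <- function(regions, fasta, sidecar = NULL) {
  if (inherits(regions, "upstream_region")) regions <- list(regions)
  seqs <- Biostrings::DNAStringSet(vapply(regions, `[[`, character(1),
                                          "sequence"))
  names(seqs) <- vapply(regions, `[[`, character(1), "target_id")
  Biostrings::writeXStringSet(seqs, fasta)
  if (!is.null(sidecar)) {
    meta <- data.frame(
      target_id = names(seqs),
      chrom = vapply(regions, `[[`, character(1), "chrom"),
      start = vapply(regions, `[[`, integer(1), "start"),
      strand = vapply(regions, `[[`, character(1), "strand"),
      length = vapply(regions, `[[`, integer(1), "length"),
      stringsAsFactors = FALSE)
    write.table(meta, sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta)
}

#' Read BED intervals
#'
#' Thin wrapper over `rtracklayer::import` returning a plain data frame in
#' native BED semantics (0-based, half-open), the convention
#' [annotate_hits()] expects.
#'
#' @param path Path to a BED file.
#' @return A `data.frame` with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

# Genomic span (1-based inclusive) of hits on an anchored region.
# On '+', offset 0 sits at `start` and offsets increase rightwards; on
# '-', offset 0 sits at `start` and offsets walk leftwards.
hit_genomic_span <- function(hits, region) {
  if (region$strand == "+") {
    g1 <- region$start + hits$start
    g2 <- region$start + hits$end - 1L
  } else {
    g1 <- region$start - hits$end + 1L
    g2 <- region$start - hits$start
  }
  data.frame(genome_start = g1, genome_end = g2)
}

#' Annotate binding-site hits with CpG-island and promoter overlap
#'
#' Maps each hit onto the genome through the region's anchor and flags
#' hits whose genomic span overlaps a CpG island or predicted promoter
#' interval by at least 1 bp. Intervals on other chromosomes never match;
#' an unanchored region leaves every flag `FALSE`.
#'
#' @param hits Hit data frame from [scan_region()].
#' @param cgi,promoters BED-style data frames (`chrom`, `start`, `end`,
#'   0-based half-open; see [read_bed()]) or `NULL`.
#' @param region The [upstream_region()] the hits came from.
#' @return The hits with `in_cgi`, `in_promoter` set and genomic
#'   coordinates added as `genome_start`, `genome_end` (1-based inclusive).
#' @export
annotate_hits <- function(hits, cgi = NULL, promoters = NULL, region) {
  stopifnot(inherits(region, "upstream_region"))
  if (!nrow(hits)) {
    hits$in_cgi <- logical(0); hits$in_promoter <- logical(0)
    hits$genome_start <- integer(0); hits$genome_end <- integer(0)
    return(hits)
  }
  if (is.na(region$chrom) || is.na(region$start)) {
    hits$in_cgi <- FALSE; hits$in_promoter <- FALSE
    hits$genome_start <- NA_integer_; hits$genome_end <- NA_integer_
    return(hits)
  }
  span <- hit_genomic_span(hits, region)
  hr <- GenomicRanges::GRanges(region$chrom,
                               IRanges::IRanges(span$genome_start,
                                                span$genome_end))
  overlap_flags <- function(bed) {
    if (is.null(bed) || !nrow(bed)) return(rep(FALSE, nrow(hits)))
    br <- GenomicRanges::GRanges(bed$chrom,
                                 IRanges::IRanges(bed$start + 1L, bed$end))
    # other-chromosome intervals simply never flag
    suppressWarnings(IRanges::overlapsAny(hr, br, minoverlap = 1L))
  }
  hits$in_cgi <- overlap_flags(cgi)
  hits$in_promoter <- overlap_flags(promoters)
  hits$genome_start <- span$genome_start
  hits$genome_end <- span$genome_end
  hits
}

#' Write binding-site hits as a TSV detail table
#'
#' One row per predicted site, mirroring the detail view of a TFBS record:
#' position id, site length, binding sequence, quality (relative) score,
#' offset on the upstream sequence, genomic span, and CGI/promoter flags.
#'
#' @param hits Annotated hit data frame.
#' @param path Output path or connection.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  out <- data.frame(
    id = hits$start,
    tf_id = hits$tf_id, target_id = hits$target_id,
    length = hits$end - hits$start,
    site_seq = hits$site_seq,
    rel_score = as.character(hits$rel_score),
    pvalue = as.character(hits$pvalue),
    start = hits$start, end = hits$end, strand = hits$strand,
    genome_start = if ("genome_start" %in% names(hits)) hits$genome_start else NA,
    genome_end = if ("genome_end" %in% names(hits)) hits$genome_end else NA,
    in_cgi = hits$in_cgi, in_promoter = hits$in_promoter,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
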