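# Tab-delimited ingestion and serialization of interaction and expression
# tables. The canonical interaction dump mirrors the downloadable
# meta-regulation network format:
#   source <TAB> source_type <TAB> target <TAB> target_type <TAB>
#   level <TAB> score <TAB> evidence <TAB> source_db
# '#'-prefixed lines are comments; gzip input is decompressed transparently
# (base R connections autodetect gzip).

INTERACTION_COLUMNS <- c("source", "source_type", "target", "target_type",
                         "level", "score", "evidence", "source_db")

#' Read an interaction table from a tab-delimited dump
#'
#' Parses the meta-regulation network TSV into a validated
#' [interaction_table()]. The entity set is inferred from the edge
#' endpoints; entity types come from the `source_type`/`target_type`
#' columns when present, else from the regulation level. Because dump
#' column names vary between releases, a `dialect` map can rename columns:
#' a named character vector mapping canonical names (`source`, `target`,
#' `level`, `score`, ...) to the names used in the file.
#'
#' Rows whose level is inconsistent with endpoint types are rejected with
#' their line numbers (warning); a score outside `[0, 1]` is an error
#' naming the offending row; duplicate `(source, target, level, source_db)`
#' rows are dropped with a warning.
#'
#' @param path Path to a TSV file (optionally gzip-compressed) or a
#'   connection.
#' @param dialect Optional named character vector, canonical -> file column.
#' @param species Species code stamped on inferred entities.
#' @return An `interaction_table`.
#' @export
read_interactions <- function(path, dialect = NULL, species = "hsa") {
  raw <- read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  if (!is.null(dialect)) {
    pos <- match(dialect, names(raw))
    names(raw)[pos[!is.na(pos)]] <- names(dialect)[!is.na(pos)]
  }
  required <- c("source", "target", "level", "score")
  absent <- setdiff(required, names(raw))
  if (length(absent)) {
    stop("interaction file is missing required column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  score <- suppressWarnings(as.numeric(raw$score))
  if (n && (anyNA(score) || any(score < 0 | score > 1))) {
    bad <- which(is.na(score) | score < 0 | score > 1)
    stop("score outside [0, 1] (or non-numeric) in data row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  level <- raw$level
  bad_level <- which(!level %in% REG_LEVELS)
  if (length(bad_level)) {
    warning("rejected row(s) with unknown level: ",
            paste(head(bad_level, 5), collapse = ", "), call. = FALSE)
  }
  src_t <- if ("source_type" %in% names(raw)) raw$source_type else
    ifelse(level == "MIRNA_GENE", "MIRNA",
           ifelse(level == "PPI", "GENE", "TF"))
  tgt_t <- if ("target_type" %in% names(raw)) raw$target_type else
    ifelse(level == "TF_MIRNA", "MIRNA", "GENE")
  ok <- level %in% REG_LEVELS
  bad_type <- ok & !level_consistent(level, src_t, tgt_t)
  if (any(bad_type)) {
    warning("rejected row(s) with level/type inconsistency: ",
            paste(head(which(bad_type), 5), collapse = ", "), call. = FALSE)
    ok <- ok & !bad_type
  }
  keep <- which(ok)
  edges <- data.frame(
    source_id = raw$source[keep], target_id = raw$target[keep],
    level = level[keep], score = score[keep],
    evidence = if ("evidence" %in% names(raw)) raw$evidence[keep]
               else "predicted",
    source_db = if ("source_db" %in% names(raw)) raw$source_db[keep]
                else "unknown",
    stringsAsFactors = FALSE)
  # Entity set inferred from endpoints; first-seen type wins on conflict.
  ids <- c(edges$source_id, edges$target_id)
  typ <- c(src_t[keep], tgt_t[keep])
  first <- !duplicated(ids)
  ents <- entities(ids[first], etype = typ[first], species = species)
  interaction_table(ents, edges)
}

#' Write an interaction table as a tab-delimited dump
#'
#' Serializes in the fixed canonical column order so that
#' `write_interactions()` then [read_interactions()] is the identity on
#' valid tables, and re-writing a freshly read file reproduces it byte for
#' byte.
#'
#' @param table An [interaction_table()].
#' @param path Output file path or connection.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(table, path) {
  stopifnot(inherits(table, "interaction_table"))
  e <- table$entities
  i <- table$interactions
  out <- data.frame(
    source = i$source_id,
    source_type = e$etype[match(i$source_id, e$id)],
    target = i$target_id,
    target_type = e$etype[match(i$target_id, e$id)],
    level = i$level,
    score = as.character(i$score),
    evidence = i$evidence,
    source_db = i$source_db,
    stringsAsFactors = FALSE)
  names(out) <- INTERACTION_COLUMNS
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression table
#'
#' Expects columns `id` and `log_ratio` (header required; extra columns are
#' ignored). The regulation direction is derived from the sign of the log
#' ratio: positive is `"up"`, negative `"down"`, zero `"unchanged"` --
#' matching the green/red display convention (down/up) used when
#' overlaying expression on networks.
#'
#' @param path TSV path (optionally gzipped) or connection.
#' @return A `data.frame` with columns `id`, `log_ratio`, `direction`,
#'   of class `expression_table`.
#' @export
read_expression <- function(path) {
  raw <- read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
  if (!all(c("id", "log_ratio") %in% names(raw))) {
    stop("expression file must have columns 'id' and 'log_ratio'",
         call. = FALSE)
  }
  lr <- suppressWarnings(as.numeric(raw$log_ratio))
  if (nrow(raw) && anyNA(lr)) {
    stop("non-numeric log_ratio in data row(s): ",
         paste(head(which(is.na(lr)), 5), collapse = ", "), call. = FALSE)
  }
  expression_table(raw$id, lr)
}

#' Construct an expression table from ids and log-ratios
#'
#' @param id Entity ids.
#' @param log_ratio Numeric log expression ratios.
#' @return An `expression_table` data frame.
#' @export
expression_table <- function(id, log_ratio) {
  if (anyDuplicated(id)) {
    stop("duplicate ids in expression table", call. = FALSE)
  }
  direction <- ifelse(log_ratio > 0, "up",
                      ifelse(log_ratio < 0, "down", "unchanged"))
  structure(data.frame(id = as.character(id), log_ratio = log_ratio,
                       direction = direction, stringsAsFactors = FALSE),
            class = c("expression_table", "data.frame"))
}

#' Write an expression table
#'
#' @param expr An `expression_table`.
#' @param path Output path or connection.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  out <- data.frame(id = expr$id, log_ratio = as.character(expr$log_ratio),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
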