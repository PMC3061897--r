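# Domain containers: typed entities (TF / miRNA / gene), scored directed
# interactions at one regulation level, and the validated table that every
# other module consumes.

#' Construct an entity data frame
#'
#' Entities are the typed nodes of the meta-regulation model: transcription
#' factors (`"TF"`), microRNA genes (`"MIRNA"`) and protein-coding genes
#' (`"GENE"`). A TF and the gene encoding it are one entity of type `"TF"`,
#' so miRNA edges onto a TF's messenger target the TF node directly.
#'
#' @param id Character vector of unique, non-empty identifiers.
#' @param symbol Display symbols; defaults to `id`.
#' @param etype Entity types, each one of `"TF"`, `"MIRNA"`, `"GENE"`.
#' @param species Species code, one of `r paste(SPECIES_CODES, collapse = ", ")`.
#' @return A `data.frame` with columns `id`, `symbol`, `etype`, `species`.
#' @examples
#' entities(c("ZEB2", "hsa-mir-200a"), etype = c("TF", "MIRNA"))
#' @export
entities <- function(id, symbol = id, etype, species = "hsa") {
  id <- as.character(id)
  if (!length(id)) {
    return(data.frame(id = character(), symbol = character(),
                      etype = character(), species = character(),
                      stringsAsFactors = FALSE))
  }
  if (any(!nzchar(id)) || anyNA(id)) {
    stop("entity ids must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(id)) {
    stop("duplicate entity ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  etype <- match.arg(as.character(etype), ETYPES, several.ok = TRUE)
  etype <- rep_len(etype, length(id)) # recycled when scalar
  if (length(etype) != length(id)) {
    stop("etype must have length 1 or length(id)", call. = FALSE)
  }
  species <- rep_len(match.arg(species, SPECIES_CODES, several.ok = TRUE),
                     length(id))
  data.frame(id = id, symbol = rep_len(as.character(symbol), length(id)),
             etype = etype, species = species, stringsAsFactors = FALSE)
}

#' Construct an interaction data frame
#'
#' Each row is one scored, typed edge: transcriptional regulation of a gene
#' (`TF_GENE`) or of a miRNA gene (`TF_MIRNA`), post-transcriptional
#' repression of a messenger (`MIRNA_GENE`), or an undirected
#' protein-protein interaction (`PPI`). Scores live on the unified 0-1
#' scale. PPI endpoints are stored in lexicographic order so undirected
#' edges deduplicate deterministically.
#'
#' @param source_id,target_id Endpoint entity ids.
#' @param level Regulation level, one of `r paste(REG_LEVELS, collapse = ", ")`.
#' @param score Numeric scores in `[0, 1]`.
#' @param evidence `"predicted"` or `"validated"`.
#' @param source_db Free-text provenance tag.
#' @return A `data.frame` with the six interaction columns.
#' @export
interactions <- function(source_id, target_id, level, score,
                         evidence = "predicted", source_db = "synthetic") {
  n <- length(source_id)
  level <- rep_len(as.character(level), n)
  bad_level <- !level %in% REG_LEVELS
  if (any(bad_level)) {
    stop("unknown regulation level: ",
         paste(unique(level[bad_level]), collapse = ", "), call. = FALSE)
  }
  score <- rep_len(as.numeric(score), n)
  if (anyNA(score) || any(score < 0 | score > 1)) {
    stop("interaction scores must lie in [0, 1]", call. = FALSE)
  }
  evidence <- rep_len(as.character(evidence), n)
  if (any(!evidence %in% EVIDENCE_KINDS)) {
    stop("evidence must be 'predicted' or 'validated'", call. = FALSE)
  }
  out <- data.frame(source_id = as.character(source_id),
                    target_id = rep_len(as.character(target_id), n),
                    level = level, score = score, evidence = evidence,
                    source_db = rep_len(as.character(source_db), n),
                    stringsAsFactors = FALSE)
  canonicalize_ppi(out)
}

# Undirected PPI edges get lexicographically ordered endpoints.
canonicalize_ppi <- function(edges) {
  flip <- edges$level == "PPI" & edges$source_id > edges$target_id
  if (any(flip)) {
    tmp <- edges$source_id[flip]
    edges$source_id[flip] <- edges$target_id[flip]
    edges$target_id[flip] <- tmp
  }
  edges
}

# Elementwise check that a level is compatible with its endpoint types.
# MIRNA_GENE edges may target a TF entity (the TF's messenger); TF_GENE
# edges likewise (TF regulating another TF's gene).
level_consistent <- function(level, source_etype, target_etype) {
  ok <- logical(length(level))
  ok[level == "TF_GENE"] <-
    (source_etype == "TF" & target_etype %in% c("GENE", "TF"))[level == "TF_GENE"]
  ok[level == "TF_MIRNA"] <-
    (source_etype == "TF" & target_etype == "MIRNA")[level == "TF_MIRNA"]
  ok[level == "MIRNA_GENE"] <-
    (source_etype == "MIRNA" & target_etype %in% c("GENE", "TF"))[level == "MIRNA_GENE"]
  ok[level == "PPI"] <- TRUE
  ok
}

#' Assemble a validated interaction table
#'
#' The central container: an entity set plus a list of scored interactions.
#' Construction enforces the table invariants: every endpoint resolves to an
#' entity, levels are consistent with endpoint types, scores lie in
#' `[0, 1]`, there are no self-edges, and duplicate
#' `(source, target, level, source_db)` rows are dropped with a warning.
#'
#' @param entities Entity `data.frame` from [entities()].
#' @param interactions Interaction `data.frame` from [interactions()].
#' @return An object of class `interaction_table` with elements `entities`
#'   and `interactions`.
#' @seealso [read_interactions()], [filter_interactions()], [build_graph()]
#' @export
interaction_table <- function(entities, interactions) {
  stopifnot(is.data.frame(entities), is.data.frame(interactions))
  missing_ep <- setdiff(c(interactions$source_id, interactions$target_id),
                        entities$id)
  if (length(missing_ep)) {
    stop("interaction endpoints not in entity set: ",
         paste(head(missing_ep, 5), collapse = ", "), call. = FALSE)
  }
  interactions <- canonicalize_ppi(interactions)
  self <- interactions$source_id == interactions$target_id
  if (any(self)) {
    stop("self-edges are not allowed (rows ",
         paste(which(self), collapse = ", "), ")", call. = FALSE)
  }
  src_t <- entities$etype[match(interactions$source_id, entities$id)]
  tgt_t <- entities$etype[match(interactions$target_id, entities$id)]
  bad <- !level_consistent(interactions$level, src_t, tgt_t)
  if (any(bad)) {
    stop("level inconsistent with endpoint types in rows: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  key <- interaction_key(interactions)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate interaction row(s) dropped",
            call. = FALSE)
    interactions <- interactions[!duplicated(key), , drop = FALSE]
  }
  rownames(interactions) <- NULL
  structure(list(entities = entities, interactions = interactions),
            class = "interaction_table")
}

interaction_key <- function(edges) {
  paste(edges$source_id, edges$target_id, edges$level, edges$source_db,
        sep = "\r")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat("Interaction table:", nrow(x$entities), "entities,",
      nrow(x$interactions), "interactions\n")
  tab <- table(factor(x$entities$etype, ETYPES))
  cat("  entities:    ", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  lev <- table(factor(x$interactions$level, REG_LEVELS))
  cat("  interactions:", paste(names(lev), lev, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Filter interactions by score, level and species
#'
#' Keeps exactly the interactions with `score >= min_score` and
#' `level %in% levels`, then prunes the entity set to referenced entities.
#' The database-wide default preset follows the common standard score
#' threshold of 0.85 used when combining all regulation levels; the filter
#' is idempotent and monotone (raising `min_score` never adds edges).
#'
#' @param table An [interaction_table()].
#' @param min_score Minimum unified score in `[0, 1]` (default 0.85).
#' @param levels Regulation levels to keep (default all).
#' @param species Optional species code; keeps entities of that species.
#' @return A filtered `interaction_table`.
#' @export
filter_interactions <- function(table, min_score = 0.85, levels = REG_LEVELS,
                                species = NULL) {
  stopifnot(inherits(table, "interaction_table"),
            min_score >= 0, min_score <= 1)
  levels <- match.arg(levels, REG_LEVELS, several.ok = TRUE)
  ints <- table$interactions
  keep <- ints$score >= min_score & ints$level %in% levels
  if (!is.null(species)) {
    species <- match.arg(species, SPECIES_CODES)
    ok_ids <- table$entities$id[table$entities$species == species]
    keep <- keep & ints$source_id %in% ok_ids & ints$target_id %in% ok_ids
  }
  ints <- ints[keep, , drop = FALSE]
  used <- unique(c(ints$source_id, ints$target_id))
  ents <- table$entities[table$entities$id %in% used, , drop = FALSE]
  rownames(ints) <- rownames(ents) <- NULL
  structure(list(entities = ents, interactions = ints),
            class = "interaction_table")
}

#' Remap species-prefixed miRNA symbols to another species
#'
#' miRNA symbols carry a species prefix (`hsa-mir-200a`); cross-species
#' queries substitute the prefix for the selected species, e.g.
#' `hsa-mir-200a` becomes `mmu-mir-200a` under mouse. Unprefixed gene or TF
#' symbols pass through unchanged and the mapping preserves positions.
#'
#' @param symbols Character vector of symbols.
#' @param target_species Species code to map onto.
#' @return Character vector of the same length.
#' @examples
#' remap_species(c("ZEB2", "hsa-mir-29a"), "rno")
#' @export
remap_species <- function(symbols, target_species) {
  if (!is.character(symbols)) symbols <- as.character(symbols)
  if (length(target_species) != 1L || !target_species %in% SPECIES_CODES) {
    stop("unknown species code '", target_species, "'; expected one of: ",
         paste(SPECIES_CODES, collapse = ", "), call. = FALSE)
  }
  pattern <- paste0("^(", paste(SPECIES_CODES, collapse = "|"), ")-")
  sub(pattern, paste0(target_species, "-"), symbols)
}
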