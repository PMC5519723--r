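# Concept vocabularies, reference graphs and scored edge lists: the node sets
# and evaluation targets every knowledge graph in this package is built over.

#' Construct a concept vocabulary
#'
#' A concept vocabulary holds the disease and symptom concepts that can appear
#' as nodes in a knowledge graph, together with their surface aliases (used for
#' text matching) and optional diagnosis-code mappings (used for structured
#' lookup). A concept's display name always counts as one of its aliases.
#'
#' Concepts listed under both roles are resolved by
#' [resolve_role_conflicts()] before the alias map is built, so a loaded
#' vocabulary never carries a dual-role concept.
#'
#' @param concepts data frame with columns `concept_id`, `name`, `role`
#'   (`"disease"` or `"symptom"`).
#' @param aliases named list, `concept_id` -> character vector of aliases
#'   (the `name` is added automatically).
#' @param codes named list, `concept_id` -> character vector of diagnosis
#'   codes (may be empty).
#' @return An object of class `concept_vocabulary`: a list with elements
#'   `concepts`, `aliases`, `codes`, `alias_map` (alias -> owning concept,
#'   longest-match metadata), `demotions` and `alias_collisions` logs.
#' @export
concept_vocabulary <- function(concepts, aliases = list(), codes = list()) {
  stopifnot(is.data.frame(concepts),
            all(c("concept_id", "name", "role") %in% names(concepts)))
  concepts <- as.data.frame(lapply(concepts[c("concept_id", "name", "role")],
                                   as.character), stringsAsFactors = FALSE)
  dup <- concepts$concept_id[duplicated(concepts$concept_id)]
  if (length(dup) > 0) {
    stop("duplicate concept_id: ", paste(unique(dup), collapse = ", "))
  }
  bad <- setdiff(unique(concepts$role), c("disease", "symptom"))
  if (length(bad) > 0) {
    stop("unknown role token: ", paste(bad, collapse = ", "))
  }
  alias_list <- lapply(seq_len(nrow(concepts)), function(i) {
    id <- concepts$concept_id[i]
    a <- unique(c(concepts$name[i], aliases[[id]]))
    a[nzchar(a)]
  })
  names(alias_list) <- concepts$concept_id
  code_list <- lapply(concepts$concept_id, function(id) {
    unique(as.character(codes[[id]] %||% character()))
  })
  names(code_list) <- concepts$concept_id

  v <- structure(list(concepts = concepts,
                      aliases = alias_list,
                      codes = code_list,
                      demotions = character(),
                      alias_collisions = NULL),
                 class = "concept_vocabulary")
  v$alias_map <- build_alias_map(v)
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Alias -> concept map with a deterministic collision policy: when one alias
# string is claimed by several concepts, the disease-role concept wins, then
# the lexicographically smallest concept_id. Collisions are logged on the
# vocabulary so round-trip tests can demand collision-free alias sets.
build_alias_map <- function(v) {
  n_alias <- lengths(v$aliases)
  map <- data.frame(
    alias = tolower(unlist(v$aliases, use.names = FALSE)),
    concept_id = rep(names(v$aliases), n_alias),
    stringsAsFactors = FALSE
  )
  map$role <- v$concepts$role[match(map$concept_id, v$concepts$concept_id)]
  map <- unique(map)
  clash <- map$alias[duplicated(map$alias)]
  collisions <- NULL
  if (length(clash) > 0) {
    collisions <- map[map$alias %in% clash, ]
    # prefer disease role, then smallest id
    map <- map[order(map$alias, map$role != "disease", map$concept_id), ]
    map <- map[!duplicated(map$alias), ]
  }
  map <- map[order(-nchar(map$alias), map$alias), c("alias", "concept_id")]
  rownames(map) <- NULL
  attr(map, "collisions") <- collisions
  map
}

#' @export
print.concept_vocabulary <- function(x, ...) {
  n <- vocabulary_counts(x)
  cat(sprintf("<concept_vocabulary> %d diseases, %d symptoms, %d aliases\n",
              n[["diseases"]], n[["symptoms"]], nrow(x$alias_map)))
  invisible(x)
}

#' Count diseases and symptoms in a vocabulary
#' @param vocabulary a `concept_vocabulary`.
#' @return Named integer vector with elements `diseases` and `symptoms`.
#' @export
vocabulary_counts <- function(vocabulary) {
  c(diseases = sum(vocabulary$concepts$role == "disease"),
    symptoms = sum(vocabulary$concepts$role == "symptom"))
}

#' Resolve disease/symptom role conflicts
#'
#' Curated concept feeds occasionally list the same concept under both roles
#' (a condition can be a disease in its own right and a symptom of another).
#' Such concepts are kept once, as diseases only; aliases and codes of the
#' merged rows are pooled and each demotion is logged. Duplicate rows sharing
#' a name within one role are also merged. The operation is idempotent.
#'
#' @param raw_concepts data frame with columns `concept_id`, `name`, `role`,
#'   and optionally list columns `aliases` and `codes` (or a
#'   `concept_vocabulary`, whose parts are reused).
#' @return A `concept_vocabulary` with no dual-role concepts.
#' @export
resolve_role_conflicts <- function(raw_concepts) {
  if (inherits(raw_concepts, "concept_vocabulary")) {
    df <- raw_concepts$concepts
    aliases <- raw_concepts$aliases
    codes <- raw_concepts$codes
  } else {
    df <- as.data.frame(raw_concepts, stringsAsFactors = FALSE)
    aliases <- if (!is.null(df$aliases)) stats::setNames(df$aliases, df$concept_id) else list()
    codes <- if (!is.null(df$codes)) stats::setNames(df$codes, df$concept_id) else list()
    df <- df[c("concept_id", "name", "role")]
  }
  key <- tolower(df$name)
  keep <- integer(0)
  demotions <- character()
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) == 1L) {
      keep <- c(keep, idx)
      next
    }
    dis <- idx[df$role[idx] == "disease"]
    chosen <- if (length(dis) > 0) dis[order(df$concept_id[dis])][1L] else idx[order(df$concept_id[idx])][1L]
    keep <- c(keep, chosen)
    if (length(dis) > 0 && any(df$role[idx] == "symptom")) {
      demotions <- c(demotions, sprintf(
        "'%s' listed as both disease and symptom; kept as disease (%s)",
        df$name[chosen], df$concept_id[chosen]))
    }
    # pool aliases/codes of the merged rows onto the surviving concept
    ids <- df$concept_id[idx]
    aliases[[df$concept_id[chosen]]] <-
      unique(c(unlist(aliases[ids], use.names = FALSE), df$name[idx]))
    codes[[df$concept_id[chosen]]] <-
      unique(unlist(codes[ids], use.names = FALSE))
  }
  keep <- sort(keep)
  v <- concept_vocabulary(df[keep, , drop = FALSE],
                          aliases = aliases, codes = codes)
  v$demotions <- demotions
  for (d in demotions) message("role conflict: ", d)
  v
}

#' Load a concept vocabulary from TSV
#'
#' Expects a UTF-8 tab-separated file with header columns `concept_id`,
#' `name`, `role`, `aliases` (pipe-separated, optional) and `codes`
#' (comma-separated, optional). Role conflicts are resolved on load and the
#' alias map is built with longest-match priority.
#'
#' @param path file path.
#' @return A `concept_vocabulary`.
#' @export
load_vocabulary <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character", quote = "",
                           na.strings = NULL, fileEncoding = "UTF-8")
  required <- c("concept_id", "name", "role")
  if (!all(required %in% names(raw))) {
    stop("vocabulary TSV must have columns: ", paste(required, collapse = ", "))
  }
  dup <- raw$concept_id[duplicated(raw$concept_id)]
  if (length(dup) > 0) {
    stop("duplicate concept_id: ", paste(unique(dup), collapse = ", "))
  }
  bad <- which(!raw$role %in% c("disease", "symptom"))
  if (length(bad) > 0) {
    stop(sprintf("unknown role token '%s' at line %d", raw$role[bad[1]],
                 bad[1] + 1L))  # +1 for the header line
  }
  split_field <- function(x, sep) {
    if (is.null(x)) return(rep(list(character()), nrow(raw)))
    lapply(strsplit(x, sep, fixed = TRUE),
           function(p) trimws(p[nzchar(trimws(p))]))
  }
  aliases <- stats::setNames(split_field(raw$aliases, "|"), raw$concept_id)
  codes <- stats::setNames(split_field(raw$codes, ","), raw$concept_id)
  v <- concept_vocabulary(raw[c("concept_id", "name", "role")],
                          aliases = aliases, codes = codes)
  resolve_role_conflicts(v)
}

#' Write a concept vocabulary to TSV
#'
#' Inverse of [load_vocabulary()]; `load_vocabulary(write_vocabulary(v))`
#' reproduces `v` for conflict-free vocabularies.
#'
#' @param vocabulary a `concept_vocabulary`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocabulary, path) {
  df <- vocabulary$concepts
  extra <- mapply(function(id, nm) {
    setdiff(vocabulary$aliases[[id]], nm)
  }, df$concept_id, df$name, SIMPLIFY = FALSE)
  out <- data.frame(
    concept_id = df$concept_id, name = df$name, role = df$role,
    aliases = vapply(extra, paste, "", collapse = "|"),
    codes = vapply(df$concept_id, function(id) {
      paste(vocabulary$codes[[id]], collapse = ",")
    }, ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Load a reference knowledge graph from JSON
#'
#' The reference graph emulates a curated disease-symptom knowledge base:
#' directed edges carrying a coarse conditional-frequency bucket
#' (`"frequent"` or `"always"`), plus an optional per-disease, per-age-bracket
#' marginal frequency table (`"very frequent"` ... `"never"`). Edges naming
#' concepts absent from `vocabulary` (or with the wrong role) are skipped with
#' a warning; the count of skipped edges is kept on the object.
#'
#' @param path JSON file with fields `edges` (array of objects with keys
#'   `disease`, `symptom`, `bucket`) and optionally `disease_frequency`.
#' @param vocabulary the companion `concept_vocabulary`.
#' @return An object of class `reference_graph` with elements `edges`
#'   (data frame `disease_id`, `symptom_id`, `bucket`), `disease_frequency`
#'   and `n_skipped`.
#' @export
load_reference_graph <- function(path, vocabulary) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  edges <- doc$edges
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0) ||
      length(edges) == 0) {
    edges <- data.frame(disease = character(), symptom = character(),
                        bucket = character(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  roles <- stats::setNames(vocabulary$concepts$role,
                           vocabulary$concepts$concept_id)
  ok <- !is.na(roles[edges$disease]) & roles[edges$disease] == "disease" &
        !is.na(roles[edges$symptom]) & roles[edges$symptom] == "symptom"
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    warning(sprintf("%d reference edge(s) named unknown or wrong-role concepts and were skipped",
                    n_skipped))
  }
  bad_bucket <- setdiff(unique(edges$bucket[ok]), c("frequent", "always"))
  if (length(bad_bucket) > 0) {
    stop("unknown frequency bucket: ", paste(bad_bucket, collapse = ", "))
  }
  kept <- edges[ok, , drop = FALSE]
  kept <- unique(data.frame(disease_id = kept$disease,
                            symptom_id = kept$symptom,
                            bucket = kept$bucket, stringsAsFactors = FALSE))
  kept <- kept[order(kept$disease_id, kept$symptom_id), , drop = FALSE]
  rownames(kept) <- NULL
  structure(list(edges = kept,
                 disease_frequency = doc$disease_frequency %||% list(),
                 n_skipped = n_skipped),
            class = "reference_graph")
}

#' Write a reference graph to JSON
#' @param reference a `reference_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reference_graph <- function(reference, path) {
  edges <- reference$edges
  doc <- list(
    edges = data.frame(disease = edges$disease_id, symptom = edges$symptom_id,
                       bucket = edges$bucket, stringsAsFactors = FALSE),
    disease_frequency = reference$disease_frequency
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.reference_graph <- function(x, ...) {
  cat(sprintf("<reference_graph> %d edges over %d diseases (%d skipped on load)\n",
              nrow(x$edges), length(unique(x$edges$disease_id)), x$n_skipped))
  invisible(x)
}

#' Test membership of disease-symptom pairs in a reference graph
#' @param reference a `reference_graph`.
#' @param disease_id,symptom_id character vectors (recycled).
#' @return Logical vector.
#' @export
reference_has_edge <- function(reference, disease_id, symptom_id) {
  paste(disease_id, symptom_id, sep = "\r") %in%
    paste(reference$edges$disease_id, reference$edges$symptom_id, sep = "\r")
}

#' Restrict a reference graph to a set of supported concepts
#'
#' Drops reference edges naming concepts outside `concept_ids`. Used to
#' compute recall against only the reference edges whose concepts survived
#' support filtering (the default denominator in the pipeline); pass the
#' full graph instead for the unrestricted denominator.
#'
#' @param reference a `reference_graph`.
#' @param concept_ids character vector of concept ids to keep.
#' @return A `reference_graph` with the reduced edge set.
#' @export
restrict_reference <- function(reference, concept_ids) {
  keep <- reference$edges$disease_id %in% concept_ids &
          reference$edges$symptom_id %in% concept_ids
  reference$edges <- reference$edges[keep, , drop = FALSE]
  rownames(reference$edges) <- NULL
  reference
}

#' Construct a scored knowledge graph
#'
#' A knowledge graph is a set of directed disease-to-symptom edges, each
#' carrying a nonnegative importance score from the model that proposed it.
#' At most one edge per (disease, symptom) pair is allowed. Edges are stored
#' in the canonical order used by [write_edge_list()]: by disease, then
#' descending importance, ties broken by symptom id.
#'
#' @param edges data frame with columns `disease_id`, `symptom_id`,
#'   `importance`.
#' @param model label of the model that produced the scores.
#' @param config optional list echoing the configuration used.
#' @return An object of class `knowledge_graph`.
#' @export
knowledge_graph <- function(edges, model = "unknown", config = list()) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("disease_id", "symptom_id", "importance") %in% names(edges)))
  edges <- edges[c("disease_id", "symptom_id", "importance")]
  edges$importance <- as.numeric(edges$importance)
  key <- paste(edges$disease_id, edges$symptom_id)
  if (anyDuplicated(key)) {
    stop("duplicate edge: ", key[duplicated(key)][1])
  }
  edges <- edges[order(edges$disease_id, -edges$importance, edges$symptom_id), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 provenance = list(model = model, config = config)),
            class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph> model=%s, %d edges over %d diseases\n",
              x$provenance$model, nrow(x$edges),
              length(unique(x$edges$disease_id))))
  invisible(x)
}

#' Write a scored edge list to TSV
#'
#' One row per edge: `disease_id`, `symptom_id`, `importance` printed at six
#' decimal places; rows sorted by disease, then descending importance, ties
#' broken by symptom id. The ordering is a total order, so re-serialization
#' is byte-identical, and the companion [read_edge_list()] round-trips the
#' graph losslessly at the printed precision.
#'
#' @param graph a `knowledge_graph` with finite importance scores.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  edges <- graph$edges
  bad <- which(!is.finite(edges$importance))
  if (length(bad) > 0) {
    stop(sprintf("non-finite importance for edge (%s, %s)",
                 edges$disease_id[bad[1]], edges$symptom_id[bad[1]]))
  }
  lines <- c("disease_id\tsymptom_id\timportance",
             sprintf("%s\t%s\t%.6f", edges$disease_id, edges$symptom_id,
                     edges$importance))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a scored edge list written by [write_edge_list()]
#' @param path TSV file path.
#' @param model,config provenance to attach.
#' @return A `knowledge_graph`.
#' @export
read_edge_list <- function(path, model = "unknown", config = list()) {
  df <- utils::read.delim(path, colClasses = c("character", "character",
                                               "numeric"), quote = "")
  knowledge_graph(df, model = model, config = config)
}
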