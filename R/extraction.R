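# Concept extraction: free-text alias matching with negation scopes plus
# structured diagnosis-code lookup, yielding the binary patient x concept
# co-occurrence matrix every model in this package is fit to.

TEXT_FIELDS <- c("chief_complaint", "triage_assessment", "nursing_notes",
                 "md_comments")
AGE_BRACKETS <- c("child", "young_adult", "adult", "senior")

#' Default negation trigger phrases
#'
#' Trigger phrases that open a forward negation scope in clinical text, in
#' the spirit of NegEx. Multi-word triggers are matched as token sequences.
#'
#' @return Character vector of trigger phrases.
#' @export
default_negation_triggers <- function() {
  c("denies", "denied", "no", "not", "without", "negative for", "free of",
    "ruled out")
}

# tokens that close an open negation scope (the scope ends before them)
SCOPE_TERMINATORS <- c("but", "however", "except", ".", ",", ";", ":", "!", "?")
SCOPE_MAX_TOKENS <- 6L

# Tokenize into words ([A-Za-z0-9']+ runs) and single punctuation marks,
# with 0-based half-open character spans.
tokenize <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(token = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  m <- gregexpr("[A-Za-z0-9']+|[^A-Za-z0-9'[:space:]]", text)[[1]]
  if (m[1] == -1) {
    return(data.frame(token = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  data.frame(token = tolower(regmatches(text, list(m))[[1]]),
             start = starts, end = starts + lens, stringsAsFactors = FALSE)
}

#' Detect negation scopes in clinical text
#'
#' Each occurrence of a trigger phrase opens a forward scope that runs from
#' the token after the trigger to the earliest of: a termination token
#' (`but`, `however`, `except`, or sentence/list punctuation `. , ; : ! ?`),
#' or six tokens. Overlapping scopes are merged. Scopes are returned as
#' 0-based half-open character intervals into `text`.
#'
#' @param text a single string (empty or `NA` yields no scopes).
#' @param triggers character vector of trigger phrases; see
#'   [default_negation_triggers()].
#' @return Data frame with integer columns `start`, `end`.
#' @export
detect_negation_scopes <- function(text,
                                   triggers = default_negation_triggers()) {
  stopifnot(length(triggers) > 0)
  toks <- tokenize(text)
  empty <- data.frame(start = integer(), end = integer())
  n <- nrow(toks)
  if (n == 0) return(empty)
  trig_seqs <- strsplit(tolower(triggers), "[[:space:]]+")
  # longest trigger first so "negative for" wins over a bare "negative"
  trig_seqs <- trig_seqs[order(-lengths(trig_seqs))]
  intervals <- NULL
  i <- 1L
  while (i <= n) {
    hit_len <- 0L
    for (ts in trig_seqs) {
      k <- length(ts)
      if (i + k - 1L <= n && all(toks$token[i:(i + k - 1L)] == ts)) {
        hit_len <- k
        break
      }
    }
    if (hit_len == 0L) {
      i <- i + 1L
      next
    }
    first <- i + hit_len
    last <- first - 1L
    while (last + 1L <= n && (last + 1L - first) < SCOPE_MAX_TOKENS &&
           !(toks$token[last + 1L] %in% SCOPE_TERMINATORS)) {
      last <- last + 1L
    }
    if (last >= first) {
      intervals <- rbind(intervals, c(toks$start[first], toks$end[last]))
    }
    i <- i + hit_len
  }
  if (is.null(intervals)) return(empty)
  merge_intervals(data.frame(start = intervals[, 1], end = intervals[, 2]))
}

merge_intervals <- function(iv) {
  if (nrow(iv) <= 1) return(iv)
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  out_s <- iv$start[1]; out_e <- iv$end[1]
  starts <- integer(); ends <- integer()
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= out_e) {
      out_e <- max(out_e, iv$end[i])
    } else {
      starts <- c(starts, out_s); ends <- c(ends, out_e)
      out_s <- iv$start[i]; out_e <- iv$end[i]
    }
  }
  data.frame(start = c(starts, out_s), end = c(ends, out_e))
}

#' Create a patient-visit text record
#'
#' @param record_id unique identifier of the visit.
#' @param age_bracket one of `"child"`, `"young_adult"`, `"adult"`,
#'   `"senior"`, or `"unknown"`.
#' @param fields named list of free-text fields; recognized names are
#'   `chief_complaint`, `triage_assessment`, `nursing_notes`, `md_comments`.
#'   Missing fields default to the empty string.
#' @param codes character vector of structured diagnosis codes.
#' @return An object of class `text_record`.
#' @export
text_record <- function(record_id, age_bracket = "unknown", fields = list(),
                        codes = character()) {
  stopifnot(age_bracket %in% c(AGE_BRACKETS, "unknown"))
  full <- stats::setNames(as.list(rep("", length(TEXT_FIELDS))), TEXT_FIELDS)
  for (nm in intersect(names(fields), TEXT_FIELDS)) {
    full[[nm]] <- as.character(fields[[nm]] %||% "")
  }
  structure(list(record_id = as.character(record_id),
                 age_bracket = age_bracket,
                 fields = full,
                 codes = as.character(codes)),
            class = "text_record")
}

#' Find concept mentions in a record's text fields
#'
#' Case-insensitive, word-boundary string matching of vocabulary aliases over
#' each free-text field, longest alias first; matched spans never overlap
#' (the longer alias wins, then the leftmost occurrence). A mention is
#' flagged negated when its span intersects any negation scope of its field.
#'
#' @param record a [text_record()].
#' @param vocabulary a `concept_vocabulary`.
#' @param triggers negation trigger phrases.
#' @return Data frame with columns `concept_id`, `field`, `start`, `end`
#'   (0-based half-open character span) and `negated`.
#' @export
find_mentions <- function(record, vocabulary,
                          triggers = default_negation_triggers()) {
  out <- list()
  amap <- vocabulary$alias_map  # already sorted longest-first
  for (fld in TEXT_FIELDS) {
    text <- record$fields[[fld]]
    if (is.null(text) || is.na(text) || !nzchar(text)) next
    low <- tolower(text)
    nch <- nchar(low)
    occupied <- rep(FALSE, nch)
    scopes <- detect_negation_scopes(text, triggers)
    hits <- list()
    for (i in seq_len(nrow(amap))) {
      alias <- amap$alias[i]
      pat <- paste0("(?<![a-z0-9'])", escape_regex(alias), "(?![a-z0-9'])")
      m <- gregexpr(pat, low, perl = TRUE)[[1]]
      if (m[1] == -1) next
      starts <- as.integer(m) - 1L
      lens <- attr(m, "match.length")
      for (k in seq_along(starts)) {
        s <- starts[k]; e <- s + lens[k]
        if (any(occupied[(s + 1L):e])) next
        occupied[(s + 1L):e] <- TRUE
        neg <- nrow(scopes) > 0 && any(scopes$start < e & s < scopes$end)
        hits[[length(hits) + 1L]] <-
          data.frame(concept_id = amap$concept_id[i], field = fld,
                     start = s, end = e, negated = neg,
                     stringsAsFactors = FALSE)
      }
    }
    if (length(hits) > 0) out[[fld]] <- do.call(rbind, hits)
  }
  if (length(out) == 0) {
    return(data.frame(concept_id = character(), field = character(),
                      start = integer(), end = integer(), negated = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$field, TEXT_FIELDS), res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Construct a binary record matrix
#'
#' @param cells integer 0/1 matrix, patients in rows (rownames = record ids),
#'   concepts in columns (colnames = concept ids).
#' @param roles named character vector mapping each concept id to `"disease"`
#'   or `"symptom"`.
#' @param age_brackets named character vector mapping each record id to an
#'   age bracket (or `"unknown"`).
#' @return An object of class `record_matrix`.
#' @export
record_matrix <- function(cells, roles, age_brackets = NULL) {
  cells <- as.matrix(cells)
  if (!all(cells %in% c(0, 1))) stop("record matrix cells must be binary 0/1")
  storage.mode(cells) <- "integer"
  if (nrow(cells) > 0 && is.null(rownames(cells))) {
    stop("cells must carry record ids (rownames)")
  }
  if (is.null(rownames(cells))) rownames(cells) <- character()
  if (is.null(colnames(cells))) {
    stop("cells must carry concept ids (colnames)")
  }
  if (!all(colnames(cells) %in% names(roles))) {
    stop("every concept column needs a role")
  }
  roles <- roles[colnames(cells)]
  stopifnot(all(roles %in% c("disease", "symptom")))
  if (is.null(age_brackets)) {
    age_brackets <- stats::setNames(rep("unknown", nrow(cells)),
                                    rownames(cells))
  }
  age_brackets <- age_brackets[rownames(cells)]
  structure(list(cells = cells, roles = roles, age_brackets = age_brackets),
            class = "record_matrix")
}

#' @export
print.record_matrix <- function(x, ...) {
  cat(sprintf("<record_matrix> %d patients x %d concepts (%d diseases, %d symptoms)\n",
              nrow(x$cells), ncol(x$cells), length(disease_ids(x)),
              length(symptom_ids(x))))
  invisible(x)
}

#' Disease / symptom column ids of a record matrix
#' @param matrix a `record_matrix`.
#' @return Character vector of concept ids.
#' @export
disease_ids <- function(matrix) names(matrix$roles)[matrix$roles == "disease"]

#' @rdname disease_ids
#' @export
symptom_ids <- function(matrix) names(matrix$roles)[matrix$roles == "symptom"]

#' Build the binary concept-by-patient matrix from records
#'
#' A cell is 1 when the record has at least one non-negated text mention of
#' the concept, or lists a structured diagnosis code mapped to it; otherwise
#' 0. Deterministic given its inputs.
#'
#' @param records list of [text_record()] objects (unique record ids).
#' @param vocabulary a `concept_vocabulary`.
#' @param triggers negation trigger phrases.
#' @return A `record_matrix` over all vocabulary concepts.
#' @export
build_record_matrix <- function(records, vocabulary,
                                triggers = default_negation_triggers()) {
  stopifnot(length(records) > 0)
  ids <- vapply(records, function(r) r$record_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate record_id: ", ids[duplicated(ids)][1])
  }
  concepts <- vocabulary$concepts$concept_id
  code_owner <- code_lookup(vocabulary)
  cells <- matrix(0L, nrow = length(records), ncol = length(concepts),
                  dimnames = list(ids, concepts))
  brackets <- stats::setNames(
    vapply(records, function(r) r$age_bracket, ""), ids)
  for (i in seq_along(records)) {
    r <- records[[i]]
    men <- find_mentions(r, vocabulary, triggers)
    pos <- unique(men$concept_id[!men$negated])
    if (length(pos) > 0) cells[i, pos] <- 1L
    hit <- stats::na.omit(code_owner[r$codes])
    if (length(hit) > 0) cells[i, unique(hit)] <- 1L
  }
  record_matrix(cells,
                stats::setNames(vocabulary$concepts$role, concepts),
                brackets)
}

# code string -> concept_id (first owner wins; duplicate code claims logged)
code_lookup <- function(vocabulary) {
  n <- lengths(vocabulary$codes)
  if (sum(n) == 0) return(stats::setNames(character(), character()))
  tab <- data.frame(code = unlist(vocabulary$codes, use.names = FALSE),
                    concept_id = rep(names(vocabulary$codes), n),
                    stringsAsFactors = FALSE)
  tab <- tab[!duplicated(tab$code), ]
  stats::setNames(tab$concept_id, tab$code)
}

#' Drop weakly supported concept columns
#'
#' Removes disease columns with fewer than `min_disease` positive mentions
#' and symptom columns with fewer than `min_symptom`; patients are retained
#' even when left all-zero. The defaults are the support thresholds used to
#' restrict a vocabulary to concepts with sufficient evidence (100 for
#' diseases, 10 for symptoms). Idempotent.
#'
#' @param matrix a `record_matrix`.
#' @param min_disease,min_symptom nonnegative integer thresholds.
#' @return A filtered `record_matrix` with attribute `dropped_fraction`.
#' @export
apply_support_filter <- function(matrix, min_disease = 100, min_symptom = 10) {
  stopifnot(min_disease >= 0, min_symptom >= 0)
  marg <- colSums(matrix$cells)
  need <- ifelse(matrix$roles == "disease", min_disease, min_symptom)
  keep <- marg >= need
  out <- record_matrix(matrix$cells[, keep, drop = FALSE],
                       matrix$roles[keep], matrix$age_brackets)
  attr(out, "dropped_fraction") <- mean(!keep)
  out
}

#' Per-age-bracket distributions of concepts per record
#'
#' For each age bracket, tabulates the number of positive disease columns and
#' positive symptom columns per record.
#'
#' @param matrix a `record_matrix`.
#' @return Named list (one element per bracket present) of lists with
#'   `diseases` and `symptoms` count tables.
#' @export
summarize_counts <- function(matrix) {
  if (nrow(matrix$cells) == 0) return(stats::setNames(list(), character()))
  d_counts <- rowSums(matrix$cells[, matrix$roles == "disease", drop = FALSE])
  s_counts <- rowSums(matrix$cells[, matrix$roles == "symptom", drop = FALSE])
  out <- list()
  for (b in unique(matrix$age_brackets)) {
    sel <- matrix$age_brackets == b
    out[[b]] <- list(diseases = table(d_counts[sel]),
                     symptoms = table(s_counts[sel]))
  }
  out
}

# ---- serialization ---------------------------------------------------------

#' Read / write patient records as JSONL
#'
#' One JSON object per line with keys `record_id`, `age_bracket`, `fields`
#' and `codes`.
#'
#' @param path file path.
#' @param records list of [text_record()] objects.
#' @return `read_records()` returns a list of `text_record`s;
#'   `write_records()` returns `path` invisibly.
#' @export
read_records <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    text_record(x$record_id, x$age_bracket %||% "unknown",
                as.list(x$fields), unlist(x$codes) %||% character())
  })
}

#' @rdname read_records
#' @export
write_records <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(list(record_id = r$record_id,
                          age_bracket = r$age_bracket,
                          fields = r$fields,
                          codes = I(r$codes)),
                     auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write a record matrix
#'
#' The matrix is stored as Matrix Market coordinate format (`<prefix>.mtx`)
#' plus two index files: `<prefix>.patients.tsv` (`record_id`, `age_bracket`)
#' and `<prefix>.concepts.tsv` (`concept_id`, `role`).
#'
#' @param matrix a `record_matrix`.
#' @param prefix path prefix for the three files.
#' @return `read_record_matrix()` returns a `record_matrix`;
#'   `write_record_matrix()` returns `prefix` invisibly.
#' @export
write_record_matrix <- function(matrix, prefix) {
  Matrix::writeMM(Matrix::Matrix(matrix$cells * 1, sparse = TRUE),
                  paste0(prefix, ".mtx"))
  utils::write.table(
    data.frame(record_id = rownames(matrix$cells),
               age_bracket = unname(matrix$age_brackets)),
    paste0(prefix, ".patients.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  utils::write.table(
    data.frame(concept_id = colnames(matrix$cells),
               role = unname(matrix$roles)),
    paste0(prefix, ".concepts.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(prefix)
}

#' @rdname write_record_matrix
#' @export
read_record_matrix <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  pat <- utils::read.delim(paste0(prefix, ".patients.tsv"),
                           colClasses = "character", quote = "")
  con <- utils::read.delim(paste0(prefix, ".concepts.tsv"),
                           colClasses = "character", quote = "")
  dimnames(m) <- list(pat$record_id, con$concept_id)
  record_matrix(m, stats::setNames(con$role, con$concept_id),
                stats::setNames(pat$age_bracket, pat$record_id))
}
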