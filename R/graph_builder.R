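# Turning fitted models into scored knowledge graphs: per-model importance
# measures, the co-occurrence de-noising floor, and edge selection by
# threshold or per-disease top-N.

#' Importance scores of a fitted logistic regression
#'
#' `IMPT_LR(i) = max(b_ij, 0)`: a symptom whose weight raises the disease
#' probability supports an edge; negative weights are truncated to zero. The
#' intercept is not part of the measure.
#'
#' @param model a `logistic_model`.
#' @return Named nonnegative numeric vector, one score per symptom.
#' @export
importance_lr <- function(model) {
  stopifnot(inherits(model, "logistic_model"))
  pmax(model$weights, 0)
}

#' Importance scores of a fitted naive Bayes model
#'
#' `IMPT_NB(i) = log p(x_i=1 | y_j=1) - log p(x_i=1 | y_j=0)` (natural log):
#' the log relative risk of the symptom under the disease. Using the
#' multiplicative rather than additive contrast means a rare symptom made
#' three times as likely by a disease scores the same as a common one
#' tripled.
#'
#' @param model a `naive_bayes_model`.
#' @return Named numeric vector, one score per symptom.
#' @export
importance_nb <- function(model) {
  stopifnot(inherits(model, "naive_bayes_model"))
  log(model$p_present) - log(model$p_absent)
}

#' Importance scores of a fitted noisy-OR network
#'
#' `IMPT_noisy-or(i, j) = 1 - f_ij`: the probability that disease `j`, when
#' present, turns on symptom `i`. Deterministic causation gives score 1; a
#' disease that never produces the symptom gives score 0.
#'
#' @param model a `noisy_or_model`.
#' @return Symptom x disease matrix of scores in `[0, 1]`.
#' @export
importance_noisy_or <- function(model) {
  stopifnot(inherits(model, "noisy_or_model"))
  1 - model$failure
}

#' Long-format score table for any fitted model
#'
#' Normalizes the per-model importance measures into a single data frame of
#' candidate edges, the common currency of [cooccurrence_filter()],
#' [build_graph()] and the evaluation functions.
#'
#' @param model a fitted model object.
#' @param ... unused.
#' @return Data frame with columns `disease_id`, `symptom_id`, `score` and
#'   attribute `model` (`"logistic"`, `"naive_bayes"` or `"noisy_or"`).
#' @export
score_table <- function(model, ...) UseMethod("score_table")

#' @export
score_table.logistic_model <- function(model, ...) {
  s <- importance_lr(model)
  tab <- data.frame(disease_id = model$disease_id, symptom_id = names(s),
                    score = unname(s), stringsAsFactors = FALSE)
  structure(tab, model = "logistic")
}

#' @export
score_table.naive_bayes_model <- function(model, ...) {
  s <- importance_nb(model)
  tab <- data.frame(disease_id = model$disease_id, symptom_id = names(s),
                    score = unname(s), stringsAsFactors = FALSE)
  structure(tab, model = "naive_bayes")
}

#' @export
score_table.noisy_or_model <- function(model, ...) {
  imp <- importance_noisy_or(model)
  tab <- data.frame(
    disease_id = rep(colnames(imp), each = nrow(imp)),
    symptom_id = rep(rownames(imp), times = ncol(imp)),
    score = as.vector(imp), stringsAsFactors = FALSE)
  structure(tab, model = "noisy_or")
}

#' Combine per-disease score tables
#' @param tables list of score tables from the same model kind.
#' @return A single score table.
#' @export
bind_score_tables <- function(tables) {
  kinds <- unique(vapply(tables, function(t) attr(t, "model") %||% "unknown", ""))
  stopifnot(length(kinds) == 1)
  structure(do.call(rbind, lapply(tables, as.data.frame)), model = kinds)
}

#' Remove weakly co-occurring pairs from a score table
#'
#' As a de-noising measure, candidate edges whose disease and symptom
#' co-occur (both positive) in fewer than `min_count` records are removed
#' from naive Bayes and logistic regression score tables. Pairs are removed
#' outright rather than zeroed, so a later threshold of 0 cannot resurrect
#' them. Noisy-OR score tables pass through unchanged by default; set
#' `applies_to` to extend the floor to them.
#'
#' @param scores a score table (see [score_table()]).
#' @param matrix the `record_matrix` the models were fit to.
#' @param min_count minimum number of co-occurrences.
#' @param applies_to model kinds subject to the filter.
#' @return The filtered score table.
#' @export
cooccurrence_filter <- function(scores, matrix, min_count = 5,
                                applies_to = c("naive_bayes", "logistic")) {
  kind <- attr(scores, "model") %||% "unknown"
  if (!(kind %in% applies_to) || min_count == 0) return(scores)
  co <- crossprod(matrix$cells[, unique(scores$disease_id), drop = FALSE],
                  matrix$cells[, unique(scores$symptom_id), drop = FALSE])
  n_co <- co[cbind(match(scores$disease_id, rownames(co)),
                   match(scores$symptom_id, colnames(co)))]
  out <- scores[n_co >= min_count, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, model = kind)
}

#' Select graph edges by importance threshold or per-disease top-N
#'
#' Threshold mode keeps every pair with `score >= threshold`. Top-N mode
#' keeps, for each disease, the `top_n` highest-scoring symptoms, breaking
#' score ties by symptom id (lexicographic) so selection is deterministic.
#'
#' @param scores a score table.
#' @param threshold keep pairs scoring at least this value (exclusive with
#'   `top_n`).
#' @param top_n keep this many symptoms per disease (exclusive with
#'   `threshold`).
#' @param model provenance label; defaults to the score table's model kind.
#' @return A [knowledge_graph()].
#' @export
build_graph <- function(scores, threshold = NULL, top_n = NULL,
                        model = attr(scores, "model") %||% "unknown") {
  if (is.null(threshold) == is.null(top_n)) {
    stop("supply exactly one of threshold or top_n")
  }
  if (!all(is.finite(scores$score))) stop("scores must be finite")
  if (!is.null(threshold)) {
    kept <- scores[scores$score >= threshold, , drop = FALSE]
    config <- list(mode = "threshold", threshold = threshold)
  } else {
    if (top_n < 0) stop("top_n must be nonnegative")
    ord <- order(scores$disease_id, -scores$score, scores$symptom_id)
    s <- scores[ord, , drop = FALSE]
    rank_in_disease <- stats::ave(seq_len(nrow(s)), s$disease_id,
                                  FUN = seq_along)
    kept <- s[rank_in_disease <= top_n, , drop = FALSE]
    config <- list(mode = "top_n", top_n = top_n)
  }
  knowledge_graph(data.frame(disease_id = kept$disease_id,
                             symptom_id = kept$symptom_id,
                             importance = kept$score,
                             stringsAsFactors = FALSE),
                  model = model, config = config)
}
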