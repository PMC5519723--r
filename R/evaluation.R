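# Evaluation of constructed knowledge graphs: micro-averaged precision-recall
# against a reference graph, the pooled physician-judgment protocol, and the
# comparison statistics (Wilcoxon signed rank, bootstrapped Spearman rho).

pair_key <- function(d, s) paste(d, s, sep = "\r")

# Micro-averaged PR sweep: every distinct score is used as a threshold;
# retrieved = scored pairs at or above it; positives is the full relevant set
# (relevant pairs never scored still count in the recall denominator).
pr_sweep <- function(scores, positive_keys, label) {
  stopifnot(nrow(scores) > 0)
  key <- pair_key(scores$disease_id, scores$symptom_id)
  dup <- duplicated(key)
  if (any(dup)) {  # duplicate candidates: keep the highest score per pair
    ord <- order(key, -scores$score)
    scores <- scores[ord, , drop = FALSE]
    key <- key[ord]
    scores <- scores[!duplicated(key), , drop = FALSE]
    key <- unique(key)
  }
  n_pos <- length(positive_keys)
  ord <- order(-scores$score)
  sc <- scores$score[ord]
  is_pos <- key[ord] %in% positive_keys
  cum_tp <- cumsum(is_pos)
  cum_ret <- seq_along(sc)
  last <- !duplicated(sc, fromLast = TRUE)  # last index at each distinct score
  pts <- data.frame(threshold = sc[last],
                    precision = cum_tp[last] / cum_ret[last],
                    recall = cum_tp[last] / n_pos)
  rownames(pts) <- NULL
  structure(pts, class = c("pr_curve", "data.frame"), label = label,
            n_positive = n_pos)
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> %s: %d points, %d relevant pairs\n",
              attr(x, "label") %||% "?", nrow(x), attr(x, "n_positive")))
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Precision at a given recall level
#'
#' Reads the highest precision achieved at any point whose recall is at
#' least `recall`; a convenience for quoting operating points off a curve.
#'
#' @param curve a `pr_curve`.
#' @param recall target recall level.
#' @return Precision (or `NA` if the recall level is never reached).
#' @export
precision_at_recall <- function(curve, recall) {
  ok <- curve$recall >= recall
  if (!any(ok)) return(NA_real_)
  max(curve$precision[ok])
}

#' Precision-recall curve against a reference graph
#'
#' The binary target is membership of a candidate (disease, symptom) pair in
#' the reference edge set. Overly general symptoms (by default `"pain"`,
#' matched against symptom ids and, when a vocabulary is supplied, names)
#' are dropped from both the candidate and reference sides. All distinct
#' scores serve as thresholds; counts are pooled over all pairs
#' (micro-averaging), and the recall denominator is the number of surviving
#' reference edges.
#'
#' @param graph_scores a score table or `knowledge_graph`.
#' @param reference a `reference_graph`.
#' @param exclude_symptoms symptom identifiers (or names) to exclude.
#' @param vocabulary optional `concept_vocabulary` used to resolve excluded
#'   names to ids.
#' @param label curve label.
#' @return A `pr_curve` data frame with columns `threshold`, `precision`,
#'   `recall`.
#' @export
pr_vs_reference <- function(graph_scores, reference,
                            exclude_symptoms = "pain", vocabulary = NULL,
                            label = NULL) {
  scores <- as_score_table(graph_scores)
  excl <- exclude_symptoms
  if (!is.null(vocabulary)) {
    excl <- union(excl, vocabulary$concepts$concept_id[
      tolower(vocabulary$concepts$name) %in% tolower(exclude_symptoms)])
  }
  ref <- reference$edges[!(reference$edges$symptom_id %in% excl), ,
                         drop = FALSE]
  if (nrow(ref) == 0) stop("reference graph is empty after exclusions")
  scores <- scores[!(scores$symptom_id %in% excl), , drop = FALSE]
  pr_sweep(scores, unique(pair_key(ref$disease_id, ref$symptom_id)),
           label %||% attr(graph_scores, "model") %||% "candidate")
}

as_score_table <- function(x) {
  if (inherits(x, "knowledge_graph")) {
    tab <- data.frame(disease_id = x$edges$disease_id,
                      symptom_id = x$edges$symptom_id,
                      score = x$edges$importance, stringsAsFactors = FALSE)
    return(structure(tab, model = x$provenance$model))
  }
  stopifnot(all(c("disease_id", "symptom_id", "score") %in% names(x)))
  x
}

#' Pool top edges across models for blinded judgment
#'
#' Implements the information-retrieval pooling protocol: the top
#' `n_per_disease` suggestions of each source graph are unioned (plus all
#' reference-graph edges when one is supplied, so the reference is judged
#' alongside the models), duplicates are merged with their provenance
#' recorded, and the presentation order is shuffled by `seed` to blind the
#' judges to the source of each suggestion. Anything outside the pool is
#' treated as irrelevant downstream.
#'
#' @param graphs named list of `knowledge_graph`s (or score tables).
#' @param n_per_disease top-N cutoff applied per disease within each source.
#' @param reference optional `reference_graph` whose edges join the pool.
#' @param seed integer seed for the presentation shuffle.
#' @return Data frame with columns `disease_id`, `symptom_id`, `sources`
#'   (comma-separated provenance) in randomized presentation order.
#' @export
pool_top_edges <- function(graphs, n_per_disease, reference = NULL, seed = 1) {
  if (is.null(names(graphs))) names(graphs) <- paste0("model", seq_along(graphs))
  take <- function(g, nm) {
    tab <- as_score_table(g)
    top <- build_graph(tab, top_n = n_per_disease)$edges
    if (nrow(top) == 0) return(NULL)
    data.frame(disease_id = top$disease_id, symptom_id = top$symptom_id,
               source = nm, stringsAsFactors = FALSE)
  }
  parts <- Map(take, graphs, names(graphs))
  if (!is.null(reference) && nrow(reference$edges) > 0) {
    parts$reference <- data.frame(disease_id = reference$edges$disease_id,
                                  symptom_id = reference$edges$symptom_id,
                                  source = "reference",
                                  stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, parts)
  agg <- stats::aggregate(source ~ disease_id + symptom_id, data = all,
                          FUN = function(s) paste(sort(unique(s)),
                                                  collapse = ","))
  names(agg)[names(agg) == "source"] <- "sources"
  agg <- agg[order(agg$disease_id, agg$symptom_id), , drop = FALSE]
  set.seed(seed)
  agg <- agg[sample.int(nrow(agg)), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

TAG_LEVELS <- c("never", "rarely", "sometimes", "always")

#' Read physician tags from CSV
#'
#' Expects columns `disease_id`, `symptom_id`, `rater_id`, `tag`, one row
#' per (edge, rater) on the four-point scale `always` / `sometimes` /
#' `rarely` / `never`.
#'
#' @param path CSV file path.
#' @return Data frame of ratings.
#' @export
read_physician_tags <- function(path) {
  tags <- utils::read.csv(path, colClasses = "character")
  required <- c("disease_id", "symptom_id", "rater_id", "tag")
  stopifnot(all(required %in% names(tags)))
  key <- paste(tags$disease_id, tags$symptom_id, tags$rater_id)
  if (anyDuplicated(key)) stop("duplicate (edge, rater) rating")
  tags[required]
}

#' Binarize four-point physician tags
#'
#' Two segmentations of the `always` / `sometimes` / `rarely` / `never`
#' scale are supported: `rarely_positive` groups `always`, `sometimes` and
#' `rarely` into the positive class (only `never` is negative);
#' `rarely_negative` assigns both `rarely` and `never` to the negative
#' class.
#'
#' @param tags data frame of ratings (see [read_physician_tags()]).
#' @param scheme `"rarely_positive"` or `"rarely_negative"`.
#' @return The ratings with an added 0/1 column `relevant`.
#' @export
binarize_tags <- function(tags, scheme = c("rarely_positive",
                                           "rarely_negative")) {
  scheme <- match.arg(scheme)
  bad <- setdiff(unique(tags$tag), TAG_LEVELS)
  if (length(bad) > 0) stop("unknown tag token: ", paste(bad, collapse = ", "))
  positive <- if (scheme == "rarely_positive") {
    c("always", "sometimes", "rarely")
  } else {
    c("always", "sometimes")
  }
  tags$relevant <- as.integer(tags$tag %in% positive)
  tags
}

#' Precision-recall curve against binarized physician tags
#'
#' Same sweep semantics as [pr_vs_reference()], with the binarized pooled
#' judgments as the binary target: pairs the judges never saw (outside the
#' pool) count as irrelevant, and the recall denominator is the number of
#' positively tagged pooled edges.
#'
#' @param graph_scores a score table or `knowledge_graph`.
#' @param relevance data frame with columns `disease_id`, `symptom_id`,
#'   `relevant` (0/1), one row per pooled edge (pre-filter to a single rater
#'   or consensus before calling).
#' @param label curve label.
#' @return A `pr_curve`.
#' @export
pr_vs_tags <- function(graph_scores, relevance, label = NULL) {
  scores <- as_score_table(graph_scores)
  key <- pair_key(relevance$disease_id, relevance$symptom_id)
  if (anyDuplicated(key)) {
    stop("multiple relevance rows per edge; aggregate raters first")
  }
  pos <- key[relevance$relevant == 1]
  if (length(pos) == 0) stop("no positively tagged edges")
  pr_sweep(scores, pos,
           label %||% attr(graph_scores, "model") %||% "candidate")
}

#' Per-disease precision at a fixed edge budget
#'
#' For each disease, takes the model's top-`n_per_disease` suggestions and
#' computes the fraction judged relevant (the pooled-judgment analogue) or
#' present in a reference graph. These matched per-disease precisions are
#' the paired samples for [wilcoxon_compare()].
#'
#' @param graph_scores a score table or `knowledge_graph`.
#' @param positives data frame with `disease_id`, `symptom_id` of relevant
#'   pairs (e.g. positively tagged pool rows or reference edges).
#' @param n_per_disease edge budget per disease.
#' @return Named numeric vector of precisions, one per disease with at least
#'   one suggestion.
#' @export
per_disease_precision <- function(graph_scores, positives, n_per_disease) {
  top <- build_graph(as_score_table(graph_scores),
                     top_n = n_per_disease)$edges
  pos_keys <- unique(pair_key(positives$disease_id, positives$symptom_id))
  hit <- pair_key(top$disease_id, top$symptom_id) %in% pos_keys
  vapply(split(hit, top$disease_id), mean, 0)
}

#' Wilcoxon signed-rank test on paired per-disease precisions
#'
#' Two-sided paired test on `a - b`. Zero differences are dropped (the
#' classic treatment; `zero_method = "pratt"` ranks them first and then
#' discards their ranks). Absolute differences are ranked with average ranks
#' for ties. With at most 25 nonzero pairs the exact null distribution of
#' the positive-rank sum is computed by dynamic programming (valid under
#' ties); beyond that a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param a,b equal-length (>= 5) paired numeric vectors.
#' @param zero_method `"drop"` or `"pratt"`.
#' @return List with `statistic` (positive-rank sum V), `p_value`,
#'   `n_nonzero` and `method`.
#' @export
wilcoxon_compare <- function(a, b, zero_method = c("drop", "pratt")) {
  zero_method <- match.arg(zero_method)
  stopifnot(length(a) == length(b), length(a) >= 5)
  d <- a - b
  if (all(d == 0)) stop("degenerate comparison: all paired differences are zero")
  if (zero_method == "drop") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    keep <- d != 0
    r <- r_all[keep]
    d <- d[keep]
  }
  V <- sum(r[d > 0])
  m <- length(d)
  if (m <= 25) {
    # exact null distribution of V: each rank joins the positive sum with
    # probability 1/2 independently; DP over doubled ranks keeps ties exact
    r2 <- as.integer(round(2 * r))
    probs <- numeric(sum(r2) + 1L)  # index k+1 holds P(2V = k)
    probs[1] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), probs[seq_len(length(probs) - rk)])
      probs <- (probs + shifted) / 2
    }
    v2 <- as.integer(round(2 * V))
    p_le <- sum(probs[seq_len(v2 + 1L)])
    p_ge <- sum(probs[(v2 + 1L):length(probs)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  list(statistic = V, p_value = p, n_nonzero = m, method = method)
}

#' Inter-rater agreement by bootstrapped Spearman correlation
#'
#' Spearman rank correlation between two raters' ordinal ratings of the same
#' edges (scale `never < rarely < sometimes < always`), with a nonparametric
#' bootstrap over edges: the mean, standard deviation and 2.5/97.5 percentile
#' interval of rho over `bootstrap_reps` resamples are reported. Replicates
#' whose resample is constant in either rater (rho undefined) are dropped
#' and counted.
#'
#' @param ratings_a,ratings_b equal-length (>= 3) vectors of tags (character
#'   on the four-point scale, ordered factor, or numeric ordinal codes).
#' @param bootstrap_reps number of bootstrap resamples.
#' @param seed integer seed.
#' @return List with `rho` (full-sample), `mean`, `sd`, `ci` (percentile),
#'   and `reps_used`.
#' @export
spearman_agreement <- function(ratings_a, ratings_b, bootstrap_reps = 1000,
                               seed = 1) {
  to_ord <- function(x) {
    if (is.numeric(x)) return(as.numeric(x))
    match(as.character(x), TAG_LEVELS)
  }
  x <- to_ord(ratings_a); y <- to_ord(ratings_b)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (anyNA(x) || anyNA(y)) stop("unknown tag token in ratings")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("rho undefined: constant rating vector")
  }
  rho <- stats::cor(x, y, method = "spearman")
  set.seed(seed)
  reps <- replicate(bootstrap_reps, {
    idx <- sample.int(length(x), replace = TRUE)
    if (length(unique(x[idx])) < 2 || length(unique(y[idx])) < 2) {
      NA_real_
    } else {
      stats::cor(x[idx], y[idx], method = "spearman")
    }
  })
  used <- reps[!is.na(reps)]
  list(rho = rho, mean = mean(used), sd = stats::sd(used),
       ci = stats::quantile(used, c(0.025, 0.975), names = FALSE),
       reps_used = length(used))
}

#' Write a PR curve to TSV
#' @param curve a `pr_curve`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pr_curve <- function(curve, path) {
  lines <- c("threshold\tprecision\trecall",
             sprintf("%.6f\t%.6f\t%.6f", curve$threshold, curve$precision,
                     curve$recall))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
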