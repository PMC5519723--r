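# Maximum-likelihood estimation of the three disease-symptom models:
# L1 logistic regression (one model per disease), naive Bayes with Laplace
# smoothing (one per disease), and a two-layer noisy-OR Bayesian network in
# which all failure and leak parameters are estimated jointly.

PROB_EPS <- 1e-6  # numerical clamp for all estimated probabilities

clamp_prob <- function(p, eps = PROB_EPS) pmin(pmax(p, eps), 1 - eps)

# Stratified fold assignment: positives and negatives are split separately so
# every fold keeps the label mix. Deterministic given the seed and invariant
# (as a partition) to patient order: units are assigned by shuffling within
# the sorted positive and negative id sets.
stratified_folds <- function(y, ids, folds, seed) {
  assign_group <- function(group_ids) {
    group_ids <- sort(group_ids)
    perm <- sample.int(length(group_ids))
    stats::setNames(rep_len(seq_len(folds), length(group_ids))[order(perm)],
                    group_ids)
  }
  set.seed(seed)
  f <- c(assign_group(ids[y == 1]), assign_group(ids[y == 0]))
  unname(f[ids])
}

check_label <- function(y, disease) {
  if (length(unique(y)) < 2) {
    stop(sprintf("degenerate label: disease column '%s' is constant", disease))
  }
}

get_xy <- function(matrix, disease) {
  if (!disease %in% disease_ids(matrix)) {
    stop("unknown disease column: ", disease)
  }
  list(X = matrix$cells[, symptom_ids(matrix), drop = FALSE],
       y = matrix$cells[, disease])
}

#' Fit an L1-regularized logistic regression for one disease
#'
#' The disease indicator is regressed on all symptom indicators with lasso
#' penalty. The penalty strength is chosen per disease by stratified k-fold
#' cross-validation: for each grid value the mean held-out log-loss is
#' computed, the minimizer is refit on all data, and ties are broken toward
#' stronger regularization. Features are binary and left unstandardized so
#' weights are directly comparable across symptoms; an intercept is included.
#'
#' @param matrix a `record_matrix`.
#' @param disease disease concept id (the label column).
#' @param l1_grid candidate penalty strengths (glmnet `lambda` values).
#' @param folds number of cross-validation folds.
#' @param seed integer seed controlling fold assignment.
#' @return An object of class `logistic_model` with elements `disease_id`,
#'   `weights` (named per symptom), `intercept`, `l1_strength`, and the CV
#'   table `cv`.
#' @export
fit_logistic <- function(matrix, disease,
                         l1_grid = 10^seq(-4, 1, length.out = 6),
                         folds = 3, seed = 1) {
  stopifnot(all(l1_grid >= 0), folds >= 2)
  d <- get_xy(matrix, disease)
  check_label(d$y, disease)
  grid <- sort(unique(l1_grid), decreasing = TRUE)
  cv <- NULL
  if (length(grid) > 1) {
    fold_of <- stratified_folds(d$y, rownames(d$X), folds, seed)
    loss <- matrix(NA_real_, nrow = folds, ncol = length(grid))
    for (k in seq_len(folds)) {
      tr <- fold_of != k
      ytr <- d$y[tr]
      if (length(unique(ytr)) < 2 || length(unique(d$y[!tr])) < 2) next
      fit <- glmnet_binomial(d$X[tr, , drop = FALSE], ytr, grid)
      Xte <- pad_features(d$X[!tr, , drop = FALSE])
      p <- vapply(grid, function(lam) {
        b <- coef_at_lambda(fit, lam)
        clamp_prob(1 / (1 + exp(-(drop(Xte %*% b[-1]) + b[1]))))
      }, numeric(nrow(Xte)))
      p <- matrix(p, nrow = nrow(Xte))
      yte <- d$y[!tr]
      loss[k, ] <- -colMeans(yte * log(p) + (1 - yte) * log(1 - p))
    }
    mean_loss <- colMeans(loss, na.rm = TRUE)
    usable <- is.finite(mean_loss)
    if (!all(usable)) {
      warning("some penalty grid values had no usable CV folds and were skipped")
    }
    if (!any(usable)) stop("no usable cross-validation folds for ", disease)
    # ties toward stronger regularization: grid is sorted descending, so the
    # first minimizer is the largest penalty among the minimizers
    best <- which(usable & mean_loss <= min(mean_loss[usable]) + 1e-12)[1]
    chosen <- grid[best]
    cv <- data.frame(l1_strength = grid, mean_log_loss = mean_loss)
  } else {
    chosen <- grid
  }
  fit <- glmnet_binomial(d$X, d$y, grid)
  beta <- coef_at_lambda(fit, chosen)
  w <- stats::setNames(beta[-1], names(beta)[-1])
  w <- w[colnames(d$X)]  # drop the pad column if one was added
  structure(list(disease_id = disease, weights = w,
                 intercept = as.numeric(beta)[1], l1_strength = chosen,
                 cv = cv),
            class = "logistic_model")
}

# glmnet requires >= 2 columns; pad single-symptom designs with an all-zero
# dummy whose weight is discarded downstream.
pad_features <- function(X) {
  if (ncol(X) >= 2) return(X)
  cbind(X, .pad. = 0L)
}

# Coefficients at a requested penalty are read off the fitted path by exact
# index (every grid value is embedded in the path, so no interpolation).
coef_at_lambda <- function(fit, lambda) {
  j <- which.min(abs(fit$lambda - lambda))
  if (abs(fit$lambda[j] - lambda) > 1e-8 * max(lambda, 1e-12)) {
    # path was truncated before reaching this penalty (glmnet early exit);
    # fall back to the smallest fitted penalty
    j <- length(fit$lambda)
  }
  c(intercept = fit$a0[[j]],
    stats::setNames(as.numeric(fit$beta[, j]), rownames(fit$beta)))
}

# The grid is embedded in a denser log-spaced path so glmnet's warm starts
# converge; coefficients are still read off exactly at the grid values.
glmnet_binomial <- function(X, y, lambda) {
  lo <- max(min(lambda), 1e-8); hi <- max(max(lambda), lo * 10)
  dense <- 10^seq(log10(hi), log10(lo),
                  length.out = max(30, 8 * ceiling(log10(hi / lo))))
  path <- sort(unique(c(lambda, dense)), decreasing = TRUE)
  glmnet::glmnet(pad_features(X), y, family = "binomial", alpha = 1,
                 lambda = path, standardize = FALSE, maxit = 1e6)
}

#' Fit a naive Bayes model for one disease
#'
#' Conditionals are closed-form Laplace-smoothed counts:
#' `p_present(i) = (n_i1 + a) / (n_1 + 2a)` and
#' `p_absent(i) = (n_i0 + a) / (n_0 + 2a)`, where `n_1`/`n_0` count records
#' with the disease present/absent and `n_i.` counts symptom-positive records
#' among them. The pseudocount `a` is chosen per disease by stratified k-fold
#' cross-validation on the held-out predictive log-likelihood of the symptoms
#' given the label, with ties broken toward stronger smoothing, then the
#' model is refit on all data.
#'
#' @inheritParams fit_logistic
#' @param pseudocount_grid candidate positive pseudocounts.
#' @return An object of class `naive_bayes_model` with `p_present`,
#'   `p_absent` (named per symptom, strictly inside (0,1)), `pseudocount`,
#'   `prior` (disease prevalence) and the CV table `cv`.
#' @export
fit_naive_bayes <- function(matrix, disease,
                            pseudocount_grid = c(0.1, 0.5, 1, 2, 5),
                            folds = 3, seed = 1) {
  stopifnot(all(pseudocount_grid > 0), folds >= 2)
  d <- get_xy(matrix, disease)
  check_label(d$y, disease)
  grid <- sort(unique(pseudocount_grid), decreasing = TRUE)
  cv <- NULL
  if (length(grid) > 1) {
    fold_of <- stratified_folds(d$y, rownames(d$X), folds, seed)
    ll <- matrix(NA_real_, nrow = folds, ncol = length(grid))
    for (k in seq_len(folds)) {
      tr <- fold_of != k
      if (length(unique(d$y[tr])) < 2) next
      Xte <- d$X[!tr, , drop = FALSE]
      yte <- d$y[!tr]
      for (g in seq_along(grid)) {
        cond <- nb_conditionals(d$X[tr, , drop = FALSE], d$y[tr], grid[g])
        p <- ifelse(yte == 1, 1, 0) %o% cond$p_present +
             ifelse(yte == 1, 0, 1) %o% cond$p_absent
        ll[k, g] <- sum(Xte * log(p) + (1 - Xte) * log(1 - p))
      }
    }
    mean_ll <- colMeans(ll, na.rm = TRUE)
    if (!any(is.finite(mean_ll))) stop("no usable cross-validation folds for ", disease)
    best <- which(mean_ll >= max(mean_ll, na.rm = TRUE) - 1e-12)[1]
    chosen <- grid[best]
    cv <- data.frame(pseudocount = grid, mean_heldout_loglik = mean_ll)
  } else {
    chosen <- grid
  }
  cond <- nb_conditionals(d$X, d$y, chosen)
  structure(list(disease_id = disease,
                 p_present = cond$p_present, p_absent = cond$p_absent,
                 pseudocount = chosen, prior = mean(d$y), cv = cv),
            class = "naive_bayes_model")
}

nb_conditionals <- function(X, y, a) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  list(p_present = clamp_prob((colSums(X[y == 1, , drop = FALSE]) + a) / (n1 + 2 * a)),
       p_absent  = clamp_prob((colSums(X[y == 0, , drop = FALSE]) + a) / (n0 + 2 * a)))
}

# ---- noisy OR --------------------------------------------------------------

#' Noisy-OR conditional probability of a symptom
#'
#' Under the noisy-OR gate, each active parent disease `j` independently
#' fails to turn on the symptom with probability `failure_row[j]`, and a leak
#' turns it on spontaneously with probability `leak`, giving
#' `P(x = 1 | y) = 1 - (1 - leak) * prod_j failure_row[j]^y_j`.
#'
#' @param parent_states binary 0/1 vector of disease states `y`.
#' @param failure_row per-disease failure probabilities in `[0, 1]`.
#' @param leak leak probability in `[0, 1]`.
#' @return The conditional probability, a number in `[0, 1]`.
#' @export
noisy_or_symptom_prob <- function(parent_states, failure_row, leak) {
  stopifnot(length(parent_states) == length(failure_row))
  if (!all(parent_states %in% c(0, 1))) stop("parent states must be binary")
  if (any(failure_row < 0 | failure_row > 1) || leak < 0 || leak > 1) {
    stop("failure and leak probabilities must lie in [0, 1]")
  }
  1 - (1 - leak) * prod(failure_row[parent_states == 1])
}

#' Construct a noisy-OR model object
#'
#' @param failure symptom x disease matrix of failure probabilities `f_ij`
#'   (dimnames: symptom ids x disease ids).
#' @param leak named per-symptom leak probabilities `l_i`.
#' @param loglik,loglik_initial,iterations,converged fit diagnostics.
#' @return An object of class `noisy_or_model`.
#' @export
noisy_or_model <- function(failure, leak, loglik = NA_real_,
                           loglik_initial = NA_real_, iterations = 0L,
                           converged = NA) {
  failure <- as.matrix(failure)
  stopifnot(nrow(failure) == length(leak),
            all(failure >= 0 & failure <= 1), all(leak >= 0 & leak <= 1))
  if (is.null(names(leak))) names(leak) <- rownames(failure)
  structure(list(failure = failure, leak = leak, loglik = loglik,
                 loglik_initial = loglik_initial, iterations = iterations,
                 converged = converged),
            class = "noisy_or_model")
}

#' @export
print.noisy_or_model <- function(x, ...) {
  cat(sprintf("<noisy_or_model> %d symptoms x %d diseases; loglik %.4f after %d iterations (%s)\n",
              nrow(x$failure), ncol(x$failure), x$loglik, x$iterations,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

# Group patients by identical disease pattern; all likelihood quantities only
# depend on (pattern, per-symptom positive count within pattern).
group_patterns <- function(Y) {
  key <- if (ncol(Y) == 0) rep("", nrow(Y)) else
    do.call(paste, c(as.data.frame(Y), sep = ""))
  idx <- split(seq_len(nrow(Y)), key)
  Yu <- Y[vapply(idx, `[`, 1L, 1L), , drop = FALSE]
  list(Yu = Yu, idx = idx, ng = lengths(idx))
}

# q[i, g] = P(x_i = 0 | pattern g) = (1 - l_i) * prod_{j in g} f_ij
pattern_q <- function(failure, leak, Yu) {
  lf <- log(clamp_prob(failure))
  q <- (1 - leak) * exp(lf %*% t(Yu))
  clamp_prob(q)
}

#' Noisy-OR log-likelihood of a record matrix
#'
#' Sum over patients and symptom columns of the log Bernoulli probability of
#' each observed symptom given that patient's disease vector under the
#' noisy-OR gate. Probabilities are clamped away from 0 and 1.
#'
#' @param model a `noisy_or_model` whose dimensions match `matrix`.
#' @param matrix a `record_matrix`.
#' @return The log-likelihood (0 for an empty matrix).
#' @export
noisy_or_log_likelihood <- function(model, matrix) {
  sids <- symptom_ids(matrix); dids <- disease_ids(matrix)
  if (nrow(matrix$cells) == 0 || length(sids) == 0) return(0)
  X <- matrix$cells[, sids, drop = FALSE]
  Y <- matrix$cells[, dids, drop = FALSE]
  f <- model$failure[sids, dids, drop = FALSE]
  l <- model$leak[sids]
  g <- group_patterns(Y)
  q <- pattern_q(f, l, g$Yu)                       # s x G
  K1 <- vapply(g$idx, function(rows) colSums(X[rows, , drop = FALSE]),
               numeric(ncol(X)))                   # s x G (s>1) or G vector
  K1 <- matrix(K1, nrow = ncol(X))
  K0 <- matrix(rep(g$ng, each = ncol(X)), nrow = ncol(X)) - K1
  sum(K1 * log(1 - q) + K0 * log(q))
}

#' Jointly fit a noisy-OR network by maximum likelihood
#'
#' All failure probabilities `f_ij` and leaks `l_i` are estimated jointly by
#' an expectation-maximization scheme over the latent per-cause activation
#' indicators of each noisy-OR gate, which increases the observed-data
#' likelihood at every iterate; a safeguard halves any (boundary-clamped)
#' update that would decrease it, so the recorded likelihood trace is
#' non-decreasing and the final value is never below the value at
#' initialization. Leaks are initialized from the symptom rate among
#' disease-free records and failures from clamped pairwise moment contrasts
#' `1 - max(0, p(x|y_j=1) - p(x|y_j=0))`; the fit is deterministic given the
#' data.
#'
#' @param matrix a binary `record_matrix` with at least one disease and one
#'   symptom column.
#' @param max_iter maximum number of EM iterations.
#' @param tol relative log-likelihood improvement below which the fit is
#'   declared converged.
#' @param seed accepted for interface uniformity; the optimizer itself is
#'   deterministic.
#' @return A `noisy_or_model` with fit diagnostics and the per-iteration
#'   log-likelihood trace in attribute `trace`.
#' @export
fit_noisy_or <- function(matrix, max_iter = 500, tol = 1e-6, seed = 1) {
  sids <- symptom_ids(matrix); dids <- disease_ids(matrix)
  if (length(sids) == 0 || length(dids) == 0) {
    stop("need at least one disease and one symptom column")
  }
  if (!all(matrix$cells %in% c(0L, 1L))) stop("record matrix must be binary")
  X <- matrix$cells[, sids, drop = FALSE]
  Y <- matrix$cells[, dids, drop = FALSE]
  n <- nrow(X); s <- ncol(X); d <- ncol(Y)

  g <- group_patterns(Y)
  Yu <- g$Yu; G <- nrow(Yu)
  K1 <- matrix(vapply(g$idx, function(rows) colSums(X[rows, , drop = FALSE]),
                      numeric(s)), nrow = s)       # s x G positives
  Ng <- g$ng
  K0 <- matrix(rep(Ng, each = s), nrow = s) - K1
  nj <- as.numeric(Ng %*% Yu)                      # records with disease j on

  # initialization: leaks from disease-free records, failures from clamped
  # pairwise moment contrasts
  free <- rowSums(Y) == 0
  base_rate <- if (any(free)) colMeans(X[free, , drop = FALSE]) else colMeans(X)
  l <- clamp_prob(base_rate)
  p_on <- sapply(seq_len(d), function(j) {
    on <- Y[, j] == 1
    if (!any(on)) return(rep(0, s))
    colMeans(X[on, , drop = FALSE])
  })
  p_off <- sapply(seq_len(d), function(j) {
    off <- Y[, j] == 0
    if (!any(off)) return(rep(0, s))
    colMeans(X[off, , drop = FALSE])
  })
  A <- clamp_prob(pmax(matrix(p_on, nrow = s) - matrix(p_off, nrow = s), 0))
  # A[i, j] = 1 - f_ij, the activation probability

  ll_of <- function(A, l) {
    q <- pattern_q(1 - A, l, Yu)
    sum(K1 * log(1 - q) + K0 * log(q))
  }
  ll <- ll_of(A, l)
  ll_init <- ll
  trace <- ll
  converged <- FALSE
  it <- 0L
  njs <- matrix(rep(pmax(nj, 1), each = s), nrow = s)
  while (it < max_iter) {
    it <- it + 1L
    q <- pattern_q(1 - A, l, Yu)
    R <- K1 / (1 - q)                              # s x G responsibility mass
    A_new <- clamp_prob(A * (R %*% Yu) / njs)
    l_new <- clamp_prob(l * rowSums(R) / n)
    ll_new <- ll_of(A_new, l_new)
    # EM is monotone; clamping can in principle break that, so reject any
    # decreasing iterate by damping toward the current point
    step <- 1
    while (ll_new < ll && step > 1e-4) {
      step <- step / 2
      A_new <- clamp_prob(A + step * (A_new - A))
      l_new <- clamp_prob(l + step * (l_new - l))
      ll_new <- ll_of(A_new, l_new)
    }
    if (ll_new < ll) {
      converged <- TRUE
      break
    }
    rel <- (ll_new - ll) / max(abs(ll), 1e-12)
    A <- A_new; l <- l_new; ll <- ll_new
    trace <- c(trace, ll)
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  failure <- 1 - A
  dimnames(failure) <- list(sids, dids)
  m <- noisy_or_model(failure, stats::setNames(l, sids), loglik = ll,
                      loglik_initial = ll_init, iterations = it,
                      converged = converged)
  attr(m, "trace") <- trace
  m
}

# ---- model serialization ---------------------------------------------------

#' Write / read fitted models as JSON
#'
#' Parameters, diagnostics and configuration echoes are stored in a single
#' JSON document keyed by model class.
#'
#' @param model a `logistic_model`, `naive_bayes_model` or `noisy_or_model`.
#' @param path file path.
#' @return `read_model()` returns the model object; `write_model()` returns
#'   `path` invisibly.
#' @export
write_model <- function(model, path) {
  cls <- class(model)[1]
  doc <- c(list(model_class = cls), unclass(model))
  # named vectors become JSON objects so names survive the round-trip
  for (nm in intersect(names(doc), c("weights", "p_present", "p_absent",
                                     "leak"))) {
    doc[[nm]] <- as.list(doc[[nm]])
  }
  if (cls == "noisy_or_model") {
    doc$failure <- list(values = as.vector(model$failure),
                        symptoms = rownames(model$failure),
                        diseases = colnames(model$failure))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cls <- doc$model_class
  if (cls == "noisy_or_model") {
    f <- matrix(doc$failure$values, nrow = length(doc$failure$symptoms),
                dimnames = list(doc$failure$symptoms, doc$failure$diseases))
    return(noisy_or_model(f, stats::setNames(unlist(doc$leak),
                                             doc$failure$symptoms),
                          loglik = doc$loglik,
                          loglik_initial = doc$loglik_initial,
                          iterations = doc$iterations,
                          converged = doc$converged))
  }
  if (cls == "logistic_model") {
    return(structure(list(disease_id = doc$disease_id,
                          weights = unlist(doc$weights),
                          intercept = doc$intercept,
                          l1_strength = doc$l1_strength,
                          cv = doc$cv),
                     class = "logistic_model"))
  }
  if (cls == "naive_bayes_model") {
    return(structure(list(disease_id = doc$disease_id,
                          p_present = unlist(doc$p_present),
                          p_absent = unlist(doc$p_absent),
                          pseudocount = doc$pseudocount,
                          prior = doc$prior, cv = doc$cv),
                     class = "naive_bayes_model"))
  }
  stop("unknown model class: ", cls)
}
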