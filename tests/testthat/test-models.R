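test_that("naive Bayes conditionals equal closed-form smoothed counts", {
  # disease present in 10 records (symptom in 4), absent in 90 (symptom in 9)
  y <- rep(c(1L, 0L), c(10, 90))
  x <- c(rep(1L, 4), rep(0L, 6), rep(1L, 9), rep(0L, 81))
  m <- quick_matrix(cbind(d1 = y, s1 = x))
  fit <- fit_naive_bayes(m, "d1", pseudocount_grid = 1)
  expect_equal(unname(fit$p_present["s1"]), 5 / 12)
  expect_equal(unname(fit$p_absent["s1"]), 10 / 92)
  expect_equal(fit$prior, 0.1)
})

test_that("naive Bayes smoothing limits behave", {
  y <- rep(c(1L, 0L), c(10, 90))
  m <- quick_matrix(cbind(d1 = y, s1 = c(rep(1L, 4), rep(0L, 96)),
                          s2 = rep(0L, 100)))
  # enormous pseudocount drives every conditional to 1/2
  big <- fit_naive_bayes(m, "d1", pseudocount_grid = 1e7)
  expect_equal(unname(big$p_present), c(0.5, 0.5), tolerance = 1e-5)
  # never-observed symptom still gets strictly positive probabilities
  sm <- fit_naive_bayes(m, "d1", pseudocount_grid = 1)
  expect_gt(sm$p_present["s2"], 0)
  expect_lt(sm$p_present["s2"], 1)
  expect_error(fit_naive_bayes(quick_matrix(cbind(d1 = rep(1L, 10),
                                                  s1 = rep(0L, 10))), "d1"),
               "degenerate label")
})

test_that("pseudocount selection is invariant to patient order", {
  cfg <- default_generator_config(n_patients = 800, seed = 31)
  m <- simulate_record_matrix(cfg)
  fit1 <- fit_naive_bayes(m, "d_influenza", seed = 4)
  perm <- sample(nrow(m$cells))
  m2 <- record_matrix(m$cells[perm, ], m$roles, m$age_brackets[perm])
  fit2 <- fit_naive_bayes(m2, "d_influenza", seed = 4)
  expect_equal(fit2$pseudocount, fit1$pseudocount)
  expect_equal(fit2$p_present, fit1$p_present)
})

test_that("logistic fit recovers a positive weight checked against an ISTA oracle", {
  # symptom s1 perfectly co-occurs with the disease; s2 is noise
  set.seed(10)
  y <- rep(c(1L, 0L), each = 10)
  X <- cbind(s1 = y, s2 = rbinom(20, 1, 0.5))
  m <- quick_matrix(cbind(d1 = y, X))
  fit <- fit_logistic(m, "d1", l1_grid = 0.05)
  expect_gt(fit$weights["s1"], 0)
  oracle <- l1_logistic_oracle(X, y, 0.05)
  expect_gt(unname(oracle$beta[1]), 0)
  expect_equal(unname(sign(fit$weights)), unname(sign(oracle$beta)))
  expect_equal(unname(fit$weights), unname(oracle$beta), tolerance = 0.05)
})

test_that("logistic shrinkage limit and degenerate grids behave", {
  set.seed(11)
  y <- rbinom(60, 1, 0.4)
  m <- quick_matrix(cbind(d1 = y, s1 = rbinom(60, 1, 0.3),
                          s2 = rbinom(60, 1, 0.6)))
  hard <- fit_logistic(m, "d1", l1_grid = 1e4)
  expect_equal(unname(hard$weights), c(0, 0))
  single <- fit_logistic(m, "d1", l1_grid = 0.01)
  expect_null(single$cv)  # no model selection on a one-point grid
  expect_error(fit_logistic(quick_matrix(cbind(d1 = rep(0L, 20),
                                               s1 = rbinom(20, 1, .5))), "d1"),
               "degenerate label")
})

test_that("l1 selection by held-out log-loss is order-invariant and tie-breaks strong", {
  cfg <- default_generator_config(n_patients = 600, seed = 13)
  m <- simulate_record_matrix(cfg)
  f1 <- fit_logistic(m, "d_migraine", seed = 8)
  perm <- rev(seq_len(nrow(m$cells)))
  m2 <- record_matrix(m$cells[perm, ], m$roles, m$age_brackets[perm])
  f2 <- fit_logistic(m2, "d_migraine", seed = 8)
  expect_equal(f1$l1_strength, f2$l1_strength)
  expect_equal(f1$weights, f2$weights)
})

test_that("the noisy-OR conditional follows the failure/leak algebra", {
  expect_equal(noisy_or_symptom_prob(c(0, 0), c(0.2, 0.3), 0.1), 0.1)
  expect_equal(noisy_or_symptom_prob(1, 0.2, 0.1), 0.82)
  expect_equal(noisy_or_symptom_prob(c(1, 1), c(0.5, 0.5), 0), 0.75)
  expect_error(noisy_or_symptom_prob(1, 1.2, 0.1), "\\[0, 1\\]")
  expect_error(noisy_or_symptom_prob(c(1, 2), c(0.5, 0.5), 0.1), "binary")
  # monotonicity: activating an extra parent never lowers the probability
  set.seed(20)
  for (rep in 1:25) {
    d <- sample(1:6, 1)
    f <- runif(d); l <- runif(1)
    y <- rbinom(d, 1, 0.5)
    off <- which(y == 0)
    if (length(off) == 0) next
    y2 <- y; y2[sample(off, 1)] <- 1
    expect_gte(noisy_or_symptom_prob(y2, f, l),
               noisy_or_symptom_prob(y, f, l))
  }
})

test_that("noisy-OR log-likelihood matches a per-cell brute force", {
  set.seed(21)
  cells <- cbind(matrix(rbinom(15, 1, 0.4), 5, 3,
                        dimnames = list(NULL, paste0("d", 1:3))),
                 matrix(rbinom(20, 1, 0.3), 5, 4,
                        dimnames = list(NULL, paste0("s", 1:4))))
  m <- quick_matrix(cells)
  model <- noisy_or_model(
    matrix(runif(12, 0.1, 0.9), 4, 3,
           dimnames = list(paste0("s", 1:4), paste0("d", 1:3))),
    stats::setNames(runif(4, 0.01, 0.2), paste0("s", 1:4)))
  expect_equal(noisy_or_log_likelihood(model, m),
               noisy_or_ll_bruteforce(model, m))

  # single patient, single symptom on, all diseases off -> log(leak)
  m1 <- quick_matrix(cbind(d1 = 0L, s1 = 1L))
  model1 <- noisy_or_model(matrix(0.5, 1, 1, dimnames = list("s1", "d1")),
                           c(s1 = 0.1))
  expect_equal(noisy_or_log_likelihood(model1, m1), log(0.1))

  # empty matrix -> 0
  m0 <- record_matrix(matrix(0L, 0, 2, dimnames = list(character(),
                                                       c("d1", "s1"))),
                      c(d1 = "disease", s1 = "symptom"))
  expect_equal(noisy_or_log_likelihood(model1, m0), 0)
})

test_that("joint noisy-OR fit matches a dense grid search on 1x1 instances", {
  for (seed in c(1, 2, 3)) {
    m <- one_pair_matrix(400, prevalence = 0.4,
                         activation = c(0.7, 0.3, 0.9)[seed],
                         leak = c(0.05, 0.15, 0.02)[seed], seed = seed)
    fit <- fit_noisy_or(m, tol = 1e-10, max_iter = 5000)
    expect_gte(fit$loglik, noisy_or_grid_oracle(m) - 1e-3)
  }
})

test_that("deterministic causation drives the fitted pair to the boundary", {
  set.seed(5)
  y <- rbinom(10000, 1, 0.3)
  m <- quick_matrix(cbind(d1 = y, s1 = y))
  fit <- fit_noisy_or(m)
  expect_lte(fit$failure["s1", "d1"], 0.01)
  expect_lte(unname(fit$leak["s1"]), 0.01)
})

test_that("generating failure and leak are recovered at large n", {
  m <- one_pair_matrix(50000, prevalence = 0.3, activation = 0.7,
                       leak = 0.05, seed = 77)
  fit <- fit_noisy_or(m)
  expect_lte(abs(fit$failure["s1", "d1"] - 0.3), 0.02)
  expect_lte(abs(fit$leak[["s1"]] - 0.05), 0.01)
})

test_that("the accepted likelihood trace never decreases", {
  cfg <- default_generator_config(n_patients = 1500, seed = 41)
  m <- simulate_record_matrix(cfg)
  fit <- fit_noisy_or(m)
  trace <- attr(fit, "trace")
  expect_true(all(diff(trace) >= 0))
  expect_gte(fit$loglik, fit$loglik_initial)
  expect_true(all(fit$failure >= 1e-6 & fit$failure <= 1 - 1e-6))
  expect_true(all(fit$leak >= 1e-6 & fit$leak <= 1 - 1e-6))
})

test_that("fit_noisy_or rejects non-binary input and missing roles", {
  bad <- quick_matrix(cbind(d1 = c(0L, 1L), s1 = c(1L, 0L)))
  bad$cells[1, 1] <- 2L
  expect_error(fit_noisy_or(bad), "binary")
  only_sym <- quick_matrix(cbind(s1 = c(0L, 1L)))
  expect_error(fit_noisy_or(only_sym), "at least one disease")
})

test_that("fitted models round-trip through JSON", {
  cfg <- default_generator_config(n_patients = 400, seed = 51)
  m <- simulate_record_matrix(cfg)
  fits <- list(fit_noisy_or(m),
               fit_naive_bayes(m, "d_influenza", seed = 1),
               fit_logistic(m, "d_influenza", l1_grid = c(0.01, 0.1), seed = 1))
  for (fit in fits) {
    p <- tempfile(fileext = ".json")
    write_model(fit, p)
    back <- read_model(p)
    expect_equal(class(back), class(fit))
    if (inherits(fit, "noisy_or_model")) {
      expect_equal(back$failure, fit$failure)
      expect_equal(back$leak, fit$leak, tolerance = 1e-12)
    } else if (inherits(fit, "naive_bayes_model")) {
      expect_equal(back$p_present, fit$p_present)
      expect_equal(back$pseudocount, fit$pseudocount)
    } else {
      expect_equal(back$weights, fit$weights)
      expect_equal(back$l1_strength, fit$l1_strength)
    }
  }
})
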