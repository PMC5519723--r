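ref_toy <- function() {
  structure(list(
    edges = data.frame(disease_id = "d", symptom_id = c("s1", "s2"),
                       bucket = "frequent", stringsAsFactors = FALSE),
    disease_frequency = list(), n_skipped = 0L),
    class = "reference_graph")
}

scores_toy <- function() {
  structure(data.frame(disease_id = "d", symptom_id = c("s1", "s3", "s2"),
                       score = c(0.9, 0.5, 0.3), stringsAsFactors = FALSE),
            model = "noisy_or")
}

test_that("the reference PR sweep matches hand enumeration", {
  curve <- pr_vs_reference(scores_toy(), ref_toy(), exclude_symptoms = character())
  expect_equal(curve$threshold, c(0.9, 0.5, 0.3))
  expect_equal(curve$precision, c(1, 1 / 2, 2 / 3))
  expect_equal(curve$recall, c(0.5, 0.5, 1))
  # integer bookkeeping: precision * retrieved = TP exactly
  retrieved <- seq_along(curve$threshold)
  expect_equal(curve$precision * retrieved, round(curve$precision * retrieved))
})

test_that("perfect retrieval reaches precision 1, recall 1", {
  scores <- structure(data.frame(disease_id = "d", symptom_id = c("s1", "s2"),
                                 score = c(0.8, 0.6), stringsAsFactors = FALSE),
                      model = "noisy_or")
  curve <- pr_vs_reference(scores, ref_toy(), exclude_symptoms = character())
  last <- nrow(curve)
  expect_equal(curve$precision[last], 1)
  expect_equal(curve$recall[last], 1)
})

test_that("symptom exclusion applies to both sides and can empty the reference", {
  # excluding s2 removes it from candidates and the recall denominator
  curve <- pr_vs_reference(scores_toy(), ref_toy(), exclude_symptoms = "s2")
  expect_equal(attr(curve, "n_positive"), 1L)
  expect_false(any(curve$recall > 0 & curve$threshold == 0.3))
  expect_error(pr_vs_reference(scores_toy(), ref_toy(),
                               exclude_symptoms = c("s1", "s2")),
               "empty")
})

test_that("PR curves ignore presentation order and duplicate candidates", {
  base <- pr_vs_reference(scores_toy(), ref_toy(), exclude_symptoms = character())
  shuffled <- scores_toy()[c(3, 1, 2), ]
  expect_equal(as.data.frame(pr_vs_reference(shuffled, ref_toy(),
                                             exclude_symptoms = character())),
               as.data.frame(base))
  dup <- rbind(scores_toy(), scores_toy()[1, ])
  expect_equal(as.data.frame(pr_vs_reference(dup, ref_toy(),
                                             exclude_symptoms = character())),
               as.data.frame(base))
})

test_that("recall never increases as the threshold rises", {
  set.seed(50)
  scores <- structure(
    data.frame(disease_id = sample(c("d1", "d2"), 40, TRUE),
               symptom_id = paste0("s", 1:40),
               score = round(runif(40), 2), stringsAsFactors = FALSE),
    model = "noisy_or")
  ref <- structure(list(
    edges = data.frame(disease_id = scores$disease_id[1:12],
                       symptom_id = scores$symptom_id[1:12],
                       bucket = "frequent", stringsAsFactors = FALSE),
    disease_frequency = list(), n_skipped = 0L), class = "reference_graph")
  curve <- pr_vs_reference(scores, ref, exclude_symptoms = character())
  ord <- order(curve$threshold)
  expect_true(all(diff(curve$recall[ord]) <= 0 + 1e-12))
  expect_true(all(curve$precision >= 0 & curve$precision <= 1))
  expect_true(all(curve$recall >= 0 & curve$recall <= 1))
})

test_that("restricting a reference to supported concepts shrinks the denominator", {
  ref <- ref_toy()
  r2 <- restrict_reference(ref, c("d", "s1"))
  expect_equal(r2$edges$symptom_id, "s1")
  curve <- pr_vs_reference(scores_toy(), r2, exclude_symptoms = character())
  expect_equal(attr(curve, "n_positive"), 1L)
  expect_equal(restrict_reference(ref, c("d", "s1", "s2"))$edges, ref$edges)
})

test_that("pooling unions per-disease top-N, merges provenance, shuffles by seed", {
  g1 <- knowledge_graph(data.frame(disease_id = "d",
                                   symptom_id = c("a", "b", "x"),
                                   importance = c(0.9, 0.8, 0.1)), "m1")
  g2 <- knowledge_graph(data.frame(disease_id = "d",
                                   symptom_id = c("b", "c", "y"),
                                   importance = c(0.9, 0.8, 0.1)), "m2")
  pool <- pool_top_edges(list(m1 = g1, m2 = g2), n_per_disease = 2, seed = 3)
  expect_setequal(pool$symptom_id, c("a", "b", "c"))
  expect_equal(pool$sources[pool$symptom_id == "b"], "m1,m2")
  # determinism under the seed
  pool2 <- pool_top_edges(list(m1 = g1, m2 = g2), n_per_disease = 2, seed = 3)
  expect_identical(pool, pool2)
  # reference edges join the pool
  ref <- ref_toy()
  pool3 <- pool_top_edges(list(m1 = g1, m2 = g2), n_per_disease = 2,
                          reference = ref, seed = 3)
  expect_true(all(c("s1", "s2") %in% pool3$symptom_id))
  # counting bound: #sources * n * #diseases + |reference|
  expect_lte(nrow(pool3), 2 * 2 * 1 + nrow(ref$edges))
})

test_that("tag binarization implements both segmentation schemes", {
  tags <- data.frame(disease_id = "d", symptom_id = paste0("s", 1:4),
                     rater_id = "r1",
                     tag = c("always", "sometimes", "rarely", "never"),
                     stringsAsFactors = FALSE)
  expect_equal(binarize_tags(tags, "rarely_positive")$relevant, c(1, 1, 1, 0))
  expect_equal(binarize_tags(tags, "rarely_negative")$relevant, c(1, 1, 0, 0))
  bad <- tags; bad$tag[1] <- "often"
  expect_error(binarize_tags(bad), "unknown tag token")
})

test_that("the tag-based sweep matches the reference sweep on an identical target", {
  scores <- scores_toy()
  rel <- data.frame(disease_id = "d", symptom_id = c("s1", "s2", "s3"),
                    relevant = c(1, 1, 0), stringsAsFactors = FALSE)
  from_tags <- pr_vs_tags(scores, rel)
  from_ref <- pr_vs_reference(scores, ref_toy(), exclude_symptoms = character())
  expect_equal(as.data.frame(from_tags), as.data.frame(from_ref))
  # all pooled edges positive: precision 1 everywhere
  all_pos <- data.frame(disease_id = "d", symptom_id = c("s1", "s2", "s3"),
                        relevant = 1, stringsAsFactors = FALSE)
  expect_true(all(pr_vs_tags(scores, all_pos)$precision == 1))
  none <- all_pos; none$relevant <- 0
  expect_error(pr_vs_tags(scores, none), "no positively tagged")
})

test_that("a six-edge pooled toy matches hand enumeration", {
  # scores are a permutation of relevance: positives at ranks 1, 3, 4
  scores <- structure(
    data.frame(disease_id = "d", symptom_id = paste0("s", 1:6),
               score = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4),
               stringsAsFactors = FALSE), model = "noisy_or")
  rel <- data.frame(disease_id = "d", symptom_id = paste0("s", 1:6),
                    relevant = c(1, 0, 1, 1, 0, 0), stringsAsFactors = FALSE)
  curve <- pr_vs_tags(scores, rel)
  expect_equal(curve$precision, c(1, 1 / 2, 2 / 3, 3 / 4, 3 / 5, 3 / 6))
  expect_equal(curve$recall, c(1, 1, 2, 3, 3, 3) / 3)
})

test_that("an unranked bucketed source yields one PR point per bucket", {
  # a static reference scored only by its two buckets produces two points
  scores <- structure(
    data.frame(disease_id = "d", symptom_id = paste0("s", 1:5),
               score = c(2, 2, 1, 1, 1), stringsAsFactors = FALSE),
    model = "reference")
  rel <- data.frame(disease_id = "d", symptom_id = paste0("s", 1:5),
                    relevant = c(1, 1, 1, 0, 0), stringsAsFactors = FALSE)
  curve <- pr_vs_tags(scores, rel)
  expect_equal(nrow(curve), 2L)
})

test_that("Wilcoxon signed-rank matches exhaustive sign-flip enumeration", {
  set.seed(60)
  for (rep in 1:30) {
    n <- sample(5:12, 1)
    b <- runif(n)
    # mixed continuous and tied differences, some zeros
    d <- sample(c(-2, -1, -0.5, 0, 0.5, 1, 2), n, replace = TRUE) +
      round(rnorm(n, sd = 0.2), 1)
    a <- b + d
    if (all(a == b)) next
    ours <- wilcoxon_compare(a, b)
    oracle <- wilcoxon_enumeration_oracle(a, b)
    expect_equal(ours$statistic, oracle$statistic)
    expect_equal(ours$p_value, oracle$p_value, tolerance = 1e-12,
                 label = paste("seeded case", rep))
  }
})

test_that("Wilcoxon handles constant shifts, symmetry, and degeneracy", {
  b <- seq(0.5, 4, by = 0.5)   # binary-exact values so differences are exact
  shifted <- wilcoxon_compare(b + 0.25, b)
  expect_equal(shifted$statistic, sum(1:8))        # all differences positive
  expect_equal(shifted$p_value, 2 * (1 / 2)^8)     # extreme exact tail
  # alternating +d/-d is perfectly symmetric: p = 1
  d <- rep(c(0.25, -0.25), 4)
  sym <- wilcoxon_compare(b + d, b)
  expect_equal(sym$p_value, 1.0)
  expect_error(wilcoxon_compare(b, b), "degenerate comparison")
  expect_error(wilcoxon_compare(1:3, 3:1), "length")
})

test_that("large-sample Wilcoxon agrees with the normal-approximation reference", {
  set.seed(61)
  a <- rnorm(40); b <- a + rnorm(40, mean = 0.3)
  ours <- wilcoxon_compare(a, b)
  expect_equal(ours$method, "normal approximation with tie correction")
  std <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(ours$statistic, unname(std$statistic))
  expect_equal(ours$p_value, std$p.value, tolerance = 1e-6)
})

test_that("per-disease precision at a budget feeds the paired test", {
  g <- knowledge_graph(data.frame(
    disease_id = rep(c("d1", "d2"), each = 3),
    symptom_id = rep(c("a", "b", "c"), 2),
    importance = c(0.9, 0.8, 0.7, 0.9, 0.8, 0.7)), "m")
  pos <- data.frame(disease_id = c("d1", "d1", "d2"),
                    symptom_id = c("a", "b", "c"), stringsAsFactors = FALSE)
  prec <- per_disease_precision(g, pos, n_per_disease = 2)
  expect_equal(prec, c(d1 = 1, d2 = 0))
})

test_that("Spearman agreement: limits, bootstrap shrinkage, and errors", {
  x <- c("never", "rarely", "sometimes", "always", "sometimes", "rarely")
  same <- spearman_agreement(x, x, bootstrap_reps = 50, seed = 2)
  expect_equal(same$rho, 1)
  expect_equal(same$mean, 1)
  rev_pair <- spearman_agreement(c(1, 2, 3, 4), c(4, 3, 2, 1),
                                 bootstrap_reps = 50, seed = 2)
  expect_equal(rev_pair$rho, -1)
  expect_error(spearman_agreement(rep("always", 5),
                                  c("never", "never", "rarely", "always",
                                    "sometimes")), "constant")
  expect_error(spearman_agreement(c("always", "often", "never"),
                                  c("never", "rarely", "always")),
               "unknown tag")
  # matched generative agreement: bootstrap spread shrinks with more edges
  gen <- function(n, seed) {
    set.seed(seed)
    x <- sample(1:4, n, replace = TRUE)
    y <- ifelse(runif(n) < 0.7, x, sample(1:4, n, replace = TRUE))
    list(x = x, y = y)
  }
  small <- gen(50, 8); big <- gen(500, 8)
  sd_small <- spearman_agreement(small$x, small$y, bootstrap_reps = 300,
                                 seed = 9)$sd
  sd_big <- spearman_agreement(big$x, big$y, bootstrap_reps = 300,
                               seed = 9)$sd
  expect_lt(sd_big, sd_small)
})
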