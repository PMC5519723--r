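# Synthetic emergency-department corpus generator with known ground truth.
# Diseases depend on a latent age bracket (the shared cause that induces
# disease-disease correlation and age confounding); symptoms are drawn from
# the generating noisy-OR gates, optionally OR-ed with direct age-bracket
# activations, then masked by a missing-not-at-random omission probability;
# free-text records are rendered from alias and negation templates.

#' Construct a generator configuration
#'
#' @param n_patients number of patient visits to simulate.
#' @param bracket_mix named probability vector over the four age brackets
#'   (`child`, `young_adult`, `adult`, `senior`).
#' @param prevalence disease x bracket matrix of per-bracket disease
#'   prevalences (rownames = disease ids, colnames = brackets).
#' @param activation symptom x disease matrix of activation probabilities
#'   `1 - f_ij` (0 = no edge); rownames = symptom ids.
#' @param leaks named per-symptom leak probabilities.
#' @param confounders data frame with columns `bracket`, `symptom_id`,
#'   `prob`: direct symptom activations by age bracket, OR-ed into the
#'   noisy-OR probability.
#' @param names named character vector of display names per concept id.
#' @param aliases named list of extra aliases per concept id.
#' @param codes named list of diagnosis codes per disease id.
#' @param omission_prob probability that a truly present symptom goes
#'   unrecorded (applied to symptoms only, emulating charting gaps).
#' @param negation_insert_prob probability that a record also mentions one
#'   absent concept inside a negation phrase.
#' @param seed integer seed; all sampling derives from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_patients, bracket_mix, prevalence, activation,
                             leaks, confounders = NULL, names = NULL,
                             aliases = list(), codes = list(),
                             omission_prob = 0, negation_insert_prob = 0,
                             seed = 1) {
  stopifnot(n_patients >= 1,
            abs(sum(bracket_mix) - 1) < 1e-8,
            all(prevalence >= 0 & prevalence <= 1),
            all(activation >= 0 & activation <= 1),
            all(leaks >= 0 & leaks <= 1),
            omission_prob >= 0, omission_prob <= 1,
            identical(colnames(activation), rownames(prevalence)),
            identical(names(leaks), rownames(activation)))
  if (is.null(confounders)) {
    confounders <- data.frame(bracket = character(), symptom_id = character(),
                              prob = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(confounders$symptom_id %in% rownames(activation)),
            all(confounders$prob >= 0 & confounders$prob <= 1))
  ids <- c(rownames(prevalence), rownames(activation))
  if (is.null(names)) names <- stats::setNames(gsub("_", " ", ids), ids)
  structure(list(n_patients = as.integer(n_patients),
                 bracket_mix = bracket_mix, prevalence = prevalence,
                 activation = activation, leaks = leaks,
                 confounders = confounders, names = names,
                 aliases = aliases, codes = codes,
                 omission_prob = omission_prob,
                 negation_insert_prob = negation_insert_prob,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Default synthetic emergency-department scenario
#'
#' Eight acute-care diseases and twenty-five symptoms with hand-set
#' age-bracket prevalences, noisy-OR activations and leaks chosen to mimic
#' an emergency-department case mix: common presenting complaints carry
#' higher leaks, disease prevalence rises with age for chronic conditions
#' and falls for appendicitis and influenza. No confounders or omission by
#' default.
#'
#' @param n_patients number of visits.
#' @param seed integer seed.
#' @param omission_prob,negation_insert_prob see [generator_config()].
#' @return A `generator_config`.
#' @export
default_generator_config <- function(n_patients = 5000, seed = 1,
                                     omission_prob = 0,
                                     negation_insert_prob = 0.25) {
  brackets <- c(child = 0.15, young_adult = 0.30, adult = 0.30, senior = 0.25)
  prev <- rbind(
    d_gallstones   = c(0.010, 0.030, 0.060, 0.080),
    d_kidney_stone = c(0.005, 0.040, 0.060, 0.050),
    d_appendicitis = c(0.050, 0.040, 0.020, 0.010),
    d_pneumonia    = c(0.040, 0.020, 0.040, 0.100),
    d_uti          = c(0.030, 0.060, 0.050, 0.090),
    d_migraine     = c(0.020, 0.080, 0.070, 0.030),
    d_influenza    = c(0.080, 0.050, 0.040, 0.050),
    d_copd         = c(0.001, 0.005, 0.040, 0.120))
  colnames(prev) <- names(brackets)
  symptoms <- c("s_abdominal_pain", "s_nausea", "s_vomiting", "s_fever",
                "s_flank_pain", "s_chills", "s_cough", "s_headache",
                "s_dysuria", "s_back_pain", "s_chest_pain",
                "s_short_of_breath", "s_fatigue", "s_dizziness", "s_diarrhea",
                "s_loss_of_appetite", "s_photophobia", "s_wheezing",
                "s_sputum", "s_urinary_frequency", "s_jaundice",
                "s_hematuria", "s_sore_throat", "s_myalgia", "s_sweating")
  act <- matrix(0, nrow = length(symptoms), ncol = nrow(prev),
                dimnames = list(symptoms, rownames(prev)))
  set_edges <- function(disease, ...) {
    e <- c(...)
    act[names(e), disease] <<- e
  }
  set_edges("d_gallstones", s_abdominal_pain = 0.70, s_nausea = 0.50,
            s_vomiting = 0.35, s_jaundice = 0.15, s_loss_of_appetite = 0.20)
  set_edges("d_kidney_stone", s_flank_pain = 0.60, s_nausea = 0.40,
            s_hematuria = 0.30, s_vomiting = 0.25, s_back_pain = 0.30)
  set_edges("d_appendicitis", s_abdominal_pain = 0.75, s_nausea = 0.45,
            s_fever = 0.30, s_vomiting = 0.30, s_loss_of_appetite = 0.40,
            s_diarrhea = 0.15)
  set_edges("d_pneumonia", s_cough = 0.70, s_fever = 0.55,
            s_short_of_breath = 0.50, s_sputum = 0.40, s_chest_pain = 0.25,
            s_chills = 0.35)
  set_edges("d_uti", s_dysuria = 0.65, s_urinary_frequency = 0.55,
            s_fever = 0.25, s_hematuria = 0.20, s_abdominal_pain = 0.15)
  set_edges("d_migraine", s_headache = 0.80, s_photophobia = 0.50,
            s_nausea = 0.40, s_dizziness = 0.25, s_vomiting = 0.20)
  set_edges("d_influenza", s_fever = 0.65, s_myalgia = 0.50, s_cough = 0.45,
            s_headache = 0.35, s_sore_throat = 0.40, s_chills = 0.45,
            s_fatigue = 0.40)
  set_edges("d_copd", s_short_of_breath = 0.70, s_cough = 0.60,
            s_wheezing = 0.50, s_sputum = 0.35, s_fatigue = 0.25,
            s_chest_pain = 0.15)
  leaks <- stats::setNames(rep(0.02, length(symptoms)), symptoms)
  leaks[c("s_abdominal_pain", "s_nausea", "s_headache", "s_fatigue")] <- 0.06
  leaks[c("s_vomiting", "s_fever", "s_cough", "s_back_pain",
          "s_dizziness", "s_chest_pain")] <- 0.04
  leaks["s_sweating"] <- 0.03
  disease_names <- c(d_gallstones = "Gallstones", d_kidney_stone = "Kidney stone",
                     d_appendicitis = "Appendicitis", d_pneumonia = "Pneumonia",
                     d_uti = "Urinary tract infection", d_migraine = "Migraine",
                     d_influenza = "Influenza", d_copd = "COPD")
  symptom_names <- stats::setNames(gsub("_", " ", sub("^s_", "", symptoms)),
                                   symptoms)
  symptom_names["s_short_of_breath"] <- "shortness of breath"
  aliases <- list(
    d_gallstones = c("cholelithiasis", "gall stones"),
    d_kidney_stone = c("renal calculus", "nephrolithiasis"),
    d_appendicitis = "acute appendicitis",
    d_uti = c("UTI", "urinary infection"),
    d_influenza = "flu",
    d_copd = "chronic obstructive pulmonary disease",
    s_abdominal_pain = "abd pain",
    s_dysuria = "painful urination",
    s_short_of_breath = c("SOB", "dyspnea"),
    s_hematuria = "blood in urine",
    s_myalgia = "muscle aches",
    s_photophobia = "light sensitivity",
    s_sputum = "productive sputum")
  codes <- list(d_gallstones = "574.2", d_kidney_stone = "592.0",
                d_appendicitis = "540.9", d_pneumonia = "486",
                d_uti = "599.0", d_migraine = "346.9", d_influenza = "487.1",
                d_copd = "496")
  generator_config(n_patients, brackets, prev, act, leaks,
                   names = c(disease_names, symptom_names), aliases = aliases,
                   codes = codes, omission_prob = omission_prob,
                   negation_insert_prob = negation_insert_prob, seed = seed)
}

#' Age-confounding scenario
#'
#' A scenario engineered to exhibit age confounding: the target disease is
#' almost exclusive to seniors, and one symptom (`s_confounded`) has no
#' disease parent at all, being directly activated by the senior bracket
#' itself. Pairwise models see a strong disease-symptom association driven
#' purely by shared old age; the jointly estimated noisy-OR network can only
#' partially absorb it (age is not one of its nodes), but its importance is
#' measured on the absolute activation scale, where the spurious edge falls
#' below the disease's genuine effects, whereas the relative-risk scale of
#' naive Bayes amplifies it.
#'
#' @param n_patients number of visits.
#' @param seed integer seed.
#' @return A `generator_config` with attribute `target` (the confounded
#'   disease id) and `confounded_symptom`.
#' @export
confounded_generator_config <- function(n_patients = 20000, seed = 1) {
  brackets <- c(child = 0.20, young_adult = 0.35, adult = 0.30, senior = 0.15)
  prev <- rbind(
    d_target  = c(0.002, 0.002, 0.002, 0.400),
    d_senior2 = c(0.010, 0.010, 0.010, 0.300),
    d_senior3 = c(0.010, 0.010, 0.010, 0.250),
    d_uniform = c(0.050, 0.050, 0.050, 0.050))
  colnames(prev) <- names(brackets)
  symptoms <- c(paste0("s_", 1:10), "s_confounded")
  act <- matrix(0, nrow = length(symptoms), ncol = nrow(prev),
                dimnames = list(symptoms, rownames(prev)))
  act[c("s_1", "s_2", "s_3", "s_4", "s_5"), "d_target"] <-
    c(0.60, 0.50, 0.42, 0.22, 0.15)
  act[c("s_6", "s_7"), "d_senior2"] <- c(0.50, 0.30)
  act[c("s_8", "s_9"), "d_senior3"] <- c(0.45, 0.25)
  act["s_10", "d_uniform"] <- 0.40
  leaks <- stats::setNames(
    c(0.15, 0.12, 0.10, 0.10, 0.08, 0.05, 0.08, 0.06, 0.07, 0.05, 0.01),
    symptoms)
  conf <- data.frame(bracket = "senior", symptom_id = "s_confounded",
                     prob = 0.35, stringsAsFactors = FALSE)
  cfg <- generator_config(n_patients, brackets, prev, act, leaks,
                          confounders = conf, seed = seed)
  attr(cfg, "target") <- "d_target"
  attr(cfg, "confounded_symptom") <- "s_confounded"
  cfg
}

#' Concept vocabulary implied by a generator configuration
#' @param config a `generator_config`.
#' @return A `concept_vocabulary` over the configured concepts.
#' @export
vocabulary_from_config <- function(config) {
  ids <- c(rownames(config$prevalence), rownames(config$activation))
  roles <- c(rep("disease", nrow(config$prevalence)),
             rep("symptom", nrow(config$activation)))
  concept_vocabulary(
    data.frame(concept_id = ids, name = unname(config$names[ids]),
               role = roles, stringsAsFactors = FALSE),
    aliases = config$aliases, codes = config$codes)
}

#' Sample disease states and age brackets
#'
#' Each patient's age bracket is drawn from the configured mix, then each
#' disease is drawn independently given the bracket. Because the bracket is
#' a shared latent cause, diseases with bracket-dependent prevalence are
#' marginally correlated. Deterministic given the configuration seed.
#'
#' @param config a `generator_config`.
#' @return List with `Y` (n x diseases binary matrix, patient ids in rows)
#'   and `brackets` (named character vector).
#' @export
sample_disease_states <- function(config) {
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("p%06d", seq_len(n))
  brackets <- sample(names(config$bracket_mix), n, replace = TRUE,
                     prob = config$bracket_mix)
  d <- nrow(config$prevalence)
  Y <- matrix(0L, nrow = n, ncol = d,
              dimnames = list(ids, rownames(config$prevalence)))
  for (j in seq_len(d)) {
    p <- config$prevalence[j, brackets]
    Y[, j] <- stats::rbinom(n, 1, p)
  }
  list(Y = Y, brackets = stats::setNames(brackets, ids))
}

#' Sample symptoms from the generating noisy-OR process
#'
#' Each symptom is drawn Bernoulli with the noisy-OR probability implied by
#' the patient's disease vector, OR-ed with any direct age-bracket
#' confounder activation, and finally masked by the omission probability
#' (a present symptom goes unrecorded with that probability). Deterministic
#' given the configuration seed.
#'
#' @param disease_states output of [sample_disease_states()].
#' @param config a `generator_config`.
#' @return n x symptoms binary matrix.
#' @export
sample_symptoms <- function(disease_states, config) {
  set.seed(config$seed + 1L)
  Y <- disease_states$Y
  brackets <- disease_states$brackets
  n <- nrow(Y)
  s <- nrow(config$activation)
  # q = P(symptom stays off): start from 1 - leak, multiply in failures of
  # active parents, then confounder non-activations
  q <- matrix(rep(1 - config$leaks, each = n), nrow = n,
              dimnames = list(rownames(Y), rownames(config$activation)))
  for (j in seq_len(ncol(Y))) {
    on <- Y[, j] == 1
    if (!any(on)) next
    f <- 1 - config$activation[, j]
    q[on, ] <- sweep(q[on, , drop = FALSE], 2, f, "*")
  }
  if (nrow(config$confounders) > 0) {
    for (k in seq_len(nrow(config$confounders))) {
      sel <- brackets == config$confounders$bracket[k]
      sym <- config$confounders$symptom_id[k]
      q[sel, sym] <- q[sel, sym] * (1 - config$confounders$prob[k])
    }
  }
  X <- matrix(stats::rbinom(n * s, 1, as.vector(1 - q)), nrow = n,
              dimnames = dimnames(q))
  omitted <- matrix(stats::runif(n * s) < config$omission_prob, nrow = n)
  X[omitted] <- 0L
  storage.mode(X) <- "integer"
  X
}

#' Simulate a complete record matrix
#'
#' Convenience wrapper: samples disease states and symptoms and assembles
#' them into a [record_matrix()] (disease columns first).
#'
#' @param config a `generator_config`.
#' @return A `record_matrix` with the generating age brackets attached.
#' @export
simulate_record_matrix <- function(config) {
  ds <- sample_disease_states(config)
  X <- sample_symptoms(ds, config)
  cells <- cbind(ds$Y, X)
  roles <- stats::setNames(
    c(rep("disease", ncol(ds$Y)), rep("symptom", ncol(X))), colnames(cells))
  record_matrix(cells, roles, ds$brackets)
}

POSITIVE_TEMPLATES <- c("reports %s.", "presents with %s.", "%s noted.",
                        "complains of %s.")
NEGATION_TEMPLATES <- c("denies %s.", "no %s.", "negative for %s.")

#' Render binary records as free-text patient records
#'
#' Every positive concept is rendered as one sentence using a randomly
#' chosen alias and positive template, placed in a randomly chosen text
#' field; positive diseases with code mappings also emit their structured
#' diagnosis code. With probability `negation_insert_prob`, one absent
#' concept is additionally mentioned inside a negation phrase (which
#' extraction must ignore). With collision-free aliases and no omission,
#' extraction over the rendered corpus reproduces the generating matrix
#' exactly.
#'
#' @param matrix a `record_matrix` (e.g. from [simulate_record_matrix()]).
#' @param config the `generator_config` that produced it.
#' @return List of [text_record()] objects.
#' @export
render_text_records <- function(matrix, config) {
  vocab <- vocabulary_from_config(config)
  missing_alias <- names(vocab$aliases)[lengths(vocab$aliases) == 0]
  if (length(missing_alias) > 0) {
    stop("concept without alias: ", missing_alias[1])
  }
  set.seed(config$seed + 2L)
  ids <- rownames(matrix$cells)
  all_concepts <- colnames(matrix$cells)
  lapply(seq_along(ids), function(i) {
    row <- matrix$cells[i, ]
    pos <- all_concepts[row == 1]
    fields <- stats::setNames(vector("list", length(TEXT_FIELDS)), TEXT_FIELDS)
    codes <- character()
    for (cid in pos) {
      alias <- sample(vocab$aliases[[cid]], 1)
      sent <- sprintf(sample(POSITIVE_TEMPLATES, 1), tolower(alias))
      fld <- sample(TEXT_FIELDS, 1)
      fields[[fld]] <- c(fields[[fld]], sent)
      codes <- c(codes, config$codes[[cid]])
    }
    absent <- setdiff(all_concepts, pos)
    if (length(absent) > 0 &&
        stats::runif(1) < config$negation_insert_prob) {
      cid <- sample(absent, 1)
      alias <- sample(vocab$aliases[[cid]], 1)
      sent <- sprintf(sample(NEGATION_TEMPLATES, 1), tolower(alias))
      fld <- sample(TEXT_FIELDS, 1)
      fields[[fld]] <- c(fields[[fld]], sent)
    }
    text_record(ids[i], matrix$age_brackets[[ids[i]]],
                fields = lapply(fields, function(x) paste(x, collapse = " ")),
                codes = codes)
  })
}

#' Ground-truth knowledge graph of a generator configuration
#'
#' Edges are the (disease, symptom) pairs with generating failure
#' probability below 1, scored by the generating importance
#' `1 - f_ij` (the activation probability).
#'
#' @param config a `generator_config`.
#' @return A `knowledge_graph` labeled `"ground_truth"`.
#' @export
make_ground_truth_graph <- function(config) {
  act <- config$activation
  idx <- which(act > 0, arr.ind = TRUE)
  edges <- data.frame(disease_id = colnames(act)[idx[, 2]],
                      symptom_id = rownames(act)[idx[, 1]],
                      importance = act[idx], stringsAsFactors = FALSE)
  knowledge_graph(edges, model = "ground_truth")
}

#' Reference graph derived from a generator's ground truth
#'
#' Buckets generating edges by activation strength (`always` for activation
#' at or above `always_cutoff`, `frequent` otherwise) and tabulates
#' per-bracket disease frequency labels from the prevalence matrix; useful
#' as the evaluation target in end-to-end synthetic runs.
#'
#' @param config a `generator_config`.
#' @param always_cutoff activation at or above this becomes bucket
#'   `"always"`.
#' @return A `reference_graph`.
#' @export
reference_from_config <- function(config, always_cutoff = 0.6) {
  truth <- make_ground_truth_graph(config)$edges
  freq_label <- function(p) {
    cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, 0.15, Inf),
        labels = c("never", "very rare", "rare", "frequent", "very frequent"))
  }
  freq <- apply(config$prevalence, 1, function(row) {
    as.list(stats::setNames(as.character(freq_label(row)), names(row)))
  })
  structure(list(
    edges = data.frame(
      disease_id = truth$disease_id, symptom_id = truth$symptom_id,
      bucket = ifelse(truth$importance >= always_cutoff, "always", "frequent"),
      stringsAsFactors = FALSE),
    disease_frequency = freq, n_skipped = 0L),
    class = "reference_graph")
}
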