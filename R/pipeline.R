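# End-to-end orchestration: extract -> support filter -> fit each requested
# model -> build graphs -> evaluate, with a manifest that makes a run a pure
# function of (inputs, config, seeds).

#' Construct a pipeline configuration
#'
#' @param records path to a JSONL record corpus (exclusive with
#'   `matrix_prefix`).
#' @param vocabulary path to the vocabulary TSV (required with `records`).
#' @param matrix_prefix path prefix of a pre-built record matrix (see
#'   [write_record_matrix()]); alternative entry point skipping extraction.
#' @param reference optional path to a reference-graph JSON for the
#'   automatic evaluation.
#' @param tags optional path to a physician-tag CSV for the clinical
#'   evaluation.
#' @param models character subset of `"noisy_or"`, `"naive_bayes"`,
#'   `"logistic"`.
#' @param min_disease,min_symptom support-filter thresholds.
#' @param min_cooccurrence co-occurrence floor for naive Bayes / logistic
#'   edges.
#' @param top_n edges per disease in the constructed graphs and the pool.
#' @param exclude_symptoms symptoms excluded from the automatic evaluation.
#' @param tag_scheme binarization scheme for physician tags.
#' @param restrict_reference when `TRUE` (default) the automatic
#'   evaluation's recall denominator counts only reference edges whose
#'   concepts survived support filtering; `FALSE` keeps the full reference.
#' @param seed master integer seed.
#' @param out_dir run directory to create.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(records = NULL, vocabulary = NULL,
                            matrix_prefix = NULL, reference = NULL,
                            tags = NULL,
                            models = c("noisy_or", "naive_bayes", "logistic"),
                            min_disease = 100, min_symptom = 10,
                            min_cooccurrence = 5, top_n = 20,
                            exclude_symptoms = "pain",
                            tag_scheme = "rarely_positive",
                            restrict_reference = TRUE,
                            seed = 1, out_dir = tempfile("healthkg_run_")) {
  stopifnot(min_disease >= 0, min_symptom >= 0, min_cooccurrence >= 0,
            top_n >= 0)
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(matrix_prefix) && (is.null(records) || is.null(vocabulary))) {
    stop("supply either records + vocabulary, or matrix_prefix")
  }
  structure(list(records = records, vocabulary = vocabulary,
                 matrix_prefix = matrix_prefix, reference = reference,
                 tags = tags, models = models, min_disease = min_disease,
                 min_symptom = min_symptom,
                 min_cooccurrence = min_cooccurrence, top_n = top_n,
                 exclude_symptoms = exclude_symptoms,
                 tag_scheme = tag_scheme,
                 restrict_reference = restrict_reference,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

stage <- function(run_dir, name, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
               file.path(run_dir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full knowledge-graph pipeline
#'
#' Executes extraction (or matrix loading), support filtering, model
#' fitting, graph construction and the configured evaluations, writing every
#' artifact plus a `manifest.json` (configuration echo, input checksums,
#' seeds, artifact list) into the run directory. Re-running with an
#' identical configuration reproduces identical outputs; any stage failure
#' aborts with the stage name and leaves a `FAILED` marker beside the
#' partial outputs.
#'
#' @param config a [pipeline_config()].
#' @return The run directory path, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  run_dir <- config$out_dir
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(run_dir, "run.log")
  log_lines <- character()
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
    message(sprintf(...))
  }

  vocab <- NULL
  if (!is.null(config$matrix_prefix)) {
    mat <- stage(run_dir, "load-matrix", read_record_matrix(config$matrix_prefix))
    say("loaded matrix: %d patients x %d concepts", nrow(mat$cells),
        ncol(mat$cells))
  } else {
    vocab <- stage(run_dir, "load-vocabulary", load_vocabulary(config$vocabulary))
    records <- stage(run_dir, "load-records", read_records(config$records))
    mat <- stage(run_dir, "extract", build_record_matrix(records, vocab))
    say("extracted %d patients x %d concepts", nrow(mat$cells),
        ncol(mat$cells))
  }
  mat <- stage(run_dir, "support-filter",
               apply_support_filter(mat, config$min_disease,
                                    config$min_symptom))
  say("support filter kept %d concepts (dropped fraction %.3f)",
      ncol(mat$cells), attr(mat, "dropped_fraction"))
  if (length(disease_ids(mat)) == 0 || length(symptom_ids(mat)) == 0) {
    stage(run_dir, "support-filter",
          stop("no diseases or no symptoms survived the support filter"))
  }
  write_record_matrix(mat, file.path(run_dir, "matrix"))

  reference <- NULL
  if (!is.null(config$reference)) {
    if (is.null(vocab)) {
      vocab <- concept_vocabulary(data.frame(
        concept_id = colnames(mat$cells),
        name = colnames(mat$cells), role = unname(mat$roles)))
    }
    reference <- stage(run_dir, "load-reference",
                       load_reference_graph(config$reference, vocab))
    if (isTRUE(config$restrict_reference)) {
      reference <- restrict_reference(reference, colnames(mat$cells))
    }
  }

  graphs <- list()
  for (model_name in config$models) {
    say("fitting %s", model_name)
    scores <- stage(run_dir, paste0("fit-", model_name), {
      if (model_name == "noisy_or") {
        fit <- fit_noisy_or(mat, seed = config$seed)
        write_model(fit, file.path(run_dir, "params_noisy_or.json"))
        score_table(fit)
      } else {
        fitter <- if (model_name == "logistic") fit_logistic else fit_naive_bayes
        tabs <- lapply(disease_ids(mat), function(d) {
          score_table(fitter(mat, d, seed = config$seed))
        })
        bind_score_tables(tabs)
      }
    })
    scores <- cooccurrence_filter(scores, mat,
                                  min_count = config$min_cooccurrence)
    graph <- stage(run_dir, paste0("graph-", model_name),
                   build_graph(scores, top_n = config$top_n))
    write_edge_list(graph, file.path(run_dir,
                                     paste0("graph_", model_name, ".tsv")))
    graphs[[model_name]] <- structure(scores, graph = graph)

    if (!is.null(reference)) {
      curve <- stage(run_dir, paste0("evaluate-auto-", model_name),
                     pr_vs_reference(scores, reference,
                                     exclude_symptoms = config$exclude_symptoms,
                                     vocabulary = vocab, label = model_name))
      write_pr_curve(curve, file.path(run_dir,
                                      paste0("pr_auto_", model_name, ".tsv")))
    }
  }

  if (!is.null(config$tags)) {
    tags <- stage(run_dir, "load-tags", read_physician_tags(config$tags))
    rater <- sort(unique(tags$rater_id))[1]
    rel <- binarize_tags(tags[tags$rater_id == rater, ], config$tag_scheme)
    for (model_name in names(graphs)) {
      curve <- stage(run_dir, paste0("evaluate-clinical-", model_name),
                     pr_vs_tags(graphs[[model_name]], rel,
                                label = model_name))
      write_pr_curve(curve,
                     file.path(run_dir,
                               paste0("pr_clinical_", model_name, ".tsv")))
    }
  } else {
    say("no physician tags supplied; clinical evaluation skipped")
  }

  inputs <- Filter(Negate(is.null),
                   list(records = config$records,
                        vocabulary = config$vocabulary,
                        reference = config$reference, tags = config$tags))
  manifest <- list(
    config = unclass(config),
    input_md5 = lapply(inputs, function(p) unname(tools::md5sum(p))),
    seed = config$seed,
    artifacts = sort(setdiff(list.files(run_dir), c("manifest.json",
                                                    "run.log"))))
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  writeLines(log_lines, log_path)
  invisible(run_dir)
}
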