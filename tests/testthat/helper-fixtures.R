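# Small programmatic fixtures shared across test files.

# quick record matrix from a cells matrix and a role prefix convention:
# columns starting with "d" are diseases, "s" are symptoms
quick_matrix <- function(cells, brackets = NULL) {
  if (is.null(rownames(cells))) {
    rownames(cells) <- sprintf("p%04d", seq_len(nrow(cells)))
  }
  roles <- ifelse(startsWith(colnames(cells), "d"), "disease", "symptom")
  record_matrix(cells, stats::setNames(roles, colnames(cells)), brackets)
}

# 1-disease / 1-symptom matrix sampled from a generating noisy-OR gate
one_pair_matrix <- function(n, prevalence, activation, leak, seed) {
  set.seed(seed)
  y <- stats::rbinom(n, 1, prevalence)
  p <- 1 - (1 - leak) * (1 - activation)^y
  x <- stats::rbinom(n, 1, p)
  quick_matrix(cbind(d1 = y, s1 = x))
}

# tiny three-concept vocabulary used by extraction tests
toy_vocabulary <- function() {
  concept_vocabulary(
    data.frame(
      concept_id = c("d_appendicitis", "s_flank_pain", "s_pain", "s_nausea",
                     "s_fever", "s_chills"),
      name = c("Appendicitis", "flank pain", "pain", "nausea", "fever",
               "chills"),
      role = c("disease", rep("symptom", 5)),
      stringsAsFactors = FALSE),
    aliases = list(d_appendicitis = "acute appendicitis"),
    codes = list(d_appendicitis = "540.9"))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path, useBytes = TRUE)
  path
}
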