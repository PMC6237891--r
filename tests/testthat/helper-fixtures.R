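# Shared fixtures, built in code at test time.

# memoised cohorts so the large study-condition cohort is generated once
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function(n = 300L, seed = 3L, target_r2 = 0.5) {
  key <- sprintf("small_%d_%d_%g", n, seed, target_r2)
  if (is.null(.fixture_env[[key]])) {
    cfg <- synthetic_config(n_proteins = n, length_range = c(50L, 150L),
                            target_r2 = target_r2, seed = seed)
    .fixture_env[[key]] <- plant_response(generate_cds_cohort(cfg))
  }
  .fixture_env[[key]]
}

# full study-condition cohort (defaults of synthetic_config) plus its
# composition feature matrix
study_cohort <- function() {
  if (is.null(.fixture_env$study)) {
    cfg <- synthetic_config(seed = 11L)
    .fixture_env$study <- generate_cds_cohort(cfg)
  }
  .fixture_env$study
}

study_features <- function() {
  if (is.null(.fixture_env$study_fm)) {
    .fixture_env$study_fm <- assemble_feature_matrix(study_cohort()$records)
  }
  .fixture_env$study_fm
}

random_protein <- function(n = 120L, seed = 7L) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  set.seed(seed)
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# the amino-acid grouping used for importance summaries, restated
# independently of the package internals
AA_GROUPS_MEMBERS <- list(
  small_hydrophobic = c("A", "I", "L", "V"),
  negative_polar = c("D", "E", "N", "Q"),
  positive = c("K", "R"),
  phospho = c("S", "T"),
  unusual = c("P", "W", "C")
)

# closed-form Pearson r, independent of stats::cor
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}
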