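# End-to-end plumbing: materialise a synthetic study on disk and chain the
# analysis stages, as driven by the command-line interface in
# inst/cli/codonlife.R.

#' Write a complete synthetic study to a directory
#'
#' Generates a cohort under \code{config}, plants a primary response plus a
#' replicate dataset, structures and annotation terms, simulates one decay
#' curve per designer target level, and writes everything as FASTA/TSV files
#' (\code{cds.fasta}, \code{responses.tsv}, \code{structures.tsv},
#' \code{annotations.tsv}, \code{decay.tsv}) together with the resolved
#' configuration (\code{config.json}).
#'
#' @param config A \code{\link{synthetic_config}}.
#' @param out_dir Output directory (created if missing).
#' @param annotation_prevalences Per-term protein counts.
#' @return Invisibly, the cohort.
#' @export
simulate_study <- function(config, out_dir,
                           annotation_prevalences = 1:20) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cds_cohort(config)
  cohort <- plant_response(cohort, config, "lifetime")
  cohort <- plant_response(cohort, config, "lifetime_rep",
                           replicate_of = "lifetime")
  cohort <- generate_structures(cohort)
  cohort <- generate_annotations(cohort, annotation_prevalences)
  write_fasta(cohort$records, file.path(out_dir, "cds.fasta"))
  write_responses(cohort$responses, file.path(out_dir, "responses.tsv"))
  write_structures(cohort$structures, file.path(out_dir, "structures.tsv"))
  write_annotations(cohort$annotations,
                    file.path(out_dir, "annotations.tsv"))
  curves <- lapply(seq(0.02, 0.10, length.out = 5), function(k) {
    simulate_decay_curves(k_deg = k, k_div = 0.01, f0 = 100, background = 5,
                          noise_sd = 2, seed = config$seed + round(1000 * k),
                          construct = sprintf("kdeg_%.2f", k))
  })
  write_decay_curves(curves, file.path(out_dir, "decay.tsv"))
  cfg <- unclass(config)
  cfg$effect_map <- as.list(cfg$effect_map)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cohort)
}
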