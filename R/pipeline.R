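#' Pipeline run configuration
#'
#' Bundles paths, predictor parameters, QC thresholds, profile windows and
#' the Bonferroni setting for the `cmd_*` pipeline entry points. All
#' defaults are logged by each command for reproducibility.
#'
#' @param genome,gtf,vcf input file paths (not needed by [cmd_simulate()]).
#' @param outdir output directory.
#' @param pwm path to a PWM TSV, or NULL for the packaged default.
#' @param lambda,d_min,d_max,L,bin_width predictor parameters (see
#'   [predict_branch_points()] and [estimate_octamer_background()]).
#' @param study_key INFO key holding submitter labels.
#' @param alpha,m_tests Bonferroni setting for position comparisons.
#' @param thresholds a [qc_thresholds()].
#' @param exonic_flank,intronic_flank splice-site profile windows.
#' @param sim a [sim_config()] for the simulate command.
#' @param seed RNG seed (simulate command).
#' @return list of class `run_config`.
#' @export
run_config <- function(genome = NULL, gtf = NULL, vcf = NULL,
                       outdir = ".", pwm = NULL, lambda = 1,
                       d_min = 9L, d_max = 150L, L = 150L, bin_width = 10L,
                       study_key = "SID", alpha = 0.05, m_tests = 1L,
                       thresholds = qc_thresholds(),
                       exonic_flank = 3L, intronic_flank = 8L,
                       seed = 1L, sim = sim_config(seed = seed)) {
  structure(list(genome = genome, gtf = gtf, vcf = vcf, outdir = outdir,
                 pwm = pwm, lambda = lambda, d_min = d_min, d_max = d_max,
                 L = L, bin_width = bin_width, study_key = study_key,
                 alpha = alpha, m_tests = m_tests, thresholds = thresholds,
                 exonic_flank = exonic_flank,
                 intronic_flank = intronic_flank,
                 seed = as.integer(seed), sim = sim),
            class = "run_config")
}

.ensure_outdir <- function(config) {
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  config$outdir
}

.load_inputs <- function(config, need = c("genome", "gtf", "vcf")) {
  for (p in need) {
    if (is.null(config[[p]]) || !file.exists(config[[p]]))
      stop("input path missing or not found: ", p,
           " (", config[[p]] %||% "NULL", ")")
  }
  out <- list()
  if ("genome" %in% need) out$genome <- read_genome(config$genome)
  if ("gtf" %in% need) out$models <- parse_annotation(config$gtf, out$genome)
  if ("vcf" %in% need)
    out$catalog <- load_variants(config$vcf, out$genome,
                                 study_key = config$study_key)
  out
}

#' Simulate a dataset and write it to disk
#'
#' Runs the generator and writes `genome.fa`, `annotation.gtf`,
#' `truth.tsv` and `variants.vcf` into the output directory. Identical
#' config and seed give byte-identical outputs.
#'
#' @param config a [run_config()]; the `sim` element parameterizes the
#'   generator.
#' @return invisible list with the simulation, catalogue and file paths.
#' @export
cmd_simulate <- function(config = run_config()) {
  dir <- .ensure_outdir(config)
  message("simulate: seed = ", config$sim$seed)
  sim <- simulate_genome(config$sim)
  catalog <- simulate_variants(sim)
  paths <- write_simulation(sim, dir)
  vcf <- file.path(dir, "variants.vcf")
  write_vcf(catalog, vcf, genome = sim$genome, study_key = config$study_key)
  paths["vcf"] <- vcf
  message("simulate: ", nrow(catalog), " SNVs, ", nrow(sim$truth),
          " planted branch points -> ", dir)
  invisible(list(sim = sim, catalog = catalog, paths = paths))
}

#' Predict branch points for an annotated genome
#'
#' Derives introns from the GTF, estimates the octanucleotide background
#' (unless `lambda = 0`), predicts one branch point per intron, and writes
#' `predictions.tsv`. Prints the consensus sequence, canonical TnA
#' fraction and distance summary.
#'
#' @param config a [run_config()] with `genome` and `gtf` set.
#' @return invisible `bps_predictions` (empty when no introns).
#' @export
cmd_predict <- function(config) {
  inp <- .load_inputs(config, c("genome", "gtf"))
  introns <- derive_introns(inp$models)
  if (!length(introns)) {
    message("predict: no introns found; nothing to do")
    return(invisible(.empty_predictions()))
  }
  pwm <- if (is.null(config$pwm)) default_pwm() else read_pwm(config$pwm)
  bg <- NULL
  if (config$lambda != 0)
    bg <- estimate_octamer_background(introns, inp$genome, L = config$L,
                                      bin_width = config$bin_width)
  preds <- predict_branch_points(introns, inp$genome, pwm, bg,
                                 lambda = config$lambda,
                                 d_min = config$d_min, d_max = config$d_max)
  dir <- .ensure_outdir(config)
  write_predictions(preds, file.path(dir, "predictions.tsv"))
  ds <- distance_summary(preds)
  message("predict: ", nrow(preds), " predicted, ",
          length(attr(preds, "unpredicted")), " unpredicted introns")
  message("predict: consensus ", consensus_sequence(preds),
          ", canonical TnA fraction ",
          round(canonical_tna_fraction(preds), 3),
          ", median BP-3'SS distance ", ds$median, " bp")
  invisible(preds)
}

#' Audit a variant database against the plausibility criteria
#'
#' @param config a [run_config()] with `genome`, `gtf` and `vcf` set.
#' @return invisible `qc_report`; also written as `qc_report.json`.
#' @export
cmd_audit <- function(config) {
  inp <- .load_inputs(config)
  introns <- derive_introns(inp$models)
  features <- build_feature_catalog(inp$models, inp$genome, introns = introns)
  report <- evaluate_database(inp$catalog, features, inp$genome, introns,
                              thresholds = config$thresholds)
  dir <- .ensure_outdir(config)
  qc_report_json(report, file.path(dir, "qc_report.json"))
  print(report)
  invisible(report)
}

#' Constraint analysis: feature variability, profiles, position comparison
#'
#' Computes the feature variability table, splice-site and BPS profiles,
#' and the Fisher comparison of heptamer positions 4 and 6 with the
#' configured Bonferroni threshold; writes them as TSV/JSON.
#'
#' @param config a [run_config()] with `genome`, `gtf` and `vcf` set.
#' @param predictions optional precomputed `bps_predictions`; by default
#'   [cmd_predict()] is run.
#' @return invisible list with `variability`, `splice_profile`,
#'   `bps_profile`, `comparison`.
#' @export
cmd_constrain <- function(config, predictions = NULL) {
  inp <- .load_inputs(config)
  introns <- derive_introns(inp$models)
  if (!length(introns)) stop("no introns found in annotation")
  features <- build_feature_catalog(inp$models, inp$genome, introns = introns)
  if (is.null(predictions)) predictions <- cmd_predict(config)

  vt <- feature_variability(inp$catalog, features, inp$genome)
  ssp <- splice_site_profile(inp$catalog, introns, inp$genome,
                             exonic_flank = config$exonic_flank,
                             intronic_flank = config$intronic_flank)
  bpp <- bps_profile(inp$catalog, predictions, inp$genome)
  cmp <- compare_positions(bpp, "4", "6", alpha = config$alpha,
                           m_tests = config$m_tests)

  dir <- .ensure_outdir(config)
  write.table(vt, file.path(dir, "feature_variability.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ssp, file.path(dir, "splice_profile.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bpp, file.path(dir, "bps_profile.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(positions = cmp$positions, table = cmp$table,
         odds_ratio = cmp$odds_ratio, p_value = cmp$p_value,
         bonferroni_threshold = cmp$threshold, alpha = cmp$alpha,
         m_tests = cmp$m_tests, significant = cmp$significant),
    file.path(dir, "position_comparison.json"),
    auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  message("constrain: Bonferroni threshold ", signif(cmp$threshold, 3),
          " (alpha ", config$alpha, " / ", config$m_tests, " tests); ",
          "positions 4 vs 6 P = ", signif(cmp$p_value, 3))
  print(cmp)
  invisible(list(variability = vt, splice_profile = ssp, bps_profile = bpp,
                 comparison = cmp))
}

#' End-to-end pipeline on a simulated dataset
#'
#' Simulates, then predicts, audits and runs the constraint analysis on the
#' simulated files.
#'
#' @param config a [run_config()].
#' @return invisible list of all stage outputs.
#' @export
cmd_all <- function(config = run_config()) {
  simres <- cmd_simulate(config)
  config$genome <- simres$paths[["genome"]]
  config$gtf <- simres$paths[["annotation"]]
  config$vcf <- simres$paths[["vcf"]]
  preds <- cmd_predict(config)
  audit <- cmd_audit(config)
  constr <- cmd_constrain(config, predictions = preds)
  invisible(list(sim = simres, predictions = preds, audit = audit,
                 constraint = constr))
}
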