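#' Configuration for end-to-end pipeline runs
#'
#' A single master seed deterministically spawns one sub-seed per
#' stochastic stage, so reruns with the same configuration are identical.
#' Configurations round-trip losslessly through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param seed Master seed.
#' @param n_lineages Founder lineage count of the synthetic population.
#' @param sampling_depth Reads per census.
#' @param emit_reads Run the FASTQ emission / extraction / merge front end
#'   for the censuses the inference consumes (otherwise frequency tables
#'   are used directly).
#' @param error_rate Per-base substitution error rate of emitted reads.
#' @param fail_q_fraction Fraction of reads failing the Q>20 filter.
#' @param min_q Quality threshold of the read filter.
#' @param max_hamming Hamming merge radius.
#' @param gef_weeks,trm_weeks Drug exposure durations, weeks.
#' @param min_f0 Baseline-frequency threshold used when summarising
#'   phenotype recovery and growth-rate error against the generator truth.
#' @param sim Named list of [sim_design()] overrides for
#'   [run_simulation_suite()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_lineages = 2000, sampling_depth = 3e5,
                       emit_reads = TRUE, error_rate = 1e-3,
                       fail_q_fraction = 0.01, min_q = 20, max_hamming = 2,
                       gef_weeks = 4, trm_weeks = 9, min_f0 = 1e-4,
                       sim = list()) {
  structure(list(seed = as.integer(seed),
                 n_lineages = as.integer(n_lineages),
                 sampling_depth = sampling_depth, emit_reads = emit_reads,
                 error_rate = error_rate,
                 fail_q_fraction = fail_q_fraction, min_q = min_q,
                 max_hamming = max_hamming, gef_weeks = gef_weeks,
                 trm_weeks = trm_weeks, min_f0 = min_f0, sim = sim),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

# deterministic per-stage sub-seeds from the master seed
.stage_seeds <- function(master, n) {
  set.seed(master)
  sample.int(2147483646L, n)
}

#' Run the full synthetic analysis chain and score it against truth
#'
#' Generates a synthetic experiment, optionally emits FASTQ reads for the
#' nine censuses the inference consumes (POT, DMSO7/8, GEF1-3, TRM4-6) and
#' re-extracts merged barcode censuses from them, infers growth rates and
#' phenotypes, and compares the result with the generator truth.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, the report is written as
#'   `report.json` and the growth table as `growth.tsv`.
#' @return A list of class `steering_report`: `records` (growth table),
#'   `confusion` (truth-by-inferred phenotype table over barcodes with
#'   baseline frequency at least `min_f0`), `phenotype_recovery` (fraction
#'   of those barcodes whose inferred phenotype matches the planted one),
#'   `rate_rmse` (RMSE of finite per-replicate growth rates against the
#'   planted clone rates, per week), `proportions`, `pooled_resistant_pot`
#'   (pooled POT frequency of planted resistant barcodes), and `log`
#'   (parameters and seeds used).
#' @export
run_synthetic_end_to_end <- function(config = run_config(),
                                     out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- .stage_seeds(config$seed, 3L)
  spec <- generate_population_spec(n_lineages = config$n_lineages)
  design <- experiment_design(sampling_depth = config$sampling_depth,
                              gef_weeks = config$gef_weeks,
                              trm_weeks = config$trm_weeks)
  dataset <- simulate_experiment(spec, design, seed = seeds[1])

  core <- c("POT", "DMSO7", "DMSO8",
            paste0("GEF", seq_len(design$n_gef)),
            paste0("TRM", design$n_gef + seq_len(design$n_trm)))
  censuses <- dataset$censuses
  if (config$emit_reads) {
    set.seed(seeds[2])
    fastq_dir <- tempfile("evosteer_fastq_")
    dir.create(fastq_dir)
    on.exit(unlink(fastq_dir, recursive = TRUE), add = TRUE)
    for (nm in core) {
      cen <- censuses[[nm]]
      tf <- attr(cen, "true_frequencies")
      if (!is.null(tf)) cen$frequencies <- tf
      fq <- file.path(fastq_dir, paste0(nm, ".fastq"))
      emit_barcode_reads(cen, fq, depth = config$sampling_depth,
                         error_rate = config$error_rate,
                         fail_q_fraction = config$fail_q_fraction,
                         flank_fwd = spec$flank_fwd,
                         flank_rev = spec$flank_rev)
      raw <- read_and_filter_fastq(fq, min_q = config$min_q,
                                   flank_fwd = spec$flank_fwd,
                                   flank_rev = spec$flank_rev,
                                   barcode_length = spec$barcode_length)
      merged <- merge_barcodes(raw, max_hamming = config$max_hamming,
                               pattern = spec$ws_pattern)
      censuses[[nm]] <- barcode_census(
        c(merged), cen$sample_id, cen$condition, cen$timepoint,
        cen$compartment)
    }
  }

  records <- infer_growth(censuses, gef_weeks = config$gef_weeks,
                          trm_weeks = config$trm_weeks)
  truth <- dataset$truth
  m <- match(records$barcode, truth$barcode)
  known <- !is.na(m) & !is.na(records$f0) & records$f0 >= config$min_f0
  confusion <- table(truth = truth$phenotype[m[known]],
                     inferred = records$phenotype[known])
  recovery <- mean(truth$phenotype[m[known]] == records$phenotype[known])

  arms <- attr(records, "arms")
  rcols <- grep("^r_", names(records), value = TRUE)
  errs <- numeric(0)
  for (j in seq_along(rcols)) {
    r_true <- if (arms[j] == "GEF") truth$r_gef[m] else truth$r_trm[m]
    r_hat <- records[[rcols[j]]]
    ok <- known & is.finite(r_hat) & !is.na(r_true)
    errs <- c(errs, r_hat[ok] - r_true[ok])
  }
  rate_rmse <- sqrt(mean(errs^2))

  props <- phenotype_proportions(records, censuses["POT"])
  resistant <- truth$phenotype %in% c("GEF_RESISTANT", "DOUBLE_RESISTANT",
                                      "TRM_RESISTANT")
  pooled_resistant_pot <- sum(truth$pot_frequency[resistant])

  report <- structure(list(
    records = records, confusion = confusion,
    phenotype_recovery = recovery, rate_rmse = rate_rmse,
    proportions = props$proportions,
    pooled_resistant_pot = pooled_resistant_pot,
    dataset = dataset,
    log = list(config = unclass(config), stage_seeds = seeds,
               n_barcodes_scored = sum(known))),
    class = "steering_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(phenotype_recovery = recovery, rate_rmse = rate_rmse,
           proportions = as.list(report$proportions),
           pooled_resistant_pot = pooled_resistant_pot,
           log = report$log),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    write.table(records, file.path(out_dir, "growth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  report
}

#' @export
print.steering_report <- function(x, ...) {
  cat("Synthetic end-to-end steering report\n")
  cat(sprintf("  barcodes scored (f0 >= %g): %d\n",
              x$log$config$min_f0, x$log$n_barcodes_scored))
  cat(sprintf("  phenotype recovery: %.1f%%\n", 100 * x$phenotype_recovery))
  cat(sprintf("  growth-rate RMSE: %.4f per week\n", x$rate_rmse))
  cat(sprintf("  pooled resistant POT frequency: %.4f\n",
              x$pooled_resistant_pot))
  invisible(x)
}

#' Run the stochastic simulation suite
#'
#' Produces the waiting-time distribution of the re-plating model and the
#' replicate-occupancy distribution of the POT outgrowth and split model,
#' with Monte Carlo standard errors and the analytic occupancy oracle.
#'
#' @param config A [run_config()]; `config$sim` entries override
#'   [sim_design()] defaults.
#' @param out_dir Optional directory for TSV outputs (`waiting_times.tsv`,
#'   `occupancy.tsv`).
#' @return List with `waiting_times` (per-simulation table),
#'   `waiting_summary` (fraction of first mutations in cycle 1, mean
#'   cycle), `occupancy` (table of k, empirical fraction, analytic exact
#'   fraction, standard error) and `design`.
#' @export
run_simulation_suite <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- .stage_seeds(config$seed, 2L)
  design <- do.call(sim_design, config$sim)
  wt <- simulate_replating_waiting_times(design, seed = seeds[1])
  obs <- wt$cycle[!wt$censored]
  waiting_summary <- list(
    n_sims = nrow(wt),
    frac_cycle1 = mean(wt$cycle == 1, na.rm = TRUE),
    mean_cycle = mean(obs),
    frac_censored = mean(wt$censored))
  occ <- simulate_pot_split(design, seed = seeds[2])
  occupancy <- data.frame(k = as.integer(names(occ$occupancy)),
                          empirical = as.numeric(occ$occupancy),
                          exact = as.numeric(occ$exact),
                          se = as.numeric(occ$se))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(wt, file.path(out_dir, "waiting_times.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(occupancy, file.path(out_dir, "occupancy.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(waiting_times = wt, waiting_summary = waiting_summary,
       occupancy = occupancy, occupancy_result = occ, design = design)
}
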