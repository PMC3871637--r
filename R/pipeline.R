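# End-to-end orchestration: simulate -> filter -> calibrate -> assign ->
# tally -> fit -> classify, with per-stage seeds derived from one master
# seed and an optional TSV output directory.

stage_seed <- function(seed, k) (as.integer(seed) * 131L + k * 7919L) %% 2147483647L

#' Run the full selection-analysis pipeline
#'
#' Executes every stage on a simulated (or supplied) experiment: grain QC,
#' allele-frequency estimation, Delta-threshold calibration, paternity
#' assignment, success tallies with the combined statistic W, one
#' hierarchical Bayesian Poisson fit per success measure, and selection-mode
#' classification. All stage seeds derive deterministically from
#' \code{seed}, so identical inputs give identical outputs.
#'
#' @param config a \code{\link{simulation_config}} (ignored when \code{exp}
#'   is supplied).
#' @param exp optionally, an existing \code{pollen_experiment} (user data);
#'   skips the simulation stage.
#' @param seed master integer seed.
#' @param policy grain QC \code{\link{filter_policy}}.
#' @param calib Delta \code{\link{calibration_config}}.
#' @param schedule MCMC \code{\link{mcmc_schedule}}.
#' @param measures success measures to fit.
#' @param w_mode combined-success mode (\code{"observed_ratio"} or
#'   \code{"unity"}).
#' @param out_dir optional directory; when given, every stage writes its TSV
#'   output there.
#' @return list of class \code{pollensel_run}: experiment, qc, freqs,
#'   thresholds, assignments, success records and summary, fits (one
#'   \code{selfit} per measure), diagnostics (R-hat per parameter per
#'   measure), classification, summary grid, and a manifest (stage seeds and
#'   timings).
#' @export
run_pipeline <- function(config = simulation_config(), exp = NULL,
                         seed = 1L, policy = filter_policy(),
                         calib = calibration_config(cycles = 2000L),
                         schedule = reduced_schedule(),
                         measures = c("visits", "acquisition", "donation",
                                      "combined"),
                         w_mode = "observed_ratio", out_dir = NULL) {
  manifest <- list(seed = seed, stages = list())
  tick <- function(name, seed_used, t0) {
    manifest$stages[[name]] <<- list(seed = seed_used,
                                     secs = round(as.numeric(Sys.time()) - t0,
                                                  2))
  }
  t0 <- as.numeric(Sys.time())
  if (is.null(exp)) {
    exp <- simulate_experiment(config, seed = stage_seed(seed, 1L))
    tick("simulate", stage_seed(seed, 1L), t0)
  }
  pollinator <- unique(exp$bouts$pollinator)

  t0 <- as.numeric(Sys.time())
  fl <- filter_grains(exp, policy, seed = stage_seed(seed, 2L))
  tick("filter", stage_seed(seed, 2L), t0)

  t0 <- as.numeric(Sys.time())
  freqs <- estimate_allele_frequencies(exp)
  thresholds <- calibrate_delta(freqs, calib, seed = stage_seed(seed, 3L))
  tick("calibrate", stage_seed(seed, 3L), t0)

  t0 <- as.numeric(Sys.time())
  assignments <- assign_paternity(exp, fl$kept, freqs, thresholds,
                                  e = calib$error)
  tick("assign", stage_seed(seed, 4L), t0)

  t0 <- as.numeric(Sys.time())
  records <- tally_success(assignments, exp)
  cs <- combined_success(records, mode = w_mode)
  tick("tally", NA, t0)

  fits <- list(); diags <- list(); cls <- list()
  for (m in measures) {
    t0 <- as.numeric(Sys.time())
    des <- build_design(cs$records, exp$plants,
                        model_spec(m, pollinator[1]))
    fits[[m]] <- fit_selection_model(des, schedule,
                                     seed = stage_seed(seed, 10L) )
    dg <- compute_rhat(fits[[m]])
    dg$measure <- m
    diags[[m]] <- dg
    cls[[m]] <- classify_selection(fits[[m]])
    tick(paste0("fit_", m), stage_seed(seed, 10L), t0)
  }
  classification <- do.call(rbind, cls)
  run <- structure(list(
    exp = exp, qc = fl$qc, kept = fl$kept, freqs = freqs,
    thresholds = thresholds, assignments = assignments,
    success = cs$records, success_summary = cs$summary, fits = fits,
    diagnostics = do.call(rbind, diags), classification = classification,
    grid = if (length(cls)) summarize_selection(classification) else NULL,
    manifest = manifest), class = "pollensel_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_experiment(run$exp, out_dir)
  wt <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE, na = "")
  wt(run$qc, "qc_report.tsv")
  k <- run$kept
  k$alleles <- vapply(k$alleles, paste, "", collapse = ";")
  wt(k, "kept.tsv")
  wt(run$assignments, "assignments.tsv")
  wt(run$thresholds$summary, "calibration.tsv")
  wt(run$success, "success.tsv")
  if (!is.null(run$diagnostics)) wt(run$diagnostics, "diagnostics.tsv")
  if (!is.null(run$classification))
    wt(run$classification, "classification.tsv")
  if (!is.null(run$grid)) wt(run$grid, "summary_grid.tsv")
  writeLines(make_report(run), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.pollensel_run <- function(x, ...) {
  cat(make_report(x), sep = "\n")
  invisible(x)
}

#' Human-readable run report
#'
#' QC counts, assignment rates, convergence flags and the trait-by-measure
#' selection-mode grid of a pipeline run.
#'
#' @param run a \code{pollensel_run}.
#' @return character vector of report lines.
#' @export
make_report <- function(run) {
  lines <- c("Pollination selection analysis", strrep("=", 30))
  lines <- c(lines, sprintf("Grains: %d raw, %d kept after QC (%d capped, %d multi-allele, %d under-typed)",
    sum(run$qc$n_raw), sum(run$qc$n_kept), sum(run$qc$n_capped),
    sum(run$qc$n_multiallelic), sum(run$qc$n_below_threshold)))
  tab <- table(run$assignments$category)
  lines <- c(lines, paste("Assignment:",
    paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", ")))
  ss <- run$success_summary
  lines <- c(lines, sprintf("Success ratio Ave.X/Ave.Y (%s): %.3f",
                            ss$pollinator[1], ss$ratio[1]))
  bad <- NULL
  if (!is.null(run$diagnostics)) {
    bad <- run$diagnostics[!run$diagnostics$pass, , drop = FALSE]
    lines <- c(lines, sprintf("Convergence: max R-hat %.3f (%s)",
                              max(run$diagnostics$rhat),
                              if (nrow(bad)) "FAILED for some parameters"
                              else "all parameters < 1.1"))
  }
  if (!is.null(run$grid)) {
    lines <- c(lines, "", "Selection modes (trait x measure):")
    lines <- c(lines, utils::capture.output(print(run$grid,
                                                  row.names = FALSE)))
    if (!is.null(bad) && nrow(bad))
      lines <- c(lines, sprintf(
        "NOTE: measures with unconverged parameters: %s -- labels there are not reliable",
        paste(unique(bad$measure), collapse = ", ")))
  }
  lines
}
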