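#' Study configuration
#'
#' One object describing an end-to-end run: where the recordings come from
#' (a synthetic study or a manifest of files on disk), how they are
#' preprocessed, the rejection criteria, the spectral grid, the fit range
#' for the aperiodic exponent, and the statistics to run.
#'
#' @param synthesis a [synthesis_config()], or NULL when reading files.
#' @param manifest data.frame with columns `file`, `group` (and optionally
#'   `fs`, `id`) describing recordings on disk; ignored when `synthesis`
#'   is given.
#' @param preprocess a [preprocess_config()].
#' @param criteria a [rejection_criteria()].
#' @param grid a [build_frequency_grid()] (built at run time from the
#'   recording rate when NULL).
#' @param fit_range frequency range for the aperiodic fit, Hz; NULL fits
#'   over the whole grid.
#' @param stats a [stats_config()].
#' @param comparisons list of `c(group_a, group_b)` pairs; NULL compares
#'   all pairs of groups present.
#' @param output_dir directory for CSV/JSON outputs (nothing written when
#'   NULL).
#' @param verbose log per-dataset progress.
#' @return object of class `"study_config"`.
#' @export
study_config <- function(synthesis = NULL, manifest = NULL,
                         preprocess = preprocess_config(),
                         criteria = rejection_criteria(),
                         grid = NULL, fit_range = NULL,
                         stats = stats_config(), comparisons = NULL,
                         output_dir = NULL, verbose = FALSE) {
  if (is.null(synthesis) && is.null(manifest))
    stop_planeeg("provide either a synthesis config or a file manifest")
  if (!is.null(manifest) && !all(c("file", "group") %in% names(manifest)))
    stop_planeeg("manifest needs 'file' and 'group' columns")
  structure(list(synthesis = synthesis, manifest = manifest,
                 preprocess = preprocess, criteria = criteria, grid = grid,
                 fit_range = fit_range, stats = stats,
                 comparisons = comparisons, output_dir = output_dir,
                 verbose = isTRUE(verbose)),
            class = "study_config")
}

#' Run the full characterization pipeline
#'
#' For every recording: band-limit (zero-phase FIR), trim and epoch, reject
#' artifactual epochs/channels, and - if the dataset survives the retention
#' rule - estimate the multitaper spectrum on the log-spaced grid and fit
#' the aperiodic exponent. Then, for every configured group pair, run the
#' per-frequency permutation test with FDR flags and the Welch t-test on
#' exponents. With an `output_dir`, writes `spectra.csv`, `exponents.csv`,
#' one `comparison_<A>_vs_<B>.csv` per pair, and a machine-readable
#' `summary.json` (group exponent means/SDs, surviving counts, seeds); the
#' JSON carries no timestamps, so identical configurations yield
#' byte-identical summaries.
#'
#' @param config a [study_config()].
#' @return object of class `"study_report"`: `datasets` (per-dataset
#'   data.frame: id, group, retained, surviving epochs/channels, exponent,
#'   offset, r_squared), `spectra` (a `"spectrum_set"` of retained
#'   datasets), `comparisons` (named list of `"group_comparison"`),
#'   `summary` (the list written as summary.json), `config`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))

  ## ---- inputs ----
  if (!is.null(config$synthesis)) {
    say("simulating study (seed %d)", config$synthesis$seed)
    study <- simulate_group_study(config$synthesis)
    recs <- study$recordings
    ids <- study$manifest$id
    groups <- study$manifest$group
    seeds <- study$manifest$seed
  } else {
    man <- config$manifest
    ids <- if ("id" %in% names(man)) man$id else
      tools::file_path_sans_ext(basename(man$file))
    groups <- man$group
    seeds <- rep(NA_integer_, nrow(man))
    recs <- lapply(seq_len(nrow(man)), function(i) {
      fs_i <- if ("fs" %in% names(man)) man$fs[i] else NULL
      tryCatch(
        read_recording(man$file[i], group = man$group[i], fs = fs_i),
        error = function(e) stop_planeeg(
          sprintf("stage io, dataset %s: %s", ids[i], conditionMessage(e))))
    })
    names(recs) <- ids
  }

  fs <- recs[[1]]$fs
  grid <- config$grid
  if (is.null(grid))
    grid <- build_frequency_grid(epoch_length = config$preprocess$epoch_length,
                                 fs = fs)

  ## ---- per-dataset stages ----
  stage <- function(name, id, expr) {
    tryCatch(expr, error = function(e) stop_planeeg(
      sprintf("stage %s, dataset %s: %s", name, id, conditionMessage(e))))
  }
  n_data <- length(recs)
  datasets <- data.frame(id = ids, group = groups, retained = FALSE,
                         n_epochs_surviving = 0L, n_channels_surviving = 0L,
                         exponent = NA_real_, offset = NA_real_,
                         r_squared = NA_real_)
  power_rows <- list()
  for (i in seq_len(n_data)) {
    t0 <- proc.time()[3]
    ep <- stage("preprocess", ids[i],
                preprocess_recording(recs[[i]], config$preprocess))
    rep_i <- stage("artifacts", ids[i], autoreject(ep, config$criteria))
    datasets$retained[i] <- rep_i$retained
    datasets$n_epochs_surviving[i] <- rep_i$n_epochs_surviving
    datasets$n_channels_surviving[i] <- rep_i$n_channels_surviving
    if (rep_i$retained) {
      clean <- stage("artifacts", ids[i], drop_rejected(ep, rep_i))
      psd <- stage("spectral", ids[i], multitaper_psd(clean, grid))
      fit <- stage("spectral", ids[i],
                   fit_aperiodic(psd, fit_range = config$fit_range))
      datasets$exponent[i] <- fit$exponent
      datasets$offset[i] <- fit$offset
      datasets$r_squared[i] <- fit$r_squared
      power_rows[[ids[i]]] <- psd$power
    }
    say("dataset %s [%s]: retained=%s exponent=%.3f (%.2f s)",
        ids[i], groups[i], datasets$retained[i], datasets$exponent[i],
        proc.time()[3] - t0)
  }
  if (length(power_rows) == 0)
    stop_planeeg("stage artifacts: no dataset survived rejection")
  kept <- datasets$retained
  spectra <- spectrum_set(do.call(rbind, power_rows), grid,
                          labels = datasets$group[kept],
                          ids = datasets$id[kept])

  ## ---- comparisons ----
  comparisons <- config$comparisons
  grp_levels <- unique(datasets$group)
  if (is.null(comparisons) && length(grp_levels) >= 2)
    comparisons <- utils::combn(grp_levels, 2, simplify = FALSE)
  for (cmp in comparisons) {
    if (!all(cmp %in% grp_levels))
      stop_planeeg("comparison references unknown group: ",
                   paste(cmp, collapse = " vs "))
  }
  cmp_results <- list()
  for (cmp in comparisons) {
    sel_a <- spectra$labels == cmp[1]; sel_b <- spectra$labels == cmp[2]
    nm <- paste0(cmp[1], "_vs_", cmp[2])
    say("comparison %s", nm)
    cmp_results[[nm]] <- stage("stats", nm, compare_groups(
      spectra$power[sel_a, , drop = FALSE],
      spectra$power[sel_b, , drop = FALSE],
      datasets$exponent[kept][sel_a], datasets$exponent[kept][sel_b],
      config$stats))
    cmp_results[[nm]]$table <- cbind(freq = grid$centers,
                                     cmp_results[[nm]]$table)
  }

  ## ---- summary ----
  by_group <- lapply(split(datasets[kept, ], datasets$group[kept]),
                     function(dd) list(
                       n_surviving = nrow(dd),
                       exponent_mean = mean(dd$exponent),
                       exponent_sd = if (nrow(dd) > 1) stats::sd(dd$exponent)
                                     else NA_real_))
  summary <- list(
    n_datasets = n_data,
    n_surviving = sum(kept),
    groups = by_group,
    grid = list(fmin = grid$fmin, fmax = grid$fmax,
                nsteps = length(grid$centers), pad_length = grid$pad_length),
    seeds = list(synthesis = if (!is.null(config$synthesis))
                   config$synthesis$seed else NULL,
                 dataset = as.list(stats::setNames(seeds, ids)),
                 stats = config$stats$seed))

  ## ---- outputs ----
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    od <- config$output_dir
    utils::write.csv(data.frame(id = spectra$ids, group = spectra$labels,
                                spectra$power, check.names = FALSE),
                     file.path(od, "spectra.csv"), row.names = FALSE)
    utils::write.csv(datasets, file.path(od, "exponents.csv"),
                     row.names = FALSE)
    for (nm in names(cmp_results))
      utils::write.csv(cmp_results[[nm]]$table,
                       file.path(od, paste0("comparison_", nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(summary, file.path(od, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(datasets = datasets, spectra = spectra,
                 comparisons = cmp_results, summary = summary,
                 config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d dataset(s), %d retained\n",
              x$summary$n_datasets, x$summary$n_surviving))
  for (g in names(x$summary$groups)) {
    gg <- x$summary$groups[[g]]
    cat(sprintf("  %-12s n = %2d  exponent %.2f (SD %.2f)\n", g,
                gg$n_surviving, gg$exponent_mean, gg$exponent_sd))
  }
  for (nm in names(x$comparisons)) {
    tab <- x$comparisons[[nm]]$table
    cat(sprintf("  %s: %d/%d frequencies significant\n", nm,
                sum(tab$significant), nrow(tab)))
  }
  invisible(x)
}
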