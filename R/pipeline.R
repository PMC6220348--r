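vmr_log <- function(level, ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
}

#' Read a run configuration file
#'
#' Flat key-value text file (YAML syntax, one scalar per key). All keys of
#' [default_config()] are accepted, plus `seed` and `out_dir`. Unknown keys
#' are rejected with a clear message; numeric fields are validated on load.
#'
#' @param path path to the config file.
#' @return List with elements `config` (a validated [default_config()] list),
#'   `seed` (or `NULL`) and `out_dir` (or `NULL`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must be a key-value mapping", call. = FALSE)
  seed <- raw$seed
  out_dir <- raw$out_dir
  raw$seed <- NULL
  raw$out_dir <- NULL
  list(config = do.call(default_config, raw), seed = seed, out_dir = out_dir)
}

config_hash <- function(config, seed) {
  keys <- sort(names(config))
  canon <- paste0(keys, "=", vapply(config[keys], format, character(1)),
                  collapse = ";")
  fnv1a32(paste0("seed=", seed, ";", canon))
}

write_manifest <- function(out_dir, seed, config, files) {
  hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(hashes) <- files
  manifest <- list(seed = seed,
                   config = config,
                   config_hash = config_hash(config, seed),
                   files = hashes)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate a cohort and write its trial tables
#'
#' Runs [simulate_cohort()] and writes `trial_table.csv`, `traits.csv`,
#' optionally `trajectories.csv`, and a `manifest.json` recording the seed,
#' the full configuration, a config hash and md5 sums of every output —
#' a fixed seed and config reproduce the outputs byte for byte.
#'
#' @param config a [default_config()] list.
#' @param seed master integer seed.
#' @param out_dir output directory (created if needed).
#' @param keep_trajectories also write the long trajectory table?
#' @return Invisibly, the paths of the written files.
#' @export
run_simulate <- function(config = default_config(), seed = 1,
                         out_dir = "results/simulation",
                         keep_trajectories = FALSE) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vmr_log("INFO", "simulating cohort: ", 4 * config$n_per_condition,
          " participants, seed ", seed)
  tab <- simulate_cohort(config$n_per_condition, config, seed,
                         keep_trajectories = keep_trajectories)
  files <- "trial_table.csv"
  write_trial_table(tab, file.path(out_dir, "trial_table.csv"))
  readr::write_csv(attr(tab, "traits"), file.path(out_dir, "traits.csv"))
  files <- c(files, "traits.csv")
  if (keep_trajectories) {
    readr::write_csv(attr(tab, "trajectories"),
                     file.path(out_dir, "trajectories.csv"))
    files <- c(files, "trajectories.csv")
  }
  write_manifest(out_dir, seed, config, files)
  vmr_log("INFO", "wrote ", length(files), " file(s) + manifest to ", out_dir)
  invisible(file.path(out_dir, c(files, "manifest.json")))
}

#' Analyze a trial table and write result tables
#'
#' Runs the full statistical pipeline on a tidy trial table (from
#' [run_simulate()] or externally supplied in the same schema): per-participant
#' block-window summaries, one-way ANOVAs with Tukey post-hoc on each window,
#' per-condition exponential fits with participant bootstrap for the
#' adaptation and washout blocks, and the end-of-adaptation vs washout
#' correlations. The familiarization block is excluded from all analyses.
#'
#' If the table has no washout block, the washout-dependent stages
#' (washout window, washout fits, correlations) are skipped with a warning.
#'
#' @param table a trial table or a path to its CSV.
#' @param config a [default_config()] list (`n_boot` controls the bootstrap).
#' @param seed integer seed for the bootstrap resampling.
#' @param out_dir output directory.
#' @return Invisibly, a list with the computed objects (`summaries`, `anova`,
#'   `fits`, `correlations`).
#' @export
run_analyze <- function(table, config = default_config(), seed = 1,
                        out_dir = "results/analysis") {
  config <- validate_config(config)
  if (is.character(table)) table <- read_trial_table(table)
  missing <- setdiff(trial_table_cols, names(table))
  if (length(missing))
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- add_errors(dplyr::filter(table, .data$block != "familiarization"))
  has_washout <- "washout" %in% tab$block
  if (!has_washout)
    vmr_log("WARN", "no washout block: washout fits and correlations skipped")

  # per-participant windows
  if (has_washout) {
    summaries <- block_summary(tab)
  } else {
    summaries <- tab |>
      dplyr::filter(.data$block == "adaptation") |>
      dplyr::arrange(.data$participant, .data$trial) |>
      dplyr::group_by(.data$participant, .data$condition) |>
      dplyr::summarise(adapt_mid10 = window_mean(.data$error, "middle"),
                       adapt_last10 = window_mean(.data$error, "last"),
                       .groups = "drop")
  }
  readr::write_csv(summaries, file.path(out_dir, "block_summaries.csv"))
  files <- "block_summaries.csv"

  # group tests
  windows <- c("adapt_mid10", "adapt_last10",
               if (has_washout) "washout_first10")
  multi_cond <- length(unique(summaries$condition)) >= 2L
  if (multi_cond) {
    anova_rows <- list(); tukey_rows <- list()
    for (w in windows) {
      res <- condition_anova(summaries, w)
      anova_rows[[w]] <- tibble::tibble(window = w, F = res$F,
                                        df1 = res$df[1], df2 = res$df[2],
                                        p = res$p)
      tukey_rows[[w]] <- tibble::add_column(res$tukey, window = w, .before = 1)
    }
    anova_tab <- dplyr::bind_rows(anova_rows)
    readr::write_csv(anova_tab, file.path(out_dir, "anova.csv"))
    readr::write_csv(dplyr::bind_rows(tukey_rows),
                     file.path(out_dir, "tukey.csv"))
    files <- c(files, "anova.csv", "tukey.csv")
  } else {
    anova_tab <- NULL
    vmr_log("WARN", "single condition: ANOVA skipped")
  }

  # exponential fits with participant bootstrap, per condition and block
  fit_rows <- list()
  boots <- list()
  for (cond in sort(unique(tab$condition))) {
    sub <- dplyr::filter(tab, .data$condition == cond)
    for (blk in c("adaptation", if (has_washout) "washout")) {
      bt <- bootstrap_fit(sub, block = blk, n_resamples = config$n_boot,
                          seed = child_seed(seed, cond,
                                            match(blk, c("adaptation", "washout"))))
      boots[[paste(cond, blk, sep = "_")]] <- bt
      ci <- bt$ci
      fit_rows[[paste(cond, blk)]] <- tibble::tibble(
        condition = cond, block = blk,
        A = bt$point[["A"]], A_lo = ci$lower[ci$param == "A"],
        A_hi = ci$upper[ci$param == "A"],
        tau = bt$point[["tau"]], tau_lo = ci$lower[ci$param == "tau"],
        tau_hi = ci$upper[ci$param == "tau"],
        r2 = bt$point[["r2"]], r2_lo = ci$lower[ci$param == "r2"],
        r2_hi = ci$upper[ci$param == "r2"],
        n_resamples = bt$n_resamples)
    }
  }
  fits <- dplyr::bind_rows(fit_rows)
  readr::write_csv(fits, file.path(out_dir, "fits.csv"))
  files <- c(files, "fits.csv")

  correlations <- NULL
  if (has_washout && all(table(summaries$condition) >= 3L)) {
    correlations <- adaptation_washout_correlation(summaries)
    readr::write_csv(correlations, file.path(out_dir, "correlations.csv"))
    files <- c(files, "correlations.csv")
  }

  write_manifest(out_dir, seed, config, files)
  vmr_log("INFO", "wrote ", length(files), " result file(s) + manifest to ",
          out_dir)
  invisible(list(summaries = summaries, anova = anova_tab, fits = fits,
                 correlations = correlations, bootstraps = boots))
}

#' Render a human-readable summary of an analysis directory
#'
#' Reads the result tables written by [run_analyze()] and prints per-condition
#' fit parameters with confidence intervals, the ANOVA/Tukey outcomes and the
#' correlations; also writes `report.txt`. Missing optional tables produce a
#' partial report with warnings; an empty directory is an error.
#'
#' @param results_dir directory written by [run_analyze()].
#' @param quiet suppress console output?
#' @return The report lines, invisibly.
#' @export
run_report <- function(results_dir, quiet = FALSE) {
  fits_path <- file.path(results_dir, "fits.csv")
  if (!dir.exists(results_dir) || !file.exists(fits_path))
    stop("no analysis results found in `", results_dir, "`", call. = FALSE)
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))

  fits <- readr::read_csv(fits_path, show_col_types = FALSE, progress = FALSE)
  add("Exponential fits Err(t) = A exp(-t/tau) per condition and block")
  add("%-10s %-11s %20s %22s %6s", "condition", "block",
      "A [95% CI] (deg)", "tau [95% CI] (trials)", "R2")
  for (i in seq_len(nrow(fits))) {
    f <- fits[i, ]
    add("%-10d %-11s %6.1f [%6.1f,%6.1f] %7.1f [%6.1f,%6.1f] %6.2f",
        f$condition, f$block, f$A, f$A_lo, f$A_hi, f$tau, f$tau_lo, f$tau_hi,
        f$r2)
  }

  anova_path <- file.path(results_dir, "anova.csv")
  if (file.exists(anova_path)) {
    an <- readr::read_csv(anova_path, show_col_types = FALSE, progress = FALSE)
    add("")
    add("One-way ANOVAs on block-window means across conditions")
    for (i in seq_len(nrow(an)))
      add("  %-16s F(%d, %d) = %.2f, p = %.2g", an$window[i], an$df1[i],
          an$df2[i], an$F[i], an$p[i])
  } else {
    warning("anova.csv missing; partial report", call. = FALSE)
  }

  cor_path <- file.path(results_dir, "correlations.csv")
  if (file.exists(cor_path)) {
    co <- readr::read_csv(cor_path, show_col_types = FALSE, progress = FALSE)
    add("")
    add("End-of-adaptation vs washout correlation per condition")
    for (i in seq_len(nrow(co)))
      add("  condition %d: r = %+.2f, p = %.2g (n = %d)", co$condition[i],
          co$r[i], co$p[i], co$n[i])
  } else {
    warning("correlations.csv missing; partial report", call. = FALSE)
  }

  writeLines(lines, file.path(results_dir, "report.txt"))
  if (!quiet) cat(lines, sep = "\n")
  invisible(lines)
}
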