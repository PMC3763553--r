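#' Correlation between per-condition rate summaries
#'
#' Pairs two labeled value sets by shared condition labels and returns the
#' squared Pearson correlation with the least-squares line — the standard
#' "correlation plot with R^2" summary. R^2 is symmetric in the arguments;
#' slope and intercept are for `y ~ x`.
#'
#' @param x,y named numeric vectors (names are condition labels).
#' @param weights optional named weights for a weighted fit (default
#'   unweighted).
#' @return list of class `correlation_result`: `labels`, `n`, `r_squared`,
#'   `slope`, `intercept`, `degenerate` (TRUE when n = 2, a perfect fit by
#'   construction).
#' @export
correlate_rates <- function(x, y, weights = NULL) {
  if (is.null(names(x)) || is.null(names(y)))
    stop("x and y must be named by condition label")
  shared <- intersect(names(x), names(y))
  if (length(shared) < 2)
    stop("need >= 2 shared condition labels, got ", length(shared))
  xv <- as.numeric(x[shared]); yv <- as.numeric(y[shared])
  w <- if (is.null(weights)) NULL else as.numeric(weights[shared])
  fit <- if (is.null(w)) lm(yv ~ xv) else lm(yv ~ xv, weights = w)
  r2 <- cor(xv, yv)^2
  degenerate <- length(shared) == 2
  if (degenerate)
    warning("only 2 shared conditions: R^2 = 1 by construction")
  structure(list(labels = shared, n = length(shared), r_squared = r2,
                 slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 degenerate = degenerate),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result> n = ", x$n, "; R^2 = ", round(x$r_squared, 3),
      "; y = ", signif(x$slope, 3), " x + ", signif(x$intercept, 3), "\n",
      sep = "")
  invisible(x)
}

#' Default pipeline configuration
#'
#' A complete demo configuration: five tri-nucleotide repeat conditions for
#' 5'-end monomer dynamics whose planted `k_off` is proportional to the
#' shipped synthetic ATPase table (so the dissociation-vs-ATPase correlation
#' is recoverable), plus six nucleation conditions whose planted nucleation
#' frequency rises with the nucleated-cluster lifetime. All condition tables
#' are ordinary data.frames and can be edited or read from CSV/JSON.
#'
#' @param seed master seed.
#' @param n_traces,duration per-condition trace count and length (s) for the
#'   end-dynamics arm.
#' @param n_traces_nuc,duration_nuc same for the nucleation arm.
#' @param k_off_per_atpase proportionality constant planting
#'   `k_off = k_off_per_atpase * atpase_rate`.
#' @return nested list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1, n_traces = 30, duration = 100,
                                    n_traces_nuc = 40, duration_nuc = 150,
                                    k_off_per_atpase = 0.02) {
  atpase <- read.csv(system.file("extdata", "atpase_rates_synthetic.csv",
                                 package = "refret"))
  end_conditions <- data.frame(
    label = atpase$label,
    k_on = c(0.22, 0.18, 0.20, 0.24, 0.19),
    k_off = k_off_per_atpase * atpase$atpase_rate,
    reca_uM = 1,
    atpase_rate = atpase$atpase_rate
  )
  ## nucleated-cluster lifetimes (s) and frequencies: sequences with longer
  ## lifetimes also nucleate more often
  nuc_tau <- c(TCA = 20, CCA = 30, TTT = 8, TTG = 15, Chi = 12, twoChi = 12)
  nuc_conditions <- data.frame(
    label = names(nuc_tau),
    k_nuc = 0.004 + 0.0004 * nuc_tau,
    k_dis = 1 / nuc_tau
  )
  list(
    seed = as.integer(seed),
    end_dynamics = list(
      conditions = end_conditions,
      n_traces = n_traces, duration = duration, frame_time = 0.1,
      total_intensity = 500, noise_sd = 25, bleach_rate = 0.005,
      donor_only_fraction = 0.1
    ),
    nucleation = list(
      conditions = nuc_conditions,
      n_traces = n_traces_nuc, duration = duration_nuc, frame_time = 0.1,
      total_intensity = 500, noise_sd = 25, bleach_rate = 0.005,
      donor_only_fraction = 0
    ),
    histogram = list(bin_width = 0.02, n_components = 3),
    hmm = list(tol = 1e-6, max_iter = 100)
  )
}

analyse_end_condition <- function(cond, cfg, seed) {
  model <- build_end_dynamics_model(cond$k_on, cond$k_off, cond$reca_uM)
  em <- end_dynamics_emission(cfg$total_intensity, cfg$noise_sd,
                              cfg$bleach_rate)
  params <- simulation_params(model, em, reca_concentration = cond$reca_uM,
                              frame_time = cfg$frame_time,
                              n_molecules = cfg$n_traces,
                              trace_duration = cfg$duration, seed = seed,
                              donor_only_fraction = cfg$donor_only_fraction)
  traces <- simulate_experiment(params)
  frets <- lapply(lapply(traces, compute_fret), truncate_photobleach)
  frets <- Filter(function(f) length(f$E) >= 20, frets)
  hmm <- fit_hmm(frets, n_states = 3, init_means = c(0.3, 0.5, 0.7),
                 tol = cfg$tol %||% 1e-6, max_iter = cfg$max_iter %||% 100)
  ideals <- lapply(frets, function(f) idealize(hmm, f))
  rates <- estimate_rates(ideals, sequence_condition(cond$label, cond$reca_uM,
                                                     cond$atpase_rate))
  list(rates = rates, hmm = hmm,
       growth = growth_rate(rates, cond$reca_uM),
       n_traces_used = length(frets))
}

analyse_nucleation_condition <- function(cond, cfg, seed) {
  model <- build_nucleation_model(cond$k_nuc, cond$k_dis)
  em <- nucleation_emission(cfg$total_intensity, cfg$noise_sd,
                            cfg$bleach_rate)
  params <- simulation_params(model, em, frame_time = cfg$frame_time,
                              n_molecules = cfg$n_traces,
                              trace_duration = cfg$duration, seed = seed,
                              donor_only_fraction = cfg$donor_only_fraction,
                              initial_state = "unbound")
  traces <- simulate_experiment(params)
  frets <- lapply(lapply(traces, compute_fret), truncate_photobleach)
  frets <- Filter(function(f) length(f$E) >= 20, frets)
  hmm <- fit_hmm(frets, n_states = 2, init_means = c(0.2, 0.7),
                 tol = cfg$tol %||% 1e-6, max_iter = cfg$max_iter %||% 100)
  ideals <- lapply(frets, function(f) idealize(hmm, f))
  nucleation_kinetics(ideals, condition = cond$label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic-data analysis pipeline
#'
#' Executes simulate -> FRET -> photobleach truncation -> HMM idealization ->
#' kinetics -> correlations for every configured condition, and returns (and
#' optionally writes) a report with the per-condition lifetimes, nucleation
#' frequencies, binding/dissociation rates, growth rates and the
#' dissociation-vs-ATPase / binding-vs-dissociation / lifetime-vs-frequency
#' correlation summaries. Fully deterministic for a fixed config: every
#' condition gets a seed derived from `config$seed`.
#'
#' @param config a [default_pipeline_config()]-shaped list (or a path to a
#'   JSON file with the same structure).
#' @param out_dir optional output directory; when given, writes
#'   `report.json`, `rates.csv`, `nucleation.csv`, `summary.txt` and
#'   `manifest.json` (config echo, seeds, package version, file checksums).
#' @return list of class `pipeline_report`: `end_dynamics` (data.frame),
#'   `nucleation` (data.frame), `correlations` (list of
#'   [correlate_rates()] results), `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(is.list(config), !is.null(config$seed))
  n_end <- nrow(config$end_dynamics$conditions)
  n_nuc <- nrow(config$nucleation$conditions)
  seeds <- derive_seeds(config$seed, n_end + n_nuc)

  cfg_e <- config$end_dynamics
  cfg_e$tol <- config$hmm$tol; cfg_e$max_iter <- config$hmm$max_iter
  end_rows <- lapply(seq_len(n_end), function(i) {
    cond <- as.list(config$end_dynamics$conditions[i, ])
    res <- tryCatch(analyse_end_condition(cond, cfg_e, seeds[i]),
                    error = function(e) stop("end-dynamics stage failed for condition '",
                                             cond$label, "': ", conditionMessage(e)))
    r <- res$rates
    data.frame(label = cond$label, true_k_on = cond$k_on,
               true_k_off = cond$k_off, atpase_rate = cond$atpase_rate,
               reca_uM = cond$reca_uM, k_on = r$k_on,
               k_on_stderr = r$k_on_stderr, k_off = r$k_off,
               k_off_stderr = r$k_off_stderr, growth_rate = res$growth,
               n_bind = r$n_bind, n_dissoc = r$n_dissoc,
               n_traces_used = res$n_traces_used)
  })
  end_df <- do.call(rbind, end_rows)

  cfg_n <- config$nucleation
  cfg_n$tol <- config$hmm$tol; cfg_n$max_iter <- config$hmm$max_iter
  nuc_rows <- lapply(seq_len(n_nuc), function(i) {
    cond <- as.list(config$nucleation$conditions[i, ])
    st <- tryCatch(analyse_nucleation_condition(cond, cfg_n, seeds[n_end + i]),
                   error = function(e) stop("nucleation stage failed for condition '",
                                            cond$label, "': ", conditionMessage(e)))
    data.frame(label = cond$label, true_k_nuc = cond$k_nuc,
               true_k_dis = cond$k_dis, tau = st$tau,
               tau_stderr = st$tau_stderr, f_nuc = st$f_nuc,
               n_events = st$n_events, n_dwells = st$n_dwells,
               n_molecules = st$n_molecules)
  })
  nuc_df <- do.call(rbind, nuc_rows)

  named <- function(df, col) setNames(df[[col]], df$label)
  correlations <- list(
    k_off_vs_atpase = correlate_rates(named(end_df, "atpase_rate"),
                                      named(end_df, "k_off")),
    k_on_vs_k_off = correlate_rates(named(end_df, "k_off"),
                                    named(end_df, "k_on")),
    tau_vs_f_nuc = correlate_rates(named(nuc_df, "tau"),
                                   named(nuc_df, "f_nuc"))
  )

  manifest <- list(config = config, seeds = seeds,
                   package_version = as.character(packageVersion("refret")),
                   r_version = R.version.string,
                   timestamp = NA_character_, checksums = list())

  report <- structure(list(end_dynamics = end_df, nucleation = nuc_df,
                           correlations = correlations, manifest = manifest),
                      class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$end_dynamics$conditions <- as.data.frame(cfg$end_dynamics$conditions)
  cfg$nucleation$conditions <- as.data.frame(cfg$nucleation$conditions)
  cfg
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rates_csv <- file.path(out_dir, "rates.csv")
  nuc_csv <- file.path(out_dir, "nucleation.csv")
  report_json <- file.path(out_dir, "report.json")
  write.csv(report$end_dynamics, rates_csv, row.names = FALSE)
  write.csv(report$nucleation, nuc_csv, row.names = FALSE)
  jsonlite::write_json(
    list(end_dynamics = report$end_dynamics, nucleation = report$nucleation,
         correlations = lapply(report$correlations, unclass)),
    report_json, auto_unbox = TRUE, digits = NA, dataframe = "rows")

  txt <- file.path(out_dir, "summary.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  writeLines("refret pipeline report", con)
  writeLines("\n== 5'-end monomer dynamics ==", con)
  writeLines(capture_table(report$end_dynamics), con)
  writeLines("\n== nucleation ==", con)
  writeLines(capture_table(report$nucleation), con)
  writeLines("\n== correlations ==", con)
  for (nm in names(report$correlations)) {
    cr <- report$correlations[[nm]]
    writeLines(sprintf("%s: R^2 = %.3f (n = %d, slope = %.4g)", nm,
                       cr$r_squared, cr$n, cr$slope), con)
  }
  files <- c(rates_csv, nuc_csv, report_json, txt)
  report$manifest$checksums <- as.list(tools::md5sum(files))
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  invisible(out_dir)
}

capture_table <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 4)
  utils::capture.output(print(df, row.names = FALSE))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n== 5'-end monomer dynamics ==\n")
  writeLines(capture_table(x$end_dynamics))
  cat("\n== nucleation ==\n")
  writeLines(capture_table(x$nucleation))
  cat("\n== correlations ==\n")
  for (nm in names(x$correlations)) {
    cr <- x$correlations[[nm]]
    cat(sprintf("%s: R^2 = %.3f (n = %d)\n", nm, cr$r_squared, cr$n))
  }
  invisible(x)
}
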