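#' Read a uniformly sampled time series from CSV
#'
#' The interchange format for all traces is plain CSV with a header row and
#' a monotone time column. Sampling uniformity is validated and the
#' sampling rate reported.
#'
#' @param path CSV file path.
#' @param expected_columns Character vector of required column names; the
#'   first is the time column.
#' @param jitter_tol Maximum tolerated relative sampling-interval jitter.
#' @return List with one numeric vector per expected column plus `fs` (Hz).
#' @export
read_timeseries_csv <- function(path, expected_columns = c("t", "angle"),
                                jitter_tol = 1e-6) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  missing <- setdiff(expected_columns, names(df))
  if (length(missing))
    stop(sprintf("missing columns in %s: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  tcol <- df[[expected_columns[1]]]
  dt <- diff(tcol)
  if (any(dt <= 0))
    stop(sprintf("non-monotone time stamps in %s", path), call. = FALSE)
  if (max(abs(dt - mean(dt))) > jitter_tol * mean(dt))
    stop(sprintf("sampling jitter exceeds tolerance in %s", path), call. = FALSE)
  out <- lapply(df[expected_columns], as.numeric)
  out$fs <- 1 / mean(dt)
  out
}

#' Write a time series as CSV
#'
#' Columns are serialised with 9 significant digits so a written file reads
#' back to an equal series.
#'
#' @param path Output file path.
#' @param t Time stamps (s).
#' @param values Numeric vector, same length as `t`.
#' @param col_names Length-2 character: names for the time and value
#'   columns.
#' @return Invisibly, `path`.
#' @export
write_timeseries_csv <- function(path, t, values, col_names = c("t", "value")) {
  if (length(t) != length(values))
    stop("`t` and `values` must have equal length", call. = FALSE)
  df <- data.frame(signif(t, 9), signif(values, 9))
  names(df) <- col_names
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Known run_pipeline configuration keys and validation.
.pipeline_keys <- c("schema", "seed", "out_dir", "thresholds", "rom_deg",
                    "emg", "resistance")

validate_run_config <- function(config) {
  unknown <- setdiff(names(config), .pipeline_keys)
  if (length(unknown))
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) stop("config must set `out_dir`", call. = FALSE)
  if (is.null(config$schema)) config$schema <- "1"
  thr <- config$thresholds
  if (!is.null(thr)) {
    for (nm in names(thr)) {
      p <- thr[[nm]]
      if (p$upper <= p$lower)
        stop(sprintf("invalid threshold pair for %s: upper <= lower", nm),
             call. = FALSE)
    }
  }
  config
}

#' Run the full synthetic-to-report pipeline
#'
#' Executes the stage chain simulate -> monitor -> iEMG -> compare ->
#' summarize on a synthetic fixture bundle: generates the bundle with
#' [gen_fixture_suite()], counts repetitions of the four elbow/shoulder
#' protocols, extracts wrist ROM and functional-ROM compliance, computes
#' the device resistance table, and integrates the surrogate sEMG records
#' (wavelet-denoised) into per-condition comparisons and across-subject
#' summaries. The resolved configuration is written next to the outputs so
#' every report is reproducible from the stored config and seed.
#'
#' @param config Either a named list or the path of a YAML file. Keys:
#'   `out_dir` (required), `seed` (default 1), `schema`, optional
#'   `thresholds` overrides (named list of `list(upper=, lower=)`).
#' @param quiet Suppress stage logging to stderr.
#' @return Invisibly, a list with `rep_counts`, `wrist_rom`,
#'   `resistance`, `iemg`, `comparison`, `subject_summary` and the paths of
#'   the written reports.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  config <- validate_run_config(config)
  log_stage <- function(...) if (!quiet) message(sprintf(...))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed)

  log_stage("stage=simulate seed=%d out=%s", seed, out_dir)
  fix_dir <- file.path(out_dir, "fixtures")
  gen_fixture_suite(fix_dir, seed = seed)

  thrs <- default_thresholds()
  if (!is.null(config$thresholds))
    for (nm in names(config$thresholds))
      thrs[[nm]] <- threshold_pair(config$thresholds[[nm]]$upper,
                                   config$thresholds[[nm]]$lower)

  log_stage("stage=count_reps patterns=%d", length(thrs))
  rep_counts <- vapply(names(thrs), function(p) {
    d <- read_timeseries_csv(file.path(fix_dir, sprintf("%s_protocol.csv", p)))
    joint <- if (startsWith(p, "elbow")) "elbow" else "shoulder"
    ser <- joint_angle_series(d$t, d$angle, joint = joint, pattern = p)
    count_reps(ser, thrs[[p]])
  }, integer(1))

  log_stage("stage=wrist_rom")
  wrist_rom <- lapply(c(fe = "fe", ru = "ru"), function(p) {
    d <- read_timeseries_csv(file.path(fix_dir, sprintf("wrist_%s.csv", p)))
    ser <- joint_angle_series(d$t, d$angle, joint = "wrist", pattern = p)
    rom <- extract_rom(ser)
    list(min = rom$min, max = rom$max,
         functional = as.list(check_functional_rom(rom, p)))
  })

  log_stage("stage=resistance_table")
  resistance <- resistance_table()

  log_stage("stage=iemg subjects=3 patterns=2 conditions=3")
  rows <- list()
  for (s in 1:3) for (p in c("fe", "ru")) for (cond in c("none", "low", "high")) {
    f <- file.path(fix_dir, sprintf("emg_S%d_%s_%s.csv", s, p, cond))
    d <- read_timeseries_csv(f, c("t", "v"))
    rec <- emg_record(d$t, d$v, condition = cond, subject = sprintf("S%d", s))
    val <- iemg(wavelet_denoise(rec))$value
    rows[[length(rows) + 1L]] <- data.frame(
      subject = sprintf("S%d", s), pattern = p, condition = cond, iemg = val)
  }
  iemg_tab <- do.call(rbind, rows)

  log_stage("stage=compare")
  comparison <- do.call(rbind, lapply(split(iemg_tab,
                                            iemg_tab[c("subject", "pattern")]),
    function(g) {
      v <- stats::setNames(g$iemg, g$condition)
      pct <- condition_comparison(v)
      data.frame(subject = g$subject[1], pattern = g$pattern[1],
                 condition = names(pct), pct_increase = as.numeric(pct))
    }))
  rownames(comparison) <- NULL

  log_stage("stage=summarize")
  subject_summary <- do.call(rbind, lapply(
    split(iemg_tab, iemg_tab[c("pattern", "condition")]),
    function(g) {
      s <- summarize_subjects(g$iemg)
      data.frame(pattern = g$pattern[1], condition = g$condition[1],
                 mean = s[["mean"]], sd = s[["sd"]], n = s[["n"]])
    }))
  rownames(subject_summary) <- NULL

  # reports
  utils::write.csv(iemg_tab, file.path(out_dir, "iemg.csv"), row.names = FALSE)
  utils::write.csv(comparison, file.path(out_dir, "iemg_comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(subject_summary, file.path(out_dir, "iemg_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(resistance, file.path(out_dir, "resistance_table.csv"),
                   row.names = FALSE)
  report <- list(rep_counts = as.list(rep_counts), wrist_rom = wrist_rom)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))

  invisible(list(rep_counts = rep_counts, wrist_rom = wrist_rom,
                 resistance = resistance, iemg = iemg_tab,
                 comparison = comparison, subject_summary = subject_summary,
                 out_dir = out_dir))
}
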