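# File-based pipeline commands.  Each command is a pure function of
# (inputs, config, seed) and writes plain CSV/JSON/PNG outputs plus a
# provenance record.

#' Pipeline run configuration
#'
#' All physical quantities are SI except where a `_uL` suffix says
#' otherwise (volumes cross the user boundary in microlitres; 1 mbar =
#' 100 Pa for pressures in reports).  `read_run_config()` reads a YAML file
#' and merges it over the defaults; unknown keys are an error.
#'
#' @param ... overrides of the default fields (see the returned list).
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    device = list(r_s = 4.75e-3, r_n = 66.5e-6, L_n = 6e-3,
                  alpha_kinetic = 2),
    fluid = list(mu = 1.0e-3, rho = 1000),
    p_ref = 101325,
    detection = list(threshold_sd = 6, refractory_s = 0.02, window_s = 0.001),
    flow = list(volume_per_click_uL = 10, truncate_tail = 2L),
    solver = list(grid_n = 160L, r_outer = 50e-3, rtol = 1e-6),
    fit = list(k_init = 1e-11, K_init = 1e5,
               k_bounds = c(1e-14, 1e-8), K_bounds = c(1e3, 1e8),
               phi0 = 0.01, p0 = 101325),
    cohort = list(detection_floor_mbar = 10),
    seed = 1L
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad))
    pp_stop("invalid_input", paste("unknown config field(s):",
                                   paste(bad, collapse = ", ")))
  for (nm in names(ov)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(ov[[nm]]))
      modifyList(cfg[[nm]], ov[[nm]]) else ov[[nm]]
  }
  chk <- c(unlist(cfg$device), unlist(cfg$fluid), p_ref = cfg$p_ref)
  if (any(chk <= 0))
    pp_stop("invalid_input", "all physical config quantities must be positive")
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

# Internal helpers shared by the commands ----------------------------------

pp_cfg_geom <- function(config)
  device_geometry(config$device$r_s, config$device$r_n, config$device$L_n,
                  config$device$alpha_kinetic)

pp_cfg_fluid <- function(config)
  fluid_props(config$fluid$mu, config$fluid$rho)

pp_cfg_vpc <- function(config) uL_to_m3(config$flow$volume_per_click_uL)

pp_provenance <- function(out_dir, stage, config, extra = list()) {
  ser <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  rec <- c(list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(packageVersion("penpress")),
    config_checksum = sum(as.integer(charToRaw(ser))),
    seed = config$seed
  ), extra)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      sep = "", file = file.path(out_dir, "run_log.jsonl"), append = TRUE)
  invisible(rec)
}

pp_read_manifest <- function(manifest) {
  df <- if (is.data.frame(manifest)) manifest else
    read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("subject_id", "role", "path")
  miss <- setdiff(need, names(df))
  if (length(miss))
    pp_stop("format_error", paste("manifest missing column(s):",
                                  paste(miss, collapse = ", ")))
  bad <- setdiff(unique(df$role), c("air_pre", "air_post", "tissue"))
  if (length(bad))
    pp_stop("format_error", paste("unknown role(s):", paste(bad, collapse = ", ")))
  gone <- df$path[!file.exists(df$path)]
  if (length(gone))
    pp_stop("missing_file", paste("missing input file(s):",
                                  paste(gone, collapse = ", ")))
  df
}

# Per-subject ingestion: air flows (pooled later) + tissue flow.
pp_load_subject <- function(rows, config) {
  vpc <- pp_cfg_vpc(config)
  trunc <- config$flow$truncate_tail
  load_one <- function(path) {
    tr <- read_click_table(path, vpc)
    flow_from_clicks(tr, truncate_tail = trunc)
  }
  air <- lapply(rows$path[rows$role %in% c("air_pre", "air_post")], load_one)
  tis <- rows$path[rows$role == "tissue"]
  if (length(air) < 1 || length(tis) != 1)
    pp_stop("format_error", sprintf(
      "subject %s needs >= 1 air and exactly 1 tissue entry",
      rows$subject_id[1]))
  list(air = air, tissue = load_one(tis))
}

#' Pipeline commands
#'
#' File-based orchestration of the analysis.  `cmd_detect()` turns WAV
#' recordings into click tables; `cmd_flow()` turns click tables into flow
#' CSVs; `cmd_counterpressure()` runs the paired air/tissue counter-pressure
#' estimate and cohort summary; `cmd_fit()` runs the tissue-parameter fits;
#' `cmd_simulate()` writes a synthetic cohort in the same formats the real
#' pipeline reads.  Every command appends a provenance record
#' (`run_log.jsonl`) in its output directory.
#'
#' @param audio_manifest data frame or CSV with columns `subject_id`,
#'   `medium`, `path` (WAV files).
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return `cmd_detect()`: paths of the click tables written.
#' @export
cmd_detect <- function(audio_manifest, config = run_config(),
                       out_dir = ".") {
  df <- if (is.data.frame(audio_manifest)) audio_manifest else
    read.csv(audio_manifest, stringsAsFactors = FALSE)
  need <- c("subject_id", "medium", "path")
  if (length(setdiff(need, names(df))))
    pp_stop("format_error", "audio manifest needs subject_id, medium, path")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  det <- config$detection
  out <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    wav <- read_wav(df$path[i])
    tr <- detect_clicks(wav, threshold_sd = det$threshold_sd,
                        refractory = det$refractory_s,
                        window = det$window_s,
                        volume_per_click = pp_cfg_vpc(config),
                        subject_id = df$subject_id[i],
                        medium = df$medium[i])
    out[i] <- file.path(out_dir, sprintf("%s_%s_clicks.csv",
                                         df$subject_id[i], df$medium[i]))
    write_click_table(tr, out[i])
  }
  pp_provenance(out_dir, "detect", config, list(n_files = nrow(df)))
  out
}

#' @rdname cmd_detect
#' @param click_tables character vector of click-table CSV paths.
#' @return `cmd_flow()`: paths of the flow CSVs written.
#' @export
cmd_flow <- function(click_tables, config = run_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(length(click_tables))
  for (i in seq_along(click_tables)) {
    tr <- read_click_table(click_tables[i], pp_cfg_vpc(config))
    fl <- flow_from_clicks(tr, truncate_tail = config$flow$truncate_tail)
    out[i] <- file.path(out_dir, sub("\\.csv$", "_flow.csv",
                                     basename(click_tables[i])))
    write_flow_table(fl, out[i])
  }
  pp_provenance(out_dir, "flow", config,
                list(n_files = length(click_tables)))
  out
}

#' @rdname cmd_detect
#' @param subject_manifest data frame or CSV with columns `subject_id`,
#'   `role` (`air_pre`/`air_post`/`tissue`), `path` (click tables).
#' @return `cmd_counterpressure()`: list with per-subject `series`, the
#'   per-subject `means` (Pa) and the cohort `stats`.
#' @export
cmd_counterpressure <- function(subject_manifest, config = run_config(),
                                out_dir = ".") {
  df <- pp_read_manifest(subject_manifest)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- pp_cfg_geom(config); fluid <- pp_cfg_fluid(config)
  subjects <- split(df, df$subject_id)
  series <- list(); means <- numeric(0)
  for (id in names(subjects)) {
    sub <- pp_load_subject(subjects[[id]], config)
    spring <- calibrate_spring(sub$air, geom, fluid, config$p_ref)
    ser <- tissue_pressure_series(spring, sub$tissue, geom, fluid,
                                  config$p_ref)
    attr(ser, "subject_id") <- id
    write_pressure_series(ser, file.path(out_dir, paste0(id, "_pressure.csv")))
    series[[id]] <- ser
    means[id] <- mean_counter_pressure(ser)
  }
  stats <- cohort_boxstats(means,
                           mbar_to_Pa(config$cohort$detection_floor_mbar))
  summary_df <- data.frame(
    stat = c("median", "q1", "q3", "whisker_low", "whisker_high",
             "notch_low", "notch_high"),
    mbar = Pa_to_mbar(c(stats$median, stats$q1, stats$q3, stats$whisker_low,
                        stats$whisker_high, stats$notch_low,
                        stats$notch_high)))
  write.csv(summary_df, file.path(out_dir, "cohort_summary.csv"),
            row.names = FALSE)
  plot_cohort(stats, file.path(out_dir, "cohort_boxplot.png"))
  pp_provenance(out_dir, "counterpressure", config,
                list(n_subjects = length(series),
                     n_included = stats$n_included,
                     n_excluded = stats$n_excluded))
  list(series = series, means = means, stats = stats)
}

#' @rdname cmd_detect
#' @param fit_control passed through to [fit_tissue_params()]'s `control`.
#' @return `cmd_fit()`: named list of `fit_result`s (JSON + overlay PNG per
#'   subject on disk).
#' @export
cmd_fit <- function(subject_manifest, config = run_config(), out_dir = ".",
                    fit_control = list()) {
  df <- pp_read_manifest(subject_manifest)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- pp_cfg_geom(config); fluid <- pp_cfg_fluid(config)
  fits <- list()
  for (id in names(split(df, df$subject_id))) {
    sub <- pp_load_subject(df[df$subject_id == id, ], config)
    spring <- calibrate_spring(sub$air, geom, fluid, config$p_ref)
    ser <- tissue_pressure_series(spring, sub$tissue, geom, fluid,
                                  config$p_ref)
    attr(ser, "subject_id") <- id
    fit <- fit_tissue_params(
      ser, sub$tissue, geom, fluid,
      phi0 = config$fit$phi0, p0 = config$fit$p0,
      init = c(config$fit$k_init, config$fit$K_init),
      bounds = list(k = config$fit$k_bounds, K = config$fit$K_bounds),
      grid_n = config$solver$grid_n, r_outer = config$solver$r_outer,
      rtol_polish = config$solver$rtol, control = fit_control)
    jsonlite::write_json(
      list(subject_id = id, k_hat = fit$k_hat, K_hat = fit$K_hat,
           sse = fit$sse, n_points = fit$n_points,
           converged = fit$converged,
           bounds_hit = as.list(fit$bounds_hit)),
      file.path(out_dir, paste0(id, "_fit.json")),
      auto_unbox = TRUE, digits = NA)
    plot_fit_overlay(fit, file.path(out_dir, paste0(id, "_fit.png")),
                     p_ref = config$p_ref)
    fits[[id]] <- fit
  }
  pp_provenance(out_dir, "fit", config, list(n_subjects = length(fits)))
  fits
}

#' @rdname cmd_detect
#' @param cohort_spec list of overrides for [make_cohort()] (e.g.
#'   `n_subjects`, `k_range`, `K_range`, `dose_range`, `jitter_sd`).
#' @return `cmd_simulate()`: the subject manifest path (click tables, truth
#'   CSV and manifest written to `out_dir`).
#' @export
cmd_simulate <- function(cohort_spec = list(), config = run_config(),
                         out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  args <- modifyList(
    list(seed = config$seed, geom = pp_cfg_geom(config),
         fluid = pp_cfg_fluid(config), p_ref = config$p_ref,
         phi0 = config$fit$phi0, p0 = config$fit$p0,
         volume_per_click = pp_cfg_vpc(config),
         grid_n = config$solver$grid_n),
    cohort_spec)
  cohort <- do.call(make_cohort, args)
  rows <- list(); truth <- list()
  for (s in cohort) {
    id <- s$subject_id
    paths <- c(air_pre = file.path(out_dir, paste0(id, "_air_pre.csv")),
               air_post = file.path(out_dir, paste0(id, "_air_post.csv")),
               tissue = file.path(out_dir, paste0(id, "_tissue.csv")))
    write_click_table(s$air[[1]]$clicks, paths[["air_pre"]])
    write_click_table(s$air[[2]]$clicks, paths[["air_post"]])
    write_click_table(s$tissue$clicks, paths[["tissue"]])
    rows[[id]] <- data.frame(subject_id = id, role = names(paths),
                             path = unname(paths))
    truth[[id]] <- data.frame(
      subject_id = id, k_true = s$truth$k, K_true = s$truth$K,
      dose_uL = m3_to_uL(s$tissue$dose),
      synthetic = TRUE)
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, manifest_path, row.names = FALSE)
  write.csv(do.call(rbind, truth),
            file.path(out_dir, "truth_synthetic.csv"), row.names = FALSE)
  pp_provenance(out_dir, "simulate", config,
                list(n_subjects = length(cohort)))
  manifest_path
}
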