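# JSON configuration and the command-line driver behind inst/cli/avdu-cli.R.

#' Read an experiment configuration from a JSON file
#'
#' The file may contain any of the option names accepted by the experiment
#' drivers and sweeps, plus two structured blocks: `detector` (arguments to
#' [avdu_params()]) and `controller` (arguments to [controller_params()]),
#' which are converted to their parameter objects.
#'
#' @param path Path to a JSON file.
#' @return A named list ready to pass as the `config` argument of the
#'   experiment drivers.
#' @export
read_avdu_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(cfg$detector)) {
    cfg$params <- do.call(avdu_params, cfg$detector)
    cfg$detector <- NULL
  }
  if (!is.null(cfg$controller)) {
    cfg$controller <- do.call(controller_params, cfg$controller)
  }
  cfg
}

#' Command-line driver
#'
#' Backs the `inst/cli/avdu-cli.R` script. Subcommands: `sweep-av`,
#' `sweep-tf`, `rectification`, `invariance`, `corridor-1a`, `corridor-1b`,
#' `odometry`. Each takes `--config <json>` (optional) and `--out <dir>`,
#' writes per-run CSV tables plus a JSON summary into the output directory,
#' and echoes the configuration used.
#'
#' @param args Character vector of command-line arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the result object of the subcommand.
#' @export
avdu_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: avdu-cli.R <subcommand> [--config file.json] [--out dir]",
    "subcommands: sweep-av | sweep-tf | rectification | invariance |",
    "             corridor-1a | corridor-1b | odometry", sep = "\n")
  if (!length(args)) stop(usage, call. = FALSE)
  cmd <- args[1]
  opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  out_dir <- opt("--out", ".")
  cfg_path <- opt("--config", NA)
  config <- if (!is.na(cfg_path)) read_avdu_config(cfg_path) else list()
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  params <- config$params
  if (is.null(params)) params <- avdu_params()

  message("subcommand: ", cmd)
  message("config: ", jsonlite::toJSON(config[!vapply(config, is.object, TRUE)],
                                       auto_unbox = TRUE, digits = NA))
  write_tab <- function(d, name)
    utils::write.csv(as.data.frame(d), file.path(out_dir, name),
                     row.names = FALSE)
  write_sum <- function(s)
    jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

  res <- switch(
    cmd,
    "sweep-av" = {
      curve <- sweep_av(params)
      fits <- fit_forms(curve)
      write_tab(curve, "sweep_av.csv")
      write_sum(list(best_form = fits$best, adjusted_r_squared = stats::setNames(
        as.list(fits$table$adj_r_squared), fits$table$form)))
      fits
    },
    "sweep-tf" = {
      curve <- sweep_tf_subunits(params)
      write_tab(curve, "sweep_tf_subunits.csv")
      write_sum(list(fast_peak_hz = as.list(peak_frequency(curve, "fast")),
                     slow_peak_hz = as.list(peak_frequency(curve, "slow"))))
      curve
    },
    "rectification" = {
      comp <- rectification_comparison(params)
      for (m in names(comp$curves)) write_tab(comp$curves[[m]],
                                              paste0("sweep_av_", m, ".csv"))
      write_sum(lapply(comp$fits, function(f)
        list(best_form = f$best)))
      comp
    },
    "invariance" = {
      rep <- invariance_report(params)
      write_tab(rep$contrast, "invariance_contrast.csv")
      write_tab(rep$wavelength, "invariance_wavelength.csv")
      write_sum(list(max_cov_contrast = max(rep$contrast$cov),
                     max_cov_wavelength = max(rep$wavelength$cov),
                     reversal_ratio = rep$reversal_ratio))
      rep
    },
    "corridor-1a" = {
      tab <- experiment_1a(config)
      write_tab(tab, "experiment_1a.csv")
      write_sum(list(assessment = attr(tab, "assessment")))
      tab
    },
    "corridor-1b" = {
      tab <- experiment_1b(config)
      write_tab(tab, "experiment_1b.csv")
      write_sum(list(n_conditions = nrow(tab),
                     known_exceptions = sum(tab$known_exception)))
      tab
    },
    "odometry" = {
      tab <- experiment_odometry(config)
      write_tab(tab, "experiment_odometry.csv")
      band <- tab$d_e[tab$freq <= 0.6]
      write_sum(list(max_min_ratio_upto_0.6 = max(band) / min(band),
                     d_e = as.list(stats::setNames(tab$d_e, tab$freq))))
      tab
    },
    stop(usage, call. = FALSE))
  invisible(res)
}
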