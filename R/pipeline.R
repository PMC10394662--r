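#' Read a pipeline configuration
#'
#' One YAML file configures the whole pipeline: the network (inline or via
#' a `network_file`), the experiment design (`times`, `c0`, `k`), the noise
#' model and the fit settings. Missing keys fall back to the package
#' defaults; the shipped default configuration is at
#' `system.file("extdata", "default_config.yaml", package = "ppdkinetics")`.
#'
#' @param path Path to a YAML config, or `NULL` for the defaults.
#' @return A `kin_config` list with elements `network`, `design`, `noise`
#'   and `fit`.
#' @export
read_config <- function(path = NULL) {
  raw <- if (is.null(path)) {
    list()
  } else {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    yaml::read_yaml(path)
  }
  network <- if (!is.null(raw$network_file)) {
    read_network_yaml(raw$network_file)
  } else if (!is.null(raw$network)) {
    network_from_list(raw$network)
  } else {
    default_network()
  }
  k <- if (!is.null(raw$k)) rate_constants(unlist(raw$k)) else
    rate_constants(reference_rate_constants()$estimate)
  times <- if (!is.null(raw$design$times)) as.numeric(raw$design$times) else
    seq(0, 360, by = 40)
  c0 <- if (!is.null(raw$design$c0)) as.numeric(raw$design$c0) else NULL
  design <- experiment_design(times = times, c0 = c0, k_true = k)
  noise <- noise_spec(
    kind = raw$noise$kind %||% "multiplicative_gaussian",
    sigma = raw$noise$sigma %||% 0.02,
    clip_negative = raw$noise$clip_negative %||% TRUE
  )
  fit <- fit_config(
    initial_guess = raw$fit$initial_guess %||% 0.01,
    lower_bound = raw$fit$lower_bound %||% 0,
    uncertainty = raw$fit$uncertainty %||% "laplace",
    weighting = raw$fit$weighting %||% "uniform"
  )
  structure(list(network = network, design = design, noise = noise,
                 fit = fit, raw = raw),
            class = "kin_config")
}

config_hash <- function(config) {
  rlang::hash(list(config$raw, config$design, unclass(config$noise),
                   unclass(config$fit)))
}

artifact_meta <- function(config, seed = NULL) {
  list(package = "ppdkinetics",
       version = as.character(utils::packageVersion("ppdkinetics")),
       config_hash = config_hash(config),
       seed = seed)
}

log_msg <- function(...) message("[ppdkinetics] ", ...)

#' Run one pipeline stage
#'
#' Programmatic equivalents of the command-line tool's subcommands; each
#' writes its artifacts into `out_dir` and returns the paths invisibly.
#' Every artifact records the package version, a config hash and the seed,
#' so a run is reproducible from its outputs.
#'
#' \itemize{
#'   \item `run_simulate()`: noiseless profile of the configured constants
#'     -> `profile.csv`.
#'   \item `run_generate()`: noisy synthetic dataset -> `dataset.csv`.
#'   \item `run_fit()`: fit a dataset -> `fit.json`, `fit.md` (a
#'     rate-constant table with 95% intervals and at-bound footnotes) and
#'     `correlation.csv`.
#'   \item `run_report()`: pathway classification and selectivity metrics
#'     -> `report.json`, `selectivity.csv`.
#' }
#'
#' @param config A `kin_config` from [read_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the noise draws (`run_generate()`).
#' @param dataset_path CSV dataset to fit / report on; for `run_report()`,
#'   `fit` may also be an existing `kin_fit`.
#' @param fit A `kin_fit` for `run_report()`; when `NULL` it is refitted
#'   from `dataset_path`.
#' @return Invisibly, a named character vector of artifact paths
#'   (`run_fit()` returns the `kin_fit` invisibly with paths in
#'   `attr(, "paths")`).
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(config = read_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prof <- simulate_profile(config$network, config$design$k_true,
                           config$design$c0, config$design$times)
  path <- file.path(out_dir, "profile.csv")
  write_profile_csv(prof, path)
  log_msg("simulate: wrote ", path, " (config ", config_hash(config), ")")
  invisible(c(profile = path))
}

#' @rdname pipeline
#' @export
run_generate <- function(config = read_config(), seed = 1, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_dataset(config$design, config$noise, seed = seed,
                         network = config$network)
  path <- file.path(out_dir, "dataset.csv")
  write_profile_csv(ds, path)
  log_msg("generate: wrote ", path, " (seed ", seed, ", sigma ",
          config$noise$sigma, ", config ", config_hash(config), ")")
  invisible(c(dataset = path))
}

#' @rdname pipeline
#' @export
run_fit <- function(config = read_config(), dataset_path, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- read_profile_csv(dataset_path)
  fit <- fit_kinetics(ds, config$network, config$fit)
  json_path <- file.path(out_dir, "fit.json")
  md_path <- file.path(out_dir, "fit.md")
  cor_path <- file.path(out_dir, "correlation.csv")
  write_fit_json(fit, json_path, meta = artifact_meta(config))
  writeLines(fit_report_markdown(fit), md_path)
  write_correlation_csv(fit, cor_path)
  if (!fit$converged) log_msg("fit: optimiser did not converge (info ",
                              fit$optim_info, ")")
  log_msg("fit: wrote ", json_path, ", ", md_path, ", ", cor_path)
  attr(fit, "paths") <- c(fit_json = json_path, fit_md = md_path,
                          correlation = cor_path)
  invisible(fit)
}

#' @rdname pipeline
#' @export
run_report <- function(config = read_config(), dataset_path = NULL,
                       fit = NULL, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(fit)) {
    if (is.null(dataset_path)) {
      stop("run_report() needs a `fit` or a `dataset_path`", call. = FALSE)
    }
    ds <- read_profile_csv(dataset_path)
    fit <- fit_kinetics(ds, config$network, config$fit)
  }
  cls <- classify_pathways(fit$estimates, config$network)
  sel <- selectivity_metrics(fit$fitted)
  report <- list(
    meta = artifact_meta(config),
    estimates = as.list(fit$estimates),
    at_bound = as.list(fit$at_bound),
    hpd95 = as.list(fit$hpd95),
    ssr = fit$ssr,
    converged = fit$converged,
    pathways = list(
      negligible_edges = paste0(cls$negligible_edges$source, "->",
                                cls$negligible_edges$target),
      preferential = cls$routes$route[cls$routes$class == "preferential"],
      intermediate = cls$routes$route[cls$routes$class == "intermediate"],
      negligible = cls$routes$route[cls$routes$class == "negligible"]
    )
  )
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  sel_path <- file.path(out_dir, "selectivity.csv")
  utils::write.csv(sel, sel_path, row.names = FALSE)
  log_msg("report: wrote ", report_path, ", ", sel_path)
  invisible(c(report = report_path, selectivity = sel_path))
}

#' Fit report as a Markdown table
#'
#' A table with one row per rate constant: the estimate in min^-1, its 95%
#' marginal HPD half-width, and a footnote marker for constants fitted to
#' the imposed lower bound.
#'
#' @param fit A `kin_fit`.
#' @return A character vector of Markdown lines.
#' @export
fit_report_markdown <- function(fit) {
  td <- tidy(fit)
  rows <- vapply(seq_len(nrow(td)), function(i) {
    hw <- if (is.na(td$hpd95[i])) "" else sprintf("±%.3e", td$hpd95[i])
    note <- if (td$at_bound[i]) "at lower bound" else ""
    sprintf("| %s | %.6e | %s | %s |", td$term[i], td$estimate[i], hw, note)
  }, character(1))
  c("| k (min^-1) | value | 95% marginal HPD | note |",
    "|---|---|---|---|",
    rows,
    "",
    sprintf("Sum of squared residuals: %.6e", fit$ssr))
}

#' Write a fit as JSON / its correlation matrix as CSV
#'
#' @param fit A `kin_fit`.
#' @param path Output file path.
#' @param meta Optional provenance list stored under `meta`.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, meta = NULL) {
  payload <- list(
    meta = meta,
    estimates = as.list(fit$estimates),
    hpd95 = as.list(fit$hpd95),
    conf_low = as.list(fit$conf.low),
    conf_high = as.list(fit$conf.high),
    at_bound = as.list(fit$at_bound),
    ssr = fit$ssr,
    sigma = fit$sigma,
    n_obs = fit$n_obs,
    n_free = fit$n_free,
    converged = fit$converged,
    uncertainty = fit$config$uncertainty
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
write_correlation_csv <- function(fit, path) {
  m <- correlation_matrix(fit)
  df <- data.frame(term = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Command-line entry point
#'
#' Backs the `inst/cli/ppdkin` Rscript. Subcommands: `simulate`,
#' `generate`, `fit`, `report`; flags `--config`, `--seed`, `--out`,
#' `--dataset`, `--uncertainty`, `--noise-sigma`.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Exit status, 0 on success (invisibly).
#' @export
kin_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!requireNamespace("optparse", quietly = TRUE)) {
    stop("kin_cli() requires the optparse package", call. = FALSE)
  }
  usage <- "ppdkin {simulate|generate|fit|report} [options]"
  if (length(args) < 1 || !args[1] %in%
        c("simulate", "generate", "fit", "report")) {
    message("usage: ", usage)
    return(invisible(2L))
  }
  cmd <- args[1]
  parser <- optparse::OptionParser(usage = usage, option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = "."),
    optparse::make_option("--dataset", type = "character", default = NULL),
    optparse::make_option("--uncertainty", type = "character",
                          default = NULL),
    optparse::make_option("--noise-sigma", type = "double", default = NULL,
                          dest = "noise_sigma")
  ))
  opts <- optparse::parse_args(parser, args = args[-1])
  status <- tryCatch({
    config <- read_config(opts$config)
    if (!is.null(opts$uncertainty)) {
      config$fit$uncertainty <- match.arg(opts$uncertainty,
                                          c("laplace", "mcmc"))
    }
    if (!is.null(opts$noise_sigma)) config$noise$sigma <- opts$noise_sigma
    switch(cmd,
      simulate = run_simulate(config, opts$out),
      generate = run_generate(config, seed = opts$seed, out_dir = opts$out),
      fit = {
        if (is.null(opts$dataset)) stop("fit requires --dataset",
                                        call. = FALSE)
        run_fit(config, opts$dataset, opts$out)
      },
      report = {
        if (is.null(opts$dataset)) stop("report requires --dataset",
                                        call. = FALSE)
        run_report(config, dataset_path = opts$dataset, out_dir = opts$out)
      }
    )
    0L
  }, error = function(e) {
    message("ppdkin error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
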