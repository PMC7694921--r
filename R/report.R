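# Pipeline front end: configuration, report writers and the full
# equity + DEA + Malmquist run.  Every table written here is produced by
# the library functions; this layer adds no computation of its own.
# Rounding for display happens only at serialisation; machine outputs
# keep full precision.

#' Assemble a run configuration
#'
#' @param input path to a panel CSV (see \code{\link{read_panel}}), or
#'   \code{NULL} to generate a synthetic panel from \code{gen_config}.
#' @param out_dir output directory (created if absent).
#' @param scheme a \code{\link{region_scheme}} or \code{NULL} (regions
#'   from the file).
#' @param bases equity bases to evaluate.
#' @param primary_resources,financial_resources resource field groups
#'   reported separately in the equity tables.
#' @param dea_model a \code{\link{dea_model}}.
#' @param run_malmquist compute Malmquist indices?
#' @param lorenz_plots write Lorenz curve PNGs?
#' @param log_base Theil logarithm base.
#' @param gen_config \code{\link{panel_gen_config}} used when
#'   \code{input} is \code{NULL}.
#' @param seed seed recorded in the manifest and used for generation.
#' @return object of class \code{hera_config}.
#' @export
hera_config <- function(input = NULL, out_dir = "hera-out",
                        scheme = NULL,
                        bases = c("population", "area"),
                        primary_resources = c("institutions", "beds",
                                              "health_workers"),
                        financial_resources = c("gov_subsidy_bn",
                                                "total_expenditure_bn"),
                        dea_model = hera::dea_model(),
                        run_malmquist = TRUE,
                        lorenz_plots = FALSE,
                        log_base = "natural",
                        gen_config = panel_gen_config(),
                        seed = NULL) {
  stopifnot(all(bases %in% c("population", "area")))
  if (!is.null(seed)) gen_config$seed <- as.integer(seed)
  structure(list(input = input, out_dir = out_dir, scheme = scheme,
                 bases = bases,
                 primary_resources = primary_resources,
                 financial_resources = financial_resources,
                 dea_model = dea_model, run_malmquist = run_malmquist,
                 lorenz_plots = lorenz_plots, log_base = log_base,
                 gen_config = gen_config, seed = seed),
            class = "hera_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys: \code{input}, \code{out_dir}, \code{bases},
#' \code{primary_resources}, \code{financial_resources},
#' \code{dea_inputs}, \code{dea_outputs}, \code{run_malmquist},
#' \code{lorenz_plots}, \code{log_base}, \code{seed}, and a
#' \code{regions} mapping (group -> list of cities).
#'
#' @param path YAML file.
#' @return a \code{\link{hera_config}}.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("input", "out_dir", "bases", "primary_resources",
              "financial_resources", "run_malmquist", "lorenz_plots",
              "log_base", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$regions))
    args$scheme <- region_scheme("config", y$regions)
  if (!is.null(y$dea_inputs) || !is.null(y$dea_outputs)) {
    dm <- dea_model()
    args$dea_model <- dea_model(
      inputs = y$dea_inputs %||% dm$inputs,
      outputs = y$dea_outputs %||% dm$outputs)
  }
  do.call(hera_config, args)
}

load_or_generate <- function(config) {
  if (is.null(config$input)) generate_panel(config$gen_config)
  else read_panel(config$input, scheme = config$scheme)
}

write_report_csv <- function(df, path, digits = 4) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) round(v, digits))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the equity stage and write its report files
#'
#' Emits per-year Gini coefficients for both bases, the Theil
#' decomposition with contribution-rate columns, per-region Theil
#' indices, and HRDI per region and per city, as CSV files in the output
#' directory; optionally Lorenz-curve PNGs with the 45-degree equality
#' line.
#'
#' @param config a \code{\link{hera_config}}.
#' @param panel optional pre-loaded \code{\link{resource_panel}}
#'   (otherwise loaded/generated per the config).
#' @return invisibly, the character vector of files written.
#' @export
run_equity <- function(config, panel = NULL) {
  if (is.null(panel)) panel <- load_or_generate(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  resources <- c(config$primary_resources, config$financial_resources)
  files <- character(0)
  p <- function(f) file.path(config$out_dir, f)

  files <- c(files, write_report_csv(
    gini_table(panel, resources, config$bases), p("gini.csv")))
  for (b in config$bases) {
    tt <- theil_table(panel, resources, b, config$log_base)
    files <- c(files,
               write_report_csv(tt$totals, p(paste0("theil_", b, ".csv"))),
               write_report_csv(tt$regions,
                                p(paste0("theil_regions_", b, ".csv"))))
  }
  files <- c(files, write_report_csv(hrdi_table(panel, resources, "region"),
                                     p("hrdi_region.csv")))
  files <- c(files, write_report_csv(hrdi_table(panel, resources, "city"),
                                     p("hrdi_city.csv")))
  if (isTRUE(config$lorenz_plots)) {
    for (b in config$bases) for (r in resources) {
      yr <- max(panel_years(panel))
      sl <- panel[panel$year == yr, ]
      f <- p(sprintf("lorenz_%s_%s_%d.png", r, b, yr))
      grDevices::png(f, width = 600, height = 600)
      plot(lorenz_curve(sl[[r]], panel_basis(sl, b), sl$city),
           main = sprintf("%s by %s, %d", r, b, yr))
      grDevices::dev.off()
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Run the DEA stage and write its report files
#'
#' One efficiency table per year (TE, PTE, SE, peers, slacks and
#' adjustment targets, with a mean/max/min summary block) as CSV.
#'
#' @inheritParams run_equity
#' @return invisibly, the files written.
#' @export
run_dea <- function(config, panel = NULL) {
  if (is.null(panel)) panel <- load_or_generate(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (y in panel_years(panel)) {
    eff <- dea_efficiency(panel, y, config$dea_model)
    adj <- dea_adjustments(eff)
    tab <- merge(eff$scores, adj, by = "city", sort = TRUE)
    f <- file.path(config$out_dir, sprintf("dea_%d.csv", y))
    files <- c(files, write_report_csv(tab, f))
    fs <- file.path(config$out_dir, sprintf("dea_summary_%d.csv", y))
    files <- c(files, write_report_csv(eff$summary, fs, digits = 3))
  }
  invisible(files)
}

#' Run the Malmquist stage and write its report files
#'
#' Writes the per-city per-pair indices plus the two standard summaries:
#' annual geometric means with frequency-distribution columns, and
#' per-city geometric means.
#'
#' @inheritParams run_equity
#' @return invisibly, the files written.
#' @export
run_malmquist <- function(config, panel = NULL) {
  if (is.null(panel)) panel <- load_or_generate(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  mr <- malmquist(panel, config$dea_model)
  files <- c(
    write_report_csv(as.data.frame(mr),
                     file.path(config$out_dir, "malmquist.csv")),
    write_report_csv(malmquist_summary(mr, "year"),
                     file.path(config$out_dir, "malmquist_by_year.csv"),
                     digits = 3),
    write_report_csv(malmquist_summary(mr, "city"),
                     file.path(config$out_dir, "malmquist_by_city.csv"),
                     digits = 3))
  invisible(files)
}

#' Run the full pipeline
#'
#' Equity, DEA and (optionally) Malmquist stages on one panel, plus a
#' JSON manifest recording the input hash, the configuration echo and
#' package version.
#'
#' @inheritParams run_equity
#' @return invisibly, the list of stage outputs (paths).
#' @export
run_full <- function(config, panel = NULL) {
  if (is.null(panel)) panel <- load_or_generate(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(equity = run_equity(config, panel),
              dea = run_dea(config, panel))
  if (isTRUE(config$run_malmquist))
    out$malmquist <- run_malmquist(config, panel)
  panel_csv <- file.path(config$out_dir, "panel.csv")
  write_panel(panel, panel_csv)
  manifest <- list(
    package = "hera",
    version = as.character(utils::packageVersion("hera")),
    input = config$input %||% "synthetic",
    seed = config$seed,
    panel_md5 = as.character(tools::md5sum(panel_csv)),
    stages = lapply(out, basename))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$manifest <- file.path(config$out_dir, "manifest.json")
  invisible(out)
}
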