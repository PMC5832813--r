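#' The packaged flume treatment dataset
#'
#' 32 single-species flume treatments of six soft-sediment bioturbator
#' species (three functional groups, densities 13-382 individuals m-2,
#' body masses ~10 to ~970 mg AFDW), each with
#' body size, body mass (mg AFDW), estimated individual and population
#' metabolic rate, and the equilibrium mass of resuspended sediment
#' observed under a 0.18 Pa bed shear stress (mean of two replicate
#' runs), all with propagated 95% CIs.
#'
#' @return data.frame in the standard treatment schema (see
#'   [read_treatment_table()]).
#' @examples
#' head(flume_treatments())
#' @export
flume_treatments <- function() {
  path <- system.file("extdata", "flume_treatments.csv",
    package = "bioturbr", mustWork = TRUE
  )
  read_treatment_table(path)
}

#' Read a treatment table from CSV
#'
#' The standard schema is UTF-8, comma-separated, dot decimal, with a
#' header row of: species, functional_group, size_value, size_metric,
#' size_ci95, mass_mg_afdw, mass_ci95, I_mW, I_ci95, density_ind_m2,
#' Itot_mW_m2, Itot_ci95, Rtot_g_m2, Rtot_ci95.
#'
#' @param path CSV file path.
#' @param required columns that must be present; defaults to the full
#'   schema.
#' @return data.frame.
#' @export
read_treatment_table <- function(path, required = .treatment_columns) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("treatment table ", path, " lacks required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  tab
}

#' Write a treatment table to CSV
#'
#' Numeric columns are serialised at 6 significant digits, which makes
#' reports diff-stable across platforms and the write/read round trip
#' value-identical at that precision.
#'
#' @param table data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_treatment_table <- function(table, path) {
  out <- table
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- signif(out[[col]], 6)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a pipeline configuration
#'
#' Reads the YAML configuration (constants, control, metabolic model,
#' species size-to-mass conversion rules, temperature scenarios) and
#' turns it into package objects. With no argument, the packaged default
#' configuration is used.
#'
#' @param path YAML file; `NULL` for the packaged default.
#' @return list with elements `constants`, `control` (a
#'   [control_spec]), `metabolic_spec`, `conversion_rules` (named list
#'   of [mass_conversion_rule]s) and `scenarios` (list of
#'   [temperature_scenario]s).
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_config.yaml",
      package = "bioturbr", mustWork = TRUE
    )
  }
  raw <- yaml::read_yaml(path)
  const <- raw$constants
  ctl <- control_spec(
    mode = raw$control$mode,
    value = raw$control$value_g_m2,
    ci95 = raw$control$ci95
  )
  ms <- raw$metabolic_model
  spec <- metabolic_model_spec(
    form = ms$form,
    a = if (is.null(ms$a)) 0.011 else ms$a,
    b = if (is.null(ms$b)) 0.75 else ms$b,
    coefficients = if (is.null(ms$coefficients)) NULL else unlist(ms$coefficients),
    energy_density = const$energy_density_j_per_mg
  )
  rules <- lapply(names(raw$conversion_rules), function(sp) {
    r <- raw$conversion_rules[[sp]]
    mass_conversion_rule(sp, r$p, r$q)
  })
  names(rules) <- names(raw$conversion_rules)
  scenarios <- lapply(raw$scenarios, function(s) {
    temperature_scenario(
      t_target_c = s$t_target_c,
      t_ref_c = const$reference_temperature_c,
      activation_energy_ev = const$activation_energy_ev,
      label = s$label
    )
  })
  list(
    constants = const, control = ctl, metabolic_spec = spec,
    conversion_rules = rules, scenarios = scenarios
  )
}

#' Fit the full resuspension-scaling analysis
#'
#' Drives the regression stage end to end on a treatment table: the
#' simple model of resuspension on population metabolism, bidirectional
#' AIC stepwise selection across the functional-group variants, rank and
#' product-moment correlations, the high-leverage exclusion refit, and
#' the per-milliwatt (`R_BIO`) models. With no input, the packaged flume
#' dataset is analysed.
#'
#' @param table treatment table (data.frame); default the packaged
#'   dataset.
#' @param input optional CSV path read instead of `table`.
#' @param control a [control_spec].
#' @param k_leverage rows to drop in the leverage check.
#' @param out_dir optional directory; when given, coefficient tables,
#'   the stepwise trace and a plain-text report are written there.
#' @return an object of class `bturb_analysis`: list with `table`,
#'   `simple_fit`, `stepwise`, `correlations`, `leverage`, `rbio`.
#' @examples
#' res <- run_fit()
#' res$simple_fit
#' @export
run_fit <- function(table = NULL, input = NULL, control = control_spec(),
                    k_leverage = 2, out_dir = NULL) {
  if (!is.null(input)) table <- read_treatment_table(input)
  if (is.null(table)) table <- flume_treatments()
  tab <- assemble_treatment_table(table, control = control)
  tab$functional_group <- factor(tab$functional_group,
    levels = functional_group_levels
  )
  res <- structure(
    list(
      table = tab,
      simple_fit = fit_linear_model(tab, Rtot_g_m2 ~ Itot_mW_m2),
      stepwise = stepwise_select(tab, Rtot_g_m2 ~ functional_group * Itot_mW_m2),
      correlations = correlation_report(tab),
      leverage = leverage_exclusion_refit(tab, k_leverage),
      rbio = rbio_models(tab)
    ),
    class = "bturb_analysis"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    num6 <- function(d) {
      d[] <- lapply(d, function(x) if (is.numeric(x)) signif(x, 6) else x)
      d
    }
    utils::write.csv(num6(res$simple_fit$coefficients),
      file.path(out_dir, "simple_model_coefficients.csv"),
      row.names = FALSE
    )
    utils::write.csv(num6(res$stepwise$steps),
      file.path(out_dir, "stepwise_trace.csv"),
      row.names = FALSE
    )
    utils::write.csv(num6(res$correlations),
      file.path(out_dir, "correlations.csv"),
      row.names = FALSE
    )
    utils::write.csv(num6(res$rbio$trace$steps),
      file.path(out_dir, "rbio_stepwise_trace.csv"),
      row.names = FALSE
    )
    writeLines(utils::capture.output(print(res)), file.path(out_dir, "report.txt"))
  }
  res
}

#' @export
print.bturb_analysis <- function(x, ...) {
  cat("== Resuspension ~ population metabolism ==\n")
  print(x$simple_fit)
  cat("\n== Functional-group stepwise selection ==\n")
  print(x$stepwise)
  cat("\n== Correlations with resuspension ==\n")
  co <- x$correlations
  co[, c("estimate", "p_value")] <- signif(co[, c("estimate", "p_value")], 3)
  print(co, row.names = FALSE)
  cat(
    "\n== Leverage check: slope after dropping", x$leverage$effective_k,
    "highest-metabolism treatment(s) ==\n"
  )
  print(x$leverage$fit)
  cat("\n== Per-milliwatt biotic effect (R_BIO) ==\n")
  cat("mean R_BIO:", signif(x$rbio$mean_rbio, 4), "g per mW\n")
  print(x$rbio$trace)
  invisible(x)
}

#' Project fitted resuspension under temperature scenarios
#'
#' @param analysis a `bturb_analysis` from [run_fit()] (its simple-model
#'   coefficients are used), or a fit accepted by
#'   [project_resuspension()].
#' @param scenarios list of [temperature_scenario]s; default the
#'   packaged configuration's scenarios.
#' @param per_treatment include projected resuspension for every
#'   treatment of the analysed table?
#' @param out_dir optional directory for the scenario CSV.
#' @return the [projection_table()] data.frame.
#' @export
run_project <- function(analysis, scenarios = NULL, per_treatment = FALSE,
                        out_dir = NULL) {
  if (is.null(scenarios)) scenarios <- load_config()$scenarios
  fit <- if (inherits(analysis, "bturb_analysis")) analysis$simple_fit else analysis
  tab <- if (per_treatment) {
    if (!inherits(analysis, "bturb_analysis")) {
      stop("per_treatment projection needs a bturb_analysis", call. = FALSE)
    }
    analysis$table
  } else {
    NULL
  }
  out <- projection_table(fit, scenarios, table = tab)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    o <- out
    o[] <- lapply(o, function(x) if (is.numeric(x)) signif(x, 6) else x)
    utils::write.csv(o, file.path(out_dir, "projection.csv"), row.names = FALSE)
  }
  out
}

#' Simulate a synthetic flume study and write it to disk
#'
#' Deterministic per seed: identical configuration and seed yield
#' byte-identical files. A ground-truth sidecar (YAML) records the
#' generating parameters for downstream test harnesses.
#'
#' @param cfg a [generator_config].
#' @param out_dir output directory.
#' @return list with `table` and the written `paths`.
#' @export
run_simulate <- function(cfg, out_dir) {
  tab <- generate_table(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  table_path <- file.path(out_dir, "synthetic_treatments.csv")
  truth_path <- file.path(out_dir, "synthetic_truth.yaml")
  write_treatment_table(tab, table_path)
  truth <- attr(tab, "truth")
  truth$group_offsets <- as.list(truth$group_offsets)
  yaml::write_yaml(truth, truth_path)
  list(table = tab, paths = c(table = table_path, truth = truth_path))
}

#' Run a parameter-recovery study and write its report
#'
#' @param cfg a [generator_config].
#' @param n_replicates simulated studies to run.
#' @param out_dir optional output directory for the report CSVs.
#' @return a `recovery_report` (see [recovery_experiment()]).
#' @export
run_recover <- function(cfg, n_replicates, out_dir = NULL) {
  rep <- recovery_experiment(cfg, n_replicates)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rep$summary, file.path(out_dir, "recovery_summary.csv"),
      row.names = FALSE
    )
    utils::write.csv(rep$estimates, file.path(out_dir, "recovery_estimates.csv"),
      row.names = FALSE
    )
    writeLines(
      utils::capture.output(print(rep)),
      file.path(out_dir, "recovery_report.txt")
    )
  }
  rep
}
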