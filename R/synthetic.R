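#' Configuration for the synthetic flume-experiment generator
#'
#' Describes a flume study to simulate: a fixed design of
#' (species, functional group, body mass, density) treatments, the true
#' linear relation between resuspension and population metabolism
#' (`Rtot = c + offset[group] + d * Itot`), treatment-level Gaussian
#' noise, between-replicate noise (two replicate runs per treatment, as
#' in the flume protocol), and the metabolic model used to derive
#' individual rates from body mass. The default design is the
#' 32-treatment layout of the packaged flume dataset, so simulated
#' studies share its leverage structure (including the two
#' high-metabolism treatments); the default `c`, `d` and noise level are
#' those the packaged dataset exhibits.
#'
#' @param design data.frame with columns `species`, `functional_group`,
#'   `mass_mg_afdw`, `mass_ci95`, `density_ind_m2` (defaults to the
#'   packaged design; size columns are carried through when present).
#' @param c true abiotic intercept, g m-2.
#' @param d true metabolic slope, g m-2 per mW m-2.
#' @param group_offsets named additive offsets (g m-2) per functional
#'   group; default all zero.
#' @param sigma treatment-level residual SD, g m-2.
#' @param replicate_sigma between-replicate SD, g m-2. The flume data
#'   report no replicate variance; the default is a package choice (see
#'   the methods vignette).
#' @param metabolic_spec a [metabolic_model_spec] used to generate
#'   individual rates from the design masses.
#' @param heteroscedastic if `TRUE`, treatment-level SD scales with
#'   `Itot` (mean-preserving); for robustness studies only.
#' @param seed integer seed (mandatory).
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(design = default_design(),
                             c = 35, d = 0.36,
                             group_offsets = c(
                               deep = 0, intermediate_IBB = 0, shallow = 0
                             ),
                             sigma = 15, replicate_sigma = 5,
                             metabolic_spec = metabolic_model_spec(),
                             heteroscedastic = FALSE,
                             seed) {
  if (missing(seed)) stop("generator_config: a seed is mandatory", call. = FALSE)
  if (sigma < 0 || replicate_sigma < 0) {
    stop("generator_config: noise SDs must be non-negative", call. = FALSE)
  }
  if (!is.data.frame(design) || nrow(design) == 0) {
    stop("generator_config: design must be a non-empty data.frame", call. = FALSE)
  }
  needed <- c("species", "functional_group", "mass_mg_afdw", "density_ind_m2")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols)) {
    stop("generator_config: design lacks column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  offs <- group_offsets[unique(design$functional_group)]
  if (anyNA(offs)) {
    stop("generator_config: group_offsets must cover every functional group",
      call. = FALSE
    )
  }
  structure(
    list(
      design = design, c = c, d = d, group_offsets = group_offsets,
      sigma = sigma, replicate_sigma = replicate_sigma,
      metabolic_spec = metabolic_spec, heteroscedastic = heteroscedastic,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' The packaged 32-treatment flume design
#'
#' Species, functional group, body mass and density of the packaged
#' flume dataset, without its measured responses: the sampling frame for
#' the synthetic generator.
#'
#' @return data.frame with 32 rows.
#' @export
default_design <- function() {
  tab <- flume_treatments()
  tab[, c(
    "species", "functional_group", "size_value", "size_metric", "size_ci95",
    "mass_mg_afdw", "mass_ci95", "density_ind_m2"
  )]
}

#' Generate a synthetic flume treatment table
#'
#' Individual rates come from the metabolic spec applied to the design
#' masses (CIs propagated); `Itot = N * I`; each of the two replicate
#' runs draws `R_r = c + offset[group] + d * Itot + e_treatment +
#' e_replicate` with Gaussian noise; `Rtot_g_m2` is the replicate mean
#' and its CI is `1.96 * sd(replicates) / sqrt(2)`. Values are not
#' truncated at zero (truncation would bias parameter-recovery studies;
#' realistic configurations never approach zero). Deterministic per
#' seed.
#'
#' @param cfg a [generator_config].
#' @return a treatment table in the standard schema with a `truth`
#'   attribute (`c`, `d`, `group_offsets`, `sigma`, `replicate_sigma`,
#'   `seed`) and a `replicates` attribute (the two raw runs).
#' @examples
#' tab <- generate_table(generator_config(seed = 1))
#' @export
generate_table <- function(cfg) {
  if (!inherits(cfg, "generator_config")) {
    stop("generate_table: 'cfg' must be a generator_config", call. = FALSE)
  }
  des <- cfg$design
  n <- nrow(des)
  mass_ci <- if (is.null(des$mass_ci95)) 0 else des$mass_ci95
  I <- metabolic_rate(qci(des$mass_mg_afdw, mass_ci), cfg$metabolic_spec)
  Itot <- population_metabolic_rate(I, des$density_ind_m2)
  mu <- cfg$c + unname(cfg$group_offsets[des$functional_group]) +
    cfg$d * Itot$value
  sd_t <- if (cfg$heteroscedastic) {
    cfg$sigma * Itot$value / mean(Itot$value)
  } else {
    rep(cfg$sigma, n)
  }
  with_seed(cfg$seed, {
    e_treat <- stats::rnorm(n, 0, sd_t)
    reps <- vapply(
      1:2,
      function(r) mu + e_treat + stats::rnorm(n, 0, cfg$replicate_sigma),
      numeric(n)
    )
    out <- data.frame(
      species = des$species,
      functional_group = des$functional_group,
      size_value = if (is.null(des$size_value)) NA_real_ else des$size_value,
      size_metric = if (is.null(des$size_metric)) NA_character_ else des$size_metric,
      size_ci95 = if (is.null(des$size_ci95)) NA_real_ else des$size_ci95,
      mass_mg_afdw = des$mass_mg_afdw,
      mass_ci95 = rep_len(mass_ci, n),
      I_mW = I$value,
      I_ci95 = I$ci95,
      density_ind_m2 = des$density_ind_m2,
      Itot_mW_m2 = Itot$value,
      Itot_ci95 = Itot$ci95,
      Rtot_g_m2 = rowMeans(reps),
      Rtot_ci95 = 1.96 * apply(reps, 1, stats::sd) / sqrt(2),
      stringsAsFactors = FALSE
    )
    attr(out, "truth") <- list(
      c = cfg$c, d = cfg$d, group_offsets = cfg$group_offsets,
      sigma = cfg$sigma, replicate_sigma = cfg$replicate_sigma,
      seed = cfg$seed
    )
    attr(out, "replicates") <- reps
    out
  })
}

#' Parameter-recovery experiment
#'
#' Generates many synthetic studies from one configuration (seeds
#' `cfg$seed, cfg$seed + 1, ...` unless given), refits the simple model
#' to each, and reports bias, RMSE and 95% CI coverage for the true
#' `(c, d)`, together with how often the bidirectional stepwise
#' procedure selects each candidate model starting from the full
#' group-by-metabolism interaction. Coverage estimates from fewer than
#' 100 replicates are flagged unreliable.
#'
#' @param cfg a [generator_config].
#' @param n_replicates number of simulated studies.
#' @param seeds optional integer vector of seeds (length
#'   `n_replicates`).
#' @return an object of class `recovery_report`.
#' @export
recovery_experiment <- function(cfg, n_replicates, seeds = NULL) {
  if (is.null(seeds)) seeds <- cfg$seed + seq_len(n_replicates) - 1L
  if (length(seeds) != n_replicates) {
    stop("recovery_experiment: need one seed per replicate", call. = FALSE)
  }
  est <- data.frame(
    seed = seeds, c_hat = NA_real_, d_hat = NA_real_,
    c_covered = NA, d_covered = NA, sigma_hat = NA_real_,
    selected = NA_character_, stringsAsFactors = FALSE
  )
  for (i in seq_len(n_replicates)) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer(seeds[i])
    tab <- generate_table(cfg_i)
    fit <- fit_linear_model(tab, Rtot_g_m2 ~ Itot_mW_m2)
    co <- fit$coefficients
    est$c_hat[i] <- co$estimate[1]
    est$d_hat[i] <- co$estimate[2]
    est$c_covered[i] <- co$ci_low[1] <= cfg$c && cfg$c <= co$ci_high[1]
    est$d_covered[i] <- co$ci_low[2] <= cfg$d && cfg$d <= co$ci_high[2]
    est$sigma_hat[i] <- fit$sigma
    tr <- stepwise_select(tab, Rtot_g_m2 ~ functional_group * Itot_mW_m2)
    est$selected[i] <- deparse(tr$selected)
  }
  summary_tab <- data.frame(
    parameter = c("c", "d"),
    truth = c(cfg$c, cfg$d),
    bias = c(mean(est$c_hat) - cfg$c, mean(est$d_hat) - cfg$d),
    rmse = c(
      sqrt(mean((est$c_hat - cfg$c)^2)),
      sqrt(mean((est$d_hat - cfg$d)^2))
    ),
    coverage = c(mean(est$c_covered), mean(est$d_covered)),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      estimates = est,
      summary = summary_tab,
      selection_freq = sort(table(est$selected) / n_replicates, decreasing = TRUE),
      n_replicates = n_replicates,
      coverage_reliable = n_replicates >= 100
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery over", x$n_replicates, "simulated studies\n")
  s <- x$summary
  s[, c("bias", "rmse", "coverage")] <- signif(s[, c("bias", "rmse", "coverage")], 3)
  print(s, row.names = FALSE)
  if (!x$coverage_reliable) {
    cat("NOTE: coverage estimated from < 100 replicates; unreliable\n")
  }
  cat("stepwise selection frequencies:\n")
  print(round(x$selection_freq, 3))
  invisible(x)
}
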