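#' Temperature scenario for metabolic projection
#'
#' A reference temperature (the experimental temperature the fitted
#' coefficients refer to), a target temperature, and the activation
#' energy of the Boltzmann-Arrhenius scaling. Temperatures are given in
#' degrees Celsius and guarded to the physically plausible range for
#' coastal seawater (-5 to 45).
#'
#' @param t_target_c target water temperature, degrees Celsius.
#' @param t_ref_c reference temperature, degrees Celsius (default 18).
#' @param activation_energy_ev activation energy E in eV (default 0.65).
#' @param label scenario label for reports.
#' @return an object of class `temperature_scenario`.
#' @export
temperature_scenario <- function(t_target_c, t_ref_c = 18,
                                 activation_energy_ev = 0.65, label = "") {
  for (t in c(t_target_c, t_ref_c)) {
    if (t < -5 || t > 45) {
      stop("temperature_scenario: temperature ", t,
        " degrees C is outside the plausible range (-5 to 45)",
        call. = FALSE
      )
    }
  }
  structure(
    list(
      t_target_c = t_target_c, t_ref_c = t_ref_c,
      activation_energy_ev = activation_energy_ev,
      label = if (nzchar(label)) label else paste0(t_target_c, "C"),
      factor = arrhenius_factor(t_ref_c, t_target_c, activation_energy_ev)
    ),
    class = "temperature_scenario"
  )
}

#' @export
print.temperature_scenario <- function(x, ...) {
  cat(
    sprintf(
      "scenario '%s': %g -> %g degrees C (E = %g eV), metabolic factor %.3f (%+d%%)\n",
      x$label, x$t_ref_c, x$t_target_c, x$activation_energy_ev,
      x$factor, round(100 * (x$factor - 1))
    )
  )
  invisible(x)
}

#' Percent change in metabolic rate under a scenario
#'
#' `100 * (arrhenius_factor - 1)`. Reports round to the nearest whole
#' percent; the raw value is returned by default. The change is
#' antisymmetric in `1/T_ref - 1/T_target`, not in the Celsius
#' difference.
#'
#' @param scenario a [temperature_scenario].
#' @param rounded round to the nearest integer percent?
#' @return signed percentage.
#' @examples
#' percent_metabolic_change(temperature_scenario(7.2), rounded = TRUE) # -63
#' @export
percent_metabolic_change <- function(scenario, rounded = FALSE) {
  pct <- 100 * (scenario$factor - 1)
  if (rounded) round(pct) else pct
}

#' Project resuspension under a temperature scenario
#'
#' Evaluates `R_TOT = c + d * I_TOT(T_ref) * arrhenius_factor`, i.e. the
#' fitted linear resuspension model with the metabolic (biotic) term
#' scaled by the Boltzmann-Arrhenius factor. The abiotic intercept `c`
#' is temperature-invariant by assumption: only metabolism responds to
#' temperature, all other resuspension mechanisms are held fixed. The
#' factor is normalised to 1 at the reference temperature, so at
#' `T_target = T_ref` the projection equals the ordinary model
#' prediction.
#'
#' The reference-temperature population metabolic rate can be given
#' directly (`Itot_ref`) or computed from density, body mass and a
#' metabolic model spec.
#'
#' @param fit fitted coefficients: either a `bturb_fit` of the simple
#'   model or a numeric vector `c(intercept, slope)`.
#' @param scenario a [temperature_scenario].
#' @param Itot_ref population metabolic rate at the reference
#'   temperature, mW m-2.
#' @param N,M,spec alternative to `Itot_ref`: density (m-2), body mass
#'   (mg AFDW) and a [metabolic_model_spec]; then
#'   `Itot_ref = N * a * M^b`.
#' @return projected resuspension, g m-2 (vectorized over `Itot_ref`).
#' @examples
#' sc <- temperature_scenario(7.2)
#' project_resuspension(c(35.11, 0.36), sc, Itot_ref = 100)
#' @export
project_resuspension <- function(fit, scenario, Itot_ref = NULL,
                                 N = NULL, M = NULL, spec = NULL) {
  cd <- coef_cd(fit)
  if (is.null(Itot_ref)) {
    if (is.null(N) || is.null(M) || is.null(spec)) {
      stop("project_resuspension: give Itot_ref, or N, M and a metabolic spec",
        call. = FALSE
      )
    }
    if (any(M <= 0)) stop("project_resuspension: M must be positive", call. = FALSE)
    Itot_ref <- population_metabolic_rate(metabolic_rate(qci(M), spec), N)$value
  }
  cd[1] + cd[2] * Itot_ref * scenario$factor
}

# Extract (intercept, slope) from a simple fit or a length-2 numeric.
coef_cd <- function(fit) {
  if (inherits(fit, "bturb_fit")) {
    co <- fit$coefficients
    if (nrow(co) != 2) {
      stop("projection needs the simple model (intercept + one slope); got ",
        nrow(co), " coefficients",
        call. = FALSE
      )
    }
    co$estimate
  } else if (is.numeric(fit) && length(fit) == 2) {
    unname(fit)
  } else {
    stop("no fitted (c, d) coefficients available", call. = FALSE)
  }
}

#' Scenario projection table
#'
#' Per-scenario Boltzmann-Arrhenius factors, percent metabolic change
#' (raw and rounded to the whole percent used in reports), and, when a
#' treatment table is supplied, the projected resuspension for every
#' treatment.
#'
#' @param fit as in [project_resuspension()].
#' @param scenarios list of [temperature_scenario]s.
#' @param table optional treatment table; adds per-treatment projections.
#' @return data.frame (one row per scenario, or per scenario x treatment
#'   when `table` is given).
#' @export
projection_table <- function(fit, scenarios, table = NULL) {
  rows <- lapply(scenarios, function(sc) {
    base <- data.frame(
      label = sc$label,
      t_ref_c = sc$t_ref_c,
      t_target_c = sc$t_target_c,
      activation_energy_ev = sc$activation_energy_ev,
      factor = sc$factor,
      pct_metabolic_change = percent_metabolic_change(sc),
      pct_metabolic_change_rounded = percent_metabolic_change(sc, rounded = TRUE),
      stringsAsFactors = FALSE
    )
    if (is.null(table)) {
      return(base)
    }
    proj <- project_resuspension(fit, sc, Itot_ref = table$Itot_mW_m2)
    cbind(
      base[rep(1, nrow(table)), , drop = FALSE],
      data.frame(
        species = table$species,
        density_ind_m2 = table$density_ind_m2,
        Itot_mW_m2 = table$Itot_mW_m2,
        projected_Rtot_g_m2 = proj,
        stringsAsFactors = FALSE
      )
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
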