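#' Boltzmann's constant in eV per kelvin
#' @export
boltzmann_k <- 8.617e-5

#' Convert degrees Celsius to kelvin
#' @param t_c temperature in degrees Celsius.
#' @return temperature in kelvin.
#' @export
celsius_to_kelvin <- function(t_c) t_c + 273.15

#' Size measurement for one organism class
#'
#' Homogeneously sized individuals are characterised either by shell
#' length (mm, bivalves) or by wet weight (mg, the lugworm
#' *Arenicola marina*), with a 95% CI on the measurement.
#'
#' @param species species identifier (e.g. `"C. edule"`).
#' @param metric `"shell_length_mm"` or `"wet_weight_mg"`.
#' @param value positive size value.
#' @param ci95 95% CI half-width of the size measurement.
#' @return an object of class `size_measurement`.
#' @export
size_measurement <- function(species, metric = c("shell_length_mm", "wet_weight_mg"),
                             value, ci95 = 0) {
  metric <- match.arg(metric)
  if (any(value <= 0)) stop("size must be positive", call. = FALSE)
  structure(
    list(species = species, metric = metric, size = qci(value, ci95)),
    class = "size_measurement"
  )
}

#' Species-specific size-to-mass power law
#'
#' Body mass M (mg AFDW) is modelled as `p * size^q`. Coefficients are
#' configurable per species (see the packaged `default_config.yaml` for
#' placeholders calibrated to the flume dataset).
#'
#' @param species species identifier the rule applies to.
#' @param p positive multiplicative coefficient.
#' @param q exponent.
#' @return an object of class `mass_rule`.
#' @export
mass_conversion_rule <- function(species, p, q) {
  if (p <= 0) stop("mass_conversion_rule: p must be positive", call. = FALSE)
  structure(list(species = species, p = p, q = q), class = "mass_rule")
}

#' Convert a size measurement to body mass (mg AFDW)
#'
#' Applies the species' power law and propagates the measurement CI by
#' the delta method.
#'
#' @param m a [size_measurement].
#' @param rule a [mass_conversion_rule] for the same species.
#' @return a [qci] body mass in mg AFDW.
#' @examples
#' m <- size_measurement("L. balthica", "shell_length_mm", 15, 0.5)
#' convert_size_to_mass(m, mass_conversion_rule("L. balthica", 0.010068, 3))
#' @export
convert_size_to_mass <- function(m, rule) {
  if (!inherits(m, "size_measurement")) {
    stop("convert_size_to_mass: 'm' must be a size_measurement", call. = FALSE)
  }
  if (!inherits(rule, "mass_rule") || !identical(rule$species, m$species)) {
    stop("convert_size_to_mass: conversion rule is for species '",
      if (inherits(rule, "mass_rule")) rule$species else "?",
      "', measurement is for '", m$species, "'",
      call. = FALSE
    )
  }
  if (any(m$size$value <= 0)) stop("size must be positive", call. = FALSE)
  propagate_delta(function(s) rule$p * s^rule$q, m$size)
}

#' Individual metabolic-rate model specification
#'
#' Two forms are supported. The `allometric` form is the metabolic-theory
#' power law `I = a * M^b` (mW, with M in mg AFDW); the default exponent
#' is the canonical 3/4 and the default normalization is calibrated to
#' the packaged flume dataset. The `ln_linear_empirical` form accepts an
#' arbitrary coefficient table for a log-linear respiration model
#' (intercept, ln-mass, inverse temperature, trait indicators), evaluated
#' in energy-per-day units and converted to mW.
#'
#' @param form `"allometric"` or `"ln_linear_empirical"`.
#' @param a positive normalization constant (mW at 1 mg AFDW).
#' @param b allometric exponent (default 0.75).
#' @param coefficients named numeric vector for the ln-linear form.
#'   Recognised term names: `intercept`, `ln_mass` (log mg AFDW),
#'   `ln_mass_energy` (log of mass times `energy_density`, i.e. log J),
#'   `inv_temp` (1/T, per kelvin); any other name must be matched by an
#'   entry in the `traits` argument of [metabolic_rate()].
#' @param energy_density energy density of body tissue, J per mg AFDW.
#' @return an object of class `metabolic_spec`.
#' @export
metabolic_model_spec <- function(form = c("allometric", "ln_linear_empirical"),
                                 a = 0.011, b = 0.75, coefficients = NULL,
                                 energy_density = 21.5) {
  form <- match.arg(form)
  if (a <= 0) stop("metabolic_model_spec: a must be positive", call. = FALSE)
  if (energy_density <= 0) {
    stop("metabolic_model_spec: energy_density must be positive", call. = FALSE)
  }
  if (form == "ln_linear_empirical") {
    if (is.null(coefficients) || is.null(names(coefficients)) ||
      !("intercept" %in% names(coefficients))) {
      stop("ln_linear_empirical form needs a named coefficient vector ",
        "including 'intercept'",
        call. = FALSE
      )
    }
  }
  structure(
    list(
      form = form, a = a, b = b, coefficients = coefficients,
      energy_density = energy_density
    ),
    class = "metabolic_spec"
  )
}

# J day-1 to mW, exact.
.j_per_day_to_mw <- 1000 / 86400

#' Individual metabolic rate from body mass
#'
#' Evaluates the metabolic model at the given body mass and temperature
#' and propagates the mass CI by the delta method. The allometric form
#' returns `a * M^b` mW directly; the ln-linear form evaluates
#' `exp(sum(coef * term))` in J per day and converts by 1000/86400.
#'
#' @param mass a [qci] body mass in mg AFDW (positive).
#' @param spec a [metabolic_model_spec].
#' @param temperature_c water temperature in degrees Celsius (only used
#'   by ln-linear coefficient tables with an `inv_temp` term).
#' @param traits named list of indicator values for any coefficient term
#'   not among the built-ins.
#' @return a [qci] metabolic rate in mW.
#' @examples
#' metabolic_rate(qci(100), metabolic_model_spec(a = 0.01, b = 0.75))
#' @export
metabolic_rate <- function(mass, spec, temperature_c = 18, traits = NULL) {
  if (!is_qci(mass)) mass <- qci(mass)
  if (any(mass$value <= 0)) stop("metabolic_rate: mass must be positive", call. = FALSE)
  if (!inherits(spec, "metabolic_spec")) {
    stop("metabolic_rate: 'spec' must be a metabolic_model_spec", call. = FALSE)
  }
  if (spec$form == "allometric") {
    return(propagate_delta(function(M) spec$a * M^spec$b, mass))
  }
  coefs <- spec$coefficients
  t_k <- celsius_to_kelvin(temperature_c)
  builtin <- c("intercept", "ln_mass", "ln_mass_energy", "inv_temp")
  extra <- setdiff(names(coefs), builtin)
  missing_tr <- setdiff(extra, names(traits))
  if (length(missing_tr)) {
    stop("metabolic_rate: no trait value supplied for coefficient term(s): ",
      paste(missing_tr, collapse = ", "),
      call. = FALSE
    )
  }
  f <- function(M) {
    lp <- 0
    for (nm in names(coefs)) {
      term <- switch(nm,
        intercept = 1,
        ln_mass = log(M),
        ln_mass_energy = log(M * spec$energy_density),
        inv_temp = 1 / t_k,
        traits[[nm]]
      )
      lp <- lp + coefs[[nm]] * term
    }
    exp(lp) * .j_per_day_to_mw
  }
  propagate_delta(f, mass)
}

#' Boltzmann-Arrhenius temperature factor
#'
#' Multiplicative change in metabolic rate between a reference and a
#' target temperature under the Boltzmann-Arrhenius model
#' `exp(-E/k * (1/T - 1/T_ref))` with temperatures in kelvin. Equals 1 at
#' the reference temperature and is strictly increasing in temperature
#' for positive activation energy.
#'
#' @param t_ref_c reference temperature, degrees Celsius.
#' @param t_c target temperature, degrees Celsius.
#' @param activation_energy_ev activation energy E in eV (default 0.65,
#'   the standard metabolic-theory value for ectotherm respiration).
#' @return dimensionless positive factor.
#' @examples
#' arrhenius_factor(18, 7.2) # winter: ~0.37
#' arrhenius_factor(18, 21) # +3 C:   ~1.30
#' @export
arrhenius_factor <- function(t_ref_c, t_c, activation_energy_ev = 0.65) {
  t_ref <- celsius_to_kelvin(t_ref_c)
  t_k <- celsius_to_kelvin(t_c)
  if (any(t_ref <= 0) || any(t_k <= 0)) {
    stop("arrhenius_factor: temperatures must be above absolute zero", call. = FALSE)
  }
  exp(-activation_energy_ev / boltzmann_k * (1 / t_k - 1 / t_ref))
}
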