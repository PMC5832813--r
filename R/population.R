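#' Functional group of a study species
#'
#' Fixed mapping of the six study species to bioturbation functional
#' groups: deep-burrowing deposit feeders (*A. marina*), Intermediate
#' Burrowing Bivalves (*A. alba*, *L. balthica*, *S. plana*,
#' *R. philippinarum*), and shallow surface-dwelling bivalves
#' (*C. edule*). Unknown species are rejected.
#'
#' @param species character vector of species identifiers.
#' @return character vector with levels `deep`, `intermediate_IBB`,
#'   `shallow`.
#' @export
functional_group_for <- function(species) {
  map <- c(
    "A. marina" = "deep",
    "A. alba" = "intermediate_IBB",
    "L. balthica" = "intermediate_IBB",
    "S. plana" = "intermediate_IBB",
    "R. philippinarum" = "intermediate_IBB",
    "C. edule" = "shallow"
  )
  unknown <- setdiff(unique(species), names(map))
  if (length(unknown)) {
    stop("no functional-group mapping for species: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  unname(map[species])
}

functional_group_levels <- c("deep", "intermediate_IBB", "shallow")

#' Population metabolic rate
#'
#' Areal population metabolic rate as the product of the individual rate
#' and the population density, `I_TOT = N * I` (mW m-2). Density is an
#' experimental design variable and treated as error-free, so the CI
#' scales linearly with N.
#'
#' @param I individual metabolic rate, a [qci] in mW (non-negative).
#' @param N density, individuals per m2 (positive).
#' @return a [qci] in mW per m2.
#' @examples
#' population_metabolic_rate(qci(0.5, 0.1), 64)
#' @export
population_metabolic_rate <- function(I, N) {
  if (!is_qci(I)) I <- qci(I)
  if (any(N <= 0)) stop("population_metabolic_rate: N must be positive", call. = FALSE)
  if (any(I$value < 0)) {
    stop("population_metabolic_rate: I must be non-negative", call. = FALSE)
  }
  qci(N * I$value, N * I$ci95)
}

#' Defaunated-control specification
#'
#' The baseline resuspension against which the biotic effect is
#' measured. `global_mean` uses a single control value for every
#' treatment (the default: the mean over defaunated control runs);
#' `per_flume` uses each flume's own internal control, supplied as a
#' vector alongside the treatment table.
#'
#' @param mode `"global_mean"` or `"per_flume"`.
#' @param value control resuspension, g m-2 (positive), either scalar
#'   (global mean) or a per-treatment vector.
#' @param ci95 95% CI half-width of the control value.
#' @return an object of class `control_spec`.
#' @export
control_spec <- function(mode = c("global_mean", "per_flume"),
                         value = 32.25, ci95 = 1.73) {
  mode <- match.arg(mode)
  if (any(value <= 0)) stop("control_spec: control value must be positive", call. = FALSE)
  if (mode == "global_mean" && length(value) != 1) {
    stop("control_spec: global_mean mode takes a single control value", call. = FALSE)
  }
  structure(list(mode = mode, value = qci(value, ci95)), class = "control_spec")
}

#' Sediment resuspended per unit of population metabolic power
#'
#' `R_BIO = (R_TOT - R_CONTROL) / I_TOT` (g per mW). Negative values are
#' allowed: a treatment can resuspend less sediment than the defaunated
#' control.
#'
#' @param Rtot observed resuspended sediment, g m-2 (numeric vector).
#' @param Itot population metabolic rate, mW m-2 (positive).
#' @param control a [control_spec], or a numeric control value.
#' @return numeric vector in g per mW.
#' @examples
#' bioturbation_per_milliwatt(145.29, 206.06, control_spec())
#' @export
bioturbation_per_milliwatt <- function(Rtot, Itot, control = control_spec()) {
  if (is.numeric(control)) control <- control_spec(value = control, ci95 = 0)
  if (!inherits(control, "control_spec")) {
    stop("bioturbation_per_milliwatt: invalid control", call. = FALSE)
  }
  if (any(Itot <= 0)) {
    stop("bioturbation_per_milliwatt: I_TOT must be positive", call. = FALSE)
  }
  rc <- control$value$value
  if (control$mode == "per_flume" && length(rc) != length(Rtot)) {
    stop("per_flume control needs one value per treatment", call. = FALSE)
  }
  (Rtot - rc) / Itot
}

.treatment_columns <- c(
  "species", "functional_group", "size_value", "size_metric", "size_ci95",
  "mass_mg_afdw", "mass_ci95", "I_mW", "I_ci95", "density_ind_m2",
  "Itot_mW_m2", "Itot_ci95", "Rtot_g_m2", "Rtot_ci95"
)

#' Assemble the analysis-ready treatment table
#'
#' Fills every derived column of the standard treatment schema: body
#' mass from size (when conversion rules are supplied), individual rate
#' from mass (when a metabolic spec is supplied), population metabolic
#' rate `I_TOT = N * I`, and the per-milliwatt biotic effect `R_BIO`.
#' When an `Itot_mW_m2` column is already present it is kept, and rows
#' where `N * I` disagrees with it beyond `itot_tolerance` (printed
#' rounding of I explains small gaps) are flagged with a warning; the
#' flagged row numbers are stored in `attr(., "validation")`.
#'
#' @param rows data.frame with at least `species`, `density_ind_m2`, and
#'   either (`mass_mg_afdw`, `I_mW`) or (`size_value`, `size_metric`)
#'   plus conversion rules; `Rtot_g_m2` for the response.
#' @param control a [control_spec] used for the `R_BIO` column.
#' @param conversion_rules named list of [mass_conversion_rule]s keyed by
#'   species (only needed when masses are missing).
#' @param metabolic_spec a [metabolic_model_spec] (only needed when
#'   individual rates are missing).
#' @param itot_tolerance consistency tolerance between `N * I` and a
#'   supplied `Itot_mW_m2`, in mW m-2.
#' @return the completed data.frame (row order preserved) with an added
#'   `R_BIO` column and a `validation` attribute listing flagged rows.
#' @export
assemble_treatment_table <- function(rows, control = control_spec(),
                                     conversion_rules = NULL,
                                     metabolic_spec = NULL,
                                     itot_tolerance = 0.5) {
  if (!is.data.frame(rows)) stop("'rows' must be a data.frame", call. = FALSE)
  if (nrow(rows) == 0) {
    out <- rows
    for (col in c(.treatment_columns, "R_BIO")) {
      if (is.null(out[[col]])) out[[col]] <- numeric(0)
    }
    attr(out, "validation") <- list(flagged_itot = integer(0))
    return(out)
  }
  if (is.null(rows$species) || is.null(rows$density_ind_m2)) {
    stop("treatment rows need 'species' and 'density_ind_m2' columns", call. = FALSE)
  }
  out <- rows
  if (is.null(out$functional_group) || anyNA(out$functional_group)) {
    out$functional_group <- functional_group_for(out$species)
  }
  if (is.null(out$mass_mg_afdw)) {
    if (is.null(conversion_rules)) {
      stop("rows lack 'mass_mg_afdw' and no conversion rules were given", call. = FALSE)
    }
    masses <- lapply(seq_len(nrow(out)), function(i) {
      sp <- out$species[i]
      rule <- conversion_rules[[sp]]
      if (is.null(rule)) stop("no conversion rule for species: ", sp, call. = FALSE)
      m <- size_measurement(sp, out$size_metric[i], out$size_value[i],
        ci95 = if (is.null(out$size_ci95)) 0 else out$size_ci95[i]
      )
      convert_size_to_mass(m, rule)
    })
    out$mass_mg_afdw <- vapply(masses, function(q) q$value, numeric(1))
    out$mass_ci95 <- vapply(masses, function(q) q$ci95, numeric(1))
  }
  if (is.null(out$I_mW)) {
    if (is.null(metabolic_spec)) {
      stop("rows lack 'I_mW' and no metabolic spec was given", call. = FALSE)
    }
    I <- metabolic_rate(qci(out$mass_mg_afdw, out$mass_ci95), metabolic_spec)
    out$I_mW <- I$value
    out$I_ci95 <- I$ci95
  }
  itot <- population_metabolic_rate(
    qci(out$I_mW, if (is.null(out$I_ci95)) 0 else out$I_ci95),
    out$density_ind_m2
  )
  flagged <- integer(0)
  if (is.null(out$Itot_mW_m2)) {
    out$Itot_mW_m2 <- itot$value
    out$Itot_ci95 <- itot$ci95
  } else {
    flagged <- which(abs(itot$value - out$Itot_mW_m2) > itot_tolerance)
    if (length(flagged)) {
      warning(
        "N * I disagrees with Itot_mW_m2 beyond ", itot_tolerance,
        " mW m-2 in row(s): ", paste(flagged, collapse = ", ")
      )
    }
  }
  if (!is.null(out$Rtot_g_m2)) {
    out$R_BIO <- bioturbation_per_milliwatt(out$Rtot_g_m2, out$Itot_mW_m2, control)
  }
  attr(out, "validation") <- list(flagged_itot = flagged)
  attr(out, "control") <- control
  out
}
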