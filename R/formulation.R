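#' Percent production yield
#'
#' `100 * actual / initial`, comparing the recovered dry product mass to the
#' total mass of drug plus excipients charged. Values above 100% are
#' possible in practice (residual solvent or moisture) and are flagged with
#' a warning rather than rejected.
#'
#' @param actual_mass Recovered product mass, mg (> 0).
#' @param initial_total_mass Total input mass of drug + excipients, mg (> 0).
#' @return Yield in percent.
#' @examples
#' percent_yield(500, 1000) # 50
#' @export
percent_yield <- function(actual_mass, initial_total_mass) {
  if (!is.numeric(actual_mass) || !is.numeric(initial_total_mass) ||
      anyNA(c(actual_mass, initial_total_mass)) ||
      any(c(actual_mass, initial_total_mass) <= 0)) {
    stop("masses must be strictly positive", call. = FALSE)
  }
  y <- 100 * actual_mass / initial_total_mass
  if (any(y > 100)) {
    warning("yield exceeds 100% (", paste(sprintf("%.2f", y[y > 100]),
            collapse = ", "), "%); check for residual solvent or moisture",
            call. = FALSE)
  }
  y
}

#' HPLC drug content percent
#'
#' `100 * (sample peak area * standard concentration) /
#' (standard peak area * nominal concentration)`: the single-point external
#' standard quantification used for content uniformity.
#'
#' @param sample_peak_area,standard_peak_area Peak areas (same units, > 0).
#' @param standard_concentration,nominal_concentration Concentrations in
#'   mg/mL (> 0).
#' @return Drug content in percent of nominal.
#' @export
drug_content_percent <- function(sample_peak_area, standard_peak_area,
                                 standard_concentration,
                                 nominal_concentration) {
  vals <- c(sample_peak_area, standard_peak_area, standard_concentration,
            nominal_concentration)
  if (!is.numeric(vals) || anyNA(vals) || any(vals <= 0)) {
    stop("peak areas and concentrations must be strictly positive",
         call. = FALSE)
  }
  100 * (sample_peak_area * standard_concentration) /
    (standard_peak_area * nominal_concentration)
}

#' Mass of a component equimolar to a reference component
#'
#' Converts a reference mass to the mass of another substance containing the
#' same number of moles: `reference_mass * target_molar_mass /
#' reference_molar_mass`.
#'
#' @param reference_mass Reference component mass, mg (> 0).
#' @param reference_molar_mass Reference molar mass, g/mol (> 0).
#' @param target_molar_mass Target molar mass, g/mol (> 0).
#' @return Target mass in mg.
#' @examples
#' equimolar_mass(300, 395.41, 40.00) # NaOH equimolar to 300 mg cefdinir
#' @export
equimolar_mass <- function(reference_mass, reference_molar_mass,
                           target_molar_mass) {
  vals <- c(reference_mass, reference_molar_mass, target_molar_mass)
  if (!is.numeric(vals) || anyNA(vals) || any(vals <= 0)) {
    stop("masses and molar masses must be strictly positive", call. = FALSE)
  }
  reference_mass * target_molar_mass / reference_molar_mass
}

#' Drug loading, percent w/w
#'
#' `100 * drug / (drug + carrier)`.
#'
#' @param drug_mass Drug mass, mg (>= 0).
#' @param carrier_mass Carrier (or total excipient) mass, mg (>= 0).
#' @return Drug loading in percent w/w.
#' @examples
#' drug_loading_percent(300, 507.2) # SBA-15 system, ~37.2% w/w
#' @export
drug_loading_percent <- function(drug_mass, carrier_mass) {
  if (!is.numeric(drug_mass) || !is.numeric(carrier_mass) ||
      anyNA(c(drug_mass, carrier_mass)) || drug_mass < 0 || carrier_mass < 0) {
    stop("masses must be non-negative", call. = FALSE)
  }
  if (drug_mass + carrier_mass == 0) {
    stop("drug and carrier masses cannot both be zero", call. = FALSE)
  }
  100 * drug_mass / (drug_mass + carrier_mass)
}

#' Load formulation compositions from YAML
#'
#' Reads a compositions file of the bundled shape: a `drug` name and a
#' `formulations` map of formulation id to `label` and `components`
#' (component name to mass in mg).
#'
#' @param path Path to the YAML file; defaults to the bundled reference
#'   compositions.
#' @return A list of class `"compositions"` with elements `drug` and
#'   `formulations`.
#' @export
load_compositions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "compositions.yaml", package = "hspscreen",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) {
    stop("compositions file not found: ", path, call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  if (is.null(y$drug) || is.null(y$formulations)) {
    stop("compositions file ", path,
         " must define 'drug' and 'formulations'", call. = FALSE)
  }
  for (id in names(y$formulations)) {
    comp <- y$formulations[[id]]$components
    if (is.null(comp) || length(comp) == 0L) {
      stop("formulation ", id, " has no components", call. = FALSE)
    }
    masses <- unlist(comp)
    if (any(!is.numeric(masses)) || any(masses <= 0)) {
      stop("formulation ", id, " has non-positive component masses",
           call. = FALSE)
    }
    if (!(y$drug %in% names(comp))) {
      stop("formulation ", id, " does not contain the drug component '",
           y$drug, "'", call. = FALSE)
    }
  }
  structure(y, class = "compositions")
}

#' Molar-ratio check for a formulation
#'
#' Reports the molar ratio actually implied by the component masses,
#' normalised so the first non-drug component is 1. Useful for checking
#' nominal "1:1:1" co-amorphous compositions against what was weighed.
#'
#' @param masses Named numeric vector of component masses, mg.
#' @param molar_masses Named numeric vector of molar masses, g/mol, covering
#'   every component.
#' @return A tibble with columns `component`, `mass_mg`, `molar_mass`,
#'   `mmol` and `ratio`.
#' @export
stoichiometry_check <- function(masses, molar_masses) {
  stopifnot(is.numeric(masses), !is.null(names(masses)),
            is.numeric(molar_masses), !is.null(names(molar_masses)))
  missing_mm <- setdiff(names(masses), names(molar_masses))
  if (length(missing_mm) > 0) {
    stop("no molar mass supplied for: ", paste(missing_mm, collapse = ", "),
         call. = FALSE)
  }
  mm <- molar_masses[names(masses)]
  mmol <- masses / mm
  ref <- if (length(mmol) > 1) mmol[[2]] else mmol[[1]]
  tibble::tibble(component = names(masses), mass_mg = unname(masses),
                 molar_mass = unname(mm), mmol = unname(mmol),
                 ratio = unname(mmol / ref))
}
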