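#' Context for Flory-Huggins calculations
#'
#' @param drug_molar_volume Molar volume of the drug, cm^3/mol (Vm). The
#'   lattice model used here takes the drug's Vm only; excipient molar
#'   volumes do not enter.
#' @param temperature Absolute temperature in K (default 298).
#' @param gas_constant Gas constant in J/(mol K) (default 8.314).
#' @return An object of class `"chi_context"`.
#' @export
chi_context <- function(drug_molar_volume, temperature = 298,
                        gas_constant = 8.314) {
  if (missing(drug_molar_volume) || !is.numeric(drug_molar_volume) ||
      length(drug_molar_volume) != 1L || is.na(drug_molar_volume) ||
      drug_molar_volume <= 0) {
    stop("drug_molar_volume (cm^3/mol) must be a single positive number; ",
         "estimate it with fedors_molar_volume() if unknown", call. = FALSE)
  }
  stopifnot(is.numeric(temperature), temperature > 0,
            is.numeric(gas_constant), gas_constant > 0)
  structure(list(drug_molar_volume = drug_molar_volume,
                 temperature = temperature, gas_constant = gas_constant),
            class = "chi_context")
}

#' Flory-Huggins interaction parameter from solubility parameters
#'
#' `chi = Vm * (delta_t_drug - delta_t_excipient)^2 / (R T)`, with total
#' solubility parameters in MPa^0.5 and Vm in cm^3/mol (MPa cm^3 = J, so chi
#' is dimensionless). Inorganic excipients are outside the lattice model and
#' return `NA`.
#'
#' @param drug,excipient [substance()] objects.
#' @param context A [chi_context()] carrying the drug's molar volume.
#' @return chi (dimensionless), or `NA` for inorganic excipients.
#' @export
flory_huggins_chi <- function(drug, excipient, context) {
  stopifnot(inherits(drug, "substance"), inherits(excipient, "substance"),
            inherits(context, "chi_context"))
  if (excipient$inorganic) return(NA_real_)
  dt <- total_parameter(drug) - total_parameter(excipient)
  context$drug_molar_volume * dt^2 /
    (context$gas_constant * context$temperature)
}

#' Classify a pair by its Flory-Huggins parameter
#'
#' @param chi Interaction parameter (dimensionless, non-negative) or `NA`.
#' @param thresholds A [miscibility_thresholds()] object.
#' @return One of `"miscible"`, `"not_miscible"`, `"not_applicable"`.
#' @export
classify_by_chi <- function(chi, thresholds = miscibility_thresholds()) {
  stopifnot(inherits(thresholds, "miscibility_thresholds"))
  if (is.na(chi)) return("not_applicable")
  if (!is.numeric(chi) || chi < 0) {
    stop("chi must be non-negative or NA", call. = FALSE)
  }
  if (chi < thresholds$chi_miscible) "miscible" else "not_miscible"
}

#' Assess one drug-excipient pair
#'
#' Computes Ra, total solubility parameters, chi and both categorical
#' classifications for a single pair. If the excipient carries literature
#' (printed) Ra or chi values that disagree with the recomputed ones, a
#' discrepancy note is attached rather than silently adopting either value.
#'
#' @param drug A [substance()] with role `"drug"`.
#' @param excipient A [substance()].
#' @param context A [chi_context()].
#' @param thresholds A [miscibility_thresholds()].
#' @return A one-row tibble (PairAssessment).
#' @export
assess_pair <- function(drug, excipient, context,
                        thresholds = miscibility_thresholds()) {
  stopifnot(inherits(drug, "substance"))
  if (!identical(drug$role, "drug")) {
    stop("assess_pair() expects a substance with role 'drug' as its first ",
         "argument (got role '", drug$role, "')", call. = FALSE)
  }
  ra <- interaction_radius(drug, excipient)
  chi <- flory_huggins_chi(drug, excipient, context)
  notes <- character(0)
  if (!is.null(excipient$printed_ra) && !is.na(excipient$printed_ra) &&
      abs(excipient$printed_ra - ra) > 0.05) {
    notes <- c(notes, sprintf(
      "literature Ra %.2f differs from Ra %.2f recomputed from the same components",
      excipient$printed_ra, ra))
  }
  if (!is.null(excipient$printed_chi) && !is.na(excipient$printed_chi) &&
      !is.na(chi) && abs(excipient$printed_chi - chi) > 0.05) {
    notes <- c(notes, sprintf(
      "literature chi %.3f differs from chi %.3f recomputed with Vm %.1f cm^3/mol",
      excipient$printed_chi, chi, context$drug_molar_volume))
  }
  exc_name <- excipient$name
  exc_role <- excipient$role
  exc_hsp <- excipient$hsp
  dt_exc <- total_parameter(excipient)
  tibble::tibble(
    excipient = exc_name,
    role = exc_role,
    delta_d = exc_hsp[["delta_d"]],
    delta_p = exc_hsp[["delta_p"]],
    delta_h = exc_hsp[["delta_h"]],
    ra = ra,
    ra_class = classify_by_ra(ra, thresholds),
    delta_t_drug = total_parameter(drug),
    delta_t_excipient = dt_exc,
    chi = chi,
    chi_class = classify_by_chi(chi, thresholds),
    notes = paste(notes, collapse = "; ")
  )
}

#' Screen a drug against a panel of candidate excipients
#'
#' Runs [assess_pair()] for every excipient, sorts assessments by ascending
#' Ra (chi, then name, as tie-breaks, so the order is total and stable) and
#' picks the best candidate within each role present.
#'
#' @param drug A [substance()] with role `"drug"`.
#' @param excipients Non-empty list of [substance()] objects with unique
#'   names.
#' @param context A [chi_context()].
#' @param thresholds A [miscibility_thresholds()].
#' @return An object of class `"screening_report"`.
#' @export
screen <- function(drug, excipients, context,
                   thresholds = miscibility_thresholds()) {
  if (!is.list(excipients) || length(excipients) == 0L) {
    stop("excipients must be a non-empty list of substances", call. = FALSE)
  }
  nms <- vapply(excipients, function(s) s$name, character(1))
  if (anyDuplicated(nms)) {
    stop("duplicate excipient name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  rows <- do.call(rbind, lapply(excipients, assess_pair, drug = drug,
                                context = context, thresholds = thresholds))
  ord <- order(rows$ra, rows$chi, rows$excipient, method = "radix",
               na.last = TRUE)
  rows <- rows[ord, , drop = FALSE]
  best <- lapply(split(rows, rows$role), function(d) d$excipient[[1]])
  structure(list(drug = drug$name, context = context,
                 thresholds = thresholds, assessments = rows,
                 best_per_role = best),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Miscibility screen: %s vs %d excipient(s)\n", x$drug,
              nrow(x$assessments)))
  cat(sprintf("  Vm(drug) = %.1f cm^3/mol, T = %.0f K; Ra bounds %g/%g MPa^0.5, chi bound %g\n",
              x$context$drug_molar_volume, x$context$temperature,
              x$thresholds$ra_miscible, x$thresholds$ra_immiscible,
              x$thresholds$chi_miscible))
  d <- x$assessments
  for (i in seq_len(nrow(d))) {
    cat(sprintf("  %-18s %-18s Ra %5.2f (%s)  chi %s (%s)\n",
                d$excipient[[i]], paste0("[", d$role[[i]], "]"), d$ra[[i]],
                d$ra_class[[i]],
                ifelse(is.na(d$chi[[i]]), "   NA",
                       sprintf("%5.3f", d$chi[[i]])),
                d$chi_class[[i]]))
  }
  cat("  Best per role:",
      paste(sprintf("%s = %s", names(x$best_per_role),
                    unlist(x$best_per_role)), collapse = "; "), "\n")
  invisible(x)
}

report_table <- function(report) {
  d <- report$assessments
  tibble::tibble(
    excipient = d$excipient,
    role = d$role,
    delta_d = sprintf("%.2f", d$delta_d),
    delta_p = sprintf("%.2f", d$delta_p),
    delta_h = sprintf("%.2f", d$delta_h),
    ra = sprintf("%.2f", d$ra),
    ra_class = d$ra_class,
    delta_t = sprintf("%.2f", d$delta_t_excipient),
    chi = ifelse(is.na(d$chi), "NA", sprintf("%.3f", d$chi)),
    chi_class = d$chi_class,
    notes = d$notes
  )
}

#' Write a screening report as CSV
#'
#' Columns follow the conventional reporting order: name, the three Hansen
#' components, Ra and its class, the total parameter, chi and its class.
#' Numbers are rounded to report precision (2 decimals for parameters, 3 for
#' chi); rerunning with identical inputs yields a byte-identical file.
#'
#' @param report A [screen()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "screening_report"))
  utils::write.csv(report_table(report), path, row.names = FALSE,
                   quote = TRUE, eol = "\n")
  invisible(path)
}

#' Render a screening report as Markdown
#'
#' @param report A [screen()] result.
#' @return Character vector of Markdown lines.
#' @export
report_markdown <- function(report) {
  stopifnot(inherits(report, "screening_report"))
  d <- report_table(report)
  header <- c(
    sprintf("## Miscibility screen: %s", report$drug),
    "",
    sprintf("Drug molar volume %.1f cm^3/mol; T = %.0f K; Ra bounds %g/%g MPa^0.5; chi bound %g.",
            report$context$drug_molar_volume, report$context$temperature,
            report$thresholds$ra_miscible, report$thresholds$ra_immiscible,
            report$thresholds$chi_miscible),
    ""
  )
  cols <- c("excipient", "role", "delta_d", "delta_p", "delta_h", "ra",
            "ra_class", "delta_t", "chi", "chi_class")
  tab <- c(paste0("| ", paste(cols, collapse = " | "), " |"),
           paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|"),
           vapply(seq_len(nrow(d)), function(i) {
             paste0("| ", paste(unlist(d[i, cols]), collapse = " | "), " |")
           }, character(1)))
  best <- sprintf("- best %s: %s", names(report$best_per_role),
                  unlist(report$best_per_role))
  notes <- d$notes[nzchar(d$notes)]
  note_block <- if (length(notes) > 0) {
    c("", "### Discrepancy notes", "", paste0("- ", notes))
  } else character(0)
  c(header, tab, "", "### Best per role", "", best, note_block)
}
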