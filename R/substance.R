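#' A named drug or excipient
#'
#' Bundles a substance name, its formulation role, Hansen components and
#' optional molar properties into one object consumed by the screening
#' functions.
#'
#' @param name Substance name (single string).
#' @param role One of `"drug"`, `"polymer"`, `"mesoporous_carrier"`,
#'   `"coformer"`, `"other"`.
#' @param hsp An [hsp()] object.
#' @param molar_volume Molar volume Vm in cm^3/mol, or `NULL`. Only the
#'   drug's Vm enters the Flory-Huggins calculation.
#' @param molar_mass Molar mass in g/mol, or `NULL`.
#' @param inorganic Logical; inorganic carriers (e.g. mesoporous silica)
#'   are excluded from the Flory-Huggins lattice model and receive chi = NA.
#' @param printed_ra,printed_chi Optional literature values carried for
#'   documentation and discrepancy reporting only; never used as inputs to
#'   any computation.
#'
#' @return An object of class `"substance"`.
#' @examples
#' substance("cefdinir", "drug", hsp(17.29, 8.2, 11.2), molar_mass = 395.41)
#' @export
substance <- function(name, role = c("drug", "polymer", "mesoporous_carrier",
                                     "coformer", "other"),
                      hsp, molar_volume = NULL, molar_mass = NULL,
                      inorganic = FALSE, printed_ra = NULL,
                      printed_chi = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  role <- match.arg(role)
  h <- as_hsp(hsp)
  chk_pos <- function(x, what) {
    if (!is.null(x) && !is.na(x) && (!is.numeric(x) || x <= 0)) {
      stop(what, " must be strictly positive when supplied", call. = FALSE)
    }
  }
  chk_pos(molar_volume, "molar_volume")
  chk_pos(molar_mass, "molar_mass")
  structure(list(name = name, role = role, hsp = h,
                 molar_volume = molar_volume, molar_mass = molar_mass,
                 inorganic = isTRUE(inorganic),
                 printed_ra = printed_ra, printed_chi = printed_chi),
            class = "substance")
}

#' @export
print.substance <- function(x, ...) {
  cat(sprintf("<substance> %s (%s%s)\n", x$name, x$role,
              if (x$inorganic) ", inorganic" else ""))
  cat(sprintf("  HSP: (%.2f, %.2f, %.2f) MPa^0.5; delta_t = %.2f\n",
              x$hsp[["delta_d"]], x$hsp[["delta_p"]], x$hsp[["delta_h"]],
              total_parameter(x)))
  if (!is.null(x$molar_volume)) {
    cat(sprintf("  Vm: %.1f cm^3/mol\n", x$molar_volume))
  }
  if (!is.null(x$molar_mass)) {
    cat(sprintf("  M: %.2f g/mol\n", x$molar_mass))
  }
  invisible(x)
}

#' Tabulate a list of substances
#'
#' @param substances List of [substance()] objects.
#' @return A tibble with one row per substance.
#' @export
substances_tibble <- function(substances) {
  stopifnot(is.list(substances))
  tibble::tibble(
    name = vapply(substances, function(s) s$name, character(1)),
    role = vapply(substances, function(s) s$role, character(1)),
    delta_d = vapply(substances, function(s) s$hsp[["delta_d"]], numeric(1)),
    delta_p = vapply(substances, function(s) s$hsp[["delta_p"]], numeric(1)),
    delta_h = vapply(substances, function(s) s$hsp[["delta_h"]], numeric(1)),
    delta_t = vapply(substances, total_parameter, numeric(1)),
    molar_mass = vapply(substances, function(s)
      if (is.null(s$molar_mass)) NA_real_ else s$molar_mass, numeric(1)),
    inorganic = vapply(substances, function(s) s$inorganic, logical(1))
  )
}
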