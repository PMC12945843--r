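#' Load a group-contribution increment table
#'
#' Returns the bundled table of functional-group increments: Hoftyzer-Van
#' Krevelen molar attraction constants (`Fd`, `Fp`, in MPa^0.5 cm^3/mol),
#' hydrogen-bond cohesion energies (`Eh`, J/mol) and Fedors molar volume
#' increments (`delta_v`, cm^3/mol). Custom tables with the same columns can
#' be supplied via `path`.
#'
#' @param scheme Scheme name; only `"hvk_fedors"` is bundled.
#' @param path Optional path to a user CSV with columns
#'   `label,smarts,priority,Fd,Fp,Eh,delta_v,heavy_atoms`.
#' @return A tibble of class `"gc_table"`, ordered by matching priority.
#' @export
group_contribution_table <- function(scheme = "hvk_fedors", path = NULL) {
  if (is.null(path)) {
    if (!identical(scheme, "hvk_fedors")) {
      stop("unknown group-contribution scheme: ", scheme, call. = FALSE)
    }
    path <- system.file("extdata", "groups_hvk_fedors.csv",
                        package = "hspscreen", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("label", "priority", "Fd", "Fp", "Eh", "delta_v", "heavy_atoms")
  if (!all(need %in% names(tab))) {
    stop("group table ", path, " lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("group table is empty: ", path, call. = FALSE)
  if (anyDuplicated(tab$label)) {
    stop("group table labels must be unique", call. = FALSE)
  }
  tab <- tab[order(tab$priority), , drop = FALSE]
  structure(tibble::as_tibble(tab), class = c("gc_table", class(tibble::tibble())),
            scheme = scheme,
            citation = paste("Hoftyzer-Van Krevelen attraction constants;",
                             "Fedors (1974) volume increments"))
}

check_fragments <- function(fragments, table) {
  if (length(fragments) == 0L ||
      (is.numeric(fragments) && all(fragments == 0))) {
    stop("fragment set is empty; at least one group with count > 0 is ",
         "required", call. = FALSE)
  }
  if (!is.numeric(fragments) || is.null(names(fragments))) {
    stop("fragments must be a named numeric vector of group counts",
         call. = FALSE)
  }
  if (any(fragments < 0) || any(fragments != round(fragments))) {
    stop("fragment counts must be non-negative integers", call. = FALSE)
  }
  unknown <- setdiff(names(fragments), table$label)
  if (length(unknown) > 0L) {
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  fragments[fragments > 0]
}

#' Fedors molar volume from functional-group counts
#'
#' Sums the Fedors volume increments over the supplied group multiset:
#' `Vm = sum(count_i * delta_v_i)` in cm^3/mol.
#'
#' @param fragments Named numeric vector of group counts (labels from the
#'   table).
#' @param table A [group_contribution_table()].
#' @return Molar volume in cm^3/mol.
#' @examples
#' tab <- group_contribution_table()
#' fedors_molar_volume(c(CH3 = 1, CH2 = 1, OH = 1), tab) # ethanol
#' @export
fedors_molar_volume <- function(fragments, table = group_contribution_table()) {
  fr <- check_fragments(fragments, table)
  dv <- stats::setNames(table$delta_v, table$label)
  v <- sum(fr * dv[names(fr)])
  if (v <= 0) {
    stop("Fedors volume sum is non-positive (", signif(v, 4),
         " cm^3/mol); the fragment set is chemically implausible",
         call. = FALSE)
  }
  v
}

#' Hoftyzer-Van Krevelen Hansen components from functional-group counts
#'
#' Computes the three Hansen components from molar attraction constants:
#' `delta_d = sum(F_d) / V`, `delta_p = sqrt(sum(F_p^2)) / V`,
#' `delta_h = sqrt(sum(E_h) / V)`, with the sums running over group
#' occurrences and V the molar volume in cm^3/mol.
#'
#' @inheritParams fedors_molar_volume
#' @param molar_volume Molar volume V in cm^3/mol (e.g. from
#'   [fedors_molar_volume()]).
#' @return An [hsp()] object.
#' @export
hvk_hsp <- function(fragments, table = group_contribution_table(),
                    molar_volume) {
  fr <- check_fragments(fragments, table)
  if (!is.numeric(molar_volume) || length(molar_volume) != 1L ||
      is.na(molar_volume) || molar_volume <= 0) {
    stop("molar_volume must be a single positive number (cm^3/mol)",
         call. = FALSE)
  }
  idx <- match(names(fr), table$label)
  fd_sum <- sum(fr * table$Fd[idx])
  # each of the `count` occurrences of a group contributes Fp^2 to the sum
  fp2_sum <- sum(fr * table$Fp[idx]^2)
  eh_sum <- sum(fr * table$Eh[idx])
  hsp(max(fd_sum, 0) / molar_volume,
      sqrt(fp2_sum) / molar_volume,
      sqrt(max(eh_sum, 0) / molar_volume))
}

#' Molar mass from a molecular formula
#'
#' @param formula Hill-notation molecular formula string, e.g.
#'   `"C14H13N5O5S2"`.
#' @return Molar mass in g/mol, from the bundled IUPAC standard atomic
#'   weights.
#' @examples
#' molar_mass("H2O")        # 18.015
#' molar_mass("C6H14N4O2")  # L-arginine, 174.20
#' @export
molar_mass <- function(formula) {
  counts <- parse_formula(formula)
  w <- atomic_weights()
  unknown <- setdiff(names(counts), names(w))
  if (length(unknown) > 0L) {
    stop("element(s) not in the bundled atomic-weight table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sum(counts * w[names(counts)])
}

#' Parse a Hill-notation molecular formula
#'
#' @param formula Formula string such as `"C14H13N5O5S2"`.
#' @return Named integer vector of atom counts per element.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  s <- gsub("[[:space:]]", "", formula)
  if (!nzchar(s)) stop("empty molecular formula", call. = FALSE)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  pieces <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (sum(nchar(pieces)) != nchar(s)) {
    stop("cannot parse molecular formula: ", formula, call. = FALSE)
  }
  el <- sub("[0-9]*$", "", pieces)
  n <- as.integer(ifelse(grepl("[0-9]+$", pieces),
                         sub("^[A-Za-z]+", "", pieces), "1"))
  if (any(n <= 0)) stop("atom counts must be positive: ", formula,
                        call. = FALSE)
  counts <- tapply(n, el, sum)
  stats::setNames(as.integer(counts), names(counts))
}

#' Bundled IUPAC standard atomic weights
#'
#' @return Named numeric vector of atomic weights (g/mol).
#' @export
atomic_weights <- function() {
  path <- system.file("extdata", "atomic_weights.csv", package = "hspscreen",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(tab$weight, tab$element)
}

#' Bundled functional-group multiset for cefdinir
#'
#' The manual decomposition of cefdinir used to estimate its Fedors molar
#' volume. See `inst/extdata/cefdinir_fragments.csv` for the derivation.
#'
#' @return Named numeric vector of group counts.
#' @export
cefdinir_fragments <- function() {
  path <- system.file("extdata", "cefdinir_fragments.csv",
                      package = "hspscreen", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab$count), tab$group)
}
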