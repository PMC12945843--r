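#' Load the bundled reference substance panel
#'
#' Reads the bundled fixture of cefdinir plus seven candidate stabilisers
#' (three polymers, one mesoporous carrier, three amino-acid coformers) with
#' their literature Hansen components, together with the reference
#' formulation compositions. Literature Ra/chi values ride along as
#' documentation-only fields (`printed_ra`, `printed_chi`) and are attached
#' to the fixture for discrepancy reporting; all screening quantities are
#' recomputed from the delta components.
#'
#' @param substances_path,compositions_path Optional overrides for the two
#'   fixture files (CSV of substances; YAML of compositions).
#' @return A list of class `"reference_fixture"` with elements `substances`
#'   (list of [substance()]), `compositions`, `printed_ra` and `printed_chi`
#'   (named vectors, documentation only).
#' @export
load_reference_substances <- function(substances_path = NULL,
                                      compositions_path = NULL) {
  if (is.null(substances_path)) {
    substances_path <- system.file("extdata", "reference_substances.csv",
                                   package = "hspscreen", mustWork = TRUE)
  }
  if (!file.exists(substances_path)) {
    stop("substance fixture not found: ", substances_path, call. = FALSE)
  }
  subs <- parse_substances_file(substances_path)
  comps <- load_compositions(compositions_path)
  is_drug <- vapply(subs, function(s) identical(s$role, "drug"), logical(1))
  if (sum(is_drug) != 1L) {
    stop("reference fixture must contain exactly one drug substance",
         call. = FALSE)
  }
  nm <- vapply(subs, function(s) s$name, character(1))
  pick <- function(field) {
    stats::setNames(vapply(subs, function(s) {
      v <- s[[field]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1)), nm)
  }
  structure(list(substances = subs, compositions = comps,
                 printed_ra = pick("printed_ra"),
                 printed_chi = pick("printed_chi"),
                 source = substances_path),
            class = "reference_fixture")
}

#' Save a reference fixture back to its text formats
#'
#' Writes the substance panel as CSV (same schema the loader reads) and the
#' compositions as YAML; a reload reproduces all values exactly.
#'
#' @param fixture A [load_reference_substances()] result.
#' @param substances_path,compositions_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
save_reference_fixture <- function(fixture, substances_path,
                                   compositions_path) {
  stopifnot(inherits(fixture, "reference_fixture"))
  subs <- fixture$substances
  df <- data.frame(
    name = vapply(subs, function(s) s$name, character(1)),
    role = vapply(subs, function(s) s$role, character(1)),
    delta_d = vapply(subs, function(s) s$hsp[["delta_d"]], numeric(1)),
    delta_p = vapply(subs, function(s) s$hsp[["delta_p"]], numeric(1)),
    delta_h = vapply(subs, function(s) s$hsp[["delta_h"]], numeric(1)),
    inorganic = vapply(subs, function(s) s$inorganic, logical(1)),
    molar_mass = vapply(subs, function(s)
      if (is.null(s$molar_mass)) NA_real_ else s$molar_mass, numeric(1)),
    formula = vapply(subs, function(s)
      if (is.null(s$formula)) "" else s$formula, character(1)),
    printed_ra = unname(fixture$printed_ra),
    printed_chi = unname(fixture$printed_chi),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, substances_path, row.names = FALSE, quote = TRUE,
                   eol = "\n")
  comp <- unclass(fixture$compositions)
  comp$source <- NULL
  yaml::write_yaml(comp, compositions_path)
  invisible(c(substances_path, compositions_path))
}

#' Generate synthetic excipients
#'
#' Draws reproducible random substances whose Hansen components are uniform
#' over per-component ranges. The default ranges span the envelope observed
#' for common pharmaceutical stabilisers (delta_d 15-19, delta_p 3-15,
#' delta_h 7-18 MPa^0.5); roles are drawn from a polymer/coformer/inorganic
#' mix. Inorganic draws are flagged `inorganic = TRUE` and assigned the
#' `mesoporous_carrier` role.
#'
#' @param n Number of substances (0 gives an empty list).
#' @param seed Integer seed; identical seeds give identical output.
#' @param ranges List with elements `delta_d`, `delta_p`, `delta_h`, each a
#'   `c(low, high)` pair in MPa^0.5 with `low < high`.
#' @param role_mix Named proportions for roles `polymer`, `coformer`,
#'   `inorganic`; must sum to 1.
#' @return List of [substance()] objects.
#' @export
generate_synthetic_excipients <- function(n, seed = 1L,
                                          ranges = list(delta_d = c(15, 19),
                                                        delta_p = c(3, 15),
                                                        delta_h = c(7, 18)),
                                          role_mix = c(polymer = 0.5,
                                                       coformer = 0.3,
                                                       inorganic = 0.2)) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 ||
      n != round(n)) {
    stop("n must be a single non-negative integer", call. = FALSE)
  }
  for (comp in c("delta_d", "delta_p", "delta_h")) {
    r <- ranges[[comp]]
    if (is.null(r) || length(r) != 2L || r[[1]] >= r[[2]] || r[[1]] < 0) {
      stop("ranges$", comp, " must be c(low, high) with 0 <= low < high",
           call. = FALSE)
    }
  }
  if (abs(sum(role_mix) - 1) > 1e-8 || any(role_mix < 0)) {
    stop("role_mix proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (n == 0L) return(list())
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  roles <- sample(names(role_mix), n, replace = TRUE, prob = role_mix)
  dd <- stats::runif(n, ranges$delta_d[1], ranges$delta_d[2])
  dp <- stats::runif(n, ranges$delta_p[1], ranges$delta_p[2])
  dh <- stats::runif(n, ranges$delta_h[1], ranges$delta_h[2])
  lapply(seq_len(n), function(i) {
    inorg <- roles[[i]] == "inorganic"
    substance(sprintf("synthetic_%03d", i),
              role = if (inorg) "mesoporous_carrier" else roles[[i]],
              hsp = hsp(dd[[i]], dp[[i]], dh[[i]]),
              inorganic = inorg)
  })
}

#' Generate a synthetic functional-group multiset
#'
#' Draws a reproducible random fragment multiset using only labels present
#' in the supplied table (ring corrections excluded), guaranteed non-empty.
#' Intended for property tests of the group-contribution estimators.
#'
#' @param seed Integer seed.
#' @param table A [group_contribution_table()].
#' @param max_groups Maximum number of distinct groups drawn (default 6).
#' @param max_count Maximum count per group (default 4).
#' @return Named numeric vector of group counts.
#' @export
generate_synthetic_fragments <- function(seed, table = group_contribution_table(),
                                         max_groups = 6L, max_count = 4L) {
  if (nrow(table) == 0L) stop("empty group table", call. = FALSE)
  labels <- table$label[table$heavy_atoms > 0]
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  k <- sample.int(min(max_groups, length(labels)), 1L)
  chosen <- sample(labels, k)
  fr <- stats::setNames(as.numeric(sample.int(max_count, k, replace = TRUE)),
                        chosen)
  # keep the multiset chemically plausible: substituted carbons and tertiary
  # nitrogens carry negative Fedors increments, so pad the backbone with CH2
  # until the volume sum is positive (real molecules always are)
  dv <- stats::setNames(table$delta_v, table$label)
  vsum <- sum(fr * dv[names(fr)])
  if (vsum <= 0) {
    pad <- ceiling((1 - vsum) / dv[["CH2"]])
    fr["CH2"] <- (if ("CH2" %in% names(fr)) fr[["CH2"]] else 0) + pad
  }
  fr
}
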