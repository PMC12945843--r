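#' Parse a substances file (CSV or YAML)
#'
#' CSV files need columns `name,role,delta_d,delta_p,delta_h,inorganic` and
#' may carry `molar_mass`, `formula`, `printed_ra`, `printed_chi`. YAML
#' files hold a `substances` list whose entries give either the three delta
#' components directly or a `fragments` map of group counts; fragment-only
#' entries are routed through the group-contribution estimators (Fedors
#' molar volume, then Hoftyzer-Van Krevelen components).
#'
#' @param path Input file; format chosen by extension (`.csv` vs
#'   `.yml`/`.yaml`).
#' @param table [group_contribution_table()] used for fragment-only entries.
#' @return List of [substance()] objects.
#' @export
parse_substances_file <- function(path, table = group_contribution_table()) {
  if (!file.exists(path)) stop("substances file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    parse_substances_yaml(path, table)
  } else if (ext == "csv") {
    parse_substances_csv(path)
  } else {
    stop("unsupported substances file format '.", ext,
         "' (expected .csv, .yml or .yaml)", call. = FALSE)
  }
}

parse_substances_csv <- function(path) {
  tab <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse substances file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(tab) == 0L) stop("substances file ", path, " has no rows",
                            call. = FALSE)
  need <- c("name", "role", "delta_d", "delta_p", "delta_h")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("substances file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    deltas <- c(row$delta_d, row$delta_p, row$delta_h)
    if (anyNA(deltas)) {
      stop("row ", i, " (", row$name, "): missing Hansen component(s): ",
           paste(c("delta_d", "delta_p", "delta_h")[is.na(deltas)],
                 collapse = ", "), call. = FALSE)
    }
    if (any(deltas < 0)) {
      stop("row ", i, " (", row$name, "): negative Hansen component",
           call. = FALSE)
    }
    opt <- function(col) {
      if (!col %in% names(tab) || is.na(row[[col]])) NULL else row[[col]]
    }
    s <- substance(row$name, role = row$role,
                   hsp = hsp(deltas[1], deltas[2], deltas[3]),
                   molar_mass = opt("molar_mass"),
                   inorganic = isTRUE(as.logical(opt("inorganic"))),
                   printed_ra = opt("printed_ra"),
                   printed_chi = opt("printed_chi"))
    f <- opt("formula")
    if (!is.null(f) && nzchar(f)) s$formula <- f
    s
  })
}

parse_substances_yaml <- function(path, table) {
  y <- tryCatch(yaml::read_yaml(path),
                error = function(e) stop("cannot parse substances file ",
                                         path, ": ", conditionMessage(e),
                                         call. = FALSE))
  entries <- if (!is.null(y$substances)) y$substances else y
  if (length(entries) == 0L) stop("substances file ", path, " is empty",
                                  call. = FALSE)
  lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    if (is.null(e$name)) stop("entry ", i, ": missing name", call. = FALSE)
    vm <- e$molar_volume
    if (!is.null(e$delta_d) || !is.null(e$delta_p) || !is.null(e$delta_h)) {
      deltas <- c(e$delta_d, e$delta_p, e$delta_h)
      if (length(deltas) != 3L) {
        stop("entry ", i, " (", e$name, "): all three Hansen components ",
             "are required when any is given", call. = FALSE)
      }
      h <- hsp(deltas[[1]], deltas[[2]], deltas[[3]])
    } else if (!is.null(e$fragments)) {
      fr <- stats::setNames(as.numeric(unlist(e$fragments)),
                            names(e$fragments))
      if (is.null(vm)) vm <- fedors_molar_volume(fr, table)
      h <- hvk_hsp(fr, table, vm)
    } else {
      stop("entry ", i, " (", e$name, "): needs either delta components ",
           "or a fragments map", call. = FALSE)
    }
    substance(e$name,
              role = if (is.null(e$role)) "other" else e$role,
              hsp = h, molar_volume = vm, molar_mass = e$molar_mass,
              inorganic = isTRUE(e$inorganic),
              printed_ra = e$printed_ra, printed_chi = e$printed_chi)
  })
}

#' Run a full screen from a configuration and write report files
#'
#' Thin driver over [load_reference_substances()] / [parse_substances_file()],
#' [screen()] and the report writers: every number in the files is
#' obtainable through those functions with identical values. Writes
#' `screening_report.csv` and `screening_summary.md` into `out_dir`.
#'
#' @param config List with elements: `substances` (path, or `NULL` for the
#'   bundled reference panel), `out_dir` (created if missing), and
#'   optionally `temperature` (K, default 298), `thresholds`
#'   (a [miscibility_thresholds()]), `scheme` (group-table scheme name,
#'   default `"hvk_fedors"`), `drug_fragments` (named counts used for the
#'   drug's Fedors molar volume when the file does not provide one;
#'   defaults to the bundled cefdinir multiset when the drug is cefdinir),
#'   and `verbose` (default `TRUE`, log to standard error).
#' @return Invisibly, a list with `status` (0 on success), `report` and the
#'   written `files`.
#' @export
run_screen_command <- function(config) {
  stopifnot(is.list(config))
  verbose <- !isFALSE(config$verbose)
  log <- function(...) if (verbose) message(...)
  table <- group_contribution_table(
    scheme = if (is.null(config$scheme)) "hvk_fedors" else config$scheme)
  subs <- if (is.null(config$substances)) {
    load_reference_substances()$substances
  } else {
    parse_substances_file(config$substances, table)
  }
  is_drug <- vapply(subs, function(s) identical(s$role, "drug"), logical(1))
  if (sum(is_drug) != 1L) {
    stop("substances input must contain exactly one substance with role ",
         "'drug' (found ", sum(is_drug), ")", call. = FALSE)
  }
  drug <- subs[is_drug][[1]]
  excipients <- subs[!is_drug]
  vm <- drug$molar_volume
  if (is.null(vm)) {
    fr <- config$drug_fragments
    if (is.null(fr) && identical(tolower(drug$name), "cefdinir")) {
      fr <- cefdinir_fragments()
    }
    if (is.null(fr)) {
      stop("no molar volume for drug '", drug$name,
           "': supply molar_volume in the substances file or ",
           "config$drug_fragments for a Fedors estimate", call. = FALSE)
    }
    vm <- fedors_molar_volume(fr, table)
    log(sprintf("Fedors molar volume for %s: %.1f cm^3/mol", drug$name, vm))
  }
  thresholds <- if (is.null(config$thresholds)) miscibility_thresholds()
                else config$thresholds
  ctx <- chi_context(drug_molar_volume = vm,
                     temperature = if (is.null(config$temperature)) 298
                                   else config$temperature)
  report <- screen(drug, excipients, ctx, thresholds)
  log(sprintf("screened %d excipients against %s (T = %.0f K, Ra bounds %g/%g, chi bound %g)",
              length(excipients), drug$name, ctx$temperature,
              thresholds$ra_miscible, thresholds$ra_immiscible,
              thresholds$chi_miscible))
  notes <- report$assessments$notes
  for (note in notes[nzchar(notes)]) log("discrepancy: ", note)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "screening_report.csv")
  md <- file.path(out_dir, "screening_summary.md")
  write_report_csv(report, csv)
  writeLines(report_markdown(report), md)
  invisible(list(status = 0L, report = report, files = c(csv = csv, md = md)))
}
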