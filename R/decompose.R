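# Structure decomposition: SMILES -> functional-group counts.
#
# Parsing and valence perception are delegated to ChemmineR/OpenBabel; the
# assignment of atoms to group-contribution groups is done here with a
# deterministic, most-specific-first rule set so that repeated runs (and
# different platforms) give identical multisets. Each heavy atom is consumed
# by exactly one group; ring corrections are added per independent cycle.

smiles_graph <- function(structure) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("structure decomposition requires the ChemmineR package",
         call. = FALSE)
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(structure)[[1]]),
    error = function(e) stop("cannot parse structure string '", structure,
                             "': ", conditionMessage(e), call. = FALSE))
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_[0-9]+$", "", rownames(ab))
  n <- length(elements)
  if (n == 0L || any(!grepl("^[A-Z][a-z]?$", elements))) {
    stop("cannot parse structure string '", structure, "'", call. = FALSE)
  }
  bonds <- if (length(bb) == 0L || is.null(dim(bb)) || nrow(bb) == 0L ||
               ncol(bb) < 3L) {
    matrix(numeric(0), ncol = 3)
  } else {
    cbind(as.numeric(bb[, 1]), as.numeric(bb[, 2]), as.numeric(bb[, 3]))
  }
  # implicit hydrogens from standard neutral valences
  valence <- c(C = 4, N = 3, O = 2, S = 2, H = 1)
  order_sum <- numeric(n)
  degree <- numeric(n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]; o <- bonds[k, 3]
      order_sum[i] <- order_sum[i] + o
      order_sum[j] <- order_sum[j] + o
      degree[i] <- degree[i] + 1
      degree[j] <- degree[j] + 1
    }
  }
  list(elements = elements, bonds = bonds,
       hydrogens = pmax(valence[elements] - order_sum, 0),
       degree = degree, order_sum = order_sum)
}

ring_counts <- function(g) {
  n <- length(g$elements)
  if (n == 0L || nrow(g$bonds) == 0L) return(c(ring3or4 = 0, ring5plus = 0))
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds[k, 1]; j <- g$bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  # spanning forest; each non-tree edge closes one independent cycle whose
  # size is taken as the shortest path between its endpoints in the forest
  visited <- rep(FALSE, n)
  parent <- rep(NA_integer_, n)
  depth <- rep(0L, n)
  tree_edge <- matrix(FALSE, n, n)
  for (root in seq_len(n)) {
    if (visited[root]) next
    queue <- root
    visited[root] <- TRUE
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (!visited[w]) {
          visited[w] <- TRUE
          parent[w] <- v
          depth[w] <- depth[v] + 1L
          tree_edge[v, w] <- tree_edge[w, v] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
  }
  small <- 0L; large <- 0L
  seen <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds[k, 1]; j <- g$bonds[k, 2]
    if (tree_edge[i, j] || seen[i, j]) next
    seen[i, j] <- seen[j, i] <- TRUE
    # path length i..j through the forest = cycle size - 1
    a <- i; b <- j; steps <- 0L
    while (a != b) {
      if (depth[a] < depth[b]) { b <- parent[b] } else { a <- parent[a] }
      steps <- steps + 1L
    }
    size <- steps + 1L
    if (size <= 4L) small <- small + 1L else large <- large + 1L
  }
  c(ring3or4 = small, ring5plus = large)
}

#' Decompose a structure string into functional-group counts
#'
#' Parses a SMILES string and assigns every heavy atom to exactly one group
#' of the increment table, most specific groups first (carboxyl before
#' carbonyl before bare carbons), with deterministic first-match-wins
#' resolution. One ring correction is added per independent cycle. Only
#' organic molecules built from C, H, N, O and S are supported; inorganic
#' inputs (e.g. silica) are rejected, matching the convention that
#' group-contribution estimates do not apply to them.
#'
#' @param structure SMILES string.
#' @param table A [group_contribution_table()]; decomposition only emits
#'   labels present in this table.
#' @return Named numeric vector of group counts.
#' @examples
#' \dontrun{
#' decompose_structure("CCO") # CH3 1, CH2 1, OH 1
#' }
#' @export
decompose_structure <- function(structure,
                                table = group_contribution_table()) {
  stopifnot(is.character(structure), length(structure) == 1L)
  if (nrow(table) == 0L) stop("empty group table", call. = FALSE)
  g <- smiles_graph(structure)
  supported <- c("C", "N", "O", "S")
  bad <- setdiff(unique(g$elements), c(supported, "H"))
  if (length(bad) > 0L) {
    stop("unsupported substance: contains element(s) ",
         paste(bad, collapse = ", "),
         "; group-contribution decomposition covers organic molecules ",
         "(C, H, N, O, S) only", call. = FALSE)
  }
  n <- length(g$elements)
  nbr <- lapply(seq_len(n), function(i) {
    if (nrow(g$bonds) == 0L) return(cbind(atom = integer(0), order = numeric(0)))
    sel1 <- g$bonds[, 1] == i
    sel2 <- g$bonds[, 2] == i
    cbind(atom = c(g$bonds[sel2, 1], g$bonds[sel1, 2]),
          order = c(g$bonds[sel2, 3], g$bonds[sel1, 3]))
  })
  assigned <- rep(FALSE, n)
  counts <- integer(0)
  add <- function(counts, label) {
    counts[label] <- if (label %in% names(counts)) counts[[label]] + 1L else 1L
    counts
  }
  el <- g$elements
  hyd <- g$hydrogens
  has_double <- vapply(seq_len(n), function(i) {
    nb <- nbr[[i]]
    nrow(nb) > 0 && any(nb[, "order"] >= 2)
  }, logical(1))

  # pass 1: multi-atom oxygen-bearing groups on carbon, in priority order
  for (i in seq_len(n)) {
    if (assigned[i] || el[i] != "C") next
    nb <- nbr[[i]]
    if (nrow(nb) == 0) next
    o_dbl <- nb[, "atom"][nb[, "order"] == 2 & el[nb[, "atom"]] == "O" &
                            !assigned[nb[, "atom"]]]
    if (length(o_dbl) == 0) next
    o_sgl <- nb[, "atom"][nb[, "order"] == 1 & el[nb[, "atom"]] == "O" &
                            !assigned[nb[, "atom"]]]
    o_sgl_h <- o_sgl[hyd[o_sgl] >= 1]
    o_sgl_r <- o_sgl[hyd[o_sgl] < 1]
    if (length(o_sgl_h) > 0 && "COOH" %in% table$label) {
      counts <- add(counts, "COOH")
      assigned[c(i, o_dbl[1], o_sgl_h[1])] <- TRUE
    } else if (length(o_sgl_r) > 0 && "COO" %in% table$label) {
      counts <- add(counts, "COO")
      assigned[c(i, o_dbl[1], o_sgl_r[1])] <- TRUE
    } else if ("C=O" %in% table$label) {
      counts <- add(counts, "C=O")
      assigned[c(i, o_dbl[1])] <- TRUE
    }
  }

  # pass 2: remaining single-atom groups
  for (i in seq_len(n)) {
    if (assigned[i]) next
    label <- switch(
      el[i],
      O = if (hyd[i] >= 1) "OH" else "O",
      N = if (has_double[i]) "N=" else if (hyd[i] >= 2) "NH2"
          else if (hyd[i] == 1) "NH" else "N",
      S = "S",
      C = if (has_double[i]) {
        if (hyd[i] >= 2) "CH2=" else if (hyd[i] == 1) "CH=" else "C="
      } else {
        if (hyd[i] >= 3) "CH3" else if (hyd[i] == 2) "CH2"
        else if (hyd[i] == 1) "CH" else "C"
      },
      NA_character_
    )
    if (is.na(label) || !(label %in% table$label)) {
      stop("atom ", i, " (", el[i], ", ", hyd[i], " H, degree ", g$degree[i],
           ") is not covered by any group in the table", call. = FALSE)
    }
    counts <- add(counts, label)
    assigned[i] <- TRUE
  }

  rings <- ring_counts(g)
  for (lab in names(rings)) {
    if (rings[[lab]] > 0) {
      if (!(lab %in% table$label)) {
        stop("ring correction '", lab, "' missing from the group table",
             call. = FALSE)
      }
      counts[lab] <- (if (lab %in% names(counts)) counts[[lab]] else 0L) +
        rings[[lab]]
    }
  }
  stats::setNames(as.numeric(counts), names(counts))
}
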