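## Cycle algebra: stability changes from alchemical legs, double-mutant-cycle
## nonadditivity, pathway composition, and the triple-mutant-box
## decomposition, all with quadrature error propagation.

#' Signed sum of free-energy estimates with quadrature errors
#'
#' @param components list of [free_energy_estimate()] objects (bare numbers
#'   are accepted and treated as exact).
#' @param signs numeric vector of +1/-1, same length.
#' @return a [free_energy_estimate()]: value = signed sum, uncertainty =
#'   square root of the sum of squared component uncertainties (components
#'   assumed independent).
#' @export
propagate <- function(components, signs = rep(1, length(components))) {
  if (length(components) != length(signs))
    stop("components and signs must have equal length")
  if (!all(signs %in% c(-1, 1))) stop("signs must be +1 or -1")
  comps <- lapply(components, function(x) {
    if (inherits(x, "free_energy_estimate")) x
    else free_energy_estimate(as.numeric(x), 0)
  })
  vals <- vapply(comps, function(x) x$value, 0)
  uncs <- vapply(comps, function(x) x$uncertainty, 0)
  off <- any(vapply(comps, function(x) isTRUE(x$offset_relative), NA))
  free_energy_estimate(sum(signs * vals), sqrt(sum(uncs^2)),
                       offset_relative = off)
}

#' Stability change from folded and unfolded alchemical legs
#'
#' The stability change of a mutation is the difference between the
#' free-energy changes of the alchemical transformation performed in the
#' folded and in the unfolded state:
#' \eqn{\Delta\Delta G = \Delta G_{folded} - \Delta G_{unfolded}}.
#' When the unfolded leg is omitted the mutation's unfolded-state
#' contribution is treated as a common constant for that mutation
#' (additivity in the unfolded state); the returned value is then flagged
#' `offset_relative`. Such offsets cancel exactly in every nonadditivity,
#' since each single mutation's offset enters a coupling once with each
#' sign.
#'
#' @param dg_folded [free_energy_estimate()] for the folded leg.
#' @param dg_unfolded [free_energy_estimate()] for the unfolded leg, or
#'   `NULL` to invoke unfolded-state cancellation.
#' @return a [free_energy_estimate()] (uncertainties combined in
#'   quadrature).
#' @export
ddg_from_legs <- function(dg_folded, dg_unfolded = NULL) {
  stopifnot(inherits(dg_folded, "free_energy_estimate"))
  if (is.null(dg_unfolded)) {
    out <- free_energy_estimate(dg_folded$value, dg_folded$uncertainty,
                                offset_relative = TRUE)
    return(out)
  }
  stopifnot(inherits(dg_unfolded, "free_energy_estimate"))
  propagate(list(dg_folded, dg_unfolded), c(1, -1))
}

## Choose the deterministic path from ref to tgt: shortest chain of table
## entries (traversable against their direction with negated sign), ties
## broken by lexicographic order of the intermediate state labels. Returns
## the table row indices and traversal signs of the chosen path plus the
## maximum pairwise discrepancy among all simple paths.
.choose_path <- function(table, ref, tgt) {
  states <- unique(c(table$reference, table$target))
  if (!(ref %in% states) || !(tgt %in% states))
    stop("no path in table from '", .show_state(ref), "' to '",
         .show_state(tgt), "'", call. = FALSE)
  ## vertex names: igraph requires non-empty, use explicit WT token
  vn <- function(s) ifelse(s == "", "WT", s)
  g <- igraph::graph_from_data_frame(
    data.frame(from = vn(table$reference), to = vn(table$target),
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = vn(states), stringsAsFactors = FALSE))
  paths <- igraph::all_simple_paths(g, from = vn(ref), to = vn(tgt))
  if (length(paths) == 0L)
    stop("no path in table from '", .show_state(ref), "' to '",
         .show_state(tgt), "'", call. = FALSE)
  edge_walk <- function(p) {
    nodes <- names(p)
    nodes[nodes == "WT"] <- ""
    rows <- integer(length(nodes) - 1L)
    signs <- integer(length(nodes) - 1L)
    for (i in seq_len(length(nodes) - 1L)) {
      j <- which(table$reference == nodes[i] & table$target == nodes[i + 1L])
      if (length(j)) { rows[i] <- j[1L]; signs[i] <- 1L }
      else {
        j <- which(table$reference == nodes[i + 1L] &
                     table$target == nodes[i])
        rows[i] <- j[1L]; signs[i] <- -1L
      }
    }
    list(rows = rows, signs = signs)
  }
  walks <- lapply(paths, edge_walk)
  vals <- vapply(walks, function(w) sum(w$signs * table$value[w$rows]), 0)
  lens <- vapply(paths, length, 0L)
  inter <- vapply(paths, function(p) paste(names(p)[-c(1L, length(p))],
                                           collapse = "|"), "")
  pick <- order(lens, inter)[1L]
  c(walks[[pick]],
    list(value = vals[pick],
         max_discrepancy = if (length(vals) > 1L) diff(range(vals)) else 0))
}

#' Compose a stability change along table pathways
#'
#' Free energy is a state function, so
#' \eqn{\Delta\Delta G_{ref}^{target}} can be accumulated along any chain
#' of table entries connecting the two states (entries may be traversed
#' against their direction with negated sign). Among all simple paths the
#' shortest is returned, ties broken by the lexicographic order of the
#' intermediate state labels; the maximum pairwise discrepancy among all
#' found paths is attached as attribute `"max_discrepancy"` (zero on a
#' thermodynamically consistent table).
#'
#' @param table a [ddg_table()].
#' @param reference,target mutation states (sets or labels).
#' @return a [free_energy_estimate()] with attribute `"max_discrepancy"`.
#' @export
compose_path <- function(table, reference, target) {
  stopifnot(inherits(table, "ddg_table"))
  ref <- state_label(reference)
  tgt <- state_label(target)
  if (ref == tgt) {
    out <- free_energy_estimate(0, 0)
    attr(out, "max_discrepancy") <- 0
    return(out)
  }
  w <- .choose_path(table, ref, tgt)
  out <- free_energy_estimate(w$value,
                              sqrt(sum(table$uncertainty[w$rows]^2)))
  attr(out, "max_discrepancy") <- w$max_discrepancy
  out
}

## Signed combination of composed ddg terms with edge-level error
## propagation: each term's path contributes its table edges with the
## term's sign; coefficients of the same edge are accumulated, so an edge
## shared between terms with opposite signs cancels and contributes no
## uncertainty. Returns value, uncertainty and the per-term estimates.
.ddg_combination <- function(table, terms) {
  coef <- numeric(nrow(table))
  ests <- vector("list", length(terms))
  for (k in seq_along(terms)) {
    tm <- terms[[k]]
    ref <- state_label(tm$ref); tgt <- state_label(tm$tgt)
    w <- .choose_path(table, ref, tgt)
    coef[w$rows] <- coef[w$rows] + tm$sign * w$signs
    ests[[k]] <- free_energy_estimate(
      w$value, sqrt(sum(table$uncertainty[w$rows]^2)))
  }
  list(value = sum(coef * table$value),
       uncertainty = sqrt(sum((coef * table$uncertainty)^2)),
       terms = ests)
}

.show_state <- function(lab) if (lab == "") "WT" else lab

#' Double-mutant-cycle nonadditivity
#'
#' The nonadditivity (thermodynamic coupling) of a mutation pair (A, B) at
#' a reference state:
#' \deqn{\delta_{ref}^{AB} = \Delta\Delta G_{ref}^{ref+AB}
#'   - \Delta\Delta G_{ref}^{ref+A} - \Delta\Delta G_{ref}^{ref+B}.}
#' A zero coupling means the two mutations act additively; a non-zero
#' coupling means they are correlated. Each term is taken from the table
#' directly or composed along pathways ([compose_path()]); uncertainties
#' combine in quadrature.
#'
#' Uncertainties are propagated at the level of the underlying table
#' entries: an entry contributing to several terms enters the combination
#' with its net coefficient, so composed pathways that reuse an edge with
#' opposite signs (e.g. `WT -> A` inside both `WT -> AB` and
#' `-Delta Delta G_WT^A`) do not double-count its noise.
#'
#' @param table a [ddg_table()].
#' @param a,b [mutation()] objects or codes for the pair.
#' @param reference reference state (default wild type).
#' @return an object of class `"coupling_result"`: fields `pair`,
#'   `reference`, `delta`, `uncertainty` (kJ/mol) and `breakdown` (the
#'   three contributing estimates).
#' @export
nonadditivity <- function(table, a, b, reference = mutation_set()) {
  stopifnot(inherits(table, "ddg_table"))
  a <- if (inherits(a, "mutation_spec")) a else mutation(a)
  b <- if (inherits(b, "mutation_spec")) b else mutation(b)
  ref <- if (inherits(reference, "mutation_set")) reference
         else parse_state(reference)
  if (.mut_key(a) == .mut_key(b))
    stop("pair mutations must be at different positions")
  if (state_contains(ref, mutation_set(a)) ||
      state_contains(ref, mutation_set(b)))
    stop("reference state must not already contain the pair mutations")
  terms <- list(
    list(ref = ref, tgt = state_union(ref, mutation_set(a, b)), sign = 1),
    list(ref = ref, tgt = state_union(ref, mutation_set(a)), sign = -1),
    list(ref = ref, tgt = state_union(ref, mutation_set(b)), sign = -1))
  names <- c(paste0(format(a), "+", format(b)), format(a), format(b))
  comb <- tryCatch(.ddg_combination(table, terms), error = function(e)
    stop("missing ddg edge for pair (", names[2], ", ", names[3],
         ") at reference '", .show_state(state_label(ref)), "': ",
         conditionMessage(e), call. = FALSE))
  coupling_result(pair = list(a, b), reference = ref,
                  delta = comb$value, uncertainty = comb$uncertainty,
                  breakdown = list(ddg_ab = comb$terms[[1]],
                                   ddg_a = comb$terms[[2]],
                                   ddg_b = comb$terms[[3]]))
}

#' Coupling result
#'
#' @param pair list of the two [mutation()] objects.
#' @param reference the reference [mutation_set()].
#' @param delta nonadditivity in kJ/mol.
#' @param uncertainty 1 SE, kJ/mol.
#' @param breakdown optional named list of contributing estimates.
#' @return an object of class `"coupling_result"`.
#' @export
coupling_result <- function(pair, reference, delta, uncertainty,
                            breakdown = NULL) {
  stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta),
            is.numeric(uncertainty), uncertainty >= 0)
  structure(list(pair = pair, reference = reference, delta = delta,
                 uncertainty = uncertainty, breakdown = breakdown),
            class = "coupling_result")
}

#' @export
format.coupling_result <- function(x, digits = 3, ...) {
  sprintf("delta_%s^{%s+%s} = %.*f ± %.*f kJ/mol",
          .show_state(state_label(x$reference)),
          format(x$pair[[1]]), format(x$pair[[2]]),
          digits, x$delta, digits, x$uncertainty)
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(format(x), "\n")
  if (!is.null(x$breakdown)) {
    for (nm in names(x$breakdown))
      cat("  ", nm, ": ", format(x$breakdown[[nm]]), "\n", sep = "")
  }
  invisible(x)
}

#' Is a pair thermodynamically coupled?
#'
#' A pair is called correlated when its nonadditivity is non-zero beyond
#' noise; as a practical cutoff,
#' `|delta| > max(threshold, 2 * uncertainty)`.
#'
#' @param x a [coupling_result()].
#' @param threshold minimum absolute coupling in kJ/mol (default 1).
#' @return logical.
#' @export
is_correlated <- function(x, threshold = 1.0) {
  stopifnot(inherits(x, "coupling_result"), threshold > 0)
  abs(x$delta) > max(threshold, 2 * x$uncertainty)
}

#' Triple-mutant-box coupling
#'
#' The coupling of a pair (A, B) in the background of a third mutation C,
#' \eqn{\delta_C^{AB}}. Two exact routes exist:
#'
#' * **direct** — the double-mutant-cycle formula with C as the reference
#'   state: \eqn{\delta_C^{AB} = \Delta\Delta G_C^{ABC}
#'   - \Delta\Delta G_C^{AC} - \Delta\Delta G_C^{BC}};
#' * **decomposition** — the wild-type coupling corrected by the cost of
#'   introducing C into each corner of the original cycle:
#'   \eqn{\delta_C^{AB} = \delta_{WT}^{AB} + \Delta\Delta G_{AB}^{ABC}
#'   + \Delta\Delta G_{WT}^{C} - \Delta\Delta G_A^{AC}
#'   - \Delta\Delta G_B^{BC}}.
#'
#' Both are consequences of free energy being a state function and agree
#' identically on a consistent table. `route = "auto"` tries the direct
#' route and falls back to the decomposition when C-referenced edges are
#' missing.
#'
#' @param table a [ddg_table()].
#' @param a,b the pair mutations ([mutation()] or codes).
#' @param c3 the external third mutation.
#' @param route `"auto"`, `"direct"` or `"decomposition"`.
#' @return a [coupling_result()] with the route's contributing terms in
#'   `breakdown` (and, for the decomposition, the wild-type coupling
#'   `delta_wt`).
#' @export
triple_box <- function(table, a, b, c3,
                       route = c("auto", "direct", "decomposition")) {
  stopifnot(inherits(table, "ddg_table"))
  route <- match.arg(route)
  a <- if (inherits(a, "mutation_spec")) a else mutation(a)
  b <- if (inherits(b, "mutation_spec")) b else mutation(b)
  c3 <- if (inherits(c3, "mutation_spec")) c3 else mutation(c3)
  keys <- vapply(list(a, b, c3), .mut_key, "")
  if (anyDuplicated(keys))
    stop("mutations A, B and C must be at three different positions")
  if (route == "direct")
    return(nonadditivity(table, a, b, reference = mutation_set(c3)))
  if (route == "auto") {
    out <- tryCatch(nonadditivity(table, a, b, reference = mutation_set(c3)),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  ## decomposition route: delta_WT^AB plus the cost of introducing C into
  ## each corner of the original cycle, combined at edge level
  A <- mutation_set(a); B <- mutation_set(b); C <- mutation_set(c3)
  AB <- mutation_set(a, b)
  WT <- mutation_set()
  terms <- list(
    list(ref = WT, tgt = AB, sign = 1),                  # delta_WT^AB ...
    list(ref = WT, tgt = A, sign = -1),
    list(ref = WT, tgt = B, sign = -1),
    list(ref = AB, tgt = state_union(AB, C), sign = 1),  # C into AB
    list(ref = WT, tgt = C, sign = 1),                   # C into WT
    list(ref = A, tgt = state_union(A, C), sign = -1),   # C into A
    list(ref = B, tgt = state_union(B, C), sign = -1))   # C into B
  comb <- tryCatch(.ddg_combination(table, terms), error = function(e)
    stop("triple box decomposition missing edges: ", conditionMessage(e),
         call. = FALSE))
  d_wt <- nonadditivity(table, a, b)
  coupling_result(pair = list(a, b), reference = C,
                  delta = comb$value, uncertainty = comb$uncertainty,
                  breakdown = list(delta_wt = d_wt,
                                   ddg_ab_to_abc = comb$terms[[4]],
                                   ddg_wt_to_c = comb$terms[[5]],
                                   ddg_a_to_ac = comb$terms[[6]],
                                   ddg_b_to_bc = comb$terms[[7]]))
}
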