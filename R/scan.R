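## Positional mutational scans of third-site effects on a coupled pair,
## and classification of how a background change alters a coupling.

#' Scan all substitutions at an external position
#'
#' For a fixed coupled pair (A, B), computes the triple-mutant-box coupling
#' \eqn{\delta_C^{AB}} for every requested substitution C at one external
#' position, then summarises the position by the mean unsigned coupling and
#' its standard error. This mirrors scanning "all possible mutations" at a
#' third site: a position whose identity modulates the pair coupling shows
#' a large mean unsigned nonadditivity; an inert position shows a small
#' one.
#'
#' @param table a [ddg_table()] covering the required triple-box edges.
#' @param a,b the pair mutations ([mutation()] or codes).
#' @param position residue position of the external site.
#' @param wt_res wild-type residue at that position; if `NULL`, inferred
#'   from mutations at that position present in the table.
#' @param substitutions one-letter codes to scan (default: the 19
#'   non-wild-type canonical residues). The wild-type identity substitution
#'   is always excluded.
#' @param chain chain of the external site (default `"A"`).
#' @param route passed to [triple_box()].
#' @return an object of class `"scan_summary"`: `per_substitution` (named
#'   list of [coupling_result()]), `mean_abs_delta`, `std_error` (sample SD
#'   of the unsigned couplings / sqrt(n)), and `missing` (substitutions
#'   excluded because table edges were unavailable).
#' @export
positional_scan <- function(table, a, b, position, wt_res = NULL,
                            substitutions = NULL, chain = "A",
                            route = "auto") {
  stopifnot(inherits(table, "ddg_table"))
  a <- if (inherits(a, "mutation_spec")) a else mutation(a)
  b <- if (inherits(b, "mutation_spec")) b else mutation(b)
  position <- as.character(position)
  if (is.null(wt_res)) {
    wt_res <- .infer_wt_res(table, chain, position)
    if (is.null(wt_res))
      stop("cannot infer wild-type residue at position ", position,
           " from the table; supply wt_res")
  }
  wt_res <- toupper(wt_res)
  if (!wt_res %in% .aa1) stop("invalid wild-type residue: ", wt_res)
  if (is.null(substitutions)) substitutions <- setdiff(.aa1, wt_res)
  substitutions <- toupper(substitutions)
  substitutions <- setdiff(unique(substitutions), wt_res)
  if (length(substitutions) == 0L)
    stop("no substitutions to scan at position ", position)
  per <- list()
  missing <- character(0)
  for (s in substitutions) {
    c3 <- mutation(chain = chain, wt_res = wt_res, position = position,
                   mut_res = s)
    res <- tryCatch(triple_box(table, a, b, c3, route = route),
                    error = function(e) NULL)
    if (is.null(res)) missing <- c(missing, format(c3))
    else per[[format(c3)]] <- res
  }
  if (length(per) == 0L)
    stop("no substitution at position ", position,
         " has the required table edges")
  deltas <- vapply(per, function(x) x$delta, 0)
  mad <- mean(abs(deltas))
  se <- if (length(deltas) > 1L)
    stats::sd(abs(deltas)) / sqrt(length(deltas)) else 0
  structure(list(pair = list(a, b), position = position, chain = chain,
                 wt_res = wt_res, per_substitution = per,
                 mean_abs_delta = mad, std_error = se,
                 missing = missing),
            class = "scan_summary")
}

.infer_wt_res <- function(table, chain, position) {
  for (lab in unique(c(table$reference, table$target))) {
    for (m in unclass(parse_state(lab))) {
      if (identical(m$chain, chain) && identical(m$position, position))
        return(m$wt_res)
    }
  }
  NULL
}

#' @export
print.scan_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Scan of position %s%s (wild type %s) on pair %s+%s\n",
              if (identical(x$chain, "A")) "" else paste0(x$chain, ":"),
              x$position, x$wt_res,
              format(x$pair[[1]]), format(x$pair[[2]])))
  cat(sprintf("  mean |delta| = %.*f ± %.*f kJ/mol over %d substitutions\n",
              digits, x$mean_abs_delta, digits, x$std_error,
              length(x$per_substitution)))
  if (length(x$missing))
    cat("  excluded (missing edges):", paste(x$missing, collapse = ", "),
        "\n")
  for (nm in names(x$per_substitution)) {
    r <- x$per_substitution[[nm]]
    cat(sprintf("  %-8s %8.*f ± %.*f\n", nm, digits, r$delta, digits,
                r$uncertainty))
  }
  invisible(x)
}

#' Convert a scan summary to a data frame
#'
#' @param x a `scan_summary`.
#' @param row.names,optional,... ignored.
#' @return data frame with one row per substitution: `substitution`,
#'   `delta_kJmol`, `uncertainty_kJmol`.
#' @export
as.data.frame.scan_summary <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  data.frame(
    substitution = names(x$per_substitution),
    delta_kJmol = vapply(x$per_substitution, function(r) r$delta, 0),
    uncertainty_kJmol = vapply(x$per_substitution,
                               function(r) r$uncertainty, 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify how a background change alters a coupling
#'
#' Compares a pair's coupling in a new background (`delta_new`, e.g. with a
#' third mutation present) against a reference background (`delta_ref`,
#' e.g. wild type), using `additive_threshold` as the magnitude below which
#' a coupling counts as additive:
#'
#' * `"erased"` — was a coupling, now additive;
#' * `"emergent"` — was additive, now a coupling;
#' * `"inverted"` — strong coupling in both, opposite signs;
#' * `"amplified"` — same sign and the magnitude grew by more than the
#'   threshold;
#' * `"retained"` — otherwise.
#'
#' The categories are exhaustive and mutually exclusive.
#'
#' @param delta_ref,delta_new couplings ([coupling_result()] or bare
#'   numbers, kJ/mol).
#' @param additive_threshold positive threshold in kJ/mol (default 1).
#' @return a character scalar, one of the five categories.
#' @export
classify_change <- function(delta_ref, delta_new, additive_threshold = 1.0) {
  stopifnot(additive_threshold > 0)
  dref <- if (inherits(delta_ref, "coupling_result")) delta_ref$delta
          else as.numeric(delta_ref)
  dnew <- if (inherits(delta_new, "coupling_result")) delta_new$delta
          else as.numeric(delta_new)
  thr <- additive_threshold
  if (abs(dnew) < thr && abs(dref) >= thr) return("erased")
  if (abs(dref) < thr && abs(dnew) >= thr) return("emergent")
  if (abs(dref) >= thr && abs(dnew) >= thr && sign(dref) != sign(dnew))
    return("inverted")
  if (abs(dref) >= thr && abs(dnew) >= thr && sign(dref) == sign(dnew) &&
      abs(dnew) > abs(dref) + thr)
    return("amplified")
  "retained"
}
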