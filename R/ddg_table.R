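## DDG tables: map (reference state, target state) -> free-energy estimate.
##
## Stored as a data frame with canonical state labels; the target state must
## strictly contain the reference state (each entry is the stability change
## of introducing the extra mutations into the reference background).

#' Table of stability changes between mutation states
#'
#' A `ddg_table` maps ordered pairs of mutation states to free-energy
#' estimates \eqn{\Delta\Delta G_{ref}^{target}} in kJ/mol, where the
#' target state strictly contains the reference state. It is the central
#' exchange format between the estimation, cycle-algebra, scanning and
#' benchmarking stages.
#'
#' @param reference character vector of reference state labels (see
#'   [state_label()]; `""` is the wild type).
#' @param target character vector of target state labels.
#' @param value numeric, kJ/mol.
#' @param uncertainty numeric, kJ/mol (1 SE); recycled if scalar.
#' @param source optional character tag per entry (e.g. `"calc"`,
#'   `"exp"`); recycled.
#' @return an object of class `"ddg_table"` (a data frame with columns
#'   `reference`, `target`, `value`, `uncertainty`, `source`).
#' @examples
#' ddg_table(reference = c("", "", ""),
#'           target = c("L37A", "G79S", "L37A+G79S"),
#'           value = c(2, 3, 9), uncertainty = 0.5)
#' @export
ddg_table <- function(reference = character(), target = character(),
                      value = numeric(), uncertainty = 0,
                      source = "calc") {
  n <- length(value)
  stopifnot(length(reference) == n, length(target) == n)
  uncertainty <- rep_len(as.numeric(uncertainty), n)
  source <- rep_len(as.character(source), n)
  value <- as.numeric(value)
  if (n > 0) {
    if (anyNA(value) || !all(is.finite(value)))
      stop("ddg values must be finite numbers")
    if (anyNA(uncertainty) || any(uncertainty < 0))
      stop("uncertainties must be non-negative numbers")
  }
  ref_sets <- lapply(reference, parse_state)
  tgt_sets <- lapply(target, parse_state)
  reference <- vapply(ref_sets, state_label, "")
  target <- vapply(tgt_sets, state_label, "")
  for (i in seq_len(n)) {
    if (!(state_contains(tgt_sets[[i]], ref_sets[[i]]) &&
          length(tgt_sets[[i]]) > length(ref_sets[[i]])))
      stop("target must strictly contain reference: '",
           reference[i], "' -> '", target[i], "'")
  }
  key <- paste(reference, target, sep = " -> ")
  if (anyDuplicated(key))
    stop("duplicate ddg entry: ", key[duplicated(key)][1L])
  df <- data.frame(reference = reference, target = target,
                   value = value, uncertainty = uncertainty,
                   source = source, stringsAsFactors = FALSE)
  class(df) <- c("ddg_table", "data.frame")
  df
}

#' @export
print.ddg_table <- function(x, ...) {
  cat(sprintf("DDG table: %d entries over %d states (kJ/mol)\n",
              nrow(x), length(unique(c(x$reference, x$target)))))
  df <- as.data.frame(x)
  df$reference[df$reference == ""] <- "WT"
  print(df, row.names = FALSE, ...)
  invisible(x)
}

#' Combine ddg tables
#'
#' @param ... `ddg_table` objects.
#' @param deparse.level unused.
#' @return a single `ddg_table`; duplicate (reference, target) keys are an
#'   error.
#' @export
rbind.ddg_table <- function(..., deparse.level = 1) {
  dfs <- lapply(list(...), as.data.frame)
  df <- do.call(rbind, dfs)
  ddg_table(df$reference, df$target, df$value, df$uncertainty, df$source)
}

## direct edge lookup; NULL when absent
.ddg_edge <- function(table, ref_label, tgt_label) {
  i <- which(table$reference == ref_label & table$target == tgt_label)
  if (length(i) == 0L) return(NULL)
  free_energy_estimate(table$value[i[1L]], table$uncertainty[i[1L]])
}

#' Look up or compose a stability change
#'
#' Returns \eqn{\Delta\Delta G_{ref}^{target}} from a direct table entry
#' when one exists, otherwise composes it along table edges via
#' [compose_path()].
#'
#' @param table a [ddg_table()].
#' @param reference,target mutation states ([mutation_set()] or labels).
#' @return a [free_energy_estimate()].
#' @export
ddg_value <- function(table, reference, target) {
  ref <- state_label(reference)
  tgt <- state_label(target)
  direct <- .ddg_edge(table, ref, tgt)
  if (!is.null(direct)) return(direct)
  compose_path(table, ref, tgt)
}

#' Read a ddg table from CSV
#'
#' Expected header: `reference,target,value_kJmol,uncertainty_kJmol,source`
#' (the `uncertainty_kJmol` and `source` columns are optional). Reference
#' and target states are `"+"`-joined mutation codes; the empty string is
#' the wild type. With `kcal = TRUE` values and uncertainties are converted
#' from kcal/mol on read (factor 4.184).
#'
#' @param path CSV file path.
#' @param kcal logical; input values are in kcal/mol.
#' @return a [ddg_table()].
#' @export
read_ddg_csv <- function(path, kcal = FALSE) {
  if (!file.exists(path)) stop("ddg csv not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = character())
  need <- c("reference", "target", "value_kJmol")
  if (!all(need %in% names(df)))
    stop("ddg csv must have columns ", paste(need, collapse = ", "),
         "; got ", paste(names(df), collapse = ", "))
  n <- nrow(df)
  value <- suppressWarnings(as.numeric(df$value_kJmol))
  if (anyNA(value))
    stop("non-numeric value_kJmol at data line ",
         which(is.na(value))[1L], " of ", path)
  unc <- if ("uncertainty_kJmol" %in% names(df)) {
    u <- suppressWarnings(as.numeric(df$uncertainty_kJmol))
    u[is.na(u) & !nzchar(df$uncertainty_kJmol)] <- 0
    if (anyNA(u))
      stop("non-numeric uncertainty_kJmol at data line ",
           which(is.na(u))[1L], " of ", path)
    u
  } else rep(0, n)
  src <- if ("source" %in% names(df)) df$source else rep("input", n)
  if (kcal) {
    value <- value * .kcal_kJ
    unc <- unc * .kcal_kJ
  }
  out <- tryCatch(
    ddg_table(df$reference, df$target, value, unc, src),
    error = function(e) stop("invalid ddg csv ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  out
}

#' Write a ddg table to CSV
#'
#' Inverse of [read_ddg_csv()]; with `kcal = TRUE` values are converted to
#' kcal/mol on write.
#'
#' @param table a [ddg_table()].
#' @param path output path.
#' @param kcal logical; write values in kcal/mol.
#' @return `path`, invisibly.
#' @export
write_ddg_csv <- function(table, path, kcal = FALSE) {
  stopifnot(inherits(table, "ddg_table"))
  df <- as.data.frame(table)
  names(df) <- c("reference", "target", "value_kJmol",
                 "uncertainty_kJmol", "source")
  if (kcal) {
    df$value_kJmol <- df$value_kJmol / .kcal_kJ
    df$uncertainty_kJmol <- df$uncertainty_kJmol / .kcal_kJ
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
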