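## Mutation specifications and mutation-set states.
##
## A mutation is rendered in the usual one-letter code, e.g. "L37A"
## (wild-type Leu at position 37 mutated to Ala). A mutation set is an
## unordered collection of mutations, at most one per (chain, position);
## the empty set is the wild type. Canonical state labels join the codes
## with "+" in (chain, position) order, so set equality is label equality.

.aa1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## side-chain charge at neutral pH; used only to flag charge-changing
## mutations (the cycle algebra treats them like any other edge)
.aa_charge <- c(D = -1, E = -1, K = 1, R = 1)

#' Mutation specification
#'
#' @param code mutation code such as `"L37A"`, optionally with a chain
#'   prefix (`"B:L37A"`). Alternatively pass `wt_res`, `position`,
#'   `mut_res` explicitly and leave `code` missing.
#' @param chain chain identifier (default `"A"`), overridden by a chain
#'   prefix in `code`.
#' @param wt_res,position,mut_res explicit components, used when `code`
#'   is missing.
#' @return an object of class `"mutation_spec"` with fields `chain`,
#'   `position`, `wt_res`, `mut_res` and a logical `charge_change` flag
#'   (set when the side-chain charge differs between wild-type and mutant
#'   residue, as for N118D).
#' @examples
#' mutation("L37A")
#' mutation(wt_res = "N", position = 118, mut_res = "D")
#' @export
mutation <- function(code, chain = "A", wt_res, position, mut_res) {
  if (!missing(code)) {
    stopifnot(is.character(code), length(code) == 1L)
    if (grepl(":", code, fixed = TRUE)) {
      parts <- strsplit(code, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stop("malformed mutation code: '", code, "'")
      chain <- parts[1L]
      code <- parts[2L]
    }
    m <- regmatches(code, regexec("^([A-Z])([0-9]+[A-Za-z]?)([A-Z])$", code))[[1]]
    if (length(m) != 4L)
      stop("malformed mutation code: '", code,
           "' (expected e.g. \"L37A\")")
    wt_res <- m[2L]; position <- m[3L]; mut_res <- m[4L]
  }
  wt_res <- toupper(wt_res); mut_res <- toupper(mut_res)
  if (!wt_res %in% .aa1 || !mut_res %in% .aa1)
    stop("residues must be canonical one-letter amino acids, got '",
         wt_res, "' and '", mut_res, "'")
  if (wt_res == mut_res)
    stop("wild-type and mutant residue are identical ('", wt_res,
         "' at ", position, ")")
  position <- as.character(position)
  if (!grepl("^[0-9]+[A-Za-z]?$", position))
    stop("invalid residue position: '", position, "'")
  cc <- .charge_of(wt_res) != .charge_of(mut_res)
  structure(list(chain = as.character(chain), position = position,
                 wt_res = wt_res, mut_res = mut_res, charge_change = cc),
            class = "mutation_spec")
}

.charge_of <- function(res) {
  v <- .aa_charge[res]
  ifelse(is.na(v), 0, v)
}

#' @export
format.mutation_spec <- function(x, ...) {
  code <- paste0(x$wt_res, x$position, x$mut_res)
  if (identical(x$chain, "A")) code else paste0(x$chain, ":", code)
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat(format(x), if (x$charge_change) " (charge-changing)" else "", "\n",
      sep = "")
  invisible(x)
}

.mut_key <- function(m) paste0(m$chain, "|", m$position)

## numeric part of the position, for ordering (insertion codes sort after)
.pos_num <- function(p) as.numeric(sub("[A-Za-z]$", "", p))

#' Mutation set (protein state)
#'
#' An unordered set of mutations relative to the wild type; the empty set
#' is the wild type itself. At most one mutation per (chain, position) is
#' allowed.
#'
#' @param ... [mutation()] objects, mutation code strings, or lists thereof.
#' @return an object of class `"mutation_set"`: a list of `mutation_spec`
#'   in canonical (chain, position) order.
#' @examples
#' mutation_set()                     # wild type
#' mutation_set("L37A", "G79S")
#' @export
mutation_set <- function(...) {
  args <- list(...)
  flat <- list()
  for (a in args) {
    if (inherits(a, "mutation_spec")) flat <- c(flat, list(a))
    else if (inherits(a, "mutation_set")) flat <- c(flat, unclass(a))
    else if (is.character(a)) flat <- c(flat, lapply(a, mutation))
    else if (is.list(a)) flat <- c(flat, lapply(a, function(x)
      if (inherits(x, "mutation_spec")) x else mutation(x)))
    else stop("cannot interpret mutation argument of class ",
              paste(class(a), collapse = "/"))
  }
  if (length(flat)) {
    keys <- vapply(flat, .mut_key, "")
    if (anyDuplicated(keys))
      stop("more than one mutation at position ",
           keys[duplicated(keys)][1L])
    ord <- order(vapply(flat, function(m) m$chain, ""),
                 vapply(flat, function(m) .pos_num(m$position), 0),
                 vapply(flat, function(m) m$position, ""))
    flat <- flat[ord]
  }
  structure(flat, class = "mutation_set")
}

#' Canonical label of a mutation state
#'
#' `""` for the wild type, otherwise `"+"`-joined mutation codes in
#' (chain, position) order, e.g. `"L37A+G79S"`.
#'
#' @param x a [mutation_set()], a `mutation_spec`, or a label string
#'   (returned canonicalised).
#' @return a character scalar.
#' @export
state_label <- function(x) {
  if (is.character(x)) x <- parse_state(x)
  if (inherits(x, "mutation_spec")) x <- mutation_set(x)
  stopifnot(inherits(x, "mutation_set"))
  if (length(x) == 0L) return("")
  paste(vapply(unclass(x), format.mutation_spec, ""), collapse = "+")
}

#' Parse a state label into a mutation set
#'
#' @param label `""` (wild type) or `"+"`-joined mutation codes.
#' @return a [mutation_set()].
#' @export
parse_state <- function(label) {
  stopifnot(is.character(label), length(label) == 1L, !is.na(label))
  label <- trimws(label)
  if (label == "" || toupper(label) == "WT") return(mutation_set())
  mutation_set(strsplit(label, "+", fixed = TRUE)[[1]])
}

#' @export
print.mutation_set <- function(x, ...) {
  cat(if (length(x) == 0L) "WT" else state_label(x), "\n")
  invisible(x)
}

## set algebra on mutation sets
state_union <- function(a, b) {
  do.call(mutation_set, c(unclass(a), unclass(b)))
}

state_contains <- function(big, small) {
  all(vapply(unclass(small), format.mutation_spec, "") %in%
        vapply(unclass(big), format.mutation_spec, ""))
}
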