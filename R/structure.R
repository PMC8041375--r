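## Minimal structure support: read residue coordinates from a PDB file and
## compute inter-residue distances (Calpha or minimum heavy atom). PDB
## record parsing is delegated to bio3d; per-residue assembly, the
## altloc/occupancy rule and the distance modes live here.

#' Read residue coordinates from a PDB file
#'
#' Parses ATOM records (HETATM are ignored) into one entry per
#' (chain, residue) with a named atom coordinate map. For alternate
#' locations the highest-occupancy conformer of each atom is kept, ties
#' resolved in favour of altloc `"A"`; insertion codes are appended to the
#' position identifier (e.g. `"27A"`).
#'
#' @param pdb path to a PDB file, or a character vector of PDB-format
#'   lines.
#' @return a list of class `"structure_model"`; each element has fields
#'   `chain`, `position`, `resid` (3-letter residue name), `atoms` (matrix
#'   with rownames = atom names, columns x/y/z in angstrom) and `elements`
#'   (chemical element per atom).
#' @export
read_structure <- function(pdb) {
  path <- pdb
  cleanup <- FALSE
  if (length(pdb) > 1L || !file.exists(pdb)) {
    path <- tempfile(fileext = ".pdb")
    writeLines(pdb, path)
    cleanup <- TRUE
  }
  on.exit(if (cleanup) unlink(path))
  parsed <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                     error = function(e)
                       stop("failed to parse PDB: ", conditionMessage(e),
                            call. = FALSE))
  at <- parsed$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in PDB input")
  at$chain[is.na(at$chain)] <- "A"
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  pos <- paste0(at$resno, at$insert)
  res_key <- paste(at$chain, pos, sep = "|")
  out <- list()
  for (k in unique(res_key)) {
    rows <- at[res_key == k, , drop = FALSE]
    ## altloc rule: per atom name keep highest occupancy, ties -> altloc 'A'
    keep <- integer(0)
    for (nm in unique(rows$elety)) {
      cand <- which(rows$elety == nm)
      if (length(cand) > 1L) {
        alt_rank <- ifelse(rows$alt[cand] == "" | rows$alt[cand] == "A",
                           0L, 1L)
        cand <- cand[order(-rows$o[cand], alt_rank)]
      }
      keep <- c(keep, cand[1L])
    }
    rows <- rows[sort(keep), , drop = FALSE]
    xyz <- as.matrix(rows[, c("x", "y", "z")])
    rownames(xyz) <- rows$elety
    if (any(!is.finite(xyz)))
      stop("non-finite coordinates in residue ", k)
    elem <- rows$elesy
    blank <- is.na(elem) | !nzchar(trimws(elem))
    ## fall back to the leading letter of the atom name
    elem[blank] <- substr(gsub("^[0-9']+", "", rows$elety[blank]), 1L, 1L)
    out[[k]] <- list(chain = rows$chain[1L],
                     position = paste0(rows$resno[1L], rows$insert[1L]),
                     resid = rows$resid[1L],
                     atoms = xyz,
                     elements = toupper(trimws(elem)))
  }
  structure(out, class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  natoms <- sum(vapply(x, function(r) nrow(r$atoms), 0L))
  cat(sprintf("Structure: %d residues, %d atoms\n", length(x), natoms))
  invisible(x)
}

.find_residue <- function(structure, res) {
  if (is.character(res) && grepl(":", res, fixed = TRUE)) {
    parts <- strsplit(res, ":", fixed = TRUE)[[1]]
    chain <- parts[1L]; position <- parts[2L]
  } else if (is.list(res)) {
    chain <- res$chain; position <- as.character(res$position)
  } else {
    chain <- "A"; position <- as.character(res)
  }
  key <- paste(chain, position, sep = "|")
  if (!key %in% names(structure))
    stop("residue not found in structure: ", chain, ":", position)
  structure[[key]]
}

#' Inter-residue distance
#'
#' @param structure a [read_structure()] result.
#' @param resA,resB residue selectors: `"chain:position"` strings (e.g.
#'   `"A:72"`), bare positions (chain `"A"` assumed), or lists with
#'   `chain`/`position`.
#' @param mode `"ca"` for the Calpha-Calpha Euclidean distance,
#'   `"min_heavy"` for the minimum over all non-hydrogen atom pairs.
#' @return distance in angstrom.
#' @export
residue_distance <- function(structure, resA, resB,
                             mode = c("min_heavy", "ca")) {
  stopifnot(inherits(structure, "structure_model"))
  mode <- match.arg(mode)
  ra <- .find_residue(structure, resA)
  rb <- .find_residue(structure, resB)
  if (mode == "ca") {
    for (r in list(ra, rb)) {
      if (!"CA" %in% rownames(r$atoms))
        stop("no CA atom in residue ", r$chain, ":", r$position)
    }
    return(sqrt(sum((ra$atoms["CA", ] - rb$atoms["CA", ])^2)))
  }
  heavy <- function(r) {
    sel <- !(r$elements %in% c("H", "D"))
    if (!any(sel))
      stop("no heavy atoms in residue ", r$chain, ":", r$position)
    r$atoms[sel, , drop = FALSE]
  }
  A <- heavy(ra); B <- heavy(rb)
  ## pairwise squared distances via the expansion |a-b|^2 = |a|^2+|b|^2-2ab
  cross <- A %*% t(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * cross
  sqrt(max(0, min(d2)))
}
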