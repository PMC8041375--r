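## Calculated-vs-experimental comparison statistics: average unsigned error,
## Pearson correlation, linear regression, and the fraction of points inside
## a +/- band (default 1 kcal/mol = 4.184 kJ/mol), optionally stratified by
## inter-residue distance.

#' Compare calculated against experimental values
#'
#' @param calc,exp paired numeric vectors in kJ/mol, equal length >= 2.
#' @param band half-width of the agreement band in kJ/mol (default 4.184,
#'   i.e. 1 kcal/mol).
#' @return an object of class `"benchmark_report"` with fields `n`, `aue`
#'   (mean unsigned error, kJ/mol), `pearson_r` (`NA` with
#'   `pearson_defined = FALSE` when either vector has zero variance),
#'   `slope`/`intercept` (ordinary least squares of calc on exp),
#'   `frac_within_band` and `band`.
#' @export
compare_ddg <- function(calc, exp, band = 4.184) {
  calc <- as.numeric(calc); exp <- as.numeric(exp)
  if (length(calc) != length(exp))
    stop("calc and exp must have equal length")
  if (length(calc) < 2L) stop("need at least 2 paired values")
  if (anyNA(calc) || anyNA(exp)) stop("calc/exp must not contain NA")
  stopifnot(is.numeric(band), length(band) == 1L, band > 0)
  n <- length(calc)
  aue <- mean(abs(calc - exp))
  v_calc <- stats::var(calc); v_exp <- stats::var(exp)
  defined <- v_calc > 0 && v_exp > 0
  r <- if (defined) stats::cor(calc, exp) else NA_real_
  if (v_exp > 0) {
    slope <- stats::cov(calc, exp) / v_exp
    intercept <- mean(calc) - slope * mean(exp)
  } else {
    slope <- NA_real_; intercept <- NA_real_
  }
  frac <- mean(abs(calc - exp) <= band)
  structure(list(n = n, aue = aue, pearson_r = r,
                 pearson_defined = defined,
                 slope = slope, intercept = intercept,
                 frac_within_band = frac, band = band),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, digits = 3, ...) {
  cat(sprintf("Benchmark over %d pairs:\n", x$n))
  cat(sprintf("  AUE: %.*f kJ/mol\n", digits, x$aue))
  if (x$pearson_defined)
    cat(sprintf("  Pearson r: %.*f\n", digits, x$pearson_r))
  else
    cat("  Pearson r: undefined (zero variance)\n")
  if (!is.na(x$slope))
    cat(sprintf("  regression calc = %.*f * exp + %.*f\n", digits, x$slope,
                digits, x$intercept))
  cat(sprintf("  within ±%.3f kJ/mol: %.1f%%\n", x$band,
              100 * x$frac_within_band))
  invisible(x)
}

#' Distance-stratified benchmark
#'
#' Partitions calc/exp pairs into half-open inter-residue-distance bins
#' `[e_i, e_{i+1})` and runs [compare_ddg()] within each bin, to check
#' whether prediction accuracy is retained from proximal to distant
#' residue pairs.
#'
#' @param results data frame with columns `pair` (identifier), `calc` and
#'   `exp` (kJ/mol).
#' @param distances named numeric vector mapping pair identifier to a
#'   distance in angstrom; every pair must be present.
#' @param edges strictly increasing bin boundaries in angstrom.
#' @param band passed to [compare_ddg()].
#' @return list of class `"stratified_benchmark"`: per bin, the range, `n`,
#'   and either a `benchmark_report` or the flag `insufficient` (fewer than
#'   2 points). Pairs outside the outermost edges are listed in
#'   `out_of_range`.
#' @export
stratify_by_distance <- function(results, distances, edges, band = 4.184) {
  stopifnot(is.data.frame(results),
            all(c("pair", "calc", "exp") %in% names(results)))
  if (length(edges) < 2L || any(diff(edges) <= 0))
    stop("edges must be strictly increasing with at least 2 values")
  d <- distances[as.character(results$pair)]
  if (anyNA(d))
    stop("missing distance for pair(s): ",
         paste(results$pair[is.na(d)], collapse = ", "))
  bin <- findInterval(d, edges, rightmost.closed = FALSE)
  bin[d >= edges[length(edges)]] <- 0L  # beyond last edge: out of range
  bins <- vector("list", length(edges) - 1L)
  for (i in seq_along(bins)) {
    sel <- bin == i
    entry <- list(from = edges[i], to = edges[i + 1L], n = sum(sel))
    if (sum(sel) >= 2L)
      entry$report <- compare_ddg(results$calc[sel], results$exp[sel],
                                  band = band)
    else entry$insufficient <- TRUE
    bins[[i]] <- entry
  }
  structure(list(bins = bins,
                 out_of_range = as.character(results$pair[bin == 0L])),
            class = "stratified_benchmark")
}

#' @export
print.stratified_benchmark <- function(x, digits = 2, ...) {
  for (b in x$bins) {
    hdr <- sprintf("[%g, %g) Å  n=%d", b$from, b$to, b$n)
    if (isTRUE(b$insufficient))
      cat(hdr, " insufficient data\n")
    else
      cat(sprintf("%s  AUE %.*f  r %s\n", hdr, digits, b$report$aue,
                  if (b$report$pearson_defined)
                    sprintf("%.*f", digits, b$report$pearson_r)
                  else "undefined"))
  }
  if (length(x$out_of_range))
    cat("out of range:", paste(x$out_of_range, collapse = ", "), "\n")
  invisible(x)
}

#' Read a benchmark CSV
#'
#' Expected header `id,calc_kJmol,exp_kJmol` with optional `distance_A`.
#'
#' @param path CSV path.
#' @param kcal logical; values are in kcal/mol and converted on read.
#' @return data frame with columns `pair`, `calc`, `exp` and optionally
#'   `distance`.
#' @export
read_benchmark_csv <- function(path, kcal = FALSE) {
  if (!file.exists(path)) stop("benchmark csv not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "calc_kJmol", "exp_kJmol")
  if (!all(need %in% names(df)))
    stop("benchmark csv must have columns ", paste(need, collapse = ", "))
  out <- data.frame(pair = as.character(df$id),
                    calc = as.numeric(df$calc_kJmol),
                    exp = as.numeric(df$exp_kJmol),
                    stringsAsFactors = FALSE)
  if (anyNA(out$calc) || anyNA(out$exp))
    stop("non-numeric calc/exp value in ", path)
  if ("distance_A" %in% names(df)) out$distance <- as.numeric(df$distance_A)
  if (kcal) {
    out$calc <- out$calc * .kcal_kJ
    out$exp <- out$exp * .kcal_kJ
  }
  out
}
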