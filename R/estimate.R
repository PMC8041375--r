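## Free-energy estimation from non-equilibrium work distributions.
##
## A work_set holds forward (WT -> mutant) and reverse (mutant -> WT) work
## samples in kJ/mol, each stored as the work done ON the system in that
## leg's own direction; estimators negate reverse work internally.

#' Forward/reverse non-equilibrium work samples
#'
#' Container for the raw material of one free-energy leg: work values from
#' repeated non-equilibrium transformations in the forward (WT to mutant)
#' and reverse (mutant to WT) direction, plus the temperature at which they
#' were collected.
#'
#' @param forward numeric vector of forward work values, kJ/mol.
#' @param reverse numeric vector of reverse work values, kJ/mol (the work of
#'   the reverse process in its own direction; not pre-negated).
#' @param temperature temperature in kelvin.
#' @return an object of class `"work_set"`.
#' @seealso [estimate_bar()], [estimate_cgi()], [estimate_jarzynski()],
#'   [generate_work_samples()]
#' @export
work_set <- function(forward = numeric(), reverse = numeric(),
                     temperature = 298.15) {
  forward <- as.numeric(forward)
  reverse <- as.numeric(reverse)
  if (anyNA(forward) || anyNA(reverse))
    stop("work values must not contain NA")
  if (!all(is.finite(forward)) || !all(is.finite(reverse)))
    stop("work values must be finite")
  if (length(forward) == 0L && length(reverse) == 0L)
    stop("at least one direction must contain work samples")
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0)
  structure(list(forward = forward, reverse = reverse,
                 temperature = temperature),
            class = "work_set")
}

#' @export
print.work_set <- function(x, ...) {
  cat(sprintf("Work set: %d forward, %d reverse samples at %.2f K\n",
              length(x$forward), length(x$reverse), x$temperature))
  invisible(x)
}

#' Read a work file
#'
#' Plain-text work files hold one value per line in kJ/mol; blank lines and
#' `#` comments (full-line or trailing) are ignored.
#'
#' @param path path to the file.
#' @return numeric vector of work values.
#' @export
read_work_file <- function(path) {
  if (!file.exists(path)) stop("work file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop("non-numeric work value in ", path, ": '", lines[bad], "'")
  }
  vals
}

#' Free-energy estimate with uncertainty
#'
#' @param value estimate in kJ/mol.
#' @param uncertainty one standard error, kJ/mol (non-negative).
#' @param method tag: one of `"bar"`, `"cgi"`, `"jarzynski"`, `"input"`.
#' @param offset_relative logical; `TRUE` when the value is only defined up
#'   to a common additive offset (unfolded-state-cancellation mode, see
#'   [ddg_from_legs()]).
#' @return an object of class `"free_energy_estimate"`.
#' @export
free_energy_estimate <- function(value, uncertainty = 0,
                                 method = "input",
                                 offset_relative = FALSE) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value),
            is.numeric(uncertainty), length(uncertainty) == 1L,
            is.finite(uncertainty))
  if (uncertainty < 0) stop("uncertainty must be >= 0")
  method <- match.arg(method, c("bar", "cgi", "jarzynski", "input"))
  structure(list(value = value, uncertainty = uncertainty, method = method,
                 offset_relative = isTRUE(offset_relative)),
            class = "free_energy_estimate")
}

#' @export
format.free_energy_estimate <- function(x, digits = 3, ...) {
  sprintf("%.*f ± %.*f kJ/mol (%s)%s", digits, x$value, digits,
          x$uncertainty, x$method,
          if (x$offset_relative) " [offset-relative]" else "")
}

#' @export
print.free_energy_estimate <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

## stable log(sum(exp(x)))
.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

## Bennett self-consistency residual at trial dg.
## f(x) = 1/(1 + exp(x)) is the Fermi function; M = log(nf/nr).
## residual(dg) = sum_f f(beta (Wf - dg) + M) - sum_r f(beta (Wr + dg) - M)
## is monotone increasing in dg, so the root is unique when bracketed.
.bar_residual <- function(dg, forward, reverse, beta, M) {
  sum(stats::plogis(-(beta * (forward - dg) + M))) -
    sum(stats::plogis(-(beta * (reverse + dg) - M)))
}

#' Bennett acceptance ratio (BAR) estimate
#'
#' Solves the Bennett self-consistency condition
#' \deqn{\sum_{i}^{n_f} f(\beta(W_i - \Delta G) + M) =
#'       \sum_{j}^{n_r} f(\beta(W'_j + \Delta G) - M)}
#' with \eqn{f} the Fermi function and \eqn{M = \ln(n_f/n_r)}, by bracketed
#' root finding on the residual. The bracket is
#' `[min - 10 s, max + 10 s]` of the pooled values `c(forward, -reverse)`
#' with `s` their standard deviation (floored at 1 kJ/mol so degenerate
#' inputs still bracket); convergence tolerance 1e-8 kJ/mol.
#'
#' @param work a [work_set()] with at least 2 samples in each direction.
#' @param error `"bootstrap"` to attach a [bootstrap_error()] standard error,
#'   `"none"` for a zero placeholder (used internally during resampling).
#' @param n_boot bootstrap resamples for the uncertainty.
#' @param seed integer seed for the bootstrap.
#' @return a [free_energy_estimate()] with `method = "bar"`.
#' @references Bennett, C. H. (1976) J. Comput. Phys. 22, 245-268.
#' @export
estimate_bar <- function(work, error = c("bootstrap", "none"),
                         n_boot = 100L, seed = 1L) {
  stopifnot(inherits(work, "work_set"))
  error <- match.arg(error)
  if (length(work$forward) < 2L || length(work$reverse) < 2L)
    stop("BAR requires at least 2 work samples in each direction")
  beta <- 1 / kT(work$temperature)
  M <- log(length(work$forward) / length(work$reverse))
  pooled <- c(work$forward, -work$reverse)
  s <- max(stats::sd(pooled), 1)
  lo <- min(pooled) - 10 * s
  hi <- max(pooled) + 10 * s
  flo <- .bar_residual(lo, work$forward, work$reverse, beta, M)
  fhi <- .bar_residual(hi, work$forward, work$reverse, beta, M)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    stop("BAR failed: work distributions do not overlap ",
         "(no sign change of the Bennett residual in [",
         signif(lo, 6), ", ", signif(hi, 6), "] kJ/mol)")
  root <- stats::uniroot(.bar_residual, c(lo, hi),
                         forward = work$forward, reverse = work$reverse,
                         beta = beta, M = M, tol = 1e-8)
  ## without phase-space overlap the residual is numerically zero over a
  ## wide plateau and the root is meaningless; detect via the Fermi
  ## occupancy at the solution, which is O(n) for overlapping data
  occ <- sum(stats::plogis(-(beta * (work$forward - root$root) + M)))
  if (occ < length(work$forward) * 1e-10)
    stop("BAR failed: work distributions do not overlap ",
         "(Fermi occupancy ", signif(occ, 3), " at the root)")
  err <- if (error == "bootstrap")
    bootstrap_error(work, estimator = "bar", n_boot = n_boot, seed = seed)
  else 0
  free_energy_estimate(root$root, err, method = "bar")
}

#' Crooks Gaussian intersection (CGI) estimate
#'
#' Fits normal densities to the forward work and to the negated reverse
#' work; the free-energy difference is the point where the two densities
#' intersect (by the Crooks fluctuation theorem the true crossing of the
#' forward and negated-reverse work distributions lies at \eqn{\Delta G}).
#' With equal fitted variances the intersection is the midpoint of the two
#' means; otherwise the quadratic in the log-density difference is solved
#' and the root lying between the two means is returned.
#'
#' @inheritParams estimate_bar
#' @return a [free_energy_estimate()] with `method = "cgi"`.
#' @export
estimate_cgi <- function(work, error = c("bootstrap", "none"),
                         n_boot = 100L, seed = 1L) {
  stopifnot(inherits(work, "work_set"))
  error <- match.arg(error)
  if (length(work$forward) < 3L || length(work$reverse) < 3L)
    stop("CGI requires at least 3 work samples in each direction")
  m1 <- mean(work$forward); s1 <- stats::sd(work$forward)
  m2 <- mean(-work$reverse); s2 <- stats::sd(-work$reverse)
  val <- .cgi_intersection(m1, s1, m2, s2)
  err <- if (error == "bootstrap")
    bootstrap_error(work, estimator = "cgi", n_boot = n_boot, seed = seed)
  else 0
  free_energy_estimate(val, err, method = "cgi")
}

.cgi_intersection <- function(m1, s1, m2, s2) {
  if (m1 == m2) return(m1)
  ## degenerate (zero-variance) fits intersect at the midpoint as well
  if (abs(s1 - s2) <= 1e-12 * max(s1, s2, 1) || s1 == 0 || s2 == 0)
    return((m1 + m2) / 2)
  ## equate log densities: quadratic a x^2 + b x + c = 0
  a <- 1 / s2^2 - 1 / s1^2
  b <- 2 * (m1 / s1^2 - m2 / s2^2)
  c0 <- m2^2 / s2^2 - m1^2 / s1^2 + 2 * log(s2 / s1)
  disc <- b^2 - 4 * a * c0
  if (disc < 0)
    stop("CGI failed: fitted densities have no real intersection ",
         "(means ", signif(m1, 6), ", ", signif(m2, 6),
         "; sds ", signif(s1, 6), ", ", signif(s2, 6), ")")
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  lo <- min(m1, m2); hi <- max(m1, m2)
  tol <- 1e-9 * max(1, hi - lo)
  inside <- roots >= lo - tol & roots <= hi + tol
  if (!any(inside))
    stop("CGI failed: no density intersection between the two means (",
         signif(lo, 6), ", ", signif(hi, 6), "); roots at ",
         paste(signif(roots, 6), collapse = ", "))
  roots[inside][1L]
}

#' Jarzynski one-sided estimate
#'
#' Exponential-average estimator from a single direction:
#' \eqn{\Delta G = -kT \ln \langle e^{-\beta W} \rangle} over forward work,
#' computed with a log-sum-exp-stable reduction; for the reverse direction
#' the same estimator is applied to the reverse-process work and the sign of
#' the result flipped so both directions estimate the forward
#' \eqn{\Delta G}. The finite-sample estimator is biased: the forward
#' estimate tends to lie above, the reverse below, the true value, so the
#' pair brackets two-sided estimators such as BAR on overlapping data.
#'
#' @param work a [work_set()].
#' @param direction `"forward"` or `"reverse"`.
#' @return a [free_energy_estimate()] with `method = "jarzynski"` and zero
#'   uncertainty (use [bootstrap_error()] for a resampled standard error).
#' @export
estimate_jarzynski <- function(work, direction = c("forward", "reverse")) {
  stopifnot(inherits(work, "work_set"))
  direction <- match.arg(direction)
  w <- work[[direction]]
  if (length(w) == 0L)
    stop("no work samples in the ", direction, " direction")
  ktemp <- kT(work$temperature)
  beta <- 1 / ktemp
  dg_own <- -ktemp * (.logsumexp(-beta * w) - log(length(w)))
  val <- if (direction == "forward") dg_own else -dg_own
  free_energy_estimate(val, 0, method = "jarzynski")
}

#' Bootstrap standard error of a work estimator
#'
#' Resamples the forward and reverse work lists independently with
#' replacement, re-runs the estimator on each resample, and returns the
#' standard deviation of the resulting estimates. Deterministic given
#' `seed`; the caller's RNG state is preserved. Resamples on which the
#' estimator fails (e.g. non-overlapping BAR distributions) are dropped;
#' failure on more than half of the resamples is an error.
#'
#' @param work a [work_set()].
#' @param estimator `"bar"`, `"cgi"`, `"jarzynski_forward"` or
#'   `"jarzynski_reverse"`.
#' @param n_boot number of resamples (>= 2).
#' @param seed integer seed.
#' @return standard error in kJ/mol.
#' @export
bootstrap_error <- function(work, estimator = c("bar", "cgi",
                                                "jarzynski_forward",
                                                "jarzynski_reverse"),
                            n_boot = 100L, seed = 1L) {
  stopifnot(inherits(work, "work_set"))
  estimator <- match.arg(estimator)
  n_boot <- as.integer(n_boot)
  if (n_boot < 2L) stop("n_boot must be >= 2")
  est_fun <- switch(estimator,
    bar = function(ws) estimate_bar(ws, error = "none")$value,
    cgi = function(ws) estimate_cgi(ws, error = "none")$value,
    jarzynski_forward = function(ws) estimate_jarzynski(ws, "forward")$value,
    jarzynski_reverse = function(ws) estimate_jarzynski(ws, "reverse")$value)
  nf <- length(work$forward); nr <- length(work$reverse)
  vals <- numeric(0)
  with_preserved_seed(seed, {
    for (b in seq_len(n_boot)) {
      f <- if (nf > 0L) work$forward[sample.int(nf, replace = TRUE)]
           else numeric(0)
      r <- if (nr > 0L) work$reverse[sample.int(nr, replace = TRUE)]
           else numeric(0)
      ws <- work_set(f, r, work$temperature)
      v <- tryCatch(est_fun(ws), error = function(e) NA_real_)
      vals[b] <- v
    }
  })
  ok <- !is.na(vals)
  if (sum(ok) < n_boot / 2)
    stop("bootstrap failed: estimator errored on ", sum(!ok), " of ",
         n_boot, " resamples")
  if (sum(ok) < 2L) stop("bootstrap failed: fewer than 2 usable resamples")
  stats::sd(vals[ok])
}

## Run code under set.seed(seed) without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}
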