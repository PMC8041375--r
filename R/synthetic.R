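## Synthetic ground truth: free-energy landscapes with planted pairwise and
## triangular couplings, noisy ddg tables derived from them, and
## Crooks-consistent Gaussian work samples. These stand in for the
## molecular-dynamics legs so that every pipeline stage can be validated
## against known answers.

#' Generate a free-energy landscape with planted couplings
#'
#' The landscape assigns every mutation state a free energy
#' \deqn{G(S) = \sum_{m \in S} g_m + \sum_{\{a,b\} \subseteq S} c_{ab}
#'   + \sum_{(\{a,b\}, c) : a,b,c \in S} t_{abc}}
#' with \eqn{G(WT) = 0}: additive single-mutation effects \eqn{g_m},
#' pairwise couplings \eqn{c_{ab}} (the source of double-mutant-cycle
#' nonadditivity), and triangular terms \eqn{t_{abc}} that switch a pair's
#' coupling on or off depending on the identity of a third site — the
#' mechanism by which, e.g., one background substitution can erase a
#' strong pair coupling entirely (plant `t = -c`).
#'
#' Ground truth for any pair and reference is available exactly through
#' [true_delta()]; the planted couplings are summarised in the returned
#' model's `ground_truth` table.
#'
#' @param n_sites number of mutable sites (positions 1..n_sites, random
#'   wild-type residues; every canonical substitution allowed).
#' @param n_pair_couplings number of site pairs given a pairwise coupling.
#' @param n_triangular number of triangular terms; each attaches a third
#'   site's specific substitution to one of the planted pairs.
#' @param single_range,pair_range,tri_range uniform effect-size ranges in
#'   kJ/mol. Defaults: singles U(-8, 8), couplings U(-10, 10), triangular
#'   terms U(-10, 10), spanning the coupling magnitudes reported for
#'   strongly nonadditive pairs in staphylococcal nuclease.
#' @param seed integer seed; generation is reproducible and leaves the
#'   caller's RNG untouched.
#' @param chain chain identifier for all sites.
#' @return an object of class `"landscape_model"`.
#' @export
generate_landscape <- function(n_sites, n_pair_couplings = 0L,
                               n_triangular = 0L,
                               single_range = c(-8, 8),
                               pair_range = c(-10, 10),
                               tri_range = c(-10, 10),
                               seed = 1L, chain = "A") {
  n_sites <- as.integer(n_sites)
  n_pair_couplings <- as.integer(n_pair_couplings)
  n_triangular <- as.integer(n_triangular)
  if (n_sites < 1L) stop("need at least one site")
  if (n_pair_couplings > choose(n_sites, 2))
    stop("infeasible: ", n_pair_couplings, " pair couplings but only ",
         choose(n_sites, 2), " site pairs available")
  if (n_triangular > 0L && (n_pair_couplings < 1L || n_sites < 3L))
    stop("infeasible: triangular terms need at least one pair coupling ",
         "and three sites")
  if (n_triangular > n_pair_couplings * (n_sites - 2L))
    stop("infeasible: too many triangular terms for the available ",
         "(pair, third-site) combinations")
  model <- with_preserved_seed(seed, {
    wt <- sample(.aa1, n_sites, replace = TRUE)
    sites <- lapply(seq_len(n_sites), function(i)
      list(position = as.character(i), wt_res = wt[i],
           substitutions = setdiff(.aa1, wt[i])))
    ## additive effect for every (site, substitution)
    singles <- list()
    for (i in seq_len(n_sites)) {
      for (s in sites[[i]]$substitutions) {
        code <- paste0(wt[i], i, s)
        singles[[code]] <- stats::runif(1, single_range[1], single_range[2])
      }
    }
    ## pairwise couplings between one specific substitution at each site
    site_pairs <- utils::combn(n_sites, 2)
    pick <- sample(ncol(site_pairs), n_pair_couplings)
    pair_couplings <- list()
    for (j in pick) {
      i1 <- site_pairs[1, j]; i2 <- site_pairs[2, j]
      m1 <- paste0(wt[i1], i1, sample(sites[[i1]]$substitutions, 1))
      m2 <- paste0(wt[i2], i2, sample(sites[[i2]]$substitutions, 1))
      pair_couplings[[length(pair_couplings) + 1L]] <-
        list(pair = sort(c(m1, m2)),
             effect = stats::runif(1, pair_range[1], pair_range[2]))
    }
    ## triangular terms: (planted pair, specific third-site substitution)
    used <- character(0)
    triangular <- list()
    for (q in seq_len(n_triangular)) {
      repeat {
        pc <- pair_couplings[[sample(length(pair_couplings), 1)]]
        pair_sites <- vapply(pc$pair,
                             function(m) mutation(m)$position, "")
        third_site <- sample(setdiff(seq_len(n_sites),
                                     as.integer(pair_sites)), 1)
        key <- paste(paste(pc$pair, collapse = "+"), third_site)
        if (!key %in% used) break
      }
      used <- c(used, key)
      m3 <- paste0(wt[third_site], third_site,
                   sample(sites[[third_site]]$substitutions, 1))
      triangular[[length(triangular) + 1L]] <-
        list(pair = pc$pair, third = m3,
             effect = stats::runif(1, tri_range[1], tri_range[2]))
    }
    list(sites = sites, singles = singles,
         pair_couplings = pair_couplings, triangular = triangular,
         chain = chain, seed = as.integer(seed))
  })
  class(model) <- "landscape_model"
  model$ground_truth <- .landscape_ground_truth(model)
  model
}

## planted couplings summarised: wild-type delta of each planted pair, and
## the third-site-modified delta for each triangular term
.landscape_ground_truth <- function(model) {
  rows <- list()
  for (pc in model$pair_couplings) {
    rows[[length(rows) + 1L]] <- data.frame(
      a = pc$pair[1], b = pc$pair[2], reference = "",
      delta = pc$effect, stringsAsFactors = FALSE)
  }
  for (tt in model$triangular) {
    base <- Filter(function(pc) identical(pc$pair, tt$pair),
                   model$pair_couplings)[[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      a = tt$pair[1], b = tt$pair[2], reference = tt$third,
      delta = base$effect + tt$effect, stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(a = character(), b = character(),
                  reference = character(), delta = numeric())
}

#' @export
print.landscape_model <- function(x, ...) {
  cat(sprintf(paste0("Landscape: %d sites, %d pair couplings, ",
                     "%d triangular terms (seed %d)\n"),
              length(x$sites), length(x$pair_couplings),
              length(x$triangular), x$seed))
  invisible(x)
}

#' Free energy of a mutation state under a landscape model
#'
#' @param model a [generate_landscape()] model.
#' @param state a [mutation_set()], label, or vector of mutation codes.
#' @return G(state) in kJ/mol relative to the wild type (G(WT) = 0).
#' @export
landscape_g <- function(model, state) {
  stopifnot(inherits(model, "landscape_model"))
  set <- if (inherits(state, "mutation_set")) state
         else if (length(state) == 1L && (is.character(state))) parse_state(state)
         else mutation_set(state)
  codes <- vapply(unclass(set), function(m)
    paste0(m$wt_res, m$position, m$mut_res), "")
  g <- 0
  for (cd in codes) {
    if (is.null(model$singles[[cd]]))
      stop("mutation not in landscape: ", cd)
    g <- g + model$singles[[cd]]
  }
  for (pc in model$pair_couplings)
    if (all(pc$pair %in% codes)) g <- g + pc$effect
  for (tt in model$triangular)
    if (all(c(tt$pair, tt$third) %in% codes)) g <- g + tt$effect
  g
}

#' Exact ground-truth coupling of a pair at a reference state
#'
#' Computed directly from the landscape's free-energy function:
#' \eqn{\delta_{ref}^{AB} = G(ref+AB) - G(ref+A) - G(ref+B) + G(ref)}.
#'
#' @param model a [generate_landscape()] model.
#' @param a,b mutation codes or [mutation()] objects.
#' @param reference reference state (default wild type).
#' @return the exact coupling in kJ/mol.
#' @export
true_delta <- function(model, a, b, reference = mutation_set()) {
  a <- if (inherits(a, "mutation_spec")) a else mutation(a)
  b <- if (inherits(b, "mutation_spec")) b else mutation(b)
  ref <- if (inherits(reference, "mutation_set")) reference
         else parse_state(reference)
  landscape_g(model, state_union(ref, mutation_set(a, b))) -
    landscape_g(model, state_union(ref, mutation_set(a))) -
    landscape_g(model, state_union(ref, mutation_set(b))) +
    landscape_g(model, ref)
}

#' Emit a ddg table from a landscape
#'
#' For each requested mutation group, writes every single-mutation
#' introduction edge between neighbouring states of the group's hypercube
#' (for a triple \{A, B, C\}: WT, A, B, C, AB, AC, BC, ABC and the twelve
#' edges between them) as the exact free-energy difference plus independent
#' Gaussian noise of standard deviation `noise_sd`; entry uncertainties are
#' set to `noise_sd`.
#'
#' @param model a [generate_landscape()] model.
#' @param groups list of mutation groups (each a character vector of codes
#'   or a [mutation_set()]); duplicated edges across groups are emitted
#'   once.
#' @param noise_sd Gaussian noise SD in kJ/mol (>= 0).
#' @param seed integer seed (caller's RNG preserved).
#' @return a [ddg_table()].
#' @export
emit_ddg_table <- function(model, groups, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(model, "landscape_model"), noise_sd >= 0)
  if (inherits(groups, "mutation_set") || is.character(groups))
    groups <- list(groups)
  edges <- list()
  for (grp in groups) {
    set <- if (inherits(grp, "mutation_set")) grp else mutation_set(grp)
    muts <- unclass(set)
    n <- length(muts)
    if (n < 1L) stop("empty mutation group")
    for (mask in 0:(2^n - 1L)) {
      members <- muts[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
      ref_set <- do.call(mutation_set, members)
      for (i in seq_len(n)) {
        if (bitwAnd(mask, 2^(i - 1L)) > 0) next
        tgt_set <- state_union(ref_set, mutation_set(muts[[i]]))
        key <- paste(state_label(ref_set), state_label(tgt_set),
                     sep = " -> ")
        if (is.null(edges[[key]]))
          edges[[key]] <- list(ref = ref_set, tgt = tgt_set)
      }
    }
  }
  vals <- with_preserved_seed(seed, {
    vapply(edges, function(e)
      landscape_g(model, e$tgt) - landscape_g(model, e$ref) +
        stats::rnorm(1, 0, noise_sd), 0)
  })
  ddg_table(reference = vapply(edges, function(e) state_label(e$ref), ""),
            target = vapply(edges, function(e) state_label(e$tgt), ""),
            value = unname(vals), uncertainty = noise_sd,
            source = "synthetic")
}

#' Crooks-consistent Gaussian work samples
#'
#' Draws forward work from \eqn{N(\Delta G + \beta\sigma^2/2, \sigma^2)}
#' and reverse work from \eqn{N(-\Delta G + \beta\sigma^2/2, \sigma^2)}.
#' This is the unique family that is Gaussian in both directions and
#' satisfies the Crooks fluctuation theorem
#' \eqn{P_f(W) / P_r(-W) = e^{\beta(W - \Delta G)}} exactly, which makes
#' the planted \eqn{\Delta G} recoverable by BAR and CGI without model
#' error.
#'
#' @param true_dg planted free-energy difference, kJ/mol.
#' @param sigma work standard deviation, kJ/mol (>= 0; 0 gives degenerate
#'   distributions at the dissipation-free values).
#' @param n_forward,n_reverse sample counts (>= 1).
#' @param temperature kelvin.
#' @param seed integer seed (caller's RNG preserved).
#' @return a [work_set()].
#' @export
generate_work_samples <- function(true_dg, sigma, n_forward, n_reverse,
                                  temperature = 298.15, seed = 1L) {
  stopifnot(sigma >= 0, n_forward >= 1L, n_reverse >= 1L)
  beta <- 1 / kT(temperature)
  drift <- sigma^2 * beta / 2
  with_preserved_seed(seed, {
    fwd <- stats::rnorm(n_forward, true_dg + drift, sigma)
    rev <- stats::rnorm(n_reverse, -true_dg + drift, sigma)
    work_set(fwd, rev, temperature)
  })
}
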