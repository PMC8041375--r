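# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: brute-force scans, naive loops, and textbook
# formulas coded directly.

kB_test <- 0.008314462618

# BAR oracle: dense grid scan of the Bennett self-consistency residual for
# its sign change, refined by bisection on the bracketing grid cell.
bar_grid_oracle <- function(forward, reverse, temperature = 298.15) {
  beta <- 1 / (kB_test * temperature)
  M <- log(length(forward) / length(reverse))
  resid <- function(dg)
    sum(1 / (1 + exp(beta * (forward - dg) + M))) -
      sum(1 / (1 + exp(beta * (reverse + dg) - M)))
  lo <- min(c(forward, -reverse)) - 30
  hi <- max(c(forward, -reverse)) + 30
  grid <- seq(lo, hi, length.out = 4001)
  vals <- vapply(grid, resid, 0)
  i <- which(diff(sign(vals)) != 0)[1]
  a <- grid[i]; b <- grid[i + 1]
  for (k in 1:80) {
    m <- (a + b) / 2
    if (sign(resid(m)) == sign(resid(a))) a <- m else b <- m
  }
  (a + b) / 2
}

# CGI oracle: bisection on the difference of the two fitted normal
# densities between the means.
cgi_bisect_oracle <- function(forward, neg_reverse) {
  m1 <- mean(forward); s1 <- sd(forward)
  m2 <- mean(neg_reverse); s2 <- sd(neg_reverse)
  f <- function(x) dnorm(x, m1, s1) - dnorm(x, m2, s2)
  a <- min(m1, m2); b <- max(m1, m2)
  stopifnot(sign(f(a)) != sign(f(b)))
  for (k in 1:200) {
    m <- (a + b) / 2
    if (sign(f(m)) == sign(f(a))) a <- m else b <- m
  }
  (a + b) / 2
}

# Naive bootstrap loop mirroring the package's documented seed policy:
# set.seed(seed), then per resample draw forward indices before reverse.
naive_bootstrap <- function(ws, est_value, n_boot, seed) {
  nf <- length(ws$forward); nr <- length(ws$reverse)
  out <- numeric(n_boot)
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    f <- ws$forward[sample.int(nf, replace = TRUE)]
    r <- ws$reverse[sample.int(nr, replace = TRUE)]
    out[b] <- est_value(work_set(f, r, ws$temperature))
  }
  sd(out)
}

# Textbook benchmark statistics coded directly from their formulas.
direct_benchmark <- function(calc, exp, band) {
  n <- length(calc)
  aue <- sum(abs(calc - exp)) / n
  mx <- sum(exp) / n; my <- sum(calc) / n
  sxy <- sum((exp - mx) * (calc - my))
  sxx <- sum((exp - mx)^2); syy <- sum((calc - my)^2)
  r <- sxy / sqrt(sxx * syy)
  slope <- sxy / sxx
  intercept <- my - slope * mx
  frac <- sum(abs(calc - exp) <= band) / n
  list(aue = aue, r = r, slope = slope, intercept = intercept, frac = frac)
}

# Brute-force minimum heavy-atom distance: exhaustive double loop.
brute_min_dist <- function(resA, resB) {
  best <- Inf
  selA <- !(resA$elements %in% c("H", "D"))
  selB <- !(resB$elements %in% c("H", "D"))
  for (i in which(selA)) for (j in which(selB)) {
    d <- sqrt(sum((resA$atoms[i, ] - resB$atoms[j, ])^2))
    if (d < best) best <- d
  }
  best
}

# A thermodynamically consistent ddg table: assign every state of a
# three-mutation box a free energy, emit all twelve single-introduction
# edges (plus optional direct double/triple edges) as exact differences.
consistent_box_table <- function(g, a = "L37A", b = "G79S", c3 = "N118D",
                                 uncertainty = 0, extra_direct = FALSE) {
  # g: named vector of state free energies; names are canonical labels
  states <- list(WT = "", A = a, B = b, C = c3,
                 AB = paste(a, b, sep = "+"), AC = paste(a, c3, sep = "+"),
                 BC = paste(b, c3, sep = "+"),
                 ABC = paste(a, b, c3, sep = "+"))
  edge <- function(r, t) data.frame(reference = states[[r]],
                                    target = states[[t]],
                                    value = g[[t]] - g[[r]],
                                    stringsAsFactors = FALSE)
  df <- rbind(edge("WT", "A"), edge("WT", "B"), edge("WT", "C"),
              edge("A", "AB"), edge("A", "AC"), edge("B", "AB"),
              edge("B", "BC"), edge("C", "AC"), edge("C", "BC"),
              edge("AB", "ABC"), edge("AC", "ABC"), edge("BC", "ABC"))
  if (extra_direct)
    df <- rbind(df, edge("WT", "AB"), edge("WT", "ABC"), edge("C", "ABC"))
  ddg_table(df$reference, df$target, df$value, uncertainty)
}

random_box_g <- function() {
  g <- rnorm(8, 0, 5)
  names(g) <- c("WT", "A", "B", "C", "AB", "AC", "BC", "ABC")
  g["WT"] <- 0
  g
}
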