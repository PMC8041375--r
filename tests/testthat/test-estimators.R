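# Free-energy estimators on non-equilibrium work samples.

test_that("BAR returns zero for symmetric work distributions", {
  expect_equal(estimate_bar(work_set(c(0, 0, 0), c(0, 0, 0), 298),
                            error = "none")$value, 0, tolerance = 1e-8)
  # mirror-symmetric about zero
  expect_equal(estimate_bar(work_set(c(1, -1), c(1, -1), 298),
                            error = "none")$value, 0, tolerance = 1e-8)
})

test_that("BAR recovers a planted free energy and matches the grid oracle", {
  ws <- generate_work_samples(5, 2, 5000, 5000, seed = 11)
  est <- estimate_bar(ws, error = "none")
  expect_lt(abs(est$value - 5), 0.15)
  expect_equal(est$value,
               bar_grid_oracle(ws$forward, ws$reverse, ws$temperature),
               tolerance = 1e-6)
})

test_that("BAR fails loudly on non-overlapping work distributions", {
  ws <- work_set(forward = c(1000, 1001, 1002),
                 reverse = c(1000, 1001, 1002), temperature = 298.15)
  expect_error(estimate_bar(ws, error = "none"), "overlap")
})

test_that("BAR and CGI are antisymmetric under direction exchange", {
  for (i in 1:20) {
    ws <- generate_work_samples(runif(1, -8, 8), runif(1, 0.5, 4),
                                40, 55, seed = 400 + i)
    swapped <- work_set(ws$reverse, ws$forward, ws$temperature)
    b1 <- estimate_bar(ws, error = "none")$value
    b2 <- estimate_bar(swapped, error = "none")$value
    expect_lt(abs(b1 + b2), 1e-9)
    # CGI legitimately refuses when the density crossing falls outside
    # the means; the refusal itself must then be direction-symmetric
    c1 <- tryCatch(estimate_cgi(ws, error = "none")$value,
                   error = function(e) NA_real_)
    c2 <- tryCatch(estimate_cgi(swapped, error = "none")$value,
                   error = function(e) NA_real_)
    expect_identical(is.na(c1), is.na(c2))
    if (!is.na(c1)) expect_lt(abs(c1 + c2), 1e-9)
  }
})

test_that("CGI equal-variance and identical-sample cases are analytic", {
  x <- rnorm(50)
  # same spread, shifted: intersection at the midpoint of the means
  ws <- work_set(forward = x + 6, reverse = -(x + 4), temperature = 298.15)
  expect_equal(estimate_cgi(ws, error = "none")$value,
               mean(x + 6) / 2 + mean(x + 4) / 2)
  # identical forward and negated-reverse samples: the common mean
  ws2 <- work_set(forward = x, reverse = -x, temperature = 298.15)
  expect_equal(estimate_cgi(ws2, error = "none")$value, mean(x))
})

test_that("CGI unequal-variance case equals the density-intersection root", {
  set.seed(21)
  for (i in 1:10) {
    fwd <- rnorm(200, 6, 1.5)
    rev <- -rnorm(300, 3, 3.0)
    ws <- work_set(fwd, rev, 298.15)
    expect_equal(estimate_cgi(ws, error = "none")$value,
                 cgi_bisect_oracle(fwd, -rev), tolerance = 1e-6)
  }
})

test_that("CGI reports failure when densities do not cross between means", {
  # narrow distribution nested inside a wide one at nearly the same mean:
  # both intersections fall outside the interval between the means
  set.seed(4)
  fwd <- rnorm(100, 0, 2)
  rev <- -(rnorm(100, 0, 0.2) + mean(fwd) + 0.05)
  ws <- work_set(fwd, rev, 298.15)
  expect_error(estimate_cgi(ws, error = "none"), "intersection")
})

test_that("Jarzynski is exact on degenerate work and matches the Gaussian
           closed form", {
  ws <- work_set(forward = c(3.2, 3.2, 3.2), reverse = c(1, 2, 3),
                 temperature = 298.15)
  expect_equal(estimate_jarzynski(ws, "forward")$value, 3.2)
  # Gaussian: dG -> mu - sigma^2 beta / 2 for large n
  mu <- 4; sigma <- 1.5
  beta <- 1 / (kB_test * 298.15)
  set.seed(31)
  big <- work_set(rnorm(2e5, mu, sigma), rnorm(10, 0, 1), 298.15)
  expect_equal(estimate_jarzynski(big, "forward")$value,
               mu - sigma^2 * beta / 2, tolerance = 0.05)
})

test_that("one-sided Jarzynski estimates straddle BAR statistically", {
  nrep <- 60
  dfwd <- drev <- numeric(nrep)
  brack <- logical(nrep)
  for (i in seq_len(nrep)) {
    ws <- generate_work_samples(5, 6, 100, 100, seed = 900 + i)
    bar <- estimate_bar(ws, error = "none")$value
    f <- estimate_jarzynski(ws, "forward")$value
    r <- estimate_jarzynski(ws, "reverse")$value
    dfwd[i] <- f - bar; drev[i] <- r - bar
    brack[i] <- f >= bar && r <= bar
  }
  # bias ordering: forward above BAR, reverse below, each at 95% confidence
  expect_gt(mean(dfwd) - 2 * sd(dfwd) / sqrt(nrep), 0)
  expect_lt(mean(drev) + 2 * sd(drev) / sqrt(nrep), 0)
  # and per-replicate bracketing in the clear majority of dissipative runs
  expect_gt(mean(brack), 0.5)
})

test_that("bootstrap error is deterministic, zero on degenerate input, and
           equals a naive resampling loop under the same seed policy", {
  ws <- generate_work_samples(3, 2, 80, 80, seed = 5)
  b1 <- bootstrap_error(ws, "bar", n_boot = 30, seed = 17)
  b2 <- bootstrap_error(ws, "bar", n_boot = 30, seed = 17)
  expect_identical(b1, b2)
  expect_gt(b1, 0)

  degen <- work_set(rep(2, 10), rep(-2, 10), 298.15)
  expect_equal(bootstrap_error(degen, "bar", n_boot = 10, seed = 1), 0,
               tolerance = 1e-8)

  oracle <- naive_bootstrap(ws, function(w) estimate_bar(w, "none")$value,
                            n_boot = 30, seed = 17)
  expect_identical(b1, oracle)
})

test_that("bootstrap does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  ws <- generate_work_samples(3, 2, 30, 30, seed = 5)
  invisible(bootstrap_error(ws, "cgi", n_boot = 10, seed = 2))
  expect_identical(runif(1), before)
})

test_that("BAR/CGI mean absolute error stays small over seeded replicates", {
  nrep <- 50
  err_bar <- err_cgi <- numeric(nrep)
  for (i in seq_len(nrep)) {
    ws <- generate_work_samples(5, 2, 1000, 1000, seed = 3000 + i)
    err_bar[i] <- abs(estimate_bar(ws, error = "none")$value - 5)
    err_cgi[i] <- abs(estimate_cgi(ws, error = "none")$value - 5)
  }
  expect_lt(mean(err_bar), 0.2)
  expect_lt(mean(err_cgi), 0.2)
})

test_that("work files accept comments and reject junk", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# forward work, kJ/mol", "1.5", "2.5 # trailing", "",
               "-0.25"), f)
  expect_equal(read_work_file(f), c(1.5, 2.5, -0.25))
  writeLines(c("1.5", "abc"), f)
  expect_error(read_work_file(f), "non-numeric")
})

test_that("work_set validates its inputs", {
  expect_error(work_set(numeric(), numeric()), "at least one")
  expect_error(work_set(c(1, NA), c(1, 2)), "NA")
  expect_error(work_set(1:3, 1:3, temperature = -1), "temperature")
  expect_error(estimate_bar(work_set(1, c(1, 2)), error = "none"),
               "at least 2")
})
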