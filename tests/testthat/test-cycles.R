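# Cycle algebra: ddg legs, nonadditivity, pathway composition, triple box.

test_that("ddg_from_legs subtracts legs with quadrature errors", {
  out <- ddg_from_legs(free_energy_estimate(4, 0.3),
                       free_energy_estimate(1, 0.4))
  expect_equal(out$value, 3)
  expect_equal(out$uncertainty, 0.5)
  expect_false(out$offset_relative)

  same <- ddg_from_legs(free_energy_estimate(2.5, 0.1),
                        free_energy_estimate(0, 0))
  expect_equal(same$value, 2.5)
})

test_that("omitting the unfolded leg flags the estimate offset-relative", {
  out <- ddg_from_legs(free_energy_estimate(4, 0.3))
  expect_equal(out$value, 4)
  expect_true(out$offset_relative)
})

test_that("per-mutation unfolded offsets cancel in every coupling", {
  set.seed(77)
  for (rep in 1:20) {
    g <- random_box_g()
    base <- consistent_box_table(g, extra_direct = FALSE)
    # an unfolded-state offset attaches to each single mutation and is
    # picked up by every edge that introduces it
    off <- c(L37A = rnorm(1), G79S = rnorm(1), N118D = rnorm(1))
    shifted <- as.data.frame(base)
    for (i in seq_len(nrow(shifted))) {
      intro <- setdiff(strsplit(shifted$target[i], "+", fixed = TRUE)[[1]],
                       strsplit(shifted$reference[i], "+",
                                fixed = TRUE)[[1]])
      shifted$value[i] <- shifted$value[i] + sum(off[intro])
    }
    tab2 <- ddg_table(shifted$reference, shifted$target, shifted$value)
    d1 <- nonadditivity(base, "L37A", "G79S")$delta
    d2 <- nonadditivity(tab2, "L37A", "G79S")$delta
    expect_equal(d1, d2, tolerance = 1e-10)
    t1 <- triple_box(base, "L37A", "G79S", "N118D")$delta
    t2 <- triple_box(tab2, "L37A", "G79S", "N118D")$delta
    expect_equal(t1, t2, tolerance = 1e-10)
  }
})

test_that("nonadditivity reproduces the additive and coupled textbook cases", {
  tab <- ddg_table(c("", "", ""), c("L37A", "G79S", "L37A+G79S"),
                   c(2, 3, 5))
  expect_equal(nonadditivity(tab, "L37A", "G79S")$delta, 0)

  tab2 <- ddg_table(c("", "", ""), c("L37A", "G79S", "L37A+G79S"),
                    c(2, 3, 9), 0.5)
  r <- nonadditivity(tab2, "L37A", "G79S")
  expect_equal(r$delta, 4)
  expect_equal(r$uncertainty, sqrt(0.75))
  expect_named(r$breakdown, c("ddg_ab", "ddg_a", "ddg_b"))
})

test_that("nonadditivity is symmetric in the pair and names missing edges", {
  tab <- ddg_table(c("", "", ""), c("L37A", "G79S", "L37A+G79S"),
                   c(2, 3, 9), 0.5)
  r1 <- nonadditivity(tab, "L37A", "G79S")
  r2 <- nonadditivity(tab, "G79S", "L37A")
  expect_identical(r1$delta, r2$delta)
  expect_identical(r1$uncertainty, r2$uncertainty)

  incomplete <- ddg_table(c("", ""), c("L37A", "G79S"), c(2, 3))
  expect_error(nonadditivity(incomplete, "L37A", "G79S"),
               "L37A\\+G79S")
})

test_that("compose_path returns direct edges unchanged and is consistent
           across pathways", {
  tab <- ddg_table(c("", "", ""),
                   c("L37A", "G79S", "L37A+G79S"),
                   c(2, 3, 9))
  direct <- compose_path(tab, "", "L37A+G79S")
  expect_equal(direct$value, 9)

  chain <- ddg_table(c("", "L37A"), c("L37A", "L37A+G79S"), c(2, 7))
  expect_equal(compose_path(chain, "", "L37A+G79S")$value, 9)
  expect_error(compose_path(chain, "", "G79S"), "no path")
})

test_that("all pathways agree on consistent tables and discrepancies are
           reported on inconsistent ones", {
  set.seed(42)
  for (rep in 1:50) {
    g <- random_box_g()
    tab <- consistent_box_table(g, extra_direct = TRUE)
    est <- compose_path(tab, "", "L37A+G79S+N118D")
    expect_equal(est$value, g[["ABC"]], tolerance = 1e-10)
    expect_lt(attr(est, "max_discrepancy"), 1e-10)
  }
  # deliberately inconsistent direct edge
  bad <- ddg_table(c("", "L37A", ""), c("L37A", "L37A+G79S", "L37A+G79S"),
                   c(2, 7, 12))
  est <- compose_path(bad, "", "L37A+G79S")
  expect_equal(est$value, 12)  # direct (shortest) edge wins
  expect_equal(attr(est, "max_discrepancy"), 3)
})

test_that("the three double-mutant-cycle pathways give one coupling", {
  set.seed(7)
  for (rep in 1:25) {
    g <- random_box_g()
    tab <- consistent_box_table(g, extra_direct = TRUE)
    # direct, via A, via B: drop edges to force each route
    df <- as.data.frame(tab)
    via_a <- ddg_table(df$reference, df$target, df$value)
    d_all <- nonadditivity(tab, "L37A", "G79S")$delta
    no_direct <- df[!(df$reference == "" & df$target == "L37A+G79S"), ]
    d_comp <- nonadditivity(ddg_table(no_direct$reference, no_direct$target,
                                      no_direct$value),
                            "L37A", "G79S")$delta
    truth <- g[["AB"]] - g[["A"]] - g[["B"]]
    expect_equal(d_all, unname(truth), tolerance = 1e-10)
    expect_equal(d_comp, unname(truth), tolerance = 1e-10)
  }
})

test_that("triple box: direct and decomposition forms agree to 1e-10", {
  set.seed(99)
  for (rep in 1:200) {
    g <- random_box_g()
    tab <- consistent_box_table(g)
    direct <- triple_box(tab, "L37A", "G79S", "N118D", route = "direct")
    decomp <- triple_box(tab, "L37A", "G79S", "N118D",
                         route = "decomposition")
    truth <- g[["ABC"]] - g[["AC"]] - g[["BC"]] + g[["C"]]
    expect_lt(abs(direct$delta - decomp$delta), 1e-10)
    expect_equal(direct$delta, unname(truth), tolerance = 1e-10)
  }
})

test_that("triple box trivial limits: background-independent C and fully
           additive landscapes", {
  # C-introduction identical at every corner: delta_C = delta_WT
  g <- c(WT = 0, A = 2, B = 3, AB = 9, C = 1.5, AC = 3.5, BC = 4.5,
         ABC = 10.5)
  tab <- consistent_box_table(g)
  d_c <- triple_box(tab, "L37A", "G79S", "N118D")
  d_wt <- nonadditivity(tab, "L37A", "G79S")
  expect_equal(d_c$delta, d_wt$delta, tolerance = 1e-12)

  # fully additive: every coupling zero
  g2 <- c(WT = 0, A = 2, B = 3, AB = 5, C = 1, AC = 3, BC = 4, ABC = 6)
  tab2 <- consistent_box_table(g2)
  expect_equal(triple_box(tab2, "L37A", "G79S", "N118D")$delta, 0,
               tolerance = 1e-12)
  expect_equal(nonadditivity(tab2, "L37A", "G79S")$delta, 0,
               tolerance = 1e-12)
})

test_that("triple box names missing decomposition edges", {
  tab <- ddg_table(c("", "", ""), c("L37A", "G79S", "L37A+G79S"),
                   c(2, 3, 9))
  expect_error(triple_box(tab, "L37A", "G79S", "N118D"), "missing")
})

test_that("propagate combines signed values with quadrature errors", {
  single <- propagate(list(free_energy_estimate(2, 0.3)), 1)
  expect_equal(single$value, 2)
  expect_equal(single$uncertainty, 0.3)

  two <- propagate(list(free_energy_estimate(1, 0.5),
                        free_energy_estimate(2, 0.5)), c(1, -1))
  expect_equal(two$value, -1)
  expect_equal(two$uncertainty, sqrt(0.5), tolerance = 1e-6)
})

test_that("quadrature matches Monte-Carlo error propagation", {
  set.seed(13)
  for (rep in 1:5) {
    k <- sample(2:5, 1)
    vals <- rnorm(k, 0, 3)
    uncs <- runif(k, 0.2, 1)
    signs <- sample(c(-1, 1), k, replace = TRUE)
    est <- propagate(mapply(free_energy_estimate, vals, uncs,
                            SIMPLIFY = FALSE), signs)
    draws <- replicate(1e5, sum(signs * rnorm(k, vals, uncs)))
    expect_equal(est$value, sum(signs * vals))
    expect_equal(est$uncertainty, sd(draws), tolerance = 0.02)
  }
})

test_that("charge-changing mutations are flagged but treated like any edge", {
  m <- mutation("N118D")
  expect_true(m$charge_change)
  expect_false(mutation("L37A")$charge_change)
  g <- random_box_g()
  tab <- consistent_box_table(g)
  # table math indifferent to the flag
  expect_silent(r <- nonadditivity(tab, "L37A", "N118D"))
  expect_equal(r$delta, unname(g[["AC"]] - g[["A"]] - g[["C"]]),
               tolerance = 1e-10)
})

test_that("is_correlated applies the coupling threshold", {
  strong <- coupling_result(list(mutation("L37A"), mutation("G79S")),
                            mutation_set(), delta = 6.85,
                            uncertainty = 1.44)
  weak <- coupling_result(list(mutation("L37A"), mutation("G79S")),
                          mutation_set(), delta = 0.4, uncertainty = 0.3)
  noisy <- coupling_result(list(mutation("L37A"), mutation("G79S")),
                           mutation_set(), delta = 2, uncertainty = 1.5)
  expect_true(is_correlated(strong))
  expect_false(is_correlated(weak))
  expect_false(is_correlated(noisy))  # |delta| < 2 * uncertainty
})
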