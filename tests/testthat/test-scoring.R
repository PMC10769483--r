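# Off-target distributions, the Jensen-Shannon selectivity score, replicate
# comparison, and the classical metrics.

test_that("off-target distribution concentrates around its activities", {
  od <- offtarget_distribution(50, seed = 2)
  expect_equal(sum(od$bins), 1, tolerance = 1e-12)
  expect_gte(sum(od$bins[9:12]), 0.99)  # ~all mass within [40,60)
  # clipped at the boundary, one sample per draw retained
  od0 <- offtarget_distribution(0, seed = 2)
  expect_gt(od0$bins[[1]], 0.95)
  # pooling: two off-targets contribute ~half the mass each
  od2 <- offtarget_distribution(c(10, 90), seed = 2)
  expect_equal(sum(od2$bins[1:4]), 0.5, tolerance = 0.05)
  expect_equal(sum(od2$bins[17:20]), 0.5, tolerance = 0.05)
  expect_error(offtarget_distribution(c(-1, 50)), "\\[0, 100\\]")
  expect_error(offtarget_distribution(50, noise_variance = 0), "positive")
})

test_that("vanishing noise recovers the exact histogram and its score", {
  acts <- c(12.5, 37.5, 62.5, 87.5)  # bin centers, >= 2 sigma from edges
  od <- offtarget_distribution(acts, noise_variance = 1e-6, seed = 4)
  expect_equal(unname(od$bins), unname(bin_distribution(acts)),
               tolerance = 1e-12)
  pen <- poisson_penalty(700, seed = 1)
  expect_equal(jsd_score(od, pen), jsd_score(bin_distribution(acts), pen),
               tolerance = 1e-12)
  # near-zero variance from a different seed agrees to well under 0.01
  od_b <- offtarget_distribution(acts, noise_variance = 1e-6, seed = 99)
  expect_equal(jsd_score(od_b, pen), jsd_score(od, pen), tolerance = 0.01)
})

test_that("JSD is a base-2 metric on the bin simplex", {
  expect_equal(jsd_score(bin_distribution(rep(33, 5)),
                         bin_distribution(rep(33, 5))), 0)
  d1 <- bin_distribution(rep(2, 10))    # all mass [0,5)
  d2 <- bin_distribution(rep(99, 10))   # all mass [95,100]
  expect_equal(jsd_score(d1, d2), 1)
  withr::with_seed(8, {
    for (i in 1:25) {
      p <- as.numeric(bin_distribution(runif(200, 0, 100)))
      q <- as.numeric(bin_distribution(runif(200, 0, 100)))
      r <- as.numeric(bin_distribution(runif(200, 0, 100)))
      expect_equal(jsd_score(p, q), jsd_score(q, p), tolerance = 1e-12)
      expect_true(jsd_score(p, q) >= 0 && jsd_score(p, q) <= 1)
      expect_lte(jsd_score(p, r), jsd_score(p, q) + jsd_score(q, r) + 1e-12)
    }
  })
  expect_error(jsd_score(d1[1:10], d2), "support")
})

test_that("lower off-target activity never hurts the score", {
  pen <- poisson_penalty(700, seed = 6)
  base <- c(95, 80, 60, 40)
  prev <- -Inf
  # shift the whole profile toward 0, away from the penalty mass
  for (shift in seq(0, 40, by = 10)) {
    od <- offtarget_distribution(base - shift, noise_variance = 1e-6,
                                 seed = 1)
    sc <- suppressWarnings(jsd_score(od, pen))
    expect_gte(sc + 1e-9, prev)
    prev <- sc
  }
})

test_that("empty off-target universe scores 1; tight penalty warns at 1", {
  pen_tight <- poisson_penalty(200, seed = 1)
  expect_equal(suppressWarnings(
    jsd_score(offtarget_distribution(numeric(0)), pen_tight)), 1)
  d_low <- bin_distribution(rep(2, 50))
  expect_warning(jsd_score(d_low, pen_tight), "broader penalty")
  pen_broad <- poisson_penalty(1200, seed = 1)
  expect_silent(jsd_score(d_low, pen_broad))
})

test_that("score replication is seed-exact and tight across seeds", {
  prof <- withr::with_seed(3, runif(60, 0, 100))
  pen <- poisson_penalty(700, seed = 5)
  s1 <- jsd_score(offtarget_distribution(prof, seed = 10), pen)
  s2 <- jsd_score(offtarget_distribution(prof, seed = 10), pen)
  expect_identical(s1, s2)
  scores <- vapply(1:20, function(s)
    jsd_score(offtarget_distribution(prof, seed = s), pen), numeric(1))
  expect_lt(sd(scores), 0.01)
})

test_that("delta_jsd applies both the t-test and the absolute cutoff", {
  combo <- c(0.95, 0.951, 0.949, 0.952, 0.95)
  single <- c(0.93, 0.931, 0.929, 0.93, 0.932)
  d <- delta_jsd(combo, single)
  expect_equal(d$delta, mean(combo) - mean(single))
  expect_lt(d$p_value, 0.05)
  expect_true(d$significant)
  # identical replicate sets: delta 0, not significant
  d0 <- delta_jsd(single, single)
  expect_equal(d0$delta, 0)
  expect_false(d0$significant)
  # tiny but statistically clean difference fails the 0.001 cutoff
  quiet <- c(0.93, 0.93010, 0.92995, 0.93005, 0.93)
  tiny <- delta_jsd(quiet + 0.0005, quiet)
  expect_lt(tiny$p_value, 0.05)
  expect_false(tiny$significant)
  expect_error(delta_jsd(0.9, c(0.8, 0.8)), "two replicate")
  # the worked two-affinity contrast: 21 vs 1.1 nM is a ~19-fold change
  expect_equal(round(fold_error(21, 1.1)), 19)
})

test_that("Gini coefficient matches closed forms", {
  expect_equal(gini_coefficient(rep(7, 12)), 0)
  for (m in c(2, 5, 20)) {
    x <- c(90, rep(0, m - 1))
    expect_equal(gini_coefficient(x), (m - 1) / m, tolerance = 1e-12)
  }
  expect_equal(gini_coefficient(c(90, 10)), 0.4)
  expect_error(gini_coefficient(rep(0, 4)), "all-zero")
})

test_that("S-score counts the universe fraction above threshold", {
  expect_equal(s_score(c(10, 20, 49.9)), 0)
  expect_equal(s_score(c(rep(80, 3), rep(10, 7))), 0.3)
  expect_equal(s_score(c(95, 80, 10), threshold = 90), 1 / 3)
  expect_error(s_score(numeric(0)), "empty")
})

test_that("relative selectivity factor is on-target share of total", {
  expect_equal(relative_selectivity_factor(90, c(90, 0, 0)), 1)
  expect_equal(relative_selectivity_factor(90, c(90, 90)), 0.5)
  expect_equal(relative_selectivity_factor(90, c(90, rep(10, 9))), 0.5)
  expect_error(relative_selectivity_factor(0, c(0, 0)), "positive")
})

test_that("reproducibility scores modal rank-1 agreement", {
  expect_equal(reproducibility(list(c("a", "b"), c("b", "a"), c("a", "b"))),
               100)
  sets <- list(c("a"), c("a"), c("a"), c("b"), c("c"))
  expect_equal(reproducibility(sets), 60)
  # two-way 2/2/1 tie resolves lexicographically
  tie <- list(c("b"), c("b"), c("a"), c("a"), c("c"))
  expect_equal(reproducibility(tie), 40)
  expect_error(reproducibility(list(c("a"))), "two replicates")
})
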