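# Combination enumeration, branch-and-bound concentration optimization, and
# the replicated nomination pipeline.

test_that("eligibility applies the potency threshold at the reference frame", {
  v <- matrix(NA_real_, 3, 2,
              dimnames = list(c("potent", "border", "weak"), c("T", "o")))
  v[, "T"] <- c(50, 110, 120)
  v[, "o"] <- 1000
  m <- potency_matrix(v, "affinity")
  pool <- eligible_pool(m, target_spec("T"))
  # 110 nM -> 90.09% (eligible); 120 nM -> 89.3% (not)
  expect_setequal(pool, c("potent", "border"))
})

test_that("multi-target pool admits compounds potent on one target only", {
  v <- matrix(NA_real_, 2, 2, dimnames = list(c("a", "b"), c("T1", "T2")))
  v["a", "T1"] <- 10; v["a", "T2"] <- 1e5
  v["b", "T2"] <- 10; v["b", "T1"] <- 1e5
  m <- potency_matrix(v, "affinity")
  spec <- target_spec(c("T1", "T2"))
  expect_setequal(eligible_pool(m, spec), c("a", "b"))
  # pair is feasible, singles are not (cannot cover both targets at 1 uM cap)
  combos <- enumerate_combinations(c("a", "b"), m, spec,
                                   optimizer_config(max_i = 2,
                                                    max_conc = 1000))
  expect_equal(combos, list(c("a", "b")))
})

test_that("enumeration counts subsets and drops the infeasible", {
  m <- orthogonal_toy(5)
  spec <- target_spec("T")
  combos <- enumerate_combinations(paste0("c", 1:5), m, spec,
                                   optimizer_config(max_i = 3))
  expect_length(combos, 5 + 10 + 10)
  # an impossible concentration ceiling removes everything
  none <- enumerate_combinations(paste0("c", 1:5), m, spec,
                                 optimizer_config(max_i = 2, max_conc = 1))
  expect_length(none, 0)
  expect_length(enumerate_combinations(character(0), m, spec), 0)
})

test_that("single-compound optimization is a threshold dilution no-op", {
  m <- two_compound_toy()
  spec <- target_spec("T")
  pen <- poisson_penalty(700, seed = 2)
  out <- optimize_concentrations("a", m, spec, pen,
                                 optimizer_config(), seed = 5)
  expect_equal(out$rounds, 0L)
  ref <- dilute_to_threshold(mixture("a", 1000), m, spec)
  expect_equal(out$mixture$concentrations, ref$concentrations)
  expect_error(optimize_concentrations("a", m, spec, pen,
                                       optimizer_config(max_conc = 1)),
               "threshold")
})

test_that("optimizer matches the exhaustive log-grid oracle on 2-compound toys", {
  # the oracle grid steps the concentration ratio by 10^0.1 (~1.26x), so the
  # pairwise variation must resolve ratios at least that finely (R1 = 1.3);
  # with only 2 off-targets the pooled noise sample is raised to the depth a
  # >=50-kinase universe gets at the default 100 draws/kinase; and since the
  # oracle's best-of-61 on a jittered objective is upward-biased, both
  # winners are re-evaluated under one fresh noise realization
  cfg <- optimizer_config(max_i = 2, R1 = 1.3, samples_per_kinase = 2500)
  spec <- target_spec("T")
  toys <- list(two_compound_toy(50, 50, 200, 200),    # all K equal
               two_compound_toy(50, 50, 200, 500),
               two_compound_toy(20, 80, 2000, 150),
               two_compound_toy(100, 30, 5000, 5000))
  for (ti in seq_along(toys)) {
    m <- toys[[ti]]
    pen <- poisson_penalty(700, seed = ti)
    opt <- optimize_concentrations(c("a", "b"), m, spec, pen, cfg,
                                   seed = ti * 11)
    oracle <- grid_oracle_best(m, spec, pen, cfg, seed = ti * 11)
    eval_seed <- 9000 + ti
    jsd_opt <- score_conc_pair(opt$mixture$concentrations[c("a", "b")],
                               m, spec, pen, cfg, eval_seed)
    jsd_oracle <- score_conc_pair(oracle$conc, m, spec, pen, cfg, eval_seed)
    expect_gte(jsd_opt, jsd_oracle - 0.005)
  }
})

test_that("incumbent score never decreases across optimization rounds", {
  cfg <- optimizer_config(max_i = 2)
  withr::with_seed(21, {
    for (case in 1:100) {
      m <- two_compound_toy(10^runif(1, 0.5, 2), 10^runif(1, 0.5, 2),
                            10^runif(1, 1.5, 4), 10^runif(1, 1.5, 4))
      pen <- poisson_penalty(sample(c(200, 700, 1200), 1),
                             seed = 1000 + case)
      out <- optimize_concentrations(c("a", "b"), m, target_spec("T"), pen,
                                     cfg, seed = case)
      expect_true(all(diff(out$trace) >= -1e-9))
      # hard constraint: threshold held at the returned concentrations
      expect_gte(attr(out$mixture, "on_target_activity"), 90)
    }
  })
})

test_that("a penalty-free compound comes to dominate the optimized mixture", {
  # compound a has a close off-target; compound b's off-target is far below
  # any penalized range, so the optimizer should push b up and a down
  v <- matrix(NA_real_, 2, 3, dimnames = list(c("a", "b"), c("T", "oa", "ob")))
  v["a", "T"] <- 50; v["a", "oa"] <- 60
  v["b", "T"] <- 50; v["b", "ob"] <- 1e6
  m <- potency_matrix(v, "affinity")
  pen <- poisson_penalty(200, seed = 3)
  out <- suppressWarnings(
    optimize_concentrations(c("a", "b"), m, target_spec("T"), pen,
                            optimizer_config(), seed = 9))
  ratio <- out$mixture$concentrations[["b"]] /
    out$mixture$concentrations[["a"]]
  expect_gt(ratio, 5)  # at least one R1 step in b's favor
  solo_a <- suppressWarnings(
    optimize_concentrations("a", m, target_spec("T"), pen,
                            optimizer_config(), seed = 9))
  expect_gt(out$jsd, solo_a$jsd)
})

test_that("activity-kind matrices stay equimolar (no optimization rounds)", {
  v <- matrix(c(95, 95, 80, 20), 2, 2,
              dimnames = list(c("a", "b"), c("T", "o")))
  m <- potency_matrix(v, "activity")
  pen <- poisson_penalty(700, seed = 2)
  out <- optimize_concentrations(c("a", "b"), m, target_spec("T"), pen,
                                 optimizer_config(), seed = 4)
  expect_equal(out$rounds, 0L)
  conc <- out$mixture$concentrations
  expect_equal(unname(conc[1] / conc[2]), 1)
})

test_that("run_mms nominates the clean single when no combo can beat it", {
  # one compound hits only the target; a second drags in an off-target
  v <- matrix(NA_real_, 2, 2, dimnames = list(c("clean", "dirty"),
                                              c("T", "o")))
  v["clean", "T"] <- 50
  v["dirty", "T"] <- 50; v["dirty", "o"] <- 50
  m <- potency_matrix(v, "affinity")
  res <- suppressWarnings(
    run_mms(m, target_spec("T"), penalty_preset("medium", seed = 1),
            optimizer_config(max_i = 2), seed = 7))
  expect_equal(res$best_single$set, "clean")
  expect_equal(res$verdict, "single_better_or_tied")
})

test_that("run_mms finds the orthogonal trio beats any single", {
  m <- orthogonal_toy(3)
  res <- run_mms(m, target_spec("T"), penalty_preset("tight", seed = 1),
                 optimizer_config(max_i = 3), seed = 42)
  expect_equal(res$verdict, "combination_better")
  expect_setequal(res$best_combo$set, c("c1", "c2", "c3"))
  expect_gt(res$delta$delta, 0)
  expect_lt(res$delta$p_value, 0.05)
  # every reported mixture respects the threshold
  expect_gte(attr(res$best_combo$mixture, "on_target_activity"), 90)
  expect_gte(attr(res$best_single$mixture, "on_target_activity"), 90)
})

test_that("run_mms is deterministic under a fixed master seed", {
  m <- orthogonal_toy(3)
  cfg <- optimizer_config(max_i = 2)
  r1 <- run_mms(m, target_spec("T"), penalty_preset("tight", seed = 1), cfg,
                seed = 11)
  r2 <- run_mms(m, target_spec("T"), penalty_preset("tight", seed = 1), cfg,
                seed = 11)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$best_combo$mixture$concentrations,
                   r2$best_combo$mixture$concentrations)
  # rescoring a returned mixture from scratch reproduces its stored score
  spec <- target_spec("T")
  rep1_seed <- mmselect:::derive_seed(11, "replicate", 1)
  pen_r <- mmselect:::resample_penalty(penalty_preset("tight", seed = 1),
                                       mmselect:::derive_seed(rep1_seed,
                                                              "penalty"))
  key <- paste(res_set <- r1$best_combo$set, collapse = " + ")
  opt <- optimize_concentrations(r1$best_combo$set, m, spec, pen_r, cfg,
                                 seed = mmselect:::derive_seed(rep1_seed,
                                                               "combo", key))
  expect_identical(opt$jsd, unname(r1$best_combo$scores[["rep1"]]))
})

test_that("an empty pool yields an infeasible verdict, not an error", {
  v <- matrix(5000, 1, 2, dimnames = list("weak", c("T", "o")))
  m <- potency_matrix(v, "affinity")
  res <- run_mms(m, target_spec("T"), penalty_preset("tight", seed = 1),
                 optimizer_config(), seed = 1)
  expect_equal(res$verdict, "infeasible")
})
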