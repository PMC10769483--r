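# Combination enumeration, branch-and-bound concentration optimization, and
# the replicated nomination pipeline.

#' Optimizer configuration
#'
#' Bundles the tunable settings of the nomination pipeline. Defaults match
#' the standard single-target protocol: pairwise concentration variation fold
#' `R1 = 5`, dilution step `R2 = 1.1`, on-target threshold 90%, noise
#' variance 2.5, five technical replicates, significance at `p < 0.05` with
#' an absolute score-improvement cutoff of 0.001.
#'
#' @param max_i Maximum number of compounds per combination; default 2.
#' @param R1 Pairwise concentration variation fold per optimization round
#'   (> 1); default 5. Values of 2-5 trade precision against run time.
#' @param R2 Dilution step factor (> 1); default 1.1.
#' @param threshold On-target percent-activity threshold; default 90.
#' @param min_conc,max_conc Concentration bounds in nM (`max_conc = NULL`
#'   means unbounded, the screening default; use 1000 for validation-style
#'   runs constrained by solubility).
#' @param n_replicates Technical replicates; default 5.
#' @param abs_cutoff Minimum mean score improvement for significance;
#'   default 0.001.
#' @param p_cutoff Significance level; default 0.05.
#' @param noise_variance Gaussian smoothing variance; default 2.5.
#' @param samples_per_kinase Noise draws per off-target kinase; default 100.
#' @param convergence_eps Minimum score improvement to continue optimizing;
#'   default 1e-6.
#' @return A list of class `optimizer_config`.
#' @export
optimizer_config <- function(max_i = 2, R1 = 5, R2 = 1.1, threshold = 90,
                             min_conc = 1e-6, max_conc = NULL,
                             n_replicates = 5, abs_cutoff = 0.001,
                             p_cutoff = 0.05, noise_variance = 2.5,
                             samples_per_kinase = 100,
                             convergence_eps = 1e-6) {
  stopifnot(R1 > 1, R2 > 1, max_i >= 1, n_replicates >= 2)
  structure(list(max_i = as.integer(max_i), R1 = R1, R2 = R2,
                 threshold = threshold, min_conc = min_conc,
                 max_conc = max_conc, n_replicates = as.integer(n_replicates),
                 abs_cutoff = abs_cutoff, p_cutoff = p_cutoff,
                 noise_variance = noise_variance,
                 samples_per_kinase = samples_per_kinase,
                 convergence_eps = convergence_eps),
            class = "optimizer_config")
}

#' Compounds potent enough to enter the combination search
#'
#' A compound joins the pool when its activity at the reference frame reaches
#' the on-target threshold against **at least one** target (for a single
#' target: against that target). At the default 90% threshold in a 1 uM
#' reference frame this corresponds to an affinity of 111 nM or better.
#' Compounds potent on only a subset of a multi-kinase target set stay in the
#' pool: they may complement each other in a combination, and combination
#' feasibility enforces the threshold at every target.
#'
#' @param m A [potency_matrix()].
#' @param spec A [target_spec()].
#' @return Character vector of eligible compound IDs (possibly empty).
#' @export
eligible_pool <- function(m, spec) {
  r <- resolve_spec(m, spec)
  act <- activities_at_ref(m)[, r$targets, drop = FALSE]
  compounds(m)[apply(act >= spec$on_target_threshold, 1, any)]
}

# Can `combo` reach the threshold at every target with each component at or
# below max_conc?
combo_feasible <- function(combo, Kt, threshold, max_conc) {
  conc <- rep(if (is.null(max_conc)) 1e9 else max_conc, length(combo))
  s <- colSums(conc / Kt[combo, , drop = FALSE])
  all(100 * s / (1 + s) >= threshold)
}

#' Enumerate feasible compound combinations
#'
#' All subsets of the eligible pool of size `1..max_i`, dropping subsets that
#' cannot maintain the threshold activity at every target even with every
#' component dosed at `max_conc` (or arbitrarily high when unbounded).
#'
#' @inheritParams eligible_pool
#' @param pool Character vector of candidate compounds (e.g. from
#'   [eligible_pool()]).
#' @param config An [optimizer_config()].
#' @return List of character vectors, each a feasible combination, ordered by
#'   size then lexicographically.
#' @export
enumerate_combinations <- function(pool, m, spec, config = optimizer_config()) {
  if (length(pool) == 0L) return(list())
  r <- resolve_spec(m, spec)
  Kt <- pseudo_affinities(m)[, r$targets, drop = FALSE]
  pool <- sort(pool)
  out <- list()
  for (i in seq_len(min(config$max_i, length(pool)))) {
    subsets <- combn(pool, i, simplify = FALSE)
    keep <- vapply(subsets, combo_feasible, logical(1), Kt = Kt,
                   threshold = spec$on_target_threshold,
                   max_conc = config$max_conc)
    out <- c(out, subsets[keep])
  }
  out
}

# Score one concentration vector: dilute onto the threshold, build the
# noisy off-target distribution, return list(jsd, mixture, feasible).
score_concentrations <- function(combo, conc, K, targets, offtargets, spec,
                                 penalty, config, seed) {
  mix <- dilute_to_threshold(mixture(combo, conc), .K_matrix_stub(K), spec,
                             R2 = config$R2, max_conc = config$max_conc,
                             min_conc = config$min_conc)
  if (!isTRUE(attr(mix, "feasible"))) {
    return(list(jsd = -Inf, mixture = mix, feasible = FALSE))
  }
  s <- colSums(mix$concentrations / K[combo, offtargets, drop = FALSE])
  profile <- 100 * s / (1 + s)
  od <- offtarget_distribution(profile, config$noise_variance,
                               config$samples_per_kinase, seed)
  list(jsd = suppressWarnings(jsd_score(od, penalty)), mixture = mix,
       feasible = TRUE)
}

# dilute_to_threshold works on a potency_matrix; wrap a pre-computed
# affinity matrix so the optimizer avoids re-deriving pseudo-affinities.
.K_matrix_stub <- function(K) {
  structure(list(values = K, value_kind = "affinity", reference_conc = 1000,
                 missing = matrix(FALSE, nrow(K), ncol(K), dimnames = dimnames(K)),
                 mutant_flags = setNames(rep(FALSE, ncol(K)), colnames(K))),
            class = "potency_matrix")
}

#' Optimize component concentrations of one combination
#'
#' Branch-and-bound hill climb on the concentration simplex. The mixture is
#' initialized equimolar at the reference concentration and diluted onto the
#' on-target threshold. Each round generates, for every unordered compound
#' pair, both orientations of an `R1`-fold variation (one component up, the
#' other down), clamps to the concentration bounds, re-dilutes each candidate
#' onto the threshold and scores it; the best candidate becomes the next
#' incumbent and all others are culled. One noise realization (derived from
#' `seed`) is shared by every scoring inside the call, so comparisons are
#' paired, the objective is deterministic, and the incumbent score is
#' non-decreasing across rounds. Optimization stops when no candidate
#' improves the incumbent score by more than the convergence epsilon. Fresh
#' noise enters between technical replicates, not within an optimization.
#'
#' For activity-kind matrices no concentration optimization is performed:
#' single-concentration screening values are too imprecise near the threshold
#' to support meaningful dilution ratios, so mixtures stay equimolar (diluted
#' onto the threshold).
#'
#' @param combo Character vector of compound IDs (a feasible combination).
#' @param m A [potency_matrix()].
#' @param spec A [target_spec()].
#' @param penalty A `penalty_distribution`.
#' @param config An [optimizer_config()].
#' @param seed RNG seed for the noise realizations (one stream per round).
#' @return List: `mixture` (optimized, threshold-compliant), `jsd` (score of
#'   the incumbent under the final noise realization), `rounds`, `trace`
#'   (incumbent score per round).
#' @export
optimize_concentrations <- function(combo, m, spec, penalty,
                                    config = optimizer_config(),
                                    seed = NULL) {
  r <- resolve_spec(m, spec)
  K <- pseudo_affinities(m)
  unknown <- setdiff(combo, compounds(m))
  if (length(unknown) > 0L) {
    stop("unknown compound(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  Kt <- K[, r$targets, drop = FALSE]
  if (!combo_feasible(combo, Kt, spec$on_target_threshold, config$max_conc)) {
    stop("combination cannot reach the on-target threshold: ",
         paste(combo, collapse = " + "), call. = FALSE)
  }
  combo <- sort(combo)
  noise_seed <- derive_seed(seed, "noise")
  conc <- rep(m$reference_conc, length(combo))
  incumbent <- score_concentrations(combo, conc, K, r$targets, r$offtargets,
                                    spec, penalty, config, noise_seed)
  if (!incumbent$feasible) {
    # equimolar start cannot reach the threshold within max_conc even
    # though some dosing can (asymmetric potencies): start from max_conc
    conc <- rep(config$max_conc, length(combo))
    incumbent <- score_concentrations(combo, conc, K, r$targets, r$offtargets,
                                      spec, penalty, config, noise_seed)
  }
  trace <- incumbent$jsd
  rounds <- 0L
  skip_optim <- m$value_kind == "activity" || length(combo) == 1L
  while (!skip_optim) {
    base <- incumbent$mixture$concentrations
    pairs <- combn(seq_along(combo), 2, simplify = FALSE)
    candidates <- list()
    for (pr in pairs) {
      for (orient in list(c(config$R1, 1 / config$R1),
                          c(1 / config$R1, config$R1))) {
        conc2 <- base
        conc2[pr] <- conc2[pr] * orient
        conc2 <- pmax(conc2, config$min_conc)
        if (!is.null(config$max_conc)) conc2 <- pmin(conc2, config$max_conc)
        candidates[[length(candidates) + 1L]] <- conc2
      }
    }
    scored <- lapply(candidates, function(cc)
      score_concentrations(combo, cc, K, r$targets, r$offtargets, spec,
                           penalty, config, noise_seed))
    jsds <- vapply(scored, `[[`, numeric(1), "jsd")
    best <- which.max(jsds)
    if (length(best) == 0L ||
        jsds[best] <= incumbent$jsd + config$convergence_eps) {
      break
    }
    # tie-break among equal scores: lower total concentration first
    tied <- which(abs(jsds - jsds[best]) < 1e-12)
    if (length(tied) > 1L) {
      totals <- vapply(scored[tied], function(s) sum(s$mixture$concentrations),
                       numeric(1))
      best <- tied[which.min(totals)]
    }
    incumbent <- scored[[best]]
    rounds <- rounds + 1L
    trace <- c(trace, incumbent$jsd)
  }
  list(mixture = incumbent$mixture, jsd = incumbent$jsd, rounds = rounds,
       trace = trace)
}

#' Run the full replicated nomination pipeline
#'
#' For each technical replicate the penalty distribution is resampled and
#' fresh Gaussian noise is used throughout; every feasible combination is
#' concentration-optimized and scored. Scores are aggregated across
#' replicates keyed by compound set. The best single inhibitor (highest mean
#' score at size 1) is compared to the best combination (size > 1) with a
#' two-sample t-test and the absolute improvement cutoff; mutant kinases are
#' excluded from every off-target distribution throughout.
#'
#' @param m A [potency_matrix()].
#' @param spec A [target_spec()].
#' @param penalty A `penalty_distribution` used as the template that is
#'   resampled per replicate.
#' @param config An [optimizer_config()].
#' @param seed Master seed; per-replicate streams are derived from it.
#' @return An `mms_result`: `table` (one row per compound set: set, size,
#'   mean/sd score, per-replicate scores, optimized concentrations from the
#'   first replicate), `best_single`, `best_combo`, `delta` (see
#'   [delta_jsd()]), `verdict` (`"combination_better"`,
#'   `"single_better_or_tied"` or `"infeasible"`), `reproducibility`, and the
#'   settings used.
#' @export
run_mms <- function(m, spec, penalty = penalty_preset("medium"),
                    config = optimizer_config(), seed = NULL) {
  pool <- eligible_pool(m, spec)
  empty_result <- function() {
    structure(list(table = NULL, best_single = NULL, best_combo = NULL,
                   delta = NULL, verdict = "infeasible",
                   reproducibility = NA_real_,
                   config = config, penalty = penalty, seed = seed),
              class = "mms_result")
  }
  if (length(pool) == 0L) return(empty_result())
  combos <- enumerate_combinations(pool, m, spec, config)
  if (length(combos) == 0L) return(empty_result())

  keys <- vapply(combos, function(s) paste(sort(s), collapse = " + "),
                 character(1))
  nrep <- config$n_replicates
  scores <- matrix(NA_real_, length(combos), nrep,
                   dimnames = list(keys, paste0("rep", seq_len(nrep))))
  first_mixtures <- vector("list", length(combos))
  rank1 <- vector("list", nrep)

  for (rep_i in seq_len(nrep)) {
    rep_seed <- derive_seed(seed, "replicate", rep_i)
    pen_r <- resample_penalty(penalty, derive_seed(rep_seed, "penalty"))
    for (ci in seq_along(combos)) {
      opt <- optimize_concentrations(combos[[ci]], m, spec, pen_r, config,
                                     seed = derive_seed(rep_seed, "combo", keys[ci]))
      scores[ci, rep_i] <- opt$jsd
      if (rep_i == 1L) first_mixtures[[ci]] <- opt$mixture
    }
    rank1[[rep_i]] <- combos[[which.max(scores[, rep_i])]]
  }

  sizes <- lengths(combos)
  mean_scores <- rowMeans(scores)
  ord <- order(-mean_scores, sizes, keys)
  tab <- data.frame(set = keys, size = sizes, mean_jsd = mean_scores,
                    sd_jsd = apply(scores, 1, stats::sd),
                    stringsAsFactors = FALSE)[ord, ]
  rownames(tab) <- NULL

  singles <- which(sizes == 1L)
  multis <- which(sizes > 1L)
  best_single_i <- singles[which.max(mean_scores[singles])]
  best_single <- list(set = combos[[best_single_i]],
                      scores = scores[best_single_i, ],
                      mixture = first_mixtures[[best_single_i]])
  best_combo <- NULL
  delta <- NULL
  verdict <- "single_better_or_tied"
  if (length(multis) > 0L) {
    best_combo_i <- multis[which.max(mean_scores[multis])]
    best_combo <- list(set = combos[[best_combo_i]],
                       scores = scores[best_combo_i, ],
                       mixture = first_mixtures[[best_combo_i]])
    delta <- delta_jsd(best_combo$scores, best_single$scores,
                       abs_cutoff = config$abs_cutoff,
                       p_cutoff = config$p_cutoff)
    if (isTRUE(delta$significant)) verdict <- "combination_better"
  }

  structure(list(table = tab, scores = scores, best_single = best_single,
                 best_combo = best_combo, delta = delta, verdict = verdict,
                 reproducibility = reproducibility(rank1),
                 rank1_sets = rank1, config = config, penalty = penalty,
                 seed = seed),
            class = "mms_result")
}

#' @export
print.mms_result <- function(x, ...) {
  cat("<mms_result> verdict:", x$verdict, "\n")
  if (!is.null(x$best_single)) {
    cat(sprintf("  best single: %s (mean JSD %.4f)\n",
                paste(x$best_single$set, collapse = " + "),
                mean(x$best_single$scores)))
  }
  if (!is.null(x$best_combo)) {
    cat(sprintf("  best combo:  %s (mean JSD %.4f, dJSD %+.4f, p = %.3g)\n",
                paste(x$best_combo$set, collapse = " + "),
                mean(x$best_combo$scores), x$delta$delta, x$delta$p_value))
  }
  if (is.finite(x$reproducibility %||% NA)) {
    cat(sprintf("  reproducibility: %.0f%%\n", x$reproducibility))
  }
  invisible(x)
}
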