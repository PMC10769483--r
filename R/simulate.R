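# Synthetic-data engine: parameterized parent selectivity profiles,
# bootstrapped inhibitor panels, the set-size scan, and the fold-error
# Monte-Carlo for mixture potency predictions. Also serves as the package's
# test-fixture generator, so everything is testable without external
# datasets.

# Default fraction of a screening-like profile's mass in the lowest bin, and
# the geometric decay rate of the mid-range tail.
PKIS2_LOW_MASS <- 0.80
PKIS2_DECAY <- 0.72

#' Build a parent selectivity profile
#'
#' A parent profile is a 20-bin probability distribution over percent
#' activity from which per-compound-per-kinase activities are drawn i.i.d.
#' Four kinds are available:
#'
#' * `"pkis2_like"` — emulates a large screening panel of relatively
#'   selective compounds: most mass (default 0.80) in the `[0,5)` bin, a
#'   geometrically decaying mid-range tail, and a small potent-hit mass.
#'   The exact panel-average vector of any real screen is not reproduced;
#'   this is a documented approximation of its shape.
#' * `"reduced_selectivity"`, `"least_selective"` — the base profile's
#'   non-hit bins mixed with a uniform distribution at weight `smoothing`
#'   (defaults 0.35 and 0.75), hit mass untouched; `"least_selective"` has
#'   nonzero mass in every bin.
#' * `"binary"` — compounds are either potent (activity in `[95,100]`) or
#'   inactive (activity in `[0,5)`).
#'
#' All kinds place the same `hit_prob` mass at >= 90% activity so the
#' probability of reaching threshold on-target activity is comparable across
#' profiles.
#'
#' @param kind Profile kind (see above).
#' @param hit_prob Probability that a drawn activity is >= 90%; default 0.02.
#' @param smoothing Uniform-mixing weight in `[0, 1]` for the smoothed kinds;
#'   `NULL` uses the kind's default.
#' @return A `parent_profile`: `bin_probs` (length 20, sums to 1),
#'   `hit_prob`, `kind`.
#' @export
parent_profile <- function(kind = c("pkis2_like", "reduced_selectivity",
                                    "least_selective", "binary"),
                           hit_prob = 0.02, smoothing = NULL) {
  kind <- match.arg(kind)
  if (!is_scalar_number(hit_prob) || hit_prob <= 0 || hit_prob >= 1) {
    stop("`hit_prob` must lie strictly between 0 and 1", call. = FALSE)
  }
  p <- numeric(N_BINS)
  if (kind == "binary") {
    p[1] <- 1 - hit_prob
    p[N_BINS] <- hit_prob
  } else {
    # base screening-like shape: heavy lowest bin, geometric mid-range decay
    # over bins 2..18, hit mass split across the two >=90% bins
    mid <- PKIS2_DECAY^(seq_len(17L) - 1L)
    low_mass <- PKIS2_LOW_MASS * (1 - hit_prob) / (1 - 0.02)
    mid_mass <- 1 - low_mass - hit_prob
    p[1] <- low_mass
    p[2:18] <- mid / sum(mid) * mid_mass
    p[19:20] <- hit_prob * c(0.5, 0.5)
    s <- switch(kind, pkis2_like = 0, reduced_selectivity = 0.35,
                least_selective = 0.75)
    if (!is.null(smoothing)) {
      if (!is_scalar_number(smoothing) || smoothing < 0 || smoothing > 1) {
        stop("`smoothing` must lie in [0, 1]", call. = FALSE)
      }
      s <- smoothing
    }
    if (s > 0) {
      nonhit <- 1:18
      u <- rep((1 - hit_prob) / length(nonhit), length(nonhit))
      p[nonhit] <- (1 - s) * p[nonhit] + s * u
    }
  }
  structure(list(bin_probs = setNames(p, bin_labels()), hit_prob = hit_prob,
                 kind = kind),
            class = "parent_profile")
}

#' @export
print.parent_profile <- function(x, ...) {
  cat(sprintf("<parent_profile> %s, hit_prob = %g\n", x$kind, x$hit_prob))
  invisible(x)
}

#' Bootstrap a simulated inhibitor panel from a parent profile
#'
#' Every compound-kinase activity is drawn i.i.d. from the parent profile: a
#' bin is sampled from `bin_probs`, then the activity uniformly within the
#' bin. The result is an activity-kind [potency_matrix()] with kinases named
#' `K001..`, compounds `cpd001..`.
#'
#' @param profile A [parent_profile()].
#' @param n_inhibitors Number of compounds (>= 1).
#' @param n_kinases Number of kinases (default 100, >= 2).
#' @param seed RNG seed.
#' @return An activity-kind [potency_matrix()].
#' @export
sample_inhibitor_set <- function(profile, n_inhibitors, n_kinases = 100,
                                 seed = NULL) {
  stopifnot(inherits(profile, "parent_profile"),
            n_inhibitors >= 1, n_kinases >= 2)
  n <- n_inhibitors * n_kinases
  act <- with_seed_or_not(seed, {
    bin <- sample.int(N_BINS, n, replace = TRUE, prob = profile$bin_probs)
    (bin - 1L) * BIN_WIDTH + runif(n) * BIN_WIDTH
  })
  values <- matrix(pmin(act, 100), n_inhibitors, n_kinases,
                   dimnames = list(sprintf("cpd%03d", seq_len(n_inhibitors)),
                                   sprintf("K%03d", seq_len(n_kinases))))
  potency_matrix(values, "activity")
}

#' Scan nomination outcomes against simulated inhibitor set size
#'
#' For each requested set size, bootstraps an inhibitor panel, runs the full
#' nomination pipeline with every kinase in turn as the single target, and
#' summarizes: the best-single score distribution, the score-improvement
#' distribution, and the percentage of targets for which a combination
#' significantly beats the best single inhibitor. Larger panels yield more
#' selective best singles and more targets improvable by combinations.
#'
#' @param profile A [parent_profile()].
#' @param set_sizes Ascending integer vector of panel sizes.
#' @param n_kinases Kinases per panel; default 100.
#' @param penalty Penalty template (resampled per replicate); default tight.
#' @param config An [optimizer_config()]; simulated panels are activity-kind
#'   so mixtures stay equimolar and no concentration optimization runs.
#' @param seed Master seed.
#' @return Data frame, one row per set size: `set_size`, `n_targets_feasible`,
#'   `mean_best_single_jsd`, `mean_delta_jsd`, `pct_improvable`.
#' @export
set_size_scan <- function(profile, set_sizes, n_kinases = 100,
                          penalty = penalty_preset("tight"),
                          config = optimizer_config(), seed = NULL) {
  stopifnot(!is.unsorted(set_sizes))
  rows <- lapply(set_sizes, function(sz) {
    m <- sample_inhibitor_set(profile, sz, n_kinases,
                              seed = derive_seed(seed, "panel", sz))
    best_single <- c(); deltas <- c(); improved <- 0L; feasible <- 0L
    for (kin in kinases(m)) {
      res <- run_mms(m, target_spec(kin, on_target_threshold = config$threshold),
                     penalty, config,
                     seed = derive_seed(seed, "target", sz, kin))
      if (identical(res$verdict, "infeasible")) next
      feasible <- feasible + 1L
      best_single <- c(best_single, mean(res$best_single$scores))
      if (!is.null(res$delta)) deltas <- c(deltas, res$delta$delta)
      if (identical(res$verdict, "combination_better")) improved <- improved + 1L
    }
    data.frame(set_size = sz, n_targets_feasible = feasible,
               mean_best_single_jsd = if (feasible) mean(best_single) else NA_real_,
               mean_delta_jsd = if (length(deltas)) mean(deltas) else NA_real_,
               pct_improvable = if (n_kinases) 100 * improved / n_kinases else 0)
  })
  do.call(rbind, rows)
}

#' Fold-error between a predicted and an observed potency
#'
#' `max(a, b) / min(a, b)`: always >= 1, with 1 a perfect prediction.
#' @param predicted,observed Positive potencies (same units).
#' @return Fold-error >= 1.
#' @export
fold_error <- function(predicted, observed) {
  if (any(predicted <= 0) || any(observed <= 0)) {
    stop("potencies must be positive", call. = FALSE)
  }
  pmax(predicted, observed) / pmin(predicted, observed)
}

#' Monte-Carlo propagation of single-compound potency errors into mixtures
#'
#' For each combination size, simulates `n_cases` equimolar mixtures whose
#' component affinities are drawn log-uniformly from 1-1000 nM (the
#' potency-eligible range). Each component affinity is independently
#' perturbed by a factor drawn uniformly from `[1, max_fold]`, applied as a
#' multiplication or division with equal probability. The fold-error between
#' the combination affinity predicted from the unperturbed components and
#' the one computed from the perturbed components is recorded; errors in
#' individual components partially average out in larger combinations.
#'
#' @param combo_sizes Integer vector of combination sizes; default 1:4.
#' @param n_cases Simulated cases per size; default 1000.
#' @param max_fold Maximum single-compound fold-error; default 4.
#' @param seed RNG seed.
#' @return Data frame with columns `size`, `case`, `fold_error`.
#' @export
fold_error_simulation <- function(combo_sizes = 1:4, n_cases = 1000,
                                  max_fold = 4, seed = NULL) {
  if (!is_scalar_number(max_fold) || max_fold <= 1) {
    stop("`max_fold` must exceed 1", call. = FALSE)
  }
  with_seed_or_not(seed, {
    rows <- lapply(combo_sizes, function(n) {
      fe <- vapply(seq_len(n_cases), function(case) {
        K <- 10^runif(n, 0, 3)                     # log-uniform 1-1000 nM
        f <- runif(n, 1, max_fold)
        dirn <- sample(c(-1, 1), n, replace = TRUE)
        Kp <- K * f^dirn
        pred <- n / sum(1 / K)                     # equimolar combination K
        obs <- n / sum(1 / Kp)
        fold_error(pred, obs)
      }, numeric(1))
      data.frame(size = n, case = seq_len(n_cases), fold_error = fe)
    })
    do.call(rbind, rows)
  })
}
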