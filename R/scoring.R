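# Selectivity scoring: Gaussian-smoothed off-target distributions, the
# Jensen-Shannon distance against a penalty distribution, the replicate
# delta-JSD comparison, and the classical selectivity metrics used for
# benchmarking (Gini coefficient, S-score, relative selectivity factor).

#' Build the Gaussian-smoothed off-target distribution of a mixture
#'
#' Each off-target activity value seeds a Gaussian centred on it (default
#' variance 2.5 on the percent-activity scale, complementing the 5% bin
#' width); every Gaussian is sampled `samples_per_kinase` times, samples are
#' clipped to `[0, 100]` (clipping, rather than discarding or reflecting,
#' keeps the per-kinase weight constant), pooled across kinases, binned at 5%
#' and normalized. The sampling noise is what makes technical replicates
#' informative.
#'
#' @param profile Numeric vector of per-off-target percent activities in
#'   `[0, 100]`. May be empty (no off-targets in the universe); the result is
#'   then a distinguished empty distribution which [jsd_score()] maps to 1.
#' @param noise_variance Variance of the Gaussian noise (activity-percent
#'   squared); default 2.5.
#' @param samples_per_kinase Draws per off-target kinase; default 100.
#' @param seed Optional RNG seed.
#' @return An `offtarget_distribution`: 20-bin probability vector plus the
#'   raw activities and sampling settings.
#' @export
offtarget_distribution <- function(profile, noise_variance = 2.5,
                                   samples_per_kinase = 100, seed = NULL) {
  if (!is_scalar_number(noise_variance) || noise_variance <= 0) {
    stop("`noise_variance` must be positive", call. = FALSE)
  }
  if (length(profile) > 0L &&
      (anyNA(profile) || any(profile < 0 | profile > 100))) {
    stop("off-target activities must lie in [0, 100]", call. = FALSE)
  }
  if (length(profile) == 0L) {
    return(structure(list(bins = NULL, raw_activities = numeric(0),
                          noise_variance = noise_variance,
                          samples_per_kinase = samples_per_kinase,
                          seed = seed, empty = TRUE),
                     class = "offtarget_distribution"))
  }
  samples <- with_seed_or_not(seed, {
    mu <- rep(profile, each = samples_per_kinase)
    pmin(pmax(mu + rnorm(length(mu), 0, sqrt(noise_variance)), 0), 100)
  })
  structure(list(bins = bin_distribution(samples), raw_activities = profile,
                 noise_variance = noise_variance,
                 samples_per_kinase = samples_per_kinase, seed = seed,
                 empty = FALSE),
            class = "offtarget_distribution")
}

#' @export
print.offtarget_distribution <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("<offtarget_distribution> empty universe\n")
  } else {
    cat(sprintf(
      "<offtarget_distribution> %d off-targets x %d samples, variance %g\n",
      length(x$raw_activities), x$samples_per_kinase, x$noise_variance))
  }
  invisible(x)
}

# Jensen-Shannon divergence with base-2 logarithms between two probability
# vectors on the same support; 0*log(0) := 0.
js_divergence2 <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Jensen-Shannon distance between off-target and penalty distributions
#'
#' The selectivity score: the square root of the base-2 Jensen-Shannon
#' divergence between the binned off-target distribution and the penalty
#' distribution. It ranges from 0 (distributions identical — all off-target
#' activity sits exactly where the penalty is heaviest) to 1 (disjoint
#' supports — no off-target activity in any penalized range), so higher is
#' more selective. An empty off-target universe scores 1 by convention.
#'
#' A score of exactly 1 under a tight penalty may simply mean no off-target
#' activity falls in the narrow penalized range; a warning suggests checking
#' with a broader penalty.
#'
#' @param offdist An [offtarget_distribution()], or a bare 20-bin
#'   probability vector.
#' @param penalty A `penalty_distribution` (see [poisson_penalty()]), or a
#'   bare 20-bin probability vector.
#' @return JSD score in `[0, 1]`.
#' @export
jsd_score <- function(offdist, penalty) {
  q <- if (inherits(penalty, "penalty_distribution")) penalty$bins else penalty
  if (inherits(offdist, "offtarget_distribution")) {
    if (isTRUE(offdist$empty)) return(1)
    p <- offdist$bins
  } else {
    p <- offdist
  }
  if (length(p) != length(q)) {
    stop("distributions must share the same bin support", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("distributions must each sum to 1", call. = FALSE)
  }
  d <- sqrt(max(js_divergence2(p, q), 0))
  d <- min(d, 1)
  if (d == 1 && inherits(penalty, "penalty_distribution") &&
      identical(penalty$shape, "poisson") && penalty$params$mu <= 300) {
    warning("JSD score of 1 under a tight penalty; a broader penalty ",
            "distribution may resolve more off-target structure",
            call. = FALSE)
  }
  d
}

#' Compare replicate JSD scores of a combination against the best single
#'
#' Two-sided two-sample Student's t-test (equal variance) on the replicate
#' score vectors, plus the absolute score-difference cutoff that screens out
#' statistically significant but functionally negligible improvements.
#' The verdict is significant only when `p < p_cutoff` **and** the mean
#' improvement is at least `abs_cutoff`.
#'
#' @param combo_scores,single_scores Numeric vectors (>= 2 replicates each)
#'   of JSD scores for the candidate combination and the best single
#'   inhibitor.
#' @param abs_cutoff Minimum mean improvement; default 0.001.
#' @param p_cutoff Significance level; default 0.05.
#' @return List: `delta` (mean difference), `combo_mean`, `combo_sd`,
#'   `single_mean`, `single_sd`, `p_value`, `significant`.
#' @export
delta_jsd <- function(combo_scores, single_scores, abs_cutoff = 0.001,
                      p_cutoff = 0.05) {
  if (length(combo_scores) < 2L || length(single_scores) < 2L) {
    stop("at least two replicate scores are required on each side",
         call. = FALSE)
  }
  delta <- mean(combo_scores) - mean(single_scores)
  p <- if (isTRUE(all.equal(combo_scores, single_scores)) &&
           stats::sd(c(combo_scores, single_scores)) == 0) {
    1  # degenerate: identical constant replicates
  } else {
    tryCatch(t.test(combo_scores, single_scores, var.equal = TRUE)$p.value,
             error = function(e) 1)
  }
  list(delta = delta,
       combo_mean = mean(combo_scores), combo_sd = stats::sd(combo_scores),
       single_mean = mean(single_scores), single_sd = stats::sd(single_scores),
       p_value = p,
       significant = is.finite(p) && p < p_cutoff && delta >= abs_cutoff)
}

#' Gini coefficient of a compound's activity vector
#'
#' Classical compound-level (not target-specific) selectivity measure: the
#' mean absolute difference between all activity pairs divided by twice the
#' mean activity. 0 for a uniform profile, approaching 1 for a compound
#' active on a single kinase.
#'
#' @param activities Non-negative per-kinase activities, not all zero.
#' @return Gini coefficient in `[0, 1]`.
#' @export
gini_coefficient <- function(activities) {
  if (length(activities) == 0L || anyNA(activities) || any(activities < 0)) {
    stop("activities must be non-negative", call. = FALSE)
  }
  if (all(activities == 0)) {
    stop("Gini coefficient undefined for an all-zero profile", call. = FALSE)
  }
  x <- sort(activities)
  n <- length(x)
  # identity: G = (2 * sum(i * x_i) / (n * sum(x))) - (n + 1) / n
  2 * sum(seq_len(n) * x) / (n * sum(x)) - (n + 1) / n
}

#' S-score: fraction of the kinase universe hit above a threshold
#'
#' @param activities Per-kinase percent activities.
#' @param threshold Activity threshold in (0, 100); default 50.
#' @return Fraction in `[0, 1]` of kinases with activity strictly above the
#'   threshold (lower = more selective).
#' @export
s_score <- function(activities, threshold = 50) {
  if (length(activities) == 0L) {
    stop("empty kinase universe", call. = FALSE)
  }
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold >= 100) {
    stop("`threshold` must lie strictly between 0 and 100", call. = FALSE)
  }
  mean(activities > threshold)
}

#' Relative selectivity factor
#'
#' On-target activity divided by the compound's total activity across all
#' kinases (target included); 1 means the compound only touches its target.
#' Shares its structure with concentration- and assay-specific relative
#' selectivity scores such as CATDS.
#'
#' @param on_target_activity Activity at the target (percent).
#' @param all_activities Activities at all kinases including the target.
#' @return Fraction in `[0, 1]`.
#' @export
relative_selectivity_factor <- function(on_target_activity, all_activities) {
  total <- sum(all_activities)
  if (!is_scalar_number(total) || total <= 0) {
    stop("total activity must be positive", call. = FALSE)
  }
  on_target_activity / total
}

#' Reproducibility of replicate rank-1 nominations
#'
#' Percentage of technical replicates whose rank-1 compound set (identity
#' only; concentrations are ignored) matches the modal rank-1 set. Ties for
#' the modal set are broken lexicographically on the sorted compound IDs so
#' reporting is deterministic. Imperfect reproducibility signals that several
#' near-equally selective sets exist; it is not a measure of validity.
#'
#' @param rank1_sets List (one element per replicate) of character vectors of
#'   compound IDs, each the replicate's top-ranked set.
#' @return Percentage in `(0, 100]`.
#' @export
reproducibility <- function(rank1_sets) {
  if (length(rank1_sets) < 2L) {
    stop("at least two replicates are required", call. = FALSE)
  }
  keys <- vapply(rank1_sets, function(s) paste(sort(s), collapse = "|"),
                 character(1))
  tab <- table(keys)
  modal <- names(tab)[tab == max(tab)]
  modal <- sort(modal)[1]  # lexicographic tie-break
  100 * mean(keys == modal)
}
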