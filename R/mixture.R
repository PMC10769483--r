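# Mixture arithmetic under the competitive-occupancy model: cumulative
# activity of several inhibitors at one kinase, the equivalent combination
# affinity, and dilution of a mixture onto the on-target threshold.

#' Construct an inhibitor mixture
#'
#' A mixture is an ordered set of (compound, concentration in nM) pairs.
#' Concentrations are non-negative; a scored mixture needs at least one
#' positive concentration.
#'
#' @param compounds Character vector of unique compound identifiers.
#' @param concentrations Numeric vector of concentrations in nM, one per
#'   compound, all `>= 0`.
#' @return An object of class `mixture`.
#' @examples
#' mixture(c("dasatinib", "foretinib"), c(50, 200))
#' @export
mixture <- function(compounds, concentrations) {
  compounds <- as.character(compounds)
  if (anyDuplicated(compounds)) {
    stop("mixture compounds must be unique", call. = FALSE)
  }
  if (length(concentrations) != length(compounds)) {
    stop("one concentration per compound required", call. = FALSE)
  }
  if (anyNA(concentrations) || any(concentrations < 0)) {
    stop("concentrations must be non-negative (nM)", call. = FALSE)
  }
  structure(list(compounds = compounds,
                 concentrations = setNames(as.numeric(concentrations),
                                           compounds)),
            class = "mixture")
}

#' @export
print.mixture <- function(x, ...) {
  cat("<mixture>\n")
  ratios <- molar_ratios(x)
  for (i in seq_along(x$compounds)) {
    cat(sprintf("  %-20s %10.4g nM  (ratio %.3g)\n", x$compounds[i],
                x$concentrations[i], ratios[i]))
  }
  invisible(x)
}

#' Molar ratios normalized to the smallest positive component
#' @param mix A [mixture()].
#' @return Numeric vector of ratios (smallest positive component = 1).
#' @export
molar_ratios <- function(mix) {
  pos <- mix$concentrations[mix$concentrations > 0]
  if (length(pos) == 0L) return(mix$concentrations)
  mix$concentrations / min(pos)
}

scale_mixture <- function(mix, factor) {
  mixture(mix$compounds, mix$concentrations * factor)
}

# Align an affinity vector with a mixture's compounds: named vectors are
# matched by name, unnamed vectors are taken positionally. Missing/NA
# affinities mean "no detectable binding" and become Inf.
match_affinities <- function(mix, affinities) {
  if (is.null(names(affinities))) {
    if (length(affinities) != length(mix$compounds)) {
      stop("affinities must cover every mixture compound", call. = FALSE)
    }
    k <- as.numeric(affinities)
  } else {
    if (!all(mix$compounds %in% names(affinities))) {
      stop("affinities must cover every mixture compound", call. = FALSE)
    }
    k <- as.numeric(affinities[mix$compounds])
  }
  k[is.na(k)] <- Inf
  if (any(k <= 0)) stop("affinities must be positive", call. = FALSE)
  k
}

#' Cumulative occupancy of one kinase by an inhibitor mixture
#'
#' Competitive inhibitors acting on the same site add up on the
#' concentration-over-affinity scale: with `S = sum_j I_j / K_j`, the total
#' occupancy is `100 * S / (1 + S)` percent. The model approximates away ATP
#' competition and enzyme depletion (pure fractional-occupancy competition).
#'
#' @param mix A [mixture()].
#' @param affinities Named numeric vector of affinities `K_j` (nM) for one
#'   kinase, one per mixture compound; `Inf` or `NA` means no detectable
#'   binding and contributes zero occupancy.
#' @return Percent occupancy in `[0, 100)`.
#' @examples
#' cumulative_activity(mixture("a", 1000), c(a = 1000))  # 50
#' @export
cumulative_activity <- function(mix, affinities) {
  stopifnot(inherits(mix, "mixture"))
  k <- match_affinities(mix, affinities)
  s <- sum(mix$concentrations / k)
  100 * s / (1 + s)
}

#' Equivalent combination affinity of a fixed-ratio mixture
#'
#' The affinity a mixture behaves as if it had at its total concentration:
#' `K_eq = (1/f - 1) * sum_j I_j` with `f` the fractional cumulative
#' occupancy. For a single compound this returns its own `K` exactly, and the
#' value is invariant under rescaling all concentrations by a common factor
#' (closed form `1 / sum_j (r_j / K_j)` for molar fractions `r_j`). An
#' equimolar mixture's `K_eq` equals the total mixture concentration at 50%
#' cumulative occupancy, i.e. its predicted combination EC50.
#'
#' @inheritParams cumulative_activity
#' @return Equivalent affinity in nM.
#' @examples
#' # equimolar three-compound mixture with single-compound EC50s
#' # 82 nM, 4.6 uM, 1.8 uM -> combination EC50 ~231 nM
#' m <- mixture(c("a", "b", "c"), c(1, 1, 1))
#' equivalent_affinity(m, c(a = 82, b = 4600, c = 1800))
#' @export
equivalent_affinity <- function(mix, affinities) {
  stopifnot(inherits(mix, "mixture"))
  k <- match_affinities(mix, affinities)
  s <- sum(mix$concentrations / k)
  if (s <= 0) {
    stop("mixture has zero cumulative occupancy; equivalent affinity undefined",
         call. = FALSE)
  }
  sum(mix$concentrations) / s
}

#' Per-kinase activity profile of a mixture
#'
#' Cumulative occupancy of every target and off-target kinase at the
#' mixture's current concentrations. Mutant kinases are excluded from the
#' off-target side automatically.
#'
#' @param mix A [mixture()]; compounds must exist in `m`.
#' @param m A [potency_matrix()].
#' @param spec A [target_spec()].
#' @return List with numeric vectors `targets` and `offtargets` of percent
#'   activities, named by kinase.
#' @export
mixture_profile <- function(mix, m, spec) {
  stopifnot(inherits(mix, "mixture"))
  r <- resolve_spec(m, spec)
  unknown <- setdiff(mix$compounds, compounds(m))
  if (length(unknown) > 0L) {
    stop("unknown compound(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  K <- pseudo_affinities(m)[mix$compounds, , drop = FALSE]
  s <- colSums(mix$concentrations / K)
  act <- 100 * s / (1 + s)
  list(targets = act[r$targets],
       offtargets = act[r$offtargets])
}

# Minimum on-target activity of a mixture (the binding constraint).
min_target_activity <- function(conc, Kt) {
  s <- colSums(conc / Kt)
  min(100 * s / (1 + s))
}

#' Dilute (or scale up) a mixture onto the on-target activity threshold
#'
#' All concentrations are divided by the step factor `R2` while the
#' cumulative activity at every target stays at or above the threshold; the
#' last compliant mixture is returned, so the achieved on-target activity
#' lies within one `R2` step of the threshold. A mixture starting below the
#' threshold is scaled up by `R2` steps until compliant; if the threshold
#' cannot be reached with every component at or below `max_conc`, the result
#' is flagged infeasible rather than failing silently.
#'
#' @param mix A [mixture()].
#' @param m A [potency_matrix()].
#' @param spec A [target_spec()] carrying the on-target threshold.
#' @param R2 Dilution step factor, `> 1`; default 1.1. Smaller steps land the
#'   mixture closer to the threshold, which keeps selectivity scores
#'   comparable between mixtures.
#' @param max_conc Per-component concentration ceiling in nM, or `NULL` for
#'   none.
#' @param min_conc Concentration floor (nM) below which components are
#'   reported as negligible; default 1e-6.
#' @return A `mixture` with attributes `feasible` (logical) and
#'   `on_target_activity` (minimum across targets).
#' @export
dilute_to_threshold <- function(mix, m, spec, R2 = 1.1, max_conc = NULL,
                                min_conc = 1e-6) {
  if (!is_scalar_number(R2) || R2 <= 1) {
    stop("`R2` must be > 1", call. = FALSE)
  }
  r <- resolve_spec(m, spec)
  K <- pseudo_affinities(m)[mix$compounds, r$targets, drop = FALSE]
  thr <- spec$on_target_threshold
  conc <- mix$concentrations
  if (all(conc == 0)) {
    out <- mix
    attr(out, "feasible") <- FALSE
    attr(out, "on_target_activity") <- 0
    return(out)
  }
  act <- min_target_activity(conc, K)
  if (act < thr) {
    # scale up until compliant or the ceiling is hit
    repeat {
      if (!is.null(max_conc) && any(conc * R2 > max_conc)) {
        out <- mixture(mix$compounds, conc)
        attr(out, "feasible") <- FALSE
        attr(out, "on_target_activity") <- act
        return(out)
      }
      conc <- conc * R2
      act <- min_target_activity(conc, K)
      if (act >= thr) break
      if (is.null(max_conc) && any(conc > 1e12)) {
        # targets unreachable (no binding): bail out as infeasible
        out <- mixture(mix$compounds, mix$concentrations)
        attr(out, "feasible") <- FALSE
        attr(out, "on_target_activity") <- act
        return(out)
      }
    }
  } else {
    while (min_target_activity(conc / R2, K) >= thr) {
      conc <- conc / R2
    }
  }
  out <- mixture(mix$compounds, conc)
  attr(out, "feasible") <- TRUE
  attr(out, "on_target_activity") <- min_target_activity(conc, K)
  attr(out, "negligible") <- mix$compounds[conc < min_conc]
  out
}

#' Write a mixture to CSV
#'
#' Two columns, `compound` and `concentration_nM`, plus a `molar_ratio`
#' column normalized to the smallest positive component.
#' @param mix A [mixture()].
#' @param path Output path.
#' @export
write_mixture <- function(mix, path) {
  df <- data.frame(compound = mix$compounds,
                   concentration_nM = unname(mix$concentrations),
                   molar_ratio = unname(molar_ratios(mix)))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
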