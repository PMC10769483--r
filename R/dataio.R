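# Potency matrices: construction, validation, IO and the activity <-> affinity
# conversion that puts every dataset on the method's common occupancy scale.

#' Construct a compound-by-kinase potency matrix
#'
#' The central data container: a numeric matrix with compounds as rows and
#' kinases as columns, holding either binding affinities
#' (\eqn{K_d}/\eqn{K_i}/\eqn{K_d^{app}} in nM, treated equivalently) or
#' percent-activity values from a single-concentration screen. Missing cells
#' are tracked explicitly and treated downstream as "no detectable binding"
#' (zero activity / infinite affinity); the kinase still belongs to the
#' off-target universe. Engineered or clinical kinase mutants can be flagged:
#' they may be targeted, but are excluded from every off-target distribution.
#'
#' @param values Numeric matrix (rows = compounds, columns = kinases) with
#'   dimnames. `NA` cells are recorded in the missing mask.
#' @param value_kind `"affinity"` (nM, positive) or `"activity"` (percent,
#'   0-100).
#' @param reference_conc Concentration (nM) at which activity values are
#'   defined and affinities are projected onto the activity scale;
#'   default 1000 nM (1 uM).
#' @param mutant_flags Logical vector, one per kinase, marking mutant kinases.
#'   Defaults to kinase names matching `mutant_pattern`.
#' @param mutant_pattern Regular expression used to auto-flag mutants when
#'   `mutant_flags` is `NULL`; the default flags names carrying a
#'   parenthesised mutation such as `"FLT3(D835Y)"`.
#' @return An object of class `potency_matrix`.
#' @seealso [load_matrix()], [subset_universe()]
#' @export
potency_matrix <- function(values, value_kind = c("affinity", "activity"),
                           reference_conc = 1000, mutant_flags = NULL,
                           mutant_pattern = "\\(") {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  compounds <- rownames(values)
  kinases <- colnames(values)
  if (is.null(compounds) || is.null(kinases)) {
    stop("`values` must have compound rownames and kinase colnames",
         call. = FALSE)
  }
  if (anyDuplicated(compounds)) {
    stop("duplicate compound identifiers: ",
         paste(unique(compounds[duplicated(compounds)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(kinases)) {
    stop("duplicate kinase identifiers: ",
         paste(unique(kinases[duplicated(kinases)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is_scalar_number(reference_conc) || reference_conc <= 0) {
    stop("`reference_conc` must be a positive number (nM)", call. = FALSE)
  }
  missing <- is.na(values)
  bad <- which(!missing &
                 (if (value_kind == "affinity") values <= 0
                  else values < 0 | values > 100),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "invalid %s value %g at [%s, %s]", value_kind,
      values[bad[1, 1], bad[1, 2]], compounds[bad[1, 1]], kinases[bad[1, 2]]),
      call. = FALSE)
  }
  if (is.null(mutant_flags)) {
    mutant_flags <- grepl(mutant_pattern, kinases)
  }
  if (length(mutant_flags) != length(kinases) || !is.logical(mutant_flags)) {
    stop("`mutant_flags` must be a logical vector, one per kinase",
         call. = FALSE)
  }
  structure(
    list(values = values, value_kind = value_kind,
         reference_conc = reference_conc, missing = missing,
         mutant_flags = setNames(as.logical(mutant_flags), kinases)),
    class = "potency_matrix")
}

#' @export
print.potency_matrix <- function(x, ...) {
  cat(sprintf(
    "<potency_matrix> %d compounds x %d kinases (%s%s)\n",
    nrow(x$values), ncol(x$values), x$value_kind,
    if (x$value_kind == "activity")
      sprintf(" at %g nM", x$reference_conc) else ", nM"))
  cat(sprintf("  missing cells: %d (%.1f%%); mutant kinases: %d\n",
              sum(x$missing), 100 * mean(x$missing), sum(x$mutant_flags)))
  invisible(x)
}

#' Compound and kinase identifiers of a potency matrix
#' @param m A [potency_matrix()].
#' @return Character vector of identifiers.
#' @export
compounds <- function(m) rownames(m$values)

#' @rdname compounds
#' @export
kinases <- function(m) colnames(m$values)

#' Define the target set and off-target universe for an analysis
#'
#' @param targets Character vector of kinase identifiers to inhibit
#'   (non-empty).
#' @param offtarget_universe Optional character vector restricting which
#'   kinases count as off-targets (e.g. only the Eph family). Defaults to
#'   every non-mutant, non-target kinase in the matrix.
#' @param on_target_threshold Minimum percent activity that must be
#'   maintained at every target; default 90.
#' @return An object of class `target_spec`.
#' @export
target_spec <- function(targets, offtarget_universe = NULL,
                        on_target_threshold = 90) {
  targets <- as.character(targets)
  if (length(targets) == 0L || anyNA(targets)) {
    stop("`targets` must be a non-empty set of kinase identifiers",
         call. = FALSE)
  }
  if (anyDuplicated(targets)) targets <- unique(targets)
  if (!is_scalar_number(on_target_threshold) ||
      on_target_threshold <= 0 || on_target_threshold >= 100) {
    stop("`on_target_threshold` must lie strictly between 0 and 100",
         call. = FALSE)
  }
  if (!is.null(offtarget_universe)) {
    offtarget_universe <- unique(as.character(offtarget_universe))
    if (length(intersect(targets, offtarget_universe)) > 0L) {
      stop("targets and off-target universe must be disjoint", call. = FALSE)
    }
  }
  structure(list(targets = targets, offtarget_universe = offtarget_universe,
                 on_target_threshold = on_target_threshold),
            class = "target_spec")
}

# Resolve a target_spec against a matrix: returns list(targets, offtargets)
# with mutants removed from the off-target side.
resolve_spec <- function(m, spec) {
  stopifnot(inherits(m, "potency_matrix"), inherits(spec, "target_spec"))
  all_k <- kinases(m)
  unknown <- setdiff(spec$targets, all_k)
  if (length(unknown) > 0L) {
    stop("unknown target kinase(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(spec$offtarget_universe)) {
    off <- setdiff(all_k[!m$mutant_flags], spec$targets)
  } else {
    unknown <- setdiff(spec$offtarget_universe, all_k)
    if (length(unknown) > 0L) {
      stop("unknown off-target kinase(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    off <- setdiff(spec$offtarget_universe[
      !m$mutant_flags[spec$offtarget_universe]], spec$targets)
  }
  list(targets = spec$targets, offtargets = off)
}

#' Convert a binding affinity to percent occupancy at a reference concentration
#'
#' Single-site competitive occupancy: a compound with affinity `k` (nM) dosed
#' at concentration `ref` (nM) occupies `100 * (ref/k) / (1 + ref/k)` percent
#' of its target, i.e. `100 / (k/ref + 1)`. At the default 1 uM reference
#' frame a 100 nM compound sits at ~91% and a 1 uM compound at exactly 50%.
#'
#' @param k Affinity in nM (positive; `Inf` allowed, yielding 0 activity).
#' @param ref Reference concentration in nM; default 1000.
#' @return Percent activity in `[0, 100)`.
#' @examples
#' affinity_to_activity(100)   # ~90.9
#' affinity_to_activity(1000)  # 50
#' @export
affinity_to_activity <- function(k, ref = 1000) {
  if (any(!is.na(k) & k <= 0)) stop("affinity must be positive", call. = FALSE)
  if (length(ref) == 0L || anyNA(ref) || any(ref <= 0)) {
    stop("`ref` must be a positive concentration (nM)", call. = FALSE)
  }
  100 / (k / ref + 1)
}

#' Convert percent activity back to an affinity
#'
#' Exact inverse of [affinity_to_activity()]: `k = ref * (100/a - 1)`.
#' Activities of exactly 0 or 100 correspond to infinite or zero affinity and
#' are rejected; clamp screening saturation values (see [pseudo_affinities()])
#' before inverting.
#'
#' @param a Percent activity, strictly between 0 and 100.
#' @inheritParams affinity_to_activity
#' @return Affinity in nM.
#' @examples
#' activity_to_affinity(90)  # 111.1 nM
#' @export
activity_to_affinity <- function(a, ref = 1000) {
  if (any(!is.na(a) & (a <= 0 | a >= 100))) {
    stop("activity must lie strictly between 0 and 100", call. = FALSE)
  }
  if (length(ref) == 0L || anyNA(ref) || any(ref <= 0)) {
    stop("`ref` must be a positive concentration (nM)", call. = FALSE)
  }
  ref * (100 / a - 1)
}

# Activity value at which screening saturation (exactly 100%) is clamped
# before inversion to a pseudo-affinity.
ACTIVITY_CLAMP <- 99.995

#' Per-cell affinities (nM) for mixture arithmetic
#'
#' Returns the matrix of affinities used in all occupancy calculations.
#' Affinity matrices pass through unchanged; activity matrices are inverted
#' to pseudo-affinities at the matrix's reference concentration, with
#' activities of 100 clamped to 99.995 first. Missing cells and zero
#' activities become `Inf` (no detectable binding: they contribute zero
#' occupancy but keep their kinase in the off-target universe).
#'
#' @param m A [potency_matrix()].
#' @return Numeric matrix of affinities in nM, `Inf` where unmeasured.
#' @export
pseudo_affinities <- function(m) {
  stopifnot(inherits(m, "potency_matrix"))
  v <- m$values
  if (m$value_kind == "affinity") {
    v[m$missing] <- Inf
    return(v)
  }
  v[m$missing] <- 0
  v[v >= 100] <- ACTIVITY_CLAMP
  k <- matrix(Inf, nrow(v), ncol(v), dimnames = dimnames(v))
  pos <- v > 0
  k[pos] <- m$reference_conc * (100 / v[pos] - 1)
  k
}

# Per-cell activities (%) at the reference frame, 0 where unmeasured.
activities_at_ref <- function(m) {
  if (m$value_kind == "activity") {
    v <- m$values
    v[m$missing] <- 0
    return(v)
  }
  k <- m$values
  k[m$missing] <- Inf
  affinity_to_activity(k, m$reference_conc)
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

MISSING_SENTINELS <- c("", "NA", "NaN", "na", "nan", "N/A")

#' Load a potency matrix from CSV/TSV
#'
#' Reads either a wide table (first column compound IDs, remaining columns
#' one per kinase) or a long table with columns `compound, kinase, value`.
#' The separator (comma or tab) is auto-detected. Blank cells and the
#' sentinels `NA`, `NaN`, `N/A` are recorded as missing.
#'
#' @param path Path to the CSV/TSV file.
#' @inheritParams potency_matrix
#' @param format `"wide"` (default) or `"long"`.
#' @param mutants Optional character vector of kinase names to flag as
#'   mutants, overriding `mutant_pattern`.
#' @return A [potency_matrix()].
#' @export
load_matrix <- function(path, value_kind = c("affinity", "activity"),
                        format = c("wide", "long"), reference_conc = 1000,
                        mutants = NULL, mutant_pattern = "\\(") {
  value_kind <- match.arg(value_kind)
  format <- match.arg(format)
  sep <- detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = MISSING_SENTINELS,
                   quote = "\"", comment.char = "")
  if (format == "long") {
    if (ncol(df) < 3L) {
      stop("long format needs columns compound, kinase, value", call. = FALSE)
    }
    cmp <- as.character(df[[1]]); kin <- as.character(df[[2]])
    val <- suppressWarnings(as.numeric(df[[3]]))
    if (anyDuplicated(paste(cmp, kin, sep = "\r"))) {
      stop("duplicate (compound, kinase) pairs in long table", call. = FALSE)
    }
    ucmp <- unique(cmp); ukin <- unique(kin)
    values <- matrix(NA_real_, length(ucmp), length(ukin),
                     dimnames = list(ucmp, ukin))
    values[cbind(match(cmp, ucmp), match(kin, ukin))] <- val
  } else {
    cmp <- as.character(df[[1]])
    values <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(values) <- "double"
    rownames(values) <- cmp
  }
  flags <- if (!is.null(mutants)) colnames(values) %in% mutants else NULL
  potency_matrix(values, value_kind, reference_conc = reference_conc,
                 mutant_flags = flags, mutant_pattern = mutant_pattern)
}

#' Write a potency matrix to CSV/TSV
#'
#' Canonical wide dialect: first column `compound`, one column per kinase,
#' empty cells for missing values. Reloading the file with [load_matrix()]
#' reproduces the matrix exactly.
#'
#' @param m A [potency_matrix()].
#' @param path Output path.
#' @param sep Field separator, `","` or `"\t"`.
#' @export
write_matrix <- function(m, path, sep = ",") {
  stopifnot(inherits(m, "potency_matrix"))
  v <- m$values
  v[m$missing] <- NA
  df <- data.frame(compound = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}

#' Restrict a matrix to a target set and its off-target universe
#'
#' Keeps only the kinase columns relevant to an analysis: the targets plus
#' the (possibly user-restricted) off-target universe, with mutant-flagged
#' kinases dropped from the off-target side automatically. Used e.g. to
#' confine scoring to one kinase family so only intrafamily off-target
#' effects are considered.
#'
#' @param m A [potency_matrix()].
#' @param spec A [target_spec()].
#' @return A [potency_matrix()] restricted to `targets` plus off-targets.
#' @export
subset_universe <- function(m, spec) {
  r <- resolve_spec(m, spec)
  keep <- c(r$targets, r$offtargets)
  potency_matrix(m$values[, keep, drop = FALSE], m$value_kind,
                 reference_conc = m$reference_conc,
                 mutant_flags = m$mutant_flags[keep])
}
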