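# Matrotrophy-index scoring, placentotrophy classification, and
# binarization of continuous male traits.

#' Slope threshold corresponding to a matrotrophy index
#'
#' On the natural-log scale, an embryo developing over a staging scale of
#' `stage_span` units with overall mass ratio `mi` (birth mass / egg mass)
#' follows a regression of ln(dry mass) on stage with slope
#' `ln(mi) / stage_span`.  With the conventional 0-50 staging scale, an MI
#' of 0.7 corresponds to a slope of -0.0071.
#'
#' @param mi Matrotrophy index (> 0).
#' @param stage_span Developmental stage span (default 50).
#' @return The regression slope in ln(mg) per stage unit.
#' @examples
#' round(slope_threshold_for_mi(0.7), 4)  # -0.0071
#' @export
slope_threshold_for_mi <- function(mi, stage_span = 50) {
  if (any(mi <= 0)) stop("mi must be > 0")
  if (any(stage_span <= 0)) stop("stage_span must be > 0")
  log(mi) / stage_span
}

#' Matrotrophy index from birth and egg dry masses
#'
#' MI is the estimated dry mass of offspring at birth divided by the dry
#' mass of the egg at fertilization.  MI < 1 indicates net embryonic mass
#' loss (yolk-only provisioning); values far above 1 indicate extensive
#' post-fertilization (placental) provisioning.
#'
#' @param birth_mass,egg_mass Dry masses (mg), > 0.
#' @return MI ratio.
#' @export
estimate_mi <- function(birth_mass, egg_mass) {
  if (any(birth_mass <= 0) || any(egg_mass <= 0))
    stop("masses must be > 0")
  birth_mass / egg_mass
}

#' Regression of log embryo dry mass on developmental stage
#'
#' Ordinary least squares of `ln(dry_mass)` on `stage` for the broods of one
#' population, with one-sided t tests (n - 2 df) of the slope against 0 and
#' against the slope corresponding to `mi_threshold` (default 0.7, i.e.
#' -0.0071 on the 0-50 scale).  The implied MI estimate is
#' `exp(slope * stage_span)`.
#'
#' @param broods Data frame with columns `stage` (0-50 scale) and
#'   `dry_mass` (mg, > 0); optionally `species` and `population` labels.
#' @param mi_threshold MI value defining the lower reference slope.
#' @param stage_span Stage span of full development (default 50).
#' @return A one-row data frame of class `population_regression` with the
#'   slope, its SE, brood count, stage range, one-sided p values and the
#'   MI estimate.
#' @export
fit_stage_mass_regression <- function(broods, mi_threshold = 0.7,
                                      stage_span = 50) {
  stopifnot(all(c("stage", "dry_mass") %in% names(broods)))
  broods <- broods[stats::complete.cases(broods[, c("stage", "dry_mass")]), ]
  if (any(broods$dry_mass <= 0)) stop("dry_mass must be > 0")
  if (any(broods$stage < 0 | broods$stage > stage_span))
    stop("stage outside [0, ", stage_span, "]")
  n <- nrow(broods)
  if (n < 3) stop("need >= 3 broods for a regression")
  if (length(unique(broods$stage)) < 2)
    stop("all stages identical; slope undefined")
  fit <- stats::lm(log(dry_mass) ~ stage, data = broods)
  slope <- unname(coef(fit)[2])
  se <- sqrt(suppressWarnings(vcov(fit))[2, 2])  # exact fits warn in summary
  df <- n - 2
  thr <- slope_threshold_for_mi(mi_threshold, stage_span)
  one_sided <- function(delta) {
    if (!is.finite(se) || se < 1e-10) {
      # (numerically) exact fit: the test degenerates to the sign of delta
      if (abs(delta) < 1e-10) return(0.5)
      return(if (delta > 0) 0 else 1)
    }
    stats::pt(delta / se, df = df, lower.tail = FALSE)
  }
  out <- data.frame(
    species = if ("species" %in% names(broods)) broods$species[1] else NA,
    population = if ("population" %in% names(broods))
      broods$population[1] else NA,
    slope = slope, slope_se = se, n_broods = n,
    stage_min = min(broods$stage), stage_max = max(broods$stage),
    stage_range = max(broods$stage) - min(broods$stage),
    p_gt_zero = one_sided(slope - 0),
    p_gt_threshold = one_sided(slope - thr),
    mi_estimate = exp(slope * stage_span),
    stringsAsFactors = FALSE)
  class(out) <- c("population_regression", class(out))
  out
}

#' Fit stage-mass regressions for every population
#'
#' @param broods Data frame with columns `species`, `population`, `stage`,
#'   `dry_mass` (one row per brood).
#' @param ... Passed to [fit_stage_mass_regression()].
#' @return A data frame with one row per (species, population).
#' @export
fit_population_regressions <- function(broods, ...) {
  stopifnot(all(c("species", "population") %in% names(broods)))
  key <- interaction(broods$species, broods$population, drop = TRUE)
  rows <- lapply(split(broods, key), fit_stage_mass_regression, ...)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Conservative placentotrophy scoring
#'
#' A species is scored as placentotrophic (1) only if its pooled collection
#' is trustworthy -- more than `n_broods_min` broods and a pooled embryo
#' stage range wider than `stage_range_min` -- and either (rule 1) the
#' ln-mass-on-stage slope is significantly greater than 0 in at least one
#' population, or (rule 2) two or more populations have an estimated MI > 1
#' with slopes significantly greater than the MI = 0.7 reference slope.
#' Insufficient data yields 0, the conservative default guarding against
#' false positives.
#'
#' @param regs Data frame of population regressions for one species
#'   (from [fit_population_regressions()] or rbind-ed
#'   [fit_stage_mass_regression()] rows).
#' @param alpha One-sided significance level (default 0.05).
#' @param n_broods_min,stage_range_min Trustworthiness thresholds (strict
#'   inequalities, defaults 7 broods and 25 stage units).
#' @param pooled If `TRUE` (default) trustworthiness is judged on the pooled
#'   species-level collection; if `FALSE`, per population, and only
#'   individually trustworthy populations enter the rules.
#' @return A one-row data frame of class `scoring_decision` with
#'   `placentotrophy`, `trustworthy` and `rule_fired` in
#'   `{none, slope_gt_zero, two_pops_mi_gt_1}`.
#' @export
score_placentotrophy <- function(regs, alpha = 0.05, n_broods_min = 7,
                                 stage_range_min = 25, pooled = TRUE) {
  if (nrow(regs) < 1) stop("need at least one population regression")
  if (pooled) {
    trustworthy <- sum(regs$n_broods) > n_broods_min &&
      (max(regs$stage_max) - min(regs$stage_min)) > stage_range_min
    use <- regs
  } else {
    ok <- regs$n_broods > n_broods_min & regs$stage_range > stage_range_min
    trustworthy <- any(ok)
    use <- regs[ok, , drop = FALSE]
  }
  rule1 <- nrow(use) > 0 && any(use$p_gt_zero < alpha)
  rule2 <- nrow(use) > 0 &&
    sum(use$mi_estimate > 1 & use$p_gt_threshold < alpha) >= 2
  placento <- as.integer(trustworthy && (rule1 || rule2))
  rule <- if (!placento) "none" else if (rule1) "slope_gt_zero"
          else "two_pops_mi_gt_1"
  out <- data.frame(
    species = if ("species" %in% names(regs)) regs$species[1] else NA,
    placentotrophy = placento,
    trustworthy = trustworthy,
    rule_fired = rule,
    stringsAsFactors = FALSE)
  class(out) <- c("scoring_decision", class(out))
  out
}

#' Sexual selection index
#'
#' Count of dichotomous male traits present (courtship, sexual
#' dichromatism, ornamentation), ranging from 0 (all absent) to 3 (all
#' present); missing if any component is missing.
#'
#' @param courtship,dichromatism,ornamentation Vectors in \{0, 1, NA\}.
#' @return Integer vector in 0..3 with NA propagated.
#' @export
sexual_selection_index <- function(courtship, dichromatism, ornamentation) {
  comp <- cbind(courtship, dichromatism, ornamentation)
  if (any(!comp[!is.na(comp)] %in% c(0, 1)))
    stop("components must be 0, 1 or NA")
  out <- rowSums(comp)
  as.integer(out)
}

#' Median-split binarization of a continuous trait
#'
#' Species are ranked ascending; the lowest `ceiling(n/2)` (the "bottom
#' 50\%") are scored 0 and the rest 1.  Values tied with the boundary value
#' are all assigned 0; missing values stay missing.
#'
#' @param values Named numeric vector (names = species).
#' @return Named integer vector in \{0, 1, NA\}.
#' @export
median_split_binarize <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) < 2) stop("need >= 2 non-missing values")
  if (length(unique(obs)) == 1L) {
    warning("all values identical; every species scored 0")
    out <- ifelse(is.na(values), NA_integer_, 0L)
    names(out) <- names(values)
    return(out)
  }
  cut <- sort(obs)[ceiling(length(obs) / 2)]
  out <- ifelse(is.na(values), NA_integer_, ifelse(values <= cut, 0L, 1L))
  names(out) <- names(values)
  out
}
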