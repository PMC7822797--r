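#' Ground-truth configuration for the synthetic-data generator
#'
#' Collects every knob of the generative model in one validated list, so
#' that a dataset can be regenerated exactly and its planted effects
#' recovered in tests. Outcomes are binary at the woman level; treatment
#' effects are specified in percentage points on the outcome percentage
#' and planted as log-odds shifts calibrated so that the model-implied
#' (infinite-n) difference-in-differences equals the configured effect
#' after marginalizing over facility heterogeneity (see
#' [planted_logit_shift()]).
#'
#' @param effect_ppts named numeric, true treatment effect per outcome in
#'   percentage points (names from [outcome_names()]; unnamed scalar is
#'   recycled). Default 0 for all outcomes.
#' @param baseline_rates named numeric in (0,1), baseline outcome
#'   probability per outcome. Defaults are plausible survey levels for a
#'   lower-middle-income setting.
#' @param wave_effects named numeric, additive log-odds shift per survey
#'   wave shared by all facilities (secular trend). Default: a mild
#'   monotone improvement of 0.06 log-odds per wave step.
#' @param facility_sd standard deviation (log-odds) of facility random
#'   intercepts. Default 0.3.
#' @param targeting_strength logistic-link coefficient tying a district's
#'   social vulnerability index to its probability of being selected for
#'   rollout. 0 means random assignment. Default 1.
#' @param confounding_strength log-odds of the outcome per unit of the
#'   district vulnerability index, added to every facility intercept in
#'   the district. Nonzero values make treated and control facilities
#'   differ in outcome *levels* (but not trends), which is exactly the
#'   selection problem matching is meant to fix. Default -0.5 (more
#'   vulnerable districts have worse outcomes).
#' @param trend_ppts_per_wave extra linear pre-trend, in percentage points
#'   per wave step, given to eventually-treated facilities. Default 0
#'   (parallel trends hold); nonzero values are used to study the power of
#'   the parallel-trends diagnostic.
#' @param women_per_facility_per_wave number of women drawn per facility
#'   and wave. Default 30.
#' @param waves integer survey years. Default `c(1992, 1995, 2000, 2005,
#'   2008, 2014)`.
#' @param rollout_waves waves at which districts can first be accredited.
#'   Default `c(2000, 2005, 2008)` (staggered uptake).
#' @param n_districts number of districts. Default 40.
#' @param facilities_per_district mean facilities per district (Poisson,
#'   minimum 1). Default 4.
#' @param target_share marginal probability that a district is selected
#'   when `targeting_strength = 0`. Default 0.4.
#' @param other_intervention_frac fraction of treated facilities flagged
#'   as subject to additional reform interventions (performance-based
#'   financing or user fees) and therefore excluded downstream. Default
#'   0.1.
#' @param jitter_sd_km isotropic Gaussian jitter (km) of a woman's GPS
#'   location around her facility. Default 2.
#' @param eligibility named numeric, probability that a woman is in an
#'   outcome's denominator (e.g. currently uses contraception, had a
#'   recent birth, has a child under five). Defaults between 0.45 and
#'   0.65 by outcome group.
#' @param seed master integer seed; every stage derives its own
#'   substream via [substream_seed()].
#' @return an object of class `truth_config`.
#' @export
truth_config <- function(effect_ppts = 0,
                         baseline_rates = NULL,
                         wave_effects = NULL,
                         facility_sd = 0.3,
                         targeting_strength = 1,
                         confounding_strength = -0.5,
                         trend_ppts_per_wave = 0,
                         women_per_facility_per_wave = 30,
                         waves = c(1992L, 1995L, 2000L, 2005L, 2008L, 2014L),
                         rollout_waves = c(2000L, 2005L, 2008L),
                         n_districts = 40,
                         facilities_per_district = 4,
                         target_share = 0.4,
                         other_intervention_frac = 0.1,
                         jitter_sd_km = 2,
                         eligibility = NULL,
                         seed = 1L) {
  outs <- outcome_names()
  expand <- function(x, default, what, lo = -Inf, hi = Inf) {
    if (is.null(x)) x <- default
    if (length(x) == 1L && is.null(names(x))) x <- setNames(rep(x, 12L), outs)
    if (!all(outs %in% names(x))) {
      full <- default
      full[names(x)] <- x
      x <- full
    }
    x <- x[outs]
    if (any(!is.finite(x)) || any(x < lo) || any(x > hi)) {
      stop_invalid("%s must be finite and in [%s, %s]", what, lo, hi)
    }
    x
  }
  default_base <- setNames(
    c(0.35, 0.35, 0.45, 0.30, 0.70, 0.65, 0.55, 0.50, 0.60, 0.10, 0.25, 0.15),
    outs)
  default_elig <- setNames(
    c(0.45, 0.45, 0.55, 0.55, 0.55, 0.55, 0.55, 0.55, 0.55, 0.65, 0.65, 0.65),
    outs)
  waves <- sort(as.integer(waves))
  if (length(waves) < 2L) stop_invalid("need at least two survey waves")
  if (is.null(wave_effects)) {
    wave_effects <- setNames(0.06 * (seq_along(waves) - 1L), as.character(waves))
  }
  if (!all(as.character(waves) %in% names(wave_effects))) {
    stop_invalid("wave_effects must name every wave")
  }
  if (women_per_facility_per_wave < 1) {
    stop_invalid("women_per_facility_per_wave must be >= 1")
  }
  cfg <- structure(list(
    effect_ppts = expand(effect_ppts, setNames(rep(0, 12L), outs),
                         "effect_ppts", -99, 99),
    baseline_rates = expand(baseline_rates, default_base, "baseline_rates",
                            1e-6, 1 - 1e-6),
    wave_effects = wave_effects[as.character(waves)],
    facility_sd = facility_sd,
    targeting_strength = targeting_strength,
    confounding_strength = confounding_strength,
    trend_ppts_per_wave = trend_ppts_per_wave,
    women_per_facility_per_wave = as.integer(women_per_facility_per_wave),
    waves = waves,
    rollout_waves = sort(as.integer(rollout_waves)),
    n_districts = as.integer(n_districts),
    facilities_per_district = facilities_per_district,
    target_share = target_share,
    other_intervention_frac = other_intervention_frac,
    jitter_sd_km = jitter_sd_km,
    eligibility = expand(eligibility, default_elig, "eligibility", 0.01, 1),
    seed = as.integer(seed)
  ), class = "truth_config")
  if (!all(cfg$rollout_waves %in% cfg$waves)) {
    stop_invalid("rollout_waves must be a subset of the survey waves")
  }
  if (any(cfg$baseline_rates + cfg$effect_ppts / 100 >= 1) ||
      any(cfg$baseline_rates + cfg$effect_ppts / 100 <= 0)) {
    stop_invalid("baseline_rates + effect_ppts/100 must stay inside (0, 1)")
  }
  cfg
}

#' @export
print.truth_config <- function(x, ...) {
  cat("<truth_config>\n")
  cat("  waves:", paste(x$waves, collapse = " "),
      "| rollout:", paste(x$rollout_waves, collapse = " "), "\n")
  cat(sprintf("  %d districts x ~%g facilities, %d women/facility/wave\n",
              x$n_districts, x$facilities_per_district,
              x$women_per_facility_per_wave))
  cat(sprintf("  targeting %.2f, confounding %.2f, facility sd %.2f, seed %d\n",
              x$targeting_strength, x$confounding_strength, x$facility_sd,
              x$seed))
  nz <- x$effect_ppts[x$effect_ppts != 0]
  if (length(nz)) {
    cat("  planted effects (ppts):",
        paste(sprintf("%s=%+g", names(nz), nz), collapse = ", "), "\n")
  } else {
    cat("  planted effects: all zero\n")
  }
  invisible(x)
}

#' Log-odds shift that plants a given percentage-point effect
#'
#' Finds the additive log-odds shift `s` such that the model-implied
#' marginal risk difference
#' `E[plogis(eta + b + s)] - E[plogis(eta + b)]`, with `b` the Gaussian
#' facility intercept, equals `effect_ppts / 100` at the configured
#' baseline. With `facility_sd = 0` this reduces to the plain conversion
#' `qlogis(base + effect/100) - qlogis(base)`; with heterogeneity the
#' plain conversion is attenuated by the logistic curvature, so the shift
#' is solved numerically with Gauss-Hermite integration over `b`.
#'
#' @param baseline baseline probability in (0,1).
#' @param effect_ppts effect in percentage points.
#' @param facility_sd sd of the Gaussian facility intercept.
#' @return the log-odds shift (0 when `effect_ppts = 0`).
#' @export
planted_logit_shift <- function(baseline, effect_ppts, facility_sd = 0) {
  if (effect_ppts == 0) return(0)
  eta <- qlogis(baseline)
  if (facility_sd <= 0) {
    return(qlogis(baseline + effect_ppts / 100) - eta)
  }
  gh <- gauss_hermite_probs(31L)
  marg <- function(shift) {
    sum(gh$w * plogis(eta + gh$x * facility_sd + shift)) -
      sum(gh$w * plogis(eta + gh$x * facility_sd))
  }
  target <- effect_ppts / 100
  stats::uniroot(function(s) marg(s) - target,
                 interval = c(-15, 15), tol = 1e-12)$root
}

# nodes/weights of Gauss-Hermite quadrature rescaled for N(0,1) expectations
gauss_hermite_probs <- function(n) {
  i <- seq_len(n - 1L)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = sqrt(2) * e$values, w = e$vectors[1L, ]^2)
}
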