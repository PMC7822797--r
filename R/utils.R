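#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible substream seed for a named pipeline stage
#'
#' One global seed is propagated through named substreams so that each
#' stage (district generation, treatment assignment, outcome draws, the
#' bootstrap, ...) can be re-run independently without disturbing the
#' others. The mapping is a small deterministic hash of the stage name
#' folded into the master seed, kept below 2^31 - 1 so the result is a
#' valid R integer seed.
#'
#' @param seed master integer seed.
#' @param stage character stage label.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003L
  as.integer((abs(seed) %% 1000003L) * 2011L + h) %% 2147483587L
}

with_stage_seed <- function(seed, stage, code) {
  withr::with_seed(substream_seed(seed, stage), code)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_invalid("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", "))
  }
  invisible(df)
}

fd_log <- function(...) {
  message(sprintf(...))
}

#' Names of the twelve health outcomes
#'
#' Family-planning counselling (side effects of the current method, other
#' available methods), antenatal-care quality (4+ visits, told of pregnancy
#' complications, weight measured, blood pressure measured, urine sample
#' collected), delivery care (institutional delivery, skilled assistance)
#' and child morbidity prevalence (acute respiratory infection, fever,
#' diarrhea).
#'
#' @return character vector of length 12.
#' @export
outcome_names <- function() {
  c("fp_side_effects", "fp_other_methods",
    "anc_4visits", "anc_complications", "anc_weight", "anc_bp", "anc_urine",
    "delivery_institutional", "delivery_skilled",
    "child_ari", "child_fever", "child_diarrhea")
}

#' Names of the eight district socio-economic indicators
#'
#' The deprivation indicators used both for rollout targeting and as
#' propensity-score covariates: illiteracy ratio, unemployment ratio,
#' income dependency ratio, share of households without electricity,
#' share without potable water, average family size, household crowding
#' factor, and district population size.
#'
#' @return character vector of length 8.
#' @export
district_indicators <- function() {
  c("illiteracy_ratio", "unemployment_ratio", "income_dependency_ratio",
    "no_electricity", "no_potable_water", "avg_family_size",
    "crowding_factor", "population_size")
}

#' Region labels
#' @return character vector of the six region labels.
#' @export
region_levels <- function() {
  c("fully-urban", "urban-lower", "rural-lower",
    "urban-upper", "rural-upper", "frontier")
}

staff_categories <- function() {
  c("practitioners", "specialists", "pharmacists", "nurses",
    "lab_technicians", "xray_technicians", "health_observers",
    "social_workers")
}
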