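#' Generate district socio-economic profiles
#'
#' Draws the eight district indicators from fixed documented
#' distributions: illiteracy Beta(5, 7), unemployment Beta(2, 18), income
#' dependency Beta(8, 12), no-electricity Beta(1.5, 28.5), no-potable-water
#' Beta(2, 18); average family size 3 + Gamma(shape 4, scale 0.4),
#' household crowding 0.8 + Gamma(shape 2, scale 0.35), population size
#' round(LogNormal(meanlog 10.2, sdlog 0.6)). Regions are sampled with
#' probabilities (0.15, 0.20, 0.25, 0.15, 0.20, 0.05) over
#' [region_levels()].
#'
#' @param n_districts number of districts (>= 2, so that treated and
#'   control pools can both exist).
#' @param seed integer seed.
#' @return data.frame with one row per district.
#' @export
gen_districts <- function(n_districts, seed = 1L) {
  if (!is.numeric(n_districts) || n_districts < 2) {
    stop_invalid("n_districts must be >= 2 (need treated and control pools)")
  }
  n <- as.integer(n_districts)
  with_stage_seed(seed, "districts", {
    data.frame(
      district_id = sprintf("D%04d", seq_len(n)),
      illiteracy_ratio = rbeta(n, 5, 7),
      unemployment_ratio = rbeta(n, 2, 18),
      income_dependency_ratio = rbeta(n, 8, 12),
      no_electricity = rbeta(n, 1.5, 28.5),
      no_potable_water = rbeta(n, 2, 18),
      avg_family_size = 3 + rgamma(n, shape = 4, scale = 0.4),
      crowding_factor = 0.8 + rgamma(n, shape = 2, scale = 0.35),
      population_size = pmax(500, round(exp(rnorm(n, 10.2, 0.6)))),
      region = sample(region_levels(), n, replace = TRUE,
                      prob = c(0.15, 0.20, 0.25, 0.15, 0.20, 0.05)),
      # district centroids on a rough Nile-valley bounding box
      centroid_lat = runif(n, 26, 31),
      centroid_lon = runif(n, 29, 33),
      stringsAsFactors = FALSE
    )
  })
}

#' Social vulnerability index of a district set
#'
#' The mean of the eight district indicators after z-standardization
#' across the supplied set, signed so that higher values mean more
#' vulnerable: the seven deprivation indicators (illiteracy,
#' unemployment, income dependency, no electricity, no potable water,
#' family size, crowding) enter with a positive sign and population size
#' with a negative sign (larger districts are treated as less
#' vulnerable). The sign vector is configurable via `signs`.
#'
#' An indicator with zero variance across the set contributes 0 to every
#' district's index, with a warning.
#'
#' @param districts data.frame from [gen_districts()] (or any table with
#'   the [district_indicators()] columns).
#' @param signs named numeric of +-1 over the eight indicators.
#' @return numeric vector of indices, one per district row.
#' @export
vulnerability_index <- function(districts,
                                signs = c(illiteracy_ratio = 1,
                                          unemployment_ratio = 1,
                                          income_dependency_ratio = 1,
                                          no_electricity = 1,
                                          no_potable_water = 1,
                                          avg_family_size = 1,
                                          crowding_factor = 1,
                                          population_size = -1)) {
  assert_cols(districts, district_indicators(), "districts")
  z <- vapply(district_indicators(), function(col) {
    x <- districts[[col]]
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      warning(sprintf("indicator '%s' has zero variance; it contributes 0",
                      col), call. = FALSE)
      return(rep(0, length(x)))
    }
    signs[[col]] * (x - mean(x)) / s
  }, numeric(nrow(districts)))
  rowMeans(z)
}

#' Classify an accreditation survey score
#'
#' Three-tier rule: a facility scoring 80% or above of the total survey
#' score is granted full accreditation; between 50% and just below 80%,
#' provisional accreditation; below 50%, accreditation is denied. The
#' half-open boundary `[0.50, 0.80)` for provisional makes the partition
#' exhaustive.
#'
#' @param survey_score numeric vector of scores as proportions in [0, 1].
#' @return character vector in `{"full", "provisional", "denied"}`.
#' @export
classify_accreditation <- function(survey_score) {
  if (!is.numeric(survey_score) || any(!is.finite(survey_score)) ||
      any(survey_score < 0) || any(survey_score > 1)) {
    stop_invalid("survey_score must be numeric in [0, 1]")
  }
  ifelse(survey_score >= 0.80, "full",
         ifelse(survey_score >= 0.50, "provisional", "denied"))
}

#' Generate primary-health-care facility records
#'
#' Places facilities around their district centroid (Gaussian scatter,
#' sd 0.12 degrees) and then enforces a minimum pairwise spacing of
#' `min_spacing_km` (default 12 km) by re-drawing offending positions —
#' catchment facilities serve separated populations, and the spacing
#' keeps nearest-facility linkage nearly always correct under the
#' default 2 km GPS jitter. Draws the eight staff-category counts from
#' Poisson distributions, samples building condition and catchment
#' population, and initializes all accreditation fields to "not
#' accredited".
#'
#' @param districts data.frame from [gen_districts()].
#' @param cfg a [truth_config()] (uses `facilities_per_district`, `seed`).
#' @return data.frame of facilities; staff counts are columns prefixed
#'   `staff_`.
#' @param min_spacing_km minimum distance between any two facilities.
#' @export
gen_facilities <- function(districts, cfg, min_spacing_km = 12) {
  stopifnot(inherits(cfg, "truth_config"))
  with_stage_seed(cfg$seed, "facilities", {
    n_per <- pmax(1L, stats::rpois(nrow(districts), cfg$facilities_per_district))
    idx <- rep(seq_len(nrow(districts)), n_per)
    n <- length(idx)
    lat <- districts$centroid_lat[idx] + rnorm(n, 0, 0.12)
    lon <- districts$centroid_lon[idx] + rnorm(n, 0, 0.12)
    for (pass in seq_len(200L)) {
      D <- outer_haversine(lat, lon, lat, lon)
      diag(D) <- Inf
      crowd <- which(apply(D < min_spacing_km, 1L, any))
      # of each close pair, re-draw the higher-indexed member
      crowd <- crowd[vapply(crowd, function(i)
        any(D[i, seq_len(i - 1L)] < min_spacing_km), logical(1L))]
      if (!length(crowd)) break
      spread <- 0.12 * (1 + pass / 10)
      lat[crowd] <- districts$centroid_lat[idx[crowd]] +
        rnorm(length(crowd), 0, spread)
      lon[crowd] <- districts$centroid_lon[idx[crowd]] +
        rnorm(length(crowd), 0, spread)
    }
    fac <- data.frame(
      facility_id = sprintf("F%05d", seq_len(n)),
      district_id = districts$district_id[idx],
      lat = lat,
      lon = lon,
      stringsAsFactors = FALSE
    )
    staff_lambda <- c(2, 1, 1, 4, 2, 1, 1, 1)
    for (k in seq_along(staff_categories())) {
      fac[[paste0("staff_", staff_categories()[k])]] <-
        stats::rpois(n, staff_lambda[k])
    }
    fac$building_condition <- sample(c("bad", "average", "good"), n,
                                     replace = TRUE, prob = c(0.2, 0.5, 0.3))
    fac$catchment_population <- pmax(200, round(exp(rnorm(n, 9.2, 0.5))))
    fac$accreditation_wave <- NA_integer_
    fac$accreditation_status <- "none"
    fac$other_interventions <- 0L
    fac
  })
}

#' Assign staggered district-level treatment
#'
#' Districts are selected for the program with probability
#' `plogis(qlogis(target_share) + targeting_strength * v)` where `v` is
#' the district's [vulnerability_index()]. Selected districts are ordered
#' by decreasing vulnerability and split into consecutive blocks, one per
#' rollout wave, so the most vulnerable districts enter earliest. Every
#' facility in a selected district receives that district's rollout wave;
#' its status (full vs provisional) follows [classify_accreditation()]
#' applied to a simulated survey score drawn Uniform(0.55, 0.98). Both
#' statuses count as treated. A fraction `other_intervention_frac` of
#' treated facilities is flagged as subject to additional reform
#' interventions, to exercise the downstream exclusion rule.
#'
#' @param districts data.frame from [gen_districts()].
#' @param facilities data.frame from [gen_facilities()].
#' @param rollout_waves waves at which accreditation can start; must be a
#'   subset of `cfg$waves`.
#' @param cfg a [truth_config()].
#' @return the facilities data.frame with `accreditation_wave`,
#'   `accreditation_status`, `survey_score` and `other_interventions`
#'   filled in.
#' @export
assign_treatment <- function(districts, facilities,
                             rollout_waves = cfg$rollout_waves, cfg) {
  stopifnot(inherits(cfg, "truth_config"))
  if (length(rollout_waves) == 0) stop_invalid("rollout_waves must be non-empty")
  if (!all(rollout_waves %in% cfg$waves)) {
    stop_invalid("rollout_waves must be a subset of the survey waves")
  }
  rollout_waves <- sort(as.integer(rollout_waves))
  v <- vulnerability_index(districts)
  with_stage_seed(cfg$seed, "treatment", {
    p <- plogis(qlogis(cfg$target_share) + cfg$targeting_strength * v)
    selected <- which(rbinom(nrow(districts), 1L, p) == 1L)
    dist_wave <- setNames(rep(NA_integer_, nrow(districts)),
                          districts$district_id)
    if (length(selected)) {
      ord <- selected[order(-v[selected])]
      blocks <- ceiling(seq_along(ord) / (length(ord) / length(rollout_waves)))
      blocks <- pmin(pmax(blocks, 1L), length(rollout_waves))
      dist_wave[districts$district_id[ord]] <- rollout_waves[blocks]
    }
    fac_wave <- dist_wave[facilities$district_id]
    treated <- !is.na(fac_wave)
    facilities$accreditation_wave <- unname(fac_wave)
    facilities$survey_score <- NA_real_
    facilities$survey_score[treated] <- runif(sum(treated), 0.55, 0.98)
    facilities$accreditation_status <- "none"
    facilities$accreditation_status[treated] <-
      classify_accreditation(facilities$survey_score[treated])
    facilities$other_interventions <- 0L
    facilities$other_interventions[treated] <-
      rbinom(sum(treated), 1L, cfg$other_intervention_frac)
    facilities
  })
}

# Per-facility log-odds intercepts: Gaussian heterogeneity plus (when the
# district table is supplied) a level shift proportional to district
# vulnerability, which induces selection-on-levels confounding.
facility_intercepts <- function(facilities, cfg, districts = NULL) {
  b <- with_stage_seed(cfg$seed, "facility_intercepts",
                       rnorm(nrow(facilities), 0, cfg$facility_sd))
  if (!is.null(districts) && cfg$confounding_strength != 0) {
    v <- vulnerability_index(districts)
    names(v) <- districts$district_id
    b <- b + cfg$confounding_strength * unname(v[facilities$district_id])
  }
  b
}

# Matrix of Bernoulli probabilities (facilities x outcomes) for one wave.
# Shared by gen_women() and gen_facility_panel() so both generators follow
# the same law.
outcome_prob_matrix <- function(facilities, wave, cfg, b) {
  outs <- outcome_names()
  wave_idx <- match(wave, cfg$waves)
  we <- cfg$wave_effects[[as.character(wave)]]
  treated_now <- !is.na(facilities$accreditation_wave) &
    wave >= facilities$accreditation_wave
  ever_treated <- !is.na(facilities$accreditation_wave)
  p <- matrix(NA_real_, nrow(facilities), length(outs),
              dimnames = list(NULL, outs))
  for (o in outs) {
    shift <- planted_logit_shift(cfg$baseline_rates[[o]], cfg$effect_ppts[[o]],
                                 cfg$facility_sd)
    eta <- qlogis(cfg$baseline_rates[[o]]) + we + b + shift * treated_now
    pr <- plogis(eta)
    if (cfg$trend_ppts_per_wave != 0) {
      pr <- pr + (cfg$trend_ppts_per_wave / 100) * (wave_idx - 1L) * ever_treated
    }
    p[, o] <- pmin(pmax(pr, 0.005), 0.995)
  }
  p
}

#' Generate woman-level survey records
#'
#' For each facility and wave, draws `women_per_facility_per_wave` women
#' located at the facility plus isotropic Gaussian GPS jitter
#' (`jitter_sd_km`). Each of the twelve binary indicators is drawn
#' Bernoulli with log-odds = logit(baseline) + wave effect + facility
#' intercept + planted treatment shift when the facility is treated in
#' that wave. A woman is in an outcome's denominator with the configured
#' eligibility probability; ineligible women carry `NA` for that
#' indicator, so denominators differ across outcomes.
#'
#' @param facilities facilities after [assign_treatment()].
#' @param waves survey waves (ascending).
#' @param cfg a [truth_config()].
#' @param districts optional district table; when supplied, facility
#'   intercepts include the vulnerability-linked level confounder.
#' @return data.frame with one row per woman: `woman_id`, `wave`, `lat`,
#'   `lon`, `true_facility_id` (ground truth for linkage checks, not an
#'   analysis input), and one 0/1/NA column per outcome.
#' @export
gen_women <- function(facilities, waves = cfg$waves, cfg, districts = NULL) {
  stopifnot(inherits(cfg, "truth_config"))
  if (nrow(facilities) == 0) stop_invalid("facilities must be non-empty")
  if (is.unsorted(waves)) stop_invalid("waves must be sorted ascending")
  b <- facility_intercepts(facilities, cfg, districts)
  m <- cfg$women_per_facility_per_wave
  outs <- outcome_names()
  with_stage_seed(cfg$seed, "women", {
    blocks <- lapply(waves, function(w) {
      fi <- rep(seq_len(nrow(facilities)), each = m)
      n <- length(fi)
      lat0 <- facilities$lat[fi]
      df <- data.frame(
        wave = rep(as.integer(w), n),
        lat = lat0 + rnorm(n, 0, cfg$jitter_sd_km / 110.574),
        lon = facilities$lon[fi] +
          rnorm(n, 0, cfg$jitter_sd_km / (111.320 * cos(lat0 * pi / 180))),
        true_facility_id = facilities$facility_id[fi],
        stringsAsFactors = FALSE
      )
      p <- outcome_prob_matrix(facilities, w, cfg, b)
      for (o in outs) {
        elig <- rbinom(n, 1L, cfg$eligibility[[o]]) == 1L
        y <- rep(NA_integer_, n)
        y[elig] <- rbinom(sum(elig), 1L, p[fi[elig], o])
        df[[o]] <- y
      }
      df
    })
    women <- do.call(rbind, blocks)
    women <- cbind(woman_id = sprintf("W%07d", seq_len(nrow(women))), women,
                   stringsAsFactors = FALSE)
    rownames(women) <- NULL
    women
  })
}

#' Draw a facility-by-wave outcome panel directly
#'
#' Samples the collapsed facility panel from the same generative law as
#' [gen_women()] followed by truth-based collapsing: per facility, wave
#' and outcome, the eligible count is Binomial(`women_per_facility_per_wave`,
#' eligibility) and the positive count Binomial(n_eligible, p) with the
#' identical probability matrix. This is the distribution of the woman
#' level pipeline without materializing individual records, and is what
#' the Monte-Carlo calibration and recovery studies use; the agreement of
#' the two routes is itself under test.
#'
#' @inheritParams gen_women
#' @return a panel data.frame in the same schema as [build_panel()]
#'   output.
#' @export
gen_facility_panel <- function(facilities, waves = cfg$waves, cfg,
                               districts = NULL) {
  stopifnot(inherits(cfg, "truth_config"))
  if (nrow(facilities) == 0) stop_invalid("facilities must be non-empty")
  b <- facility_intercepts(facilities, cfg, districts)
  outs <- outcome_names()
  m <- cfg$women_per_facility_per_wave
  nf <- nrow(facilities)
  rows <- with_stage_seed(cfg$seed, "women", {
    do.call(rbind, lapply(waves, function(w) {
      p <- outcome_prob_matrix(facilities, w, cfg, b)
      df <- data.frame(facility_id = facilities$facility_id,
                       wave = rep(as.integer(w), nf),
                       stringsAsFactors = FALSE)
      for (o in outs) {
        n_elig <- rbinom(nf, m, cfg$eligibility[[o]])
        pos <- rbinom(nf, n_elig, p[, o])
        df[[paste0("n_", o)]] <- n_elig
        df[[paste0("pct_", o)]] <-
          ifelse(n_elig > 0, 100 * pos / n_elig, NA_real_)
      }
      df
    }))
  })
  build_panel(rows, facilities, districts)
}

#' Generate a complete synthetic dataset
#'
#' Runs district generation, facility generation, treatment assignment
#' and woman-level simulation under one config, and returns the tables
#' together with a "truth sidecar" (planted effects, per-district
#' vulnerability, woman-to-facility ground truth lives in
#' `women$true_facility_id`).
#'
#' @param cfg a [truth_config()].
#' @return list with `districts`, `facilities`, `women`, `truth`.
#' @export
generate_dataset <- function(cfg = truth_config()) {
  districts <- gen_districts(cfg$n_districts, cfg$seed)
  facilities <- gen_facilities(districts, cfg)
  facilities <- assign_treatment(districts, facilities, cfg$rollout_waves, cfg)
  women <- gen_women(facilities, cfg$waves, cfg, districts)
  truth <- list(
    effect_ppts = as.list(cfg$effect_ppts),
    baseline_rates = as.list(cfg$baseline_rates),
    targeting_strength = cfg$targeting_strength,
    confounding_strength = cfg$confounding_strength,
    vulnerability = setNames(as.list(vulnerability_index(districts)),
                             districts$district_id),
    seed = cfg$seed
  )
  list(districts = districts, facilities = facilities, women = women,
       truth = truth, cfg = cfg)
}

#' Write a synthetic dataset to disk
#'
#' Writes `districts.csv`, `facilities.csv` and `women.csv`, the config
#' as `config.yaml`, and the truth sidecar as `truth.json`.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_data <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(dataset$districts, file.path(dir, "districts.csv"),
            row.names = FALSE)
  write.csv(dataset$facilities, file.path(dir, "facilities.csv"),
            row.names = FALSE)
  write.csv(dataset$women, file.path(dir, "women.csv"), row.names = FALSE)
  cfg <- dataset$cfg
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x),
    file.path(dir, "config.yaml"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
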