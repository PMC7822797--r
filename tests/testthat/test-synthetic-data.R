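test_that("district generation is reproducible and respects invariants", {
  d1 <- gen_districts(10, seed = 1)
  d2 <- gen_districts(10, seed = 1)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 10L)
  props <- c("illiteracy_ratio", "unemployment_ratio",
             "income_dependency_ratio", "no_electricity", "no_potable_water")
  for (p in props) expect_true(all(d1[[p]] >= 0 & d1[[p]] <= 1))
  expect_true(all(d1$population_size >= 1))
  expect_true(all(d1$avg_family_size >= 1))
  expect_true(all(d1$region %in% region_levels()))

  d3 <- gen_districts(2, seed = 7)
  expect_equal(length(unique(d3$district_id)), 2L)
  expect_error(gen_districts(1), "n_districts")
})

test_that("illiteracy draws match the configured Beta(5, 7) distribution", {
  d <- gen_districts(1000, seed = 3)
  beta_mean <- 5 / 12
  beta_se <- sqrt(5 * 7 / (12^2 * 13) / 1000)
  expect_lt(abs(mean(d$illiteracy_ratio) - beta_mean), 3 * beta_se)
})

test_that("vulnerability index is zero for identical districts and monotone in deprivation", {
  d <- gen_districts(5, seed = 1)
  same <- d[rep(1, 4), ]
  warns <- capture_warnings(v <- vulnerability_index(same))
  expect_true(any(grepl("zero variance", warns)))
  expect_equal(v, rep(0, 4))

  # district 2 strictly worse on all deprivation indicators, smaller population
  two <- d[1:2, ]
  for (col in setdiff(district_indicators(), "population_size")) {
    two[[col]] <- c(0.2, 0.6) * if (col %in% c("avg_family_size",
                                               "crowding_factor")) 10 else 1
  }
  two$population_size <- c(50000, 10000)
  v2 <- vulnerability_index(two)
  expect_gt(v2[2], v2[1])
})

test_that("vulnerability index equals the hand-computed signed z-score mean", {
  d <- gen_districts(5, seed = 11)
  # independent elementwise computation
  expected <- numeric(5)
  signs <- c(1, 1, 1, 1, 1, 1, 1, -1)
  for (i in 1:5) {
    acc <- 0
    for (k in seq_along(district_indicators())) {
      x <- d[[district_indicators()[k]]]
      acc <- acc + signs[k] * (x[i] - mean(x)) / sd(x)
    }
    expected[i] <- acc / 8
  }
  expect_equal(vulnerability_index(d), expected, tolerance = 1e-12)
})

test_that("accreditation classification follows the 50/80 thresholds", {
  expect_identical(classify_accreditation(0.80), "full")
  expect_identical(classify_accreditation(0.50), "provisional")
  expect_identical(classify_accreditation(0.49), "denied")
  expect_identical(classify_accreditation(c(1, 0.799, 0.795, 0, 0.9)),
                   c("full", "provisional", "provisional", "denied", "full"))
  expect_error(classify_accreditation(1.2), "survey_score")
  expect_error(classify_accreditation(-0.1), "survey_score")
})

test_that("null targeting makes assignment independent of vulnerability", {
  cfg <- truth_config(targeting_strength = 0, n_districts = 30,
                      facilities_per_district = 2, seed = 5)
  d <- gen_districts(30, seed = 5)
  f <- gen_facilities(d, cfg)
  v <- vulnerability_index(d)
  cors <- sapply(1:200, function(r) {
    cfg_r <- truth_config(targeting_strength = 0, n_districts = 30,
                          facilities_per_district = 2, seed = 5000 + r)
    fr <- assign_treatment(d, f, cfg$rollout_waves, cfg_r)
    treated_d <- tapply(!is.na(fr$accreditation_wave), fr$district_id, any)
    suppressWarnings(cor(v, as.numeric(treated_d[d$district_id])))
  })
  cors <- cors[!is.na(cors)]
  expect_lt(abs(mean(cors)), 3 * sd(cors) / sqrt(length(cors)))
})

test_that("strong targeting selects more vulnerable districts", {
  d <- gen_districts(40, seed = 2)
  cfg0 <- truth_config(n_districts = 40, facilities_per_district = 2, seed = 2)
  f <- gen_facilities(d, cfg0)
  v <- setNames(vulnerability_index(d), d$district_id)
  gaps <- sapply(1:200, function(r) {
    cfg <- truth_config(targeting_strength = 4, n_districts = 40,
                        facilities_per_district = 2, seed = 9000 + r)
    fr <- assign_treatment(d, f, cfg$rollout_waves, cfg)
    treated_d <- tapply(!is.na(fr$accreditation_wave), fr$district_id, any)
    treated_d <- treated_d[d$district_id]
    if (all(treated_d) || !any(treated_d)) return(NA_real_)
    mean(v[treated_d]) - mean(v[!treated_d])
  })
  expect_gt(mean(gaps, na.rm = TRUE), 0.2)
})

test_that("treatment assignment invariants hold", {
  cfg <- truth_config(seed = 3)
  d <- gen_districts(cfg$n_districts, cfg$seed)
  f <- assign_treatment(d, gen_facilities(d, cfg), cfg$rollout_waves, cfg)
  has_wave <- !is.na(f$accreditation_wave)
  expect_identical(has_wave, f$accreditation_status != "none")
  expect_true(all(f$accreditation_status %in% c("none", "provisional", "full")))
  expect_true(all(f$accreditation_wave[has_wave] %in% cfg$rollout_waves))
  # treatment is district-level: status constant within district
  expect_true(all(tapply(has_wave, f$district_id,
                         function(x) all(x) || !any(x))))
  expect_error(assign_treatment(d, f, integer(), cfg), "rollout_waves")

  # forcing every district in: all facilities get a wave
  cfg_all <- truth_config(targeting_strength = 0, target_share = 1, seed = 3)
  f_all <- assign_treatment(d, gen_facilities(d, cfg_all),
                            cfg_all$rollout_waves, cfg_all)
  expect_true(all(!is.na(f_all$accreditation_wave)))
})

test_that("woman generation is deterministic and schema-complete", {
  cfg <- truth_config(n_districts = 4, facilities_per_district = 2,
                      women_per_facility_per_wave = 5,
                      waves = c(2000L, 2005L), rollout_waves = 2005L, seed = 8)
  d <- gen_districts(4, cfg$seed)
  f <- assign_treatment(d, gen_facilities(d, cfg), cfg$rollout_waves, cfg)
  w1 <- gen_women(f, cfg$waves, cfg, d)
  w2 <- gen_women(f, cfg$waves, cfg, d)
  expect_identical(w1, w2)
  expect_true(all(outcome_names() %in% names(w1)))
  for (o in outcome_names()) {
    expect_true(all(w1[[o]] %in% c(0L, 1L, NA_integer_)))
  }
  expect_equal(nrow(w1), nrow(f) * 5 * 2)
  expect_error(gen_women(f[0, ], cfg$waves, cfg), "non-empty")
})

test_that("zero planted effects leave no treated-control outcome gap", {
  cfg <- truth_config(effect_ppts = 0, targeting_strength = 0,
                      confounding_strength = 0, n_districts = 30,
                      facilities_per_district = 3,
                      women_per_facility_per_wave = 60,
                      waves = c(2000L, 2005L), rollout_waves = 2005L,
                      seed = 21)
  d <- gen_districts(30, cfg$seed)
  f <- assign_treatment(d, gen_facilities(d, cfg), cfg$rollout_waves, cfg)
  w <- gen_women(f, cfg$waves, cfg, d)
  treated <- f$facility_id[!is.na(f$accreditation_wave)]
  post <- w[w$wave == 2005, ]
  y <- post$anc_4visits
  gap <- mean(y[post$true_facility_id %in% treated], na.rm = TRUE) -
    mean(y[!post$true_facility_id %in% treated], na.rm = TRUE)
  n_eff <- sum(!is.na(y)) / 4
  expect_lt(abs(gap), 4 * sqrt(0.25 / n_eff) + 0.02)
})

test_that("a planted -5 ppt diarrhea effect is realized at large n", {
  cfg <- truth_config(effect_ppts = c(child_diarrhea = -5),
                      baseline_rates = c(child_diarrhea = 0.25),
                      targeting_strength = 0, confounding_strength = 0,
                      n_districts = 40, facilities_per_district = 4,
                      women_per_facility_per_wave = 150,
                      waves = c(2000L, 2005L), rollout_waves = 2005L,
                      seed = 31)
  d <- gen_districts(40, cfg$seed)
  f <- assign_treatment(d, gen_facilities(d, cfg), cfg$rollout_waves, cfg)
  w <- gen_women(f, cfg$waves, cfg, d)
  treated <- f$facility_id[!is.na(f$accreditation_wave)]
  did <- function(o) {
    cell <- function(tr, wv) {
      sel <- (w$true_facility_id %in% treated) == tr & w$wave == wv
      mean(w[[o]][sel], na.rm = TRUE)
    }
    100 * ((cell(TRUE, 2005) - cell(TRUE, 2000)) -
             (cell(FALSE, 2005) - cell(FALSE, 2000)))
  }
  expect_lt(abs(did("child_diarrhea") - (-5)), 1.2)
})

test_that("planted logit shifts reproduce the configured marginal effect", {
  # independent Monte-Carlo integration oracle over the facility intercepts
  withr::with_seed(99, {
    b <- rnorm(4e5, 0, 0.3)
    for (case in list(c(0.1, 5), c(0.5, 10), c(0.9, -5), c(0.3, -8))) {
      base <- case[1]; eff <- case[2]
      s <- planted_logit_shift(base, eff, facility_sd = 0.3)
      did_mc <- 100 * (mean(plogis(qlogis(base) + b + s)) -
                         mean(plogis(qlogis(base) + b)))
      expect_lt(abs(did_mc - eff), 0.1)
    }
  })
  # degenerate case: no heterogeneity reduces to the plain conversion
  expect_equal(planted_logit_shift(0.4, 10, 0),
               qlogis(0.5) - qlogis(0.4), tolerance = 1e-12)
  expect_identical(planted_logit_shift(0.4, 0, 0.3), 0)
})

test_that("collapsed-form sampler agrees with the woman-level route", {
  mk_cfg <- function(seed) truth_config(
    effect_ppts = 10, n_districts = 12, facilities_per_district = 4,
    women_per_facility_per_wave = 120, waves = c(2000L, 2005L),
    rollout_waves = 2005L, seed = seed)
  cfg <- mk_cfg(17)
  d <- gen_districts(cfg$n_districts, cfg$seed)
  f <- assign_treatment(d, gen_facilities(d, cfg), cfg$rollout_waves, cfg)
  w <- gen_women(f, cfg$waves, cfg, d)
  fp <- gen_facility_panel(f, cfg$waves, cfg, d)
  for (o in c("anc_4visits", "child_fever")) {
    womans <- 100 * mean(w[[o]], na.rm = TRUE)
    fast <- weighted.mean(fp[[paste0("pct_", o)]], fp[[paste0("n_", o)]],
                          na.rm = TRUE)
    # both are draws of the same binomial law; compare pooled means
    expect_lt(abs(womans - fast), 4)
  }
  expect_true(all(paste0("pct_", outcome_names()) %in% names(fp)))
})

test_that("dataset writer round-trips through CSV", {
  cfg <- truth_config(n_districts = 3, facilities_per_district = 2,
                      women_per_facility_per_wave = 3,
                      waves = c(2000L, 2005L), rollout_waves = 2005L,
                      seed = 12)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_synthetic_data(ds, dir)
  expect_true(all(file.exists(file.path(
    dir, c("districts.csv", "facilities.csv", "women.csv",
           "config.yaml", "truth.json")))))
  back <- read.csv(file.path(dir, "women.csv"))
  expect_equal(nrow(back), nrow(ds$women))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$effect_ppts$anc_4visits, 0)
})
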