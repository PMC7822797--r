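# shared fixtures and independent oracles

# independent great-circle oracle: spherical law of cosines
loc_km <- function(lat1, lon1, lat2, lon2, R = 6371.0088) {
  rad <- pi / 180
  ca <- sin(lat1 * rad) * sin(lat2 * rad) +
    cos(lat1 * rad) * cos(lat2 * rad) * cos((lon2 - lon1) * rad)
  R * acos(pmin(pmax(ca, -1), 1))
}

# brute-force nearest facility: all pairs, scalar loop
brute_nearest <- function(woman, facilities) {
  best_d <- Inf
  best_id <- NA_character_
  for (k in seq_len(nrow(facilities))) {
    d <- loc_km(woman$lat, woman$lon, facilities$lat[k], facilities$lon[k])
    if (d < best_d - 1e-12 ||
        (abs(d - best_d) <= 1e-12 && facilities$facility_id[k] < best_id)) {
      best_d <- d
      best_id <- facilities$facility_id[k]
    }
  }
  best_id
}

# a small hand-made panel: n_treated + n_control facilities, two waves,
# one outcome column, with the bookkeeping columns the estimators expect
hand_panel <- function(pre_t, post_t, pre_c, post_c,
                       waves = c(2000L, 2005L), outcome = "anc_4visits",
                       district_per_facility = TRUE) {
  nt <- length(pre_t); nc <- length(pre_c)
  fid <- sprintf("F%02d", seq_len(nt + nc))
  treated <- c(rep(1L, nt), rep(0L, nc))
  rows <- do.call(rbind, lapply(1:2, function(p) {
    data.frame(facility_id = fid,
               wave = waves[p],
               district_id = if (district_per_facility) paste0("D", fid) else
                 rep(c("DT", "DC"), c(nt, nc)),
               ever_treated = treated,
               policy = if (p == 2L) treated else 0L,
               stringsAsFactors = FALSE)
  }))
  rows[[paste0("pct_", outcome)]] <- c(pre_t, pre_c, post_t, post_c)
  rows[[paste0("n_", outcome)]] <- 30L
  rows
}

# generated panel via the collapsed-form sampler, sample rules applied
fast_panel <- function(cfg) {
  d <- gen_districts(cfg$n_districts, cfg$seed)
  f <- assign_treatment(d, gen_facilities(d, cfg), cfg$rollout_waves, cfg)
  p <- suppressMessages(suppressWarnings(
    apply_sample_rules(gen_facility_panel(f, cfg$waves, cfg, d))))
  attr(p, "districts") <- d
  attr(p, "facilities") <- f
  p
}

# hand-made propensity model (for support/weight fixtures)
hand_pmodel <- function(scores, treatment, ids = names(scores)) {
  structure(list(coefficients = numeric(), vcov = NULL, se = numeric(),
                 scores = setNames(scores, ids), converged = TRUE,
                 n_iterations = 0L, treatment = as.numeric(treatment)),
            class = "propensity_model")
}
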