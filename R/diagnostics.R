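#' Group-specific linear pre-trend test
#'
#' Restricted to pre-treatment waves, fits the within-facility model
#' `y_it = wave dummies + theta * (ever_treated_i x wave step) + delta_i
#' + e_it` and reports the cluster-robust t test of `theta = 0`. Under
#' parallel trends eventually-treated and never-treated facilities share
#' the wave dummies, so `theta` (ppts per wave step) captures any
#' divergent linear pre-trend; a small p value flags divergence.
#'
#' @param panel panel data.frame (with `ever_treated`).
#' @param outcome outcome name.
#' @param pre_waves at least two waves that precede any treatment.
#' @param cluster_level `"district"` or `"facility"`.
#' @return object of class `diagnostic_result` with the trend estimate
#'   (ppts/wave step), its t statistic and p value.
#' @export
parallel_trends_test <- function(panel, outcome, pre_waves,
                                 cluster_level = c("district", "facility")) {
  cluster_level <- match.arg(cluster_level)
  pre_waves <- sort(unique(as.integer(pre_waves)))
  if (length(pre_waves) < 2L) {
    stop_invalid("parallel-trends test needs at least two pre-treatment waves")
  }
  ycol <- resolve_outcome_col(panel, outcome)
  d <- panel[panel$wave %in% pre_waves & !is.na(panel[[ycol]]), , drop = FALSE]
  if (any(d$policy == 1L)) {
    stop_invalid("pre_waves contain treated observations; they must precede treatment")
  }
  keep <- names(which(table(d$facility_id) >= 2L))
  d <- d[d$facility_id %in% keep, , drop = FALSE]
  if (length(unique(d$ever_treated)) < 2L) {
    stop_invalid("need both eventually-treated and never-treated facilities")
  }
  step <- match(d$wave, pre_waves) - 1L
  X <- cbind(sapply(pre_waves[-1L], function(w) as.numeric(d$wave == w)),
             treat_trend = d$ever_treated * step)
  colnames(X) <- c(paste0("wave", pre_waves[-1L]), "treat_trend")
  g <- d$facility_id
  Xd <- demean_by(X, g)
  yd <- demean_by(d[[ycol]], g)[, 1L]
  beta <- qr.coef(qr(Xd), yd)
  e <- as.vector(yd - Xd %*% beta)
  cl <- if (cluster_level == "district") d$district_id else d$facility_id
  V <- cluster_robust_cov(Xd, e, cl, n_absorbed = length(unique(g)))
  est <- unname(beta["treat_trend"])
  se <- sqrt(V["treat_trend", "treat_trend"])
  G <- length(unique(cl))
  t_stat <- est / se
  structure(list(name = "parallel_trends", outcome = outcome,
                 estimate = est, se = se, statistic = t_stat,
                 p_value = 2 * pt(-abs(t_stat), df = G - 1),
                 n_obs = nrow(d), n_clusters = G),
            class = "diagnostic_result")
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat(sprintf("<diagnostic:%s> %s\n", x$name, x$outcome))
  if (x$name == "parallel_trends") {
    cat(sprintf("  divergent pre-trend %.3f ppts/wave (se %.3f), t = %.2f, p = %.4f\n",
                x$estimate, x$se, x$statistic, x$p_value))
  } else {
    cat(sprintf("  rejection rate %.3f at nominal 5%% over %d placebo draws (mean estimate %.3f)\n",
                x$rejection_rate, x$n_reps, x$statistic))
  }
  invisible(x)
}

#' Placebo treatment experiments
#'
#' Repeatedly assigns a fake treatment and re-estimates the effect; the
#' share of nominally significant (5%) fake effects estimates the
#' procedure's false-positive rate, which should sit near 0.05.
#'
#' Two labeled modes: `"fake_group"` (default) keeps only never-treated
#' facilities and pseudo-treats whole districts — preserving the
#' district-level assignment mechanism and the treated district share —
#' with pseudo-timing drawn from the real rollout waves; `"fake_timing"`
#' keeps only waves strictly before any real accreditation and
#' pseudo-treats the actually-treated districts from a middle pre-wave,
#' probing anticipation effects.
#'
#' @param panel panel data.frame.
#' @param outcome outcome name.
#' @param estimator currently `"did_fe"`.
#' @param n_reps number of placebo draws (>= 1).
#' @param seed integer seed.
#' @param mode `"fake_group"` or `"fake_timing"`.
#' @param cluster_level passed to the estimator.
#' @return `diagnostic_result` with `rejection_rate`, `n_reps`, the mean
#'   placebo estimate as `statistic`, and a binomial p value comparing
#'   the rejection count with the nominal 5%.
#' @export
placebo_test <- function(panel, outcome, estimator = "did_fe",
                         n_reps = 200L, seed = 1L,
                         mode = c("fake_group", "fake_timing"),
                         cluster_level = c("district", "facility")) {
  mode <- match.arg(mode)
  cluster_level <- match.arg(cluster_level)
  estimator <- match.arg(estimator, "did_fe")
  if (n_reps < 1L) stop_invalid("n_reps must be >= 1")
  treated_dist <- unique(panel$district_id[panel$ever_treated == 1L])
  all_dist <- unique(panel$district_id)
  control_dist <- setdiff(all_dist, treated_dist)
  if (mode == "fake_group") {
    share <- length(treated_dist) / length(all_dist)
    n_pseudo <- max(1L, round(share * length(control_dist)))
    if (length(control_dist) < 2L * n_pseudo) {
      stop_invalid("need at least twice as many never-treated districts (%d) as pseudo-treated (%d)",
                   length(control_dist), n_pseudo)
    }
    base <- panel[panel$district_id %in% control_dist, , drop = FALSE]
    pseudo_waves <- panel$wave[panel$policy == 1L]
    pseudo_waves <- if (length(pseudo_waves)) {
      sort(unique(tapply(panel$wave[panel$policy == 1L],
                         panel$facility_id[panel$policy == 1L], min)))
    } else stats::median(unique(panel$wave))
  } else {
    first_treat <- min(panel$wave[panel$policy == 1L], Inf)
    base <- panel[panel$wave < first_treat, , drop = FALSE]
    if (length(unique(base$wave)) < 2L) {
      stop_invalid("fake_timing mode needs at least two pre-treatment waves")
    }
    if (!length(treated_dist)) stop_invalid("no treated districts to fake-time")
    pre_waves <- sort(unique(base$wave))
    # pseudo-treatment must switch on strictly inside the pre-period
    fake_wave <- pre_waves[min(length(pre_waves),
                               max(2L, ceiling((length(pre_waves) + 1) / 2)))]
  }
  ests <- numeric(n_reps); rej <- logical(n_reps)
  with_stage_seed(seed, "placebo", {
    for (r in seq_len(n_reps)) {
      d <- base
      if (mode == "fake_group") {
        pd <- sample(control_dist, n_pseudo)
        wv <- if (length(pseudo_waves) == 1L) rep(pseudo_waves, n_pseudo) else
          sample(pseudo_waves, n_pseudo, replace = TRUE)
        names(wv) <- pd
        d$ever_treated <- as.integer(d$district_id %in% pd)
        d$policy <- as.integer(d$ever_treated == 1L &
                                 d$wave >= wv[d$district_id])
      } else {
        d$ever_treated <- as.integer(d$district_id %in% treated_dist)
        d$policy <- as.integer(d$ever_treated == 1L & d$wave >= fake_wave)
      }
      fit <- tryCatch(
        suppressMessages(fit_did_fe(d, outcome, cluster_level = cluster_level)),
        error = function(e) NULL)
      if (is.null(fit)) { ests[r] <- NA; rej[r] <- NA } else {
        ests[r] <- fit$estimate
        rej[r] <- fit$p_value < 0.05
      }
    }
  })
  ok <- !is.na(rej)
  if (!any(ok)) stop_invalid("every placebo draw failed to estimate")
  rate <- mean(rej[ok])
  btest <- stats::binom.test(sum(rej[ok]), sum(ok), p = 0.05)
  structure(list(name = "placebo", outcome = outcome,
                 statistic = mean(ests[ok]), rejection_rate = rate,
                 n_reps = sum(ok), p_value = btest$p.value,
                 mode = mode),
            class = "diagnostic_result")
}

#' Run the full evaluation pipeline from a config
#'
#' Executes generate -> link -> collapse -> panel -> estimate (panel
#' fixed-effects DiD, two-period DiD, kernel PSM-DiD) -> diagnostics for
#' every configured outcome, logs the sample accounting at every stage,
#' and (when `out_dir` is set) writes `results.json`, `estimates.csv`,
#' `balance.csv`, `support.csv` and `links.csv`.
#'
#' @param config a nested list (or path to a YAML file) with blocks
#'   `truth` (arguments of [truth_config()]), `outcomes` (default all
#'   twelve), `estimators` (`baseline_wave`, `followup_wave`, `kernel`,
#'   `bandwidth`, `n_boot`, `cluster_level`), `linkage`
#'   (`max_distance_km`), `panel` (`min_denominator`), `diagnostics`
#'   (`placebo_reps`, `placebo_seed`), and `out_dir`.
#' @return (invisibly) list with the dataset, links, panel, an
#'   `estimates` data.frame, `diagnostics`, `balance`, and the
#'   sample-accounting list.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- do.call(truth_config, config$truth %||% list())
  est_cfg <- config$estimators %||% list()
  outcomes <- config$outcomes %||% outcome_names()
  t0 <- Sys.time()
  stage <- function(what) fd_log("[%5.1fs] %s",
                                 as.numeric(Sys.time() - t0, units = "secs"),
                                 what)

  stage("generating synthetic data")
  ds <- generate_dataset(cfg)
  stage(sprintf("linking %d women to %d facilities", nrow(ds$women),
                nrow(ds$facilities)))
  links <- link_cohort(ds$women, ds$facilities,
                       max_distance_km = config$linkage$max_distance_km)
  mislink <- mean(links$facility_id[match(ds$women$woman_id, links$woman_id)] !=
                    ds$women$true_facility_id, na.rm = TRUE)
  stage(sprintf("collapsing outcomes (mis-linkage rate %.4f)", mislink))
  rows <- do.call(rbind, lapply(cfg$waves, function(w)
    collapse_outcomes(links, ds$women, w, ds$facilities)))
  panel <- build_panel(rows, ds$facilities, ds$districts)
  panel <- apply_sample_rules(panel,
                              min_denominator =
                                config$panel$min_denominator %||% 5)

  baseline <- est_cfg$baseline_wave %||% min(cfg$rollout_waves)
  followup <- est_cfg$followup_wave %||%
    min(cfg$waves[cfg$waves > min(cfg$rollout_waves)])
  kernel <- est_cfg$kernel %||% "epanechnikov"
  bandwidth <- est_cfg$bandwidth %||% 0.06
  cluster_level <- est_cfg$cluster_level %||% "district"
  n_boot <- est_cfg$n_boot %||% 0L
  # two-period estimators contrast the wave before first rollout with followup
  pre_wave <- max(cfg$waves[cfg$waves < min(cfg$rollout_waves)])

  stage("estimating treatment effects")
  est_rows <- list(); balance <- NULL; support <- NULL
  for (o in outcomes) {
    fe <- tryCatch(suppressMessages(
      fit_did_fe(panel, o, cluster_level = cluster_level)),
      error = function(e) NULL)
    tp <- tryCatch(suppressMessages(
      fit_did_2period(panel, baseline, followup, o,
                      cluster_level = cluster_level)),
      error = function(e) NULL)
    ps <- tryCatch(suppressMessages(
      psm_did(panel, pre_wave, followup, o, kernel = kernel,
              bandwidth = bandwidth)),
      error = function(e) NULL)
    if (!is.null(ps) && n_boot > 0) {
      bs <- tryCatch(bootstrap_se(
        function(p) psm_did(p, pre_wave, followup, o, kernel = kernel,
                            bandwidth = bandwidth)$estimate,
        panel, n_boot = n_boot, seed = cfg$seed), error = function(e) NULL)
      if (!is.null(bs)) {
        ps$se <- bs$se
        ps$t_stat <- ps$estimate / ps$se
        ps$p_value <- 2 * pnorm(-abs(ps$t_stat))
        ps$details$ci <- bs$ci
      }
    }
    if (!is.null(ps) && is.null(balance)) {
      pre_rows <- panel[panel$wave == pre_wave, , drop = FALSE]
      acc_flag <- treated_as_of(panel, followup)
      balance <- balance_tests(pre_rows[, district_indicators()],
                               unname(acc_flag[pre_rows$facility_id]),
                               weights = match_weights(ps$details$propensity,
                                                       ps$details$support,
                                                       kernel = kernel,
                                                       bandwidth = bandwidth),
                               ids = pre_rows$facility_id)
      support <- ps$details$support$histogram
    }
    for (e in Filter(Negate(is.null), list(fe, tp, ps))) {
      est_rows[[length(est_rows) + 1L]] <- as.data.frame(e)
    }
  }
  estimates <- do.call(rbind, est_rows)

  stage("diagnostics")
  diag_cfg <- config$diagnostics %||% list()
  pre_waves <- cfg$waves[cfg$waves < min(cfg$rollout_waves)]
  diagnostics <- list()
  if (length(pre_waves) >= 2L) {
    diagnostics$parallel_trends <- lapply(outcomes, function(o)
      tryCatch(suppressMessages(parallel_trends_test(panel, o, pre_waves)),
               error = function(e) NULL))
    names(diagnostics$parallel_trends) <- outcomes
  }
  placebo_reps <- diag_cfg$placebo_reps %||% 0L
  if (placebo_reps > 0) {
    diagnostics$placebo <- tryCatch(suppressMessages(
      placebo_test(panel, outcomes[[1L]], n_reps = placebo_reps,
                   seed = diag_cfg$placebo_seed %||% cfg$seed)),
      error = function(e) NULL)
  }

  accounting <- list(
    women_generated = nrow(ds$women),
    women_linked = attr(links, "summary")$n_linked,
    women_dropped_linkage = attr(links, "summary")$n_dropped,
    mislinkage_rate = mislink,
    facilities_generated = nrow(ds$facilities),
    facilities_dropped_other_interventions =
      attr(panel, "dropped")$facilities_other_interventions,
    cells_masked_min_denominator =
      attr(panel, "dropped")$cells_below_min_denominator,
    panel_rows = nrow(panel)
  )

  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(estimates, file.path(out_dir, "estimates.csv"),
              row.names = FALSE)
    if (!is.null(balance)) {
      write.csv(balance, file.path(out_dir, "balance.csv"), row.names = FALSE)
    }
    if (!is.null(support)) {
      write.csv(support, file.path(out_dir, "support.csv"), row.names = FALSE)
    }
    write.csv(links, file.path(out_dir, "links.csv"), row.names = FALSE)
    results <- list(
      config = list(seed = cfg$seed, waves = cfg$waves,
                    rollout_waves = cfg$rollout_waves,
                    baseline_wave = baseline, followup_wave = followup,
                    kernel = kernel, bandwidth = bandwidth),
      accounting = accounting,
      estimates = estimates,
      parallel_trends = lapply(diagnostics$parallel_trends, function(x)
        if (is.null(x)) NULL else x[c("estimate", "se", "statistic", "p_value")]),
      placebo = if (is.null(diagnostics$placebo)) NULL else
        diagnostics$placebo[c("statistic", "rejection_rate", "n_reps")]
    )
    jsonlite::write_json(results, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         na = "null")
  }
  stage("done")
  invisible(list(dataset = ds, links = links, panel = panel,
                 estimates = estimates, diagnostics = diagnostics,
                 balance = balance, accounting = accounting))
}
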