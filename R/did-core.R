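#' Construct an effect-estimate record
#'
#' Standard container returned by all three estimators: point estimate
#' and standard error in percentage points, t statistic, p value,
#' sample-size and clustering metadata, and an estimator-specific
#' `details` list.
#'
#' @param outcome outcome name.
#' @param estimator one of `"did_fe"`, `"did_2period"`, `"psm_did"`.
#' @param estimate,se point estimate and standard error (ppts).
#' @param n_obs,n_clusters sample sizes.
#' @param df degrees of freedom for the t reference distribution
#'   (clusters minus one by convention).
#' @param period,covariate_set labels.
#' @param details list of estimator-specific extras.
#' @return object of class `effect_estimate`.
#' @export
effect_estimate <- function(outcome, estimator, estimate, se, n_obs,
                            n_clusters, df = n_clusters - 1L, period = "",
                            covariate_set = "", details = list()) {
  t_stat <- if (is.finite(se) && se > 0) estimate / se else NA_real_
  p_value <- if (is.finite(t_stat)) 2 * pt(-abs(t_stat), df = df) else NA_real_
  structure(list(outcome = outcome, estimator = estimator,
                 estimate = estimate, se = se, t_stat = t_stat,
                 p_value = p_value, n_obs = n_obs, n_clusters = n_clusters,
                 df = df, period = period, covariate_set = covariate_set,
                 details = details),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  stars <- if (is.na(x$p_value)) "" else
    if (x$p_value < 0.01) "***" else if (x$p_value < 0.05) "**" else
      if (x$p_value < 0.1) "*" else ""
  cat(sprintf("<%s> %s [%s]\n", x$estimator, x$outcome, x$period))
  cat(sprintf("  estimate %8.3f ppts (se %.3f)%s  t = %.2f, p = %.4f\n",
              x$estimate, x$se, stars, x$t_stat, x$p_value))
  cat(sprintf("  n = %d observations, %d clusters, %s\n",
              x$n_obs, x$n_clusters, x$covariate_set))
  invisible(x)
}

#' @export
as.data.frame.effect_estimate <- function(x, ...) {
  data.frame(outcome = x$outcome, estimator = x$estimator,
             estimate = x$estimate, se = x$se, t_stat = x$t_stat,
             p_value = x$p_value, n_obs = x$n_obs, n_clusters = x$n_clusters,
             period = x$period, covariate_set = x$covariate_set,
             stringsAsFactors = FALSE)
}

#' Cluster-robust covariance of OLS coefficients
#'
#' Sandwich estimator summing score outer products within clusters,
#' with the small-sample correction `G/(G-1) * (N-1)/(N-K)` (the usual
#' CR1 convention), where `G` is the number of clusters, `N` the number
#' of observations and `K` the number of estimated parameters including
#' any absorbed fixed effects (`n_absorbed`). With singleton clusters it
#' reduces to the HC1 heteroskedasticity-robust covariance.
#'
#' @param X numeric design matrix (full column rank).
#' @param residuals OLS residuals.
#' @param cluster cluster id per row.
#' @param n_absorbed number of parameters absorbed before `X` was formed
#'   (e.g. facility fixed effects swept out by demeaning).
#' @return covariance matrix of the coefficients.
#' @export
cluster_robust_cov <- function(X, residuals, cluster, n_absorbed = 0L) {
  X <- as.matrix(X)
  cluster <- as.character(cluster)
  G <- length(unique(cluster))
  if (G < 2L) stop_invalid("cluster-robust covariance needs >= 2 clusters")
  N <- nrow(X)
  K <- ncol(X) + n_absorbed
  if (N <= K) stop_invalid("more parameters (%d) than observations (%d)", K, N)
  bread <- chol2inv(chol(crossprod(X)))
  scores <- rowsum(X * residuals, cluster)
  meat <- crossprod(scores)
  adj <- (G / (G - 1)) * ((N - 1) / (N - K))
  V <- adj * bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

# 0/1 per facility: accredited at or before `wave` (policy switched on)
treated_as_of <- function(panel, wave) {
  on <- panel$policy == 1L & panel$wave <= wave
  flag <- tapply(on, panel$facility_id, any)
  setNames(as.integer(flag), names(flag))
}

# demean a matrix/vector within groups
demean_by <- function(x, g) {
  x <- as.matrix(x)
  m <- rowsum(x, g) / as.vector(table(g)[sort(unique(as.character(g)))])
  x - m[as.character(g), , drop = FALSE]
}

resolve_outcome_col <- function(panel, outcome) {
  col <- if (outcome %in% names(panel)) outcome else paste0("pct_", outcome)
  if (!col %in% names(panel)) {
    stop_invalid("outcome column '%s' not found in panel", outcome)
  }
  col
}

#' Fixed-effects difference-in-differences on the full panel
#'
#' Estimates `y_it = alpha + beta * policy_it + gamma_t + delta_i + e_it`
#' by the within transformation: outcome, policy and wave dummies are
#' demeaned within facility and the coefficient on `policy` is obtained
#' by OLS on the transformed data — numerically identical to including a
#' dummy per facility. Standard errors are cluster-robust
#' ([cluster_robust_cov()]) at the district level by default, since
#' treatment is assigned at the district level; p values use a t
#' distribution with (clusters - 1) degrees of freedom.
#'
#' @param panel panel from [build_panel()] / [apply_sample_rules()].
#' @param outcome outcome name (or a `pct_*` column name).
#' @param cluster_level `"district"` (default) or `"facility"`.
#' @return an [effect_estimate()]; `details$wave_coefs` holds the wave
#'   dummy coefficients.
#' @export
fit_did_fe <- function(panel, outcome,
                       cluster_level = c("district", "facility")) {
  cluster_level <- match.arg(cluster_level)
  ycol <- resolve_outcome_col(panel, outcome)
  d <- panel[!is.na(panel[[ycol]]), , drop = FALSE]
  if (length(unique(d$wave)) < 2L) {
    stop_invalid("outcome '%s' observed in fewer than two waves", outcome)
  }
  keep <- names(which(table(d$facility_id) >= 2L))
  if (length(keep) < 2L) {
    stop_invalid("fewer than two facilities with repeated observations")
  }
  d <- d[d$facility_id %in% keep, , drop = FALSE]
  waves <- sort(unique(d$wave))
  X <- cbind(policy = d$policy,
             sapply(waves[-1L], function(w) as.numeric(d$wave == w)))
  colnames(X) <- c("policy", paste0("wave", waves[-1L]))
  g <- d$facility_id
  Xd <- demean_by(X, g)
  yd <- demean_by(d[[ycol]], g)[, 1L]
  if (sum(Xd[, "policy"]^2) < 1e-10) {
    stop_invalid("no identifying variation: policy is constant within every facility")
  }
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    drop_cols <- colnames(Xd)[qrX$pivot[(qrX$rank + 1L):ncol(Xd)]]
    if ("policy" %in% drop_cols) {
      stop_invalid("no identifying variation: policy collinear with wave dummies")
    }
    warning(sprintf("dropping collinear column(s): %s",
                    paste(drop_cols, collapse = ", ")), call. = FALSE)
    Xd <- Xd[, setdiff(colnames(Xd), drop_cols), drop = FALSE]
    qrX <- qr(Xd)
  }
  beta <- qr.coef(qrX, yd)
  e <- yd - Xd %*% beta
  cl <- if (cluster_level == "district") d$district_id else d$facility_id
  V <- cluster_robust_cov(Xd, as.vector(e), cl,
                          n_absorbed = length(unique(g)))
  effect_estimate(
    outcome = outcome, estimator = "did_fe",
    estimate = unname(beta["policy"]),
    se = sqrt(V["policy", "policy"]),
    n_obs = nrow(d), n_clusters = length(unique(cl)),
    period = paste(range(waves), collapse = "-"),
    covariate_set = "wave dummies + facility fixed effects",
    details = list(wave_coefs = beta[-1L], vcov = V,
                   cluster_level = cluster_level)
  )
}

#' Two-period covariate-adjusted difference-in-differences
#'
#' Estimates, on facilities observed in both chosen waves,
#' `y_it = alpha + beta * acc_i + gamma * d_post + delta * acc_i x d_post
#' + zeta' fac_i + eta' dist_i + e_it` and returns the interaction
#' coefficient delta. `acc_i` indicates facilities accredited
#' (provisionally or fully) by the follow-up wave — facilities entering
#' the program only later serve as controls for the period pair —
#' and `d_post` the follow-up wave. Facility controls
#' are the eight staff counts, building condition (reference "bad") and
#' catchment population; district controls are the eight indicators plus
#' region dummies (reference "fully-urban"). Collinear covariates are
#' dropped with a warning. Inference is cluster-robust at the district
#' level by default.
#'
#' @param panel panel data.frame.
#' @param baseline_wave,followup_wave the two waves (followup > baseline).
#' @param outcome outcome name.
#' @param facility_covariates,district_covariates include the control
#'   blocks (default TRUE; covariates absent from the panel are skipped).
#' @param cluster_level `"district"` or `"facility"`.
#' @return an [effect_estimate()]; `details$coefficients` holds the full
#'   coefficient vector.
#' @export
fit_did_2period <- function(panel, baseline_wave, followup_wave, outcome,
                            facility_covariates = TRUE,
                            district_covariates = TRUE,
                            cluster_level = c("district", "facility")) {
  cluster_level <- match.arg(cluster_level)
  if (followup_wave <= baseline_wave) {
    stop_invalid("followup_wave must be after baseline_wave")
  }
  if (!all(c(baseline_wave, followup_wave) %in% panel$wave)) {
    stop_invalid("both waves must be present in the panel")
  }
  ycol <- resolve_outcome_col(panel, outcome)
  d <- panel[panel$wave %in% c(baseline_wave, followup_wave) &
               !is.na(panel[[ycol]]), , drop = FALSE]
  both <- names(which(table(d$facility_id) == 2L))
  n_dropped <- length(unique(d$facility_id)) - length(both)
  if (n_dropped > 0) {
    fd_log("fit_did_2period: dropped %d facilities not observed in both waves",
           n_dropped)
  }
  d <- d[d$facility_id %in% both, , drop = FALSE]
  if (length(both) < 4L) {
    stop_invalid("need at least 4 facilities observed in both waves")
  }
  # treated means accredited (provisional or full) by the follow-up wave;
  # facilities accredited only later are controls for this period pair
  acc_flag <- treated_as_of(panel, followup_wave)
  d$acc <- unname(acc_flag[d$facility_id])
  if (length(unique(d$acc)) < 2L) {
    stop_invalid("no identifying variation: all facilities share one treatment status")
  }
  d$d_post <- as.numeric(d$wave == followup_wave)
  terms <- c("acc", "d_post", "acc:d_post")
  covariate_set <- "none"
  if (facility_covariates) {
    fc <- intersect(c(paste0("staff_", staff_categories()),
                      "building_condition", "catchment_population"), names(d))
    if ("building_condition" %in% fc) {
      d$building_condition <- factor(d$building_condition,
                                     levels = c("bad", "average", "good"))
    }
    terms <- c(terms, fc)
    if (length(fc)) covariate_set <- "facility"
  }
  if (district_covariates) {
    dc <- intersect(c(district_indicators(), "region"), names(d))
    if ("region" %in% dc) {
      d$region <- factor(d$region, levels = region_levels())
    }
    terms <- c(terms, dc)
    if (length(dc)) {
      covariate_set <- if (covariate_set == "facility")
        "facility + district" else "district"
    }
  }
  fml <- as.formula(paste0("`", ycol, "` ~ ", paste(terms, collapse = " + ")))
  fit <- lm(fml, data = d)
  cf <- coef(fit)
  if (anyNA(cf)) {
    dropped <- names(cf)[is.na(cf)]
    warning(sprintf("dropping collinear covariate(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  X <- model.matrix(fit)[, !is.na(cf), drop = FALSE]
  cl <- if (cluster_level == "district") d$district_id else d$facility_id
  V <- cluster_robust_cov(X, stats::residuals(fit), cl)
  est_name <- "acc:d_post"
  effect_estimate(
    outcome = outcome, estimator = "did_2period",
    estimate = unname(cf[est_name]),
    se = sqrt(V[est_name, est_name]),
    n_obs = nrow(d), n_clusters = length(unique(cl)),
    period = paste0(baseline_wave, "-", followup_wave),
    covariate_set = covariate_set,
    details = list(coefficients = cf[!is.na(cf)], vcov = V,
                   n_facilities = length(both),
                   n_dropped_unbalanced = n_dropped,
                   cluster_level = cluster_level)
  )
}
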