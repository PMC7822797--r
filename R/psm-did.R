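#' Fit a propensity-score model by IRLS
#'
#' Logistic regression of treatment status on the supplied covariates,
#' fit by iteratively reweighted least squares. Covariates are
#' standardized internally for numerical stability and coefficients
#' reported on the original scale. Convergence is declared when the
#' largest coefficient change falls below `tol` (default 1e-8) within
#' `max_iter` iterations. Perfect separation is detected (fitted
#' probabilities pinned at 0/1 with diverging coefficients) and reported
#' as an error naming the worst covariate.
#'
#' @param covariates data.frame of numeric covariates and/or factors
#'   (typically the eight district indicators, optionally region).
#' @param treatment 0/1 (or logical) treatment labels, one per row.
#' @param ids optional unit identifiers used to name the scores.
#' @param tol,max_iter IRLS convergence controls.
#' @return object of class `propensity_model`: coefficients, their
#'   covariance (inverse Fisher information), scores in (0, 1),
#'   `converged`, `n_iterations`, and the treatment labels.
#' @export
fit_propensity <- function(covariates, treatment, ids = NULL,
                           tol = 1e-8, max_iter = 100L) {
  y <- as.numeric(treatment)
  if (!all(y %in% c(0, 1))) stop_invalid("treatment must be 0/1")
  if (length(unique(y)) < 2L) {
    stop_invalid("treatment has a single class; propensity model unidentified")
  }
  covariates <- as.data.frame(covariates)
  X <- if (ncol(covariates)) model.matrix(~ ., data = covariates) else
    matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  if (nrow(X) != length(y)) stop_invalid("covariates and treatment differ in length")
  if (ncol(X) > 1L) {
    const <- apply(X[, -1L, drop = FALSE], 2L, function(col) sd(col) == 0)
    if (any(const)) {
      warning(sprintf("dropping constant covariate(s): %s",
                      paste(names(const)[const], collapse = ", ")),
              call. = FALSE)
      X <- X[, c(TRUE, !const), drop = FALSE]
    }
  }
  ctr <- colMeans(X); ctr[1L] <- 0
  scl <- apply(X, 2L, sd); scl[1L] <- 1; scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  beta <- rep(0, ncol(Xs))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- as.vector(Xs %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    if (max(abs(beta)) > 30 && (min(mu) < 1e-12 || max(mu) > 1 - 1e-12)) {
      worst <- colnames(X)[-1L][which.max(abs(beta[-1L]))]
      stop_invalid("perfect separation detected (covariate '%s')", worst)
    }
    z <- eta + (y - mu) / pmax(w, 1e-12)
    XtW <- t(Xs * w)
    beta_new <- solve(XtW %*% Xs, XtW %*% z)[, 1L]
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  # back-transform to the original covariate scale
  b <- beta / scl
  b[1L] <- beta[1L] - sum((ctr / scl * beta)[-1L])
  names(b) <- colnames(X)
  eta <- as.vector(X %*% b)
  mu <- plogis(eta)
  info <- crossprod(X * sqrt(mu * (1 - mu)))
  V <- tryCatch(chol2inv(chol(info)), error = function(e) solve(info))
  dimnames(V) <- list(colnames(X), colnames(X))
  scores <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  if (!is.null(ids)) names(scores) <- ids
  structure(list(coefficients = b, vcov = V, se = sqrt(diag(V)),
                 scores = scores, converged = converged,
                 n_iterations = iter, treatment = y),
            class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("<propensity_model> %d units (%d treated), %s in %d iterations\n",
              length(x$scores), sum(x$treatment),
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  print(round(cbind(coef = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' Common-support region of the propensity scores
#'
#' Min-max rule: the support interval is
#' `[max(min treated, min control), min(max treated, max control)]`.
#' Units with scores outside are flagged off-support and excluded from
#' estimation. Also returns binned score counts per group for overlap
#' plots.
#'
#' @param model a converged [fit_propensity()] model.
#' @param n_bins bins for the overlap histogram.
#' @return list with `interval`, logical `on_support` (named like the
#'   scores), exclusion counts, and `histogram` (bin mid, treated count,
#'   control count).
#' @export
common_support <- function(model, n_bins = 25L) {
  stopifnot(inherits(model, "propensity_model"))
  if (!model$converged) stop_invalid("propensity model did not converge")
  s <- model$scores
  tr <- model$treatment == 1
  lo <- max(min(s[tr]), min(s[!tr]))
  hi <- min(max(s[tr]), max(s[!tr]))
  if (lo > hi) {
    stop_invalid("no overlap: treated scores [%.3f, %.3f] vs control [%.3f, %.3f]",
                 min(s[tr]), max(s[tr]), min(s[!tr]), max(s[!tr]))
  }
  on <- s >= lo & s <= hi
  if (any(!on)) {
    fd_log("common_support: excluded %d treated and %d control units off [%.3f, %.3f]",
           sum(!on & tr), sum(!on & !tr), lo, hi)
  }
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  mids <- (head(breaks, -1L) + breaks[-1L]) / 2
  cut_idx <- findInterval(s, breaks, rightmost.closed = TRUE)
  hist_df <- data.frame(
    mid = mids,
    treated = tabulate(cut_idx[tr], nbins = n_bins),
    control = tabulate(cut_idx[!tr], nbins = n_bins)
  )
  list(interval = c(lower = lo, upper = hi), on_support = on,
       n_excluded_treated = sum(!on & tr),
       n_excluded_control = sum(!on & !tr),
       histogram = hist_df)
}

#' Kernel weights of controls matched to one treated unit
#'
#' `w(i, j) = K((p_j - p_i)/h) / sum_k K((p_k - p_i)/h)` with
#' Epanechnikov kernel `K(u) = 0.75 (1 - u^2)` on `|u| < 1` (default) or
#' the Gaussian kernel. If no control receives positive kernel value the
#' treated unit cannot be matched: `NULL` is returned with a warning.
#'
#' @param score_i propensity score of the treated unit.
#' @param control_scores scores of candidate controls (names kept).
#' @param kernel `"epanechnikov"` (bounded support) or `"gaussian"`.
#' @param bandwidth kernel bandwidth `h` on the propensity scale
#'   (default 0.06).
#' @return normalized nonnegative weights summing to 1, or `NULL`.
#' @export
kernel_weights <- function(score_i, control_scores,
                           kernel = c("epanechnikov", "gaussian"),
                           bandwidth = 0.06) {
  kernel <- match.arg(kernel)
  if (bandwidth <= 0) stop_invalid("bandwidth must be > 0")
  u <- (control_scores - score_i) / bandwidth
  k <- switch(kernel,
              epanechnikov = ifelse(abs(u) < 1, 0.75 * (1 - u^2), 0),
              gaussian = dnorm(u))
  tot <- sum(k)
  if (tot <= 0) {
    warning(sprintf("no control within bandwidth of score %.3f; treated unit dropped",
                    score_i), call. = FALSE)
    return(NULL)
  }
  k / tot
}

#' Build the full treated-to-control weight map
#'
#' Applies [kernel_weights()] to every treated unit on common support,
#' matching against controls on support. Treated units with no control
#' inside the kernel window are dropped (logged).
#'
#' @param model a [fit_propensity()] model with named scores.
#' @param support result of [common_support()] (computed if omitted).
#' @inheritParams kernel_weights
#' @return object of class `match_weights`: `weights` (list, one named
#'   weight vector per retained treated id), `support`, `dropped_treated`,
#'   `control_ids`, plus kernel metadata.
#' @export
match_weights <- function(model, support = common_support(model),
                          kernel = c("epanechnikov", "gaussian"),
                          bandwidth = 0.06) {
  kernel <- match.arg(kernel)
  s <- model$scores
  if (is.null(names(s))) names(s) <- as.character(seq_along(s))
  tr <- model$treatment == 1
  on <- support$on_support
  t_ids <- names(s)[tr & on]
  c_ids <- names(s)[!tr & on]
  if (!length(t_ids)) stop_invalid("no treated units on common support")
  if (!length(c_ids)) stop_invalid("no control units on common support")
  w_list <- list()
  dropped <- character()
  for (i in t_ids) {
    w <- suppressWarnings(
      kernel_weights(s[[i]], s[c_ids], kernel = kernel, bandwidth = bandwidth))
    if (is.null(w)) dropped <- c(dropped, i) else w_list[[i]] <- w
  }
  if (length(dropped)) {
    fd_log("match_weights: dropped %d treated unit(s) with no control within bandwidth",
           length(dropped))
  }
  if (!length(w_list)) stop_invalid("every treated unit is unmatched at bandwidth %.3f",
                                    bandwidth)
  structure(list(weights = w_list, support = support,
                 dropped_treated = dropped, control_ids = c_ids,
                 kernel = kernel, bandwidth = bandwidth),
            class = "match_weights")
}

#' Kernel PSM difference-in-differences estimate
#'
#' For each matched treated facility i,
#' `delta_i = (y_i,post - y_i,pre) - sum_j w(i,j) (y_j,post - y_j,pre)`;
#' the overall estimate averages `delta_i` over treated facilities on
#' support, either with equal weight (default) or weighted by catchment
#' population. Facilities missing either period are dropped with a
#' logged count; weights over the surviving controls are renormalized.
#' The standard error is left `NA` here — use [bootstrap_se()], which
#' re-runs the matching inside each resample.
#'
#' @param panel panel data.frame containing both waves.
#' @param pre_wave,post_wave the two waves.
#' @param outcome outcome name.
#' @param weights a [match_weights()] object built on the same facility
#'   ids.
#' @param treated_aggregation `"equal"` or `"catchment_population"`.
#' @return an [effect_estimate()]; `details$delta_i` has the
#'   per-treated-facility contributions.
#' @export
psm_did_estimate <- function(panel, pre_wave, post_wave, outcome, weights,
                             treated_aggregation = c("equal",
                                                     "catchment_population")) {
  stopifnot(inherits(weights, "match_weights"))
  treated_aggregation <- match.arg(treated_aggregation)
  ycol <- resolve_outcome_col(panel, outcome)
  pre <- panel[panel$wave == pre_wave, c("facility_id", ycol)]
  post <- panel[panel$wave == post_wave, c("facility_id", ycol)]
  ch <- merge(pre, post, by = "facility_id", suffixes = c("_pre", "_post"))
  ch <- ch[complete.cases(ch), , drop = FALSE]
  changes <- setNames(ch[[paste0(ycol, "_post")]] - ch[[paste0(ycol, "_pre")]],
                      ch$facility_id)
  delta_i <- c()
  n_dropped <- 0L
  used_controls <- character()
  for (i in names(weights$weights)) {
    if (!i %in% names(changes)) { n_dropped <- n_dropped + 1L; next }
    w <- weights$weights[[i]]
    w <- w[names(w) %in% names(changes)]
    if (!length(w) || sum(w) <= 0) { n_dropped <- n_dropped + 1L; next }
    w <- w / sum(w)
    used_controls <- union(used_controls, names(w)[w > 0])
    delta_i[i] <- changes[[i]] - sum(w * changes[names(w)])
  }
  if (n_dropped > 0) {
    fd_log("psm_did_estimate: dropped %d treated facilities missing a period or all matched controls",
           n_dropped)
  }
  if (!length(delta_i)) {
    stop_invalid("no treated facility on support with both periods observed")
  }
  est <- if (treated_aggregation == "equal") {
    mean(delta_i)
  } else {
    pop <- panel$catchment_population[match(names(delta_i), panel$facility_id)]
    weighted.mean(delta_i, pop)
  }
  effect_estimate(
    outcome = outcome, estimator = "psm_did",
    estimate = est, se = NA_real_,
    n_obs = 2L * (length(delta_i) + length(used_controls)),
    n_clusters = length(delta_i) + length(used_controls),
    period = paste0(pre_wave, "-", post_wave),
    covariate_set = sprintf("%s kernel, h = %g", weights$kernel,
                            weights$bandwidth),
    details = list(delta_i = delta_i, n_treated = length(delta_i),
                   n_controls = length(used_controls),
                   n_dropped = n_dropped,
                   treated_aggregation = treated_aggregation)
  )
}

#' One-call kernel PSM-DiD on a panel
#'
#' Convenience wrapper chaining [fit_propensity()] (on the facility-level
#' district indicators taken from the pre-period rows),
#' [common_support()], [match_weights()] and [psm_did_estimate()].
#'
#' @inheritParams psm_did_estimate
#' @param covariate_cols covariate columns for the propensity model.
#'   Default: the eight district indicators. Pass
#'   `c(district_indicators(), "region")` to add region dummies; because
#'   treatment is assigned at the district level the effective sample is
#'   the number of districts, and the extra dummies make perfect
#'   separation likely unless the district count is large.
#' @inheritParams kernel_weights
#' @return an [effect_estimate()]; `details$propensity` and
#'   `details$support` expose the intermediate objects.
#' @export
psm_did <- function(panel, pre_wave, post_wave, outcome,
                    covariate_cols = NULL,
                    kernel = c("epanechnikov", "gaussian"),
                    bandwidth = 0.06,
                    treated_aggregation = c("equal", "catchment_population")) {
  kernel <- match.arg(kernel)
  pre <- panel[panel$wave == pre_wave, , drop = FALSE]
  if (!nrow(pre)) stop_invalid("pre_wave %s not present in panel", pre_wave)
  if (is.null(covariate_cols)) {
    covariate_cols <- intersect(district_indicators(), names(pre))
  }
  if (!length(covariate_cols)) stop_invalid("no propensity covariates found")
  covs <- pre[, covariate_cols, drop = FALSE]
  if ("region" %in% names(covs)) {
    covs$region <- factor(covs$region, levels = region_levels())
    covs$region <- droplevels(covs$region)
    if (nlevels(covs$region) < 2L) covs$region <- NULL
  }
  # treated = accredited by the post wave; later entrants are controls here
  acc_flag <- treated_as_of(panel, post_wave)
  model <- fit_propensity(covs, unname(acc_flag[pre$facility_id]),
                          ids = pre$facility_id)
  support <- common_support(model)
  mw <- match_weights(model, support, kernel = kernel, bandwidth = bandwidth)
  est <- psm_did_estimate(panel, pre_wave, post_wave, outcome, mw,
                          treated_aggregation = treated_aggregation)
  est$details$propensity <- model
  est$details$support <- support
  est
}

#' Cluster bootstrap for a matched (or any) panel estimator
#'
#' Resamples clusters (districts by default, matching the treatment
#' assignment level) with replacement, re-runs the entire supplied
#' pipeline — propensity fit, support, weights, estimate — on each
#' resample, and returns the bootstrap standard deviation and 2.5/97.5
#' percentile interval. Resampled clusters keep their rows; duplicated
#' clusters receive fresh pseudo-ids so facilities are not merged.
#' Draws that fail (e.g. no overlap after resampling) are skipped; a
#' failure rate above 20% is an error.
#'
#' @param pipeline function(panel) returning a numeric estimate (e.g.
#'   `function(p) psm_did(p, 2000, 2005, "anc_4visits")$estimate`).
#' @param panel panel data.frame with the cluster column.
#' @param n_boot number of bootstrap draws (>= 50).
#' @param seed integer seed.
#' @param cluster_col column defining resampling clusters.
#' @return list: `se`, `ci` (percentile 95%), `estimates` (successful
#'   draws), `n_failed`.
#' @export
bootstrap_se <- function(pipeline, panel, n_boot = 199L, seed = 1L,
                         cluster_col = "district_id") {
  if (n_boot < 50L) stop_invalid("n_boot must be >= 50")
  assert_cols(panel, cluster_col, "panel")
  ids <- unique(panel[[cluster_col]])
  rows_of <- split(seq_len(nrow(panel)), panel[[cluster_col]])
  ests <- rep(NA_real_, n_boot)
  with_stage_seed(seed, "bootstrap", {
    for (b in seq_len(n_boot)) {
      take <- sample(ids, length(ids), replace = TRUE)
      parts <- lapply(seq_along(take), function(k) {
        block <- panel[rows_of[[as.character(take[k])]], , drop = FALSE]
        # pseudo-ids: a district drawn twice contributes two distinct copies
        block[[cluster_col]] <- paste0(block[[cluster_col]], "*", k)
        block$facility_id <- paste0(block$facility_id, "*", k)
        block
      })
      bp <- do.call(rbind, parts)
      ests[b] <- tryCatch(suppressMessages(pipeline(bp)),
                          error = function(e) NA_real_)
    }
  })
  n_failed <- sum(is.na(ests))
  if (n_failed > 0.2 * n_boot) {
    stop_invalid("bootstrap failure rate %.1f%% exceeds 20%% (%d of %d draws)",
                 100 * n_failed / n_boot, n_failed, n_boot)
  }
  ok <- ests[!is.na(ests)]
  list(se = sd(ok),
       ci = quantile(ok, c(0.025, 0.975), names = FALSE),
       estimates = ok, n_failed = n_failed)
}

#' Covariate balance before and after matching
#'
#' For every covariate: raw treated and control means; the
#' kernel-weighted control mean (each control weighted by its total
#' weight across matched treated units); two-sample t statistics and p
#' values before matching (Welch) and after matching (Welch on the
#' weighted control sample via its effective sample size); and
#' standardized mean differences before and after, both scaled by the
#' pre-matching pooled standard deviation. A zero-variance covariate
#' reports SMD 0 with a warning.
#'
#' @param covariates data.frame of numeric covariates, rows aligned with
#'   `treatment`.
#' @param treatment 0/1 labels.
#' @param weights a [match_weights()] object whose ids index
#'   `covariates` rows (via `ids` supplied to [fit_propensity()]).
#' @param ids unit ids aligning covariate rows with the weight map.
#' @return data.frame, one row per covariate.
#' @export
balance_tests <- function(covariates, treatment, weights, ids) {
  stopifnot(inherits(weights, "match_weights"))
  tr <- treatment == 1
  t_ids <- names(weights$weights)
  cw <- setNames(rep(0, length(weights$control_ids)), weights$control_ids)
  for (w in weights$weights) cw[names(w)] <- cw[names(w)] + w
  cw <- cw / length(weights$weights)
  rows <- lapply(names(covariates), function(v) {
    x <- covariates[[v]]
    if (!is.numeric(x)) return(NULL)
    xt <- x[tr]; xc <- x[!tr]
    sd_pool <- sqrt((var(xt) + var(xc)) / 2)
    if (!is.finite(sd_pool) || sd_pool == 0) {
      warning(sprintf("covariate '%s' has zero variance; SMD set to 0", v),
              call. = FALSE)
      sd_pool <- Inf
    }
    tt_before <- tryCatch(t.test(xt, xc), error = function(e) NULL)
    xt_m <- x[match(t_ids, ids)]
    xc_w <- x[match(names(cw), ids)]
    mean_c_matched <- sum(cw * xc_w) / sum(cw)
    # effective control sample size under the aggregated kernel weights
    n_eff <- sum(cw)^2 / sum(cw^2)
    var_c_w <- sum(cw * (xc_w - mean_c_matched)^2) / sum(cw)
    se_after <- sqrt(var(xt_m) / length(xt_m) + var_c_w / n_eff)
    t_after <- if (is.finite(se_after) && se_after > 0) {
      (mean(xt_m) - mean_c_matched) / se_after
    } else 0
    df_after <- max(2, length(xt_m) + n_eff - 2)
    data.frame(
      covariate = v,
      mean_treated = mean(xt), mean_control = mean(xc),
      mean_control_matched = mean_c_matched,
      t_before = if (is.null(tt_before)) 0 else unname(tt_before$statistic),
      p_before = if (is.null(tt_before)) 1 else tt_before$p.value,
      t_after = t_after,
      p_after = 2 * pt(-abs(t_after), df = df_after),
      smd_before = (mean(xt) - mean(xc)) / sd_pool,
      smd_after = (mean(xt_m) - mean_c_matched) / sd_pool,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
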