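test_that("intercept-only propensity model returns the treated fraction", {
  y <- rep(c(1, 0), c(12, 28))
  m <- fit_propensity(data.frame(row.names = seq_along(y)), y)
  expect_true(m$converged)
  expect_equal(unname(m$scores), rep(0.3, 40), tolerance = 1e-10)
})

test_that("propensity IRLS matches glm and recovers known coefficients", {
  withr::with_seed(50, {
    n <- 5000
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x1 - 0.5 * x2))
  })
  covs <- data.frame(x1 = x1, x2 = x2)
  m <- fit_propensity(covs, y)
  ref <- glm(y ~ x1 + x2, family = binomial())
  expect_equal(unname(m$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(m$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
  expect_lt(abs(m$coefficients[["x1"]] - 0.8), 3 * m$se[["x1"]])
  expect_lt(abs(m$coefficients[["x2"]] - (-0.5)), 3 * m$se[["x2"]])
  expect_true(all(m$scores > 0 & m$scores < 1))
})

test_that("null covariates yield null slopes; degenerate inputs error clearly", {
  withr::with_seed(51, {
    n <- 2000
    covs <- data.frame(a = rnorm(n), b = runif(n))
    y <- rbinom(n, 1, 0.4)
  })
  m <- fit_propensity(covs, y)
  expect_lt(abs(m$coefficients[["a"]]), 3 * m$se[["a"]])
  expect_lt(abs(m$coefficients[["b"]]), 3 * m$se[["b"]])

  expect_error(fit_propensity(covs, rep(1, n)), "single class")
  sep <- data.frame(x = c(rnorm(30, -3), rnorm(30, 3)))
  expect_error(fit_propensity(sep, rep(c(0, 1), each = 30)), "separation")
  expect_warning(fit_propensity(data.frame(c0 = rep(1, n), a = covs$a), y),
                 "constant")
})

test_that("common support follows the min-max rule", {
  m_same <- hand_pmodel(c(0.2, 0.4, 0.6, 0.2, 0.4, 0.6),
                        c(1, 1, 1, 0, 0, 0),
                        ids = sprintf("F%d", 1:6))
  cs <- common_support(m_same)
  expect_true(all(cs$on_support))

  m_fix <- hand_pmodel(c(0.3, 0.5, 0.9, 0.1, 0.4, 0.6),
                       c(1, 1, 1, 0, 0, 0), ids = sprintf("F%d", 1:6))
  cs2 <- suppressMessages(common_support(m_fix))
  expect_equal(unname(cs2$interval), c(0.3, 0.6))
  expect_identical(unname(which(!cs2$on_support)), c(3L, 4L))

  m_disj <- hand_pmodel(c(0.7, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_error(common_support(m_disj), "no overlap")
})

test_that("kernel weights match hand arithmetic and normalize exactly", {
  w <- kernel_weights(0.5, c(a = 0.48, b = 0.55, c = 0.90), bandwidth = 0.06)
  # K(-1/3) = 2/3, K(5/6) = 11/48, K(20/3) = 0 -> weights 32/43, 11/43, 0
  expect_equal(unname(w), c(32 / 43, 11 / 43, 0), tolerance = 1e-12)

  w_eq <- kernel_weights(0.4, rep(0.4, 5))
  expect_equal(unname(w_eq), rep(0.2, 5))
  w_one <- kernel_weights(0.4, c(far = 0.9, near = 0.42), bandwidth = 0.05)
  expect_equal(unname(w_one), c(0, 1))
  expect_warning(w_none <- kernel_weights(0.1, c(0.9, 0.95), bandwidth = 0.05),
                 "dropped")
  expect_null(w_none)
  expect_error(kernel_weights(0.5, 0.4, bandwidth = 0), "bandwidth")
})

test_that("weights are nonnegative and sum to one across random configurations", {
  withr::with_seed(60, {
    for (r in 1:25) {
      n_t <- sample(3:10, 1); n_c <- sample(5:30, 1)
      scores <- c(runif(n_t, 0.2, 0.8), runif(n_c, 0.1, 0.9))
      ids <- sprintf("U%02d", seq_along(scores))
      m <- hand_pmodel(scores, rep(c(1, 0), c(n_t, n_c)), ids)
      bw <- runif(1, 0.05, 0.4)
      kern <- sample(c("epanechnikov", "gaussian"), 1)
      mw <- tryCatch(
        suppressMessages(match_weights(m, kernel = kern, bandwidth = bw)),
        error = function(e) NULL)
      if (is.null(mw)) next
      for (w in mw$weights) {
        expect_true(all(w >= 0))
        expect_lt(abs(sum(w) - 1), 1e-12)
      }
    }
  })
})

test_that("widening the bandwidth never loses matched treated units", {
  withr::with_seed(61, {
    scores <- c(runif(8, 0.15, 0.85), runif(20, 0.1, 0.9))
    m <- hand_pmodel(scores, rep(c(1, 0), c(8, 20)),
                     sprintf("U%02d", 1:28))
  })
  kept <- sapply(c(0.02, 0.05, 0.1, 0.2, 0.4), function(bw) {
    mw <- tryCatch(suppressMessages(suppressWarnings(
      match_weights(m, bandwidth = bw))), error = function(e) NULL)
    if (is.null(mw)) 0L else length(mw$weights)
  })
  expect_true(all(diff(kept) >= 0))
})

test_that("the six-facility fixture reproduces the hand-computed kernel DiD", {
  # dyadic scores so every kernel evaluation is exact in binary floating
  # point; expected values are hand-derived rationals:
  #   T1 (1/4):  weights (16/23, 7/23, 0),   delta = 20 - 150/23 = 310/23
  #   T2 (3/8):  weights (4/13, 5/13, 4/13), delta = 15 -  82/13 = 113/13
  #   T3 (1/2):  weights (0, 15/31, 16/31),  delta = 25 - 198/31 = 577/31
  ids <- c("T1", "T2", "T3", "C1", "C2", "C3")
  m <- hand_pmodel(c(1 / 4, 3 / 8, 1 / 2, 1 / 4, 7 / 16, 1 / 2),
                   c(1, 1, 1, 0, 0, 0), ids)
  cs <- common_support(m)
  expect_true(all(cs$on_support))
  mw <- match_weights(m, cs, bandwidth = 1 / 4)
  panel <- data.frame(
    facility_id = rep(ids, 2),
    wave = rep(c(2000L, 2005L), each = 6),
    district_id = rep(paste0("D", 1:6), 2),
    pct_anc_4visits = c(40, 50, 30, 50, 40, 60,
                        60, 65, 55, 55, 50, 63),
    stringsAsFactors = FALSE
  )
  est <- psm_did_estimate(panel, 2000, 2005, "anc_4visits", mw)
  expect_equal(unname(est$details$delta_i),
               c(310 / 23, 113 / 13, 577 / 31), tolerance = 1e-14)
  expect_equal(est$estimate, 378022 / 27807, tolerance = 1e-14)
})

test_that("identical outcome changes give a zero estimate", {
  ids <- c("T1", "T2", "C1", "C2", "C3")
  m <- hand_pmodel(c(0.4, 0.5, 0.35, 0.45, 0.55), c(1, 1, 0, 0, 0), ids)
  mw <- suppressMessages(match_weights(m, bandwidth = 0.4))
  panel <- data.frame(facility_id = rep(ids, 2),
                      wave = rep(c(2000L, 2005L), each = 5),
                      pct_anc_4visits = c(rep(40, 5), rep(47, 5)))
  est <- psm_did_estimate(panel, 2000, 2005, "anc_4visits", mw)
  expect_equal(est$estimate, 0, tolerance = 1e-12)
})

test_that("identical covariates reduce kernel PSM-DiD to the plain DiD", {
  withr::with_seed(70, {
    nt <- 6; nc <- 9
    pre_t <- 40 + rnorm(nt, 0, 6); post_t <- 52 + rnorm(nt, 0, 6)
    pre_c <- 45 + rnorm(nc, 0, 6); post_c <- 48 + rnorm(nc, 0, 6)
  })
  p <- hand_panel(pre_t, post_t, pre_c, post_c)
  for (col in district_indicators()) p[[col]] <- 0.5
  est <- suppressWarnings(psm_did(p, 2000, 2005, "anc_4visits"))
  plain <- (mean(post_t) - mean(pre_t)) - (mean(post_c) - mean(pre_c))
  expect_equal(est$estimate, plain, tolerance = 1e-10)
})

test_that("bootstrap inference is reproducible, stable, and flags degenerate data", {
  cfg <- truth_config(effect_ppts = 8, n_districts = 60,
                      facilities_per_district = 4,
                      women_per_facility_per_wave = 25,
                      waves = c(1995L, 2005L), rollout_waves = 2005L,
                      seed = 71)
  p <- fast_panel(cfg)
  # a parsimonious propensity set: cluster resampling roughly halves the
  # number of distinct district covariate rows, so the full eight-indicator
  # model would frequently separate inside bootstrap draws
  pcovs <- c("illiteracy_ratio", "unemployment_ratio", "crowding_factor")
  pipe <- function(pp) suppressWarnings(
    psm_did(pp, 1995, 2005, "anc_4visits", covariate_cols = pcovs)$estimate)
  b1 <- bootstrap_se(pipe, p, n_boot = 99, seed = 5)
  b2 <- bootstrap_se(pipe, p, n_boot = 99, seed = 5)
  expect_identical(b1$ci, b2$ci)
  expect_gt(b1$se, 0)
  b3 <- bootstrap_se(pipe, p, n_boot = 199, seed = 5)
  expect_lt(abs(b1$se - b3$se) / b3$se, 0.25)
  expect_error(bootstrap_se(pipe, p, n_boot = 10), "n_boot")

  # zero-variance changes: every facility shifts by the same amount
  ids <- c("T1", "T2", "C1", "C2", "C3", "C4")
  flat <- data.frame(facility_id = rep(ids, 2),
                     wave = rep(c(2000L, 2005L), each = 6),
                     district_id = rep(paste0("D", 1:6), 2),
                     ever_treated = rep(c(1L, 1L, 0L, 0L, 0L, 0L), 2),
                     policy = c(rep(0L, 6), 1L, 1L, 0L, 0L, 0L, 0L),
                     pct_anc_4visits = c(rep(40, 6), rep(45, 6)))
  for (col in district_indicators()) flat[[col]] <- 0.5
  flat_pipe <- function(pp) suppressWarnings(
    psm_did(pp, 2000, 2005, "anc_4visits")$estimate)
  bf <- bootstrap_se(flat_pipe, flat, n_boot = 60, seed = 9)
  expect_equal(bf$se, 0, tolerance = 1e-12)
})

test_that("balance diagnostics behave on identical, confounded, and degenerate inputs", {
  # identical groups: all t ~ 0, SMD ~ 0
  withr::with_seed(80, x <- rnorm(20))
  covs <- data.frame(x = c(x, x))
  ids <- sprintf("U%02d", 1:40)
  m <- hand_pmodel(rep(0.5, 40), rep(c(1, 0), each = 20), ids)
  mw <- match_weights(m, bandwidth = 0.2)
  bal <- balance_tests(covs, rep(c(1, 0), each = 20), mw, ids)
  expect_lt(abs(bal$t_before), 1e-8)
  expect_equal(bal$smd_before, 0, tolerance = 1e-12)
  expect_equal(bal$smd_after, 0, tolerance = 1e-12)

  # zero-variance covariate: warning, SMD 0, no NaN
  covs2 <- data.frame(x = c(x, x), z = 1)
  expect_warning(bal2 <- balance_tests(covs2, rep(c(1, 0), each = 20), mw, ids),
                 "zero variance")
  expect_equal(bal2$smd_before[bal2$covariate == "z"], 0)

  # confounded assignment: matching shrinks the mean |SMD|
  improved <- sapply(1:100, function(r) {
    withr::local_seed(7000 + r)
    n <- 90
    u <- rnorm(n)
    covs <- data.frame(v1 = u + rnorm(n, 0, 0.5), v2 = -u + rnorm(n, 0, 0.5))
    tr <- rbinom(n, 1, plogis(1.2 * u))
    if (sum(tr) < 5 || sum(1 - tr) < 10) return(NA)
    ids <- sprintf("U%03d", 1:n)
    pm <- fit_propensity(covs, tr, ids = ids)
    mw <- tryCatch(suppressMessages(suppressWarnings(
      match_weights(pm, bandwidth = 0.1))), error = function(e) NULL)
    if (is.null(mw)) return(NA)
    bal <- balance_tests(covs, tr, mw, ids)
    mean(abs(bal$smd_before)) - mean(abs(bal$smd_after))
  })
  expect_gt(mean(improved, na.rm = TRUE), 0)
})
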