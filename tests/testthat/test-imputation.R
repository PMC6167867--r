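test_that("imputation reproduces the censoring structure of both strata", {
  coh <- toy_cohort()
  set.seed(1)
  imp <- impute_uniform(coh)
  # an IE subject appears in the pre-IE data censored exactly at W
  z1 <- coh$Z == 1
  expect_equal(imp$T0_data$time[z1], coh$W[z1])
  expect_true(all(imp$T0_data$delta[z1] == 0))
  # censored IE subjects enter the post-IE data at L, censored, truncated at W
  i <- which(coh$Z == 1 & coh$delta == 0)        # subject 6
  j <- match(i, which(z1))
  expect_equal(imp$T1_data$time[j], coh$L[i])
  expect_equal(imp$T1_data$delta[j], 0)
  expect_equal(imp$T1_data$W[j], coh$W[i])
  # censored non-IE subjects are censored at L in the pre-IE data
  k <- which(coh$Z == 0 & coh$delta == 0)
  expect_equal(imp$T0_data$time[k], coh$L[k])
})

test_that("imputed event times respect interval and truncation constraints", {
  cfg <- scenario_config(theta_A = 0.5, theta_B = 0.3, m1_A = 2, m1_B = 1,
                         c_p = 0.3, n_per_group = 120)
  set.seed(17)
  coh <- generate_cohort(cfg)
  cands <- build_candidate_sets(coh)
  for (weighted in c(FALSE, TRUE)) {
    set.seed(18)
    w <- if (weighted)
      list(est0 = stratum_npmle(coh, 0L), est1 = stratum_npmle(coh, 1L))
    draws <- icie:::draw_imputations_(coh, cands, M = 5L,
                                      weights = if (weighted) w)
    L <- coh$L[draws$rows]; R <- coh$R[draws$rows]
    W <- coh$W[draws$rows]; Z <- coh$Z[draws$rows]
    for (r in 1:5) {
      expect_true(all(draws$times[, r] > L & draws$times[, r] <= R))
      expect_true(all(draws$times[Z == 1, r] > W[Z == 1]))
    }
  }
})

test_that("uniform imputation draws each candidate equally often", {
  coh <- data.frame(id = 1:4, group = c("A", "B", "A", "B"),
                    L = c(0.5, 1.0, 1.5, 2.0), R = c(2.0, 1.5, 2.0, Inf),
                    delta = c(1, 1, 1, 0), Z = 0L, W = NA_real_)
  cands <- build_candidate_sets(coh)
  # subject 1 candidates: points in (0.5, 2] = {1, 1.5, 2}
  set.seed(4)
  M <- 1e4
  draws <- icie:::draw_imputations_(coh, cands, M = M)
  f <- table(factor(draws$times[1, ], levels = c(1, 1.5, 2))) / M
  se <- sqrt((1 / 3) * (2 / 3) / M)
  expect_true(all(abs(f - 1 / 3) < 3 * se))
})

test_that("a flat NPMLE makes the weighted draw uniform", {
  est <- turnbull_npmle(L = c(1, 1.5, 2), R = c(1, 1.5, 2))  # equal atoms
  cm <- conditional_mass(est, 0.5, 2)
  expect_equal(cm$prob, rep(1 / 3, 3))
  # an NPMLE point mass inside the interval imputes deterministically
  est2 <- list(points = c(1, 2), mass = c(0, 1))
  class(est2) <- "icie_npmle"
  cm2 <- conditional_mass(est2, 0.5, 2.5)
  expect_equal(sample(cm2$points, 5, replace = TRUE, prob = cm2$prob),
               rep(2, 5))
})

test_that("weighted NPMLE draw frequencies follow the renormalised mass", {
  est <- list(points = c(1, 2, 3), mass = c(0.2, 0.3, 0.5))
  class(est) <- "icie_npmle"
  cm <- conditional_mass(est, 0, 2)
  set.seed(8)
  M <- 1e4
  draws <- sample(cm$points, M, replace = TRUE, prob = cm$prob)
  expect_lt(abs(mean(draws == 1) - 0.4), 3 * sqrt(0.4 * 0.6 / M))
  expect_lt(abs(mean(draws == 2) - 0.6), 3 * sqrt(0.4 * 0.6 / M))
})

test_that("Rubin pooling follows the printed variance combinations", {
  # identical replicates: no between-imputation spread
  p <- list(S0 = 2, V0 = 1, S1 = 0.5, V1 = 2)
  pooled <- pool_rubin(list(p, p, p))
  expect_equal(pooled$between0, 0)
  expect_equal(pooled$V1_0, 1)
  expect_equal(pooled$V2_0, 1)
  expect_equal(pooled$chi2_add, 2^2 / 1 + 0.5^2 / 2)
  # replicate scores (1, 2, 3) with unit within-variance
  ps <- lapply(c(1, 2, 3), function(s) list(S0 = s, V0 = 1, S1 = 0, V1 = 1))
  pooled2 <- pool_rubin(ps)
  expect_equal(pooled2$S_bar_0, 2)
  expect_equal(pooled2$between0, 1)
  expect_equal(pooled2$V1_0, 1 + (1 + 1 / 3) * 1)
  # subtractive variance 1 - 1 = 0: the guard replaces it by the additive form
  expect_true(pooled2$v2_fallback[1])
  expect_equal(pooled2$V2_0, pooled2$V1_0)
  expect_warning(pool_rubin(list(p)), "M = 1")
})

test_that("the variance-form identity V1 - V2 = (2 + 1/M) B holds", {
  set.seed(12)
  for (rep in 1:10) {
    M <- sample(3:15, 1)
    ps <- lapply(seq_len(M), function(r)
      list(S0 = rnorm(1), V0 = 5 + runif(1), S1 = rnorm(1), V1 = 5 + runif(1)))
    pooled <- pool_rubin(ps)
    if (!any(pooled$v2_fallback)) {
      expect_equal(pooled$V1_0 - pooled$V2_0, (2 + 1 / M) * pooled$between0)
      expect_equal(pooled$V1_1 - pooled$V2_1, (2 + 1 / M) * pooled$between1)
      # chi2_sub >= chi2_add since V2 <= V1
      expect_gte(pooled$chi2_sub, pooled$chi2_add)
    }
  }
})

test_that("with exact intervals the MI test reduces to the direct score test", {
  set.seed(21)
  lat <- generate_latent(80, theta = 0.5, lambda0 = 1, m1 = 2, c_p = 0.2)
  t_obs <- ifelse(lat$delta == 1, lat$T_true, lat$T_true * 0.8)
  t_obs <- pmax(t_obs, ifelse(lat$Z == 1, lat$W, 0)) + 1e-9
  coh <- data.frame(id = 1:80, group = rep(c("A", "B"), 40),
                    L = t_obs, R = ifelse(lat$delta == 1, t_obs, Inf),
                    delta = lat$delta, Z = lat$Z, W = lat$W)
  direct <- nam_zelen_score(data.frame(time = t_obs, delta = lat$delta,
                                       Z = lat$Z, W = lat$W,
                                       x = as.integer(coh$group == "A")))
  for (m in c("uniform", "weighted")) {
    mt <- mi_test(coh, method = m, M = 3L)
    expect_equal(mt$S_bar_0, direct$S0)
    expect_equal(mt$S_bar_1, direct$S1)
    expect_equal(mt$between0, 0)
    expect_equal(mt$V1_0, direct$V0)
    expect_equal(mt$V2_0, direct$V0)
    expect_equal(mt$chi2_add, chi2_tests(pair = direct)$chi2)
  }
})

test_that("M = 1 gives a defined result with zero between-variance", {
  coh <- toy_cohort()
  set.seed(3)
  expect_warning(mt <- mi_test(coh, method = "uniform", M = 1L), "M = 1")
  expect_equal(mt$between0, 0)
  expect_equal(mt$V1_0, mt$within0)
  expect_false(is.na(mt$p_add))
})
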