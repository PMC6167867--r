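test_that("score statistics match the brute-force oracle on toys", {
  # 4 subjects, no IE: hand-enumerable sum over the four event times
  d <- data.frame(time = c(1, 2, 3, 4), delta = 1, Z = 0L, W = NA_real_,
                  x = c(1, 0, 1, 0))
  sc <- nam_zelen_score(d)
  expect_equal(sc$S0, 1 - 1 / 2 + 0 - 1 / 3 + 1 - 1 / 2 + 0 - 0)
  expect_equal(sc$V0, 1 / 4 + 2 / 9 + 1 / 4 + 0)
  expect_equal(sc$S1, 0)
  expect_equal(sc$V1, 0)
  orc <- oracle_nz_score(d$time, d$delta, d$Z, d$W, d$x)
  expect_equal(sc[c("S0", "V0", "S1", "V1")], orc)

  # mixed-strata toy with events on both sides of the IE
  d2 <- data.frame(time = c(0.8, 1.5, 2.0, 2.5, 1.2, 3.0, 0.6, 2.2),
                   delta = c(1, 1, 1, 0, 1, 1, 1, 0),
                   Z = c(0, 1, 1, 0, 0, 1, 0, 1),
                   W = c(NA, 0.5, 1.0, NA, NA, 1.1, NA, 0.9),
                   x = c(1, 1, 0, 1, 0, 0, 0, 1))
  sc2 <- nam_zelen_score(d2)
  orc2 <- oracle_nz_score(d2$time, d2$delta, d2$Z, d2$W, d2$x)
  expect_equal(sc2[c("S0", "V0", "S1", "V1")], orc2)
})

test_that("implementation agrees with the oracle on random complete data", {
  set.seed(55)
  for (rep in 1:8) {
    lat <- generate_latent(40, theta = 0.5, lambda0 = 1, m1 = 2, c_p = 0.3)
    x <- rbinom(40, 1, 0.5)
    sc <- nam_zelen_score(data.frame(time = lat$T_true, delta = lat$delta,
                                     Z = lat$Z, W = lat$W, x = x))
    orc <- oracle_nz_score(lat$T_true, lat$delta, lat$Z, lat$W, x)
    expect_equal(sc[c("S0", "V0", "S1", "V1")], orc)
  }
})

test_that("swapping group labels negates scores and preserves variances", {
  set.seed(66)
  lat <- generate_latent(60, theta = 0.4, lambda0 = 1, m1 = 1.5, c_p = 0.2)
  x <- rbinom(60, 1, 0.5)
  a <- nam_zelen_score(data.frame(time = lat$T_true, delta = lat$delta,
                                  Z = lat$Z, W = lat$W, x = x))
  b <- nam_zelen_score(data.frame(time = lat$T_true, delta = lat$delta,
                                  Z = lat$Z, W = lat$W, x = 1 - x))
  expect_equal(a$S0, -b$S0)
  expect_equal(a$S1, -b$S1)
  expect_equal(a$V0, b$V0)
  expect_equal(a$V1, b$V1)
})

test_that("degenerate configurations are handled", {
  # single group: shares are identically 1, scores and variances vanish
  d <- data.frame(time = 1:4, delta = 1, Z = 0L, W = NA_real_, x = 1)
  sc <- nam_zelen_score(d)
  expect_equal(sc$S0, 0); expect_equal(sc$V0, 0)
  # no events at all
  d0 <- data.frame(time = 1:3, delta = 0, Z = 0L, W = NA_real_,
                   x = c(1, 0, 1))
  expect_warning(sc0 <- nam_zelen_score(d0), "no events")
  expect_equal(sc0$S0, 0)
})

test_that("chi-square tests combine and separate components correctly", {
  t0 <- chi2_tests(S0 = 0, V0 = 1, S1 = 0, V1 = 1)
  expect_equal(t0$chi2, 0)
  expect_equal(t0$p, 1)
  t1 <- chi2_tests(S0 = 1, V0 = 1, S1 = 2, V1 = 2)
  expect_equal(t1$chi2, 3)
  expect_equal(t1$df, 2L)
  expect_equal(t1$p, exp(-3 / 2))      # closed-form 2-df tail
  expect_equal(t1$chi1_beta0, 1)
  expect_equal(t1$p_beta1, pchisq(2, 1, lower.tail = FALSE))
  # the alpha = 0.05 rejection threshold is the 2-df quantile 5.991
  expect_lt(chi2_tests(S0 = sqrt(5.99), V0 = 1, S1 = 0.1, V1 = 1e6)$p, 0.0501)
  # a zero-variance component drops with a df reduction
  expect_warning(t2 <- chi2_tests(S0 = 1, V0 = 1, S1 = 0, V1 = 0), "df")
  expect_equal(t2$df, 1L)
  expect_equal(t2$p, pchisq(1, 1, lower.tail = FALSE))
  expect_warning(t3 <- chi2_tests(S0 = 0, V0 = 0, S1 = 0, V1 = 0),
                 "undefined")
  expect_true(is.na(t3$chi2))
})

test_that("with no IE the 2-df test degenerates to the 1-df pre-IE test and
           S0 reduces to the log-rank numerator", {
  set.seed(91)
  time <- rexp(50); delta <- rbinom(50, 1, 0.8); x <- rbinom(50, 1, 0.5)
  sc <- nam_zelen_score(data.frame(time = time, delta = delta, Z = 0L,
                                   W = NA_real_, x = x))
  expect_equal(sc$S1, 0); expect_equal(sc$V1, 0)
  orc <- oracle_logrank_oe(time, delta, x)
  expect_equal(sc$S0, orc$OE, tolerance = 1e-12)
  expect_warning(tt <- chi2_tests(pair = sc), "df")
  expect_equal(tt$chi2, sc$S0^2 / sc$V0)
})

test_that("log-rank comparator matches the brute-force O-E oracle", {
  time <- c(1, 2, 3, 4, 5, 6)
  delta <- c(1, 1, 0, 1, 1, 1)
  x <- c(1, 0, 1, 0, 1, 0)
  lr <- logrank_test(time, delta, x)
  orc <- oracle_logrank_oe(time, delta, x)
  expect_equal(lr$statistic, orc$chisq, tolerance = 1e-9)
  # label-swapped copies give an exactly balanced statistic
  sym <- data.frame(time = rep(c(1, 2, 3), 2), delta = 1,
                    x = rep(c(1, 0), each = 3))
  expect_equal(logrank_test(sym$time, sym$delta, sym$x)$statistic, 0,
               tolerance = 1e-12)
  expect_error(logrank_test(1:3, c(1, 1, 1), c(1, 1, 1)), "two groups")
  expect_error(logrank_test(1:4, c(0, 0, 0, 0), c(1, 0, 1, 0)), "no events")
})

test_that("stratified log-rank sums O-E across the IE strata", {
  set.seed(23)
  time <- c(0.8, 1.5, 2.0, 2.5, 1.2, 3.0, 0.6, 2.2)
  delta <- c(1, 1, 1, 0, 1, 1, 1, 1)
  x <- c(1, 1, 0, 1, 0, 0, 0, 1)
  Z <- c(0, 1, 1, 0, 0, 1, 0, 1)
  st <- stratified_logrank(time, delta, x, Z)
  orc <- oracle_stratified_logrank(time, delta, x, Z)
  expect_equal(st$statistic, orc$chisq, tolerance = 1e-9)
  # a single populated stratum reduces to the unstratified test
  st1 <- stratified_logrank(time, delta, x, Z = rep(0, 8))
  lr1 <- logrank_test(time, delta, x)
  expect_equal(st1$statistic, lr1$statistic, tolerance = 1e-12)
})
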