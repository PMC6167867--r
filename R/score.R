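#' Nam-Zelen two-sample score statistics in the presence of an IE
#'
#' Computes the stratum-specific score statistics for comparing two groups
#' under the proportional-hazards pair `Q_kA(t) = Q_kB(t)^(beta_k)`,
#' `k = 0, 1`, from exact or right-censored event times with an exactly
#' observed IE time.  With `z_j(t) = I(W_j <= t)` (identically 0 for
#' subjects without the IE) and risk indicator `R_j(t) = I(T_j >= t)`:
#'
#' \deqn{S_1 = \sum_{i: z_i(t_i) = 1} (x_i - p_i), \quad p_i = n_i / N_i,}
#'
#' where `n_i` and `N_i` count group-A and all subjects in the post-IE risk
#' set at the event time `t_i`, with null variance
#' `V(S_1) = sum p_i (1 - p_i)`; `S_0` is the analogue over pre-IE events
#' with shares `pi_i = m_i / M_i` from the pre-IE risk set
#' (`R_j(t)(1 - z_j(t))`).  Each event contributes to exactly one of
#' `S_0`/`S_1` according to `z` at its own event time (an event exactly at
#' `W` counts as post-IE).  Tied events share the risk-set shares.
#'
#' @param data a data.frame with columns `time` (exact or censoring time),
#'   `delta` (event indicator), `Z` (IE indicator), `W` (IE time, `NA` when
#'   `Z = 0`) and `x` (1 for group A, 0 for group B).
#'
#' @return An object of class `icie_score`: a list with `S0`, `V0`, `S1`,
#'   `V1` and the event counts `n_events0`, `n_events1` in each stratum.
#' @export
#' @examples
#' d <- data.frame(time = c(1, 2, 3, 4), delta = 1, Z = 0, W = NA,
#'                 x = c(1, 0, 1, 0))
#' nam_zelen_score(d)
nam_zelen_score <- function(data) {
  need <- c("time", "delta", "Z", "W", "x")
  stopifnot(all(need %in% names(data)))
  res <- nz_score_(data$time, data$delta, data$Z, data$W, data$x)
  class(res) <- "icie_score"
  res
}

# vectorised core; W may be NA where Z == 0
nz_score_ <- function(time, delta, Z, W, x) {
  ev <- delta == 1
  if (!any(ev)) {
    warning("no events: scores and variances are zero")
    return(list(S0 = 0, V0 = 0, S1 = 0, V1 = 0,
                n_events0 = 0L, n_events1 = 0L))
  }
  te <- time[ev]
  xe <- x[ev]
  ze <- Z[ev] == 1 & !is.na(W[ev]) & W[ev] <= te

  z1 <- Z == 1
  W1 <- sort(W[z1]); T1 <- sort(time[z1])
  W1A <- sort(W[z1 & x == 1]); T1A <- sort(time[z1 & x == 1])
  T0 <- sort(time[!z1]); T0A <- sort(time[!z1 & x == 1])

  cnt_le <- function(v, t) findInterval(t, v)
  cnt_ge <- function(v, t) length(v) - findInterval(t, v, left.open = TRUE)

  ut <- sort(unique(te))
  # post-IE risk set: Z = 1, W <= t <= T
  Npost <- cnt_le(W1, ut) - (length(T1) - cnt_ge(T1, ut))
  npost <- cnt_le(W1A, ut) - (length(T1A) - cnt_ge(T1A, ut))
  # pre-IE risk set: (Z = 0, T >= t) or (Z = 1, W > t)
  Mpre <- cnt_ge(T0, ut) + (length(W1) - cnt_le(W1, ut))
  mpre <- cnt_ge(T0A, ut) + (length(W1A) - cnt_le(W1A, ut))

  i <- match(te, ut)
  p <- ifelse(Npost[i] > 0, npost[i] / Npost[i], NA_real_)
  q <- ifelse(Mpre[i] > 0, mpre[i] / Mpre[i], NA_real_)

  use1 <- ze & !is.na(p)
  use0 <- !ze & !is.na(q)
  list(S0 = sum(xe[use0] - q[use0]), V0 = sum(q[use0] * (1 - q[use0])),
       S1 = sum(xe[use1] - p[use1]), V1 = sum(p[use1] * (1 - p[use1])),
       n_events0 = sum(!ze), n_events1 = sum(ze))
}

#' @export
print.icie_score <- function(x, ...) {
  cat(sprintf("Nam-Zelen scores: S0 = %.4f (V0 = %.4f, %d events), S1 = %.4f (V1 = %.4f, %d events)\n",
              x$S0, x$V0, x$n_events0, x$S1, x$V1, x$n_events1))
  invisible(x)
}

#' Composite and separable chi-square tests from score statistics
#'
#' Forms the 2-df composite statistic
#' `chi2 = S1^2 / V(S1) + S0^2 / V(S0)` for the joint null
#' `beta_0 = beta_1 = 0`, and the separable 1-df statistics
#' `S_k^2 / V(S_k)` for each parameter.  A component with zero variance is
#' dropped from the composite and the degrees of freedom reduced
#' accordingly (with a warning); if both variances vanish the test is
#' undefined (`NA` with a warning).
#'
#' @param S0,V0,S1,V1 score statistics and null variances, or pass an
#'   `icie_score`/pooled result via `pair`.
#' @param pair optional object with elements `S0`, `V0`, `S1`, `V1`
#'   (overrides the scalar arguments).
#'
#' @return A list with `chi2`, `df`, `p` (composite) and `chi1_beta0`,
#'   `p_beta0`, `chi1_beta1`, `p_beta1` (separable, `NA` when the
#'   corresponding variance is zero).
#' @export
#' @examples
#' chi2_tests(S0 = 1, V0 = 1, S1 = 2, V1 = 2)$chi2  # 3
chi2_tests <- function(S0, V0, S1, V1, pair = NULL) {
  if (!is.null(pair)) {
    S0 <- pair$S0; V0 <- pair$V0; S1 <- pair$S1; V1 <- pair$V1
  }
  stopifnot(V0 >= 0 || is.na(V0), V1 >= 0 || is.na(V1))
  ok0 <- !is.na(V0) && V0 > 0
  ok1 <- !is.na(V1) && V1 > 0
  c0 <- if (ok0) S0^2 / V0 else NA_real_
  c1 <- if (ok1) S1^2 / V1 else NA_real_
  df <- sum(ok0, ok1)
  if (df == 0L) {
    warning("both variance components are zero: test undefined")
    chi2 <- NA_real_; p <- NA_real_
  } else {
    if (df == 1L) warning("zero-variance component dropped; df reduced to 1")
    chi2 <- sum(c(c0, c1), na.rm = TRUE)
    p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  }
  list(chi2 = chi2, df = df, p = p,
       chi1_beta0 = c0,
       p_beta0 = if (ok0) stats::pchisq(c0, 1, lower.tail = FALSE) else NA_real_,
       chi1_beta1 = c1,
       p_beta1 = if (ok1) stats::pchisq(c1, 1, lower.tail = FALSE) else NA_real_)
}

#' Two-sample log-rank test on exact/right-censored times
#'
#' Comparator test on the true event times (ignoring the IE), wrapping
#' [survival::survdiff()].
#'
#' @param time event or censoring times.
#' @param delta event indicators.
#' @param x group labels (two levels; 1/0 or "A"/"B").
#' @return A list with `statistic` (1-df chi-square) and `p`.
#' @export
logrank_test <- function(time, delta, x) {
  if (length(unique(x)) != 2L) stop("exactly two groups required")
  if (!any(delta == 1)) stop("no events: log-rank test undefined")
  fit <- survival::survdiff(survival::Surv(time, delta) ~ x)
  list(statistic = fit$chisq,
       p = stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE))
}

#' Log-rank test stratified by IE status
#'
#' Comparator test on the true event times, accumulating the log-rank
#' observed-minus-expected and variance within the two IE strata
#' (`Z = 0` and `Z = 1`) and summing; wraps [survival::survdiff()] with
#' `strata(Z)`.  A stratum without events contributes nothing.
#'
#' @inheritParams logrank_test
#' @param Z IE stratum indicators.
#' @return A list with `statistic` (1-df chi-square) and `p`.
#' @export
stratified_logrank <- function(time, delta, x, Z) {
  if (length(unique(x)) != 2L) stop("exactly two groups required")
  if (!any(delta == 1)) stop("no events: stratified log-rank test undefined")
  fit <- survival::survdiff(
    survival::Surv(time, delta) ~ x + survival::strata(Z))
  list(statistic = fit$chisq,
       p = stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE))
}
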