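# Brute-force oracles, kept deliberately independent of the package's
# vectorised implementations: direct per-event evaluation of the printed
# formulas.

# Nam-Zelen score pair by double loop over events and subjects.
# z_j(t) = I(W_j <= t) (0 when Z_j = 0), R_j(t) = I(T_j >= t).
oracle_nz_score <- function(time, delta, Z, W, x) {
  S0 <- V0 <- S1 <- V1 <- 0
  zfun <- function(j, t) if (Z[j] == 1 && W[j] <= t) 1 else 0
  for (i in seq_along(time)) {
    if (delta[i] != 1) next
    t <- time[i]
    n_i <- N_i <- m_i <- M_i <- 0
    for (j in seq_along(time)) {
      atrisk <- time[j] >= t
      if (!atrisk) next
      zj <- zfun(j, t)
      N_i <- N_i + zj
      n_i <- n_i + x[j] * zj
      M_i <- M_i + (1 - zj)
      m_i <- m_i + x[j] * (1 - zj)
    }
    if (zfun(i, t) == 1) {
      if (N_i > 0) {
        p <- n_i / N_i
        S1 <- S1 + x[i] - p
        V1 <- V1 + p * (1 - p)
      }
    } else {
      if (M_i > 0) {
        q <- m_i / M_i
        S0 <- S0 + x[i] - q
        V0 <- V0 + q * (1 - q)
      }
    }
  }
  list(S0 = S0, V0 = V0, S1 = S1, V1 = V1)
}

# Two-sample log-rank by direct O-E enumeration with the usual tie-corrected
# hypergeometric variance (the convention survdiff also uses).
oracle_logrank_oe <- function(time, delta, x) {
  ut <- sort(unique(time[delta == 1]))
  O <- E <- V <- 0
  for (t in ut) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & x == 1)
    d <- sum(time == t & delta == 1)
    d1 <- sum(time == t & delta == 1 & x == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(OE = O - E, V = V, chisq = (O - E)^2 / V)
}

oracle_stratified_logrank <- function(time, delta, x, Z) {
  OE <- V <- 0
  for (s in unique(Z)) {
    i <- Z == s
    if (!any(delta[i] == 1)) next
    r <- oracle_logrank_oe(time[i], delta[i], x[i])
    OE <- OE + r$OE
    V <- V + r$V
  }
  list(chisq = OE^2 / V)
}

# small deterministic interval-censored cohort used across tests
toy_cohort <- function() {
  data.frame(
    id = 1:6, group = c("A", "A", "A", "B", "B", "B"),
    L = c(1.0, 0.5, 2.0, 1.5, 0.0, 1.0),
    R = c(2.0, 1.5, Inf, 2.5, 1.0, Inf),
    delta = c(1, 1, 0, 1, 1, 0),
    Z = c(0, 1, 0, 1, 0, 1),
    W = c(NA, 0.25, NA, 1.0, NA, 0.75),
    T_true = c(1.4, 1.1, 2.6, 2.2, 0.7, 1.9))
}
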