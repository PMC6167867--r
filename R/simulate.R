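#' Generate latent event times, IE waiting times and censoring indicators
#'
#' Draws, for one group, the latent quantities of the data-generating model:
#' IE waiting time `W ~ Exponential(mu)`, pre-IE event time
#' `T0 ~ Exponential(lambda0)`, and -- when the IE occurs first
#' (`W <= T0`, so `Z = 1`) -- a post-IE event time `T1` from the
#' Exponential(`1/m1`) distribution left-truncated at `W`, via the inversion
#' `Q1(T1) ~ U(0, Q1(W))`.  The event indicator `delta` is
#' Bernoulli(`1 - c_p`), independent of the event time.
#'
#' Uses the current R random number stream; seed it with [set.seed()] for
#' reproducibility.
#'
#' @param n number of subjects.
#' @param theta probability of experiencing the IE; the waiting-time rate is
#'   `mu = theta * lambda0 / (1 - theta)` (`theta = 0` means the IE never
#'   occurs).
#' @param lambda0 pre-IE hazard rate, strictly positive.
#' @param m1 post-IE mean time to failure, strictly positive.
#' @param c_p censoring probability in `[0, 1)`.
#'
#' @return A data.frame with columns `T_true` (latent event time), `W` (IE
#'   waiting time, `NA` when `Z = 0`), `Z` (IE indicator) and `delta`
#'   (event indicator).
#' @export
#' @examples
#' set.seed(1)
#' lat <- generate_latent(5, theta = 0.5, lambda0 = 1, m1 = 2, c_p = 0)
generate_latent <- function(n, theta, lambda0, m1, c_p = 0) {
  if (lambda0 <= 0 || m1 <= 0) stop("rates must be strictly positive")
  if (theta < 0 || theta >= 1) stop("'theta' must lie in [0, 1)")
  if (c_p < 0 || c_p >= 1) stop("'c_p' must lie in [0, 1)")
  n <- as.integer(n)
  mu <- theta * lambda0 / (1 - theta)
  W <- if (mu > 0) stats::rexp(n, rate = mu) else rep(Inf, n)
  T0 <- stats::rexp(n, rate = lambda0)
  Z <- as.integer(W <= T0)
  lambda1 <- 1 / m1
  T_true <- T0
  ie <- Z == 1L
  if (any(ie)) {
    # inversion for the truncated exponential: U ~ U(0, 1) gives
    # T1 = W - log(U)/lambda1, i.e. Q1(T1) uniform on (0, Q1(W))
    T_true[ie] <- W[ie] - log(stats::runif(sum(ie))) / lambda1
  }
  delta <- stats::rbinom(n, 1L, 1 - c_p)
  data.frame(T_true = T_true,
             W = ifelse(ie, W, NA_real_),
             Z = Z, delta = delta)
}

#' Convert true event times into visit-based censoring intervals
#'
#' Simulates the follow-up visit process.  The first visit time is
#' `E ~ U(0, psi)` for subjects without the IE and `E ~ U(W, W + psi)` for
#' subjects with it (follow-up for the post-IE stratum starts at the IE);
#' subsequent visits are at `E + k * psi`.  Every subject attends the first
#' visit; each later visit is missed independently, with probability
#' `miss_prob_year1` when the visit falls before time 1 and
#' `miss_prob_later` afterwards.  Visits are generated until one attended
#' visit exceeds `T_true` (no cap on the number of visits).
#'
#' For an observed event (`delta = 1`) the interval is `(L, R]` with `L` the
#' largest attended visit below `T_true` and `R` the smallest attended visit
#' above it; when no attended visit precedes the event, `L` is the start of
#' follow-up (0, or `W` for the post-IE stratum).  For a censored subject
#' `L` is kept as the last attended visit before `T_true` and `R = Inf`.
#'
#' @param T_true vector of true event times (strictly positive).
#' @param W IE waiting times (`NA` when `Z = 0`).
#' @param Z IE indicators in `{0, 1}`.
#' @param delta event indicators in `{0, 1}`.
#' @param psi inter-visit interval.
#' @param miss_prob_year1,miss_prob_later per-visit miss probabilities.
#'
#' @return A data.frame with columns `L` and `R` (the half-open censoring
#'   interval `(L, R]`; `R = Inf` when `delta = 0`).
#' @export
schedule_visits <- function(T_true, W, Z, delta, psi = 0.5,
                            miss_prob_year1 = 0.1, miss_prob_later = 0.2) {
  n <- length(T_true)
  if (n == 0L) return(data.frame(L = numeric(0), R = numeric(0)))
  stopifnot(all(T_true > 0), all(Z %in% c(0, 1)), all(delta %in% c(0, 1)))
  base <- ifelse(Z == 1, W, 0)
  E <- base + stats::runif(n, 0, psi)

  # j = smallest visit index k >= 0 with E + k*psi > T
  j <- ifelse(T_true <= E, 0L, as.integer(ceiling((T_true - E) / psi)))
  j <- ifelse(E + j * psi <= T_true, j + 1L, j)

  # attendance of visits k = 1..K (visit 0 is always attended)
  K <- max(j) + 25L
  vt <- outer(E, seq_len(K) * psi, "+")
  pmiss <- ifelse(vt < 1, miss_prob_year1, miss_prob_later)
  att <- matrix(stats::runif(n * K), n, K) >= pmiss
  kidx <- matrix(rep(seq_len(K), each = n), n, K)

  # L: largest attended visit index strictly below j (index 0 always counts)
  candL <- ifelse(att & kidx < j, kidx, 0L)
  kL <- do.call(pmax, as.data.frame(candL))
  L <- E + kL * psi
  L[j == 0L] <- base[j == 0L]

  # R: smallest attended visit index >= j (visit 0 if j = 0)
  candR <- ifelse(att & kidx >= j, kidx, NA_integer_)
  kR <- do.call(function(...) pmin(..., na.rm = TRUE), as.data.frame(candR))
  kR[j == 0L] <- 0L
  # extend for the (vanishingly rare) subjects whose next 25+ visits were all
  # missed
  while (anyNA(kR)) {
    miss <- which(is.na(kR))
    K2 <- K + 25L
    vt2 <- outer(E[miss], (K + 1):K2 * psi, "+")
    p2 <- ifelse(vt2 < 1, miss_prob_year1, miss_prob_later)
    att2 <- matrix(stats::runif(length(miss) * 25L), length(miss), 25L) >= p2
    first <- apply(att2, 1L, function(a) if (any(a)) which(a)[1L] else NA_integer_)
    kR[miss] <- K + first
    K <- K2
  }
  R <- E + kR * psi
  R[delta == 0] <- Inf
  data.frame(L = L, R = R)
}

#' Generate a two-group interval-censored cohort with an intermediate event
#'
#' Composes [generate_latent()] and [schedule_visits()] for both groups of a
#' scenario: latent times and censoring indicators are drawn per group
#' (group A first), then a single visit process converts every true time into
#' a censoring interval.
#'
#' @param cfg an `icie_scenario` from [scenario_config()].
#'
#' @return A data.frame with one row per subject and columns `id`, `group`
#'   (`"A"`/`"B"`), `L`, `R`, `delta`, `Z`, `W` (`NA` when `Z = 0`) and
#'   `T_true` (retained for comparator tests on true times).
#' @export
#' @examples
#' cfg <- scenario_config(theta_A = 0.5, m1_A = 2, n_per_group = 20)
#' set.seed(42)
#' coh <- generate_cohort(cfg)
#' head(coh)
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "icie_scenario"))
  n <- cfg$n_per_group
  latA <- generate_latent(n, cfg$theta_A, cfg$lambda0_A, cfg$m1_A, cfg$c_p)
  latB <- generate_latent(n, cfg$theta_B, cfg$lambda0_B, cfg$m1_B, cfg$c_p)
  lat <- rbind(latA, latB)
  group <- rep(c("A", "B"), each = n)
  if (nrow(lat) == 0L) {
    return(data.frame(id = integer(0), group = character(0),
                      L = numeric(0), R = numeric(0), delta = integer(0),
                      Z = integer(0), W = numeric(0), T_true = numeric(0)))
  }
  iv <- schedule_visits(lat$T_true, lat$W, lat$Z, lat$delta,
                        psi = cfg$psi,
                        miss_prob_year1 = cfg$miss_prob_year1,
                        miss_prob_later = cfg$miss_prob_later)
  data.frame(id = seq_len(2L * n), group = group,
             L = iv$L, R = iv$R, delta = lat$delta,
             Z = lat$Z, W = lat$W, T_true = lat$T_true)
}

#' Read and write cohort files
#'
#' Cohorts are exchanged as comma-separated text with header
#' `id,group,L,R,delta,Z,W,T_true`, `inf` for an unbounded right endpoint and
#' an empty field for an undefined waiting time.
#'
#' @param cohort a cohort data.frame as returned by [generate_cohort()]
#'   (`T_true` optional).
#' @param path file path.
#' @return `read_cohort` returns the cohort data.frame; `write_cohort`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$R <- ifelse(is.infinite(out$R), "inf", format(out$R, digits = 15L,
                                                   trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "group", "L", "R", "delta", "Z", "W")
  if (!all(need %in% names(d)))
    stop("cohort file must have columns ", paste(need, collapse = ", "))
  d$R <- as.numeric(d$R)  # "inf" parses to Inf
  d$W <- as.numeric(d$W)
  validate_cohort(d)
  d
}

#' Validate the per-subject invariants of a cohort
#'
#' Checks `0 <= L <= R`, `delta = 0` iff `R = Inf`, and that subjects with
#' the IE have an exactly observed waiting time not exceeding `L` (the IE
#' precedes the censoring interval).
#'
#' @param cohort a cohort data.frame.
#' @return The cohort, invisibly; errors describe the first violated
#'   invariant.
#' @export
validate_cohort <- function(cohort) {
  with(cohort, {
    if (any(L < 0)) stop("negative left endpoints")
    if (any(L > R)) stop("intervals with L > R")
    if (any((delta == 0) != is.infinite(R)))
      stop("delta = 0 must coincide with R = Inf")
    if (any(Z == 1 & (is.na(W) | W > L)))
      stop("subjects with Z = 1 must have W observed and W <= L")
    if (any(Z == 0 & !is.na(W)))
      stop("subjects with Z = 0 must have W undefined (NA)")
  })
  invisible(cohort)
}
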