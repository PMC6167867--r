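#' Scenario configuration for cohort simulation
#'
#' Bundles and validates every parameter of the data-generating mechanism:
#' group-specific probabilities of experiencing the intermediate event (IE),
#' pre- and post-IE exponential hazards, independent Bernoulli censoring, and
#' the follow-up visit process that converts true event times into censoring
#' intervals.
#'
#' The IE waiting time W is exponential with rate `mu_g` chosen so that the
#' probability of experiencing the IE before the event is
#' `theta_g = mu_g / (mu_g + lambda0_g)`, i.e.
#' `mu_g = theta_g * lambda0_g / (1 - theta_g)`.  After the IE the residual
#' hazard is `lambda1_g = 1 / m1_g`, parameterised by the post-IE mean time to
#' failure `m1_g`.
#'
#' @param theta_A,theta_B probability of experiencing the IE, per group, in
#'   `[0, 1)`.
#' @param lambda0_A,lambda0_B pre-IE hazard rates (1/time), strictly positive.
#' @param m1_A,m1_B post-IE mean times to failure (time units), strictly
#'   positive; the post-IE rate is `1/m1`.
#' @param c_p censoring probability in `[0, 1)`: the event indicator is
#'   Bernoulli(1 - c_p), independent of the event time.
#' @param psi inter-visit interval (time units), default 0.5.
#' @param miss_prob_year1,miss_prob_later per-visit miss probabilities before
#'   and after time 1.0 (defaults 0.1 and 0.2); the first visit is always
#'   attended.
#' @param n_per_group subjects per group.
#' @param n_reps replications for simulation studies (default 1000).
#' @param M imputations per multiple-imputation test (default 10).
#' @param seed root RNG seed for [run_scenario()].
#'
#' @return An object of class `icie_scenario`: a validated list of the above
#'   together with the derived rates `mu_A`, `mu_B`, `lambda1_A`, `lambda1_B`.
#' @seealso [generate_cohort()], [run_scenario()]
#' @export
#' @examples
#' cfg <- scenario_config(theta_A = 0.5, theta_B = 0.5, m1_A = 2, m1_B = 2,
#'                        n_per_group = 50)
#' cfg$mu_A  # 1 when theta = 0.5 and lambda0 = 1
scenario_config <- function(theta_A, theta_B = theta_A,
                            lambda0_A = 1, lambda0_B = 1,
                            m1_A, m1_B = m1_A,
                            c_p = 0, psi = 0.5,
                            miss_prob_year1 = 0.1, miss_prob_later = 0.2,
                            n_per_group = 200, n_reps = 1000, M = 10,
                            seed = 1L) {
  chk_prob <- function(x, nm, open_right = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
        (if (open_right) x >= 1 else x > 1))
      stop(sprintf("'%s' must be a single probability in [0, 1%s", nm,
                   if (open_right) ")" else "]"), call. = FALSE)
  }
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
      stop(sprintf("'%s' must be strictly positive", nm), call. = FALSE)
  }
  chk_prob(theta_A, "theta_A"); chk_prob(theta_B, "theta_B")
  chk_pos(lambda0_A, "lambda0_A"); chk_pos(lambda0_B, "lambda0_B")
  chk_pos(m1_A, "m1_A"); chk_pos(m1_B, "m1_B")
  chk_prob(c_p, "c_p")
  chk_pos(psi, "psi")
  chk_prob(miss_prob_year1, "miss_prob_year1")
  chk_prob(miss_prob_later, "miss_prob_later")
  if (!is.numeric(n_per_group) || n_per_group < 0 ||
      n_per_group != round(n_per_group))
    stop("'n_per_group' must be a non-negative integer", call. = FALSE)
  if (!is.numeric(n_reps) || n_reps < 0 || n_reps != round(n_reps))
    stop("'n_reps' must be a non-negative integer", call. = FALSE)
  if (!is.numeric(M) || M < 1 || M != round(M))
    stop("'M' must be a positive integer", call. = FALSE)

  cfg <- list(theta_A = theta_A, theta_B = theta_B,
              lambda0_A = lambda0_A, lambda0_B = lambda0_B,
              m1_A = m1_A, m1_B = m1_B,
              c_p = c_p, psi = psi,
              miss_prob_year1 = miss_prob_year1,
              miss_prob_later = miss_prob_later,
              n_per_group = as.integer(n_per_group),
              n_reps = as.integer(n_reps), M = as.integer(M),
              seed = as.integer(seed),
              mu_A = theta_A * lambda0_A / (1 - theta_A),
              mu_B = theta_B * lambda0_B / (1 - theta_B),
              lambda1_A = 1 / m1_A, lambda1_B = 1 / m1_B)
  class(cfg) <- "icie_scenario"
  cfg
}

#' @export
print.icie_scenario <- function(x, ...) {
  cat("Simulation scenario (two groups, intermediate event)\n")
  cat(sprintf("  theta  (IE prob):   A = %.3g, B = %.3g\n", x$theta_A, x$theta_B))
  cat(sprintf("  lambda0 (pre-IE):   A = %.3g, B = %.3g\n", x$lambda0_A, x$lambda0_B))
  cat(sprintf("  m1 (post-IE mean):  A = %.3g, B = %.3g\n", x$m1_A, x$m1_B))
  cat(sprintf("  censoring prob c_p = %.3g, visit interval psi = %.3g\n",
              x$c_p, x$psi))
  cat(sprintf("  miss prob: %.2g (t < 1), %.2g (t >= 1)\n",
              x$miss_prob_year1, x$miss_prob_later))
  cat(sprintf("  n per group = %d, replications = %d, M = %d, seed = %d\n",
              x$n_per_group, x$n_reps, x$M, x$seed))
  invisible(x)
}
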