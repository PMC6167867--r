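#' Candidate mass-point sets for the two IE strata
#'
#' Assembles, per stratum, the ordered set of distinct time points that can
#' carry probability mass for the stratum-specific survival distribution, and
#' each eligible subject's candidate subset `{s_j : L_i < s_j <= R_i}` used
#' for imputation.
#'
#' For the pre-IE stratum (`k = 0`) the set collects `{0}`, the interval
#' endpoints `L_i, R_i` of subjects without the IE, the waiting times `W_i`
#' of subjects with the IE (which act as right-censoring times for the
#' pre-IE distribution: nothing beyond `W` is observable for that subject's
#' pre-IE time), and `Inf`.  For the post-IE stratum (`k = 1`) it collects
#' `{0}`, `L_i`, `R_i` and `W_i` of subjects with the IE (the waiting time is
#' the left-truncation point, which may itself carry mass), and `Inf`.
#' Subjects without the IE contribute nothing to the `k = 1` set.
#'
#' @param cohort a cohort data.frame (see [generate_cohort()]).
#'
#' @return A list with elements `k0` and `k1`, each a list with `points`
#'   (strictly increasing, beginning with 0 and ending with `Inf`) and
#'   `subjects` (a data.frame with the eligible subjects' `id`, `L`, `R`,
#'   `delta`); `k1$empty` flags the degenerate case with no IE subjects.
#' @export
#' @examples
#' coh <- data.frame(id = 1:2, group = c("A", "B"),
#'                   L = c(1, 1.5), R = c(2, 3), delta = c(1, 1),
#'                   Z = c(0, 1), W = c(NA, 0.5))
#' cs <- build_candidate_sets(coh)
#' cs$k0$points  # 0, 0.5, 1, 2, Inf
#' cs$k1$points  # 0, 0.5, 1.5, 3, Inf
build_candidate_sets <- function(cohort) {
  if (nrow(cohort) == 0L) stop("empty cohort")
  validate_cohort(cohort)
  z0 <- cohort$Z == 0
  z1 <- cohort$Z == 1
  pts0 <- sort(unique(c(0, cohort$L[z0], cohort$R[z0], cohort$W[z1], Inf)))
  pts1 <- sort(unique(c(0, cohort$L[z1], cohort$R[z1], cohort$W[z1], Inf)))
  list(
    k0 = list(points = pts0,
              subjects = cohort[z0, c("id", "L", "R", "delta")]),
    k1 = list(points = pts1,
              subjects = cohort[z1, c("id", "L", "R", "delta")],
              empty = !any(z1))
  )
}

# innermost (Turnbull) intervals from left endpoints (observation lower
# endpoints and truncation points) and right endpoints: pairs (p, q] with
# p a left endpoint, q the immediately following right endpoint, and no
# other endpoint strictly between.  At a tied value the right endpoint is
# ordered first so empty (v, v] pairs never form.
innermost_intervals <- function(lefts, rights) {
  lefts <- sort(unique(lefts))
  rights <- sort(unique(rights))
  val <- c(rights, lefts)
  typ <- rep(c(0L, 1L), c(length(rights), length(lefts)))  # 0 right, 1 left
  o <- order(val, typ)  # rights before lefts at ties
  val <- val[o]; typ <- typ[o]
  i <- which(typ[-length(typ)] == 1L & typ[-1L] == 0L)
  data.frame(left = val[i], right = val[i + 1L])
}

# one self-consistency (EM) step for mass vector p
npmle_em_ <- function(p, alpha, beta, omb, truncated) {
  A <- as.vector(alpha %*% p)
  d <- p * as.vector(crossprod(alpha, 1 / A))        # expected counts
  if (truncated) {
    B <- as.vector(beta %*% p)
    d <- d + p * as.vector(crossprod(omb, 1 / B))    # ghosts outside B_i
  }
  d / sum(d)
}

npmle_loglik_ <- function(p, alpha, beta, truncated) {
  A <- alpha %*% p
  if (any(A <= 0)) return(-Inf)
  ll <- sum(log(A))
  if (truncated) ll <- ll - sum(log(beta %*% p))
  ll
}

#' Turnbull NPMLE for interval-censored data with left truncation
#'
#' Self-consistency (EM) estimation of the nonparametric maximum likelihood
#' distribution from observation intervals `(L, R]` and optional per-subject
#' truncation sets `(trunc, Inf)`.  Mass is restricted to the innermost
#' (Turnbull) intervals computed from all observation and truncation
#' endpoints; the EM fixed point maximises
#' `prod_i P(T in (L_i, R_i]) / P(T > trunc_i)`.
#'
#' Exact observations (`L = R`) are accommodated by treating the atom at `R`
#' as an (eps-shifted) innermost interval of its own.  The log-likelihood is
#' non-decreasing over iterations; the algorithm stops when the largest
#' absolute mass change falls below `tol`.
#'
#' @param L,R interval endpoints (`0 <= L <= R`, `R = Inf` for right
#'   censoring, `L = R` for an exact observation).
#' @param trunc optional left-truncation times (`-Inf`/0 or `NULL` for
#'   none); each must satisfy `trunc <= L`.
#' @param tol convergence tolerance on the maximum absolute mass change
#'   (default `1e-6`).
#' @param max_iter iteration cap (default 5000); exceeding it returns a
#'   result flagged `converged = FALSE`.
#'
#' @return An object of class `icie_npmle`: a list with `support_left`,
#'   `support_right` (innermost-interval endpoints), `points` (the
#'   right endpoints, the point representatives used for imputation),
#'   `mass` (probabilities, summing to 1), `loglik`, `loglik_trace`,
#'   `n_iter` and `converged`.
#' @references Turnbull-type self-consistency with truncation sets; see the
#'   methods vignette for the estimating equations.
#' @export
#' @examples
#' est <- turnbull_npmle(L = c(0, 1), R = c(2, 3))
#' est$mass  # all mass on the innermost interval (1, 2]
turnbull_npmle <- function(L, R, trunc = NULL, tol = 1e-6, max_iter = 5000L) {
  n <- length(L)
  if (n == 0L) stop("empty data")
  stopifnot(length(R) == n, all(L <= R), all(L >= 0 | !is.finite(L)))
  if (is.null(trunc)) trunc <- rep(-Inf, n)
  stopifnot(length(trunc) == n, all(trunc <= L))

  # eps-shift exact observations so the atom {R} is its own interval
  finite <- c(L[is.finite(L)], R[is.finite(R)], trunc[is.finite(trunc)])
  eps <- 1e-9 * max(1, finite)
  Ls <- ifelse(L == R, L - eps, L)

  iv <- innermost_intervals(lefts = c(Ls, trunc[is.finite(trunc)]), rights = R)
  m <- nrow(iv)
  # membership: interval j in subject i's observation set / truncation set
  alpha <- outer(Ls, iv$left, "<=") & outer(R, iv$right, ">=")
  beta <- outer(trunc, iv$left, "<=")
  storage.mode(alpha) <- "double"
  storage.mode(beta) <- "double"
  if (any(rowSums(alpha) == 0))
    stop("some observation interval contains no innermost interval")

  truncated <- any(is.finite(trunc))
  omb <- if (truncated) 1 - beta else NULL

  # self-consistency iteration, accelerated with SQUAREM-style extrapolation;
  # an extrapolated iterate is kept only if it does not decrease the
  # likelihood, so the trace stays monotone
  p <- rep(1 / m, m)
  trace <- npmle_loglik_(p, alpha, beta, truncated)
  converged <- m == 1L
  it <- 0L
  while (!converged && it < max_iter) {
    p1 <- npmle_em_(p, alpha, beta, omb, truncated)
    p2 <- npmle_em_(p1, alpha, beta, omb, truncated)
    it <- it + 2L
    r <- p1 - p
    v <- (p2 - p1) - r
    p_new <- p2
    vv <- sum(v^2)
    if (vv > 0) {
      a <- -sqrt(sum(r^2) / vv)
      pa <- pmax(p - 2 * a * r + a^2 * v, 1e-12)
      pa <- npmle_em_(pa / sum(pa), alpha, beta, omb, truncated)
      it <- it + 1L
      if (npmle_loglik_(pa, alpha, beta, truncated) >=
          npmle_loglik_(p2, alpha, beta, truncated)) p_new <- pa
    }
    trace <- c(trace, npmle_loglik_(p_new, alpha, beta, truncated))
    if (max(abs(p_new - p)) < tol) converged <- TRUE
    p <- p_new
  }
  structure(list(support_left = iv$left, support_right = iv$right,
                 points = iv$right, mass = p,
                 loglik = trace[length(trace)], loglik_trace = trace,
                 n_iter = it, converged = converged),
            class = "icie_npmle")
}

#' @export
print.icie_npmle <- function(x, ...) {
  cat(sprintf("Turnbull NPMLE: %d support intervals, loglik %.4f (%d iterations%s)\n",
              length(x$mass), x$loglik, x$n_iter,
              if (x$converged) "" else ", NOT converged"))
  sup <- data.frame(left = x$support_left, right = x$support_right,
                    mass = x$mass)
  print(utils::head(sup[sup$mass > 1e-8, ], 10L), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.icie_npmle <- function(x, ...) {
  data.frame(support_left = x$support_left, support_right = x$support_right,
             mass = x$mass)
}

#' Survival function of an NPMLE at given times
#'
#' Evaluates `S(t) = P(T > t)` of the estimated distribution, placing each
#' support interval's mass at its right endpoint (the point representative).
#'
#' @param est an `icie_npmle` object.
#' @param times evaluation times.
#' @return A numeric vector of survival probabilities.
#' @export
npmle_survival <- function(est, times) {
  vapply(times, function(t) sum(est$mass[est$points > t]), numeric(1))
}

#' Conditional imputation distribution on an interval
#'
#' Restricts an NPMLE to the support points inside `(L, R]` and renormalises:
#' the sampling distribution for an imputed event time conditional on
#' `L < T <= R`.
#'
#' @param est an `icie_npmle` object.
#' @param L,R interval endpoints.
#' @return A list with `points`, `prob` (summing to 1) and `total` (the
#'   unnormalised mass on the interval).  When no support point falls in
#'   `(L, R]`, `total = 0`, `points` is empty, and the caller is expected to
#'   fall back to the uniform candidate distribution.
#' @export
#' @examples
#' est <- turnbull_npmle(L = c(0.9, 1.9, 2.9), R = c(1, 2, 3))  # atoms 1,2,3
#' conditional_mass(est, 0, 2)  # P(1) = P(2) = 0.5
conditional_mass <- function(est, L, R) {
  idx <- est$points > L & est$points <= R
  total <- sum(est$mass[idx])
  if (total <= 0)
    return(list(points = numeric(0), prob = numeric(0), total = 0))
  list(points = est$points[idx], prob = est$mass[idx] / total, total = total)
}
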