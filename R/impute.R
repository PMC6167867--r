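# per-subject imputation draws for the delta = 1 subjects of a cohort.
# Returns an n_d1 x M matrix of imputed event times, plus fallback counts.
# weights: NULL for the uniform method, otherwise list(est0, est1) where each
# element is an icie_npmle or a per-group list with elements "A" and "B".
draw_imputations_ <- function(cohort, cands, M, weights = NULL) {
  d1 <- which(cohort$delta == 1)
  out <- matrix(NA_real_, length(d1), M)
  n_fallback <- 0L
  pick_est <- function(e, grp)
    if (inherits(e, "icie_npmle") || is.null(e)) e else e[[grp]]
  for (ii in seq_along(d1)) {
    i <- d1[ii]
    L <- cohort$L[i]; R <- cohort$R[i]
    k1 <- cohort$Z[i] == 1
    pts <- if (k1) cands$k1$points else cands$k0$points
    cand <- pts[pts > L & pts <= R & is.finite(pts)]
    if (length(cand) == 0L) {
      # exact observation (L = R) or no interior candidate: R is always a
      # valid upper bound for T
      out[ii, ] <- R
      next
    }
    prob <- NULL
    if (!is.null(weights)) {
      est <- pick_est(if (k1) weights$est1 else weights$est0, cohort$group[i])
      cm <- if (is.null(est)) list(total = 0) else conditional_mass(est, L, R)
      if (cm$total > 0) {
        cand <- cm$points
        prob <- cm$prob
      } else {
        n_fallback <- n_fallback + 1L  # uniform fallback
      }
    }
    out[ii, ] <- if (length(cand) == 1L) rep(cand, M)
                 else sample(cand, M, replace = TRUE, prob = prob)
  }
  list(rows = d1, times = out, n_fallback = n_fallback)
}

# NPMLE weights for the weighted method: one estimate per IE stratum within
# each treatment group
group_npmle_ <- function(cohort, tol, max_iter) {
  ests <- lapply(split(cohort, cohort$group), function(sub)
    list(est0 = stratum_npmle(sub, 0L, tol = tol, max_iter = max_iter),
         est1 = stratum_npmle(sub, 1L, tol = tol, max_iter = max_iter)))
  list(est0 = lapply(ests, `[[`, "est0"), est1 = lapply(ests, `[[`, "est1"))
}

# assemble the r-th completed data set: exact/right-censored times for all
# subjects (IE subjects keep their truncation time W)
completed_dataset_ <- function(cohort, draws, r) {
  time <- cohort$L             # delta = 0: censored at last attended visit
  time[draws$rows] <- draws$times[, r]
  data.frame(time = time, delta = cohort$delta, Z = cohort$Z,
             W = cohort$W, x = as.integer(cohort$group == "A"))
}

#' Single imputation of an interval-censored IE cohort
#'
#' Produces one completed data set following the imputation rules.  The
#' pre-IE part `T0_data` contains every subject: censored at `L` when
#' `delta = 0, Z = 0`, censored at `W` when `Z = 1` (nothing about the
#' pre-IE time beyond `W` is observable), and an imputed exact time when
#' `delta = 1, Z = 0`.  The post-IE part `T1_data` contains only the IE
#' subjects, censored at `L` when `delta = 0` or imputed when `delta = 1`,
#' each carrying its left-truncation time `W`.
#'
#' `impute_uniform` samples imputed times uniformly from the candidate
#' subset `{s_j : L_i < s_j <= R_i}` of the stratum's mass-point set;
#' `impute_weighted` samples them from the Turnbull NPMLE restricted and
#' renormalised to `(L_i, R_i]` (see [conditional_mass()]), falling back to
#' the uniform draw when the interval carries no NPMLE mass.  NPMLE weights
#' are estimated separately within each treatment group (imputation should
#' reflect each sample's own distribution; a pooled estimate would shrink
#' the group contrast).  A subject whose candidate subset is empty (an
#' exact observation, `L = R`) is imputed at `R`.
#'
#' @param cohort a cohort data.frame (see [generate_cohort()]).
#' @param cands candidate sets from [build_candidate_sets()] (built from the
#'   same cohort); computed when `NULL`.
#' @param est0,est1 NPMLE weights for the pre- and post-IE strata: either a
#'   single `icie_npmle` (applied to both groups) or a list with elements
#'   `A` and `B` (see [stratum_npmle()]).  When `NULL`, estimated per
#'   treatment group from `cohort`.
#'
#' @return A list with data.frames `T0_data` (`time`, `delta`, `x`) and
#'   `T1_data` (`time`, `delta`, `x`, `W`), and `completed` (the combined
#'   per-subject data set with columns `time`, `delta`, `Z`, `W`, `x` used
#'   by [nam_zelen_score()]).
#' @export
impute_uniform <- function(cohort, cands = NULL) {
  if (is.null(cands)) cands <- build_candidate_sets(cohort)
  draws <- draw_imputations_(cohort, cands, 1L)
  split_imputed_(cohort, completed_dataset_(cohort, draws, 1L))
}

#' @rdname impute_uniform
#' @export
impute_weighted <- function(cohort, cands = NULL, est0 = NULL, est1 = NULL) {
  if (is.null(cands)) cands <- build_candidate_sets(cohort)
  if (is.null(est0) && is.null(est1)) {
    weights <- group_npmle_(cohort, tol = 1e-6, max_iter = 5000L)
  } else {
    weights <- list(est0 = est0, est1 = est1)
  }
  draws <- draw_imputations_(cohort, cands, 1L, weights = weights)
  split_imputed_(cohort, completed_dataset_(cohort, draws, 1L))
}

split_imputed_ <- function(cohort, comp) {
  z1 <- comp$Z == 1
  T0_time <- ifelse(z1, cohort$W, comp$time)
  T0_delta <- ifelse(z1, 0L, comp$delta)
  list(T0_data = data.frame(time = T0_time, delta = T0_delta, x = comp$x),
       T1_data = data.frame(time = comp$time[z1], delta = comp$delta[z1],
                            x = comp$x[z1], W = comp$W[z1]),
       completed = comp)
}

#' Stratum-specific NPMLE from the original interval-censored data
#'
#' For the pre-IE stratum (`stratum = 0`) the estimator uses the intervals
#' `(L, R]` of subjects without the IE together with the IE subjects as
#' right-censored at `W` (their pre-IE time is only known to exceed `W`).
#' For the post-IE stratum (`stratum = 1`) it uses the IE subjects'
#' intervals with left-truncation sets `(W, Inf)`.
#'
#' @param cohort a cohort data.frame.
#' @param stratum 0 or 1.
#' @param ... passed to [turnbull_npmle()].
#' @return An `icie_npmle` object (or `NULL` for an empty post-IE stratum).
#' @export
stratum_npmle <- function(cohort, stratum, ...) {
  z1 <- cohort$Z == 1
  if (stratum == 0L) {
    turnbull_npmle(L = c(cohort$L[!z1], cohort$W[z1]),
                   R = c(cohort$R[!z1], rep(Inf, sum(z1))), ...)
  } else {
    if (!any(z1)) return(NULL)
    turnbull_npmle(L = cohort$L[z1], R = cohort$R[z1],
                   trunc = cohort$W[z1], ...)
  }
}

#' Rubin-style pooling of score statistics across imputations
#'
#' Pools `M` replicate Nam-Zelen score pairs.  For each stratum `k`, the
#' pooled statistic is the mean `S_bar_k` of the replicate scores; the
#' within-imputation variance is the mean of the replicate variances and the
#' between-imputation variance `B_k` is the sample variance of the replicate
#' scores.  Two combined variances are formed:
#'
#' \deqn{V_1 = \bar{V} + (1 + 1/M) B \qquad \text{(additive)},}
#' \deqn{V_2 = \bar{V} - B \qquad \text{(subtractive)},}
#'
#' and the composite 2-df statistic
#' `S_bar_0^2 / V_l(S_0) + S_bar_1^2 / V_l(S_1)` is referred to a
#' chi-square with 2 df for each form `l = 1, 2` (with the same
#' zero-variance df reduction as [chi2_tests()]).  A non-positive
#' subtractive variance is replaced by the additive one for that component
#' and flagged.  The identity `V_1 - V_2 = (2 + 1/M) B` holds whenever no
#' guard triggers.
#'
#' @param pairs a list of `M` score pairs (each with `S0`, `V0`, `S1`,
#'   `V1`), e.g. from [nam_zelen_score()].
#' @return An object of class `icie_mitest`; see [mi_test()] for the
#'   fields.
#' @export
#' @examples
#' p <- list(S0 = 2, V0 = 1, S1 = 0, V1 = 1)
#' pool_rubin(list(p, p, p))$V1_0  # 1: no between-imputation spread
pool_rubin <- function(pairs) {
  M <- length(pairs)
  stopifnot(M >= 1L)
  if (M == 1L)
    warning("M = 1: between-imputation variance set to 0")
  S <- sapply(pairs, function(p) c(p$S0, p$S1))  # 2 x M
  V <- sapply(pairs, function(p) c(p$V0, p$V1))
  Sbar <- rowMeans(S)
  within <- rowMeans(V)
  between <- if (M > 1L) apply(S, 1L, stats::var) else c(0, 0)
  V1 <- within + (1 + 1 / M) * between
  V2 <- within - between
  v2_fallback <- V2 <= 0 & V1 > 0
  V2[v2_fallback] <- V1[v2_fallback]
  add <- chi2_tests(S0 = Sbar[1L], V0 = V1[1L], S1 = Sbar[2L], V1 = V1[2L])
  sub <- chi2_tests(S0 = Sbar[1L], V0 = V2[1L], S1 = Sbar[2L], V1 = V2[2L])
  structure(list(S_bar_0 = Sbar[1L], S_bar_1 = Sbar[2L],
                 within0 = within[1L], within1 = within[2L],
                 between0 = between[1L], between1 = between[2L],
                 V1_0 = V1[1L], V1_1 = V1[2L],
                 V2_0 = V2[1L], V2_1 = V2[2L],
                 v2_fallback = v2_fallback,
                 chi2_add = add$chi2, df_add = add$df, p_add = add$p,
                 chi2_sub = sub$chi2, df_sub = sub$df, p_sub = sub$p,
                 add = add, sub = sub, M = M),
            class = "icie_mitest")
}

#' Multiple-imputation score test for interval-censored IE data
#'
#' The package's main test.  Builds the stratum candidate sets (and, for the
#' weighted method, the per-group Turnbull NPMLEs) from the observed data,
#' imputes `M`
#' completed data sets, computes the Nam-Zelen score pair on each (the
#' pre-IE stratum as right-censored data, the post-IE stratum as
#' left-truncated right-censored data), and pools with [pool_rubin()].
#' Both the additive and subtractive variance combinations are reported,
#' together with the separable 1-df tests of `beta_0 = 0` and
#' `beta_1 = 0`.
#'
#' Imputation draws consume the current R random number stream; seed it with
#' [set.seed()] for reproducibility.
#'
#' @param cohort a cohort data.frame with columns `group`, `L`, `R`,
#'   `delta`, `Z`, `W` (see [generate_cohort()] / [read_cohort()]).
#' @param method `"uniform"` or `"weighted"`.
#' @param M number of imputations (default 10).
#' @param npmle_tol,npmle_max_iter convergence controls for the NPMLE of the
#'   weighted method.
#'
#' @return An object of class `icie_mitest` with pooled scores `S_bar_0`,
#'   `S_bar_1`, within/between variances, combined variances `V1_*`
#'   (additive) and `V2_*` (subtractive), composite statistics `chi2_add`,
#'   `chi2_sub` with p-values `p_add`, `p_sub`, separable tests in `add`
#'   and `sub`, the method, and `n_fallback` (weighted draws that fell back
#'   to uniform).
#' @export
#' @examples
#' cfg <- scenario_config(theta_A = 0.5, m1_A = 2, n_per_group = 40)
#' set.seed(7)
#' coh <- generate_cohort(cfg)
#' mi_test(coh, method = "uniform")
mi_test <- function(cohort, method = c("uniform", "weighted"), M = 10L,
                    npmle_tol = 1e-6, npmle_max_iter = 5000L) {
  method <- match.arg(method)
  stopifnot(M >= 1L)
  validate_cohort(cohort)
  cands <- build_candidate_sets(cohort)
  weights <- NULL
  if (method == "weighted")
    weights <- group_npmle_(cohort, tol = npmle_tol,
                            max_iter = npmle_max_iter)
  draws <- draw_imputations_(cohort, cands, M, weights = weights)
  pairs <- lapply(seq_len(M), function(r) {
    comp <- completed_dataset_(cohort, draws, r)
    nz_score_(comp$time, comp$delta, comp$Z, comp$W, comp$x)
  })
  res <- pool_rubin(pairs)
  res$method <- method
  res$n_fallback <- draws$n_fallback
  res
}

#' @export
print.icie_mitest <- function(x, ...) {
  cat(sprintf("Multiple-imputation Nam-Zelen test (%s weights, M = %d)\n",
              if (is.null(x$method)) "pooled" else x$method, x$M))
  cat(sprintf("  pooled scores: S0 = %.4f, S1 = %.4f\n", x$S_bar_0, x$S_bar_1))
  cat(sprintf("  additive    variance: V(S0) = %.4f, V(S1) = %.4f, chi2(%d df) = %.3f, p = %.4g\n",
              x$V1_0, x$V1_1, x$df_add, x$chi2_add, x$p_add))
  cat(sprintf("  subtractive variance: V(S0) = %.4f, V(S1) = %.4f, chi2(%d df) = %.3f, p = %.4g\n",
              x$V2_0, x$V2_1, x$df_sub, x$chi2_sub, x$p_sub))
  if (any(x$v2_fallback))
    cat("  note: non-positive subtractive variance replaced by the additive form\n")
  if (!is.null(x$n_fallback) && x$n_fallback > 0)
    cat(sprintf("  note: %d weighted draws fell back to the uniform distribution\n",
                x$n_fallback))
  invisible(x)
}
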