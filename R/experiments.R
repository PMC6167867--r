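#' Empirical size/power of the five tests for one scenario
#'
#' Replicates a scenario `n_reps` times.  In each replication a cohort is
#' generated, the log-rank and stratified log-rank comparators are run on
#' the true event times, and the multiple-imputation score tests (uniform
#' and/or NPMLE-weighted, each with additive and subtractive variance) are
#' run on the interval-censored data.  The row reports the fraction of
#' replications with `p < alpha` per test, together with per-cell
#' Monte-Carlo standard errors `sqrt(p(1-p)/n_reps)`.
#'
#' One child seed per replication is drawn from `cfg$seed`, so a row is
#' reproducible and individual replications can be replayed.  Replications
#' that fail (degenerate cohorts) are logged and excluded; a row with more
#' than 1% failures is flagged invalid.
#'
#' @param cfg an `icie_scenario` from [scenario_config()].
#' @param tests subset of `c("logrank", "stratified", "uniform",
#'   "weighted")` to run (the expensive weighted method can be switched
#'   off).
#' @param alpha significance level (default 0.05; rejection is strict
#'   `p < alpha`).
#' @param progress print a progress message every 200 replications.
#'
#' @return A one-row data.frame of class `icie_table_row` with the scenario
#'   parameters, rejection proportions (`logrank`, `strat_logrank`,
#'   `uniform_add`, `uniform_sub`, `weighted_add`, `weighted_sub`; `NA` for
#'   tests not run), `n_reps`, `n_failed`, `mc_se_*` columns and `valid`.
#' @export
#' @examples
#' cfg <- scenario_config(theta_A = 0.5, m1_A = 2, n_per_group = 30,
#'                        n_reps = 20, seed = 1)
#' run_scenario(cfg, tests = c("logrank", "uniform"))
run_scenario <- function(cfg,
                         tests = c("logrank", "stratified", "uniform",
                                   "weighted"),
                         alpha = 0.05, progress = FALSE) {
  stopifnot(inherits(cfg, "icie_scenario"))
  tests <- match.arg(tests, several.ok = TRUE)
  if (cfg$n_reps < 1L) stop("n_reps must be at least 1")
  set.seed(cfg$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_reps)

  cells <- c("logrank", "strat_logrank", "uniform_add", "uniform_sub",
             "weighted_add", "weighted_sub")
  rej <- matrix(NA, cfg$n_reps, length(cells),
                dimnames = list(NULL, cells))
  failed <- 0L
  for (b in seq_len(cfg$n_reps)) {
    set.seed(rep_seeds[b])
    ok <- tryCatch({
      coh <- generate_cohort(cfg)
      x <- as.integer(coh$group == "A")
      if ("logrank" %in% tests)
        rej[b, "logrank"] <-
          logrank_test(coh$T_true, coh$delta, x)$p < alpha
      if ("stratified" %in% tests)
        rej[b, "strat_logrank"] <-
          stratified_logrank(coh$T_true, coh$delta, x, coh$Z)$p < alpha
      if ("uniform" %in% tests) {
        mt <- mi_test(coh, method = "uniform", M = cfg$M)
        rej[b, "uniform_add"] <- mt$p_add < alpha
        rej[b, "uniform_sub"] <- mt$p_sub < alpha
      }
      if ("weighted" %in% tests) {
        mt <- mi_test(coh, method = "weighted", M = cfg$M)
        rej[b, "weighted_add"] <- mt$p_add < alpha
        rej[b, "weighted_sub"] <- mt$p_sub < alpha
      }
      TRUE
    }, error = function(e) {
      message(sprintf("replication %d failed: %s", b, conditionMessage(e)))
      FALSE
    })
    if (!ok) failed <- failed + 1L
    if (progress && b %% 200L == 0L)
      message(sprintf("  replication %d/%d", b, cfg$n_reps))
  }
  prop <- colMeans(rej, na.rm = TRUE)
  prop[!is.finite(prop)] <- NA_real_
  n_eff <- cfg$n_reps - failed
  mc_se <- sqrt(prop * (1 - prop) / n_eff)
  row <- data.frame(theta_A = cfg$theta_A, theta_B = cfg$theta_B,
                    m0_A = 1 / cfg$lambda0_A, m0_B = 1 / cfg$lambda0_B,
                    m1_A = cfg$m1_A, m1_B = cfg$m1_B,
                    c_p = cfg$c_p, n_per_group = cfg$n_per_group,
                    t(prop), n_reps = n_eff, n_failed = failed,
                    t(stats::setNames(mc_se, paste0("mc_se_", cells))),
                    valid = failed <= 0.01 * cfg$n_reps)
  class(row) <- c("icie_table_row", class(row))
  row
}

#' Run a table of scenarios from a configuration file
#'
#' Reads a YAML (or JSON) configuration listing scenarios, runs each with
#' [run_scenario()] and binds the rows.  The file has an optional
#' `defaults` mapping and a `scenarios` list; each scenario entry may set
#' any [scenario_config()] argument and inherits the rest from the
#' defaults.
#'
#' @param config path to the configuration file, or an already-parsed list.
#' @param reps optional override of `n_reps` for every scenario (smoke
#'   runs).
#' @param seed optional override of the root seed; scenario `i` uses
#'   `seed + i - 1`.
#' @param tests passed to [run_scenario()].
#' @param out optional path: the table is written there as CSV.
#' @param progress print one message per scenario.
#'
#' @return A data.frame with one row per scenario (see [run_scenario()]).
#' @export
run_tables <- function(config, reps = NULL, seed = NULL,
                       tests = c("logrank", "stratified", "uniform",
                                 "weighted"),
                       out = NULL, progress = TRUE) {
  cfg_list <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg_list$scenarios) || length(cfg_list$scenarios) == 0L)
    stop("configuration must contain a non-empty 'scenarios' list")
  defaults <- cfg_list$defaults %||% list()
  rows <- vector("list", length(cfg_list$scenarios))
  for (i in seq_along(cfg_list$scenarios)) {
    sc <- cfg_list$scenarios[[i]]
    if (!is.list(sc))
      stop(sprintf("scenario %d is not a mapping", i))
    args <- utils::modifyList(defaults, sc)
    if (!is.null(reps)) args$n_reps <- reps
    if (!is.null(seed)) args$seed <- seed + i - 1L
    cfg <- tryCatch(do.call(scenario_config, args),
                    error = function(e)
                      stop(sprintf("scenario %d: %s", i,
                                   conditionMessage(e)), call. = FALSE))
    if (progress)
      message(sprintf("scenario %d/%d: theta = (%.2g, %.2g), m1 = (%.3g, %.3g), c_p = %.2g, n = %d",
                      i, length(cfg_list$scenarios), cfg$theta_A, cfg$theta_B,
                      cfg$m1_A, cfg$m1_B, cfg$c_p, cfg$n_per_group))
    rows[[i]] <- run_scenario(cfg, tests = tests)
  }
  tab <- do.call(rbind, rows)
  if (!is.null(out)) utils::write.csv(tab, out, row.names = FALSE)
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
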