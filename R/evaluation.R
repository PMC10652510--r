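# Simulation bench: parameter recovery of the risk-set-matched conditional
# odds ratio, and the bias of the naive ever-versus-never comparison under
# resuscitation-time confounding.

#' Naive ever-versus-never treatment estimator
#'
#' The comparator that risk-set matching is designed to replace: a 2x2 table
#' of ever-ECPR versus never-ECPR against the binary 30-day outcome, ignoring
#' treatment timing. Patients must survive in arrest long enough to be
#' treated, so this estimator carries resuscitation-time (immortal-time)
#' bias whenever time in arrest predicts outcome.
#'
#' @param x a `cohort`.
#' @param outcome `"survival_30d"` or `"cpc_1_2"`.
#' @return list with `log_or`, `or`, `se`, `ci_low`, `ci_high`, the 2x2
#'   counts, and `continuity_corrected` (TRUE when 0.5 was added to empty
#'   cells, which is flagged rather than silent).
#' @export
naive_estimator <- function(x, outcome = c("survival_30d", "cpc_1_2")) {
  outcome <- match.arg(outcome)
  treated <- x$timelines$disposition %in% "ECPR"
  y <- x$timelines[[outcome]]
  if (!any(treated) || all(treated))
    stop("need both ever-treated and never-treated patients")
  a <- sum(treated & y); b <- sum(treated & !y)
  c_ <- sum(!treated & y); d <- sum(!treated & !y)
  cc <- any(c(a, b, c_, d) == 0)
  if (cc) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  log_or <- log(a * d / (b * c_))
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  list(log_or = log_or, or = exp(log_or), se = se,
       ci_low = exp(log_or - qnorm(0.975) * se),
       ci_high = exp(log_or + qnorm(0.975) * se),
       counts = c(treated_event = a, treated_no = b,
                  control_event = c_, control_no = d),
       continuity_corrected = cc)
}

#' Bench preset: a single-stratum cohort generator
#'
#' An all-shockable configuration with the eligibility-violation rates set to
#' zero, so every simulated patient enters the analysis and the fitted
#' propensity model matches the covariates that drive treatment timing in the
#' generator. Treatment timing depends on prognosis through observed
#' covariates (age, witnessed status); [bias_scenario()] adds the latent
#' pathway on top.
#'
#' @param n patients per replicate.
#' @param beta_treat true conditional log-odds effect of ECPR on survival.
#' @param seed integer seed.
#' @return a `sim_config`.
#' @export
bench_config <- function(n = 2000, beta_treat = 0, seed = 1) {
  sim_config(
    n = n, seed = seed, beta_treat = beta_treat,
    covariate_params = list(
      rhythm_probs = c(VF_VT = 1, PEA = 0, asystole = 0),
      age_mean = 63, n_hospitals = 6,
      p_no_resuscitation = 0, p_external_cause = 0,
      p_no_arrest_on_contact = 0, p_rosc_sustained = 0))
}

.bench_covariates <- c("sex", "age", "witnessed", "bystander_cpr",
                       "prehosp_adrenaline_n", "call_to_hospital_min",
                       "defib_by", "intub_by", "adren_by")

#' Run the estimator bench
#'
#' Per replicate: simulate a cohort, apply the eligibility filter, optionally
#' inject and impute missingness (when the config carries a `missingness`
#' spec), fit the time-dependent propensity model, match, and estimate the
#' matched conditional log-OR alongside the naive ever-versus-never log-OR.
#' Replicate-level failures (separation, no matches, no discordant pairs) are
#' counted and logged, not silently dropped.
#'
#' @param config a `sim_config` (see [bench_config()]); its `beta_treat` is
#'   the recovery target (the configured conditional pair-level log-OR).
#' @param n_replicates number of replicates.
#' @param base_seed integer; replicate seeds are drawn from it.
#' @param covariates propensity-model covariates (default: the bench set
#'   matching the generator's treatment-timing drivers).
#' @param caliper_k caliper width in score-SD units.
#' @return object of class `bench_result`: `summary` (per-estimator mean
#'   log-OR, SD, absolute bias versus truth, 95% CI coverage, replicate
#'   counts), `truth`, `replicates` (per-replicate estimates) and `failures`.
#' @export
run_bench <- function(config, n_replicates = 200, base_seed = 1,
                      covariates = .bench_covariates, caliper_k = 0.2) {
  stopifnot(inherits(config, "sim_config"), n_replicates >= 1)
  set.seed(base_seed)
  rep_seeds <- sample.int(2^31 - 1, n_replicates)
  truth <- config$beta_treat
  rows_out <- vector("list", n_replicates)
  failures <- character(0)
  for (i in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- rep_seeds[i]
    res <- tryCatch({
      sim <- simulate_cohort(cfg)
      elig <- apply_exclusion_criteria(sim$cohort)$eligible
      if (!is.null(cfg$missingness)) {
        elig <- inject_missingness(elig, cfg$missingness,
                                   seed = rep_seeds[i])
        elig <- impute_missing(elig, seed = rep_seeds[i])$cohort
      }
      pmt <- build_person_minute_table(elig)
      fit <- fit_td_finegray(pmt, covariates = covariates)
      rs <- build_risk_sets(elig$timelines)
      m <- sequential_match(rs, ps_scores(fit, pmt), caliper_k = caliper_k,
                            score_sd = fit$score_sd, seed = rep_seeds[i])
      if (!nrow(m$pairs)) stop("no in-caliper matches")
      eff <- conditional_logit_1to1(
        pair_outcomes(m, elig$timelines, "survival_30d"))
      if (eff$estimate_type != "MLE") stop("zero discordant cell")
      nv <- naive_estimator(elig, "survival_30d")
      data.frame(
        replicate = i, seed = rep_seeds[i],
        matched_log_or = eff$log_or,
        matched_cover = log(eff$ci_low) <= truth &
          truth <= log(eff$ci_high),
        naive_log_or = nv$log_or,
        naive_cover = log(nv$ci_low) <= truth & truth <= log(nv$ci_high),
        n_pairs = eff$n_pairs)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, sprintf("replicate %d: %s", i, res))
    } else {
      rows_out[[i]] <- res
    }
  }
  reps <- do.call(rbind, rows_out)
  if (is.null(reps)) stop("all replicates failed; first failure: ",
                          failures[1])
  summarize <- function(est, cov) data.frame(
    mean_log_or = mean(est), sd_log_or = sd(est),
    abs_bias = abs(mean(est) - truth), coverage = mean(cov))
  summary <- cbind(
    estimator = c("naive", "riskset_matched"),
    rbind(summarize(reps$naive_log_or, reps$naive_cover),
          summarize(reps$matched_log_or, reps$matched_cover)))
  summary$n_replicates <- n_replicates
  summary$n_used <- nrow(reps)
  summary$n_failed <- n_replicates - nrow(reps)
  structure(list(summary = summary, truth = truth, replicates = reps,
                 failures = failures, base_seed = base_seed),
            class = "bench_result")
}

#' @export
print.bench_result <- function(x, ...) {
  cat(sprintf("<bench_result> truth (conditional log-OR): %.4f, %d/%d replicates used\n",
              x$truth, x$summary$n_used[1], x$summary$n_replicates[1]))
  print(x$summary, row.names = FALSE, digits = 4)
  if (length(x$failures)) cat(length(x$failures), "failure(s) logged\n")
  invisible(x)
}
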