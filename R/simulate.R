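# Seeded generator of registry-like OHCA cohorts with known ground truth.
#
# Terminal events (ECPR start, ROSC, termination of resuscitation) compete on
# a discrete 0-119 minute clock: at each minute one categorical draw selects
# at most one terminal event, with per-minute hazards that are inverse-logit
# linear functions of baseline covariates, elapsed time, the time-dependent
# in-hospital intervention indicators, and an optional latent prognosis
# variable. Survivors of the loop are administratively censored at 120.

default_covariate_params <- function() list(
  p_male = 0.62,
  age_mean = 70, age_sd = 15, age_min = 18, age_max = 100,
  rhythm_probs = c(VF_VT = 0.10, PEA = 0.28, asystole = 0.62),
  p_witnessed = c(shockable = 0.60, non_shockable = 0.40),
  p_bystander_cpr = 0.48,
  p_bystander_aed = c(shockable = 0.06, non_shockable = 0.015),
  p_physician_staffed = 0.10,
  p_shock_by_paramedic = c(shockable = 0.95, non_shockable = 0.05),
  airway_probs = c(intubation = 0.10, SGA = 0.48, none = 0.42),
  adrenaline_probs = c(0.70, 0.09, 0.08, 0.06, 0.04, 0.03),
  p_prehosp_rosc = 0.05,
  call_meanlog = log(32), call_sdlog = 0.28,
  n_hospitals = 8,
  p_no_resuscitation = 0.01, p_external_cause = 0.03,
  p_no_arrest_on_contact = 0.02, p_rosc_sustained = 0.02
)

# Linear predictors use derived regressors: age_c = (age - 65)/15,
# call_c = (call_to_hospital_min - 32)/10, shockable = 1{VF/VT}, male,
# witnessed, bystander_cpr, prehosp_rosc (0/1).
default_hazard_params <- function() list(
  # calibrated so that a sustained-arrest cohort resolves as roughly 45-50%
  # ROSC (mostly early), 35-40% termination (mostly after 30-60 minutes of
  # effort) and 10-15% ECPR with a median start around 20-25 minutes
  ecpr = list(intercept = -6.7, time = 0.01,
              coefs = c(age_c = -0.25, witnessed = 0.25, shockable = 0.7),
              td = c(defib_by = 0, intub_by = 0, adren_by = 0.3),
              latent = 0.8, min_time = 5L),
  rosc = list(intercept = -4.6, time = -0.03,
              coefs = c(age_c = -0.3, witnessed = 0.3, shockable = 0.5,
                        bystander_cpr = 0.2),
              td = c(defib_by = 0.15, intub_by = 0, adren_by = 0.1),
              latent = -0.8, min_time = 0L),
  death = list(intercept = -6.5, time = 0.075,
               coefs = c(age_c = 0.3),
               td = c(defib_by = 0, intub_by = 0, adren_by = 0),
               latent = 0.2, min_time = 0L)
)

# in-hospital defibrillation is far more frequent when the initial rhythm is
# shockable, but still occurs in non-shockable arrests (rhythm conversion)
default_intervention_params <- function() list(
  defib = list(hazard = 0.04, hazard_nonshockable = 0.008, once = FALSE),
  intubation = list(hazard = 0.05, once = TRUE),
  adrenaline = list(hazard = 0.08, once = FALSE)
)

default_outcome_params <- function() list(
  intercept = -1.8,
  coefs = c(age_c = -0.5, witnessed = 0.4, bystander_cpr = 0.2,
            shockable = 0.6),
  latent = -1.0,
  decay = 0,            # optional per-minute decay of the treatment benefit
  cpc_intercept = -1.0, # favourable neurology given 30-day survival
  cpc_coefs = c(age_c = -0.3),
  cpc_treat = 0
)

#' Simulation configuration for synthetic registry cohorts
#'
#' Defaults approximate a mixed-rhythm OHCA registry: covariate marginals in
#' the range reported for large Japanese registries, minute-resolution
#' competing terminal events over a 0-120 minute horizon, prognosis-dependent
#' ECPR timing, and logistic 30-day outcomes with a configurable true
#' conditional treatment log-odds (`beta_treat`). The latent prognosis
#' variable is inert unless `latent_sd > 0` (see [bias_scenario()]).
#'
#' @param n number of patients.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param beta_treat true conditional log-odds effect of ECPR on 30-day
#'   survival (0 = exact null: potential outcomes identical patient-wise).
#' @param latent_sd SD of the latent prognosis variable (0 disables it).
#' @param covariate_params,hazard_params,intervention_params,outcome_params
#'   named lists overriding entries of the documented defaults.
#' @param missingness optional spec for [inject_missingness()], applied by
#'   [run_pipeline()]/[run_bench()] when present: list with `mechanism`
#'   ("MCAR" or "MAR") and `rates` (named per-field probabilities).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n = 2000, seed = 1, beta_treat = 0, latent_sd = 0,
                       covariate_params = list(), hazard_params = list(),
                       intervention_params = list(), outcome_params = list(),
                       missingness = NULL) {
  stopifnot(n >= 1, is.numeric(seed))
  cfg <- list(
    n = as.integer(n), seed = as.integer(seed),
    beta_treat = beta_treat, latent_sd = latent_sd,
    covariate_params = modifyList(default_covariate_params(),
                                  covariate_params),
    hazard_params = modifyList(default_hazard_params(), hazard_params),
    intervention_params = modifyList(default_intervention_params(),
                                     intervention_params),
    outcome_params = modifyList(default_outcome_params(), outcome_params),
    missingness = missingness)
  class(cfg) <- "sim_config"
  cfg
}

#' Resuscitation-time-bias scenario preset
#'
#' Returns a configuration in which a latent prognosis variable raises the
#' per-minute ECPR hazard and lowers the ROSC hazard (clinicians escalate on
#' refractory patients) while also lowering 30-day survival, with
#' `beta_treat = 0`. The naive ever-versus-never comparison is then biased
#' under the null, while risk-set matching, which compares patients still in
#' arrest at the same minute, largely removes the selection.
#'
#' @param config a `sim_config` to modify (its `beta_treat` is forced to 0).
#' @param effect nonnegative multiplier of the latent pathway; 0 reduces to
#'   the base configuration.
#' @return a `sim_config`.
#' @export
bias_scenario <- function(config = sim_config(), effect = 1) {
  stopifnot(inherits(config, "sim_config"), effect >= 0)
  config$beta_treat <- 0
  if (effect == 0) {
    # a zero-strength latent pathway is the base configuration: the latent
    # coefficients are inert when latent_sd = 0
    config$latent_sd <- 0
    return(config)
  }
  config$latent_sd <- 1
  config$hazard_params$ecpr$latent <- 0.8 * effect
  config$hazard_params$rosc$latent <- -0.8 * effect
  config$hazard_params$death$latent <- 0.2 * effect
  config$outcome_params$latent <- -1.0 * effect
  config
}

# regressor matrix for the hazard / outcome linear predictors
derived_regressors <- function(rec) {
  cbind(age_c = (rec$age - 65) / 15,
        call_c = (rec$call_to_hospital_min - 32) / 10,
        shockable = as.numeric(rec$initial_rhythm == "VF_VT"),
        male = as.numeric(rec$sex == "male"),
        witnessed = as.numeric(rec$witnessed),
        bystander_cpr = as.numeric(rec$bystander_cpr),
        prehosp_rosc = as.numeric(rec$prehosp_rosc))
}

fixed_lp <- function(par, reg, latent) {
  lp <- rep(par$intercept, nrow(reg))
  for (nm in names(par$coefs)) {
    if (!nm %in% colnames(reg)) stop("unknown hazard regressor: ", nm)
    lp <- lp + par$coefs[[nm]] * reg[, nm]
  }
  if (!is.null(par$latent)) lp <- lp + par$latent * latent
  lp
}

#' Simulate a registry-like cohort with known ground truth
#'
#' Draws covariates, iterates minutes 0..119 drawing intervention onsets and
#' a single terminal event per minute among ECPR / ROSC / termination (first
#' event wins; mutually exclusive within a minute via one categorical draw),
#' censors survivors at 120, and draws 30-day outcomes from a logistic model
#' given realized treatment. Potential outcomes under treated/untreated are
#' generated with a shared uniform, so `beta_treat = 0` yields identical
#' potential outcomes patient-wise and survival is monotone in `beta_treat`.
#'
#' Terminal hazards at minute t use the intervention indicators as of strictly
#' before t, matching the half-open convention of the propensity model.
#'
#' @param config a [sim_config()].
#' @return list with `cohort` (a [cohort()]) and `truth` (data.frame with the
#'   latent prognosis value and both potential outcomes per patient, plus a
#'   `beta_treat` attribute).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n
  cp <- config$covariate_params
  hz <- config$hazard_params
  ip <- config$intervention_params
  op <- config$outcome_params

  rhythm <- sample(names(cp$rhythm_probs), n, TRUE,
                   prob = cp$rhythm_probs / sum(cp$rhythm_probs))
  shock <- rhythm == "VF_VT"
  pick <- function(p) ifelse(shock, p[["shockable"]], p[["non_shockable"]])
  age <- as.integer(pmin(pmax(round(rnorm(n, cp$age_mean, cp$age_sd)),
                              cp$age_min), cp$age_max))
  rec <- data.frame(
    id = sprintf("p%05d", seq_len(n)),
    sex = ifelse(runif(n) < cp$p_male, "male", "female"),
    age = age,
    witnessed = runif(n) < pick(cp$p_witnessed),
    bystander_cpr = runif(n) < cp$p_bystander_cpr,
    initial_rhythm = rhythm,
    bystander_aed = runif(n) < pick(cp$p_bystander_aed),
    physician_staffed = runif(n) < cp$p_physician_staffed,
    shock_by_paramedic = runif(n) < pick(cp$p_shock_by_paramedic),
    advanced_airway = sample(c("intubation", "SGA", "none"), n, TRUE,
                             prob = cp$airway_probs),
    prehosp_adrenaline_n = sample(0:5, n, TRUE, prob = cp$adrenaline_probs),
    prehosp_rosc = runif(n) < cp$p_prehosp_rosc,
    call_to_hospital_min = pmax(5L, as.integer(round(
      rlnorm(n, cp$call_meanlog, cp$call_sdlog)))),
    hospital_id = sample(sprintf("h%02d", seq_len(cp$n_hospitals)), n, TRUE,
                         prob = seq(2, 1, length.out = cp$n_hospitals)),
    resuscitation_attempted = runif(n) >= cp$p_no_resuscitation,
    arrest_cause = ifelse(runif(n) < cp$p_external_cause,
                          "external", "medical"),
    arrest_on_ems_contact = runif(n) >= cp$p_no_arrest_on_contact,
    rosc_before_arrival_sustained = runif(n) < cp$p_rosc_sustained,
    stringsAsFactors = FALSE)
  rec <- rec[, names(.record_cols)]  # canonical dictionary column order
  latent <- if (config$latent_sd > 0) rnorm(n, 0, config$latent_sd)
            else numeric(n)
  reg <- derived_regressors(rec)
  lp_e <- fixed_lp(hz$ecpr, reg, latent)
  lp_r <- fixed_lp(hz$rosc, reg, latent)
  lp_d <- fixed_lp(hz$death, reg, latent)

  disposition <- rep(NA_character_, n)
  disp_min <- rep(HORIZON_MIN, n)
  intub_min <- rep(NA_integer_, n)
  ev_id <- list(defib = integer(0), adren = integer(0))
  ev_t <- list(defib = integer(0), adren = integer(0))
  td <- matrix(0, n, 3, dimnames = list(NULL,
                                        c("defib_by", "intub_by", "adren_by")))
  active <- rep(TRUE, n)
  for (t in 0:(HORIZON_MIN - 1)) {
    idx <- which(active)
    if (!length(idx)) break
    td_e <- td[idx, , drop = FALSE] %*% hz$ecpr$td
    td_r <- td[idx, , drop = FALSE] %*% hz$rosc$td
    td_d <- td[idx, , drop = FALSE] %*% hz$death$td
    he <- plogis(lp_e[idx] + hz$ecpr$time * t + td_e)
    hr <- plogis(lp_r[idx] + hz$rosc$time * t + td_r)
    hd <- plogis(lp_d[idx] + hz$death$time * t + td_d)
    if (t < hz$ecpr$min_time) he[] <- 0
    if (t < hz$rosc$min_time) hr[] <- 0
    if (t < hz$death$min_time) hd[] <- 0
    tot <- he + hr + hd
    if (any(tot > 1))
      stop("config error: per-minute hazards sum above 1 at minute ", t)
    u <- runif(length(idx))
    ev <- ifelse(u < he, "ECPR",
                 ifelse(u < he + hr, "ROSC",
                        ifelse(u < tot, "death", NA)))
    # in-hospital intervention onsets during minute t (affect hazards from
    # minute t+1 onward, per the half-open convention)
    u_def <- runif(length(idx)); u_int <- runif(length(idx))
    u_adr <- runif(length(idx))
    def_rate <- ifelse(shock[idx], ip$defib$hazard,
                       ip$defib$hazard_nonshockable %||% ip$defib$hazard)
    def_now <- u_def < def_rate &
      !(ip$defib$once & td[idx, "defib_by"] == 1)
    int_now <- u_int < ip$intubation$hazard &
      !(ip$intubation$once & td[idx, "intub_by"] == 1) &
      rec$advanced_airway[idx] != "intubation"
    adr_now <- u_adr < ip$adrenaline$hazard &
      !(ip$adrenaline$once & td[idx, "adren_by"] == 1)
    if (any(def_now)) {
      ev_id$defib <- c(ev_id$defib, idx[def_now])
      ev_t$defib <- c(ev_t$defib, rep(t, sum(def_now)))
    }
    if (any(int_now)) intub_min[idx[int_now]] <- t
    if (any(adr_now)) {
      ev_id$adren <- c(ev_id$adren, idx[adr_now])
      ev_t$adren <- c(ev_t$adren, rep(t, sum(adr_now)))
    }
    td[idx[def_now], "defib_by"] <- 1
    td[idx[int_now], "intub_by"] <- 1
    td[idx[adr_now], "adren_by"] <- 1
    done <- !is.na(ev)
    if (any(done)) {
      disposition[idx[done]] <- ev[done]
      disp_min[idx[done]] <- t
      active[idx[done]] <- FALSE
    }
  }
  disposition[is.na(disposition)] <- "censored"

  collect <- function(which) {
    out <- rep("", n)
    if (length(ev_id[[which]])) {
      sp <- split(ev_t[[which]], ev_id[[which]])
      out[as.integer(names(sp))] <- vapply(sp, function(v)
        paste(sort(v), collapse = ";"), character(1))
    }
    out
  }

  treated <- disposition == "ECPR"
  lp_out <- fixed_lp(list(intercept = op$intercept, coefs = op$coefs,
                          latent = op$latent), reg, latent)
  eff <- rep(config$beta_treat, n)
  if (op$decay > 0 && any(treated))
    eff[treated] <- pmax(0, config$beta_treat -
                           op$decay * disp_min[treated])
  p1 <- plogis(lp_out + eff)
  p0 <- plogis(lp_out)
  u_out <- runif(n)
  y1 <- u_out < p1
  y0 <- u_out < p0
  survival <- ifelse(treated, y1, y0)
  lp_cpc <- fixed_lp(list(intercept = op$cpc_intercept, coefs = op$cpc_coefs,
                          latent = op$latent), reg, latent)
  cpc <- survival & (runif(n) < plogis(lp_cpc + op$cpc_treat * treated))

  tl <- data.frame(
    id = rec$id,
    defib_minutes = collect("defib"),
    intubation_minute = intub_min,
    adrenaline_minutes = collect("adren"),
    ecpr_minute = ifelse(treated, disp_min, NA_integer_),
    disposition = disposition,
    disposition_minute = disp_min,
    survival_30d = survival,
    cpc_1_2 = cpc,
    stringsAsFactors = FALSE)
  truth <- data.frame(id = rec$id, latent = latent, y0 = y0, y1 = y1,
                      treated = treated, stringsAsFactors = FALSE)
  attr(truth, "beta_treat") <- config$beta_treat
  list(cohort = cohort(rec, tl), truth = truth)
}

.maskable_fields <- setdiff(names(.record_cols), c("id", "hospital_id"))

#' Inject missingness into cohort covariates
#'
#' MCAR masks each cell independently; MAR makes the masking probability
#' depend on the (always observed) disposition minute via a logistic link
#' centred so the field-level rate is approximately the configured one.
#' Event times, dispositions and outcomes are never masked.
#'
#' @param x a `cohort`.
#' @param spec list with `mechanism` ("MCAR" or "MAR") and `rates`, a named
#'   vector of per-field probabilities in \[0, 1\].
#' @param seed integer seed.
#' @return the cohort with `NA`s inserted.
#' @export
inject_missingness <- function(x, spec, seed = 1) {
  stopifnot(is.list(spec), !is.null(spec$rates))
  mech <- match.arg(spec$mechanism, c("MCAR", "MAR"))
  rates <- spec$rates
  bad <- setdiff(names(rates), .maskable_fields)
  if (length(bad))
    stop("config error: field '", bad[1],
         "' cannot be masked (timeline fields and ids are never missing)")
  if (any(rates < 0 | rates > 1)) stop("config error: rates must be in [0,1]")
  set.seed(seed)
  n <- nrow(x$records)
  shift <- if (mech == "MAR") {
    dm <- x$timelines$disposition_minute
    0.05 * (dm - mean(dm))
  } else 0
  for (f in names(rates)) {
    r <- rates[[f]]
    p <- if (r <= 0) rep(0, n) else if (r >= 1) rep(1, n)
         else plogis(qlogis(r) + shift)
    x$records[[f]][runif(n) < p] <- NA
  }
  x
}
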