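# Person-minute analysis table and the time-dependent propensity model:
# a subdistribution-hazard (Fine-Gray type) partial likelihood for ECPR
# initiation, with ROSC/termination as competing risks, minute-resolution
# time-dependent in-hospital covariates, and administrative censoring at 120
# minutes. Within the 0-120 window the only censoring is administrative at a
# fixed time, so the inverse-censoring weights of competing-event patients
# are identically 1 and their covariates are carried forward frozen at the
# last pre-event value.

.ps_x_cols <- c("sex", "age", "witnessed", "bystander_cpr", "initial_rhythm",
                "bystander_aed", "physician_staffed", "shock_by_paramedic",
                "advanced_airway", "prehosp_adrenaline_n", "prehosp_rosc",
                "call_to_hospital_min", "ecpr_volume")
.ps_td_cols <- c("defib_by", "intub_by", "adren_by")

#' Default covariate set of the time-dependent propensity model
#'
#' Time-independent: sex, age, witnessed status, bystander CPR, initial
#' rhythm, bystander AED use, physician-staffed unit, defibrillation by
#' paramedics, advanced airway type, pre-hospital adrenaline count,
#' pre-hospital ROSC, call-to-hospital time, and hospital ECPR-volume
#' category. Time-dependent: in-hospital defibrillation, intubation and
#' adrenaline indicators.
#'
#' @param include_rhythm drop `initial_rhythm` with `FALSE` — required in a
#'   shockable-only stratum, where the rhythm is constant by definition.
#' @param extra_drop further covariates to drop by name.
#' @return character vector of column names.
#' @export
ps_covariates <- function(include_rhythm = TRUE, extra_drop = character(0)) {
  out <- c(.ps_x_cols, .ps_td_cols)
  if (!include_rhythm) out <- setdiff(out, "initial_rhythm")
  setdiff(out, extra_drop)
}

#' Build the person-minute analysis table
#'
#' Expands a single-stratum cohort to one row per patient-minute for
#' t = 0..min(disposition minute, 119). The time-dependent indicators follow
#' the half-open convention: an intervention at minute s switches the
#' indicator on from row s+1 (events during minute t cannot predict treatment
#' at minute t). The event code is `"ECPR"` or `"competing"` on the
#' disposition-minute row, or `"censored"` on the final row of patients still
#' under resuscitation at the horizon; all rows carry subdistribution weight
#' 1 (administrative-only censoring).
#'
#' @param x a `cohort`, eligible and imputed, with a single stratum. The
#'   `ecpr_volume` column is derived from the cohort if absent.
#' @return data.frame of class `person_minute_table` with columns `id`,
#'   `minute`, `event`, `weight`, the time-independent covariates and the
#'   three time-dependent indicators; the stratum is kept as an attribute.
#' @export
build_person_minute_table <- function(x) {
  stopifnot(inherits(x, "cohort"))
  if (x$stratum == "mixed")
    stop("person-minute tables are built per rhythm stratum; ",
         "run stratify_by_rhythm() first")
  if (!"ecpr_volume" %in% names(x$records)) x <- assign_hospital_volume(x)
  rec <- x$records; tl <- x$timelines
  if (any(tl$disposition_minute == 0))
    stop("disposition_minute = 0 present; apply_exclusion_criteria() first")
  xcols <- intersect(.ps_x_cols, names(rec))
  if (anyNA(rec[xcols]))
    stop("missing covariate values; impute before building the table")

  last <- pmin(tl$disposition_minute, HORIZON_MIN - 1L)
  n_rows <- last + 1L
  ridx <- rep(seq_len(nrow(rec)), n_rows)
  minute <- sequence(n_rows) - 1L

  first_defib <- first_minute(tl$defib_minutes)
  first_adren <- first_minute(tl$adrenaline_minutes)
  inf_na <- function(v) ifelse(is.na(v), Inf, v)
  out <- data.frame(id = rec$id[ridx], minute = minute,
                    stringsAsFactors = FALSE)
  out$event <- "none"
  is_ecpr <- tl$disposition == "ECPR"
  is_comp <- tl$disposition %in% c("ROSC", "death")
  at_disp <- minute == tl$disposition_minute[ridx]
  out$event[at_disp & is_ecpr[ridx]] <- "ECPR"
  out$event[at_disp & is_comp[ridx]] <- "competing"
  out$event[minute == HORIZON_MIN - 1L &
              (tl$disposition == "censored")[ridx]] <- "censored"
  out$weight <- 1
  for (f in xcols) out[[f]] <- rec[[f]][ridx]
  out$defib_by <- as.numeric(minute > inf_na(first_defib)[ridx])
  out$intub_by <- as.numeric(minute > inf_na(tl$intubation_minute)[ridx])
  out$adren_by <- as.numeric(minute > inf_na(first_adren)[ridx])
  attr(out, "stratum") <- x$stratum
  class(out) <- c("person_minute_table", "data.frame")
  out
}

# reference-coded model matrix over the requested covariates; reference level
# is the first level in the documented dictionary order
ps_model_matrix <- function(rows, covariates, levels_map = NULL) {
  cols <- list()
  store <- list()
  for (f in covariates) {
    v <- rows[[f]]
    if (is.null(v)) stop("layout mismatch: column '", f, "' not in table")
    if (is.numeric(v) || is.logical(v)) {
      cols[[f]] <- as.numeric(v)
      store[[f]] <- NA
    } else {
      lv <- if (!is.null(levels_map)) {
        if (is.null(levels_map[[f]]) || all(is.na(levels_map[[f]])))
          stop("layout mismatch: '", f, "' was numeric at fit time")
        levels_map[[f]]
      } else {
        dict <- .record_levels[[f]]
        if (is.null(dict)) sort(unique(v)) else intersect(dict, unique(v))
      }
      if (!all(v %in% lv))
        stop("layout mismatch: unseen level '", setdiff(v, lv)[1],
             "' in '", f, "'")
      store[[f]] <- lv
      for (l in lv[-1]) cols[[paste(f, l, sep = "_")]] <- as.numeric(v == l)
    }
  }
  m <- do.call(cbind, cols)
  attr(m, "levels_map") <- store
  m
}

#' Fit the time-dependent subdistribution-hazard propensity model
#'
#' Maximizes, by Newton's method with step-halving, the Breslow-tied weighted
#' partial likelihood over ECPR event minutes: at each event minute the
#' treated patient's `exp(eta)` is compared against the subdistribution risk
#' set, which keeps competing-event patients (ROSC or termination) with
#' weight 1 and covariates frozen at their last pre-event value until the
#' 120-minute horizon. With no competing events this reduces exactly to a
#' Cox partial likelihood on the same person-minute data.
#'
#' @param rows a [build_person_minute_table()] result (single stratum).
#' @param covariates covariate columns to include; see [ps_covariates()].
#'   Categorical columns are reference-coded against the first dictionary
#'   level.
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @return object of class `ps_fit`: named `coefficients`, `loglik`,
#'   `grad_norm`, `iterations`, `score_sd` (SD of the linear predictor over
#'   treated patients at their treatment minutes — the caliper scale),
#'   `n_events`, `stratum`, and the covariate layout needed by
#'   [linear_predictor()].
#' @export
fit_td_finegray <- function(rows, covariates = ps_covariates(),
                            tol = 1e-8, max_iter = 100) {
  stopifnot(inherits(rows, "data.frame"))
  ev_rows <- rows$event == "ECPR"
  if (!any(ev_rows)) stop("no ECPR events in the table")
  ev_minutes <- sort(unique(rows$minute[ev_rows]))

  # risk-set membership: every physical row whose minute is an event minute
  # (patients still untreated at that minute), plus the frozen final row of
  # each competing-event patient, replicated for later event minutes
  direct <- which(rows$minute %in% ev_minutes)
  comp <- which(rows$event == "competing")
  comp_rep <- lapply(comp, function(i) {
    later <- ev_minutes[ev_minutes > rows$minute[i]]
    if (!length(later)) return(NULL)
    cbind(row = i, minute = later)
  })
  comp_rep <- do.call(rbind, comp_rep)
  use_rows <- c(direct, comp_rep[, "row"])
  grp_minute <- c(rows$minute[direct], comp_rep[, "minute"])

  mm <- ps_model_matrix(rows[use_rows, , drop = FALSE], covariates)
  levels_map <- attr(mm, "levels_map")
  cn <- colnames(mm)
  degen <- which(apply(mm, 2, function(v) max(v) - min(v)) == 0)
  if (length(degen))
    stop("degenerate covariate: '", cn[degen[1]],
         "' has zero variance over the risk sets")
  w <- rows$weight[use_rows]
  is_ev <- rows$event[use_rows] == "ECPR" &
    rows$minute[use_rows] == grp_minute
  g <- match(grp_minute, ev_minutes)
  d <- as.numeric(rowsum(as.numeric(is_ev), g))  # tied events per minute
  ctr <- colMeans(mm)
  mc <- sweep(mm, 2, ctr)
  xev <- colSums(mc[is_ev, , drop = FALSE])

  p <- ncol(mm)
  beta <- numeric(p)
  loglik_at <- function(eta) {
    emax <- max(eta)
    s0 <- as.numeric(rowsum(w * exp(eta - emax), g))
    list(ll = sum(eta[is_ev]) - sum(d * (log(s0) + emax)), s0 = s0,
         emax = emax)
  }
  eta <- as.numeric(mc %*% beta)
  cur <- loglik_at(eta)
  iterations <- 0L
  grad_norm <- Inf
  for (iter in seq_len(max_iter)) {
    r <- w * exp(eta - cur$emax)
    s0 <- cur$s0
    xbar <- rowsum(mc * r, g) / s0
    grad <- xev - colSums(xbar * d)
    h1 <- crossprod(mc, mc * (r * (d / s0)[g]))
    h2 <- crossprod(xbar * sqrt(d))
    H <- h1 - h2
    grad_norm <- sqrt(sum(grad^2))
    iterations <- iter
    if (grad_norm < tol) break
    step <- tryCatch(solve(H, grad), error = function(e)
      stop("singular information matrix; check for collinear covariates"))
    # step-halving keeps the iterates monotone in the (concave) likelihood
    ok <- FALSE
    for (h in 0:20) {
      cand <- beta + step / 2^h
      eta_c <- as.numeric(mc %*% cand)
      new <- loglik_at(eta_c)
      if (new$ll >= cur$ll - 1e-12) {
        beta <- cand; eta <- eta_c; cur <- new; ok <- TRUE; break
      }
    }
    if (!ok) break
    if (any(abs(beta) > 10) && grad_norm > tol * 10 && iter > 5)
      stop("separation: a coefficient diverged (|beta| > 10) with the ",
           "partial likelihood still increasing")
  }
  if (grad_norm >= tol)
    stop("non-convergence after ", iterations,
         " Newton iterations (|grad| = ", format(grad_norm), ")")
  names(beta) <- cn
  fit <- structure(list(
    coefficients = beta, loglik = cur$ll,
    grad_norm = grad_norm, iterations = iterations,
    n_events = sum(is_ev), covariates = covariates,
    levels_map = levels_map, stratum = attr(rows, "stratum")),
    class = "ps_fit")
  sc <- linear_predictor(fit, rows[rows$event == "ECPR", , drop = FALSE])
  fit$score_sd <- sd(sc)
  if (is.na(fit$score_sd) || fit$score_sd <= 0)
    stop("score_sd is not positive; need >= 2 treated patients with ",
         "distinct scores")
  fit
}

#' @export
print.ps_fit <- function(x, ...) {
  cat(sprintf(
    "<ps_fit> stratum: %s, %d events, loglik %.4f, %d Newton iterations\n",
    x$stratum %||% "?", x$n_events, x$loglik, x$iterations))
  print(round(x$coefficients, 4))
  cat(sprintf("score_sd (caliper scale): %.4f\n", x$score_sd))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Linear predictor (propensity score scale) of a fitted model
#'
#' Returns `beta . [X, Z(t)]` for each row; this log-hazard-scale linear
#' predictor is the matching distance scale, and the caliper is expressed in
#' SDs of it over treated patients at their treatment minutes.
#'
#' @param fit a `ps_fit`.
#' @param rows person-minute rows with the fit's covariate layout.
#' @return numeric vector of scores.
#' @export
linear_predictor <- function(fit, rows) {
  stopifnot(inherits(fit, "ps_fit"))
  mm <- ps_model_matrix(rows, fit$covariates, fit$levels_map)
  if (!identical(colnames(mm), names(fit$coefficients)))
    stop("layout mismatch: model columns differ from the fit")
  as.numeric(mm %*% fit$coefficients)
}

#' Propensity scores for every person-minute row
#'
#' @param fit a `ps_fit`.
#' @param rows a person-minute table.
#' @return data.frame with `id`, `minute`, `score`.
#' @export
ps_scores <- function(fit, rows) {
  data.frame(id = rows$id, minute = rows$minute,
             score = linear_predictor(fit, rows),
             stringsAsFactors = FALSE)
}
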