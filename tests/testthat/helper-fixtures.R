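# Toy-cohort builders and independent oracle implementations used across the
# suite. The oracles are deliberately naive (loops, enumeration, grid search)
# and share no code with the package internals they check.

toy_record <- function(id, ...) {
  rec <- list(
    id = id, sex = "male", age = 60L, witnessed = TRUE,
    bystander_cpr = FALSE, initial_rhythm = "VF_VT", bystander_aed = FALSE,
    physician_staffed = FALSE, shock_by_paramedic = TRUE,
    advanced_airway = "none", prehosp_adrenaline_n = 0L,
    prehosp_rosc = FALSE, call_to_hospital_min = 30L, hospital_id = "h1",
    arrest_cause = "medical", resuscitation_attempted = TRUE,
    arrest_on_ems_contact = TRUE, rosc_before_arrival_sustained = FALSE)
  utils::modifyList(rec, list(...))
}

toy_timeline <- function(id, disposition = "censored", minute = 120L,
                         ecpr = NA_integer_, survival = FALSE, cpc = FALSE,
                         defib = "", intub = NA_integer_, adren = "") {
  list(id = id, defib_minutes = defib, intubation_minute = intub,
       adrenaline_minutes = adren, ecpr_minute = ecpr,
       disposition = disposition, disposition_minute = as.integer(minute),
       survival_30d = survival, cpc_1_2 = cpc)
}

toy_cohort <- function(records, timelines, validate = TRUE) {
  bind <- function(rows, template) {
    if (!length(rows))
      return(as.data.frame(template, stringsAsFactors = FALSE)[0, ])
    do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  cohort(bind(records, toy_record("template")),
         bind(timelines, toy_timeline("template")),
         validate = validate)
}

# a matched cohort with prescribed outcome counts, for printed-count checks
counts_pairs <- function(n_pairs, treated_events, control_events) {
  pairs <- data.frame(
    minute = 10L,
    treated_id = sprintf("t%04d", seq_len(n_pairs)),
    control_id = sprintf("c%04d", seq_len(n_pairs)),
    treated_score = 0, control_score = 0, distance = 0,
    stringsAsFactors = FALSE)
  tl <- data.frame(
    id = c(pairs$treated_id, pairs$control_id),
    survival_30d = c(seq_len(n_pairs) <= treated_events,
                     seq_len(n_pairs) <= control_events),
    stringsAsFactors = FALSE)
  tl$cpc_1_2 <- tl$survival_30d
  list(pairs = pairs, timelines = tl)
}

# brute-force risk sets: direct set comprehension over every id x minute
oracle_risk_sets <- function(tl) {
  ecpr <- stats::setNames(tl$ecpr_minute, tl$id)
  out <- list()
  for (t in 0:119) {
    treated <- tl$id[!is.na(tl$ecpr_minute) & tl$ecpr_minute == t]
    if (!length(treated)) next
    cand <- character(0)
    for (i in seq_len(nrow(tl))) {
      still <- tl$disposition_minute[i] > t
      untreated <- is.na(tl$ecpr_minute[i]) || tl$ecpr_minute[i] > t
      if (still && untreated) cand <- c(cand, tl$id[i])
    }
    out[[length(out) + 1]] <- list(minute = t, treated_ids = treated,
                                   candidate_ids = cand)
  }
  out
}

# brute-force sequential matcher following the documented contract: one
# set.seed at entry, minutes ascending, one sample() per risk set with > 1
# treated, nearest in-caliper candidate, ties to the smaller control id,
# with replacement
oracle_match <- function(risk_sets, scores, caliper_k, score_sd, seed) {
  sc <- function(id, minute) {
    v <- scores$score[scores$id == id & scores$minute == minute]
    if (length(v) != 1) stop("missing score")
    v
  }
  set.seed(seed)
  pairs <- NULL
  unmatched <- character(0)
  for (rs in risk_sets[order(sapply(risk_sets, `[[`, "minute"))]) {
    treated <- rs$treated_ids
    if (length(treated) > 1) treated <- sample(treated)
    for (tid in treated) {
      ts <- sc(tid, rs$minute)
      best <- NULL
      for (cid in sort(rs$candidate_ids)) {
        d <- abs(sc(cid, rs$minute) - ts)
        if (d <= caliper_k * score_sd && (is.null(best) || d < best$d))
          best <- list(cid = cid, d = d)
      }
      if (is.null(best)) unmatched <- c(unmatched, tid)
      else pairs <- rbind(pairs, data.frame(
        minute = rs$minute, treated_id = tid, control_id = best$cid,
        distance = best$d, stringsAsFactors = FALSE))
    }
  }
  list(pairs = pairs, unmatched = unmatched)
}

# small random single-stratum cohorts for the matcher equivalence checks
random_small_cohort <- function(seed, n = 15) {
  set.seed(seed)
  recs <- lapply(seq_len(n), function(i)
    toy_record(sprintf("p%02d", i), age = sample(30:85, 1),
               witnessed = runif(1) < 0.5))
  tls <- lapply(seq_len(n), function(i) {
    id <- sprintf("p%02d", i)
    u <- runif(1)
    if (u < 0.35) {
      t <- sample(1:30, 1)
      toy_timeline(id, "ECPR", t, ecpr = t, survival = runif(1) < 0.3)
    } else if (u < 0.7) {
      toy_timeline(id, sample(c("ROSC", "death"), 1), sample(1:40, 1),
                   survival = runif(1) < 0.3)
    } else toy_timeline(id, "censored", 120, survival = runif(1) < 0.1)
  })
  toy_cohort(recs, tls)
}

# independent conditional-likelihood maximizer for 1:1 pairs (grid + optimize
# on the raw pair-level likelihood, not the discordant-count shortcut)
oracle_clogit <- function(yt, yc) {
  ll <- function(b) {
    v <- 0
    for (i in seq_along(yt)) {
      if (yt[i] == yc[i]) next  # concordant pairs are ancillary
      v <- v + (if (yt[i]) b else 0) - log(1 + exp(b))
    }
    v
  }
  stats::optimize(ll, c(-15, 15), maximum = TRUE, tol = 1e-10)$maximum
}

# 5-patient toy for the subdistribution-hazard fit: events at minutes 2
# (X = 1) and 5 (X = 0); one early competing event stays in later risk sets
finegray_toy <- function() {
  recs <- list(
    toy_record("A", witnessed = TRUE),
    toy_record("B", witnessed = FALSE),
    toy_record("C", witnessed = TRUE),
    toy_record("D", witnessed = FALSE),
    toy_record("E", witnessed = FALSE))
  tls <- list(
    toy_timeline("A", "ECPR", 2, ecpr = 2L),
    toy_timeline("B", "ECPR", 5, ecpr = 5L),
    toy_timeline("C", "censored", 120),
    toy_timeline("D", "ROSC", 1),
    toy_timeline("E", "censored", 120))
  toy_cohort(recs, tls)
}

# its partial log-likelihood, from the hand enumeration of the risk sets
finegray_toy_loglik <- function(b) b - log(2 * exp(b) + 3) - log(exp(b) + 3)
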