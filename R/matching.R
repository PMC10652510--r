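# Sequential 1:1 nearest-neighbour risk-set matching: each treated patient is
# matched, at their treatment minute, to a patient still undergoing
# resuscitation who has not received ECPR before or within that minute, with
# replacement and a caliper of 0.2 SD of the propensity score. Matching uses
# only information available up to the matching minute.

#' Build the per-minute matching risk sets
#'
#' One risk set per minute with at least one treated patient (ECPR started at
#' exactly that minute). Candidates are patients still undergoing
#' resuscitation during that minute: disposition minute strictly later, and
#' no ECPR before or within the minute. A terminal event during minute t
#' removes candidacy at t; this boundary rule is applied to all terminal
#' event types alike.
#'
#' @param timelines a cohort's `timelines` data.frame (single stratum).
#' @return list of risk sets, each a list with `minute`, `treated_ids`,
#'   `candidate_ids`.
#' @export
build_risk_sets <- function(timelines) {
  tl <- timelines
  ecpr <- tl$ecpr_minute
  minutes <- sort(unique(ecpr[!is.na(ecpr)]))
  lapply(minutes, function(t) {
    list(minute = t,
         treated_ids = tl$id[!is.na(ecpr) & ecpr == t],
         candidate_ids = tl$id[tl$disposition_minute > t &
                                 (is.na(ecpr) | ecpr > t)])
  })
}

#' Sequential nearest-neighbour matching within risk sets
#'
#' Minutes are processed in increasing order; within a minute, treated
#' patients are processed in a seeded random order (one `sample()` of the
#' treated ids per risk set with more than one treated, after a single
#' `set.seed(seed)` at entry). Each treated patient is matched to the
#' candidate minimizing the absolute score difference among candidates within
#' the caliper `caliper_k * score_sd`; exact distance ties go to the smaller
#' control id. Matching is with replacement: a control stays available for
#' later minutes and for other treated in the same minute, and may later be
#' treated (and matched) itself. Treated patients with no in-caliper
#' candidate are recorded unmatched and excluded from analysis.
#'
#' @param risk_sets output of [build_risk_sets()].
#' @param scores data.frame with `id`, `minute`, `score` covering every
#'   (id, minute) needed (see [ps_scores()]).
#' @param caliper_k caliper width in score-SD units (default 0.2).
#' @param score_sd SD of the score over treated patients at their treatment
#'   minutes (from the `ps_fit`).
#' @param seed integer seed for the within-minute processing order.
#' @return object of class `matched_cohort`: list with `pairs` (data.frame:
#'   minute, treated_id, control_id, treated_score, control_score, distance),
#'   `unmatched_treated` ids, `caliper` (the absolute width used) and
#'   `stratum`.
#' @export
sequential_match <- function(risk_sets, scores, caliper_k = 0.2, score_sd,
                             seed = 1) {
  stopifnot(is.numeric(score_sd), score_sd > 0, caliper_k >= 0)
  key <- paste(scores$id, scores$minute, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (id, minute) in scores")
  lookup <- setNames(scores$score, key)
  get_score <- function(ids, minute) {
    s <- lookup[paste(ids, minute, sep = "\r")]
    if (anyNA(s)) {
      miss <- ids[is.na(s)][1]
      stop("missing score for id '", miss, "' at minute ", minute)
    }
    unname(s)
  }
  caliper <- caliper_k * score_sd
  set.seed(seed)
  pairs <- vector("list", length(risk_sets))
  unmatched <- character(0)
  ord <- order(vapply(risk_sets, function(r) r$minute, numeric(1)))
  for (k in ord) {
    rs <- risk_sets[[k]]
    treated <- rs$treated_ids
    if (length(treated) > 1) treated <- sample(treated)
    cand <- rs$candidate_ids
    cscore <- if (length(cand)) get_score(cand, rs$minute) else numeric(0)
    # deterministic tie-break: pre-sort candidates by id so the first minimum
    # is the smallest id
    if (length(cand) > 1) {
      o <- order(cand)
      cand <- cand[o]; cscore <- cscore[o]
    }
    got <- vector("list", length(treated))
    for (j in seq_along(treated)) {
      tid <- treated[j]
      tsc <- get_score(tid, rs$minute)
      if (!length(cand)) { unmatched <- c(unmatched, tid); next }
      dist <- abs(cscore - tsc)
      ok <- which(dist <= caliper)
      if (!length(ok)) { unmatched <- c(unmatched, tid); next }
      best <- ok[which.min(dist[ok])]
      got[[j]] <- data.frame(
        minute = rs$minute, treated_id = tid, control_id = cand[best],
        treated_score = tsc, control_score = cscore[best],
        distance = dist[best], stringsAsFactors = FALSE)
    }
    pairs[[k]] <- do.call(rbind, got)
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs))
    pairs <- data.frame(minute = integer(0), treated_id = character(0),
                        control_id = character(0), treated_score = numeric(0),
                        control_score = numeric(0), distance = numeric(0),
                        stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, unmatched_treated = unmatched,
                 caliper = caliper, stratum = attr(risk_sets, "stratum")),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("<matched_cohort> %d pairs, %d unmatched treated\n",
              nrow(x$pairs), length(x$unmatched_treated)))
  invisible(x)
}

#' Summarize a matched cohort
#'
#' Reports pair and unmatched counts, the score-distance distribution, and
#' the fraction of control patients who later received ECPR themselves
#' (denominator: unique patients ever used as control).
#'
#' @param matched a `matched_cohort`.
#' @param timelines the cohort's `timelines` data.frame.
#' @return list with `n_pairs`, `n_unmatched_treated`, `n_unique_controls`,
#'   `n_controls_later_treated`, `pct_controls_later_treated` and
#'   `distance_summary`.
#' @export
match_summary <- function(matched, timelines) {
  stopifnot(inherits(matched, "matched_cohort"))
  p <- matched$pairs
  ctrl <- unique(p$control_id)
  later <- timelines$id[!is.na(timelines$ecpr_minute)]
  n_later <- sum(ctrl %in% later)
  list(
    n_pairs = nrow(p),
    n_unmatched_treated = length(matched$unmatched_treated),
    n_unique_controls = length(ctrl),
    n_controls_later_treated = n_later,
    pct_controls_later_treated =
      if (length(ctrl)) 100 * n_later / length(ctrl) else 0,
    distance_summary = if (nrow(p)) summary(p$distance) else
      summary(numeric(0)))
}
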