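# Balance diagnostics (standardized mean differences), descriptive tables,
# and the matched-pairs conditional logistic effect estimate.

#' Standardized mean difference between two groups
#'
#' Continuous: `(m1 - m2) / sqrt((s1^2 + s2^2) / 2)` with sample variances.
#' Binary: the same with `p(1 - p)` variances. Categorical with more than two
#' levels: the Mahalanobis-type multivariate SMD over the level-proportion
#' vectors (one nonnegative number per variable, as balance tables print).
#'
#' @param values_g1,values_g2 vectors of observations per group. Logical
#'   vectors are treated as binary, numeric as continuous,
#'   character/factor as categorical (two observed levels reduce to binary on
#'   the second level).
#' @param type override the automatic type.
#' @return a single numeric SMD (signed for continuous/binary, nonnegative
#'   for categorical).
#' @export
smd <- function(values_g1, values_g2,
                type = c("auto", "continuous", "binary", "categorical")) {
  type <- match.arg(type)
  v1 <- values_g1[!is.na(values_g1)]
  v2 <- values_g2[!is.na(values_g2)]
  if (!length(v1) || !length(v2))
    stop("need at least one observation per group")
  if (type == "auto") {
    type <- if (is.logical(v1)) "binary"
      else if (is.numeric(v1)) "continuous"
      else "categorical"
  }
  if (type == "categorical") {
    lv <- sort(unique(c(as.character(v1), as.character(v2))))
    if (length(lv) < 2) return(0)
    if (length(lv) == 2) {
      v1 <- as.character(v1) == lv[2]
      v2 <- as.character(v2) == lv[2]
      type <- "binary"
    }
  }
  if (type == "binary") {
    p1 <- mean(v1); p2 <- mean(v2)
    pooled <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
    if (pooled == 0) {
      if (p1 == p2) return(0)
      stop("degenerate comparison: zero pooled variance with unequal means")
    }
    return((p1 - p2) / sqrt(pooled))
  }
  if (type == "continuous") {
    m1 <- mean(v1); m2 <- mean(v2)
    pooled <- (var(v1) + var(v2)) / 2
    if (is.na(pooled) || pooled == 0) {
      if (isTRUE(all.equal(m1, m2))) return(0)
      stop("degenerate comparison: zero pooled variance with unequal means")
    }
    return((m1 - m2) / sqrt(pooled))
  }
  # categorical, > 2 levels: Mahalanobis form of Yang & Dalton
  lv <- sort(unique(c(as.character(v1), as.character(v2))))
  p1 <- as.numeric(table(factor(v1, levels = lv))) / length(v1)
  p2 <- as.numeric(table(factor(v2, levels = lv))) / length(v2)
  k <- length(lv) - 1
  t1 <- p1[seq_len(k)]; t2 <- p2[seq_len(k)]
  S <- ((diag(t1, k) - tcrossprod(t1)) + (diag(t2, k) - tcrossprod(t2))) / 2
  d <- t1 - t2
  val <- drop(t(d) %*% MASS::ginv(S) %*% d)
  sqrt(max(val, 0))
}

.balance_covariates <- c("sex", "age", "witnessed", "bystander_cpr",
                         "initial_rhythm", "bystander_aed",
                         "physician_staffed", "shock_by_paramedic",
                         "advanced_airway", "prehosp_adrenaline_n",
                         "prehosp_rosc", "call_to_hospital_min",
                         "ecpr_volume")

fmt_median_iqr <- function(v) {
  q <- quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  sprintf("%g (%g, %g)", q[2], q[1], q[3])
}

fmt_n_pct <- function(k, n) sprintf("%d (%.0f%%)", k, 100 * k / n)

balance_rows <- function(rec1, rec2, covariates) {
  out <- list()
  for (f in covariates) {
    v1 <- rec1[[f]]; v2 <- rec2[[f]]
    if (is.null(v1)) stop("unknown covariate: '", f, "'")
    if (is.numeric(v1) && !f %in% "prehosp_adrenaline_n") {
      s <- smd(v1, v2, "continuous")
      out[[length(out) + 1]] <- data.frame(
        covariate = f, level = "", type = "continuous",
        g1 = fmt_median_iqr(v1), g2 = fmt_median_iqr(v2),
        smd = s, stringsAsFactors = FALSE)
    } else if (is.logical(v1)) {
      s <- smd(v1, v2, "binary")
      out[[length(out) + 1]] <- data.frame(
        covariate = f, level = "TRUE", type = "binary",
        g1 = fmt_n_pct(sum(v1, na.rm = TRUE), length(v1)),
        g2 = fmt_n_pct(sum(v2, na.rm = TRUE), length(v2)),
        smd = s, stringsAsFactors = FALSE)
    } else {
      v1c <- as.character(v1); v2c <- as.character(v2)
      s <- smd(v1c, v2c, "categorical")
      lv <- .record_levels[[f]] %||% sort(unique(c(v1c, v2c)))
      lv <- intersect(lv, c(v1c, v2c))
      if (f == "prehosp_adrenaline_n") lv <- sort(unique(c(v1c, v2c)))
      first <- TRUE
      for (l in lv) {
        out[[length(out) + 1]] <- data.frame(
          covariate = f, level = l, type = "categorical",
          g1 = fmt_n_pct(sum(v1c == l), length(v1c)),
          g2 = fmt_n_pct(sum(v2c == l), length(v2c)),
          smd = if (first) s else NA_real_, stringsAsFactors = FALSE)
        first <- FALSE
      }
    }
  }
  res <- do.call(rbind, out)
  res$balanced <- ifelse(is.na(res$smd), NA, abs(res$smd) < 0.25)
  rownames(res) <- NULL
  res
}

#' Covariate balance table with standardized mean differences
#'
#' For a plain cohort the comparison is ever-ECPR versus never-ECPR (the
#' original-cohort table); for a `matched_cohort` the two arms are the
#' treated and control members of each pair, one row per pair, so controls
#' reused under matching with replacement are counted once per pair.
#' Continuous covariates are summarized as median (IQR), categorical ones as
#' n (%). `|SMD| < 0.25` is flagged as balanced.
#'
#' @param x a `cohort` or a `matched_cohort`.
#' @param cohort for the `matched_cohort` method: the cohort supplying the
#'   covariates.
#' @param covariates covariate names (default: the propensity-model
#'   time-independent set present in the records).
#' @param ... unused.
#' @return data.frame with per-covariate (and per-level) group summaries,
#'   `smd` and a `balanced` flag; `cohort_label` attribute records which
#'   comparison was made.
#' @export
balance_table <- function(x, ...) UseMethod("balance_table")

#' @rdname balance_table
#' @export
balance_table.cohort <- function(x, covariates = NULL, ...) {
  if (!"ecpr_volume" %in% names(x$records)) x <- assign_hospital_volume(x)
  covariates <- covariates %||%
    intersect(.balance_covariates, names(x$records))
  treated <- x$timelines$disposition %in% "ECPR"
  res <- balance_rows(x$records[treated, , drop = FALSE],
                      x$records[!treated, , drop = FALSE], covariates)
  attr(res, "cohort_label") <- "original"
  res
}

#' @rdname balance_table
#' @export
balance_table.matched_cohort <- function(x, cohort, covariates = NULL, ...) {
  if (!"ecpr_volume" %in% names(cohort$records))
    cohort <- assign_hospital_volume(cohort)
  covariates <- covariates %||%
    intersect(.balance_covariates, names(cohort$records))
  idx <- function(ids) cohort$records[match(ids, cohort$records$id), ,
                                      drop = FALSE]
  res <- balance_rows(idx(x$pairs$treated_id), idx(x$pairs$control_id),
                      covariates)
  attr(res, "cohort_label") <- "matched"
  res
}

#' Outcome counts and percentages per matched arm
#'
#' The ECPR arm is the treated member of each pair and the control arm the
#' control member, at pair level (a control reused under replacement is
#' counted once per pair), so both arm sizes equal the number of pairs.
#'
#' @param pairs the `pairs` data.frame of a `matched_cohort` (or the
#'   `matched_cohort` itself).
#' @param timelines the cohort's `timelines` data.frame.
#' @param outcome `"survival_30d"` or `"cpc_1_2"`.
#' @return data.frame with one row per arm: `arm`, `events`, `n`, `pct`
#'   (percentage to one decimal).
#' @export
outcome_proportions <- function(pairs, timelines,
                                outcome = c("survival_30d", "cpc_1_2")) {
  outcome <- match.arg(outcome)
  if (inherits(pairs, "matched_cohort")) pairs <- pairs$pairs
  y <- setNames(timelines[[outcome]], timelines$id)
  yt <- y[pairs$treated_id]; yc <- y[pairs$control_id]
  n <- nrow(pairs)
  data.frame(
    arm = c("ECPR", "control"),
    events = c(sum(yt), sum(yc)),
    n = c(n, n),
    pct = if (n) round(100 * c(sum(yt), sum(yc)) / n, 1) else c(0, 0),
    stringsAsFactors = FALSE)
}

#' Attach per-member binary outcomes to matched pairs
#'
#' @inheritParams outcome_proportions
#' @return the pairs data.frame with logical `treated_outcome` and
#'   `control_outcome` columns.
#' @export
pair_outcomes <- function(pairs, timelines,
                          outcome = c("survival_30d", "cpc_1_2")) {
  outcome <- match.arg(outcome)
  if (inherits(pairs, "matched_cohort")) pairs <- pairs$pairs
  y <- setNames(timelines[[outcome]], timelines$id)
  pairs$treated_outcome <- unname(y[pairs$treated_id])
  pairs$control_outcome <- unname(y[pairs$control_id])
  pairs
}

#' Conditional logistic regression for 1:1 matched pairs
#'
#' With a single binary exposure the conditional maximum-likelihood odds
#' ratio is the ratio of discordant-pair counts, `n10 / n01` (concordant
#' pairs carry no information), with Wald 95% CI
#' `exp(log(n10/n01) +- 1.96 sqrt(1/n10 + 1/n01))`. The closed form is
#' verified internally against a numeric maximizer of the full conditional
#' likelihood. If one discordant count is zero the estimate is flagged
#' infinite/zero and a one-sided 95% profile-type bound (exact binomial on
#' the discordant-pair success probability) replaces the Wald interval.
#' Pairs sharing a control under matching with replacement are treated as
#' independent, mirroring the matched-pairs analysis this package emulates;
#' see the vignette for the robustness caveat.
#'
#' @param pairs_out data.frame with logical `treated_outcome` and
#'   `control_outcome` columns (see [pair_outcomes()]).
#' @param outcome_label label stored on the estimate.
#' @return object of class `effect_estimate`: `n_pairs`, discordant counts
#'   `n10`/`n01`, `or`, `ci_low`, `ci_high`, `log_or`, `se_log_or`,
#'   `or_numeric` (the numeric conditional-ML check) and `estimate_type`.
#' @export
conditional_logit_1to1 <- function(pairs_out, outcome_label = "outcome") {
  stopifnot(all(c("treated_outcome", "control_outcome") %in%
                  names(pairs_out)))
  yt <- pairs_out$treated_outcome; yc <- pairs_out$control_outcome
  n10 <- sum(yt & !yc)
  n01 <- sum(!yt & yc)
  if (n10 + n01 < 1) stop("no discordant pairs: the conditional likelihood ",
                          "is flat")
  est <- list(outcome = outcome_label, n_pairs = nrow(pairs_out),
              n10 = n10, n01 = n01)
  if (n10 > 0 && n01 > 0) {
    log_or <- log(n10 / n01)
    se <- sqrt(1 / n10 + 1 / n01)
    # independent numeric check: maximize the conditional log-likelihood
    nll <- function(b) -(n10 * b - (n10 + n01) * log1p(exp(b)))
    opt <- optimize(nll, c(-20, 20), tol = 1e-10)
    est <- c(est, list(
      or = exp(log_or), log_or = log_or, se_log_or = se,
      ci_low = exp(log_or - qnorm(0.975) * se),
      ci_high = exp(log_or + qnorm(0.975) * se),
      or_numeric = exp(opt$minimum), estimate_type = "MLE"))
  } else {
    m <- n10 + n01
    if (n01 == 0) {
      # one-sided lower bound on p = OR/(1+OR) among discordant pairs
      p_low <- qbeta(0.05, n10, n01 + 1)
      est <- c(est, list(or = Inf, log_or = Inf, se_log_or = NA_real_,
                         ci_low = p_low / (1 - p_low), ci_high = Inf,
                         or_numeric = NA_real_, estimate_type = "infinite"))
    } else {
      p_high <- qbeta(0.95, n10 + 1, n01)
      est <- c(est, list(or = 0, log_or = -Inf, se_log_or = NA_real_,
                         ci_low = 0, ci_high = p_high / (1 - p_high),
                         or_numeric = NA_real_, estimate_type = "zero"))
    }
  }
  structure(est, class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf(
    "<effect_estimate> %s: OR %.2f [95%% CI %.2f-%.2f] (n10=%d, n01=%d, %d pairs)\n",
    x$outcome, x$or, x$ci_low, x$ci_high, x$n10, x$n01, x$n_pairs))
  invisible(x)
}
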