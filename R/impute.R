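# Iterative tree-ensemble imputation of missing covariates.
#
# Missing entries are initialized with the observed mean (continuous) or mode
# (categorical); variables are then revisited in increasing order of
# missingness, each refitted with a random forest on the currently completed
# other covariates and its missing rows re-predicted, until the normalized
# change statistic first increases (the previous iterate is returned) or
# max_iter is reached.

.continuous_fields <- c("age", "prehosp_adrenaline_n", "call_to_hospital_min")
.integer_bounds <- list(age = c(0, 120), prehosp_adrenaline_n = c(0, 5),
                        call_to_hospital_min = c(1, Inf))

impute_frame <- function(rec) {
  # imputation operates on covariate fields only; ids and timelines are kept
  # aside and never touched
  flds <- setdiff(names(.record_cols), c("id", "hospital_id"))
  df <- rec[flds]
  for (f in flds) {
    if (f %in% .continuous_fields) df[[f]] <- as.numeric(df[[f]])
    else df[[f]] <- factor(df[[f]])
  }
  df
}

#' Impute missing covariates with an iterative random-forest scheme
#'
#' @param x a `cohort` (run [apply_exclusion_criteria()] first; the procedure
#'   is intended for the eligible participants).
#' @param seed integer seed; results are deterministic given it.
#' @param max_iter maximum number of sweeps over the incomplete variables.
#' @param num_trees trees per forest (default 100).
#' @param mtry variables tried per split; default `sqrt(p)` rounded up.
#' @return an object of class `imputation_result`: list with `cohort` (the
#'   completed cohort), `iterations_run`, `converged`, and `history` (the
#'   per-iteration continuous and categorical change statistics).
#' @details The continuous change statistic is
#'   `sum((new - old)^2) / sum(new^2)` over imputed continuous cells; the
#'   categorical one is the fraction of imputed categorical cells that
#'   changed. The loop stops the first time every monitored statistic
#'   increases relative to the previous sweep, returning the previous
#'   iterate. Observed cells are never modified; categorical imputations take
#'   values only from the observed level set; integer-valued fields are
#'   rounded and clamped to their valid range.
#' @export
impute_missing <- function(x, seed = 1, max_iter = 10, num_trees = 100,
                           mtry = NULL) {
  stopifnot(inherits(x, "cohort"))
  rec <- x$records
  df <- impute_frame(rec)
  miss <- is.na(df)
  n_miss <- colSums(miss)
  if (all(n_miss == 0)) {
    return(structure(list(cohort = x, iterations_run = 0L, converged = TRUE,
                          history = data.frame(iter = integer(0),
                                               cont = numeric(0),
                                               cat = numeric(0))),
                     class = "imputation_result"))
  }
  if (any(n_miss == nrow(df)))
    stop("cannot impute: field '", names(df)[which(n_miss == nrow(df))[1]],
         "' is 100% missing")
  if (!any(n_miss == 0))
    stop("cannot impute: no fully observed field available")

  # mean/mode initialization
  for (f in names(df)[n_miss > 0]) {
    if (is.numeric(df[[f]])) {
      df[[f]][miss[, f]] <- mean(df[[f]], na.rm = TRUE)
    } else {
      tab <- table(df[[f]])
      df[[f]][miss[, f]] <- names(tab)[which.max(tab)]
    }
  }
  if (any(!vapply(df, function(v) all(is.finite(as.numeric(v))) ||
                    is.factor(v), logical(1))))
    stop("non-finite learner inputs")

  targets <- names(df)[n_miss > 0][order(n_miss[n_miss > 0])]
  is_cont <- vapply(df[targets], is.numeric, logical(1))
  set.seed(seed)
  prev <- df
  history <- data.frame(iter = integer(0), cont = numeric(0),
                        cat = numeric(0))
  last_stat <- c(cont = Inf, cat = Inf)
  converged <- FALSE
  iterations_run <- 0L
  if (is.null(mtry)) mtry <- max(1L, ceiling(sqrt(ncol(df) - 1L)))

  for (iter in seq_len(max_iter)) {
    old <- df
    for (f in targets) {
      obs <- !miss[, f]
      dat <- df[, setdiff(names(df), f), drop = FALSE]
      fit <- ranger::ranger(
        x = dat[obs, , drop = FALSE], y = df[[f]][obs],
        num.trees = num_trees, mtry = min(mtry, ncol(dat)),
        respect.unordered.factors = "order",
        seed = sample.int(.Machine$integer.max, 1), num.threads = 1)
      pred <- predict(fit, data = dat[!obs, , drop = FALSE],
                      num.threads = 1)$predictions
      if (is.numeric(df[[f]]) && f %in% names(.integer_bounds)) {
        b <- .integer_bounds[[f]]
        pred <- pmin(pmax(round(pred), b[1]), b[2])
      }
      df[[f]][!obs] <- pred
    }
    # normalized change over imputed cells, by variable type
    stat <- c(cont = 0, cat = 0)
    have <- c(cont = any(is_cont), cat = any(!is_cont))
    if (have["cont"]) {
      num <- den <- 0
      for (f in targets[is_cont]) {
        num <- num + sum((df[[f]][miss[, f]] - old[[f]][miss[, f]])^2)
        den <- den + sum(df[[f]][miss[, f]]^2)
      }
      stat["cont"] <- if (den > 0) num / den else 0
    }
    if (have["cat"]) {
      chg <- tot <- 0
      for (f in targets[!is_cont]) {
        chg <- chg + sum(df[[f]][miss[, f]] != old[[f]][miss[, f]])
        tot <- tot + sum(miss[, f])
      }
      stat["cat"] <- chg / tot
    }
    history <- rbind(history, data.frame(iter = iter, cont = stat[["cont"]],
                                         cat = stat[["cat"]]))
    iterations_run <- iter
    increased <- (!have["cont"] | stat["cont"] >= last_stat["cont"]) &
                 (!have["cat"] | stat["cat"] >= last_stat["cat"])
    if (iter > 1 && increased) {
      df <- prev  # return the previous sweep's values
      converged <- TRUE
      break
    }
    prev <- df
    last_stat <- stat
    if (all(stat[have] == 0)) { converged <- TRUE; break }
  }

  for (f in targets) {
    v <- df[[f]]
    if (is.factor(v)) v <- as.character(v)
    if (f %in% names(.record_cols) && .record_cols[[f]] == "logical")
      v <- as.logical(v)
    if (f %in% names(.record_cols) && .record_cols[[f]] == "integer")
      v <- as.integer(round(as.numeric(v)))
    rec[[f]][miss[, f]] <- v[miss[, f]]
  }
  x$records <- rec
  structure(list(cohort = x, iterations_run = iterations_run,
                 converged = converged, history = history),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> %d iteration(s), converged: %s\n",
              x$iterations_run, x$converged))
  if (nrow(x$history)) print(x$history, row.names = FALSE)
  invisible(x)
}
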