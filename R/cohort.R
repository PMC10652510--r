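#' @importFrom stats plogis qlogis quantile rnorm runif rbinom rlnorm sd var
#'   median setNames optimize qbeta qnorm predict
#' @importFrom utils read.csv write.csv modifyList
#' @importFrom tools md5sum
NULL

# Column dictionary shared by the reader, writer and validator.  Each cohort
# is serialized as one row per patient: patient/pre-hospital covariates plus
# the in-hospital event timeline on a 0-120 minute clock.
.record_levels <- list(
  sex            = c("male", "female"),
  initial_rhythm = c("VF_VT", "PEA", "asystole"),
  advanced_airway = c("intubation", "SGA", "none"),
  arrest_cause   = c("medical", "external"),
  ecpr_volume    = c("low", "middle", "high")
)

.record_cols <- c(
  id = "character", sex = "character", age = "integer", witnessed = "logical",
  bystander_cpr = "logical", initial_rhythm = "character",
  bystander_aed = "logical", physician_staffed = "logical",
  shock_by_paramedic = "logical", advanced_airway = "character",
  prehosp_adrenaline_n = "integer", prehosp_rosc = "logical",
  call_to_hospital_min = "integer", hospital_id = "character",
  arrest_cause = "character", resuscitation_attempted = "logical",
  arrest_on_ems_contact = "logical", rosc_before_arrival_sustained = "logical"
)

.timeline_cols <- c(
  id = "character", defib_minutes = "minutes", intubation_minute = "integer",
  adrenaline_minutes = "minutes", ecpr_minute = "integer",
  disposition = "character", disposition_minute = "integer",
  survival_30d = "logical", cpc_1_2 = "logical"
)

.dispositions <- c("ROSC", "death", "ECPR", "censored")

#' Horizon of the in-hospital clock, in minutes from arrival
#'
#' Events are recorded at integer minutes; an event "at minute t" occupies the
#' half-open interval \[t, t+1). Resuscitation still ongoing at the horizon is
#' administratively censored.
#' @export
HORIZON_MIN <- 120L

#' Parse and join ";"-separated minute lists
#'
#' Multi-event columns (in-hospital defibrillation and adrenaline) hold sorted
#' integer minutes joined by ";"; the empty string means no events.
#' @param x character vector of joined minute lists.
#' @return `parse_minutes`: a list of integer vectors. `join_minutes`: a
#'   character vector.
#' @export
parse_minutes <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(integer(0))
    out <- suppressWarnings(as.integer(strsplit(s, ";", fixed = TRUE)[[1]]))
    if (anyNA(out)) stop("non-integer minute in minute list: ", s)
    out
  })
}

#' @rdname parse_minutes
#' @param m list of integer vectors.
#' @export
join_minutes <- function(m) {
  vapply(m, function(v) paste(v, collapse = ";"), character(1))
}

first_minute <- function(x) {
  vapply(parse_minutes(x), function(v) if (length(v)) min(v) else NA_integer_,
         integer(1))
}

#' Construct a registry-style cohort
#'
#' A cohort couples one `records` row per patient (baseline and pre-hospital
#' covariates) with one `timelines` row per patient (in-hospital event minutes
#' and 30-day outcomes). The stratum label is derived from the initial rhythm:
#' all VF/pulseless-VT gives `"shockable"`, none gives `"non_shockable"`,
#' otherwise `"mixed"`.
#'
#' @param records data.frame of patient records (see `cohort_dictionary()`).
#' @param timelines data.frame of event timelines keyed by `id`.
#' @param validate run integrity checks (default TRUE).
#' @return an object of class `cohort`.
#' @export
cohort <- function(records, timelines, validate = TRUE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  timelines <- as.data.frame(timelines, stringsAsFactors = FALSE)
  timelines <- timelines[match(records$id, timelines$id), , drop = FALSE]
  rownames(records) <- rownames(timelines) <- NULL
  rhythm <- records$initial_rhythm
  known <- rhythm[!is.na(rhythm)]
  stratum <- if (length(known) && all(known == "VF_VT")) "shockable"
    else if (length(known) && !any(known == "VF_VT")) "non_shockable"
    else "mixed"
  obj <- structure(list(records = records, timelines = timelines,
                        stratum = stratum), class = "cohort")
  if (validate) validate_cohort(obj)
  obj
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients, stratum: %s\n", nrow(x$records),
              x$stratum))
  tab <- table(factor(x$timelines$disposition, levels = .dispositions),
               useNA = "ifany")
  cat("dispositions:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of patients in a cohort
#' @param x a `cohort`.
#' @return integer count.
#' @export
n_patients <- function(x) nrow(x$records)

#' Validate cohort integrity
#'
#' Checks id bijectivity, column presence and types, minute ranges, adrenaline
#' top-coding, and the timeline invariants: exactly one terminal event, an
#' ECPR disposition if and only if the ECPR minute equals the disposition
#' minute, censoring exactly at the 120-minute horizon, and a favourable
#' neurological outcome (CPC 1-2) implying 30-day survival. Missing covariate
#' values are allowed; the invariants are enforced where observed.
#'
#' @param x a `cohort`.
#' @return invisibly `x`; stops with an informative error on violation.
#' @export
validate_cohort <- function(x) {
  rec <- x$records; tl <- x$timelines
  for (col in names(.record_cols))
    if (!col %in% names(rec)) stop("schema error: missing record column '",
                                   col, "'")
  for (col in names(.timeline_cols))
    if (!col %in% names(tl)) stop("schema error: missing timeline column '",
                                  col, "'")
  if (anyDuplicated(rec$id)) stop("integrity error: duplicate patient id '",
                                  rec$id[duplicated(rec$id)][1], "'")
  if (!setequal(rec$id, tl$id) || nrow(rec) != nrow(tl))
    stop("integrity error: record/timeline ids are not bijective")
  if (nrow(rec) == 0) return(invisible(x))

  ok_lvl <- function(v, lv) all(is.na(v) | v %in% lv)
  for (f in c("sex", "initial_rhythm", "advanced_airway", "arrest_cause"))
    if (!ok_lvl(rec[[f]], .record_levels[[f]]))
      stop("parse error: invalid level in '", f, "'")
  if (!ok_lvl(tl$disposition, .dispositions))
    stop("parse error: invalid disposition")
  adr <- rec$prehosp_adrenaline_n
  if (any(!is.na(adr) & (adr < 0 | adr > 5)))
    stop("integrity error: prehosp_adrenaline_n must be top-coded to 0..5")
  if (any(!is.na(rec$age) & rec$age < 0)) stop("integrity error: negative age")

  dm <- tl$disposition_minute
  if (any(!is.na(dm) & (dm < 0 | dm > HORIZON_MIN)))
    stop("integrity error: disposition_minute outside [0, 120]")
  em <- tl$ecpr_minute
  is_ecpr <- !is.na(tl$disposition) & tl$disposition == "ECPR"
  bad <- is_ecpr & (is.na(em) | is.na(dm) | em != dm)
  if (any(bad))
    stop("integrity error: disposition 'ECPR' requires ecpr_minute == ",
         "disposition_minute (id '", tl$id[bad][1], "')")
  bad <- !is.na(em) & !is_ecpr
  if (any(bad))
    stop("integrity error: ecpr_minute present without ECPR disposition (id '",
         tl$id[bad][1], "')")
  is_cens <- !is.na(tl$disposition) & tl$disposition == "censored"
  bad <- is_cens & (is.na(dm) | dm != HORIZON_MIN)
  if (any(bad))
    stop("integrity error: censored disposition requires disposition_minute ",
         "= 120 (id '", tl$id[bad][1], "')")
  cpc <- tl$cpc_1_2; sv <- tl$survival_30d
  bad <- !is.na(cpc) & cpc & !is.na(sv) & !sv
  if (any(bad))
    stop("integrity error: cpc_1_2 implies survival_30d (id '",
         tl$id[bad][1], "')")
  for (f in c("defib_minutes", "adrenaline_minutes")) {
    mm <- parse_minutes(tl[[f]])
    bad <- vapply(mm, function(v)
      length(v) && (is.unsorted(v) || min(v) < 0 || max(v) > HORIZON_MIN),
      logical(1))
    if (any(bad)) stop("integrity error: unsorted or out-of-range '", f,
                       "' (id '", tl$id[bad][1], "')")
  }
  invisible(x)
}

#' Column dictionary for cohort files
#'
#' Documents every column of the single-table serialization: name, type,
#' units, allowed levels and the missing-value marker (empty cell).
#' @return data.frame with columns name, table, type, units, levels, missing.
#' @export
cohort_dictionary <- function() {
  mk <- function(cols, table) data.frame(
    name = names(cols), table = table,
    type = unname(cols),
    units = ifelse(grepl("minute|call_to", names(cols)),
                   "minutes from hospital arrival", ""),
    levels = vapply(names(cols), function(nm) {
      lv <- .record_levels[[nm]]
      if (nm == "disposition") lv <- .dispositions
      if (is.null(lv)) "" else paste(lv, collapse = "|")
    }, character(1)),
    missing = "empty cell", stringsAsFactors = FALSE)
  d <- rbind(mk(.record_cols, "record"),
             mk(.timeline_cols[-1], "timeline"))
  d$units[d$name == "call_to_hospital_min"] <- "minutes from emergency call"
  d$units[d$name == "age"] <- "years"
  rownames(d) <- NULL
  d
}

coerce_col <- function(v, type, name) {
  if (type %in% c("character", "minutes")) {
    v <- as.character(v)
    if (type == "minutes") {
      v[is.na(v)] <- ""
      parse_minutes(v)  # errors on non-integer content
    }
    return(v)
  }
  if (type == "integer") {
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & (is.na(num) | num != floor(num)))
    if (length(bad))
      stop("parse error: non-integer minute/value in column '", name,
           "' at row ", bad[1])
    return(as.integer(num))
  }
  if (type == "logical") {
    if (is.logical(v)) return(v)
    ch <- toupper(as.character(v))
    out <- rep(NA, length(v))
    out[ch %in% c("TRUE", "T", "1")] <- TRUE
    out[ch %in% c("FALSE", "F", "0")] <- FALSE
    bad <- which(!is.na(v) & nzchar(trimws(as.character(v))) & is.na(out))
    if (length(bad))
      stop("parse error: non-logical value in column '", name, "' at row ",
           bad[1])
    return(out)
  }
  v
}

#' Read a cohort file
#'
#' Reads the single-table serialization (one row per patient) written by
#' [write_cohort()]. Unknown columns raise a schema error; minute fields must
#' be integers; duplicate ids raise an integrity error. Missing values (empty
#' cells) are preserved as `NA`.
#'
#' @param path file path.
#' @param format `"csv"` (UTF-8, header row) or `"parquet"` (columnar binary,
#'   requires the `arrow` package).
#' @return a validated [cohort()].
#' @export
read_cohort <- function(path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA"),
             colClasses = "character", fileEncoding = "UTF-8")
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the 'arrow' package is required for parquet cohorts")
    as.data.frame(arrow::read_parquet(path))
  }
  all_cols <- c(.record_cols, .timeline_cols[-1])
  unknown <- setdiff(names(df), names(all_cols))
  if (length(unknown))
    stop("schema error: unknown column '", unknown[1], "'")
  missing <- setdiff(names(all_cols), names(df))
  if (length(missing))
    stop("schema error: missing column '", missing[1], "'")
  for (nm in names(all_cols)) {
    v <- df[[nm]]
    if (all_cols[[nm]] != "minutes" && is.character(v)) v[v == ""] <- NA
    df[[nm]] <- coerce_col(v, all_cols[[nm]], nm)
    if (all_cols[[nm]] == "minutes") {
      v <- as.character(df[[nm]]); v[is.na(v)] <- ""; df[[nm]] <- v
    }
  }
  cohort(df[names(.record_cols)],
         df[c("id", names(.timeline_cols)[-1])])
}

#' Write a cohort file
#'
#' Lossless inverse of [read_cohort()]: `read_cohort(write_cohort(x, p), )`
#' reproduces `x` field by field.
#'
#' @param x a `cohort`.
#' @param path output path.
#' @inheritParams read_cohort
#' @return invisibly, the path.
#' @export
write_cohort <- function(x, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  validate_cohort(x)
  df <- merge(x$records, x$timelines, by = "id", sort = FALSE)
  df <- df[match(x$records$id, df$id),
           c(names(.record_cols), names(.timeline_cols)[-1])]
  if (format == "csv") {
    write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the 'arrow' package is required for parquet cohorts")
    arrow::write_parquet(df, path)
  }
  invisible(path)
}

.exclusion_reasons <- c(
  "no_resuscitation_attempt", "age_lt_18", "external_cause",
  "no_arrest_on_ems_contact", "rosc_before_arrival",
  "hospital_without_ecpr", "missing_disposition",
  "zero_time_to_disposition")

#' Apply the eligibility (exclusion) criteria
#'
#' Removes, in fixed order: no resuscitation attempt by paramedics; age under
#' 18; arrest of external cause; no arrest at first EMS contact; sustained
#' ROSC before/on hospital arrival; transfer to a hospital without ECPR
#' capability; missing final disposition; and zero time from arrival to final
#' disposition. A patient is counted once, at the first failing criterion.
#'
#' ECPR capability is derived from the cohort itself, mirroring registries
#' where non-ECPR centres register no ECPR cases: a hospital is capable when
#' at least one of its patients has disposition ECPR and is not excluded by
#' the preceding patient-level criteria (an ECPR start in minute 0 still
#' proves capability). The operation is idempotent whenever no
#' capability-granting case is itself a minute-0 ECPR start, which holds by
#' construction for simulated cohorts (ECPR begins no earlier than minute 5).
#'
#' @param x a `cohort`.
#' @return list with `eligible` (a `cohort`) and `flow` (data.frame of
#'   per-reason exclusion counts, plus `n_input`/`n_eligible` attributes).
#' @export
apply_exclusion_criteria <- function(x) {
  rec <- x$records; tl <- x$timelines
  n <- nrow(rec)
  fails <- matrix(FALSE, n, length(.exclusion_reasons),
                  dimnames = list(NULL, .exclusion_reasons))
  fails[, "no_resuscitation_attempt"] <- rec$resuscitation_attempted %in% FALSE
  fails[, "age_lt_18"] <- !is.na(rec$age) & rec$age < 18
  fails[, "external_cause"] <- rec$arrest_cause %in% "external"
  fails[, "no_arrest_on_ems_contact"] <- rec$arrest_on_ems_contact %in% FALSE
  fails[, "rosc_before_arrival"] <- rec$rosc_before_arrival_sustained %in% TRUE
  fails[, "missing_disposition"] <- is.na(tl$disposition)
  fails[, "zero_time_to_disposition"] <-
    !is.na(tl$disposition_minute) & tl$disposition_minute == 0
  # a hospital is ECPR-capable when it has an ECPR case among patients not
  # excluded by the preceding (patient-level) criteria; an ECPR start in
  # minute 0 still proves capability
  pass_prior <- !apply(fails[, .exclusion_reasons[1:5], drop = FALSE], 1, any)
  capable <- unique(rec$hospital_id[pass_prior & tl$disposition %in% "ECPR"])
  fails[, "hospital_without_ecpr"] <- !rec$hospital_id %in% capable
  ord <- apply(fails[, .exclusion_reasons, drop = FALSE], 1, function(f)
    if (any(f)) which(f)[1] else NA_integer_)
  first_fail <- .exclusion_reasons[ord]
  keep <- is.na(first_fail)
  flow <- data.frame(
    reason = .exclusion_reasons,
    n_excluded = vapply(.exclusion_reasons,
                        function(r) sum(first_fail %in% r), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(flow, "n_input") <- n
  attr(flow, "n_eligible") <- sum(keep)
  eligible <- cohort(rec[keep, , drop = FALSE], tl[keep, , drop = FALSE],
                     validate = FALSE)
  list(eligible = eligible, flow = flow)
}

#' Stratify a cohort by initial cardiac rhythm
#'
#' Partitions into a shockable cohort (VF / pulseless VT) and a non-shockable
#' cohort (PEA or asystole). The union equals the input.
#'
#' @param x a `cohort` with no missing `initial_rhythm` (impute first).
#' @return list with `shockable` and `non_shockable` cohorts.
#' @export
stratify_by_rhythm <- function(x) {
  r <- x$records$initial_rhythm
  if (anyNA(r))
    stop("integrity error: missing initial_rhythm; impute before stratifying")
  sh <- r == "VF_VT"
  list(
    shockable = cohort(x$records[sh, , drop = FALSE],
                       x$timelines[sh, , drop = FALSE], validate = FALSE),
    non_shockable = cohort(x$records[!sh, , drop = FALSE],
                           x$timelines[!sh, , drop = FALSE], validate = FALSE))
}

#' Classify hospitals by ECPR case volume
#'
#' Splits hospitals at the 1/3 and 2/3 empirical quantiles of their ECPR case
#' counts into low / middle / high volume. Counts tied with a tertile
#' boundary go to the lower category (deterministic). A single hospital is
#' classified "high": a lone centre performing ECPR is the reference centre
#' and the quantiles are degenerate.
#'
#' @param ecpr_counts named non-negative numeric vector, one entry per
#'   hospital id.
#' @return named character vector of `"low"`, `"middle"`, `"high"`.
#' @export
derive_hospital_volume <- function(ecpr_counts) {
  if (length(ecpr_counts) == 0) stop("empty hospital count map")
  if (is.null(names(ecpr_counts)) || any(!nzchar(names(ecpr_counts))))
    stop("ecpr_counts must be named by hospital id")
  if (any(ecpr_counts < 0)) stop("negative ECPR count")
  if (length(ecpr_counts) == 1)
    return(setNames("high", names(ecpr_counts)))
  q <- quantile(ecpr_counts, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  out <- ifelse(ecpr_counts <= q[1], "low",
                ifelse(ecpr_counts <= q[2], "middle", "high"))
  setNames(out, names(ecpr_counts))
}

#' Attach the hospital ECPR-volume category to a cohort
#'
#' Counts ECPR dispositions per hospital within the cohort, classifies
#' hospitals with [derive_hospital_volume()], and adds an `ecpr_volume`
#' column (`low`/`middle`/`high`) to the records.
#'
#' @param x a `cohort`.
#' @return the cohort with `records$ecpr_volume` added.
#' @export
assign_hospital_volume <- function(x) {
  hosp <- unique(x$records$hospital_id)
  ecpr <- x$timelines$disposition %in% "ECPR"
  counts <- table(factor(x$records$hospital_id[ecpr], levels = hosp))
  vol <- derive_hospital_volume(setNames(as.numeric(counts), hosp))
  x$records$ecpr_volume <- unname(vol[x$records$hospital_id])
  x
}
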