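scores_from <- function(ids, minutes, values) {
  expand <- expand.grid(id = ids, minute = minutes,
                        stringsAsFactors = FALSE)
  expand$score <- values[expand$id]
  expand
}

test_that("risk-set boundaries follow the within-minute exclusion rule", {
  # lone treated patient: nobody else alive at the treatment minute
  solo <- data.frame(id = "a", ecpr_minute = 4L, disposition = "ECPR",
                     disposition_minute = 4L, stringsAsFactors = FALSE)
  rs <- build_risk_sets(solo)
  expect_length(rs, 1)
  expect_equal(rs[[1]]$candidate_ids, character(0))

  # ROSC during the treatment minute removes candidacy at that minute
  tl <- data.frame(id = c("a", "b", "c"),
                   ecpr_minute = c(4L, NA, NA),
                   disposition = c("ECPR", "ROSC", "ROSC"),
                   disposition_minute = c(4L, 4L, 5L),
                   stringsAsFactors = FALSE)
  rs <- build_risk_sets(tl)
  expect_equal(rs[[1]]$candidate_ids, "c")
})

test_that("risk sets equal brute-force enumeration on staggered toys", {
  tl <- data.frame(
    id = c("p1", "p2", "p3", "p4", "p5", "p6"),
    ecpr_minute = c(3L, 7L, NA, NA, 9L, NA),
    disposition = c("ECPR", "ECPR", "ROSC", "death", "ECPR", "censored"),
    disposition_minute = c(3L, 7L, 5L, 8L, 9L, 120L),
    stringsAsFactors = FALSE)
  got <- build_risk_sets(tl)
  want <- oracle_risk_sets(tl)
  expect_equal(length(got), length(want))
  for (k in seq_along(got)) {
    expect_equal(got[[k]]$minute, want[[k]]$minute)
    expect_setequal(got[[k]]$treated_ids, want[[k]]$treated_ids)
    expect_setequal(got[[k]]$candidate_ids, want[[k]]$candidate_ids)
  }
})

test_that("caliper acceptance and rejection behave as specified", {
  rs <- list(list(minute = 5, treated_ids = "t", candidate_ids = "c"))
  sc <- data.frame(id = c("t", "c"), minute = 5, score = c(0, 0.02))
  m <- sequential_match(rs, sc, caliper_k = 0.2, score_sd = 1, seed = 1)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$control_id, "c")
  expect_equal(m$pairs$distance, 0.02)

  sc$score[2] <- 0.3  # 1.5 x the caliper width
  m2 <- sequential_match(rs, sc, caliper_k = 0.2, score_sd = 1, seed = 1)
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(m2$unmatched_treated, "t")

  sc$score[2] <- 0.5
  expect_error(
    sequential_match(rs, sc[1, ], caliper_k = 0.2, score_sd = 1, seed = 1),
    "missing score for id 'c' at minute 5")
})

test_that("a control can be reused and later matched as treated", {
  tl <- data.frame(
    id = c("t1", "t2", "c", "x"),
    ecpr_minute = c(3L, 7L, 9L, NA),
    disposition = c("ECPR", "ECPR", "ECPR", "censored"),
    disposition_minute = c(3L, 7L, 9L, 120L),
    stringsAsFactors = FALSE)
  ids <- tl$id
  sc <- data.frame(
    id     = c("t1", "t2", "c", "x",  "t2", "c", "x",  "c", "x"),
    minute = c(3,    3,    3,   3,     7,    7,   7,    9,   9),
    score  = c(0,    10,   0.05, 10,   0,    0.05, 10,  0,   0.01),
    stringsAsFactors = FALSE)
  m <- sequential_match(build_risk_sets(tl), sc, caliper_k = 0.2,
                        score_sd = 1, seed = 2)
  expect_equal(nrow(m$pairs), 3)
  expect_equal(sum(m$pairs$control_id == "c"), 2)  # matched at minutes 3 and 7
  expect_equal(sum(m$pairs$treated_id == "c"), 1)  # own ECPR at minute 9
  expect_true(all(m$pairs$minute[m$pairs$control_id == "c"] <
                    tl$ecpr_minute[tl$id == "c"]))

  s <- match_summary(m, data.frame(id = ids, ecpr_minute = tl$ecpr_minute,
                                   stringsAsFactors = FALSE))
  expect_equal(s$n_pairs, 3)
  # unique controls: c (later treated) and x (never treated)
  expect_equal(s$n_unique_controls, 2)
  expect_equal(s$pct_controls_later_treated, 50)
})

test_that("no-pair and never-treated summaries are all zero", {
  m <- sequential_match(list(), data.frame(id = character(0),
                                           minute = integer(0),
                                           score = numeric(0)),
                        caliper_k = 0.2, score_sd = 1, seed = 1)
  s <- match_summary(m, data.frame(id = "a", ecpr_minute = NA_integer_))
  expect_equal(s$n_pairs, 0)
  expect_equal(s$n_unique_controls, 0)
  expect_equal(s$pct_controls_later_treated, 0)
})

test_that("matching never uses future information (truncation check)", {
  co <- apply_exclusion_criteria(
    simulate_cohort(bench_config(n = 500, seed = 25))$cohort)$eligible
  pmt <- build_person_minute_table(co)
  fit <- fit_td_finegray(pmt, covariates = c("age", "witnessed", "adren_by"))
  sc <- ps_scores(fit, pmt)
  full <- sequential_match(build_risk_sets(co$timelines), sc, 0.2,
                           fit$score_sd, seed = 3)
  t0 <- 15
  # delete everything strictly after minute t0: later dispositions become
  # administrative censoring, later interventions and ECPR starts vanish
  tl <- co$timelines
  late <- tl$disposition_minute > t0
  tl$disposition[late] <- "censored"
  tl$disposition_minute[late] <- 120L
  tl$ecpr_minute[late] <- NA_integer_
  trunc <- sequential_match(build_risk_sets(tl), sc, 0.2, fit$score_sd,
                            seed = 3)
  early <- full$pairs[full$pairs$minute <= t0, ]
  expect_gt(nrow(early), 0)
  expect_equal(trunc$pairs[trunc$pairs$minute <= t0, ], early,
               ignore_attr = TRUE)
})

test_that("every emitted pair satisfies the caliper and at-risk invariants", {
  co <- apply_exclusion_criteria(
    simulate_cohort(bench_config(n = 800, seed = 26))$cohort)$eligible
  pmt <- build_person_minute_table(co)
  fit <- fit_td_finegray(pmt, covariates = c("age", "witnessed", "adren_by",
                                             "bystander_cpr"))
  m <- sequential_match(build_risk_sets(co$timelines), ps_scores(fit, pmt),
                        0.2, fit$score_sd, seed = 4)
  p <- m$pairs
  expect_gt(nrow(p), 0)
  expect_true(all(p$distance <= 0.2 * fit$score_sd))
  expect_equal(p$distance, abs(p$treated_score - p$control_score))
  tl <- co$timelines
  dm <- setNames(tl$disposition_minute, tl$id)
  em <- setNames(tl$ecpr_minute, tl$id)
  expect_true(all(dm[p$control_id] > p$minute))
  expect_true(all(is.na(em[p$control_id]) | em[p$control_id] > p$minute))
  expect_true(all(em[p$treated_id] == p$minute))
  expect_true(all(table(p$treated_id) == 1))
})

test_that("matching equals the brute-force matcher and is seed-stable", {
  for (seed in 1:25) {
    co <- random_small_cohort(seed, n = 12 + seed %% 8)
    tl <- co$timelines
    set.seed(seed * 100)
    ids <- tl$id
    vals <- setNames(rnorm(length(ids)), ids)
    minutes <- sort(unique(tl$ecpr_minute[!is.na(tl$ecpr_minute)]))
    if (!length(minutes)) next
    sc <- scores_from(ids, minutes, vals)
    rs <- build_risk_sets(tl)
    got <- sequential_match(rs, sc, caliper_k = 0.5, score_sd = 1,
                            seed = seed)
    want <- oracle_match(rs, sc, caliper_k = 0.5, score_sd = 1, seed = seed)
    if (is.null(want$pairs)) {
      expect_equal(nrow(got$pairs), 0)
    } else {
      expect_equal(got$pairs[order(got$pairs$minute, got$pairs$treated_id),
                             c("minute", "treated_id", "control_id")],
                   want$pairs[order(want$pairs$minute, want$pairs$treated_id),
                              c("minute", "treated_id", "control_id")],
                   ignore_attr = TRUE)
    }
    expect_setequal(got$unmatched_treated, want$unmatched)
    again <- sequential_match(rs, sc, caliper_k = 0.5, score_sd = 1,
                              seed = seed)
    expect_identical(got$pairs, again$pairs)
  }
})
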