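test_that("write_cohort / read_cohort round-trips cohorts losslessly", {
  paths <- file.path(tempdir(), c("empty.csv", "one.csv", "big.csv"))
  on.exit(unlink(paths))

  empty <- toy_cohort(list(), list())
  sm <- toy_cohort(list(toy_record("a1", age = 44L)),
                   list(toy_timeline("a1", "ROSC", 12, survival = TRUE,
                                     cpc = TRUE, defib = "3;7",
                                     adren = "4", intub = 6L)))
  big <- simulate_cohort(sim_config(n = 1000, seed = 31))$cohort
  for (co in list(empty, sm, big)) {
    p <- paths[[1 + (n_patients(co) > 0) + (n_patients(co) > 1)]]
    write_cohort(co, p)
    back <- read_cohort(p)
    expect_identical(back$records, co$records)
    expect_identical(back$timelines, co$timelines)
    expect_identical(back$stratum, co$stratum)
  }
})

test_that("parquet serialization round-trips like CSV", {
  co <- simulate_cohort(sim_config(n = 200, seed = 5))$cohort
  p <- file.path(tempdir(), "cohort.parquet")
  on.exit(unlink(p))
  write_cohort(co, p, format = "parquet")
  back <- read_cohort(p, format = "parquet")
  expect_identical(back$records, co$records)
  expect_identical(back$timelines, co$timelines)
})

test_that("reader rejects malformed files with named errors", {
  co <- toy_cohort(list(toy_record("a1")), list(toy_timeline("a1")))
  p <- file.path(tempdir(), "bad.csv")
  on.exit(unlink(p))

  write_cohort(co, p)
  df <- utils::read.csv(p, colClasses = "character")
  df$mystery <- 1
  utils::write.csv(df, p, row.names = FALSE)
  expect_error(read_cohort(p), "unknown column 'mystery'")

  df$mystery <- NULL
  df$age <- "60.5"
  utils::write.csv(df, p, row.names = FALSE)
  expect_error(read_cohort(p), "non-integer .* 'age' at row 1")

  write_cohort(co, p)
  df <- utils::read.csv(p, colClasses = "character")
  utils::write.csv(rbind(df, df), p, row.names = FALSE)
  expect_error(read_cohort(p), "duplicate patient id")

  # ECPR disposition without an ECPR minute is an integrity violation
  df$disposition <- "ECPR"
  df$ecpr_minute <- ""
  utils::write.csv(df, p, row.names = FALSE)
  expect_error(read_cohort(p), "ecpr_minute == disposition_minute")
})

test_that("cohort invariants are enforced", {
  expect_error(
    toy_cohort(list(toy_record("x")),
               list(toy_timeline("x", "censored", 100))),
    "censored .* 120")
  expect_error(
    toy_cohort(list(toy_record("x")),
               list(toy_timeline("x", "ROSC", 10, survival = FALSE,
                                 cpc = TRUE))),
    "cpc_1_2 implies survival_30d")
  expect_error(
    toy_cohort(list(toy_record("x", prehosp_adrenaline_n = 7L)),
               list(toy_timeline("x", "ROSC", 10))),
    "top-coded")
})

test_that("exclusion criteria count each record once, in documented order", {
  # one record violating each criterion, in the order they are applied;
  # records 7 and 8 sit at the hospital whose capability comes from record 8
  # (an ECPR start in minute 0, itself excluded for zero disposition time)
  recs <- list(
    toy_record("r1", resuscitation_attempted = FALSE),
    toy_record("r2", age = 17L),
    toy_record("r3", arrest_cause = "external"),
    toy_record("r4", arrest_on_ems_contact = FALSE),
    toy_record("r5", rosc_before_arrival_sustained = TRUE),
    toy_record("r6", hospital_id = "h_no_ecpr"),
    toy_record("r7", hospital_id = "h2"),
    toy_record("r8", hospital_id = "h2"))
  tls <- list(
    toy_timeline("r1", "ROSC", 10),
    toy_timeline("r2", "ROSC", 10),
    toy_timeline("r3", "ROSC", 10),
    toy_timeline("r4", "ROSC", 10),
    toy_timeline("r5", "ROSC", 10),
    toy_timeline("r6", "ROSC", 10),
    toy_timeline("r7", NA_character_, 10),
    toy_timeline("r8", "ECPR", 0, ecpr = 0L))
  res <- apply_exclusion_criteria(toy_cohort(recs, tls))
  expect_equal(res$flow$n_excluded, rep(1L, 8))
  expect_equal(n_patients(res$eligible), 0)
  expect_equal(attr(res$flow, "n_input") - attr(res$flow, "n_eligible"),
               sum(res$flow$n_excluded))
})

test_that("exclusion filter is idempotent and conserves counts", {
  co <- simulate_cohort(sim_config(n = 800, seed = 9))$cohort
  r1 <- apply_exclusion_criteria(co)
  r2 <- apply_exclusion_criteria(r1$eligible)
  expect_equal(n_patients(r2$eligible), n_patients(r1$eligible))
  expect_equal(sum(r2$flow$n_excluded), 0)
  expect_equal(sum(r1$flow$n_excluded),
               n_patients(co) - n_patients(r1$eligible))
})

test_that("rhythm stratification partitions the cohort", {
  recs <- list(toy_record("a", initial_rhythm = "VF_VT"),
               toy_record("b", initial_rhythm = "PEA"),
               toy_record("c", initial_rhythm = "asystole"))
  tls <- list(toy_timeline("a", "ROSC", 5), toy_timeline("b", "ROSC", 5),
              toy_timeline("c", "ROSC", 5))
  s <- stratify_by_rhythm(toy_cohort(recs, tls))
  expect_equal(n_patients(s$shockable), 1)
  expect_equal(n_patients(s$non_shockable), 2)
  expect_equal(s$shockable$stratum, "shockable")

  allvf <- toy_cohort(recs[1], tls[1])
  s2 <- stratify_by_rhythm(allvf)
  expect_equal(n_patients(s2$non_shockable), 0)

  cfg <- sim_config(n = 100, seed = 2, covariate_params = list(
    rhythm_probs = c(VF_VT = 0.3, PEA = 0.4, asystole = 0.3)))
  co <- simulate_cohort(cfg)$cohort
  s3 <- stratify_by_rhythm(co)
  expect_equal(n_patients(s3$shockable) + n_patients(s3$non_shockable), 100)
  expect_equal(n_patients(s3$shockable),
               sum(co$records$initial_rhythm == "VF_VT"))
  expect_setequal(c(s3$shockable$records$id, s3$non_shockable$records$id),
                  co$records$id)
})

test_that("hospital volume tertiles split counts with ties going low", {
  counts <- c(a = 1, b = 2, c = 3, d = 10, e = 20, f = 30,
              g = 40, h = 50, i = 60)
  vol <- derive_hospital_volume(counts)
  expect_equal(unname(vol[c("a", "b", "c")]), rep("low", 3))
  expect_equal(unname(vol[c("d", "e", "f")]), rep("middle", 3))
  expect_equal(unname(vol[c("g", "h", "i")]), rep("high", 3))

  expect_equal(unname(derive_hospital_volume(c(x = 4, y = 4, z = 4))),
               rep("low", 3))
  expect_equal(unname(derive_hospital_volume(c(solo = 12))), "high")
  expect_error(derive_hospital_volume(numeric(0)), "empty")
})
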