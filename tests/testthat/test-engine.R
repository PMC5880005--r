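test_that("identity dynamics keep the occupancy at the start state", {
  id <- diag(12)
  r <- predict_risk(id, "OW", horizon = 7)
  expect_true(all(r$occupancy[, "OW"] == 1))
  expect_true(all(r$ms_occupancy == 0))
  expect_true(all(r$ms_cumulative == 0))
  r_ms <- predict_risk(id, "MS", horizon = 3)
  expect_true(all(r_ms$ms_occupancy == 1))
  # a non-stochastic matrix is rejected before propagation
  bad <- diag(12); bad[1, 1] <- 0.9
  expect_error(predict_risk(bad, "NONE"), "row-stochastic")
})

test_that("year-1 occupancy equals the matrix row of the start state", {
  m <- printed_matrix("men_18_49")
  for (s in c("NONE", "HYP", "MS")) {
    r <- predict_risk(m, s, horizon = 1)
    expect_equal(unname(r$occupancy["1", ]), unname(m$probs[s, ]))
  }
  # published one-step MS retention
  expect_equal(unname(predict_risk(m, "MS", 1)$ms_occupancy["1"]),
               unname(m$probs["MS", "MS"]))
  # two-step risk from NONE equals the hand-computed dot product
  r2 <- predict_risk(m, "NONE", horizon = 2)
  expect_equal(unname(r2$ms_occupancy["2"]),
               sum(m$probs["NONE", ] * m$probs[, "MS"]), tolerance = 1e-12)
})

test_that("stepwise propagation satisfies Chapman-Kolmogorov", {
  set.seed(602)
  mats <- c(list(printed_matrix("women_18_49")$probs),
            replicate(5, random_stochastic(), simplify = FALSE))
  for (P in mats) {
    r <- predict_risk(P, "NONE", horizon = 13)
    # conservation at every year
    expect_true(all(abs(rowSums(r$occupancy) - 1) < 1e-9))
    # occupancy at year n equals e1' P^n from the matrix-power oracle
    for (n in c(3, 7, 13)) {
      expect_equal(unname(r$occupancy[as.character(n), ]),
                   unname(mat_power(P, n)[1, ]), tolerance = 1e-9)
    }
  }
})

test_that("cumulative incidence is monotone, dominates occupancy, tends to 1", {
  for (nm in c("men_18_49", "women_50plus")) {
    m <- printed_matrix(nm)
    r <- predict_risk(m, "NONE", horizon = 500)
    expect_true(all(diff(r$ms_cumulative) >= -1e-12))
    expect_true(all(r$ms_cumulative - r$ms_occupancy >= -1e-12))
    expect_true(all(r$ms_cumulative <= 1 + 1e-12))
    # MS column strictly positive from every transient state -> absorption
    expect_lt(abs(r$ms_cumulative["500"] - 1), 1e-6)
  }
})

test_that("risk panels expose all starts and the two figure splits", {
  m <- printed_matrix("women_18_49")
  panel <- risk_panel(m, horizon = 10)
  expect_equal(nrow(panel), 12 * 11)
  splits <- attr(panel, "splits")
  expect_true("NONE" %in% splits$isolated)
  expect_true("NONE" %in% splits$pairs)
  expect_setequal(splits$isolated, c("NONE", "OW", "HTN", "DYS", "HYP"))
  expect_length(splits$pairs, 7)
  # panel rows match single-start predictions
  r <- predict_risk(m, "DYS", horizon = 10)
  expect_equal(panel$ms_occupancy[panel$start_state == "DYS"],
               unname(r$ms_occupancy))
})

test_that("validation compares predicted and empirical prevalence", {
  # degenerate cohort: everyone starts and stays in MS, identity dynamics
  ms_rec <- function(id, yr) make_record(subject_id = id, visit_year = yr,
                                         bmi = 28, sbp = 150, dbp = 95,
                                         tg = 2.5, fpg = 7.0)
  cohort <- classify_records(do.call(rbind, lapply(1:5, function(i)
    rbind(ms_rec(sprintf("m%d", i), 2010),
          transform(ms_rec(sprintf("m%d", i), 2012), age = 42)))))
  expect_true(all(cohort$state == "MS"))
  v <- validate_prevalence(ms_matrix(diag(12)), cohort, "MS", years = 2)
  expect_equal(v$predicted, 1)
  expect_equal(v$empirical, 1)
  expect_equal(v$n_at_risk, 5)
  # nobody observed that far out: NA with a warning, not an error
  expect_warning(v0 <- validate_prevalence(ms_matrix(diag(12)), cohort,
                                           "MS", years = 4),
                 "no subjects")
  expect_true(is.na(v0$empirical))

  # simulated cohort from a known matrix: empirical within binomial error
  spec <- cohort_spec(n_subjects = c("male_18-49" = 20000, "female_18-49" = 0,
                                     "male_50+" = 0, "female_50+" = 0),
                      dropout = 0, seed = 19)
  cohort <- classify_records(apply_eligibility(simulate_cohort(spec))$records)
  m <- printed_matrix("men_18_49")
  v <- validate_prevalence(m, cohort, "NONE", years = 3)
  se <- sqrt(v$predicted * (1 - v$predicted) / v$n_at_risk)
  expect_gt(v$n_at_risk, 200)
  expect_lt(abs(v$empirical - v$predicted), 4 * se + 1e-6)
})
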