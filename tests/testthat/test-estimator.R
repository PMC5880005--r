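test_that("cycle matrices are observed proportions with NA undefined rows", {
  states <- ms_states()
  one <- data.frame(subject_id = "s", stratum = "male_18-49", cycle = 1L,
                    from = factor("NONE", states), to = factor("MS", states))
  cm <- cycle_matrix(one, 1)
  expect_equal(unname(cm$props["NONE", ]), c(rep(0, 11), 1))
  expect_equal(unname(cm$denominators["NONE"]), 1)
  expect_true(all(is.na(cm$props[-1, ])))
  # no pairs at all: everything undefined
  cm0 <- cycle_matrix(one[0, ], 3)
  expect_true(all(is.na(cm0$props)))
  expect_error(cycle_matrix(one, 0), "cycle")
  expect_error(cycle_matrix(one, 6), "cycle")
})

test_that("cycle tallies agree with brute-force enumeration", {
  set.seed(501)
  for (rep in 1:20) {
    pairs <- random_pairs(n = sample(10:80, 1))
    k <- sample(1:5, 1)
    got <- cycle_matrix(pairs, k)
    want <- brute_cycle_tally(pairs, k)
    expect_equal(got$props, want$props, tolerance = 1e-12)
    expect_equal(unname(got$denominators), unname(want$denominators))
  }
})

test_that("row averaging skips undefined cycles and renormalizes", {
  states <- ms_states()
  # row defined in cycles 1 and 3 only: two-point average
  mk <- function(row_vals, cycle) {
    props <- matrix(NA_real_, 12, 12, dimnames = list(states, states))
    counts <- matrix(0L, 12, 12, dimnames = list(states, states))
    denom <- stats::setNames(rep(0, 12), states)
    props["NONE", ] <- row_vals
    counts["NONE", ] <- as.integer(row_vals * 10)
    denom["NONE"] <- 10
    # make every other state observed as pure self-retention
    for (s in states[-1]) {
      props[s, ] <- as.numeric(states == s)
      denom[s] <- 5
    }
    list(props = props, counts = counts, denominators = denom, cycle = cycle)
  }
  r1 <- c(0.4, 0.6, rep(0, 10))
  r3 <- c(0.6, 0.4, rep(0, 10))
  avg <- mean_matrix(list(mk(r1, 1), mk(r3, 3)))
  expect_equal(unname(avg$probs["NONE", 1:2]), c(0.5, 0.5))
  expect_equal(sum(avg$probs["NONE", ]), 1)
  # averaging identical matrices is the identity operation
  same <- mean_matrix(list(mk(r1, 1), mk(r1, 2), mk(r1, 3)))
  expect_equal(unname(same$probs["NONE", 1:2]), c(0.4, 0.6))
  # cycle order does not matter
  rev_avg <- mean_matrix(list(mk(r3, 3), mk(r1, 1)))
  expect_equal(rev_avg$probs, avg$probs)
})

test_that("never-observed rows default to identity and are flagged", {
  states <- ms_states()
  pairs <- data.frame(subject_id = "s", stratum = "male_18-49", cycle = 1L,
                      from = factor("NONE", states),
                      to = factor("OW", states))
  est <- estimate_matrix(pairs)
  expect_setequal(est$identity_rows, setdiff(states, "NONE"))
  for (s in est$identity_rows)
    expect_equal(unname(est$probs[s, ]), as.numeric(states == s))
  expect_equal(unname(est$probs["NONE", "OW"]), 1)
  # estimation output is row-stochastic to machine precision
  expect_true(all(abs(rowSums(est$probs) - 1) < 1e-9))
})

test_that("published matrices load, validate and carry the printed entries", {
  for (nm in c("men_18_49", "women_18_49", "men_50plus", "women_50plus")) {
    m <- printed_matrix(nm)
    expect_s3_class(m, "ms_matrix")
    expect_true(all(abs(rowSums(m$probs) - 1) < 1e-9))
    expect_true(all(m$probs >= 0 & m$probs <= 1))
  }
  m <- printed_matrix("men_18_49")
  # printed percent entries survive conversion (renormalization shifts
  # entries by at most 5e-4 of their size, the printed row-sum tolerance)
  expect_equal(m$probs["MS", "MS"], 0.7525, tolerance = 1e-3)
  expect_equal(m$probs["NONE", "NONE"], 0.6644, tolerance = 1e-3)
  w <- printed_matrix("women_50plus")
  expect_equal(w$probs["HTN_HYP", "MS"], 0.2499, tolerance = 1e-3)
  expect_equal(w$probs["HTN_HYP", "HTN_HYP"], 0.7501, tolerance = 1e-3)
})

test_that("the corrupt isolated-hyperglycemia cell supports both placements", {
  default <- printed_matrix("men_18_49")
  alt <- printed_matrix("men_18_49", hyperglycemia_cell = "OW_DYS")
  expect_equal(default$probs["HYP", "OW_HYP"], 0.0624, tolerance = 1e-3)
  expect_equal(default$probs["HYP", "OW_DYS"], 0)
  expect_equal(alt$probs["HYP", "OW_DYS"], 0.0624, tolerance = 1e-3)
  expect_equal(alt$probs["HYP", "OW_HYP"], 0)
  # only that one row differs between the two readings
  diff_rows <- which(rowSums(abs(default$probs - alt$probs)) > 0)
  expect_equal(names(diff_rows), "HYP")
})
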