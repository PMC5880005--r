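test_that("boundary values follow the printed inequality directions", {
  # every non-BMI value just below its cut-off, BMI exactly on it
  rec <- make_record(bmi = 25.0, sbp = 139, dbp = 89, tg = 1.69,
                     hdl = 0.90, fpg = 6.09)
  comp <- diagnose_components(rec)
  expect_equal(unlist(comp), c(overweight_obesity = TRUE,
                               hypertension = FALSE,
                               dyslipidemia = FALSE,
                               hyperglycemia = FALSE))

  # at-cut-off value is positive for every >= criterion
  ge_cases <- list(list(bmi = 25.0, comp = "overweight_obesity"),
                   list(sbp = 140, comp = "hypertension"),
                   list(dbp = 90, comp = "hypertension"),
                   list(tg = 1.7, comp = "dyslipidemia"),
                   list(fpg = 6.1, comp = "hyperglycemia"),
                   list(pg2h = 7.8, comp = "hyperglycemia"))
  for (case in ge_cases) {
    args <- case[names(case) != "comp"]
    got <- diagnose_components(do.call(make_record, args))
    expect_true(got[[case$comp]], info = names(args))
    expect_equal(sum(unlist(got)), 1, info = names(args))
  }

  # HDL criterion is strictly '<': the cut-off itself is negative
  expect_false(diagnose_components(
    make_record(sex = "female", hdl = 1.0, tg = 1.0))$dyslipidemia)
  expect_false(diagnose_components(
    make_record(sex = "male", hdl = 0.9))$dyslipidemia)
  expect_true(diagnose_components(
    make_record(sex = "male", hdl = 0.89))$dyslipidemia)
  # sex-specific cut-offs: 0.95 is low for a woman, normal for a man
  expect_true(diagnose_components(
    make_record(sex = "female", hdl = 0.95))$dyslipidemia)
  expect_false(diagnose_components(
    make_record(sex = "male", hdl = 0.95))$dyslipidemia)
})

test_that("all 16 component profiles cover the 12 states, five give MS", {
  grid <- expand.grid(ow = c(FALSE, TRUE), htn = c(FALSE, TRUE),
                      dys = c(FALSE, TRUE), hyp = c(FALSE, TRUE))
  st <- state_of(grid$ow, grid$htn, grid$dys, grid$hyp)
  expect_false(anyNA(st))
  expect_setequal(as.character(unique(st)), ms_states())
  expect_equal(sum(st == "MS"), 5)
  expect_equal(sum(st == "NONE"), 1)
  # named spot checks
  expect_equal(as.character(state_of(TRUE, FALSE, TRUE, FALSE)), "OW_DYS")
  expect_equal(as.character(state_of(TRUE, TRUE, TRUE, FALSE)), "MS")
  expect_equal(as.character(state_of(TRUE, TRUE, TRUE, TRUE)), "MS")
})

test_that("medication flags substitute only for their own component", {
  comp <- diagnose_components(
    make_record(on_antihypertensive = TRUE, sbp = 110, dbp = 70))
  expect_true(comp$hypertension)
  expect_false(any(comp$overweight_obesity, comp$dyslipidemia,
                   comp$hyperglycemia))
  comp <- diagnose_components(
    make_record(on_antihyperglycemic = TRUE, fpg = 4.5))
  expect_true(comp$hyperglycemia)
  expect_false(comp$hypertension)
})

test_that("BMI is recomputed from height and weight when they disagree", {
  rec <- make_record(bmi = 22)
  rec$height <- 1.70
  rec$weight <- 80         # true BMI 27.7, supplied 22
  expect_message(comp <- diagnose_components(rec), "recomputed")
  expect_true(comp$overweight_obesity)
  # agreement within 0.1 keeps the supplied value silently
  rec2 <- make_record(bmi = 80 / 1.7^2)
  rec2$height <- 1.70
  rec2$weight <- 80
  expect_no_message(diagnose_components(rec2))
})

test_that("missing fields and unknown sex labels raise identifiable errors", {
  rec <- make_record()
  expect_error(diagnose_components(rec[setdiff(names(rec), "tg")]), "tg")
  expect_error(diagnose_components(make_record(fpg = NA_real_)), "fpg")
  expect_error(diagnose_components(make_record(sex = "unknown")), "sex")
  # absent pg2h column is fine
  expect_no_error(diagnose_components(make_record()[
    setdiff(names(make_record()), "pg2h")]))
})

test_that("classification is deterministic and row-order independent", {
  set.seed(401)
  n <- 50
  recs <- do.call(rbind, lapply(seq_len(n), function(i)
    make_record(subject_id = sprintf("s%02d", i),
                bmi = runif(1, 20, 30), sbp = sample(100:180, 1),
                dbp = sample(60:100, 1), tg = runif(1, 0.5, 3),
                hdl = runif(1, 0.5, 2), fpg = runif(1, 4, 8))))
  cls <- classify_records(recs)
  perm <- sample(n)
  cls_perm <- classify_records(recs[perm, ])
  expect_equal(as.character(cls_perm$state), as.character(cls$state)[perm])
  expect_equal(classify_records(recs)$state, cls$state)
})
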