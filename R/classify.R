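#' CDS 2004 diagnostic cut-offs
#'
#' The component thresholds used by [diagnose_components()].  Equality
#' follows the published inequality direction: BMI, SBP, DBP, TG, FPG and
#' 2-h PG criteria are "greater than or equal", the HDL-C criterion is
#' strictly "less than" its sex-specific cut-off.  Anti-hypertensive
#' medication counts as hypertension and anti-hyperglycemic medication as
#' hyperglycemia, regardless of the measured values.
#'
#' @return Named list of numeric cut-offs (units: BMI kg/m2, blood
#'   pressure mmHg, lipids and glucose mmol/L).
#' @export
cds_cutoffs <- function() {
  list(bmi = 25.0, sbp = 140, dbp = 90, tg = 1.7,
       hdl_male = 0.9, hdl_female = 1.0, fpg = 6.1, pg2h = 7.8)
}

.required_fields <- c("age", "sex", "bmi", "sbp", "dbp", "tg", "hdl", "fpg",
                      "on_antihypertensive", "on_antihyperglycemic")

# Resolve the bmi column: recompute from height/weight when both are present
# and prefer the recomputed value if it disagrees with a supplied bmi by more
# than 0.1 kg/m2 (the discrepancy count is reported via message()).
.resolve_bmi <- function(records) {
  if (all(c("height", "weight") %in% names(records))) {
    hw <- !is.na(records$height) & !is.na(records$weight) & records$height > 0
    bmi_hw <- ifelse(hw, records$weight / records$height^2, NA_real_)
    if (!"bmi" %in% names(records)) {
      records$bmi <- bmi_hw
    } else {
      disagree <- hw & !is.na(records$bmi) & abs(records$bmi - bmi_hw) > 0.1
      if (any(disagree))
        message(sum(disagree), " record(s) had a supplied BMI differing from ",
                "weight/height^2 by > 0.1 kg/m2; the recomputed value was used")
      records$bmi[hw] <- bmi_hw[hw]
    }
  }
  records
}

#' Diagnose the four CDS components
#'
#' Applies the CDS 2004 criteria to raw check-up measurements:
#' overweight/obesity (BMI >= 25.0 kg/m2), hypertension (SBP >= 140 mmHg
#' or DBP >= 90 mmHg or anti-hypertensive use), dyslipidemia (TG >= 1.7
#' mmol/L or HDL-C < 0.9 mmol/L in men / < 1.0 mmol/L in women), and
#' hyperglycemia (FPG >= 6.1 mmol/L or 2-h post-meal glucose >= 7.8
#' mmol/L or anti-hyperglycemic use).  Each medication flag substitutes
#' only for its own component.  The 2-h glucose column \code{pg2h} is
#' optional; when absent or \code{NA}, hyperglycemia is decided from FPG
#' and medication alone.
#'
#' @param records Data frame with one row per subject-visit.  Required
#'   columns: \code{age}, \code{sex} ("male"/"female"), \code{bmi} (or
#'   \code{height} in m and \code{weight} in kg), \code{sbp}, \code{dbp},
#'   \code{tg}, \code{hdl}, \code{fpg}, \code{on_antihypertensive},
#'   \code{on_antihyperglycemic}.  Optional: \code{pg2h}.
#' @return Data frame with logical columns \code{overweight_obesity},
#'   \code{hypertension}, \code{dyslipidemia}, \code{hyperglycemia}.
#' @seealso [classify_records()] to also attach the 12-level state.
#' @export
diagnose_components <- function(records) {
  records <- .resolve_bmi(records)
  missing_cols <- setdiff(.required_fields, names(records))
  if (length(missing_cols))
    stop("missing required field(s): ", paste(missing_cols, collapse = ", "))
  for (f in .required_fields)
    if (anyNA(records[[f]]))
      stop("missing values in required field '", f,
           "'; filter incomplete records first (see apply_eligibility)")
  sex <- as.character(records$sex)
  if (!all(sex %in% c("male", "female")))
    stop("unknown sex label(s): ",
         paste(unique(sex[!sex %in% c("male", "female")]), collapse = ", "))
  cut <- cds_cutoffs()
  pg2h <- if ("pg2h" %in% names(records)) records$pg2h else
    rep(NA_real_, nrow(records))
  hdl_cut <- ifelse(sex == "male", cut$hdl_male, cut$hdl_female)
  data.frame(
    overweight_obesity = records$bmi >= cut$bmi,
    hypertension = records$sbp >= cut$sbp | records$dbp >= cut$dbp |
      as.logical(records$on_antihypertensive),
    dyslipidemia = records$tg >= cut$tg | records$hdl < hdl_cut,
    hyperglycemia = records$fpg >= cut$fpg |
      (!is.na(pg2h) & pg2h >= cut$pg2h) |
      as.logical(records$on_antihyperglycemic)
  )
}

#' Classify check-up records into metabolic states
#'
#' Augments a table of subject-visits with the four component indicator
#' columns and the 12-level \code{state} column.
#'
#' @inheritParams diagnose_components
#' @return The input data frame with columns \code{overweight_obesity},
#'   \code{hypertension}, \code{dyslipidemia}, \code{hyperglycemia} and
#'   \code{state} (factor with levels \code{ms_states()}) appended.
#' @examples
#' rec <- data.frame(subject_id = "a", visit_year = 2010, age = 40,
#'                   sex = "male", bmi = 27, sbp = 120, dbp = 75,
#'                   tg = 2.1, hdl = 1.2, fpg = 5.0,
#'                   on_antihypertensive = FALSE,
#'                   on_antihyperglycemic = FALSE)
#' classify_records(rec)$state  # OW_DYS
#' @export
classify_records <- function(records) {
  comp <- diagnose_components(records)
  records <- .resolve_bmi(records)
  out <- cbind(records, comp)
  out$state <- state_of(comp$overweight_obesity, comp$hypertension,
                        comp$dyslipidemia, comp$hyperglycemia)
  out
}
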