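#' Assign age bands and modelling strata
#'
#' Subjects are stratified by sex and baseline age.  Modelling uses the
#' coarse bands 18-49 and 50+; descriptive tables use the fine bands
#' 18-39, 40-49, 50-59 and 60+.  A subject's stratum is fixed at the
#' baseline visit and never updated, even when follow-up crosses a band
#' boundary.
#'
#' @param age Numeric vector of baseline ages (years).
#' @param type \code{"model"} for the two coarse bands, \code{"fine"} for
#'   the four descriptive bands.
#' @return Factor of band labels.
#' @examples
#' age_band(c(39, 49, 50, 63))
#' age_band(c(39, 49, 50, 63), type = "fine")
#' @export
age_band <- function(age, type = c("model", "fine")) {
  type <- match.arg(type)
  if (any(age < 18 | age > 88, na.rm = TRUE))
    stop("age outside 18-88; ineligible subjects should have been filtered")
  if (type == "model")
    cut(age, c(18, 50, 89), right = FALSE, labels = c("18-49", "50+"))
  else
    cut(age, c(18, 40, 50, 60, 89), right = FALSE,
        labels = c("18-39", "40-49", "50-59", "60+"))
}

#' @rdname age_band
#' @param sex Character vector, \code{"male"}/\code{"female"}.
#' @return \code{assign_stratum()}: factor of stratum labels such as
#'   \code{"male_18-49"}, in the canonical order men 18-49, women 18-49,
#'   men 50+, women 50+.
#' @export
assign_stratum <- function(sex, age, type = c("model", "fine")) {
  type <- match.arg(type)
  band <- age_band(age, type)
  lev <- as.vector(outer(levels(band), c("male", "female"),
                         function(b, s) paste(s, b, sep = "_")))
  factor(paste(as.character(sex), as.character(band), sep = "_"), levels = lev)
}

#' The four modelling strata
#' @return Character vector of the stratum labels used for matrix
#'   estimation, in canonical order.
#' @export
ms_strata <- function() {
  c("male_18-49", "female_18-49", "male_50+", "female_50+")
}

#' Apply cohort eligibility filters
#'
#' Retains subjects whose baseline (first-visit) age is in 18-88 years,
#' who are free of coronary heart disease, type I diabetes and familial
#' hyperlipidemia, whose retained visits all carry complete and
#' physiologically valid required fields, and who have at least two
#' visits in consecutive calendar years.  Exclusions are reported per
#' subject under the first triggering reason, in the fixed priority
#' order \code{age}, \code{disease}, \code{missing_information},
#' \code{no_consecutive_visits}.  Records with impossible values (BMI
#' <= 0, SBP <= DBP, negative lipids/glucose) count as missing
#' information.
#'
#' @param records Data frame of raw check-up rows (see
#'   [diagnose_components()] for the schema; additionally
#'   \code{subject_id}, \code{visit_year}, and the history flags
#'   \code{has_chd}, \code{has_t1dm}, \code{has_familial_hyperlipidemia}).
#' @return List with elements \code{records} (the eligible rows),
#'   \code{excluded} (data frame \code{subject_id}, \code{reason}) and
#'   \code{counts} (named exclusion tally).  An error is raised on empty
#'   input.
#' @examples
#' # see the synthetic generator for a full example:
#' spec <- cohort_spec(n_subjects = 50, seed = 1)
#' elig <- apply_eligibility(simulate_cohort(spec))
#' elig$counts
#' @export
apply_eligibility <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    stop("empty cohort: no records to filter")
  records <- .resolve_bmi(records)
  flag_cols <- c("has_chd", "has_t1dm", "has_familial_hyperlipidemia")
  for (f in c("subject_id", "visit_year", .required_fields))
    if (!f %in% names(records))
      stop("missing required field(s): ", f)
  for (f in flag_cols)
    if (!f %in% names(records)) records[[f]] <- FALSE

  ord <- order(records$subject_id, records$visit_year)
  records <- records[ord, , drop = FALSE]
  id <- records$subject_id
  first <- !duplicated(id)

  # per-record completeness / validity
  bad_rec <- rep(FALSE, nrow(records))
  for (f in .required_fields) bad_rec <- bad_rec | is.na(records[[f]])
  sex_chr <- as.character(records$sex)
  bad_rec <- bad_rec | (!is.na(sex_chr) & !sex_chr %in% c("male", "female"))
  num_ok <- !bad_rec
  bad_rec[num_ok] <- bad_rec[num_ok] |
    records$bmi[num_ok] <= 0 |
    records$sbp[num_ok] <= records$dbp[num_ok] |
    records$dbp[num_ok] <= 0 |
    records$tg[num_ok] < 0 | records$hdl[num_ok] < 0 | records$fpg[num_ok] < 0

  base_age <- records$age[first][match(id, id[first])]
  subj_bad_age <- is.na(base_age) | base_age < 18 | base_age > 88
  subj_disease <- rep(FALSE, nrow(records))
  for (f in flag_cols)
    subj_disease <- subj_disease |
      as.logical(stats::ave(records[[f]], id, FUN = function(x) any(x %in% TRUE)))
  subj_missing <- as.logical(stats::ave(bad_rec, id, FUN = any))

  # consecutive-year requirement on visits that survive the record filters
  has_consec <- vapply(split(records$visit_year, id), function(y)
    length(y) >= 2 && any(diff(sort(unique(y))) == 1), logical(1))
  subj_consec <- has_consec[match(id, names(has_consec))]

  reason <- rep(NA_character_, nrow(records))
  reason[!subj_consec] <- "no_consecutive_visits"
  reason[subj_missing] <- "missing_information"
  reason[subj_disease] <- "disease"
  reason[subj_bad_age] <- "age"

  keep <- is.na(reason)
  excluded <- unique(data.frame(subject_id = id[!keep],
                                reason = reason[!keep],
                                stringsAsFactors = FALSE))
  reasons <- c("age", "disease", "missing_information", "no_consecutive_visits")
  counts <- stats::setNames(
    vapply(reasons, function(r) sum(excluded$reason == r), integer(1)), reasons)
  counts <- c(counts, total = nrow(excluded),
              retained = length(unique(id[keep])))
  list(records = records[keep, , drop = FALSE],
       excluded = excluded[order(excluded$subject_id), , drop = FALSE],
       counts = counts)
}

#' Extract annual state-transition pairs
#'
#' Pairs adjacent visits of the same subject that are exactly one
#' calendar year apart; visits separated by a gap contribute nothing.  A
#' subject with k consecutive annual visits yields k - 1 pairs.  The
#' Markov cycle index of a pair is its from-visit year minus the cohort
#' start year plus 1, so a 2010-2015 window gives cycles 1 to 5.
#'
#' @param cohort Classified, eligible records (must carry
#'   \code{subject_id}, \code{visit_year}, \code{state}, and \code{sex} /
#'   \code{age} to fix the baseline stratum).
#' @param start_year First calendar year of the observation window
#'   (default 2010).
#' @return Data frame with columns \code{subject_id}, \code{stratum},
#'   \code{cycle}, \code{from}, \code{to}.
#' @export
extract_pairs <- function(cohort, start_year = 2010) {
  if (!"state" %in% names(cohort))
    stop("cohort has no 'state' column; run classify_records() first")
  ord <- order(cohort$subject_id, cohort$visit_year)
  cohort <- cohort[ord, , drop = FALSE]
  id <- cohort$subject_id
  first <- !duplicated(id)
  stratum <- assign_stratum(cohort$sex[first],
                            cohort$age[first])[match(id, id[first])]
  n <- nrow(cohort)
  if (n < 2)
    return(data.frame(subject_id = character(0), stratum = character(0),
                      cycle = integer(0),
                      from = factor(character(0), ms_states()),
                      to = factor(character(0), ms_states())))
  same <- id[-1] == id[-n]
  gap1 <- diff(cohort$visit_year) == 1
  i <- which(same & gap1)
  data.frame(subject_id = id[i],
             stratum = stratum[i],
             cycle = cohort$visit_year[i] - start_year + 1L,
             from = cohort$state[i],
             to = cohort$state[i + 1L])
}
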