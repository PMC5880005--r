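#' Specify a synthetic longitudinal check-up cohort
#'
#' Full parameterization of the seeded simulator used to exercise and
#' test the pipeline: staggered cohort entry over five calendar years,
#' geometric follow-up attrition capped at the end of the observation
#' window, stratum-specific Markov state dynamics (defaulting to the
#' four published matrices), and a measurement model that renders each
#' state as raw clinical values guaranteed to classify back to it.
#'
#' @param n_subjects Subjects per stratum: a single number or a named
#'   vector over [ms_strata()].
#' @param matrices Named list of [ms_matrix()] objects per stratum
#'   (default [printed_matrices()]).
#' @param entry_years Possible first-visit calendar years.
#' @param entry_probs Entry-year distribution (default uniform).
#' @param end_year Last calendar year with visits.
#' @param dropout Per-year probability of leaving the cohort after each
#'   visit (geometric follow-up length, capped at \code{end_year}).
#' @param initial_distribution Baseline state distribution (length 12,
#'   \code{ms_states()} order); default uniform.  May be a named list of
#'   per-stratum vectors.
#' @param p_medication Probability that a hypertensive (resp.
#'   hyperglycemic) subject-visit is positive through the medication
#'   flag rather than measured values.
#' @param p_pg2h Probability that a measured hyperglycemia positive
#'   comes from the 2-h post-meal glucose with normal FPG.
#' @param margin Exclusion margin around every diagnostic cut-off, in
#'   the variable's own units; 0 (default) allows values exactly on the
#'   legal side of each boundary.
#' @param contamination Named counts of planted ineligible subjects
#'   (\code{disease}, \code{missing}, \code{age}) appended to the
#'   cohort, two visits each.
#' @param seed Integer seed; together with the spec it fully determines
#'   the output.
#' @return Object of class \code{ms_cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 1000,
                        matrices = printed_matrices(),
                        entry_years = 2010:2014,
                        entry_probs = NULL,
                        end_year = 2015,
                        dropout = 0.25,
                        initial_distribution = NULL,
                        p_medication = 0.2,
                        p_pg2h = 0.1,
                        margin = 0,
                        contamination = c(disease = 0, missing = 0, age = 0),
                        seed = 1) {
  strata <- ms_strata()
  if (is.null(names(n_subjects)))
    n_subjects <- stats::setNames(rep(n_subjects[1], 4), strata)
  stopifnot(all(strata %in% names(n_subjects)),
            all(strata %in% names(matrices)))
  for (s in strata)
    if (!inherits(matrices[[s]], "ms_matrix"))
      stop("matrices[['", s, "']] is not an ms_matrix")
  if (is.null(entry_probs)) entry_probs <- rep(1, length(entry_years))
  entry_probs <- entry_probs / sum(entry_probs)
  if (any(entry_probs < 0)) stop("entry_probs must be non-negative")
  if (is.null(initial_distribution)) initial_distribution <- rep(1 / 12, 12)
  if (!is.list(initial_distribution))
    initial_distribution <- stats::setNames(
      rep(list(initial_distribution), 4), strata)
  for (s in strata) {
    d <- initial_distribution[[s]]
    if (length(d) != 12 || any(d < 0) || abs(sum(d) - 1) > 1e-9)
      stop("initial_distribution for ", s, " is not a proper 12-vector")
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  cont <- c(disease = 0, missing = 0, age = 0)
  cont[names(contamination)] <- contamination
  structure(list(n_subjects = n_subjects[strata], matrices = matrices[strata],
                 entry_years = entry_years, entry_probs = entry_probs,
                 end_year = end_year, dropout = dropout,
                 initial_distribution = initial_distribution[strata],
                 p_medication = p_medication, p_pg2h = p_pg2h,
                 margin = margin, contamination = cont,
                 seed = as.integer(seed)),
            class = "ms_cohort_spec")
}

#' @export
print.ms_cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat("  subjects/stratum:", paste(names(x$n_subjects), x$n_subjects,
                                   sep = "=", collapse = ", "), "\n")
  cat("  entry years:", paste(range(x$entry_years), collapse = "-"),
      " end:", x$end_year, " dropout:", x$dropout, "\n")
  cat("  contamination:", paste(names(x$contamination), x$contamination,
                                sep = "=", collapse = ", "),
      " seed:", x$seed, "\n")
  invisible(x)
}

.band_of_stratum <- function(s) sub("^(male|female)_", "", s)
.sex_of_stratum <- function(s) sub("_.*$", "", s)

#' Simulate metabolic state sequences
#'
#' Realizes each subject's annual visit sequence as a Markov chain from
#' the stratum's transition matrix: entry year and baseline state are
#' sampled from the spec's distributions, follow-up length is geometric
#' with the spec's dropout probability capped at the window end, and
#' each subsequent year's state is drawn from the current state's matrix
#' row.  Subjects are independent given the stratum matrix.
#'
#' @param spec A [cohort_spec()].
#' @param .seed Set the spec's seed before sampling (default TRUE; used
#'   internally to chain stages on one stream).
#' @return Data frame: \code{subject_id}, \code{stratum}, \code{sex},
#'   \code{age}, \code{visit_year}, \code{state}.
#' @export
simulate_states <- function(spec, .seed = TRUE) {
  stopifnot(inherits(spec, "ms_cohort_spec"))
  if (.seed) set.seed(spec$seed)
  states <- ms_states()
  out <- vector("list", length(ms_strata()))
  for (si in seq_along(ms_strata())) {
    s <- ms_strata()[si]
    n <- spec$n_subjects[[s]]
    if (n == 0) next
    P <- spec$matrices[[s]]$probs
    entry <- sample(spec$entry_years, n, TRUE, prob = spec$entry_probs)
    extra_max <- spec$end_year - entry
    n_extra <- if (spec$dropout > 0)
      pmin(stats::rgeom(n, spec$dropout), extra_max) else extra_max
    band <- .band_of_stratum(s)
    age0 <- if (band == "18-49") sample(18:49, n, TRUE) else
      sample(50:78, n, TRUE)
    state0 <- sample.int(12, n, TRUE, prob = spec$initial_distribution[[s]])
    id <- sprintf("%s_%05d", c("M1", "F1", "M5", "F5")[si], seq_len(n))

    max_v <- max(n_extra) + 1L
    seq_mat <- matrix(NA_integer_, n, max_v)
    seq_mat[, 1] <- state0
    for (t in seq_len(max_v - 1L)) {
      active <- which(n_extra >= t)
      if (!length(active)) break
      cur <- seq_mat[active, t]
      nxt <- integer(length(cur))
      for (k in unique(cur)) {
        idx <- which(cur == k)
        nxt[idx] <- sample.int(12, length(idx), TRUE, prob = P[k, ])
      }
      seq_mat[active, t + 1L] <- nxt
    }
    visit <- which(!is.na(seq_mat), arr.ind = TRUE)
    visit <- visit[order(visit[, 1], visit[, 2]), , drop = FALSE]
    off <- visit[, 2] - 1L
    out[[si]] <- data.frame(
      subject_id = id[visit[, 1]],
      stratum = s,
      sex = .sex_of_stratum(s),
      age = age0[visit[, 1]] + off,
      visit_year = entry[visit[, 1]] + off,
      state = factor(states[seq_mat[visit]], states))
  }
  do.call(rbind, out)
}

# grid sampler: uniform on seq(lo, hi, by = prec); degenerate range allowed
.sample_grid <- function(n, lo, hi, prec) {
  if (n == 0) return(numeric(0))
  if (hi < lo) stop("empty sampling grid (margin too large?)")
  grid <- seq(lo, hi, by = prec)
  grid[sample.int(length(grid), n, replace = TRUE)]
}

#' Render state sequences as raw check-up measurements
#'
#' Inverts the CDS classifier: for each subject-visit, samples clinical
#' values on the appropriate side of every diagnostic cut-off so the row
#' classifies back to exactly its generating state (round-trip
#' guarantee).  Hypertension and hyperglycemia positives arise through
#' the medication flag with probability \code{spec$p_medication}, and
#' measured hyperglycemia through 2-h post-meal glucose (normal FPG)
#' with probability \code{spec$p_pg2h}; values are drawn from truncated
#' uniform grids at measurement precision (BMI 0.1 kg/m2, blood
#' pressure 1 mmHg, lipids/glucose 0.01 mmol/L), leaving the spec's
#' exclusion margin around each cut-off.  The MS state is rendered by
#' sampling one of its five admissible component profiles uniformly.
#'
#' @param state_df Output of [simulate_states()].
#' @param spec The [cohort_spec()].
#' @param seed Optional seed; \code{NULL} continues the current stream.
#' @return Data frame in the raw check-up schema (see
#'   [diagnose_components()]), plus \code{subject_id} and
#'   \code{visit_year}; disease-history flags all \code{FALSE}.
#' @export
render_measurements <- function(state_df, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(state_df)
  cut <- cds_cutoffs()
  mar <- spec$margin
  st <- as.character(state_df$state)
  sex <- as.character(state_df$sex)

  flags <- matrix(FALSE, n, 4, dimnames = list(NULL, .components))
  not_ms <- st != "MS"
  if (any(not_ms)) flags[not_ms, ] <- .state_profile(st[not_ms])
  ims <- which(!not_ms)
  if (length(ims)) {
    profs <- .state_profiles_all("MS")
    flags[ims, ] <- profs[sample.int(nrow(profs), length(ims), TRUE), ,
                          drop = FALSE]
  }
  owf <- flags[, "OW"]; htnf <- flags[, "HTN"]
  dysf <- flags[, "DYS"]; hypf <- flags[, "HYP"]

  bmi <- numeric(n)
  bmi[owf] <- .sample_grid(sum(owf), cut$bmi + mar, 34, 0.1)
  bmi[!owf] <- .sample_grid(sum(!owf), 18.5, cut$bmi - 0.1 - mar, 0.1)

  # blood pressure: medication, SBP-only, DBP-only, or both mechanisms
  bmar <- ceiling(mar)
  med_htn <- htnf & stats::runif(n) < spec$p_medication
  mech <- sample.int(3, n, TRUE)
  sbp <- integer(n); dbp <- integer(n)
  neg_bp <- !htnf | med_htn
  i <- which(neg_bp)
  dbp[i] <- .sample_grid(length(i), 60, cut$dbp - 1 - bmar, 1)
  sbp[i] <- dbp[i] + .sample_grid(length(i), 20,
                                  cut$sbp - 1 - bmar - 89, 1) # stays < 140
  i <- which(htnf & !med_htn & mech == 1)               # SBP-only
  sbp[i] <- .sample_grid(length(i), cut$sbp + bmar, 195, 1)
  dbp[i] <- .sample_grid(length(i), 60, cut$dbp - 1 - bmar, 1)
  i <- which(htnf & !med_htn & mech == 2)               # DBP-only
  dbp[i] <- .sample_grid(length(i), cut$dbp + bmar, 112, 1)
  sbp[i] <- dbp[i] + .sample_grid(length(i), 5, 139 - bmar - 112, 1)
  i <- which(htnf & !med_htn & mech == 3)               # both
  sbp[i] <- .sample_grid(length(i), cut$sbp + bmar, 195, 1)
  dbp[i] <- .sample_grid(length(i), cut$dbp + bmar, 112, 1)

  # lipids: TG-only, low-HDL-only, or both
  hdl_cut <- ifelse(sex == "male", cut$hdl_male, cut$hdl_female)
  mech <- sample.int(3, n, TRUE)
  tg <- numeric(n); hdl <- numeric(n)
  i <- which(!dysf)
  tg[i] <- .sample_grid(length(i), 0.40, cut$tg - 0.01 - mar, 0.01)
  hdl[i] <- hdl_cut[i] + mar +
    .sample_grid(length(i), 0, 1.2, 0.01)
  i <- which(dysf & mech == 1)                          # TG-only
  tg[i] <- .sample_grid(length(i), cut$tg + mar, 6, 0.01)
  hdl[i] <- hdl_cut[i] + mar + .sample_grid(length(i), 0, 1.2, 0.01)
  low_hdl <- function(i) {           # strictly below the sex-specific cut-off
    out <- numeric(length(i))
    for (sx in c("male", "female")) {
      j <- sex[i] == sx
      cutx <- if (sx == "male") cut$hdl_male else cut$hdl_female
      out[j] <- .sample_grid(sum(j), 0.40, cutx - 0.01 - mar, 0.01)
    }
    out
  }
  i <- which(dysf & mech == 2)                          # low-HDL-only
  tg[i] <- .sample_grid(length(i), 0.40, cut$tg - 0.01 - mar, 0.01)
  hdl[i] <- low_hdl(i)
  i <- which(dysf & mech == 3)                          # both
  tg[i] <- .sample_grid(length(i), cut$tg + mar, 6, 0.01)
  hdl[i] <- low_hdl(i)

  # glucose: medication, 2-h PG (normal FPG), or FPG mechanisms
  med_hyp <- hypf & stats::runif(n) < spec$p_medication
  pg_mech <- hypf & !med_hyp & stats::runif(n) < spec$p_pg2h
  fpg <- numeric(n)
  pg2h <- rep(NA_real_, n)
  i <- which(!hypf | med_hyp)
  fpg[i] <- .sample_grid(length(i), 3.9, cut$fpg - 0.01 - mar, 0.01)
  i <- which(pg_mech)
  fpg[i] <- .sample_grid(length(i), 3.9, cut$fpg - 0.01 - mar, 0.01)
  pg2h[i] <- .sample_grid(length(i), cut$pg2h + mar, 16, 0.01)
  i <- which(hypf & !med_hyp & !pg_mech)
  fpg[i] <- .sample_grid(length(i), cut$fpg + mar, 13, 0.01)
  # occasionally a measured-but-normal 2-h PG on negatives
  i <- which(!hypf & stats::runif(n) < 0.1)
  pg2h[i] <- .sample_grid(length(i), 4, cut$pg2h - 0.01 - mar, 0.01)

  data.frame(subject_id = state_df$subject_id,
             visit_year = state_df$visit_year,
             age = state_df$age,
             sex = sex,
             bmi = bmi, sbp = sbp, dbp = dbp, tg = tg, hdl = hdl,
             fpg = fpg, pg2h = pg2h,
             on_antihypertensive = med_htn,
             on_antihyperglycemic = med_hyp,
             has_chd = FALSE, has_t1dm = FALSE,
             has_familial_hyperlipidemia = FALSE)
}

# planted ineligible subjects: two annual visits each, rendered as valid
# NONE-state measurements, then one violation per subject
.contaminate <- function(spec) {
  cont <- spec$contamination
  total <- sum(cont)
  if (total == 0) return(NULL)
  entry <- sample(spec$entry_years[spec$entry_years < spec$end_year],
                  total, TRUE)
  base <- data.frame(
    subject_id = sprintf("X%s_%04d",
                         rep(names(cont), cont), seq_len(total)),
    stratum = "male_18-49", sex = "male",
    age = sample(20:45, total, TRUE),
    visit_year = entry,
    state = factor("NONE", ms_states()))
  rows <- rbind(base, transform(base, age = age + 1L,
                                visit_year = visit_year + 1L))
  rows <- rows[order(rows$subject_id, rows$visit_year), ]
  rec <- render_measurements(rows, spec)
  kind <- rep(rep(names(cont), cont), each = 2)
  dis_flags <- c("has_chd", "has_t1dm", "has_familial_hyperlipidemia")
  i <- which(kind == "disease")
  if (length(i)) {
    f <- dis_flags[(match(rec$subject_id[i], unique(rec$subject_id[i])) - 1) %%
                     3 + 1]
    for (k in seq_along(i)) rec[i[k], f[k]] <- TRUE
  }
  i <- which(kind == "missing" & !duplicated(rec$subject_id))
  miss_fields <- c("bmi", "tg", "fpg", "sbp")
  if (length(i)) {
    f <- miss_fields[(seq_along(i) - 1) %% length(miss_fields) + 1]
    for (k in seq_along(i)) rec[i[k], f[k]] <- NA
  }
  i <- which(kind == "age")
  if (length(i)) {
    first <- !duplicated(rec$subject_id[i])
    bad_age <- sample(c(15:17, 89:95), sum(first), TRUE)
    rec$age[i][first] <- bad_age
    rec$age[i][!first] <- bad_age + 1L
  }
  rec
}

#' Generate a complete synthetic check-up cohort
#'
#' Runs [simulate_states()] and [render_measurements()] on one seeded
#' stream and appends any planted ineligible subjects, producing a
#' table in the same schema as real check-up input.  Identical specs
#' (including seed) produce identical output.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame of raw check-up rows.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_subjects = 100, seed = 7))
#' head(classify_records(cohort)$state)
#' @export
simulate_cohort <- function(spec) {
  states <- simulate_states(spec)
  rec <- render_measurements(states, spec)
  rec <- rbind(rec, .contaminate(spec))
  rownames(rec) <- NULL
  rec
}

#' Parameter-recovery experiment
#'
#' The analysis-grade end-to-end check: simulate a cohort from known
#' transition matrices, render measurements, classify, filter, extract
#' pairs, re-estimate the matrices, and report the per-stratum
#' discrepancy between estimate and truth over the rows actually
#' observed (identity-completed rows are excluded).
#'
#' @param spec A [cohort_spec()].
#' @return List with \code{estimates} (per-stratum [ms_matrix()]),
#'   \code{errors} (data frame: stratum, n_pairs, max_abs, rms) and
#'   \code{cohort_size}.
#' @export
recovery_experiment <- function(spec) {
  cohort <- simulate_cohort(spec)
  elig <- apply_eligibility(cohort)
  cls <- classify_records(elig$records)
  pairs <- extract_pairs(cls, start_year = min(spec$entry_years))
  n_cycles <- spec$end_year - min(spec$entry_years)
  estimates <- list()
  errors <- NULL
  for (s in ms_strata()) {
    ps <- pairs[pairs$stratum == s, , drop = FALSE]
    if (!nrow(ps)) next
    est <- estimate_matrix(ps, stratum = s, n_cycles = n_cycles)
    estimates[[s]] <- est
    rows <- setdiff(ms_states(), est$identity_rows)
    d <- est$probs[rows, , drop = FALSE] -
      spec$matrices[[s]]$probs[rows, , drop = FALSE]
    errors <- rbind(errors, data.frame(
      stratum = s, n_pairs = nrow(ps),
      max_abs = max(abs(d)), rms = sqrt(mean(d^2))))
  }
  list(estimates = estimates, errors = errors, cohort_size = nrow(cohort))
}
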