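#' Fit the 12-state annual Markov model of metabolic syndrome progression
#'
#' The package's main entry point.  Takes raw longitudinal check-up
#' records, applies the eligibility filters ([apply_eligibility()]),
#' classifies every subject-visit into the 12 metabolic states
#' ([classify_records()]), extracts annual transition pairs
#' ([extract_pairs()]) and estimates, for each of the four
#' gender-by-age strata, the annual transition-probability matrix as
#' the mean of the per-cycle transition proportions
#' ([estimate_matrix()]).
#'
#' @param data Data frame of raw check-up rows, one per subject-visit
#'   (schema in [diagnose_components()]; plus \code{subject_id},
#'   \code{visit_year} and the disease-history flags).
#' @param start_year,end_year Observation window (defaults 2010-2015,
#'   i.e. five annual Markov cycles).
#' @return Object of class \code{ms_markov}: list with
#'   \code{matrices} (named list of [ms_matrix()] per stratum),
#'   \code{pairs}, \code{cohort} (classified eligible records),
#'   \code{exclusions}, \code{n_subjects}, \code{years}, \code{call}.
#' @seealso [predict.ms_markov()], [simulate.ms_markov()],
#'   [printed_matrices()] for the published matrices.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_subjects = 300, seed = 11))
#' fit <- ms_markov(cohort)
#' fit
#' round(100 * predict(fit, stratum = "male_18-49")$ms_occupancy, 2)
#' @export
ms_markov <- function(data, start_year = 2010, end_year = 2015) {
  cl <- match.call()
  if (end_year <= start_year) stop("end_year must exceed start_year")
  elig <- apply_eligibility(data)
  cohort <- classify_records(elig$records)
  pairs <- extract_pairs(cohort, start_year = start_year)
  n_cycles <- end_year - start_year
  matrices <- list()
  for (s in ms_strata()) {
    ps <- pairs[pairs$stratum == s, , drop = FALSE]
    if (nrow(ps))
      matrices[[s]] <- estimate_matrix(ps, stratum = s, n_cycles = n_cycles)
  }
  if (!length(matrices))
    stop("no transition pairs in any stratum; cannot fit")
  structure(list(matrices = matrices, pairs = pairs, cohort = cohort,
                 exclusions = elig[c("excluded", "counts")],
                 n_subjects = length(unique(cohort$subject_id)),
                 years = c(start = start_year, end = end_year),
                 call = cl),
            class = "ms_markov")
}

#' @export
print.ms_markov <- function(x, ...) {
  cat("12-state annual Markov model of metabolic syndrome progression\n")
  cat("  window:", x$years["start"], "-", x$years["end"],
      " (", x$years["end"] - x$years["start"], "cycles )\n")
  cat("  subjects:", x$n_subjects,
      " excluded:", x$exclusions$counts[["total"]],
      " transition pairs:", nrow(x$pairs), "\n")
  cat("  strata fitted:", paste(names(x$matrices), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ms_markov <- function(object, ...) {
  strata <- names(object$matrices)
  per <- data.frame(
    stratum = strata,
    n_subjects = vapply(strata, function(s) {
      first <- !duplicated(object$cohort$subject_id)
      b <- object$cohort[first, ]
      sum(assign_stratum(b$sex, b$age) == s)
    }, numeric(1)),
    n_pairs = vapply(strata, function(s)
      sum(object$pairs$stratum == s), numeric(1)),
    identity_rows = vapply(strata, function(s)
      paste(object$matrices[[s]]$identity_rows, collapse = ","),
      character(1)))
  rownames(per) <- NULL
  first <- !duplicated(object$cohort$subject_id)
  base_states <- table(object$cohort$state[first])
  out <- list(per_stratum = per, exclusions = object$exclusions$counts,
              baseline_states = base_states, years = object$years)
  class(out) <- "summary.ms_markov"
  out
}

#' @export
print.summary.ms_markov <- function(x, ...) {
  cat("Exclusions by reason:\n")
  print(x$exclusions)
  cat("\nPer-stratum fit:\n")
  print(x$per_stratum)
  cat("\nBaseline state distribution:\n")
  print(x$baseline_states)
  invisible(x)
}

#' Extract fitted transition matrices
#'
#' @param object An [ms_markov()] fit.
#' @param stratum Optional stratum label; when given, the bare 12x12
#'   probability matrix for that stratum, otherwise a named list of all
#'   fitted matrices.
#' @param ... Unused.
#' @export
coef.ms_markov <- function(object, stratum = NULL, ...) {
  if (is.null(stratum))
    lapply(object$matrices, `[[`, "probs")
  else {
    stratum <- match.arg(stratum, names(object$matrices))
    object$matrices[[stratum]]$probs
  }
}

#' Predict MS risk from a fitted model
#'
#' @param object An [ms_markov()] fit.
#' @param stratum Stratum whose matrix to propagate (default: first
#'   fitted).
#' @param start_state Starting state (default no-component).
#' @param horizon Years to project (default 10).
#' @param ... Unused.
#' @return An \code{ms_risk} trajectory; see [predict_risk()].
#' @export
predict.ms_markov <- function(object, stratum = NULL, start_state = "NONE",
                              horizon = 10, ...) {
  if (is.null(stratum)) stratum <- names(object$matrices)[1]
  stratum <- match.arg(stratum, names(object$matrices))
  predict_risk(object$matrices[[stratum]], start_state, horizon)
}

#' Plot fitted risk curves
#'
#' Draws the 10-year MS predictive-rate curves for one stratum, in the
#' two standard splits (no-component plus isolated starts; no-component
#' plus 2-component starts).
#'
#' @param x An [ms_markov()] fit.
#' @param stratum Stratum to plot (default: first fitted).
#' @param split Curve grouping, see [plot_risk_panel()].
#' @param horizon Years to project.
#' @param ... Passed to [plot_risk_panel()].
#' @export
plot.ms_markov <- function(x, stratum = NULL, split = "isolated",
                           horizon = 10, ...) {
  if (is.null(stratum)) stratum <- names(x$matrices)[1]
  stratum <- match.arg(stratum, names(x$matrices))
  panel <- risk_panel(x$matrices[[stratum]], horizon = horizon)
  plot_risk_panel(panel, split = split, ...)
}

#' Simulate new cohorts from a fitted model
#'
#' Uses the fitted transition matrices as the generating dynamics of
#' the synthetic cohort generator, with the fitted baseline state
#' distribution as the initial distribution.
#'
#' @param object An [ms_markov()] fit covering all four strata.
#' @param nsim Number of cohorts.
#' @param seed Seed for the first cohort (subsequent cohorts use
#'   \code{seed + 1}, ...).
#' @param n_subjects Subjects per stratum (default 1000).
#' @param ... Further arguments to [cohort_spec()].
#' @return A data frame (\code{nsim = 1}) or list of data frames.
#' @export
simulate.ms_markov <- function(object, nsim = 1, seed = 1,
                               n_subjects = 1000, ...) {
  if (!all(ms_strata() %in% names(object$matrices)))
    stop("simulate() needs a fit covering all four strata")
  first <- !duplicated(object$cohort$subject_id)
  base <- object$cohort[first, ]
  strat <- assign_stratum(base$sex, base$age)
  init <- lapply(ms_strata(), function(s) {
    tab <- table(base$state[strat == s])
    if (sum(tab) == 0) rep(1 / 12, 12) else as.numeric(tab / sum(tab))
  })
  names(init) <- ms_strata()
  out <- lapply(seq_len(nsim), function(k)
    simulate_cohort(cohort_spec(n_subjects = n_subjects,
                                matrices = object$matrices,
                                initial_distribution = init,
                                seed = seed + k - 1, ...)))
  if (nsim == 1) out[[1]] else out
}
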