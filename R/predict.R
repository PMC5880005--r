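#' Predict multi-year MS risk from a starting state
#'
#' Propagates a point mass on the starting state through the annual
#' transition matrix: occupancy at year t is occupancy at year t-1 times
#' the matrix.  The MS "predictive rate" is the probability of occupying
#' the MS state at each year under the full reversible matrix (exits
#' from MS are allowed, as the published matrices contain them).  The
#' cumulative-incidence variant — probability of having ever entered MS,
#' computed with the MS row made absorbing — is always returned
#' alongside.
#'
#' @param matrix An [ms_matrix()] object (or a bare 12x12 row-stochastic
#'   matrix in \code{ms_states()} order).
#' @param start_state One of \code{ms_states()}.
#' @param horizon Number of annual cycles to propagate (default 10).
#' @return Object of class \code{ms_risk}: list with \code{occupancy}
#'   ((horizon + 1) x 12 matrix, row "0" the point mass),
#'   \code{ms_occupancy} and \code{ms_cumulative} (named numeric
#'   vectors over years 0..horizon), \code{start_state}, \code{stratum}.
#' @examples
#' r <- predict_risk(printed_matrix("men_18_49"), "NONE", horizon = 10)
#' round(100 * r$ms_occupancy["5"], 2)  # 5-year MS risk in percent
#' @export
predict_risk <- function(matrix, start_state = "NONE", horizon = 10) {
  states <- ms_states()
  stratum <- NA_character_
  if (inherits(matrix, "ms_matrix")) {
    stratum <- matrix$stratum
    P <- matrix$probs
  } else {
    P <- as.matrix(matrix)
    dimnames(P) <- list(states, states)
  }
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9))
    stop("transition matrix is not row-stochastic")
  start_state <- match.arg(start_state, states)
  if (horizon < 1) stop("horizon must be >= 1")

  occ <- matrix(NA_real_, horizon + 1, 12,
                dimnames = list(0:horizon, states))
  v <- as.numeric(states == start_state)
  occ[1, ] <- v
  Pa <- P
  Pa["MS", ] <- as.numeric(states == "MS")
  va <- v
  cum <- numeric(horizon + 1)
  cum[1] <- va[12]
  for (t in seq_len(horizon)) {
    v <- as.vector(v %*% P)
    va <- as.vector(va %*% Pa)
    occ[t + 1, ] <- v
    cum[t + 1] <- va[12]
  }
  structure(list(occupancy = occ,
                 ms_occupancy = stats::setNames(occ[, "MS"], 0:horizon),
                 ms_cumulative = stats::setNames(cum, 0:horizon),
                 start_state = start_state, stratum = stratum,
                 horizon = horizon),
            class = "ms_risk")
}

#' @export
print.ms_risk <- function(x, ...) {
  cat("MS risk trajectory — start:", x$start_state,
      " stratum:", x$stratum, "\n")
  out <- rbind(`MS occupancy (%)` = 100 * x$ms_occupancy,
               `MS cumulative (%)` = 100 * x$ms_cumulative)
  print(round(out, 2), ...)
  invisible(x)
}

#' @export
as.data.frame.ms_risk <- function(x, ...) {
  data.frame(stratum = x$stratum, start_state = x$start_state,
             year = 0:x$horizon,
             ms_occupancy = unname(x$ms_occupancy),
             ms_cumulative = unname(x$ms_cumulative))
}

#' @export
plot.ms_risk <- function(x, ...) {
  yrs <- 1:x$horizon
  graphics::matplot(yrs, 100 * cbind(x$ms_occupancy[-1], x$ms_cumulative[-1]),
                    type = "b", pch = c(16, 1), lty = c(1, 2), col = 1,
                    xlab = "Years after start",
                    ylab = "Predictive rate of MS (%)",
                    main = paste0(x$stratum, ", start ", x$start_state), ...)
  graphics::legend("topleft", c("occupancy", "cumulative (absorbing)"),
                   pch = c(16, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Risk curves for all twelve starting states
#'
#' Runs [predict_risk()] from every state and returns the curves in
#' long format, together with the two figure splits used for reporting:
#' the no-component state plus the four isolated states, and the
#' no-component state plus the six pair states.
#'
#' @inheritParams predict_risk
#' @return Data frame (\code{stratum}, \code{start_state}, \code{year},
#'   \code{ms_occupancy}, \code{ms_cumulative}) with attribute
#'   \code{splits}, a list of the two start-state groupings.
#' @export
risk_panel <- function(matrix, horizon = 10) {
  out <- do.call(rbind, lapply(ms_states(), function(s)
    as.data.frame(predict_risk(matrix, s, horizon))))
  out$start_state <- factor(out$start_state, ms_states())
  attr(out, "splits") <- list(
    isolated = c("NONE", .isolated_states),
    pairs = c("NONE", .pair_states))
  out
}

#' Plot a risk panel in the style of the published figures
#'
#' One line per starting state, years 1..horizon on the x axis and the
#' MS predictive rate (percent occupancy) on the y axis.
#'
#' @param panel Result of [risk_panel()].
#' @param split \code{"isolated"} (no-component + isolated starts) or
#'   \code{"pairs"} (no-component + 2-component starts).
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the plotted wide matrix of percentages.
#' @export
plot_risk_panel <- function(panel, split = c("isolated", "pairs"), ...) {
  split <- match.arg(split)
  starts <- attr(panel, "splits")[[split]]
  sub <- panel[panel$start_state %in% starts & panel$year >= 1, ]
  wide <- 100 * vapply(starts, function(s)
    sub$ms_occupancy[sub$start_state == s], numeric(max(panel$year)))
  graphics::matplot(seq_len(nrow(wide)), wide, type = "b",
                    pch = seq_along(starts), lty = 1,
                    col = seq_along(starts),
                    xlab = "Years after start",
                    ylab = "Predictive rate of MS (%)",
                    main = unique(as.character(sub$stratum))[1], ...)
  graphics::legend("topleft", starts, pch = seq_along(starts),
                   col = seq_along(starts), lty = 1, bty = "n", cex = 0.8)
  invisible(wide)
}

#' Validate model predictions against observed prevalence
#'
#' Compares the model-predicted MS occupancy after a given number of
#' years with the empirical MS fraction among cohort subjects who
#' started in the given state and were observed exactly that many years
#' after baseline.
#'
#' @param matrix An [ms_matrix()] for the cohort's stratum (or the whole
#'   cohort if unstratified).
#' @param cohort Classified records (with \code{subject_id},
#'   \code{visit_year}, \code{state}).
#' @param start_state Baseline state to condition on.
#' @param years Follow-up length in years (default 5).
#' @return One-row data frame: \code{start_state}, \code{years},
#'   \code{predicted} and \code{empirical} MS probabilities,
#'   \code{n_at_risk}, \code{n_ms}.  When no subject has the required
#'   follow-up the empirical columns are \code{NA} (with a warning), not
#'   an error.
#' @export
validate_prevalence <- function(matrix, cohort, start_state = "NONE",
                                years = 5) {
  pred <- predict_risk(matrix, start_state, horizon = years)
  ord <- order(cohort$subject_id, cohort$visit_year)
  cohort <- cohort[ord, , drop = FALSE]
  first <- !duplicated(cohort$subject_id)
  base <- cohort[first, c("subject_id", "visit_year", "state")]
  base <- base[base$state == start_state, , drop = FALSE]
  tgt_year <- base$visit_year + years
  key <- paste(cohort$subject_id, cohort$visit_year)
  hit <- match(paste(base$subject_id, tgt_year), key)
  obs <- cohort$state[hit[!is.na(hit)]]
  n <- length(obs)
  if (n == 0) {
    warning("no subjects starting in ", start_state,
            " observed ", years, " years after baseline")
    emp <- NA_real_
    n_ms <- NA_integer_
  } else {
    n_ms <- sum(obs == "MS")
    emp <- n_ms / n
  }
  data.frame(start_state = start_state, years = years,
             predicted = unname(pred$ms_occupancy[as.character(years)]),
             empirical = emp, n_at_risk = n, n_ms = n_ms)
}
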