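#' Construct an annual transition-probability matrix object
#'
#' Container for a 12x12 row-stochastic matrix together with its
#' provenance: per-cycle proportion matrices and denominators when
#' estimated from data, transition counts, and flags for states never
#' observed at risk (whose rows are completed as identity).
#'
#' @param probs 12x12 numeric matrix, rows and columns in
#'   \code{ms_states()} order; every row must sum to 1 within 1e-9.
#' @param stratum Stratum label (see [ms_strata()]), or \code{NA}.
#' @param counts Optional 12x12 matrix of transition counts.
#' @param per_cycle Optional list of per-cycle results from
#'   [cycle_matrix()].
#' @param identity_rows Character vector of states whose rows were
#'   defaulted to identity because no transition from them was observed.
#' @param source Free-text provenance (e.g. the source table of a
#'   published matrix).
#' @return Object of class \code{ms_matrix}.
#' @export
ms_matrix <- function(probs, stratum = NA_character_, counts = NULL,
                      per_cycle = NULL, identity_rows = character(0),
                      source = "estimated") {
  states <- ms_states()
  probs <- as.matrix(probs)
  if (!all(dim(probs) == c(12, 12)))
    stop("probs must be a 12x12 matrix")
  dimnames(probs) <- list(states, states)
  if (any(probs < 0) || any(probs > 1))
    stop("transition probabilities must lie in [0, 1]")
  dev <- abs(rowSums(probs) - 1)
  if (any(dev > 1e-9))
    stop("matrix is not row-stochastic; worst row '",
         states[which.max(dev)], "' deviates by ", signif(max(dev), 3))
  structure(list(probs = probs, stratum = stratum, counts = counts,
                 per_cycle = per_cycle, identity_rows = identity_rows,
                 source = source),
            class = "ms_matrix")
}

#' @export
print.ms_matrix <- function(x, digits = 4, ...) {
  cat("Annual transition-probability matrix (12 metabolic states)\n")
  cat("  stratum:", x$stratum, "  source:", x$source, "\n")
  if (length(x$identity_rows))
    cat("  unobserved rows set to identity:",
        paste(x$identity_rows, collapse = ", "), "\n")
  print(round(x$probs, digits), ...)
  invisible(x)
}

#' Per-cycle transition-proportion matrix
#'
#' Tallies the transition pairs of one Markov cycle into a 12x12
#' proportion matrix: entry (i, j) is the number of pairs moving from
#' state i to state j divided by the number of pairs leaving state i in
#' that cycle.  Rows with zero denominator are returned as \code{NA}
#' (undefined), never as zeros.
#'
#' @param pairs Transition pairs from [extract_pairs()], already
#'   restricted to one stratum.
#' @param cycle Cycle index to tally.
#' @param n_cycles Number of cycles in the observation window (default
#'   5); \code{cycle} must lie in \code{1:n_cycles}.
#' @return List with \code{props} (12x12, \code{NA} rows where
#'   undefined), \code{counts} (12x12 integer), \code{denominators}
#'   (length-12 integer) and \code{cycle}.
#' @export
cycle_matrix <- function(pairs, cycle, n_cycles = 5) {
  if (length(cycle) != 1 || is.na(cycle) || cycle < 1 || cycle > n_cycles)
    stop("cycle must be a single integer in 1..", n_cycles)
  states <- ms_states()
  p <- pairs[pairs$cycle == cycle, , drop = FALSE]
  counts <- table(factor(p$from, states), factor(p$to, states))
  counts <- matrix(as.integer(counts), 12, 12,
                   dimnames = list(states, states))
  denom <- rowSums(counts)
  props <- counts / ifelse(denom > 0, denom, NA_real_)
  list(props = props, counts = counts, denominators = denom, cycle = cycle)
}

#' Average per-cycle matrices into the annual transition matrix
#'
#' Each row of the final matrix is the arithmetic mean of that row over
#' the cycles in which it is defined (observed at least once);
#' zero-denominator rows are excluded from the mean rather than averaged
#' as zeros.  After averaging, every row is renormalized to sum to
#' exactly 1 (pre-normalization deviation is available in the
#' \code{row_deviation} attribute).  States observed in no cycle get the
#' identity row (self-retention 1) and are flagged in
#' \code{identity_rows}.
#'
#' @param cycles List of per-cycle results from [cycle_matrix()].
#' @param stratum Stratum label to record on the result.
#' @return An [ms_matrix()] object.
#' @export
mean_matrix <- function(cycles, stratum = NA_character_) {
  if (!length(cycles)) stop("no cycle matrices supplied")
  states <- ms_states()
  probs <- matrix(0, 12, 12, dimnames = list(states, states))
  counts <- matrix(0L, 12, 12, dimnames = list(states, states))
  defined <- numeric(12)
  for (cm in cycles) {
    ok <- cm$denominators > 0
    probs[ok, ] <- probs[ok, ] + cm$props[ok, , drop = FALSE]
    defined <- defined + ok
    counts <- counts + cm$counts
  }
  identity_rows <- states[defined == 0]
  probs[defined > 0, ] <- probs[defined > 0, , drop = FALSE] /
    defined[defined > 0]
  rs <- rowSums(probs)
  deviation <- stats::setNames(rs - 1, states)
  deviation[defined == 0] <- NA_real_
  probs[defined > 0, ] <- probs[defined > 0, , drop = FALSE] /
    rs[defined > 0]
  for (s in identity_rows) probs[s, ] <- as.numeric(states == s)
  out <- ms_matrix(probs, stratum = stratum, counts = counts,
                   per_cycle = cycles, identity_rows = identity_rows)
  attr(out, "row_deviation") <- deviation
  out
}

#' Estimate the annual transition matrix from pairs
#'
#' Convenience wrapper: tallies every cycle with [cycle_matrix()] and
#' averages with [mean_matrix()].
#'
#' @inheritParams cycle_matrix
#' @inheritParams mean_matrix
#' @return An [ms_matrix()] object.
#' @export
estimate_matrix <- function(pairs, stratum = NA_character_, n_cycles = 5) {
  cycles <- lapply(seq_len(n_cycles), function(k)
    cycle_matrix(pairs, k, n_cycles = n_cycles))
  mean_matrix(cycles, stratum = stratum)
}
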