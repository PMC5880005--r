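#' The twelve metabolic states
#'
#' The state space used throughout the package: one no-component state,
#' four isolated-component states, six two-component states, and the
#' metabolic-syndrome (MS) state, which pools every profile with three or
#' more components.  The order returned here is the canonical row/column
#' order of every transition matrix in the package.
#'
#' @return Character vector of the 12 state labels.
#' @examples
#' ms_states()
#' @export
ms_states <- function() {
  c("NONE", "OW", "HTN", "DYS", "HYP",
    "OW_HTN", "OW_DYS", "OW_HYP", "HTN_DYS", "HTN_HYP", "DYS_HYP", "MS")
}

# component short codes, in the order used to build pair-state labels
.components <- c("OW", "HTN", "DYS", "HYP")

# component column names on classified records
.component_cols <- c("overweight_obesity", "hypertension",
                     "dyslipidemia", "hyperglycemia")

.isolated_states <- c("OW", "HTN", "DYS", "HYP")
.pair_states <- c("OW_HTN", "OW_DYS", "OW_HYP", "HTN_DYS", "HTN_HYP", "DYS_HYP")

#' Map component profiles to metabolic states
#'
#' Collapses the four CDS component indicators into one of the 12 states.
#' Zero positive components give \code{NONE}; one gives the matching
#' isolated state; two give the matching pair state; three or four give
#' \code{MS}.  The map is total: every one of the 16 possible profiles
#' has exactly one state.
#'
#' @param overweight_obesity,hypertension,dyslipidemia,hyperglycemia
#'   Logical vectors of equal length (or length 1, recycled).
#' @return Factor with levels \code{ms_states()}.
#' @examples
#' state_of(FALSE, FALSE, FALSE, FALSE)  # NONE
#' state_of(TRUE, FALSE, TRUE, FALSE)    # OW_DYS
#' state_of(TRUE, TRUE, TRUE, TRUE)      # MS
#' @export
state_of <- function(overweight_obesity, hypertension,
                     dyslipidemia, hyperglycemia) {
  flags <- cbind(OW = as.logical(overweight_obesity),
                 HTN = as.logical(hypertension),
                 DYS = as.logical(dyslipidemia),
                 HYP = as.logical(hyperglycemia))
  if (anyNA(flags))
    stop("component flags must not contain NA")
  n_comp <- rowSums(flags)
  out <- character(nrow(flags))
  out[n_comp == 0] <- "NONE"
  out[n_comp >= 3] <- "MS"
  one <- n_comp == 1
  if (any(one))
    out[one] <- .components[apply(flags[one, , drop = FALSE], 1, which.max)]
  two <- n_comp == 2
  if (any(two))
    out[two] <- apply(flags[two, , drop = FALSE], 1, function(f)
      paste(.components[f], collapse = "_"))
  factor(out, levels = ms_states())
}

# canonical component profile for each non-MS state; MS has five admissible
# profiles (the four 3-component ones and the 4-component one) and is handled
# by callers that need a concrete profile.
.state_profile <- function(state) {
  state <- as.character(state)
  parts <- strsplit(state, "_", fixed = TRUE)
  t(vapply(parts, function(p) {
    if (identical(p, "NONE")) return(stats::setNames(rep(FALSE, 4), .components))
    if (identical(p, "MS")) stop("MS has no unique component profile")
    stats::setNames(.components %in% p, .components)
  }, logical(4)))
}

# all component profiles compatible with a state (5 rows for MS, 1 otherwise)
.state_profiles_all <- function(state) {
  if (state != "MS") return(.state_profile(state))
  grid <- as.matrix(expand.grid(OW = c(FALSE, TRUE), HTN = c(FALSE, TRUE),
                                DYS = c(FALSE, TRUE), HYP = c(FALSE, TRUE)))
  grid[rowSums(grid) >= 3, , drop = FALSE]
}
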