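#' Load a published transition matrix
#'
#' The package ships the four published annual transition-probability
#' matrices for the gender-by-age strata (men and women, 18-49 and 50+
#' years) as plain-text JSON fixtures carrying the printed two-decimal
#' percent entries.  Loading validates every row sum against 100 within
#' +/- 0.05 percent, converts to proportions and renormalizes each row
#' to sum to exactly 1.
#'
#' The isolated-hyperglycemia row of the men 18-49 matrix is printed
#' with a typographically corrupt cell ("0.6.24"); the fixture resolves
#' it as 6.24 percent in the overweight/obesity-and-hyperglycemia
#' (\code{OW_HYP}) column, under which the row sums to 99.99 and the
#' analogous cell is nonzero in the other strata.  The alternate reading
#' (6.24 in the \code{OW_DYS} column) is available through
#' \code{hyperglycemia_cell = "OW_DYS"}.
#'
#' @param name One of \code{"men_18_49"}, \code{"women_18_49"},
#'   \code{"men_50plus"}, \code{"women_50plus"}.
#' @param hyperglycemia_cell Placement of the corrupt men-18-49 cell;
#'   ignored for the other matrices.
#' @return An [ms_matrix()] object (proportions, row-stochastic).
#' @examples
#' m <- printed_matrix("men_18_49")
#' m$probs["MS", "MS"]  # 0.7525 before renormalization rounding
#' @export
printed_matrix <- function(name = c("men_18_49", "women_18_49",
                                    "men_50plus", "women_50plus"),
                           hyperglycemia_cell = c("OW_HYP", "OW_DYS")) {
  name <- match.arg(name)
  hyperglycemia_cell <- match.arg(hyperglycemia_cell)
  path <- system.file("extdata", paste0(name, ".json"), package = "msprog")
  if (path == "")
    stop("fixture '", name, "' not found")
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  states <- ms_states()
  stopifnot(identical(j$states, states))
  pct <- do.call(rbind, j$rows[states])
  colnames(pct) <- states
  if (name == "men_18_49" && hyperglycemia_cell == "OW_DYS") {
    pct["HYP", "OW_DYS"] <- pct["HYP", "OW_HYP"]
    pct["HYP", "OW_HYP"] <- 0
  }
  bad <- abs(rowSums(pct) - 100) > 0.05
  if (any(bad))
    stop("fixture-integrity error in '", name, "': row(s) ",
         paste(states[bad], collapse = ", "),
         " do not sum to 100 within +/- 0.05")
  probs <- pct / 100
  probs <- probs / rowSums(probs)
  ms_matrix(probs,
            stratum = paste(j$stratum$sex, j$stratum$age_band, sep = "_"),
            source = paste0("published (", j$source_table, ")"))
}

#' @rdname printed_matrix
#' @return \code{printed_matrices()}: named list of all four matrices,
#'   keyed by the [ms_strata()] labels.
#' @export
printed_matrices <- function() {
  nm <- c("men_18_49", "women_18_49", "men_50plus", "women_50plus")
  out <- lapply(nm, printed_matrix)
  stats::setNames(out, ms_strata())
}
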