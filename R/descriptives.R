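#' Pearson chi-square across groups
#'
#' Tests equality of a proportion across k groups by the uncorrected
#' Pearson chi-square on the 2 x k table (positive/negative by group),
#' with k - 1 degrees of freedom.  This is the test used for the
#' categorical rows of the descriptive tables.
#'
#' @param positives Integer vector of positive counts, one per group.
#' @param totals Integer vector of group denominators.
#' @return List with \code{statistic}, \code{df}, \code{p.value} and
#'   \code{p.formatted} (\code{"< 0.0001"} below that threshold).
#' @examples
#' chisq_across_groups(c(2220, 2781, 1513, 933), c(4730, 5088, 2678, 1754))
#' @export
chisq_across_groups <- function(positives, totals) {
  k <- length(positives)
  if (k < 2 || length(totals) != k)
    stop("need k >= 2 groups with matching denominators")
  if (any(totals <= 0)) stop("all denominators must be > 0")
  if (any(positives < 0) || any(positives > totals))
    stop("positives must lie in [0, totals]")
  tab <- rbind(positives, totals - positives)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0))
    stop("zero expected cell count; chi-square is undefined")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  p <- unname(ct$p.value)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = p,
       p.formatted = if (p < 1e-4) "< 0.0001" else format(round(p, 4)))
}

.outcomes <- function() c(.component_cols, "MS")

#' Prevalence tables by stratum or follow-up year
#'
#' Reproduces the descriptive layer of the analysis: counts and
#' percentages of the four components and of MS, either at baseline by
#' sex and fine age band (18-39, 40-49, 50-59, 60+) with a chi-square
#' test across the bands within each sex, or by follow-up year across
#' the whole cohort.
#'
#' @param cohort Classified records ([classify_records()] output with
#'   \code{subject_id} and \code{visit_year}).
#' @param by \code{"sex_age"} for the baseline table (first visit per
#'   subject), \code{"follow_up"} for the per-follow-up-year table.
#' @return Data frame with one row per group: \code{n}, \code{age_mean},
#'   \code{age_sd}, and for each outcome a count and a percentage
#'   (2 decimals).  For \code{by = "sex_age"} the result carries a
#'   \code{tests} attribute: chi-square statistic, df and p per sex and
#'   outcome across the age bands.
#' @export
prevalence_table <- function(cohort, by = c("sex_age", "follow_up")) {
  by <- match.arg(by)
  ord <- order(cohort$subject_id, cohort$visit_year)
  cohort <- cohort[ord, , drop = FALSE]
  cohort$MS <- cohort$state == "MS"
  if (by == "sex_age") {
    base <- cohort[!duplicated(cohort$subject_id), , drop = FALSE]
    base$band <- age_band(base$age, "fine")
    groups <- split(base, list(base$sex, base$band), drop = FALSE)
    grp_names <- expand.grid(band = levels(base$band),
                             sex = c("male", "female"))
    keys <- paste(grp_names$sex, grp_names$band, sep = ".")
    rows <- lapply(keys, function(k) .prev_row(groups[[k]]))
    out <- cbind(grp_names[, c("sex", "band")], do.call(rbind, rows))
    tests <- do.call(rbind, lapply(c("male", "female"), function(sx) {
      do.call(rbind, lapply(.outcomes(), function(oc) {
        pos <- out[out$sex == sx, paste0(oc, "_n")]
        tot <- out[out$sex == sx, "n"]
        if (any(tot == 0))
          return(data.frame(sex = sx, outcome = oc, statistic = NA_real_,
                            df = NA_real_, p = NA_character_))
        cs <- chisq_across_groups(pos, tot)
        data.frame(sex = sx, outcome = oc, statistic = cs$statistic,
                   df = cs$df, p = cs$p.formatted)
      }))
    }))
    attr(out, "tests") <- tests
  } else {
    cohort$fy <- stats::ave(cohort$visit_year, cohort$subject_id,
                            FUN = function(y) y - min(y))
    groups <- split(cohort, cohort$fy)
    out <- cbind(data.frame(follow_up_year = as.integer(names(groups))),
                 do.call(rbind, lapply(groups, .prev_row)))
    rownames(out) <- NULL
  }
  out
}

.prev_row <- function(g) {
  n <- if (is.null(g)) 0L else nrow(g)
  row <- data.frame(n = n,
                    age_mean = if (n) round(mean(g$age), 2) else NA_real_,
                    age_sd = if (n) round(stats::sd(g$age), 2) else NA_real_)
  for (oc in .outcomes()) {
    cnt <- if (n) sum(g[[oc]]) else 0L
    row[[paste0(oc, "_n")]] <- cnt
    row[[paste0(oc, "_pct")]] <- if (n) round(100 * cnt / n, 2) else NA_real_
  }
  row
}
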