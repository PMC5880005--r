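# shared fixtures and independent oracles (deliberately naive implementations)

# a single valid check-up row, fields overridable
make_record <- function(...) {
  rec <- data.frame(subject_id = "s1", visit_year = 2010, age = 40,
                    sex = "male", bmi = 22, sbp = 120, dbp = 75,
                    tg = 1.0, hdl = 1.3, fpg = 5.0, pg2h = NA_real_,
                    on_antihypertensive = FALSE, on_antihyperglycemic = FALSE,
                    has_chd = FALSE, has_t1dm = FALSE,
                    has_familial_hyperlipidemia = FALSE,
                    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

# a clean subject with visits in the given years (NONE state measurements)
make_subject <- function(id, years, age0 = 40, sex = "male", ...) {
  do.call(rbind, lapply(seq_along(years), function(k)
    make_record(subject_id = id, visit_year = years[k],
                age = age0 + (years[k] - years[1]), sex = sex, ...)))
}

# brute-force per-cycle tally: explicit double loop, no shared code with
# cycle_matrix()
brute_cycle_tally <- function(pairs, cycle) {
  states <- ms_states()
  counts <- matrix(0, 12, 12, dimnames = list(states, states))
  for (r in seq_len(nrow(pairs))) {
    if (pairs$cycle[r] == cycle) {
      i <- match(as.character(pairs$from[r]), states)
      j <- match(as.character(pairs$to[r]), states)
      counts[i, j] <- counts[i, j] + 1
    }
  }
  denom <- rowSums(counts)
  props <- counts
  for (i in 1:12)
    props[i, ] <- if (denom[i] > 0) counts[i, ] / denom[i] else NA_real_
  list(props = props, counts = counts, denominators = denom)
}

# matrix power by repeated squaring (independent of step-wise propagation)
mat_power <- function(P, n) {
  out <- diag(nrow(P))
  B <- P
  while (n > 0) {
    if (n %% 2 == 1) out <- out %*% B
    B <- B %*% B
    n <- n %/% 2
  }
  out
}

# chi-square by the direct sum over observed/expected cells
brute_chisq <- function(positives, totals) {
  tab <- rbind(positives, totals - positives)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# random row-stochastic 12x12 matrix
random_stochastic <- function() {
  x <- matrix(stats::rgamma(144, shape = 1), 12, 12)
  x / rowSums(x)
}

# random small set of transition pairs across cycles
random_pairs <- function(n = 60) {
  states <- ms_states()
  data.frame(subject_id = sprintf("p%03d", seq_len(n)),
             stratum = "male_18-49",
             cycle = sample(1:5, n, TRUE),
             from = factor(sample(states, n, TRUE), states),
             to = factor(sample(states, n, TRUE), states))
}
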