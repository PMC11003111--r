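# Brute-force day-resolution oracle for the supply-diary coverage engine,
# plus small fixture builders shared across test files.

# simulate the balance one calendar day at a time: at the start of each day,
# cap the balance at an interval boundary, add any dispensing, then consume
# one day if supply is on hand
oracle_covered_days <- function(disp_dates, index_date, end_date,
                                supply_days = 182L, cap_days = 182L) {
  covered <- logical(max(end_date - index_date, 0L))
  bal <- 0
  for (d in seq(index_date, end_date - 1L)) {
    if (d > index_date && (d - index_date) %% 182L == 0L)
      bal <- min(bal, cap_days)
    if (d %in% disp_dates) bal <- bal + supply_days
    if (bal > 0) { covered[d - index_date + 1L] <- TRUE; bal <- bal - 1 }
  }
  covered
}

oracle_pdc <- function(disp_dates, index_date, end_date,
                       interval_len = 182L, min_final = 14L) {
  cov <- oracle_covered_days(disp_dates, index_date, end_date)
  span <- end_date - index_date
  n_int <- as.integer(ceiling(span / interval_len))
  starts <- (seq_len(n_int) - 1L) * interval_len
  ends <- pmin(starts + interval_len, span)
  denom <- ends - starts
  if (n_int > 1L && denom[n_int] < min_final) {
    n_int <- n_int - 1L
    starts <- starts[seq_len(n_int)]; ends <- ends[seq_len(n_int)]
    denom <- denom[seq_len(n_int)]
  }
  covered <- vapply(seq_len(n_int), function(k)
    sum(cov[(starts[k] + 1L):ends[k]]), numeric(1))
  data.frame(t = seq_len(n_int) - 1L, covered_days = covered,
             denominator_days = denom, pdc = covered / denom)
}

make_visits <- function(id, dates, reported = TRUE, therapy = "TAM") {
  data.frame(patient_id = id, visit_date = as.integer(dates),
             aet_reported = rep_len(reported, length(dates)),
             therapy = rep_len(therapy, length(dates)),
             stringsAsFactors = FALSE)
}

make_censoring <- function(id, date, reason = "death") {
  data.frame(patient_id = id, event_date = as.integer(date),
             reason = reason, stringsAsFactors = FALSE)
}

empty_censoring <- function() {
  data.frame(patient_id = character(), event_date = integer(),
             reason = character(), stringsAsFactors = FALSE)
}

make_patients <- function(ids, diagnosis_date = 0L, age = 45) {
  data.frame(patient_id = ids,
             diagnosis_date = rep_len(as.integer(diagnosis_date), length(ids)),
             age_at_diagnosis = rep_len(age, length(ids)),
             stringsAsFactors = FALSE)
}

# standard three-group generating model used across recovery tests
recovery_polys <- function() {
  list(high = c(0.97, 0, 0),
       slow = c(0.98, -0.20, -0.35),
       rapid = c(0.95, -2.40, 1.20))
}
recovery_mixing <- function() c(0.57, 0.36, 0.07)
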