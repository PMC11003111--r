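# Eligibility cascade, supply diaries and interval PDC panels.
#
# Supply model: every visit at which endocrine-therapy use is reported adds a
# 182-day supply to a running on-hand balance, consumed one day per calendar
# day from the day of dispensing; at each 182-day interval boundary the
# balance carried into the next interval is capped at 182 days. Aromatase-
# inhibitor registrations after tamoxifen initiation count as adherence.

#' Arithmetic of an exclusion cascade
#'
#' Applies an ordered sequence of step removals to a starting count and
#' returns the per-step ledger: removed and remaining at each step.
#'
#' @param n_start starting count
#' @param removals integer vector of counts removed per step, in order
#' @param labels optional step labels
#' @return data frame (step, n_removed, n_remaining) with attribute
#'   \code{n_start}; the last \code{n_remaining} is the analytic cohort size
#' @export
cascade_table <- function(n_start, removals, labels = NULL) {
  stopifnot(n_start >= 0, all(removals >= 0))
  remaining <- n_start - cumsum(removals)
  if (any(remaining < 0)) stop("removals exceed available count", call. = FALSE)
  out <- data.frame(
    step = labels %||% paste0("step_", seq_along(removals)),
    n_removed = as.integer(removals),
    n_remaining = as.integer(remaining),
    stringsAsFactors = FALSE
  )
  attr(out, "n_start") <- as.integer(n_start)
  out
}

first_initiation <- function(visits) {
  v <- visits[visits$aet_reported, , drop = FALSE]
  if (nrow(v) == 0L)
    return(data.frame(patient_id = character(), init_date = integer(),
                      init_therapy = character(), stringsAsFactors = FALSE))
  v <- v[order(v$patient_id, v$visit_date), ]
  keep <- !duplicated(v$patient_id)
  data.frame(patient_id = v$patient_id[keep],
             init_date = v$visit_date[keep],
             init_therapy = v$therapy[keep],
             stringsAsFactors = FALSE)
}

earliest_censoring <- function(censoring) {
  if (is.null(censoring) || nrow(censoring) == 0L)
    return(data.frame(patient_id = character(), event_date = integer(),
                      reason = character(), stringsAsFactors = FALSE))
  cc <- censoring[order(censoring$patient_id, censoring$event_date), ]
  cc[!duplicated(cc$patient_id), c("patient_id", "event_date", "reason")]
}

#' Apply the cohort eligibility cascade
#'
#' Ordered exclusions: ER-negative patients (when an \code{er_status} column
#' is present); patients who never registered endocrine-therapy use; less
#' than one year of follow-up after initiation; age 55 or older at diagnosis
#' or first registered therapy an aromatase inhibitor; initiation before
#' diagnosis, after a recurrence, or after a second primary cancer. Order is
#' fixed: a patient is counted against the first step that catches them.
#'
#' @param patients patient table (needs patient_id, diagnosis_date,
#'   age_at_diagnosis; optionally er_status)
#' @param visits visit table (patient_id, visit_date, aet_reported, therapy)
#' @param censoring censoring table (patient_id, event_date, reason)
#' @param min_follow_up_days minimum post-initiation follow-up (default 365)
#' @param max_age maximum age at diagnosis (default 55, exclusive)
#' @return list with \code{eligible_ids} and \code{log} (a
#'   \code{\link{cascade_table}})
#' @export
apply_eligibility <- function(patients, visits, censoring,
                              min_follow_up_days = 365L, max_age = 55) {
  orphans <- setdiff(unique(c(visits$patient_id, censoring$patient_id)),
                     patients$patient_id)
  if (length(orphans))
    stop("visit/censoring records reference unknown patients: ",
         paste(head(orphans, 5L), collapse = ", "), call. = FALSE)

  init <- first_initiation(visits)
  cens <- earliest_censoring(censoring)
  d <- patients[, c("patient_id", "diagnosis_date", "age_at_diagnosis")]
  d$init_date <- init$init_date[match(d$patient_id, init$patient_id)]
  d$init_therapy <- init$init_therapy[match(d$patient_id, init$patient_id)]
  d$cens_date <- cens$event_date[match(d$patient_id, cens$patient_id)]
  d$cens_reason <- cens$reason[match(d$patient_id, cens$patient_id)]
  d$end_date <- pmin(d$diagnosis_date + FIVE_YEARS_DAYS,
                     ifelse(is.na(d$cens_date), Inf, d$cens_date))

  alive <- rep(TRUE, nrow(d))
  steps <- character(0); removed <- integer(0)
  drop_step <- function(name, hit) {
    hit <- hit & alive
    steps <<- c(steps, name)
    removed <<- c(removed, sum(hit))
    alive <<- alive & !hit
  }

  if ("er_status" %in% names(patients))
    drop_step("er_negative",
              as.character(patients$er_status) == "negative")
  drop_step("no_aet_initiation", is.na(d$init_date))
  drop_step("follow_up_lt_1yr",
            !is.na(d$init_date) &
              (d$end_date - d$init_date) < min_follow_up_days)
  drop_step("age_ge_55_or_ai_initiation",
            d$age_at_diagnosis >= max_age |
              (!is.na(d$init_therapy) & d$init_therapy == "AI"))
  drop_step("initiation_timing",
            !is.na(d$init_date) &
              (d$init_date < d$diagnosis_date |
                 (!is.na(d$cens_date) &
                    d$cens_reason %in% c("recurrence", "second_primary") &
                    d$init_date > d$cens_date)))

  log <- cascade_table(nrow(d), removed, steps)
  list(eligible_ids = d$patient_id[alive], log = log)
}

#' Build a patient's supply diary
#'
#' Turns a patient's visit registrations into day-level medication coverage.
#' The diary runs from the first registration of endocrine-therapy use
#' (index date) to the earlier of censoring and five years after diagnosis.
#' Each use registration dispenses a 182-day supply added to a running
#' balance consumed one day per day; at each 182-day interval boundary the
#' carried-over balance is capped at 182 days. Same-day duplicates collapse
#' to one dispensing; therapy type is ignored for coverage (a switch to an
#' aromatase inhibitor still counts as adherence).
#'
#' @param visits this patient's visit rows
#' @param censoring this patient's censoring rows (may be empty)
#' @param diagnosis_date integer day offset of diagnosis
#' @param supply_days days supplied per registration (default 182)
#' @param cap_days maximum balance carried past an interval boundary
#'   (default 182)
#' @return an object of class \code{"supply_diary"}: patient_id, index_date,
#'   end_date, dispensings, and \code{coverage} (data frame of covered
#'   day-ranges \code{[start, end)})
#' @export
build_supply_diary <- function(visits, censoring, diagnosis_date,
                               supply_days = INTERVAL_DAYS,
                               cap_days = INTERVAL_DAYS) {
  use <- visits[visits$aet_reported, , drop = FALSE]
  if (nrow(use) == 0L)
    stop("no endocrine-therapy registration: supply diary undefined",
         call. = FALSE)
  disp <- sort(unique(use$visit_date))
  index_date <- disp[1L]
  end_date <- diagnosis_date + FIVE_YEARS_DAYS
  if (!is.null(censoring) && nrow(censoring) > 0L)
    end_date <- min(end_date, min(censoring$event_date))
  if (end_date <= index_date)
    stop("diary window is empty (end_date <= index_date)", call. = FALSE)
  disp <- disp[disp >= index_date & disp < end_date]

  # event-driven sweep: dispensings and interval boundaries, cap before add
  boundaries <- seq(index_date, end_date, by = INTERVAL_DAYS)[-1L]
  ev <- sort(unique(c(disp, boundaries, end_date)))
  bal <- 0
  cur <- index_date
  cov_start <- integer(0); cov_end <- integer(0)
  for (e in ev) {
    gap <- e - cur
    if (gap > 0 && bal > 0) {
      covered <- min(bal, gap)
      cov_start <- c(cov_start, cur)
      cov_end <- c(cov_end, cur + covered)
      bal <- bal - covered
    }
    cur <- e
    if (e >= end_date) break
    if (e %in% boundaries) bal <- min(bal, cap_days)
    if (e %in% disp) bal <- bal + supply_days
  }
  # merge adjacent ranges
  if (length(cov_start) > 1L) {
    keep_s <- cov_start[1L]; s <- integer(0); eo <- integer(0)
    prev_e <- cov_end[1L]
    for (i in seq_along(cov_start)[-1L]) {
      if (cov_start[i] == prev_e) prev_e <- cov_end[i]
      else { s <- c(s, keep_s); eo <- c(eo, prev_e)
             keep_s <- cov_start[i]; prev_e <- cov_end[i] }
    }
    s <- c(s, keep_s); eo <- c(eo, prev_e)
    cov_start <- s; cov_end <- eo
  }
  structure(list(
    patient_id = visits$patient_id[1L],
    index_date = index_date,
    end_date = end_date,
    dispensings = data.frame(date = disp, days_supplied = supply_days),
    coverage = data.frame(start = cov_start, end = cov_end)
  ), class = "supply_diary")
}

#' @export
print.supply_diary <- function(x, ...) {
  cat("Supply diary for", x$patient_id, "\n",
      " window: [", x$index_date, ",", x$end_date, ") —",
      x$end_date - x$index_date, "days\n",
      " dispensings:", nrow(x$dispensings),
      " covered days:", sum(x$coverage$end - x$coverage$start), "\n")
  invisible(x)
}

#' Compute an interval PDC panel from a supply diary
#'
#' Tiles the diary window with consecutive intervals anchored at the index
#' date. Each interval's PDC is covered days over interval length; the final
#' interval's denominator is shortened to the days remaining before the diary
#' ends (censoring), and a final fragment shorter than \code{min_final_days}
#' is dropped as uninformative.
#'
#' @param diary a \code{\link{build_supply_diary}} result
#' @param interval_len_days interval length (default 182)
#' @param min_final_days drop a final partial interval shorter than this
#'   (default 14)
#' @return data frame (patient_id, t, covered_days, denominator_days, pdc)
#' @export
compute_pdc <- function(diary, interval_len_days = INTERVAL_DAYS,
                        min_final_days = 14L) {
  span <- diary$end_date - diary$index_date
  if (span <= 0) stop("empty panel: end_date <= index_date", call. = FALSE)
  n_int <- as.integer(ceiling(span / interval_len_days))
  starts <- diary$index_date + (seq_len(n_int) - 1L) * interval_len_days
  ends <- pmin(starts + interval_len_days, diary$end_date)
  denom <- ends - starts
  if (n_int > 1L && denom[n_int] < min_final_days) {
    n_int <- n_int - 1L
    starts <- starts[seq_len(n_int)]; ends <- ends[seq_len(n_int)]
    denom <- denom[seq_len(n_int)]
  }
  covered <- vapply(seq_len(n_int), function(k) {
    s <- pmax(diary$coverage$start, starts[k])
    e <- pmin(diary$coverage$end, ends[k])
    sum(pmax(e - s, 0))
  }, numeric(1))
  data.frame(patient_id = diary$patient_id,
             t = seq_len(n_int) - 1L,
             covered_days = as.integer(covered),
             denominator_days = as.integer(denom),
             pdc = covered / denom,
             stringsAsFactors = FALSE)
}

#' Build PDC panels for a cohort
#'
#' Applies \code{\link{build_supply_diary}} and \code{\link{compute_pdc}} to
#' every requested patient and stacks the results in long format.
#'
#' @param patients patient table
#' @param visits visit table
#' @param censoring censoring table
#' @param ids patients to include (default: all with a use registration)
#' @param interval_len_days,min_final_days passed to \code{compute_pdc}
#' @return long data frame (patient_id, t, covered_days, denominator_days,
#'   pdc)
#' @export
build_pdc_panels <- function(patients, visits, censoring, ids = NULL,
                             interval_len_days = INTERVAL_DAYS,
                             min_final_days = 14L) {
  if (is.null(ids))
    ids <- intersect(patients$patient_id,
                     unique(visits$patient_id[visits$aet_reported]))
  vsp <- split(visits, visits$patient_id)
  csp <- if (nrow(censoring)) split(censoring, censoring$patient_id) else list()
  dx <- setNames(patients$diagnosis_date, patients$patient_id)
  out <- lapply(ids, function(id) {
    v <- vsp[[id]]
    if (is.null(v) || !any(v$aet_reported)) return(NULL)
    diary <- build_supply_diary(v, csp[[id]], dx[[id]])
    compute_pdc(diary, interval_len_days, min_final_days)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Reshape a long PDC panel into a patient-by-interval matrix
#'
#' @param panel long panel from \code{\link{build_pdc_panels}} or
#'   \code{\link{simulate_pdc_panels}}
#' @return numeric matrix (patients x intervals) with NA where a patient has
#'   no observation; rownames are patient ids
#' @export
as_pdc_matrix <- function(panel) {
  ids <- unique(panel$patient_id)
  Tmax <- max(panel$t) + 1L
  y <- matrix(NA_real_, length(ids), Tmax,
              dimnames = list(ids, paste0("t", seq_len(Tmax) - 1L)))
  y[cbind(match(panel$patient_id, ids), panel$t + 1L)] <- panel$pdc
  y
}
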