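# Synthetic registry-style cohort generator.
#
# Emulates a premenopausal, hormone-receptor-positive breast-cancer cohort
# followed at semi-annual hospital visits for five years after diagnosis,
# with endocrine-therapy supply handed out at each attended visit. Latent
# adherence-behaviour groups with polynomial mean-PDC trajectories drive
# visit attendance/reported use, so the downstream trajectory model has a
# known ground truth to recover.

#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by
#' \code{\link{generate_cohort}} and \code{\link{generate_follow_up}}.
#'
#' Defaults describe the study conditions the package targets: three latent
#' adherence groups (high adherers, slow decliners, rapid decliners) mixing
#' at 57/36/7 percent, a constant trajectory for high adherers and
#' second-order declines for the other two, residual SD 0.15 on the adherence
#' propensity, endocrine-therapy initiation a median 6.3 months after
#' diagnosis, and about 1 percent missingness in stage, tumour size and nodal
#' status.
#'
#' @param n_patients number of patients to simulate
#' @param group_mixing baseline mixing proportions over latent groups
#'   (must sum to 1)
#' @param group_polynomials list of per-group coefficient vectors
#'   (intercept, slope, quadratic) on scaled interval time \eqn{\tau \in
#'   [0,1]}, in PDC units
#' @param sigma residual SD of the latent adherence propensity (> 0)
#' @param covariate_effects list of effects, each
#'   \code{list(covariate =, level =, group =, log_or =)}, added to the
#'   baseline multinomial-logit of group membership; \code{NULL} for none
#' @param censoring_hazards named per-cause daily hazards (recurrence, death,
#'   second primary, emigration); defaults split a modest total evenly across
#'   causes
#' @param initiation_delay list(meanlog, sdlog) of the log-normal
#'   diagnosis-to-initiation delay in months (default median 6.3 months)
#' @param missingness_rates named MCAR rates for stage, tumor_size,
#'   positive_nodes
#' @param prescription_window_months month offsets before diagnosis defining
#'   the prior-medication exposure window (default \code{c(3, 27)};
#'   sensitivity analyses use \code{c(12, 36)})
#' @param ai_initiation_rate fraction starting therapy on an aromatase
#'   inhibitor (these patients are later excluded by eligibility)
#' @param ai_switch_prob probability a tamoxifen patient switches to an
#'   aromatase inhibitor at some later visit (still counted as adherent)
#' @param attend_no_use_rate probability that a patient whose use-propensity
#'   draw fails still attends the visit and reports no use
#' @param visit_jitter_sd SD (days) of Gaussian jitter around the semi-annual
#'   visit schedule after the first registration; real clinic visits do not
#'   fall exactly 182 days apart, and the jitter produces the partial-interval
#'   coverage (interior PDC values) seen in registry supply diaries
#' @param er_negative_rate fraction simulated ER-negative (0 disables the ER
#'   column; eligibility removes them when present)
#' @return a validated list of class \code{"sim_config"}
#' @export
sim_config <- function(n_patients = 2000,
                       group_mixing = c(high = 0.57, slow = 0.36, rapid = 0.07),
                       group_polynomials = list(
                         high  = c(0.97, 0, 0),
                         slow  = c(0.98, -0.20, -0.35),
                         rapid = c(0.95, -2.40, 1.20)
                       ),
                       sigma = 0.15,
                       covariate_effects = default_covariate_effects(),
                       censoring_hazards = c(recurrence = 6e-06, death = 6e-06,
                                             second_primary = 6e-06,
                                             emigration = 6e-06),
                       initiation_delay = list(meanlog = log(6.3), sdlog = 0.28),
                       missingness_rates = c(stage = 0.01, tumor_size = 0.01,
                                             positive_nodes = 0.01),
                       prescription_window_months = c(3, 27),
                       ai_initiation_rate = 0.02,
                       ai_switch_prob = 0.10,
                       attend_no_use_rate = 0.02,
                       visit_jitter_sd = 14,
                       er_negative_rate = 0) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    group_mixing = group_mixing,
    group_polynomials = group_polynomials,
    sigma = sigma,
    covariate_effects = covariate_effects,
    censoring_hazards = censoring_hazards,
    initiation_delay = initiation_delay,
    missingness_rates = missingness_rates,
    prescription_window_months = prescription_window_months,
    ai_initiation_rate = ai_initiation_rate,
    ai_switch_prob = ai_switch_prob,
    attend_no_use_rate = attend_no_use_rate,
    visit_jitter_sd = visit_jitter_sd,
    er_negative_rate = er_negative_rate
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      is.na(cfg$n_patients) || cfg$n_patients < 1)
    stop("n_patients must be a positive count", call. = FALSE)
  pm <- cfg$group_mixing
  if (any(pm < 0) || abs(sum(pm) - 1) > 1e-9)
    stop("group_mixing must be a probability vector summing to 1", call. = FALSE)
  if (length(cfg$group_polynomials) != length(pm))
    stop("group_polynomials must have one coefficient vector per group",
         call. = FALSE)
  if (!is.numeric(cfg$sigma) || cfg$sigma <= 0)
    stop("sigma must be > 0", call. = FALSE)
  rates <- c(cfg$missingness_rates, cfg$ai_initiation_rate,
             cfg$ai_switch_prob, cfg$attend_no_use_rate, cfg$er_negative_rate)
  if (any(rates < 0 | rates > 1))
    stop("all rates must lie in [0, 1]", call. = FALSE)
  if (any(cfg$censoring_hazards < 0))
    stop("censoring hazards must be non-negative", call. = FALSE)
  invisible(cfg)
}

#' Default covariate effects on trajectory-group membership
#'
#' Log-odds shifts applied on top of the baseline group mixing, chosen to
#' mirror the magnitudes typically reported for endocrine-therapy adherence:
#' early-stage disease, omission of chemotherapy, comorbidity and prior
#' chronic medication use all push membership toward the declining groups.
#'
#' @return a list of effect specifications
#' @export
default_covariate_effects <- function() {
  list(
    list(covariate = "stage", level = "I", group = "rapid", log_or = log(1.9)),
    list(covariate = "stage", level = "I", group = "slow",  log_or = log(1.4)),
    list(covariate = "chemotherapy", level = "no", group = "rapid", log_or = log(4.3)),
    list(covariate = "chemotherapy", level = "no", group = "slow",  log_or = log(3.4)),
    list(covariate = "cci", level = "1+", group = "rapid", log_or = log(1.6)),
    list(covariate = "cci", level = "1+", group = "slow",  log_or = log(1.5)),
    list(covariate = "prior_med_any", level = "yes", group = "rapid", log_or = log(1.3))
  )
}

# does a patient row match an effect's covariate level?
match_effect_level <- function(patients, covariate, level) {
  if (covariate == "cci") {
    if (level %in% c("1+", ">=1", "one_or_higher")) return(patients$cci >= 1)
    return(patients$cci == suppressWarnings(as.numeric(level)))
  }
  as.character(patients[[covariate]]) == level
}

sample_cat <- function(n, levels, probs) {
  levels[sample.int(length(levels), n, replace = TRUE, prob = probs)]
}

#' Generate a synthetic patient cohort with latent adherence groups
#'
#' Draws baseline patient, tumour and treatment characteristics from
#' registry-like marginal distributions, then assigns each patient a latent
#' trajectory group from a multinomial-logit model: baseline log-odds from
#' \code{config$group_mixing} plus the additive \code{covariate_effects}.
#'
#' @param config a \code{\link{sim_config}} object
#' @param seed integer seed; the same config and seed reproduce the cohort
#'   exactly
#' @return list with \code{patients} (one row per patient) and \code{truth}
#'   (latent group, membership probabilities)
#' @export
generate_cohort <- function(config, seed = 1L) {
  validate_sim_config(config)
  set.seed(seed)
  n <- config$n_patients
  J <- length(config$group_mixing)
  gnames <- names(config$group_mixing) %||% paste0("g", seq_len(J))

  age <- runif(n, 25, 54.999)
  patients <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    diagnosis_date = as.integer(floor(runif(n, 0, 3653))),
    age_at_diagnosis = round(age, 1),
    age_cat = cut(age, c(0, 40, 50, 55), right = FALSE,
                  labels = c("<40", "40-49", "50-55")),
    stage = sample_cat(n, c("I", "II", "III"), c(0.26, 0.54, 0.20)),
    tumor_size = sample_cat(n, c("<2cm", "2-5cm", ">5cm"), c(0.58, 0.38, 0.04)),
    positive_nodes = sample_cat(n, c("none", "one", "two_plus"),
                                c(0.37, 0.26, 0.37)),
    grade = sample_cat(n, c("I", "II", "III", "unknown"),
                       c(0.21, 0.52, 0.21, 0.06)),
    her2 = sample_cat(n, c("negative", "positive", "unknown"),
                      c(0.63, 0.13, 0.24)),
    chemotherapy = sample_cat(n, c("yes", "no"), c(0.91, 0.09)),
    surgery_rt = sample_cat(n, c("mastectomy_no_rt", "mastectomy_rt",
                                 "lumpectomy"), c(0.14, 0.30, 0.56)),
    cci = ifelse(runif(n) < 0.90, 0L, 1L + stats::rpois(n, 0.4)),
    income = sample_cat(n, c("low", "medium", "high"), c(1, 1, 1) / 3),
    education = sample_cat(n, c("short", "medium", "long"),
                           c(0.30, 0.45, 0.25)),
    cohabitation = sample_cat(n, c("alone", "cohabiting"), c(0.25, 0.75)),
    stringsAsFactors = FALSE
  )
  med_classes <- c("psychoanaleptic", "psycholeptic", "thyroid",
                   "hormonal_contraceptive", "analgesic",
                   "diuretic_antihypertensive", "airway_antihistamine")
  class_rates <- c(0.07, 0.06, 0.04, 0.10, 0.09, 0.06, 0.06)
  for (i in seq_along(med_classes)) {
    patients[[paste0("prior_med_", med_classes[i])]] <-
      ifelse(runif(n) < class_rates[i], "yes", "no")
  }
  any_med <- Reduce(`|`, lapply(med_classes, function(m)
    patients[[paste0("prior_med_", m)]] == "yes"))
  patients$prior_med_any <- ifelse(any_med, "yes", "no")
  if (config$er_negative_rate > 0) {
    patients$er_status <- ifelse(runif(n) < config$er_negative_rate,
                                 "negative", "positive")
  }

  # group membership: baseline logits (vs group 1) + additive covariate shifts
  eta <- matrix(rep(log(config$group_mixing / config$group_mixing[1]),
                    each = n), n, J)
  for (eff in config$covariate_effects %||% list()) {
    jg <- if (is.character(eff$group)) match(eff$group, gnames) else eff$group
    if (is.na(jg)) stop("unknown group in covariate effect: ", eff$group,
                        call. = FALSE)
    hit <- match_effect_level(patients, eff$covariate, eff$level)
    eta[hit, jg] <- eta[hit, jg] + eff$log_or
  }
  pr <- exp(eta - apply(eta, 1L, max))
  pr <- pr / rowSums(pr)
  true_group <- vapply(seq_len(n), function(i)
    sample.int(J, 1L, prob = pr[i, ]), integer(1))

  truth <- data.frame(patient_id = patients$patient_id,
                      true_group = true_group,
                      true_group_label = gnames[true_group],
                      stringsAsFactors = FALSE)
  colnames(pr) <- paste0("prob_", gnames)
  truth <- cbind(truth, as.data.frame(pr))
  list(patients = patients, truth = truth)
}

poly_eval <- function(coefs, tau) {
  drop(cbind(1, tau, tau^2)[, seq_along(coefs), drop = FALSE] %*% coefs)
}

#' Generate follow-up visits and censoring events
#'
#' Schedules semi-annual visits from endocrine-therapy initiation (a
#' log-normal delay after diagnosis, median 6.3 months by default) to five
#' years post-diagnosis. At each scheduled visit the patient registers
#' continued use with probability equal to the latent group's polynomial
#' trajectory evaluated at that interval, clamped to [0,1] after adding
#' Gaussian noise; failed draws usually produce no registration
#' (non-attendance) and occasionally an attended visit reporting no use.
#' Censoring dates are drawn from per-cause exponential hazards.
#'
#' @param patients,truth outputs of \code{\link{generate_cohort}}
#' @param config a \code{\link{sim_config}}
#' @param seed integer seed
#' @return list with \code{visits} (patient_id, visit_date, aet_reported,
#'   therapy) and \code{censoring} (patient_id, event_date, reason)
#' @export
generate_follow_up <- function(patients, truth, config, seed = 1L) {
  validate_sim_config(config)
  if (!identical(patients$patient_id, truth$patient_id))
    stop("patients and truth must be aligned by patient_id", call. = FALSE)
  set.seed(seed)
  n <- nrow(patients)
  polys <- config$group_polynomials
  causes <- names(config$censoring_hazards)

  delay_days <- round(rlnorm(n, config$initiation_delay$meanlog,
                             config$initiation_delay$sdlog) * DAYS_PER_MONTH)
  initiation <- patients$diagnosis_date + as.integer(delay_days)
  ai_start <- runif(n) < config$ai_initiation_rate

  # earliest censoring cause per patient (days after diagnosis)
  cens_t <- matrix(Inf, n, length(causes))
  for (k in seq_along(causes)) {
    h <- config$censoring_hazards[k]
    if (h > 0) cens_t[, k] <- rexp(n, rate = h)
  }
  first <- apply(cens_t, 1L, which.min)
  cens_days <- cens_t[cbind(seq_len(n), first)]

  vis <- vector("list", n)
  cen <- vector("list", n)
  n_int <- as.integer(FIVE_YEARS_DAYS %/% INTERVAL_DAYS)  # 10 semi-annual slots
  for (i in seq_len(n)) {
    end_i <- patients$diagnosis_date[i] + FIVE_YEARS_DAYS
    if (is.finite(cens_days[i]) && cens_days[i] < FIVE_YEARS_DAYS) {
      cdate <- patients$diagnosis_date[i] + as.integer(ceiling(cens_days[i]))
      cen[[i]] <- data.frame(patient_id = patients$patient_id[i],
                             event_date = cdate,
                             reason = causes[first[i]],
                             stringsAsFactors = FALSE)
      end_i <- min(end_i, cdate)
    }
    if (initiation[i] >= end_i) next
    dates <- seq(initiation[i], end_i - 1L, by = INTERVAL_DAYS)
    if (length(dates) > 1L && config$visit_jitter_sd > 0) {
      jit <- round(rnorm(length(dates) - 1L, 0, config$visit_jitter_sd))
      dates[-1L] <- dates[-1L] + as.integer(jit)
      dates <- pmin(pmax(cummax(dates), initiation[i]), end_i - 1L)
      dates <- unique(dates)
    }
    k <- seq_along(dates) - 1L
    mu <- poly_eval(polys[[truth$true_group[i]]], pmin(k / (n_int - 1L), 1))
    p <- pmin(pmax(mu + rnorm(length(k), 0, config$sigma), 0), 1)
    use <- runif(length(k)) < p
    attend_nouse <- !use & runif(length(k)) < config$attend_no_use_rate
    keep <- use | attend_nouse
    if (!any(keep)) next
    therapy <- rep(if (ai_start[i]) "AI" else "TAM", length(k))
    if (!ai_start[i] && runif(1) < config$ai_switch_prob && length(k) > 1L) {
      sw <- sample.int(length(k) - 1L, 1L) + 1L
      therapy[sw:length(k)] <- "AI"
    }
    vis[[i]] <- data.frame(patient_id = patients$patient_id[i],
                           visit_date = dates[keep],
                           aet_reported = use[keep],
                           therapy = therapy[keep],
                           stringsAsFactors = FALSE)
  }
  visits <- do.call(rbind, vis[!vapply(vis, is.null, logical(1))])
  censoring <- do.call(rbind, cen[!vapply(cen, is.null, logical(1))])
  if (is.null(visits))
    visits <- data.frame(patient_id = character(), visit_date = integer(),
                         aet_reported = logical(), therapy = character(),
                         stringsAsFactors = FALSE)
  if (is.null(censoring))
    censoring <- data.frame(patient_id = character(), event_date = integer(),
                            reason = character(), stringsAsFactors = FALSE)
  rownames(visits) <- NULL
  rownames(censoring) <- NULL
  list(visits = visits, censoring = censoring)
}

#' Inject missingness into stage, tumour size and nodal status
#'
#' Sets the three designated tumour characteristics to missing completely at
#' random at the configured rates; no other field is touched.
#'
#' @param patients patient table
#' @param config a \code{\link{sim_config}} (uses \code{missingness_rates})
#' @param seed integer seed
#' @return the patient table with NAs injected
#' @export
inject_missingness <- function(patients, config, seed = 1L) {
  rates <- config$missingness_rates
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0,1]", call. = FALSE)
  set.seed(seed)
  for (f in intersect(names(rates), c("stage", "tumor_size", "positive_nodes"))) {
    if (rates[[f]] > 0)
      patients[[f]][runif(nrow(patients)) < rates[[f]]] <- NA
  }
  patients
}

#' Simulate PDC panels directly from a censored-normal mixture
#'
#' Draws panels straight from the trajectory model's own data-generating
#' process (latent group, polynomial mean on scaled time, Gaussian noise,
#' clamped to [0,1]) — the reference process for parameter-recovery studies,
#' bypassing the visit/supply machinery.
#'
#' @param n number of patients
#' @param mixing group mixing proportions
#' @param polynomials list of per-group coefficient vectors on scaled time
#' @param sigma residual SD
#' @param n_intervals panel length (intervals per patient)
#' @param seed integer seed
#' @return list with \code{panel} (long data frame: patient_id, t, pdc) and
#'   \code{truth} (patient_id, true_group)
#' @export
simulate_pdc_panels <- function(n, mixing, polynomials, sigma,
                                n_intervals = 9L, seed = 1L) {
  stopifnot(abs(sum(mixing) - 1) < 1e-9, sigma > 0, n_intervals >= 1)
  set.seed(seed)
  J <- length(mixing)
  g <- sample.int(J, n, replace = TRUE, prob = mixing)
  tau <- if (n_intervals == 1L) 0 else
    (seq_len(n_intervals) - 1L) / (n_intervals - 1L)
  mu <- vapply(seq_len(J), function(j) poly_eval(polynomials[[j]], tau),
               numeric(n_intervals))
  y <- mu[, g, drop = FALSE] + matrix(rnorm(n * n_intervals, 0, sigma),
                                      n_intervals, n)
  y <- pmin(pmax(y, 0), 1)
  ids <- sprintf("S%06d", seq_len(n))
  panel <- data.frame(
    patient_id = rep(ids, each = n_intervals),
    t = rep(seq_len(n_intervals) - 1L, times = n),
    pdc = as.vector(y),
    stringsAsFactors = FALSE
  )
  list(panel = panel,
       truth = data.frame(patient_id = ids, true_group = g,
                          stringsAsFactors = FALSE))
}
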