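# expand a contingency table of counts into individual-level rows
expand_counts <- function(levels_exposure, groups, counts) {
  d <- expand.grid(exposure = levels_exposure, group = groups,
                   stringsAsFactors = FALSE)
  d <- d[rep(seq_len(nrow(d)), times = counts), ]
  rownames(d) <- NULL
  d
}

test_that("crude multinomial ORs equal contingency cross-products", {
  # observed cohort counts: chemotherapy by adherence group
  counts <- c(2354, 111,    # high:  yes, no
              1362, 225,    # slow:  yes, no
              247,  54)     # rapid: yes, no
  d <- expand_counts(c("yes", "no"), c("high", "slow", "rapid"), counts)
  n <- nrow(d)
  patients <- data.frame(patient_id = sprintf("x%04d", seq_len(n)),
                         chemotherapy = d$exposure,
                         stringsAsFactors = FALSE)
  assignments <- data.frame(patient_id = patients$patient_id,
                            assigned_group = match(d$group,
                                                   c("high", "slow", "rapid")))
  spec <- exposure_spec("chemotherapy", exposure_reference = "yes")
  tab <- fit_multinomial(assignments, patients, spec, outcome_reference = 1)
  or_rapid <- tab$or[tab$level == "no" & tab$outcome_group == "group_3"]
  or_slow <- tab$or[tab$level == "no" & tab$outcome_group == "group_2"]
  expect_equal(or_rapid, (54 * 2354) / (111 * 247), tolerance = 1e-6)
  expect_equal(or_slow, (225 * 2354) / (111 * 1362), tolerance = 1e-6)
  expect_true(all(tab$ci_low[!is.na(tab$ci_low)] <=
                    tab$or[!is.na(tab$ci_low)]))
  expect_equal(tab$or[tab$level == "yes"], c(1, 1))
})

test_that("relabelling the exposure reference rescales ORs exactly", {
  set.seed(5)
  n <- 3000
  patients <- data.frame(patient_id = sprintf("r%04d", 1:n),
                         stage = sample(c("I", "II", "III"), n, TRUE,
                                        prob = c(0.3, 0.5, 0.2)),
                         stringsAsFactors = FALSE)
  g <- sample(1:3, n, TRUE, prob = c(0.6, 0.3, 0.1))
  assignments <- data.frame(patient_id = patients$patient_id,
                            assigned_group = g)
  t_ii <- fit_multinomial(assignments, patients,
                          exposure_spec("stage", exposure_reference = "II"))
  t_i <- fit_multinomial(assignments, patients,
                         exposure_spec("stage", exposure_reference = "I"))
  for (gg in c("group_2", "group_3")) {
    orII <- setNames(t_ii$or[t_ii$outcome_group == gg],
                     t_ii$level[t_ii$outcome_group == gg])
    orI <- setNames(t_i$or[t_i$outcome_group == gg],
                    t_i$level[t_i$outcome_group == gg])
    expect_equal(unname(orI["III"]), unname(orII["III"] / orII["I"]),
                 tolerance = 1e-5)
  }
})

test_that("a null exposure shows ORs near one and empty levels are dropped", {
  # exactly independent 2x3 design (margins 0.7/0.3 x 0.57/0.36/0.07 at
  # n = 20,000 give integer cells): every OR is exactly 1
  counts <- c(7980, 3420, 5040, 2160, 980, 420)
  d <- expand_counts(c("no", "yes"), c("high", "slow", "rapid"), counts)
  n <- nrow(d)
  patients <- data.frame(patient_id = sprintf("n%05d", 1:n),
                         prior_med_any = d$exposure,
                         stringsAsFactors = FALSE)
  assignments <- data.frame(patient_id = patients$patient_id,
                            assigned_group = match(d$group,
                                                   c("high", "slow", "rapid")))
  tab <- fit_multinomial(assignments, patients,
                         exposure_spec("prior_med_any",
                                       exposure_reference = "no"))
  nn <- tab$level == "yes"
  expect_equal(tab$or[nn], c(1, 1), tolerance = 1e-6)
  expect_true(all(tab$ci_low[nn] < 1 & tab$ci_high[nn] > 1))

  set.seed(6)
  patients$grade <- factor(sample(c("I", "II"), n, TRUE),
                           levels = c("I", "II", "III"))
  expect_warning(
    fit_multinomial(assignments, patients, exposure_spec("grade")),
    "empty")
})

test_that("generator-configured covariate effects are recovered with adjustment", {
  eff <- list(list(covariate = "stage", level = "I", group = "rapid",
                   log_or = log(1.9)))
  cfg <- sim_config(n_patients = 20000, covariate_effects = eff)
  coh <- generate_cohort(cfg, seed = 15)
  assignments <- data.frame(patient_id = coh$patients$patient_id,
                            assigned_group = coh$truth$true_group)
  spec <- exposure_spec("stage", adjustment_set = "age_cat",
                        exposure_reference = "II")
  tab <- fit_multinomial(assignments, coh$patients, spec,
                         outcome_reference = 1)
  or_rapid <- tab$or[tab$level == "I" & tab$outcome_group == "group_3"]
  expect_gt(or_rapid, 1.7)
  expect_lt(or_rapid, 2.1)
})

test_that("imputation is deterministic, idempotent without missingness, and MCAR-consistent", {
  cfg <- sim_config(n_patients = 3000)
  coh <- generate_cohort(cfg, seed = 23)
  complete <- coh$patients
  expect_identical(impute_missing(complete, m = 3, seed = 1), complete)

  pat <- inject_missingness(complete, cfg, seed = 24)
  i1 <- impute_missing(pat, m = 5, seed = 9)
  i2 <- impute_missing(pat, m = 5, seed = 9)
  expect_identical(i1, i2)
  expect_false(anyNA(i1$stage))
  expect_false(anyNA(i1$tumor_size))
  expect_false(anyNA(i1$positive_nodes))
  # untouched where observed
  obs <- !is.na(pat$stage)
  expect_identical(i1$stage[obs], pat$stage[obs])

  # imputed marginal distribution close to the complete-data distribution
  p_true <- prop.table(table(complete$stage))
  p_imp <- prop.table(table(i1$stage))
  n_miss <- sum(is.na(pat$stage))
  se <- sqrt(p_true * (1 - p_true) / n_miss)
  expect_true(all(abs(p_imp - p_true) < 3 * pmax(se, 0.02)))

  # single patient missing: constant imputations aggregate to the mode
  one <- complete[1:50, ]
  one$stage <- "II"; one$stage[1] <- NA
  out <- impute_missing(one, m = 7, seed = 2)
  expect_equal(out$stage[1], "II")

  bad <- complete
  bad$grade[1] <- NA
  expect_error(impute_missing(bad), "imputable")
})

test_that("the association suite runs one model per spec deterministically", {
  cfg <- sim_config(n_patients = 1500)
  coh <- generate_cohort(cfg, seed = 33)
  assignments <- data.frame(patient_id = coh$patients$patient_id,
                            assigned_group = coh$truth$true_group)
  specs <- default_exposure_specs()
  expect_gte(length(specs), 11)
  sub <- specs[c("stage", "chemotherapy", "cci", "prior_med_any")]
  t1 <- run_association_suite(assignments, coh$patients, sub)
  t2 <- run_association_suite(assignments, coh$patients, sub)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  expect_setequal(unique(t1$exposure),
                  c("stage", "chemotherapy", "cci", "prior_med_any"))
  expect_error(run_association_suite(assignments, coh$patients, list()),
               "non-empty")
})

test_that("prior-medication window sensitivity leaves null associations unchanged", {
  # same cohort analysed under the main (3-27 months) and shifted (12-36
  # months) exposure windows: with no true medication effect the ORs differ
  # only by Monte Carlo noise
  cfg_main <- sim_config(n_patients = 8000, covariate_effects = NULL,
                         prescription_window_months = c(3, 27))
  cfg_sens <- sim_config(n_patients = 8000, covariate_effects = NULL,
                         prescription_window_months = c(12, 36))
  coh_m <- generate_cohort(cfg_main, seed = 41)
  coh_s <- generate_cohort(cfg_sens, seed = 42)
  spec <- exposure_spec("prior_med_any", exposure_reference = "no")
  am <- data.frame(patient_id = coh_m$patients$patient_id,
                   assigned_group = coh_m$truth$true_group)
  as_ <- data.frame(patient_id = coh_s$patients$patient_id,
                    assigned_group = coh_s$truth$true_group)
  tm <- fit_multinomial(am, coh_m$patients, spec)
  ts <- fit_multinomial(as_, coh_s$patients, spec)
  dif <- abs(log(tm$or[tm$level == "yes"]) - log(ts$or[ts$level == "yes"]))
  expect_true(all(dif < 0.5))
  expect_true(all(abs(log(tm$or[tm$level == "yes"])) < 0.35))
})
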