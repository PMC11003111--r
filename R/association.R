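# Exposure-trajectory association models.
#
# Each baseline exposure is analysed in its own multinomial logistic model of
# assigned trajectory group (high-adherence group as outcome reference) with
# an exposure-specific adjustment set. Missing stage / tumour size / nodal
# status are multiply imputed by chained equations and aggregated by
# averaging the ordinal codes across imputations and rounding.

IMPUTABLE_FIELDS <- c("stage", "tumor_size", "positive_nodes")

ordinal_levels <- list(
  stage = c("I", "II", "III"),
  tumor_size = c("<2cm", "2-5cm", ">5cm"),
  positive_nodes = c("none", "one", "two_plus")
)

# one conditional draw of an ordinal variable given predictors; proportional
# odds first, multinomial then marginal frequencies as fallbacks
draw_ordinal <- function(var, data, miss_idx, predictors) {
  lev <- ordinal_levels[[var]]
  obs <- data[!seq_len(nrow(data)) %in% miss_idx, , drop = FALSE]
  newd <- data[miss_idx, , drop = FALSE]
  f <- as.formula(paste(var, "~", paste(predictors, collapse = " + ")))
  probs <- NULL
  fit <- tryCatch(
    suppressWarnings(MASS::polr(f, data = obs, Hess = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit))
    probs <- tryCatch(predict(fit, newdata = newd, type = "probs"),
                      error = function(e) NULL)
  if (is.null(probs)) {
    fit <- tryCatch(
      nnet::multinom(f, data = obs, trace = FALSE),
      error = function(e) NULL)
    if (!is.null(fit))
      probs <- tryCatch(predict(fit, newdata = newd, type = "probs"),
                        error = function(e) NULL)
  }
  if (is.null(probs)) {
    marg <- prop.table(table(factor(obs[[var]], levels = lev)))
    probs <- matrix(rep(as.numeric(marg), each = length(miss_idx)),
                    nrow = length(miss_idx))
  }
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = length(miss_idx),
                                           byrow = length(miss_idx) > 1)
  colnames(probs) <- NULL
  lev[vapply(seq_len(nrow(probs)), function(i)
    sample.int(length(lev), 1L, prob = pmax(probs[i, ], 1e-12)), integer(1))]
}

#' Multiple imputation of missing tumour characteristics
#'
#' Chained-equation imputation of stage, tumour size and nodal status
#' (ordinal, proportional-odds conditional models with fallbacks) using the
#' other patient and tumour characteristics as predictors. The \code{m}
#' completed datasets are aggregated by averaging each patient's ordinal
#' codes across imputations and rounding to the nearest category.
#'
#' @param patients patient table; only the three designated fields may carry
#'   missing values
#' @param m number of imputations (default 50)
#' @param seed integer seed (deterministic given seed)
#' @param cycles chained-equation cycles per imputation (default 10)
#' @return completed patient table (no missing values in the three fields)
#' @export
impute_missing <- function(patients, m = 50L, seed = 1L, cycles = 10L) {
  other <- setdiff(names(patients)[vapply(patients, anyNA, logical(1))],
                   IMPUTABLE_FIELDS)
  if (length(other))
    stop("missingness outside the imputable fields: ",
         paste(other, collapse = ", "), call. = FALSE)
  targets <- IMPUTABLE_FIELDS[vapply(IMPUTABLE_FIELDS, function(f)
    f %in% names(patients) && anyNA(patients[[f]]), logical(1))]
  if (!length(targets)) return(patients)

  predictors <- intersect(c("age_cat", "grade", "her2", "chemotherapy",
                            "surgery_rt"), names(patients))
  base <- patients
  for (v in IMPUTABLE_FIELDS)
    if (v %in% names(base))
      base[[v]] <- factor(base[[v]], levels = ordinal_levels[[v]],
                          ordered = TRUE)
  base$cci_bin <- if ("cci" %in% names(base))
    factor(ifelse(base$cci >= 1, "1+", "0")) else NULL
  if (!is.null(base$cci_bin)) predictors <- c(predictors, "cci_bin")
  miss_idx <- lapply(targets, function(v) which(is.na(base[[v]])))
  names(miss_idx) <- targets

  set.seed(seed)
  codes <- matrix(0, nrow(base), length(targets),
                  dimnames = list(NULL, targets))
  for (rep_i in seq_len(m)) {
    d <- base
    # initial fill from observed marginals
    for (v in targets) {
      lev <- ordinal_levels[[v]]
      marg <- prop.table(table(factor(d[[v]], levels = lev)))
      d[[v]][miss_idx[[v]]] <- lev[sample.int(length(lev),
                                              length(miss_idx[[v]]),
                                              replace = TRUE,
                                              prob = as.numeric(marg))]
    }
    for (cyc in seq_len(cycles)) {
      for (v in targets) {
        preds <- c(predictors, setdiff(targets, v))
        d[[v]][miss_idx[[v]]] <-
          draw_ordinal(v, d, miss_idx[[v]], preds)
      }
    }
    for (vi in seq_along(targets)) {
      v <- targets[vi]
      codes[, vi] <- codes[, vi] +
        as.integer(factor(as.character(d[[v]]),
                          levels = ordinal_levels[[v]]))
    }
  }
  out <- patients
  for (vi in seq_along(targets)) {
    v <- targets[vi]
    avg <- codes[, vi] / m
    filled <- ordinal_levels[[v]][pmin(pmax(round(avg), 1L),
                                       length(ordinal_levels[[v]]))]
    out[[v]][miss_idx[[v]]] <- filled[miss_idx[[v]]]
  }
  out
}

#' Specification of one exposure-trajectory model
#'
#' @param exposure covariate name
#' @param adjustment_set covariate names to adjust for (may be empty)
#' @param exposure_reference reference level; \code{NULL} picks the largest
#'   cohort level, the conventional choice when no a-priori reference exists
#' @return a list of class \code{"exposure_spec"}
#' @export
exposure_spec <- function(exposure, adjustment_set = character(0),
                          exposure_reference = NULL) {
  if (exposure %in% adjustment_set)
    stop("exposure cannot appear in its own adjustment set", call. = FALSE)
  structure(list(exposure = exposure,
                 adjustment_set = adjustment_set,
                 exposure_reference = exposure_reference),
            class = "exposure_spec")
}

# covariates enter models in analysis form: CCI dichotomised at >= 1
analysis_covariate <- function(patients, name) {
  if (name == "cci") {
    f <- factor(ifelse(patients$cci >= 1, "1+", "0"), levels = c("0", "1+"))
    return(f)
  }
  v <- patients[[name]]
  if (is.null(v)) stop("covariate not found: ", name, call. = FALSE)
  if (!is.factor(v)) v <- factor(v)
  v
}

#' Fit one exposure-trajectory multinomial logistic model
#'
#' Maximum-likelihood multinomial logit of assigned trajectory group on the
#' exposure plus its adjustment set. Odds ratios are exponentiated
#' coefficients per non-reference outcome group; 95 percent confidence
#' intervals are Wald intervals from the observed information matrix. Empty
#' exposure levels are dropped with a warning.
#'
#' @param assignments output of \code{\link{posterior_assign}} (needs
#'   patient_id, assigned_group)
#' @param patients completed patient table
#' @param spec an \code{\link{exposure_spec}}
#' @param outcome_reference trajectory group used as outcome reference
#'   (default 1, the high-adherence group under the standard labelling)
#' @param group_labels optional labels for the outcome groups
#' @return data frame of class \code{"or_table"}: exposure, level,
#'   outcome_group, or, ci_low, ci_high, n_level (reference rows carry
#'   OR = 1 with NA intervals); attributes \code{spec}, \code{n},
#'   \code{converged}
#' @export
fit_multinomial <- function(assignments, patients, spec,
                            outcome_reference = 1L, group_labels = NULL) {
  d <- merge(patients,
             assignments[, c("patient_id", "assigned_group")],
             by = "patient_id")
  if (nrow(d) == 0L) stop("no overlap between assignments and patients",
                          call. = FALSE)
  J <- max(assignments$assigned_group)
  glab <- group_labels %||% paste0("group_", seq_len(J))
  d$.outcome <- factor(glab[d$assigned_group], levels = glab)
  d$.outcome <- stats::relevel(d$.outcome, ref = glab[outcome_reference])

  ex <- analysis_covariate(d, spec$exposure)
  empty <- levels(ex)[table(ex)[levels(ex)] == 0]
  if (length(empty)) {
    warning("dropping empty exposure level(s): ",
            paste(empty, collapse = ", "))
    ex <- droplevels(ex)
  }
  ref <- spec$exposure_reference %||%
    names(which.max(table(ex)))
  ex <- stats::relevel(ex, ref = ref)
  d$.exposure <- ex
  rhs <- ".exposure"
  for (a in spec$adjustment_set) {
    d[[paste0(".adj_", a)]] <- analysis_covariate(d, a)
    rhs <- c(rhs, paste0(".adj_", a))
  }
  f <- as.formula(paste(".outcome ~", paste(rhs, collapse = " + ")))
  fit <- nnet::multinom(f, data = d, trace = FALSE, maxit = 1000,
                        reltol = 1e-14)
  cf <- coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                     dimnames = list(levels(d$.outcome)[2],
                                                     names(cf)))
  V <- vcov(fit)
  se <- matrix(sqrt(diag(V)), nrow = nrow(cf), byrow = TRUE,
               dimnames = dimnames(cf))
  zq <- qnorm(0.975)

  lev_nonref <- setdiff(levels(ex), ref)
  rows <- list()
  for (g in rownames(cf)) {
    rows[[length(rows) + 1L]] <- data.frame(
      exposure = spec$exposure, level = ref, outcome_group = g,
      or = 1, ci_low = NA_real_, ci_high = NA_real_,
      n_level = sum(ex == ref), stringsAsFactors = FALSE)
    for (lv in lev_nonref) {
      cn <- paste0(".exposure", lv)
      b <- cf[g, cn]; s <- se[g, cn]
      rows[[length(rows) + 1L]] <- data.frame(
        exposure = spec$exposure, level = lv, outcome_group = g,
        or = exp(b), ci_low = exp(b - zq * s), ci_high = exp(b + zq * s),
        n_level = sum(ex == lv), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "spec") <- spec
  attr(out, "n") <- nrow(d)
  attr(out, "converged") <- fit$convergence == 0
  class(out) <- c("or_table", class(out))
  out
}

#' Default exposure model specifications
#'
#' One model per baseline exposure with its own adjustment set, mirroring
#' the DAG-directed per-exposure approach: age unadjusted; tumour
#' characteristics adjusted for age; treatment exposures adjusted for age,
#' comorbidity and stage; comorbidity adjusted for age and education; prior
#' medication exposures adjusted for age, comorbidity and socioeconomic
#' covariates with "no use" as the a-priori reference. Shipped as editable
#' JSON (\code{inst/extdata/exposure_specs.json}).
#'
#' @param path optional path to a specs JSON file
#' @return named list of \code{\link{exposure_spec}} objects
#' @export
default_exposure_specs <- function(path = NULL) {
  path <- path %||% system.file("extdata", "exposure_specs.json",
                                package = "adhertraj")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  specs <- lapply(raw$specs, function(s)
    exposure_spec(s$exposure,
                  adjustment_set = unlist(s$adjustment_set) %||% character(0),
                  exposure_reference = s$exposure_reference))
  names(specs) <- vapply(specs, `[[`, "", "exposure")
  specs
}

#' Fit the full suite of exposure-trajectory models
#'
#' One multinomial model per specification; results are stacked into a
#' single odds-ratio table suitable for forest plotting.
#'
#' @param assignments posterior assignments
#' @param patients completed patient table
#' @param specs list of \code{\link{exposure_spec}} objects
#' @param outcome_reference,group_labels passed through to
#'   \code{\link{fit_multinomial}}
#' @return stacked \code{or_table} with an \code{exposure} column per row
#' @export
run_association_suite <- function(assignments, patients, specs,
                                  outcome_reference = 1L,
                                  group_labels = NULL) {
  if (!length(specs)) stop("specs must be non-empty", call. = FALSE)
  tabs <- lapply(specs, function(s)
    fit_multinomial(assignments, patients, s,
                    outcome_reference = outcome_reference,
                    group_labels = group_labels))
  out <- do.call(rbind, lapply(tabs, as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("or_table", class(out))
  attr(out, "n_models") <- length(tabs)
  out
}
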