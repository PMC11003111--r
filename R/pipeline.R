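# End-to-end pipeline: simulate -> eligibility -> diaries/PDC -> trajectory
# model -> associations -> report. All tabular I/O is delimited text; model
# state is JSON. One master seed fans out to per-stage child seeds so stages
# rerun in isolation reproduce their in-pipeline streams.

#' Write a simulated cohort to a directory
#'
#' @param cohort list with patients/truth (from \code{\link{generate_cohort}})
#' @param follow_up list with visits/censoring
#' @param dir output directory (created if needed)
#' @return dir, invisibly
#' @export
write_cohort <- function(cohort, follow_up, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$patients, file.path(dir, "patients.csv"), row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  write.csv(follow_up$visits, file.path(dir, "visits.csv"), row.names = FALSE)
  write.csv(follow_up$censoring, file.path(dir, "censoring.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory
#'
#' @param dir directory holding patients.csv, visits.csv, censoring.csv and
#'   optionally truth.csv
#' @return list(patients, visits, censoring, truth)
#' @export
read_cohort <- function(dir) {
  rd <- function(f, required = TRUE) {
    p <- file.path(dir, f)
    if (!file.exists(p)) {
      if (required) stop("missing input file: ", p, call. = FALSE)
      return(NULL)
    }
    read.csv(p, stringsAsFactors = FALSE)
  }
  out <- list(patients = rd("patients.csv"), visits = rd("visits.csv"),
              censoring = rd("censoring.csv"),
              truth = rd("truth.csv", required = FALSE))
  out$visits$aet_reported <- as.logical(out$visits$aet_reported)
  out
}

#' Run the full adherence-trajectory pipeline
#'
#' Stages: simulate (or load external tables), eligibility cascade, supply
#' diaries and PDC panels, trajectory model selection, imputation and
#' exposure-association models. Every intermediate artifact is written under
#' \code{out_dir}; the same config and seed reproduce all numeric outputs.
#'
#' @param config list with elements: \code{sim} (a \code{\link{sim_config}};
#'   or \code{input_dir} for external-input mode), \code{out_dir},
#'   \code{seed}, and optional \code{j_range}, \code{n_restarts},
#'   \code{specs}, \code{group_labels}, \code{impute_m}
#' @return a \code{run_report} list: exclusion log, selected model summary,
#'   group shares, diagnostics, OR table, paths and seed stamp
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed)) stop("config$seed is mandatory", call. = FALSE)
  out_dir <- config$out_dir %||% tempfile("adhertraj_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  stage <- "simulate"
  report <- list(seed = seed, out_dir = out_dir,
                 package_version = as.character(utils::packageVersion("adhertraj")))
  tryCatch({
    if (!is.null(config$input_dir)) {
      dat <- read_cohort(config$input_dir)
      truth <- dat$truth
    } else {
      sim <- config$sim %||% sim_config()
      cohort <- generate_cohort(sim, seed = child_seed(seed, 1L))
      fu <- generate_follow_up(cohort$patients, cohort$truth, sim,
                               seed = child_seed(seed, 2L))
      cohort$patients <- inject_missingness(cohort$patients, sim,
                                            seed = child_seed(seed, 3L))
      write_cohort(cohort, fu, out_dir)
      dat <- list(patients = cohort$patients, visits = fu$visits,
                  censoring = fu$censoring)
      truth <- cohort$truth
    }

    stage <- "eligibility"
    elig <- apply_eligibility(dat$patients, dat$visits, dat$censoring)
    jsonlite::write_json(list(n_start = attr(elig$log, "n_start"),
                              steps = elig$log),
                         file.path(out_dir, "exclusions.json"),
                         auto_unbox = TRUE, digits = NA)
    report$exclusions <- elig$log

    stage <- "diary"
    panel <- build_pdc_panels(dat$patients, dat$visits, dat$censoring,
                              ids = elig$eligible_ids)
    write.csv(panel, file.path(out_dir, "panel.csv"), row.names = FALSE)
    if (all(panel$pdc >= 1 - 1e-12)) {
      warning("all PDC values are 1: cohort is degenerately adherent; ",
              "a single-group assignment is reported and model fitting ",
              "and association analyses are skipped")
      ids <- unique(panel$patient_id)
      report$degenerate <- TRUE
      report$exclusions <- elig$log
      report$group_shares <- 1
      report$assignments <- data.frame(patient_id = ids,
                                       post_1 = 1, assigned_group = 1L,
                                       max_posterior = 1,
                                       stringsAsFactors = FALSE)
      report$panel <- panel
      class(report) <- "run_report"
      return(report)
    }

    stage <- "fit"
    sel <- select_model(panel, j_range = config$j_range %||% 2:7,
                        seed = child_seed(seed, 4L),
                        n_restarts = config$n_restarts %||% 5L)
    model <- sel$model
    write.csv(sel$assignments, file.path(out_dir, "assignments.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(J = model$J, orders = model$orders, beta = model$beta,
           sigma = model$sigma, pi = model$pi, loglik = model$loglik,
           bic = model$bic, k_params = model$k_params,
           converged = model$converged, trace = sel$trace,
           diagnostics = sel$diagnostics$table),
      file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
    report$model <- model
    report$assignments <- sel$assignments
    report$selection_trace <- sel$trace
    report$diagnostics <- sel$diagnostics
    shares <- sel$diagnostics$table$share
    report$group_shares <- shares

    stage <- "associate"
    patients_elig <- dat$patients[dat$patients$patient_id %in%
                                    elig$eligible_ids, ]
    patients_c <- impute_missing(patients_elig,
                                 m = config$impute_m %||% 50L,
                                 seed = child_seed(seed, 5L))
    # outcome reference: group with the highest mean observed PDC
    mean_pdc <- tapply(panel$pdc, panel$patient_id, mean)
    by_grp <- tapply(mean_pdc[sel$assignments$patient_id],
                     sel$assignments$assigned_group, mean)
    ref_group <- as.integer(names(by_grp)[which.max(by_grp)])
    specs <- config$specs %||% default_exposure_specs()
    or_table <- run_association_suite(sel$assignments, patients_c, specs,
                                      outcome_reference = ref_group,
                                      group_labels = config$group_labels)
    write.csv(or_table, file.path(out_dir, "or_table.csv"), row.names = FALSE)
    report$or_table <- or_table
    report$outcome_reference <- ref_group
    report$panel <- panel
    report$truth <- truth
    class(report) <- "run_report"
    report
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s (partial artifacts in %s)",
                 stage, conditionMessage(e), out_dir), call. = FALSE)
  })
}

#' @export
print.run_report <- function(x, ...) {
  cat("Adherence-trajectory pipeline run (seed", x$seed, ")\n")
  cat("Exclusion cascade:\n")
  print(x$exclusions)
  if (isTRUE(x$degenerate)) {
    cat("\nDegenerate cohort: all PDC values are 1; single-group report.\n")
    return(invisible(x))
  }
  cat(sprintf("\nSelected model: %d groups (orders %s), BIC %.1f\n",
              x$model$J, paste(x$model$orders, collapse = ","), x$model$bic))
  cat("Group shares (%):",
      paste(sprintf("%.1f", 100 * x$group_shares), collapse = " / "), "\n")
  invisible(x)
}

#' Plot group mean trajectories with confidence bands
#'
#' @param model fitted \code{gbtm_fit} with \code{vcov}
#' @param group_labels optional labels
#' @return a ggplot object (y axis clamped to [0, 1])
#' @export
plot_trajectories <- function(model, group_labels = NULL) {
  glab <- group_labels %||% paste0("group ", seq_len(model$J))
  dd <- do.call(rbind, lapply(seq_len(model$J), function(j) {
    d <- predicted_trajectory(model, j, t_grid = seq(0, model$Tmax - 1L,
                                                     by = 0.25))
    d$group <- glab[j]
    d
  }))
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$t, y = .data$mean,
                                   colour = .data$group,
                                   fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "six-month interval since initiation",
                  y = "proportion of days covered",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Spaghetti plot of observed PDC series for one assigned group
#'
#' @param diagnostics output of \code{\link{gbtm_diagnostics}} with a
#'   spaghetti bundle
#' @param group group index
#' @param max_lines subsample cap on plotted patients (default 200)
#' @return a ggplot object
#' @export
plot_spaghetti <- function(diagnostics, group, max_lines = 200L) {
  sp <- diagnostics$spaghetti
  if (is.null(sp)) stop("diagnostics carry no spaghetti bundle", call. = FALSE)
  sp <- sp[sp$assigned_group == group, ]
  ids <- unique(sp$patient_id)
  if (length(ids) > max_lines)
    sp <- sp[sp$patient_id %in% sample(ids, max_lines), ]
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$t, y = .data$pdc,
                                   group = .data$patient_id)) +
    ggplot2::geom_line(alpha = 0.15) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(title = paste("assigned group", group),
                  x = "six-month interval", y = "PDC") +
    ggplot2::theme_minimal()
}

#' Forest plot of exposure odds ratios
#'
#' @param or_table stacked odds-ratio table
#' @return a ggplot object (log-scaled x axis)
#' @export
plot_forest <- function(or_table) {
  d <- or_table[!is.na(or_table$ci_low), ]
  d$label <- paste(d$exposure, d$level, sep = ": ")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~outcome_group) +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Render a pipeline run to figures and a markdown summary
#'
#' Writes the trajectory plot, one spaghetti plot per group, the forest
#' plot, and \code{report.md} summarising the exclusion cascade, the
#' selected model and the group shares.
#'
#' @param report a \code{run_report} from \code{\link{run_pipeline}}
#' @param dir output directory (default: the run's out_dir)
#' @return character vector of written file paths
#' @export
render_report <- function(report, dir = NULL) {
  dir <- dir %||% report$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "trajectory_plot.png")
  ggplot2::ggsave(p, plot_trajectories(report$model), width = 7, height = 5,
                  dpi = 150)
  paths <- c(paths, p)
  for (j in seq_len(report$model$J)) {
    pj <- file.path(dir, sprintf("spaghetti_%d.png", j))
    ggplot2::ggsave(pj, plot_spaghetti(report$diagnostics, j),
                    width = 7, height = 5, dpi = 150)
    paths <- c(paths, pj)
  }
  pf <- file.path(dir, "forest.png")
  ggplot2::ggsave(pf, plot_forest(report$or_table), width = 8, height = 10,
                  dpi = 150)
  paths <- c(paths, pf)

  md <- file.path(dir, "report.md")
  shares <- sprintf("%.1f", 100 * report$group_shares)
  lines <- c(
    "# Adherence trajectory run report", "",
    sprintf("- seed: %d; package version: %s", report$seed,
            report$package_version),
    "", "## Exclusion cascade", "",
    paste0("| step | removed | remaining |"), "|---|---|---|",
    sprintf("| %s | %d | %d |", report$exclusions$step,
            report$exclusions$n_removed, report$exclusions$n_remaining),
    "", "## Selected model", "",
    sprintf("- %d groups, polynomial orders (%s), sigma = %.3f",
            report$model$J, paste(report$model$orders, collapse = ", "),
            report$model$sigma),
    sprintf("- log-likelihood %.2f, BIC %.2f", report$model$loglik,
            report$model$bic),
    sprintf("- group shares (%%): %s", paste(shares, collapse = " / ")),
    "", "## Diagnostics", "",
    "| group | n | share | APPA | OCC |", "|---|---|---|---|---|",
    sprintf("| %d | %d | %.3f | %.3f | %.1f |",
            report$diagnostics$table$group, report$diagnostics$table$n,
            report$diagnostics$table$share, report$diagnostics$table$appa,
            report$diagnostics$table$occ),
    "", "Figures: trajectory_plot.png, spaghetti_<j>.png, forest.png.")
  writeLines(lines, md)
  c(paths, md)
}
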