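# Censored-normal group-based trajectory model (latent class growth model).
#
# Observation model: within group j the latent adherence propensity at
# interval t is y* ~ N(x_t' beta_j, sigma), with x_t a polynomial basis on
# interval time scaled to [0,1]; the observed PDC is y* clamped to [0,1], so
# the likelihood uses the Gaussian density for interior values and normal
# tail probabilities for values at the bounds. Groups mix with proportions
# pi; estimation is EM on the latent group indicator. The M-step collapses
# the expected complete-data likelihood to per-(group, interval) sufficient
# statistics (weighted boundary counts and interior moments), so its inner
# optimisation costs O(J*T) per evaluation regardless of cohort size.

EPS_BOUND <- 1e-12

#' Censored-normal log-likelihood of one PDC observation
#'
#' Log-density contribution of an observed PDC value under the
#' doubly-censored normal model with bounds 0 and 1: the left tail mass
#' \eqn{\log\Phi((0-\mu)/\sigma)} at y = 0, the right tail mass
#' \eqn{\log(1-\Phi((1-\mu)/\sigma))} at y = 1, and the Gaussian log-density
#' in the interior. Vectorised over its arguments.
#'
#' @param y PDC value(s) in [0, 1]
#' @param mu linear-predictor mean(s)
#' @param sigma residual SD (> 0)
#' @return log-likelihood contribution(s)
#' @export
cnorm_obs_loglik <- function(y, mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  if (any(y < 0 | y > 1)) stop("y must lie in [0, 1]", call. = FALSE)
  n <- max(length(y), length(mu))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  out <- numeric(n)
  lo <- y <= EPS_BOUND
  hi <- y >= 1 - EPS_BOUND
  mid <- !lo & !hi
  if (any(lo)) out[lo] <- pnorm((0 - mu[lo]) / sigma, log.p = TRUE)
  if (any(hi)) out[hi] <- pnorm((1 - mu[hi]) / sigma, lower.tail = FALSE,
                                log.p = TRUE)
  if (any(mid)) out[mid] <- dnorm(y[mid], mu[mid], sigma, log = TRUE)
  out
}

# scaled polynomial basis: interval indices 0..Tmax-1 mapped onto [0,1]
time_basis <- function(Tmax, order = 2L) {
  tau <- if (Tmax == 1L) 0 else (seq_len(Tmax) - 1L) / (Tmax - 1L)
  X <- cbind(intercept = rep(1, Tmax), tau = tau, tau2 = tau^2)
  X[, seq_len(order + 1L), drop = FALSE]
}

panel_to_matrix <- function(panel) {
  if (is.matrix(panel)) return(panel)
  as_pdc_matrix(panel)
}

# per-patient per-group loglik matrix (n x J)
patient_group_loglik <- function(Y, masks, Xfull, beta, sigma) {
  n <- nrow(Y); Tmax <- ncol(Y); J <- length(beta)
  L <- matrix(0, n, J)
  for (j in seq_len(J)) {
    mu_t <- drop(Xfull[, seq_along(beta[[j]]), drop = FALSE] %*% beta[[j]])
    MU <- matrix(mu_t, n, Tmax, byrow = TRUE)
    ll <- matrix(0, n, Tmax)
    if (any(masks$lo)) ll[masks$lo] <- pnorm(-MU[masks$lo] / sigma, log.p = TRUE)
    if (any(masks$hi)) ll[masks$hi] <- pnorm((1 - MU[masks$hi]) / sigma,
                                             lower.tail = FALSE, log.p = TRUE)
    if (any(masks$mid)) ll[masks$mid] <- dnorm(Y[masks$mid], MU[masks$mid],
                                               sigma, log = TRUE)
    L[, j] <- rowSums(ll)
  }
  L
}

obs_masks <- function(Y) {
  obs <- !is.na(Y)
  lo <- obs & Y <= EPS_BOUND
  hi <- obs & Y >= 1 - EPS_BOUND
  list(obs = obs, lo = lo, hi = hi, mid = obs & !lo & !hi)
}

#' Mixture log-likelihood of a fitted (or hypothesised) trajectory model
#'
#' \eqn{\sum_i \log \sum_j \pi_j \exp(\sum_t \ell(y_{it}; x_t'\beta_j,
#' \sigma))}, computed with log-sum-exp stabilisation.
#'
#' @param panel long PDC panel or patient-by-interval matrix
#' @param model a \code{gbtm_fit}, or a list with \code{beta} (list of
#'   coefficient vectors), \code{sigma}, \code{pi}
#' @return total log-likelihood (scalar)
#' @export
mixture_loglik <- function(panel, model) {
  Y <- panel_to_matrix(panel)
  if (nrow(Y) == 0L) stop("empty panel set", call. = FALSE)
  masks <- obs_masks(Y)
  Xfull <- time_basis(ncol(Y), 2L)
  L <- patient_group_loglik(Y, masks, Xfull, model$beta, model$sigma)
  sum(row_log_sum_exp(sweep(L, 2L, log(model$pi), `+`)))
}

# ---- M-step machinery -------------------------------------------------

# sufficient statistics per (group, interval): weighted censored counts and
# interior moments, given posterior weights W (n x J)
mstep_stats <- function(Y, masks, W) {
  J <- ncol(W); Tmax <- ncol(Y)
  st <- list(nL = matrix(0, J, Tmax), nR = matrix(0, J, Tmax),
             W1 = matrix(0, J, Tmax), S1 = matrix(0, J, Tmax),
             S2 = matrix(0, J, Tmax))
  Ymid <- ifelse(masks$mid, Y, 0)
  for (j in seq_len(J)) {
    w <- W[, j]
    st$nL[j, ] <- colSums(w * masks$lo)
    st$nR[j, ] <- colSums(w * masks$hi)
    st$W1[j, ] <- colSums(w * masks$mid)
    st$S1[j, ] <- colSums(w * Ymid)
    st$S2[j, ] <- colSums(w * Ymid^2)
  }
  st
}

unpack_par <- function(par, orders) {
  beta <- list(); k <- 0L
  for (j in seq_along(orders)) {
    beta[[j]] <- par[k + seq_len(orders[j] + 1L)]
    k <- k + orders[j] + 1L
  }
  list(beta = beta, sigma = exp(par[k + 1L]))
}

# expected complete-data loglik (Q) and its gradient from collapsed stats
q_fn_factory <- function(st, Xfull, orders) {
  Tmax <- ncol(st$nL); J <- nrow(st$nL)
  Xs <- lapply(orders, function(d) Xfull[, seq_len(d + 1L), drop = FALSE])
  log2pi <- log(2 * pi)
  qfn <- function(par) {
    p <- unpack_par(par, orders); s <- p$sigma
    val <- 0
    for (j in seq_len(J)) {
      mu <- drop(Xs[[j]] %*% p$beta[[j]])
      a <- -mu / s; b <- (1 - mu) / s
      val <- val +
        sum(st$nL[j, ] * pnorm(a, log.p = TRUE)) +
        sum(st$nR[j, ] * pnorm(b, lower.tail = FALSE, log.p = TRUE)) -
        sum(st$W1[j, ]) * (log(s) + 0.5 * log2pi) -
        sum(st$S2[j, ] - 2 * mu * st$S1[j, ] + mu^2 * st$W1[j, ]) / (2 * s^2)
    }
    -val
  }
  qgr <- function(par) {
    p <- unpack_par(par, orders); s <- p$sigma
    g <- numeric(length(par)); k <- 0L; gls <- 0
    for (j in seq_len(J)) {
      mu <- drop(Xs[[j]] %*% p$beta[[j]])
      a <- -mu / s; b <- (1 - mu) / s
      mills_l <- exp(dnorm(a, log = TRUE) - pnorm(a, log.p = TRUE))
      mills_r <- exp(dnorm(b, log = TRUE) -
                       pnorm(b, lower.tail = FALSE, log.p = TRUE))
      gmu <- -st$nL[j, ] * mills_l / s + st$nR[j, ] * mills_r / s +
        (st$S1[j, ] - mu * st$W1[j, ]) / s^2
      g[k + seq_len(orders[j] + 1L)] <- drop(crossprod(Xs[[j]], gmu))
      k <- k + orders[j] + 1L
      gls <- gls + sum(-st$nL[j, ] * a * mills_l + st$nR[j, ] * b * mills_r) -
        sum(st$W1[j, ]) +
        sum(st$S2[j, ] - 2 * mu * st$S1[j, ] + mu^2 * st$W1[j, ]) / s^2
    }
    g[k + 1L] <- gls
    -g
  }
  list(fn = qfn, gr = qgr)
}

pack_par <- function(beta, sigma) c(unlist(beta), log(sigma))

# weighted least-squares start for one group's coefficients
wls_beta <- function(Y, obs, X_j, w) {
  Tmax <- ncol(Y)
  Wm <- matrix(w, nrow(Y), Tmax) * obs
  wt <- colSums(Wm)
  ybar <- colSums(Wm * ifelse(obs, Y, 0)) / pmax(wt, 1e-12)
  keep <- wt > 1e-9
  XtW <- crossprod(X_j[keep, , drop = FALSE] * wt[keep],
                   X_j[keep, , drop = FALSE])
  rhs <- crossprod(X_j[keep, , drop = FALSE] * wt[keep], ybar[keep])
  drop(solve(XtW + diag(1e-8, ncol(X_j)), rhs))
}

em_run <- function(Y, masks, orders, beta0, sigma0, pi0, tol, max_iter) {
  n <- nrow(Y); J <- length(orders)
  Xfull <- time_basis(ncol(Y), 2L)
  beta <- beta0; sigma <- sigma0; pival <- pi0
  trace <- numeric(0)
  ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    L <- patient_group_loglik(Y, masks, Xfull, beta, sigma)
    lp <- sweep(L, 2L, log(pival), `+`)
    lse <- row_log_sum_exp(lp)
    ll <- sum(lse)
    trace <- c(trace, ll)
    W <- exp(lp - lse)
    pival <- colMeans(W)
    if (min(pival) < 1 / n) return(list(degenerate = TRUE, trace = trace))
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1)) { converged <- TRUE; break }
    ll_old <- ll
    st <- mstep_stats(Y, masks, W)
    qf <- q_fn_factory(st, Xfull, orders)
    opt <- optim(pack_par(beta, sigma), qf$fn, qf$gr, method = "BFGS",
                 control = list(maxit = 60, reltol = 1e-12))
    p <- unpack_par(opt$par, orders)
    beta <- p$beta; sigma <- max(p$sigma, 1e-6)
  }
  # final loglik at the returned parameters
  L <- patient_group_loglik(Y, masks, Xfull, beta, sigma)
  ll <- sum(row_log_sum_exp(sweep(L, 2L, log(pival), `+`)))
  list(degenerate = FALSE, beta = beta, sigma = sigma, pi = pival,
       loglik = ll, trace = c(trace, ll), converged = converged,
       iterations = length(trace))
}

#' Fit a censored-normal group-based trajectory model by EM
#'
#' Maximum-likelihood fit of a J-group mixture of polynomial PDC
#' trajectories under the doubly-censored normal observation model with a
#' shared residual SD. Initialisation splits patients into J strata by
#' quantiles of their mean PDC; additional restarts perturb the starting
#' coefficients (N(0, 0.05)) and reshuffle 10 percent of initial
#' memberships. The restart with the highest log-likelihood is returned; the
#' log-likelihood is non-decreasing across EM iterations within every run.
#'
#' @param panel long PDC panel (patient_id, t, pdc) or patient-by-interval
#'   matrix with NA past censoring
#' @param J number of groups
#' @param orders per-group polynomial degrees in \{0, 1, 2\} (recycled if
#'   scalar)
#' @param seed integer seed controlling initialisation and restarts
#' @param tol relative log-likelihood convergence tolerance
#' @param max_iter maximum EM iterations per restart
#' @param n_restarts number of initialisations
#' @return an object of class \code{"gbtm_fit"}: \code{beta} (list of
#'   per-group coefficients on scaled time), \code{sigma}, \code{pi},
#'   \code{orders}, \code{loglik}, \code{bic}, \code{k_params},
#'   \code{n_patients}, \code{converged}, \code{n_restarts_used},
#'   \code{loglik_trace}
#' @export
fit_gbtm <- function(panel, J, orders = 2L, seed = 1L, tol = 1e-8,
                     max_iter = 500L, n_restarts = 5L) {
  stopifnot(J >= 1)
  orders <- as.integer(rep_len(orders, J))
  if (any(orders < 0 | orders > 2))
    stop("polynomial orders must be in {0, 1, 2}", call. = FALSE)
  Y <- panel_to_matrix(panel)
  if (nrow(Y) == 0L) stop("empty panel set", call. = FALSE)
  masks <- obs_masks(Y)
  n <- nrow(Y); Tmax <- ncol(Y)
  Xfull <- time_basis(Tmax, 2L)
  set.seed(seed)

  ybar <- rowMeans(Y, na.rm = TRUE)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    # quantile-split initial memberships (jitter breaks the heavy ties at 1)
    ord <- order(ybar + runif(n, 0, 1e-6))
    strata <- ceiling(seq_along(ord) / (n / J))
    memb <- integer(n)
    memb[ord] <- pmin(pmax(strata, 1L), J)
    if (r > 1L) {
      flip <- sample.int(n, max(1L, round(0.10 * n)))
      memb[flip] <- sample.int(J, length(flip), replace = TRUE)
    }
    W0 <- matrix(0, n, J); W0[cbind(seq_len(n), memb)] <- 1
    beta0 <- lapply(seq_len(J), function(j)
      wls_beta(Y, masks$obs, Xfull[, seq_len(orders[j] + 1L), drop = FALSE],
               W0[, j]))
    if (r > 1L)
      beta0 <- lapply(beta0, function(b) b + rnorm(length(b), 0, 0.05))
    res_mid <- ifelse(masks$mid, Y, NA)
    sigma0 <- max(sd(res_mid[masks$mid]), 0.05)
    if (!is.finite(sigma0)) sigma0 <- 0.1
    pi0 <- pmax(colMeans(W0), 1 / n); pi0 <- pi0 / sum(pi0)

    run <- em_run(Y, masks, orders, beta0, sigma0, pi0, tol, max_iter)
    if (run$degenerate) next
    if (is.null(best) || run$loglik > best$loglik) {
      best <- run
      best$n_restarts_used <- r
    }
  }
  if (is.null(best))
    stop("all restarts collapsed to a degenerate (empty-group) solution",
         call. = FALSE)

  k_params <- sum(orders + 1L) + (J - 1L) + 1L
  fit <- structure(list(
    J = J, orders = orders, beta = best$beta, sigma = best$sigma,
    pi = best$pi, bounds = c(0, 1), loglik = best$loglik,
    n_patients = n, n_obs = sum(masks$obs), Tmax = Tmax,
    k_params = k_params, converged = best$converged,
    n_restarts_used = best$n_restarts_used,
    iterations = best$iterations, loglik_trace = best$trace
  ), class = "gbtm_fit")
  fit$bic <- bic(fit)
  fit
}

#' @export
print.gbtm_fit <- function(x, ...) {
  cat(sprintf("Censored-normal trajectory model: %d groups, n = %d, T = %d\n",
              x$J, x$n_patients, x$Tmax))
  cat(sprintf("  loglik = %.3f   BIC = %.3f   sigma = %.4f   %s\n",
              x$loglik, x$bic, x$sigma,
              if (x$converged) "converged" else "NOT converged"))
  for (j in seq_len(x$J))
    cat(sprintf("  group %d: pi = %.3f, order %d, beta = (%s)\n",
                j, x$pi[j], x$orders[j],
                paste(sprintf("%.3f", x$beta[[j]]), collapse = ", ")))
  invisible(x)
}

#' Bayesian information criterion (larger-is-better convention)
#'
#' \eqn{BIC = \ell - (k/2)\log n}, the convention used for trajectory-model
#' group-number selection: the candidate with the highest value wins.
#'
#' @param model a fitted \code{gbtm_fit}
#' @return scalar BIC
#' @export
bic <- function(model) {
  model$loglik - 0.5 * model$k_params * log(model$n_patients)
}

#' Posterior group membership and modal assignment
#'
#' Bayes posteriors \eqn{\pi_j L_{ij} / \sum_k \pi_k L_{ik}} per patient and
#' the modal group (ties break to the lowest group index).
#'
#' @param model a fitted \code{gbtm_fit}
#' @param panel the PDC panel to score (long or matrix form)
#' @return data frame: patient_id, one \code{post_j} column per group,
#'   assigned_group, max_posterior
#' @export
posterior_assign <- function(model, panel) {
  Y <- panel_to_matrix(panel)
  masks <- obs_masks(Y)
  Xfull <- time_basis(model$Tmax, 2L)
  if (ncol(Y) > model$Tmax)
    stop("panel has more intervals than the fitted model", call. = FALSE)
  if (ncol(Y) < model$Tmax)
    Xfull <- time_basis(model$Tmax, 2L)[seq_len(ncol(Y)), , drop = FALSE]
  L <- patient_group_loglik(Y, masks, Xfull, model$beta, model$sigma)
  lp <- sweep(L, 2L, log(model$pi), `+`)
  W <- exp(lp - row_log_sum_exp(lp))
  assigned <- apply(W, 1L, which.max)  # which.max -> lowest index on ties
  out <- data.frame(patient_id = rownames(Y) %||% as.character(seq_len(nrow(Y))),
                    stringsAsFactors = FALSE)
  for (j in seq_len(model$J)) out[[paste0("post_", j)]] <- W[, j]
  out$assigned_group <- assigned
  out$max_posterior <- W[cbind(seq_len(nrow(W)), assigned)]
  out
}

#' Classification diagnostics for a trajectory model
#'
#' Average posterior probability of assignment (APPA) and odds of correct
#' classification (OCC) per group, assigned group shares, and a long-format
#' bundle of observed PDC series keyed by assigned group for spaghetti
#' plotting. Groups with APPA below \code{appa_threshold} are flagged.
#'
#' @param model fitted \code{gbtm_fit}
#' @param assignments output of \code{\link{posterior_assign}}
#' @param panel optional long panel to attach as the spaghetti bundle
#' @param appa_threshold adequacy threshold (default 0.70)
#' @return list: \code{table} (group, n, share, appa, occ, flagged),
#'   \code{spaghetti} (long panel with assigned_group), \code{appa_threshold}
#' @export
gbtm_diagnostics <- function(model, assignments, panel = NULL,
                             appa_threshold = 0.70) {
  J <- model$J
  tab <- data.frame(group = seq_len(J))
  tab$n <- vapply(seq_len(J), function(j)
    sum(assignments$assigned_group == j), integer(1))
  tab$share <- tab$n / nrow(assignments)
  tab$appa <- vapply(seq_len(J), function(j) {
    m <- assignments$assigned_group == j
    if (!any(m)) NA_real_ else mean(assignments$max_posterior[m])
  }, numeric(1))
  occ <- function(appa, p) {
    if (is.na(appa) || p <= 0 || p >= 1) return(NA_real_)
    if (appa >= 1) return(Inf)
    (appa / (1 - appa)) / (p / (1 - p))
  }
  tab$occ <- mapply(occ, tab$appa, model$pi)
  tab$flagged <- is.na(tab$appa) | tab$appa < appa_threshold
  spag <- NULL
  if (!is.null(panel) && !is.matrix(panel)) {
    spag <- panel
    spag$assigned_group <- assignments$assigned_group[
      match(spag$patient_id, assignments$patient_id)]
  }
  list(table = tab, spaghetti = spag, appa_threshold = appa_threshold)
}

# ---- standard errors ---------------------------------------------------

# observed-data loglik and analytic score over the full parameter vector
# (betas, mixing logits alpha_2..J, log sigma); Hessian by numerically
# differentiating the score (stats::optimHess)
full_par <- function(model) {
  c(unlist(model$beta), log(model$pi[-1L] / model$pi[1L]), log(model$sigma))
}

obs_loglik_factory <- function(Y, masks, orders, Tmax) {
  J <- length(orders)
  Xfull <- time_basis(Tmax, 2L)
  nb <- sum(orders + 1L)
  split_par <- function(par) {
    beta <- list(); k <- 0L
    for (j in seq_len(J)) { beta[[j]] <- par[k + seq_len(orders[j] + 1L)]
                            k <- k + orders[j] + 1L }
    alpha <- c(0, par[nb + seq_len(J - 1L)])
    pival <- exp(alpha - log_sum_exp(alpha))
    list(beta = beta, pi = pival, sigma = exp(par[nb + J]))
  }
  fn <- function(par) {
    p <- split_par(par)
    L <- patient_group_loglik(Y, masks, Xfull, p$beta, p$sigma)
    sum(row_log_sum_exp(sweep(L, 2L, log(p$pi), `+`)))
  }
  gr <- function(par) {
    p <- split_par(par)
    L <- patient_group_loglik(Y, masks, Xfull, p$beta, p$sigma)
    lp <- sweep(L, 2L, log(p$pi), `+`)
    W <- exp(lp - row_log_sum_exp(lp))
    st <- mstep_stats(Y, masks, W)
    qf <- q_fn_factory(st, Xfull, orders)
    gq <- -qf$gr(pack_par(p$beta, p$sigma))  # score for betas and log sigma
    galpha <- colSums(W)[-1L] - nrow(Y) * p$pi[-1L]
    c(gq[seq_len(nb)], galpha, gq[nb + 1L])
  }
  list(fn = fn, gr = gr, nb = nb, J = J)
}

#' Parameter covariance from the observed information matrix
#'
#' @param model fitted \code{gbtm_fit}
#' @param panel the panel the model was fitted to
#' @return the model with \code{vcov} (full parameter covariance, order:
#'   per-group betas, mixing logits, log sigma) and \code{par_index}
#'   attached
#' @export
gbtm_vcov <- function(model, panel) {
  Y <- panel_to_matrix(panel)
  masks <- obs_masks(Y)
  of <- obs_loglik_factory(Y, masks, model$orders, model$Tmax)
  par <- full_par(model)
  H <- optimHess(par, of$fn, of$gr)
  V <- tryCatch(solve(-H), error = function(e) MASS::ginv(-H))
  idx <- list()
  k <- 0L
  for (j in seq_len(model$J)) {
    idx[[paste0("beta_", j)]] <- k + seq_len(model$orders[j] + 1L)
    k <- k + model$orders[j] + 1L
  }
  idx$alpha <- k + seq_len(model$J - 1L)
  idx$log_sigma <- k + model$J
  model$vcov <- V
  model$par_index <- idx
  model
}

# Wald z for each group's highest-order coefficient (order >= 1)
top_order_wald <- function(model, panel) {
  if (is.null(model$vcov)) model <- gbtm_vcov(model, panel)
  out <- data.frame(group = seq_len(model$J), order = model$orders,
                    estimate = NA_real_, se = NA_real_, z = NA_real_,
                    p = NA_real_)
  for (j in seq_len(model$J)) {
    if (model$orders[j] == 0L) next
    ii <- model$par_index[[paste0("beta_", j)]]
    top <- ii[length(ii)]
    est <- model$beta[[j]][length(model$beta[[j]])]
    se <- sqrt(max(model$vcov[top, top], 0))
    out$estimate[j] <- est; out$se[j] <- se
    out$z[j] <- est / se
    out$p[j] <- 2 * pnorm(-abs(est / se))
  }
  out
}

#' Three-step trajectory model selection
#'
#' Step 1 fits all-quadratic models over the candidate group numbers and
#' picks the number of groups by BIC among admissible candidates (every
#' group share at least \code{min_share}, converged). Step 2, holding the
#' group number fixed, prunes polynomial orders: the highest-order
#' coefficient with the largest non-significant Wald p-value (above
#' \code{alpha}) is removed and the model refitted, until every retained
#' top-order term is significant. Step 3 computes posterior-assignment
#' diagnostics on the final model.
#'
#' @param panel long PDC panel or matrix
#' @param j_range candidate group numbers (default 2:7)
#' @param seed integer seed
#' @param n_restarts restarts per fit
#' @param min_share minimum admissible group share in step 1 (default 0.02)
#' @param alpha Wald significance level for order pruning (default 0.05)
#' @param tol,max_iter EM controls
#' @return list: \code{model} (final \code{gbtm_fit} with vcov),
#'   \code{assignments}, \code{diagnostics}, \code{trace} (candidate table),
#'   \code{step2} (pruning records)
#' @export
select_model <- function(panel, j_range = 2:7, seed = 1L, n_restarts = 5L,
                         min_share = 0.02, alpha = 0.05,
                         tol = 1e-8, max_iter = 500L) {
  Y <- panel_to_matrix(panel)
  cand <- list(); rows <- list()
  for (J in j_range) {
    fit <- tryCatch(
      fit_gbtm(Y, J, orders = 2L, seed = child_seed(seed, J),
               tol = tol, max_iter = max_iter, n_restarts = n_restarts),
      error = function(e) NULL)
    cand[[as.character(J)]] <- fit
    rows[[as.character(J)]] <- data.frame(
      step = 1L, J = J,
      orders = if (is.null(fit)) NA_character_ else
        paste(fit$orders, collapse = ","),
      loglik = if (is.null(fit)) NA_real_ else fit$loglik,
      bic = if (is.null(fit)) NA_real_ else fit$bic,
      min_share = if (is.null(fit)) NA_real_ else min(fit$pi),
      converged = if (is.null(fit)) FALSE else fit$converged,
      admissible = !is.null(fit) && fit$converged && min(fit$pi) >= min_share,
      chosen = FALSE, stringsAsFactors = FALSE)
  }
  trace <- do.call(rbind, rows)
  ok <- which(trace$admissible)
  if (!length(ok)) {
    ok <- which(!is.na(trace$bic))
    if (!length(ok))
      stop("no candidate model converged in step 1", call. = FALSE)
  }
  pick <- ok[which.max(trace$bic[ok])]
  trace$chosen[pick] <- TRUE
  J_star <- trace$J[pick]
  fit <- cand[[as.character(J_star)]]

  # step 2: prune highest-order terms, most non-significant first
  step2 <- list()
  orders <- fit$orders
  repeat {
    wald <- top_order_wald(fit, Y)
    step2[[length(step2) + 1L]] <- cbind(orders = paste(orders, collapse = ","),
                                         wald)
    prunable <- which(!is.na(wald$p) & wald$p > alpha)
    if (!length(prunable)) break
    drop_j <- prunable[which.max(wald$p[prunable])]
    orders[drop_j] <- orders[drop_j] - 1L
    fit <- fit_gbtm(Y, J_star, orders = orders,
                    seed = child_seed(seed, 100L + length(step2)),
                    tol = tol, max_iter = max_iter, n_restarts = n_restarts)
  }
  fit <- gbtm_vcov(fit, Y)
  assignments <- posterior_assign(fit, Y)
  diag <- gbtm_diagnostics(fit, assignments,
                           panel = if (!is.matrix(panel)) panel else NULL)
  list(model = fit, assignments = assignments, diagnostics = diag,
       trace = trace, step2 = do.call(rbind, step2))
}

#' Model-implied mean PDC trajectory with pointwise confidence band
#'
#' The expectation of the clamped latent propensity
#' \eqn{E[\min(1,\max(0,y^*))]} in closed form:
#' \eqn{\mu(\Phi(b)-\Phi(a)) + \sigma(\phi(a)-\phi(b)) + (1-\Phi(b))} with
#' \eqn{a=-\mu/\sigma}, \eqn{b=(1-\mu)/\sigma}. The confidence band is a
#' delta-method interval over the coefficient covariance (sigma and mixing
#' treated as fixed); note \eqn{\partial E/\partial\mu = \Phi(b)-\Phi(a)}.
#'
#' @param model fitted \code{gbtm_fit} (with \code{vcov}; computed on the
#'   fly via \code{panel} if absent)
#' @param group group index
#' @param t_grid interval indices (may be fractional; values outside the
#'   fitted range trigger an extrapolation warning)
#' @param level confidence level (default 0.95)
#' @param panel panel for covariance computation when \code{model$vcov} is
#'   missing
#' @return data frame: t, mu (latent mean), mean (clamped mean), ci_low,
#'   ci_high
#' @export
predicted_trajectory <- function(model, group, t_grid = NULL, level = 0.95,
                                 panel = NULL) {
  stopifnot(group >= 1, group <= model$J)
  if (is.null(t_grid)) t_grid <- seq_len(model$Tmax) - 1L
  if (any(t_grid < 0 | t_grid > model$Tmax - 1L))
    warning("t_grid extends beyond the fitted interval range; extrapolating")
  tau <- if (model$Tmax == 1L) rep(0, length(t_grid)) else
    t_grid / (model$Tmax - 1L)
  d <- model$orders[group]
  X <- cbind(1, tau, tau^2)[, seq_len(d + 1L), drop = FALSE]
  mu <- drop(X %*% model$beta[[group]])
  s <- model$sigma
  a <- -mu / s; b <- (1 - mu) / s
  mean_clamped <- mu * (pnorm(b) - pnorm(a)) + s * (dnorm(a) - dnorm(b)) +
    (1 - pnorm(b))
  if (is.null(model$vcov)) {
    if (is.null(panel))
      stop("model has no vcov; supply the fitted panel", call. = FALSE)
    model <- gbtm_vcov(model, panel)
  }
  Vb <- model$vcov[model$par_index[[paste0("beta_", group)]],
                   model$par_index[[paste0("beta_", group)]], drop = FALSE]
  var_mu <- rowSums((X %*% Vb) * X)
  se <- (pnorm(b) - pnorm(a)) * sqrt(pmax(var_mu, 0))
  zq <- qnorm(1 - (1 - level) / 2)
  data.frame(t = t_grid, mu = mu, mean = mean_clamped,
             ci_low = pmax(mean_clamped - zq * se, 0),
             ci_high = pmin(mean_clamped + zq * se, 1))
}

#' Match estimated groups to reference groups
#'
#' Brute-force search over label permutations minimising the summed squared
#' distance between estimated and reference mean curves — used to align
#' labels before comparing a fit against a known generating model.
#'
#' @param est_curves J x T matrix of estimated group means
#' @param ref_curves J x T matrix of reference group means
#' @return integer permutation p with est group j matching ref group p[j]
#' @export
match_group_labels <- function(est_curves, ref_curves) {
  J <- nrow(est_curves)
  perms <- permutations_of(J)
  costs <- vapply(perms, function(p)
    sum((est_curves - ref_curves[p, , drop = FALSE])^2), numeric(1))
  perms[[which.min(costs)]]
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    sub <- permutations_of(n - 1L)
    rest <- setdiff(seq_len(n), i)
    out <- c(out, lapply(sub, function(p) c(i, rest[p])))
  }
  out
}

#' Group mean curves of a fitted model on the interval grid
#'
#' @param model fitted \code{gbtm_fit}
#' @param clamped return the censored-normal clamped mean (default) or the
#'   raw latent mean
#' @return J x Tmax matrix of group means
#' @export
group_mean_curves <- function(model, clamped = TRUE) {
  t_grid <- seq_len(model$Tmax) - 1L
  out <- matrix(NA_real_, model$J, model$Tmax)
  for (j in seq_len(model$J)) {
    tau <- if (model$Tmax == 1L) 0 else t_grid / (model$Tmax - 1L)
    d <- model$orders[j]
    mu <- drop(cbind(1, tau, tau^2)[, seq_len(d + 1L), drop = FALSE] %*%
                 model$beta[[j]])
    if (clamped) {
      s <- model$sigma; a <- -mu / s; b <- (1 - mu) / s
      mu <- mu * (pnorm(b) - pnorm(a)) + s * (dnorm(a) - dnorm(b)) +
        (1 - pnorm(b))
    }
    out[j, ] <- mu
  }
  out
}
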