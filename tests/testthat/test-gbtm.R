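test_that("censored-normal observation log-likelihood matches closed forms", {
  # y at the upper bound with mu on the bound: half the mass is censored
  expect_equal(cnorm_obs_loglik(1, 1, 0.2), log(0.5), tolerance = 1e-12)
  # interior value at the mean: standard normal density scaled by 1/sigma
  expect_equal(cnorm_obs_loglik(0.5, 0.5, 0.2), log(dnorm(0) / 0.2),
               tolerance = 1e-12)
  # y = 0 with mu = 0.3, sigma = 0.15: left-tail mass Phi(-2) via erf
  phi_m2 <- 0.5 * (1 + pracma::erf(-2 / sqrt(2)))
  expect_equal(cnorm_obs_loglik(0, 0.3, 0.15), log(phi_m2), tolerance = 1e-9)
  expect_error(cnorm_obs_loglik(1.2, 0.5, 0.1), "0, 1")
  expect_error(cnorm_obs_loglik(0.5, 0.5, 0), "sigma")
})

test_that("mixture log-likelihood equals brute-force enumeration on tiny fixtures", {
  # 3 patients x 2 intervals, fixed parameters, exhaustive sum over groups
  y <- matrix(c(1.0, 0.8, 0.4, 0.0, 0.9, 1.0), nrow = 3, byrow = TRUE)
  rownames(y) <- c("a", "b", "c")
  model <- list(beta = list(c(0.9, -0.1), c(0.3, -0.3, 0.1)),
                sigma = 0.2, pi = c(0.6, 0.4))
  tau <- c(0, 1)
  brute <- 0
  for (i in 1:3) {
    li <- 0
    for (j in 1:2) {
      mu <- drop(cbind(1, tau, tau^2)[, seq_along(model$beta[[j]])] %*%
                   model$beta[[j]])
      li <- li + model$pi[j] *
        prod(exp(cnorm_obs_loglik(y[i, ], mu, model$sigma)))
    }
    brute <- brute + log(li)
  }
  expect_equal(mixture_loglik(y, model), brute, tolerance = 1e-10)

  # degenerate mixtures: J = 1, and two identical components
  m1 <- list(beta = list(c(0.9, -0.1)), sigma = 0.2, pi = 1)
  ll1 <- mixture_loglik(y, m1)
  mu1 <- drop(cbind(1, tau) %*% c(0.9, -0.1))
  expect_equal(ll1, sum(cnorm_obs_loglik(as.vector(t(y)),
                                         rep(mu1, 3), 0.2)),
               tolerance = 1e-10)
  m2 <- list(beta = list(c(0.9, -0.1), c(0.9, -0.1)), sigma = 0.2,
             pi = c(0.5, 0.5))
  expect_equal(mixture_loglik(y, m2), ll1, tolerance = 1e-10)
})

test_that("label permutation leaves loglik and BIC unchanged", {
  sim <- simulate_pdc_panels(300, recovery_mixing(), recovery_polys(),
                             0.15, 9, seed = 4)
  fit <- fit_gbtm(sim$panel, J = 3, seed = 1, n_restarts = 1)
  perm <- c(3, 1, 2)
  permuted <- fit
  permuted$beta <- fit$beta[perm]
  permuted$pi <- fit$pi[perm]
  expect_equal(mixture_loglik(sim$panel, permuted), fit$loglik,
               tolerance = 1e-8)
})

test_that("with no censored observations a one-group fit is the least-squares solution", {
  set.seed(12)
  n <- 150; Tn <- 6
  tau <- (0:(Tn - 1)) / (Tn - 1)
  y <- matrix(0.5 + 0.15 * rep(tau, each = n) +
                rnorm(n * Tn, 0, 0.04), n, Tn)
  stopifnot(all(y > 0 & y < 1))
  rownames(y) <- paste0("p", 1:n)
  fit <- fit_gbtm(y, J = 1, orders = 1, seed = 1, n_restarts = 1)
  ols <- lm(as.vector(y) ~ rep(tau, each = n))
  expect_equal(unname(fit$beta[[1]]), unname(coef(ols)), tolerance = 1e-6)
  sig_ml <- sqrt(mean(ols$residuals^2))
  expect_equal(fit$sigma, sig_ml, tolerance = 1e-6)
})

test_that("EM log-likelihood is monotone non-decreasing on every fit", {
  for (s in 1:3) {
    sim <- simulate_pdc_panels(250, recovery_mixing(), recovery_polys(),
                               0.15, 9, seed = s)
    fit <- fit_gbtm(sim$panel, J = 3, seed = s, n_restarts = 1)
    expect_true(all(diff(fit$loglik_trace) > -1e-6))
    expect_true(fit$converged)
  }
})

test_that("BIC uses the larger-is-better convention and penalises parameters", {
  m <- list(loglik = -100, k_params = 5, n_patients = 100)
  expect_equal(bic(m), -100 - 0.5 * 5 * log(100), tolerance = 1e-12)
  m2 <- list(loglik = -100, k_params = 6, n_patients = 100)
  expect_lt(bic(m2), bic(m))
})

test_that("posterior assignment matches a hand-computed Bayes ratio", {
  model <- structure(list(J = 2, orders = c(0L, 0L),
                          beta = list(0.9, 0.3), sigma = 0.2,
                          pi = c(0.7, 0.3), Tmax = 2L), class = "gbtm_fit")
  y <- matrix(c(0.8, 0.6), 1, 2, dimnames = list("pt", NULL))
  a <- posterior_assign(model, y)
  l1 <- sum(cnorm_obs_loglik(c(0.8, 0.6), 0.9, 0.2))
  l2 <- sum(cnorm_obs_loglik(c(0.8, 0.6), 0.3, 0.2))
  p1 <- 0.7 * exp(l1) / (0.7 * exp(l1) + 0.3 * exp(l2))
  expect_equal(a$post_1, p1, tolerance = 1e-12)
  expect_equal(a$post_1 + a$post_2, 1, tolerance = 1e-12)
  expect_equal(a$assigned_group, 1L)

  # symmetric two-group tie breaks to the lowest index
  tie <- structure(list(J = 2, orders = c(0L, 0L),
                        beta = list(0.4, 0.6), sigma = 0.2,
                        pi = c(0.5, 0.5), Tmax = 1L), class = "gbtm_fit")
  at <- posterior_assign(tie, matrix(0.5, 1, 1, dimnames = list("q", NULL)))
  expect_equal(at$post_1, 0.5, tolerance = 1e-12)
  expect_equal(at$assigned_group, 1L)

  # J = 1: posterior is identically one
  m1 <- structure(list(J = 1, orders = 0L, beta = list(0.5), sigma = 0.2,
                       pi = 1, Tmax = 2L), class = "gbtm_fit")
  expect_equal(posterior_assign(m1, y)$post_1, 1)
})

test_that("diagnostics compute APPA, OCC and the OCC identity", {
  assign <- data.frame(patient_id = as.character(1:10),
                       assigned_group = rep(1:2, each = 5),
                       max_posterior = rep(c(1, 1), each = 5))
  model <- list(J = 2, pi = c(0.5, 0.5))
  d <- gbtm_diagnostics(model, assign)
  expect_equal(d$table$appa, c(1, 1))
  expect_equal(d$table$occ, c(Inf, Inf))
  expect_false(any(d$table$flagged))
  # uninformative posteriors: APPA_j = pi_j implies OCC = 1
  model2 <- list(J = 2, pi = c(0.7, 0.3))
  assign2 <- data.frame(patient_id = as.character(1:10),
                        assigned_group = rep(1:2, each = 5),
                        max_posterior = rep(c(0.7, 0.3), each = 5))
  d2 <- gbtm_diagnostics(model2, assign2)
  expect_equal(d2$table$occ, c(1, 1), tolerance = 1e-12)
})

test_that("predicted trajectory matches theory and a Monte Carlo oracle", {
  sim <- simulate_pdc_panels(400, recovery_mixing(), recovery_polys(),
                             0.15, 9, seed = 8)
  fit <- fit_gbtm(sim$panel, J = 3, seed = 1, n_restarts = 1)
  fit <- gbtm_vcov(fit, sim$panel)

  # degenerate-noise and saturation limits of the clamped mean
  flat_model <- function(b, s)
    structure(list(J = 1, orders = 0L, beta = list(b), sigma = s, pi = 1,
                   Tmax = 9L, vcov = matrix(0, 2, 2),
                   par_index = list(beta_1 = 1L)), class = "gbtm_fit")
  pt <- predicted_trajectory(flat_model(0.5, 1e-9), 1, t_grid = 0)
  expect_equal(pt$mean, 0.5, tolerance = 1e-9)
  expect_equal(predicted_trajectory(flat_model(2, 0.1), 1, t_grid = 0)$mean,
               1, tolerance = 1e-9)

  # closed-form clamped mean vs simulation at mu = 0.5, sigma = 0.5
  set.seed(99)
  draws <- pmin(pmax(rnorm(1e7, 0.5, 0.5), 0), 1)
  est <- predicted_trajectory(flat_model(0.5, 0.5), 1, t_grid = 0)$mean
  mc_se <- sd(draws) / sqrt(1e7)
  expect_lt(abs(est - mean(draws)), 3 * mc_se)

  # fitted-model band: finite, ordered, inside [0,1]
  tr <- predicted_trajectory(fit, 2)
  expect_true(all(tr$ci_low <= tr$mean & tr$mean <= tr$ci_high))
  expect_true(all(tr$ci_low >= 0 & tr$ci_high <= 1))
  expect_warning(predicted_trajectory(fit, 2, t_grid = 12), "extrapolat")
})

test_that("three-step selection recovers group number and functional forms", {
  sim <- simulate_pdc_panels(700, recovery_mixing(), recovery_polys(),
                             0.15, 9, seed = 31)
  sel <- select_model(sim$panel, j_range = 2:4, seed = 3, n_restarts = 1)
  expect_equal(nrow(sel$trace), 3)  # one step-1 candidate per J
  expect_equal(sel$model$J, 3)
  # the constant generating group is pruned to order 0
  curves <- group_mean_curves(sel$model, clamped = FALSE)
  flat_j <- which.min(apply(curves, 1, function(r) max(r) - min(r)))
  expect_equal(sel$model$orders[flat_j], 0L)
  # posterior rows sum to 1; APPA in a valid range
  W <- as.matrix(sel$assignments[, paste0("post_", 1:3)])
  expect_true(all(abs(rowSums(W) - 1) < 1e-9))
  expect_true(all(sel$diagnostics$table$appa >= 1 / 3 - 1e-9))

  # restricting the search to the true J trivially returns it
  sel3 <- select_model(sim$panel, j_range = 3, seed = 3, n_restarts = 1)
  expect_equal(sel3$model$J, 3)
  expect_equal(nrow(sel3$trace), 1)
})
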