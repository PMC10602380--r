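runif_seeded <- function(n, lo, hi, seed) {
  set.seed(seed)
  runif(n, lo, hi)
}

free_energy_of <- function(traj, seed) {
  fit <- fit_map(traj, 1, opts = optimizer_options(seed = seed))
  free_energy(fit, traj, 1)$F
}

test_that("Kalman marginal log-likelihood equals the dense joint-Gaussian density", {
  set.seed(101)
  cases <- expand.grid(order = 1:2, n = 1:2, T = c(5, 12, 20))
  for (k in seq_len(nrow(cases))) {
    order <- cases$order[k]; n <- cases$n[k]; Tn <- cases$T[k]
    a <- runif(n, -1, -0.2)
    cg <- runif(n, 0.2, 1)
    x0 <- runif(n, -1, 1)
    xd0 <- runif(n, -1, 1)
    ls <- runif(1, -0.5, 2)   # sigma_s in ~[0.37, 1.3]
    lo <- runif(1, 0, 3)
    dt <- 0.72
    y <- matrix(rnorm(Tn * n), Tn, n)
    v <- matrix(rbinom(Tn * n, 1, 0.3), Tn, n)
    th <- named_theta(order, a, cg, x0, xd0, ls, lo)
    got <- marginal_loglik(th, as_trajectory((0:(Tn - 1)) * dt, y, v), order)
    want <- oracle_dense_loglik(order, a, cg, x0, if (order == 2) xd0,
                                sigma_s = exp(-ls / 2), sigma_o = exp(-lo / 2),
                                dt = dt, y = y, v = v)
    expect_equal(got, want, tolerance = 1e-8,
                 label = sprintf("case order=%d n=%d T=%d", order, n, Tn))
  }
})

test_that("the likelihood of a zero-mean model is sign-symmetric in the data", {
  y <- matrix(rnorm(40), 20, 2)
  traj_p <- as_trajectory((0:19) * 0.5, y)
  traj_m <- as_trajectory((0:19) * 0.5, -y)
  th <- named_theta(1, a = c(-0.5, -0.8), c_gain = c(0, 0), x0 = c(0, 0),
                    lambda_state = 1, lambda_obs = 1)
  expect_identical(marginal_loglik(th, traj_p, 1),
                   marginal_loglik(th, traj_m, 1))
})

test_that("independent identical regions factorize the likelihood", {
  set.seed(7)
  y1 <- matrix(rnorm(30), 30, 1)
  times <- (0:29) * 0.72
  th1 <- named_theta(2, a = -0.6, c_gain = 0.4, x0 = 0.2, xdot0 = -0.1,
                     lambda_state = 1, lambda_obs = 0.5)
  th2 <- named_theta(2, a = rep(-0.6, 2), c_gain = rep(0.4, 2),
                     x0 = rep(0.2, 2), xdot0 = rep(-0.1, 2),
                     lambda_state = 1, lambda_obs = 0.5)
  ll1 <- marginal_loglik(th1, as_trajectory(times, y1), 2)
  ll2 <- marginal_loglik(th2, as_trajectory(times, cbind(y1, y1)), 2)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-10)
})

test_that("an infinitely tight prior pins the posterior to the prior mean", {
  traj <- quick_series(1, n = 1, n_timepoints = 60, seed = 2)
  pr <- default_priors(1, 1)
  pr$var[] <- 1e-12
  fit <- fit_map(traj, 1, priors = pr, opts = optimizer_options(n_restarts = 0))
  expect_lt(max(abs(fit$mean - pr$mean)), 1e-6)
})

test_that("Laplace matches the conjugate linear-Gaussian posterior and evidence", {
  # state noise off, couplings/gains/precisions fixed: x0 is the only
  # unknown and enters the mean linearly, so the exact posterior and
  # evidence have closed forms.
  n <- 2
  Tn <- 25
  dt <- 0.72
  a <- c(-0.4, -0.9)
  sigma_o <- 0.2
  set.seed(31)
  x0_true <- c(0.8, -0.6)
  X <- sapply(a, function(ai) exp(ai * dt * (0:(Tn - 1))))  # per-region decay
  y <- sweep(X, 2, x0_true, `*`) + matrix(rnorm(Tn * n, 0, sigma_o), Tn, n)
  traj <- as_trajectory((0:(Tn - 1)) * dt, y)

  lambda_obs <- -log(sigma_o^2)
  fixed <- c(a_1 = a[1], a_2 = a[2], c_1 = 0, c_2 = 0,
             lambda_state = Inf, lambda_obs = lambda_obs)
  fit <- fit_map(traj, 1, opts = optimizer_options(n_restarts = 0),
                 fixed = fixed)
  ed <- free_energy(fit, traj, 1)

  # closed forms, region-wise (design X_i = exp(a_i t), prior N(0, 1))
  post_var <- 1 / (colSums(X^2) / sigma_o^2 + 1)
  post_mean <- post_var * colSums(X * y) / sigma_o^2
  logev <- sum(sapply(1:n, function(i) {
    S <- X[, i] %*% t(X[, i]) + diag(sigma_o^2, Tn)
    ch <- chol(S)
    z <- backsolve(ch, y[, i], transpose = TRUE)
    -0.5 * (Tn * log(2 * pi) + sum(z^2)) - sum(log(diag(ch)))
  }))

  expect_equal(unname(fit$mean[c("x0_1", "x0_2")]), post_mean, tolerance = 1e-6)
  expect_equal(unname(diag(fit$cov)), post_var, tolerance = 1e-4)
  expect_equal(ed$F, logev, tolerance = 1e-4)
})

test_that("free energy decomposes as accuracy minus complexity", {
  for (seed in c(4, 9)) {
    traj <- quick_series((seed %% 2) + 1, n = 2, n_timepoints = 80, seed = seed)
    ev <- invert_both_orders(traj, opts = optimizer_options(seed = seed))
    for (ed in ev) {
      expect_equal(ed$F, ed$accuracy - ed$complexity, tolerance = 1e-8)
      expect_gte(ed$complexity, 0)
    }
  }
})

test_that("the Gaussian KL term matches closed forms", {
  kl <- orderstates:::gaussian_kl
  # KL(N(1,1) || N(0,1)) = 0.5 nats
  expect_equal(kl(1, matrix(1), 0, 1), 0.5, tolerance = 1e-12)
  # identical Gaussians: zero complexity, F = accuracy
  traj <- quick_series(1, n = 1, n_timepoints = 50, seed = 5)
  pr <- default_priors(1, 1)
  post <- structure(list(mean = pr$mean, cov = diag(pr$var), converged = TRUE,
                         n_iterations = 0L, order = 1L, fixed = numeric(0),
                         hessian_repaired = FALSE),
                    class = "parameter_posterior")
  ed <- free_energy(post, traj, 1, pr)
  expect_equal(ed$complexity, 0, tolerance = 1e-12)
  expect_identical(ed$F, ed$accuracy)
})

test_that("an unused input regressor cannot raise the free energy on average", {
  # data generated with zero input gain; offering a (known, non-zero)
  # regressor adds parameters that complexity must pay for
  dF <- sapply(1:5, function(seed) {
    m <- first_order_model(a = runif_seeded(1, -1, -0.3, seed),
                           c = 0, sigma_state = 0.2, sigma_obs = 0.1,
                           x0 = 0.5)
    traj <- simulate_model(m, duration = 120 * 0.72, dt = 0.72, seed = seed)
    with_input <- traj
    with_input$inputs <- make_input(input_boxcar(seq(10, 80, by = 30), 10),
                                    traj$times, 1)
    f_with <- free_energy_of(with_input, seed)
    f_without <- free_energy_of(traj, seed)
    f_with - f_without
  })
  expect_lte(mean(dF), 0.5)
})

test_that("inversion is deterministic given the optimizer seed", {
  traj <- quick_series(2, n = 2, n_timepoints = 100, seed = 3)
  e1 <- invert_both_orders(traj, opts = optimizer_options(seed = 77))
  e2 <- invert_both_orders(traj, opts = optimizer_options(seed = 77))
  expect_identical(e1$order1$F, e2$order1$F)
  expect_identical(e1$order2$F, e2$order2$F)
})

test_that("degenerate and inconsistent inputs raise contract errors", {
  traj <- quick_series(1, n = 1, n_timepoints = 50, seed = 6)
  th <- named_theta(1, a = NA_real_, c_gain = 0, x0 = 0)
  expect_error(marginal_loglik(th, traj, 1), "non-finite")
  bad <- traj
  bad$observed[3, 1] <- NA
  expect_error(fit_map(bad, 1), "finite")
  pr <- default_priors(1, 1)
  expect_error(prior_spec(pr$mean, pr$var * 0), "positive")
})
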