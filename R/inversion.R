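#' Gaussian prior specification over free parameters
#'
#' Priors are independent Gaussians over the free-parameter vector
#' (self-couplings `a_i`, input gains `c_i`, initial conditions `x0_i`
#' [and `xdot0_i` for order 2], and the log-precisions of state and
#' observation noise). Coupling and gain priors default to mean zero — the
#' inversion "forgets" the generating parameters and must recover them from
#' the data.
#'
#' @param mean named numeric vector of prior means.
#' @param var named numeric vector of prior variances (all positive), same
#'   names as `mean`.
#' @return a `prior_spec` object.
#' @export
prior_spec <- function(mean, var) {
  stopifnot(length(mean) == length(var),
            !is.null(names(mean)),
            identical(names(mean), names(var)))
  if (any(var <= 0)) stop("all prior variances must be positive")
  if (any(!is.finite(c(mean, var)))) stop("priors must be finite")
  structure(list(mean = mean, var = var), class = "prior_spec")
}

#' Default priors for a given model order
#'
#' Zero-mean, unit-variance Gaussians on every coupling, gain and initial
#' condition, and standard-normal priors on the two noise log-precisions
#' (so noise variances are log-normal a priori).
#'
#' @param order 1 or 2.
#' @param n_regions number of regions.
#' @return a [prior_spec()].
#' @export
default_priors <- function(order, n_regions) {
  nm <- param_names(order, n_regions)
  prior_spec(mean = setNames(rep(0, length(nm)), nm),
             var = setNames(rep(1, length(nm)), nm))
}

param_names <- function(order, n) {
  c(paste0("a_", seq_len(n)), paste0("c_", seq_len(n)),
    paste0("x0_", seq_len(n)),
    if (order == 2) paste0("xdot0_", seq_len(n)),
    "lambda_state", "lambda_obs")
}

# Unpack a full named parameter vector into the pieces the likelihood needs.
unpack_params <- function(theta, order, n) {
  list(a = unname(theta[paste0("a_", seq_len(n))]),
       c = unname(theta[paste0("c_", seq_len(n))]),
       x0 = unname(theta[paste0("x0_", seq_len(n))]),
       xdot0 = if (order == 2) unname(theta[paste0("xdot0_", seq_len(n))]) else rep(0, n),
       lambda_state = unname(theta[["lambda_state"]]),
       lambda_obs = unname(theta[["lambda_obs"]]))
}

#' Marginal log-likelihood of a timeseries under a linear-Gaussian model
#'
#' Exact log-likelihood of the observations under the discretized
#' linear-Gaussian state-space model of the given order, with the latent
#' states integrated out by a forward Kalman filter (prediction-error
#' decomposition). The initial latent state is the parameter
#' (`x0`[, `xdot0`]) with zero initial covariance; noise magnitudes enter
#' as log-precisions (`lambda_state`, `lambda_obs`), i.e.
#' \eqn{\sigma^2 = e^{-\lambda}}.
#'
#' @param params named numeric vector over the full parameter set, or a list
#'   with elements `a`, `c`, `x0` (`xdot0` for order 2), `lambda_state`,
#'   `lambda_obs`.
#' @param data a `trajectory` (uniform dt; inputs treated as known).
#' @param order 1 or 2.
#' @return log-likelihood in nats.
#' @export
marginal_loglik <- function(params, data, order) {
  stopifnot(inherits(data, "trajectory"), order %in% c(1, 2))
  n <- ncol(data$observed)
  if (is.numeric(params)) params <- unpack_params(params, order, n)
  stopifnot(length(params$a) == n, length(params$c) == n,
            length(params$x0) == n)
  if (order == 2 && is.null(params$xdot0)) stop("order 2 requires xdot0")
  vals <- c(params$a, params$c, params$x0, params$lambda_obs)
  if (any(!is.finite(vals))) stop("non-finite parameters")
  dt <- data$times[2] - data$times[1]
  ll_lingauss_cpp(as.integer(order), params$a, params$c, params$x0,
                  if (order == 2) params$xdot0 else rep(0, n),
                  params$lambda_state, params$lambda_obs,
                  dt, data$observed, data$inputs)
}

#' Optimizer options for model inversion
#'
#' @param n_restarts extra optimizer starts jittered around the prior mean
#'   (the prior mean itself is always a start).
#' @param jitter_sd standard deviation of the start jitter.
#' @param max_iter iteration cap per start.
#' @param reltol relative convergence tolerance for the objective.
#' @param seed seed controlling the jittered starts.
#' @return list of options for [fit_map()].
#' @export
optimizer_options <- function(n_restarts = 2, jitter_sd = 0.5,
                              max_iter = 500, reltol = 1e-10, seed = 1L) {
  list(n_restarts = n_restarts, jitter_sd = jitter_sd,
       max_iter = max_iter, reltol = reltol, seed = as.integer(seed))
}

#' Fit a model of a given order by variational Laplace
#'
#' Finds the posterior mode of the free parameters — maximizing
#' `marginal_loglik(theta) + log p(theta | priors)` — by quasi-Newton
#' optimization with multiple deterministic starts, then takes the Gaussian
#' (Laplace) posterior whose covariance is the inverse negative Hessian of
#' the log-joint at the mode. Noise log-precisions are estimated alongside
#' the couplings, gains and initial conditions. If the Hessian is not
#' negative definite it is repaired to the nearest symmetric
#' positive-definite precision (recorded in the result).
#'
#' @param data a `trajectory`.
#' @param order 1 or 2.
#' @param priors a [prior_spec()]; defaults to [default_priors()].
#' @param opts [optimizer_options()].
#' @param fixed optional named numeric vector of parameters held fixed
#'   (excluded from the free set and from the posterior).
#' @return a `parameter_posterior`: list with `mean`, `cov`, `converged`,
#'   `n_iterations`, `logpost`, `order`, `fixed`, `hessian_repaired`.
#' @export
fit_map <- function(data, order, priors = NULL, opts = optimizer_options(),
                    fixed = NULL) {
  stopifnot(inherits(data, "trajectory"), order %in% c(1, 2))
  if (any(!is.finite(data$observed))) stop("data must be finite")
  n <- ncol(data$observed)
  nm_all <- param_names(order, n)
  if (is.null(priors)) priors <- default_priors(order, n)
  if (is.null(fixed)) fixed <- numeric(0)
  if (length(fixed) && !all(names(fixed) %in% nm_all))
    stop("unknown fixed parameter names")
  free_nm <- setdiff(nm_all, names(fixed))
  if (!all(free_nm %in% names(priors$mean)))
    stop("priors must cover every free parameter")
  mu0 <- priors$mean[free_nm]
  tau0 <- 1 / priors$var[free_nm]
  p <- length(free_nm)

  full_theta <- function(th) {
    out <- setNames(numeric(length(nm_all)), nm_all)
    out[free_nm] <- th
    if (length(fixed)) out[names(fixed)] <- fixed
    out
  }
  # negative log joint (objective to minimize)
  nlj <- function(th) {
    ll <- marginal_loglik(full_theta(th), data, order)
    lp <- -0.5 * sum(tau0 * (th - mu0)^2)
    val <- -(ll + lp)
    if (!is.finite(val)) val <- 1e12
    val
  }

  starts <- list(unname(mu0))
  if (opts$n_restarts > 0) {
    jit <- with_seed(opts$seed, {
      lapply(seq_len(opts$n_restarts), function(i)
        unname(mu0) + rnorm(p, 0, opts$jitter_sd))
    })
    starts <- c(starts, jit)
  }

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, nlj, method = "BFGS",
            control = list(maxit = opts$max_iter, reltol = opts$reltol,
                           ndeps = rep(1e-6, p))),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  # polish from the best start: BFGS occasionally stops early on flat spots
  polish <- tryCatch(
    optim(best$par, nlj, method = "BFGS",
          control = list(maxit = opts$max_iter, reltol = opts$reltol,
                         ndeps = rep(1e-6, p))),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) {
    polish$counts <- polish$counts + best$counts
    best <- polish
  }

  H <- optimHess(best$par, nlj, control = list(ndeps = rep(1e-5, p)))
  H <- (H + t(H)) / 2
  repaired <- FALSE
  ev <- eigen(H, symmetric = TRUE)
  if (any(ev$values <= 0)) {
    # nearest-SPD repair of the precision matrix
    vals <- pmax(ev$values, 1e-8 * max(abs(ev$values), 1))
    H <- ev$vectors %*% diag(vals, p, p) %*% t(ev$vectors)
    repaired <- TRUE
    warning("Hessian not positive definite at the mode; repaired to nearest SPD")
  }
  Sigma <- solve(H)
  Sigma <- (Sigma + t(Sigma)) / 2

  structure(
    list(mean = setNames(best$par, free_nm),
         cov = `dimnames<-`(Sigma, list(free_nm, free_nm)),
         converged = best$convergence == 0,
         n_iterations = unname(best$counts[1]),
         logpost = -best$value,
         order = as.integer(order),
         fixed = fixed,
         hessian_repaired = repaired),
    class = "parameter_posterior")
}

#' @export
print.parameter_posterior <- function(x, ...) {
  cat(sprintf("<parameter posterior, order %d, %d free parameters%s>\n",
              x$order, length(x$mean),
              if (x$converged) "" else ", NOT converged"))
  sds <- sqrt(pmax(diag(x$cov), 0))
  print(data.frame(mean = signif(x$mean, 4), sd = signif(sds, 4)))
  invisible(x)
}

# KL( N(mq, Sq) || N(mp, diag(vp)) ), closed form, in nats.
gaussian_kl <- function(mq, Sq, mp, vp) {
  p <- length(mq)
  tau <- 1 / vp
  quad <- sum(tau * (mq - mp)^2)
  tr <- sum(tau * diag(Sq))
  ldp <- sum(log(vp))
  ldq <- determinant(Sq, logarithm = TRUE)$modulus[1]
  0.5 * (tr + quad - p + ldp - ldq)
}

#' Variational free energy of a fitted model
#'
#' Decomposes the log-evidence approximation as accuracy minus complexity:
#' accuracy is the expected log-likelihood under the Gaussian posterior
#' (the plug-in log-likelihood at the posterior mean plus the second-order
#' curvature correction \eqn{\frac{1}{2}(tr(\Sigma_q \Pi_0) - d)}, which is
#' exact when the log-likelihood is quadratic), and complexity is the
#' Kullback-Leibler divergence from the prior to the posterior. The best
#' model accounts for the data accurately with minimal complexity, so extra
#' parameters only help if they buy accuracy; in the conjugate
#' linear-Gaussian case F coincides with the exact log evidence.
#'
#' @param posterior a `parameter_posterior` from [fit_map()] on the same
#'   data/order/priors.
#' @param data the `trajectory` it was fitted to.
#' @param order 1 or 2.
#' @param priors the [prior_spec()] used in the fit.
#' @return an `evidence_decomposition`: list with `F`, `accuracy`,
#'   `complexity` (nats) and `order`; `F = accuracy - complexity`.
#' @export
free_energy <- function(posterior, data, order, priors = NULL) {
  stopifnot(inherits(posterior, "parameter_posterior"))
  n <- ncol(data$observed)
  if (is.null(priors)) priors <- default_priors(order, n)
  free_nm <- names(posterior$mean)
  if (!all(free_nm %in% names(priors$mean)))
    stop("posterior and priors disagree on parameter names")
  full <- c(posterior$mean, posterior$fixed)
  ll_mean <- marginal_loglik(full[param_names(order, n)], data, order)
  tau0 <- 1 / priors$var[free_nm]
  # expected log-likelihood under q: plug-in value plus the Gaussian
  # curvature correction (the likelihood Hessian at the mode equals the
  # prior precision minus the joint precision, whose trace against the
  # posterior covariance is tr(Sigma Pi0) - d)
  acc <- ll_mean + 0.5 * (sum(tau0 * diag(posterior$cov)) - length(free_nm))
  cx <- gaussian_kl(posterior$mean, posterior$cov,
                    priors$mean[free_nm], priors$var[free_nm])
  cx <- max(cx, 0)  # KL is non-negative; clip tiny negative rounding
  structure(list(F = acc - cx, accuracy = acc, complexity = cx,
                 order = as.integer(order)),
            class = "evidence_decomposition")
}

#' @export
print.evidence_decomposition <- function(x, ...) {
  cat(sprintf("<order-%d evidence: F = %.3f (accuracy %.3f - complexity %.3f) nats>\n",
              x$order, x$F, x$accuracy, x$complexity))
  invisible(x)
}

#' Invert both model orders on one timeseries
#'
#' Runs [fit_map()] and [free_energy()] for the first- and second-order
#' models under matched priors and returns both evidence decompositions.
#'
#' @param data a `trajectory`.
#' @param priors optional named list with elements `order1`, `order2`
#'   ([prior_spec()]s); defaults to [default_priors()] per order.
#' @param opts [optimizer_options()].
#' @return list with elements `order1` and `order2`, each an
#'   `evidence_decomposition` with the fitted posterior attached as
#'   `$posterior`.
#' @export
invert_both_orders <- function(data, priors = NULL, opts = optimizer_options()) {
  n <- ncol(data$observed)
  pr1 <- if (!is.null(priors$order1)) priors$order1 else default_priors(1, n)
  pr2 <- if (!is.null(priors$order2)) priors$order2 else default_priors(2, n)
  out <- list()
  for (ord in 1:2) {
    pr <- if (ord == 1) pr1 else pr2
    post <- fit_map(data, ord, pr, opts)
    ed <- free_energy(post, data, ord, pr)
    ed$posterior <- post
    out[[paste0("order", ord)]] <- ed
  }
  out
}
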