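# Independent oracles used across the test files. These deliberately avoid
# the package's own filtering code path: the joint observation density is
# assembled densely and evaluated through a Cholesky factor.

# Exact one-step matrices for dx = (A x + B u) dt + dW, cov(dW) = Q dt.
oracle_discretize <- function(A, B, Q, dt) {
  m <- nrow(A)
  k <- ncol(B)
  E1 <- as.matrix(Matrix::expm(rbind(cbind(A, B), matrix(0, k, m + k)) * dt))
  E2 <- as.matrix(Matrix::expm(rbind(cbind(-A, Q),
                                     cbind(matrix(0, m, m), t(A))) * dt))
  Phi <- E1[1:m, 1:m, drop = FALSE]
  Qd <- Phi %*% E2[1:m, m + (1:m), drop = FALSE]
  list(Phi = Phi, Gamma = E1[1:m, m + (1:k), drop = FALSE],
       Qd = (Qd + t(Qd)) / 2)
}

# Full continuous-time system matrices for n decoupled regions of a given
# order (positions observed, noise and input on the highest derivative).
oracle_system <- function(order, a, c_gain, sigma_s, x0, xdot0 = NULL) {
  n <- length(a)
  sig2 <- rep_len(sigma_s^2, n)
  if (order == 1) {
    list(A = diag(a, n, n), B = diag(c_gain, n, n),
         Q = diag(sig2, n, n), x0 = x0, H = diag(n))
  } else {
    list(A = rbind(cbind(matrix(0, n, n), diag(n)),
                   cbind(diag(a, n, n), matrix(0, n, n))),
         B = rbind(matrix(0, n, n), diag(c_gain, n, n)),
         Q = diag(c(rep(0, n), sig2), 2 * n, 2 * n),
         x0 = c(x0, xdot0), H = cbind(diag(n), matrix(0, n, n)))
  }
}

# Brute-force marginal log-likelihood: assemble the T*n-dimensional joint
# Gaussian over the observations and evaluate its log-density directly.
oracle_dense_loglik <- function(order, a, c_gain, x0, xdot0 = NULL,
                                sigma_s, sigma_o, dt, y, v) {
  sys <- oracle_system(order, a, c_gain, sigma_s, x0, xdot0)
  d <- oracle_discretize(sys$A, sys$B, sys$Q, dt)
  Tn <- nrow(y)
  n <- ncol(y)
  m <- nrow(sys$A)

  # latent means
  mu <- matrix(0, Tn, m)
  mu[1, ] <- sys$x0
  for (t in seq_len(Tn - 1)) {
    mu[t + 1, ] <- d$Phi %*% mu[t, ] + d$Gamma %*% v[t, ]
  }
  # powers of Phi
  pows <- vector("list", Tn)
  pows[[1]] <- diag(m)
  for (k in 2:Tn) pows[[k]] <- d$Phi %*% pows[[k - 1]]
  # latent covariance blocks: x_1 deterministic, noise w_k enters x_{k+1}
  covlat <- function(s, t) {
    out <- matrix(0, m, m)
    kmax <- min(s, t) - 1
    if (kmax >= 1) {
      for (k in seq_len(kmax)) {
        out <- out + pows[[s - k]] %*% d$Qd %*% t(pows[[t - k]])
      }
    }
    out
  }
  S <- matrix(0, Tn * n, Tn * n)
  for (s in seq_len(Tn)) {
    for (t in seq_len(Tn)) {
      blk <- sys$H %*% covlat(s, t) %*% t(sys$H)
      if (s == t) blk <- blk + diag(sigma_o^2, n, n)
      S[(s - 1) * n + (1:n), (t - 1) * n + (1:n)] <- blk
    }
  }
  S <- (S + t(S)) / 2
  yvec <- as.numeric(t(y))
  muvec <- as.numeric(t(mu %*% t(sys$H)))
  ch <- chol(S)
  z <- backsolve(ch, yvec - muvec, transpose = TRUE)
  -0.5 * (length(yvec) * log(2 * pi) + sum(z^2)) - sum(log(diag(ch)))
}

# Independent construction of the diffusion operator used by the embedding
# (row sparsification, cosine affinity, alpha normalization, symmetric
# normalization), written against base R only.
oracle_diffusion_operator <- function(fc, sparsity = 0.9, alpha = 0.5) {
  r <- nrow(fc)
  A <- fc
  diag(A) <- 0
  for (i in 1:r) {
    thr <- stats::quantile(A[i, ], probs = sparsity, names = FALSE)
    A[i, ][A[i, ] < thr] <- 0
  }
  W <- matrix(0, r, r)
  for (i in 1:r) {
    for (j in 1:r) {
      den <- sqrt(sum(A[i, ]^2)) * sqrt(sum(A[j, ]^2))
      W[i, j] <- if (den > 0) sum(A[i, ] * A[j, ]) / den else 0
    }
  }
  W[W < 0] <- 0
  diag(W) <- 1
  d <- rowSums(W)
  W <- W / (outer(d, d)^alpha)
  d2 <- rowSums(W)
  M <- diag(1 / sqrt(d2)) %*% W %*% diag(1 / sqrt(d2))
  (M + t(M)) / 2
}

# A quick synthetic subject series for inversion tests (small T, strong
# signal) without going through the cohort machinery.
quick_series <- function(order, n = 2, n_timepoints = 200, tr = 0.72,
                         seed = 1L) {
  draw <- sample_random_model(order, n, seed = seed)
  simulate_model(draw$model, duration = (n_timepoints - 1) * tr, dt = tr,
                 input_spec = draw$input_spec, seed = seed + 5000L)
}

# Named parameter vector in the package's ordering.
named_theta <- function(order, a, c_gain, x0, xdot0 = NULL,
                        lambda_state = 0, lambda_obs = 0) {
  n <- length(a)
  th <- c(a, c_gain, x0, if (order == 2) xdot0, lambda_state, lambda_obs)
  names(th) <- c(paste0("a_", 1:n), paste0("c_", 1:n), paste0("x0_", 1:n),
                 if (order == 2) paste0("xdot0_", 1:n),
                 "lambda_state", "lambda_obs")
  th
}
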