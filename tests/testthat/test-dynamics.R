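test_that("zero dynamics leave the state constant", {
  m <- first_order_model(a = c(0, 0, 0), x0 = c(1, 1, 1))
  traj <- simulate_model(m, duration = 20, dt = 1, seed = 1)
  expect_true(all(traj$observed == 1))
})

test_that("noise-free first-order decay matches the exponential closed form", {
  m <- first_order_model(a = -1, x0 = 1)
  traj <- simulate_model(m, duration = 5, dt = 0.1, seed = 1)
  expect_lt(max(abs(traj$observed[, 1] - exp(-traj$times))), 1e-10)
})

test_that("noise-free undamped second-order motion matches the cosine closed form", {
  m <- second_order_model(a = -1, x0 = 1, xdot0 = 0)
  traj <- simulate_model(m, duration = 12, dt = 0.05, seed = 1)
  expect_lt(max(abs(traj$observed[, 1] - cos(traj$times))), 1e-8)
})

test_that("long-run sample variance matches the OU stationary variance", {
  # dx = -x dt + dW has stationary variance sigma^2 / (2|a|) = 1/2
  m <- first_order_model(a = -1, sigma_state = 1, x0 = 0)
  traj <- simulate_model(m, duration = 2000, dt = 0.5, seed = 42)
  burn <- traj$observed[traj$times > 20, 1]
  expect_equal(var(burn), 0.5, tolerance = 0.15)
})

test_that("companion form has the right structure and eigenvalues", {
  m <- second_order_model(a = -1)
  cf <- companion_form(m)
  expect_equal(cf$drift, rbind(c(0, 1), c(-1, 0)))
  expect_equal(sort(Im(eigen(cf$drift)$values)), c(-1, 1))

  m4 <- second_order_model(a = -4)
  expect_equal(sort(Im(eigen(companion_form(m4)$drift)$values)), c(-2, 2))

  # noise enters the velocity block only
  m2 <- second_order_model(a = c(-1, -2), sigma_state = c(0.3, 0.4))
  cf2 <- companion_form(m2)
  expect_equal(diag(cf2$noise_cov), c(0, 0, 0.09, 0.16))
})

test_that("second-order simulation equals its companion-form embedding sample-for-sample", {
  m <- second_order_model(a = c(-0.5, -1.2), c = c(0.6, 0.3),
                          sigma_state = c(0.2, 0.1), sigma_obs = 0.05,
                          x0 = c(1, -0.5), xdot0 = c(0, 0.4))
  ispec <- input_boxcar(onsets = c(5, 30), durations = 10)
  times <- seq(0, 60, by = 0.5)
  v <- make_input(ispec, times, 2)
  direct <- simulate_model(m, duration = 60, dt = 0.5, input_spec = ispec,
                           seed = 7)
  cf <- companion_form(m)
  emb <- orderstates:::simulate_lds(cf$drift, cf$input_matrix, cf$noise_cov,
                                    cf$x0_aug, cf$obs_matrix, m$sigma_obs,
                                    times, v, seed = 7)
  expect_identical(direct$observed, emb$observed)
  expect_identical(direct$latent, emb$latent)
})

test_that("noise-free companion integration matches an independent exponential-map oracle", {
  m <- second_order_model(a = c(-0.7, -2), x0 = c(1, 0.3), xdot0 = c(-0.2, 1))
  traj <- simulate_model(m, duration = 30, dt = 0.3, seed = 1)
  sys <- oracle_system(2, m$a, m$c, m$sigma_state, m$x0, m$xdot0)
  d <- oracle_discretize(sys$A, sys$B, sys$Q, 0.3)
  x <- sys$x0
  for (t in seq_len(nrow(traj$observed) - 1)) {
    x <- d$Phi %*% x
    expect_lt(max(abs(traj$latent[t + 1, ] - x)), 1e-10)
  }
})

test_that("discretization is exact, not Euler", {
  d <- discretize_lds(matrix(-1), matrix(1), matrix(0), dt = 0.5)
  expect_equal(d$Phi[1, 1], exp(-0.5), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(d$Phi[1, 1], 0.5, tolerance = 0.01)))
  # Van Loan noise integral for the scalar OU: sigma^2 (1 - e^{-2 dt}) / 2
  d2 <- discretize_lds(matrix(-1), matrix(0, 1, 1), matrix(4), dt = 0.5)
  expect_equal(d2$Qd[1, 1], 4 * (1 - exp(-1)) / 2, tolerance = 1e-10)
})

test_that("the noise-free response is linear in the input amplitude", {
  m <- first_order_model(a = c(-0.5, -1), c = c(1, 0.7))
  base <- simulate_model(m, 40, 0.5, input_none(), seed = 1)$observed
  one <- simulate_model(m, 40, 0.5, input_boxcar(5, 10, amplitude = 1), seed = 1)$observed
  three <- simulate_model(m, 40, 0.5, input_boxcar(5, 10, amplitude = 3), seed = 1)$observed
  expect_equal(three - base, 3 * (one - base), tolerance = 1e-10)
})

test_that("simulation is deterministic in the seed", {
  m <- first_order_model(a = c(-0.5, -1), sigma_state = c(0.3, 0.2),
                         sigma_obs = 0.1)
  t1 <- simulate_model(m, 50, 0.72, seed = 11)
  t2 <- simulate_model(m, 50, 0.72, seed = 11)
  t3 <- simulate_model(m, 50, 0.72, seed = 12)
  expect_identical(t1$observed, t2$observed)
  expect_false(identical(t1$observed, t3$observed))
})

test_that("input construction matches its specifications", {
  times <- 0:29
  expect_equal(make_input(input_none(), times, 3), matrix(0, 30, 3))

  v <- make_input(input_boxcar(onsets = 10, durations = 5), times, 2)
  expect_equal(which(v[, 1] == 1), 11:15)  # t = 10..14
  expect_true(all(v[-(11:15), ] == 0))
  expect_identical(v[, 1], v[, 2])

  spec <- input_random_boxcar(rate = 0.05, duration = 5, seed = 9)
  va <- make_input(spec, times, 3)
  vb <- make_input(spec, times, 3)
  expect_identical(va, vb)

  bad <- structure(list(kind = "sine"), class = "input_spec")
  expect_error(make_input(bad, times, 1), "unknown input spec")
})

test_that("invalid simulation configurations are rejected", {
  m <- first_order_model(a = -1)
  expect_error(simulate_model(m, duration = 10, dt = 0), "dt")
  expect_error(simulate_model(m, duration = 0.5, dt = 1), "duration")
  expect_error(simulate_model(m, duration = 5, dt = 1), "10 samples")
  expect_error(first_order_model(a = NaN), "non-finite")
  expect_error(first_order_model(a = -1, sigma_state = -0.1), "non-negative")
  expect_error(second_order_model(a = c(-1, -2), x0 = c(0, 0, 0)), "length")
})

test_that("trajectories round-trip through the TSV writer", {
  m <- second_order_model(a = c(-0.5, -1), c = c(0.5, 0.2),
                          sigma_state = c(0.1, 0.1), sigma_obs = 0.05,
                          x0 = c(1, 0), xdot0 = c(0, 1))
  traj <- simulate_model(m, 30, 0.72, input_boxcar(5, 8), seed = 3)
  path <- file.path(tempdir(), "traj.tsv")
  write_trajectory(traj, path)
  expect_true(file.exists(file.path(tempdir(), "traj_inputs.tsv")))
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_trajectory(path)
  expect_equal(back$times, traj$times)
  expect_equal(unname(back$observed), unname(traj$observed), tolerance = 1e-12)
  expect_equal(unname(back$inputs), unname(traj$inputs), tolerance = 1e-12)
  expect_equal(back$meta$order, 2)
})
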