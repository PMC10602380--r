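#' First-order linear stochastic model
#'
#' A system of decoupled regions whose future is determined by the present:
#' \eqn{\dot x_i = a_{ii} x_i + c_{ii} v_i + \omega_i}. Each region is
#' coupled only to itself (diagonal Jacobian) and driven by its own external
#' input in the presence of state noise \eqn{\omega} and additive
#' observation noise.
#'
#' @param a numeric vector of self-coupling rates \eqn{a_{ii}} (1/s);
#'   negative values give stable (decaying) dynamics.
#' @param c numeric vector of input gains \eqn{c_{ii}} (dimensionless).
#' @param sigma_state state-noise standard deviation per region
#'   (signal units per \eqn{\sqrt{s}}); scalar recycled.
#' @param sigma_obs observation-noise standard deviation (signal units),
#'   a single value.
#' @param x0 initial state per region (signal units).
#' @return an object of class `first_order_model`.
#' @export
first_order_model <- function(a, c = 0, sigma_state = 0, sigma_obs = 0,
                              x0 = 0) {
  n <- length(a)
  m <- structure(
    list(n_regions = n,
         a = as.numeric(a),
         c = fit_len(c, n, "c"),
         sigma_state = fit_len(sigma_state, n, "sigma_state"),
         sigma_obs = as.numeric(sigma_obs)[1],
         x0 = fit_len(x0, n, "x0"),
         order = 1L),
    class = c("first_order_model", "linear_model"))
  validate_model(m)
  m
}

# scalars broadcast; anything else must match n_regions exactly
fit_len <- function(v, n, what) {
  if (length(v) == 1) return(rep(as.numeric(v), n))
  if (length(v) != n) stop(what, " must have length 1 or n_regions")
  as.numeric(v)
}

#' Second-order linear stochastic model
#'
#' Same structure as [first_order_model()] but second-order in time:
#' \eqn{\ddot x_i = a_{ii} x_i + c_{ii} v_i + \omega_i}. There is no damping
#' (\eqn{\dot x}) term, so with \eqn{a_{ii} < 0} each region is an undamped
#' stochastic oscillator of angular frequency \eqn{\sqrt{-a_{ii}}}. The state
#' of a region is now (position, velocity), so the model carries initial
#' velocities `xdot0` as extra parameters.
#'
#' @inheritParams first_order_model
#' @param xdot0 initial first derivative per region (signal units / s).
#' @return an object of class `second_order_model`.
#' @export
second_order_model <- function(a, c = 0, sigma_state = 0, sigma_obs = 0,
                               x0 = 0, xdot0 = 0) {
  n <- length(a)
  m <- structure(
    list(n_regions = n,
         a = as.numeric(a),
         c = fit_len(c, n, "c"),
         sigma_state = fit_len(sigma_state, n, "sigma_state"),
         sigma_obs = as.numeric(sigma_obs)[1],
         x0 = fit_len(x0, n, "x0"),
         xdot0 = fit_len(xdot0, n, "xdot0"),
         order = 2L),
    class = c("second_order_model", "linear_model"))
  validate_model(m)
  m
}

validate_model <- function(m) {
  n <- m$n_regions
  stopifnot(n >= 1)
  lens <- c(length(m$a), length(m$c), length(m$sigma_state), length(m$x0))
  if (m$order == 2L) lens <- c(lens, length(m$xdot0))
  if (any(lens != n)) stop("model parameter vectors must all have length n_regions")
  vals <- c(m$a, m$c, m$sigma_state, m$sigma_obs, m$x0,
            if (m$order == 2L) m$xdot0)
  if (any(!is.finite(vals))) stop("non-finite model parameters")
  if (any(m$sigma_state < 0) || m$sigma_obs < 0)
    stop("noise standard deviations must be non-negative")
  invisible(m)
}

#' @export
print.linear_model <- function(x, ...) {
  cat(sprintf("<%s-order linear stochastic model, %d region%s>\n",
              if (x$order == 1L) "first" else "second",
              x$n_regions, if (x$n_regions == 1L) "" else "s"))
  cat("  a:           ", paste(signif(x$a, 4), collapse = " "), "\n")
  cat("  c:           ", paste(signif(x$c, 4), collapse = " "), "\n")
  cat("  sigma_state: ", paste(signif(x$sigma_state, 4), collapse = " "), "\n")
  cat("  sigma_obs:   ", signif(x$sigma_obs, 4), "\n")
  invisible(x)
}

#' Companion (first-order augmented) form of a second-order model
#'
#' Rewrites the n-region second-order system as a 2n-dimensional first-order
#' system over positions then velocities. The drift is the block companion
#' matrix \eqn{[[0, I], [diag(a), 0]]}; inputs and state noise enter the
#' velocity block only; only positions are observed.
#'
#' @param model a [second_order_model()].
#' @return list with `drift` (2n x 2n), `input_matrix` (2n x n),
#'   `noise_cov` (2n x 2n), `x0_aug` (length 2n), and `obs_matrix` (n x 2n).
#' @export
companion_form <- function(model) {
  stopifnot(inherits(model, "second_order_model"))
  n <- model$n_regions
  drift <- rbind(cbind(matrix(0, n, n), diag(n)),
                 cbind(diag(model$a, n, n), matrix(0, n, n)))
  input_matrix <- rbind(matrix(0, n, n), diag(model$c, n, n))
  noise_cov <- diag(c(rep(0, n), model$sigma_state^2), 2 * n, 2 * n)
  list(drift = drift,
       input_matrix = input_matrix,
       noise_cov = noise_cov,
       x0_aug = c(model$x0, model$xdot0),
       obs_matrix = cbind(diag(n), matrix(0, n, n)))
}

# Continuous-time system matrices (drift, input, noise cov, initial state,
# observation matrix) for either model order.
model_matrices <- function(model) {
  n <- model$n_regions
  if (model$order == 1L) {
    list(drift = diag(model$a, n, n),
         input_matrix = diag(model$c, n, n),
         noise_cov = diag(model$sigma_state^2, n, n),
         x0_aug = model$x0,
         obs_matrix = diag(n))
  } else {
    companion_form(model)
  }
}

#' Exact discretization of a linear stochastic system
#'
#' For \eqn{dx = (A x + B u)\,dt + dW}, \eqn{cov(dW) = Q\,dt}, returns the
#' one-step transition under a zero-order hold on the input:
#' `Phi = expm(A dt)`, `Gamma = int_0^dt expm(A s) ds B`, and the integrated
#' (Van Loan) process-noise covariance `Qd`. Exact for the linear drift, so
#' the discretization introduces no step-size bias.
#'
#' @param A drift matrix (m x m).
#' @param B input matrix (m x k).
#' @param Q continuous-time noise covariance (m x m).
#' @param dt step, seconds.
#' @return list with matrices `Phi` (m x m), `Gamma` (m x k), `Qd` (m x m).
#' @export
discretize_lds <- function(A, B, Q, dt) {
  stopifnot(dt > 0)
  m <- nrow(A)
  k <- ncol(B)
  aug <- rbind(cbind(A, B), matrix(0, k, m + k))
  E1 <- as.matrix(Matrix::expm(aug * dt))
  Phi <- E1[seq_len(m), seq_len(m), drop = FALSE]
  Gamma <- E1[seq_len(m), m + seq_len(k), drop = FALSE]
  vl <- rbind(cbind(-A, Q), cbind(matrix(0, m, m), t(A)))
  E2 <- as.matrix(Matrix::expm(vl * dt))
  Qd <- Phi %*% E2[seq_len(m), m + seq_len(m), drop = FALSE]
  Qd <- (Qd + t(Qd)) / 2
  list(Phi = Phi, Gamma = Gamma, Qd = Qd)
}

#' Input (driving signal) specifications
#'
#' Constructors for the external input \eqn{v(t)}: no input, a deterministic
#' boxcar train (shared across regions, e.g. a task block design), or
#' per-region random boxcar bursts (Poisson onsets).
#'
#' @param onsets,durations boxcar onsets and durations, seconds (recycled
#'   against each other).
#' @param amplitude boxcar height.
#' @param rate expected burst onset rate, events per second per region.
#' @param duration burst duration, seconds.
#' @param seed integer seed making the random train reproducible.
#' @return an `input_spec` object for [make_input()].
#' @export
input_none <- function() {
  structure(list(kind = "none"), class = "input_spec")
}

#' @rdname input_none
#' @export
input_boxcar <- function(onsets, durations, amplitude = 1) {
  k <- max(length(onsets), length(durations))
  structure(list(kind = "boxcar",
                 onsets = rep_len(as.numeric(onsets), k),
                 durations = rep_len(as.numeric(durations), k),
                 amplitude = amplitude),
            class = "input_spec")
}

#' @rdname input_none
#' @export
input_random_boxcar <- function(rate, duration, amplitude = 1, seed = 1L) {
  stopifnot(rate > 0, duration > 0)
  structure(list(kind = "random_boxcar", rate = rate, duration = duration,
                 amplitude = amplitude, seed = as.integer(seed)),
            class = "input_spec")
}

#' Evaluate an input specification on a time grid
#'
#' @param spec an `input_spec` from [input_none()], [input_boxcar()] or
#'   [input_random_boxcar()].
#' @param times numeric vector of sample times, seconds.
#' @param n_regions number of regions (columns of the returned matrix).
#' @return a `length(times) x n_regions` matrix of input values.
#' @export
make_input <- function(spec, times, n_regions) {
  if (!inherits(spec, "input_spec")) stop("spec must be an input_spec")
  nt <- length(times)
  v <- matrix(0, nt, n_regions)
  if (spec$kind == "none") return(v)
  if (spec$kind == "boxcar") {
    on <- rep(FALSE, nt)
    for (j in seq_along(spec$onsets)) {
      on <- on | (times >= spec$onsets[j] &
                    times < spec$onsets[j] + spec$durations[j])
    }
    v[on, ] <- spec$amplitude
    return(v)
  }
  if (spec$kind == "random_boxcar") {
    span <- max(times) - min(times)
    with_seed(spec$seed, {
      for (i in seq_len(n_regions)) {
        n_events <- stats::rpois(1, spec$rate * span)
        if (n_events > 0) {
          onsets <- min(times) + sort(runif(n_events, 0, span))
          for (o in onsets) {
            v[times >= o & times < o + spec$duration, i] <- spec$amplitude
          }
        }
      }
    })
    return(v)
  }
  stop("unknown input spec kind: ", spec$kind)
}

#' Simulate a linear stochastic model
#'
#' Simulates either model order on a uniform time grid. Second-order models
#' are first rewritten in companion form so both orders share one
#' integrator. Discretization is exact for the linear drift (matrix
#' exponential transition + Van Loan integrated noise covariance), so the
#' sampled trajectory has no step-size bias; the input is held constant
#' within each step. Observation noise is added independently per sample.
#' The same (model, duration, dt, input, seed) always reproduces the same
#' trajectory bit-for-bit.
#'
#' @param model a [first_order_model()] or [second_order_model()].
#' @param duration total simulated time, seconds.
#' @param dt sample interval, seconds.
#' @param input_spec an `input_spec`; default none.
#' @param seed integer seed for state and observation noise.
#' @return a `trajectory` object: list with `times`, `inputs` (T x n),
#'   `latent` (T x m state dim), `observed` (T x n), `meta`.
#' @export
simulate_model <- function(model, duration, dt, input_spec = input_none(),
                           seed = 1L) {
  validate_model(model)
  if (dt <= 0) stop("dt must be positive")
  if (duration <= dt) stop("duration must exceed dt")
  times <- seq(0, duration, by = dt)
  if (length(times) < 10) stop("duration/dt must give at least 10 samples")
  mats <- model_matrices(model)
  v <- make_input(input_spec, times, model$n_regions)
  sim <- simulate_lds(mats$drift, mats$input_matrix, mats$noise_cov,
                      mats$x0_aug, mats$obs_matrix, model$sigma_obs,
                      times, v, seed)
  new_trajectory(times, v, sim$latent, sim$observed,
                 meta = list(order = model$order, seed = as.integer(seed),
                             dt = dt, model = unclass(model)))
}

# Generic exact-discretization simulator over explicit system matrices.
# Noise draws: T-1 standard-normal vectors for the state (mapped through a
# symmetric square root of Qd), then T x n for the observations.
simulate_lds <- function(A, B, Q, x0, H, sigma_obs, times, v, seed) {
  nt <- length(times)
  m <- nrow(A)
  n <- nrow(H)
  dt <- times[2] - times[1]
  d <- discretize_lds(A, B, Q, dt)
  # symmetric PSD square root (Qd may be singular, e.g. noise-free runs)
  e <- eigen(d$Qd, symmetric = TRUE)
  sqrtQ <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), m, m) %*% t(e$vectors)
  X <- matrix(0, nt, m)
  X[1, ] <- x0
  with_seed(seed, {
    zs <- matrix(rnorm((nt - 1) * m), nt - 1, m)
    zo <- matrix(rnorm(nt * n), nt, n)
    for (t in seq_len(nt - 1)) {
      X[t + 1, ] <- d$Phi %*% X[t, ] + d$Gamma %*% v[t, ] + sqrtQ %*% zs[t, ]
    }
  })
  Y <- X %*% t(H) + sigma_obs * zo
  list(latent = X, observed = Y)
}

new_trajectory <- function(times, inputs, latent, observed, meta = NULL) {
  dts <- diff(times)
  if (any(dts <= 0)) stop("times must be strictly increasing")
  if (max(abs(dts - dts[1])) > 1e-9 * dts[1])
    stop("times must be uniformly spaced")
  structure(list(times = as.numeric(times), inputs = inputs, latent = latent,
                 observed = observed, meta = meta),
            class = "trajectory")
}

#' Construct a trajectory from observed data
#'
#' Wraps an observed multivariate timeseries (and optionally the known
#' driving input) so it can be passed to the inversion routines.
#'
#' @param times sample times, seconds (uniform grid).
#' @param observed T x n matrix of observed signals.
#' @param inputs optional T x n matrix of known driving inputs; zeros if
#'   omitted.
#' @return a `trajectory` object.
#' @export
as_trajectory <- function(times, observed, inputs = NULL) {
  observed <- as.matrix(observed)
  if (is.null(inputs)) inputs <- matrix(0, nrow(observed), ncol(observed))
  inputs <- as.matrix(inputs)
  stopifnot(length(times) == nrow(observed),
            nrow(inputs) == nrow(observed),
            ncol(inputs) == ncol(observed))
  new_trajectory(times, inputs, latent = NULL, observed = observed)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d samples x %d regions, dt = %.4g s>\n",
              nrow(x$observed), ncol(x$observed),
              x$times[2] - x$times[1]))
  if (!is.null(x$meta$order))
    cat(sprintf("  simulated from an order-%d model (seed %d)\n",
                x$meta$order, x$meta$seed))
  invisible(x)
}

#' Write / read a trajectory as tab-separated text
#'
#' The observed series goes to `<path>` with columns `time_s`,
#' `region_1..region_n`; the inputs to `<path>` with suffix `_inputs` before
#' the extension; metadata (order, seed, parameters) to a JSON sidecar
#' `<path>.json`.
#'
#' @param traj a `trajectory`.
#' @param path output TSV path for the observed series.
#' @export
write_trajectory <- function(traj, path) {
  n <- ncol(traj$observed)
  df <- data.frame(time_s = traj$times, traj$observed)
  names(df) <- c("time_s", paste0("region_", seq_len(n)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  dfv <- data.frame(time_s = traj$times, traj$inputs)
  names(dfv) <- c("time_s", paste0("region_", seq_len(n)))
  write.table(dfv, sibling_path(path, "_inputs"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(traj$meta)) {
    jsonlite::write_json(traj$meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @param path TSV path previously written by [write_trajectory()] (or any
#'   file in that layout).
#' @export
read_trajectory <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  vpath <- sibling_path(path, "_inputs")
  inputs <- NULL
  if (file.exists(vpath)) {
    dfv <- read.delim(vpath, check.names = FALSE)
    inputs <- as.matrix(dfv[, -1, drop = FALSE])
  }
  traj <- as_trajectory(df$time_s, as.matrix(df[, -1, drop = FALSE]), inputs)
  jpath <- paste0(path, ".json")
  if (file.exists(jpath)) traj$meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  traj
}

sibling_path <- function(path, suffix) {
  sub("(\\.[^./\\\\]+)?$", paste0(suffix, "\\1"), path, perl = TRUE)
  # note: keeps extension, e.g. ts.tsv -> ts_inputs.tsv
}
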