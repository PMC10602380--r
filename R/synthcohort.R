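#' Draw a randomized linear model of a given order
#'
#' Samples the internal (self-)couplings, external gains, noise magnitudes,
#' initial conditions and a random driving-input train for one synthetic
#' subject. Self-couplings are drawn negative so the dynamics never explode:
#' Uniform(-1.0, -0.2) per second for first-order (decay),
#' Uniform(-1.0, -0.1) per second squared for second-order (undamped
#' oscillation at 0.3-1 rad/s). Gains are Uniform(0.2, 1.0); state- and
#' observation-noise SDs Uniform(0.05, 0.3); initial conditions
#' Uniform(-1, 1). The driving input is a per-region random boxcar train
#' (Poisson onsets).
#'
#' @param order 1 or 2.
#' @param n number of regions (the study's toy systems use 3).
#' @param seed integer seed; same seed, same model and input.
#' @return list with `model` (a [first_order_model()] or
#'   [second_order_model()]) and `input_spec` (an `input_spec`).
#' @export
sample_random_model <- function(order, n = 3, seed = 1L) {
  if (!order %in% c(1, 2)) stop("order must be 1 or 2")
  with_seed(seed, {
    a <- if (order == 1) runif(n, -1.0, -0.2) else runif(n, -1.0, -0.1)
    cc <- runif(n, 0.2, 1.0)
    ss <- runif(n, 0.05, 0.3)
    so <- runif(1, 0.05, 0.3)
    x0 <- runif(n, -1, 1)
    xd0 <- runif(n, -1, 1)
    ispec <- input_random_boxcar(rate = 1 / 40, duration = 10, amplitude = 1,
                                 seed = derive_seed(seed, 1L))
    model <- if (order == 1) {
      first_order_model(a, cc, ss, so, x0)
    } else {
      second_order_model(a, cc, ss, so, x0, xd0)
    }
    list(model = model, input_spec = ispec)
  })
}

#' Cohort specification for the synthetic-subject generator
#'
#' Describes a cohort emulating parcellated fMRI data: each subject has
#' low-dimensional latent dynamics of known order (living directly in
#' gradient space), projected onto orthonormal spatial maps over
#' `n_regions` regions, plus spatial Gaussian noise. Defaults mirror a
#' typical resting-state acquisition: 100 regions, 400 timepoints at
#' TR = 0.72 s.
#'
#' @param n_subjects number of subjects.
#' @param n_regions number of parcellated regions.
#' @param n_timepoints samples per subject.
#' @param tr sampling interval, seconds.
#' @param n_gradients latent dimensionality (gradient count).
#' @param order_mix fraction of subjects generated with second-order
#'   dynamics (the rest are first-order).
#' @param condition "rest" (no shared input) or "task" (shared block-design
#'   boxcar input: 27.5 s blocks separated by 15 s baselines).
#' @param spatial_noise_sd SD of the spatial Gaussian noise added to every
#'   region and timepoint.
#' @param seed master seed; per-subject seeds are derived from it.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 10, n_regions = 100, n_timepoints = 400,
                        tr = 0.72, n_gradients = 3, order_mix = 0.5,
                        condition = c("rest", "task"),
                        spatial_noise_sd = 0.1, seed = 1L) {
  condition <- match.arg(condition)
  stopifnot(n_subjects >= 1, n_regions >= 2, n_timepoints >= 10,
            tr > 0, n_gradients >= 1, n_gradients < n_regions,
            order_mix >= 0, order_mix <= 1, spatial_noise_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_regions = as.integer(n_regions),
                 n_timepoints = as.integer(n_timepoints),
                 tr = tr, n_gradients = as.integer(n_gradients),
                 order_mix = order_mix, condition = condition,
                 spatial_noise_sd = spatial_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Mutually orthogonal loading maps over regions, also orthogonal to the
# constant map so per-timepoint Pearson correlation with a loading recovers
# the matching latent coordinate up to a per-frame scale. Columns are
# scaled to norm sqrt(n_regions) (unit RMS per region), putting the maps in
# the same signal units as a normalized regional timeseries.
synthetic_gradient_loadings <- function(n_regions, n_gradients, seed) {
  with_seed(seed, {
    G <- matrix(rnorm(n_regions * (n_gradients + 1)), n_regions)
    G[, 1] <- 1
    Q <- qr.Q(qr(G))
    L <- Q[, -1, drop = FALSE]
    # fix signs deterministically
    s <- sign(L[1, ])
    s[s == 0] <- 1
    sweep(L, 2, s, `*`) * sqrt(n_regions)
  })
}

# Task block design: alternating active blocks and baselines, matching a
# working-memory block paradigm (27.5 s blocks, 15 s baselines).
task_input_spec <- function(duration, block_s = 27.5, baseline_s = 15) {
  onsets <- seq(baseline_s, duration, by = block_s + baseline_s)
  input_boxcar(onsets, rep(block_s, length(onsets)), amplitude = 1)
}

#' Generate one synthetic subject
#'
#' Draws a randomized model with `n_gradients` latent dimensions via
#' [sample_random_model()], simulates the latent trajectory, projects the
#' latent positions onto synthetic orthonormal gradient maps, and adds
#' spatial Gaussian noise. Resting subjects have no external drive — their
#' fluctuations are purely endogenous (state noise) — while "task"
#' subjects receive a shared block-design boxcar input on every latent
#' dimension.
#'
#' @param spec a [cohort_spec()].
#' @param true_order 1 or 2: the generating order.
#' @param seed subject seed.
#' @return a `synthetic_subject`: list with `region_ts` (time x region),
#'   `true_order`, `latent` (the generating gradient-space `trajectory`),
#'   `latent_scaled` (the standardized latent coordinates actually
#'   projected), `gradients_used` (region x gradient loadings), `seed`.
#' @export
make_subject <- function(spec, true_order, seed) {
  stopifnot(inherits(spec, "cohort_spec"), true_order %in% c(1, 2))
  g <- spec$n_gradients
  duration <- (spec$n_timepoints - 1) * spec$tr
  draw <- sample_random_model(true_order, n = g, seed = seed)
  ispec <- if (spec$condition == "task") task_input_spec(duration) else input_none()
  latent <- simulate_model(draw$model, duration, spec$tr, ispec,
                           seed = derive_seed(seed, 2L))
  L <- synthetic_gradient_loadings(spec$n_regions, g, derive_seed(seed, 3L))
  pos <- latent$latent[, seq_len(g), drop = FALSE]
  # standardize each latent coordinate (normalized dependent variables), so
  # spatial_noise_sd is expressed relative to unit signal amplitude
  sds <- apply(pos, 2, stats::sd)
  sds[sds < .Machine$double.eps] <- 1
  pos <- sweep(pos, 2, sds, `/`)
  noise <- with_seed(derive_seed(seed, 4L), {
    matrix(rnorm(spec$n_timepoints * spec$n_regions, 0, spec$spatial_noise_sd),
           spec$n_timepoints, spec$n_regions)
  })
  region_ts <- pos %*% t(L) + noise
  structure(list(region_ts = region_ts, true_order = as.integer(true_order),
                 latent = latent, latent_scaled = pos,
                 gradients_used = L, seed = as.integer(seed),
                 condition = spec$condition),
            class = "synthetic_subject")
}

#' Generate a synthetic cohort
#'
#' `n_subjects` independent subjects; the first
#' `round(order_mix * n_subjects)` are second-order and the rest
#' first-order (a deterministic split). Per-subject seeds are derived from
#' `spec$seed`, so an identical spec always reproduces the identical
#' cohort.
#'
#' @param spec a [cohort_spec()].
#' @return list of `synthetic_subject`s.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n2 <- round(spec$order_mix * spec$n_subjects)
  orders <- c(rep(2L, n2), rep(1L, spec$n_subjects - n2))
  lapply(seq_len(spec$n_subjects), function(i) {
    make_subject(spec, orders[i], derive_seed(spec$seed, i))
  })
}

#' Synthetic block-structured functional-connectivity matrix
#'
#' Stand-in for a group-average functional-connectivity matrix: a symmetric
#' block matrix (high within-community, low between-community connectivity)
#' with unit diagonal plus small symmetric Gaussian noise. Used to exercise
#' the diffusion embedding.
#'
#' @param n_regions matrix size.
#' @param n_blocks number of equal communities.
#' @param within,between connectivity inside / across communities
#'   (`within > between`).
#' @param noise_sd SD of the symmetric perturbation.
#' @param seed integer seed.
#' @return symmetric `n_regions x n_regions` matrix.
#' @export
make_fc_matrix <- function(n_regions = 100, n_blocks = 2, within = 0.9,
                           between = 0.1, noise_sd = 0.02, seed = 1L) {
  stopifnot(within > between, n_blocks >= 1, n_regions >= n_blocks)
  block <- rep(seq_len(n_blocks), length.out = n_regions)
  block <- sort(block)
  fc <- matrix(between, n_regions, n_regions)
  for (b in seq_len(n_blocks)) {
    idx <- which(block == b)
    fc[idx, idx] <- within
  }
  if (noise_sd > 0) {
    e <- with_seed(seed, matrix(rnorm(n_regions^2, 0, noise_sd), n_regions))
    fc <- fc + (e + t(e)) / 2
  }
  diag(fc) <- 1
  fc
}
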