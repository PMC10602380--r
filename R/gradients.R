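#' Diffusion-map embedding of a functional-connectivity matrix
#'
#' Builds low-dimensional "gradients" — continuous spatial axes of
#' connectivity similarity — from a symmetric region x region
#' functional-connectivity matrix. Each row is sparsified to its strongest
#' entries, a cosine-similarity affinity is computed between the sparsified
#' connectivity profiles, the affinity is alpha-normalized
#' (\eqn{W_{ij} / (d_i d_j)^\alpha}) to control the influence of sampling
#' density, and the symmetric normalized diffusion operator
#' \eqn{D^{-1/2} W D^{-1/2}} is eigendecomposed. The trivial stationary
#' component is dropped; the remaining eigenvectors (unit norm, mutually
#' orthogonal) are the gradients, ordered by eigenvalue, with
#' variance-explained fractions from the normalized non-trivial
#' eigenvalues.
#'
#' @param fc symmetric region x region matrix, finite entries.
#' @param n_components number of gradients to keep (`< nrow(fc)`).
#' @param sparsity per-row fraction of entries zeroed out before the
#'   affinity (0.9 keeps the top 10 percent per row).
#' @param alpha density-normalization exponent; 0.5 gives the
#'   Fokker-Planck normalization standard for connectivity gradients.
#' @return a `gradient_set`: list with `loadings` (region x gradient,
#'   unit-norm orthogonal columns), `variance_explained`, `eigenvalues`,
#'   `n_regions`, `n_gradients`.
#' @export
diffusion_embedding <- function(fc, n_components = 3, sparsity = 0.9,
                                alpha = 0.5) {
  fc <- as.matrix(fc)
  r <- nrow(fc)
  if (ncol(fc) != r) stop("fc must be square")
  if (any(!is.finite(fc))) stop("fc must be finite")
  if (max(abs(fc - t(fc))) > 1e-8) stop("fc must be symmetric (within 1e-8)")
  if (n_components >= r) stop("n_components must be < n_regions")
  stopifnot(sparsity >= 0, sparsity < 1)

  op <- diffusion_operator(fc, sparsity, alpha)
  e <- eigen(op, symmetric = TRUE)
  # first eigenvector (eigenvalue ~1) is the trivial stationary component
  keep <- 1 + seq_len(n_components)
  loadings <- e$vectors[, keep, drop = FALSE]
  # deterministic sign: largest-magnitude entry positive
  for (j in seq_len(ncol(loadings))) {
    k <- which.max(abs(loadings[, j]))
    if (loadings[k, j] < 0) loadings[, j] <- -loadings[, j]
  }
  lam <- e$values[-1]
  lam_pos <- pmax(lam, 0)
  ve <- lam_pos[seq_len(n_components)] / sum(lam_pos)
  structure(list(loadings = loadings,
                 variance_explained = ve,
                 eigenvalues = e$values[keep],
                 n_regions = r, n_gradients = as.integer(n_components)),
            class = "gradient_set")
}

# Symmetric normalized diffusion operator from an FC matrix: row-wise
# sparsification, cosine affinity (negatives clipped to 0), alpha
# normalization, then D^{-1/2} W D^{-1/2}.
diffusion_operator <- function(fc, sparsity, alpha) {
  r <- nrow(fc)
  A <- fc
  diag(A) <- 0
  for (i in seq_len(r)) {
    thr <- stats::quantile(A[i, ], probs = sparsity, names = FALSE, type = 7)
    A[i, A[i, ] < thr] <- 0
  }
  # cosine similarity between sparsified profiles
  nrm <- sqrt(rowSums(A^2))
  nrm[nrm == 0] <- 1
  W <- (A %*% t(A)) / outer(nrm, nrm)
  W[W < 0] <- 0
  diag(W) <- 1
  d <- rowSums(W)
  d[d == 0] <- 1
  W <- W / outer(d, d)^alpha
  d2 <- rowSums(W)
  d2[d2 == 0] <- 1
  M <- W / sqrt(outer(d2, d2))
  (M + t(M)) / 2
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("<gradient set: %d regions x %d gradients>\n",
              x$n_regions, x$n_gradients))
  cat("  variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$variance_explained), collapse = " "), "\n")
  invisible(x)
}

#' Project a region timeseries onto gradients
#'
#' For every timepoint, correlates the spatial activity map (one row of the
#' region timeseries) with each gradient's loading map (Pearson, i.e.
#' centered across regions). The result is a time x gradient matrix of
#' per-timepoint correlations (each between -1 and 1), describing the
#' extent to which
#' each timepoint expresses each gradient. Timepoints with zero spatial
#' variance map to 0 with a warning rather than an error.
#'
#' @param region_ts time x region matrix.
#' @param gradients a `gradient_set`, or a region x gradient loading
#'   matrix.
#' @return a `gradient_timeseries`: list with `values` (time x gradient),
#'   `shifted` flag (FALSE here), `condition` (NA).
#' @export
gradient_timeseries <- function(region_ts, gradients) {
  L <- if (inherits(gradients, "gradient_set")) gradients$loadings else as.matrix(gradients)
  region_ts <- as.matrix(region_ts)
  if (ncol(region_ts) != nrow(L))
    stop("region count mismatch between timeseries and gradients")
  r <- nrow(L)
  Xc <- region_ts - rowMeans(region_ts)
  sx <- sqrt(rowSums(Xc^2))
  degenerate <- sx < .Machine$double.eps * r
  if (any(degenerate)) {
    warning(sum(degenerate), " timepoint(s) with zero spatial variance mapped to 0")
    sx[degenerate] <- 1
  }
  Lc <- sweep(L, 2, colMeans(L))
  sl <- sqrt(colSums(Lc^2))
  vals <- (Xc %*% Lc) / outer(sx, sl)
  vals[degenerate, ] <- 0
  vals <- pmin(pmax(vals, -1), 1)
  structure(list(values = vals, shifted = FALSE, condition = NA_character_),
            class = "gradient_timeseries")
}

#' Circular-shift surrogate of a region timeseries
#'
#' Rotates each region's time course by an independent uniform random
#' integer offset. This preserves every region's power spectrum, mean,
#' variance and circular autocorrelation exactly (a rotation only permutes
#' samples) while destroying inter-regional temporal dependence — a null
#' model for analyses that rely on spatial structure across regions.
#'
#' @param region_ts time x region matrix (>= 2 timepoints).
#' @param seed integer seed; offsets are drawn uniformly from `0:(T-1)`.
#' @param offsets optional explicit integer offsets (length = regions),
#'   overriding the random draw (all zero gives the identity).
#' @return shifted matrix of the same shape, with the offsets attached as
#'   attribute `"offsets"`.
#' @export
circular_shift_null <- function(region_ts, seed = 1L, offsets = NULL) {
  region_ts <- as.matrix(region_ts)
  nt <- nrow(region_ts)
  nr <- ncol(region_ts)
  if (nt < 2) stop("need at least 2 timepoints")
  if (is.null(offsets)) {
    offsets <- with_seed(seed, sample.int(nt, nr, replace = TRUE) - 1L)
  }
  stopifnot(length(offsets) == nr)
  offsets <- as.integer(offsets %% nt)
  out <- region_ts
  for (i in seq_len(nr)) {
    k <- offsets[i]
    if (k > 0) out[, i] <- region_ts[c((nt - k + 1):nt, 1:(nt - k)), i]
  }
  attr(out, "offsets") <- offsets
  out
}

#' Sample autocorrelation function
#'
#' Standard biased-normalized sample ACF (covariances divided by the lag-0
#' covariance with the 1/T normalization), so `acf[lag 0] = 1`.
#'
#' @param series univariate numeric series (length > `max_lag`).
#' @param max_lag largest lag, in samples.
#' @return numeric vector of length `max_lag + 1` (lags 0..max_lag).
#' @export
acf_curve <- function(series, max_lag) {
  series <- as.numeric(series)
  if (length(series) <= max_lag) stop("series must be longer than max_lag")
  if (stats::sd(series) == 0) stop("autocorrelation undefined for a constant series")
  a <- stats::acf(series, lag.max = max_lag, plot = FALSE, demean = TRUE)
  as.numeric(a$acf)
}

#' Group-average autocorrelation curves
#'
#' Averages each subject's per-gradient ACF over gradients, then averages
#' those curves over subjects within each model-order group. The study's
#' key contrast: subjects better described by second-order models carry
#' consistently higher autocorrelation than first-order subjects.
#'
#' @param subjects list of entries, each a list with `gradient_ts` (a
#'   `gradient_timeseries` or plain time x gradient matrix) and `winner`
#'   (1 or 2).
#' @param max_lag largest lag, in samples.
#' @return list with elements `order1` and `order2` (mean ACF per lag,
#'   `NULL` with a warning if a group is empty), `lags`, and per-group
#'   subject counts `n`.
#' @export
group_acf <- function(subjects, max_lag) {
  winners <- vapply(subjects, function(s) as.integer(s$winner), integer(1))
  per_subject <- lapply(subjects, function(s) {
    v <- if (inherits(s$gradient_ts, "gradient_timeseries")) s$gradient_ts$values else as.matrix(s$gradient_ts)
    curves <- apply(v, 2, acf_curve, max_lag = max_lag)
    rowMeans(curves)
  })
  out <- list(lags = 0:max_lag, n = c(order1 = sum(winners == 1L),
                                      order2 = sum(winners == 2L)))
  for (g in 1:2) {
    idx <- which(winners == g)
    nm <- paste0("order", g)
    if (length(idx) == 0) {
      warning("no subjects in group ", nm, "; its curve is absent")
      out[[nm]] <- NULL
    } else {
      out[[nm]] <- rowMeans(do.call(cbind, per_subject[idx]))
    }
  }
  out
}
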