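#' Posterior model probabilities from free energies
#'
#' Two-model softmax over free energies: under equal model priors the
#' posterior probability of the first-order model is the logistic function
#' of the evidence difference, `p1 = 1 / (1 + exp(F2 - F1))`.
#'
#' @param F1,F2 free energies (nats) of the first- and second-order models.
#' @return named numeric vector `c(p1 = , p2 = )`, summing to 1.
#' @export
posterior_model_probability <- function(F1, F2) {
  if (!is.finite(F1) || !is.finite(F2)) stop("free energies must be finite")
  p1 <- 1 / (1 + exp(F2 - F1))
  c(p1 = p1, p2 = 1 - p1)
}

# Tie rule: within 1e-9 nats the first-order (more parsimonious) model wins.
pick_winner <- function(F1, F2, tol = 1e-9) {
  if (abs(F1 - F2) <= tol) {
    attr(tol, "tie") <- TRUE
    return(structure(1L, tie = TRUE))
  }
  structure(if (F1 > F2) 1L else 2L, tie = FALSE)
}

#' Classify one subject as first- or second-order
#'
#' Inverts both model orders on the subject's timeseries, converts the
#' free energies to posterior model probabilities, and records the winner
#' (higher F; exact ties go to the more parsimonious first-order model).
#'
#' @param data a `trajectory`.
#' @param priors,opts passed to [invert_both_orders()].
#' @param subject_id,condition labels carried into the result.
#' @param n_gradients optional integer recorded alongside (how many
#'   gradient dimensions the series has), `NA` if not applicable.
#' @return a `comparison_result`: list with `subject_id`, `condition`,
#'   `F1`, `F2`, `p1`, `p2`, `winner`, `tie`, `n_gradients`, `evidence`.
#' @export
classify_subject <- function(data, priors = NULL, opts = optimizer_options(),
                             subject_id = "subject", condition = "rest",
                             n_gradients = NA_integer_) {
  ev <- invert_both_orders(data, priors, opts)
  F1 <- ev$order1$F
  F2 <- ev$order2$F
  p <- posterior_model_probability(F1, F2)
  w <- pick_winner(F1, F2)
  structure(list(subject_id = subject_id, condition = condition,
                 F1 = F1, F2 = F2, p1 = unname(p["p1"]), p2 = unname(p["p2"]),
                 winner = as.integer(w), tie = isTRUE(attr(w, "tie")),
                 n_gradients = n_gradients, evidence = ev),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s [%s]: F1 = %.2f, F2 = %.2f -> order %d (p = %.3f)%s>\n",
              x$subject_id, x$condition, x$F1, x$F2, x$winner,
              max(x$p1, x$p2), if (x$tie) " [tie]" else ""))
  invisible(x)
}

#' Summarize a cohort of model comparisons
#'
#' Counts how many subjects are better described by first- vs second-order
#' models and the corresponding proportions.
#'
#' @param results list of `comparison_result`s (uniform condition).
#' @param condition condition label; defaults to the first result's.
#' @param n_gradients gradient count label; defaults to the first result's.
#' @return a `cohort_summary`: one-row data.frame with `condition`,
#'   `n_gradients`, `n_subjects`, `n_first`, `n_second`, `prop_first`,
#'   `prop_second`.
#' @export
summarize_cohort <- function(results, condition = NULL, n_gradients = NULL) {
  if (length(results) == 0) stop("results must be non-empty")
  winners <- vapply(results, function(r) r$winner, integer(1))
  conds <- vapply(results, function(r) r$condition, character(1))
  if (is.null(condition)) condition <- conds[1]
  if (!all(conds == condition)) stop("results mix conditions")
  if (is.null(n_gradients)) n_gradients <- results[[1]]$n_gradients
  n <- length(winners)
  n1 <- sum(winners == 1L)
  out <- data.frame(condition = condition,
                    n_gradients = as.integer(n_gradients),
                    n_subjects = n, n_first = n1, n_second = n - n1,
                    prop_first = n1 / n, prop_second = (n - n1) / n)
  class(out) <- c("cohort_summary", class(out))
  out
}
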