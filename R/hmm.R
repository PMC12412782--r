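# Two-state Gaussian hidden Markov model, fitted with Baum-Welch (scaled
# forward-backward) and decoded with Viterbi. State 1 is the low-mean
# (polymerase-depleted) state, state 2 the high-mean (occupied) state.

#' Default HMM parameter seed
#'
#' State means at the 25th/75th percentiles of the data (falling back to
#' the data range when those coincide, as they do for strongly unbalanced
#' two-level signals), a common variance equal to the overall variance
#' (floored), sticky transitions (0.9/0.1) and uniform initial
#' probabilities.
#'
#' @param values Numeric observation vector.
#' @param var_floor Lower bound on emission variances (default 1e-6).
#' @return An `hmm_params` list.
#' @export
hmm_init <- function(values, var_floor = 1e-6) {
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  if (abs(q[2] - q[1]) < 1e-12) q <- range(values)
  v <- max(stats::var(values) * (length(values) - 1) / length(values),
           var_floor)
  structure(list(means = q, variances = c(v, v),
                 transition_matrix = matrix(c(0.9, 0.1, 0.1, 0.9), 2L, 2L,
                                            byrow = TRUE),
                 initial_probs = c(0.5, 0.5),
                 log_likelihood = -Inf, n_iterations = 0L,
                 converged = FALSE),
            class = "hmm_params")
}

# Scaled forward-backward. Returns per-position scaled alpha/beta, the
# scaling factors, state posteriors gamma, pairwise posteriors xi (as a
# (L-1) x 4 matrix), and the log-likelihood.
forward_backward <- function(values, params) {
  L <- length(values)
  A <- params$transition_matrix
  em <- cbind(stats::dnorm(values, params$means[1],
                           sqrt(params$variances[1])),
              stats::dnorm(values, params$means[2],
                           sqrt(params$variances[2])))
  em <- pmax(em, 1e-300)
  alpha <- matrix(0, L, 2L); beta <- matrix(0, L, 2L); cs <- numeric(L)
  a <- params$initial_probs * em[1L, ]
  cs[1L] <- sum(a); alpha[1L, ] <- a / cs[1L]
  for (t in seq.int(2L, L)) {
    a <- (alpha[t - 1L, ] %*% A) * em[t, ]
    cs[t] <- sum(a); alpha[t, ] <- a / cs[t]
  }
  beta[L, ] <- 1
  for (t in seq.int(L - 1L, 1L)) {
    b <- A %*% (em[t + 1L, ] * beta[t + 1L, ])
    beta[t, ] <- b / cs[t + 1L]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi <- matrix(0, L - 1L, 4L)
  for (t in seq_len(L - 1L)) {
    x <- (alpha[t, ] %o% (em[t + 1L, ] * beta[t + 1L, ])) * A / cs[t + 1L]
    xi[t, ] <- as.vector(x)
  }
  list(alpha = alpha, beta = beta, scale = cs, gamma = gamma, xi = xi,
       log_likelihood = sum(log(cs)))
}

#' Fit the two-state Gaussian HMM by Baum-Welch
#'
#' EM iterations run until the log-likelihood improves by less than `tol`
#' or `max_iter` is reached; the scaled forward-backward recursion keeps
#' the computation stable on long vectors. On return states are relabeled
#' so that `means[1] <= means[2]`. An input with zero spread cannot
#' identify two emission components: the fit is flagged `converged =
#' FALSE` and callers treat the gene as a no-call.
#'
#' @param values Numeric vector, length at least 4.
#' @param init Parameter seed, by default [hmm_init()].
#' @param tol Log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations (default 1000).
#' @param var_floor Lower bound on emission variances (default 1e-6).
#' @return An `hmm_params` object with `means`, `variances`,
#'   `transition_matrix`, `initial_probs`, `log_likelihood`,
#'   `log_likelihood_trace`, `n_iterations`, `converged`.
#' @export
baum_welch <- function(values, init = NULL, tol = 1e-6, max_iter = 1000,
                       var_floor = 1e-6) {
  stopifnot(length(values) >= 4L, all(is.finite(values)))
  if (max(values) == min(values)) {
    out <- hmm_init(values, var_floor)
    out$converged <- FALSE
    out$degenerate <- TRUE
    return(out)
  }
  p <- if (is.null(init)) hmm_init(values, var_floor) else init
  ll_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    fb <- forward_backward(values, p)
    trace <- c(trace, fb$log_likelihood)
    if (is.finite(ll_prev) && fb$log_likelihood - ll_prev < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    # M-step
    g <- fb$gamma
    denom <- colSums(g)
    mu <- colSums(g * values) / denom
    va <- pmax(colSums(g * (outer(values, mu, "-")^2)) / denom, var_floor)
    xs <- colSums(fb$xi)                       # order: a11, a21, a12, a22
    A <- matrix(c(xs[1], xs[3], xs[2], xs[4]), 2L, 2L, byrow = TRUE)
    A <- A / rowSums(A)
    p$means <- mu; p$variances <- va
    p$transition_matrix <- A
    p$initial_probs <- g[1L, ] / sum(g[1L, ])
    ll_prev <- fb$log_likelihood
    it <- it + 1L
  }
  p$log_likelihood <- trace[length(trace)]
  p$log_likelihood_trace <- trace
  p$n_iterations <- it
  p$converged <- converged
  p$degenerate <- FALSE
  # canonical state order: state 1 = lower mean
  if (p$means[1] > p$means[2]) {
    sw <- c(2L, 1L)
    p$means <- p$means[sw]; p$variances <- p$variances[sw]
    p$transition_matrix <- p$transition_matrix[sw, sw]
    p$initial_probs <- p$initial_probs[sw]
  }
  p
}

#' Viterbi decoding of the two-state Gaussian HMM
#'
#' @param values Numeric observation vector.
#' @param params An `hmm_params` object (see [baum_welch()]).
#' @return Integer vector of most-probable states (1 = low mean,
#'   2 = high mean).
#' @export
viterbi <- function(values, params) {
  L <- length(values)
  logem <- cbind(stats::dnorm(values, params$means[1],
                              sqrt(params$variances[1]), log = TRUE),
                 stats::dnorm(values, params$means[2],
                              sqrt(params$variances[2]), log = TRUE))
  logA <- log(pmax(params$transition_matrix, 1e-300))
  delta <- matrix(-Inf, L, 2L); back <- matrix(1L, L, 2L)
  delta[1L, ] <- log(pmax(params$initial_probs, 1e-300)) + logem[1L, ]
  if (L > 1L) for (t in seq.int(2L, L)) {
    for (j in 1:2) {
      cand <- delta[t - 1L, ] + logA[, j]
      back[t, j] <- which.max(cand)
      delta[t, j] <- cand[back[t, j]] + logem[t, j]
    }
  }
  path <- integer(L)
  path[L] <- which.max(delta[L, ])
  if (L > 1L) for (t in seq.int(L - 1L, 1L)) path[t] <- back[t + 1L,
                                                             path[t + 1L]]
  path
}

#' HMM-based transition pointer
#'
#' Fits the two-state model, decodes the state path, and reports the last
#' index of the leading depleted-state (state 1) block, so that segments
#' `[1..p]` and `[p+1..L]` align with the split-scan semantics. The call
#' is invalid when the fit is degenerate, the path does not start in the
#' depleted state, or no switch to the occupied state occurs.
#'
#' @param values Numeric vector, length at least 4.
#' @param ... Passed to [baum_welch()].
#' @return List with `pointer` (integer or `NA`), `valid` (logical),
#'   `params`, `path`.
#' @export
hmm_transition_point <- function(values, ...) {
  fit <- baum_welch(values, ...)
  if (isTRUE(fit$degenerate))
    return(list(pointer = NA_integer_, valid = FALSE, params = fit,
                path = NULL))
  path <- viterbi(values, fit)
  valid <- path[1L] == 1L && any(path == 2L)
  pointer <- if (valid) which(path == 2L)[1L] - 1L else NA_integer_
  list(pointer = pointer, valid = valid, params = fit, path = path)
}
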