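#' Emission matrix of the binned-heterozygosity HMM
#'
#' For hidden TMRCA `t` (interval representative time) and per-bin scaled
#' mutation rate `theta`: `P(HOM | t) = exp(-theta * t)`,
#' `P(HET | t) = 1 - exp(-theta * t)`, and `P(MISSING | t) = 1` (a missing
#' bin is uninformative).
#'
#' @param theta Positive per-bin scaled mutation rate.
#' @param grid A [time_grid()].
#' @param representatives Optional representative times; defaults to the
#'   grid's unit-size representatives. [hmm_matrices()] passes
#'   model-dependent representatives.
#' @return `n_intervals x 3` matrix with columns `HOM`, `HET`, `MISSING`.
#' @export
emission_matrix <- function(theta, grid, representatives = grid$representatives) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0)
    stop("`theta` must be a positive scalar", call. = FALSE)
  hom <- pmax(exp(-theta * representatives), PROB_FLOOR)
  cbind(HOM = hom, HET = pmax(1 - hom, PROB_FLOOR),
        MISSING = rep(1, length(hom)))
}

# Smallest probability kept in HMM matrices. Entries below this are raised
# to it (and rows renormalized). Tiny matrix entries propagate into the
# scaled forward variables, whose products then fall into subnormal range
# and make every forward-backward multiplication pay the hardware denormal
# penalty; with a floor f the scaled variables stay above ~f^2/n, safely
# normal. Entries at 1e-40 carry no usable likelihood signal.
PROB_FLOOR <- 1e-40

floor_rows <- function(Q) {
  Q <- Q / rowSums(Q)
  if (any(Q < PROB_FLOOR)) {
    Q[Q < PROB_FLOOR] <- PROB_FLOOR
    Q <- Q / rowSums(Q)
  }
  Q
}

# Renormalized q matrix under a single size history (rows sum to 1).
q_single_matrix <- function(lam, grid, representatives = NULL) {
  if (is.null(representatives))
    representatives <- interval_representatives(grid, lam)
  floor_rows(q_kernel_cpp(lam, representatives, grid$boundaries))
}

#' Single-population conditional transition probability
#'
#' The probability, given a recombination event on the branch, that the TMRCA
#' moves from source interval `s_index` to destination interval `t_index`
#' under one piecewise-constant size history `lam`. Computed by
#' piecewise-analytic integration of the coalescent kernel over the grid and
#' row-normalized.
#'
#' @param s_index,t_index Interval indices in `1:n_intervals`.
#' @param lam Per-interval relative sizes (length `n_intervals`).
#' @param grid A [time_grid()].
#' @param representatives Optional source times; defaults to the conditional
#'   means under `lam`.
#' @return A probability.
#' @export
q_single <- function(s_index, t_index, lam, grid, representatives = NULL) {
  n <- grid$n_intervals
  stopifnot(s_index >= 1, s_index <= n, t_index >= 1, t_index <= n)
  if (length(lam) == 1L) lam <- rep(lam, n)
  q_single_matrix(lam, grid, representatives)[s_index, t_index]
}

# Full admixture-aware q' matrix (renormalized rows).
# Case split on the admixture boundary index k (intervals 1..k at/below t_a):
#   t above t_a            -> single-population kernel with lambda_a
#   t at/below t_a < s     -> q_a + q_b - 2 q_a q_b (recombination resolved in
#                             exactly one of the two source populations)
#   both at/below t_a      -> single-population kernel with the merged size
#                             lambda' = (1 + c) * lambda_a
q_admix_matrix <- function(model, representatives = NULL) {
  grid <- model$grid
  n <- grid$n_intervals
  k <- model$t_a_index
  lam_a <- lambda_a_intervals(model)
  c_ <- model$admix_ratio
  if (is.null(representatives))
    representatives <- interval_representatives(grid, lambda_prime(model))
  if (k == 0L || c_ <= 0) {
    return(floor_rows(q_kernel_cpp(lam_a, representatives, grid$boundaries)))
  }
  Qa <- q_kernel_cpp(lam_a, representatives, grid$boundaries)
  Qm <- q_kernel_cpp(lambda_prime(model), representatives, grid$boundaries)
  below <- seq_len(k)
  Q <- Qa
  if (k < n) {
    above <- (k + 1L):n
    Qb <- q_kernel_cpp(c_ * lam_a, representatives, grid$boundaries)
    # rows from above t_a, destinations at/below: one-of-two-populations rule
    qa <- Qa[above, below, drop = FALSE]
    qb <- Qb[above, below, drop = FALSE]
    Q[above, below] <- qa + qb - 2 * qa * qb
  }
  # rows at/below t_a, destinations at/below: merged population
  Q[below, below] <- Qm[below, below]
  floor_rows(Q)
}

#' Admixture-aware conditional transition probability
#'
#' Three-case kernel for the TMRCA move given a recombination event:
#' destination above the admixture time uses the focal-population kernel;
#' destination at/below `t_a` with source above uses
#' `q_a + q_b - 2 q_a q_b`; source and destination both at/below `t_a` use the
#' merged-population kernel with `lambda' = (1 + c) lambda_a`.
#'
#' @param s_index,t_index Interval indices in `1:n_intervals`.
#' @param model An [admixture_model()].
#' @return A probability (after row normalization over destinations).
#' @export
q_admix <- function(s_index, t_index, model) {
  n <- model$grid$n_intervals
  stopifnot(s_index >= 1, s_index <= n, t_index >= 1, t_index <= n)
  q_admix_matrix(model)[s_index, t_index]
}

#' Full HMM transition matrix
#'
#' Mixes the recombination-conditional kernel with the no-recombination
#' self-transition: `p'(t | s) = (1 - exp(-rho * s)) q'(t | s) +
#' exp(-rho * s) delta(t, s)`, with `s` the representative time of the source
#' interval and `delta` the Kronecker delta on interval indices. Rows of `q'`
#' are renormalized before mixing, so every row sums to 1.
#'
#' @param model An [admixture_model()].
#' @param representatives Optional representative times.
#' @return `n x n` row-stochastic matrix.
#' @export
transition_matrix <- function(model, representatives = NULL) {
  if (is.null(representatives))
    representatives <- interval_representatives(model$grid, lambda_prime(model))
  qn <- q_admix_matrix(model, representatives)
  stay <- exp(-model$rho * representatives)
  P <- (1 - stay) * qn
  diag(P) <- diag(P) + stay
  P
}

#' Initial (stationary coalescent) distribution on TMRCA intervals
#'
#' The probability that two lineages coalesce in each interval under the
#' pure-death coalescent with rate `1 / lambda'(t)`:
#' `pi_i = S(b_i) - S(b_{i+1})` with survival
#' `S(t) = exp(-integral_0^t dv / lambda'(v))`; the last interval takes the
#' remaining tail mass.
#'
#' @param model An [admixture_model()].
#' @return Probability vector of length `n_intervals`, summing to 1.
#' @export
initial_distribution <- function(model) {
  grid <- model$grid
  n <- grid$n_intervals
  lamp <- lambda_prime(model)
  len <- diff(grid$boundaries)
  haz <- cumsum(len[seq_len(n - 1L)] / lamp[seq_len(n - 1L)])
  surv <- c(1, exp(-haz)) # S at boundaries 0..n-1
  pi_ <- c(-diff(surv), surv[n])
  pi_ / sum(pi_)
}

#' Bundle all HMM matrices for a model
#'
#' Recomputes interval representatives under the model's combined size
#' history `lambda'`, then builds the emission matrix, the admixture-aware
#' transition matrix and the initial distribution.
#'
#' @param model An [admixture_model()].
#' @return An `hmm_matrices` object: list with `emission`, `transition`,
#'   `initial`, `representatives`, `grid`.
#' @export
hmm_matrices <- function(model) {
  reps <- interval_representatives(model$grid, lambda_prime(model))
  structure(
    list(emission = emission_matrix(model$theta, model$grid, reps),
         transition = transition_matrix(model, reps),
         initial = initial_distribution(model),
         representatives = reps,
         grid = model$grid),
    class = "hmm_matrices")
}

# Coerce a ternary sequence (or raw integer/character codes) to 0/1/2 ints.
obs_codes <- function(obs) {
  if (inherits(obs, "ternary_sequence")) return(unclass(obs)$codes)
  if (is.character(obs) && length(obs) == 1L)
    obs <- strsplit(obs, "")[[1]]
  if (is.character(obs)) {
    codes <- c("0" = 0L, "1" = 1L, "." = 2L)[obs]
    if (anyNA(codes)) stop("unknown observation symbol", call. = FALSE)
    return(unname(codes))
  }
  if (is.numeric(obs)) {
    codes <- as.integer(obs)
    if (any(is.na(codes) | codes < 0L | codes > 2L))
      stop("integer observations must be 0 (HOM), 1 (HET) or 2 (MISSING)",
           call. = FALSE)
    return(codes)
  }
  stop("cannot interpret observations", call. = FALSE)
}

#' Forward-backward inference over one ternary sequence
#'
#' Scaled forward-backward returning the log-likelihood, the per-bin
#' posterior over TMRCA intervals, and the pooled sufficient statistics that
#' the EM M-step consumes (expected transition counts, expected per-state
#' HET/HOM emission counts, position-1 posterior).
#'
#' @param obs A [ternary_sequence()], a `"01."` string, or an integer vector
#'   of codes 0/1/2.
#' @param matrices An [hmm_matrices()] bundle.
#' @param want_posterior Keep the full `L x n` posterior matrix? Set `FALSE`
#'   for long sequences when only the statistics are needed.
#' @return List with `loglik`, `posterior` (or `NULL`), `trans_counts`
#'   (`n x n`), `het_counts`, `hom_counts`, `init_counts`.
#' @export
forward_backward <- function(obs, matrices, want_posterior = TRUE) {
  stopifnot(inherits(matrices, "hmm_matrices"))
  codes <- obs_codes(obs)
  if (length(codes) == 0L) stop("empty observation sequence", call. = FALSE)
  fb_cpp(codes, matrices$emission, matrices$transition, matrices$initial,
         want_posterior)
}

#' Posterior decoding of the TMRCA track
#'
#' Marginal maximum a posteriori state per bin (the argmax of the
#' forward-backward posterior), with ties broken toward the more recent
#' (smaller) interval.
#'
#' @inheritParams forward_backward
#' @return Integer vector of interval indices (1-based), one per bin.
#' @export
posterior_decode <- function(obs, matrices) {
  fb <- forward_backward(obs, matrices, want_posterior = TRUE)
  max.col(fb$posterior, ties.method = "first")
}
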