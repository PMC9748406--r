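#' Discretize coalescent time into atomic intervals with grouped parameters
#'
#' Builds the discrete TMRCA state space of the hidden Markov model: `n`
#' atomic intervals on a log-uniform grid of coalescent time (units of
#' `2 * N0` generations), plus a PSMC-style free-parameter grouping pattern
#' that ties the relative population size of neighbouring intervals together.
#'
#' Boundaries follow `t_i = 0.1 * (exp((i/n) * log(1 + 10 * t_max)) - 1)`,
#' so `t_0 = 0` and `t_n = t_max`; the last interval is treated as unbounded
#' during integration. The pattern string uses the PSMC syntax: terms
#' separated by `+`, each either a plain count (one group of that many
#' intervals) or `g*k` (`g` groups of `k` intervals each). The default
#' `"4+25*2+4+6"` yields 64 intervals in 28 groups.
#'
#' @param n_intervals Number of atomic time intervals (>= 2).
#' @param t_max Last finite boundary, in coalescent units.
#' @param pattern Free-parameter grouping string.
#'
#' @return A `time_grid` object: a list with `n_intervals`, `boundaries`
#'   (length `n + 1`), `representatives` (one interior time per interval,
#'   computed under a constant unit population size; model-dependent
#'   representatives are recomputed by [hmm_matrices()]), `pattern`,
#'   `group_map` (interval -> group index), and `n_groups`.
#'
#' @examples
#' g <- time_grid(64, 15, "4+25*2+4+6")
#' g$n_groups # 28
#' @export
time_grid <- function(n_intervals = 64L, t_max = 15, pattern = "4+25*2+4+6") {
  n_intervals <- as.integer(n_intervals)
  if (is.na(n_intervals) || n_intervals < 2L)
    stop("`n_intervals` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(t_max) || t_max <= 0)
    stop("`t_max` must be positive", call. = FALSE)
  group_map <- parse_pattern(pattern)
  if (length(group_map) != n_intervals)
    stop(sprintf(
      "pattern '%s' implies %d atomic intervals but `n_intervals` is %d",
      pattern, length(group_map), n_intervals), call. = FALSE)
  i <- seq(0L, n_intervals)
  boundaries <- 0.1 * (exp((i / n_intervals) * log(1 + 10 * t_max)) - 1)
  boundaries[1] <- 0
  boundaries[n_intervals + 1] <- t_max
  grid <- structure(
    list(n_intervals = n_intervals,
         boundaries = boundaries,
         representatives = NULL,
         pattern = pattern,
         group_map = group_map,
         n_groups = max(group_map),
         t_max = t_max),
    class = "time_grid")
  grid$representatives <- interval_representatives(grid, rep(1, n_intervals))
  grid
}

#' Expand a PSMC-style grouping pattern
#'
#' @param pattern Pattern string, e.g. `"4+25*2+4+6"`.
#' @return Integer vector mapping each atomic interval to its group index.
#' @keywords internal
parse_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    stop("`pattern` must be a single non-empty string", call. = FALSE)
  terms <- strsplit(pattern, "+", fixed = TRUE)[[1]]
  sizes <- integer(0)
  for (term in terms) {
    if (grepl("*", term, fixed = TRUE)) {
      gk <- strsplit(term, "*", fixed = TRUE)[[1]]
      if (length(gk) != 2L) stop("malformed pattern term: ", term, call. = FALSE)
      g <- suppressWarnings(as.integer(gk[1]))
      k <- suppressWarnings(as.integer(gk[2]))
      if (is.na(g) || is.na(k) || g < 1L || k < 1L)
        stop("malformed pattern term: ", term, call. = FALSE)
      sizes <- c(sizes, rep(k, g))
    } else {
      k <- suppressWarnings(as.integer(term))
      if (is.na(k) || k < 1L) stop("malformed pattern term: ", term, call. = FALSE)
      sizes <- c(sizes, k)
    }
  }
  rep(seq_along(sizes), sizes)
}

#' Interval representative times under a piecewise-constant size history
#'
#' The representative of a bounded interval is the conditional mean coalescent
#' time given coalescence in that interval (truncated-exponential mean under
#' the interval's hazard `1/lambda`); the unbounded last interval uses the
#' fallback `t_max + 1`.
#'
#' @param grid A [time_grid()].
#' @param lam Per-interval relative sizes (length `n_intervals`).
#' @return Numeric vector of length `n_intervals`, each strictly inside its
#'   interval.
#' @keywords internal
interval_representatives <- function(grid, lam) {
  n <- grid$n_intervals
  b <- grid$boundaries
  a <- b[seq_len(n)]
  len <- diff(b)
  reps <- numeric(n)
  j <- seq_len(n - 1L)
  x <- len[j] / lam[j]
  reps[j] <- a[j] + lam[j] - len[j] / expm1(x)
  # guard against catastrophic cancellation for very short intervals
  tiny <- x < 1e-8
  reps[j][tiny] <- (a[j][tiny] + b[j + 1L][tiny]) / 2
  reps[n] <- grid$t_max + 1
  reps
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf(
    "<time_grid> %d intervals, %d lambda groups (pattern %s), t_max = %g (coalescent units)\n",
    x$n_intervals, x$n_groups, x$pattern, x$t_max))
  invisible(x)
}
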