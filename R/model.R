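#' Construct an admixture-aware demographic model
#'
#' The full parameter vector of the HMM: per-bin scaled mutation and
#' recombination rates, a piecewise-constant relative size history
#' `lambda_a(t)` for the focal population P1 (one free value per grid group),
#' the size ratio `c` of the admixed population P2 (`lambda_b(t) =
#' c * lambda_a(t)` at or below the admixture time), and the admixture time
#' `t_a` itself, restricted to a grid boundary and stored as a boundary index
#' (`0` = no admixture).
#'
#' @param theta Scaled mutation rate per bin (`4 * N0 * mu * bin_size`), > 0.
#' @param rho Scaled recombination rate per bin, > 0.
#' @param lambda_a Relative sizes of P1, either one value per group or a
#'   scalar recycled to all groups. All > 0.
#' @param admix_ratio Nonnegative scalar `c` with `lambda_b = c * lambda_a`.
#' @param t_a_index Integer in `0:n_intervals`; the admixture time is the
#'   grid boundary with that index (0-based), so intervals `1..t_a_index`
#'   lie at or below `t_a`.
#' @param grid A [time_grid()].
#'
#' @return An `admixture_model` object.
#' @examples
#' g <- time_grid(8, 15, "8*1")
#' m <- admixture_model(theta = 1, rho = 0.2, lambda_a = 1,
#'                      admix_ratio = 1, t_a_index = 3, grid = g)
#' combined_lambda(m, 2) # 2: below t_a, lambda_a + lambda_b
#' combined_lambda(m, 5) # 1: above t_a
#' @export
admixture_model <- function(theta, rho, lambda_a, admix_ratio = 0,
                            t_a_index = 0L, grid = time_grid()) {
  stopifnot(inherits(grid, "time_grid"))
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0)
    stop("`theta` must be a positive scalar", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0)
    stop("`rho` must be a positive scalar", call. = FALSE)
  if (length(lambda_a) == 1L) lambda_a <- rep(lambda_a, grid$n_groups)
  if (length(lambda_a) != grid$n_groups)
    stop("`lambda_a` must have one value per grid group", call. = FALSE)
  if (any(lambda_a <= 0)) stop("all `lambda_a` must be > 0", call. = FALSE)
  if (!is.numeric(admix_ratio) || length(admix_ratio) != 1L || admix_ratio < 0)
    stop("`admix_ratio` must be a nonnegative scalar", call. = FALSE)
  t_a_index <- as.integer(t_a_index)
  if (is.na(t_a_index) || t_a_index < 0L || t_a_index > grid$n_intervals)
    stop("`t_a_index` must be a boundary index in 0:n_intervals", call. = FALSE)
  structure(
    list(theta = theta, rho = rho, lambda_a = as.numeric(lambda_a),
         admix_ratio = admix_ratio, t_a_index = t_a_index, grid = grid),
    class = "admixture_model")
}

#' Admixture time of a model, in coalescent units
#' @param model An [admixture_model()].
#' @return The grid boundary at `t_a_index` (0 when no admixture).
#' @export
t_a_coal <- function(model) {
  model$grid$boundaries[model$t_a_index + 1L]
}

#' Per-interval lambda_a of a model (groups expanded to atomic intervals)
#' @param model An [admixture_model()].
#' @return Numeric vector of length `n_intervals`.
#' @export
lambda_a_intervals <- function(model) {
  model$lambda_a[model$grid$group_map]
}

#' Combined relative effective population size
#'
#' The size history the data actually experiences: `lambda_a(t)` above the
#' admixture time and `lambda_a(t) + lambda_b(t)` at or below it, with
#' `lambda_b = admix_ratio * lambda_a`. Intervals are classified by index
#' against the admixture boundary, so moving `t_a` by one boundary changes
#' the result on exactly one atomic interval.
#'
#' @param model An [admixture_model()].
#' @param interval_index Interval index in `1:n_intervals`.
#' @return Positive scalar `lambda'` on that interval.
#' @export
combined_lambda <- function(model, interval_index) {
  n <- model$grid$n_intervals
  i <- as.integer(interval_index)
  if (any(is.na(i)) || any(i < 1L) || any(i > n))
    stop("`interval_index` out of bounds", call. = FALSE)
  lam <- lambda_a_intervals(model)
  below <- i <= model$t_a_index
  lam[i] * ifelse(below, 1 + model$admix_ratio, 1)
}

#' Per-interval combined size vector lambda'
#' @param model An [admixture_model()].
#' @return Numeric vector of length `n_intervals`.
#' @export
lambda_prime <- function(model) {
  n <- model$grid$n_intervals
  lam <- lambda_a_intervals(model)
  k <- model$t_a_index
  if (k > 0L) lam[seq_len(k)] <- lam[seq_len(k)] * (1 + model$admix_ratio)
  lam
}

#' @export
print.admixture_model <- function(x, ...) {
  cat(sprintf(
    "<admixture_model> theta = %.4g, rho = %.4g per bin; %d lambda groups\n",
    x$theta, x$rho, length(x$lambda_a)))
  if (x$t_a_index > 0L && x$admix_ratio > 0) {
    cat(sprintf("  admixture at boundary %d (t_a = %.4g coalescent units), size ratio c = %.3g\n",
                x$t_a_index, t_a_coal(x), x$admix_ratio))
  } else {
    cat("  no admixture (t_a = 0)\n")
  }
  invisible(x)
}
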