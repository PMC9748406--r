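THETA_BOUNDS <- c(1e-5, 50)
PHASE1_CAP <- 6L # most flat-size EM iterations before the size history opens
RHO_BOUNDS <- c(1e-6, 10)
LAMBDA_BOUNDS <- c(1e-3, 1e3)

#' EM fitting configuration
#'
#' @param max_iter Iteration cap (default 25).
#' @param tol Relative log-likelihood convergence threshold.
#' @param t_a_search Candidate admixture boundary indices (default all,
#'   `0:n_intervals`).
#' @param ratio_search Candidate values of the admixed-population size ratio
#'   `c`; a zero entry is equivalent to no admixture. Each M-step refines the
#'   best candidate with one golden-section pass.
#' @param penalty Expected complete-data log-likelihood gain required to
#'   introduce an admixture event over the no-admixture profile. The default
#'   `"auto"` calibrates it per fit by a parametric bootstrap: simulate
#'   `n_null` genomes of matching length from the no-admixture starting
#'   model and take the largest profile gain observed (floor 0.5), a
#'   Monte-Carlo test at level about `1/(n_null+1)`. A fixed numeric value
#'   may be supplied instead; note that information-criterion penalties
#'   keyed to the bin count overstate the effective sample size because
#'   neighbouring bins share TMRCA segments.
#' @param lambda_delay Minimum number of initial EM iterations during which
#'   the per-group size history is held at its flat starting value while
#'   `theta`, `rho` and the admixture pair are updated (the flat phase runs
#'   until the admixture pair stabilizes, at most 6 iterations). The
#'   admixture signature (a step in the combined size) would otherwise be
#'   absorbed by the free per-group sizes before the profile search has
#'   seen it; once the history is free, the likelihood is nearly flat in
#'   the admixture time.
#' @param seed Optional integer seeding the penalty calibration (and any
#'   other randomized step); defaults to 1 inside [smc_fit()].
#' @param n_null Number of bootstrap null genomes for `penalty = "auto"`.
#' @return A `fit_config` list.
#' @export
fit_config <- function(max_iter = 25L, tol = 1e-6, t_a_search = NULL,
                       ratio_search = c(0, 0.25, 1/3, 0.5, 1),
                       penalty = "auto", lambda_delay = 2L, seed = NULL,
                       n_null = 10L) {
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) stop("`max_iter` must be >= 1", call. = FALSE)
  if (!is.numeric(tol) || tol <= 0) stop("`tol` must be > 0", call. = FALSE)
  structure(list(max_iter = max_iter, tol = tol, t_a_search = t_a_search,
                 ratio_search = ratio_search, penalty = penalty,
                 lambda_delay = as.integer(lambda_delay), seed = seed,
                 n_null = as.integer(n_null)),
            class = "fit_config")
}

#' E-step: pooled sufficient statistics over one or more sequences
#'
#' Runs forward-backward under the current model on every sequence and pools
#' expected transition counts, expected per-state HET/HOM emission counts,
#' expected initial-state counts, and the total log-likelihood.
#'
#' @param obs_list A [ternary_sequence()] or list of them.
#' @param model An [admixture_model()].
#' @return An `em_stats` list.
#' @export
e_step <- function(obs_list, model) {
  if (inherits(obs_list, "ternary_sequence")) obs_list <- list(obs_list)
  mats <- hmm_matrices(model)
  n <- model$grid$n_intervals
  A <- matrix(0, n, n)
  het <- hom <- init <- numeric(n)
  ll <- 0
  n_bins <- 0L
  for (s in obs_list) {
    fb <- forward_backward(s, mats, want_posterior = FALSE)
    A <- A + fb$trans_counts
    het <- het + fb$het_counts
    hom <- hom + fb$hom_counts
    init <- init + fb$init_counts
    ll <- ll + fb$loglik
    n_bins <- n_bins + length(obs_codes(s))
  }
  structure(list(trans_counts = A, het_counts = het, hom_counts = hom,
                 init_counts = init, loglik = ll, n_bins = n_bins,
                 n_seq = length(obs_list)),
            class = "em_stats")
}

# Expected complete-data log-likelihood of a candidate model given E-step
# statistics (the EM surrogate objective; increasing it increases the true
# log-likelihood for a fixed discretization).
ecdll <- function(model, stats) {
  ecdll_cpp(model$lambda_a, model$grid$group_map, model$admix_ratio,
            model$t_a_index, model$theta, model$rho,
            model$grid$boundaries, model$grid$t_max,
            stats$trans_counts, stats$het_counts, stats$hom_counts,
            stats$init_counts)
}

# R reference implementation of the same objective, via the full matrix
# build; retained for cross-checking the compiled path.
ecdll_ref <- function(model, stats) {
  m <- hmm_matrices(model)
  sum(stats$trans_counts * log(pmax(m$transition, 1e-300))) +
    sum(stats$hom_counts * log(pmax(m$emission[, 1], 1e-300))) +
    sum(stats$het_counts * log(pmax(m$emission[, 2], 1e-300))) +
    sum(stats$init_counts * log(pmax(m$initial, 1e-300)))
}

set_model <- function(model, ...) {
  upd <- list(...)
  for (nm in names(upd)) model[[nm]] <- upd[[nm]]
  model
}

# Best (t_a boundary, ratio) pair by ECDLL over the candidate grid, with one
# golden-section refinement of the ratio at the best boundary.
profile_search <- function(cur, stats, ks, cs) {
  best_k <- 0L; best_c <- 0; best_val <- -Inf
  for (k in setdiff(ks, 0L)) {
    for (cc in cs) {
      v <- ecdll(set_model(cur, t_a_index = as.integer(k), admix_ratio = cc), stats)
      if (v > best_val) { best_val <- v; best_k <- as.integer(k); best_c <- cc }
    }
  }
  if (best_k > 0L) {
    f_c <- function(cc) ecdll(set_model(cur, t_a_index = best_k, admix_ratio = cc), stats)
    ref <- optimize(f_c, lower = max(1e-3, best_c / 2.5),
                    upper = min(4, best_c * 2.5), maximum = TRUE, tol = 5e-3)
    if (ref$objective > best_val) { best_val <- ref$objective; best_c <- ref$maximum }
  }
  list(k = best_k, c = best_c, val = best_val)
}

# Parametric-bootstrap calibration of the admixture-introduction penalty:
# the largest profile gain seen on `n_null` genomes simulated from the
# no-admixture starting model, floored at 0.5.
calibrate_penalty <- function(model0, n_bins, config) {
  mats <- hmm_matrices(model0)
  ks <- config$t_a_search
  if (is.null(ks)) ks <- 0:model0$grid$n_intervals
  cs <- setdiff(config$ratio_search, 0)
  gains <- vapply(seq_len(config$n_null), function(i) {
    codes <- sample_hmm_obs(mats, n_bins)
    stats <- e_step(list(ternary_sequence(codes)), model0)
    base <- ecdll(model0, stats)
    prof <- profile_search(model0, stats, ks, cs)
    max(0, prof$val - base)
  }, numeric(1))
  max(0.5, max(gains))
}

#' M-step: update all parameters from sufficient statistics
#'
#' Coordinate ascent on the expected complete-data log-likelihood (ECDLL):
#' `theta` and `rho` by bounded one-dimensional optimization; the admixture
#' pair `(t_a, c)` by profile search over candidate boundaries and ratios
#' (run before the size-history update so the admixture step is not absorbed
#' into the free per-group sizes), accepted over the no-admixture profile
#' only when the ECDLL gain exceeds the configured penalty; then one sweep of
#' bounded per-group `lambda_a` updates. The incoming parameter point is
#' always in the candidate set, so the ECDLL never decreases and the EM
#' iteration is monotone for a fixed discretization.
#'
#' @param stats An `em_stats` object from [e_step()].
#' @param model The current [admixture_model()].
#' @param config A [fit_config()].
#' @param t_a_fixed Optional boundary index pinning the admixture time
#'   (`0` forces a single-population PSMC fit).
#' @param update_lambda Run the per-group size sweep? [smc_fit()] passes
#'   `FALSE` during the first `config$lambda_delay` iterations.
#' @return The updated [admixture_model()].
#' @export
m_step <- function(stats, model, config = fit_config(), t_a_fixed = NULL,
                   update_lambda = TRUE) {
  grid <- model$grid
  n <- grid$n_intervals
  penalty <- config$penalty
  if (is.null(penalty) || identical(penalty, "auto")) penalty <- 2
  cur <- model
  cur_val <- ecdll(cur, stats)

  # -- theta: emission term only (representatives held at the current model)
  reps <- interval_representatives(grid, lambda_prime(cur))
  f_theta <- function(lt) {
    th <- exp(lt)
    hom_p <- exp(-th * reps)
    sum(stats$hom_counts * (-th * reps)) +
      sum(stats$het_counts * log(pmax(1 - hom_p, 1e-300)))
  }
  opt <- optimize(f_theta, log(THETA_BOUNDS), maximum = TRUE, tol = 1e-5)
  if (opt$objective > f_theta(log(cur$theta))) {
    cur <- set_model(cur, theta = exp(opt$maximum))
    cur_val <- ecdll(cur, stats)
  }

  # -- rho: transition term with the recombination-conditional kernel cached
  qn <- q_admix_matrix(cur, reps)
  f_rho <- function(lr) {
    stay <- exp(-exp(lr) * reps)
    P <- (1 - stay) * qn
    diag(P) <- diag(P) + stay
    sum(stats$trans_counts * log(pmax(P, 1e-300)))
  }
  opt <- optimize(f_rho, log(RHO_BOUNDS), maximum = TRUE, tol = 1e-5)
  if (opt$objective > f_rho(log(cur$rho))) {
    cur <- set_model(cur, rho = exp(opt$maximum))
    cur_val <- ecdll(cur, stats)
  }

  # -- flat-phase global size scale: with per-group sizes pinned, a single
  # shared multiplier is still fitted so that an overall scale misfit cannot
  # masquerade as a deep admixture boundary (t_a near t_max with ratio c is
  # likelihood-equivalent to rescaling the whole history by 1 + c)
  if (!update_lambda) {
    f_s <- function(x) {
      lam <- pmin(pmax(cur$lambda_a * exp(x), LAMBDA_BOUNDS[1]),
                  LAMBDA_BOUNDS[2])
      ecdll(set_model(cur, lambda_a = lam), stats)
    }
    opt <- optimize(f_s, c(-log(20), log(20)), maximum = TRUE, tol = 5e-3)
    if (opt$objective > cur_val) {
      cur <- set_model(cur, lambda_a = pmin(pmax(
        cur$lambda_a * exp(opt$maximum), LAMBDA_BOUNDS[1]), LAMBDA_BOUNDS[2]))
      cur_val <- opt$objective
    }
  }

  # -- (t_a, c): profile search over boundary indices x ratio candidates
  ks <- config$t_a_search
  if (is.null(ks)) ks <- 0:n
  if (!is.null(t_a_fixed)) ks <- as.integer(t_a_fixed)
  cs <- setdiff(config$ratio_search, 0)
  null_val <- if (cur$t_a_index == 0L || cur$admix_ratio == 0) cur_val else
    ecdll(set_model(cur, t_a_index = 0L, admix_ratio = 0), stats)
  prof <- profile_search(cur, stats, ks, cs)
  had_admixture <- cur$t_a_index > 0L && cur$admix_ratio > 0
  allow_admix <- prof$k > 0L && (had_admixture || prof$val - null_val > penalty)
  # candidate set always contains the incoming point (via cur_val)
  if (allow_admix && prof$val > cur_val && prof$val >= null_val) {
    cur <- set_model(cur, t_a_index = prof$k, admix_ratio = prof$c)
    cur_val <- prof$val
  } else if (null_val > cur_val) {
    cur <- set_model(cur, t_a_index = 0L, admix_ratio = 0)
    cur_val <- null_val
  }

  # -- lambda_a: one coordinate-ascent sweep over groups
  if (!update_lambda) return(cur)
  for (g in seq_len(grid$n_groups)) {
    lg <- log(cur$lambda_a[g])
    lo <- max(log(LAMBDA_BOUNDS[1]), lg - log(50))
    hi <- min(log(LAMBDA_BOUNDS[2]), lg + log(50))
    f_g <- function(x) {
      lam <- cur$lambda_a
      lam[g] <- exp(x)
      ecdll(set_model(cur, lambda_a = lam), stats)
    }
    opt <- optimize(f_g, c(lo, hi), maximum = TRUE, tol = 5e-3)
    if (opt$objective > cur_val) {
      lam <- cur$lambda_a
      lam[g] <- exp(opt$maximum)
      cur <- set_model(cur, lambda_a = lam)
      cur_val <- opt$objective
    }
  }
  cur
}

loglik_of <- function(obs_list, model) {
  if (inherits(obs_list, "ternary_sequence")) obs_list <- list(obs_list)
  mats <- hmm_matrices(model)
  sum(vapply(obs_list, function(s)
    loglik_cpp(obs_codes(s), mats$emission, mats$transition, mats$initial),
    numeric(1)))
}

# Re-locate the admixture pair by actual log-likelihood around the profile
# choice. The EM surrogate (ECDLL) can lock onto a boundary one or two
# intervals early: a move of t_a that would raise the likelihood may lower
# the minorizer, so once the flat-size phase has stabilized we scan the true
# likelihood (forward passes only) over nearby boundaries and ratio scalings
# and keep the best point.
rescan_admixture <- function(obs_list, model, window = 4L,
                             c_grid = c(0.25, 0.5, 1, 2)) {
  k0 <- model$t_a_index
  c0 <- model$admix_ratio
  n <- model$grid$n_intervals
  best <- model
  best_ll <- loglik_of(obs_list, model)
  # stage 1: locate the boundary with two ratio anchors per candidate
  ks <- max(1L, k0 - window):min(n, k0 + window)
  cs1 <- sort(unique(c(c0, 1)))
  for (k in ks) {
    for (cc in cs1) {
      if (k == k0 && cc == c0) next
      cand <- set_model(model, t_a_index = as.integer(k), admix_ratio = cc)
      ll <- loglik_of(obs_list, cand)
      if (ll > best_ll) { best_ll <- ll; best <- cand }
    }
  }
  # stage 2: ratio grid at the chosen boundary
  for (cc in setdiff(c_grid, c(best$admix_ratio))) {
    cand <- set_model(best, admix_ratio = cc)
    ll <- loglik_of(obs_list, cand)
    if (ll > best_ll) { best_ll <- ll; best <- cand }
  }
  # golden-section pass on the ratio at the chosen boundary, against the
  # actual likelihood
  if (best$t_a_index > 0L) {
    f_c <- function(cc) loglik_of(obs_list, set_model(best, admix_ratio = cc))
    ref <- optimize(f_c, lower = max(1e-3, best$admix_ratio / 2.5),
                    upper = min(4, best$admix_ratio * 2.5), maximum = TRUE,
                    tol = 0.02)
    if (ref$objective > best_ll) best <- set_model(best, admix_ratio = ref$maximum)
  }
  best
}

#' Fit the admixture-aware coalescent HMM by Baum-Welch EM
#'
#' Starts from a single-population model with constant size and the
#' admixture time at 0, then alternates the E-step ([e_step()]) and the
#' profile M-step ([m_step()]) until the relative log-likelihood change
#' falls below `config$tol` or `config$max_iter` is reached. The fit runs
#' in two phases: the size history is held flat while `theta`, `rho` and
#' the admixture pair `(t_a, c)` stabilize (the admixture step is
#' identifiable only against a smooth background history), the admixture
#' location is then refined against the actual log-likelihood, and the
#' per-group sizes are released. Interval representatives track the
#' current size history; should that drift ever decrease the
#' log-likelihood by more than `1e-6`, the previous model is restored and
#' iteration stops, so the recorded trace is non-decreasing.
#'
#' @param obs A [ternary_sequence()] or list of them.
#' @param grid A [time_grid()].
#' @param config A [fit_config()].
#' @param t_a_fixed Optional boundary index pinning the admixture time;
#'   `0` reproduces a vanilla single-population PSMC fit.
#' @param mu,gen_years If `mu` is supplied the result is also converted to
#'   physical units via [scale_to_physical()] (bin size taken from the data).
#' @return An `smc_fit` object: the final model, `loglik_trace`,
#'   `converged`, the fitted `theta`, `rho`, `admix_ratio`, `t_a_index` and
#'   `t_a_coal`, plus physical-unit fields when scaled.
#' @examples
#' \donttest{
#' spec <- simulation_spec(length_bp = 2e5, admix_time_years = 6e4,
#'                         admix_ratio = 1, seed = 1)
#' sim <- simulate_sequence(spec)
#' fit <- smc_fit(sim$sequence, config = fit_config(max_iter = 5),
#'                mu = spec$mu, gen_years = spec$gen_years)
#' glance(fit)
#' }
#' @export
smc_fit <- function(obs, grid = time_grid(), config = fit_config(),
                    t_a_fixed = NULL, mu = NULL, gen_years = 5) {
  if (inherits(obs, "ternary_sequence")) obs <- list(obs)
  if (length(obs) == 0L) stop("no observation sequences", call. = FALSE)
  codes <- lapply(obs, obs_codes)
  n_het <- sum(vapply(codes, function(x) sum(x == 1L), numeric(1)))
  n_hom <- sum(vapply(codes, function(x) sum(x == 0L), numeric(1)))
  h <- n_het / max(1, n_het + n_hom)
  theta0 <- min(max(h / max(1 - h, 1e-6), 1e-4), 10)
  model <- admixture_model(theta = theta0, rho = theta0 / 5,
                           lambda_a = 1, admix_ratio = 0, t_a_index = 0L,
                           grid = grid)
  if (!is.null(t_a_fixed) && t_a_fixed == 0) {
    config$ratio_search <- 0
  }
  if (identical(config$penalty, "auto")) {
    if (is.null(t_a_fixed) || t_a_fixed > 0) {
      seed <- if (!is.null(config$seed)) config$seed else 1L
      rng_had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
      rng_old <- if (rng_had) get(".Random.seed", envir = globalenv()) else NULL
      set.seed(seed + 77L)
      config$penalty <- calibrate_penalty(model, sum(lengths(codes)), config)
      if (rng_had) assign(".Random.seed", rng_old, envir = globalenv())
    } else {
      config$penalty <- Inf # admixture disabled; no calibration needed
    }
  }
  trace <- numeric(0)
  prev_model <- model
  converged <- FALSE
  lambda_open <- FALSE
  prev_kc <- c(model$t_a_index, model$admix_ratio)
  phase1_min <- max(2L, config$lambda_delay)
  for (it in seq_len(config$max_iter)) {
    stats <- e_step(obs, model)
    ll <- stats$loglik
    if (length(trace) > 0L) {
      last <- trace[length(trace)]
      if (ll < last - 1e-6) { # representative drift: restore and stop
        model <- prev_model
        converged <- TRUE
        break
      }
      if (lambda_open && abs(ll - last) < config$tol * abs(last)) {
        trace <- c(trace, ll)
        converged <- TRUE
        break
      }
    }
    trace <- c(trace, ll)
    prev_model <- model
    model <- m_step(stats, model, config, t_a_fixed,
                    update_lambda = lambda_open)
    if (!lambda_open) {
      kc <- c(model$t_a_index, model$admix_ratio)
      stable <- it >= phase1_min && kc[1] == prev_kc[1] &&
        abs(kc[2] - prev_kc[2]) <= 0.1 * max(prev_kc[2], 0.05)
      if (stable || it >= PHASE1_CAP) {
        if (model$t_a_index > 0L && is.null(t_a_fixed))
          model <- rescan_admixture(obs, model)
        lambda_open <- TRUE
      }
      prev_kc <- kc
    }
  }
  if (!converged) {
    ll <- loglik_of(obs, model)
    if (ll < trace[length(trace)] - 1e-6) {
      model <- prev_model
    } else {
      trace <- c(trace, ll)
    }
  }
  res <- structure(
    list(model = model, loglik_trace = trace, converged = converged,
         n_iter = length(trace), theta = model$theta, rho = model$rho,
         admix_ratio = model$admix_ratio, t_a_index = model$t_a_index,
         t_a_coal = t_a_coal(model), grid = grid, config = config,
         penalty = config$penalty, n_bins = sum(lengths(codes)),
         n0_estimate = NA_real_, t_a_years = NA_real_, ne_curve = NULL),
    class = "smc_fit")
  if (!is.null(mu)) {
    bin <- if (inherits(obs[[1]], "ternary_sequence"))
      unclass(obs[[1]])$bin_size else 100L
    res <- scale_to_physical(res, mu = mu, gen_years = gen_years,
                             bin_size = bin)
  }
  res
}

#' Convert a fitted model to physical units
#'
#' Inherits the PSMC scaling convention: the baseline diploid effective size
#' is `N0 = theta / (4 * mu * bin_size)`, times in years are
#' `t_coalescent * 2 * N0 * gen_years`, and per-interval effective sizes are
#' `lambda'(t) * N0`.
#'
#' @param result An `smc_fit` object.
#' @param mu Per-site per-generation mutation rate (> 0).
#' @param gen_years Years per generation (> 0).
#' @param bin_size Bases per bin (>= 1).
#' @return The `smc_fit` with `n0_estimate`, `t_a_years` and the `ne_curve`
#'   tibble (`interval`, `group`, `time_lo_years`, `time_hi_years`,
#'   `lambda`, `ne`) filled in.
#' @export
scale_to_physical <- function(result, mu = 2.5e-8, gen_years = 5,
                              bin_size = 100L) {
  stopifnot(inherits(result, "smc_fit"))
  if (!is.numeric(mu) || mu <= 0) stop("`mu` must be > 0", call. = FALSE)
  if (!is.numeric(gen_years) || gen_years <= 0)
    stop("`gen_years` must be > 0", call. = FALSE)
  if (!is.numeric(bin_size) || bin_size < 1)
    stop("`bin_size` must be >= 1", call. = FALSE)
  model <- result$model
  grid <- model$grid
  n <- grid$n_intervals
  n0 <- model$theta / (4 * mu * bin_size)
  to_years <- 2 * n0 * gen_years
  lamp <- lambda_prime(model)
  b <- grid$boundaries
  result$n0_estimate <- n0
  result$t_a_years <- result$t_a_coal * to_years
  result$scaling <- list(mu = mu, gen_years = gen_years, bin_size = bin_size)
  result$ne_curve <- tibble::tibble(
    interval = seq_len(n),
    group = grid$group_map,
    time_lo_years = b[seq_len(n)] * to_years,
    time_hi_years = b[seq_len(n) + 1L] * to_years,
    lambda = lamp,
    ne = lamp * n0)
  result
}

#' @export
print.smc_fit <- function(x, ...) {
  cat(sprintf("<smc_fit> %d bins, %d EM iterations (%s), loglik %.2f\n",
              x$n_bins, x$n_iter,
              if (x$converged) "converged" else "not converged",
              x$loglik_trace[length(x$loglik_trace)]))
  cat(sprintf("  theta = %.4g, rho = %.4g per bin\n", x$theta, x$rho))
  if (x$t_a_index > 0L && x$admix_ratio > 0) {
    cat(sprintf("  admixture at boundary %d: t_a = %.4g coalescent units%s, c = %.3g\n",
                x$t_a_index, x$t_a_coal,
                if (!is.na(x$t_a_years)) sprintf(" (%.1f kya)", x$t_a_years / 1000) else "",
                x$admix_ratio))
  } else {
    cat("  no admixture detected (t_a = 0)\n")
  }
  invisible(x)
}

#' Tidy the fitted size history
#'
#' @param x An `smc_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per atomic interval: `interval`, `group`,
#'   interval boundaries (coalescent units and, when scaled, years), the
#'   combined relative size `lambda` and (when scaled) `ne`.
#' @method tidy smc_fit
#' @export
tidy.smc_fit <- function(x, ...) {
  grid <- x$grid
  n <- grid$n_intervals
  b <- grid$boundaries
  out <- tibble::tibble(
    interval = seq_len(n),
    group = grid$group_map,
    time_lo = b[seq_len(n)],
    time_hi = b[seq_len(n) + 1L],
    lambda = lambda_prime(x$model))
  if (!is.null(x$ne_curve)) {
    out$time_lo_years <- x$ne_curve$time_lo_years
    out$time_hi_years <- x$ne_curve$time_hi_years
    out$ne <- x$ne_curve$ne
  }
  out
}

#' One-row summary of a fit
#'
#' @param x An `smc_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `loglik`, `n_iter`, `converged`, `theta`,
#'   `rho`, `admix_ratio`, `t_a_index`, `t_a_coal`, `n0_estimate`,
#'   `t_a_years`.
#' @method glance smc_fit
#' @export
glance.smc_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik_trace[length(x$loglik_trace)],
    n_iter = x$n_iter,
    converged = x$converged,
    theta = x$theta,
    rho = x$rho,
    admix_ratio = x$admix_ratio,
    t_a_index = x$t_a_index,
    t_a_coal = x$t_a_coal,
    n0_estimate = x$n0_estimate,
    t_a_years = x$t_a_years)
}

#' Plot the fitted effective-size history
#'
#' Step plot of the combined effective size against time (log axes when in
#' physical units), with the estimated admixture time marked.
#'
#' @param object An `smc_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot smc_fit
#' @export
autoplot.smc_fit <- function(object, ...) {
  td <- tidy(object)
  if (!is.null(object$ne_curve)) {
    d <- dplyr::filter(td, .data$time_lo_years > 0)
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_lo_years, y = .data$ne)) +
      ggplot2::geom_step(direction = "hv") +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "years before present", y = "effective population size")
    if (object$t_a_index > 0L)
      p <- p + ggplot2::geom_vline(xintercept = object$t_a_years,
                                   linetype = "dashed", colour = "orange")
  } else {
    d <- dplyr::filter(td, .data$time_lo > 0)
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_lo, y = .data$lambda)) +
      ggplot2::geom_step(direction = "hv") +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "coalescent time (2 N0 generations)",
                    y = "relative size lambda'")
    if (object$t_a_index > 0L)
      p <- p + ggplot2::geom_vline(xintercept = object$t_a_coal,
                                   linetype = "dashed", colour = "orange")
  }
  p
}
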