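# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: the path-enumeration likelihood works on
# the raw matrices, and the quadrature oracle integrates the transition
# kernel numerically.

# Exhaustive-path log-likelihood of an HMM (for tiny L and n).
brute_force_loglik <- function(obs_codes, emission, transition, initial) {
  L <- length(obs_codes)
  n <- length(initial)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), L)))
  total <- 0
  for (p in seq_len(nrow(paths))) {
    st <- paths[p, ]
    pr <- initial[st[1]] * emission[st[1], obs_codes[1] + 1L]
    if (L > 1) {
      for (l in 2:L) {
        pr <- pr * transition[st[l - 1L], st[l]] *
          emission[st[l], obs_codes[l] + 1L]
      }
    }
    total <- total + pr
  }
  unname(log(total))
}

# Piecewise cumulative hazard of a piecewise-constant size history.
piecewise_hazard <- function(lam, boundaries) {
  n <- length(lam)
  function(t) {
    vapply(t, function(tt) {
      j <- min(findInterval(tt, boundaries), n)
      h <- 0
      if (j > 1) h <- sum((boundaries[2:j] - boundaries[1:(j - 1)]) / lam[1:(j - 1)])
      h + (tt - boundaries[j]) / lam[j]
    }, numeric(1))
  }
}

# Numeric-quadrature destination-interval probabilities of the coalescent
# transition kernel from source time s (before row renormalization).
quadrature_q_row <- function(lam, s, grid) {
  n <- grid$n_intervals
  b <- grid$boundaries
  G <- piecewise_hazard(lam, b)
  lam_at <- function(t) lam[pmin(findInterval(t, b), n)]
  dens <- function(t) {
    vapply(t, function(tt) {
      hi <- min(s, tt)
      cuts <- sort(unique(c(0, b[b > 0 & b < hi], hi)))
      inner <- 0
      for (p in seq_len(length(cuts) - 1L)) { # piecewise: integrand is a single exponential per piece
        inner <- inner + stats::integrate(function(u) exp(G(u) - G(tt)),
                                          cuts[p], cuts[p + 1L],
                                          rel.tol = 1e-9)$value
      }
      inner / (lam_at(tt) * s)
    }, numeric(1))
  }
  out <- numeric(n)
  for (j in seq_len(n)) {
    hi <- if (j == n) b[n] + 60 * max(lam) else b[j + 1]
    out[j] <- stats::integrate(dens, b[j], hi, rel.tol = 1e-8,
                               subdivisions = 2000L)$value
  }
  out
}

# Random valid model on a small grid, for property-style checks.
random_small_model <- function(n = 3L, admixed = FALSE) {
  g <- time_grid(n, 15, paste0(n, "*1"))
  k <- if (admixed) sample.int(n, 1L) else 0L
  admixture_model(
    theta = exp(runif(1, -2, 0.5)),
    rho = exp(runif(1, -3, 0)),
    lambda_a = exp(runif(n, -1, 1)),
    admix_ratio = if (admixed) runif(1, 0.2, 2) else 0,
    t_a_index = k,
    grid = g)
}

# Batch-means Monte-Carlo standard error of the mean of a correlated 0/1
# series (the simulator's bins share TMRCA segments).
batch_means_se <- function(x, batch = 1000L) {
  nb <- length(x) %/% batch
  m <- colMeans(matrix(x[seq_len(nb * batch)], batch, nb))
  stats::sd(m) / sqrt(nb)
}
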