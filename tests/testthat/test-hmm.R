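test_that("emission probabilities follow the exponential no-mutation law", {
  g <- time_grid(4, 15, "4*1")
  E <- emission_matrix(0.1, g, representatives = c(0.5, 1, 2, 4))
  expect_equal(unname(E[2, "HOM"]), exp(-0.1), tolerance = 1e-12)
  expect_equal(unname(E[2, "HET"]), 1 - exp(-0.1), tolerance = 1e-12)
  expect_equal(unname(round(E[2, "HOM"], 6)), 0.904837)
  expect_equal(unname(round(E[2, "HET"], 6)), 0.095163)
  expect_equal(unname(E[, "MISSING"]), rep(1, 4))
  expect_equal(unname(E[, "HOM"] + E[, "HET"]), rep(1, 4))
  # theta -> 0 limit: everything homozygous
  E0 <- emission_matrix(1e-12, g, representatives = c(0.5, 1, 2, 4))
  expect_equal(unname(E0[, "HOM"]), rep(1, 4), tolerance = 1e-9)
  expect_error(emission_matrix(0, g), "positive")
})

test_that("constant-size kernel matches its closed form", {
  # with lambda == 1 the kernel density from source s is
  # (1 - exp(-t)) / s below s and exp(-t) (exp(s) - 1) / s above s;
  # destination-interval masses integrate those in closed form
  n <- 6L
  g <- time_grid(n, 15, paste0(n, "*1"))
  lam <- rep(1, n)
  reps <- admixsmc:::interval_representatives(g, lam)
  Q <- admixsmc:::q_kernel_cpp(lam, reps, g$boundaries)
  b <- g$boundaries
  for (is in seq_len(n)) {
    s <- reps[is]
    expected <- numeric(n)
    for (j in seq_len(n)) {
      lo <- b[j]
      hi <- if (j == n) Inf else b[j + 1]
      below <- function(x) x + exp(-x)           # antiderivative of 1 - e^-t
      above <- function(x) -(exp(s) - 1) * exp(-x)
      if (hi <= s) {
        expected[j] <- (below(hi) - below(lo)) / s
      } else if (lo >= s) {
        hi_v <- if (is.finite(hi)) above(hi) else 0
        expected[j] <- (hi_v - above(lo)) / s
      } else {
        hi_v <- if (is.finite(hi)) above(hi) else 0
        expected[j] <- (below(s) - below(lo)) / s + (hi_v - above(s)) / s
      }
    }
    expect_equal(unname(Q[is, ]), expected, tolerance = 1e-10)
  }
  expect_equal(unname(rowSums(Q)), rep(1, n), tolerance = 1e-10)
})

test_that("kernel matches numeric quadrature for random size histories", {
  set.seed(7)
  for (trial in 1:4) {
    n <- 4L
    g <- time_grid(n, 15, paste0(n, "*1"))
    lam <- exp(runif(n, -1, 1))
    reps <- admixsmc:::interval_representatives(g, lam)
    Q <- admixsmc:::q_kernel_cpp(lam, reps, g$boundaries)
    for (is in seq_len(n)) {
      expect_equal(unname(Q[is, ]), quadrature_q_row(lam, reps[is], g),
                   tolerance = 1e-7)
    }
  }
})

test_that("doubling the size history shifts transition mass to older intervals", {
  n <- 6L
  g <- time_grid(n, 15, paste0(n, "*1"))
  reps <- admixsmc:::interval_representatives(g, rep(1, n))
  Q1 <- admixsmc:::q_kernel_cpp(rep(1, n), reps, g$boundaries)
  Q2 <- admixsmc:::q_kernel_cpp(rep(2, n), reps, g$boundaries)
  for (is in seq_len(n)) {
    # first-order stochastic dominance of the destination distribution
    cdf1 <- cumsum(Q1[is, ] / sum(Q1[is, ]))
    cdf2 <- cumsum(Q2[is, ] / sum(Q2[is, ]))
    expect_true(all(cdf2 - cdf1 <= 1e-12))
  }
})

test_that("admixture kernel reduces to the single-population limits", {
  g <- time_grid(8, 15, "8*1")
  lam_groups <- exp(seq(-0.5, 0.5, length.out = 8))
  # t_a = 0: identical to the vanilla kernel with lambda_a
  m0 <- admixture_model(1, 0.2, lam_groups, admix_ratio = 0.7, t_a_index = 0L, grid = g)
  expect_equal(transition_matrix(m0),
               transition_matrix(admixture_model(1, 0.2, lam_groups, 0, 0L, g)),
               tolerance = 1e-12)
  # t_a at the last boundary: identical to vanilla with (1 + c) * lambda_a
  mfull <- admixture_model(1, 0.2, lam_groups, admix_ratio = 0.7, t_a_index = 8L, grid = g)
  expect_equal(transition_matrix(mfull),
               transition_matrix(admixture_model(1, 0.2, (1 + 0.7) * lam_groups, 0, 0L, g)),
               tolerance = 1e-12)
})

test_that("equal-size populations give the 2q(1-q) crossing entries", {
  # with c = 1, q_b = q_a, so crossing entries are proportional to
  # 2 q_a (1 - q_a); row renormalization cancels in entry ratios
  g <- time_grid(8, 15, "8*1")
  k <- 4L
  m <- admixture_model(1, 0.2, 1, admix_ratio = 1, t_a_index = k, grid = g)
  reps <- admixsmc:::interval_representatives(g, lambda_prime(m))
  Qa <- admixsmc:::q_kernel_cpp(rep(1, 8), reps, g$boundaries)
  Qadx <- admixsmc:::q_admix_matrix(m, reps)
  for (i in (k + 1):8) {
    ref <- 2 * Qa[i, 1:k] * (1 - Qa[i, 1:k])
    expect_equal(unname(Qadx[i, 1:k] / Qadx[i, 1]), unname(ref / ref[1]),
                 tolerance = 1e-10)
  }
  # scalar accessor agrees with the matrix
  expect_equal(q_admix(6, 2, m), Qadx[6, 2], tolerance = 1e-12)
  expect_equal(q_single(3, 2, rep(1, 8), g, representatives = reps),
               (Qa / rowSums(Qa))[3, 2], tolerance = 1e-12)
})

test_that("transition matrix is row-stochastic with the delta self-term", {
  set.seed(21)
  for (trial in 1:10) {
    m <- random_small_model(n = 5L, admixed = trial %% 2 == 0)
    P <- transition_matrix(m)
    expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-10)
    expect_true(all(P >= 0))
  }
  # rho -> 0: identity (no recombination)
  g <- time_grid(5, 15, "5*1")
  m <- admixture_model(1, 1e-12, 1, grid = g)
  expect_equal(transition_matrix(m), diag(5), tolerance = 1e-9)
  # rho large: rows approach the renormalized kernel
  mbig <- admixture_model(1, 1e4, 1, grid = g)
  reps <- admixsmc:::interval_representatives(g, rep(1, 5))
  qn <- admixsmc:::q_admix_matrix(mbig, reps)
  expect_equal(transition_matrix(mbig), qn, tolerance = 1e-8)
})

test_that("initial distribution is the coalescent prior under lambda'", {
  g <- time_grid(6, 15, "6*1")
  m <- admixture_model(1, 0.2, 1, grid = g)
  pi_ <- initial_distribution(m)
  b <- g$boundaries
  expect_equal(pi_[1:5], exp(-b[1:5]) - exp(-b[2:6]), tolerance = 1e-12)
  expect_equal(sum(pi_), 1, tolerance = 1e-12)
  # halving lambda' shifts mass to more recent intervals
  m_small <- admixture_model(1, 0.2, 0.5, grid = g)
  expect_true(all(cumsum(initial_distribution(m_small)) >= cumsum(pi_) - 1e-12))
})

test_that("forward-backward matches exhaustive path enumeration", {
  set.seed(31)
  for (trial in 1:12) {
    n <- sample(2:3, 1)
    L <- sample(3:6, 1)
    m <- random_small_model(n = n, admixed = trial %% 3 == 0)
    mats <- hmm_matrices(m)
    obs <- sample(0:2, L, replace = TRUE)
    fb <- forward_backward(obs, mats)
    expect_equal(fb$loglik,
                 brute_force_loglik(obs, mats$emission, mats$transition, mats$initial),
                 tolerance = 1e-10)
    expect_equal(unname(rowSums(fb$posterior)), rep(1, L), tolerance = 1e-10)
    expect_equal(sum(fb$trans_counts), L - 1, tolerance = 1e-8)
  }
})

test_that("an all-missing sequence has probability one", {
  g <- time_grid(6, 15, "6*1")
  mats <- hmm_matrices(admixture_model(1, 0.2, 1, grid = g))
  fb <- forward_backward(rep(2L, 12), mats)
  expect_equal(fb$loglik, 0, tolerance = 1e-12)
  expect_equal(fb$het_counts, rep(0, 6))
  expect_equal(fb$hom_counts, rep(0, 6))
})

test_that("posterior decoding is marginal MAP with recent-first ties", {
  g <- time_grid(2, 15, "2*1")
  m <- admixture_model(0.5, 0.2, 1, grid = g)
  mats <- hmm_matrices(m)
  # single HET bin: pick the state with larger pi * e(HET | t)
  d <- posterior_decode(1L, mats)
  expect_identical(d, which.max(mats$initial * mats$emission[, 2]))
  # all-missing: posterior equals the prior at every bin, decode is constant
  dmiss <- posterior_decode(rep(2L, 10), mats)
  expect_identical(unique(dmiss), which.max(mats$initial))
  # ties broken toward the smaller interval
  tie_mats <- mats
  tie_mats$initial <- c(0.5, 0.5)
  tie_mats$emission[, 3] <- 1
  expect_identical(posterior_decode(2L, tie_mats), 1L)
})

test_that("decoded states track the true TMRCA on simulated data", {
  spec <- simulation_spec(length_bp = 2e5, seed = 5)
  sim <- simulate_sequence(spec)
  mats <- hmm_matrices(sim$model)
  dec <- posterior_decode(sim$sequence, mats)
  expect_gt(cor(dec, sim$states, method = "spearman"), 0.2)
})
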