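small_grid <- function(n = 6L) time_grid(n, 15, paste0(n, "*1"))

test_that("E-step statistics are additive over sequences", {
  g <- small_grid()
  m <- admixture_model(1, 0.2, 1, grid = g)
  set.seed(2)
  s1 <- ternary_sequence(sample(0:1, 50, replace = TRUE))
  s2 <- ternary_sequence(sample(0:2, 80, replace = TRUE))
  a <- e_step(list(s1), m)
  b <- e_step(list(s2), m)
  ab <- e_step(list(s1, s2), m)
  expect_equal(ab$trans_counts, a$trans_counts + b$trans_counts)
  expect_equal(ab$het_counts, a$het_counts + b$het_counts)
  expect_equal(ab$loglik, a$loglik + b$loglik)
  expect_equal(sum(a$trans_counts), 49, tolerance = 1e-8)
  expect_equal(sum(ab$trans_counts), 49 + 79, tolerance = 1e-8)
})

test_that("an all-missing sequence contributes nothing", {
  g <- small_grid()
  m <- admixture_model(1, 0.2, 1, grid = g)
  st <- e_step(list(ternary_sequence(rep(2L, 30))), m)
  expect_equal(st$loglik, 0, tolerance = 1e-10)
  expect_equal(st$het_counts, rep(0, 6))
  expect_equal(st$hom_counts, rep(0, 6))
})

test_that("compiled ECDLL agrees with the matrix-built reference", {
  set.seed(13)
  g <- time_grid()
  spec <- simulation_spec(length_bp = 2e5, admix_time_years = 5e4,
                          admix_ratio = 0.5, seed = 3)
  sim <- simulate_sequence(spec)
  m0 <- admixture_model(1, 0.2, 1, grid = g)
  stats <- e_step(list(sim$sequence), m0)
  for (trial in 1:8) {
    lam <- exp(runif(28, -0.7, 0.7))
    m <- admixture_model(exp(runif(1, -0.3, 0.3)), exp(runif(1, -2, -1)),
                         lam, admix_ratio = runif(1, 0, 2),
                         t_a_index = sample(0:10, 1), grid = g)
    expect_equal(admixsmc:::ecdll(m, stats), admixsmc:::ecdll_ref(m, stats),
                 tolerance = 1e-9)
  }
})

test_that("the M-step is a fixed point at exact expected statistics", {
  g <- time_grid()
  m <- admixture_model(1, 0.2, 1, admix_ratio = 0, t_a_index = 0L, grid = g)
  mats <- hmm_matrices(m)
  P <- mats$transition
  ev <- eigen(t(P))
  pi_st <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi_st <- pi_st / sum(pi_st)
  L <- 1e5
  stats <- structure(list(
    trans_counts = (L - 1) * pi_st * P,
    het_counts = L * pi_st * mats$emission[, 2],
    hom_counts = L * pi_st * mats$emission[, 1],
    init_counts = pi_st, loglik = NA_real_, n_bins = L, n_seq = 1L),
    class = "em_stats")
  m2 <- m_step(stats, m, fit_config(penalty = 2))
  expect_equal(m2$theta, m$theta, tolerance = 1e-3)
  expect_equal(m2$rho, m$rho, tolerance = 1e-3)
  expect_equal(m2$lambda_a, m$lambda_a, tolerance = 2e-2)
  expect_identical(m2$t_a_index, 0L)
})

test_that("zero heterozygous counts drive theta to its lower bound", {
  g <- small_grid()
  m <- admixture_model(0.5, 0.1, 1, grid = g)
  stats <- e_step(list(ternary_sequence(rep(0L, 400))), m)
  m2 <- m_step(stats, m, fit_config(penalty = 2))
  expect_lt(m2$theta, 1.1 * admixsmc:::THETA_BOUNDS[1])
})

test_that("a single-candidate search space pins the admixture time", {
  spec <- simulation_spec(length_bp = 5e5, admix_time_years = 6e4,
                          admix_ratio = 1, seed = 9)
  sim <- simulate_sequence(spec)
  fit <- smc_fit(sim$sequence, config = fit_config(max_iter = 6), t_a_fixed = 0L)
  expect_identical(fit$t_a_index, 0L)
  expect_identical(fit$admix_ratio, 0)
})

test_that("EM log-likelihood traces never decrease", {
  set.seed(17)
  for (trial in 1:4) {
    spec <- simulation_spec(length_bp = 1e6,
                            admix_time_years = c(0, 6e4)[trial %% 2 + 1],
                            admix_ratio = c(0, 1)[trial %% 2 + 1],
                            seed = 40 + trial)
    sim <- simulate_sequence(spec)
    fit <- smc_fit(sim$sequence, config = fit_config(max_iter = 12))
    expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  }
})

test_that("freeing the admixture time never loses likelihood", {
  spec <- simulation_spec(length_bp = 2e6, admix_time_years = 6e4,
                          admix_ratio = 1, seed = 23)
  sim <- simulate_sequence(spec)
  cfg <- fit_config(max_iter = 12)
  free <- smc_fit(sim$sequence, config = cfg)
  fixed <- smc_fit(sim$sequence, config = cfg, t_a_fixed = 0L)
  expect_gte(max(free$loglik_trace), max(fixed$loglik_trace) - 1e-6)
})
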