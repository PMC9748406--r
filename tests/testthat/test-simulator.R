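test_that("physical parameters convert to per-bin coalescent units", {
  spec <- simulation_spec(length_bp = 1e5, admix_time_years = 6e4,
                          admix_ratio = 1, seed = 1)
  sim <- simulate_sequence(spec)
  expect_equal(sim$theta, 1)   # 4 * 1e5 * 2.5e-8 * 100
  expect_equal(sim$rho, 0.2)   # 4 * 1e5 * 5e-9 * 100
  expect_equal(sim$t_a_coal, 0.06) # 6e4 / (2 * 1e5 * 5)
  # unit round trip is exact
  expect_equal(coal_to_years(years_to_coal(6e4, 1e5, 5), 1e5, 5), 6e4,
               tolerance = 1e-12)
  # the true admixture time is a boundary of the simulation grid
  expect_true(any(abs(sim$model$grid$boundaries - 0.06) < 1e-12))
})

test_that("simulation is deterministic for a fixed seed", {
  spec <- simulation_spec(length_bp = 2e5, admix_time_years = 4e4,
                          admix_ratio = 0.5, seed = 42)
  a <- simulate_sequence(spec)
  b <- simulate_sequence(spec)
  expect_identical(unclass(a$sequence)$codes, unclass(b$sequence)$codes)
  expect_identical(a$states, b$states)
  spec2 <- spec; spec2$seed <- 43L
  expect_false(identical(unclass(simulate_sequence(spec2)$sequence)$codes,
                         unclass(a$sequence)$codes))
})

test_that("empirical heterozygosity matches the closed-form expectation", {
  spec <- simulation_spec(length_bp = 1e7, seed = 77) # 1e5 bins
  sim <- simulate_sequence(spec)
  x <- as.integer(unclass(sim$sequence)$codes == 1L)
  se <- batch_means_se(x)
  expect_lt(abs(mean(x) - expected_het_fraction(sim$model)), 3 * se)
})

test_that("constant-TMRCA runs shorten as recombination increases", {
  mean_run <- function(rec, seed) {
    spec <- simulation_spec(length_bp = 2e6, rec = rec, seed = seed)
    mean(rle(simulate_sequence(spec)$states)$lengths)
  }
  runs_lo <- sapply(1:3, function(s) mean_run(2e-9, s))
  runs_hi <- sapply(1:3, function(s) mean_run(2e-8, s))
  expect_true(all(runs_hi < runs_lo))
})

test_that("experiment grids record one row per cell with the requested truths", {
  tab <- run_experiment_grid(6e4, 1, reps = 1,
                             base_spec = simulation_spec(length_bp = 2e5),
                             seed = 5, config = fit_config(max_iter = 3))
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$time_true_years, 6e4)
  tab2 <- run_experiment_grid(c(3e4, 6e4), c(1, 0.25), reps = 2,
                              base_spec = simulation_spec(length_bp = 1e5),
                              seed = 5, config = fit_config(max_iter = 2))
  expect_identical(nrow(tab2), 8L)
  expect_setequal(unique(tab2$time_true_years), c(3e4, 6e4))
  expect_setequal(unique(tab2$ratio), c(1, 0.25))
  # deterministic per master seed
  tab3 <- run_experiment_grid(c(3e4, 6e4), c(1, 0.25), reps = 2,
                              base_spec = simulation_spec(length_bp = 1e5),
                              seed = 5, config = fit_config(max_iter = 2))
  expect_equal(tab2$time_est_years, tab3$time_est_years)
})
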