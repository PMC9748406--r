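test_that("combined size follows the two-population merge rule", {
  g <- time_grid(8, 15, "8*1")
  # boundary 4 of this grid separates representative times 0.3-ish and up
  k <- 4L
  m <- admixture_model(1, 0.2, 1, admix_ratio = 1, t_a_index = k, grid = g)
  expect_equal(combined_lambda(m, 2), 2) # below t_a: lambda_a + lambda_b
  expect_equal(combined_lambda(m, 7), 1) # above t_a: lambda_a only
  m0 <- admixture_model(1, 0.2, 1, admix_ratio = 0, t_a_index = k, grid = g)
  expect_equal(sapply(1:8, combined_lambda, model = m0), rep(1, 8))
})

test_that("moving t_a one boundary changes exactly one interval", {
  g <- time_grid(8, 15, "8*1")
  for (k in 0:7) {
    a <- lambda_prime(admixture_model(1, .2, 1, 0.5, k, g))
    b <- lambda_prime(admixture_model(1, .2, 1, 0.5, k + 1L, g))
    expect_identical(sum(a != b), 1L)
  }
})

test_that("model validation rejects invalid parameters", {
  g <- time_grid(4, 15, "4*1")
  expect_error(admixture_model(-1, 0.2, 1, grid = g), "theta")
  expect_error(admixture_model(1, 0, 1, grid = g), "rho")
  expect_error(admixture_model(1, 0.2, c(1, 1), grid = g), "per grid group")
  expect_error(admixture_model(1, 0.2, 1, admix_ratio = -0.1, grid = g), "nonnegative")
  expect_error(admixture_model(1, 0.2, 1, t_a_index = 5, grid = g), "boundary index")
})

test_that("physical scaling matches the PSMC convention and round-trips", {
  g <- time_grid(8, 15, "8*1")
  m <- admixture_model(0.01, 0.002, 1, admix_ratio = 1, t_a_index = 3L, grid = g)
  fit <- structure(
    list(model = m, loglik_trace = -1, converged = TRUE, n_iter = 1L,
         theta = m$theta, rho = m$rho, admix_ratio = 1, t_a_index = 3L,
         t_a_coal = t_a_coal(m), grid = g, n_bins = 10L),
    class = "smc_fit")
  sc <- scale_to_physical(fit, mu = 2.5e-8, gen_years = 5, bin_size = 100)
  expect_equal(sc$n0_estimate, 1000) # 0.01 / (4 * 2.5e-8 * 100)
  expect_equal(sc$t_a_years, t_a_coal(m) * 2 * 1000 * 5)
  # doubling generation time doubles all year values
  sc2 <- scale_to_physical(fit, mu = 2.5e-8, gen_years = 10, bin_size = 100)
  expect_equal(sc2$t_a_years, 2 * sc$t_a_years)
  expect_equal(sc2$ne_curve$time_hi_years, 2 * sc$ne_curve$time_hi_years)
  # inverse rescaling recovers coalescent units to machine precision
  expect_equal(sc$t_a_years / (2 * sc$n0_estimate * 5), sc$t_a_coal,
               tolerance = 1e-12)
  expect_equal(sc$ne_curve$time_lo_years / (2 * sc$n0_estimate * 5),
               g$boundaries[1:8], tolerance = 1e-12)
  expect_error(scale_to_physical(fit, mu = -1), "mu")
})

test_that("glance and tidy expose the fitted quantities as tibbles", {
  g <- time_grid(8, 15, "8*1")
  m <- admixture_model(0.01, 0.002, 1, admix_ratio = 1, t_a_index = 3L, grid = g)
  fit <- structure(
    list(model = m, loglik_trace = c(-2, -1), converged = TRUE, n_iter = 2L,
         theta = m$theta, rho = m$rho, admix_ratio = 1, t_a_index = 3L,
         t_a_coal = t_a_coal(m), grid = g, n_bins = 10L,
         n0_estimate = NA_real_, t_a_years = NA_real_, ne_curve = NULL),
    class = "smc_fit")
  gl <- glance(fit)
  expect_s3_class(gl, "tbl_df")
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$loglik, -1)
  td <- tidy(fit)
  expect_identical(nrow(td), 8L)
  expect_equal(td$lambda[1:3], rep(2, 3))
  expect_equal(td$lambda[4:8], rep(1, 5))
})
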