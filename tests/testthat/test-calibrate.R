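test_that("normalised errors match hand-computed values", {
  expect_equal(error_leading_edge(c(2, 2), c(1, 3)), 0.25)
  expect_equal(error_leading_edge(c(1, 1), c(0, 0)), 1)
  expect_equal(error_leading_edge(c(5, 6), c(5, 6)), 0)
  expect_equal(error_density_profile(matrix(0.5, 2, 98),
                                     matrix(0.25, 2, 98)), 0.25)
  ed <- matrix(1, 2, 98)
  sd_ <- ed
  sd_[1, 1] <- 0
  expect_equal(error_density_profile(ed, sd_), 1 / 196)
  expect_equal(error_clustering(c(0.4, 0.2), c(0.2, 0.4)), 0.4)
  expect_equal(error_clustering(c(0.4, 0.2), c(0, 0)), 1)
  expect_error(normalised_error(c(0, 0), c(1, 1)), "degenerate")
  expect_error(normalised_error(1:3, 1:2), "same shape")
})

test_that("normalised errors are scale-invariant and positive-definite", {
  set.seed(8)
  for (i in 1:20) {
    obs <- runif(10, 0.1, 1)
    sim <- runif(10, 0.1, 1)
    e <- normalised_error(obs, sim)
    expect_gte(e, 0)
    k <- runif(1, 0.1, 10)
    expect_equal(normalised_error(k * obs, k * sim), e)
    expect_equal(normalised_error(obs, obs), 0)
  }
})

test_that("the logistic solution solves the growth equation", {
  expect_equal(logistic_solution(0.3, 0, c(0, 10, 100)), rep(0.3, 3))
  expect_equal(logistic_solution(1, 0.05, c(0, 24)), c(1, 1))
  # frozen value from an independent numerical integration of the ODE
  expect_equal(logistic_solution(0.5, 0.0305, 24), 0.675244,
               tolerance = 1e-5)
  # monotone towards the carrying capacity
  tt <- seq(0, 96, by = 8)
  cc <- logistic_solution(0.1, 0.04, tt)
  expect_true(all(diff(cc) > 0) && all(cc <= 1))
  expect_error(logistic_solution(1.2, 0.05, 1), "\\[0, 1\\]")
})

test_that("proliferation-rate fitting recovers known rates", {
  # noiseless self-consistency
  tab <- tibble::tibble(t = c(0, 24, 48),
                        density = logistic_solution(0.2, 0.03, c(0, 24, 48)))
  fit <- fit_proliferation_rate(tab)
  expect_s3_class(fit, "logistic_fit")
  expect_equal(fit$lambda, 0.03, tolerance = 1e-3)
  expect_equal(fit$c0, 0.2)
  expect_equal(fit$doubling_time, log(2) / fit$lambda)
  expect_lte(fit$range[["low"]], fit$lambda)
  expect_gte(fit$range[["high"]], fit$lambda)
  # constant densities give a rate at (or next to) zero
  flat <- tibble::tibble(t = c(0, 24, 48), density = rep(0.31, 3))
  expect_lt(fit_proliferation_rate(flat)$lambda, 1e-3)
  expect_error(fit_proliferation_rate(tibble::tibble(t = c(24, 48),
                                                     density = c(.2, .3))),
               "t = 0")
})

test_that("rate recovery from noisy replicate densities is accurate", {
  set.seed(31)
  rel_err <- vapply(1:100, function(i) {
    tab <- generate_logistic_counts(0.3, 0.0398, times = c(0, 24, 48),
                                    noise_cv = 0.05, replicates = 4,
                                    seed = 3000 + i)
    fit <- fit_proliferation_rate(tab)
    abs(fit$lambda - 0.0398) / 0.0398
  }, numeric(1))
  expect_lt(median(rel_err), 0.10)
})

test_that("tidiers expose the logistic fit as tibbles", {
  tab <- generate_logistic_counts(0.25, 0.03, noise_cv = 0.02, seed = 5)
  fit <- fit_proliferation_rate(tab)
  td <- tidy(fit)
  expect_identical(td$term, c("lambda", "c0"))
  expect_true(td$low[1] <= td$estimate[1] & td$estimate[1] <= td$high[1])
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_named(gl, c("lambda", "c0", "doubling_time", "error"))
  pred <- predict(fit, times = c(0, 12))
  expect_equal(pred$density[1], fit$c0)
})

make_surface <- function(df, data_type = "clustering") {
  structure(tibble::as_tibble(df), data_type = data_type,
            times = c(24, 48), seed = 1,
            class = c("error_surface", "tbl_df", "tbl", "data.frame"))
}

test_that("q estimation reads intervals off the marginal error curve", {
  grid <- expand.grid(D = c(81, 162), q = seq(0, 1, 0.25))
  # bowl in q with minimum at 0.5, no D dependence
  grid$error <- (grid$q - 0.5)^2 + 0.01
  s <- make_surface(grid)
  est <- estimate_q(s, tolerance_factor = 2)
  expect_equal(est$q_hat, 0.5)
  expect_lte(est$q_low, 0.5)
  expect_gte(est$q_high, 0.5)
  expect_gt(est$q_to_D_variation, 1e6) # no D variation at all
  # unique zero at one q with tolerance 1 gives a singleton
  grid$error <- ifelse(grid$q == 0.25, 0, 1)
  est <- estimate_q(make_surface(grid), tolerance_factor = 1)
  expect_equal(c(est$q_low, est$q_high), c(0.25, 0.25))
  # flat surface warns and returns the full grid
  grid$error <- 0.3
  expect_warning(est <- estimate_q(make_surface(grid)), "not identifiable")
  expect_equal(c(est$q_low, est$q_high), c(0, 1))
})

test_that("the conditional D range reads one row of the surface", {
  grid <- expand.grid(D = 81 * 1:5, q = c(0, 0.5, 1))
  grid$error <- with(grid, ifelse(q == 0.5, (D - 243)^2 / 1e5 + 0.01, 1))
  s <- make_surface(grid, "leading_edge")
  rng <- conditional_D_range(s, 0.5, tolerance_factor = 1)
  expect_equal(rng$D_hat, 243)
  expect_equal(c(rng$D_low, rng$D_high), c(243, 243))
  # constant errors across D span the full grid
  grid$error <- 0.2
  rng <- conditional_D_range(make_surface(grid, "leading_edge"), 0.5)
  expect_equal(c(rng$D_low, rng$D_high), c(81, 405))
  # off-grid q snaps to the nearest grid value with a warning
  expect_warning(rng <- conditional_D_range(s, 0.45), "nearest|not on")
  expect_equal(rng$q, 0.5)
})
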