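test_that("homogeneous mixing recovers the plain scaling law", {
  ct <- city("h", rbind(c(300, 200), c(250, 250)))
  p <- model_parameters(h_in = 0, h_bet0 = 0)
  k <- per_capita_interactions(ct, p)
  expect_equal(k$k_total, ct$population^p$delta)
  expect_equal(k$k_total, k$k_within + k$k_between)
})

test_that("full avoidance between two equal groups halves interactions", {
  ct <- city("eq", rbind(c(500, 500)))
  p <- model_parameters(h_in = 0, h_bet0 = 1)
  k <- per_capita_interactions(ct, p)
  expect_equal(k$k_between, 0)
  expect_equal(k$k_total, ct$population^p$delta / 2)
})

test_that("heterogeneous interaction formula matches direct evaluation", {
  # N = 1e6, f = (0.7, 0.3), h_in = 0.1, h_bet = 0.2, delta = 1/6
  n <- 1e6L
  ct <- city("big", rbind(c(0.7 * n, 0.3 * n)))
  p <- model_parameters(delta = 1 / 6, h_in = 0.1, h_bet0 = 0.2)
  k <- per_capita_interactions(ct, p)
  bracket <- (0.7^2 + 0.3^2) * 1.1 + 2 * 0.7 * 0.3 * 0.8
  expect_equal(k$k_total, n^(1 / 6) * bracket, tolerance = 1e-12)
  expect_error(per_capita_interactions(ct, p, h_bet = c(1.5, 0)),
               "negative")
})

test_that("expected bias follows the closed-form learning curve", {
  n <- 1e6L
  ct <- city("b", rbind(c(n / 2, n / 2)))
  p <- model_parameters(delta = 1 / 6, alpha = 0.2, h_bet0 = 0, b_bet = 0,
                        prefactor = 1, noise_sd = 0)
  b <- expected_bias(ct, p, seg = c(0, 0))
  expect_equal(log(b), -(1 / 30) * log(n) - 0.2 * log(0.25) - 0.2 * log(2),
               tolerance = 1e-12)
  # alpha = 0 decouples bias from everything
  p0 <- model_parameters(alpha = 0, prefactor = 0.5)
  expect_equal(expected_bias(ct, p0, seg = c(0.3, 0.2)), 0.5)
  # doubling N at fixed composition multiplies b by 2^(-delta*alpha)
  ct2 <- city("b2", rbind(c(n, n)))
  expect_equal(expected_bias(ct2, p, seg = c(0, 0)) / b, 2^(-1 / 30),
               tolerance = 1e-12)
})

test_that("expected bias is monotone in population, avoidance, and diversity", {
  p <- model_parameters(noise_sd = 0)
  mk <- function(n, f1) city("m", rbind(c(round(f1 * n), n - round(f1 * n))))
  b_n <- vapply(c(1e5, 1e6, 1e7), function(n)
    expected_bias(mk(n, 0.7), p, seg = c(0.1, 0.1)), numeric(1))
  expect_true(all(diff(b_n) < 0))
  b_h <- vapply(c(0, 0.2, 0.4), function(h0)
    expected_bias(mk(1e6, 0.7),
                  model_parameters(h_bet0 = h0, noise_sd = 0),
                  seg = c(0.1, 0.1)), numeric(1))
  expect_true(all(diff(b_h) > 0))
  b_f <- vapply(c(0.9, 0.7, 0.5), function(f1)
    expected_bias(mk(1e6, f1), p, seg = c(0.1, 0.1)), numeric(1))
  expect_true(all(diff(b_f) < 0))  # more diversity, less bias
})

test_that("diversity adjustment is symmetric and errors at zero diversity", {
  expect_equal(diversity_adjustment(0.5), log(0.25))
  expect_equal(diversity_adjustment(0.9), diversity_adjustment(0.1))
  expect_equal(diversity_adjustment(0.83), log(0.83 - 0.83^2))
  expect_error(diversity_adjustment(1), "zero-diversity")
  expect_error(diversity_adjustment(0), "zero-diversity")
})

test_that("segregation adjustment is the plain sum with a tight linearization", {
  expect_equal(segregation_adjustment(0, 0), 0)
  expect_equal(segregation_adjustment(0.1, 0.07), 0.17)
  expect_error(segregation_adjustment(-0.1, 0), ">= 0")
  # ln(2 - x) ~ ln 2 - x/2 is accurate to < 0.01 for x <= 0.26
  x <- seq(0, 0.26, by = 0.001)
  expect_lt(max(abs(log(2 - x) - (log(2) - x / 2))), 0.01)
})

test_that("doubling gain matches 100 (2^delta - 1)", {
  expect_equal(round(doubling_gain(1 / 6)), 12)
  expect_equal(doubling_gain(0), 0)
  expect_equal(doubling_gain(1), 100)
})

test_that("log bias is exactly linear in the three structural regressors", {
  # four noise-free cities; solve the 4x4 linear system and recover
  # (-delta*alpha, -alpha, -alpha)
  p <- model_parameters(delta = 1 / 6, alpha = 0.3, h_bet0 = 0.05,
                        b_bet = 0.4, noise_sd = 0, prefactor = 0.8)
  specs <- list(c(2e5, 0.6, 0.05, 0.10), c(8e5, 0.7, 0.20, 0.15),
                c(3e6, 0.55, 0.10, 0.05), c(1e7, 0.8, 0.30, 0.25))
  rows <- t(vapply(specs, function(s) {
    n <- s[1]; f1 <- s[2]; seg <- s[3:4]
    ct <- city("x", rbind(c(round(f1 * n), n - round(f1 * n))))
    f1r <- ct$group_totals[1] / ct$population
    h <- p$h_bet0 + p$b_bet * seg
    c(1, log(ct$population), diversity_adjustment(f1r), log(2 - sum(h)),
      log(expected_bias(ct, p, seg = seg)))
  }, numeric(5)))
  beta <- solve(rows[, 1:4], rows[, 5])
  expect_equal(unname(beta),
               c(log(p$prefactor), -p$delta * p$alpha, -p$alpha, -p$alpha),
               tolerance = 1e-8)
})
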