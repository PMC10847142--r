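test_that("scaling fit recovers the exact slope on noise-free fixed-composition data", {
  # identical composition and segregation across cities: ln b is exactly
  # linear in ln N with slope -delta*alpha = -1/30
  p <- model_parameters(delta = 1 / 6, alpha = 0.2, noise_sd = 0, b_bet = 0)
  ns <- c(1e5, 3e5, 1e6, 3e6, 1e7)
  cities <- lapply(seq_along(ns), function(i) {
    city(sprintf("c%d", i), rbind(c(0.7 * ns[i], 0.3 * ns[i])))
  })
  obs <- generate_bias(cities, p, seed = 1)
  sf <- fit_scaling(obs, cities)
  expect_equal(sf$beta1, -1 / 30, tolerance = 1e-10)
  expect_equal(sf$r2, 1, tolerance = 1e-10)
  expect_equal(unname(mean(sf$residuals)), 0, tolerance = 1e-12)
})

test_that("scaling fit handles flat data, filtering, and tiny samples", {
  cities <- lapply(1:5, function(i) {
    city(sprintf("c%d", i), rbind(c(10^(4 + i), 10^(4 + i))))
  })
  flat <- data.frame(city_id = sprintf("c%d", 1:5), year = 2020L,
                     b = rep(0.4, 5), n_respondents = 1000L)
  sf <- fit_scaling(flat, cities)
  expect_equal(sf$beta1, 0, tolerance = 1e-12)
  expect_equal(sf$r2, 0, tolerance = 1e-12)
  # respondent filter: cities below the cutoff drop out
  mixed <- flat
  mixed$n_respondents <- c(1000, 1000, 1000, 100, 100)
  expect_equal(fit_scaling(mixed, cities, min_responses = 500)$n_cities, 3L)
  expect_error(fit_scaling(mixed[4:5, ], cities), "fewer than 3")
  neg <- flat
  neg$b[1] <- -0.2
  expect_warning(fit_scaling(neg, cities), "nonpositive")
})

test_that("two-stage fit recovers alpha exactly on the factorial design", {
  p <- model_parameters(alpha = 0.2, noise_sd = 0, b_bet = 0)
  g <- generate_city_grid(5, 4, 3, pop_range = c(5e4, 5e6), seed = 2)
  seg <- urbanbias:::segregation_values(g, "mean_deviance")
  obs <- generate_bias(g, p, seg = seg, seed = 3)
  sf <- fit_scaling(obs, g)
  af <- fit_adjustments(sf, g, seg = seg)
  lr <- estimate_learning_rates(sf, af, delta = p$delta)
  expect_equal(lr$alpha_scaling, 0.2, tolerance = 1e-8)
  expect_equal(lr$alpha_diversity, 0.2, tolerance = 1e-8)
  expect_equal(af$beta2, -0.2, tolerance = 1e-8)
  expect_equal(af$beta3, 0, tolerance = 1e-8)
})

test_that("zero residual input yields zero adjustment coefficients", {
  g <- generate_city_grid(3, 3, 2, pop_range = c(5e4, 5e5), seed = 4)
  obs <- generate_bias(g, model_parameters(noise_sd = 0), seed = 5)
  sf <- fit_scaling(obs, g)
  sf$residuals[] <- 0
  af <- fit_adjustments(sf, g)
  expect_equal(af$C2, 0, tolerance = 1e-12)
  expect_equal(af$beta2, 0, tolerance = 1e-12)
  expect_equal(af$beta3, 0, tolerance = 1e-12)
})

test_that("constant regressors are dropped with a warning rather than fitted", {
  cities <- lapply(1:6, function(i) {
    n <- round(10^(4 + i / 2) / 10) * 10  # multiples of 10: f1 exactly 0.7
    city(sprintf("c%d", i), rbind(c(round(0.7 * n), n - round(0.7 * n))))
  })
  obs <- generate_bias(cities, model_parameters(noise_sd = 0.05), seed = 6)
  sf <- fit_scaling(obs, cities)
  expect_warning(af <- fit_adjustments(sf, cities), "constant")
  expect_true(is.na(af$beta2))  # fixed composition: no diversity variance
})

test_that("learning-rate arithmetic and CI transformation are exact", {
  sf <- structure(list(beta1 = -1 / 30, ci_beta1 = c(-0.05, -0.02)),
                  class = "scaling_fit")
  af <- structure(list(beta2 = -0.2, ci_beta2 = c(-0.25, -0.15)),
                  class = "adjustment_fit")
  lr <- estimate_learning_rates(sf, af, delta = 1 / 6)
  expect_equal(lr$alpha_scaling, 0.2)
  expect_equal(lr$ci_alpha_scaling, c(0.12, 0.30))
  expect_equal(lr$alpha_diversity, 0.2)
  expect_equal(lr$ci_alpha_diversity, c(0.15, 0.25))
})

test_that("variance inflation matches a nested-R2 oracle and flags collinearity", {
  set.seed(30)
  x <- matrix(rnorm(300), 100, 3)
  expect_true(all(abs(variance_inflation(x) - 1) < 0.2))  # near-orthogonal
  # known pairwise correlation 0.8 between columns 1 and 2
  z <- rnorm(100)
  d <- cbind(a = z, b = 0.8 * z + sqrt(1 - 0.64) * rnorm(100),
             c = rnorm(100))
  v <- variance_inflation(d)
  oracle <- vapply(1:3, function(j) {
    r2 <- summary(lm(d[, j] ~ d[, -j]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  expect_equal(unname(v), oracle, tolerance = 1e-10)
  dup <- cbind(d, a2 = d[, "a"])
  expect_true(is.infinite(variance_inflation(dup)[["a"]]))
})

test_that("variance decomposition isolates the active structural factors", {
  # world without segregation dependence: segregation share near zero
  p <- model_parameters(alpha = 0.25, b_bet = 0, noise_sd = 0.02)
  g <- generate_city_grid(5, 4, 4, pop_range = c(5e4, 5e6), seed = 8)
  seg <- urbanbias:::segregation_values(g, "mean_deviance")
  obs <- generate_bias(g, p, seg = seg, seed = 9)
  sf <- fit_scaling(obs, g)
  af <- fit_adjustments(sf, g, seg = seg)
  vd <- variance_decomposition(sf, af)
  # the realized mean-deviance values covary with composition (their scale is
  # p(1-p)-dependent), and the order-averaged split assigns half of that
  # shared variance to segregation: the null share is small, not exactly 0
  expect_lt(vd$segregation, 0.25 * vd$diversity)
  expect_lt(vd$segregation, 0.05)
  expect_gt(vd$diversity, 0.2)
  expect_lte(vd$total, 1)
})

test_that("two-step coefficients agree with the joint fit on an orthogonal design", {
  p <- model_parameters(alpha = 0.2, b_bet = 0.5, noise_sd = 0.05)
  g <- generate_city_grid(5, 4, 4, pop_range = c(5e4, 5e6), seed = 10)
  seg <- urbanbias:::segregation_values(g, "mean_deviance")
  obs <- generate_bias(g, p, seg = seg, seed = 11)
  sf <- fit_scaling(obs, g)
  af <- fit_adjustments(sf, g, seg = seg)
  info <- urbanbias:::city_info(g)
  rownames(info) <- info$city_id
  ids <- names(sf$residuals)
  joint <- lm(log(obs$b) ~ log(info[obs$city_id, "N"]) +
                diversity_adjustment(info[obs$city_id, "f1"]) +
                I(seg[obs$city_id, 1] + seg[obs$city_id, 2]))
  expect_equal(af$beta2, unname(coef(joint)[3]), tolerance = 0.02)
  expect_equal(af$beta3, unname(coef(joint)[4]), tolerance = 0.05)
})

test_that("the bias_model wrapper exposes coherent methods", {
  cities <- generate_cities(40, pop_range = c(2e4, 2e6), tract_size = 2000,
                            seed = 12)
  obs <- generate_bias(cities, seed = 13)
  fit <- bias_model(obs, cities)
  expect_s3_class(fit, "bias_model")
  cf <- coef(fit)
  expect_named(cf, c("C", "beta1", "C2", "beta2", "beta3"))
  expect_equal(length(residuals(fit)), fit$scaling$n_cities)
  pr <- predict(fit, cities, type = "link")
  expect_length(pr, 40L)
  expect_true(all(is.finite(pr)))
  expect_output(print(summary(fit)), "Variance of ln b")
  expect_true(all(fit$vif >= 1))
})
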