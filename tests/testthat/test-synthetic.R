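test_that("generated cities conserve counts exactly and are seed-deterministic", {
  cities <- generate_cities(20, pop_range = c(2e4, 5e5), tract_size = 2000,
                            seed = 7)
  for (ct in cities) {
    expect_equal(sum(ct$tract_counts), ct$population)
    expect_equal(colSums(ct$tract_counts), ct$group_totals)
    expect_equal(rowSums(ct$tract_counts), ct$tract_totals)
    expect_true(all(ct$tract_counts >= 0))
  }
  again <- generate_cities(20, pop_range = c(2e4, 5e5), tract_size = 2000,
                           seed = 7)
  expect_identical(lapply(cities, `[[`, "tract_counts"),
                   lapply(again, `[[`, "tract_counts"))
  expect_identical(generate_cities(0), list())
  expect_error(generate_cities(3, pop_range = c(1000, 500)), "pop_range")
  expect_error(generate_cities(3, seg_level_range = c(0.5, 1.2)),
               "seg_level_range")
})

test_that("the unevenness knob spans even to fully segregated cities", {
  even <- generate_cities(10, pop_range = c(5e4, 2e5),
                          seg_level_range = c(0, 0), seed = 1)
  for (ct in even) {
    expect_lt(dissimilarity(ct, 1), 0.02)  # only integer rounding remains
    expect_lt(mean_deviance(ct, 1), 0.01)
  }
  # monotone: average dissimilarity increases with the knob
  mean_d <- vapply(c(0.05, 0.3, 0.7), function(s) {
    cts <- generate_cities(50, pop_range = c(2e4, 2e5), tract_size = 2000,
                           seg_level_range = c(s, s), seed = 99)
    mean(vapply(cts, dissimilarity, numeric(1), group = 1L))
  }, numeric(1))
  expect_true(all(diff(mean_d) > 0))
  # knob at 1 - eps: whole tracts are single-group, dissimilarity -> 1
  hi <- generate_cities(5, pop_range = c(5e4, 1e5),
                        seg_level_range = c(0.9995, 0.9995), seed = 3)
  expect_gt(mean(vapply(hi, dissimilarity, numeric(1), group = 1L)), 0.95)
})

test_that("the factorial city grid is orthogonal by construction", {
  g <- generate_city_grid(4, 3, 3, pop_range = c(5e4, 2e6), seed = 5)
  expect_length(g, 36L)
  info <- urbanbias:::city_info(g)
  # realized compositions sit exactly on the grid: diversity orthogonal to ln N
  expect_lt(abs(cor(log(info$N), diversity_adjustment(info$f1))), 1e-10)
})

test_that("generated bias follows the forward model exactly when noise-free", {
  p <- model_parameters(delta = 1 / 6, alpha = 0.2, h_bet0 = 0.1,
                        b_bet = 0.5, prefactor = 0.5, noise_sd = 0)
  cities <- generate_cities(8, pop_range = c(5e4, 5e5), seed = 11)
  obs <- generate_bias(cities, p, seed = 12)
  manual <- vapply(cities, function(ct) {
    expected_bias(ct, p, seg = c(mean_deviance(ct, 1), mean_deviance(ct, 2)))
  }, numeric(1))
  expect_equal(obs$b, unname(manual), tolerance = 1e-12)
  # alpha = 0: bias equals the prefactor everywhere
  obs0 <- generate_bias(cities, model_parameters(alpha = 0, noise_sd = 0,
                                                 prefactor = 0.5), seed = 1)
  expect_equal(obs0$b, rep(0.5, length(cities)))
})

test_that("single-group cities are flagged and excluded, not silently dropped", {
  good <- city("good", rbind(c(600, 400), c(500, 500)))
  lone <- city("lone", rbind(c(1000, 0), c(900, 0)))
  expect_warning(
    obs <- generate_bias(list(good, lone),
                         model_parameters(noise_sd = 0), seed = 1),
    "lone")
  expect_equal(obs$city_id, "good")
  expect_equal(attr(obs, "excluded"), "lone")
})

test_that("respondent draws concentrate on the city mean and are reproducible", {
  obs <- data.frame(city_id = "a", year = 2020L, b = 0.37,
                    n_respondents = 10000L)
  r0 <- generate_individuals(obs, model_parameters(individual_sd = 0),
                             seed = 1)
  expect_true(all(r0$d_biep == 0.37))
  r <- generate_individuals(obs, model_parameters(individual_sd = 0.4),
                            seed = 2)
  expect_equal(nrow(r), 10000L)
  expect_lt(abs(mean(r$d_biep) - 0.37), 3 * 0.4 / 100)
  expect_identical(r, generate_individuals(
    obs, model_parameters(individual_sd = 0.4), seed = 2))
})

test_that("panels have the study dimensions and reject too-short series", {
  panels <- generate_panel(43, 10, seed = 4)
  expect_length(panels, 43L)
  expect_equal(nrow(panels[[1]]), 10L)
  expect_named(panels[[1]], c("city_id", "year", "ln_N", "diversity_adj",
                              "seg_sum", "ln_b"))
  expect_true(all(diff(panels[[1]]$year) == 1))
  expect_error(generate_panel(5, 6, coupling = list(direction = "none",
                                                    lag = 2)),
               "too short")
})
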