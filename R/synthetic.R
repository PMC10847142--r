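#' @title Synthetic city, respondent and panel generators
#' @description Generators that emulate the statistical structure of the real
#'   inputs — tract-level two-group census counts, city-mean bias
#'   observations, respondent-level bias scores, and multi-year city panels —
#'   so the whole analysis pipeline can be exercised and validated without
#'   external data.
#' @name synthetic-data
NULL

# Integer apportionment of `total` units over tracts proportional to `quota`,
# never exceeding per-tract capacities `cap`, conserving the total exactly.
# Water-filling finds the capped proportional allocation; largest-remainder
# rounding then yields integers.
apportion <- function(quota, total, cap) {
  stopifnot(length(quota) == length(cap), total >= 0, total <= sum(cap))
  m <- length(quota)
  if (total == 0) return(integer(m))
  quota <- pmax(quota, 0)
  alloc <- numeric(m)
  if (sum(quota) <= 0) quota <- cap  # degenerate weights: fill by capacity
  free <- rep(TRUE, m)
  remaining <- total
  repeat {
    lambda <- remaining / sum(quota[free])
    over <- free & (lambda * quota >= cap)
    if (!any(over)) {
      alloc[free] <- lambda * quota[free]
      break
    }
    alloc[over] <- cap[over]
    remaining <- remaining - sum(cap[over])
    free[over] <- FALSE
    if (!any(free) || remaining <= 0) break
  }
  x <- floor(alloc + 1e-9)
  rem <- total - sum(x)
  if (rem > 0) {
    frac <- alloc - x
    frac[x >= cap] <- -Inf
    idx <- order(frac, decreasing = TRUE)
    idx <- idx[x[idx] < cap][seq_len(rem)]
    x[idx] <- x[idx] + 1
  }
  as.integer(x)
}

# Build one two-group city: split N into ~tract_size tracts, draw tract-level
# group-1 shares from a Beta centred on the city share with unevenness set by
# seg_level, then apportion integer counts conserving N1 exactly.
make_city <- function(city_id, n_pop, f1, seg_level, tract_size) {
  m <- max(1L, as.integer(round(n_pop / tract_size)))
  base <- n_pop %/% m
  sizes <- rep(base, m) + as.integer(seq_len(m) <= n_pop %% m)
  n1 <- as.integer(round(f1 * n_pop))
  if (seg_level <= 0) {
    shares <- rep(n1 / n_pop, m)
  } else if (seg_level >= 0.999) {
    # complete-segregation limit: fill whole tracts with group 1 in a random
    # order (at most one boundary tract is mixed)
    ord <- sample.int(m)
    g1 <- integer(m)
    left <- n1
    for (t in ord) {
      take <- min(left, sizes[t])
      g1[t] <- take
      left <- left - take
      if (left == 0) break
    }
    return(city(city_id, cbind(group1 = g1, group2 = sizes - g1)))
  } else {
    # Beta with mean p and concentration kappa = (1 - s)/s, so the
    # between-tract share variance is s * p(1 - p): the seg_level knob is
    # (approximately) the correlation ratio of the generated city.
    p <- n1 / n_pop
    kappa <- (1 - seg_level) / seg_level
    shares <- stats::rbeta(m, p * kappa, (1 - p) * kappa)
  }
  g1 <- apportion(shares * sizes, n1, sizes)
  city(city_id, cbind(group1 = g1, group2 = sizes - g1))
}

#' Generate synthetic two-group cities
#'
#' Populations are drawn log-uniformly over \code{pop_range}; the
#' majority-group fraction uniformly over \code{majority_frac_range}; each
#' city's unevenness level uniformly over \code{seg_level_range}.  Tracts of
#' roughly \code{tract_size} inhabitants receive group-1 shares from a Beta
#' distribution centred on the city share, with dispersion set by the city's
#' unevenness level (level 0 means every tract matches the city share; levels
#' near 1 approach single-group tracts).  Integer counts are apportioned by
#' largest remainder so group and city totals are conserved exactly.
#'
#' @param n_cities number of cities (0 returns an empty list).
#' @param params \code{\link{model_parameters}} (unused by the demographic
#'   draw itself; accepted for interface symmetry with the other generators).
#' @param pop_range population range (log-uniform draw); the lower end must
#'   be at least two tracts' worth of people.
#' @param tract_size target tract population (the census-tract scale of
#'   roughly 4,000 inhabitants).
#' @param seg_level_range range of per-city unevenness levels, in \[0, 1).
#' @param majority_frac_range range of group-1 fractions, in \[0, 1).
#' @param seed integer seed; the same seed reproduces the same cities.
#' @return list of \code{\link{city}} objects.
#' @examples
#' cities <- generate_cities(5, pop_range = c(2e4, 1e5), seed = 1)
#' sapply(cities, function(ct) ct$population)
#' @export
generate_cities <- function(n_cities, params = model_parameters(),
                            pop_range = c(5e4, 2e7), tract_size = 4000,
                            seg_level_range = c(0.05, 0.4),
                            majority_frac_range = c(0.55, 0.85),
                            seed = NULL) {
  stopifnot(n_cities >= 0, length(pop_range) == 2L, tract_size >= 1)
  if (n_cities == 0) return(list())
  if (pop_range[1L] < 2 * tract_size || pop_range[2L] < pop_range[1L]) {
    stop("invalid 'pop_range': need 2 * tract_size <= min <= max")
  }
  check_unit_range <- function(r, nm) {
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 0 || r[2L] >= 1) {
      stop(sprintf("invalid '%s': need 0 <= lo <= hi < 1", nm))
    }
  }
  check_unit_range(seg_level_range, "seg_level_range")
  check_unit_range(majority_frac_range, "majority_frac_range")
  with_seed(seed, {
    pops <- round(exp(stats::runif(n_cities, log(pop_range[1L]),
                                   log(pop_range[2L]))))
    f1 <- stats::runif(n_cities, majority_frac_range[1L],
                       majority_frac_range[2L])
    seg <- stats::runif(n_cities, seg_level_range[1L], seg_level_range[2L])
    lapply(seq_len(n_cities), function(i) {
      make_city(sprintf("city%03d", i), pops[i], f1[i], seg[i], tract_size)
    })
  })
}

#' Generate a balanced factorial design of cities
#'
#' Produces \code{n_pop * n_frac * n_seg} cities on a full-factorial grid of
#' population, composition and unevenness level.  Populations are snapped to
#' multiples of 1000 and composition fractions to multiples of 1/1000, so
#' every group total is integer-exact and the realized diversity regressor is
#' orthogonal in-sample to \eqn{\ln N} by construction.  This is the design
#' used for exact parameter-recovery checks, where an unbalanced random
#' design would leak composition variance into the first-stage scaling slope.
#'
#' @param n_pop,n_frac,n_seg number of grid levels per factor.
#' @param pop_range,majority_frac_range,seg_level_range grid endpoints
#'   (population levels are log-spaced).
#' @param tract_size target tract population.
#' @param seed integer seed for the tract-level draws.
#' @return list of \code{\link{city}} objects.
#' @export
generate_city_grid <- function(n_pop = 6, n_frac = 5, n_seg = 5,
                               pop_range = c(5e4, 2e7),
                               majority_frac_range = c(0.55, 0.85),
                               seg_level_range = c(0.05, 0.4),
                               tract_size = 4000, seed = NULL) {
  stopifnot(n_pop >= 1, n_frac >= 1, n_seg >= 1)
  pops <- round(exp(seq(log(pop_range[1L]), log(pop_range[2L]),
                        length.out = n_pop)) / 1000) * 1000
  fracs <- round(seq(majority_frac_range[1L], majority_frac_range[2L],
                     length.out = n_frac), 3)
  segs <- seq(seg_level_range[1L], seg_level_range[2L], length.out = n_seg)
  grid <- expand.grid(pop = pops, f1 = fracs, seg = segs)
  with_seed(seed, {
    lapply(seq_len(nrow(grid)), function(i) {
      make_city(sprintf("city%03d", i), grid$pop[i], grid$f1[i],
                grid$seg[i], tract_size)
    })
  })
}

#' Generate city-mean bias observations from the forward model
#'
#' For each city, \eqn{\ln b} is the forward-model prediction
#' \eqn{\ln A - \delta\alpha \ln N - \alpha \ln(f_1 - f_1^2)
#'  - \alpha \ln(2 - h_1 - h_2)} plus Gaussian noise of sd
#' \code{params$noise_sd}, with \eqn{h_g = h^{bet}_0 + b^{bet} s_g} and
#' \eqn{s_g} the chosen segregation measure of the generated city
#' (mean deviance by default).  Cities whose diversity term is nonpositive
#' (single-group cities) are excluded with a warning and listed in the
#' \code{"excluded"} attribute rather than silently dropped.
#'
#' @param cities list of \code{\link{city}} objects (two groups each).
#' @param params \code{\link{model_parameters}}.
#' @param year calendar year stamped on the observations.
#' @param n_respondents respondent count recorded per city (scalar or vector).
#' @param measure segregation measure used for the proxy \eqn{s_g}.
#' @param seg optional precomputed city-by-group matrix of segregation
#'   values (as from \code{urbanbias:::segregation_values}); avoids
#'   recomputation in repeated-noise simulations.
#' @param seed integer seed for the noise draw.
#' @return data frame with columns \code{city_id}, \code{year}, \code{b},
#'   \code{n_respondents}; excluded city ids in \code{attr(, "excluded")}.
#' @export
generate_bias <- function(cities, params = model_parameters(), year = 2020L,
                          n_respondents = 1000L,
                          measure = "mean_deviance", seg = NULL,
                          seed = NULL) {
  stopifnot(length(cities) >= 1L, inherits(params, "model_parameters"))
  ids <- vapply(cities, `[[`, character(1), "city_id")
  f1 <- vapply(cities, function(ct) group_fractions(ct)[[1L]], numeric(1))
  div <- f1 - f1^2
  ok <- div > 0  # single-group cities have no segregation proxy either
  if (is.null(seg)) {
    seg <- matrix(NA_real_, length(cities), 2L, dimnames = list(ids, NULL))
    if (any(ok)) {
      seg[ok, ] <- segregation_values(cities[ok], measure)
    }
  } else {
    seg <- seg[ids, , drop = FALSE]
  }
  h_sum <- 2 * params$h_bet0 + params$b_bet * (seg[, 1L] + seg[, 2L])
  ok <- ok & !is.na(h_sum) & (2 - h_sum) > 0
  if (any(!ok)) {
    warning(sprintf(
      "excluding %d city(ies) with nonpositive diversity or mixing term: %s",
      sum(!ok), paste(ids[!ok], collapse = ", ")))
  }
  n_resp <- rep_len(as.integer(n_respondents), length(cities))
  pops <- vapply(cities, `[[`, numeric(1), "population")
  with_seed(seed, {
    noise <- stats::rnorm(length(cities), 0, params$noise_sd)
    ln_b <- log(params$prefactor) -
      params$delta * params$alpha * log(pops[ok]) -
      params$alpha * log(div[ok]) -
      params$alpha * log(2 - h_sum[ok]) +
      noise[ok]
    out <- data.frame(city_id = ids[ok], year = as.integer(year),
                      b = exp(ln_b), n_respondents = n_resp[ok],
                      stringsAsFactors = FALSE)
    attr(out, "excluded") <- ids[!ok]
    out
  })
}

#' Generate respondent-level bias scores around city means
#'
#' Each observation row spawns \code{n_respondents} respondents whose
#' \code{d_biep} scores are Normal around the city mean with sd
#' \code{params$individual_sd}; demographic covariates are drawn from
#' configurable categorical distributions.
#'
#' @param obs data frame of bias observations (as from
#'   \code{\link{generate_bias}}).
#' @param params \code{\link{model_parameters}}.
#' @param demographics list with named probability vectors \code{race},
#'   \code{edu14} (length 14) and \code{birth_sex}.
#' @param seed integer seed.
#' @return data frame with columns \code{city_id}, \code{year},
#'   \code{d_biep}, \code{race}, \code{edu14}, \code{birth_sex}.
#' @export
generate_individuals <- function(obs, params = model_parameters(),
                                 demographics = list(
                                   race = c(white = 0.6, black = 0.12,
                                            multiracial = 0.08,
                                            unknown = 0.2),
                                   edu14 = rep(1 / 14, 14),
                                   birth_sex = c(f = 0.5, m = 0.5)),
                                 seed = NULL) {
  stopifnot(is.data.frame(obs), all(c("city_id", "b", "n_respondents")
                                    %in% names(obs)),
            all(obs$n_respondents >= 1))
  year <- if ("year" %in% names(obs)) obs$year else 0L
  with_seed(seed, {
    n <- obs$n_respondents
    total <- sum(n)
    idx <- rep(seq_len(nrow(obs)), n)
    data.frame(
      city_id = obs$city_id[idx],
      year = as.integer(year)[if (length(year) > 1L) idx else
                                rep(1L, total)],
      d_biep = stats::rnorm(total, obs$b[idx], params$individual_sd),
      race = sample(names(demographics$race), total, TRUE,
                    demographics$race),
      edu14 = sample.int(14L, total, TRUE, demographics$edu14),
      birth_sex = sample(names(demographics$birth_sex), total, TRUE,
                         demographics$birth_sex),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate multi-year city panels with optional lagged coupling
#'
#' Each city's structural series (\code{ln_N}, \code{diversity_adj},
#' \code{seg_sum}) evolve as Gaussian random walks with drift that share a
#' common city-growth factor: a fraction \code{common_frac} of each series'
#' innovation variance comes from one latent random walk per city (growing
#' cities tend to gain population, diversity and changing segregation
#' together), the rest is idiosyncratic.  Under
#' \code{direction = "structural_to_bias"}, the bias series is the lagged
#' common structural factor scaled by \code{strength} plus independent
#' noise of sd \code{noise_sd}; under \code{"bias_to_structural"} the
#' structural series respond to lagged bias; under \code{"none"} bias is an
#' independent random walk.
#'
#' @param n_cities number of cities.
#' @param n_years panel length (must exceed \code{lag + 4}).
#' @param coupling list with elements \code{direction} (one of
#'   \code{"none"}, \code{"structural_to_bias"}, \code{"bias_to_structural"}),
#'   \code{lag} (years), \code{strength} (coupling coefficient) and
#'   \code{noise_sd} (innovation sd of the responding series).
#' @param common_frac fraction of structural innovation variance carried by
#'   the shared city-growth factor, in \[0, 1\].
#' @param start_year first calendar year.
#' @param seed integer seed.
#' @return list of \code{city_panel} data frames with columns \code{city_id},
#'   \code{year}, \code{ln_N}, \code{diversity_adj}, \code{seg_sum},
#'   \code{ln_b}.
#' @examples
#' panels <- generate_panel(5, 10, seed = 3)
#' head(panels[[1]])
#' @export
generate_panel <- function(n_cities, n_years,
                           coupling = list(direction = "none", lag = 1L,
                                           strength = 0, noise_sd = 0.1),
                           common_frac = 0.7, start_year = 2011L,
                           seed = NULL) {
  stopifnot(n_cities >= 1, n_years >= 1,
            common_frac >= 0, common_frac <= 1)
  direction <- match.arg(coupling$direction,
                         c("none", "structural_to_bias",
                           "bias_to_structural"))
  lag <- as.integer(coupling$lag %||% 1L)
  strength <- coupling$strength %||% 0
  noise_sd <- coupling$noise_sd %||% 0.1
  if (n_years <= lag + 4L) {
    stop(sprintf("'n_years' (%d) too short for lag %d: need n_years > lag + 4",
                 n_years, lag))
  }
  struct_names <- c("ln_N", "diversity_adj", "seg_sum")
  struct_sd <- c(0.05, 0.05, 0.03)
  cum0 <- function(z) cumsum(c(0, z))
  with_seed(seed, {
    lapply(seq_len(n_cities), function(i) {
      starts <- c(stats::runif(1, log(1e5), log(1e7)),
                  stats::runif(1, -2.0, -1.4),
                  stats::runif(1, 0.1, 0.5))
      drifts <- c(0.01, 0, 0)
      common <- stats::rnorm(n_years - 1L)         # shared factor innovations
      factor_path <- cum0(common)
      s <- vapply(seq_len(3L), function(j) {
        innov <- sqrt(common_frac) * common +
          sqrt(1 - common_frac) * stats::rnorm(n_years - 1L)
        starts[j] + drifts[j] * (seq_len(n_years) - 1L) +
          struct_sd[j] * cum0(innov)
      }, numeric(n_years))
      colnames(s) <- struct_names
      ln_b <- switch(
        direction,
        none = ,
        bias_to_structural =
          stats::runif(1, -1.2, -0.8) + 0.1 * cum0(stats::rnorm(n_years - 1L)),
        structural_to_bias = {
          b <- stats::runif(1, -1.2, -0.8) +
            stats::rnorm(n_years, 0, noise_sd)
          idx <- (lag + 1L):n_years
          b[idx] <- b[idx] + strength * 0.05 * factor_path[idx - lag]
          b
        })
      if (direction == "bias_to_structural") {
        idx <- (lag + 1L):n_years
        for (j in seq_len(3L)) {
          s[, j] <- s[, j] + stats::rnorm(n_years, 0, noise_sd * struct_sd[j])
          s[idx, j] <- s[idx, j] + strength * struct_sd[j] * ln_b[idx - lag]
        }
      }
      out <- data.frame(city_id = sprintf("city%03d", i),
                        year = start_year + seq_len(n_years) - 1L,
                        s, ln_b = ln_b, stringsAsFactors = FALSE)
      class(out) <- c("city_panel", "data.frame")
      out
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
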