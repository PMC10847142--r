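#' First-stage scaling fit of city bias on population
#'
#' Ordinary least squares of \eqn{\ln b_i} on \eqn{\ln N_i} across cities,
#' after filtering to cities with at least \code{min_responses} respondents.
#' The slope is the empirical bias scaling exponent; its deviations
#' \eqn{\epsilon_i} (the residuals) feed the second-stage fit.  Cities are
#' equally weighted regardless of respondent counts (set
#' \code{weight_by_n = TRUE} to weight by respondents).
#'
#' @param obs data frame of bias observations with columns \code{city_id},
#'   \code{b}, \code{n_respondents}.
#' @param cities list of \code{\link{city}} objects or a data frame with
#'   columns \code{city_id} and \code{N}.
#' @param min_responses minimum respondent count for a city to be retained
#'   (default 500; 250 and 1000 are the usual robustness alternates).
#' @param weight_by_n weight cities by respondent counts (off by default).
#' @return object of class \code{"scaling_fit"}: coefficients \code{C} and
#'   \code{beta1}, the 95\% CI \code{ci_beta1}, named residuals, \code{r2},
#'   \code{n_cities}, and the underlying \code{lm} fit.
#' @examples
#' cities <- generate_cities(30, pop_range = c(2e4, 1e6), seed = 1)
#' obs <- generate_bias(cities, model_parameters(noise_sd = 0), seed = 2)
#' fit_scaling(obs, cities)
#' @export
fit_scaling <- function(obs, cities, min_responses = 500,
                        weight_by_n = FALSE) {
  stopifnot(is.data.frame(obs),
            all(c("city_id", "b", "n_respondents") %in% names(obs)))
  pop <- city_populations(cities)
  obs <- obs[obs$n_respondents >= min_responses, , drop = FALSE]
  bad <- !is.finite(obs$b) | obs$b <= 0
  if (any(bad)) {
    warning(sprintf("excluding %d city(ies) with nonpositive bias: %s",
                    sum(bad), paste(obs$city_id[bad], collapse = ", ")))
    obs <- obs[!bad, , drop = FALSE]
  }
  obs <- obs[obs$city_id %in% names(pop), , drop = FALSE]
  if (nrow(obs) < 3L) {
    stop("fewer than 3 cities remain after filtering; cannot fit")
  }
  dat <- data.frame(city_id = obs$city_id,
                    ln_b = log(obs$b),
                    ln_N = log(pop[obs$city_id]),
                    w = obs$n_respondents,
                    stringsAsFactors = FALSE)
  fit <- if (weight_by_n) stats::lm(ln_b ~ ln_N, data = dat, weights = w)
         else stats::lm(ln_b ~ ln_N, data = dat)
  ci <- stats::confint(fit, "ln_N", level = 0.95)
  res <- stats::residuals(fit)
  names(res) <- dat$city_id
  structure(
    list(C = unname(stats::coef(fit)[1L]),
         beta1 = unname(stats::coef(fit)[2L]),
         ci_beta1 = c(ci[1L], ci[2L]),
         residuals = res,
         r2 = summary(fit)$r.squared,
         n_cities = nrow(dat),
         data = dat, lm = fit),
    class = "scaling_fit"
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "Scaling fit (ln b ~ ln N) on %d cities:\n  beta1 = %.4f  [%.4f, %.4f]  (R^2 = %.3f)\n",
    x$n_cities, x$beta1, x$ci_beta1[1L], x$ci_beta1[2L], x$r2))
  invisible(x)
}

#' Second-stage fit of scaling deviations on diversity and segregation
#'
#' Regresses the first-stage residuals \eqn{\epsilon_i} on the diversity
#' adjustment \eqn{\ln(f_1 - f_1^2)} and the segregation sum
#' \eqn{s_1 + s_2} (the linearized between-group mixing regressor), with
#' intercept.  Partial R-squared values are nested-model increments averaged
#' over the two addition orders.
#'
#' @param sfit a \code{\link{fit_scaling}} result.
#' @param cities list of \code{\link{city}} objects covering the fitted
#'   cities.
#' @param measure segregation measure for \eqn{s_g}.
#' @param seg optional precomputed city-by-group segregation matrix.
#' @return object of class \code{"adjustment_fit"} with coefficients
#'   \code{C2}, \code{beta2}, \code{beta3}, 95\% CIs, residuals \code{xi},
#'   and partial R-squared components (fractions of the residual variance:
#'   \code{r2_diversity}, \code{r2_segregation}, \code{r2_stage2}).
#' @export
fit_adjustments <- function(sfit, cities, measure = "mean_deviance",
                            seg = NULL) {
  stopifnot(inherits(sfit, "scaling_fit"))
  info <- city_info(cities)
  ids <- names(sfit$residuals)
  keep <- ids %in% info$city_id[info$f1 > 0 & info$f1 < 1]
  dropped <- ids[!keep]
  if (length(dropped)) {
    warning(sprintf("excluding %d single-group city(ies): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  ids <- ids[keep]
  if (length(ids) < 3L) stop("fewer than 3 cities with positive diversity")
  if (is.null(seg)) {
    sub <- cities_by_id(cities, ids)
    segm <- segregation_values(sub, measure)
  } else {
    segm <- seg[ids, , drop = FALSE]
  }
  f1 <- stats::setNames(info$f1, info$city_id)[ids]
  dat <- data.frame(
    city_id = ids,
    eps = unname(sfit$residuals[ids]),
    diversity_adj = diversity_adjustment(f1),
    seg_sum = segregation_adjustment(segm[, 1L], segm[, 2L]),
    stringsAsFactors = FALSE
  )
  const_div <- stats::var(dat$diversity_adj) < .Machine$double.eps * 100
  const_seg <- stats::var(dat$seg_sum) < .Machine$double.eps * 100
  if (const_div) warning("diversity regressor is constant; beta2 set to NA")
  if (const_seg) warning("segregation regressor is constant; beta3 set to NA")
  rhs <- c(if (!const_div) "diversity_adj", if (!const_seg) "seg_sum")
  form <- stats::reformulate(if (length(rhs)) rhs else "1", response = "eps")
  fit <- stats::lm(form, data = dat)
  cf <- stats::coef(fit)
  ci <- if (length(rhs)) stats::confint(fit, level = 0.95) else NULL
  grab <- function(term) {
    if (term %in% names(cf)) {
      list(est = unname(cf[[term]]), ci = unname(ci[term, ]))
    } else list(est = NA_real_, ci = c(NA_real_, NA_real_))
  }
  b2 <- grab("diversity_adj"); b3 <- grab("seg_sum")
  r2_of <- function(terms) {
    if (!length(terms)) return(0)
    summary(stats::lm(stats::reformulate(terms, "eps"), data = dat))$r.squared
  }
  r2_d <- r2_of(if (!const_div) "diversity_adj")
  r2_s <- r2_of(if (!const_seg) "seg_sum")
  r2_ds <- r2_of(rhs)
  # order-averaged nested increments on the residual variance
  inc_div <- ((r2_ds - r2_s) + r2_d) / 2
  inc_seg <- ((r2_ds - r2_d) + r2_s) / 2
  res <- stats::residuals(fit)
  names(res) <- dat$city_id
  structure(
    list(C2 = unname(cf[["(Intercept)"]]),
         beta2 = b2$est, ci_beta2 = b2$ci,
         beta3 = b3$est, ci_beta3 = b3$ci,
         residuals = res,
         r2_diversity = inc_div,
         r2_segregation = inc_seg,
         r2_stage2 = r2_ds,
         n_cities = nrow(dat),
         measure = measure,
         data = dat, lm = fit),
    class = "adjustment_fit"
  )
}

#' @export
print.adjustment_fit <- function(x, ...) {
  cat(sprintf(
    paste0("Adjustment fit (eps ~ diversity + segregation [%s]) on %d",
           " cities:\n  beta2 = %.4f  [%.4f, %.4f]\n  beta3 = %.4f",
           "  [%.4f, %.4f]\n"),
    x$measure, x$n_cities, x$beta2, x$ci_beta2[1L], x$ci_beta2[2L],
    x$beta3, x$ci_beta3[1L], x$ci_beta3[2L]))
  invisible(x)
}

#' Learning-rate estimates from the two-stage fit
#'
#' Two independent estimates of the learning rate \eqn{\alpha}: from the
#' scaling slope, \eqn{\hat\alpha_{scaling} = -\beta_1/\delta}, and from the
#' diversity coefficient, \eqn{\hat\alpha_{diversity} = -\beta_2}.  The signs
#' are chosen so that a positive learning rate means bias decreases with
#' inter-group exposure (the model gives \eqn{\beta_1 = -\delta\alpha} and
#' \eqn{\beta_2 = -\alpha}).  Confidence intervals are the linearly
#' transformed coefficient CIs (exact for a scalar multiple).
#'
#' @param sfit a \code{\link{fit_scaling}} result.
#' @param afit a \code{\link{fit_adjustments}} result.
#' @param delta assumed interaction scaling exponent (default 1/6).
#' @return object of class \code{"learning_rates"} with
#'   \code{alpha_scaling}, \code{alpha_diversity}, their 95\% CIs and
#'   \code{delta_assumed}.
#' @export
estimate_learning_rates <- function(sfit, afit, delta = 1 / 6) {
  stopifnot(inherits(sfit, "scaling_fit"), inherits(afit, "adjustment_fit"),
            delta > 0)
  structure(
    list(alpha_scaling = -sfit$beta1 / delta,
         ci_alpha_scaling = sort(-sfit$ci_beta1 / delta),
         alpha_diversity = -afit$beta2,
         ci_alpha_diversity = sort(-afit$ci_beta2),
         delta_assumed = delta),
    class = "learning_rates"
  )
}

#' @export
print.learning_rates <- function(x, ...) {
  cat(sprintf(
    paste0("Learning-rate estimates (delta = %.4g):\n",
           "  alpha_scaling   = %.4f  [%.4f, %.4f]\n",
           "  alpha_diversity = %.4f  [%.4f, %.4f]\n"),
    x$delta_assumed,
    x$alpha_scaling, x$ci_alpha_scaling[1L], x$ci_alpha_scaling[2L],
    x$alpha_diversity, x$ci_alpha_diversity[1L], x$ci_alpha_diversity[2L]))
  invisible(x)
}

#' Variance inflation factors
#'
#' \eqn{VIF_j = 1/(1 - R_j^2)} with \eqn{R_j^2} from regressing column
#' \eqn{j} on the remaining columns (with intercept).  Perfectly collinear
#' columns report \code{Inf} rather than raising an error.
#'
#' @param design numeric matrix or data frame of regressors (\eqn{\ge 2}
#'   columns, \eqn{\ge 3} rows).
#' @return named numeric vector of VIFs (each \eqn{\ge 1}).
#' @export
variance_inflation <- function(design) {
  x <- as.matrix(design)
  stopifnot(is.numeric(x), ncol(x) >= 2L, nrow(x) >= 3L)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  vapply(seq_len(ncol(x)), function(j) {
    r2 <- summary(stats::lm(x[, j] ~ x[, -j, drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(colnames(x))
}

#' Variance decomposition of city bias into scaling, diversity, segregation
#'
#' Shares of the variance of \eqn{\ln b} attributed to each structural
#' factor: the scaling share is the first-stage R-squared; diversity and
#' segregation shares are the second-stage nested-model increments rescaled
#' by the residual variance fraction \eqn{(1 - R^2_{scaling})}, so the three
#' shares are on a common scale and sum to at most 1.
#'
#' @param sfit a \code{\link{fit_scaling}} result.
#' @param afit a \code{\link{fit_adjustments}} result from the same cities.
#' @return list with \code{scaling}, \code{diversity}, \code{segregation}
#'   and \code{total} (their sum).
#' @export
variance_decomposition <- function(sfit, afit) {
  stopifnot(inherits(sfit, "scaling_fit"), inherits(afit, "adjustment_fit"))
  resid_frac <- 1 - sfit$r2
  out <- list(scaling = sfit$r2,
              diversity = afit$r2_diversity * resid_frac,
              segregation = afit$r2_segregation * resid_frac)
  out$total <- out$scaling + out$diversity + out$segregation
  out
}

# --- helpers -----------------------------------------------------------

city_populations <- function(cities) {
  if (is.data.frame(cities)) {
    stopifnot(all(c("city_id", "N") %in% names(cities)))
    return(stats::setNames(cities$N, cities$city_id))
  }
  stats::setNames(vapply(cities, `[[`, numeric(1), "population"),
                  vapply(cities, `[[`, character(1), "city_id"))
}

city_info <- function(cities) {
  if (is.data.frame(cities)) {
    stopifnot(all(c("city_id", "N", "N1") %in% names(cities)))
    return(data.frame(city_id = cities$city_id, N = cities$N,
                      f1 = cities$N1 / cities$N, stringsAsFactors = FALSE))
  }
  data.frame(
    city_id = vapply(cities, `[[`, character(1), "city_id"),
    N = vapply(cities, `[[`, numeric(1), "population"),
    f1 = vapply(cities, function(ct) group_fractions(ct)[[1L]], numeric(1)),
    stringsAsFactors = FALSE
  )
}

cities_by_id <- function(cities, ids) {
  all_ids <- vapply(cities, `[[`, character(1), "city_id")
  missing <- setdiff(ids, all_ids)
  if (length(missing)) {
    stop(sprintf("tract-level data missing for city(ies): %s",
                 paste(missing, collapse = ", ")))
  }
  cities[match(ids, all_ids)]
}
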