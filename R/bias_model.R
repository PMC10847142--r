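#' Fit the full city-bias scaling model
#'
#' The package's flagship fit: a two-stage ordinary-least-squares analysis
#' of city-mean implicit bias.  Stage one regresses \eqn{\ln b_i} on
#' \eqn{\ln N_i} (the scaling relationship); stage two regresses the
#' resulting deviations on the diversity adjustment \eqn{\ln(f_1 - f_1^2)}
#' and the segregation sum \eqn{s_1 + s_2}.  The object bundles both
#' stages, learning-rate estimates, the variance decomposition, and
#' collinearity diagnostics.
#'
#' @param obs data frame of bias observations (\code{city_id}, \code{b},
#'   \code{n_respondents}).
#' @param cities list of \code{\link{city}} objects.
#' @param measure segregation measure used for \eqn{s_g}; one of
#'   \code{"mean_deviance"}, \code{"dissimilarity"}, \code{"gini"},
#'   \code{"correlation_ratio"}.
#' @param min_responses minimum respondents per retained city (default 500).
#' @param delta assumed interaction scaling exponent for learning-rate
#'   estimation (default 1/6).
#' @param seg optional precomputed city-by-group segregation matrix.
#' @return object of class \code{"bias_model"} with elements
#'   \code{scaling} (\code{\link{fit_scaling}}), \code{adjustments}
#'   (\code{\link{fit_adjustments}}), \code{learning_rates},
#'   \code{decomposition}, \code{vif}, \code{measure} and \code{delta}.
#' @examples
#' cities <- generate_cities(40, pop_range = c(2e4, 2e6), seed = 1)
#' obs <- generate_bias(cities, seed = 2)
#' fit <- bias_model(obs, cities)
#' fit
#' coef(fit)
#' @export
bias_model <- function(obs, cities, measure = "mean_deviance",
                       min_responses = 500, delta = 1 / 6, seg = NULL) {
  sfit <- fit_scaling(obs, cities, min_responses = min_responses)
  afit <- fit_adjustments(sfit, cities, measure = measure, seg = seg)
  rates <- estimate_learning_rates(sfit, afit, delta = delta)
  decomp <- variance_decomposition(sfit, afit)
  design <- merge(sfit$data[, c("city_id", "ln_N")],
                  afit$data[, c("city_id", "diversity_adj", "seg_sum")],
                  by = "city_id")
  vif <- variance_inflation(design[, c("ln_N", "diversity_adj", "seg_sum")])
  structure(
    list(scaling = sfit, adjustments = afit, learning_rates = rates,
         decomposition = decomp, vif = vif, measure = measure,
         delta = delta),
    class = "bias_model"
  )
}

#' @export
print.bias_model <- function(x, ...) {
  cat("Two-stage city bias scaling model\n")
  cat(sprintf("  segregation measure: %s; cities: %d\n\n",
              x$measure, x$scaling$n_cities))
  print(x$scaling)
  print(x$adjustments)
  print(x$learning_rates)
  invisible(x)
}

#' @export
summary.bias_model <- function(object, ...) {
  structure(list(model = object), class = "summary.bias_model")
}

#' @export
print.summary.bias_model <- function(x, ...) {
  m <- x$model
  print(m)
  d <- m$decomposition
  cat(sprintf(
    paste0("Variance of ln b explained:\n  scaling %.3f | diversity %.3f",
           " | segregation %.3f | total %.3f\n"),
    d$scaling, d$diversity, d$segregation, d$total))
  cat(sprintf("Max variance inflation factor: %.2f\n", max(m$vif)))
  invisible(x)
}

#' @export
coef.bias_model <- function(object, ...) {
  c(C = object$scaling$C, beta1 = object$scaling$beta1,
    C2 = object$adjustments$C2, beta2 = object$adjustments$beta2,
    beta3 = object$adjustments$beta3)
}

#' @export
residuals.bias_model <- function(object, stage = c("adjustments", "scaling"),
                                 ...) {
  stage <- match.arg(stage)
  if (stage == "scaling") object$scaling$residuals
  else object$adjustments$residuals
}

#' Predict city bias from a fitted model
#'
#' Combines the two stages into a single linear predictor
#' \eqn{\widehat{\ln b} = (C + C_2) + \beta_1 \ln N +
#'   \beta_2 \ln(f_1 - f_1^2) + \beta_3 (s_1 + s_2)}.
#'
#' @param object a \code{\link{bias_model}}.
#' @param cities list of \code{\link{city}} objects to predict for.
#' @param type \code{"response"} for bias on its natural scale,
#'   \code{"link"} for \eqn{\ln b}.
#' @param ... unused.
#' @return named numeric vector of predictions.
#' @export
predict.bias_model <- function(object, cities,
                               type = c("response", "link"), ...) {
  type <- match.arg(type)
  info <- city_info(cities)
  segm <- segregation_values(cities, object$measure)
  cf <- coef(object)
  b3 <- if (is.na(cf[["beta3"]])) 0 else cf[["beta3"]]
  b2 <- if (is.na(cf[["beta2"]])) 0 else cf[["beta2"]]
  eta <- cf[["C"]] + cf[["C2"]] + cf[["beta1"]] * log(info$N) +
    b2 * diversity_adjustment(info$f1) +
    b3 * (segm[, 1L] + segm[, 2L])
  names(eta) <- info$city_id
  if (type == "link") eta else exp(eta)
}

#' Diagnostic plot of the scaling relationship
#'
#' Plots \eqn{\ln b} against \eqn{\ln N} with the stage-one fit line.
#'
#' @param x a \code{\link{bias_model}}.
#' @param ... passed to \code{plot}.
#' @export
plot.bias_model <- function(x, ...) {
  d <- x$scaling$data
  graphics::plot(d$ln_N, d$ln_b, xlab = "ln N", ylab = "ln b",
                 main = "City bias scaling", ...)
  graphics::abline(x$scaling$C, x$scaling$beta1, col = 2, lwd = 2)
  invisible(x)
}
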