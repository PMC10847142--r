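#' Per-capita social interactions under heterogeneous mixing
#'
#' Evaluates the heterogeneous-mixing scaling model
#' \deqn{k = N^{\delta} \left[\sum_g f_g^2 (1 + h^{in}_g) +
#'   \sum_g \sum_{j \ne g} f_g f_j (1 - h^{bet}_g)\right]}
#' with group fractions \eqn{f_g = N_g/N}, a within-group interaction boost
#' \eqn{h^{in}} and a between-group reduction \eqn{h^{bet}} (one value per
#' group; every group avoids all other groups equally).  The proportionality
#' constant is fixed to 1.  With \eqn{h^{in} = h^{bet} = 0} the bracket is
#' \eqn{(\sum_g f_g)^2 = 1}, recovering the homogeneous scaling law
#' \eqn{k = N^{\delta}}.
#'
#' @param x a \code{\link{city}}.
#' @param params \code{\link{model_parameters}}.
#' @param h_bet optional vector of per-group between-group reductions; by
#'   default \code{params$h_bet0} for every group (no segregation proxy).
#' @return list with components \code{k_total}, \code{k_within},
#'   \code{k_between} (\code{k_total = k_within + k_between}).
#' @examples
#' ct <- city("toy", rbind(c(400, 400), c(400, 400)))
#' per_capita_interactions(ct, model_parameters(h_in = 0, h_bet0 = 0))
#' @export
per_capita_interactions <- function(x, params = model_parameters(),
                                    h_bet = NULL) {
  stopifnot(inherits(x, "city"), inherits(params, "model_parameters"))
  f <- group_fractions(x)
  if (is.null(h_bet)) h_bet <- rep(params$h_bet0, x$G)
  stopifnot(length(h_bet) == x$G)
  if (any(h_bet > 1)) {
    stop("between-group reduction h_bet > 1 gives a negative interaction rate")
  }
  scale <- x$population^params$delta
  k_within <- scale * sum(f^2 * (1 + params$h_in))
  # sum over ordered pairs g != j of f_g f_j (1 - h_bet_g)
  k_between <- scale * sum(f * (sum(f) - f) * (1 - h_bet))
  list(k_total = k_within + k_between,
       k_within = k_within,
       k_between = k_between)
}

#' Expected mean bias of a two-group city
#'
#' The learning-curve prediction for city-average implicit bias,
#' \deqn{b = A \cdot N^{-\delta\alpha} \cdot (f_1 - f_1^2)^{-\alpha} \cdot
#'   (2 - h_1 - h_2)^{-\alpha},}
#' with \eqn{A} the prefactor and \eqn{h_g = h^{bet}_0 + b^{bet} s_g} the
#' segregation-proxied between-group reduction of group \eqn{g}.  Bias falls
#' with population (scaling), with diversity (\eqn{f_1 - f_1^2} maximal at a
#' 50/50 split) and rises with segregation.
#'
#' @param x a \code{\link{city}} with two groups.
#' @param params \code{\link{model_parameters}}.
#' @param seg numeric vector of the two groups' segregation values
#'   \eqn{(s_1, s_2)}; defaults to the mean-deviance measures of \code{x}.
#' @return expected bias (positive scalar).
#' @export
expected_bias <- function(x, params = model_parameters(), seg = NULL) {
  stopifnot(inherits(x, "city"), inherits(params, "model_parameters"))
  if (x$G != 2L) stop("expected_bias is defined for two-group cities")
  if (is.null(seg)) {
    seg <- c(mean_deviance(x, 1L), mean_deviance(x, 2L))
  }
  stopifnot(length(seg) == 2L, all(seg >= 0))
  f1 <- group_fractions(x)[[1L]]
  div <- f1 - f1^2
  if (div <= 0) {
    stop(sprintf("city '%s' has no diversity (f1 = %g); bias undefined",
                 x$city_id, f1))
  }
  h <- params$h_bet0 + params$b_bet * seg
  mix <- 2 - sum(h)
  if (mix <= 0) {
    stop(sprintf("city '%s' is over-segregated (2 - h1 - h2 = %g <= 0)",
                 x$city_id, mix))
  }
  params$prefactor * x$population^(-params$delta * params$alpha) *
    div^(-params$alpha) * mix^(-params$alpha)
}

#' Diversity adjustment regressor
#'
#' \eqn{\ln(f_1 - f_1^2)}, the log of the two-group mixing term; symmetric
#' under \eqn{f_1 \leftrightarrow 1 - f_1} and maximal at \eqn{f_1 = 1/2}.
#'
#' @param f1 majority-group fraction(s), each strictly inside (0, 1).
#' @return numeric vector.
#' @examples
#' diversity_adjustment(0.5)  # log(0.25)
#' @export
diversity_adjustment <- function(f1) {
  if (any(f1 <= 0 | f1 >= 1)) {
    stop("zero-diversity composition: f1 must lie strictly in (0, 1)")
  }
  log(f1 - f1^2)
}

#' Segregation adjustment regressor
#'
#' The regressor \eqn{s_1 + s_2} arising from the linearization
#' \eqn{\ln(2 - x) \approx \ln 2 - x/2} of the between-group mixing term;
#' the proxy constants are absorbed into the fitted coefficient.
#'
#' @param s1,s2 nonnegative segregation values of the two groups.
#' @return numeric vector \code{s1 + s2}.
#' @export
segregation_adjustment <- function(s1, s2) {
  if (any(s1 < 0) || any(s2 < 0)) stop("segregation values must be >= 0")
  s1 + s2
}

#' Per-capita interaction gain from doubling city population
#'
#' @param delta scaling exponent (\eqn{\ge 0}).
#' @return percentage gain \eqn{100 (2^{\delta} - 1)}; about 12 for the
#'   reference exponent \eqn{\delta = 1/6}.
#' @examples
#' doubling_gain(1 / 6)
#' @export
doubling_gain <- function(delta) {
  stopifnot(all(delta >= 0))
  100 * (2^delta - 1)
}
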