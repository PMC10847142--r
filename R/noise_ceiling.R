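#' Split-half noise ceiling for city-mean bias
#'
#' Measurement noise caps the variance any model of city-mean bias can
#' explain.  For each of \code{n_splits} random permutations, respondents in
#' every city are partitioned into two halves (an odd respondent joins a
#' half uniformly at random); city half-means are then correlated across
#' cities.  The lower bound is the mean between-half correlation; the upper
#' bound is the mean of each half's correlation with the full-sample city
#' means.  With between-city sd \eqn{\tau}, within-city sd \eqn{\sigma} and
#' \eqn{n} respondents per city, the lower bound approaches
#' \eqn{\tau^2 / (\tau^2 + 2\sigma^2/n)}.
#'
#' @param responses data frame of respondents with columns \code{city_id}
#'   and \code{d_biep}.
#' @param n_splits number of split permutations (default 500).
#' @param method correlation type, \code{"pearson"} (default) or
#'   \code{"spearman"}.
#' @param seed integer seed; splits are reproducible.
#' @return object of class \code{"noise_ceiling"} with \code{lower},
#'   \code{upper}, \code{n_splits}, \code{n_cities} and the per-split values.
#' @examples
#' obs <- data.frame(city_id = rep(c("a", "b", "c"), each = 4),
#'                   b = c(0.2, 0.4, 0.6), n_respondents = 4)
#' resp <- generate_individuals(obs, model_parameters(individual_sd = 0.1),
#'                              seed = 1)
#' noise_ceiling(resp, n_splits = 20, seed = 2)
#' @export
noise_ceiling <- function(responses, n_splits = 500,
                          method = c("pearson", "spearman"), seed = NULL) {
  method <- match.arg(method)
  stopifnot(is.data.frame(responses),
            all(c("city_id", "d_biep") %in% names(responses)),
            n_splits >= 1)
  counts <- table(responses$city_id)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    warning(sprintf("excluding %d city(ies) with a single respondent: %s",
                    length(small), paste(small, collapse = ", ")))
    responses <- responses[!responses$city_id %in% small, , drop = FALSE]
  }
  cid <- factor(responses$city_id)
  if (nlevels(cid) < 2L) stop("need at least 2 cities with >= 2 respondents")
  d <- responses$d_biep
  full_mean <- tapply(d, cid, mean)
  with_seed(seed, {
    vals <- vapply(seq_len(n_splits), function(s) {
      # random within-city half assignment: shuffle ranks within city
      u <- stats::runif(length(d))
      r <- stats::ave(u, cid, FUN = function(z) {
        h <- rank(z, ties.method = "first")
        n <- length(z)
        k <- n %/% 2L
        # odd counts: the extra respondent lands in a random half
        if (n %% 2L == 1L && stats::runif(1) < 0.5) k <- k + 1L
        as.numeric(h <= k)
      })
      in_first <- r == 1
      m1 <- tapply(d[in_first], cid[in_first], mean)
      m2 <- tapply(d[!in_first], cid[!in_first], mean)
      ids <- intersect(names(m1)[!is.na(m1)], names(m2)[!is.na(m2)])
      lower <- stats::cor(m1[ids], m2[ids], method = method)
      upper <- (stats::cor(m1[ids], full_mean[ids], method = method) +
                stats::cor(m2[ids], full_mean[ids], method = method)) / 2
      c(lower, upper)
    }, numeric(2))
    structure(
      list(lower = mean(vals[1L, ]), upper = mean(vals[2L, ]),
           n_splits = n_splits, n_cities = nlevels(cid),
           per_split = data.frame(lower = vals[1L, ], upper = vals[2L, ])),
      class = "noise_ceiling"
    )
  })
}

#' @export
print.noise_ceiling <- function(x, ...) {
  cat(sprintf(
    "Noise ceiling over %d cities (%d splits): lower = %.3f, upper = %.3f\n",
    x$n_cities, x$n_splits, x$lower, x$upper))
  invisible(x)
}

#' Noise-corrected R-squared
#'
#' Rescales a model R-squared by the explainable variance implied by the
#' noise-ceiling lower bound: \eqn{R^2 / \mathrm{lower}^2}.
#'
#' @param r2 model R-squared.
#' @param ceiling a \code{\link{noise_ceiling}} or a numeric lower bound.
#' @return corrected R-squared.
#' @export
noise_corrected_r2 <- function(r2, ceiling) {
  lower <- if (inherits(ceiling, "noise_ceiling")) ceiling$lower
           else as.numeric(ceiling)
  stopifnot(is.finite(lower), lower > 0)
  r2 / lower^2
}
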