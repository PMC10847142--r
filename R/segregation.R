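#' Residential segregation indices
#'
#' Four aspatial measures of how unevenly a demographic group is distributed
#' over a city's census tracts, computed from tract-level counts.  Writing
#' \eqn{p_m = N_{g,m}/N_m} for the group's share in tract \eqn{m} and
#' \eqn{p = N_g/N} for its city-wide share:
#'
#' \itemize{
#'   \item \code{mean_deviance}: \eqn{\Delta = (1/M) \sum_m |p_m - p|} — the
#'     average absolute deviation of tract shares from the city share.
#'     Moving residents between two tracts that are both above (or both
#'     below) the city share leaves it unchanged.
#'   \item \code{dissimilarity}: \eqn{D = \sum_m |p_m - p| N_m /
#'     (2 N p (1-p))} — the population-weighted, normalized version;
#'     the fraction of the group that would have to relocate for an even
#'     distribution.
#'   \item \code{gini}: \eqn{\sum_m \sum_l |p_m - p_l| N_m N_l /
#'     (2 N^2 p (1-p))} — pairwise-tract unevenness, sensitive to
#'     redistribution anywhere in the distribution.
#'   \item \code{correlation_ratio}: \eqn{\eta^2 = (I - p)/(1 - p)} where
#'     \eqn{I = \sum_m N_{g,m}^2 / (N_m N_g)} is the isolation index — the
#'     variance ratio (eta-squared) of group membership explained by tract.
#' }
#'
#' All four are 0 when every tract share equals the city share;
#' dissimilarity, Gini and the correlation ratio are 1 under complete
#' segregation (every tract single-group) and never exceed 1.
#'
#' @param x a \code{\link{city}}.
#' @param group group (column) index, default 1.
#' @param literal for \code{correlation_ratio} only: if \code{TRUE}, evaluate
#'   the variant \eqn{\sum_m N_{g,m}^2 / (N_g (1-p)) - p/(1-p)} that omits the
#'   per-tract total from each summand.  That form does not reduce to 0 for an
#'   even distribution nor to 1 under complete segregation and is provided
#'   only for comparison; the default is the standard correlation ratio.
#' @return a single numeric value.
#' @examples
#' ct <- city("toy", rbind(c(80, 20), c(20, 80)))
#' mean_deviance(ct, 1)     # 0.3
#' dissimilarity(ct, 1)     # 0.6
#' gini(ct, 1)              # 0.6
#' correlation_ratio(ct, 1) # 0.36
#' @name segregation-indices
NULL

check_seg_input <- function(x, group, need_two_sided = TRUE) {
  stopifnot(inherits(x, "city"))
  if (length(group) != 1L || group < 1L || group > x$G) {
    stop("'group' must be a single group index in 1..G")
  }
  empty <- which(x$tract_totals == 0)
  if (length(empty)) {
    stop(sprintf("tract(s) %s have zero total population",
                 paste(empty, collapse = ", ")))
  }
  if (x$group_totals[[group]] == 0) {
    stop(sprintf("group %d has zero population", group))
  }
  if (need_two_sided && x$group_totals[[group]] == x$population) {
    stop(sprintf(
      "group %d is the entire population; index undefined (p = 1)", group))
  }
  invisible(TRUE)
}

#' @rdname segregation-indices
#' @export
mean_deviance <- function(x, group = 1L) {
  check_seg_input(x, group, need_two_sided = FALSE)
  p_m <- x$tract_counts[, group] / x$tract_totals
  p <- x$group_totals[[group]] / x$population
  mean(abs(p_m - p))
}

#' @rdname segregation-indices
#' @export
dissimilarity <- function(x, group = 1L) {
  check_seg_input(x, group)
  p_m <- x$tract_counts[, group] / x$tract_totals
  p <- x$group_totals[[group]] / x$population
  sum(abs(p_m - p) * x$tract_totals) / (2 * x$population * p * (1 - p))
}

#' @rdname segregation-indices
#' @export
gini <- function(x, group = 1L) {
  check_seg_input(x, group)
  p_m <- x$tract_counts[, group] / x$tract_totals
  p <- x$group_totals[[group]] / x$population
  w <- x$tract_totals
  # sum over ordered tract pairs of |p_m - p_l| w_m w_l, computed in
  # O(M log M) by sorting (the m = l terms are zero)
  o <- order(p_m)
  ps <- p_m[o]
  ws <- w[o]
  cw <- cumsum(ws)
  cwp <- cumsum(ws * ps)
  m <- length(ps)
  half <- sum(ws[-1L] * (ps[-1L] * cw[-m] - cwp[-m]))
  2 * half / (2 * x$population^2 * p * (1 - p))
}

#' @rdname segregation-indices
#' @export
correlation_ratio <- function(x, group = 1L, literal = FALSE) {
  check_seg_input(x, group)
  n_gm <- x$tract_counts[, group]
  n_g <- x$group_totals[[group]]
  p <- n_g / x$population
  if (literal) {
    return(sum(n_gm^2) / (n_g * (1 - p)) - p / (1 - p))
  }
  isolation <- sum(n_gm^2 / x$tract_totals) / n_g
  (isolation - p) / (1 - p)
}

#' All segregation measures for every group of a city
#'
#' @param x a \code{\link{city}}.
#' @return data frame with one row per group and columns \code{city_id},
#'   \code{group}, \code{mean_deviance}, \code{dissimilarity}, \code{gini},
#'   \code{correlation_ratio}.
#' @examples
#' segregation_measures(city("toy", rbind(c(80, 20), c(20, 80))))
#' @export
segregation_measures <- function(x) {
  stopifnot(inherits(x, "city"))
  do.call(rbind, lapply(seq_len(x$G), function(g) {
    data.frame(city_id = x$city_id, group = g,
               mean_deviance = mean_deviance(x, g),
               dissimilarity = dissimilarity(x, g),
               gini = gini(x, g),
               correlation_ratio = correlation_ratio(x, g),
               stringsAsFactors = FALSE)
  }))
}

# Segregation value s_g for each group of each city under one named measure;
# returns a matrix (city x group).  Used by the generator and the fits.
segregation_values <- function(cities, measure = c("mean_deviance",
                                                   "dissimilarity", "gini",
                                                   "correlation_ratio")) {
  measure <- match.arg(measure)
  fn <- switch(measure,
               mean_deviance = mean_deviance,
               dissimilarity = dissimilarity,
               gini = gini,
               correlation_ratio = correlation_ratio)
  out <- t(vapply(cities, function(ct) {
    vapply(seq_len(ct$G), function(g) fn(ct, g), numeric(1))
  }, numeric(cities[[1L]]$G)))
  rownames(out) <- vapply(cities, `[[`, character(1), "city_id")
  out
}
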