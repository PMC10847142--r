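#' Construct a city from tract-level group counts
#'
#' A city is described entirely by its census-tract composition: an
#' \eqn{M \times G} matrix of nonnegative integer counts \eqn{N_{g,m}},
#' with tracts in rows and demographic groups in columns.  Group totals
#' \eqn{N_g}, tract totals \eqn{N_m} and the city population \eqn{N} are
#' derived.  All analyses in this package use \eqn{G = 2} groups, but the
#' container itself is general.
#'
#' @param city_id character scalar identifying the city.
#' @param tract_counts numeric matrix (tracts x groups) of nonnegative
#'   integer counts; column names, if present, name the groups.
#' @return An object of class \code{"city"} with elements \code{city_id},
#'   \code{tract_counts}, \code{group_totals}, \code{tract_totals},
#'   \code{population}, \code{M} and \code{G}.
#' @examples
#' ct <- city("toy", rbind(c(80, 20), c(20, 80)))
#' ct$population
#' @export
city <- function(city_id, tract_counts) {
  stopifnot(is.character(city_id), length(city_id) == 1L)
  tract_counts <- as.matrix(tract_counts)
  if (!is.numeric(tract_counts) || nrow(tract_counts) < 1L ||
      ncol(tract_counts) < 1L) {
    stop("'tract_counts' must be a numeric matrix with >= 1 tract and group")
  }
  if (any(tract_counts < 0)) stop("tract counts must be nonnegative")
  if (any(tract_counts != round(tract_counts))) {
    stop("tract counts must be integers")
  }
  storage.mode(tract_counts) <- "double"
  group_totals <- colSums(tract_counts)
  tract_totals <- rowSums(tract_counts)
  if (all(group_totals == 0)) {
    stop("at least one group must have positive population")
  }
  structure(
    list(city_id = city_id,
         tract_counts = tract_counts,
         group_totals = group_totals,
         tract_totals = tract_totals,
         population = sum(group_totals),
         M = nrow(tract_counts),
         G = ncol(tract_counts)),
    class = "city"
  )
}

#' @export
print.city <- function(x, ...) {
  cat(sprintf("City '%s': N = %s across %d tracts, %d groups (%s)\n",
              x$city_id, format(x$population, big.mark = ","), x$M, x$G,
              paste(signif(x$group_totals / x$population, 3),
                    collapse = " / ")))
  invisible(x)
}

#' Group population fractions of a city
#'
#' @param x a \code{city}.
#' @return numeric vector \eqn{f_g = N_g / N}.
#' @export
group_fractions <- function(x) {
  stopifnot(inherits(x, "city"))
  x$group_totals / x$population
}

#' Tabulate a list of cities
#'
#' @param cities list of \code{city} objects.
#' @return \code{cities_table}: data frame with columns \code{city_id},
#'   \code{N}, \code{N1}, \code{N2}; \code{tracts_table}: long data frame
#'   with columns \code{city_id}, \code{tract_id}, \code{count_group1},
#'   \code{count_group2}.
#' @export
cities_table <- function(cities) {
  stopifnot(length(cities) > 0L || is.list(cities))
  do.call(rbind, lapply(cities, function(ct) {
    data.frame(city_id = ct$city_id,
               N = ct$population,
               N1 = ct$group_totals[[1L]],
               N2 = if (ct$G >= 2L) ct$group_totals[[2L]] else 0,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname cities_table
#' @export
tracts_table <- function(cities) {
  do.call(rbind, lapply(cities, function(ct) {
    data.frame(city_id = ct$city_id,
               tract_id = sprintf("%s_t%04d", ct$city_id, seq_len(ct$M)),
               count_group1 = ct$tract_counts[, 1L],
               count_group2 = if (ct$G >= 2L) ct$tract_counts[, 2L] else 0,
               stringsAsFactors = FALSE)
  }))
}
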