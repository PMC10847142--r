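#' Write a synthetic dataset to CSV contracts
#'
#' Writes \code{tracts.csv} (\code{city_id, tract_id, count_group1,
#' count_group2}), \code{cities.csv} (\code{city_id, N, N1, N2}) and, when
#' given, \code{bias.csv} (\code{city_id, year, b, n_respondents}) and
#' \code{respondents.csv}.  Counts round-trip exactly; reals are written at
#' full precision.
#'
#' @param cities list of \code{\link{city}} objects.
#' @param dir output directory (created if needed).
#' @param bias optional bias-observation data frame.
#' @param respondents optional respondent data frame.
#' @return invisibly, the paths written.
#' @export
write_city_data <- function(cities, dir, bias = NULL, respondents = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tracts = file.path(dir, "tracts.csv"),
             cities = file.path(dir, "cities.csv"))
  utils::write.csv(tracts_table(cities), paths[["tracts"]],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cities_table(cities), paths[["cities"]],
                   row.names = FALSE, quote = FALSE)
  if (!is.null(bias)) {
    paths[["bias"]] <- file.path(dir, "bias.csv")
    utils::write.csv(format_reals(bias), paths[["bias"]],
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(respondents)) {
    paths[["respondents"]] <- file.path(dir, "respondents.csv")
    utils::write.csv(format_reals(respondents), paths[["respondents"]],
                     row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

# serialize doubles losslessly (17 significant digits round-trips IEEE754)
format_reals <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("file '%s' is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")))
  }
}

#' Read tract-level counts into city objects
#'
#' Expects the \code{tracts.csv} contract (\code{city_id, tract_id,
#' count_group1, count_group2}).  Negative counts and tracts with
#' nonpositive totals are rejected with row-numbered errors.  If a
#' delineation map is supplied (columns \code{tract_id, city_id}), the
#' file's own \code{city_id} column is optional: tracts are assigned
#' through the map, and unmapped tracts are excluded with a warning.
#'
#' @param path CSV path.
#' @param delineation optional data frame mapping \code{tract_id} to
#'   \code{city_id} (see \code{\link{read_delineation}}).
#' @return list of \code{\link{city}} objects.
#' @export
read_tracts <- function(path, delineation = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("tract_id", "count_group1", "count_group2"), path)
  if (!is.null(delineation)) {
    stopifnot(all(c("tract_id", "city_id") %in% names(delineation)))
    if (anyDuplicated(delineation$tract_id)) {
      stop("delineation maps some tract to more than one city")
    }
    df$city_id <- delineation$city_id[match(df$tract_id,
                                            delineation$tract_id)]
    unmapped <- is.na(df$city_id)
    if (any(unmapped)) {
      warning(sprintf("excluding %d unmapped tract(s): %s", sum(unmapped),
                      paste(df$tract_id[unmapped], collapse = ", ")))
      df <- df[!unmapped, , drop = FALSE]
    }
  }
  require_columns(df, "city_id", path)
  neg <- which(df$count_group1 < 0 | df$count_group2 < 0)
  if (length(neg)) {
    stop(sprintf("negative count(s) in '%s' at row(s): %s", path,
                 paste(neg, collapse = ", ")))
  }
  zero <- which(df$count_group1 + df$count_group2 <= 0)
  if (length(zero)) {
    stop(sprintf("nonpositive tract total(s) in '%s' at row(s): %s", path,
                 paste(zero, collapse = ", ")))
  }
  lapply(split(df, df$city_id), function(d) {
    city(d$city_id[1L], cbind(group1 = d$count_group1,
                              group2 = d$count_group2))
  })
}

#' Read city-mean bias observations
#'
#' Expects the \code{bias.csv} contract (\code{city_id, year, b,
#' n_respondents}).  Cities below \code{min_responses} respondents are
#' filtered at read time (set it to 0 to keep everything).
#'
#' @param path CSV path.
#' @param min_responses read-time respondent filter (default 500).
#' @return data frame of bias observations.
#' @export
read_bias <- function(path, min_responses = 500) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("city_id", "year", "b", "n_respondents"), path)
  bad <- which(!is.finite(df$b) | df$b <= 0)
  if (length(bad)) {
    stop(sprintf("nonpositive bias value(s) in '%s' at row(s): %s", path,
                 paste(bad, collapse = ", ")))
  }
  df[df$n_respondents >= min_responses, , drop = FALSE]
}

#' Read respondent-level bias scores
#'
#' Expects the \code{respondents.csv} contract (\code{city_id, year,
#' d_biep, race, edu14, birth_sex}).
#'
#' @param path CSV path.
#' @return data frame of respondents.
#' @export
read_respondents <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("city_id", "d_biep", "race", "edu14", "birth_sex"),
                  path)
  df
}

#' Read a tract-to-city delineation map
#'
#' @param path CSV path with columns \code{tract_id}, \code{city_id}.
#' @return data frame mapping each tract to at most one city.
#' @export
read_delineation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("tract_id", "city_id"), path)
  if (anyDuplicated(df$tract_id)) {
    stop(sprintf("duplicate tract_id(s) in '%s'", path))
  }
  df
}
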