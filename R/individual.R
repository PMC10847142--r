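#' Recode the 14-point educational attainment scale
#'
#' Collapses the respondent-level \code{edu14} code (1..14) into three
#' categories.  The cut points are configurable; the defaults place codes
#' 1-6 in \code{"HS-or-below"}, 7-11 in \code{"some-college-or-grad"} and
#' 12-14 in \code{"advanced"}.  Missing values stay missing.
#'
#' @param edu14 integer vector of codes in 1..14 (NAs allowed).
#' @param cuts named numeric vector with elements \code{hs_max} and
#'   \code{some_college_max}.
#' @return factor with levels \code{HS-or-below},
#'   \code{some-college-or-grad}, \code{advanced}.
#' @export
recode_education <- function(edu14, cuts = c(hs_max = 6,
                                             some_college_max = 11)) {
  ok <- is.na(edu14) | (edu14 >= 1 & edu14 <= 14 & edu14 == round(edu14))
  if (!all(ok)) {
    stop(sprintf("edu14 values out of range 1..14: %s",
                 paste(unique(edu14[!ok]), collapse = ", ")))
  }
  lv <- c("HS-or-below", "some-college-or-grad", "advanced")
  out <- ifelse(is.na(edu14), NA_character_,
                ifelse(edu14 <= cuts[["hs_max"]], lv[1L],
                       ifelse(edu14 <= cuts[["some_college_max"]], lv[2L],
                              lv[3L])))
  factor(out, levels = lv)
}

#' Recode self-reported race into analysis categories
#'
#' Maps raw race strings to \code{White}, \code{Black}, \code{Multiracial},
#' or the base category \code{other-base} (other races, unknown, empty and
#' missing values).  A user-supplied \code{code_map} (named character
#' vector, raw value -> category) overrides or extends the default mapping,
#' which matches case-insensitively on common labels.
#'
#' @param raw character vector of raw race codes/labels.
#' @param code_map optional named character vector of extra mappings.
#' @return factor with levels \code{other-base}, \code{White},
#'   \code{Black}, \code{Multiracial} (base category first).
#' @export
recode_race <- function(raw, code_map = NULL) {
  lv <- c("other-base", "White", "Black", "Multiracial")
  default <- c(white = "White",
               black = "Black", "african american" = "Black",
               "black or african american" = "Black",
               multiracial = "Multiracial", multi = "Multiracial",
               "more than one race" = "Multiracial")
  key <- tolower(trimws(as.character(raw)))
  out <- unname(default[key])
  if (!is.null(code_map)) {
    stopifnot(!is.null(names(code_map)),
              all(code_map %in% lv))
    hit <- key %in% tolower(names(code_map))
    out[hit] <- unname(code_map[match(key[hit], tolower(names(code_map)))])
  }
  out[is.na(out)] <- "other-base"
  factor(out, levels = lv)
}

#' Individual-level logistic control model
#'
#' Logistic regression of the indicator \eqn{D_{biep} > 0} (a positive
#' implicit bias) on the city-level structural variables (\eqn{\ln N}, the
#' diversity adjustment, the segregation sum) joined by city, plus the
#' individual covariates race, recoded education and birth sex.  Covariate
#' categories with no respondents are dropped with a warning; a constant
#' outcome (complete separation) raises an explicit error rather than
#' returning a silent estimate.
#'
#' @param responses data frame of respondents with columns \code{city_id},
#'   \code{d_biep}, \code{race}, \code{edu14}, \code{birth_sex}.
#' @param city_covariates data frame with columns \code{city_id},
#'   \code{ln_N}, \code{diversity_adj}, \code{seg_sum}.
#' @param edu_cuts passed to \code{\link{recode_education}}.
#' @return list with \code{coefficients} (a data frame with estimate,
#'   standard error, z and p per term) and the underlying \code{glm}.
#' @export
fit_individual <- function(responses, city_covariates,
                           edu_cuts = c(hs_max = 6, some_college_max = 11)) {
  stopifnot(is.data.frame(responses),
            all(c("city_id", "d_biep", "race", "edu14", "birth_sex")
                %in% names(responses)),
            all(c("city_id", "ln_N", "diversity_adj", "seg_sum")
                %in% names(city_covariates)))
  dat <- merge(responses, city_covariates, by = "city_id")
  if (nrow(dat) < nrow(responses)) {
    warning(sprintf("%d respondent(s) without city covariates dropped",
                    nrow(responses) - nrow(dat)))
  }
  dat$positive <- as.integer(dat$d_biep > 0)
  if (length(unique(dat$positive)) < 2L) {
    stop("outcome is constant (all D_biep on one side of 0): separation")
  }
  dat$education <- recode_education(dat$edu14, cuts = edu_cuts)
  dat$race_cat <- recode_race(dat$race)
  dat$birth_sex <- factor(dat$birth_sex)
  terms <- c("ln_N", "diversity_adj", "seg_sum")
  for (v in c("race_cat", "education", "birth_sex")) {
    present <- droplevels(dat[[v]][!is.na(dat[[v]])])
    if (nlevels(present) >= 2L) {
      dat[[v]] <- droplevels(dat[[v]])
      terms <- c(terms, v)
    } else {
      warning(sprintf("covariate '%s' has fewer than 2 observed levels; excluded",
                      v))
    }
  }
  fit <- stats::glm(stats::reformulate(terms, "positive"),
                    family = stats::binomial(), data = dat)
  sm <- summary(fit)$coefficients
  list(coefficients = data.frame(term = rownames(sm),
                                 estimate = sm[, 1L], se = sm[, 2L],
                                 z = sm[, 3L], p = sm[, 4L],
                                 row.names = NULL,
                                 stringsAsFactors = FALSE),
       glm = fit)
}
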