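#' Forward-model parameters
#'
#' Bundles the parameters of the heterogeneous-mixing scaling model and of its
#' learning-curve coupling to implicit bias.  The model says per-capita social
#' interactions scale as \eqn{k \sim N^{\delta}} modulated by group mixing, and
#' mean bias follows a learning curve \eqn{b \sim k_{inter}^{-\alpha}} in the
#' number of inter-group interactions.  Between-group avoidance of group
#' \eqn{g} is proxied linearly by its residential segregation:
#' \eqn{h_g = h^{bet}_0 + b^{bet} s_g}.
#'
#' Defaults describe a realistic synthetic study: \code{delta = 1/6} (the
#' reference interaction scaling exponent), \code{alpha = 0.2} (a learning
#' rate compatible with observed city-level scaling and diversity slopes),
#' \code{b_bet = 0.5} and \code{h_bet0 = 0.1} (small positive avoidance with a
#' moderate segregation dependence), \code{prefactor = 0.5} (mean city bias
#' near 0.4, the scale of IAT D-score city means), \code{noise_sd = 0.1}
#' (city-level residual spread giving total model R-squared near 1/3) and
#' \code{individual_sd = 0.4} (respondent-level D-score spread).
#'
#' @param delta interaction scaling exponent, in \[0, 1\].
#' @param alpha learning rate of the bias learning curve, in (0, 1).
#' @param h_in within-group interaction boost (\eqn{\ge 0}).
#' @param h_bet0 baseline between-group interaction reduction (intercept of
#'   the segregation proxy).
#' @param b_bet slope of the between-group reduction on segregation.
#' @param prefactor positive scaling prefactor of the bias model.
#' @param noise_sd standard deviation of additive noise on \eqn{\ln b}
#'   (multiplicative on \eqn{b}).
#' @param individual_sd respondent-level standard deviation around the city
#'   mean bias.
#' @return An object of class \code{"model_parameters"}.
#' @examples
#' model_parameters(alpha = 0.25, noise_sd = 0)
#' @export
model_parameters <- function(delta = 1 / 6, alpha = 0.2, h_in = 0,
                             h_bet0 = 0.1, b_bet = 0.5, prefactor = 0.5,
                             noise_sd = 0.1, individual_sd = 0.4) {
  stopifnot(
    is.numeric(delta), length(delta) == 1L, delta >= 0, delta <= 1,
    is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha < 1,
    is.numeric(h_in), length(h_in) == 1L, h_in >= 0,
    is.numeric(h_bet0), length(h_bet0) == 1L,
    is.numeric(b_bet), length(b_bet) == 1L,
    is.numeric(prefactor), length(prefactor) == 1L, prefactor > 0,
    is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0,
    is.numeric(individual_sd), length(individual_sd) == 1L, individual_sd >= 0
  )
  structure(
    list(delta = delta, alpha = alpha, h_in = h_in, h_bet0 = h_bet0,
         b_bet = b_bet, prefactor = prefactor, noise_sd = noise_sd,
         individual_sd = individual_sd),
    class = "model_parameters"
  )
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Forward-model parameters:\n")
  cat(sprintf("  delta (scaling exponent):        %.4g\n", x$delta))
  cat(sprintf("  alpha (learning rate):           %.4g\n", x$alpha))
  cat(sprintf("  h_in (within-group boost):       %.4g\n", x$h_in))
  cat(sprintf("  h_bet0 + b_bet * s (avoidance):  %.4g + %.4g * s\n",
              x$h_bet0, x$b_bet))
  cat(sprintf("  prefactor:                       %.4g\n", x$prefactor))
  cat(sprintf("  noise_sd (city, on ln b):        %.4g\n", x$noise_sd))
  cat(sprintf("  individual_sd (respondent):      %.4g\n", x$individual_sd))
  invisible(x)
}

# Run code with a temporary RNG state seeded by `seed`; the caller's RNG
# stream is untouched.  All generators route their randomness through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
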