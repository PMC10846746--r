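#' Shifted-gamma log likelihood
#'
#' Log density of the shifted-gamma observation model: for each observed
#' response `m`, `y_m + shift_c ~ Gamma(exp(log_alpha_m), exp(log_alpha_m) /
#' (mu_m + shift_c))`, so `E[y_m] = mu_m` while effects stay on the additive
#' scale. Missing responses (NA in `y` or `FALSE` in `observed`) contribute
#' zero.
#'
#' @param y Observed response vector (length `M`), NA for missing.
#' @param mu Expected values, same length.
#' @param log_alpha Log shape per response, same length.
#' @param shift_c Shift constant `c >= 0`.
#' @param observed Optional logical mask; defaults to `!is.na(y)`.
#' @return The summed log likelihood (scalar).
#' @export
gamma_shift_loglik <- function(y, mu, log_alpha, shift_c, observed = NULL) {
  stopifnot(length(mu) == length(y), length(log_alpha) == length(y))
  observed <- observed %||% !is.na(y)
  observed <- observed & !is.na(y)
  if (!any(observed)) return(0)
  bad <- which(observed & (mu + shift_c <= 0))
  if (length(bad) > 0)
    abort(sprintf(
      "mu + shift_c <= 0 for response %d (mu = %.4g, shift_c = %.4g); shift_c is too small",
      bad[1], mu[bad[1]], shift_c))
  if (any(y[observed] + shift_c <= 0))
    abort("y + shift_c must be > 0 for observed responses")
  a <- exp(log_alpha[observed])
  sum(dgamma(y[observed] + shift_c, shape = a,
             rate = a / (mu[observed] + shift_c), log = TRUE))
}
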