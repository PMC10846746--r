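# Shared fixtures: everything is generated in code at test time.

`%||%` <- rlang::`%||%`

quick_sampler <- function(chains = 2, draws = 400, warmup = 400, seed = 1) {
  sampler_config(chains = chains, draws = draws, warmup = warmup, seed = seed)
}

small_cohort <- function(K = 8, sizes = c(4, 2, 2), n_obs = 3, p = 3, M = 2,
                         seed = 11, ...) {
  simulate_cohort(cohort_config(K = K, treatment_sizes = sizes, n_obs = n_obs,
                                p = p, M = M, seed = seed,
                                response_names = paste0("resp", seq_len(M)),
                                ...))
}

# Independent shifted-gamma log-density oracle, written from the density
# formula rather than dgamma(), for checking the likelihood implementation.
oracle_loglik <- function(y, mu, log_alpha, shift_c) {
  a <- exp(log_alpha)
  ys <- y + shift_c
  rate <- a / (mu + shift_c)
  sum(a * log(rate) - lgamma(a) + (a - 1) * log(ys) - rate * ys)
}

# Hand-built posterior in the shape fit_hsur() returns, with constant or
# supplied draws; lets graph/recommendation/evaluation logic be tested
# without MCMC.
fake_fit <- function(beta, g = NULL, b = NULL, intercept = NULL,
                     log_alpha = NULL, n_draws = 50, K = NULL, L = NULL,
                     shift_c = 5, Sigma_g = NULL, Sigma_b = NULL,
                     noise = 0, seed = 99,
                     predictors = NULL, responses = NULL) {
  p <- nrow(beta); M <- ncol(beta); pM <- p * M
  K <- K %||% (if (!is.null(b)) nrow(b) else 2L)
  L <- L %||% (if (!is.null(g)) nrow(g) else 1L)
  g <- g %||% matrix(0, L, pM)
  b <- b %||% matrix(0, K, pM)
  intercept <- intercept %||% rep(0, M)
  log_alpha <- log_alpha %||% rep(log(50), M)
  set.seed(seed)
  rep_draws <- function(v, dims) {
    base <- array(rep(v, each = n_draws), dim = c(n_draws, dims))
    if (noise > 0) base + array(rnorm(prod(dim(base)), 0, noise), dim(base))
    else base
  }
  draws <- list(
    beta = rep_draws(c(beta), c(p, M)),
    g = rep_draws(c(g), c(L, pM)),
    b = rep_draws(c(b), c(K, pM)),
    intercept_raw = rep_draws(intercept, M),
    log_alpha = rep_draws(log_alpha, M),
    Sigma_g = if (!is.null(Sigma_g)) rep_draws(c(Sigma_g), c(pM, pM)),
    Sigma_b = if (!is.null(Sigma_b)) rep_draws(c(Sigma_b), c(pM, pM))
  )
  structure(list(
    draws = draws, n_draws = n_draws, chains = 1L,
    diagnostics = tibble::tibble(parameter = character(), ess = numeric(),
                                 rhat = numeric()),
    meta = list(
      spec = model_spec(), sampler = quick_sampler(), shift_c = shift_c,
      center = rep(0, p), scale = rep(1, p),
      predictors = predictors %||% paste0("x", seq_len(p)),
      responses = responses %||% paste0("resp", seq_len(M)),
      binary = rep(FALSE, p),
      treat_of = rep(seq_len(L), length.out = K), K = K, L = L
    )
  ), class = "hsur_fit")
}

# Minimal cohort wrapper around an intake matrix for one or more patients.
fake_cohort_for <- function(X, patient = NULL, treatment = NULL,
                            Y = NULL, responses = NULL) {
  p <- ncol(X)
  n <- nrow(X)
  patient <- patient %||% rep(1L, n)
  treatment <- treatment %||% rep(1L, n)
  predictors <- paste0("x", seq_len(p))
  data <- tibble::tibble(patient = patient, treatment = treatment,
                         obs = stats::ave(patient, patient,
                                          FUN = seq_along))
  for (j in seq_len(p)) data[[paste0("x_", predictors[j])]] <- X[, j]
  responses <- responses %||%
    (if (!is.null(Y)) paste0("resp", seq_len(ncol(Y))) else "resp1")
  if (is.null(Y)) Y <- matrix(1, n, length(responses))
  for (m in seq_along(responses)) {
    data[[paste0("y_", responses[m])]] <- Y[, m]
    data[[paste0("src_", responses[m])]] <- ifelse(is.na(Y[, m]), "missing",
                                                   "observed")
  }
  structure(list(data = data, predictors = predictors,
                 responses = responses, binary = rep(FALSE, p),
                 truth = NULL, config = NULL), class = "cohort")
}

flat_ranges <- function(responses, lower, upper) {
  tibble::tibble(response = responses,
                 lower = rep_len(lower, length(responses)),
                 upper = rep_len(upper, length(responses)))
}
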