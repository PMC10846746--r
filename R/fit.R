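#' Model specification for the hierarchical gamma SUR
#'
#' @param variant One of `"two_level"` (general effects + treatment-level +
#'   patient-level deviations, full cross-response effect correlations at both
#'   levels), `"single_level"` (no treatment layer; patient deviations centered
#'   directly on the general effects) or `"separate_univariate"` (each response
#'   fitted independently with its own within-response effect covariance and no
#'   cross-response correlation parameters).
#' @param shift_c Shift constant of the shifted-gamma likelihood. `NULL`
#'   (default) resolves at fit time to `2 * max(abs(y))` over observed
#'   responses.
#' @param priors Named list overriding any of: `beta_sd` (scale of the normal
#'   prior on decorrelated general effects, default 5), `icpt_sd_mult`
#'   (intercept prior sd as a multiple of the response sd, default 10),
#'   `cov_scale` (`s0` in the inverse-Wishart prior `Sigma ~ IW(s0^2 I, pM +
#'   2)` on each effect covariance, default 0.5), `la_loc`, `la_sd` (normal
#'   prior on log shape, default 3 and 1.5).
#' @param responses Subset of responses to fit (indices or names); `NULL` fits
#'   all.
#' @param include_intercept Per-response intercept (default `TRUE`). With the
#'   intercept disabled predictors are scaled but not centered.
#' @param b_within_only Restrict the patient-level covariance to
#'   within-response blocks (an option for very small cohorts); default
#'   `FALSE`.
#' @return A `model_spec` object.
#' @export
model_spec <- function(variant = c("two_level", "single_level",
                                   "separate_univariate"),
                       shift_c = NULL,
                       priors = list(),
                       responses = NULL,
                       include_intercept = TRUE,
                       b_within_only = FALSE) {
  variant <- match.arg(variant)
  if (!is.null(shift_c) && shift_c < 0) abort("shift_c must be >= 0")
  defaults <- list(beta_sd = 5, icpt_sd_mult = 10, cov_scale = 0.5,
                   la_loc = NULL, la_sd = 1.5)
  unknown <- setdiff(names(priors), names(defaults))
  if (length(unknown) > 0)
    abort(sprintf("unknown prior component(s): %s",
                  paste(unknown, collapse = ", ")))
  defaults[names(priors)] <- priors
  structure(list(variant = variant, shift_c = shift_c, priors = defaults,
                 responses = responses,
                 include_intercept = include_intercept,
                 b_within_only = b_within_only),
            class = "model_spec")
}

#' Sampler configuration
#'
#' Defaults mirror the reference analysis: 4 chains, 3000 retained draws per
#' chain after a 1000-iteration warm-up. Reduce for simulation studies.
#'
#' @param chains Number of MCMC chains.
#' @param draws Retained draws per chain.
#' @param warmup Adaptation + burn-in iterations per chain.
#' @param thin Thinning interval.
#' @param seed Integer seed; fits are reproducible given the full config.
#' @export
sampler_config <- function(chains = 4, draws = 3000, warmup = 1000,
                           thin = 1, seed = 1L) {
  stopifnot(chains >= 1, draws >= 10, warmup >= 10)
  structure(list(chains = as.integer(chains), draws = as.integer(draws),
                 warmup = as.integer(warmup), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "sampler_config")
}

#' Fit the hierarchical gamma SUR model
#'
#' Draws from the posterior of the two-level hierarchical multivariate gamma
#' regression: shifted-gamma responses with additive expected values
#' `mu = intercept_m + sum_j x_j (beta_jm + g_ljm + b_kjm)`, treatment-level
#' deviations `g ~ N(0, Sigma_g)` and patient-level deviations
#' `b ~ N(0, Sigma_b)` whose `pM x pM` covariances carry within- and
#' cross-response effect correlations. General effects are sampled on the
#' decorrelated thin-QR scale (`beta_star`) over centered/scaled predictors
#' and mapped back to the original predictor units in the stored draws.
#' Missing response cells are marginalized by the sampler (likelihood
#' masking), which also yields their posterior-predictive imputations.
#'
#' Sampling uses Gibbs/slice updates (JAGS); effect covariances get conjugate
#' inverse-Wishart priors and their standard-deviation/correlation-Cholesky
#' factors `T`, `L` are derived per draw.
#'
#' @param cohort A `cohort`.
#' @param spec A [model_spec()].
#' @param sampler A [sampler_config()].
#' @return An object of class `hsur_fit` with elements `draws` (arrays indexed
#'   draw-first: `beta` (p x M, original scale), `beta_star`, `intercept_raw`,
#'   `g`, `b`, `log_alpha`, `Sigma_g`, `Sigma_b` (or per-response
#'   `Sigma_*_blocks` for the separate variant), `mu`), `diagnostics`
#'   (per-parameter ESS and split-Rhat), and `meta`.
#' @export
fit_hsur <- function(cohort, spec = model_spec(),
                     sampler = sampler_config()) {
  stopifnot(inherits(cohort, "cohort"), inherits(spec, "model_spec"),
            inherits(sampler, "sampler_config"))
  resp_idx <- resolve_responses(cohort, spec$responses)
  M <- length(resp_idx)
  p <- length(cohort$predictors)
  Y <- cohort_Y(cohort)[, resp_idx, drop = FALSE]
  obs_mask <- cohort_observed(cohort)[, resp_idx, drop = FALSE]
  Y[!obs_mask] <- NA
  shift_c <- spec$shift_c %||% (2 * max(abs(Y), na.rm = TRUE))
  if (any(Y + shift_c <= 0, na.rm = TRUE))
    abort("shift_c too small: some observed y + shift_c <= 0")

  X <- cohort_X(cohort)
  std <- standardize_predictors(X, cohort$binary,
                                center = spec$include_intercept)
  dec <- thin_qr(std$X)
  pat <- cohort$data$patient
  treat_of <- patient_treatment(cohort)
  if (any(is.na(treat_of))) abort("every patient needs a treatment label")
  K <- max(pat); L <- max(treat_of)

  if (spec$variant == "separate_univariate") {
    fit <- fit_separate(Y, std, dec, pat, treat_of, shift_c, spec, sampler)
  } else {
    fit <- fit_joint(Y, std, dec, pat, treat_of, shift_c, spec, sampler)
  }

  fit$meta <- list(
    spec = spec, sampler = sampler, shift_c = shift_c,
    qr = dec, center = std$center, scale = std$scale,
    predictors = cohort$predictors, responses = cohort$responses[resp_idx],
    resp_idx = resp_idx, binary = cohort$binary,
    pat = pat, treat_of = treat_of, K = K, L = L,
    X = X, Y = Y, obs_mask = obs_mask
  )
  class(fit) <- "hsur_fit"
  fit$diagnostics <- fit_diagnostics(fit)
  fit
}

resolve_responses <- function(cohort, responses) {
  if (is.null(responses)) return(seq_along(cohort$responses))
  if (is.character(responses)) {
    idx <- match(responses, cohort$responses)
    if (anyNA(idx))
      abort(sprintf("unknown response(s): %s",
                    paste(responses[is.na(idx)], collapse = ", ")))
    idx
  } else as.integer(responses)
}

# --- JAGS model builders ----------------------------------------------------

jags_model_joint <- function(two_level, intercept, b_within_only,
                             scalar = FALSE) {
  g_term <- if (two_level)
    " + inprod(Xs[r,1:p], g[treat[r], ((m-1)*p+1):(m*p)])" else ""
  icpt_term <- if (intercept) "icpt[m]" else "0"
  # a 1x1 effect covariance degenerates the Wishart to a gamma precision
  b_prior <- if (scalar) "
  for (k in 1:K) { b[k, 1] ~ dnorm(0, Ob) }
  Ob ~ dgamma(df / 2, Rscale / 2)" else if (b_within_only) "
  for (k in 1:K) { for (mm in 1:M) {
    b[k, ((mm-1)*p+1):(mm*p)] ~ dmnorm(zeros_p, Obm[1:p,1:p,mm])
  } }
  for (mm in 1:M) { Obm[1:p,1:p,mm] ~ dwish(Rscale_p, df_p) }" else "
  for (k in 1:K) { b[k, 1:pM] ~ dmnorm(zeros, Ob) }
  Ob ~ dwish(Rscale, df)"
  g_prior <- if (!two_level) "" else if (scalar) "
  for (l in 1:L) { g[l, 1] ~ dnorm(0, Og) }
  Og ~ dgamma(df / 2, Rscale / 2)" else "
  for (l in 1:L) { g[l, 1:pM] ~ dmnorm(zeros, Og) }
  Og ~ dwish(Rscale, df)"
  icpt_prior <- if (intercept) "
  for (m in 1:M) { icpt[m] ~ dnorm(icpt_loc[m], icpt_prec[m]) }" else ""
  paste0("model {
  for (r in 1:N) {
    for (m in 1:M) {
      ys[r,m] ~ dgamma(alpha[m], alpha[m] / mup[r,m])
      mup[r,m] <- max(mu[r,m] + c, 1e-10)
      mu[r,m] <- ", icpt_term,
  " + inprod(Q[r,1:p], bstar[((m-1)*p+1):(m*p)])", g_term,
  " + inprod(Xs[r,1:p], b[pat[r], ((m-1)*p+1):(m*p)])
    }
  }
  for (d in 1:pM) { bstar[d] ~ dnorm(0, prec_beta) }",
  icpt_prior, g_prior, b_prior, "
  for (m in 1:M) { alpha[m] <- exp(la[m]); la[m] ~ dnorm(la_loc, la_prec) }
}")
}

jags_model_single_resp <- function(intercept, scalar = FALSE) {
  icpt_term <- if (intercept) "icpt" else "0"
  icpt_prior <- if (intercept) "
  icpt ~ dnorm(icpt_loc, icpt_prec)" else ""
  covs <- if (scalar) "
  for (l in 1:L) { g[l, 1] ~ dnorm(0, Og) }
  for (k in 1:K) { b[k, 1] ~ dnorm(0, Ob) }
  Og ~ dgamma(df_p / 2, Rs_p / 2)
  Ob ~ dgamma(df_p / 2, Rs_p / 2)" else "
  for (l in 1:L) { g[l, 1:p] ~ dmnorm(zeros_p, Og) }
  for (k in 1:K) { b[k, 1:p] ~ dmnorm(zeros_p, Ob) }
  Og ~ dwish(Rscale_p, df_p)
  Ob ~ dwish(Rscale_p, df_p)"
  paste0("model {
  for (r in 1:N) {
    ys[r] ~ dgamma(alpha, alpha / mup[r])
    mup[r] <- max(mu[r] + c, 1e-10)
    mu[r] <- ", icpt_term, " + inprod(Q[r,1:p], bstar[1:p])
      + inprod(Xs[r,1:p], g[treat[r], 1:p])
      + inprod(Xs[r,1:p], b[pat[r], 1:p])
  }
  for (d in 1:p) { bstar[d] ~ dnorm(0, prec_beta) }",
  icpt_prior, covs, "
  alpha <- exp(la); la ~ dnorm(la_loc, la_prec)
}")
}

run_jags <- function(model_string, data, inits, monitor, sampler) {
  n_adapt <- max(100, sampler$warmup %/% 2)
  # short warm-ups trip JAGS's "adaptation incomplete" notice; burn-in below
  # finishes the job, so the notice is noise here
  jm <- withCallingHandlers(
    rjags::jags.model(textConnection(model_string), data = data,
                      inits = inits, n.chains = sampler$chains,
                      n.adapt = n_adapt, quiet = TRUE),
    warning = function(w) {
      if (grepl("Adaptation incomplete", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (sampler$warmup > n_adapt) update(jm, sampler$warmup - n_adapt)
  rjags::coda.samples(jm, variable.names = monitor,
                      n.iter = sampler$draws * sampler$thin,
                      thin = sampler$thin)
}

jags_inits <- function(sampler, init_list, offset = 0L) {
  lapply(seq_len(sampler$chains), function(ch) {
    c(init_list,
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = sampler$seed + offset + ch))
  })
}

# Extract named columns of an mcmc.list into a draws-major array.
pull_array <- function(samp, base, dims) {
  idx <- expand.grid(lapply(dims, seq_len))
  cols <- paste0(base, "[", do.call(paste, c(idx, sep = ",")), "]")
  mat <- do.call(rbind, lapply(samp, function(ch) as.matrix(ch)[, cols,
                                                                drop = FALSE]))
  array(mat, dim = c(nrow(mat), dims))
}
pull_vec <- function(samp, base, d) {
  cols <- if (d == 1) base else paste0(base, "[", seq_len(d), "]")
  do.call(rbind, lapply(samp, function(ch) as.matrix(ch)[, cols,
                                                         drop = FALSE]))
}

init_log_alpha <- function(Y, shift_c) {
  a <- vapply(seq_len(ncol(Y)), function(m) {
    y <- Y[, m]; y <- y[!is.na(y)]
    s <- stats::sd(y)
    if (!is.finite(s) || s < 1e-8) s <- 0.05 * (mean(y) + shift_c)
    ((mean(y) + shift_c) / s)^2
  }, numeric(1))
  pmin(pmax(log(a), 0), 9)
}

fit_joint <- function(Y, std, dec, pat, treat_of, shift_c, spec, sampler) {
  p <- ncol(std$X); M <- ncol(Y); pM <- p * M
  K <- max(pat); L <- max(treat_of)
  two_level <- spec$variant == "two_level"
  scalar <- pM == 1
  if (spec$b_within_only && p == 1)
    abort("b_within_only needs p > 1; use the default full covariance")
  pr <- spec$priors
  la_loc <- pr$la_loc %||% mean(init_log_alpha(Y, shift_c))
  ysd <- apply(Y, 2, stats::sd, na.rm = TRUE)
  ysd[!is.finite(ysd) | ysd < 1e-8] <- 1
  data <- list(
    ys = Y + shift_c, Q = dec$Q_star, Xs = std$X,
    pat = pat, treat = treat_of[pat],
    N = nrow(Y), M = M, p = p, pM = pM, K = K, L = L, c = shift_c,
    prec_beta = 1 / pr$beta_sd^2,
    zeros = rep(0, pM),
    Rscale = diag(pr$cov_scale^2, pM), df = pM + 2,
    la_loc = la_loc, la_prec = 1 / pr$la_sd^2
  )
  if (scalar) { data$Rscale <- pr$cov_scale^2; data$zeros <- NULL }
  if (!two_level) { data$treat <- NULL; data$L <- NULL }
  if (spec$include_intercept) {
    data$icpt_loc <- colMeans(Y, na.rm = TRUE)
    data$icpt_prec <- 1 / (pr$icpt_sd_mult * ysd)^2
  }
  if (spec$b_within_only) {
    data$zeros_p <- rep(0, p)
    data$Rscale_p <- diag(pr$cov_scale^2, p)
    data$df_p <- p + 2
    if (!two_level) { data$Rscale <- NULL; data$df <- NULL; data$zeros <- NULL }
  }
  init <- list(bstar = rep(0, pM), la = init_log_alpha(Y, shift_c))
  if (spec$include_intercept) init$icpt <- colMeans(Y, na.rm = TRUE)
  monitor <- c("bstar", "la", "b", "mu",
               if (spec$include_intercept) "icpt",
               if (two_level) c("g", "Og"),
               if (spec$b_within_only) "Obm" else "Ob")
  model <- jags_model_joint(two_level, spec$include_intercept,
                            spec$b_within_only, scalar)
  samp <- run_jags(model, data, jags_inits(sampler, init), monitor, sampler)

  n_draw <- sampler$draws * sampler$chains
  bstar <- pull_vec(samp, "bstar", pM)
  # back to original predictor scale: beta_std = R*^{-1} beta*, beta = beta_std / s
  beta <- array(0, c(n_draw, p, M))
  for (m in seq_len(M)) {
    blk <- (m - 1) * p + seq_len(p)
    beta[, , m] <- t(dec$R_star_inv %*% t(bstar[, blk, drop = FALSE])) /
      matrix(std$scale, n_draw, p, byrow = TRUE)
  }
  rescale_fx <- function(arr) {    # [draw, unit, pM] std -> original scale
    sc <- rep(std$scale, M)
    sweep(arr, 3, sc, "/")
  }
  g <- if (two_level) rescale_fx(pull_array(samp, "g", c(L, pM))) else NULL
  b <- rescale_fx(pull_array(samp, "b", c(K, pM)))
  la <- pull_vec(samp, "la", M)
  icpt <- if (spec$include_intercept) pull_vec(samp, "icpt", M)
          else matrix(0, n_draw, M)
  mu <- pull_array(samp, "mu", c(nrow(Y), M))

  orig_cov <- function(prec_arr) {   # invert precision draws, rescale
    sc <- rep(std$scale, M)
    out <- array(0, dim(prec_arr))
    for (i in seq_len(dim(prec_arr)[1])) {
      S <- chol2inv(chol(prec_arr[i, , ]))
      out[i, , ] <- S / outer(sc, sc)
    }
    out
  }
  scalar_cov <- function(base) {
    prec <- pull_vec(samp, base, 1)
    array(1 / prec / std$scale[1]^2, c(n_draw, 1, 1))
  }
  draws <- list(beta_star = bstar, beta = beta, intercept_raw = icpt,
                g = g, b = b, log_alpha = la, mu = mu)
  if (spec$b_within_only) {
    Obm <- pull_array(samp, "Obm", c(p, p, M))
    draws$Sigma_b_blocks <- lapply(seq_len(M), function(m) {
      blk <- array(0, c(n_draw, p, p))
      for (i in seq_len(n_draw))
        blk[i, , ] <- chol2inv(chol(Obm[i, , , m])) / outer(std$scale,
                                                            std$scale)
      blk
    })
  } else if (scalar) {
    draws$Sigma_b <- scalar_cov("Ob")
  } else {
    draws$Sigma_b <- orig_cov(pull_array(samp, "Ob", c(pM, pM)))
  }
  if (two_level)
    draws$Sigma_g <- if (scalar) scalar_cov("Og")
                     else orig_cov(pull_array(samp, "Og", c(pM, pM)))
  list(draws = draws, n_draws = n_draw, chains = sampler$chains,
       samples = samp)
}

fit_separate <- function(Y, std, dec, pat, treat_of, shift_c, spec, sampler) {
  p <- ncol(std$X); M <- ncol(Y); pM <- p * M
  K <- max(pat); L <- max(treat_of)
  pr <- spec$priors
  n_draw <- sampler$draws * sampler$chains
  beta <- array(0, c(n_draw, p, M))
  bstar <- matrix(0, n_draw, pM)
  g <- array(0, c(n_draw, L, pM))
  b <- array(0, c(n_draw, K, pM))
  la <- matrix(0, n_draw, M)
  icpt <- matrix(0, n_draw, M)
  mu <- array(0, c(n_draw, nrow(Y), M))
  Sg_blocks <- vector("list", M)
  Sb_blocks <- vector("list", M)
  samples <- vector("list", M)
  scalar <- p == 1
  model <- jags_model_single_resp(spec$include_intercept, scalar)
  for (m in seq_len(M)) {
    y <- Y[, m]
    ysd <- stats::sd(y, na.rm = TRUE)
    if (!is.finite(ysd) || ysd < 1e-8) ysd <- 1
    data <- list(
      ys = y + shift_c, Q = dec$Q_star, Xs = std$X,
      pat = pat, treat = treat_of[pat],
      N = length(y), p = p, K = K, L = L, c = shift_c,
      prec_beta = 1 / pr$beta_sd^2, df_p = p + 2,
      la_loc = pr$la_loc %||% init_log_alpha(Y[, m, drop = FALSE], shift_c),
      la_prec = 1 / pr$la_sd^2
    )
    if (scalar) data$Rs_p <- pr$cov_scale^2
    else { data$zeros_p <- rep(0, p); data$Rscale_p <- diag(pr$cov_scale^2, p) }
    if (spec$include_intercept) {
      data$icpt_loc <- mean(y, na.rm = TRUE)
      data$icpt_prec <- 1 / (pr$icpt_sd_mult * ysd)^2
    }
    init <- list(bstar = rep(0, p),
                 la = init_log_alpha(Y[, m, drop = FALSE], shift_c))
    if (spec$include_intercept) init$icpt <- mean(y, na.rm = TRUE)
    monitor <- c("bstar", "la", "g", "b", "Og", "Ob", "mu",
                 if (spec$include_intercept) "icpt")
    samp <- run_jags(model, data, jags_inits(sampler, init, offset = m * 100L),
                     monitor, sampler)
    samples[[m]] <- samp
    blk <- (m - 1) * p + seq_len(p)
    bs <- pull_vec(samp, "bstar", p)
    bstar[, blk] <- bs
    beta[, , m] <- t(dec$R_star_inv %*% t(bs)) /
      matrix(std$scale, n_draw, p, byrow = TRUE)
    g[, , blk] <- sweep(pull_array(samp, "g", c(L, p)), 3, std$scale, "/")
    b[, , blk] <- sweep(pull_array(samp, "b", c(K, p)), 3, std$scale, "/")
    la[, m] <- pull_vec(samp, "la", 1)
    if (spec$include_intercept) icpt[, m] <- pull_vec(samp, "icpt", 1)
    mu[, , m] <- pull_array(samp, "mu", nrow(Y))
    inv_blk <- function(base) {
      if (scalar)
        return(array(1 / pull_vec(samp, base, 1) / std$scale[1]^2,
                     c(n_draw, 1, 1)))
      pr_arr <- pull_array(samp, base, c(p, p))
      out <- array(0, c(n_draw, p, p))
      for (i in seq_len(n_draw))
        out[i, , ] <- chol2inv(chol(pr_arr[i, , ])) / outer(std$scale,
                                                            std$scale)
      out
    }
    Sg_blocks[[m]] <- inv_blk("Og")
    Sb_blocks[[m]] <- inv_blk("Ob")
  }
  list(draws = list(beta_star = bstar, beta = beta, intercept_raw = icpt,
                    g = g, b = b, log_alpha = la, mu = mu,
                    Sigma_g_blocks = Sg_blocks, Sigma_b_blocks = Sb_blocks),
       n_draws = n_draw, chains = sampler$chains, samples = samples)
}

# --- diagnostics ------------------------------------------------------------

split_rhat <- function(mat_by_chain) {
  # mat_by_chain: list of draws x 1 vectors (one per chain); split each in two
  halves <- unlist(lapply(mat_by_chain, function(v) {
    n <- length(v) %/% 2
    list(v[seq_len(n)], v[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W < 1e-300) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

fit_diagnostics <- function(fit) {
  samp_list <- if (is.list(fit$samples) &&
                   !inherits(fit$samples, "mcmc.list"))
    fit$samples else list(fit$samples)
  purrr::map_dfr(samp_list, function(samp) {
    mats <- lapply(samp, as.matrix)
    keep <- grep("^(bstar|la|icpt|g\\[|b\\[)", colnames(mats[[1]]),
                 value = TRUE)
    ess <- tryCatch(
      coda::effectiveSize(coda::as.mcmc.list(
        lapply(mats, function(m) coda::mcmc(m[, keep, drop = FALSE])))),
      error = function(e) rep(NA_real_, length(keep)))
    rhat <- vapply(keep, function(cn)
      split_rhat(lapply(mats, function(m) m[, cn])), numeric(1))
    tibble(parameter = keep, ess = as.numeric(ess[keep]), rhat = rhat)
  })
}

#' @export
print.hsur_fit <- function(x, ...) {
  cat(sprintf(
    "<hsur_fit> variant=%s, %d draws (%d chains), p=%d predictors, M=%d responses\n",
    x$meta$spec$variant, x$n_draws, x$chains,
    length(x$meta$predictors), length(x$meta$responses)))
  cat(sprintf("  shift_c=%.3g, mean ESS=%.0f, mean Rhat=%.3f\n",
              x$meta$shift_c, mean(x$diagnostics$ess, na.rm = TRUE),
              mean(x$diagnostics$rhat, na.rm = TRUE)))
  invisible(x)
}
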