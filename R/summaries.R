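#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy posterior effect summaries
#'
#' Summarizes nutrient effects at a chosen level of the hierarchy: `"general"`
#' gives the population effects `beta_jm`, `"treatment"` adds the
#' treatment-level deviation (`beta + g`), and `"personal"` the full personal
#' effect (`beta + g + b`). Each row carries the posterior mean and a credible
#' interval, plus the posterior mean between-treatment effect sd `sigma_g`
#' where the fitted variant has a treatment layer.
#'
#' @param x An `hsur_fit`.
#' @param level `"general"`, `"treatment"` or `"personal"`.
#' @param conf_level Credible-interval mass (default 0.9).
#' @param ... Unused.
#' @return A tibble with columns `level`, `unit` (treatment or patient id, NA
#'   for general), `predictor`, `response`, `estimate`, `conf.low`,
#'   `conf.high`, `sigma_g`.
#' @method tidy hsur_fit
#' @export
tidy.hsur_fit <- function(x, level = c("general", "treatment", "personal"),
                          conf_level = 0.9, ...) {
  level <- match.arg(level)
  summarize_effects(x, level, conf_level)
}

#' @rdname tidy.hsur_fit
#' @param post An `hsur_fit`.
#' @export
summarize_effects <- function(post, level = c("general", "treatment",
                                              "personal"),
                              conf_level = 0.9) {
  level <- match.arg(level)
  p <- length(post$meta$predictors); M <- length(post$meta$responses)
  qs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  sig_g <- sigma_g_mean(post)    # p x M or NULL

  units <- switch(level,
    general = NA_integer_,
    treatment = seq_len(post$meta$L),
    personal = seq_len(post$meta$K))
  purrr::map_dfr(units, function(u) {
    rows <- tidyr::expand_grid(m = seq_len(M), j = seq_len(p))
    purrr::pmap_dfr(rows, function(m, j) {
      d <- (m - 1) * p + j
      dr <- post$draws$beta[, j, m]
      if (level %in% c("treatment", "personal") && !is.null(post$draws$g)) {
        l <- if (level == "treatment") u else post$meta$treat_of[u]
        dr <- dr + post$draws$g[, l, d]
      }
      if (level == "personal") dr <- dr + post$draws$b[, u, d]
      q <- unname(quantile(dr, qs))
      tibble(level = level, unit = u,
             predictor = post$meta$predictors[j],
             response = post$meta$responses[m],
             estimate = mean(dr), conf.low = q[1], conf.high = q[2],
             sigma_g = if (is.null(sig_g)) NA_real_ else sig_g[j, m])
    })
  })
}

sigma_g_mean <- function(post) {
  p <- length(post$meta$predictors); M <- length(post$meta$responses)
  if (!is.null(post$draws[["Sigma_g"]])) {
    matrix(sqrt(pmax(rowMeans(apply(post$draws[["Sigma_g"]], 1, diag)), 0)),
           p, M)
  } else if (!is.null(post$draws[["Sigma_g_blocks"]])) {
    sapply(post$draws[["Sigma_g_blocks"]], function(blk)
      sqrt(pmax(rowMeans(apply(blk, 1, diag)), 0)))
  } else NULL
}

#' @method glance hsur_fit
#' @export
glance.hsur_fit <- function(x, ...) {
  tibble(
    variant = x$meta$spec$variant,
    chains = x$chains,
    n_draws = x$n_draws,
    shift_c = x$meta$shift_c,
    ess_mean = mean(x$diagnostics$ess, na.rm = TRUE),
    rhat_mean = mean(x$diagnostics$rhat, na.rm = TRUE),
    rhat_max = max(x$diagnostics$rhat, na.rm = TRUE)
  )
}

#' Posterior covariance structure of hierarchical effects
#'
#' Returns the posterior-mean effect covariance at the requested level,
#' decomposed as `Sigma = T C T'` with `T = diag(sigma)` and `C = L L'`
#' (lower-triangular correlation Cholesky). For the separate-univariate
#' variant the cross-response blocks were never modelled; the matrix is
#' assembled block-diagonally and flagged with `cross_absent = TRUE`.
#'
#' @param fit An `hsur_fit`.
#' @param level `"treatment"` or `"personal"`.
#' @return An object of class `covariance_structure`: list with `sigma`,
#'   `C`, `L_corr`, `Sigma`, `level`, `cross_absent`.
#' @export
cov_structure <- function(fit, level = c("treatment", "personal")) {
  level <- match.arg(level)
  p <- length(fit$meta$predictors); M <- length(fit$meta$responses)
  nm <- if (level == "treatment") "Sigma_g" else "Sigma_b"
  cross_absent <- FALSE
  if (!is.null(fit$draws[[nm]])) {
    Sigma <- apply(fit$draws[[nm]], c(2, 3), mean)
  } else if (!is.null(fit$draws[[paste0(nm, "_blocks")]])) {
    blocks <- fit$draws[[paste0(nm, "_blocks")]]
    Sigma <- matrix(0, p * M, p * M)
    for (m in seq_len(M)) {
      blk <- (m - 1) * p + seq_len(p)
      Sigma[blk, blk] <- apply(blocks[[m]], c(2, 3), mean)
    }
    cross_absent <- TRUE
  } else {
    abort(sprintf("fit has no %s-level covariance draws", level))
  }
  tcl <- cov_to_tcl(Sigma)
  structure(list(sigma = tcl$sigma, C = tcl$C, L_corr = tcl$L,
                 Sigma = Sigma, level = level, cross_absent = cross_absent),
            class = "covariance_structure")
}

#' Split an effect correlation matrix into within/cross-response blocks
#'
#' Partitions a `pM x pM` effect correlation matrix into the `M` within-model
#' blocks `D^(m)` on the diagonal and the cross-model blocks `C^(nm)` off the
#' diagonal; [assemble_correlation()] reverses the partition exactly.
#'
#' @param C Correlation matrix of order `p * M`.
#' @param p,M Block dimensions.
#' @return A list with `within` (list of `M` matrices) and `cross` (an
#'   `M x M` list-matrix; `cross[[n, m]]` for `n != m`, satisfying
#'   `C^(nm) = t(C^(mn))`).
#' @export
correlation_blocks <- function(C, p, M) {
  stopifnot(nrow(C) == p * M)
  idx <- function(m) (m - 1) * p + seq_len(p)
  within <- lapply(seq_len(M), function(m) C[idx(m), idx(m), drop = FALSE])
  cross <- matrix(list(), M, M)
  for (n in seq_len(M)) for (m in seq_len(M))
    if (n != m) cross[[n, m]] <- C[idx(n), idx(m), drop = FALSE]
  list(within = within, cross = cross, p = p, M = M)
}

#' @rdname correlation_blocks
#' @param blocks A result of [correlation_blocks()].
#' @export
assemble_correlation <- function(blocks) {
  p <- blocks$p; M <- blocks$M
  C <- matrix(0, p * M, p * M)
  idx <- function(m) (m - 1) * p + seq_len(p)
  for (m in seq_len(M)) C[idx(m), idx(m)] <- blocks$within[[m]]
  for (n in seq_len(M)) for (m in seq_len(M))
    if (n != m) C[idx(n), idx(m)] <- blocks$cross[[n, m]]
  C
}

#' Posterior predictive check
#'
#' Draws replicated concentrations at the observed predictors from a thinned
#' set of posterior draws and compares them with the observed data: for an
#' unbiased model the replicated and observed distributions align. Missing
#' cells are excluded from all statistics.
#'
#' @param post An `hsur_fit`.
#' @param n_rep Number of replicated data sets (posterior draws used).
#' @param seed RNG seed for the gamma noise.
#' @return An `hsur_ppc` object: `summary` tibble with per-response observed
#'   mean, replicated mean, `bias` (replicated - observed) and its Monte Carlo
#'   SE; `y_rep` array `[rep, row, response]`; the observed matrix.
#' @export
posterior_predictive_check <- function(post, n_rep = 200, seed = 1L) {
  stopifnot(inherits(post, "hsur_fit"))
  n_rep <- min(n_rep, post$n_draws)
  idx <- round(seq(1, post$n_draws, length.out = n_rep))
  mu <- post$draws$mu[idx, , , drop = FALSE]
  alpha <- exp(post$draws$log_alpha[idx, , drop = FALSE])
  cshift <- post$meta$shift_c
  N <- dim(mu)[2]; M <- dim(mu)[3]
  y_rep <- with_seed(seed, {
    arr <- array(0, c(n_rep, N, M))
    for (m in seq_len(M)) {
      a <- matrix(alpha[, m], n_rep, N)
      arr[, , m] <- matrix(
        rgamma(n_rep * N, shape = a, rate = a / (mu[, , m] + cshift)),
        n_rep, N) - cshift
    }
    arr
  })
  obs <- post$meta$Y
  mask <- post$meta$obs_mask
  summary <- purrr::map_dfr(seq_len(M), function(m) {
    ok <- mask[, m]
    rep_means <- rowMeans(y_rep[, ok, m, drop = FALSE])
    tibble(response = post$meta$responses[m],
           obs_mean = mean(obs[ok, m]),
           rep_mean = mean(rep_means),
           bias = mean(rep_means) - mean(obs[ok, m]),
           mc_se = stats::sd(rep_means) / sqrt(n_rep))
  })
  structure(list(summary = summary, y_rep = y_rep, observed = obs,
                 mask = mask, responses = post$meta$responses),
            class = "hsur_ppc")
}

#' @export
print.hsur_ppc <- function(x, ...) {
  cat("<hsur_ppc> replicated-vs-observed concentration summary\n")
  print(x$summary)
  invisible(x)
}

#' Impute missing response cells from the fitted model
#'
#' Replaces missing concentration cells with their posterior-predictive
#' expected values (the posterior mean of the cell's expected concentration)
#' and flags them `"imputed"` in the provenance mask. Rows in which every
#' response is missing are left untouched with a warning, as the model has no
#' observation there to anchor the row.
#'
#' @param post An `hsur_fit` fitted to `cohort` (with likelihood masking of
#'   the missing cells).
#' @param cohort The cohort the fit was run on.
#' @return A `cohort` with imputed cells and updated `src_*` columns.
#' @export
impute_missing <- function(post, cohort) {
  stopifnot(inherits(post, "hsur_fit"), inherits(cohort, "cohort"))
  if (dim(post$draws$mu)[2] != nrow(cohort$data))
    abort("fit and cohort have different numbers of observations")
  mu_hat <- apply(post$draws$mu, c(2, 3), mean)
  out <- cohort
  resp <- post$meta$responses
  mask <- post$meta$obs_mask
  all_missing_row <- rowSums(mask) == 0
  if (any(all_missing_row))
    warn(sprintf(
      "%d row(s) have no observed responses at all; left unimputed",
      sum(all_missing_row)))
  for (m in seq_along(resp)) {
    yc <- paste0("y_", resp[m]); sc <- paste0("src_", resp[m])
    fill <- !mask[, m] & !all_missing_row
    if (any(fill)) {
      out$data[[yc]][fill] <- mu_hat[fill, m]
      out$data[[sc]][fill] <- "imputed"
    }
  }
  out
}
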