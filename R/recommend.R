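#' Recommendation query
#'
#' Defines which nutrients are queried for a personalized intake
#' recommendation and how the acceptance sampling is run. The default queries
#' potassium and phosphorus with uniform proposals on (0, 5800) and
#' (0, 2550) mg/d — population-level maximum intakes — and asks for 90%
#' confidence that every concentration lands inside its target range.
#'
#' @param queried Character vector of queried predictor names.
#' @param proposal_bounds Named list of `c(lower, upper)` proposal bounds per
#'   queried nutrient; defaults are supplied for `potassium` and
#'   `phosphorus`.
#' @param S Number of proposal samples.
#' @param conf_level Target confidence `c` in `[0, 1)`.
#' @param l_x,l_beta Point-estimate rule for intake and effect nodes:
#'   `"mean"` (default) or a quantile in (0, 1) for sensitivity analysis.
#' @param seed RNG seed for the proposal sampling.
#' @return A `recommendation_query` object.
#' @export
recommendation_query <- function(queried = c("potassium", "phosphorus"),
                                 proposal_bounds = NULL,
                                 S = 10000,
                                 conf_level = 0.9,
                                 l_x = "mean", l_beta = "mean",
                                 seed = 1L) {
  defaults <- list(potassium = c(0, 5800), phosphorus = c(0, 2550))
  proposal_bounds <- proposal_bounds %||% defaults[queried]
  if (!all(queried %in% names(proposal_bounds)))
    abort("proposal_bounds must name every queried nutrient")
  proposal_bounds <- proposal_bounds[queried]
  for (b in proposal_bounds)
    if (length(b) != 2 || b[1] >= b[2])
      abort("each proposal bound must be c(lower, upper) with lower < upper")
  if (conf_level < 0 || conf_level >= 1)
    abort("conf_level must be in [0, 1)")
  check_l <- function(l, nm) {
    if (identical(l, "mean")) return()
    if (!is.numeric(l) || l <= 0 || l >= 1)
      abort(sprintf("%s must be \"mean\" or a quantile in (0, 1)", nm))
  }
  check_l(l_x, "l_x"); check_l(l_beta, "l_beta")
  if (S < 0) abort("S must be >= 0")
  structure(list(queried = queried, proposal_bounds = proposal_bounds,
                 S = as.integer(S), conf_level = conf_level,
                 l_x = l_x, l_beta = l_beta, seed = as.integer(seed)),
            class = "recommendation_query")
}

# Point estimates of every node used by the sampling: intakes at l_x,
# effects/intercept at l_beta, gamma shape at its posterior mean.
graph_point_estimates <- function(graph, query) {
  bad <- setdiff(query$queried, graph$predictors)
  if (length(bad) > 0)
    abort(sprintf("queried nutrient(s) not among predictors: %s",
                  paste(bad, collapse = ", ")))
  p <- length(graph$predictors); M <- length(graph$responses)
  x_hat <- if (identical(query$l_x, "mean")) graph$intakes$mean
           else stats::qnorm(query$l_x, graph$intakes$mean, graph$intakes$sd)
  est_q <- function(draws, l) {
    if (identical(l, "mean")) mean(draws) else unname(quantile(draws, l))
  }
  eff_hat <- matrix(0, p, M)
  icpt_hat <- numeric(M)
  for (m in seq_len(M)) {
    for (j in seq_len(p))
      eff_hat[j, m] <- est_q(graph$effect_draws[, j, m], query$l_beta)
    icpt_hat[m] <- est_q(graph$intercept_draws[, m], query$l_beta)
  }
  alpha_hat <- colMeans(graph$alpha_draws)
  q_idx <- match(query$queried, graph$predictors)
  list(x_hat = x_hat, eff_hat = eff_hat, icpt_hat = icpt_hat,
       alpha_hat = alpha_hat, q_idx = q_idx)
}

#' Baseline expected concentrations without the queried nutrients
#'
#' The fixed starting point of a recommendation: the expected value of each
#' concentration with the queried nutrients' contributions removed,
#' `mu_q0_m = intercept_m + sum_{j not queried} x_hat_j * eff_hat_jm`, using
#' personal-level point estimates of intakes and effects.
#'
#' @param graph A `personal_graph`.
#' @param query A [recommendation_query()].
#' @return Named numeric vector, one baseline per response.
#' @export
baseline_mu <- function(graph, query) {
  est <- graph_point_estimates(graph, query)
  keep <- setdiff(seq_along(graph$predictors), est$q_idx)
  mu0 <- est$icpt_hat +
    as.numeric(crossprod(est$eff_hat[keep, , drop = FALSE], est$x_hat[keep]))
  setNames(mu0, graph$responses)
}

#' Sampling limits for one concentration
#'
#' The proposal-stage limits for a concentration: the target range, widened to
#' include the baseline `mu_q0` when it falls outside, so the constrained
#' sampling cannot fail outright: `l_m = min(mu_q0, y_lo)`,
#' `u_m = max(mu_q0, y_hi)`.
#'
#' @param mu_q0 Baseline expected concentration.
#' @param y_lo,y_hi Target range.
#' @return Numeric `c(l, u)`.
#' @export
sampling_limits <- function(mu_q0, y_lo, y_hi) {
  if (y_lo >= y_hi) abort("y_lo must be < y_hi")
  c(min(mu_q0, y_lo), max(mu_q0, y_hi))
}

#' Probability mass of a shifted-gamma concentration inside a range
#'
#' `P(y_lo <= Y <= y_hi)` for `Y + shift_c ~ Gamma(alpha, alpha / (mu +
#' shift_c))` — the confidence that a concentration with expected value `mu`
#' lands inside its target range.
#'
#' @param mu Expected concentration (vectorized).
#' @param alpha Gamma shape.
#' @param y_lo,y_hi Target range.
#' @param shift_c Shift constant.
#' @return Probabilities in `[0, 1]`.
#' @export
gamma_confidence <- function(mu, alpha, y_lo, y_hi, shift_c) {
  if (y_lo >= y_hi) abort("degenerate range: y_lo must be < y_hi")
  if (any(alpha <= 0)) abort("alpha must be > 0")
  out <- numeric(length(mu))
  ok <- mu + shift_c > 0
  rate <- alpha / (mu[ok] + shift_c)
  out[ok] <- pgamma(pmax(y_hi + shift_c, 0), alpha, rate = rate) -
    pgamma(pmax(y_lo + shift_c, 0), alpha, rate = rate)
  out
}

# Evaluate per-response and overall confidences for a matrix of proposals
# (S x R) against the original target ranges.
evaluate_proposals <- function(Q, est, mu_q0, ranges, shift_c) {
  M <- length(mu_q0)
  eff_q <- est$eff_hat[est$q_idx, , drop = FALSE]       # R x M
  conf <- matrix(0, nrow(Q), M)
  mu_all <- Q %*% eff_q + matrix(mu_q0, nrow(Q), M, byrow = TRUE)
  for (m in seq_len(M))
    conf[, m] <- gamma_confidence(mu_all[, m], est$alpha_hat[m],
                                  ranges$lower[m], ranges$upper[m], shift_c)
  list(conf = conf, overall = apply(conf, 1, min), mu = mu_all)
}

ordered_ranges <- function(graph) {
  if (is.null(graph$ranges))
    abort("personal graph has no target ranges; supply `ranges` when building it")
  rg <- graph$ranges[match(graph$responses, graph$ranges$response), ]
  if (anyNA(rg$lower) || anyNA(rg$upper))
    abort("target ranges missing for some responses")
  rg
}

finalize_recommendation <- function(Q, ev, mu_q0, limits, query, graph,
                                    method) {
  accepted <- which(ev$overall > query$conf_level)
  succeeded <- length(accepted) > 0
  bounds <- purrr::map_dfr(seq_along(query$queried), function(r) {
    if (succeeded) {
      q <- unname(quantile(Q[accepted, r], c(0.025, 0.975)))
    } else q <- c(NA_real_, NA_real_)
    tibble(nutrient = query$queried[r], q_min = q[1], q_max = q[2])
  })
  samples <- as_tibble(setNames(as.data.frame(Q), query$queried))
  for (m in seq_along(graph$responses))
    samples[[paste0("conf_", graph$responses[m])]] <- ev$conf[, m]
  samples$confidence <- ev$overall
  structure(list(
    samples = samples,
    accepted = samples[accepted, , drop = FALSE],
    bounds = bounds,
    mu_q0 = mu_q0,
    limits = limits,
    p_m_max = setNames(apply(ev$conf, 2, max), graph$responses),
    p_max = max(ev$overall),
    succeeded = succeeded,
    conf_level = query$conf_level,
    patient = graph$patient,
    query = query,
    method = method
  ), class = "recommendation")
}

#' Personalized intake recommendation by multivariate acceptance sampling
#'
#' Implements the acceptance-sampling recommendation: intake proposals for the
#' queried nutrients are drawn uniformly from their proposal boxes subject to
#' every response's point-estimate mean `mu_q0_m + sum_r q_r eff_rm` lying
#' within the (baseline-widened) sampling limits; each proposal's confidence
#' is the minimum across responses of the shifted-gamma probability mass
#' inside the original target range; proposals with confidence above
#' `conf_level` form the accepted set whose per-nutrient 2.5%/97.5% quantiles
#' are the reported recommendation. Maximum per-response and overall
#' confidences are tracked even when no proposal is accepted.
#'
#' For up to two queried nutrients the constrained proposals are drawn by
#' exact rejection sampling; larger queries use hit-and-run sampling over the
#' constrained polytope.
#'
#' @param graph A `personal_graph` built with target ranges.
#' @param query A [recommendation_query()].
#' @return A `recommendation` object; see [recommendation_query()] for the
#'   sampling controls and `tidy()`/`glance()` for summaries.
#' @export
recommend <- function(graph, query = recommendation_query()) {
  stopifnot(inherits(graph, "personal_graph"),
            inherits(query, "recommendation_query"))
  if (query$S == 0) abort("S must be > 0")
  est <- graph_point_estimates(graph, query)
  rg <- ordered_ranges(graph)
  mu_q0 <- baseline_mu(graph, query)
  limits <- purrr::map_dfr(seq_along(mu_q0), function(m) {
    lu <- sampling_limits(mu_q0[m], rg$lower[m], rg$upper[m])
    tibble(response = graph$responses[m], l = lu[1], u = lu[2])
  })
  R <- length(query$queried)
  lo <- vapply(query$proposal_bounds, `[`, numeric(1), 1)
  hi <- vapply(query$proposal_bounds, `[`, numeric(1), 2)
  eff_q <- est$eff_hat[est$q_idx, , drop = FALSE]

  in_region <- function(Q) {
    mu <- Q %*% eff_q + matrix(mu_q0, nrow(Q), length(mu_q0), byrow = TRUE)
    ok <- rep(TRUE, nrow(Q))
    for (m in seq_along(mu_q0))
      ok <- ok & mu[, m] >= limits$l[m] & mu[, m] <= limits$u[m]
    ok
  }

  with_seed(query$seed, {
    if (R <= 2) {
      acc <- matrix(0, 0, R)
      tries <- 0L
      first_batch <- NULL
      while (nrow(acc) < query$S && tries < 400L) {
        batch <- matrix(runif(query$S * R, rep(lo, each = query$S),
                              rep(hi, each = query$S)), query$S, R)
        if (is.null(first_batch)) first_batch <- batch
        acc <- rbind(acc, batch[in_region(batch), , drop = FALSE])
        tries <- tries + 1L
      }
      if (nrow(acc) == 0) {
        # constrained region (numerically) empty: report diagnostics from
        # unconstrained proposals
        ev <- evaluate_proposals(first_batch, est, mu_q0, rg, graph$shift_c)
        res <- finalize_recommendation(first_batch, ev, mu_q0, limits, query,
                                       graph, "rejection")
        res$succeeded <- FALSE
        res$accepted <- res$samples[0, ]
        res$bounds$q_min <- NA_real_
        res$bounds$q_max <- NA_real_
        res$region_empty <- TRUE
        return(res)
      }
      Qm <- acc[seq_len(min(nrow(acc), query$S)), , drop = FALSE]
    } else {
      Qm <- hit_and_run(query$S, lo, hi, in_region)
      if (is.null(Qm)) abort("could not find a feasible starting point")
    }
    ev <- evaluate_proposals(Qm, est, mu_q0, rg, graph$shift_c)
    res <- finalize_recommendation(Qm, ev, mu_q0, limits, query, graph,
                                   if (R <= 2) "rejection" else "hit_and_run")
    res$region_empty <- FALSE
    res
  })
}

# Hit-and-run sampler over {q in box : in_region(q)}.
hit_and_run <- function(S, lo, hi, in_region) {
  R <- length(lo)
  start <- NULL
  for (i in seq_len(20000)) {
    cand <- matrix(runif(R, lo, hi), 1, R)
    if (in_region(cand)) { start <- cand; break }
  }
  if (is.null(start)) return(NULL)
  out <- matrix(0, S, R)
  cur <- start
  for (s in seq_len(S)) {
    dir <- rnorm(R)
    dir <- dir / sqrt(sum(dir^2))
    # line search extents within the box
    tmax <- min(ifelse(dir > 0, (hi - cur) / dir, (lo - cur) / dir))
    tmin <- -min(ifelse(dir > 0, (cur - lo) / dir, (cur - hi) / dir))
    for (try in seq_len(50)) {
      t <- runif(1, tmin, tmax)
      cand <- cur + t * dir
      if (in_region(matrix(cand, 1, R))) { cur <- cand; break }
      if (t > 0) tmax <- t else tmin <- t
    }
    out[s, ] <- cur
  }
  out
}

#' Exhaustive grid oracle for the recommendation
#'
#' Evaluates the recommendation on a dense regular grid over the proposal box
#' (tractable for one or two queried nutrients), applying the identical
#' constraint, confidence and quantile logic as [recommend()]. Used as the
#' definitional test oracle for the acceptance sampler.
#'
#' @param graph A `personal_graph` with ranges.
#' @param query A [recommendation_query()].
#' @param grid_points Grid resolution per dimension.
#' @return A `recommendation` object with `method = "grid"`.
#' @export
recommend_grid_oracle <- function(graph, query = recommendation_query(),
                                  grid_points = 100) {
  est <- graph_point_estimates(graph, query)
  R <- length(query$queried)
  if (R > 2) abort("grid oracle supports at most 2 queried nutrients")
  rg <- ordered_ranges(graph)
  mu_q0 <- baseline_mu(graph, query)
  limits <- purrr::map_dfr(seq_along(mu_q0), function(m) {
    lu <- sampling_limits(mu_q0[m], rg$lower[m], rg$upper[m])
    tibble(response = graph$responses[m], l = lu[1], u = lu[2])
  })
  axes <- lapply(query$proposal_bounds, function(b)
    seq(b[1], b[2], length.out = grid_points))
  Qm <- as.matrix(expand.grid(axes))
  colnames(Qm) <- NULL
  eff_q <- est$eff_hat[est$q_idx, , drop = FALSE]
  mu <- Qm %*% eff_q + matrix(mu_q0, nrow(Qm), length(mu_q0), byrow = TRUE)
  keep <- rep(TRUE, nrow(Qm))
  for (m in seq_along(mu_q0))
    keep <- keep & mu[, m] >= limits$l[m] & mu[, m] <= limits$u[m]
  Qc <- Qm[keep, , drop = FALSE]
  if (nrow(Qc) == 0) Qc <- Qm
  ev <- evaluate_proposals(Qc, est, mu_q0, rg, graph$shift_c)
  res <- finalize_recommendation(Qc, ev, mu_q0, limits, query, graph, "grid")
  res$region_empty <- !any(keep)
  if (res$region_empty) {
    res$succeeded <- FALSE
    res$accepted <- res$samples[0, ]
    res$bounds$q_min <- NA_real_
    res$bounds$q_max <- NA_real_
  }
  res
}

#' Sensitivity analysis of a recommendation
#'
#' Re-runs the acceptance sampling with tail-quantile point estimates of the
#' intake and effect nodes (default 5%, 50% and 95%) and with alternative
#' confidence levels (default 80% and 90%), to check that recommendations are
#' robust to the width of those distributions.
#'
#' @param graph A `personal_graph` with ranges.
#' @param query Base [recommendation_query()].
#' @param quantile_pairs List of `c(l_x, l_beta)` pairs.
#' @param conf_levels Confidence levels to scan.
#' @return A tibble with one row per combination: `l_x`, `l_beta`,
#'   `conf_level`, `succeeded`, `p_max`, `n_accepted` and a `result` list
#'   column of `recommendation` objects.
#' @export
sensitivity <- function(graph, query = recommendation_query(),
                        quantile_pairs = list(c(0.05, 0.05), c(0.5, 0.5),
                                              c(0.95, 0.95)),
                        conf_levels = c(0.8, 0.9)) {
  grid <- tidyr::crossing(pair = seq_along(quantile_pairs),
                          conf_level = conf_levels)
  purrr::pmap_dfr(grid, function(pair, conf_level) {
    qp <- quantile_pairs[[pair]]
    q2 <- query
    q2$l_x <- qp[1]; q2$l_beta <- qp[2]; q2$conf_level <- conf_level
    res <- recommend(graph, q2)
    tibble(l_x = qp[1], l_beta = qp[2], conf_level = conf_level,
           succeeded = res$succeeded, p_max = res$p_max,
           n_accepted = nrow(res$accepted), result = list(res))
  })
}

#' @export
print.recommendation <- function(x, ...) {
  cat(sprintf("<recommendation> patient %s (%s sampling): %s\n",
              x$patient, x$method,
              if (x$succeeded) "succeeded" else "no proposal reached the confidence target"))
  cat(sprintf("  P_max = %.3f (target %.2f), accepted %d / %d\n",
              x$p_max, x$conf_level, nrow(x$accepted), nrow(x$samples)))
  print(x$bounds)
  invisible(x)
}

#' @method tidy recommendation
#' @export
tidy.recommendation <- function(x, ...) {
  dplyr::mutate(x$bounds, succeeded = x$succeeded,
                conf_level = x$conf_level)
}

#' @method glance recommendation
#' @export
glance.recommendation <- function(x, ...) {
  tibble(patient = x$patient, succeeded = x$succeeded, p_max = x$p_max,
         n_accepted = nrow(x$accepted), n_samples = nrow(x$samples),
         conf_level = x$conf_level, method = x$method)
}
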