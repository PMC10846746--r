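#' Normalized root mean square error report
#'
#' Scores predictions of repeated concentration measurements:
#' `NRMSE_km = RMSE over observations / mean observed value` per patient and
#' response, averaged over responses to a per-patient score and over patients
#' to the overall score.
#'
#' @param data A tibble with columns `patient`, `response`, `observed`,
#'   `predicted` (one row per observation; additional columns are ignored).
#' @param variant Optional label for the report.
#' @return An `nrmse_report`: list with `by_cell` (patient x response),
#'   `by_patient`, `overall` (scalar), `by_response` (convenience column
#'   means) and `variant`.
#' @export
nrmse <- function(data, variant = NA_character_) {
  need <- c("patient", "response", "observed", "predicted")
  if (!all(need %in% names(data)))
    abort("data needs columns patient, response, observed, predicted")
  data <- dplyr::filter(data, !is.na(.data$observed) & !is.na(.data$predicted))
  by_cell <- data |>
    dplyr::group_by(.data$patient, .data$response) |>
    dplyr::summarise(
      ybar = mean(.data$observed),
      rmse = sqrt(mean((.data$predicted - .data$observed)^2)),
      .groups = "drop")
  if (any(by_cell$ybar == 0))
    abort("mean observed value is zero for some patient/response; NRMSE undefined")
  by_cell <- dplyr::mutate(by_cell, nrmse = .data$rmse / .data$ybar)
  by_patient <- by_cell |>
    dplyr::group_by(.data$patient) |>
    dplyr::summarise(nrmse = mean(.data$nrmse), .groups = "drop")
  by_response <- by_cell |>
    dplyr::group_by(.data$response) |>
    dplyr::summarise(nrmse = mean(.data$nrmse), .groups = "drop")
  structure(list(by_cell = by_cell[, c("patient", "response", "nrmse")],
                 by_patient = by_patient,
                 by_response = by_response,
                 overall = mean(by_patient$nrmse),
                 variant = variant),
            class = "nrmse_report")
}

#' @export
print.nrmse_report <- function(x, ...) {
  cat(sprintf("<nrmse_report>%s overall NRMSE = %.4f\n",
              if (is.na(x$variant)) "" else paste0(" [", x$variant, "]"),
              x$overall))
  print(x$by_response)
  invisible(x)
}

# Long prediction table from a fitted model: posterior-mean expected values
# against the observed concentrations (missing cells dropped).
cohort_predictions <- function(fit) {
  mu_hat <- apply(fit$draws$mu, c(2, 3), mean)
  M <- length(fit$meta$responses)
  purrr::map_dfr(seq_len(M), function(m) {
    tibble(patient = fit$meta$pat,
           response = fit$meta$responses[m],
           observed = ifelse(fit$meta$obs_mask[, m], fit$meta$Y[, m],
                             NA_real_),
           predicted = mu_hat[, m])
  })
}

#' In-sample NRMSE of a fitted model
#'
#' @param fit An `hsur_fit`.
#' @return An `nrmse_report` scoring posterior-mean expected concentrations
#'   against the observed values.
#' @export
nrmse_in_sample <- function(fit) {
  nrmse(cohort_predictions(fit), variant = fit$meta$spec$variant)
}

# Posterior-mean ingredients needed to predict new patients.
fit_point_estimates <- function(fit) {
  p <- length(fit$meta$predictors); M <- length(fit$meta$responses)
  pM <- p * M
  beta_hat <- apply(fit$draws$beta, c(2, 3), mean)
  g_hat <- if (!is.null(fit$draws$g)) apply(fit$draws$g, c(2, 3), mean)
           else matrix(0, fit$meta$L, pM)
  icpt_hat <- colMeans(fit$draws$intercept_raw)
  alpha_hat <- colMeans(exp(fit$draws$log_alpha))
  Sigma_b <- if (!is.null(fit$draws[["Sigma_b"]])) {
    apply(fit$draws[["Sigma_b"]], c(2, 3), mean)
  } else {
    S <- matrix(0, pM, pM)
    for (m in seq_len(M)) {
      blk <- (m - 1) * p + seq_len(p)
      S[blk, blk] <- apply(fit$draws[["Sigma_b_blocks"]][[m]], c(2, 3), mean)
    }
    S
  }
  list(beta = beta_hat, g = g_hat, icpt = icpt_hat, alpha = alpha_hat,
       Sigma_b = Sigma_b, center = fit$meta$center,
       shift_c = fit$meta$shift_c, p = p, M = M)
}

#' Predict personal effects for held-out patients
#'
#' For patients absent from the fit, finds the personal effect deviations most
#' probable under the fitted hierarchy given their observations: the mode of
#' the standard-normal latent `z` maximizing `log N(z; 0, I) +` the
#' shifted-gamma log likelihood at `mu = X beta_hat + X g_hat + X (T_b L_b
#' z)`, with all population-level parameters fixed at posterior means;
#' `b_hat = T_b L_b z_hat`. A draw-averaged conditional-mean alternative
#' (`method = "mean"`, self-normalized importance sampling over the latent
#' prior) is available for comparison.
#'
#' @param post An `hsur_fit`.
#' @param new_cohort A `cohort` holding only the new patients (treatment
#'   labels must exist in the fit).
#' @param method `"mode"` (default) or `"mean"`.
#' @param n_is Importance-sample size for `method = "mean"`.
#' @return A matrix (new patients x `p * M`) of personal effect deviations on
#'   the original predictor scale, with attributes `z` (latent modes) and
#'   `convergence`.
#' @export
predict_personal_effects <- function(post, new_cohort,
                                     method = c("mode", "mean"),
                                     n_is = 500) {
  method <- match.arg(method)
  est <- fit_point_estimates(post)
  p <- est$p; M <- est$M; pM <- p * M
  W <- with(cov_to_tcl(est$Sigma_b), diag(sigma, pM) %*% L)
  degenerate <- max(abs(W)) < 1e-12
  pats <- sort(unique(new_cohort$data$patient))
  treat_of <- patient_treatment(new_cohort)
  Xall <- cohort_X(new_cohort)
  Yall <- cohort_Y(new_cohort)
  maskall <- cohort_observed(new_cohort)

  out <- matrix(0, length(pats), pM,
                dimnames = list(pats, NULL))
  zs <- matrix(0, length(pats), pM)
  conv <- integer(length(pats))
  for (i in seq_along(pats)) {
    rows <- which(new_cohort$data$patient == pats[i])
    l <- treat_of[[as.character(pats[i])]]
    if (is.na(l) || l > nrow(est$g)) abort("unknown treatment for new patient")
    Xc <- sweep(Xall[rows, , drop = FALSE], 2, est$center)
    Y <- Yall[rows, , drop = FALSE]
    mask <- maskall[rows, , drop = FALSE]
    if (!any(mask) || degenerate) next

    base_mu <- matrix(0, length(rows), M)
    for (m in seq_len(M)) {
      blk <- (m - 1) * p + seq_len(p)
      base_mu[, m] <- est$icpt[m] +
        Xc %*% (est$beta[, m] + est$g[l, blk])
    }
    mu_of <- function(z) {
      bz <- W %*% z
      add <- matrix(0, length(rows), M)
      for (m in seq_len(M))
        add[, m] <- Xc %*% bz[(m - 1) * p + seq_len(p)]
      base_mu + add
    }
    negpost <- function(z) {
      mu <- mu_of(z)
      # out-of-support expected values get a smooth penalty so line searches
      # can back off instead of erroring
      viol <- mask & (mu + est$shift_c <= 1e-8)
      if (any(viol))
        return(1e8 + 1e8 * sum((1e-8 - (mu + est$shift_c))[viol]))
      ll <- sum(vapply(seq_len(nrow(mu)), function(r)
        gamma_shift_loglik(ifelse(mask[r, ], Y[r, ], NA), mu[r, ],
                           log(est$alpha), est$shift_c), numeric(1)))
      0.5 * sum(z^2) - ll
    }
    grad <- function(z) {
      mu <- mu_of(z)
      gmu <- matrix(0, length(rows), M)   # d(-ll)/d(mu)
      for (m in seq_len(M)) {
        a <- est$alpha[m]
        ok <- mask[, m]
        gmu[ok, m] <- -a * ((Y[ok, m] + est$shift_c) -
                              (mu[ok, m] + est$shift_c)) /
          (mu[ok, m] + est$shift_c)^2
      }
      gz <- z
      for (m in seq_len(M)) {
        blk <- (m - 1) * p + seq_len(p)
        gz <- gz + t(W[blk, , drop = FALSE]) %*%
          (t(Xc) %*% gmu[, m, drop = FALSE])
      }
      as.numeric(gz)
    }
    if (method == "mode") {
      opt <- stats::optim(rep(0, pM), negpost, grad, method = "BFGS",
                          control = list(maxit = 300))
      if (opt$convergence != 0) {
        gn <- sqrt(sum(grad(opt$par)^2))
        if (gn > 1e-2)
          abort(sprintf(
            "personal-effect optimizer did not converge for patient %s (gradient norm %.3g)",
            pats[i], gn))
      }
      zs[i, ] <- opt$par
      conv[i] <- opt$convergence
    } else {
      Z <- matrix(rnorm(n_is * pM), n_is, pM)
      lw <- -apply(Z, 1, negpost) - (-0.5 * rowSums(Z^2))
      w <- exp(lw - max(lw)); w <- w / sum(w)
      zs[i, ] <- colSums(Z * w)
    }
    out[i, ] <- as.numeric(W %*% zs[i, ])
  }
  attr(out, "z") <- zs
  attr(out, "convergence") <- conv
  out
}

#' Patient-level fold plan
#'
#' Seeded random partition of patients into folds, stratified by treatment so
#' that removing one fold never empties a treatment group.
#'
#' @param cohort A `cohort`.
#' @param n_folds Number of folds (>= 2).
#' @param seed RNG seed.
#' @return A `fold_plan`: tibble `(patient, treatment, fold)` with attributes
#'   `n_folds`, `seed`.
#' @export
fold_plan <- function(cohort, n_folds = 10, seed = 1L) {
  if (n_folds < 2) abort("n_folds must be >= 2")
  treat_of <- patient_treatment(cohort)
  pats <- seq_along(treat_of)
  plan <- with_seed(seed, {
    order_all <- unlist(lapply(split(pats, treat_of),
                               function(x) x[sample.int(length(x))]))
    tibble(patient = order_all,
           fold = rep_len(seq_len(n_folds), length(order_all)))
  })
  plan <- plan |>
    dplyr::mutate(treatment = unname(treat_of[.data$patient])) |>
    dplyr::arrange(.data$patient) |>
    dplyr::select("patient", "treatment", "fold")
  structure(plan, n_folds = n_folds, seed = seed,
            class = c("fold_plan", class(plan)))
}

# Rebuild a cohort containing only `patients`, renumbered 1..n (JAGS needs
# contiguous ids); attribute `patient_map` restores originals.
subset_cohort <- function(cohort, patients) {
  patients <- sort(patients)
  data <- dplyr::filter(cohort$data, .data$patient %in% patients)
  map <- setNames(seq_along(patients), patients)
  data$patient <- unname(map[as.character(data$patient)])
  out <- cohort
  out$data <- data
  out$truth <- NULL
  attr(out, "patient_map") <- patients
  out
}

#' Patient-level cross-validation
#'
#' Fits the model on each fold's retained patients, predicts the held-out
#' patients' personal effects with [predict_personal_effects()] (general and
#' treatment effects kept as modelled), scores their predicted concentrations,
#' and aggregates in-sample (full-fit posterior means) and out-of-sample
#' NRMSE reports.
#'
#' @param cohort A `cohort`.
#' @param spec A [model_spec()].
#' @param folds A [fold_plan()].
#' @param sampler A [sampler_config()].
#' @param full_fit Optional pre-computed full-data fit for the in-sample
#'   report.
#' @return List with `in_sample` and `out_of_sample` `nrmse_report`s and the
#'   fold plan.
#' @export
cross_validate <- function(cohort, spec = model_spec(),
                           folds = fold_plan(cohort),
                           sampler = sampler_config(),
                           full_fit = NULL) {
  treat_of <- patient_treatment(cohort)
  for (f in sort(unique(folds$fold))) {
    kept <- folds$patient[folds$fold != f]
    if (length(unique(treat_of[kept])) < length(unique(treat_of)))
      abort(sprintf("fold %d would empty a treatment group", f))
  }
  full_fit <- full_fit %||% fit_hsur(cohort, spec, sampler)
  in_sample <- nrmse_in_sample(full_fit)

  oos <- purrr::map_dfr(sort(unique(folds$fold)), function(f) {
    held <- folds$patient[folds$fold == f]
    train <- subset_cohort(cohort, setdiff(folds$patient, held))
    sub_sampler <- sampler
    sub_sampler$seed <- sampler$seed + f
    fit_f <- fit_hsur(train, spec, sub_sampler)
    test <- subset_cohort(cohort, held)
    b_hat <- predict_personal_effects(fit_f, test)
    predict_rows(fit_f, test, b_hat)
  })
  out_of_sample <- nrmse(oos, variant = paste0(spec$variant, "_cv"))
  list(in_sample = in_sample, out_of_sample = out_of_sample, folds = folds)
}

# Expected concentrations for (new) patients given personal effect vectors.
predict_rows <- function(fit, new_cohort, b_hat) {
  est <- fit_point_estimates(fit)
  p <- est$p; M <- est$M
  treat_of <- patient_treatment(new_cohort)
  X <- cohort_X(new_cohort)
  Y <- cohort_Y(new_cohort)
  mask <- cohort_observed(new_cohort)
  pats <- rownames(b_hat)
  orig_ids <- attr(new_cohort, "patient_map") %||%
    sort(unique(new_cohort$data$patient))
  purrr::map_dfr(seq_len(M), function(m) {
    blk <- (m - 1) * p + seq_len(p)
    pred <- vapply(seq_len(nrow(X)), function(r) {
      k <- new_cohort$data$patient[r]
      l <- treat_of[[as.character(k)]]
      eff <- est$beta[, m] + est$g[l, blk] +
        b_hat[match(as.character(k), pats), blk]
      est$icpt[m] + sum((X[r, ] - est$center) * eff)
    }, numeric(1))
    tibble(patient = orig_ids[new_cohort$data$patient],
           response = fit$meta$responses[m],
           observed = ifelse(mask[, m], Y[, m], NA_real_),
           predicted = pred)
  })
}

#' Compare model variants by in-sample NRMSE
#'
#' Fits each variant on the same cohort and tabulates per-response and
#' overall NRMSE, one row per variant.
#'
#' @param cohort A `cohort`.
#' @param variants Character vector of [model_spec()] variants.
#' @param spec_base Base spec whose non-variant settings are reused.
#' @param sampler A [sampler_config()].
#' @return A tibble: `variant`, one NRMSE column per response, `average`, and
#'   a `report` list column.
#' @export
compare_variants <- function(cohort,
                             variants = c("two_level", "single_level",
                                          "separate_univariate"),
                             spec_base = model_spec(),
                             sampler = sampler_config()) {
  if (length(variants) < 2) abort("need at least 2 variants to compare")
  purrr::map_dfr(variants, function(v) {
    spec <- spec_base
    spec$variant <- v
    fit <- fit_hsur(cohort, spec, sampler)
    rep <- nrmse_in_sample(fit)
    row <- tibble(variant = v, average = rep$overall, report = list(rep))
    for (i in seq_len(nrow(rep$by_response)))
      row[[rep$by_response$response[i]]] <- rep$by_response$nrmse[i]
    row
  })
}
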