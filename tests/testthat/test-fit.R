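# One moderately sized fit is shared by the structural assertions below.
ch_fit <- small_cohort(K = 8, sizes = c(4, 2, 2), n_obs = 4, p = 3, M = 2,
                       seed = 42)
fit2l <- fit_hsur(ch_fit, model_spec(), quick_sampler(seed = 7))

test_that("posterior draws have the documented shapes and provenance", {
  p <- 3; M <- 2; pM <- p * M
  expect_equal(dim(fit2l$draws$beta), c(fit2l$n_draws, p, M))
  expect_equal(dim(fit2l$draws$beta_star), c(fit2l$n_draws, pM))
  expect_equal(dim(fit2l$draws$g), c(fit2l$n_draws, 3, pM))
  expect_equal(dim(fit2l$draws$b), c(fit2l$n_draws, 8, pM))
  expect_equal(dim(fit2l$draws$Sigma_g), c(fit2l$n_draws, pM, pM))
  expect_equal(dim(fit2l$draws$mu), c(fit2l$n_draws, nrow(ch_fit$data), M))
  expect_true(all(is.finite(fit2l$draws$log_alpha)))
  expect_s3_class(glance(fit2l), "tbl_df")
  expect_gt(mean(fit2l$diagnostics$ess, na.rm = TRUE), 20)
})

test_that("stored beta draws are the QR back-transformation of beta_star", {
  # recompute beta from beta_star draw-by-draw through R*^-1 and the
  # predictor scaling; must match the stored original-scale draws
  dec <- fit2l$meta$qr
  scale <- fit2l$meta$scale
  p <- 3; M <- 2
  for (m in 1:M) {
    blk <- (m - 1) * p + 1:p
    manual <- t(dec$R_star_inv %*% t(fit2l$draws$beta_star[, blk])) /
      matrix(scale, fit2l$n_draws, p, byrow = TRUE)
    expect_lt(max(abs(manual - fit2l$draws$beta[, , m])), 1e-8)
  }
})

test_that("expected values computed from original-scale draws match mu draws", {
  # QR-parameterization equivalence at the whole-model level
  X <- as.matrix(ch_fit$data[, paste0("x_", ch_fit$predictors)])
  Xc <- sweep(X, 2, fit2l$meta$center)
  pat <- ch_fit$data$patient
  l_of <- fit2l$meta$treat_of
  idx <- seq(1, fit2l$n_draws, length.out = 25)
  p <- 3
  for (i in round(idx)) {
    for (m in 1:2) {
      blk <- (m - 1) * p + 1:p
      eff <- matrix(fit2l$draws$beta[i, , m], nrow(X), p, byrow = TRUE) +
        fit2l$draws$g[i, l_of[pat], blk] +
        fit2l$draws$b[i, pat, blk]
      mu_manual <- fit2l$draws$intercept_raw[i, m] + rowSums(Xc * eff)
      expect_lt(max(abs(mu_manual - fit2l$draws$mu[i, , m])), 1e-8)
    }
  }
})

test_that("posterior covariances decompose into valid sd/correlation factors", {
  for (lev in c("treatment", "personal")) {
    cs <- cov_structure(fit2l, lev)
    expect_true(all(cs$sigma >= 0))
    expect_lt(max(abs(diag(cs$C) - 1)), 1e-8)
    expect_lt(max(abs(cs$C - t(cs$C))), 1e-8)
    expect_gt(min(eigen(cs$C, symmetric = TRUE,
                        only.values = TRUE)$values), -1e-8)
    expect_true(all(cs$L_corr[upper.tri(cs$L_corr)] == 0))
    expect_lt(max(abs(cs$L_corr %*% t(cs$L_corr) - cs$C)), 1e-6)
    # per-draw validity on a subset
    for (i in c(1, fit2l$n_draws %/% 2, fit2l$n_draws)) {
      S <- fit2l$draws[[if (lev == "treatment") "Sigma_g" else "Sigma_b"]][i, , ]
      expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
                -1e-8)
    }
  }
  blocks <- correlation_blocks(cov_structure(fit2l, "personal")$C, 3, 2)
  expect_equal(assemble_correlation(blocks),
               cov_structure(fit2l, "personal")$C)
  expect_lt(max(abs(blocks$cross[[1, 2]] - t(blocks$cross[[2, 1]]))), 1e-12)
})

test_that("single-level variant omits the treatment layer", {
  fit1l <- fit_hsur(ch_fit, model_spec("single_level"),
                    quick_sampler(draws = 200, warmup = 200, seed = 8))
  expect_null(fit1l$draws$g)
  expect_null(fit1l$draws$Sigma_g)
  expect_equal(dim(fit1l$draws$b), c(fit1l$n_draws, 8, 6))
})

test_that("separate-univariate variant carries no cross-response parameters", {
  fits <- fit_hsur(ch_fit, model_spec("separate_univariate"),
                   quick_sampler(draws = 200, warmup = 200, seed = 9))
  expect_null(fits$draws[["Sigma_g"]])
  expect_null(fits$draws[["Sigma_b"]])
  expect_length(fits$draws$Sigma_b_blocks, 2)
  expect_equal(dim(fits$draws$Sigma_b_blocks[[1]])[2:3], c(3, 3))
  cs <- cov_structure(fits, "personal")
  expect_true(cs$cross_absent)
  expect_true(all(cs$Sigma[1:3, 4:6] == 0))
})

test_that("fits are reproducible under a fixed sampler seed", {
  s <- quick_sampler(chains = 1, draws = 100, warmup = 150, seed = 12)
  f1 <- fit_hsur(ch_fit, model_spec(), s)
  f2 <- fit_hsur(ch_fit, model_spec(), s)
  expect_identical(f1$draws$beta, f2$draws$beta)
})

test_that("posterior mean beta agrees with a maximum-likelihood gamma GLM", {
  # independent oracle: one predictor, one response, no group variance
  cfg <- cohort_config(K = 6, treatment_sizes = c(3, 3), n_obs = 10, p = 1,
                       M = 1, beta_true = matrix(2), intercept_true = 20,
                       sigma_g = 0, sigma_b = 0, alpha_true = 200,
                       intake_mean_range = c(0.5, 3), seed = 33,
                       binary = FALSE, predictor_names = "x1")
  ch <- simulate_cohort(cfg)
  fit <- fit_hsur(ch, model_spec("single_level"),
                  quick_sampler(draws = 400, warmup = 400, seed = 3))
  y <- ch$data$y_y1 + fit$meta$shift_c
  x <- ch$data$x_x1
  glm_fit <- suppressWarnings(
    stats::glm(y ~ x, family = Gamma(link = "identity"),
               start = c(mean(y), 0)))
  bdraws <- fit$draws$beta[, 1, 1]
  expect_lt(abs(mean(bdraws) - coef(glm_fit)[["x"]]), 2 * sd(bdraws))
})

test_that("missing cells are masked in the likelihood and imputed afterwards", {
  holdout <- c(2, 5, 7, 12, 14, 17, 20, 23, 26, 29)
  # mask-and-recover over replicate cohorts; pooled standardized pairs must
  # agree in rank with the held-out truths
  pairs <- purrr::map_dfr(c(55, 155, 255), function(sd0) {
    ch <- small_cohort(K = 10, sizes = c(4, 3, 3), n_obs = 3, p = 3, M = 3,
                       seed = sd0, alpha_true = 400)
    truth_y <- ch$data$y_resp3
    ch$data$y_resp3[holdout] <- NA
    ch$data$src_resp3[holdout] <- "missing"
    fit <- fit_hsur(ch, model_spec(),
                    quick_sampler(draws = 300, warmup = 300, seed = 5))
    imp <- impute_missing(fit, ch)
    if (sd0 == 55) {
      expect_identical(imp$data$src_resp3[holdout],
                       rep("imputed", length(holdout)))
      expect_identical(imp$data$src_resp3[-holdout],
                       rep("observed", nrow(ch$data) - length(holdout)))
      expect_true(all(is.finite(imp$data$y_resp3)))
    }
    tibble::tibble(imputed = scale(imp$data$y_resp3[holdout])[, 1],
                   truth = scale(truth_y[holdout])[, 1])
  })
  expect_gt(cor(pairs$imputed, pairs$truth, method = "spearman"), 0)
  # untouched when nothing is missing
  ch_full <- small_cohort(seed = 56)
  fit_full <- fit_hsur(ch_full, model_spec(),
                       quick_sampler(draws = 150, warmup = 200, seed = 6))
  expect_equal(impute_missing(fit_full, ch_full)$data, ch_full$data)
})

test_that("rows with every response missing are left alone with a warning", {
  ch <- small_cohort(K = 8, sizes = c(4, 2, 2), n_obs = 3, p = 3, M = 2,
                     seed = 57)
  ch$data$y_resp1[4] <- NA; ch$data$y_resp2[4] <- NA
  ch$data$src_resp1[4] <- "missing"; ch$data$src_resp2[4] <- "missing"
  fit <- fit_hsur(ch, model_spec(), quick_sampler(draws = 150, warmup = 200,
                                                  seed = 7))
  expect_warning(imp <- impute_missing(fit, ch), "no observed responses")
  expect_true(is.na(imp$data$y_resp1[4]))
  expect_identical(imp$data$src_resp1[4], "missing")
})

test_that("effect summaries follow the draw distribution exactly", {
  # degenerate constant draws: estimate v with a zero-width interval
  beta <- matrix(c(1, -2, 0.5, 3), 2, 2)
  ff <- fake_fit(beta, K = 3, L = 2)
  td <- tidy(ff, "general")
  expect_equal(td$estimate, c(beta))
  expect_equal(td$conf.low, td$estimate)
  expect_equal(td$conf.high, td$estimate)
  # g = 0 draws: treatment rows equal general rows
  tt <- tidy(ff, "treatment")
  expect_equal(tt$estimate[tt$unit == 1], td$estimate)
  expect_equal(tt$estimate[tt$unit == 2], td$estimate)

  # 10 hand-written draws checked against a manual order-statistics quantile
  ff2 <- fake_fit(matrix(0, 1, 1), K = 1, L = 1, n_draws = 10)
  draws <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  ff2$draws$beta[, 1, 1] <- draws
  td2 <- tidy(ff2, "general", conf_level = 0.9)
  manual_q <- function(x, p) {      # type-7 interpolation from sorted array
    s <- sort(x); h <- (length(s) - 1) * p
    s[floor(h) + 1] + (h - floor(h)) * (s[min(floor(h) + 2, length(s))] -
                                          s[floor(h) + 1])
  }
  expect_equal(td2$conf.low, manual_q(draws, 0.05))
  expect_equal(td2$conf.high, manual_q(draws, 0.95))
  expect_equal(td2$estimate, mean(draws))
})

test_that("posterior predictive replication is unbiased for self-generated data", {
  ppc <- posterior_predictive_check(fit2l, n_rep = 300, seed = 3)
  expect_true(all(abs(ppc$summary$bias) < 3 * ppc$summary$mc_se +
                    0.05 * abs(ppc$summary$obs_mean)))
  # huge shape: replicates collapse onto mu
  ffa <- fake_fit(matrix(1, 1, 1), K = 2, L = 1, log_alpha = 20)
  ffa$draws$mu <- array(7, c(ffa$n_draws, 4, 1))
  ffa$meta$Y <- matrix(7, 4, 1)
  ffa$meta$obs_mask <- matrix(TRUE, 4, 1)
  ppc2 <- posterior_predictive_check(ffa, n_rep = 50, seed = 4)
  expect_lt(max(abs(ppc2$y_rep - 7)), 0.05)
  # masked cells are excluded from the bias statistic
  ffa$meta$obs_mask[1:2, 1] <- FALSE
  ffa$meta$Y[1:2, 1] <- 1e6
  ppc3 <- posterior_predictive_check(ffa, n_rep = 50, seed = 4)
  expect_lt(abs(ppc3$summary$obs_mean - 7), 1e-9)
})

test_that("predictions are invariant to the shift constant on positive data", {
  ch <- small_cohort(K = 6, sizes = c(3, 3), n_obs = 4, p = 2, M = 1,
                     seed = 60)
  f_small <- fit_hsur(ch, model_spec(shift_c = 5),
                      quick_sampler(draws = 400, warmup = 400, seed = 2))
  f_large <- fit_hsur(ch, model_spec(shift_c = 15),
                      quick_sampler(draws = 400, warmup = 400, seed = 2))
  mu_s <- apply(f_small$draws$mu, c(2, 3), mean)
  mu_l <- apply(f_large$draws$mu, c(2, 3), mean)
  # predictive means agree within Monte Carlo error
  mc <- apply(f_small$draws$mu, c(2, 3), sd) / sqrt(f_small$n_draws / 10)
  expect_lt(max(abs(mu_s - mu_l) / (mc + 0.05 * abs(mu_s))), 4)
})
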