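# A controllable one-patient graph: degenerate posterior with chosen effects.
rec_graph <- function(beta, intakes, alpha = 400, intercept = NULL,
                      ranges = NULL, sd_frac = 0.05, noise = 0,
                      n_draws = if (noise > 0) 400 else 1, shift_c = 5) {
  p <- nrow(beta); M <- ncol(beta)
  ff <- fake_fit(beta, K = 1, L = 1, n_draws = n_draws,
                 log_alpha = rep(log(alpha), M),
                 intercept = intercept %||% rep(0, M),
                 shift_c = shift_c, noise = noise)
  X <- rbind(intakes, intakes)
  ch <- fake_cohort_for(X, patient = c(1, 1), Y = matrix(5, 2, M))
  gg <- build_personal_graph(ff, ch, 1, ranges = ranges)
  gg$intakes$sd <- pmax(sd_frac * abs(gg$intakes$mean), 1e-6)
  gg
}

simple_query <- function(gg, queried, bounds, S = 4000, conf = 0.5,
                         seed = 2, ...) {
  recommendation_query(queried = queried,
                       proposal_bounds = setNames(bounds, queried),
                       S = S, conf_level = conf, seed = seed, ...)
}

test_that("query validation catches malformed inputs", {
  expect_error(recommendation_query(conf_level = 1), "conf_level")
  expect_error(recommendation_query(l_x = 1.2), "quantile")
  expect_error(recommendation_query(queried = "zinc"), "proposal_bounds")
  expect_error(recommendation_query(
    queried = "zinc", proposal_bounds = list(zinc = c(3, 1))), "lower < upper")
})

test_that("baseline excludes exactly the queried nutrients", {
  beta <- matrix(c(0.5, 1, 2), 3, 1)
  gg <- rec_graph(beta, intakes = c(1, 2, 4))
  q3 <- simple_query(gg, "x3", list(c(0, 5)))
  expect_equal(unname(baseline_mu(gg, q3)), 1 * 0.5 + 2 * 1)  # = 2.5
  # all queried: only the intercept survives
  gg_i <- rec_graph(beta, intakes = c(1, 2, 4), intercept = 3)
  q_all <- simple_query(gg_i, c("x1", "x2", "x3"),
                        list(c(0, 5), c(0, 5), c(0, 5)))
  expect_equal(unname(baseline_mu(gg_i, q_all)), 3)
  # none queried: the full point prediction
  q_none <- recommendation_query(queried = character(0),
                                 proposal_bounds = list(), S = 10)
  expect_equal(unname(baseline_mu(gg_i, q_none)), 3 + 2.5 + 8)
  expect_error(baseline_mu(gg, simple_query(gg, "nope", list(c(0, 1)))),
               "not among predictors")
})

test_that("sampling limits widen to include an out-of-range baseline", {
  expect_equal(sampling_limits(5, 3, 8), c(3, 8))    # inside: unchanged
  expect_equal(sampling_limits(-2, 3, 8), c(-2, 8))  # below: lower replaced
  expect_equal(sampling_limits(13, 3, 8), c(3, 13))  # above: upper replaced
  expect_error(sampling_limits(5, 8, 3), "y_lo")
})

test_that("confidence is the gamma mass in the range", {
  expect_equal(gamma_confidence(2, 50, -5 + 1e-12, 1e7, 5), 1,
               tolerance = 1e-9)
  # quadrature oracle on random configurations
  set.seed(9)
  for (i in 1:40) {
    mu <- runif(1, 0.5, 6); a <- runif(1, 2, 300); cs <- runif(1, 1, 8)
    lo <- mu - runif(1, 0.1, 2); hi <- mu + runif(1, 0.1, 2)
    dens <- function(y) dgamma(y + cs, a, rate = a / (mu + cs))
    oracle <- stats::integrate(dens, lo, hi, rel.tol = 1e-12)$value
    expect_equal(gamma_confidence(mu, a, lo, hi, cs), oracle,
                 tolerance = 1e-8)
  }
  # concentration: huge shape puts all mass at mu when mu is inside
  expect_gt(gamma_confidence(5, 1e8, 4.99, 5.01, 5), 0.999)
  expect_equal(gamma_confidence(-10, 50, 1, 2, 5), 0)   # mu + c <= 0
  expect_error(gamma_confidence(1, 50, 2, 2, 5), "degenerate")
})

test_that("with unbounded targets every proposal is accepted", {
  gg <- rec_graph(matrix(c(1, 0.5), 1, 2), intakes = 2,
                  ranges = flat_ranges(c("resp1", "resp2"), -1e7, 1e7))
  q <- simple_query(gg, "x1", list(c(0, 10)), S = 5000, conf = 0.5)
  res <- recommend(gg, q)
  expect_true(res$succeeded)
  expect_equal(nrow(res$accepted), nrow(res$samples))
  expect_equal(res$bounds$q_min, 0.25, tolerance = 0.05)
  expect_equal(res$bounds$q_max, 9.75, tolerance = 0.05)
  expect_equal(res$p_max, 1)
})

test_that("a query that cannot move the concentration fails honestly", {
  # queried effect zero and baseline far outside the target range
  beta <- matrix(c(0, 1), 2, 1)   # x1 queried with zero effect
  gg <- rec_graph(beta, intakes = c(1, 10), alpha = 100,
                  ranges = flat_ranges("resp1", 20, 25))
  q <- simple_query(gg, "x1", list(c(0, 5)), conf = 0.9)
  res <- recommend(gg, q)
  expect_false(res$succeeded)
  expect_equal(nrow(res$accepted), 0)
  base_conf <- gamma_confidence(10, 100, 20, 25, gg$shift_c)
  expect_equal(res$p_max, base_conf, tolerance = 1e-9)
  expect_lt(res$p_max, q$conf_level)
  expect_true(all(is.na(res$bounds$q_min)))
})

test_that("sampler agrees with the dense grid oracle in one dimension", {
  beta <- matrix(1.2, 1, 1)
  gg <- rec_graph(beta, intakes = 2, alpha = 200,
                  ranges = flat_ranges("resp1", 2, 6), intercept = 1)
  q <- simple_query(gg, "x1", list(c(0, 8)), S = 6000, conf = 0.8, seed = 4)
  res <- recommend(gg, q)
  orc <- recommend_grid_oracle(gg, q, grid_points = 4000)
  expect_true(res$succeeded && orc$succeeded)
  width <- 8
  expect_lt(max(abs(res$bounds$q_min - orc$bounds$q_min),
                abs(res$bounds$q_max - orc$bounds$q_max)), 0.02 * width)
  # monotone single-response setup: accepted region is an interval
  acc <- sort(res$accepted$x1)
  gaps <- diff(acc)
  expect_lt(max(gaps), 0.05 * width)     # no interior holes at this density
})

test_that("sampler agrees with the grid oracle in two dimensions", {
  beta <- matrix(c(1, -0.4, 0.3, 0.8), 2, 2)
  gg <- rec_graph(beta, intakes = c(1, 1), alpha = 300,
                  ranges = flat_ranges(c("resp1", "resp2"), 0.5, 3))
  q <- simple_query(gg, c("x1", "x2"), list(c(0, 4), c(0, 4)), S = 6000,
                    conf = 0.6, seed = 5)
  res <- recommend(gg, q)
  orc <- recommend_grid_oracle(gg, q, grid_points = 250)
  expect_equal(res$succeeded, orc$succeeded)
  if (res$succeeded) {
    for (r in 1:2) {
      expect_lt(abs(res$bounds$q_min[r] - orc$bounds$q_min[r]), 0.02 * 4)
      expect_lt(abs(res$bounds$q_max[r] - orc$bounds$q_max[r]), 0.02 * 4)
    }
  }
  expect_lt(abs(res$p_max - orc$p_max), 0.02)
})

test_that("failure is consistent between sampler and oracle", {
  beta <- matrix(0.1, 1, 1)
  gg <- rec_graph(beta, intakes = 1, alpha = 500,
                  ranges = flat_ranges("resp1", 50, 51))
  q <- simple_query(gg, "x1", list(c(0, 2)), conf = 0.99)
  res <- recommend(gg, q)
  orc <- recommend_grid_oracle(gg, q, grid_points = 500)
  expect_false(res$succeeded)
  expect_false(orc$succeeded)
  expect_lt(res$p_max, 0.99)
})

test_that("raising the confidence level never widens the recommendation", {
  beta <- matrix(c(0.9, 0.2, -0.3, 1.1), 2, 2)
  gg <- rec_graph(beta, intakes = c(1.5, 1), alpha = 150,
                  ranges = flat_ranges(c("resp1", "resp2"), 0.5, 3.5))
  q8 <- simple_query(gg, c("x1", "x2"), list(c(0, 4), c(0, 4)), S = 4000,
                     conf = 0.8, seed = 6)
  q9 <- q8; q9$conf_level <- 0.9
  r8 <- recommend(gg, q8); r9 <- recommend(gg, q9)
  if (r9$succeeded) {
    expect_true(r8$succeeded)
    expect_true(all(r9$bounds$q_min >= r8$bounds$q_min - 1e-9))
    expect_true(all(r9$bounds$q_max <= r8$bounds$q_max + 1e-9))
    # acceptance set nesting on identical draws
    expect_true(all(r9$accepted$confidence > 0.8))
    expect_lte(nrow(r9$accepted), nrow(r8$accepted))
  }
})

test_that("accepted-region edges are pinned by some response at conf_level", {
  beta <- matrix(1.5, 1, 1)
  gg <- rec_graph(beta, intakes = 1, alpha = 200,
                  ranges = flat_ranges("resp1", 2, 6))
  q <- simple_query(gg, "x1", list(c(0, 8)), S = 8000, conf = 0.85, seed = 7)
  res <- recommend(gg, q)
  expect_true(res$succeeded)
  est <- nephrodiet:::graph_point_estimates(gg, q)
  conf_at <- function(qv) {
    mu <- unname(baseline_mu(gg, q)) + qv * est$eff_hat[1, 1]
    gamma_confidence(mu, est$alpha_hat, 2, 6, gg$shift_c)
  }
  # both interior edges of the recommendation sit near the threshold
  expect_lt(abs(conf_at(res$bounds$q_min) - 0.85), 0.05)
  expect_lt(abs(conf_at(res$bounds$q_max) - 0.85), 0.05)
})

test_that("self-consistency: a comfortable current diet is recommended", {
  beta <- matrix(c(1, 0.5), 1, 2)
  # current intake 2 gives mu = (2, 1): both mid-range below
  gg <- rec_graph(beta, intakes = 2, alpha = 500,
                  ranges = flat_ranges(c("resp1", "resp2"),
                                       c(1, 0.5), c(3, 1.5)))
  q <- simple_query(gg, "x1", list(c(0, 6)), conf = 0.9, S = 4000)
  res <- recommend(gg, q)
  expect_true(res$succeeded)
  expect_gt(2, res$bounds$q_min)
  expect_lt(2, res$bounds$q_max)
})

test_that("sensitivity runs the quantile-pair and confidence grid", {
  beta <- matrix(1, 1, 1)
  gg_deg <- rec_graph(beta, intakes = 2, alpha = 200,
                      ranges = flat_ranges("resp1", 1, 4))
  gg_deg$intakes$sd <- 1e-12        # degenerate: all quantiles coincide
  q <- simple_query(gg_deg, "x1", list(c(0, 5)), S = 2000, conf = 0.8)
  sens <- sensitivity(gg_deg, q, conf_levels = 0.8)
  expect_equal(nrow(sens), 3)
  expect_lt(max(abs(sens$p_max - sens$p_max[1])), 1e-9)
  expect_lt(diff(range(purrr::map_dbl(sens$result,
                                      ~ .x$bounds$q_min))), 1e-6)

  # wide posterior, constructed so that both tail point estimates move the
  # baseline/effects adversely: tail runs accept no more than the median run
  gg_wide <- rec_graph(beta, intakes = 2, alpha = 200, noise = 0.6,
                       ranges = flat_ranges("resp1", 1, 4))
  gg_wide$intercept_draws <- gg_wide$intercept_draws * 6
  qw <- simple_query(gg_wide, "x1", list(c(0, 5)), S = 3000, conf = 0.8)
  sw <- sensitivity(gg_wide, qw, conf_levels = 0.8)
  n_med <- sw$n_accepted[sw$l_beta == 0.5]
  expect_gt(n_med, 0)
  expect_lte(sw$n_accepted[sw$l_beta == 0.05], n_med)
  expect_lte(sw$n_accepted[sw$l_beta == 0.95], n_med)
  expect_gte(sw$p_max[sw$l_beta == 0.5],
             max(sw$p_max[sw$l_beta != 0.5]))
  # threshold monotonicity across conf levels
  s2 <- sensitivity(gg_wide, qw, quantile_pairs = list(c(0.5, 0.5)),
                    conf_levels = c(0.8, 0.9))
  expect_lte(s2$n_accepted[s2$conf_level == 0.9],
             s2$n_accepted[s2$conf_level == 0.8])
})

test_that("degenerate sampling inputs error cleanly", {
  gg <- rec_graph(matrix(1, 1, 1), intakes = 1,
                  ranges = flat_ranges("resp1", 0, 5))
  q <- simple_query(gg, "x1", list(c(0, 2)))
  q$S <- 0L
  expect_error(recommend(gg, q), "S must be > 0")
  gg2 <- rec_graph(matrix(1, 1, 1), intakes = 1)   # no ranges
  expect_error(recommend(gg2, simple_query(gg2, "x1", list(c(0, 2)))),
               "target ranges")
})

test_that("recommendations are reproducible under a fixed seed", {
  beta <- matrix(c(1, -0.2), 1, 2)
  gg <- rec_graph(beta, intakes = 2, alpha = 100,
                  ranges = flat_ranges(c("resp1", "resp2"), 0, 4))
  q <- simple_query(gg, "x1", list(c(0, 5)), S = 1000, conf = 0.5, seed = 11)
  expect_identical(recommend(gg, q)$samples, recommend(gg, q)$samples)
})
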