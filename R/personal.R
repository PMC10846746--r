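#' Target concentration ranges
#'
#' Builds per-patient normal (target) ranges for the three modelled plasma
#' concentrations. Potassium (P-K) and fasting phosphate (fP-Pi) targets are
#' the same for everyone (3.4-4.7 mmol/l and 1.13-1.78 mmol/l); the albumin
#' (P-Alb) range depends on age: 36-48 g/l up to age 39, 36-45 g/l for ages
#' 40-69, and 34-45 g/l from age 70 (age taken at the first observation).
#'
#' @param ages Named or unnamed numeric vector of patient ages; names (or
#'   positions) become patient ids.
#' @return A tibble with columns `patient`, `response`, `lower`, `upper`.
#' @export
normal_ranges <- function(ages) {
  ids <- if (!is.null(names(ages))) names(ages) else seq_along(ages)
  purrr::map_dfr(seq_along(ages), function(i) {
    alb <- if (ages[i] <= 39) c(36, 48)
           else if (ages[i] <= 69) c(36, 45)
           else c(34, 45)
    tibble(patient = ids[i],
           response = c("P_K", "fP_Pi", "P_Alb"),
           lower = c(3.4, 1.13, alb[1]),
           upper = c(4.7, 1.78, alb[2]))
  })
}

#' Read / write normal-range tables as YAML
#'
#' @param ranges A tibble as returned by [normal_ranges()].
#' @param path YAML file path.
#' @export
write_normal_ranges <- function(ranges, path) {
  yaml::write_yaml(lapply(split(ranges, ranges$patient), function(df)
    lapply(split(df, df$response), function(r)
      list(lower = r$lower, upper = r$upper))), path)
  invisible(path)
}

#' @rdname write_normal_ranges
#' @export
read_normal_ranges <- function(path) {
  raw <- yaml::read_yaml(path)
  purrr::imap_dfr(raw, function(resps, pid)
    purrr::imap_dfr(resps, function(rg, resp)
      tibble(patient = pid, response = resp,
             lower = rg$lower, upper = rg$upper)))
}

#' Estimate a patient's current intake distributions
#'
#' The expected intake of each predictor is the mean of the patient's
#' observations and the uncertainty is the sample sd (n-1 denominator). With a
#' single observation, or when the observations are identical, the sd is
#' floored at `sd_floor_frac` times the absolute mean so sampling from the
#' intake node stays possible.
#'
#' @param cohort A `cohort`.
#' @param patient Patient id.
#' @param sd_floor_frac Fraction of |mean| used as the sd floor (default 5%).
#' @return A tibble with columns `patient`, `predictor`, `mean`, `sd`, `n`.
#' @export
estimate_intakes <- function(cohort, patient, sd_floor_frac = 0.05) {
  rows <- cohort$data$patient == patient
  if (!any(rows)) abort(sprintf("unknown patient %s", patient))
  X <- cohort_X(cohort)[rows, , drop = FALSE]
  n <- nrow(X)
  mn <- unname(colMeans(X))
  s <- if (n >= 2) unname(apply(X, 2, stats::sd)) else rep(0, ncol(X))
  floor_sd <- sd_floor_frac * abs(mn)
  tibble(patient = patient, predictor = cohort$predictors,
         mean = mn, sd = pmax(s, floor_sd), n = n)
}

#' Build a patient's generative graphical model
#'
#' Combines the patient's intake distributions (normal, from
#' [estimate_intakes()]) with the draw-aligned personal effect posterior
#' (`beta + g_l + b_k`, the most detailed level of the hierarchy), the
#' per-response gamma shape draws and the patient's target concentration
#' ranges into one generative object: intake nodes feed every response node
#' through `p * M` effect edges.
#'
#' @param post An `hsur_fit`.
#' @param cohort The cohort the fit used.
#' @param patient Patient id.
#' @param ranges Optional tibble of target ranges (`response`, `lower`,
#'   `upper`; a `patient` column is filtered if present).
#' @param effects Optional personal-effect vector (length `p * M`, original
#'   scale) for patients absent from the fit, e.g. a row of
#'   [predict_personal_effects()]; their `b` is then this constant instead of
#'   posterior draws.
#' @param treatment Treatment id, required only with `effects` when the
#'   patient is not in `cohort`.
#' @return A `personal_graph` object.
#' @export
build_personal_graph <- function(post, cohort, patient, ranges = NULL,
                                 effects = NULL, treatment = NULL) {
  stopifnot(inherits(post, "hsur_fit"))
  p <- length(post$meta$predictors); M <- length(post$meta$responses)
  in_fit <- patient <= post$meta$K && is.null(effects)
  if (!in_fit && is.null(effects))
    abort(sprintf("patient %s is not in the fit; supply `effects`", patient))
  l <- treatment %||% unname(patient_treatment(cohort)[as.character(patient)])
  if (is.na(l) || is.null(l)) abort("missing treatment assignment")

  eff <- array(0, c(post$n_draws, p, M))
  for (m in seq_len(M)) {
    blk <- (m - 1) * p + seq_len(p)
    eff[, , m] <- post$draws$beta[, , m]
    if (!is.null(post$draws$g))
      eff[, , m] <- eff[, , m] + post$draws$g[, l, blk]
    if (in_fit) {
      eff[, , m] <- eff[, , m] + post$draws$b[, patient, blk]
    } else {
      eff[, , m] <- sweep(eff[, , m], 2, effects[blk], "+")
    }
  }
  # personal intercept absorbs the predictor centering of the fitted model
  icpt <- post$draws$intercept_raw
  for (m in seq_len(M))
    icpt[, m] <- icpt[, m] -
      as.numeric(matrix(eff[, , m], nrow = post$n_draws) %*% post$meta$center)

  if (!is.null(ranges) && "patient" %in% names(ranges))
    ranges <- ranges[ranges$patient == patient, ]
  intakes <- estimate_intakes(cohort, patient)

  structure(list(
    patient = patient, treatment = l,
    intakes = intakes,
    effect_draws = eff,                    # [draw, predictor, response]
    intercept_draws = icpt,                # [draw, response]
    alpha_draws = exp(post$draws$log_alpha),
    shift_c = post$meta$shift_c,
    predictors = post$meta$predictors,
    responses = post$meta$responses,
    ranges = ranges
  ), class = "personal_graph")
}

#' @export
print.personal_graph <- function(x, ...) {
  cat(sprintf(
    "<personal_graph> patient %s (treatment %s): %d intake nodes -> %d responses, %d effect edges, %d draws\n",
    x$patient, x$treatment, length(x$predictors), length(x$responses),
    length(x$predictors) * length(x$responses), nrow(x$intercept_draws)))
  invisible(x)
}

#' Convert a personal graph to an igraph object
#'
#' The generative model as a directed bipartite graph: one node per intake
#' distribution and one per concentration, with an edge per (predictor,
#' response) pair carrying the posterior-mean personal effect.
#'
#' @param graph A `personal_graph`.
#' @return An `igraph` graph.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "personal_graph"))
  p <- length(graph$predictors); M <- length(graph$responses)
  eff_mean <- apply(graph$effect_draws, c(2, 3), mean)
  edges <- tidyr::crossing(from = graph$predictors, to = graph$responses)
  edges$weight <- mapply(function(f, t)
    eff_mean[match(f, graph$predictors), match(t, graph$responses)],
    edges$from, edges$to)
  g <- igraph::graph_from_data_frame(
    edges,
    vertices = data.frame(
      name = c(graph$predictors, graph$responses),
      type = rep(c("intake", "response"), c(p, M))))
  g
}

#' Serialize a personal graph to JSON
#'
#' @param graph A `personal_graph`.
#' @param path Output path.
#' @export
write_personal_graph <- function(graph, path) {
  eff_mean <- apply(graph$effect_draws, c(2, 3), mean)
  out <- list(
    patient = graph$patient, treatment = graph$treatment,
    shift_c = graph$shift_c,
    intakes = graph$intakes,
    effects = list(predictors = graph$predictors,
                   responses = graph$responses,
                   mean = pack_mat(eff_mean)),
    alpha_mean = colMeans(graph$alpha_draws),
    ranges = graph$ranges
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate current concentrations from a personal graph
#'
#' Draws intakes from the patient's intake normals (truncated at zero:
#' negative intake is physically impossible), combines them with draw-aligned
#' personal effects and intercept, and samples shifted-gamma concentrations.
#' With the current diet unconditioned, the simulated concentrations are
#' expected to settle on the measured values.
#'
#' @param graph A `personal_graph`.
#' @param n_draws Number of simulated concentration vectors.
#' @param seed RNG seed.
#' @return A tibble `(draw, response, mu, value)`; attribute `"rejections"`
#'   counts draws resampled because the expected value fell at or below
#'   `-shift_c`.
#' @export
simulate_current <- function(graph, n_draws = 1000, seed = 1L) {
  stopifnot(inherits(graph, "personal_graph"))
  M <- length(graph$responses); p <- length(graph$predictors)
  if (n_draws == 0) {
    out <- tibble(draw = integer(), response = character(),
                  mu = numeric(), value = numeric())
    attr(out, "rejections") <- 0L
    return(out)
  }
  n_post <- nrow(graph$intercept_draws)
  with_seed(seed, {
    idx <- if (n_post >= n_draws) sample.int(n_post, n_draws)
           else sample.int(n_post, n_draws, replace = TRUE)
    rejections <- 0L
    draw_mu <- function(n, which_idx) {
      Xsim <- matrix(rnorm(n * p, mean = rep(graph$intakes$mean, each = n),
                           sd = rep(graph$intakes$sd, each = n)), n, p)
      Xsim <- pmax(Xsim, 0)
      mu <- matrix(0, n, M)
      for (m in seq_len(M))
        mu[, m] <- graph$intercept_draws[which_idx, m] +
          rowSums(Xsim * graph$effect_draws[which_idx, , m])
      mu
    }
    mu <- draw_mu(n_draws, idx)
    bad <- which(apply(mu + graph$shift_c <= 0, 1, any))
    tries <- 0
    while (length(bad) > 0 && tries < 100) {
      rejections <- rejections + length(bad)
      mu[bad, ] <- draw_mu(length(bad), idx[bad])
      bad <- bad[apply(mu[bad, , drop = FALSE] + graph$shift_c <= 0, 1, any)]
      tries <- tries + 1
    }
    if (length(bad) > 0)
      abort("could not find expected values above -shift_c after 100 resampling rounds")
    a <- graph$alpha_draws[idx, , drop = FALSE]
    y <- matrix(rgamma(n_draws * M, shape = a,
                       rate = a / (mu + graph$shift_c)),
                n_draws, M) - graph$shift_c
    out <- tibble(
      draw = rep(seq_len(n_draws), M),
      response = rep(graph$responses, each = n_draws),
      mu = c(mu), value = c(y))
    attr(out, "rejections") <- rejections
    out
  })
}
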