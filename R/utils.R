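#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats rnorm runif rgamma rbinom dgamma pgamma qgamma quantile
#'   sd optim setNames cov2cor
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Stacked-effect indexing: effect vectors of length p*M are laid out
# predictor-fastest within response blocks, d = (m-1)*p + j.
effect_index <- function(p, M, predictors = NULL, responses = NULL) {
  tibble(
    d = seq_len(p * M),
    j = rep(seq_len(p), M),
    m = rep(seq_len(M), each = p),
    predictor = rep(predictors %||% paste0("x", seq_len(p)), M),
    response  = rep(responses %||% paste0("y", seq_len(M)), each = p)
  )
}

check_corr <- function(C, name = "C") {
  if (!is.matrix(C) || nrow(C) != ncol(C))
    abort(sprintf("%s must be a square matrix", name))
  if (max(abs(C - t(C))) > 1e-8)
    abort(sprintf("%s must be symmetric", name))
  if (max(abs(diag(C) - 1)) > 1e-8)
    abort(sprintf("%s must have a unit diagonal", name))
  ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10)
    abort(sprintf(
      "%s is not positive definite (smallest eigenvalue %.3e)", name, ev))
  invisible(C)
}

#' Random correlation matrix
#'
#' Draws a random correlation matrix by the C-vine method with Beta-distributed
#' partial correlations, giving a draw whose density is proportional to
#' \eqn{\det(C)^{\eta - 1}} (the usual shape-controlled family used as a prior
#' on correlation matrices). Larger `eta` concentrates mass near the identity.
#'
#' @param d Dimension.
#' @param eta Concentration parameter (> 0). `eta = 1` is uniform over
#'   correlation matrices.
#' @param seed Optional integer seed; when given the draw is reproducible and
#'   the caller's RNG state is untouched.
#' @return A `d x d` correlation matrix.
#' @export
rcorr_vine <- function(d, eta = 2, seed = NULL) {
  draw <- function() {
    if (d == 1) return(matrix(1, 1, 1))
    P <- matrix(0, d, d)
    S <- diag(d)
    for (k in seq_len(d - 1)) {
      for (i in seq(k + 1, d)) {
        a <- eta + (d - 1 - k) / 2
        P[k, i] <- 2 * stats::rbeta(1, a, a) - 1
        rho <- P[k, i]
        if (k > 1) {
          for (l in seq(k - 1, 1)) {
            rho <- rho * sqrt((1 - P[l, i]^2) * (1 - P[l, k]^2)) +
              P[l, i] * P[l, k]
          }
        }
        S[k, i] <- S[i, k] <- rho
      }
    }
    S
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Cross-response effect correlation matrix
#'
#' Builds a `p*M x p*M` correlation matrix in which each predictor's effects on
#' different responses are correlated with strength `rho` while effects of
#' different predictors are uncorrelated: `C = R_M %x% I_p` where `R_M` is the
#' `M x M` equicorrelation matrix. Used to generate cohorts whose effects are
#' correlated across responses (the structure a multivariate fit can exploit).
#'
#' @param p Predictor count.
#' @param M Response count.
#' @param rho Cross-response correlation, in `(-1/(M-1), 1)`.
#' @return A correlation matrix of order `p * M`.
#' @export
cross_response_corr <- function(p, M, rho) {
  if (rho <= -1 / (M - 1) || rho >= 1)
    abort("rho must lie in (-1/(M-1), 1) for positive definiteness")
  R <- matrix(rho, M, M)
  diag(R) <- 1
  R %x% diag(p)
}

# Decompose a covariance matrix into sd vector, correlation and its Cholesky.
cov_to_tcl <- function(Sigma) {
  s <- sqrt(pmax(diag(Sigma), 0))
  C <- if (all(s > 0)) stats::cov2cor(Sigma) else diag(nrow(Sigma))
  L <- t(chol(C + diag(1e-10, nrow(C))))
  list(sigma = s, C = C, L = L)
}
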