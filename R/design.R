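#' Build the stacked SUR design system
#'
#' Assembles the single "univariate" design of the multivariate model: the
#' predictor matrix is replicated block-diagonally over the `M` response
#' blocks (`X_full = I_M %x% X`), and treatment / patient selector matrices
#' `Zg_full`, `Zb_full` place the same predictor values into the column block
#' of the observation's treatment (resp. patient), so that for any coefficient
#' vectors `X_full %*% beta + Zg_full %*% g + Zb_full %*% b` reproduces every
#' observation's expected value `sum_j x_j (beta_jm + g_ljm + b_kjm)`.
#'
#' Rows are ordered response-block-major (all observations of response 1, then
#' response 2, ...). Effect vectors use the package-wide layout
#' `d = (m - 1) * p + j`; the `g` vector stacks `L` such blocks, `b` stacks
#' `K`.
#'
#' @param cohort A `cohort`.
#' @return An object of class `design_system` with elements `X_full`,
#'   `Zg_full`, `Zb_full`, `row_index` (tibble `row, k, m, i`), and column
#'   index tibbles `col_index_beta`, `col_index_g`, `col_index_b`.
#' @export
build_design <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  d <- cohort$data
  if (any(is.na(d$treatment)))
    abort(sprintf("patient %d has no treatment assignment",
                  d$patient[which(is.na(d$treatment))[1]]))
  p <- length(cohort$predictors); M <- length(cohort$responses)
  K <- max(d$patient); L <- max(d$treatment)
  X <- cohort_X(cohort)
  n <- nrow(X)
  pM <- p * M

  X_full <- diag(M) %x% X

  Zg_full <- matrix(0, M * n, L * pM)
  Zb_full <- matrix(0, M * n, K * pM)
  for (m in seq_len(M)) {
    rows <- (m - 1) * n + seq_len(n)
    for (r in seq_len(n)) {
      off <- (m - 1) * p + seq_len(p)
      Zg_full[rows[r], (d$treatment[r] - 1) * pM + off] <- X[r, ]
      Zb_full[rows[r], (d$patient[r] - 1) * pM + off] <- X[r, ]
    }
  }

  row_index <- tibble(
    row = seq_len(M * n),
    k = rep(d$patient, M),
    m = rep(seq_len(M), each = n),
    i = rep(d$obs, M)
  )
  col_index_beta <- effect_index(p, M, cohort$predictors, cohort$responses)
  col_index_g <- tidyr::crossing(l = seq_len(L), col_index_beta) |>
    dplyr::mutate(col = dplyr::row_number())
  col_index_b <- tidyr::crossing(k = seq_len(K), col_index_beta) |>
    dplyr::mutate(col = dplyr::row_number())

  structure(list(
    X_full = X_full, Zg_full = Zg_full, Zb_full = Zb_full,
    row_index = row_index, col_index_beta = col_index_beta,
    col_index_g = col_index_g, col_index_b = col_index_b,
    p = p, M = M, K = K, L = L, n = n
  ), class = "design_system")
}

#' Thin QR decorrelation of a design matrix
#'
#' Computes the scaled thin QR decomposition used to decorrelate collinear
#' predictors before posterior sampling: `Q_star = Q * sqrt(n - 1)`,
#' `R_star = R / sqrt(n - 1)`, so `Q_star %*% R_star = X` and regression on
#' `Q_star` yields decorrelated coefficients `beta_star` with
#' `beta = R_star^{-1} beta_star`.
#'
#' @param X Design matrix with full column rank.
#' @param n Row count used in the scaling (defaults to `nrow(X)`).
#' @return An object of class `qr_decorrelation` with `Q_star`, `R_star`,
#'   `R_star_inv`.
#' @export
thin_qr <- function(X, n = nrow(X)) {
  X <- as.matrix(X)
  if (n <= 1) abort("n must be > 1 for the sqrt(n - 1) scaling")
  dec <- qr(X)
  Q <- qr.Q(dec)
  R <- qr.R(dec)
  # pivoting is off by default; enforce positive diagonal for a unique factor
  sgn <- sign(diag(R))
  sgn[sgn == 0] <- 1
  Q <- Q %*% diag(sgn, ncol(X))
  R <- diag(sgn, ncol(X)) %*% R
  rel <- abs(diag(R)) / max(abs(diag(R)))
  if (any(rel < 1e-10)) {
    bad <- which(rel < 1e-10)[1]
    cors <- abs(stats::cor(X))
    diag(cors) <- 0
    partner <- which.max(cors[bad, ])
    abort(sprintf(
      "design is rank deficient: column %d is collinear (closest partner: column %d, |cor| = %.3f)",
      bad, partner, cors[bad, partner]))
  }
  s <- sqrt(n - 1)
  R_star <- R / s
  structure(list(
    Q_star = Q * s,
    R_star = R_star,
    R_star_inv = backsolve(R_star, diag(ncol(X))),
    n = n
  ), class = "qr_decorrelation")
}

#' Map decorrelated coefficients back to the predictor scale
#'
#' @param beta_star Coefficient vector (or matrix with one column per
#'   response block) on the decorrelated `Q_star` scale.
#' @param qr A [thin_qr()] result.
#' @return `R_star_inv %*% beta_star`, same shape as the input.
#' @export
recover_beta <- function(beta_star, qr) {
  stopifnot(inherits(qr, "qr_decorrelation"))
  bs <- as.matrix(beta_star)
  if (nrow(bs) != ncol(qr$R_star_inv))
    abort(sprintf("beta_star has length %d but the QR factor is %d x %d",
                  nrow(bs), nrow(qr$R_star), ncol(qr$R_star)))
  out <- qr$R_star_inv %*% bs
  if (is.vector(beta_star)) drop(out) else out
}

# Center/scale predictors for stable sampling. Continuous predictors are
# centered and scaled by their sample sd; binary ones are centered only.
# Returns the transformed matrix plus the affine map needed to report effects
# back on the original scale.
standardize_predictors <- function(X, binary, center = TRUE) {
  ctr <- if (center) colMeans(X) else rep(0, ncol(X))
  scl <- apply(X, 2, stats::sd)
  scl[binary] <- 1
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  list(X = Xs, center = ctr, scale = scl)
}
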