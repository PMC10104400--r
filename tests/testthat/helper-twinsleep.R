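# helpers shared across test files; all fixtures are generated in code

# pair data whose sample moments (n denominator) exactly equal a target
# bivariate-normal structure: mean 0, unit variances, correlation r
exact_moment_pairs <- function(n, r, zyg, seed = 1) {
  set.seed(seed)
  Y <- matrix(rnorm(2 * n), n)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  S <- crossprod(Y) / n
  Y <- Y %*% solve(chol(S)) %*% chol(matrix(c(1, r, r, 1), 2))
  tibble::tibble(family_id = paste0(zyg, seq_len(n)), zygosity = zyg,
                 y1 = Y[, 1], y2 = Y[, 2])
}

# 4-variate analogue for the bivariate models: sample moments set exactly
# to a target per-zygosity covariance with zero means
exact_moment_pairs4 <- function(n, sigma, zyg, seed = 1) {
  set.seed(seed)
  Y <- matrix(rnorm(4 * n), n)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  S <- crossprod(Y) / n
  Y <- Y %*% solve(chol(S)) %*% chol(sigma)
  tibble::tibble(family_id = paste0(zyg, seq_len(n)), zygosity = zyg,
                 x1 = Y[, 1], y1 = Y[, 2], x2 = Y[, 3], y2 = Y[, 4])
}

# lower-triangular Cholesky path set from target A, C, E covariance matrices
paths_from_matrices <- function(A, C, E) {
  list(A = t(chol(A)), C = t(chol(C)), E = t(chol(E)))
}

# closed-form -2lnL of the fully saturated 4-variate model per zygosity
# (free mean vector and covariance), complete data only
saturated_biv_m2ll <- function(pairs2) {
  Y <- as.matrix(pairs2[, c("x1", "y1", "x2", "y2")])
  total <- 0
  for (g in c("MZ", "DZ")) {
    Yg <- Y[pairs2$zygosity == g, , drop = FALSE]
    n <- nrow(Yg)
    S <- crossprod(scale(Yg, center = TRUE, scale = FALSE)) / n
    total <- total + n * (4 * log(2 * pi) +
                            as.numeric(determinant(S)$modulus) + 4)
  }
  total
}

quiet_falconer <- function(...) suppressWarnings(falconer(...))
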