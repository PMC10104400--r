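# ---- bivariate sufficient statistics ---------------------------------------
#
# Per-pair observation vector is (x1, y1, x2, y2): traits x and y for twin 1
# and twin 2. Full-information handling of missing entries works by grouping
# rows by zygosity and missingness pattern; each pattern contributes through
# the marginal normal of its observed coordinates, so subjects with a missing
# co-twin or a missing trait (e.g. no school nights) stay in the likelihood.

biv_stats <- function(pairs2) {
  pairs2 <- as_tibble(pairs2)
  need <- c("zygosity", "x1", "y1", "x2", "y2")
  if (!all(need %in% names(pairs2))) {
    abort("pairs need columns zygosity, x1, y1, x2, y2")
  }
  if (!all(pairs2$zygosity %in% c("MZ", "DZ"))) {
    abort("zygosity must be 'MZ' or 'DZ'")
  }
  Y <- as.matrix(pairs2[, c("x1", "y1", "x2", "y2")])
  obs <- !is.na(Y)
  keep <- rowSums(obs) > 0
  Y <- Y[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  zyg <- pairs2$zygosity[keep]
  pat_key <- paste(zyg, apply(obs, 1, paste, collapse = ""))
  groups <- lapply(split(seq_along(pat_key), pat_key), function(idx) {
    o <- which(obs[idx[1], ])
    Yi <- Y[idx, o, drop = FALSE]
    list(zyg = zyg[idx[1]], obs = o, n = length(idx),
         S = crossprod(Yi), s = colSums(Yi))
  })
  structure(groups,
            hash = rlang::hash(list(zyg, Y)),
            n_pairs = c(MZ = sum(zyg == "MZ" & rowSums(obs) == 4),
                        DZ = sum(zyg == "DZ" & rowSums(obs) == 4)))
}

neg2ll_biv <- function(stats, sigma_mz, sigma_dz, mu) {
  tot <- 0
  for (g in stats) {
    sig <- if (g$zyg == "MZ") sigma_mz else sigma_dz
    o <- g$obs
    S <- sig[o, o, drop = FALSE]
    m <- mu[o]
    dt <- determinant(S, logarithm = TRUE)
    if (dt$sign <= 0) return(Inf)
    Sinv <- tryCatch(solve(S), error = function(e) NULL)
    if (is.null(Sinv)) return(Inf)
    M <- g$S - tcrossprod(g$s, m) - tcrossprod(m, g$s) + g$n * tcrossprod(m)
    tot <- tot + g$n * (length(o) * log(2 * pi) + as.numeric(dt$modulus)) +
      sum(Sinv * M)
  }
  tot
}

lower2 <- function(d1, off, d2) matrix(c(d1, off, 0, d2), 2)

# moment-based starting A, C, E matrices from complete-pair moments
biv_moment_start <- function(pairs2) {
  W <- matrix(0, 2, 2); B <- list(MZ = matrix(0.3, 2, 2),
                                  DZ = matrix(0.15, 2, 2))
  d <- pairs2[complete.cases(pairs2[, c("x1", "y1", "x2", "y2")]), ]
  mu <- c(0, 0)
  if (nrow(d) >= 8) {
    M <- as.matrix(d[, c("x1", "y1", "x2", "y2")])
    mu <- colMeans(M)[1:2]
    for (g in c("MZ", "DZ")) {
      Mg <- M[d$zygosity == g, , drop = FALSE]
      if (nrow(Mg) >= 4) {
        Cv <- stats::cov(Mg)
        W <- W + (Cv[1:2, 1:2] + Cv[3:4, 3:4]) / 4
        B[[g]] <- (Cv[1:2, 3:4] + t(Cv[1:2, 3:4])) / 2
      }
    }
  }
  if (all(W == 0)) W <- diag(2)
  A <- 2 * (B$MZ - B$DZ); C <- 2 * B$DZ - B$MZ; E <- W - A - C
  list(mu = mu, A = near_pd(A, W), C = near_pd(C, W), E = near_pd(E, W))
}

near_pd <- function(M, W) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  lam <- pmax(e$values, 0.05 * mean(diag(W)))
  e$vectors %*% diag(lam) %*% t(e$vectors)
}

chol_start <- function(M) {
  L <- t(chol(M + diag(1e-8, 2)))
  c(L[1, 1], L[2, 1], L[2, 2])
}

# enforce reporting sign convention: nonnegative diagonals (column sign
# flips leave L %*% t(L) unchanged)
fix_signs <- function(L) {
  for (k in 1:2) if (L[k, k] < 0) L[, k] <- -L[, k]
  L
}

run_biv_opt <- function(start, obj) {
  perturb <- c(1, 0.6, 1.5, 0.3, 2)
  best <- NULL
  for (f in perturb) {
    s <- start
    s[-(1:2)] <- s[-(1:2)] * f
    opt <- suppressWarnings(
      nlminb(s, obj, control = list(eval.max = 5000, iter.max = 2000,
                                    rel.tol = 1e-13)))
    if (is.null(best) || opt$objective < best$objective - 1e-12) best <- opt
  }
  pol <- suppressWarnings(optim(best$par, obj, method = "BFGS",
                                control = list(reltol = 1e-13, maxit = 3000)))
  if (pol$value < best$objective) best <- list(par = pol$par,
                                               objective = pol$value)
  best
}

# ---- Cholesky decomposition ------------------------------------------------

#' Fit a bivariate Cholesky twin decomposition
#'
#' Maximum-likelihood fit of the 4-variate per-pair normal in which each of
#' the additive-genetic (A), shared-environmental (C) and
#' unique-environmental (E) covariance matrices is parameterized as a 2x2
#' lower-triangular path matrix (`A = L_A L_A'` etc.). Cross-twin blocks are
#' weighted `1.0 * A + C` for MZ and `0.5 * A + C` for DZ; E never crosses
#' twins. The triangular parameterization is saturated for a two-trait
#' genetic covariance structure, so the attained `-2 lnL` is identical
#' whichever trait is ordered first; what changes with order is the
#' common/specific split for the second trait, which is why the model is
#' conventionally run in both orders.
#'
#' @param pairs2 Pair-level tibble with `zygosity`, `x1`, `y1`, `x2`, `y2`
#'   (standardized residual traits x and y per twin; any entry may be
#'   missing).
#' @param order `c(1, 2)` fits with trait x first; `c(2, 1)` reverses the
#'   order (the data are permuted internally and results are reported in the
#'   fitted order).
#' @return Object of class `"chol_fit"`: `paths` (list `A`, `C`, `E` of
#'   lower-triangular matrices, nonnegative diagonals), `matrices` (the
#'   implied A/C/E covariance matrices), `decomposition` (per-trait common
#'   and specific variance shares; "common" for the second trait is the
#'   variance transmitted through the first trait's factors),
#'   `correlations` (from [correlation_decomposition()]), `minus2LL`,
#'   `n_params`, `AIC`, `order`, `traits`.
#' @export
fit_cholesky <- function(pairs2, order = c(1, 2)) {
  if (!identical(order, c(1, 2)) && !identical(order, c(2, 1))) {
    abort("order must be c(1, 2) or c(2, 1)")
  }
  traits <- c("x", "y")[order]
  d <- as_tibble(pairs2)
  if (identical(order, c(2, 1))) {
    d <- dplyr::rename(d, x1 = "y1", y1 = "x1", x2 = "y2", y2 = "x2")
  }
  stats <- biv_stats(d)
  mom <- biv_moment_start(d)
  start <- c(mom$mu, chol_start(mom$A), chol_start(mom$C), chol_start(mom$E))
  obj <- function(par) {
    A <- tcrossprod(lower2(par[3], par[4], par[5]))
    C <- tcrossprod(lower2(par[6], par[7], par[8]))
    E <- tcrossprod(lower2(par[9], par[10], par[11]))
    sig <- implied_biv_sigma(A, C, E)
    neg2ll_biv(stats, sig$MZ, sig$DZ, c(par[1], par[2], par[1], par[2]))
  }
  best <- run_biv_opt(start, obj)
  p <- best$par
  paths <- list(A = fix_signs(lower2(p[3], p[4], p[5])),
                C = fix_signs(lower2(p[6], p[7], p[8])),
                E = fix_signs(lower2(p[9], p[10], p[11])))
  mats <- lapply(paths, tcrossprod)
  V <- diag(mats$A + mats$C + mats$E)
  decomp <- map_dfr(c("A", "C", "E"), function(src) {
    L <- paths[[src]]
    tibble(source = src,
           trait = traits,
           share = diag(mats[[src]]) / V,
           common = c(L[1, 1]^2, L[2, 1]^2) / V,
           specific = c(0, L[2, 2]^2) / V)
  })
  structure(list(paths = paths, matrices = mats,
                 decomposition = decomp,
                 correlations = correlation_decomposition(mats),
                 mu = p[1:2], minus2LL = best$objective, n_params = 11,
                 AIC = best$objective + 22,
                 converged = is.finite(best$objective),
                 order = order, traits = traits,
                 data_hash = attr(stats, "hash"),
                 n_pairs = attr(stats, "n_pairs")),
            class = "chol_fit")
}

#' @export
print.chol_fit <- function(x, ...) {
  cat(sprintf("Bivariate Cholesky twin model (order: %s then %s)\n",
              x$traits[1], x$traits[2]))
  print(as.data.frame(x$decomposition), row.names = FALSE)
  cat(sprintf("  -2lnL = %.3f  AIC = %.3f\n", x$minus2LL, x$AIC))
  invisible(x)
}

#' @method tidy chol_fit
#' @export
tidy.chol_fit <- function(x, ...) x$decomposition

#' @method glance chol_fit
#' @export
glance.chol_fit <- function(x, ...) {
  cr <- x$correlations$summary
  tibble(minus2LL = x$minus2LL, n_params = x$n_params, AIC = x$AIC,
         converged = x$converged, rP = cr$rP, rG = cr$rG, rC = cr$rC,
         rE = cr$rE)
}

# ---- independent pathway model ---------------------------------------------

#' Fit a constrained bivariate independent-pathway twin model
#'
#' Common-factor model: one latent A, one C and one E factor load on both
#' traits, plus trait-specific A/C/E factors. Under the default constraint
#' the two loadings of each common factor are equated, leaving 9 structural
#' parameters — exactly the number of distinct moment conditions a two-group
#' bivariate twin design supplies, so any source left unconstrained makes
#' the model under-identified and is rejected before optimization.
#'
#' @inheritParams fit_cholesky
#' @param constraints Character vector of sources whose common-factor
#'   loadings are constrained equal across the two traits; must include all
#'   of `"A"`, `"C"`, `"E"` for identification (with two traits, a source
#'   with free loadings has four parameters against its three identified
#'   covariance entries, an unresolvable ridge).
#' @param drop Character vector of paths to fix at zero, from `"A_c"`,
#'   `"C_c"`, `"E_c"` (common loadings) and `"A_s1"`, `"A_s2"`, `"C_s1"`,
#'   `"C_s2"`, `"E_s1"`, `"E_s2"` (trait-specific paths) — the standard
#'   follow-up of dropping paths whose estimates are at or near zero.
#' @return Object of class `"ip_fit"`: `loadings` (common loading and
#'   specific paths per source), `matrices`, `decomposition` (per trait:
#'   common share `Ac`/`Cc`/`Ec` and specific share `As`/`Cs`/`Es` of total
#'   variance), `correlations`, `minus2LL`, `n_params`, `AIC`.
#' @export
fit_independent_pathway <- function(pairs2, constraints = c("A", "C", "E"),
                                    drop = character()) {
  if (!all(c("A", "C", "E") %in% constraints)) {
    abort(paste("under-identified: common-factor loadings must be",
                "constrained for all of A, C, E (free loadings leave more",
                "parameters than the 9 distinct moment conditions resolve)"),
          class = "twinsleep_identification_error")
  }
  pnames <- c("A_c", "A_s1", "A_s2", "C_c", "C_s1", "C_s2",
              "E_c", "E_s1", "E_s2")
  if (!all(drop %in% pnames)) {
    abort(paste("drop must be a subset of:", paste(pnames, collapse = ", ")))
  }
  free <- setdiff(pnames, drop)
  d <- as_tibble(pairs2)
  stats <- biv_stats(d)
  mom <- biv_moment_start(d)
  start_src <- function(M) {
    off <- sign(M[1, 2]) * sqrt(min(abs(M[1, 2]), 0.9 * min(diag(M))))
    c(off, sqrt(pmax(diag(M) - off^2, 0.05)))
  }
  start_all <- setNames(c(start_src(mom$A), start_src(mom$C),
                          start_src(mom$E)), pnames)
  start <- c(mom$mu, start_all[free])
  src_mat <- function(l, u1, u2) {
    tcrossprod(c(l, l)) + diag(c(u1^2, u2^2))
  }
  expand <- function(par) {
    full <- setNames(numeric(9), pnames)
    full[free] <- par[-(1:2)]
    full
  }
  obj <- function(par) {
    q <- expand(par)
    A <- src_mat(q["A_c"], q["A_s1"], q["A_s2"])
    C <- src_mat(q["C_c"], q["C_s1"], q["C_s2"])
    E <- src_mat(q["E_c"], q["E_s1"], q["E_s2"])
    sig <- implied_biv_sigma(A, C, E)
    neg2ll_biv(stats, sig$MZ, sig$DZ, c(par[1], par[2], par[1], par[2]))
  }
  best <- run_biv_opt(start, obj)
  p <- best$par
  q <- abs(expand(p))
  loads <- tibble(source = c("A", "C", "E"),
                  common = q[c("A_c", "C_c", "E_c")],
                  specific1 = q[c("A_s1", "C_s1", "E_s1")],
                  specific2 = q[c("A_s2", "C_s2", "E_s2")])
  mats <- list(A = src_mat(q["A_c"], q["A_s1"], q["A_s2"]),
               C = src_mat(q["C_c"], q["C_s1"], q["C_s2"]),
               E = src_mat(q["E_c"], q["E_s1"], q["E_s2"]))
  V <- diag(mats$A + mats$C + mats$E)
  decomp <- map_dfr(1:3, function(i) {
    tibble(source = loads$source[i],
           trait = c("x", "y"),
           share = diag(mats[[i]]) / V,
           common = loads$common[i]^2 / V,
           specific = c(loads$specific1[i], loads$specific2[i])^2 / V)
  })
  k <- 2 + length(free)
  structure(list(loadings = loads, matrices = mats, decomposition = decomp,
                 correlations = correlation_decomposition(mats),
                 mu = p[1:2], minus2LL = best$objective, n_params = k,
                 AIC = best$objective + 2 * k,
                 converged = is.finite(best$objective),
                 constraints = constraints, dropped = drop,
                 data_hash = attr(stats, "hash"),
                 n_pairs = attr(stats, "n_pairs")),
            class = "ip_fit")
}

#' @export
print.ip_fit <- function(x, ...) {
  cat("Constrained independent-pathway twin model\n")
  print(as.data.frame(x$decomposition), row.names = FALSE)
  cat(sprintf("  -2lnL = %.3f  AIC = %.3f\n", x$minus2LL, x$AIC))
  invisible(x)
}

#' @method tidy ip_fit
#' @export
tidy.ip_fit <- function(x, ...) x$decomposition

#' @method glance ip_fit
#' @export
glance.ip_fit <- function(x, ...) {
  cr <- x$correlations$summary
  tibble(minus2LL = x$minus2LL, n_params = x$n_params, AIC = x$AIC,
         converged = x$converged, rP = cr$rP, rG = cr$rG, rC = cr$rC,
         rE = cr$rE)
}

# ---- correlations and shared proportions -----------------------------------

#' Phenotypic, genetic and environmental correlations from a bivariate fit
#'
#' Given the A, C, E covariance matrices of a bivariate twin decomposition
#' (or a fitted `"chol_fit"`/`"ip_fit"`), computes the genetic correlation
#' `rG = A12 / sqrt(A11 * A22)` (and analogously `rC`, `rE`), the phenotypic
#' correlation `rP` as the standardized sum of the source covariances, and
#' the additive contribution of each source to `rP`, which sum to `rP`
#' exactly. A source with zero variance in either trait has an undefined
#' correlation, reported as `NA`.
#'
#' @param x A `"chol_fit"`, an `"ip_fit"`, or a list with 2x2 matrices `A`,
#'   `C`, `E`.
#' @return List with `summary` (one-row tibble `rP`, `rG`, `rC`, `rE`) and
#'   `contributions` (tibble: source, covariance, correlation, and its
#'   contribution to `rP`).
#' @examples
#' A <- matrix(c(.63, .35, .35, .44), 2)
#' C <- matrix(c(.05, 0, 0, .1), 2)
#' E <- diag(c(.32, .46))
#' correlation_decomposition(list(A = A, C = C, E = E))
#' @export
correlation_decomposition <- function(x) {
  mats <- if (inherits(x, c("chol_fit", "ip_fit"))) x$matrices else x
  if (!all(c("A", "C", "E") %in% names(mats))) {
    abort("need matrices A, C and E")
  }
  Vt <- mats$A + mats$C + mats$E
  sdP <- sqrt(diag(Vt))
  contrib <- map_dfr(c("A", "C", "E"), function(src) {
    M <- mats[[src]]
    v1 <- M[1, 1]; v2 <- M[2, 2]
    r <- if (v1 <= 1e-12 || v2 <= 1e-12) NA_real_ else
      M[1, 2] / sqrt(v1 * v2)
    tibble(source = src, covariance = M[1, 2], correlation = r,
           contribution_to_rP = M[1, 2] / (sdP[1] * sdP[2]))
  })
  rP <- sum(contrib$contribution_to_rP)
  list(summary = tibble(rP = rP,
                        rG = contrib$correlation[1],
                        rC = contrib$correlation[2],
                        rE = contrib$correlation[3]),
       contributions = contrib)
}

#' Shared proportion of a variance source
#'
#' Expresses how much of one trait's total variance from a source (e.g. its
#' genetic variance) is transmitted through the factor common to both
#' traits: `100 * common_share / total_share`, rounded to the nearest
#' integer percent for reporting.
#'
#' @param common_share Variance share through the common factor.
#' @param total_share The trait's total share from that source; must be
#'   positive and at least `common_share`.
#' @return Integer percentage.
#' @examples
#' shared_proportion(0.35, 0.63)  # 56
#' shared_proportion(0.18, 0.44)  # 41
#' @export
shared_proportion <- function(common_share, total_share) {
  if (any(total_share <= 0)) {
    abort("total share must be positive", class = "twinsleep_undefined")
  }
  if (any(common_share < 0) || any(common_share > total_share + 1e-12)) {
    abort("common share must lie in [0, total share]")
  }
  round(100 * common_share / total_share)
}
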