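# generating structure used throughout: genetic overlap between a
# duration-like trait (a2 = 0.63) and a midpoint-like trait (a2 = 0.44)
A_gen <- matrix(c(0.63, 0.35, 0.35, 0.44), 2)
C_gen <- matrix(c(0.05, 0.02, 0.02, 0.10), 2)
E_gen <- matrix(c(0.32, 0.01, 0.01, 0.46), 2)

biv_sigma <- function(A, C, E, r) {
  W <- A + C + E
  rbind(cbind(W, r * A + C), cbind(r * A + C, W))
}

test_that("Cholesky -2lnL is invariant to variable order", {
  cfg <- sim_config(n_mz_pairs = 400, n_dz_pairs = 400, n_singletons = 0,
                    bivariate_paths = paths_from_matrices(A_gen, C_gen,
                                                          E_gen))
  d <- simulate_bivariate_cholesky(cfg, seed = 51)
  f12 <- fit_cholesky(d, order = c(1, 2))
  f21 <- fit_cholesky(d, order = c(2, 1))
  expect_lt(abs(f12$minus2LL - f21$minus2LL), 1e-6)
  expect_equal(f12$traits, c("x", "y"))
  expect_equal(f21$traits, c("y", "x"))
})

test_that("Cholesky fit on exact moments recovers the generating matrices", {
  d <- dplyr::bind_rows(
    exact_moment_pairs4(600, biv_sigma(A_gen, C_gen, E_gen, 1), "MZ",
                        seed = 52),
    exact_moment_pairs4(600, biv_sigma(A_gen, C_gen, E_gen, 0.5), "DZ",
                        seed = 53))
  f <- fit_cholesky(d)
  expect_lt(max(abs(f$matrices$A - A_gen)), 1e-4)
  expect_lt(max(abs(f$matrices$C - C_gen)), 1e-4)
  expect_lt(max(abs(f$matrices$E - E_gen)), 1e-4)
  # closed-form oracle for rG from the generating path algebra
  rg_true <- A_gen[1, 2] / sqrt(A_gen[1, 1] * A_gen[2, 2])
  expect_equal(f$correlations$summary$rG, rg_true, tolerance = 1e-4)
})

test_that("genetic correlation near .54 is recovered at scale", {
  rg <- 0.54
  A <- matrix(c(0.63, rg * sqrt(0.63 * 0.44), rg * sqrt(0.63 * 0.44),
                0.44), 2)
  C <- diag(c(0.05, 0.10)); E <- diag(c(0.32, 0.46))
  cfg <- sim_config(n_mz_pairs = 5000, n_dz_pairs = 5000, n_singletons = 0,
                    bivariate_paths = paths_from_matrices(A, C, E))
  d <- simulate_bivariate_cholesky(cfg, seed = 54)
  f <- fit_cholesky(d)
  expect_equal(f$correlations$summary$rG, rg, tolerance = 0.05)
})

test_that("independent traits give null correlations", {
  paths <- paths_from_matrices(diag(c(0.6, 0.4)), diag(c(0.1, 0.2)),
                               diag(c(0.3, 0.4)))
  cfg <- sim_config(n_mz_pairs = 2000, n_dz_pairs = 2000, n_singletons = 0,
                    bivariate_paths = paths)
  d <- simulate_bivariate_cholesky(cfg, seed = 55)
  f <- fit_cholesky(d)
  expect_lt(abs(f$correlations$summary$rP), 0.05)
  expect_lt(abs(f$correlations$summary$rG), 0.12)
})

test_that("constrained IP recovers its own generating structure", {
  # equal-loadings IP truth with unit trait variances by construction
  l2 <- c(A = 0.25, C = 0.05, E = 0.08)
  mk <- function(lv2, u1, u2) tcrossprod(c(sqrt(lv2), sqrt(lv2))) +
    diag(c(u1, u2))
  A <- mk(l2["A"], 0.30, 0.15)   # shares .55 / .40
  C <- mk(l2["C"], 0.10, 0.15)   # shares .15 / .20
  E <- mk(l2["E"], 0.22, 0.32)   # shares .30 / .40
  # the model is just-identified, so on exact population moments the ML
  # fit must reproduce the generating loadings to optimizer precision
  dm <- dplyr::bind_rows(
    exact_moment_pairs4(400, biv_sigma(A, C, E, 1), "MZ", seed = 56),
    exact_moment_pairs4(400, biv_sigma(A, C, E, 0.5), "DZ", seed = 57))
  fm <- fit_independent_pathway(dm)
  expect_lt(max(abs(fm$loadings$common^2 - unname(l2))), 1e-5)
  # and on simulated cohorts it recovers them within Monte-Carlo error
  cfg <- sim_config(n_mz_pairs = 5000, n_dz_pairs = 5000, n_singletons = 0,
                    bivariate_paths = paths_from_matrices(A, C, E))
  d <- simulate_bivariate_cholesky(cfg, seed = 56)
  f <- fit_independent_pathway(d)
  expect_lt(max(abs(f$loadings$common^2 - unname(l2))), 0.05)
  dA <- f$decomposition[f$decomposition$source == "A", ]
  expect_lt(max(abs(dA$share - c(0.55, 0.40))), 0.05)
})

test_that("null components are recovered as zero and can be dropped", {
  # common-A-only overlap: no specific A, no C at all
  A <- tcrossprod(c(sqrt(0.5), sqrt(0.5)))
  C <- diag(c(1e-12, 1e-12)) + 0
  E <- diag(c(0.5, 0.5))
  sig_mz <- biv_sigma(A, C, E, 1); sig_dz <- biv_sigma(A, C, E, 0.5)
  d <- dplyr::bind_rows(exact_moment_pairs4(500, sig_mz, "MZ", seed = 57),
                        exact_moment_pairs4(500, sig_dz, "DZ", seed = 58))
  f <- fit_independent_pathway(d)
  dec <- f$decomposition
  expect_lt(max(dec$specific[dec$source == "A"]), 1e-3)
  expect_lt(max(dec$share[dec$source == "C"]), 1e-3)
  # dropping the zero paths leaves -2lnL unchanged
  f_drop <- fit_independent_pathway(
    d, drop = c("C_c", "C_s1", "C_s2", "A_s1", "A_s2"))
  expect_lt(abs(f_drop$minus2LL - f$minus2LL), 1e-6)
  expect_equal(f_drop$n_params, f$n_params - 5)
})

test_that("under-identified constraint sets are rejected upfront", {
  d <- dplyr::bind_rows(
    exact_moment_pairs4(50, biv_sigma(A_gen, C_gen, E_gen, 1), "MZ",
                        seed = 59),
    exact_moment_pairs4(50, biv_sigma(A_gen, C_gen, E_gen, 0.5), "DZ",
                        seed = 60))
  expect_error(fit_independent_pathway(d, constraints = c("C", "E")),
               class = "twinsleep_identification_error")
  expect_error(fit_independent_pathway(d, drop = "bogus"))
})

test_that("likelihoods order as saturated <= Cholesky <= constrained IP", {
  # generating structure violates the equal-loadings IP, so the IP must
  # fit strictly worse than the Cholesky at scale
  cfg <- sim_config(n_mz_pairs = 1500, n_dz_pairs = 1500, n_singletons = 0,
                    bivariate_paths = paths_from_matrices(A_gen, C_gen,
                                                          E_gen))
  d <- simulate_bivariate_cholesky(cfg, seed = 61)
  ch <- fit_cholesky(d)
  ip <- fit_independent_pathway(d)
  sat <- saturated_biv_m2ll(d)
  expect_lte(sat, ch$minus2LL + 1e-6)
  expect_lte(ch$minus2LL, ip$minus2LL + 1e-6)
})

test_that("bivariate per-trait shares agree with univariate ACE fits", {
  cfg <- sim_config(n_mz_pairs = 3000, n_dz_pairs = 3000, n_singletons = 0,
                    bivariate_paths = paths_from_matrices(A_gen, C_gen,
                                                          E_gen))
  d <- simulate_bivariate_cholesky(cfg, seed = 62)
  ch <- fit_cholesky(d)
  uni_x <- fit_ace_family(
    dplyr::transmute(d, family_id, zygosity, y1 = x1, y2 = x2), "ACE")
  share_x <- ch$decomposition$share[ch$decomposition$source == "A" &
                                      ch$decomposition$trait == "x"]
  expect_equal(share_x, uni_x$components$proportion[1], tolerance = 0.05)
})

test_that("correlation decomposition follows the path algebra", {
  dec <- correlation_decomposition(list(A = A_gen, C = C_gen, E = E_gen))
  rg <- A_gen[1, 2] / sqrt(A_gen[1, 1] * A_gen[2, 2])
  expect_equal(dec$summary$rG, rg, tolerance = 1e-12)
  # contributions sum to rP exactly
  expect_equal(sum(dec$contributions$contribution_to_rP), dec$summary$rP,
               tolerance = 1e-8)
  # single-source overlap: rP = rG * sqrt(a2_1 * a2_2)
  Aonly <- correlation_decomposition(
    list(A = A_gen, C = diag(c(0.05, 0.1)), E = diag(c(0.32, 0.46))))
  V1 <- A_gen[1, 1] + 0.05 + 0.32; V2 <- A_gen[2, 2] + 0.1 + 0.46
  expect_equal(Aonly$summary$rP,
               Aonly$summary$rG * sqrt(A_gen[1, 1] / V1 * A_gen[2, 2] / V2),
               tolerance = 1e-12)
  # all cross-paths zero
  null_dec <- correlation_decomposition(
    list(A = diag(c(0.5, 0.4)), C = diag(c(0.2, 0.2)),
         E = diag(c(0.3, 0.4))))
  expect_equal(null_dec$summary$rP, 0)
  expect_equal(null_dec$summary$rG, 0)
  # zero component variance: correlation undefined
  z <- correlation_decomposition(
    list(A = matrix(0, 2, 2), C = diag(c(0.5, 0.5)), E = diag(c(0.5, 0.5))))
  expect_true(is.na(z$summary$rG))
})

test_that("shared proportions match the printed overlap percentages", {
  expect_equal(shared_proportion(0.35, 0.63), 56)
  expect_equal(shared_proportion(0.18, 0.44), 41)
  expect_equal(shared_proportion(0.3, 0.3), 100)
  expect_error(shared_proportion(0.2, 0), class = "twinsleep_undefined")
  expect_error(shared_proportion(0.5, 0.4))
})

test_that("shared-genetic overlap of the generating IP structure is 56/41", {
  # unequal common shares (0.35 of trait 1, 0.18 of trait 2) are a property
  # of the generator; the Cholesky fit recovers the full genetic covariance
  # and the overlap percentages follow from the generating shares
  lA <- c(sqrt(0.35), sqrt(0.18))
  A <- tcrossprod(lA) + diag(c(0.28, 0.26))
  C <- diag(c(0.05, 0.10)); E <- diag(c(0.32, 0.46))
  cfg <- sim_config(n_mz_pairs = 4000, n_dz_pairs = 4000, n_singletons = 0,
                    bivariate_paths = paths_from_matrices(A, C, E))
  d <- simulate_bivariate_cholesky(cfg, seed = 63)
  f <- fit_cholesky(d)
  expect_lt(max(abs(f$matrices$A - A)), 0.05)
  expect_equal(shared_proportion(0.35, A[1, 1]), 56)
  expect_equal(shared_proportion(0.18, A[2, 2]), 41)
})
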