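test_that("falconer reproduces the printed component decompositions", {
  expect_equal(falconer(0.70, 0.39),
               c(a2 = 0.62, c2 = 0.08, e2 = 0.30))
  expect_equal(falconer(0.87, 0.65),
               c(a2 = 0.44, c2 = 0.43, e2 = 0.13))
  expect_equal(falconer(0.5, 0.25), c(a2 = 0.5, c2 = 0, e2 = 0.5))
  expect_warning(out <- falconer(0.4, 0.1), "clamped")
  expect_equal(unname(out["c2"]), 0)
  expect_error(falconer(1.2, 0.5))
})

test_that("ML ACE fit equals the closed-form oracle on exact moments", {
  d <- dplyr::bind_rows(exact_moment_pairs(400, 0.70, "MZ", seed = 1),
                        exact_moment_pairs(400, 0.39, "DZ", seed = 2))
  fit <- fit_ace_family(d, "ACE")
  expect_lt(max(abs(fit$components$proportion - c(0.62, 0.08, 0.30))), 1e-6)
  expect_equal(fit$mu, 0, tolerance = 1e-7)
  expect_equal(fit$variance, 1, tolerance = 1e-6)
})

test_that("no genetic signal when MZ and DZ correlations are equal", {
  d <- dplyr::bind_rows(exact_moment_pairs(300, 0.4, "MZ", seed = 3),
                        exact_moment_pairs(300, 0.4, "DZ", seed = 4))
  fit <- fit_ace_family(d, "ACE")
  expect_lt(fit$components$proportion[1], 1e-4)
})

test_that("saturated model recovers generating twin correlations", {
  cfg <- sim_config(n_mz_pairs = 5000, n_dz_pairs = 5000, n_singletons = 0,
                    a2 = 0.44, c2 = 0.43, e2 = 0.13)  # rMZ .87, rDZ .65
  d <- simulate_ace_pairs(cfg, seed = 31)
  names(d) <- c("family_id", "zygosity", "y1", "y2")
  s <- fit_saturated(d)
  est <- s$estimates
  expect_equal(est$correlation[est$zygosity == "MZ"], 0.87, tolerance = 0.02)
  expect_equal(est$correlation[est$zygosity == "DZ"], 0.65, tolerance = 0.02)
})

test_that("degenerate identical MZ pairs give a correlation of one", {
  y <- rnorm(50)
  d <- dplyr::bind_rows(
    tibble::tibble(family_id = paste0("M", 1:50), zygosity = "MZ",
                   y1 = y, y2 = y),
    exact_moment_pairs(50, 0.5, "DZ", seed = 5))
  s <- fit_saturated(d)
  expect_equal(s$estimates$correlation[s$estimates$zygosity == "MZ"], 1,
               tolerance = 1e-3)
})

test_that("ML correlation matches product-moment under equated moments", {
  set.seed(32)
  for (r in c(0.2, 0.6)) {
    d <- simulate_ace_pairs(sim_config(n_mz_pairs = 3000, n_dz_pairs = 3000,
                                       n_singletons = 0, a2 = r,
                                       c2 = 0, e2 = 1 - r), seed = NULL)
    s <- fit_saturated(d, equate = c("means_twin", "means_zyg",
                                     "vars_twin", "vars_zyg"))
    for (g in c("MZ", "DZ")) {
      pm <- with(d[d$zygosity == g & !is.na(d$y2), ], cor(y1, y2))
      ml <- s$estimates$correlation[s$estimates$zygosity == g]
      expect_lt(abs(ml - pm), 0.01)
    }
  }
})

test_that("equality tests accept true constraints and reject false ones", {
  d <- dplyr::bind_rows(exact_moment_pairs(400, 0.7, "MZ", seed = 6),
                        exact_moment_pairs(400, 0.4, "DZ", seed = 7))
  s <- fit_saturated(d)
  # moments are exactly equal across twins and zygosity: all tests pass
  expect_true(all(s$tests$p_value > 0.99))
  # inject a strong twin-2 mean shift in MZ pairs
  d2 <- d
  d2$y2[d2$zygosity == "MZ"] <- d2$y2[d2$zygosity == "MZ"] + 1
  s2 <- fit_saturated(d2)
  expect_lt(s2$tests$p_value[s2$tests$constraint == "means_twin"], 1e-6)
})

test_that("likelihoods are monotone across nested models", {
  for (seed in c(41, 42, 43)) {
    cfg <- sim_config(n_mz_pairs = 150, n_dz_pairs = 150, n_singletons = 20,
                      a2 = 0.5, c2 = 0.2, e2 = 0.3)
    d <- simulate_ace_pairs(cfg, seed = seed)
    fits <- lapply(c("ACE", "AE", "CE", "E"),
                   function(m) fit_ace_family(d, m))
    m2 <- vapply(fits, function(f) f$minus2LL, 0)
    names(m2) <- c("ACE", "AE", "CE", "E")
    expect_lte(m2["ACE"], m2["AE"] + 1e-6)
    expect_lte(m2["ACE"], m2["CE"] + 1e-6)
    expect_lte(m2["AE"], m2["E"] + 1e-6)
    expect_lte(m2["CE"], m2["E"] + 1e-6)
    # AIC bookkeeping
    for (f in fits) expect_equal(f$AIC, f$minus2LL + 2 * f$n_params)
  }
})

test_that("estimates are invariant to twin order and family shuffling", {
  cfg <- sim_config(n_mz_pairs = 200, n_dz_pairs = 200, n_singletons = 30)
  d <- simulate_ace_pairs(cfg, seed = 44)
  f0 <- fit_ace_family(d, "ACE")
  sw <- d  # swap twin slots within complete pairs

  comp <- !is.na(sw$y2)
  tmp <- sw$y1[comp]; sw$y1[comp] <- sw$y2[comp]; sw$y2[comp] <- tmp
  f1 <- fit_ace_family(sw, "ACE")
  f2 <- fit_ace_family(d[sample(nrow(d)), ], "ACE")
  expect_equal(f1$components$proportion, f0$components$proportion,
               tolerance = 1e-6)
  expect_equal(f2$components$proportion, f0$components$proportion,
               tolerance = 1e-6)
})

test_that("singletons contribute through the marginal likelihood", {
  cfg <- sim_config(n_mz_pairs = 300, n_dz_pairs = 300, n_singletons = 0)
  d <- simulate_ace_pairs(cfg, seed = 45)
  extra <- tibble::tibble(family_id = paste0("X", 1:100), zygosity = "MZ",
                          y1 = rnorm(100, 0, 1), y2 = NA_real_)
  f_with <- fit_ace_family(dplyr::bind_rows(d, extra), "ACE")
  f_without <- fit_ace_family(d, "ACE")
  expect_gt(f_with$minus2LL, f_without$minus2LL)  # more data, more -2lnL
  # proportions barely move: singletons carry no covariance information
  expect_equal(f_with$components$proportion,
               f_without$components$proportion, tolerance = 0.06)
})

test_that("model comparison ranks by AIC with correct bookkeeping", {
  d <- dplyr::bind_rows(exact_moment_pairs(250, 0.8, "MZ", seed = 8),
                        exact_moment_pairs(250, 0.4, "DZ", seed = 9))
  fits <- lapply(c("ACE", "AE", "CE", "E"),
                 function(m) fit_ace_family(d, m))
  cmp <- compare_models(fits)
  expect_equal(cmp$model[nrow(cmp)], "E")  # strongly familial: E last
  expect_equal(attr(cmp, "best"), cmp$model[1])
  expect_true(all(diff(cmp$AIC) >= 0))
  # mixed datasets rejected
  other <- fit_ace_family(exact_moment_pairs(100, 0.5, "MZ", seed = 10) |>
                            dplyr::bind_rows(exact_moment_pairs(
                              100, 0.2, "DZ", seed = 11)), "ACE")
  expect_error(compare_models(list(fits[[1]], other)),
               class = "twinsleep_data_mismatch")
})

test_that("AE is preferred over ACE in most replicates when C is zero", {
  set.seed(46)
  wins <- 0; nrep <- 20
  for (i in 1:nrep) {
    cfg <- sim_config(n_mz_pairs = 500, n_dz_pairs = 500, n_singletons = 0,
                      a2 = 0.5, c2 = 0, e2 = 0.5)
    d <- simulate_ace_pairs(cfg, seed = NULL)
    cmp <- compare_models(list(fit_ace_family(d, "ACE"),
                               fit_ace_family(d, "AE")))
    wins <- wins + (attr(cmp, "best") == "AE")
  }
  expect_gt(wins / nrep, 0.5)
})

test_that("profile intervals respect bounds and tighten with n", {
  d_small <- dplyr::bind_rows(exact_moment_pairs(80, 0.7, "MZ", seed = 12),
                              exact_moment_pairs(80, 0.4, "DZ", seed = 13))
  d_big <- dplyr::bind_rows(exact_moment_pairs(2000, 0.7, "MZ", seed = 14),
                            exact_moment_pairs(2000, 0.4, "DZ", seed = 15))
  f_small <- fit_ace_family(d_small, "ACE")
  f_big <- fit_ace_family(d_big, "ACE")
  ci_small <- profile_ci(f_small, "a2")
  ci_big <- profile_ci(f_big, "a2")
  expect_gte(ci_small["lower"], 0)
  expect_lte(ci_small["upper"], 1)
  expect_lt(diff(ci_big), diff(ci_small))
  # interval covers the point estimate
  ahat <- f_big$components$proportion[1]
  expect_true(ci_big["lower"] <= ahat && ahat <= ci_big["upper"])
  ci_e <- profile_ci(f_small, "e2")
  expect_gte(ci_e["lower"], 0)
  expect_error(profile_ci(fit_ace_family(d_small, "AE"), "c2"))
})

test_that("heritability estimates are unbiased at large sample sizes", {
  set.seed(47)
  for (a2_true in c(0.2, 0.5, 0.8)) {
    ahat <- vapply(1:40, function(i) {
      cfg <- sim_config(n_mz_pairs = 1000, n_dz_pairs = 1000,
                        n_singletons = 0, a2 = a2_true,
                        c2 = 0.1, e2 = 0.9 - a2_true)
      d <- simulate_ace_pairs(cfg, seed = NULL)
      fit_ace_family(d, "ACE")$components$proportion[1]
    }, 0)
    expect_lt(abs(mean(ahat) - a2_true), 0.03)
  }
})
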