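# ---- sufficient statistics -------------------------------------------------
#
# All univariate twin likelihoods run off per-zygosity sufficient statistics:
# complete pairs contribute through their uncentered scatter matrix, and
# incomplete pairs (singletons / missing co-twins) through per-slot marginal
# sums, the full-information treatment of missing-at-random co-twins. This
# makes each likelihood evaluation O(1) in the number of families.

uni_stats <- function(pairs) {
  pairs <- as_tibble(pairs)
  need <- c("zygosity", "y1", "y2")
  if (!all(need %in% names(pairs))) {
    abort("pairs need columns zygosity, y1, y2")
  }
  if (!all(pairs$zygosity %in% c("MZ", "DZ"))) {
    abort("zygosity must be 'MZ' or 'DZ'")
  }
  pairs <- filter(pairs, !(is.na(.data$y1) & is.na(.data$y2)))
  out <- lapply(c(MZ = "MZ", DZ = "DZ"), function(g) {
    d <- pairs[pairs$zygosity == g, ]
    comp <- d[!is.na(d$y1) & !is.na(d$y2), ]
    Y <- cbind(comp$y1, comp$y2)
    singles <- lapply(1:2, function(j) {
      v <- if (j == 1) d$y1[is.na(d$y2)] else d$y2[is.na(d$y1)]
      v[!is.na(v)]
    })
    list(n = nrow(Y),
         S = if (nrow(Y)) crossprod(Y) else matrix(0, 2, 2),
         s = if (nrow(Y)) colSums(Y) else c(0, 0),
         singles = singles)
  })
  attr(out, "hash") <- rlang::hash(list(pairs$zygosity, pairs$y1, pairs$y2))
  attr(out, "n_pairs") <- c(MZ = out$MZ$n, DZ = out$DZ$n)
  attr(out, "n_obs") <- sum(vapply(out, function(g)
    2 * g$n + sum(lengths(g$singles)), 0))
  out
}

# -2 log likelihood of one zygosity group given a 2x2 Sigma and mean vector
neg2ll_group <- function(st, sigma, mu) {
  det2 <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2]^2
  if (!is.finite(det2) || det2 <= 0 || sigma[1, 1] <= 0 || sigma[2, 2] <= 0) {
    return(Inf)
  }
  total <- 0
  if (st$n > 0) {
    M <- st$S - tcrossprod(st$s, mu) - tcrossprod(mu, st$s) +
      st$n * tcrossprod(mu)
    tr <- (sigma[2, 2] * M[1, 1] + sigma[1, 1] * M[2, 2] -
             2 * sigma[1, 2] * M[1, 2]) / det2
    total <- total + st$n * (2 * log(2 * pi) + log(det2)) + tr
  }
  for (j in 1:2) {
    v <- st$singles[[j]]
    if (length(v)) {
      total <- total + length(v) * (log(2 * pi) + log(sigma[j, j])) +
        sum((v - mu[j])^2) / sigma[j, j]
    }
  }
  total
}

ace_sigma <- function(a2, c2, e2, r) {
  v <- a2 + c2 + e2
  cv <- r * a2 + c2
  matrix(c(v, cv, cv, v), 2)
}

neg2ll_ace <- function(mu, a2, c2, e2, stats) {
  neg2ll_group(stats$MZ, ace_sigma(a2, c2, e2, 1), c(mu, mu)) +
    neg2ll_group(stats$DZ, ace_sigma(a2, c2, e2, 0.5), c(mu, mu))
}

# ---- ACE-family fits -------------------------------------------------------

#' Closed-form ACE decomposition from a pair of twin correlations
#'
#' The Falconer-style solution of the classical twin model when it is
#' just-identified by the two correlations: `a2 = 2 * (rmz - rdz)`,
#' `c2 = 2 * rdz - rmz`, `e2 = 1 - rmz`. Serves as the independent oracle
#' for the maximum-likelihood machinery: on data whose sample moments equal
#' a population ACE structure, the ML fit must reproduce this output.
#' Negative components are clamped to zero with a warning (no refitting).
#'
#' @param rmz,rdz MZ and DZ within-pair correlations, with
#'   `-1 <= rdz <= rmz <= 1`.
#' @return Named numeric `c(a2, c2, e2)` on the proportion scale.
#' @examples
#' falconer(0.70, 0.39)  # c(0.62, 0.08, 0.30)
#' @export
falconer <- function(rmz, rdz) {
  rmz <- as.numeric(rmz); rdz <- as.numeric(rdz)
  if (any(abs(c(rmz, rdz)) > 1)) abort("correlations must lie in [-1, 1]")
  out <- c(a2 = 2 * (rmz - rdz), c2 = 2 * rdz - rmz, e2 = 1 - rmz)
  if (any(out < 0)) {
    warn("negative variance component clamped to 0")
    out <- pmax(out, 0)
  }
  out
}

#' Fit a univariate ACE-family twin model by maximum likelihood
#'
#' Maximizes the structured bivariate-normal likelihood of twin-pair data:
#' both twins share a grand mean and total variance `a2 + c2 + e2`, and the
#' within-pair covariance is `a2 + c2` for MZ pairs and `0.5 * a2 + c2` for
#' DZ pairs (additive-genetic correlation fixed at 1.0/0.5 by kinship,
#' shared environment at 1.0, unique environment at 0). Paths are estimated
#' as unconstrained coefficients and squared, so variance components are
#' nonnegative by construction. Incomplete pairs contribute their marginal
#' likelihood. The E-only model has a closed-form solution. Optimization
#' uses quasi-Newton iterations from five perturbed moment-based starts.
#'
#' @param pairs Pair-level tibble with `zygosity`, `y1`, `y2` (standardized
#'   residuals; either twin may be missing).
#' @param model `"ACE"`, `"AE"`, `"CE"`, or `"E"`.
#' @param ci Logical: also compute 95% profile-likelihood intervals for the
#'   standardized components (see [profile_ci()]).
#' @return An object of class `"ace_fit"`: list with `model`, `components`
#'   (tibble of standardized `a2`, `c2`, `e2` and optional CIs), `mu`,
#'   `variance` (total), `minus2LL`, `n_params`, `AIC`, `converged`, and the
#'   sufficient statistics used. `tidy()`, `glance()` and `autoplot()`
#'   methods are available.
#' @examples
#' cfg <- sim_config(n_mz_pairs = 400, n_dz_pairs = 400, n_singletons = 0)
#' fit <- fit_ace_family(simulate_ace_pairs(cfg, seed = 7), "ACE")
#' tidy(fit)
#' @export
fit_ace_family <- function(pairs, model = c("ACE", "AE", "CE", "E"),
                           ci = FALSE) {
  model <- match.arg(model)
  stats <- uni_stats(pairs)
  fit <- fit_ace_core(stats, model)
  if (ci) {
    comps <- intersect(strsplit(model, "")[[1]], c("A", "C", "E"))
    lab <- c(A = "a2", C = "c2", E = "e2")
    cis <- map(lab[comps], function(cmp) profile_ci_core(fit, cmp))
    fit$components$lo <- NA_real_
    fit$components$hi <- NA_real_
    for (cmp in lab[comps]) {
      i <- match(cmp, fit$components$component)
      fit$components$lo[i] <- cis[[match(cmp, lab[comps])]][1]
      fit$components$hi[i] <- cis[[match(cmp, lab[comps])]][2]
    }
  }
  fit
}

fit_ace_core <- function(stats, model) {
  n_obs <- attr(stats, "n_obs")
  if (model == "E") {
    # closed form: mu = overall mean, v = ML mean squared deviation
    tot_n <- n_obs
    tot_sum <- sum(vapply(stats, function(g)
      sum(g$s) + sum(unlist(g$singles)), 0))
    mu <- tot_sum / tot_n
    ss <- sum(vapply(stats, function(g) {
      sum(diag(g$S)) - 2 * mu * sum(g$s) + 2 * g$n * mu^2 +
        sum((unlist(g$singles) - mu)^2)
    }, 0))
    v <- ss / tot_n
    m2 <- tot_n * (log(2 * pi) + log(v) + 1)
    return(new_ace_fit(model, mu, a2 = 0, c2 = 0, e2 = v,
                       minus2LL = m2, n_params = 2, converged = TRUE,
                       stats = stats))
  }
  free <- switch(model, ACE = c("a", "c", "e"), AE = c("a", "e"),
                 CE = c("c", "e"))
  # moment-based start
  mom <- moment_start(stats)
  start0 <- c(mu = mom$mu, sqrt(pmax(mom$comp, 0.02)) * sqrt(mom$v))
  names(start0) <- c("mu", "a", "c", "e")
  obj <- function(par) {
    a <- if ("a" %in% free) par[["a"]] else 0
    cc <- if ("c" %in% free) par[["c"]] else 0
    e <- par[["e"]]
    neg2ll_ace(par[["mu"]], a^2, cc^2, e^2, stats)
  }
  best <- NULL
  # deterministic spread of starting points (keeps fits RNG-independent)
  perturb <- list(c(1, 1, 1), c(1.4, 0.6, 1), c(0.6, 1.4, 1.1),
                  c(1.8, 1.8, 0.7), c(0.4, 0.4, 1.3))
  set_restarts <- lapply(perturb, function(f) {
    s <- start0[c("mu", free)]
    s[-1] <- s[-1] * f[seq_along(free)]
    s
  })
  for (s in set_restarts) {
    opt <- suppressWarnings(
      nlminb(s, obj, control = list(eval.max = 2000, iter.max = 1000,
                                    rel.tol = 1e-14, x.tol = 1e-14)))
    if (is.null(best) || opt$objective < best$objective - 1e-12) best <- opt
  }
  # quasi-Newton polish from the best point
  pol <- suppressWarnings(optim(best$par, obj, method = "BFGS",
                                control = list(reltol = 1e-14,
                                               maxit = 1000)))
  if (pol$value < best$objective) best <- list(par = pol$par,
                                               objective = pol$value,
                                               convergence = pol$convergence)
  par <- best$par
  a2 <- if ("a" %in% free) par[["a"]]^2 else 0
  c2 <- if ("c" %in% free) par[["c"]]^2 else 0
  e2 <- par[["e"]]^2
  new_ace_fit(model, par[["mu"]], a2, c2, e2,
              minus2LL = best$objective, n_params = 1 + length(free),
              converged = is.finite(best$objective), stats = stats)
}

moment_start <- function(stats) {
  cors <- vapply(stats, function(g) {
    if (g$n >= 3) {
      m <- g$s / g$n
      C <- g$S / g$n - tcrossprod(m)
      r <- C[1, 2] / sqrt(C[1, 1] * C[2, 2])
      if (is.finite(r)) max(min(r, 0.99), -0.99) else 0.3
    } else 0.3
  }, 0)
  if (cors["DZ"] > cors["MZ"]) cors["DZ"] <- cors["MZ"] * 0.5
  if (cors["MZ"] < 0) cors["MZ"] <- 0.1
  if (cors["DZ"] < 0) cors["DZ"] <- 0.05
  comp <- suppressWarnings(falconer(cors["MZ"], cors["DZ"]))
  n_obs <- attr(stats, "n_obs")
  tot_sum <- sum(vapply(stats, function(g)
    sum(g$s) + sum(unlist(g$singles)), 0))
  mu <- tot_sum / n_obs
  ss <- sum(vapply(stats, function(g)
    sum(diag(g$S)) - 2 * mu * sum(g$s) + 2 * g$n * mu^2 +
      sum((unlist(g$singles) - mu)^2), 0))
  list(mu = mu, v = ss / n_obs, comp = comp)
}

new_ace_fit <- function(model, mu, a2, c2, e2, minus2LL, n_params,
                        converged, stats) {
  v <- a2 + c2 + e2
  structure(list(
    model = model, mu = mu, variance = v,
    components = tibble(component = c("a2", "c2", "e2"),
                        variance = c(a2, c2, e2),
                        proportion = c(a2, c2, e2) / v),
    minus2LL = minus2LL, n_params = n_params,
    AIC = minus2LL + 2 * n_params,
    converged = converged,
    n_pairs = attr(stats, "n_pairs"),
    data_hash = attr(stats, "hash"),
    stats = stats), class = "ace_fit")
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf("%s twin model (%d MZ, %d DZ complete pairs)\n", x$model,
              x$n_pairs["MZ"], x$n_pairs["DZ"]))
  p <- x$components$proportion
  cat(sprintf("  a2 = %.3f  c2 = %.3f  e2 = %.3f\n", p[1], p[2], p[3]))
  cat(sprintf("  -2lnL = %.3f  AIC = %.3f (%d params)\n",
              x$minus2LL, x$AIC, x$n_params))
  invisible(x)
}

#' @method tidy ace_fit
#' @export
tidy.ace_fit <- function(x, ...) {
  out <- x$components
  names(out)[names(out) == "proportion"] <- "estimate"
  out$model <- x$model
  select(out, "model", "component", "estimate",
           dplyr::any_of(c("lo", "hi")))
}

#' @method glance ace_fit
#' @export
glance.ace_fit <- function(x, ...) {
  tibble(model = x$model, minus2LL = x$minus2LL, n_params = x$n_params,
         AIC = x$AIC, converged = x$converged,
         n_mz = unname(x$n_pairs["MZ"]), n_dz = unname(x$n_pairs["DZ"]))
}

# ---- saturated model -------------------------------------------------------

sat_par_map <- function(equate) {
  grp <- c("MZ", "DZ")
  name_grid <- function(prefix, eq_zyg, eq_twin) {
    m <- matrix("", 2, 2, dimnames = list(grp, NULL))
    for (g in 1:2) for (j in 1:2) {
      g2 <- if (eq_zyg %in% equate) "G" else grp[g]
      j2 <- if (eq_twin %in% equate) "1" else as.character(j)
      m[g, j] <- paste0(prefix, "_", g2, "_", j2)
    }
    m
  }
  mu_names <- name_grid("mu", "means_zyg", "means_twin")
  sd_names <- name_grid("lsd", "vars_zyg", "vars_twin")
  cor_names <- setNames(c("z_MZ", "z_DZ"), grp)
  list(mu = mu_names, sd = sd_names, cor = cor_names,
       free = unique(c(mu_names, sd_names, cor_names)))
}

neg2ll_sat <- function(par, map, stats) {
  tot <- 0
  for (g in c("MZ", "DZ")) {
    mu <- c(par[map$mu[g, 1]], par[map$mu[g, 2]])
    sds <- exp(c(par[map$sd[g, 1]], par[map$sd[g, 2]]))
    r <- tanh(par[map$cor[g]])
    sigma <- matrix(c(sds[1]^2, r * sds[1] * sds[2],
                      r * sds[1] * sds[2], sds[2]^2), 2)
    tot <- tot + neg2ll_group(stats[[g]], sigma, mu)
  }
  tot
}

fit_sat_core <- function(stats, equate) {
  map <- sat_par_map(equate)
  start <- setNames(numeric(length(map$free)), map$free)
  mom <- moment_start(stats)
  start[grepl("^mu", names(start))] <- mom$mu
  start[grepl("^lsd", names(start))] <- log(sqrt(mom$v))
  start[grepl("^z", names(start))] <- atanh(0.3)
  opt <- suppressWarnings(
    nlminb(start, neg2ll_sat, map = map, stats = stats,
           control = list(eval.max = 5000, iter.max = 2000,
                          rel.tol = 1e-13)))
  pol <- suppressWarnings(optim(opt$par, neg2ll_sat, map = map, stats = stats,
                                method = "BFGS",
                                control = list(reltol = 1e-13, maxit = 2000)))
  if (pol$value < opt$objective) {
    opt <- list(par = pol$par, objective = pol$value)
  }
  par <- opt$par
  est <- map_dfr(c("MZ", "DZ"), function(g) {
    tibble(zygosity = g,
           mean1 = unname(par[map$mu[g, 1]]),
           mean2 = unname(par[map$mu[g, 2]]),
           sd1 = exp(unname(par[map$sd[g, 1]])),
           sd2 = exp(unname(par[map$sd[g, 2]])),
           correlation = tanh(unname(par[map$cor[g]])))
  })
  list(estimates = est, minus2LL = opt$objective,
       n_params = length(map$free))
}

#' Fit the saturated twin model with optional equality constraints
#'
#' Estimates means, variances, and the within-pair correlation separately
#' for MZ and DZ pairs by full-information maximum likelihood (incomplete
#' pairs contribute marginally). Equality constraints across twin order or
#' zygosity can be imposed, and each candidate constraint is tested against
#' the fully free model by likelihood ratio — the standard preliminary step
#' before structural twin modeling.
#'
#' @inheritParams fit_ace_family
#' @param equate Character subset of `"means_twin"`, `"means_zyg"`,
#'   `"vars_twin"`, `"vars_zyg"` applied to the returned fit.
#' @return Object of class `"sat_fit"`: `estimates` (per-zygosity means,
#'   SDs, ML twin correlation), `minus2LL`, `n_params`, `AIC`, and `tests`
#'   (likelihood-ratio test of each single constraint against the free
#'   model).
#' @export
fit_saturated <- function(pairs, equate = character()) {
  ok <- c("means_twin", "means_zyg", "vars_twin", "vars_zyg")
  if (!all(equate %in% ok)) {
    abort(paste("equate must be a subset of:", paste(ok, collapse = ", ")))
  }
  stats <- uni_stats(pairs)
  for (g in c("MZ", "DZ")) {
    if (stats[[g]]$n < 2) abort("need at least 2 complete pairs per zygosity")
  }
  free <- fit_sat_core(stats, character())
  fit <- if (length(equate)) fit_sat_core(stats, equate) else free
  tests <- map_dfr(ok, function(con) {
    con_fit <- fit_sat_core(stats, con)
    df <- free$n_params - con_fit$n_params
    lr <- max(con_fit$minus2LL - free$minus2LL, 0)
    tibble(constraint = con, chisq = lr, df = df,
           p_value = pchisq(lr, df, lower.tail = FALSE))
  })
  structure(list(estimates = fit$estimates, equate = equate,
                 minus2LL = fit$minus2LL, n_params = fit$n_params,
                 AIC = fit$minus2LL + 2 * fit$n_params,
                 minus2LL_free = free$minus2LL, tests = tests,
                 n_pairs = attr(stats, "n_pairs"),
                 data_hash = attr(stats, "hash")),
            class = "sat_fit")
}

#' @export
print.sat_fit <- function(x, ...) {
  cat("Saturated twin model\n")
  print(as.data.frame(x$estimates), row.names = FALSE)
  cat(sprintf("  -2lnL = %.3f  AIC = %.3f (%d params)\n",
              x$minus2LL, x$AIC, x$n_params))
  invisible(x)
}

#' @method tidy sat_fit
#' @export
tidy.sat_fit <- function(x, ...) x$estimates

#' @method glance sat_fit
#' @export
glance.sat_fit <- function(x, ...) {
  tibble(minus2LL = x$minus2LL, n_params = x$n_params, AIC = x$AIC,
         n_mz = unname(x$n_pairs["MZ"]), n_dz = unname(x$n_pairs["DZ"]))
}

# ---- model comparison ------------------------------------------------------

#' Compare ACE-family model fits by AIC
#'
#' Ranks fits of the same data by Akaike's information criterion
#' (`-2 lnL + 2 * n_params`); lower is better, ties broken by fewer
#' parameters. Likelihood-ratio p-values of each submodel against the ACE
#' fit are reported when an ACE fit is supplied.
#'
#' @param fits List of `"ace_fit"` objects fitted to the same pair data.
#' @return Tibble `model`, `minus2LL`, `n_params`, `AIC`, `delta_AIC`,
#'   `lrt_p_vs_ACE`, ordered best first; the best model name is attached as
#'   `attr(, "best")`.
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "ace_fit")) fits <- list(fits)
  hashes <- vapply(fits, function(f) f$data_hash, "")
  if (length(unique(hashes)) != 1) {
    abort("fits were not computed on identical data",
          class = "twinsleep_data_mismatch")
  }
  tab <- map_dfr(fits, glance)
  ace <- purrr::detect(fits, function(f) f$model == "ACE")
  tab$lrt_p_vs_ACE <- vapply(fits, function(f) {
    if (is.null(ace) || f$model == "ACE") return(NA_real_)
    df <- ace$n_params - f$n_params
    if (df <= 0) return(NA_real_)
    pchisq(max(f$minus2LL - ace$minus2LL, 0), df, lower.tail = FALSE)
  }, 0)
  tab <- tab |>
    arrange(.data$AIC, .data$n_params) |>
    mutate(delta_AIC = .data$AIC - min(.data$AIC)) |>
    select("model", "minus2LL", "n_params", "AIC", "delta_AIC",
           "lrt_p_vs_ACE")
  attr(tab, "best") <- tab$model[1]
  tab
}

# ---- profile-likelihood confidence intervals -------------------------------

# -2lnL profiled at a fixed standardized proportion of one component.
# Parameterization: fixed target proportion t, one free proportion q for the
# remaining component(s) (ACE only), total variance v, grand mean mu.
profile_obj <- function(t, component, model, stats) {
  present <- switch(model, ACE = c("a2", "c2", "e2"),
                    AE = c("a2", "e2"), CE = c("c2", "e2"), E = "e2")
  if (!component %in% present) {
    abort(sprintf("component %s is fixed at 0 in the %s model",
                  component, model))
  }
  others <- setdiff(present, component)
  obj <- function(par) {
    mu <- par[1]; v <- par[2]
    if (v <= 1e-10) return(Inf)
    p <- setNames(numeric(3), c("a2", "c2", "e2"))
    p[component] <- t
    if (length(others) == 1) {
      p[others] <- 1 - t
    } else {
      q <- par[3]
      if (q < 0 || q > 1 - t) return(Inf)
      p[others[1]] <- q
      p[others[2]] <- 1 - t - q
    }
    neg2ll_ace(mu, p["a2"] * v, p["c2"] * v, p["e2"] * v, stats)
  }
  mom <- moment_start(stats)
  start <- c(mom$mu, mom$v)
  lower <- c(-Inf, 1e-8)
  upper <- c(Inf, Inf)
  if (length(others) == 2) {
    start <- c(start, min(max(mom$comp[others[1]], 0.01), 0.98 * (1 - t)))
    lower <- c(lower, 0)
    upper <- c(upper, 1 - t)
  }
  opt <- suppressWarnings(
    nlminb(start, obj, lower = lower, upper = upper,
           control = list(eval.max = 2000, iter.max = 1000,
                          rel.tol = 1e-12)))
  opt$objective
}

profile_ci_core <- function(fit, component, level = 0.95) {
  stats <- fit$stats
  crit <- qchisq(level, 1)
  thr <- fit$minus2LL + crit
  phat <- fit$components$proportion[match(component,
                                          fit$components$component)]
  f <- function(t) profile_obj(t, component, fit$model, stats) - thr
  eps <- 1e-6
  lo <- if (phat <= eps || f(eps) <= 0) 0 else
    uniroot(f, c(eps, phat), tol = 1e-6)$root
  hi <- if (phat >= 1 - eps || f(1 - eps) <= 0) 1 else
    uniroot(f, c(phat, 1 - eps), tol = 1e-6)$root
  c(lower = lo, upper = hi)
}

#' Profile-likelihood confidence interval for a variance proportion
#'
#' Likelihood-based interval for a standardized variance component: the set
#' of proportions whose profile `-2 lnL` (re-maximizing all other
#' parameters) rises no more than the chi-square(1) critical value above the
#' minimum. Bounded at the parameter limits 0 and 1; a profile that never
#' crosses the threshold reports the bound at the limit.
#'
#' @param fit An `"ace_fit"` from [fit_ace_family()].
#' @param component `"a2"`, `"c2"`, or `"e2"` (must be free in the model).
#' @param level Confidence level.
#' @return Named numeric `c(lower, upper)`.
#' @export
profile_ci <- function(fit, component = c("a2", "c2", "e2"), level = 0.95) {
  component <- match.arg(component)
  if (!inherits(fit, "ace_fit")) abort("fit must be an ace_fit")
  if (!fit$converged) abort("cannot profile a non-converged fit")
  profile_ci_core(fit, component, level)
}
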