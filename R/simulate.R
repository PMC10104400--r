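#' Simulation configuration for synthetic twin sleep cohorts
#'
#' Bundles every knob of the synthetic-data generators: cohort composition,
#' the generating ACE variance fractions, the per-phenotype night model, and
#' the data-quality processes (missing nights, diary noise, extreme
#' diary/device disparities). Defaults reproduce the study conditions of a
#' two-week adolescent twin actigraphy protocol: 93 MZ and 117 DZ pairs plus
#' 75 unpaired twins aged 9-17 (55% female), 14 nights per subject, and
#' sleep-duration-like generating components a2 = 0.62, c2 = 0.08, e2 = 0.30.
#'
#' The night model is a per-phenotype table of fixed effects. `mean` and `sd`
#' are the school-night subject-level mean and between-subject SD (minutes on
#' the noon-anchored axis for timing phenotypes, minutes for duration, a
#' probability for restorative sleep); `school_shift` is added on nonschool
#' nights; `age_slope` is per year of age centred at 13; `sex_effect` is the
#' male-minus-female contrast; `night_sd` is the within-subject nightly noise
#' SD. Restorative sleep is a nightly Bernoulli whose subject-level logit is
#' `qlogis(mean + fixed effects) + sd * latent`, with the same standardized
#' ACE latent construction as the continuous phenotypes, so `sd` for that row
#' is on the logit scale.
#'
#' @param n_mz_pairs,n_dz_pairs,n_singletons Cohort composition counts.
#' @param age_range Numeric length-2, years; ages drawn uniformly per family.
#' @param prop_female Probability an individual is female (MZ co-twins share
#'   sex; DZ co-twins are drawn independently, allowing opposite-sex pairs).
#' @param a2,c2,e2 Generating variance fractions; must sum to 1.
#' @param bivariate_paths Optional list of 2x2 lower-triangular path matrices
#'   `list(A =, C =, E =)` for [simulate_bivariate_cholesky()].
#' @param night_model Data frame with columns `phenotype` (onset, wake,
#'   duration, restorative), `mean`, `sd`, `school_shift`, `age_slope`,
#'   `sex_effect`, `night_sd`. Defaults described above.
#' @param n_nights Nights per subject (study period).
#' @param p_missing_night Probability a night's device data are missing
#'   (non-wear, malfunction).
#' @param diary_noise_sd SD (minutes) of diary-time error around truth.
#' @param p_extreme_disparity Probability a night's device onset is displaced
#'   by more than 6 h from the diary bedtime (device mix-up/malfunction
#'   nights that the preprocessing filter must catch).
#' @param start_dow Day-of-week of night 1's evening (1 = Monday ... 7 =
#'   Sunday). Nights whose evening is Friday or Saturday precede weekend
#'   mornings and are nonschool.
#' @param holiday_nights Integer night indices that fall in school holidays
#'   (also nonschool); set to `1:n_nights` to emulate subjects measured
#'   entirely during holidays.
#' @param age_ref Centring age (years) for `age_slope`.
#' @param seed Default seed used by generators when they are not given one.
#' @return A list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_mz_pairs = 10, n_dz_pairs = 10, n_singletons = 2)
#' cfg$a2 + cfg$c2 + cfg$e2
#' @export
sim_config <- function(n_mz_pairs = 93, n_dz_pairs = 117, n_singletons = 75,
                       age_range = c(9, 17), prop_female = 0.55,
                       a2 = 0.62, c2 = 0.08, e2 = 0.30,
                       bivariate_paths = NULL,
                       night_model = default_night_model(),
                       n_nights = 14, p_missing_night = 0.08,
                       diary_noise_sd = 10, p_extreme_disparity = 0.01,
                       start_dow = 1, holiday_nights = integer(),
                       age_ref = 13, seed = 20211022) {
  fr <- c(a2 = a2, c2 = c2, e2 = e2, prop_female = prop_female,
          p_missing_night = p_missing_night,
          p_extreme_disparity = p_extreme_disparity)
  if (any(fr < 0 | fr > 1)) {
    abort("variance fractions and probabilities must lie in [0, 1]",
          class = "twinsleep_config_error")
  }
  if (abs(a2 + c2 + e2 - 1) > 1e-12) {
    abort("a2 + c2 + e2 must equal 1", class = "twinsleep_config_error")
  }
  if (n_nights < 1) abort("n_nights must be >= 1",
                          class = "twinsleep_config_error")
  stopifnot(length(age_range) == 2, age_range[1] <= age_range[2])
  night_model <- as_tibble(night_model)
  need <- c("phenotype", "mean", "sd", "school_shift", "age_slope",
            "sex_effect", "night_sd")
  if (!all(need %in% names(night_model))) {
    abort(paste("night_model needs columns:", paste(need, collapse = ", ")),
          class = "twinsleep_config_error")
  }
  if (any(night_model$sd <= 0)) abort("night_model SDs must be positive",
                                      class = "twinsleep_config_error")
  if (!is.null(bivariate_paths)) validate_paths(bivariate_paths)
  structure(
    list(n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs,
         n_singletons = n_singletons, age_range = age_range,
         prop_female = prop_female, a2 = a2, c2 = c2, e2 = e2,
         bivariate_paths = bivariate_paths, night_model = night_model,
         n_nights = n_nights, p_missing_night = p_missing_night,
         diary_noise_sd = diary_noise_sd,
         p_extreme_disparity = p_extreme_disparity,
         start_dow = start_dow, holiday_nights = holiday_nights,
         age_ref = age_ref, seed = seed),
    class = "sim_config")
}

#' @rdname sim_config
#' @export
default_night_model <- function() {
  tibble(
    phenotype    = c("onset", "wake", "duration", "restorative"),
    # school-night means: onset 21:38, wake 06:39 on the noon axis,
    # duration 7 h 35 min, restorative sleep on 40% of nights
    mean         = c(hm_to_min("21:38"), hm_to_min("06:39"), 455, 0.40),
    sd           = c(60, 42, 36, 1.5),
    school_shift = c(25, 15, 2, 0.06),
    age_slope    = c(14, 6, -7, -0.02),
    sex_effect   = c(0, 0, -15, 0),
    night_sd     = c(45, 40, 50, NA_real_)
  )
}

# run code under a fixed seed without disturbing the caller's RNG stream;
# seed = NULL means "use the ambient stream"
maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

validate_paths <- function(paths) {
  if (!is.list(paths) || !all(c("A", "C", "E") %in% names(paths))) {
    abort("bivariate_paths must be list(A = , C = , E = ) of 2x2 matrices",
          class = "twinsleep_config_error")
  }
  for (nm in c("A", "C", "E")) {
    L <- paths[[nm]]
    if (!is.matrix(L) || !all(dim(L) == 2) || any(!is.finite(L)) ||
        abs(L[1, 2]) > 1e-12) {
      abort(sprintf("bivariate path matrix %s must be 2x2 lower-triangular", nm),
            class = "twinsleep_config_error")
    }
  }
  invisible(paths)
}

#' Generate a synthetic twin cohort roster
#'
#' Draws subjects with family structure: MZ and DZ complete pairs plus
#' unpaired twins (singletons). Co-twins share family id and age; MZ co-twins
#' share sex; zygosity of singletons is assigned at the MZ:DZ ratio of the
#' paired part of the cohort.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return Tibble with columns `subject_id`, `family_id`, `zygosity`,
#'   `twin_order` (1, 2, or "singleton"), `age`, `sex`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed) {
  maybe_with_seed(seed, {
    n_fam <- config$n_mz_pairs + config$n_dz_pairs + config$n_singletons
    zyg_prob <- if (config$n_mz_pairs + config$n_dz_pairs > 0) {
      c(config$n_mz_pairs, config$n_dz_pairs)
    } else c(1, 1)
    zyg_fam <- c(rep("MZ", config$n_mz_pairs), rep("DZ", config$n_dz_pairs),
                 sample(c("MZ", "DZ"), config$n_singletons, replace = TRUE,
                        prob = zyg_prob))
    paired <- rep(c(TRUE, FALSE),
                  c(config$n_mz_pairs + config$n_dz_pairs, config$n_singletons))
    age_fam <- runif(n_fam, config$age_range[1], config$age_range[2])
    k <- ifelse(paired, 2L, 1L)
    fam_idx <- rep(seq_len(n_fam), k)
    ord <- unlist(lapply(k, function(m) if (m == 2L) c("1", "2") else
      "singleton"), use.names = FALSE)
    draw_sex <- function(n) sample(c("F", "M"), n, replace = TRUE,
                                   prob = c(config$prop_female,
                                            1 - config$prop_female))
    sex1_fam <- draw_sex(n_fam)       # twin 1 / singleton sex per family
    sex <- sex1_fam[fam_idx]
    is2 <- ord == "2"
    # MZ co-twins share sex; DZ co-twin sex drawn independently
    sex[is2 & zyg_fam[fam_idx] == "DZ"] <-
      draw_sex(sum(is2 & zyg_fam[fam_idx] == "DZ"))
    tibble(subject_id = sprintf("S%05d", seq_along(fam_idx)),
           family_id = sprintf("F%05d", fam_idx),
           zygosity = zyg_fam[fam_idx],
           twin_order = ord,
           age = age_fam[fam_idx],
           sex = sex)
  })
}

# standardized ACE latent values for a cohort roster: one column per draw.
# A is shared for MZ co-twins and correlated 0.5 for DZ via a common +
# segregating split, C is shared within family, E is individual, so the
# kinship correlations are exact by construction.
ace_latent <- function(cohort, a2, c2, e2) {
  fam <- factor(cohort$family_id)
  nf <- nlevels(fam)
  a_fam <- rnorm(nf)[fam]
  a_ind <- rnorm(nrow(cohort))
  a <- ifelse(cohort$zygosity == "MZ", a_fam,
              sqrt(0.5) * a_fam + sqrt(0.5) * a_ind)
  c_fam <- rnorm(nf)[fam]
  e_ind <- rnorm(nrow(cohort))
  sqrt(a2) * a + sqrt(c2) * c_fam + sqrt(e2) * e_ind
}

#' Simulate pair-level phenotypes under a univariate ACE model
#'
#' Draws one standardized phenotype per subject with the familial covariance
#' the classical twin design assumes: additive-genetic latent values
#' correlate 1.0 within MZ pairs and 0.5 within DZ pairs, shared-environment
#' values correlate 1.0 in both, and unique-environment values are
#' independent, giving within-pair covariance `a2 + c2` (MZ) and
#' `0.5 * a2 + c2` (DZ). Singletons receive a marginal draw and appear with
#' `y2 = NA`.
#'
#' @inheritParams simulate_cohort
#' @return Tibble with `family_id`, `zygosity`, `y1`, `y2`.
#' @examples
#' cfg <- sim_config(n_mz_pairs = 200, n_dz_pairs = 200, n_singletons = 0,
#'                   a2 = 0.62, c2 = 0.08, e2 = 0.30)
#' pairs <- simulate_ace_pairs(cfg, seed = 1)
#' with(pairs[pairs$zygosity == "MZ", ], cor(y1, y2))
#' @export
simulate_ace_pairs <- function(config = sim_config(), seed = config$seed) {
  maybe_with_seed(seed, {
    cohort <- simulate_cohort(config, seed = NULL)
    cohort$y <- ace_latent(cohort, config$a2, config$c2, config$e2)
    wide_pairs(cohort, "y")
  })
}

# long roster with per-subject values -> pair-level wide table
# (twin 1 and singleton values land in the *1 slot, co-twins in *2)
wide_pairs <- function(cohort, cols) {
  first <- cohort[cohort$twin_order %in% c("1", "singleton"), , drop = FALSE]
  second <- cohort[cohort$twin_order == "2", , drop = FALSE]
  out <- tibble(family_id = first$family_id, zygosity = first$zygosity)
  idx <- match(first$family_id, second$family_id)
  for (v in cols) {
    out[[paste0(v, "1")]] <- first[[v]]
    out[[paste0(v, "2")]] <- second[[v]][idx]
  }
  arrange(out, .data$family_id)
}

#' Simulate two correlated phenotypes from Cholesky twin paths
#'
#' Generates pair-level data for two traits whose additive-genetic, shared-
#' and unique-environmental (co)variances are given by 2x2 lower-triangular
#' path matrices `L_A`, `L_C`, `L_E` (so e.g. the genetic covariance matrix
#' is `A = L_A %*% t(L_A)`). Cross-twin blocks follow kinship weighting:
#' `r * A + C` with `r` = 1 (MZ) or 0.5 (DZ); unique environment never
#' crosses twins. Trait variances are standardized to 1 (rows of the path
#' matrices are rescaled if needed, which leaves every variance share and
#' correlation unchanged).
#'
#' @inheritParams simulate_cohort
#' @param paths `list(A =, C =, E =)` of 2x2 lower-triangular matrices;
#'   defaults to `config$bivariate_paths`.
#' @return Tibble with `family_id`, `zygosity`, `x1`, `y1`, `x2`, `y2`
#'   (trait x and y for twin 1 and twin 2; singletons have twin-2 columns
#'   `NA`). The analytic implied 4x4 covariance matrices are attached as
#'   `attr(, "implied")`, a list with elements `MZ` and `DZ`.
#' @export
simulate_bivariate_cholesky <- function(config = sim_config(),
                                        paths = config$bivariate_paths,
                                        seed = config$seed) {
  if (is.null(paths)) abort("bivariate paths are required",
                            class = "twinsleep_config_error")
  validate_paths(paths)
  paths <- standardize_paths(paths)
  implied <- implied_biv_sigma(paths$A %*% t(paths$A),
                               paths$C %*% t(paths$C),
                               paths$E %*% t(paths$E))
  for (g in c("MZ", "DZ")) {
    ev <- eigen(implied[[g]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10) {
      abort("implied covariance is not positive definite",
            class = "twinsleep_config_error")
    }
  }
  maybe_with_seed(seed, {
    cohort <- simulate_cohort(config, seed = NULL)
    n <- nrow(cohort)
    fam <- factor(cohort$family_id)
    nf <- nlevels(fam)
    draw_factors <- function(r) {
      # 2 factor scores per person with cross-twin correlation r
      f_fam <- matrix(rnorm(2 * nf), nf)[fam, , drop = FALSE]
      f_ind <- matrix(rnorm(2 * n), n)
      mz <- cohort$zygosity == "MZ"
      w <- ifelse(mz, 1, r)  # MZ always share A fully
      sqrt(w) * f_fam + sqrt(1 - w) * f_ind
    }
    fA <- draw_factors(0.5)
    fC <- matrix(rnorm(2 * nf), nf)[fam, , drop = FALSE]
    fE <- matrix(rnorm(2 * n), n)
    Y <- fA %*% t(paths$A) + fC %*% t(paths$C) + fE %*% t(paths$E)
    cohort$x <- Y[, 1]
    cohort$y <- Y[, 2]
    out <- wide_pairs(cohort, c("x", "y"))
    out <- select(out, "family_id", "zygosity", "x1", "y1", "x2", "y2")
    attr(out, "implied") <- implied
    attr(out, "paths") <- paths
    out
  })
}

standardize_paths <- function(paths) {
  V <- diag(paths$A %*% t(paths$A) + paths$C %*% t(paths$C) +
            paths$E %*% t(paths$E))
  if (any(V <= 0)) abort("path matrices imply zero trait variance",
                         class = "twinsleep_config_error")
  if (max(abs(V - 1)) > 1e-8) {
    s <- 1 / sqrt(V)
    paths <- lapply(paths, function(L) diag(s) %*% L)
  }
  paths
}

# 4x4 implied covariance (order x1, y1, x2, y2) per zygosity from A, C, E
implied_biv_sigma <- function(A, C, E) {
  W <- A + C + E
  list(MZ = rbind(cbind(W, A + C), cbind(A + C, W)),
       DZ = rbind(cbind(W, 0.5 * A + C), cbind(0.5 * A + C, W)))
}

#' Simulate night-level sleep records for a cohort
#'
#' Gives each subject `n_nights` diary + device records. Each phenotype gets
#' a subject-level true value built from a standardized ACE latent (fresh
#' familial structure per phenotype) plus the night model's fixed age, sex
#' and school/nonschool effects, then independent nightly noise. Nights whose
#' evening is a Friday or Saturday, or that fall in a configured holiday
#' block, are nonschool. Device data go missing at `p_missing_night`;
#' a fraction `p_extreme_disparity` of nights get device onsets displaced
#' 6.2-9 h from the diary bedtime. Restorative sleep is a nightly Bernoulli
#' from a subject-level logit. All clock fields are minutes on the
#' noon-anchored axis (see [hm_to_min()]).
#'
#' @inheritParams simulate_cohort
#' @param cohort A cohort roster from [simulate_cohort()]; generated from
#'   `config` when omitted.
#' @return Tibble of night records: `subject_id`, `family_id`, `zygosity`,
#'   `twin_order`, `age`, `sex`, `night`, `night_type`, `diary_bed`,
#'   `diary_wake`, `dev_onset`, `dev_wake`, `duration`, `midpoint`,
#'   `restorative`. The per-subject true phenotype values are attached as
#'   `attr(, "truth")`.
#' @export
simulate_night_records <- function(config = sim_config(),
                                   cohort = NULL, seed = config$seed) {
  maybe_with_seed(seed, {
    if (is.null(cohort)) cohort <- simulate_cohort(config, seed = NULL)
    nm <- config$night_model
    male <- as.numeric(cohort$sex == "M")
    agec <- cohort$age - config$age_ref
    truth <- tibble(subject_id = cohort$subject_id)
    for (p in nm$phenotype) {
      r <- nm[nm$phenotype == p, ]
      lat <- ace_latent(cohort, config$a2, config$c2, config$e2)
      base <- r$mean + r$age_slope * agec + r$sex_effect * male
      truth[[p]] <- if (p == "restorative") {
        stats::plogis(stats::qlogis(pmin(pmax(base, 0.01), 0.99)) + r$sd * lat)
      } else base + r$sd * lat
    }
    nights <- seq_len(config$n_nights)
    dow <- (config$start_dow + nights - 2) %% 7 + 1  # 1 = Monday
    nonschool <- dow %in% c(5, 6) | nights %in% config$holiday_nights
    shift <- function(p) nm$school_shift[nm$phenotype == p]
    nsd <- function(p) nm$night_sd[nm$phenotype == p]
    n_sub <- nrow(cohort)
    nn <- config$n_nights
    long <- tibble(
      subject_id = rep(cohort$subject_id, each = nn),
      family_id = rep(cohort$family_id, each = nn),
      zygosity = rep(cohort$zygosity, each = nn),
      twin_order = rep(cohort$twin_order, each = nn),
      age = rep(cohort$age, each = nn),
      sex = rep(cohort$sex, each = nn),
      night = rep(nights, n_sub),
      night_type = rep(ifelse(nonschool, "nonschool", "school"), n_sub)
    )
    ns <- as.numeric(long$night_type == "nonschool")
    onset <- rep(truth$onset, each = nn) + shift("onset") * ns +
      rnorm(nrow(long), 0, nsd("onset"))
    wake <- rep(truth$wake, each = nn) + shift("wake") * ns +
      rnorm(nrow(long), 0, nsd("wake"))
    wake <- pmax(wake, onset + 60)  # guard: at least an hour in bed
    dur <- rep(truth$duration, each = nn) + shift("duration") * ns +
      rnorm(nrow(long), 0, nsd("duration"))
    dur <- pmin(pmax(dur, 30), wake - onset)
    # nonschool shift on the probability scale, clamped to (0, 1)
    p_rest <- pmin(pmax(rep(truth$restorative, each = nn) +
                          shift("restorative") * ns, 0.01), 0.99)
    long$restorative <- rbinom(nrow(long), 1, p_rest)
    long$diary_bed <- onset - 15 + rnorm(nrow(long), 0, config$diary_noise_sd)
    long$diary_wake <- wake + rnorm(nrow(long), 0, config$diary_noise_sd)
    extreme <- runif(nrow(long)) < config$p_extreme_disparity
    onset <- onset + extreme * sample(c(-1, 1), nrow(long), replace = TRUE) *
      runif(nrow(long), 372, 540)
    long$dev_onset <- onset
    long$dev_wake <- wake
    long$duration <- dur
    long$midpoint <- (long$dev_onset + long$dev_wake) / 2
    miss <- runif(nrow(long)) < config$p_missing_night
    for (v in c("dev_onset", "dev_wake", "duration", "midpoint")) {
      long[[v]][miss] <- NA_real_
    }
    attr(long, "truth") <- truth
    long
  })
}

#' Simulate a night of 5-second arm-angle epochs plus a diary entry
#'
#' Builds the raw input of the sleep detector: an arm-angle trace at 5 s
#' epochs over a recording window. During true sleep, epoch-to-epoch angle
#' changes are small Gaussian jitter (below the 5-degree detection threshold
#' unless `sleep_jitter_sd` is set large); outside it, epochs move by a
#' super-threshold amount at rate `wake_activity`. Brief nocturnal arousals
#' (1-min movement bursts) occur at `arousal_rate` per hour of sleep. Times
#' are minutes on the noon-anchored axis; the true onset/wake are snapped to
#' the epoch grid and returned so detector accuracy can be scored.
#'
#' @param true_onset,true_wake True sleep window, minutes from noon.
#' @param rec_start,rec_end Recording span, minutes from noon.
#' @param sleep_jitter_sd SD (degrees) of epoch-to-epoch angle change during
#'   sleep.
#' @param wake_activity Probability an awake epoch moves super-threshold.
#' @param arousal_rate Expected arousals per hour of sleep.
#' @param diary_noise_sd SD (minutes) of diary error; the diary window is
#'   bedtime = onset - `bed_lead` and rise time = wake + `rise_lag`, plus
#'   noise.
#' @param bed_lead,rise_lag Minutes the diary window extends beyond the true
#'   sleep window.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return List with `angles` (tibble `time`, `angle`), `diary` (tibble
#'   `bed`, `rise`), and `truth` (named numeric `onset`, `wake`, grid-snapped).
#' @export
simulate_angle_series <- function(true_onset, true_wake,
                                  rec_start = 300, rec_end = 1440,
                                  sleep_jitter_sd = 1, wake_activity = 0.3,
                                  arousal_rate = 0, diary_noise_sd = 0,
                                  bed_lead = 30, rise_lag = 30, seed = NULL) {
  if (!(rec_start <= true_onset && true_onset < true_wake &&
        true_wake <= rec_end)) {
    abort("sleep window must lie inside the recording span",
          class = "twinsleep_config_error")
  }
  maybe_with_seed(seed, {
    ep <- 5 / 60  # minutes
    times <- seq(rec_start, rec_end, by = ep)
    n <- length(times)
    onset <- times[which.min(abs(times - true_onset))]
    wake <- times[which.min(abs(times - true_wake))]
    asleep <- times >= onset & times < wake
    if (arousal_rate > 0) {
      hours <- (wake - onset) / 60
      k <- stats::rpois(1, arousal_rate * hours)
      if (k > 0) {
        starts <- runif(k, onset, wake - 1)
        for (s in starts) asleep[times >= s & times < s + 1] <- FALSE
      }
    }
    dchg <- numeric(n)
    move <- !asleep & (runif(n) < wake_activity)
    dchg[move] <- sample(c(-1, 1), sum(move), TRUE) * runif(sum(move), 10, 60)
    dchg[asleep] <- rnorm(sum(asleep), 0, sleep_jitter_sd)
    angle <- cumsum(dchg)
    angle <- angle - angle[1]
    diary <- tibble(
      bed = onset - bed_lead + rnorm(1, 0, diary_noise_sd),
      rise = wake + rise_lag + rnorm(1, 0, diary_noise_sd))
    list(angles = tibble(time = times, angle = angle),
         diary = diary,
         truth = c(onset = onset, wake = wake))
  })
}
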