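#' Analysis configuration for the end-to-end pipeline
#'
#' @param sim A [sim_config()] describing the synthetic cohort (or `NULL`
#'   if `nights` are supplied to [run_pipeline()] directly).
#' @param stratum `"full"`, `"younger"` (aged 9-14) or `"older"` (aged
#'   16-17); residualization and twin models are run within the stratum.
#' @param night_scopes Subset of `"all"`, `"school"`, `"nonschool"`.
#' @param phenotypes Phenotypes to model.
#' @param models Univariate ACE-family models to fit and compare.
#' @param bivariate_pair Two phenotypes for the duration-vs-timing style
#'   bivariate decomposition (run on the `"all"` scope), or `NULL` to skip.
#' @param ci Logical: compute profile-likelihood CIs for univariate
#'   components (slower).
#' @param seed Pipeline seed (also stamped on every output row).
#' @param out_dir Output directory for CSV/JSON tables, or `NULL` to skip
#'   writing.
#' @return List of class `"analysis_config"`.
#' @export
analysis_config <- function(sim = sim_config(),
                            stratum = c("full", "younger", "older"),
                            night_scopes = c("all", "school", "nonschool"),
                            phenotypes = c("onset", "wake", "duration",
                                           "midpoint", "restorative"),
                            models = c("ACE", "AE", "CE", "E"),
                            bivariate_pair = c("duration", "midpoint"),
                            ci = FALSE,
                            seed = if (!is.null(sim)) sim$seed else 20211022,
                            out_dir = NULL) {
  stratum <- match.arg(stratum)
  night_scopes <- match.arg(night_scopes, several.ok = TRUE)
  structure(list(sim = sim, stratum = stratum, night_scopes = night_scopes,
                 phenotypes = phenotypes, models = models,
                 bivariate_pair = bivariate_pair, ci = ci, seed = seed,
                 out_dir = out_dir),
            class = "analysis_config")
}

stratum_filter <- function(data, stratum) {
  out <- switch(stratum,
                full = data,
                younger = filter(data, .data$age < 15),
                older = filter(data, .data$age >= 16))
  if (nrow(out) == 0) {
    abort(sprintf("stratum '%s' contains no subjects", stratum),
          class = "twinsleep_empty_stratum")
  }
  out
}

#' Run the full twin sleep analysis pipeline
#'
#' Orchestrates simulate (or ingest) -> preprocess -> univariate ->
#' bivariate and emits machine-readable result tables: subject-level
#' descriptives by night scope, ML twin correlations (free and with
#' means/variances equated), univariate model-fit comparisons with variance
#' components, and the bivariate Cholesky (both orders) plus
#' independent-pathway decomposition. Every output row carries the seed and
#' a hash of the configuration, and the run is deterministic given the
#' seed.
#'
#' @param config An [analysis_config()].
#' @param nights Optional externally supplied night-record table with the
#'   columns of [simulate_night_records()]; when omitted, a cohort is
#'   simulated from `config$sim`.
#' @return List of class `"twin_pipeline"`: `descriptives`, `correlations`,
#'   `model_fits`, `bivariate`, `subjects` (per-scope subject tables),
#'   `exclusions`, `seed`, `config_hash`. Tables are also written as CSV
#'   (plus a JSON fit bundle) when `config$out_dir` is set.
#' @export
run_pipeline <- function(config = analysis_config(), nights = NULL) {
  if (is.null(nights)) {
    if (is.null(config$sim)) abort("either nights or config$sim is required")
    nights <- simulate_night_records(config$sim, seed = config$seed)
  }
  # hash the scientific configuration only, not where results are written
  hashable <- unclass(config)
  hashable$out_dir <- NULL
  cfg_hash <- rlang::hash(lapply(hashable, unclass))
  filt <- filter_nights(nights)
  subj <- lapply(setNames(config$night_scopes, config$night_scopes),
                 function(sc) {
                   stratum_filter(aggregate_subject(filt$nights, sc),
                                  config$stratum)
                 })
  desc <- descriptive_table(subj)

  cors <- list(); fits_tab <- list(); bundle <- list()
  for (ph in config$phenotypes) {
    for (sc in config$night_scopes) {
      d <- prepare_phenotype(subj[[sc]], ph)
      zcol <- paste0(ph, "_z")
      pr <- pairs_from_subjects(d, zcol)
      names(pr)[3:4] <- c("y1", "y2")
      sat_free <- fit_saturated(pr)
      sat_eq <- fit_saturated(pr, equate = c("means_twin", "means_zyg",
                                             "vars_twin", "vars_zyg"))
      cors[[paste(ph, sc)]] <- map_dfr(
        list(free = sat_free, constrained = sat_eq),
        function(f) {
          e <- f$estimates
          tibble(rMZ = e$correlation[e$zygosity == "MZ"],
                 rDZ = e$correlation[e$zygosity == "DZ"])
        }, .id = "saturated") |>
        mutate(phenotype = ph, scope = sc)
      fits <- map(setNames(config$models, config$models),
                  function(m) fit_ace_family(pr, m, ci = config$ci))
      cmp <- compare_models(fits)
      comps <- map_dfr(fits, function(f) {
        tidy(f) |>
          tidyr::pivot_wider(names_from = "component",
                             values_from = dplyr::any_of(c("estimate",
                                                           "lo", "hi")))
      })
      names(comps) <- sub("^estimate_", "", names(comps))
      fits_tab[[paste(ph, sc)]] <- cmp |>
        left_join(comps, by = "model") |>
        mutate(phenotype = ph, scope = sc,
               best = .data$model == attr(cmp, "best"))
      bundle[[paste(ph, sc, sep = "_")]] <- list(
        phenotype = ph, scope = sc,
        comparison = cmp, best = attr(cmp, "best"),
        saturated_tests = sat_free$tests)
    }
  }
  cors <- bind_rows(cors)
  fits_tab <- bind_rows(fits_tab)

  biv <- NULL
  if (!is.null(config$bivariate_pair) && "all" %in% config$night_scopes) {
    bp <- config$bivariate_pair
    d <- subj$all
    for (ph in bp) d <- prepare_phenotype(d, ph)
    pr2 <- pairs_from_subjects(d, paste0(bp, "_z"))
    names(pr2)[3:6] <- c("x1", "y1", "x2", "y2")
    ch12 <- fit_cholesky(pr2, order = c(1, 2))
    ch21 <- fit_cholesky(pr2, order = c(2, 1))
    ip <- fit_independent_pathway(pr2)
    lab <- function(f, nm) mutate(tidy(f), fit = nm,
                                  trait = bp[match(.data$trait, c("x", "y"))])
    biv <- bind_rows(lab(ch12, "cholesky_12"), lab(ch21, "cholesky_21"),
                     lab(ip, "independent_pathway")) |>
      mutate(pair = paste(bp, collapse = "~"))
    bundle$bivariate <- list(pair = bp,
                             cholesky = glance(ch12),
                             cholesky_reversed = glance(ch21),
                             independent_pathway = glance(ip))
  }

  stamp <- function(d) {
    if (is.null(d)) return(NULL)
    mutate(d, seed = config$seed, config_hash = cfg_hash)
  }
  out <- structure(list(descriptives = stamp(desc),
                        correlations = stamp(cors),
                        model_fits = stamp(fits_tab),
                        bivariate = stamp(biv),
                        subjects = subj, exclusions = filt$exclusions,
                        seed = config$seed, config_hash = cfg_hash),
                   class = "twin_pipeline")
  if (!is.null(config$out_dir)) write_pipeline(out, bundle, config$out_dir)
  out
}

write_pipeline <- function(out, bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(out$descriptives, file.path(dir, "descriptives.csv"))
  readr::write_csv(out$correlations, file.path(dir,
                                               "twin_correlations.csv"))
  readr::write_csv(out$model_fits, file.path(dir, "model_fits.csv"))
  if (!is.null(out$bivariate)) {
    readr::write_csv(out$bivariate, file.path(dir, "bivariate.csv"))
  }
  readr::write_csv(out$exclusions, file.path(dir, "exclusions.csv"))
  jsonlite::write_json(
    c(bundle, list(seed = out$seed, config_hash = out$config_hash)),
    file.path(dir, "fit_bundle.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(dir)
}

#' @export
print.twin_pipeline <- function(x, ...) {
  cat("Twin sleep pipeline result\n")
  cat(sprintf("  seed %s, config %s\n", x$seed, x$config_hash))
  cat(sprintf("  %d descriptive rows, %d correlation rows, %d fit rows\n",
              nrow(x$descriptives), nrow(x$correlations),
              nrow(x$model_fits)))
  invisible(x)
}

#' Descriptive phenotype table by night scope
#'
#' Mean, SD, range and N per phenotype and night scope, in the format of a
#' cohort descriptives table: timing phenotypes additionally as `"hh:mm"`
#' strings. School-vs-nonschool mean differences (and younger-vs-older on
#' all nights, when ages are present) are tested with Welch's t-test and
#' flagged at the Bonferroni-style threshold `p < alpha` (default .05/5).
#'
#' @param subjects Named list of subject-level tibbles (from
#'   [aggregate_subject()]) keyed by scope, e.g. `list(all =, school =,
#'   nonschool =)`.
#' @param alpha Significance threshold for the contrasts.
#' @return Tibble with one row per phenotype x scope; contrast tests are
#'   attached as `attr(, "tests")`.
#' @export
descriptive_table <- function(subjects, alpha = 0.05 / 5) {
  phen <- c("onset", "wake", "duration", "midpoint", "restorative")
  timing <- c("onset", "wake", "midpoint")
  rows <- map_dfr(names(subjects), function(sc) {
    d <- subjects[[sc]]
    map_dfr(intersect(phen, names(d)), function(p) {
      v <- d[[p]][!is.na(d[[p]])]
      tibble(phenotype = p, scope = sc, mean = mean(v), sd = sd(v),
             min = min(v), max = max(v), n = length(v),
             mean_hm = if (p %in% timing) min_to_hm(mean(v)) else
               NA_character_)
    })
  })
  tests <- NULL
  if (all(c("school", "nonschool") %in% names(subjects))) {
    tests <- map_dfr(intersect(phen, names(subjects$school)), function(p) {
      tt <- t.test(subjects$nonschool[[p]], subjects$school[[p]])
      tibble(contrast = "nonschool_vs_school", phenotype = p,
             difference = unname(diff(rev(tt$estimate))),
             p_value = tt$p.value, significant = tt$p.value < alpha)
    })
  }
  if ("all" %in% names(subjects) && "age" %in% names(subjects$all)) {
    d <- subjects$all
    yo <- map_dfr(intersect(phen, names(d)), function(p) {
      y <- d[[p]][d$age < 15]; o <- d[[p]][d$age >= 16]
      if (length(y) < 3 || length(o) < 3) return(NULL)
      tt <- t.test(o, y)
      tibble(contrast = "older_vs_younger", phenotype = p,
             difference = unname(diff(rev(tt$estimate))),
             p_value = tt$p.value, significant = tt$p.value < alpha)
    })
    tests <- bind_rows(tests, yo)
  }
  attr(rows, "tests") <- tests
  rows
}
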