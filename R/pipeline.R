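#' Configuration for the end-to-end pipeline
#'
#' Either a generator config (synthetic run) or paths to input tables
#' (response panel CSV, catalog JSON, covariate and outcome CSVs), plus
#' stage toggles and stage parameters.
#'
#' @param generator a \code{\link{generator_config}} (exclusive with
#'   \code{paths}).
#' @param paths named list with \code{panel}, \code{catalog},
#'   \code{covariates}, \code{outcomes} file paths (exclusive with
#'   \code{generator}).
#' @param stages character subset of
#'   \code{c("factor", "irt", "determinants", "patterns")}.
#' @param split_frac development-sample fraction for the factor screen.
#' @param fa_threshold baseline missingness exclusion threshold.
#' @param irt_threshold person-wave missingness exclusion threshold.
#' @param irt_models variance configurations to fit and compare.
#' @param n_iter,burn_in chain settings applied to every fitted model.
#' @param assign_cutoff loading cutoff for item-factor assignment.
#' @param n_trees_forest,n_trees_patterns ensemble sizes.
#' @param seed global seed.
#' @return Object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(generator = NULL, paths = NULL,
                            stages = c("factor", "irt", "determinants",
                                       "patterns"),
                            split_frac = 0.7, fa_threshold = 0.25,
                            irt_threshold = 0.5,
                            irt_models = c("M1_none",
                                           "M2_itemwise_intercept",
                                           "M3_homogeneous_intercept",
                                           "M4_hierarchical_full"),
                            n_iter = 5000L, burn_in = 100L,
                            assign_cutoff = 0.25,
                            n_trees_forest = 500L,
                            n_trees_patterns = 100L,
                            seed = 1L) {
  if (is.null(generator) == is.null(paths)) {
    stop("exactly one of generator or paths must be given")
  }
  if (!is.null(paths)) {
    missing_files <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(missing_files)) {
      stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
    }
  }
  structure(list(generator = generator, paths = paths, stages = stages,
                 split_frac = split_frac, fa_threshold = fa_threshold,
                 irt_threshold = irt_threshold, irt_models = irt_models,
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 assign_cutoff = assign_cutoff,
                 n_trees_forest = as.integer(n_trees_forest),
                 n_trees_patterns = as.integer(n_trees_patterns),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of \code{\link{pipeline_config}}; a
#' \code{generator:} block is passed to \code{\link{generator_config}}.
#'
#' @param path YAML file path.
#' @return A \code{"pipeline_config"}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$generator)) y$generator <- do.call(generator_config, y$generator)
  do.call(pipeline_config, y)
}

#' Run the full pipeline
#'
#' Executes, in order: cohort simulation or loading; item-prep filters;
#' the factor screen on the development/validation split of the baseline
#' wave (polychoric matrix, MAP test, minres EFA with geomin rotation,
#' item assignment, second-order CFA); multilevel IRT fits for the
#' requested variance configurations with model comparison; EAP scoring
#' and the 0-100 transform; determinant analyses (crossed mixed model,
#' LRT versus the linear model, pseudo R-squared, conditional ICC,
#' criterion-validity regression, gender-adjusted AUCs versus the
#' chronic-condition count); and pattern mining on the binned score. All
#' artifacts are plain CSV/JSON files under \code{out_dir}, with a
#' manifest recording seeds and parameters; any stage failure aborts
#' with the stage name after persisting earlier artifacts.
#'
#' @param config a \code{"pipeline_config"}.
#' @param out_dir output directory (created if needed); NULL skips
#'   writing.
#' @param verbose print stage timings.
#' @return Invisible list with every stage result.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  res <- list(config = config)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    say("stage %-12s %6.1fs", name,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }
  write_json <- function(x, f) {
    if (!is.null(out_dir)) {
      jsonlite::write_json(x, file.path(out_dir, f), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, force = TRUE)
    }
  }
  write_df <- function(x, f) {
    if (!is.null(out_dir)) write.csv(x, file.path(out_dir, f),
                                     row.names = FALSE)
  }

  # ---- data ---------------------------------------------------------------
  res$cohort <- stage("data", {
    if (!is.null(config$generator)) generate_cohort(config$generator)
    else load_cohort(config$paths)
  })
  coh <- res$cohort
  write_df(coh$panel, "response_panel.csv")

  # ---- item prep ----------------------------------------------------------
  res$prep <- stage("prep", {
    fa <- filter_participants_fa(coh$panel, threshold = config$fa_threshold)
    irt_panel <- filter_personwave_irt(fa$panel,
                                       threshold = config$irt_threshold)
    list(fa = fa, irt_panel = irt_panel,
         classes = classify_items(coh$catalog))
  })
  write_json(res$prep$fa$report, "exclusion_report.json")

  # ---- factor screen ------------------------------------------------------
  if ("factor" %in% config$stages) {
    res$factor <- stage("factor", {
      base <- panel_to_matrix(res$prep$fa$panel, wave = 1L)
      persons <- data.frame(person_id = as.integer(rownames(base)))
      persons <- merge(persons, coh$covariates, by = "person_id",
                       sort = TRUE)
      split <- split_sample(persons, frac = config$split_frac,
                            seed = config$seed)
      dev <- base[rownames(base) %in% as.character(split$development), ]
      val <- base[rownames(base) %in% as.character(split$validation), ]
      poly_dev <- polychoric_matrix(dev)
      map <- map_test(poly_dev, max_factors = min(10, ncol(base) - 1))
      nf <- max(map$n_factors, 1L)
      efa <- rotate_geomin(efa_minres(poly_dev, nf), seed = config$seed)
      assignment <- assign_items(efa, cutoff = config$assign_cutoff)
      cfa <- tryCatch(
        cfa_second_order(polychoric_matrix(val), assignment, N = nrow(val)),
        error = function(e) e)
      list(split = split, map = map, efa = efa, assignment = assignment,
           cfa = cfa)
    })
    if (!inherits(res$factor$cfa, "error")) {
      write_json(list(n_factors = res$factor$map$n_factors,
                      map_curve = res$factor$map$map_curve,
                      fit = unclass(res$factor$cfa$fit)),
                 "factor_screen.json")
    }
    write_df(as.data.frame(res$factor$efa$loadings), "efa_loadings.csv")
  }

  # ---- IRT ----------------------------------------------------------------
  if ("irt" %in% config$stages) {
    res$irt <- stage("irt", {
      fits <- list()
      for (mcfg in config$irt_models) {
        fits[[mcfg]] <- fit_mlirt(res$prep$irt_panel, coh$catalog,
                                  mlirt_spec(mcfg, n_iter = config$n_iter,
                                             burn_in = config$burn_in,
                                             seed = config$seed))
      }
      comparison <- compare_models(fits)
      best <- fits[[comparison$selected]]
      eap <- eap_scores(best)
      scores <- to_health_score(eap)
      list(fits = fits, comparison = comparison, best = best,
           eap = eap, scores = scores,
           reliability = eap_reliability(best), icc = wave_icc(best),
           sum_r = sumscore_correlation(scores, res$prep$irt_panel))
    })
    write_df(res$irt$scores, "health_scores.csv")
    write_df(res$irt$comparison$table, "model_comparison.csv")
    write_json(list(selected = res$irt$comparison$selected,
                    eap_reliability = res$irt$reliability,
                    wave_icc = res$irt$icc$icc,
                    wave_icc_ci = res$irt$icc$ci,
                    sumscore_correlation = res$irt$sum_r),
               "irt_summary.json")
  }

  # ---- determinants -------------------------------------------------------
  if ("determinants" %in% config$stages && !is.null(res$irt)) {
    res$determinants <- stage("determinants", {
      sc <- merge(res$irt$scores, coh$covariates, by = "person_id")
      covars <- intersect(names(default_covariate_effects()), names(sc))
      Xf <- data.frame(lapply(sc[covars], factor))
      lmm <- fit_lmm(sc$score, Xf, sc$person_id, sc$wave)
      ols <- lm(score ~ ., data = cbind(score = sc$score, Xf))
      lrt <- lrt_vs_linear(lmm, ols)
      base <- merge(sc[sc$wave == 1L, ], coh$outcomes, by = "person_id")
      cc <- chronic_count(base[paste0("cond", 1:8)])
      crit <- ols_standardized(
        base$score, cbind(base[paste0("cond", 1:8)],
                          base[c("gender", "age_group", "education")]))
      auc_h <- auc_gender_adjusted(base$score, base$mortality, base$gender)
      auc_c <- auc_gender_adjusted(-cc, base$mortality, base$gender)
      cmp <- compare_auc(base$score, -cc, base$mortality, base$gender)
      list(lmm = lmm, lrt = lrt,
           mcfadden = mcfadden_adjusted(lmm, ols_null(sc$score)),
           icc = conditional_icc(lmm), criterion = crit,
           auc_health = auc_h, auc_chronic = auc_c, auc_test = cmp)
    })
    write_df(res$determinants$lmm$coefficients, "mixed_model.csv")
    write_json(list(lrt = res$determinants$lrt,
                    mcfadden_adjusted = res$determinants$mcfadden,
                    conditional_icc = res$determinants$icc,
                    auc_health = res$determinants$auc_health$auc,
                    auc_chronic = res$determinants$auc_chronic$auc,
                    auc_delta_p = res$determinants$auc_test$p),
               "determinants.json")
  }

  # ---- patterns -----------------------------------------------------------
  if ("patterns" %in% config$stages && !is.null(res$irt)) {
    res$patterns <- stage("patterns", {
      sc <- merge(res$irt$scores, coh$covariates, by = "person_id")
      covars <- intersect(names(default_covariate_effects()), names(sc))
      Xf <- data.frame(lapply(sc[covars], factor))
      cls <- bin_health(sc$score)
      forest <- bagged_forest(Xf, cls, n_trees = config$n_trees_forest,
                              seed = config$seed)
      mda <- mda_importance(forest, Xf, cls, seed = config$seed)
      rules <- extract_patterns(Xf, cls,
                                n_trees = config$n_trees_patterns,
                                seed = config$seed)
      top <- top_patterns(rules)
      list(classes = cls, forest = forest, mda = mda, rules = rules,
           top = top)
    })
    write_df(res$patterns$mda, "mda_importance.csv")
    write_json(lapply(res$patterns$top$selected, function(r) {
      list(rule = format(r), class = r$class, support = r$support,
           accuracy = r$accuracy)
    }), "top_patterns.json")
  }

  # ---- manifest -----------------------------------------------------------
  if (!is.null(out_dir)) {
    manifest <- list(
      package_version = as.character(utils::packageVersion("healthtrait")),
      seed = config$seed, stages = config$stages,
      n_iter = config$n_iter, burn_in = config$burn_in,
      generator = if (!is.null(config$generator)) {
        unclass(config$generator)[c("n_persons", "n_waves", "n_items",
                                    "mcar_rate", "wave_effect_sd",
                                    "person_resid_sd", "seed")]
      },
      timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
    write_json(manifest, "manifest.json")
  }
  invisible(res)
}

# intercept-only lm as the pseudo-R2 null
ols_null <- function(y) {
  fit <- lm(y ~ 1)
  list(loglik = as.numeric(logLik(fit)), k = 2)
}

# load a cohort from plain files (schema written by run_pipeline /
# generate_cohort)
load_cohort <- function(paths) {
  panel <- read.csv(paths$panel, stringsAsFactors = FALSE)
  class(panel) <- c("response_panel", "data.frame")
  catalog <- read_catalog_json(paths$catalog)
  covariates <- read.csv(paths$covariates)
  outcomes <- if (!is.null(paths$outcomes)) read.csv(paths$outcomes)
  structure(list(panel = panel, catalog = catalog,
                 covariates = covariates, outcomes = outcomes),
            class = "synthetic_cohort")
}

#' Write / read an item catalog as JSON
#'
#' @param catalog an \code{"item_catalog"}.
#' @param path file path.
#' @return \code{read_catalog_json} returns the catalog.
#' @export
write_catalog_json <- function(catalog, path) {
  jsonlite::write_json(
    list(items = catalog$items,
         availability = as.data.frame(catalog$availability)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_catalog_json
#' @export
read_catalog_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  avail <- as.matrix(j$availability)
  rownames(avail) <- j$items$item_id
  j$items$factor2 <- as.integer(j$items$factor2)
  structure(list(items = j$items, availability = avail),
            class = "item_catalog")
}
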