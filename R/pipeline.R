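#' Pipeline configuration
#'
#' Bundles every option of the end-to-end analysis. Inputs are either CSV
#' paths (`cohort_csv`, `normative_csv`) or, when both are `NULL`, cohorts
#' simulated from `generator` at `seed`. Unknown option names are
#' rejected, so typos in YAML configs fail loudly.
#'
#' @param cohort_csv,normative_csv input paths, or `NULL` to simulate.
#' @param generator a [generator_config()] used when simulating.
#' @param covariates confound-model terms for the clinical cohort.
#' @param fit_population `"pooled"` or `"controls"` (see [adjust_all()]).
#' @param rank_offset rank-INT offset constant.
#' @param reference reference group for contrasts.
#' @param ss_type ANOVA sums-of-squares type.
#' @param extraction,rotation factor-analysis options.
#' @param selection a [selection_rules()].
#' @param cv_scheme,cv_folds,seed cross-validation scheme and the seed
#'   recorded in every output.
#' @param benchmark_battery which battery the reduced composite and the
#'   scale benchmark evaluate: `"catalog"` (the recommended battery
#'   recorded in the task catalog; the default, since benchmarking
#'   addresses the published battery) or `"selected"` (the battery
#'   re-selected from this run's estimated task metrics).
#' @param output_dir directory for artifacts, or `NULL` to skip writing.
#' @return List of class `cb_pipeline_config`.
#' @export
pipeline_config <- function(cohort_csv = NULL, normative_csv = NULL,
                            generator = generator_config(),
                            covariates = c("age_decade", "sex",
                                           "education_band"),
                            fit_population = "pooled",
                            rank_offset = 3 / 8,
                            reference = "control",
                            ss_type = "II",
                            extraction = "paf",
                            rotation = "varimax",
                            selection = selection_rules(),
                            cv_scheme = "kfold",
                            cv_folds = 25,
                            seed = 1,
                            benchmark_battery = c("catalog", "selected"),
                            output_dir = NULL) {
  if (cv_folds < 2) {
    cb_abort("cv_folds must be at least 2", "cb_config_error")
  }
  benchmark_battery <- match.arg(benchmark_battery)
  structure(list(
    cohort_csv = cohort_csv, normative_csv = normative_csv,
    generator = generator, covariates = covariates,
    fit_population = fit_population, rank_offset = rank_offset,
    reference = reference, ss_type = ss_type, extraction = extraction,
    rotation = rotation, selection = selection, cv_scheme = cv_scheme,
    cv_folds = cv_folds, seed = seed,
    benchmark_battery = benchmark_battery, output_dir = output_dir),
    class = "cb_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipeline_config()] arguments;
#' `selection:` sub-keys map to [selection_rules()] arguments. Unknown
#' keys at either level raise a configuration error.
#'
#' @param path YAML file.
#' @return A `cb_pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), "generator")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    cb_abort(paste0("unknown config key(s): ",
                    paste(unknown, collapse = ", ")), "cb_config_error")
  }
  if (!is.null(raw$selection)) {
    sel_known <- names(formals(selection_rules))
    sel_unknown <- setdiff(names(raw$selection), sel_known)
    if (length(sel_unknown)) {
      cb_abort(paste0("unknown selection threshold key(s): ",
                      paste(sel_unknown, collapse = ", ")),
               "cb_config_error")
    }
    raw$selection <- do.call(selection_rules, raw$selection)
  }
  do.call(pipeline_config, raw)
}

#' Run the full evaluation pipeline
#'
#' Stages: load or simulate the clinical cohort and normative sample;
#' validate; confound-adjust and rank-normalize all measures; estimate
#' per-measure group contrasts, the two-way group x task ANOVA with Tukey
#' post-hocs, and normative age-decade contrasts; factor the primary
#' measures (Kaiser retention, varimax) and build global accuracy /
#' latency composites; assemble task metrics and select the battery;
#' benchmark the reduced-battery composite against the MoCA; and run the
#' cross-validation, model-variant, subgroup and motor-correlation
#' sensitivity analyses. Artifacts are written as CSV/JSON under
#' `output_dir` when set; the run is a pure function of (inputs, config,
#' seed).
#'
#' @param config a [pipeline_config()].
#' @return A `cb_pipeline_bundle` list with all stage outputs, invisibly
#'   when written to disk.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cb_abort(paste0("stage ", name, ": ", conditionMessage(e)),
               "cb_pipeline_error", stage = name, parent = e)
    })
  }
  catalog <- config$generator$catalog

  inputs <- stage("inputs", {
    if (!is.null(config$cohort_csv)) {
      list(cohort = load_cohort(config$cohort_csv, catalog),
           normative = load_cohort(config$normative_csv, catalog),
           truth = NULL)
    } else {
      gen <- generate_cohort(config$generator, config$seed)
      norm <- generate_normative_sample(config$generator, config$seed + 1)
      list(cohort = gen$cohort, normative = norm, truth = gen$truth)
    }
  })
  cohort <- inputs$cohort
  normative <- inputs$normative
  inform(sprintf("cohort %d x %d; normative %d x %d", nrow(cohort),
                 ncol(cohort), nrow(normative), ncol(normative)))

  checks <- stage("validate", validate_cohort(cohort, catalog))

  adjusted <- stage("adjustment", adjust_all(
    cohort, covariates = config$covariates,
    fit_population = config$fit_population, offset = config$rank_offset))
  norm_adjusted <- stage("adjustment", adjust_all(
    normative, covariates = config$covariates, offset = config$rank_offset))
  norm_age <- stage("adjustment", adjust_all(
    normative, covariates = setdiff(config$covariates, "age_decade"),
    offset = config$rank_offset))

  prim <- intersect(catalog_measures(catalog, "primary"),
                    colnames(adjusted$scores))
  contrasts <- stage("contrasts", dplyr::bind_rows(lapply(
    colnames(adjusted$scores), function(m) {
      group_contrast(adjusted, m, reference = config$reference)
    })))
  anova_res <- stage("contrasts", two_way_anova(
    stack_adjusted(adjusted, prim), ss_type = config$ss_type))
  age_contrasts <- stage("contrasts", dplyr::bind_rows(lapply(
    prim, function(m) age_decade_contrast(norm_age, m))))

  corr <- stage("factors", correlation_matrix(adjusted, prim))
  n_factors <- stage("factors", kaiser_n_factors(
    eigen(corr, symmetric = TRUE, only.values = TRUE)$values))
  solution <- stage("factors", fit_efa(
    corr, max(n_factors, 1), rotation = config$rotation,
    data = adjusted$scores[, prim], extraction = config$extraction))
  acc_measures <- intersect(catalog_measures(catalog, "accuracy"),
                            colnames(adjusted$scores))
  lat_measures <- intersect(catalog_measures(catalog, "latency"),
                            colnames(adjusted$scores))
  composites <- stage("factors", list(
    accuracy = global_composite(adjusted, acc_measures, "accuracy"),
    latency = global_composite(adjusted, lat_measures, "latency"),
    combined = global_composite(adjusted, c(acc_measures, lat_measures),
                                "combined")))

  metrics <- stage("selection", {
    per_task <- lapply(catalog$task_id, function(t) {
      m <- paste0(t, ".primary")
      disc <- discriminability_range(
        contrasts[contrasts$measure_id == m, ])
      dev <- device_sensitivity(norm_adjusted, m)
      c(disc = disc, dev = dev)
    })
    task_metrics(catalog$task_id,
                 vapply(per_task, `[[`, 0, "disc"),
                 vapply(per_task, `[[`, 0, "dev"),
                 solution, config$selection)
  })
  selection <- stage("selection",
                     select_battery(metrics, config$selection, catalog))
  battery_tasks <- if (config$benchmark_battery == "selected") {
    catalog[catalog$battery_task %in% selection$battery, ]
  } else {
    catalog[catalog$final_battery_member, ]
  }
  battery_measures <- intersect(
    catalog_measures(battery_tasks, "primary"),
    colnames(adjusted$scores))
  reduced_composite <- stage("selection", {
    if (length(battery_measures) >= 2) {
      global_composite(adjusted, battery_measures, "reduced_battery")
    }
  })

  benchmark <- stage("benchmark", {
    if ("moca_total.assessment" %in% names(cohort) &&
        !is.null(reduced_composite)) {
      benchmark_scale(cohort, adjusted, reduced_composite,
                      battery_measures, scale = "moca")
    }
  })

  sens <- stage("sensitivity", {
    cv_loo <- crossvalidate_composite_model(composites$accuracy,
                                            scheme = "loo")
    cv_k <- crossvalidate_composite_model(
      composites$accuracy, scheme = "kfold", folds = config$cv_folds,
      seed = config$seed)
    variants <- lapply(
      c("one_model", "continuous_age_cubic"),
      function(v) model_variant_contrasts(cohort, v, measures = prim))
    names(variants) <- c("one_model", "continuous_age_cubic")
    subgroups <- if (!is.null(cohort$probable_rbd)) {
      subgroup_contrasts(cohort, composites[c("accuracy", "latency")])
    }
    motor <- if ("updrs3" %in% names(cohort)) {
      comps <- composites[c("accuracy", "latency")]
      if (!is.null(reduced_composite)) {
        comps$reduced_battery <- reduced_composite
      }
      motor_confound_correlation(cohort, comps)
    }
    list(cv = list(loo = cv_loo, kfold = cv_k), variants = variants,
         subgroups = subgroups, motor = motor)
  })

  bundle <- structure(list(
    config = config, cohort = cohort, normative = normative,
    truth = inputs$truth, checks = checks, adjusted = adjusted,
    contrasts = contrasts, anova = anova_res,
    age_contrasts = age_contrasts, correlation = corr,
    n_factors = n_factors, solution = solution, composites = composites,
    metrics = metrics, selection = selection,
    reduced_composite = reduced_composite, benchmark = benchmark,
    sensitivity = sens), class = "cb_pipeline_bundle")

  if (!is.null(config$output_dir)) {
    write_bundle(bundle, config$output_dir)
    return(invisible(bundle))
  }
  bundle
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(dir, f)
  wj <- function(x, f) jsonlite::write_json(x, out(f), auto_unbox = TRUE,
                                            digits = NA, pretty = TRUE,
                                            null = "null")
  seed <- bundle$config$seed

  adj <- as.data.frame(bundle$adjusted$scores)
  adj <- cbind(participant_id = rownames(bundle$adjusted$scores), adj)
  utils::write.csv(adj, out("adjusted.csv"), row.names = FALSE, na = "")
  wj(list(seed = seed,
          models = lapply(bundle$adjusted$models, function(m) {
            list(coefficients = as.list(m$coefficients),
                 r_squared = m$r_squared)
          })), "adjustment_models.json")
  utils::write.csv(cbind(bundle$contrasts,
                         label = effect_size_label(bundle$contrasts$smd)),
                   out("contrasts.csv"), row.names = FALSE, na = "")
  utils::write.csv(bundle$age_contrasts, out("age_contrasts.csv"),
                   row.names = FALSE, na = "")
  wj(list(seed = seed, ss_type = bundle$anova$ss_type,
          table = bundle$anova$table, tukey = bundle$anova$tukey),
     "anova.json")
  utils::write.csv(
    cbind(measure_id = rownames(bundle$solution$loadings),
          as.data.frame(bundle$solution$loadings)),
    out("loadings.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(component = seq_along(bundle$solution$eigenvalues),
               eigenvalue = bundle$solution$eigenvalues),
    out("eigenvalues.csv"), row.names = FALSE)
  comp <- dplyr::bind_rows(lapply(names(bundle$composites), function(l) {
    x <- bundle$composites[[l]]
    tibble::tibble(participant_id = as.character(x$participant_id),
                   group = as.character(x$group), composite = l,
                   score = x$score)
  }))
  utils::write.csv(comp, out("composites.csv"), row.names = FALSE)
  utils::write.csv(bundle$selection$decisions, out("selection_report.csv"),
                   row.names = FALSE, na = "")
  wj(list(seed = seed, battery = bundle$selection$battery,
          duration_min = bundle$selection$duration_min,
          rules = unclass(bundle$selection$rules),
          notes = bundle$selection$notes), "selection_report.json")
  if (!is.null(bundle$benchmark)) {
    b <- bundle$benchmark
    wj(list(seed = seed, scale = b$scale,
            scale_from_tasks = b$scale_from_tasks[c("r_squared", "p_value",
                                                    "n")],
            task_correlations = b$task_correlations,
            composite_scale_r = b$composite_scale_r,
            composite_scale_p = b$composite_scale_p,
            composite_raw_scale_r = b$composite_raw_scale_r,
            composite_from_subscales = b$composite_from_subscales,
            scale_discriminability = b$scale_discriminability,
            paired_change = b$paired_change), "benchmark_report.json")
  }
  s <- bundle$sensitivity
  wj(list(seed = seed,
          cv = lapply(s$cv, function(x) {
            list(scheme = x$scheme, folds = x$folds,
                 correlation = x$correlation, mse = x$mse)
          }),
          variant_agreement = lapply(s$variants, `[[`, "agreement"),
          subgroups = s$subgroups, motor = s$motor),
     "sensitivity_report.json")
  utils::write.csv(s$cv$kfold$predictions, out("cv_predictions.csv"),
                   row.names = FALSE)
  wj(list(seed = seed,
          n_cohort = nrow(bundle$cohort),
          n_normative = nrow(bundle$normative),
          n_factors = bundle$n_factors,
          battery = bundle$selection$battery,
          battery_duration_min = bundle$selection$duration_min,
          composite_contrasts = summarize_composites(bundle)),
     "summary.json")
  invisible(dir)
}

summarize_composites <- function(bundle) {
  lapply(bundle$composites, function(comp) {
    sc <- comp$score
    g <- as.character(comp$group)
    ref <- mean(sc[g == "control"])
    lapply(setdiff(unique(g), "control"), function(x) {
      list(contrast = paste0(x, "-control"),
           smd = mean(sc[g == x]) - ref)
    })
  })
}

#' @export
print.cb_pipeline_bundle <- function(x, ...) {
  cat(sprintf(
    "<cb_pipeline_bundle> %d participants, %d factors, battery of %d tasks\n",
    nrow(x$cohort), x$n_factors, length(x$selection$battery)))
  invisible(x)
}
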