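# End-to-end experiment orchestration: simulate -> preprocess -> extract ->
# train -> evaluate, with one global seed fanned out to per-stage seeds.

#' Experiment configuration
#'
#' @param n_train,n_test Training and test cohort sizes.
#' @param mode `"2d_axial"`, `"multiview"` or `"3d"`.
#' @param extractor_dim Toy extractor embedding dimension.
#' @param endpoints Subset of `"OS"`, `"LRC"`, `"FFDM"`.
#' @param baselines Subset of `"radiomics"`, `"clinical"`, `"multimodal"`.
#' @param mil Named list of overrides passed to [mil_config()] (e.g.
#'   `list(epochs = 10, model_dim = 64)`).
#' @param cohort Named list of overrides passed to [cohort_config()].
#' @param n_boot Bootstrap replicates for AUROC CIs.
#' @param n_perm Permutation replicates for model comparisons.
#' @param seed Global seed; every stage seed is derived from it.
#' @param out_dir Optional output directory for the report JSON.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_train = 300L, n_test = 200L,
                              mode = c("2d_axial", "multiview", "3d"),
                              extractor_dim = 128L,
                              endpoints = "OS",
                              baselines = c("radiomics", "clinical", "multimodal"),
                              mil = list(), cohort = list(),
                              n_boot = 1000L, n_perm = 1000L,
                              seed = 1337L, out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(endpoints) >= 1L, all(endpoints %in% c("OS", "LRC", "FFDM")),
            all(baselines %in% c("radiomics", "clinical", "multimodal")))
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 mode = mode, extractor_dim = as.integer(extractor_dim),
                 endpoints = endpoints, baselines = baselines,
                 mil = mil, cohort = cohort,
                 n_boot = as.integer(n_boot), n_perm = as.integer(n_perm),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

# preprocess one patient: body masking, 1 mm resampling, then either
# windowed 2D patches or normalized 3D subvolumes; plus radiomics features
preprocess_patient <- function(record, mode, extractor, seed,
                               with_radiomics = TRUE) {
  bm <- mask_body(record$ct)
  rs <- resample_isotropic(bm$ct_masked, record$gtvp_mask, record$spacing)
  rad <- if (with_radiomics)
    compute_radiomics_features(rs$ct, rs$mask, rs$spacing) else NULL
  instances <- if (mode == "3d") {
    ctn <- normalize_3d(rs$ct)
    set.seed(derive_seed(seed, paste0("subvol_", record$patient_id)))
    sample_subvolumes(ctn, rs$mask, patient_id = record$patient_id)
  } else {
    ct01 <- window_hu(rs$ct)
    views <- if (mode == "multiview") c("axial", "coronal", "sagittal")
    else "axial"
    extract_view_slices(ct01, rs$mask, views, record$patient_id)
  }
  bag <- embed_bag(instances, extractor,
                   patient_id = record$patient_id,
                   seed = derive_seed(seed, paste0("aug_", record$patient_id)))
  list(bag = bag, radiomics = rad)
}

preprocess_cohort <- function(cohort, mode, extractor, seed,
                              with_radiomics = TRUE) {
  bags <- vector("list", length(cohort))
  rad <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    pp <- preprocess_patient(cohort[[i]], mode, extractor, seed,
                             with_radiomics)
    bags[[i]] <- pp$bag
    rad[[i]] <- pp$radiomics
  }
  rad_tab <- if (with_radiomics) do.call(rbind, rad) else NULL
  if (!is.null(rad_tab))
    rownames(rad_tab) <- vapply(cohort, `[[`, "", "patient_id")
  list(bags = bags, radiomics = rad_tab)
}

label_vector <- function(labels_df) {
  keep <- labels_df$label != "excluded"
  list(keep = which(keep),
       y = as.numeric(labels_df$label[keep] == "positive"))
}

#' Run an end-to-end experiment on synthetic cohorts
#'
#' Generates a training and a test phantom cohort with distinct derived
#' seeds, preprocesses every patient into an instance bag (and radiomics
#' feature vector), trains the MIL model with cross-validation per
#' endpoint, fits the configured baselines, and assembles the evaluation
#' report: AUROCs with class-stratified bootstrap CIs, paired permutation
#' comparisons (BH-adjusted), training-median risk stratification and
#' score-clinical correlations.
#'
#' @param config An [experiment_config()].
#' @return An `experiment_report` (nested list; also written as JSON when
#'   `config$out_dir` is set).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  cohort_args_tr <- c(list(n_patients = config$n_train,
                           seed = derive_seed(seed, "train_cohort")),
                      config$cohort)
  cohort_args_te <- c(list(n_patients = config$n_test,
                           seed = derive_seed(seed, "test_cohort")),
                      config$cohort)
  train_cohort <- stage("simulate",
                        generate_cohort(do.call(cohort_config, cohort_args_tr)))
  test_cohort <- stage("simulate",
                       generate_cohort(do.call(cohort_config, cohort_args_te)))

  input_kind <- if (config$mode == "3d") "subvolume3d" else "patch2d"
  extractor <- toy_extractor(config$extractor_dim, input_kind,
                             seed = derive_seed(seed, "extractor"))
  with_rad <- "radiomics" %in% config$baselines
  tr <- stage("preprocess",
              preprocess_cohort(train_cohort, config$mode, extractor, seed,
                                with_rad))
  te <- stage("preprocess",
              preprocess_cohort(test_cohort, config$mode, extractor, seed,
                                with_rad))

  clin_tr_raw <- cohort_clinical_table(train_cohort)
  clin_te_raw <- cohort_clinical_table(test_cohort)
  surv_te <- cohort_endpoint_table(test_cohort)

  report <- list(config = config,
                 provenance = list(seed = seed,
                                   package_version = as.character(utils::packageVersion("hnmil"))),
                 endpoints = list())

  for (ep in config$endpoints) {
    lab_tr <- cohort_labels(train_cohort, ep)
    lab_te <- cohort_labels(test_cohort, ep)
    lv_tr <- label_vector(lab_tr); lv_te <- label_vector(lab_te)

    milcfg <- do.call(mil_config, c(list(embed_dim_in = config$extractor_dim,
                                         seed = derive_seed(seed, paste0("mil_", ep))),
                                    config$mil))
    fold_models <- stage(paste0("train_", ep),
                         train_mil_cv(tr$bags[lv_tr$keep], lv_tr$y, milcfg))
    deployed <- select_deployment_model(fold_models)
    pred_tr <- predict_cohort(tr$bags[lv_tr$keep], deployed)
    pred_te_all <- predict_cohort(te$bags, deployed)
    s_tr <- mil_scores(pred_tr)$score
    s_te_all <- mil_scores(pred_te_all)$score
    s_te <- s_te_all[lv_te$keep]

    scores <- list(mil = s_te)
    models <- list(mil = list(
      holdout_aurocs = vapply(fold_models, `[[`, 0, "holdout_auroc"),
      deployed_fold = deployed$fold_id))

    if ("radiomics" %in% config$baselines) {
      trace <- select_features(tr$radiomics[lv_tr$keep, , drop = FALSE], lv_tr$y)
      rmod <- fit_radiomics_classifier(
        tr$radiomics[lv_tr$keep, trace$selected, drop = FALSE], lv_tr$y)
      scores$radiomics <- predict(rmod, as.data.frame(
        te$radiomics[lv_te$keep, , drop = FALSE]))
      models$radiomics <- list(selected = trace$selected,
                               k_selected = trace$k_selected)
    }

    clin_models <- NULL
    if ("clinical" %in% config$baselines) {
      imp <- impute_clinical(clin_tr_raw[lv_tr$keep, , drop = FALSE])
      Xtr <- clinical_design_matrix(imp$table)
      imp_te <- impute_clinical(clin_te_raw[lv_te$keep, , drop = FALSE],
                                imp$params)
      Xte <- clinical_design_matrix(imp_te$table)
      cmod <- fit_clinical_baseline(Xtr, lv_tr$y)
      scores$clinical <- predict(cmod, Xte)
      if ("multimodal" %in% config$baselines) {
        mmod <- fit_multimodal(Xtr, s_tr, lv_tr$y)
        scores$multimodal <- predict(mmod, add_mil_score(Xte, s_te))
        lor <- multivariate_lor(Xtr, s_tr, lv_tr$y)
        models$multimodal <- list(lor = lor$coefficients,
                                  separation_flag = lor$separation_flag)
      }
      clin_models <- cmod
    }

    # evaluation
    aurocs <- lapply(names(scores), function(m)
      bootstrap_auroc_ci(scores[[m]], lv_te$y, n_boot = config$n_boot,
                         seed = derive_seed(seed, paste0("boot_", ep, "_", m))))
    names(aurocs) <- names(scores)

    comparisons <- list()
    if (!is.null(scores$radiomics))
      comparisons$mil_vs_radiomics <- permutation_auroc_test(
        scores$mil, scores$radiomics, lv_te$y, n_perm = config$n_perm,
        alternative = "greater",
        seed = derive_seed(seed, paste0("perm_", ep, "_mr")))
    if (!is.null(scores$multimodal))
      comparisons$multimodal_vs_clinical <- permutation_auroc_test(
        scores$multimodal, scores$clinical, lv_te$y, n_perm = config$n_perm,
        alternative = "greater",
        seed = derive_seed(seed, paste0("perm_", ep, "_mc")))
    if (length(comparisons)) {
      adj <- bh_adjust(vapply(comparisons, `[[`, 0, "p_value"))
      for (i in seq_along(comparisons))
        comparisons[[i]]$p_adjusted <- adj[[i]]
    }

    ep_surv <- surv_te[surv_te$endpoint == ep, ]
    strat <- stratify_by_median(s_tr, s_te_all, ep_surv$time_months,
                                ep_surv$event)

    corr_df <- clin_te_raw
    corr_df$hpv_positive <- as.numeric(corr_df$hpv == "positive")
    correlations <- correlate_scores_clinical(
      s_te_all, corr_df[, c("age", "t_stage", "n_stage", "sex", "chemo",
                            "hpv_positive")])

    report$endpoints[[ep]] <- list(
      labels = list(train = table(lab_tr$label), test = table(lab_te$label)),
      auroc = aurocs, comparisons = comparisons,
      stratification = strat, correlations = correlations,
      scores = scores, test_labels = lv_te$y, models = models,
      train_scores = s_tr)
  }

  class(report) <- "experiment_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report_to_json(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

report_to_json <- function(report) {
  lapply(report$endpoints, function(ep) list(
    auroc = lapply(ep$auroc, function(a)
      list(auroc = a$auroc, ci_low = a$ci_low, ci_high = a$ci_high)),
    comparisons = lapply(ep$comparisons, function(cp)
      list(p_value = cp$p_value, p_adjusted = cp$p_adjusted %||% NA)),
    stratification = list(cutoff = ep$stratification$cutoff,
                          hr = ep$stratification$hr,
                          logrank_p = ep$stratification$logrank_p,
                          degenerate = ep$stratification$degenerate_flag),
    correlations = ep$correlations))
}

#' Compare two models from an experiment report
#'
#' Delegates to [permutation_auroc_test()] on the stored test scores and
#' applies Benjamini-Hochberg adjustment across the requested comparison
#' family.
#'
#' @param report An `experiment_report`.
#' @param model_a,model_b Character vectors (recycled pairwise) naming
#'   models present in the report (`"mil"`, `"radiomics"`, `"clinical"`,
#'   `"multimodal"`).
#' @param endpoint Endpoint to compare on.
#' @param alternative Passed to [permutation_auroc_test()].
#' @param n_perm Permutation replicates.
#' @param seed Seed.
#' @return Data frame with one row per comparison: `model_a`, `model_b`,
#'   `observed`, `p_value`, `p_adjusted`.
#' @export
compare_models <- function(report, model_a, model_b, endpoint = "OS",
                           alternative = "two.sided", n_perm = 1000L,
                           seed = 1L) {
  ep <- report$endpoints[[endpoint]]
  if (is.null(ep)) stop("endpoint not present in report", call. = FALSE)
  k <- max(length(model_a), length(model_b))
  model_a <- rep_len(model_a, k); model_b <- rep_len(model_b, k)
  rows <- lapply(seq_len(k), function(i) {
    for (m in c(model_a[i], model_b[i]))
      if (is.null(ep$scores[[m]]))
        stop(sprintf("model '%s' not present in report", m), call. = FALSE)
    pt <- permutation_auroc_test(ep$scores[[model_a[i]]],
                                 ep$scores[[model_b[i]]], ep$test_labels,
                                 n_perm = n_perm, alternative = alternative,
                                 seed = derive_seed(seed, paste0("cmp", i)))
    data.frame(model_a = model_a[i], model_b = model_b[i],
               observed = pt$observed, p_value = pt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out
}
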