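# Shared, lazily built fixtures. The heavyweight study fixture (the full
# phantom study at n_train = 300 / n_test = 200 with the D = 128 toy
# extractor) is built once and reused by the feature, MIL and acceptance
# tests so the expensive preprocessing runs a single time per session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# small cohort for unit tests of preprocessing / IO
small_cohort <- function(n = 6, seed = 42) {
  memo(sprintf("cohort_%d_%d", n, seed), function()
    generate_cohort(cohort_config(n_patients = n, seed = seed)))
}

# the full study fixture: cohorts, bags, radiomics tables, OS labels
study_fixture <- function() {
  memo("study", function() {
    seed <- 1337L
    train_cohort <- generate_cohort(
      cohort_config(n_patients = 300L, seed = derive_seed(seed, "train_cohort")))
    test_cohort <- generate_cohort(
      cohort_config(n_patients = 200L, seed = derive_seed(seed, "test_cohort")))
    extractor <- toy_extractor(128L, "patch2d", seed = derive_seed(seed, "extractor"))
    tr <- hnmil:::preprocess_cohort(train_cohort, "2d_axial", extractor, seed)
    te <- hnmil:::preprocess_cohort(test_cohort, "2d_axial", extractor, seed)
    strip <- function(cohort) lapply(cohort, function(r) {
      r$ct <- NULL; r$gtvp_mask <- NULL; r
    })
    lab_tr <- cohort_labels(train_cohort, "OS")
    lab_te <- cohort_labels(test_cohort, "OS")
    list(seed = seed,
         clin_tr = cohort_clinical_table(train_cohort),
         clin_te = cohort_clinical_table(test_cohort),
         surv_te = cohort_endpoint_table(test_cohort),
         truth_tr = lapply(train_cohort, `[[`, "truth"),
         latent_te = vapply(test_cohort, `[[`, 0, "latent_risk"),
         bags_tr = tr$bags, bags_te = te$bags,
         rad_tr = tr$radiomics, rad_te = te$radiomics,
         lab_tr = lab_tr, lab_te = lab_te,
         keep_tr = which(lab_tr$label != "excluded"),
         y_tr = as.numeric(lab_tr$label[lab_tr$label != "excluded"] == "positive"),
         keep_te = which(lab_te$label != "excluded"),
         y_te = as.numeric(lab_te$label[lab_te$label != "excluded"] == "positive"))
  })
}

# the MIL configuration used for the phantom study (10-epoch budget,
# annealing from the stated 1e-3 initial rate; see the methods vignette)
study_mil_config <- function() {
  mil_config(embed_dim_in = 128L, model_dim = 32L, n_layers = 1L,
             n_heads = 4L, attn_dim = 16L, epochs = 10L, patience = 10L,
             batch_size = 4L, lr_max = 1e-3, seed = 1337L)
}

# deployed MIL model trained on the study fixture
study_mil <- function() {
  memo("study_mil", function() {
    fx <- study_fixture()
    fold_models <- train_mil_cv(fx$bags_tr[fx$keep_tr], fx$y_tr,
                                study_mil_config())
    deployed <- select_deployment_model(fold_models)
    list(fold_models = fold_models, deployed = deployed,
         scores_te = mil_scores(predict_cohort(fx$bags_te, deployed))$score,
         scores_tr = mil_scores(predict_cohort(fx$bags_tr[fx$keep_tr],
                                               deployed))$score)
  })
}

# label-permuted control: mean test AUROC over three permutation retrainings
study_permuted_control <- function() {
  memo("study_perm", function() {
    fx <- study_fixture()
    mean(vapply(1:3, function(k) {
      set.seed(derive_seed(fx$seed, paste0("label_permutation_", k)))
      y_perm <- sample(fx$y_tr)
      dep <- select_deployment_model(
        train_mil_cv(fx$bags_tr[fx$keep_tr], y_perm, study_mil_config()))
      auroc(mil_scores(predict_cohort(fx$bags_te[fx$keep_te], dep))$score,
            fx$y_te)
    }, 0))
  })
}

# mean-pooled bag embeddings (for linear probes)
pool_bags <- function(bags) {
  t(vapply(bags, function(b) colMeans(b$embeddings),
           numeric(ncol(bags[[1]]$embeddings))))
}
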