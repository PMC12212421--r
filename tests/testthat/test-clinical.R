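raw_clin <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(patient_id = sprintf("P%03d", 1:n),
             age = rnorm(n, 63, 9), sex = rbinom(n, 1, 0.8),
             t_stage = sample(1:4, n, TRUE), n_stage = sample(0:3, n, TRUE),
             hpv = sample(c("positive", "negative", "unknown"), n, TRUE),
             chemo = rbinom(n, 1, 0.6), stringsAsFactors = FALSE)
}

test_that("imputation uses training mean/mode and freezes its parameters", {
  tab <- data.frame(patient_id = c("a", "b", "c"),
                    age = c(50, 60, NA), sex = c(1, 1, NA),
                    t_stage = c(2, NA, 2), n_stage = c(0, 1, 1),
                    hpv = c("positive", "positive", NA),
                    chemo = c(1, 0, 1), stringsAsFactors = FALSE)
  imp <- impute_clinical(tab)
  expect_equal(imp$table$age[3], 55)
  expect_equal(imp$table$hpv[3], "positive")
  expect_equal(imp$table$t_stage[2], 2)
  # the mode rule with [pos, pos, neg, missing]
  t2 <- raw_clin(4)
  t2$hpv <- c("positive", "positive", "negative", NA)
  expect_equal(impute_clinical(t2)$table$hpv[4], "positive")
  # frozen parameters beat the test-set mode
  test_tab <- data.frame(patient_id = "z", age = NA, sex = 0, t_stage = 1,
                         n_stage = 0, hpv = NA, chemo = 0,
                         stringsAsFactors = FALSE)
  out <- impute_clinical(test_tab, imp$params)
  expect_equal(out$table$age, 55)
  expect_equal(out$table$hpv, "positive")
  bad <- tab; bad$age <- NA
  expect_error(impute_clinical(bad), "fully missing")
})

test_that("the design matrix encodes stages and HPV as configured", {
  tab <- impute_clinical(raw_clin(20))$table
  X <- clinical_design_matrix(tab)
  expect_equal(colnames(X), c("age", "sex", "chemo", "t_stage", "n_stage",
                              "hpv_positive", "hpv_unknown"))
  Xd <- clinical_design_matrix(tab, stage_coding = "dummy")
  expect_true(all(c("t_stage2", "t_stage4", "n_stage3") %in% colnames(Xd)))
  # HPV reference level is negative: both dummies zero
  neg <- tab$hpv == "negative"
  expect_true(all(X[neg, c("hpv_positive", "hpv_unknown")] == 0))
  tab$age[1] <- NA
  expect_error(clinical_design_matrix(tab), "imputed")
  # imputation followed by encoding is idempotent
  imp <- impute_clinical(raw_clin(15, seed = 3))
  again <- impute_clinical(imp$table, imp$params)
  expect_equal(again$table, imp$table)
})

test_that("balanced class weights follow the n/(2*n_c) convention", {
  y <- rep(c(1, 0), c(100, 300))
  w <- hnmil:::balanced_weights(y)
  expect_equal(unique(w[y == 1]), 2.0)
  expect_equal(unique(w[y == 0]), 2 / 3)
  expect_error(hnmil:::balanced_weights(rep(1, 5)), "single-class")
})

test_that("the clinical baseline recovers a T-stage-driven outcome", {
  set.seed(15)
  n <- 1000
  tab <- impute_clinical(raw_clin(n, seed = 15))$table
  y <- rbinom(n, 1, plogis(1.2 * (tab$t_stage - 2.5)))
  X <- clinical_design_matrix(tab)
  tr <- 1:500
  fit <- fit_clinical_baseline(X[tr, ], y[tr])
  expect_gt(coef(fit$fit)[["t_stage"]], 0)
  expect_gt(auroc(predict(fit, X[-tr, ]), y[-tr]), 0.7)

  # chance level when labels are independent of the covariates
  y0 <- rbinom(n, 1, 0.3)
  fit0 <- fit_clinical_baseline(X[tr, ], y0[tr])
  auc0 <- auroc(predict(fit0, X[-tr, ]), y0[-tr])
  expect_gt(auc0, 0.4); expect_lt(auc0, 0.6)
  expect_error(fit_clinical_baseline(X[tr, ], rep(1, 500)), "single-class")
})

test_that("label swap mirrors the balanced logistic coefficients", {
  set.seed(25)
  tab <- impute_clinical(raw_clin(200, seed = 25))$table
  y <- rbinom(200, 1, plogis(tab$t_stage - 2))
  X <- clinical_design_matrix(tab)
  f1 <- fit_clinical_baseline(X, y)
  f2 <- fit_clinical_baseline(X, 1 - y)
  expect_equal(unname(coef(f1$fit)), -unname(coef(f2$fit)), tolerance = 1e-6)
})

test_that("multimodal fusion adds value only when the image signal drives outcome", {
  set.seed(35)
  n <- 1000
  tab <- impute_clinical(raw_clin(n, seed = 35))$table
  X <- clinical_design_matrix(tab)
  rownames(X) <- tab$patient_id
  img_signal <- rnorm(n)
  mil <- plogis(img_signal + rnorm(n, sd = 0.4))
  y <- rbinom(n, 1, plogis(1.5 * img_signal))
  tr <- 1:500; te <- 501:n
  cm <- fit_clinical_baseline(X[tr, ], y[tr])
  mm <- fit_multimodal(X[tr, ], mil[tr], y[tr])
  p_c <- predict(cm, X[te, ])
  p_m <- predict(mm, add_mil_score(X[te, ], mil[te]))
  expect_gt(auroc(p_m, y[te]), auroc(p_c, y[te]))
  pt <- permutation_auroc_test(p_m, p_c, y[te], n_perm = 300,
                               alternative = "greater", seed = 2)
  expect_lt(pt$p_value, 0.05)

  # constant MIL column: multimodal collapses onto the clinical baseline
  mm0 <- fit_multimodal(X[tr, ], rep(0.5, 500), y[tr])
  p_m0 <- predict(mm0, add_mil_score(X[te, ], rep(0.5, 500)))
  expect_equal(p_m0, predict(cm, X[te, ]), tolerance = 1e-6)

  # clinical-driven outcome: fusion does not help materially
  y2 <- rbinom(n, 1, plogis(1.2 * (tab$t_stage - 2.5)))
  cm2 <- fit_clinical_baseline(X[tr, ], y2[tr])
  mm2 <- fit_multimodal(X[tr, ], mil[tr], y2[tr])
  a_c <- auroc(predict(cm2, X[te, ]), y2[te])
  a_m <- auroc(predict(mm2, add_mil_score(X[te, ], mil[te])), y2[te])
  expect_lt(abs(a_m - a_c), 0.05)
  expect_error(fit_multimodal(X[tr, ],
                              data.frame(patient_id = "nope", score = 1),
                              y[tr]), "misaligned")
})

test_that("multivariate LOR covers a true MIL coefficient of 1 and flags pathologies", {
  covered <- 0
  for (i in 1:100) {
    set.seed(500 + i)
    n <- 1000
    mil <- rnorm(n)
    X <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
    y <- rbinom(n, 1, plogis(-0.3 + 1.0 * mil))
    rep <- multivariate_lor(X, mil, y)
    row <- rep$coefficients[rep$coefficients$variable == "mil_score", ]
    if (row$ci_low <= 1 && row$ci_high >= 1) covered <- covered + 1
  }
  expect_gte(covered, 90)

  # null scores: small LOR, ~uniform p
  set.seed(61)
  rejections <- 0; lors <- numeric(50)
  for (i in 1:50) {
    n <- 400
    mil <- rnorm(n); y <- rbinom(n, 1, 0.4)
    rep <- multivariate_lor(cbind(age = rnorm(n)), mil, y)
    row <- rep$coefficients[rep$coefficients$variable == "mil_score", ]
    lors[i] <- row$lor
    if (row$p_value < 0.05) rejections <- rejections + 1
  }
  expect_lt(mean(abs(lors)), 0.2)
  expect_lte(rejections, 9)

  # duplicated column -> collinearity flagged
  set.seed(71)
  Xd <- cbind(age = rnorm(100), age_copy = 0)
  Xd[, 2] <- Xd[, 1]
  rep <- multivariate_lor(Xd, rnorm(100), rbinom(100, 1, 0.5))
  expect_gt(length(rep$collinear), 0)

  # perfect separation -> flagged, not silent
  xs <- c(rnorm(50, -5), rnorm(50, 5))
  ys <- rep(0:1, each = 50)
  rep2 <- multivariate_lor(cbind(x = xs), rep(0, 100), ys)
  expect_true(rep2$separation_flag)
})

test_that("subgroup filtering treats unknown HPV as non-positive", {
  tab <- data.frame(patient_id = c("a", "b", "c"),
                    hpv = c("positive", "negative", "unknown"),
                    stringsAsFactors = FALSE)
  out <- subgroup_filter(tab, "non_hpv_positive")
  expect_equal(out$patient_id, c("b", "c"))
  expect_equal(subgroup_filter(tab, "all"), tab)
  allpos <- data.frame(patient_id = "a", hpv = "positive",
                       stringsAsFactors = FALSE)
  expect_warning(subgroup_filter(allpos, "non_hpv_positive"), "empty")
  expect_error(subgroup_filter(tab, "sometimes"), "arg")
  expect_error(subgroup_filter(tab, "contrast"), "contrast")
  co <- small_cohort()
  sub <- subgroup_filter(co, "non_hpv_positive")
  expect_s3_class(sub, "hn_cohort")
  expect_true(all(vapply(sub, function(r)
    is.na(r$clinical$hpv) || r$clinical$hpv != "positive", logical(1))))
})
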