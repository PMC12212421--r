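# Clinical baseline, imputation, multimodal fusion with MIL scores,
# multivariate log-odds-ratio analysis, and subgroup filtering.

#' Impute missing clinical covariates
#'
#' Numeric variables are imputed with the training-set mean, categorical
#' variables with the training-set mode. Passing the returned `params` back
#' in applies the frozen training parameters to a test table.
#'
#' @param raw_table Clinical data frame with columns `patient_id`, `age`,
#'   `sex`, `t_stage`, `n_stage`, `hpv`, `chemo` (missing values as `NA`).
#' @param params Optional frozen imputation parameters from a previous call.
#' @return List with `table` (imputed data frame) and `params`.
#' @export
impute_clinical <- function(raw_table, params = NULL) {
  numeric_cols <- c("age")
  cat_cols <- c("sex", "t_stage", "n_stage", "hpv", "chemo")
  tab <- raw_table
  if (is.null(params)) {
    params <- list()
    for (cn in numeric_cols) {
      v <- tab[[cn]]
      if (all(is.na(v))) stop(sprintf("column '%s' fully missing", cn), call. = FALSE)
      params[[cn]] <- mean(v, na.rm = TRUE)
    }
    for (cn in cat_cols) {
      v <- tab[[cn]]
      if (all(is.na(v))) stop(sprintf("column '%s' fully missing", cn), call. = FALSE)
      params[[cn]] <- stat_mode(v)
    }
  }
  for (cn in c(numeric_cols, cat_cols)) {
    v <- tab[[cn]]
    v[is.na(v)] <- params[[cn]]
    tab[[cn]] <- v
  }
  list(table = tab, params = params)
}

#' Build the clinical design matrix
#'
#' Encodes the imputed clinical table for modeling: `age` numeric, `sex` and
#' `chemo` binary, T/N stage as ordinal integers (default) or dummy-coded,
#' and HPV status dummy-coded with reference level `"negative"`
#' (`hpv_positive` and `hpv_unknown` indicators).
#'
#' @param table Imputed clinical data frame.
#' @param stage_coding `"ordinal"` (default) or `"dummy"`.
#' @return Numeric matrix with one row per patient; the encoding is recorded
#'   in attribute `"encoding"` and patient ids in the rownames.
#' @export
clinical_design_matrix <- function(table, stage_coding = c("ordinal", "dummy")) {
  stage_coding <- match.arg(stage_coding)
  if (anyNA(table[c("age", "sex", "t_stage", "n_stage", "hpv", "chemo")]))
    stop("design matrix requires an imputed table (no NAs)", call. = FALSE)
  base <- cbind(age = as.numeric(table$age), sex = as.numeric(table$sex),
                chemo = as.numeric(table$chemo))
  stg <- if (stage_coding == "ordinal") {
    cbind(t_stage = as.numeric(table$t_stage),
          n_stage = as.numeric(table$n_stage))
  } else {
    td <- sapply(2:4, function(k) as.numeric(table$t_stage == k))
    nd <- sapply(1:3, function(k) as.numeric(table$n_stage == k))
    colnames(td) <- paste0("t_stage", 2:4)
    colnames(nd) <- paste0("n_stage", 1:3)
    cbind(td, nd)
  }
  hp <- cbind(hpv_positive = as.numeric(table$hpv == "positive"),
              hpv_unknown = as.numeric(table$hpv == "unknown"))
  X <- cbind(base, stg, hp)
  rownames(X) <- table$patient_id
  attr(X, "encoding") <- stage_coding
  X
}

# balanced class weights, n / (2 * n_class) convention
balanced_weights <- function(labels) {
  n <- length(labels)
  n1 <- sum(labels == 1); n0 <- n - n1
  if (n1 == 0 || n0 == 0) stop("single-class labels", call. = FALSE)
  ifelse(labels == 1, n / (2 * n1), n / (2 * n0))
}

fit_weighted_logistic <- function(X, labels, weights) {
  df <- data.frame(X, y = as.numeric(labels), check.names = FALSE)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                     family = stats::binomial(),
                                     weights = weights))
  structure(list(fit = fit, features = colnames(X)),
            class = "hnmil_weighted_logistic")
}

#' @export
predict.hnmil_weighted_logistic <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$features, drop = FALSE]
  as.numeric(stats::predict(object$fit,
                            newdata = data.frame(X, check.names = FALSE),
                            type = "response"))
}

#' Fit the clinical baseline model
#'
#' Logistic regression on the clinical design matrix with balanced class
#' weights (each sample weighted by `n / (2 * n_class)`).
#'
#' @param matrix Clinical design matrix from [clinical_design_matrix()].
#' @param labels Binary labels (0/1).
#' @return An `hnmil_weighted_logistic` scoring model.
#' @export
fit_clinical_baseline <- function(matrix, labels) {
  fit_weighted_logistic(matrix, labels, balanced_weights(labels))
}

#' Fit the multimodal (clinical + MIL score) model
#'
#' Balanced logistic regression on the clinical design matrix augmented with
#' the MIL score as one numeric column.
#'
#' @param matrix Clinical design matrix with patient ids as rownames.
#' @param mil_scores Data frame with `patient_id` and `score`, or a numeric
#'   vector aligned with the matrix rows.
#' @param labels Binary labels (0/1).
#' @return An `hnmil_weighted_logistic`; score test data with a matrix that
#'   carries a `mil_score` column (see [add_mil_score()]).
#' @export
fit_multimodal <- function(matrix, mil_scores, labels) {
  fit_weighted_logistic(add_mil_score(matrix, mil_scores), labels,
                        balanced_weights(labels))
}

#' Append the MIL score column to a clinical design matrix
#' @param matrix Design matrix with patient ids as rownames.
#' @param mil_scores Data frame (`patient_id`, `score`) or aligned vector.
#' @return The matrix with an extra `mil_score` column.
#' @export
add_mil_score <- function(matrix, mil_scores) {
  if (is.data.frame(mil_scores)) {
    idx <- match(rownames(matrix), mil_scores$patient_id)
    if (anyNA(idx)) stop("MIL scores and design matrix ids are misaligned",
                         call. = FALSE)
    s <- mil_scores$score[idx]
  } else {
    if (length(mil_scores) != nrow(matrix))
      stop("MIL scores and design matrix ids are misaligned", call. = FALSE)
    s <- as.numeric(mil_scores)
  }
  cbind(matrix, mil_score = s)
}

#' Multivariate log-odds-ratio report for MIL scores and clinical factors
#'
#' Unpenalized logistic regression of the outcome on the clinical design
#' matrix plus the MIL score; reports per-variable log-odds ratios with Wald
#' 95% confidence intervals and p-values. Collinear columns and apparent
#' separation are flagged rather than silently diverging.
#'
#' @param matrix Clinical design matrix.
#' @param mil_scores MIL scores (data frame or aligned vector).
#' @param labels Binary labels (0/1).
#' @return A `coefficient_report`: data frame `coefficients` (variable,
#'   `lor`, `ci_low`, `ci_high`, `p_value`) plus `collinear` and
#'   `separation_flag`.
#' @export
multivariate_lor <- function(matrix, mil_scores, labels) {
  X <- add_mil_score(matrix, mil_scores)
  df <- data.frame(X, y = as.numeric(labels), check.names = FALSE)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  cf <- stats::coef(fit)
  collinear <- names(cf)[is.na(cf)]
  keep <- rownames(sm)
  est <- sm[, 1]; se <- sm[, 2]; pv <- sm[, 4]
  rep_df <- data.frame(variable = keep, lor = est,
                       ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
                       p_value = pv, row.names = NULL,
                       stringsAsFactors = FALSE)
  sep <- !fit$converged || any(abs(est) > 15) || any(se > 100)
  structure(list(coefficients = rep_df, collinear = collinear,
                 separation_flag = sep, fit = fit),
            class = "coefficient_report")
}

#' Filter a cohort or clinical table into a subgroup
#'
#' `non_hpv_positive` keeps HPV-negative and HPV-unknown patients and drops
#' HPV-positive ones; `all` is the identity; `contrast`/`non_contrast`
#' require a `contrast` column.
#'
#' @param x An `hn_cohort` or a clinical data frame with an `hpv` column.
#' @param rule One of `"all"`, `"non_hpv_positive"`, `"contrast"`,
#'   `"non_contrast"`.
#' @return The filtered object, same type as the input.
#' @export
subgroup_filter <- function(x, rule = c("all", "non_hpv_positive",
                                        "contrast", "non_contrast")) {
  rule <- match.arg(rule)
  hpv_of <- function(obj) {
    if (inherits(obj, "hn_cohort"))
      vapply(obj, function(r) r$clinical$hpv %||% NA_character_, "")
    else obj$hpv
  }
  keep <- switch(rule,
    all = rep(TRUE, if (inherits(x, "hn_cohort")) length(x) else nrow(x)),
    non_hpv_positive = {
      h <- hpv_of(x)
      is.na(h) | h != "positive"
    },
    contrast = ,
    non_contrast = {
      cc <- if (inherits(x, "hn_cohort"))
        vapply(x, function(r) r$clinical$contrast %||% NA_real_, 0)
      else x$contrast
      if (is.null(cc) || all(is.na(cc)))
        stop("contrast status not available in this cohort", call. = FALSE)
      if (rule == "contrast") cc == 1 else cc == 0
    })
  if (!any(keep)) warning("subgroup filter produced an empty subset")
  if (inherits(x, "hn_cohort"))
    structure(x[keep], class = "hn_cohort", config = attr(x, "config"))
  else x[keep, , drop = FALSE]
}
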