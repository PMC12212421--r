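# Cross-validated MIL training: class-stratified folds, per-epoch
# augmented/plain feature switching, cosine-annealed ADAM, holdout-loss
# checkpointing with early stopping, and median-AUROC deployment selection.

# class-stratified fold assignment; fold class counts are within one sample
# of the cohort proportions
stratified_folds <- function(labels, k, seed) {
  set.seed(derive_seed(seed, "folds"))
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

bag_loss_grad <- function(X, y, p, cfg, w, drop_masks = NULL) {
  fw <- mil_fwd(X, p, cfg, keep_cache = TRUE, drop_masks = drop_masks)
  pr <- pmin(pmax(fw$score, 1e-12), 1 - 1e-12)
  loss <- w * -(y * log(pr) + (1 - y) * log(1 - pr))
  dlogit <- w * (fw$score - y)
  list(loss = loss, grad = mil_bwd(dlogit, p, cfg, fw$cache, drop_masks))
}

cohort_loss <- function(bags, labels, p, cfg, prop) {
  pr <- vapply(bags, function(b) mil_fwd(b$embeddings, p, cfg)$score, 0)
  weighted_bce(pr, labels, prop)
}

#' Train MIL models with class-stratified cross-validation
#'
#' Runs `n_folds`-fold class-stratified cross-validation on the training
#' bags. Each epoch, every training bag is fed either its augmented or its
#' plain embeddings with probability `aug_prob`; optimization is ADAM with
#' cosine-annealed learning rate and a weighted binary cross-entropy whose
#' weights are the inverse class proportions of the training split. The
#' checkpoint with the lowest holdout loss is retained per fold (plain
#' features only for evaluation), with early stopping after `patience`
#' epochs without improvement. Fully deterministic given `config$seed`.
#'
#' @param bags List of `instance_bag`s.
#' @param labels Binary labels (0/1) aligned with `bags`.
#' @param config A [mil_config()].
#' @return List of per-fold trained models (class `trained_mil`), each with
#'   `params`, `config`, `fold_id`, `holdout_auroc` and a per-epoch
#'   `training_log`.
#' @export
train_mil_cv <- function(bags, labels, config) {
  stopifnot(inherits(config, "mil_config"), length(bags) == length(labels))
  labels <- as.numeric(labels)
  if (sum(labels == 1) < 2 || sum(labels == 0) < 2)
    stop("need at least 2 patients per class", call. = FALSE)
  fold <- stratified_folds(labels, config$n_folds, config$seed)
  lapply(seq_len(config$n_folds), function(f)
    train_mil_fold(bags, labels, config, fold, f))
}

# frozen per-dimension standardization of instance embeddings, learned on
# the fold-training bags; stabilizes optimization when extractor features
# share a large common offset
embedding_norm <- function(bags) {
  E <- do.call(rbind, lapply(bags, `[[`, "embeddings"))
  ctr <- colMeans(E)
  scl <- apply(E, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_norm <- function(X, norm) {
  if (is.null(norm)) return(X)
  X <- X - matrix(norm$center, nrow(X), ncol(X), byrow = TRUE)
  X / matrix(norm$scale, nrow(X), ncol(X), byrow = TRUE)
}

train_mil_fold <- function(bags, labels, config, fold, f) {
  tr <- which(fold != f); ho <- which(fold == f)
  if (length(unique(labels[ho])) < 2L)
    stop(sprintf(paste0("fold %d holdout contains a single class; ",
                        "reduce n_folds"), f), call. = FALSE)
  norm <- embedding_norm(bags[tr])
  bags <- lapply(bags, function(b) {
    b$embeddings <- apply_norm(b$embeddings, norm)
    if (!is.null(b$embeddings_aug))
      b$embeddings_aug <- apply_norm(b$embeddings_aug, norm)
    b
  })
  prop <- c(pos = mean(labels[tr] == 1), neg = mean(labels[tr] == 0))
  wts <- ifelse(labels == 1, 1 / prop[["pos"]], 1 / prop[["neg"]])

  set.seed(derive_seed(config$seed, sprintf("init_f%d", f)))
  p <- mil_init(config)
  state <- list(t = 0L, m = list(), v = list())
  best_loss <- Inf; best_epoch <- 0L; checkpoint <- p
  log_rows <- list()
  ho_bags <- bags[ho]; ho_y <- labels[ho]

  for (epoch in seq_len(config$epochs)) {
    lr <- config$lr_max * 0.5 *
      (1 + cos(pi * (epoch - 1) / max(1, config$epochs - 1)))
    set.seed(derive_seed(config$seed, sprintf("epoch%d_f%d", epoch, f)))
    ord <- tr[sample.int(length(tr))]
    use_aug <- stats::runif(length(ord)) < config$aug_prob
    drop_p <- config$dropout
    ep_loss <- 0
    i <- 1L
    while (i <= length(ord)) {
      j <- min(i + config$batch_size - 1L, length(ord))
      idx <- i:j
      acc <- NULL; bl <- 0
      for (m in seq_along(idx)) {
        b <- bags[[ord[idx[m]]]]
        X <- if (use_aug[idx[m]] && !is.null(b$embeddings_aug))
          b$embeddings_aug else b$embeddings
        masks <- if (drop_p > 0)
          lapply(seq_len(config$n_layers), function(l)
            matrix(stats::rbinom(nrow(X) * 2L * config$model_dim, 1, 1 - drop_p) /
                     (1 - drop_p), nrow(X), 2L * config$model_dim))
        else NULL
        lg <- bag_loss_grad(X, labels[ord[idx[m]]], p, config,
                            wts[ord[idx[m]]], masks)
        bl <- bl + lg$loss
        if (is.null(acc)) acc <- lg$grad
        else for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + lg$grad[[nm]]
      }
      nb <- length(idx)
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / nb
      up <- adam_step(p, acc, state, lr, beta1 = config$momentum)
      p <- up$p; state <- up$state
      ep_loss <- ep_loss + bl
      i <- j + 1L
    }
    ho_loss <- cohort_loss(ho_bags, ho_y, p, config, prop)
    log_rows[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                    train_loss = ep_loss / length(ord),
                                    holdout_loss = ho_loss)
    if (ho_loss < best_loss - 1e-12) {
      best_loss <- ho_loss; best_epoch <- epoch; checkpoint <- p
    } else if (epoch - best_epoch >= config$patience) break
  }

  ho_scores <- vapply(ho_bags, function(b)
    mil_fwd(b$embeddings, checkpoint, config)$score, 0)
  structure(list(params = checkpoint, config = config, fold_id = f,
                 norm = norm,
                 holdout_auroc = auroc(ho_scores, ho_y),
                 best_epoch = best_epoch,
                 training_log = do.call(rbind, log_rows)),
            class = "trained_mil")
}

#' Select the deployment model across CV folds
#'
#' Returns the fold model whose holdout AUROC is closest to the median
#' holdout AUROC across folds; ties are broken by the lowest fold id.
#'
#' @param fold_models List of `trained_mil` models from [train_mil_cv()].
#' @return A single `trained_mil`.
#' @export
select_deployment_model <- function(fold_models) {
  stopifnot(length(fold_models) >= 1L)
  aurocs <- vapply(fold_models, `[[`, 0, "holdout_auroc")
  med <- stats::median(aurocs)
  ord <- order(abs(aurocs - med), vapply(fold_models, `[[`, 0L, "fold_id"))
  fold_models[[ord[1L]]]
}

#' Score a cohort of bags with a deployed model
#'
#' Plain (non-augmented) embeddings only are used for evaluation.
#'
#' @param bags List of `instance_bag`s.
#' @param model A `trained_mil`.
#' @return List of `mil_prediction`s, one per patient, in input order.
#' @export
predict_cohort <- function(bags, model) {
  lapply(bags, mil_forward, model = model)
}

#' Collect MIL predictions into a data frame
#' @param predictions List of `mil_prediction`s.
#' @return Data frame with `patient_id` and `score`.
#' @export
mil_scores <- function(predictions) {
  data.frame(patient_id = vapply(predictions, `[[`, "", "patient_id"),
             score = vapply(predictions, `[[`, 0, "score"),
             stringsAsFactors = FALSE)
}
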