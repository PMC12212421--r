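tiny_cfg <- function(...) {
  args <- list(embed_dim_in = 6L, model_dim = 8L, n_layers = 1L,
               n_heads = 2L, attn_dim = 4L, epochs = 3L, patience = 3L,
               n_folds = 2L, batch_size = 4L, seed = 99L)
  over <- list(...)
  args[names(over)] <- over
  do.call(mil_config, args)
}

tiny_model <- function(cfg = tiny_cfg(), seed = 1) {
  set.seed(seed)
  structure(list(params = hnmil:::mil_init(cfg), config = cfg),
            class = "trained_mil")
}

random_bag <- function(n, d = 6, id = "p") {
  structure(list(patient_id = id, embeddings = matrix(rnorm(n * d), n, d),
                 embeddings_aug = matrix(rnorm(n * d), n, d)),
            class = "instance_bag")
}

test_that("weighted BCE uses inverse class-proportion weights", {
  # proportions {pos 0.25, neg 0.75} -> weights {4, 4/3}
  p <- c(0.8, 0.3); y <- c(1, 0)
  expected <- mean(c(4 * -log(0.8), 4 / 3 * -log(0.7)))
  expect_equal(weighted_bce(p, y, c(pos = 0.25, neg = 0.75)), expected)
  # near-perfect predictions drive the loss toward 0
  expect_lt(weighted_bce(c(1 - 1e-9, 1e-9), c(1, 0),
                         c(pos = 0.5, neg = 0.5)), 1e-6)
  # balanced classes: exactly twice the unweighted mean BCE
  set.seed(8)
  pr <- runif(10, 0.05, 0.95); yy <- rep(0:1, 5)
  plain <- mean(-(yy * log(pr) + (1 - yy) * log(1 - pr)))
  expect_equal(weighted_bce(pr, yy, c(pos = 0.5, neg = 0.5)), 2 * plain)
  expect_error(weighted_bce(pr, yy, c(pos = 0, neg = 1)), "zero proportion")
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_cfg(embed_dim_in = 5L)
  set.seed(2)
  p <- hnmil:::mil_init(cfg)
  X <- matrix(rnorm(4 * 5), 4, 5)
  y <- 1; w <- 1.7
  loss_of <- function(pp) {
    s <- hnmil:::mil_fwd(X, pp, cfg)$score
    w * -(y * log(s) + (1 - y) * log(1 - s))
  }
  fw <- hnmil:::mil_fwd(X, p, cfg, keep_cache = TRUE)
  g <- hnmil:::mil_bwd(w * (fw$score - y), p, cfg, fw$cache)
  eps <- 1e-6
  set.seed(5)
  for (nm in names(g)) {
    ks <- sample(length(g[[nm]]), min(3, length(g[[nm]])))
    for (k in ks) {
      p2 <- p; p2[[nm]][k] <- p2[[nm]][k] + eps
      p3 <- p; p3[[nm]][k] <- p3[[nm]][k] - eps
      fd <- (loss_of(p2) - loss_of(p3)) / (2 * eps)
      expect_lt(abs(fd - g[[nm]][k]) / max(1e-6, abs(fd) + abs(g[[nm]][k])),
                1e-4)
    }
  }
})

test_that("bag scoring is permutation-invariant with normalized attention", {
  model <- tiny_model()
  set.seed(3)
  for (rep in 1:5) {
    bag <- random_bag(7)
    pr <- mil_forward(bag, model)
    expect_equal(sum(pr$attention), 1, tolerance = 1e-6)
    perm <- sample(7)
    bag2 <- bag; bag2$embeddings <- bag$embeddings[perm, ]
    pr2 <- mil_forward(bag2, model)
    expect_equal(pr2$score, pr$score, tolerance = 1e-12)
    expect_equal(pr2$attention, pr$attention[perm], tolerance = 1e-12)
  }
  # identical instances share the attention mass uniformly
  one <- matrix(rnorm(6), 1)
  same <- structure(list(patient_id = "s",
                         embeddings = one[rep(1, 5), , drop = FALSE]),
                    class = "instance_bag")
  pr <- mil_forward(same, model)
  expect_equal(pr$attention, rep(0.2, 5), tolerance = 1e-12)
  expect_error(mil_forward(matrix(numeric(0), 0, 6), model), "empty")
  expect_error(mil_forward(random_bag(3, d = 9), model), "does not match")
})

test_that("stratified folds balance classes within one sample", {
  y <- c(rep(1, 23), rep(0, 77))
  fold <- hnmil:::stratified_folds(y, 5, seed = 42)
  for (f in 1:5) {
    expect_lte(abs(sum(y[fold == f] == 1) - 23 / 5), 1)
    expect_lte(abs(sum(y[fold == f] == 0) - 77 / 5), 1)
  }
  expect_identical(fold, hnmil:::stratified_folds(y, 5, seed = 42))
})

test_that("cross-validated training is deterministic and checkpoints by holdout loss", {
  set.seed(10)
  bags <- lapply(1:14, function(i) random_bag(4, id = sprintf("p%d", i)))
  y <- rep(0:1, 7)
  cfg <- tiny_cfg(epochs = 4L, patience = 4L)
  m1 <- train_mil_cv(bags, y, cfg)
  m2 <- train_mil_cv(bags, y, cfg)
  expect_identical(m1[[1]]$params, m2[[1]]$params)
  expect_identical(m1[[2]]$holdout_auroc, m2[[2]]$holdout_auroc)
  expect_s3_class(m1[[1]]$training_log, "data.frame")
  expect_error(train_mil_cv(bags, rep(c(1, 0), c(12, 2)),
                            tiny_cfg(n_folds = 5L)), "single class|2 patients")
  expect_error(train_mil_cv(bags[1:3], c(1, 1, 0), cfg), "2 patients")
})

test_that("early stopping halts at best epoch + patience when nothing improves", {
  set.seed(11)
  bags <- lapply(1:12, function(i) random_bag(3))
  y <- rep(0:1, 6)
  cfg <- tiny_cfg(epochs = 30L, patience = 3L, lr_max = 0)
  models <- train_mil_cv(bags, y, cfg)
  for (m in models) {
    expect_equal(m$best_epoch, 1L)
    expect_equal(nrow(m$training_log), 1L + 3L)
  }
})

test_that("deployment selection picks the fold closest to the median AUROC", {
  mk <- function(aurocs) lapply(seq_along(aurocs), function(i)
    structure(list(fold_id = i, holdout_auroc = aurocs[i]),
              class = "trained_mil"))
  expect_equal(select_deployment_model(mk(c(0.6, 0.65, 0.7, 0.75, 0.8)))$fold_id, 3L)
  expect_equal(select_deployment_model(mk(rep(0.7, 5)))$fold_id, 1L)
  expect_equal(select_deployment_model(mk(c(0.6, 0.7, 0.7, 0.8)))$fold_id, 2L)
})

test_that("attention concentrates on signal instances in a planted-signal bag", {
  set.seed(31)
  d <- 6
  mk_bag <- function(y) {
    sig <- matrix(rnorm(3 * d, mean = ifelse(y == 1, 1.5, -1.5), sd = 0.3),
                  3, d)
    noise <- matrix(rnorm(3 * d, sd = 3), 3, d)
    structure(list(patient_id = "x", embeddings = rbind(sig, noise),
                   embeddings_aug = rbind(sig, noise)),
              class = "instance_bag")
  }
  y <- rep(0:1, 20)
  bags <- lapply(y, mk_bag)
  cfg <- tiny_cfg(epochs = 15L, patience = 15L, n_folds = 2L,
                  batch_size = 1L, lr_max = 3e-3, seed = 5L)
  model <- select_deployment_model(train_mil_cv(bags, y, cfg))
  att <- vapply(bags, function(b) {
    a <- mil_forward(b, model)$attention
    mean(a[1:3]) - mean(a[4:6])
  }, 0)
  expect_gt(mean(att), 0)
})

test_that("cohort prediction is order-independent and uses plain embeddings", {
  model <- tiny_model()
  set.seed(6)
  bags <- lapply(1:6, function(i) random_bag(5, id = sprintf("p%d", i)))
  preds <- predict_cohort(bags, model)
  scores <- mil_scores(preds)
  expect_true(all(scores$score >= 0 & scores$score <= 1))
  rev_scores <- mil_scores(predict_cohort(rev(bags), model))
  expect_equal(rev_scores$score, rev(scores$score))
  # plain embeddings only: mutating the augmented twin changes nothing
  bags2 <- lapply(bags, function(b) { b$embeddings_aug <- b$embeddings_aug * 100; b })
  expect_equal(mil_scores(predict_cohort(bags2, model))$score, scores$score)
})
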