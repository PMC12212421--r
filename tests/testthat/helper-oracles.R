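# Independent brute-force oracles used to check the statistical machinery.

# AUROC by exhaustive pairwise concordance enumeration (ties count 1/2)
bf_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Kaplan-Meier by the product-limit definition evaluated at a time point
bf_km_surv <- function(times, events, t) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  for (tt in ut[ut <= t]) {
    n_risk <- sum(times >= tt)
    d <- sum(times == tt & events == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

# Cox partial log-likelihood for a binary covariate, no ties assumed
bf_cox_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# maximize the partial likelihood by grid/golden search
bf_cox_hr <- function(times, events, x) {
  opt <- stats::optimize(function(b) -bf_cox_loglik(b, times, events, x),
                         interval = c(-5, 5), tol = 1e-7)
  exp(opt$minimum)
}

# simple logistic AUROC probe with ridge-stabilized IRLS via glm
probe_auroc <- function(X_tr, y_tr, X_te, y_te) {
  fit <- suppressWarnings(glmnet::glmnet(X_tr, y_tr, family = "binomial",
                                         alpha = 0, lambda = 0.05))
  p <- as.numeric(stats::predict(fit, X_te, type = "response"))
  auroc(p, y_te)
}
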