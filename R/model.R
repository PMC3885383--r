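# Classifier stack: ridge-stabilized logistic regression, greedy forward
# feature selection on inner-validation AUC, and out-of-fold risk
# prediction under contiguous cross-validation. The fitter is written
# in-package because selection repeatedly fits one- and two-column designs
# that mainstream penalized-regression interfaces reject; it is
# cross-checked against stats::glm in the test suite.

#' Fit a ridge-penalized logistic regression
#'
#' Maximizes the Bernoulli log-likelihood minus `ridge/2 * sum(beta^2)`
#' (intercept unpenalized) by Newton iterations with step halving. With
#' `ridge = 0` this is plain logistic regression. The fit is deterministic;
#' features should already be on comparable scales (see
#' [cross_val_risk()], which standardizes using training-fold statistics).
#'
#' @param X numeric matrix, observations x features (no intercept column).
#' @param y binary outcome (0/1 or logical); both classes must be present.
#' @param ridge non-negative penalty scale.
#' @param tol convergence tolerance on the penalized deviance.
#' @param max_iter maximum Newton iterations.
#' @return An object of class `logistic_model` with elements `intercept`,
#'   `coef`, `converged`, `deviance`.
#' @export
fit_logistic <- function(X, y, ridge = 1e-4, tol = 1e-9, max_iter = 50L) {
  if (!is.matrix(X)) X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  if (!all(is.finite(X))) stop("X contains non-finite values")
  if (length(unique(y)) < 2L)
    stop("y contains a single class; cannot fit a classifier")
  p <- ncol(X)
  beta <- c(log(mean(y) / (1 - mean(y))), rep(0, p))
  Z <- cbind(1, X)
  pen <- c(0, rep(ridge, p))
  obj <- function(b) {
    eta <- drop(Z %*% b)
    # log(1 + exp(eta)) - y*eta, numerically stable
    sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta) +
      0.5 * sum(pen * b^2)
  }
  f_old <- obj(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(Z, mu - y)) + pen * beta
    H <- crossprod(Z * w, Z)
    diag(H) <- diag(H) + pen
    step <- tryCatch(solve(H, grad), error = function(e)
      solve(H + diag(1e-8, p + 1L), grad))
    # step halving on the penalized objective
    s <- 1
    repeat {
      cand <- beta - s * step
      f_new <- obj(cand)
      if (is.finite(f_new) && f_new <= f_old + 1e-12) break
      s <- s / 2
      if (s < 1e-8) { cand <- beta; f_new <- f_old; break }
    }
    done <- abs(f_old - f_new) < tol * (abs(f_old) + tol)
    beta <- cand
    f_old <- f_new
    if (done) { converged <- TRUE; break }
  }
  structure(list(intercept = beta[1L], coef = beta[-1L],
                 converged = converged,
                 deviance = 2 * (f_old - 0.5 * sum(pen * beta^2))),
            class = "logistic_model")
}

#' @export
predict.logistic_model <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  stats::plogis(drop(newdata %*% object$coef) + object$intercept)
}

# Mann-Whitney AUC from ranks (ties handled by midranks). pROC serves as
# the independent cross-check in the tests.
auc_rank <- function(scores, y) {
  y <- as.logical(y)
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Contiguous split of 1..n into k runs with sizes differing by <= 1.
contiguous_split <- function(n, k) {
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  split(seq_len(n), rep(seq_len(k), times = sizes))
}

# log10(PIB + eps) transform applied before scaling; eps guards exact zeros.
log_pib <- function(X) log10(X + .Machine$double.xmin)

#' Greedy forward feature selection by inner-validation AUC
#'
#' Starting from the empty set, each step adds the feature that maximizes
#' the mean out-of-fold AUC of the refitted classifier over a contiguous
#' inner split of the (time-ordered) training rows; ties break to the
#' lowest column index. Only training data is ever seen.
#'
#' @param X numeric matrix of training features (time-ordered rows,
#'   already transformed/scaled).
#' @param y binary training labels.
#' @param k number of features to select.
#' @param n_inner number of contiguous inner validation folds.
#' @param ridge penalty passed to [fit_logistic()].
#' @return Integer vector of selected column indices, in selection order.
#' @export
forward_select <- function(X, y, k, n_inner = 5L, ridge = 1e-4) {
  if (!is.matrix(X)) X <- as.matrix(X)
  y <- as.numeric(y)
  if (k > ncol(X)) stop("cannot select more features than available columns")
  if (k == 0L) return(integer(0))
  inner <- contiguous_split(nrow(X), n_inner)
  usable <- Filter(function(idx) {
    length(unique(y[idx])) == 2L && length(unique(y[-idx])) == 2L
  }, inner)
  in_sample <- length(usable) == 0L
  if (in_sample) {
    # all positives sit in one contiguous stretch: no inner split carries
    # both classes on both sides, so fall back to in-sample AUC
    warning("no inner fold contains both classes; using in-sample AUC")
    usable <- list(seq_len(nrow(X)))
  }
  selected <- integer(0)
  remaining <- seq_len(ncol(X))
  for (step in seq_len(k)) {
    crit <- vapply(remaining, function(j) {
      cols <- c(selected, j)
      mean(vapply(usable, function(idx) {
        tr <- if (in_sample) idx else setdiff(seq_len(nrow(X)), idx)
        # looser tolerance: screening only needs a stable AUC ranking
        fit <- fit_logistic(X[tr, cols, drop = FALSE], y[tr],
                            ridge = ridge, tol = 1e-6)
        auc_rank(predict(fit, X[idx, cols, drop = FALSE]), y[idx])
      }, 0))
    }, 0)
    best <- remaining[which.max(crit)]  # first max -> lowest index on ties
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}

#' Out-of-fold seizure risk under contiguous cross-validation
#'
#' For each fold, feature selection, feature scaling, and classifier
#' weights are computed on the other folds' labeled blocks only, and the
#' fitted model predicts a relative seizure risk in \[0, 1\] for every
#' valid non-ictal block of the held-out fold. Features enter as
#' `log10(PIB + eps)` standardized with training-fold statistics. Risks on
#' the training blocks themselves are retained per fold for warning
#' threshold calibration. A training split lacking pre-ictal blocks yields
#' `NA` risks for that fold, with a warning.
#'
#' @param fm a labeled [pib_features()] with folds assigned.
#' @param config a [run_config()].
#' @return An object of class `risk_series`: a data frame with columns
#'   `block_start_s`, `risk`, `fold`, `label` (one row per valid non-ictal
#'   block), with per-fold model details in `attr(, "models")` and the
#'   block length / record span in attributes.
#' @export
cross_val_risk <- function(fm, config = run_config()) {
  stopifnot(inherits(fm, "pib_features"), !is.null(fm$label), !is.null(fm$fold))
  use <- fm$valid & !is.na(fm$label) & fm$label != "ictal_excluded"
  if (!any(use)) stop("no labeled non-ictal blocks available")
  L <- log_pib(fm$X[use, , drop = FALSE])
  y <- as.numeric(fm$label[use] == "preictal")
  fold <- fm$fold[use]
  bs <- fm$block_start_s[use]
  risk <- rep(NA_real_, length(y))
  models <- list()
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) {
      warning(sprintf("fold %d: training split lacks a class; risks set NA", f))
      models[[as.character(f)]] <- list(fold = f, ok = FALSE)
      next
    }
    ctr <- colMeans(L[tr, , drop = FALSE])
    scl <- apply(L[tr, , drop = FALSE], 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    S <- sweep(sweep(L, 2L, ctr), 2L, scl, "/")
    sel <- forward_select(S[tr, , drop = FALSE], y[tr],
                          k = min(config$n_features, ncol(S)),
                          n_inner = config$n_inner_folds,
                          ridge = config$ridge)
    fit <- fit_logistic(S[tr, sel, drop = FALSE], y[tr], ridge = config$ridge)
    risk[!tr] <- predict(fit, S[!tr, sel, drop = FALSE])
    models[[as.character(f)]] <- list(
      fold = f, ok = TRUE, selected = sel,
      feature_names = colnames(fm$X)[sel],
      intercept = fit$intercept, coef = fit$coef,
      center = ctr[sel], scale = scl[sel],
      train_risk = data.frame(block_start_s = bs[tr],
                              risk = predict(fit, S[tr, sel, drop = FALSE])))
  }
  out <- data.frame(block_start_s = bs, risk = risk, fold = fold,
                    label = fm$label[use])
  structure(out, class = c("risk_series", "data.frame"),
            models = models, block_len = fm$block_len,
            span = max(fm$block_start_s) + fm$block_len)
}

#' Serialize per-fold model artifacts to JSON
#' @param risks a `risk_series` from [cross_val_risk()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(risks, path) {
  models <- attr(risks, "models")
  slim <- lapply(models, function(m)
    m[intersect(names(m), c("fold", "ok", "selected", "feature_names",
                            "intercept", "coef", "center", "scale"))])
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
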