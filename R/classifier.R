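#' Train one-vs-rest L2-penalized logistic classifiers
#'
#' Fits one binary logistic model per condition (condition vs. all others) on
#' the labelled volumes, by Newton iteration on the penalized log-likelihood
#'
#'   -sum_i \[ y_i log p_i + (1 - y_i) log(1 - p_i) \] + lambda ||w||^2,
#'
#' with the intercept unpenalized. `penalty` is lambda in this convention
#' (the coefficient on the *summed* likelihood, as in the Princeton MVPA
#' toolbox); glmnet users note the mapping `lambda_glmnet = 2 * penalty / N`
#' with `alpha = 0, standardize = FALSE`. The default 0.01 is deliberately
#' weak: it only tames weight blow-up under separability.
#'
#' @param data A [voxel_timeseries()] (or voxels x volumes matrix) of
#'   preprocessed signal; typically detrended and label-shifted.
#' @param labels A [label_series()] aligned with `data`; `NA` (unlabelled)
#'   volumes are excluded from training.
#' @param penalty L2 strength lambda (> 0), default 0.01.
#' @param conditions Conditions to fit, in canonical order; every one must be
#'   present among the labels.
#' @param standardize Z-score each voxel on the training volumes before
#'   fitting (means/sds stored in the model and re-applied at prediction).
#'   Off by default.
#' @param tol Convergence tolerance on the Newton step (max absolute
#'   coefficient change), default 1e-6.
#' @param max_iter Iteration cap per binary model.
#' @return An object of class `ia_classifier` with `weights`
#'   (conditions x voxels), `intercepts`, `penalty`, `condition_order`,
#'   `training_volume_count`.
#' @export
train_classifier <- function(data, labels, penalty = 0.01,
                             conditions = ia_conditions(),
                             standardize = FALSE,
                             tol = 1e-6, max_iter = 100L) {
  X <- if (inherits(data, "voxel_timeseries")) data$data else as.matrix(data)
  y <- if (inherits(labels, "label_series")) labels$labels else as.character(labels)
  if (length(y) != ncol(X))
    stop_shape("labels length must equal the volume count")
  if (penalty <= 0) stop_invalid("penalty must be positive")
  keep <- !is.na(y)
  X <- t(X[, keep, drop = FALSE])   # volumes x voxels
  y <- y[keep]
  if (nrow(X) < 10L) stop_invalid("need at least 10 labelled volumes")
  present <- unique(y)
  if (length(present) < 2L) stop_invalid("need at least 2 conditions present")
  missing_cond <- setdiff(conditions, present)
  if (length(missing_cond))
    stop_missing_class(sprintf("condition(s) absent from training labels: %s",
                               paste(missing_cond, collapse = ", ")))
  center <- scale_sd <- NULL
  if (standardize) {
    center <- colMeans(X)
    scale_sd <- apply(X, 2L, stats::sd)
    scale_sd[scale_sd == 0] <- 1
    X <- sweep(sweep(X, 2L, center), 2L, scale_sd, "/")
  }
  fits <- lapply(conditions, function(cond)
    ridge_logistic(X, as.numeric(y == cond), lambda = penalty,
                   tol = tol, max_iter = max_iter))
  weights <- do.call(rbind, lapply(fits, `[[`, "w"))
  rownames(weights) <- conditions
  structure(list(weights = weights,
                 intercepts = stats::setNames(
                   vapply(fits, `[[`, numeric(1), "b"), conditions),
                 penalty = penalty,
                 condition_order = conditions,
                 training_volume_count = nrow(X),
                 standardize = standardize, center = center,
                 scale_sd = scale_sd,
                 iterations = vapply(fits, `[[`, integer(1), "iter"),
                 converged = all(vapply(fits, `[[`, logical(1), "converged"))),
            class = "ia_classifier")
}

# Newton/IRLS fit of a single binary ridge logistic model.
# X: n x p (no intercept column); y in {0,1}; minimizes
# -loglik + lambda * ||w||^2, intercept unpenalized.
ridge_logistic <- function(X, y, lambda, tol = 1e-6, max_iter = 100L) {
  n <- nrow(X); p <- ncol(X)
  theta <- numeric(p + 1L)
  Xd <- cbind(1, X)
  pen <- c(0, rep(2 * lambda, p))
  obj <- function(th) {
    eta <- drop(Xd %*% th)
    # log(1 + exp(eta)) - y*eta, numerically stable
    sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta) +
      lambda * sum(th[-1L]^2)
  }
  f <- obj(theta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(Xd %*% theta)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(Xd, mu - y)) + pen * theta
    wvec <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xd * sqrt(wvec))
    diag(H) <- diag(H) + pen
    delta <- solve(H, g)
    step <- 1
    repeat {
      cand <- theta - step * delta
      f_new <- obj(cand)
      if (f_new <= f + 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    theta <- cand; f <- f_new
    if (max(abs(step * delta)) < tol) { converged <- TRUE; break }
  }
  list(b = theta[1L], w = theta[-1L], converged = converged, iter = iter)
}

#' @export
print.ia_classifier <- function(x, ...) {
  cat(sprintf("<ia_classifier> %d conditions x %d voxels, penalty = %g, trained on %d volumes\n",
              nrow(x$weights), ncol(x$weights), x$penalty,
              x$training_volume_count))
  invisible(x)
}

#' Classifier evidence for each volume
#'
#' Applies the five binary models to every volume, giving one evidence value
#' in (0, 1) per condition per volume. Evidences come from independent
#' one-vs-rest models and are deliberately not renormalized to sum to 1.
#'
#' @param model An `ia_classifier`.
#' @param data A [voxel_timeseries()] or voxels x volumes matrix on the same
#'   voxel grid as the training data.
#' @param type `"evidence"` (default) for sigmoid outputs, `"link"` for the
#'   linear scores. The sigmoid is monotone, so argmax decisions agree; the
#'   pipeline decides on link scores, which cannot saturate in double
#'   precision when margins are large.
#' @return Numeric matrix, volumes x conditions; evidence values are strictly
#'   inside (0, 1).
#' @export
predict_evidence <- function(model, data, type = c("evidence", "link")) {
  stopifnot(inherits(model, "ia_classifier"))
  type <- match.arg(type)
  X <- if (inherits(data, "voxel_timeseries")) data$data else as.matrix(data)
  if (nrow(X) != ncol(model$weights))
    stop_shape(sprintf("data has %d voxels but the model expects %d",
                       nrow(X), ncol(model$weights)))
  X <- t(X)
  if (isTRUE(model$standardize)) {
    X <- sweep(sweep(X, 2L, model$center), 2L, model$scale_sd, "/")
  }
  eta <- sweep(X %*% t(model$weights), 2L, model$intercepts, "+")
  if (type == "link") return(eta)
  # clamp so evidence stays strictly inside (0, 1) in double precision
  stats::plogis(pmin(pmax(eta, -30), 30))
}

#' Categorical decisions from evidence values
#'
#' The condition with the highest evidence value is the decision at each
#' volume, optionally restricted to a subset of conditions (e.g. the three
#' meditation-relevant states). Exact ties are broken in favour of the
#' earliest condition in the model's condition order, with a warning.
#'
#' @param evidence Volumes x conditions matrix from [predict_evidence()]
#'   (column names identify the conditions).
#' @param allowed Conditions to choose among (default: all columns).
#' @return Character vector of decisions, one per volume.
#' @export
decide <- function(evidence, allowed = colnames(evidence)) {
  evidence <- as.matrix(evidence)
  if (is.null(colnames(evidence)))
    stop_invalid("evidence must have condition column names")
  if (length(allowed) < 1L) stop_invalid("allowed set must be non-empty")
  bad <- setdiff(allowed, colnames(evidence))
  if (length(bad))
    stop_missing_class(sprintf("evidence has no column for: %s",
                               paste(bad, collapse = ", ")))
  ev <- evidence[, allowed, drop = FALSE]
  best <- max.col(ev, ties.method = "first")
  n_tied <- rowSums(ev == ev[cbind(seq_len(nrow(ev)), best)])
  if (any(n_tied > 1L))
    warning(sprintf("%d volume(s) had tied evidence; earliest condition in order chosen",
                    sum(n_tied > 1L)))
  allowed[best]
}

#' Leave-one-block-out cross-validation
#'
#' k-fold cross-validation with folds = blocks (scanner runs): for each fold
#' a classifier is trained on the labelled volumes of the other blocks and
#' tested on the held-out block, so every labelled volume is tested exactly
#' once by a model that never saw its block. With the default six-block
#' design this produces 2,160 decisions from folds trained on 1,800 volumes.
#'
#' @param blocks List of per-block [voxel_timeseries()] objects.
#' @param labels List of matching [label_series()] (already hemodynamically
#'   shifted; see [shift_labels()]).
#' @param penalty L2 strength, passed to [train_classifier()].
#' @param conditions Condition set; every block must contain all of them.
#' @param ... Further arguments to [train_classifier()].
#' @return An object of class `crossval_result`: a list with `decisions`
#'   (data frame: block, volume, trial_id, truth, decision), `evidence`
#'   (volumes x conditions), and `fold_train_counts`.
#' @export
cross_validate <- function(blocks, labels, penalty = 0.01,
                           conditions = ia_conditions(), ...) {
  if (length(blocks) < 2L) stop_invalid("need at least 2 blocks")
  if (length(labels) != length(blocks))
    stop_shape("blocks and labels must have the same length")
  for (b in seq_along(blocks)) {
    miss <- setdiff(conditions, unique(stats::na.omit(labels[[b]]$labels)))
    if (length(miss))
      stop_missing_class(sprintf("block %d is missing condition(s): %s",
                                 b, paste(miss, collapse = ", ")))
  }
  res <- vector("list", length(blocks))
  ev_all <- vector("list", length(blocks))
  train_counts <- integer(length(blocks))
  for (b in seq_along(blocks)) {
    train_idx <- setdiff(seq_along(blocks), b)
    tr <- concat_blocks(blocks[train_idx], labels[train_idx])
    model <- train_classifier(tr$ts, tr$labels, penalty = penalty,
                              conditions = conditions, ...)
    train_counts[b] <- model$training_volume_count
    test_keep <- which(!is.na(labels[[b]]$labels))
    score <- predict_evidence(model,
                              blocks[[b]]$data[, test_keep, drop = FALSE],
                              type = "link")
    ev <- stats::plogis(pmin(pmax(score, -30), 30))
    res[[b]] <- data.frame(block = b, volume = test_keep,
                           trial_id = labels[[b]]$trial_id[test_keep],
                           truth = labels[[b]]$labels[test_keep],
                           decision = decide(score))
    ev_all[[b]] <- ev
  }
  structure(list(decisions = do.call(rbind, res),
                 evidence = do.call(rbind, ev_all),
                 fold_train_counts = train_counts,
                 conditions = conditions, penalty = penalty),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("<crossval_result> %d decisions over %d folds (train counts: %s)\n",
              nrow(x$decisions), length(x$fold_train_counts),
              paste(x$fold_train_counts, collapse = ", ")))
  cat(sprintf("overall accuracy: %.1f%%\n",
              100 * mean(x$decisions$decision == x$decisions$truth)))
  invisible(x)
}

#' Detrend, shift and cross-validate one subject
#'
#' Convenience pipeline for a simulated (or loaded) subject: per-block linear
#' detrending, a hemodynamic label shift, then leave-one-block-out
#' cross-validation.
#'
#' @param subject A list with `blocks` and `labels` as produced by
#'   [simulate_subject()].
#' @param penalty L2 strength (default 0.01).
#' @param lag_seconds Hemodynamic label shift (default 6 s).
#' @param detrend Apply [detrend_linear()] first (default TRUE).
#' @param ... Passed on to [cross_validate()].
#' @return A `crossval_result`.
#' @export
crossval_subject <- function(subject, penalty = 0.01, lag_seconds = 6,
                             detrend = TRUE, ...) {
  blocks <- subject$blocks
  if (detrend) blocks <- lapply(blocks, detrend_linear)
  labs <- lapply(subject$labels, shift_labels, lag_seconds = lag_seconds)
  cross_validate(blocks, labs, penalty = penalty, ...)
}
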