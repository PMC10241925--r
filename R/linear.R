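#' Balanced class weights
#'
#' Inverse-prevalence weights: a subject of class `c` receives `N / (2 * N_c)`,
#' so the total weight carried by each class is equal (`N/2` each) and the
#' mean weight is 1 for balanced classes. This is the weighting that turns the
#' ordinary log-loss into the balanced log-loss minimized during search.
#'
#' @param labels 0/1 vector with both classes present.
#' @return numeric vector of positive per-case weights.
#' @export
class_weights <- function(labels) {
  n <- length(labels)
  n1 <- sum(labels == 1)
  n0 <- n - n1
  if (n1 == 0L || n0 == 0L) stop("both classes must be present to balance weights")
  ifelse(labels == 1, n / (2 * n1), n / (2 * n0))
}

#' Balanced (weighted) logistic loss
#'
#' Per-case loss is `-w_i * [y_i log p_i + (1 - y_i) log(1 - p_i)]` with
#' probabilities clipped to `[eps, 1 - eps]`; the aggregate is the
#' weight-normalized sum, `sum(per_case) / sum(w)`. With all `p_i = 0.5` the
#' aggregate is `log(2)` for any class mix. Clipping keeps per-case losses
#' finite so that a single confident mistake cannot dominate lexicase
#' selection with an infinity.
#'
#' @param labels 0/1 vector.
#' @param probabilities predicted P(y = 1).
#' @param weights per-case weights (default: [class_weights()] of `labels`).
#' @param eps clipping bound (default 1e-12).
#' @return list with `per_case` (numeric vector) and `aggregate` (scalar).
#' @export
balanced_log_loss <- function(labels, probabilities, weights = NULL,
                              eps = 1e-12) {
  n <- length(labels)
  if (length(probabilities) != n) stop("labels and probabilities differ in length")
  if (is.null(weights)) weights <- class_weights(labels)
  if (length(weights) != n) stop("weights length mismatch")
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  per_case <- -weights * (labels * log(p) + (1 - labels) * log1p(-p))
  list(per_case = per_case, aggregate = sum(per_case) / sum(weights))
}

#' Fit the logistic layer on derived features
#'
#' Minimizes the balanced log-loss plus a small ridge penalty
#' `ridge * ||beta||^2 / 2` (intercept unpenalized) by damped Newton
#' iteration. The ridge stabilizes the frequent case where a Boolean derived
#' column perfectly separates a small training fold; convergence is declared
#' when the penalized loss changes by less than `tol` or after `max_iter`
#' iterations, and the fit is deterministic in its inputs.
#'
#' @param phi N x p derived-feature matrix (finite values).
#' @param labels 0/1 vector.
#' @param weights per-case weights (default balanced).
#' @param ridge ridge penalty on the coefficients (default 1e-6).
#' @param tol convergence tolerance on the loss (default 1e-8).
#' @param max_iter Newton iteration cap (default 100).
#' @return list with `beta` (length p), `intercept`, `loss` (final balanced
#'   log-loss without penalty), `converged`, `iterations`.
#' @export
fit_logistic <- function(phi, labels, weights = NULL, ridge = 1e-6,
                         tol = 1e-8, max_iter = 100L) {
  phi <- as.matrix(phi)
  n <- nrow(phi)
  p <- ncol(phi)
  if (!all(is.finite(phi))) stop("derived-feature matrix contains non-finite values")
  if (length(labels) != n) stop("labels length != nrow(phi)")
  if (is.null(weights)) weights <- class_weights(labels)
  if (n <= p) {
    warning("fewer cases than derived features; fit may be unstable")
  }
  const_col <- apply(phi, 2L, function(col) max(col) == min(col))
  if (any(const_col)) {
    warning("constant derived-feature column(s): ",
            paste(which(const_col), collapse = ", "),
            "; coefficients held near 0 by the ridge penalty")
  }
  wsum <- sum(weights)
  X <- cbind(1, phi)
  coef <- numeric(p + 1L)
  # numerically stable balanced cross-entropy:
  # -[y log p + (1-y) log(1-p)] = max(eta, 0) + log1p(exp(-|eta|)) - y*eta
  pen_loss <- function(coef) {
    eta <- drop(X %*% coef)
    ll <- pmax(eta, 0) + log1p(exp(-abs(eta))) - labels * eta
    sum(weights * ll) / wsum + ridge * sum(coef[-1L]^2) / 2
  }
  cur <- pen_loss(coef)
  converged <- FALSE
  iter <- 0L
  ridge_vec <- c(0, rep(ridge, p))
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% coef)
    pr <- plogis(eta)
    grad <- drop(crossprod(X, weights * (pr - labels))) / wsum + ridge_vec * coef
    wdiag <- weights * pr * (1 - pr)
    H <- crossprod(X, X * wdiag) / wsum + diag(ridge_vec + 1e-12, p + 1L)
    step <- tryCatch(solve(H, grad), error = function(e) grad)
    # damping: halve until the penalized loss does not increase
    lambda <- 1
    repeat {
      cand <- coef - lambda * step
      new <- pen_loss(cand)
      if (new <= cur + 1e-15 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    if (lambda < 1e-8 && new > cur) break  # no descent direction left
    improved <- cur - new
    coef <- cand
    cur <- new
    if (improved < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% coef)
  coef <- unname(coef)
  list(beta = coef[-1L], intercept = coef[1L],
       loss = balanced_log_loss(labels, plogis(eta), weights)$aggregate,
       converged = converged, iterations = iter)
}

#' Fitted model: representation + logistic coefficients
#'
#' @param rep a [representation()].
#' @param beta coefficient vector, one per tree.
#' @param intercept scalar intercept.
#' @param feature_names raw input column names the representation binds to.
#' @param decision_threshold probability cut for classification (default 0.5).
#' @param meta list of training metadata (seed, config hash, diagnostics).
#' @return An object of class `bf_model`.
#' @export
bf_model <- function(rep, beta, intercept, feature_names,
                     decision_threshold = 0.5, meta = list()) {
  stopifnot(inherits(rep, "bf_representation"))
  if (length(beta) != rep_p(rep)) stop("length(beta) != number of trees")
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    stop("decision_threshold must lie in (0, 1)")
  }
  structure(list(representation = rep, beta = as.numeric(beta),
                 intercept = as.numeric(intercept),
                 feature_names = feature_names,
                 decision_threshold = decision_threshold, meta = meta),
            class = "bf_model")
}

#' Predict probabilities from a fitted model
#'
#' Columns are bound by feature name, so scoring data may permute or extend
#' the training columns; a missing training column is a schema error.
#'
#' @param model a [bf_model()].
#' @param ds a [bf_dataset()] or numeric matrix with named columns.
#' @return numeric vector of probabilities `P(y = 1 | x)`.
#' @export
predict_proba <- function(model, ds) {
  x <- if (inherits(ds, "bf_dataset")) ds$features else as.matrix(ds)
  nms <- colnames(x)
  if (is.null(nms)) {
    if (ncol(x) < length(model$feature_names)) {
      stop("scoring data has fewer columns than the training schema")
    }
  } else if (!identical(nms[seq_along(model$feature_names)], model$feature_names)) {
    missing <- setdiff(model$feature_names, nms)
    if (length(missing) > 0L) {
      stop("scoring data is missing training columns: ",
           paste(missing, collapse = ", "))
    }
    x <- x[, model$feature_names, drop = FALSE]
  }
  phi <- evaluate_representation(model$representation, x)
  plogis(drop(phi %*% model$beta) + model$intercept)
}

#' Classify subjects at the model's decision threshold
#'
#' @param model a [bf_model()].
#' @param ds dataset or matrix to score.
#' @return integer 0/1 vector; positive iff probability >= threshold.
#' @export
predict_class <- function(model, ds) {
  as.integer(predict_proba(model, ds) >= model$decision_threshold)
}

#' @export
print.bf_model <- function(x, ...) {
  ord <- order(abs(x$beta), decreasing = TRUE)
  cat(sprintf("<bf_model> p = %d, size = %d, decision threshold = %.3f\n",
              rep_p(x$representation), rep_size(x$representation),
              x$decision_threshold))
  for (i in ord) {
    cat(sprintf("  %+8.4f * [%s]\n", x$beta[i],
                format_node(x$representation$trees[[i]], x$feature_names)))
  }
  cat(sprintf("  intercept %+.4f\n", x$intercept))
  invisible(x)
}

#' Serialize / restore a model as JSON
#'
#' The JSON carries the representation (trees keyed by feature name), the
#' coefficients, intercept, decision threshold, and training metadata;
#' numbers are written at full precision so a round-trip is bit-exact.
#'
#' @param model a [bf_model()].
#' @param path output path.
#' @return `path` (write) / a [bf_model()] (read).
#' @export
write_model <- function(model, path) {
  obj <- list(
    representation = rep_to_list(model$representation, model$feature_names),
    feature_names = model$feature_names,
    beta = model$beta,
    intercept = model$intercept,
    decision_threshold = model$decision_threshold,
    meta = model$meta
  )
  # I(17) significant digits guarantees a bit-exact double round-trip
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feature_names <- unlist(obj$feature_names)
  rep <- rep_from_list(obj$representation, feature_names)
  bf_model(rep, unlist(obj$beta), obj$intercept, feature_names,
           obj$decision_threshold, obj$meta)
}
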