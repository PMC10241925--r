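#' Select the final model from a Pareto archive
#'
#' Evaluates every archived model on the held-out validation split and
#' returns the one with the lowest balanced log-loss; ties fall to the
#' smaller size, then the smaller complexity, then the earlier archive
#' position.
#'
#' @param archive a `bf_archive` (see [feat_run()]) or plain list of
#'   [bf_model()]s.
#' @param validation a [bf_dataset()] with both classes present.
#' @param op_weights operator-cost table for the complexity tie-break.
#' @return The selected [bf_model()], with attribute `validation_loss`.
#' @export
select_final <- function(archive, validation, op_weights = default_op_weights()) {
  models <- archive_models(archive)
  if (length(models) == 0L) stop("archive is empty")
  w <- class_weights(validation$labels)
  loss <- vapply(models, function(m) {
    balanced_log_loss(validation$labels, predict_proba(m, validation), w)$aggregate
  }, numeric(1L))
  size <- vapply(models, function(m) rep_size(m$representation), integer(1L))
  cx <- vapply(models, function(m) rep_complexity(m$representation, op_weights),
               numeric(1L))
  best <- order(loss, size, cx, seq_along(models))[1L]
  out <- models[[best]]
  attr(out, "validation_loss") <- loss[best]
  out
}

archive_models <- function(archive) {
  if (inherits(archive, "bf_archive")) {
    lapply(archive$members, function(e) e$model)
  } else if (inherits(archive, "bf_model")) {
    list(archive)
  } else {
    archive
  }
}

#' Robust model selection over restarts
#'
#' The search is rerun several times (typically 10) with reshuffled seeds,
#' yielding one selected model per restart with its validation average
#' precision. Models strictly below the 25th percentile (linear
#' interpolation) of validation AUPRC are excluded, and the smallest of the
#' survivors is returned; ties fall to the higher AUPRC, then the earlier
#' restart.
#'
#' @param models list of [bf_model()]s, one per restart.
#' @param val_auprc numeric vector of validation AUPRC per restart.
#' @return The selected [bf_model()], with attribute `restart` (its index).
#' @export
robust_select <- function(models, val_auprc) {
  stopifnot(length(models) == length(val_auprc), length(models) >= 2L)
  cut <- stats::quantile(val_auprc, 0.25, type = 7, names = FALSE)
  keep <- which(val_auprc >= cut)
  size <- vapply(models[keep], function(m) rep_size(m$representation), integer(1L))
  best <- keep[order(size, -val_auprc[keep], keep)[1L]]
  out <- models[[best]]
  attr(out, "restart") <- best
  out
}

#' Calibrate the decision threshold to a target PPV
#'
#' Scans every distinct score as a cut-point (classify positive iff
#' `score >= cut`), computing sensitivity, specificity, and the
#' prevalence-adjusted positive predictive value
#' `PPV = se * rho / (se * rho + (1 - sp) * (1 - rho))` at the stated
#' deployment prevalence `rho`. Returns the lowest qualifying cut — i.e. the
#' most sensitive operating point whose adjusted PPV meets the target. When
#' no cut qualifies, the cut maximizing adjusted PPV is returned with a
#' warning. Scores are typically taken from the combined training and
#' validation subjects.
#'
#' @param scores predicted probabilities in `[0, 1]`.
#' @param labels 0/1 vector with both classes present.
#' @param target_ppv desired adjusted PPV (default 0.70).
#' @param deployment_prevalence assumed outcome prevalence where the model
#'   will be deployed (e.g. 0.075 for resistant hypertension in primary
#'   care).
#' @return list with `threshold`, `sensitivity`, `specificity`,
#'   `adjusted_ppv`, and `achieved` (whether the target was met).
#' @export
choose_threshold <- function(scores, labels, target_ppv = 0.70,
                             deployment_prevalence) {
  if (deployment_prevalence <= 0 || deployment_prevalence >= 1) {
    stop("deployment_prevalence must lie in (0, 1)")
  }
  if (length(unique(labels)) < 2L) stop("both classes required")
  rho <- deployment_prevalence
  cuts <- sort(unique(scores))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  se <- sp <- ppv <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    pos <- scores >= cuts[i]
    se[i] <- sum(pos & labels == 1) / n1
    sp[i] <- sum(!pos & labels == 0) / n0
    denom <- se[i] * rho + (1 - sp[i]) * (1 - rho)
    ppv[i] <- if (denom == 0) NA_real_ else se[i] * rho / denom
  }
  ok <- which(!is.na(ppv) & ppv >= target_ppv)
  if (length(ok) > 0L) {
    i <- ok[1L]  # cuts are ascending: lowest qualifying threshold
    achieved <- TRUE
  } else {
    warning(sprintf("target adjusted PPV %.2f unreachable; best achievable %.3f",
                    target_ppv, max(ppv, na.rm = TRUE)))
    i <- which.max(ppv)
    achieved <- FALSE
  }
  list(threshold = cuts[i], sensitivity = se[i], specificity = sp[i],
       adjusted_ppv = ppv[i], achieved = achieved)
}

#' Prevalence-adjusted positive predictive value
#'
#' `PPV = se * rho / (se * rho + (1 - sp) * (1 - rho))`: the PPV the
#' operating point `(se, sp)` would attain in a population with outcome
#' prevalence `rho`.
#'
#' @param sensitivity,specificity operating point in `[0, 1]`.
#' @param prevalence deployment prevalence in `(0, 1)`.
#' @return adjusted PPV.
#' @export
adjusted_ppv <- function(sensitivity, specificity, prevalence) {
  sensitivity * prevalence /
    (sensitivity * prevalence + (1 - specificity) * (1 - prevalence))
}
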