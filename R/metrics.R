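#' Area under the precision-recall curve (average precision)
#'
#' Computed as average precision: `sum_k (R_k - R_{k-1}) * P_k` over the
#' score-ranked list, with tied scores grouped into a single step so the
#' result does not depend on the order of ties.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric scores (higher = more positive).
#' @return average precision in (0, 1].
#' @export
auprc <- function(labels, scores) {
  if (length(unique(labels)) < 2L) stop("both classes required for AUPRC")
  if (length(scores) != length(labels)) stop("length mismatch")
  n_pos <- sum(labels == 1)
  # group tied scores: descending unique score values
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tabulate(grp)
  tp <- cumsum(tp_g)
  pred_pos <- cumsum(n_g)
  precision <- tp / pred_pos
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Area under the ROC curve
#'
#' Equals the normalized Mann-Whitney U statistic: the probability that a
#' random positive outscores a random negative, with ties counted 1/2.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric scores.
#' @return AUROC in [0, 1]; 0.5 for constant scores.
#' @export
auroc <- function(labels, scores) {
  if (length(unique(labels)) < 2L) stop("both classes required for AUROC")
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated stratified k-fold cross-validation of the full pipeline
#'
#' For each repeat the data are shuffled and split into `k` label-stratified
#' folds; the full search pipeline (including optional restart-based robust
#' selection) is trained on k-1 folds and scored on the held-out fold, and
#' fold scores are averaged within the repeat. Everything is driven by the
#' repeat seeds, so a rerun reproduces the table exactly.
#'
#' @param ds preprocessed [bf_dataset()].
#' @param cfg an [evolution_config()].
#' @param n_repeats number of repeats (default 50).
#' @param k folds per repeat (default 5).
#' @param seeds optional integer vector of per-repeat seeds.
#' @param n_restarts restarts per fold for robust selection (1 = plain fit).
#' @return data.frame with one row per repeat: mean test `auprc`, `auroc`,
#'   and mean final model `size` across folds.
#' @export
repeated_cv <- function(ds, cfg, n_repeats = 50L, k = 5L, seeds = NULL,
                        n_restarts = 1L) {
  n <- nrow(ds$features)
  if (n < 5L * 1L || n < k) stop("dataset too small for ", k, "-fold CV")
  if (is.null(seeds)) seeds <- seq_len(n_repeats)
  if (length(seeds) != n_repeats) stop("need one seed per repeat")
  res <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    folds <- stratified_folds(ds$labels, k, seeds[r])
    fold_auprc <- fold_auroc <- fold_size <- numeric(k)
    for (fi in seq_len(k)) {
      test_idx <- which(folds == fi)
      train_idx <- setdiff(seq_len(n), test_idx)
      stopifnot(length(intersect(train_idx, test_idx)) == 0L)
      train <- dataset_rows(ds, train_idx)
      test <- dataset_rows(ds, test_idx)
      fold_cfg <- cfg
      fold_cfg$seed <- seeds[r] * 1000L + fi
      model <- fit_feat(train, fold_cfg, n_restarts = n_restarts)
      sc <- predict_proba(model, test)
      fold_auprc[fi] <- auprc(test$labels, sc)
      fold_auroc[fi] <- auroc(test$labels, sc)
      fold_size[fi] <- rep_size(model$representation)
    }
    res[[r]] <- data.frame(repeat_id = r, auprc = mean(fold_auprc),
                           auroc = mean(fold_auroc), size = mean(fold_size))
  }
  do.call(rbind, res)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin into k folds.
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  local_rng(seed, {
    for (cls in unique(labels)) {
      rows <- sample(which(labels == cls))
      folds[rows] <- rep_len(seq_len(k), length(rows))
    }
  })
  folds
}

#' Variant-ablation benchmark harness
#'
#' Runs each search-configuration variant on each dataset for `n_trials`
#' shuffled stratified train/test splits (default 75/25), recording test
#' average precision and final model size, and computes pairwise two-sided
#' Wilcoxon rank-sum comparisons between variants on the per-trial values.
#'
#' @param datasets named list of preprocessed [bf_dataset()]s.
#' @param variants named list of [evolution_config()]s.
#' @param n_trials trials per dataset (default 10).
#' @param split train fraction (default 0.75).
#' @param seed base seed.
#' @return list with `results` (long data.frame: dataset, variant, trial,
#'   auprc, size) and `comparisons` (pairwise Wilcoxon p-values on AUPRC and
#'   size).
#' @export
variant_ablation <- function(datasets, variants, n_trials = 10L, split = 0.75,
                             seed = 1L) {
  if (is.null(names(datasets))) names(datasets) <- paste0("dataset", seq_along(datasets))
  if (is.null(names(variants))) names(variants) <- paste0("variant", seq_along(variants))
  rows <- list()
  for (di in seq_along(datasets)) {
    ds <- datasets[[di]]
    n <- nrow(ds$features)
    for (trial in seq_len(n_trials)) {
      split_seed <- seed + 7919L * di + trial
      sp <- split_train_validation(ds, validation_frac = 1 - split,
                                   seed = split_seed)
      for (vi in seq_along(variants)) {
        cfg <- variants[[vi]]
        cfg$seed <- split_seed * 131L + vi
        model <- fit_feat(sp$train, cfg)
        sc <- predict_proba(model, sp$validation)
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = names(datasets)[di], variant = names(variants)[vi],
          trial = trial, auprc = auprc(sp$validation$labels, sc),
          size = rep_size(model$representation))
      }
    }
  }
  results <- do.call(rbind, rows)
  vn <- names(variants)
  comps <- list()
  if (length(vn) >= 2L) {
    for (i in seq_len(length(vn) - 1L)) {
      for (j in seq((i + 1L), length(vn))) {
        a <- results[results$variant == vn[i], ]
        b <- results[results$variant == vn[j], ]
        comps[[length(comps) + 1L]] <- data.frame(
          variant_a = vn[i], variant_b = vn[j],
          p_auprc = stats::wilcox.test(a$auprc, b$auprc, exact = FALSE)$p.value,
          p_size = stats::wilcox.test(a$size, b$size, exact = FALSE)$p.value)
      }
    }
  }
  list(results = results,
       comparisons = if (length(comps)) do.call(rbind, comps) else NULL)
}
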