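#' Prune the most redundant derived feature
#'
#' Computes pairwise Pearson correlations between the derived-feature
#' columns (for 0/1 columns this is the phi coefficient), finds the pair
#' with the largest absolute correlation, and deletes the member of that
#' pair that is less correlated (point-biserial) with the outcome; on a tie
#' the later tree is deleted. This is the correlation-deletion mutation used
#' both as a variation operator during search and iteratively during
#' post-run simplification.
#'
#' @param rep a [representation()] with `p >= 2`.
#' @param ds dataset or matrix the representation is evaluated on.
#' @param labels 0/1 outcome vector.
#' @return A representation with one fewer tree (`p - 1`), with attributes
#'   `deleted_index` and `pair_correlation`.
#' @export
prune_correlated <- function(rep, ds, labels) {
  if (rep_p(rep) < 2L) {
    warning("representation has a single tree; nothing to prune")
    return(rep)
  }
  phi <- evaluate_representation(rep, ds)
  p <- ncol(phi)
  best <- c(NA_integer_, NA_integer_)
  best_r <- -Inf
  for (i in seq_len(p - 1L)) {
    for (j in seq((i + 1L), p)) {
      r <- abs(safe_cor(phi[, i], phi[, j]))
      if (r > best_r) {
        best_r <- r
        best <- c(i, j)
      }
    }
  }
  ry_i <- abs(safe_cor(phi[, best[1L]], labels))
  ry_j <- abs(safe_cor(phi[, best[2L]], labels))
  # delete the less outcome-correlated member; tie -> the later tree
  del <- if (ry_i < ry_j) best[1L] else best[2L]
  out <- representation(rep$trees[-del])
  attr(out, "deleted_index") <- del
  attr(out, "pair_correlation") <- best_r
  out
}

# Pearson correlation robust to zero-variance columns: identical constant
# columns count as perfectly correlated (they are redundant by definition);
# otherwise a constant column correlates 0 with anything.
safe_cor <- function(a, b) {
  if (isTRUE(all.equal(stats::sd(a), 0)) || isTRUE(all.equal(stats::sd(b), 0))) {
    if (all(a == b)) return(1)
    return(0)
  }
  stats::cor(a, b)
}

#' Remove redundant logical operations
#'
#' Rewrites a representation to a fixpoint of the exact-equivalence rules
#' `NOT(NOT(a)) -> a`, `AND(a, a) -> a`, `OR(a, a) -> a`, and collapse of
#' duplicate operands inside same-operator chains (e.g.
#' `OR(a, OR(a, b)) -> OR(a, b)`). Predictions are identical on every input;
#' only the tree shrinks.
#'
#' @param rep a [representation()] (or single `bf_node`).
#' @return The rewritten representation (same class as the input).
#' @export
remove_redundant_ops <- function(rep) {
  if (inherits(rep, "bf_node")) return(simplify_node(rep))
  representation(lapply(rep$trees, simplify_node))
}

simplify_node <- function(node) {
  if (length(node$children) > 0L) {
    node$children <- lapply(node$children, simplify_node)
  }
  k <- node$kind
  if (k == "NOT" && node$children[[1L]]$kind == "NOT") {
    return(node$children[[1L]]$children[[1L]])
  }
  if (k %in% c("AND", "OR")) {
    ops <- flatten_chain(node, k)
    uniq <- list()
    for (op in ops) {
      dup <- any(vapply(uniq, function(u) identical(strip_attrs(u), strip_attrs(op)),
                        logical(1L)))
      if (!dup) uniq[[length(uniq) + 1L]] <- op
    }
    if (length(uniq) == 1L) return(uniq[[1L]])
    out <- uniq[[1L]]
    for (i in seq(2L, length(uniq))) {
      out <- new_node(k, children = list(out, uniq[[i]]))
    }
    return(out)
  }
  node
}

flatten_chain <- function(node, kind) {
  if (node$kind != kind) return(list(node))
  c(flatten_chain(node$children[[1L]], kind),
    flatten_chain(node$children[[2L]], kind))
}

strip_attrs <- function(node) {
  attributes(node) <- list(class = class(node), names = names(node))
  node$children <- lapply(node$children, strip_attrs)
  node
}

#' Post-run simplification of a fitted model
#'
#' Hill-climbing bloat removal applied after the search: (1) exact
#' redundant-operation rewrites; (2) iterated correlation deletion, accepted
#' unconditionally when the pruned pair is perfectly correlated
#' (`|r| = 1` within 1e-12) and otherwise only if, after refitting the
#' coefficients, the mean absolute change in predicted probability on the
#' training data relative to the *original* model stays within `tolerance`
#' (so the drift bound is cumulative across accepted steps); (3) iterated
#' uniform subtree deletion, replacing a uniformly chosen internal subtree
#' with a type-correct leaf drawn from inside it, accepted under the same
#' cumulative rule, with a proposal budget of `5 * size` to bound runtime.
#' Coefficients are refit after every accepted change. With `tolerance = 0`
#' only exact-equivalence simplifications survive.
#'
#' @param model a fitted [bf_model()].
#' @param ds the training [bf_dataset()] the model was fit on.
#' @param tolerance mean |delta probability| budget (default 0.005).
#' @param weights per-case weights used for refits (default balanced).
#' @param ridge ridge penalty for refits.
#' @return A simplified [bf_model()]; never larger than the input, and mean
#'   |p_final - p_original| on `ds` is at most `tolerance`.
#' @export
simplify_post_run <- function(model, ds, tolerance = 0.005, weights = NULL,
                              ridge = 1e-6) {
  labels <- ds$labels
  if (is.null(weights)) weights <- class_weights(labels)
  p0 <- predict_proba(model, ds)

  refit <- function(rep) {
    phi <- evaluate_representation(rep, ds)
    fit <- fit_logistic(phi, labels, weights, ridge = ridge)
    bf_model(rep, fit$beta, fit$intercept, model$feature_names,
             model$decision_threshold, model$meta)
  }
  drift <- function(m) mean(abs(predict_proba(m, ds) - p0))

  # Phase 1: exact rewrites (prediction-preserving before the refit, and the
  # refit of a semantically identical feature matrix is deterministic).
  cur <- suppressWarnings(refit(remove_redundant_ops(model$representation)))

  # Phase 2: correlation deletion
  while (rep_p(cur$representation) >= 2L) {
    pruned <- prune_correlated(cur$representation, ds, labels)
    exact <- attr(pruned, "pair_correlation") >= 1 - 1e-12
    cand <- suppressWarnings(refit(pruned))
    if (exact || drift(cand) <= tolerance) {
      cur <- cand
    } else {
      break
    }
  }

  # Phase 3: uniform subtree deletion under a fixed proposal budget; at
  # tolerance 0 only the exact phases above apply, so the phase is skipped.
  if (tolerance > 0) {
    budget <- 5L * rep_size(cur$representation)
    for (k in seq_len(max(budget, 0L))) {
      prop <- propose_subtree_deletion(cur$representation)
      if (is.null(prop)) break
      cand <- suppressWarnings(refit(prop))
      if (drift(cand) <= tolerance) cur <- cand
    }
  }

  stopifnot(rep_size(cur$representation) <= rep_size(model$representation))
  cur
}

# Replace a uniformly chosen internal subtree with a type-correct leaf taken
# from inside it (a comparison for Boolean subtrees, a feature leaf for
# numeric ones). Returns NULL when no internal node exists. Strictly
# size-decreasing when it applies. Uses the caller's RNG stream.
propose_subtree_deletion <- function(rep) {
  locs <- list()
  for (ti in seq_along(rep$trees)) {
    paths <- internal_paths(rep$trees[[ti]], integer(0))
    for (pth in paths) locs[[length(locs) + 1L]] <- list(tree = ti, path = pth)
  }
  if (length(locs) == 0L) return(NULL)
  pick <- locs[[sample.int(length(locs), 1L)]]
  tree <- rep$trees[[pick$tree]]
  sub <- node_at(tree, pick$path)
  leaf_kinds <- if (node_type(sub) == "bool") CMP_OPS else "FEATURE"
  leaves <- collect_nodes(sub, leaf_kinds)
  if (length(leaves) == 0L) return(NULL)
  leaf <- leaves[[sample.int(length(leaves), 1L)]]
  rep$trees[[pick$tree]] <- replace_at(tree, pick$path, leaf)
  rep
}

# Paths (child-index vectors) to internal nodes, i.e. NOT/AND/OR/arithmetic.
internal_paths <- function(node, path) {
  out <- list()
  if (length(node$children) > 0L) {
    out[[1L]] <- path
    for (i in seq_along(node$children)) {
      out <- c(out, internal_paths(node$children[[i]], c(path, i)))
    }
  }
  out
}

node_at <- function(node, path) {
  for (i in path) node <- node$children[[i]]
  node
}

replace_at <- function(node, path, new) {
  if (length(path) == 0L) return(new)
  node$children[[path[1L]]] <- replace_at(node$children[[path[1L]]],
                                          path[-1L], new)
  node
}

collect_nodes <- function(node, kinds) {
  out <- if (node$kind %in% kinds) list(node) else list()
  for (ch in node$children) out <- c(out, collect_nodes(ch, kinds))
  out
}
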