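#' Typed Boolean expression trees
#'
#' Candidate features are expression trees over the operator set
#' `{<, >, AND, OR, NOT}` plus bare feature leaves. Comparisons are
#' leaf-level: an `LT`/`GT` node references a raw input column directly and
#' carries a learned threshold in that column's units, so every comparison in
#' a model reads as `feature > theta` in interpretable raw units. `NOT` takes
#' one Boolean child; `AND`/`OR` take two. An optional arithmetic operator set
#' (`ADD`, `SUB`, `MUL`, `DIV`) is available for ablation experiments that
#' emulate unrestricted symbolic regression; it is off by default.
#'
#' Boolean node outputs are encoded 0/1 when evaluated, so they enter the
#' logistic layer as indicator columns.
#'
#' @name expression-trees
NULL

BOOL_OPS <- c("AND", "OR", "NOT")
CMP_OPS <- c("LT", "GT")
ARITH_OPS <- c("ADD", "SUB", "MUL", "DIV")
ALL_KINDS <- c("FEATURE", CMP_OPS, BOOL_OPS, ARITH_OPS)

new_node <- function(kind, feature = NA_integer_, threshold = NA_real_,
                     children = list()) {
  structure(list(kind = kind, feature = as.integer(feature),
                 threshold = threshold, children = children),
            class = "bf_node")
}

#' Node constructors
#'
#' `node_feature(j)` is a raw-column leaf; `node_gt(j, theta)` /
#' `node_lt(j, theta)` are thresholded comparisons of column `j` against
#' `theta` (strict `>` and `<`); `node_and`, `node_or`, `node_not` combine
#' Boolean subtrees; `node_arith(kind, a, b)` builds an arithmetic node for
#' the unrestricted operator set (division is protected: x/0 evaluates to 1).
#'
#' @param j integer column index of a raw input feature.
#' @param theta comparison threshold, in the feature's units.
#' @param a,b child nodes.
#' @param kind one of `"ADD"`, `"SUB"`, `"MUL"`, `"DIV"`.
#' @return A `bf_node`.
#' @export
node_feature <- function(j) new_node("FEATURE", feature = j)

#' @rdname node_feature
#' @export
node_gt <- function(j, theta) new_node("GT", feature = j, threshold = theta)

#' @rdname node_feature
#' @export
node_lt <- function(j, theta) new_node("LT", feature = j, threshold = theta)

#' @rdname node_feature
#' @export
node_and <- function(a, b) new_node("AND", children = list(a, b))

#' @rdname node_feature
#' @export
node_or <- function(a, b) new_node("OR", children = list(a, b))

#' @rdname node_feature
#' @export
node_not <- function(a) new_node("NOT", children = list(a))

#' @rdname node_feature
#' @export
node_arith <- function(kind, a, b) {
  stopifnot(kind %in% ARITH_OPS)
  new_node(kind, children = list(a, b))
}

# Output type of a node: "bool" or "num".
node_type <- function(node) {
  switch(node$kind,
         FEATURE = "num",
         LT = "bool", GT = "bool",
         AND = "bool", OR = "bool", NOT = "bool",
         ADD = "num", SUB = "num", MUL = "num", DIV = "num",
         stop("unknown node kind: ", node$kind))
}

node_depth <- function(node) {
  if (length(node$children) == 0L) return(1L)
  1L + max(vapply(node$children, node_depth, integer(1L)))
}

#' Feature representation: an ordered list of expression trees
#'
#' A representation Phi(x) is an ordered list of `p` root nodes; evaluating
#' it on a dataset yields an N x p derived-feature matrix feeding the
#' logistic layer. Roots must produce Boolean output or be bare raw-feature
#' leaves (arithmetic roots are admitted only under the unrestricted
#' operator set).
#'
#' @param trees list of `bf_node` roots.
#' @return An object of class `bf_representation`.
#' @export
representation <- function(trees) {
  if (inherits(trees, "bf_node")) trees <- list(trees)
  stopifnot(length(trees) >= 1L)
  structure(list(trees = trees), class = "bf_representation")
}

rep_p <- function(rep) length(rep$trees)

#' Evaluate a representation into derived features
#'
#' @param rep a [representation()].
#' @param ds a [bf_dataset()] or numeric matrix.
#' @return N x p numeric matrix; Boolean roots yield 0/1 columns, bare
#'   feature roots copy the raw column.
#' @export
evaluate_representation <- function(rep, ds) {
  x <- if (inherits(ds, "bf_dataset")) ds$features else as.matrix(ds)
  out <- vapply(rep$trees, function(tr) eval_node(tr, x), numeric(nrow(x)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(x))
  out
}

eval_node <- function(node, x) {
  k <- node$kind
  if (k == "FEATURE") {
    if (node$feature < 1L || node$feature > ncol(x)) {
      stop("feature index out of range: ", node$feature)
    }
    return(x[, node$feature])
  }
  if (k == "GT" || k == "LT") {
    if (node$feature < 1L || node$feature > ncol(x)) {
      stop("feature index out of range: ", node$feature)
    }
    col <- x[, node$feature]
    return(as.numeric(if (k == "GT") col > node$threshold else col < node$threshold))
  }
  if (k == "NOT") return(1 - eval_node(node$children[[1L]], x))
  a <- eval_node(node$children[[1L]], x)
  b <- eval_node(node$children[[2L]], x)
  switch(k,
         AND = a * b,
         OR = pmax(a, b),
         ADD = a + b,
         SUB = a - b,
         MUL = a * b,
         DIV = {
           # protected division: near-zero denominators yield 1, which also
           # bounds the magnitude of derived features
           r <- a / b
           r[abs(b) < 1e-6] <- 1
           r
         },
         stop("unknown node kind: ", k))
}

#' Model size: split nodes plus leaves
#'
#' Size counts, over all trees, the comparison/logical/arithmetic nodes plus
#' the raw-feature leaves: a thresholded comparison contributes one split
#' node plus one feature leaf (2), a bare feature leaf contributes 1, and
#' each `NOT`/`AND`/`OR` (or arithmetic) node contributes 1. Thresholds are
#' node attributes and are not counted. This is the "total number of split
#' nodes and leaf nodes" accounting used for tree-based models.
#'
#' @param rep a [representation()] or single `bf_node`.
#' @return integer size.
#' @export
rep_size <- function(rep) {
  if (inherits(rep, "bf_node")) return(node_size(rep))
  sum(vapply(rep$trees, node_size, integer(1L)))
}

node_size <- function(node) {
  switch(node$kind,
         FEATURE = 1L,
         LT = 2L, GT = 2L,
         1L + sum(vapply(node$children, node_size, integer(1L))))
}

#' Default operator cost table
#'
#' Costs used by [rep_complexity()]: raw feature leaves cost 1, `NOT` costs
#' 1, comparisons and binary logical operators cost 2, arithmetic operators
#' cost 3 (so the unrestricted set is penalized consistently with its lower
#' interpretability). All entries are configurable.
#'
#' @return named numeric vector of per-operator weights.
#' @export
default_op_weights <- function() {
  c(FEATURE = 1, LT = 2, GT = 2, AND = 2, OR = 2, NOT = 1,
    ADD = 3, SUB = 3, MUL = 3, DIV = 3)
}

#' Representation complexity
#'
#' Recursively weighted node count: a leaf costs `w_FEATURE`; an operator
#' node costs `w_op * (1 + sum of child complexities)`. A comparison node
#' carries an implicit feature leaf as its operand, so with `w_GT = 2`,
#' `w_FEATURE = 1`, `c(GT) = 2 * (1 + 1) = 4`. With all weights equal to 1
#' this reduces to a node count; adding any node strictly increases the
#' total, which is what makes complexity a usable minimization objective.
#'
#' @param rep a [representation()] or single `bf_node`.
#' @param weights named operator-cost vector, see [default_op_weights()].
#' @return numeric complexity.
#' @export
rep_complexity <- function(rep, weights = default_op_weights()) {
  if (inherits(rep, "bf_node")) return(node_complexity(rep, weights))
  sum(vapply(rep$trees, node_complexity, numeric(1L), weights = weights))
}

node_complexity <- function(node, weights) {
  k <- node$kind
  if (!k %in% names(weights)) stop("no complexity weight for operator ", k)
  w <- weights[[k]]
  if (w <= 0) stop("operator weights must be positive")
  if (k == "FEATURE") return(w)
  if (k %in% CMP_OPS) {
    if (!"FEATURE" %in% names(weights)) stop("no complexity weight for operator FEATURE")
    return(w * (1 + weights[["FEATURE"]]))
  }
  w * (1 + sum(vapply(node$children, node_complexity, numeric(1L),
                      weights = weights)))
}

#' Learn a comparison threshold by Gini impurity
#'
#' Scans the midpoints between consecutive sorted distinct values of a
#' column and returns the one minimizing the weighted Gini impurity of the
#' induced split `{x > theta}` vs `{x <= theta}`, exactly as a CART decision
#' stump would. Ties are broken toward the smallest threshold, so the
#' learned cut always lies strictly between two observed values.
#'
#' @param column numeric vector with at least two distinct values.
#' @param labels 0/1 vector.
#' @param weights nonnegative case weights (default unit).
#' @return the threshold `theta`.
#' @export
learn_threshold <- function(column, labels, weights = NULL) {
  n <- length(column)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(labels) == n, length(weights) == n)
  ord <- order(column)
  x <- column[ord]
  w <- weights[ord]
  wy <- w * labels[ord]
  # candidate boundaries: positions where the next value differs
  boundary <- which(diff(x) > 0)
  if (length(boundary) == 0L) {
    stop("constant column: no threshold separates any pair of values")
  }
  cw <- cumsum(w)
  cwy <- cumsum(wy)
  W <- cw[n]
  WY <- cwy[n]
  wl <- cw[boundary]            # weight mass in {x <= theta}
  wyl <- cwy[boundary]
  wr <- W - wl
  wyr <- WY - wyl
  gini_l <- 1 - (wyl / wl)^2 - ((wl - wyl) / wl)^2
  gini_r <- 1 - (wyr / wr)^2 - ((wr - wyr) / wr)^2
  impurity <- (wl * gini_l + wr * gini_r) / W
  best <- boundary[which.min(impurity)]   # which.min takes the first = smallest theta
  (x[best] + x[best + 1L]) / 2
}

# All candidate midpoints of a column (used by the threshold point mutation).
threshold_candidates <- function(column) {
  v <- sort(unique(column))
  if (length(v) < 2L) return(numeric(0))
  (v[-length(v)] + v[-1L]) / 2
}

#' Validate a representation against structural invariants
#'
#' Checks node arities, operator typing (logical operators take Boolean
#' children), feature-index ranges, the dimensionality bound `p <= max_dim`,
#' the depth bound, and (unless `allow_arith`) the Boolean-only operator
#' restriction. Violations are returned, not raised.
#'
#' @param rep a [representation()].
#' @param d number of raw input columns.
#' @param max_dim maximum number of trees.
#' @param max_depth maximum tree depth (a leaf has depth 1).
#' @param allow_arith admit arithmetic operators and numeric roots.
#' @return list with `ok` (logical) and `violations` (character vector).
#' @export
validate_representation <- function(rep, d, max_dim = 10L, max_depth = 3L,
                                    allow_arith = FALSE) {
  v <- character(0)
  p <- rep_p(rep)
  if (p < 1L || p > max_dim) {
    v <- c(v, sprintf("dimensionality p=%d outside [1, %d]", p, max_dim))
  }
  for (i in seq_len(p)) {
    tr <- rep$trees[[i]]
    v <- c(v, check_node(tr, d, allow_arith, prefix = sprintf("tree %d", i)))
    if (node_depth(tr) > max_depth) {
      v <- c(v, sprintf("tree %d: depth %d exceeds max_depth %d",
                        i, node_depth(tr), max_depth))
    }
    if (!allow_arith && node_type(tr) == "num" && tr$kind != "FEATURE") {
      v <- c(v, sprintf("tree %d: numeric root of kind %s not allowed", i, tr$kind))
    }
  }
  list(ok = length(v) == 0L, violations = v)
}

check_node <- function(node, d, allow_arith, prefix) {
  v <- character(0)
  k <- node$kind
  if (!k %in% ALL_KINDS) return(sprintf("%s: unknown kind %s", prefix, k))
  if (!allow_arith && k %in% ARITH_OPS) {
    v <- c(v, sprintf("%s: arithmetic operator %s not in the Boolean set", prefix, k))
  }
  expected_arity <- switch(k, FEATURE = 0L, LT = 0L, GT = 0L, NOT = 1L, 2L)
  if (length(node$children) != expected_arity) {
    v <- c(v, sprintf("%s: %s has %d children, expected %d",
                      prefix, k, length(node$children), expected_arity))
  }
  if (k %in% c("FEATURE", CMP_OPS)) {
    if (is.na(node$feature) || node$feature < 1L || node$feature > d) {
      v <- c(v, sprintf("%s: feature index %s out of range 1..%d",
                        prefix, node$feature, d))
    }
    if (k %in% CMP_OPS && (is.na(node$threshold) || !is.finite(node$threshold))) {
      v <- c(v, sprintf("%s: %s threshold missing or non-finite", prefix, k))
    }
  }
  if (k %in% BOOL_OPS) {
    for (ch in node$children) {
      ty <- tryCatch(node_type(ch), error = function(e) "unknown")
      if (ty != "bool") {
        v <- c(v, sprintf("%s: %s child of kind %s is not Boolean", prefix, k, ch$kind))
      }
    }
  }
  for (ch in node$children) {
    v <- c(v, check_node(ch, d, allow_arith, prefix))
  }
  v
}

#' Human-readable rule text
#'
#' Formats a node or representation the way a clinician reads the model
#' report: one line per derived feature, comparisons in raw units, e.g.
#' `"# enc 3+ meds, sum" > 1 AND "SBP, max" > 140`.
#'
#' @param node a `bf_node`.
#' @param feature_names character vector of raw column names.
#' @param digits significant digits for thresholds.
#' @return character scalar.
#' @export
format_node <- function(node, feature_names, digits = 4) {
  fmt <- function(nd) {
    k <- nd$kind
    nm <- function(j) {
      n <- feature_names[j]
      if (grepl("[^A-Za-z0-9_.]", n)) paste0("\"", n, "\"") else n
    }
    switch(k,
           FEATURE = nm(nd$feature),
           GT = paste0(nm(nd$feature), " > ", signif(nd$threshold, digits)),
           LT = paste0(nm(nd$feature), " < ", signif(nd$threshold, digits)),
           NOT = paste0("NOT (", fmt(nd$children[[1L]]), ")"),
           AND = paste0("(", fmt(nd$children[[1L]]), " AND ",
                        fmt(nd$children[[2L]]), ")"),
           OR = paste0("(", fmt(nd$children[[1L]]), " OR ",
                       fmt(nd$children[[2L]]), ")"),
           ADD = paste0("(", fmt(nd$children[[1L]]), " + ", fmt(nd$children[[2L]]), ")"),
           SUB = paste0("(", fmt(nd$children[[1L]]), " - ", fmt(nd$children[[2L]]), ")"),
           MUL = paste0("(", fmt(nd$children[[1L]]), " * ", fmt(nd$children[[2L]]), ")"),
           DIV = paste0("(", fmt(nd$children[[1L]]), " / ", fmt(nd$children[[2L]]), ")"))
  }
  fmt(node)
}

#' @export
print.bf_representation <- function(x, ...) {
  nms <- attr(x, "feature_names")
  if (is.null(nms)) nms <- paste0("f", seq_len(1e6))
  cat(sprintf("<bf_representation> p = %d, size = %d\n", rep_p(x), rep_size(x)))
  for (tr in x$trees) cat("  ", format_node(tr, nms), "\n", sep = "")
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

node_to_list <- function(node, feature_names) {
  out <- list(kind = node$kind)
  if (node$kind %in% c("FEATURE", CMP_OPS)) {
    out$feature_name <- feature_names[node$feature]
  }
  if (node$kind %in% CMP_OPS) out$threshold <- node$threshold
  if (length(node$children) > 0L) {
    out$children <- lapply(node$children, node_to_list, feature_names = feature_names)
  }
  out
}

node_from_list <- function(lst, feature_names) {
  kind <- lst$kind
  if (kind %in% c("FEATURE", CMP_OPS)) {
    j <- match(lst$feature_name, feature_names)
    if (is.na(j)) stop("unknown feature name in serialized tree: ", lst$feature_name)
    if (kind == "FEATURE") return(node_feature(j))
    return(new_node(kind, feature = j, threshold = lst$threshold))
  }
  children <- lapply(lst$children, node_from_list, feature_names = feature_names)
  new_node(kind, children = children)
}

rep_to_list <- function(rep, feature_names) {
  lapply(rep$trees, node_to_list, feature_names = feature_names)
}

rep_from_list <- function(lst, feature_names) {
  representation(lapply(lst, node_from_list, feature_names = feature_names))
}
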