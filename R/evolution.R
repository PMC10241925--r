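#' Search configuration
#'
#' Bundles every tunable of the evolutionary search. Defaults follow the
#' interpretable-phenotyping setup: population 100, 100 generations, at most
#' 10 derived features of depth at most 3, the Boolean operator set, and
#' variation rates insertion .2 / deletion .2 / point .3 / crossover .2 /
#' correlation-deletion .1 (summing to 1). `epsilon_mode` selects the
#' epsilon-lexicase tolerance: `"mad"` uses the per-case median absolute
#' deviation of losses over the surviving pool, `"zero"` is strict lexicase.
#' `allow_arith = TRUE` opens the arithmetic operator set (ablation
#' experiments emulating unrestricted symbolic regression); `simplify`
#' toggles post-run simplification of the archive.
#'
#' @param pop_size population size (>= 4).
#' @param generations number of generations.
#' @param max_dim maximum number of derived features per candidate.
#' @param max_depth maximum expression-tree depth.
#' @param operator_set character vector of operator kinds available to the
#'   search. The default is the Boolean set `c("LT", "GT", "AND", "OR",
#'   "NOT")`; `c("ADD", "SUB", "MUL", "DIV")` emulates a conventional
#'   symbolic-regression search over continuous expressions (no learned
#'   thresholds), used as the unrestricted comparator in ablations; the
#'   union of both is also allowed. Comparisons require `LT` and `GT`
#'   together.
#' @param rates named numeric vector of variation probabilities
#'   (`insertion`, `deletion`, `point`, `crossover`, `correlation_deletion`),
#'   summing to 1.
#' @param epsilon_mode `"mad"` or `"zero"`.
#' @param seed integer master seed; every random draw in a run flows from it.
#' @param simplify_tolerance mean |delta p| budget for post-run
#'   simplification.
#' @param validation_frac internal held-out fraction (default 0.20).
#' @param ridge ridge penalty of the logistic layer.
#' @param op_weights operator-cost table for complexity.
#' @param allow_arith admit arithmetic operators.
#' @param simplify apply post-run simplification to the archive.
#' @return list of class `bf_config`.
#' @export
evolution_config <- function(pop_size = 100L, generations = 100L,
                             max_dim = 10L, max_depth = 3L,
                             operator_set = c("LT", "GT", "AND", "OR", "NOT"),
                             rates = c(insertion = 0.2, deletion = 0.2,
                                       point = 0.3, crossover = 0.2,
                                       correlation_deletion = 0.1),
                             epsilon_mode = c("mad", "zero"), seed = 1L,
                             simplify_tolerance = 0.005,
                             validation_frac = 0.20, ridge = 1e-6,
                             op_weights = default_op_weights(),
                             simplify = TRUE) {
  epsilon_mode <- match.arg(epsilon_mode)
  if (pop_size < 4L) stop("pop_size must be >= 4")
  if (max_dim < 1L) stop("max_dim must be >= 1")
  bad_ops <- setdiff(operator_set, setdiff(ALL_KINDS, "FEATURE"))
  if (length(bad_ops) > 0L || length(operator_set) == 0L) {
    stop("operator_set must be a non-empty subset of ",
         paste(setdiff(ALL_KINDS, "FEATURE"), collapse = ", "))
  }
  if (xor("LT" %in% operator_set, "GT" %in% operator_set)) {
    stop("comparisons require both LT and GT in the operator set")
  }
  if (any(BOOL_OPS %in% operator_set) && !"GT" %in% operator_set) {
    stop("logical operators need comparison leaves: include LT and GT")
  }
  if (any(rates < 0) || abs(sum(rates) - 1) > 1e-9) {
    stop("variation rates must be nonnegative and sum to 1")
  }
  needed <- c("insertion", "deletion", "point", "crossover", "correlation_deletion")
  if (!all(needed %in% names(rates))) {
    stop("rates must name: ", paste(needed, collapse = ", "))
  }
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 max_dim = as.integer(max_dim),
                 max_depth = as.integer(max_depth),
                 operator_set = operator_set,
                 rates = rates, epsilon_mode = epsilon_mode,
                 seed = as.integer(seed),
                 simplify_tolerance = simplify_tolerance,
                 validation_frac = validation_frac, ridge = ridge,
                 op_weights = op_weights,
                 allow_arith = any(ARITH_OPS %in% operator_set),
                 simplify = simplify),
            class = "bf_config")
}

#' Initial feature weighting by univariate logistic strength
#'
#' Each input column is standardized and fit alone in a balanced-weight
#' logistic regression; the absolute coefficient magnitudes, normalized to
#' sum to 1, become the sampling probabilities used to seed and mutate
#' candidates. Strong univariate predictors are therefore sampled more
#' often, biasing the initial population toward informative low-dimensional
#' linear models.
#'
#' @param ds preprocessed [bf_dataset()].
#' @return numeric vector of d nonnegative weights summing to 1.
#' @export
univariate_feature_weights <- function(ds) {
  x <- ds$features
  y <- ds$labels
  w <- class_weights(y)
  coefs <- vapply(seq_len(ncol(x)), function(j) {
    col <- x[, j]
    s <- stats::sd(col)
    if (s == 0) stop("zero-variance feature '", colnames(x)[j],
                     "' reached weighting; run preprocess() first")
    z <- (col - mean(col)) / s
    fit <- suppressWarnings(fit_logistic(matrix(z, ncol = 1L), y, w))
    abs(fit$beta)
  }, numeric(1L))
  if (sum(coefs) == 0) return(rep(1 / ncol(x), ncol(x)))
  coefs / sum(coefs)
}

#' Initialize the candidate population
#'
#' Half the population are "linear seeds": 1..max_dim bare feature leaves
#' sampled without replacement in proportion to the univariate weights.
#' The other half are random typed trees of depth at most `max_depth`, whose
#' feature leaves are sampled by the same weights and whose comparison
#' thresholds are learned by Gini impurity on the training labels. Every
#' candidate passes [validate_representation()]. Draws come from the
#' caller's RNG stream.
#'
#' @param ds training [bf_dataset()].
#' @param cfg an [evolution_config()].
#' @param feature_weights output of [univariate_feature_weights()].
#' @return list of [representation()]s of length `cfg$pop_size`.
#' @export
init_population <- function(ds, cfg, feature_weights = NULL) {
  if (is.null(feature_weights)) feature_weights <- univariate_feature_weights(ds)
  d <- ncol(ds$features)
  w_cases <- class_weights(ds$labels)
  n_linear <- ceiling(cfg$pop_size / 2)
  pop <- vector("list", cfg$pop_size)
  for (i in seq_len(cfg$pop_size)) {
    if (i <= n_linear) {
      k <- sample.int(min(cfg$max_dim, d), 1L)
      feats <- sample_features(d, k, feature_weights)
      pop[[i]] <- representation(lapply(feats, node_feature))
    } else {
      p <- sample.int(cfg$max_dim, 1L)
      trees <- lapply(seq_len(p), function(t_) {
        random_tree(ds, cfg, feature_weights, w_cases,
                    depth = sample.int(cfg$max_depth, 1L))
      })
      pop[[i]] <- representation(trees)
    }
    chk <- validate_representation(pop[[i]], d, cfg$max_dim, cfg$max_depth,
                                   cfg$allow_arith)
    stopifnot(chk$ok)
  }
  pop
}

# Weighted sampling without replacement; tolerates zero weights by flooring.
sample_features <- function(d, k, weights) {
  pr <- weights + 1e-12
  sample.int(d, size = min(k, d), replace = FALSE, prob = pr)
}

# A random typed tree of depth <= `depth`, drawn from cfg$operator_set.
# Boolean grammar: comparison leaves at the frontier, NOT/AND/OR above;
# an arithmetic grammar grows feature leaves under ADD/SUB/MUL/DIV.
random_tree <- function(ds, cfg, feature_weights, w_cases, depth,
                        want = NULL) {
  has_cmp <- "GT" %in% cfg$operator_set
  arith <- intersect(ARITH_OPS, cfg$operator_set)
  if (is.null(want)) {
    want <- if (!has_cmp) "num"
    else if (length(arith) > 0L && stats::runif(1) < 0.5) "num"
    else "bool"
  }
  d <- ncol(ds$features)
  if (want == "num") {
    if (depth <= 1L || length(arith) == 0L || stats::runif(1) < 0.3) {
      return(node_feature(sample_features(d, 1L, feature_weights)))
    }
    kind <- sample(arith, 1L)
    return(node_arith(kind,
                      random_tree(ds, cfg, feature_weights, w_cases, depth - 1L, "num"),
                      random_tree(ds, cfg, feature_weights, w_cases, depth - 1L, "num")))
  }
  logic <- intersect(BOOL_OPS, cfg$operator_set)
  if (depth <= 1L || length(logic) == 0L || stats::runif(1) < 0.35) {
    return(random_comparison(ds, feature_weights, w_cases))
  }
  kind <- sample(logic, 1L)
  if (kind == "NOT") {
    return(node_not(random_tree(ds, cfg, feature_weights, w_cases, depth - 1L, "bool")))
  }
  new_node(kind, children = list(
    random_tree(ds, cfg, feature_weights, w_cases, depth - 1L, "bool"),
    random_tree(ds, cfg, feature_weights, w_cases, depth - 1L, "bool")))
}

# A fresh comparison leaf: feature sampled by weight, direction at random,
# threshold learned by Gini impurity; resamples if a column is degenerate.
random_comparison <- function(ds, feature_weights, w_cases, tries = 10L) {
  d <- ncol(ds$features)
  for (t_ in seq_len(tries)) {
    j <- sample_features(d, 1L, feature_weights)
    theta <- tryCatch(learn_threshold(ds$features[, j], ds$labels, w_cases),
                      error = function(e) NULL)
    if (!is.null(theta)) {
      return(if (stats::runif(1) < 0.5) node_gt(j, theta) else node_lt(j, theta))
    }
  }
  stop("could not sample a non-degenerate comparison; preprocess the data")
}

#' Epsilon-lexicase parent selection
#'
#' For each parent slot the training cases are shuffled and the candidate
#' pool is filtered case by case: only candidates whose loss on the case is
#' within `epsilon` of the pool's best survive, where `epsilon` is the
#' median absolute deviation of that case's losses over the current pool
#' (`mad` mode) or zero. Filtering stops when one candidate survives or all
#' cases are used; the parent is drawn uniformly from the survivors. This
#' preserves specialists that excel on rare or difficult subjects even when
#' their average loss is mediocre.
#'
#' @param loss_matrix candidates x cases matrix of per-case losses (finite).
#' @param n_parents number of parents to select.
#' @param epsilon_mode `"mad"` or `"zero"`.
#' @return integer vector of selected candidate indices.
#' @export
epsilon_lexicase_select <- function(loss_matrix, n_parents,
                                    epsilon_mode = "mad") {
  n_cand <- nrow(loss_matrix)
  n_case <- ncol(loss_matrix)
  if (is.null(n_cand) || n_cand == 0L) stop("empty population")
  # cases on which the whole population agrees can never shrink any pool
  # (every candidate is within any epsilon of the elite), so restricting the
  # shuffle to informative cases leaves the selection distribution unchanged
  informative <- which(apply(loss_matrix, 2L, function(col) {
    max(col) > min(col)
  }))
  out <- integer(n_parents)
  for (k in seq_len(n_parents)) {
    pool <- seq_len(n_cand)
    if (length(informative) > 0L) {
      for (case in sample(informative)) {
        col <- loss_matrix[pool, case]
        mn <- min(col)
        if (max(col) == mn) next    # uninformative for this sub-pool
        eps <- if (epsilon_mode == "mad") median_abs_dev(col) else 0
        pool <- pool[col <= mn + eps]
        if (length(pool) == 1L) break
      }
    }
    out[k] <- if (length(pool) == 1L) pool else pool[sample.int(length(pool), 1L)]
  }
  out
}

# Unscaled median absolute deviation, the lexicase convention.
median_abs_dev <- function(x) qmedian(abs(x - qmedian(x)))

# Dispatch-free median via partial sort.
qmedian <- function(x) {
  n <- length(x)
  h <- (n + 1L) %/% 2L
  if (n %% 2L == 1L) {
    sort.int(x, partial = h)[h]
  } else {
    s <- sort.int(x, partial = c(h, h + 1L))
    (s[h] + s[h + 1L]) / 2
  }
}

#' Variation: produce offspring from selected parents
#'
#' Each offspring is the result of exactly one variation applied to a copy
#' of its parent: insertion (append a random tree while `p < max_dim`,
#' otherwise wrap a Boolean root in `NOT` or join it with a fresh comparison
#' under `AND`/`OR`), deletion (drop one tree while `p > 1`, otherwise
#' replace an internal subtree by a type-correct leaf), point mutation
#' (`AND <-> OR` swap, `LT <-> GT` toggle with the threshold re-learned,
#' feature-leaf resampling by the univariate weights, or a threshold step to
#' an adjacent Gini-candidate midpoint), crossover (exchange a whole tree or
#' a type-compatible subtree with another parent), or correlation deletion
#' ([prune_correlated()]). When no type-correct variation applies, the
#' parent is copied unchanged and the event counted in the `fallbacks`
#' attribute. Every offspring passes [validate_representation()].
#'
#' @param parents list of [representation()]s.
#' @param cfg an [evolution_config()].
#' @param ds training [bf_dataset()] (thresholds, weights, correlations).
#' @param feature_weights univariate sampling weights.
#' @return list of offspring representations (same length as `parents`).
#' @export
vary <- function(parents, cfg, ds, feature_weights = NULL) {
  if (is.null(feature_weights)) feature_weights <- univariate_feature_weights(ds)
  d <- ncol(ds$features)
  w_cases <- class_weights(ds$labels)
  ops <- names(cfg$rates)
  fallbacks <- 0L
  offspring <- vector("list", length(parents))
  for (i in seq_along(parents)) {
    op <- sample(ops, 1L, prob = cfg$rates)
    parent <- parents[[i]]
    child <- switch(op,
      insertion = vary_insert(parent, cfg, ds, feature_weights, w_cases),
      deletion = vary_delete(parent),
      point = vary_point(parent, cfg, ds, feature_weights, w_cases),
      crossover = {
        if (length(parents) >= 2L) {
          j <- sample.int(length(parents), 1L)
          if (j == i) j <- (i %% length(parents)) + 1L
          vary_crossover(parent, parents[[j]])
        } else NULL
      },
      correlation_deletion = {
        if (rep_p(parent) >= 2L) {
          suppressWarnings(prune_correlated(parent, ds, ds$labels))
        } else NULL
      })
    if (is.null(child)) {
      fallbacks <- fallbacks + 1L
      child <- parent
    }
    chk <- validate_representation(child, d, cfg$max_dim, cfg$max_depth,
                                   cfg$allow_arith)
    if (!chk$ok) {
      fallbacks <- fallbacks + 1L
      child <- parent
    }
    offspring[[i]] <- child
  }
  attr(offspring, "fallbacks") <- fallbacks
  offspring
}

vary_insert <- function(rep, cfg, ds, feature_weights, w_cases) {
  if (rep_p(rep) < cfg$max_dim) {
    tr <- random_tree(ds, cfg, feature_weights, w_cases,
                      depth = sample.int(cfg$max_depth, 1L))
    return(representation(c(rep$trees, list(tr))))
  }
  # at the dimensionality cap: grow one root instead
  ti <- sample.int(rep_p(rep), 1L)
  root <- rep$trees[[ti]]
  if (node_depth(root) + 1L > cfg$max_depth) return(NULL)
  wrapped <- if (node_type(root) == "bool") {
    logic <- intersect(BOOL_OPS, cfg$operator_set)
    if (length(logic) == 0L) return(NULL)
    kind <- sample(logic, 1L)
    if (kind == "NOT") node_not(root)
    else new_node(kind, children = list(root, random_comparison(ds, feature_weights,
                                                                w_cases)))
  } else {
    arith <- intersect(ARITH_OPS, cfg$operator_set)
    if (length(arith) == 0L) return(NULL)
    node_arith(sample(arith, 1L), root,
               node_feature(sample_features(ncol(ds$features), 1L,
                                            feature_weights)))
  }
  rep$trees[[ti]] <- wrapped
  rep
}

vary_delete <- function(rep) {
  if (rep_p(rep) > 1L) {
    drop <- sample.int(rep_p(rep), 1L)
    return(representation(rep$trees[-drop]))
  }
  propose_subtree_deletion(rep)  # NULL when the single tree is a leaf
}

vary_point <- function(rep, cfg, ds, feature_weights, w_cases) {
  # enumerate mutable node locations across all trees
  locs <- list()
  for (ti in seq_along(rep$trees)) {
    for (pth in all_paths(rep$trees[[ti]], integer(0))) {
      locs[[length(locs) + 1L]] <- list(tree = ti, path = pth)
    }
  }
  pick <- locs[[sample.int(length(locs), 1L)]]
  tree <- rep$trees[[pick$tree]]
  nd <- node_at(tree, pick$path)
  mutated <- mutate_node(nd, cfg, ds, feature_weights, w_cases)
  if (is.null(mutated)) return(NULL)
  rep$trees[[pick$tree]] <- replace_at(tree, pick$path, mutated)
  rep
}

all_paths <- function(node, path) {
  out <- list(path)
  for (i in seq_along(node$children)) {
    out <- c(out, all_paths(node$children[[i]], c(path, i)))
  }
  out
}

mutate_node <- function(nd, cfg, ds, feature_weights, w_cases) {
  k <- nd$kind
  ops <- cfg$operator_set
  if (k == "AND") {
    if (!"OR" %in% ops) return(NULL)
    return(new_node("OR", children = nd$children))
  }
  if (k == "OR") {
    if (!"AND" %in% ops) return(NULL)
    return(new_node("AND", children = nd$children))
  }
  if (k %in% ARITH_OPS) {
    alt <- setdiff(intersect(ARITH_OPS, ops), k)
    if (length(alt) == 0L) return(NULL)
    return(new_node(sample(alt, 1L), children = nd$children))
  }
  if (k == "FEATURE") {
    j <- sample_features(ncol(ds$features), 1L, feature_weights)
    return(node_feature(j))
  }
  if (k %in% CMP_OPS) {
    choice <- sample.int(3L, 1L)
    if (choice == 1L) {
      # toggle direction, threshold re-learned
      theta <- learn_threshold(ds$features[, nd$feature], ds$labels, w_cases)
      return(new_node(if (k == "GT") "LT" else "GT", feature = nd$feature,
                      threshold = theta))
    }
    if (choice == 2L) {
      # step to an adjacent candidate midpoint
      cands <- threshold_candidates(ds$features[, nd$feature])
      if (length(cands) < 2L) return(NULL)
      pos <- which.min(abs(cands - nd$threshold))
      adj <- pos + sample(c(-1L, 1L), 1L)
      adj <- min(max(adj, 1L), length(cands))
      return(new_node(k, feature = nd$feature, threshold = cands[adj]))
    }
    # resample the feature, re-learning the threshold
    cmp <- random_comparison(ds, feature_weights, w_cases)
    cmp$kind <- k
    return(cmp)
  }
  NULL  # NOT has no point mutation
}

vary_crossover <- function(a, b) {
  if (stats::runif(1) < 0.5) {
    # exchange one whole tree
    ti <- sample.int(rep_p(a), 1L)
    tj <- sample.int(rep_p(b), 1L)
    a$trees[[ti]] <- b$trees[[tj]]
    return(a)
  }
  # type-compatible subtree exchange
  ti <- sample.int(rep_p(a), 1L)
  pa <- all_paths(a$trees[[ti]], integer(0))
  pick_a <- pa[[sample.int(length(pa), 1L)]]
  ty <- node_type(node_at(a$trees[[ti]], pick_a))
  donors <- list()
  for (tj in seq_along(b$trees)) {
    for (pth in all_paths(b$trees[[tj]], integer(0))) {
      if (node_type(node_at(b$trees[[tj]], pth)) == ty) {
        donors[[length(donors) + 1L]] <- node_at(b$trees[[tj]], pth)
      }
    }
  }
  if (length(donors) == 0L) return(NULL)
  donor <- donors[[sample.int(length(donors), 1L)]]
  a$trees[[ti]] <- replace_at(a$trees[[ti]], pick_a, donor)
  a
}

#' NSGA-II survival
#'
#' Fast non-dominated sorting of the merged parent + offspring pool on the
#' two minimization objectives (balanced training loss, complexity), then
#' front-by-front filling of the next population; the last, partially taken
#' front is ordered by descending crowding distance with random tie-breaks.
#'
#' @param objectives n x 2 matrix (column 1 loss, column 2 complexity).
#' @param pop_size number of survivors.
#' @return integer indices of the survivors.
#' @export
nsga2_survive <- function(objectives, pop_size) {
  n <- nrow(objectives)
  if (pop_size >= n) return(seq_len(n))
  fronts <- nondominated_fronts(objectives)
  chosen <- integer(0)
  for (front in fronts) {
    if (length(chosen) + length(front) <= pop_size) {
      chosen <- c(chosen, front)
      if (length(chosen) == pop_size) break
    } else {
      need <- pop_size - length(chosen)
      cd <- crowding_distance(objectives[front, , drop = FALSE])
      ord <- order(-cd, stats::runif(length(front)))
      chosen <- c(chosen, front[ord[seq_len(need)]])
      break
    }
  }
  chosen
}

# Fronts by repeated extraction of the non-dominated set (O(n^2 m) per pass).
nondominated_fronts <- function(objectives) {
  remaining <- seq_len(nrow(objectives))
  fronts <- list()
  while (length(remaining) > 0L) {
    obj <- objectives[remaining, , drop = FALSE]
    nd <- nondominated_mask(obj)
    fronts[[length(fronts) + 1L]] <- remaining[nd]
    remaining <- remaining[!nd]
  }
  fronts
}

# TRUE for rows not dominated by any other row (both objectives minimized).
nondominated_mask <- function(obj) {
  n <- nrow(obj)
  mask <- rep(TRUE, n)
  for (i in seq_len(n)) {
    dominated <- obj[, 1L] <= obj[i, 1L] & obj[, 2L] <= obj[i, 2L] &
      (obj[, 1L] < obj[i, 1L] | obj[, 2L] < obj[i, 2L])
    if (any(dominated)) mask[i] <- FALSE
  }
  mask
}

crowding_distance <- function(obj) {
  n <- nrow(obj)
  cd <- numeric(n)
  for (m in seq_len(ncol(obj))) {
    ord <- order(obj[, m])
    rng <- obj[ord[n], m] - obj[ord[1L], m]
    cd[ord[c(1L, n)]] <- Inf
    if (n > 2L && rng > 0) {
      for (i in seq(2L, n - 1L)) {
        cd[ord[i]] <- cd[ord[i]] + (obj[ord[i + 1L], m] - obj[ord[i - 1L], m]) / rng
      }
    }
  }
  cd
}

# Fit the logistic layer for a candidate representation and record fitness.
# The Newton iteration cap is lowered during evolution: on separable Boolean
# features the unbounded fit creeps along a flat ridge-dominated direction,
# and 40 iterations already order candidates identically.
eval_candidate <- function(rep, train, w_cases, cfg) {
  phi <- evaluate_representation(rep, train)
  fit <- suppressWarnings(fit_logistic(phi, train$labels, w_cases,
                                       ridge = cfg$ridge, max_iter = 25L))
  pr <- plogis(drop(phi %*% fit$beta) + fit$intercept)
  bll <- balanced_log_loss(train$labels, pr, w_cases)
  list(rep = rep, beta = fit$beta, intercept = fit$intercept,
       loss = bll$aggregate, per_case = bll$per_case,
       complexity = rep_complexity(rep, cfg$op_weights),
       size = rep_size(rep))
}

# Merge candidates into the cumulative archive of non-dominated
# (loss, complexity) points, keeping one candidate per distinct point.
update_archive <- function(archive, candidates) {
  all <- c(archive, candidates)
  obj <- cbind(vapply(all, `[[`, numeric(1L), "loss"),
               vapply(all, `[[`, numeric(1L), "complexity"))
  keep <- which(nondominated_mask(obj))
  keep <- keep[!duplicated(obj[keep, , drop = FALSE])]
  all[keep]
}

#' Run the evolutionary search
#'
#' The top-level loop: the data are split 80/20 into internal training and
#' validation parts (stratified, driven by `cfg$seed`), the population is
#' initialized from univariate-weighted linear seeds and random trees, and
#' each generation applies epsilon-lexicase parent selection, variation,
#' logistic refitting of offspring, and NSGA-II survival on (balanced
#' training loss, complexity). A cumulative archive keeps every
#' non-dominated candidate seen. After the loop the archived models are
#' post-run simplified (unless `cfg$simplify` is off) and the final model is
#' the archive member with the lowest validation balanced log-loss.
#'
#' @param ds preprocessed [bf_dataset()] with both classes.
#' @param cfg an [evolution_config()].
#' @return list of class `bf_feat_fit` with elements `model` (selected
#'   [bf_model()]), `archive` (class `bf_archive`), `history` (per-generation
#'   data.frame), `train_idx`, `validation_idx`, `config`.
#' @export
feat_run <- function(ds, cfg = evolution_config()) {
  stopifnot(inherits(ds, "bf_dataset"))
  set.seed(cfg$seed)
  sp <- split_train_validation(ds, cfg$validation_frac, seed = cfg$seed)
  train <- sp$train
  w_cases <- class_weights(train$labels)
  fw <- univariate_feature_weights(train)

  pop_reps <- init_population(train, cfg, fw)
  pop <- lapply(pop_reps, eval_candidate, train = train, w_cases = w_cases,
                cfg = cfg)
  archive <- update_archive(list(), pop)

  history <- data.frame(generation = integer(0), best_loss = numeric(0),
                        median_complexity = numeric(0),
                        archive_size = integer(0))
  record <- function(gen) {
    data.frame(generation = gen,
               best_loss = min(vapply(archive, `[[`, numeric(1L), "loss")),
               median_complexity = stats::median(
                 vapply(pop, `[[`, numeric(1L), "complexity")),
               archive_size = length(archive))
  }
  history <- rbind(history, record(0L))

  for (gen in seq_len(cfg$generations)) {
    loss_matrix <- do.call(rbind, lapply(pop, `[[`, "per_case"))
    parent_idx <- epsilon_lexicase_select(loss_matrix, cfg$pop_size,
                                          cfg$epsilon_mode)
    parents <- lapply(pop[parent_idx], `[[`, "rep")
    offspring_reps <- vary(parents, cfg, train, fw)
    # unchanged copies (variation fallbacks) inherit the parent's fitness
    offspring <- lapply(seq_along(offspring_reps), function(i) {
      if (identical(offspring_reps[[i]], parents[[i]])) {
        pop[[parent_idx[i]]]
      } else {
        eval_candidate(offspring_reps[[i]], train, w_cases, cfg)
      }
    })
    combined <- c(pop, offspring)
    obj <- cbind(vapply(combined, `[[`, numeric(1L), "loss"),
                 vapply(combined, `[[`, numeric(1L), "complexity"))
    pop <- combined[nsga2_survive(obj, cfg$pop_size)]
    archive <- update_archive(archive, offspring)
    history <- rbind(history, record(gen))
  }

  members <- lapply(archive, function(e) {
    m <- bf_model(e$rep, e$beta, e$intercept, ds$feature_names,
                  meta = list(seed = cfg$seed))
    if (cfg$simplify) {
      m <- simplify_post_run(m, train, cfg$simplify_tolerance, w_cases,
                             cfg$ridge)
    }
    list(model = m, loss = e$loss,
         complexity = rep_complexity(m$representation, cfg$op_weights),
         size = rep_size(m$representation))
  })
  arch <- structure(list(members = members), class = "bf_archive")
  model <- select_final(arch, sp$validation, cfg$op_weights)
  model$meta <- c(model$meta, list(
    config_hash = config_hash(cfg),
    validation_loss = attr(model, "validation_loss")))

  structure(list(model = model, archive = arch, history = history,
                 train_idx = sp$train_idx, validation_idx = sp$validation_idx,
                 config = cfg),
            class = "bf_feat_fit")
}

config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "")
  # small rolling hash; identifies a configuration in model metadata
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

#' @export
print.bf_feat_fit <- function(x, ...) {
  cat(sprintf("<bf_feat_fit> %d archived models, %d generations\n",
              length(x$archive$members), max(x$history$generation)))
  print(x$model)
  invisible(x)
}

#' @export
print.bf_archive <- function(x, ...) {
  cat(sprintf("<bf_archive> %d non-dominated models\n", length(x$members)))
  invisible(x)
}

#' Fit the full pipeline, optionally with robust restarts
#'
#' Convenience wrapper around [feat_run()]: with `n_restarts = 1` it returns
#' the selected model of a single run; with more restarts it reruns the
#' search with reshuffled seeds (each restart re-draws its internal split),
#' scores each restart's selected model by validation average precision, and
#' applies [robust_select()].
#'
#' @param ds preprocessed [bf_dataset()].
#' @param cfg an [evolution_config()].
#' @param n_restarts number of independent restarts (default 1).
#' @return The selected [bf_model()].
#' @export
fit_feat <- function(ds, cfg = evolution_config(), n_restarts = 1L) {
  if (n_restarts <= 1L) return(feat_run(ds, cfg)$model)
  models <- vector("list", n_restarts)
  val_ap <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    rcfg <- cfg
    rcfg$seed <- (cfg$seed + r * 10007L) %% .Machine$integer.max
    fit <- feat_run(ds, rcfg)
    models[[r]] <- fit$model
    val <- dataset_rows(ds, fit$validation_idx)
    val_ap[r] <- auprc(val$labels, predict_proba(fit$model, val))
  }
  robust_select(models, val_ap)
}

#' Export a run's archive as JSON
#'
#' Writes the archived models (serialized trees, coefficients, training
#' loss, complexity, size) so the Pareto front can be inspected or plotted.
#'
#' @param fit a `bf_feat_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_archive <- function(fit, path) {
  entries <- lapply(fit$archive$members, function(e) {
    list(representation = rep_to_list(e$model$representation,
                                      e$model$feature_names),
         beta = e$model$beta, intercept = e$model$intercept,
         train_loss = e$loss, complexity = e$complexity, size = e$size)
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}
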