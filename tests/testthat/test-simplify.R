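test_that("correlation pruning deletes the redundant, less predictive tree", {
  ds <- fixture_planted_and(n = 200, seed = 31)$dataset
  a <- node_gt(1, 0.5)
  b <- node_gt(3, 0)
  # two identical trees: one of them is deleted
  rep2 <- representation(list(a, a))
  out <- prune_correlated(rep2, ds, ds$labels)
  expect_equal(boolfeat:::rep_p(out), 1L)
  expect_equal(attr(out, "pair_correlation"), 1)

  # duplicate of a label-correlated tree goes, the unrelated tree stays
  rep3 <- representation(list(a, a, b))
  out3 <- prune_correlated(rep3, ds, ds$labels)
  expect_equal(boolfeat:::rep_p(out3), 2L)
  kinds <- vapply(out3$trees, function(t) t$feature, integer(1))
  expect_true(3 %in% kinds)  # b survived
  expect_true(1 %in% kinds)  # one copy of a survived

  expect_warning(prune_correlated(representation(a), ds, ds$labels), "single")
})

test_that("correlation pruning agrees with an exhaustive all-pairs scan", {
  brute_prune <- function(rep, ds, labels) {
    phi <- evaluate_representation(rep, ds)
    p <- ncol(phi)
    pairs <- t(combn(p, 2))
    cors <- apply(pairs, 1, function(pr)
      abs(boolfeat:::safe_cor(phi[, pr[1]], phi[, pr[2]])))
    best <- pairs[which.max(cors), ]
    ri <- abs(boolfeat:::safe_cor(phi[, best[1]], labels))
    rj <- abs(boolfeat:::safe_cor(phi[, best[2]], labels))
    if (ri < rj) best[1] else best[2]
  }
  set.seed(41)
  ds <- fixture_planted_and(n = 120, seed = 13)$dataset
  for (k in 1:25) {
    rep <- random_fixture_rep(ds, max_dim = 4)
    if (boolfeat:::rep_p(rep) < 2) next
    out <- prune_correlated(rep, ds, ds$labels)
    expect_equal(attr(out, "deleted_index"), brute_prune(rep, ds, ds$labels))
  }
})

test_that("redundant-operation rewrites are exact and reach a fixpoint", {
  g <- node_gt(1, 2)
  expect_identical(remove_redundant_ops(representation(node_not(node_not(g)))),
                   representation(g))
  a <- node_lt(2, 0)
  b <- node_gt(3, 1)
  collapsed <- remove_redundant_ops(representation(node_or(a, node_or(a, b))))
  expect_equal(rep_size(collapsed), rep_size(representation(node_or(a, b))))
  expect_identical(remove_redundant_ops(representation(node_and(a, a))),
                   representation(a))

  # equivalence fuzzing over random trees
  set.seed(52)
  ds <- fixture_planted_and(n = 60, seed = 14)$dataset
  for (k in 1:300) {
    rep <- random_fixture_rep(ds, max_dim = 2)
    # graft in redundancy: double negation around a Boolean root (NOT is
    # only typed for Boolean children)
    bool_roots <- which(vapply(rep$trees, function(t)
      boolfeat:::node_type(t) == "bool", logical(1)))
    if (length(bool_roots)) {
      bi <- bool_roots[1]
      rep$trees[[bi]] <- node_not(node_not(rep$trees[[bi]]))
    }
    simp <- remove_redundant_ops(rep)
    expect_identical(evaluate_representation(simp, ds),
                     evaluate_representation(rep, ds))
    expect_lte(rep_size(simp), rep_size(rep))
    # idempotent
    expect_identical(remove_redundant_ops(simp), simp)
  }
})

test_that("post-run simplification removes duplicates without changing output", {
  # label noise keeps the fit away from separation so refits are stable
  ds <- fixture_planted_and(n = 150, noise = 0.15, seed = 15)$dataset
  a <- node_gt(1, 0.5)
  rep <- representation(list(a, a, node_gt(2, -0.3)))
  phi <- evaluate_representation(rep, ds)
  fit <- suppressWarnings(fit_logistic(phi, ds$labels, class_weights(ds$labels)))
  model <- bf_model(rep, fit$beta, fit$intercept, ds$feature_names)
  set.seed(1)
  simp <- simplify_post_run(model, ds, tolerance = 0)
  expect_lt(boolfeat:::rep_p(simp$representation), 3)
  expect_lt(max(abs(predict_proba(simp, ds) - predict_proba(model, ds))), 1e-5)
})

test_that("tolerance zero admits only exact simplifications and is idempotent", {
  ds <- fixture_planted_and(n = 150, seed = 16)$dataset
  rep <- representation(list(node_not(node_not(node_gt(1, 0.5))),
                             node_gt(2, -0.3), node_feature(4)))
  phi <- evaluate_representation(rep, ds)
  fit <- suppressWarnings(fit_logistic(phi, ds$labels, class_weights(ds$labels)))
  model <- bf_model(rep, fit$beta, fit$intercept, ds$feature_names)
  set.seed(2)
  once <- simplify_post_run(model, ds, tolerance = 0)
  set.seed(2)
  twice <- simplify_post_run(once, ds, tolerance = 0)
  expect_identical(twice$representation, once$representation)
  # the double negation must be gone; the informative trees must survive
  expect_equal(rep_size(once$representation),
               rep_size(representation(list(node_gt(1, 0.5), node_gt(2, -0.3),
                                            node_feature(4)))))
})

test_that("simplification never grows models and bounds prediction drift", {
  set.seed(61)
  gen <- fixture_planted_and(n = 150, seed = 17)
  ds <- gen$dataset
  w <- class_weights(ds$labels)
  tol <- 0.005
  n_checked <- 0
  for (k in 1:40) {
    rep <- random_fixture_rep(ds, max_dim = 4)
    phi <- evaluate_representation(rep, ds)
    fit <- suppressWarnings(fit_logistic(phi, ds$labels, w))
    model <- bf_model(rep, fit$beta, fit$intercept, ds$feature_names)
    p_before <- predict_proba(model, ds)
    simp <- simplify_post_run(model, ds, tolerance = tol)
    expect_lte(rep_size(simp$representation), rep_size(model$representation))
    expect_lte(rep_complexity(simp$representation),
               rep_complexity(model$representation))
    expect_lte(mean(abs(predict_proba(simp, ds) - p_before)), tol + 1e-12)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 30)
})
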