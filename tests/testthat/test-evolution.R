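test_that("univariate feature weights rank signal above noise", {
  set.seed(50)
  n <- 2000
  x <- cbind(strong = NA, n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
             n4 = rnorm(n))
  y <- rbinom(n, 1, 0.3)
  x[, "strong"] <- y + rnorm(n, 0, 0.01)  # essentially the label itself
  ds <- bf_dataset(x, y)
  w <- univariate_feature_weights(ds)
  expect_equal(sum(w), 1)
  expect_equal(which.max(w), 1L)
  expect_true(all(w[2:5] < 2 / 5))  # pure-noise columns stay small
  # permutation equivariance
  perm <- c(3, 1, 5, 2, 4)
  ds_p <- bf_dataset(x[, perm], y, feature_names = colnames(x)[perm])
  expect_equal(univariate_feature_weights(ds_p), w[perm], tolerance = 1e-10)
})

test_that("initial populations are valid, seeded, and weight-driven", {
  gen <- fixture_planted_and(n = 120, seed = 3)
  ds <- gen$dataset
  cfg <- evolution_config(pop_size = 20, max_dim = 4, seed = 1)
  w <- univariate_feature_weights(ds)

  set.seed(5); pop1 <- init_population(ds, cfg, w)
  set.seed(5); pop2 <- init_population(ds, cfg, w)
  expect_identical(pop1, pop2)
  for (rep in pop1) {
    expect_true(validate_representation(rep, ncol(ds$features), 4, 3)$ok)
  }

  # d = 1: every candidate uses the single feature
  ds1 <- bf_dataset(matrix(rnorm(50), 50, 1), rbinom(50, 1, 0.5) |>
                      (\(y) {y[1:2] <- c(0, 1); y})())
  set.seed(1)
  pop <- init_population(ds1, evolution_config(pop_size = 10, max_dim = 3), c(1))
  for (rep in pop) {
    feats <- unlist(lapply(rep$trees, function(t)
      boolfeat:::collect_nodes(t, c("FEATURE", "LT", "GT")) |>
        lapply(`[[`, "feature")))
    expect_true(all(feats == 1))
  }
})

test_that("feature sampling frequency tracks the univariate weights", {
  gen <- fixture_planted_and(n = 150, d = 8, seed = 11)
  ds <- gen$dataset
  w <- univariate_feature_weights(ds)
  cfg <- evolution_config(pop_size = 10, max_dim = 5, seed = 1)
  counts <- numeric(8)
  set.seed(99)
  for (k in 1:200) {
    pop <- init_population(ds, cfg, w)
    for (rep in pop) {
      for (tr in rep$trees) {
        for (nd in boolfeat:::collect_nodes(tr, c("FEATURE", "LT", "GT"))) {
          counts[nd$feature] <- counts[nd$feature] + 1
        }
      }
    }
  }
  expect_gt(cor(counts, w, method = "spearman"), 0.8)
})

test_that("epsilon-lexicase selects a strict winner and treats clones uniformly", {
  # one candidate strictly best on every case, zero epsilon
  lm <- rbind(c(0.1, 0.1), c(0.5, 0.4), c(0.9, 0.2))
  set.seed(1)
  sel <- epsilon_lexicase_select(lm, 50, epsilon_mode = "zero")
  expect_true(all(sel == 1L))
  # identical candidates: uniform selection
  lm_same <- matrix(0.3, nrow = 4, ncol = 5)
  set.seed(2)
  sel <- epsilon_lexicase_select(lm_same, 10000)
  tab <- tabulate(sel, 4)
  expect_gt(chisq.test(tab)$p.value, 0.01)
  expect_error(epsilon_lexicase_select(matrix(numeric(0), 0, 2), 1), "empty")
})

test_that("lexicase selection frequencies match exhaustive case-order enumeration", {
  # 3 candidates x 2 cases with hand-set losses; epsilon = 0 so survivors are
  # exact per-case minima. Enumerate both case orders by hand:
  # losses:      case1  case2
  # cand 1:       0.1    0.9
  # cand 2:       0.9    0.1
  # cand 3:       0.1    0.1
  # order (1,2): case1 keeps {1,3}; case2 keeps {3}        -> 3
  # order (2,1): case2 keeps {2,3}; case1 keeps {3}        -> 3
  # so candidate 3 must always win under zero epsilon.
  lm <- rbind(c(0.1, 0.9), c(0.9, 0.1), c(0.1, 0.1))
  set.seed(3)
  sel <- epsilon_lexicase_select(lm, 2000, epsilon_mode = "zero")
  expect_true(all(sel == 3L))

  # a pool where enumeration yields 50/50 between specialists:
  # cand 3 removed; order (1,2) -> {1}; order (2,1) -> {2}
  lm2 <- rbind(c(0.1, 0.9), c(0.9, 0.1))
  set.seed(4)
  sel2 <- epsilon_lexicase_select(lm2, 10000, epsilon_mode = "zero")
  frac1 <- mean(sel2 == 1L)
  expect_gt(binom.test(sum(sel2 == 1L), 10000, 0.5)$p.value, 0.01)
})

test_that("variation always yields valid, non-empty representations", {
  gen <- fixture_planted_and(n = 100, seed = 21)
  ds <- gen$dataset
  cfg <- evolution_config(pop_size = 10, max_dim = 4, seed = 1)
  w <- univariate_feature_weights(ds)

  # deletion on a single bare feature cannot empty the representation
  set.seed(7)
  single <- representation(node_feature(1))
  for (k in 1:20) {
    child <- boolfeat:::vary_delete(single)
    expect_true(is.null(child) || rep_p(child) >= 1)
  }

  # point mutation AND -> OR preserves arity and depth
  nd <- node_and(node_gt(1, 0), node_lt(2, 1))
  mut <- boolfeat:::mutate_node(nd, cfg, ds, w, class_weights(ds$labels))
  expect_equal(mut$kind, "OR")
  expect_length(mut$children, 2)

  # fuzz: thousands of random variations all validate
  set.seed(8)
  pop <- init_population(ds, cfg, w)
  for (k in 1:100) {
    parents <- pop[sample.int(length(pop), 10, replace = TRUE)]
    offspring <- vary(parents, cfg, ds, w)
    for (ch in offspring) {
      expect_true(validate_representation(ch, ncol(ds$features), 4, 3)$ok)
    }
  }
})

test_that("NSGA-II survival respects dominance and matches brute force", {
  obj <- rbind(c(1, 1), c(2, 2), c(1, 2))
  set.seed(1)
  surv <- nsga2_survive(obj, 2)
  expect_true(1 %in% surv)
  expect_false(2 %in% surv)  # dominated by (1,1)

  # front assignment vs O(n^2) brute force
  brute_fronts <- function(obj) {
    n <- nrow(obj)
    rank <- integer(n)
    remaining <- seq_len(n)
    f <- 0L
    while (length(remaining)) {
      f <- f + 1L
      nd <- remaining[vapply(remaining, function(i) {
        !any(vapply(remaining, function(j) {
          j != i && obj[j, 1] <= obj[i, 1] && obj[j, 2] <= obj[i, 2] &&
            (obj[j, 1] < obj[i, 1] || obj[j, 2] < obj[i, 2])
        }, logical(1)))
      }, logical(1))]
      rank[nd] <- f
      remaining <- setdiff(remaining, nd)
    }
    rank
  }
  set.seed(12)
  for (trial in 1:20) {
    obj <- cbind(sample(6, 50, replace = TRUE) / 2, sample(8, 50, replace = TRUE))
    fronts <- boolfeat:::nondominated_fronts(obj)
    rank <- integer(50)
    for (f in seq_along(fronts)) rank[fronts[[f]]] <- f
    expect_equal(rank, brute_fronts(obj))
  }

  # all-identical objectives: seeded subset of the requested size
  obj_same <- matrix(1, 10, 2)
  set.seed(3); s1 <- nsga2_survive(obj_same, 4)
  set.seed(3); s2 <- nsga2_survive(obj_same, 4)
  expect_identical(s1, s2)
  expect_length(s1, 4)
})

test_that("the search recovers a planted single-threshold rule", {
  gen <- make_planted_rule(synthetic_spec(
    n = 1000, d = 10, rule = node_gt(1, 0.5), label_noise = 0, seed = 0))
  cfg <- evolution_config(pop_size = 50, generations = 50, seed = 0)
  fit <- feat_run(gen$dataset, cfg)
  val <- boolfeat:::dataset_rows(gen$dataset, fit$validation_idx)
  expect_gte(auroc(val$labels, predict_proba(fit$model, val)), 0.99)
  expect_lte(rep_size(fit$model$representation), 6)
  # best archived training loss never increases over generations
  expect_true(all(diff(fit$history$best_loss) <= 1e-12))
})

test_that("the raw archive stays mutually non-dominated", {
  gen <- fixture_planted_and(n = 200, seed = 44)
  cfg <- quick_config(seed = 2, simplify = FALSE)
  fit <- feat_run(gen$dataset, cfg)
  obj <- cbind(vapply(fit$archive$members, `[[`, numeric(1), "loss"),
               vapply(fit$archive$members, `[[`, numeric(1), "complexity"))
  expect_true(all(boolfeat:::nondominated_mask(obj)))
})

test_that("identical seeds reproduce the identical run", {
  gen <- fixture_planted_and(n = 200, seed = 5)
  cfg <- quick_config(seed = 11)
  f1 <- feat_run(gen$dataset, cfg)
  f2 <- feat_run(gen$dataset, cfg)
  expect_identical(f1$model$beta, f2$model$beta)
  expect_identical(f1$model$representation, f2$model$representation)
  expect_identical(f1$history, f2$history)
  expect_equal(length(f1$archive$members), length(f2$archive$members))
})

test_that("zero generations selects the validation-best initial candidate", {
  gen <- fixture_planted_and(n = 200, seed = 6)
  cfg <- evolution_config(pop_size = 20, generations = 0, seed = 2)
  fit <- feat_run(gen$dataset, cfg)
  expect_equal(nrow(fit$history), 1L)
  val <- boolfeat:::dataset_rows(gen$dataset, fit$validation_idx)
  # the selected model is the archive argmin of validation balanced loss
  losses <- vapply(fit$archive$members, function(e) {
    balanced_log_loss(val$labels, predict_proba(e$model, val),
                      class_weights(val$labels))$aggregate
  }, numeric(1))
  sel_loss <- balanced_log_loss(val$labels, predict_proba(fit$model, val),
                                class_weights(val$labels))$aggregate
  expect_equal(sel_loss, min(losses))
})

test_that("max_dim = 1 restricts every archived model to one derived feature", {
  gen <- fixture_planted_and(n = 200, seed = 8)
  cfg <- evolution_config(pop_size = 20, generations = 5, max_dim = 1, seed = 3)
  fit <- feat_run(gen$dataset, cfg)
  for (e in fit$archive$members) {
    expect_equal(boolfeat:::rep_p(e$model$representation), 1L)
  }
  expect_equal(boolfeat:::rep_p(fit$model$representation), 1L)
})
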