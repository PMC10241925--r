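# Independent oracles used below: a row-by-row interpreter written against
# plain R control flow (no vectorization shared with the implementation),
# and a bottom-up complexity fold.
eval_rep_by_rows <- function(rep, x) {
  eval1 <- function(nd, row) {
    switch(nd$kind,
           FEATURE = row[nd$feature],
           GT = if (row[nd$feature] > nd$threshold) 1 else 0,
           LT = if (row[nd$feature] < nd$threshold) 1 else 0,
           NOT = 1 - eval1(nd$children[[1]], row),
           AND = min(eval1(nd$children[[1]], row), eval1(nd$children[[2]], row)),
           OR = max(eval1(nd$children[[1]], row), eval1(nd$children[[2]], row)))
  }
  t(apply(x, 1, function(row) vapply(rep$trees, eval1, numeric(1), row = row)))
}

complexity_fold <- function(rep, w) {
  fold <- function(nd) {
    if (nd$kind == "FEATURE") return(w[["FEATURE"]])
    if (nd$kind %in% c("LT", "GT")) return(w[[nd$kind]] * (1 + w[["FEATURE"]]))
    kids <- sum(vapply(nd$children, fold, numeric(1)))
    w[[nd$kind]] * (1 + kids)
  }
  sum(vapply(rep$trees, fold, numeric(1)))
}

test_that("evaluation matches direct examples and a per-row oracle", {
  x <- cbind(f1 = c(3, 5), f2 = c(1, -1))
  expect_equal(evaluate_representation(representation(node_feature(1)), x),
               matrix(c(3, 5), 2, 1))
  expect_equal(evaluate_representation(representation(node_gt(1, 4)), x),
               matrix(c(0, 1), 2, 1))

  set.seed(21)
  x20 <- matrix(rnorm(20 * 3), 20, 3)
  rep <- representation(list(
    node_and(node_gt(1, 1), node_not(node_lt(2, 0))),
    node_or(node_lt(3, 0.5), node_gt(2, 0)),
    node_feature(2)))
  got <- evaluate_representation(rep, x20)
  expect_equal(got, unname(eval_rep_by_rows(rep, x20)))
  # purity: identical output on re-evaluation
  expect_identical(got, evaluate_representation(rep, x20))
})

test_that("size counts split nodes plus leaves", {
  expect_equal(rep_size(representation(node_feature(3))), 1L)
  expect_equal(rep_size(node_and(node_gt(1, 0), node_gt(2, 0))), 5L)
  expect_equal(rep_size(node_not(node_not(node_lt(1, 2)))), 4L)
  rep <- representation(list(node_gt(1, 0), node_feature(2)))
  expect_equal(rep_size(rep), 3L)
})

test_that("complexity follows the recursive weighting and its oracle", {
  w1 <- c(FEATURE = 1, LT = 1, GT = 1, AND = 1, OR = 1, NOT = 1)
  expect_equal(rep_complexity(representation(node_feature(1)), w1), 1)
  w <- c(FEATURE = 1, GT = 2, LT = 2, AND = 2, OR = 2, NOT = 1)
  expect_equal(rep_complexity(representation(node_not(node_gt(1, 0))), w), 5)

  set.seed(33)
  ds <- fixture_planted_and(n = 50)$dataset
  for (i in 1:20) {
    rep <- random_fixture_rep(ds)
    expect_equal(rep_complexity(rep), complexity_fold(rep, default_op_weights()))
    expect_gte(rep_complexity(rep), rep_size(rep))  # all weights >= 1
  }
  expect_error(rep_complexity(representation(node_gt(1, 0)), c(FEATURE = 1)),
               "no complexity weight")
})

test_that("adding a node strictly increases complexity", {
  base <- node_gt(1, 0)
  grown <- node_and(node_gt(1, 0), node_gt(2, 1))
  expect_gt(rep_complexity(representation(grown)),
            rep_complexity(representation(base)))
  expect_gt(rep_complexity(representation(node_not(base))),
            rep_complexity(representation(base)))
})

test_that("learn_threshold minimizes Gini impurity with smallest-theta ties", {
  expect_equal(learn_threshold(c(1, 2, 3, 4), c(0, 0, 1, 1)), 2.5)
  # all labels identical: every split has impurity 0, smallest midpoint wins
  expect_equal(learn_threshold(c(1, 2, 5, 9), c(1, 1, 1, 1)), 1.5)
  expect_error(learn_threshold(c(2, 2, 2), c(0, 1, 0)), "constant column")
})

test_that("learn_threshold equals exhaustive midpoint search", {
  brute <- function(column, labels, weights) {
    v <- sort(unique(column))
    mids <- (v[-length(v)] + v[-1]) / 2
    imp <- vapply(mids, function(m) {
      l <- column <= m
      gini <- function(idx) {
        wl <- sum(weights[idx])
        if (wl == 0) return(0)
        p1 <- sum(weights[idx & labels == 1]) / wl
        wl * (1 - p1^2 - (1 - p1)^2)
      }
      (gini(l) + gini(!l)) / sum(weights)
    }, numeric(1))
    mids[which.min(imp)]
  }
  set.seed(17)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    col <- round(rnorm(n), sample(0:2, 1))  # ties are common
    if (length(unique(col)) < 2) next
    y <- rbinom(n, 1, plogis(col))
    if (length(unique(y)) < 2) next
    w <- runif(n, 0.5, 2)
    expect_equal(learn_threshold(col, y, w), brute(col, y, w))
  }
})

test_that("learned thresholds lie strictly between observed values", {
  set.seed(3)
  for (i in 1:20) {
    col <- rnorm(30)
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    th <- learn_threshold(col, y)
    expect_false(th %in% col)
    expect_true(th > min(col) && th < max(col))
  }
})

test_that("validation reports arity, range, and depth violations", {
  bad_arity <- representation(structure(
    list(kind = "AND", feature = NA_integer_, threshold = NA_real_,
         children = list(node_gt(1, 0))), class = "bf_node"))
  res <- validate_representation(bad_arity, d = 3)
  expect_false(res$ok)
  expect_match(res$violations, "children", all = FALSE)

  out_of_range <- representation(node_gt(4, 0))
  expect_false(validate_representation(out_of_range, d = 3)$ok)

  ok <- representation(node_and(node_gt(1, 0), node_not(node_lt(2, 1))))
  expect_true(validate_representation(ok, d = 3)$ok)

  deep <- representation(node_not(node_not(node_not(node_gt(1, 0)))))
  expect_false(validate_representation(deep, d = 3, max_depth = 3)$ok)

  arith <- representation(node_arith("ADD", node_feature(1), node_feature(2)))
  expect_false(validate_representation(arith, d = 3)$ok)
  expect_true(validate_representation(arith, d = 3, allow_arith = TRUE)$ok)
})

test_that("De Morgan rewrites evaluate identically", {
  set.seed(8)
  x <- matrix(rnorm(200), 50, 4)
  for (i in 1:20) {
    a <- node_gt(sample(4, 1), rnorm(1))
    b <- node_lt(sample(4, 1), rnorm(1))
    lhs <- representation(node_not(node_and(a, b)))
    rhs <- representation(node_or(node_not(a), node_not(b)))
    expect_equal(evaluate_representation(lhs, x),
                 evaluate_representation(rhs, x))
  }
})

test_that("representations serialize through JSON losslessly", {
  nms <- c("SBP, max", "Potassium, min", "# enc 3+ meds, sum")
  rep <- representation(list(
    node_and(node_gt(3, 1.5), node_lt(2, 3.6)),
    node_feature(1)))
  lst <- boolfeat:::rep_to_list(rep, nms)
  back <- boolfeat:::rep_from_list(lst, nms)
  x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, nms))
  expect_equal(evaluate_representation(back, x), evaluate_representation(rep, x))
  expect_equal(rep_size(back), rep_size(rep))
})

test_that("rule text reads in raw units", {
  nms <- c("SBP, max", "age")
  expect_equal(format_node(node_gt(1, 140), nms), "\"SBP, max\" > 140")
  expect_equal(format_node(node_and(node_gt(2, 65), node_lt(1, 120)), nms),
               "(age > 65 AND \"SBP, max\" < 120)")
})
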