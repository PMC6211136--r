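test_that("tree evaluation implements Boolean semantics", {
  x <- matrix(c(0L, 1L,
                1L, 1L,
                0L, 0L), 2, 3,
              dimnames = list(NULL, c("x1", "x2", "x3")))
  expect_equal(evaluate_tree(lt_leaf(1), x), c(0L, 1L))
  expect_equal(evaluate_tree(lt_leaf(1, neg = TRUE), x), c(1L, 0L))
  tr <- lt_or(lt_and(lt_leaf(1), lt_leaf(2)), lt_leaf(3))
  expect_equal(evaluate_tree(tr, matrix(c(1L, 1L, 0L), 1)), 1L)
  expect_equal(evaluate_tree(tr, matrix(c(1L, 0L, 0L), 1)), 0L)
})

test_that("a three-implicant tree fires when only one condition is met", {
  # (psc AND !a) OR (b OR c): a subject meeting only condition b is a case
  tr <- lt_or(lt_and(lt_leaf(1), lt_leaf(2, neg = TRUE)),
              lt_or(lt_leaf(3), lt_leaf(4)))
  row_b_only <- matrix(c(0L, 1L, 1L, 0L), 1)
  expect_equal(evaluate_tree(tr, row_b_only), 1L)
  expect_equal(length(to_dnf(tr)), 3L)
})

test_that("DNF extraction distributes, simplifies and absorbs", {
  # OR of an AND and two leaves -> three prime implicants
  tr <- lt_or(lt_and(lt_leaf(1), lt_leaf(2, neg = TRUE)),
              lt_or(lt_leaf(3), lt_leaf(4)))
  keys <- sort(vapply(to_dnf(tr), pi_key, ""))
  expect_equal(keys, sort(c("1 -2", "3", "4")))

  # AND over OR distributes
  tr2 <- lt_and(lt_or(lt_leaf(1), lt_leaf(2)), lt_leaf(3))
  keys2 <- sort(vapply(to_dnf(tr2), pi_key, ""))
  expect_equal(keys2, sort(c("1 3", "2 3")))

  # contradiction collapses to the empty DNF
  expect_equal(length(to_dnf(lt_and(lt_leaf(1), lt_leaf(1, neg = TRUE)))), 0L)

  # absorption: x1 OR (x1 AND x2) = x1
  tr3 <- lt_or(lt_leaf(1), lt_and(lt_leaf(1), lt_leaf(2)))
  expect_equal(vapply(to_dnf(tr3), pi_key, ""), "1")

  # duplicate literal within a term merges
  tr4 <- lt_and(lt_leaf(1), lt_leaf(1))
  expect_equal(vapply(to_dnf(tr4), pi_key, ""), "1")
})

test_that("DNF equals the tree on every truth assignment (random trees)", {
  set.seed(41)
  p <- 10
  for (r in 1:60) {
    tr <- rand_tree(p)
    x <- assignment_grid(tr, p)
    expect_equal(naive_dnf_eval(to_dnf(tr), x),
                 naive_tree_eval(tr, x))
    # and the C++ evaluator agrees with the naive R one
    expect_equal(evaluate_tree(tr, x), naive_tree_eval(tr, x))
  }
})

test_that("score is the mismatch fraction", {
  set.seed(42)
  d <- planted_data(10, 4)
  tr <- rand_tree(4)
  yhat <- naive_tree_eval(tr, d$x)
  expect_equal(score_tree(tr, d), mean(d$y != yhat))
  # constant-ish checks
  d0 <- lf_data(matrix(rep(0:1, each = 10), 20, 1), rep(c(1L, 0L), c(6, 14)))
  expect_equal(score_tree(lt_and(lt_leaf(1), lt_leaf(1, TRUE)), d0), 0.3)
})

test_that("random moves preserve tree invariants over many iterations", {
  set.seed(43)
  p <- 7
  tr <- lt_leaf(3)
  for (k in 1:10000) {
    tr <- propose_tree_move(tr, p, max_leaves = 8)
  }
  # spot-check structural invariants on the end state and a fresh walk
  check_tree <- function(t) {
    expect_gte(n_leaves(t), 1L)
    expect_lte(n_leaves(t), 8L)
    internal <- which(t$type %in% 1:2)
    for (i in internal) {
      expect_false(is.na(t$left[i]))
      expect_false(is.na(t$right[i]))
    }
    leaves <- which(t$type == 0L)
    expect_true(all(t$var[leaves] >= 1 & t$var[leaves] <= p))
  }
  check_tree(tr)
  tr2 <- lt_leaf(1)
  for (k in 1:500) {
    tr2 <- propose_tree_move(tr2, p, max_leaves = 3)
    expect_lte(n_leaves(tr2), 3L)
  }
})

test_that("moves from a single leaf never empty the tree", {
  set.seed(44)
  for (k in 1:200) {
    tr <- propose_tree_move(lt_leaf(2), p = 5, max_leaves = 8)
    expect_gte(n_leaves(tr), 1L)
  }
})

test_that("annealing recovers planted Boolean structure", {
  set.seed(45)
  # single-predictor truth
  x <- matrix(rbinom(2000, 1, 0.5), 200, 10,
              dimnames = list(NULL, paste0("x", 1:10)))
  d <- lf_data(x, x[, 3])
  tr <- fit_logic_tree(d, control = fast_ctl(4000))
  expect_equal(vapply(to_dnf(tr), pi_key, ""), "3")
  expect_equal(tr$score, 0)

  # two-literal conjunction
  set.seed(46)
  d2 <- planted_data(400, 8)
  tr2 <- fit_logic_tree(d2, control = fast_ctl(6000))
  expect_equal(vapply(to_dnf(tr2), pi_key, ""), "1 2")
  expect_equal(tr2$score, 0)
})

test_that("pure-noise fits cannot beat the prevalence bound by much", {
  set.seed(47)
  n <- 300
  x <- matrix(rbinom(n * 5, 1, 0.5), n, 5)
  y <- rbinom(n, 1, 0.3)
  d <- lf_data(x, y)
  tr <- fit_logic_tree(d, control = fast_ctl(3000))
  bound <- min(mean(y), 1 - mean(y))
  expect_lt(abs(tr$score - bound), 0.12)   # in-sample overfit is limited
  # and never worse than the trivial constant classifier
  expect_lte(tr$score, bound)
})

test_that("fitting is bit-reproducible under a fixed seed", {
  d <- withr::with_seed(48, planted_data(100, 6, noise = 0.2))
  set.seed(99)
  t1 <- fit_logic_tree(d, control = fast_ctl(2000))
  set.seed(99)
  t2 <- fit_logic_tree(d, control = fast_ctl(2000))
  expect_identical(t1, t2)
})

test_that("a constant outcome yields a single-leaf fallback with warning", {
  x <- matrix(rbinom(40, 1, 0.5), 20, 2)
  expect_warning(tr <- fit_logic_tree(lf_data(x, rep(0L, 20))),
                 "constant")
  expect_equal(n_leaves(tr), 1L)
})

test_that("trees serialize to text and lists and round-trip", {
  set.seed(49)
  labs <- c("psc", "snp_rs2359661_R", "snp_rs4632147_R")
  tr <- lt_or(lt_and(lt_leaf(1), lt_leaf(2, TRUE)), lt_leaf(3))
  txt <- deparse_tree(tr, labs)
  expect_equal(txt, "((psc AND !snp_rs2359661_R) OR snp_rs4632147_R)")
  back <- parse_tree(txt, labs)
  x <- assignment_grid(tr, 3)
  expect_equal(naive_tree_eval(back, x), naive_tree_eval(tr, x))

  for (r in 1:20) {
    t0 <- rand_tree(6)
    x <- assignment_grid(t0, 6)
    t1 <- parse_tree(deparse_tree(t0), labels = NULL)
    expect_equal(naive_tree_eval(t1, x), naive_tree_eval(t0, x))
    t2 <- tree_from_list(tree_to_list(t0))
    expect_identical(t2$type, t0$type)
    expect_equal(naive_tree_eval(t2, x), naive_tree_eval(t0, x))
  }
})
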