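# assemble a logic_forest object by hand so OOB/vote rules can be checked
# against constructed examples
forge_model <- function(trees, oob, data, inbag = NULL) {
  keys <- lapply(trees, function(t) vapply(to_dnf(t), pi_key, ""))
  terms <- list()
  for (kk in unlist(keys)) if (is.null(terms[[kk]])) terms[[kk]] <- pi_from_key(kk)
  m <- structure(list(
    trees = trees, oob = oob,
    inbag = inbag %||% lapply(oob, function(o) setdiff(seq_len(data$n), o)),
    pi_keys = keys, pi_terms = terms, B = length(trees), n = data$n,
    p = data$p, max_leaves = 8, control = anneal_control(),
    descriptors = data$descriptors, data = data), class = "logic_forest")
  m$tree_oob_err <- vapply(seq_len(m$B), function(b)
    tree_oob_misclassification(m, b), 0)
  m
}

test_that("OOB votes follow the >= 0.5 majority rule, ties to case", {
  x <- matrix(c(1L, 0L,
                1L, 1L), 2, 2, dimnames = list(NULL, c("x1", "x2")))
  d <- lf_data(x, c(1L, 0L))
  # subject 1: OOB in trees 1,2 voting (x1=1, x2=1) -> share 1
  # subject 2: OOB in trees 1,2 voting (x1=0, x2=1) -> share 0.5 -> class 1
  m <- forge_model(list(lt_leaf(1), lt_leaf(2)),
                   oob = list(c(1L, 2L), c(1L, 2L)), data = d)
  pr <- oob_predict(m)
  expect_equal(as.integer(pr), c(1L, 1L))
  expect_equal(attr(pr, "share"), c(1, 0.5))
  # all-zero votes -> 0 (subject 2 has x1 = 0)
  m0 <- forge_model(list(lt_leaf(1)), oob = list(2L), data = d)
  expect_equal(as.integer(suppressWarnings(oob_predict(m0))[2]), 0L)
})

test_that("subjects never out-of-bag are flagged and excluded", {
  x <- matrix(rep(0:1, 5), 10, 1)
  d <- lf_data(x, rep(0:1, 5))
  m <- forge_model(list(lt_leaf(1)), oob = list(1:8), data = d)
  expect_warning(pr <- oob_predict(m), "out-of-bag in no tree")
  expect_true(all(is.na(pr[9:10])))
  expect_equal(suppressWarnings(oob_misclassification(m)), 0)  # x1 == y
})

test_that("forest and per-tree OOB errors match a naive double-loop recount", {
  set.seed(51)
  for (r in 1:8) {
    d <- planted_data(n = 25, p = 5, noise = 0.3)
    f <- suppressWarnings(
      logic_forest(d, B = sample(3:8, 1), control = fast_ctl(300)))
    oracle <- naive_oob(f, d)
    pr <- suppressWarnings(oob_predict(f))
    expect_equal(as.integer(pr), oracle$pred)
    expect_equal(suppressWarnings(oob_misclassification(f)), oracle$mc)
    expect_equal(f$tree_oob_err, oracle$tree_mc)
  }
})

test_that("bootstrap bookkeeping: inbag size n, OOB the exact complement", {
  set.seed(52)
  d <- planted_data(150, 5, noise = 0.2)
  f <- logic_forest(d, B = 12, control = fast_ctl(300))
  for (b in seq_len(f$B)) {
    expect_length(f$inbag[[b]], d$n)
    expect_equal(sort(unique(c(f$inbag[[b]], f$oob[[b]]))), seq_len(d$n))
    expect_length(intersect(f$inbag[[b]], f$oob[[b]]), 0)
    frac <- length(f$oob[[b]]) / d$n
    expect_gt(frac, 0.25)
    expect_lt(frac, 0.50)
  }
})

test_that("forest fits are reproducible under a fixed seed", {
  d <- withr::with_seed(53, planted_data(80, 5, noise = 0.2))
  set.seed(7)
  f1 <- logic_forest(d, B = 6, control = fast_ctl(400))
  set.seed(7)
  f2 <- logic_forest(d, B = 6, control = fast_ctl(400))
  expect_identical(f1$trees, f2$trees)
  expect_identical(f1$oob, f2$oob)
})

test_that("VI2 is exactly tree_count / B and VI1 of unused predictors is 0", {
  set.seed(54)
  d <- planted_data(120, 6)          # y = x1 & x2, columns 3:6 noise
  f <- logic_forest(d, B = 10, control = fast_ctl(2000))
  imp <- importance(f)
  expect_equal(imp$pi$vi2, imp$pi$tree_count / f$B)
  expect_true(all(imp$pi$vi2 >= 0 & imp$pi$vi2 <= 1))
  expect_true(all(imp$pi$vi1 >= -1 & imp$pi$vi1 <= 1))
  used <- unique(unlist(lapply(unlist(f$pi_keys), pi_from_key)))
  unused <- setdiff(seq_len(d$p), abs(used))
  for (j in unused) expect_identical(vi_permutation(f, j), 0)
  # planted conjunction dominates frequency importance
  expect_equal(imp$pi$pi[which.max(imp$pi$vi2)], "1 2")
  expect_equal(vi_frequency(f, c(1L, 2L)), max(imp$pi$vi2))
})

test_that("VI1 equals a from-scratch recount under the same permutation", {
  set.seed(55)
  d <- planted_data(60, 4, noise = 0.25)
  f <- logic_forest(d, B = 5, control = fast_ctl(500))
  key <- f$pi_keys[[1]][1]
  term <- pi_from_key(key)
  set.seed(123)
  v <- vi_permutation(f, key)
  # replay: same RNG draw, naive per-tree OOB errors before/after
  set.seed(123)
  perm <- sample.int(d$n)
  xp <- d$x
  cols <- unique(abs(term))
  xp[, cols] <- xp[perm, cols, drop = FALSE]
  deltas <- vapply(seq_len(f$B), function(b) {
    ob <- f$oob[[b]]
    before <- mean(d$y[ob] != naive_tree_eval(f$trees[[b]], d$x)[ob])
    after <- mean(d$y[ob] != naive_tree_eval(f$trees[[b]], xp)[ob])
    after - before
  }, 0)
  expect_equal(v, mean(deltas))
})

test_that("aggregation: normalization fixed point and coverage of trees", {
  set.seed(56)
  d <- planted_data(100, 5, noise = 0.1)
  f <- logic_forest(d, B = 8, control = fast_ctl(800))
  imp <- importance(f)
  expect_equal(max(abs(imp$pi$normalized_vi1)), 1)
  expect_equal(imp$pi$normalized_vi1[which.max(imp$pi$vi1)], 1)
  expect_gte(sum(imp$pi$tree_count), f$B)  # every tree has >= 1 implicant
  # two identical single-leaf trees -> one record with vi2 = 1
  d2 <- lf_data(matrix(rep(0:1, 10), 20, 1), rep(0:1, 10))
  m <- forge_model(list(lt_leaf(1), lt_leaf(1)), oob = list(1:4, 5:8),
                   data = d2)
  imp2 <- importance(m)
  expect_equal(nrow(imp2$pi), 1L)
  expect_equal(imp2$pi$vi2, 1)
})

test_that("prediction votes over all trees with the >= 0.5 label rule", {
  x <- matrix(c(1L, 0L, 1L, 0L), 1, 4,
              dimnames = list(NULL, paste0("x", 1:4)))
  d <- lf_data(rbind(x, x), c(1L, 0L))
  m <- forge_model(list(lt_leaf(1), lt_leaf(2), lt_leaf(3), lt_leaf(4)),
                   oob = list(1L, 1L, 2L, 2L), data = d)
  pr <- predict(m, rbind(x))
  expect_equal(attr(pr, "share"), 0.5)      # votes (1,0,1,0)
  expect_equal(as.integer(pr), 1L)
  expect_equal(predict(m, rbind(x), type = "prob"), 0.5)
  # single-tree forest reduces to plain evaluation
  m1 <- forge_model(list(lt_and(lt_leaf(1), lt_leaf(3))), oob = list(1L),
                    data = d)
  xs <- matrix(rbinom(40, 1, 0.5), 10, 4,
               dimnames = list(NULL, paste0("x", 1:4)))
  expect_equal(as.integer(predict(m1, xs)),
               naive_tree_eval(m1$trees[[1]], xs))
  expect_error(predict(m1, xs[, 1:3]), "x4")
})

test_that("a saved model reloads with identical OOB quantities", {
  set.seed(57)
  d <- planted_data(50, 4, noise = 0.2)
  f <- logic_forest(d, B = 4, control = fast_ctl(300))
  path <- tempfile(fileext = ".json")
  lf_save(f, path)
  g <- lf_load(path)
  expect_equal(suppressWarnings(oob_misclassification(g)),
               suppressWarnings(oob_misclassification(f)))
  expect_identical(g$pi_keys, f$pi_keys)
  expect_equal(g$tree_oob_err, f$tree_oob_err)
  key <- f$pi_keys[[1]][1]
  expect_equal(vi_frequency(g, key), vi_frequency(f, key))
  set.seed(1); v1 <- vi_permutation(f, key)
  set.seed(1); v2 <- vi_permutation(g, key)
  expect_equal(v1, v2)
})
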