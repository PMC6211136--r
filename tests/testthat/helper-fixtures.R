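# Shared fixtures and independent oracles.  The oracles here deliberately
# re-derive quantities with naive pure-R loops so they share no code with the
# implementation under test.

`%||%` <- function(a, b) if (is.null(a)) b else a

# random logic tree with k leaves over p predictors, built by repeatedly
# joining random subtrees with random operators
rand_tree <- function(p, max_leaves = 8) {
  k <- sample.int(max_leaves, 1)
  subs <- replicate(k, lt_leaf(sample.int(p, 1), sample(c(TRUE, FALSE), 1)),
                    simplify = FALSE)
  while (length(subs) > 1) {
    i <- sample.int(length(subs), 2)
    join <- if (runif(1) < 0.5) lt_and else lt_or
    subs[[i[1]]] <- join(subs[[i[1]]], subs[[i[2]]])
    subs <- subs[-i[2]]
  }
  subs[[1]]
}

# pure-R recursive tree evaluation (independent of the C++ evaluator)
naive_tree_eval <- function(tree, x) {
  rec <- function(i) {
    if (tree$type[i] == 0L) {
      v <- x[, tree$var[i]]
      if (tree$neg[i]) 1L - v else v
    } else if (tree$type[i] == 1L) {
      rec(tree$left[i]) & rec(tree$right[i])
    } else {
      rec(tree$left[i]) | rec(tree$right[i])
    }
  }
  as.integer(rec(1L))
}

# evaluate a DNF (list of signed-literal terms) as an OR of ANDs, naively
naive_dnf_eval <- function(terms, x) {
  if (!length(terms)) return(rep(0L, nrow(x)))
  hit <- rep(FALSE, nrow(x))
  for (tm in terms) {
    ind <- rep(TRUE, nrow(x))
    for (l in tm) ind <- ind & (if (l > 0) x[, l] == 1L else x[, -l] == 0L)
    hit <- hit | ind
  }
  as.integer(hit)
}

# all truth assignments of the predictors a tree touches (other columns 0)
assignment_grid <- function(tree, p) {
  vars <- sort(unique(tree$var[!is.na(tree$var)]))
  g <- as.matrix(expand.grid(rep(list(0:1), length(vars))))
  x <- matrix(0L, nrow(g), p)
  x[, vars] <- g
  x
}

# naive double-loop OOB recount: per-subject votes, forest and per-tree
# misclassification (Eq 1/2/3 semantics re-derived from scratch)
naive_oob <- function(model, data) {
  n <- data$n
  pred <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    votes <- integer(0)
    for (b in seq_len(model$B)) {
      if (i %in% model$oob[[b]]) {
        yhat <- naive_tree_eval(model$trees[[b]], data$x)[i]
        votes <- c(votes, yhat)
      }
    }
    if (length(votes)) pred[i] <- as.integer(mean(votes) >= 0.5)
  }
  ok <- !is.na(pred)
  mc <- mean((data$y[ok] - pred[ok])^2)
  tree_mc <- vapply(seq_len(model$B), function(b) {
    ob <- model$oob[[b]]
    yh <- naive_tree_eval(model$trees[[b]], data$x)[ob]
    mean((data$y[ob] - yh)^2)
  }, 0)
  list(pred = pred, mc = mc, tree_mc = tree_mc)
}

# small binary dataset with a planted conjunction y = x1 & x2 plus noise cols
planted_data <- function(n = 200, p = 6, noise = 0) {
  x <- matrix(rbinom(n * p, 1, 0.5), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  y <- as.integer(x[, 1] & x[, 2])
  if (noise > 0) {
    flip <- runif(n) < noise
    y[flip] <- 1L - y[flip]
  }
  lf_data(x, y)
}

# fast annealing settings for small test problems
fast_ctl <- function(iterations = 1000) anneal_control(iterations = iterations)

# genotype TSV fixture written to a temp file
write_geno_fixture <- function(tab, path = tempfile(fileext = ".tsv")) {
  writeLines(tab, path)
  path
}
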