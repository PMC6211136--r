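#' Fit a logic forest
#'
#' Fits an ensemble of `B` Boolean logic trees, each by simulated annealing
#' on an independent bootstrap sample (uniform with replacement, size n) of
#' the data.  Each tree sees all predictors; only rows are resampled.  The
#' model keeps, per tree, the bootstrap multiset, its out-of-bag (OOB)
#' complement, the prime implicants of the tree's disjunctive normal form,
#' and the tree's OOB misclassification, so all OOB error and importance
#' quantities can be recomputed exactly.  A bootstrap draw that leaves no
#' subject out-of-bag is redrawn (possible only at tiny n).
#'
#' Results are reproducible under `set.seed()`.
#'
#' @param x an [lf_data()], or a binary predictor matrix.
#' @param y binary outcome when `x` is a plain matrix.
#' @param B number of trees (default 200).
#' @param max_leaves per-tree leaf cap (default 8).
#' @param control an [anneal_control()].
#' @param keep_data keep the training data inside the model (needed for OOB
#'   and importance computations; default `TRUE`).
#' @return an object of class `logic_forest`.
#' @seealso [importance.logic_forest()], [oob_misclassification()],
#'   [permutation_pvalues()]
#' @export
logic_forest <- function(x, y = NULL, B = 200, max_leaves = 8,
                         control = anneal_control(), keep_data = TRUE) {
  data <- if (inherits(x, "lf_data")) x else lf_data(x, y)
  stopifnot(B >= 1, data$p >= 1)
  if (data$n < 10) stop("need at least 10 subjects to fit a forest")
  n <- data$n
  trees <- vector("list", B)
  inbag <- vector("list", B)
  oob <- vector("list", B)
  keys <- vector("list", B)
  terms <- list()
  for (b in seq_len(B)) {
    repeat {
      rows <- sample.int(n, n, replace = TRUE)
      ob <- setdiff(seq_len(n), rows)
      if (length(ob)) break
      message("bootstrap draw ", b, " had empty OOB set; redrawn")
    }
    tr <- fit_logic_tree(data, max_leaves = max_leaves, control = control,
                         rows = rows)
    dnf <- to_dnf(tr)
    kk <- vapply(dnf, pi_key, "")
    for (i in seq_along(kk))
      if (is.null(terms[[kk[i]]])) terms[[kk[i]]] <- dnf[[i]]
    trees[[b]] <- tr
    inbag[[b]] <- rows
    oob[[b]] <- ob
    keys[[b]] <- kk
  }
  model <- structure(list(
    trees = trees, inbag = inbag, oob = oob, pi_keys = keys,
    pi_terms = terms, B = B, n = n, p = data$p, max_leaves = max_leaves,
    control = control, descriptors = data$descriptors,
    data = if (keep_data) data,
    call = match.call()), class = "logic_forest")
  model$tree_oob_err <- vapply(seq_len(B), function(b)
    tree_oob_misclassification(model, b), 0)
  model
}

.model_data <- function(model, data = NULL) {
  data <- data %||% model$data
  if (is.null(data))
    stop("model was fitted with keep_data = FALSE; supply the data")
  data
}

#' Out-of-bag predictions (ensemble vote over OOB trees)
#'
#' For each subject, the vote share among the trees whose OOB set contains
#' the subject; the predicted class is 1 when the share is >= 0.5.  Subjects
#' that are out-of-bag in no tree get `NA` and are flagged with a warning.
#'
#' @param model a fitted [logic_forest()].
#' @param data the training [lf_data()] (only needed if the model did not
#'   keep it).
#' @return integer 0/1/NA vector with attribute `"share"` (the OOB vote
#'   shares) and `"n_oob"` (per-subject OOB tree counts).
#' @export
oob_predict <- function(model, data = NULL) {
  data <- .model_data(model, data)
  votes <- numeric(model$n)
  cnt <- integer(model$n)
  for (b in seq_len(model$B)) {
    ob <- model$oob[[b]]
    votes[ob] <- votes[ob] + evaluate_tree(model$trees[[b]], data$x, ob)
    cnt[ob] <- cnt[ob] + 1L
  }
  share <- ifelse(cnt > 0, votes / cnt, NA_real_)
  pred <- ifelse(is.na(share), NA_integer_, as.integer(share >= 0.5))
  if (anyNA(pred))
    warning(sum(is.na(pred)), " subject(s) out-of-bag in no tree; excluded ",
            "from OOB metrics", call. = FALSE)
  structure(pred, share = share, n_oob = cnt)
}

#' Forest out-of-bag misclassification
#'
#' Mean of (y - yhat_OOB)^2 over subjects with at least one OOB vote --
#' identical to the mismatch fraction for binary outcomes.
#'
#' @inheritParams oob_predict
#' @return fraction in [0, 1].
#' @export
oob_misclassification <- function(model, data = NULL) {
  data <- .model_data(model, data)
  pred <- oob_predict(model, data)
  ok <- !is.na(pred)
  mean((data$y[ok] - pred[ok])^2)
}

#' Per-tree out-of-bag misclassification
#'
#' Mismatch fraction of tree `b` on its own OOB subjects, optionally with a
#' replacement predictor matrix (used for permutation importance).
#'
#' @inheritParams oob_predict
#' @param b tree index.
#' @param x_override optional predictor matrix evaluated in place of the
#'   training matrix (same dimensions).
#' @return fraction in [0, 1].
#' @export
tree_oob_misclassification <- function(model, b, data = NULL,
                                       x_override = NULL) {
  data <- .model_data(model, data)
  stopifnot(b >= 1, b <= model$B)
  ob <- model$oob[[b]]
  x <- x_override %||% data$x
  pred <- evaluate_tree(model$trees[[b]], x, ob)
  mean((data$y[ob] - pred)^2)
}

#' Permutation importance (VI1) of a prime implicant
#'
#' The average, over all `B` trees, of the increase in per-tree OOB
#' misclassification after the predictor column(s) making up the prime
#' implicant are permuted by one shared random row permutation -- the
#' implicant's internal joint distribution is preserved while its
#' association with the outcome and the remaining predictors is broken.
#' Ranges over [-1, 1]; a predictor used by no tree scores exactly 0.
#'
#' @inheritParams oob_predict
#' @param term prime implicant as a signed integer vector or canonical key
#'   (see [pi_key()]).
#' @param n_reps number of independent permutations to average over.
#' @return the VI1 value.
#' @export
vi_permutation <- function(model, term, data = NULL, n_reps = 1) {
  data <- .model_data(model, data)
  if (is.character(term)) term <- pi_from_key(term)
  cols <- unique(abs(term))
  if (any(cols > data$p)) stop("prime implicant references unknown columns")
  used <- vapply(seq_len(model$B), function(b) {
    any(abs(unlist(lapply(model$pi_keys[[b]], pi_from_key))) %in% cols)
  }, TRUE)
  if (!any(used)) return(0)  # predictions cannot change
  out <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    perm <- sample.int(data$n)
    xp <- data$x
    xp[, cols] <- xp[perm, cols, drop = FALSE]
    delta <- vapply(seq_len(model$B), function(b) {
      if (!used[b]) return(0)
      tree_oob_misclassification(model, b, data, x_override = xp) -
        model$tree_oob_err[b]
    }, 0)
    out[r] <- mean(delta)
  }
  mean(out)
}

#' Frequency importance (VI2) of a prime implicant
#'
#' The fraction of trees whose disjunctive normal form contains the prime
#' implicant (canonical-key equality), i.e. tree count / B.
#'
#' @inheritParams vi_permutation
#' @return fraction in [0, 1].
#' @export
vi_frequency <- function(model, term) {
  key <- if (is.character(term)) term else pi_key(term)
  mean(vapply(model$pi_keys, function(k) key %in% k, TRUE))
}

#' Importance of every prime implicant and predictor in a forest
#'
#' Aggregates the forest: every unique prime implicant across the trees'
#' DNFs gets its VI1 (permutation) and VI2 (frequency) importance and tree
#' count; separately, every individual predictor gets the same record (a
#' predictor occurs in a tree when any of the tree's implicants contains
#' it, complemented or not, and its VI1 permutes that single column).
#' `normalized_vi1` is VI1 divided by the maximum absolute VI1 of the same
#' table (a reporting convention; the two tables are normalized
#' independently).  Rows are sorted by (VI1, VI2) descending.
#'
#' @param model a fitted [logic_forest()].
#' @param data training data if not kept in the model.
#' @param n_reps permutations per VI1 evaluation.
#' @param ... unused.
#' @return list of class `lf_importance` with data.frames `pi` and
#'   `predictors`.
#' @export
importance <- function(model, ...) UseMethod("importance")

#' @rdname importance
#' @export
importance.logic_forest <- function(model, data = NULL, n_reps = 1, ...) {
  data <- .model_data(model, data)
  all_keys <- unique(unlist(model$pi_keys))
  tree_count <- vapply(all_keys, function(k)
    sum(vapply(model$pi_keys, function(kk) k %in% kk, TRUE)), 0L)
  vi1 <- vapply(all_keys, function(k)
    vi_permutation(model, k, data, n_reps), 0)
  pi_tab <- data.frame(
    pi = all_keys,
    label = vapply(all_keys, function(k)
      pi_render(k, model$descriptors), ""),
    n_literals = vapply(all_keys, function(k) length(pi_from_key(k)), 0L),
    tree_count = tree_count, vi2 = tree_count / model$B, vi1 = vi1,
    stringsAsFactors = FALSE, row.names = NULL)

  # predictor-level: union of DNF literal columns per tree
  tree_pred <- lapply(model$pi_keys, function(kk)
    unique(abs(unlist(lapply(kk, pi_from_key)))))
  preds <- sort(unique(unlist(tree_pred)))
  pcount <- vapply(preds, function(j)
    sum(vapply(tree_pred, function(v) j %in% v, TRUE)), 0L)
  pvi1 <- vapply(preds, function(j)
    vi_permutation(model, j, data, n_reps), 0)
  pred_tab <- data.frame(
    predictor = colnames(data$x)[preds],
    column = preds, tree_count = pcount, vi2 = pcount / model$B,
    vi1 = pvi1, stringsAsFactors = FALSE, row.names = NULL)

  norm <- function(v) if (all(v == 0)) v else v / max(abs(v))
  pi_tab$normalized_vi1 <- norm(pi_tab$vi1)
  pred_tab$normalized_vi1 <- norm(pred_tab$vi1)
  pi_tab <- pi_tab[order(-pi_tab$vi1, -pi_tab$vi2), , drop = FALSE]
  pred_tab <- pred_tab[order(-pred_tab$vi1, -pred_tab$vi2), , drop = FALSE]
  pi_tab$rank <- seq_len(nrow(pi_tab))
  pred_tab$rank <- seq_len(nrow(pred_tab))
  rownames(pi_tab) <- rownames(pred_tab) <- NULL
  structure(list(pi = pi_tab, predictors = pred_tab, B = model$B),
            class = "lf_importance")
}

#' @export
print.lf_importance <- function(x, n = 10, ...) {
  cat("Prime implicants (", nrow(x$pi), " unique across ", x$B,
      " trees); top ", min(n, nrow(x$pi)), ":\n", sep = "")
  print(head(x$pi[, c("rank", "label", "tree_count", "vi2", "vi1")], n),
        row.names = FALSE)
  cat("\nPredictors; top ", min(n, nrow(x$predictors)), ":\n", sep = "")
  print(head(x$predictors[, c("rank", "predictor", "tree_count", "vi2",
                              "vi1")], n), row.names = FALSE)
  invisible(x)
}

#' Predict from a logic forest
#'
#' Vote share over all `B` trees; class label 1 when the share is >= 0.5.
#'
#' @param object a fitted [logic_forest()].
#' @param newdata binary predictor matrix (or [lf_data()]) with the model's
#'   predictor columns.
#' @param type `"class"` for 0/1 labels (with shares as attribute) or
#'   `"prob"` for the vote shares.
#' @param ... unused.
#' @export
predict.logic_forest <- function(object, newdata, type = c("class", "prob"),
                                 ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "lf_data")) newdata$x else as.matrix(newdata)
  nm <- model_colnames(object)
  if (!is.null(colnames(x)) && !is.null(nm)) {
    missing_cols <- setdiff(nm, colnames(x))
    if (length(missing_cols))
      stop("newdata lacks predictor column(s): ",
           paste(missing_cols, collapse = ", "))
    x <- x[, nm, drop = FALSE]
  }
  if (ncol(x) != object$p)
    stop("newdata must have ", object$p, " predictor columns")
  storage.mode(x) <- "integer"
  rows <- seq_len(nrow(x))
  votes <- numeric(nrow(x))
  for (b in seq_len(object$B))
    votes <- votes + cpp_eval_tree(object$trees[[b]], x, rows)
  share <- votes / object$B
  if (type == "prob") share
  else structure(as.integer(share >= 0.5), share = share)
}

model_colnames <- function(model) {
  if (!is.null(model$data)) colnames(model$data$x)
  else model$descriptors$name
}

#' @export
print.logic_forest <- function(x, ...) {
  cat("logic_forest: B =", x$B, "trees, n =", x$n, ", p =", x$p,
      ", max_leaves =", x$max_leaves, "\n")
  cat("  unique prime implicants:", length(x$pi_terms), "\n")
  if (!is.null(x$data))
    cat("  OOB misclassification:",
        sprintf("%.3f", oob_misclassification(x)), "\n")
  invisible(x)
}

#' @export
summary.logic_forest <- function(object, n_reps = 1, ...) {
  imp <- importance(object, n_reps = n_reps)
  mc <- if (!is.null(object$data)) oob_misclassification(object) else NA
  auc <- if (!is.null(object$data)) {
    sh <- attr(oob_predict(object), "share")
    ok <- !is.na(sh)
    if (length(unique(object$data$y[ok])) == 2)
      roc_auc(sh[ok], object$data$y[ok])$auc else NA
  } else NA
  structure(list(importance = imp, oob_mc = mc, auc = auc, B = object$B,
                 n = object$n, p = object$p), class = "summary.logic_forest")
}

#' @export
print.summary.logic_forest <- function(x, ...) {
  cat("Logic forest of", x$B, "trees on", x$n, "subjects,", x$p,
      "binary predictors\n")
  if (!is.na(x$oob_mc))
    cat(sprintf("OOB misclassification: %.3f   OOB ROC AUC: %.3f\n",
                x$oob_mc, x$auc))
  cat("\n")
  print(x$importance)
  invisible(x)
}

#' Frequency-versus-importance scatter of a fitted forest
#'
#' Plots tree count against normalized VI1 for prime implicants
#' (`what = "pi"`) or individual predictors (`what = "predictors"`), the
#' standard way of eyeballing which effects are both frequent and
#' influential.  The top `label_top` points are labelled.
#'
#' @param x a fitted [logic_forest()].
#' @param what `"pi"` or `"predictors"`.
#' @param imp optionally a precomputed [importance.logic_forest()] result.
#' @param label_top number of points to label (default 5).
#' @param ... passed to [plot()].
#' @export
plot.logic_forest <- function(x, what = c("pi", "predictors"), imp = NULL,
                              label_top = 5, ...) {
  what <- match.arg(what)
  imp <- imp %||% importance(x)
  tab <- imp[[what]]
  lab <- if (what == "pi") tab$label else tab$predictor
  plot(tab$tree_count, tab$normalized_vi1,
       xlab = "number of trees containing the term",
       ylab = "normalized permutation importance (VI1)", ...)
  top <- head(order(-tab$vi1), label_top)
  if (length(top))
    text(tab$tree_count[top], tab$normalized_vi1[top], lab[top],
         pos = 2, cex = 0.7)
  invisible(imp)
}

#' Save / load a logic forest as JSON
#'
#' The dump records trees, bootstrap and OOB index sets, per-tree prime
#' implicant keys and configuration; reloading reproduces every OOB
#' quantity exactly.  The training data itself is stored alongside so the
#' reloaded model is self-contained.
#'
#' @param model a fitted [logic_forest()].
#' @param path JSON file.
#' @export
lf_save <- function(model, path) {
  dump <- list(
    B = model$B, n = model$n, p = model$p, max_leaves = model$max_leaves,
    control = unclass(model$control),
    trees = lapply(model$trees, tree_to_list),
    inbag = model$inbag, oob = model$oob, pi_keys = model$pi_keys,
    tree_oob_err = model$tree_oob_err,
    descriptors = model$descriptors,
    x = if (!is.null(model$data)) model$data$x,
    colnames = if (!is.null(model$data)) colnames(model$data$x),
    y = if (!is.null(model$data)) model$data$y)
  jsonlite::write_json(dump, path, auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null")
  invisible(path)
}

#' @rdname lf_save
#' @export
lf_load <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = FALSE)
  iv <- function(v) vapply(v, function(e)
    if (is.null(e)) NA_integer_ else as.integer(e), 0L)
  lv <- function(v) vapply(v, function(e)
    if (is.null(e)) NA else as.logical(e), TRUE)
  trees <- lapply(d$trees, function(t) {
    ty <- iv(t$type)
    m <- length(ty)
    pad_i <- function(v) { o <- iv(v); if (length(o) < m) rep(NA_integer_, m) else o }
    pad_l <- function(v) { o <- lv(v); if (length(o) < m) rep(NA, m) else o }
    tree_from_list(list(type = ty, var = pad_i(t$var), neg = pad_l(t$neg),
                        left = pad_i(t$left), right = pad_i(t$right),
                        score = t$score))
  })
  desc <- do.call(rbind, lapply(d$descriptors, function(r)
    data.frame(name = r$name, origin = r$origin,
               source_snp = r$source_snp %||% NA_character_,
               encoding = r$encoding, label_true = r$label_true,
               label_false = r$label_false, stringsAsFactors = FALSE)))
  data <- if (!is.null(d$x) && length(d$x)) {
    x <- do.call(rbind, lapply(d$x, iv))
    colnames(x) <- vapply(d$colnames, as.character, "")
    lf_data(x, iv(d$y), desc)
  }
  keys <- lapply(d$pi_keys, function(k)
    vapply(k, as.character, "", USE.NAMES = FALSE))
  terms <- list()
  for (kk in unique(unlist(keys))) terms[[kk]] <- pi_from_key(kk)
  ctl <- anneal_control(
    iterations = d$control$iterations,
    t_start = d$control$t_start,
    accept_end = d$control$accept_end, pilot = d$control$pilot)
  structure(list(
    trees = trees, inbag = lapply(d$inbag, iv), oob = lapply(d$oob, iv),
    pi_keys = keys, pi_terms = terms, B = as.integer(d$B),
    n = as.integer(d$n), p = as.integer(d$p),
    max_leaves = as.integer(d$max_leaves), control = ctl,
    descriptors = desc, data = data,
    tree_oob_err = vapply(d$tree_oob_err, as.numeric, 0),
    call = NULL), class = "logic_forest")
}
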