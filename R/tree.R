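# Logic trees are stored flat: parallel vectors over nodes in preorder with
# the root at index 1.  type: 0 leaf, 1 AND, 2 OR; leaves carry `var`
# (1-based predictor column) and `neg`; internal nodes carry child indices.
# This is the same layout the C++ annealing core uses, so trees cross the
# boundary without translation.

.new_tree <- function(type, var, neg, left, right, score = NULL) {
  structure(list(type = as.integer(type), var = as.integer(var),
                 neg = as.logical(neg), left = as.integer(left),
                 right = as.integer(right), score = score),
            class = "logic_tree")
}

#' Build logic trees by hand
#'
#' Constructors for single literals and AND/OR joins, mainly for tests,
#' examples, and programmatic tree surgery.  `lt_leaf(3, neg = TRUE)` is the
#' complement of predictor 3; `lt_and()`/`lt_or()` join two trees.
#'
#' @param var 1-based predictor column index.
#' @param neg logical; `TRUE` for the complemented literal.
#' @param a,b `logic_tree` objects to join.
#' @return a `logic_tree`.
#' @export
lt_leaf <- function(var, neg = FALSE)
  .new_tree(0L, var, neg, NA, NA)

#' @rdname lt_leaf
#' @export
lt_and <- function(a, b) .lt_join(1L, a, b)

#' @rdname lt_leaf
#' @export
lt_or <- function(a, b) .lt_join(2L, a, b)

.lt_join <- function(op, a, b) {
  stopifnot(inherits(a, "logic_tree"), inherits(b, "logic_tree"))
  na <- length(a$type)
  .new_tree(c(op, a$type, b$type),
            c(NA, a$var, b$var),
            c(NA, a$neg, b$neg),
            c(2L, a$left + 1L, b$left + 1L + na),
            c(2L + na, a$right + 1L, b$right + 1L + na))
}

#' Number of leaves of a logic tree
#' @param tree a `logic_tree`.
#' @export
n_leaves <- function(tree) sum(tree$type == 0L)

#' Evaluate a logic tree on a binary predictor matrix
#'
#' Standard Boolean evaluation: a leaf returns its predictor column (or
#' 1 - column when complemented); AND/OR combine children elementwise.
#'
#' @param tree a `logic_tree`.
#' @param x binary integer matrix or an [lf_data()].
#' @param rows optional row indices to evaluate (default all).
#' @return integer 0/1 vector.
#' @export
evaluate_tree <- function(tree, x, rows = NULL) {
  if (inherits(x, "lf_data")) x <- x$x
  storage.mode(x) <- "integer"
  rows <- if (is.null(rows)) seq_len(nrow(x)) else as.integer(rows)
  if (any(tree$var > ncol(x), na.rm = TRUE))
    stop("tree references predictor columns beyond ncol(x)")
  cpp_eval_tree(tree, x, rows)
}

#' In-sample misclassification of a tree
#'
#' Mean of (y - yhat)^2 over the given rows, identical to the mismatch
#' fraction for binary y; this is the annealing objective.
#'
#' @param tree a `logic_tree`.
#' @param data an [lf_data()].
#' @param rows optional row indices (e.g. a bootstrap sample).
#' @return fraction in [0, 1].
#' @export
score_tree <- function(tree, data, rows = NULL) {
  rows <- if (is.null(rows)) seq_len(data$n) else as.integer(rows)
  mean((data$y[rows] - evaluate_tree(tree, data$x, rows))^2)
}

#' One random move of the tree-search kernel
#'
#' Applies one move drawn uniformly from the legal subset of the classical
#' logic-regression move set: alternate-leaf (replace a leaf's literal,
#' complement toggles included), alternate-operator, split-leaf,
#' grow-branch, delete-leaf, prune-branch.  Growth moves are illegal at
#' `max_leaves` leaves; removal moves are illegal on a single leaf, so the
#' result is never empty.
#'
#' @param tree a `logic_tree`.
#' @param p number of predictor columns.
#' @param max_leaves leaf cap (default 8).
#' @return a new `logic_tree`.
#' @export
propose_tree_move <- function(tree, p, max_leaves = 8) {
  out <- cpp_propose_move(tree, as.integer(p), as.integer(max_leaves))
  .new_tree(out$type, out$var, out$neg, out$left, out$right)
}

#' Annealing schedule parameters
#'
#' @param iterations number of annealing proposals (default 25000).
#' @param t_start start temperature; `NULL` calibrates it from a pilot of
#'   random moves so that roughly half of typical worsening moves are
#'   accepted.
#' @param accept_end target acceptance probability for a typical worsening
#'   move at the final temperature (default 0.01); cooling is geometric.
#' @param pilot number of pilot moves for temperature calibration.
#' @return list of class `anneal_control`.
#' @export
anneal_control <- function(iterations = 25000, t_start = NULL,
                           accept_end = 0.01, pilot = 100) {
  stopifnot(iterations >= 1, accept_end > 0, accept_end < 1, pilot >= 1)
  structure(list(iterations = as.integer(iterations),
                 t_start = t_start, accept_end = accept_end,
                 pilot = as.integer(pilot)),
            class = "anneal_control")
}

#' Fit a single logic tree by simulated annealing
#'
#' Minimises in-sample misclassification over AND/OR trees of at most
#' `max_leaves` literal leaves, starting from a random single leaf and
#' accepting worsening moves with probability exp(-delta/t) under a
#' geometric cooling schedule.  The best state visited is returned (score
#' ties prefer fewer leaves).  Results are reproducible under `set.seed()`.
#'
#' @param data an [lf_data()] (or binary matrix `x` with `y` supplied).
#' @param y outcome when `data` is a plain matrix.
#' @param max_leaves leaf cap (default 8).
#' @param control an [anneal_control()].
#' @param rows row indices to fit on (e.g. a bootstrap sample); default all.
#' @return a `logic_tree` with the achieved `score`.
#' @export
fit_logic_tree <- function(data, y = NULL, max_leaves = 8,
                           control = anneal_control(), rows = NULL) {
  if (!inherits(data, "lf_data")) data <- lf_data(data, y)
  rows <- if (is.null(rows)) seq_len(data$n) else as.integer(rows)
  yr <- data$y[rows]
  if (all(yr == yr[1])) {
    warning("outcome is constant on the fitting rows; returning the best ",
            "single-leaf tree", call. = FALSE)
    best <- NULL
    best_bad <- Inf
    for (j in seq_len(data$p)) for (ng in c(FALSE, TRUE)) {
      tr <- lt_leaf(j, ng)
      bad <- sum(yr != evaluate_tree(tr, data$x, rows))
      if (bad < best_bad) { best <- tr; best_bad <- bad }
    }
    best$score <- best_bad / length(rows)
    return(best)
  }
  out <- cpp_fit_tree(data$x, data$y, rows, as.integer(max_leaves),
                      control$iterations,
                      if (is.null(control$t_start)) -1 else control$t_start,
                      control$accept_end, control$pilot)
  .new_tree(out$type, out$var, out$neg, out$left, out$right,
            score = out$score)
}

## ---- prime implicants / DNF ----

# A term is a sorted integer vector: +j for predictor j, -j for its
# complement.  Canonical keys are the terms pasted, so equal literal sets
# compare equal regardless of construction order.

.term_sort <- function(t) t[order(abs(t), t)]

#' Canonical key of a prime-implicant term
#' @param term signed integer vector (+j predictor, -j complement).
#' @export
pi_key <- function(term) paste(.term_sort(term), collapse = " ")

#' Parse a canonical key back to a term
#' @param key string produced by [pi_key()].
#' @export
pi_from_key <- function(key) as.integer(strsplit(key, " ", fixed = TRUE)[[1]])

#' Disjunctive normal form of a logic tree
#'
#' Recursively distributes AND over OR: the DNF of a leaf is the literal
#' itself, OR takes the union of the children's terms, AND the pairwise
#' conjunctions.  Terms containing a literal and its complement are dropped,
#' duplicate literals merged, duplicate terms collapsed, and absorbed terms
#' (strict supersets of another term) removed.  The surviving conjunctions
#' are the tree's prime implicants; evaluated as an OR of ANDs they
#' reproduce the tree on every input.
#'
#' @param tree a `logic_tree`.
#' @return list of signed-integer terms (possibly empty for a contradictory
#'   tree).
#' @export
to_dnf <- function(tree) {
  rec <- function(i) {
    if (tree$type[i] == 0L)
      return(list(if (tree$neg[i]) -tree$var[i] else tree$var[i]))
    l <- rec(tree$left[i])
    r <- rec(tree$right[i])
    if (tree$type[i] == 2L) return(c(l, r))
    out <- list()
    for (a in l) for (b in r) {
      t <- unique(.term_sort(c(a, b)))
      if (any(t %in% -t)) next  # contradictory conjunction
      out[[length(out) + 1L]] <- t
    }
    out
  }
  terms <- rec(1L)
  if (!length(terms)) return(list())
  terms <- terms[!duplicated(vapply(terms, pi_key, ""))]
  # absorption: drop terms that strictly contain another term
  keep <- rep(TRUE, length(terms))
  for (i in seq_along(terms)) for (j in seq_along(terms)) {
    if (i == j || !keep[i] || !keep[j]) next
    if (length(terms[[j]]) < length(terms[[i]]) &&
        all(terms[[j]] %in% terms[[i]]))
      keep[i] <- FALSE
  }
  terms[keep]
}

#' Evaluate a prime implicant (conjunction of literals)
#' @param term signed integer vector.
#' @param x binary matrix or [lf_data()].
#' @return integer 0/1 indicator per row.
#' @export
pi_indicator <- function(x, term) {
  if (is.character(term) && length(term) == 1) term <- pi_from_key(term)
  if (inherits(x, "lf_data")) x <- x$x
  out <- rep(1L, nrow(x))
  for (l in term)
    out <- out & (if (l > 0) x[, l] else 1L - x[, -l])
  as.integer(out)
}

#' Render a prime implicant for humans
#' @param term signed integer vector or canonical key.
#' @param descriptors descriptor data.frame from an [lf_data()]; `NULL`
#'   falls back to `x<j>` / `!x<j>`.
#' @export
pi_render <- function(term, descriptors = NULL) {
  if (is.character(term) && length(term) == 1) term <- pi_from_key(term)
  term <- .term_sort(term)
  lit <- vapply(term, function(l) {
    j <- abs(l)
    if (is.null(descriptors)) {
      if (l > 0) paste0("x", j) else paste0("!x", j)
    } else if (l > 0) descriptors$label_true[j] else descriptors$label_false[j]
  }, "")
  paste(lit, collapse = " & ")
}

## ---- serialization ----

#' @export
format.logic_tree <- function(x, labels = NULL, ...) {
  rec <- function(i) {
    if (x$type[i] == 0L) {
      nm <- if (is.null(labels)) paste0("x", x$var[i]) else labels[x$var[i]]
      return(paste0(if (x$neg[i]) "!" else "", nm))
    }
    op <- if (x$type[i] == 1L) " AND " else " OR "
    paste0("(", rec(x$left[i]), op, rec(x$right[i]), ")")
  }
  rec(1L)
}

#' @export
print.logic_tree <- function(x, labels = NULL, ...) {
  cat("logic_tree [", n_leaves(x), "leaves ]:", format(x, labels), "\n")
  if (!is.null(x$score)) cat("  score:", x$score, "\n")
  invisible(x)
}

#' Serialize / parse logic trees as text
#'
#' `deparse_tree()` writes the parenthesized form, e.g.
#' `((psc AND !snp1_R) OR snp2_R)`; `parse_tree()` reads it back, resolving
#' names against `labels` (defaults to `x1`, `x2`, ...).  The two functions
#' round-trip.
#'
#' @param tree a `logic_tree`.
#' @param text serialized tree text.
#' @param labels character vector of predictor names (position = column).
#' @export
deparse_tree <- function(tree, labels = NULL) format(tree, labels)

#' @rdname deparse_tree
#' @export
parse_tree <- function(text, labels = NULL) {
  toks <- regmatches(text, gregexpr("\\(|\\)|AND|OR|![A-Za-z0-9_.:-]+|[A-Za-z0-9_.:-]+",
                                    text))[[1]]
  toks <- toks[!(toks %in% c("")) ]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else ""
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  leaf_of <- function(tok) {
    neg <- startsWith(tok, "!")
    nm <- sub("^!", "", tok)
    j <- if (is.null(labels)) {
      if (!grepl("^x[0-9]+$", nm))
        stop("unknown predictor '", nm, "' (no labels supplied)")
      as.integer(sub("^x", "", nm))
    } else match(nm, labels)
    if (is.na(j)) stop("unknown predictor name: ", nm)
    lt_leaf(j, neg)
  }
  expr <- function() {
    if (peek() == "(") {
      take()
      a <- expr()
      op <- take()
      if (!op %in% c("AND", "OR")) stop("expected AND/OR, got '", op, "'")
      b <- expr()
      if (take() != ")") stop("expected ')'")
      if (op == "AND") lt_and(a, b) else lt_or(a, b)
    } else leaf_of(take())
  }
  out <- expr()
  if (pos <= length(toks)) stop("trailing tokens in tree text")
  out
}

#' @rdname deparse_tree
#' @param x a `logic_tree` (for `tree_to_list`).
#' @param node_list list produced by `tree_to_list`.
#' @export
tree_to_list <- function(x)
  list(type = x$type, var = x$var, neg = x$neg, left = x$left,
       right = x$right, score = x$score)

#' @rdname deparse_tree
#' @export
tree_from_list <- function(node_list)
  .new_tree(node_list$type, node_list$var, node_list$neg, node_list$left,
            node_list$right, score = node_list$score %||% NULL)
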