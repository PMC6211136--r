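#' Permutation p-values for prime implicants
#'
#' For each of `n_perm` permutations the outcome vector is shuffled
#' uniformly, a fresh forest of `B` trees is fitted to the permuted data,
#' and the chosen importance measure is computed for every target prime
#' implicant -- zero when the implicant appears in no tree of the permuted
#' forest, since the forest then carries no evidence for it.  The p-value
#' is the proportion of permuted forests whose importance meets or exceeds
#' the observed one.  Its resolution is 1/n_perm; a zero exceedance count
#' is displayed as "< 1/n_perm".  With `plus_one = TRUE` the small-sample
#' corrected (count + 1)/(n_perm + 1) is reported instead.
#'
#' Permuted refits default to a shorter annealing schedule than the
#' original fit to keep many refits tractable; pass `control` to override.
#'
#' @param model the fitted [logic_forest()] on the original data.
#' @param terms prime implicants to test: list of signed integer vectors or
#'   canonical keys; default the implicants of the original model ranked
#'   first by an [importance.logic_forest()] call, capped at `top_k`.
#' @param data training data if the model did not keep it.
#' @param n_perm number of outcome permutations (default 500).
#' @param B trees per permuted forest (default: the model's B).
#' @param measure importance measure for the exceedance comparison:
#'   `"vi1"` (default) or `"vi2"`; the other is computed alongside and
#'   reported.
#' @param control [anneal_control()] for the permuted refits (default a
#'   quarter of the model's iterations).
#' @param top_k how many top implicants to test when `terms` is NULL.
#' @param plus_one use the (count+1)/(n_perm+1) correction.
#' @param imp optional precomputed importance table (to avoid recomputing
#'   observed VI1 values).
#' @return data.frame of class `lf_permtest`: one row per term with
#'   `observed`, `exceed`, `n_perm`, `perm_p`, `perm_p_display`.
#' @export
permutation_pvalues <- function(model, terms = NULL, data = NULL,
                                n_perm = 500, B = NULL,
                                measure = c("vi1", "vi2"),
                                control = NULL, top_k = 10,
                                plus_one = FALSE, imp = NULL) {
  measure <- match.arg(measure)
  data <- .model_data(model, data)
  B <- B %||% model$B
  control <- control %||% anneal_control(
    iterations = max(500L, model$control$iterations %/% 4L),
    pilot = model$control$pilot)
  if (is.null(terms)) {
    imp <- imp %||% importance(model, data)
    terms <- as.list(head(imp$pi$pi, top_k))
  }
  keys <- vapply(terms, function(t)
    if (is.character(t)) t else pi_key(t), "")
  absent <- !(keys %in% unlist(model$pi_keys))
  if (any(absent))
    stop("term(s) absent from the original model: ",
         paste(keys[absent], collapse = "; "))

  observed <- vapply(keys, function(k) {
    if (measure == "vi1") {
      if (!is.null(imp)) {
        hit <- match(k, imp$pi$pi)
        if (!is.na(hit)) return(imp$pi$vi1[hit])
      }
      vi_permutation(model, k, data)
    } else vi_frequency(model, k)
  }, 0)

  exceed <- integer(length(keys))
  for (r in seq_len(n_perm)) {
    yp <- sample(data$y)
    dp <- lf_data(data$x, yp, data$descriptors)
    fp <- logic_forest(dp, B = B, max_leaves = model$max_leaves,
                       control = control)
    for (i in seq_along(keys)) {
      k <- keys[i]
      present <- any(vapply(fp$pi_keys, function(kk) k %in% kk, TRUE))
      val <- if (!present) 0
             else if (measure == "vi1") vi_permutation(fp, k, dp)
             else vi_frequency(fp, k)
      if (val >= observed[i]) exceed[i] <- exceed[i] + 1L
    }
  }
  p <- if (plus_one) (exceed + 1) / (n_perm + 1) else exceed / n_perm
  disp <- ifelse(exceed == 0 & !plus_one,
                 paste0("< ", format(1 / n_perm, digits = 3)),
                 format(p, digits = 3))
  out <- data.frame(
    pi = keys,
    label = vapply(keys, function(k) pi_render(k, model$descriptors), ""),
    measure = measure, observed = observed, exceed = exceed,
    n_perm = n_perm, perm_p = p, perm_p_display = disp,
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("lf_permtest", "data.frame")
  out
}

#' @export
print.lf_permtest <- function(x, ...) {
  cat("Permutation test (", x$n_perm[1], " outcome permutations, measure ",
      x$measure[1], "):\n", sep = "")
  print(data.frame(label = x$label,
                   observed = signif(x$observed, 3),
                   perm_p = x$perm_p_display), row.names = FALSE)
  invisible(x)
}
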