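#' Configuration for a synthetic case-control study
#'
#' Describes a simulated study shaped like a candidate-gene G x E
#' case-control analysis: independent (or block-correlated) Hardy-Weinberg
#' genotypes at given minor-allele frequencies, independent binary
#' exposures at given prevalences, and a disease outcome drawn from a
#' logistic model with planted Boolean risk terms over the
#' recessive-encoded predictors.
#'
#' Defaults mirror a ~200-subject study with 148 SNPs and five binary
#' exposure/demographic variables (childhood and adult passive smoke,
#' ever/current smoker, female) at the pooled prevalences of such a cohort,
#' with no planted effects.  When `snp_mafs` is `NULL`, frequencies are
#' drawn uniformly on [0.1, 0.5] at generation time.
#'
#' @param n_subjects number of subjects (default 204).
#' @param n_snps number of SNPs (default 148).
#' @param snp_mafs per-SNP minor-allele frequencies in (0, 0.5], or `NULL`
#'   to draw them uniformly on [0.1, 0.5].
#' @param ld_blocks optional list of `list(size =, rho =)` blocks of
#'   adjacent SNPs with within-block haplotype correlation `rho`; SNPs not
#'   covered by a block are independent.
#' @param exposure_prev named vector of exposure prevalences in (0, 1).
#' @param truth list of planted terms, each `list(term =, beta =)` where
#'   `term` is a character vector of encoded predictor names (prefix `!`
#'   for the complement, e.g. `c("psc", "!snp001_R")`) and `beta` a finite
#'   log-odds effect.
#' @param baseline_log_odds intercept of the outcome model (default
#'   `qlogis(0.49)`, matching a balanced case-control-sized cohort when no
#'   terms are planted).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 204, n_snps = 148, snp_mafs = NULL,
                       ld_blocks = NULL,
                       exposure_prev = c(psc = 0.338, psa = 0.186,
                                         ever_smoker = 0.235,
                                         current_smoker = 0.147,
                                         female = 0.858),
                       truth = list(), baseline_log_odds = qlogis(0.49)) {
  stopifnot(n_subjects >= 1, n_snps >= 1)
  if (!is.null(snp_mafs)) {
    stopifnot(length(snp_mafs) == n_snps)
    if (any(snp_mafs <= 0 | snp_mafs > 0.5))
      stop("snp_mafs must lie in (0, 0.5]")
  }
  if (any(exposure_prev <= 0 | exposure_prev >= 1))
    stop("exposure prevalences must lie in (0, 1)")
  if (is.null(names(exposure_prev)) || any(names(exposure_prev) == ""))
    stop("exposure_prev must be a named vector")
  for (t in truth) {
    if (!is.list(t) || is.null(t$term) || is.null(t$beta))
      stop("each truth entry needs $term and $beta")
    if (!is.finite(t$beta)) stop("planted effects must be finite")
  }
  if (!is.null(ld_blocks)) {
    covered <- sum(vapply(ld_blocks, function(b) b$size, 0))
    if (covered > n_snps) stop("LD blocks cover more SNPs than exist")
    for (b in ld_blocks)
      if (b$rho < 0 || b$rho >= 1) stop("LD rho must lie in [0, 1)")
  }
  structure(list(n_subjects = n_subjects, n_snps = n_snps,
                 snp_mafs = snp_mafs, ld_blocks = ld_blocks,
                 exposure_prev = exposure_prev, truth = truth,
                 baseline_log_odds = baseline_log_odds),
            class = "sim_config")
}

.snp_names <- function(n) sprintf("snp%03d", seq_len(n))

#' Generate Hardy-Weinberg genotypes
#'
#' Each SNP's dosage is the sum of two allele draws at its minor-allele
#' frequency, giving the HWE genotype probabilities (q^2, 2pq, p^2).  LD
#' blocks are generated by thresholding correlated latent Gaussian vectors
#' per haplotype, so the realized pairwise genotype correlation
#' approximates the requested within-block value while the per-SNP margins
#' stay at HWE.  Positions are synthesized as 8 equal gene regions on
#' chromosomes 1-8 so that region filters are exercisable.
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()].
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  m <- config$n_snps
  mafs <- config$snp_mafs %||% runif(m, 0.1, 0.5)
  # block structure: list of index vectors with a common rho
  blocks <- list()
  idx <- 1L
  for (b in config$ld_blocks %||% list()) {
    blocks[[length(blocks) + 1L]] <- list(cols = idx:(idx + b$size - 1L),
                                          rho = b$rho)
    idx <- idx + b$size
  }
  if (idx <= m) blocks[[length(blocks) + 1L]] <- list(cols = idx:m, rho = 0)

  haplotype <- function() {
    h <- matrix(0L, n, m)
    for (bl in blocks) {
      k <- length(bl$cols)
      z <- matrix(rnorm(n * k), n, k)
      if (bl$rho > 0) {
        shared <- rnorm(n)
        z <- sqrt(bl$rho) * shared + sqrt(1 - bl$rho) * z
      }
      h[, bl$cols] <- sweep(z, 2, qnorm(mafs[bl$cols]), `<`) * 1L
    }
    h
  }
  dos <- haplotype() + haplotype()
  storage.mode(dos) <- "integer"
  rownames(dos) <- sprintf("S%04d", seq_len(n))
  colnames(dos) <- .snp_names(m)

  gene <- sort(rep_len(seq_len(min(8, m)), m))
  within <- unlist(lapply(split(seq_len(m), gene), seq_along))
  positions <- data.frame(
    chrom = as.character(gene),
    pos = as.integer(100000 + (within - 1) * 1000),
    stringsAsFactors = FALSE)
  genotype_matrix(dos, positions = positions)
}

#' Draw a disease outcome from a logistic model with Boolean terms
#'
#' P(y = 1) = plogis(baseline + sum of beta * I(term true)); terms are
#' conjunctions over named binary columns of `x`, `!` prefix denoting the
#' complement.
#'
#' @param x binary matrix with column names (the encoded predictors).
#' @param truth list of `list(term =, beta =)` entries.
#' @param baseline_log_odds intercept.
#' @return integer 0/1 outcome vector.
#' @export
generate_outcome <- function(x, truth, baseline_log_odds) {
  eta <- rep(baseline_log_odds, nrow(x))
  for (t in truth) {
    ind <- rep(1L, nrow(x))
    for (nm in t$term) {
      neg <- startsWith(nm, "!")
      col <- sub("^!", "", nm)
      if (!col %in% colnames(x))
        stop("truth term references unknown column: ", col)
      v <- x[, col]
      ind <- ind & (if (neg) 1L - v else v)
    }
    eta <- eta + t$beta * as.integer(ind)
  }
  as.integer(rbinom(nrow(x), 1, plogis(eta)))
}

#' Generate a full synthetic study
#'
#' Draws genotypes and exposures, encodes the SNPs under the recessive
#' model to evaluate the planted terms, draws the outcome, and returns the
#' raw study pieces plus a ground-truth manifest (the planted implicants as
#' encoded-name terms, their signed-index form in the recessive-encoded
#' dataset, and their canonical keys) for downstream recovery scoring.
#' All randomness uses the current RNG state; wrap in `set.seed()` for
#' reproducibility.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_study` with `genotypes`
#'   ([genotype_matrix()]), `phenotypes` (`phenotype_table`), `truth`
#'   (manifest), `config`.
#' @export
sim_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gm <- generate_genotypes(config)
  n <- config$n_subjects
  ev <- config$exposure_prev
  expo <- vapply(names(ev), function(nm) rbinom(n, 1, ev[[nm]]), integer(n))
  rownames(expo) <- rownames(gm$dosage)

  # recessive encoding to evaluate planted terms
  enc <- lapply(colnames(gm$dosage), function(s)
    encode_snp(gm$dosage[, s], "recessive", snp = s))
  xg <- do.call(cbind, lapply(enc, `[[`, "columns"))
  x <- cbind(xg, expo)
  y <- generate_outcome(x, config$truth, config$baseline_log_odds)

  ph <- data.frame(subject_id = rownames(gm$dosage), status = y,
                   expo, stringsAsFactors = FALSE, check.names = FALSE)
  class(ph) <- c("phenotype_table", "data.frame")

  manifest <- lapply(config$truth, function(t) {
    signed <- vapply(t$term, function(nm) {
      neg <- startsWith(nm, "!")
      j <- match(sub("^!", "", nm), colnames(x))
      if (neg) -j else j
    }, 0L)
    list(term_names = t$term, beta = t$beta,
         term = .term_sort(signed), key = pi_key(signed))
  })
  structure(list(genotypes = gm, phenotypes = ph,
                 truth = manifest, config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("sim_study:", x$config$n_subjects, "subjects,", x$config$n_snps,
      "SNPs,", length(x$config$exposure_prev), "exposures;",
      sum(x$phenotypes$status), "cases\n")
  for (t in x$truth)
    cat("  planted:", paste(t$term_names, collapse = " & "),
        sprintf("(log-odds %.3f)\n", t$beta))
  invisible(x)
}

#' Write / read a simulation config as YAML
#'
#' Flat key-value serialization of a [sim_config()]; round-trips exactly.
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  obj <- unclass(config)
  obj$exposure_prev <- as.list(config$exposure_prev)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  sim_config(
    n_subjects = obj$n_subjects, n_snps = obj$n_snps,
    snp_mafs = if (!is.null(obj$snp_mafs)) as.numeric(obj$snp_mafs),
    ld_blocks = obj$ld_blocks,
    exposure_prev = unlist(obj$exposure_prev),
    truth = lapply(obj$truth, function(t)
      list(term = as.character(t$term), beta = as.numeric(t$beta))),
    baseline_log_odds = obj$baseline_log_odds)
}

#' Write a simulated study to disk
#'
#' Genotype TSV, phenotype TSV and a JSON truth manifest in `dir`.
#'
#' @param study a [sim_study()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- file.path(dir, "genotypes.tsv")
  p <- file.path(dir, "phenotypes.tsv")
  m <- file.path(dir, "truth.json")
  write_genotypes(study$genotypes, g)
  write_phenotypes(study$phenotypes, p)
  jsonlite::write_json(study$truth, m, auto_unbox = TRUE, digits = NA)
  invisible(c(genotypes = g, phenotypes = p, truth = m))
}
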