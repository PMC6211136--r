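#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Goodness of fit of observed genotype counts (hom-reference, het,
#' hom-alternate for one biallelic marker) to the Hardy-Weinberg proportions
#' (q^2, 2pq, p^2) at the allele frequency estimated from the same counts.
#' The default is the conventional 1-df chi-square without continuity
#' correction; `method = "exact"` gives the exact conditional test
#' (two-sided, summing the probabilities of all heterozygote counts no more
#' likely than the observed one, conditional on the allele counts).
#' A monomorphic marker returns p = 1 with `monomorphic = TRUE`.
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts.
#' @param method `"chisq"` (default) or `"exact"`.
#' @return list with `statistic` (chi-square only), `p.value`, `method`,
#'   `monomorphic`.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa, method = c("chisq", "exact")) {
  method <- match.arg(method)
  cnt <- c(n_AA, n_Aa, n_aa)
  if (any(cnt < 0) || sum(cnt) == 0)
    stop("genotype counts must be non-negative with positive total")
  n <- sum(cnt)
  nA <- 2 * n_AA + n_Aa
  if (nA == 0 || nA == 2 * n)
    return(list(statistic = 0, p.value = 1, method = method,
                monomorphic = TRUE))
  p <- nA / (2 * n)
  if (method == "chisq") {
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    stat <- sum((cnt - e)^2 / e)
    list(statistic = stat, p.value = pchisq(stat, df = 1, lower.tail = FALSE),
         method = "chisq", monomorphic = FALSE)
  } else {
    # exact conditional: enumerate heterozygote counts with the observed
    # parity, probabilities via log factorials
    nB <- 2 * n - nA
    nh_max <- min(nA, nB)
    nh <- seq(nA %% 2, nh_max, by = 2)
    logp <- lfactorial(n) - lfactorial((nA - nh) / 2) - lfactorial(nh) -
      lfactorial((nB - nh) / 2) + nh * log(2) +
      lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
    pr <- exp(logp - max(logp))
    pr <- pr / sum(pr)
    obs <- pr[match(n_Aa, nh)]
    list(statistic = NA_real_,
         p.value = min(1, sum(pr[pr <= obs + 1e-12])),
         method = "exact", monomorphic = FALSE)
  }
}

#' Minor allele frequency from genotype counts
#'
#' `min(f, 1 - f)` of the counted allele, so the result is orientation
#' invariant and lies in [0, 0.5].
#'
#' @inheritParams hwe_test
#' @return frequency in [0, 0.5].
#' @export
snp_maf <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("total genotype count must be positive")
  f <- (2 * n_aa + n_Aa) / (2 * n)
  min(f, 1 - f)
}

#' Marker quality control
#'
#' Applies the standard screening filters: Hardy-Weinberg equilibrium in
#' controls only (drop if p < `hwe_p_min`), minor allele frequency in all
#' subjects (drop if below `maf_min`), and per-marker missingness in all
#' subjects (drop if above `max_missing`; the default 0 drops any marker
#' with missing calls).  A marker is retained iff it passes every enabled
#' filter.
#'
#' @param gm a [genotype_matrix()].
#' @param controls subject ids (or logical/integer index) of controls; used
#'   for the HWE filter.
#' @param hwe_p_min HWE p-value floor (default 0.001); `NULL` disables.
#' @param maf_min MAF floor (default 0.05); `NULL` disables.
#' @param max_missing maximum tolerated missing fraction (default 0).
#' @param hwe_method passed to [hwe_test()].
#' @return list with `genotypes` (filtered [genotype_matrix()]) and
#'   `report` (data.frame of class `qc_report`, one row per input SNP).
#'   Errors (with the report attached to the condition) if no SNP survives.
#' @export
apply_qc <- function(gm, controls, hwe_p_min = 0.001, maf_min = 0.05,
                     max_missing = 0, hwe_method = c("chisq", "exact")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  hwe_method <- match.arg(hwe_method)
  dos <- gm$dosage
  if (is.character(controls)) controls <- rownames(dos) %in% controls
  ctl <- dos[controls, , drop = FALSE]
  if (!is.null(hwe_p_min) && nrow(ctl) == 0)
    stop("control subset is empty but the HWE filter is enabled")

  per_snp <- function(j) {
    v <- dos[, j]
    cv <- ctl[, j]
    cnt <- function(x) c(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                         sum(x == 2, na.rm = TRUE))
    ca <- cnt(v)
    cc <- cnt(cv)
    hw <- if (sum(cc) > 0) hwe_test(cc[1], cc[2], cc[3], hwe_method)
          else list(p.value = NA_real_, monomorphic = TRUE)
    data.frame(
      snp_id = colnames(dos)[j],
      maf = if (sum(ca) > 0) snp_maf(ca[1], ca[2], ca[3]) else NA_real_,
      hwe_p = hw$p.value,
      monomorphic = hw$monomorphic,
      missing_fraction = mean(is.na(v)),
      stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, lapply(seq_len(ncol(dos)), per_snp))
  rep$fail_hwe <- if (is.null(hwe_p_min)) FALSE
                  else !is.na(rep$hwe_p) & rep$hwe_p < hwe_p_min
  rep$fail_maf <- if (is.null(maf_min)) FALSE
                  else is.na(rep$maf) | rep$maf < maf_min
  rep$fail_missing <- rep$missing_fraction > max_missing
  rep$retained <- !(rep$fail_hwe | rep$fail_maf | rep$fail_missing)
  rep$fail_reasons <- apply(rep[, c("fail_hwe", "fail_maf", "fail_missing")],
                            1, function(f)
    paste(c("hwe", "maf", "missing")[f], collapse = ","))
  class(rep) <- c("qc_report", "data.frame")
  attr(rep, "thresholds") <- list(hwe_p_min = hwe_p_min, maf_min = maf_min,
                                  max_missing = max_missing,
                                  hwe_method = hwe_method)
  if (!any(rep$retained))
    stop(errorCondition("no SNP survives quality control",
                        report = rep, class = "logicgxe_qc_error"))
  keep <- rep$snp_id[rep$retained]
  out <- genotype_matrix(
    dos[, keep, drop = FALSE],
    alleles = if (!is.null(gm$alleles)) gm$alleles[keep, , drop = FALSE],
    positions = if (!is.null(gm$positions)) gm$positions[keep, , drop = FALSE])
  list(genotypes = out, report = rep)
}

#' Write a QC report as TSV
#' @param report a `qc_report` from [apply_qc()].
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  cols <- c("snp_id", "maf", "hwe_p", "missing_fraction", "fail_reasons",
            "retained")
  write.table(report[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read gene intervals from BED or 1-based TSV
#'
#' BED input (0-based, half-open) is converted to the package's internal
#' 1-based closed convention; TSV input (`chrom`, `start`, `end` header,
#' 1-based closed) is taken verbatim.
#'
#' @param path interval file.
#' @param format `"bed"` or `"tsv"`.
#' @return data.frame with `chrom`, `start`, `end` (1-based, closed) and
#'   `name` when available.
#' @export
read_gene_intervals <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- read.table(path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE)
    out <- data.frame(chrom = as.character(df[[1]]),
                      start = as.integer(df[[2]]) + 1L,
                      end = as.integer(df[[3]]),
                      stringsAsFactors = FALSE)
    if (ncol(df) >= 4) out$name <- as.character(df[[4]])
    message("read ", nrow(out),
            " interval(s) as BED (0-based half-open, converted to 1-based)")
  } else {
    out <- read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "start", "end") %in% names(out)))
    out$chrom <- as.character(out$chrom)
    message("read ", nrow(out), " interval(s) as 1-based closed TSV")
  }
  out
}

#' Restrict a genotype matrix to gene regions
#'
#' Keeps SNPs whose position falls inside any interval extended by `flank`
#' base pairs on both sides; intervals are 1-based and closed, and the
#' extended boundaries are inclusive.
#'
#' @param gm a [genotype_matrix()] with positions.
#' @param gene_intervals data.frame with `chrom`, `start`, `end`.
#' @param flank flanking width in bp (default 5000).
#' @return the filtered [genotype_matrix()].
#' @export
select_region <- function(gm, gene_intervals, flank = 5000) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$positions))
    stop("genotype matrix carries no positions; cannot window by region")
  pos <- gm$positions
  keep <- rep(FALSE, nrow(pos))
  for (k in seq_len(nrow(gene_intervals))) {
    g <- gene_intervals[k, ]
    keep <- keep | (pos$chrom == g$chrom &
                    pos$pos >= g$start - flank &
                    pos$pos <= g$end + flank)
  }
  ids <- rownames(pos)[keep]
  genotype_matrix(
    gm$dosage[, ids, drop = FALSE],
    alleles = if (!is.null(gm$alleles)) gm$alleles[ids, , drop = FALSE],
    positions = pos[ids, , drop = FALSE])
}
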