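#' Binary encodings of SNP dosage
#'
#' Turns a minor-allele dosage vector into indicator column(s):
#' \describe{
#'   \item{recessive}{1 iff two copies of the minor allele (dosage 2);
#'     the complement reads as ">= 1 copy of the major allele".}
#'   \item{dominant}{1 iff at least one copy of the minor allele.}
#'   \item{genotypic}{two indicators, 1 iff exactly one copy and 1 iff two
#'     copies, with zero copies as the reference.}
#' }
#' Missing dosages propagate to missing indicators (such subjects are
#' dropped at dataset assembly).
#'
#' @param dosages integer vector in \{0,1,2,NA\}.
#' @param scheme encoding scheme.
#' @param snp SNP name used for column naming and literal rendering.
#' @return list with `columns` (integer matrix, 1 or 2 columns) and
#'   `descriptors` (data.frame, one row per column).
#' @export
encode_snp <- function(dosages, scheme = c("recessive", "dominant",
                                           "genotypic"), snp = "snp") {
  scheme <- match.arg(scheme)
  if (!all(dosages %in% c(0L, 1L, 2L, NA)))
    stop("dosages must be 0, 1, 2 or NA")
  d <- as.integer(dosages)
  desc <- function(name, encoding, lab_true, lab_false)
    data.frame(name = name, origin = "snp", source_snp = snp,
               encoding = encoding, label_true = lab_true,
               label_false = lab_false, stringsAsFactors = FALSE)
  switch(scheme,
    recessive = list(
      columns = matrix(as.integer(d == 2L), ncol = 1,
                       dimnames = list(NULL, paste0(snp, "_R"))),
      descriptors = desc(paste0(snp, "_R"), "recessive",
        paste0("2 copies of the minor allele of ", snp),
        paste0(">=1 copy of the major allele of ", snp))),
    dominant = list(
      columns = matrix(as.integer(d >= 1L), ncol = 1,
                       dimnames = list(NULL, paste0(snp, "_D"))),
      descriptors = desc(paste0(snp, "_D"), "dominant",
        paste0(">=1 copy of the minor allele of ", snp),
        paste0("0 copies of the minor allele of ", snp))),
    genotypic = list(
      columns = matrix(c(as.integer(d == 1L), as.integer(d == 2L)), ncol = 2,
                       dimnames = list(NULL, paste0(snp, c("_G1", "_G2")))),
      descriptors = rbind(
        desc(paste0(snp, "_G1"), "genotypic_1",
          paste0("1 copy of the minor allele of ", snp),
          paste0("0 or 2 copies of the minor allele of ", snp)),
        desc(paste0(snp, "_G2"), "genotypic_2",
          paste0("2 copies of the minor allele of ", snp),
          paste0("0 or 1 copies of the minor allele of ", snp)))))
}

#' Construct an analysis dataset
#'
#' The unit the forest consumes: an n x p strictly binary predictor matrix
#' `x`, a 0/1 outcome `y`, and one descriptor row per predictor column
#' recording its origin (snp / exposure / demographic), source SNP,
#' encoding, and human-readable renderings of the predictor and its
#' complement.
#'
#' @param x binary integer matrix with column names.
#' @param y binary outcome vector, length `nrow(x)`.
#' @param descriptors data.frame with columns `name`, `origin`,
#'   `source_snp`, `encoding`, `label_true`, `label_false`; default derives
#'   plain descriptors from column names.
#' @return object of class `lf_data` with elements `x`, `y`, `descriptors`,
#'   `n`, `p`.
#' @export
lf_data <- function(x, y, descriptors = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  y <- as.integer(y)
  .check_binary(x, "predictor matrix")
  .check_binary(y, "outcome y")
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (is.null(descriptors))
    descriptors <- data.frame(
      name = colnames(x), origin = "exposure", source_snp = NA_character_,
      encoding = "raw_binary", label_true = colnames(x),
      label_false = paste0("no ", colnames(x)), stringsAsFactors = FALSE)
  stopifnot(nrow(descriptors) == ncol(x),
            identical(descriptors$name, colnames(x)))
  structure(list(x = x, y = y, descriptors = descriptors,
                 n = nrow(x), p = ncol(x)),
            class = "lf_data")
}

#' @export
print.lf_data <- function(x, ...) {
  cat("lf_data:", x$n, "subjects x", x$p, "binary predictors; ",
      sum(x$y), "cases /", sum(1 - x$y), "controls\n")
  tab <- table(x$descriptors$origin)
  cat("  origins:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Assemble the analysis dataset from genotypes and phenotypes
#'
#' Matches subjects by identifier, encodes every SNP under the chosen
#' scheme, appends the named exposure/demographic columns, and drops
#' listwise any subject with a missing genotype, status, or selected
#' exposure (strict complete-case analysis); the number dropped is
#' reported via `message()`.  Constant predictor columns are retained with
#' a warning.
#'
#' @param gm a [genotype_matrix()].
#' @param ph a `phenotype_table` (see [read_phenotypes()]).
#' @param scheme SNP encoding scheme, see [encode_snp()].
#' @param exposures exposure column names to include; default all.
#' @return an [lf_data()].
#' @export
assemble_dataset <- function(gm, ph,
                             scheme = c("recessive", "dominant", "genotypic"),
                             exposures = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(gm, "genotype_matrix"))
  exposures <- exposures %||% setdiff(names(ph), c("subject_id", "status"))
  miss_col <- setdiff(exposures, names(ph))
  if (length(miss_col))
    stop("exposure column(s) not in phenotype table: ",
         paste(miss_col, collapse = ", "))
  ids <- intersect(rownames(gm$dosage), ph$subject_id)
  if (!length(ids)) stop("no overlapping subject ids")
  ph <- ph[match(ids, ph$subject_id), , drop = FALSE]
  dos <- gm$dosage[ids, , drop = FALSE]
  keep <- !is.na(ph$status) & complete.cases(dos) &
    complete.cases(ph[, exposures, drop = FALSE])
  dropped <- sum(!keep)
  if (dropped) message(dropped,
    " subject(s) dropped for missing genotype/exposure/status")
  if (!any(keep)) stop("no subjects remain after dropping missing data")
  ph <- ph[keep, , drop = FALSE]
  dos <- dos[keep, , drop = FALSE]

  enc <- lapply(colnames(dos), function(s)
    encode_snp(dos[, s], scheme, snp = s))
  xg <- do.call(cbind, lapply(enc, `[[`, "columns"))
  dg <- do.call(rbind, lapply(enc, `[[`, "descriptors"))
  xe <- as.matrix(ph[, exposures, drop = FALSE])
  storage.mode(xe) <- "integer"
  de <- data.frame(
    name = exposures,
    origin = ifelse(exposures %in% c("female", "sex", "male"),
                    "demographic", "exposure"),
    source_snp = rep(NA_character_, length(exposures)),
    encoding = rep("raw_binary", length(exposures)),
    label_true = exposures,
    label_false = if (length(exposures)) paste0("no ", exposures)
                  else character(0),
    stringsAsFactors = FALSE)
  x <- if (length(exposures)) cbind(xg, xe) else xg
  rownames(x) <- ph$subject_id
  const <- which(apply(x, 2, function(v) all(v == v[1])))
  if (length(const))
    warning("constant predictor column(s) retained: ",
            paste(colnames(x)[const], collapse = ", "), call. = FALSE)
  lf_data(x, ph$status, rbind(dg, de))
}
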