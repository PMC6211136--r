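#' Construct a genotype matrix
#'
#' Container for minor-allele dosage data: an n-subject by m-SNP integer
#' matrix with entries 0, 1, 2 or `NA`.  Optional per-SNP allele labels
#' (minor, major) and genomic positions (1-based) travel with the matrix so
#' that downstream region filters and reports can use them.
#'
#' @param dosage integer matrix of minor-allele copy counts; rownames are
#'   subject identifiers, colnames are SNP identifiers (or supply
#'   `subject_ids` / `snp_ids`).
#' @param subject_ids,snp_ids identifier vectors; default taken from dimnames.
#' @param alleles optional data.frame with columns `minor`, `major` (one row
#'   per SNP).
#' @param positions optional data.frame with columns `chrom`, `pos`
#'   (1-based base-pair coordinate, one row per SNP).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, subject_ids = rownames(dosage),
                            snp_ids = colnames(dosage), alleles = NULL,
                            positions = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(subject_ids) || is.null(snp_ids))
    stop("subject and SNP identifiers are required")
  subject_ids <- as.character(subject_ids)
  snp_ids <- as.character(snp_ids)
  if (anyDuplicated(subject_ids))
    stop("duplicated subject id: ", subject_ids[duplicated(subject_ids)][1])
  if (anyDuplicated(snp_ids))
    stop("duplicated SNP id: ", snp_ids[duplicated(snp_ids)][1])
  if (nrow(dosage) != length(subject_ids) || ncol(dosage) != length(snp_ids))
    stop("dosage dimensions do not match identifier lengths")
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad))
    stop("dosage values outside {0,1,2,NA}: first offending value ",
         dosage[which(bad)[1]])
  dimnames(dosage) <- list(subject_ids, snp_ids)
  if (!is.null(positions)) {
    stopifnot(all(c("chrom", "pos") %in% names(positions)),
              nrow(positions) == length(snp_ids))
    if (any(positions$pos < 1 | positions$pos != round(positions$pos)))
      stop("positions must be positive 1-based integers")
    rownames(positions) <- snp_ids
  }
  if (!is.null(alleles)) {
    stopifnot(all(c("minor", "major") %in% names(alleles)),
              nrow(alleles) == length(snp_ids))
    rownames(alleles) <- snp_ids
  }
  structure(list(dosage = dosage, alleles = alleles, positions = positions),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- x$dosage
  cat("genotype_matrix:", nrow(d), "subjects x", ncol(d), "SNPs\n")
  nm <- sum(is.na(d))
  cat("  missing entries:", nm,
      sprintf("(%.2f%%)", 100 * nm / length(d)), "\n")
  if (!is.null(x$positions)) cat("  positions: present\n")
  if (!is.null(x$alleles)) cat("  allele labels: present\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Read genotypes from TSV, PLINK .raw, or VCF
#'
#' All formats are normalised to minor-allele dosage.  The TSV dialect is a
#' header row `subject_id` plus one column per SNP with values 0/1/2/NA.
#' PLINK `.raw` files are whitespace-separated with the standard
#' `FID IID PAT MAT SEX PHENOTYPE` preamble columns (IID becomes the subject
#' id; dosage columns are used as-is).  VCF input must be biallelic with GT
#' fields; the minor allele is the lesser-frequency allele among the file's
#' samples, ties broken toward ALT.
#'
#' @param path file to read.
#' @param format one of `"tsv"`, `"plink_raw"`, `"vcf"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "plink_raw", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         tsv = .read_geno_tsv(path),
         plink_raw = .read_geno_raw(path),
         vcf = .read_geno_vcf(path))
}

.parse_dosage_cols <- function(df, path) {
  m <- as.matrix(df)
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m)))
  bad <- which(is.na(num) & !(m %in% c("NA", "", NA)))
  if (length(bad)) {
    line <- (bad[1] - 1) %% nrow(m) + 2  # +1 header, +1 one-based
    stop("malformed dosage value '", m[bad[1]], "' in ", path,
         " near line ", line)
  }
  out <- which(!is.na(num) & !(num %in% c(0, 1, 2)))
  if (length(out)) {
    line <- (out[1] - 1) %% nrow(m) + 2
    stop("dosage outside {0,1,2}: value ", num[out[1]], " in ", path,
         " near line ", line)
  }
  storage.mode(num) <- "integer"
  dimnames(num) <- dimnames(m)
  num
}

.read_geno_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character", na.strings = "NA")
  if (names(df)[1] != "subject_id")
    stop("genotype TSV must start with a 'subject_id' column: ", path)
  ids <- df[[1]]
  num <- .parse_dosage_cols(df[, -1, drop = FALSE], path)
  rownames(num) <- ids
  genotype_matrix(num)
}

.read_geno_raw <- function(path) {
  df <- read.table(path, header = TRUE, check.names = FALSE,
                   colClasses = "character", na.strings = c("NA", "-9"))
  pre <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(pre %in% names(df)[seq_along(pre)]))
    stop("not a PLINK .raw header (expected FID IID PAT MAT SEX PHENOTYPE): ",
         path)
  ids <- df[["IID"]]
  num <- .parse_dosage_cols(df[, setdiff(names(df), pre), drop = FALSE], path)
  rownames(num) <- ids
  genotype_matrix(num)
}

.read_geno_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi))
    stop("multi-allelic VCF site(s): ",
         paste(fix[multi, "ID"], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  # ALT-allele dosage from GT strings such as 0/1, 1|1, ./.
  alt_dos <- function(g) {
    if (is.na(g) || grepl("\\.", g)) return(NA_integer_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]))
  }
  dos <- apply(gt, c(1, 2), alt_dos)
  bad <- which(!is.na(dos) & !(dos %in% 0:2))
  if (length(bad)) stop("VCF genotype implies dosage outside {0,1,2}")
  n2 <- 2 * colSums(!is.na(t(dos)))  # per-site called allele count
  alt_f <- rowSums(dos, na.rm = TRUE) / ifelse(n2 > 0, n2, 1)
  # minor allele = lesser-frequency allele; ties (0.5) go to ALT
  flip <- alt_f > 0.5
  dos[flip, ] <- 2L - dos[flip, , drop = FALSE]
  alleles <- data.frame(
    minor = ifelse(flip, fix[, "REF"], fix[, "ALT"]),
    major = ifelse(flip, fix[, "ALT"], fix[, "REF"]),
    stringsAsFactors = FALSE)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  genotype_matrix(t(dos), subject_ids = colnames(gt), snp_ids = ids,
                  alleles = alleles,
                  positions = data.frame(chrom = fix[, "CHROM"],
                                         pos = as.integer(fix[, "POS"]),
                                         stringsAsFactors = FALSE))
}

#' Write a genotype matrix to the TSV dialect
#'
#' Inverse of `read_genotypes(format = "tsv")`; missing values are written
#' as `NA`.  Allele labels and positions are not serialised by this dialect.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @export
write_genotypes <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  df <- data.frame(subject_id = rownames(gm$dosage), gm$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
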