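#' Read a phenotype/exposure table
#'
#' Tab-separated file with a header row: `subject_id`, `status`
#' (1 = case, 0 = control), then zero or more binary exposure or demographic
#' columns (e.g. `psc` for childhood passive smoke, `female`).  Exposure
#' entries other than 0/1/NA are set to missing with a warning; a missing or
#' non-binary `status` is an error.
#'
#' @param path file to read.
#' @return a data.frame of class `phenotype_table` with columns
#'   `subject_id`, `status`, and the exposure columns as integers.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character", na.strings = "NA")
  if (!"subject_id" %in% names(df) || !"status" %in% names(df))
    stop("phenotype file must have 'subject_id' and 'status' columns: ", path)
  if (anyDuplicated(df$subject_id))
    stop("duplicated subject_id: ",
         df$subject_id[duplicated(df$subject_id)][1])
  status <- suppressWarnings(as.integer(df$status))
  bad <- !is.na(df$status) & (is.na(status) | !(status %in% 0:1))
  if (any(bad))
    stop("status values must be 0, 1 or NA; found '",
         df$status[which(bad)[1]], "'")
  out <- data.frame(subject_id = df$subject_id, status = status,
                    stringsAsFactors = FALSE)
  for (col in setdiff(names(df), c("subject_id", "status"))) {
    v <- suppressWarnings(as.integer(df[[col]]))
    odd <- !is.na(df[[col]]) & (is.na(v) | !(v %in% 0:1))
    if (any(odd)) {
      warning(sum(odd), " non-binary value(s) in exposure '", col,
              "' set to missing", call. = FALSE)
      v[odd] <- NA_integer_
    }
    out[[col]] <- v
  }
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Write a phenotype table
#' @param ph a `phenotype_table` (or compatible data.frame).
#' @param path output file.
#' @export
write_phenotypes <- function(ph, path) {
  write.table(ph, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
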