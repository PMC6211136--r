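#' End-to-end run configuration
#'
#' Bundles every knob of the full analytic flow: QC -> encoding -> one
#' logic forest per encoding -> importance aggregation -> permutation
#' p-values for the top implicants -> logistic confirmation -> reports.
#'
#' @param genotypes path to the genotype file.
#' @param phenotypes path to the phenotype TSV.
#' @param genotype_format `"tsv"`, `"plink_raw"` or `"vcf"`.
#' @param gene_intervals optional interval file for region windowing.
#' @param interval_format `"bed"` or `"tsv"`.
#' @param flank region flank in bp (default 5000).
#' @param hwe_p_min,maf_min,max_missing QC thresholds, see [apply_qc()].
#' @param encodings subset of `c("recessive", "dominant", "genotypic")`
#'   (default all three).
#' @param exposures exposure columns to include (default all).
#' @param B trees per forest (default 200).
#' @param max_leaves per-tree leaf cap (default 8).
#' @param n_perm outcome permutations for p-values (default 500).
#' @param top_k implicants taken to permutation testing and confirmation
#'   (default 10).
#' @param measure importance measure for permutation p-values.
#' @param control an [anneal_control()].
#' @param seed master seed; every stochastic stage is seeded from it
#'   deterministically.
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(genotypes, phenotypes, genotype_format = "tsv",
                       gene_intervals = NULL, interval_format = "bed",
                       flank = 5000, hwe_p_min = 0.001, maf_min = 0.05,
                       max_missing = 0,
                       encodings = c("recessive", "dominant", "genotypic"),
                       exposures = NULL, B = 200, max_leaves = 8,
                       n_perm = 500, top_k = 10, measure = "vi1",
                       control = anneal_control(), seed = 1,
                       out_dir = "logicgxe_run") {
  encodings <- match.arg(encodings, several.ok = TRUE)
  stopifnot(length(encodings) >= 1, B >= 1, max_leaves >= 1, n_perm >= 0,
            hwe_p_min >= 0, hwe_p_min <= 1, maf_min >= 0, maf_min <= 0.5,
            max_missing >= 0, max_missing <= 1)
  structure(as.list(environment()), class = "run_config")
}

.stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(paste0("FAILED at stage: ", name, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full study pipeline
#'
#' Executes the configured flow and writes, under `config$out_dir`: the QC
#' report, and per encoding a prime-implicant importance report (with
#' permutation p-values for the top implicants), a predictor report,
#' frequency-versus-importance scatter TSVs, an OOB error and ROC/AUC
#' summary, a confirmation table, and a machine-readable JSON manifest of
#' the whole run.  Encodings are ranked by OOB misclassification in the
#' manifest; no automatic model selection is performed.
#'
#' @param config a [run_config()].
#' @return invisibly, the manifest list.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out, "FAILED"))
  t_start <- Sys.time()

  gm <- .stage("read_genotypes", out,
               read_genotypes(config$genotypes, config$genotype_format))
  ph <- .stage("read_phenotypes", out, read_phenotypes(config$phenotypes))

  if (!is.null(config$gene_intervals)) {
    iv <- .stage("read_intervals", out,
                 read_gene_intervals(config$gene_intervals,
                                     config$interval_format))
    gm <- .stage("select_region", out, select_region(gm, iv, config$flank))
  }

  controls <- ph$subject_id[!is.na(ph$status) & ph$status == 0]
  qc <- .stage("qc", out,
               apply_qc(gm, controls, hwe_p_min = config$hwe_p_min,
                        maf_min = config$maf_min,
                        max_missing = config$max_missing))
  write_qc_report(qc$report, file.path(out, "qc_report.tsv"))

  manifest <- list(config = .serializable_config(config),
                   seed = config$seed,
                   n_snps_input = ncol(gm$dosage),
                   n_snps_retained = sum(qc$report$retained),
                   encodings = list())

  for (enc in config$encodings) {
    edir <- file.path(out, enc)
    dir.create(edir, showWarnings = FALSE)
    # deterministic per-encoding seed derived from the master seed
    eseed <- (config$seed * 1000L +
                match(enc, c("recessive", "dominant", "genotypic"))) %%
      .Machine$integer.max
    set.seed(eseed)
    dat <- .stage(paste0("assemble:", enc), out,
                  assemble_dataset(qc$genotypes, ph, scheme = enc,
                                   exposures = config$exposures))
    model <- .stage(paste0("fit:", enc), out,
                    logic_forest(dat, B = config$B,
                                 max_leaves = config$max_leaves,
                                 control = config$control))
    imp <- .stage(paste0("importance:", enc), out, importance(model))

    perm <- NULL
    if (config$n_perm > 0 && nrow(imp$pi) > 0) {
      perm <- .stage(paste0("permtest:", enc), out,
                     permutation_pvalues(model, n_perm = config$n_perm,
                                         top_k = config$top_k,
                                         measure = config$measure,
                                         imp = imp))
      imp$pi$perm_p <- perm$perm_p[match(imp$pi$pi, perm$pi)]
      imp$pi$perm_p_display <-
        perm$perm_p_display[match(imp$pi$pi, perm$pi)]
    }

    conf <- .stage(paste0("confirm:", enc), out,
                   confirm_pis(dat, as.list(head(imp$pi$pi, config$top_k))))

    pred <- oob_predict(model)
    share <- attr(pred, "share")
    ok <- !is.na(share)
    auc <- if (length(unique(dat$y[ok])) == 2)
      roc_auc(share[ok], dat$y[ok])$auc else NA_real_
    mc <- oob_misclassification(model)

    write.table(imp$pi, file.path(edir, "pi_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(imp$predictors, file.path(edir, "predictor_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(imp$pi[, c("label", "tree_count", "normalized_vi1")],
                file.path(edir, "scatter_pi.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(imp$predictors[, c("predictor", "tree_count",
                                   "normalized_vi1")],
                file.path(edir, "scatter_predictors.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(conf, file.path(edir, "confirmation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(jsonlite::toJSON(list(oob_misclassification = mc,
                                     auc = auc, n = dat$n, p = dat$p,
                                     B = model$B),
                                auto_unbox = TRUE, digits = NA, na = "null"),
               file.path(edir, "performance.json"))
    lf_save(model, file.path(edir, "model.json"))

    manifest$encodings[[enc]] <- list(
      seed = eseed, n = dat$n, p = dat$p,
      oob_misclassification = mc, auc = auc,
      n_unique_pi = nrow(imp$pi),
      top_pi = if (nrow(imp$pi)) imp$pi$label[1] else NA)
  }

  ranks <- order(vapply(manifest$encodings, `[[`, 0,
                        "oob_misclassification"))
  manifest$encoding_ranking <- names(manifest$encodings)[ranks]
  manifest$runtime_seconds <-
    as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  manifest$package_version <-
    as.character(utils::packageVersion("logicgxe"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", null = "null")
  invisible(manifest)
}

.serializable_config <- function(config) {
  out <- unclass(config)
  out$control <- unclass(out$control)
  out
}
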