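test_that("HWE chi-square matches hand-computed references", {
  # exact HWE proportions: statistic 0, p = 1
  h <- hwe_test(25, 50, 25)
  expect_equal(h$statistic, 0)
  expect_equal(h$p.value, 1)
  # no heterozygotes at p = 0.5: observed (50,0,50) vs expected (25,50,25)
  h2 <- hwe_test(50, 0, 50)
  expect_equal(h2$statistic, 100)
  expect_lt(h2$p.value, 0.001)
  # monomorphic marker: p = 1 with flag
  h3 <- hwe_test(100, 0, 0)
  expect_equal(h3$p.value, 1)
  expect_true(h3$monomorphic)
})

test_that("exact HWE test agrees with direct enumeration", {
  # independent oracle: enumerate all heterozygote counts with the allele
  # count fixed and sum probabilities <= observed
  exact_oracle <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    nA <- 2 * nAA + nAa
    nh <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
    pr <- vapply(nh, function(h)
      exp(lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
            lfactorial((2 * n - nA - h) / 2) + h * log(2) +
            lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)), 0)
    sum(pr[pr <= pr[match(nAa, nh)] + 1e-12])
  }
  set.seed(31)
  for (r in 1:10) {
    cnt <- c(sample(5:40, 2), sample(0:20, 1))
    p_mine <- hwe_test(cnt[1], cnt[2], cnt[3], method = "exact")$p.value
    expect_equal(p_mine, min(1, exact_oracle(cnt[1], cnt[2], cnt[3])),
                 tolerance = 1e-10)
  }
})

test_that("chi-square and exact HWE p-values track each other on big counts", {
  set.seed(32)
  checked <- 0
  while (checked < 5) {
    maf <- runif(1, 0.4, 0.5)
    g <- table(factor(rbinom(700, 2, maf), 0:2))
    pc <- hwe_test(g[[1]], g[[2]], g[[3]], "chisq")$p.value
    pe <- hwe_test(g[[1]], g[[2]], g[[3]], "exact")$p.value
    if (pc >= 0.2 && pc <= 0.8 && all(g >= 100)) {
      expect_lt(abs(pc - pe), 0.05)
      checked <- checked + 1
    }
  }
})

test_that("MAF computes the lesser allele frequency, orientation invariant", {
  expect_equal(snp_maf(81, 18, 1), 0.10)
  expect_equal(snp_maf(98, 2, 0), 0.01)
  expect_equal(snp_maf(25, 50, 25), 0.50)
  set.seed(33)
  for (r in 1:10) {
    cnt <- sample(0:50, 3, replace = TRUE) + c(1, 0, 0)
    expect_equal(snp_maf(cnt[1], cnt[2], cnt[3]),
                 snp_maf(cnt[3], cnt[2], cnt[1]))
  }
})

qc_fixture <- function() {
  # 60 controls + 60 cases; m_hwe violates HWE in controls, m_rare has low
  # MAF, m_miss has a missing call, m_ok passes everything
  set.seed(34)
  n <- 120
  ctl <- paste0("c", 1:60)
  cas <- paste0("k", 1:60)
  m_ok <- rbinom(n, 2, 0.3)
  m_hwe <- c(rep(c(0L, 2L), 30), rbinom(60, 2, 0.5))  # controls all hom
  m_rare <- rbinom(n, 2, 0.01)
  m_miss <- rbinom(n, 2, 0.3)
  m_miss[5] <- NA
  dos <- cbind(m_ok = m_ok, m_hwe = m_hwe, m_rare = m_rare, m_miss = m_miss)
  rownames(dos) <- c(ctl, cas)
  list(gm = genotype_matrix(dos), controls = ctl)
}

test_that("QC filters act on the right cohort and statistic", {
  fx <- qc_fixture()
  qc <- apply_qc(fx$gm, fx$controls)
  rep <- qc$report
  expect_false(rep$retained[rep$snp_id == "m_hwe"])
  expect_true(rep$fail_hwe[rep$snp_id == "m_hwe"])
  expect_false(rep$retained[rep$snp_id == "m_rare"])
  expect_true(rep$fail_maf[rep$snp_id == "m_rare"])
  expect_false(rep$retained[rep$snp_id == "m_miss"])
  expect_true(rep$retained[rep$snp_id == "m_ok"])
  expect_equal(colnames(qc$genotypes$dosage), "m_ok")
})

test_that("QC is idempotent and errors when nothing survives", {
  fx <- qc_fixture()
  qc1 <- apply_qc(fx$gm, fx$controls)
  qc2 <- apply_qc(qc1$genotypes, fx$controls)
  expect_identical(qc1$genotypes$dosage, qc2$genotypes$dosage)
  expect_true(all(qc2$report$retained))

  rare_only <- genotype_matrix(fx$gm$dosage[, "m_rare", drop = FALSE])
  err <- tryCatch(apply_qc(rare_only, fx$controls), condition = identity)
  expect_s3_class(err, "logicgxe_qc_error")
  expect_s3_class(err$report, "qc_report")
})

test_that("gene-region windowing honors inclusive 5 kb boundaries", {
  dos <- matrix(rbinom(12, 2, 0.5), 2, 6,
                dimnames = list(c("a", "b"), paste0("m", 1:6)))
  gm <- genotype_matrix(dos, positions = data.frame(
    chrom = c("1", "1", "1", "1", "2", "1"),
    pos = c(4999L, 5000L, 15000L, 25000L, 15000L, 25001L)))
  iv <- data.frame(chrom = "1", start = 10000L, end = 20000L)
  kept <- select_region(gm, iv, flank = 5000)
  expect_equal(colnames(kept$dosage), c("m2", "m3", "m4"))
  # overlapping windows keep a SNP once
  iv2 <- rbind(iv, data.frame(chrom = "1", start = 12000L, end = 22000L))
  expect_equal(colnames(select_region(gm, iv2)$dosage),
               c("m2", "m3", "m4", "m6"))
  expect_error(select_region(genotype_matrix(dos), iv), "no positions")
})

test_that("BED intervals are shifted to 1-based, TSV taken verbatim", {
  bed <- tempfile(fileext = ".bed")
  writeLines("1\t9999\t20000\tGENE1", bed)
  suppressMessages(iv <- read_gene_intervals(bed, "bed"))
  expect_equal(iv$start, 10000L)
  expect_equal(iv$end, 20000L)
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend", "1\t10000\t20000"), tsv)
  suppressMessages(iv2 <- read_gene_intervals(tsv, "tsv"))
  expect_equal(iv2$start, 10000L)
})
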