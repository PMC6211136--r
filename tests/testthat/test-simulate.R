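test_that("genotypes concentrate at the requested MAF under HWE", {
  set.seed(81)
  cfg <- sim_config(n_subjects = 10000, n_snps = 3,
                    snp_mafs = c(0.3, 0.3, 0.1))
  gm <- generate_genotypes(cfg)
  emp <- colMeans(gm$dosage) / 2
  expect_true(all(abs(emp - c(0.3, 0.3, 0.1)) < 0.01))
  # genotype frequencies conform to HWE (generated under the null)
  for (j in 1:3) {
    cnt <- table(factor(gm$dosage[, j], 0:2))
    expect_gt(hwe_test(cnt[[1]], cnt[[2]], cnt[[3]])$p.value, 0.001)
  }
})

test_that("generation is seed-deterministic", {
  cfg <- sim_config(n_subjects = 50, n_snps = 5)
  set.seed(82); a <- sim_study(cfg)
  set.seed(82); b <- sim_study(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$phenotypes$status, b$phenotypes$status)
})

test_that("outcome model: baseline prevalence and planted odds ratio", {
  set.seed(83)
  x <- matrix(rbinom(20000 * 2, 1, 0.4), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  y0 <- generate_outcome(x, list(), 0)
  expect_lt(abs(mean(y0) - 0.5), 3 * sqrt(0.25 / 20000) + 0.01)
  # single planted term at log OR ln(2): realized OR near 2 at n = 20,000
  y1 <- generate_outcome(x, list(list(term = "a", beta = log(2))), -0.5)
  tab <- table(x[, "a"], y1)
  or <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  expect_lt(abs(or - 2), 0.25)
  expect_error(generate_outcome(x, list(list(term = "zz", beta = 1)), 0),
               "unknown column")
  expect_error(sim_config(truth = list(list(term = "a", beta = Inf))),
               "finite")
})

test_that("realized prevalence sits within 3 SE of the model expectation", {
  set.seed(84)
  cfg <- sim_config(n_subjects = 2000, n_snps = 10,
                    truth = list(list(term = c("psc", "!snp001_R"),
                                      beta = log(2.3))))
  st <- sim_study(cfg)
  # expected prevalence from the model, computed from the realized design
  enc <- encode_snp(st$genotypes$dosage[, "snp001"], "recessive", "snp001")
  ind <- as.integer(st$phenotypes$psc == 1 & enc$columns[, 1] == 0)
  pexp <- mean(plogis(cfg$baseline_log_odds + log(2.3) * ind))
  se <- sqrt(pexp * (1 - pexp) / 2000)
  expect_lt(abs(mean(st$phenotypes$status) - pexp), 3 * se)
})

test_that("the default study shape encodes to 153 predictors", {
  set.seed(85)
  st <- sim_study(sim_config(snp_mafs = runif(148, 0.2, 0.5)))
  d <- suppressWarnings(
    assemble_dataset(st$genotypes, st$phenotypes, "recessive"))
  expect_equal(d$p, 153L)
  expect_equal(d$n, 204L)
  expect_equal(st$truth, list())
})

test_that("planted-term manifest carries canonical keys", {
  set.seed(86)
  cfg <- sim_config(n_subjects = 40, n_snps = 5,
                    truth = list(list(term = c("psc", "!snp002_R"),
                                      beta = 0.5)))
  st <- sim_study(cfg)
  expect_equal(st$truth[[1]]$key, pi_key(c(-2L, 6L)))  # psc is column 6
})

test_that("generated common SNPs pass QC at standard thresholds", {
  set.seed(87)
  cfg <- sim_config(n_subjects = 400, n_snps = 60,
                    snp_mafs = runif(60, 0.1, 0.5))
  st <- sim_study(cfg)
  controls <- st$phenotypes$subject_id[st$phenotypes$status == 0]
  qc <- apply_qc(st$genotypes, controls)
  expect_gte(mean(qc$report$retained), 0.95)
})

test_that("LD blocks induce the requested genotype correlation", {
  set.seed(88)
  cfg <- sim_config(n_subjects = 4000, n_snps = 6,
                    snp_mafs = rep(0.3, 6),
                    ld_blocks = list(list(size = 3, rho = 0.8)))
  gm <- generate_genotypes(cfg)
  cc <- cor(gm$dosage)
  expect_gt(mean(c(cc[1, 2], cc[2, 3])), 0.4)  # correlated inside the block
  expect_lt(abs(cc[1, 5]), 0.1)                # independent outside
})

test_that("simulation configs round-trip through YAML", {
  cfg <- sim_config(n_subjects = 77, n_snps = 9,
                    snp_mafs = seq(0.1, 0.5, length.out = 9),
                    exposure_prev = c(psc = 0.3, female = 0.8),
                    truth = list(list(term = c("psc", "!snp001_R"),
                                      beta = log(2.3))),
                    baseline_log_odds = -0.25)
  f <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_equal(cfg2$n_subjects, cfg$n_subjects)
  expect_equal(cfg2$snp_mafs, cfg$snp_mafs)
  expect_equal(cfg2$exposure_prev, cfg$exposure_prev)
  expect_equal(cfg2$truth, cfg$truth)
  expect_equal(cfg2$baseline_log_odds, cfg$baseline_log_odds)
})

test_that("studies write out in the package file dialects", {
  set.seed(89)
  st <- sim_study(sim_config(n_subjects = 30, n_snps = 4))
  dir <- tempfile()
  paths <- write_study(st, dir)
  gm <- read_genotypes(paths[["genotypes"]], "tsv")
  ph <- read_phenotypes(paths[["phenotypes"]])
  expect_identical(gm$dosage, st$genotypes$dosage)
  expect_equal(ph$status, st$phenotypes$status)
})
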