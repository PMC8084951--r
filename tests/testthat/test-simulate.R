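test_that("simulated genotypes hit their MAF and LD targets", {
  snps <- tibble::tibble(snp_id = c("a", "b", "c", "d"),
                         maf = c(0.06, 0.06, 0.3, 0.3),
                         block = c("b1", "b1", NA, NA))
  cfg <- sim_config(20000, snps, block_r2 = c(b1 = 0.98), seed = 5)
  g <- simulate_genotypes(cfg)
  emp <- geno_summary(g)
  expect_lt(max(abs(emp$maf - snps$maf)), 0.005)
  expect_equal(ld_r2(geno_vector(g, "a"), geno_vector(g, "b")), 0.98,
               tolerance = 0.02)
  # cross-block SNPs are independent
  expect_lt(ld_r2(geno_vector(g, "a"), geno_vector(g, "c")), 0.01)
  expect_lt(ld_r2(geno_vector(g, "c"), geno_vector(g, "d")), 0.01)

  # HWE holds for the copula-generated block SNPs
  x <- geno_vector(g, "a")
  expect_gt(hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2)), 1e-4)
})

test_that("infeasible LD targets fail with the feasible bound reported", {
  snps <- tibble::tibble(snp_id = c("a", "b"), maf = c(0.06, 0.4),
                         block = c("b1", "b1"))
  cfg <- sim_config(100, snps, block_r2 = c(b1 = 0.95), seed = 1)
  expect_error(simulate_genotypes(cfg), "feasible r\\^2 at most")
})

test_that("phenotype prevalence is calibrated and effects are recoverable", {
  snps <- tibble::tibble(snp_id = sprintf("m%02d", 1:10),
                         maf = seq(0.1, 0.45, length.out = 10))
  cfg <- sim_config(20000, snps, seed = 6)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(g, cfg)
  expect_equal(mean(ph$y), 0.226, tolerance = 0.01)

  # all-zero effects and an empty model give the identical distribution
  cfg0 <- sim_config(20000, snps, seed = 6,
                     true_pairs = tibble::tibble(snp1 = "m01", snp2 = "m02",
                                                 pattern = "AA_int_oo", log_or = 0))
  ph0 <- simulate_phenotype(g, cfg0)
  expect_identical(ph0$y, ph$y)

  # a configured interaction is recovered by refitting the exact pattern
  cfg1 <- sim_config(20000, snps, seed = 7,
                     true_pairs = tibble::tibble(snp1 = "m05", snp2 = "m06",
                                                 pattern = "AA_int_ro",
                                                 log_or = log(1.29)))
  g1 <- simulate_genotypes(cfg1)
  ph1 <- simulate_phenotype(g1, cfg1)
  f <- fit_pattern(ph1$y, geno_vector(g1, "m05"), geno_vector(g1, "m06"),
                   "AA_int_ro")
  row <- tidy(f)[tidy(f)$term == "snp1_x_snp2", ]
  expect_gt(row$or.conf.high, 1.29 * 0.98)
  expect_lt(row$or.conf.low, 1.29 * 1.02)
})

test_that("expression traits carry the configured interaction signal", {
  set.seed(8)
  snps <- tibble::tibble(snp_id = c("x", "z"), maf = c(0.3, 0.35))
  cfg <- sim_config(5000, snps, seed = 8)
  g <- simulate_genotypes(cfg)

  # beta = 0: no association (p roughly uniform across replicates)
  tr0 <- simulate_expression(g, "x", "z", "AA_int_oo", beta = 0, seed = 9)
  f0 <- fit_pattern(tr0, geno_vector(g, "x"), geno_vector(g, "z"),
                    "AA_int_oo", link = "linear")
  expect_gt(f0$interaction_p, 1e-4)

  # same seed reproduces the trait exactly
  expect_identical(simulate_expression(g, "x", "z", "AA_int_oo", 0.3, seed = 10),
                   simulate_expression(g, "x", "z", "AA_int_oo", 0.3, seed = 10))

  # beta chosen for partial R^2 ~ 0.02 lands near 0.02
  xx <- pair_interaction_vector(g, "x", "z", "AA_int_oo")
  beta <- sqrt(0.02 / (1 - 0.02) / var(xx))
  tr <- simulate_expression(g, "x", "z", "AA_int_oo", beta, 1, seed = 11)
  r2 <- summary(lm(tr ~ xx))$r.squared
  expect_lt(abs(r2 - 0.02), 0.005)
})

test_that("fixture presets write deterministic bundles with the documented shapes", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  fx1 <- make_fixture("tiny", dir1, seed = 3)
  fx2 <- make_fixture("tiny", dir2, seed = 3)
  for (nm in names(fx1$paths)) {
    expect_identical(unname(tools::md5sum(fx1$paths[[nm]])),
                     unname(tools::md5sum(fx2$paths[[nm]])), label = nm)
  }
  g <- read_geno_tsv(fx1$paths$genotypes, fx1$paths$snps)
  expect_equal(dim(g), c(500, 50))

  truth <- jsonlite::read_json(fx1$paths$truth, simplifyVector = TRUE)
  expect_equal(truth$preset, "tiny")
  expect_equal(nrow(truth$true_pairs), 1)

  # the hub preset's truth has one SNP participating in >= 5 pairs
  cfg <- snpint:::fixture_presets("klk3_like", seed = 1)
  members <- c(cfg$true_pairs$snp1, cfg$true_pairs$snp2)
  expect_gte(max(table(members)), 5)
  expect_error(make_fixture("nope", dir1, seed = 1), "unknown fixture preset")
})

test_that("simulation config validates its invariants", {
  snps <- tibble::tibble(snp_id = "a", maf = 0.3)
  expect_error(sim_config(10, tibble::tibble(snp_id = "a", maf = 0.7)),
               "\\(0, 0.5\\]")
  expect_error(sim_config(10, snps, block_r2 = c(b = 1)), "\\[0, 1\\)")
  expect_error(sim_config(10, snps, prevalence = 0), "\\(0, 1\\)")
  expect_error(sim_config(10, snps,
                          subpops = tibble::tibble(prop = c(0.6, 0.6),
                                                   maf_offset = c(0, 0))),
               "sum to 1")
})
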