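test_that("screening thresholds derive the Bonferroni levels from test counts", {
  cfg <- screen_config(n_snps_tested = 8587, n_pairs_tested = n_candidate_pairs(5345))
  expect_equal(signif(cfg$bonferroni_individual, 2), 5.8e-6)
  expect_equal(signif(cfg$bonferroni_interaction, 2), 3.5e-9)
  expect_error(screen_config(stage1_p = 0), "\\(0, 1\\)")
})

test_that("site-stratified split halves every site reproducibly", {
  set.seed(201)
  subjects <- tibble::tibble(
    subject_id = paste0("s", 1:20270),
    site = rep(paste0("site", 1:10), c(rep(2027, 10)))
  )
  sp <- split_cohort(subjects, seed = 9)
  # odd-size sites split 1014/1013, but totals balance to 10135 per set
  expect_equal(sort(as.integer(table(sp$set))), c(10135L, 10135L))
  by_site <- table(sp$site, sp$set)
  expect_true(all(abs(by_site[, 1] - by_site[, 2]) <= 1))
  expect_identical(split_cohort(subjects, seed = 9), sp)
  expect_false(identical(split_cohort(subjects, seed = 10)$set, sp$set))

  odd <- tibble::tibble(subject_id = paste0("o", 1:7), site = "x")
  tab <- table(split_cohort(odd, seed = 1)$set)
  expect_true(all(sort(unname(tab)) == c(3, 4)))
  expect_error(split_cohort(tibble::tibble(subject_id = "a", site = "x")),
               "at least 2")
})

test_that("candidate pair enumeration matches the closed form and genomic order", {
  snps <- tibble::tibble(snp_id = paste0("r", 1:10), chrom = "1", pos = 10:1 * 100)
  cp <- candidate_pairs(snps)
  expect_equal(nrow(cp), 45)
  expect_equal(nrow(candidate_pairs(snps[1:2, ])), 1)
  # snp1 precedes snp2 in genomic order (positions are reversed here)
  pos <- setNames(snps$pos, snps$snp_id)
  expect_true(all(pos[cp$snp1] < pos[cp$snp2]))
  for (n in c(2, 10, 100, 5345)) {
    expect_equal(n_candidate_pairs(n), choose(n, 2))
  }
  expect_equal(signif(n_candidate_pairs(5345), 2), 1.4e7)
  expect_error(candidate_pairs(snps[1, ]), "at least 2")
})

test_that("two-stage scan screens on the additive search then refines with the full scope", {
  set.seed(202)
  n <- 3000
  g <- sim_geno(n, c(0.3, 0.3, 0.3, 0.35, 0.4, 0.25))
  y <- rbinom(n, 1, plogis(-1.2 + 0.55 * geno_vector(g, "s001") * geno_vector(g, "s002")))
  pairs <- tibble::tibble(snp1 = c("s001", "s003", "s005"),
                          snp2 = c("s002", "s004", "s006"))
  ts <- two_stage_scan(g, y, pairs)
  expect_true(all(ts$aa9int_p < 0.001))
  # the true pair survives; its full-scope BIC can only improve (superset)
  expect_true(any(ts$snp1 == "s001" & ts$snp2 == "s002"))
  row <- ts[ts$snp1 == "s001", ]
  aa_fit <- select_best_pattern(y, geno_vector(g, "s001"), geno_vector(g, "s002"),
                                scope = "aa9int")
  expect_lte(row$sipi_bic, aa_fit$fit$bic + 1e-9)

  # no survivors: empty tibble, no error
  y_null <- rbinom(n, 1, 0.25)
  expect_equal(nrow(two_stage_scan(g, y_null, pairs[2:3, ])), 0)
})

test_that("full-scope BIC never exceeds additive-scope BIC across simulated pairs", {
  set.seed(203)
  for (r in 1:20) {
    n <- 1200
    g1 <- rbinom(n, 2, runif(1, 0.1, 0.4)); g2 <- rbinom(n, 2, runif(1, 0.1, 0.4))
    y <- rbinom(n, 1, plogis(-1 + runif(1, 0, 0.5) * (g1 >= 1) * (g2 >= 1)))
    aa <- select_best_pattern(y, g1, g2, scope = "aa9int")
    si <- select_best_pattern(y, g1, g2, scope = "sipi")
    expect_lte(si$fit$bic, aa$fit$bic + 1e-9)
  }
})

test_that("pair qualification flags implement the replication and multiplicity rules", {
  cfg <- screen_config(n_snps_tested = 100, n_pairs_tested = 1e5)
  pairs <- tibble::tibble(snp1 = c("a", "a", "c"), snp2 = c("b", "c", "d"))
  mk <- function(p) dplyr::mutate(pairs, p_int = p)
  disc <- mk(c(1e-4, 1e-4, 0.5))
  valid <- mk(c(2e-3, 1e-4, 0.9))
  comb <- mk(c(1e-10, 1e-6, 0.7))
  ind <- tibble::tibble(snp_id = c("a", "b", "c", "d"), p = c(1e-3, 1e-2, 0.5, 0.9))
  q <- qualify_pairs(disc, valid, comb, ind, cfg)
  expect_equal(q$validated, c(FALSE, TRUE, FALSE))   # pair 1 fails validation
  expect_equal(q$promising, c(FALSE, TRUE, FALSE))
  expect_equal(q$bonferroni_significant, c(TRUE, FALSE, FALSE))  # cut at 5e-7
  expect_equal(q$interaction_stronger, c(TRUE, TRUE, FALSE))
  # flag monotonicity: Bonferroni significance implies the promising cutoff
  # whenever promising_p >= the Bonferroni level
  expect_true(all(!q$bonferroni_significant |
                    q$p_combined < max(cfg$promising_p, cfg$bonferroni_interaction)))
  expect_error(qualify_pairs(disc[1:2, ], valid, comb, ind, cfg), "same pairs")
  expect_error(qualify_pairs(disc, valid, comb, ind[1:2, ], cfg), "missing")
})

test_that("3x3 prevalence table matches a brute-force cross-tabulation", {
  set.seed(204)
  n <- 700
  g1 <- rbinom(n, 2, 0.4); g2 <- rbinom(n, 2, 0.15)
  g1[1:10] <- NA
  y <- rbinom(n, 1, 0.3)
  tab <- prevalence_3x3(y, g1, g2)
  expect_equal(nrow(tab), 9)
  expect_equal(sum(tab$n), sum(!is.na(g1) & !is.na(g2) & !is.na(y)))
  for (i in 0:2) for (j in 0:2) {
    sel <- !is.na(g1) & !is.na(g2) & g1 == i & g2 == j
    cell <- tab[tab$g1 == i & tab$g2 == j, ]
    expect_equal(cell$n, sum(sel))
    if (sum(sel)) expect_equal(cell$prevalence, mean(y[sel]))
  }
  all_case <- prevalence_3x3(rep(1, n), g1, g2)
  expect_true(all(all_case$prevalence[all_case$n > 0] == 1))
  p <- ggplot2::autoplot(tab)
  expect_s3_class(p, "ggplot")
})
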