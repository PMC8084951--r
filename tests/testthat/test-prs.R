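test_that("hub clustering assigns pairs to the larger cluster and partitions them", {
  pairs <- tibble::tibble(snp1 = c("a", "a", "a", "e"),
                          snp2 = c("b", "c", "d", "f"))
  cl <- build_clusters(pairs)
  expect_equal(cl$hub[1:3], rep("a", 3))
  expect_true(cl$hub[4] %in% c("e", "f"))

  # a pair bridging two hubs lands only in the larger cluster
  bridge <- tibble::tibble(snp1 = c("a", "a", "a", "e", "a"),
                           snp2 = c("b", "c", "d", "f", "e"))
  cl2 <- build_clusters(bridge)
  expect_equal(cl2$hub[5], "a")

  # clusters partition the pairs (each pair exactly one hub)
  set.seed(301)
  rand <- tibble::tibble(snp1 = sample(letters[1:8], 30, TRUE),
                         snp2 = sample(letters[9:16], 30, TRUE))
  cl3 <- build_clusters(rand)
  expect_equal(nrow(cl3), nrow(rand))
  expect_false(anyNA(cl3$hub))
  expect_error(build_clusters(rand[0, ]), "at least 1")
})

test_that("correlated-pair pruning keeps a low-correlation subset, best p first", {
  set.seed(302)
  g <- sim_geno(1500, c(0.3, 0.3, 0.35, 0.4, 0.25, 0.3))
  pairs <- tibble::tibble(
    snp1 = c("s001", "s001", "s003", "s005"),
    snp2 = c("s002", "s002", "s004", "s006"),
    pattern = "AA_int_oo",
    p_combined = c(1e-8, 1e-6, 1e-5, 1e-4)
  )
  kept <- prune_correlated_pairs(pairs, g)
  # the duplicated pair (r = 1) loses its weaker copy
  expect_equal(sum(kept$snp1 == "s001"), 1)
  expect_equal(kept$p_combined[kept$snp1 == "s001"], 1e-8)
  # disjoint independent pairs all survive
  expect_true(all(c("s003", "s005") %in% kept$snp1))

  # post-condition audit
  vecs <- lapply(seq_len(nrow(kept)), function(i)
    pair_interaction_vector(g, kept$snp1[i], kept$snp2[i], kept$pattern[i]))
  for (i in seq_along(vecs)) for (j in seq_along(vecs)) {
    if (i < j) expect_lt(abs(cor(vecs[[i]], vecs[[j]])), 0.7)
  }
})

test_that("stepwise block selection honours its entry threshold and recovers true terms", {
  set.seed(303)
  n <- 1500
  x1 <- rbinom(n, 2, 0.3); x2 <- rbinom(n, 2, 0.4); x3 <- rbinom(n, 2, 0.35)
  y <- rbinom(n, 1, plogis(-1 + 0.45 * x1 + 0.4 * x2))
  blocks <- list(b1 = cbind(t1 = x1), b2 = cbind(t2 = x2), b_null = cbind(t3 = x3))
  sel <- stepwise_select(y, blocks, alpha = 0.01)
  expect_setequal(sel, c("b1", "b2"))
  # alpha = 1 admits everything; a null candidate at alpha = 0.1 stays out
  expect_setequal(stepwise_select(y, blocks, alpha = 0.9999), names(blocks))
  y_null <- rbinom(n, 1, 0.3)
  expect_length(stepwise_select(y_null, blocks["b_null"], alpha = 0.1), 0)
})

test_that("the fitted risk score spans 0-100 with 7 ordered groups and OR reference 1", {
  set.seed(304)
  cfg <- snpint:::fixture_presets("klk3_like", seed = 304)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(g, cfg)
  covars <- tibble::tibble(site = attr(g, "site")) |>
    dplyr::bind_cols(compute_pcs(g, 6)[-1])
  pairs <- dplyr::mutate(cfg$true_pairs, p_combined = 1e-8)
  m <- fit_prs(ph$y, g, pairs, covars)

  sc <- m$training$score
  expect_gte(min(sc, na.rm = TRUE), 0)
  expect_lte(max(sc, na.rm = TRUE), 100)
  expect_equal(range(sc, na.rm = TRUE), c(0, 100))
  expect_length(m$cutpoints, 6)
  expect_true(all(diff(m$cutpoints) >= 0))
  expect_equal(levels(m$training$group), as.character(1:7))

  # predicting the training genotypes reproduces the training scores
  pred <- predict(m, g)
  expect_equal(pred$score, sc)
  expect_equal(pred$group, m$training$group)

  # group odds ratios: reference exactly 1, strong effects increase with group
  ors <- group_odds_ratios(m$training$group, ph$y, covars)
  expect_equal(ors$or[ors$group == "4"], 1)
  expect_gt(cor(as.integer(ors$group), ors$or, method = "spearman"), 0.9)
  expect_error(group_odds_ratios(factor(rep(1, 10), levels = 1:7),
                                 rbinom(10, 1, 0.5)), "empty risk group")

  # group assignment is invariant to an affine rescaling of the raw predictor
  m2 <- m
  shift <- 3.7; scale <- 2.4
  m2$coefficients <- m$coefficients * scale
  m2$scale_min <- m$scale_min * scale + shift
  m2$scale_max <- m$scale_max * scale + shift
  m2$intercept <- m$intercept - shift
  # recompute raw lp under rescaled coefficients; subtracting the shift via
  # scale_min keeps scores identical
  blocks <- snpint:::pair_term_blocks(g, m$pairs)
  lp <- as.numeric(do.call(cbind, blocks) %*% m$coefficients)
  lp2 <- lp * scale + shift
  s1 <- 100 * (lp - m$scale_min) / (m$scale_max - m$scale_min)
  s2 <- 100 * (lp2 - m2$scale_min) / (m2$scale_max - m2$scale_min)
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("group sizes track the percentile design and prevalence is monotone", {
  set.seed(305)
  cfg <- snpint:::fixture_presets("klk3_like", seed = 305)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(g, cfg)
  covars <- tibble::tibble(site = attr(g, "site")) |>
    dplyr::bind_cols(compute_pcs(g, 6)[-1])
  m <- fit_prs(ph$y, g, dplyr::mutate(cfg$true_pairs, p_combined = 1e-8), covars)
  shares <- as.numeric(table(m$training$group)) / nrow(m$training)
  design <- c(0.01, 0.09, 0.15, 0.5, 0.15, 0.09, 0.01)
  # the score is a sum of a few discrete codings, so percentile boundaries
  # land on ties; group shares still track the design loosely
  expect_equal(which.max(shares), 4)
  expect_true(all(shares[c(1, 7)] < 0.05))
  pv <- group_prevalence(m$training$group, ph$y)
  expect_gt(cor(as.integer(pv$group), pv$prevalence, method = "spearman"), 0.9)
  expect_s3_class(ggplot2::autoplot(pv), "ggplot")
  expect_equal(nrow(tidy(m)), length(m$coefficients))
  expect_equal(glance(m)$n_pairs, nrow(cfg$true_pairs))
})

test_that("rank AUC, DeLong comparison, and bootstrap CI behave at the edges", {
  set.seed(306)
  y <- rbinom(10000, 1, 0.3)
  expect_equal(auc_rank(runif(10000), y), 0.5, tolerance = 0.02)
  expect_equal(auc_rank(y + 0.001 * runif(10000), y), 1)
  expect_error(auc_rank(runif(5), rep(1, 5)), "both classes")

  s <- runif(10000)
  same <- compare_auc(s, s, y)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  strong <- y + rnorm(10000, sd = 0.8)
  cmp <- compare_auc(strong, s, y)
  expect_gt(cmp$auc_a, cmp$auc_b)
  expect_lt(cmp$p.value, 1e-10)

  ci <- bootstrap_auc_ci(strong, y, B = 300, seed = 7)
  expect_lt(ci$conf.low, ci$auc)
  expect_gt(ci$conf.high, ci$auc)
  expect_identical(bootstrap_auc_ci(strong, y, B = 300, seed = 7), ci)
})
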