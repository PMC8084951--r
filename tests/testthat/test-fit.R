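test_that("logistic fits agree with the independent Newton oracle", {
  set.seed(101)
  n <- 600
  g1 <- rbinom(n, 2, 0.3); g2 <- rbinom(n, 2, 0.25)
  covars <- sim_covars(n)
  y <- rbinom(n, 1, plogis(-1 + 0.3 * g1 + 0.2 * g1 * g2))
  f <- fit_pattern(y, g1, g2, "AA_Full", covars)
  X <- cbind(1, covariate_matrix(covars), pattern_design("AA_Full", g1, g2))
  beta <- newton_logistic(X, y)
  expect_equal(tidy(f)$estimate, beta, tolerance = 1e-8)
  ll <- loglik_bernoulli(X, y, beta)
  expect_equal(f$loglik, ll, tolerance = 1e-8)
  expect_equal(f$bic, -2 * ll + ncol(X) * log(n), tolerance = 1e-8)
})

test_that("linear fits agree with closed-form OLS and its Gaussian BIC", {
  set.seed(102)
  n <- 300
  g1 <- rbinom(n, 2, 0.4); g2 <- rbinom(n, 2, 0.35)
  trait <- 0.5 * g1 * g2 + rnorm(n)
  f <- fit_pattern(trait, g1, g2, "AA_M1_int_o1", link = "linear")
  X <- cbind(1, pattern_design("AA_M1_int_o1", g1, g2))
  o <- ols_oracle(X, trait)
  expect_equal(tidy(f)$estimate, o$beta, tolerance = 1e-10)
  expect_equal(f$loglik, o$loglik, tolerance = 1e-10)
  expect_equal(f$bic, -2 * o$loglik + (ncol(X) + 1) * log(n), tolerance = 1e-10)
})

test_that("a binary interaction-only fit reproduces the 2x2 cross-product odds ratio", {
  # contingency counts: exposure = DD interaction indicator
  counts <- c(n00 = 420, n01 = 80, n10 = 230, n11 = 120)  # (exposed, case)
  x <- rep(c(0, 0, 1, 1), counts)
  y <- rep(c(0, 1, 0, 1), counts)
  # both SNPs carriers <=> exposed: set g1 = g2 = 2*x so DD coding equals x
  f <- fit_pattern(y, 2 * x, 2 * x, "DD_int_oo")
  or_hand <- (counts["n11"] * counts["n00"]) / (counts["n10"] * counts["n01"])
  expect_equal(tidy(f)$or[2], unname(or_hand), tolerance = 1e-8)
})

test_that("separation is flagged as non-convergence, not an exception", {
  y <- c(rep(0, 30), rep(1, 30))
  g1 <- c(rep(0, 30), rep(2, 30))
  g2 <- rep(c(0, 1, 2), 20)
  f <- fit_pattern(y, g1, g2, "AA_M1_int_o1")
  expect_true(f$evaluable)
  expect_false(f$converged)
})

test_that("degenerate designs are signalled as not evaluable", {
  set.seed(103)
  g2 <- rbinom(200, 2, 0.3)
  y <- rbinom(200, 1, 0.3)
  f <- fit_pattern(y, rep(1, 200), g2, "RR_int_oo")  # monomorphic SNP1
  expect_false(f$evaluable)
  expect_equal(nrow(tidy(f)), 0)
  f2 <- aa_full_test(y, rep(0, 200), g2)
  expect_false(f2$evaluable)
})

test_that("BIC selection returns the lowest-BIC pattern with a deterministic tie rule", {
  set.seed(104)
  n <- 800
  g1 <- rbinom(n, 2, 0.3); g2 <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-1 + 0.5 * (g1 >= 1) * (g2 >= 1)))
  # scope restricted to one pattern returns that pattern
  one <- sipi_patterns("sipi")[3, ]
  sel <- select_best_pattern(y, g1, g2, scope = one)
  expect_equal(sel$fit$label, one$label)

  # exact tie (duplicated scope rows): the earlier row wins
  dup <- dplyr::bind_rows(one, one)
  dup$label[2] <- paste0(one$label, "_copy")
  sel2 <- select_best_pattern(y, g1, g2, scope = dup)
  expect_equal(sel2$fit$label, one$label)

  # full search agrees with an exhaustive refit
  sel3 <- select_best_pattern(y, g1, g2, scope = "sipi")
  all_bic <- vapply(seq_len(45), function(i) {
    f <- fit_pattern(y, g1, g2, sipi_patterns("sipi")[i, ])
    if (f$evaluable && isTRUE(f$converged)) f$bic else Inf
  }, numeric(1))
  expect_equal(sel3$fit$bic, min(all_bic))
  # the pair-dropped signal
  expect_null(select_best_pattern(y, rep(0, n), rep(0, n), scope = "sipi"))
})

test_that("the conventional additive full test equals an independent refit", {
  set.seed(105)
  n <- 500
  g1 <- rbinom(n, 2, 0.3); g2 <- rbinom(n, 2, 0.4)
  y <- rbinom(n, 1, plogis(-1 + 0.2 * g1 - 0.1 * g2))
  f <- aa_full_test(y, g1, g2)
  ref <- glm(y ~ g1 + g2 + I(g1 * g2), family = binomial())
  expect_equal(f$interaction_p, summary(ref)$coefficients["I(g1 * g2)", 4],
               tolerance = 1e-6)
})

test_that("best inheritance mode recovers the generating mode and orders ties", {
  set.seed(106)
  hits_add <- 0; hits_rec <- 0
  for (r in 1:40) {
    n <- 4000
    g <- rbinom(n, 2, 0.3)
    y_add <- rbinom(n, 1, plogis(-1.4 + log(1.45) * g))
    y_rec <- rbinom(n, 1, plogis(-1.3 + 0.9 * (g == 2)))
    if (best_inheritance_mode(y_add, g)$mode == "A") hits_add <- hits_add + 1
    if (best_inheritance_mode(y_rec, g)$mode == "R") hits_rec <- hits_rec + 1
  }
  expect_gt(hits_add / 40, 0.5)
  expect_gt(hits_rec / 40, 0.5)
  expect_error(best_inheritance_mode(rbinom(100, 1, 0.3), rep(2, 100)), "monomorphic")
})

test_that("pattern selection is invariant to subject order and covariate column order", {
  set.seed(107)
  n <- 500
  g1 <- rbinom(n, 2, 0.35); g2 <- rbinom(n, 2, 0.3)
  covars <- sim_covars(n)
  y <- rbinom(n, 1, plogis(-1 + 0.4 * (g1 >= 1) * (g2 >= 1)))
  sel <- select_best_pattern(y, g1, g2, covars, scope = "sipi")
  perm <- sample(n)
  sel_p <- select_best_pattern(y[perm], g1[perm], g2[perm], covars[perm, ],
                               scope = "sipi")
  expect_equal(sel_p$fit$label, sel$fit$label)
  expect_equal(sel_p$fit$bic, sel$fit$bic, tolerance = 1e-9)
  sel_c <- select_best_pattern(y, g1, g2, covars[, c(4:7, 1:3)], scope = "sipi")
  expect_equal(sel_c$fit$label, sel$fit$label)
  expect_equal(sel_c$fit$bic, sel$fit$bic, tolerance = 1e-9)
})
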