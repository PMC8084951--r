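#' Cluster qualified SNP pairs around hub SNPs
#'
#' A hub is a SNP participating in many qualified pairs. Hubs are chosen
#' greedily by descending pair-membership count; each pair is assigned to the
#' cluster of its member SNP with the larger total count (ties by SNP id), so
#' a pair appearing under two potential hubs is kept only in the larger
#' cluster and the clusters partition the pairs.
#'
#' @param pairs Tibble with `snp1`, `snp2` (qualified pairs).
#' @return Input tibble plus a `hub` column.
#' @export
build_clusters <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (!nrow(pairs)) stop("need at least 1 qualified pair")
  counts <- sort(table(c(pairs$snp1, pairs$snp2)), decreasing = TRUE)
  cnt <- function(id) as.integer(counts[id])
  hub <- purrr::map2_chr(pairs$snp1, pairs$snp2, function(a, b) {
    ca <- cnt(a); cb <- cnt(b)
    if (ca > cb) a else if (cb > ca) b else min(a, b)
  })
  dplyr::mutate(pairs, hub = hub)
}

#' Interaction-coded term vector for a pair under its selected pattern
#' @param g A [geno] object.
#' @param snp1,snp2 SNP ids.
#' @param pattern Pattern label.
#' @return Numeric vector (the product term), `NA` where genotypes are missing.
#' @export
pair_interaction_vector <- function(g, snp1, snp2, pattern) {
  p <- as_pattern(pattern)
  x1 <- encode_genotype(geno_vector(g, snp1), p$mode1, p$code1)
  x2 <- encode_genotype(geno_vector(g, snp2), p$mode2, p$code2)
  interaction_term(x1, x2)
}

#' Drop highly correlated SNP pairs within a cluster
#'
#' Pairs are considered in order of ascending combined p-value and retained
#' only if the absolute Pearson correlation between their interaction-coded
#' term vectors and every already-retained pair's vector stays below `r_max`.
#'
#' @param pairs Tibble with `snp1`, `snp2`, `pattern`, and a combined
#'   p-value column `p_combined`.
#' @param g A [geno] object.
#' @param r_max Correlation ceiling (default 0.7).
#' @return The retained subset of `pairs`, in retention order.
#' @export
prune_correlated_pairs <- function(pairs, g, r_max = 0.7) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("snp1", "snp2", "pattern", "p_combined") %in% names(pairs)))
  ord <- order(pairs$p_combined, pairs$snp1, pairs$snp2)
  vecs <- list()
  keep <- integer(0)
  for (i in ord) {
    v <- pair_interaction_vector(g, pairs$snp1[i], pairs$snp2[i], pairs$pattern[i])
    ok <- TRUE
    for (w in vecs) {
      r <- suppressWarnings(cor(v, w, use = "pairwise.complete.obs"))
      if (!is.na(r) && abs(r) >= r_max) { ok <- FALSE; break }
      if (is.na(r)) { ok <- FALSE; break }  # constant vector duplicates nothing useful
    }
    if (ok) {
      keep <- c(keep, i)
      vecs[[length(vecs) + 1]] <- v
    }
  }
  pairs[keep, ]
}

# Build the named list of term-column blocks for a set of pairs. Each block
# holds the design columns of the pair's selected pattern (1 column for Int,
# 2 for M1_int/M2_int, 3 for Full); blocks enter/leave models together.
pair_term_blocks <- function(g, pairs) {
  blocks <- purrr::pmap(pairs[c("snp1", "snp2", "pattern")],
                        function(snp1, snp2, pattern) {
    D <- pattern_design(pattern, geno_vector(g, snp1), geno_vector(g, snp2))
    colnames(D) <- paste(snp1, snp2, colnames(D), sep = ".")
    D
  })
  names(blocks) <- paste(pairs$snp1, pairs$snp2, sep = "|")
  blocks
}

#' Stepwise selection over term blocks
#'
#' Forward selection with backward elimination at a single significance level
#' `alpha` (entry = stay). Candidates are ordered deterministically by
#' ascending marginal p-value (ties by name); covariates are always retained;
#' a block's p-value is the Wald p of its interaction term. A block's columns
#' enter and leave the model together.
#'
#' @param y Binary outcome vector.
#' @param blocks Named list of numeric matrices (term blocks), e.g. from
#'   pair designs; each matrix's last column is its interaction term.
#' @param covariates Optional covariate data frame.
#' @param alpha Entry/stay significance level.
#' @return Character vector of selected block names (possibly empty).
#' @export
stepwise_select <- function(y, blocks, covariates = NULL, alpha = 0.05) {
  if (!length(blocks)) stop("need at least 1 candidate block")
  if (is.null(names(blocks)) || anyNA(names(blocks))) {
    stop("blocks must be named")
  }
  cm <- covariate_matrix(covariates)
  base_X <- if (ncol(cm)) cbind(`(Intercept)` = 1, cm) else
    matrix(1, nrow = length(y), dimnames = list(NULL, "(Intercept)"))

  block_p <- function(selected, candidate) {
    # Wald p of `candidate`'s interaction term in the model with `selected`
    X <- base_X
    for (nm in selected) X <- cbind(X, blocks[[nm]])
    X <- cbind(X, blocks[[candidate]])
    cc <- complete.cases(X) & !is.na(y)
    Xc <- X[cc, , drop = FALSE]
    if (nrow(Xc) < ncol(Xc) + 10) return(NA_real_)
    f <- tryCatch(fit_design(Xc, y[cc], "logistic"), error = function(e) NULL)
    if (is.null(f) || !f$converged) return(NA_real_)
    j <- ncol(Xc)
    if (f$aliased[j]) return(NA_real_)
    unname(f$p_value[j])
  }

  marg <- vapply(names(blocks), function(nm) block_p(character(0), nm), numeric(1))
  cand <- names(blocks)[order(marg, names(blocks))]
  selected <- character(0)
  repeat {
    remaining <- setdiff(cand, selected)
    if (!length(remaining)) break
    ps <- vapply(remaining, function(nm) block_p(selected, nm), numeric(1))
    if (all(is.na(ps)) || min(ps, na.rm = TRUE) >= alpha) break
    entrant <- remaining[which.min(ps)]
    selected <- c(selected, entrant)
    # backward: refit and drop any earlier block whose interaction p >= alpha
    repeat {
      droppable <- setdiff(selected, entrant)
      if (!length(droppable)) break
      drop_p <- vapply(droppable, function(nm) {
        block_p(setdiff(selected, nm), nm)
      }, numeric(1))
      worst <- which.max(drop_p)
      if (!length(worst) || is.na(drop_p[worst]) || drop_p[worst] < alpha) break
      selected <- setdiff(selected, names(drop_p)[worst])
    }
  }
  selected
}

#' Fit the SNP-interaction polygenic risk score model
#'
#' Joint logistic fit of the outcome on covariates plus the selected pairs'
#' pattern term blocks. The risk score is the genotype-only linear predictor
#' (covariates excluded), min-max scaled to 0-100 on the training cohort.
#' Subjects are stratified into 7 risk groups at the score percentiles
#' \{1, 10, 25, 75, 90, 99\}; the middle group (25-75%) is the reference.
#'
#' @param y Binary outcome vector.
#' @param g A [geno] object.
#' @param pairs Tibble with `snp1`, `snp2`, `pattern` (the selected pairs).
#' @param covariates Optional covariate data frame.
#' @return Object of class `prs_model`: selected terms with coefficients,
#'   training score scaling, group cutpoints, and per-subject training
#'   scores/groups. Supports [tidy()], [glance()], [predict()].
#' @export
fit_prs <- function(y, g, pairs, covariates = NULL) {
  stopifnot(nrow(pairs) >= 1)
  blocks <- pair_term_blocks(g, pairs)
  term_mat <- do.call(cbind, blocks)
  cm <- covariate_matrix(covariates)
  X <- if (ncol(cm)) cbind(`(Intercept)` = 1, cm, term_mat)
       else cbind(`(Intercept)` = 1, term_mat)
  cc <- complete.cases(X) & !is.na(y)
  f <- fit_design(X[cc, , drop = FALSE], y[cc], "logistic")
  if (!f$converged) stop("PRS model fit did not converge")
  term_idx <- seq(ncol(X) - ncol(term_mat) + 1, ncol(X))
  beta <- f$coefficients[term_idx]
  beta[is.na(beta)] <- 0

  lp <- as.numeric(term_mat %*% beta)  # all subjects with complete genotypes
  lp[!complete.cases(term_mat)] <- NA
  lp_train <- lp[cc]
  lo <- min(lp_train); hi <- max(lp_train)
  degenerate <- hi - lo <= .Machine$double.eps * max(1, abs(hi))
  score <- if (degenerate) rep(0, length(lp)) else 100 * (lp - lo) / (hi - lo)

  cut_q <- c(0.01, 0.10, 0.25, 0.75, 0.90, 0.99)
  cuts <- quantile(score[cc], cut_q, na.rm = TRUE, names = FALSE)
  model <- structure(list(
    pairs = tibble::as_tibble(pairs),
    coefficients = setNames(as.numeric(beta), colnames(term_mat)),
    intercept = unname(f$coefficients[1]),
    covariate_coefficients = if (ncol(cm))
      setNames(f$coefficients[2:(1 + ncol(cm))], colnames(cm)) else numeric(0),
    scale_min = lo, scale_max = hi, cutpoints = cuts,
    reference_group = 4L, degenerate = degenerate,
    loglik = f$loglik, bic = f$bic, n_used = f$n
  ), class = "prs_model")
  model$training <- tibble::tibble(score = score,
                                   group = prs_group(model, score))
  model
}

prs_group <- function(model, score) {
  if (model$degenerate) return(factor(rep(NA_integer_, length(score)), levels = 1:7))
  cuts <- model$cutpoints
  if (any(diff(cuts) <= 0)) {
    # collapsed percentiles (small n): jitter cutpoints minimally upward to
    # keep the 7-level factor well defined
    cuts <- cummax(cuts + seq_along(cuts) * 1e-9)
  }
  factor(findInterval(score, cuts) + 1L, levels = 1:7)
}

#' @export
print.prs_model <- function(x, ...) {
  cat("<prs_model> ", nrow(x$pairs), " SNP-pair term block(s), ",
      length(x$coefficients), " genotype term(s)\n", sep = "")
  cat("  score range 0-100 (training linear predictor ",
      signif(x$scale_min, 4), " .. ", signif(x$scale_max, 4), ")\n", sep = "")
  cat("  group cutpoints: ", paste(signif(x$cutpoints, 4), collapse = ", "),
      " (reference group ", x$reference_group, ")\n", sep = "")
  if (x$degenerate) cat("  NOTE: degenerate score (all coefficients zero)\n")
  invisible(x)
}

#' @rdname fit_prs
#' @param object,x A `prs_model`.
#' @param newdata A [geno] object to score.
#' @param ... Unused.
#' @return `predict()`: tibble with `subject_id`, `score` (0-100 scale,
#'   training scaling; scores outside the training range are not truncated)
#'   and `group` (1-7).
#' @export
predict.prs_model <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "geno"))
  blocks <- pair_term_blocks(newdata, object$pairs)
  term_mat <- do.call(cbind, blocks)
  beta <- object$coefficients[colnames(term_mat)]
  lp <- as.numeric(term_mat %*% beta)
  lp[!complete.cases(term_mat)] <- NA
  score <- if (object$degenerate) rep(0, length(lp))
           else 100 * (lp - object$scale_min) / (object$scale_max - object$scale_min)
  tibble::tibble(subject_id = newdata$subject_ids, score = score,
                 group = prs_group(object, score))
}

#' @rdname fit_prs
#' @method tidy prs_model
#' @export
tidy.prs_model <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @rdname fit_prs
#' @method glance prs_model
#' @export
glance.prs_model <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$pairs), n_terms = length(x$coefficients),
                 logLik = x$loglik, BIC = x$bic, nobs = x$n_used,
                 degenerate = x$degenerate)
}

#' Odds ratios of risk groups against the reference group
#'
#' Logistic fit of the outcome on risk-group indicators plus covariates; the
#' reference (middle 50%) group's OR is fixed at 1.
#'
#' @param groups Factor of risk groups (levels 1-7) per subject.
#' @param y Binary outcome vector.
#' @param covariates Optional covariate data frame.
#' @param reference Reference level (default `"4"`).
#' @return Tibble: `group`, `or`, `conf.low`, `conf.high`, `p.value`
#'   (reference row has OR 1 and `NA` inference columns).
#' @export
group_odds_ratios <- function(groups, y, covariates = NULL, reference = "4") {
  if (!is.factor(groups)) {
    groups <- factor(groups, levels = sort(unique(as.character(groups))))
  }
  tab <- table(groups)
  if (any(tab == 0)) {
    stop("empty risk group(s): ", paste(names(tab)[tab == 0], collapse = ", "))
  }
  groups <- stats::relevel(groups, ref = reference)
  gm <- model.matrix(~ groups)[, -1, drop = FALSE]
  colnames(gm) <- sub("^groups", "group", colnames(gm))
  cm <- covariate_matrix(covariates)
  X <- if (ncol(cm)) cbind(`(Intercept)` = 1, gm, cm)
       else cbind(`(Intercept)` = 1, gm)
  cc <- complete.cases(X) & !is.na(y)
  f <- fit_design(X[cc, , drop = FALSE], y[cc], "logistic")
  idx <- 1 + seq_len(ncol(gm))
  est <- f$coefficients[idx]; se <- f$se[idx]
  out <- tibble::tibble(
    group = sub("^group", "", colnames(gm)),
    or = exp(unname(est)),
    conf.low = exp(unname(est - qnorm(0.975) * se)),
    conf.high = exp(unname(est + qnorm(0.975) * se)),
    p.value = unname(f$p_value[idx])
  )
  dplyr::bind_rows(
    tibble::tibble(group = reference, or = 1, conf.low = NA_real_,
                   conf.high = NA_real_, p.value = NA_real_),
    out
  ) |>
    dplyr::arrange(.data$group)
}

#' Area under the ROC curve via the rank statistic
#' @param scores Numeric risk scores.
#' @param y Binary outcome (both classes required).
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, y) {
  cc <- !is.na(scores) & !is.na(y)
  scores <- scores[cc]; y <- y[cc]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("y must contain both classes")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compare two risk scores by AUC on the same subjects
#'
#' AUCs computed by the rank statistic; the paired comparison uses the
#' DeLong asymptotic test for correlated ROC curves.
#'
#' @param scores_a,scores_b Numeric scores on the same subjects.
#' @param y Binary outcome.
#' @return Tibble: `auc_a`, `auc_b`, `statistic`, `p.value`.
#' @export
compare_auc <- function(scores_a, scores_b, y) {
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(y)) {
    stop("scores_a, scores_b and y must have equal length")
  }
  a <- auc_rank(scores_a, y)
  b <- auc_rank(scores_b, y)
  if (isTRUE(all.equal(scores_a, scores_b))) {
    return(tibble::tibble(auc_a = a, auc_b = b, statistic = 0, p.value = 1))
  }
  ra <- pROC::roc(y, scores_a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(y, scores_b, quiet = TRUE, direction = "<")
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  tibble::tibble(auc_a = a, auc_b = b,
                 statistic = unname(tst$statistic), p.value = tst$p.value)
}

#' Bootstrap percentile confidence interval for an AUC
#' @param scores Numeric risk scores.
#' @param y Binary outcome.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return Tibble: `auc`, `conf.low`, `conf.high`, `B`.
#' @export
bootstrap_auc_ci <- function(scores, y, B = 1000, seed = 1L, level = 0.95) {
  point <- auc_rank(scores, y)
  n <- length(y)
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) < 2) return(NA_real_)
      auc_rank(scores[idx], y[idx])
    }, numeric(1))
  })
  qs <- quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                 na.rm = TRUE, names = FALSE)
  tibble::tibble(auc = point, conf.low = qs[1], conf.high = qs[2], B = B)
}

#' Prevalence of the outcome by risk group
#' @param groups Factor of risk groups.
#' @param y Binary outcome.
#' @return Tibble of class `prs_group_prevalence`: `group`, `n`, `prevalence`.
#' @export
group_prevalence <- function(groups, y) {
  out <- tibble::tibble(group = groups, y = y) |>
    dplyr::filter(!is.na(.data$group), !is.na(.data$y)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), prevalence = mean(.data$y), .groups = "drop")
  class(out) <- c("prs_group_prevalence", class(out))
  out
}

#' @rdname group_prevalence
#' @param object A `prs_group_prevalence` tibble.
#' @param ... Unused.
#' @method autoplot prs_group_prevalence
#' @export
autoplot.prs_group_prevalence <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$group, y = .data$prevalence)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Risk group (1 = lowest score)", y = "Outcome prevalence") +
    ggplot2::theme_minimal()
}
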