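#' Build a covariate model matrix
#'
#' Converts a covariate data frame (study `site` plus numeric columns such as
#' principal components `PC1..PC6`) into a numeric matrix without intercept.
#' `site` (and any other character/factor column) is treatment-coded against
#' its first level. A `subject_id` column, if present, is dropped.
#'
#' @param covariates Data frame or `NULL`.
#' @return Numeric matrix (0 columns when `covariates` is `NULL`).
#' @export
covariate_matrix <- function(covariates) {
  if (is.null(covariates)) return(matrix(numeric(0), nrow = 0, ncol = 0))
  df <- as.data.frame(covariates)
  df$subject_id <- NULL
  for (nm in names(df)) if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  mm <- model.matrix(~., data = df)
  mm[, -1, drop = FALSE]
}

validate_covariate_set <- function(covariates) {
  if (is.null(covariates)) return(invisible(NULL))
  nms <- names(covariates)
  pcs <- grep("^PC[0-9]+$", nms, value = TRUE)
  if (!"site" %in% nms || length(pcs) != 6) {
    stop("a covariate set requires a `site` column and exactly 6 PC columns; ",
         "found ", length(pcs), " PC column(s)")
  }
  if (!length(unique(covariates$site))) stop("site must have at least 1 level")
  invisible(NULL)
}

# Maximum-likelihood fit of y on X (X includes the intercept). Returns
# coefficients, standard errors, log-likelihood, BIC, and convergence status.
# logistic: IRLS via glm.fit; quasi-separation (any |coef| > 15 on the logit
# scale) is flagged as non-convergence. linear: least squares; the variance
# parameter counts toward BIC's parameter count.
fit_design <- function(X, y, link = c("logistic", "linear")) {
  link <- match.arg(link)
  n <- length(y)
  p_all <- ncol(X)
  if (link == "logistic") {
    fit <- suppressWarnings(
      glm.fit(X, y, family = binomial(),
              control = list(maxit = 100, epsilon = 1e-10))
    )
    coefs <- fit$coefficients
    rank <- fit$rank
    aliased <- is.na(coefs)
    Rmat <- fit$qr$qr[seq_len(rank), seq_len(rank), drop = FALSE]
    Rmat[lower.tri(Rmat)] <- 0
    cov_unscaled <- chol2inv(Rmat)
    se <- rep(NA_real_, p_all)
    se[fit$qr$pivot[seq_len(rank)]] <- sqrt(diag(cov_unscaled))
    mu <- fit$fitted.values
    eps <- 1e-12
    loglik <- sum(y * log(pmax(mu, eps)) + (1 - y) * log(pmax(1 - mu, eps)))
    k <- rank
    converged <- isTRUE(fit$converged) &&
      all(abs(coefs[!aliased]) <= 15)
    stat <- coefs / se
    pval <- 2 * pnorm(-abs(stat))
  } else {
    fit <- stats::lm.fit(X, y)
    coefs <- fit$coefficients
    rank <- fit$rank
    aliased <- is.na(coefs)
    Rmat <- fit$qr$qr[seq_len(rank), seq_len(rank), drop = FALSE]
    Rmat[lower.tri(Rmat)] <- 0
    cov_unscaled <- chol2inv(Rmat)
    rss <- sum(fit$residuals^2)
    df_res <- n - rank
    sigma2_hat <- rss / df_res
    se <- rep(NA_real_, p_all)
    se[fit$qr$pivot[seq_len(rank)]] <- sqrt(diag(cov_unscaled) * sigma2_hat)
    loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
    k <- rank + 1  # variance parameter
    converged <- df_res > 0
    stat <- coefs / se
    pval <- 2 * pt(-abs(stat), df = df_res)
  }
  list(coefficients = coefs, se = se, statistic = stat, p_value = pval,
       loglik = loglik, bic = -2 * loglik + k * log(n), k = k, n = n,
       converged = converged, aliased = aliased)
}

new_pattern_fit <- function(label, link, terms, loglik = NA_real_,
                            bic = NA_real_, n_used = NA_integer_,
                            converged = NA, evaluable = TRUE,
                            interaction_p = NA_real_) {
  structure(list(label = label, link = link, terms = terms, loglik = loglik,
                 bic = bic, n_used = n_used, converged = converged,
                 evaluable = evaluable, interaction_p = interaction_p),
            class = "pattern_fit")
}

#' Fit one interaction pattern for a SNP pair
#'
#' Maximum-likelihood fit of the outcome on intercept + covariates (site
#' dummies and principal components) + the pattern's design terms, under a
#' logistic (binary outcome) or linear (continuous trait) link. Per-term Wald
#' statistics and 95% confidence intervals are reported, along with the
#' log-likelihood and BIC (`-2 loglik + k log(n)` with `k` the number of
#' estimated parameters, including intercept and covariates, plus the
#' residual variance under the linear link).
#'
#' A design whose pattern columns are constant or aliased over complete cases
#' is not evaluable (distinct from a fit that fails to converge, e.g. under
#' quasi-separation, which returns `converged = FALSE`).
#'
#' @param y Outcome vector (binary for logistic, numeric for linear).
#' @param g1,g2 Genotype vectors (minor-allele counts, `NA` allowed).
#' @param pattern Pattern label or one-row tibble (see [sipi_patterns()]).
#' @param covariates Optional covariate data frame (see [covariate_matrix()]).
#' @param link `"logistic"` or `"linear"`.
#' @return A `pattern_fit` object; use [tidy()] for the per-term table and
#'   [glance()] for the one-row model summary.
#' @export
fit_pattern <- function(y, g1, g2, pattern, covariates = NULL,
                        link = c("logistic", "linear")) {
  link <- match.arg(link)
  p <- as_pattern(pattern)
  D <- pattern_design(p, g1, g2)
  cm <- covariate_matrix(covariates)
  if (nrow(cm) && nrow(cm) != length(y)) {
    stop("covariates have ", nrow(cm), " rows but y has length ", length(y))
  }
  X <- if (ncol(cm)) cbind(`(Intercept)` = 1, cm, D) else cbind(`(Intercept)` = 1, D)
  cc <- complete.cases(X) & !is.na(y)
  X <- X[cc, , drop = FALSE]
  yc <- y[cc]
  n_terms <- ncol(D)
  term_cols <- seq(ncol(X) - n_terms + 1, ncol(X))

  degenerate <- !nrow(X) ||
    any(apply(X[, term_cols, drop = FALSE], 2,
              function(col) length(unique(col)) < 2)) ||
    nrow(X) < ncol(X) + 10
  if (degenerate) {
    return(new_pattern_fit(p$label, link, terms = NULL, evaluable = FALSE,
                           n_used = nrow(X)))
  }

  f <- fit_design(X, yc, link)
  if (any(f$aliased[term_cols])) {
    return(new_pattern_fit(p$label, link, terms = NULL, evaluable = FALSE,
                           n_used = f$n))
  }
  zcrit <- if (link == "logistic") qnorm(0.975) else stats::qt(0.975, df = f$n - f$k + 1)
  terms <- tibble::tibble(
    term = colnames(X),
    estimate = unname(f$coefficients),
    std.error = unname(f$se),
    statistic = unname(f$statistic),
    p.value = unname(f$p_value),
    conf.low = unname(f$coefficients - zcrit * f$se),
    conf.high = unname(f$coefficients + zcrit * f$se)
  )
  if (link == "logistic") {
    terms$or <- exp(terms$estimate)
    terms$or.conf.low <- exp(terms$conf.low)
    terms$or.conf.high <- exp(terms$conf.high)
  }
  int_p <- terms$p.value[terms$term == "snp1_x_snp2"]
  new_pattern_fit(p$label, link, terms, loglik = f$loglik, bic = f$bic,
                  n_used = f$n, converged = f$converged,
                  interaction_p = if (length(int_p)) int_p else NA_real_)
}

#' @export
print.pattern_fit <- function(x, ...) {
  cat("<pattern_fit> ", x$label, " (", x$link, ")\n", sep = "")
  if (!x$evaluable) {
    cat("  not evaluable (degenerate design)\n")
    return(invisible(x))
  }
  cat("  n = ", x$n_used, ", BIC = ", signif(x$bic, 8),
      ", converged = ", x$converged,
      ", interaction p = ", signif(x$interaction_p, 3), "\n", sep = "")
  print(x$terms)
  invisible(x)
}

#' @rdname fit_pattern
#' @param x A `pattern_fit` object.
#' @param ... Unused.
#' @method tidy pattern_fit
#' @export
tidy.pattern_fit <- function(x, ...) {
  if (!x$evaluable) return(tibble::tibble())
  x$terms
}

#' @rdname fit_pattern
#' @method glance pattern_fit
#' @export
glance.pattern_fit <- function(x, ...) {
  tibble::tibble(label = x$label, link = x$link, logLik = x$loglik,
                 BIC = x$bic, nobs = x$n_used, converged = x$converged,
                 evaluable = x$evaluable, interaction_p = x$interaction_p)
}

#' Select the best interaction pattern for a SNP pair by BIC
#'
#' Fits every pattern in the scope and returns the evaluable, converged fit
#' with the lowest BIC. Exact ties resolve to the canonical pattern order
#' (`Int` < `M1_int` < `M2_int` < `Full`, then lexicographic label). The
#' pair's headline p-value is the Wald p of the selected pattern's
#' interaction term.
#'
#' @inheritParams fit_pattern
#' @param scope `"sipi"` or `"aa9int"`, or a pattern tibble from
#'   [sipi_patterns()] (possibly filtered).
#' @return List with `pattern` (one-row tibble), `fit` (a `pattern_fit`) and
#'   `n_evaluable`; `NULL` when no pattern is evaluable (pair dropped).
#' @export
select_best_pattern <- function(y, g1, g2, covariates = NULL,
                                scope = "sipi",
                                link = c("logistic", "linear")) {
  link <- match.arg(link)
  patterns <- if (is.data.frame(scope)) scope else sipi_patterns(scope)
  best <- NULL
  best_i <- NA_integer_
  n_eval <- 0L
  for (i in seq_len(nrow(patterns))) {
    f <- fit_pattern(y, g1, g2, patterns[i, ], covariates, link)
    if (!f$evaluable || !isTRUE(f$converged)) next
    n_eval <- n_eval + 1L
    if (is.null(best) || f$bic < best$bic) {
      best <- f
      best_i <- i
    }
  }
  if (is.null(best)) return(NULL)
  list(pattern = patterns[best_i, ], fit = best, n_evaluable = n_eval)
}

#' Conventional full-interaction test under additive coding
#'
#' Wald p-value of the product term in the additive-additive full model
#' (SNP1 + SNP2 + SNP1 x SNP2 plus covariates), the conventional epistasis
#' test against which the pattern search is compared.
#'
#' @inheritParams fit_pattern
#' @return A `pattern_fit` for the `AA_Full` model (its `interaction_p` is
#'   the test p-value).
#' @export
aa_full_test <- function(y, g1, g2, covariates = NULL) {
  fit_pattern(y, g1, g2, "AA_Full", covariates, link = "logistic")
}

#' Best single-SNP inheritance mode
#'
#' Fits single-SNP logistic models under additive, dominant, and recessive
#' coding (original direction, adjusted for covariates) and returns the mode
#' with the smallest SNP-term Wald p-value; exact ties resolve in the order
#' A < D < R.
#'
#' @param y Binary outcome vector.
#' @param g Genotype vector (minor-allele counts).
#' @param covariates Optional covariate data frame.
#' @return List with `mode` (`"A"`, `"D"` or `"R"`), `p` (SNP-term p-value),
#'   and `fits`, a tibble of all three mode fits (`mode`, `estimate`, `or`,
#'   `conf.low`, `conf.high`, `p.value`, `bic`, `converged`).
#' @export
best_inheritance_mode <- function(y, g, covariates = NULL) {
  gg <- g[!is.na(g)]
  if (length(unique(gg)) < 2) stop("SNP is monomorphic")
  cm <- covariate_matrix(covariates)
  rows <- purrr::map(c("A", "D", "R"), function(m) {
    x <- encode_genotype(g, m, "o")
    X <- if (ncol(cm)) cbind(`(Intercept)` = 1, cm, snp = x)
         else cbind(`(Intercept)` = 1, snp = x)
    cc <- complete.cases(X) & !is.na(y)
    Xc <- X[cc, , drop = FALSE]
    if (length(unique(Xc[, "snp"])) < 2) {
      return(tibble::tibble(mode = m, estimate = NA_real_, or = NA_real_,
                            conf.low = NA_real_, conf.high = NA_real_,
                            p.value = NA_real_, bic = NA_real_, converged = FALSE))
    }
    f <- fit_design(Xc, y[cc], "logistic")
    j <- ncol(Xc)
    est <- f$coefficients[j]
    se <- f$se[j]
    tibble::tibble(mode = m, estimate = unname(est), or = exp(unname(est)),
                   conf.low = exp(unname(est - qnorm(0.975) * se)),
                   conf.high = exp(unname(est + qnorm(0.975) * se)),
                   p.value = unname(f$p_value[j]), bic = f$bic,
                   converged = f$converged)
  })
  fits <- dplyr::bind_rows(rows)
  ok <- which(!is.na(fits$p.value) & fits$converged)
  if (!length(ok)) stop("no evaluable inheritance-mode fit for this SNP")
  best <- ok[which.min(fits$p.value[ok])]  # ties: first in A < D < R order
  list(mode = fits$mode[best], p = fits$p.value[best], fits = fits)
}
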