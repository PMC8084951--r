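# Independent oracles and small fixture builders shared across tests.

# Hand-rolled Bernoulli log-likelihood.
loglik_bernoulli <- function(X, y, beta) {
  eta <- as.numeric(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

# Independent logistic MLE: plain Newton-Raphson on the hand-written
# likelihood (no IRLS / glm machinery).
newton_logistic <- function(X, y, max_iter = 200, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    mu <- plogis(as.numeric(X %*% beta))
    grad <- as.numeric(t(X) %*% (y - mu))
    H <- t(X * (mu * (1 - mu))) %*% X
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  unname(beta)
}

# Closed-form OLS with the Gaussian MLE log-likelihood.
ols_oracle <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y)
  rss <- sum(res^2)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  list(beta = as.numeric(beta), loglik = ll)
}

# Brute-force exact HWE test: enumerate the full conditional distribution of
# heterozygote counts from the log-factorial formula (independent of the
# recurrence used by the implementation).
hwe_brute_force <- function(n_hom_major, n_het, n_hom_minor) {
  n <- n_hom_major + n_het + n_hom_minor
  n_minor <- 2 * n_hom_minor + n_het
  rare <- min(n_minor, 2 * n - n_minor)
  if (rare == 0) return(1)
  het_vals <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(het_vals, function(het) {
    hom_r <- (rare - het) / 2
    hom_c <- n - het - hom_r
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(het + 1) - lgamma(hom_c + 1) +
      het * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  obs <- probs[het_vals == n_het]
  min(sum(probs[probs <= obs * (1 + 1e-10)]), 1)
}

# Quick genotype panel: independent SNPs at given MAFs, no metadata frills.
sim_geno <- function(n, mafs, ids = sprintf("s%03d", seq_along(mafs))) {
  values <- vapply(mafs, function(p) rbinom(n, 2, p), numeric(n))
  geno(values, tibble::tibble(snp_id = ids, chrom = "1",
                              pos = seq_along(mafs) * 2e5, maf = mafs))
}

# Site + 6 PC covariate frame with mild real structure.
sim_covars <- function(n, n_sites = 2) {
  tibble::tibble(site = sample(paste0("site", seq_len(n_sites)), n, TRUE)) |>
    dplyr::bind_cols(tibble::as_tibble(
      matrix(rnorm(n * 6, sd = 0.5), n, dimnames = list(NULL, paste0("PC", 1:6)))))
}
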