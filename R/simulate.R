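# Latent Gaussian-copula correlation achieving a target correlation between
# two Bernoulli allele indicators with frequencies p1, p2. The allele of a
# haplotype is 1 when the latent normal falls below qnorm(p); genotypes are
# sums of two independent haplotypes, so the genotype correlation equals the
# allele correlation.
latent_allele_rho <- function(p1, p2, r_target) {
  if (r_target == 0) return(0)
  t1 <- qnorm(p1); t2 <- qnorm(p2)
  denom <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  allele_cor <- function(rho) {
    p11 <- integrate(function(z) {
      dnorm(z) * pnorm((t2 - rho * z) / sqrt(1 - rho^2))
    }, lower = -Inf, upper = t1, rel.tol = 1e-11)$value
    (p11 - p1 * p2) / denom
  }
  lim <- 1 - 1e-10
  r_max <- allele_cor(lim)
  r_min <- allele_cor(-lim)
  if (r_target > r_max || r_target < r_min) {
    stop(sprintf(
      "target allele correlation %.3f infeasible for MAFs %.3f/%.3f; feasible r^2 at most %.3f",
      r_target, p1, p2, max(r_max^2, r_min^2)))
  }
  uniroot(function(rho) allele_cor(rho) - r_target,
          lower = -lim, upper = lim, tol = 1e-10)$root
}

#' Simulation configuration
#'
#' Describes a synthetic cohort: genotype panel (per-SNP MAF, genomic layout,
#' LD blocks with target pairwise r^2), study sites with random site effects,
#' optional ancestry subpopulations expressed as MAF offsets (so principal
#' components carry real signal), a true disease model (SNP-pair interaction
#' terms with log odds ratios plus individual additive SNP effects), and the
#' marginal outcome prevalence the intercept is calibrated to.
#'
#' @param n_subjects Number of subjects.
#' @param snps Tibble with `snp_id`, `maf` and optionally `chrom`, `pos`,
#'   `block` (block label; `NA` = independent SNP).
#' @param block_r2 Named numeric vector of target pairwise genotype r^2 per
#'   block label (default 0.9 for any unnamed block).
#' @param n_sites Number of study sites (default 2).
#' @param site_effect_sd SD of per-site log-odds effects (default 0.1).
#' @param subpops Optional tibble with `prop` and `maf_offset` defining
#'   ancestry subpopulations (proportions must sum to 1).
#' @param true_pairs Tibble with `snp1`, `snp2`, `pattern`, `log_or` (and
#'   optionally `log_or_main` for patterns with a main-effect term).
#' @param true_snps Tibble with `snp_id`, `log_or` (additive per-allele).
#' @param prevalence Target marginal outcome prevalence (default 0.226).
#' @param missing_rate Genotype missingness rate (default 0).
#' @param seed Integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_subjects, snps, block_r2 = NULL, n_sites = 2,
                       site_effect_sd = 0.1, subpops = NULL,
                       true_pairs = NULL, true_snps = NULL,
                       prevalence = 0.226, missing_rate = 0, seed = 1L) {
  snps <- tibble::as_tibble(snps)
  stopifnot(all(c("snp_id", "maf") %in% names(snps)))
  if (!"chrom" %in% names(snps)) snps$chrom <- "1"
  if (!"pos" %in% names(snps)) snps$pos <- seq_len(nrow(snps)) * 200000L
  if (!"block" %in% names(snps)) snps$block <- NA_character_
  if (any(snps$maf <= 0 | snps$maf > 0.5)) stop("MAFs must lie in (0, 0.5]")
  if (!is.null(block_r2) && any(block_r2 < 0 | block_r2 >= 1)) {
    stop("target r^2 must lie in [0, 1)")
  }
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must lie in (0, 1)")
  if (!is.null(subpops)) {
    subpops <- tibble::as_tibble(subpops)
    stopifnot(all(c("prop", "maf_offset") %in% names(subpops)))
    if (abs(sum(subpops$prop) - 1) > 1e-8) stop("subpop proportions must sum to 1")
  }
  structure(list(n_subjects = n_subjects, snps = snps, block_r2 = block_r2,
                 n_sites = n_sites, site_effect_sd = site_effect_sd,
                 subpops = subpops,
                 true_pairs = if (is.null(true_pairs)) NULL else tibble::as_tibble(true_pairs),
                 true_snps = if (is.null(true_snps)) NULL else tibble::as_tibble(true_snps),
                 prevalence = prevalence, missing_rate = missing_rate,
                 seed = seed),
            class = "sim_config")
}

#' Simulate a genotype panel with block LD structure
#'
#' Within an LD block, haplotypes are drawn from a latent multivariate normal
#' (Gaussian copula) whose correlation is solved numerically so the pairwise
#' genotype r^2 matches the block's target; across blocks SNPs are
#' independent, and Hardy-Weinberg equilibrium holds within each ancestry
#' subpopulation (genotype = sum of two independent haplotypes).
#'
#' @param cfg A [sim_config].
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return A [geno] object; the subject-level subpopulation and site labels
#'   are attached as attributes `subpop` and `site`.
#' @export
simulate_genotypes <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_subjects
  snps <- cfg$snps
  m <- nrow(snps)
  with_seed(seed, {
    subpop <- if (is.null(cfg$subpops)) rep(1L, n) else {
      sample.int(nrow(cfg$subpops), n, replace = TRUE, prob = cfg$subpops$prop)
    }
    site <- sample(paste0("site", seq_len(cfg$n_sites)), n, replace = TRUE)
    values <- matrix(NA_real_, n, m)

    blocks <- split(seq_len(m), ifelse(is.na(snps$block), paste0(".solo", seq_len(m)),
                                       snps$block))
    for (pop in sort(unique(subpop))) {
      rows <- which(subpop == pop)
      offset <- if (is.null(cfg$subpops)) 0 else cfg$subpops$maf_offset[pop]
      p <- pmin(pmax(snps$maf + offset, 0.005), 0.6)
      for (bl in names(blocks)) {
        idx <- blocks[[bl]]
        if (length(idx) == 1L) {
          values[rows, idx] <- rbinom(length(rows), 2, p[idx])
        } else {
          r2 <- if (!is.null(cfg$block_r2) && bl %in% names(cfg$block_r2)) {
            cfg$block_r2[[bl]]
          } else 0.9
          r <- sqrt(r2)
          R <- diag(length(idx))
          for (a in seq_along(idx)) for (b in seq_along(idx)) {
            if (a < b) {
              R[a, b] <- R[b, a] <- latent_allele_rho(p[idx[a]], p[idx[b]], r)
            }
          }
          U <- tryCatch(chol(R), error = function(e) {
            stop("infeasible LD block '", bl,
                 "': latent correlation matrix is not positive definite")
          })
          thr <- qnorm(p[idx])
          gsum <- matrix(0, length(rows), length(idx))
          for (h in 1:2) {
            Z <- matrix(rnorm(length(rows) * length(idx)), length(rows)) %*% U
            gsum <- gsum + (sweep(Z, 2, thr, "<") * 1)
          }
          values[rows, idx] <- gsum
        }
      }
    }
    if (cfg$missing_rate > 0) {
      mask <- matrix(runif(n * m) < cfg$missing_rate, n, m)
      values[mask] <- NA
    }
    g <- geno(values, snps, paste0("S", seq_len(n)))
    attr(g, "subpop") <- subpop
    attr(g, "site") <- site
    g
  })
}

# Linear predictor (excluding intercept and site effects) of the true model.
true_model_eta <- function(g, cfg) {
  eta <- rep(0, length(g$subject_ids))
  if (!is.null(cfg$true_snps) && nrow(cfg$true_snps)) {
    for (i in seq_len(nrow(cfg$true_snps))) {
      x <- encode_genotype(geno_vector(g, cfg$true_snps$snp_id[i]), "A", "o")
      eta <- eta + cfg$true_snps$log_or[i] * ifelse(is.na(x), 0, x)
    }
  }
  if (!is.null(cfg$true_pairs) && nrow(cfg$true_pairs)) {
    for (i in seq_len(nrow(cfg$true_pairs))) {
      tp <- cfg$true_pairs[i, ]
      D <- pattern_design(tp$pattern, geno_vector(g, tp$snp1),
                          geno_vector(g, tp$snp2))
      xx <- D[, "snp1_x_snp2"]
      eta <- eta + tp$log_or * ifelse(is.na(xx), 0, xx)
      if ("log_or_main" %in% names(tp) && !is.na(tp$log_or_main) &&
          ncol(D) > 1) {
        main <- D[, 1]
        eta <- eta + tp$log_or_main * ifelse(is.na(main), 0, main)
      }
    }
  }
  eta
}

#' Simulate a binary phenotype under a logistic model
#'
#' The linear predictor combines per-site effects (drawn once from
#' `N(0, site_effect_sd)`) with the configured true SNP and SNP-pair effects;
#' the intercept is calibrated by root finding so the expected marginal
#' prevalence equals the configured baseline.
#'
#' @param g A [geno] object from [simulate_genotypes()].
#' @param cfg The [sim_config].
#' @param site Per-subject site labels (defaults to the labels attached to `g`).
#' @param seed Integer seed (defaults to `cfg$seed + 1`).
#' @return List: `y` (0/1 vector), `alpha` (calibrated intercept),
#'   `site_effects` (named vector), `expected_prevalence`.
#' @export
simulate_phenotype <- function(g, cfg, site = attr(g, "site"),
                               seed = cfg$seed + 1L) {
  stopifnot(inherits(g, "geno"), inherits(cfg, "sim_config"))
  if (is.null(site)) site <- rep("site1", length(g$subject_ids))
  with_seed(seed, {
    levels <- sort(unique(site))
    site_eff <- setNames(rnorm(length(levels), 0, cfg$site_effect_sd), levels)
    site_eff <- site_eff - site_eff[1]  # first site is the baseline
    eta <- true_model_eta(g, cfg) + unname(site_eff[site])
    f <- function(a) mean(plogis(a + eta)) - cfg$prevalence
    if (f(-30) > 0 || f(30) < 0) {
      stop("target prevalence ", cfg$prevalence,
           " unattainable under the configured effects")
    }
    alpha <- uniroot(f, c(-30, 30), tol = 1e-12)$root
    y <- rbinom(length(eta), 1, plogis(alpha + eta))
    list(y = y, alpha = alpha, site_effects = site_eff,
         expected_prevalence = cfg$prevalence)
  })
}

#' Simulate an expression trait driven by a SNP-pair interaction
#'
#' `trait = beta * interaction coding + N(0, noise_sd)`, with the interaction
#' coding taken from the pair's pattern. Missing genotypes yield missing
#' trait contributions (set to the coding's mean so the trait stays complete).
#'
#' @param g A [geno] object.
#' @param snp1,snp2 SNP ids.
#' @param pattern Pattern label (e.g. `"AA_int_oo"`).
#' @param beta Effect size per unit of interaction coding.
#' @param noise_sd Residual standard deviation (default 1).
#' @param seed Integer seed.
#' @return Numeric trait vector.
#' @export
simulate_expression <- function(g, snp1, snp2, pattern, beta, noise_sd = 1,
                                seed = 1L) {
  xx <- pair_interaction_vector(g, snp1, snp2, pattern)
  xx[is.na(xx)] <- mean(xx, na.rm = TRUE)
  with_seed(seed, beta * xx + rnorm(length(xx), 0, noise_sd))
}

fixture_presets <- function(preset, seed) {
  spread_maf <- function(k) round(seq(0.06, 0.5, length.out = k), 3)
  if (preset == "tiny") {
    k <- 50
    snps <- tibble::tibble(
      snp_id = sprintf("snp%02d", seq_len(k)), chrom = "1",
      pos = seq_len(k) * 200000L, maf = spread_maf(k),
      block = NA_character_)
    snps$block[1:2] <- "b1"; snps$pos[2] <- snps$pos[1] + 10000L
    snps$maf[2] <- snps$maf[1]  # tight LD pair mimicking two markers of one signal
    sim_config(500, snps, block_r2 = c(b1 = 0.98),
               true_pairs = tibble::tibble(snp1 = "snp05", snp2 = "snp10",
                                           pattern = "AA_int_ro",
                                           log_or = log(1.5)),
               seed = seed)
  } else if (preset == "null") {
    k <- 60
    snps <- tibble::tibble(
      snp_id = sprintf("snp%02d", seq_len(k)), chrom = "1",
      pos = seq_len(k) * 200000L, maf = spread_maf(k),
      block = NA_character_)
    sim_config(2000, snps, seed = seed)
  } else if (preset %in% c("klk3_like", "klk3-like")) {
    k <- 40
    snps <- tibble::tibble(
      snp_id = c("rs_hub", sprintf("snp%02d", seq_len(k - 1))), chrom = "1",
      pos = seq_len(k) * 200000L,
      maf = c(0.12, spread_maf(k - 1)), block = NA_character_)
    # partners span moderate-to-common MAFs and both coding directions of the
    # hub, so the multi-pair risk score has a well-spread distribution
    partners <- sprintf("snp%02d", c(8, 14, 20, 26, 32, 38))
    sim_config(10000, snps,
               true_pairs = tibble::tibble(
                 snp1 = partners, snp2 = "rs_hub",
                 pattern = c("AA_int_or", "AA_int_rr", "DD_int_oo",
                             "AA_int_ro", "RD_int_ro", "AA_int_or"),
                 log_or = log(c(1.35, 1.4, 1.8, 1.5, 2.0, 0.75))),
               true_snps = tibble::tibble(snp_id = "rs_hub", log_or = log(1.3)),
               seed = seed)
  } else {
    stop("unknown fixture preset: ", preset,
         " (available: tiny, null, klk3_like)")
  }
}

#' Write a synthetic fixture bundle to disk
#'
#' Generates genotypes, phenotype, covariates (site + 6 principal components
#' computed from the genotypes) for a named preset and writes a TSV bundle
#' plus a JSON truth file recording the generating model, suitable for
#' recovery tests. Regeneration under the same seed is byte-identical.
#'
#' Presets: `"tiny"` (500 subjects x 50 SNPs, one true interaction pair),
#' `"null"` (2000 x 60, no effects), `"klk3_like"` (10000 x 40, one hub SNP
#' participating in 6 true pairs plus an individual effect).
#'
#' @param preset Preset name.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a list with the file `paths` and the generating `cfg`.
#' @export
make_fixture <- function(preset, dir = tempdir(), seed = 1L) {
  cfg <- fixture_presets(preset, seed)
  g <- simulate_genotypes(cfg)
  site <- attr(g, "site")
  ph <- simulate_phenotype(g, cfg)
  pcs <- compute_pcs(g, k = 6)
  # deterministic sign convention so regeneration is byte-identical across
  # LAPACK builds
  for (j in 2:7) if (pcs[[j]][1] < 0) pcs[[j]] <- -pcs[[j]]
  covars <- dplyr::bind_cols(tibble::tibble(subject_id = g$subject_ids,
                                            site = site),
                             pcs[-1])
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    genotypes = file.path(dir, paste0(preset, "_genotypes.tsv")),
    snps = file.path(dir, paste0(preset, "_snps.tsv")),
    phenotype = file.path(dir, paste0(preset, "_phenotype.tsv")),
    covariates = file.path(dir, paste0(preset, "_covariates.tsv")),
    truth = file.path(dir, paste0(preset, "_truth.json"))
  )
  write_geno_tsv(g, paths$genotypes, paths$snps)
  write_tsv_plain(tibble::tibble(subject_id = g$subject_ids, aggressive = ph$y),
                  paths$phenotype)
  write_tsv_plain(covars, paths$covariates)
  truth <- list(preset = preset, seed = seed, n_subjects = cfg$n_subjects,
                prevalence = cfg$prevalence, alpha = ph$alpha,
                site_effects = as.list(ph$site_effects),
                true_pairs = cfg$true_pairs, true_snps = cfg$true_snps)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(list(paths = paths, cfg = cfg))
}
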