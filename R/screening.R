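#' Screening configuration
#'
#' Thresholds for the two-stage discovery/validation workflow: stage-1
#' (additive-additive) screening p, validation p, the relaxed "promising"
#' cutoff, and Bonferroni levels derived from the numbers of SNPs and pairs
#' tested (0.05 / n).
#'
#' @param stage1_p Stage-1 screening threshold (default 0.001).
#' @param validation_p Replication threshold in each set (default 0.001).
#' @param promising_p Combined-set threshold for promising pairs (1e-5).
#' @param n_snps_tested Number of SNPs tested individually (for the
#'   individual-effect Bonferroni level).
#' @param n_pairs_tested Number of SNP pairs tested (for the interaction
#'   Bonferroni level).
#' @param split_fraction Fraction of each site assigned to discovery (0.5).
#' @param seed Integer seed for the cohort split.
#' @return List of class `screen_config` with derived `bonferroni_individual`
#'   and `bonferroni_interaction`.
#' @examples
#' cfg <- screen_config(n_snps_tested = 8587, n_pairs_tested = 1.4e7)
#' signif(cfg$bonferroni_individual, 2)  # 5.8e-06
#' signif(cfg$bonferroni_interaction, 2)  # 3.5e-09
#' @export
screen_config <- function(stage1_p = 0.001, validation_p = 0.001,
                          promising_p = 1e-5, n_snps_tested = NULL,
                          n_pairs_tested = NULL, split_fraction = 0.5,
                          seed = 1L) {
  cfg <- list(stage1_p = stage1_p, validation_p = validation_p,
              promising_p = promising_p,
              n_snps_tested = n_snps_tested, n_pairs_tested = n_pairs_tested,
              bonferroni_individual = if (is.null(n_snps_tested)) NA_real_
                                      else 0.05 / n_snps_tested,
              bonferroni_interaction = if (is.null(n_pairs_tested)) NA_real_
                                       else 0.05 / n_pairs_tested,
              split_fraction = split_fraction, seed = seed)
  ps <- c(cfg$stage1_p, cfg$validation_p, cfg$promising_p, cfg$split_fraction)
  if (any(ps <= 0 | ps >= 1)) stop("thresholds and split fraction must lie in (0, 1)")
  structure(cfg, class = "screen_config")
}

#' Site-stratified random split into discovery and validation sets
#'
#' Within every study site, subjects are randomly assigned so that set sizes
#' differ by at most one; the assignment is reproducible under `seed`.
#'
#' @param subjects Data frame with `subject_id` and `site` columns.
#' @param fraction Fraction assigned to the discovery set (default 0.5).
#' @param seed Integer seed.
#' @return Input tibble plus a `set` column (`"discovery"`/`"validation"`).
#' @export
split_cohort <- function(subjects, fraction = 0.5, seed = 1L) {
  subjects <- tibble::as_tibble(subjects)
  stopifnot(all(c("subject_id", "site") %in% names(subjects)))
  sizes <- table(subjects$site)
  if (any(sizes < 2)) {
    stop("every site needs at least 2 subjects; offending site(s): ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  with_seed(seed, {
    subjects$set <- NA_character_
    carry <- 0  # spread fractional site targets so global totals balance
    for (s in unique(subjects$site)) {
      idx <- which(subjects$site == s)
      target <- length(idx) * fraction + carry
      n_disc <- floor(target + 0.5)
      carry <- target - n_disc
      pick <- sample(idx, n_disc)
      subjects$set[pick] <- "discovery"
      subjects$set[setdiff(idx, pick)] <- "validation"
    }
  })
  subjects
}

#' All candidate SNP pairs
#'
#' Unordered pairs of SNPs, each listed once with `snp1` preceding `snp2` in
#' genomic order (chromosome, then position).
#'
#' @param snps SNP metadata tibble with `snp_id`, `chrom`, `pos`.
#' @return Tibble with `snp1`, `snp2` (n(n-1)/2 rows).
#' @export
candidate_pairs <- function(snps) {
  snps <- tibble::as_tibble(snps)
  if (nrow(snps) < 2) stop("need at least 2 SNPs")
  ord <- snps[order(snps$chrom, snps$pos), ]
  idx <- combn(nrow(ord), 2)
  tibble::tibble(snp1 = ord$snp_id[idx[1, ]], snp2 = ord$snp_id[idx[2, ]])
}

#' Number of unordered SNP pairs
#' @param n Number of SNPs.
#' @return n(n-1)/2.
#' @export
n_candidate_pairs <- function(n) n * (n - 1) / 2

#' Scan SNP pairs with the pattern search
#'
#' Runs [select_best_pattern()] for every pair and collects the best pattern,
#' its BIC, headline interaction p-value, and the interaction-term odds ratio
#' (logistic link). Pairs with no evaluable pattern are returned with
#' `evaluable = FALSE`.
#'
#' @param g A [geno] object.
#' @param y Outcome vector aligned with `g`'s subjects.
#' @param pairs Tibble with `snp1`, `snp2`.
#' @param covariates Optional covariate data frame.
#' @param scope `"sipi"`, `"aa9int"`, or a pattern tibble.
#' @param link `"logistic"` or `"linear"`.
#' @return Tibble: `snp1`, `snp2`, `pattern`, `p_int`, `bic`, `n_used`,
#'   `or`, `or.conf.low`, `or.conf.high`, `evaluable`.
#' @export
interaction_scan <- function(g, y, pairs, covariates = NULL, scope = "sipi",
                             link = c("logistic", "linear")) {
  link <- match.arg(link)
  stopifnot(inherits(g, "geno"))
  patterns <- if (is.data.frame(scope)) scope else sipi_patterns(scope)
  rows <- purrr::pmap(pairs[c("snp1", "snp2")], function(snp1, snp2) {
    g1 <- geno_vector(g, snp1)
    g2 <- geno_vector(g, snp2)
    sel <- select_best_pattern(y, g1, g2, covariates, patterns, link)
    if (is.null(sel)) {
      return(tibble::tibble(snp1 = snp1, snp2 = snp2, pattern = NA_character_,
                            p_int = NA_real_, bic = NA_real_,
                            n_used = NA_integer_, or = NA_real_,
                            or.conf.low = NA_real_, or.conf.high = NA_real_,
                            evaluable = FALSE))
    }
    tm <- sel$fit$terms
    irow <- which(tm$term == "snp1_x_snp2")
    tibble::tibble(snp1 = snp1, snp2 = snp2, pattern = sel$fit$label,
                   p_int = sel$fit$interaction_p, bic = sel$fit$bic,
                   n_used = sel$fit$n_used,
                   or = if (link == "logistic") tm$or[irow] else tm$estimate[irow],
                   or.conf.low = if (link == "logistic") tm$or.conf.low[irow] else tm$conf.low[irow],
                   or.conf.high = if (link == "logistic") tm$or.conf.high[irow] else tm$conf.high[irow],
                   evaluable = TRUE)
  })
  dplyr::bind_rows(rows)
}

#' Two-stage interaction scan (additive screen, then full pattern search)
#'
#' Stage 1 scans every pair with the 9-pattern additive-additive search in
#' the discovery data; pairs passing `cfg$stage1_p` are re-searched with the
#' full 45-pattern scope. Results carry both stage p-values.
#'
#' @param g A [geno] object (discovery subjects).
#' @param y Discovery outcome vector.
#' @param pairs Tibble with `snp1`, `snp2`.
#' @param covariates Optional covariate data frame (discovery subjects).
#' @param cfg A [screen_config].
#' @return Tibble of stage-1 survivors with `aa9int_p`, `aa9int_pattern`,
#'   `sipi_p`, `sipi_pattern`, `sipi_bic`, `sipi_or`, `n_used`.
#' @export
two_stage_scan <- function(g, y, pairs, covariates = NULL,
                           cfg = screen_config()) {
  stage1 <- interaction_scan(g, y, pairs, covariates, scope = "aa9int")
  surv <- stage1[!is.na(stage1$p_int) & stage1$p_int < cfg$stage1_p, ]
  if (!nrow(surv)) {
    return(tibble::tibble(snp1 = character(), snp2 = character(),
                          aa9int_p = numeric(), aa9int_pattern = character(),
                          sipi_p = numeric(), sipi_pattern = character(),
                          sipi_bic = numeric(), sipi_or = numeric(),
                          n_used = integer()))
  }
  stage2 <- interaction_scan(g, y, surv[c("snp1", "snp2")], covariates,
                             scope = "sipi")
  dplyr::tibble(snp1 = surv$snp1, snp2 = surv$snp2,
                aa9int_p = surv$p_int, aa9int_pattern = surv$pattern,
                sipi_p = stage2$p_int, sipi_pattern = stage2$pattern,
                sipi_bic = stage2$bic, sipi_or = stage2$or,
                n_used = stage2$n_used)
}

#' Individual SNP effect scan
#'
#' Per SNP, the best single-SNP inheritance mode (lowest Wald p among
#' additive/dominant/recessive logistic fits).
#'
#' @param g A [geno] object.
#' @param y Binary outcome vector.
#' @param covariates Optional covariate data frame.
#' @param snp_ids SNPs to scan (default: all in `g`).
#' @return Tibble: `snp_id`, `mode`, `p`, `or`, `conf.low`, `conf.high`.
#' @export
individual_snp_scan <- function(g, y, covariates = NULL, snp_ids = NULL) {
  stopifnot(inherits(g, "geno"))
  if (is.null(snp_ids)) snp_ids <- g$snps$snp_id
  rows <- purrr::map(snp_ids, function(id) {
    res <- tryCatch(best_inheritance_mode(y, geno_vector(g, id), covariates),
                    error = function(e) NULL)
    if (is.null(res)) {
      return(tibble::tibble(snp_id = id, mode = NA_character_, p = NA_real_,
                            or = NA_real_, conf.low = NA_real_,
                            conf.high = NA_real_))
    }
    best <- res$fits[res$fits$mode == res$mode, ]
    tibble::tibble(snp_id = id, mode = res$mode, p = res$p, or = best$or,
                   conf.low = best$conf.low, conf.high = best$conf.high)
  })
  dplyr::bind_rows(rows)
}

#' Qualify SNP pairs against validation and multiplicity criteria
#'
#' Combines discovery, validation, and combined-set scan results for the same
#' pairs and sets the qualification flags:
#' `validated` (p < `validation_p` in both independent sets), `promising`
#' (validated and combined p < `promising_p`), `bonferroni_significant`
#' (combined p below 0.05 / n pairs tested), and `interaction_stronger`
#' (combined interaction p smaller than both constituent SNPs' combined
#' individual-effect p-values).
#'
#' @param discovery,validation,combined Tibbles with `snp1`, `snp2` and a
#'   p-value column named `p_int` or `sipi_p`.
#' @param individual Tibble from [individual_snp_scan()] on the combined set
#'   (`snp_id`, `p`).
#' @param cfg A [screen_config] with `n_pairs_tested` set.
#' @return Tibble keyed by pair with per-set p-values and logical flags.
#' @export
qualify_pairs <- function(discovery, validation, combined, individual,
                          cfg = screen_config()) {
  pcol <- function(df) {
    nm <- intersect(c("sipi_p", "p_int"), names(df))[1]
    if (is.na(nm)) stop("result set lacks a p_int/sipi_p column")
    dplyr::select(tibble::as_tibble(df), "snp1", "snp2", p = dplyr::all_of(nm))
  }
  d <- pcol(discovery); v <- pcol(validation); cb <- pcol(combined)
  out <- d |>
    dplyr::rename(p_discovery = "p") |>
    dplyr::inner_join(dplyr::rename(v, p_validation = "p"), by = c("snp1", "snp2")) |>
    dplyr::inner_join(dplyr::rename(cb, p_combined = "p"), by = c("snp1", "snp2"))
  if (nrow(out) != nrow(d) || nrow(out) != nrow(v) || nrow(out) != nrow(cb)) {
    stop("discovery, validation and combined results must cover the same pairs")
  }
  ind <- setNames(individual$p, individual$snp_id)
  p1 <- unname(ind[out$snp1])
  p2 <- unname(ind[out$snp2])
  if (anyNA(p1) || anyNA(p2)) {
    stop("individual results missing for SNP(s): ",
         paste(unique(c(out$snp1[is.na(p1)], out$snp2[is.na(p2)])), collapse = ", "))
  }
  out$validated <- !is.na(out$p_discovery) & !is.na(out$p_validation) &
    out$p_discovery < cfg$validation_p & out$p_validation < cfg$validation_p
  out$promising <- out$validated & !is.na(out$p_combined) &
    out$p_combined < cfg$promising_p
  out$bonferroni_significant <- !is.na(out$p_combined) &
    !is.na(cfg$bonferroni_interaction) &
    out$p_combined < cfg$bonferroni_interaction
  out$interaction_stronger <- !is.na(out$p_combined) &
    out$p_combined < p1 & out$p_combined < p2
  out$p_individual_snp1 <- p1
  out$p_individual_snp2 <- p2
  out
}

#' 3x3 genotype-combination prevalence table
#'
#' Outcome prevalence and subject count for each of the nine genotype
#' combinations of a SNP pair; the tabular analog of the heat tables used to
#' display interaction patterns.
#'
#' @param y Binary outcome vector.
#' @param g1,g2 Genotype vectors (minor-allele counts).
#' @return Tibble of class `prev3x3` with `g1`, `g2`, `n`, `prevalence`
#'   (prevalence is `NA` for empty cells). Plot with [autoplot()].
#' @export
prevalence_3x3 <- function(y, g1, g2) {
  cc <- !is.na(y) & !is.na(g1) & !is.na(g2)
  grid <- tidyr::expand_grid(g1 = 0:2, g2 = 0:2)
  obs <- tibble::tibble(y = y[cc], g1 = g1[cc], g2 = g2[cc]) |>
    dplyr::group_by(.data$g1, .data$g2) |>
    dplyr::summarise(n = dplyr::n(), prevalence = mean(.data$y), .groups = "drop")
  out <- grid |>
    dplyr::left_join(obs, by = c("g1", "g2")) |>
    dplyr::mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  class(out) <- c("prev3x3", class(out))
  out
}

#' Heat-table plot of a 3x3 prevalence table
#' @param object A `prev3x3` tibble from [prevalence_3x3()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prev3x3
#' @export
autoplot.prev3x3 <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$lab <- ifelse(df$n == 0, "-",
                   sprintf("%.0f%% (%d)", 100 * df$prevalence, df$n))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$g2), y = factor(.data$g1),
                                   fill = .data$prevalence)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$lab), size = 3.5) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 na.value = "grey90", name = "Prevalence") +
    ggplot2::labs(x = "SNP2 minor-allele count", y = "SNP1 minor-allele count") +
    ggplot2::theme_minimal()
}
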