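#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact two-sided test conditional on the observed allele counts: the
#' p-value is the summed probability of all heterozygote counts whose
#' conditional probability does not exceed that of the observed
#' configuration. Probabilities are computed by the standard recurrence over
#' heterozygote counts (numerically stable for the sample sizes used in
#' genotyping QC). Monomorphic SNPs return 1.
#'
#' @param n_hom_major,n_het,n_hom_minor Genotype counts.
#' @return Exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25)
#' hwe_exact_test(100, 0, 0)
#' @export
hwe_exact_test <- function(n_hom_major, n_het, n_hom_minor) {
  counts <- c(n_hom_major, n_het, n_hom_minor)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) stop("total genotype count must be positive")
  n_minor <- 2 * n_hom_minor + n_het
  n_major <- 2 * n_hom_major + n_het
  rare <- min(n_minor, n_major)
  if (rare == 0) return(1)

  # heterozygote counts share the parity of the rare-allele count
  het_vals <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(het_vals))
  # start from the largest heterozygote count, whose probability we set to 1
  # and normalize at the end
  m <- length(het_vals)
  probs[m] <- 1
  if (m > 1) {
    for (i in seq(m, 2)) {
      het <- het_vals[i]
      hom_r <- (rare - het) / 2
      hom_c <- n - het - hom_r
      # P(het - 2) / P(het) = het * (het - 1) / (4 * (hom_r + 1) * (hom_c + 1))
      probs[i - 1] <- probs[i] * het * (het - 1) / (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- which(het_vals == n_het)
  if (!length(obs)) {
    stop("observed heterozygote count inconsistent with allele counts")
  }
  p <- sum(probs[probs <= probs[obs] * (1 + 1e-10)])
  min(p, 1)
}

#' Quality-control thresholds for SNP filtering
#'
#' Defaults follow common genotyping-array practice: exclude SNPs with a call
#' rate below 95%, a call rate below 99% when MAF < 5%, MAF below 1%, or an
#' exact Hardy-Weinberg p-value below 1e-12. Interaction analyses further
#' restrict to MAF > 5% and LD-pruned panels (r^2 <= 0.8 within 100 kb).
#'
#' @param min_call_rate Minimum call rate (default 0.95).
#' @param min_call_rate_low_maf Minimum call rate for low-MAF SNPs (0.99).
#' @param low_maf_cut MAF below which the stricter call rate applies (0.05).
#' @param min_maf Minimum MAF (0.01).
#' @param hwe_p_floor Minimum exact HWE p-value (1e-12).
#' @param interaction_maf_floor MAF floor for interaction scans (0.05).
#' @param ld_r2_max Maximum tolerated pairwise r^2 when pruning (0.8).
#' @param ld_window_bp Window in base pairs for LD pruning (1e5).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, min_call_rate_low_maf = 0.99,
                          low_maf_cut = 0.05, min_maf = 0.01,
                          hwe_p_floor = 1e-12, interaction_maf_floor = 0.05,
                          ld_r2_max = 0.8, ld_window_bp = 1e5) {
  thr <- list(min_call_rate = min_call_rate,
              min_call_rate_low_maf = min_call_rate_low_maf,
              low_maf_cut = low_maf_cut, min_maf = min_maf,
              hwe_p_floor = hwe_p_floor,
              interaction_maf_floor = interaction_maf_floor,
              ld_r2_max = ld_r2_max, ld_window_bp = ld_window_bp)
  fr <- unlist(thr[c("min_call_rate", "min_call_rate_low_maf", "low_maf_cut",
                     "min_maf", "interaction_maf_floor")])
  if (any(fr <= 0 | fr > 1)) stop("threshold fractions must lie in (0, 1]")
  if (ld_window_bp <= 0) stop("ld_window_bp must be positive")
  structure(thr, class = "qc_thresholds")
}

#' SNP quality-control filter
#'
#' Applies the call-rate, MAF, and Hardy-Weinberg exclusion rules in order;
#' the recorded exclusion reason is the first rule a SNP fails
#' (`call_rate`, `call_rate_low_maf`, `maf`, `hwe`).
#'
#' @param g A [geno] object.
#' @param thresholds A [qc_thresholds] object.
#' @return Tibble with one row per SNP: `snp_id`, `call_rate`, `maf`,
#'   `hwe_p`, `keep` (logical) and `reason` (`NA` for retained SNPs).
#' @export
snp_qc <- function(g, thresholds = qc_thresholds()) {
  stopifnot(inherits(g, "geno"))
  thr <- thresholds
  v <- g$values
  cr <- colMeans(!is.na(v))
  freq <- colMeans(v, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  hwe <- vapply(seq_len(ncol(v)), function(j) {
    x <- v[, j]
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))

  reason <- rep(NA_character_, ncol(v))
  reason[is.na(reason) & cr < thr$min_call_rate] <- "call_rate"
  reason[is.na(reason) & cr < thr$min_call_rate_low_maf & maf < thr$low_maf_cut] <-
    "call_rate_low_maf"
  reason[is.na(reason) & maf < thr$min_maf] <- "maf"
  reason[is.na(reason) & (!is.na(hwe) & hwe < thr$hwe_p_floor)] <- "hwe"

  tibble::tibble(snp_id = g$snps$snp_id, call_rate = cr, maf = as.numeric(maf),
                 hwe_p = hwe, keep = is.na(reason), reason = reason)
}

#' Pairwise LD as squared genotype correlation
#'
#' r^2 is the squared Pearson correlation of minor-allele counts over
#' pairwise-complete subjects (composite, genotype-based LD; no phase
#' information is used).
#'
#' @param g1,g2 Genotype vectors (minor-allele counts).
#' @return Squared correlation in \[0, 1\].
#' @export
ld_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) stop("fewer than 2 pairwise-complete subjects")
  x <- g1[ok]; y <- g2[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    stop("LD undefined: monomorphic SNP in the pairwise-complete overlap")
  }
  cor(x, y)^2
}

#' LD pruning within a genomic window
#'
#' Greedy left-to-right sweep over SNPs sorted by (chromosome, position):
#' whenever two retained SNPs on the same chromosome within `window_bp` have
#' r^2 exceeding `r2_max`, the less informative member of the pair is
#' dropped - lower call rate first, then lower MAF, then larger position.
#' The retained panel contains no same-chromosome pair within the window
#' with r^2 > `r2_max`.
#'
#' @param g A [geno] object.
#' @param window_bp Window size in base pairs (default 1e5).
#' @param r2_max Maximum tolerated r^2 (default 0.8).
#' @return Tibble with `snp_id`, `keep`, and `dropped_for` (the retained SNP
#'   that triggered the drop, `NA` otherwise).
#' @export
ld_prune <- function(g, window_bp = 1e5, r2_max = 0.8) {
  stopifnot(inherits(g, "geno"))
  s <- g$snps
  ord <- order(s$chrom, s$pos)
  v <- g$values
  cr <- colMeans(!is.na(v))
  freq <- colMeans(v, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)

  keep <- rep(TRUE, nrow(s))
  dropped_for <- rep(NA_character_, nrow(s))
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (!keep[i]) next
    b <- a + 1L
    while (b <= length(ord)) {
      j <- ord[b]
      if (s$chrom[j] != s$chrom[i] || s$pos[j] - s$pos[i] > window_bp) break
      if (keep[j]) {
        r2 <- tryCatch(ld_r2(v[, i], v[, j]), error = function(e) NA_real_)
        if (!is.na(r2) && r2 > r2_max) {
          # drop the less informative SNP of the pair
          drop_i <- if (cr[i] != cr[j]) cr[i] < cr[j]
                    else if (maf[i] != maf[j]) maf[i] < maf[j]
                    else s$pos[i] > s$pos[j]
          if (drop_i) {
            keep[i] <- FALSE
            dropped_for[i] <- s$snp_id[j]
            break
          } else {
            keep[j] <- FALSE
            dropped_for[j] <- s$snp_id[i]
          }
        }
      }
      b <- b + 1L
    }
  }
  tibble::tibble(snp_id = s$snp_id, keep = keep, dropped_for = dropped_for)
}

#' Principal components of the genotype matrix
#'
#' Columns are mean-imputed and standardized before the singular value
#' decomposition; scores are ordered by decreasing variance explained and are
#' column-orthogonal. Used to adjust association models for population
#' stratification.
#'
#' @param g A [geno] object.
#' @param k Number of components (default 6).
#' @return Tibble with `subject_id` and `PC1..PCk`.
#' @export
compute_pcs <- function(g, k = 6) {
  stopifnot(inherits(g, "geno"))
  v <- g$values
  mu <- colMeans(v, na.rm = TRUE)
  for (j in seq_len(ncol(v))) {
    miss <- is.na(v[, j])
    if (any(miss)) v[miss, j] <- mu[j]
  }
  sds <- apply(v, 2, sd)
  poly <- sds > 0
  if (sum(poly) < k) stop("need at least k = ", k, " polymorphic SNPs")
  z <- scale(v[, poly, drop = FALSE])
  pc <- prcomp(z, center = FALSE, scale. = FALSE, rank. = k)
  if (ncol(pc$x) < k) stop("requested k = ", k, " exceeds the matrix rank")
  scores <- pc$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  dplyr::bind_cols(tibble::tibble(subject_id = g$subject_ids),
                   tibble::as_tibble(scores))
}
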