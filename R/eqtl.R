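#' Two-way eQTL scan over SNP pairs and expression traits
#'
#' For every (SNP pair, gene) combination, runs the additive-additive
#' 9-pattern search under a linear link on the gene's expression trait and
#' reports the best pattern by BIC with its interaction-term p-value.
#' Significance uses a Bonferroni threshold `alpha / n_tests`; because the
#' total number of tests in a campaign can exceed the combinations scanned in
#' one call, `n_tests` is an explicit input rather than being inferred.
#'
#' Constant expression traits are not evaluable and are skipped (flagged in
#' the returned table, with a message).
#'
#' @param expression Numeric genes x subjects matrix; rownames are gene
#'   identifiers, columns aligned with `g`'s subjects.
#' @param pairs Tibble with `snp1`, `snp2`.
#' @param g A [geno] object.
#' @param covariates Optional covariate data frame.
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests Total number of eQTL tests for the Bonferroni correction.
#' @param scope Pattern scope, `"aa9int"` by default (the full `"sipi"`
#'   scope is available).
#' @return Tibble: `snp1`, `snp2`, `gene`, `pattern`, `p_int`, `bic`,
#'   `significant`, `skipped`.
#' @export
eqtl_scan <- function(expression, pairs, g, covariates = NULL, alpha = 0.05,
                      n_tests, scope = "aa9int") {
  stopifnot(inherits(g, "geno"))
  expression <- as.matrix(expression)
  if (is.null(rownames(expression))) {
    rownames(expression) <- paste0("gene", seq_len(nrow(expression)))
  }
  if (ncol(expression) != length(g$subject_ids)) {
    stop("expression has ", ncol(expression), " subjects but genotypes have ",
         length(g$subject_ids))
  }
  if (missing(n_tests) || is.null(n_tests) || n_tests <= 0) {
    stop("n_tests (total number of eQTL tests) is required")
  }
  threshold <- alpha / n_tests
  patterns <- if (is.data.frame(scope)) scope else sipi_patterns(scope)

  skipped_genes <- character(0)
  rows <- purrr::map(rownames(expression), function(gene) {
    trait <- expression[gene, ]
    if (sd(trait, na.rm = TRUE) == 0 || all(is.na(trait))) {
      skipped_genes <<- c(skipped_genes, gene)
      return(tibble::tibble(snp1 = pairs$snp1, snp2 = pairs$snp2, gene = gene,
                            pattern = NA_character_, p_int = NA_real_,
                            bic = NA_real_, significant = NA, skipped = TRUE))
    }
    res <- interaction_scan(g, trait, pairs, covariates, scope = patterns,
                            link = "linear")
    tibble::tibble(snp1 = res$snp1, snp2 = res$snp2, gene = gene,
                   pattern = res$pattern, p_int = res$p_int, bic = res$bic,
                   significant = !is.na(res$p_int) & res$p_int < threshold,
                   skipped = FALSE)
  })
  if (length(skipped_genes)) {
    message("skipped constant expression trait(s): ",
            paste(skipped_genes, collapse = ", "))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "threshold") <- threshold
  out
}
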