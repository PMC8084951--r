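#' Genotype container
#'
#' Bundles a subjects x SNPs matrix of minor-allele counts with per-SNP
#' metadata. Entries must be 0, 1, 2 or `NA`. On construction every SNP is
#' oriented to minor-allele counting: if the empirical allele-1 frequency
#' exceeds 0.5 the counts are flipped (`2 - g`), the allele labels swapped,
#' and the MAF recomputed, so downstream encodings can assume the
#' minor-allele convention.
#'
#' @param values Integer/numeric matrix, subjects in rows, SNPs in columns.
#' @param snps Data frame of SNP metadata with at least `snp_id`; recognised
#'   columns are `chrom`, `pos` (1-based), `minor_allele`, `major_allele`,
#'   `maf`, `gene_label`, `pathway`. Missing columns are filled with defaults.
#' @param subject_ids Character vector of subject identifiers (defaults to
#'   rownames of `values` or `S1..Sn`).
#' @return An object of class `geno`: list with elements `values` (matrix),
#'   `snps` (tibble) and `subject_ids`.
#' @export
geno <- function(values, snps, subject_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  ok <- is.na(values) | values == 0 | values == 1 | values == 2
  if (!all(ok)) {
    stop("genotype matrix contains values outside {0, 1, 2, NA}")
  }
  snps <- tibble::as_tibble(snps)
  if (!"snp_id" %in% names(snps)) stop("`snps` must have a snp_id column")
  if (nrow(snps) != ncol(values)) {
    stop("snps metadata has ", nrow(snps), " rows but genotype matrix has ",
         ncol(values), " columns")
  }
  defaults <- list(chrom = "1", pos = seq_len(nrow(snps)),
                   minor_allele = "A", major_allele = "G",
                   maf = NA_real_, gene_label = NA_character_,
                   pathway = NA_character_)
  for (nm in names(defaults)) {
    if (!nm %in% names(snps)) snps[[nm]] <- defaults[[nm]]
  }
  if (any(!is.na(snps$pos) & snps$pos < 1)) stop("SNP positions must be >= 1")
  if (is.null(subject_ids)) {
    subject_ids <- rownames(values)
    if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(values)))
  }
  dimnames(values) <- list(subject_ids, snps$snp_id)

  # orient to minor-allele counts
  freq <- colMeans(values, na.rm = TRUE) / 2
  flip <- which(!is.na(freq) & freq > 0.5)
  if (length(flip)) {
    values[, flip] <- 2 - values[, flip]
    tmp <- snps$minor_allele[flip]
    snps$minor_allele[flip] <- snps$major_allele[flip]
    snps$major_allele[flip] <- tmp
    freq[flip] <- 1 - freq[flip]
  }
  snps$maf <- as.numeric(freq)

  structure(list(values = values, snps = snps, subject_ids = subject_ids),
            class = "geno")
}

#' @export
print.geno <- function(x, ...) {
  cat("<geno> ", nrow(x$values), " subjects x ", ncol(x$values), " SNPs\n", sep = "")
  cat("  MAF range: ", paste(signif(range(x$snps$maf, na.rm = TRUE), 3), collapse = " - "),
      "; missing entries: ", sum(is.na(x$values)), "\n", sep = "")
  print(head(x$snps, 5))
  invisible(x)
}

#' @export
dim.geno <- function(x) dim(x$values)

#' Extract one SNP's genotype vector
#' @param g A `geno` object.
#' @param snp_id SNP identifier.
#' @return Named numeric vector of minor-allele counts.
#' @export
geno_vector <- function(g, snp_id) {
  stopifnot(inherits(g, "geno"))
  j <- match(snp_id, g$snps$snp_id)
  if (is.na(j)) stop("unknown SNP id: ", snp_id)
  g$values[, j]
}

#' Subset a geno object by SNP ids and/or subjects
#' @param g A `geno` object.
#' @param snp_ids Character vector of SNP ids to keep (default all).
#' @param subjects Character vector or logical/integer index of subjects.
#' @return A `geno` object.
#' @export
geno_subset <- function(g, snp_ids = NULL, subjects = NULL) {
  stopifnot(inherits(g, "geno"))
  v <- g$values
  s <- g$snps
  if (!is.null(snp_ids)) {
    j <- match(snp_ids, s$snp_id)
    if (anyNA(j)) stop("unknown SNP id(s): ", paste(snp_ids[is.na(j)], collapse = ", "))
    v <- v[, j, drop = FALSE]
    s <- s[j, ]
  }
  if (!is.null(subjects)) {
    if (is.character(subjects)) subjects <- match(subjects, g$subject_ids)
    v <- v[subjects, , drop = FALSE]
  }
  geno(v, s, rownames(v))
}

#' Per-SNP empirical summary: call rate and minor allele frequency
#' @param g A `geno` object.
#' @return Tibble with `snp_id`, `call_rate`, `maf`.
#' @export
geno_summary <- function(g) {
  stopifnot(inherits(g, "geno"))
  v <- g$values
  tibble::tibble(
    snp_id = g$snps$snp_id,
    call_rate = colMeans(!is.na(v)),
    maf = pmin(colMeans(v, na.rm = TRUE) / 2, 1 - colMeans(v, na.rm = TRUE) / 2)
  )
}
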