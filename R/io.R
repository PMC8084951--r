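# Deterministic TSV writer: UTF-8, tab-separated, header row, "NA" for
# missing, >= 10 significant digits for numerics (re-reading reconstructs
# flag logic exactly).
write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      df[[nm]] <- ifelse(is.na(df[[nm]]), NA,
                         format(df[[nm]], digits = 15, trim = TRUE,
                                scientific = FALSE))
    }
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_plain <- function(path) {
  tibble::as_tibble(read.table(path, sep = "\t", header = TRUE,
                               na.strings = "NA", stringsAsFactors = FALSE,
                               check.names = FALSE))
}

#' Write / read genotypes in the plain TSV dialect
#'
#' The genotype table is subjects-as-rows: a `subject_id` column followed by
#' one column per SNP holding minor-allele counts (`NA` for missing). SNP
#' metadata travels in a sidecar TSV (`snp_id`, `chrom`, `pos`,
#' `minor_allele`, `major_allele`, `maf`, `gene_label`, `pathway`).
#' On reading, SNPs are re-oriented to minor-allele counts if the stored
#' counts track the major allele (MAF recomputed, alleles swapped).
#'
#' @param g A [geno] object.
#' @param genotype_path,snp_path Paths for the genotype matrix and the SNP
#'   metadata sidecar.
#' @return `write_geno_tsv()`: the genotype path, invisibly.
#'   `read_geno_tsv()`: a [geno] object.
#' @export
write_geno_tsv <- function(g, genotype_path, snp_path) {
  stopifnot(inherits(g, "geno"))
  df <- data.frame(subject_id = g$subject_ids, g$values, check.names = FALSE)
  write_tsv_plain(df, genotype_path)
  write_tsv_plain(g$snps, snp_path)
  invisible(genotype_path)
}

#' @rdname write_geno_tsv
#' @export
read_geno_tsv <- function(genotype_path, snp_path) {
  gt <- read_tsv_plain(genotype_path)
  if (!"subject_id" %in% names(gt)) {
    stop("genotype TSV lacks a subject_id column: ", genotype_path)
  }
  snps <- read_tsv_plain(snp_path)
  values <- as.matrix(gt[setdiff(names(gt), "subject_id")])
  if (!identical(colnames(values), as.character(snps$snp_id))) {
    # allow metadata to carry the same SNPs in a different order
    j <- match(colnames(values), snps$snp_id)
    if (anyNA(j)) {
      stop("SNP metadata does not match genotype columns in ", snp_path)
    }
    snps <- snps[j, ]
  }
  geno(values, snps, as.character(gt$subject_id))
}

#' Read a PLINK bed/bim/fam triplet
#'
#' Decodes the binary biallelic SNP-major .bed format to minor-allele counts
#' with missing values preserved. Allele-1 counts are re-checked against
#' empirical frequencies on load and re-oriented to minor-allele counting
#' where needed (allele labels swapped, MAF recomputed). Positions in the
#' .bim are 1-based.
#'
#' @param bed,bim,fam File paths.
#' @return A [geno] object.
#' @export
read_plink <- function(bed, bim, fam) {
  bim_df <- read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                       col.names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"))
  fam_df <- read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n_snps <- nrow(bim_df)
  n_subj <- nrow(fam_df)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK .bed file (bad magic number): ", bed)
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only SNP-major .bed files are supported: ", bed)
  }
  bytes_per_snp <- ceiling(n_subj / 4)
  expected <- 3 + bytes_per_snp * n_snps
  if (length(raw) != expected) {
    stop("dimension mismatch: ", bed, " has ", length(raw), " bytes but ",
         bim, " (", n_snps, " SNPs) and ", fam, " (", n_subj,
         " subjects) imply ", expected)
  }
  body <- as.integer(raw[-(1:3)])
  # unpack 2-bit genotype codes, subjects within byte from the low bits
  codes <- matrix(0L, nrow = 4 * bytes_per_snp, ncol = n_snps)
  shifted <- matrix(body, nrow = bytes_per_snp)
  for (k in 0:3) {
    codes[seq(k + 1, 4 * bytes_per_snp, by = 4), ] <- shifted %% 4L
    shifted <- shifted %/% 4L
  }
  codes <- codes[seq_len(n_subj), , drop = FALSE]
  # 00 -> 2 copies of allele 1; 10 -> 1; 11 -> 0; 01 -> missing
  counts <- matrix(NA_real_, n_subj, n_snps)
  counts[codes == 0L] <- 2
  counts[codes == 2L] <- 1
  counts[codes == 3L] <- 0
  snps <- tibble::tibble(snp_id = bim_df$snp_id, chrom = as.character(bim_df$chrom),
                         pos = bim_df$pos, minor_allele = bim_df$a1,
                         major_allele = bim_df$a2)
  geno(counts, snps, as.character(fam_df[[2]]))
}

#' Write a [geno] object as a PLINK bed/bim/fam triplet
#' @param g A [geno] object.
#' @param prefix Output path prefix (writes `prefix.bed/.bim/.fam`).
#' @return Invisibly, the three paths.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "geno"))
  v <- g$values
  n_subj <- nrow(v); n_snps <- ncol(v)
  bytes_per_snp <- ceiling(n_subj / 4)
  # map counts of allele 1 (minor): 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code <- matrix(1L, 4 * bytes_per_snp, n_snps)  # pad with "missing"
  code[seq_len(n_subj), ][!is.na(v) & v == 2] <- 0L
  code[seq_len(n_subj), ][!is.na(v) & v == 1] <- 2L
  code[seq_len(n_subj), ][!is.na(v) & v == 0] <- 3L
  bytes <- integer(bytes_per_snp * n_snps)
  for (k in 0:3) {
    bytes <- bytes + as.vector(code[seq(k + 1, 4 * bytes_per_snp, by = 4), ,
                                    drop = FALSE]) * 4L^k
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  close(con)
  s <- g$snps
  write.table(data.frame(s$chrom, s$snp_id, 0, s$pos, s$minor_allele,
                         s$major_allele),
              paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(g$subject_ids, g$subject_ids, 0, 0, 0, -9),
              paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

#' Read and align phenotype, covariate, and expression tables
#'
#' Each table must carry a `subject_id` column; tables are inner-joined on
#' it, and join losses are reported with counts. The covariate table must
#' contain `site` and `PC1..PC6`. The expression table, if given, is
#' subjects-as-rows with one column per gene and is returned as a genes x
#' subjects matrix.
#'
#' @param phenotype_path,covariate_path TSV paths.
#' @param expression_path Optional TSV path.
#' @return List: `data` (tibble with phenotype + covariates, aligned),
#'   `expression` (matrix or `NULL`), `n_dropped`.
#' @export
read_tables <- function(phenotype_path, covariate_path,
                        expression_path = NULL) {
  ph <- read_tsv_plain(phenotype_path)
  cv <- read_tsv_plain(covariate_path)
  for (nm in c("phenotype", "covariate")) {
    df <- if (nm == "phenotype") ph else cv
    if (!"subject_id" %in% names(df)) {
      stop(nm, " table lacks a subject_id column")
    }
  }
  missing_cols <- setdiff(c("site", paste0("PC", 1:6)), names(cv))
  if (length(missing_cols)) {
    stop("covariate table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  joined <- dplyr::inner_join(ph, cv, by = "subject_id")
  n_dropped <- (nrow(ph) - nrow(joined)) + (nrow(cv) - nrow(joined))
  if (!nrow(joined)) stop("no overlapping subjects between the tables")
  expr <- NULL
  if (!is.null(expression_path)) {
    ex <- read_tsv_plain(expression_path)
    if (!"subject_id" %in% names(ex)) {
      stop("expression table lacks a subject_id column")
    }
    keep <- intersect(joined$subject_id, ex$subject_id)
    n_dropped <- n_dropped + (nrow(joined) - length(keep)) +
      (nrow(ex) - length(keep))
    joined <- joined[joined$subject_id %in% keep, ]
    ex <- ex[match(joined$subject_id, ex$subject_id), ]
    expr <- t(as.matrix(ex[setdiff(names(ex), "subject_id")]))
    colnames(expr) <- joined$subject_id
  }
  if (n_dropped > 0) message("dropped ", n_dropped, " non-overlapping row(s)")
  list(data = joined, expression = expr, n_dropped = n_dropped)
}
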