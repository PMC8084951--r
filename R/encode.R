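#' Encode a genotype vector under an inheritance mode and coding direction
#'
#' Genotypes are minor-allele counts in \{0, 1, 2\}. Three inheritance modes
#' are supported: additive (`"A"`, the count itself), dominant (`"D"`,
#' indicator of carrying at least one minor allele) and recessive (`"R"`,
#' indicator of the minor homozygote). Each mode has an original (`"o"`)
#' coding based on the minor allele and a reverse (`"r"`) coding: `2 - g` for
#' additive, `1 - x` for the binary modes, i.e. the coding obtained by
#' swapping the roles of the minor and major alleles.
#'
#' Missing genotypes propagate to missing coded values; model fits downstream
#' use complete cases.
#'
#' @param g Integer/numeric vector of minor-allele counts (0, 1, 2 or `NA`).
#' @param mode One of `"A"`, `"D"`, `"R"`.
#' @param direction One of `"o"` (original) or `"r"` (reverse).
#' @return Numeric vector of coded genotypes, same length as `g`.
#' @examples
#' encode_genotype(c(0, 1, 2, NA), "A", "r")
#' encode_genotype(0:2, "R", "o")
#' @export
encode_genotype <- function(g, mode = c("A", "D", "R"), direction = c("o", "r")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  g <- as.numeric(g)
  bad <- !is.na(g) & !(g %in% c(0, 1, 2))
  if (any(bad)) {
    stop("invalid genotype value(s): ", paste(unique(g[bad]), collapse = ", "),
         "; expected minor-allele counts 0/1/2 or NA")
  }
  x <- switch(mode,
    A = g,
    D = as.numeric(g >= 1),
    R = as.numeric(g == 2)
  )
  if (direction == "r") {
    x <- if (mode == "A") 2 - x else 1 - x
  }
  x
}

#' Product interaction term of two coded genotype vectors
#'
#' The interaction term entering the pattern models is the elementwise
#' product of the two coded SNP vectors. For two additive codings its value
#' set is a subset of \{0, 1, 2, 4\}; for two binary-mode codings it is an
#' indicator in \{0, 1\}.
#'
#' @param x1,x2 Coded genotype vectors of equal length.
#' @return Numeric product vector.
#' @examples
#' interaction_term(c(0, 1, 2), c(2, 2, 2))
#' @export
interaction_term <- function(x1, x2) {
  if (length(x1) != length(x2)) {
    stop("x1 and x2 must have the same length (", length(x1), " vs ", length(x2), ")")
  }
  as.numeric(x1) * as.numeric(x2)
}
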