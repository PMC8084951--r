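#' Enumerate SNP-SNP interaction model patterns
#'
#' Candidate models for a SNP pair combine an inheritance-mode pair, a model
#' family, and coding directions for each SNP:
#'
#' * families: `Full` (SNP1 + SNP2 + SNP1 x SNP2), `M1_int`
#'   (SNP1 + SNP1 x SNP2), `M2_int` (SNP2 + SNP1 x SNP2), `Int`
#'   (SNP1 x SNP2 only);
#' * mode pairs: `AA` for the additive-additive scope (`"aa9int"`), plus
#'   `DD`, `DR`, `RD`, `RR` for the full scope (`"sipi"`);
#' * coding directions: original (`o`) or reverse (`r`) per SNP.
#'
#' The raw family x coding grid is collapsed by design-span equivalence on a
#' generic genotype grid (with an intercept, the `Full` family is invariant
#' to both coding directions, and `M1_int`/`M2_int` to the coding of the SNP
#' whose main effect is absent). The additive-additive scope yields 9
#' patterns; the full scope yields 9 per mode pair, 45 in total.
#'
#' Pattern labels follow the `"(mode1)(mode2)_family[_codes]"` grammar, e.g.
#' `AA_Full`, `DD_M1_int_r1`, `AA_int_ro`.
#'
#' @param scope `"sipi"` (45 patterns) or `"aa9int"` (9 patterns).
#' @return Tibble with columns `label`, `mode1`, `mode2`, `family`, `code1`,
#'   `code2`, in canonical order (`Int` before `M1_int`, `M2_int`, `Full`;
#'   lexicographic label within family).
#' @examples
#' nrow(sipi_patterns("aa9int"))
#' nrow(sipi_patterns("sipi"))
#' @export
sipi_patterns <- function(scope = c("sipi", "aa9int")) {
  scope <- match.arg(scope)
  mode_pairs <- if (scope == "aa9int") "AA" else c("AA", "DD", "DR", "RD", "RR")
  grid <- expand.grid(g1 = 0:2, g2 = 0:2)

  raw <- tidyr::expand_grid(
    mode_pair = mode_pairs,
    family = c("Int", "M1_int", "M2_int", "Full"),
    code1 = c("o", "r"),
    code2 = c("o", "r")
  )
  raw$mode1 <- substr(raw$mode_pair, 1, 1)
  raw$mode2 <- substr(raw$mode_pair, 2, 2)

  designs <- purrr::pmap(raw, function(mode_pair, family, code1, code2, mode1, mode2) {
    pattern_design(list(family = family, mode1 = mode1, mode2 = mode2,
                        code1 = code1, code2 = code2),
                   grid$g1, grid$g2)
  })

  # collapse by span equivalence (including an intercept column)
  same_span <- function(a, b) {
    a1 <- cbind(1, a); b1 <- cbind(1, b)
    ra <- qr(a1)$rank; rb <- qr(b1)$rank
    ra == rb && qr(cbind(a1, b1))$rank == ra
  }
  group <- integer(nrow(raw))
  reps <- list()
  for (i in seq_len(nrow(raw))) {
    hit <- 0L
    for (k in seq_along(reps)) {
      if (same_span(designs[[i]], designs[[reps[[k]]]])) { hit <- k; break }
    }
    if (hit == 0L) {
      reps[[length(reps) + 1L]] <- i
      group[i] <- length(reps)
    } else {
      group[i] <- hit
    }
  }

  fam_rank <- c(Int = 1, M1_int = 2, M2_int = 3, Full = 4)
  raw$group <- group
  canon <- raw |>
    dplyr::mutate(.rank = fam_rank[.data$family]) |>
    dplyr::arrange(.data$group, .data$.rank, .data$code1, .data$code2) |>
    dplyr::distinct(.data$group, .keep_all = TRUE)

  lab <- function(mode_pair, family, code1, code2) {
    switch(family,
      Full = paste0(mode_pair, "_Full"),
      M1_int = paste0(mode_pair, "_M1_int_", code1, "1"),
      M2_int = paste0(mode_pair, "_M2_int_", code2, "2"),
      Int = paste0(mode_pair, "_int_", code1, code2)
    )
  }
  out <- tibble::tibble(
    label = purrr::pmap_chr(canon[c("mode_pair", "family", "code1", "code2")],
                            function(mode_pair, family, code1, code2)
                              lab(mode_pair, family, code1, code2)),
    mode1 = canon$mode1, mode2 = canon$mode2, family = canon$family,
    # canonical representative fixes the free coding at "o"
    code1 = ifelse(canon$family %in% c("Full", "M2_int"), "o", canon$code1),
    code2 = ifelse(canon$family %in% c("Full", "M1_int"), "o", canon$code2)
  )
  out |>
    dplyr::mutate(.rank = fam_rank[.data$family]) |>
    dplyr::arrange(.data$mode1, .data$mode2, .data$.rank, .data$label) |>
    dplyr::select(-".rank")
}

#' Parse a pattern label into its components
#' @param label Pattern label such as `"AA_int_ro"` or `"DD_M2_int_r2"`.
#' @return One-row tibble with `label`, `mode1`, `mode2`, `family`, `code1`,
#'   `code2`.
#' @export
parse_pattern <- function(label) {
  m <- regmatches(label,
                  regexec("^([ADR])([ADR])_(Full|M1_int_([or])1|M2_int_([or])2|int_([or])([or]))$",
                          label))[[1]]
  if (!length(m)) stop("unparseable pattern label: ", label)
  mode1 <- m[2]; mode2 <- m[3]
  body <- m[4]
  if (body == "Full") {
    family <- "Full"; code1 <- "o"; code2 <- "o"
  } else if (startsWith(body, "M1_int")) {
    family <- "M1_int"; code1 <- m[5]; code2 <- "o"
  } else if (startsWith(body, "M2_int")) {
    family <- "M2_int"; code1 <- "o"; code2 <- m[6]
  } else {
    family <- "Int"; code1 <- m[7]; code2 <- m[8]
  }
  tibble::tibble(label = label, mode1 = mode1, mode2 = mode2,
                 family = family, code1 = code1, code2 = code2)
}

as_pattern <- function(pattern) {
  if (is.character(pattern)) return(parse_pattern(pattern))
  if (is.data.frame(pattern)) {
    stopifnot(nrow(pattern) == 1)
    return(pattern)
  }
  if (is.list(pattern)) return(pattern)
  stop("pattern must be a label, a one-row tibble, or a list")
}

#' Model design columns for a pattern on a genotype pair
#'
#' Encodes the two genotype vectors under the pattern's inheritance modes and
#' coding directions and assembles the family's terms: 3 columns for `Full`
#' (`snp1`, `snp2`, `snp1_x_snp2`), 2 for `M1_int`/`M2_int`, and 1 for `Int`.
#'
#' @param pattern Pattern label, one-row tibble from [sipi_patterns()], or a
#'   list with `family`, `mode1`, `mode2`, `code1`, `code2`.
#' @param g1,g2 Genotype vectors (minor-allele counts) of equal length.
#' @return Numeric matrix with named columns; attribute `degenerate` is set
#'   to `TRUE` when any column is constant over complete cases.
#' @export
pattern_design <- function(pattern, g1, g2) {
  p <- as_pattern(pattern)
  if (length(g1) != length(g2)) stop("g1 and g2 must have the same length")
  x1 <- encode_genotype(g1, p$mode1, p$code1)
  x2 <- encode_genotype(g2, p$mode2, p$code2)
  xx <- interaction_term(x1, x2)
  X <- switch(p$family,
    Full = cbind(snp1 = x1, snp2 = x2, snp1_x_snp2 = xx),
    M1_int = cbind(snp1 = x1, snp1_x_snp2 = xx),
    M2_int = cbind(snp2 = x2, snp1_x_snp2 = xx),
    Int = cbind(snp1_x_snp2 = xx),
    stop("unknown family: ", p$family)
  )
  cc <- complete.cases(X)
  degen <- !any(cc) ||
    any(apply(X[cc, , drop = FALSE], 2, function(col) length(unique(col)) < 2))
  attr(X, "degenerate") <- degen
  X
}

#' Count distinct predicted-risk groups induced by a pattern
#'
#' Over subjects spanning all nine genotype combinations (covariates held
#' fixed), a pattern's fitted linear predictor takes a limited number of
#' distinct values: with binary (dominant/recessive) modes these are 2, 3,
#' and 4 for the interaction-only, main + interaction, and full-interaction
#' families. Counted by enumerating the genotype grid under generic nonzero
#' coefficients.
#'
#' @param pattern Pattern label or one-row tibble.
#' @param coefficients Optional coefficient vector for the pattern terms;
#'   defaults to generic values (distinct logs of primes) that avoid
#'   accidental collisions.
#' @return Integer count of distinct linear-predictor values.
#' @examples
#' risk_group_count("DD_int_oo")  # 2
#' risk_group_count("RR_Full")    # 4
#' @export
risk_group_count <- function(pattern, coefficients = NULL) {
  grid <- expand.grid(g1 = 0:2, g2 = 0:2)
  D <- pattern_design(pattern, grid$g1, grid$g2)
  if (is.null(coefficients)) coefficients <- log(c(2, 3, 5))[seq_len(ncol(D))]
  if (length(coefficients) != ncol(D)) {
    stop("need ", ncol(D), " coefficient(s) for this pattern")
  }
  lp <- as.numeric(D %*% coefficients)
  length(unique(round(lp, 12)))
}
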