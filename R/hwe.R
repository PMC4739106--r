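#' Per-allele Hardy-Weinberg screen
#'
#' Scoring-quality screen for allele-specific departures from Hardy-Weinberg
#' proportions, as arise from allele dropout or null alleles. Each allele is
#' considered in turn, all other alleles at the locus are pooled, and the
#' inbreeding coefficient `F_IS = 1 - Ho/He` (with `He = 2p(1-p)`, the
#' classical definition) is computed on the recoded biallelic data. The
#' default test statistic is the classical one-degree-of-freedom chi-square
#' `X^2 = n F_IS^2`; `stat = "n_fis"` reproduces the literal form `X^2 =
#' n F_IS` instead (which can be negative; its upper chi-square tail is then
#' 1). P-values are upper tails of the chi-square distribution with df = 1.
#'
#' @param geno A genotype table.
#' @param panel Optional locus panel.
#' @param stat `"n_fis_sq"` (default, classical) or `"n_fis"` (literal).
#' @return A tibble with columns `sample`, `locus`, `allele`, `n`
#'   (non-missing individuals), `freq`, `f_is`, `chi2`, `df`, `p`. Alleles
#'   whose recoded locus is monomorphic (frequency 0 or 1) are skipped.
#' @export
hwe_allele_tests <- function(geno, panel = NULL, stat = c("n_fis_sq", "n_fis")) {
  stat <- match.arg(stat)
  geno <- as_geno_tbl(check_geno(geno))
  if (!is.null(panel)) geno <- subset_loci(geno, panel)
  obs <- geno[!is.na(geno$allele_1), ]
  if (nrow(obs) == 0) abort("No non-missing calls; nothing to screen.")

  one_locus <- function(d) {
    alleles <- sort(unique(c(d$allele_1, d$allele_2)))
    if (length(alleles) < 2) return(NULL)
    n <- nrow(d)
    res <- lapply(alleles, function(a) {
      copies <- (d$allele_1 == a) + (d$allele_2 == a)
      p <- sum(copies) / (2 * n)
      if (p <= 0 || p >= 1) return(NULL)
      ho <- mean(copies == 1L)
      he <- 2 * p * (1 - p)
      f <- 1 - ho / he
      chi2 <- if (stat == "n_fis_sq") n * f^2 else n * f
      tibble(
        allele = a, n = n, freq = p, f_is = f, chi2 = chi2, df = 1L,
        p = pchisq(chi2, df = 1, lower.tail = FALSE)
      )
    })
    dplyr::bind_rows(res)
  }

  obs |>
    dplyr::group_by(.data$sample, .data$locus) |>
    dplyr::group_modify(function(d, key) {
      out <- one_locus(d)
      if (is.null(out)) tibble() else out
    }) |>
    dplyr::ungroup()
}
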