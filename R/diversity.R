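#' Allele frequencies per sample and locus
#'
#' The substrate of every estimator in the package: allele counts and
#' frequencies from non-missing calls, with the gene count (2 x non-missing
#' individuals) carried alongside.
#'
#' @param geno A genotype table.
#' @return A tibble with columns `sample`, `locus`, `allele`, `count`,
#'   `freq`, `gene_count`. Sample x locus combinations with no data are
#'   absent from the result.
#' @export
allele_freqs <- function(geno) {
  geno <- as_geno_tbl(check_geno(geno))
  obs <- geno[!is.na(geno$allele_1), ]
  if (nrow(obs) == 0) abort("No non-missing genotype calls; allele frequencies undefined.")
  long <- tibble(
    sample = rep(obs$sample, 2),
    locus = rep(obs$locus, 2),
    allele = c(obs$allele_1, obs$allele_2)
  )
  long |>
    dplyr::count(.data$sample, .data$locus, .data$allele, name = "count") |>
    dplyr::group_by(.data$sample, .data$locus) |>
    dplyr::mutate(gene_count = sum(.data$count), freq = .data$count / .data$gene_count) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sample, .data$locus, .data$allele) |>
    dplyr::select("sample", "locus", "allele", "count", "freq", "gene_count")
}

#' Per-sample diversity statistics
#'
#' Observed heterozygosity `Ho` (proportion of heterozygotes among
#' non-missing calls), Nei's unbiased expected heterozygosity
#' `He = (2n/(2n-1)) (1 - sum p^2)` with `2n` the gene count at the locus,
#' and the allele count `Na`, each averaged over the panel loci that carry at
#' least one non-missing genotype in the sample.
#'
#' @param geno A genotype table.
#' @param panel Optional locus panel (character); defaults to all loci.
#' @return A tibble with columns `sample`, `n` (individuals), `n_loci`
#'   (loci entering the averages), `He`, `Ho`, `Na`.
#' @export
diversity_stats <- function(geno, panel = NULL) {
  geno <- as_geno_tbl(check_geno(geno))
  if (!is.null(panel)) geno <- subset_loci(geno, panel)
  n_tbl <- sample_sizes(geno)

  obs <- geno[!is.na(geno$allele_1), ]
  if (nrow(obs) == 0) abort("All loci empty in every sample; diversity undefined.")
  per_locus <- obs |>
    dplyr::group_by(.data$sample, .data$locus) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      Ho = mean(.data$allele_1 != .data$allele_2),
      He = {
        p <- tabulate(factor(c(.data$allele_1, .data$allele_2)))
        p <- p / sum(p)
        g <- 2 * dplyr::n()
        if (g > 1) (g / (g - 1)) * (1 - sum(p^2)) else 0
      },
      Na = length(unique(c(.data$allele_1, .data$allele_2))),
      .groups = "drop"
    )

  empty <- length(locus_levels(geno)) * nrow(n_tbl) - nrow(per_locus)
  if (empty > 0) {
    warn(sprintf("%d sample-locus combination(s) with no data excluded from diversity averages.", empty))
  }

  per_locus |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      n_loci = dplyr::n(),
      He = mean(.data$He), Ho = mean(.data$Ho), Na = mean(.data$Na),
      .groups = "drop"
    ) |>
    dplyr::left_join(n_tbl, by = "sample") |>
    dplyr::select("sample", "n", "n_loci", "He", "Ho", "Na")
}
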