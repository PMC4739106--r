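#' Build pooled reference populations
#'
#' Aggregates spawning-sample genotypes into reference pools holding per-locus
#' allele-count tables, the baseline for all assignment computations. Pooling
#' reference samples both reduces the number of candidate populations and
#' increases reference sample sizes.
#'
#' @param geno A genotype table of reference individuals.
#' @param pooling Optional named character vector mapping sample label to
#'   pool name (as in [pool_samples()]). With `NULL`, every sample becomes
#'   its own pool.
#' @return An object of class `ref_pools` with elements `pools` (names, in
#'   configuration order -- the order used for tie-breaking), `loci`,
#'   `counts` (`counts[[pool]][[locus]]` named count vector), `gene`
#'   (pool x locus gene-count matrix), `n` (individuals per pool), and
#'   `members` (the member genotype table, sample = pool). Missing calls
#'   contribute no genes.
#' @export
build_pools <- function(geno, pooling = NULL) {
  geno <- as_geno_tbl(check_geno(geno))
  if (!is.null(pooling)) geno <- pool_samples(geno, pooling)
  pools <- sample_levels(geno)
  loci <- locus_levels(geno)
  af <- allele_freqs(geno)
  counts <- lapply(pools, function(q) {
    sub <- af[af$sample == q, ]
    out <- lapply(loci, function(l) {
      d <- sub[as.character(sub$locus) == l, ]
      setNames(as.numeric(d$count), as.character(d$allele))
    })
    names(out) <- loci
    out
  })
  names(counts) <- pools
  gene <- matrix(0, length(pools), length(loci), dimnames = list(pools, loci))
  for (q in pools) for (l in loci) gene[q, l] <- sum(counts[[q]][[l]])
  nvec <- setNames(sample_sizes(geno)$n, sample_sizes(geno)$sample)[pools]
  structure(
    list(pools = pools, loci = loci, counts = counts, gene = gene,
         n = nvec, members = geno),
    class = "ref_pools"
  )
}

#' @export
print.ref_pools <- function(x, ...) {
  cat(sprintf("Reference pools (%d): %s\n", length(x$pools),
              paste(sprintf("%s (n=%d)", x$pools, x$n), collapse = ", ")))
  cat(sprintf("  %d loci: %s\n", length(x$loci), paste(x$loci, collapse = ", ")))
  invisible(x)
}

#' @method tidy ref_pools
#' @export
tidy.ref_pools <- function(x, ...) {
  purrr::imap(x$counts, function(by_locus, pool) {
    purrr::imap(by_locus, function(cnt, locus) {
      if (length(cnt) == 0) return(NULL)
      tibble(pool = pool, locus = locus,
             allele = as.integer(names(cnt)), count = as.numeric(cnt))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

# Distinct-allele count per locus over the union of all pools plus any scored
# individuals: the shared Dirichlet prior dimension, fixed once per run.
allele_union_k <- function(pools, extra_geno = NULL) {
  k <- setNames(integer(length(pools$loci)), pools$loci)
  for (l in pools$loci) {
    u <- unique(unlist(lapply(pools$counts, function(cl) names(cl[[l]]))))
    if (!is.null(extra_geno)) {
      sub <- extra_geno[as.character(extra_geno$locus) == l & !is.na(extra_geno$allele_1), ]
      u <- unique(c(u, as.character(sub$allele_1), as.character(sub$allele_2)))
    }
    k[l] <- length(u)
  }
  k
}
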