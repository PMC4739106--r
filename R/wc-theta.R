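# Weir-Cockerham (1984) variance components for one locus.
# uid/a1/a2: non-missing calls; grp: sample factor per uid (global).
# Returns c(a, abc) summed over alleles, or NULL if the locus is uninformative
# (fewer than two samples with data, or mean sample size <= 1).
wc_locus_components <- function(uid, a1, a2, grp) {
  g <- grp[uid]
  g <- droplevels(g)
  r <- nlevels(g)
  if (r < 2) return(NULL)
  ni <- tabulate(g, nbins = r)
  nbar <- mean(ni)
  if (nbar <= 1) return(NULL)
  N <- sum(ni)
  nc <- (N - sum(ni^2) / N) / (r - 1)

  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  af <- factor(c(a1, a2), levels = alleles)
  cnt <- matrix(tabulate(
    (rep(as.integer(g), 2) - 1L) * k + as.integer(af), nbins = r * k
  ), nrow = r, byrow = TRUE)                       # counts[sample, allele]
  p <- cnt / (2 * ni)

  het <- a1 != a2
  hcnt <- matrix(0, r, k)
  if (any(het)) {
    gi <- as.integer(g)[het]
    i1 <- (gi - 1L) * k + match(a1[het], alleles)
    i2 <- (gi - 1L) * k + match(a2[het], alleles)
    hcnt <- matrix(tabulate(c(i1, i2), nbins = r * k), nrow = r, byrow = TRUE)
  }
  h <- hcnt / ni

  pbar <- colSums(ni * p) / N
  s2 <- colSums(ni * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(ni * h) / N

  inner <- pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4
  a <- (nbar / nc) * (s2 - inner / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = sum(a), abc = sum(a + b + cc))
}

# Multilocus theta from a geno_split and a grouping factor (used directly by
# the permutation test so individuals can be re-labelled cheaply).
theta_from_split <- function(split, grp, per_locus = FALSE) {
  comp <- lapply(split$loci, function(l) {
    if (length(l$uid) == 0) return(NULL)
    wc_locus_components(l$uid, l$a1, l$a2, grp)
  })
  A <- vapply(comp, function(x) if (is.null(x)) NA_real_ else x[["a"]], numeric(1))
  ABC <- vapply(comp, function(x) if (is.null(x)) NA_real_ else x[["abc"]], numeric(1))
  ok <- !is.na(ABC)
  if (!any(ok) || sum(ABC[ok]) == 0) {
    abort("theta undefined: no polymorphic locus with data in two or more samples.")
  }
  theta <- sum(A[ok]) / sum(ABC[ok])
  if (!per_locus) return(theta)
  list(theta = theta, a = A, abc = ABC)
}

#' Weir-Cockerham F_ST estimator (theta)
#'
#' Moment estimator of F_ST from the among-population (`a`), among-individual
#' (`b`) and within-individual (`c`) variance components of Weir & Cockerham
#' (1984), summed over alleles. The multilocus estimate is the ratio of sums
#' `sum(a) / sum(a+b+c)` over loci and alleles, never the mean of per-locus
#' ratios; negative estimates are reported as such. Unequal sample sizes and
#' missing data are handled through per-locus gene counts; loci with data in
#' fewer than two samples are dropped.
#'
#' @param geno A genotype table.
#' @param samples Optional subset of sample labels (default: all).
#' @param panel Optional locus panel.
#' @return An object of class `wc_fst` with components `theta` (multilocus),
#'   `per_locus` (tibble: locus, a, abc, theta), `labels`, `n`. Methods:
#'   [tidy()] (per-locus), [glance()] (one row).
#' @examples
#' geno <- sim_reference_panel(sim_config(fst = 0.05, sample_sizes = c(60, 60), seed = 1))$geno
#' wc_theta(geno)
#' @export
wc_theta <- function(geno, samples = NULL, panel = NULL) {
  geno <- as_geno_tbl(check_geno(geno))
  if (!is.null(samples)) {
    unknown <- setdiff(samples, sample_levels(geno))
    if (length(unknown) > 0) {
      abort(sprintf("Unknown sample(s): %s.", paste(unknown, collapse = ", ")))
    }
    geno <- as_geno_tbl(geno[as.character(geno$sample) %in% samples, ],
                        loci = locus_levels(geno), samples = samples)
  }
  if (!is.null(panel)) geno <- subset_loci(geno, panel)
  if (length(sample_levels(geno)) < 2) abort("theta needs at least two samples.")
  split <- geno_split(geno)
  res <- theta_from_split(split, split$grp, per_locus = TRUE)
  per_locus <- tibble(
    locus = locus_levels(geno), a = res$a, abc = res$abc,
    theta = ifelse(res$abc == 0, NA_real_, res$a / res$abc)
  )
  structure(
    list(theta = res$theta, per_locus = per_locus,
         labels = sample_levels(geno), n = nrow(split$ind), p = NULL, reps = NULL),
    class = "wc_fst"
  )
}

#' @export
print.wc_fst <- function(x, ...) {
  cat(sprintf("Weir-Cockerham theta over %d samples (%d individuals, %d loci)\n",
              length(x$labels), x$n, nrow(x$per_locus)))
  cat(sprintf("  multilocus theta = %.6f\n", x$theta))
  if (!is.null(x$p)) cat(sprintf("  permutation P = %.4g (%d reps)\n", x$p, x$reps))
  invisible(x)
}

#' @method tidy wc_fst
#' @export
tidy.wc_fst <- function(x, ...) x$per_locus

#' @method glance wc_fst
#' @export
glance.wc_fst <- function(x, ...) {
  tibble(theta = x$theta, n_samples = length(x$labels), n_individuals = x$n,
         n_loci = sum(!is.na(x$per_locus$theta)),
         p = if (is.null(x$p)) NA_real_ else x$p,
         reps = if (is.null(x$reps)) NA_integer_ else x$reps)
}

#' Permutation test of genetic differentiation
#'
#' Significance of multilocus theta by permuting whole multilocus individuals
#' among samples (sample sizes preserved), with the +1-corrected Monte-Carlo
#' p-value `p = (1 + #{theta* >= theta_obs}) / (reps + 1)`.
#'
#' @inheritParams wc_theta
#' @param reps Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return A `wc_fst` object with `p` and `reps` filled in.
#' @export
fst_permutation_test <- function(geno, samples = NULL, panel = NULL, reps = 999, seed = 1) {
  if (reps < 99) abort("`reps` must be at least 99.")
  fit <- wc_theta(geno, samples = samples, panel = panel)
  geno2 <- as_geno_tbl(check_geno(geno))
  if (!is.null(samples)) {
    geno2 <- as_geno_tbl(geno2[as.character(geno2$sample) %in% samples, ],
                         loci = locus_levels(geno2), samples = samples)
  }
  if (!is.null(panel)) geno2 <- subset_loci(geno2, panel)
  split <- geno_split(geno2)
  obs <- fit$theta
  grp <- split$grp
  hits <- 0L
  with_seed(seed, {
    for (i in seq_len(reps)) {
      perm <- grp[sample.int(length(grp))]
      th <- tryCatch(theta_from_split(split, perm), error = function(e) NA_real_)
      if (!is.na(th) && th >= obs) hits <- hits + 1L
    }
  })
  fit$p <- (1 + hits) / (reps + 1)
  fit$reps <- as.integer(reps)
  fit
}

#' Pairwise multilocus theta matrix
#'
#' @inheritParams wc_theta
#' @return An object of class `pairwise_fst`: a tibble with columns
#'   `sample_1`, `sample_2`, `theta` (one row per unordered pair; `NA` where
#'   the pair estimate is undefined, recorded with a warning rather than
#'   failing globally). `as.matrix()` yields the symmetric, zero-diagonal
#'   matrix.
#' @export
pairwise_fst <- function(geno, panel = NULL) {
  geno <- as_geno_tbl(check_geno(geno))
  if (!is.null(panel)) geno <- subset_loci(geno, panel)
  labs <- sample_levels(geno)
  if (length(labs) < 2) abort("Need at least two samples for a pairwise matrix.")
  pairs <- utils::combn(labs, 2)
  theta <- apply(pairs, 2, function(pr) {
    tryCatch(wc_theta(geno, samples = pr)$theta, error = function(e) {
      warn(sprintf("Pair %s - %s: %s", pr[1], pr[2], conditionMessage(e)))
      NA_real_
    })
  })
  out <- tibble(sample_1 = pairs[1, ], sample_2 = pairs[2, ], theta = theta)
  structure(out, labels = labs, class = c("pairwise_fst", class(out)))
}

#' @export
as.matrix.pairwise_fst <- function(x, ...) {
  labs <- attr(x, "labels")
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  i <- match(x$sample_1, labs)
  j <- match(x$sample_2, labs)
  m[cbind(i, j)] <- x$theta
  m[cbind(j, i)] <- x$theta
  m
}

#' Year-class stability of regional differentiation
#'
#' Within each region, individuals are regrouped by cohort (year class) and
#' every cohort pair is tested for differentiation with [wc_theta()] plus the
#' individual-permutation test. Cohorts below `min_n` individuals are
#' excluded with a warning; regions with fewer than two usable cohorts
#' contribute no rows.
#'
#' @param geno A genotype table carrying a `cohort` column.
#' @param region_map Named character vector mapping sample label to region.
#' @param panel Optional locus panel.
#' @param reps Permutations per pair.
#' @param min_n Minimum cohort size (default 10).
#' @param seed Integer seed.
#' @return A tibble: `region`, `cohort_1`, `cohort_2`, `n_1`, `n_2`,
#'   `theta`, `p`.
#' @export
temporal_stability <- function(geno, region_map, panel = NULL, reps = 999,
                               min_n = 10, seed = 1) {
  geno <- as_geno_tbl(check_geno(geno))
  if (!"cohort" %in% names(geno)) abort("`geno` must carry a `cohort` column for year-class tests.")
  if (!is.null(panel)) geno <- subset_loci(geno, panel)
  out <- list()
  for (region in unique(unname(region_map))) {
    members <- names(region_map)[region_map == region]
    sub <- geno[as.character(geno$sample) %in% members & !is.na(geno$cohort), ]
    if (nrow(sub) == 0) next
    sub$sample <- paste0(region, ":", sub$cohort)
    sizes <- sample_sizes(as_geno_tbl(sub, loci = locus_levels(geno),
                                      samples = unique(sub$sample)))
    small <- sizes$sample[sizes$n < min_n]
    if (length(small) > 0) {
      warn(sprintf("Region %s: cohort(s) below n=%d excluded: %s.",
                   region, min_n, paste(sub("^.*:", "", small), collapse = ", ")))
    }
    keep <- setdiff(sizes$sample, small)
    if (length(keep) < 2) next
    sub <- as_geno_tbl(sub[sub$sample %in% keep, ], loci = locus_levels(geno), samples = keep)
    prs <- utils::combn(keep, 2)
    for (pcol in seq_len(ncol(prs))) {
      pr <- prs[, pcol]
      fit <- fst_permutation_test(sub, samples = pr, reps = reps,
                                  seed = derive_seed(seed, paste(region, pr[1], pr[2])))
      out[[length(out) + 1]] <- tibble(
        region = region,
        cohort_1 = sub("^.*:", "", pr[1]), cohort_2 = sub("^.*:", "", pr[2]),
        n_1 = sizes$n[sizes$sample == pr[1]], n_2 = sizes$n[sizes$sample == pr[2]],
        theta = fit$theta, p = fit$p
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(region = character(), cohort_1 = character(), cohort_2 = character(),
                  n_1 = integer(), n_2 = integer(), theta = double(), p = double()))
  }
  dplyr::bind_rows(out)
}
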