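# Vectorised log-likelihood of query genotypes under one pool.
#
# query: genotype table rows (long form); k: named vector of prior dimensions
# per locus; loo_ids: individual ids whose own two genes must be removed from
# the pool counts before scoring (leave-one-out).
#
# Bayesian criterion: Dirichlet(1/k per allele) posterior predictive. With
# per-locus allele count n_i and gene count G (alpha = G + 1):
#   P(homozygote ii)   = (n_i + 1/k)(n_i + 1 + 1/k) / (alpha (alpha + 1))
#   P(heterozygote ij) = 2 (n_i + 1/k)(n_j + 1/k)  / (alpha (alpha + 1))
# Frequency criterion: observed frequencies, unobserved alleles replaced by
# the pseudo-frequency 1/(2N+1).
pool_loglik_one <- function(query, pools, pool, k, method, loo_ids = character(0)) {
  obs <- query[!is.na(query$allele_1), ]
  ids <- unique(query$individual_id)
  ll <- setNames(rep(0, length(ids)), ids)
  n_loci_used <- setNames(integer(length(ids)), ids)
  for (l in pools$loci) {
    d <- obs[as.character(obs$locus) == l, ]
    if (nrow(d) == 0) next
    cnt <- pools$counts[[pool]][[l]]
    G <- pools$gene[pool, l]
    if (G == 0) next  # all-missing locus in the pool: skipped for everyone
    n1 <- cnt[as.character(d$allele_1)]
    n2 <- cnt[as.character(d$allele_2)]
    n1[is.na(n1)] <- 0
    n2[is.na(n2)] <- 0
    hom <- d$allele_1 == d$allele_2
    adj <- d$individual_id %in% loo_ids
    n1 <- n1 - ifelse(adj, ifelse(hom, 2, 1), 0)
    n2 <- n2 - ifelse(adj, ifelse(hom, 2, 1), 0)
    Gi <- G - 2 * adj
    if (any(n1 < 0 | n2 < 0 | Gi < 0)) {
      abort("Leave-one-out removed more genes than the pool holds; is the individual a pool member?")
    }
    contrib <- if (method == "bayesian") {
      ik <- 1 / k[l]
      al <- Gi + 1
      ifelse(hom,
             log(n1 + ik) + log(n1 + 1 + ik) - log(al) - log(al + 1),
             log(2) + log(n1 + ik) + log(n2 + ik) - log(al) - log(al + 1))
    } else {
      pseudo <- 1 / (2 * pools$n[pool] + 1)
      f1 <- ifelse(n1 > 0, n1 / Gi, pseudo)
      f2 <- ifelse(n2 > 0, n2 / Gi, pseudo)
      ifelse(hom, 2 * log(f1), log(2) + log(f1) + log(f2))
    }
    ll[d$individual_id] <- ll[d$individual_id] + contrib
    n_loci_used[d$individual_id] <- n_loci_used[d$individual_id] + 1L
  }
  list(loglik = ll, n_loci = n_loci_used)
}

#' Genotype log-likelihood under reference pools
#'
#' Scores multilocus genotypes against each reference pool under the
#' Rannala-Mountain-style Dirichlet posterior-predictive criterion (default)
#' or a plain frequency criterion. Missing loci are skipped; the Dirichlet
#' pseudo-count `1/k` (with `k` the distinct-allele count at the locus over
#' all pools plus the scored individuals) guarantees every genotype a finite
#' log-likelihood.
#'
#' @param geno A genotype table of the individuals to score.
#' @param pools A `ref_pools` object.
#' @param method `"bayesian"` (default) or `"frequency"`.
#' @param loo Leave-one-out: remove each scored individual's own two genes
#'   from its origin pool before scoring it there. Requires `origin`.
#' @param origin Named character vector individual_id -> pool, for `loo`.
#' @return A tibble with one row per individual x pool: `individual_id`,
#'   `pool`, `loglik`, `n_loci` (loci actually scored; 0 means no shared
#'   locus and `loglik` is `NA`).
#' @export
genotype_loglik <- function(geno, pools, method = c("bayesian", "frequency"),
                            loo = FALSE, origin = NULL) {
  method <- match.arg(method)
  if (!inherits(pools, "ref_pools")) abort("`pools` must be a ref_pools object.")
  geno <- as_geno_tbl(check_geno(geno))
  if (loo && is.null(origin)) abort("`loo = TRUE` requires `origin`.")
  k <- allele_union_k(pools, extra_geno = geno)
  out <- lapply(pools$pools, function(q) {
    loo_ids <- if (loo) names(origin)[origin == q] else character(0)
    sc <- pool_loglik_one(geno, pools, q, k, method, loo_ids = loo_ids)
    tibble(individual_id = names(sc$loglik), pool = q,
           loglik = unname(ifelse(sc$n_loci == 0, NA_real_, sc$loglik)),
           n_loci = unname(sc$n_loci))
  })
  dplyr::bind_rows(out)
}

# argmax with ties broken toward `prefer` (first match in pool order),
# recording the tie.
assign_from_scores <- function(scores, pool_order, prefer = NULL) {
  scores |>
    dplyr::mutate(pool = factor(.data$pool, levels = pool_order)) |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::group_modify(function(d, key) {
      if (all(is.na(d$loglik))) {
        return(tibble(assigned = NA_character_, tie = NA, max_loglik = NA_real_,
                      error = "no shared locus with any pool"))
      }
      mx <- max(d$loglik, na.rm = TRUE)
      top <- as.character(d$pool[!is.na(d$loglik) & d$loglik >= mx - 1e-12])
      tie <- length(top) > 1
      pick <- top[1]
      pref <- prefer[[key$individual_id[1]]]
      if (tie && !is.null(pref) && pref %in% top) pick <- pref
      tibble(assigned = pick, tie = tie, max_loglik = mx, error = NA_character_)
    }) |>
    dplyr::ungroup()
}

#' Assign individuals to reference pools
#'
#' Each individual is assigned to the pool under which its multilocus
#' genotype has maximal log-likelihood. Ties are broken toward the pool
#' listed first in the pool configuration and flagged in the `tie` column;
#' individuals sharing no locus with the pools yield an error record rather
#' than a failure.
#'
#' @inheritParams genotype_loglik
#' @return A tibble with one row per individual: `individual_id`,
#'   `assigned`, `tie`, `max_loglik`, `error`, plus one log-likelihood
#'   column per pool (named by pool).
#' @export
assign_individuals <- function(geno, pools, method = c("bayesian", "frequency")) {
  method <- match.arg(method)
  scores <- genotype_loglik(geno, pools, method = method)
  rec <- assign_from_scores(scores, pools$pools)
  wide <- tidyr::pivot_wider(scores[, c("individual_id", "pool", "loglik")],
                             names_from = "pool", values_from = "loglik")
  n_tie <- sum(rec$tie, na.rm = TRUE)
  if (n_tie > 0) inform(sprintf("%d assignment tie(s) broken toward the first-listed pool.", n_tie))
  dplyr::left_join(rec, wide, by = "individual_id")
}

#' Leave-one-out self-assignment of reference individuals
#'
#' Every pool member is scored against its own pool with its two genes per
#' locus removed (leaving the assigned individual out of the sample) and
#' against all other pools intact, then assigned by maximal log-likelihood.
#' Ties are broken toward the individual's own pool and flagged.
#'
#' @param pools A `ref_pools` object.
#' @param method `"bayesian"` (default) or `"frequency"`.
#' @return A list with `records` (per-individual tibble including `origin`)
#'   and `summary` (per origin pool: counts and proportions assigned to each
#'   pool, from [summarise_assignment()]).
#' @export
self_assignment <- function(pools, method = c("bayesian", "frequency")) {
  method <- match.arg(method)
  members <- pools$members
  ind <- dplyr::distinct(members, .data$sample, .data$individual_id)
  if (anyDuplicated(ind$individual_id)) {
    abort("Self-assignment requires globally unique individual ids across pools.")
  }
  origin <- setNames(as.character(ind$sample), ind$individual_id)
  scores <- genotype_loglik(members, pools, method = method, loo = TRUE, origin = origin)
  rec <- assign_from_scores(scores, pools$pools, prefer = as.list(origin))
  rec$origin <- unname(origin[rec$individual_id])
  n_tie <- sum(rec$tie, na.rm = TRUE)
  if (n_tie > 0) inform(sprintf("%d self-assignment tie(s) broken toward the own pool.", n_tie))
  list(records = rec, summary = summarise_assignment(rec, group = "origin", pools = pools$pools))
}

#' Summarise assignment counts and proportions by group
#'
#' @param records A tibble with an `assigned` column (error records dropped).
#' @param group Name of the grouping column in `records` (e.g. `"origin"` or
#'   a behavioural-group column).
#' @param pools Optional pool name vector fixing the column universe.
#' @return A tibble: `group`, `n` (group size), one count column per pool
#'   (`n_<pool>`) and one proportion column per pool (`prop_<pool>`);
#'   proportions sum to 1 within each group.
#' @export
summarise_assignment <- function(records, group, pools = NULL) {
  d <- records[!is.na(records$assigned), ]
  pools <- pools %||% sort(unique(d$assigned))
  d$assigned <- factor(d$assigned, levels = pools)
  long <- d |>
    dplyr::count(.data[[group]], .data$assigned, .drop = FALSE, name = "count") |>
    dplyr::rename(group = dplyr::all_of(group)) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(n = sum(.data$count), prop = .data$count / .data$n) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n > 0)
  wide_n <- tidyr::pivot_wider(long[, c("group", "n", "assigned", "count")],
                               names_from = "assigned", values_from = "count",
                               names_prefix = "n_")
  wide_p <- tidyr::pivot_wider(long[, c("group", "assigned", "prop")],
                               names_from = "assigned", values_from = "prop",
                               names_prefix = "prop_")
  dplyr::left_join(wide_n, wide_p, by = "group")
}

#' @describeIn summarise_assignment Stacked-bar plot of assignment
#'   proportions per group.
#' @param object A summary tibble from [summarise_assignment()].
#' @param ... Unused.
#' @export
plot_assignment <- function(object, ...) {
  long <- tidyr::pivot_longer(object, dplyr::starts_with("prop_"),
                              names_to = "pool", values_to = "prop",
                              names_prefix = "prop_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$prop, fill = .data$pool)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Proportion assigned", fill = "Reference pool") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
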