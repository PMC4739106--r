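#' Monte-Carlo exclusion test of population membership
#'
#' Evaluates whether individuals could plausibly originate from each
#' reference pool: the individual's log-likelihood under a pool is ranked
#' within the log-likelihoods of `n_sim` multilocus genotypes simulated from
#' that pool (two alleles per locus drawn independently, i.e. under HWE,
#' from the pool's posterior allele frequencies including the Dirichlet
#' `1/k` prior mass, for consistency with the scoring model). The rank
#' p-value uses the +1 correction, so it is never exactly zero:
#' `p = (1 + #\{simulated loglik <= observed\}) / (n_sim + 1)`.
#'
#' Simulated genotypes are scored on exactly the loci the focal individual
#' carries, so missing data do not bias the rank. Per-individual random
#' streams are derived by stable hashing of the id, making results
#' independent of processing order.
#'
#' @inheritParams genotype_loglik
#' @param n_sim Simulated genotypes per pool (>= 100; the study design uses
#'   1000).
#' @param seed Integer root seed.
#' @param threshold Minimum max-over-pools probability below which an
#'   individual is flagged as covered by neither reference (default 0.01;
#'   the flag gates a warning only, no record is dropped).
#' @return A tibble with one row per individual x pool: `individual_id`,
#'   `pool`, `loglik`, `exclusion_p`; attribute `threshold`.
#' @seealso [exclusion_summary()]
#' @export
exclusion_test <- function(geno, pools, n_sim = 1000, seed = 1,
                           method = c("bayesian", "frequency"), threshold = 0.01) {
  method <- match.arg(method)
  if (n_sim < 100) abort("`n_sim` must be at least 100.")
  if (!inherits(pools, "ref_pools")) abort("`pools` must be a ref_pools object.")
  geno <- as_geno_tbl(check_geno(geno))
  obs_scores <- genotype_loglik(geno, pools, method = method)
  # union allele sets per locus (prior dimension shared across pools)
  union_alleles <- lapply(pools$loci, function(l) {
    u <- unique(unlist(lapply(pools$counts, function(cl) names(cl[[l]]))))
    sub <- geno[as.character(geno$locus) == l & !is.na(geno$allele_1), ]
    sort(as.integer(unique(c(u, sub$allele_1, sub$allele_2))))
  })
  names(union_alleles) <- pools$loci

  fish_loci <- geno[!is.na(geno$allele_1), ] |>
    dplyr::distinct(.data$individual_id, .data$locus)

  out <- list()
  for (q in pools$pools) {
    for (id in unique(geno$individual_id)) {
      # fixed locus order so results do not depend on input row order
      present <- as.character(fish_loci$locus[fish_loci$individual_id == id])
      loci_f <- pools$loci[pools$loci %in% present]
      loci_f <- loci_f[pools$gene[q, loci_f] > 0]
      obs <- obs_scores$loglik[obs_scores$individual_id == id & obs_scores$pool == q]
      if (length(loci_f) == 0 || is.na(obs)) {
        out[[length(out) + 1]] <- tibble(individual_id = id, pool = q,
                                         loglik = NA_real_, exclusion_p = NA_real_)
        next
      }
      sim_ll <- with_seed(derive_seed(seed, paste0(id, "::", q)), {
        ll <- numeric(n_sim)
        for (l in loci_f) {
          u <- union_alleles[[l]]
          k_l <- length(u)
          cnt <- pools$counts[[q]][[l]][as.character(u)]
          cnt[is.na(cnt)] <- 0
          G <- pools$gene[q, l]
          pr <- (cnt + 1 / k_l) / (G + 1)
          i1 <- sample.int(k_l, n_sim, replace = TRUE, prob = pr)
          i2 <- sample.int(k_l, n_sim, replace = TRUE, prob = pr)
          n1 <- cnt[i1]
          n2 <- cnt[i2]
          hom <- i1 == i2
          ll <- ll + if (method == "bayesian") {
            ik <- 1 / k_l
            al <- G + 1
            ifelse(hom,
                   log(n1 + ik) + log(n1 + 1 + ik),
                   log(2) + log(n1 + ik) + log(n2 + ik)) - log(al) - log(al + 1)
          } else {
            pseudo <- 1 / (2 * pools$n[q] + 1)
            f1 <- ifelse(n1 > 0, n1 / G, pseudo)
            f2 <- ifelse(n2 > 0, n2 / G, pseudo)
            ifelse(hom, 2 * log(f1), log(2) + log(f1) + log(f2))
          }
        }
        ll
      })
      out[[length(out) + 1]] <- tibble(
        individual_id = id, pool = q, loglik = obs,
        exclusion_p = (1 + sum(sim_ll <= obs)) / (n_sim + 1)
      )
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "threshold") <- threshold
  covered <- exclusion_summary(res, threshold = threshold)
  if (any(!covered$covered)) {
    warn(sprintf("%d individual(s) below the exclusion threshold %.3g in every pool: %s.",
                 sum(!covered$covered), threshold,
                 paste(covered$individual_id[!covered$covered], collapse = ", ")))
  }
  res
}

#' Per-individual exclusion summary
#'
#' @param exclusion A tibble from [exclusion_test()].
#' @param threshold Coverage threshold (default: the attribute stored by
#'   [exclusion_test()], falling back to 0.01).
#' @return A tibble per individual: `individual_id`, `max_p` (max over
#'   pools), `covered`.
#' @export
exclusion_summary <- function(exclusion, threshold = NULL) {
  threshold <- threshold %||% attr(exclusion, "threshold") %||% 0.01
  exclusion |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(max_p = max(.data$exclusion_p, na.rm = TRUE), .groups = "drop") |>
    dplyr::mutate(covered = .data$max_p >= threshold)
}

#' Reference-subsampling robustness of assignment
#'
#' Guards against bias towards a larger reference pool: every pool larger
#' than `n_target` is subsampled to `n_target` individuals without
#' replacement, the allele-count tables are rebuilt, all individuals are
#' re-assigned, and mean assignment proportions per group over `reps`
#' repetitions are reported. With `n_target` equal to every pool size the
#' result equals the original assignment. Bit-reproducible for a fixed seed.
#'
#' @inheritParams genotype_loglik
#' @param groups Named character vector individual_id -> group label
#'   (e.g. behavioural group); with `NULL` all individuals form one group.
#' @param n_target Subsample size (default: smallest pool size). Must not
#'   exceed any pool's size being subsampled from.
#' @param reps Number of subsampling repetitions (default 10).
#' @param seed Integer seed.
#' @return A tibble per group: `group`, `n`, mean proportion columns
#'   `prop_<pool>` averaged over repetitions; attribute `reps`.
#' @export
subsample_assignment <- function(geno, pools, groups = NULL, n_target = NULL,
                                 reps = 10, seed = 1,
                                 method = c("bayesian", "frequency")) {
  method <- match.arg(method)
  if (!inherits(pools, "ref_pools")) abort("`pools` must be a ref_pools object.")
  n_target <- n_target %||% min(pools$n)
  if (n_target > max(pools$n)) abort("`n_target` exceeds the largest pool size.")
  members <- pools$members
  ind <- dplyr::distinct(members, .data$sample, .data$individual_id)
  per_rep <- vector("list", reps)
  for (r in seq_len(reps)) {
    keep_ids <- with_seed(derive_seed(seed, paste0("subsample-", r)), {
      unlist(lapply(pools$pools, function(q) {
        ids <- ind$individual_id[ind$sample == q]
        if (length(ids) > n_target) sample(ids, n_target) else ids
      }))
    })
    sub_members <- members[members$individual_id %in% keep_ids, ]
    sub_pools <- build_pools(as_geno_tbl(sub_members, loci = pools$loci,
                                         samples = pools$pools))
    rec <- assign_individuals(geno, sub_pools, method = method)
    rec$group <- if (is.null(groups)) "all" else unname(groups[rec$individual_id])
    per_rep[[r]] <- summarise_assignment(rec, group = "group", pools = pools$pools)
  }
  out <- dplyr::bind_rows(per_rep) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("n_"), mean),
                     n = mean(.data$n),
                     dplyr::across(dplyr::starts_with("prop_"), mean),
                     .groups = "drop")
  attr(out, "reps") <- reps
  out
}
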