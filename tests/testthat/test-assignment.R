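# Two single-locus pools: pool P holds 2 AA individuals (allele counts A=4),
# pool Q holds 2 BB individuals, so the union allele set has k = 2.
two_tiny_pools <- function() {
  build_pools(make_geno(list(
    P = list(L1 = rbind(c(1, 1), c(1, 1))),
    Q = list(L1 = rbind(c(2, 2), c(2, 2)))
  )))
}

test_that("the Dirichlet posterior-predictive likelihood matches the closed form", {
  pools <- two_tiny_pools()
  gAA <- make_geno(list(tagged = list(L1 = rbind(c(1, 1)))))
  ll <- genotype_loglik(gAA, pools)
  # pool P: counts A=4, gene count 4, k=2 -> P(AA) = (4.5 * 5.5) / (5 * 6)
  expect_equal(ll$loglik[ll$pool == "P"], log(0.825), tolerance = 1e-12)
  # pool Q: A absent (count 0): (0.5 * 1.5) / (5 * 6) -- finite, positive
  expect_equal(ll$loglik[ll$pool == "Q"], log(0.5 * 1.5 / 30), tolerance = 1e-12)
  # heterozygote: 2 (n_A + 1/k)(n_B + 1/k) / (alpha (alpha + 1))
  gAB <- make_geno(list(tagged = list(L1 = rbind(c(1, 2)))))
  llh <- genotype_loglik(gAB, pools)
  expect_equal(llh$loglik[llh$pool == "P"], log(2 * 4.5 * 0.5 / 30), tolerance = 1e-12)
})

test_that("likelihoods are finite and symmetric across identical pools", {
  pools <- build_pools(make_geno(list(
    P = list(L1 = rbind(c(1, 2), c(1, 1)), L2 = rbind(c(3, 4), c(4, 4))),
    Q = list(L1 = rbind(c(1, 2), c(1, 1)), L2 = rbind(c(3, 4), c(4, 4)))
  )))
  g <- make_geno(list(tagged = list(L1 = rbind(c(2, 2)), L2 = rbind(c(5, 5)))))
  ll <- genotype_loglik(g, pools)
  expect_true(all(is.finite(ll$loglik)))
  expect_equal(ll$loglik[ll$pool == "P"], ll$loglik[ll$pool == "Q"])
})

test_that("leave-one-out strictly lowers the own-pool log-likelihood", {
  cfg <- sim_config(n_loci = 6, sample_sizes = c(30, 30), fst = 0.05, seed = 17,
                    missing_rate = 0)
  pools <- sim_reference_panel(cfg)$pools
  members <- pools$members
  ind <- dplyr::distinct(members, sample, individual_id)
  origin <- setNames(as.character(ind$sample), ind$individual_id)
  plain <- genotype_loglik(members, pools)
  loo <- genotype_loglik(members, pools, loo = TRUE, origin = origin)
  own <- dplyr::inner_join(
    dplyr::filter(plain, pool == origin[individual_id]),
    dplyr::filter(loo, pool == origin[individual_id]),
    by = c("individual_id", "pool")
  )
  expect_true(all(own$loglik.y < own$loglik.x))
})

test_that("self-assignment accuracy grows with divergence", {
  acc <- vapply(c(0.004, 0.02, 0.1), function(F) {
    accs <- vapply(1:5, function(s) {
      cfg <- sim_config(fst = F, n_loci = 12, sample_sizes = c(100, 100),
                        missing_rate = 0, seed = 500 + s + round(F * 1e4))
      sa <- self_assignment(sim_reference_panel(cfg)$pools)
      rec <- sa$records
      mean(rec$assigned == rec$origin)
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
  expect_gt(acc[3], 0.9)          # F = 0.1, 12 loci, n = 100: strong recovery
  expect_gt(acc[2], 0.75)
})

test_that("near-identical pools split self-assignment about evenly", {
  # two samples drawn from the same population: no information to separate
  cfg <- sim_config(n_loci = 12, sample_sizes = c(100, 100), fst = 0.05, seed = 23)
  freqs <- sim_allele_freqs(cfg)
  g1 <- sim_genotypes(freqs[freqs$pop == "Kattegat", ], 80, seed = 1, label = "P")
  g2 <- sim_genotypes(freqs[freqs$pop == "Kattegat", ], 80, seed = 2, label = "Q")
  pools <- build_pools(as_geno_tbl_test(dplyr::bind_rows(g1, g2),
                                        unique(as.character(g1$locus)), c("P", "Q")))
  sa <- self_assignment(pools)
  props <- sa$summary$prop_P
  expect_true(all(props > 0.25 & props < 0.75))
})

test_that("tagged fish assign to their origin pool and error records are collected", {
  cfg <- sim_config(fst = 0.02, sample_sizes = c(200, 200), n_tagged = 200,
                    missing_rate = 0, seed = 29)
  study <- sim_study(cfg)
  rec <- assign_individuals(study$fish_geno, study$pools)
  truth <- setNames(study$truth$origin, study$truth$fish_id)
  expect_gt(mean(rec$assigned == truth[rec$individual_id]), 0.5)

  # all-missing fish -> error record, not a failure
  ghost <- study$fish_geno[study$fish_geno$individual_id == "fish_001", ]
  ghost$individual_id <- "ghost"
  ghost$allele_1 <- NA_integer_
  ghost$allele_2 <- NA_integer_
  rec2 <- assign_individuals(ghost, study$pools)
  expect_true(is.na(rec2$assigned))
  expect_match(rec2$error, "no shared locus")
})

test_that("pooling pools equals pooling the union", {
  cfg <- sim_config(n_loci = 4, sample_sizes = c(20, 20), fst = 0.02, seed = 31)
  ref <- sim_reference_panel(cfg)
  extra <- sim_genotypes(ref$freqs[ref$freqs$pop == "Kattegat", ], 15,
                         seed = 3, label = "KA2")
  geno <- as_geno_tbl_test(dplyr::bind_rows(ref$geno, extra),
                           levels(ref$geno$locus),
                           c("Kattegat", "NorthSea_WSkagerrak", "KA2"))
  merged <- build_pools(geno, c(Kattegat = "K", KA2 = "K",
                                NorthSea_WSkagerrak = "NS"))
  direct <- build_pools(pool_samples(geno, c(Kattegat = "K", KA2 = "K",
                                             NorthSea_WSkagerrak = "NS")))
  expect_equal(merged$counts, direct$counts)
  expect_equal(merged$n, direct$n)
  # single-sample pool: counts equal the sample's allele counts
  single <- build_pools(ref$geno)
  af <- allele_freqs(ref$geno)
  ka <- af[af$sample == "Kattegat" & af$locus == "loc01", ]
  expect_equal(unname(single$counts$Kattegat$loc01[as.character(ka$allele)]),
               as.numeric(ka$count))
})

test_that("subsampling at the full pool size reproduces the original assignment", {
  cfg <- sim_config(fst = 0.05, sample_sizes = c(60, 40), n_tagged = 30,
                    missing_rate = 0, seed = 37)
  study <- sim_study(cfg)
  base <- assign_individuals(study$fish_geno, study$pools)
  sub <- subsample_assignment(study$fish_geno, study$pools,
                              n_target = max(study$pools$n), reps = 2, seed = 1)
  base_prop <- mean(base$assigned == "Kattegat")
  expect_equal(sub$prop_Kattegat, base_prop, tolerance = 1e-12)
  # fixed seed -> bit-identical summaries
  s1 <- subsample_assignment(study$fish_geno, study$pools, n_target = 40,
                             reps = 3, seed = 11)
  s2 <- subsample_assignment(study$fish_geno, study$pools, n_target = 40,
                             reps = 3, seed = 11)
  expect_identical(s1, s2)
  expect_error(subsample_assignment(study$fish_geno, study$pools, n_target = 1000),
               "exceeds")
})
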