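# Independent transcription of the Weir-Cockerham (1984) variance components
# for a single biallelic locus, kept deliberately naive (scalar arithmetic,
# explicit loops) as the oracle for the vectorised implementation.
oracle_theta_biallelic <- function(geno) {
  samples <- levels(geno$sample)
  ni <- p <- h <- numeric(length(samples))
  for (i in seq_along(samples)) {
    d <- geno[geno$sample == samples[i] & !is.na(geno$allele_1), ]
    ni[i] <- nrow(d)
    p[i] <- sum(c(d$allele_1, d$allele_2) == 1) / (2 * nrow(d))
    h[i] <- mean(d$allele_1 != d$allele_2)
  }
  r <- length(ni)
  nbar <- mean(ni); N <- sum(ni)
  nc <- (N - sum(ni^2) / N) / (r - 1)
  abc <- function(p, h) {
    pbar <- sum(ni * p) / N
    s2 <- sum(ni * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * h) / N
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    c(a, b, hbar / 2)
  }
  v1 <- abc(p, h); v2 <- abc(1 - p, h)
  (v1[1] + v2[1]) / (sum(v1) + sum(v2))
}

test_that("theta on the toy table equals the variance-component oracle", {
  geno <- toy_theta_geno()
  fit <- wc_theta(geno)
  expect_equal(fit$theta, 11 / 56, tolerance = 1e-12)          # frozen pre-build value
  expect_equal(fit$theta, oracle_theta_biallelic(geno), tolerance = 1e-12)
  # per-locus components are exposed and consistent
  td <- tidy(fit)
  expect_equal(sum(td$a) / sum(td$abc), fit$theta, tolerance = 1e-14)
  expect_equal(glance(fit)$theta, fit$theta)
})

test_that("theta agrees with the oracle on random small tables", {
  set.seed(21)
  for (rep in 1:20) {
    genos <- lapply(1:3, function(i) {
      n <- sample(3:6, 1)
      g <- matrix(sample(1:2, 2 * n, replace = TRUE), ncol = 2)
      list(L1 = g)
    })
    names(genos) <- paste0("S", 1:3)
    geno <- make_geno(genos)
    th <- tryCatch(wc_theta(geno)$theta, error = function(e) NA)
    or <- tryCatch(oracle_theta_biallelic(geno), error = function(e) NA)
    if (is.na(th) || is.na(or) || !is.finite(or)) next
    expect_equal(th, or, tolerance = 1e-12)
  }
})

test_that("fixation gives theta = 1 and identical samples give theta near 0", {
  fix <- make_geno(list(
    A = list(L1 = matrix(rep(c(1, 1), 5), ncol = 2, byrow = TRUE)),
    B = list(L1 = matrix(rep(c(2, 2), 5), ncol = 2, byrow = TRUE))
  ))
  expect_equal(wc_theta(fix)$theta, 1)
  # one population split in two labels
  cfg <- sim_config(n_loci = 8, sample_sizes = c(120, 120), fst = 0.05, seed = 2)
  ref <- sim_reference_panel(cfg)
  one_pop <- sim_genotypes(ref$freqs[ref$freqs$pop == "Kattegat", ], n = 120,
                           seed = 77, label = "X")
  half <- one_pop
  half$sample <- as.character(half$sample)
  half$sample[half$individual_id %in% sprintf("X_%04d", 1:60)] <- "X1"
  half$sample[half$sample == "X"] <- "X2"
  expect_lt(abs(wc_theta(half)$theta), 0.02)
})

test_that("theta handles missing data and all-monomorphic input", {
  geno <- toy_theta_geno()
  geno$allele_1[1] <- NA; geno$allele_2[1] <- NA
  expect_true(is.finite(wc_theta(geno)$theta))
  mono <- make_geno(list(
    A = list(L1 = matrix(rep(c(1, 1), 4), ncol = 2, byrow = TRUE)),
    B = list(L1 = matrix(rep(c(1, 1), 4), ncol = 2, byrow = TRUE))
  ))
  expect_error(wc_theta(mono), "undefined")
})

test_that("permutation p is small under fixation and valid under the null", {
  fix <- make_geno(list(
    A = list(L1 = matrix(rep(c(1, 1), 5), ncol = 2, byrow = TRUE)),
    B = list(L1 = matrix(rep(c(2, 2), 5), ncol = 2, byrow = TRUE))
  ))
  fit <- fst_permutation_test(fix, reps = 999, seed = 4)
  expect_lt(fit$p, 0.05)

  # null: one simulated population split in two; +1-corrected p is valid
  cfg <- sim_config(n_loci = 4, alleles_per_locus = 5, sample_sizes = c(40, 40),
                    fst = 0.05, seed = 10)
  freqs <- sim_allele_freqs(cfg)
  pvals <- vapply(1:200, function(i) {
    g <- sim_genotypes(freqs[freqs$pop == "Kattegat", ], n = 40, seed = 1000 + i,
                       label = "Z")
    g$sample <- as.character(g$sample)
    g$sample[g$individual_id %in% sprintf("Z_%04d", 1:20)] <- "Z1"
    g$sample[g$sample == "Z"] <- "Z2"
    fst_permutation_test(g, reps = 99, seed = i)$p
  }, numeric(1))
  for (alpha in c(0.05, 0.1)) {
    se <- sqrt(alpha * (1 - alpha) / 200)
    expect_lte(mean(pvals <= alpha), alpha + 2 * se)
  }
})

test_that("a strongly diverged simulated pair is detected", {
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(n_loci = 8, sample_sizes = c(50, 50), fst = 0.05,
                      missing_rate = 0, seed = 300 + s)
    fst_permutation_test(sim_reference_panel(cfg)$geno, reps = 199, seed = s)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("pairwise matrices are symmetric, zero-diagonal, with NA for failed pairs", {
  cfg <- sim_config(n_loci = 4, sample_sizes = c(25, 25), fst = 0.01, seed = 5)
  ref <- sim_reference_panel(cfg)
  third <- sim_genotypes(ref$freqs[ref$freqs$pop == "Kattegat", ], n = 25,
                         seed = 6, label = "C")
  geno <- as_geno_tbl_test(dplyr::bind_rows(ref$geno, third),
                           levels(ref$geno$locus), c(levels(ref$geno$sample), "C"))
  pw <- pairwise_fst(geno)
  m <- as.matrix(pw)
  expect_equal(m, t(m))
  expect_equal(diag(m), setNames(rep(0, 3), rownames(m)))
  expect_true(all(abs(m) < 0.05))

  # a fully monomorphic pair yields an NA cell and a warning, not a failure
  mono <- make_geno(list(
    A = list(L1 = matrix(rep(c(1, 1), 4), ncol = 2, byrow = TRUE)),
    B = list(L1 = matrix(rep(c(1, 1), 4), ncol = 2, byrow = TRUE)),
    C = list(L1 = rbind(c(1, 2), c(1, 1), c(2, 2), c(1, 2)))
  ))
  expect_warning(pwm <- pairwise_fst(mono), "Pair A - B")
  expect_true(is.na(pwm$theta[pwm$sample_1 == "A" & pwm$sample_2 == "B"]))
})

test_that("year-class screening flags mixed-origin cohorts and guards small ones", {
  cfg <- sim_config(n_loci = 10, sample_sizes = c(60, 60), fst = 0.1,
                    missing_rate = 0, seed = 12)
  ref <- sim_reference_panel(cfg)
  geno <- ref$geno
  # cohorts within the true populations: no heterogeneity expected
  set.seed(31)
  geno$cohort <- sample(c("2000", "2001"), nrow(geno), replace = TRUE)
  geno <- dplyr::group_by(geno, individual_id) |>
    dplyr::mutate(cohort = cohort[1]) |> dplyr::ungroup()
  region_map <- c(Kattegat = "KattegatRegion", NorthSea_WSkagerrak = "NSRegion")
  ts <- temporal_stability(geno, region_map, reps = 99, seed = 9)
  expect_equal(nrow(ts), 2)
  expect_true(all(ts$p > 0.001))

  # two true populations mislabelled as cohorts of one region: strong signal
  mixed <- geno
  mixed$cohort <- ifelse(mixed$sample == "Kattegat", "2000", "2001")
  mixed$sample <- factor("onepop")
  ts2 <- temporal_stability(mixed, c(onepop = "R"), reps = 199, seed = 9)
  expect_lt(ts2$p, 0.05)

  # tiny cohort excluded with a warning
  tiny <- geno
  tiny$cohort[tiny$individual_id %in% unique(tiny$individual_id)[1:3]] <- "1999"
  expect_warning(temporal_stability(tiny, region_map, reps = 99, seed = 9),
                 "below n=10")
})
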