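test_that("Genepop parsing decodes 3-digit calls, missing codes and pop labels", {
  gp <- read_genepop(write_toy_genepop())
  expect_equal(levels(gp$locus), c("Gmo2", "Tch5"))
  expect_equal(sample_sizes(gp)$n, c(3L, 3L))
  # pops named after the last individual id of each block
  expect_equal(levels(gp$sample), c("KA_3", "SK_3"))
  first <- gp[gp$individual_id == "KA_1" & gp$locus == "Gmo2", ]
  expect_equal(c(first$allele_1, first$allele_2), c(102L, 104L))
  miss <- gp[gp$individual_id == "KA_2" & gp$locus == "Tch5", ]
  expect_true(is.na(miss$allele_1) && is.na(miss$allele_2))
})

test_that("Genepop write/read round-trip preserves allele codes bit-exactly", {
  for (digits in c(2, 3)) {
    cfg <- sim_config(n_loci = 4, alleles_per_locus = 6, fst = 0.05,
                      sample_sizes = c(15, 10), missing_rate = 0.1, seed = 3)
    geno <- sim_reference_panel(cfg)$geno
    if (digits == 2) {
      # 2-digit dialect needs codes < 100; simulated codes are 1..6 already
      expect_true(max(geno$allele_1, na.rm = TRUE) < 100)
    }
    path <- tempfile(fileext = ".gen")
    write_genepop(geno, path, digits = digits)
    back <- read_genepop(path)
    expect_equal(levels(back$locus), levels(geno$locus))
    # identical individuals with identical calls (row order is locus-major in
    # the simulator, individual-major in the file: align by key)
    a <- sort_geno(back)
    b <- sort_geno(geno)
    expect_equal(a$individual_id, b$individual_id)
    expect_equal(a$allele_1, b$allele_1)
    expect_equal(a$allele_2, b$allele_2)
    expect_equal(as.integer(a$sample), as.integer(b$sample))
  }
})

test_that("Genepop format errors are reported with context", {
  bad <- tempfile()
  writeLines(c("t", "L1", "pop", "a , 10210"), bad)    # odd-width call
  expect_error(read_genepop(bad), "width|characters")
  writeLines(c("t", "L1", "L2", "pop", "a , 102102"), bad)  # locus count mismatch
  expect_error(read_genepop(bad), "loci declared")
  geno <- read_genepop(write_toy_genepop())
  expect_error(write_genepop(geno, tempfile(), digits = 2), "fit in 2 digits")
  expect_error(write_genepop(geno[0, ], tempfile()), "empty")
})

test_that("subset_loci restricts the panel, keeps n, and is idempotent", {
  cfg <- sim_config(n_loci = 12, sample_sizes = c(20, 20), fst = 0.05, seed = 1)
  geno <- sim_reference_panel(cfg)$geno
  panel <- locus_levels <- levels(geno$locus)[1:8]
  sub <- subset_loci(geno, panel)
  expect_equal(levels(sub$locus), panel)
  expect_equal(sample_sizes(sub)$n, sample_sizes(geno)$n)
  expect_identical(subset_loci(sub, panel), sub)
  expect_identical(levels(subset_loci(geno, levels(geno$locus))$locus), levels(geno$locus))
  expect_error(subset_loci(geno, character(0)), "at least one")
  expect_error(subset_loci(geno, "nope"), "Unknown locus")
})

test_that("pool_samples reproduces the published pooled reference sizes", {
  sizes <- c(SK00 = 31, SK01 = 70, NS02 = 100,
             KA00 = 77, OR00 = 99, KA01 = 58, KA04a = 41, KA04b = 60, KA04c = 100)
  genos <- lapply(sizes, function(n) list(L1 = matrix(rep(c(1, 2), n), ncol = 2, byrow = TRUE)))
  geno <- make_geno(genos)
  pooling <- c(SK00 = "NS/WSk", SK01 = "NS/WSk", NS02 = "NS/WSk",
               KA00 = "Kattegat", OR00 = "Kattegat", KA01 = "Kattegat",
               KA04a = "Kattegat", KA04b = "Kattegat", KA04c = "Kattegat")
  pooled <- pool_samples(geno, pooling)
  n <- sample_sizes(pooled)
  expect_equal(n$n[n$sample == "NS/WSk"], 201L)
  expect_equal(n$n[n$sample == "Kattegat"], 435L)
  expect_equal(sum(n$n), 636L)
  # individuals conserved; identity pooling changes labels only
  ident <- pool_samples(geno, setNames(names(sizes), names(sizes)))
  expect_equal(sample_sizes(ident)$n, unname(sizes))
  expect_error(pool_samples(geno, c(QQ = "x")), "unknown sample")
})

test_that("track tables round-trip with date-sorted daily rows", {
  fish <- make_fish(track_lons = 11 + cumsum(rnorm(60, 0, 0.05)))
  # shuffle daily rows on disk
  path <- tempfile(fileext = ".csv")
  write_track_table(fish, path)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  daily <- raw[is.na(raw$release_date), ]
  raw <- rbind(raw[!is.na(raw$release_date), ], daily[sample(nrow(daily)), ])
  readr::write_csv(raw, path)
  back <- read_track_table(path)
  expect_equal(nrow(back$track[[1]]), 60)
  expect_equal(back$track[[1]]$longitude, fish$track[[1]]$longitude)
  expect_false(is.unsorted(back$track[[1]]$date))

  # fish with no daily rows -> zero-length track
  lone <- make_fish(fish_id = "f9", track_lons = numeric(0))
  write_track_table(lone, path)
  expect_equal(nrow(read_track_table(path)$track[[1]]), 0)

  # chronology and orphan errors
  bad <- make_fish()
  bad$recapture_date <- bad$release_date - 1
  write_track_table(bad, path)
  expect_error(read_track_table(path), "before release")
  orphan <- make_fish(track_lons = c(11, 11.1))
  orphan$track[[1]]$longitude <- c(11, 11.1)
  write_track_table(orphan, path)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  raw$fish_id[is.na(raw$release_date)] <- "ghost"
  readr::write_csv(raw, path)
  expect_error(read_track_table(path), "unknown fish_id")
})

test_that("half-missing calls are rejected at the boundary", {
  geno <- geno_from_counts(2, 2, 2)
  geno$allele_2[1] <- NA
  expect_error(diversity_stats(geno), "half-missing")
})
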