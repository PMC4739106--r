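# Fixtures built in code: genotype tables, Genepop files, tagged fish.

# Long genotype table from a per-sample list of genotype matrices.
# genos: named list sample -> list of loci -> two-column matrix of allele
# codes (rows = individuals; NA rows = missing calls).
make_geno <- function(genos, loci = NULL) {
  samples <- names(genos)
  loci <- loci %||% names(genos[[1]])
  rows <- list()
  for (s in samples) {
    n <- nrow(genos[[s]][[1]])
    for (l in loci) {
      m <- genos[[s]][[l]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample = s, individual_id = sprintf("%s_%02d", s, seq_len(n)),
        locus = l, allele_1 = as.integer(m[, 1]), allele_2 = as.integer(m[, 2])
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$sample <- factor(out$sample, levels = samples)
  out$locus <- factor(out$locus, levels = loci)
  out
}

# Single-locus biallelic sample from genotype counts (alleles 1 and 2).
geno_from_counts <- function(n11, n12, n22, sample = "S", locus = "L1") {
  make_geno(setNames(list(setNames(list(rbind(
    matrix(rep(c(1, 1), n11), ncol = 2, byrow = TRUE),
    matrix(rep(c(1, 2), n12), ncol = 2, byrow = TRUE),
    matrix(rep(c(2, 2), n22), ncol = 2, byrow = TRUE)
  )), locus)), sample))
}

# The toy from the variance-component oracle: A = {AA,AA,AB,AB,BB},
# B = {AB,BB,BB,BB,AB} at one locus (A=1, B=2).
toy_theta_geno <- function() {
  make_geno(list(
    A = list(L1 = rbind(c(1, 1), c(1, 1), c(1, 2), c(1, 2), c(2, 2))),
    B = list(L1 = rbind(c(1, 2), c(2, 2), c(2, 2), c(2, 2), c(1, 2)))
  ))
}

# Two-sample, two-locus Genepop file with 3-digit codes.
write_toy_genepop <- function(path = tempfile(fileext = ".gen")) {
  writeLines(c(
    "toy dataset", "Gmo2", "Tch5",
    "pop",
    "KA_1 , 102104 101101",
    "KA_2 , 102102 000000",
    "KA_3 , 104104 101103",
    "pop",
    "SK_1 , 102102 103103",
    "SK_2 , 104102 101103",
    "SK_3 , 104104 103101"
  ), path)
  path
}

# The published contingency layout: rows = assignment, cols = direction.
paper_table <- function() {
  matrix(c(3L, 0L, 12L, 20L), nrow = 2,
         dimnames = list(assigned = c("Kattegat", "NorthSea_WSkagerrak"),
                         direction = c("towardsKattegat", "towardsNorthSea")))
}

# One tagged fish row for classification tests.
make_fish <- function(fish_id = "f1", release_region = "ESkagerrak",
                      release_lon = 11.4, release_lat = 58.2,
                      release_date = as.Date("2003-10-01"),
                      days = 120,
                      recapture_lon = release_lon, recapture_lat = release_lat,
                      track_lons = numeric(0)) {
  tibble::tibble(
    fish_id = fish_id,
    release_date = release_date, release_lat = release_lat,
    release_lon = release_lon, release_region = release_region,
    recapture_date = release_date + days,
    recapture_lat = recapture_lat, recapture_lon = recapture_lon,
    track = list(tibble::tibble(
      date = release_date + seq_along(track_lons),
      longitude = track_lons
    ))
  )
}

# Re-level sample/locus factors after combining genotype tables.
as_geno_tbl_test <- function(geno, loci, samples) {
  geno$locus <- factor(as.character(geno$locus), levels = loci)
  geno$sample <- factor(as.character(geno$sample), levels = samples)
  geno
}

`%||%` <- rlang::`%||%`

# Canonical row order for genotype-table comparisons.
sort_geno <- function(geno) {
  geno[order(as.integer(geno$sample), geno$individual_id, as.integer(geno$locus)), ]
}
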