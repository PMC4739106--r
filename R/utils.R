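# Internal helpers shared across modules.

# A genotype table is a tibble in long form: one row per individual x locus.
# Required columns: sample, individual_id, locus, allele_1, allele_2.
# Missing calls have NA in both allele slots; half-missing is rejected at the
# boundary (no estimator here is defined for a single gene copy).
check_geno <- function(geno, arg = "geno") {
  required <- c("sample", "individual_id", "locus", "allele_1", "allele_2")
  if (!is.data.frame(geno)) {
    abort(sprintf("`%s` must be a data frame of genotype calls.", arg))
  }
  missing_cols <- setdiff(required, names(geno))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`%s` lacks column(s): %s.", arg, paste(missing_cols, collapse = ", ")
    ))
  }
  half <- xor(is.na(geno$allele_1), is.na(geno$allele_2))
  if (any(half)) {
    abort(sprintf(
      "`%s` contains %d half-missing call(s); both allele slots must be present or both missing.",
      arg, sum(half)
    ))
  }
  bad <- !is.na(geno$allele_1) & (geno$allele_1 <= 0 | geno$allele_2 <= 0)
  if (any(bad)) {
    abort(sprintf("`%s` contains non-positive allele codes; code 0 is reserved for missing.", arg))
  }
  invisible(geno)
}

# Locus order: factor levels if present, else order of appearance.
locus_levels <- function(geno) {
  if (is.factor(geno$locus)) levels(geno$locus) else unique(as.character(geno$locus))
}

sample_levels <- function(geno) {
  if (is.factor(geno$sample)) levels(geno$sample) else unique(as.character(geno$sample))
}

# Re-assert locus/sample ordering after dplyr verbs that drop factor levels.
as_geno_tbl <- function(geno, loci = NULL, samples = NULL) {
  loci <- loci %||% locus_levels(geno)
  samples <- samples %||% sample_levels(geno)
  geno$locus <- factor(as.character(geno$locus), levels = loci)
  geno$sample <- factor(as.character(geno$sample), levels = samples)
  as_tibble(geno)
}

# Split a genotype table into a fast internal representation:
#   ind  : tibble(uid, individual_id, sample) one row per individual
#   loci : per locus, list(uid, a1, a2) for non-missing calls only
geno_split <- function(geno) {
  geno <- as_geno_tbl(check_geno(geno))
  ind <- dplyr::distinct(geno, .data$sample, .data$individual_id)
  ind$uid <- seq_len(nrow(ind))
  key <- paste(ind$sample, ind$individual_id, sep = "\r")
  uid_of <- setNames(ind$uid, key)
  guid <- unname(uid_of[paste(geno$sample, geno$individual_id, sep = "\r")])
  loci <- lapply(locus_levels(geno), function(l) {
    rows <- which(geno$locus == l & !is.na(geno$allele_1))
    list(uid = guid[rows], a1 = geno$allele_1[rows], a2 = geno$allele_2[rows])
  })
  names(loci) <- locus_levels(geno)
  list(ind = ind, loci = loci, grp = factor(as.character(ind$sample), levels = sample_levels(geno)))
}

# Deterministic 32-bit seed stream: root seed combined with a stable string
# hash so per-fish results do not depend on processing order.
derive_seed <- function(seed, key) {
  h <- 0
  for (v in utf8ToInt(as.character(key))) h <- (h * 31 + v) %% 2147483647L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Dirichlet draw via normalised gammas; alpha a positive vector.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) {
    # numerically degenerate tiny alphas: fall back to a single category
    g[sample.int(length(alpha), 1, prob = alpha)] <- 1
  }
  g / sum(g)
}

# TSV writer used by the pipeline: 4-decimal display values plus a sidecar
# JSON carrying full precision.
write_table4 <- function(df, path) {
  disp <- df
  for (nm in names(disp)) {
    if (is.double(disp[[nm]])) disp[[nm]] <- round(disp[[nm]], 4)
  }
  readr::write_tsv(disp, path, progress = FALSE)
  jsonlite::write_json(df, paste0(path, ".json"), digits = NA, dataframe = "columns")
  invisible(path)
}
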