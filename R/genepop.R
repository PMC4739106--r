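#' Read a Genepop genotype file
#'
#' Parses the classical Genepop exchange format: a title line, one locus name
#' per line (or a single comma-separated line), and population blocks opened
#' by a line reading `pop`. Allele calls are fixed-width 2- or 3-digit codes
#' (detected from the file); the all-zero code marks a missing call.
#'
#' Population labels follow the Genepop convention of naming each block after
#' its last individual identifier; blocks with duplicated or empty labels fall
#' back to `pop1 ... popK`.
#'
#' @param path Path to a Genepop file. The parser is dialect-tolerant: it
#'   accepts comma- or whitespace-separated locus name lines and any amount of
#'   whitespace around genotype fields.
#' @return A tibble of genotype calls in long form with columns `sample`,
#'   `individual_id`, `locus` (both factors preserving file order),
#'   `allele_1`, `allele_2` (integer; `NA` for missing calls).
#' @examples
#' gp <- tempfile(fileext = ".gen")
#' writeLines(c("toy", "LocA", "LocB", "pop",
#'   "fishA1 , 102104 101101", "fishA2 , 102102 000000",
#'   "pop", "fishB1 , 104104 101102"), gp)
#' read_genepop(gp)
#' @seealso [write_genepop()], [subset_loci()], [pool_samples()]
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  if (length(lines) < 3) abort("Genepop file too short: need title, loci and at least one pop block.")
  is_pop <- grepl("^pop\\b", lines, ignore.case = TRUE) & !grepl(",", lines)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) abort("Genepop file has no `pop` line.")
  header <- lines[2:(first_pop - 1)]
  loci <- unlist(strsplit(header, "[,\t]"))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0) abort("Genepop file declares no loci.")
  if (anyDuplicated(loci)) abort("Genepop locus names must be unique.")

  pop_starts <- which(is_pop)
  pop_ends <- c(pop_starts[-1] - 1L, length(lines))
  blocks <- Map(function(s, e) if (e > s) lines[(s + 1):e] else character(0), pop_starts, pop_ends)
  blocks <- lapply(blocks, function(b) b[nzchar(b)])
  if (any(lengths(blocks) == 0)) abort("Genepop file contains an empty pop block.")

  parse_block <- function(block, offset) {
    ids <- character(length(block))
    calls <- vector("list", length(block))
    for (i in seq_along(block)) {
      line_no <- offset + i
      parts <- strsplit(block[i], ",")[[1]]
      if (length(parts) < 2) {
        abort(sprintf("Line %d: expected `id , genotypes` with a comma separator.", line_no))
      }
      ids[i] <- trimws(parts[1])
      toks <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[[:space:]]+")[[1]]
      toks <- toks[nzchar(toks)]
      if (length(toks) != length(loci)) {
        abort(sprintf(
          "Line %d: %d genotype field(s) but %d loci declared.", line_no, length(toks), length(loci)
        ))
      }
      if (any(!grepl("^[0-9]+$", toks))) {
        abort(sprintf("Line %d: non-numeric genotype field.", line_no))
      }
      w <- unique(nchar(toks))
      if (length(w) != 1 || !(w %in% c(4L, 6L))) {
        abort(sprintf(
          "Line %d: genotype fields must all be 4 (2-digit) or 6 (3-digit) characters; saw width(s) %s.",
          line_no, paste(sort(unique(nchar(toks))), collapse = ", ")
        ))
      }
      calls[[i]] <- toks
    }
    list(ids = ids, calls = calls)
  }
  parsed <- Map(parse_block, blocks, pop_starts)

  widths <- unique(unlist(lapply(parsed, function(p) nchar(p$calls[[1]][1]))))
  if (length(widths) != 1) abort("Mixed 2- and 3-digit allele encodings in one file.")
  digits <- widths / 2L

  labels <- vapply(parsed, function(p) p$ids[length(p$ids)], character(1))
  if (anyDuplicated(labels) || any(!nzchar(labels))) {
    labels <- paste0("pop", seq_along(parsed))
  }

  out <- vector("list", length(parsed))
  for (b in seq_along(parsed)) {
    p <- parsed[[b]]
    toks <- unlist(p$calls)
    a1 <- as.integer(substr(toks, 1L, digits))
    a2 <- as.integer(substr(toks, digits + 1L, 2L * digits))
    miss <- a1 == 0L & a2 == 0L
    if (any(xor(a1 == 0L, a2 == 0L))) {
      abort("Half-missing genotype (one allele slot zero) is not a valid Genepop call.")
    }
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
    out[[b]] <- tibble(
      sample = labels[b],
      individual_id = rep(p$ids, each = length(loci)),
      locus = rep(loci, times = length(p$ids)),
      allele_1 = a1,
      allele_2 = a2
    )
  }
  geno <- dplyr::bind_rows(out)
  geno$sample <- factor(geno$sample, levels = labels)
  geno$locus <- factor(geno$locus, levels = loci)
  check_geno(geno)
}

#' Write a genotype table to Genepop format
#'
#' @param geno A genotype table (see [read_genepop()] for the column contract).
#' @param path Output file path.
#' @param digits Allele code width, 2 or 3. Every allele code must be
#'   representable in this width.
#' @param title Title line written as the first file line.
#' @return `path`, invisibly. The file re-reads to an identical dataset
#'   (bit-exact allele codes, input ordering preserved).
#' @export
write_genepop <- function(geno, path, digits = 3, title = "codhoming export") {
  geno <- as_geno_tbl(check_geno(geno))
  if (nrow(geno) == 0) abort("Refusing to write an empty genotype table.")
  digits <- as.integer(digits)
  if (!digits %in% c(2L, 3L)) abort("`digits` must be 2 or 3.")
  max_code <- max(c(geno$allele_1, geno$allele_2), na.rm = TRUE)
  if (max_code >= 10^digits) {
    abort(sprintf("Allele code %d does not fit in %d digits.", max_code, digits))
  }
  loci <- locus_levels(geno)
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    formatC(a, width = digits, flag = "0")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, loci), con)
  for (s in sample_levels(geno)) {
    block <- geno[geno$sample == s, ]
    if (nrow(block) == 0) next
    writeLines("pop", con)
    ids <- unique(block$individual_id)
    # fixed locus order per individual
    m1 <- matrix(NA_integer_, length(ids), length(loci), dimnames = list(ids, loci))
    m2 <- m1
    m1[cbind(match(block$individual_id, ids), match(as.character(block$locus), loci))] <- block$allele_1
    m2[cbind(match(block$individual_id, ids), match(as.character(block$locus), loci))] <- block$allele_2
    gstr <- matrix(paste0(fmt(m1), fmt(m2)), nrow = length(ids))
    writeLines(paste(ids, ",", apply(gstr, 1, paste, collapse = " ")), con)
  }
  invisible(path)
}

#' Restrict a genotype table to a locus panel
#'
#' Mirrors the study design of reporting statistics on both the 8-locus and
#' the full 12-locus microsatellite panels. Individuals are retained even if
#' fully missing on the panel.
#'
#' @param geno A genotype table.
#' @param panel Character vector of locus names, a subset of the table's loci.
#' @return The genotype table restricted to `panel`, locus order as in `panel`.
#' @export
subset_loci <- function(geno, panel) {
  geno <- as_geno_tbl(check_geno(geno))
  panel <- as.character(panel)
  if (length(panel) == 0) abort("`panel` must name at least one locus.")
  unknown <- setdiff(panel, locus_levels(geno))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown locus name(s): %s.", paste(unknown, collapse = ", ")))
  }
  out <- geno[as.character(geno$locus) %in% panel, ]
  as_geno_tbl(out, loci = panel, samples = sample_levels(geno))
}

#' Pool samples into regional reference groups
#'
#' Replaces sample labels by pool names. Samples not mentioned in the pooling
#' map are dropped; pooled sample size is the sum of member sizes.
#'
#' @param geno A genotype table.
#' @param pooling Named character vector mapping sample label to pool name,
#'   e.g. `c(KA00 = "Kattegat", SK00 = "NorthSea_WSkagerrak")`.
#' @return A genotype table with one sample per pool (pool order = order of
#'   first appearance in `pooling`).
#' @export
pool_samples <- function(geno, pooling) {
  geno <- as_geno_tbl(check_geno(geno))
  if (is.null(names(pooling)) || any(!nzchar(names(pooling)))) {
    abort("`pooling` must be a named vector: names are sample labels, values pool names.")
  }
  unknown <- setdiff(names(pooling), sample_levels(geno))
  if (length(unknown) > 0) {
    abort(sprintf("Pooling refers to unknown sample(s): %s.", paste(unknown, collapse = ", ")))
  }
  pools <- unique(unname(pooling))
  out <- geno[as.character(geno$sample) %in% names(pooling), ]
  out$sample <- unname(pooling[as.character(out$sample)])
  empty <- setdiff(pools, unique(out$sample))
  if (length(empty) > 0) {
    abort(sprintf("Pool(s) with no members: %s.", paste(empty, collapse = ", ")))
  }
  as_geno_tbl(out, loci = locus_levels(geno), samples = pools)
}

#' Count individuals per sample
#'
#' @param geno A genotype table.
#' @return A tibble with columns `sample` and `n`.
#' @export
sample_sizes <- function(geno) {
  geno <- as_geno_tbl(check_geno(geno))
  dplyr::distinct(geno, .data$sample, .data$individual_id) |>
    dplyr::count(.data$sample, name = "n")
}
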