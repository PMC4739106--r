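#' Build the migration-direction x assignment contingency table
#'
#' Keeps only directionally migrating fish: categories ending in
#' `ToNorthSea` map to the `towardsNorthSea` column, `SkagerrakToKattegat`
#' to `towardsKattegat`; nonmigratory and excluded fish are dropped. Rows
#' are the genetic assignment pools.
#'
#' @param records A data frame with columns `category` (see
#'   [classify_behaviour()]) and `assigned` (pool name per fish).
#' @param pools Optional row order (pool names). Default: `Kattegat`-named
#'   pool first when present.
#' @return An integer matrix, rows = assignment pools, columns =
#'   `towardsKattegat`, `towardsNorthSea`.
#' @export
build_contingency <- function(records, pools = NULL) {
  needed <- c("category", "assigned")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("`records` lacks column(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  d <- records[!is.na(records$assigned), ]
  direction <- dplyr::case_when(
    d$category %in% c("SkagerrakToNorthSea", "KattegatToNorthSea") ~ "towardsNorthSea",
    d$category == "SkagerrakToKattegat" ~ "towardsKattegat",
    TRUE ~ NA_character_
  )
  d <- d[!is.na(direction), ]
  direction <- direction[!is.na(direction)]
  if (nrow(d) == 0) abort("No directionally migrating fish: contingency table undefined.")
  if (is.null(pools)) {
    pools <- unique(d$assigned)
    if ("Kattegat" %in% pools) pools <- c("Kattegat", setdiff(pools, "Kattegat"))
  }
  tab <- table(factor(d$assigned, levels = pools),
               factor(direction, levels = c("towardsKattegat", "towardsNorthSea")))
  m <- matrix(as.integer(tab), nrow = length(pools),
              dimnames = list(assigned = pools,
                              direction = c("towardsKattegat", "towardsNorthSea")))
  m
}

# Fisher p-values for every table (x1, n1-x1; x2, n2-x2), x1 = 0..n1 rows,
# x2 = 0..n2 columns. Success = row 1, groups = columns (sizes n1, n2).
# one-sided: fixed direction p1 > p2 (upper tail of the first group's
# success count conditional on both margins).
fisher_p_grid <- function(n1, n2, sided) {
  N <- n1 + n2
  P <- matrix(NA_real_, n1 + 1, n2 + 1)
  for (m in 0:N) {
    lo <- max(0, m - n2)
    hi <- min(n1, m)
    supp <- lo:hi
    dp <- dhyper(supp, m, N - m, n1)
    for (x1 in supp) {
      x2 <- m - x1
      p <- if (sided == "one") {
        sum(dp[supp >= x1])
      } else {
        d0 <- dp[supp == x1]
        sum(dp[dp <= d0 * (1 + 1e-7)])
      }
      P[x1 + 1, x2 + 1] <- min(1, p)
    }
  }
  P
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact conditional test by direct hypergeometric enumeration over the cell
#' `(1,1)` given both margins. One-sided takes the tail in the direction of
#' the observed association; two-sided sums all point probabilities not
#' exceeding the observed one. Used standalone and as the embedded statistic
#' of [boschloo_test()].
#'
#' @param tab 2x2 integer matrix (rows = assignment, columns = migration
#'   direction).
#' @param sided `"one"` or `"two"`.
#' @return An `exact_test` object: `method`, `sided`, `p`, `table`.
#'   Degenerate margins give `p = 1` with a message.
#' @export
fisher_exact <- function(tab, sided = c("one", "two")) {
  sided <- match.arg(sided)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    abort("`tab` must be a 2x2 matrix of non-negative counts.")
  }
  n1 <- sum(tab[, 1])
  n2 <- sum(tab[, 2])
  if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0 || n1 == 0 || n2 == 0) {
    inform("Degenerate margin: p = 1 by convention.")
    return(structure(list(method = "fisher", sided = sided, p = 1, table = tab),
                     class = "exact_test"))
  }
  x1 <- tab[1, 1]
  x2 <- tab[1, 2]
  p <- if (sided == "one" && x1 / n1 < x2 / n2) {
    # observed association is the reverse direction: lower tail of x1
    fisher_p_grid(n2, n1, "one")[x2 + 1, x1 + 1]
  } else {
    fisher_p_grid(n1, n2, sided)[x1 + 1, x2 + 1]
  }
  structure(list(method = "fisher", sided = sided, p = p, table = tab),
            class = "exact_test")
}

#' Boschloo's unconditional exact test of independence for a 2x2 table
#'
#' Tests whether migration direction is independent of genetic assignment.
#' The two migration-direction groups (column totals) are treated as fixed
#' binomial sample sizes; Fisher's conditional p-value is the test
#' statistic, and the p-value is the rejection probability maximised over
#' the common success probability (the nuisance parameter) on a uniform
#' grid, optionally refined around the argmax. Uniformly at least as
#' powerful as Fisher's test: `p_boschloo <= p_fisher` always.
#'
#' The default one-sided alternative is the philopatry direction: fish
#' migrate towards the population they are genetically assigned to (more
#' row-1 successes in column 1 than in column 2).
#'
#' @param tab 2x2 integer matrix, rows = assignment pools (`Kattegat`
#'   first), columns = `towardsKattegat`, `towardsNorthSea`.
#' @param sided `"one"` (default) or `"two"`.
#' @param grid_size Nuisance-parameter grid points on (0.001, 0.999),
#'   at least 101 (default 1001).
#' @param refine Golden-section refinement around the grid argmax
#'   (default `TRUE`).
#' @param orientation `"columns"` (default: direction groups are the fixed
#'   binomial samples) or `"rows"` (transposed convention).
#' @return An `exact_test` object: `method = "boschloo"`, `sided`, `p`,
#'   `fisher_p` (the observed embedded statistic), `pi_argmax`, `table`.
#' @examples
#' tab <- matrix(c(3, 0, 12, 20), nrow = 2,
#'               dimnames = list(c("Kattegat", "NorthSea_WSkagerrak"),
#'                               c("towardsKattegat", "towardsNorthSea")))
#' boschloo_test(tab)
#' @export
boschloo_test <- function(tab, sided = c("one", "two"), grid_size = 1001,
                          refine = TRUE, orientation = c("columns", "rows")) {
  sided <- match.arg(sided)
  orientation <- match.arg(orientation)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    abort("`tab` must be a 2x2 matrix of non-negative counts.")
  }
  if (grid_size < 101) abort("`grid_size` must be at least 101.")
  work <- if (orientation == "columns") tab else t(tab)
  n1 <- sum(work[, 1])
  n2 <- sum(work[, 2])
  if (n1 == 0 || n2 == 0) abort("A group (column total) is zero: Boschloo's test undefined.")
  x1 <- work[1, 1]
  x2 <- work[1, 2]

  Tm <- fisher_p_grid(n1, n2, sided)
  Tobs <- Tm[x1 + 1, x2 + 1]
  rej <- which(Tm <= Tobs + 1e-12, arr.ind = TRUE)
  ri <- rej[, 1] - 1L  # x1 values in the rejection set
  rj <- rej[, 2] - 1L  # x2 values
  size_at <- function(pi) {
    sum(dbinom(ri, n1, pi) * dbinom(rj, n2, pi))
  }
  grid <- seq(0.001, 0.999, length.out = grid_size)
  vals <- vapply(grid, size_at, numeric(1))
  best <- which.max(vals)
  p <- vals[best]
  pi_star <- grid[best]
  if (refine) {
    lo <- grid[max(1, best - 1)]
    hi <- grid[min(grid_size, best + 1)]
    opt <- stats::optimize(size_at, c(lo, hi), maximum = TRUE, tol = 1e-10)
    if (opt$objective > p) {
      p <- opt$objective
      pi_star <- opt$maximum
    }
  }
  structure(list(method = "boschloo", sided = sided, p = min(1, p),
                 fisher_p = Tobs, pi_argmax = pi_star, table = tab,
                 grid_size = grid_size, orientation = orientation),
            class = "exact_test")
}

#' @export
print.exact_test <- function(x, ...) {
  cat(sprintf("%s exact test (%s-sided)\n",
              if (x$method == "boschloo") "Boschloo unconditional" else "Fisher", x$sided))
  print(x$table)
  cat(sprintf("  P = %.6g\n", x$p))
  if (!is.null(x$fisher_p)) {
    cat(sprintf("  embedded Fisher statistic = %.6g; nuisance argmax = %.4f\n",
                x$fisher_p, x$pi_argmax))
  }
  invisible(x)
}

#' @method tidy exact_test
#' @export
tidy.exact_test <- function(x, ...) {
  tibble(method = x$method, sided = x$sided, p = x$p,
         fisher_p = x$fisher_p %||% NA_real_,
         pi_argmax = x$pi_argmax %||% NA_real_)
}

#' @method glance exact_test
#' @export
glance.exact_test <- function(x, ...) tidy(x)
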