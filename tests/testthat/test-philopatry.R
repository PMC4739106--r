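test_that("the contingency table keeps only directional migrants", {
  # the published group structure: 10/17, 2/3, 3/0 among migrants,
  # plus nonmigratory fish that must be dropped
  records <- tibble::tibble(
    category = c(rep("SkagerrakToNorthSea", 27), rep("KattegatToNorthSea", 5),
                 rep("SkagerrakToKattegat", 3), rep("NonmigratorySkagerrak", 29),
                 rep("NonmigratoryKattegat", 36)),
    assigned = c(rep(c("Kattegat", "NorthSea_WSkagerrak"), c(10, 17)),
                 rep(c("Kattegat", "NorthSea_WSkagerrak"), c(2, 3)),
                 rep("Kattegat", 3),
                 rep(c("Kattegat", "NorthSea_WSkagerrak"), c(11, 18)),
                 rep(c("Kattegat", "NorthSea_WSkagerrak"), c(24, 12)))
  )
  tab <- build_contingency(records)
  expect_equal(sum(tab), 35)
  expect_equal(unname(tab), matrix(c(3L, 0L, 12L, 20L), 2))
  expect_equal(rownames(tab), c("Kattegat", "NorthSea_WSkagerrak"))

  expect_error(build_contingency(records[records$category == "NonmigratoryKattegat", ]),
               "No directionally migrating")
  single <- tibble::tibble(category = "SkagerrakToKattegat", assigned = "Kattegat")
  expect_equal(unname(build_contingency(single, pools = c("Kattegat", "NS"))),
               matrix(c(1L, 0L, 0L, 0L), 2))
})

test_that("Fisher enumeration matches the closed forms and fisher.test", {
  f <- fisher_exact(paper_table(), sided = "one")
  expect_equal(f$p, 455 / 6545, tolerance = 1e-12)   # frozen pre-build enumeration
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2), sided = "two")$p, 1)
  corner <- fisher_exact(matrix(c(10, 0, 0, 10), 2), sided = "one")
  expect_equal(corner$p, 1 / choose(20, 10), tolerance = 1e-12)
  # independent cross-check against stats::fisher.test on random tables
  set.seed(61)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    two <- fisher_exact(tab, "two")$p
    expect_equal(two, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    one <- fisher_exact(tab, "one")$p
    alt <- if (tab[1, 1] / sum(tab[, 1]) >= tab[1, 2] / sum(tab[, 2])) "greater" else "less"
    expect_equal(one, stats::fisher.test(tab, alternative = alt)$p.value,
                 tolerance = 1e-9)
  }
  # degenerate margin convention
  expect_message(d <- fisher_exact(matrix(c(0, 3, 0, 5), 2)), "Degenerate")
  expect_equal(d$p, 1)
})

test_that("Boschloo agrees with a plain enumeration oracle at small n", {
  # oracle: double loop over all tables, fisher.test as statistic, exact
  # binomial sums at every grid point, no pruning or refinement
  oracle_boschloo <- function(tab, grid) {
    n1 <- sum(tab[, 1]); n2 <- sum(tab[, 2])
    stat <- function(x1, x2) {
      stats::fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), 2),
                         alternative = "greater")$p.value
    }
    Tobs <- stat(tab[1, 1], tab[1, 2])
    best <- 0
    for (pi in grid) {
      tot <- 0
      for (x1 in 0:n1) for (x2 in 0:n2) {
        if (stat(x1, x2) <= Tobs + 1e-12) {
          tot <- tot + dbinom(x1, n1, pi) * dbinom(x2, n2, pi)
        }
      }
      best <- max(best, tot)
    }
    best
  }
  grid <- seq(0.001, 0.999, length.out = 101)
  set.seed(67)
  for (i in 1:8) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    tab <- matrix(c(x1 <- sample(0:n1, 1), n1 - x1,
                    x2 <- sample(0:n2, 1), n2 - x2), 2)
    if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0) next
    got <- boschloo_test(tab, grid_size = 101, refine = FALSE)$p
    expect_equal(got, oracle_boschloo(tab, grid), tolerance = 1e-10)
  }
})

test_that("Boschloo dominates Fisher and is calm on null tables", {
  set.seed(71)
  for (i in 1:100) {
    n1 <- sample(3:25, 1); n2 <- sample(3:25, 1)
    tab <- matrix(c(x1 <- sample(0:n1, 1), n1 - x1,
                    x2 <- sample(0:n2, 1), n2 - x2), 2)
    if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0) next
    for (sided in c("one", "two")) {
      b <- boschloo_test(tab, sided = sided)
      expect_lte(b$p, b$fisher_p + 1e-12)
    }
  }
  expect_gte(boschloo_test(matrix(c(5, 5, 5, 5), 2), sided = "two")$p, 0.99)
  expect_error(boschloo_test(matrix(c(0, 0, 3, 5), 2)), "undefined")
})

test_that("grid resolution and orientation conventions are stable", {
  tab <- paper_table()
  p1 <- boschloo_test(tab, grid_size = 1001)$p
  p2 <- boschloo_test(tab, grid_size = 10001)$p
  expect_lte(abs(p1 - p2), 0.001)
  # transposed convention stays in the tolerance band around the printed value
  pr <- boschloo_test(tab, orientation = "rows")$p
  expect_true(pr > 0 && pr < 1)
  pt <- boschloo_test(tab, sided = "two")$p
  expect_gte(pt, p1)
  td <- tidy(boschloo_test(tab))
  expect_equal(td$method, "boschloo")
  expect_true(td$pi_argmax > 0 && td$pi_argmax < 1)
})
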