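test_that("an exact permutation null yields Q = 0 and no DE calls", {
  set.seed(11)
  half <- matrix(rpois(60 * 40, 1.5), 60, 40)
  x <- small_counts(cbind(half, half[, sample(40)]),
                    cells = sprintf("c%02d", 1:80))
  grp <- rep(c(1L, 2L), each = 40)
  names(grp) <- colnames(x)
  res <- suppressWarnings(run_heart(x, grp))
  expect_true(all(res$table$Q == 0))
  expect_true(all(res$table$p == 1))
  expect_false(any(res$table$is_de))
})

test_that("swapping the group labels leaves Li, Q and p unchanged", {
  x <- random_counts(300, 120, seed = 5, lambda_mean = 1.2)
  grp <- rep(c(1L, 2L), each = 60)
  names(grp) <- colnames(x)
  r1 <- run_heart(x, grp)
  r2 <- run_heart(x, 3L - grp)
  for (col in c("L1", "L2", "L3", "Q", "p", "q", "is_de"))
    expect_equal(r1$table[[col]], r2$table[[col]], tolerance = 1e-12)
  expect_equal(r1$table$z, -r2$table$z, tolerance = 1e-12)
  expect_equal(r1$table$t, -r2$table$t, tolerance = 1e-12)
})

test_that("results are invariant to gene and cell order", {
  x <- random_counts(250, 100, seed = 6, lambda_mean = 1)
  grp <- rep(c(1L, 2L), 50)
  names(grp) <- colnames(x)
  r1 <- run_heart(x, grp)

  set.seed(7)
  gperm <- sample(nrow(x)); cperm <- sample(ncol(x))
  r2 <- run_heart(x[gperm, cperm], grp[cperm])
  t1 <- r1$table[order(r1$table$gene_id), ]
  t2 <- r2$table[order(r2$table$gene_id), ]
  rownames(t1) <- rownames(t2) <- NULL
  expect_equal(t1, t2, tolerance = 1e-12)
  expect_equal(r1$fitted_df, r2$fitted_df, tolerance = 1e-12)
})

test_that("per-gene rows agree with the exported component tests", {
  x <- random_counts(120, 90, seed = 8, lambda_mean = 2)
  grp <- rep(c(1L, 2L), c(45, 45))
  names(grp) <- colnames(x)
  res <- run_heart(x, grp)
  dense <- as.matrix(x)
  for (g in sample(rownames(x), 15)) {
    row <- res$table[res$table$gene_id == g, ]
    a <- dense[g, grp == 1]; a <- a[a > 0]
    b <- dense[g, grp == 2]; b <- b[b > 0]
    pr <- proportion_test(length(a), 45, length(b), 45)
    expect_equal(row$L1,
                 if ((length(a) + length(b)) %in% c(0, 90)) 1 else pr$L1,
                 tolerance = 1e-12)
    if (length(a) >= 3 && length(b) >= 3) {
      expect_equal(row$L2, location_test(a, b)$L2, tolerance = 1e-12)
      expect_equal(row$L3, scale_test(a, b)$L3, tolerance = 1e-12)
    } else {
      expect_identical(row$L2, 1)
      expect_identical(row$L3, 1)
    }
    expect_equal(row$Q, -2 * (log(row$L1) + log(row$L2) + log(row$L3)),
                 tolerance = 1e-12)
  }
})

test_that("degenerate inputs are handled as specified", {
  x <- small_counts(rbind(rep(0, 80), c(rep(3, 40), rep(5, 40)), rep(1, 80)),
                    genes = c("silent", "shifted", "constant"))
  grp <- rep(c(1L, 2L), each = 40)
  names(grp) <- colnames(x)
  res <- suppressWarnings(run_heart(x, grp))
  tab <- res$table
  # all-zero gene: no component computable
  expect_identical(tab[tab$gene_id == "silent", "p"], 1)
  expect_identical(tab[tab$gene_id == "silent", "q"], 1)
  expect_identical(tab[tab$gene_id == "silent", "n_valid"], 0L)
  # constant-everywhere gene: detection saturated, no positive-part spread
  expect_identical(tab[tab$gene_id == "constant", "n_valid"], 0L)
  # constant-but-different gene: location evidence is overwhelming
  expect_lt(tab[tab$gene_id == "shifted", "p"], 1e-10)

  expect_error(run_heart(x, rep(1L, 80)), "both groups")
  # tiny run warns about both the sample size and the df fallback
  expect_warning(
    expect_warning(run_heart(x[, 1:20], rep(c(1L, 2L), each = 10)),
                   "unreliable"),
    "fewer than 50")
})

test_that("group labels align by cell id and unlabelled cells are dropped", {
  x <- random_counts(150, 80, seed = 9, lambda_mean = 1.5)
  grp <- rep(c(1L, 2L), each = 40)
  names(grp) <- colnames(x)
  r_all <- run_heart(x, grp)
  shuffled <- grp[sample(names(grp))]
  r_shuf <- run_heart(x, shuffled)
  expect_equal(r_all$table, r_shuf$table, tolerance = 1e-12)

  expect_warning(r_drop <- run_heart(x, grp[1:70]), "dropped")
  expect_identical(r_drop$n1 + r_drop$n2, 70L)
})
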