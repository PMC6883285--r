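grouped_ds <- function(cq, sizes = NULL) {
  if (is.null(sizes)) sizes <- c(A = ceiling(nrow(cq) / 2),
                                 B = floor(nrow(cq) / 2))
  make_ds(cq, groups = rep(names(sizes), sizes))
}

test_that("the decomposition matches a literal transcription of the estimators", {
  set.seed(61)
  cq <- random_cq(9, 5)
  ds <- grouped_ds(cq, c(A = 3, B = 3, C = 3))
  res <- normfinder(ds)
  or <- oracle_normfinder(cq, rep(c("A", "B", "C"), each = 3))
  expect_equal(res$table$rho, or$rho, tolerance = 1e-12)
  expect_equal(unname(res$inter_var), or$d, tolerance = 1e-12)
  expect_equal(unname(res$intra_var), or$intra_var, tolerance = 1e-12)
  expect_equal(res$gamma2, or$gamma2, tolerance = 1e-12)
  # structural invariants of the deviations
  expect_equal(unname(rowSums(res$inter_var)), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(colSums(res$inter_var * c(3, 3, 3))), rep(0, 5),
               tolerance = 1e-10)
})

test_that("a constant gene attains the minimal rho and near-zero variation", {
  set.seed(62)
  cq <- random_cq(16, 4, 24.5, 25.5)
  cq[, 2] <- 25
  res <- normfinder(grouped_ds(cq, c(A = 8, B = 8)))
  # fitting sample effects leaks a small share of the other genes' noise into
  # the constant gene, so its estimates are near zero, not exactly zero
  expect_true(all(res$intra_var[, 2] < apply(res$intra_var[, -2], 1, min)))
  expect_lt(max(abs(res$inter_var[, 2])), 0.2)
  expect_identical(res$table$rank[2], 1)

  # fully degenerate data: every term is exactly zero
  flat <- matrix(rep(c(20, 25, 30), each = 6), 6, 3,
                 dimnames = list(paste0("S", 1:6), paste0("g", 1:3)))
  resf <- normfinder(grouped_ds(flat, c(A = 3, B = 3)))
  expect_equal(resf$table$rho, rep(0, 3))
  expect_identical(resf$mode, "grouped_no_intergroup_dispersion")
})

test_that("rho is invariant to sample-wise and gene-wise constant shifts", {
  set.seed(63)
  cq <- random_cq(10, 4)
  ds <- grouped_ds(cq, c(A = 5, B = 5))
  base <- normfinder(ds)$table$rho
  shifted_samples <- cq + stats::rnorm(10, 0, 2)
  expect_equal(normfinder(grouped_ds(shifted_samples, c(A = 5, B = 5)))$table$rho,
               base, tolerance = 1e-10)
  shifted_genes <- sweep(cq, 2, c(5, -3, 0, 1), `+`)
  expect_equal(normfinder(grouped_ds(shifted_genes, c(A = 5, B = 5)))$table$rho,
               base, tolerance = 1e-10)
})

test_that("a planted group shift makes a gene least stable", {
  set.seed(64)
  n_per <- 4
  cq <- random_cq(3 * n_per, 5, 24.8, 25.2)
  grp <- rep(c("A", "B", "C"), each = n_per)
  cq[grp == "B", 3] <- cq[grp == "B", 3] + 1.0
  res <- normfinder(make_ds(cq, groups = grp))
  expect_identical(which.max(res$table$rho), 3L)
  expect_identical(res$table$rank[3], 5)
})

test_that("shrinkage pulls null group deviations toward zero as groups grow", {
  set.seed(65)
  mean_abs_d <- vapply(c(4, 10, 25), function(n_per) {
    reps <- vapply(1:40, function(i) {
      cq <- random_cq(2 * n_per, 4, 24.5, 25.5)
      res <- normfinder(grouped_ds(cq, c(A = n_per, B = n_per)))
      mean(abs(res$d_shrunk))
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  expect_true(all(diff(mean_abs_d) < 0))
})

test_that("planted intra-group SDs are recovered by the variance estimator", {
  set.seed(66)
  n_per <- 20
  sds <- c(0.1, 0.2, 0.4, 0.6, 0.8)
  est <- replicate(100, {
    loading <- stats::rnorm(2 * n_per, 0, 0.5)
    cq <- sapply(sds, function(s) 25 + loading + stats::rnorm(2 * n_per, 0, s))
    colnames(cq) <- paste0("g", 1:5)
    rownames(cq) <- sprintf("S%02d", 1:(2 * n_per))
    res <- normfinder(grouped_ds(cq, c(A = n_per, B = n_per)))
    sqrt(colMeans(res$intra_var))
  })
  rmse <- sqrt(rowMeans((est - sds)^2))
  # the estimator is unbiased but inherits an absolute noise floor from the
  # other genes through the fitted sample effects, so the relative criterion
  # applies to the ladder rungs above that floor
  expect_lt(max(abs(rowMeans(est) - sds)), 0.03)
  expect_true(all(rmse < 0.1))
  expect_true(all((rmse / sds)[sds >= 0.4] < 0.2))
})

test_that("single-group mode orders genes like their per-gene SD on loading-free data", {
  set.seed(67)
  sds <- c(0.1, 0.25, 0.5, 0.9)
  cq <- sapply(seq_along(sds), function(j) 25 + stats::rnorm(30, 0, sds[j]))
  dimnames(cq) <- list(sprintf("S%02d", 1:30), paste0("g", 1:4))
  res <- normfinder(make_ds(cq, groups = rep("all", 30)))
  expect_identical(res$mode, "single_group")
  expect_identical(order(res$table$rho), order(apply(cq, 2, stats::sd)))
})

test_that("the best pair is found by exhaustive search and exploits cancellation", {
  set.seed(68)
  cq <- random_cq(12, 5)
  ds <- grouped_ds(cq, c(A = 6, B = 6))
  res <- normfinder(ds)
  bp <- normfinder_best_pair(res)
  # independent enumeration over all pairs from the stored decomposition
  genes <- res$table$gene
  best_val <- Inf; best_pair <- NULL
  for (i in 1:4) for (j in (i + 1):5) {
    v <- mean(abs((res$d_shrunk[, i] + res$d_shrunk[, j]) / 2) +
                sqrt((res$var_d_shrunk[, i] + res$var_d_shrunk[, j]) / 4))
    if (v < best_val) { best_val <- v; best_pair <- genes[c(i, j)] }
  }
  expect_identical(sort(bp$pair), sort(best_pair))
  expect_equal(bp$value, best_val, tolerance = 1e-12)

  # mirrored group deviations cancel: the mirrored pair beats either gene alone
  n_per <- 6
  grp <- rep(c("A", "B"), each = n_per)
  base <- random_cq(2 * n_per, 3, 24.9, 25.1)
  mirror <- base
  mirror[grp == "B", 1] <- mirror[grp == "B", 1] + 0.8
  mirror[grp == "B", 2] <- mirror[grp == "B", 2] - 0.8
  resm <- normfinder(make_ds(mirror, groups = grp))
  bpm <- normfinder_best_pair(resm)
  expect_setequal(bpm$pair, c("g1", "g2"))
  expect_lt(bpm$value, min(resm$table$rho[1:2]))
})

test_that("grouped mode rejects single-sample groups and degenerate grouping", {
  cq <- random_cq(5, 3)
  expect_error(normfinder(make_ds(cq, groups = c("A", "A", "A", "A", "B"))),
               "at least 2 samples")
  res <- normfinder(make_ds(cq, groups = rep("X", 5)))
  expect_identical(res$mode, "single_group")
})
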