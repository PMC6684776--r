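test_that("PCA recovers rank-1 structure and reconstructs completely", {
  set.seed(21)
  v <- rnorm(12)
  scores_true <- rnorm(8)
  X <- outer(scores_true, v) + matrix(5, 8, 12) # rank 1 plus common mean
  p1 <- fit_pca(X, 1)
  expect_equal(p1$explained_variance[1] / p1$total_variance, 1,
    tolerance = 1e-12
  )
  # full-rank reconstruction equals the centered data
  Xr <- matrix(rnorm(8 * 5), 8, 5)
  pf <- fit_pca(Xr, 5)
  recon <- pf$scores %*% t(pf$loadings)
  expect_equal(recon, sweep(Xr, 2, colMeans(Xr)),
    ignore_attr = TRUE, tolerance = 1e-8
  )
  # loadings orthonormal
  expect_equal(crossprod(pf$loadings), diag(5), tolerance = 1e-8)
  # explained variances non-increasing and summing to total
  expect_true(all(diff(pf$explained_variance) <= 1e-12))
  expect_equal(sum(pf$all_eigenvalues), pf$total_variance, tolerance = 1e-10)
})

test_that("reconstruction error decreases monotonically with components", {
  set.seed(22)
  X <- matrix(rnorm(20 * 15), 20, 15) %*% diag(seq(3, 0.2, length.out = 15))
  errs <- vapply(1:6, function(k) {
    p <- fit_pca(X, k)
    sum((sweep(X, 2, colMeans(X)) - p$scores %*% t(p$loadings))^2)
  }, 1)
  expect_true(all(diff(errs) < 0))
  expect_error(fit_pca(X, 20), "n_components")
})

test_that("PCA sign convention is deterministic", {
  set.seed(23)
  X <- matrix(rnorm(30), 10, 3)
  p1 <- fit_pca(X, 2)
  p2 <- fit_pca(X[sample(10), ], 2)
  for (j in 1:2) {
    i <- which.max(abs(p1$loadings[, j]))
    expect_gt(p1$loadings[i, j], 0)
    expect_equal(abs(p1$loadings[, j]), abs(p2$loadings[, j]),
      tolerance = 1e-8
    )
  }
})

test_that("T2 and Q behave at the model's geometric extremes", {
  set.seed(24)
  # data exactly in a 2-D plane: all Q are numerically zero
  B <- qr.Q(qr(matrix(rnorm(6 * 2), 6, 2)))
  X <- matrix(rnorm(20 * 2), 20, 2) %*% t(B)
  p <- fit_pca(X, 2)
  rep_ <- t2_q_outliers(p, X)
  expect_true(all(rep_$report$q < 1e-16))
  expect_false(any(rep_$report$flagged))
  # a sample at the centroid has T2 = 0
  Xc <- rbind(X, colMeans(X))
  rep2 <- t2_q_outliers(p, Xc)
  expect_equal(rep2$report$t2[21], 0, tolerance = 1e-16)
  expect_error(t2_q_outliers(p, X, confidence = 1.2), "between 0 and 1")
})

test_that("the conjunctive T2/Q rule flags exactly a planted outlier", {
  # 20 in-class spectra whose amplitude variability spans the model
  # plane, plus one sample with peaks at alien masses: high T2 (its
  # in-class markers are missing) AND high Q (alien peaks are off-model)
  tpl <- class_template(
    "A", data.frame(center = c(2600, 4200), amplitude = c(10, 8), width = 40),
    n_points = 300
  )
  p <- sim_params(
    intensity_noise_cv = 0.3, additive_noise_sd = 0.05,
    baseline_level = 0, global_shift_sd = 0, local_warp_sd = 0,
    n_replicates = 1, seed = 77
  )
  m <- simulate_dataset(tpl, tpl, c(10, 10), p)
  alien <- class_template(
    "A", data.frame(
      center = c(2200, 5600), amplitude = c(5, 4), width = 40
    ),
    n_points = 300
  )
  out_spec <- simulate_spectrum(alien, p, "alien", sample_index = 99L)[[1]]
  X <- rbind(m$X, out_spec$intensity)
  m21 <- crp_matrix(X, m$axis, c(m$sample_ids, "alien"))
  pca <- fit_pca(m21, 2)
  rep_ <- t2_q_outliers(pca, m21)
  expect_identical(
    rep_$report$sample_id[rep_$report$flagged], "alien"
  )
})

test_that("outlier flags are invariant to row permutation", {
  set.seed(25)
  X <- rbind(matrix(rnorm(40 * 6), 40, 6), rnorm(6, 20))
  ids <- sprintf("s%02d", 1:41)
  m <- crp_matrix(X, 1:6, ids)
  p <- fit_pca(m, 2)
  f1 <- t2_q_outliers(p, m)$report
  perm <- sample(41)
  mp <- crp_matrix(X[perm, ], 1:6, ids[perm])
  pp <- fit_pca(mp, 2)
  f2 <- t2_q_outliers(pp, mp)$report
  expect_setequal(
    f1$sample_id[f1$flagged], f2$sample_id[f2$flagged]
  )
})

test_that("Ward clustering merges near points first with monotone heights", {
  X <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  d <- hca_ward(crp_matrix(cbind(X, X), c(1, 2),
    sample_ids = c("a", "b", "c", "d")
  ))
  hc <- d$hclust
  # first two merges pair the close points (both pairs tie, either order)
  first_two <- rbind(sort(hc$merge[1, ]), sort(hc$merge[2, ]))
  expect_equal(
    first_two[order(first_two[, 1]), ],
    rbind(c(-4, -3), c(-2, -1))
  )
  expect_true(all(diff(hc$height) >= -1e-12))
  k2 <- cut_dendrogram(d, k = 2)
  expect_equal(k2$cluster[1], k2$cluster[2])
  expect_equal(k2$cluster[3], k2$cluster[4])
  expect_false(k2$cluster[1] == k2$cluster[3])
})

test_that("dendrogram cuts cover the degenerate cases", {
  set.seed(26)
  m <- crp_matrix(matrix(rnorm(12), 4, 3), 1:3)
  d <- hca_ward(m)
  expect_equal(unique(cut_dendrogram(d, k = 1)$cluster), 1L)
  expect_equal(sort(cut_dendrogram(d, k = 4)$cluster), 1:4)
  expect_equal(length(unique(cut_dendrogram(d, height = 0)$cluster)), 4)
  expect_error(cut_dendrogram(d, k = 9), "k")
  two <- crp_matrix(matrix(c(1, 2, 1, 2), 2, 2, byrow = TRUE), 1:2)
  expect_equal(hca_ward(two)$hclust$height[1], 0)
})

test_that("a low-noise two-class dataset cuts into its true classes", {
  tt <- tiny_templates(250)
  p <- sim_params(
    intensity_noise_cv = 0.03, additive_noise_sd = 0.02,
    baseline_level = 0.2, global_shift_sd = 0.5, local_warp_sd = 0.2,
    n_replicates = 3, seed = 13
  )
  m <- simulate_dataset(tt$A, tt$B, c(8, 9), p)
  cl <- cut_dendrogram(hca_ward(snv(m)), k = 2)
  tab <- table(cl$cluster, m$class_labels)
  # each cluster is pure (one class per cluster)
  expect_equal(sum(apply(tab, 1, max)), 17)
})

test_that("Ward merge heights stay monotone on random fixtures", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(15 * 4), 15, 4)
    hc <- hca_ward(crp_matrix(X, 1:4))$hclust
    expect_true(all(diff(hc$height) >= -1e-10))
  }
})

test_that("Newick export parenthesizes all leaves", {
  m <- crp_matrix(matrix(rnorm(12), 4, 3), 1:3,
    sample_ids = c("w", "x", "y", "z")
  )
  nwk <- dendrogram_newick(hca_ward(m))
  expect_match(nwk, ";$")
  for (lab in c("w", "x", "y", "z")) expect_match(nwk, lab)
})
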