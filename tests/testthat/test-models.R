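test_that("scaling variants satisfy their defining identities and invert", {
  set.seed(4)
  X <- matrix(rnorm(40, sd = 3), nrow = 8)
  labels <- rep(c("A", "B"), each = 4)
  for (m in c("center", "pareto", "auto", "class_centroid")) {
    sm <- fit_scaling(X, m, labels = labels)
    Xs <- apply_scaling(sm, X)
    expect_equal(invert_scaling(sm, Xs), X, tolerance = 1e-12)
  }
  auto <- apply_scaling(fit_scaling(X, "auto"), X)
  expect_equal(unname(colMeans(auto)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(auto, 2, sd)), rep(1, 5), tolerance = 1e-12)
  par <- fit_scaling(X, "pareto")
  expect_equal(par$scales, sqrt(apply(X, 2, sd)))
})

test_that("class-centroid scaling balances the two classes", {
  XA <- matrix(c(0, 0), nrow = 1)
  XB <- matrix(c(2, 4), nrow = 1)
  sm <- suppressWarnings(fit_scaling(rbind(XA, XB), "class_centroid",
                                     labels = c("A", "B")))
  expect_equal(unname(sm$offsets), c(1, 2))
  # scaled class means are exact negatives of each other
  set.seed(5)
  X <- rbind(matrix(rnorm(30, 1), nrow = 6), matrix(rnorm(20, -2), nrow = 4))
  labels <- rep(c("A", "B"), c(6, 4))
  sm <- fit_scaling(X, "class_centroid", labels = labels)
  Xs <- apply_scaling(sm, X)
  mA <- colMeans(Xs[labels == "A", ])
  mB <- colMeans(Xs[labels == "B", ])
  expect_equal(mA, -mB, tolerance = 1e-10)
})

test_that("PCA reproduces rank structure and variance bookkeeping", {
  u <- c(1, 2, 3, 4); v <- c(2, -1, 0.5)
  p1 <- pca_fit(outer(u, v), K = 2)
  expect_equal(p1$explained_variance_fraction[1], 1)
  expect_true(p1$zero_variance[2])

  X <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12), nrow = 4)
  Xs <- scale(X, scale = FALSE)
  pm <- pca_fit(Xs, K = min(dim(Xs)))
  expect_equal(pm$scores %*% t(pm$loadings), Xs, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(crossprod(pm$loadings), diag(ncol(pm$loadings)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(pm$explained_variance_fraction) <= 1e-12))
  expect_lte(sum(pm$explained_variance_fraction), 1 + 1e-12)
})

test_that("PCA separates the classes of a strong-marker cohort", {
  ds <- standard_fixture(seed = 19, n_points = 1024)
  ds <- exclude_regions(ds)
  ds <- baseline_correct(ds)$dataset
  ds <- pqn_normalize(ds)$dataset
  sm <- fit_scaling(ds$intensities, "pareto")
  pm <- pca_fit(apply_scaling(sm, ds$intensities), K = 2)
  scz <- ds$samples$class_label == "Schizophrenia"
  cA <- colMeans(pm$scores[scz, 1:2]); cB <- colMeans(pm$scores[!scz, 1:2])
  spread <- mean(c(sqrt(rowSums((pm$scores[scz, 1:2] -
                                   rep(cA, each = sum(scz)))^2)),
                   sqrt(rowSums((pm$scores[!scz, 1:2] -
                                   rep(cB, each = sum(!scz)))^2))))
  expect_gt(sqrt(sum((cA - cB)^2)), 2 * spread)
})

test_that("OPLS finds nothing orthogonal in purely y-correlated data", {
  set.seed(6)
  y <- rep(c(0, 1), each = 6)
  tt <- y - mean(y)
  w_true <- rnorm(15); w_true <- w_true / sqrt(sum(w_true^2))
  X <- outer(tt, w_true)
  m <- opls_fit(X, y, n_orth = 1)
  expect_equal(m$n_orth, 0L)
  expect_lt(m$stopped_norm, 1e-8)
})

test_that("OPLS with k orthogonal components matches PLS1 with k+1", {
  worst <- 0
  for (s in 1:20) {
    set.seed(s)
    X <- matrix(rnorm(20 * 30), nrow = 20)
    y <- rep(c(0, 1), each = 10)
    Xs <- scale(X)
    for (k in 0:2) {
      m <- opls_fit(Xs, y, k)
      worst <- max(worst, max(abs(m$fitted - oracle_pls1_fitted(Xs, y, k + 1))))
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("orthogonal scores are orthogonal to the centred response", {
  for (s in 1:5) {
    set.seed(100 + s)
    X <- scale(matrix(rnorm(24 * 40), nrow = 24))
    y <- rep(c(0, 1), each = 12)
    m <- opls_fit(X, y, 3)
    if (m$n_orth > 0) {
      expect_lt(max(abs(crossprod(m$T_o, y - mean(y)))), 1e-8)
      expect_lt(max(abs(crossprod(m$W_o, m$w))), 1e-10)
    }
  }
})

test_that("prediction is consistent and blind to orthogonal perturbations", {
  set.seed(7)
  X <- scale(matrix(rnorm(20 * 25), nrow = 20))
  y <- rep(c(0, 1), each = 10)
  m <- opls_fit(X, y, 2)
  expect_equal(opls_predict(m, X), m$fitted, tolerance = 1e-10)
  # closed-form coefficient path agrees with sequential removal
  expect_equal(as.numeric(X %*% m$b) + m$y_mean, m$fitted, tolerance = 1e-10)
  if (m$n_orth > 0) {
    perturbed <- X[3, ] + 5 * m$P_o[, 1]
    expect_equal(opls_predict(m, rbind(perturbed)),
                 opls_predict(m, X[3, , drop = FALSE]), tolerance = 1e-8)
  }
})

test_that("held-out class means fall on the correct sides of 0.5", {
  ds <- standard_fixture(seed = 23, n_points = 1024)
  subj <- unique(ds$samples$subject_id)
  test_subj <- c(subj[1:2], subj[11:12]) # 2 per class
  te <- ds$samples$subject_id %in% test_subj
  sm <- fit_scaling(ds$intensities[!te, ], "auto")
  cod_y <- as.numeric(ds$samples$class_label[!te] == "Schizophrenia")
  m <- opls_fit(apply_scaling(sm, ds$intensities[!te, ]), cod_y, 1)
  pred <- opls_predict(m, apply_scaling(sm, ds$intensities[te, ]))
  scz_te <- ds$samples$class_label[te] == "Schizophrenia"
  expect_gt(mean(pred[scz_te]), 0.5)
  expect_lt(mean(pred[!scz_te]), 0.5)
})

test_that("back-scaled loadings and correlation weights follow their definitions", {
  set.seed(8)
  X <- matrix(rnorm(18 * 12), nrow = 18)
  y <- rep(c(0, 1), each = 9)
  sm <- fit_scaling(X, "center")
  Xs <- apply_scaling(sm, X)
  m <- opls_fit(Xs, y, 1)
  bs <- backscale_loadings(m, sm, Xs)
  expect_equal(bs$backscaled, m$p) # scale 1 under centering
  # weights equal a brute-force correlation loop
  oracle <- vapply(seq_len(ncol(Xs)),
                   function(j) abs(cor(Xs[, j], m$t)), numeric(1))
  expect_equal(unname(bs$weights), oracle, tolerance = 1e-12)
  # a variable equal to t itself has weight 1
  X2 <- cbind(Xs, m$t)
  sm2 <- fit_scaling(X2, "center")
  Xs2 <- apply_scaling(sm2, X2)
  m2 <- opls_fit(Xs2, y, 1)
  bs2 <- backscale_loadings(m2, sm2, Xs2)
  expect_equal(unname(bs2$weights[ncol(X2)]),
               unname(abs(cor(Xs2[, ncol(X2)], m2$t))), tolerance = 1e-12)
})
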