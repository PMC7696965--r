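# Gaussian discriminant classifiers against explicit log-density oracles

test_that("discriminant scores equal Gaussian log-density + log-prior", {
  set.seed(12)
  toy <- toy_gaussian(n_per_class = 25, p = 3, sep = 1.5)
  for (kind in c("linear", "quadratic")) {
    model <- fit_discriminant(toy$X, toy$labels, kind, ridge = 0)
    sc <- discriminant_scores(model, toy$X)
    # oracle: evaluate the multivariate normal log-density directly with
    # solve() and det(), bypassing the model's Cholesky machinery
    for (cl in model$classes) {
      S <- model$covariances[[cl]]
      mu <- model$means[[cl]]
      prior <- model$priors[match(cl, model$classes)]
      dev <- sweep(toy$X, 2, mu)
      ld <- -0.5 * (ncol(toy$X) * log(2 * pi) + log(det(S)) +
                      rowSums((dev %*% solve(S)) * dev)) + log(prior)
      expect_lt(max(abs(sc[, cl] - ld)), 1e-8)
    }
  }
})

test_that("1-D equal-prior LDA thresholds at the midpoint of class means", {
  # equal class sizes and (by pooling) equal covariances: the decision
  # boundary is the midpoint, checked by probing either side of it
  set.seed(3)
  x <- matrix(c(rnorm(30, 0, 1), rnorm(30, 4, 1)), ncol = 1)
  lab <- rep(c("normal", "tumor"), each = 30)
  m <- fit_discriminant(x, lab, "linear")
  mid <- (m$means$normal + m$means$tumor) / 2
  eps <- 1e-6
  expect_equal(as.character(predict_discriminant(m, matrix(mid - eps))),
               "normal")
  expect_equal(as.character(predict_discriminant(m, matrix(mid + eps))),
               "tumor")
})

test_that("degenerate fits are refused", {
  set.seed(5)
  X <- matrix(rnorm(40), 20, 2)
  # same data relabeled: class means coincide, boundary undefined
  expect_error(fit_discriminant(rbind(X, X),
                                rep(c("a", "b"), each = 20), "linear"),
               class = "oralfusion_degenerate_input")
  # singular covariance without ridge
  Xs <- cbind(1:10, 1:10)  # rank 1
  expect_error(fit_discriminant(Xs, rep(c("a", "b"), 5), "linear",
                                ridge = 0),
               class = "oralfusion_singular_covariance")
  expect_error(fit_discriminant(X[1:3, ], c("a", "a", "b"), "linear"),
               class = "oralfusion_invalid_spec")
})

test_that("the linear discriminant boundary is affine in x", {
  set.seed(9)
  toy <- toy_gaussian(n_per_class = 30, p = 4, sep = 2)
  m <- fit_discriminant(toy$X, toy$labels, "linear")
  probes <- matrix(rnorm(40 * 4), 40, 4)
  sc <- discriminant_scores(m, probes)
  d <- sc[, 2] - sc[, 1]
  # recover the affine form from p + 1 probes, predict the rest exactly
  A <- cbind(1, probes[1:5, ])
  coefs <- solve(crossprod(A), crossprod(A, d[1:5]))
  expect_lt(max(abs(cbind(1, probes) %*% coefs - d)), 1e-8)
})

test_that("QDA approaches LDA when class covariances are equal", {
  # both classes drawn from the same covariance; with generous n the fitted
  # per-class covariances converge and the two rules agree almost surely
  set.seed(14)
  n <- 600
  X <- rbind(matrix(rnorm(2 * n), n, 2),
             sweep(matrix(rnorm(2 * n), n, 2), 2, c(2.5, 1), "+"))
  lab <- rep(c("normal", "tumor"), each = n)
  lda <- fit_discriminant(X, lab, "linear")
  qda <- fit_discriminant(X, lab, "quadratic")
  grid <- as.matrix(expand.grid(seq(-3, 5.5, length.out = 40),
                                seq(-3, 4, length.out = 40)))
  agree <- mean(predict_discriminant(lda, grid) ==
                  predict_discriminant(qda, grid))
  expect_gte(agree, 0.99)
})

test_that("both classifiers separate linearly separable toy data perfectly", {
  toy <- toy_gaussian(n_per_class = 20, p = 2, sep = 8)
  for (kind in c("linear", "quadratic")) {
    m <- fit_discriminant(toy$X, toy$labels, kind)
    expect_equal(mean(predict_discriminant(m, toy$X) == toy$labels), 1)
  }
  # prediction at a class mean returns that class
  m <- fit_discriminant(toy$X, toy$labels, "linear")
  expect_equal(as.character(predict_discriminant(m, matrix(m$means$tumor, 1))),
               "tumor")
})

test_that("predictions agree with the reference implementations", {
  skip_if_not_installed("MASS")
  set.seed(20)
  toy <- toy_gaussian(n_per_class = 40, p = 3, sep = 1.2)
  m_lda <- fit_discriminant(toy$X, toy$labels, "linear", ridge = 0)
  r_lda <- MASS::lda(toy$X, toy$labels)
  expect_gte(mean(predict_discriminant(m_lda, toy$X) ==
                    predict(r_lda, toy$X)$class), 0.99)
  m_qda <- fit_discriminant(toy$X, toy$labels, "quadratic", ridge = 0)
  r_qda <- MASS::qda(toy$X, toy$labels)
  expect_gte(mean(predict_discriminant(m_qda, toy$X) ==
                    predict(r_qda, toy$X)$class), 0.99)
})

test_that("fusion concatenates aligned PC scores into 4 features", {
  co <- tiny_cohort(n_patients = 35, seed = 16)
  rfm <- preprocess_cohort(co)
  vfm <- quantify_cohort(co)
  rs <- transform_pca(fit_pca(rfm, 2), rfm)
  vs <- transform_pca(fit_pca(vfm, 2), vfm)
  fused <- fuse_features(rs, vs)
  expect_equal(dim(fused$values), c(70, 4))
  expect_equal(fused$modality, "fused")
  # fusing a matrix with itself duplicates columns
  self <- fuse_features(rs, rs)
  expect_equal(ncol(self$values), 4)
  expect_equal(unname(self$values[, 1]), unname(self$values[, 3]))
  # permuting the second input's rows changes nothing after ID alignment
  perm <- sample(nrow(vs$values))
  vs_perm <- feature_matrix(vs$values[perm, ], vs$labels[perm],
                            vs$sample_ids[perm], "velscope")
  expect_equal(fuse_features(rs, vs_perm)$values, fused$values)
  # mismatched ids are reported
  vs_bad <- feature_matrix(vs$values[-1, ], vs$labels[-1],
                           vs$sample_ids[-1], "velscope")
  expect_error(fuse_features(rs, vs_bad), "P01_normal",
               class = "oralfusion_sample_mismatch")
})
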