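make_sets <- function(ns, d = 4, seed = 1) {
  set.seed(seed)
  lapply(seq_along(ns), function(i) {
    structure(list(vectors = matrix(rnorm(ns[i] * d), ns[i]),
                   centers_px = cbind(seq_len(ns[i]), seq_len(ns[i])),
                   source_id = paste0("s", i), image_dim = c(512L, 512L)),
              class = "descriptor_set")
  })
}

test_that("descriptor subsampling is balanced, saturating and reproducible", {
  sets <- make_sets(c(800, 800, 900, 900))
  labels <- c("low", "low", "high", "high")
  s <- subsample_descriptors(sets, labels, total = 1000, seed = 3)
  expect_equal(nrow(s), 1000)

  s2 <- subsample_descriptors(sets, labels, total = 1000, seed = 3)
  expect_identical(s, s2)
  s3 <- subsample_descriptors(sets, labels, total = 1000, seed = 4)
  expect_false(identical(s, s3))

  # class balance: low rows come first and match rows drawn from sets 1-2
  low_pool <- rbind(sets[[1]]$vectors, sets[[2]]$vectors)
  expect_true(all(s[1:500, 1] %in% low_pool[, 1]))

  sets_sat <- make_sets(c(800, 800, 1300, 1200))
  expect_warning(sat <- subsample_descriptors(sets_sat, labels, total = 4000,
                                              seed = 1),
                 "taking all")
  expect_equal(nrow(sat), 1600 + 2000)
  expect_error(subsample_descriptors(sets, rep("low", 4), total = 100),
               "both label classes")
})

test_that("PCA recovers degenerate geometry and satisfies spectral identities", {
  set.seed(8)
  t_par <- rnorm(100)
  line <- cbind(3 * t_par, 4 * t_par) + 10
  p <- fit_pca(line, 1)
  expect_equal(abs(sum(p$components * c(3, 4) / 5)), 1, tolerance = 1e-8)

  x <- matrix(rnorm(300), 100, 3)
  p3 <- fit_pca(x, 3)
  expect_equal(pca_reconstruct(p3, pca_project(p3, x)), x, tolerance = 1e-8)
  # orthonormal rows, positive largest-magnitude loading
  expect_equal(p3$components %*% t(p3$components), diag(3), tolerance = 1e-6,
               ignore_attr = TRUE)
  for (r in 1:3)
    expect_gt(p3$components[r, which.max(abs(p3$components[r, ]))], 0)
  # explained variance equals the top-k covariance eigenvalues
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  expect_equal(p3$eigenvalues, ev[1:3], tolerance = 1e-10)
  expect_equal(sum(apply(pca_project(p3, x)[, 1:2], 2, var)), sum(ev[1:2]),
               tolerance = 1e-8)

  expect_error(fit_pca(line, 2), "rank")
})

test_that("GMM EM recovers separated components and honours its guarantees", {
  set.seed(13)
  n <- 1000
  x <- rbind(matrix(rnorm(n, -3, 0.5), n / 2),
             matrix(rnorm(n, 3, 0.5), n / 2))
  x <- cbind(x, rnorm(n))
  g <- fit_gmm(x, K = 2, seed = 2)
  mu1 <- sort(g$means[, 1])
  expect_lt(abs(mu1[1] + 3), 0.15)
  expect_lt(abs(mu1[2] - 3), 0.15)
  expect_lt(max(abs(g$weights - 0.5)), 0.05)
  expect_equal(sum(g$weights), 1, tolerance = 1e-9)
  expect_true(all(diff(g$loglik_trace) > -1e-8))

  # K = 1 closed form: sample mean and ML (biased) per-dim variance
  y <- matrix(rnorm(200), 100)
  g1 <- fit_gmm(y, K = 1, seed = 1)
  expect_equal(as.numeric(g1$means), colMeans(y), tolerance = 1e-8)
  expect_equal(as.numeric(g1$variances),
               apply(y, 2, function(v) mean((v - mean(v))^2)),
               tolerance = 1e-6)
})

test_that("IFV matches its closed-form anchors", {
  g1 <- small_gmm(1, matrix(c(0, 0), 1), matrix(c(1, 1), 1))
  v <- encode_ifv(matrix(0, 5, 2), g1)
  expect_equal(v, c(0, 0, -1 / sqrt(2), -1 / sqrt(2)))

  raw <- encode_ifv(matrix(c(0.3, -0.2), 1), g1, normalize = FALSE)
  expect_equal(raw[1:2], c(0.3, -0.2))

  set.seed(4)
  xx <- matrix(rnorm(30), 15)
  g3 <- fit_gmm(matrix(rnorm(200), 100), K = 3, seed = 1)
  expect_equal(encode_ifv(xx, g3), encode_ifv(rbind(xx, xx), g3),
               tolerance = 1e-8)
  expect_equal(sqrt(sum(encode_ifv(xx, g3)^2)), 1, tolerance = 1e-9)
  expect_length(encode_ifv(xx, g3), 2 * 3 * 2)
  expect_error(encode_ifv(matrix(0, 0, 2), g3), "empty")
})

test_that("the fitted encoder produces orderless deterministic 48-dim-style features", {
  set.seed(6)
  sets <- make_sets(c(120, 130, 125, 140, 150, 135), d = 6, seed = 2)
  labels <- rep(c("low", "high"), 3)
  model <- fit_ifv_encoder(sets, labels, pre_components = 3, K = 2,
                           post_components = 4, subsample_total = 400,
                           seed = 9)
  expect_equal(dim(model$train_features), c(6, 4))
  f <- encode_spot(sets[[1]], model)
  expect_length(f, 4)
  perm <- sets[[1]]
  idx <- sample(nrow(perm$vectors))
  perm$vectors <- perm$vectors[idx, ]
  expect_equal(encode_spot(perm, model), f, tolerance = 1e-8)
  expect_equal(encode_spot(sets[[1]], model), f)
  expect_error(encode_spot(sets[[1]], list()), "fitted")

  # structural chain: raw IFV dimension is 2 K d
  expect_equal(length(model$post_pca$mean),
               2 * length(model$gmm$weights) * model$pre_pca$n_components)
})

test_that("cached descriptor sets behave like in-memory sets", {
  sets <- make_sets(c(300, 300), d = 3, seed = 5)
  dir <- tempfile("cache_")
  refs <- lapply(sets, cache_descriptor_set, dir = dir)
  expect_equal(drscore:::fetch_descriptors(refs[[1]]), sets[[1]]$vectors)
  s_mem <- subsample_descriptors(sets, c("low", "high"), 100, seed = 1)
  s_ref <- subsample_descriptors(refs, c("low", "high"), 100, seed = 1)
  expect_identical(s_mem, s_ref)
})
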