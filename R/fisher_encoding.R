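#' Balanced subsampling of training descriptors
#'
#' Draws `total/2` descriptors uniformly at random from the pooled
#' low-risk spots and `total/2` from the pooled high-risk spots, so the
#' unsupervised encoder sees both outcome classes equally. When a class
#' holds fewer descriptors than its half, all of them are taken and a
#' warning is raised.
#'
#' Descriptor sets may be given either as `descriptor_set` objects or as
#' cache references produced by [cache_descriptor_set()], in which case
#' each cached file is loaded at most once.
#'
#' @param sets list of `descriptor_set` objects or cache references.
#' @param labels character vector (`"low"`/`"high"`) aligned with `sets`.
#' @param total total number of descriptors to draw (>= 2).
#' @param seed RNG seed.
#' @return numeric matrix of sampled descriptors (rows).
#' @export
subsample_descriptors <- function(sets, labels, total = 4e6, seed = 1L) {
  stopifnot(length(sets) == length(labels), total >= 2)
  labels <- as.character(labels)
  if (!all(labels %in% c("low", "high")))
    stop("labels must be 'low' or 'high'")
  if (length(unique(labels)) < 2L)
    stop("both label classes must be present for balanced subsampling")
  counts <- vapply(sets, descriptor_count, numeric(1))
  half <- floor(total / 2)
  out <- vector("list", 2L)
  names(out) <- c("low", "high")
  for (cls in c("low", "high")) {
    in_cls <- which(labels == cls)
    n_cls <- sum(counts[in_cls])
    take <- half
    if (n_cls < half) {
      warning(sprintf(
        "class '%s' has only %d descriptors (< %d requested): taking all",
        cls, n_cls, half))
      take <- n_cls
    }
    pick <- with_seed(derive_seed(seed, match(cls, c("low", "high")), 5L),
                      sort(sample.int(n_cls, take)))
    # map pooled indices back to (set, row)
    ends <- cumsum(counts[in_cls])
    starts <- c(0, ends[-length(ends)])
    rows <- vector("list", length(in_cls))
    for (j in seq_along(in_cls)) {
      local_idx <- pick[pick > starts[j] & pick <= ends[j]] - starts[j]
      if (length(local_idx))
        rows[[j]] <- fetch_descriptors(sets[[in_cls[j]]])[local_idx, ,
                                                          drop = FALSE]
    }
    out[[cls]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

descriptor_count <- function(x) {
  if (inherits(x, "descriptor_set")) nrow(x$vectors)
  else if (inherits(x, "descriptor_cache_ref")) x$n
  else stop("not a descriptor set or cache reference")
}

fetch_descriptors <- function(x) {
  if (inherits(x, "descriptor_set")) x$vectors
  else if (inherits(x, "descriptor_cache_ref")) readRDS(x$path)$vectors
  else stop("not a descriptor set or cache reference")
}

#' On-disk descriptor cache
#'
#' Spot descriptor matrices are large; the pipeline caches them one file
#' per spot and streams them back when fitting the encoder, keeping the
#' memory footprint to a single spot at a time.
#'
#' @param dset a `descriptor_set`.
#' @param dir cache directory.
#' @return an object of class `descriptor_cache_ref` (fields `path`,
#'   `n`, `source_id`).
#' @export
cache_descriptor_set <- function(dset, dir) {
  stopifnot(inherits(dset, "descriptor_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0(dset$source_id, "_descriptors.rds"))
  saveRDS(dset, path)
  structure(list(path = path, n = nrow(dset$vectors),
                 source_id = dset$source_id),
            class = "descriptor_cache_ref")
}

#' Fit a PCA model
#'
#' Mean-centred eigendecomposition of the sample covariance, components
#' sorted by decreasing eigenvalue. Sign convention: the
#' largest-magnitude loading of every component is positive, so fitted
#' models are bit-reproducible across platforms. Errors if the data rank
#' is below `n_components`.
#'
#' @param x numeric matrix (rows = observations).
#' @param n_components number of components to keep.
#' @param whiten if `TRUE`, projections are scaled to unit variance per
#'   component.
#' @return object of class `pca_model` (fields `mean`, `components`
#'   (`k x d`, orthonormal rows), `eigenvalues`, `n_components`,
#'   `whiten`).
#' @export
fit_pca <- function(x, n_components, whiten = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < n_components)
    stop("need at least `n_components` rows to fit a PCA")
  mu <- colMeans(x)
  sv <- svd(sweep(x, 2, mu), nu = 0)
  eig <- sv$d^2 / (nrow(x) - 1)
  tol <- max(eig) * 1e-10
  if (sum(eig > tol) < n_components)
    stop(sprintf("data rank (%d) below requested %d components",
                 sum(eig > tol), n_components))
  comp <- t(sv$v[, seq_len(n_components), drop = FALSE])
  flip <- apply(comp, 1, function(r) sign(r[which.max(abs(r))]))
  comp <- comp * flip
  structure(list(mean = mu, components = comp,
                 eigenvalues = eig[seq_len(n_components)],
                 n_components = as.integer(n_components),
                 whiten = isTRUE(whiten)),
            class = "pca_model")
}

#' Project rows into a fitted PCA space
#'
#' @param model a [fit_pca()] model.
#' @param x matrix with the model's input dimension.
#' @return `n x k` matrix of projections.
#' @export
pca_project <- function(model, x) {
  stopifnot(inherits(model, "pca_model"))
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  z <- sweep(x, 2, model$mean) %*% t(model$components)
  if (model$whiten) z <- sweep(z, 2, sqrt(model$eigenvalues), "/")
  z
}

#' Reconstruct from PCA projections
#'
#' @param model a [fit_pca()] model.
#' @param z projected matrix (`n x k`).
#' @return matrix in the original space.
#' @export
pca_reconstruct <- function(model, z) {
  stopifnot(inherits(model, "pca_model"))
  if (model$whiten) z <- sweep(z, 2, sqrt(model$eigenvalues), "*")
  sweep(z %*% model$components, 2, model$mean, "+")
}

# k-means++ seeding: first centre uniform, then each next centre drawn
# with probability proportional to squared distance to the nearest
# chosen centre.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    p <- d2 / sum(d2)
    centers[j, ] <- x[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

# Log density of x under each diagonal Gaussian component: N x K matrix.
gmm_log_component_density <- function(x, means, variances) {
  K <- nrow(means)
  n <- nrow(x)
  out <- matrix(0, n, K)
  x2 <- x^2
  for (k in seq_len(K)) {
    iv <- 1 / variances[k, ]
    const <- -0.5 * sum(log(2 * pi * variances[k, ]))
    out[, k] <- const - 0.5 * (x2 %*% iv - 2 * (x %*% (means[k, ] * iv)) +
                                 sum(means[k, ]^2 * iv))
  }
  out
}

#' Posterior responsibilities under a diagonal GMM
#'
#' @param model a [fit_gmm()] model.
#' @param x matrix in the model's space.
#' @return `N x K` matrix of posteriors, rows summing to one.
#' @export
gmm_posteriors <- function(model, x) {
  stopifnot(inherits(model, "gmm_model"))
  lp <- sweep(gmm_log_component_density(x, model$means, model$variances),
              2, log(model$weights), "+")
  m <- apply(lp, 1, max)
  p <- exp(lp - m)
  p / rowSums(p)
}

gmm_loglik <- function(weights, means, variances, x) {
  lp <- sweep(gmm_log_component_density(x, means, variances), 2,
              log(weights), "+")
  m <- apply(lp, 1, max)
  sum(m + log(rowSums(exp(lp - m))))
}

#' Fit a diagonal-covariance Gaussian mixture model by EM
#'
#' k-means++ initialisation from `seed`, expectation-maximisation with
#' diagonal covariances, convergence when the mean log-likelihood gain
#' per point drops below `tol` (default 1e-5) or after `max_iter`
#' iterations. Per-dimension variances are floored at `1e-4` times the
#' sample variance of that dimension. A component that collapses to
#' (numerically) zero responsibility is re-seeded at the point with the
#' lowest model likelihood (the "farthest" point) and EM continues.
#'
#' @param x numeric matrix (rows = observations, already in PCA space).
#' @param K number of mixture components.
#' @param seed RNG seed for the initialisation.
#' @param max_iter iteration cap.
#' @param tol per-point log-likelihood convergence tolerance.
#' @param var_floor_frac variance floor as a fraction of the sample
#'   variance.
#' @return object of class `gmm_model` (fields `weights`, `means`
#'   (`K x d`), `variances` (`K x d`), `loglik`, `loglik_trace`, `n_iter`,
#'   `converged`).
#' @export
fit_gmm <- function(x, K = 64L, seed = 1L, max_iter = 200L, tol = 1e-5,
                    var_floor_frac = 1e-4) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n < K) stop("need at least K observations")
  floor_vec <- pmax(var_floor_frac * apply(x, 2, var), 1e-12)
  with_seed(derive_seed(seed, K, 6L), {
    means <- kmeanspp_centers(x, K)
    # hard-assignment initial parameters
    d2 <- vapply(seq_len(K), function(k) rowSums(sweep(x, 2, means[k, ])^2),
                 numeric(n))
    assign0 <- max.col(-d2, ties.method = "first")
    weights <- tabulate(assign0, K) / n
    weights[weights == 0] <- 1 / n
    weights <- weights / sum(weights)
    variances <- matrix(rep(apply(x, 2, var), each = K), K, d)
    for (k in seq_len(K)) {
      rows <- which(assign0 == k)
      if (length(rows) > 1)
        variances[k, ] <- pmax(apply(x[rows, , drop = FALSE], 2, var),
                               floor_vec)
    }
    variances[!is.finite(variances)] <- 1
    ll_old <- -Inf
    ll_trace <- numeric()
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      lp <- sweep(gmm_log_component_density(x, means, variances), 2,
                  log(weights), "+")
      m <- apply(lp, 1, max)
      pe <- exp(lp - m)
      rs <- rowSums(pe)
      ll <- sum(m + log(rs))
      ll_trace <- c(ll_trace, ll)
      gamma <- pe / rs
      nk <- colSums(gamma)
      dead <- which(nk < 1e-8)
      if (length(dead)) {
        # re-seed collapsed components at the worst-modelled points
        point_ll <- m + log(rs)
        far <- order(point_ll)[seq_along(dead)]
        for (q in seq_along(dead)) {
          k <- dead[q]
          means[k, ] <- x[far[q], ]
          variances[k, ] <- pmax(apply(x, 2, var), floor_vec)
          weights[k] <- 1 / n
        }
        weights <- weights / sum(weights)
        message(sprintf("fit_gmm: re-seeded %d empty component(s) at iteration %d",
                        length(dead), iter))
        ll_old <- -Inf
        next
      }
      means <- (t(gamma) %*% x) / nk
      ex2 <- (t(gamma) %*% (x^2)) / nk
      variances <- sweep(pmax(ex2 - means^2, 0), 2, floor_vec, pmax)
      weights <- nk / n
      if (is.finite(ll_old) && (ll - ll_old) / n < tol) {
        converged <- TRUE
        ll_old <- ll
        break
      }
      ll_old <- ll
    }
    structure(list(weights = as.numeric(weights), means = means,
                   variances = variances,
                   loglik = gmm_loglik(weights, means, variances, x),
                   loglik_trace = ll_trace,
                   n_iter = iter, converged = converged),
              class = "gmm_model")
  })
}

#' Improved Fisher vector encoding of a descriptor matrix
#'
#' Aggregates `N` descriptors into the gradient of the diagonal-GMM
#' log-likelihood with respect to the component means and standard
#' deviations. With posteriors `gamma_k(x_i)`, the mean block of
#' component `k` is `1/(N sqrt(w_k)) * sum_i gamma_k(x_i) (x_i - mu_k) /
#' sigma_k` and the variance block is `1/(N sqrt(2 w_k)) * sum_i
#' gamma_k(x_i) [((x_i - mu_k)/sigma_k)^2 - 1]`; blocks are concatenated
#' over components (all mean blocks, then all variance blocks). The
#' "improved" part applies the signed square root
#' (`sign(z) sqrt(|z|)`) per coordinate followed by global L2
#' normalisation; an all-zero vector is returned unchanged.
#'
#' @param x `N x d` descriptor matrix in the GMM's space, `N >= 1`.
#' @param gmm a [fit_gmm()] model.
#' @param normalize apply signed square root + L2 normalisation
#'   (default `TRUE`; `FALSE` gives the raw Fisher gradients).
#' @return numeric vector of length `2 K d`.
#' @export
encode_ifv <- function(x, gmm, normalize = TRUE) {
  stopifnot(inherits(gmm, "gmm_model"))
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  n <- nrow(x)
  if (n < 1L) stop("cannot encode an empty descriptor set")
  K <- nrow(gmm$means); d <- ncol(gmm$means)
  gamma <- gmm_posteriors(gmm, x)                    # N x K
  s0 <- colSums(gamma)                               # K
  s1 <- t(gamma) %*% x                               # K x d
  s2 <- t(gamma) %*% (x^2)                           # K x d
  sigma <- sqrt(gmm$variances)
  g_mu <- (s1 - gmm$means * s0) / sigma /
    (n * sqrt(gmm$weights))
  g_sig <- ((s2 - 2 * gmm$means * s1 + gmm$means^2 * s0) / gmm$variances -
              s0) / (n * sqrt(2 * gmm$weights))
  v <- c(t(g_mu), t(g_sig))   # mean blocks k = 1..K, then variance blocks
  if (normalize) {
    v <- sign(v) * sqrt(abs(v))
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
  }
  v
}

#' Fit the full IFV encoder stack
#'
#' Balanced descriptor subsample -> PCA compression of descriptors
#' (512 -> 16 by default) -> diagonal GMM (64 components by default) ->
#' IFV encoding of every training spot -> PCA compression of the IFVs
#' (-> 48 by default). The post-encoding PCA is fitted on training-set
#' IFVs only, so no test information leaks into the model.
#'
#' @param sets list of `descriptor_set`s or cache references (training
#'   spots).
#' @param labels `"low"`/`"high"` per spot (training risk labels).
#' @param pre_components descriptor PCA dimension d.
#' @param K GMM components.
#' @param post_components output feature dimension.
#' @param subsample_total descriptors drawn for the unsupervised fit.
#' @param seed RNG seed.
#' @param whiten whiten the descriptor PCA.
#' @return object of class `ifv_encoder_model` with elements `pre_pca`,
#'   `gmm`, `post_pca` and `train_features` (matrix of encoded training
#'   spots, rownames = source ids).
#' @export
fit_ifv_encoder <- function(sets, labels, pre_components = 16L, K = 64L,
                            post_components = 48L, subsample_total = 4e6,
                            seed = 1L, whiten = FALSE) {
  sample_mat <- subsample_descriptors(sets, labels, subsample_total, seed)
  pre_pca <- fit_pca(sample_mat, pre_components, whiten = whiten)
  gmm <- fit_gmm(pca_project(pre_pca, sample_mat), K = K, seed = seed)
  ifv <- t(vapply(sets, function(s) {
    encode_ifv(pca_project(pre_pca, fetch_descriptors(s)), gmm)
  }, numeric(2L * K * pre_components)))
  rownames(ifv) <- vapply(sets, function(s) s$source_id, character(1))
  post_pca <- fit_pca(ifv, post_components)
  model <- structure(list(pre_pca = pre_pca, gmm = gmm, post_pca = post_pca),
                     class = "ifv_encoder_model")
  model$train_features <- pca_project(post_pca, ifv)
  rownames(model$train_features) <- rownames(ifv)
  model
}

#' @export
print.ifv_encoder_model <- function(x, ...) {
  cat(sprintf(
    "<ifv_encoder_model> %d -> %d (PCA) -> IFV(K = %d, dim %d) -> %d (PCA)\n",
    length(x$pre_pca$mean), x$pre_pca$n_components, length(x$gmm$weights),
    2L * length(x$gmm$weights) * x$pre_pca$n_components,
    x$post_pca$n_components))
  invisible(x)
}

#' Encode one spot with a fitted IFV encoder
#'
#' @param descriptors a `descriptor_set`, cache reference, or raw `N x D`
#'   matrix of foreground descriptors.
#' @param model a fitted [fit_ifv_encoder()] model.
#' @return numeric feature vector (length `post_components`).
#' @export
encode_spot <- function(descriptors, model) {
  if (!inherits(model, "ifv_encoder_model"))
    stop("`model` must be a fitted ifv_encoder_model")
  x <- if (is.matrix(descriptors)) descriptors
       else fetch_descriptors(descriptors)
  if (nrow(x) == 0L)
    stop("empty descriptor set: spot must pass the area criterion upstream")
  ifv <- encode_ifv(pca_project(model$pre_pca, x), model$gmm)
  as.numeric(pca_project(model$post_pca, matrix(ifv, nrow = 1L)))
}
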