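# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals.

# Otsu: exhaustive search over the 256 candidate bin-edge thresholds,
# scoring each candidate from the actual pixel partition (bin-centre
# values, matching the histogram formulation).
oracle_otsu_threshold <- function(x, n_bins = 256L) {
  lo <- min(x); hi <- max(x)
  bin <- pmin(floor((x - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  cen <- lo + (bin - 0.5) * (hi - lo) / n_bins
  edges <- lo + seq_len(n_bins - 1L) * (hi - lo) / n_bins
  best <- -Inf; best_thr <- NA_real_
  for (thr in edges) {
    below <- x <= thr
    if (!any(below) || all(below)) next
    w0 <- mean(below)
    v <- w0 * (1 - w0) * (mean(cen[below]) - mean(cen[!below]))^2
    if (v > best + 1e-15) { best <- v; best_thr <- thr }
  }
  best_thr
}

# Harrell's C: explicit double loop over all pairs.
oracle_cindex <- function(s, t, e) {
  num <- 0; den <- 0
  n <- length(s)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (t[i] == t[j]) next
    short <- if (t[i] < t[j]) i else j
    long <- if (t[i] < t[j]) j else i
    if (e[short] == 0) next
    den <- den + 1
    num <- num + if (s[short] > s[long]) 1
                 else if (s[short] == s[long]) 0.5 else 0
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Kaplan-Meier: direct product over risk sets at each distinct event time.
oracle_km <- function(t, e) {
  times <- sort(unique(t[e == 1]))
  surv <- numeric(length(times))
  s <- 1
  for (q in seq_along(times)) {
    at_risk <- sum(t >= times[q])
    d <- sum(t == times[q] & e == 1)
    s <- s * (1 - d / at_risk)
    surv[q] <- s
  }
  list(times = times, surv = surv)
}

# Two-group log-rank chi-square, written out from observed-vs-expected
# event counts over the shared risk sets (for the permutation oracle).
oracle_logrank_chisq <- function(t, e, g) {
  times <- sort(unique(t[e == 1]))
  o_minus_e <- 0; v <- 0
  for (tt in times) {
    at_risk <- t >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(t == tt & e == 1); d1 <- sum(t == tt & e == 1 & g == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Naive two-loop improved Fisher vector.
oracle_ifv <- function(x, gmm) {
  N <- nrow(x); K <- nrow(gmm$means); d <- ncol(x)
  gam <- matrix(0, N, K)
  for (i in seq_len(N)) {
    lg <- vapply(seq_len(K), function(k)
      log(gmm$weights[k]) + sum(stats::dnorm(x[i, ], gmm$means[k, ],
                                             sqrt(gmm$variances[k, ]),
                                             log = TRUE)), numeric(1))
    gam[i, ] <- exp(lg - max(lg))
    gam[i, ] <- gam[i, ] / sum(gam[i, ])
  }
  gm <- c(); gs <- c()
  for (k in seq_len(K)) {
    mu <- gmm$means[k, ]; sg <- sqrt(gmm$variances[k, ])
    w <- gmm$weights[k]
    m <- rep(0, d); s <- rep(0, d)
    for (i in seq_len(N)) {
      m <- m + gam[i, k] * (x[i, ] - mu) / sg
      s <- s + gam[i, k] * (((x[i, ] - mu) / sg)^2 - 1)
    }
    gm <- c(gm, m / (N * sqrt(w)))
    gs <- c(gs, s / (N * sqrt(2 * w)))
  }
  v <- c(gm, gs)
  v <- sign(v) * sqrt(abs(v))
  nr <- sqrt(sum(v^2))
  if (nr > 0) v <- v / nr
  v
}

# Mann-Whitney AUC by explicit pair enumeration.
oracle_auc <- function(s, y) {
  pos <- s[y]; neg <- s[!y]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Shared scaled-down pipeline settings for small synthetic cohorts
# (64-512 px spots; the area thresholds scale with the smaller discs).
small_params <- function(image_size, seed = 1L, K = 8L, pre = 8L,
                         post = 8L, subsample = 4000) {
  disc_px <- pi * (0.42 * image_size)^2
  drs_params(pre_components = pre, K = K, post_components = post,
             subsample_total = subsample,
             min_area_mm2 = 0.3 * disc_px * (0.22 / 1000)^2,
             min_object_px = round(disc_px / 5),
             seed = seed)
}

small_gmm <- function(weights, means, variances) {
  structure(list(weights = weights, means = means, variances = variances),
            class = "gmm_model")
}
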