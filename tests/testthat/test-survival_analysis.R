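test_that("DSS and OS endpoints encode cause and censoring correctly", {
  cl <- data.frame(
    patient_id = c("a", "b", "c"),
    followup_years = c(4, 4, 16),
    cause = c("breast_cancer_death", "other_death", "alive"))
  dss <- build_dss(cl)
  expect_equal(dss$time_years, c(4, 4, 16))
  expect_equal(dss$event, c(1L, 0L, 0L))
  os <- build_os(cl)
  expect_equal(os$event, c(1L, 1L, 0L))
  # OS events are a superset of DSS events
  set.seed(9)
  cl2 <- generate_cohort(cohort_config(n_patients = 80, seed = 3),
                         images = "none")$clinical
  expect_gte(sum(build_os(cl2)$event), sum(build_dss(cl2)$event))
})

test_that("Kaplan-Meier matches the hand product-limit and the risk-set oracle", {
  km <- km_estimate(endpoints(c(1, 2, 3), c(1L, 0L, 1L)))
  expect_equal(km$event_times, c(1, 3))
  expect_equal(km$survival, c(2 / 3, 0))
  expect_true(all(diff(km$survival) <= 0))

  flat <- km_estimate(endpoints(c(1, 2, 3), c(0L, 0L, 0L)))
  expect_length(flat$event_times, 0)
  expect_equal(survival_at(flat, 10)$estimate, 1)

  set.seed(17)
  for (r in 1:20) {
    n <- sample(4:15, 1)
    t <- sample(1:8, n, TRUE) + 0.5
    e <- rbinom(n, 1, 0.6)
    if (sum(e) == 0) e[1] <- 1L
    km_r <- km_estimate(endpoints(t, e))
    orc <- oracle_km(t, e)
    expect_equal(km_r$event_times, orc$times)
    expect_equal(km_r$survival, orc$surv, tolerance = 1e-12)
  }

  # invariance to input order within ties
  t <- c(2, 2, 2, 5, 5, 7)
  e <- c(1L, 0L, 1L, 0L, 1L, 0L)
  p <- sample(6)
  expect_equal(km_estimate(endpoints(t, e))$survival,
               km_estimate(endpoints(t[p], e[p]))$survival)
})

test_that("survival_at reads the step function with its CI", {
  km <- km_estimate(endpoints(c(1, 2, 3), c(1L, 0L, 1L)))
  expect_equal(survival_at(km, 0)$estimate, 1)
  expect_equal(survival_at(km, 2.5)$estimate, 2 / 3)
  expect_equal(survival_at(km, 100)$estimate, 0)
  s <- survival_at(km, 2.5)
  expect_lte(s$lower, s$estimate)
  expect_gte(s$upper, s$estimate)
})

test_that("log-rank test: symmetry null, strong separation, permutation oracle", {
  ep_same <- endpoints(rep(c(1, 2, 3, 4), 2), rep(c(1L, 1L, 0L, 1L), 2))
  g <- rep(c(0, 1), each = 4)
  lr <- logrank_test(ep_same, g)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)

  # all group-A events strictly before any group-B event
  ep_sep <- endpoints(c(1:20 / 10, 3 + 1:20 / 10),
                      rep(1L, 40))
  lr2 <- logrank_test(ep_sep, rep(c("A", "B"), each = 20))
  expect_lt(lr2$p_value, 0.001)

  expect_error(logrank_test(ep_same, rep(0, 8)), "two non-empty")

  set.seed(23)
  t <- rexp(20); e <- rbinom(20, 1, 0.8); grp <- rep(c(0, 1), 10)
  if (sum(e) == 0) e[1] <- 1L
  obs <- logrank_test(endpoints(t, e), grp)
  perm_stat <- replicate(10000,
    oracle_logrank_chisq(t, e, sample(grp)))
  p_perm <- mean(perm_stat >= obs$chisq - 1e-12)
  expect_lt(abs(obs$p_value - p_perm), 0.03)
})

test_that("Cox fit recovers a known hazard ratio and rejects bad input", {
  set.seed(31)
  n <- 1000
  z <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.08 * 2^z)
  cens <- pmin(rexp(n, 0.03), 20)
  ep <- endpoints(pmax(pmin(t_ev, cens), 1e-3),
                  as.integer(t_ev <= cens))
  fit <- cox_fit(ep, data.frame(z = z))
  expect_lt(abs(fit$coefficients[["z"]] - log(2)), 3 * fit$se[["z"]])
  expect_equal(fit$hazard_ratios, exp(fit$coefficients), tolerance = 1e-12)
  expect_true(all(fit$ci95[, 1] <= fit$ci95[, 2]))

  expect_error(cox_fit(ep, data.frame(z = rep(0, n))), "constant")
  expect_error(cox_fit(endpoints(1:3, c(1L, 1L, 0L)),
                       data.frame(a = 1:3, b = 3:1, c = c(1, 3, 2))),
               "more observations")
})

test_that("Cox null p-values are uniform", {
  set.seed(41)
  pvals <- replicate(200, {
    n <- 60
    t <- rexp(n, 0.1); e <- rbinom(n, 1, 0.8)
    if (sum(e) < 2) e[1:2] <- 1L
    cox_fit(endpoints(t, e), data.frame(z = rnorm(n)))$p_values[[1]]
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("Cox score test at beta = 0 equals the log-rank statistic", {
  set.seed(53)
  for (r in 1:5) {
    n <- 30
    t <- rexp(n)                       # continuous: no ties
    e <- rbinom(n, 1, 0.7)
    if (sum(e) < 2) e[1:2] <- 1L
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2) g[1:2] <- c(0, 1)
    sc <- survival::coxph(survival::Surv(t, e) ~ g)$score
    lr <- logrank_test(endpoints(t, e), g)$chisq
    expect_equal(sc, lr, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("concordance index matches the all-pairs oracle and its symmetries", {
  ep <- endpoints(c(5, 4, 3, 2, 1), rep(1L, 5))
  expect_equal(concordance_index(1:5, ep), 1)
  expect_equal(concordance_index(rep(2, 5), ep), 0.5)

  set.seed(61)
  for (r in 1:20) {
    n <- sample(5:30, 1)
    t <- round(rexp(n), 1) + 0.05
    e <- rbinom(n, 1, 0.7)
    if (sum(e) == 0) e[1] <- 1L
    s <- sample(1:5, n, TRUE)
    expect_equal(concordance_index(s, endpoints(t, e)),
                 oracle_cindex(s, t, e))
  }
  # C(s) = 1 - C(-s) when scores are tie-free
  t <- rexp(25); e <- rbinom(25, 1, 0.8); s <- rnorm(25)
  if (sum(e) == 0) e[1] <- 1L
  expect_equal(concordance_index(s, endpoints(t, e)),
               1 - concordance_index(-s, endpoints(t, e)))

  expect_error(concordance_index(1:3, endpoints(1:3, c(0L, 0L, 0L))),
               "one event")
})

test_that("bootstrap C-index CI brackets the point estimate", {
  set.seed(71)
  t <- rexp(60); e <- rbinom(60, 1, 0.7); s <- -t + rnorm(60, 0, 0.5)
  ci <- cindex_bootstrap_ci(s, endpoints(t, e), n_boot = 300, seed = 2)
  expect_lte(ci$lower, ci$estimate)
  expect_gte(ci$upper, ci$estimate)
})

test_that("nested Cox models compare by likelihood ratio", {
  set.seed(83)
  n <- 500
  z <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.05 * 3^z)
  e <- rep(1L, n)
  ep <- endpoints(t, e)
  covs <- data.frame(z = z, noise = rnorm(n))
  fit_z <- cox_fit(ep, covs["z"])
  fit_full <- cox_fit(ep, covs)
  fit_noise <- cox_fit(ep, covs["noise"])

  same <- compare_models_lrt(fit_z, fit_z)
  expect_equal(same$chisq, 0)
  expect_equal(same$p_value, 1)

  strong <- compare_models_lrt(fit_noise, cox_fit(ep, covs))
  expect_lt(strong$p_value, 0.001)

  expect_error(compare_models_lrt(fit_full, fit_z), "subset")

  # adding pure noise gives uniform p-values
  set.seed(97)
  pvals <- replicate(200, {
    m <- 60
    tt <- rexp(m, 0.1); ee <- rbinom(m, 1, 0.8)
    if (sum(ee) < 2) ee[1:2] <- 1L
    epp <- endpoints(tt, ee)
    zz <- rnorm(m)
    compare_models_lrt(cox_fit(epp, data.frame(z = zz)),
                       cox_fit(epp, data.frame(z = zz,
                                               u = rnorm(m))))$p_value
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("proportionality check flags a covariate with a time-varying effect", {
  set.seed(101)
  n <- 400
  z <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.1 * 2^z)
  fit <- cox_fit(endpoints(t, rep(1L, n)), data.frame(z = z))
  tab <- check_proportionality(fit)
  expect_true(is.data.frame(tab))
  expect_true(all(c("term", "p_value", "violates") %in% names(tab)))
  expect_false(tab$violates[1])  # proportional by construction
})
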