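mk_scores <- function(...) rater_scores(rbind(...))

test_that("not-evaluable exclusion removes any spot with at least one such call", {
  sc <- mk_scores(c("low", "high", "low"),
                  c("low", "not_evaluable", "high"),
                  c("high", "high", "high"),
                  c("not_evaluable", "not_evaluable", "not_evaluable"))
  ex <- exclude_not_evaluable(sc)
  expect_equal(ex$n_excluded, 2)
  expect_equal(ex$n_evaluable, 2)
  expect_equal(ex$n_evaluable + ex$n_excluded, nrow(sc))
  expect_equal(nrow(ex$evaluable), 2)
})

test_that("majority vote follows 2-of-3 and is order invariant", {
  expect_equal(majority_vote(c("high", "high", "low")), "high")
  expect_equal(majority_vote(c("low", "low", "low")), "low")
  expect_equal(majority_vote(c("high", "low", "high")), "high")
  for (r in 1:5) {
    calls <- sample(c("high", "high", "low"))
    expect_equal(majority_vote(calls), "high")
  }
  expect_error(majority_vote(c("high", "low")), "odd")
  expect_error(majority_vote(c("high", "not_evaluable", "low")), "evaluable")
})

test_that("percent agreement: unanimous default, closed-form null, pairwise collapse", {
  sc <- mk_scores(c("low", "low", "low"),
                  c("high", "high", "high"),
                  c("low", "high", "low"))
  expect_equal(percent_agreement(sc), 2 / 3)
  expect_equal(percent_agreement(sc[1:2, , drop = FALSE] |> rater_scores()),
               1)

  # three independent uniform raters agree unanimously with prob 1/4
  set.seed(3)
  big <- rater_scores(matrix(sample(c("low", "high"), 3 * 20000, TRUE),
                             ncol = 3))
  expect_lt(abs(percent_agreement(big) - 0.25), 0.02)

  two <- mk_scores(c("low", "low"), c("low", "high"), c("high", "high"),
                   c("high", "low"))
  expect_equal(percent_agreement(two, mode = "pairwise"),
               mean(two[, 1] == two[, 2]))
})

test_that("Cohen's kappa matches hand-computed tables and is symmetric", {
  a <- rep(c("low", "high"), 25)
  expect_equal(cohens_kappa(a, a)$kappa, 1)

  # 2x2 table [[25,25],[25,25]]: independence
  b25 <- c(rep("low", 25), rep("high", 25), rep("low", 25), rep("high", 25))
  a25 <- c(rep("low", 50), rep("high", 50))
  expect_equal(cohens_kappa(a25, b25)$kappa, 0)

  # 2x2 table [[40,10],[10,40]]: p_o = 0.8, p_e = 0.5, kappa = 0.6
  a40 <- c(rep("low", 50), rep("high", 50))
  b40 <- c(rep("low", 40), rep("high", 10), rep("low", 10), rep("high", 40))
  k <- cohens_kappa(a40, b40)
  expect_equal(k$kappa, 0.6)
  expect_equal(k$p_observed, 0.8)
  expect_equal(k$p_expected, 0.5)
  expect_lt(k$p_value, 0.001)

  k_ab <- cohens_kappa(a40, b40)$kappa
  k_ba <- cohens_kappa(b40, a40)$kappa
  expect_equal(k_ab, k_ba)
  expect_lte(k_ab, 1)

  expect_error(cohens_kappa(rep("low", 10), rep("low", 10)), "degenerate")
})

test_that("association tests dispatch to chi-square and Kruskal-Wallis", {
  flat <- association_tests(rep(c("a", "b"), each = 20),
                            rep(c("x", "y"), 20))
  expect_equal(flat$method, "chi_square")
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  # [[30,10],[10,30]]: all expected counts 20, statistic = 4 * 100/20 = 20
  a <- c(rep("r1", 40), rep("r2", 40))
  b <- c(rep("c1", 30), rep("c2", 10), rep("c1", 10), rep("c2", 30))
  chi <- association_tests(a, b)
  hand <- sum((abs(table(a, b) - 20))^2 / 20)
  expect_equal(chi$statistic, hand)
  expect_equal(chi$statistic, 20)

  kw <- association_tests(c(rnorm(10), rnorm(10)),
                          rep(c("g1", "g2"), each = 10))
  expect_equal(kw$method, "kruskal_wallis")
  same <- association_tests(rep(1:5, 2), rep(c("g1", "g2"), each = 5))
  expect_equal(same$statistic, 0, tolerance = 1e-12)

  expect_error(association_tests(rnorm(5), rnorm(5)), "categorical")
})

test_that("kappa test holds its nominal size under independent raters", {
  set.seed(5)
  rej <- mean(replicate(200, {
    a <- sample(c("low", "high"), 100, TRUE)
    b <- sample(c("low", "high"), 100, TRUE)
    cohens_kappa(a, b)$p_value < 0.05
  }))
  expect_gte(rej, 0.01)
  expect_lte(rej, 0.10)
})
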