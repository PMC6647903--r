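test_that("spot images are deterministic and carry a tissue disc", {
  a <- generate_spot_image(latent_score = 0, image_size = 96, seed = 7)
  b <- generate_spot_image(latent_score = 0, image_size = 96, seed = 7)
  expect_identical(a$pixels, b$pixels)
  expect_gt(sum(attr(a, "truth")$disc_mask), 0)
  # segmentation finds tissue on the default texture
  fg <- compute_foreground(a, min_object_px = 500L)
  expect_gt(fg$area_pixels, 0)
  expect_error(generate_spot_image(image_size = 32), "at least 64")
})

test_that("blob count increases with the latent score", {
  counts <- sapply(c(-2, 2), function(z) {
    mean(sapply(1:50, function(s) {
      img <- generate_spot_image(latent_score = z, image_size = 96, seed = s)
      # independent connected-component count on the pre-noise blob mask
      lab <- drscore:::label_components_cpp(attr(img, "truth")$blob_mask, 8L)
      max(lab)
    }))
  })
  expect_gt(counts[2], counts[1])
})

test_that("survival times follow the configured exponential model", {
  cfg <- cohort_config(n_patients = 2, effect_size_beta = 0,
                       baseline_rate = 0.25, other_cause_rate = 0,
                       admin_censor_years = Inf)
  n <- 2000
  times <- vapply(seq_len(n), function(i)
    simulate_survival(0, cfg, seed = i)$followup_years, numeric(1))
  se <- (1 / 0.25) / sqrt(n)
  expect_lt(abs(mean(times) - 1 / 0.25), 3 * se)

  cfg0 <- cohort_config(n_patients = 2, baseline_rate = 0,
                        other_cause_rate = 0, admin_censor_years = 16)
  rec <- lapply(1:50, function(i) simulate_survival(1, cfg0, seed = i))
  expect_true(all(vapply(rec, `[[`, character(1), "cause") == "alive"))
  expect_true(all(vapply(rec, `[[`, numeric(1), "followup_years") == 16))

  expect_error(cohort_config(n_patients = 10, baseline_rate = -1),
               "non-negative")
})

test_that("a Cox fit recovers the simulated log-hazard ratio", {
  cfg <- cohort_config(n_patients = 1000, effect_size_beta = log(2),
                       baseline_rate = 0.05, other_cause_rate = 0.01,
                       latent_mode = "continuous", seed = 31)
  co <- generate_cohort(cfg, images = "none")
  fit <- cox_fit(build_dss(co$clinical),
                 data.frame(z = co$clinical$latent_score))
  expect_lt(abs(fit$coefficients[["z"]] - log(2)), 3 * fit$se[["z"]])
})

test_that("cohorts are reproducible and internally consistent", {
  cfg <- cohort_config(n_patients = 10, image_size = 64, seed = 5)
  a <- generate_cohort(cfg, images = "memory")
  b <- generate_cohort(cfg, images = "memory")
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$image_list[["P0003"]]$pixels,
                   b$image_list[["P0003"]]$pixels)
  expect_equal(nrow(a$clinical), 10)
  expect_equal(length(a$image_list), 10)
  expect_identical(names(a$image_list), a$clinical$patient_id)
  expect_true(all(a$clinical$followup_years <= cfg$admin_censor_years))
  expect_true(all(a$clinical$cause %in%
                    c("breast_cancer_death", "other_death", "alive")))
  # lazy provider regenerates the identical image
  expect_identical(a$image_fun("P0003")$pixels,
                   a$image_list[["P0003"]]$pixels)
})

test_that("clinical CSV round-trips", {
  cfg <- cohort_config(n_patients = 8, seed = 2)
  co <- generate_cohort(cfg, images = "none")
  path <- tempfile(fileext = ".csv")
  write_clinical_csv(co$clinical, path)
  back <- read_clinical_csv(path)
  expect_equal(back$patient_id, co$clinical$patient_id)
  expect_equal(back$followup_years, co$clinical$followup_years)
})

test_that("ground-truth discrimination never degrades as the effect grows", {
  grid <- c(0, 0.6, 1.2)
  mean_c <- vapply(grid, function(beta) {
    mean(vapply(1:50, function(r) {
      cfg <- cohort_config(n_patients = 150, effect_size_beta = beta,
                           baseline_rate = 0.05, seed = 1000 * beta + r)
      cl <- generate_cohort(cfg, images = "none")$clinical
      concordance_index(cl$latent_score, build_dss(cl))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_c) > -0.01))
  expect_gt(mean_c[3], mean_c[1])
})
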