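#' Texture parameters for synthetic spot images
#'
#' The synthetic spot emulates an H&E-stained TMA core at a coarse level:
#' a roughly circular tissue disc in a pink-ish matrix colour on a
#' near-white background, filled with dark nucleus-like elliptical blobs.
#' The blob density carries the image signal: the expected blob count
#' interpolates between `blob_density_range[1]` and
#' `blob_density_range[2]` (counts per 512 px spot, scaled with image
#' area) through a logistic function of the latent score.
#'
#' @param blob_density_range expected blob counts per 512-px spot for
#'   latent scores of -Inf / +Inf.
#' @param blob_radius_range_px blob semi-axis range in pixels.
#' @param stain_dark RGB colour of blobs (haematoxylin-like).
#' @param matrix_col RGB colour of the tissue matrix (eosin-like).
#' @param background background grey level.
#' @param disc_radius_frac tissue disc radius as a fraction of image side.
#' @param noise_sd per-pixel Gaussian colour noise standard deviation.
#' @param texture_gain slope of the logistic mapping latent score to
#'   blob density.
#' @return list of class `texture_params`.
#' @export
texture_params <- function(blob_density_range = c(150, 600),
                           blob_radius_range_px = c(2, 5),
                           stain_dark = c(0.36, 0.28, 0.55),
                           matrix_col = c(0.91, 0.74, 0.82),
                           background = 0.97,
                           disc_radius_frac = 0.42,
                           noise_sd = 0.02,
                           texture_gain = 1) {
  stopifnot(length(blob_density_range) == 2L, all(blob_density_range >= 0),
            length(blob_radius_range_px) == 2L,
            all(blob_radius_range_px > 0),
            length(stain_dark) == 3L, length(matrix_col) == 3L,
            background >= 0, background <= 1,
            disc_radius_frac > 0, disc_radius_frac < 0.5,
            noise_sd >= 0, texture_gain > 0)
  structure(list(blob_density_range = blob_density_range,
                 blob_radius_range_px = blob_radius_range_px,
                 stain_dark = stain_dark, matrix_col = matrix_col,
                 background = background,
                 disc_radius_frac = disc_radius_frac,
                 noise_sd = noise_sd, texture_gain = texture_gain),
            class = "texture_params")
}

#' Configuration of a synthetic cohort
#'
#' Defines the survival model and imaging parameters of a simulated
#' cohort. Breast-cancer death times are exponential with rate
#' `baseline_rate * exp(effect_size_beta * latent_score)`, other-cause
#' death times exponential with rate `other_cause_rate`, and follow-up is
#' administratively censored at `admin_censor_years` (16 years by
#' default, matching a cohort whose median follow-up approaches that
#' horizon). The latent score is the ground-truth image covariate: in
#' `"binary"` mode it is -1 (low texture class) or +1 (high) with equal
#' probability; `"continuous"` mode draws a standard normal score for
#' coefficient-recovery experiments.
#'
#' @param n_patients cohort size (>= 2).
#' @param image_size image side in pixels (>= 64); 512 by default.
#' @param pixel_size_um physical pixel size (0.22 um by default).
#' @param effect_size_beta log-hazard increase per unit latent score. The
#'   default `log(2.1)/2` makes the hazard ratio between the binary
#'   classes 2.1.
#' @param baseline_rate breast-cancer death rate (events/year) at latent
#'   score 0.
#' @param other_cause_rate competing other-cause death rate (events/year).
#' @param admin_censor_years administrative censoring horizon; may be `Inf`.
#' @param texture non-image parameters, see [texture_params()].
#' @param latent_mode `"binary"` or `"continuous"`.
#' @param seed master seed; the whole cohort is a pure function of the
#'   configuration including this seed.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 400L,
                          image_size = 512L,
                          pixel_size_um = 0.22,
                          effect_size_beta = log(2.1) / 2,
                          baseline_rate = 0.04,
                          other_cause_rate = 0.02,
                          admin_censor_years = 16,
                          texture = texture_params(),
                          latent_mode = c("binary", "continuous"),
                          seed = 1L) {
  latent_mode <- match.arg(latent_mode)
  if (n_patients < 2L) stop("`n_patients` must be at least 2")
  if (image_size < 64L) stop("`image_size` must be at least 64 pixels")
  if (baseline_rate < 0 || other_cause_rate < 0)
    stop("event rates must be non-negative")
  if (admin_censor_years <= 0) stop("`admin_censor_years` must be positive")
  stopifnot(inherits(texture, "texture_params"), pixel_size_um > 0)
  structure(list(n_patients = as.integer(n_patients),
                 image_size = as.integer(image_size),
                 pixel_size_um = pixel_size_um,
                 effect_size_beta = effect_size_beta,
                 baseline_rate = baseline_rate,
                 other_cause_rate = other_cause_rate,
                 admin_censor_years = admin_censor_years,
                 texture = texture,
                 latent_mode = latent_mode,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate one synthetic TMA spot image
#'
#' Draws a jittered tissue disc and fills it with dark elliptical blobs
#' whose expected count increases monotonically with `latent_score`
#' through a logistic ramp. The ground truth (disc mask, pre-noise blob
#' mask, blob count) is attached as attribute `"truth"` so segmentation
#' and texture statistics can be validated against construction.
#'
#' @param texture a [texture_params()].
#' @param latent_score real-valued ground-truth risk covariate.
#' @param image_size image side in pixels (>= 64).
#' @param seed RNG seed for this image.
#' @param pixel_size_um physical pixel size.
#' @return a [spot_image()] with attribute `"truth"`.
#' @export
generate_spot_image <- function(texture = texture_params(), latent_score = 0,
                                image_size = 512L, seed = 1L,
                                pixel_size_um = 0.22) {
  if (image_size < 64L) stop("`image_size` must be at least 64 pixels")
  stopifnot(inherits(texture, "texture_params"))
  n <- as.integer(image_size)
  with_seed(seed, {
    cx <- n / 2 * (1 + runif(1, -0.03, 0.03))
    cy <- n / 2 * (1 + runif(1, -0.03, 0.03))
    r  <- texture$disc_radius_frac * n * (1 + runif(1, -0.03, 0.03))
    xs <- matrix(seq_len(n), n, n)
    ys <- matrix(seq_len(n), n, n, byrow = TRUE)
    disc <- (xs - cx)^2 + (ys - cy)^2 <= r^2

    dens <- texture$blob_density_range
    p <- stats::plogis(texture$texture_gain * latent_score)
    n_blobs <- round((dens[1] + (dens[2] - dens[1]) * p) * (n / 512)^2)

    blob <- matrix(FALSE, n, n)
    if (n_blobs > 0) {
      # uniform centres in the disc interior via polar sampling
      rad <- r * 0.95 * sqrt(runif(n_blobs))
      ang <- runif(n_blobs, 0, 2 * pi)
      bx <- cx + rad * cos(ang)
      by <- cy + rad * sin(ang)
      a <- runif(n_blobs, texture$blob_radius_range_px[1],
                 texture$blob_radius_range_px[2])
      b <- a * runif(n_blobs, 0.5, 1)
      th <- runif(n_blobs, 0, pi)
      for (i in seq_len(n_blobs)) {
        w <- ceiling(a[i]) + 1L
        ix <- max(1L, floor(bx[i]) - w):min(n, ceiling(bx[i]) + w)
        iy <- max(1L, floor(by[i]) - w):min(n, ceiling(by[i]) + w)
        dx <- outer(ix - bx[i], rep(1, length(iy)))
        dy <- outer(rep(1, length(ix)), iy - by[i])
        u <-  dx * cos(th[i]) + dy * sin(th[i])
        v <- -dx * sin(th[i]) + dy * cos(th[i])
        blob[ix, iy] <- blob[ix, iy] | (u^2 / a[i]^2 + v^2 / b[i]^2 <= 1)
      }
      blob <- blob & disc
    }

    px <- array(0, c(n, n, 3L))
    for (ch in 1:3) {
      plane <- matrix(texture$background, n, n)
      plane[disc] <- texture$matrix_col[ch]
      plane[blob] <- texture$stain_dark[ch]
      if (texture$noise_sd > 0)
        plane <- plane + rnorm(n * n, 0, texture$noise_sd)
      px[, , ch] <- pmin(pmax(plane, 0), 1)
    }
    img <- spot_image(px, pixel_size_um)
    attr(img, "truth") <- list(disc_mask = disc, blob_mask = blob,
                               n_blobs = n_blobs, latent_score = latent_score)
    img
  })
}

#' Simulate one censored survival record
#'
#' Competing exponential processes: breast-cancer death with rate
#' `baseline_rate * exp(effect_size_beta * latent_score)`, other-cause
#' death with rate `other_cause_rate`, administrative censoring at
#' `admin_censor_years`. The observed time is the minimum of the three
#' and the cause is set accordingly (`alive` for administrative
#' censoring).
#'
#' @param latent_score ground-truth risk covariate.
#' @param config a [cohort_config()].
#' @param seed RNG seed.
#' @return list with `followup_years` and `cause` (one of
#'   `"breast_cancer_death"`, `"other_death"`, `"alive"`).
#' @export
simulate_survival <- function(latent_score, config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  rate_bc <- config$baseline_rate * exp(config$effect_size_beta * latent_score)
  with_seed(seed, {
    t_bc  <- if (rate_bc > 0) rexp(1, rate_bc) else Inf
    t_oth <- if (config$other_cause_rate > 0)
      rexp(1, config$other_cause_rate) else Inf
    t_adm <- config$admin_censor_years
    t <- min(t_bc, t_oth, t_adm)
    cause <- if (t == t_adm && t < Inf) "alive"
             else if (t == t_bc) "breast_cancer_death"
             else "other_death"
    if (!is.finite(t)) stop("no event process and infinite censoring horizon")
    list(followup_years = t, cause = cause)
  })
}

#' Generate a synthetic cohort
#'
#' Draws a latent score per patient, simulates the survival record, and
#' provides the spot images either in memory, as PNG files, or as a lazy
#' deterministic image provider (images are a pure function of the
#' configuration, so they can be re-generated on demand instead of being
#' stored).
#'
#' @param config a [cohort_config()].
#' @param images `"lazy"` (default; cohort carries `image_fun`),
#'   `"memory"` (list of [spot_image()]s, only sensible for small
#'   cohorts), `"png"` (written to `image_dir`), or `"none"`
#'   (clinical table only).
#' @param image_dir directory for `images = "png"`.
#' @return list of class `synthetic_cohort` with elements `clinical`
#'   (data.frame: patient_id, followup_years, cause, latent_score,
#'   latent_class), `config`, `image_fun(patient_id)` and, depending on
#'   `images`, `image_list` or `image_paths`.
#' @export
generate_cohort <- function(config,
                            images = c("lazy", "memory", "png", "none"),
                            image_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  images <- match.arg(images)
  n <- config$n_patients
  z <- with_seed(derive_seed(config$seed, 0L, 1L), {
    if (config$latent_mode == "binary")
      sample(c(-1, 1), n, replace = TRUE) else rnorm(n)
  })
  surv <- lapply(seq_len(n), function(i)
    simulate_survival(z[i], config, derive_seed(config$seed, i, 2L)))
  clinical <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    followup_years = vapply(surv, `[[`, numeric(1), "followup_years"),
    cause = vapply(surv, `[[`, character(1), "cause"),
    latent_score = z,
    latent_class = ifelse(z > 0, "high_texture", "low_texture"),
    stringsAsFactors = FALSE
  )
  image_fun <- local({
    cfg <- config
    ids <- clinical$patient_id
    zz <- z
    function(patient_id) {
      i <- match(patient_id, ids)
      if (is.na(i)) stop("unknown patient id: ", patient_id)
      generate_spot_image(cfg$texture, zz[i], cfg$image_size,
                          derive_seed(cfg$seed, i, 3L), cfg$pixel_size_um)
    }
  })
  out <- list(clinical = clinical, config = config, image_fun = image_fun)
  if (images == "memory") {
    out$image_list <- setNames(lapply(clinical$patient_id, image_fun),
                               clinical$patient_id)
  } else if (images == "png") {
    if (is.null(image_dir)) stop("`image_dir` required for images = 'png'")
    dir.create(image_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(image_dir, paste0(clinical$patient_id, ".png"))
    for (i in seq_len(n))
      write_spot_png(image_fun(clinical$patient_id[i]), paths[i])
    out$image_paths <- setNames(paths, clinical$patient_id)
  }
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> n = %d, beta = %.3f, mode = %s\n",
              x$config$n_patients, x$config$effect_size_beta,
              x$config$latent_mode))
  invisible(x)
}

#' Write / read the clinical table of a cohort
#'
#' Plain CSV with columns patient_id, followup_years, cause,
#' latent_score and any further covariate columns.
#'
#' @param clinical data.frame as produced by [generate_cohort()].
#' @param path output file.
#' @export
write_clinical_csv <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_clinical_csv
#' @export
read_clinical_csv <- function(path) {
  cl <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "followup_years", "cause")
  if (!all(req %in% names(cl)))
    stop("clinical table must contain columns: ",
         paste(req, collapse = ", "))
  bad <- setdiff(unique(cl$cause),
                 c("breast_cancer_death", "other_death", "alive"))
  if (length(bad)) stop("unknown cause values: ", paste(bad, collapse = ", "))
  cl
}
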