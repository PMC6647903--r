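#' Pipeline parameters
#'
#' One object bundling every tunable constant of the digital risk score
#' pipeline. Defaults are the full-scale analysis settings (descriptor
#' PCA to 16 dimensions, 64 GMM components, 48 output features, 4e6
#' subsampled descriptors, 0.02 mm^2 spot-area criterion, 10-year label
#' horizon); scaled-down experiments override them explicitly.
#'
#' @param pre_components descriptor PCA dimension.
#' @param K GMM mixture components.
#' @param post_components encoded feature dimension.
#' @param subsample_total descriptors subsampled for encoder fitting.
#' @param margin_parameter SVM cost.
#' @param horizon_years label horizon (years).
#' @param min_area_mm2 spot-area inclusion criterion (mm^2).
#' @param min_object_px small-object removal threshold (pixels).
#' @param smooth_radius_px Gaussian truncation radius for segmentation.
#' @param extractor a [descriptor_extractor()]; default
#'   `fixture_extractor(seed)`.
#' @param split_fraction training fraction for random splits.
#' @param seed master seed for subsampling, GMM initialisation and
#'   splitting.
#' @return list of class `drs_params`.
#' @export
drs_params <- function(pre_components = 16L, K = 64L, post_components = 48L,
                       subsample_total = 4e6, margin_parameter = 1,
                       horizon_years = 10, min_area_mm2 = 0.02,
                       min_object_px = 12500L, smooth_radius_px = 15,
                       extractor = NULL, split_fraction = 2 / 3,
                       seed = 1L) {
  stopifnot(pre_components >= 1, K >= 1, post_components >= 1,
            subsample_total >= 2, margin_parameter > 0, horizon_years > 0,
            min_area_mm2 >= 0, split_fraction > 0, split_fraction < 1)
  if (is.null(extractor)) extractor <- fixture_extractor(seed)
  stopifnot(inherits(extractor, "descriptor_extractor"))
  structure(list(pre_components = as.integer(pre_components),
                 K = as.integer(K),
                 post_components = as.integer(post_components),
                 subsample_total = subsample_total,
                 margin_parameter = margin_parameter,
                 horizon_years = horizon_years,
                 min_area_mm2 = min_area_mm2,
                 min_object_px = as.integer(min_object_px),
                 smooth_radius_px = smooth_radius_px,
                 extractor = extractor,
                 split_fraction = split_fraction,
                 seed = as.integer(seed)),
            class = "drs_params")
}

# Resolve <id>.png / <id>.tif(f) files under a directory; missing spots
# are a hard error up front rather than midway through training.
locate_spot_files <- function(image_dir, patient_ids) {
  paths <- vapply(patient_ids, function(id) {
    for (ext in c(".png", ".tif", ".tiff")) {
      p <- file.path(image_dir, paste0(id, ext))
      if (file.exists(p)) return(p)
    }
    NA_character_
  }, character(1))
  if (anyNA(paths))
    stop("missing image files for: ",
         paste(utils::head(patient_ids[is.na(paths)], 5), collapse = ", "))
  setNames(paths, patient_ids)
}

# Normalise the many ways of pointing at spot images into one accessor:
# function(patient_id) -> spot_image.
resolve_spot_source <- function(x, pixel_size_um = 0.22) {
  if (inherits(x, "synthetic_cohort")) {
    if (!is.null(x$image_list)) {
      imgs <- x$image_list
      return(function(id) imgs[[id]])
    }
    if (!is.null(x$image_paths)) {
      paths <- x$image_paths
      psz <- x$config$pixel_size_um
      return(function(id) read_spot_png(paths[[id]], psz))
    }
    return(x$image_fun)
  }
  if (is.function(x)) return(x)
  if (is.list(x)) return(function(id) x[[id]])
  if (is.character(x)) return(function(id) read_spot_image(x[[id]],
                                                           pixel_size_um))
  stop("cannot interpret the spot image source")
}

#' Random train/test split by patient id
#'
#' @param patient_ids character vector.
#' @param fraction training fraction (default 2/3, mirroring a 67%/33%
#'   design).
#' @param seed RNG seed.
#' @return list with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
split_cohort <- function(patient_ids, fraction = 2 / 3, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1, !anyDuplicated(patient_ids))
  n_train <- round(length(patient_ids) * fraction)
  train <- with_seed(derive_seed(seed, length(patient_ids), 9L),
                     sort(sample(patient_ids, n_train)))
  list(train = train, test = setdiff(patient_ids, train))
}

# Segment, extract and mask-filter one spot. Returns NULL (with a reason
# attribute) when the spot fails the area criterion or has no foreground
# descriptors.
process_spot <- function(image, id, params) {
  fg <- compute_foreground(image, params$smooth_radius_px,
                           params$min_object_px)
  if (!passes_area_criterion(fg, params$min_area_mm2))
    return(structure(list(NULL), reason = "area", area_mm2 = fg$area_mm2))
  dset <- filter_by_mask(extract_descriptors(image, params$extractor, id), fg)
  if (nrow(dset$vectors) == 0L)
    return(structure(list(NULL), reason = "area", area_mm2 = fg$area_mm2))
  structure(list(dset), reason = "ok", area_mm2 = fg$area_mm2)
}

#' Train the full DRS pipeline
#'
#' Applies, per training spot: foreground segmentation, the spot-area
#' criterion, outcome-label assignment, descriptor extraction and
#' foreground filtering; then fits the IFV encoder on a balanced
#' descriptor subsample and the linear SVM on the encoded training
#' spots. Spots failing the area criterion and label-indeterminate
#' records are excluded and counted in the report.
#'
#' @param spots image source: a [generate_cohort()] result, a named list
#'   of [spot_image()]s, a named vector of PNG paths, or a
#'   `function(patient_id)`.
#' @param clinical clinical table with `patient_id`, `followup_years`,
#'   `cause`.
#' @param params a [drs_params()] object.
#' @param patient_ids subset of patients to train on (default: all rows
#'   of `clinical`).
#' @param cache_dir directory for the per-spot descriptor cache
#'   (default: a session temporary directory).
#' @return object of class `drs_fit`: `encoder`, `classifier`,
#'   `features`, `labels`, `report`, `params`.
#' @export
drs_train <- function(spots, clinical, params = drs_params(),
                      patient_ids = clinical$patient_id,
                      cache_dir = tempfile("drs_cache_")) {
  stopifnot(inherits(params, "drs_params"))
  check_clinical(clinical)
  source_fun <- resolve_spot_source(spots)
  clinical <- clinical[match(patient_ids, clinical$patient_id), ]
  if (anyNA(clinical$patient_id))
    stop("patient ids missing from the clinical table")
  labels_all <- assign_training_labels(clinical$cause,
                                       clinical$followup_years,
                                       params$horizon_years)
  sets <- list(); labels <- character(); areas <- numeric()
  excluded_area <- character(); excluded_indet <- character()
  for (i in seq_along(patient_ids)) {
    id <- patient_ids[i]
    if (labels_all[i] == "indeterminate") {
      excluded_indet <- c(excluded_indet, id)
      next
    }
    res <- process_spot(source_fun(id), id, params)
    if (attr(res, "reason") != "ok") {
      excluded_area <- c(excluded_area, id)
      next
    }
    sets[[length(sets) + 1L]] <- cache_descriptor_set(res[[1]], cache_dir)
    labels <- c(labels, as.character(labels_all[i]))
    areas <- c(areas, attr(res, "area_mm2"))
  }
  if (length(excluded_indet))
    warning(sprintf("%d record(s) with breast-cancer death at or beyond %g years are label-indeterminate and were excluded from supervision",
                    length(excluded_indet), params$horizon_years))
  if (length(sets) == 0L)
    stop("no spots passed the area criterion (min_area_mm2 = ",
         params$min_area_mm2, ", min_object_px = ", params$min_object_px,
         "); check the thresholds against the image scale")
  encoder <- fit_ifv_encoder(sets, labels,
                             pre_components = params$pre_components,
                             K = params$K,
                             post_components = params$post_components,
                             subsample_total = params$subsample_total,
                             seed = params$seed)
  classifier <- train_drs(encoder$train_features, labels,
                          margin_parameter = params$margin_parameter,
                          seed = params$seed)
  train_scores <- predict_drs(encoder$train_features, classifier)$drs_score
  report <- list(
    n_input = length(patient_ids),
    n_trained = length(labels),
    n_excluded_area = length(excluded_area),
    n_excluded_indeterminate = length(excluded_indet),
    excluded_area_ids = excluded_area,
    excluded_indeterminate_ids = excluded_indet,
    train_ids = vapply(sets, function(s) s$source_id, character(1)),
    label_counts = table(factor(labels, c("low", "high"))),
    train_auc = evaluate_auc(train_scores, labels == "high"),
    mean_area_mm2 = mean(areas)
  )
  structure(list(encoder = encoder, classifier = classifier,
                 features = encoder$train_features, labels = labels,
                 report = report, params = params),
            class = "drs_fit")
}

#' @export
print.drs_fit <- function(x, ...) {
  r <- x$report
  cat(sprintf("<drs_fit> trained on %d/%d spots (%d area-excluded, %d indeterminate), train AUC %.3f\n",
              r$n_trained, r$n_input, r$n_excluded_area,
              r$n_excluded_indeterminate, r$train_auc))
  invisible(x)
}

#' Score spots with a fitted pipeline
#'
#' @param fit a [drs_train()] result (or a loaded model archive).
#' @param spots image source (see [drs_train()]).
#' @param patient_ids spots to score.
#' @return data.frame: `patient_id`, `included` (passed the area
#'   criterion), `area_mm2`, `drs_score`, `drs_group`.
#' @export
drs_predict <- function(fit, spots, patient_ids) {
  stopifnot(inherits(fit, "drs_fit"))
  source_fun <- resolve_spot_source(spots)
  params <- fit$params
  out <- data.frame(patient_id = patient_ids, included = FALSE,
                    area_mm2 = NA_real_, drs_score = NA_real_,
                    drs_group = factor(rep(NA, length(patient_ids)),
                                       levels = c("low", "high")),
                    stringsAsFactors = FALSE)
  for (i in seq_along(patient_ids)) {
    res <- process_spot(source_fun(patient_ids[i]), patient_ids[i], params)
    out$area_mm2[i] <- attr(res, "area_mm2")
    if (attr(res, "reason") != "ok") next
    feat <- encode_spot(res[[1]]$vectors, fit$encoder)
    pr <- predict_drs(feat, fit$classifier)
    out$included[i] <- TRUE
    out$drs_score[i] <- pr$drs_score
    out$drs_group[i] <- pr$drs_group
  }
  out
}

#' Evaluate a fitted pipeline on a held-out test split
#'
#' Scores the test spots, then reports the paper-style evaluation layer:
#' held-out AUC against the outcome-derived labels, Kaplan-Meier curves
#' for disease-specific and overall survival by DRS group with the
#' log-rank test, 10-year DSS per group, a univariate Cox model of the
#' DRS group (plus an optional multivariate model with clinical
#' covariates), and the concordance index of the DRS grouping with a
#' percentile-bootstrap confidence interval. When rater scores are
#' supplied, the visual-score comparison (not-evaluable exclusion,
#' majority vote, percent agreement, pairwise kappas, and the combined
#' DRS + visual Cox model) is added. Train/test leakage (shared patient
#' ids) is a hard error.
#'
#' @param fit a [drs_train()] result.
#' @param spots image source for the test spots.
#' @param clinical clinical table covering the test patients.
#' @param patient_ids test patient ids (disjoint from training ids).
#' @param covariates optional data.frame of clinical covariates
#'   (rows aligned with `patient_ids`) for the multivariate Cox model.
#' @param raters optional [rater_scores()] for the test spots.
#' @param n_boot bootstrap resamples for the C-index CI.
#' @return list of class `drs_evaluation`.
#' @export
drs_evaluate <- function(fit, spots, clinical, patient_ids,
                         covariates = NULL, raters = NULL, n_boot = 2000L) {
  stopifnot(inherits(fit, "drs_fit"))
  leak <- intersect(patient_ids, fit$report$train_ids)
  if (length(leak))
    stop("train/test leakage: shared patient ids: ",
         paste(utils::head(leak, 5), collapse = ", "))
  preds <- drs_predict(fit, spots, patient_ids)
  cl <- clinical[match(patient_ids, clinical$patient_id), ]
  keep <- preds$included
  scored <- cbind(preds[keep, ], cl[keep, setdiff(names(cl), "patient_id")])
  labels <- assign_training_labels(scored$cause, scored$followup_years,
                                   fit$params$horizon_years)
  determinate <- labels != "indeterminate"
  test_auc <- if (length(unique(labels[determinate])) == 2L)
    evaluate_auc(scored$drs_score[determinate],
                 labels[determinate] == "high") else NA_real_
  dss <- build_dss(scored)
  os <- build_os(scored)
  grp <- scored$drs_group
  both_groups <- nlevels(droplevels(grp)) == 2L
  km_dss <- lapply(split(seq_len(nrow(scored)), droplevels(grp)), function(ix)
    km_estimate(endpoints(dss$time_years[ix], dss$event[ix])))
  ten_year <- lapply(km_dss, survival_at, t = 10)
  logrank_dss <- if (both_groups) logrank_test(dss, grp) else NULL
  logrank_os <- if (both_groups) logrank_test(os, grp) else NULL
  # degenerate test splits (e.g. complete separation at tiny n) yield no
  # usable Cox fit; report NULL rather than aborting the evaluation
  cox_uni <- if (both_groups)
    tryCatch(cox_fit(dss, data.frame(drs_group = grp)),
             error = function(e) NULL) else NULL
  cox_multi <- NULL
  if (!is.null(covariates) && both_groups) {
    cov_scored <- covariates[match(scored$patient_id, patient_ids), ,
                             drop = FALSE]
    cox_multi <- tryCatch(
      cox_fit(dss, cbind(data.frame(drs_group = grp), cov_scored)),
      error = function(e) NULL)
  }
  cindex <- cindex_bootstrap_ci(as.integer(grp == "high"), dss,
                                n_boot = n_boot, seed = fit$params$seed)
  visual <- NULL
  if (!is.null(raters)) {
    ev <- exclude_not_evaluable(raters)
    vote <- majority_votes(ev$evaluable)
    common <- intersect(names(vote), scored$patient_id)
    ix <- match(common, scored$patient_id)
    kappas <- utils::combn(ncol(raters), 2, simplify = FALSE)
    kappas <- lapply(kappas, function(p) {
      k <- cohens_kappa(ev$evaluable[, p[1]], ev$evaluable[, p[2]])
      k$raters <- p
      k
    })
    vis_ep <- endpoints(scored$followup_years[ix],
                        as.integer(scored$cause[ix] == "breast_cancer_death"))
    cox_combined <- tryCatch(
      cox_fit(vis_ep, data.frame(drs_group = droplevels(grp[ix]),
                                 visual = factor(vote[common],
                                                 c("low", "high")))),
      error = function(e) NULL)
    visual <- list(
      n_excluded_not_evaluable = ev$n_excluded,
      n_evaluable = ev$n_evaluable,
      vote = vote,
      percent_agreement = percent_agreement(ev$evaluable),
      kappas = kappas,
      agreement_with_drs = mean(vote[common] ==
                                  as.character(grp[ix])),
      cox_combined = cox_combined)
  }
  structure(list(
    predictions = preds,
    n_scored = sum(keep),
    n_excluded_area = sum(!keep),
    test_auc = test_auc,
    group_counts = table(grp),
    km_dss = km_dss,
    ten_year_dss = ten_year,
    logrank_dss = logrank_dss,
    logrank_os = logrank_os,
    cox_univariate = cox_uni,
    cox_multivariate = cox_multi,
    cindex = cindex,
    visual = visual
  ), class = "drs_evaluation")
}

#' @export
print.drs_evaluation <- function(x, ...) {
  cat(sprintf("<drs_evaluation> %d scored (%d excluded), AUC %.3f\n",
              x$n_scored, x$n_excluded_area, x$test_auc))
  if (!is.null(x$logrank_dss))
    cat(sprintf("  log-rank (DSS) p = %.4g; C-index %.3f (%.3f-%.3f)\n",
                x$logrank_dss$p_value, x$cindex$estimate, x$cindex$lower,
                x$cindex$upper))
  invisible(x)
}

#' Save / load the fitted models as a versioned JSON archive
#'
#' Serialises the PCA models, the GMM, the SVM hyperplane and the
#' pipeline constants (not the extractor closure: the extractor is
#' reconstructed from its recorded seed) to a single JSON file with
#' full numeric precision.
#'
#' @param fit a [drs_train()] result.
#' @param path output file.
#' @return `load_drs_models()` returns a `drs_fit`-compatible object
#'   usable with [drs_predict()] / [drs_evaluate()].
#' @export
save_drs_models <- function(fit, path) {
  stopifnot(inherits(fit, "drs_fit"))
  pca_pack <- function(p) list(mean = p$mean, components = p$components,
                               eigenvalues = p$eigenvalues,
                               n_components = p$n_components,
                               whiten = p$whiten)
  obj <- list(
    format = "drscore_model",
    version = 1L,
    params = fit$params[setdiff(names(fit$params), "extractor")],
    extractor = list(name = fit$params$extractor$name,
                     descriptor_dim = fit$params$extractor$descriptor_dim,
                     grid_stride_px = fit$params$extractor$grid_stride_px),
    pre_pca = pca_pack(fit$encoder$pre_pca),
    gmm = list(weights = fit$encoder$gmm$weights,
               means = fit$encoder$gmm$means,
               variances = fit$encoder$gmm$variances),
    post_pca = pca_pack(fit$encoder$post_pca),
    classifier = list(weights = fit$classifier$weights,
                      bias = fit$classifier$bias,
                      margin_parameter = fit$classifier$margin_parameter),
    report = fit$report[c("n_input", "n_trained", "n_excluded_area",
                          "n_excluded_indeterminate", "train_auc",
                          "train_ids")]
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_drs_models
#' @param extractor extractor to attach on load (must match the one used
#'   in training; defaults to a fixture extractor with the archived
#'   stride and dimension and the archived pipeline seed).
#' @export
load_drs_models <- function(path, extractor = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "drscore_model"))
    stop("not a drscore model archive")
  pca_unpack <- function(p) structure(
    list(mean = p$mean, components = p$components,
         eigenvalues = p$eigenvalues,
         n_components = as.integer(p$n_components), whiten = p$whiten),
    class = "pca_model")
  if (is.null(extractor))
    extractor <- fixture_extractor(obj$params$seed,
                                   obj$extractor$descriptor_dim,
                                   obj$extractor$grid_stride_px)
  params <- do.call(drs_params, c(obj$params, list(extractor = extractor)))
  encoder <- structure(list(
    pre_pca = pca_unpack(obj$pre_pca),
    gmm = structure(list(weights = obj$gmm$weights, means = obj$gmm$means,
                         variances = obj$gmm$variances),
                    class = "gmm_model"),
    post_pca = pca_unpack(obj$post_pca)), class = "ifv_encoder_model")
  classifier <- structure(list(weights = obj$classifier$weights,
                               bias = obj$classifier$bias,
                               margin_parameter =
                                 obj$classifier$margin_parameter),
                          class = "drs_model")
  structure(list(encoder = encoder, classifier = classifier,
                 report = obj$report, params = params),
            class = "drs_fit")
}

#' Write encoded features as TSV
#'
#' One row per spot: id column plus one column per feature dimension,
#' printed with 12 significant digits so identical fits produce
#' byte-identical files.
#'
#' @param features numeric matrix with rownames.
#' @param path output file.
#' @export
write_features_tsv <- function(features, path) {
  df <- data.frame(spot_id = rownames(features),
                   signif(as.data.frame(features), 12))
  names(df) <- c("spot_id", sprintf("f%02d", seq_len(ncol(features))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the file-based training workflow
#'
#' Thin wrapper over [drs_train()]: reads the clinical CSV and PNG spot
#' images from disk, trains, and writes the model archive, the training
#' feature TSV, predictions for the training split and a JSON report
#' into `output_dir`.
#'
#' @param image_dir directory of `<patient_id>.png` spot images.
#' @param clinical_csv clinical table path.
#' @param output_dir output directory.
#' @param params a [drs_params()].
#' @param patient_ids training ids (default: all).
#' @param pixel_size_um physical pixel size of the images.
#' @return the [drs_train()] fit, invisibly.
#' @export
run_train <- function(image_dir, clinical_csv, output_dir,
                      params = drs_params(),
                      patient_ids = NULL, pixel_size_um = 0.22) {
  clinical <- read_clinical_csv(clinical_csv)
  if (is.null(patient_ids)) patient_ids <- clinical$patient_id
  paths <- locate_spot_files(image_dir, patient_ids)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- drs_train(function(id) read_spot_image(paths[[id]], pixel_size_um),
                   clinical, params, patient_ids)
  save_drs_models(fit, file.path(output_dir, "drs_models.json"))
  write_features_tsv(fit$features,
                     file.path(output_dir, "train_features.tsv"))
  jsonlite::write_json(
    fit$report[setdiff(names(fit$report), "label_counts")],
    file.path(output_dir, "train_report.json"),
    digits = NA, auto_unbox = TRUE)
  invisible(fit)
}

#' Run the file-based evaluation workflow
#'
#' Loads (or accepts) a fitted model, scores the test split from PNG
#' images, and writes predictions TSV, the Cox table TSV, Kaplan-Meier
#' curves TSV and a JSON evaluation report into `output_dir`.
#'
#' @param fit a `drs_fit` or the path of a model archive.
#' @param image_dir directory of test spot images.
#' @param clinical_csv clinical table path.
#' @param output_dir output directory.
#' @param patient_ids test ids (default: all clinical rows not used in
#'   training).
#' @param rater_csv optional long-format rater CSV.
#' @param n_boot bootstrap resamples for the C-index CI.
#' @param pixel_size_um physical pixel size of the images.
#' @return the [drs_evaluate()] result, invisibly.
#' @export
run_evaluate <- function(fit, image_dir, clinical_csv, output_dir,
                         patient_ids = NULL, rater_csv = NULL,
                         n_boot = 2000L, pixel_size_um = 0.22) {
  if (is.character(fit)) fit <- load_drs_models(fit)
  clinical <- read_clinical_csv(clinical_csv)
  if (is.null(patient_ids))
    patient_ids <- setdiff(clinical$patient_id, fit$report$train_ids)
  paths <- locate_spot_files(image_dir, patient_ids)
  raters <- if (!is.null(rater_csv)) read_rater_csv(rater_csv) else NULL
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  ev <- drs_evaluate(fit,
                     function(id) read_spot_image(paths[[id]], pixel_size_um),
                     clinical, patient_ids, raters = raters,
                     n_boot = n_boot)
  utils::write.table(ev$predictions, file.path(output_dir,
                                               "predictions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(ev$cox_univariate))
    utils::write.table(cox_table(ev$cox_univariate),
                       file.path(output_dir, "cox_univariate.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  km_tab <- do.call(rbind, lapply(names(ev$km_dss), function(g) {
    k <- ev$km_dss[[g]]
    if (!length(k$event_times)) return(NULL)
    data.frame(drs_group = g, time_years = k$event_times,
               survival = k$survival, lower95 = k$lower,
               upper95 = k$upper, n_at_risk = k$n_at_risk)
  }))
  if (!is.null(km_tab))
    utils::write.table(km_tab, file.path(output_dir, "km_dss.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  report <- list(
    n_scored = ev$n_scored,
    n_excluded_area = ev$n_excluded_area,
    test_auc = ev$test_auc,
    group_counts = as.list(ev$group_counts),
    logrank_dss_p = if (!is.null(ev$logrank_dss))
      ev$logrank_dss$p_value else NULL,
    logrank_os_p = if (!is.null(ev$logrank_os))
      ev$logrank_os$p_value else NULL,
    hr_high_vs_low = if (!is.null(ev$cox_univariate))
      unname(ev$cox_univariate$hazard_ratios[1]) else NULL,
    cindex = ev$cindex[c("estimate", "lower", "upper")],
    ten_year_dss = lapply(ev$ten_year_dss, function(s) s$estimate),
    percent_agreement = if (!is.null(ev$visual))
      ev$visual$percent_agreement else NULL
  )
  jsonlite::write_json(report, file.path(output_dir, "evaluation.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(ev)
}
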