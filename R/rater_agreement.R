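#' Rater score table
#'
#' Per-spot, per-rater risk calls. Internally a character matrix with
#' one row per spot (rownames = spot ids) and one column per rater,
#' every cell one of `"low"`, `"high"`, `"not_evaluable"`.
#'
#' @param x matrix/data.frame of calls, or a long data.frame with
#'   columns `spot_id`, `rater_id`, `label`.
#' @return character matrix of class `rater_scores`.
#' @export
rater_scores <- function(x) {
  if (is.data.frame(x) &&
      all(c("spot_id", "rater_id", "label") %in% names(x))) {
    wide <- tapply(as.character(x$label),
                   list(as.character(x$spot_id), as.character(x$rater_id)),
                   identity)
    x <- wide
  }
  m <- as.matrix(x)
  mode(m) <- "character"
  if (anyNA(m)) stop("every (spot, rater) cell must have exactly one value")
  bad <- setdiff(unique(as.vector(m)), c("low", "high", "not_evaluable"))
  if (length(bad))
    stop("invalid labels: ", paste(bad, collapse = ", "))
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%04d", seq_len(nrow(m)))
  class(m) <- c("rater_scores", class(m))
  m
}

#' Read rater scores from a long CSV
#'
#' Expected columns: `spot_id`, `rater_id`, `label`.
#'
#' @param path CSV file.
#' @return a [rater_scores()] matrix.
#' @export
read_rater_csv <- function(path) {
  rater_scores(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Drop spots any rater marked not evaluable
#'
#' A spot is excluded iff at least one rater called it `not_evaluable`.
#'
#' @param scores a [rater_scores()] matrix.
#' @return list with `evaluable` (subset matrix), `excluded_ids`, and
#'   counts `n_evaluable` / `n_excluded`.
#' @export
exclude_not_evaluable <- function(scores) {
  stopifnot(inherits(scores, "rater_scores"))
  drop <- apply(unclass(scores) == "not_evaluable", 1, any)
  ev <- scores[!drop, , drop = FALSE]
  class(ev) <- class(scores)
  list(evaluable = ev,
       excluded_ids = rownames(scores)[drop],
       n_evaluable = sum(!drop), n_excluded = sum(drop))
}

#' Majority-vote visual risk score
#'
#' The label given by more than half of an odd number of raters. An even
#' rater count is rejected (no tie rule is defined).
#'
#' @param calls character vector of `"low"`/`"high"` calls for one spot.
#' @return `"low"` or `"high"`.
#' @export
majority_vote <- function(calls) {
  calls <- as.character(calls)
  if (length(calls) %% 2L == 0L)
    stop("majority vote requires an odd number of raters")
  if (!all(calls %in% c("low", "high")))
    stop("spot must be evaluable (low/high calls only)")
  if (sum(calls == "high") > length(calls) / 2) "high" else "low"
}

#' @rdname majority_vote
#' @param scores a [rater_scores()] matrix of evaluable spots.
#' @return `majority_votes()`: named character vector, one vote per spot.
#' @export
majority_votes <- function(scores) {
  stopifnot(inherits(scores, "rater_scores"))
  setNames(apply(unclass(scores), 1, majority_vote), rownames(scores))
}

#' Percent agreement between raters
#'
#' Default (`"unanimous"`): the fraction of evaluable spots on which all
#' raters give the same label. `"pairwise"` averages simple matching
#' over all rater pairs; for two raters the modes coincide.
#'
#' @param scores a [rater_scores()] matrix of evaluable spots.
#' @param mode `"unanimous"` or `"pairwise"`.
#' @return fraction in `[0, 1]`.
#' @export
percent_agreement <- function(scores, mode = c("unanimous", "pairwise")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scores, "rater_scores"))
  m <- unclass(scores)
  if (nrow(m) == 0L) stop("no evaluable spots")
  if (mode == "unanimous") {
    mean(apply(m, 1, function(r) length(unique(r)) == 1L))
  } else {
    pairs <- utils::combn(ncol(m), 2)
    mean(apply(pairs, 2, function(p) mean(m[, p[1]] == m[, p[2]])))
  }
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement `p_e` from the product of the marginals. The
#' p-value is the large-sample normal test of `kappa = 0` using the
#' standard error under independence.
#'
#' @param rater_a,rater_b label vectors over the same spots.
#' @return list with `kappa`, `se0`, `z`, `p_value`, `p_observed`,
#'   `p_expected`, `n`.
#' @export
cohens_kappa <- function(rater_a, rater_b) {
  a <- as.character(rater_a); b <- as.character(rater_b)
  stopifnot(length(a) == length(b), length(a) > 0)
  lev <- sort(unique(c(a, b)))
  tab <- table(factor(a, lev), factor(b, lev))
  n <- sum(tab)
  p <- tab / n
  po <- sum(diag(p))
  pa <- rowSums(p); pb <- colSums(p)
  pe <- sum(pa * pb)
  if (1 - pe < .Machine$double.eps)
    stop("degenerate marginals (p_e = 1): kappa undefined")
  kappa <- (po - pe) / (1 - pe)
  # SE of kappa under H0 of independence (Fleiss, Cohen & Everitt)
  se0 <- sqrt((pe + pe^2 - sum(pa * pb * (pa + pb))) / (n * (1 - pe)^2))
  z <- kappa / se0
  list(kappa = kappa, se0 = se0, z = z, p_value = 2 * pnorm(-abs(z)),
       p_observed = po, p_expected = pe, n = n)
}

#' Association tests between two variables
#'
#' Categorical vs categorical: Pearson chi-square on the contingency
#' table (no continuity correction). Continuous vs categorical:
#' Kruskal-Wallis rank test with tie correction. A contingency table
#' with an expected count of zero is flagged with a warning.
#'
#' @param a,b vectors; at least one must be categorical
#'   (character/factor/logical).
#' @return list with `method`, `statistic`, `df` (chi-square only),
#'   `p_value`.
#' @export
association_tests <- function(a, b) {
  cat_a <- is.character(a) || is.factor(a) || is.logical(a)
  cat_b <- is.character(b) || is.factor(b) || is.logical(b)
  if (cat_a && cat_b) {
    tab <- table(a, b)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected == 0))
      warning("contingency table has expected cell count 0")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(method = "chi_square", statistic = unname(ct$statistic),
         df = unname(ct$parameter), p_value = ct$p.value)
  } else if (xor(cat_a, cat_b)) {
    cont <- if (cat_a) b else a
    grp <- if (cat_a) a else b
    kw <- stats::kruskal.test(cont, factor(grp))
    list(method = "kruskal_wallis", statistic = unname(kw$statistic),
         df = unname(kw$parameter), p_value = kw$p.value)
  } else {
    stop("at least one variable must be categorical")
  }
}
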