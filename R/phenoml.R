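# Fisher-criterion sequential forward selection and cross-validated
# two-class classification.

#' Two-class Fisher ratio of one feature
#'
#' `J = (mu1 - mu2)^2 / (s1^2 + s2^2)` with unbiased class variances; larger
#' means more separable. If both class variances are zero the ratio is
#' `+Inf` (with a warning) when the means differ, 0 when they coincide.
#'
#' @param feature_values Numeric vector.
#' @param labels Two-class label vector of the same length.
#' @return Dimensionless separability score.
#' @export
fisher_ratio <- function(feature_values, labels) {
  lev <- sort(unique(labels))
  if (length(lev) != 2) stopf("need exactly two classes")
  x1 <- feature_values[labels == lev[1]]
  x2 <- feature_values[labels == lev[2]]
  if (length(x1) < 2 || length(x2) < 2) {
    stopf("both classes need >= 2 samples")
  }
  num <- (mean(x1) - mean(x2))^2
  den <- stats::var(x1) + stats::var(x2)
  if (den == 0) {
    if (num == 0) return(0)
    warnf("zero within-class variance; Fisher ratio is +Inf")
    return(Inf)
  }
  num / den
}

#' Assemble a feature table
#'
#' @param features Numeric matrix or data.frame, samples x named parameters.
#' @param labels Integer labels (1 = control, 2 = drought).
#' @param sample_id Optional sample identifiers.
#' @param day,genotype Optional metadata columns.
#' @return A data.frame of class `feature_table` with metadata columns
#'   (`sample_id`, `label`, optionally `day`, `genotype`) followed by the
#'   feature columns. Any missing value is an error.
#' @export
feature_table <- function(features, labels, sample_id = NULL, day = NULL,
                          genotype = NULL) {
  features <- as.data.frame(features, check.names = FALSE)
  if (nrow(features) != length(labels)) {
    stopf("labels length must match rows")
  }
  if (anyNA(features)) stopf("feature table contains missing values")
  if (is.null(sample_id)) {
    sample_id <- sprintf("plant_%03d", seq_len(nrow(features)))
  }
  meta <- data.frame(sample_id = sample_id, label = as.integer(labels),
                     stringsAsFactors = FALSE)
  if (!is.null(day)) meta$day <- day
  if (!is.null(genotype)) meta$genotype <- genotype
  out <- cbind(meta, features)
  class(out) <- c("feature_table", "data.frame")
  out
}

feature_columns <- function(table) {
  setdiff(names(table), c("sample_id", "label", "day", "genotype",
                          "preset"))
}

#' Extract the 105-parameter vector from one plant's stacks
#'
#' Full single-plant pipeline: segment the plant on the dark-adapted Fm
#' flash frame (highest contrast), extract the canopy-mean kinetic trace,
#' locate the base signals, compute the 89-entry chlorophyll catalogue, and
#' add the 16 multicolor parameters from the UV stack using the same mask.
#'
#' @param chl_stack Kinetic `frame_stack` following protocol `p`.
#' @param mc_stack Multicolor `frame_stack` ([simulate_multicolor()] shape).
#' @param p The `protocol_definition`.
#' @param seg A [segmentation_config()].
#' @return Named numeric vector of length 105.
#' @export
extract_features <- function(chl_stack, mc_stack, p,
                             seg = segmentation_config()) {
  fm_fl <- Filter(function(f) identical(f$yields, "Fm"), p$flashes)[[1]]
  sel <- which(chl_stack$light_state == "saturating" &
                 chl_stack$times_s >= fm_fl$time_s &
                 chl_stack$times_s <= fm_fl$time_s +
                   fm_fl$duration_ms / 1000)
  ref <- chl_stack$frames[, , sel[ceiling(length(sel) / 2)]]
  mask <- segment_plant(ref, seg)
  trace <- extract_trace(chl_stack, mask)
  sig <- extract_basic_signals(trace, p)
  chl <- compute_catalogue(sig)
  mc <- multicolor_parameters(multicolor_signals(mc_stack, mask))
  c(unclass(chl), unclass(mc))
}

#' Feature table of a simulated cohort
#'
#' @param cohort A [simulate_cohort()] result materialized as `"features"`.
#' @param day,genotype Optional metadata to attach.
#' @return A [feature_table()] with 105 feature columns.
#' @export
cohort_feature_table <- function(cohort, day = NULL, genotype = NULL) {
  feats <- do.call(rbind, lapply(cohort$samples, `[[`, "features"))
  feature_table(feats, cohort$manifest$label,
                sample_id = cohort$manifest$sample_id,
                day = day, genotype = genotype)
}

#' Sequential forward selection under the Fisher criterion
#'
#' Greedy bottom-up selection: starting from the empty set, repeatedly adds
#' the feature with the best criterion value until `k` features are chosen.
#' Two subset criteria are provided (the published method names only "SFS
#' with Fisher criterion", so the subset score is a design choice, isolated
#' here so alternatives can be swapped):
#'
#' * `"decorrelated"` (default) - the subset-augmented two-class Fisher
#'   score `J(S) = d' Sw^-1 d`, where `d` is the vector of class-mean
#'   differences over the subset and `Sw` the sum of the two unbiased
#'   class covariance matrices. This equals the sum of univariate Fisher
#'   ratios over within-class-whitened (decorrelated) components, so a
#'   near-duplicate of an already-selected feature adds ~0 and the greedy
#'   search favors complementary features.
#' * `"ranking"` - the classic per-feature criterion (subset score = sum of
#'   raw Fisher ratios), which degenerates to top-`k` ranking; redundant
#'   but highly stable under resampling.
#'
#' Under both criteria the first selection is the plain per-feature
#' Fisher-ratio maximizer. Deterministic; ties are broken by feature name
#' order.
#'
#' @param table A [feature_table()].
#' @param k Number of features to select (default 9).
#' @param criterion `"decorrelated"` or `"ranking"`.
#' @return An object of class `selection_result`: `selected` (ordered
#'   names), `criterion` (subset criterion value after each addition),
#'   `k`, and the criterion `kind`.
#' @export
sfs_select <- function(table, k = 9,
                       criterion = c("decorrelated", "ranking")) {
  criterion <- match.arg(criterion)
  cols <- feature_columns(table)
  if (k > length(cols)) {
    stopf("k = %d exceeds the %d available features", k, length(cols))
  }
  y <- table$label
  lev <- sort(unique(y))
  if (length(lev) != 2) stopf("need exactly two classes")
  x <- as.matrix(as.data.frame(table, check.names = FALSE)[, cols,
                                                           drop = FALSE])
  storage.mode(x) <- "double"
  selected <- character(0)
  trajectory <- numeric(0)
  remaining <- cols
  if (criterion == "ranking") {
    total <- 0
    for (step in seq_len(k)) {
      scores <- vapply(remaining, function(nm)
        suppressWarnings(fisher_ratio(x[, nm], y)), numeric(1))
      best <- max(scores)
      pick <- sort(remaining[scores == best])[1]
      total <- total + if (is.finite(best)) best else 0
      selected <- c(selected, pick)
      trajectory <- c(trajectory, total)
      remaining <- setdiff(remaining, pick)
    }
  } else {
    d <- colMeans(x[y == lev[2], , drop = FALSE]) -
      colMeans(x[y == lev[1], , drop = FALSE])
    Sw <- stats::cov(x[y == lev[1], , drop = FALSE]) +
      stats::cov(x[y == lev[2], , drop = FALSE])
    subset_J <- function(ss) {
      tryCatch(drop(crossprod(d[ss], solve(Sw[ss, ss, drop = FALSE],
                                           d[ss]))),
               error = function(e) -Inf)
    }
    for (step in seq_len(k)) {
      scores <- vapply(remaining, function(nm)
        subset_J(c(selected, nm)), numeric(1))
      best <- max(scores)
      pick <- sort(remaining[scores == best])[1]
      selected <- c(selected, pick)
      trajectory <- c(trajectory,
                      if (is.finite(best)) best
                      else if (length(trajectory)) trajectory[step - 1]
                      else 0)
      remaining <- setdiff(remaining, pick)
    }
  }
  structure(list(selected = selected, criterion = trajectory, k = k,
                 kind = criterion),
            class = "selection_result")
}

#' Stratified 10-fold cross-validated classification
#'
#' Trains a linear maximum-margin classifier ([linear_svm()], C = 1) per
#' fold on z-scored selected features - the scaler is fit on the training
#' fold only - and aggregates per-class and overall accuracy over the held-
#' out folds. Fold assignment is stratified by class and reproducible under
#' `seed`.
#'
#' @param table A [feature_table()].
#' @param features A [sfs_select()] result, or a character vector of feature
#'   names.
#' @param folds Number of folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @param C Soft-margin cost of the classifier.
#' @return An object of class `cv_report`: `overall`, `control`, `drought`
#'   accuracies in percent, `fold` (per-sample fold id), `predicted`,
#'   `seed`, `n`.
#' @export
cv_classify <- function(table, features, folds = 10, seed = 1, C = 1) {
  sel <- if (inherits(features, "selection_result")) features$selected
  else as.character(features)
  missing <- setdiff(sel, names(table))
  if (length(missing)) stopf("unknown feature '%s'", missing[1])
  y <- table$label
  lev <- sort(unique(y))
  if (length(lev) != 2) stopf("need exactly two classes in the table")
  if (min(table(y)) < folds) {
    warnf("fewer than %d samples in a class; folds will be uneven", folds)
  }
  x <- as.matrix(as.data.frame(table, check.names = FALSE)[, sel,
                                                           drop = FALSE])
  storage.mode(x) <- "double"
  n <- nrow(x)
  fold <- integer(n)
  with_seed(seed, {
    for (cl in lev) {
      i <- which(y == cl)
      fold[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
  })
  pred <- rep(NA_integer_, n)
  for (f in sort(unique(fold))) {
    tr <- fold != f
    mu <- colMeans(x[tr, , drop = FALSE])
    sg <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    xt <- sweep(sweep(x, 2, mu), 2, sg, "/")
    fit <- linear_svm(xt[tr, , drop = FALSE], y[tr], C = C)
    pred[!tr] <- as.integer(predict(fit, xt[!tr, , drop = FALSE]))
  }
  acc <- function(i) 100 * mean(pred[i] == y[i])
  structure(list(
    overall = acc(seq_len(n)),
    control = acc(which(y == lev[1])),
    drought = acc(which(y == lev[2])),
    fold = fold, predicted = pred, seed = seed, n = n,
    features = sel
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV report (n = %d, seed = %d)\n  control %.1f%%  drought %.1f%%  overall %.1f%%\n",
    length(unique(x$fold)), x$n, x$seed, x$control, x$drought, x$overall))
  invisible(x)
}
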