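# Background segmentation, ROI handling, kinetic-trace extraction, and
# projected leaf area.

#' Segmentation configuration
#'
#' @param method `"otsu"` (parameter-free histogram threshold, the default)
#'   or `"fixed_threshold"`.
#' @param threshold Count threshold for fixed mode (> 0).
#' @param min_object_px Connected components smaller than this are removed.
#' @param reference Which image the threshold applies to; informational
#'   (`"Fm"` for the chlorophyll stacks, `"IrF"` for multicolor).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(method = c("otsu", "fixed_threshold"),
                                threshold = NULL, min_object_px = 50,
                                reference = "Fm") {
  method <- match.arg(method)
  if (min_object_px < 1) stopf("min_object_px must be >= 1")
  if (method == "fixed_threshold" &&
      (!is_number(threshold) || threshold <= 0)) {
    stopf("fixed_threshold mode needs threshold > 0")
  }
  structure(list(method = method, threshold = threshold,
                 min_object_px = min_object_px, reference = reference),
            class = "segmentation_config")
}

#' Otsu's threshold of an image
#'
#' Exhaustive between-class-variance maximization over a 256-bin histogram.
#' Deterministic; ties resolved toward the lowest threshold.
#'
#' @param x Numeric matrix (or vector) of counts.
#' @param n_bins Histogram resolution.
#' @return The threshold value; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- as.numeric(x)
  rng <- range(x)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    stopf("cannot threshold a constant image")
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), n_bins)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  breaks[k + 1]
}

# Run-based connected-component labeling, 4-connectivity. Returns an
# integer matrix of component labels (0 = background).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  # find vertical runs per column via diff on the logical matrix
  runs <- list(); nrun <- 0L
  parent <- integer()
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  run_start <- integer(); run_end <- integer(); run_col <- integer()
  for (j in seq_len(nc)) {
    colv <- mask[, j]
    if (!any(colv)) next
    d <- diff(c(FALSE, colv, FALSE))
    starts <- which(d == 1L)
    ends <- which(d == -1L) - 1L
    for (k in seq_along(starts)) {
      nrun <- nrun + 1L
      run_start[nrun] <- starts[k]
      run_end[nrun] <- ends[k]
      run_col[nrun] <- j
      parent[nrun] <- nrun
    }
  }
  if (nrun == 0L) return(lab)
  # union runs in adjacent columns whose row ranges overlap
  ord <- order(run_col, run_start)
  by_col <- split(ord, run_col[ord])
  cols <- as.integer(names(by_col))
  for (ci in seq_along(cols)[-1]) {
    if (cols[ci] - cols[ci - 1] != 1L) next
    for (a in by_col[[ci]]) {
      for (b in by_col[[ci - 1]]) {
        if (run_start[a] <= run_end[b] && run_end[a] >= run_start[b]) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
  }
  roots <- vapply(seq_len(nrun), find, integer(1))
  ids <- match(roots, sort(unique(roots)))
  for (k in seq_len(nrun)) {
    lab[run_start[k]:run_end[k], run_col[k]] <- ids[k]
  }
  lab
}

#' Segment the plant from the background
#'
#' Thresholds a reference image (by default with Otsu's method on the
#' highest-contrast frame, the dark-adapted Fm flash), removes connected
#' components below `min_object_px`, and merges the surviving components
#' into one canopy ROI.
#'
#' @param reference_image 2-D numeric matrix of counts.
#' @param cfg A [segmentation_config()].
#' @return Logical plant mask.
#' @export
segment_plant <- function(reference_image, cfg = segmentation_config()) {
  if (!is.matrix(reference_image)) stopf("reference_image must be a matrix")
  thr <- if (cfg$method == "otsu") {
    rng <- range(reference_image)
    if (diff(rng) == 0) stopf("no plant detected")
    otsu_threshold(reference_image)
  } else {
    cfg$threshold
  }
  raw <- reference_image > thr
  if (!any(raw)) stopf("no plant detected")
  lab <- label_components(raw)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= cfg$min_object_px)
  mask <- matrix(lab %in% keep & lab > 0L, nrow(raw), ncol(raw))
  if (!any(mask)) stopf("no plant detected")
  mask
}

#' Extract the canopy-mean kinetic trace from a frame stack
#'
#' Per-frame mean and SD over the mask pixels, inheriting the stack's frame
#' times and light states.
#'
#' @param stack A `frame_stack`.
#' @param mask Logical matrix, same shape as the frames, with >= 1 pixel.
#' @return An object of class `kinetic_trace`: data.frame-backed list with
#'   `times_s`, `mean_counts`, `sd_counts`, `n_pixels`, `light_state`, plus
#'   the stack's `band` labels when present.
#' @export
extract_trace <- function(stack, mask) {
  dm <- dim(stack$frames)
  if (!is.logical(mask) || any(dim(mask) != dm[1:2])) {
    stopf("mask shape does not match frames")
  }
  idx <- which(mask)
  if (length(idx) == 0) stopf("empty mask")
  nt <- dm[3]
  flat <- stack$frames
  dim(flat) <- c(dm[1] * dm[2], nt)
  sub <- flat[idx, , drop = FALSE]
  np <- length(idx)
  mu <- colMeans(sub)
  sdv <- if (np > 1) {
    sqrt(pmax(colSums(sub^2) - np * mu^2, 0) / (np - 1))
  } else {
    rep(NA_real_, nt)
  }
  tr <- structure(list(
    times_s = stack$times_s,
    mean_counts = mu,
    sd_counts = sdv,
    n_pixels = length(idx),
    light_state = stack$light_state,
    meta = stack$meta
  ), class = "kinetic_trace")
  if (!is.null(stack$band)) tr$band <- stack$band
  tr
}

#' Projected leaf area from a plant mask
#'
#' The pixel count of the segmented canopy, optionally converted to mm^2.
#'
#' @param mask Logical matrix.
#' @param px_scale mm^2 per pixel, or `NULL` for pixels only.
#' @return List with `pixels` and, when `px_scale` is given, `mm2`.
#' @export
projected_leaf_area <- function(mask, px_scale = NULL) {
  if (!is.logical(mask)) stopf("mask must be logical")
  px <- sum(mask)
  out <- list(pixels = px)
  if (!is.null(px_scale)) out$mm2 <- px * px_scale
  out
}
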